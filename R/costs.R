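#' Reference patient for dose calculation
#'
#' @param weight_kg Body weight (default 65 kg).
#' @param bsa_m2 Body surface area (default 1.72 m^2).
#' @return A `patient_profile` list.
#' @export
patient_profile <- function(weight_kg = 65, bsa_m2 = 1.72) {
  if (weight_kg <= 0 || bsa_m2 <= 0) stop("weight and BSA must be > 0")
  structure(list(weight_kg = weight_kg, bsa_m2 = bsa_m2),
            class = "patient_profile")
}

#' One drug of a regimen
#'
#' @param name Drug label.
#' @param dose Dose quantity in mg per administration (before basis
#'   scaling).
#' @param basis `"flat"` (mg as given) or `"per_m2"` (mg multiplied by
#'   body surface area).
#' @param admins_per_cycle Administrations per 21-day cycle (for daily
#'   5-FU on days 1-4 this is 4).
#' @param vial_mg Package size in mg.
#' @param vial_price Package price in USD.
#' @param max_cycles Last cycle in which the drug is given (Inf = until
#'   progression).
#' @param pap_gated Whether the tiered assistance schedule applies to this
#'   drug's payment.
#' @return A `regimen_component` list.
#' @export
regimen_component <- function(name, dose, basis = c("flat", "per_m2"),
                              admins_per_cycle = 1, vial_mg, vial_price,
                              max_cycles = Inf, pap_gated = FALSE) {
  basis <- match.arg(basis)
  if (dose < 0 || vial_mg <= 0 || vial_price < 0 || admins_per_cycle < 1)
    stop("invalid regimen component for ", name)
  structure(list(name = name, dose = dose, basis = basis,
                 admins_per_cycle = admins_per_cycle, vial_mg = vial_mg,
                 vial_price = vial_price, max_cycles = max_cycles,
                 pap_gated = isTRUE(pap_gated)),
            class = "regimen_component")
}

#' Whole vials needed for a dose
#'
#' Vial-wastage billing: partial vials are charged as whole vials per
#' administration (no sharing between days or patients).
#'
#' @param dose_mg Administered dose in mg (>= 0).
#' @param vial_mg Vial size in mg (> 0).
#' @return Integer vial count; 0 for a zero dose.
#' @export
vials_needed <- function(dose_mg, vial_mg) {
  if (any(dose_mg < 0) || any(vial_mg <= 0)) stop("dose must be >= 0 and vial > 0")
  as.integer(ceiling(dose_mg / vial_mg))
}

.component_dose <- function(comp, profile) {
  switch(comp$basis,
         flat = comp$dose,
         per_m2 = comp$dose * profile$bsa_m2)
}

.component_cycle_cost <- function(comp, profile) {
  vials_needed(.component_dose(comp, profile), comp$vial_mg) *
    comp$admins_per_cycle * comp$vial_price
}

#' Drug acquisition cost of one treatment cycle
#'
#' Sum over components of whole-vial cost per administration times the
#' number of administrations in the cycle. Cycle caps and assistance
#' gating are applied later, in [arm_discounted_cost].
#'
#' @param regimen List of [regimen_component]s.
#' @param profile A [patient_profile].
#' @return USD per cycle.
#' @export
cycle_drug_cost <- function(regimen, profile = patient_profile()) {
  sum(vapply(regimen, .component_cycle_cost, numeric(1), profile = profile))
}

#' One-off adverse event cost
#'
#' Expected management cost of grade >= 3 events, applied once at model
#' entry: the dot product of trial incidences and unit costs.
#'
#' @param ae Data frame with columns `incidence` (in `[0,1]`) and `cost`
#'   (USD >= 0); zero rows give 0.
#' @return USD.
#' @export
ae_cost_oneoff <- function(ae) {
  if (is.null(ae) || nrow(ae) == 0) return(0)
  if (any(ae$incidence < 0 | ae$incidence > 1)) stop("incidences must be in [0,1]")
  if (any(ae$cost < 0)) stop("AE costs must be >= 0")
  sum(ae$incidence * ae$cost)
}

#' Tiered patient-assistance payment schedule
#'
#' @param tiers List of `(paid, free)` integer pairs walked in order;
#'   default is the three-tier donation scheme: 2 purchased + 2 free,
#'   2 + 25, then 1 + 3.
#' @param after Payment status once the schedule is exhausted
#'   (`"free"`, the default, or `"paid"`).
#' @return A `pap_schedule` list.
#' @export
pap_schedule <- function(tiers = list(c(2L, 2L), c(2L, 25L), c(1L, 3L)),
                         after = c("free", "paid")) {
  after <- match.arg(after)
  for (tr in tiers)
    if (length(tr) != 2 || any(tr < 0) || any(tr != floor(tr)))
      stop("each tier must be two nonnegative integers (paid, free)")
  structure(list(tiers = tiers, after = after), class = "pap_schedule")
}

#' Is a cycle paid under the assistance schedule?
#'
#' Walks the tiers in order (paid block, then free block); cycles beyond
#' the last tier follow the schedule's `after` policy.
#'
#' @param schedule A [pap_schedule].
#' @param j Cycle index (>= 1, vectorized).
#' @return Logical vector, `TRUE` where the cycle is purchased.
#' @export
pap_paid <- function(schedule, j) {
  stopifnot(inherits(schedule, "pap_schedule"))
  if (any(j < 1)) stop("cycle index must be >= 1")
  pattern <- unlist(lapply(schedule$tiers, function(tr)
    c(rep(TRUE, tr[1]), rep(FALSE, tr[2]))))
  out <- rep(schedule$after == "paid", length(j))
  inside <- j <= length(pattern)
  out[inside] <- pattern[j[inside]]
  out
}

#' Non-drug cost inputs
#'
#' @param post_progression_per_cycle Second-line cost per cycle while in
#'   the PD state (USD).
#' @param hospitalization_per_cycle Hospitalization cost per alive cycle
#'   (USD).
#' @param ae Adverse-event data frame (`name`, `incidence`, `cost`).
#' @return A `cost_inputs` list.
#' @export
cost_inputs <- function(post_progression_per_cycle = 753.49,
                        hospitalization_per_cycle = 142.10,
                        ae = NULL) {
  if (post_progression_per_cycle < 0 || hospitalization_per_cycle < 0)
    stop("costs must be >= 0")
  structure(list(post_progression_per_cycle = post_progression_per_cycle,
                 hospitalization_per_cycle = hospitalization_per_cycle,
                 ae = ae),
            class = "cost_inputs")
}

#' Discounted total cost of one arm
#'
#' Accumulates, cycle by cycle with the same start-of-cycle convention as
#' the QALY engine: drug cost weighted by PFS occupancy (respecting each
#' component's cycle cap and, when a schedule is supplied, assistance
#' gating of the gated components), hospitalization weighted by alive
#' occupancy, second-line cost weighted by PD occupancy; plus the one-off
#' adverse-event cost, undiscounted, at entry.
#'
#' @param trace A `psm_trace`.
#' @param regimen List of [regimen_component]s.
#' @param costs A [cost_inputs].
#' @param econ An [econ_params].
#' @param profile A [patient_profile].
#' @param pap Optional [pap_schedule]; `NULL` disables gating.
#' @return USD (scalar).
#' @export
arm_discounted_cost <- function(trace, regimen, costs,
                                econ = econ_params(),
                                profile = patient_profile(),
                                pap = NULL) {
  stopifnot(inherits(trace, "psm_trace"), inherits(costs, "cost_inputs"))
  w <- .cycle_weights(trace, econ)
  n <- econ$n_cycles
  cyc <- seq_len(n)
  drug <- numeric(n)
  for (comp in regimen) {
    on <- cyc <= comp$max_cycles
    if (comp$pap_gated && !is.null(pap)) on <- on & pap_paid(pap, cyc)
    drug <- drug + .component_cycle_cost(comp, profile) * on
  }
  p_pfs <- trace$p_pfs[w$idx]
  p_pd <- trace$p_pd[w$idx]
  alive <- p_pfs + p_pd
  sum(w$disc * (drug * p_pfs +
                costs$hospitalization_per_cycle * alive +
                costs$post_progression_per_cycle * p_pd)) +
    ae_cost_oneoff(costs$ae)
}
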