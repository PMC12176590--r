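# Default model configuration: first-line sugemalimab + cisplatin/5-FU vs
# chemotherapy alone for advanced ESCC, Chinese health-system perspective.
# All money in 2023 USD. Time unit of survival parameters: model cycles
# (1 cycle = 21 days).

econ:
  discount_rate: 0.05        # per year
  cycle_days: 21
  horizon_years: 10          # -> 174 cycles
  wtp: 23901.90              # USD/QALY (1.94 x 2024 per-capita GDP)

patient:
  weight_kg: 65
  bsa_m2: 1.72

utilities:
  pfs: 0.75
  pd: 0.60

costs:
  post_progression_per_cycle: 753.49   # second line: irinotecan + S-1, lump per cycle
  hospitalization_per_cycle: 142.10

drugs:
  sugemalimab:
    dose: 1200               # mg, flat, iv q3w
    basis: flat
    admins_per_cycle: 1
    vial_mg: 600
    vial_price: 1732.50
    max_cycles: 35           # 24-month maintenance cap at q3w dosing
    pap_gated: true
  cisplatin:
    dose: 80                 # mg/m2, day 1
    basis: per_m2
    admins_per_cycle: 1
    vial_mg: 30
    vial_price: 2.68
    max_cycles: 4            # induction cycles
    pap_gated: false
  fluorouracil:
    dose: 800                # mg/m2/day, days 1-4
    basis: per_m2
    admins_per_cycle: 4
    vial_mg: 250
    vial_price: 20.44
    max_cycles: 4
    pap_gated: false

arms:
  sugemalimab_chemo: [sugemalimab, cisplatin, fluorouracil]
  chemo: [cisplatin, fluorouracil]

adverse_events:              # grade >= 3, incidence >= 3%; one-off at entry
  unit_costs:
    nausea: 82.62
    anemia: 140.40
    neutropenia: 116.37
    leukopenia: 116.37
    vomiting: 82.62
    thrombocytopenia: 1523.82
    lymphopenia: 149.60
  risks:
    sugemalimab_chemo:
      nausea: 0.037
      anemia: 0.167
      neutropenia: 0.204
      leukopenia: 0.088
      vomiting: 0.051
      thrombocytopenia: 0.057
      lymphopenia: 0.045
    chemo:
      nausea: 0.049
      anemia: 0.143
      neutropenia: 0.209
      leukopenia: 0.104
      vomiting: 0.049
      thrombocytopenia: 0.044
      lymphopenia: 0.033

pap:                         # donation tiers: (purchased cycles, free cycles)
  tiers:
    - [2, 2]
    - [2, 25]
    - [1, 3]
  after: free

survival:                    # fitted extrapolation parameters, cycle units
  whole:
    sugemalimab_chemo:
      pfs: {family: loglogistic, scale: 9.06, shape: 2.15}
      os:  {family: loglogistic, scale: 20.92, shape: 1.66}
    chemo:
      pfs: {family: loglogistic, scale: 6.61, shape: 2.53}
      os:  {family: loglogistic, scale: 16.12, shape: 2.00}
  cps_lt1:
    sugemalimab_chemo:
      pfs: {family: loglogistic, scale: 7.92, shape: 2.05}
      os:  {family: weibull, rate: 0.01, shape: 1.32}
    chemo:
      pfs: {family: lognormal, meanlog: 1.80, sdlog: 0.72}
      os:  {family: lognormal, meanlog: 2.62, sdlog: 0.86}
  cps_1_10:
    sugemalimab_chemo:
      pfs: {family: loglogistic, scale: 8.21, shape: 1.82}
      os:  {family: loglogistic, scale: 18.14, shape: 1.59}
    chemo:
      pfs: {family: loglogistic, scale: 7.32, shape: 2.20}
      os:  {family: lognormal, meanlog: 2.81, sdlog: 0.83}
  cps_ge10:
    sugemalimab_chemo:
      pfs: {family: loglogistic, scale: 10.00, shape: 2.50}
      os:  {family: loglogistic, scale: 22.51, shape: 1.90}
    chemo:
      pfs: {family: loglogistic, scale: 6.62, shape: 2.54}
      os:  {family: loglogistic, scale: 14.96, shape: 1.90}

scenarios:
  whole:    {survival: whole, pap: false}
  cps_lt1:  {survival: cps_lt1, pap: false}
  cps_1_10: {survival: cps_1_10, pap: false}
  cps_ge10: {survival: cps_ge10, pap: false}
  pap:      {survival: whole, pap: true}

sensitivity:
  default_range: 0.20        # +-20% when no literature range exists
  parameters:
    - {path: drugs.sugemalimab.vial_price,  low: 1386.00, high: 2079.00, family: gamma, role: cost}
    - {path: drugs.cisplatin.vial_price,    low: 2.14,    high: 3.22,    family: gamma, role: cost}
    - {path: drugs.fluorouracil.vial_price, low: 16.35,   high: 24.53,   family: gamma, role: cost}
    - {path: costs.post_progression_per_cycle, low: 602.79, high: 904.19, family: gamma, role: cost}
    # published bounds for this row are inconsistent with its baseline;
    # +-20% used instead
    - {path: costs.hospitalization_per_cycle,  low: 113.68, high: 170.52, family: gamma, role: cost}
    - {path: adverse_events.unit_costs.nausea,           low: 66.10,   high: 99.14,   family: gamma, role: cost}
    - {path: adverse_events.unit_costs.anemia,           low: 112.32,  high: 168.48,  family: gamma, role: cost}
    - {path: adverse_events.unit_costs.neutropenia,      low: 93.10,   high: 139.64,  family: gamma, role: cost}
    - {path: adverse_events.unit_costs.leukopenia,       low: 93.10,   high: 139.64,  family: gamma, role: cost}
    - {path: adverse_events.unit_costs.vomiting,         low: 66.10,   high: 99.14,   family: gamma, role: cost}
    - {path: adverse_events.unit_costs.thrombocytopenia, low: 1219.06, high: 1828.58, family: gamma, role: cost}
    - {path: adverse_events.unit_costs.lymphopenia,      low: 119.68,  high: 179.52,  family: gamma, role: cost}
    - {path: adverse_events.risks.sugemalimab_chemo.nausea,           low: 0.0296, high: 0.0444, family: beta, role: probability}
    - {path: adverse_events.risks.sugemalimab_chemo.anemia,           low: 0.1336, high: 0.2004, family: beta, role: probability}
    - {path: adverse_events.risks.sugemalimab_chemo.neutropenia,      low: 0.1632, high: 0.2448, family: beta, role: probability}
    - {path: adverse_events.risks.sugemalimab_chemo.leukopenia,       low: 0.0704, high: 0.1056, family: beta, role: probability}
    - {path: adverse_events.risks.sugemalimab_chemo.vomiting,         low: 0.0408, high: 0.0612, family: beta, role: probability}
    - {path: adverse_events.risks.sugemalimab_chemo.thrombocytopenia, low: 0.0456, high: 0.0684, family: beta, role: probability}
    - {path: adverse_events.risks.sugemalimab_chemo.lymphopenia,      low: 0.0360, high: 0.0540, family: beta, role: probability}
    - {path: adverse_events.risks.chemo.nausea,           low: 0.0392, high: 0.0588, family: beta, role: probability}
    - {path: adverse_events.risks.chemo.anemia,           low: 0.1144, high: 0.1716, family: beta, role: probability}
    - {path: adverse_events.risks.chemo.neutropenia,      low: 0.1672, high: 0.2508, family: beta, role: probability}
    - {path: adverse_events.risks.chemo.leukopenia,       low: 0.0832, high: 0.1248, family: beta, role: probability}
    - {path: adverse_events.risks.chemo.vomiting,         low: 0.0392, high: 0.0588, family: beta, role: probability}
    - {path: adverse_events.risks.chemo.thrombocytopenia, low: 0.0352, high: 0.0528, family: beta, role: probability}
    - {path: adverse_events.risks.chemo.lymphopenia,      low: 0.0264, high: 0.0396, family: beta, role: probability}
    - {path: utilities.pfs, low: 0.60, high: 0.90, family: beta, role: utility}
    - {path: utilities.pd,  low: 0.48, high: 0.72, family: beta, role: utility}
    - {path: econ.discount_rate, low: 0.04, high: 0.06, family: beta, role: rate}

seed: 20250605
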