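Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Modelling for First-Line
    Advanced ESCC Immunochemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A config-driven partitioned survival cost-effectiveness
    pipeline comparing sugemalimab plus cisplatin/5-FU chemotherapy against
    chemotherapy alone as first-line treatment of advanced oesophageal
    squamous cell carcinoma, from the Chinese health-system perspective.
    Provides parametric survival extrapolation (six families fitted by
    maximum likelihood with AIC/BIC selection), Kaplan-Meier pseudo
    individual-patient-data reconstruction from digitized curve coordinates
    and numbers at risk, a three-state cycle model accumulating discounted
    costs and quality-adjusted life years, dosing-based drug costing with
    vial wastage and a tiered patient-assistance payment schedule, subgroup
    and price-cap analyses, and one-way plus probabilistic sensitivity
    analysis with acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    flexsurv,
    optparse
Config/testthat/edition: 3
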