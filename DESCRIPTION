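Package: gastricCEA
Title: Cost-Effectiveness of Nivolumab Plus Chemotherapy in Advanced
    Gastric and Esophageal Adenocarcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-state (progression-free, progressive disease, death)
    partitioned-survival cohort model for the cost-effectiveness of
    first-line nivolumab plus chemotherapy versus chemotherapy alone in
    advanced gastric, gastroesophageal junction and esophageal
    adenocarcinoma, from the Chinese and US perspectives. Parametric
    survival curves are built from published medians and hazard ratios or
    fitted to digitized Kaplan-Meier coordinates; a microcosting engine
    with vial-level drug rounding turns unit prices and dosing rules into
    per-cycle cost streams; discounted QALYs, costs and ICERs are
    accumulated per arm; one-way (tornado) and probabilistic sensitivity
    analyses propagate Beta- and Gamma-distributed parameter uncertainty.
    A synthetic-data module generates digitized-curve coordinate sets with
    known ground truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
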