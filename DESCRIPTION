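Package: ktdial
Title: Solute-Specific Dialysis Kt Metrics from Dialysate Balance and
    Instant Dialysate-to-Plasma Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the solute-specific Kt factor (liters of plasma
    totally cleared of a solute per dialysis session) for urea,
    creatinine, phosphorus and beta-2-microglobulin, either from whole
    spent-dialysate mass balances or from instant dialysate/plasma (D/P)
    concentration ratios multiplied by effluent volume.  Includes the
    blood-side urea kinetic reference chain (Daugirdas second-generation
    spKt/V and equilibrated eKt/V, Leypoldt standardized weekly Kt/V,
    Watson total body water, urea distribution volume from dialysate
    balance), plasma-water and hemoconcentration corrections with
    Tattersall post-dialysis rebound equilibration, a variable-volume
    two-pool kinetic simulator of dialysis sessions with cardiopulmonary
    disequilibrium for validation, cohort summary statistics (paired t,
    Pearson regression, one-way ANOVA with Scheffe post-hoc), and CSV
    session readers/writers with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), readxl, jsonlite
Config/testthat/edition: 3
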