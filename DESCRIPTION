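Package: myowork
Title: Regional Myocardial Work Estimation from Endocardial Surface Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates regional myocardial work from time-resolved
    triangulated left-ventricular endocardial surfaces and ventricular
    pressure. Implements endocardial area-change strain (RS_CT), five
    pressure- and Laplace-law-based wall stress surrogates, signed
    stress-strain loop-area work, regional work heterogeneity and
    negative-work metrics, responder stratification for cardiac
    resynchronization therapy, and a synthetic dyssynchronous-ventricle
    cohort generator with planted metric-to-outcome structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
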