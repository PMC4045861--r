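Package: screenyield
Title: Projected Yield of Diabetes and Prediabetes Screening Guidelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating how many asymptomatic adults would be
    screened, and how many cases of undiagnosed type 2 diabetes and
    undetected prediabetes would be detected, under alternative screening
    guidelines. Fits a survey-weighted polytomous (multinomial) logistic
    risk model on a lab-bearing health survey, projects individual risk
    onto a second survey that records health-care utilisation, encodes
    American Diabetes Association (ADA) and US Preventive Services Task
    Force (USPSTF) eligibility rules, and summarises expected detection
    yield, screening efficiency, visit patterns by risk stratum, and
    split-sample validation. Includes a synthetic survey generator with a
    known data-generating model so the full pipeline can be exercised and
    tested without restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
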