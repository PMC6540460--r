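Package: oscibp
Title: Oscillometric Blood Pressure Estimation with Bootstrap Confidence
    Limits and Deep-Belief-Network Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating systolic and diastolic blood pressure (SBP,
    DBP) from oscillometric waveform features with quantified per-subject
    uncertainty.  Small per-subject samples (five measurements) are augmented
    by a parametric Gaussian bootstrap; a deep belief network (a
    Gaussian-Bernoulli restricted Boltzmann machine stacked with
    Bernoulli-Bernoulli layers, pre-trained by contrastive divergence and
    fine-tuned by momentum back-propagation) regresses the features onto
    reference pressures; percentile-bootstrap confidence limits are computed
    per subject; and a statistical suite (kurtosis and skewness z tests, a
    one-sample Kolmogorov-Smirnov test with exact finite-sample critical
    values, and a Spearman rank independence test) verifies the normality and
    independence assumptions behind those limits.  Includes a synthetic
    cohort generator that emulates the study design (85 subjects, 5
    measurements, 11 features) and AAMI SP10 / BHS accuracy grading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
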