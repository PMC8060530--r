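Package: emaprofiles
Title: Latent Suicide-Risk Profiles from Sparse Ecological Momentary Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse sparse smartphone ecological momentary assessment
    (EMA) streams collected under a question turn-over design, in which only a
    small random subset of a 32-item risk questionnaire is delivered each day.
    Responses are standardised to the unit interval with worse-is-higher
    polarity, latent risk profiles are discovered with an Indian buffet process
    linear-Gaussian feature model fitted by Gibbs sampling that evaluates the
    likelihood over observed entries only, and profile prevalence is contrasted
    between two calendar periods with continuity-corrected chi-squared tests,
    percent changes and exact binomial confidence intervals. A synthetic EMA
    generator with known latent structure supports end-to-end testing when no
    patient data are available.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
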