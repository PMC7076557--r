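Package: rity
Title: Phenology Model of the European Spruce Bark Beetle
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the temperature-driven phenology of the European
    spruce bark beetle (Ips typographus) from daily minimum, mean and
    maximum air temperatures. Corrects gridded-product temperatures to
    forest-stand air and bark temperatures with published linear models,
    converts bark temperature to daily effective temperature with a
    piecewise linear/nonlinear development-rate function, and steps a
    daily engine from early March to the end of October that predicts the
    onset of spring swarming and infestation, the initiation and relative
    thermal sums of up to three filial generations and three sister
    broods under a photoperiod diapause gate, developmental stages, and
    the annual number of potential generations under MIN, AVG and MAX
    temperature scenarios. Includes the iterative start-date calibration
    that minimises the mean absolute error of predicted onset dates, a
    seeded synthetic weather generator, and gridded simulation with a
    host-species mask.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
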