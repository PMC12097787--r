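Package: gritclean
Title: Optimal Food-Cleaning Economics and Sand-Particle Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the behavioral economics of food cleaning in
    primates. Fits a marginal-value-theorem model of grit removal in
    which the fraction of sand removed saturates with cleaning time,
    estimates the cleaning inefficiency (half-saturation constant) of
    brushing and washing from efficacy assays, predicts rate-maximizing
    optimal cleaning times with Monte-Carlo uncertainty propagation,
    maps the brushing/washing strategy frontier, and quantifies
    overcleaning from behavioral bout data. Also provides sand-particle
    morphometrics (circularity, Feret diameters, grittiness fractions),
    a bout-data pipeline emitting model-ready tables, and seeded
    synthetic-data generators with a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
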