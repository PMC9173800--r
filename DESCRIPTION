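Package: ergdose
Title: Simulation and Kinship-Adjusted Association Analysis of
    Electroretinogram Components
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how full-field electroretinogram (ERG)
    waveform parameters relate to allelic dosage at a biallelic locus in a
    twin cohort.  Provides a deterministic cellular-component forward model
    of flash and 30-Hz flicker ERG responses (rod and cone photoreceptor
    PIII, ON- and OFF-bipolar PII, oscillatory potentials) with lesion
    switches emulating central retinal artery occlusion and complete
    congenital stationary night blindness; a synthetic twin-cohort generator
    with Hardy-Weinberg genotypes, Mendelian sibling sharing and a kinship
    matrix; ISCEV-style waveform processing (baseline estimation, artifact
    rejection, sweep averaging, a-/b-wave and flicker measurement, rod
    isolation by rod-saturating-background subtraction); and a spectral REML
    linear mixed model with a kinship random effect for dosage association
    testing, together with an end-to-end study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
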