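Package: abrcues
Title: Auditory Brainstem Response Quantification and Binaural Acoustic Cues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying rodent auditory brainstem responses (ABRs)
    and the acoustic cues available for binaural hearing. Provides epoch
    filtering and averaging, automatic wave I-IV peak-to-trough quantification
    with manual annotation support, descending-level audiogram threshold
    estimation, computation of the binaural interaction component (BIC) and
    its DN1 deflection across interaural time differences, and a
    head-related transfer function (HRTF) pipeline that turns two-ear swept
    sine recordings into gains, directional transfer functions, interaural
    level difference spectra and cross-correlation interaural time
    differences. A synthetic-data generator emulates click and tone ABR
    sessions and rigid-head binaural acoustic scenes so that every analysis
    stage can be exercised and validated without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
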