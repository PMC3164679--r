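Package: motorinv
Title: Phonetic Motor Invariants for Plosive Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline studying whether kinematic motor invariants of
    plosive consonants - the stereotyped closure-release (plosion) of the lips or
    tongue tip - improve automatic discrimination of bilabial (/b/, /p/) versus
    dental (/d/, /t/) stops, especially across speakers, coarticulation contexts
    and additive noise. Includes a seeded generator of synchronized synthetic
    audio and articulograph-like trajectories; kinematic landmark detection of
    plosions from articulator-distance velocity and acceleration; an audio-motor
    map (a feed-forward network regressing articulator kinematics from sliding
    Mel-spectrogram contexts); Mel-cepstral and cubic-fit motor feature
    encodings; RBF-kernel support vector classifiers with calibrated posteriors;
    and six cross-validation schemas with balanced-error-rate evaluation under
    speaker, coarticulation and noise stress.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    nnet,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
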