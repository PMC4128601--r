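Package: lungeit
Title: Functional Validation and Comparison of Lung EIT Reconstruction Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A testbed for time-difference electrical impedance tomography (EIT)
    of the ventilated lung. Provides a 2D complete-electrode-model finite element
    forward solver with the 16-electrode adjacent (Sheffield) protocol, adjoint
    conductivity and electrode-movement sensitivity matrices, a family of one-step
    regularized Gauss-Newton reconstructors and their variants (plain vs normalized
    difference data, lung-background priors, reciprocity noise weighting,
    movement-augmented noise covariance, spatial high-pass and NOSER priors,
    truncated SVD, robust-norm and total-variation iterative solvers), noise-figure
    based hyperparameter equalization, functional evaluation of image sequences
    (breath detection, tidal images, lung regions of interest, tidal volume and
    centre of ventilation), a paired statistical test battery with equivalence
    margins, and a synthetic ventilated-thorax phantom generator emulating
    PEEP/FiO2 interventions so the whole pipeline can be exercised without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
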