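Package: scotomafmri
Title: Event-Related fMRI Analysis of Lateral Modulation and Perceptual
    Filling-In
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reusable pipeline for an event-related fMRI study of lateral
    modulation and perceptual filling-in with center-surround radial
    sinusoidal gratings. Covers stimulus synthesis (radial gratings,
    Gaussian-power annular windows, meridian masks, counterphase flicker),
    experiment-design arithmetic and randomized trial sequences, a
    synthetic-data generator for ROI BOLD time series and gaze records,
    voxelwise GLM contrasts with group-level inference, trial time-course
    and time-to-peak statistics, localizer-based ROI voxel selection,
    trial-wise multivoxel pattern analysis with leave-one-run-out linear
    SVM and a group permutation null, and fixation-stability control via
    the bivariate contour ellipse area with bootstrap and
    repeated-measures tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    jsonlite,
    png,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
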