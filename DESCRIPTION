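Package: retinalflow
Title: Simulation and Analysis of Retinal Optic Flow During Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Geometric simulation of the retinal optic flow experienced by a
    walker who stabilizes gaze on the ground while moving. A fixating
    spherical pinhole eye is carried along arbitrary trajectories above a
    flat ground plane; ground points are projected to retinal polar
    coordinates frame by frame and the resulting flow field is interpolated
    onto a regular retinal grid. Planar vector-field calculus (numerical
    divergence and curl, streamline particle advection) extracts the
    flow features that encode heading relative to gaze: the curl of flow
    around the fovea, the point of maximum divergence and its ground
    back-projection, and the divergence iso-contour through the fovea.
    Also included: a focus-of-expansion tracker for head-centered flow
    fields based on particle drift on the negated field, a
    vestibulo-ocular-reflex (VOR) based calibration that recovers a fixed
    eye-tracker misalignment rotation by minimizing gaze/ground
    intersection error, and a synthetic trajectory generator (straight
    approaches, sinusoid and corkscrew paths, gait-like head oscillation,
    fixation slip and saccade perturbations) so the whole pipeline is
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
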