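Package: bonerecon
Title: Fracture-Aware 3D Reconstruction of the Proximal Femur from Biplanar Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing voxel-based 3D proximal femur shape,
    including fracture detail, from a pair of simulated Judet-view radiographs
    (-45/+45 degrees about the vertical axis). Provides synthetic femur
    phantoms, digitally reconstructed radiograph (DRR) simulation, a
    morphological auxiliary class that labels the fracture gap between bone
    fragments, a fractural augmentation engine that manufactures nondisplaced
    fracture samples from intact bone using self-affine rough surfaces, a
    compact dense-block encoder / 2D-to-3D decoder / multi-scale fusion
    reconstruction network trained with a weighted voxel-wise focal loss, and
    overlap (IoU) and surface-distance (ASSD) evaluation with stratified
    cross-validation utilities.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
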