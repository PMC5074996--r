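Package: vesselcal
Title: Contrast-Free Vessel Caliber Quantification from Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies pulmonary vessel calibers from non-contrast micro-CT
    volumes. A multi-scale Hessian (Frangi) vesselness filter produces a
    tubularity probability volume together with the per-voxel Gaussian kernel
    scale that maximizes vesselness (S_MAX). Synthetic tube phantoms with
    known diameters calibrate a linear mapping from S_MAX to physical vessel
    caliber (D_CT), validated against automated full-width-at-half-maximum
    (FWHM) diameter measurement on maximum-intensity projections and on
    contrast-enhanced 2D angiography sequences. Includes seeded flood-fill
    segmentation, 3D topological thinning to a centerline tree, forward
    projection of volumes and tree attributes, imaging-protocol arithmetic,
    and SWC/CSV/NIfTI/TIFF input and output.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    tiff,
    RNifti
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
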