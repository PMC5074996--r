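#' Imaging geometry
#'
#' @param detector_pixel detector pixel pitch in mm.
#' @param source_to_isocenter,source_to_detector distances in mm with
#'   `0 < source_to_isocenter < source_to_detector`.
#' @return An `imaging_geometry` object.
#' @export
imaging_geometry <- function(detector_pixel, source_to_isocenter,
                             source_to_detector) {
  if (detector_pixel <= 0) stop("`detector_pixel` must be positive")
  if (!(source_to_isocenter > 0 && source_to_isocenter < source_to_detector))
    stop("need 0 < source_to_isocenter < source_to_detector")
  structure(list(detector_pixel = detector_pixel,
                 source_to_isocenter = source_to_isocenter,
                 source_to_detector = source_to_detector),
            class = "imaging_geometry")
}

#' Effective isotropic voxel size of the reconstruction
#'
#' `detector_pixel * source_to_isocenter / source_to_detector` — the
#' detector pitch demagnified to the isocenter.
#'
#' @param g an [imaging_geometry()].
#' @param digits significant digits for the `formatted` element (3 by
#'   default, matching how such geometries are usually reported).
#' @return list with `mm` (exact) and `formatted` (rounded) voxel size.
#' @export
effective_voxel_size <- function(g, digits = 3) {
  stopifnot(inherits(g, "imaging_geometry"))
  v <- g$detector_pixel * g$source_to_isocenter / g$source_to_detector
  list(mm = v, formatted = signif(v, digits))
}

#' Dose protocol
#'
#' @param n_projections number of projection exposures.
#' @param exposure seconds per projection.
#' @param kerma_rate air kerma rate in mGy/s.
#' @param ld50 lethal dose LD50/30 in Gy (~7 Gy for BALB/c mice).
#' @return A `dose_protocol` object.
#' @export
dose_protocol <- function(n_projections, exposure, kerma_rate, ld50 = 7) {
  if (any(c(n_projections, exposure, kerma_rate, ld50) <= 0))
    stop("all dose protocol fields must be positive")
  structure(list(n_projections = n_projections, exposure = exposure,
                 kerma_rate = kerma_rate, ld50 = ld50),
            class = "dose_protocol")
}

#' Total delivered dose of a CT scan
#'
#' `n_projections * exposure * kerma_rate`, in mGy.
#'
#' @param p a [dose_protocol()].
#' @return dose in mGy.
#' @export
total_dose <- function(p) {
  stopifnot(inherits(p, "dose_protocol"))
  p$n_projections * p$exposure * p$kerma_rate
}

#' Dose as a percentage of the LD50/30
#'
#' @param dose_mgy dose in mGy.
#' @param ld50_gy LD50/30 in Gy.
#' @return list with `percent` (exact) and `formatted` (one decimal).
#' @export
dose_fraction_of_ld50 <- function(dose_mgy, ld50_gy) {
  if (ld50_gy <= 0) stop("`ld50_gy` must be positive")
  p <- 100 * dose_mgy / (1000 * ld50_gy)
  list(percent = p, formatted = round(p, 1))
}

#' Respiratory rate from inspiratory/expiratory times
#'
#' @param insp_ms,exp_ms inspiratory and expiratory times in ms;
#'   their sum must be positive.
#' @return breaths per minute.
#' @export
respiratory_rate <- function(insp_ms, exp_ms) {
  if (insp_ms + exp_ms <= 0) stop("breath duration must be positive")
  60000 / (insp_ms + exp_ms)
}

#' Summarize an imaging protocol configuration
#'
#' Reads a YAML protocol description (geometry, dose, ventilation) and
#' returns the derived quantities.
#'
#' @param path YAML file with fields `detector_pixel_mm`,
#'   `source_to_isocenter_mm`, `source_to_detector_mm`, `n_projections`,
#'   `exposure_s`, `kerma_rate_mgy_s`, `ld50_gy`, `insp_ms`, `exp_ms`.
#' @return list with `voxel_size_mm`, `total_dose_mgy`, `ld50_percent`,
#'   `breaths_per_min` and the raw config.
#' @export
protocol_summary <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- imaging_geometry(cfg$detector_pixel_mm, cfg$source_to_isocenter_mm,
                        cfg$source_to_detector_mm)
  p <- dose_protocol(cfg$n_projections, cfg$exposure_s, cfg$kerma_rate_mgy_s,
                     cfg$ld50_gy)
  dose <- total_dose(p)
  list(voxel_size_mm = effective_voxel_size(g)$formatted,
       total_dose_mgy = dose,
       ld50_percent = dose_fraction_of_ld50(dose, cfg$ld50_gy)$formatted,
       breaths_per_min = respiratory_rate(cfg$insp_ms, cfg$exp_ms),
       config = cfg)
}
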