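#' Oocyte detection configuration
#'
#' Thresholds applied when selecting oocytes among detected objects in a
#' whole-mount micrograph. Defaults reproduce the standard whole-mount
#' autodiametric workflow for stained cod ovary samples: size 100--1600 um,
#' grey tone < 111 (8-bit), roundness 0.8--1.0, ellipticity >= 0.91, at an
#' image resolution of 0.1803 px/um.
#'
#' Shape descriptors are defined as follows (the classical image-analysis
#' conventions; users comparing against other toolchains should audit these):
#' \itemize{
#'   \item roundness = 4 * area / (pi * major_axis^2), 1 for a circle;
#'   \item ellipticity = object area / fitted-ellipse area (pi/4 * major *
#'     minor), capped at 1 -- how well the object fills its moment ellipse;
#'   \item diameter = sqrt(major * minor), the equivalent-area diameter of
#'     the fitted ellipse.
#' }
#'
#' Boundary semantics: the size, roundness and ellipticity bounds are
#' inclusive; the grey-tone bound is strict (mean grey < \code{max_grey}).
#'
#' @param min_diameter_um,max_diameter_um accepted equivalent-diameter range
#'   (um).
#' @param max_grey 8-bit grey-tone threshold; objects must have mean grey
#'   strictly below this value (dark, stained objects on a light background).
#' @param roundness_min,roundness_max accepted roundness range.
#' @param ellipticity_min minimum accepted ellipticity.
#' @param resolution_px_per_um image resolution in pixels per micron.
#' @return An object of class \code{detection_config} (a named list).
#' @export
#' @examples
#' detection_config()
#' detection_config(min_diameter_um = 200)
detection_config <- function(min_diameter_um = 100,
                             max_diameter_um = 1600,
                             max_grey = 111,
                             roundness_min = 0.8,
                             roundness_max = 1.0,
                             ellipticity_min = 0.91,
                             resolution_px_per_um = 0.1803) {
  stopifnot(
    min_diameter_um > 0, min_diameter_um < max_diameter_um,
    roundness_min >= 0, roundness_min <= roundness_max, roundness_max <= 1,
    ellipticity_min > 0, ellipticity_min <= 1,
    max_grey > 0, max_grey <= 255,
    resolution_px_per_um > 0
  )
  structure(
    list(
      min_diameter_um = min_diameter_um,
      max_diameter_um = max_diameter_um,
      max_grey = max_grey,
      roundness_min = roundness_min,
      roundness_max = roundness_max,
      ellipticity_min = ellipticity_min,
      resolution_px_per_um = resolution_px_per_um
    ),
    class = "detection_config"
  )
}

#' Oocyte classification windows and ORC breaks
#'
#' Size windows and oocyte-ratio breaks for the ultrametric classifier.
#' Previtellogenic oocytes (PVOs) occupy the half-open window
#' [\code{pvo_min_um}, \code{dev_min_um}) um; developing oocytes
#' (vitellogenic + final maturation, VO + FOM) the closed window
#' [\code{dev_min_um}, \code{dev_max_um}] um; anything larger is counted as
#' hydrated/ovulated and excluded from the oocyte ratio. The oocyte ratio
#' category (ORC) is cut at OR <= 1, (1, 3], (3, 15] and > 15. When the
#' developing count is zero it is replaced by
#' \code{zero_denominator_substitute} so that an OR can still be computed.
#'
#' A lower developing threshold of 200 um (historically used for maturity
#' splits) can be selected via \code{dev_min_um}; 250 um is the default as it
#' gives the clearer separation between developmental stages.
#'
#' @param pvo_min_um lower counting limit (um); oocytes below this are
#'   considered lost to the staining/washing protocol.
#' @param dev_min_um PVO/developing split (um).
#' @param dev_max_um upper developing limit (um); larger oocytes are hydrated.
#' @param orc_breaks strictly increasing OR cut points between the four ORCs.
#' @param zero_denominator_substitute denominator used when no developing
#'   oocytes are present.
#' @return An object of class \code{class_bounds}.
#' @export
#' @examples
#' class_bounds()
#' class_bounds(dev_min_um = 200)
class_bounds <- function(pvo_min_um = 100,
                         dev_min_um = 250,
                         dev_max_um = 1200,
                         orc_breaks = c(1, 3, 15),
                         zero_denominator_substitute = 1) {
  stopifnot(
    pvo_min_um > 0, pvo_min_um < dev_min_um, dev_min_um < dev_max_um,
    length(orc_breaks) == 3, all(diff(orc_breaks) > 0),
    zero_denominator_substitute > 0
  )
  structure(
    list(
      pvo_min_um = pvo_min_um,
      dev_min_um = dev_min_um,
      dev_max_um = dev_max_um,
      orc_breaks = orc_breaks,
      zero_denominator_substitute = zero_denominator_substitute
    ),
    class = "class_bounds"
  )
}

#' Stereology configuration for POF counting
#'
#' Coefficients for the Weibel--Gomez particle-number estimator
#' Nv = (k / beta) * Na^(3/2) / Vv^(1/2) and the ovary-volume conversion.
#' beta = 1.38 is the shape coefficient for spherical profiles; k = 1 assumes
#' a narrow size distribution. Ovary volume is obtained from ovary weight at
#' a specific gravity of 1.0464 g/cm^3.
#'
#' @param beta dimensionless shape coefficient (>= 1; 1.38 for spheres).
#' @param k_size size-distribution coefficient (> 0).
#' @param specific_gravity_g_per_cm3 ovary specific gravity (g/cm^3).
#' @return An object of class \code{stereology_config}.
#' @export
stereology_config <- function(beta = 1.38,
                              k_size = 1.0,
                              specific_gravity_g_per_cm3 = 1.0464) {
  stopifnot(beta >= 1, k_size > 0, specific_gravity_g_per_cm3 > 0)
  structure(
    list(
      beta = beta,
      k_size = k_size,
      specific_gravity_g_per_cm3 = specific_gravity_g_per_cm3
    ),
    class = "stereology_config"
  )
}

#' Assemble, save and load a full run configuration
#'
#' Bundles the detection thresholds, classification windows, stereology
#' coefficients, OSFD smoothing/annotation parameters and the RNG seed into
#' one object that round-trips losslessly through YAML.
#'
#' @param detection a \code{\link{detection_config}}.
#' @param bounds a \code{\link{class_bounds}}.
#' @param stereology a \code{\link{stereology_config}}.
#' @param osfd named list of OSFD parameters (bin width, KDE bandwidth limits,
#'   peak/valley/tail/gap fractions); see \code{\link{annotate_cohorts}}.
#' @param seed integer RNG seed recorded with the run.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(detection = detection_config(),
                       bounds = class_bounds(),
                       stereology = stereology_config(),
                       osfd = list(
                         bin_width_um = 20,
                         bandwidth_min_um = 10,
                         bandwidth_max_um = 40,
                         prominence_frac = 0.05,
                         valley_frac = 0.5,
                         tail_frac = 0.05,
                         gap_frac = 0.10,
                         gap_occupancy_frac = 0.03
                       ),
                       seed = 1L) {
  stopifnot(inherits(detection, "detection_config"),
            inherits(bounds, "class_bounds"),
            inherits(stereology, "stereology_config"))
  structure(
    list(detection = detection, bounds = bounds, stereology = stereology,
         osfd = osfd, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config a \code{run_config} to serialize.
#' @param path file path for the YAML configuration.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(
    detection = do.call(detection_config, raw$detection),
    bounds = do.call(class_bounds, raw$bounds),
    stereology = do.call(stereology_config, raw$stereology),
    osfd = raw$osfd,
    seed = raw$seed
  )
}
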