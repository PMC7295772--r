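#' Compute the oocyte ratio of a fish
#'
#' The oocyte ratio OR is the number of previtellogenic oocytes (PVOs, below
#' the developing window) divided by the number of developing oocytes
#' (vitellogenic + final maturation, within the developing window). Oocytes
#' larger than the developing window are free hydrated/ovulated eggs; they
#' are excluded from the ratio (their proportion relative to sectioned tissue
#' varies between samples) and tallied separately. Because the PVO pool is
#' comparatively stable while the developing pool is spawned out batch by
#' batch, OR increases as a fish approaches the end of spawning.
#'
#' When a fish has no developing oocytes the zero denominator is replaced by
#' \code{bounds$zero_denominator_substitute} (default 1) so that an OR can
#' still be computed, and \code{zero_denominator_used} is set.
#'
#' @param diameters_um accepted oocyte diameters (um), already filtered to the
#'   countable range.
#' @param bounds a \code{\link{class_bounds}}.
#' @return A one-row tibble: \code{n_pvo}, \code{n_dev}, \code{n_hydrated},
#'   \code{or_value}, \code{zero_denominator_used}.
#' @export
#' @examples
#' oocyte_ratio(c(runif(300, 100, 249), runif(100, 300, 900)))
oocyte_ratio <- function(diameters_um, bounds = class_bounds()) {
  stopifnot(inherits(bounds, "class_bounds"))
  d <- diameters_um[diameters_um >= bounds$pvo_min_um]
  n_pvo <- sum(d < bounds$dev_min_um)
  n_dev <- sum(d >= bounds$dev_min_um & d <= bounds$dev_max_um)
  n_hyd <- sum(d > bounds$dev_max_um)
  if (n_pvo == 0 && n_dev == 0) {
    stop("no countable oocytes in the PVO or developing windows")
  }
  zero_used <- n_dev == 0
  denom <- if (zero_used) bounds$zero_denominator_substitute else n_dev
  tibble::tibble(
    n_pvo = n_pvo,
    n_dev = n_dev,
    n_hydrated = n_hyd,
    or_value = n_pvo / denom,
    zero_denominator_used = zero_used
  )
}

#' Assign the oocyte ratio category
#'
#' Cuts the oocyte ratio at the three breaks (default 1, 3, 15) into the four
#' spawning-stage categories: 1 = pre-/early-spawning (OR <= 1),
#' 2 = mid-spawning (1 < OR <= 3), 3 = late-spawning (3 < OR <= 15),
#' 4 = very late-/post-spawning (OR > 15). Classification is applied to the
#' unrounded OR.
#'
#' @param or_value oocyte ratio value(s), strictly positive.
#' @param bounds a \code{\link{class_bounds}}.
#' @return Integer vector of categories in 1..4.
#' @export
#' @examples
#' classify_orc(c(1, 2.5, 15, 15.1)) # 1 2 3 4
classify_orc <- function(or_value, bounds = class_bounds()) {
  stopifnot(inherits(bounds, "class_bounds"))
  if (any(!is.finite(or_value)) || any(or_value <= 0)) {
    stop("oocyte ratio must be positive and finite")
  }
  br <- bounds$orc_breaks
  as.integer(1L + (or_value > br[1]) + (or_value > br[2]) + (or_value > br[3]))
}

#' Estimate previtellogenic-oocyte fecundity
#'
#' F_PVO = OW x OR x OPD_VO: the whole-ovary PVO number from ovary weight
#' (g), the oocyte ratio, and the vitellogenic oocyte packing density
#' (oocytes per gram). The packing density can be supplied directly, or
#' through a user-supplied autodiametric power-law calibration
#' OPD = alpha * mean_vo_um^gamma. There is no default calibration: it is
#' stock-specific and must come from the user.
#'
#' @param or_value oocyte ratio (> 0), e.g. from \code{\link{oocyte_ratio}}.
#' @param ow_g whole ovary weight (g, > 0).
#' @param opd_vo_per_g vitellogenic oocyte packing density (g^-1), or NULL to
#'   use the power-law calibration.
#' @param opd_alpha,opd_gamma,mean_vo_um power-law calibration coefficients
#'   and the mean vitellogenic oocyte diameter (um).
#' @return A one-row tibble: \code{ow_g}, \code{or_value},
#'   \code{opd_vo_per_g}, \code{f_pvo}.
#' @export
#' @examples
#' pvo_fecundity(2, ow_g = 500, opd_vo_per_g = 1000) # f_pvo = 1e6
pvo_fecundity <- function(or_value, ow_g, opd_vo_per_g = NULL,
                          opd_alpha = NULL, opd_gamma = NULL,
                          mean_vo_um = NULL) {
  stopifnot(or_value > 0, ow_g > 0)
  if (is.null(opd_vo_per_g)) {
    if (is.null(opd_alpha) || is.null(opd_gamma) || is.null(mean_vo_um)) {
      stop("no oocyte packing density calibration available: supply ",
           "opd_vo_per_g, or opd_alpha/opd_gamma with mean_vo_um")
    }
    opd_vo_per_g <- opd_alpha * mean_vo_um^opd_gamma
  }
  stopifnot(opd_vo_per_g > 0)
  tibble::tibble(
    ow_g = ow_g,
    or_value = or_value,
    opd_vo_per_g = opd_vo_per_g,
    f_pvo = ow_g * or_value * opd_vo_per_g
  )
}

#' Classify every fish in a per-oocyte table
#'
#' Convenience wrapper running \code{\link{oocyte_ratio}} and
#' \code{\link{classify_orc}} per fish on a long table of accepted oocyte
#' diameters.
#'
#' @param oocytes tibble with \code{fish_id} and \code{diameter_um}; rows with
#'   a \code{passed_filter} column set to FALSE are dropped first.
#' @param bounds a \code{\link{class_bounds}}.
#' @return A tibble with one row per fish: counts, \code{or_value},
#'   \code{orc}, \code{zero_denominator_used}.
#' @export
classify_fish <- function(oocytes, bounds = class_bounds()) {
  stopifnot(is.data.frame(oocytes), "diameter_um" %in% names(oocytes))
  if (!"fish_id" %in% names(oocytes)) oocytes$fish_id <- "fish"
  if ("passed_filter" %in% names(oocytes)) {
    oocytes <- dplyr::filter(oocytes, .data$passed_filter)
  }
  oocytes |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::reframe(oocyte_ratio(.data$diameter_um, bounds)) |>
    dplyr::mutate(orc = classify_orc(.data$or_value, bounds))
}
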