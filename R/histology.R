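#' Prevalence of alpha atresia across fish
#'
#' Fraction of females with any alpha-atretic vitellogenic oocytes among all
#' females scored.
#'
#' @param samples tibble with one row per fish and an \code{n_alpha} column
#'   (count of alpha-atretic oocytes; an \code{n_normal} column may be
#'   present).
#' @return A one-row tibble: \code{n_fish}, \code{n_atretic},
#'   \code{prevalence} (fraction) and \code{percent} (to one decimal).
#' @export
#' @examples
#' atresia_prevalence(tibble::tibble(n_alpha = c(rep(0, 66), rep(1, 6))))
atresia_prevalence <- function(samples) {
  stopifnot(is.data.frame(samples), "n_alpha" %in% names(samples))
  if (nrow(samples) == 0) stop("no fish in atresia table")
  stopifnot(all(samples$n_alpha >= 0))
  n_atr <- sum(samples$n_alpha > 0)
  tibble::tibble(
    n_fish = nrow(samples),
    n_atretic = n_atr,
    prevalence = n_atr / nrow(samples),
    percent = round(100 * n_atr / nrow(samples), 1)
  )
}

#' Intensity of alpha atresia
#'
#' I_alpha = N_i / (N_i + N_j), the count of alpha-atretic oocytes over all
#' scored (atretic + normal) oocytes.
#'
#' @param n_alpha,n_normal non-negative counts (vectorized); each pair must
#'   have a positive total.
#' @return Numeric vector of intensities as fractions in [0, 1].
#' @export
#' @examples
#' atresia_intensity(3, 47) # 0.06
atresia_intensity <- function(n_alpha, n_normal) {
  stopifnot(length(n_alpha) == length(n_normal),
            all(n_alpha >= 0), all(n_normal >= 0))
  if (any(n_alpha + n_normal == 0)) {
    stop("atresia intensity undefined when no oocytes were scored")
  }
  n_alpha / (n_alpha + n_normal)
}

#' Weibel point-count estimate of POF number
#'
#' Stereological estimate of the number of post-ovulatory follicles (POFs) in
#' the whole ovary from point counts and profile counts over systematic
#' counting fields (default protocol: a 256-point grid over 10 fields of
#' 6 mm^2 each). Fields are pooled before estimation:
#' \itemize{
#'   \item volume fraction Vv = total points on POFs / total grid points;
#'   \item profile density Na = total POF profiles / total field area (mm^-2);
#'   \item number density Nv = (k / beta) * Na^(3/2) / Vv^(1/2) (mm^-3),
#'     the Weibel--Gomez estimator;
#'   \item ovary volume = ovary weight / specific gravity (cm^3);
#'   \item F_POF = Nv * ovary volume (in mm^3).
#' }
#'
#' @param points_on_pof per-field counts of grid points hitting POFs.
#' @param pof_profiles per-field POF profile counts.
#' @param ow_g whole ovary weight (g).
#' @param grid_points grid points per field (default 256).
#' @param field_area_mm2 area of one counting field (mm^2, default 6).
#' @param config a \code{\link{stereology_config}}.
#' @return A one-row tibble: \code{n_fields}, \code{vv}, \code{na_per_mm2},
#'   \code{nv_per_mm3}, \code{ovary_volume_cm3}, \code{f_pof}.
#' @export
#' @examples
#' weibel_pof_number(points_on_pof = rep(26, 10), pof_profiles = rep(3, 10),
#'                   ow_g = 104.64)
weibel_pof_number <- function(points_on_pof, pof_profiles, ow_g,
                              grid_points = 256, field_area_mm2 = 6,
                              config = stereology_config()) {
  stopifnot(inherits(config, "stereology_config"),
            length(points_on_pof) == length(pof_profiles),
            length(points_on_pof) >= 1,
            all(points_on_pof >= 0), all(points_on_pof <= grid_points),
            all(pof_profiles >= 0), ow_g > 0)
  n_fields <- length(points_on_pof)
  vv <- sum(points_on_pof) / (n_fields * grid_points)
  na <- sum(pof_profiles) / (n_fields * field_area_mm2)
  if (vv == 0 && na > 0) {
    stop("inconsistent counts: POF profiles present but no grid points hit")
  }
  nv <- if (na == 0) 0 else (config$k_size / config$beta) * na^1.5 / sqrt(vv)
  vol_cm3 <- ow_g / config$specific_gravity_g_per_cm3
  tibble::tibble(
    n_fields = n_fields,
    vv = vv,
    na_per_mm2 = na,
    nv_per_mm3 = nv,
    ovary_volume_cm3 = vol_cm3,
    f_pof = nv * vol_cm3 * 1000
  )
}

#' POF size metrics and recent-spawner flags
#'
#' Size of the largest POF cross-section (POF_XSA, assuming equatorial
#' transection), relative POF fecundities, and the recent-spawner flags
#' raised when POF_XSA strictly exceeds 0.10 or 0.11 mm^2 (larger POFs are
#' younger, so their presence marks a recent spawning event).
#'
#' @param pof_areas_mm2 measured POF cross-sectional areas for one fish
#'   (mm^2); may be empty.
#' @param bw_g whole body weight (g); must exceed \code{ow_g}.
#' @param ow_g ovary weight (g).
#' @param f_pof total POF number (e.g. from \code{\link{weibel_pof_number}}).
#' @param thresholds_mm2 the two POF_XSA size thresholds (mm^2).
#' @return A one-row tibble: \code{pof_xsa_mm2} (NA when no POFs),
#'   \code{rf_pof} = F_POF / BW, \code{rf_o_pof} = F_POF / (BW - OW),
#'   \code{recent_spawner_010}, \code{recent_spawner_011}.
#' @export
#' @examples
#' pof_size_metrics(c(0.05, 0.11, 0.09), bw_g = 10000, ow_g = 500, f_pof = 1000)
pof_size_metrics <- function(pof_areas_mm2, bw_g, ow_g, f_pof,
                             thresholds_mm2 = c(0.10, 0.11)) {
  stopifnot(all(pof_areas_mm2 > 0), ow_g >= 0, f_pof >= 0)
  if (bw_g <= ow_g) stop("body weight must exceed ovary weight")
  xsa <- if (length(pof_areas_mm2)) max(pof_areas_mm2) else NA_real_
  tibble::tibble(
    pof_xsa_mm2 = xsa,
    rf_pof = f_pof / bw_g,
    rf_o_pof = f_pof / (bw_g - ow_g),
    recent_spawner_010 = !is.na(xsa) && xsa > thresholds_mm2[1],
    recent_spawner_011 = !is.na(xsa) && xsa > thresholds_mm2[2]
  )
}

#' Per-category POF summaries
#'
#' Median POF_XSA, median relative POF fecundity and the proportion of fish
#' above each recent-spawner threshold, by oocyte ratio category.
#'
#' @param metrics tibble with one row per fish: \code{orc},
#'   \code{pof_xsa_mm2}, \code{rf_pof}, \code{recent_spawner_010},
#'   \code{recent_spawner_011}.
#' @return A tibble with one row per ORC.
#' @export
summarise_pof_by_orc <- function(metrics) {
  stopifnot(is.data.frame(metrics), "orc" %in% names(metrics))
  metrics |>
    dplyr::group_by(.data$orc) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_pof_xsa_mm2 = stats::median(.data$pof_xsa_mm2, na.rm = TRUE),
      median_rf_pof = stats::median(.data$rf_pof, na.rm = TRUE),
      prop_recent_010 = mean(.data$recent_spawner_010, na.rm = TRUE),
      prop_recent_011 = mean(.data$recent_spawner_011, na.rm = TRUE),
      .groups = "drop"
    )
}
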