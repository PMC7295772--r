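#' Build an oocyte size frequency distribution
#'
#' Bins accepted oocyte diameters into half-open bins
#' [edge, edge + bin_width) starting at \code{origin_um}, and optionally
#' attaches a smoothed density (see \code{\link{smooth_osfd}}).
#'
#' @param diameters_um numeric vector of oocyte diameters (um), all > 0.
#' @param bin_width_um histogram bin width (um), default 20.
#' @param origin_um left edge of the first bin (um), default 100 (the lower
#'   counting limit of the staining protocol).
#' @param fish_id optional label.
#' @return An object of class \code{osfd}: a list with \code{fish_id},
#'   \code{diameters_um}, \code{bin_width_um}, a \code{histogram} tibble
#'   (\code{bin_start_um}, \code{count}) and \code{density} (NULL until
#'   smoothed).
#' @export
#' @examples
#' o <- build_osfd(c(110, 115, 130, 500, 520))
#' o$histogram
build_osfd <- function(diameters_um, bin_width_um = 20, origin_um = 100,
                       fish_id = NULL) {
  if (length(diameters_um) == 0) stop("cannot build an OSFD from zero diameters")
  stopifnot(all(diameters_um > 0), bin_width_um > 0)
  edges <- seq(
    origin_um,
    origin_um + bin_width_um * (floor(max(diameters_um - origin_um) / bin_width_um) + 1),
    by = bin_width_um
  )
  idx <- findInterval(diameters_um, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  structure(
    list(
      fish_id = fish_id,
      diameters_um = diameters_um,
      bin_width_um = bin_width_um,
      histogram = tibble::tibble(
        bin_start_um = edges[-length(edges)],
        count = counts
      ),
      density = NULL
    ),
    class = "osfd"
  )
}

#' @export
print.osfd <- function(x, ...) {
  cat("<osfd", if (!is.null(x$fish_id)) paste0("'", x$fish_id, "'"), ">",
      length(x$diameters_um), "oocytes,",
      "range", round(min(x$diameters_um)), "-", round(max(x$diameters_um)),
      "um, bin", x$bin_width_um, "um",
      if (!is.null(x$density)) "(smoothed)" else "", "\n")
  invisible(x)
}

silverman_bw <- function(x, lo = 10, hi = 40) {
  bw <- stats::bw.nrd0(x)
  min(max(bw, lo), hi)
}

#' Smooth an OSFD by Gaussian kernel density estimation
#'
#' Evaluates a Gaussian KDE of the diameters on a 1-um grid over
#' [\code{grid_min_um}, \code{grid_max_um}] and renormalizes so the curve
#' integrates to one over the grid. The bandwidth defaults to Silverman's
#' rule bounded to [10, 40] um, which resolves the previtellogenic and
#' vitellogenic structure of typical samples without over-smoothing.
#'
#' @param osfd an \code{\link{build_osfd}} object (needs >= 5 diameters).
#' @param bandwidth_um Gaussian kernel bandwidth (um); NULL for the bounded
#'   Silverman default.
#' @param grid_min_um,grid_max_um density grid limits (um).
#' @return The \code{osfd} with its \code{density} slot set to a tibble
#'   (\code{diameter_um}, \code{density}) and a \code{bandwidth_um} attribute.
#' @export
smooth_osfd <- function(osfd, bandwidth_um = NULL,
                        grid_min_um = 100, grid_max_um = 1600) {
  stopifnot(inherits(osfd, "osfd"))
  x <- osfd$diameters_um
  if (length(x) < 5) stop("need at least 5 diameters to smooth an OSFD")
  if (is.null(bandwidth_um)) bandwidth_um <- silverman_bw(x)
  grid <- seq(grid_min_um, grid_max_um, by = 1)
  d <- stats::density(x, bw = bandwidth_um, from = grid_min_um,
                      to = grid_max_um, n = length(grid))
  y <- d$y
  total <- sum((y[-1] + y[-length(y)]) / 2) # trapezoid, 1-um spacing
  y <- y / total
  osfd$density <- tibble::tibble(diameter_um = grid, density = y)
  osfd$bandwidth_um <- bandwidth_um
  osfd
}

#' Mean diameter of the leading cohort
#'
#' Mean of the \code{k} largest oocyte diameters (the "leading cohort", by
#' convention the 5 most advanced oocytes). Ties at the k-th largest value
#' are resolved deterministically by stable sort order: exactly k values are
#' averaged.
#'
#' @param diameters_um numeric vector of diameters (um).
#' @param k number of leading oocytes, default 5.
#' @return The leading-cohort mean diameter (um).
#' @export
#' @examples
#' leading_cohort_mean(c(100, 200, 300, 400, 500, 600, 700)) # 500
leading_cohort_mean <- function(diameters_um, k = 5) {
  if (length(diameters_um) < k) {
    stop("need at least k = ", k, " diameters, got ", length(diameters_um))
  }
  mean(sort(diameters_um, decreasing = TRUE, method = "radix")[seq_len(k)])
}

# Local maxima of y with topographic prominence >= min_prom.
# Returns a data.frame(index, height, prominence), tallest first.
find_peaks <- function(y, min_prom = 0) {
  n <- length(y)
  if (n < 3) return(data.frame(index = integer(0), height = numeric(0), prominence = numeric(0)))
  cand <- which(diff(sign(diff(y))) < 0) + 1
  cand <- cand[y[cand] > 0]
  if (length(cand) == 0) return(data.frame(index = integer(0), height = numeric(0), prominence = numeric(0)))
  prom <- vapply(cand, function(i) {
    h <- y[i]
    # walk left/right to the nearest strictly-higher point; key saddle is the
    # minimum on the way; prominence = h - max(left saddle, right saddle)
    left <- y[seq_len(i - 1)]
    higher_l <- which(left > h)
    sad_l <- if (length(higher_l) == 0) min(y[seq_len(i)]) else min(left[(max(higher_l)):(i - 1)])
    right <- y[(i + 1):n]
    higher_r <- which(right > h)
    sad_r <- if (length(higher_r) == 0) min(y[i:n]) else min(right[seq_len(min(higher_r))])
    h - max(sad_l, sad_r)
  }, numeric(1))
  keep <- prom >= min_prom
  out <- data.frame(index = cand[keep], height = y[cand][keep], prominence = prom[keep])
  out[order(-out$height), , drop = FALSE]
}

#' Annotate cohort structure of a smoothed OSFD
#'
#' Detects density modes and derives the qualitative flags used when reading
#' spawning OSFDs: the number of cohorts in the developing window, whether
#' two vitellogenic cohorts are clearly separable (\code{bimodal_vo}),
#' whether the upper of two modes reflects oocytes budding off into final
#' maturation (\code{budding_peak}, upper mode in [850, 1200] um), and
#' whether an exceptionally long tail of oocytes trails the largest cohort
#' (\code{long_tail}).
#'
#' Modes are local maxima of the smoothed density with topographic prominence
#' at least \code{prominence_frac} of the global maximum. \code{bimodal_vo}
#' requires the valley between the two tallest developing modes to drop below
#' \code{valley_frac} times the lower of the two peak heights.
#' \code{long_tail} is raised when the fraction of non-hydrated diameters
#' lying more than two cohort standard deviations above the largest
#' developing mode exceeds \code{tail_frac}.
#'
#' @param osfd a smoothed \code{osfd} (see \code{\link{smooth_osfd}}; smoothing
#'   is applied on the fly if missing).
#' @param bounds a \code{\link{class_bounds}} giving the developing window.
#' @param prominence_frac,valley_frac,tail_frac tuning fractions (see above).
#' @return A one-row tibble: \code{n_modes}, \code{n_cohorts_dev},
#'   \code{mode_diameters_um} (list-column), \code{bimodal_vo},
#'   \code{budding_peak}, \code{long_tail}.
#' @export
annotate_cohorts <- function(osfd, bounds = class_bounds(),
                             prominence_frac = 0.05, valley_frac = 0.5,
                             tail_frac = 0.05) {
  stopifnot(inherits(osfd, "osfd"))
  if (is.null(osfd$density)) osfd <- smooth_osfd(osfd)
  g <- osfd$density$diameter_um
  y <- osfd$density$density
  pk <- find_peaks(y, min_prom = prominence_frac * max(y))
  modes <- g[pk$index]
  dev_sel <- modes >= bounds$dev_min_um & modes <= bounds$dev_max_um
  dev_modes <- modes[dev_sel]
  dev_heights <- pk$height[dev_sel]
  n_dev <- length(dev_modes)

  bimodal <- FALSE
  budding <- FALSE
  if (n_dev >= 2) {
    ord <- order(-dev_heights)[1:2]
    m2 <- sort(dev_modes[ord])
    h2 <- dev_heights[ord]
    valley <- min(y[g >= m2[1] & g <= m2[2]])
    bimodal <- valley < valley_frac * min(h2)
    budding <- m2[2] >= 850 && m2[2] <= bounds$dev_max_um
  }

  long_tail <- FALSE
  if (n_dev >= 1) {
    top_mode <- max(dev_modes)
    body <- osfd$diameters_um[osfd$diameters_um <= bounds$dev_max_um]
    # cohort SD from the left flank of the top cohort only, so the estimate
    # is not inflated by the very tail being tested
    left <- body[body <= top_mode & body > top_mode - 200]
    cohort_sd <- if (length(left) >= 10) {
      sqrt(mean((top_mode - left)^2))
    } else {
      osfd$bandwidth_um %||% 30
    }
    if (is.finite(cohort_sd) && cohort_sd > 0) {
      long_tail <- mean(body > top_mode + 2 * cohort_sd) > tail_frac
    }
  }

  tibble::tibble(
    fish_id = osfd$fish_id %||% NA_character_,
    n_modes = length(modes),
    n_cohorts_dev = n_dev,
    mode_diameters_um = list(sort(modes)),
    bimodal_vo = bimodal,
    budding_peak = budding,
    long_tail = long_tail
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate the previtellogenic--vitellogenic hiatus
#'
#' Places the gap ("hiatus") limits between the previtellogenic cohort and
#' the smallest developing cohort: the lower limit is where the smoothed
#' density first falls below \code{gap_frac} of the PVO peak height above the
#' PVO mode; the upper limit is where it last falls below \code{gap_frac} of
#' the first developing peak height below that mode. The placement is flagged
#' ambiguous when the mean density inside the candidate gap exceeds
#' \code{gap_occupancy_frac} of the PVO peak height, i.e. when oocytes occupy
#' the gap and limit placement would be subjective.
#'
#' Hiatus placement uses a sharper density than cohort counting (bandwidth
#' capped at \code{bandwidth_um}, default 20 um): kernel tails otherwise
#' bleed into a genuinely empty gap and mimic occupancy.
#'
#' @param osfd an \code{osfd} object.
#' @param bounds a \code{\link{class_bounds}}.
#' @param gap_frac density-drop fraction locating each limit.
#' @param gap_occupancy_frac mean-density fraction above which placement is
#'   declared ambiguous (calibrated on simulated contaminated-gap scenarios).
#' @param prominence_frac mode-detection prominence (fraction of global max).
#' @param bandwidth_um bandwidth cap for the hiatus-resolution density (um).
#' @return A one-row tibble: \code{hiatus_present}, \code{lower_um},
#'   \code{upper_um}, \code{width_um}, \code{ambiguous}. When no developing
#'   cohort exists, \code{hiatus_present} is FALSE and the limits are NA.
#' @export
hiatus_limits <- function(osfd, bounds = class_bounds(), gap_frac = 0.10,
                          gap_occupancy_frac = 0.03, prominence_frac = 0.05,
                          bandwidth_um = 20) {
  stopifnot(inherits(osfd, "osfd"))
  bw <- min(silverman_bw(osfd$diameters_um), bandwidth_um)
  osfd <- smooth_osfd(osfd, bandwidth_um = bw)
  g <- osfd$density$diameter_um
  y <- osfd$density$density
  pk <- find_peaks(y, min_prom = prominence_frac * max(y))
  modes <- g[pk$index]
  pvo_sel <- modes < bounds$dev_min_um
  dev_sel <- modes >= bounds$dev_min_um & modes <= bounds$dev_max_um
  none <- tibble::tibble(
    fish_id = osfd$fish_id %||% NA_character_, hiatus_present = FALSE,
    lower_um = NA_real_, upper_um = NA_real_, width_um = NA_real_,
    ambiguous = FALSE
  )
  if (!any(pvo_sel) || !any(dev_sel)) return(none)
  pvo_mode <- modes[pvo_sel][which.max(pk$height[pvo_sel])]
  pvo_h <- max(pk$height[pvo_sel])
  dev_mode <- min(modes[dev_sel])
  dev_h <- pk$height[dev_sel][which.min(modes[dev_sel])]
  if (dev_mode <= pvo_mode) return(none)

  between <- g > pvo_mode & g < dev_mode
  low_cand <- g[between & y < gap_frac * pvo_h]
  up_cand <- g[between & y < gap_frac * dev_h]
  lower <- if (length(low_cand)) min(low_cand) else NA_real_
  upper <- if (length(up_cand)) max(up_cand) else NA_real_
  if (is.na(lower) || is.na(upper) || lower >= upper) {
    none$ambiguous <- TRUE
    return(none)
  }
  inside <- y[g >= lower & g <= upper]
  ambiguous <- mean(inside) > gap_occupancy_frac * pvo_h
  tibble::tibble(
    fish_id = osfd$fish_id %||% NA_character_, hiatus_present = TRUE,
    lower_um = lower, upper_um = upper, width_um = upper - lower,
    ambiguous = ambiguous
  )
}
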