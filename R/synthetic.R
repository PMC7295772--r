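#' Specification of a simulated oocyte cohort structure
#'
#' Describes the oocyte population of one simulated fish as a mixture of
#' truncated-normal cohorts: a stable previtellogenic (PVO) pool, one or more
#' developing (vitellogenic/FOM) cohorts whose counts shrink as spawning
#' progresses, and an optional hydrated cohort above the developing window.
#' Default geometry: PVO 160 +/- 35 um; developing modes at 500 +/- 60 and
#' 800 +/- 70 um; hydrated 1300 +/- 80 um.
#'
#' \code{depletion} is the fraction of the initial developing pool still
#' present: 1 leaves the developing cohorts intact (pre-spawning), 0 removes
#' them entirely (spawned out). \code{gap_contamination} scatters a fraction
#' of the oocytes uniformly through the hiatus region between the PVO window
#' and the smallest developing mode, emulating fish whose gap limits are
#' subjective; \code{tail_fraction} scatters a fraction uniformly between the
#' largest developing mode and the top of the developing window, emulating
#' the long-tail phenotype.
#'
#' @param pvo c(mean, sd, count) for the PVO cohort (um, um, oocytes).
#' @param dev_components list of c(mean, sd, count) developing cohorts.
#' @param hydrated c(mean, sd, count) hydrated cohort.
#' @param depletion fraction of the developing pool remaining, in [0, 1].
#' @param gap_contamination fraction of all oocytes scattered into the hiatus.
#' @param tail_fraction fraction scattered into a trailing tail.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(pvo = c(mean = 160, sd = 35, count = 300),
                        dev_components = list(c(mean = 500, sd = 60, count = 180),
                                              c(mean = 800, sd = 70, count = 120)),
                        hydrated = c(mean = 1300, sd = 80, count = 0),
                        depletion = 1,
                        gap_contamination = 0,
                        tail_fraction = 0) {
  stopifnot(depletion >= 0, depletion <= 1,
            gap_contamination >= 0, gap_contamination < 1,
            tail_fraction >= 0, tail_fraction < 1,
            pvo[["count"]] >= 0, hydrated[["count"]] >= 0)
  dev_means <- vapply(dev_components, `[[`, numeric(1), "mean")
  stopifnot(all(pvo[["mean"]] < dev_means),
            all(dev_means < hydrated[["mean"]]))
  structure(
    list(pvo = pvo, dev_components = dev_components, hydrated = hydrated,
         depletion = depletion, gap_contamination = gap_contamination,
         tail_fraction = tail_fraction),
    class = "cohort_spec"
  )
}

rtruncnorm <- function(n, mean, sd, lo = 100, hi = 1600) {
  if (n == 0) return(numeric(0))
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}

#' Draw an oocyte population from a cohort specification
#'
#' Samples oocyte diameters from the truncated-normal mixture described by a
#' \code{\link{cohort_spec}}, computes the realized (ground-truth) oocyte
#' ratio using the same classification windows as the analysis
#' (\code{\link{oocyte_ratio}}), and records the intended category. Draws are
#' deterministic for a fixed seed.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param seed integer seed; NULL to use the current RNG state.
#' @param bounds a \code{\link{class_bounds}} shared with the classifier.
#' @return A list: \code{diameters} tibble (\code{diameter_um},
#'   \code{component}), \code{truth} one-row tibble from
#'   \code{\link{oocyte_ratio}} plus \code{true_orc}.
#' @export
simulate_cohort <- function(spec, seed = NULL, bounds = class_bounds()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_pvo <- round(spec$pvo[["count"]])
  dev_counts <- vapply(spec$dev_components, function(cmp) {
    round(cmp[["count"]] * spec$depletion)
  }, numeric(1))
  n_hyd <- round(spec$hydrated[["count"]])

  # each component is truncated to its own class window (a PVO is by
  # definition below the developing window, etc.), so realized class counts
  # equal component counts and the intended category is constructed exactly
  parts <- list(
    tibble::tibble(
      diameter_um = rtruncnorm(n_pvo, spec$pvo[["mean"]], spec$pvo[["sd"]],
                               lo = bounds$pvo_min_um,
                               hi = bounds$dev_min_um - 0.01),
      component = rep("pvo", n_pvo)
    )
  )
  for (i in seq_along(spec$dev_components)) {
    cmp <- spec$dev_components[[i]]
    parts <- c(parts, list(tibble::tibble(
      diameter_um = rtruncnorm(dev_counts[i], cmp[["mean"]], cmp[["sd"]],
                               lo = bounds$dev_min_um, hi = bounds$dev_max_um),
      component = rep(paste0("dev", i), dev_counts[i])
    )))
  }
  parts <- c(parts, list(tibble::tibble(
    diameter_um = rtruncnorm(n_hyd, spec$hydrated[["mean"]], spec$hydrated[["sd"]],
                             lo = bounds$dev_max_um + 0.01, hi = 1600),
    component = rep("hydrated", n_hyd)
  )))

  n_core <- n_pvo + sum(dev_counts) + n_hyd
  if (spec$gap_contamination > 0 && length(spec$dev_components) > 0) {
    n_gap <- round(spec$gap_contamination * n_core)
    lo <- bounds$dev_min_um
    hi <- min(vapply(spec$dev_components, `[[`, numeric(1), "mean"))
    parts <- c(parts, list(tibble::tibble(
      diameter_um = stats::runif(n_gap, lo, hi),
      component = rep("gap", n_gap)
    )))
  }
  if (spec$tail_fraction > 0 && length(spec$dev_components) > 0) {
    n_tail <- round(spec$tail_fraction * n_core)
    lo <- max(vapply(spec$dev_components, `[[`, numeric(1), "mean"))
    parts <- c(parts, list(tibble::tibble(
      diameter_um = stats::runif(n_tail, lo, bounds$dev_max_um),
      component = rep("tail", n_tail)
    )))
  }

  diameters <- dplyr::bind_rows(parts)
  truth <- oocyte_ratio(diameters$diameter_um, bounds)
  truth$true_orc <- classify_orc(truth$or_value, bounds)
  list(diameters = diameters, truth = truth)
}

#' Scene specification for synthetic micrograph rendering
#'
#' Geometry and intensity model of a synthetic stained whole-mount field:
#' dark anti-aliased elliptical oocytes (axis ratio drawn in [0.85, 1]) on a
#' light background, plus optional dark concave debris blobs built from
#' overlapping elongated lobes so that their roundness falls below the
#' acceptance threshold by construction.
#'
#' @param size_px image side length (square image), pixels; NA picks a side
#'   just large enough (with dart-throwing headroom) for the oocytes being
#'   rendered.
#' @param resolution_px_per_um pixels per micron (default 0.1803).
#' @param background_grey light background level (8-bit).
#' @param oocyte_grey_range dark fill range for oocytes (below the grey-tone
#'   acceptance threshold).
#' @param axis_ratio_range minor/major ratio range for rendered ellipses.
#' @param debris_count number of debris blobs per image.
#' @param allow_overlap allow oocytes to overlap (default FALSE:
#'   dart-throwing placement with a 500-attempt cap; unplaceable oocytes are
#'   returned as overflow, to be carried to the next image).
#' @param noise_sd Gaussian pixel-noise standard deviation (grey levels).
#' @return An object of class \code{scene_spec}.
#' @export
scene_spec <- function(size_px = NA,
                       resolution_px_per_um = 0.1803,
                       background_grey = 230,
                       oocyte_grey_range = c(15, 40),
                       axis_ratio_range = c(0.85, 1),
                       debris_count = 0,
                       allow_overlap = FALSE,
                       noise_sd = 2) {
  stopifnot(is.na(size_px) || size_px > 10, resolution_px_per_um > 0,
            max(oocyte_grey_range) < background_grey,
            background_grey <= 255, noise_sd >= 0)
  structure(
    list(size_px = size_px, resolution_px_per_um = resolution_px_per_um,
         background_grey = background_grey,
         oocyte_grey_range = oocyte_grey_range,
         axis_ratio_range = axis_ratio_range,
         debris_count = debris_count, allow_overlap = allow_overlap,
         noise_sd = noise_sd),
    class = "scene_spec"
  )
}

# Anti-aliased filled-ellipse patch (dark on light): coverage of each pixel
# is approximated from the signed pixel distance to the boundary. Returns
# the row/col window and the patch values; the caller assigns them, so the
# image is modified in place instead of being copied per ellipse.
ellipse_patch <- function(nrow_img, ncol_img, cx, cy, a, b, theta, grey, bg) {
  r0 <- max(1, floor(cx - a - 2)); r1 <- min(nrow_img, ceiling(cx + a + 2))
  c0 <- max(1, floor(cy - a - 2)); c1 <- min(ncol_img, ceiling(cy + a + 2))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  R <- matrix(rows, length(rows), length(cols))
  C <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  u <- cos(theta) * (R - cx) + sin(theta) * (C - cy)
  v <- -sin(theta) * (R - cx) + cos(theta) * (C - cy)
  d <- sqrt((u / a)^2 + (v / b)^2)
  gd <- sqrt((u / a^2)^2 + (v / b^2)^2)
  pxdist <- ifelse(gd > 0, (d - 1) / gd, -min(a, b))
  cov <- pmin(pmax(0.5 - pxdist, 0), 1)
  list(rows = rows, cols = cols, values = round(bg + cov * (grey - bg)))
}

#' Render a synthetic whole-mount micrograph
#'
#' Places the given oocyte diameters as non-overlapping (by default)
#' anti-aliased dark ellipses on a light background, plus debris blobs, and
#' returns both the 8-bit image and a ground-truth record per placed oocyte.
#' Oocytes that cannot be placed without overlap within 500 dart-throwing
#' attempts are returned in \code{overflow} so callers can carry them to the
#' next image.
#'
#' @param diameters_um oocyte diameters to render (um).
#' @param scene a \code{\link{scene_spec}}.
#' @param seed integer seed; NULL to use the current RNG state.
#' @return A list: \code{pixels} (integer matrix), \code{truth} tibble
#'   (\code{diameter_um}, \code{major_um}, \code{minor_um},
#'   \code{centroid_row}, \code{centroid_col}, 0-based), \code{overflow}
#'   (unplaced diameters, um).
#' @export
render_micrograph <- function(diameters_um, scene = scene_spec(), seed = NULL) {
  stopifnot(inherits(scene, "scene_spec"))
  if (!is.null(seed)) set.seed(seed)
  res <- scene$resolution_px_per_um
  n <- scene$size_px
  if (is.na(n)) {
    # side chosen so the filled area stays below ~30% (dart-throwing headroom)
    occupied <- sum(pi * (diameters_um * res / 2)^2) +
      scene$debris_count * pi * (500 * res / 2)^2 * 0.3
    n <- max(400, ceiling(sqrt(occupied / 0.30)),
             ceiling(2.2 * max(0, diameters_um) * res + 10))
  }
  img <- matrix(as.integer(scene$background_grey), n, n)

  placed <- list()
  centers <- matrix(numeric(0), 0, 3) # row, col, radius(px)
  overflow <- numeric(0)
  # large first: easier packing
  for (d_um in sort(diameters_um, decreasing = TRUE)) {
    rho <- stats::runif(1, scene$axis_ratio_range[1], scene$axis_ratio_range[2])
    major_um <- d_um / sqrt(rho)
    minor_um <- d_um * sqrt(rho)
    a <- major_um / 2 * res
    b <- minor_um / 2 * res
    theta <- stats::runif(1, 0, pi)
    margin <- a + 3
    if (2 * margin >= n) {
      overflow <- c(overflow, d_um)
      next
    }
    ok <- FALSE
    for (try in 1:500) {
      cr <- stats::runif(1, margin, n - margin)
      cc <- stats::runif(1, margin, n - margin)
      if (!scene$allow_overlap && nrow(centers) > 0) {
        dd <- sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2)
        if (any(dd < centers[, 3] + a + 2)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) {
      overflow <- c(overflow, d_um)
      next
    }
    grey <- stats::runif(1, scene$oocyte_grey_range[1], scene$oocyte_grey_range[2])
    p <- ellipse_patch(n, n, cr, cc, a, b, theta, grey, scene$background_grey)
    img[p$rows, p$cols] <- pmin(img[p$rows, p$cols], p$values)
    centers <- rbind(centers, c(cr, cc, a))
    placed <- c(placed, list(tibble::tibble(
      diameter_um = d_um, major_um = major_um, minor_um = minor_um,
      theta = theta, centroid_row = cr - 1, centroid_col = cc - 1
    )))
  }

  # debris: two overlapping elongated dark lobes -> concave, low roundness
  for (k in seq_len(scene$debris_count)) {
    len_um <- stats::runif(1, 300, 700)
    a <- len_um / 2 * res
    b <- a * stats::runif(1, 0.12, 0.2)
    margin <- a + 3
    cr <- stats::runif(1, margin, n - margin)
    cc <- stats::runif(1, margin, n - margin)
    if (!scene$allow_overlap && nrow(centers) > 0) {
      dd <- sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2)
      if (any(dd < centers[, 3] + a + 2)) next
    }
    th <- stats::runif(1, 0, pi)
    grey <- stats::runif(1, 40, 90)
    p <- ellipse_patch(n, n, cr, cc, a, b, th, grey, scene$background_grey)
    img[p$rows, p$cols] <- pmin(img[p$rows, p$cols], p$values)
    off <- a * 0.45
    p <- ellipse_patch(n, n, cr + off * sin(th), cc + off * cos(th),
                       a * 0.8, b, th + stats::runif(1, 0.5, 1.1), grey,
                       scene$background_grey)
    img[p$rows, p$cols] <- pmin(img[p$rows, p$cols], p$values)
    centers <- rbind(centers, c(cr, cc, a * 1.3))
  }

  if (scene$noise_sd > 0) {
    img <- img + matrix(round(stats::rnorm(n * n, 0, scene$noise_sd)), n, n)
    img <- pmin(pmax(img, 0L), 255L)
  }
  storage.mode(img) <- "integer"
  truth <- if (length(placed)) dplyr::bind_rows(placed) else
    tibble::tibble(diameter_um = numeric(0), major_um = numeric(0),
                   minor_um = numeric(0), theta = numeric(0),
                   centroid_row = numeric(0), centroid_col = numeric(0))
  list(pixels = img, truth = truth, overflow = overflow)
}

#' Render all micrographs for one fish
#'
#' Splits a fish's oocytes across \code{n_micrographs} images (emulating the
#' three-micrograph sampling protocol); oocytes that do not fit an image are
#' carried forward, with extra images appended if needed.
#'
#' @param diameters_um the fish's oocyte diameters (um).
#' @param scene a \code{\link{scene_spec}}.
#' @param n_micrographs target number of micrographs.
#' @param seed integer seed.
#' @param max_extra maximum number of overflow images appended.
#' @return A list of \code{\link{render_micrograph}} results, one per image.
#' @export
render_fish_micrographs <- function(diameters_um, scene = scene_spec(),
                                    n_micrographs = 3, seed = NULL,
                                    max_extra = 3) {
  if (!is.null(seed)) set.seed(seed)
  queue <- sample(diameters_um)
  chunk <- ceiling(length(queue) / n_micrographs)
  images <- list()
  carried <- numeric(0)
  for (i in seq_len(n_micrographs + max_extra)) {
    if (i <= n_micrographs) {
      take <- utils::head(queue, chunk)
      queue <- utils::tail(queue, -length(take))
    } else {
      take <- numeric(0)
    }
    batch <- c(carried, take)
    if (length(batch) == 0 && i > n_micrographs) break
    out <- render_micrograph(batch, scene)
    carried <- out$overflow
    images <- c(images, list(out))
    if (i >= n_micrographs && length(carried) == 0 && length(queue) == 0) break
  }
  images
}

stage_defaults <- function() {
  # per-ORC simulation targets: OR mid-range, hydrated fraction, GSI and
  # condition medians encoding the capital-breeder energy drawdown
  tibble::tibble(
    stage = 1:4,
    target_or = c(0.5, 2, 8, 30),
    hydrated_frac = c(0.03, 0.08, 0.05, 0.02),
    gsi_median = c(12, 7, 3.5, 1.5),
    csw_median = c(1.05, 1.0, 0.95, 0.9),
    p_new_pof = c(0.34, 0.25, 0.12, 0.02),
    pof_profiles_per_field = c(2, 4, 5, 3),
    p_atresia = c(0.28, 0.06, 0, 0)
  )
}

#' Simulate a full spawning study
#'
#' Generates a ground-truthed multi-fish dataset emulating a spawning-season
#' sampling program: per-fish oocyte diameters along a vitellogenic-depletion
#' trajectory (stable PVO pool, shrinking developing pool, occasional
#' hydrated cohort), biometry with a capital-breeder energy drawdown (GSI and
#' somatic condition declining with stage), and human-scored histology tables
#' (POF point counts/profile areas with an inverted-U POF-number pattern, and
#' alpha-atresia counts concentrated in early-spawning fish).
#'
#' Stage targets (oocyte-ratio mid-values 0.5/2/8/30, hydrated fractions,
#' GSI/condition medians, POF and atresia rates) are fixed defaults chosen to
#' emulate a Northeast-Arctic cod spawning study; see the methods vignette.
#'
#' @param n_fish number of fish (allocated round-robin across the 4 stages).
#' @param n_oocytes oocytes drawn per fish (multinomial across windows).
#' @param seed integer seed for the whole study.
#' @param bounds a \code{\link{class_bounds}}.
#' @param biometry_cv lognormal coefficient of variation applied to somatic
#'   weight around the allometric expectation.
#' @return A list of tibbles: \code{fish} (biometry + stage truth),
#'   \code{oocytes} (long per-oocyte table), \code{atresia},
#'   \code{pof_fields}, \code{pof_areas}; plus \code{stage_table}.
#' @export
simulate_study <- function(n_fish = 72, n_oocytes = 400, seed = 1,
                           bounds = class_bounds(), biometry_cv = 0.08) {
  set.seed(seed)
  st <- stage_defaults()
  stages <- rep(st$stage, length.out = n_fish)

  fish <- vector("list", n_fish)
  oocytes <- vector("list", n_fish)
  atresia <- vector("list", n_fish)
  pof_fields <- vector("list", n_fish)
  pof_areas <- vector("list", n_fish)

  for (i in seq_len(n_fish)) {
    s <- st[st$stage == stages[i], ]
    id <- sprintf("fish%03d", i)

    # oocyte mixture: multinomial over pvo/dev/hydrated at the stage's target OR
    or_t <- s$target_or * exp(stats::rnorm(1, 0, 0.1))
    p_hyd <- s$hydrated_frac
    p_dev <- (1 - p_hyd) / (1 + or_t)
    p_pvo <- 1 - p_hyd - p_dev
    counts <- stats::rmultinom(1, n_oocytes, c(p_pvo, p_dev, p_hyd))[, 1]
    # split the developing pool across two modes; late stages keep one
    w2 <- if (stages[i] <= 2) 0.4 else 0
    n_dev2 <- stats::rbinom(1, counts[2], w2)
    d <- c(
      rtruncnorm(counts[1], 160, 35, lo = 100, hi = 249.9),
      rtruncnorm(counts[2] - n_dev2, if (stages[i] >= 3) 800 else 500, 60,
                 lo = 250, hi = 1200),
      rtruncnorm(n_dev2, 800, 70, lo = 250, hi = 1200),
      rtruncnorm(counts[3], 1300, 80, lo = 1200.1, hi = 1600)
    )
    oocytes[[i]] <- tibble::tibble(fish_id = id, diameter_um = d)
    or_realized <- oocyte_ratio(d, bounds)$or_value
    orc_realized <- classify_orc(or_realized, bounds)

    # biometry: TL ~ stock size structure; SW from allometry with noise;
    # OW backed out of the stage GSI
    tl <- min(max(stats::rnorm(1, 96, 10), 63), 126)
    sw <- expected_sw(tl) * exp(stats::rnorm(1, 0, biometry_cv)) *
      s$csw_median
    ow <- gsi_to_ow(s$gsi_median * exp(stats::rnorm(1, 0, 0.15)), tl)
    fish[[i]] <- tibble::tibble(
      fish_id = id, stage = stages[i], target_or = or_t,
      true_or = or_realized, true_orc = orc_realized,
      tl_cm = tl, bw_g = sw + ow, ow_g = ow
    )

    # histology: atresia counts
    atretic <- stats::runif(1) < s$p_atresia
    n_scored <- 60
    n_alpha <- if (atretic) max(1, stats::rbinom(1, n_scored, stats::runif(1, 0.015, 0.083))) else 0
    atresia[[i]] <- tibble::tibble(
      fish_id = id, n_alpha = n_alpha, n_normal = n_scored - n_alpha
    )

    # POF stereology: 10 fields, profile counts Poisson at the stage rate,
    # point counts tied to profile count via a mean profile area
    lam <- s$pof_profiles_per_field
    profiles <- stats::rpois(10, lam)
    mean_area <- 0.06 # mm^2
    vv_field <- pmin(profiles * mean_area / 6, 1)
    points <- stats::rbinom(10, 256, vv_field)
    pof_fields[[i]] <- tibble::tibble(
      fish_id = id, field = 1:10,
      points_on_pof = points, pof_profiles = profiles
    )
    n_prof <- sum(profiles)
    if (n_prof > 0) {
      new_pof <- stats::runif(1) < s$p_new_pof
      areas <- stats::runif(min(n_prof, 30), 0.01, 0.095)
      if (new_pof) areas[1] <- stats::runif(1, 0.105, 0.16)
      pof_areas[[i]] <- tibble::tibble(fish_id = id, pof_area_mm2 = areas)
    }
  }

  list(
    fish = dplyr::bind_rows(fish),
    oocytes = dplyr::bind_rows(oocytes),
    atresia = dplyr::bind_rows(atresia),
    pof_fields = dplyr::bind_rows(pof_fields),
    pof_areas = dplyr::bind_rows(pof_areas),
    stage_table = st
  )
}

# invert GSI = OW / TL^3.23 * 1e4
gsi_to_ow <- function(gsi_value, tl_cm, exponent = 3.23) {
  gsi_value * tl_cm^exponent / 1e4
}
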