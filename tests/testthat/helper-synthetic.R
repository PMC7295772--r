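# Shared fixtures built in code.

# Cohort spec whose expected oocyte ratio is `or_target`: a fixed PVO pool
# over a depleting developing pool (base 600 oocytes at full retention).
spec_for_or <- function(or_target, pvo_count = 300, dev_base = 600,
                        hydrated_count = 0, ...) {
  cohort_spec(
    pvo = c(mean = 160, sd = 35, count = pvo_count),
    dev_components = list(
      c(mean = 500, sd = 60, count = dev_base * 0.6),
      c(mean = 800, sd = 70, count = dev_base * 0.4)
    ),
    hydrated = c(mean = 1300, sd = 80, count = hydrated_count),
    depletion = min(1, pvo_count / (or_target * dev_base)),
    ...
  )
}

# Run one fish through rendering -> detection -> filtering -> pooling and
# return the accepted diameters.
detect_fish_diameters <- function(diameters_um, seed,
                                  scene = scene_spec(debris_count = 1),
                                  config = detection_config()) {
  imgs <- render_fish_micrographs(diameters_um, scene, seed = seed)
  det <- dplyr::bind_rows(lapply(seq_along(imgs), function(i) {
    filter_oocytes(detect_oocytes(imgs[[i]]$pixels, config,
                                  micrograph_id = i), config)
  }))
  det$diameter_um[det$passed_filter]
}

# Match detections to ground truth by nearest centroid (px). Returns counts
# for recall/precision plus the absolute relative diameter errors of matches.
match_detections <- function(truth, detections, max_dist_px = 10) {
  det <- detections[detections$passed_filter, ]
  if (nrow(truth) == 0 || nrow(det) == 0) {
    return(list(tp = 0, fn = nrow(truth), fp = nrow(det), rel_err = numeric(0)))
  }
  used <- rep(FALSE, nrow(det))
  rel_err <- numeric(0)
  tp <- 0
  for (i in seq_len(nrow(truth))) {
    dd <- sqrt((det$centroid_row - truth$centroid_row[i])^2 +
               (det$centroid_col - truth$centroid_col[i])^2)
    dd[used] <- Inf
    j <- which.min(dd)
    if (length(j) == 1 && dd[j] <= max_dist_px) {
      used[j] <- TRUE
      tp <- tp + 1
      rel_err <- c(rel_err,
                   abs(det$diameter_um[j] - truth$diameter_um[i]) /
                     truth$diameter_um[i])
    }
  }
  list(tp = tp, fn = nrow(truth) - tp, fp = sum(!used), rel_err = rel_err)
}
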