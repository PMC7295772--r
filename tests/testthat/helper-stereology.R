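# Brute-force sphere-sectioning oracle for the Weibel number estimator.
#
# Places spheres of radius r_mm at true number density nv_true (per mm^3) by
# a Poisson process, sections them with the plane z = 0, and scores the
# section exactly as the histology protocol does: per square counting field,
# the number of profile centres inside the field and the number of points of
# a regular 16 x 16 grid falling inside any profile circle.
section_sphere_counts <- function(nv_true, r_mm, n_fields = 10,
                                  field_area_mm2 = 6, grid_side = 16) {
  side <- sqrt(field_area_mm2)
  pad <- 2 * r_mm
  lx <- n_fields * side + 2 * pad
  ly <- side + 2 * pad
  vol <- lx * ly * 2 * r_mm
  n_sph <- stats::rpois(1, nv_true * vol)
  x <- stats::runif(n_sph, 0, lx)
  y <- stats::runif(n_sph, 0, ly)
  z <- stats::runif(n_sph, -r_mm, r_mm)
  pr <- sqrt(r_mm^2 - z^2) # profile radii at the section plane

  gp <- (seq_len(grid_side) - 0.5) / grid_side * side
  points_on <- integer(n_fields)
  profiles <- integer(n_fields)
  for (f in seq_len(n_fields)) {
    x0 <- pad + (f - 1) * side
    y0 <- pad
    inside <- x >= x0 & x < x0 + side & y >= y0 & y < y0 + side
    profiles[f] <- sum(inside)
    gx <- rep(x0 + gp, each = grid_side)
    gy <- rep(y0 + gp, times = grid_side)
    near <- which(abs(x - (x0 + side / 2)) < side / 2 + r_mm &
                  abs(y - (y0 + side / 2)) < side / 2 + r_mm)
    if (length(near) == 0) next
    hit <- rep(FALSE, length(gx))
    for (s in near) {
      hit <- hit | ((gx - x[s])^2 + (gy - y[s])^2 <= pr[s]^2)
    }
    points_on[f] <- sum(hit)
  }
  list(points_on_pof = points_on, pof_profiles = profiles,
       grid_points = grid_side^2, field_area_mm2 = field_area_mm2)
}
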