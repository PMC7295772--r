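#' Fit a log-log length-weight (allometric) regression
#'
#' Ordinary least squares of ln(weight) on ln(length): W = a * TL^b. Returns
#' the fitted exponent with the half-width of its 95% confidence interval
#' (t-based, n - 2 degrees of freedom), so the lower CI limit is
#' \code{exponent - ci_half_width}.
#'
#' @param tl_cm total lengths (cm), all positive.
#' @param weight_g weights (g), all positive; same length as \code{tl_cm};
#'   use somatic weight (body minus ovary) to remove the ovary's influence
#'   during spawning.
#' @return An object of class \code{allometric_fit}: list with
#'   \code{log_intercept} (ln a), \code{exponent} (b), \code{r2},
#'   \code{ci_half_width}, \code{n} and the underlying \code{lm} fit.
#' @export
#' @examples
#' tl <- c(60, 80, 96, 110)
#' fit_allometry(tl, exp(-5.82) * tl^3.23)
fit_allometry <- function(tl_cm, weight_g) {
  stopifnot(length(tl_cm) == length(weight_g), length(tl_cm) >= 3)
  if (any(tl_cm <= 0) || any(weight_g <= 0)) {
    stop("lengths and weights must be strictly positive")
  }
  fit <- stats::lm(log(weight_g) ~ log(tl_cm))
  sm <- summary(fit)
  se <- sm$coefficients["log(tl_cm)", "Std. Error"]
  n <- length(tl_cm)
  structure(
    list(
      log_intercept = unname(stats::coef(fit)[1]),
      exponent = unname(stats::coef(fit)[2]),
      r2 = sm$r.squared,
      ci_half_width = stats::qt(0.975, df = n - 2) * se,
      n = n,
      model = fit
    ),
    class = "allometric_fit"
  )
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf(
    "<allometric_fit> W = exp(%.3f) * TL^%.3f  (n = %d, R2 = %.3f, 95%% CI half-width = %.3f)\n",
    x$log_intercept, x$exponent, x$n, x$r2, x$ci_half_width
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.allometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("log_intercept", "exponent"),
    estimate = c(x$log_intercept, x$exponent),
    conf.low = c(NA_real_, x$exponent - x$ci_half_width),
    conf.high = c(NA_real_, x$exponent + x$ci_half_width)
  )
}

#' @export
glance.allometric_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2,
    exponent = x$exponent,
    ci_half_width = x$ci_half_width,
    nobs = x$n
  )
}

#' Expected somatic weight from the allometric fit
#'
#' SW_expected = a * TL^b. Defaults are a spawning-season cod calibration
#' (a = e^-5.82, b = 3.23, somatic weight in g, length in cm); pass an
#' \code{\link{fit_allometry}} object to use a stock-specific fit.
#'
#' @param tl_cm total length (cm), vectorized.
#' @param fit optional \code{allometric_fit}; overrides \code{log_a}/\code{b}.
#' @param log_a,b default calibration coefficients (ln-intercept and slope).
#' @return Expected somatic weight (g).
#' @export
#' @examples
#' expected_sw(96) # about 7.5 kg
expected_sw <- function(tl_cm, fit = NULL, log_a = -5.82, b = 3.23) {
  stopifnot(all(tl_cm > 0))
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "allometric_fit"))
    log_a <- fit$log_intercept
    b <- fit$exponent
  }
  exp(log_a) * tl_cm^b
}

#' Gonadosomatic index
#'
#' GSI = OW / TL^exponent * 1e4, with ovary weight in g and total length in
#' cm. The default exponent 3.23 comes from the somatic length-weight fit of
#' the spawning-season cod calibration and is stock-specific: fine adjustment
#' is likely needed when reusing it across stocks or environments.
#'
#' @param ow_g ovary weight (g), >= 0, vectorized.
#' @param tl_cm total length (cm), > 0.
#' @param exponent length exponent (default 3.23).
#' @return Dimensionless index values.
#' @export
#' @examples
#' gsi(1000, 100)
gsi <- function(ow_g, tl_cm, exponent = 3.23) {
  stopifnot(all(ow_g >= 0), all(tl_cm > 0))
  ow_g / tl_cm^exponent * 1e4
}

#' Condition and gonadosomatic indices for a biometry table
#'
#' Adds to a per-fish biometry table: somatic weight \code{sw_g} = BW - OW,
#' Fulton's condition factor \code{k_fulton} = 100 BW / TL^3, its somatic
#' variant \code{k_sw} = 100 (BW - OW) / TL^3, the relative somatic condition
#' \code{c_sw} = SW_observed / SW_expected (1 when observed equals expected),
#' and \code{gsi}. Weights in g, lengths in cm; \code{c_sw} is unit-consistent
#' as long as the fit and the observations share units.
#'
#' @param biometry tibble with \code{tl_cm}, \code{bw_g}, \code{ow_g}.
#' @param fit optional \code{\link{fit_allometry}} for the expected somatic
#'   weight; defaults to the built-in calibration of \code{\link{expected_sw}}.
#' @param gsi_exponent length exponent for \code{\link{gsi}}.
#' @return The input tibble with \code{sw_g}, \code{expected_sw_g},
#'   \code{c_sw}, \code{k_fulton}, \code{k_sw}, \code{gsi} columns added.
#' @export
condition_indices <- function(biometry, fit = NULL, gsi_exponent = 3.23) {
  stopifnot(is.data.frame(biometry),
            all(c("tl_cm", "bw_g", "ow_g") %in% names(biometry)))
  if (any(biometry$tl_cm <= 0)) stop("total length must be positive")
  if (any(biometry$bw_g <= biometry$ow_g)) {
    stop("body weight must exceed ovary weight")
  }
  biometry |>
    dplyr::mutate(
      sw_g = .data$bw_g - .data$ow_g,
      expected_sw_g = expected_sw(.data$tl_cm, fit = fit),
      c_sw = .data$sw_g / .data$expected_sw_g,
      k_fulton = 100 * .data$bw_g / .data$tl_cm^3,
      k_sw = 100 * .data$sw_g / .data$tl_cm^3,
      gsi = gsi(.data$ow_g, .data$tl_cm, exponent = gsi_exponent)
    )
}
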