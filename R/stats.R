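#' Kruskal-Wallis comparison across groups
#'
#' Tie-corrected Kruskal-Wallis rank-sum test with the chi-square
#' approximation on k - 1 degrees of freedom.
#'
#' @param values numeric response.
#' @param groups grouping factor/vector aligned with \code{values}.
#' @return A one-row tibble: \code{statistic}, \code{df}, \code{p.value}.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 non-empty groups")
  if (any(table(droplevels(groups)) == 0)) stop("empty group")
  kt <- stats::kruskal.test(values, droplevels(groups))
  tibble::tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p.value = kt$p.value
  )
}

# Insert-and-absorb compact letter display from a logical "significantly
# different" matrix (TRUE = groups differ). Groups sharing a letter do not
# differ at alpha.
compact_letters <- function(diff_mat) {
  g <- rownames(diff_mat)
  sets <- list(g)
  for (i in seq_along(g)) {
    for (j in seq_along(g)) {
      if (j <= i || !isTRUE(diff_mat[i, j])) next
      new_sets <- list()
      for (s in sets) {
        if (all(c(g[i], g[j]) %in% s)) {
          new_sets <- c(new_sets, list(setdiff(s, g[i])), list(setdiff(s, g[j])))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb sets contained in another
      keep <- rep(TRUE, length(new_sets))
      for (s in seq_along(new_sets)) {
        for (t in seq_along(new_sets)) {
          if (s == t || !keep[s]) next
          contained <- all(new_sets[[s]] %in% new_sets[[t]])
          if (contained && (length(new_sets[[s]]) < length(new_sets[[t]]) || s > t)) {
            keep[s] <- FALSE
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  # stable letter order by first group appearance
  ord <- order(vapply(sets, function(s) min(match(s, g)), numeric(1)))
  sets <- sets[ord]
  letters_out <- stats::setNames(rep("", length(g)), g)
  for (s in seq_along(sets)) {
    for (m in sets[[s]]) letters_out[m] <- paste0(letters_out[m], letters[s])
  }
  letters_out
}

#' Pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment
#'
#' All k(k-1)/2 unpaired two-sided rank-sum tests, with BH step-up adjustment
#' over the family, plus a compact letter display at \code{alpha}: groups
#' sharing a letter are not significantly different. Pairs where either group
#' has fewer than 2 observations are reported as missing.
#'
#' @param values numeric response.
#' @param groups grouping vector aligned with \code{values}.
#' @param alpha significance level for the letter display.
#' @return A list of class \code{pairwise_wilcoxon}: \code{pairs} tibble
#'   (\code{group1}, \code{group2}, \code{p.value}, \code{p.adjusted}),
#'   symmetric matrix \code{p_matrix} of adjusted p-values, and
#'   \code{letters}.
#' @export
pairwise_wilcoxon_bh <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  combs <- utils::combn(lev, 2)
  raw <- apply(combs, 2, function(pr) {
    x <- values[groups == pr[1]]
    y <- values[groups == pr[2]]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  })
  adj <- stats::p.adjust(raw, method = "BH")
  pm <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  diag(pm) <- 1
  for (i in seq_len(ncol(combs))) {
    pm[combs[1, i], combs[2, i]] <- adj[i]
    pm[combs[2, i], combs[1, i]] <- adj[i]
  }
  diff_mat <- !is.na(pm) & pm < alpha
  structure(
    list(
      pairs = tibble::tibble(
        group1 = combs[1, ], group2 = combs[2, ],
        p.value = raw, p.adjusted = adj
      ),
      p_matrix = pm,
      letters = compact_letters(diff_mat),
      alpha = alpha
    ),
    class = "pairwise_wilcoxon"
  )
}

#' @export
print.pairwise_wilcoxon <- function(x, ...) {
  cat("<pairwise_wilcoxon> BH-adjusted rank-sum tests, alpha =", x$alpha, "\n")
  print(x$pairs)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for repeated measurements on the same fish
#' (e.g. leading-cohort diameters before and after ultrasonication). Exact
#' p-values are used for n <= 25 non-zero differences (when free of ties),
#' the normal approximation otherwise.
#'
#' @param before,after equal-length paired measurements.
#' @param exact_max largest n for which the exact distribution is used.
#' @return A one-row tibble: \code{statistic} (V), \code{p.value},
#'   \code{n} (non-zero differences), \code{exact}.
#' @export
wilcoxon_paired <- function(before, after, exact_max = 25) {
  stopifnot(length(before) == length(after))
  d <- after - before
  d <- d[d != 0]
  if (length(d) == 0) stop("all paired differences are zero; test degenerate")
  use_exact <- length(d) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(after, before, paired = TRUE, exact = use_exact,
                       correct = !use_exact)
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p.value = wt$p.value,
    n = length(d),
    exact = use_exact && !any(duplicated(abs(d)))
  )
}

#' Compare a metric across oocyte ratio categories
#'
#' The validation workflow: a Kruskal-Wallis test across ORCs and, when the
#' initial test is significant at \code{alpha}, pairwise Wilcoxon rank-sum
#' tests with Benjamini-Hochberg adjustment and a compact letter display.
#'
#' @param data tibble with the metric and the category column.
#' @param metric,orc column names (strings) of the response and the grouping.
#' @param alpha significance level.
#' @return An object of class \code{orc_comparison} with elements
#'   \code{metric}, \code{kruskal} (tibble), \code{pairwise}
#'   (\code{pairwise_wilcoxon} or NULL when the initial test is not
#'   significant) and \code{group_summary}.
#' @export
compare_orc_groups <- function(data, metric, orc = "orc", alpha = 0.05) {
  stopifnot(is.data.frame(data), metric %in% names(data), orc %in% names(data))
  values <- data[[metric]]
  groups <- as.factor(data[[orc]])
  kw <- kruskal_wallis(values, groups)
  pw <- if (kw$p.value < alpha) pairwise_wilcoxon_bh(values, groups, alpha) else NULL
  gs <- tibble::tibble(!!orc := groups, value = values) |>
    dplyr::group_by(.data[[orc]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$value),
      q25 = stats::quantile(.data$value, 0.25),
      q75 = stats::quantile(.data$value, 0.75),
      .groups = "drop"
    )
  if (!is.null(pw)) gs$letters <- unname(pw$letters[as.character(gs[[orc]])])
  structure(
    list(metric = metric, kruskal = kw, pairwise = pw, group_summary = gs,
         alpha = alpha),
    class = "orc_comparison"
  )
}

#' @export
print.orc_comparison <- function(x, ...) {
  cat("<orc_comparison>", x$metric, ": Kruskal-Wallis chi2 =",
      signif(x$kruskal$statistic, 4), ", df =", x$kruskal$df,
      ", p =", signif(x$kruskal$p.value, 3), "\n")
  print(x$group_summary)
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' @export
tidy.orc_comparison <- function(x, ...) {
  if (is.null(x$pairwise)) return(tibble::tibble(
    group1 = character(0), group2 = character(0),
    p.value = numeric(0), p.adjusted = numeric(0)
  ))
  x$pairwise$pairs
}

#' @export
glance.orc_comparison <- function(x, ...) {
  tibble::tibble(
    metric = x$metric,
    statistic = x$kruskal$statistic,
    df = x$kruskal$df,
    p.value = x$kruskal$p.value,
    n_groups = nrow(x$group_summary)
  )
}
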