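check_schema <- function(df, mandatory, path, checks = list()) {
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop("schema error in '", path, "': missing mandatory column(s) ",
         paste0("'", missing_cols, "'", collapse = ", "))
  }
  for (nm in names(checks)) {
    bad <- which(!checks[[nm]](df))
    if (length(bad) > 0) {
      stop("validation error in '", path, "': ", nm, " violated on data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "")
    }
  }
  df
}

#' Read a per-fish biometry table
#'
#' CSV with header; mandatory columns \code{fish_id}, \code{tl_cm},
#' \code{bw_g}, \code{ow_g}. Unknown columns are preserved; rows violating
#' the biometry invariants (positive length, body weight exceeding ovary
#' weight) are reported with their row numbers.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_biometry_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, c("fish_id", "tl_cm", "bw_g", "ow_g"), path, checks = list(
    "tl_cm > 0" = function(d) d$tl_cm > 0,
    "ow_g >= 0" = function(d) d$ow_g >= 0,
    "bw_g > ow_g" = function(d) d$bw_g > d$ow_g
  ))
}

#' Read a per-oocyte measurement table
#'
#' CSV with header; mandatory columns \code{fish_id}, \code{diameter_um};
#' optional \code{micrograph_id}, \code{passed_filter} and the shape/grey
#' descriptor columns written by \code{\link{write_oocyte_csv}}.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_oocyte_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, c("fish_id", "diameter_um"), path, checks = list(
    "diameter_um > 0" = function(d) d$diameter_um > 0
  ))
}

#' Read histology count tables
#'
#' \code{read_atresia_csv}: mandatory \code{fish_id}, \code{n_alpha},
#' \code{n_normal}. \code{read_pof_fields_csv}: one row per counting field
#' with \code{fish_id}, \code{points_on_pof}, \code{pof_profiles}.
#' \code{read_pof_areas_csv}: one row per measured POF with \code{fish_id},
#' \code{pof_area_mm2}.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_atresia_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, c("fish_id", "n_alpha", "n_normal"), path, checks = list(
    "counts >= 0" = function(d) d$n_alpha >= 0 & d$n_normal >= 0
  ))
}

#' @rdname read_atresia_csv
#' @export
read_pof_fields_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, c("fish_id", "points_on_pof", "pof_profiles"), path,
    checks = list(
      "counts >= 0" = function(d) d$points_on_pof >= 0 & d$pof_profiles >= 0
    ))
}

#' @rdname read_atresia_csv
#' @export
read_pof_areas_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, c("fish_id", "pof_area_mm2"), path, checks = list(
    "pof_area_mm2 > 0" = function(d) d$pof_area_mm2 > 0
  ))
}

#' Write a per-oocyte CSV
#'
#' Writes the standard per-oocyte interchange table (fish_id, micrograph_id,
#' diameter and shape descriptors, filter outcome).
#'
#' @param records tibble of (filtered) detection records.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_oocyte_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_oocyte_csv
#' @param tbl any result tibble (per-fish classification, metrics, ...).
#' @export
write_report_csv <- function(tbl, path) {
  drop <- vapply(tbl, is.list, logical(1))
  readr::write_csv(tbl[!drop], path)
  invisible(path)
}
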