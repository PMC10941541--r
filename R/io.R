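# Plain-text readers/writers for the pipeline's tabular artefacts.
# Expression matrices and centroids travel as TSV (regions prefixed
# "lh_"/"rh_"), cohort tables as CSV, truth objects as JSON-ready lists.

#' Read / write a wide expression table as TSV
#'
#' @param path File path.
#' @param x Wide expression tibble (`region`, `hemisphere`, gene columns).
#' @return `read_expression_tsv()` returns the tibble; the writer returns
#'   `x` invisibly.
#' @export
read_expression_tsv <- function(path) {
  rlang::check_installed("readr")
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"hemisphere" %in% names(out) && "region" %in% names(out)) {
    out <- mutate(out,
                  hemisphere = ifelse(startsWith(.data$region, "rh_"),
                                      "right", "left"),
                  .after = "region")
  }
  check_expression_df(out)
  out
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(x, path) {
  rlang::check_installed("readr")
  check_expression_df(x)
  readr::write_tsv(x, path)
  invisible(x)
}

#' Read / write parcel centroids as TSV
#'
#' @param path File path.
#' @param x Centroid tibble (`region`, `hemisphere`, `x`, `y`, `z`).
#' @export
read_centroids_tsv <- function(path) {
  rlang::check_installed("readr")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_centroids_tsv
#' @export
write_centroids_tsv <- function(x, path) {
  rlang::check_installed("readr")
  readr::write_tsv(x, path)
  invisible(x)
}
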