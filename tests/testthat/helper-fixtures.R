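# Small in-code fixtures shared across test files.

# Wide expression tibble from a regions x genes matrix (regions split evenly
# into left/right blocks).
make_expression_df <- function(m, genes = sprintf("g%03d", seq_len(ncol(m)))) {
  n <- nrow(m)
  colnames(m) <- genes
  dplyr::bind_cols(
    tibble::tibble(
      region = c(sprintf("lh_r%02d", seq_len(n / 2)),
                 sprintf("rh_r%02d", seq_len(n / 2))),
      hemisphere = rep(c("left", "right"), each = n / 2)
    ),
    tibble::as_tibble(m)
  )
}

# Exact rank-2 regional structure: two orthogonal score maps mixed into
# `n_genes` gene profiles (no noise).
make_rank2_df <- function(n_regions = 20, n_genes = 40, seed = 1) {
  set.seed(seed)
  s <- qr.Q(qr(matrix(rnorm(n_regions * 2), n_regions)))
  w <- matrix(rnorm(2 * n_genes), 2)
  make_expression_df(s %*% w)
}

# Long donor tibble from a named list of regions x genes matrices.
make_donors_long <- function(mats, genes = NULL) {
  purrr::imap(mats, function(m, d) {
    df <- make_expression_df(m, genes %||% sprintf("g%03d", seq_len(ncol(m))))
    tidyr::pivot_longer(df, cols = -c("region", "hemisphere"),
                        names_to = "gene", values_to = "expression") |>
      dplyr::mutate(donor = d, .before = 1)
  }) |>
    purrr::list_rbind()
}

`%||%` <- rlang::`%||%`
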