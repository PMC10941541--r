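# Internal helpers shared across modules.
#
# The canonical tabular layouts are:
#   * expression table: tibble with `region`, `hemisphere`, then one column per
#     gene (wide; regions are rows, as in a regions-by-genes matrix);
#   * regional map table: tibble with `region`, `hemisphere`, then one or more
#     numeric map columns;
#   * donor profiles: long tibble with `donor`, `region`, `hemisphere`, `gene`,
#     `expression`.

# Columns that are bookkeeping rather than data in wide regional tables.
REGION_COLS <- c("region", "hemisphere")

is_expression_df <- function(df) {
  is.data.frame(df) && all(REGION_COLS %in% names(df))
}

check_expression_df <- function(df, arg = "df") {
  if (!is_expression_df(df)) {
    abort(sprintf("`%s` must be a data frame with `region` and `hemisphere` columns.", arg))
  }
  if (anyDuplicated(df$region) > 0) {
    abort(sprintf("`%s` has duplicated region ids.", arg))
  }
  value_cols <- setdiff(names(df), REGION_COLS)
  vals <- as.matrix(df[value_cols])
  if (length(vals) && !all(is.finite(vals))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  invisible(df)
}

# Wide regional table -> numeric matrix (regions x value columns), keeping the
# region/hemisphere labels as attributes.
expr_matrix <- function(df) {
  value_cols <- setdiff(names(df), REGION_COLS)
  m <- as.matrix(df[value_cols])
  rownames(m) <- df$region
  attr(m, "hemisphere") <- df$hemisphere
  m
}

as_expression_tibble <- function(m, region, hemisphere) {
  if (is.null(colnames(m))) {
    colnames(m) <- sprintf("g%03d", seq_len(ncol(m)))
  }
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(region = region, hemisphere = hemisphere), out)
  out
}

gene_cols <- function(df) setdiff(names(df), REGION_COLS)

# Sample SD with the n-1 denominator, erroring on degenerate input.
zscale <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("Cannot standardise a zero-variance vector.")
  }
  (x - mean(x)) / s
}

# Derive a stream of child seeds from one integer seed, staying within the
# 32-bit integer range.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
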