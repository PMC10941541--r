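# Principal components of regional gene expression and the Tucker-congruence
# validation suite (partition stability, cross-model comparison).

#' Principal components of a regional expression matrix
#'
#' Correlation-matrix PCA of a regions-by-genes table: genes are standardised
#' across regions, the standardised matrix is decomposed by singular values,
#' loadings are scaled to equal each gene's correlation with the component,
#' and component scores are the standardised data projected on the
#' unit-norm weight vectors, then z-scaled separately per hemisphere (via
#' [scale_by_hemisphere()]) to remove the hemisphere sampling artefact.
#' Optionally the first `k` components are varimax-rotated (Kaiser
#' normalisation); rotated components are ordered by explained variance and
#' every component is oriented so its largest-magnitude loading is positive
#' (direction is otherwise arbitrary).
#'
#' @param x Wide expression tibble (`region`, `hemisphere`, gene columns).
#' @param k Number of components to retain (default 2).
#' @param rotate Apply varimax rotation to the retained components.
#' @param scale_scores Hemisphere-scale the scores (default TRUE).
#' @return Object of class `"expression_pca"` with elements `loadings`
#'   (tibble `gene`, `C1..Ck`), `scores` (tibble `region`, `hemisphere`,
#'   `C1..Ck`), `variance_explained` (% per retained component),
#'   `eigenvalue_shares` (% for the full unrotated spectrum), `rotation`
#'   ("varimax" or "none"), `k`, `n_regions`, `n_genes`.
#' @export
fit_expression_components <- function(x, k = 2, rotate = TRUE,
                                      scale_scores = TRUE) {
  check_expression_df(x)
  m <- expr_matrix(x)
  n <- nrow(m)
  sds <- apply(m, 2, sd)
  drop <- !is.finite(sds) | sds == 0
  if (any(drop)) {
    warn(sprintf("Dropping %d zero-variance gene column(s).", sum(drop)))
    m <- m[, !drop, drop = FALSE]
  }
  p <- ncol(m)
  if (k > min(n - 1, p)) {
    abort(sprintf("`k` must be at most min(regions - 1, genes) = %d.", min(n - 1, p)))
  }
  z <- scale(m)  # genes standardised across regions (n - 1)
  sv <- svd(z)
  d_pos <- sv$d > sv$d[1] * 1e-12
  eig <- sv$d^2 / (n - 1)
  shares <- eig / p * 100

  # correlation-scale loadings and projected scores for the first k components
  load_k <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sqrt(eig[seq_len(k)]), k)
  score_k <- z %*% sv$v[, seq_len(k), drop = FALSE]
  rotation <- "none"
  if (rotate && k > 1) {
    vm <- varimax(load_k, normalize = TRUE, eps = 1e-10)
    load_k <- load_k %*% vm$rotmat
    score_k <- score_k %*% vm$rotmat
    ord <- order(colSums(load_k^2), decreasing = TRUE)
    load_k <- load_k[, ord, drop = FALSE]
    score_k <- score_k[, ord, drop = FALSE]
    rotation <- "varimax"
  }
  # canonical orientation: largest |loading| positive
  for (j in seq_len(k)) {
    if (load_k[which.max(abs(load_k[, j])), j] < 0) {
      load_k[, j] <- -load_k[, j]
      score_k[, j] <- -score_k[, j]
    }
  }
  comp_names <- paste0("C", seq_len(k))
  colnames(load_k) <- comp_names
  colnames(score_k) <- comp_names

  scores <- dplyr::bind_cols(
    tibble(region = x$region, hemisphere = x$hemisphere),
    as_tibble(score_k)
  )
  if (scale_scores) scores <- scale_by_hemisphere(scores)

  structure(
    list(
      loadings = dplyr::bind_cols(tibble(gene = colnames(m)), as_tibble(load_k)),
      scores = scores,
      variance_explained = setNames(colSums(load_k^2) / p * 100, comp_names),
      eigenvalue_shares = shares,
      rotation = rotation,
      k = k,
      n_regions = n,
      n_genes = p
    ),
    class = "expression_pca"
  )
}

#' @export
print.expression_pca <- function(x, ...) {
  cat(sprintf("<expression_pca> %d regions x %d genes, k = %d (%s)\n",
              x$n_regions, x$n_genes, x$k, x$rotation))
  cat("  variance explained (%):",
      paste(sprintf("%s %.1f", names(x$variance_explained), x$variance_explained),
            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_expression_components
#' @param x An `"expression_pca"` object.
#' @param ... Unused.
#' @export
tidy.expression_pca <- function(x, ...) {
  x$loadings |>
    tidyr::pivot_longer(-"gene", names_to = "component", values_to = "loading")
}

#' @rdname fit_expression_components
#' @export
glance.expression_pca <- function(x, ...) {
  tibble(
    n_regions = x$n_regions, n_genes = x$n_genes, k = x$k,
    rotation = x$rotation,
    variance_explained_total = sum(x$variance_explained),
    variance_explained_c1 = x$variance_explained[[1]],
    variance_explained_c2 = if (x$k >= 2) x$variance_explained[[2]] else NA_real_
  )
}

#' Tucker coefficient of factor congruence
#'
#' `phi = sum(a * b) / sqrt(sum(a^2) * sum(b^2))`: the cosine similarity of
#' two loading vectors, scale-invariant and in \[-1, 1\].
#'
#' @param a,b Numeric loading vectors of equal length.
#' @return The congruence coefficient.
#' @examples
#' congruence_coefficient(c(1, 2, 3), c(3, 2, 1))  # 10/14
#' @export
congruence_coefficient <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1) {
    abort("`a` and `b` must be non-empty vectors of equal length.")
  }
  na <- sum(a^2)
  nb <- sum(b^2)
  if (na == 0 || nb == 0) abort("Congruence is undefined for a zero vector.")
  sum(a * b) / sqrt(na * nb)
}

#' Partition stability of expression components
#'
#' Repeatedly splits the regions into `n_folds` random near-equal partitions
#' (`n_reps` times). Each partition in turn plays the small set, with the
#' union of the remaining partitions as the large set; unrotated components
#' are fitted to both (genes standardised within each set) and the absolute
#' congruence of matching component indices is recorded for the first `k`
#' components, giving `n_folds * n_reps` train/test evaluations.
#'
#' @param x Wide expression tibble.
#' @param n_folds Partitions per repetition (default 5).
#' @param n_reps Repetitions (default 50).
#' @param k Components compared (default 10; truncated with a warning for
#'   folds too small to support it).
#' @param seed Integer seed.
#' @return Object of class `"congruence_report"`: a tibble `rep`, `fold`,
#'   `component`, `abs_phi` with attribute `context = "partition-fold"`.
#' @export
partition_stability <- function(x, n_folds = 5, n_reps = 50, k = 10, seed = 1) {
  check_expression_df(x)
  n <- nrow(x)
  if (n < n_folds * 2) abort("Need at least 2 regions per fold.")
  m <- expr_matrix(x)

  res <- with_seed(seed, {
    rows <- vector("list", n_reps * n_folds)
    idx <- 0L
    for (r in seq_len(n_reps)) {
      fold_id <- sample(rep_len(seq_len(n_folds), n))
      for (f in seq_len(n_folds)) {
        small <- m[fold_id == f, , drop = FALSE]
        large <- m[fold_id != f, , drop = FALSE]
        k_eff <- min(k, nrow(small) - 1, nrow(large) - 1)
        if (k_eff < k) {
          warn(sprintf("Fold with %d regions: comparing only %d components.",
                       nrow(small), k_eff))
        }
        la <- unrotated_loadings(small, k_eff)
        lb <- unrotated_loadings(large, k_eff)
        # components beyond the numerical rank of either set carry no signal
        phi <- vapply(seq_len(k_eff), function(j) {
          if (sum(la[, j]^2) < 1e-16 || sum(lb[, j]^2) < 1e-16) {
            return(NA_real_)
          }
          abs(congruence_coefficient(la[, j], lb[, j]))
        }, numeric(1))
        idx <- idx + 1L
        rows[[idx]] <- tibble(rep = r, fold = f,
                              component = seq_len(k_eff), abs_phi = phi)
      }
    }
    list_rbind(rows)
  })
  structure(res, class = c("congruence_report", class(res)),
            context = "partition-fold")
}

# Unrotated correlation-PCA loadings of a raw (sub)matrix; genes standardised
# within the given set of regions, zero-variance genes dropped silently.
unrotated_loadings <- function(m, k) {
  sds <- apply(m, 2, sd)
  keep <- is.finite(sds) & sds > 0
  full <- matrix(0, ncol(m), k)
  z <- scale(m[, keep, drop = FALSE])
  sv <- svd(z, nu = 0, nv = k)
  eig <- (sv$d^2 / (nrow(m) - 1))[seq_len(k)]
  full[keep, ] <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sqrt(eig), k)
  full
}

#' Summarise a congruence report
#'
#' @param object A `"congruence_report"`.
#' @param ... Unused.
#' @return Tibble with per-component mean and SD of the absolute congruence
#'   and the number of evaluations.
#' @export
summary.congruence_report <- function(object, ...) {
  object |>
    group_by(.data$component) |>
    summarise(mean_abs_phi = mean(.data$abs_phi),
              sd_abs_phi = sd(.data$abs_phi),
              n = dplyr::n(), .groups = "drop")
}

#' Congruence between two component models
#'
#' Computes the absolute-congruence matrix between the loading columns of
#' two fitted component models on a matched gene set and finds the pairing
#' of components that maximises the total absolute congruence (exhaustive
#' over permutations for up to 6 components, greedy beyond), so that e.g. a
#' second component of one model pairing with the third of the other is
#' representable.
#'
#' @param a,b `"expression_pca"` objects.
#' @param genes Gene ids to match on; defaults to the intersection.
#' @return List with `phi_matrix` (|phi|, rows = components of `a`),
#'   `assignment` (tibble `component_a`, `component_b`, `abs_phi`) and
#'   `n_genes`.
#' @export
cross_model_congruence <- function(a, b, genes = NULL) {
  stopifnot(inherits(a, "expression_pca"), inherits(b, "expression_pca"))
  if (is.null(genes)) genes <- intersect(a$loadings$gene, b$loadings$gene)
  if (length(genes) < 2) abort("Fewer than 2 matched genes between the models.")
  la <- as.matrix(a$loadings[match(genes, a$loadings$gene), -1])
  lb <- as.matrix(b$loadings[match(genes, b$loadings$gene), -1])
  ka <- ncol(la)
  kb <- ncol(lb)
  phi <- matrix(0, ka, kb, dimnames = list(colnames(la), colnames(lb)))
  for (i in seq_len(ka)) {
    for (j in seq_len(kb)) {
      phi[i, j] <- abs(congruence_coefficient(la[, i], lb[, j]))
    }
  }
  k <- min(ka, kb)
  if (k <= 6) {
    perms <- permutations_of(seq_len(kb), k)
    best <- NULL
    best_total <- -Inf
    for (pp in perms) {
      total <- sum(phi[cbind(seq_len(k), pp)])
      if (total > best_total + 1e-15) {
        best_total <- total
        best <- pp
      }
    }
    assign_b <- best
  } else {
    assign_b <- integer(k)
    taken <- rep(FALSE, kb)
    for (i in seq_len(k)) {
      j <- which(!taken)[which.max(phi[i, !taken])]
      assign_b[i] <- j
      taken[j] <- TRUE
    }
  }
  list(
    phi_matrix = phi,
    assignment = tibble(
      component_a = seq_len(k),
      component_b = assign_b,
      abs_phi = phi[cbind(seq_len(k), assign_b)]
    ),
    n_genes = length(genes)
  )
}

# All ordered selections of `k` elements from `v` (k! * choose(n, k) lists).
permutations_of <- function(v, k) {
  if (k == 1) return(as.list(v))
  out <- list()
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i], k - 1)
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}
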