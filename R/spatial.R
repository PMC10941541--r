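# Map-level association tests between regional maps, with parametric and
# spin-permutation p-values. The spin null applies a uniform random 3D
# rotation to one hemisphere's parcel centroids (and its sagittal mirror to
# the other hemisphere) and rebuilds a region-to-region bijection by greedy
# nearest-centroid matching, preserving each map's value multiset and its
# spatial autocorrelation.

#' Spin permutations of a spherical parcellation
#'
#' Generates `n_perm` hemisphere-preserving permutations of the regions. Per
#' permutation a uniform random rotation (normalised quaternion) is applied
#' to the left-hemisphere centroids and its mirror through the sagittal
#' plane to the right-hemisphere centroids; each original region is then
#' assigned the nearest unassigned rotated region, visiting regions in
#' random order (the documented tie-break for the assignment step).
#'
#' @param parcellation Tibble `region`, `hemisphere`, `x`, `y`, `z` with
#'   unit-norm centroids (e.g. from [simulate_sphere_parcellation()]).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; a fixed seed gives an identical permutation
#'   set.
#' @return Object of class `"spin_perms"`: integer matrix `n_perm` x
#'   `n_regions`, each row a bijection of region indices (regions stay
#'   within hemisphere), with the parcellation in attributes.
#' @export
spin_permutations <- function(parcellation, n_perm = 1000, seed = 1) {
  req <- c("region", "hemisphere", "x", "y", "z")
  if (!all(req %in% names(parcellation))) {
    abort("`parcellation` needs columns region, hemisphere, x, y, z.")
  }
  xyz <- as.matrix(parcellation[c("x", "y", "z")])
  norms <- sqrt(rowSums(xyz^2))
  if (any(abs(norms - 1) > 1e-6)) abort("Centroids must have unit norm.")
  for (h in unique(parcellation$hemisphere)) {
    sub <- xyz[parcellation$hemisphere == h, , drop = FALSE]
    d <- as.matrix(stats::dist(sub))
    diag(d) <- Inf
    if (min(d) < 1e-9) abort("Duplicate centroids make the assignment ambiguous.")
    if (nrow(sub) < 3) abort("Need at least 3 regions per hemisphere.")
  }
  hemis <- unique(parcellation$hemisphere)
  mirror <- diag(c(-1, 1, 1))

  perms <- with_seed(seed, {
    out <- matrix(NA_integer_, n_perm, nrow(parcellation))
    for (i in seq_len(n_perm)) {
      rot <- quaternion_rotation(rnorm(4))
      for (h in hemis) {
        idx <- which(parcellation$hemisphere == h)
        r_h <- if (h == hemis[1]) rot else mirror %*% rot %*% mirror
        rotated <- xyz[idx, , drop = FALSE] %*% t(r_h)
        out[i, idx] <- idx[greedy_assignment(xyz[idx, , drop = FALSE], rotated,
                                             sample.int(length(idx)))]
      }
    }
    out
  })
  structure(perms, class = "spin_perms",
            parcellation = parcellation, seed = seed)
}

# Rotation matrix from an (unnormalised) quaternion; uniform on SO(3) when
# the components are iid standard normal.
quaternion_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}

# For each original centroid (visited in `order`), pick the nearest
# still-unassigned rotated centroid. Returns, per original position, the
# index of the rotated region assigned to it.
greedy_assignment <- function(original, rotated, order) {
  n <- nrow(original)
  assign_to <- integer(n)
  taken <- rep(FALSE, n)
  d2 <- outer(rowSums(original^2), rowSums(rotated^2), "+") -
    2 * tcrossprod(original, rotated)
  for (i in order) {
    free <- which(!taken)
    j <- free[which.min(d2[i, free])]
    assign_to[i] <- j
    taken[j] <- TRUE
  }
  assign_to
}

#' @export
print.spin_perms <- function(x, ...) {
  cat(sprintf("<spin_perms> %d permutations of %d regions (seed %s)\n",
              nrow(x), ncol(x), attr(x, "seed")))
  invisible(x)
}

#' Spatial association between two regional maps
#'
#' Tests the association between two aligned regional maps with both a
#' parametric p-value and a spin-permutation p-value. Forms:
#' * `"linear"` — Pearson correlation of `map_a` with `map_b`;
#' * `"absolute"` — Pearson correlation of `|map_a|` with `map_b` (the
#'   balance test on absolute component scores);
#' * `"quadratic"` — least squares `map_b ~ map_a + map_a^2`, reporting the
#'   quadratic coefficient.
#' The spin null applies each permutation to `map_a` only (the
#' expression/predictor side), recomputes the statistic, and uses the
#' two-sided `(1 + #{|null| >= |observed|}) / (1 + n_perm)` estimator, which
#' can never return 0.
#'
#' @param map_a,map_b Numeric vectors aligned to the same region order (no
#'   missing values). `map_a` is the side that is permuted.
#' @param perms A `"spin_perms"` matrix whose columns match the region
#'   order, or NULL to skip the spin p-value.
#' @param form `"linear"`, `"absolute"` or `"quadratic"`.
#' @return One-row tibble: `form`, `statistic` (r or quadratic
#'   coefficient), `beta_linear` (quadratic form only), `p_parametric`,
#'   `p_spin`, `n_perm`, `n_regions`.
#' @export
spatial_correlation <- function(map_a, map_b, perms = NULL,
                                form = c("linear", "absolute", "quadratic")) {
  form <- match.arg(form)
  if (length(map_a) != length(map_b)) abort("Maps must have equal length.")
  if (anyNA(map_a) || anyNA(map_b)) abort("Maps must not contain missing values.")
  if (sd(map_a) == 0 || sd(map_b) == 0) abort("Zero-variance map.")
  n <- length(map_a)

  stat_fun <- switch(form,
    linear = function(a) cor(a, map_b),
    absolute = function(a) cor(abs(a), map_b),
    quadratic = function(a) {
      x <- cbind(1, a, a^2)
      qr.coef(qr(x), map_b)[3]
    }
  )
  beta_linear <- NA_real_
  if (form == "quadratic") {
    x <- cbind(1, map_a, map_a^2)
    fit <- lm(map_b ~ map_a + I(map_a^2))
    sm <- summary(fit)$coefficients
    statistic <- sm[3, 1]
    beta_linear <- sm[2, 1]
    p_par <- sm[3, 4]
  } else {
    a_eff <- if (form == "absolute") abs(map_a) else map_a
    ct <- cor.test(a_eff, map_b)
    statistic <- unname(ct$estimate)
    p_par <- ct$p.value
  }

  p_spin <- NA_real_
  n_perm <- NA_integer_
  if (!is.null(perms)) {
    if (ncol(perms) != n) abort("Permutation matrix does not match the map length.")
    n_perm <- nrow(perms)
    null_stats <- vapply(seq_len(n_perm), function(i) {
      stat_fun(map_a[perms[i, ]])
    }, numeric(1))
    p_spin <- (1 + sum(abs(null_stats) >= abs(statistic))) / (1 + n_perm)
  }
  tibble(form = form, statistic = statistic, beta_linear = beta_linear,
         p_parametric = p_par, p_spin = p_spin, n_perm = n_perm,
         n_regions = n)
}
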