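# Synthetic-data generators.
#
# Every pipeline input can be generated with known ground truth: donor-level
# expression with a planted two-component low-rank structure, a hemisphere
# mean-offset artefact and donor noise; spherical parcellations; per-cohort
# cognitive batteries with a latent g; and regional morphometry whose true
# g-association map is a known function of the planted component scores plus
# planted gene-specific signals.

#' Simulate parcel centroids on the unit sphere
#'
#' Places `n_per_hemisphere` well-spread centroids on the left half of the
#' unit sphere via a golden-angle (Fibonacci) spiral around the left-pointing
#' axis, then mirrors them through the sagittal plane to obtain the right
#' hemisphere. The seed rotates the spiral's azimuthal phase and adds a small
#' deterministic jitter so that different seeds give different, reproducible
#' parcellations.
#'
#' @param n_per_hemisphere Number of regions per hemisphere (>= 3).
#' @param seed Integer seed; fixed seed gives a bit-identical table.
#' @return A tibble with columns `region`, `hemisphere` ("left"/"right"),
#'   `x`, `y`, `z`; all centroids have unit norm and left/right pairs mirror
#'   in `x`.
#' @examples
#' simulate_sphere_parcellation(10, seed = 1)
#' @export
simulate_sphere_parcellation <- function(n_per_hemisphere = 34, seed = 1) {
  if (!is.numeric(n_per_hemisphere) || n_per_hemisphere < 3) {
    abort("`n_per_hemisphere` must be at least 3.")
  }
  n <- as.integer(n_per_hemisphere)
  golden <- pi * (3 - sqrt(5))
  jitter <- with_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    phase + runif(n, -0.05, 0.05)
  })
  # cosine of the angle from the (-1, 0, 0) axis, uniform over the hemisphere
  ca <- (seq_len(n) - 0.5) / n
  sa <- sqrt(1 - ca^2)
  az <- golden * seq_len(n) + jitter
  left <- cbind(x = -ca, y = sa * cos(az), z = sa * sin(az))
  right <- left
  right[, "x"] <- -right[, "x"]
  ids <- sprintf("region_%02d", seq_len(n))
  tibble(
    region = c(paste0("lh_", ids), paste0("rh_", ids)),
    hemisphere = rep(c("left", "right"), each = n),
    x = c(left[, "x"], right[, "x"]),
    y = c(left[, "y"], right[, "y"]),
    z = c(left[, "z"], right[, "z"])
  )
}

#' Simulate donor-level regional expression with planted components
#'
#' Generates a regions-by-genes expression study with two planted spatial
#' components. Each gene's standardised regional profile is a mixture
#' `sqrt(f) * (c1 * s1 + c2 * s2) + sqrt(1 - f) * noise`, where `s1`, `s2`
#' are the planted component score maps, `c1^2 + c2^2 = 1` per gene, and `f`
#' is the planted variance fraction, so the first two eigenvalue shares of a
#' correlation-matrix PCA sum to about `f`. Optionally the last
#' `n_planted_genes` genes form a co-expressed module carrying a shared
#' spatial profile orthogonal to both components; this is the ground-truth
#' signal for component-adjusted single-gene mapping. A constant offset is
#' added to left-hemisphere raw values, emulating the sampling artefact in
#' which one hemisphere shows slightly higher mean expression, and each donor
#' matrix adds independent Gaussian noise.
#'
#' @param n_regions Even number of regions (half per hemisphere).
#' @param n_genes Number of genes (>= 10), including any planted module.
#' @param n_donors Number of donors (>= 1).
#' @param planted_var_frac Fraction of standardised per-gene variance carried
#'   by the two planted components (default 0.5).
#' @param component_weights Length-2 positive weights giving the expected
#'   split of planted variance between the two components; the default
#'   `c(0.65, 0.35)` yields unrotated eigenvalue shares near 32% and 17%.
#' @param hemisphere_offset Constant (log2-intensity units) added to the left
#'   hemisphere's raw expression; default 0.056.
#' @param donor_noise_sd SD of per-donor measurement noise.
#' @param score_pair_cor Target correlation between paired left/right region
#'   scores (> 0.7 by construction at the default 0.9).
#' @param profile_sd SD of a gene's regional profile in raw units.
#' @param gene_mean_range Range of per-gene baseline expression.
#' @param n_planted_genes Number of genes in the planted specific module.
#' @param planted_gene_jitter SD of gene-specific deviation around the shared
#'   module profile (the module genes correlate ~`sqrt(1 - jitter^2)` with it).
#' @param seed Integer seed.
#' @return A list of class `"expression_sim"`:
#'   * `median`: wide expression tibble (`region`, `hemisphere`, genes),
#'     the element-wise median across donors;
#'   * `donors`: long tibble (`donor`, `region`, `hemisphere`, `gene`,
#'     `expression`);
#'   * `truth`: list with `scores` (regions x 2, orthogonal columns,
#'     hemisphere-centred), `loadings` (genes x 2 mixing coefficients),
#'     `planted_genes`, `planted_profile`, `hemisphere_offset`,
#'     `donor_noise_sd`, `gene_mean`.
#' @export
simulate_expression <- function(n_regions = 68,
                                n_genes = 2000,
                                n_donors = 6,
                                planted_var_frac = 0.5,
                                component_weights = c(0.65, 0.35),
                                hemisphere_offset = 0.056,
                                donor_noise_sd = 0.1,
                                score_pair_cor = 0.9,
                                profile_sd = 0.5,
                                gene_mean_range = c(4, 8),
                                n_planted_genes = 0,
                                planted_gene_jitter = 0.3,
                                seed = 1) {
  if (n_regions %% 2 != 0) abort("`n_regions` must be even (paired hemispheres).")
  if (n_genes < 10) abort("`n_genes` must be at least 10.")
  if (n_donors < 1) abort("`n_donors` must be at least 1.")
  if (n_planted_genes >= n_genes) abort("`n_planted_genes` must be smaller than `n_genes`.")
  stopifnot(planted_var_frac >= 0, planted_var_frac <= 1)

  nl <- n_regions / 2L
  w <- component_weights / sum(component_weights)

  out <- with_seed(seed, {
    ## planted component scores: left base, mirrored-with-noise right
    base <- matrix(rnorm(nl * 2), nl, 2)
    right <- score_pair_cor * base +
      sqrt(1 - score_pair_cor^2) * matrix(rnorm(nl * 2), nl, 2)
    s <- rbind(base, right)
    hemi <- rep(c("left", "right"), each = nl)
    # centre and scale within hemisphere, then orthogonalise column 2
    for (j in 1:2) {
      s[hemi == "left", j] <- zscale(s[hemi == "left", j])
      s[hemi == "right", j] <- zscale(s[hemi == "right", j])
    }
    s[, 2] <- s[, 2] - sum(s[, 1] * s[, 2]) / sum(s[, 1]^2) * s[, 1]
    s[, 2] <- s[, 2] / sd(s[, 2])

    ## per-gene mixing coefficients on the two components (unit rows);
    ## the squared weight on component 1 is Beta-distributed with mean w[1],
    ## so the expected eigenvalue split matches `component_weights`
    n_struct <- n_genes - n_planted_genes
    share1 <- stats::rbeta(n_struct, 4 * w[1], 4 * w[2])
    c_norm <- cbind(
      sample(c(-1, 1), n_struct, replace = TRUE) * sqrt(share1),
      sample(c(-1, 1), n_struct, replace = TRUE) * sqrt(1 - share1)
    )

    s_z <- scale(s)  # overall z for mixing (columns already near mean 0 sd 1)
    struct <- s_z %*% t(c_norm) * sqrt(planted_var_frac) +
      sqrt(1 - planted_var_frac) * matrix(rnorm(n_regions * n_struct), n_regions)

    ## planted co-expressed module orthogonal to both components
    planted_ids <- character(0)
    u <- NULL
    if (n_planted_genes > 0) {
      u <- rnorm(n_regions)
      fit <- cbind(1, s)
      u <- u - fit %*% solve(crossprod(fit), crossprod(fit, u))
      u <- as.numeric(u) / sd(u)
      jit <- planted_gene_jitter
      module <- sqrt(1 - jit^2) * matrix(u, n_regions, n_planted_genes) +
        jit * matrix(rnorm(n_regions * n_planted_genes), n_regions)
      struct <- cbind(struct, module)
      planted_ids <- sprintf("gene_%04d", (n_struct + 1):n_genes)
    }

    gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
    gene_mean <- runif(n_genes, gene_mean_range[1], gene_mean_range[2])
    x0 <- sweep(struct * profile_sd, 2, gene_mean, "+")
    x0[hemi == "left", ] <- x0[hemi == "left", ] + hemisphere_offset

    region <- c(sprintf("lh_region_%02d", seq_len(nl)),
                sprintf("rh_region_%02d", seq_len(nl)))
    donor_mats <- lapply(seq_len(n_donors), function(d) {
      x0 + donor_noise_sd * matrix(rnorm(length(x0)), nrow(x0))
    })

    loadings <- matrix(0, n_genes, 2,
                       dimnames = list(gene_ids, c("C1", "C2")))
    loadings[seq_len(n_struct), ] <- c_norm

    list(region = region, hemi = hemi, gene_ids = gene_ids,
         donor_mats = donor_mats, scores = s, loadings = loadings,
         gene_mean = gene_mean, planted_ids = planted_ids, u = u)
  })

  med <- apply(simplify2array(out$donor_mats), c(1, 2), median)
  colnames(med) <- out$gene_ids
  median_df <- as_expression_tibble(med, out$region, out$hemi)

  donors_long <- purrr::imap(out$donor_mats, function(m, d) {
    colnames(m) <- out$gene_ids
    tidyr::pivot_longer(
      as_expression_tibble(m, out$region, out$hemi),
      cols = -dplyr::all_of(REGION_COLS),
      names_to = "gene", values_to = "expression"
    ) |>
      mutate(donor = sprintf("donor_%02d", d), .before = 1)
  }) |>
    list_rbind()

  scores <- out$scores
  dimnames(scores) <- list(out$region, c("C1", "C2"))

  structure(
    list(
      median = median_df,
      donors = donors_long,
      truth = list(
        scores = scores,
        hemisphere = out$hemi,
        loadings = out$loadings,
        planted_genes = out$planted_ids,
        planted_profile = out$u,
        planted_gene_jitter = planted_gene_jitter,
        hemisphere_offset = hemisphere_offset,
        donor_noise_sd = donor_noise_sd,
        planted_var_frac = planted_var_frac,
        gene_mean = setNames(out$gene_mean, out$gene_ids)
      )
    ),
    class = "expression_sim"
  )
}

#' @export
print.expression_sim <- function(x, ...) {
  cat(sprintf(
    "<expression_sim> %d regions x %d genes, %d donors, %d planted specific genes\n",
    nrow(x$median), length(gene_cols(x$median)),
    length(unique(x$donors$donor)), length(x$truth$planted_genes)
  ))
  invisible(x)
}

#' Construct true regional g-association maps from planted structure
#'
#' Builds, for each morphometry measure, the true standardised association
#' between g and that measure in every region as a quadratic polynomial of
#' the planted component scores (a balance term that is maximal where both
#' scores are near zero, plus linear alignment with the score maps), plus the
#' planted gene module profile, plus spatially uncorrelated noise. The map is
#' assembled on a standardised scale from variance fractions and then placed
#' on the published effect-size scale via per-measure centre and spread.
#'
#' @param expr An `"expression_sim"` object (supplies scores and the planted
#'   module profile), or a list with elements `scores` and optionally
#'   `planted_profile`.
#' @param linear_frac Fraction of map variance aligned linearly with the two
#'   score maps.
#' @param quad_frac Fraction carried by the balance (negative squared-score)
#'   term.
#' @param gene_effect Coefficient (standardised-map units) of the planted
#'   module profile; the measured component-adjusted standardised beta of a
#'   module gene is close to this value. Ignored when no module was planted.
#' @param noise_frac Fraction of spatially uncorrelated map noise.
#' @param centre,spread Named per-measure centre and spread of the raw
#'   standardised-beta scale; defaults follow typical meta-analytic g-map
#'   magnitudes (means ~0.10/0.10/0.03, SDs ~0.03).
#' @param measures Measure names.
#' @param seed Integer seed for the map noise.
#' @return A tibble `region`, `hemisphere`, one column per measure, with the
#'   standardised-scale components stored in attribute `"map_truth"`.
#' @export
simulate_beta_maps <- function(expr,
                               linear_frac = 0.62,
                               quad_frac = 0.18,
                               gene_effect = 0.4,
                               noise_frac = 0.04,
                               centre = c(volume = 0.103, surface_area = 0.102,
                                          thickness = 0.031),
                               spread = c(volume = 0.034, surface_area = 0.027,
                                          thickness = 0.035),
                               measures = names(centre),
                               seed = 1) {
  truth <- if (inherits(expr, "expression_sim")) expr$truth else expr
  s <- truth$scores
  n <- nrow(s)
  hemi <- truth$hemisphere %||% rep(c("left", "right"), each = n / 2)
  u <- truth$planted_profile
  c_gene <- if (is.null(u)) 0 else gene_effect
  stopifnot(linear_frac >= 0, quad_frac >= 0, noise_frac >= 0)

  lin <- zscale(s[, 1] + s[, 2])
  quad <- zscale(-(s[, 1]^2 + s[, 2]^2))
  eps <- with_seed(seed, matrix(rnorm(n * length(measures)), n))

  maps <- vapply(seq_along(measures), function(m) {
    z <- sqrt(linear_frac) * lin + sqrt(quad_frac) * quad +
      c_gene * (u %||% 0) + sqrt(noise_frac) * eps[, m]
    centre[[m]] + spread[[m]] * z
  }, numeric(n))
  colnames(maps) <- measures

  out <- dplyr::bind_cols(
    tibble(region = rownames(s), hemisphere = hemi),
    as_tibble(maps)
  )
  attr(out, "map_truth") <- list(
    linear = lin, quadratic = quad, gene = u, gene_effect = c_gene,
    centre = centre, spread = spread
  )
  out
}

#' Simulate a cohort with a latent g, covariates and regional morphometry
#'
#' Generates per-participant cognitive test scores as `lambda * g +
#' within-domain residual + unique noise` (all on unit-variance scales) with
#' planted age and sex effects, plus regional morphometry in which each
#' region-by-measure true standardised g-association is taken from
#' `beta_map`, with small covariate effects (age, sex, site, scanner head
#' position) and Gaussian noise.
#'
#' @param n_participants Cohort size.
#' @param beta_map Tibble from [simulate_beta_maps()]: `region`,
#'   `hemisphere`, one column per morphometry measure holding the true
#'   standardised g-association.
#' @param n_tests Number of cognitive tests (>= 3).
#' @param loadings True test loadings on g, in (0, 1); recycled to
#'   `n_tests`.
#' @param domain_labels Per-test cognitive-domain labels; tests sharing a
#'   label share a within-domain residual factor. Defaults to pairs.
#' @param residual_cov Within-domain residual covariance (shared variance of
#'   the domain factor), a single value in [0, 1).
#' @param missing_rate MCAR missingness rate applied to test scores.
#' @param age_range Uniform age range in years.
#' @param n_sites Number of testing sites.
#' @param covariate_beta Standardised effect of each covariate on
#'   morphometry.
#' @param test_age_beta,test_sex_beta Planted age/sex effects on tests.
#' @param seed Integer seed.
#' @return A list of class `"cohort_sim"`: `phenotypes` (one row per
#'   participant: `id`, `age`, `sex`, `site`, `head_x/y/z`, `test_*`),
#'   `morphometry` (long: `id`, `region`, `hemisphere`, one column per
#'   measure) and `truth` (`g`, `test_loadings`, `domain_labels`,
#'   `residual_cov`, `beta_map`).
#' @export
simulate_cohort <- function(n_participants,
                            beta_map,
                            n_tests = 10,
                            loadings = 0.7,
                            domain_labels = NULL,
                            residual_cov = 0.1,
                            missing_rate = 0,
                            age_range = c(45, 80),
                            n_sites = 2,
                            covariate_beta = 0.1,
                            test_age_beta = 0.2,
                            test_sex_beta = 0.1,
                            seed = 1) {
  if (n_tests < 3) abort("`n_tests` must be at least 3 for one-factor identifiability.")
  lambda <- rep_len(loadings, n_tests)
  if (any(lambda < 0 | lambda >= 1)) abort("test loadings must lie in [0, 1).")
  if (any(lambda^2 + residual_cov >= 1)) {
    abort("`loadings^2 + residual_cov` must be below 1.")
  }
  if (is.null(domain_labels)) {
    domain_labels <- paste0("domain_", rep(seq_len(ceiling(n_tests / 2)),
                                           each = 2)[seq_len(n_tests)])
  }
  check_expression_df(beta_map, "beta_map")
  measures <- gene_cols(beta_map)
  bm <- expr_matrix(beta_map)

  sim <- with_seed(seed, {
    n <- n_participants
    g <- rnorm(n)
    age <- runif(n, age_range[1], age_range[2])
    sex <- rbinom(n, 1, 0.5)
    site <- sample(paste0("site_", seq_len(n_sites)), n, replace = TRUE)
    head <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("head_x", "head_y", "head_z")))

    doms <- unique(domain_labels)
    dom_f <- matrix(rnorm(n * length(doms)), n, dimnames = list(NULL, doms))
    tests <- vapply(seq_len(n_tests), function(j) {
      lam <- lambda[j]
      uniq <- 1 - lam^2 - residual_cov
      lam * g + sqrt(residual_cov) * dom_f[, domain_labels[j]] +
        sqrt(uniq) * rnorm(n) +
        test_age_beta * zscale(age) + test_sex_beta * sex
    }, numeric(n))
    colnames(tests) <- sprintf("test_%02d", seq_len(n_tests))
    if (missing_rate > 0) {
      tests[matrix(runif(length(tests)) < missing_rate, nrow(tests))] <- NA
    }

    site_eff <- setNames(seq_len(n_sites) - mean(seq_len(n_sites)),
                         paste0("site_", seq_len(n_sites))) * covariate_beta
    cov_part <- -2 * covariate_beta * zscale(age) + covariate_beta * sex +
      site_eff[site] + 0.5 * covariate_beta * rowSums(head)
    var_cov <- var(cov_part)

    morph <- lapply(measures, function(m) {
      b <- bm[, m]
      noise_sd <- sqrt(pmax(1 - b^2 - var_cov, 0.1))
      vals <- outer(g, b) + cov_part +
        matrix(rnorm(n * length(b)), n) %*% diag(noise_sd)
      colnames(vals) <- rownames(bm)
      vals
    })
    names(morph) <- measures
    list(g = g, age = age, sex = sex, site = site, head = head,
         tests = tests, morph = morph)
  })

  ids <- sprintf("p_%05d", seq_len(n_participants))
  phenotypes <- dplyr::bind_cols(
    tibble(id = ids, age = sim$age, sex = sim$sex, site = sim$site),
    as_tibble(sim$head),
    as_tibble(sim$tests)
  )
  morphometry <- purrr::imap(sim$morph, function(vals, m) {
    as_tibble(vals) |>
      mutate(id = ids, .before = 1) |>
      tidyr::pivot_longer(-"id", names_to = "region", values_to = m)
  }) |>
    purrr::reduce(function(a, b) left_join(a, b, by = c("id", "region"))) |>
    left_join(dplyr::select(beta_map, dplyr::all_of(REGION_COLS)), by = "region") |>
    dplyr::relocate("hemisphere", .after = "region")

  structure(
    list(
      phenotypes = phenotypes,
      morphometry = morphometry,
      truth = list(
        g = setNames(sim$g, ids),
        test_loadings = lambda,
        domain_labels = domain_labels,
        residual_cov = residual_cov,
        beta_map = beta_map
      )
    ),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<cohort_sim> %d participants, %d tests, %d regions x %d measures\n",
    nrow(x$phenotypes),
    sum(startsWith(names(x$phenotypes), "test_")),
    dplyr::n_distinct(x$morphometry$region),
    length(setdiff(names(x$morphometry), c("id", REGION_COLS)))
  ))
  invisible(x)
}

#' Simulate a full multi-cohort study
#'
#' Convenience wrapper generating every pipeline input at once: a spherical
#' parcellation, a donor-level expression study with planted components and a
#' planted specific-gene module, true g-association maps, and several cohorts
#' with latent-g batteries and regional morphometry.
#'
#' @param seed Integer seed driving all generators.
#' @param n_regions,n_genes,n_donors,n_planted_genes Passed to
#'   [simulate_expression()].
#' @param cohort_sizes Named integer vector of cohort sizes.
#' @param cohort_ages List of age ranges per cohort.
#' @param n_tests Tests per cohort (recycled).
#' @param ... Further arguments to [simulate_expression()].
#' @return List with `parcellation`, `expression`, `beta_map`, `cohorts`
#'   (named list of `"cohort_sim"`), and `seeds`.
#' @export
simulate_study <- function(seed = 1,
                           n_regions = 68,
                           n_genes = 8235,
                           n_donors = 6,
                           n_planted_genes = 10,
                           cohort_sizes = c(cohort_a = 37840, cohort_b = 1043,
                                            cohort_c = 636),
                           cohort_ages = list(c(44, 83), c(26, 84), c(70, 74)),
                           n_tests = 10,
                           ...) {
  seeds <- derive_seeds(seed, 4 + length(cohort_sizes))
  parcellation <- simulate_sphere_parcellation(n_regions / 2, seed = seeds[1])
  expression <- simulate_expression(
    n_regions = n_regions, n_genes = n_genes, n_donors = n_donors,
    n_planted_genes = n_planted_genes, seed = seeds[2], ...
  )
  beta_map <- simulate_beta_maps(expression, seed = seeds[3])
  n_tests <- rep_len(n_tests, length(cohort_sizes))
  cohorts <- purrr::imap(as.list(cohort_sizes), function(nn, nm) {
    i <- match(nm, names(cohort_sizes))
    simulate_cohort(nn, beta_map, n_tests = n_tests[i],
                    age_range = cohort_ages[[i]], seed = seeds[3 + i])
  })
  list(parcellation = parcellation, expression = expression,
       beta_map = beta_map, cohorts = cohorts, seeds = seeds)
}
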