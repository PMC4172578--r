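test_that("spectral REML agrees with the dense-matrix oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:20, 1)
    G <- impute_missing(random_genotypes(n, 30, seed = seed + 50))
    K <- compute_kinship(G)
    spec <- model_spec(n)
    y <- as.numeric(K$values %*% rnorm(n)) * 0.5 + rnorm(n)
    vc <- estimate_variance_components(y, K, spec)
    oracle <- dense_reml_oracle(y, spec$X, K$values, n_grid = 2001)
    expect_gte(vc$reml_loglik, oracle$grid_max - 1e-6)
    expect_equal(vc$reml_loglik, oracle$refined_max, tolerance = 1e-6)
    expect_equal(vc$sigma_e2 / vc$sigma_a2, vc$delta, tolerance = 1e-8)
    expect_gte(vc$sigma_a2, 0)
    expect_gte(vc$sigma_e2, 0)
  }
})

test_that("variance components are scale-equivariant and delta is not", {
  G <- impute_missing(random_genotypes(15, 40, seed = 77))
  K <- compute_kinship(G)
  set.seed(77)
  y <- as.numeric(K$values %*% rnorm(15)) + rnorm(15)
  vc1 <- estimate_variance_components(y, K)
  vc2 <- estimate_variance_components(2 * y, K)
  expect_equal(vc2$sigma_a2, 4 * vc1$sigma_a2, tolerance = 1e-4)
  expect_equal(vc2$sigma_e2, 4 * vc1$sigma_e2, tolerance = 1e-4)
  expect_equal(vc2$delta, vc1$delta, tolerance = 1e-4)
})

test_that("a trait perfectly explained by the fixed effects is degenerate", {
  G <- impute_missing(random_genotypes(10, 20, seed = 3))
  K <- compute_kinship(G)
  expect_error(estimate_variance_components(rep(3, 10), K),
               class = "supergwas_error_degenerate_fit")
  covs <- matrix(rnorm(10), ncol = 1)
  spec <- model_spec(10, covs)
  expect_error(
    estimate_variance_components(2 + 3 * covs[, 1], K, spec),
    class = "supergwas_error_degenerate_fit"
  )
})

test_that("GLS marker tests reduce to ordinary regression when V is identity", {
  set.seed(10)
  n <- 10
  y <- rnorm(n)
  w <- rbinom(n, 2, 0.4)
  covs <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "age"))
  spec <- model_spec(n, covs)
  vc0 <- estimate_variance_components(
    y, compute_kinship(impute_missing(random_genotypes(n, 15, seed = 1))), spec
  )
  # context with sigma_a2 forced to zero is exactly OLS
  vc0$sigma_a2 <- 0
  vc0$sigma_e2 <- 1
  ctx <- make_p3d_context(vc0, NULL, spec)
  res <- test_marker_gls(ctx, y, w, "w")
  fit <- lm(y ~ covs + w)
  an <- anova(fit)
  expect_equal(res$f_stat, an["w", "F value"], tolerance = 1e-10)
  expect_equal(res$p_value, an["w", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(res$effect, unname(coef(fit)["w"]), tolerance = 1e-10)
  expect_equal(res$df_den, n - 2L - 1L)
})

test_that("a cached P3D context reproduces per-marker fresh factorizations", {
  G <- impute_missing(random_genotypes(25, 100, seed = 21))
  K <- compute_kinship(G)
  set.seed(21)
  y <- as.numeric(K$values %*% rnorm(25)) + rnorm(25)
  spec <- model_spec(25)
  vc <- estimate_variance_components(y, K, spec)
  reused <- mlm_scan(G, y, K = K) # one context shared across all markers
  fresh <- purrr::map_dfr(seq_len(100), function(j) {
    test_marker_gls(make_p3d_context(vc, K, spec), y, G$dosages[, j],
                    G$map$id[j])
  })
  expect_equal(reused$f_stat, fresh$f_stat, tolerance = 1e-12)
  expect_equal(reused$p_value, fresh$p_value, tolerance = 1e-12)
})

test_that("collinear markers return a no-test sentinel, repeats are identical", {
  set.seed(4)
  n <- 12
  y <- rnorm(n)
  spec <- model_spec(n)
  ctx <- make_p3d_context(
    structure(list(sigma_a2 = 0, sigma_e2 = 1, delta = Inf,
                   reml_loglik = NA_real_, n = n, rank_x = 1,
                   kinship_fingerprint = NA_character_),
              class = "variance_components"),
    NULL, spec
  )
  mono <- test_marker_gls(ctx, y, rep(2, n), "mono")
  expect_true(is.na(mono$p_value))
  expect_identical(mono$reason, "collinear_with_fixed_effects")
  w <- rbinom(n, 2, 0.5)
  expect_identical(test_marker_gls(ctx, y, w, "w"),
                   test_marker_gls(ctx, y, w, "w"))
})

test_that("GLM null p-values are uniform in an unstructured population", {
  G <- simulate_genotypes(
    population_model(n_markers = 2000, n_chromosomes = 5, n_subpops = 1,
                     fst = 0, ld_rho = 0),
    n_per_subpop = 200, seed = 31
  )
  set.seed(32)
  y <- rnorm(200)
  scan <- glm_scan(G, y)
  ks <- suppressWarnings(ks.test(scan$p_value, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(2000)) # 1% critical value
})

test_that("MLM with all-SNP kinship deflates the structure-driven inflation of GLM", {
  G <- simulate_genotypes(
    population_model(n_markers = 2000, n_chromosomes = 5, n_subpops = 2,
                     fst = 0.2, ld_rho = 0.5),
    n_per_subpop = 100, seed = 41
  )
  set.seed(42)
  y <- 1.5 * (sim_subpops(G) - 1) + rnorm(200) # structured, no QTN
  lam_glm <- lambda_gc(glm_scan(G, y)$p_value)
  lam_mlm <- lambda_gc(mlm_scan(G, y)$p_value)
  expect_gt(lam_glm, 1.2)
  expect_gt(lam_mlm, 0.9)
  expect_lt(lam_mlm, 1.1)
})

test_that("single-marker scans compose and scans are reproducible", {
  G <- impute_missing(random_genotypes(20, 1, seed = 8))
  K_ext <- compute_kinship(impute_missing(random_genotypes(20, 40, seed = 9)))
  set.seed(8)
  y <- rnorm(20)
  scan <- mlm_scan(G, y, K = K_ext)
  spec <- model_spec(20)
  vc <- estimate_variance_components(y, K_ext, spec)
  single <- test_marker_gls(make_p3d_context(vc, K_ext, spec), y,
                            G$dosages[, 1], G$map$id[1])
  expect_equal(scan$f_stat, single$f_stat, tolerance = 1e-12)
  expect_identical(mlm_scan(G, y, K = K_ext), mlm_scan(G, y, K = K_ext))
})
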