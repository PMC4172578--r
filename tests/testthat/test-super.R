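test_that("bin assignment follows floor((pos - 1) / b) per chromosome", {
  v <- data.frame(id = c("a", "b", "c"), chromosome = "1",
                  position = c(1, 999999, 1000001))
  part <- assign_bins(v, 1e6)
  expect_equal(part$bin_index, c(0, 0, 1))

  v2 <- data.frame(id = paste0("m", 1:6), chromosome = rep(c("1", "2"), each = 3),
                   position = rep(c(10, 5000, 90000), 2))
  expect_equal(dplyr::n_distinct(assign_bins(v2, 1e8)$bin), 2) # one per chrom
  expect_equal(dplyr::n_distinct(assign_bins(v2, 1)$bin), 6)   # one per position
  expect_error(assign_bins(v2, 0), class = "supergwas_error_validation")
})

test_that("bin representatives are ranked by p with positional tie-breaks", {
  v <- data.frame(
    id = c("x1", "x2", "y1", "y2"), chromosome = "1",
    position = c(500, 900, 1000500, 1000900)
  )
  part <- assign_bins(v, 1e6)
  fs <- tibble::tibble(
    marker = v$id, p_value = c(1e-3, 1e-3, 1e-6, 0.5)
  )
  pq <- choose_representatives(part, fs, s = 1)
  expect_equal(pq$markers, "y1") # lowest rep p wins
  pq2 <- choose_representatives(part, fs, s = 10)
  expect_equal(pq2$s_effective, 2) # saturates at non-empty bins
  # tie within the first bin: position 500 beats 900
  expect_true("x1" %in% pq2$markers)
  expect_false("x2" %in% pq2$markers)
  fs_na <- dplyr::mutate(fs, p_value = NA_real_)
  expect_error(choose_representatives(part, fs_na, 1),
               class = "supergwas_error_selection")
})

test_that("squared-correlation LD matches hand-computed values", {
  expect_equal(ld_r2(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(ld_r2(c(0, 1, 2), c(2, 1, 0)), 1) # coding flip
  expect_equal(ld_r2(c(0, 0, 1, 2), c(0, 1, 1, 2)), 4 / 5.5, tolerance = 1e-12)
  expect_equal(ld_r2(c(0, 1, 2), c(1, 1, 1)), 0) # monomorphic convention
  expect_error(ld_r2(c(0, 1), c(0, 1, 2)), class = "supergwas_error_dimension")
})

test_that("the (s, b) grid optimizer picks the likelihood maximizer", {
  G <- cached_panel()
  trait <- simulate_phenotype(G, 5, 0.8, seed = 55)
  fs <- glm_scan(G, trait$y)
  single <- optimize_pseudo_qtns(G, trait$y, fs, s_grid = 7, b_grid = 5e6)
  expect_equal(single$s, 7L)
  expect_equal(single$b, 5e6)
  expect_equal(nrow(single$grid_log), 1L)

  pq <- optimize_pseudo_qtns(G, trait$y, fs, s_grid = c(5, 10, 1000),
                             b_grid = c(5e6, 5e7))
  expect_equal(max(pq$grid_log$reml_loglik, na.rm = TRUE), pq$reml_loglik)
  # s far beyond the available bins is evaluated at the cap and flagged
  capped <- dplyr::filter(pq$grid_log, s == 1000)
  expect_true(all(capped$capped))
  expect_true(all(capped$s_effective < 1000))
})

test_that("optimized pseudo-QTN sets beat random sets of the same size", {
  G <- simulate_genotypes(
    population_model(n_markers = 2000, n_chromosomes = 5, n_subpops = 2,
                     fst = 0.2, ld_rho = 0.5),
    n_per_subpop = 100, seed = 61
  )
  spec <- model_spec(n_samples(G))
  wins <- 0L
  reps <- 20
  for (r in seq_len(reps)) {
    trait <- simulate_phenotype(G, 5, 0.9, seed = 600 + r)
    fs <- glm_scan(G, trait$y)
    pq <- optimize_pseudo_qtns(G, trait$y, fs)
    set.seed(700 + r)
    rand <- sample(G$map$id, length(pq$markers))
    vc_rand <- estimate_variance_components(
      trait$y, compute_kinship(G, markers = rand, keep_crossproduct = FALSE),
      spec
    )
    if (pq$reml_loglik >= vc_rand$reml_loglik) wins <- wins + 1L
  }
  expect_gte(wins, 0.9 * reps)
})

test_that("SUPER collapses to the MLM and GLM limits at extreme thresholds", {
  G <- cached_panel()
  trait <- simulate_phenotype(G, 6, 0.75, seed = 71)
  fs <- glm_scan(G, trait$y)
  pq <- optimize_pseudo_qtns(G, trait$y, fs, s_grid = c(5, 10),
                             b_grid = c(5e6, 5e7))
  never <- super_scan(G, trait$y, pq, t = 1.01)
  mlm_ref <- mlm_scan(G, trait$y,
                      K = compute_kinship(G, markers = pq$markers))
  expect_lt(max(abs(never$p_value - mlm_ref$p_value), na.rm = TRUE), 1e-10)
  expect_true(all(never$n_excluded == 0))

  always <- super_scan(G, trait$y, pq, t = 0)
  glm_ref <- glm_scan(G, trait$y)
  expect_lt(max(abs(always$p_value - glm_ref$p_value), na.rm = TRUE), 1e-10)
  expect_true(all(always$n_excluded == length(pq$markers)))
})

test_that("a pseudo-QTN always excludes itself from its own test kinship", {
  G <- cached_panel()
  trait <- simulate_phenotype(G, 6, 0.75, seed = 72)
  scan <- super_scan(G, trait$y, trait$qtn_ids, t = 0.10)
  own <- scan[scan$marker %in% trait$qtn_ids, ]
  expect_true(all(own$n_excluded >= 1))
})

test_that("exclusion counts shrink monotonically as the threshold rises", {
  G <- cached_panel()
  trait <- simulate_phenotype(G, 6, 0.75, seed = 73)
  pseudo <- trait$qtn_ids
  n_ex <- sapply(c(0.05, 0.10, 0.30, 0.80), function(t) {
    super_scan(G, trait$y, pseudo, t = t)$n_excluded
  })
  expect_true(all(diff(t(n_ex)) <= 0))
  expect_true(any(n_ex[, 1] > 0))
})

test_that("per-marker SUPER kinships equal from-scratch complements", {
  G <- cached_panel()
  trait <- simulate_phenotype(G, 5, 0.75, seed = 74)
  pseudo <- trait$qtn_ids
  t <- 0.10
  K_full <- compute_kinship(G, markers = pseudo, keep_crossproduct = TRUE)
  for (m in c(pseudo[1], G$map$id[c(3, 101)])) {
    r2 <- sapply(pseudo, function(q) {
      ld_r2(G$dosages[, m], G$dosages[, q])
    })
    excl <- pseudo[r2 >= t]
    if (length(excl) == 0 || length(excl) == length(pseudo)) next
    K_down <- exclude_markers(K_full, G, excl)
    K_ref <- compute_kinship(G, markers = setdiff(pseudo, excl))
    expect_lt(max(abs(K_down$values - K_ref$values)), 1e-10)
  }
})
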