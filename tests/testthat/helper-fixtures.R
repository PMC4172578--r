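# Shared fixtures and independent oracles for the test suite.

# 3-sample, 2-marker toy panel with a hand-checkable kinship:
# p = 0.5 for both markers, c = 1, K = [[2,0,-2],[0,0,0],[-2,0,2]].
toy_genotypes <- function() {
  genotype_matrix(
    matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
           dimnames = list(c("A", "B", "C"), NULL)),
    data.frame(id = c("m1", "m2"), chromosome = "1", position = c(100, 200)),
    samples = c("A", "B", "C")
  )
}

# random dosage panel on a simple map (no structure, no LD)
random_genotypes <- function(n, m, seed, n_chrom = 2, maf_range = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  dos <- matrix(rbinom(n * m, 2, rep(p, each = n)), nrow = n)
  map <- data.frame(
    id = paste0("m", seq_len(m)),
    chromosome = as.character(rep_len(seq_len(n_chrom), m)),
    position = rep(seq_len(ceiling(m / n_chrom)) * 1000, length.out = m)
  )
  genotype_matrix(dos, map, samples = paste0("s", seq_len(n)))
}

# Dense-matrix REML oracle: explicit V inversion and log-determinants on a
# grid in ln(delta), plus a local refinement of the dense objective. Shares
# no code with the package's spectral path.
dense_reml_oracle <- function(y, X, Kmat, n_grid = 10001,
                              range = c(-10, 10)) {
  n <- length(y)
  q <- qr(X)$rank
  ll <- function(ln_delta) {
    V0 <- Kmat + exp(ln_delta) * diag(n)
    Vi <- solve(V0)
    XtViX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
    s2 <- as.numeric(crossprod(y, P %*% y)) / (n - q)
    as.numeric(
      -0.5 * ((n - q) * log(2 * pi * s2) + (n - q) +
                determinant(V0, logarithm = TRUE)$modulus +
                determinant(XtViX, logarithm = TRUE)$modulus -
                determinant(crossprod(X), logarithm = TRUE)$modulus)
    )
  }
  grid <- seq(range[1], range[2], length.out = n_grid)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, n_grid)]
  refined <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-10)
  list(grid_max = max(vals), refined_max = refined$objective, f = ll)
}

# Hudson-type Fst for two subpopulations (ratio of averages)
hudson_fst <- function(dosages, subpop) {
  stopifnot(length(unique(subpop)) == 2)
  g1 <- dosages[subpop == unique(subpop)[1], , drop = FALSE]
  g2 <- dosages[subpop == unique(subpop)[2], , drop = FALSE]
  n1 <- 2 * nrow(g1)
  n2 <- 2 * nrow(g2)
  p1 <- colMeans(g1) / 2
  p2 <- colMeans(g2) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

write_test_vcf <- function(path, ds_only = FALSE, multiallelic = FALSE) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3"
  )
  records <- if (multiallelic) {
    "1\t100\tv1\tA\tC,G\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"
  } else if (ds_only) {
    c(
      "1\t100\tv1\tA\tC\t.\tPASS\t.\tDS\t0.1\t1.2\t2.0",
      "1\t200\tv2\tG\tT\t.\tPASS\t.\tDS\t1.0\t0.0\t0.5"
    )
  } else {
    c(
      "1\t100\tv1\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
      "1\t200\tv2\tG\tT\t.\tPASS\t.\tGT\t1|1\t0|0\t./.",
      "2\t150\tv3\tC\tA\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0"
    )
  }
  writeLines(c(header, records), path)
  path
}

# small structured panel reused by several test files (built once per run)
cached_panel <- local({
  cache <- new.env(parent = emptyenv())
  function(key = "default") {
    if (is.null(cache[[key]])) {
      cache[[key]] <- switch(key,
        default = simulate_genotypes(
          population_model(n_markers = 400, n_chromosomes = 4,
                           n_subpops = 2, fst = 0.2, ld_rho = 0.5),
          n_per_subpop = 40, seed = 424
        ),
        unstructured = simulate_genotypes(
          population_model(n_markers = 400, n_chromosomes = 4,
                           n_subpops = 1, fst = 0, ld_rho = 0),
          n_per_subpop = 80, seed = 425
        )
      )
    }
    cache[[key]]
  }
})
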