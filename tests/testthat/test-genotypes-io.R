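test_that("numeric-tsv genotypes round-trip exactly, map field for field", {
  G <- random_genotypes(6, 8, seed = 1)
  G$dosages[2, 3] <- NA
  G <- genotype_matrix(G$dosages, G$map[, c("id", "chromosome", "position")],
                       G$samples)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(G, path)
  G2 <- read_genotypes(path, "numeric-tsv")
  expect_identical(G2$dosages, G$dosages)
  expect_identical(G2$map$id, G$map$id)
  expect_identical(G2$map$chromosome, G$map$chromosome)
  expect_identical(G2$map$position, G$map$position)
  expect_identical(G2$samples, G$samples)
})

test_that("a small dosage table reads with the expected shape and map", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxa\tm1\tm2", "a\t0\t2", "b\t1\t1", "c\t2\t0"), path)
  writeLines(c("marker\tchromosome\tposition", "m1\t1\t100", "m2\t1\t200"),
             paste0(path, ".map"))
  G <- read_genotypes(path, "numeric-tsv")
  expect_equal(dim(G), c(3L, 2L))
  expect_equal(unname(G$dosages[, "m1"]), c(0, 1, 2))
  expect_equal(G$map$position, c(100, 200))
})

test_that("out-of-range dosages and malformed headers are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxa\tm1", "a\t3", "b\t1"), path)
  writeLines(c("marker\tchromosome\tposition", "m1\t1\t100"),
             paste0(path, ".map"))
  expect_error(read_genotypes(path, "numeric-tsv"),
               class = "supergwas_error_validation")
  writeLines(c("id\tm1", "a\t1"), path)
  expect_error(read_genotypes(path, "numeric-tsv"),
               class = "supergwas_error_parse")
  expect_error(read_genotypes(tempfile(), "numeric-tsv"),
               class = "supergwas_error_input")
})

test_that("VCF GT codes map to 0/1/2 dosages with missing flagged", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path)
  G <- read_genotypes(path, "vcf")
  expect_equal(dim(G), c(3L, 3L))
  expect_equal(unname(G$dosages[, "v1"]), c(0, 1, 2))
  expect_equal(unname(G$dosages[, "v2"]), c(2, 0, NA)) # phased + missing
  expect_equal(unname(G$dosages[, "v3"]), c(1, 1, 0))
  expect_equal(G$map$chromosome, c("1", "1", "2"))
})

test_that("VCF DS dosages pass through and multi-allelics are rejected", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, ds_only = TRUE)
  G <- read_genotypes(path, "vcf")
  expect_equal(unname(G$dosages[, "v1"]), c(0.1, 1.2, 2.0))
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path2, multiallelic = TRUE)
  expect_error(read_genotypes(path2, "vcf"),
               class = "supergwas_error_validation")
})

test_that("filter_variants applies maf >= and missingness <= thresholds", {
  # mafs 0.05, 0.10, 0.25, 0.0 over 10 samples, no missing data
  dos <- cbind(
    c(1, rep(0, 9)),            # p = 0.05
    c(2, rep(0, 9)),            # p = 0.10
    c(2, 2, 1, rep(0, 7)),      # p = 0.25
    rep(0, 10)                  # monomorphic
  )
  G <- genotype_matrix(dos, data.frame(
    id = paste0("m", 1:4), chromosome = "1", position = 1:4 * 100
  ), samples = paste0("s", 1:10))
  expect_equal(G$map$maf, c(0.05, 0.10, 0.25, 0))
  kept <- filter_variants(G, min_maf = 0.1, max_missing = 0)
  expect_equal(kept$map$id, c("m2", "m3")) # boundary maf 0.10 retained
  expect_identical(filter_variants(G, 0, 1)$dosages, G$dosages) # no-op bounds
  expect_error(filter_variants(G, 0.5, 0), "removed",
               class = "supergwas_error_validation")
})

test_that("filter_variants is idempotent and drops high-missingness markers", {
  G <- random_genotypes(20, 30, seed = 3)
  d <- G$dosages
  d[1:5, 2] <- NA # 25% missing
  hit <- G$map$id[2]
  G <- genotype_matrix(d, G$map[, c("id", "chromosome", "position")], G$samples)
  f1 <- filter_variants(G, 0.1, 0.05)
  f2 <- filter_variants(f1, 0.1, 0.05)
  expect_identical(f2$dosages, f1$dosages)
  expect_false(hit %in% f1$map$id)
})

test_that("mean imputation fills gaps, preserves means, errors on empty markers", {
  dos <- cbind(c(0, 2, NA), c(1, 1, 1))
  G <- genotype_matrix(dos, data.frame(
    id = c("a", "b"), chromosome = "1", position = c(1, 2)
  ), samples = c("x", "y", "z"))
  I <- impute_missing(G)
  expect_equal(unname(I$dosages[, "a"]), c(0, 2, 1.0))
  expect_false(anyNA(I$dosages))
  expect_identical(impute_missing(I)$dosages, I$dosages) # no-missing identity

  G2 <- random_genotypes(15, 10, seed = 5)
  d <- G2$dosages
  d[sample(length(d), 20)] <- NA
  d[, 4] <- pmin(d[, 4], 2) # keep in range
  G2 <- genotype_matrix(d, G2$map[, c("id", "chromosome", "position")],
                        G2$samples)
  I2 <- impute_missing(G2)
  expect_equal(colMeans(I2$dosages), colMeans(G2$dosages, na.rm = TRUE),
               tolerance = 1e-12)

  dos3 <- cbind(c(NA, NA, NA), c(0, 1, 2))
  G3 <- genotype_matrix(dos3, data.frame(
    id = c("gone", "ok"), chromosome = "1", position = c(1, 2)
  ), samples = c("x", "y", "z"))
  expect_error(impute_missing(G3), "gone",
               class = "supergwas_error_validation")
})

test_that("align_samples restricts both inputs to the shared ids in order", {
  G <- toy_genotypes() # samples A, B, C
  P <- tibble::tibble(taxa = c("C", "B"), trait = c(1.5, 2.5))
  expect_message(ali <- align_samples(G, P), "dropped")
  expect_equal(ali$genotypes$samples, c("B", "C")) # G's order
  expect_equal(ali$phenotypes$taxa, c("B", "C"))
  expect_equal(ali$phenotypes$trait, c(2.5, 1.5))

  P_full <- tibble::tibble(taxa = c("A", "B", "C"), trait = 1:3)
  ali2 <- align_samples(G, P_full)
  expect_identical(ali2$genotypes$dosages, G$dosages)

  expect_error(align_samples(G, tibble::tibble(taxa = "Z", trait = 1)),
               class = "supergwas_error_alignment")
})
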