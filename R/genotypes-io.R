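#' Read genotypes from a numeric dosage table or a VCF
#'
#' The numeric-tsv dialect is a tab-separated table with header
#' `taxa<TAB>m1<TAB>m2...`, one row per sample, entries in `[0, 2]` or `NA`
#' for missing, accompanied by a sidecar map file (same path with `.map`
#' appended, or given explicitly) with header `marker<TAB>chromosome<TAB>position`.
#' VCF input uses the GT field when present (hom-ref = 0, het = 1,
#' hom-alt = 2) and falls back to DS dosages; multi-allelic records are
#' rejected. Missing entries are flagged (`NA`), never imputed here.
#'
#' @param path Path to the genotype file.
#' @param format `"numeric-tsv"` or `"vcf"`.
#' @param map_path Sidecar variant map for `numeric-tsv`; defaults to
#'   `paste0(path, ".map")`.
#' @return A [genotype_matrix()].
#' @seealso [filter_variants()], [impute_missing()], [align_samples()]
#' @export
read_genotypes <- function(path, format = c("numeric-tsv", "vcf"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_input(sprintf("Genotype file not found: %s", path))
  }
  switch(format,
    "numeric-tsv" = read_numeric_tsv(path, map_path),
    "vcf" = read_vcf_genotypes(path)
  )
}

read_numeric_tsv <- function(path, map_path = NULL) {
  if (is.null(map_path)) map_path <- paste0(path, ".map")
  if (!file.exists(map_path)) {
    abort_input(sprintf("Variant map file not found: %s", map_path))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) {
    abort_parse(sprintf("%s: expected `taxa` plus marker columns.", path))
  }
  if (tolower(names(tab)[1]) != "taxa") {
    abort_parse(sprintf(
      "%s: first header field must be `taxa`, found `%s`.", path, names(tab)[1]
    ))
  }
  samples <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(dos)) {
    bad <- names(tab)[-1][!vapply(tab[-1], is.numeric, logical(1))][1]
    abort_parse(sprintf("%s: non-numeric dosage column `%s`.", path, bad))
  }
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 3) {
    abort_parse(sprintf(
      "%s: expected columns marker, chromosome, position.", map_path
    ))
  }
  names(map)[1:3] <- c("id", "chromosome", "position")
  missing_map <- setdiff(colnames(dos), map$id)
  if (length(missing_map) > 0) {
    abort_dimension(sprintf(
      "%d marker(s) in %s have no map entry (first: %s).",
      length(missing_map), path, missing_map[1]
    ))
  }
  map <- map[match(colnames(dos), map$id), , drop = FALSE]
  genotype_matrix(dos, map[, c("id", "chromosome", "position")], samples)
}

read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix)) # single-record file
  if (nrow(fix) == 0) abort_parse(sprintf("%s: no variant records.", path))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    abort_validation(sprintf(
      "%s: %d multi-allelic record(s) (first at %s:%s); only biallelic SNPs are supported.",
      path, sum(multi), fix[multi, "CHROM"][1], fix[multi, "POS"][1]
    ))
  }
  fmt <- vcf@gt[, 1]
  has_gt <- all(grepl("(^|:)GT(:|$)", fmt))
  if (has_gt) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- apply(gt, c(1, 2), gt_to_dosage)
  } else if (all(grepl("(^|:)DS(:|$)", fmt))) {
    dos <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    abort_parse(sprintf("%s: records carry neither GT nor DS.", path))
  }
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  map <- data.frame(
    id = ids, chromosome = fix[, "CHROM"],
    position = as.numeric(fix[, "POS"])
  )
  genotype_matrix(t(dos), map, samples = colnames(dos))
}

gt_to_dosage <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(as.numeric(alleles) != 0)
}

#' Write genotypes in the numeric-tsv dialect
#'
#' Writes the dosage table and its `.map` sidecar; [read_genotypes()] on the
#' pair round-trips the object.
#'
#' @param G A `genotype_matrix`.
#' @param path Output path for the dosage table; the map goes to
#'   `paste0(path, ".map")`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  tab <- data.frame(taxa = G$samples, G$dosages, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- data.frame(
    marker = G$map$id, chromosome = G$map$chromosome,
    position = format(G$map$position, scientific = FALSE, trim = TRUE)
  )
  utils::write.table(map, paste0(path, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Expects a tab-separated file with header `taxa<TAB>trait[<TAB>cov1...]`.
#'
#' @param path Path to the table.
#' @return A tibble with columns `taxa`, `trait`, and any covariates.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) {
    abort_input(sprintf("Phenotype file not found: %s", path))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) {
    abort_parse(sprintf("%s: expected `taxa` plus a trait column.", path))
  }
  names(tab)[1:2] <- c("taxa", "trait")
  tab$taxa <- as.character(tab$taxa)
  num <- vapply(tab[-1], is.numeric, logical(1))
  if (!all(num)) {
    abort_parse(sprintf(
      "%s: non-numeric column `%s`.", path, names(tab)[-1][!num][1]
    ))
  }
  tibble::as_tibble(tab)
}

#' Filter markers on minor-allele frequency and missingness
#'
#' Retains exactly the markers with `maf >= min_maf` and missing fraction
#' `<= max_missing`; the sample set and the order of retained markers are
#' unchanged. The conventional GWAS quality filter drops rare variants
#' (default MAF < 0.1) and poorly genotyped ones (default > 5% missing).
#'
#' @param G A `genotype_matrix`.
#' @param min_maf Minimum minor-allele frequency in `[0, 0.5]`.
#' @param max_missing Maximum missing-call fraction in `[0, 1]`.
#' @return A filtered `genotype_matrix`.
#' @export
filter_variants <- function(G, min_maf = 0.1, max_missing = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (min_maf < 0 || min_maf > 0.5) {
    abort_validation("`min_maf` must lie in [0, 0.5].")
  }
  if (max_missing < 0 || max_missing > 1) {
    abort_validation("`max_missing` must lie in [0, 1].")
  }
  keep_maf <- G$map$maf >= min_maf
  keep_miss <- G$map$missing_rate <= max_missing
  keep <- keep_maf & keep_miss
  if (!any(keep)) {
    abort_validation(sprintf(
      "All %d markers removed (%d failed MAF >= %g, %d failed missingness <= %g).",
      n_markers(G), sum(!keep_maf), min_maf, sum(!keep_miss), max_missing
    ))
  }
  subset_genotypes(G, markers = keep)
}

#' Impute missing dosages by the marker mean
#'
#' Each missing entry is replaced by that marker's mean dosage over the
#' non-missing samples, which preserves the marker's allele-frequency
#' estimate. A marker with no observed calls is an error.
#'
#' @param G A `genotype_matrix`.
#' @return A `genotype_matrix` with no missing entries.
#' @export
impute_missing <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosages
  nmiss <- colSums(is.na(dos))
  if (any(nmiss == nrow(dos))) {
    bad <- G$map$id[nmiss == nrow(dos)]
    abort_validation(sprintf(
      "Marker(s) with no observed calls cannot be imputed: %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  if (any(nmiss > 0)) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  genotype_matrix(dos, G$map[, c("id", "chromosome", "position")], G$samples)
}

#' Align genotypes and phenotypes on their common samples
#'
#' Restricts both inputs to the intersection of their sample identifiers, in
#' the genotype matrix's order, and reports dropped samples via a message.
#'
#' @param G A `genotype_matrix`.
#' @param P A phenotype tibble with a `taxa` column (see [read_phenotypes()]).
#' @return A list with elements `genotypes` and `phenotypes`, row-aligned.
#' @export
align_samples <- function(G, P) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!"taxa" %in% names(P)) {
    abort_validation("Phenotype table must have a `taxa` column.")
  }
  common <- G$samples[G$samples %in% P$taxa]
  if (length(common) == 0) {
    rlang::abort("No samples shared between genotypes and phenotypes.",
                 class = "supergwas_error_alignment")
  }
  dropped_g <- setdiff(G$samples, common)
  dropped_p <- setdiff(P$taxa, common)
  if (length(dropped_g) + length(dropped_p) > 0) {
    rlang::inform(sprintf(
      "align_samples: dropped %d genotyped-only and %d phenotyped-only sample(s); %d retained.",
      length(dropped_g), length(dropped_p), length(common)
    ))
  }
  P2 <- P[match(common, P$taxa), , drop = FALSE]
  if (anyNA(P2$trait)) {
    abort_validation("Missing trait values among the aligned samples.")
  }
  list(
    genotypes = subset_genotypes(G, samples = common),
    phenotypes = tibble::as_tibble(P2)
  )
}
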