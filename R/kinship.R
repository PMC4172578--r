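#' VanRaden genomic kinship
#'
#' Computes the genomic relationship matrix K = M M' / c, where column j of
#' M is the mean-centred dosage (dosage_j - 2 p_j), p_j is the observed
#' allele frequency (mean dosage / 2), and c = 2 * sum_j p_j (1 - p_j) over
#' the included polymorphic markers. Monomorphic (constant-dosage) markers
#' contribute zero to both the cross-product and the normalizer, so
#' appending one leaves K unchanged.
#'
#' @param G A `genotype_matrix` with no missing entries (see
#'   [impute_missing()]).
#' @param markers Marker subset (indices, ids, or logical mask); `NULL`
#'   uses every marker.
#' @param keep_crossproduct Retain the raw M M' matrix so that
#'   [exclude_markers()] can downdate K in O(n^2) per excluded marker
#'   instead of recomputing from scratch. Doubles the memory held.
#' @return A `kinship_matrix`: list with `values` (n x n symmetric matrix),
#'   `normalizer` (c), `marker_fingerprint`, `marker_ids`, `samples`, and
#'   optionally `raw_crossproduct`.
#' @export
compute_kinship <- function(G, markers = NULL, keep_crossproduct = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"))
  idx <- resolve_index(markers, G$map$id, "marker")
  if (length(idx) == 0) abort_input("`markers` must be non-empty.")
  dos <- G$dosages[, idx, drop = FALSE]
  if (anyNA(dos)) {
    abort_input("Kinship requires imputed dosages; missing entries found.")
  }
  p <- colMeans(dos) / 2
  poly <- marker_is_polymorphic(dos)
  cnorm <- 2 * sum(p[poly] * (1 - p[poly]))
  if (cnorm <= 0) {
    rlang::abort(
      "All included markers are monomorphic; kinship is degenerate.",
      class = "supergwas_error_degenerate_kinship"
    )
  }
  M <- sweep(dos, 2, 2 * p)
  raw <- tcrossprod(M)
  K <- raw / cnorm
  new_kinship(K, cnorm, G$map$id[idx], G$samples,
              raw_crossproduct = if (keep_crossproduct) raw else NULL)
}

# polymorphic = non-constant dosage column (covers the all-heterozygote
# corner where p(1-p) > 0 but the centred column is zero)
marker_is_polymorphic <- function(dos) {
  matrixStats_range <- apply(dos, 2, function(x) max(x) - min(x))
  matrixStats_range > 0
}

new_kinship <- function(values, normalizer, marker_ids, samples,
                        raw_crossproduct = NULL) {
  values <- (values + t(values)) / 2 # enforce symmetry against round-off
  dimnames(values) <- list(samples, samples)
  structure(
    list(
      values = values,
      normalizer = normalizer,
      marker_fingerprint = rlang::hash(sort(marker_ids)),
      marker_ids = marker_ids,
      samples = samples,
      raw_crossproduct = raw_crossproduct
    ),
    class = "kinship_matrix"
  )
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf(
    "<kinship_matrix> %d x %d from %d marker(s); normalizer c = %.4g%s\n",
    nrow(x$values), ncol(x$values), length(x$marker_ids), x$normalizer,
    if (is.null(x$raw_crossproduct)) "" else " (downdatable)"
  ))
  invisible(x)
}

#' Downdate a kinship matrix by excluding markers
#'
#' Removes a marker subset from a kinship built with
#' `keep_crossproduct = TRUE`, subtracting each excluded marker's centred
#' outer product from the raw cross-product and its 2 p (1 - p) term from
#' the normalizer. The result equals [compute_kinship()] on the retained
#' subset to within round-off, at O(n^2) per excluded marker. This is the
#' workhorse of the SUPER scan, which needs a complementary kinship
#' (pseudo-QTNs minus those in LD with the tested marker) for every test.
#'
#' @param K A `kinship_matrix` carrying `raw_crossproduct`.
#' @param G The `genotype_matrix` the kinship was computed from.
#' @param excluded Marker ids or indices (into `G`) to remove; must be a
#'   subset of `K$marker_ids`.
#' @return A `kinship_matrix` over the retained markers. Excluding every
#'   marker raises a condition of class `supergwas_empty_kinship` (callers
#'   such as [super_scan()] fall back to a fixed-effects-only test).
#' @export
exclude_markers <- function(K, G, excluded) {
  stopifnot(inherits(K, "kinship_matrix"), inherits(G, "genotype_matrix"))
  if (is.null(K$raw_crossproduct)) {
    abort_input("Kinship was built without `keep_crossproduct`; cannot downdate.")
  }
  ex_idx <- resolve_index(excluded, G$map$id, "marker")
  ex_ids <- G$map$id[ex_idx]
  if (!all(ex_ids %in% K$marker_ids)) {
    abort_input("`excluded` must be a subset of the kinship's markers.")
  }
  if (length(ex_ids) == 0) return(K)
  retained <- setdiff(K$marker_ids, ex_ids)
  if (length(retained) == 0) {
    rlang::abort("Exclusion removed every kinship marker.",
                 class = c("supergwas_empty_kinship", "supergwas_error_input"))
  }
  dos <- G$dosages[, ex_idx, drop = FALSE]
  if (anyNA(dos)) abort_input("Excluded markers contain missing dosages.")
  p <- colMeans(dos) / 2
  poly <- marker_is_polymorphic(dos)
  Mex <- sweep(dos, 2, 2 * p)
  raw <- K$raw_crossproduct - tcrossprod(Mex)
  cnorm <- K$normalizer - 2 * sum(p[poly] * (1 - p[poly]))
  if (cnorm <= 0) {
    rlang::abort("Retained markers are all monomorphic after exclusion.",
                 class = "supergwas_error_degenerate_kinship")
  }
  new_kinship(raw / cnorm, cnorm, retained, K$samples, raw_crossproduct = raw)
}

#' Export / import a kinship matrix as tab-separated text
#'
#' Square matrix with a sample-id header row and leading id column.
#'
#' @param K A `kinship_matrix`.
#' @param path Output path.
#' @return `path` (write) or a `kinship_matrix` without cross-product (read).
#' @export
write_kinship <- function(K, path) {
  tab <- data.frame(taxa = K$samples, K$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("Kinship file not found: %s", path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  samples <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (nrow(vals) != ncol(vals)) {
    abort_dimension(sprintf("%s: kinship table is not square.", path))
  }
  if (max(abs(vals - t(vals))) > 1e-8) {
    abort_validation(sprintf("%s: kinship table is not symmetric.", path))
  }
  new_kinship(vals, NA_real_, character(0), samples)
}

# Eigendecomposition with the PSD repair policy: eigenvalues below -1e-8 are
# an input error, those in [-1e-8, 0) are floored to zero.
kinship_eigen <- function(K) {
  eg <- eigen(K$values, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    abort_input(sprintf(
      "Kinship is not positive semidefinite (min eigenvalue %.3g).",
      min(eg$values)
    ))
  }
  eg$values[eg$values < 0] <- 0
  eg
}
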