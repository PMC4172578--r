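#' Construct a genotype matrix
#'
#' Bundles a samples-by-markers allele-dosage matrix with its variant map.
#' Dosages are on the 0--2 scale (fractional values are permitted, e.g. after
#' mean imputation, and `NA` marks a missing call). Markers are sorted by
#' (chromosome, position) on construction; chromosome labels that look numeric
#' are ordered numerically, others lexicographically after them. Minor-allele
#' frequencies are (re)computed from the non-missing dosages.
#'
#' @param dosages Numeric matrix, one row per sample and one column per
#'   marker. Row and column names are optional; `samples` and `map$id`
#'   take precedence.
#' @param map Data frame with columns `id`, `chromosome`, `position`
#'   (1-based base pairs), one row per marker, in the column order of
#'   `dosages`.
#' @param samples Character vector of sample identifiers. Defaults to the
#'   row names of `dosages`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (matrix), `map` (tibble with `id`, `chromosome`, `position`,
#'   `maf`, `missing_rate`), and `samples`.
#' @export
#' @examples
#' d <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("m1", "m2")))
#' m <- data.frame(id = c("m1", "m2"), chromosome = "1", position = c(100, 200))
#' genotype_matrix(d, m)
genotype_matrix <- function(dosages, map, samples = rownames(dosages)) {
  if (!is.matrix(dosages) || !is.numeric(dosages)) {
    abort_validation("`dosages` must be a numeric matrix.")
  }
  map <- tibble::as_tibble(map)
  required <- c("id", "chromosome", "position")
  if (!all(required %in% names(map))) {
    abort_validation(paste0(
      "`map` must have columns ", paste(required, collapse = ", "), "."
    ))
  }
  if (nrow(map) != ncol(dosages)) {
    abort_dimension(sprintf(
      "Variant map has %d rows but the dosage matrix has %d columns.",
      nrow(map), ncol(dosages)
    ))
  }
  if (is.null(samples)) {
    samples <- paste0("sample", seq_len(nrow(dosages)))
  }
  samples <- as.character(samples)
  if (length(samples) != nrow(dosages)) {
    abort_dimension(sprintf(
      "%d sample ids for %d dosage rows.", length(samples), nrow(dosages)
    ))
  }
  if (anyDuplicated(map$id)) {
    abort_validation("Marker ids must be unique.")
  }
  if (anyDuplicated(samples)) {
    abort_validation("Sample ids must be unique.")
  }
  map$id <- as.character(map$id)
  map$chromosome <- as.character(map$chromosome)
  map$position <- as.numeric(map$position)
  if (any(!is.finite(map$position)) || any(map$position < 1)) {
    abort_validation("Positions must be finite and >= 1.")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (!all(is.na(dosages)) && (rng[1] < 0 || rng[2] > 2)) {
    abort_validation(sprintf(
      "Dosages must lie in [0, 2]; observed range [%g, %g].", rng[1], rng[2]
    ))
  }
  ord <- variant_order(map$chromosome, map$position)
  map <- map[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  dimnames(dosages) <- list(samples, map$id)
  map$maf <- marker_maf(dosages)
  map$missing_rate <- unname(colMeans(is.na(dosages)))
  structure(
    list(dosages = dosages, map = map, samples = samples),
    class = "genotype_matrix"
  )
}

# numeric-looking chromosome labels first in numeric order, others after,
# lexicographically; positions non-decreasing within chromosome
variant_order <- function(chromosome, position) {
  num <- suppressWarnings(as.numeric(chromosome))
  order(is.na(num), num, chromosome, position)
}

marker_maf <- function(dosages) {
  p <- unname(colMeans(dosages, na.rm = TRUE)) / 2
  pmin(p, 1 - p)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d markers on %d chromosome(s)\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chromosome))
  ))
  cat(sprintf(
    "  missing: %.2f%%  |  median MAF: %.3f\n",
    100 * mean(is.na(x$dosages)), stats::median(x$map$maf, na.rm = TRUE)
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of samples and markers
#'
#' @param G A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(G) nrow(G$dosages)

#' @rdname n_samples
#' @export
n_markers <- function(G) ncol(G$dosages)

#' Subset a genotype matrix by markers and/or samples
#'
#' @param G A `genotype_matrix`.
#' @param markers Marker indices, logical mask, or ids; `NULL` keeps all.
#' @param samples Sample indices, logical mask, or ids; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the selection (MAF recomputed).
#' @export
subset_genotypes <- function(G, markers = NULL, samples = NULL) {
  midx <- resolve_index(markers, G$map$id, "marker")
  sidx <- resolve_index(samples, G$samples, "sample")
  genotype_matrix(
    G$dosages[sidx, midx, drop = FALSE],
    G$map[midx, c("id", "chromosome", "position")],
    samples = G$samples[sidx]
  )
}

resolve_index <- function(i, ids, what) {
  if (is.null(i)) return(seq_along(ids))
  if (is.logical(i)) {
    if (length(i) != length(ids)) {
      abort_dimension(sprintf("Logical %s mask has the wrong length.", what))
    }
    return(which(i))
  }
  if (is.character(i)) {
    idx <- match(i, ids)
    if (anyNA(idx)) {
      abort_validation(sprintf(
        "Unknown %s id(s): %s", what, paste(i[is.na(idx)], collapse = ", ")
      ))
    }
    return(idx)
  }
  i <- as.integer(i)
  if (any(i < 1L | i > length(ids))) {
    abort_validation(sprintf("%s index out of range.", what))
  }
  i
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "supergwas_error_validation")
}
abort_dimension <- function(msg) {
  rlang::abort(msg, class = "supergwas_error_dimension")
}
abort_parse <- function(msg) {
  rlang::abort(msg, class = "supergwas_error_parse")
}
abort_input <- function(msg) {
  rlang::abort(msg, class = "supergwas_error_input")
}
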