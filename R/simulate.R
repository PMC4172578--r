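#' Describe a structured population to simulate
#'
#' Parameters of the Balding–Nichols-style genotype generator: ancestral
#' allele frequencies are uniform on \[0.1, 0.9\]; each subpopulation's
#' frequency is Beta-distributed around the ancestral one with
#' differentiation `fst`; local LD arises by copying the previous marker's
#' allelic state along each gamete with probability `ld_rho`.
#'
#' @param n_markers Total marker count, spread evenly over chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in base pairs;
#'   markers are evenly spaced.
#' @param n_subpops Number of subpopulations.
#' @param fst Differentiation parameter in `[0, 1)`; 0 means all
#'   subpopulations share the ancestral frequency.
#' @param ld_rho Adjacent-marker copying probability in `[0, 1)`.
#' @param coding `"diploid"` (dosages 0/1/2 from two gametes) or
#'   `"inbred"` (a single allelic state doubled to 0/2).
#' @return A `population_model` list.
#' @export
population_model <- function(n_markers = 3000, n_chromosomes = 10,
                             chromosome_length = 1e8, n_subpops = 2,
                             fst = 0.2, ld_rho = 0.5,
                             coding = c("diploid", "inbred")) {
  coding <- match.arg(coding)
  if (fst < 0 || fst >= 1) abort_validation("`fst` must lie in [0, 1).")
  if (ld_rho < 0 || ld_rho >= 1) abort_validation("`ld_rho` must lie in [0, 1).")
  if (n_subpops < 1) abort_validation("`n_subpops` must be >= 1.")
  if (n_markers < 1 || n_chromosomes < 1) {
    abort_validation("Need at least one marker and one chromosome.")
  }
  per <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  structure(
    list(
      n_subpops = as.integer(n_subpops), fst = fst, ld_rho = ld_rho,
      coding = coding,
      plan = tibble::tibble(
        chromosome = as.character(seq_len(n_chromosomes)),
        n_markers = as.integer(per),
        length_bp = chromosome_length
      )
    ),
    class = "population_model"
  )
}

#' Simulate structured genotypes
#'
#' Draws genotype dosages under the model of [population_model()]:
#' Balding–Nichols subpopulation frequencies
#' `Beta(p (1 - fst) / fst, (1 - p)(1 - fst) / fst)` around ancestral
#' `p ~ U(0.1, 0.9)`, first-order local LD by allele copying along each
#' gamete, evenly spaced positions, deterministic given `seed`. The
#' subpopulation assignment is attached as attribute `"subpop"` (and
#' returned by [sim_subpops()]).
#'
#' @param model A `population_model`.
#' @param n_per_subpop Individuals per subpopulation.
#' @param seed Integer seed; required for reproducibility.
#' @return A `genotype_matrix`.
#' @export
simulate_genotypes <- function(model, n_per_subpop, seed) {
  stopifnot(inherits(model, "population_model"))
  if (n_per_subpop < 1) abort_validation("`n_per_subpop` must be >= 1.")
  n <- model$n_subpops * n_per_subpop
  m <- sum(model$plan$n_markers)
  subpop <- rep(seq_len(model$n_subpops), each = n_per_subpop)
  n_gam <- if (model$coding == "diploid") 2L else 1L
  set.seed(as.integer(seed))
  p_anc <- stats::runif(m, 0.1, 0.9)
  freq <- matrix(p_anc, nrow = model$n_subpops, ncol = m, byrow = TRUE)
  if (model$fst > 0) {
    scale <- (1 - model$fst) / model$fst
    freq[] <- stats::rbeta(
      model$n_subpops * m,
      rep(p_anc, each = model$n_subpops) * scale,
      rep(1 - p_anc, each = model$n_subpops) * scale
    )
  }
  pf <- freq[subpop, , drop = FALSE] # n x m per-individual frequencies
  gam <- array(0L, dim = c(n, m, n_gam))
  fresh <- array(stats::runif(n * m * n_gam), dim = c(n, m, n_gam)) <
    array(pf, dim = c(n, m, n_gam))
  copy <- array(stats::runif(n * m * n_gam), dim = c(n, m, n_gam)) <
    model$ld_rho
  chrom_of <- rep(model$plan$chromosome, model$plan$n_markers)
  gam[, 1, ] <- fresh[, 1, ]
  for (j in 2:max(m, 2)) {
    if (m == 1) break
    same_chrom <- chrom_of[j] == chrom_of[j - 1]
    if (same_chrom) {
      gam[, j, ] <- ifelse(copy[, j, ], gam[, j - 1, ], fresh[, j, ])
    } else {
      gam[, j, ] <- fresh[, j, ]
    }
  }
  dos <- if (n_gam == 2L) gam[, , 1] + gam[, , 2] else 2L * gam[, , 1]
  map <- dplyr::bind_rows(lapply(seq_len(nrow(model$plan)), function(ci) {
    mc <- model$plan$n_markers[ci]
    tibble::tibble(
      chromosome = model$plan$chromosome[ci],
      position = round(seq(1, model$plan$length_bp[ci], length.out = mc))
    )
  }))
  map$id <- sprintf("snp_%s_%d", map$chromosome, map$position)
  G <- genotype_matrix(
    matrix(as.numeric(dos), nrow = n),
    map[, c("id", "chromosome", "position")],
    samples = sprintf("ind%04d", seq_len(n))
  )
  attr(G, "subpop") <- subpop
  G
}

#' Subpopulation assignment of a simulated panel
#'
#' @param G A `genotype_matrix` from [simulate_genotypes()].
#' @return Integer vector of subpopulation labels, or `NULL`.
#' @export
sim_subpops <- function(G) attr(G, "subpop")

#' Simulate an additive phenotype at a target heritability
#'
#' Samples `n_qtn` causal markers (QTNs) uniformly without replacement —
#' optionally avoiding one held-out chromosome — draws their effects from
#' N(0, 1), forms each individual's additive value as the effect-weighted
#' sum of raw dosages, and adds N(0, ve) residuals with
#' `ve = va (1 - h2) / h2`, where `va` is the realized (empirical)
#' variance of the additive values. `h2 = 1` returns the additive values
#' exactly; `h2 = 0` (the formula's pole) is defined as pure noise of
#' variance `va`, with the sampled QTNs and effects recorded but unused —
#' a message flags this. Genotype, QTN-sampling, effect, and residual
#' randomness use separate streams derived from `seed`, so replicates
#' differ only where intended.
#'
#' @param G Imputed `genotype_matrix`.
#' @param n_qtn Number of causal markers.
#' @param h2 Target heritability in `[0, 1]`.
#' @param seed Integer seed.
#' @param excluded_chromosome Optional chromosome label; QTNs are never
#'   sampled from it (its markers then carry a clean null).
#' @return A `sim_trait`: list with `y`, `qtn_indices`, `qtn_ids`,
#'   `qtn_effects`, `h2`, `va`, `ve`.
#' @export
simulate_phenotype <- function(G, n_qtn, h2, seed,
                               excluded_chromosome = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (h2 < 0 || h2 > 1) abort_validation("`h2` must lie in [0, 1].")
  eligible <- seq_len(n_markers(G))
  if (!is.null(excluded_chromosome)) {
    eligible <- which(!(G$map$chromosome %in% as.character(excluded_chromosome)))
  }
  if (n_qtn > length(eligible)) {
    abort_validation(sprintf(
      "n_qtn = %d exceeds the %d eligible markers.", n_qtn, length(eligible)
    ))
  }
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 3)
  set.seed(sub_seeds[1])
  qtn <- sort(eligible[sample.int(length(eligible), n_qtn)])
  set.seed(sub_seeds[2])
  effects <- stats::rnorm(n_qtn, 0, 1)
  additive <- as.numeric(G$dosages[, qtn, drop = FALSE] %*% effects)
  va <- stats::var(additive)
  set.seed(sub_seeds[3])
  if (h2 == 0) {
    rlang::inform(
      "h2 = 0: trait is pure noise of variance va; QTN effects recorded but unused."
    )
    ve <- va
    y <- stats::rnorm(length(additive), 0, sqrt(va))
  } else if (h2 == 1) {
    ve <- 0
    y <- additive
  } else {
    ve <- va * (1 - h2) / h2
    y <- additive + stats::rnorm(length(additive), 0, sqrt(ve))
  }
  structure(
    list(y = y, qtn_indices = qtn, qtn_ids = G$map$id[qtn],
         qtn_effects = effects, h2 = h2, va = va, ve = ve),
    class = "sim_trait"
  )
}

#' @export
print.sim_trait <- function(x, ...) {
  cat(sprintf(
    "<sim_trait> n = %d, %d QTN(s), target h2 = %.2f (va = %.3g, ve = %.3g)\n",
    length(x$y), length(x$qtn_indices), x$h2, x$va, x$ve
  ))
  invisible(x)
}

#' Export the simulated-trait truth table
#'
#' Tab-separated `qtn_marker chromosome position effect`.
#'
#' @param trait A `sim_trait`.
#' @param G The `genotype_matrix` it was simulated from.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_truth <- function(trait, G, path) {
  tab <- data.frame(
    qtn_marker = trait$qtn_ids,
    chromosome = G$map$chromosome[trait$qtn_indices],
    position = G$map$position[trait$qtn_indices],
    effect = trait$qtn_effects
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
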