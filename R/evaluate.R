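#' Empirical null p-value threshold at a target type-I error
#'
#' Returns the lower empirical alpha-quantile of the null p-values: the
#' `ceiling(alpha * k)`-th smallest of the `k` p-values observed at known
#' non-causal markers. By construction the fraction of null p-values at or
#' below the threshold is at least `alpha` and minimally so.
#'
#' @param null_pvalues P-values at null (non-QTN) markers; `NA` entries
#'   (untestable markers) are dropped.
#' @param alpha Target type-I error in `(0, 1]`; 0.05 is the conventional
#'   operating point.
#' @return A single p-value threshold.
#' @export
empirical_threshold <- function(null_pvalues, alpha = 0.05) {
  p <- null_pvalues[!is.na(null_pvalues)]
  if (length(p) == 0) abort_input("No null p-values supplied.")
  if (alpha <= 0 || alpha > 1) abort_validation("`alpha` must lie in (0, 1].")
  if (length(p) < 1 / alpha) {
    rlang::warn(sprintf(
      "Only %d null p-values for alpha = %g; the empirical quantile is coarse.",
      length(p), alpha
    ))
  }
  sort(p)[ceiling(alpha * length(p))]
}

#' Statistical power at a threshold
#'
#' The fraction of causal-marker (QTN) p-values at or below the threshold.
#' Untestable markers (`NA`) count as failures.
#'
#' @param qtn_pvalues P-values at the true causal markers.
#' @param threshold P-value threshold (typically from
#'   [empirical_threshold()]).
#' @return Proportion in `[0, 1]`.
#' @export
compute_power <- function(qtn_pvalues, threshold) {
  if (length(qtn_pvalues) == 0) abort_input("No QTN p-values supplied.")
  mean(!is.na(qtn_pvalues) & qtn_pvalues <= threshold)
}

#' Genomic-control inflation factor
#'
#' Converts each p-value to its 1-df chi-square quantile and divides the
#' median by 0.4549364 (the 1-df chi-square median). Calibrated tests give
#' 1.0; confounded scans inflate above it.
#'
#' @param pvalues P-values in `(0, 1]`; zeros are clamped with a warning,
#'   `NA`s dropped.
#' @return The inflation factor lambda.
#' @export
lambda_gc <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (length(p) == 0) abort_input("No p-values supplied.")
  if (any(p <= 0)) {
    rlang::warn("p-values of 0 clamped to the smallest representable value.")
    p[p <= 0] <- .Machine$double.xmin
  }
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Multiple-testing adjustment
#'
#' `"bonferroni-threshold"` returns the single genome-wide p-value
#' threshold `alpha / m`; `"bh-fdr"` returns Benjamini–Hochberg step-up
#' q-values (monotone in p-rank), one per input p-value.
#'
#' @param pvalues P-values in `(0, 1]`.
#' @param method `"bonferroni-threshold"` or `"bh-fdr"`.
#' @param alpha Family-wise error target for the Bonferroni threshold.
#' @return A single threshold, or a vector of q-values.
#' @export
adjust_pvalues <- function(pvalues, method = c("bonferroni-threshold", "bh-fdr"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (length(pvalues) == 0) abort_input("No p-values supplied.")
  if (alpha <= 0 || alpha >= 1) abort_validation("`alpha` must lie in (0, 1).")
  if (method == "bonferroni-threshold") {
    return(alpha / length(pvalues))
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Simulation-based power and type-I-error study
#'
#' Reproduces the empirical-null power protocol: per replicate, simulate a
#' structured genotype panel (or reuse one fixed panel) and an additive
#' trait at heritability `h2`, run each requested scan, build the null
#' distribution from the non-QTN markers (`scenario = "random-qtns"`) or
#' from the held-out last chromosome (`scenario = "held-out-chromosome"`,
#' where QTNs are never sampled from that chromosome), take the empirical
#' `alpha`-threshold, and score the fraction of QTNs detected. Replicate
#' means and standard errors are reported per method.
#'
#' Methods: `"glm"`, `"mlm-all-snps"`, `"mlm-all-snps-excl-qtns"`,
#' `"mlm-qtn-only"`, `"super-known-qtns"` (true QTNs as the pseudo-QTN
#' pool), `"super"` (full three-step pipeline with masked QTNs).
#'
#' @param methods Character vector from the roster above.
#' @param reps Number of replicates.
#' @param alpha Type-I error target.
#' @param model A [population_model()] for the genotype panel.
#' @param n_per_subpop Individuals per subpopulation.
#' @param n_qtn Number of causal markers per trait.
#' @param h2 Trait heritability.
#' @param scenario Null-construction scenario (see above).
#' @param t LD exclusion threshold for the SUPER scans.
#' @param s_grid,b_grid Pseudo-QTN optimization grids for `"super"`.
#' @param first_stage `"glm"` (default, fast) or `"mlm"` preliminary scan
#'   for `"super"`.
#' @param seed Master seed; panel and per-replicate trait seeds derive
#'   from it.
#' @param regenerate_genotypes Draw a fresh panel every replicate instead
#'   of reusing one (slower; default reuses, as when a real panel is
#'   re-used across simulated traits).
#' @param panel Optional pre-built, imputed `genotype_matrix` (e.g. a real
#'   panel) used for every replicate instead of simulating one; overrides
#'   `model` and `regenerate_genotypes`.
#' @return A `power_study_result`: summary tibble with `method`, `power`,
#'   `se`, `reps_ok`; per-replicate detail in `attr(, "replicates")`,
#'   configuration snapshot in `attr(, "config")`.
#' @export
run_power_study <- function(methods = c("glm", "mlm-all-snps", "super"),
                            reps = 30, alpha = 0.05,
                            model = population_model(),
                            n_per_subpop = 100, n_qtn = 20, h2 = 0.75,
                            scenario = c("random-qtns", "held-out-chromosome"),
                            t = 0.10,
                            s_grid = c(10, 20, 40, 80),
                            b_grid = c(5e5, 5e6, 5e7),
                            first_stage = c("glm", "mlm"),
                            seed = 1,
                            regenerate_genotypes = FALSE,
                            panel = NULL) {
  scenario <- match.arg(scenario)
  first_stage <- match.arg(first_stage)
  roster <- c("glm", "mlm-all-snps", "mlm-all-snps-excl-qtns",
              "mlm-qtn-only", "super-known-qtns", "super")
  bad <- setdiff(methods, roster)
  if (length(bad) > 0) {
    abort_validation(sprintf("Unknown method(s): %s", paste(bad, collapse = ", ")))
  }
  if (reps < 1) abort_validation("`reps` must be >= 1.")
  set.seed(as.integer(seed))
  geno_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  trait_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  held_out <- if (scenario == "held-out-chromosome") {
    if (is.null(panel)) {
      utils::tail(model$plan$chromosome, 1)
    } else {
      utils::tail(unique(panel$map$chromosome), 1)
    }
  } else NULL

  G <- NULL
  K_all <- NULL
  need_kall <- any(c("mlm-all-snps", "mlm-all-snps-excl-qtns") %in% methods)
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "genotype_matrix"))
    if (anyNA(panel$dosages)) {
      abort_input("`panel` must be imputed before the power study.")
    }
    G <- panel
    K_all <- if (need_kall) compute_kinship(G, keep_crossproduct = TRUE) else NULL
    regenerate_genotypes <- FALSE
  }
  rows <- list()
  truth <- vector("list", reps)
  for (r in seq_len(reps)) {
    if (is.null(G) || regenerate_genotypes) {
      G <- simulate_genotypes(model, n_per_subpop, geno_seeds[r])
      K_all <- if (need_kall) compute_kinship(G, keep_crossproduct = TRUE) else NULL
    }
    trait <- simulate_phenotype(G, n_qtn, h2, trait_seeds[r],
                                excluded_chromosome = held_out)
    truth[[r]] <- tibble::tibble(
      rep = r, qtn_marker = trait$qtn_ids,
      chromosome = G$map$chromosome[trait$qtn_indices],
      effect = trait$qtn_effects
    )
    null_idx <- if (is.null(held_out)) {
      setdiff(seq_len(n_markers(G)), trait$qtn_indices)
    } else {
      which(G$map$chromosome == held_out)
    }
    for (meth in methods) {
      res <- tryCatch(
        power_one_method(meth, G, trait, K_all, alpha, null_idx,
                         t, s_grid, b_grid, first_stage),
        error = function(e) {
          rlang::warn(sprintf(
            "Replicate %d, method %s failed and is excluded: %s",
            r, meth, conditionMessage(e)
          ))
          NULL
        }
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        method = meth, rep = r,
        power = if (is.null(res)) NA_real_ else res$power,
        threshold = if (is.null(res)) NA_real_ else res$threshold
      )
    }
  }
  detail <- dplyr::bind_rows(rows)
  summary <- detail |>
    dplyr::filter(!is.na(.data$power)) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      se = stats::sd(.data$power) / sqrt(dplyr::n()),
      power = mean(.data$power),
      reps_ok = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("method", "power", "se", "reps_ok") |>
    dplyr::arrange(match(.data$method, roster))
  class(summary) <- c("power_study_result", class(summary))
  attr(summary, "replicates") <- detail
  attr(summary, "truth") <- dplyr::bind_rows(truth)
  attr(summary, "config") <- list(
    methods = methods, reps = reps, alpha = alpha, model = model,
    n_per_subpop = n_per_subpop, n_qtn = n_qtn, h2 = h2,
    scenario = scenario, t = t, s_grid = s_grid, b_grid = b_grid,
    first_stage = first_stage, seed = seed,
    regenerate_genotypes = regenerate_genotypes
  )
  summary
}

power_one_method <- function(method, G, trait, K_all, alpha, null_idx,
                             t, s_grid, b_grid, first_stage) {
  y <- trait$y
  scan <- switch(method,
    "glm" = glm_scan(G, y),
    "mlm-all-snps" = mlm_scan(G, y, K = K_all),
    "mlm-all-snps-excl-qtns" = {
      K_ex <- exclude_markers(K_all, G, trait$qtn_ids)
      mlm_scan(G, y, K = K_ex)
    },
    "mlm-qtn-only" = {
      K_q <- compute_kinship(G, markers = trait$qtn_indices,
                             keep_crossproduct = FALSE)
      mlm_scan(G, y, K = K_q)
    },
    "super-known-qtns" = super_scan(G, y, trait$qtn_ids, t = t),
    "super" = {
      fs <- if (first_stage == "glm") glm_scan(G, y) else mlm_scan(G, y)
      pq <- optimize_pseudo_qtns(G, y, fs, s_grid = s_grid, b_grid = b_grid)
      super_scan(G, y, pq, t = t)
    }
  )
  thr <- empirical_threshold(scan$p_value[null_idx], alpha)
  list(power = compute_power(scan$p_value[trait$qtn_indices], thr),
       threshold = thr)
}

#' @export
print.power_study_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<power_study_result> %d replicate(s), alpha = %g, h2 = %g, %d QTN(s)\n",
    cfg$reps, cfg$alpha, cfg$h2, cfg$n_qtn
  ))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Write a power study as tab-separated text
#'
#' Long per-replicate format `method rep power threshold`, plus a
#' `.summary` companion with the per-method means and standard errors.
#'
#' @param result A `power_study_result`.
#' @param path Output path for the long table.
#' @return `path`, invisibly.
#' @export
write_power_study <- function(result, path) {
  utils::write.table(as.data.frame(attr(result, "replicates")), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(tibble::as_tibble(result)),
                     paste0(path, ".summary"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
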