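#' Partition markers into genomic bins
#'
#' Assigns the marker at 1-based position p on chromosome c to bin index
#' `floor((p - 1) / b)` on c, for bin size `b` base pairs. Bins with no
#' markers are simply absent from the output.
#'
#' @param variants A variant map: tibble/data frame with columns `id`,
#'   `chromosome`, `position` (a `genotype_matrix` `$map` works directly).
#' @param b Bin size in base pairs, `>= 1`.
#' @return A tibble with columns `id`, `chromosome`, `position`,
#'   `bin_index`, `bin` (a `"chromosome:index"` key).
#' @export
assign_bins <- function(variants, b) {
  if (inherits(variants, "genotype_matrix")) variants <- variants$map
  if (!is.numeric(b) || length(b) != 1 || b < 1) {
    abort_validation("Bin size `b` must be a single number >= 1.")
  }
  tibble::tibble(
    id = as.character(variants$id),
    chromosome = as.character(variants$chromosome),
    position = as.numeric(variants$position),
    bin_index = floor((as.numeric(variants$position) - 1) / b)
  ) |>
    dplyr::mutate(bin = paste0(.data$chromosome, ":", .data$bin_index))
}

#' Select bin representatives (pseudo-QTN candidates)
#'
#' For each non-empty bin, the representative is the marker with the
#' smallest first-stage p-value (ties broken by smaller position, then
#' lexicographic id); untestable markers (no-test sentinels) are
#' ineligible. Bins are ranked by their representative's p-value and the
#' top `s` representatives are returned in rank order.
#'
#' @param partition Output of [assign_bins()].
#' @param first_stage A `scan_result` covering the same markers (the
#'   preliminary scan, by default a GLM).
#' @param s Number of bins to select, `>= 1`; values beyond the number of
#'   non-empty bins saturate.
#' @return A `pseudo_qtn_set`: list with `markers` (ids, in rank order),
#'   `table` (tibble `marker`, `chromosome`, `position`, `first_stage_p`,
#'   `bin_index`), `s` (bins requested), `s_effective`, `b` (`NA` here;
#'   filled by [optimize_pseudo_qtns()]), `reml_loglik` (`NA` here).
#' @export
choose_representatives <- function(partition, first_stage, s) {
  if (!is.numeric(s) || length(s) != 1 || s < 1) {
    abort_validation("`s` must be a single integer >= 1.")
  }
  joined <- dplyr::inner_join(
    partition,
    tibble::tibble(id = first_stage$marker, p = first_stage$p_value),
    by = "id"
  ) |>
    dplyr::filter(!is.na(.data$p))
  if (nrow(joined) == 0) {
    rlang::abort("No testable markers to select representatives from.",
                 class = "supergwas_error_selection")
  }
  reps <- joined |>
    dplyr::arrange(.data$p, .data$position, .data$id) |>
    dplyr::distinct(.data$bin, .keep_all = TRUE) |>
    dplyr::arrange(.data$p, .data$position, .data$id)
  s_eff <- min(as.integer(s), nrow(reps))
  reps <- reps[seq_len(s_eff), , drop = FALSE]
  new_pseudo_qtn_set(
    markers = reps$id,
    table = tibble::tibble(
      marker = reps$id, chromosome = reps$chromosome,
      position = reps$position, first_stage_p = reps$p,
      bin_index = reps$bin_index
    ),
    s = as.integer(s), s_effective = s_eff, b = NA_real_,
    reml_loglik = NA_real_
  )
}

new_pseudo_qtn_set <- function(markers, table, s, s_effective, b,
                               reml_loglik, grid_log = NULL) {
  structure(
    list(markers = markers, table = table, s = s,
         s_effective = s_effective, b = b, reml_loglik = reml_loglik,
         grid_log = grid_log),
    class = "pseudo_qtn_set"
  )
}

#' @export
print.pseudo_qtn_set <- function(x, ...) {
  cat(sprintf(
    "<pseudo_qtn_set> %d pseudo-QTN(s)%s%s\n",
    length(x$markers),
    if (is.na(x$b)) "" else sprintf(" | optimized (s = %d, b = %g bp)", x$s, x$b),
    if (is.na(x$reml_loglik)) "" else sprintf(", REML ll = %.3f", x$reml_loglik)
  ))
  invisible(x)
}

#' Optimize the pseudo-QTN set over bin size and bin count
#'
#' For every `(s, b)` cell of the grid: partition the genome into bins of
#' `b` bp, pick the top `s` bin representatives from the first-stage scan,
#' build a VanRaden kinship from them, and record the restricted
#' log-likelihood of the no-marker mixed model under that kinship. The
#' cell with the maximal restricted likelihood wins (ties: smaller `s`,
#' then smaller `b`). `s` is capped at `n - rank(X) - 2` to keep the
#' variance-component fit identifiable, and at the number of non-empty
#' bins; capped cells are flagged in the grid log.
#'
#' @param G Imputed `genotype_matrix`.
#' @param y Trait vector.
#' @param first_stage A `scan_result` from the preliminary scan.
#' @param covariates Optional fixed-effect covariates.
#' @param s_grid Candidate bin counts.
#' @param b_grid Candidate bin sizes (bp).
#' @return A `pseudo_qtn_set` with the winning markers, `(s, b)`,
#'   `reml_loglik`, and the full grid in `$grid_log` (tibble `s`, `b`,
#'   `s_effective`, `reml_loglik`, `capped`).
#' @export
optimize_pseudo_qtns <- function(G, y, first_stage, covariates = NULL,
                                 s_grid = c(10, 20, 40, 80),
                                 b_grid = c(5e5, 5e6, 5e7)) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (length(s_grid) == 0 || length(b_grid) == 0) {
    abort_validation("`s_grid` and `b_grid` must be non-empty.")
  }
  spec <- model_spec(n_samples(G), covariates)
  s_cap <- n_samples(G) - spec$rank - 2L
  if (s_cap < 1) abort_input("Too few individuals to select any pseudo-QTN.")
  cells <- tidyr::expand_grid(s = sort(unique(as.integer(s_grid))),
                              b = sort(unique(as.numeric(b_grid))))
  best <- NULL
  log_rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    s_i <- cells$s[i]
    b_i <- cells$b[i]
    s_req <- min(s_i, s_cap)
    fit <- tryCatch({
      part <- assign_bins(G$map, b_i)
      pq <- choose_representatives(part, first_stage, s_req)
      K <- compute_kinship(G, markers = pq$markers, keep_crossproduct = FALSE)
      vc <- estimate_variance_components(y, K, spec)
      list(pq = pq, ll = vc$reml_loglik)
    }, error = function(e) NULL)
    ll <- if (is.null(fit)) NA_real_ else fit$ll
    s_eff <- if (is.null(fit)) NA_integer_ else fit$pq$s_effective
    log_rows[[i]] <- tibble::tibble(
      s = s_i, b = b_i, s_effective = s_eff, reml_loglik = ll,
      capped = !is.na(s_eff) && s_eff < s_i
    )
    # ties go to smaller s then smaller b: the sweep is s-major, b-minor
    # ascending, so keeping only strict improvements implements the rule
    if (!is.null(fit) && (is.null(best) || ll > best$ll)) {
      best <- list(pq = fit$pq, ll = ll, s = s_i, b = b_i)
    }
  }
  grid_log <- dplyr::bind_rows(log_rows)
  if (is.null(best)) {
    rlang::abort("Every (s, b) grid cell failed to produce a usable fit.",
                 class = "supergwas_error_optimization")
  }
  new_pseudo_qtn_set(
    markers = best$pq$markers, table = best$pq$table,
    s = best$s, s_effective = best$pq$s_effective, b = best$b,
    reml_loglik = best$ll, grid_log = grid_log
  )
}

#' Squared linkage-disequilibrium correlation between two markers
#'
#' The square of the Pearson correlation of the two dosage vectors; if
#' either vector is constant (monomorphic) the result is 0 by convention.
#'
#' @param g1,g2 Equal-length numeric dosage vectors (imputed).
#' @return r^2 in `[0, 1]`.
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) abort_dimension("Dosage vectors differ in length.")
  if (length(g1) < 2) abort_input("Need at least two samples for LD.")
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0) return(0)
  stats::cor(g1, g2)^2
}

# r^2 of every marker of G against the pseudo-QTN columns; monomorphic
# columns get 0 by the same convention as ld_r2().
ld_r2_matrix <- function(G, pseudo_idx) {
  W <- G$dosages
  P <- W[, pseudo_idx, drop = FALSE]
  sd_w <- apply(W, 2, stats::sd)
  sd_p <- apply(P, 2, stats::sd)
  r <- suppressWarnings(stats::cor(W, P))
  r[sd_w == 0, ] <- 0
  r[, sd_p == 0] <- 0
  r[is.na(r)] <- 0
  r^2
}

#' SUPER genome scan under complementary trait-specific kinship
#'
#' The final SUPER stage. Variance components are estimated once from the
#' kinship built on the full pseudo-QTN set (P3D). For each tested marker
#' m, the pseudo-QTNs whose genome-wide LD with m reaches `t`
#' (`r^2 >= t`) are excluded, the kinship is downdated to the remaining
#' pseudo-QTNs, and m is F-tested under the fixed variance components. A
#' marker in LD with every pseudo-QTN (including each pseudo-QTN itself,
#' whose self-r^2 is 1) falls back to a fixed-effects-only (GLM) test.
#' Markers sharing an exclusion set share one cached factorization.
#'
#' `t > 1` means "never exclude" (the scan then equals [mlm_scan()] under
#' the full pseudo-QTN kinship); `t = 0` excludes everything (the scan
#' then equals [glm_scan()]).
#'
#' @param G Imputed `genotype_matrix`.
#' @param y Trait vector.
#' @param pseudo A `pseudo_qtn_set`, or a vector of marker ids/indices
#'   (e.g. known QTNs) to use directly as the pseudo-QTN pool.
#' @param t LD exclusion threshold on r^2; default 0.10.
#' @param covariates Optional fixed-effect covariates.
#' @param p3d If `FALSE`, re-estimate variance components for every marker
#'   with the marker in the fixed effects (slow; the default reuses the
#'   single no-marker fit).
#' @return A `scan_result` tibble; `n_excluded` records the size of each
#'   marker's exclusion set.
#' @export
super_scan <- function(G, y, pseudo, t = 0.10, covariates = NULL,
                       p3d = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (inherits(pseudo, "pseudo_qtn_set")) pseudo <- pseudo$markers
  pseudo_idx <- resolve_index(pseudo, G$map$id, "marker")
  if (length(pseudo_idx) == 0) abort_input("`pseudo` must be non-empty.")
  if (!is.numeric(t) || length(t) != 1 || t < 0) {
    abort_validation("`t` must be a single non-negative number.")
  }
  spec <- model_spec(n_samples(G), covariates)
  K_full <- compute_kinship(G, markers = pseudo_idx, keep_crossproduct = TRUE)
  vc <- estimate_variance_components(y, K_full, spec)
  r2 <- ld_r2_matrix(G, pseudo_idx)
  excl_mask <- r2 >= t
  keys <- apply(excl_mask, 1, function(z) paste(which(z), collapse = ","))
  groups <- split(seq_len(n_markers(G)), keys)
  s_total <- length(pseudo_idx)
  tests <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    midx <- groups[[gi]]
    excl <- which(excl_mask[midx[1], ])
    n_ex <- length(excl)
    if (p3d) {
      ctx <- if (n_ex == s_total) {
        glm_context(spec)
      } else if (n_ex == 0) {
        make_p3d_context(vc, K_full, spec)
      } else {
        K_sub <- exclude_markers(K_full, G, G$map$id[pseudo_idx[excl]])
        make_p3d_context(vc, K_sub, spec)
      }
      tests[[gi]] <- gls_batch_test(ctx, y, G$dosages[, midx, drop = FALSE],
                                    G$map$id[midx], n_excluded = n_ex)
    } else {
      K_sub <- if (n_ex == 0) K_full else if (n_ex < s_total) {
        exclude_markers(K_full, G, G$map$id[pseudo_idx[excl]])
      } else NULL
      tests[[gi]] <- purrr::map_dfr(midx, function(j) {
        w <- G$dosages[, j]
        res <- super_exact_test(G, y, w, K_sub, covariates, spec)
        res$n_excluded <- n_ex
        res$marker <- G$map$id[j]
        res
      })
    }
  }
  out <- new_scan_result(dplyr::bind_rows(tests), G, "super",
                         K_full$marker_fingerprint, vc)
  out
}

# exact (non-P3D) SUPER test of one marker: re-estimate variance
# components with the marker among the fixed effects, then F-test it
super_exact_test <- function(G, y, w, K_sub, covariates, spec) {
  if (is.null(K_sub)) { # every pseudo-QTN excluded: fixed-effects test
    return(gls_batch_test(glm_context(spec), y, matrix(w, ncol = 1), "m"))
  }
  spec_m <- tryCatch(
    model_spec(n_samples(G),
               cbind(if (is.null(covariates)) NULL else as.matrix(covariates),
                     marker = w)),
    supergwas_error_validation = function(e) NULL
  )
  if (is.null(spec_m)) return(no_test_row("m", length(y), spec$rank))
  vc_m <- estimate_variance_components(y, K_sub, spec_m)
  gls_batch_test(make_p3d_context(vc_m, K_sub, spec), y,
                 matrix(w, ncol = 1), "m")
}

#' Export a pseudo-QTN set and its optimization grid
#'
#' Writes the selected markers as tab-separated
#' `marker chromosome position first_stage_p bin_index`; with
#' `grid_path`, also the `(s, b)` likelihood grid as `s b reml_loglik`.
#'
#' @param pseudo A `pseudo_qtn_set`.
#' @param path Output path for the marker table.
#' @param grid_path Optional output path for the grid log.
#' @return `path`, invisibly.
#' @export
write_pseudo_qtns <- function(pseudo, path, grid_path = NULL) {
  stopifnot(inherits(pseudo, "pseudo_qtn_set"))
  utils::write.table(as.data.frame(pseudo$table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(grid_path) && !is.null(pseudo$grid_log)) {
    utils::write.table(
      as.data.frame(pseudo$grid_log[, c("s", "b", "reml_loglik")]),
      grid_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}
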