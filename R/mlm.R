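#' Fixed-effect design specification
#'
#' Builds the fixed-effect design matrix X (intercept plus optional numeric
#' covariates) used by every scan. The random polygenic effect always maps
#' one individual to one effect (no grouping/compression), so only X needs
#' specifying.
#'
#' @param n Number of individuals.
#' @param covariates Optional numeric matrix or data frame of fixed-effect
#'   covariates (e.g. age, sex, body-mass index, structure PCs), one row per
#'   individual.
#' @return A `model_spec`: list with `X` (n x q design matrix) and `rank`.
#' @export
model_spec <- function(n, covariates = NULL) {
  X <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    cov <- as.matrix(covariates)
    if (!is.numeric(cov)) abort_validation("Covariates must be numeric.")
    if (nrow(cov) != n) {
      abort_dimension(sprintf(
        "Covariates have %d rows for %d individuals.", nrow(cov), n
      ))
    }
    if (is.null(colnames(cov))) {
      colnames(cov) <- paste0("cov", seq_len(ncol(cov)))
    }
    X <- cbind(X, cov)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    abort_validation("Fixed-effect design matrix is rank deficient.")
  }
  structure(list(X = X, rank = qr_x$rank), class = "model_spec")
}

#' Estimate variance components by spectral REML
#'
#' Maximizes the restricted likelihood of the mixed model
#' y = X b + u + e, with u ~ N(0, sigma_a^2 K) and e ~ N(0, sigma_e^2 I),
#' over the single ratio delta = sigma_e^2 / sigma_a^2 (the EMMA
#' reduction). The kinship is projected onto the residual space of X via an
#' orthonormal complement of X, eigendecomposed once, and the profiled
#' restricted log-likelihood is maximized on a grid uniform in ln(delta)
#' over \[-10, 10\] (100 points by default) followed by bounded scalar
#' refinement in every bracketing interval, to 1e-8 in ln(delta).
#'
#' @param y Numeric trait vector.
#' @param K A `kinship_matrix` over the same individuals.
#' @param spec A [model_spec()]; defaults to intercept only.
#' @param n_grid Number of ln(delta) grid points.
#' @param ln_delta_range Search interval for ln(delta).
#' @return A `variance_components` object: `sigma_a2`, `sigma_e2`, `delta`,
#'   `reml_loglik`, plus bookkeeping (`n`, `rank_x`).
#' @export
estimate_variance_components <- function(y, K, spec = NULL,
                                         n_grid = 100,
                                         ln_delta_range = c(-10, 10)) {
  stopifnot(inherits(K, "kinship_matrix"))
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(spec)) spec <- model_spec(n)
  X <- spec$X
  q <- spec$rank
  if (nrow(X) != n || nrow(K$values) != n) {
    abort_dimension("y, X and K must agree on the number of individuals.")
  }
  if (n <= q + 1) abort_input("Need n > rank(X) + 1 individuals.")
  qr_x <- qr(X)
  rss0 <- sum(qr.resid(qr_x, y)^2)
  if (rss0 <= 1e-12 * max(sum(y^2), 1)) {
    rlang::abort(
      "Trait is (numerically) perfectly explained by the fixed effects.",
      class = "supergwas_error_degenerate_fit"
    )
  }
  sp <- reml_spectral_parts(y, K, qr_x, n, q)
  opt <- reml_optimize_delta(sp$theta, sp$eta2, n - q, n_grid, ln_delta_range)
  delta <- exp(opt$ln_delta)
  sigma_a2 <- sum(sp$eta2 / (sp$theta + delta)) / (n - q)
  structure(
    list(
      sigma_a2 = sigma_a2,
      sigma_e2 = delta * sigma_a2,
      delta = delta,
      reml_loglik = opt$loglik,
      n = n,
      rank_x = q,
      kinship_fingerprint = K$marker_fingerprint
    ),
    class = "variance_components"
  )
}

# Projection of K to the residual space of X: theta are the n - q
# eigenvalues of Q2' K Q2 (equivalently of SKS restricted), eta the
# rotated residual data.
reml_spectral_parts <- function(y, K, qr_x, n, q) {
  Q2 <- qr.Q(qr_x, complete = TRUE)[, (q + 1):n, drop = FALSE]
  A <- crossprod(Q2, K$values %*% Q2)
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  theta <- eg$values
  if (min(theta) < -1e-8) {
    abort_input(sprintf(
      "Kinship is not positive semidefinite (projected eigenvalue %.3g).",
      min(theta)
    ))
  }
  theta[theta < 0] <- 0
  eta <- crossprod(eg$vectors, crossprod(Q2, y))
  list(theta = theta, eta2 = as.numeric(eta)^2)
}

reml_loglik_delta <- function(ln_delta, theta, eta2, nq) {
  d <- theta + exp(ln_delta)
  0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(sum(eta2 / d)) -
           sum(log(d)))
}

reml_optimize_delta <- function(theta, eta2, nq, n_grid, ln_delta_range) {
  grid <- seq(ln_delta_range[1], ln_delta_range[2], length.out = n_grid)
  ll <- vapply(grid, reml_loglik_delta, numeric(1),
               theta = theta, eta2 = eta2, nq = nq)
  step <- grid[2] - grid[1]
  # refine around every interior local maximum and at the boundaries
  cand_idx <- which(
    ll >= c(-Inf, ll[-n_grid]) & ll >= c(ll[-1], -Inf)
  )
  best <- list(ln_delta = grid[which.max(ll)], loglik = max(ll))
  for (i in cand_idx) {
    lo <- grid[max(i - 1, 1)]
    hi <- grid[min(i + 1, n_grid)]
    if (hi > lo) {
      o <- stats::optimize(reml_loglik_delta, c(lo, hi), maximum = TRUE,
                           tol = 1e-8, theta = theta, eta2 = eta2, nq = nq)
      if (o$objective > best$loglik) {
        best <- list(ln_delta = o$maximum, loglik = o$objective)
      }
    }
  }
  best
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> sigma_a2 = %.4g, sigma_e2 = %.4g, delta = %.4g\n  REML log-likelihood = %.4f (n = %d, rank(X) = %d)\n",
    x$sigma_a2, x$sigma_e2, x$delta, x$reml_loglik, x$n, x$rank_x
  ))
  invisible(x)
}

#' Build a reusable P3D test context
#'
#' Factorizes V = sigma_a^2 K + sigma_e^2 I once (spectrally), so that each
#' subsequent marker test is a generalized-least-squares fit at O(n^2)
#' without re-estimating the variance components — the P3D/EMMAX strategy.
#' Eigenvalues of V that underflow are floored at a relative 1e-12 of the
#' largest so the whitening transform stays finite.
#'
#' @param vc A `variance_components` fit (on the same trait/design).
#' @param K The `kinship_matrix` used for the fit, or `NULL` for a
#'   fixed-effects-only (V proportional to I) context.
#' @param spec The [model_spec()].
#' @return A `p3d_context` holding the whitening transform and the
#'   whitened design.
#' @export
make_p3d_context <- function(vc, K, spec) {
  n <- nrow(spec$X)
  if (is.null(K)) {
    transform <- NULL # identity whitening: V proportional to I
    X_star <- spec$X
  } else {
    stopifnot(inherits(K, "kinship_matrix"))
    if (nrow(K$values) != n) abort_dimension("K dimension does not match X.")
    eg <- kinship_eigen(K)
    v <- vc$sigma_a2 * eg$values + vc$sigma_e2
    v[v < max(v) * 1e-12] <- max(v) * 1e-12
    transform <- eg$vectors %*% (t(eg$vectors) / sqrt(v))
    X_star <- transform %*% spec$X
  }
  qr_x <- qr(X_star)
  structure(
    list(
      transform = transform,
      X_star = X_star,
      Qx = qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE],
      n = n,
      rank_x = spec$rank,
      vc = vc,
      kinship_fingerprint = if (is.null(K)) NA_character_ else K$marker_fingerprint
    ),
    class = "p3d_context"
  )
}

glm_context <- function(spec) {
  vc0 <- structure(
    list(sigma_a2 = 0, sigma_e2 = 1, delta = Inf, reml_loglik = NA_real_,
         n = nrow(spec$X), rank_x = spec$rank,
         kinship_fingerprint = NA_character_),
    class = "variance_components"
  )
  make_p3d_context(vc0, NULL, spec)
}

#' Test one marker by generalized least squares under a fixed context
#'
#' Fits \[X | w\] by GLS under the context's fixed V and returns the 1-df F
#' test of the marker effect, with denominator degrees of freedom
#' n - rank(X) - 1. A marker collinear with X (e.g. monomorphic) yields a
#' no-test sentinel row (`p_value = NA`, `reason` recorded) rather than an
#' error, so downstream power bookkeeping can distinguish "untestable"
#' from "not significant".
#'
#' @param ctx A `p3d_context`.
#' @param y Trait vector.
#' @param w Marker dosage vector.
#' @param marker_id Label for the output row.
#' @return A one-row tibble: `marker`, `effect`, `f_stat`, `df_num`,
#'   `df_den`, `p_value`, `n_excluded`, `reason`.
#' @export
test_marker_gls <- function(ctx, y, w, marker_id = "marker") {
  res <- gls_batch_test(ctx, y, matrix(as.numeric(w), ncol = 1), marker_id)
  res
}

# Vectorized GLS F-tests of many markers under one whitening transform.
gls_batch_test <- function(ctx, y, W, marker_ids,
                           n_excluded = 0L) {
  y <- as.numeric(y)
  if (length(y) != ctx$n) abort_dimension("Trait length does not match context.")
  if (nrow(W) != ctx$n) abort_dimension("Marker length does not match context.")
  if (is.null(ctx$transform)) {
    y_star <- y
    W_star <- W
  } else {
    y_star <- as.numeric(ctx$transform %*% y)
    W_star <- ctx$transform %*% W
  }
  Qx <- ctx$Qx
  y_res <- y_star - Qx %*% crossprod(Qx, y_star)
  rss0 <- sum(y_res^2)
  W_res <- W_star - Qx %*% crossprod(Qx, W_star)
  ww <- unname(colSums(W_res^2))
  wy <- as.numeric(crossprod(W_res, y_res))
  w_norm2 <- unname(colSums(W_star^2))
  collinear <- ww <= pmax(w_norm2, 1) * 1e-10
  df_den <- ctx$n - ctx$rank_x - 1L
  effect <- ifelse(collinear, NA_real_, wy / ww)
  rss1 <- pmax(rss0 - ifelse(collinear, 0, wy^2 / ww), 1e-300)
  f_stat <- ifelse(collinear, NA_real_, (rss0 - rss1) * df_den / rss1)
  p_value <- ifelse(
    collinear, NA_real_,
    pmax(stats::pf(f_stat, 1, df_den, lower.tail = FALSE),
         .Machine$double.xmin)
  )
  tibble::tibble(
    marker = as.character(marker_ids),
    effect = effect,
    f_stat = f_stat,
    df_num = 1L,
    df_den = df_den,
    p_value = p_value,
    n_excluded = as.integer(n_excluded),
    reason = ifelse(collinear, "collinear_with_fixed_effects", NA_character_)
  )
}

new_scan_result <- function(tests, G, method, kinship_fingerprint = NA_character_,
                            vc = NULL) {
  out <- dplyr::left_join(
    tibble::tibble(marker = G$map$id, chromosome = G$map$chromosome,
                   position = G$map$position),
    tests,
    by = "marker"
  )
  out$method <- method
  class(out) <- c("scan_result", class(out))
  attr(out, "provenance") <- list(
    method = method,
    kinship_fingerprint = kinship_fingerprint,
    variance_components = vc
  )
  out
}

#' Fixed-effects-only (GLM) genome scan
#'
#' Per-marker F tests with V proportional to the identity — no polygenic
#' random effect. Fast, but anticonservative in structured populations,
#' which is the motivating failure mode for the mixed-model scans.
#'
#' @param G An imputed, aligned `genotype_matrix`.
#' @param y Trait vector in `G`'s sample order.
#' @param covariates Optional numeric covariates (see [model_spec()]).
#' @return A `scan_result` tibble, one row per marker, with columns
#'   `marker`, `chromosome`, `position`, `effect`, `f_stat`, `df_num`,
#'   `df_den`, `p_value`, `n_excluded`, `reason`, `method`.
#' @export
glm_scan <- function(G, y, covariates = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  spec <- model_spec(n_samples(G), covariates)
  ctx <- glm_context(spec)
  tests <- gls_batch_test(ctx, y, G$dosages, G$map$id)
  new_scan_result(tests, G, "glm")
}

#' Mixed linear model genome scan
#'
#' MLM association scan under a genomic kinship. With `p3d = TRUE`
#' (default) the variance components are estimated once, without any
#' marker, and fixed for all tests (P3D/EMMAX). With `p3d = FALSE` they
#' are re-estimated for every marker with the marker in the fixed effects
#' (the exact EMMA treatment), at much higher cost.
#'
#' @inheritParams glm_scan
#' @param K A `kinship_matrix`; defaults to VanRaden kinship from all
#'   markers of `G`.
#' @param p3d Fix variance components after a single no-marker fit?
#' @return A `scan_result` tibble (see [glm_scan()]).
#' @export
mlm_scan <- function(G, y, K = NULL, covariates = NULL, p3d = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(K)) K <- compute_kinship(G, keep_crossproduct = FALSE)
  spec <- model_spec(n_samples(G), covariates)
  if (p3d) {
    vc <- estimate_variance_components(y, K, spec)
    ctx <- make_p3d_context(vc, K, spec)
    tests <- gls_batch_test(ctx, y, G$dosages, G$map$id)
    return(new_scan_result(tests, G, "mlm_p3d", K$marker_fingerprint, vc))
  }
  tests <- purrr::map_dfr(seq_len(n_markers(G)), function(j) {
    w <- G$dosages[, j]
    spec_m <- tryCatch(
      model_spec(n_samples(G),
                 cbind(if (is.null(covariates)) NULL else as.matrix(covariates),
                       marker = w)),
      supergwas_error_validation = function(e) NULL
    )
    if (is.null(spec_m)) {
      return(no_test_row(G$map$id[j], length(y), spec$rank))
    }
    vc_m <- estimate_variance_components(y, K, spec_m)
    ctx_m <- make_p3d_context(vc_m, K, spec)
    gls_batch_test(ctx_m, y, matrix(w, ncol = 1), G$map$id[j])
  })
  new_scan_result(tests, G, "mlm_exact", K$marker_fingerprint, NULL)
}

no_test_row <- function(marker_id, n, rank_x) {
  tibble::tibble(
    marker = marker_id, effect = NA_real_, f_stat = NA_real_, df_num = 1L,
    df_den = n - rank_x - 1L, p_value = NA_real_, n_excluded = 0L,
    reason = "collinear_with_fixed_effects"
  )
}

#' Write a genome scan as tab-separated text
#'
#' @param scan A `scan_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  cols <- c("marker", "chromosome", "position", "effect", "f_stat",
            "df_num", "df_den", "p_value", "n_excluded", "method")
  utils::write.table(as.data.frame(scan)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
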