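#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a variance-component fit
#'
#' @param x A `variance_components` object.
#' @param ... Unused.
#' @return One row per component (`sigma_a2`, `sigma_e2`) with its
#'   estimate.
#' @method tidy variance_components
#' @export
tidy.variance_components <- function(x, ...) {
  tibble::tibble(
    component = c("sigma_a2", "sigma_e2"),
    estimate = c(x$sigma_a2, x$sigma_e2)
  )
}

#' @rdname tidy.variance_components
#' @return For `glance()`: a one-row tibble with `sigma_a2`, `sigma_e2`,
#'   `delta`, `reml_loglik`, `heritability` (sigma_a2 / (sigma_a2 +
#'   sigma_e2)), `n`, `rank_x`.
#' @method glance variance_components
#' @export
glance.variance_components <- function(x, ...) {
  tibble::tibble(
    sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2, delta = x$delta,
    reml_loglik = x$reml_loglik,
    heritability = x$sigma_a2 / (x$sigma_a2 + x$sigma_e2),
    n = x$n, rank_x = x$rank_x
  )
}

#' Tidy a pseudo-QTN set
#'
#' @param x A `pseudo_qtn_set`.
#' @param ... Unused.
#' @return The per-marker table (`marker`, `chromosome`, `position`,
#'   `first_stage_p`, `bin_index`).
#' @method tidy pseudo_qtn_set
#' @export
tidy.pseudo_qtn_set <- function(x, ...) x$table

#' @rdname tidy.pseudo_qtn_set
#' @return For `glance()`: one row with `s`, `s_effective`, `b`,
#'   `reml_loglik`, `n_markers`.
#' @method glance pseudo_qtn_set
#' @export
glance.pseudo_qtn_set <- function(x, ...) {
  tibble::tibble(
    s = x$s, s_effective = x$s_effective, b = x$b,
    reml_loglik = x$reml_loglik, n_markers = length(x$markers)
  )
}

#' Tidy a power study
#'
#' @param x A `power_study_result`.
#' @param ... Unused.
#' @return The per-replicate long table (`method`, `rep`, `power`,
#'   `threshold`).
#' @method tidy power_study_result
#' @export
tidy.power_study_result <- function(x, ...) attr(x, "replicates")

#' @rdname tidy.power_study_result
#' @return For `glance()`: the per-method summary (mean power, standard
#'   error, replicate count).
#' @method glance power_study_result
#' @export
glance.power_study_result <- function(x, ...) tibble::as_tibble(x)

#' Tidy a genome scan
#'
#' A `scan_result` is already a tibble; `tidy()` strips the class and
#' drops the sentinel bookkeeping column, `glance()` summarises the scan.
#'
#' @param x A `scan_result`.
#' @param ... Unused.
#' @method tidy scan_result
#' @export
tidy.scan_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out[, setdiff(names(out), "reason")]
}

#' @rdname tidy.scan_result
#' @method glance scan_result
#' @export
glance.scan_result <- function(x, ...) {
  prov <- attr(x, "provenance")
  ok <- !is.na(x$p_value)
  tibble::tibble(
    method = prov$method,
    n_markers = nrow(x),
    n_tested = sum(ok),
    min_p = if (any(ok)) min(x$p_value[ok]) else NA_real_,
    lambda_gc = if (any(ok)) lambda_gc(x$p_value[ok]) else NA_real_
  )
}
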