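# broom-style tidiers for fitted objects

#' Tidy a kinetics trace fit
#'
#' @param x A `trace_fit` from [fit_trace()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @method tidy trace_fit
#' @export
tidy.trace_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(
    term = c("kc", "residual_fraction", "bleach_rate", "amplitude"),
    estimate = c(x$kc, x$model$residual_fraction, x$model$bleach_rate,
                 x$amplitude)
  )
}

#' @rdname tidy.trace_fit
#' @method glance trace_fit
#' @export
glance.trace_fit <- function(x, ...) {
  tibble::tibble(
    kc = x$kc,
    residual_fraction = if (x$converged) x$model$residual_fraction else
      NA_real_,
    bleach_rate = if (x$converged) x$model$bleach_rate else NA_real_,
    fit_rmse = x$fit_rmse,
    reduction_pct = x$reduction_pct,
    reduction_pct_bleach_corrected = x$reduction_pct_bleach_corrected,
    n = nrow(x$data),
    converged = x$converged
  )
}

#' Tidy a cross-reactivity report
#'
#' @param x A `crossreactivity_report` from [cross_reactivity()].
#' @param ... Unused.
#' @return `tidy()`: the per-pair run-length table; `glance()`: one row
#'   with `max_run`, `threshold`, `orthogonal`, `intra_set`.
#' @method tidy crossreactivity_report
#' @export
tidy.crossreactivity_report <- function(x, ...) {
  x$per_pair_scores
}

#' @rdname tidy.crossreactivity_report
#' @method glance crossreactivity_report
#' @export
glance.crossreactivity_report <- function(x, ...) {
  tibble::tibble(
    set_a = x$set_a, set_b = x$set_b, max_run = x$max_run,
    threshold = x$threshold, orthogonal = x$orthogonal,
    intra_set = x$intra_set
  )
}

#' Summarize a gate validation report
#'
#' @param x A `gate_validation` from [verify_gate()].
#' @param ... Unused.
#' @return One row: `gate`, `n_checks`, `n_passed`, `all_pass`.
#' @method glance gate_validation
#' @export
glance.gate_validation <- function(x, ...) {
  tibble::tibble(
    gate = attr(x, "gate"),
    n_checks = nrow(x),
    n_passed = sum(x$pass),
    all_pass = all(x$pass)
  )
}
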