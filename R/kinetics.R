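#' Pseudo-first-order displacement kinetics model
#'
#' During label exchange the invader is present in large excess over the
#' surface-bound dye-labeled template, so toehold-mediated displacement is
#' modeled as an irreversible pseudo-first-order reaction with effective rate
#' `k_disp * invader_conc`. A separable exponential photobleaching term
#' accounts for intensity loss before and during invader action, and a
#' residual fraction captures template that is never displaced.
#'
#' The default bimolecular rate constant (`1e5` per molar per second) is in
#' the range published for 8-nt toeholds; at micromolar invader
#' concentrations any value above a few thousand drives displacement to
#' saturation within minutes.
#'
#' @param k_disp Bimolecular displacement rate constant (M^-1 s^-1), > 0.
#' @param invader_conc Invader concentration (molar), >= 0.
#' @param bleach_rate Photobleaching rate (s^-1), >= 0.
#' @param residual_fraction Fraction of template never displaced, in `[0, 1]`.
#' @param t_invader Time at which invader is added (s), >= 0.
#' @return A `kinetics_model` list with the five fields above.
#' @examples
#' m <- kinetics_model(invader_conc = 4.87e-6)
#' displaced_fraction(320, m)     # essentially complete after 300 s
#' time_to_fraction(m, 0.95)      # seconds to 95 % removal
#' @export
kinetics_model <- function(k_disp = 1e5, invader_conc = 4.87e-6,
                           bleach_rate = 0, residual_fraction = 0,
                           t_invader = 20) {
  stopifnot(
    is.numeric(k_disp), length(k_disp) == 1L, k_disp > 0,
    is.numeric(invader_conc), invader_conc >= 0,
    is.numeric(bleach_rate), bleach_rate >= 0,
    is.numeric(residual_fraction),
    residual_fraction >= 0, residual_fraction <= 1,
    is.numeric(t_invader), t_invader >= 0
  )
  structure(
    list(k_disp = k_disp, invader_conc = invader_conc,
         bleach_rate = bleach_rate, residual_fraction = residual_fraction,
         t_invader = t_invader),
    class = "kinetics_model"
  )
}

#' @export
print.kinetics_model <- function(x, ...) {
  cat(sprintf(
    paste0("<kinetics model> k_disp %.3g /M/s, invader %.3g M ",
           "(k*c = %.4g /s), bleach %.3g /s, residual %.3g, ",
           "t_invader %.3g s\n"),
    x$k_disp, x$invader_conc, x$k_disp * x$invader_conc,
    x$bleach_rate, x$residual_fraction, x$t_invader))
  invisible(x)
}

#' Fraction of template displaced at time t
#'
#' Closed form
#' `(1 - residual) * (1 - exp(-k_disp * invader_conc * (t - t_invader)))`
#' for `t >= t_invader`.
#'
#' @param t Time in seconds (vectorized); must be `>= t_invader`.
#' @param model A [kinetics_model()].
#' @return Displaced fraction(s) in `[0, 1 - residual_fraction]`.
#' @export
displaced_fraction <- function(t, model) {
  stopifnot(inherits(model, "kinetics_model"))
  if (any(t < model$t_invader)) {
    abort("`t` must be >= t_invader (no invader present before then).",
          class = "seqstorm_domain_error")
  }
  kc <- model$k_disp * model$invader_conc
  (1 - model$residual_fraction) * (1 - exp(-kc * (t - model$t_invader)))
}

#' Relative fluorescence intensity at time t
#'
#' Photobleaching applies throughout; displacement only after the invader is
#' added: `exp(-bleach_rate * t)` for `t < t_invader`, and
#' `exp(-bleach_rate * t) * (1 - displaced_fraction(t))` afterwards.
#'
#' @inheritParams displaced_fraction
#' @return Relative intensity (1 at `t = 0` in the absence of bleaching).
#' @export
intensity_model <- function(t, model) {
  stopifnot(inherits(model, "kinetics_model"), all(t >= 0))
  bleach <- exp(-model$bleach_rate * t)
  post <- t >= model$t_invader
  out <- bleach
  if (any(post)) {
    out[post] <- bleach[post] * (1 - displaced_fraction(t[post], model))
  }
  out
}

#' Time for displacement to reach a given fraction
#'
#' Inverts [displaced_fraction()]:
#' `t_invader + (-log(1 - f / (1 - residual))) / (k_disp * invader_conc)`.
#' The returned value is seconds elapsed since invader addition.
#'
#' @param model A [kinetics_model()].
#' @param f Target displaced fraction, with `0 < f < 1 - residual_fraction`.
#' @return Seconds after invader addition needed to reach fraction `f`.
#' @export
time_to_fraction <- function(model, f) {
  stopifnot(inherits(model, "kinetics_model"))
  ceiling_f <- 1 - model$residual_fraction
  if (any(f <= 0) || any(f >= ceiling_f)) {
    abort(sprintf(
      "`f` must lie in (0, %.4g): fractions above 1 - residual are unreachable.",
      ceiling_f), class = "seqstorm_unreachable_fraction")
  }
  kc <- model$k_disp * model$invader_conc
  -log(1 - f / ceiling_f) / kc
}

#' Fit the displacement model to an invader time-course trace
#'
#' Fits [intensity_model()] to a normalized intensity trace in two stages,
#' mirroring how the acquisition is designed: the pre-invader segment (the
#' ~20 s imaged before invader addition) determines the photobleaching rate
#' by log-linear regression; the post-invader segment then determines the
#' effective displacement rate `k*c` and the residual fraction by bounded
#' Levenberg-Marquardt least squares with the bleach rate held fixed.
#' Starting values: `k*c` from the time at which the post-segment decays to
#' 1/e of its span, residual from the mean of the final 10 % of samples.
#'
#' @param times Strictly increasing sample times (s).
#' @param intensities Intensities (any scale; normalized internally to the
#'   trace maximum).
#' @param t_invader Time invader was added (s); must leave at least 10
#'   samples on each side.
#' @return A `trace_fit` object: list with `data` (tibble: `time_s`,
#'   `normalized_intensity`, `fitted`), `model` (the fitted
#'   [kinetics_model()]), `kc` (the identifiable product
#'   `k_disp * invader_conc`, s^-1), `fit_rmse`, `reduction_pct` and
#'   `reduction_pct_bleach_corrected` (percent drop from invader addition to
#'   the late-time plateau, raw and bleach-corrected), and `converged`. A
#'   non-convergent fit returns `converged = FALSE` with diagnostics in
#'   `diagnostics`, not an error.
#' @examples
#' m <- kinetics_model(k_disp = 1e5, invader_conc = 2e-7,
#'                     residual_fraction = 0.03)
#' t <- seq(0, 300, by = 0.5)
#' fit <- fit_trace(t, intensity_model(t, m), t_invader = 20)
#' glance(fit)
#' @export
fit_trace <- function(times, intensities, t_invader) {
  stopifnot(is.numeric(times), is.numeric(intensities),
            length(times) == length(intensities))
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    abort("`times` must be finite and strictly increasing.",
          class = "seqstorm_invalid_trace")
  }
  if (any(!is.finite(intensities)) || all(intensities == 0)) {
    abort("intensities must be finite and not all zero.",
          class = "seqstorm_invalid_trace")
  }
  pre <- times < t_invader
  if (sum(pre) < 10L || sum(!pre) < 10L) {
    abort("need >= 10 samples both before and after `t_invader`.",
          class = "seqstorm_invalid_trace")
  }
  y <- intensities / max(intensities)

  # photobleaching from the pre-invader segment (log-linear)
  ypre <- y[pre]
  ok <- ypre > 0
  bleach <- 0
  if (sum(ok) >= 2L) {
    slope <- coef(lm(log(ypre[ok]) ~ times[pre][ok]))[[2L]]
    bleach <- max(0, -slope)
  }

  tp <- times[!pre]
  yp <- y[!pre]
  # initial values per the staged design
  n_tail <- max(3L, ceiling(0.1 * length(yp)))
  y0 <- yp[1L]
  # keep the start strictly inside the bounds: res = 1 zeroes the kc
  # gradient and stalls the optimizer on degenerate (flat) traces
  res0 <- min(0.995, max(0.001, mean(tail(yp, n_tail)) /
                           max(y0, .Machine$double.eps)))
  span <- y0 - mean(tail(yp, n_tail))
  target <- y0 - (1 - exp(-1)) * span
  idx <- which(yp <= target)
  tau <- if (length(idx) > 0L) max(tp[idx[1L]] - t_invader,
                                   diff(range(tp)) / 100) else
    diff(range(tp)) / 2
  kc0 <- 1 / tau
  i0_0 <- max(y0 / exp(-bleach * tp[1L]), .Machine$double.eps)

  resid_fn <- function(par) {
    par["i0"] * exp(-bleach * tp) *
      (par["res"] + (1 - par["res"]) * exp(-par["kc"] * (tp - t_invader))) -
      yp
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(i0 = i0_0, kc = kc0, res = res0),
      lower = c(i0 = 1e-8, kc = 1e-8, res = 0),
      upper = c(i0 = Inf, kc = Inf, res = 1),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  # info codes 1:4 indicate convergence in the Levenberg-Marquardt sense
  if (!inherits(fit, "error") && !(fit$info %in% 1:4)) {
    fit <- simpleError(fit$message)
  }

  if (inherits(fit, "error")) {
    return(structure(
      list(data = tibble::tibble(time_s = times, normalized_intensity = y,
                                 fitted = NA_real_),
           model = NULL, kc = NA_real_, fit_rmse = NA_real_,
           reduction_pct = NA_real_,
           reduction_pct_bleach_corrected = NA_real_,
           converged = FALSE,
           diagnostics = list(message = conditionMessage(fit),
                              bleach_rate = bleach, start = list(
                                i0 = i0_0, kc = kc0, res = res0))),
      class = "trace_fit"
    ))
  }

  cf <- fit$par
  kc <- unname(cf[["kc"]])
  res <- unname(cf[["res"]])
  i0 <- unname(cf[["i0"]])
  model <- kinetics_model(
    k_disp = max(kc, 1e-12), invader_conc = 1, bleach_rate = bleach,
    residual_fraction = res, t_invader = t_invader
  )
  fitted_all <- i0 * intensity_model(times, model)
  rmse <- sqrt(mean((y - fitted_all)^2))

  # percent reduction from invader addition to the late plateau
  at_inv <- i0 * exp(-bleach * t_invader)
  t_end <- max(times)
  plateau_raw <- i0 * exp(-bleach * t_end) * res
  reduction <- 100 * (1 - plateau_raw / at_inv)
  reduction_bc <- 100 * (1 - res)

  structure(
    list(
      data = tibble::tibble(time_s = times, normalized_intensity = y,
                            fitted = fitted_all),
      model = model,
      kc = kc,
      amplitude = i0,
      fit_rmse = rmse,
      reduction_pct = reduction,
      reduction_pct_bleach_corrected = reduction_bc,
      converged = TRUE,
      diagnostics = list(iterations = fit$niter, info = fit$info,
                         message = fit$message)
    ),
    class = "trace_fit"
  )
}

#' @export
print.trace_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<trace fit: NOT converged>", x$diagnostics$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    paste0("<trace fit> k*c = %.4g /s, residual %.3g, bleach %.3g /s, ",
           "RMSE %.3g\n  reduction %.1f%% (%.1f%% bleach-corrected)\n"),
    x$kc, x$model$residual_fraction, x$model$bleach_rate, x$fit_rmse,
    x$reduction_pct, x$reduction_pct_bleach_corrected))
  invisible(x)
}

#' Read or write a two-column time/intensity trace
#'
#' Plain delimited text with header columns `time_s`, `intensity`.
#'
#' @param path File path.
#' @param trace A data frame with columns `time_s` and `intensity`.
#' @return `read_trace()` returns a tibble with those two columns.
#' @export
read_trace <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("time_s", "intensity") %in% names(out)))
  out
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(all(c("time_s", "intensity") %in% names(trace)))
  readr::write_csv(trace[, c("time_s", "intensity")], path)
  invisible(path)
}
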