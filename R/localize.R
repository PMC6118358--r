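#' Fitting and filtering configuration
#'
#' Defaults follow established single-molecule localization practice:
#' 7 x 7 pixel fitting ROIs, a fixed PSF width matching the simulator, 20
#' Newton-Raphson iterations, and the acceptance filters used for dSTORM
#' reconstruction — background at most 200 photons, at least 250 photons
#' per frame per emitter, and a data-model goodness-of-fit p-value cutoff
#' of 0.01. Thresholds are inclusive for acceptance.
#'
#' @param roi_size Odd ROI side length in pixels (>= 5).
#' @param psf_sigma PSF standard deviation in pixels (fixed during the fit).
#' @param max_iterations Newton-Raphson iterations.
#' @param detection_threshold Candidate threshold: estimated peak amplitude
#'   (photons above local background) on the band-passed image.
#' @param max_background Maximum accepted background (photons / pixel).
#' @param min_photons Minimum accepted photons per frame per emitter.
#' @param p_cutoff Minimum accepted goodness-of-fit p-value.
#' @return A `fit_config` list.
#' @export
fit_config <- function(roi_size = 7L, psf_sigma = 1.3, max_iterations = 20L,
                       detection_threshold = 10, max_background = 200,
                       min_photons = 250, p_cutoff = 0.01) {
  roi_size <- as.integer(roi_size)
  stopifnot(roi_size >= 5L, roi_size %% 2L == 1L, psf_sigma > 0,
            max_iterations >= 1L, detection_threshold >= 0,
            max_background >= 0, min_photons >= 0,
            p_cutoff >= 0, p_cutoff <= 1)
  structure(
    list(roi_size = roi_size, psf_sigma = psf_sigma,
         max_iterations = as.integer(max_iterations),
         detection_threshold = detection_threshold,
         max_background = max_background, min_photons = min_photons,
         p_cutoff = p_cutoff),
    class = "fit_config"
  )
}

# truncated, renormalized 1-D Gaussian blur as a band matrix, so that
# blur(X) = K %*% X (rows) / X %*% t(K) (cols); reflects nothing: edge
# kernels are renormalized over the in-image support
blur_matrix <- function(n, sigma) {
  hw <- ceiling(3 * sigma)
  idx <- seq_len(n)
  K <- matrix(0, n, n)
  for (i in idx) {
    j <- max(1L, i - hw):min(n, i + hw)
    w <- exp(-(j - i)^2 / (2 * sigma^2))
    K[i, j] <- w / sum(w)
  }
  K
}

#' Detect candidate emitters in one frame
#'
#' Band-pass filters the frame with a difference of Gaussians at
#' `psf_sigma` and `2 * psf_sigma`, calibrated so the response at an
#' emitter approximates its peak amplitude above background, then takes
#' local maxima above `detection_threshold`. Maxima closer than half an
#' ROI are merged keeping the brighter (ties: smaller row, then column);
#' candidates whose ROI would be clipped at a border are discarded.
#'
#' @param frame Matrix in photon units.
#' @param config A [fit_config()].
#' @param kernels Optional precomputed blur matrices (internal reuse).
#' @return Tibble with 0-based `row`, `col` ROI centers and the filter
#'   `response`.
#' @export
detect_candidates <- function(frame, config = fit_config(), kernels = NULL) {
  if (any(!is.finite(frame))) {
    abort("frame contains non-finite pixels.")
  }
  nr <- nrow(frame)
  nc <- ncol(frame)
  if (is.null(kernels)) {
    kernels <- list(
      r1 = blur_matrix(nr, config$psf_sigma),
      c1 = blur_matrix(nc, config$psf_sigma),
      r2 = blur_matrix(nr, 2 * config$psf_sigma),
      c2 = blur_matrix(nc, 2 * config$psf_sigma)
    )
  }
  # DoG of a unit-amplitude Gaussian spot has peak 1/2 - 1/5 = 0.3
  dog <- (kernels$r1 %*% frame %*% t(kernels$c1) -
            kernels$r2 %*% frame %*% t(kernels$c2)) / 0.3

  above <- dog > config$detection_threshold
  if (!any(above)) {
    return(tibble::tibble(row = integer(), col = integer(),
                          response = numeric()))
  }
  # strict local maxima over the 3x3 neighborhood
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- dog
  is_max <- above
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
      is_max <- is_max & (dog > nb | (dog == nb & (dr > 0 | (dr == 0 & dc > 0))))
    }
  }
  idx <- which(is_max, arr.ind = TRUE)
  cand <- tibble::tibble(row = unname(idx[, 1L]) - 1L,
                         col = unname(idx[, 2L]) - 1L,
                         response = unname(dog[idx]))
  cand <- dplyr::arrange(cand, dplyr::desc(.data$response), .data$row,
                         .data$col)
  # greedy merge: drop maxima within roi_size/2 of a brighter accepted one
  min_d2 <- (config$roi_size / 2)^2
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    prior <- which(keep)
    if (length(prior) == 0L ||
        all((cand$row[prior] - cand$row[i])^2 +
              (cand$col[prior] - cand$col[i])^2 >= min_d2)) {
      keep[i] <- TRUE
    }
  }
  cand <- cand[keep, ]
  h <- config$roi_size %/% 2L
  dplyr::filter(cand, .data$row >= h, .data$row <= nr - 1L - h,
                .data$col >= h, .data$col <= nc - 1L - h)
}

localization_columns <- function() {
  tibble::tibble(
    frame = integer(), x = numeric(), y = numeric(), photons = numeric(),
    background = numeric(), crlb_x = numeric(), crlb_y = numeric(),
    loglike = numeric(), pvalue = numeric()
  )
}

# fit a stack of ROIs (sz x sz x n array) and return localization rows in
# ROI coordinates (0-based; x = 3.0 is the center of ROI column 3)
fit_rois <- function(rois, config) {
  sz <- config$roi_size
  n <- length(rois) / (sz * sz)
  fit <- .mle_fit_rois(as.numeric(rois), sz, config$psf_sigma,
                       config$max_iterations)
  col <- function(name) unname(fit[, name])
  tibble::tibble(
    x = col("x"), y = col("y"),
    photons = col("photons"), background = col("background"),
    crlb_x = col("crlb_x"), crlb_y = col("crlb_y"),
    loglike = col("loglike"),
    pvalue = unname(pchisq(fit[, "llr"], df = sz^2 - 4,
                           lower.tail = FALSE)),
    fit_ok = col("ok") == 1
  )
}

#' Fit one ROI by maximum likelihood
#'
#' Fits the four-parameter model `mu_k = N * Ex_k * Ey_k + b` (integrated
#' Gaussian PSF of fixed width, uniform background) to a square pixel ROI
#' under the Poisson likelihood, by sequential per-parameter
#' Newton-Raphson. Precisions are Cramer-Rao lower bounds from the 4 x 4
#' Fisher information; goodness of fit is the likelihood-ratio deviance
#' referred to a chi-square law with `roi_size^2 - 4` degrees of freedom.
#'
#' @param roi Square matrix (`roi_size` x `roi_size`), photon units.
#' @param config A [fit_config()].
#' @return One-row localization tibble (ROI coordinates: `x = 3` is the
#'   center of ROI column 3, 0-based).
#' @export
fit_mle <- function(roi, config = fit_config()) {
  stopifnot(is.matrix(roi), nrow(roi) == config$roi_size,
            ncol(roi) == config$roi_size)
  fit_rois(array(roi, dim = c(dim(roi), 1L)), config)
}

#' Apply the localization acceptance filters
#'
#' A localization is accepted iff `background <= max_background` and
#' `photons >= min_photons` and `pvalue >= p_cutoff` (thresholds inclusive
#' for acceptance) and the fit itself was sound. Order is preserved,
#' fitted values are never mutated; the first failing criterion is
#' recorded as the rejection reason.
#'
#' @param locs Localization tibble.
#' @param config A [fit_config()].
#' @return `locs` with `accepted` and `reject_reason` columns.
#' @export
filter_localizations <- function(locs, config = fit_config()) {
  fit_ok <- if ("fit_ok" %in% names(locs)) locs$fit_ok else TRUE
  fit_ok <- fit_ok & is.finite(locs$photons) & is.finite(locs$pvalue) &
    is.finite(locs$crlb_x) & is.finite(locs$crlb_y)
  pass_bg <- locs$background <= config$max_background
  pass_ph <- locs$photons >= config$min_photons
  pass_p <- locs$pvalue >= config$p_cutoff
  reason <- rep(NA_character_, nrow(locs))
  reason[!pass_p] <- "pvalue"
  reason[!pass_ph] <- "min_photons"
  reason[!pass_bg] <- "max_background"
  reason[!fit_ok] <- "fit"
  dplyr::mutate(locs,
                accepted = fit_ok & pass_bg & pass_ph & pass_p,
                reject_reason = reason)
}

#' Localize every frame of a movie
#'
#' Runs detection, MLE fitting and filtering over all frames. Deterministic
#' given the input. ADU movies are converted to approximate photon units
#' with `(adu - offset) / adu_per_photon`, then halved to account for EM
#' excess noise in the Poisson likelihood (a documented approximation;
#' simulate in photon units when exactness matters).
#'
#' @param movie A `seqstorm_movie` (or bare 3-D array in photon units).
#' @param config A [fit_config()].
#' @return Localization tibble: `frame`, global 0-based sub-pixel `x`, `y`
#'   (pixels), `photons`, `background`, `crlb_x`, `crlb_y`, `loglike`,
#'   `pvalue`, `accepted`, `reject_reason`. Stage counts are in
#'   `attr(, "summary")`.
#' @export
localize_stack <- function(movie, config = fit_config()) {
  frames <- if (inherits(movie, "seqstorm_movie")) movie$frames else movie
  stopifnot(length(dim(frames)) == 3L)
  if (inherits(movie, "seqstorm_movie") && movie$units == "adu") {
    cam <- movie$camera
    frames <- pmax(0, (frames - cam$adu_offset) / cam$adu_per_photon) / 2
  }
  nr <- dim(frames)[1L]
  nc <- dim(frames)[2L]
  nf <- dim(frames)[3L]
  kernels <- list(
    r1 = blur_matrix(nr, config$psf_sigma),
    c1 = blur_matrix(nc, config$psf_sigma),
    r2 = blur_matrix(nr, 2 * config$psf_sigma),
    c2 = blur_matrix(nc, 2 * config$psf_sigma)
  )
  sz <- config$roi_size
  h <- sz %/% 2L

  cand_list <- vector("list", nf)
  for (f in seq_len(nf)) {
    cand <- detect_candidates(frames[, , f], config, kernels)
    if (nrow(cand) > 0L) cand$frame <- f
    cand_list[[f]] <- cand
  }
  cand <- dplyr::bind_rows(cand_list)
  n_cand <- nrow(cand)
  if (n_cand == 0L) {
    out <- filter_localizations(
      dplyr::mutate(localization_columns(), fit_ok = logical(0)), config)
    attr(out, "summary") <- list(n_frames = nf, n_candidates = 0L,
                                 n_fits = 0L, n_accepted = 0L)
    return(out)
  }

  rois <- array(0, dim = c(sz, sz, n_cand))
  for (i in seq_len(n_cand)) {
    r <- cand$row[i] + 1L   # back to 1-based matrix indices
    c <- cand$col[i] + 1L
    rois[, , i] <- frames[(r - h):(r + h), (c - h):(c + h), cand$frame[i]]
  }
  fit <- fit_rois(rois, config)
  locs <- dplyr::bind_cols(
    tibble::tibble(frame = cand$frame),
    dplyr::mutate(fit,
                  x = .data$x + cand$col - h,   # ROI -> global pixel coords
                  y = .data$y + cand$row - h)
  )
  out <- filter_localizations(locs, config)
  attr(out, "summary") <- list(
    n_frames = nf, n_candidates = n_cand, n_fits = nrow(out),
    n_accepted = sum(out$accepted)
  )
  out
}
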