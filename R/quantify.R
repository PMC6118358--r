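#' Render a super-resolution image
#'
#' Each accepted localization is drawn as a unit-mass anisotropic 2-D
#' Gaussian centered at its fitted position with `sigma_x`, `sigma_y` equal
#' to its localization precisions (the CRLBs), truncated at 5 sigma and
#' renormalized so every rendered localization contributes exactly unit
#' integral to the image. Localizations with a precision worse than one
#' camera pixel are rendered but flagged, never silently dropped.
#'
#' @param locs Localization tibble with `x`, `y`, `crlb_x`, `crlb_y`
#'   (camera-pixel units). Only rows with `accepted == TRUE` are rendered
#'   when the column is present.
#' @param zoom Super-resolution pixels per camera pixel (default 10).
#' @param extent Camera-pixel extent `c(xmin, xmax, ymin, ymax)` covered by
#'   the image; defaults to the bounding box of the localizations padded by
#'   one pixel.
#' @return An `sr_image`: list with `img` (matrix, SR pixels), `zoom`,
#'   `extent`, `n_rendered`, and `n_flagged` (precision worse than one
#'   camera pixel).
#' @export
render <- function(locs, zoom = 10, extent = NULL) {
  if ("accepted" %in% names(locs)) {
    locs <- dplyr::filter(locs, .data$accepted)
  }
  if (nrow(locs) == 0L) {
    warn("no localizations to render; returning a zero image.")
    extent <- extent %||% c(0, 1, 0, 1)
    nx <- max(1L, round((extent[2] - extent[1]) * zoom))
    ny <- max(1L, round((extent[4] - extent[3]) * zoom))
    return(structure(list(img = matrix(0, ny, nx), zoom = zoom,
                          extent = extent, n_rendered = 0L, n_flagged = 0L),
                     class = "sr_image"))
  }
  stopifnot(all(is.finite(locs$crlb_x)), all(is.finite(locs$crlb_y)))
  extent <- extent %||% c(floor(min(locs$x)) - 1, ceiling(max(locs$x)) + 1,
                          floor(min(locs$y)) - 1, ceiling(max(locs$y)) + 1)
  nx <- round((extent[2] - extent[1]) * zoom)
  ny <- round((extent[4] - extent[3]) * zoom)
  img <- matrix(0, ny, nx)
  # SR pixel centers in camera-pixel coordinates
  xs <- extent[1] + (seq_len(nx) - 0.5) / zoom
  ys <- extent[3] + (seq_len(ny) - 0.5) / zoom
  n_flagged <- 0L
  for (i in seq_len(nrow(locs))) {
    sx <- locs$crlb_x[i]
    sy <- locs$crlb_y[i]
    if (sx > 1 || sy > 1) n_flagged <- n_flagged + 1L
    cx <- which(abs(xs - locs$x[i]) <= 5 * sx)
    cy <- which(abs(ys - locs$y[i]) <= 5 * sy)
    if (length(cx) == 0L || length(cy) == 0L) next
    gx <- exp(-(xs[cx] - locs$x[i])^2 / (2 * sx^2))
    gy <- exp(-(ys[cy] - locs$y[i])^2 / (2 * sy^2))
    patch <- gy %o% gx
    img[cy, cx] <- img[cy, cx] + patch / sum(patch)
  }
  structure(
    list(img = img, zoom = zoom, extent = extent,
         n_rendered = nrow(locs), n_flagged = n_flagged),
    class = "sr_image"
  )
}

#' @export
print.sr_image <- function(x, ...) {
  cat(sprintf("<SR image> %d x %d SR px (zoom %g), %d localizations (mass %.1f)\n",
              nrow(x$img), ncol(x$img), x$zoom, x$n_rendered, sum(x$img)))
  invisible(x)
}

#' Write an SR image to 32-bit float TIFF
#'
#' @param sr An `sr_image`.
#' @param path Output path.
#' @export
write_sr_image <- function(sr, path) {
  stopifnot(inherits(sr, "sr_image"))
  tiff::writeTIFF(sr$img / max(sr$img, 1e-12), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' Frame-sum intensity trace of a movie
#'
#' Reproduces the time-course processing used for invader kinetics: from
#' each frame subtract a scalar background offset estimated as a pixel
#' percentile (default 20th), clamp at zero, sum the frame, and normalize
#' the trace to its maximum.
#'
#' @param movie A `seqstorm_movie` (or 3-D array); needs at least 2 frames.
#' @param background_percentile Percentile (0-100) used as the scalar
#'   offset.
#' @param frame_rate Frames per second; taken from the movie's `times`
#'   attribute or camera when available.
#' @return Tibble: `time_s`, `intensity` (background-subtracted frame sum),
#'   `normalized_intensity`.
#' @export
movie_to_trace <- function(movie, background_percentile = 20,
                           frame_rate = NULL) {
  frames <- if (inherits(movie, "seqstorm_movie")) movie$frames else movie
  stopifnot(length(dim(frames)) == 3L)
  nf <- dim(frames)[3L]
  if (nf < 2L) {
    abort("movie must have at least 2 frames to form a trace.")
  }
  times <- attr(movie, "times", exact = TRUE)
  if (is.null(times)) {
    fr <- frame_rate %||%
      (if (inherits(movie, "seqstorm_movie")) movie$camera$frame_rate else 1)
    times <- (seq_len(nf) - 1L) / fr
  }
  sums <- vapply(seq_len(nf), function(f) {
    fr <- frames[, , f]
    off <- quantile(fr, background_percentile / 100, names = FALSE)
    sum(pmax(fr - off, 0))
  }, numeric(1))
  # a constant movie yields a constant trace; its normalized form is 1
  # everywhere (the offset estimator absorbs the whole signal)
  norm <- if (max(sums) > 0) sums / max(sums) else rep(1, nf)
  tibble::tibble(
    time_s = times,
    intensity = sums,
    normalized_intensity = norm
  )
}

#' Residual cross-talk from before/after localization counts
#'
#' The cross-talk of an invader step is the ratio of the number of accepted
#' localizations after invader treatment to the number before, from
#' equal-length acquisitions filtered with the same configuration (counts
#' scale with acquisition length, so matched lengths are required for the
#' ratio to be meaningful).
#'
#' @param locs_before,locs_after Localization tibbles (only `accepted` rows
#'   are counted when the column is present), or bare counts.
#' @return A `crosstalk_result` tibble row: `n_before`, `n_after`, `ratio`,
#'   `percent`.
#' @examples
#' crosstalk(1000, 20)   # 2 % residual
#' @export
crosstalk <- function(locs_before, locs_after) {
  count <- function(x) {
    if (is.numeric(x) && length(x) == 1L) return(as.integer(x))
    if ("accepted" %in% names(x)) sum(x$accepted) else nrow(x)
  }
  n_before <- count(locs_before)
  n_after <- count(locs_after)
  if (n_before <= 0L) {
    abort("n_before must be > 0: cross-talk ratio undefined.",
          class = "seqstorm_undefined_ratio")
  }
  out <- tibble::tibble(
    n_before = n_before, n_after = n_after,
    ratio = n_after / n_before,
    percent = 100 * n_after / n_before
  )
  class(out) <- c("crosstalk_result", class(out))
  out
}

#' Accepted localization counts per imaging round
#'
#' Tallies accepted localizations per (round, target) and summarizes the
#' consistency of relabeling as the coefficient of variation of counts
#' across rounds for each target (`NA` when a target was imaged once).
#'
#' @param locs Localization tibble with `round` and `target_id` columns
#'   (e.g. from [run_experiment()]).
#' @return List with `counts` (tibble: `round`, `target_id`, `n`) and
#'   `dispersion` (tibble: `target_id`, `n_rounds`, `mean_n`, `sd_n`,
#'   `cv`).
#' @export
round_counts <- function(locs) {
  stopifnot(all(c("round", "target_id") %in% names(locs)))
  if ("accepted" %in% names(locs)) {
    locs <- dplyr::filter(locs, .data$accepted)
  }
  counts <- dplyr::count(locs, .data$round, .data$target_id, name = "n")
  dispersion <- counts |>
    dplyr::group_by(.data$target_id) |>
    dplyr::summarise(
      n_rounds = dplyr::n(),
      mean_n = mean(.data$n),
      sd_n = ifelse(dplyr::n() > 1L, sd(.data$n), NA_real_),
      cv = ifelse(dplyr::n() > 1L, sd(.data$n) / mean(.data$n), NA_real_),
      .groups = "drop"
    )
  list(counts = counts, dispersion = dispersion)
}

#' Estimate the shift between two reference images
#'
#' Computational replacement for hardware re-alignment between rounds:
#' finds the integer shift maximizing the cross-correlation of the
#' mean-subtracted images (via FFT), then refines to sub-pixel precision by
#' parabolic interpolation of the correlation peak. Applying `(-dx, -dy)`
#' to the second round's localizations aligns the rounds.
#'
#' @param ref_a,ref_b Matrices of identical size with overlapping content.
#' @return List with `dx`, `dy` (pixels): `ref_b` is `ref_a` shifted by
#'   `(dx, dy)` (x right / columns, y down / rows).
#' @export
register_rounds <- function(ref_a, ref_b) {
  stopifnot(is.matrix(ref_a), is.matrix(ref_b),
            all(dim(ref_a) == dim(ref_b)))
  a <- ref_a - mean(ref_a)
  b <- ref_b - mean(ref_b)
  if (sd(a) == 0 || sd(b) == 0) {
    abort("flat reference image: registration impossible.",
          class = "seqstorm_registration_failure")
  }
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  nr <- nrow(cc)
  nc <- ncol(cc)
  peak <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)   # 0-based lag
  # parabolic sub-pixel refinement around the peak (circular neighbors)
  ref1d <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else 0.5 * (cm - cp) / den
  }
  pr <- peak[1L]
  pc <- peak[2L]
  idx <- function(i, n) ((i - 1L) %% n) + 1L
  dr <- ref1d(cc[idx(pr - 1L, nr), pc], cc[pr, pc], cc[idx(pr + 1L, nr), pc])
  dc <- ref1d(cc[pr, idx(pc - 1L, nc)], cc[pr, pc], cc[pr, idx(pc + 1L, nc)])
  list(dx = unname(wrap(pc - 1L, nc) + dc),
       dy = unname(wrap(pr - 1L, nr) + dr))
}
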