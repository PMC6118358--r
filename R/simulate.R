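# Synthetic multi-round dSTORM acquisition: blinking photophysics,
# integrated-Gaussian image formation, Poisson photon statistics, optional
# EMCCD readout.

#' Camera model
#'
#' Defaults follow a typical EMCCD dSTORM configuration: 0.1067 um pixels,
#' EM gain 100, 256 x 256 frames at 60 Hz. Movies are generated in photon
#' units by default; the EMCCD stage ("adu" units) models gamma-distributed
#' electron multiplication, an ADU offset and Gaussian read noise.
#'
#' @param pixel_size_um Pixel size (micrometers).
#' @param em_gain Electron-multiplying gain (>= 1).
#' @param adu_offset Camera offset (counts).
#' @param adu_per_photon Net conversion (counts per photon at the set gain).
#' @param read_noise Read noise (counts RMS).
#' @param frame_size Frame side length (pixels).
#' @param frame_rate Acquisition rate (Hz).
#' @return A `camera_model` list.
#' @export
camera_model <- function(pixel_size_um = 0.1067, em_gain = 100,
                         adu_offset = 100, adu_per_photon = 5,
                         read_noise = 10, frame_size = 256L,
                         frame_rate = 60) {
  stopifnot(pixel_size_um > 0, em_gain >= 1, frame_size >= 8,
            adu_per_photon > 0, read_noise >= 0, frame_rate > 0)
  structure(
    list(pixel_size_um = pixel_size_um, em_gain = em_gain,
         adu_offset = adu_offset, adu_per_photon = adu_per_photon,
         read_noise = read_noise, frame_size = as.integer(frame_size),
         frame_rate = frame_rate),
    class = "camera_model"
  )
}

#' Blinking photophysics parameters
#'
#' Minimal dSTORM-like switching model: each dark emitter activates per
#' frame with probability `p_on`, stays on for a geometric number of frames
#' with mean `mean_on_frames`, and bleaches permanently with probability
#' `bleach_prob` per on-frame. While on it emits `photons_per_frame`
#' expected photons.
#'
#' @param p_on Per-frame activation probability of a dark emitter.
#' @param mean_on_frames Mean on-time in frames (>= 1).
#' @param photons_per_frame Expected photons per frame while on.
#' @param bleach_prob Per-on-frame permanent bleaching probability.
#' @return A `photophysics_params` list.
#' @export
photophysics_params <- function(p_on = 5e-4, mean_on_frames = 3,
                                photons_per_frame = 800, bleach_prob = 0) {
  stopifnot(p_on >= 0, p_on <= 1, mean_on_frames >= 1,
            photons_per_frame > 0, bleach_prob >= 0, bleach_prob <= 1)
  structure(
    list(p_on = p_on, mean_on_frames = mean_on_frames,
         photons_per_frame = photons_per_frame, bleach_prob = bleach_prob),
    class = "photophysics_params"
  )
}

#' Labeling specification for one imaging round
#'
#' @param round_index Round number (1-based).
#' @param target_id Which target's sites receive fresh dye this round.
#' @param label_prob Fraction of the target's sites carrying a fresh dye.
#' @param carryover_residual Fraction of the previous round's labeled sites
#'   still dye-bound this round (models incomplete invader displacement,
#'   i.e. the source of residual cross-talk).
#' @return A `round_spec` list.
#' @export
round_spec <- function(round_index, target_id, label_prob = 1,
                       carryover_residual = 0) {
  stopifnot(round_index >= 1, label_prob >= 0, label_prob <= 1,
            carryover_residual >= 0, carryover_residual <= 1)
  structure(
    list(round_index = as.integer(round_index),
         target_id = as.integer(target_id),
         label_prob = label_prob, carryover_residual = carryover_residual),
    class = "round_spec"
  )
}

#' Construct a movie stack
#'
#' @param frames 3-D array `[row, col, frame]`, non-negative.
#' @param camera A [camera_model()].
#' @param units `"photons"` or `"adu"`.
#' @return A `seqstorm_movie` list with `frames`, `camera`, `units`,
#'   `n_frames`.
#' @export
movie_stack <- function(frames, camera, units = c("photons", "adu")) {
  units <- match.arg(units)
  stopifnot(length(dim(frames)) == 3L, all(frames >= 0))
  structure(
    list(frames = frames, camera = camera, units = units,
         n_frames = dim(frames)[3L]),
    class = "seqstorm_movie"
  )
}

#' @export
print.seqstorm_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie> %d frames of %d x %d px (%s units), %.4f um/px\n",
              d[3L], d[1L], d[2L], x$units, x$camera$pixel_size_um))
  invisible(x)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# integrated-Gaussian pixel weights along one axis for pixel centers `k`
# (0-based) and emitter coordinate `pos` (pixel units)
int_gauss_1d <- function(k, pos, sigma) {
  s <- sqrt(2) * sigma
  0.5 * (erf((k - pos + 0.5) / s) - erf((k - pos - 0.5) / s))
}

# expected-photon patch for one emitter; returns rows/cols (1-based matrix
# indices into the frame) and the patch matrix, clipped to the frame
psf_patch <- function(x_px, y_px, photons, sigma, nrow_px, ncol_px,
                      half_width = NULL) {
  hw <- half_width %||% ceiling(4 * sigma + 1)
  cols <- max(0, floor(x_px) - hw):min(ncol_px - 1, floor(x_px) + hw)
  rows <- max(0, floor(y_px) - hw):min(nrow_px - 1, floor(y_px) + hw)
  if (length(cols) == 0L || length(rows) == 0L) return(NULL)
  ex <- int_gauss_1d(cols, x_px, sigma)
  ey <- int_gauss_1d(rows, y_px, sigma)
  list(rows = rows + 1L, cols = cols + 1L,
       patch = photons * (ey %o% ex))
}

# simulate the on/off/bleach state sequence for `n_sites` emitters over
# `n_frames` frames; returns logical matrix [site, frame]
blink_states <- function(n_sites, n_frames, ph) {
  on <- matrix(FALSE, n_sites, n_frames)
  if (n_sites == 0L) return(on)
  state <- integer(n_sites)            # 0 dark, 1 on, 2 bleached
  p_stay <- 1 - 1 / ph$mean_on_frames  # geometric on-times, mean as given
  for (f in seq_len(n_frames)) {
    dark <- state == 0L
    if (any(dark)) {
      state[dark][runif(sum(dark)) < ph$p_on] <- 1L
    }
    lit <- state == 1L
    on[lit, f] <- TRUE
    if (any(lit)) {
      u <- runif(sum(lit))
      idx <- which(lit)
      bleached <- u < ph$bleach_prob
      turn_off <- !bleached & (runif(sum(lit)) > p_stay)
      state[idx[bleached]] <- 2L
      state[idx[turn_off]] <- 0L
    }
  }
  on
}

# choose which sites are dye-bound this round: fresh labeling of the
# round's target plus binomial carryover from the previous round
labeled_sites <- function(scene, spec, prev_labeled) {
  target_sites <- scene$sites$site_id[scene$sites$target_id == spec$target_id]
  fresh <- target_sites[runif(length(target_sites)) < spec$label_prob]
  carry <- integer(0)
  if (!is.null(prev_labeled) && spec$carryover_residual > 0) {
    prev <- setdiff(prev_labeled, fresh)
    carry <- prev[runif(length(prev)) < spec$carryover_residual]
  }
  sort(unique(c(fresh, carry)))
}

#' Simulate one imaging round
#'
#' Labels the round's target (plus binomial carryover from the previous
#' round's labeled sites), runs the blinking process, and forms images:
#' while an emitter is on, each pixel's expected value is
#' `N * Ex * Ey + b` with integrated-Gaussian factors `Ex`, `Ey` (error
#' function differences over the pixel edges) of width `psf_sigma`; photon
#' counts are Poisson draws. With `units = "adu"` the EMCCD stage is
#' applied on top.
#'
#' @param scene A [make_scene()] scene.
#' @param spec A [round_spec()].
#' @param photophysics A [photophysics_params()].
#' @param camera A [camera_model()].
#' @param n_frames Number of frames.
#' @param seed Integer seed (all randomness in the round derives from it).
#' @param background Uniform background (photons / pixel / frame).
#' @param psf_sigma PSF standard deviation in pixels.
#' @param prev_labeled Site ids labeled in the previous round (for
#'   carryover); `NULL` for the first round.
#' @param units Output units, `"photons"` (default) or `"adu"`.
#' @return List with `movie` (a `seqstorm_movie`), `truth` (tibble of every
#'   on-event: `frame`, `site_id`, `target_id`, `x_px`, `y_px`, `photons`,
#'   `round`), and `labeled` (the dye-bound site ids this round).
#' @export
simulate_round <- function(scene, spec, photophysics, camera,
                           n_frames, seed, background = 5,
                           psf_sigma = 1.3, prev_labeled = NULL,
                           units = c("photons", "adu")) {
  units <- match.arg(units)
  stopifnot(inherits(scene, "seqstorm_scene"), inherits(spec, "round_spec"),
            n_frames >= 1, background >= 0, psf_sigma > 0)
  if (psf_sigma < 0.5) {
    warn("psf_sigma < 0.5 pixel: the PSF is undersampled.")
  }
  npx <- camera$frame_size
  with_seed(seed, {
    lab <- labeled_sites(scene, spec, prev_labeled)
    sites <- scene$sites[match(lab, scene$sites$site_id), ]
    x_px <- sites$x_um / camera$pixel_size_um
    y_px <- sites$y_um / camera$pixel_size_um
    on <- blink_states(nrow(sites), n_frames, photophysics)
    patches <- purrr::map(seq_len(nrow(sites)), function(i) {
      psf_patch(x_px[i], y_px[i], photophysics$photons_per_frame,
                psf_sigma, npx, npx)
    })
    frames <- array(0, dim = c(npx, npx, n_frames))
    truth <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      mu <- matrix(background, npx, npx)
      lit <- which(on[, f])
      for (i in lit) {
        p <- patches[[i]]
        if (!is.null(p)) mu[p$rows, p$cols] <- mu[p$rows, p$cols] + p$patch
      }
      frames[, , f] <- rpois(npx * npx, mu)
      if (length(lit) > 0L) {
        truth[[f]] <- tibble::tibble(
          frame = f, site_id = sites$site_id[lit],
          target_id = sites$target_id[lit],
          x_px = x_px[lit], y_px = y_px[lit],
          photons = photophysics$photons_per_frame,
          round = spec$round_index
        )
      }
    }
    truth <- dplyr::bind_rows(truth)
    if (nrow(truth) == 0L) {
      truth <- tibble::tibble(
        frame = integer(), site_id = integer(), target_id = integer(),
        x_px = numeric(), y_px = numeric(), photons = numeric(),
        round = integer()
      )
    }
    if (units == "adu") frames <- photons_to_adu(frames, camera)
    list(movie = movie_stack(frames, camera, units), truth = truth,
         labeled = lab)
  })
}

photons_to_adu <- function(frames, camera) {
  n <- length(frames)
  electrons <- numeric(n)
  pos <- frames > 0
  # gamma EM-multiplication noise: shape = photon count, scale = em_gain
  electrons[pos] <- rgamma(sum(pos), shape = frames[pos],
                           scale = camera$em_gain)
  adu <- camera$adu_offset + electrons * camera$adu_per_photon /
    camera$em_gain + rnorm(n, 0, camera$read_noise)
  array(pmax(0, round(adu)), dim = dim(frames))
}

#' Simulate an invader time-course movie
#'
#' Emulates the low-excitation 2 Hz acquisition used to follow invader
#' action: every dye-bound site emits continuously (no blinking); each
#' site's dye is displaced at an exponential random time after
#' `t_invader` with rate `k_disp * invader_conc`, except a
#' `residual_fraction` that is never displaced; photobleaching scales the
#' emission of every bound dye by `exp(-bleach_rate * t)`. The expected
#' frame-sum trace therefore follows [intensity_model()].
#'
#' @param scene A [make_scene()] scene; all sites are dye-bound at t = 0.
#' @param model A [kinetics_model()].
#' @param camera A [camera_model()].
#' @param duration Total duration (s); must cover `t_invader`.
#' @param seed Integer seed.
#' @param frame_rate Frames per second (default 2).
#' @param photons_per_frame Expected photons per site per frame at t = 0.
#' @param background Uniform background (photons / pixel / frame).
#' @param psf_sigma PSF standard deviation (pixels).
#' @return A `seqstorm_movie` with attribute `times` (frame times, s).
#' @export
simulate_timecourse_movie <- function(scene, model, camera, duration, seed,
                                      frame_rate = 2, photons_per_frame = 400,
                                      background = 2, psf_sigma = 1.3) {
  stopifnot(inherits(scene, "seqstorm_scene"),
            inherits(model, "kinetics_model"),
            duration > model$t_invader)
  npx <- camera$frame_size
  times <- seq(0, duration, by = 1 / frame_rate)
  kc <- model$k_disp * model$invader_conc
  with_seed(seed, {
    n <- nrow(scene$sites)
    x_px <- scene$sites$x_um / camera$pixel_size_um
    y_px <- scene$sites$y_um / camera$pixel_size_um
    never <- runif(n) < model$residual_fraction
    t_disp <- model$t_invader + stats::rexp(n, rate = max(kc, 1e-300))
    t_disp[never] <- Inf
    # base expected image with every site bound, unit bleach factor
    base <- matrix(0, npx, npx)
    patches <- purrr::map(seq_len(n), function(i) {
      psf_patch(x_px[i], y_px[i], photons_per_frame, psf_sigma, npx, npx)
    })
    for (p in patches) {
      if (!is.null(p)) base[p$rows, p$cols] <- base[p$rows, p$cols] + p$patch
    }
    frames <- array(0, dim = c(npx, npx, length(times)))
    current <- base
    ord <- order(t_disp)
    k <- 1L
    for (f in seq_along(times)) {
      t <- times[f]
      while (k <= n && t_disp[ord[k]] <= t) {
        p <- patches[[ord[k]]]
        if (!is.null(p)) {
          current[p$rows, p$cols] <- current[p$rows, p$cols] - p$patch
        }
        k <- k + 1L
      }
      mu <- background + pmax(current, 0) * exp(-model$bleach_rate * t)
      frames[, , f] <- rpois(npx * npx, mu)
    }
    out <- movie_stack(frames, camera, "photons")
    attr(out, "times") <- times
    out
  })
}
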