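# Orchestration of the full in-silico sequential imaging experiment:
# simulate N label-image-remove rounds, localize, filter, register, render,
# and report cross-talk and per-round counts from one config.

# parse "4.87 uM" / "300 nM" / "0.5 mM" / numeric -> molar
parse_molar <- function(x, key) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec(
    "^\\s*([0-9.eE+-]+)\\s*(M|mM|uM|µM|μM|nM|pM)\\s*$", x))[[1L]]
  if (length(m) == 0L) {
    abort(sprintf("%s: cannot parse concentration '%s' (expected e.g. '4.87 uM').",
                  key, x), class = "seqstorm_config_error")
  }
  mult <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, "μM" = 1e-6,
            nM = 1e-9, pM = 1e-12)[[m[3L]]]
  as.numeric(m[2L]) * mult
}

# parse "5 min" / "20 s" / "1 h" / numeric -> seconds
parse_seconds <- function(x, key) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*(s|sec|min|h)\\s*$",
                             x))[[1L]]
  if (length(m) == 0L) {
    abort(sprintf("%s: cannot parse time '%s' (expected e.g. '20 s', '5 min').",
                  key, x), class = "seqstorm_config_error")
  }
  mult <- c(s = 1, sec = 1, min = 60, h = 3600)[[m[3L]]]
  as.numeric(m[2L]) * mult
}

# parse "0.1067 um" / "107 nm" / numeric -> micrometers
parse_um <- function(x, key) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec(
    "^\\s*([0-9.eE+-]+)\\s*(um|µm|μm|nm|mm)\\s*$", x))[[1L]]
  if (length(m) == 0L) {
    abort(sprintf("%s: cannot parse length '%s' (expected e.g. '0.1067 um').",
                  key, x), class = "seqstorm_config_error")
  }
  mult <- c(um = 1, "µm" = 1, "μm" = 1, nm = 1e-3, mm = 1e3)[[m[3L]]]
  as.numeric(m[2L]) * mult
}

check_range <- function(errors, value, key, min = -Inf, max = Inf,
                        strict_min = FALSE) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    return(c(errors, sprintf("%s: expected a single finite number.", key)))
  }
  bad <- if (strict_min) value <= min else value < min
  if (bad || value > max) {
    return(c(errors, sprintf(
      "%s: value %g out of range %s%g, %g].", key, value,
      if (strict_min) "(" else "[", min, max)))
  }
  errors
}

#' Validate an experiment configuration
#'
#' Schema-checks a config (YAML path or list), fills documented defaults,
#' and normalizes units: concentrations like `"4.87 uM"` to molar, times
#' like `"5 min"` to seconds, lengths like `"107 nm"` to micrometers. Every
#' violation is reported with its key path; nothing is simulated before
#' validation passes.
#'
#' @param config Path to a YAML file, or an equivalent nested list with
#'   keys `scene` (`field_size_um`, `structures`), `rounds`, and optional
#'   `camera`, `photophysics`, `fit`, `kinetics`, `n_frames`, `background`,
#'   `psf_sigma`, `seed`, `out_dir`.
#' @return An `experiment_config` list with all components instantiated
#'   (`scene` spec, `rounds` as [round_spec()]s, [camera_model()],
#'   [photophysics_params()], [fit_config()], [kinetics_model()], `seed`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "seqstorm_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  errors <- character()

  cam_in <- config$camera %||% list()
  cam_in$frame_size <- cam_in$frame_size %||% 64L
  if (!is.null(cam_in$pixel_size_um)) {
    cam_in$pixel_size_um <- tryCatch(
      parse_um(cam_in$pixel_size_um, "camera.pixel_size_um"),
      seqstorm_config_error = function(e) {
        errors <<- c(errors, conditionMessage(e)); NA_real_
      })
    errors <- check_range(errors, cam_in$pixel_size_um,
                          "camera.pixel_size_um", 0, Inf, strict_min = TRUE)
  }
  if (!is.null(cam_in$em_gain)) {
    errors <- check_range(errors, cam_in$em_gain, "camera.em_gain", 1)
  }

  if (is.null(config$scene) || is.null(config$scene$field_size_um)) {
    errors <- c(errors, "scene.field_size_um: required.")
  } else {
    errors <- check_range(errors, config$scene$field_size_um,
                          "scene.field_size_um", 0, Inf, strict_min = TRUE)
  }
  structures <- purrr::map(config$scene$structures %||% list(), function(s) {
    if (identical(s$type, "filament")) {
      do.call(filament, s[setdiff(names(s), "type")])
    } else if (identical(s$type, "cluster")) {
      do.call(cluster, s[setdiff(names(s), "type")])
    } else {
      errors <<- c(errors, sprintf(
        "scene.structures: unknown type '%s' (filament or cluster).",
        s$type %||% "<missing>"))
      NULL
    }
  })

  rounds_in <- config$rounds %||% list()
  if (length(rounds_in) == 0L) {
    errors <- c(errors, "rounds: at least one round is required.")
  }
  scene_targets <- unique(unlist(purrr::map(structures, "target_id")))
  rounds <- purrr::imap(rounds_in, function(r, i) {
    key <- sprintf("rounds[%d]", i)
    if (is.null(r$target_id)) {
      errors <<- c(errors, sprintf("%s.target_id: required.", key))
      return(NULL)
    }
    if (!r$target_id %in% scene_targets) {
      errors <<- c(errors, sprintf(
        "%s.target_id: %s not present in scene structures (have: %s).",
        key, r$target_id, paste(scene_targets, collapse = ", ")))
    }
    lp <- r$label_prob %||% 1
    co <- r$carryover_residual %||% 0
    errors <<- check_range(errors, lp, paste0(key, ".label_prob"), 0, 1)
    errors <<- check_range(errors, co, paste0(key, ".carryover_residual"),
                           0, 1)
    list(round_index = r$round_index %||% i, target_id = r$target_id,
         label_prob = lp, carryover_residual = co)
  })

  kin_in <- config$kinetics %||% list()
  if (!is.null(kin_in$invader_conc)) {
    kin_in$invader_conc <- tryCatch(
      parse_molar(kin_in$invader_conc, "kinetics.invader_conc"),
      seqstorm_config_error = function(e) {
        errors <<- c(errors, conditionMessage(e)); NA_real_
      })
  }
  if (!is.null(kin_in$t_invader)) {
    kin_in$t_invader <- tryCatch(
      parse_seconds(kin_in$t_invader, "kinetics.t_invader"),
      seqstorm_config_error = function(e) {
        errors <<- c(errors, conditionMessage(e)); NA_real_
      })
  }

  n_frames <- config$n_frames %||% 2000L
  errors <- check_range(errors, n_frames, "n_frames", 1)
  background <- config$background %||% 5
  errors <- check_range(errors, background, "background", 0)
  psf_sigma <- config$psf_sigma %||% 1.3
  errors <- check_range(errors, psf_sigma, "psf_sigma", 0, Inf,
                        strict_min = TRUE)
  seed <- config$seed %||% 1L
  errors <- check_range(errors, seed, "seed", 0)

  if (length(errors) > 0L) {
    abort(c("invalid experiment config:", setNames(errors, rep("x",
                                                               length(errors)))),
          class = "seqstorm_config_error")
  }

  structure(
    list(
      scene_spec = list(structures = structures,
                        field_size_um = config$scene$field_size_um),
      rounds = purrr::map(rounds, ~ do.call(round_spec, .x)),
      camera = do.call(camera_model, cam_in),
      photophysics = do.call(photophysics_params,
                             config$photophysics %||% list()),
      fit = do.call(fit_config, config$fit %||% list()),
      kinetics = do.call(kinetics_model, kin_in),
      n_frames = as.integer(n_frames),
      background = background,
      psf_sigma = psf_sigma,
      crosstalk_check = config$crosstalk_check %||% TRUE,
      seed = as.integer(seed),
      out_dir = config$out_dir %||% NULL
    ),
    class = "experiment_config"
  )
}

# deterministic per-stage seed stream, kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 97) %% .Machine$integer.max)
}

#' Simulated brightfield reference image
#'
#' Stand-in for the brightfield image used to re-locate each cell between
#' rounds: a diffraction-blurred density of all scene structures (labeled
#' or not) on a uniform illumination background, with Poisson shot noise.
#' It depicts the same cell every round regardless of which target is
#' currently dye-labeled, so consecutive rounds can be registered by
#' cross-correlation.
#'
#' @param scene A [make_scene()] scene.
#' @param camera A [camera_model()].
#' @param seed Integer seed for the shot noise.
#' @param blur_sigma_px Blur width (pixels) of the structure density.
#' @param illumination Background illumination level (photons / pixel).
#' @param contrast Photons contributed per binding site.
#' @return Matrix (`frame_size` x `frame_size`) in photon units.
#' @export
brightfield_reference <- function(scene, camera, seed, blur_sigma_px = 2,
                                  illumination = 200, contrast = 20) {
  npx <- camera$frame_size
  mu <- matrix(illumination, npx, npx)
  for (i in seq_len(nrow(scene$sites))) {
    p <- psf_patch(scene$sites$x_um[i] / camera$pixel_size_um,
                   scene$sites$y_um[i] / camera$pixel_size_um,
                   contrast, blur_sigma_px, npx, npx)
    if (!is.null(p)) mu[p$rows, p$cols] <- mu[p$rows, p$cols] + p$patch
  }
  with_seed(seed, matrix(rpois(npx * npx, mu), npx, npx))
}

#' Run the full sequential-imaging experiment in silico
#'
#' For each configured round: simulate the acquisition (fresh labeling of
#' the round's target plus carryover from the previous round), localize and
#' filter, register the round's reference image against round 1, and render
#' a super-resolution image. Between consecutive rounds an inter-round
#' acquisition of identical length is simulated with only the carryover
#' label present, mirroring the before/after-invader measurement used to
#' quantify residual cross-talk (disable with `crosstalk_check: false`).
#' Idempotent for fixed seeds: every reported number is recomputable from
#' the echoed config.
#'
#' @param config An `experiment_config` from [validate_config()] (or a
#'   path / list, validated on the fly).
#' @return An `experiment_report`: list with `localizations` (all rounds,
#'   with `round` and `target_id` columns), `round_counts`, `dispersion`,
#'   `crosstalk` (one row per invader step), `registration` (per-round
#'   shifts), `sr_paths` (when `out_dir` is set), `config`, and `seeds`.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "experiment_config")) {
    config <- validate_config(config)
  }
  run_stage <- function(stage, round, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed at round %d: %s", stage, round,
                    conditionMessage(e)),
            class = "seqstorm_stage_failure", parent = e)
    })
  }
  scene <- run_stage("scene", 0L, make_scene(
    config$scene_spec$structures, config$scene_spec$field_size_um,
    derive_seed(config$seed, 0L)))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(config_echo(config), file.path(config$out_dir,
                                                    "config_echo.yaml"))
  }

  n_rounds <- length(config$rounds)
  locs_all <- vector("list", n_rounds)
  refs <- vector("list", n_rounds)
  labeled_prev <- NULL
  counts_before <- integer(n_rounds)
  xtalk <- vector("list", max(n_rounds - 1L, 0L))
  seeds <- integer(0)
  sr_paths <- character(0)

  for (r in seq_len(n_rounds)) {
    spec <- config$rounds[[r]]
    sim_seed <- derive_seed(config$seed, r)
    seeds <- c(seeds, sim_seed)
    sim <- run_stage("simulate", r, simulate_round(
      scene, spec, config$photophysics, config$camera, config$n_frames,
      seed = sim_seed, background = config$background,
      psf_sigma = config$psf_sigma, prev_labeled = labeled_prev))
    locs <- run_stage("localize", r, localize_stack(sim$movie, config$fit))
    locs$round <- spec$round_index
    locs$target_id <- spec$target_id
    locs_all[[r]] <- locs
    counts_before[r] <- sum(locs$accepted)

    # per-round brightfield stand-in: same cell outline every round,
    # independent of which target is currently labeled
    refs[[r]] <- run_stage("reference", r, brightfield_reference(
      scene, config$camera, derive_seed(config$seed, 200L + r)))

    if (!is.null(config$out_dir)) {
      sr <- run_stage("render", r, render(
        locs, zoom = 10,
        extent = c(0, config$camera$frame_size, 0,
                   config$camera$frame_size)))
      p <- file.path(config$out_dir, sprintf("round%02d_sr.tif", r))
      write_sr_image(sr, p)
      sr_paths <- c(sr_paths, p)
    }

    # inter-round acquisition: carryover only (the after-invader picture)
    if (r < n_rounds && config$crosstalk_check) {
      nxt <- config$rounds[[r + 1L]]
      check_spec <- round_spec(spec$round_index, spec$target_id,
                               label_prob = 0,
                               carryover_residual = nxt$carryover_residual)
      chk_seed <- derive_seed(config$seed, 100L + r)
      seeds <- c(seeds, chk_seed)
      chk <- run_stage("crosstalk", r, {
        sim_after <- simulate_round(
          scene, check_spec, config$photophysics, config$camera,
          config$n_frames, seed = chk_seed, background = config$background,
          psf_sigma = config$psf_sigma, prev_labeled = sim$labeled)
        locs_after <- localize_stack(sim_after$movie, config$fit)
        dplyr::mutate(crosstalk(locs, locs_after),
                      after_round = spec$round_index,
                      target_id = spec$target_id, .before = 1L)
      })
      xtalk[[r]] <- chk
    }
    labeled_prev <- sim$labeled
  }

  registration <- purrr::map_dfr(seq_len(n_rounds), function(r) {
    sh <- run_stage("register", r, register_rounds(refs[[1L]], refs[[r]]))
    tibble::tibble(round = config$rounds[[r]]$round_index,
                   dx = sh$dx, dy = sh$dy)
  })

  locs_all <- dplyr::bind_rows(locs_all)
  rc <- round_counts(locs_all)
  report <- structure(
    list(
      localizations = locs_all,
      round_counts = rc$counts,
      dispersion = rc$dispersion,
      crosstalk = dplyr::bind_rows(xtalk),
      registration = registration,
      sr_paths = sr_paths,
      config = config,
      seeds = seeds
    ),
    class = "experiment_report"
  )
  if (!is.null(config$out_dir)) {
    readr::write_csv(report$round_counts,
                     file.path(config$out_dir, "round_counts.csv"))
    if (nrow(report$crosstalk) > 0L) {
      readr::write_csv(report$crosstalk,
                       file.path(config$out_dir, "crosstalk.csv"))
    }
  }
  report
}

# plain-list echo of an experiment_config (YAML-serializable)
config_echo <- function(config) {
  list(
    scene = list(field_size_um = config$scene_spec$field_size_um,
                 structures = config$scene_spec$structures),
    rounds = purrr::map(config$rounds, unclass),
    camera = unclass(config$camera),
    photophysics = unclass(config$photophysics),
    fit = unclass(config$fit),
    kinetics = unclass(config$kinetics),
    n_frames = config$n_frames,
    background = config$background,
    psf_sigma = config$psf_sigma,
    crosstalk_check = config$crosstalk_check,
    seed = config$seed
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment report> %d rounds, %d accepted localizations\n",
              nrow(x$round_counts), sum(x$round_counts$n)))
  print(x$round_counts)
  if (nrow(x$crosstalk) > 0L) {
    cat("cross-talk per invader step:\n")
    print(dplyr::select(x$crosstalk, "after_round", "target_id",
                        "n_before", "n_after", "percent"))
  }
  invisible(x)
}
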