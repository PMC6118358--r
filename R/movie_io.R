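#' Write / read a movie as multi-page 16-bit TIFF
#'
#' Frames are stored as 16-bit TIFF pages; acquisition metadata (camera
#' model, units, intensity scale) goes to a YAML sidecar `<path>.yaml` so
#' it round-trips unchanged. Integer-valued movies up to 65535 are stored
#' losslessly.
#'
#' @param movie A `seqstorm_movie`.
#' @param path Output TIFF path.
#' @return `write_movie()` returns `path` invisibly; `read_movie()` returns
#'   the reconstructed `seqstorm_movie`.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "seqstorm_movie"))
  scale <- max(movie$frames, 1)
  pages <- purrr::map(seq_len(movie$n_frames), function(f) {
    movie$frames[, , f] / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    units = movie$units,
    scale = scale,
    n_frames = movie$n_frames,
    camera = unclass(movie$camera)
  )
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path)) {
    abort(sprintf("metadata sidecar not found: %s", meta_path))
  }
  meta <- yaml::read_yaml(meta_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  frames <- array(0, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]),
                             length(pages)))
  for (f in seq_along(pages)) {
    frames[, , f] <- round(pages[[f]] * 65535) * meta$scale / 65535
  }
  cam <- do.call(camera_model, meta$camera)
  movie_stack(frames, cam, meta$units)
}

#' Write / read a localization table
#'
#' Plain delimited text with the full localization column set and a
#' commented provenance block carrying the fit configuration.
#'
#' @param locs Localization tibble (from [localize_stack()]).
#' @param path Output path.
#' @param config Optional [fit_config()] recorded in the header block.
#' @return `read_localizations()` returns the localization tibble.
#' @export
write_localizations <- function(locs, path, config = NULL) {
  header <- character(0)
  if (!is.null(config)) {
    header <- paste0("# ", strsplit(yaml::as.yaml(unclass(config)),
                                    "\n")[[1L]])
  }
  writeLines(c(header, sub("\n$", "", readr::format_csv(locs))), path)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
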