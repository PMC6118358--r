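# Ground-truth scenes: binding-site positions on schematic structures.
# Coordinates: x right / y down, origin at the center of camera pixel (0,0);
# micrometers in user-facing fields, converted to pixels via the camera model.

#' Describe a ground-truth structure
#'
#' Two schematic structure types emulate the targets imaged in sequential
#' dSTORM experiments: `filament()` — tubulin-like line segments carrying
#' binding sites at a fixed linear density — and `cluster()` — clathrin-like
#' disks of ~75 nm radius with Poisson-distributed site counts. Geometry
#' left `NULL` is drawn uniformly at random inside the field when the scene
#' is built.
#'
#' @param n Number of copies of the structure.
#' @param length_um Filament length (micrometers).
#' @param site_spacing_um Distance between consecutive filament sites.
#' @param radius_um Cluster disk radius.
#' @param sites_mean Mean (Poisson) number of sites per cluster.
#' @param target_id Integer label tying the structure to an imaging target.
#' @param x0_um,y0_um Optional fixed anchor (filament start / cluster
#'   center).
#' @param theta Optional fixed filament orientation (radians).
#' @return A structure descriptor list, consumed by [make_scene()].
#' @export
filament <- function(n = 1, length_um = 2, site_spacing_um = 0.02,
                     target_id = 1L, x0_um = NULL, y0_um = NULL,
                     theta = NULL) {
  list(type = "filament", n = n, length_um = length_um,
       site_spacing_um = site_spacing_um, target_id = as.integer(target_id),
       x0_um = x0_um, y0_um = y0_um, theta = theta)
}

#' @rdname filament
#' @export
cluster <- function(n = 1, radius_um = 0.075, sites_mean = 40,
                    target_id = 1L, x0_um = NULL, y0_um = NULL) {
  list(type = "cluster", n = n, radius_um = radius_um,
       sites_mean = sites_mean, target_id = as.integer(target_id),
       x0_um = x0_um, y0_um = y0_um)
}

# run code under a local RNG state seeded with `seed`, restoring afterwards
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Build a ground-truth scene
#'
#' Places every structure inside the field and instantiates its binding
#' sites. The result is bit-for-bit reproducible from `seed`; the caller's
#' RNG state is left untouched.
#'
#' @param structures List of descriptors from [filament()] / [cluster()].
#'   An empty list yields a valid empty scene.
#' @param field_size_um Side length of the square field of view
#'   (micrometers).
#' @param seed Integer seed.
#' @param margin_um Sites are kept inside `[margin_um, field - margin_um]`
#'   by mirror reflection at the margin, so structures never hug the field
#'   border (where fitting ROIs would be clipped). Fixed-anchor structures
#'   placed inside the margin are unaffected.
#' @return A `seqstorm_scene`: list with `sites` (tibble: `site_id`, `x_um`,
#'   `y_um`, `target_id`, `structure_id`, `type`), `field_size_um`,
#'   `structures`, `seed`.
#' @examples
#' sc <- make_scene(list(filament(length_um = 2, x0_um = 1, y0_um = 1,
#'                                theta = 0)),
#'                  field_size_um = 6, seed = 1)
#' nrow(sc$sites)   # 101 sites at 20 nm spacing
#' @export
make_scene <- function(structures, field_size_um, seed, margin_um = 0.4) {
  stopifnot(is.numeric(field_size_um), field_size_um > 0,
            margin_um >= 0, 2 * margin_um < field_size_um)
  # mirror-reflect coordinates into [lo, hi]
  reflect <- function(v, lo, hi) {
    span <- hi - lo
    v <- (v - lo) %% (2 * span)
    lo + ifelse(v > span, 2 * span - v, v)
  }
  sites <- with_seed(seed, {
    sid <- 0L
    purrr::imap_dfr(structures, function(st, structure_id) {
      purrr::map_dfr(seq_len(st$n), function(copy) {
        lo <- margin_um
        hi <- field_size_um - margin_um
        if (st$type == "filament") {
          x0 <- st$x0_um %||% runif(1, lo, hi)
          y0 <- st$y0_um %||% runif(1, lo, hi)
          th <- st$theta %||% runif(1, 0, pi)
          s <- seq(0, st$length_um, by = st$site_spacing_um)
          x <- reflect(x0 + s * cos(th), lo, hi)
          y <- reflect(y0 + s * sin(th), lo, hi)
        } else if (st$type == "cluster") {
          x0 <- st$x0_um %||% runif(1, lo, hi)
          y0 <- st$y0_um %||% runif(1, lo, hi)
          k <- rpois(1, st$sites_mean)
          r <- st$radius_um * sqrt(runif(k))
          a <- runif(k, 0, 2 * pi)
          x <- reflect(x0 + r * cos(a), lo, hi)
          y <- reflect(y0 + r * sin(a), lo, hi)
        } else {
          abort(sprintf("unknown structure type '%s'", st$type))
        }
        keep <- x >= 0 & x <= field_size_um & y >= 0 & y <= field_size_um
        tibble::tibble(
          x_um = x[keep], y_um = y[keep],
          target_id = st$target_id,
          structure_id = structure_id,
          type = st$type
        )
      })
    })
  })
  if (nrow(sites) == 0L) {
    sites <- tibble::tibble(
      x_um = numeric(), y_um = numeric(), target_id = integer(),
      structure_id = integer(), type = character()
    )
  }
  sites <- dplyr::mutate(sites, site_id = dplyr::row_number(),
                         .before = 1L)
  structure(
    list(sites = sites, field_size_um = field_size_um,
         structures = structures, seed = seed),
    class = "seqstorm_scene"
  )
}

#' @export
print.seqstorm_scene <- function(x, ...) {
  cat(sprintf("<scene> %d sites on %d structure spec(s), %.2f um field, seed %d\n",
              nrow(x$sites), length(x$structures), x$field_size_um, x$seed))
  invisible(x)
}
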