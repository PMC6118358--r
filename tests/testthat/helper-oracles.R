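# Independent oracles and small fixture builders used across tests.

# reverse complement written independently of the package (vector ops)
oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

# brute-force longest antiparallel complementary run: enumerate every
# substring of `a` and test whether its reverse complement occurs in `b`
oracle_longest_run <- function(a, b) {
  n <- nchar(a)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (grepl(oracle_revcomp(substr(a, i, j)), b, fixed = TRUE)) {
        best <- max(best, j - i + 1L)
      } else {
        break
      }
    }
  }
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# noiseless / Poisson model ROI on the integrated-Gaussian PSF
model_roi <- function(sz, x, y, N, b, sigma = 1.3, noisy = FALSE) {
  k <- seq_len(sz) - 1L
  erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
  e1d <- function(p) 0.5 * (erf((k - p + 0.5) / (sqrt(2) * sigma)) -
                              erf((k - p - 0.5) / (sqrt(2) * sigma)))
  mu <- N * (e1d(y) %o% e1d(x)) + b
  if (noisy) matrix(rpois(sz^2, mu), sz, sz) else mu
}

# shift an image by integer (dx, dy): out[r, c] = img[r - dy, c - dx]
shift_image <- function(img, dx, dy) {
  n <- nrow(img)
  m <- ncol(img)
  out <- matrix(mean(img), n, m)
  rs <- (1:n) - dy
  cs <- (1:m) - dx
  ok_r <- rs >= 1 & rs <= n
  ok_c <- cs >= 1 & cs <= m
  out[ok_r, ok_c] <- img[rs[ok_r], cs[ok_c]]
  out
}

# fraction of truth on-events with an accepted localization within 1 px
# in the same frame
recall_vs_truth <- function(locs, truth, radius = 1) {
  acc <- locs[locs$accepted, ]
  hits <- vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    any(acc$frame == tr$frame &
          (acc$x - tr$x_px)^2 + (acc$y - tr$y_px)^2 <= radius^2)
  }, logical(1))
  mean(hits)
}
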