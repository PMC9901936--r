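# Shared fixture builders and brute-force oracles. Oracles are written as
# plain loops, structurally independent of the package's vectorized /
# compiled paths.

# small, fast mosaic spec (16 um field at 4 px/um = 64 px)
tiny_mosaic_spec <- function(...) {
  args <- modifyList(list(field_size_um = 16, px_per_um = 4,
                          n_red_cells = 6L, n_green_only_cells = 4L,
                          double_positive_fraction = 0.5,
                          cell_radius_um = 1.5, min_spacing_um = 3.4,
                          psf_sigma_px = 0, noise_sd = 0,
                          exact_counts = TRUE, seed = 42L),
                     list(...))
  do.call(mosaic_spec, args)
}

# normalized green channel matrix with the flag set; anchors 0 and 1 so
# the field_image invariant holds
normalized_green <- function(nr, nc, fill = 0) {
  g <- matrix(fill, nr, nc)
  g[1, 1] <- 0
  g[nr, nc] <- 1
  attr(g, "normalized") <- TRUE
  g
}

# paint a hard disk into a matrix (loop-free test-side rasterizer)
test_disk <- function(m, cx, cy, r, value, add = TRUE) {
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      if ((i - cy)^2 + (j - cx)^2 <= r^2)
        m[i, j] <- if (add) m[i, j] + value else value
  m
}

# brute-force per-pixel binary erosion oracle (disk or square element)
brute_erode <- function(fg, r, element = "disk") {
  nr <- nrow(fg); nc <- ncol(fg)
  out <- matrix(FALSE, nr, nc)
  offs <- expand.grid(dy = -ceiling(r):ceiling(r),
                      dx = -ceiling(r):ceiling(r))
  if (element == "disk")
    offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      if (!fg[i, j]) next
      ok <- TRUE
      for (q in seq_len(nrow(offs))) {
        y <- i + offs$dy[q]; x <- j + offs$dx[q]
        if (y < 1 || y > nr || x < 1 || x > nc || !fg[y, x]) {
          ok <- FALSE
          break
        }
      }
      out[i, j] <- ok
    }
  out
}

# brute-force label-wise erosion oracle built on brute_erode
brute_erode_labels <- function(labels, r, element = "disk") {
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (lab in setdiff(unique(as.vector(labels)), 0L)) {
    er <- brute_erode(labels == lab, r, element)
    out[er] <- lab
  }
  out
}

# independent loop-based transcription of the Conover-Iman formula,
# deliberately separate from the package's vectorized implementation
reference_conover <- function(groups, H) {
  x <- c(); g <- c()
  for (i in seq_along(groups)) {
    x <- c(x, groups[[i]])
    g <- c(g, rep(i, length(groups[[i]])))
  }
  r <- rank(x)
  N <- length(x); k <- length(groups)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    Ri <- mean(r[g == i]); Rj <- mean(r[g == j])
    se <- sqrt(S2 * ((N - 1 - H) / (N - k)) *
                 (1 / sum(g == i) + 1 / sum(g == j)))
    t <- (Ri - Rj) / se
    out <- rbind(out, data.frame(i = i, j = j, t = t,
                                 p = 2 * pt(-abs(t), N - k)))
  }
  out
}

# random label mask of non-overlapping disks; returns the integer matrix
random_disk_mask <- function(nr, nc, n_disks, r, seed) {
  set.seed(seed)
  m <- matrix(0L, nr, nc)
  centers <- NULL
  tries <- 0
  while (is.null(centers) || nrow(centers) < n_disks) {
    tries <- tries + 1
    if (tries > 500) break
    cx <- runif(1, r + 1, nc - r); cy <- runif(1, r + 1, nr - r)
    if (!is.null(centers) &&
        any((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 <
              (2 * r + 2)^2)) next
    centers <- rbind(centers, c(cx, cy))
    m <- test_disk(m, cx, cy, r, nrow(centers), add = FALSE)
  }
  m
}
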