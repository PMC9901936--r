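#' Reference segmentation parameters
#'
#' Parameters of the deterministic reference segmenter, a transparent
#' stand-in for learned cell segmenters plus manual correction: Gaussian
#' smoothing, global threshold, 8-connected components, optional
#' distance-transform watershed splitting, and a minimum-area filter.
#'
#' @param smooth_sigma_px Gaussian smoothing sd in px (>= 0).
#' @param threshold_method `"otsu"` or a fixed numeric threshold in
#'   detector units.
#' @param min_area_px discard regions smaller than this many pixels.
#' @param split_touching if `TRUE`, split merged regions by a
#'   marker-controlled watershed on the Euclidean distance transform.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_sigma_px = 1,
                                threshold_method = "otsu",
                                min_area_px = 9L,
                                split_touching = FALSE) {
  check_scalar_number(smooth_sigma_px, "smooth_sigma_px", min = 0)
  check_scalar_number(min_area_px, "min_area_px", min = 1)
  if (!identical(threshold_method, "otsu"))
    check_scalar_number(threshold_method, "threshold_method")
  structure(list(smooth_sigma_px = smooth_sigma_px,
                 threshold_method = threshold_method,
                 min_area_px = as.integer(min_area_px),
                 split_touching = isTRUE(split_touching)),
            class = "segmentation_params")
}

#' Otsu's threshold
#'
#' Histogram-based threshold maximizing between-class variance, computed
#' on 256 bins over the observed range.
#'
#' @param image numeric matrix.
#' @return threshold value on the image's intensity scale.
#' @export
otsu_threshold <- function(image) {
  x <- as.vector(image)
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  nb <- 256L
  breaks <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- tabulate(pmin(nb, findInterval(x, breaks, rightmost.closed = TRUE)),
                nbins = nb)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nb + 1L)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nb]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  # drop the last bin (omega = 1); tie broken toward the lower threshold
  breaks[which.max(sigma_b[-nb]) + 1L]
}

# local-maximum markers for watershed splitting: within each component,
# the pixels whose distance to background exceeds `level_frac` of the
# component's maximum form the marker blobs. One blob -> no split.
watershed_markers <- function(comp, dsq, level_frac = 0.8) {
  markers <- matrix(0L, nrow(comp), ncol(comp))
  nxt <- 0L
  idx_all <- which(comp > 0L)
  by_comp <- split(idx_all, comp[idx_all])
  for (lab_chr in names(by_comp)) {
    li <- by_comp[[lab_chr]]
    mx <- max(dsq[li])
    core <- li[dsq[li] >= level_frac^2 * mx]
    sub <- matrix(FALSE, nrow(comp), ncol(comp))
    sub[core] <- TRUE
    blobs <- cpp_label_components(sub, 8L)
    nb <- max(blobs)
    markers[core] <- blobs[core] + nxt
    nxt <- nxt + nb
  }
  markers
}

# renumber labels canonically: 1, 2, ... in raster (row-major) order of
# each label's first pixel, making results bit-stable
canonical_renumber <- function(lab) {
  idx <- which(t(lab) > 0L)          # raster order = column order of t()
  if (!length(idx)) return(lab)
  v <- t(lab)[idx]
  first <- !duplicated(v)
  map <- integer(max(v))
  map[v[first]] <- seq_len(sum(first))
  out <- lab
  pos <- lab > 0L
  out[pos] <- map[lab[pos]]
  out
}

#' Reference cell segmentation
#'
#' Deterministic pipeline: Gaussian smoothing, global threshold (Otsu by
#' default), 8-connected component labelling, optional watershed splitting
#' of touching cells on the distance transform, and a minimum-area filter.
#' Labels are renumbered canonically by raster order of each region's
#' first pixel, so identical input gives bit-identical masks. An
#' all-background result is a valid empty mask, not an error.
#'
#' @param image 2-D numeric matrix (one channel, raw detector units).
#' @param params a [segmentation_params()].
#' @param channel name recorded as the mask's channel of origin.
#' @return a [label_mask()].
#' @export
segment_reference <- function(image, params = segmentation_params(),
                              channel = NA_character_) {
  abort_if(!is.matrix(image) || !is.numeric(image),
           "image must be a 2-D numeric matrix")
  stopifnot(inherits(params, "segmentation_params"))
  sm <- gaussian_blur(image, params$smooth_sigma_px)
  thr <- if (identical(params$threshold_method, "otsu"))
    otsu_threshold(sm) else params$threshold_method
  fg <- sm > thr
  lab <- cpp_label_components(fg, 8L)
  if (params$split_touching && max(lab) > 0L) {
    dsq <- cpp_edt_sq(fg)
    markers <- watershed_markers(lab, dsq)
    lab <- cpp_marker_watershed(lab, dsq, markers)
  }
  if (max(lab) > 0L && params$min_area_px > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    small <- which(sizes > 0L & sizes < params$min_area_px)
    if (length(small)) lab[lab %in% small] <- 0L
  }
  label_mask(canonical_renumber(lab), channel)
}
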