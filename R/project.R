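#' Maximum intensity projection of a z-stack
#'
#' Collapses selected planes of a 3-D stack into a single 2-D image by the
#' pixel-wise maximum, the standard projection for counting photoreceptors
#' across the slight axial curvature of the retina. Following common
#' practice only a small subset of planes (those containing the cells) is
#' projected; the plane range is a user decision.
#'
#' @param stack 3-D numeric array (rows x cols x planes).
#' @param plane_range inclusive integer pair `c(first, last)`; `NULL`
#'   projects the full stack.
#' @return 2-D matrix of the same storage mode as the input.
#' @export
max_project <- function(stack, plane_range = NULL) {
  abort_if(!is.array(stack) || length(dim(stack)) != 3L,
           "stack must be a 3-D array")
  np <- dim(stack)[3]
  if (is.null(plane_range)) plane_range <- c(1L, np)
  abort_if(length(plane_range) != 2L || any(is.na(plane_range)),
           "plane_range must be an inclusive index pair")
  plane_range <- as.integer(plane_range)
  abort_if(plane_range[1] > plane_range[2] || plane_range[1] < 1L ||
             plane_range[2] > np,
           "plane_range out of range for stack with ", np, " planes")
  planes <- lapply(plane_range[1]:plane_range[2],
                   function(i) stack[, , i])
  out <- Reduce(pmax, planes)
  dim(out) <- dim(stack)[1:2]
  out
}

#' Min-max normalize a channel to \[0, 1\]
#'
#' Rescales a whole image linearly so its minimum maps to 0 and its
#' maximum to 1, making per-cell fluorescence averages comparable across
#' fields acquired with different detector gain. A constant image (no
#' dynamic range at all) is defined to map to all zeros, with a warning.
#'
#' @param image numeric matrix with finite values.
#' @param clip_quantiles optional length-2 vector of lower/upper quantiles
#'   to clip at before rescaling (off by default).
#' @return matrix in \[0, 1\] carrying attribute `normalized = TRUE`.
#' @export
normalize_channel <- function(image, clip_quantiles = NULL) {
  abort_if(!is.matrix(image) || !is.numeric(image) || length(image) == 0L,
           "image must be a non-empty numeric matrix")
  abort_if(any(!is.finite(image)), "image contains non-finite pixels")
  x <- image
  if (!is.null(clip_quantiles)) {
    abort_if(length(clip_quantiles) != 2L || any(clip_quantiles < 0) ||
               any(clip_quantiles > 1) ||
               clip_quantiles[1] >= clip_quantiles[2],
             "clip_quantiles must be an increasing pair in [0, 1]")
    q <- quantile(x, clip_quantiles, names = FALSE, type = 7)
    x <- pmin(pmax(x, q[1]), q[2])
  }
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant image: normalization defined as all zeros")
    out <- matrix(0, nrow(x), ncol(x))
  } else {
    out <- (x - rng[1]) / (rng[2] - rng[1])
  }
  attr(out, "normalized") <- TRUE
  out
}
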