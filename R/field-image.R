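#' Two-channel retinal field image
#'
#' Container for a projected, calibrated confocal field: named 2-D channel
#' matrices (typically `red` marker and `green` GFP, optionally `nuclear`)
#' sharing one shape, plus the physical pixel size. Raw values are in
#' detector units (the synthetic generator uses a 12-bit 0-4095 scale); a
#' channel that has been passed through [normalize_channel()] carries a
#' `normalized` attribute and spans \[0, 1\].
#'
#' @param channels named list of numeric matrices of identical dimensions.
#' @param px_per_um pixels per micron (> 0). The default 16 corresponds to
#'   a 64 um field imaged at 1024 x 1024 px.
#' @param provenance optional list (source file, projection planes, ...).
#' @return an object of class `field_image`.
#' @export
field_image <- function(channels, px_per_um = 16, provenance = NULL) {
  abort_if(!is.list(channels) || length(channels) == 0L ||
             is.null(names(channels)) || any(names(channels) == ""),
           "channels must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  abort_if(any(vapply(channels, function(m) !is.matrix(m) ||
                        !is.numeric(m), logical(1))),
           "all channels must be numeric matrices")
  abort_if(length(unique(vapply(dims, paste, character(1),
                                collapse = "x"))) != 1L,
           "all channels must share the same dimensions")
  check_scalar_number(px_per_um, "px_per_um", min = 0, strict_min = TRUE)
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (isTRUE(attr(ch, "normalized"))) {
      rng <- range(ch)
      abort_if(!(all(ch == 0) || (rng[1] == 0 && rng[2] == 1)),
               "channel '", nm,
               "' is flagged normalized but does not span [0, 1]")
    }
  }
  structure(list(channels = channels, px_per_um = px_per_um,
                 provenance = provenance),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image> %d x %d px (%.1f x %.1f um), channels: %s\n",
              d[1], d[2], d[1] / x$px_per_um, d[2] / x$px_per_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Integer cell label mask
#'
#' A 2-D integer matrix aligned to a [field_image()]: 0 is background and
#' each positive value labels one segmented cell. Labels must be unique per
#' cell but need not be consecutive.
#'
#' @param labels integer matrix with non-negative entries.
#' @param channel_of_origin name of the channel the mask was derived from.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, channel_of_origin = NA_character_) {
  abort_if(!is.matrix(labels) || !is.numeric(labels),
           "labels must be an integer matrix")
  abort_if(any(labels < 0) || any(labels != floor(labels)),
           "labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, channel_of_origin = channel_of_origin),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d labels (origin: %s)\n",
              nrow(x$labels), ncol(x$labels),
              length(setdiff(unique(as.vector(x$labels)), 0L)),
              x$channel_of_origin))
  invisible(x)
}

#' Labels present in a mask
#' @param mask a [label_mask()].
#' @return sorted integer vector of positive labels.
#' @export
mask_labels <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  sort(setdiff(unique(as.vector(mask$labels)), 0L))
}

check_aligned <- function(field, mask) {
  abort_if(!identical(dim(field$channels[[1]]), dim(mask$labels)),
           "label mask and field image have different shapes")
}

#' Is a channel flagged as normalized?
#' @param channel a channel matrix.
#' @return logical.
#' @export
is_normalized <- function(channel) isTRUE(attr(channel, "normalized"))
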