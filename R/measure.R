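#' Quantification configuration
#'
#' Parameters of the per-cell GFP measurement and double-positive
#' classification chain. The defaults encode the reference workflow: a
#' 10 px disk erosion at 16 px/um (0.625 um) to discard blur-contaminated
#' borders, threshold calibration at a 5% target control exceedance, and
#' the published fixed thresholds (L: 0.195, S: 0.275) available as an
#' alternative to calibration.
#'
#' @param erosion_radius_px integer erosion radius in px (default 10, at
#'   the reference resolution of 16 px/um; see [scale_erosion_radius()]).
#' @param alpha target control exceedance fraction for calibration.
#' @param fixed_thresholds named numeric vector of per-subtype fixed
#'   thresholds in \[0, 1\].
#' @param strict_greater if `TRUE` (default) "exceeds" means strictly
#'   greater; ties classify negative.
#' @param overlap_fraction minimum fractional pixel overlap at which a
#'   green segment is excluded as an already-counted red cell.
#' @param field_area_um2 field area for density conversion.
#' @param element erosion structuring element, `"disk"` or `"square"`.
#' @return object of class `quant_config`.
#' @export
quant_config <- function(erosion_radius_px = 10L, alpha = 0.05,
                         fixed_thresholds = c(L = 0.195, S = 0.275),
                         strict_greater = TRUE, overlap_fraction = 0.5,
                         field_area_um2 = 64 * 64,
                         element = c("disk", "square")) {
  element <- match.arg(element)
  check_scalar_number(erosion_radius_px, "erosion_radius_px", min = 0)
  check_scalar_number(alpha, "alpha", min = 0, max = 1,
                      strict_min = TRUE, strict_max = TRUE)
  abort_if(any(fixed_thresholds < 0) || any(fixed_thresholds > 1),
           "fixed thresholds must be in [0, 1]")
  check_scalar_number(overlap_fraction, "overlap_fraction", min = 0,
                      max = 1, strict_min = TRUE)
  check_scalar_number(field_area_um2, "field_area_um2", min = 0,
                      strict_min = TRUE)
  structure(list(erosion_radius_px = as.integer(erosion_radius_px),
                 alpha = alpha, fixed_thresholds = fixed_thresholds,
                 strict_greater = isTRUE(strict_greater),
                 overlap_fraction = overlap_fraction,
                 field_area_um2 = field_area_um2, element = element),
            class = "quant_config")
}

#' Convert an erosion radius between image resolutions
#'
#' The reference erosion of 10 px is defined at 16 px/um. Fields imaged
#' or simulated at a different resolution use the physically equivalent
#' radius, `round(radius_px * px_per_um / ref_px_per_um)`, floored at
#' 1 px.
#'
#' @param radius_px radius at the reference resolution.
#' @param px_per_um target resolution.
#' @param ref_px_per_um reference resolution (default 16).
#' @return integer radius in pixels at the target resolution.
#' @export
scale_erosion_radius <- function(radius_px, px_per_um, ref_px_per_um = 16) {
  check_scalar_number(radius_px, "radius_px", min = 0)
  check_scalar_number(px_per_um, "px_per_um", min = 0, strict_min = TRUE)
  if (radius_px == 0) return(0L)
  max(1L, as.integer(round(radius_px * px_per_um / ref_px_per_um)))
}

#' Measure per-cell normalized GFP inside eroded marker masks
#'
#' For each label of the (red-channel) mask: erode by the configured
#' radius, then average the normalized green channel over the surviving
#' pixels. Cells eroded to nothing are returned with `valid = FALSE` and
#' carry no mean; geometry (area, centroid) always refers to the
#' uneroded label. The green channel must already be normalized with
#' [normalize_channel()] - raw input is an error, which enforces the
#' image-wide 0-1 normalization step of the workflow.
#'
#' @param field a [field_image()] whose `green` channel is normalized.
#' @param mask a [label_mask()] aligned to the field (typically from the
#'   red marker channel).
#' @param config a [quant_config()].
#' @param marker subtype label of the segmented marker channel (`"L"`,
#'   `"S"`, ...).
#' @param field_id identifier recorded in each row.
#' @return data.frame of class `cell_measurements`: `field_id`,
#'   `cell_id`, `marker`, `area_px`, `eroded_area_px`, `centroid_row`,
#'   `centroid_col`, `mean_norm_gfp`, `valid`.
#' @export
measure_cells <- function(field, mask, config = quant_config(),
                          marker = "L", field_id = NA_character_) {
  stopifnot(inherits(field, "field_image"), inherits(mask, "label_mask"),
            inherits(config, "quant_config"))
  green <- field$channels$green
  abort_if(is.null(green), "field has no green channel")
  abort_if(!is_normalized(green),
           "green channel is not normalized; run normalize_channel() first")
  check_aligned(field, mask)
  labs <- mask_labels(mask)
  if (!length(labs))
    return(empty_measurements())
  im <- mask$labels
  idx <- which(im > 0L)
  lab_of <- im[idx]
  nr <- nrow(im)
  rowpos <- (idx - 1L) %% nr + 1L
  colpos <- (idx - 1L) %/% nr + 1L
  area <- tabulate(lab_of, nbins = max(labs))[labs]
  cent_r <- rowsum(rowpos, lab_of)[, 1] / area
  cent_c <- rowsum(colpos, lab_of)[, 1] / area
  er <- erode_labels(mask, config$erosion_radius_px, config$element)
  eim <- er$mask$labels
  eidx <- which(eim > 0L)
  elab <- eim[eidx]
  e_area <- tabulate(elab, nbins = max(labs))[labs]
  gsum <- rep(0, max(labs))
  if (length(eidx)) {
    gs <- rowsum(green[eidx], elab)
    gsum[as.integer(rownames(gs))] <- gs[, 1]
  }
  valid <- e_area > 0L
  mean_gfp <- ifelse(valid, gsum[labs] / e_area, NA_real_)
  structure(data.frame(field_id = field_id, cell_id = labs,
                       marker = marker, area_px = as.integer(area),
                       eroded_area_px = as.integer(e_area),
                       centroid_row = unname(cent_r),
                       centroid_col = unname(cent_c),
                       mean_norm_gfp = unname(mean_gfp),
                       valid = unname(valid)),
            class = c("cell_measurements", "data.frame"))
}

empty_measurements <- function() {
  structure(data.frame(field_id = character(0), cell_id = integer(0),
                       marker = character(0), area_px = integer(0),
                       eroded_area_px = integer(0),
                       centroid_row = numeric(0), centroid_col = numeric(0),
                       mean_norm_gfp = numeric(0), valid = logical(0)),
            class = c("cell_measurements", "data.frame"))
}

#' Calibrate a classification threshold from control cells
#'
#' Empirical surrogate for choosing a threshold "from the distribution":
#' the threshold is the smallest observed control value t such that the
#' fraction of control values strictly above t is at most `alpha` - the
#' nearest-rank (1 - alpha) quantile. Applied back to its own calibration
#' set the threshold's exceedance is therefore <= alpha by construction
#' (with alpha = 0.05 this mirrors a threshold exceeded by ~5% of control
#' cells).
#'
#' @param control_values numeric vector of per-cell mean normalized GFP
#'   values from control cells; at least 20 values in \[0, 1\].
#' @param alpha target exceedance fraction.
#' @param subtype marker subtype the calibration refers to.
#' @return object of class `threshold_calibration`: `subtype`,
#'   `threshold`, `alpha_target`, `n_control_cells`,
#'   `observed_exceedance`, `source`.
#' @export
calibrate_threshold <- function(control_values, alpha = 0.05,
                                subtype = NA_character_) {
  abort_if(length(control_values) < 20L,
           "calibration needs >= 20 control values, got ",
           length(control_values))
  abort_if(any(is.na(control_values)) || any(control_values < 0) ||
             any(control_values > 1),
           "control values must be in [0, 1]")
  check_scalar_number(alpha, "alpha", min = 0, max = 1,
                      strict_min = TRUE, strict_max = TRUE)
  v <- sort(control_values)
  n <- length(v)
  thr <- v[ceiling(n * (1 - alpha))]
  structure(list(subtype = subtype, threshold = unname(thr),
                 alpha_target = alpha, n_control_cells = n,
                 observed_exceedance = mean(control_values > thr),
                 source = "calibrated"),
            class = "threshold_calibration")
}

#' @rdname calibrate_threshold
#' @param threshold fixed threshold value in \[0, 1\] (e.g. the published
#'   0.195 for L cones or 0.275 for S cones).
#' @export
fixed_threshold <- function(threshold, subtype = NA_character_) {
  check_scalar_number(threshold, "threshold", min = 0, max = 1)
  structure(list(subtype = subtype, threshold = threshold,
                 alpha_target = NA_real_, n_control_cells = 0L,
                 observed_exceedance = NA_real_, source = "fixed"),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "<threshold_calibration> %s threshold %.4g (%s; exceedance %s)\n",
    x$subtype, x$threshold, x$source,
    if (is.na(x$observed_exceedance)) "-" else
      sprintf("%.3f of %d cells", x$observed_exceedance,
              x$n_control_cells)))
  invisible(x)
}

#' Classify cells as double-positive
#'
#' A valid cell is positive when its mean normalized GFP exceeds the
#' calibrated (or fixed) threshold; with `strict_greater` (default) a
#' value exactly at the threshold is negative. Cells whose eroded mask
#' was empty (`valid = FALSE`) are excluded from the fraction rather than
#' counted negative.
#'
#' @param cells a `cell_measurements` data.frame from [measure_cells()].
#' @param calibration a [calibrate_threshold()] / [fixed_threshold()]
#'   result, or a bare numeric threshold.
#' @param strict_greater comparison strictness.
#' @return list of class `dp_classification`: `positive` (logical, one
#'   per valid cell, named by cell id), `n_valid`, `n_positive`,
#'   `fraction`, `threshold`.
#' @export
classify_double_positive <- function(cells, calibration,
                                     strict_greater = TRUE) {
  if (is.numeric(calibration) && length(calibration) == 1L)
    calibration <- fixed_threshold(calibration)
  stopifnot(inherits(calibration, "threshold_calibration"))
  v <- cells[cells$valid, , drop = FALSE]
  abort_if(nrow(v) == 0L, "no cells to classify")
  thr <- calibration$threshold
  pos <- if (strict_greater) v$mean_norm_gfp > thr else
    v$mean_norm_gfp >= thr
  structure(list(positive = stats::setNames(pos, v$cell_id),
                 n_valid = nrow(v), n_positive = sum(pos),
                 fraction = mean(pos), threshold = thr),
            class = "dp_classification")
}

#' Count GFP-only cells
#'
#' Mechanized version of counting single-positive ("GFP only") cells by
#' excluding cells already segmented in the red marker channel: a green
#' label is counted unless at least `overlap_fraction` of its pixels lie
#' inside some red label.
#'
#' @param green_mask,red_mask aligned [label_mask()]s.
#' @param overlap_fraction exclusion threshold in (0, 1\].
#' @return integer count, with attribute `per_label` (data.frame of each
#'   green label's overlap fraction and counted flag).
#' @export
count_gfp_only <- function(green_mask, red_mask, overlap_fraction = 0.5) {
  stopifnot(inherits(green_mask, "label_mask"),
            inherits(red_mask, "label_mask"))
  abort_if(!identical(dim(green_mask$labels), dim(red_mask$labels)),
           "green and red masks have different shapes")
  check_scalar_number(overlap_fraction, "overlap_fraction", min = 0,
                      max = 1, strict_min = TRUE)
  labs <- mask_labels(green_mask)
  if (!length(labs)) {
    out <- 0L
    attr(out, "per_label") <- data.frame(label = integer(0),
                                         overlap = numeric(0),
                                         counted = logical(0))
    return(out)
  }
  gidx <- which(green_mask$labels > 0L)
  glab <- green_mask$labels[gidx]
  inred <- red_mask$labels[gidx] > 0L
  area <- tabulate(glab, nbins = max(labs))[labs]
  ov <- rep(0, max(labs))
  s <- rowsum(as.numeric(inred), glab)
  ov[as.integer(rownames(s))] <- s[, 1]
  frac <- ov[labs] / area
  counted <- frac < overlap_fraction
  out <- sum(counted)
  attr(out, "per_label") <- data.frame(label = labs, overlap = frac,
                                       counted = counted)
  out
}

#' Summarize one field
#'
#' Per-field counts and densities (the field is the experimental unit:
#' one value per retina enters the group comparison). Densities per mm2
#' divide the count by the field area in mm2; a 64 um field holding 100
#' cells is 24414.0625 cells/mm2. With no valid cells the
#' double-positive fraction is missing (`NA`), never 0.
#'
#' @param cells a `cell_measurements` data.frame.
#' @param classification optional [classify_double_positive()] result.
#' @param config a [quant_config()] (supplies the field area).
#' @param field_id,group identifiers.
#' @param gfp_only_count optional [count_gfp_only()] result.
#' @return one-row data.frame of class `field_summary`.
#' @export
summarize_field <- function(cells, classification = NULL,
                            config = quant_config(),
                            field_id = NA_character_, group = NA_character_,
                            gfp_only_count = NA_integer_) {
  stopifnot(inherits(config, "quant_config"))
  n_cells <- nrow(cells)
  n_valid <- sum(cells$valid)
  area_mm2 <- config$field_area_um2 / 1e6
  dp_count <- if (!is.null(classification))
    classification$n_positive else NA_integer_
  dp_fraction <- if (!is.null(classification) && classification$n_valid > 0)
    classification$fraction else NA_real_
  structure(data.frame(field_id = field_id, group = group,
                       marker = if (n_cells) cells$marker[1] else
                         NA_character_,
                       n_cells = n_cells, n_valid = n_valid,
                       count_per_field = n_cells,
                       density_per_mm2 = n_cells / area_mm2,
                       double_positive_count = dp_count,
                       double_positive_fraction = dp_fraction,
                       gfp_only_count = as.integer(gfp_only_count)),
            class = c("field_summary", "data.frame"))
}
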