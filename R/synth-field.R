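#' Specification of a synthetic cone-mosaic field
#'
#' Describes one simulated two-channel confocal field of the larval
#' zebrafish photoreceptor mosaic: a jittered arrangement of red-marker
#' cells (e.g. L or S cones carrying a red transgene) and green-only cells
#' (e.g. M cones of the GFP line), of which a specified fraction of the
#' red cells is double-positive (expresses GFP above baseline). Cells are
#' rendered as hard-edged disks, blurred by a single Gaussian PSF, and
#' corrupted by additive background and Gaussian detector noise on a
#' 12-bit (0-4095) scale.
#'
#' Defaults emulate the acquisition geometry of the screen this package
#' models: a 64 um x 64 um central-retina field at 1024 x 1024 px
#' (16 px/um), on the order of a hundred marker cells per field.
#'
#' @param field_size_um side of the square field in microns.
#' @param px_per_um pixels per micron.
#' @param n_red_cells,n_green_only_cells cell counts per field.
#' @param double_positive_fraction proportion in \[0, 1\] of red cells
#'   that also express green.
#' @param cell_radius_um cell footprint radius in microns.
#' @param min_spacing_um minimum center-to-center distance in microns.
#' @param intensity_params named list of `c(mean, sd)` pairs in detector
#'   units: `red` (red signal in red cells), `green_only` (green signal in
#'   green-only cells), `double_positive` (green signal in double-positive
#'   cells; `NULL` defaults to `green_only`), `green_baseline` (residual
#'   green in red-only cells, default mean 5% of the green-only mean).
#' @param psf_sigma_px Gaussian blur sd in pixels.
#' @param background_level,noise_sd additive background and Gaussian noise
#'   in detector units.
#' @param layout `"rejection"` (hard-core rejection sampling, default) or
#'   `"hex"` (jittered hexagonal lattice for stricter regularity).
#' @param hex_jitter_um positional jitter sd for the hex layout.
#' @param exact_counts if `TRUE`, exactly `round(f * n_red_cells)` cells
#'   are double-positive; otherwise each red cell is an independent
#'   Bernoulli draw.
#' @param seed integer random seed; identical spec + seed gives
#'   bit-identical output.
#' @return object of class `mosaic_spec`.
#' @export
mosaic_spec <- function(field_size_um = 64,
                        px_per_um = 16,
                        n_red_cells = 100L,
                        n_green_only_cells = 60L,
                        double_positive_fraction = 0.05,
                        cell_radius_um = 1.5,
                        min_spacing_um = 3.4,
                        intensity_params = list(),
                        psf_sigma_px = 2,
                        background_level = 80,
                        noise_sd = 20,
                        layout = c("rejection", "hex"),
                        hex_jitter_um = 0.25,
                        exact_counts = FALSE,
                        seed = 1L) {
  layout <- match.arg(layout)
  check_scalar_number(field_size_um, "field_size_um", min = 0,
                      strict_min = TRUE)
  check_scalar_number(px_per_um, "px_per_um", min = 0, strict_min = TRUE)
  check_scalar_number(n_red_cells, "n_red_cells", min = 0)
  check_scalar_number(n_green_only_cells, "n_green_only_cells", min = 0)
  check_scalar_number(double_positive_fraction,
                      "double_positive_fraction", min = 0, max = 1)
  check_scalar_number(cell_radius_um, "cell_radius_um", min = 0,
                      strict_min = TRUE)
  check_scalar_number(min_spacing_um, "min_spacing_um", min = 0,
                      strict_min = TRUE)
  check_scalar_number(psf_sigma_px, "psf_sigma_px", min = 0)
  check_scalar_number(background_level, "background_level", min = 0)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  defaults <- list(red = c(mean = 2000, sd = 300),
                   green_only = c(mean = 2000, sd = 300),
                   double_positive = NULL,
                   green_baseline = NULL)
  ip <- modifyList(defaults, intensity_params, keep.null = TRUE)
  if (is.null(ip$double_positive)) ip$double_positive <- ip$green_only
  if (is.null(ip$green_baseline))
    ip$green_baseline <- c(mean = unname(0.05 * ip$green_only["mean"]),
                           sd = unname(0.05 * ip$green_only["sd"]))
  for (nm in c("red", "green_only", "double_positive", "green_baseline"))
    abort_if(length(ip[[nm]]) != 2L || any(ip[[nm]] < 0),
             "intensity_params$", nm, " must be c(mean, sd), both >= 0")
  # coarse feasibility check; placement itself enforces the hard bound
  n_total <- n_red_cells + n_green_only_cells
  usable <- (field_size_um - 2 * cell_radius_um)^2
  abort_if(usable <= 0 || n_total * pi * (min_spacing_um / 2)^2 >
             0.68 * usable,
           "field too crowded: ", n_total, " cells at spacing ",
           min_spacing_um, " um cannot fit in ", field_size_um, " um")
  structure(list(field_size_um = field_size_um, px_per_um = px_per_um,
                 n_red_cells = as.integer(n_red_cells),
                 n_green_only_cells = as.integer(n_green_only_cells),
                 double_positive_fraction = double_positive_fraction,
                 cell_radius_um = cell_radius_um,
                 min_spacing_um = min_spacing_um,
                 intensity_params = ip, psf_sigma_px = psf_sigma_px,
                 background_level = background_level, noise_sd = noise_sd,
                 layout = layout, hex_jitter_um = hex_jitter_um,
                 exact_counts = isTRUE(exact_counts),
                 seed = as.integer(seed)),
            class = "mosaic_spec")
}

# hard-core placement by rejection sampling; returns n x 2 matrix (um)
place_rejection <- function(n, field, margin, spacing) {
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- max(2000L, 400L * n)
  lo <- margin; hi <- field - margin
  abort_if(hi <= lo, "field too crowded: no room inside the cell margin")
  sp2 <- spacing^2
  while (placed < n) {
    attempts <- attempts + 1L
    abort_if(attempts > max_attempts,
             "field too crowded: placement failed after ", max_attempts,
             " attempts (", placed, "/", n, " cells placed)")
    x <- runif(1, lo, hi); y <- runif(1, lo, hi)
    if (placed == 0L ||
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >=
        sp2) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
  }
  cbind(x = xs, y = ys)
}

# jittered hexagonal lattice; n points sampled from the lattice sites
place_hex <- function(n, field, margin, spacing, jitter) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  dy <- spacing * sqrt(3) / 2
  ys <- seq(margin, field - margin, by = dy)
  pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
    off <- if (i %% 2L == 0L) spacing / 2 else 0
    xs <- seq(margin + off, field - margin, by = spacing)
    cbind(x = xs, y = ys[i])
  }))
  abort_if(nrow(pts) < n, "field too crowded: hex lattice holds only ",
           nrow(pts), " sites for ", n, " cells")
  pts <- pts[sample.int(nrow(pts), n), , drop = FALSE]
  pts + matrix(rnorm(2 * n, 0, jitter), ncol = 2)
}

rtrunc_norm <- function(n, mean, sd) pmax(0, rnorm(n, mean, sd))

# linear indices of the disk of radius r_px around (cx, cy) (px coords)
# in an nr x nc matrix
disk_indices <- function(nr, nc, cx, cy, r_px) {
  r0 <- max(1L, floor(cy - r_px)); r1 <- min(nr, ceiling(cy + r_px))
  c0 <- max(1L, floor(cx - r_px)); c1 <- min(nc, ceiling(cx + r_px))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  sel <- outer((rows - cy)^2, (cols - cx)^2, "+") <= r_px^2
  (rep.int(cols - 1L, rep.int(length(rows), length(cols))) * nr +
      rows)[sel]
}

#' Generate one synthetic field with ground truth
#'
#' Renders the mosaic described by a [mosaic_spec()]: places cell centers
#' (hard-core rejection sampling or jittered hex lattice), assigns
#' classes (red-only / double-positive / green-only), draws per-cell
#' intensities, rasterizes disks into the red and green channels, applies
#' Gaussian blur, adds background and noise, and quantizes to integer
#' detector units clamped to the 12-bit range. The ground-truth label mask
#' is noise-free, labelled 1..n in placement order (red cells first).
#'
#' @param spec a [mosaic_spec()].
#' @return list of class `synthetic_field` with elements `field` (a
#'   [field_image()]) and `truth` (list: `label_mask`, `cell_table` with
#'   one row per cell - class, center in um, radius, drawn intensities).
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "mosaic_spec"))
  with_seed(spec$seed, generate_field_impl(spec))
}

generate_field_impl <- function(spec) {
  npx <- as.integer(round(spec$field_size_um * spec$px_per_um))
  n_red <- spec$n_red_cells; n_green <- spec$n_green_only_cells
  n <- n_red + n_green
  red <- matrix(0, npx, npx); green <- matrix(0, npx, npx)
  mask <- matrix(0L, npx, npx)
  cell_table <- data.frame(cell_id = integer(0), class = character(0),
                           x_um = numeric(0), y_um = numeric(0),
                           radius_um = numeric(0),
                           red_intensity = numeric(0),
                           green_intensity = numeric(0))
  if (n > 0L) {
    centers <- if (spec$layout == "rejection")
      place_rejection(n, spec$field_size_um, spec$cell_radius_um,
                      spec$min_spacing_um)
    else
      place_hex(n, spec$field_size_um, spec$cell_radius_um,
                spec$min_spacing_um, spec$hex_jitter_um)
    classes <- rep(c("red", "green_only"), c(n_red, n_green))
    if (n_red > 0L) {
      k <- if (spec$exact_counts) {
        k_dp <- as.integer(round(spec$double_positive_fraction * n_red))
        dp_idx <- if (k_dp > 0L) sample.int(n_red, k_dp) else integer(0)
        dp_idx
      } else {
        which(runif(n_red) < spec$double_positive_fraction)
      }
      classes[k] <- "double_positive"
      classes[classes == "red"] <- "red_only"
    }
    ip <- spec$intensity_params
    red_int <- numeric(n); green_int <- numeric(n)
    is_red <- classes %in% c("red_only", "double_positive")
    red_int[is_red] <- rtrunc_norm(sum(is_red), ip$red["mean"],
                                   ip$red["sd"])
    for (cls in c("red_only", "double_positive", "green_only")) {
      sel <- classes == cls
      if (!any(sel)) next
      p <- switch(cls, red_only = ip$green_baseline,
                  double_positive = ip$double_positive,
                  green_only = ip$green_only)
      green_int[sel] <- rtrunc_norm(sum(sel), p["mean"], p["sd"])
    }
    r_px <- spec$cell_radius_um * spec$px_per_um
    for (i in seq_len(n)) {
      cx <- centers[i, "x"] * spec$px_per_um + 0.5
      cy <- centers[i, "y"] * spec$px_per_um + 0.5
      di <- disk_indices(npx, npx, cx, cy, r_px)
      if (is_red[i]) red[di] <- red[di] + red_int[i]
      green[di] <- green[di] + green_int[i]
      mask[di] <- i
    }
    cell_table <- data.frame(cell_id = seq_len(n), class = classes,
                             x_um = unname(centers[, "x"]),
                             y_um = unname(centers[, "y"]),
                             radius_um = spec$cell_radius_um,
                             red_intensity = red_int,
                             green_intensity = green_int)
  }
  finish <- function(ch) {
    if (spec$psf_sigma_px > 0) ch <- gaussian_blur(ch, spec$psf_sigma_px)
    ch <- ch + spec$background_level
    if (spec$noise_sd > 0)
      ch <- ch + matrix(rnorm(length(ch), 0, spec$noise_sd),
                        nrow(ch), ncol(ch))
    matrix(as.integer(pmin(4095, pmax(0, round(ch)))), nrow(ch), ncol(ch))
  }
  red <- finish(red)
  green <- finish(green)
  field <- field_image(list(red = red, green = green), spec$px_per_um,
                       provenance = list(generator = "conemosaiq",
                                         seed = spec$seed))
  truth <- list(label_mask = label_mask(storage_int(mask), "truth"),
                cell_table = cell_table)
  structure(list(field = field, truth = truth, spec = spec),
            class = "synthetic_field")
}

storage_int <- function(m) { storage.mode(m) <- "integer"; m }

#' Specification of a synthetic control/mutant cohort
#'
#' Named groups of fields sharing a base [mosaic_spec()] with per-group
#' overrides (typically densities and/or the double-positive fraction
#' differ between a control and an F0-mutant group). Field seeds are
#' derived deterministically from `base_seed`, the group name, and the
#' field index.
#'
#' @param groups named list; each element is a list with `n_fields` and
#'   optionally any [mosaic_spec()] fields to override.
#' @param base a base [mosaic_spec()] (its seed is ignored).
#' @param base_seed integer master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, base = mosaic_spec(), base_seed = 1L) {
  abort_if(!is.list(groups) || length(groups) == 0L ||
             is.null(names(groups)) || any(names(groups) == ""),
           "groups must be a non-empty named list")
  for (g in names(groups)) {
    abort_if(is.null(groups[[g]]$n_fields) || groups[[g]]$n_fields < 1L,
             "group '", g, "' needs n_fields >= 1")
    bad <- setdiff(setdiff(names(groups[[g]]), "n_fields"),
                   setdiff(names(base), "seed"))
    abort_if(length(bad) > 0L, "unknown mosaic_spec override(s) in group '",
             g, "': ", paste(bad, collapse = ", "))
  }
  stopifnot(inherits(base, "mosaic_spec"))
  structure(list(groups = groups, base = base,
                 base_seed = as.integer(base_seed)),
            class = "cohort_spec")
}

#' Generate a cohort of synthetic fields
#'
#' One `(field, truth)` pair per field per group, with a manifest
#' recording group, field index, derived seed, and the true generating
#' parameters. Deterministic under `base_seed`.
#'
#' @param cohort a [cohort_spec()].
#' @return list of class `synthetic_cohort`: `fields` (named list of
#'   `synthetic_field`, names `<group>_<index>`) and `manifest`
#'   (data.frame).
#' @export
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  fields <- list()
  rows <- list()
  for (g in names(cohort$groups)) {
    grp <- cohort$groups[[g]]
    overrides <- grp[setdiff(names(grp), "n_fields")]
    for (i in seq_len(grp$n_fields)) {
      seed_i <- derive_seed(cohort$base_seed, g, i)
      annotate <- function(e)
        stop("group '", g, "', field ", i, ": ", conditionMessage(e),
             call. = FALSE)
      spec_i <- tryCatch({
        args <- modifyList(unclass(cohort$base), overrides)
        args$seed <- seed_i
        do.call(mosaic_spec, args[names(formals(mosaic_spec))])
      }, error = annotate)
      sf <- tryCatch(generate_field(spec_i), error = annotate)
      id <- paste0(g, "_", i)
      fields[[id]] <- sf
      rows[[id]] <- data.frame(
        field_id = id, group = g, field_index = i, seed = seed_i,
        n_red_cells = spec_i$n_red_cells,
        n_green_only_cells = spec_i$n_green_only_cells,
        double_positive_fraction = spec_i$double_positive_fraction,
        true_dp_count = sum(sf$truth$cell_table$class == "double_positive"))
    }
  }
  structure(list(fields = fields,
                 manifest = do.call(rbind, c(rows,
                                             make.row.names = FALSE))),
            class = "synthetic_cohort")
}
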