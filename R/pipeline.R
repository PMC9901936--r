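# Orchestration: one config document drives simulate -> segment ->
# quantify -> compare (run_screen) and the expression workflow (run_xpr).
# Configs are plain R lists or JSON files; unknown keys are rejected so a
# typo in a threshold name cannot silently fall back to a default.

SCREEN_CONFIG_KEYS <- list(
  top = c("seed", "cohort", "control_group", "segmentation", "quant",
          "stats"),
  cohort = c("base", "groups"),
  segmentation = c("smooth_sigma_px", "threshold_method", "min_area_px",
                   "split_touching"),
  quant = c("erosion_radius_px", "alpha", "fixed_thresholds",
            "strict_greater", "overlap_fraction", "field_area_um2",
            "element", "marker", "threshold", "scale_erosion_to_field"),
  stats = c("significance_level"))

XPR_CONFIG_KEYS <- list(
  top = c("seed", "expression", "counts", "comparisons", "tf_genes",
          "rho_gene", "criteria"),
  counts = c("counts_csv", "gene_lengths_csv", "metadata_csv"),
  criteria = c("min_fold", "max_p", "max_padj", "min_positive_fraction"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  abort_if(length(bad) > 0L, "unknown config key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    abort_if(!file.exists(config), "config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  abort_if(!is.list(config), "config must be a list or a JSON file path")
  config
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full screen pipeline on a synthetic cohort
#'
#' Executes cohort simulation, reference segmentation of the red marker
#' channel, green-channel normalization, eroded per-cell measurement,
#' threshold calibration on the pooled control cells (or a fixed
#' threshold), double-positive classification, per-field summaries, and
#' the group comparison on per-field double-positive fractions. All
#' randomness derives from `config$seed`; rerunning the same config and
#' seed reproduces the outputs byte for byte.
#'
#' The quantification erosion radius is interpreted at the reference
#' resolution of 16 px/um and scaled to the simulated field's resolution
#' (see [scale_erosion_radius()]); set
#' `quant$scale_erosion_to_field = FALSE` to use the radius verbatim.
#'
#' @param config nested list (or JSON path): `seed`; `cohort` (`base`
#'   mosaic overrides, `groups`); `control_group`; optional
#'   `segmentation`, `quant` (including `marker` and `threshold` =
#'   `"calibrate"` or a fixed number), `stats`.
#' @param out_dir optional output directory; writes
#'   `field_summaries.csv`, `cell_measurements.csv`, `comparison.json`,
#'   `calibration.json` and `manifest.json`. Partial outputs are removed
#'   on failure.
#' @return list of class `screen_report`.
#' @export
run_screen <- function(config, out_dir = NULL) {
  config <- load_config(config)
  check_keys(config, SCREEN_CONFIG_KEYS$top, "screen config")
  for (k in c("cohort", "segmentation", "quant", "stats"))
    if (!is.null(config[[k]]))
      check_keys(config[[k]], SCREEN_CONFIG_KEYS[[k]], k)
  abort_if(is.null(config$cohort) || is.null(config$cohort$groups),
           "config$cohort$groups is required")
  control <- config$control_group
  abort_if(is.null(control) ||
             !control %in% names(config$cohort$groups),
           "no control group for calibration")
  seed <- as.integer(config$seed %||% 1L)

  cohort <- run_stage("simulate", {
    base_args <- config$cohort$base %||% list()
    base <- do.call(mosaic_spec, base_args)
    generate_cohort(cohort_spec(config$cohort$groups, base = base,
                                base_seed = seed))
  })

  seg_params <- do.call(segmentation_params,
                        config$segmentation %||% list())
  qc_cfg <- config$quant %||% list()
  marker <- qc_cfg$marker %||% "L"
  thr_mode <- qc_cfg$threshold %||% "calibrate"
  scale_erosion <- qc_cfg$scale_erosion_to_field %||% TRUE
  qc_args <- qc_cfg[setdiff(names(qc_cfg),
                            c("marker", "threshold",
                              "scale_erosion_to_field"))]
  qc <- do.call(quant_config, qc_args)
  first_spec <- cohort$fields[[1]]$spec
  qc$field_area_um2 <- first_spec$field_size_um^2
  if (isTRUE(scale_erosion))
    qc$erosion_radius_px <- scale_erosion_radius(qc$erosion_radius_px,
                                                 first_spec$px_per_um)

  measured <- run_stage("quantify", {
    lapply(names(cohort$fields), function(id) {
      sf <- cohort$fields[[id]]
      mask <- segment_reference(sf$field$channels$red, seg_params, "red")
      sf$field$channels$green <-
        normalize_channel(sf$field$channels$green)
      measure_cells(sf$field, mask, qc, marker = marker, field_id = id)
    })
  })
  names(measured) <- names(cohort$fields)

  calibration <- run_stage("calibrate", {
    if (identical(thr_mode, "calibrate")) {
      ctrl_ids <- cohort$manifest$field_id[cohort$manifest$group ==
                                             control]
      pool <- unlist(lapply(measured[ctrl_ids], function(m)
        m$mean_norm_gfp[m$valid]))
      calibrate_threshold(pool, alpha = qc$alpha, subtype = marker)
    } else {
      fixed_threshold(as.numeric(thr_mode), subtype = marker)
    }
  })

  summaries <- run_stage("classify", {
    do.call(rbind, lapply(names(measured), function(id) {
      cls <- classify_double_positive(measured[[id]], calibration,
                                      strict_greater = qc$strict_greater)
      summarize_field(measured[[id]], cls, qc, field_id = id,
                      group = cohort$manifest$group[
                        cohort$manifest$field_id == id])
    }))
  })

  stats_cfg <- config$stats %||% list()
  comparison <- run_stage("compare", {
    groups <- split(summaries$double_positive_fraction, summaries$group)
    groups <- groups[unique(summaries$group)]  # stable group order
    compare_groups(groups, control,
                   significance_level =
                     stats_cfg$significance_level %||% 0.01)
  })

  report <- structure(
    list(field_summaries = summaries, cell_measurements = measured,
         calibration = calibration, comparison = comparison,
         manifest = list(seed = seed, config_hash = config_hash(config),
                         package_version =
                           as.character(utils::packageVersion("conemosaiq")),
                         n_fields = nrow(cohort$manifest),
                         groups = names(config$cohort$groups))),
    class = "screen_report")
  if (!is.null(out_dir)) write_screen_report(report, out_dir)
  report
}

write_screen_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("stage 'write' failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    f <- file.path(out_dir, "field_summaries.csv")
    write.csv(report$field_summaries, f, row.names = FALSE)
    written <- c(written, f)
    f <- file.path(out_dir, "cell_measurements.csv")
    write.csv(do.call(rbind, report$cell_measurements), f,
              row.names = FALSE)
    written <- c(written, f)
    f <- file.path(out_dir, "calibration.json")
    jsonlite::write_json(unclass(report$calibration), f,
                         auto_unbox = TRUE, digits = NA)
    written <- c(written, f)
    f <- file.path(out_dir, "comparison.json")
    cmp <- report$comparison
    jsonlite::write_json(
      list(kruskal = unclass(cmp$kruskal),
           pairwise = cmp$pairwise,
           summaries = cmp$summaries,
           significance_level = cmp$significance_level,
           significant = cmp$significant),
      f, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    written <- c(written, f)
    f <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(report$manifest, f, auto_unbox = TRUE,
                         digits = NA)
    written <- c(written, f)
  }, error = on_fail)
  invisible(out_dir)
}

#' Read an expression matrix from CSV files
#'
#' `counts_csv`: first column gene names, remaining columns samples.
#' `gene_lengths_csv`: columns `gene`, `length`. `metadata_csv`: columns
#' `sample`, `subtype` (optional `replicate`, `total`).
#'
#' @param counts_csv,gene_lengths_csv,metadata_csv file paths.
#' @return an [expression_matrix()].
#' @export
read_expression_csv <- function(counts_csv, gene_lengths_csv,
                                metadata_csv) {
  cdf <- read.csv(counts_csv, check.names = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf[[1]]
  ldf <- read.csv(gene_lengths_csv)
  mdf <- read.csv(metadata_csv)
  abort_if(!all(colnames(counts) %in% mdf$sample),
           "metadata missing sample(s): ",
           paste(setdiff(colnames(counts), mdf$sample), collapse = ", "))
  mdf <- mdf[match(colnames(counts), mdf$sample), ]
  expression_matrix(counts,
                    gene_lengths = stats::setNames(ldf$length, ldf$gene),
                    totals = if ("total" %in% names(mdf)) mdf$total,
                    subtype = mdf$subtype,
                    replicate = mdf$replicate)
}

#' Run the expression workflow
#'
#' FPKM transform, per-gene statistics (internal stand-in or ingested),
#' the differential-expression filter per requested comparison, the
#' transcription-factor expression criterion, and the rod-contamination
#' report.
#'
#' @param config nested list (or JSON path): `seed`; either `expression`
#'   ([synth_expression_spec()] overrides) or `counts` (CSV paths);
#'   `comparisons` (list of `list(a =, b =, rod_vs_cone =)`); optional
#'   `tf_genes`, `rho_gene`, `criteria`.
#' @param out_dir optional output directory.
#' @return list of class `xpr_report`.
#' @export
run_xpr <- function(config, out_dir = NULL) {
  config <- load_config(config)
  check_keys(config, XPR_CONFIG_KEYS$top, "xpr config")
  seed <- as.integer(config$seed %||% 1L)
  em <- run_stage("ingest", {
    if (!is.null(config$counts)) {
      check_keys(config$counts, XPR_CONFIG_KEYS$counts, "counts")
      do.call(read_expression_csv, config$counts)
    } else {
      spec_args <- config$expression %||% list()
      spec_args$seed <- seed
      generate_expression(do.call(synth_expression_spec,
                                  spec_args))$matrix
    }
  })
  crit_args <- config$criteria %||% list()
  if (!is.null(crit_args))
    check_keys(crit_args, XPR_CONFIG_KEYS$criteria, "criteria")
  comparisons <- config$comparisons %||% list()
  valid_subtypes <- unique(em$subtype)
  deg <- run_stage("deg", lapply(comparisons, function(cmp) {
    abort_if(!all(c(cmp$a, cmp$b) %in% valid_subtypes),
             "unknown comparison group(s) '", cmp$a, "'/'", cmp$b,
             "'; valid subtype labels: ",
             paste(valid_subtypes, collapse = ", "))
    crit <- do.call(deg_criteria,
                    c(crit_args,
                      list(rod_vs_cone_mode = isTRUE(cmp$rod_vs_cone))))
    deg_filter(em, cmp$a, cmp$b, criteria = crit)
  }))
  names(deg) <- vapply(comparisons, function(cmp)
    paste0(cmp$a, "_vs_", cmp$b), character(1))
  tf <- if (!is.null(config$tf_genes))
    run_stage("tf", tf_expressed(em, unlist(config$tf_genes))) else NULL
  contamination <- if ((config$rho_gene %||% "rho") %in%
                         rownames(em$counts) &&
                       "rod" %in% em$subtype)
    run_stage("contamination",
              rod_contamination(em, config$rho_gene %||% "rho")) else NULL
  report <- structure(
    list(matrix = em, fpkm = fpkm(em), deg = deg, tf = tf,
         contamination = contamination,
         manifest = list(seed = seed, config_hash = config_hash(config),
                         package_version =
                           as.character(utils::packageVersion("conemosaiq")))),
    class = "xpr_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(report$deg))
      write.csv(report$deg[[nm]],
                file.path(out_dir, paste0("deg_", nm, ".csv")),
                row.names = FALSE)
    if (!is.null(report$tf))
      write.csv(report$tf, file.path(out_dir, "tf_expressed.csv"),
                row.names = FALSE)
    if (!is.null(report$contamination))
      write.csv(report$contamination,
                file.path(out_dir, "contamination.csv"),
                row.names = FALSE)
    jsonlite::write_json(report$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}
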