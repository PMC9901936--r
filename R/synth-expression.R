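#' Default planted enriched gene sets
#'
#' Marker-style enrichment for the five zebrafish photoreceptor subtypes:
#' each subtype gets `n_per_set` genes enriched `fold`-fold, anchored by
#' the canonical opsins (`rho`; `opn1sw1`; `opn1sw2`; `opn1mw1-4`;
#' `opn1lw1-2`) and padded with filler genes. Sets are subtype-exclusive
#' (mean zero outside the enriched subtype), which makes `rho` a clean
#' rod-contamination sentinel.
#'
#' @param n_per_set genes per subtype set.
#' @param fold planted fold size (> 0; 1 plants no effect).
#' @return named list of per-subtype sets `list(genes, fold, exclusive)`.
#' @export
default_enriched_sets <- function(n_per_set = 10L, fold = 10) {
  anchors <- list(rod = "rho", UV = "opn1sw1", S = "opn1sw2",
                  M = paste0("opn1mw", 1:4), L = paste0("opn1lw", 1:2))
  filler_start <- 0L
  sets <- list()
  for (s in names(anchors)) {
    extra <- max(0L, n_per_set - length(anchors[[s]]))
    filler <- if (extra > 0L)
      sprintf("%s_enr%02d", tolower(s), seq_len(extra)) else character(0)
    sets[[s]] <- list(genes = c(anchors[[s]], filler), fold = fold,
                      exclusive = TRUE)
    filler_start <- filler_start + extra
  }
  sets
}

#' Specification of a synthetic photoreceptor expression matrix
#'
#' Negative-binomial gene x sample counts for the five photoreceptor
#' subtypes, emulating pooled-cell bulk profiles: a flat baseline mean,
#' planted per-subtype enriched sets (optionally subtype-exclusive),
#' per-sample library-size scaling, and a tunable rod-contamination
#' fraction implemented as a count-level mixture with the rod mean
#' profile.
#'
#' Defaults mirror the study design this package models: 35 samples
#' (rod 6, UV 5, S 6, M 7, L 6), each a pool of 20 cells of one subtype.
#'
#' @param n_genes total number of genes (>= number of planted genes).
#' @param n_samples named integer vector of replicates per subtype.
#' @param enriched_sets list as produced by [default_enriched_sets()];
#'   sets must be disjoint.
#' @param baseline_mean baseline negative-binomial mean (raw scale, before
#'   library-size scaling).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts.
#' @param gene_lengths named vector of lengths in bp, or `NULL` to draw
#'   them reproducibly in 500-4000 bp.
#' @param library_size expected total counts per sample.
#' @param contamination_fraction proportion in \[0, 1) of each cone
#'   sample's counts drawn from the rod mean profile.
#' @param seed integer seed.
#' @return object of class `synth_expression_spec`.
#' @export
synth_expression_spec <- function(n_genes = 500L,
                                  n_samples = c(rod = 6L, UV = 5L, S = 6L,
                                                M = 7L, L = 6L),
                                  enriched_sets = default_enriched_sets(),
                                  baseline_mean = 50,
                                  dispersion = 0.2,
                                  gene_lengths = NULL,
                                  library_size = 2e6,
                                  contamination_fraction = 0,
                                  seed = 1L) {
  abort_if(is.null(names(n_samples)) || any(n_samples < 1L),
           "n_samples must be a named vector of positive counts")
  check_scalar_number(baseline_mean, "baseline_mean", min = 0,
                      strict_min = TRUE)
  check_scalar_number(dispersion, "dispersion", min = 0)
  check_scalar_number(library_size, "library_size", min = 0,
                      strict_min = TRUE)
  check_scalar_number(contamination_fraction, "contamination_fraction",
                      min = 0, max = 1, strict_max = TRUE)
  all_genes <- unlist(lapply(enriched_sets, `[[`, "genes"))
  abort_if(anyDuplicated(all_genes) > 0L,
           "enriched sets overlap: ",
           paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "))
  abort_if(!all(names(enriched_sets) %in% names(n_samples)),
           "enriched set subtype(s) missing from n_samples: ",
           paste(setdiff(names(enriched_sets), names(n_samples)),
                 collapse = ", "))
  abort_if(n_genes < length(all_genes),
           "n_genes smaller than the number of planted genes")
  for (s in names(enriched_sets))
    abort_if(enriched_sets[[s]]$fold <= 0, "fold must be > 0 for set ", s)
  structure(list(n_genes = as.integer(n_genes), n_samples = n_samples,
                 enriched_sets = enriched_sets,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 gene_lengths = gene_lengths, library_size = library_size,
                 contamination_fraction = contamination_fraction,
                 seed = as.integer(seed)),
            class = "synth_expression_spec")
}

#' Generate a synthetic expression matrix with truth tables
#'
#' Builds the per-subtype mean profile (baseline everywhere; enriched
#' genes at `fold * baseline` in their subtype, zero elsewhere when
#' exclusive), scales each subtype's profile to the target library size,
#' mixes a `contamination_fraction` of the rod profile into each cone
#' sample's means, and draws negative-binomial counts.
#'
#' @param spec a [synth_expression_spec()].
#' @return list of class `synth_expression`: `matrix` (an
#'   [expression_matrix()]), `truth` (data.frame of planted genes:
#'   gene, subtype, fold, exclusive), and `mean_profile` (gene x subtype
#'   expected raw means).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synth_expression_spec"))
  with_seed(spec$seed, generate_expression_impl(spec))
}

generate_expression_impl <- function(spec) {
  planted <- unname(unlist(lapply(spec$enriched_sets, `[[`, "genes")))
  n_fill <- spec$n_genes - length(planted)
  genes <- c(planted,
             if (n_fill > 0L) sprintf("gene%05d", seq_len(n_fill)))
  subtypes <- names(spec$n_samples)
  mu <- matrix(spec$baseline_mean, spec$n_genes, length(subtypes),
               dimnames = list(genes, subtypes))
  truth_rows <- list()
  for (s in names(spec$enriched_sets)) {
    set <- spec$enriched_sets[[s]]
    if (isTRUE(set$exclusive)) mu[set$genes, ] <- 0
    mu[set$genes, s] <- set$fold * spec$baseline_mean
    truth_rows[[s]] <- data.frame(gene = set$genes, subtype = s,
                                  fold = set$fold,
                                  exclusive = isTRUE(set$exclusive))
  }
  # scale each subtype profile to the target library size
  mu_scaled <- sweep(mu, 2, colSums(mu), "/") * spec$library_size
  lengths <- spec$gene_lengths
  if (is.null(lengths))
    lengths <- stats::setNames(round(runif(spec$n_genes, 500, 4000)), genes)
  abort_if(length(lengths) != spec$n_genes,
           "gene_lengths must have one entry per gene")
  samples <- unlist(lapply(subtypes, function(s)
    paste0(s, "_", seq_len(spec$n_samples[[s]]))))
  meta <- data.frame(sample = samples,
                     subtype = rep(subtypes, spec$n_samples),
                     replicate = unlist(lapply(spec$n_samples, seq_len)))
  counts <- matrix(0L, spec$n_genes, length(samples),
                   dimnames = list(genes, samples))
  cf <- spec$contamination_fraction
  for (j in seq_along(samples)) {
    s <- meta$subtype[j]
    m <- mu_scaled[, s]
    if (s != "rod" && cf > 0 && "rod" %in% subtypes)
      m <- (1 - cf) * m + cf * mu_scaled[, "rod"]
    counts[, j] <- if (spec$dispersion > 0)
      rnbinom(spec$n_genes, mu = m, size = 1 / spec$dispersion)
    else rpois(spec$n_genes, m)
  }
  em <- expression_matrix(counts, gene_lengths = lengths,
                          totals = colSums(counts),
                          subtype = meta$subtype,
                          replicate = meta$replicate)
  structure(list(matrix = em,
                 truth = do.call(rbind, c(truth_rows,
                                          make.row.names = FALSE)),
                 mean_profile = mu),
            class = "synth_expression")
}
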