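#' Gene x sample expression matrix
#'
#' Counts with the side information the downstream criteria need: gene
#' lengths (bp), per-sample total mapped reads, and per-sample subtype
#' metadata. The study design this models is five photoreceptor subtypes
#' (rod, UV, S, M, L) with 6/5/6/7/6 replicates, but any design is
#' accepted.
#'
#' @param counts non-negative integer matrix, genes in rows (rownames
#'   required), samples in columns (colnames required).
#' @param gene_lengths named numeric vector of transcript lengths in bp.
#' @param totals per-sample total mapped reads; defaults to column sums.
#' @param subtype character vector, one subtype label per sample.
#' @param replicate optional replicate ids.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, gene_lengths, totals = NULL,
                              subtype, replicate = NULL) {
  abort_if(!is.matrix(counts) || is.null(rownames(counts)) ||
             is.null(colnames(counts)),
           "counts must be a matrix with gene rownames and sample colnames")
  abort_if(any(counts < 0) || any(counts != floor(counts)),
           "counts must be non-negative integers")
  if (is.null(totals)) totals <- colSums(counts)
  if (!is.null(names(gene_lengths)))
    gene_lengths <- gene_lengths[rownames(counts)]
  abort_if(length(gene_lengths) != nrow(counts) || any(is.na(gene_lengths)),
           "gene_lengths must cover every gene: missing ",
           paste(utils::head(rownames(counts)[is.na(gene_lengths)], 3),
                 collapse = ", "))
  abort_if(any(gene_lengths <= 0), "gene lengths must be > 0")
  abort_if(length(totals) != ncol(counts) || any(totals <= 0),
           "totals must be positive, one per sample")
  abort_if(length(subtype) != ncol(counts),
           "subtype metadata must cover every sample")
  storage.mode(counts) <- "double"
  structure(list(counts = counts,
                 gene_lengths = stats::setNames(as.numeric(gene_lengths),
                                                rownames(counts)),
                 totals = stats::setNames(as.numeric(totals),
                                          colnames(counts)),
                 subtype = stats::setNames(as.character(subtype),
                                           colnames(counts)),
                 replicate = replicate),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(table(x$subtype)),
                            table(x$subtype)), collapse = ", ")))
  invisible(x)
}

samples_of <- function(em, subtype) {
  s <- names(em$subtype)[em$subtype == subtype]
  abort_if(length(s) == 0L, "no samples of subtype '", subtype,
           "'; available: ",
           paste(unique(em$subtype), collapse = ", "))
  s
}

#' FPKM transform
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM[g, s] = counts[g, s] / (length[g] / 1000) / (totals[s] / 1e6)`.
#'
#' @param em an [expression_matrix()].
#' @return numeric matrix of FPKM values, same dimnames as the counts.
#' @export
fpkm <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  em$counts / (em$gene_lengths / 1000) /
    rep(em$totals / 1e6, each = nrow(em$counts))
}

#' Built-in opsin aggregation presets
#'
#' The zebrafish M and L opsins are tandemly duplicated; for quantifying
#' "M-opsin" or "L-opsin" expression the member genes are summed:
#' M-opsin = opn1mw1 + opn1mw2 + opn1mw3 + opn1mw4, L-opsin = opn1lw1 +
#' opn1lw2.
#'
#' @return named list of member-gene vectors.
#' @export
opsin_presets <- function() {
  list("M-opsin" = paste0("opn1mw", 1:4),
       "L-opsin" = paste0("opn1lw", 1:2))
}

#' Aggregate member genes into one summed row
#'
#' Per-sample sum of the member genes' values, on counts (default) or any
#' gene x sample layer such as [fpkm()] output.
#'
#' @param x an [expression_matrix()] or a gene x sample matrix.
#' @param group_name name of the aggregate (e.g. `"M-opsin"`); when it
#'   matches an [opsin_presets()] entry and `member_genes` is missing, the
#'   preset members are used.
#' @param member_genes character vector of member genes.
#' @return named numeric vector, one value per sample.
#' @export
aggregate_genes <- function(x, group_name, member_genes = NULL) {
  layer <- if (inherits(x, "expression_matrix")) x$counts else x
  abort_if(!is.matrix(layer) || is.null(rownames(layer)),
           "x must be an expression_matrix or a matrix with gene rownames")
  if (is.null(member_genes)) {
    member_genes <- opsin_presets()[[group_name]]
    abort_if(is.null(member_genes), "no preset named '", group_name,
             "'; supply member_genes")
  }
  missing <- setdiff(member_genes, rownames(layer))
  abort_if(length(missing) > 0L, "member gene(s) not in matrix: ",
           paste(missing, collapse = ", "))
  colSums(layer[member_genes, , drop = FALSE])
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: the i-th smallest p becomes
#' `min_{j >= i} (m * p_(j) / j)`, capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  abort_if(any(is.na(p)) || any(p < 0) || any(p > 1),
           "p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, cummin(rev(m * p[o] / seq_len(m))))
  out <- numeric(m)
  out[o] <- rev(adj)
  out
}

#' Per-gene two-group statistics (stand-in test)
#'
#' A transparently simple stand-in for dedicated count-model packages:
#' Welch's two-sample t-test on `log2(FPKM + 1)` per gene, with
#' Benjamini-Hochberg adjustment across genes. Genes with zero variance
#' in both groups get p = 1 by convention. Alternatively, externally
#' computed statistics (e.g. from a count-model fit) can be supplied to
#' [deg_filter()] directly and are used unchanged.
#'
#' @param em an [expression_matrix()].
#' @param group_a,group_b subtype labels; each must have >= 2 samples.
#' @return data.frame with columns `gene`, `p`, `padj`.
#' @export
per_gene_stats <- function(em, group_a, group_b) {
  stopifnot(inherits(em, "expression_matrix"))
  sa <- samples_of(em, group_a); sb <- samples_of(em, group_b)
  abort_if(length(sa) < 2L || length(sb) < 2L,
           "both groups need >= 2 samples")
  lf <- log2(fpkm(em) + 1)
  xa <- lf[, sa, drop = FALSE]; xb <- lf[, sb, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  p[se2 == 0] <- 1  # zero variance in both groups
  data.frame(gene = rownames(em$counts), p = unname(p),
             padj = bh_adjust(unname(p)))
}

#' Differential-expression filter criteria
#'
#' The conjunction of thresholds a gene must pass to be called
#' differentially expressed: fold-enrichment > `min_fold`, p <
#' `max_p`, adjusted p < `max_padj`, and positive raw counts in more than
#' `min_positive_fraction` of the enriched group's samples (all strict).
#' In rod-vs-cone comparisons the fold requirement is dropped
#' (`rod_vs_cone_mode`), so differences carried by only one or two cone
#' subtypes are not masked.
#'
#' @param min_fold minimum fold-enrichment (default 1.5).
#' @param max_p maximum raw p (default 0.01).
#' @param max_padj maximum adjusted p (default 0.1).
#' @param min_positive_fraction minimum fraction of enriched-group samples
#'   with positive counts, strict (default 0.5; at n = 6 this requires
#'   >= 4 positive samples).
#' @param rod_vs_cone_mode drop the fold criterion.
#' @return object of class `deg_criteria`.
#' @export
deg_criteria <- function(min_fold = 1.5, max_p = 0.01, max_padj = 0.1,
                         min_positive_fraction = 0.5,
                         rod_vs_cone_mode = FALSE) {
  check_scalar_number(min_fold, "min_fold", min = 0, strict_min = TRUE)
  check_scalar_number(max_p, "max_p", min = 0, strict_min = TRUE)
  check_scalar_number(max_padj, "max_padj", min = 0, strict_min = TRUE)
  check_scalar_number(min_positive_fraction, "min_positive_fraction",
                      min = 0, max = 1, strict_min = TRUE)
  structure(list(min_fold = min_fold, max_p = max_p, max_padj = max_padj,
                 min_positive_fraction = min_positive_fraction,
                 rod_vs_cone_mode = isTRUE(rod_vs_cone_mode)),
            class = "deg_criteria")
}

#' Apply the differential-expression filter
#'
#' For each gene: the enriched group is the one with the larger mean FPKM;
#' fold-enrichment is the ratio of group mean FPKMs, with a 0.01 FPKM
#' pseudocount in the denominator when the smaller mean is zero; the gene
#' passes if all criteria in [deg_criteria()] hold (the fold criterion is
#' skipped in rod-vs-cone mode). Per-criterion flags are returned so the
#' decision is auditable.
#'
#' @param em an [expression_matrix()].
#' @param group_a,group_b subtype labels to compare.
#' @param stats optional external data.frame (`gene`, `p`, `padj`),
#'   ingested unchanged; default computes [per_gene_stats()].
#' @param criteria a [deg_criteria()].
#' @return data.frame of class `deg_result`, one row per gene: group
#'   means, `enriched_group`, `fold`, `p`, `padj`,
#'   `positive_fraction`, per-criterion flags and `pass`.
#' @export
deg_filter <- function(em, group_a, group_b, stats = NULL,
                       criteria = deg_criteria()) {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(criteria, "deg_criteria"))
  sa <- samples_of(em, group_a); sb <- samples_of(em, group_b)
  if (is.null(stats)) stats <- per_gene_stats(em, group_a, group_b)
  abort_if(!all(c("gene", "p", "padj") %in% names(stats)),
           "stats must have columns gene, p, padj")
  idx <- match(rownames(em$counts), stats$gene)
  abort_if(any(is.na(idx)), "stats missing gene(s): ",
           paste(utils::head(rownames(em$counts)[is.na(idx)], 3),
                 collapse = ", "))
  fk <- fpkm(em)
  mean_a <- rowMeans(fk[, sa, drop = FALSE])
  mean_b <- rowMeans(fk[, sb, drop = FALSE])
  a_enriched <- mean_a >= mean_b
  enriched_group <- ifelse(a_enriched, group_a, group_b)
  hi <- pmax(mean_a, mean_b)
  lo <- pmin(mean_a, mean_b)
  fold <- hi / ifelse(lo == 0, 0.01, lo)
  pos <- em$counts > 0
  pf_a <- rowMeans(pos[, sa, drop = FALSE])
  pf_b <- rowMeans(pos[, sb, drop = FALSE])
  positive_fraction <- ifelse(a_enriched, pf_a, pf_b)
  p <- stats$p[idx]; padj <- stats$padj[idx]
  pass_fold <- if (criteria$rod_vs_cone_mode)
    rep(NA, length(fold)) else fold > criteria$min_fold
  pass_p <- p < criteria$max_p
  pass_padj <- padj < criteria$max_padj
  pass_positive <- positive_fraction > criteria$min_positive_fraction
  pass <- (criteria$rod_vs_cone_mode | pass_fold) & pass_p & pass_padj &
    pass_positive
  out <- data.frame(gene = rownames(em$counts),
                    mean_a = unname(mean_a), mean_b = unname(mean_b),
                    enriched_group = unname(enriched_group),
                    fold = unname(fold), p = p, padj = padj,
                    positive_fraction = unname(positive_fraction),
                    pass_fold = unname(pass_fold), pass_p = pass_p,
                    pass_padj = pass_padj,
                    pass_positive = unname(pass_positive),
                    pass = unname(pass))
  attr(out, "groups") <- c(group_a, group_b)
  attr(out, "criteria") <- criteria
  class(out) <- c("deg_result", "data.frame")
  out
}

#' Transcription factors with detectable expression
#'
#' A transcription factor counts as expressed when at least
#' `min_fraction` of all samples have positive raw counts (the 20%
#' criterion: 7 of 35 samples in the reference design). Unknown gene
#' names are reported with a warning and skipped.
#'
#' @param em an [expression_matrix()].
#' @param tf_genes character vector of transcription-factor gene names.
#' @param min_fraction minimum fraction of positive samples (default 0.2,
#'   inclusive).
#' @return data.frame `gene`, `n_positive`, `fraction`, `expressed`.
#' @export
tf_expressed <- function(em, tf_genes, min_fraction = 0.2) {
  stopifnot(inherits(em, "expression_matrix"))
  if (length(tf_genes) == 0L)
    return(data.frame(gene = character(0), n_positive = integer(0),
                      fraction = numeric(0), expressed = logical(0)))
  unknown <- setdiff(tf_genes, rownames(em$counts))
  if (length(unknown))
    warning("unknown gene(s) skipped: ", paste(unknown, collapse = ", "))
  tf_genes <- setdiff(tf_genes, unknown)
  npos <- rowSums(em$counts[tf_genes, , drop = FALSE] > 0)
  frac <- npos / ncol(em$counts)
  data.frame(gene = tf_genes, n_positive = unname(as.integer(npos)),
             fraction = unname(frac),
             expressed = unname(frac >= min_fraction))
}

#' Rod-contamination score from rhodopsin signal
#'
#' Rhodopsin detection in non-rod samples is a simple contamination
#' proxy: the score is each sample's rho FPKM as a percentage of the mean
#' rho FPKM over rod samples, so pure rod samples sit near 100 and a
#' cone sample whose reads are a fraction c rod-derived sits near 100 c.
#' Band labels follow the conventional cutoffs: low < 5, high > 15,
#' moderate in between.
#'
#' @param em an [expression_matrix()]; must contain >= 1 rod sample.
#' @param rho_gene rhodopsin gene id (default `"rho"`).
#' @param rod_subtype subtype label of the rod reference samples.
#' @return data.frame `sample`, `subtype`, `score`, `band`.
#' @export
rod_contamination <- function(em, rho_gene = "rho", rod_subtype = "rod") {
  stopifnot(inherits(em, "expression_matrix"))
  abort_if(!rho_gene %in% rownames(em$counts),
           "gene '", rho_gene, "' not in matrix")
  rods <- samples_of(em, rod_subtype)
  fk_rho <- fpkm(em)[rho_gene, ]
  rod_mean <- mean(fk_rho[rods])
  abort_if(rod_mean == 0, "no rod reference signal: mean rod ",
           rho_gene, " FPKM is 0")
  score <- 100 * fk_rho / rod_mean
  band <- cut(score, c(-Inf, 5, 15, Inf),
              labels = c("low", "moderate", "high"), right = FALSE)
  # score exactly 5 or 15 falls in the lower band (bands are < 5, > 15)
  band[score == 15] <- "moderate"
  data.frame(sample = names(fk_rho), subtype = unname(em$subtype),
             score = unname(score), band = as.character(band))
}
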