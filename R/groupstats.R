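check_groups <- function(groups) {
  abort_if(!is.list(groups) || length(groups) < 2L,
           "need at least 2 groups")
  abort_if(any(vapply(groups, length, integer(1)) == 0L),
           "every group must be non-empty")
  abort_if(any(!vapply(groups, is.numeric, logical(1))),
           "groups must be numeric vectors")
  abort_if(any(vapply(groups, function(g) any(is.na(g)), logical(1))),
           "groups contain missing values")
  invisible(groups)
}

#' Kruskal-Wallis test with tie correction
#'
#' Rank-based k-group test of identical distributions. Mid-ranks are used
#' for ties and the statistic carries the standard tie correction:
#' \deqn{H = \frac{\frac{12}{N(N+1)} \sum_i R_i^2/n_i - 3(N+1)}
#'            {1 - \sum_t (t^3 - t) / (N^3 - N)}}
#' with p from the chi-square distribution on k - 1 df. When all values
#' are tied the statistic is undefined; the conservative convention
#' H = 0, p = 1 is returned. The screen's significance convention is
#' p < 0.01.
#'
#' @param groups list of >= 2 non-empty numeric vectors (one value per
#'   field/retina).
#' @return list of class `kruskal_wallis`: `H`, `p`, `df`, `n`
#'   (per-group sizes), `N`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  abort_if(N < 3L, "need at least 3 observations in total")
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)  # mid-ranks
  g <- rep(seq_along(groups), n)
  Ri <- rowsum(r, g)[, 1]
  H_num <- 12 / (N * (N + 1)) * sum(Ri^2 / n) - 3 * (N + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tie_corr == 0) {  # all observations identical
    H <- 0
    p <- 1
  } else {
    H <- H_num / tie_corr
    p <- pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  }
  structure(list(H = H, p = p, df = length(groups) - 1L, n = n, N = N),
            class = "kruskal_wallis")
}

#' @export
print.kruskal_wallis <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g, df = %d, p = %.4g (N = %d)\n",
              x$H, x$df, x$p, x$N))
  invisible(x)
}

#' Conover-Iman post hoc pairwise comparisons
#'
#' Rank-based pairwise t statistics conditioned on the Kruskal-Wallis
#' statistic computed from the same data:
#' \deqn{t_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{S^2 \frac{N-1-H}{N-k} (1/n_i + 1/n_j)}}, \quad
#'   S^2 = \frac{\sum R^2 - N(N+1)^2/4}{N-1}}
#' over the pooled mid-ranks, with two-sided p from Student's t on N - k
#' df and a Bonferroni adjustment over all k(k-1)/2 pairs. If H exceeds
#' N - 1 the variance factor is clamped to zero and p = 1 is returned
#' with a warning.
#'
#' @param groups the same list of groups passed to [kruskal_wallis()].
#' @param H optionally, the precomputed tie-corrected statistic; computed
#'   from `groups` when omitted.
#' @return data.frame of class `conover_iman`, one row per pair:
#'   `group_i`, `group_j`, `mean_rank_i`, `mean_rank_j`, `t`, `df`, `p`,
#'   `p_adjusted`.
#' @export
conover_iman <- function(groups, H = NULL) {
  check_groups(groups)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  k <- length(groups)
  abort_if(N <= k, "need more observations than groups")
  if (is.null(H)) H <- kruskal_wallis(groups)$H
  if (inherits(H, "kruskal_wallis")) H <- H$H
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)
  g <- rep(seq_len(k), n)
  Rbar <- rowsum(r, g)[, 1] / n
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  slack <- N - 1 - H  # 0 when groups are perfectly separated
  tol <- 1e-8 * max(1, N - 1)
  clamped <- FALSE
  if (slack < -tol) {
    warning("H exceeds N - 1; variance factor clamped to 0, p set to 1")
    slack <- 0
    clamped <- TRUE
  } else if (slack < tol) slack <- 0
  vf <- S2 * slack / (N - k)
  nms <- names(groups) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  res <- lapply(seq_len(ncol(pairs)), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    se <- sqrt(vf * (1 / n[i] + 1 / n[j]))
    if (S2 == 0) {        # all observations tied
      t_ij <- 0; p <- 1
    } else if (clamped || se == 0) {
      t_ij <- if (Rbar[i] == Rbar[j]) 0 else
        sign(Rbar[i] - Rbar[j]) * Inf
      p <- 1
    } else {
      t_ij <- (Rbar[i] - Rbar[j]) / se
      p <- 2 * pt(-abs(t_ij), df = N - k)
    }
    data.frame(group_i = nms[i], group_j = nms[j],
               mean_rank_i = unname(Rbar[i]), mean_rank_j = unname(Rbar[j]),
               t = t_ij, df = N - k, p = p)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bonferroni_adjust(out$p, nrow(out))
  class(out) <- c("conover_iman", "data.frame")
  out
}

#' Bonferroni adjustment
#'
#' Each p-value is multiplied by the number of comparisons and capped at
#' 1.
#'
#' @param p p-values in \[0, 1\].
#' @param m number of comparisons (>= `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  abort_if(any(is.na(p)) || any(p < 0) || any(p > 1),
           "p-values must be in [0, 1]")
  abort_if(m < length(p), "m must be at least length(p)")
  pmin(1, m * p)
}

#' Per-group summaries and effect sizes vs a control group
#'
#' Mean, sample standard deviation (n - 1 denominator), and n per group,
#' plus effects relative to a designated control: fold change
#' (mean / control mean) and percent change
#' (100 (control - group) / control). With a zero control mean the
#' effects are reported missing, not infinite.
#'
#' @param groups named list of numeric vectors.
#' @param control_label name of the control group.
#' @return data.frame: `group`, `n`, `mean`, `sd`, `fold_change`,
#'   `percent_change`.
#' @export
summarize_groups <- function(groups, control_label) {
  check_groups(groups)
  abort_if(is.null(names(groups)) || !control_label %in% names(groups),
           "control group '", control_label, "' not present")
  mc <- mean(groups[[control_label]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else NA_real_,
               fold_change = if (mc == 0) NA_real_ else mean(v) / mc,
               percent_change = if (mc == 0) NA_real_ else
                 100 * (mc - mean(v)) / mc)
  }))
  attr(out, "control") <- control_label
  out
}

#' Full group comparison
#'
#' Bundles the screen's statistical block: tie-corrected Kruskal-Wallis,
#' Conover-Iman pairwise post hoc tests with Bonferroni adjustment, and
#' per-group summaries with effects vs the control.
#'
#' @param groups named list of per-group values (one per field/retina).
#' @param control_label control group name.
#' @param significance_level significance threshold recorded in the
#'   result (default 0.01, the screen's convention).
#' @return list of class `group_comparison`: `kruskal`, `pairwise`,
#'   `summaries`, `significant`.
#' @export
compare_groups <- function(groups, control_label,
                           significance_level = 0.01) {
  check_scalar_number(significance_level, "significance_level", min = 0,
                      max = 1, strict_min = TRUE, strict_max = TRUE)
  kw <- kruskal_wallis(groups)
  structure(list(kruskal = kw,
                 pairwise = conover_iman(groups, kw$H),
                 summaries = summarize_groups(groups, control_label),
                 significance_level = significance_level,
                 significant = kw$p < significance_level),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$kruskal)
  cat(sprintf("significant at %.3g: %s\n", x$significance_level,
              x$significant))
  print(x$pairwise, row.names = FALSE)
  print(x$summaries, row.names = FALSE)
  invisible(x)
}
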