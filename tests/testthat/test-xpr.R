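# small helper: expression matrix straight from components
make_em <- function(counts, lengths = NULL, totals = NULL, subtype) {
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  expression_matrix(counts, gene_lengths = setNames(lengths,
                                                    rownames(counts)),
                    totals = totals, subtype = subtype)
}

rand_counts <- function(ng, ns, seed, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(ng * ns, lambda), ng, ns,
              dimnames = list(sprintf("g%03d", 1:ng),
                              sprintf("s%02d", 1:ns)))
  m
}

test_that("fpkm implements the unit formula", {
  counts <- matrix(c(10, 0), 2, 1,
                   dimnames = list(c("a", "b"), "s1"))
  em <- make_em(counts, lengths = c(1000, 2000), totals = 1e6,
                subtype = "rod")
  fk <- fpkm(em)
  expect_equal(fk["a", "s1"], 10)
  expect_equal(fk["b", "s1"], 0)
})

test_that("fpkm equals an explicit double-loop oracle", {
  counts <- rand_counts(50, 10, 7)
  lengths <- round(runif(50, 300, 5000))
  totals <- round(runif(10, 5e5, 5e6))
  em <- make_em(counts, lengths, totals, subtype = rep("rod", 10))
  fk <- fpkm(em)
  for (g in 1:50) for (s in 1:10)
    expect_equal(fk[g, s],
                 counts[g, s] / (lengths[g] / 1000) / (totals[s] / 1e6))
})

test_that("doubling a sample's total mapped reads halves its FPKM", {
  counts <- rand_counts(20, 4, 8)
  totals <- c(1e6, 1e6, 2e6, 4e6)
  em <- make_em(counts, totals = totals, subtype = rep("L", 4))
  fk <- fpkm(em)
  em2 <- make_em(counts, totals = totals * 2, subtype = rep("L", 4))
  expect_equal(fpkm(em2), fk / 2)
})

test_that("aggregate_genes sums members per sample", {
  counts <- matrix(0, 6, 2,
                   dimnames = list(c(paste0("opn1mw", 1:4), "rho", "x"),
                                   c("s1", "s2")))
  counts[1:4, 1] <- 1:4
  counts[1:4, 2] <- 0
  em <- make_em(counts, totals = c(1e6, 1e6), subtype = c("M", "M"))
  agg <- aggregate_genes(em, "M-opsin")
  expect_equal(unname(agg), c(10, 0))
  # loop oracle on random values
  counts2 <- rand_counts(8, 5, 12)
  em2 <- make_em(counts2, subtype = rep("S", 5))
  members <- c("g001", "g004", "g007")
  agg2 <- aggregate_genes(em2, "set", members)
  for (s in 1:5) {
    tot <- 0
    for (g in members) tot <- tot + counts2[g, s]
    expect_equal(unname(agg2[s]), tot)
  }
  expect_error(aggregate_genes(em2, "L-opsin"), "not in matrix")
  expect_error(aggregate_genes(em2, "nope"), "no preset")
})

test_that("per_gene_stats: null convention, BH fixture, and t-test oracle", {
  counts <- matrix(5, 4, 6,
                   dimnames = list(paste0("g", 1:4),
                                   paste0("s", 1:6)))
  em <- make_em(counts, totals = rep(1e6, 6),
                subtype = rep(c("UV", "S"), each = 3))
  st <- per_gene_stats(em, "UV", "S")
  expect_true(all(st$p == 1))  # zero variance in both groups

  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  p <- runif(40)
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))

  # Welch reference oracle on noisy data
  counts2 <- rand_counts(30, 12, 9, lambda = 200)
  em2 <- make_em(counts2, totals = round(runif(12, 8e5, 1.2e6)),
                 subtype = rep(c("M", "L"), each = 6))
  st2 <- per_gene_stats(em2, "M", "L")
  lf <- log2(fpkm(em2) + 1)
  for (g in sample(30, 10)) {
    ref <- stats::t.test(lf[g, 1:6], lf[g, 7:12])
    expect_equal(st2$p[g], ref$p.value, tolerance = 1e-8)
  }
})

test_that("deg_filter applies the conjunction of criteria", {
  # two groups of 6; gene rows engineered per criterion
  sub <- rep(c("S", "M"), each = 6)
  counts <- rbind(
    strong  = c(rep(200, 6), rep(60, 6)),   # fold > 1.5, all positive
    weak    = c(rep(140, 6), rep(100, 6)),  # fold 1.4 < 1.5
    sparse  = c(200, 200, 200, 0, 0, 0, rep(1, 6)),  # positive 3/6 = 0.5
    null    = rep(50, 12))
  colnames(counts) <- paste0("s", 1:12)
  em <- make_em(counts, totals = rep(1e6, 12), subtype = sub)
  stats_df <- data.frame(gene = rownames(counts),
                         p = c(0.001, 0.001, 0.001, 1),
                         padj = c(0.05, 0.05, 0.05, 1))
  res <- deg_filter(em, "S", "M", stats = stats_df)
  expect_identical(res$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(res$enriched_group[1], "S")
  expect_false(res$pass_fold[2])
  expect_false(res$pass_positive[3])  # 0.5 is not > 0.5
  # rod-vs-cone mode drops the fold requirement
  res2 <- deg_filter(em, "S", "M", stats = stats_df,
                     criteria = deg_criteria(rod_vs_cone_mode = TRUE))
  expect_true(res2$pass[2])
  expect_true(all(is.na(res2$pass_fold)))
})

test_that("deg_filter matches a brute-force predicate oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    ng <- 40
    counts <- matrix(rpois(ng * 12, 3), ng, 12,
                     dimnames = list(sprintf("g%03d", 1:ng),
                                     sprintf("s%02d", 1:12)))
    em <- make_em(counts, lengths = round(runif(ng, 500, 3000)),
                  totals = round(runif(12, 5e5, 2e6)),
                  subtype = rep(c("UV", "L"), each = 6))
    stats_df <- data.frame(gene = rownames(counts), p = runif(ng),
                           padj = runif(ng))
    for (mode in c(FALSE, TRUE)) {
      res <- deg_filter(em, "UV", "L", stats = stats_df,
                        criteria = deg_criteria(rod_vs_cone_mode = mode))
      fk <- fpkm(em)
      for (g in 1:ng) {
        ma <- mean(fk[g, 1:6]); mb <- mean(fk[g, 7:12])
        enr <- if (ma >= mb) 1:6 else 7:12
        hi <- max(ma, mb); lo <- min(ma, mb)
        fold <- hi / (if (lo == 0) 0.01 else lo)
        posfrac <- sum(counts[g, enr] > 0) / 6
        ok <- (mode || fold > 1.5) && stats_df$p[g] < 0.01 &&
          stats_df$padj[g] < 0.1 && posfrac > 0.5
        expect_identical(res$pass[g], ok)
      }
    }
  }
})

test_that("tf_expressed implements the 20%-of-samples criterion", {
  counts <- matrix(0, 3, 35,
                   dimnames = list(c("tf7", "tf6", "tfall"),
                                   paste0("s", 1:35)))
  counts["tf7", 1:7] <- 5
  counts["tf6", 1:6] <- 5
  counts["tfall", ] <- 1
  em <- make_em(counts, subtype = rep(c("rod", "UV", "S", "M", "L"), 7))
  res <- tf_expressed(em, c("tf7", "tf6", "tfall"))
  expect_identical(res$expressed, c(TRUE, FALSE, TRUE))
  expect_identical(res$n_positive[1], 7L)
  expect_warning(res2 <- tf_expressed(em, c("tf7", "ghost")), "unknown")
  expect_identical(nrow(res2), 1L)
  expect_identical(nrow(tf_expressed(em, character(0))), 0L)
  # brute-force fraction oracle on a random binary matrix
  set.seed(33)
  bin <- matrix(rbinom(20 * 10, 1, 0.25), 20, 10,
                dimnames = list(sprintf("g%03d", 1:20),
                                sprintf("s%02d", 1:10)))
  em2 <- make_em(bin, subtype = rep("rod", 10))
  res3 <- tf_expressed(em2, rownames(bin))
  for (g in 1:20) {
    np <- 0
    for (s in 1:10) if (bin[g, s] > 0) np <- np + 1
    expect_identical(res3$expressed[g], np / 10 >= 0.2)
  }
})

test_that("rod_contamination scores against the rod rho mean", {
  counts <- matrix(0, 2, 4,
                   dimnames = list(c("rho", "x"), paste0("s", 1:4)))
  counts["rho", ] <- c(1000, 1000, 50, 0)
  counts["x", ] <- 10
  em <- make_em(counts, totals = rep(1e6, 4),
                subtype = c("rod", "rod", "L", "UV"))
  res <- rod_contamination(em)
  expect_equal(res$score, c(100, 100, 5, 0))
  expect_identical(res$band, c("high", "high", "moderate", "low"))
  em0 <- make_em(matrix(0, 2, 2,
                        dimnames = list(c("rho", "x"), c("a", "b"))),
                 totals = c(1, 1), subtype = c("rod", "L"))
  expect_error(rod_contamination(em0), "no rod reference")
})

test_that("contamination scores recover the planted mixture fraction", {
  means <- vapply(1:4, function(seed) {
    se <- generate_expression(synth_expression_spec(
      n_genes = 120L, contamination_fraction = 0.2, seed = seed))
    res <- rod_contamination(se$matrix)
    mean(res$score[res$subtype != "rod"])
  }, numeric(1))
  expect_lt(abs(mean(means) - 20), 3 * sd(means) + 1)
  # and rod samples sit near 100
  se <- generate_expression(synth_expression_spec(
    n_genes = 120L, contamination_fraction = 0.2, seed = 9))
  res <- rod_contamination(se$matrix)
  expect_lt(abs(mean(res$score[res$subtype == "rod"]) - 100), 15)
})

test_that("rod_contamination is invariant to joint rescaling of totals", {
  counts <- rand_counts(10, 6, 44)
  rownames(counts)[1] <- "rho"
  em <- make_em(counts, totals = rep(1e6, 6),
                subtype = rep(c("rod", "L"), each = 3))
  em2 <- make_em(counts, totals = rep(3e6, 6),
                 subtype = rep(c("rod", "L"), each = 3))
  expect_equal(rod_contamination(em)$score, rod_contamination(em2)$score)
})

test_that("null matrices pass the raw-p criterion at the nominal rate", {
  se <- generate_expression(synth_expression_spec(
    n_genes = 1500L, enriched_sets = list(),
    n_samples = c(UV = 6L, S = 6L), seed = 31L))
  st <- per_gene_stats(se$matrix, "UV", "S")
  rate <- mean(st$p < 0.01)
  expect_lt(abs(rate - 0.01), 3.5 * sqrt(0.01 * 0.99 / 1500))
  res <- deg_filter(se$matrix, "UV", "S", stats = st)
  expect_lte(mean(res$pass), rate)
})

test_that("planted folds are recovered by the full filter", {
  se <- generate_expression(synth_expression_spec(
    n_genes = 200L,
    n_samples = c(UV = 6L, S = 6L),
    enriched_sets = list(UV = list(genes = sprintf("uv%02d", 1:10),
                                   fold = 10, exclusive = FALSE),
                         S = list(genes = sprintf("ss%02d", 1:10),
                                  fold = 10, exclusive = FALSE)),
    dispersion = 0.2, seed = 77L))
  res <- deg_filter(se$matrix, "UV", "S")
  planted <- se$truth$gene
  sens <- mean(res$pass[match(planted, res$gene)])
  expect_gte(sens, 0.9)
})
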