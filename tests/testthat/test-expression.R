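test_that("fold change is the difference of stratum means", {
  e <- gen_expression_dataset(5, 0, effect_lfc = 0, seed = 1,
                              substrates = "AV1", timepoints = c(0, 6))
  d <- e$data
  # overwrite with fixed numbers for an arithmetic check
  d$mat["gene0001", d$samples$substrate == "AV1" & d$samples$time_h == 6] <-
    c(9.1, 9.3, 8.9, 9.1)
  d$mat["gene0001", d$samples$substrate == "CONTROL" &
          d$samples$time_h == 6] <- c(8.0, 8.2, 7.8, 8.0)
  expect_equal(unname(fold_change_contrast(d, "AV1", 6, "gene0001")), 1.1)
  d$mat["gene0002", ] <- 7
  expect_equal(unname(fold_change_contrast(d, "AV1", 6, "gene0002")), 0)
  expect_error(fold_change_contrast(d, "AV1", 41), "missing stratum")
})

test_that("variance-prior moments recover planted hyperparameters", {
  # degenerate: identical variances
  expect_equal(moderated_variance(rep(0.25, 100), 6),
               list(d0 = Inf, s0_sq = 0.25))
  # two very different variances -> finite, weak shrinkage
  mv <- moderated_variance(c(0.1, 10), 6)
  expect_true(is.finite(mv$d0))
  expect_lt(mv$d0, 6)
  # parameter recovery from a scaled inverse-chi-squared prior
  set.seed(7)
  d0 <- 4; s0 <- 1; df <- 6; n <- 10000
  sigma2 <- d0 * s0 / stats::rchisq(n, d0)
  s2 <- sigma2 * stats::rchisq(n, df) / df
  est <- moderated_variance(s2, df)
  expect_equal(est$d0, d0, tolerance = 0.1)
  expect_equal(est$s0_sq, s0, tolerance = 0.1)
  # agreement with limma's independent implementation of the same model
  sq <- limma::squeezeVar(s2, df)
  expect_equal(est$d0, sq$df.prior, tolerance = 0.02)
  expect_equal(est$s0_sq, sq$var.prior, tolerance = 0.02)
})

test_that("moderated t reduces to classical pooled t at d0 = 0", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(4, 9); y <- rnorm(4, 8)
    got <- moderated_t_p(x, y, d0 = 0, s0_sq = 0)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("moderated t matches a direct evaluation of the formulas", {
  x <- c(9.1, 9.3, 8.9, 9.1); y <- c(8.0, 8.2, 7.8, 8.0)
  d0 <- 4; s0 <- 0.05
  got <- moderated_t_p(x, y, d0, s0)
  # independent arithmetic
  sg <- (3 * var(x) + 3 * var(y)) / 6
  st <- (d0 * s0 + 6 * sg) / (d0 + 6)
  tt <- (mean(x) - mean(y)) / sqrt(st * 0.5)
  expect_equal(got$t_stat, tt, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * pt(-abs(tt), 10), tolerance = 1e-10)
  # d0 = Inf uses the prior variance exactly, normal reference
  gi <- moderated_t_p(x, y, Inf, s0)
  expect_equal(gi$t_stat, (mean(x) - mean(y)) / sqrt(s0 * 0.5),
               tolerance = 1e-10)
  expect_equal(gi$p_value, 2 * pnorm(-abs(gi$t_stat)), tolerance = 1e-10)
  expect_warning(moderated_t_p(c(1, 1), c(2, 2), 0, 0), "zero posterior")
})

test_that("moderated pipeline agrees with limma on a shared dataset", {
  set.seed(21)
  n <- 400
  mat <- matrix(rnorm(n * 8, 8, 0.5), n, 8)
  mat[1:40, 1:4] <- mat[1:40, 1:4] + 1.5
  design <- cbind(1, rep(c(1, 0), each = 4))
  fit <- limma::eBayes(limma::lmFit(mat, design))
  vx <- apply(mat[, 1:4], 1, var); vy <- apply(mat[, 5:8], 1, var)
  sg <- (3 * vx + 3 * vy) / 6
  pr <- moderated_variance(sg, 6)
  ours <- vapply(seq_len(n), function(i)
    moderated_t_p(mat[i, 1:4], mat[i, 5:8], pr$d0, pr$s0_sq)$p_value, 0)
  theirs <- fit$p.value[, 2]
  expect_equal(pr$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(ours, unname(theirs), tolerance = 1e-8)
})

test_that("induction calls apply strict dual thresholds antisymmetrically", {
  expect_equal(call_induction(0.5, 0.005), 1L)
  expect_equal(call_induction(0.4, 0.005), 0L)    # strict lfc bound
  expect_equal(call_induction(3.0, 0.05), 0L)
  expect_equal(call_induction(-0.5, 0.005), -1L)
  expect_equal(call_induction(0.5, 0.01), 0L)     # strict p bound
  lfc <- seq(-2, 2, by = 0.1); p <- rep(0.001, length(lfc))
  expect_equal(call_induction(-lfc, p), -call_induction(lfc, p))
})

test_that("induced and core sets follow the substrate-class rules", {
  calls <- data.frame(
    gene_id = c("a", "a", "b", "b", "c"),
    substrate = c("SO", "XO", "AV1", "BO", "BS"),
    time_h = 17,
    call = c(1L, 1L, -1L, 0L, 0L))
  expect_equal(induced_gene_set(calls), "a")
  expect_equal(induced_gene_set(calls[calls$call == 0L, ]), character(0))
  # monotone: adding +1 calls never shrinks the set
  more <- rbind(calls, data.frame(gene_id = "c", substrate = "SO",
                                  time_h = 41, call = 1L))
  expect_true(all(induced_gene_set(calls) %in% induced_gene_set(more)))
  # core rule: cellulose AND xylan AND >= ceil(0.7 * n) substrates
  cm <- default_class_map()
  subs <- names(cm)
  mk <- function(gene, on) data.frame(gene_id = gene, substrate = subs,
                                      time_h = 17,
                                      call = ifelse(subs %in% on, 1L, 0L))
  all10 <- mk("g1", subs)
  expect_equal(core_induced_set(all10, cm), "g1")
  no_xyl <- mk("g2", setdiff(subs, c("XO", "XB")))       # 8, no xylan
  expect_equal(core_induced_set(no_xyl, cm), character(0))
  seven <- mk("g3", c("AV1", "XO", "BO", "BS", "BE", "WH", "SP"))
  expect_equal(core_induced_set(seven, cm), "g3")        # exactly 7 of 10
  six <- mk("g4", c("AV1", "XO", "BO", "BS", "BE", "WH"))
  expect_equal(core_induced_set(six, cm), character(0))
})

test_that("family induction matrix reproduces a planted contingency table", {
  ann <- c(a = "GH7", b = "GH7", c = "GH3")
  calls <- data.frame(
    gene_id = c("a", "b", "c", "c", "a"),
    substrate = c("SO", "SO", "XO", "XO", "AV1"),
    time_h = c(6, 17, 6, 17, 6),
    call = c(1L, 1L, 1L, 1L, 0L))
  fm <- family_induction_matrix(calls, ann)
  expect_equal(fm$matrix["GH7", "SO"], 2L)
  expect_equal(fm$matrix["GH3", "XO"], 1L)   # two time points, one gene
  expect_equal(unname(fm$genes_per_substrate[c("SO", "XO", "AV1")]),
               c(2L, 1L, 0L))
  expect_equal(unname(fm$families_per_substrate[["SO"]]), 1L)
  # no +1 calls -> zero matrix
  z <- family_induction_matrix(transform(calls, call = 0L), ann)
  expect_true(all(z$matrix == 0))
  expect_warning(family_induction_matrix(
    data.frame(gene_id = "zz", substrate = "SO", time_h = 6, call = 1L),
    ann), "UNASSIGNED")
})

test_that("maximal-induction profile takes the per-substrate maximum", {
  calls <- data.frame(gene_id = "g", substrate = "SO",
                      time_h = c(6, 17, 41), call = 0L,
                      lfc = c(0.1, 2.3, 1.0))
  expect_equal(max_induction_profile(calls)["g", "SO"], 2.3)
  neg <- transform(calls[1:2, ], lfc = c(-1, -2))
  expect_equal(max_induction_profile(neg)["g", "SO"], -1)
  expect_equal(max_induction_profile(calls[1, ])["g", "SO"], 0.1)
})

test_that("co-expression branching recovers planted groups and is stable", {
  set.seed(31)
  prof <- rbind(matrix(rnorm(20 * 6, 0, 0.3), 20, 6),
                matrix(rnorm(20 * 6, 10, 0.3), 20, 6))
  rownames(prof) <- paste0("g", 1:40)
  br <- cluster_coexpression_branches(prof, k = 2)
  expect_equal(length(unique(br[1:20])), 1)
  expect_equal(length(unique(br[21:40])), 1)
  expect_equal(unname(br[1]), "A")           # first gene anchors label A
  expect_false(br[1] == br[40])
  expect_equal(unique(unname(cluster_coexpression_branches(prof, 1))), "A")
  # duplicate rows co-branch
  dup <- prof[c(1, 1, 21), ]
  expect_equal(length(unique(cluster_coexpression_branches(dup, 2)[1:2])), 1)
  expect_error(cluster_coexpression_branches(prof, 0), "between 1")
  expect_error(cluster_coexpression_branches(prof, 41), "between 1")
  # partition invariant to row permutation (labels may swap)
  perm <- sample(nrow(prof))
  br2 <- cluster_coexpression_branches(prof[perm, ], k = 2)[rownames(prof)]
  tab <- table(br, br2)
  expect_equal(sum(tab > 0), 2)
})

test_that("contrast table covers all strata and respects batches", {
  e <- gen_expression_dataset(50, 0.2, seed = 41, replicates = 4)
  ct <- contrast_table(e$data)
  expect_setequal(unique(ct$substrate), SUBSTRATES)
  expect_setequal(unique(ct$time_h), TIMEPOINTS)
  expect_equal(nrow(ct), 50 * length(SUBSTRATES) * length(TIMEPOINTS))
  expect_true(all(ct$p_value >= 0 & ct$p_value <= 1))
  # calls obey their defining inequalities
  up <- ct$call == 1L
  expect_true(all(ct$p_value[up] < 0.01 & ct$lfc[up] > 0.4))
  dn <- ct$call == -1L
  expect_true(all(ct$p_value[dn] < 0.01 & ct$lfc[dn] < -0.4))
})
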