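test_that("gene filtering removes zero-variance then low-expression genes", {
  ex <- make_cosinor_experiment(phases = rep(1, 5), noise_sd = 0)
  expr <- ex$expr
  expr["g001", ] <- 3                    # constant -> zero variance
  expr["g002", ] <- 7                    # constant -> zero variance
  expr["g003", ] <- expr["g003", ] - 10  # all means negative -> low expression
  # g004 hovers below zero except one time point
  expr["g004", ] <- rep(c(-1, -0.5, 0.2, -2), each = 3) +
    rep(c(0, 0, 0.01, 0), each = 3) * 0  # means (-1, -0.5, 0.2, -2)
  expr["g004", ex$meta$treatment == "WL"] <- expr["g004", ex$meta$treatment == "WW"]
  f <- filter_genes(expr, ex$meta)
  expect_setequal(rownames(f$expr), c("g004", "g005"))
  expect_setequal(f$removed$gene[f$removed$reason == "zero_variance"],
                  c("g001", "g002"))
  expect_true("g003" %in% f$removed$gene[f$removed$reason == "low_expression"])
  expect_warning(filter_genes(matrix(1, 2, 24,
                                     dimnames = list(c("a", "b"),
                                                     colnames(expr))),
                              ex$meta), "all genes removed")
})

test_that("single missing replicates are imputed as the median of the rest", {
  ex <- make_cosinor_experiment(phases = c(1, 7), noise_sd = 0)
  expr <- ex$expr
  cols <- ex$meta$sample_id[ex$meta$treatment == "WW" & ex$meta$ZT == 1]
  expr["g001", cols] <- c(4, 10, NA)
  imp <- impute_missing_replicate(expr, ex$meta)
  expect_equal(unname(imp$expr["g001", cols[3]]), 7)  # median of {4, 10}
  expect_equal(nrow(imp$imputed), 1)
  # replicate mean now equals the mean of the two real values
  expect_equal(unname(mean(imp$expr["g001", cols])), 7)
  # equal remaining values impute to themselves
  expr["g002", cols] <- c(2.5, 2.5, NA)
  imp2 <- impute_missing_replicate(expr, ex$meta)
  expect_equal(unname(imp2$expr["g002", cols[3]]), 2.5)
  # two missing replicates: flagged unusable, not imputed
  expr["g001", cols[1:2]] <- NA
  imp3 <- impute_missing_replicate(expr, ex$meta)
  expect_true("g001" %in% imp3$unusable$gene)
  expect_true(anyNA(imp3$expr["g001", cols]))
})

test_that("count normalization is depth-invariant and TMM matches a hand oracle", {
  set.seed(1)
  counts <- matrix(rpois(40, 200), 20, 2,
                   dimnames = list(sprintf("g%02d", 1:20), c("s1", "s2")))
  same <- normalize_counts(cbind(s1 = counts[, 1], s2 = counts[, 1]))
  expect_equal(same$logexpr[, 1], same$logexpr[, 2])
  expect_equal(unname(same$scale_factors), c(1, 1))

  doubled <- normalize_counts(cbind(s1 = counts[, 1], s2 = 2L * counts[, 1]))
  expect_equal(doubled$logexpr[, 1], doubled$logexpr[, 2], tolerance = 1e-9)

  expect_error(normalize_counts(cbind(s1 = counts[, 1], s2 = 0 * counts[, 1])),
               "zero library size")

  # hand-computed doubly trimmed weighted mean of M values (brute force)
  tmm_oracle <- function(obs, ref) {
    n_o <- sum(obs); n_r <- sum(ref)
    keep <- obs > 0 & ref > 0
    obs <- obs[keep]; ref <- ref[keep]
    m <- log2((obs / n_o) / (ref / n_r))
    a <- 0.5 * log2((obs / n_o) * (ref / n_r))
    w <- (n_o - obs) / (n_o * obs) + (n_r - ref) / (n_r * ref)
    n <- length(m)
    lo_m <- floor(n * 0.3) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
    sel <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    2^(sum(m[sel] / w[sel]) / sum(1 / w[sel]))
  }
  set.seed(2)
  raw <- matrix(rnbinom(40, mu = 300, size = 5) + 1, 20, 2,
                dimnames = list(sprintf("g%02d", 1:20), c("s1", "s2")))
  sf <- normalize_counts(raw)$scale_factors
  f_hand <- tmm_oracle(raw[, 2], raw[, 1])
  expect_equal(unname(sf["s2"] / sf["s1"]), f_hand, tolerance = 1e-8)
})

test_that("kME and Med scores isolate pattern versus level changes", {
  eig <- cosine_eigengene(phase = 1)
  # identical treatments: both scores vanish
  ex0 <- make_cosinor_experiment(phases = c(1, 7, 13), noise_sd = 0)
  sc0 <- pattern_change_scores(ex0$expr, ex0$meta, eig, "Acc1")
  expect_equal(sc0$kME, rep(0, 3))
  expect_equal(sc0$Med, rep(0, 3))
  # antiphase under WL: correlation flips from +1 to -1, kME = 2
  ex1 <- make_cosinor_experiment(phases = 1, shifts = 12, noise_sd = 0)
  sc1 <- pattern_change_scores(ex1$expr, ex1$meta, eig, "Acc1")
  expect_equal(sc1$kME, 2, tolerance = 1e-10)
  # pure median shift with identical shape: Med = shift, kME ~ 0
  ex2 <- make_cosinor_experiment(phases = 1, offsets = 0.8, noise_sd = 0)
  sc2 <- pattern_change_scores(ex2$expr, ex2$meta, eig, "Acc1")
  expect_equal(sc2$Med, 0.8, tolerance = 1e-10)
  expect_lt(sc2$kME, 1e-10)
})

test_that("kME is invariant to a level offset while Med tracks it exactly", {
  eig <- cosine_eigengene(phase = 7)
  ex <- make_cosinor_experiment(phases = c(7, 13), noise_sd = 0.1, seed = 4)
  sc <- pattern_change_scores(ex$expr, ex$meta, eig, "Acc1")
  shifted <- ex$expr
  shifted[, ex$meta$treatment == "WL"] <-
    shifted[, ex$meta$treatment == "WL"] + 2
  sc_sh <- pattern_change_scores(shifted, ex$meta, eig, "Acc1")
  expect_equal(sc_sh$kME, sc$kME, tolerance = 1e-8)
  # Med is |median(WL) - median(WW)|; shifting WL by +2 moves the signed
  # difference by exactly +2
  signed <- apply(ex$expr[, ex$meta$treatment == "WL"], 1, median) -
    apply(ex$expr[, ex$meta$treatment == "WW"], 1, median)
  expect_equal(sc_sh$Med, unname(abs(signed + 2)), tolerance = 1e-10)
  # gene-order invariance
  perm <- c(2, 1)
  sc_perm <- pattern_change_scores(ex$expr[perm, ], ex$meta, eig, "Acc1")
  expect_equal(sc_perm$kME, sc$kME[perm])
})

test_that("eigengene basis recovers planted orthogonal shapes", {
  # two antipodal-pair shapes: cosine peaking at ZT1 and at ZT7
  ex <- make_cosinor_experiment(phases = rep(c(1, 7), each = 30),
                                noise_sd = 0.05, seed = 6)
  eig <- build_eigengene_basis(ex$expr, ex$meta, min_cluster_size = 10)
  shapes <- cbind(cos(2 * pi * (ZT4 - 1) / 24), cos(2 * pi * (ZT4 - 7) / 24))
  best <- apply(abs(cor(eig, shapes)), 2, max)
  expect_true(all(best > 0.9))
})

test_that("permutation calls are reproducible and validate n_perm", {
  ex <- make_cosinor_experiment(phases = rep(c(1, 7), 10), noise_sd = 0.2,
                                seed = 2)
  eig <- build_eigengene_basis(ex$expr, ex$meta, min_cluster_size = 5)
  expect_error(permutation_calls(ex$expr, ex$meta, eig, "Acc1", n_perm = 0),
               "n_perm")
  p1 <- permutation_calls(ex$expr, ex$meta, eig, "Acc1", n_perm = 25, seed = 3)
  p2 <- permutation_calls(ex$expr, ex$meta, eig, "Acc1", n_perm = 25, seed = 3)
  expect_identical(p1, p2)
  expect_true(all(p1$fdr_kME >= 0 & p1$fdr_kME <= 1))
})

test_that("pointwise Welch validation finds planted single-ZT shifts", {
  set.seed(9)
  n <- 40
  ex <- make_cosinor_experiment(phases = rep(1, n), noise_sd = 0.1, seed = 9)
  expr <- ex$expr
  # plant a very large (20 sd) shift at ZT13 under WL for the first 3 genes:
  # with 3 vs 3 replicates the Welch p-value floor is set by the tiny
  # degrees of freedom, so the planted effect must dominate decisively
  hit <- ex$meta$treatment == "WL" & ex$meta$ZT == 13
  expr[1:3, hit] <- expr[1:3, hit] + 2
  v <- validate_with_pointwise_tests(expr, ex$meta, "Acc1", alpha = 0.05,
                                     calls = rownames(expr)[1:3])
  expect_true(all(v$table$padj_any[1:3]))
  expect_lt(mean(v$table$padj_any[-(1:3)]), 0.05)
  expect_gt(v$jaccard, 0.7)
})

test_that("low-signal accessions are dropped by kME call count", {
  counts <- c(Qu = 17, Ze = 16, Av = 311, St = 1204)
  r <- drop_low_signal_accessions(counts, min_kME_genes = 50)
  expect_setequal(r$dropped, c("Qu", "Ze"))
  expect_setequal(r$retained, c("Av", "St"))
  expect_equal(drop_low_signal_accessions(counts, 0)$dropped, character(0))
})
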