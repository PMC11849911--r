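test_that("phase is the argmax ZT with earliest-ZT tie-breaking", {
  expect_equal(estimate_phase(c(1, 5, 2, 0)), 7)
  expect_equal(estimate_phase(c(5, 5, 2, 0)), 1)     # tie -> earliest
  expect_true(is.na(estimate_phase(c(3, 3, 3, 3))))  # flat -> undefined
  # noiseless cosine peaking at ZT13 sampled on the grid
  prof <- cos(2 * pi * (c(1, 7, 13, 19) - 13) / 24)
  expect_equal(estimate_phase(prof), 13)
  # matrix input vectorizes over rows
  m <- rbind(c(1, 5, 2, 0), prof)
  expect_equal(unname(estimate_phase(m)), c(7, 13))
})

test_that("phase-change classifier matches an exhaustive circular oracle", {
  grid <- c(1, 7, 13, 19)
  # independent oracle: minimal circular displacement, with the 12 h
  # ambiguity resolved by the sign of the raw difference
  oracle <- function(ww, wl) {
    d <- ww - wl
    cands <- c(d, d + 24, d - 24)
    g <- cands[which.min(abs(cands))]
    if (abs(g) == 12) g <- sign(d) * 12
    g
  }
  pairs <- expand.grid(ww = grid, wl = grid)
  got <- phase_change_group(pairs$ww, pairs$wl)
  want <- mapply(oracle, pairs$ww, pairs$wl)
  expect_equal(got, as.integer(want))
  # five classes with the expected multiplicities
  expect_equal(as.vector(table(factor(got, levels = c(-12, -6, 0, 6, 12)))),
               c(2, 4, 4, 4, 2))
  # the Methods legend's worked case: WW 13, WL 7 -> WL peaks 6 h earlier
  expect_equal(phase_change_group(13, 7), 6L)
  # wrap: WW 1, WL 19 is 6 h earlier across midnight
  expect_equal(phase_change_group(1, 19), 6L)
  expect_equal(phase_change_group(1, 19, flip_sign = TRUE), -6L)
  expect_error(phase_change_group(2, 7), "grid")
})

test_that("phase tables classify planted shifts end to end", {
  ex <- make_cosinor_experiment(phases = c(13, 13, 1), shifts = c(6, 0, -6),
                                noise_sd = 0)
  pt <- phase_table(ex$expr, ex$meta, "Acc1")
  expect_equal(pt$phase_WW, c(13, 13, 1))
  expect_equal(pt$phase_WL, c(7, 13, 7))
  expect_equal(pt$group, c(6L, 0L, -6L))
})

test_that("phase-group proportions are simplex-valued per stratum", {
  map <- make_map(6)
  rec <- data.frame(
    accession = rep(c("A1", "A2"), each = 6),
    gene = rep(map$gene_id, 1),
    group = c(0, 0, 6, 6, -6, 12, 0, 0, 0, 0, 0, -12))
  pr <- subgenome_phase_proportions(rec, map)
  sums <- rowSums(pr$by_accession[, -1])
  expect_equal(unname(sums), rep(1, 2), tolerance = 1e-12)
  sums2 <- rowSums(pr$by_subgenome[, -(1:2)])
  expect_equal(unname(sums2), rep(1, nrow(pr$by_subgenome)), tolerance = 1e-12)
  # all genes in one group -> indicator vector
  rec0 <- data.frame(accession = "A1", gene = map$gene_id,
                     group = rep(0, 12))
  pr0 <- subgenome_phase_proportions(rec0, map)
  expect_equal(unname(unlist(pr0$by_accession[1, -1])), c(0, 0, 1, 0, 0))
  # unmapped genes reported
  rec_un <- rbind(rec, data.frame(accession = "A1", gene = "ghost", group = 0))
  expect_true("ghost" %in% subgenome_phase_proportions(rec_un, map)$unmapped)
})

test_that("subgenome expression bias recovers a planted BnC/BnA ratio", {
  des <- expression_sim_design(n_ortholog_groups = 150, accessions = "A1",
                               bnc_bias = 1.1, responsive_fraction = 0,
                               noise_sd = 0.2, seed = 12)
  sim <- gen_expression_data(des)
  b <- subgenome_expression_bias(sim$expr, sim$meta, sim$map, seed = 1)
  expect_equal(b$diff, log2(1.1), tolerance = 0.04)
  expect_true(b$ci_lo < log2(1.1) && log2(1.1) < b$ci_hi)
  # identical expression for all genes -> zero difference
  flat <- sim$expr; flat[] <- 5 + rep(rnorm(ncol(flat), 0, 0.1),
                                      each = nrow(flat))
  b0 <- subgenome_expression_bias(flat, sim$meta, sim$map, seed = 1)
  expect_equal(b0$diff, 0, tolerance = 1e-12)
  # gene-order invariance
  perm <- sample(nrow(sim$expr))
  bp <- subgenome_expression_bias(sim$expr[perm, ], sim$meta, sim$map, seed = 1)
  expect_equal(bp$diff, b$diff, tolerance = 1e-12)
})

test_that("ortholog-level sharing is the union of member-gene accession sets", {
  map <- make_map(4)
  calls <- list(A1 = c("BnA_OG01", "BnA_OG02"),
                A2 = c("BnC_OG01", "BnA_OG02"),
                A3 = c("BnC_OG03"))
  sh <- gene_sharing_distribution(calls, map)
  # per-gene counts
  expect_equal(unname(sh$gene_counts[c("BnA_OG01", "BnC_OG01", "BnA_OG02")]),
               c(1L, 1L, 2L))
  # union property: OG01 called in A1 (via BnA) and A2 (via BnC)
  expect_setequal(sh$ortholog_accession_sets[["OG01"]], c("A1", "A2"))
  expect_equal(unname(sh$ortholog_counts[c("OG01", "OG02", "OG03")]),
               c(2L, 2L, 1L))
  # per-ortholog count >= max per-member count, always (random fixtures)
  set.seed(5)
  for (i in 1:10) {
    cs <- lapply(1:4, function(a) sample(map$gene_id, sample(3:6, 1)))
    names(cs) <- paste0("A", 1:4)
    s <- gene_sharing_distribution(cs, map)
    for (og in names(s$ortholog_counts)) {
      members <- map$gene_id[map$ortholog_group == og]
      mx <- max(c(0L, s$gene_counts[intersect(members, names(s$gene_counts))]),
                na.rm = TRUE)
      expect_gte(s$ortholog_counts[[og]], mx)
    }
  }
  expect_equal(sum(sh$gene$proportion), 1)
})

test_that("responsive-homoeolog profiles reproduce planted truth", {
  map <- rbind(make_map(2),
               data.frame(gene_id = "BnC_OG01_b", subgenome = "BnC",
                          ortholog_group = "OG01",
                          arabidopsis_ortholog = "AT01"))
  calls <- list(A1 = c("BnC_OG01"), A2 = c("BnA_OG01", "BnC_OG01", "BnC_OG01_b"))
  pr <- responsive_homoeolog_profile("OG01", calls, map)
  expect_equal(pr$n_responsive, c(1, 3))
  expect_equal(pr$n_BnA, c(0, 1))
  expect_equal(pr$n_BnC, c(1, 2))
  expect_error(responsive_homoeolog_profile("OG99", calls, map), "unknown")
  # simulation round-trip: truth record matches profile
  des <- expression_sim_design(n_ortholog_groups = 30,
                               accessions = c("A1", "A2"),
                               responsive_fraction = 0.3, seed = 3)
  sim <- gen_expression_data(des)
  truth_sets <- lapply(sim$truth$responsive, function(t) t$gene_id)
  og <- sim$truth$responsive[["A1"]]$ortholog_group[1]
  prof <- responsive_homoeolog_profile(og, truth_sets, sim$map)
  for (acc in c("A1", "A2")) {
    tr <- sim$truth$responsive[[acc]]
    in_og <- tr$gene_id[tr$ortholog_group == og]
    expect_equal(prof$n_responsive[prof$accession == acc], length(in_og))
  }
})
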