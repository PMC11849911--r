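test_that("response scores are replicate-mean WL - WW differences", {
  # identical treatments -> zero scores; constant offset -> constant scores
  ex0 <- make_cosinor_experiment(phases = c(1, 7), noise_sd = 0)
  rs0 <- compute_response_scores(ex0$expr, ex0$meta)
  expect_true(all(rs0$scores == 0))
  ex1 <- make_cosinor_experiment(phases = c(1, 7), offsets = c(1, 1),
                                 noise_sd = 0)
  rs1 <- compute_response_scores(ex1$expr, ex1$meta)
  expect_true(all(abs(rs1$scores - 1) < 1e-12))
  # planted +6 h phase shift: scores follow the closed-form cosine difference
  ex2 <- make_cosinor_experiment(phases = 13, shifts = 6, noise_sd = 0)
  rs2 <- compute_response_scores(ex2$expr, ex2$meta)
  zt <- c(1, 7, 13, 19)
  want <- cos(2 * pi * (zt - 7) / 24) - cos(2 * pi * (zt - 13) / 24)
  expect_equal(unname(rs2$scores[1, ]), want, tolerance = 1e-12)
  # an accession missing one treatment is excluded with a report
  half <- ex0$meta$treatment == "WW"
  expect_error(compute_response_scores(ex0$expr[, half], ex0$meta[half, ]),
               "no accession")
})

test_that("signed network adjacency follows the soft-threshold formula", {
  s <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),    # cor +1
             c = c(4, 3, 2, 1),                        # cor -1 with a
             d = c(5, 5, 5, 5))                        # zero variance
  colnames(s) <- paste0("X_ZT", c(1, 7, 13, 19))
  net <- build_network(s, beta = 6)
  expect_equal(net$removed, "d")
  expect_equal(net$dissimilarity["a", "b"], 0)
  expect_equal(net$adjacency["a", "c"], 0)
  expect_equal(net$dissimilarity["a", "c"], 1)
  expect_equal(diag(net$dissimilarity), rep(0, 3), ignore_attr = TRUE)
  # beta = 1, cor = 0 -> dissimilarity 0.5
  set.seed(1)
  z <- rbind(e = c(1, -1, 1, -1), f = c(1, 1, -1, -1))
  colnames(z) <- colnames(s)
  net2 <- build_network(z, beta = 1)
  expect_equal(net2$dissimilarity["e", "f"], 0.5)
})

test_that("module detection recovers planted patterns and isolates noise", {
  sim <- gen_response_archetypes(n_archetypes = 4, genes_per = 60,
                                 n_accessions = 6, within_cor = 0.9, seed = 2)
  mods <- detect_modules(sim$scores, min_module_size = 30)
  expect_length(mods$modules, 4)
  tab <- table(sim$truth, mods$assignment[names(sim$truth)])
  expect_gt(sum(apply(tab, 1, max)) / length(sim$truth), 0.95)
  # labels ordered by decreasing size
  sizes <- lengths(mods$modules)
  expect_true(all(diff(sizes) <= 0))
  # gene-order invariance of the partition
  perm <- sample(nrow(sim$scores))
  mods_p <- detect_modules(sim$scores[perm, ], min_module_size = 30)
  agree <- outer(mods$assignment, mods$assignment, "==")
  agree_p <- outer(mods_p$assignment[names(mods$assignment)],
                   mods_p$assignment[names(mods$assignment)], "==")
  expect_true(all(agree == agree_p))
  # single planted pattern -> a single module
  one <- gen_response_archetypes(n_archetypes = 1, genes_per = 80,
                                 n_accessions = 6, seed = 3)
  expect_length(detect_modules(one$scores, min_module_size = 30)$modules, 1)
  # pure noise at the same cut: most genes land in the null module
  set.seed(4)
  noise <- matrix(rnorm(300 * 24), 300, 24,
                  dimnames = list(sprintf("n%03d", 1:300),
                                  colnames(one$scores)))
  nm <- detect_modules(noise, min_module_size = 30)
  expect_gt(mean(nm$assignment == "M0"), 0.5)
})

test_that("module eigengene is the sign-oriented leading PC", {
  accs <- paste0("A", 1:3)
  cn <- as.vector(t(outer(accs, c(1, 7, 13, 19),
                          function(a, z) paste0(a, "_ZT", z))))
  v <- sin(seq_len(12))
  sub <- matrix(rep(v, each = 20), 20, 12, dimnames = list(NULL, cn)) +
    matrix(rnorm(240, 0, 1e-6), 20, 12)
  eg <- module_eigengene(sub)
  expect_equal(dim(eg), c(3, 4))
  expect_gt(attr(eg, "explained_variance"), 0.999)
  zv <- (v - mean(v)) / sd(v)
  expect_gt(cor(as.vector(t(eg)), zv), 0.999)  # oriented with the mean
  # a two-gene v / -v module: full variance on PC1, opposing flag set
  sub2 <- rbind(v, -v); colnames(sub2) <- cn
  eg2 <- module_eigengene(sub2)
  expect_equal(attr(eg2, "explained_variance"), 1)
  expect_true(attr(eg2, "opposing"))
})

test_that("eigengene explained variance is maximal among unit summaries", {
  set.seed(8)
  cn <- as.vector(t(outer(paste0("A", 1:2), c(1, 7, 13, 19),
                          function(a, z) paste0(a, "_ZT", z))))
  sub <- matrix(rnorm(80), 10, 8, dimnames = list(NULL, cn))
  eg <- module_eigengene(sub)
  z <- t(scale(t(sub)))
  v_eg <- as.vector(t(eg)); v_eg <- v_eg / sqrt(sum(v_eg^2))
  var_eg <- sum((z %*% v_eg)^2)
  for (i in 1:50) {
    u <- rnorm(8); u <- u / sqrt(sum(u^2))
    expect_lte(sum((z %*% u)^2), var_eg + 1e-8)
  }
})

test_that("modules with opposing accession responses are split by sign", {
  accs <- paste0("A", 1:4)
  cn <- as.vector(t(outer(accs, c(1, 7, 13, 19),
                          function(a, z) paste0(a, "_ZT", z))))
  p <- cos(2 * pi * (c(1, 7, 13, 19) - 13) / 24)
  prof <- c(p, p, -p, -p)  # A1, A2 up; A3, A4 down
  sub <- matrix(rep(prof, each = 30), 30, 16, dimnames = list(NULL, cn)) +
    matrix(rnorm(480, 0, 0.01), 30, 16)
  sp <- split_opposing_modules(sub, opposing_threshold = 0.75)
  expect_length(sp, 2)
  parts <- lapply(sp, `[[`, "accessions")
  expect_true(setequal(parts[[1]], c("A1", "A2")) ||
                setequal(parts[[1]], c("A3", "A4")))
  # concordant accessions: module unchanged
  sub2 <- matrix(rep(c(p, p, p, p), each = 30), 30, 16,
                 dimnames = list(NULL, cn)) +
    matrix(rnorm(480, 0, 0.01), 30, 16)
  expect_length(split_opposing_modules(sub2), 1)
})
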