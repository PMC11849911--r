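# Simulators for growth, diel expression, and targeted-metabolite data with
# known ground truth. Defaults mirror the study design: 16 plants per
# treatment group phenotyped daily over 26 days; 4 diel time points
# (ZT 1, 7, 13, 19) x 3 replicates for expression; metabolite sampling at
# ZT 4, 12, 20. Every random choice is recorded in a `truth` element.

ZT_EXPR <- c(1, 7, 13, 19)
ZT_METAB <- c(4, 12, 20)

#' Design for the growth simulator
#'
#' @param n_plants_per_group Plants per accession x treatment group (>= 2).
#' @param days Strictly increasing observation days.
#' @param params Named list: one element per group (e.g. `"WW"`, `"WL"`),
#'   each a list with `A`, `B`, `C` (Gompertz) and `subA`, `subB`, `subC`
#'   (variance profile), all positive.
#' @param noise_df Student-t degrees of freedom of the observation noise
#'   (>= 1).
#' @param accession Accession label attached to the simulated plants.
#' @param seed Integer seed.
#' @return A list of class `"growth_sim_design"`.
#' @export
growth_sim_design <- function(n_plants_per_group = 16, days = 0:26,
                              params = list(
                                WW = list(A = 130, B = 15, C = 0.25,
                                          subA = 20, subB = 10, subC = 3),
                                WL = list(A = 65, B = 14, C = 0.25,
                                          subA = 20, subB = 10, subC = 3)),
                              noise_df = 10, accession = "Acc1", seed = 1) {
  if (n_plants_per_group < 2) stop("invalid design: need >= 2 plants per group")
  if (is.unsorted(days, strictly = TRUE)) stop("invalid design: days must be strictly increasing")
  if (noise_df < 1) stop("invalid design: noise_df must be >= 1")
  for (g in names(params)) {
    p <- params[[g]]
    if (!all(c("A", "B", "C", "subA", "subB", "subC") %in% names(p)) ||
        any(unlist(p) <= 0))
      stop("invalid design: non-positive or missing parameter in group ", g)
  }
  structure(list(n_plants_per_group = n_plants_per_group, days = days,
                 params = params, noise_df = noise_df,
                 accession = accession, seed = seed),
            class = "growth_sim_design")
}

#' Simulate plant-area growth series
#'
#' Draws per-plant areas as
#' `area = gompertz_mean(day) + variance_profile(day) * t(noise_df)`,
#' one series per plant, reproducible from the design seed.
#'
#' @param design A [growth_sim_design()].
#' @return List with `data` (data.frame: plant_id, accession, treatment, day,
#'   area_cm2) and `truth` (the generative parameters).
#' @export
gen_growth_data <- function(design) {
  stopifnot(inherits(design, "growth_sim_design"))
  set.seed(design$seed)
  rows <- list()
  for (g in names(design$params)) {
    p <- design$params[[g]]
    for (i in seq_len(design$n_plants_per_group)) {
      mu <- gompertz_mean(design$days, p$A, p$B, p$C)
      sd <- variance_profile(design$days, p$subA, p$subB, p$subC)
      rows[[length(rows) + 1]] <- data.frame(
        plant_id = sprintf("%s_%s_p%02d", design$accession, g, i),
        accession = design$accession, treatment = g, day = design$days,
        area_cm2 = mu + sd * stats::rt(length(design$days), df = design$noise_df))
    }
  }
  list(data = do.call(rbind, rows),
       truth = list(params = design$params, noise_df = design$noise_df,
                    seed = design$seed))
}

#' Design for the diel expression simulator
#'
#' Simulates homoeolog-resolved diel expression for an allopolyploid:
#' ortholog groups carry a variable number of copies on each subgenome
#' (BnA, BnC), BnC copies get a mild multiplicative expression bias, every
#' gene follows a 24-h cosinor sampled at ZT 1/7/13/19 in 3 replicates, and
#' in each accession a random subset of genes responds to water limitation
#' with a phase shift from a discrete menu and/or a median (level) shift.
#'
#' @param n_ortholog_groups Number of ortholog groups.
#' @param copy_probs Probability of 1, 2 or 3 copies per subgenome.
#' @param accessions Character vector of accession names (non-empty).
#' @param baseline_log2 Mean log2 expression level.
#' @param amplitude Cosinor amplitude, log2 units (>= 0).
#' @param bnc_bias Multiplicative BnC/BnA expression ratio (> 0).
#' @param responsive_fraction Fraction of genes WL-responsive per accession.
#' @param phase_shift_menu Subset of `c(0, 6, -6, 12, -12)` hours; positive
#'   means the WL peak is earlier.
#' @param median_shift Log2 offset added under WL for responsive genes drawn
#'   as level-responders.
#' @param noise_sd Residual log2 sd.
#' @param replicate_dropout_rate Probability that one of the three replicates
#'   of a gene x ZT cell is missing (at most one per cell).
#' @param seed Integer seed.
#' @return A list of class `"expression_sim_design"`.
#' @export
expression_sim_design <- function(n_ortholog_groups = 200,
                                  copy_probs = c(`1` = 0.6, `2` = 0.3, `3` = 0.1),
                                  accessions = paste0("Acc", 1:4),
                                  baseline_log2 = 4, amplitude = 1,
                                  bnc_bias = 1.1, responsive_fraction = 0.1,
                                  phase_shift_menu = c(6, -6, 12, -12),
                                  median_shift = 1, noise_sd = 0.2,
                                  replicate_dropout_rate = 0,
                                  seed = 1) {
  if (!length(accessions)) stop("invalid design: empty accession list")
  if (amplitude < 0) stop("invalid design: amplitude must be >= 0")
  if (bnc_bias <= 0) stop("invalid design: bnc_bias must be > 0")
  if (responsive_fraction < 0 || responsive_fraction > 1)
    stop("invalid design: responsive_fraction must be in [0, 1]")
  if (!all(phase_shift_menu %in% c(0, 6, -6, 12, -12)))
    stop("invalid design: phase shifts must be in {0, +/-6, +/-12}")
  structure(list(n_ortholog_groups = n_ortholog_groups,
                 copy_probs = copy_probs, accessions = accessions,
                 baseline_log2 = baseline_log2, amplitude = amplitude,
                 bnc_bias = bnc_bias,
                 responsive_fraction = responsive_fraction,
                 phase_shift_menu = phase_shift_menu,
                 median_shift = median_shift, noise_sd = noise_sd,
                 replicate_dropout_rate = replicate_dropout_rate,
                 seed = seed),
            class = "expression_sim_design")
}

.cosinor <- function(zt, phase, amplitude) {
  amplitude * cos(2 * pi * (zt - phase) / 24)
}

#' Simulate homoeolog-resolved diel expression
#'
#' @param design An [expression_sim_design()].
#' @return List with `expr` (gene x sample matrix of log2 expression, NA for
#'   dropped replicates), `meta` (sample_id, accession, treatment, ZT,
#'   replicate), `map` (gene_id, subgenome, ortholog_group,
#'   arabidopsis_ortholog), and `truth` (per accession: responsive genes,
#'   their phase/median shifts; per gene: base phase).
#' @export
gen_expression_data <- function(design) {
  stopifnot(inherits(design, "expression_sim_design"))
  set.seed(design$seed)
  # homoeolog map
  genes <- list()
  for (og in seq_len(design$n_ortholog_groups)) {
    for (sg in c("BnA", "BnC")) {
      n_cop <- sample(1:3, 1, prob = design$copy_probs)
      for (k in seq_len(n_cop)) {
        genes[[length(genes) + 1]] <- data.frame(
          gene_id = sprintf("%s_OG%04d_c%d", sg, og, k), subgenome = sg,
          ortholog_group = sprintf("OG%04d", og),
          arabidopsis_ortholog = sprintf("AT%04d", og))
      }
    }
  }
  map <- do.call(rbind, genes)
  n_genes <- nrow(map)
  base_phase <- sample(ZT_EXPR, n_genes, replace = TRUE)
  gene_baseline <- design$baseline_log2 +
    ifelse(map$subgenome == "BnC", log2(design$bnc_bias), 0)

  meta <- expand.grid(replicate = 1:3, ZT = ZT_EXPR,
                      treatment = c("WW", "WL"),
                      accession = design$accessions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("accession", "treatment", "ZT", "replicate")]
  meta$sample_id <- with(meta, sprintf("%s_%s_ZT%d_r%d",
                                       accession, treatment, ZT, replicate))
  expr <- matrix(NA_real_, n_genes, nrow(meta),
                 dimnames = list(map$gene_id, meta$sample_id))
  truth_resp <- list()
  for (acc in design$accessions) {
    n_resp <- round(design$responsive_fraction * n_genes)
    resp_idx <- sample.int(n_genes, n_resp)
    menu <- design$phase_shift_menu
    shift <- if (n_resp)
      menu[sample.int(length(menu), n_resp, replace = TRUE)] else integer()
    med <- if (n_resp)
      ifelse(shift == 0, design$median_shift,
             sample(c(0, design$median_shift), n_resp, replace = TRUE))
    else numeric()
    truth_resp[[acc]] <- data.frame(
      gene_id = map$gene_id[resp_idx],
      subgenome = map$subgenome[resp_idx],
      ortholog_group = map$ortholog_group[resp_idx],
      phase_shift = if (n_resp) shift else integer(),
      median_shift = if (n_resp) med else numeric())
    for (trt in c("WW", "WL")) {
      phase <- base_phase
      offset <- numeric(n_genes)
      if (trt == "WL" && n_resp) {
        # positive shift = WL peak earlier in the day
        phase[resp_idx] <- (base_phase[resp_idx] - shift) %% 24
        offset[resp_idx] <- med
      }
      for (zt in ZT_EXPR) {
        cols <- meta$accession == acc & meta$treatment == trt & meta$ZT == zt
        mu <- gene_baseline + offset + .cosinor(zt, phase, design$amplitude)
        for (j in which(cols))
          expr[, j] <- mu + stats::rnorm(n_genes, 0, design$noise_sd)
      }
    }
  }
  # replicate dropout: at most one of three replicates per gene x cell
  dropped <- NULL
  if (design$replicate_dropout_rate > 0) {
    cells <- unique(meta[, c("accession", "treatment", "ZT")])
    drops <- list()
    for (ci in seq_len(nrow(cells))) {
      cols <- which(meta$accession == cells$accession[ci] &
                    meta$treatment == cells$treatment[ci] &
                    meta$ZT == cells$ZT[ci])
      hit <- which(stats::runif(n_genes) < design$replicate_dropout_rate)
      if (length(hit)) {
        pick <- sample(cols, length(hit), replace = TRUE)
        expr[cbind(hit, pick)] <- NA_real_
        drops[[length(drops) + 1]] <- data.frame(
          gene_id = rownames(expr)[hit], sample_id = meta$sample_id[pick])
      }
    }
    if (length(drops)) dropped <- do.call(rbind, drops)
  }
  list(expr = expr, meta = meta, map = map,
       truth = list(responsive = truth_resp, base_phase = base_phase,
                    dropped = dropped, seed = design$seed))
}

#' Design for the targeted-metabolite simulator
#'
#' @param n_features Number of metabolite features.
#' @param accessions Accession names.
#' @param n_replicates Biological replicates per treatment x ZT.
#' @param n_injections Technical injections per biological sample.
#' @param background_level Background peak height (> 0).
#' @param mean_log_abundance,noise_sd Log-scale abundance location and sd.
#' @param effects Character vector recycled over features, each in
#'   `c("none", "zt", "interaction", "censored")`: `zt` plants a ZT main
#'   effect in both treatments, `interaction` plants a WW-only ZT trend,
#'   `censored` draws the feature below the detection limit.
#' @param effect_size Log-scale magnitude of planted effects.
#' @param run_scale_sd Lognormal sd of per-injection scale factors (> 0
#'   values result; 0 disables run variation).
#' @param seed Integer seed.
#' @return List of class `"metab_sim_design"`.
#' @export
metab_sim_design <- function(n_features = 20, accessions = "Mu",
                             n_replicates = 4, n_injections = 3,
                             background_level = 5e3,
                             mean_log_abundance = log(5e5), noise_sd = 0.25,
                             effects = c("none", "zt", "interaction"),
                             effect_size = 1, run_scale_sd = 0.3, seed = 1) {
  if (background_level <= 0) stop("invalid design: background must be > 0")
  stopifnot(all(effects %in% c("none", "zt", "interaction", "censored")),
            run_scale_sd >= 0)
  structure(list(n_features = n_features, accessions = accessions,
                 n_replicates = n_replicates, n_injections = n_injections,
                 background_level = background_level,
                 mean_log_abundance = mean_log_abundance,
                 noise_sd = noise_sd, effects = effects,
                 effect_size = effect_size, run_scale_sd = run_scale_sd,
                 seed = seed),
            class = "metab_sim_design")
}

#' Simulate a targeted metabolite feature table
#'
#' Features carry planted diel/treatment structure on the log scale, are
#' multiplied by per-injection run scale factors, and `censored` features
#' are drawn below twice the background so downstream censoring flags them
#' not-detected. A pseudo-feature `region_sum` row is not generated; instead
#' each injection also reports `region_signal`, the summed abundance of a
#' representative region, proportional to the run scale factor, for
#' normalization.
#'
#' @param design A [metab_sim_design()].
#' @return List with `data` (long data.frame: feature, accession, treatment,
#'   ZT, replicate, injection, sample_id, area, height, region_signal) and
#'   `truth` (per-feature effect labels, per-injection scale factors).
#' @export
gen_metabolite_data <- function(design) {
  stopifnot(inherits(design, "metab_sim_design"))
  set.seed(design$seed)
  eff <- rep_len(design$effects, design$n_features)
  feat <- sprintf("F%03d", seq_len(design$n_features))
  inj_grid <- expand.grid(injection = seq_len(design$n_injections),
                          replicate = seq_len(design$n_replicates),
                          ZT = ZT_METAB, treatment = c("WW", "WL"),
                          accession = design$accessions,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  inj_grid$sample_id <- with(inj_grid, sprintf("%s_%s_ZT%d_r%d_i%d",
                                               accession, treatment, ZT,
                                               replicate, injection))
  scale_factors <- exp(stats::rnorm(nrow(inj_grid), 0, design$run_scale_sd))
  region_base <- 1e7
  rows <- list()
  zt_trend <- (match(inj_grid$ZT, ZT_METAB) - 2) / 1  # -1, 0, 1 over ZT
  for (f in seq_len(design$n_features)) {
    mu <- rep(design$mean_log_abundance, nrow(inj_grid))
    if (eff[f] == "zt") mu <- mu + design$effect_size * zt_trend
    if (eff[f] == "interaction")
      mu <- mu + design$effect_size * zt_trend * (inj_grid$treatment == "WW")
    if (eff[f] == "censored")
      mu <- rep(log(0.5 * design$background_level), nrow(inj_grid))
    ab <- exp(mu + stats::rnorm(nrow(inj_grid), 0, design$noise_sd))
    ab <- ab * scale_factors
    rows[[f]] <- data.frame(feature = feat[f], inj_grid,
                            area = ab, height = ab / 10,
                            region_signal = region_base * scale_factors)
  }
  list(data = do.call(rbind, rows),
       truth = list(effects = stats::setNames(eff, feat),
                    scale_factors = stats::setNames(scale_factors,
                                                    inj_grid$sample_id),
                    seed = design$seed))
}

#' Simulate response-score archetype data
#'
#' Generates per-gene response-score vectors (accession x ZT, concatenated)
#' as noisy copies of a set of mutually near-orthogonal archetypal temporal
#' patterns, for testing co-expression module recovery. Each gene's
#' correlation with its archetype is `sqrt(within_cor)` so that two genes
#' from the same archetype correlate at about `within_cor`.
#'
#' @param n_archetypes Number of planted patterns.
#' @param genes_per Genes per pattern.
#' @param n_accessions Number of accessions (profile length is
#'   `4 * n_accessions`).
#' @param within_cor Target within-pattern gene-gene correlation.
#' @param seed Integer seed.
#' @return List with `scores` (gene x (accession x ZT) matrix), `truth`
#'   (archetype label per gene), `archetypes` (pattern matrix), `accessions`
#'   and `zt`.
#' @export
gen_response_archetypes <- function(n_archetypes = 11, genes_per = 200,
                                    n_accessions = 14, within_cor = 0.9,
                                    seed = 1) {
  stopifnot(n_archetypes >= 1, genes_per >= 1,
            within_cor > 0, within_cor <= 1)
  set.seed(seed)
  p <- 4 * n_accessions
  if (n_archetypes > p) stop("more archetypes than profile dimensions")
  # near-orthogonal archetypes: QR of a random Gaussian matrix
  arch <- qr.Q(qr(matrix(stats::rnorm(p * n_archetypes), p)))[, seq_len(n_archetypes)]
  arch <- scale(arch)  # z-score columns
  lab <- rep(seq_len(n_archetypes), each = genes_per)
  r <- sqrt(within_cor)
  noise <- matrix(stats::rnorm(length(lab) * p), length(lab), p)
  noise <- t(apply(noise, 1, function(x) (x - mean(x)) / stats::sd(x)))
  scores <- r * t(arch)[lab, , drop = FALSE] + sqrt(1 - r^2) * noise
  accs <- paste0("Acc", seq_len(n_accessions))
  colnames(scores) <- as.vector(t(outer(accs, ZT_EXPR,
                                        function(a, z) paste0(a, "_ZT", z))))
  rownames(scores) <- sprintf("G%05d", seq_along(lab))
  list(scores = scores, truth = stats::setNames(lab, rownames(scores)),
       archetypes = arch, accessions = accs, zt = ZT_EXPR)
}
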