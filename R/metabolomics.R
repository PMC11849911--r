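# Targeted metabolomics: censoring at detection/quantification limits,
# representative-region-sum run normalization, and time-of-day x treatment
# statistics on log peak areas.

#' Limit specification for censoring
#'
#' Detection and quantification limits derived from the instrument
#' background (`LOD = lod_multiplier * background`,
#' `LOQ = loq_multiplier * background`), with optional absolute overrides
#' applied verbatim (e.g. LOD 1.0e4 / LOQ 5.0e4 peak height).
#'
#' @param background Background peak height (> 0).
#' @param lod_multiplier,loq_multiplier Multipliers (default 2x and 5x).
#' @param lod_absolute,loq_absolute Optional absolute overrides.
#' @return List of class `"limit_spec"` with resolved `lod` and `loq`.
#' @export
limit_spec <- function(background, lod_multiplier = 2, loq_multiplier = 5,
                       lod_absolute = NULL, loq_absolute = NULL) {
  stopifnot(background > 0)
  lod <- if (is.null(lod_absolute)) lod_multiplier * background else lod_absolute
  loq <- if (is.null(loq_absolute)) loq_multiplier * background else loq_absolute
  if (!(loq >= lod && lod > 0)) stop("need loq >= lod > 0")
  structure(list(background = background, lod = lod, loq = loq),
            class = "limit_spec")
}

#' Censor a metabolite feature table at LOD/LOQ
#'
#' Flags each measurement by peak height: below the limit of detection ->
#' `"ND"` (not detected); at or above LOD but below the limit of
#' quantification -> `"<LOQ"` (detected, not quantifiable); at or above LOQ
#' -> `"quantified"`. Boundary values fall in the upper category.
#'
#' @param data Long-format data.frame with a `height` column (>= 0).
#' @param limits A [limit_spec()].
#' @return `data` with a `flag` factor column added.
#' @export
censor <- function(data, limits) {
  stopifnot(inherits(limits, "limit_spec"), "height" %in% names(data))
  if (any(data$height < 0, na.rm = TRUE)) stop("negative peak heights")
  data$flag <- factor(
    ifelse(data$height >= limits$loq, "quantified",
           ifelse(data$height >= limits$lod, "<LOQ", "ND")),
    levels = c("ND", "<LOQ", "quantified"))
  data
}

#' Representative-region-sum run normalization
#'
#' Divides each sample's abundances by that sample's summed signal over a
#' representative region, then multiplies by the mean region sum across all
#' samples, so that after normalization every sample's region sum equals
#' that mean exactly. The operation is idempotent.
#'
#' @param data Long-format data.frame with `sample_id`, `area`, and a
#'   `region_signal` column giving each sample's representative-region sum
#'   (constant within sample).
#' @return List with `data` (normalized `area` and updated
#'   `region_signal`), `factors` (per-sample multipliers), and `excluded`
#'   (samples with non-positive region sums, removed).
#' @export
normalize_region <- function(data) {
  stopifnot(all(c("sample_id", "area", "region_signal") %in% names(data)))
  sums <- tapply(data$region_signal, data$sample_id, function(x) x[1])
  sums <- stats::setNames(as.numeric(sums), names(sums))
  bad <- names(sums)[!(sums > 0)]
  if (length(bad)) data <- data[!(data$sample_id %in% bad), , drop = FALSE]
  sums <- sums[!(names(sums) %in% bad)]
  if (!length(sums)) stop("no sample with positive region sum")
  target <- mean(sums)
  fac <- target / sums
  f <- unname(fac[data$sample_id])
  data$area <- data$area * f
  data$region_signal <- data$region_signal * f
  if ("height" %in% names(data)) data$height <- data$height * f
  list(data = data, factors = fac, excluded = bad)
}

#' Time-of-day x treatment statistics for one feature
#'
#' Two-way fixed-effects model `log(area) ~ treatment * ZT` on quantified
#' measurements (technical injections averaged per biological sample
#' first), reporting the ZT main-effect and interaction p-values and
#' Holm-adjusted pairwise ZT contrasts within each treatment. Censored
#' values are excluded and counted; features with an entirely censored
#' cell are flagged partial and contrasts touching that cell are skipped.
#'
#' @param data Long-format rows of one feature: `treatment`, `ZT`,
#'   `replicate`, `area`, `flag` (from [censor()]); optional `injection`.
#' @param min_reps Minimum quantified biological replicates per cell for
#'   the cell to count as usable.
#' @return List with `anova` (p_zt, p_interaction), `contrasts` (treatment,
#'   ZT pair, p_raw, p_holm), `n_censored`, `partial`, `degenerate`.
#' @export
diel_treatment_stats <- function(data, min_reps = 2) {
  req <- c("treatment", "ZT", "replicate", "area", "flag")
  stopifnot(all(req %in% names(data)))
  ok <- data$flag == "quantified" & !is.na(data$area) & data$area > 0
  n_censored <- sum(!ok)
  d <- data[ok, , drop = FALSE]
  # average technical injections within biological sample
  key <- interaction(d$treatment, d$ZT, d$replicate, drop = TRUE)
  d <- data.frame(treatment = tapply(as.character(d$treatment), key, `[`, 1),
                  ZT = tapply(d$ZT, key, `[`, 1),
                  replicate = tapply(d$replicate, key, `[`, 1),
                  log_area = as.vector(tapply(log(d$area), key, mean)))
  cells <- expand.grid(treatment = unique(data$treatment),
                       ZT = unique(data$ZT), stringsAsFactors = FALSE)
  cells$n <- mapply(function(tr, z)
    sum(d$treatment == tr & d$ZT == z), cells$treatment, cells$ZT)
  partial <- any(cells$n == 0)
  if (nrow(d) < 4 || length(unique(d$ZT)) < 2 ||
      length(unique(d$treatment)) < 2 || stats::var(d$log_area) == 0) {
    return(list(anova = c(p_zt = NA_real_, p_interaction = NA_real_),
                contrasts = NULL, n_censored = n_censored,
                partial = partial, degenerate = TRUE))
  }
  d$treatment <- factor(d$treatment); d$ZTf <- factor(d$ZT)
  fit <- stats::aov(log_area ~ treatment * ZTf, data = d)
  an <- summary(fit)[[1]]
  p <- an[["Pr(>F)"]]
  rn <- trimws(rownames(an))
  res <- c(p_zt = p[match("ZTf", rn)],
           p_interaction = p[match("treatment:ZTf", rn)])
  # pairwise ZT contrasts within treatment, Holm across all of them
  zts <- sort(unique(d$ZT))
  contr <- list()
  for (tr in levels(d$treatment)) {
    for (i in seq_along(zts)) for (j in seq_along(zts)) {
      if (j <= i) next
      x <- d$log_area[d$treatment == tr & d$ZT == zts[i]]
      y <- d$log_area[d$treatment == tr & d$ZT == zts[j]]
      if (length(x) < min_reps || length(y) < min_reps) next
      pv <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
      contr[[length(contr) + 1]] <- data.frame(
        treatment = tr, zt_a = zts[i], zt_b = zts[j], p_raw = pv)
    }
  }
  contrasts <- if (length(contr)) {
    ct <- do.call(rbind, contr)
    ct$p_holm <- stats::p.adjust(ct$p_raw, method = "holm")
    ct
  } else NULL
  list(anova = res, contrasts = contrasts, n_censored = n_censored,
       partial = partial, degenerate = FALSE)
}
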