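# Preprocessing and differential-pattern detection for diel expression
# time courses sampled at ZT 1, 7, 13, 19 in two treatments (WW, WL).

#' Filter uninformative genes
#'
#' Removes genes with zero variance across all samples, then retains genes
#' whose replicate-mean log2 expression exceeds zero at at least one time
#' point in either treatment.
#'
#' @param expr Gene x sample matrix of log2 normalized expression.
#' @param meta Sample metadata data.frame with columns `sample_id`,
#'   `treatment`, `ZT` (and typically `accession`, `replicate`); rows must
#'   cover `colnames(expr)`.
#' @return List with `expr` (filtered matrix) and `removed` (data.frame:
#'   gene, reason in `c("zero_variance", "low_expression")`).
#' @export
filter_genes <- function(expr, meta) {
  stopifnot(is.matrix(expr), nrow(expr) > 0)
  meta <- .match_meta(expr, meta)
  v <- apply(expr, 1, stats::var, na.rm = TRUE)
  zero_var <- !is.na(v) & v == 0
  keep1 <- expr[!zero_var, , drop = FALSE]
  cell <- interaction(meta$treatment, meta$ZT, drop = TRUE)
  if (nrow(keep1)) {
    cell_means <- vapply(levels(cell), function(cl)
      rowMeans(keep1[, cell == cl, drop = FALSE], na.rm = TRUE),
      numeric(nrow(keep1)))
    cell_means <- matrix(cell_means, nrow = nrow(keep1))
    expressed <- apply(cell_means > 0, 1, any, na.rm = TRUE)
  } else expressed <- logical(0)
  removed <- rbind(
    if (any(zero_var)) data.frame(gene = rownames(expr)[zero_var],
                                  reason = "zero_variance"),
    if (any(!expressed)) data.frame(gene = rownames(keep1)[!expressed],
                                    reason = "low_expression"))
  out <- keep1[expressed, , drop = FALSE]
  if (!nrow(out)) warning("all genes removed by filtering")
  list(expr = out, removed = removed)
}

.match_meta <- function(expr, meta) {
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta))
  missing <- setdiff(colnames(expr), meta$sample_id)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
}

#' Library-size normalization of raw counts
#'
#' Per-sample scaling with trimmed-mean-of-M-values (TMM) effective library
#' sizes, an optional per-kilobase correction when gene lengths are given
#' (FPKM-like; otherwise CPM-like), then `log2(x + 1)`.
#'
#' @param counts Gene x sample matrix of non-negative counts.
#' @param gene_lengths Optional numeric vector of gene lengths in bp.
#' @return List with `logexpr` (log2 normalized matrix) and `scale_factors`
#'   (TMM factors per sample).
#' @export
normalize_counts <- function(counts, gene_lengths = NULL) {
  stopifnot(is.matrix(counts), all(counts >= 0, na.rm = TRUE))
  lib <- colSums(counts, na.rm = TRUE)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  sf <- edgeR::calcNormFactors(counts, method = "TMM")
  eff_lib <- lib * sf
  x <- sweep(counts, 2, eff_lib / 1e6, "/")
  if (!is.null(gene_lengths)) {
    stopifnot(length(gene_lengths) == nrow(counts), all(gene_lengths > 0))
    x <- x / (gene_lengths / 1e3)
  }
  list(logexpr = log2(x + 1), scale_factors = stats::setNames(sf, colnames(counts)))
}

#' Impute a single missing replicate
#'
#' The missing replicate of a gene x time point cell is imputed as the
#' median of the two remaining replicates (for two values the median equals
#' their mean). Cells with two or more missing replicates are not imputed;
#' their genes are reported as unusable.
#'
#' @param expr Gene x sample matrix with `NA` for missing replicates.
#' @param meta Sample metadata (`sample_id`, `accession`, `treatment`, `ZT`,
#'   `replicate`).
#' @return List with `expr` (imputed matrix), `imputed` (data.frame of
#'   gene/sample imputations) and `unusable` (data.frame gene x accession
#'   with >= 2 missing replicates somewhere).
#' @export
impute_missing_replicate <- function(expr, meta) {
  meta <- .match_meta(expr, meta)
  cell <- interaction(meta$accession, meta$treatment, meta$ZT, drop = TRUE)
  imputed <- list(); unusable <- list()
  for (cl in levels(cell)) {
    cols <- which(cell == cl)
    sub <- expr[, cols, drop = FALSE]
    n_miss <- rowSums(is.na(sub))
    one <- which(n_miss == 1)
    if (length(one)) {
      filled <- character(length(one))
      for (k in seq_along(one)) {
        g <- one[k]
        j <- cols[which(is.na(sub[g, ]))]
        expr[g, j] <- stats::median(sub[g, ], na.rm = TRUE)
        filled[k] <- meta$sample_id[j]
      }
      imputed[[length(imputed) + 1]] <- data.frame(
        gene = rownames(expr)[one], sample_id = filled, cell = cl)
    }
    many <- which(n_miss >= 2)
    if (length(many))
      unusable[[length(unusable) + 1]] <- data.frame(
        gene = rownames(expr)[many],
        accession = meta$accession[cols[1]], cell = cl)
  }
  list(expr = expr,
       imputed = if (length(imputed)) do.call(rbind, imputed) else NULL,
       unusable = if (length(unusable)) unique(do.call(rbind, unusable)) else NULL)
}

# Replicate-mean 4-point profile per gene for one accession x treatment.
.replicate_means <- function(expr, meta, accession, treatment) {
  zt <- sort(unique(meta$ZT))
  cols <- lapply(zt, function(z)
    which(meta$accession == accession & meta$treatment == treatment &
          meta$ZT == z))
  prof <- vapply(cols, function(j)
    rowMeans(expr[, j, drop = FALSE], na.rm = TRUE), numeric(nrow(expr)))
  prof <- matrix(prof, nrow = nrow(expr),
                 dimnames = list(rownames(expr), paste0("ZT", zt)))
  prof
}

.zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  out <- (m - mu) / ifelse(sd > 0, sd, 1)
  out[sd == 0, ] <- 0
  out
}

#' Build an eigengene basis from combined WW + WL profiles
#'
#' Pools the z-scored replicate-mean time-course profiles of both treatments
#' (across all accessions), clusters them by signed correlation with
#' average-linkage hierarchical clustering, and returns one sign-oriented
#' first-principal-component eigengene per cluster.
#'
#' @param expr Gene x sample matrix (imputation already applied).
#' @param meta Sample metadata.
#' @param cut_height Static tree-cut height on `1 - cor` dissimilarity.
#' @param min_cluster_size Clusters smaller than this are dropped from the
#'   basis (if none survive, the overall mean profile is the single
#'   eigengene).
#' @return Matrix with one column per eigengene, rows = time points.
#' @export
build_eigengene_basis <- function(expr, meta, cut_height = 0.5,
                                  min_cluster_size = 10) {
  meta <- .match_meta(expr, meta)
  profs <- list()
  for (acc in unique(meta$accession))
    for (trt in unique(meta$treatment))
      profs[[paste(acc, trt)]] <- .replicate_means(expr, meta, acc, trt)
  pm <- do.call(rbind, profs)
  pm <- pm[stats::complete.cases(pm) & apply(pm, 1, stats::sd) > 0, , drop = FALSE]
  z <- .zscore_rows(pm)
  if (nrow(z) < max(2, min_cluster_size)) {
    e <- colMeans(z)
    return(matrix(e / sqrt(sum(e^2) + 1e-12), ncol = 1,
                  dimnames = list(colnames(z), "E1")))
  }
  d <- stats::as.dist(1 - stats::cor(t(z)))
  cl <- stats::cutree(stats::hclust(d, method = "average"), h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_cluster_size]
  if (!length(keep)) keep <- names(sizes)[which.max(sizes)]
  eig <- sapply(keep, function(k) {
    sub <- z[cl == k, , drop = FALSE]
    if (nrow(sub) == 1) return(as.numeric(sub) / sqrt(sum(sub^2)))
    v <- svd(sub, nu = 0, nv = 1)$v[, 1]
    if (sum(v * colMeans(sub)) < 0) v <- -v
    v
  })
  eig <- as.matrix(eig)
  rownames(eig) <- colnames(z)
  colnames(eig) <- paste0("E", seq_len(ncol(eig)))
  eig
}

# Correlations of per-replicate sample vectors with an eigengene expanded
# to sample level; zero-variance vectors get correlation 0. Using the full
# replicate-level vectors (rather than replicate means) matters for the
# permutation null: correlations of replicate means are scale-invariant, so
# mixed-label pseudo-groups would retain a planted pattern change, while at
# replicate level a 2:1 mixed group dilutes the correlation to ~1/3.
.sample_cor <- function(expr, meta, accession, treatment, eigengenes) {
  cols <- which(meta$accession == accession & meta$treatment == treatment)
  ord <- cols[order(meta$ZT[cols], meta$replicate[cols])]
  m <- expr[, ord, drop = FALSE]
  e_exp <- eigengenes[paste0("ZT", meta$ZT[ord]), , drop = FALSE]
  keep <- !apply(is.na(m), 1, any)
  cc <- matrix(0, nrow(m), ncol(eigengenes),
               dimnames = list(rownames(m), colnames(eigengenes)))
  if (any(keep)) {
    sub <- m[keep, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    cvals <- suppressWarnings(stats::cor(t(sub), e_exp))
    cvals[sds == 0 | !is.finite(cvals)] <- 0
    cc[keep, ] <- cvals
  }
  cc
}

#' Pattern-change (kME) and median-change (Med) scores
#'
#' For each gene, `kME` is the summed absolute change, across eigengenes, in
#' the correlation of its replicate-level time-course vector with each
#' eigengene between treatments; it detects changes of temporal pattern
#' (phase) regardless of level. `Med` is the absolute difference of the
#' gene's median expression between treatments over all samples; it detects
#' level shifts regardless of pattern.
#'
#' @param expr Gene x sample matrix (imputed).
#' @param meta Sample metadata for one accession (or with `accession` given).
#' @param eigengenes Eigengene matrix from [build_eigengene_basis()].
#' @param accession Accession to score.
#' @return Data.frame: gene, kME, Med, flag for zero-variance profiles.
#' @export
pattern_change_scores <- function(expr, meta, eigengenes, accession) {
  meta <- .match_meta(expr, meta)
  cw <- .sample_cor(expr, meta, accession, "WW", eigengenes)
  cl <- .sample_cor(expr, meta, accession, "WL", eigengenes)
  kme <- rowSums(abs(cl - cw))
  ww_cols <- meta$accession == accession & meta$treatment == "WW"
  wl_cols <- meta$accession == accession & meta$treatment == "WL"
  med <- abs(apply(expr[, wl_cols, drop = FALSE], 1, stats::median, na.rm = TRUE) -
             apply(expr[, ww_cols, drop = FALSE], 1, stats::median, na.rm = TRUE))
  pw <- .replicate_means(expr, meta, accession, "WW")
  pl <- .replicate_means(expr, meta, accession, "WL")
  data.frame(gene = rownames(expr), kME = kme, Med = med,
             flat_profile = apply(pw, 1, stats::sd) == 0 |
               apply(pl, 1, stats::sd) == 0,
             row.names = NULL)
}

# Empirical FDR with monotone (q-value style) correction: for each observed
# score, FDR = (mean permutation exceedance count)/(observed exceedance
# count), then cumulative minimum from the most stringent threshold down.
.empirical_fdr <- function(obs, null_scores, n_perm) {
  ord <- order(obs, decreasing = TRUE)
  sorted <- obs[ord]
  null_sorted <- sort(null_scores)
  n_null_ge <- length(null_scores) - findInterval(sorted - 1e-12, null_sorted)
  fdr <- pmin((n_null_ge / n_perm) / seq_along(sorted), 1)
  q <- rev(cummin(rev(fdr)))  # q_i = min FDR over thresholds at or below s_i
  out <- numeric(length(obs))
  out[ord] <- q
  out
}

#' Permutation calls for kME and Med scores
#'
#' Builds a null by shuffling treatment labels of whole replicate time
#' courses within the accession, recomputing both scores per permutation,
#' and converting observed scores to empirical FDRs (pooled null, monotone
#' corrected). Genes are called at the most permissive threshold whose FDR
#' stays at or below the target.
#'
#' @param expr Gene x sample matrix (imputed).
#' @param meta Sample metadata.
#' @param eigengenes Eigengene basis.
#' @param accession Accession to test.
#' @param n_perm Number of label permutations (>= 1; >= 50 recommended).
#' @param fdr_target Empirical FDR target.
#' @param seed Integer seed (permutation set is reproducible).
#' @return Data.frame: gene, kME, Med, fdr_kME, fdr_Med, called_kME,
#'   called_Med.
#' @export
permutation_calls <- function(expr, meta, eigengenes, accession,
                              n_perm = 100, fdr_target = 0.05, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  meta <- .match_meta(expr, meta)
  obs <- pattern_change_scores(expr, meta, eigengenes, accession)
  # replicate series = (treatment, replicate); shuffle their treatment labels
  acc_rows <- meta$accession == accession
  series <- unique(meta[acc_rows, c("treatment", "replicate")])
  set.seed(seed)
  null_k <- matrix(NA_real_, nrow(expr), n_perm)
  null_m <- matrix(NA_real_, nrow(expr), n_perm)
  ww_set <- which(series$treatment == "WW")
  for (p in seq_len(n_perm)) {
    # resample until the induced treatment partition differs from the
    # original one (identity and full-swap relabelings reproduce the
    # observed scores and would contaminate the null)
    repeat {
      perm <- sample(nrow(series))
      new_ww <- sort(perm[ww_set])
      if (!identical(new_ww, sort(ww_set)) &&
          !identical(new_ww, sort(setdiff(seq_len(nrow(series)), ww_set))))
        break
    }
    meta_p <- meta
    for (i in seq_len(nrow(series))) {
      rows <- acc_rows & meta$treatment == series$treatment[i] &
        meta$replicate == series$replicate[i]
      meta_p$treatment[rows] <- series$treatment[perm[i]]
      meta_p$replicate[rows] <- series$replicate[perm[i]]
    }
    sc <- pattern_change_scores(expr, meta_p, eigengenes, accession)
    null_k[, p] <- sc$kME
    null_m[, p] <- sc$Med
  }
  fdr_k <- .empirical_fdr(obs$kME, as.vector(null_k), n_perm)
  fdr_m <- .empirical_fdr(obs$Med, as.vector(null_m), n_perm)
  data.frame(gene = obs$gene, kME = obs$kME, Med = obs$Med,
             fdr_kME = fdr_k, fdr_Med = fdr_m,
             called_kME = fdr_k <= fdr_target,
             called_Med = fdr_m <= fdr_target, row.names = NULL)
}

#' Pointwise single-time-point validation of pattern calls
#'
#' Welch two-sample t-test per gene x ZT between treatments,
#' Benjamini-Hochberg adjusted across genes within each ZT; a gene is
#' flagged if significant at any ZT. Reports the Jaccard overlap with a set
#' of permutation calls when given.
#'
#' @param expr Gene x sample matrix.
#' @param meta Sample metadata.
#' @param accession Accession to test.
#' @param alpha BH-adjusted significance level.
#' @param calls Optional logical vector (or gene names) of permutation calls
#'   to compare against.
#' @return List with `table` (gene, p per ZT, adjusted p, any_zt flag) and
#'   `jaccard` (or `NA` when `calls` is missing).
#' @export
validate_with_pointwise_tests <- function(expr, meta, accession, alpha = 0.05,
                                          calls = NULL) {
  meta <- .match_meta(expr, meta)
  zts <- sort(unique(meta$ZT))
  pmat <- sapply(zts, function(z) {
    ww <- expr[, meta$accession == accession & meta$treatment == "WW" &
                 meta$ZT == z, drop = FALSE]
    wl <- expr[, meta$accession == accession & meta$treatment == "WL" &
                 meta$ZT == z, drop = FALSE]
    if (ncol(ww) < 2 || ncol(wl) < 2) return(rep(NA_real_, nrow(expr)))
    vapply(seq_len(nrow(expr)), function(g) {
      x <- ww[g, ]; y <- wl[g, ]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2 ||
          (stats::var(x) == 0 && stats::var(y) == 0)) return(NA_real_)
      stats::t.test(x, y)$p.value
    }, 0)
  })
  colnames(pmat) <- paste0("p_ZT", zts)
  padj <- apply(pmat, 2, stats::p.adjust, method = "BH")
  any_zt <- apply(padj <= alpha, 1, any, na.rm = TRUE)
  jac <- NA_real_
  if (!is.null(calls)) {
    if (is.character(calls)) calls <- rownames(expr) %in% calls
    inter <- sum(any_zt & calls)
    uni <- sum(any_zt | calls)
    jac <- if (uni > 0) inter / uni else NA_real_
  }
  list(table = data.frame(gene = rownames(expr), pmat, padj_any = any_zt,
                          row.names = NULL),
       jaccard = jac)
}

#' Drop accessions with too few pattern-change calls
#'
#' Accessions whose kME call count falls below a threshold carry too little
#' signal to be informative and are removed from downstream analyses.
#'
#' @param call_counts Named integer vector: kME calls per accession.
#' @param min_kME_genes Minimum number of kME calls to retain an accession.
#' @return List with `retained` and `dropped` accession name vectors.
#' @export
drop_low_signal_accessions <- function(call_counts, min_kME_genes = 50) {
  stopifnot(!is.null(names(call_counts)))
  keep <- call_counts >= min_kME_genes
  list(retained = names(call_counts)[keep],
       dropped = names(call_counts)[!keep])
}
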