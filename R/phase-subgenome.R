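# Diel phase estimation, circular phase-change classification into five
# groups, and subgenome / homoeolog divergence summaries.

PHASE_GRID <- c(1, 7, 13, 19)

#' Estimate diel phase from a 4-point profile
#'
#' Phase is the ZT of the maximum replicate-mean expression; ties are broken
#' toward the earliest ZT. An all-equal profile has undefined phase (`NA`).
#'
#' @param profile Numeric vector of replicate means at ZT 1, 7, 13, 19 (in
#'   that order), or a gene x 4 matrix.
#' @return ZT of peak per profile (`NA` where undefined).
#' @export
estimate_phase <- function(profile) {
  if (is.matrix(profile)) {
    stopifnot(ncol(profile) == 4)
    return(apply(profile, 1, estimate_phase))
  }
  stopifnot(length(profile) == 4)
  if (anyNA(profile) || max(profile) == min(profile)) return(NA_real_)
  PHASE_GRID[which.max(profile)]
}

#' Classify a WW -> WL phase change into the five circular groups
#'
#' The difference `phase_WW - phase_WL` in hours is wrapped on the 24-h
#' circle (+18 -> -6, -18 -> +6), yielding the groups
#' `{-12, -6, 0, +6, +12}`. Positive values mean the WL peak is earlier in
#' the day; the two 12-h groups are distinguished by the sign of the
#' unwrapped difference. Set `flip_sign = TRUE` to report the opposite
#' convention (positive = WL delayed).
#'
#' @param phase_WW,phase_WL Phases in `{1, 7, 13, 19}` (vectorized).
#' @param flip_sign Flip the reported sign convention.
#' @return Integer group in `{-12, -6, 0, 6, 12}` (`NA` propagates).
#' @export
phase_change_group <- function(phase_WW, phase_WL, flip_sign = FALSE) {
  ok <- is.na(phase_WW) | phase_WW %in% PHASE_GRID
  ok2 <- is.na(phase_WL) | phase_WL %in% PHASE_GRID
  if (!all(ok) || !all(ok2)) stop("phases must lie on the ZT grid {1,7,13,19}")
  d <- phase_WW - phase_WL
  d <- ifelse(d == 18, -6, ifelse(d == -18, 6, d))
  if (flip_sign) d <- -d
  as.integer(d)
}

#' Phase table for called genes
#'
#' Convenience wrapper: replicate-mean profiles per treatment, phase per
#' treatment, and phase-change group for a set of genes in one accession.
#'
#' @param expr Gene x sample matrix (imputed).
#' @param meta Sample metadata.
#' @param accession Accession name.
#' @param genes Optional subset of genes (default: all rows).
#' @param flip_sign Passed to [phase_change_group()].
#' @return Data.frame: gene, phase_WW, phase_WL, group (NA rows for
#'   undefined phases are retained and flagged `excluded`).
#' @export
phase_table <- function(expr, meta, accession, genes = rownames(expr),
                        flip_sign = FALSE) {
  meta <- .match_meta(expr, meta)
  sub <- expr[genes, , drop = FALSE]
  pw <- estimate_phase(.replicate_means(sub, meta, accession, "WW"))
  pl <- estimate_phase(.replicate_means(sub, meta, accession, "WL"))
  grp <- ifelse(is.na(pw) | is.na(pl), NA_integer_,
                phase_change_group(pw, pl, flip_sign = flip_sign))
  data.frame(gene = genes, phase_WW = pw, phase_WL = pl, group = grp,
             excluded = is.na(pw) | is.na(pl), row.names = NULL)
}

#' Subgenome proportions of WL genes across phase-change groups
#'
#' For each accession (and optionally stratified by subgenome), the
#' proportion of called WL-responsive genes falling in each of the five
#' phase-change groups. Proportions sum to one within each stratum.
#'
#' @param phase_records Data.frame with columns `accession`, `gene`,
#'   `group` (typically stacked [phase_table()] results for called genes).
#' @param map Homoeolog map (`gene_id`, `subgenome`, `ortholog_group`).
#' @return List with `by_accession` and `by_subgenome` proportion tables and
#'   `unmapped` (genes absent from the map).
#' @export
subgenome_phase_proportions <- function(phase_records, map) {
  stopifnot(all(c("accession", "gene", "group") %in% names(phase_records)))
  rec <- phase_records[!is.na(phase_records$group), ]
  rec$subgenome <- map$subgenome[match(rec$gene, map$gene_id)]
  unmapped <- unique(rec$gene[is.na(rec$subgenome)])
  grp_levels <- c(-12, -6, 0, 6, 12)
  prop_tab <- function(d, by) {
    out <- do.call(rbind, lapply(split(d, d[by], drop = TRUE), function(s) {
      counts <- table(factor(s$group, levels = grp_levels))
      cbind(s[1, by, drop = FALSE],
            as.data.frame.matrix(t(counts / sum(counts))))
    }))
    rownames(out) <- NULL
    out
  }
  list(by_accession = prop_tab(rec, "accession"),
       by_subgenome = prop_tab(rec[!is.na(rec$subgenome), ],
                               c("accession", "subgenome")),
       unmapped = unmapped)
}

#' Subgenome expression-bias summary
#'
#' Per accession: mean and log-sum of expression by subgenome, the BnC - BnA
#' mean difference, and a gene-bootstrap percentile interval for it.
#'
#' @param expr Gene x sample matrix of log2 expression.
#' @param meta Sample metadata.
#' @param map Homoeolog map.
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return Data.frame: accession, mean_BnA, mean_BnC, logsum_BnA,
#'   logsum_BnC, diff (BnC - BnA), ci_lo, ci_hi.
#' @export
subgenome_expression_bias <- function(expr, meta, map, n_boot = 200,
                                      seed = 1) {
  meta <- .match_meta(expr, meta)
  sg <- map$subgenome[match(rownames(expr), map$gene_id)]
  if (!any(sg == "BnA", na.rm = TRUE) || !any(sg == "BnC", na.rm = TRUE))
    stop("a subgenome has no genes in the expression matrix")
  set.seed(seed)
  out <- lapply(unique(meta$accession), function(acc) {
    cols <- meta$accession == acc
    gm <- rowMeans(expr[, cols, drop = FALSE], na.rm = TRUE)
    a <- gm[which(sg == "BnA")]; c_ <- gm[which(sg == "BnC")]
    boots <- replicate(n_boot,
      mean(sample(c_, replace = TRUE)) - mean(sample(a, replace = TRUE)))
    data.frame(accession = acc, mean_BnA = mean(a), mean_BnC = mean(c_),
               logsum_BnA = log2(sum(2^a)), logsum_BnC = log2(sum(2^c_)),
               diff = mean(c_) - mean(a),
               ci_lo = stats::quantile(boots, 0.025),
               ci_hi = stats::quantile(boots, 0.975), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Gene- and ortholog-level sharing of WL calls across accessions
#'
#' For each gene, the number of accessions in which it was called; for each
#' ortholog group, the size of the union of its member genes' accession
#' sets. Returns histograms and proportions at both levels.
#'
#' @param call_sets Named list: accession -> character vector of called
#'   genes (>= 2 accessions).
#' @param map Homoeolog map.
#' @return List with `gene` and `ortholog` data.frames
#'   (`n_accessions`, `count`, `proportion`) and the per-gene /
#'   per-ortholog accession counts.
#' @export
gene_sharing_distribution <- function(call_sets, map) {
  stopifnot(length(call_sets) >= 2, !is.null(names(call_sets)))
  genes <- unique(unlist(call_sets))
  gene_n <- vapply(genes, function(g)
    sum(vapply(call_sets, function(s) g %in% s, TRUE)), 0L)
  og <- map$ortholog_group[match(genes, map$gene_id)]
  og_sets <- lapply(split(genes[!is.na(og)], og[!is.na(og)]), function(members) {
    accs <- names(call_sets)[vapply(call_sets, function(s)
      any(members %in% s), TRUE)]
    accs
  })
  og_n <- vapply(og_sets, length, 0L)
  hist_tab <- function(n) {
    tab <- table(factor(n, levels = seq_len(length(call_sets))))
    data.frame(n_accessions = as.integer(names(tab)),
               count = as.integer(tab),
               proportion = as.integer(tab) / max(sum(tab), 1))
  }
  list(gene = hist_tab(gene_n), ortholog = hist_tab(og_n),
       gene_counts = gene_n, ortholog_counts = og_n,
       ortholog_accession_sets = og_sets)
}

#' Responsive-homoeolog profile of an ortholog group
#'
#' For one ortholog group, tabulates per accession how many member copies
#' are WL-responsive and on which subgenome they reside.
#'
#' @param ortholog_group Ortholog group id.
#' @param call_sets Named list: accession -> called genes.
#' @param map Homoeolog map covering the group.
#' @return Data.frame: accession, n_responsive, n_BnA, n_BnC, members
#'   (comma-joined responsive gene ids).
#' @export
responsive_homoeolog_profile <- function(ortholog_group, call_sets, map) {
  members <- map[map$ortholog_group == ortholog_group, ]
  if (!nrow(members)) stop("unknown ortholog group: ", ortholog_group)
  out <- lapply(names(call_sets), function(acc) {
    resp <- members[members$gene_id %in% call_sets[[acc]], ]
    data.frame(accession = acc, n_responsive = nrow(resp),
               n_BnA = sum(resp$subgenome == "BnA"),
               n_BnC = sum(resp$subgenome == "BnC"),
               members = paste(resp$gene_id, collapse = ","))
  })
  do.call(rbind, out)
}
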