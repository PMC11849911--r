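# Global response-score co-expression modules: per-gene WL - WW response
# scores concatenated across accessions, a signed weighted network on their
# correlations, average-linkage clustering with a static cut, eigengene
# summaries, and splitting of modules with opposing accession responses.

#' Compute per-gene response scores
#'
#' `score(gene, accession, ZT) = replicate-mean log2 WL - replicate-mean
#' log2 WW`. Accessions missing a treatment are excluded and reported.
#'
#' @param expr Gene x sample matrix (imputed).
#' @param meta Sample metadata.
#' @param accessions Accessions to include (default: all in `meta`).
#' @return List with `scores` (gene x (accession x ZT) matrix, columns named
#'   `<accession>_ZT<zt>`), `accessions`, and `excluded`.
#' @export
compute_response_scores <- function(expr, meta,
                                    accessions = unique(meta$accession)) {
  meta <- .match_meta(expr, meta)
  keep <- character(); excluded <- character()
  blocks <- list()
  for (acc in accessions) {
    trts <- unique(meta$treatment[meta$accession == acc])
    if (!all(c("WW", "WL") %in% trts)) { excluded <- c(excluded, acc); next }
    keep <- c(keep, acc)
    d <- .replicate_means(expr, meta, acc, "WL") -
      .replicate_means(expr, meta, acc, "WW")
    colnames(d) <- paste0(acc, "_", colnames(d))
    blocks[[acc]] <- d
  }
  if (!length(blocks)) stop("no accession has both treatments")
  list(scores = do.call(cbind, blocks), accessions = keep,
       excluded = excluded)
}

#' Signed co-expression network on response scores
#'
#' Genes are z-scored across their concatenated accession x ZT vectors;
#' signed adjacency `a_ij = ((1 + cor_ij)/2)^beta` and dissimilarity
#' `1 - a_ij`. Zero-variance genes are removed before correlation.
#'
#' @param scores Gene x (accession x ZT) response-score matrix.
#' @param beta Soft-threshold power.
#' @return List with `dissimilarity` (symmetric matrix, zero diagonal),
#'   `adjacency`, and `removed` (zero-variance genes).
#' @export
build_network <- function(scores, beta = 6) {
  stopifnot(is.matrix(scores), beta > 0)
  sds <- apply(scores, 1, stats::sd)
  removed <- rownames(scores)[is.na(sds) | sds == 0]
  z <- .zscore_rows(scores[!(rownames(scores) %in% removed), , drop = FALSE])
  cc <- stats::cor(t(z))
  adj <- ((1 + cc) / 2)^beta
  diss <- 1 - adj
  diag(diss) <- 0
  list(dissimilarity = diss, adjacency = adj, removed = removed)
}

#' Detect response modules
#'
#' Average-linkage hierarchical clustering of the network dissimilarity with
#' a static cut; clusters below the minimum size fall into the null module
#' `"M0"`. Module eigengenes are computed and modules whose eigengenes
#' correlate at or above `merge_threshold` are merged. Modules are labelled
#' `M1, M2, ...` by decreasing size.
#'
#' @param scores Gene x (accession x ZT) response-score matrix.
#' @param beta Soft power for [build_network()].
#' @param cut_height Static tree-cut height on the dissimilarity dendrogram.
#' @param min_module_size Minimum genes per module.
#' @param merge_threshold Eigengene correlation at which modules merge.
#' @return Object of class `"response_modules"`: list with `assignment`
#'   (named module label per gene, `"M0"` = unassigned), `modules` (list of
#'   gene sets), `eigengenes` (list of accession x ZT matrices), `scores`.
#' @export
detect_modules <- function(scores, beta = 6, cut_height = 0.6,
                           min_module_size = 30, merge_threshold = 0.75) {
  net <- build_network(scores, beta = beta)
  d <- net$dissimilarity
  genes <- rownames(d)
  if (length(genes) < min_module_size) {
    assignment <- stats::setNames(rep("M1", length(genes)), genes)
  } else if (all(d == 0)) {
    assignment <- stats::setNames(rep("M1", length(genes)), genes)
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cl <- stats::cutree(hc, h = cut_height)
    sizes <- table(cl)
    good <- names(sizes)[sizes >= min_module_size]
    assignment <- stats::setNames(
      ifelse(cl %in% as.integer(good), paste0("C", cl), "M0"), genes)
    # merge modules with highly correlated eigengenes
    repeat {
      mods <- setdiff(unique(assignment), "M0")
      if (length(mods) < 2) break
      eigs <- sapply(mods, function(m) as.vector(
        .module_eigengene_vec(scores[names(assignment)[assignment == m], ,
                                     drop = FALSE])))
      ec <- stats::cor(eigs)
      ec[lower.tri(ec, diag = TRUE)] <- NA
      hit <- which(ec >= merge_threshold, arr.ind = TRUE)
      if (!nrow(hit)) break
      a <- mods[hit[1, 1]]; b <- mods[hit[1, 2]]
      assignment[assignment == b] <- a
    }
  }
  mods <- setdiff(unique(assignment), "M0")
  ord <- order(-vapply(mods, function(m) sum(assignment == m), 0L))
  relabel <- stats::setNames(paste0("M", seq_along(mods)), mods[ord])
  assignment[assignment != "M0"] <- relabel[assignment[assignment != "M0"]]
  mods <- sort(unique(assignment[assignment != "M0"]))
  module_sets <- lapply(stats::setNames(mods, mods), function(m)
    names(assignment)[assignment == m])
  eigs <- lapply(module_sets, function(g)
    module_eigengene(scores[g, , drop = FALSE]))
  structure(list(assignment = assignment, modules = module_sets,
                 eigengenes = eigs, scores = scores,
                 params = list(beta = beta, cut_height = cut_height,
                               min_module_size = min_module_size,
                               merge_threshold = merge_threshold)),
            class = "response_modules")
}

#' @export
print.response_modules <- function(x, ...) {
  cat("Response-score co-expression modules\n")
  n0 <- sum(x$assignment == "M0")
  for (m in names(x$modules))
    cat(sprintf("  %s: %d genes\n", m, length(x$modules[[m]])))
  cat(sprintf("  unassigned (M0): %d genes\n", n0))
  invisible(x)
}

# First principal component (loadings over columns) of the z-scored module
# submatrix, sign-oriented toward the module mean profile.
.module_eigengene_vec <- function(sub) {
  z <- .zscore_rows(sub)
  if (nrow(z) == 1) return(as.numeric(z))
  v <- svd(z, nu = 0, nv = 1)$v[, 1]
  if (sum(v * colMeans(z)) < 0) v <- -v
  v * sqrt(ncol(z))  # scale comparable to z-scored profiles
}

#' Module eigengene as an accession x ZT profile
#'
#' First principal component of the z-scored gene x (accession x ZT)
#' submatrix, sign-oriented so that its correlation with the module's mean
#' profile is non-negative, reshaped to accession x ZT.
#'
#' @param sub Response-score submatrix restricted to one module (columns
#'   named `<accession>_ZT<zt>`).
#' @return Matrix accession x ZT with attributes `explained_variance` and
#'   `opposing` (TRUE when the mean profile is negligible relative to the
#'   eigengene, indicating sign-opposed gene groups).
#' @export
module_eigengene <- function(sub) {
  stopifnot(is.matrix(sub), nrow(sub) >= 1)
  z <- .zscore_rows(sub)
  if (nrow(z) == 1) {
    v <- as.numeric(z); expl <- 1
  } else {
    sv <- svd(z, nu = 0, nv = 1)
    v <- sv$v[, 1]
    expl <- sv$d[1]^2 / sum(sv$d^2)
    if (sum(v * colMeans(z)) < 0) v <- -v
  }
  parts <- strsplit(colnames(sub), "_ZT")
  acc <- vapply(parts, `[`, "", 1)
  zt <- as.numeric(vapply(parts, `[`, "", 2))
  out <- matrix(v, nrow = length(unique(acc)), byrow = TRUE,
                dimnames = list(unique(acc),
                                paste0("ZT", zt[seq_len(sum(acc == acc[1]))])))
  attr(out, "explained_variance") <- expl
  attr(out, "opposing") <- sqrt(mean(colMeans(z)^2)) < 0.1 * sqrt(mean(v^2))
  out
}

#' Split modules with opposing accession responses
#'
#' If any pair of per-accession mean response profiles within a module is
#' strongly anticorrelated, accessions are partitioned by the sign of the
#' projection of their mean profile onto the leading principal shape of the
#' per-accession profiles, and one sub-module per sign is emitted (same
#' gene set, accession annotation split).
#'
#' @param sub Response-score submatrix of one module.
#' @param opposing_threshold Anticorrelation magnitude that triggers a split.
#' @return List of sub-modules, each with `accessions`, `sign`, `genes`; a
#'   single element (sign `"+"`) when no split is needed.
#' @export
split_opposing_modules <- function(sub, opposing_threshold = 0.75) {
  parts <- strsplit(colnames(sub), "_ZT")
  acc <- vapply(parts, `[`, "", 1)
  accs <- unique(acc)
  z <- .zscore_rows(sub)
  # per-accession mean profile over genes
  prof <- t(vapply(accs, function(a)
    colMeans(z[, acc == a, drop = FALSE]), numeric(sum(acc == accs[1]))))
  genes <- rownames(sub)
  if (length(accs) >= 2) {
    pc <- stats::cor(t(prof))
    pc[!is.finite(pc)] <- 0
    trigger <- any(pc[upper.tri(pc)] < -opposing_threshold)
  } else trigger <- FALSE
  if (!trigger)
    return(list(list(accessions = accs, sign = "+", genes = genes)))
  # common 4-point reference shape: leading principal component of the
  # accession mean profiles (each accession's own eigengene segment tracks
  # its own sign, so projecting onto it cannot separate the groups)
  ref <- svd(prof, nu = 0, nv = 1)$v[, 1]
  if (sum(ref * colMeans(prof)) < 0 && any(colMeans(prof) != 0)) ref <- -ref
  proj <- drop(prof %*% ref)
  pos <- accs[proj >= 0]; neg <- accs[proj < 0]
  out <- list()
  if (length(pos)) out <- c(out, list(list(accessions = pos, sign = "+",
                                           genes = genes)))
  if (length(neg)) out <- c(out, list(list(accessions = neg, sign = "-",
                                           genes = genes)))
  out
}
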