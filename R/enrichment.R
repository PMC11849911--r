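# Over-representation analysis of gene sets against term annotations, with
# ortholog mapping and broad-descriptor rollups.

#' Map genes to Arabidopsis orthologs
#'
#' @param genes Character vector of gene ids.
#' @param map Homoeolog map with `gene_id` and `arabidopsis_ortholog`
#'   columns (non-empty).
#' @return List with `orthologs` (de-duplicated ortholog ids) and
#'   `unmapped` (genes absent from the map or without an ortholog).
#' @export
map_to_orthologs <- function(genes, map) {
  if (is.null(map) || !nrow(map)) stop("empty ortholog map")
  hit <- map$arabidopsis_ortholog[match(genes, map$gene_id)]
  list(orthologs = unique(hit[!is.na(hit) & hit != ""]),
       unmapped = genes[is.na(hit) | hit == ""])
}

#' Hypergeometric term enrichment
#'
#' One-sided hypergeometric upper-tail p-value per term (equivalent to a
#' one-sided Fisher exact test on the 2x2 table), Benjamini-Hochberg
#' adjusted across terms within the analysis. Terms with no annotated gene
#' in the background are skipped and reported.
#'
#' @param study Character vector of study genes (must be a subset of
#'   `background`).
#' @param background Character vector of background genes.
#' @param annotations Data.frame with columns `term` and `gene`.
#' @param descriptors Optional data.frame with columns `term` and
#'   `descriptor`.
#' @return List with `results` (term, study_count, background_count,
#'   p_value, p_adjusted, descriptor) and `skipped` terms.
#' @export
hypergeometric_enrichment <- function(study, background, annotations,
                                      descriptors = NULL) {
  stopifnot(all(study %in% background))
  study <- unique(study); background <- unique(background)
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  skipped <- setdiff(unique(annotations$term), unique(ann$term))
  if (!nrow(ann))
    return(list(results = data.frame(), skipped = skipped))
  by_term <- split(unique(ann[c("term", "gene")])$gene,
                   unique(ann[c("term", "gene")])$term)
  n_bg <- length(background); n_st <- length(study)
  rows <- lapply(names(by_term), function(tm) {
    k_bg <- length(by_term[[tm]])
    k_st <- sum(study %in% by_term[[tm]])
    p <- stats::phyper(k_st - 1, k_bg, n_bg - k_bg, n_st, lower.tail = FALSE)
    data.frame(term = tm, study_count = k_st, background_count = k_bg,
               p_value = p)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res$descriptor <- if (!is.null(descriptors))
    descriptors$descriptor[match(res$term, descriptors$term)] else NA_character_
  res$descriptor[is.na(res$descriptor)] <- "unassigned"
  list(results = res[order(res$p_value), ], skipped = skipped)
}

#' Roll enrichment results up to broad descriptors
#'
#' Groups term-level results under their broad descriptor (a coarse parent
#' label), reporting member terms and the best p-value per descriptor, and
#' an optional presence matrix across analyses.
#'
#' @param results Data.frame of enrichment results, or a named list of them
#'   (one per analysis, e.g. accession x module) each as returned in
#'   `$results` by [hypergeometric_enrichment()].
#' @param alpha Adjusted-p threshold defining "significant" presence.
#' @return List with `table` (descriptor, n_terms, best_p per analysis) and
#'   `presence` (descriptor x analysis logical matrix).
#' @export
rollup_broad_descriptors <- function(results, alpha = 0.05) {
  if (is.data.frame(results)) results <- list(analysis = results)
  stopifnot(length(results) >= 1, !is.null(names(results)))
  descs <- sort(unique(unlist(lapply(results, `[[`, "descriptor"))))
  tab <- do.call(rbind, lapply(names(results), function(an) {
    r <- results[[an]]
    do.call(rbind, lapply(split(r, r$descriptor), function(s)
      data.frame(analysis = an, descriptor = s$descriptor[1],
                 n_terms = nrow(s), best_p = min(s$p_adjusted),
                 terms = paste(s$term, collapse = ";"))))
  }))
  rownames(tab) <- NULL
  presence <- sapply(names(results), function(an) {
    r <- results[[an]]
    sig <- r$descriptor[r$p_adjusted <= alpha]
    descs %in% sig
  })
  presence <- matrix(presence, nrow = length(descs),
                     dimnames = list(descs, names(results)))
  list(table = tab, presence = presence)
}
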