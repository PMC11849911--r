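# Readers/writers for the plain-text formats the pipeline consumes and
# emits, plus the end-to-end synthetic pipeline driver.

#' Read an expression matrix with sample metadata
#'
#' @param path TSV with gene ids in the first column and one column per
#'   sample.
#' @param meta_path TSV with columns `sample_id`, `accession`, `treatment`,
#'   `ZT`, `replicate` covering every sample column.
#' @param zt_grid Allowed ZT values.
#' @return List with `expr` (matrix, `NA` marks missing replicates), `meta`
#'   and `mask` (data.frame of gene x sample missing entries).
#' @export
read_expression <- function(path, meta_path, zt_grid = c(1, 7, 13, 19)) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (anyDuplicated(tab[[1]]))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
  expr <- as.matrix(tab[, -1, drop = FALSE])
  rownames(expr) <- tab[[1]]
  meta <- utils::read.delim(meta_path)
  req <- c("sample_id", "accession", "treatment", "ZT", "replicate")
  if (!all(req %in% names(meta)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  extra <- setdiff(colnames(expr), meta$sample_id)
  if (length(extra))
    stop("samples in matrix but not metadata: ", paste(extra, collapse = ", "))
  off <- setdiff(unique(meta$ZT), zt_grid)
  if (length(off))
    stop("off-grid ZT values in metadata: ", paste(off, collapse = ", "))
  meta <- meta[match(colnames(expr), meta$sample_id), ]
  miss <- which(is.na(expr), arr.ind = TRUE)
  mask <- if (nrow(miss))
    data.frame(gene = rownames(expr)[miss[, 1]],
               sample_id = colnames(expr)[miss[, 2]]) else
    data.frame(gene = character(), sample_id = character())
  list(expr = expr, meta = meta, mask = mask)
}

#' Write an expression matrix as TSV
#'
#' @param expr Gene x sample matrix.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(data.frame(gene_id = rownames(expr), expr,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a growth trait table
#'
#' @param path CSV with header `plant_id, accession, treatment, day,
#'   area_cm2`; `day` must be non-negative numeric.
#' @return Validated data.frame.
#' @export
read_growth <- function(path) {
  d <- utils::read.csv(path)
  req <- c("plant_id", "accession", "treatment", "day", "area_cm2")
  if (!all(req %in% names(d)))
    stop("growth table must have columns: ", paste(req, collapse = ", "))
  if (!is.numeric(d$day) || any(d$day < 0, na.rm = TRUE))
    stop("day must be non-negative numeric")
  d
}

#' Read a homoeolog map
#'
#' @param path TSV with columns `gene_id`, `subgenome`, `ortholog_group`
#'   and optionally `arabidopsis_ortholog`.
#' @return Validated data.frame.
#' @export
read_homoeolog_map <- function(path) {
  m <- utils::read.delim(path)
  req <- c("gene_id", "subgenome", "ortholog_group")
  if (!all(req %in% names(m)))
    stop("homoeolog map must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(m$gene_id)) stop("duplicate gene ids in homoeolog map")
  bad <- setdiff(unique(m$subgenome), c("BnA", "BnC"))
  if (length(bad)) stop("unknown subgenome label(s): ",
                        paste(bad, collapse = ", "))
  m
}

#' Default pipeline configuration
#'
#' All tunable parameters of the synthetic end-to-end pipeline with their
#' defaults; any element can be overridden via `...`.
#'
#' @param ... Named overrides.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(seed = 1,
              expr_design = list(),       # overrides for expression_sim_design()
              growth_design = list(),     # overrides for growth_sim_design()
              metab_design = list(),      # overrides for metab_sim_design()
              n_perm = 100, fdr_target = 0.05, min_kME_genes = 50,
              beta = 6, cut_height = 0.6, min_module_size = 30,
              merge_threshold = 0.75,
              chains = 2, warmup = 1000, draws = 1000,
              background = 5e3)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end synthetic pipeline
#'
#' Generates growth, expression and metabolite data from the configured
#' designs, then runs preprocessing, differential-pattern calls, phase and
#' subgenome summaries, response-score modules, and metabolite
#' normalization/censoring/statistics, writing every stage's tables plus a
#' JSON run manifest under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  message("[simulate] generating synthetic datasets (seed ", seed, ")")
  edesign <- do.call(expression_sim_design,
                     c(config$expr_design,
                       list(seed = seed)[!("seed" %in% names(config$expr_design))]))
  gdesign <- do.call(growth_sim_design,
                     c(config$growth_design,
                       list(seed = seed + 1)[!("seed" %in% names(config$growth_design))]))
  mdesign <- do.call(metab_sim_design,
                     c(config$metab_design,
                       list(seed = seed + 2)[!("seed" %in% names(config$metab_design))]))
  esim <- gen_expression_data(edesign)
  gsim <- gen_growth_data(gdesign)
  msim <- gen_metabolite_data(mdesign)
  write_expression(esim$expr, file.path(out_dir, "expression.tsv"))
  utils::write.table(esim$meta, file.path(out_dir, "expression_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(esim$map, file.path(out_dir, "homoeolog_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(gsim$data, file.path(out_dir, "growth.csv"),
                   row.names = FALSE)
  utils::write.csv(msim$data, file.path(out_dir, "metabolites.csv"),
                   row.names = FALSE)

  message("[preprocess] filtering and imputing expression")
  imp <- impute_missing_replicate(esim$expr, esim$meta)
  filt <- filter_genes(imp$expr, esim$meta)
  expr <- filt$expr

  message("[dipattern] eigengene basis and permutation calls")
  eig <- build_eigengene_basis(expr, esim$meta)
  accs <- unique(esim$meta$accession)
  calls <- list()
  for (i in seq_along(accs))
    calls[[accs[i]]] <- permutation_calls(expr, esim$meta, eig, accs[i],
                                          n_perm = config$n_perm,
                                          fdr_target = config$fdr_target,
                                          seed = seed + 10 + i)
  call_tab <- do.call(rbind, lapply(names(calls), function(a)
    cbind(accession = a, calls[[a]])))
  utils::write.table(call_tab, file.path(out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  kme_counts <- vapply(calls, function(x) sum(x$called_kME), 0L)
  retained <- drop_low_signal_accessions(kme_counts, config$min_kME_genes)

  message("[phase] phase tables and subgenome summaries")
  call_sets <- lapply(calls, function(x)
    x$gene[x$called_kME | x$called_Med])
  phases <- do.call(rbind, lapply(accs, function(a) {
    g <- call_sets[[a]]
    if (!length(g)) return(NULL)
    cbind(accession = a, phase_table(expr, esim$meta, a, genes = g))
  }))
  if (!is.null(phases))
    utils::write.table(phases, file.path(out_dir, "phase.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  props <- if (!is.null(phases))
    subgenome_phase_proportions(phases, esim$map) else NULL
  if (!is.null(props))
    utils::write.table(props$by_accession,
                       file.path(out_dir, "phase_proportions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  sharing <- if (sum(lengths(call_sets) > 0) >= 2)
    gene_sharing_distribution(call_sets[lengths(call_sets) > 0], esim$map) else NULL
  if (!is.null(sharing))
    utils::write.table(cbind(level = "gene", sharing$gene),
                       file.path(out_dir, "sharing_gene.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  bias <- subgenome_expression_bias(expr, esim$meta, esim$map,
                                    seed = seed + 20)
  utils::write.table(bias, file.path(out_dir, "subgenome_bias.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  message("[modules] response-score co-expression modules")
  rs <- compute_response_scores(expr, esim$meta)
  mods <- detect_modules(rs$scores, beta = config$beta,
                         cut_height = config$cut_height,
                         min_module_size = config$min_module_size,
                         merge_threshold = config$merge_threshold)
  utils::write.table(data.frame(gene = names(mods$assignment),
                                module = mods$assignment),
                     file.path(out_dir, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  message("[growth-fit] Bayesian Gompertz growth model")
  gfit <- fit_growth_model(gsim$data, chains = config$chains,
                           warmup = config$warmup, draws = config$draws,
                           seed = seed + 30)
  gsum <- summary(gfit)
  utils::write.table(gsum, file.path(out_dir, "growth_parameters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hyp <- do.call(rbind, lapply(c("asymptote_50", "inflection_5", "rate_5"),
                               function(h) {
    r <- test_hypothesis(gfit, gdesign$accession, h)
    data.frame(hypothesis = h, probability = r$probability,
               effect_size = r$effect_size, supported = r$supported)
  }))
  utils::write.table(hyp, file.path(out_dir, "growth_hypotheses.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  message("[metab] censoring, normalization, statistics")
  lim <- limit_spec(config$background)
  norm <- normalize_region(msim$data)
  cen <- censor(norm$data, lim)
  utils::write.csv(cen, file.path(out_dir, "metabolites_normalized.csv"),
                   row.names = FALSE)
  stats_tab <- do.call(rbind, lapply(split(cen, cen$feature), function(fd) {
    st <- diel_treatment_stats(fd)
    data.frame(feature = fd$feature[1], p_zt = st$anova[["p_zt"]],
               p_interaction = st$anova[["p_interaction"]],
               n_censored = st$n_censored, partial = st$partial)
  }))
  utils::write.table(stats_tab, file.path(out_dir, "metabolite_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(package = "dielWL",
                   version = as.character(utils::packageVersion("dielWL")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = seed,
                   config = unclass(config)[!vapply(config, is.list, TRUE)],
                   retained_accessions = retained$retained,
                   dropped_accessions = retained$dropped,
                   n_genes_after_filter = nrow(expr),
                   n_modules = length(mods$modules))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(expression = esim, growth = gsim, metab = msim,
                 calls = calls, retained = retained, phases = phases,
                 proportions = props, sharing = sharing, bias = bias,
                 modules = mods, growth_fit = gfit, hypotheses = hyp,
                 metab_stats = stats_tab, manifest = manifest))
}
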