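# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk.

ZT4 <- c(1, 7, 13, 19)

# Expression matrix for one accession, two treatments, 3 replicates, with
# per-gene WW phases and optional WL phase shifts (hours, positive = WL
# peak earlier) and WL level offsets.
make_cosinor_experiment <- function(phases, shifts = rep(0, length(phases)),
                                    offsets = rep(0, length(phases)),
                                    amplitude = 1, baseline = 4,
                                    noise_sd = 0, accession = "Acc1",
                                    seed = 1) {
  set.seed(seed)
  n <- length(phases)
  meta <- expand.grid(replicate = 1:3, ZT = ZT4, treatment = c("WW", "WL"),
                      stringsAsFactors = FALSE)
  meta$accession <- accession
  meta$sample_id <- with(meta, sprintf("%s_%s_ZT%d_r%d",
                                       accession, treatment, ZT, replicate))
  expr <- matrix(NA_real_, n, nrow(meta),
                 dimnames = list(sprintf("g%03d", seq_len(n)), meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    ph <- if (meta$treatment[j] == "WL") (phases - shifts) %% 24 else phases
    off <- if (meta$treatment[j] == "WL") offsets else 0
    mu <- baseline + off + amplitude * cos(2 * pi * (meta$ZT[j] - ph) / 24)
    expr[, j] <- mu + stats::rnorm(n, 0, noise_sd)
  }
  list(expr = expr, meta = meta[, c("sample_id", "accession", "treatment",
                                    "ZT", "replicate")])
}

# A single-cosine eigengene basis at a given peak time.
cosine_eigengene <- function(phase = 1) {
  e <- cos(2 * pi * (ZT4 - phase) / 24)
  matrix(e / sqrt(sum(e^2)), ncol = 1,
         dimnames = list(paste0("ZT", ZT4), "E1"))
}

# Tiny homoeolog map: n_og ortholog groups x one BnA + one BnC copy.
make_map <- function(n_og = 4) {
  do.call(rbind, lapply(seq_len(n_og), function(i)
    data.frame(gene_id = sprintf(c("BnA_OG%02d", "BnC_OG%02d"), i),
               subgenome = c("BnA", "BnC"),
               ortholog_group = sprintf("OG%02d", i),
               arabidopsis_ortholog = sprintf("AT%02d", i))))
}
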