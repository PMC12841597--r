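# In-memory fixture builders shared across test files. Everything is
# generated in code under fixed seeds; nothing is read from disk except
# files the tests themselves write to tempdir().

toy_gene_matrix <- function(values, samples) {
  panepiclock:::new_gene_matrix(values, samples)
}

make_samples <- function(n, layer = "H3K4me3", dataset = "ds1",
                         species = "human", tissue = "liver",
                         ages = NULL, donor_prefix = "d") {
  data.frame(
    sample_id = sprintf("%s%03d_%s_%s", donor_prefix, seq_len(n), tissue, layer),
    donor_id = sprintf("%s%03d", donor_prefix, seq_len(n)),
    species = species, tissue = tissue, layer = layer, dataset = dataset,
    age_years = ages %||% seq(10, 70, length.out = n),
    diet = "standard", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small featurized cohort, simulated once and cached for the session.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, cfg) {
  if (is.null(.cohort_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("cohort_", key))
    out <- simulate_cohort(cfg, dir)
    gm <- featurize_cohort(out$sample_sheet, out$paths$annotations,
                           out$paths$orthologs)
    .cohort_cache[[key]] <- list(out = out, gm = gm, cfg = cfg)
  }
  .cohort_cache[[key]]
}

# Brute-force O(n*m) all-pairs overlap aggregation oracle.
brute_force_chip <- function(peaks, genes) {
  vals <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  for (i in seq_len(nrow(genes))) {
    scores <- c()
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] == genes$chrom[i] &&
          peaks$start[j] < genes$end[i] && peaks$end[j] > genes$start[i]) {
        scores <- c(scores, peaks$score[j])
      }
    }
    vals[i] <- if (length(scores) > 0) mean(scores) else 0
  }
  vals
}

brute_force_meth <- function(cpgs, genes) {
  vals <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  for (i in seq_len(nrow(genes))) {
    fr <- c()
    for (j in seq_len(nrow(cpgs))) {
      if (cpgs$chrom[j] == genes$chrom[i] &&
          cpgs$pos[j] >= genes$start[i] && cpgs$pos[j] < genes$end[i]) {
        fr <- c(fr, cpgs$meth_fraction[j])
      }
    }
    vals[i] <- if (length(fr) > 0) mean(fr) else 0
  }
  vals
}

# Exact two-sided Mann-Whitney U p-value by enumeration of all
# choose(m+n, m) group assignments of the pooled values.
mwu_enumerate <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), m)
  mu <- m * length(y) / 2
  hits <- 0
  for (c_i in seq_len(ncol(combos))) {
    idx <- combos[, c_i]
    u <- u_stat(pooled[idx], pooled[-idx])
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-9) hits <- hits + 1
  }
  hits / ncol(combos)
}
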