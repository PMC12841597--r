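#' Per-gene Spearman age associations for one species x layer stratum
#'
#' For every gene, Spearman's rho between the gene's harmonized signal and
#' donor chronological age across the stratum's samples (average ranks for
#' ties); two-sided p from the Student-t model
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df; q = BH within
#' the stratum. Constant gene columns have undefined rho and are recorded
#' as rho = 0, p = 1 with `flagged = TRUE`.
#'
#' @param gm harmonized GeneMatrix.
#' @param species,layer stratum selectors (NULL = no filter on that field).
#' @return an `AssocTable` data.frame: gene_id, rho, n, p, q, flagged,
#'   with attributes `species`/`layer`.
#' @export
age_association <- function(gm, species = NULL, layer = NULL) {
  keep <- rep(TRUE, nrow(gm$samples))
  if (!is.null(species)) keep <- keep & gm$samples$species == species
  if (!is.null(layer)) keep <- keep & gm$samples$layer == layer
  abort_if(sum(keep) < 4, "need >= 4 samples in the stratum")
  X <- gm$values[keep, , drop = FALSE]
  age <- gm$samples$age_years[keep]
  n <- nrow(X)
  rho <- spearman_vec(X, age)
  flagged <- is.na(rho)
  p <- spearman_p(rho, n)
  rho[flagged] <- 0
  p[flagged] <- 1
  tab <- data.frame(gene_id = colnames(X), rho = rho, n = n, p = p,
                    q = p.adjust(p, method = "BH"), flagged = flagged,
                    row.names = NULL)
  attr(tab, "species") <- species
  attr(tab, "layer") <- layer
  class(tab) <- c("AssocTable", "data.frame")
  tab
}

## Two-sided Mann-Whitney U p-value: exact (via wilcox.test) for small
## tie-free groups, normal approximation with continuity correction
## otherwise.
mwu_p <- function(x, y) {
  suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
}

shared_genes <- function(tableA, tableB) {
  g <- intersect(tableA$gene_id, tableB$gene_id)
  abort_if(length(g) == 0, "no shared genes between association tables")
  g
}

#' Correlation between two age-association profiles
#'
#' Spearman correlation of per-gene rho vectors over the shared gene
#' universe of two strata, with the Student-t p-value model.
#'
#' @param tableA,tableB `AssocTable`s.
#' @return list(rho, p, n_genes).
#' @export
assoc_vector_correlation <- function(tableA, tableB) {
  g <- shared_genes(tableA, tableB)
  a <- tableA$rho[match(g, tableA$gene_id)]
  b <- tableB$rho[match(g, tableB$gene_id)]
  rho <- suppressWarnings(cor(a, b, method = "spearman"))
  list(rho = rho, p = spearman_p(rho, length(g)), n_genes = length(g))
}

## Gene ids of the k strongest entries of `score` (descending), ties at
## the k-th rank broken by ascending gene id for reproducibility.
top_k_genes <- function(gene_id, score, k) {
  o <- order(-score, gene_id)
  gene_id[o[seq_len(k)]]
}

#' Top-k overlap enrichment between two age-association rankings
#'
#' Genes are ranked by unsigned |rho| in each table; the overlap of the
#' two top-k sets is compared with the expectation `k^2 / G` for two
#' independent k-sets from a universe of G shared genes. Fold enrichment =
#' observed / expected; significance from a two-sided exact binomial with
#' success probability `k / G` over k trials (set `null = "hypergeometric"`
#' for the exact sampling-without-replacement null); Bonferroni over
#' `n_comparisons` tested pairs.
#'
#' @param tableA,tableB `AssocTable`s.
#' @param k top-set size (default 1000).
#' @param n_comparisons Bonferroni family size.
#' @param null binomial (default) or hypergeometric overlap null.
#' @return an `EnrichmentResult` list: k_top, G, observed, expected, fold,
#'   p, p_bonf.
#' @export
top_k_overlap_enrichment <- function(tableA, tableB, k = 1000,
                                     n_comparisons = 1,
                                     null = c("binomial", "hypergeometric")) {
  null <- match.arg(null)
  g <- shared_genes(tableA, tableB)
  G <- length(g)
  abort_if(G <= k, "shared gene universe must exceed k")
  topA <- top_k_genes(g, abs(tableA$rho[match(g, tableA$gene_id)]), k)
  topB <- top_k_genes(g, abs(tableB$rho[match(g, tableB$gene_id)]), k)
  observed <- length(intersect(topA, topB))
  expected <- k^2 / G
  p <- if (null == "binomial") {
    binom.test(observed, k, p = k / G, alternative = "two.sided")$p.value
  } else {
    dens <- stats::dhyper(0:k, k, G - k, k)
    sum(dens[dens <= dens[observed + 1] * (1 + 1e-7)])
  }
  structure(list(k_top = k, G = G, observed = observed, expected = expected,
                 fold = observed / expected, p = p,
                 p_bonf = min(p * n_comparisons, 1)),
            class = "EnrichmentResult")
}

#' Cross-species concordance of age-associated genes
#'
#' Identical contract to [top_k_overlap_enrichment()], applied to the same
#' layer's human and mouse association tables (shared human-ortholog gene
#' universe).
#'
#' @inheritParams top_k_overlap_enrichment
#' @param human_table,mouse_table per-species `AssocTable`s for one layer.
#' @export
cross_species_overlap <- function(human_table, mouse_table, k = 1000,
                                  n_comparisons = 1) {
  top_k_overlap_enrichment(human_table, mouse_table, k = k,
                           n_comparisons = n_comparisons)
}

#' Cross-layer crosstalk statistic
#'
#' Takes layer A's k most positively and k most negatively age-associated
#' genes (signed rho), extracts layer B's rho over each set, and reports
#' the median difference (increasing minus decreasing) with a two-sided
#' Mann-Whitney U p-value, Bonferroni-corrected over `family` layer pairs
#' (21 for 7 layers).
#'
#' @param tableA,tableB `AssocTable`s for layers A and B.
#' @param k set size (default 1000).
#' @param family Bonferroni family size (default `choose(7, 2)`).
#' @return a `CrosstalkResult` list: median_diff, p, p_bonf, family, k.
#' @export
crosstalk <- function(tableA, tableB, k = 1000, family = choose(7, 2)) {
  g <- shared_genes(tableA, tableB)
  rhoA <- tableA$rho[match(g, tableA$gene_id)]
  rhoB <- tableB$rho[match(g, tableB$gene_id)]
  abort_if(length(g) < 2 * k, "need >= 2k shared genes")
  inc <- top_k_genes(g, rhoA, k)
  dec <- top_k_genes(g, -rhoA, k)
  b_inc <- rhoB[match(inc, g)]
  b_dec <- rhoB[match(dec, g)]
  p <- mwu_p(b_inc, b_dec)
  structure(list(median_diff = median(b_inc) - median(b_dec), p = p,
                 p_bonf = min(p * family, 1), family = family, k = k),
            class = "CrosstalkResult")
}

#' Number of Bonferroni comparisons for all-pairs crosstalk
#'
#' @param n_layers number of epigenetic layers.
#' @return `choose(n_layers, 2)` unordered layer pairs.
#' @export
crosstalk_family_size <- function(n_layers = 7) {
  choose(n_layers, 2)
}

#' Fraction of genes significantly age-associated in a stratum
#'
#' @param table an `AssocTable`.
#' @param q_threshold BH FDR threshold (default 0.05).
#' @return fraction of genes with q < threshold.
#' @export
significant_fraction <- function(table, q_threshold = 0.05) {
  mean(table$q < q_threshold)
}

#' Genes age-associated in every layer at several FDR levels
#'
#' @param tables list of `AssocTable`s (one per layer).
#' @param fdr_levels FDR thresholds.
#' @return data.frame (fdr, n_genes) counting genes with q < fdr in every
#'   table; counts are non-decreasing in the FDR level.
#' @export
all_layer_intersection <- function(tables, fdr_levels = c(0.05, 0.1, 0.2)) {
  g <- Reduce(intersect, lapply(tables, `[[`, "gene_id"))
  counts <- vapply(fdr_levels, function(level) {
    hit <- rep(TRUE, length(g))
    for (tab in tables) hit <- hit & tab$q[match(g, tab$gene_id)] < level
    sum(hit)
  }, numeric(1))
  data.frame(fdr = fdr_levels, n_genes = counts)
}

#' Direction-consistent age-regulated gene sets
#'
#' "Repressed with age" = genes in the top-k most positively
#' age-associated set of every repressive mark (H3K27me3, H3K9me3, DNAm)
#' and the top-k most negatively age-associated set of every activating
#' mark (H3K27ac, H3K36me3, H3K4me1, H3K4me3), intersected within each
#' species then across species. "Activated" is the converse. Marks absent
#' from `tables` are skipped.
#'
#' @param tables named list of `AssocTable`s with names `"species|layer"`.
#' @param k per-mark top-set size.
#' @return list(repressed, activated) of gene-id vectors.
#' @export
select_direction_genesets <- function(tables, k = 1000) {
  key <- do.call(rbind, strsplit(names(tables), "|", fixed = TRUE))
  species <- key[, 1]; layer <- key[, 2]
  directional_set <- function(sign_for_repressive) {
    per_species <- lapply(unique(species), function(sp) {
      sets <- lapply(which(species == sp), function(i) {
        tab <- tables[[i]]
        s <- if (layer[i] %in% REPRESSIVE_MARKS) sign_for_repressive else
          -sign_for_repressive
        top_k_genes(tab$gene_id, s * tab$rho, min(k, nrow(tab)))
      })
      Reduce(intersect, sets)
    })
    Reduce(intersect, per_species)
  }
  list(repressed = directional_set(1), activated = directional_set(-1))
}

#' Read a GMT gene-set library
#'
#' @param path GMT file (term, description, genes..., tab-separated).
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[`, character(1), 1))
}

#' Local gene-set over-representation test
#'
#' One-sided Fisher exact (hypergeometric) test of a query gene set
#' against each library term within a stated universe, BH-corrected across
#' terms. Terms overlapping the query in fewer than two genes, or with
#' BH-adjusted p >= `q_max`, are excluded from the result.
#'
#' @param geneset character vector of query gene ids.
#' @param library named list of term gene sets (see [read_gmt()]).
#' @param universe character vector of testable gene ids.
#' @param q_max BH threshold for reporting (default 0.05).
#' @return data.frame (term, overlap, term_size, p, q) sorted by p.
#' @export
geneset_enrichment <- function(geneset, library, universe, q_max = 0.05) {
  geneset <- intersect(geneset, universe)
  empty <- data.frame(term = character(), overlap = integer(),
                      term_size = integer(), p = numeric(), q = numeric())
  if (length(geneset) == 0 || length(library) == 0) return(empty)
  res <- do.call(rbind, lapply(names(library), function(term) {
    t_genes <- intersect(library[[term]], universe)
    ov <- length(intersect(geneset, t_genes))
    p <- phyper(ov - 1, length(t_genes), length(universe) - length(t_genes),
                length(geneset), lower.tail = FALSE)
    data.frame(term = term, overlap = ov, term_size = length(t_genes), p = p)
  }))
  res$q <- p.adjust(res$p, method = "BH")
  res <- res[res$overlap >= 2 & res$q < q_max, , drop = FALSE]
  res[order(res$p, res$term), , drop = FALSE]
}
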