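#' Min-max normalization per \{dataset x layer\} stratum
#'
#' `minmax_fit()` records the global minimum and maximum of all values in
#' each stratum; `minmax_apply()` maps `x -> (x - min) / (max - min)`,
#' clipping applied values into \[0,1\]. A constant stratum (max == min)
#' maps to 0. Scope is global over the stratum, not per gene: per-gene
#' location/scale is handled by the inverse normal transform that follows.
#'
#' @param gm a GeneMatrix (strata are `dataset x layer` of its samples).
#' @return `minmax_fit`: a `MinMaxParams` data.frame (stratum, min, max);
#'   `minmax_apply`: the GeneMatrix with transformed values.
#' @export
minmax_fit <- function(gm) {
  strata <- strata_of(gm$samples)
  out <- lapply(unique(strata), function(s) {
    v <- gm$values[strata == s, , drop = FALSE]
    rng <- range(v, na.rm = TRUE)
    data.frame(stratum = s, min = rng[1], max = rng[2])
  })
  structure(do.call(rbind, out), class = c("MinMaxParams", "data.frame"))
}

#' @rdname minmax_fit
#' @param params a `MinMaxParams` from [minmax_fit()].
#' @export
minmax_apply <- function(params, gm) {
  strata <- strata_of(gm$samples)
  abort_if(!all(strata %in% params$stratum),
           paste0("unfitted stratum: ",
                  paste(setdiff(strata, params$stratum), collapse = ", ")))
  vals <- gm$values
  for (s in unique(strata)) {
    i <- strata == s
    p <- params[params$stratum == s, ]
    if (p$max > p$min) {
      vals[i, ] <- pmin(pmax((vals[i, , drop = FALSE] - p$min) /
                               (p$max - p$min), 0), 1)
    } else {
      block <- vals[i, , drop = FALSE]
      block[!is.na(block)] <- 0
      vals[i, ] <- block
    }
  }
  new_gene_matrix(vals, gm$samples)
}

#' Mean imputation of missing DNA methylation values
#'
#' Fits per-\{dataset x layer\} per-gene training means over DNAm rows;
#' applying substitutes the *training* mean for missing test values.
#' Missingness in non-DNAm rows is an error (histone aggregation yields
#' explicit zeros, never missing).
#'
#' @param gm GeneMatrix to fit on (training rows).
#' @param layer layer whose missing values are imputable.
#' @return `impute_fit`: an `ImputeParams` list; `impute_apply`: GeneMatrix
#'   without missing values.
#' @export
impute_fit <- function(gm, layer = "DNAm") {
  strata <- strata_of(gm$samples)
  rows <- gm$samples$layer == layer
  means <- lapply(unique(strata[rows]), function(s) {
    block <- gm$values[strata == s, , drop = FALSE]
    m <- colMeans(block, na.rm = TRUE)
    abort_if(any(is.nan(m) & apply(block, 2, function(x) any(is.na(x)))),
             "all-missing gene column in an imputation stratum")
    m
  })
  structure(list(layer = layer,
                 means = stats::setNames(means, unique(strata[rows]))),
            class = "ImputeParams")
}

#' @rdname impute_fit
#' @param params `ImputeParams` from [impute_fit()].
#' @export
impute_apply <- function(params, gm) {
  strata <- strata_of(gm$samples)
  vals <- gm$values
  miss_rows <- which(rowSums(is.na(vals)) > 0)
  for (i in miss_rows) {
    abort_if(gm$samples$layer[i] != params$layer,
             paste0("missing values in non-", params$layer, " sample ",
                    gm$samples$sample_id[i]))
    mu <- params$means[[strata[i]]]
    abort_if(is.null(mu), paste0("unfitted imputation stratum ", strata[i]))
    j <- is.na(vals[i, ])
    vals[i, j] <- mu[colnames(vals)[j]]
  }
  new_gene_matrix(vals, gm$samples)
}

#' Per-dataset per-gene inverse normal transform (INT)
#'
#' Fit rows (training): each gene's values within a dataset are ranked
#' across samples (average ranks for ties), converted to percentiles
#' `r / (n + 1)`, and mapped through the standard normal quantile. The
#' fitted parameter is the per-gene table of sorted training values.
#'
#' Apply rows (held-out data): a value is mapped to a percentile by linear
#' interpolation of the training empirical CDF, clipped to
#' `[1/(n+1), n/(n+1)]`, then through the normal quantile — so test data
#' never alter the fitted transform.
#'
#' @param gm GeneMatrix (training rows) to fit on.
#' @return `int_fit`: an `INTParams` list of per-dataset sorted-value
#'   matrices; `int_apply`: GeneMatrix of z-scores.
#' @export
int_fit <- function(gm) {
  ds <- gm$samples$dataset
  tabs <- lapply(unique(ds), function(d) {
    block <- gm$values[ds == d, , drop = FALSE]
    abort_if(nrow(block) < 2, paste0("dataset ", d, " has < 2 samples"))
    abort_if(anyNA(block), "missing values at INT fit time; impute first")
    apply(block, 2L, sort)
  })
  structure(list(tables = stats::setNames(tabs, unique(ds))),
            class = "INTParams")
}

## Percentile of x under the training ECDF given sorted training values v,
## by linear interpolation between the knots (v_i, i/(n+1)), clipped to
## [1/(n+1), n/(n+1)]. Ties in v collapse to their average percentile, so
## training values reproduce the average-rank fit-transform exactly.
int_percentile <- function(x, v) {
  n <- length(v)
  p <- seq_len(n) / (n + 1)
  if (anyDuplicated(v)) {
    agg <- tapply(p, v, mean)
    vv <- as.numeric(names(agg)); pp <- as.numeric(agg)
  } else {
    vv <- v; pp <- p
  }
  if (length(vv) == 1L) {
    y <- rep(0.5, length(x))
  } else {
    y <- approx(vv, pp, xout = x, rule = 2)$y
  }
  # values strictly outside the training range take the boundary percentile
  y[x < vv[1]] <- 1 / (n + 1)
  y[x > vv[length(vv)]] <- n / (n + 1)
  pmin(pmax(y, 1 / (n + 1)), n / (n + 1))
}

#' @rdname int_fit
#' @param params `INTParams` from [int_fit()].
#' @export
int_apply <- function(params, gm) {
  ds <- gm$samples$dataset
  vals <- gm$values
  for (d in unique(ds)) {
    tab <- params$tables[[d]]
    abort_if(is.null(tab), paste0("unfitted dataset at INT apply time: ", d))
    missing_genes <- setdiff(colnames(vals), colnames(tab))
    abort_if(length(missing_genes) > 0,
             paste0("gene absent from INT parameters: ", missing_genes[1]))
    rows <- which(ds == d)
    for (g in colnames(vals)) {
      vals[rows, g] <- qnorm(int_percentile(vals[rows, g], tab[, g]))
    }
  }
  new_gene_matrix(vals, gm$samples)
}

#' One-shot fit-and-apply harmonization
#'
#' Convenience for whole-cohort analyses (age associations, enrichment):
#' min-max per \{dataset x layer\}, mean imputation of missing DNAm
#' values, then per-dataset per-gene INT, all fitted on the full matrix.
#' Clock training instead fits imputation/INT inside each CV fold; see
#' [train_clock()].
#'
#' @param gm GeneMatrix of raw gene-level values.
#' @return harmonized GeneMatrix.
#' @export
harmonize_matrix <- function(gm) {
  gm <- minmax_apply(minmax_fit(gm), gm)
  if (anyNA(gm$values)) gm <- impute_apply(impute_fit(gm), gm)
  int_apply(int_fit(gm), gm)
}

#' Combine per-stratum matrices, keeping fully observed genes
#'
#' Row-concatenates a list of GeneMatrix objects (typically one per
#' \{dataset x layer\}) restricted to the genes present (non-missing) in
#' every sample of every matrix.
#'
#' @param matrices list of GeneMatrix.
#' @return combined GeneMatrix; warns and returns zero genes if the
#'   intersection is empty.
#' @export
combine_layers <- function(matrices) {
  stopifnot(length(matrices) > 0)
  complete_genes <- function(gm) {
    g <- gm$genes[colSums(is.na(gm$values)) == 0]
    g
  }
  genes <- Reduce(intersect, lapply(matrices, complete_genes))
  if (length(genes) == 0) {
    warning("no gene is observed in every sample; combined matrix is empty")
  }
  vals <- do.call(rbind, lapply(matrices, function(gm) {
    gm$values[, genes, drop = FALSE]
  }))
  samples <- do.call(rbind, lapply(matrices, `[[`, "samples"))
  new_gene_matrix(vals, samples)
}
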