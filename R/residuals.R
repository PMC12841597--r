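#' Per-donor per-layer age-prediction residuals
#'
#' Residual = predicted minus actual age in years, averaged over a donor's
#' tissues within each layer; positive residuals mean the epigenome looks
#' older than the calendar age. With `adjusted = TRUE` an age-adjusted
#' variant is added per layer: the residual of a linear fit of the
#' residuals on the rank of actual age, so cross-layer correlations of
#' `residual_adj` are partial correlations controlling for chronological
#' age.
#'
#' @param records `PredictionRecord` data.frame from [predict_age()].
#' @param adjusted also compute the age-adjusted residual.
#' @return a `ResidualTable` data.frame: donor_id, layer, species, diet,
#'   actual_years, residual_years, and residual_adj when requested.
#' @export
compute_residuals <- function(records, adjusted = TRUE) {
  records$residual <- records$predicted_years - records$actual_years
  agg <- stats::aggregate(residual ~ donor_id + layer + species + diet +
                            actual_years, data = records, FUN = mean)
  names(agg)[names(agg) == "residual"] <- "residual_years"
  abort_if(anyDuplicated(agg[, c("donor_id", "layer")]) > 0,
           "multiple rows per donor x layer after aggregation")
  if (adjusted) {
    agg$residual_adj <- NA_real_
    for (l in unique(agg$layer)) {
      i <- agg$layer == l
      agg$residual_adj[i] <- resid(lm(residual_years ~ rank(actual_years),
                                      data = agg[i, ]))
    }
  }
  class(agg) <- c("ResidualTable", "data.frame")
  agg
}

#' Cross-layer synchronization of aging rates
#'
#' Pairwise Spearman correlation of per-donor residuals between layers,
#' over the donors shared by each pair, with Student-t p-values. Uses the
#' age-adjusted residuals by default so each cell is a partial correlation
#' controlling for chronological age.
#'
#' @param table `ResidualTable`.
#' @param adjusted use `residual_adj` (default) or raw `residual_years`.
#' @param min_shared minimum shared donors per pair (default 10).
#' @return a `SyncMatrix` list: rho (symmetric, unit diagonal), p, n.
#' @export
layer_sync <- function(table, adjusted = TRUE, min_shared = 10) {
  col <- if (adjusted && "residual_adj" %in% names(table)) "residual_adj"
  else "residual_years"
  layers <- sort(unique(table$layer))
  k <- length(layers)
  rho <- diag(1, k); p <- matrix(NA_real_, k, k); n <- matrix(0L, k, k)
  dimnames(rho) <- dimnames(p) <- dimnames(n) <- list(layers, layers)
  wide <- lapply(layers, function(l) {
    r <- table[table$layer == l, ]
    stats::setNames(r[[col]], r$donor_id)
  })
  names(wide) <- layers
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    shared <- intersect(names(wide[[i]]), names(wide[[j]]))
    abort_if(length(shared) < min_shared,
             paste0("layers ", layers[i], "/", layers[j], " share < ",
                    min_shared, " donors"))
    r <- suppressWarnings(cor(wide[[i]][shared], wide[[j]][shared],
                              method = "spearman"))
    rho[i, j] <- rho[j, i] <- r
    p[i, j] <- p[j, i] <- spearman_p(r, length(shared))
    n[i, j] <- n[j, i] <- length(shared)
  }
  structure(list(rho = rho, p = p, n = n), class = "SyncMatrix")
}

#' Binned residual-vs-residual curve
#'
#' Donors are grouped by their layer-X residual rounded to the nearest
#' integer year (bin = center plus/minus 1 year half-width); for each bin
#' the mean and standard error of the layer-Y residual are reported. Bins
#' with fewer than two donors are dropped.
#'
#' @param table `ResidualTable`.
#' @param layerX,layerY the binning and the averaged layer.
#' @return data.frame: center, mean_y, se, n.
#' @export
binned_residual_curve <- function(table, layerX, layerY) {
  x <- table[table$layer == layerX, ]
  y <- table[table$layer == layerY, ]
  shared <- intersect(x$donor_id, y$donor_id)
  rx <- x$residual_years[match(shared, x$donor_id)]
  ry <- y$residual_years[match(shared, y$donor_id)]
  center <- round(rx)
  out <- lapply(sort(unique(center)), function(cc) {
    v <- ry[center == cc]
    if (length(v) < 2) return(NULL)
    data.frame(center = cc, mean_y = mean(v), se = sd(v) / sqrt(length(v)),
               n = length(v))
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Caloric-restriction effect on age-prediction residuals
#'
#' Compares residuals between diet groups (standard vs caloric
#' restriction) with a two-sided Mann-Whitney U test. `layers` selects a
#' single layer (e.g., DNAm) or a pooled histone group; mouse residuals
#' are reported in months (x 12).
#'
#' @param table `ResidualTable` (typically mouse donors).
#' @param layers layer name(s); multiple names are pooled by averaging a
#'   donor's residuals over the named layers.
#' @param species species whose donors are compared (default mouse).
#' @return list: median_by_diet (months for mice), p, n_by_diet, unit.
#' @export
cr_comparison <- function(table, layers = "DNAm", species = "mouse") {
  r <- table[table$species == species & table$layer %in% layers, ]
  abort_if(nrow(r) == 0, "no residuals for the requested layers/species")
  agg <- stats::aggregate(residual_years ~ donor_id + diet, data = r,
                          FUN = mean)
  unit_mult <- if (species == "mouse") 12 else 1
  agg$residual <- agg$residual_years * unit_mult
  groups <- split(agg$residual, agg$diet)
  abort_if(!all(c("standard", "CR") %in% names(groups)),
           "need both standard and CR donors")
  list(median_by_diet = vapply(groups, median, numeric(1)),
       p = mwu_p(groups[["CR"]], groups[["standard"]]),
       n_by_diet = vapply(groups, length, numeric(1)),
       unit = if (unit_mult == 12) "months" else "years")
}
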