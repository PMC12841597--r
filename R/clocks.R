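DEFAULT_TISSUE_EXCLUSIONS <- c("prostate", "breast", "ovary", "testis",
                               "uterus", "placenta", "cell_line")

#' Clock configuration
#'
#' Freezes the training contract of the age clocks: a gradient-boosted
#' decision-tree ensemble with squared-error loss, 100 boosting rounds,
#' maximum tree depth 6 and learning rate 0.3 (the library defaults of
#' the reference gradient-boosting implementation, restated as explicit
#' values), 10-fold donor-grouped age-quintile-balanced cross-validation,
#' and fold-wise feature selection keeping genes whose Spearman
#' age-association exceeds |rho| > 0.2 in both species with consistent
#' sign.
#'
#' @param mode `"pan"` (one model over all layers) or `"single-layer"`.
#' @param layers layers entering training.
#' @param n_folds CV folds (10).
#' @param nrounds,max_depth,eta boosting rounds, tree depth, learning rate.
#' @param feature_rho_threshold per-species |rho| cutoff for features.
#' @param seed RNG seed for fold construction and the learner.
#' @return a `ClockConfig` list.
#' @export
clock_config <- function(mode = c("pan", "single-layer"),
                         layers = CLOCK_LAYERS, n_folds = 10,
                         nrounds = 100, max_depth = 6, eta = 0.3,
                         feature_rho_threshold = 0.2, seed = 0L) {
  mode <- match.arg(mode)
  abort_if(length(layers) == 0, "layers must be non-empty")
  abort_if(feature_rho_threshold < 0, "feature threshold must be >= 0")
  structure(list(mode = mode, layers = layers, n_folds = as.integer(n_folds),
                 nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth), eta = eta,
                 feature_rho_threshold = feature_rho_threshold,
                 seed = as.integer(seed)),
            class = "ClockConfig")
}

#' Filter a cohort matrix down to the clock dataset
#'
#' Drops profiles from excluded tissues (cell lines, sex-specific tissues,
#' placenta by default), tissues represented by fewer than `min_libraries`
#' profiles, and the sparse marks H3K36me3/H3K9me3; calorically restricted
#' samples are split off into a withheld matrix that is never used for
#' fitting but can be predicted afterwards.
#'
#' @param gm GeneMatrix of raw or min-max normalized values.
#' @param min_libraries minimum profiles per retained tissue (default 50).
#' @param excluded_tissues tissue names always dropped.
#' @param excluded_layers marks dropped from clock work.
#' @return list(training = GeneMatrix, withheld_cr = GeneMatrix or NULL).
#' @export
filter_clock_dataset <- function(gm, min_libraries = 50,
                                 excluded_tissues = DEFAULT_TISSUE_EXCLUSIONS,
                                 excluded_layers = c("H3K36me3", "H3K9me3")) {
  keep <- !(gm$samples$tissue %in% excluded_tissues) &
    !(gm$samples$layer %in% excluded_layers)
  counts <- table(gm$samples$tissue[keep])
  small <- names(counts)[counts < min_libraries]
  keep <- keep & !(gm$samples$tissue %in% small)
  cr <- keep & gm$samples$diet == "CR"
  list(training = gm[keep & !cr, ],
       withheld_cr = if (any(cr)) gm[cr, ] else NULL)
}

#' Donor-grouped, age-quintile-balanced fold assignment
#'
#' Donors are binned into quintiles of lifespan-scaled age; within each
#' quintile donors are ordered by profile count (descending, seeded
#' shuffle for ties) and assigned greedily to the fold currently holding
#' the fewest profiles. All profiles of a donor share one fold.
#'
#' @param samples sample-sheet data.frame of the training matrix.
#' @param n_folds number of folds.
#' @param seed tie-shuffling seed.
#' @return named integer vector donor_id -> fold in 1..n_folds.
#' @export
make_folds <- function(samples, n_folds = 10, seed = 0L) {
  donors <- unique(samples[, c("donor_id", "species", "age_years")])
  abort_if(nrow(donors) < n_folds, "fewer donors than folds")
  donors$scaled <- scale_age(donors$age_years, donors$species)
  qs <- quantile(donors$scaled, probs = seq(0, 1, 0.2), type = 7)
  donors$quintile <- cut(donors$scaled, breaks = unique(qs),
                         include.lowest = TRUE, labels = FALSE)
  profiles <- table(samples$donor_id)
  donors$n_profiles <- as.integer(profiles[donors$donor_id])
  fold_of <- integer(0)
  load <- numeric(n_folds)
  with_seed(seed, {
    for (qt in sort(unique(donors$quintile))) {
      dd <- donors[donors$quintile == qt, ]
      dd <- dd[sample.int(nrow(dd)), ]          # seeded tie shuffle
      dd <- dd[order(-dd$n_profiles), ]
      for (i in seq_len(nrow(dd))) {
        f <- which.min(load)
        load[f] <- load[f] + dd$n_profiles[i]
        fold_of[dd$donor_id[i]] <- f
      }
    }
  })
  fold_of
}

#' Cross-species consistent feature selection
#'
#' Per gene, Spearman rho against chronological age is computed separately
#' over the human and mouse training profiles (layers pooled as given);
#' genes pass when |rho| exceeds the threshold in both species with equal
#' sign. With a single-species matrix the threshold applies to that
#' species alone (with a warning).
#'
#' @param gm harmonized training GeneMatrix.
#' @param rho_threshold per-species |rho| cutoff.
#' @return character vector of selected gene ids.
#' @export
select_features <- function(gm, rho_threshold = 0.2) {
  species <- unique(gm$samples$species)
  rhos <- lapply(species, function(sp) {
    rows <- gm$samples$species == sp
    spearman_vec(gm$values[rows, , drop = FALSE],
                 gm$samples$age_years[rows])
  })
  if (length(species) == 1) {
    warning("single-species training data; feature threshold applied to ",
            species, " only")
    keep <- !is.na(rhos[[1]]) & abs(rhos[[1]]) > rho_threshold
  } else {
    a <- rhos[[1]]; b <- rhos[[2]]
    keep <- !is.na(a) & !is.na(b) & abs(a) > rho_threshold &
      abs(b) > rho_threshold & sign(a) == sign(b)
  }
  gm$genes[keep]
}

fit_booster <- function(X, y, config) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  params <- list(objective = "reg:squarederror",
                 max_depth = config$max_depth, eta = config$eta,
                 nthread = 1, seed = config$seed)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = config$nrounds, verbose = 0)
}

## Fold-local harmonization + feature selection + booster fit.
fit_fold <- function(train_gm, config) {
  imp <- if (anyNA(train_gm$values)) impute_fit(train_gm) else NULL
  if (!is.null(imp)) train_gm <- impute_apply(imp, train_gm)
  int <- int_fit(train_gm)
  train_gm <- int_apply(int, train_gm)
  features <- select_features(train_gm, config$feature_rho_threshold)
  abort_if(length(features) == 0,
           "no feature passed selection; reduce feature_rho_threshold")
  y <- scale_age(train_gm$samples$age_years, train_gm$samples$species)
  booster <- fit_booster(train_gm$values[, features, drop = FALSE], y, config)
  structure(list(booster = booster, features = features, impute = imp,
                 int = int, config = config),
            class = "ClockModel")
}

#' Train per-fold clock models
#'
#' The input matrix must already be min-max normalized per
#' \{dataset x layer\} stratum; imputation and the inverse normal
#' transform are fitted inside each fold on its training rows only, then
#' applied to held-out rows at prediction time, so no held-out information
#' reaches the fitted transforms. Each fold's model is a `ClockModel`
#' bundling the booster, its selected features, and its harmonization
#' parameters. The regression target is lifespan-scaled age.
#'
#' @param gm min-max normalized training GeneMatrix (clock-filtered).
#' @param config a `ClockConfig`.
#' @param folds donor -> fold map from [make_folds()]; built from `gm` if
#'   NULL.
#' @return list of `ClockModel`, one per fold, with the fold map attached
#'   as attribute `folds`.
#' @export
train_clock <- function(gm, config = clock_config(), folds = NULL) {
  gm <- gm[gm$samples$layer %in% config$layers, ]
  if (is.null(folds)) folds <- make_folds(gm$samples, config$n_folds,
                                          config$seed)
  models <- lapply(sort(unique(folds)), function(f) {
    train_rows <- folds[gm$samples$donor_id] != f
    fit_fold(gm[train_rows, ], config)
  })
  attr(models, "folds") <- folds
  models
}

apply_model_transform <- function(model, gm) {
  if (anyNA(gm$values)) {
    abort_if(is.null(model$impute), "missing values but no fitted imputation")
    gm <- impute_apply(model$impute, gm)
  }
  int_apply(model$int, gm)
}

predict_with_model <- function(model, gm) {
  h <- apply_model_transform(model, gm)
  stats::predict(model$booster,
                 xgboost::xgb.DMatrix(
                   h$values[, model$features, drop = FALSE], nthread = 1))
}

#' Held-out age prediction
#'
#' Every sample whose donor has a fold is predicted by the model of the
#' fold holding that donor out; samples of donors absent from the fold map
#' (e.g., withheld calorically restricted mice) are predicted by every
#' fold's model and averaged. Predicted scaled ages are mapped back to
#' years with the inverse lifespan transform.
#'
#' @param models list of `ClockModel` from [train_clock()] (fold map in
#'   attribute `folds`, or pass `folds`).
#' @param gm min-max normalized GeneMatrix of samples to predict.
#' @param folds optional donor -> fold map override.
#' @return `PredictionRecord` data.frame: sample_id, donor_id, species,
#'   tissue, layer, fold, predicted_scaled, predicted_years, actual_years,
#'   diet.
#' @export
predict_age <- function(models, gm, folds = NULL) {
  folds <- folds %||% attr(models, "folds")
  fold_ids <- sort(unique(folds))
  fold_of <- folds[gm$samples$donor_id]
  pred <- rep(NA_real_, nrow(gm$samples))

  for (f in fold_ids) {
    rows <- which(!is.na(fold_of) & fold_of == f)
    if (length(rows) > 0) {
      pred[rows] <- predict_with_model(models[[match(f, fold_ids)]], gm[rows, ])
    }
  }
  ensemble_rows <- which(is.na(fold_of))
  if (length(ensemble_rows) > 0) {
    block <- gm[ensemble_rows, ]
    per_fold <- vapply(models, predict_with_model, numeric(length(ensemble_rows)),
                       gm = block)
    pred[ensemble_rows] <- rowMeans(matrix(per_fold,
                                           nrow = length(ensemble_rows)))
  }
  data.frame(
    sample_id = gm$samples$sample_id, donor_id = gm$samples$donor_id,
    species = gm$samples$species, tissue = gm$samples$tissue,
    layer = gm$samples$layer, fold = unname(fold_of),
    predicted_scaled = pred,
    predicted_years = unscale_age(pred, gm$samples$species),
    actual_years = gm$samples$age_years, diet = gm$samples$diet,
    row.names = NULL)
}

#' Held-out prediction accuracy by group
#'
#' Predictions are first averaged per donor within the grouping unit
#' (e.g., over tissues within a layer), then Spearman-correlated with the
#' donors' actual ages on the lifespan-scaled basis (rank-equivalent to
#' years within a species, and the meaningful common scale when species
#' are pooled). Groups with fewer than `min_donors` donors are dropped
#' with a warning; a group with constant predictions reports rho = 0 and
#' `flagged = TRUE`.
#'
#' @param records `PredictionRecord` data.frame.
#' @param group_by one of "overall", "layer", "tissue", "species", "donor"
#'   or a vector of record columns to group on.
#' @param min_donors minimum donors per evaluated group.
#' @return data.frame: group, rho, n_donors, flagged.
#' @export
evaluate_predictions <- function(records, group_by = "overall",
                                 min_donors = 4) {
  cols <- switch(group_by[1],
                 overall = character(0),
                 layer = "layer", tissue = "tissue", species = "species",
                 donor = character(0),
                 group_by)
  records$actual_scaled <- scale_age(records$actual_years, records$species)
  key <- if (length(cols) == 0) rep("all", nrow(records)) else
    do.call(paste, c(records[cols], sep = "|"))
  out <- lapply(unique(key), function(kk) {
    r <- records[key == kk, ]
    agg <- stats::aggregate(
      cbind(predicted_scaled, actual_scaled) ~ donor_id, data = r, FUN = mean)
    if (nrow(agg) < min_donors) {
      warning("group ", kk, " has < ", min_donors, " donors; skipped")
      return(NULL)
    }
    rho <- suppressWarnings(cor(agg$predicted_scaled, agg$actual_scaled,
                                method = "spearman"))
    data.frame(group = kk, rho = ifelse(is.na(rho), 0, rho),
               n_donors = nrow(agg), flagged = is.na(rho))
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

group_rho <- function(records, group = NULL) {
  ev <- evaluate_predictions(records, group %||% "overall")
  stats::setNames(ev$rho, ev$group)
}

#' Leave-one-layer-out cross-layer transfer
#'
#' For each layer L the pan clock is retrained without any L profile under
#' 5-fold donor-grouped CV, then evaluated on (1) all L samples (predicted
#' by every fold model, averaged) and (2) the held-out samples of the
#' training layers. Percent change is reported against the full pan clock
#' trained under the same fold assignment:
#' `100 * (rho_without - rho_full) / rho_full`.
#'
#' @param gm min-max normalized clock-training GeneMatrix.
#' @param config `ClockConfig` (its `layers` define the pan set; `n_folds`
#'   is forced to 5 for this analysis).
#' @return list: `percent_change` (evaluated layer x left-out layer
#'   matrix), `rho_without`, `rho_full` (per evaluated layer).
#' @export
leave_one_layer_out <- function(gm, config = clock_config()) {
  config$n_folds <- 5L
  gm <- gm[gm$samples$layer %in% config$layers, ]
  folds <- make_folds(gm$samples, config$n_folds, config$seed)

  full_models <- train_clock(gm, config, folds = folds)
  full_rec <- predict_age(full_models, gm, folds = folds)
  rho_full <- group_rho(full_rec, "layer")

  layers <- config$layers
  pc <- matrix(NA_real_, length(layers), length(layers),
               dimnames = list(evaluated = layers, left_out = layers))
  rho_wo <- pc
  for (lo in layers) {
    train_gm <- gm[gm$samples$layer != lo, ]
    sub_folds <- folds[unique(train_gm$samples$donor_id)]
    models <- train_clock(train_gm, config, folds = sub_folds)
    heldin <- predict_age(models, train_gm, folds = sub_folds)
    lo_gm <- gm[gm$samples$layer == lo, ]
    lo_rec <- predict_age(models, lo_gm,
                          folds = stats::setNames(
                            rep(NA_integer_, length(unique(lo_gm$samples$donor_id))),
                            unique(lo_gm$samples$donor_id)))
    rec <- rbind(heldin, lo_rec)
    r <- group_rho(rec, "layer")
    rho_wo[names(r), lo] <- r
    pc[names(r), lo] <- 100 * (r - rho_full[names(r)]) / rho_full[names(r)]
  }
  list(percent_change = pc, rho_without = rho_wo, rho_full = rho_full)
}

#' Scaling rate of single-layer age prediction
#'
#' Repeatedly samples training cohorts of increasing donor count, trains a
#' single-layer clock on each, records held-out (non-sampled donors)
#' Spearman accuracy, and summarizes with the slope of a zero-intercept
#' least-squares fit of rho on log10(training donors):
#' `b = sum(rho_i * log10(n_i)) / sum(log10(n_i)^2)`.
#'
#' @param gm min-max normalized GeneMatrix.
#' @param layer the single layer to train on.
#' @param sizes training-cohort sizes (donors).
#' @param reps repetitions per size.
#' @param config `ClockConfig` template (mode forced to single-layer).
#' @param seed sampling seed.
#' @return list(slope, table of size/rep/rho).
#' @export
scaling_rate <- function(gm, layer, sizes = seq(20, 200, 20), reps = 10,
                         config = clock_config(), seed = 0L) {
  gm <- gm[gm$samples$layer == layer, ]
  config$mode <- "single-layer"
  config$layers <- layer
  donors <- unique(gm$samples$donor_id)
  abort_if(max(sizes) >= length(donors),
           "largest training size must leave held-out donors")
  grid <- expand.grid(rep = seq_len(reps), size = sizes)
  rho <- with_seed(seed, {
    vapply(seq_len(nrow(grid)), function(i) {
      tr_donors <- sample(donors, grid$size[i])
      tr <- gm[gm$samples$donor_id %in% tr_donors, ]
      te <- gm[!(gm$samples$donor_id %in% tr_donors), ]
      model <- fit_fold(tr, config)
      rec <- predict_age(list(model), te,
                         folds = stats::setNames(
                           rep(NA_integer_, length(unique(te$samples$donor_id))),
                           unique(te$samples$donor_id)))
      unname(group_rho(rec))
    }, numeric(1))
  })
  grid$rho <- rho
  list(slope = zero_intercept_slope(grid$rho, grid$size), table = grid)
}

## Zero-intercept OLS slope of rho on log10(n):
## b = sum(rho_i * log10(n_i)) / sum(log10(n_i)^2).
zero_intercept_slope <- function(rho, n) {
  lx <- log10(n)
  sum(rho * lx) / sum(lx^2)
}
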