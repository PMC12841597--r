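# A small noise-free two-layer cohort used for recovery checks; simulated
# and featurized once per session.
clock_cohort <- function() {
  cached_cohort("clock", sim_config(
    n_genes = 150, n_informative = 50, n_donors_per_species = 80,
    layers = c("DNAm", "H3K4me3"), n_datasets = 1,
    noise_sd = 0, donor_rate_sd = 0, batch_shift_sd = 0, cr_fraction = 0,
    seed = 21))
}

# Noisy variant for null (permuted-label) controls: under zero noise every
# informative gene is the same monotone curve, which degenerates the
# permutation null.
noisy_cohort <- function() {
  cached_cohort("clock_noisy", sim_config(
    n_genes = 150, n_informative = 50, n_donors_per_species = 30,
    layers = c("DNAm", "H3K4me3"), n_datasets = 1, cr_fraction = 0,
    seed = 22))
}

test_that("clock dataset filtering enforces the tissue, layer and diet rules", {
  samples <- rbind(
    make_samples(60, layer = "H3K4me3", tissue = "liver"),
    make_samples(49, layer = "H3K4me3", tissue = "skin", donor_prefix = "s"),
    make_samples(10, layer = "H3K9me3", tissue = "liver", donor_prefix = "k"),
    make_samples(10, layer = "H3K4me3", tissue = "prostate",
                 donor_prefix = "p"))
  cr <- make_samples(5, layer = "H3K4me3", tissue = "liver",
                     donor_prefix = "c", species = "mouse",
                     ages = rep(1, 5))
  cr$diet <- "CR"
  samples <- rbind(samples, cr)
  m <- matrix(runif(nrow(samples) * 3), ncol = 3,
              dimnames = list(samples$sample_id, c("g1", "g2", "g3")))
  flt <- filter_clock_dataset(toy_gene_matrix(m, samples), min_libraries = 50)
  tr <- flt$training$samples
  expect_false(any(tr$tissue == "skin"))      # 49 < 50 libraries
  expect_false(any(tr$layer == "H3K9me3"))    # sparse mark excluded
  expect_false(any(tr$tissue == "prostate"))  # sex-specific tissue
  expect_false(any(tr$diet == "CR"))          # withheld, not dropped
  expect_equal(nrow(flt$withheld_cr$samples), 5)
})

test_that("fold assignment groups donors, balances quintiles and is deterministic", {
  s <- make_samples(10)
  f <- make_folds(s, 10, seed = 1)
  expect_equal(sort(unname(f)), 1:10)  # one donor per fold

  # a multi-profile donor lands in exactly one fold
  s2 <- rbind(make_samples(20), make_samples(20, layer = "DNAm"))
  s2 <- rbind(s2, make_samples(1, tissue = "brain"))  # d001 gets 3 profiles
  f2 <- make_folds(s2, 5, seed = 3)
  expect_equal(length(f2), 20)
  profile_folds <- f2[s2$donor_id]
  expect_equal(length(unique(profile_folds[s2$donor_id == "d001"])), 1)

  # per-fold profile loads balanced within 1 where arithmetic allows
  s3 <- make_samples(50)
  f3 <- make_folds(s3, 10, seed = 2)
  loads <- table(f3[s3$donor_id])
  expect_lte(max(loads) - min(loads), 1)

  expect_identical(make_folds(s3, 10, seed = 7), make_folds(s3, 10, seed = 7))
  expect_error(make_folds(make_samples(4), 10), "fewer donors")
})

test_that("feature selection demands cross-species strength and sign agreement", {
  ages <- seq(1, 60, length.out = 30)
  h <- make_samples(30, species = "human", ages = ages)
  m <- make_samples(30, species = "mouse", ages = ages / 30,
                    donor_prefix = "m", dataset = "ds2")
  up <- c(ages, ages / 30)                 # rho = +1 in both
  flip <- c(ages, -ages / 30)              # sign disagreement
  weak_h <- c(rep(c(1, 2), 15), ages / 30) # |rho_h| ~ 0 in humans
  vals <- cbind(up = up, flip = flip, weak_h = weak_h)
  rownames(vals) <- c(h$sample_id, m$sample_id)
  gm <- toy_gene_matrix(vals, rbind(h, m))
  expect_identical(select_features(gm, 0.2), "up")

  # single-species input warns and applies the threshold to that species
  expect_warning(got <- select_features(gm[gm$samples$species == "human", ],
                                        0.2), "single-species")
  expect_setequal(got, c("up", "flip", "weak_h")[c(1, 2)])
})

test_that("noise-free synthetic cohorts are recovered almost perfectly", {
  co <- clock_cohort()
  gm_mm <- minmax_apply(minmax_fit(co$gm), co$gm)
  cc <- clock_config(layers = c("DNAm", "H3K4me3"), seed = 1)
  folds <- make_folds(gm_mm$samples, 10, 1)
  models <- train_clock(gm_mm, cc, folds = folds)
  rec <- predict_age(models, gm_mm, folds = folds)

  # held-out audit: every sample predicted by the fold holding out its donor
  expect_true(all(rec$fold == folds[rec$donor_id]))
  per_layer <- evaluate_predictions(rec, "layer")
  expect_true(all(per_layer$rho >= 0.99))
  expect_true(all(rec$predicted_years > 0))
  expect_true(all(rec$predicted_years <
                    lifespan_registry()[rec$species]))

  # determinism: retraining with the same seed reproduces predictions
  rec2 <- predict_age(train_clock(gm_mm, cc, folds = folds), gm_mm,
                      folds = folds)
  expect_identical(rec$predicted_scaled, rec2$predicted_scaled)

  # fold-wise leakage audit: refitting a fold's harmonization from its
  # training rows reproduces the stored parameters exactly
  f1_train <- gm_mm[folds[gm_mm$samples$donor_id] != 1, ]
  expect_identical(int_fit(f1_train)$tables, models[[1]]$int$tables)
  expect_false(identical(models[[1]]$int$tables, models[[2]]$int$tables))
})

test_that("permuted age labels destroy held-out accuracy", {
  co <- noisy_cohort()
  gm_mm <- minmax_apply(minmax_fit(co$gm), co$gm)
  perm <- gm_mm
  set.seed(77)
  for (sp in c("human", "mouse")) {
    i <- which(perm$samples$species == sp)
    donor_age <- tapply(perm$samples$age_years[i], perm$samples$donor_id[i],
                        `[`, 1)
    shuffled <- setNames(sample(donor_age), names(donor_age))
    perm$samples$age_years[i] <- shuffled[perm$samples$donor_id[i]]
  }
  cc <- clock_config(layers = c("DNAm", "H3K4me3"),
                     feature_rho_threshold = 0, seed = 1)
  folds <- make_folds(perm$samples, 10, 1)
  rec <- predict_age(train_clock(perm, cc, folds = folds), perm,
                     folds = folds)
  overall <- evaluate_predictions(rec, "overall")
  expect_lt(abs(overall$rho), 0.3)
})

test_that("withheld donors are predicted by the averaged fold ensemble", {
  co <- clock_cohort()
  gm_mm <- minmax_apply(minmax_fit(co$gm), co$gm)
  cc <- clock_config(layers = c("DNAm", "H3K4me3"), seed = 1)
  holdout_donors <- unique(gm_mm$samples$donor_id)[1:3]
  train <- gm_mm[!(gm_mm$samples$donor_id %in% holdout_donors), ]
  folds <- make_folds(train$samples, 5, 1)
  models <- train_clock(train, cc, folds = folds)
  wh <- gm_mm[gm_mm$samples$donor_id %in% holdout_donors, ]
  rec <- predict_age(models, wh,
                     folds = setNames(rep(NA_integer_, 3), holdout_donors))
  expect_true(all(is.na(rec$fold)))
  # the ensemble mean equals the mean of individual fold predictions
  manual <- rowMeans(vapply(models, panepiclock:::predict_with_model,
                            numeric(nrow(wh$samples)), gm = wh))
  expect_equal(rec$predicted_scaled, unname(manual))
})

test_that("evaluation aggregates donors and handles degenerate groups", {
  rec <- data.frame(
    sample_id = sprintf("s%d", 1:8),
    donor_id = rep(sprintf("d%d", 1:4), 2), species = "human",
    tissue = rep(c("liver", "blood"), each = 4), layer = "DNAm",
    fold = 1L, predicted_scaled = NA, predicted_years = rep(c(20, 30, 40, 50), 2),
    actual_years = rep(c(20, 30, 40, 50), 2), diet = "standard")
  rec$predicted_scaled <- scale_age(rec$predicted_years, "human")
  expect_equal(evaluate_predictions(rec, "overall")$rho, 1)

  const <- rec
  const$predicted_scaled <- 0.5
  ev <- evaluate_predictions(const, "overall")
  expect_equal(ev$rho, 0)
  expect_true(ev$flagged)

  expect_warning(
    got <- evaluate_predictions(rec[rec$donor_id %in% c("d1", "d2"), ],
                                "overall"),
    "donors")
  expect_null(got)
})

test_that("scaling-rate slope matches the zero-intercept closed form", {
  expect_equal(panepiclock:::zero_intercept_slope(c(0.5, 1.0), c(10, 100)),
               0.5)
  expect_equal(panepiclock:::zero_intercept_slope(rep(0, 5),
                                                  c(20, 40, 60, 80, 100)), 0)
  # informative layer improves with training size on the noise-free cohort
  co <- clock_cohort()
  gm_mm <- minmax_apply(minmax_fit(co$gm), co$gm)
  sr <- scaling_rate(gm_mm, "DNAm", sizes = c(10, 20, 40), reps = 2,
                     config = clock_config(layers = "DNAm", seed = 2),
                     seed = 2)
  expect_gt(sr$slope, 0)
  expect_equal(nrow(sr$table), 6)
  expect_true(all(is.finite(sr$table$rho)))
})
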