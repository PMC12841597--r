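#' Aggregate a raw cohort into a gene-level matrix
#'
#' Reads the sample sheet, per-species gene annotations and the ortholog
#' map, aggregates each profile to gene level (mean overlapping-peak score
#' for histone layers, mean contained-CpG methylated fraction for DNAm),
#' maps mouse genes onto their one-to-one human orthologs, and assembles
#' the samples x genes matrix (dropping genes covered in no sample of some
#' \{dataset x layer\} stratum).
#'
#' @param sample_sheet path to the sample-sheet TSV (sample_id, donor_id,
#'   species, tissue, layer, dataset, age_years, diet, file_path).
#' @param annotations named character vector of annotation paths per
#'   species (BED or GTF/GFF3).
#' @param orthologs path to the mouse-to-human one-to-one ortholog TSV.
#' @param score_col narrowPeak column aggregated for histone layers.
#' @return a GeneMatrix in human gene coordinates.
#' @export
featurize_cohort <- function(sample_sheet, annotations, orthologs = NULL,
                             score_col = "score") {
  sheet <- as.data.frame(data.table::fread(sample_sheet, sep = "\t"))
  need <- c("sample_id", "donor_id", "species", "tissue", "layer", "dataset",
            "age_years", "file_path")
  abort_if(!all(need %in% names(sheet)),
           paste0("sample sheet lacks column(s): ",
                  paste(setdiff(need, names(sheet)), collapse = ", ")))
  # file paths may be absolute or relative to the sheet's directory
  rel <- !file.exists(sheet$file_path)
  sheet$file_path[rel] <- file.path(dirname(sample_sheet),
                                    sheet$file_path[rel])
  anns <- lapply(stats::setNames(nm = names(annotations)), function(sp) {
    read_gene_annotation(annotations[[sp]], sp)
  })
  ortho <- if (!is.null(orthologs)) read_ortholog_map(orthologs) else NULL
  vectors <- lapply(seq_len(nrow(sheet)), function(i) {
    s <- sheet[i, ]
    ann <- anns[[s$species]]
    abort_if(is.null(ann), paste0("no annotation for species ", s$species))
    v <- if (s$layer == "DNAm") {
      gene_level_meth(read_cpg_table(s$file_path), ann)
    } else {
      gene_level_chip(read_narrowpeak(s$file_path), ann,
                      score_col = score_col)
    }
    map_orthologs(v, s$species, ortho)
  })
  assemble_matrix(vectors, sheet)
}

#' Pipeline run configuration
#'
#' @param out_dir run output directory.
#' @param sim `SimConfig` to generate the cohort, or NULL when `paths`
#'   point at existing raw data.
#' @param paths list(sample_sheet, annotations (named by species),
#'   orthologs) for pre-existing cohorts.
#' @param clock `ClockConfig` for the clock stages.
#' @param k top-set size for overlap/crosstalk statistics.
#' @param fdr_levels FDR levels for the all-layer intersection.
#' @param run_clocks run the (slower) clock/residual stages.
#' @param min_libraries minimum profiles per retained tissue in the clock
#'   filter (see [filter_clock_dataset()]).
#' @param seed master seed, propagated to all stochastic stages.
#' @return a `RunConfig` list.
#' @export
run_config <- function(out_dir, sim = sim_config(), paths = NULL,
                       clock = clock_config(), k = 1000,
                       fdr_levels = c(0.05, 0.1, 0.2),
                       run_clocks = TRUE, min_libraries = 50, seed = 0L) {
  abort_if(is.null(sim) && is.null(paths), "need either sim or paths")
  structure(list(out_dir = out_dir, sim = sim, paths = paths, clock = clock,
                 k = k, fdr_levels = fdr_levels, run_clocks = run_clocks,
                 min_libraries = min_libraries, seed = as.integer(seed)),
            class = "RunConfig")
}

config_hash <- function(config) {
  stable_hash(paste(deparse(unclass(config)), collapse = ""))
}

write_stage_table <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash=", hash), con)
  close(con)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> featurize -> harmonize -> per-stratum age
#' associations, pairwise crosstalk and top-k overlap summaries -> pan and
#' single-layer clocks with held-out predictions -> residual
#' synchronization and caloric-restriction comparison. All tables are
#' written as TSV under `out_dir` with the config hash in a `#` header
#' line, plus a JSON run manifest; identical configs (including seed)
#' reproduce all outputs.
#'
#' @param config a `RunConfig` from [run_config()].
#' @return invisible list of in-memory stage results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stage <- function(name, expr) {
    message("[panepiclock] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  paths <- config$paths
  if (!is.null(config$sim)) {
    sim_out <- stage("simulate", {
      cohort <- simulate_cohort(config$sim, file.path(config$out_dir, "cohort"))
      cohort
    })
    paths <- list(sample_sheet = sim_out$sample_sheet,
                  annotations = sim_out$paths$annotations,
                  orthologs = sim_out$paths$orthologs)
  }

  gm_raw <- stage("featurize", featurize_cohort(
    paths$sample_sheet, paths$annotations, paths$orthologs))
  write_gene_matrix(gm_raw, file.path(config$out_dir, "matrix_raw"))

  gm_norm <- stage("harmonize", harmonize_matrix(gm_raw))

  assoc <- stage("associate", {
    strata <- unique(gm_norm$samples[, c("species", "layer")])
    tabs <- lapply(seq_len(nrow(strata)), function(i) {
      age_association(gm_norm, species = strata$species[i],
                      layer = strata$layer[i])
    })
    names(tabs) <- paste(strata$species, strata$layer, sep = "|")
    for (nm in names(tabs)) {
      write_stage_table(tabs[[nm]], file.path(
        config$out_dir, paste0("assoc_", gsub("\\|", "_", nm), ".tsv")), hash)
    }
    tabs
  })

  stats_out <- stage("layer-statistics", {
    k_eff <- min(config$k, floor(length(assoc[[1]]$gene_id) / 2) - 1)
    pair_stats <- list()
    for (sp in unique(gm_norm$samples$species)) {
      nm <- names(assoc)[startsWith(names(assoc), paste0(sp, "|"))]
      if (length(nm) < 2) next
      pairs <- utils::combn(nm, 2)
      fam <- ncol(pairs)
      for (i in seq_len(fam)) {
        a <- pairs[1, i]; b <- pairs[2, i]
        enr <- top_k_overlap_enrichment(assoc[[a]], assoc[[b]], k = k_eff,
                                        n_comparisons = fam)
        ct <- crosstalk(assoc[[a]], assoc[[b]], k = k_eff,
                        family = crosstalk_family_size(length(nm)))
        pair_stats[[paste(a, b, sep = " vs ")]] <- data.frame(
          pair = paste(a, b, sep = " vs "), k = k_eff, G = enr$G,
          observed = enr$observed, expected = enr$expected, fold = enr$fold,
          overlap_p_bonf = enr$p_bonf, crosstalk_median_diff = ct$median_diff,
          crosstalk_p_bonf = ct$p_bonf)
      }
    }
    df <- do.call(rbind, pair_stats)
    if (!is.null(df)) {
      write_stage_table(df, file.path(config$out_dir, "layer_pair_stats.tsv"),
                        hash)
    }
    for (sp in unique(gm_norm$samples$species)) {
      nm <- names(assoc)[startsWith(names(assoc), paste0(sp, "|"))]
      if (length(nm) < 2) next
      inter <- all_layer_intersection(assoc[nm], config$fdr_levels)
      write_stage_table(inter, file.path(
        config$out_dir, paste0("all_layer_intersection_", sp, ".tsv")), hash)
    }
    df
  })

  clocks_out <- NULL
  if (isTRUE(config$run_clocks)) {
    clocks_out <- stage("clocks", {
      gm_mm <- minmax_apply(minmax_fit(gm_raw), gm_raw)
      flt <- filter_clock_dataset(gm_mm,
                                  min_libraries = config$min_libraries)
      cc <- config$clock
      cc$seed <- config$seed
      folds <- make_folds(flt$training$samples, cc$n_folds, cc$seed)
      models <- train_clock(flt$training, cc, folds = folds)
      rec <- predict_age(models, flt$training, folds = folds)
      if (!is.null(flt$withheld_cr)) {
        cr_folds <- stats::setNames(
          rep(NA_integer_, length(unique(flt$withheld_cr$samples$donor_id))),
          unique(flt$withheld_cr$samples$donor_id))
        rec <- rbind(rec, predict_age(models, flt$withheld_cr,
                                      folds = cr_folds))
      }
      write_stage_table(rec, file.path(config$out_dir, "predictions.tsv"),
                        hash)
      perf <- rbind(evaluate_predictions(rec, "species"),
                    evaluate_predictions(rec, c("species", "layer")))
      write_stage_table(perf, file.path(config$out_dir, "performance.tsv"),
                        hash)
      list(records = rec, performance = perf, folds = folds)
    })

    resid_out <- stage("residuals", {
      tab <- compute_residuals(clocks_out$records)
      write_stage_table(tab, file.path(config$out_dir, "residuals.tsv"), hash)
      sync <- layer_sync(tab)
      cr <- if (any(tab$diet == "CR")) cr_comparison(tab, layers = "DNAm")
      else NULL
      list(table = tab, sync = sync, cr = cr)
    })
    clocks_out$residuals <- resid_out
  }

  manifest <- list(package = "panepiclock",
                   version = as.character(utils::packageVersion("panepiclock")),
                   config_hash = hash, seed = config$seed,
                   timestamp_free = TRUE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(matrix = gm_raw, assoc = assoc, pair_stats = stats_out,
                 clocks = clocks_out, manifest = manifest))
}

#' Summarize a completed run directory
#'
#' Collects the tables a run wrote into a named list; stages that were not
#' computed appear as the marker string `"not computed"` rather than being
#' silently absent. Re-entrant: repeated calls return identical summaries.
#'
#' @param run_dir directory written by [run_all()].
#' @return named list of data.frames / markers.
#' @export
report <- function(run_dir) {
  read_tab <- function(name) {
    path <- file.path(run_dir, name)
    if (!file.exists(path)) return("not computed")
    as.data.frame(data.table::fread(path, sep = "\t", skip = 1))
  }
  list(layer_pair_stats = read_tab("layer_pair_stats.tsv"),
       performance = read_tab("performance.tsv"),
       residuals = read_tab("residuals.tsv"),
       manifest = if (file.exists(file.path(run_dir, "manifest.json"))) {
         jsonlite::read_json(file.path(run_dir, "manifest.json"))
       } else "not computed")
}
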