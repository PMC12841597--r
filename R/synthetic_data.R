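CLOCK_LAYERS <- c("DNAm", "H3K4me3", "H3K27ac", "H3K27me3", "H3K4me1")
ALL_LAYERS <- c(CLOCK_LAYERS, "H3K36me3", "H3K9me3")
REPRESSIVE_MARKS <- c("H3K27me3", "H3K9me3", "DNAm")
ACTIVATING_MARKS <- c("H3K27ac", "H3K36me3", "H3K4me1", "H3K4me3")

#' Empirical per-mark age-trend direction map
#'
#' Directions of age-related change observed in gene-body signal:
#' repressive marks (DNAm, H3K27me3, H3K9me3) together with H3K27ac and
#' H3K4me3 trend one way (+1), while H3K4me1 and H3K36me3 trend the
#' opposite way (-1). Useful as a `layer_sign_map` when simulating the
#' opposing-mark structure probed by the crosstalk and direction-gene-set
#' analyses.
#'
#' @return named numeric vector of +1/-1 over the seven layers.
#' @export
mark_direction_map <- function() {
  c(DNAm = 1, H3K4me3 = 1, H3K27ac = 1, H3K27me3 = 1, H3K9me3 = 1,
    H3K4me1 = -1, H3K36me3 = -1)
}

#' Synthetic-cohort configuration
#'
#' Defines the generative model realized by [simulate_cohort()]: for donor
#' d, gene g, layer l the latent gene-level signal is
#' `sign(l) * loading(g) * (scaled_age(d) + rate_factor(d)) +
#'  batch_shift(dataset, l) + noise`,
#' where `scaled_age` is the lifespan-scaled age of the donor's effective
#' age (reduced by `cr_offset_frac` of relative lifespan for calorically
#' restricted mice), `loading` is a shared per-gene coefficient (zero
#' outside the informative set), and `rate_factor` is a donor-level
#' aging-rate offset common to all of the donor's layers. Latent values are
#' realized as narrowPeak scores (histone layers) or CpG methylated
#' fractions (DNAm) through a strictly increasing logistic squash, so
#' rank-based downstream statistics see the latent structure exactly.
#'
#' Defaults describe the cohort used throughout the package's recovery
#' tests: two species (human/mouse), 200 donors each, the five clock
#' layers with concordant (+1) signs, 2000 genes of which 300 carry age
#' signal, two datasets per species, unit loading and noise scales, and a
#' 10% caloric-restriction arm in mice.
#'
#' @param n_genes,n_informative genes simulated / genes carrying age signal.
#' @param n_donors_per_species donors per species.
#' @param layers epigenetic layers (must be a subset of the seven known).
#' @param tissues_per_donor tissues profiled per donor.
#' @param n_datasets datasets per species (donors split round-robin).
#' @param age_range_frac interval of relative lifespan donors are drawn from.
#' @param shared_loading_sd sd of informative-gene loadings.
#' @param layer_sign_map named +1/-1 per layer; default +1 everywhere (the
#'   aligned pan-epigenetic component); see [mark_direction_map()] for the
#'   opposing-mark variant.
#' @param noise_sd per-sample per-gene latent noise sd.
#' @param batch_shift_sd sd of dataset-by-layer latent offsets.
#' @param donor_rate_sd sd of the donor aging-rate factor.
#' @param cr_fraction fraction of mouse donors under caloric restriction.
#' @param cr_offset_frac reduction of effective relative age in CR mice.
#' @param seed cohort RNG seed; per-sample noise uses substreams hashed
#'   from sample ids so extending a cohort never reshuffles existing samples.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_genes = 2000, n_informative = 300,
                       n_donors_per_species = 200,
                       layers = CLOCK_LAYERS,
                       tissues_per_donor = 1, n_datasets = 2,
                       age_range_frac = c(0.05, 0.9),
                       shared_loading_sd = 1,
                       layer_sign_map = NULL,
                       noise_sd = 1, batch_shift_sd = 0.5,
                       donor_rate_sd = 0.1,
                       cr_fraction = 0.1, cr_offset_frac = 0.15,
                       seed = 0L) {
  if (is.null(layer_sign_map)) {
    layer_sign_map <- stats::setNames(rep(1, length(layers)), layers)
  }
  cfg <- list(
    n_genes = as.integer(n_genes), n_informative = as.integer(n_informative),
    n_donors_per_species = as.integer(n_donors_per_species),
    layers = layers, tissues_per_donor = as.integer(tissues_per_donor),
    n_datasets = as.integer(n_datasets),
    age_range_frac = age_range_frac,
    shared_loading_sd = shared_loading_sd,
    layer_sign_map = layer_sign_map,
    noise_sd = noise_sd, batch_shift_sd = batch_shift_sd,
    donor_rate_sd = donor_rate_sd,
    cr_fraction = cr_fraction, cr_offset_frac = cr_offset_frac,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "SimConfig")
}

validate_sim_config <- function(cfg) {
  abort_if(cfg$n_informative > cfg$n_genes, "n_informative > n_genes")
  abort_if(!all(cfg$layers %in% ALL_LAYERS),
           paste0("unknown layer(s): ",
                  paste(setdiff(cfg$layers, ALL_LAYERS), collapse = ", ")))
  abort_if(any(c(cfg$shared_loading_sd, cfg$noise_sd, cfg$batch_shift_sd,
                 cfg$donor_rate_sd) < 0), "sd parameters must be >= 0")
  abort_if(cfg$cr_fraction < 0 || cfg$cr_fraction > 1, "cr_fraction outside [0,1]")
  abort_if(length(cfg$age_range_frac) != 2 ||
             cfg$age_range_frac[1] <= 0 || cfg$age_range_frac[2] >= 1 ||
             diff(cfg$age_range_frac) <= 0,
           "age_range_frac must be an increasing interval within (0,1)")
  abort_if(!all(cfg$layers %in% names(cfg$layer_sign_map)),
           "layer_sign_map must cover every layer")
  abort_if(!all(cfg$layer_sign_map %in% c(-1, 1)), "layer signs must be +1/-1")
  invisible(cfg)
}

TISSUE_POOL <- c("liver", "blood", "muscle", "kidney", "brain", "heart",
                 "skin", "lung", "spleen", "colon", "pancreas", "thymus")

#' Write peak records as a narrowPeak file
#'
#' Ten tab-separated columns (BED6+4), sorted by chromosome then start.
#' Records need chrom/start/end/score; missing optional columns are filled
#' with narrowPeak placeholders (name ".", strand ".", signal 0, p/q/summit
#' -1).
#'
#' @param records data.frame with chrom, start, end (0-based half-open),
#'   score (>= 0); optionally name, strand, signal, pvalue, qvalue, summit.
#' @param path output path.
#' @return `path`, invisibly. Empty input writes an empty file.
#' @export
write_narrowpeak <- function(records, path) {
  if (nrow(records) == 0) { file.create(path); return(invisible(path)) }
  abort_if(any(records$start < 0), "negative coordinates")
  abort_if(any(records$end <= records$start), "end must exceed start")
  abort_if(any(records$score < 0), "negative narrowPeak score")
  o <- order(records$chrom, records$start, records$end)
  r <- records[o, , drop = FALSE]
  n <- nrow(r)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%s\t%s\t%s\t%g\t%g\t%g",
    r$chrom, as.integer(r$start), as.integer(r$end),
    r$name %||% rep(".", n), sprintf("%.10g", r$score),
    r$strand %||% rep(".", n),
    sprintf("%.10g", r$signal %||% rep(0, n)),
    r$pvalue %||% rep(-1, n), r$qvalue %||% rep(-1, n),
    r$summit %||% rep(-1, n))
  writeLines(lines, path)
  invisible(path)
}

#' Write CpG records as a 4-column methylation TSV
#'
#' Columns: chrom, pos (0-based), methylated fraction, coverage; sorted by
#' coordinate, no header.
#'
#' @param records data.frame with chrom, pos, meth_fraction, coverage.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(records, path) {
  if (nrow(records) == 0) { file.create(path); return(invisible(path)) }
  abort_if(any(records$pos < 0), "negative coordinates")
  abort_if(any(records$meth_fraction < 0 | records$meth_fraction > 1),
           "methylated fraction outside [0, 1]")
  o <- order(records$chrom, records$pos)
  r <- records[o, , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%.10g\t%d", r$chrom, as.integer(r$pos),
                     r$meth_fraction, as.integer(r$coverage)), path)
  invisible(path)
}

#' Simulate age-prediction records with planted residual structure
#'
#' Generates `PredictionRecord` rows directly at the residual level,
#' bypassing clock training: each donor has a persistent aging-rate
#' offset (in years, shared by all of the donor's layers) plus
#' independent per-layer noise, and calorically restricted donors are
#' shifted younger by a fixed offset. Used for calibration and power
#' studies of the residual-synchronization and caloric-restriction
#' analyses, where the quantity under test is the residual machinery
#' rather than the regressor.
#'
#' @param n_donors number of donors.
#' @param layers layers each donor is profiled in.
#' @param rate_sd sd (years) of the shared per-donor aging-rate offset.
#' @param noise_sd sd (years) of per-layer prediction noise.
#' @param species single species for all donors.
#' @param cr_fraction fraction of donors under caloric restriction.
#' @param cr_offset_years years subtracted from CR donors' predictions.
#' @param age_range_frac interval of relative lifespan for donor ages.
#' @param seed RNG seed.
#' @return `PredictionRecord` data.frame compatible with
#'   [compute_residuals()].
#' @export
simulate_prediction_records <- function(n_donors, layers = CLOCK_LAYERS,
                                        rate_sd = 1, noise_sd = 1,
                                        species = "human",
                                        cr_fraction = 0,
                                        cr_offset_years = 0,
                                        age_range_frac = c(0.05, 0.9),
                                        seed = 0L) {
  L <- lifespan_registry()[[species]]
  with_seed(seed, {
    age <- runif(n_donors, age_range_frac[1], age_range_frac[2]) * L
    rate <- rnorm(n_donors, 0, rate_sd)
    cr <- seq_len(n_donors) <= round(cr_fraction * n_donors)
    rec <- expand.grid(donor = seq_len(n_donors), layer = layers,
                       stringsAsFactors = FALSE)
    pred <- age[rec$donor] + rate[rec$donor] +
      rnorm(nrow(rec), 0, noise_sd) - cr[rec$donor] * cr_offset_years
    pred <- pmin(pmax(pred, 1 / 365.25), L - 1 / 365.25)
    data.frame(
      sample_id = sprintf("d%04d_%s", rec$donor, rec$layer),
      donor_id = sprintf("d%04d", rec$donor), species = species,
      tissue = "liver", layer = rec$layer, fold = NA_integer_,
      predicted_scaled = scale_age(pred, species),
      predicted_years = pred, actual_years = age[rec$donor],
      diet = ifelse(cr[rec$donor], "CR", "standard"), row.names = NULL)
  })
}

synthetic_annotation <- function(n_genes, species) {
  n_chrom <- if (species == "human") 22L else 19L
  prefix <- if (species == "human") "HG" else "MG"
  chrom_idx <- rep(seq_len(n_chrom), length.out = n_genes)
  within <- stats::ave(seq_len(n_genes), chrom_idx, FUN = seq_along)
  start <- (within - 1L) * 10000L + 1000L
  data.frame(
    gene_id = sprintf("%s%05d", prefix, seq_len(n_genes)),
    chrom = paste0("chr", chrom_idx),
    start = start, end = start + 1000L, strand = "+",
    species = species, stringsAsFactors = FALSE)
}

write_bed4 <- function(ann, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", ann$chrom, ann$start, ann$end,
                     ann$gene_id), path)
  invisible(path)
}

#' Simulate a raw-format synthetic cohort
#'
#' Realizes the generative model of [sim_config()] as on-disk raw files:
#' one narrowPeak file per histone profile (a single gene-spanning peak
#' per gene, score `1000 * plogis(latent / 2)`, peaks under `peak_floor`
#' omitted), one CpG table per methylome (ten CpGs per gene body sharing
#' the fraction `plogis(latent / 2)`), a BED gene annotation per species,
#' a one-to-one ortholog map, a sample sheet, and a `truth/` TSV bundle
#' with every latent quantity. Byte-identical outputs for identical
#' configs.
#'
#' @param config a `SimConfig` from [sim_config()].
#' @param out_dir output directory (created if absent).
#' @param peak_floor minimum narrowPeak score below which the peak is
#'   omitted (the gene then reads back as 0).
#' @return list with `sample_sheet` (path), `truth` (list of data.frames:
#'   loadings, donors, batch_shifts), and `paths` (annotations, ortholog
#'   map, per-sample files directory).
#' @export
simulate_cohort <- function(config, out_dir, peak_floor = 1) {
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  abort_if(!dir.exists(out_dir), paste0("cannot create directory ", out_dir))
  samples_dir <- file.path(out_dir, "samples")
  truth_dir <- file.path(out_dir, "truth")
  dir.create(samples_dir, showWarnings = FALSE)
  dir.create(truth_dir, showWarnings = FALSE)

  ann_h <- synthetic_annotation(config$n_genes, "human")
  ann_m <- synthetic_annotation(config$n_genes, "mouse")
  ortho <- data.frame(from = ann_m$gene_id, to = ann_h$gene_id)
  registry <- lifespan_registry()

  cohort <- with_seed(config$seed, {
    loading <- numeric(config$n_genes)
    informative <- sort(sample.int(config$n_genes, config$n_informative))
    loading[informative] <- rnorm(config$n_informative, 0, config$shared_loading_sd)

    donors <- do.call(rbind, lapply(c("human", "mouse"), function(sp) {
      n <- config$n_donors_per_species
      ids <- sprintf("%s_d%04d", ifelse(sp == "human", "hs", "mm"),
                     seq_len(n))
      # per-donor substreams: growing the cohort never redraws the ages or
      # rate factors of donors that were already present
      draws <- vapply(ids, function(id) {
        with_seed(substream_seed(config$seed + 2L, id),
                  c(runif(1, config$age_range_frac[1],
                          config$age_range_frac[2]),
                    rnorm(1, 0, config$donor_rate_sd)))
      }, numeric(2))
      rel <- draws[1, ]
      data.frame(
        donor_id = ids, species = sp, rel_age = rel,
        age_years = rel * registry[[sp]],
        rate_factor = draws[2, ],
        dataset = sprintf("%s_ds%d", ifelse(sp == "human", "hs", "mm"),
                          (seq_len(n) - 1L) %% config$n_datasets + 1L),
        stringsAsFactors = FALSE)
    }))
    donors$cr_flag <- FALSE
    mice <- which(donors$species == "mouse")
    n_cr <- round(config$cr_fraction * length(mice))
    if (n_cr > 0) donors$cr_flag[sample(mice, n_cr)] <- TRUE
    donors$diet <- ifelse(donors$species == "mouse",
                          ifelse(donors$cr_flag, "CR", "standard"), "standard")

    shifts <- expand.grid(dataset = unique(donors$dataset),
                          layer = config$layers, stringsAsFactors = FALSE)
    shifts$shift <- rnorm(nrow(shifts), 0, config$batch_shift_sd)
    list(loading = loading, informative = informative, donors = donors,
         shifts = shifts)
  })

  donors <- cohort$donors
  rel_eff <- ifelse(donors$cr_flag,
                    pmax(donors$rel_age - config$cr_offset_frac, 0.01),
                    donors$rel_age)
  donors$scaled_eff <- -log(-log(rel_eff))

  tissues <- TISSUE_POOL[seq_len(config$tissues_per_donor)]
  sheet <- expand.grid(layer = config$layers, tissue = tissues,
                       donor_row = seq_len(nrow(donors)),
                       stringsAsFactors = FALSE)
  d <- donors[sheet$donor_row, ]
  sheet <- data.frame(
    sample_id = sprintf("%s_%s_%s", d$donor_id, sheet$tissue, sheet$layer),
    donor_id = d$donor_id, species = d$species, tissue = sheet$tissue,
    layer = sheet$layer, dataset = d$dataset, age_years = d$age_years,
    diet = d$diet, stringsAsFactors = FALSE)

  shift_key <- paste(cohort$shifts$dataset, cohort$shifts$layer)
  gene_ids <- list(human = ann_h$gene_id, mouse = ann_m$gene_id)
  anns <- list(human = ann_h, mouse = ann_m)

  sheet$file_path <- vapply(seq_len(nrow(sheet)), function(i) {
    s <- sheet[i, ]
    drow <- donors[match(s$donor_id, donors$donor_id), ]
    shift <- cohort$shifts$shift[match(paste(s$dataset, s$layer), shift_key)]
    noise <- with_seed(substream_seed(config$seed, s$sample_id),
                       rnorm(config$n_genes, 0, config$noise_sd))
    latent <- config$layer_sign_map[[s$layer]] * cohort$loading *
      (drow$scaled_eff + drow$rate_factor) + shift + noise
    ann <- anns[[s$species]]
    if (s$layer == "DNAm") {
      frac <- stats::plogis(latent / 2)
      cov <- with_seed(substream_seed(config$seed + 1L, s$sample_id),
                       rpois(10L * config$n_genes, 30)) + 1L
      rec <- data.frame(
        chrom = rep(ann$chrom, each = 10L),
        pos = rep(ann$start, each = 10L) + 50L + 100L * (0:9),
        meth_fraction = rep(frac, each = 10L), coverage = cov)
      path <- file.path(samples_dir, paste0(s$sample_id, ".cpg.tsv"))
      write_cpg_table(rec, path)
    } else {
      score <- 1000 * stats::plogis(latent / 2)
      keep <- score >= peak_floor
      rec <- data.frame(chrom = ann$chrom[keep], start = ann$start[keep],
                        end = ann$end[keep], score = score[keep])
      path <- file.path(samples_dir, paste0(s$sample_id, ".narrowPeak"))
      write_narrowpeak(rec, path)
    }
    path
  }, character(1))

  bed_h <- file.path(out_dir, "human_genes.bed")
  bed_m <- file.path(out_dir, "mouse_genes.bed")
  write_bed4(ann_h, bed_h)
  write_bed4(ann_m, bed_m)
  ortho_path <- file.path(out_dir, "orthologs.tsv")
  writeLines(sprintf("%s\t%s", ortho$from, ortho$to), ortho_path)
  # file paths are stored relative to the cohort directory so identical
  # configs yield byte-identical sheets wherever they are written
  sheet_disk <- sheet
  sheet_disk$file_path <- file.path("samples", basename(sheet$file_path))
  sheet_path <- file.path(out_dir, "sample_sheet.tsv")
  data.table::fwrite(sheet_disk, sheet_path, sep = "\t")

  truth <- list(
    loadings = data.frame(gene_id = ann_h$gene_id, loading = cohort$loading,
                          informative = seq_len(config$n_genes) %in%
                            cohort$informative),
    donors = donors[, c("donor_id", "species", "age_years", "rate_factor",
                        "cr_flag", "diet")],
    batch_shifts = cohort$shifts)
  for (nm in names(truth)) {
    data.table::fwrite(truth[[nm]], file.path(truth_dir, paste0(nm, ".tsv")),
                       sep = "\t")
  }
  yaml::write_yaml(unclass(config), file.path(out_dir, "sim_config.yaml"))

  list(sample_sheet = sheet_path, truth = truth,
       paths = list(annotations = c(human = bed_h, mouse = bed_m),
                    orthologs = ortho_path, samples_dir = samples_dir))
}
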