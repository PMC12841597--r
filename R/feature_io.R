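#' Read a narrowPeak (BED6+4) file
#'
#' @param path path to a tab-separated narrowPeak file (>= 10 columns,
#'   no header). Coordinates are 0-based half-open and preserved as such.
#' @return data.frame with columns chrom, start, end, name, score, strand,
#'   signal, pvalue, qvalue, summit. Empty file -> zero-row frame.
#' @export
read_narrowpeak <- function(path) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signal", "pvalue", "qvalue", "summit")
  if (file.size(path) == 0) {
    return(stats::setNames(
      data.frame(character(), integer(), integer(), character(), numeric(),
                 character(), numeric(), numeric(), numeric(), numeric()),
      cols))
  }
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 10L)
  abort_if(length(bad) > 0,
           paste0("malformed narrowPeak line ", bad[1], " in ", path,
                  ": expected >= 10 tab-separated columns, got ", nf[bad[1]]))
  m <- do.call(rbind, lapply(fields, `[`, 1:10))
  out <- data.frame(
    chrom = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]),
    name = m[, 4], score = as.numeric(m[, 5]), strand = m[, 6],
    signal = as.numeric(m[, 7]), pvalue = as.numeric(m[, 8]),
    qvalue = as.numeric(m[, 9]), summit = as.numeric(m[, 10]),
    stringsAsFactors = FALSE)
  bad <- which(is.na(out$start) | is.na(out$end) | is.na(out$score))
  abort_if(length(bad) > 0,
           paste0("malformed narrowPeak line ", bad[1], " in ", path,
                  ": non-numeric coordinate or score"))
  abort_if(any(out$start < 0), "negative coordinates in narrowPeak file")
  abort_if(any(out$end <= out$start), "narrowPeak interval with end <= start")
  out
}

#' Read a per-CpG methylation table
#'
#' Four tab-separated columns, no header: chrom, pos (0-based),
#' meth_fraction in \[0,1\], coverage.
#'
#' @param path file path.
#' @return data.frame with columns chrom, pos, meth_fraction, coverage.
#' @export
read_cpg_table <- function(path) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  cols <- c("chrom", "pos", "meth_fraction", "coverage")
  if (file.size(path) == 0) {
    return(stats::setNames(
      data.frame(character(), integer(), numeric(), integer()), cols))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  abort_if(ncol(dt) < 4L,
           paste0("CpG table ", path, " has ", ncol(dt), " columns; expected 4"))
  out <- stats::setNames(as.data.frame(dt[, 1:4]), cols)
  out$pos <- as.integer(out$pos)
  out$coverage <- as.integer(out$coverage)
  abort_if(anyNA(out$pos) || any(out$pos < 0), "negative or non-numeric CpG position")
  frac <- out$meth_fraction
  abort_if(anyNA(frac) || any(frac < 0 | frac > 1),
           "methylated fraction outside [0, 1] in CpG table")
  out
}

#' Read gene-body annotations (GTF/GFF3 or BED)
#'
#' GTF/GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention; BED is taken as-is. Only autosomal genes
#' are retained (sex chromosomes and scaffolds dropped).
#'
#' @param path annotation file; format chosen by extension
#'   (`.gtf`/`.gff`/`.gff3` vs `.bed`).
#' @param species species label stored on each record.
#' @return data.frame with columns gene_id, chrom, start, end, strand, species.
#' @export
read_gene_annotation <- function(path, species) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene"]
    }
    ids <- S4Vectors::mcols(gr)$gene_id
    abort_if(is.null(ids), "annotation lacks gene_id attribute")
    ann <- data.frame(
      gene_id = as.character(ids),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  } else if (ext == "bed") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    abort_if(ncol(dt) < 4L, "BED annotation needs >= 4 columns (incl. gene id)")
    ann <- data.frame(
      gene_id = as.character(dt[[4]]), chrom = as.character(dt[[1]]),
      start = as.integer(dt[[2]]), end = as.integer(dt[[3]]),
      strand = if (ncol(dt) >= 6) as.character(dt[[6]]) else ".",
      stringsAsFactors = FALSE)
  } else {
    stop("unknown annotation format: .", ext, call. = FALSE)
  }
  ann <- ann[is_autosome(ann$chrom), , drop = FALSE]
  abort_if(anyDuplicated(ann$gene_id) > 0, "duplicate gene_id in annotation")
  ann$species <- species
  rownames(ann) <- NULL
  ann
}

ranges_of <- function(df, start_col = "start", end_col = "end") {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df[[start_col]] + 1L, end = df[[end_col]]))
}

#' Gene-level ChIP-seq signal
#'
#' The value of a gene is the arithmetic mean of the scores of all peaks
#' overlapping its body by at least 1 bp (unweighted by overlap length;
#' strand ignored). Genes without any overlapping peak get 0. A peak
#' overlapping several genes contributes to each of their means.
#'
#' @param peaks data.frame as from [read_narrowpeak()].
#' @param genes annotation data.frame as from [read_gene_annotation()].
#' @param score_col which column carries the aggregated signal:
#'   `"score"` (narrowPeak column 5, default) or `"signal"` (column 7).
#' @return named numeric vector over `genes$gene_id`.
#' @export
gene_level_chip <- function(peaks, genes, score_col = c("score", "signal")) {
  score_col <- match.arg(score_col)
  abort_if(nrow(genes) == 0, "empty gene list")
  vals <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  if (nrow(peaks) == 0) return(vals)
  hits <- GenomicRanges::findOverlaps(ranges_of(genes), ranges_of(peaks),
                                      ignore.strand = TRUE)
  if (length(hits) > 0) {
    sums <- tapply(peaks[[score_col]][S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), mean)
    vals[as.integer(names(sums))] <- as.numeric(sums)
  }
  vals
}

#' Gene-level DNA methylation
#'
#' Mean methylated fraction over the CpGs contained in the gene body
#' (0-based positions; a CpG at the exclusive end coordinate is outside).
#' Genes without CpGs get 0.
#'
#' @param cpgs data.frame as from [read_cpg_table()].
#' @param genes annotation data.frame.
#' @return named numeric vector over `genes$gene_id`.
#' @export
gene_level_meth <- function(cpgs, genes) {
  abort_if(nrow(genes) == 0, "empty gene list")
  vals <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  if (nrow(cpgs) == 0) return(vals)
  sites <- GenomicRanges::GRanges(
    seqnames = cpgs$chrom,
    ranges = IRanges::IRanges(start = cpgs$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(ranges_of(genes), sites,
                                      ignore.strand = TRUE)
  if (length(hits) > 0) {
    means <- tapply(cpgs$meth_fraction[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), mean)
    vals[as.integer(names(means))] <- as.numeric(means)
  }
  vals
}

#' Read a one-to-one ortholog map
#'
#' @param path two-column TSV (source gene id, target gene id), no header.
#' @return data.frame with columns from, to.
#' @export
read_ortholog_map <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  abort_if(ncol(dt) < 2L, "ortholog map needs two columns")
  map <- data.frame(from = as.character(dt[[1]]), to = as.character(dt[[2]]),
                    stringsAsFactors = FALSE)
  abort_if(anyDuplicated(map$from) > 0 || anyDuplicated(map$to) > 0,
           "ortholog map is not one-to-one")
  map
}

#' Map a gene-level vector onto human ortholog ids
#'
#' Mouse gene ids are replaced by their one-to-one human orthologs; mouse
#' genes absent from the map are dropped. Human vectors pass through
#' unchanged.
#'
#' @param values named numeric vector (names = gene ids).
#' @param species species of the vector.
#' @param ortho ortholog map as from [read_ortholog_map()] (from = mouse id,
#'   to = human id), or NULL for human input.
#' @return named numeric vector keyed by human gene ids.
#' @export
map_orthologs <- function(values, species, ortho = NULL) {
  if (identical(species, "human")) return(values)
  abort_if(is.null(ortho), "ortholog map required for non-human input")
  idx <- match(names(values), ortho$from)
  keep <- !is.na(idx)
  out <- stats::setNames(unname(values[keep]), ortho$to[idx[keep]])
  abort_if(anyDuplicated(names(out)) > 0, "duplicate target id after ortholog mapping")
  out
}

#' Assemble per-sample gene vectors into a GeneMatrix
#'
#' Rows follow the order of `samples` (the sample sheet); columns are the
#' union of gene ids. A gene absent from a sample's vector is recorded as
#' missing (NA), distinct from an observed 0. Genes whose value is zero or
#' missing in every sample of some \{dataset x layer\} stratum are dropped
#' matrix-wide, mirroring the discard of genes never covered by a peak.
#'
#' @param vectors list of named numeric vectors, one per sample, in
#'   sample-sheet order.
#' @param samples sample-sheet data.frame (needs sample_id, donor_id,
#'   species, tissue, layer, dataset, age_years; optionally diet).
#' @param drop_all_zero drop genes all-zero/missing within some stratum.
#' @return a `GeneMatrix`: list(values = samples x genes matrix,
#'   samples = data.frame, genes = character()).
#' @export
assemble_matrix <- function(vectors, samples, drop_all_zero = TRUE) {
  stopifnot(length(vectors) == nrow(samples))
  genes <- sort(unique(unlist(lapply(vectors, names))))
  values <- matrix(NA_real_, nrow = length(vectors), ncol = length(genes),
                   dimnames = list(samples$sample_id, genes))
  for (i in seq_along(vectors)) {
    v <- vectors[[i]]
    values[i, names(v)] <- unname(v)
  }
  gm <- new_gene_matrix(values, samples)
  if (drop_all_zero) gm <- drop_uncovered_genes(gm) else gm
}

new_gene_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), nrow(values) == nrow(samples))
  abort_if(anyDuplicated(colnames(values)) > 0, "duplicate gene ids")
  if (!"diet" %in% names(samples)) samples$diet <- "unknown"
  structure(list(values = values, samples = samples,
                 genes = colnames(values)),
            class = "GeneMatrix")
}

#' @export
print.GeneMatrix <- function(x, ...) {
  cat("GeneMatrix:", nrow(x$values), "samples x", ncol(x$values), "genes;",
      length(unique(x$samples$donor_id)), "donors;",
      "layers:", paste(sort(unique(x$samples$layer)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.GeneMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  new_gene_matrix(x$values[i, j, drop = FALSE],
                  x$samples[i, , drop = FALSE])
}

strata_of <- function(samples) {
  paste(samples$dataset, samples$layer, sep = "|")
}

drop_uncovered_genes <- function(gm) {
  strata <- strata_of(gm$samples)
  dead <- rep(FALSE, ncol(gm$values))
  for (s in unique(strata)) {
    block <- gm$values[strata == s, , drop = FALSE]
    dead <- dead | apply(block, 2L, function(col) all(is.na(col) | col == 0))
  }
  gm[, !dead]
}

#' Write / read a GeneMatrix as TSV with a sample-sheet sidecar
#'
#' @param gm a GeneMatrix.
#' @param prefix file prefix; writes `<prefix>_values.tsv` (sample_id +
#'   one column per gene) and `<prefix>_samples.tsv`.
#' @return the prefix, invisibly.
#' @export
write_gene_matrix <- function(gm, prefix) {
  vals <- data.table::data.table(sample_id = rownames(gm$values))
  vals <- cbind(vals, data.table::as.data.table(gm$values))
  data.table::fwrite(vals, paste0(prefix, "_values.tsv"), sep = "\t")
  data.table::fwrite(gm$samples, paste0(prefix, "_samples.tsv"), sep = "\t")
  invisible(prefix)
}

#' @rdname write_gene_matrix
#' @export
read_gene_matrix <- function(prefix) {
  vals <- data.table::fread(paste0(prefix, "_values.tsv"), sep = "\t")
  samples <- as.data.frame(data.table::fread(paste0(prefix, "_samples.tsv"),
                                             sep = "\t"))
  m <- as.matrix(vals[, -1])
  rownames(m) <- vals[[1]]
  stopifnot(identical(rownames(m), samples$sample_id))
  new_gene_matrix(m, samples)
}
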