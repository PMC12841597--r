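test_that("narrowPeak writer emits the canonical 10-column line and round-trips", {
  path <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(data.frame(chrom = "chr1", start = 100, end = 200,
                              score = 500), path)
  expect_identical(readLines(path), "chr1\t100\t200\t.\t500\t.\t0\t-1\t-1\t-1")

  peaks <- read_narrowpeak(path)
  expect_equal(peaks$start, 100)
  expect_equal(peaks$end, 200)
  expect_equal(peaks$score, 500)

  # empty record list -> empty, readable file
  empty <- tempfile()
  write_narrowpeak(data.frame(chrom = character(), start = integer(),
                              end = integer(), score = numeric()), empty)
  expect_equal(nrow(read_narrowpeak(empty)), 0)

  # multi-record round trip preserves coordinates and scores
  rec <- data.frame(chrom = c("chr2", "chr1", "chr1"),
                    start = c(10L, 500L, 0L), end = c(400L, 900L, 100L),
                    score = c(12.25, 800, 3.5))
  p2 <- tempfile()
  write_narrowpeak(rec, p2)
  back <- read_narrowpeak(p2)
  o <- order(rec$chrom, rec$start)
  expect_equal(back$start, rec$start[o])
  expect_equal(back$score, rec$score[o])
})

test_that("malformed narrowPeak input errors name the offending line", {
  path <- tempfile()
  writeLines(c("chr1\t1\t2\t.\t5\t.\t0\t-1\t-1\t-1", "chr1\t10\t20"), path)
  expect_error(read_narrowpeak(path), "line 2")
  expect_error(write_narrowpeak(
    data.frame(chrom = "chr1", start = -5, end = 10, score = 1), tempfile()),
    "negative")
})

test_that("CpG table IO validates fractions and round-trips", {
  rec <- data.frame(chrom = "chr1", pos = c(10L, 20L),
                    meth_fraction = c(0.2, 0.8), coverage = c(30L, 12L))
  path <- tempfile()
  write_cpg_table(rec, path)
  back <- read_cpg_table(path)
  expect_equal(back$meth_fraction, c(0.2, 0.8))
  expect_equal(back$coverage, c(30L, 12L))

  bad <- tempfile()
  writeLines("chr1\t10\t1.2\t30", bad)
  expect_error(read_cpg_table(bad), "fraction")
  expect_error(write_cpg_table(
    data.frame(chrom = "chr1", pos = 1L, meth_fraction = -0.1, coverage = 1L),
    tempfile()), "fraction")
})

test_that("gene annotations unify GTF and BED to 0-based half-open autosomes", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t101\t200\t.\t+\t.\tgene_id "gA";',
    'chrX\tsrc\tgene\t500\t900\t.\t-\t.\tgene_id "gX";',
    'chr2\tsrc\tgene\t1\t50\t.\t+\t.\tgene_id "gB";'), gtf)
  ann <- read_gene_annotation(gtf, "human")
  expect_setequal(ann$gene_id, c("gA", "gB"))  # chrX dropped
  expect_equal(ann$start[ann$gene_id == "gA"], 100)  # 1-based -> 0-based
  expect_equal(ann$end[ann$gene_id == "gA"], 200)

  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tgeneA", bed)
  annb <- read_gene_annotation(bed, "mouse")
  expect_equal(annb$start, 100)
  expect_equal(annb$end, 200)

  dup <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t10\tg1", "chr2\t1\t10\tg1"), dup)
  expect_error(read_gene_annotation(dup, "human"), "duplicate")
})

test_that("gene-level ChIP aggregation is the unweighted mean of overlapping peaks", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 100, end = 200)
  peaks <- data.frame(chrom = "chr1", start = c(150, 190), end = c(160, 250),
                      score = c(10, 30))
  expect_equal(unname(gene_level_chip(peaks, genes)), 20)

  # no overlapping peak -> 0, and half-open: peak ending at gene start misses
  far <- data.frame(chrom = "chr1", start = c(0, 300), end = c(100, 400),
                    score = c(99, 99))
  expect_equal(unname(gene_level_chip(far, genes)), 0)

  # one peak spanning two genes contributes to both means
  two <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                    start = c(100, 250), end = c(200, 350))
  spanning <- data.frame(chrom = "chr1", start = 150, end = 300, score = 40)
  expect_equal(unname(gene_level_chip(spanning, two)),
               unname(brute_force_chip(spanning, two)))
  expect_equal(unname(gene_level_chip(spanning, two)), c(40, 40))

  expect_error(gene_level_chip(peaks, genes[0, ]), "empty gene list")
})

test_that("gene-level methylation averages contained CpGs with half-open bounds", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 0, end = 100)
  cpgs <- data.frame(chrom = "chr1", pos = c(10, 20, 100),
                     meth_fraction = c(0.2, 0.8, 1.0), coverage = 10L)
  # CpG at pos == end (exclusive) is outside the gene
  expect_equal(unname(gene_level_meth(cpgs, genes)), 0.5)
  expect_equal(unname(gene_level_meth(cpgs[0, ], genes)), 0)
})

test_that("interval aggregation agrees with a brute-force overlap scan", {
  set.seed(42)
  for (rep in 1:5) {
    genes <- data.frame(
      gene_id = sprintf("g%02d", 1:20),
      chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
      start = sample(0:500, 20))
    genes$end <- genes$start + sample(20:200, 20, replace = TRUE)
    peaks <- data.frame(
      chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
      start = sample(0:600, 100, replace = TRUE))
    peaks$end <- peaks$start + sample(5:100, 100, replace = TRUE)
    peaks$score <- runif(100, 0, 1000)
    expect_equal(gene_level_chip(peaks, genes), brute_force_chip(peaks, genes))

    cpgs <- data.frame(chrom = sample(c("chr1", "chr2"), 80, replace = TRUE),
                       pos = sample(0:700, 80, replace = TRUE),
                       meth_fraction = runif(80), coverage = 5L)
    expect_equal(gene_level_meth(cpgs, genes), brute_force_meth(cpgs, genes))
  }
})

test_that("ortholog mapping renames, drops unmapped genes and keeps values", {
  ortho <- data.frame(from = c("Mg1", "Mg2"), to = c("Hg1", "Hg2"))
  v <- c(Mg1 = 5, Mg2 = 7, Mg3 = 9)
  out <- map_orthologs(v, "mouse", ortho)
  expect_equal(out, c(Hg1 = 5, Hg2 = 7))          # Mg3 dropped
  expect_setequal(unname(out), c(5, 7))           # value multiset preserved
  expect_identical(map_orthologs(v, "human"), v)  # human passes through

  bad <- data.frame(from = c("Mg1", "Mg2"), to = c("Hg1", "Hg1"))
  expect_error(map_orthologs(v, "mouse", bad), "duplicate target")
})

test_that("matrix assembly drops stratum-wide-zero genes and keeps sheet order", {
  samples <- make_samples(3)
  vectors <- list(c(g1 = 0, g2 = 1, g3 = 0),
                  c(g1 = 0, g2 = 2, g3 = 0),
                  c(g1 = 0, g2 = 0, g3 = 4))
  gm <- assemble_matrix(vectors, samples)
  expect_setequal(gm$genes, c("g2", "g3"))        # g1 zero everywhere
  expect_identical(rownames(gm$values), samples$sample_id)

  # absent gene is missing (NA), distinct from observed zero
  v2 <- list(c(g1 = 1, g2 = 0), c(g1 = 2, g2 = 3))
  gm2 <- assemble_matrix(c(v2, list(c(g1 = 3, g2 = 1, g4 = 2))),
                         make_samples(3))
  expect_true(is.na(gm2$values[1, "g4"]))
  expect_equal(gm2$values[1, "g2"], 0)
})

test_that("a GeneMatrix round-trips through its TSV serialization", {
  samples <- make_samples(4, layer = "DNAm")
  m <- matrix(c(runif(14), NA, 0.5), 4, 4,
              dimnames = list(samples$sample_id, paste0("g", 1:4)))
  gm <- toy_gene_matrix(m, samples)
  prefix <- tempfile("gmio")
  write_gene_matrix(gm, prefix)
  back <- read_gene_matrix(prefix)
  expect_equal(back$values, gm$values)
  expect_equal(back$samples$donor_id, gm$samples$donor_id)
  expect_identical(back$genes, gm$genes)
})
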