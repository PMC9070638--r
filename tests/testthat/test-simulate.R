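test_that("genome simulation is seed-reproducible with the stated GC", {
  spec <- simulation_spec(seed = 5, chrom_lengths = c(c1 = 100000L),
                          gc = 0.5)
  g1 <- simulate_genome(spec)
  g2 <- simulate_genome(spec)
  expect_identical(unclass(g1), unclass(g2))
  bases <- table(strsplit(unclass(g1)[["c1"]], "")[[1]])
  gc_obs <- sum(bases[c("G", "C")]) / sum(bases)
  expect_lt(abs(gc_obs - 0.5), 0.02)
  at_only <- simulate_genome(simulation_spec(seed = 1, gc = 0,
                                             chrom_lengths = c(c1 = 5000L)))
  expect_false(grepl("[GC]", unclass(at_only)[["c1"]]))
})

test_that("simulated CDSs start with ATG, end at a stop, no internal stop", {
  spec <- simulation_spec(seed = 8, chrom_lengths = c(chr1 = 80000L))
  ann <- simulate_annotation(simulate_genome(spec), spec)
  for (g in ann$genes$genes$gene_id) {
    cd <- ann$genes$cds[ann$genes$cds$gene_id == g, ]
    cd <- cd[order(cd$start), ]
    chunks <- ncpep:::.extract_seq(ann$genome, cd$chrom, cd$start, cd$end,
                                   "+")
    sense <- if (cd$strand[1] == "+") paste(chunks, collapse = "") else
      paste(rev(vapply(chunks, ncpep:::.revcomp, character(1))),
            collapse = "")
    aa <- translate_frame(sense, "+1")
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 2, nchar(aa) - 1), fixed = TRUE))
  }
})

test_that("planting in an absent region type is an error", {
  spec <- simulation_spec(seed = 4, chrom_lengths = c(chr1 = 60000L),
                          n_cds_exons_range = c(1L, 1L),  # no introns
                          planted = c(NCP_intron = 3L))
  ann <- simulate_annotation(simulate_genome(spec), spec)
  expect_error(plant_peptides(ann$genome, ann$genes, spec),
               "NCP_intron")
})

test_that("planted peptides re-extract from their recorded locus", {
  spec <- simulation_spec(seed = 12, chrom_lengths = c(chr1 = 120000L),
                          planted = c(CP = 4L, NCP_intron = 4L,
                                      NCP_intergenic = 12L))
  ann <- simulate_annotation(simulate_genome(spec), spec)
  pl <- plant_peptides(ann$genome, ann$genes, spec)
  ext <- ncpep:::.extract_seq(pl$genome, pl$truth$chrom, pl$truth$start,
                              pl$truth$end, pl$truth$strand)
  back <- vapply(ext, function(x) translate_frame(x, "+1"), character(1),
                 USE.NAMES = FALSE)
  expect_identical(back, pl$truth$peptide)
})

test_that("full detection puts every planted peptide in every sample", {
  spec <- simulation_spec(seed = 30, chrom_lengths = c(chr1 = 100000L),
                          planted = c(NCP_intergenic = 15L),
                          detection_prob = 1, n_decoys = 3L)
  ann <- simulate_annotation(simulate_genome(spec), spec)
  pl <- plant_peptides(ann$genome, ann$genes, spec)
  ids <- simulate_identifications(pl$truth, spec, pl$genome)
  for (s in spec$samples) {
    expect_true(all(pl$truth$peptide %in% ids$Peptide[ids$Sample == s]))
  }
  # decoys are genome-absent: they never place in the six-frame database
  db <- build_sixframe_db(pl$genome)
  loc <- locate_peptides(attr(ids, "decoys"), db)
  expect_true(all(loc$peptides$locus_status == "unplaced"))
  # deterministic given the spec seed
  ids2 <- simulate_identifications(pl$truth, spec, pl$genome)
  expect_identical(ids, ids2)
})

test_that("rho = 1 forces every intergenic plant into a SNP flank", {
  spec <- simulation_spec(seed = 14, chrom_lengths = c(chr1 = 200000L),
                          planted = c(NCP_intergenic = 20L), rho = 1,
                          n_snps = 4L)
  ann <- simulate_annotation(simulate_genome(spec), spec)
  snps <- simulate_snps(ann$genome, spec)
  flanks <- snp_flanks(snps, chrom_lengths(ann$genome), spec$flank_bp)
  pl <- plant_peptides(ann$genome, ann$genes, spec, flanks = flanks)
  expect_true(all(pl$truth$in_flank))
})

test_that("uniform placement sets match flank coverage; rho = 1 is total", {
  lens <- c(c1 = 2000000L, c2 = 1000000L)
  flanks <- data.frame(chrom = c("c1", "c2"),
                       start = c(0L, 0L), end = c(300000L, 150000L))
  coverage <- sum(flanks$end - flanks$start) / sum(lens)
  spec <- simulation_spec(seed = 1)
  pl <- simulate_placement_set(lens, 2000L, spec, seed = 77L)
  in_flank <- ncpep:::.count_flank_overlaps(pl, flanks) / nrow(pl)
  expect_lt(abs(in_flank - coverage), 0.03)
  forced <- simulate_placement_set(lens, 100L, spec, flanks = flanks,
                                   rho = 1, seed = 78L)
  expect_identical(ncpep:::.count_flank_overlaps(forced, flanks), 100L)
})

test_that("simulated tracks are reproducible and stay on the genome", {
  spec <- simulation_spec(seed = 19, chrom_lengths = c(chr1 = 150000L))
  ann <- simulate_annotation(simulate_genome(spec), spec)
  t1 <- simulate_tracks(ann$genome, NULL, spec)
  t2 <- simulate_tracks(ann$genome, NULL, spec)
  expect_identical(t1, t2)
  lens <- chrom_lengths(ann$genome)
  for (tr in t1) {
    expect_true(all(tr$start >= 0L))
    expect_true(all(tr$end <= lens[tr$chrom]))
  }
})
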