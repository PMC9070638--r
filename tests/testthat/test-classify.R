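# one gene on c1: [100, 400) with a single-exon CDS [150, 350), phase 0
flat_gff <- function(strand = "+") {
  c("##gff-version 3",
    paste("c1", "t", "gene", 101, 400, ".", strand, ".", "ID=g1",
          sep = "\t"),
    paste("c1", "t", "mRNA", 101, 400, ".", strand, ".",
          "ID=g1.t1;Parent=g1", sep = "\t"),
    paste("c1", "t", "exon", 101, 400, ".", strand, ".", "Parent=g1.t1",
          sep = "\t"),
    paste("c1", "t", "CDS", 151, 350, ".", strand, 0, "Parent=g1.t1",
          sep = "\t"))
}

flat_genome <- new_genome(c(c1 = paste(rep("ACGTGA", 1000), collapse = "")))

place <- function(start, end, strand = "+", pep = "p1") {
  data.frame(peptide = pep, chrom = "c1", start = start, end = end,
             strand = strand)
}

test_that("in-frame CDS containment is CP; out-of-frame is NCP_exonic", {
  ann <- read_annotation(write_lines_tmp(flat_gff("+"), ".gff3"),
                         flat_genome)
  cp <- classify_placements(place(150L, 180L), ann,
                            chrom_lengths = chrom_lengths(flat_genome))
  expect_identical(cp$category, "CP")
  expect_identical(cp$gene_id, "g1")
  expect_identical(cp$overlap_bp, 30L)
  shifted <- classify_placements(place(151L, 181L), ann,
                                 chrom_lengths = chrom_lengths(flat_genome))
  expect_identical(shifted$category, "NCP_exonic")
  # antisense in-frame CDS overlap is also non-conventional
  anti <- classify_placements(place(150L, 180L, "-"), ann,
                              chrom_lengths = chrom_lengths(flat_genome))
  expect_identical(anti$category, "NCP_exonic")
})

test_that("upstream window and intergenic calls use the 1-kb rule", {
  ann <- read_annotation(write_lines_tmp(flat_gff("+"), ".gff3"),
                         flat_genome)
  up <- classify_placements(place(50L, 80L), ann,
                            chrom_lengths = chrom_lengths(flat_genome))
  expect_identical(up$category, "NCP_upstream")
  inter <- classify_placements(place(5000L, 5030L), ann,
                               chrom_lengths = chrom_lengths(flat_genome))
  expect_identical(inter$category, "NCP_intergenic")
  expect_true(is.na(inter$gene_id))
  # just beyond the downstream window
  far <- classify_placements(place(1401L, 1431L), ann,
                             chrom_lengths = chrom_lengths(flat_genome))
  expect_identical(far$category, "NCP_intergenic")
  near <- classify_placements(place(1390L, 1420L), ann,
                              chrom_lengths = chrom_lengths(flat_genome))
  expect_identical(near$category, "NCP_downstream")
})

test_that("start codons read from the correct strand", {
  g <- new_genome(c(c1 = "ATGAAATAGGGC"))
  sc <- start_codon(data.frame(chrom = "c1", start = c(0L, 4L),
                               end = c(6L, 10L), strand = "+"), g)
  expect_identical(sc$start_codon, c("ATG", "AAT"))
  expect_identical(sc$is_aug, c(TRUE, FALSE))
  # - strand: first codon is revcomp of the last three bases
  sc2 <- start_codon(data.frame(chrom = "c1", start = 0L, end = 12L,
                                strand = "-"), g)
  expect_identical(sc2$start_codon, "GCC")
  expect_false(sc2$is_aug)
})

test_that("classification partitions all placements and counts strands", {
  ann <- read_annotation(write_lines_tmp(flat_gff("+"), ".gff3"),
                         flat_genome)
  placements <- rbind(place(150L, 180L, pep = "a"),
                      place(50L, 80L, pep = "b"),
                      place(5000L, 5030L, "-", pep = "c"),
                      place(210L, 240L, "-", pep = "d"))
  res <- classify_all(placements, ann, genome = flat_genome)
  expect_identical(sum(res$category_counts), nrow(placements))
  expect_identical(unname(res$strand_counts), c(2L, 2L))
  expect_identical(nrow(res$calls), nrow(placements))
  expect_true(all(c("start_codon", "is_aug") %in% names(res$calls)))
  empty <- classify_all(placements[0, ], ann)
  expect_identical(sum(empty$category_counts), 0L)
})

test_that("planted CP peptides are substrings of their annotated protein", {
  spec <- simulation_spec(seed = 21, chrom_lengths = c(chr1 = 80000L),
                          planted = c(CP = 8L))
  ann <- simulate_annotation(simulate_genome(spec), spec)
  pl <- plant_peptides(ann$genome, ann$genes, spec)
  cls <- classify_all(pl$truth, ann$genes, chrom_lengths =
                        chrom_lengths(pl$genome))
  expect_true(all(cls$calls$category == "CP"))
  for (i in seq_len(nrow(pl$truth))) {
    gene <- cls$calls$gene_id[i]
    cd <- ann$genes$cds[ann$genes$cds$gene_id == gene, ]
    cd <- cd[order(cd$start), ]
    chunks <- ncpep:::.extract_seq(pl$genome, cd$chrom, cd$start, cd$end,
                                   "+")
    sense <- paste(if (cd$strand[1] == "+") chunks else
      rev(vapply(chunks, ncpep:::.revcomp, character(1))), collapse = "")
    protein <- translate_frame(sense, "+1")
    expect_true(grepl(pl$truth$peptide[i], protein, fixed = TRUE))
  }
})
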