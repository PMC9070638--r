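ids_csv <- function(rows) {
  write_lines_tmp(c("Peptide,Sample,z,m/z,Mass,Score", rows), ".csv")
}

test_that("identification CSV parses, strips modifications, rejects junk", {
  path <- ids_csv(c("PEPTIDE,EL32,2,400.69,799.36,87.2",
                    "PEPT(+15.99)IDE,EL34,1,816.36,815.35,70.0",
                    "AAXB,EL32,2,100.0,198.0,60.0"))
  expect_message(ids <- read_identifications(path), "rejected")
  expect_identical(nrow(ids), 2L)
  expect_identical(ids$peptide, c("PEPTIDE", "PEPTIDE"))
  expect_identical(attr(ids, "n_rejected"), 1L)
  expect_identical(ids$z, c(2L, 1L))
})

test_that("missing mandatory columns are a hard error", {
  path <- write_lines_tmp(c("Peptide,Sample,z", "AAA,EL32,2"), ".csv")
  expect_error(read_identifications(path), "Mass")
})

test_that("deduplication is global and per sample", {
  ids <- data.frame(peptide = c("AAA", "AAA", "AAK", "AAA"),
                    sample = c("EL32", "EL32", "EL32", "EL36"))
  d <- deduplicate_peptides(ids)
  expect_identical(d$global, c("AAA", "AAK"))
  expect_identical(d$per_sample$EL32, c("AAA", "AAK"))
  expect_identical(d$per_sample$EL36, "AAA")
  empty <- deduplicate_peptides(data.frame(peptide = character(),
                                           sample = character()))
  expect_length(empty$global, 0L)
})

test_that("monoisotopic masses match hand values and are additive", {
  expect_equal(monoisotopic_mass("G"), 75.03203, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("PEPTIDE"), 799.3600, tolerance = 1e-4)
  expect_error(monoisotopic_mass(""), "empty")
  expect_error(monoisotopic_mass("AB"), "unknown residue")
  # additivity: mass(AB) = mass(A) + mass(B) - water
  set.seed(2)
  for (i in 1:20) {
    a <- random_peptide(sample(3:12, 1))
    b <- random_peptide(sample(3:12, 1))
    expect_equal(monoisotopic_mass(paste0(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("m/z follows (M + z * proton)/z and inverts", {
  expect_equal(theoretical_mz(799.3600, 2), 400.6873, tolerance = 1e-4)
  expect_equal(theoretical_mz(75.03203, 1), 76.03931, tolerance = 1e-4)
  expect_error(theoretical_mz(100, 0), "charge")
  mz <- theoretical_mz(1234.5, 3)
  expect_equal(mz * 3 - 3 * 1.007276, 1234.5, tolerance = 1e-9)
})

test_that("peptides locate at all and only their occurrences", {
  db <- build_sixframe_db(new_genome(c(c1 = "ATGAAATAGGGC")))
  loc <- locate_peptides(c("MK", "G", "QQQ"), db)
  p <- loc$peptides
  expect_identical(p$locus_status[p$peptide == "MK"], "single_locus")
  expect_identical(p$locus_status[p$peptide == "G"], "multi_locus")
  expect_identical(p$locus_status[p$peptide == "QQQ"], "unplaced")
  mk <- loc$placements[loc$placements$peptide == "MK", ]
  expect_identical(mk$start, 0L)
  expect_identical(mk$end, 6L)
  expect_identical(mk$strand, "+")
  expect_identical(p$n_placements[p$peptide == "G"], 2L)
})

test_that("I/L equivalence is off by default and works when enabled", {
  # ATG ATT AAG TAA encodes MIK*
  db <- build_sixframe_db(new_genome(c(c1 = "ATGATTAAGTAA")))
  off <- locate_peptides("MLK", db)
  expect_identical(off$peptides$locus_status, "unplaced")
  on <- locate_peptides("MLK", db, il_equivalent = TRUE)
  expect_identical(on$peptides$locus_status, "single_locus")
  expect_identical(on$placements$start, 0L)
})

test_that("every placement re-extracts and translates to its peptide", {
  set.seed(31)
  seq <- random_dna(3000)
  g <- new_genome(c(c1 = seq))
  db <- build_sixframe_db(g)
  # take real substrings of segments as query peptides
  long <- db[nchar(db$seq) >= 8, ]
  peps <- unique(vapply(sample(nrow(long), 25), function(i) {
    s <- long$seq[i]
    a <- sample(nchar(s) - 6, 1)
    substr(s, a, a + 5)
  }, character(1)))
  loc <- locate_peptides(peps, db)
  pl <- loc$placements
  expect_gt(nrow(pl), 0L)
  ext <- ncpep:::.extract_seq(g, pl$chrom, pl$start, pl$end, pl$strand)
  back <- vapply(ext, function(x) translate_frame(x, "+1"), character(1),
                 USE.NAMES = FALSE)
  expect_identical(back, pl$peptide)
  # placement count equals a brute-force per-segment scan
  for (p in peps) {
    n_brute <- sum(vapply(db$seq, function(s) {
      m <- gregexpr(p, s, fixed = TRUE)[[1]]
      if (m[1] == -1L) 0L else length(m)
    }, integer(1)))
    expect_identical(sum(pl$peptide == p), n_brute)
  }
})

test_that("catalog summaries recompute from known inputs", {
  calls <- data.frame(
    peptide = c("AAAAAAAA", "AAAAAAAAAA", "AAAAAAAAAAAA",  # lengths 8,10,12
                "GGGGG"),
    category = c("NCP_intergenic", "NCP_intron", "NCP_intergenic", "CP"))
  s <- summarize_catalog(calls)
  ncp <- s[s$group == "NCP", ]
  expect_identical(ncp$n, 3L)
  expect_equal(ncp$length_median, 10)
  expect_identical(ncp$frac_below_cutoff, 1)
  expect_equal(ncp$mean_mass, mean(monoisotopic_mass(calls$peptide[1:3])))
  none <- summarize_catalog(calls[calls$category != "CP", ])
  expect_true(is.na(none$length_median[none$group == "CP"]))
})
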