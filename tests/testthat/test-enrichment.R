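test_that("SNP flanks clip to chromosomes and merge when overlapping", {
  lens <- c(c1 = 1000000L)
  f <- snp_flanks(data.frame(chrom = "c1", pos = 50000L), lens)
  expect_identical(c(f$start, f$end), c(40000L, 60001L))
  clipped <- snp_flanks(data.frame(chrom = "c1", pos = 3000L), lens)
  expect_identical(c(clipped$start, clipped$end), c(0L, 13001L))
  merged <- snp_flanks(data.frame(chrom = "c1", pos = c(50000L, 55000L)),
                       lens)
  expect_identical(nrow(merged), 1L)
  expect_identical(c(merged$start, merged$end), c(40000L, 65001L))
})

test_that("SNP tables read 1-based positions", {
  path <- write_lines_tmp(c("chrom\tpos\ttrait", "c1\t50001\tberry_weight"),
                          ".tsv")
  s <- read_snps(path)
  expect_identical(s$pos, 50000L)
  expect_identical(s$trait, "berry_weight")
})

test_that("matched backgrounds preserve per-chromosome counts and lengths", {
  lens <- c(c1 = 100000L, c2 = 50000L)
  pl <- data.frame(chrom = c("c1", "c1", "c1", "c2", "c2"),
                   start = c(10L, 500L, 900L, 40L, 80L),
                   end = c(40L, 560L, 990L, 100L, 170L))
  bg <- matched_background(pl, lens, n_replicates = 20L, seed = 9L)
  for (r in 1:20) {
    rep_r <- bg[bg$replicate == r, ]
    expect_identical(table(rep_r$chrom), table(pl$chrom))
    expect_identical(sort(rep_r$end - rep_r$start),
                     sort(pl$end - pl$start))
    expect_true(all(rep_r$start >= 0L))
    expect_true(all(rep_r$end <= lens[rep_r$chrom]))
  }
  bg2 <- matched_background(pl, lens, n_replicates = 20L, seed = 9L)
  expect_identical(bg, bg2)
  too_long <- data.frame(chrom = "c2", start = 0L, end = 60000L)
  expect_error(matched_background(too_long, lens), "longer")
})

test_that("enrichment test handles the degenerate and symmetric cases", {
  lens <- c(c1 = 100000L)
  flanks <- data.frame(chrom = "c1", start = 0L, end = 1000L)
  inside <- data.frame(chrom = "c1", start = c(10L, 200L), end = c(40L, 230L))
  # all replicates identical to the observed count: sd = 0
  bg_same <- data.frame(replicate = rep(1:10, each = 2),
                        chrom = "c1", start = rep(c(10L, 200L), 10),
                        end = rep(c(40L, 230L), 10))
  r <- enrichment_test(inside, flanks, bg_same)
  expect_true(r$degenerate)
  expect_identical(r$p_empirical, 1)
  expect_identical(r$p_normal, 1)
  # half the replicates land 1 fragment, half 3: mean = observed = 2
  bg_sym <- data.frame(replicate = rep(1:10, each = 3),
                       chrom = "c1",
                       start = c(rep(c(10L, 5000L, 6000L), 5),
                                 rep(c(10L, 200L, 400L), 5)),
                       end = NA_integer_)
  bg_sym$end <- bg_sym$start + 30L
  r2 <- enrichment_test(inside, flanks, bg_sym)
  expect_false(r2$degenerate)
  expect_equal(r2$mu, 2)
  expect_equal(r2$p_normal, 0.5)
  expect_error(enrichment_test(inside, flanks,
                               data.frame(chrom = character(),
                                          start = integer(),
                                          end = integer())),
               "replicate")
})

test_that("p_normal is monotone in the observed count, backgrounds fixed", {
  lens <- c(c1 = 200000L)
  flanks <- data.frame(chrom = "c1", start = 0L, end = 20000L)
  set.seed(41)
  base <- data.frame(chrom = "c1",
                     start = sample.int(180000L, 50L),
                     end = NA_integer_)
  base$end <- base$start + 30L
  bg <- matched_background(base, lens, n_replicates = 50L, seed = 11L)
  p_prev <- Inf
  for (k in c(0L, 10L, 25L, 50L)) {
    pl <- base
    pl$start[seq_len(k)] <- sample.int(19000L, max(k, 1L))[seq_len(k)]
    pl$end <- pl$start + 30L
    r <- enrichment_test(pl, flanks, bg)
    expect_lte(r$p_normal, p_prev + 1e-12)
    p_prev <- r$p_normal
  }
})

test_that("replicate order does not change the result", {
  lens <- c(c1 = 100000L)
  flanks <- data.frame(chrom = "c1", start = 0L, end = 10000L)
  pl <- data.frame(chrom = "c1", start = seq(100L, 90000L, by = 5000L),
                   end = seq(130L, 90030L, by = 5000L))
  bg <- matched_background(pl, lens, n_replicates = 30L, seed = 3L)
  r1 <- enrichment_test(pl, flanks, bg)
  perm <- sample(30L)
  bg2 <- bg
  bg2$replicate <- perm[bg2$replicate]
  r2 <- enrichment_test(pl, flanks, bg2)
  expect_equal(r1$mu, r2$mu)
  expect_equal(r1$sigma, r2$sigma)
  expect_equal(r1$p_normal, r2$p_normal)
  expect_equal(r1$p_empirical, r2$p_empirical)
  expect_identical(sort(r1$replicate_counts), sort(r2$replicate_counts))
})
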