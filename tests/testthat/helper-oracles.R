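# Independent oracles used by the tests. These deliberately avoid the
# package's code paths: their own codon table, their own reverse
# complement, and position-walk coordinate bookkeeping instead of the
# closed-form interval arithmetic.

ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_revcomp <- function(s) {
  comp <- chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB", s)
  paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
}

# stop-to-stop segmentation of all six frames of one chromosome; genomic
# coordinates derived by walking per-codon genomic intervals
oracle_sixframe <- function(seq, chrom) {
  L <- nchar(seq)
  out <- list()
  for (sign in c("+", "-")) {
    s <- if (sign == "+") seq else oracle_revcomp(seq)
    for (k in 0:2) {
      n <- (nchar(s) - k) %/% 3L
      if (n < 1L) next
      cod_start_local <- k + 3L * (seq_len(n) - 1L)  # 0-based, in s
      codons <- substring(s, cod_start_local + 1L, cod_start_local + 3L)
      aa <- unname(ORACLE_CODE[codons])
      aa[is.na(aa)] <- "X"
      # genomic interval of each codon
      if (sign == "+") {
        g_start <- cod_start_local
      } else {
        g_start <- L - cod_start_local - 3L
      }
      is_res <- aa != "*"
      r <- rle(is_res)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in seq_along(r$values)) {
        if (!r$values[j]) next
        idx <- starts[j]:ends[j]
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom,
          frame = paste0(sign, k + 1L),
          start = min(g_start[idx]),
          end = max(g_start[idx]) + 3L,
          strand = sign,
          seq = paste(aa[idx], collapse = ""))
      }
    }
  }
  do.call(rbind, out)
}

# residue masses summed one residue at a time (monoisotopic, Da)
ORACLE_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)

oracle_mass <- function(pep) {
  total <- 18.010565
  for (aa in strsplit(pep, "")[[1L]]) total <- total + ORACLE_MONO[[aa]]
  total
}

oracle_mz <- function(mass, z) mass / z + 1.007276

random_dna <- function(n, p_n = 0) {
  probs <- c(rep((1 - p_n) / 4, 4), p_n)
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = probs), collapse = "")
}

random_peptide <- function(len) {
  paste(sample(names(ORACLE_MONO), len, replace = TRUE), collapse = "")
}

# comparable canonical form of a segment table
segment_key <- function(df) {
  k <- paste(df$chrom, df$frame, df$start, df$end, df$strand, df$seq)
  sort(k)
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small hand-built GFF3: one + strand and one - strand two-exon gene
toy_gff_lines <- function(strand = "+") {
  c("##gff-version 3",
    paste("c1", "test", "gene", 101, 400, ".", strand, ".",
          "ID=g1", sep = "\t"),
    paste("c1", "test", "mRNA", 101, 400, ".", strand, ".",
          "ID=g1.t1;Parent=g1", sep = "\t"),
    paste("c1", "test", "exon", 101, 200, ".", strand, ".",
          "ID=e1;Parent=g1.t1", sep = "\t"),
    paste("c1", "test", "exon", 301, 400, ".", strand, ".",
          "ID=e2;Parent=g1.t1", sep = "\t"),
    paste("c1", "test", "CDS", 151, 200, ".", strand,
          if (strand == "+") 0 else 1,
          "ID=c1cds;Parent=g1.t1", sep = "\t"),
    paste("c1", "test", "CDS", 301, 350, ".", strand,
          if (strand == "+") 1 else 0,
          "ID=c1cds;Parent=g1.t1", sep = "\t"))
}
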