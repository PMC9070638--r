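.CATEGORIES <- c("CP", "NCP_exonic", "NCP_5UTR", "NCP_3UTR", "NCP_intron",
                 "NCP_upstream", "NCP_downstream", "NCP_intergenic")
# NCP feature classes in precedence order (ties broken left to right)
.NCP_CLASSES <- c(NCP_exonic = "cds", NCP_5UTR = "utr5", NCP_3UTR = "utr3",
                  NCP_intron = "introns", NCP_upstream = "upstream",
                  NCP_downstream = "downstream")

# 1-kb windows anchored at each gene's 5' (upstream) or 3' (downstream)
# end, clipped to the chromosome
.gene_windows <- function(genes, chrom_lengths, upstream_bp, downstream_bp) {
  g <- genes$genes
  len <- chrom_lengths[g$chrom]
  up_start <- ifelse(g$strand == "+", g$start - upstream_bp, g$end)
  up_end <- ifelse(g$strand == "+", g$start, g$end + upstream_bp)
  dn_start <- ifelse(g$strand == "+", g$end, g$start - downstream_bp)
  dn_end <- ifelse(g$strand == "+", g$end + downstream_bp, g$start)
  clip <- function(s, e) {
    df <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                     start = pmax(s, 0L), end = pmin(e, len),
                     strand = g$strand)
    df[df$start < df$end, , drop = FALSE]
  }
  list(upstream = clip(up_start, up_end), downstream = clip(dn_start, dn_end))
}

#' Classify peptide placements as CP or NCP with an origin category
#'
#' A placement is a conventional peptide (CP) when its interval lies
#' entirely within a CDS part of a gene on the same strand and is in frame
#' with that CDS (its offset from the phase-adjusted reading frame is 0
#' mod 3). Everything else is a non-conventional peptide (NCP), categorized
#' by the feature class with the largest overlap: out-of-frame or antisense
#' CDS overlap is `NCP_exonic`; then `NCP_5UTR`, `NCP_3UTR`, `NCP_intron`,
#' `NCP_upstream` (within `upstream_bp` of a gene's TSS), and
#' `NCP_downstream`; ties are broken in that precedence order. A placement
#' overlapping no gene feature and no upstream/downstream window is
#' `NCP_intergenic`. Feature overlap (other than the CP frame rule) ignores
#' strand.
#'
#' @param placements data.frame of placements (`peptide, chrom, start, end,
#'   strand`), e.g. from [single_locus_placements()].
#' @param genes a `gene_annotation` object.
#' @param upstream_bp upstream window size anchored at the TSS (default
#'   1000).
#' @param downstream_bp downstream window size anchored at the gene 3' end
#'   (default 1000, mirroring the upstream window).
#' @param chrom_lengths named chromosome lengths, used to clip windows;
#'   defaults to a large bound when omitted.
#' @return data.frame with columns `peptide, chrom, start, end, strand,
#'   category, gene_id, overlap_bp`.
#' @export
classify_placements <- function(placements, genes, upstream_bp = 1000L,
                                downstream_bp = 1000L,
                                chrom_lengths = NULL) {
  n <- nrow(placements)
  out <- placements[, c("peptide", "chrom", "start", "end", "strand")]
  out$category <- rep("NCP_intergenic", n)
  out$gene_id <- rep(NA_character_, n)
  out$overlap_bp <- rep(0L, n)
  if (n == 0L) return(out)

  if (is.null(chrom_lengths)) {
    chrom_lengths <- setNames(
      rep(.Machine$integer.max, length(unique(placements$chrom))),
      unique(placements$chrom))
    chrom_lengths[genes$genes$chrom] <- .Machine$integer.max
  }
  win <- .gene_windows(genes, chrom_lengths, upstream_bp, downstream_bp)
  feats <- list(cds = genes$cds, utr5 = genes$utr5, utr3 = genes$utr3,
                introns = genes$introns, upstream = win$upstream,
                downstream = win$downstream)

  pep_gr <- .gr0(out, use_strand = TRUE)

  # CP: same-strand, within a CDS part, in frame
  if (nrow(genes$cds) > 0L) {
    cds_gr <- .gr0(genes$cds, use_strand = TRUE)
    hits <- GenomicRanges::findOverlaps(pep_gr, cds_gr, type = "within",
                                        ignore.strand = FALSE)
    if (length(hits) > 0L) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      cd <- genes$cds[si, ]
      plus <- cd$strand == "+"
      inframe <- ifelse(
        plus,
        (out$start[qi] - (cd$start + cd$phase)) %% 3L == 0L,
        ((cd$end - cd$phase) - out$end[qi]) %% 3L == 0L)
      cp <- qi[inframe]
      if (length(cp) > 0L) {
        first <- !duplicated(cp)
        out$category[cp[first]] <- "CP"
        out$gene_id[cp[first]] <- cd$gene_id[inframe][first]
        out$overlap_bp[cp[first]] <-
          (out$end - out$start)[cp[first]]
      }
    }
  }

  # NCP categories by largest feature overlap (strand ignored)
  todo <- which(out$category != "CP")
  if (length(todo) > 0L) {
    width <- matrix(0L, nrow = n, ncol = length(.NCP_CLASSES),
                    dimnames = list(NULL, names(.NCP_CLASSES)))
    gene_of <- matrix(NA_character_, nrow = n, ncol = length(.NCP_CLASSES))
    for (j in seq_along(.NCP_CLASSES)) {
      f <- feats[[.NCP_CLASSES[[j]]]]
      if (is.null(f) || nrow(f) == 0L) next
      f_gr <- .gr0(f)
      hits <- GenomicRanges::findOverlaps(pep_gr, f_gr,
                                          ignore.strand = TRUE)
      if (length(hits) == 0L) next
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      w <- pmin(out$end[qi], f$end[si]) - pmax(out$start[qi], f$start[si])
      best <- tapply(seq_along(qi), qi, function(ii) ii[which.max(w[ii])])
      idx <- as.integer(names(best))
      width[idx, j] <- w[unlist(best)]
      gene_of[idx, j] <- f$gene_id[si[unlist(best)]]
    }
    for (i in todo) {
      if (any(width[i, ] > 0L)) {
        j <- which.max(width[i, ])  # first max = precedence order
        out$category[i] <- names(.NCP_CLASSES)[j]
        out$gene_id[i] <- gene_of[i, j]
        out$overlap_bp[i] <- width[i, j]
      }
    }
  }
  out
}

#' Start codon of a peptide placement
#'
#' Returns the first codon of each placement's genomic span (the reverse
#' complement of the last three bases for - strand placements) and whether
#' it is ATG. A codon containing a non-ACGT base is reported as-is with
#' `is_aug = FALSE`.
#'
#' @param placements data.frame with `chrom, start, end, strand`.
#' @param genome an `ncp_genome`.
#' @return data.frame with columns `start_codon` and `is_aug`.
#' @export
start_codon <- function(placements, genome) {
  if (nrow(placements) == 0L) {
    return(data.frame(start_codon = character(), is_aug = logical()))
  }
  plus <- placements$strand == "+"
  s <- ifelse(plus, placements$start, placements$end - 3L)
  codon <- .extract_seq(genome, placements$chrom, s, s + 3L,
                        ifelse(plus, "+", "-"))
  data.frame(start_codon = codon, is_aug = codon == "ATG")
}

#' Classify all single-locus peptides and tabulate categories and strands
#'
#' @param located a `located_peptides` object or a placements data.frame.
#' @param genes a `gene_annotation` object.
#' @param genome optional `ncp_genome`; when given, start codons are
#'   appended to the calls.
#' @param upstream_bp,downstream_bp window sizes passed to
#'   [classify_placements()].
#' @param chrom_lengths named chromosome lengths (derived from `genome`
#'   when given).
#' @return list with `calls` (one row per peptide), `category_counts`
#'   (named integer vector over all categories), and `strand_counts`
#'   (sense/antisense, i.e. + and - placements).
#' @export
classify_all <- function(located, genes, genome = NULL,
                         upstream_bp = 1000L, downstream_bp = 1000L,
                         chrom_lengths = NULL) {
  placements <- if (inherits(located, "located_peptides")) {
    single_locus_placements(located)
  } else located
  if (!is.null(genome) && is.null(chrom_lengths)) {
    chrom_lengths <- chrom_lengths(genome)
  }
  calls <- classify_placements(placements, genes, upstream_bp,
                               downstream_bp, chrom_lengths)
  if (!is.null(genome)) {
    calls <- cbind(calls, start_codon(calls, genome))
  }
  category_counts <- table(factor(calls$category, levels = .CATEGORIES))
  strand_counts <- table(factor(calls$strand, levels = c("+", "-")))
  list(calls = calls,
       category_counts = setNames(as.integer(category_counts),
                                  names(category_counts)),
       strand_counts = setNames(as.integer(strand_counts),
                                c("sense", "antisense")))
}
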