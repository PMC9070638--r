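#' Read a genome from a FASTA file
#'
#' Loads every record of a FASTA file into an in-memory genome: an ordered,
#' named set of uppercase nucleotide sequences. Record ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @return an object of class `ncp_genome`: a named character vector of
#'   uppercase sequences, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGT"), fa)
#' g <- read_genome(fa)
#' chrom_lengths(g)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  new_genome(setNames(toupper(as.character(seqs)), ids))
}

#' Construct a genome object from named sequences
#'
#' @param seqs named character vector of nucleotide sequences.
#' @return an `ncp_genome` object.
#' @export
new_genome <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            !anyDuplicated(names(seqs)), all(nzchar(names(seqs))))
  structure(toupper(seqs), class = "ncp_genome")
}

#' Chromosome lengths of a genome
#' @param genome an `ncp_genome` or a named character vector of sequences.
#' @return named integer vector of sequence lengths (bp).
#' @export
chrom_lengths <- function(genome) {
  setNames(nchar(unclass(genome)), names(genome))
}

#' Write a genome to FASTA
#' @param genome an `ncp_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' @export
print.ncp_genome <- function(x, ...) {
  cat("ncp_genome with", length(x), "chromosome(s);",
      format(sum(chrom_lengths(x)), big.mark = ","), "bp total\n")
  invisible(x)
}

# extract genomic DNA at a 0-based half-open interval, minus-strand
# intervals reverse-complemented (vectorized over chrom/start/end)
.extract_seq <- function(genome, chrom, start, end, strand = "+") {
  out <- substring(unclass(genome)[chrom], start + 1L, end)
  neg <- strand == "-"
  if (any(neg)) out[neg] <- .revcomp(out[neg])
  out
}

#' Read a GFF3 gene annotation into gene-level models
#'
#' Parses gene/mRNA/exon/CDS features from a GFF3 file, converts them to
#' 0-based half-open coordinates, and collapses them to gene level: exon and
#' CDS intervals are unioned across isoforms, 5'/3' UTRs are derived as exon
#' minus CDS, and introns as the gaps between merged exons. Features on
#' chromosomes absent from the genome are dropped with a warning, as are
#' genes with unknown strand. Transcripts whose CDS extends outside their
#' exons are skipped with a warning.
#'
#' CDS reading-frame phase is taken from the GFF3 phase column when the gene
#' has a single transcript, and recomputed from the 5'-most CDS base of the
#' merged gene-level CDS otherwise.
#'
#' @param path path to a GFF3 file (1-based inclusive coordinates).
#' @param genome an `ncp_genome` the annotation refers to.
#' @return an object of class `gene_annotation`: a list of data.frames
#'   `genes` (gene_id, chrom, start, end, strand, tss), `exons`, `cds`
#'   (with `phase`), `utr5`, `utr3`, `introns`, all 0-based half-open.
#' @export
read_annotation <- function(path, genome) {
  if (!file.exists(path)) stop("GFF3 not found: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gff)),
                   start = GenomicRanges::start(gff) - 1L,
                   end = GenomicRanges::end(gff),
                   strand = as.character(GenomicRanges::strand(gff)),
                   type = as.character(gff$type),
                   id = if (is.null(gff$ID)) NA_character_ else gff$ID,
                   phase = if (is.null(gff$phase)) NA_integer_ else
                     as.integer(as.character(gff$phase)),
                   stringsAsFactors = FALSE)
  df$parent <- vapply(
    if (is.null(gff$Parent)) replicate(nrow(df), character(), FALSE)
    else as.list(gff$Parent),
    function(p) if (length(p)) p[[1]] else NA_character_, character(1))

  known <- df$chrom %in% names(genome)
  if (!all(known)) {
    warning(sum(!known), " feature(s) on chromosomes absent from genome ",
            "dropped")
    df <- df[known, , drop = FALSE]
  }

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cdss <- df[df$type == "CDS", , drop = FALSE]

  stranded <- genes$strand %in% c("+", "-")
  if (!all(stranded)) {
    warning(sum(!stranded), " gene(s) with unknown strand skipped")
    genes <- genes[stranded, , drop = FALSE]
  }
  if (nrow(genes) == 0L) stop("no usable gene features in ", path)

  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character())
  out <- list(genes = NULL, exons = empty, cds = cbind(empty,
              phase = integer()), utr5 = empty, utr3 = empty,
              introns = empty)
  gene_rows <- list()

  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx_ids <- mrnas$id[!is.na(mrnas$parent) & mrnas$parent == g$id]
    keep_tx <- character()
    for (tx in tx_ids) {
      ex <- exons[!is.na(exons$parent) & exons$parent == tx, , drop = FALSE]
      cd <- cdss[!is.na(cdss$parent) & cdss$parent == tx, , drop = FALSE]
      if (nrow(cd) > 0L && nrow(ex) > 0L) {
        inside <- vapply(seq_len(nrow(cd)), function(j) {
          any(cd$start[j] >= ex$start & cd$end[j] <= ex$end)
        }, logical(1))
        if (!all(inside)) {
          warning("transcript ", tx, " has CDS outside its exons; skipped")
          next
        }
      }
      keep_tx <- c(keep_tx, tx)
    }
    ex <- exons[!is.na(exons$parent) & exons$parent %in% keep_tx, ,
                drop = FALSE]
    cd <- cdss[!is.na(cdss$parent) & cdss$parent %in% keep_tx, ,
               drop = FALSE]
    gm <- .gene_model(g$id, g$chrom, g$start, g$end, g$strand,
                      exons = ex[, c("start", "end")],
                      cds = cd[, c("start", "end")],
                      cds_phase = if (length(keep_tx) == 1L) cd$phase else
                        NULL)
    gene_rows[[length(gene_rows) + 1L]] <- gm$gene
    for (nm in c("exons", "cds", "utr5", "utr3", "introns")) {
      out[[nm]] <- rbind(out[[nm]], gm[[nm]])
    }
  }
  out$genes <- do.call(rbind, gene_rows)
  rownames(out$genes) <- NULL
  structure(out, class = "gene_annotation")
}

# build one gene-level model from raw exon/CDS intervals (0-based).
# Returns list(gene=, exons=, cds=, utr5=, utr3=, introns=).
.gene_model <- function(gene_id, chrom, start, end, strand, exons, cds,
                        cds_phase = NULL) {
  tag <- function(df) {
    if (nrow(df) == 0L) {
      return(data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character()))
    }
    data.frame(gene_id = gene_id, chrom = chrom, start = df$start,
               end = df$end, strand = strand)
  }
  mk <- function(s, e) data.frame(chrom = chrom, start = s, end = e)

  ex <- .reduce0(mk(exons$start, exons$end))
  ex <- ex[order(ex$start), , drop = FALSE]
  cdm <- .reduce0(mk(cds$start, cds$end))
  cdm <- cdm[order(cdm$start), , drop = FALSE]

  # phase: honor file values for a single isoform, else derive cumulatively
  if (!is.null(cds_phase) && nrow(cdm) == nrow(cds) &&
      !anyNA(cds_phase)) {
    ph <- cds_phase[order(cds$start)]
  } else if (nrow(cdm) > 0L) {
    ord <- if (strand == "+") order(cdm$start) else order(-cdm$start)
    w <- (cdm$end - cdm$start)[ord]
    cum <- cumsum(c(0L, head(w, -1L)))
    ph <- integer(nrow(cdm))
    ph[ord] <- (3L - cum %% 3L) %% 3L
  } else {
    ph <- integer(0)
  }

  utr <- .setdiff0(ex, cdm)
  if (nrow(cdm) > 0L && nrow(utr) > 0L) {
    cds_lo <- min(cdm$start); cds_hi <- max(cdm$end)
    before <- utr$end <= cds_lo
    after <- utr$start >= cds_hi
    if (strand == "+") {
      u5 <- utr[before, , drop = FALSE]; u3 <- utr[after, , drop = FALSE]
    } else {
      u5 <- utr[after, , drop = FALSE]; u3 <- utr[before, , drop = FALSE]
    }
  } else {
    u5 <- utr[0, , drop = FALSE]; u3 <- utr[0, , drop = FALSE]
  }

  introns <- if (nrow(ex) > 1L) {
    data.frame(chrom = chrom, start = ex$end[-nrow(ex)],
               end = ex$start[-1L])
  } else {
    data.frame(chrom = character(), start = integer(), end = integer())
  }

  cds_out <- tag(cdm)
  cds_out$phase <- ph
  list(gene = data.frame(gene_id = gene_id, chrom = chrom, start = start,
                         end = end, strand = strand,
                         tss = if (strand == "+") start else end - 1L),
       exons = tag(ex), cds = cds_out, utr5 = tag(u5), utr3 = tag(u3),
       introns = tag(introns))
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "gene(s),", nrow(x$cds),
      "CDS part(s),", nrow(x$introns), "intron(s)\n")
  invisible(x)
}

#' Translation-start anchor positions of annotated genes
#'
#' The TSS of a gene model is the 5' end of its gene interval:
#' `start` for a + strand gene, `end - 1` for a - strand gene
#' (0-based genomic positions).
#'
#' @param genes a `gene_annotation` object or its `genes` data.frame.
#' @return named integer vector of TSS positions, one per gene.
#' @examples
#' df <- data.frame(gene_id = c("a", "b"), chrom = "c1",
#'                  start = c(100L, 100L), end = c(400L, 400L),
#'                  strand = c("+", "-"))
#' tss_of(df)  # 100 and 399
#' @export
tss_of <- function(genes) {
  df <- if (inherits(genes, "gene_annotation")) genes$genes else genes
  if (any(!df$strand %in% c("+", "-"))) {
    stop("tss_of: gene(s) without strand")
  }
  setNames(ifelse(df$strand == "+", df$start, df$end - 1L), df$gene_id)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA (one per gene), exon, and CDS records with 1-based
#' inclusive coordinates and CDS phase. UTRs and introns are not emitted;
#' they are re-derived on read.
#'
#' @param genes a `gene_annotation` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  stopifnot(inherits(genes, "gene_annotation"))
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes$genes))) {
    g <- genes$genes[i, ]
    tx <- paste0(g$gene_id, ".t1")
    rec <- function(type, s, e, phase, attrs) {
      paste(g$chrom, "ncpep", type, s + 1L, e, ".", g$strand, phase, attrs,
            sep = "\t")
    }
    lines <- c(lines,
               rec("gene", g$start, g$end, ".", paste0("ID=", g$gene_id)),
               rec("mRNA", g$start, g$end, ".",
                   paste0("ID=", tx, ";Parent=", g$gene_id)))
    ex <- genes$exons[genes$exons$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, rec("exon", ex$start[j], ex$end[j], ".",
                            paste0("ID=", tx, ".exon", j, ";Parent=", tx)))
    }
    cd <- genes$cds[genes$cds$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(cd))) {
      lines <- c(lines, rec("CDS", cd$start[j], cd$end[j], cd$phase[j],
                            paste0("ID=", tx, ".cds;Parent=", tx)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
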