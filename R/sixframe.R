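#' Translate one reading frame of a nucleotide sequence
#'
#' Translates a nucleotide sequence in one of the six reading frames using
#' the standard genetic code. Stop codons are written as `*`. Any codon
#' containing a base other than A/C/G/T (N or another IUPAC ambiguity code)
#' is translated as `X` -- ambiguity is never resolved, even when the codon
#' family would be unambiguous. A trailing partial codon (< 3 nt) is
#' dropped.
#'
#' @param seq a single nucleotide string.
#' @param frame frame label, one of `"+1","+2","+3","-1","-2","-3"`; minus
#'   frames translate the reverse complement.
#' @return the amino-acid string (may contain `*` and `X`); `""` when fewer
#'   than 3 nt remain after the frame offset.
#' @examples
#' translate_frame("ATGAAATAGGGC", "+1")  # "MK*G"
#' translate_frame("ATGAAATAGGGC", "-1")  # "ALFH"
#' @export
translate_frame <- function(seq, frame) {
  frame <- match.arg(frame, .FRAMES)
  s <- toupper(seq)
  if (substr(frame, 1, 1) == "-") s <- .revcomp(s)
  off <- as.integer(substr(frame, 2, 2)) - 1L
  n <- nchar(s) - off
  if (n < 3L) return("")
  ncod <- n %/% 3L
  starts <- off + 1L + 3L * (seq_len(ncod) - 1L)
  aa <- unname(.GENETIC_CODE[substring(s, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Split a translated frame into stop-to-stop segments with coordinates
#'
#' Splits an amino-acid string produced by [translate_frame()] at stop
#' codons (`*`) and computes the exact genomic interval of each resulting
#' segment. `X` residues never terminate a segment. The first piece of a
#' frame is flagged `leading` (no stop precedes it) and the last piece is
#' flagged `trailing` when the frame does not end at a stop.
#'
#' Coordinate arithmetic, with frame offset `k` (0, 1, 2) and a piece
#' spanning residues `[a, b)` of the translation: a plus frame maps to
#' genomic `[k + 3a, k + 3b)`; a minus frame over the reverse complement of
#' a chromosome of length `L` maps to `[L - k - 3b, L - k - 3a)`.
#'
#' @param aa amino-acid string from [translate_frame()] for this
#'   chromosome/frame.
#' @param frame frame label.
#' @param chrom chromosome id.
#' @param chrom_len chromosome length (bp).
#' @return data.frame with columns `chrom, frame, start, end, strand, seq,
#'   leading, trailing, contains_X` (0-based half-open coordinates).
#' @examples
#' segment_frame("MK*G", "+1", "c1", 12L)
#' @export
segment_frame <- function(aa, frame, chrom, chrom_len) {
  frame <- match.arg(frame, .FRAMES)
  empty <- data.frame(chrom = character(), frame = character(),
                      start = integer(), end = integer(),
                      strand = character(), seq = character(),
                      leading = logical(), trailing = logical(),
                      contains_X = logical())
  if (!nzchar(aa)) return(empty)
  pieces <- strsplit(aa, "*", fixed = TRUE)[[1L]]
  if (length(pieces) == 0L) return(empty)  # aa was all stops
  lens <- nchar(pieces)
  a <- cumsum(c(0L, head(lens, -1L) + 1L))
  b <- a + lens
  ntot <- nchar(aa)
  off <- as.integer(substr(frame, 2, 2)) - 1L
  if (substr(frame, 1, 1) == "+") {
    start <- off + 3L * a
    end <- off + 3L * b
    strand <- "+"
  } else {
    start <- chrom_len - off - 3L * b
    end <- chrom_len - off - 3L * a
    strand <- "-"
  }
  out <- data.frame(chrom = chrom, frame = frame, start = start, end = end,
                    strand = strand, seq = pieces,
                    leading = a == 0L, trailing = b == ntot,
                    contains_X = grepl("X", pieces, fixed = TRUE))
  out[lens > 0L, , drop = FALSE]
}

#' Build the six-frame stop-to-stop peptide database of a genome
#'
#' Translates every chromosome in all six reading frames, splits each frame
#' at stop codons, and records the exact genomic interval of every
#' stop-to-stop segment. Leading and trailing (stop-less) frame ends are
#' kept as segments. Segment ids `SEG1, SEG2, ...` are assigned
#' deterministically in (chromosome order, frame order +1,+2,+3,-1,-2,-3,
#' residue position order).
#'
#' @param genome an `ncp_genome`.
#' @param min_len minimum segment length in residues (default 1; segments
#'   shorter than this are dropped).
#' @return a data.frame of class `sixframe_db` with columns
#'   `id, chrom, frame, start, end, strand, seq, leading, trailing,
#'   contains_X`.
#' @export
build_sixframe_db <- function(genome, min_len = 1L) {
  stopifnot(min_len >= 1L)
  lens <- chrom_lengths(genome)
  parts <- vector("list", length(genome) * 6L)
  k <- 0L
  for (chrom in names(genome)) {
    fwd <- unclass(genome)[[chrom]]
    rev <- .revcomp(fwd)
    for (frame in .FRAMES) {
      s <- if (substr(frame, 1, 1) == "+") fwd else rev
      aa <- .translate_offset(s, as.integer(substr(frame, 2, 2)) - 1L)
      k <- k + 1L
      parts[[k]] <- segment_frame(aa, frame, chrom, lens[[chrom]])
    }
  }
  db <- do.call(rbind, parts)
  db <- db[nchar(db$seq) >= min_len, , drop = FALSE]
  rownames(db) <- NULL
  db <- cbind(id = paste0("SEG", seq_len(nrow(db))), db)
  class(db) <- c("sixframe_db", "data.frame")
  db
}

#' @export
print.sixframe_db <- function(x, ...) {
  cat("sixframe_db:", nrow(x), "stop-to-stop segment(s) on",
      length(unique(x$chrom)), "chromosome(s);",
      sum(x$contains_X), "contain X\n")
  if (nrow(x) > 0L) {
    print.data.frame(utils::head(as.data.frame(x), 5L))
    if (nrow(x) > 5L) cat("... and", nrow(x) - 5L, "more rows\n")
  }
  invisible(x)
}

# translate an already-oriented nucleotide string at a given offset
.translate_offset <- function(s, off) {
  n <- nchar(s) - off
  if (n < 3L) return("")
  ncod <- n %/% 3L
  starts <- off + 1L + 3L * (seq_len(ncod) - 1L)
  aa <- unname(.GENETIC_CODE[substring(s, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Write a six-frame database to FASTA
#'
#' Header dialect (one record per segment):
#' `>SEG{n}|{chrom}|{frame}|{start}|{end}|{strand}|L={0/1}|T={0/1}` with
#' `start`/`end` 0-based half-open and `L`/`T` the leading/trailing flags.
#' Sequences are wrapped at 60 characters.
#'
#' @param db a `sixframe_db` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_db_fasta <- function(db, path) {
  if (nrow(db) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  headers <- sprintf("%s|%s|%s|%d|%d|%s|L=%d|T=%d",
                     db$id, db$chrom, db$frame, db$start, db$end, db$strand,
                     as.integer(db$leading), as.integer(db$trailing))
  x <- Biostrings::AAStringSet(db$seq)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a six-frame database written by [write_db_fasta()]
#' @param path path to the FASTA file.
#' @return a `sixframe_db` data.frame.
#' @export
read_db_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0L) {
    db <- data.frame(id = character(), chrom = character(),
                     frame = character(), start = integer(),
                     end = integer(), strand = character(),
                     seq = character(), leading = logical(),
                     trailing = logical(), contains_X = logical())
    class(db) <- c("sixframe_db", "data.frame")
    return(db)
  }
  f <- strsplit(names(x), "|", fixed = TRUE)
  if (any(lengths(f) != 8L)) stop("malformed six-frame FASTA header")
  g <- function(i) vapply(f, `[[`, character(1), i)
  seqs <- as.character(x)
  db <- data.frame(id = g(1), chrom = g(2), frame = g(3),
                   start = as.integer(g(4)), end = as.integer(g(5)),
                   strand = g(6),
                   seq = seqs,
                   leading = sub("L=", "", g(7)) == "1",
                   trailing = sub("T=", "", g(8)) == "1",
                   contains_X = grepl("X", seqs, fixed = TRUE))
  rownames(db) <- NULL
  class(db) <- c("sixframe_db", "data.frame")
  db
}

#' Export intervals as BED6
#'
#' Writes a 0-based half-open interval table as BED6. Works for six-frame
#' segments (name = segment id), peptide placements (name = peptide), or
#' any data.frame with `chrom, start, end` and optional `strand`.
#'
#' @param df interval data.frame.
#' @param path output path.
#' @param name character vector of feature names (default: `df$id`,
#'   `df$peptide`, or row index).
#' @param score numeric scores (default 0).
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, name = NULL, score = 0) {
  if (is.null(name)) {
    name <- if (!is.null(df$id)) df$id else if (!is.null(df$peptide))
      df$peptide else as.character(seq_len(nrow(df)))
  }
  strand <- if (!is.null(df$strand)) df$strand else "."
  out <- data.frame(df$chrom, df$start, df$end, name, score, strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
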