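#' Read a feature track (BED or labeled TSV)
#'
#' Two dialects are supported. BED: whitespace-delimited, no header,
#' 0-based half-open `chrom start end [name ...]`; the 4th column, when
#' present, becomes the feature label. Labeled TSV: tab-delimited with a
#' header `chrom start end label ...`, 1-based inclusive coordinates,
#' converted to 0-based half-open on read. Malformed lines (non-numeric
#' coordinates, start >= end after conversion) are skipped with a warning;
#' a file with no usable line is an error. When a genome is supplied,
#' intervals extending beyond the chromosome end are clipped with a
#' warning and intervals on unknown chromosomes are dropped.
#'
#' @param path path to the track file.
#' @param format `"auto"` (by file extension), `"bed"`, or `"tsv"`.
#' @param genome optional `ncp_genome` for validation/clipping.
#' @param track_name name stored in the `track_name` attribute (defaults
#'   to the file name).
#' @return data.frame `chrom, start, end, label` (label NA when absent)
#'   with attribute `track_name`.
#' @export
read_track <- function(path, format = c("auto", "bed", "tsv"),
                       genome = NULL, track_name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("track file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else
      "tsv"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (format == "tsv" && length(lines) > 0L) lines <- lines[-1L]  # header
  fields <- strsplit(lines, "\\s+")
  parsed <- lapply(fields, function(f) {
    if (length(f) < 3L) return(NULL)
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e)) return(NULL)
    if (format == "tsv") s <- s - 1L  # 1-based inclusive -> 0-based
    if (s < 0L || s >= e) return(NULL)
    data.frame(chrom = f[1L], start = s, end = e,
               label = if (length(f) >= 4L) f[4L] else NA_character_)
  })
  bad <- sum(vapply(parsed, is.null, logical(1)))
  if (bad > 0L) warning(bad, " malformed track line(s) skipped")
  out <- do.call(rbind, parsed)
  if (is.null(out) || nrow(out) == 0L) {
    stop("no usable intervals in track file: ", path)
  }
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    known <- out$chrom %in% names(lens)
    if (!all(known)) {
      warning(sum(!known), " interval(s) on unknown chromosomes dropped")
      out <- out[known, , drop = FALSE]
    }
    over <- out$end > lens[out$chrom]
    if (any(over)) {
      warning(sum(over), " interval(s) clipped to chromosome end")
      out$end <- pmin(out$end, unname(lens[out$chrom]))
      out <- out[out$start < out$end, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  attr(out, "track_name") <- if (is.null(track_name)) basename(path) else
    track_name
  out
}

#' Overlap peptide placements with a feature track
#'
#' Assigns each peptide to every feature it overlaps by at least
#' `min_overlap_bp` (strand is ignored; tracks are unstranded). A peptide
#' may be assigned to several labels but is counted at most once per
#' label. The overall fraction is the share of peptides overlapping at
#' least one feature.
#'
#' @param placements data.frame with `peptide, chrom, start, end`.
#' @param track data.frame from [read_track()] (or any `chrom, start, end,
#'   label` table in 0-based half-open coordinates).
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return list with `assignments` (data.frame `peptide, chrom,
#'   feature_start, feature_end, label, overlap_bp`), `label_counts`
#'   (named integer vector of distinct peptides per label), `n_overlapping`
#'   and `fraction`.
#' @export
overlap_peptides <- function(placements, track, min_overlap_bp = 1L) {
  total <- length(unique(placements$peptide))
  empty <- data.frame(peptide = character(), chrom = character(),
                      feature_start = integer(), feature_end = integer(),
                      label = character(), overlap_bp = integer())
  if (nrow(placements) == 0L || nrow(track) == 0L) {
    return(list(assignments = empty,
                label_counts = integer(0), n_overlapping = 0L,
                fraction = if (total > 0L) 0 else NA_real_))
  }
  hits <- GenomicRanges::findOverlaps(.gr0(placements), .gr0(track),
                                      minoverlap = min_overlap_bp,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  assignments <- data.frame(
    peptide = placements$peptide[qi],
    chrom = track$chrom[si],
    feature_start = track$start[si],
    feature_end = track$end[si],
    label = if (is.null(track$label)) NA_character_ else track$label[si],
    overlap_bp = pmin(placements$end[qi], track$end[si]) -
      pmax(placements$start[qi], track$start[si]))
  rownames(assignments) <- NULL
  with_label <- assignments[!is.na(assignments$label), , drop = FALSE]
  label_counts <- if (nrow(with_label) > 0L) {
    vapply(split(with_label$peptide, with_label$label),
           function(x) length(unique(x)), integer(1))
  } else integer(0)
  n_over <- length(unique(assignments$peptide))
  list(assignments = assignments, label_counts = label_counts,
       n_overlapping = n_over,
       fraction = if (total > 0L) n_over / total else NA_real_)
}
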