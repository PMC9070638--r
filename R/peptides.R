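# Residue masses (Da). Monoisotopic values follow the convention used by
# MS search engines; average masses provided for the optional average-mass
# summaries. Water is added once per peptide.
.MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
.AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.WATER_MONO <- 18.010565
.WATER_AVG <- 18.01528
.PROTON <- 1.007276
.AA20 <- names(.MONO_MASS)

#' Read an identified-peptide table (PEAKS-export-style CSV)
#'
#' Expects a header row with at least the columns `Peptide`, `Sample`, `z`,
#' `m/z`, and `Mass`; extra columns (e.g. `Score`) are carried through when
#' recognized and otherwise ignored. Modification annotations in
#' parentheses or square brackets are stripped from the sequences. Rows
#' whose stripped sequence contains characters outside the 20 standard
#' residues are rejected; the rejected count is reported via a message and
#' stored in the `n_rejected` attribute.
#'
#' @param path path to the CSV file.
#' @return data.frame with columns `peptide, sample, z, mz, mass, score`
#'   and attribute `n_rejected`.
#' @export
read_identifications <- function(path) {
  if (!file.exists(path)) stop("identification CSV not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Peptide", "Sample", "z", "m/z", "Mass")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("identification CSV lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  seqs <- gsub("\\([^)]*\\)|\\[[^]]*\\]", "", df$Peptide)
  ok <- grepl(paste0("^[", paste(.AA20, collapse = ""), "]+$"), seqs)
  n_rejected <- sum(!ok)
  if (n_rejected > 0L) {
    message(n_rejected, " row(s) with non-standard residues rejected")
  }
  out <- data.frame(peptide = seqs[ok],
                    sample = as.character(df$Sample)[ok],
                    z = as.integer(df$z)[ok],
                    mz = as.numeric(df$`m/z`)[ok],
                    mass = as.numeric(df$Mass)[ok],
                    score = if ("Score" %in% names(df))
                      as.numeric(df$Score)[ok] else NA_real_)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Non-redundant peptide sets, globally and per sample
#'
#' @param ids data.frame from [read_identifications()] (needs `peptide` and
#'   `sample` columns).
#' @return list with `global` (sorted unique sequences) and `per_sample`
#'   (named list of sorted unique sequences per sample).
#' @export
deduplicate_peptides <- function(ids) {
  if (nrow(ids) == 0L) {
    return(list(global = character(), per_sample = list()))
  }
  list(global = sort(unique(ids$peptide)),
       per_sample = lapply(split(ids$peptide, ids$sample),
                           function(x) sort(unique(x))))
}

.residue_sum <- function(seq, table, water) {
  if (length(seq) == 0L) return(numeric(0))
  if (any(!nzchar(seq) | is.na(seq))) stop("empty peptide sequence")
  vapply(strsplit(seq, ""), function(res) {
    m <- table[res]
    if (anyNA(m)) {
      stop("unknown residue(s): ",
           paste(unique(res[is.na(m)]), collapse = ", "))
    }
    sum(m) + water
  }, numeric(1))
}

#' Monoisotopic peptide mass
#' @param seq character vector of peptide sequences (20 standard residues).
#' @return numeric vector of monoisotopic masses (Da), including one water.
#' @examples
#' monoisotopic_mass("PEPTIDE")  # 799.36 Da
#' @export
monoisotopic_mass <- function(seq) .residue_sum(seq, .MONO_MASS, .WATER_MONO)

#' Average peptide mass
#' @param seq character vector of peptide sequences.
#' @return numeric vector of average masses (Da).
#' @export
average_mass <- function(seq) .residue_sum(seq, .AVG_MASS, .WATER_AVG)

#' Theoretical m/z of a peptide ion
#' @param mass neutral monoisotopic mass (Da).
#' @param z charge state (positive integer).
#' @return m/z in thomson: `(mass + z * 1.007276) / z`.
#' @examples
#' theoretical_mz(799.36, 2)
#' @export
theoretical_mz <- function(mass, z) {
  if (any(z < 1L)) stop("charge must be >= 1")
  (mass + z * .PROTON) / z
}

#' Locate peptides in a six-frame database
#'
#' Finds every exact occurrence of each peptide within the segment amino
#' acid sequences and converts each hit to its genomic interval. With
#' `il_equivalent = TRUE`, isoleucine and leucine are treated as
#' interchangeable during matching (MS cannot distinguish them). A hit at
#' residue offset `a` (0-based) in a + strand segment starting at genomic
#' `s` spans `[s + 3a, s + 3a + 3 len)`; in a - strand segment ending at
#' genomic `e` it spans `[e - 3a - 3 len, e - 3a)`.
#'
#' @param peptides character vector of peptide sequences, or a data.frame
#'   with a `peptide` column (unique sequences are searched).
#' @param db a `sixframe_db` data.frame.
#' @param il_equivalent treat I and L as equivalent during matching
#'   (default `FALSE`).
#' @return an object of class `located_peptides`: a list with `peptides`
#'   (data.frame `peptide, n_placements, locus_status` where status is one
#'   of `unplaced`, `single_locus`, `multi_locus`) and `placements`
#'   (data.frame `peptide, segment_id, offset, chrom, start, end, strand,
#'   frame`).
#' @export
locate_peptides <- function(peptides, db, il_equivalent = FALSE) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  peptides <- unique(peptides)
  seg_seq <- db$seq
  pat_seq <- if (il_equivalent) chartr("I", "L", seg_seq) else seg_seq
  pat_pep <- if (il_equivalent) chartr("I", "L", peptides) else peptides

  big <- paste(pat_seq, collapse = "#")
  seg_first <- c(0L, cumsum(nchar(seg_seq) + 1L)[-length(seg_seq)])

  place <- vector("list", length(peptides))
  for (i in seq_along(peptides)) {
    m <- gregexpr(pat_pep[i], big, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    p0 <- as.integer(m) - 1L
    seg <- findInterval(p0, seg_first)
    offset <- p0 - seg_first[seg]
    len <- nchar(peptides[i])
    s <- db$start[seg]; e <- db$end[seg]; neg <- db$strand[seg] == "-"
    gs <- ifelse(neg, e - 3L * offset - 3L * len, s + 3L * offset)
    ge <- ifelse(neg, e - 3L * offset, s + 3L * offset + 3L * len)
    place[[i]] <- data.frame(peptide = peptides[i],
                             segment_id = db$id[seg], offset = offset,
                             chrom = db$chrom[seg], start = gs, end = ge,
                             strand = db$strand[seg], frame = db$frame[seg])
  }
  placements <- do.call(rbind, c(place, list(
    data.frame(peptide = character(), segment_id = character(),
               offset = integer(), chrom = character(), start = integer(),
               end = integer(), strand = character(), frame = character()))))
  rownames(placements) <- NULL
  n <- vapply(place, function(p) if (is.null(p)) 0L else nrow(p), integer(1))
  status <- c("unplaced", "single_locus", "multi_locus")[
    pmin(n, 2L) + 1L]
  out <- list(peptides = data.frame(peptide = peptides, n_placements = n,
                                    locus_status = status),
              placements = placements)
  class(out) <- "located_peptides"
  out
}

#' @export
print.located_peptides <- function(x, ...) {
  tab <- table(factor(x$peptides$locus_status,
                      c("single_locus", "multi_locus", "unplaced")))
  cat("located_peptides:", nrow(x$peptides), "peptide(s) --",
      tab[["single_locus"]], "single-locus,", tab[["multi_locus"]],
      "multi-locus,", tab[["unplaced"]], "unplaced\n")
  invisible(x)
}

#' Placements of single-locus peptides
#'
#' Downstream genomic analyses operate on peptides assigned to exactly one
#' genomic locus; multi-locus and unplaced peptides are reported separately.
#'
#' @param located a `located_peptides` object.
#' @return data.frame of placements restricted to single-locus peptides.
#' @export
single_locus_placements <- function(located) {
  stopifnot(inherits(located, "located_peptides"))
  single <- located$peptides$peptide[
    located$peptides$locus_status == "single_locus"]
  out <- located$placements[located$placements$peptide %in% single, ,
                            drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a classified peptide catalog
#'
#' Per group (CP vs NCP, from the classification categories): peptide
#' count, length median and quartiles, the length below which 90% of the
#' group falls, mean monoisotopic mass (the group's average molecular
#' weight), and the fraction of peptides lighter than `mass_cutoff`.
#'
#' @param calls data.frame with columns `peptide` and `category` (as
#'   produced by [classify_all()]).
#' @param mass_cutoff mass threshold in Da for the light-peptide fraction
#'   (default 2500).
#' @param use_average_mass use average instead of monoisotopic masses.
#' @return data.frame with one row per group (`CP`, `NCP`); empty groups
#'   yield NA rows.
#' @export
summarize_catalog <- function(calls, mass_cutoff = 2500,
                              use_average_mass = FALSE) {
  group <- ifelse(calls$category == "CP", "CP", "NCP")
  massfun <- if (use_average_mass) average_mass else monoisotopic_mass
  rows <- lapply(c("CP", "NCP"), function(g) {
    seqs <- calls$peptide[group == g]
    if (length(seqs) == 0L) {
      return(data.frame(group = g, n = 0L, length_median = NA_real_,
                        length_q25 = NA_real_, length_q75 = NA_real_,
                        length_p90 = NA_real_, mean_mass = NA_real_,
                        frac_below_cutoff = NA_real_))
    }
    len <- nchar(seqs)
    mass <- massfun(seqs)
    data.frame(group = g, n = length(seqs),
               length_median = median(len),
               length_q25 = unname(quantile(len, 0.25)),
               length_q75 = unname(quantile(len, 0.75)),
               length_p90 = unname(quantile(len, 0.90)),
               mean_mass = mean(mass),
               frac_below_cutoff = mean(mass < mass_cutoff))
  })
  do.call(rbind, rows)
}
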