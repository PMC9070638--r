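#' Peptide counts in non-overlapping genomic windows
#'
#' Tiles each chromosome with fixed-width windows (the last window is
#' truncated at the chromosome end) and counts the peptide placements whose
#' genomic start falls in each window.
#'
#' @param placements data.frame with `chrom` and `start` columns.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param window_bp window width in bp (default 1 Mb).
#' @return data.frame `chrom, window, start, end, count` with one row per
#'   window (`window` is the 0-based window index).
#' @export
window_density <- function(placements, chrom_lengths, window_bp = 1e6) {
  window_bp <- as.integer(window_bp)
  rows <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    nwin <- max(1L, as.integer(ceiling(len / window_bp)))
    idx <- seq_len(nwin) - 1L
    starts <- placements$start[placements$chrom == chrom]
    cnt <- tabulate(starts %/% window_bp + 1L, nbins = nwin)
    data.frame(chrom = chrom, window = idx, start = idx * window_bp,
               end = pmin((idx + 1L) * window_bp, len), count = cnt)
  })
  do.call(rbind, rows)
}

#' Intensive (hotspot) regions from window densities
#'
#' Flags windows whose count meets a density threshold, merges adjacent
#' flagged windows into regions, and reports the fraction of peptides that
#' fall inside those regions.
#'
#' @param densities data.frame from [window_density()].
#' @param threshold minimum peptide count for a window to be flagged
#'   (default 2).
#' @return list with `regions` (data.frame `chrom, start, end, n_windows,
#'   count`) and `fraction` (peptides inside regions / total peptides; NA
#'   when there are no peptides).
#' @export
intensive_regions <- function(densities, threshold = 2L) {
  flagged <- densities[densities$count >= threshold, , drop = FALSE]
  total <- sum(densities$count)
  if (nrow(flagged) == 0L) {
    return(list(regions = data.frame(chrom = character(), start = integer(),
                                     end = integer(), n_windows = integer(),
                                     count = integer()),
                fraction = if (total > 0L) 0 else NA_real_))
  }
  # merge runs of adjacent flagged windows per chromosome
  ord <- order(flagged$chrom, flagged$window)
  flagged <- flagged[ord, ]
  new_run <- c(TRUE, flagged$chrom[-1L] != flagged$chrom[-nrow(flagged)] |
                 diff(flagged$window) != 1L)
  run <- cumsum(new_run)
  regions <- do.call(rbind, lapply(split(flagged, run), function(w) {
    data.frame(chrom = w$chrom[1L], start = min(w$start), end = max(w$end),
               n_windows = nrow(w), count = sum(w$count))
  }))
  rownames(regions) <- NULL
  list(regions = regions,
       fraction = if (total > 0L) sum(regions$count) / total else NA_real_)
}

#' Distances between neighboring peptides on each chromosome
#'
#' Sorts placements by genomic start per chromosome and reports the
#' start-to-start distances between consecutive placements, together with
#' the fraction of distances at or below a cutoff. Chromosomes with fewer
#' than two placements contribute no distances.
#'
#' @param placements data.frame with `chrom` and `start`.
#' @param cutoff_bp distance cutoff for the summary fraction (default
#'   500 kb).
#' @return list with `distances` (data.frame `chrom, distance`) and
#'   `fraction` (NA when no distances exist).
#' @export
neighbor_distances <- function(placements, cutoff_bp = 5e5) {
  rows <- lapply(split(placements$start, placements$chrom), sort)
  d <- do.call(rbind, lapply(names(rows), function(chrom) {
    s <- rows[[chrom]]
    if (length(s) < 2L) return(NULL)
    data.frame(chrom = chrom, distance = diff(s))
  }))
  if (is.null(d)) d <- data.frame(chrom = character(), distance = integer())
  list(distances = d,
       fraction = if (nrow(d) > 0L) mean(d$distance <= cutoff_bp) else
         NA_real_)
}

#' Distance from each peptide to the nearest gene TSS
#'
#' The distance from a placement `[start, end)` to a TSS position `t` is 0
#' when the TSS falls within the placement, `start - t` when the TSS lies
#' upstream of the interval, and `t - (end - 1)` when it lies beyond it.
#' The nearest TSS on either strand is used. The fraction of peptides
#' within `cutoff_bp` of a TSS is reported.
#'
#' @param placements data.frame with `chrom, start, end`.
#' @param genes a `gene_annotation` object (or its `genes` data.frame).
#' @param cutoff_bp cutoff for the summary fraction (default 2 kb).
#' @return list with `distances` (numeric, NA where the chromosome has no
#'   gene) and `fraction` (computed over non-NA distances).
#' @export
tss_distances <- function(placements, genes, cutoff_bp = 2000) {
  gdf <- if (inherits(genes, "gene_annotation")) genes$genes else genes
  n <- nrow(placements)
  out <- rep(NA_real_, n)
  if (n == 0L || nrow(gdf) == 0L) {
    return(list(distances = out, fraction = NA_real_))
  }
  tss <- tss_of(gdf)
  tss_by_chrom <- split(unname(tss), gdf$chrom)
  for (chrom in unique(placements$chrom)) {
    tt <- sort(tss_by_chrom[[chrom]])
    if (is.null(tt) || length(tt) == 0L) next
    sel <- which(placements$chrom == chrom)
    s <- placements$start[sel]
    last <- placements$end[sel] - 1L
    d <- vapply(seq_along(sel), function(k) {
      inside <- any(tt >= s[k] & tt <= last[k])
      if (inside) return(0)
      min(abs(tt - s[k]), abs(tt - last[k]))
    }, numeric(1))
    out[sel] <- d
  }
  frac <- if (all(is.na(out))) NA_real_ else
    mean(out[!is.na(out)] <= cutoff_bp)
  list(distances = out, fraction = frac)
}

#' Correlation between peptide count and chromosome length
#'
#' Pearson correlation between per-chromosome placement counts (including
#' zero-count chromosomes) and chromosome lengths, with a two-sided test.
#'
#' @param placements data.frame with a `chrom` column.
#' @param chrom_lengths named chromosome lengths (at least 3 chromosomes).
#' @return list with `r`, `p`, and `n` (number of chromosomes); `r` and `p`
#'   are NA when the counts are constant.
#' @export
count_length_correlation <- function(placements, chrom_lengths) {
  if (length(chrom_lengths) < 3L) {
    stop("count_length_correlation needs at least 3 chromosomes")
  }
  counts <- vapply(names(chrom_lengths), function(chrom) {
    sum(placements$chrom == chrom)
  }, numeric(1))
  if (sd(counts) == 0 || sd(chrom_lengths) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(chrom_lengths)))
  }
  ct <- cor.test(counts, as.numeric(chrom_lengths), method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(chrom_lengths))
}

#' Venn partition of peptide sets across samples
#'
#' For every combination of samples, counts the peptides found in exactly
#' that combination (the Venn partition), plus the pairwise intersection
#' sizes.
#'
#' @param sample_sets named list (>= 2 entries) of peptide sequence
#'   vectors, one per sample.
#' @return list with `venn` (data.frame `samples` -- sample names joined
#'   with `&` -- and `count`) and `pairwise` (data.frame `sample1, sample2,
#'   shared`).
#' @export
stage_overlap <- function(sample_sets) {
  if (length(sample_sets) < 2L) stop("stage_overlap needs >= 2 samples")
  samples <- names(sample_sets)
  sets <- lapply(sample_sets, unique)
  all_pep <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_pep %in% s,
                   logical(length(all_pep)))
  if (length(all_pep) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, samples))
  key <- apply(member, 1L, function(m) paste(samples[m], collapse = "&"))
  combos <- unlist(lapply(seq_along(samples), function(k) {
    utils::combn(samples, k, paste, collapse = "&")
  }))
  counts <- table(factor(key, levels = combos))
  venn <- data.frame(samples = combos, count = as.integer(counts))
  pairs <- utils::combn(samples, 2L)
  pairwise <- data.frame(sample1 = pairs[1L, ], sample2 = pairs[2L, ],
                         shared = apply(pairs, 2L, function(p) {
                           length(intersect(sets[[p[1L]]], sets[[p[2L]]]))
                         }))
  list(venn = venn, pairwise = pairwise)
}
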