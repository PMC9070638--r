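# reverse map: amino acid -> codons (stops excluded from residue coding)
.CODONS_OF <- split(names(Biostrings::GENETIC_CODE),
                    unname(Biostrings::GENETIC_CODE))
.STOPS <- .CODONS_OF[["*"]]
.NONSTOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), .STOPS)

.QTL_TRAITS <- c("berry_weight", "berry_color", "anthocyanins", "tannins",
                 "flowering", "growth", "downy_mildew", "chlorosis",
                 "seed_fresh_weight", "drought_stress",
                 "water_use_efficiency", "leaf_area")

#' Simulation specification for a synthetic peptidogenomic study
#'
#' Bundles every knob of the synthetic-data generator, with defaults that
#' emulate the conditions of a berry-development peptidomics study at desk
#' scale: a small multi-chromosome genome, protein-coding genes with UTRs
#' and introns, a peptide catalog dominated by intergenic NCPs with a
#' length distribution centred near 10-11 residues, three
#' developmental-stage samples with partial per-stage detection, and
#' feature/SNP tracks with a controllable planted association fraction.
#'
#' @param seed integer seed governing every stochastic stage (per-stage
#'   seeds are derived from it by fixed offsets).
#' @param chrom_lengths named chromosome lengths in bp.
#' @param gc GC fraction of the background sequence.
#' @param genes_per_mb gene density used by [simulate_annotation()].
#' @param utr_len_range,intron_len_range,cds_exon_len_range,n_cds_exons_range
#'   gene-structure distributions (uniform over the given ranges).
#' @param planted named integer vector of planted peptide counts per origin
#'   category (names from `CP, NCP_exonic, NCP_5UTR, NCP_3UTR, NCP_intron,
#'   NCP_upstream, NCP_downstream, NCP_intergenic`).
#' @param peptide_len_range planted peptide lengths are drawn from a
#'   discretized log-normal (`len_meanlog`, `len_sdlog`) truncated to this
#'   range (residues).
#' @param len_meanlog,len_sdlog log-normal parameters of the peptide length
#'   distribution (defaults give a median near 10.5 residues).
#' @param samples sample (developmental stage) names.
#' @param detection_prob per-sample Bernoulli detection probability of each
#'   planted peptide.
#' @param n_decoys number of genome-absent decoy peptides added to the
#'   identification table.
#' @param mass_noise_sd Gaussian noise added to observed masses (Da).
#' @param n_snps number of simulated trait-associated SNPs.
#' @param flank_bp SNP flank size (bp) used when planting associations.
#' @param rho planted association fraction: share of intergenic NCP plants
#'   forced into SNP-flanking regions.
#' @param tracks list of per-track settings (`n`, `size_range`) for the
#'   qtl, ltr, sweep, lncrna and reads tracks.
#' @param ... overrides for any of the above.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L,
                            chrom_lengths = c(chr1 = 300000L,
                                              chr2 = 220000L,
                                              chr3 = 160000L),
                            gc = 0.35,
                            genes_per_mb = 60,
                            utr_len_range = c(120L, 250L),
                            intron_len_range = c(100L, 400L),
                            cds_exon_len_range = c(120L, 400L),
                            n_cds_exons_range = c(1L, 3L),
                            planted = c(CP = 15L, NCP_exonic = 5L,
                                        NCP_5UTR = 3L, NCP_3UTR = 2L,
                                        NCP_intron = 8L, NCP_upstream = 6L,
                                        NCP_downstream = 5L,
                                        NCP_intergenic = 150L),
                            peptide_len_range = c(7L, 30L),
                            len_meanlog = log(10.5), len_sdlog = 0.30,
                            samples = c("EL32", "EL34", "EL36"),
                            detection_prob = 0.35,
                            n_decoys = 10L,
                            mass_noise_sd = 0.01,
                            n_snps = 8L, flank_bp = 10000L, rho = 0,
                            tracks = list(
                              qtl = list(n = 12L,
                                         size_range = c(20000L, 60000L)),
                              ltr = list(n = 25L,
                                         size_range = c(3000L, 12000L)),
                              sweep = list(n = 8L,
                                           size_range = c(15000L, 50000L)),
                              lncrna = list(n = 15L,
                                            size_range = c(1000L, 4000L)),
                              reads = list(n = 60L,
                                           size_range = c(2000L, 6000L))),
                            ...) {
  spec <- c(as.list(environment()), list(...))
  spec <- spec[!duplicated(names(spec))]
  stopifnot(all(spec$planted >= 0), spec$rho >= 0, spec$rho <= 1,
            all(spec$chrom_lengths >= 1000))
  class(spec) <- "simulation_spec"
  spec
}

#' Simulate a random genome
#'
#' I.i.d. bases at the GC fraction of the spec; reproducible from the
#' spec's seed.
#'
#' @param spec a `simulation_spec`.
#' @return an `ncp_genome`.
#' @export
simulate_genome <- function(spec) {
  set.seed(spec$seed)
  p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2,
         T = (1 - spec$gc) / 2)
  seqs <- vapply(spec$chrom_lengths, function(len) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  new_genome(seqs)
}

# replace a 0-based half-open slice of one chromosome
.edit_genome <- function(genome, chrom, start, nt) {
  s <- unclass(genome)[[chrom]]
  substr(s, start + 1L, start + nchar(nt)) <- nt
  g <- unclass(genome)
  g[[chrom]] <- s
  new_genome(g)
}

#' Simulate a gene annotation consistent with a genome
#'
#' Lays out non-overlapping genes (spaced so their 1-kb upstream and
#' downstream windows never collide), each with a 5'UTR, one to three CDS
#' exons separated by introns, and a 3'UTR. The genome is rewritten at CDS
#' sites so that every coding sequence starts with ATG, ends with a stop,
#' and contains no internal in-frame stop.
#'
#' @param genome an `ncp_genome` (as built by [simulate_genome()]).
#' @param spec a `simulation_spec`.
#' @return list with `genome` (edited) and `genes` (a `gene_annotation`).
#' @export
simulate_annotation <- function(genome, spec) {
  set.seed(spec$seed + 1L)
  lens <- chrom_lengths(genome)
  min_gap <- 2600L  # keeps 1-kb windows of neighboring genes disjoint
  margin <- 1500L
  runi <- function(r) sample(seq(r[1L], r[2L]), 1L)

  gene_models <- list()
  gid <- 0L
  for (chrom in names(lens)) {
    n_genes <- max(1L, round(spec$genes_per_mb * lens[[chrom]] / 1e6))
    pos <- margin
    placed <- 0L
    while (placed < n_genes) {
      utr5 <- runi(spec$utr_len_range)
      utr3 <- runi(spec$utr_len_range)
      n_ex <- runi(spec$n_cds_exons_range)
      cds_parts <- vapply(seq_len(n_ex), function(i)
        runi(spec$cds_exon_len_range), integer(1))
      extra <- (3L - sum(cds_parts) %% 3L) %% 3L
      cds_parts[n_ex] <- cds_parts[n_ex] + extra
      introns <- if (n_ex > 1L) vapply(seq_len(n_ex - 1L), function(i)
        runi(spec$intron_len_range), integer(1)) else integer(0)
      glen <- utr5 + sum(cds_parts) + sum(introns) + utr3
      if (pos + glen + margin > lens[[chrom]]) break
      gid <- gid + 1L
      strand <- sample(c("+", "-"), 1L)
      gene_models[[gid]] <- list(gene_id = sprintf("g%03d", gid),
                                 chrom = chrom, start = pos,
                                 strand = strand, utr5 = utr5,
                                 utr3 = utr3, cds_parts = cds_parts,
                                 introns = introns)
      pos <- pos + glen + min_gap + sample(0:800, 1L)
      placed <- placed + 1L
    }
    if (placed < n_genes) {
      stop("cannot fit ", n_genes, " genes on ", chrom,
           " (", lens[[chrom]], " bp)")
    }
  }

  ann <- list(genes = NULL, exons = NULL, cds = NULL, utr5 = NULL,
              utr3 = NULL, introns = NULL)
  rows <- list()
  for (gm in gene_models) {
    # transcription-order block lengths; genomic order flips on -
    n_ex <- length(gm$cds_parts)
    ex_tx <- gm$cds_parts
    ex_tx[1L] <- ex_tx[1L] + gm$utr5
    ex_tx[n_ex] <- ex_tx[n_ex] + gm$utr3
    blocks_tx <- integer(0)
    for (i in seq_len(n_ex)) {
      blocks_tx <- c(blocks_tx, ex_tx[i],
                     if (i < n_ex) gm$introns[i] else integer(0))
    }
    blocks_gen <- if (gm$strand == "+") blocks_tx else rev(blocks_tx)
    bounds <- gm$start + cumsum(c(0L, blocks_gen))
    is_exon_tx <- rep(c(TRUE, FALSE), length.out = length(blocks_tx))
    is_exon <- if (gm$strand == "+") is_exon_tx else rev(is_exon_tx)
    ex_start <- bounds[-length(bounds)][is_exon]
    ex_end <- bounds[-1L][is_exon]
    gend <- gm$start + sum(blocks_tx)

    # CDS parts in genomic order
    if (gm$strand == "+") {
      cds_start <- ex_start
      cds_end <- ex_end
      cds_start[1L] <- cds_start[1L] + gm$utr5
      cds_end[n_ex] <- cds_end[n_ex] - gm$utr3
    } else {
      cds_start <- ex_start
      cds_end <- ex_end
      cds_end[n_ex] <- cds_end[n_ex] - gm$utr5   # 5'UTR at genomic right
      cds_start[1L] <- cds_start[1L] + gm$utr3   # 3'UTR at genomic left
    }
    gmod <- .gene_model(gm$gene_id, gm$chrom, gm$start, gend, gm$strand,
                        exons = data.frame(start = ex_start, end = ex_end),
                        cds = data.frame(start = cds_start, end = cds_end),
                        cds_phase = NULL)
    rows[[length(rows) + 1L]] <- gmod
  }
  ann$genes <- do.call(rbind, lapply(rows, `[[`, "gene"))
  for (nm in c("exons", "cds", "utr5", "utr3", "introns")) {
    ann[[nm]] <- do.call(rbind, lapply(rows, `[[`, nm))
    rownames(ann[[nm]]) <- NULL
  }
  rownames(ann$genes) <- NULL
  class(ann) <- "gene_annotation"

  # rewrite the genome at CDS sites: ATG + non-stop codons + stop
  for (g in unique(ann$cds$gene_id)) {
    cd <- ann$cds[ann$cds$gene_id == g, , drop = FALSE]
    cd <- cd[order(cd$start), , drop = FALSE]
    strand <- cd$strand[1L]
    total <- sum(cd$end - cd$start)
    ncod <- total %/% 3L
    codons <- c("ATG",
                sample(setdiff(.NONSTOP_CODONS, "ATG"), ncod - 2L,
                       replace = TRUE),
                sample(.STOPS, 1L))
    sense <- paste(codons, collapse = "")
    # distribute the sense sequence over parts in transcription order
    ord <- if (strand == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
    offset <- 0L
    for (i in ord) {
      w <- cd$end[i] - cd$start[i]
      chunk <- substr(sense, offset + 1L, offset + w)
      offset <- offset + w
      nt <- if (strand == "+") chunk else .revcomp(chunk)
      genome <- .edit_genome(genome, cd$chrom[i], cd$start[i], nt)
    }
  }
  list(genome = genome, genes = ann)
}

# six-frame translations of every chromosome, as one vector of strings
.sixframe_strings <- function(genome) {
  out <- character(0)
  for (chrom in names(genome)) {
    fwd <- unclass(genome)[[chrom]]
    rev <- .revcomp(fwd)
    for (off in 0:2) {
      out <- c(out, .translate_offset(fwd, off), .translate_offset(rev, off))
    }
  }
  out
}

.count_occurrences <- function(peptides, frame_strings) {
  big <- paste(frame_strings, collapse = "#")
  vapply(peptides, function(p) {
    m <- gregexpr(p, big, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1))
}

.sample_peptide_len <- function(spec, max_len = Inf) {
  r <- spec$peptide_len_range
  hi <- min(r[2L], max_len)
  if (hi < r[1L]) return(NA_integer_)
  l <- round(exp(rnorm(1L, spec$len_meanlog, spec$len_sdlog)))
  as.integer(min(max(l, r[1L]), hi))
}

.random_peptide <- function(len) {
  paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

.encode_peptide <- function(pep) {
  paste(vapply(strsplit(pep, "")[[1L]], function(aa) {
    sample(.CODONS_OF[[aa]], 1L)
  }, character(1)), collapse = "")
}

#' Plant peptides of known origin categories into a genome
#'
#' For each requested origin category, samples a landing site inside a
#' region of that category chosen so the classification is unambiguous
#' (the site overlaps exactly one feature class), then rewrites the local
#' genome so that the chosen frame encodes a random peptide with no
#' internal stop. CP plants are placed in frame within a CDS;
#' `NCP_exonic` plants are placed out of frame within a CDS. After
#' editing, each planted sequence is verified to occur exactly once in the
#' six-frame translation of the edited genome; duplicated sequences are
#' re-drawn and re-planted.
#'
#' @param genome an `ncp_genome` (after [simulate_annotation()]).
#' @param genes the matching `gene_annotation`.
#' @param spec a `simulation_spec` (`planted` gives counts per category).
#' @param flanks optional merged SNP-flank intervals; when given, a
#'   fraction `spec$rho` of the intergenic plants is forced inside them.
#' @return list with `genome` (edited) and `truth` (data.frame `peptide,
#'   category, chrom, start, end, strand, gene_id, in_flank`).
#' @export
plant_peptides <- function(genome, genes, spec, flanks = NULL) {
  set.seed(spec$seed + 2L)
  lens <- chrom_lengths(genome)

  win <- .gene_windows(genes, lens, 1000L, 1000L)
  gene_bodies <- genes$genes[, c("chrom", "start", "end")]
  all_feat <- rbind(gene_bodies,
                    win$upstream[, c("chrom", "start", "end")],
                    win$downstream[, c("chrom", "start", "end")])
  chrom_df <- data.frame(chrom = names(lens), start = 50L,
                         end = unname(lens) - 50L)
  intergenic <- .setdiff0(chrom_df, all_feat)

  shrink <- function(df, by = 3L) {
    df$start <- df$start + by
    df$end <- df$end - by
    df[df$start < df$end, , drop = FALSE]
  }
  pools <- list(
    CP = genes$cds,                       # frame-aware sampling below
    NCP_exonic = genes$cds,
    NCP_5UTR = shrink(genes$utr5),
    NCP_3UTR = shrink(genes$utr3),
    NCP_intron = shrink(genes$introns),
    NCP_upstream = shrink(win$upstream, 10L),
    NCP_downstream = shrink(win$downstream, 10L),
    NCP_intergenic = intergenic)

  flank_intergenic <- if (!is.null(flanks) && nrow(flanks) > 0L) {
    gr <- GenomicRanges::intersect(.gr0(intergenic), .gr0(flanks))
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr))
  } else NULL

  occupied <- data.frame(chrom = character(), start = integer(),
                         end = integer())
  overlaps_occupied <- function(chrom, s, e) {
    any(occupied$chrom == chrom & occupied$start < e + 3L &
          occupied$end > s - 3L)
  }

  truth <- list()
  for (cat in names(spec$planted)) {
    k <- spec$planted[[cat]]
    if (k == 0L) next
    pool <- pools[[cat]]
    if (is.null(pool) || nrow(pool) == 0L) {
      stop("no region of type ", cat, " available for planting")
    }
    n_forced <- if (cat == "NCP_intergenic" && !is.null(flank_intergenic) &&
                    spec$rho > 0) ceiling(spec$rho * k) else 0L
    for (j in seq_len(k)) {
      use_pool <- if (j <= n_forced) flank_intergenic else pool
      site <- NULL
      for (try in 1:200) {
        widths <- use_pool$end - use_pool$start
        len <- .sample_peptide_len(spec, max_len = max(widths) %/% 3L)
        if (is.na(len)) break
        fit <- widths >= 3L * len
        if (cat %in% c("CP", "NCP_exonic")) {
          fit <- fit & widths >= 3L * len + 9L  # keep ATG/stop margins
        }
        if (!any(fit)) next
        cand <- use_pool[fit, , drop = FALSE]
        i <- sample(nrow(cand), 1L, prob = cand$end - cand$start)
        r <- cand[i, ]
        if (cat %in% c("CP", "NCP_exonic")) {
          anchor <- if (r$strand == "+") r$start + r$phase else
            r$end - r$phase
          shift <- if (cat == "CP") 0L else sample(1:2, 1L)
          if (r$strand == "+") {
            lo <- anchor + shift + 3L
            hi <- r$end - 3L * len - 3L
            if (hi < lo) next
            m <- sample(0:((hi - lo) %/% 3L), 1L)
            s <- lo + 3L * m
          } else {
            hi <- anchor - shift - 3L
            lo <- r$start + 3L + 3L * len
            if (hi < lo) next
            m <- sample(0:((hi - lo) %/% 3L), 1L)
            e <- hi - 3L * m
            s <- e - 3L * len
          }
          e <- s + 3L * len
          strand <- r$strand
          gene_id <- r$gene_id
        } else {
          s <- r$start + sample(0:(r$end - r$start - 3L * len), 1L)
          e <- s + 3L * len
          strand <- if (!is.null(r$strand) && !is.na(r$strand[1L]) &&
                        cat != "NCP_intergenic") r$strand else
            sample(c("+", "-"), 1L)
          gene_id <- if (!is.null(r$gene_id)) r$gene_id else NA_character_
        }
        if (overlaps_occupied(r$chrom, s, e)) next
        site <- list(chrom = r$chrom, start = s, end = e, strand = strand,
                     gene_id = gene_id, len = len)
        break
      }
      if (is.null(site)) {
        stop("could not place a ", cat, " peptide after 200 tries")
      }
      occupied <- rbind(occupied, data.frame(chrom = site$chrom,
                                             start = site$start,
                                             end = site$end))
      truth[[length(truth) + 1L]] <-
        data.frame(peptide = NA_character_, category = cat,
                   chrom = site$chrom, start = site$start, end = site$end,
                   strand = site$strand, gene_id = site$gene_id,
                   len = site$len)
    }
  }
  truth <- do.call(rbind, truth)

  # write sequences, then enforce six-frame uniqueness by redrawing
  truth$peptide <- vapply(truth$len, .random_peptide, character(1))
  write_plant <- function(genome, row) {
    nt <- .encode_peptide(row$peptide)
    if (row$strand == "-") nt <- .revcomp(nt)
    .edit_genome(genome, row$chrom, row$start, nt)
  }
  for (i in seq_len(nrow(truth))) genome <- write_plant(genome, truth[i, ])
  for (iter in 1:20) {
    occ <- .count_occurrences(truth$peptide, .sixframe_strings(genome))
    dup <- which(occ != 1L | duplicated(truth$peptide) |
                   duplicated(truth$peptide, fromLast = TRUE))
    if (length(dup) == 0L) break
    if (iter == 20L) stop("could not make planted peptides unique")
    for (i in dup) {
      truth$peptide[i] <- .random_peptide(truth$len[i])
      genome <- write_plant(genome, truth[i, ])
    }
  }

  truth$in_flank <- if (!is.null(flanks) && nrow(flanks) > 0L) {
    .gr_hit <- GenomicRanges::findOverlaps(.gr0(truth), .gr0(flanks))
    seq_len(nrow(truth)) %in% S4Vectors::queryHits(.gr_hit)
  } else FALSE
  truth$len <- NULL
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

#' Simulate a PEAKS-like identification table
#'
#' Each planted peptide is detected in each sample with probability
#' `spec$detection_prob`; observed masses are the theoretical monoisotopic
#' masses plus Gaussian noise, m/z follows from a charge drawn from
#' \{1, 2, 3\}, and identification scores are uniform. Decoy peptides --
#' random sequences verified (by literal six-frame search) to be absent
#' from the genome -- are appended.
#'
#' @param truth truth table from [plant_peptides()].
#' @param spec a `simulation_spec`.
#' @param genome the edited `ncp_genome` (needed to verify decoys).
#' @return data.frame with columns `Peptide, Sample, z, m/z, Mass, Score`,
#'   with attribute `decoys` (the decoy sequences).
#' @export
simulate_identifications <- function(truth, spec, genome) {
  set.seed(spec$seed + 3L)
  frames <- .sixframe_strings(genome)

  decoys <- character(0)
  while (length(decoys) < spec$n_decoys) {
    cand <- .random_peptide(.sample_peptide_len(spec))
    if (.count_occurrences(cand, frames) == 0L &&
        !cand %in% c(truth$peptide, decoys)) {
      decoys <- c(decoys, cand)
    }
  }

  all_pep <- c(truth$peptide, decoys)
  rows <- list()
  for (s in spec$samples) {
    det <- runif(length(all_pep)) < spec$detection_prob
    pep <- all_pep[det]
    if (length(pep) == 0L) next
    z <- sample(1:3, length(pep), replace = TRUE,
                prob = c(0.2, 0.5, 0.3))
    mass <- monoisotopic_mass(pep) + rnorm(length(pep), 0,
                                           spec$mass_noise_sd)
    rows[[length(rows) + 1L]] <-
      data.frame(Peptide = pep, Sample = s, z = z,
                 `m/z` = theoretical_mz(mass, z), Mass = mass,
                 Score = round(runif(length(pep), 60, 99), 2),
                 check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "decoys") <- decoys
  out
}

#' Write an identification table to CSV
#' @param ids data.frame from [simulate_identifications()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_identifications <- function(ids, path) {
  write.csv(ids, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate trait-associated SNP positions
#'
#' SNP counts per chromosome are proportional to chromosome length;
#' positions are uniform; traits are drawn from a small vocabulary.
#'
#' @param genome an `ncp_genome`.
#' @param spec a `simulation_spec`.
#' @return data.frame `chrom, pos, trait` (pos 0-based).
#' @export
simulate_snps <- function(genome, spec) {
  set.seed(spec$seed + 4L)
  lens <- chrom_lengths(genome)
  n_per <- setNames(pmax(1L, round(spec$n_snps * lens / sum(lens))),
                    names(lens))
  rows <- lapply(names(lens), function(chrom) {
    data.frame(chrom = chrom,
               pos = sort(sample.int(lens[[chrom]], n_per[[chrom]]) - 1L),
               trait = sample(.QTL_TRAITS, n_per[[chrom]], replace = TRUE))
  })
  do.call(rbind, rows)
}

#' Simulate feature tracks (QTL, LTR, sweep, lncRNA, long-read intervals)
#'
#' Track intervals are uniform with the spec's per-track size
#' distributions; the `reads` track additionally covers a random subset of
#' the planted NCP sites (with padding) so that transcription-verification
#' overlap has signal.
#'
#' @param genome an `ncp_genome`.
#' @param truth optional truth table from [plant_peptides()].
#' @param spec a `simulation_spec`.
#' @return named list of track data.frames (`chrom, start, end, label`).
#' @export
simulate_tracks <- function(genome, truth = NULL, spec) {
  set.seed(spec$seed + 5L)
  lens <- chrom_lengths(genome)
  uniform_track <- function(n, size_range, labels) {
    chrom <- sample(names(lens), n, replace = TRUE,
                    prob = lens / sum(lens))
    size <- sample(seq(size_range[1L], size_range[2L]), n, replace = TRUE)
    size <- pmin(size, unname(lens[chrom]) - 2L)
    start <- vapply(seq_len(n), function(i) {
      sample.int(lens[[chrom[i]]] - size[i], 1L) - 1L
    }, integer(1))
    data.frame(chrom = chrom, start = start, end = start + size,
               label = sample(labels, n, replace = TRUE))
  }
  out <- list(
    qtl = uniform_track(spec$tracks$qtl$n, spec$tracks$qtl$size_range,
                        .QTL_TRAITS),
    ltr = uniform_track(spec$tracks$ltr$n, spec$tracks$ltr$size_range,
                        c("Copia", "Gypsy")),
    sweep = uniform_track(spec$tracks$sweep$n,
                          spec$tracks$sweep$size_range,
                          c("domestication", "improvement")),
    lncrna = uniform_track(spec$tracks$lncrna$n,
                           spec$tracks$lncrna$size_range, "lncRNA"),
    reads = uniform_track(spec$tracks$reads$n,
                          spec$tracks$reads$size_range, "isoseq"))
  if (!is.null(truth)) {
    ncp <- truth[truth$category != "CP", , drop = FALSE]
    if (nrow(ncp) > 0L) {
      covered <- ncp[sample(nrow(ncp), max(1L, nrow(ncp) %/% 5L)), ,
                     drop = FALSE]
      pad <- sample(200:1500, nrow(covered), replace = TRUE)
      extra <- data.frame(chrom = covered$chrom,
                          start = pmax(covered$start - pad, 0L),
                          end = pmin(covered$end + pad,
                                     unname(lens[covered$chrom])),
                          label = "isoseq")
      out$reads <- rbind(out$reads, extra)
    }
  }
  out
}

#' Uniform or flank-associated placement sets
#'
#' A lightweight placement-level generator for calibration and power
#' studies of the SNP-flank enrichment test: `n` peptide-sized fragments
#' are placed on the genome, chromosomes chosen proportionally to length
#' and starts uniform; a fraction `rho` is instead forced inside the given
#' flank intervals.
#'
#' @param chrom_lengths named chromosome lengths.
#' @param n number of placements.
#' @param spec a `simulation_spec` (for the peptide length distribution).
#' @param flanks merged flank intervals (required when `rho > 0`).
#' @param rho fraction of placements forced into flanks.
#' @param seed optional seed.
#' @return data.frame `peptide, chrom, start, end, strand`.
#' @export
simulate_placement_set <- function(chrom_lengths, n, spec = simulation_spec(),
                                   flanks = NULL, rho = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (rho > 0 && (is.null(flanks) || nrow(flanks) == 0L)) {
    stop("rho > 0 requires flank intervals")
  }
  lens <- vapply(seq_len(n), function(i) .sample_peptide_len(spec),
                 integer(1)) * 3L
  n_forced <- round(rho * n)
  chrom <- character(n); start <- integer(n)
  if (n_forced > 0L) {
    w <- flanks$end - flanks$start
    fi <- sample(nrow(flanks), n_forced, replace = TRUE, prob = w)
    for (k in seq_len(n_forced)) {
      f <- flanks[fi[k], ]
      lens[k] <- min(lens[k], f$end - f$start)
      chrom[k] <- f$chrom
      start[k] <- f$start + sample.int(f$end - f$start - lens[k] + 1L,
                                       1L) - 1L
    }
  }
  if (n_forced < n) {
    idx <- (n_forced + 1L):n
    chrom[idx] <- sample(names(chrom_lengths), length(idx), replace = TRUE,
                         prob = chrom_lengths / sum(chrom_lengths))
    start[idx] <- vapply(idx, function(k) {
      sample.int(chrom_lengths[[chrom[k]]] - lens[k] + 1L, 1L) - 1L
    }, integer(1))
  }
  data.frame(peptide = sprintf("p%04d", seq_len(n)), chrom = chrom,
             start = start, end = start + lens,
             strand = sample(c("+", "-"), n, replace = TRUE))
}

#' Simulate a complete peptidogenomic dataset
#'
#' Orchestrates the generator end to end: genome, annotation, SNPs and
#' flanks, planted peptides (with the spec's association fraction),
#' identification table, and feature tracks.
#'
#' @param spec a `simulation_spec`.
#' @return list with `spec, genome, genes, snps, flanks, truth,
#'   identifications, tracks`.
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  genome <- simulate_genome(spec)
  ann <- simulate_annotation(genome, spec)
  snps <- simulate_snps(ann$genome, spec)
  flanks <- snp_flanks(snps, chrom_lengths(ann$genome), spec$flank_bp)
  planted <- plant_peptides(ann$genome, ann$genes, spec, flanks = flanks)
  ids <- simulate_identifications(planted$truth, spec, planted$genome)
  tracks <- simulate_tracks(planted$genome, planted$truth, spec)
  list(spec = spec, genome = planted$genome, genes = ann$genes,
       snps = snps, flanks = flanks, truth = planted$truth,
       identifications = ids, tracks = tracks)
}

#' Write a simulated dataset to disk in the pipeline's input dialects
#'
#' Emits genome FASTA, annotation GFF3, identification CSV, track BED
#' files, and the SNP TSV into a directory.
#'
#' @param ds list from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gff = file.path(dir, "annotation.gff3"),
             identifications = file.path(dir, "identifications.csv"),
             snps = file.path(dir, "snps.tsv"))
  write_genome(ds$genome, paths[["genome"]])
  write_gff3(ds$genes, paths[["gff"]])
  write_identifications(ds$identifications, paths[["identifications"]])
  snp_out <- data.frame(chrom = ds$snps$chrom, pos = ds$snps$pos + 1L,
                        trait = ds$snps$trait)
  write.table(snp_out, paths[["snps"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (tr in names(ds$tracks)) {
    p <- file.path(dir, paste0(tr, ".bed"))
    write_bed(ds$tracks[[tr]], p, name = ds$tracks[[tr]]$label)
    paths[[tr]] <- p
  }
  paths
}
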