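#' Configuration for an end-to-end pipeline run
#'
#' Collects the input paths and analysis parameters for [run_pipeline()].
#' Track and SNP inputs are optional; the corresponding stages are skipped
#' when they are absent.
#'
#' @param genome path to the genome FASTA.
#' @param gff path to the annotation GFF3.
#' @param identifications path to the identified-peptide CSV.
#' @param out_dir output directory.
#' @param tracks named list of track file paths (BED or labeled TSV).
#' @param snps path to the SNP TSV, or NULL.
#' @param min_len minimum six-frame segment length (residues).
#' @param il_equivalent treat I/L as equivalent when locating peptides.
#' @param window_bp density window width (default 1 Mb).
#' @param intensive_threshold window count threshold for intensive regions.
#' @param upstream_bp,downstream_bp classification window sizes.
#' @param neighbor_cutoff_bp neighbor-distance summary cutoff (500 kb).
#' @param tss_cutoff_bp TSS-distance summary cutoff (2 kb).
#' @param mass_cutoff_da light-peptide mass cutoff (2500 Da).
#' @param flank_bp SNP flank size (10 kb).
#' @param n_replicates matched-background replicates (100).
#' @param seed seed for the background generation.
#' @return a list of class `run_config`.
#' @export
run_config <- function(genome, gff, identifications, out_dir,
                       tracks = list(), snps = NULL,
                       min_len = 1L, il_equivalent = FALSE,
                       window_bp = 1e6, intensive_threshold = 2L,
                       upstream_bp = 1000L, downstream_bp = 1000L,
                       neighbor_cutoff_bp = 5e5, tss_cutoff_bp = 2000,
                       mass_cutoff_da = 2500, flank_bp = 10000L,
                       n_replicates = 100L, seed = 1L) {
  cfg <- as.list(environment())
  for (p in c(genome, gff, identifications, unlist(tracks), snps)) {
    if (!is.null(p) && !file.exists(p)) stop("input not found: ", p)
  }
  stopifnot(min_len >= 1L, window_bp > 0, n_replicates >= 1L)
  class(cfg) <- "run_config"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full peptidogenomic analysis
#'
#' Executes build-db, locate, classify, distribution, track-overlap, and
#' SNP-enrichment stages on the configured inputs, writing a TSV for every
#' result plus a manifest recording inputs, parameters, and the seed.
#' Stage counts (peptides read, deduplicated, placed, single-locus, per
#' category) are reported via messages.
#'
#' @param config a `run_config`.
#' @return invisibly, a list with all intermediate and final results
#'   (`genome, genes, db, ids, dedup, located, classification, summary,
#'   densities, intensive, neighbors, tss, correlation, stages, overlaps,
#'   enrichment`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  tsv <- function(df, name) {
    write.table(df, out(name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  set.seed(config$seed)

  genome <- .stage("read-genome", read_genome(config$genome))
  genes <- .stage("read-annotation",
                  read_annotation(config$gff, genome))
  db <- .stage("build-db", build_sixframe_db(genome, config$min_len))
  message("six-frame database: ", nrow(db), " segments")

  ids <- .stage("read-identifications",
                read_identifications(config$identifications))
  dedup <- deduplicate_peptides(ids)
  message("peptides: ", nrow(ids), " rows, ", length(dedup$global),
          " non-redundant")

  located <- .stage("locate",
                    locate_peptides(dedup$global, db,
                                    config$il_equivalent))
  n_status <- table(located$peptides$locus_status)
  message("located: ", sum(located$peptides$n_placements > 0L),
          " placed, ",
          sum(located$peptides$locus_status == "single_locus"),
          " single-locus")
  placements <- single_locus_placements(located)

  classification <- .stage("classify",
                           classify_all(located, genes, genome,
                                        config$upstream_bp,
                                        config$downstream_bp))
  message("categories: ",
          paste(names(classification$category_counts),
                classification$category_counts, sep = "=",
                collapse = ", "))
  catalog_summary <- summarize_catalog(classification$calls,
                                       config$mass_cutoff_da)

  lens <- chrom_lengths(genome)
  densities <- .stage("distribution",
                      window_density(placements, lens, config$window_bp))
  intensive <- intensive_regions(densities, config$intensive_threshold)
  neighbors <- neighbor_distances(placements, config$neighbor_cutoff_bp)
  tssd <- tss_distances(placements, genes, config$tss_cutoff_bp)
  correlation <- if (length(lens) >= 3L) {
    count_length_correlation(placements, lens)
  } else NULL
  stages <- if (length(dedup$per_sample) >= 2L) {
    stage_overlap(dedup$per_sample)
  } else NULL

  overlaps <- list()
  for (tr in names(config$tracks)) {
    track <- .stage(paste0("read-track-", tr),
                    read_track(config$tracks[[tr]], genome = genome,
                               track_name = tr))
    overlaps[[tr]] <- .stage(paste0("overlap-", tr),
                             overlap_peptides(placements, track))
  }

  enrichment <- NULL
  if (!is.null(config$snps)) {
    enrichment <- .stage("snp-enrich", {
      snps <- read_snps(config$snps)
      flanks <- snp_flanks(snps, lens, config$flank_bp)
      bg <- matched_background(placements, lens, config$n_replicates,
                               seed = config$seed)
      enrichment_test(placements, flanks, bg)
    })
  }

  # outputs
  tsv(located$peptides, "peptides.tsv")
  tsv(placements, "placements.tsv")
  write_bed(placements, out("placements.bed"))
  tsv(classification$calls, "classification.tsv")
  tsv(data.frame(category = names(classification$category_counts),
                 count = classification$category_counts),
      "category_counts.tsv")
  tsv(catalog_summary, "catalog_summary.tsv")
  tsv(densities, "window_density.tsv")
  tsv(intensive$regions, "intensive_regions.tsv")
  tsv(neighbors$distances, "neighbor_distances.tsv")
  tsv(data.frame(peptide = placements$peptide, distance = tssd$distances),
      "tss_distances.tsv")
  if (!is.null(stages)) tsv(stages$venn, "stage_overlap.tsv")
  for (tr in names(overlaps)) {
    tsv(overlaps[[tr]]$assignments, paste0("overlap_", tr, ".tsv"))
  }
  if (!is.null(enrichment)) {
    tsv(data.frame(replicate = seq_along(enrichment$replicate_counts),
                   count = enrichment$replicate_counts),
        "enrichment_replicates.tsv")
    tsv(data.frame(observed = enrichment$observed, mu = enrichment$mu,
                   sigma = enrichment$sigma, z = enrichment$z,
                   p_normal = enrichment$p_normal,
                   p_empirical = enrichment$p_empirical,
                   n_replicates = enrichment$n_replicates,
                   degenerate = enrichment$degenerate),
        "enrichment.tsv")
  }
  manifest <- data.frame(
    key = c("package_version", "seed", "genome", "gff", "identifications",
            "snps", "min_len", "window_bp", "intensive_threshold",
            "upstream_bp", "downstream_bp", "flank_bp", "n_replicates",
            "il_equivalent"),
    value = c(as.character(utils::packageVersion("ncpep")),
              config$seed, config$genome, config$gff,
              config$identifications,
              if (is.null(config$snps)) "" else config$snps,
              config$min_len, config$window_bp,
              config$intensive_threshold, config$upstream_bp,
              config$downstream_bp, config$flank_bp, config$n_replicates,
              config$il_equivalent))
  tsv(manifest, "manifest.tsv")

  invisible(list(genome = genome, genes = genes, db = db, ids = ids,
                 dedup = dedup, located = located,
                 classification = classification,
                 summary = catalog_summary, densities = densities,
                 intensive = intensive, neighbors = neighbors, tss = tssd,
                 correlation = correlation, stages = stages,
                 overlaps = overlaps, enrichment = enrichment))
}
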