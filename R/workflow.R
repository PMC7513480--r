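# End-to-end pipeline: run every stage over an input (or simulated)
# alignment and write a report bundle with a JSON manifest.

#' Pipeline configuration
#'
#' @param fasta Path to an aligned, labelled FASTA (ignored when
#'   `sim` is given).
#' @param sim Optional [sim_config()]; when set, the input alignment is
#'   simulated instead of read.
#' @param bin_width Gap-histogram bin width (distance units).
#' @param bootstrap_replicates Bootstrap replicates for the NJ tree
#'   (0 disables the bootstrap).
#' @param thresholds Distance thresholds at which the proportion of
#'   inter-specific distances below each value is reported.
#' @param enzyme_table Optional TSV of enzyme definitions
#'   (default: the built-in MseI/PstI/AvaII set).
#' @param groups Optional sample-to-group map for the polymorphism
#'   summaries (default: species labels).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for all randomness.
#' @return List of class `run_config`.
#' @export
run_config <- function(fasta = NULL, sim = NULL, bin_width = 0.008,
                       bootstrap_replicates = 1000L,
                       thresholds = numeric(), enzyme_table = NULL,
                       groups = NULL, out_dir = "results", seed = 1L) {
  if (is.null(fasta) && is.null(sim)) {
    stop("either 'fasta' or 'sim' must be given")
  }
  structure(list(fasta = fasta, sim = sim, bin_width = bin_width,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 thresholds = thresholds, enzyme_table = enzyme_table,
                 groups = groups, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

.wtsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full barcode-evaluation pipeline
#'
#' Stages: distance matrix, divergence summary, gap histogram (+ plot),
#' leave-one-out identification, polymorphism/neutrality summaries,
#' restriction digest report and enzyme ranking, NJ tree (with bootstrap
#' when requested), and a JSON manifest listing every output with the
#' package version and seed.  Degenerate inputs are handled per stage:
#' with a single species, identification and the inter-specific metrics
#' are skipped with a notice while the polymorphism stage still runs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest` (also written to `manifest.json` in `out_dir`).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  files <- character()
  notices <- character()
  add <- function(p) files[[length(files) + 1L]] <<- p

  if (!is.null(cfg$sim)) {
    cfg$sim$seed <- cfg$seed
    sim <- simulate_barcode_set(cfg$sim)
    aln <- sim$aln
    add(write_fasta(aln_records(aln),
                    file.path(cfg$out_dir, "input_synthetic.fasta")))
    add(.wtsv(sim$truth$assignment,
              file.path(cfg$out_dir, "truth_assignment.tsv")))
  } else {
    aln <- validate_alignment(read_fasta(cfg$fasta))
  }
  species <- setNames(aln$meta$species, aln$meta$sample_id)
  n_species <- length(unique(species))

  d <- k2p_matrix(aln, quiet = TRUE)
  add(write_dist_tsv(d, file.path(cfg$out_dir, "distances.tsv")))
  add(write_dist_phylip(d, file.path(cfg$out_dir, "distances.phy")))

  divergence <- gap <- ident <- thresholds <- NULL
  if (n_species >= 2L) {
    divergence <- divergence_summary(d, species)
    add(.wtsv(divergence, file.path(cfg$out_dir, "divergence_summary.tsv")))
    gap <- suppressWarnings(gap_histogram(d, species, cfg$bin_width))
    add(.wtsv(gap$bins, file.path(cfg$out_dir, "gap_histogram.tsv")))
    png_path <- file.path(cfg$out_dir, "gap_histogram.png")
    grDevices::png(png_path, width = 900, height = 500)
    plot(gap)
    grDevices::dev.off()
    add(png_path)
    if (length(cfg$thresholds)) {
      pd <- pair_distances(d, species)
      inter <- pd$distance[pd$type == "inter"]
      thresholds <- data.frame(
        threshold = cfg$thresholds,
        proportion_inter_below = vapply(cfg$thresholds, function(th)
          proportion_below(inter, th), 0))
      add(.wtsv(thresholds, file.path(cfg$out_dir, "thresholds.tsv")))
    }
    ident <- evaluate_identification(aln, d = d)
    add(.wtsv(ident$per_query,
              file.path(cfg$out_dir, "identification_queries.tsv")))
    add(.wtsv(ident$per_method,
              file.path(cfg$out_dir, "identification_summary.tsv")))
    add(.wtsv(ident$per_species,
              file.path(cfg$out_dir, "identification_per_species.tsv")))
  } else {
    notices <- c(notices,
                 "single species: identification and inter-specific metrics skipped")
  }

  grouping <- cfg$groups
  if (is.null(grouping)) grouping <- species
  popgen <- group_summaries(aln, grouping)
  add(.wtsv(popgen, file.path(cfg$out_dir, "popgen_summary.tsv")))

  enzymes <- if (!is.null(cfg$enzyme_table)) read_enzyme_table(cfg$enzyme_table)
             else restriction_enzymes()
  recs <- aln_records(aln)
  digests <- digest_profiles(recs, enzymes)
  add(.wtsv(digests, file.path(cfg$out_dir, "digest_report.tsv")))
  hap <- haplotypes(aln)
  ranking <- if (hap$H >= 2L) {
    discriminate_haplotypes(digests, hap$assignment)
  } else {
    notices <- c(notices, "single haplotype: enzyme ranking skipped")
    NULL
  }
  if (!is.null(ranking)) {
    add(.wtsv(ranking, file.path(cfg$out_dir, "enzyme_ranking.tsv")))
  }

  tree <- NULL
  if (nrow(aln$mat) >= 3L && !anyNA(d)) {
    tree <- if (cfg$bootstrap_replicates > 0L) {
      bootstrap_support(aln, cfg$bootstrap_replicates, seed = cfg$seed)
    } else nj_tree(d, quiet = TRUE)
    add(write_newick(tree, file.path(cfg$out_dir, "tree.nwk")))
  } else {
    notices <- c(notices, "tree skipped (too few samples or undefined distances)")
  }

  manifest <- list(
    package = "barcodeval",
    version = as.character(utils::packageVersion("barcodeval")),
    seed = cfg$seed,
    n_samples = nrow(aln$mat), n_species = n_species,
    alignment_length = aln$length,
    bin_width = cfg$bin_width,
    bootstrap_replicates = cfg$bootstrap_replicates,
    notices = notices,
    files = basename(unlist(files)))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(aln = aln, distances = d, divergence = divergence,
                 gap = gap, thresholds = thresholds,
                 identification = ident, popgen = popgen,
                 digests = digests, ranking = ranking, tree = tree,
                 manifest = manifest))
}
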