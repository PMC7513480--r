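test_that("generator honors its configuration contracts", {
  expect_error(sim_config(n_species = 0), "n_species")
  expect_error(sim_config(inter_divergence = 0.1, intra_divergence = 0.2))

  # zero intra-divergence: conspecific samples identical
  set <- simulate_barcode_set(sim_config(
    n_species = 3, samples_per_species = 4, inter_divergence = 0.2,
    intra_divergence = 0, seed = 91))
  for (s in unique(set$aln$meta$species)) {
    rows <- set$aln$mat[set$aln$meta$species == s, ]
    expect_true(all(apply(rows, 2, function(col) length(unique(col)) == 1)))
  }
  d <- k2p_matrix(set$aln, quiet = TRUE)
  ds <- divergence_summary(d, setNames(set$aln$meta$species,
                                       set$aln$meta$sample_id))
  expect_equal(ds$mean[ds$metric == "all_intra"], 0)

  # alignment length within the requested range
  expect_true(set$aln$length >= 325 && set$aln$length <= 375)
})

test_that("a fixed seed reproduces the output byte for byte", {
  cfg <- sim_config(seed = 92)
  fa1 <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(aln_records(simulate_barcode_set(cfg)$aln), fa1)
  write_fasta(aln_records(simulate_barcode_set(cfg)$aln), fa2)
  expect_identical(readLines(fa1), readLines(fa2))
})

test_that("root GC tracks the target", {
  set.seed(93)
  gc <- vapply(1:20, function(r) {
    set <- simulate_barcode_set(sim_config(
      n_species = 2, samples_per_species = 1, inter_divergence = 0,
      intra_divergence = 0, length_range = c(350L, 350L)))
    # with zero branch lengths every record equals the root
    mean(strsplit(set$truth$species_ancestors[[1]], "")[[1]] %in% c("G", "C"))
  }, 0)
  expect_true(all(abs(gc - 0.60) < 0.03 + 3 * sqrt(0.24 / 350)))
  expect_lt(abs(mean(gc) - 0.60), 0.02)
})

test_that("K2P estimates recover the configured divergences", {
  set.seed(94)
  stats <- vapply(1:20, function(r) {
    set <- simulate_barcode_set(sim_config(
      n_species = 6, samples_per_species = 3, inter_divergence = 0.2,
      intra_divergence = 0.02, length_range = c(350L, 350L)))
    d <- k2p_matrix(set$aln, quiet = TRUE)
    ds <- divergence_summary(d, setNames(set$aln$meta$species,
                                         set$aln$meta$sample_id))
    c(inter = ds$mean[ds$metric == "all_inter"],
      intra = ds$mean[ds$metric == "all_intra"])
  }, c(inter = 0, intra = 0))
  for (k in 1:2) {
    target <- c(0.2, 0.02)[k]
    se <- sd(stats[k, ]) / sqrt(ncol(stats))
    expect_lt(abs(mean(stats[k, ]) - target), 3 * se)
  }
})

test_that("coalescent simulator: degenerate and error paths", {
  co0 <- simulate_coalescent(8, 0, 100, seed = 95)
  expect_equal(segregating_sites(co0)$S, 0L)
  expect_equal(haplotypes(co0)$H, 1L)
  expect_error(simulate_coalescent(10, 1e5, 3, seed = 95), "increase 'sites'")
})

test_that("coalescent moments match neutral expectations (small run)", {
  set.seed(96)
  reps <- t(vapply(1:200, function(r) {
    co <- simulate_coalescent(10, 4, 300)
    div <- diversity(co)
    c(S = div$S, k = div$mean_pairwise_k)
  }, c(S = 0, k = 0)))
  a1 <- sum(1 / (1:9))
  se_S <- sd(reps[, "S"]) / sqrt(nrow(reps))
  se_k <- sd(reps[, "k"]) / sqrt(nrow(reps))
  expect_lt(abs(mean(reps[, "S"]) - 4 * a1), 3 * se_S)
  expect_lt(abs(mean(reps[, "k"]) - 4), 3 * se_k)
})

test_that("planted haplotypes: construction honors its own truth table", {
  base <- strrep("ACGTG", 80)
  one <- plant_restriction_haplotypes(base, 1)
  expect_equal(nrow(one$truth), 0L)

  two <- plant_restriction_haplotypes(base, 2,
                                      enzymes = restriction_enzymes()[
                                        c("MseI", "PstI")])
  # hap2 carries one MseI site, PstI none anywhere
  expect_equal(unname(two$site_counts[, "MseI"]), c(0L, 1L))
  tt <- two$truth
  expect_true(tt$separated[tt$enzyme == "MseI"])
  expect_false(tt$separated[tt$enzyme == "PstI"])
  prof <- digest_profiles(two$records)
  rk <- discriminate_haplotypes(prof, setNames(two$records$sample_id,
                                               two$records$sample_id),
                                pairs = FALSE)
  expect_equal(rk$power[rk$enzymes == "MseI"], 1L)
  expect_equal(rk$power[rk$enzymes == "PstI"], 0L)

  expect_error(plant_restriction_haplotypes(strrep("ACGT", 5), 30),
               "too short")
})

test_that("end-to-end clear-gap invariants hold", {
  set <- simulate_barcode_set(sim_config(
    n_species = 5, samples_per_species = 4, inter_divergence = 0.2,
    intra_divergence = 0.02, length_range = c(350L, 350L), seed = 97))
  d <- k2p_matrix(set$aln, quiet = TRUE)
  sp <- setNames(set$aln$meta$species, set$aln$meta$sample_id)
  expect_equal(gap_histogram(d, sp)$overlap_fraction, 0)
  rep_id <- evaluate_identification(set$aln, methods = "distance", d = d)
  expect_equal(rep_id$per_method$correct_pct, 100)
  phy <- nj_tree(d, quiet = TRUE)
  for (s in unique(sp)) {
    expect_true(ape::is.monophyletic(phy, names(sp)[sp == s]))
  }
})

test_that("indel mode produces gaps the pipeline tolerates", {
  set <- simulate_barcode_set(sim_config(
    n_species = 4, samples_per_species = 3, inter_divergence = 0.15,
    intra_divergence = 0.02, length_range = c(300L, 300L),
    indel_rate = 2, seed = 120))
  expect_true(any(set$aln$mat == "-"))
  d <- k2p_matrix(set$aln, quiet = TRUE)
  expect_false(anyNA(d))            # pairwise deletion keeps pairs defined
  div <- diversity(set$aln)         # indel columns are excluded
  expect_lt(div$L, 300L)
  expect_gte(div$pi, 0)
})

test_that("bifurcating mode recovers its own species tree via NJ", {
  skip_if_not_installed("phangorn")
  set <- simulate_barcode_set(sim_config(
    n_species = 6, samples_per_species = 1, inter_divergence = 0.15,
    intra_divergence = 0, length_range = c(2000L, 2000L),
    species_tree = "bifurcating", seed = 121))
  truth_tree <- set$truth$species_phylogeny
  expect_s3_class(truth_tree, "phylo")
  d <- k2p_matrix(set$aln, quiet = TRUE)
  rownames(d) <- colnames(d) <- set$aln$meta$species
  phy <- nj_tree(d, quiet = TRUE)
  expect_equal(phangorn::RF.dist(ape::unroot(truth_tree), phy), 0)
})
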