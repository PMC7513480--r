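mk_dist <- function(labels, species, fill) {
  d <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (entry in fill) d[entry[[1]], entry[[2]]] <- d[entry[[2]], entry[[1]]] <-
      as.numeric(entry[[3]])
  attr(d, "species") <- setNames(species, labels)
  d
}

test_that("six metrics on a two-singleton toy", {
  d <- mk_dist(c("x", "y"), c("X", "Y"), list(list("x", "y", 0.2)))
  ds <- divergence_summary(d, attr(d, "species"))
  m <- setNames(ds$mean, ds$metric)
  expect_equal(unname(m[c("all_inter", "theta_prime", "min_inter")]),
               rep(0.2, 3))
  expect_true(all(is.na(m[c("all_intra", "theta", "coalescent_depth")])))
  expect_equal(ds$n[ds$metric == "all_intra"], 0L)
})

test_that("six metrics on the hand-enumerated three-sample case", {
  # species X {x1, x2} with d = 0.02; singleton Y; d(x., y) = 0.20
  d <- mk_dist(c("x1", "x2", "y1"), c("X", "X", "Y"),
               list(list("x1", "x2", 0.02), list("x1", "y1", 0.20),
                    list("x2", "y1", 0.20)))
  ds <- divergence_summary(d, attr(d, "species"))
  m <- setNames(ds$mean, ds$metric)
  expect_equal(unname(m), c(0.20, 0.20, 0.20, 0.02, 0.02, 0.02))
  # units: 2 inter sample pairs, 1 species pair, 2 species, 1 intra pair
  n <- setNames(ds$n, ds$metric)
  expect_equal(unname(n), c(2L, 1L, 2L, 1L, 1L, 1L))
})

test_that("theta_prime weights species pairs, not sample pairs", {
  # species A (3 samples) vs B (1): six a-b distances at 0.1;
  # species C (1): two c distances at 0.4 to A's samples... build explicit
  labels <- c("a1", "a2", "a3", "b1", "c1")
  sp <- c("A", "A", "A", "B", "C")
  fill <- list()
  for (a in c("a1", "a2", "a3")) fill <- c(fill, list(list(a, "b1", 0.1)))
  for (a in c("a1", "a2", "a3")) fill <- c(fill, list(list(a, "c1", 0.4)))
  fill <- c(fill, list(list("b1", "c1", 0.4)))
  d <- mk_dist(labels, sp, fill)
  ds <- divergence_summary(d, setNames(sp, labels))
  # all_inter averages 7 sample pairs; theta_prime averages 3 species pairs
  expect_equal(ds$mean[ds$metric == "all_inter"], (3 * .1 + 4 * .4) / 7)
  expect_equal(ds$mean[ds$metric == "theta_prime"], (0.1 + 0.4 + 0.4) / 3)
})

test_that("simulated clear-gap sets separate the metrics", {
  set.seed(41)
  set <- simulate_barcode_set(sim_config(
    n_species = 10, samples_per_species = 5, inter_divergence = 0.2,
    intra_divergence = 0.02, length_range = c(350L, 350L)))
  d <- k2p_matrix(set$aln, quiet = TRUE)
  sp <- setNames(set$aln$meta$species, set$aln$meta$sample_id)
  ds <- divergence_summary(d, sp)
  m <- setNames(ds$mean, ds$metric)
  expect_gt(m[["all_inter"]], m[["all_intra"]])
  expect_gt(m[["min_inter"]], m[["coalescent_depth"]])
  # mean intra <= mean of per-species maxima
  expect_lte(m[["all_intra"]], m[["coalescent_depth"]] + 1e-12)
})

test_that("gap histogram bins are half-open, anchored at zero", {
  d2 <- mk_dist(c("a1", "a2", "a3", "b1"), c("A", "A", "A", "B"),
                list(list("a1", "a2", 0.0), list("a1", "a3", 0.135),
                     list("a2", "a3", 0.135), list("a1", "b1", 0.002),
                     list("a2", "b1", 0.184), list("a3", "b1", 0.184)))
  g <- gap_histogram(d2, attr(d2, "species"))
  expect_equal(g$intra_range, c(0.000, 0.135))
  expect_equal(g$inter_range, c(0.002, 0.184))
  # 1 of 3 inter distances <= max intra 0.135... 0.002 only
  expect_equal(g$overlap_fraction, 1 / 3)
  expect_equal(sum(g$bins$intra_count), 3)
  expect_equal(sum(g$bins$inter_count), 3)
  # value on a bin edge falls in the upper bin: 0.008 -> bin [0.008, 0.016)
  d3 <- mk_dist(c("p1", "p2", "q1"), c("P", "P", "Q"),
                list(list("p1", "p2", 0.008), list("p1", "q1", 0.02),
                     list("p2", "q1", 0.02)))
  g3 <- gap_histogram(d3, attr(d3, "species"))
  expect_equal(g3$bins$intra_count[g3$bins$bin_lo == 0.008], 1)
  # all distances inside the first bin occupy a single bin
  d4 <- mk_dist(c("p1", "p2", "q1"), c("P", "P", "Q"),
                list(list("p1", "p2", 0.001), list("p1", "q1", 0.007),
                     list("p2", "q1", 0.005)))
  g4 <- gap_histogram(d4, attr(d4, "species"))
  expect_equal(nrow(g4$bins), 1L)
})

test_that("overlap vanishes as the gap widens", {
  set.seed(43)
  set <- simulate_barcode_set(sim_config(
    n_species = 8, samples_per_species = 4, inter_divergence = 0.2,
    intra_divergence = 0.02, length_range = c(350L, 350L)))
  d <- k2p_matrix(set$aln, quiet = TRUE)
  g <- gap_histogram(d, setNames(set$aln$meta$species,
                                 set$aln$meta$sample_id))
  expect_equal(g$overlap_fraction, 0)
})

test_that("proportion_below counts as documented", {
  v <- c(0.01, 0.05, 0.2, 0.3)
  expect_equal(proportion_below(v, 0.135), 0.5)
  expect_equal(proportion_below(c(0.2, 0.3), 0.1), 0)
  expect_equal(proportion_below(c(0.1, 0.2), 0.1, strict = FALSE), 0.5)
  expect_error(proportion_below(numeric(), 0.1), "empty")
  # threshold planted at a quantile recovers the quantile
  set.seed(5)
  x <- runif(1000, 0.1, 0.3)
  th <- quantile(x, 0.0833, type = 1)  # 84th order statistic of 1000
  expect_equal(proportion_below(x, th, strict = FALSE), 0.084)
})

test_that("rank-sum test: exact path, ties, and degenerate input", {
  r <- wilcoxon_ranksum(c(1, 2), c(3, 4))
  expect_equal(r$method, "exact")
  expect_equal(r$p.value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$p.value, oracle_ranksum_exact(c(1, 2), c(3, 4)),
               tolerance = 1e-12)

  x <- c(3, 1, 4, 1, 5)
  expect_equal(wilcoxon_ranksum(x, x)$p.value, 1)
  expect_equal(wilcoxon_ranksum(c(2, 2), c(2, 2))$p.value, 1)
})

test_that("exact p matches full enumeration for assorted small samples", {
  set.seed(6)
  for (nx in c(2, 3, 5)) for (ny in c(2, 4, 6)) {
    v <- sample(1000, nx + ny)
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(wilcoxon_ranksum(x, y)$p.value,
                 oracle_ranksum_exact(x, y), tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p at moderate sizes", {
  set.seed(7)
  for (r in 1:40) {
    nx <- sample(5:8, 1); ny <- sample(5:8, 1)
    v <- sample(10000, nx + ny)
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    pn <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(pn - oracle_ranksum_exact(x, y)), 0.02)
  }
})
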