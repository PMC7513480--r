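mk_dist2 <- function(labels, fill) {
  d <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (e in fill) d[e[[1]], e[[2]]] <- d[e[[2]], e[[1]]] <- as.numeric(e[[3]])
  d
}

test_that("nearest-distance outcome rules on constructed toys", {
  labels <- c("q", "a1", "b1")
  sp <- setNames(c("A", "A", "B"), labels)
  d <- mk_dist2(labels, list(list("q", "a1", 0.01), list("q", "b1", 0.2),
                             list("a1", "b1", 0.2)))
  expect_equal(nearest_distance_identify("q", d, sp)$outcome, "correct")

  # two references from different species tied at the minimum
  d2 <- mk_dist2(labels, list(list("q", "a1", 0.05), list("q", "b1", 0.05),
                              list("a1", "b1", 0.2)))
  out <- nearest_distance_identify("q", d2, sp)
  expect_equal(out$outcome, "ambiguous")
  expect_setequal(strsplit(out$hit_species, ";")[[1]], c("A", "B"))

  # heterospecific hit strictly closer than any conspecific
  d3 <- mk_dist2(labels, list(list("q", "a1", 0.2), list("q", "b1", 0.01),
                              list("a1", "b1", 0.2)))
  expect_equal(nearest_distance_identify("q", d3, sp)$outcome, "incorrect")

  # conspecific tie stays correct
  labels4 <- c("q", "a1", "a2", "b1")
  sp4 <- setNames(c("A", "A", "A", "B"), labels4)
  d4 <- mk_dist2(labels4, list(list("q", "a1", 0.01), list("q", "a2", 0.01),
                               list("q", "b1", 0.3), list("a1", "a2", 0.02),
                               list("a1", "b1", 0.3), list("a2", "b1", 0.3)))
  expect_equal(nearest_distance_identify("q", d4, sp4)$outcome, "correct")
})

test_that("all-undefined distances yield an unassignable outcome", {
  labels <- c("q", "a1", "b1")
  d <- mk_dist2(labels, list(list("q", "a1", NA), list("q", "b1", NA),
                             list("a1", "b1", 0.1)))
  out <- nearest_distance_identify("q", d, setNames(c("A", "A", "B"), labels))
  expect_equal(out$outcome, "unassignable")
})

test_that("a planted incorrect case verified by exhaustive distances", {
  # 3 species x 2 samples; one A sample moved into the B cluster
  set.seed(51)
  base <- random_seq(200)
  mut <- function(s, k, from = 1) {
    ch <- strsplit(s, "")[[1]]
    pos <- seq.int(from, from + k - 1)
    ch[pos] <- vapply(ch[pos], function(x)
      setdiff(c("A", "C", "G", "T"), x)[1], "")
    paste(ch, collapse = "")
  }
  aseq <- base; bseq <- mut(base, 40, 1); cseq <- mut(base, 40, 100)
  rec <- make_records(
    c(aseq, mut(bseq, 2, 60),                 # "a2" planted near B
      bseq, mut(bseq, 1, 80), cseq, mut(cseq, 1, 160)),
    c("A", "A", "B", "B", "C", "C"))
  aln <- validate_alignment(rec)
  d <- k2p_matrix(aln, quiet = TRUE)
  sp <- setNames(rec$species, rec$sample_id)
  out <- nearest_distance_identify("s2", d, sp)
  expect_equal(out$outcome, "incorrect")
  expect_equal(out$hit_species, "B")
  # exhaustive listing: s2's nearest is indeed a B sample
  dq <- d["s2", -2]
  expect_equal(names(which.min(dq)), "s3")
})

test_that("local-alignment identification follows the same rules", {
  refA <- strrep("ACGT", 5)
  refB <- paste0(strrep("TTGC", 4), "GGCC")
  q <- list(sample_id = "q", species = "A", residues = refA)
  refs <- make_records(c(refA, refB), c("A", "B"), c("a1", "b1"))
  out <- blast1_identify(q, refs)
  expect_equal(out$outcome, "correct")
  expect_equal(out$score_or_distance, 20)  # query length x match score

  # two identical references from different species: forced tie
  refs2 <- make_records(c(refA, refA), c("A", "B"), c("a1", "b1"))
  expect_equal(blast1_identify(q, refs2)$outcome, "ambiguous")

  expect_error(blast1_identify(q, refs2[0, ]), "empty")
})

test_that("alignment scores match a brute-force affine-gap DP", {
  set.seed(52)
  sc <- blast1_scoring()
  for (r in 1:15) {
    q <- random_seq(20)
    ref <- random_seq(sample(15:30, 1))
    got <- blast1_identify(list(sample_id = "q", species = "X", residues = q),
                           make_records(ref, "X", "r1"))$score_or_distance
    expect_equal(got, oracle_sw(q, ref, sc$match, sc$mismatch,
                                sc$gap_open, sc$gap_ext))
  }
  # 1-mismatch reference beats a 3-mismatch reference
  q <- random_seq(20)
  mut_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(x)
      setdiff(c("A", "C", "G", "T"), x)[1], "")
    paste(ch, collapse = "")
  }
  refs <- make_records(c(mut_at(q, 10), mut_at(q, c(3, 10, 17))),
                       c("near", "far"), c("n1", "f1"))
  out <- blast1_identify(list(sample_id = "q", species = "near",
                              residues = q), refs)
  expect_equal(out$hit_species, "near")
  expect_equal(out$score_or_distance,
               oracle_sw(q, refs$residues[1], sc$match, sc$mismatch,
                         sc$gap_open, sc$gap_ext))
})

test_that("leave-one-out report: percentages, singletons, degeneracies", {
  # all samples identical across two species -> everything ambiguous
  rec <- make_records(rep(strrep("ACGT", 10), 4), c("A", "A", "B", "B"))
  rep_id <- evaluate_identification(validate_alignment(rec))
  expect_equal(rep_id$per_method$ambiguous_pct, c(100, 100))

  # percentages sum to 100 exactly
  sums <- rowSums(rep_id$per_method[, c("correct_pct", "ambiguous_pct",
                                        "incorrect_pct", "unassignable_pct")])
  expect_equal(unname(sums), c(100, 100))

  # a singleton species among well-separated clusters is never correct
  set.seed(53)
  set <- simulate_barcode_set(sim_config(
    n_species = 3, samples_per_species = 3, inter_divergence = 0.2,
    intra_divergence = 0.01, length_range = c(300L, 300L)))
  rec2 <- aln_records(set$aln)[-1, ]  # sp01 keeps 2 samples; drop one
  # a divergent but unsaturated singleton built off one of the clusters
  loner_seq <- local({
    ch <- strsplit(rec2$residues[1], "")[[1]]
    pos <- sample(300, 45)
    ch[pos] <- vapply(ch[pos], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(ch, collapse = "")
  })
  rec2 <- rbind(rec2, make_records(loner_seq, "LONER", "loner1"))
  rep2 <- evaluate_identification(validate_alignment(rec2),
                                  methods = "distance")
  loner <- rep2$per_query[rep2$per_query$query_id == "loner1", ]
  expect_true(loner$outcome %in% c("incorrect", "ambiguous"))
  ps <- rep2$per_species[rep2$per_species$species == "LONER", ]
  expect_true(ps$singleton)
  expect_equal(ps$correct, 0L)
})

test_that("both methods agree in the zero-noise regime", {
  set.seed(54)
  set <- simulate_barcode_set(sim_config(
    n_species = 4, samples_per_species = 3, inter_divergence = 0.15,
    intra_divergence = 0, length_range = c(250L, 250L)))
  rep_id <- evaluate_identification(set$aln)
  pq <- rep_id$per_query
  dist_oc <- pq$outcome[pq$method == "DISTANCE"]
  blast_oc <- pq$outcome[pq$method == "BLAST1"]
  expect_equal(dist_oc, blast_oc)
  expect_true(all(dist_oc == "correct"))
})

test_that("raising intra-specific noise never helps identification", {
  rates <- vapply(c(0.01, 0.08, 0.18), function(intra) {
    mean(vapply(1:4, function(s) {
      set.seed(100 + s)
      set <- simulate_barcode_set(sim_config(
        n_species = 5, samples_per_species = 4, inter_divergence = 0.2,
        intra_divergence = intra, length_range = c(300L, 300L)))
      evaluate_identification(set$aln,
                              methods = "distance")$per_method$correct_pct
    }, 0))
  }, 0)
  expect_true(all(diff(rates) <= 0))
})
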