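# Leave-one-out species identification: nearest-distance and best
# local-alignment-hit ("BLAST1"-style) methods with correct / ambiguous /
# incorrect outcome rules.

#' Default scoring for the local-alignment identifier
#'
#' Megablast-style scoring: match +1, mismatch -2; a gap of length k costs
#' `gap_open + k * gap_ext` (5 + 2k).  Ambiguity codes never match.
#'
#' @return List with `match`, `mismatch`, `gap_open`, `gap_ext`.
#' @export
blast1_scoring <- function() {
  list(match = 1, mismatch = -2, gap_open = 5, gap_ext = 2)
}

# Substitution matrix over the IUPAC alphabet: +match on identical ACGT
# letters, mismatch everywhere else (ambiguity codes never match, not even
# themselves).
.blast1_submat <- function(scoring) {
  letters <- setdiff(IUPAC_NT, "-")
  m <- matrix(scoring$mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  for (b in c("A", "C", "G", "T")) m[b, b] <- scoring$match
  m
}

.outcome_from_hits <- function(query_species, hit_species) {
  hit_species <- unique(hit_species)
  if (length(hit_species) >= 2L) "ambiguous"
  else if (identical(hit_species, query_species)) "correct"
  else "incorrect"
}

#' Identify one query by nearest K2P distance
#'
#' Leave-one-out: the query's row of the distance matrix is compared
#' against all other samples; the hit set is every reference within
#' `tol` of the smallest distance.  Outcomes follow the standard rules:
#' correct if all top hits are the query's species, ambiguous if the top
#' hits span two or more species, incorrect if the single top-hit species
#' differs from the query's.  If every distance to the query is undefined
#' the outcome is `"unassignable"`.
#'
#' @param query_id Sample id of the query (must be in `d`).
#' @param d Distance matrix over queries and references ([k2p_matrix()]).
#' @param species Sample-to-species map (named by sample id, or in matrix
#'   order).
#' @param tol Tie tolerance on distances.
#' @return Data frame row: `query_id`, `method = "DISTANCE"`, `outcome`,
#'   `hit_species` (`;`-collapsed), `score_or_distance`.
#' @export
nearest_distance_identify <- function(query_id, d, species, tol = 1e-12) {
  species <- .species_named(d, species)
  qi <- match(query_id, rownames(d))
  if (is.na(qi)) stop("query '", query_id, "' not in the distance matrix")
  dq <- d[qi, -qi]
  ref_sp <- species[rownames(d)[-qi]]
  if (all(is.na(dq))) {
    return(data.frame(query_id = query_id, method = "DISTANCE",
                      outcome = "unassignable", hit_species = NA_character_,
                      score_or_distance = NA_real_, stringsAsFactors = FALSE))
  }
  dmin <- min(dq, na.rm = TRUE)
  hits <- which(!is.na(dq) & dq <= dmin + tol)
  data.frame(query_id = query_id, method = "DISTANCE",
             outcome = .outcome_from_hits(unname(species[query_id]),
                                          unname(ref_sp[hits])),
             hit_species = paste(unique(unname(ref_sp[hits])), collapse = ";"),
             score_or_distance = dmin, stringsAsFactors = FALSE)
}

#' Identify one query by best local-alignment hit
#'
#' Smith-Waterman local alignment (via [Biostrings::pairwiseAlignment()])
#' of the gap-stripped query against every gap-stripped reference; the hit
#' set is the exact top-score set (scores are integers under the default
#' scoring), and the same correct / ambiguous / incorrect rules apply.
#'
#' @param query A one-row record data frame (columns `sample_id`,
#'   `species`, `residues`) or a list with those fields.
#' @param refs Record data frame of references (the query must not be in
#'   it).
#' @param scoring Scoring parameters, see [blast1_scoring()].
#' @return Data frame row as in [nearest_distance_identify()], with
#'   `method = "BLAST1"` and the best alignment score.
#' @export
blast1_identify <- function(query, refs, scoring = blast1_scoring()) {
  if (nrow(refs) == 0L) stop("empty reference set")
  strip <- function(s) gsub("-", "", s, fixed = TRUE)
  qseq <- strip(query$residues)
  rseqs <- Biostrings::DNAStringSet(strip(refs$residues))
  scores <- Biostrings::pairwiseAlignment(
    pattern = rseqs, subject = Biostrings::DNAString(qseq),
    type = "local", substitutionMatrix = .blast1_submat(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext,
    scoreOnly = TRUE)
  best <- max(scores)
  hits <- which(scores == best)
  data.frame(query_id = query$sample_id, method = "BLAST1",
             outcome = .outcome_from_hits(query$species, refs$species[hits]),
             hit_species = paste(unique(refs$species[hits]), collapse = ";"),
             score_or_distance = best, stringsAsFactors = FALSE)
}

# full symmetric matrix of pairwise local-alignment scores
.blast1_score_matrix <- function(residues, scoring = blast1_scoring()) {
  seqs <- Biostrings::DNAStringSet(gsub("-", "", residues, fixed = TRUE))
  n <- length(seqs)
  submat <- .blast1_submat(scoring)
  sc <- matrix(NA_real_, n, n)
  diag(sc) <- 0
  for (i in seq_len(n - 1L)) {
    s <- Biostrings::pairwiseAlignment(
      pattern = seqs[seq.int(i + 1L, n)], subject = seqs[[i]],
      type = "local", substitutionMatrix = submat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext,
      scoreOnly = TRUE)
    sc[i, seq.int(i + 1L, n)] <- sc[seq.int(i + 1L, n), i] <- s
  }
  sc
}

#' Leave-one-out identification report
#'
#' Runs every sample once as a query against all remaining samples
#' (conspecifics retained), for the nearest-distance method and/or the
#' local-alignment method, and tallies correct / ambiguous / incorrect
#' (/ unassignable) outcomes overall and per species.
#'
#' Samples from single-sample species can never be identified correctly
#' under leave-one-out; they are flagged in the per-species table.
#'
#' @param aln An `aligned_set`.
#' @param methods Any of `"distance"`, `"blast1"`.
#' @param scoring Scoring for the alignment method.
#' @param tol Distance tie tolerance.
#' @param d Optional precomputed distance matrix (saves recomputation).
#' @return Object of class `identification_report`: list with `per_query`
#'   (one row per query x method), `per_method` (percentages; they sum to
#'   100 before rounding) and `per_species` (counts and correct % per
#'   species x method, with a `singleton` flag).
#' @export
evaluate_identification <- function(aln, methods = c("distance", "blast1"),
                                    scoring = blast1_scoring(),
                                    tol = 1e-12, d = NULL) {
  aln <- validate_alignment(aln)
  methods <- match.arg(methods, c("distance", "blast1"), several.ok = TRUE)
  recs <- aln_records(aln)
  species <- setNames(aln$meta$species, aln$meta$sample_id)
  rows <- list()
  if ("distance" %in% methods) {
    if (is.null(d)) d <- k2p_matrix(aln, quiet = TRUE)
    for (id in aln$meta$sample_id) {
      rows[[length(rows) + 1L]] <-
        nearest_distance_identify(id, d, species, tol = tol)
    }
  }
  if ("blast1" %in% methods) {
    # local-alignment scores are symmetric, so the leave-one-out scores
    # for all queries come from one pass over unordered pairs
    sc <- .blast1_score_matrix(recs$residues, scoring)
    for (i in seq_len(nrow(recs))) {
      scores <- sc[i, -i]
      best <- max(scores)
      hits <- which(scores == best)
      ref_sp <- recs$species[-i]
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = recs$sample_id[i], method = "BLAST1",
        outcome = .outcome_from_hits(recs$species[i], ref_sp[hits]),
        hit_species = paste(unique(ref_sp[hits]), collapse = ";"),
        score_or_distance = best, stringsAsFactors = FALSE)
    }
  }
  per_query <- do.call(rbind, rows)

  outcomes <- c("correct", "ambiguous", "incorrect", "unassignable")
  per_method <- do.call(rbind, lapply(unique(per_query$method), function(m) {
    oc <- per_query$outcome[per_query$method == m]
    counts <- vapply(outcomes, function(o) sum(oc == o), 0L)
    data.frame(method = m, n_queries = length(oc), t(counts),
               correct_pct = 100 * counts[["correct"]] / length(oc),
               ambiguous_pct = 100 * counts[["ambiguous"]] / length(oc),
               incorrect_pct = 100 * counts[["incorrect"]] / length(oc),
               unassignable_pct = 100 * counts[["unassignable"]] / length(oc),
               stringsAsFactors = FALSE)
  }))

  counts_by_sp <- table(aln$meta$species)
  per_species <- do.call(rbind, lapply(unique(per_query$method), function(m) {
    pq <- per_query[per_query$method == m, ]
    sp <- species[pq$query_id]
    do.call(rbind, lapply(sort(unique(sp)), function(s) {
      oc <- pq$outcome[sp == s]
      data.frame(species = s, method = m, n = length(oc),
                 correct = sum(oc == "correct"),
                 ambiguous = sum(oc == "ambiguous"),
                 incorrect = sum(oc == "incorrect"),
                 unassignable = sum(oc == "unassignable"),
                 correct_pct = 100 * mean(oc == "correct"),
                 singleton = counts_by_sp[[s]] == 1L,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(per_method) <- rownames(per_species) <- NULL
  structure(list(per_query = per_query, per_method = per_method,
                 per_species = per_species),
            class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  cat("identification_report (leave-one-out,",
      x$per_method$n_queries[1L], "queries)\n")
  for (i in seq_len(nrow(x$per_method))) {
    r <- x$per_method[i, ]
    cat(sprintf("  %-8s correct %.1f%%  ambiguous %.1f%%  incorrect %.1f%%",
                r$method, r$correct_pct, r$ambiguous_pct, r$incorrect_pct))
    if (r$unassignable > 0) cat(sprintf("  unassignable %.1f%%",
                                        r$unassignable_pct))
    cat("\n")
  }
  invisible(x)
}
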