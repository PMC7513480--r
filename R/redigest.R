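# In silico restriction digestion with IUPAC-degenerate recognition
# sites, and enzyme ranking for haplotype discrimination (PCR-RFLP).

# IUPAC bitmasks: A=1, C=2, G=4, T=8
.IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L,
                 W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L,
                 V = 7L, N = 15L)

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param recognition Recognition pattern in IUPAC letters (e.g. `"GGWCC"`).
#' @param cut_offset Bases from the pattern start to the cut on the top
#'   strand (0 = cut before the first pattern base).
#' @return Object of class `enzyme`.
#' @export
#' @examples
#' enzyme("AvaII", "GGWCC", 1)
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  pat <- strsplit(recognition, "")[[1L]]
  if (!all(pat %in% names(.IUPAC_BITS))) {
    stop("recognition pattern contains non-IUPAC letters")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > length(pat)) {
    stop("cut_offset must lie within the pattern (0..", length(pat), ")")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset), class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  pat <- x$recognition
  cat(x$name, ": ", substr(pat, 1L, x$cut_offset), "^",
      substr(pat, x$cut_offset + 1L, nchar(pat)), "\n", sep = "")
  invisible(x)
}

#' Built-in restriction enzymes
#'
#' MseI (`T^TAA`), PstI (`CTGCA^G`) and AvaII (`G^GWCC`) -- all
#' palindromic, so forward-strand scanning finds every site.
#'
#' @return Named list of `enzyme` objects.
#' @export
restriction_enzymes <- function() {
  list(MseI = enzyme("MseI", "TTAA", 1L),
       PstI = enzyme("PstI", "CTGCAG", 5L),
       AvaII = enzyme("AvaII", "GGWCC", 1L))
}

#' Read enzyme definitions from TSV
#'
#' @param path TSV with header and columns `name`, `recognition`,
#'   `cut_offset`.
#' @return Named list of `enzyme` objects.
#' @export
read_enzyme_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  enz <- lapply(seq_len(nrow(tab)), function(i)
    enzyme(tab$name[i], tab$recognition[i], tab$cut_offset[i]))
  setNames(enz, tab$name)
}

.strip_gaps <- function(s) gsub("-", "", s, fixed = TRUE)

#' Find recognition sites in a sequence
#'
#' Scans the gap-stripped forward strand exhaustively (overlapping
#' matches included).  In strict mode (default) a sequence position
#' matches a pattern letter only if it is an unambiguous A/C/G/T within
#' the pattern letter's IUPAC set; ambiguity codes in the sequence never
#' match.  In permissive mode a position matches when the IUPAC sets of
#' the sequence and pattern letters intersect.
#'
#' @param seq Residue string (gaps are stripped before scanning).
#' @param enz An `enzyme`.
#' @param permissive Use intersection matching for sequence ambiguity
#'   codes.
#' @return Sorted 1-based start positions of the recognition sites on the
#'   ungapped sequence.
#' @export
find_sites <- function(seq, enz, permissive = FALSE) {
  stopifnot(inherits(enz, "enzyme"))
  s <- strsplit(toupper(.strip_gaps(seq)), "")[[1L]]
  pat <- strsplit(enz$recognition, "")[[1L]]
  m <- length(pat)
  n <- length(s)
  if (n < m) return(integer())
  sbits <- .IUPAC_BITS[s]
  sbits[is.na(sbits)] <- 0L
  if (!permissive) sbits[!(s %in% c("A", "C", "G", "T"))] <- 0L
  ok <- rep(TRUE, n - m + 1L)
  for (k in seq_len(m)) {
    pb <- .IUPAC_BITS[[pat[k]]]
    ok <- ok & (bitwAnd(sbits[seq.int(k, n - m + k)], pb) > 0L)
  }
  which(ok)
}

#' Digest a linear sequence with one enzyme
#'
#' @param seq Residue string or one-row record data frame / list with a
#'   `residues` field (and optionally `sample_id`).
#' @param enz An `enzyme`.
#' @param permissive Passed to [find_sites()].
#' @return Object of class `digest_profile`: list with `sample_id`,
#'   `enzyme`, `cut_positions` (1-based position of the base after which
#'   the top strand is cleaved, deduplicated; cuts falling at either
#'   molecule end are not cuts) and `fragment_lengths` (ascending; sums
#'   to the ungapped length).
#' @export
digest <- function(seq, enz, permissive = FALSE) {
  sample_id <- NA_character_
  if (is.list(seq)) {
    if (!is.null(seq$sample_id)) sample_id <- seq$sample_id[[1L]]
    seq <- seq$residues[[1L]]
  }
  L <- nchar(.strip_gaps(seq))
  sites <- find_sites(seq, enz, permissive = permissive)
  cuts <- sort(unique(sites + enz$cut_offset - 1L))
  cuts <- cuts[cuts >= 1L & cuts < L]
  frags <- diff(c(0L, cuts, L))
  structure(list(sample_id = sample_id, enzyme = enz$name,
                 cut_positions = as.integer(cuts),
                 fragment_lengths = sort(as.integer(frags))),
            class = "digest_profile")
}

#' Digest profiles for a set of records and enzymes
#'
#' @param records Record data frame (from [read_fasta()] or
#'   [aln_records()]); gaps are stripped per sequence.
#' @param enzymes Named list of `enzyme` objects
#'   (default [restriction_enzymes()]).
#' @param permissive Passed to [find_sites()].
#' @return Data frame with one row per sample x enzyme: `sample_id`,
#'   `enzyme`, `n_cuts`, `cut_positions` and `fragment_lengths`
#'   (`,`-collapsed strings; fragment lengths ascending).
#' @export
digest_profiles <- function(records, enzymes = restriction_enzymes(),
                            permissive = FALSE) {
  rows <- list()
  for (i in seq_len(nrow(records))) {
    for (enz in enzymes) {
      p <- digest(records[i, ], enz, permissive = permissive)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = records$sample_id[i], enzyme = enz$name,
        n_cuts = length(p$cut_positions),
        cut_positions = paste(p$cut_positions, collapse = ","),
        fragment_lengths = paste(p$fragment_lengths, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Rank enzymes (and enzyme pairs) by haplotype discrimination power
#'
#' Discrimination power of an enzyme set is the number of haplotype pairs
#' it separates, i.e. pairs whose fragment-length multisets differ for at
#' least one enzyme of the set.  Ties are broken by fewer total cuts, then
#' by name.  Each haplotype is represented by its first sample's profile.
#'
#' @param profiles Data frame from [digest_profiles()].
#' @param haplotype_of Named vector mapping sample id to haplotype id.
#' @param pairs Also rank all two-enzyme combinations.
#' @return Data frame `enzymes`, `power`, `n_pairs`, `total_cuts`, ranked
#'   descending by power.  With a single haplotype, a zero-row frame (with
#'   a message).
#' @export
discriminate_haplotypes <- function(profiles, haplotype_of, pairs = TRUE) {
  haps <- unique(haplotype_of)
  if (length(haps) < 2L) {
    message("only one haplotype: nothing to discriminate")
    return(data.frame(enzymes = character(), power = integer(),
                      n_pairs = integer(), total_cuts = integer(),
                      stringsAsFactors = FALSE))
  }
  reps <- vapply(haps, function(h)
    names(haplotype_of)[haplotype_of == h][1L], "")
  enz_names <- unique(profiles$enzyme)
  frag_of <- function(sample, e) {
    profiles$fragment_lengths[profiles$sample_id == sample &
                                profiles$enzyme == e]
  }
  cuts_of <- function(sample, e) {
    profiles$n_cuts[profiles$sample_id == sample & profiles$enzyme == e]
  }
  hap_pairs <- combn(seq_along(haps), 2L)
  sep_by <- function(enz_set) {
    apply(hap_pairs, 2L, function(pr) {
      any(vapply(enz_set, function(e)
        !identical(frag_of(reps[pr[1L]], e), frag_of(reps[pr[2L]], e)),
        TRUE))
    })
  }
  sets <- as.list(enz_names)
  if (pairs && length(enz_names) >= 2L) {
    sets <- c(sets, combn(enz_names, 2L, simplify = FALSE))
  }
  out <- do.call(rbind, lapply(sets, function(es) {
    data.frame(enzymes = paste(es, collapse = "+"),
               power = sum(sep_by(es)),
               n_pairs = ncol(hap_pairs),
               total_cuts = sum(vapply(es, function(e)
                 sum(vapply(reps, cuts_of, 0L, e = e)), 0L)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$power, out$total_cuts, out$enzymes), ]
  rownames(out) <- NULL
  out
}
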