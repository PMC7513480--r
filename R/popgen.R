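# Nucleotide polymorphism and neutrality statistics: segregating sites,
# haplotypes, pi, Watterson's theta, Tajima's D.
#
# Indel rule: any column containing a gap or an ambiguity code in any
# sequence of the analysed set is excluded from all statistics, so each
# group is analysed over its own maximal indel-free site set.

# indices of columns where every residue is A/C/G/T
.included_sites <- function(aln) {
  ok <- apply(aln$mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  which(ok)
}

#' Segregating sites
#'
#' @param aln An `aligned_set`.
#' @return List with `S` (count) and `positions` (1-based alignment
#'   columns, among gap/ambiguity-free columns only).
#' @export
segregating_sites <- function(aln) {
  aln <- validate_alignment(aln)
  inc <- .included_sites(aln)
  if (!length(inc)) return(list(S = 0L, positions = integer()))
  seg <- inc[vapply(inc, function(j)
    length(unique(aln$mat[, j])) > 1L, TRUE)]
  list(S = length(seg), positions = as.integer(seg))
}

#' Haplotype count and assignment
#'
#' Haplotypes are distinct residue strings over the indel-free columns;
#' numbering is deterministic by first occurrence.
#'
#' @param aln An `aligned_set`.
#' @return List with `H` (count) and `assignment` (named integer vector,
#'   sample id -> haplotype id).
#' @export
haplotypes <- function(aln) {
  aln <- validate_alignment(aln)
  inc <- .included_sites(aln)
  key <- apply(aln$mat[, inc, drop = FALSE], 1L, paste, collapse = "")
  ids <- as.integer(factor(key, levels = unique(key)))
  list(H = length(unique(ids)),
       assignment = setNames(ids, aln$meta$sample_id))
}

#' Nucleotide diversity and Watterson's theta
#'
#' Over the `L` indel-free columns: `mean_pairwise_k` is the average
#' number of pairwise differences, `pi = mean_pairwise_k / L`, and
#' `theta_w = S / (a1 * L)` with `a1 = sum_{i=1}^{n-1} 1/i`.
#'
#' @param aln An `aligned_set` with >= 2 sequences.
#' @return List with `pi`, `theta_w`, `mean_pairwise_k`, `S`, `L`, `n`.
#'   When `L = 0` the per-site quantities are `NA` (flagged via `L`).
#' @export
diversity <- function(aln) {
  aln <- validate_alignment(aln)
  n <- nrow(aln$mat)
  inc <- .included_sites(aln)
  L <- length(inc)
  if (L == 0L) {
    return(list(pi = NA_real_, theta_w = NA_real_,
                mean_pairwise_k = NA_real_, S = 0L, L = 0L, n = n))
  }
  m <- aln$mat[, inc, drop = FALSE]
  k <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) k <- k + sum(m[i, ] != m[j, ])
  }
  k_bar <- k / (n * (n - 1L) / 2L)
  S <- sum(vapply(seq_len(L), function(jj)
    length(unique(m[, jj])) > 1L, TRUE))
  a1 <- sum(1 / seq_len(n - 1L))
  list(pi = k_bar / L, theta_w = S / (a1 * L), mean_pairwise_k = k_bar,
       S = as.integer(S), L = L, n = n)
}

#' Tajima's D
#'
#' Standard formulation: with `k` the mean pairwise difference count,
#' `S` segregating sites, and the usual constants
#' `a1, a2, b1, b2, c1, c2, e1, e2`,
#' `D = (k - S/a1) / sqrt(e1*S + e2*S*(S-1))`.
#' Requires `n >= 4` and `S >= 1`; otherwise the statistic is undefined
#' and `NA` is returned (never coerced to 0).
#'
#' @param aln An `aligned_set`.
#' @return Numeric scalar, or `NA` with attribute `"reason"` when
#'   undefined.
#' @export
tajima_d <- function(aln) {
  aln <- validate_alignment(aln)
  div <- diversity(aln)
  n <- div$n
  if (n < 4L) return(structure(NA_real_, reason = "n < 4"))
  if (is.na(div$pi) || div$S < 1L) {
    return(structure(NA_real_, reason = "no segregating sites"))
  }
  S <- div$S
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (div$mean_pairwise_k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Polymorphism and neutrality summaries per group
#'
#' Computes, per group (e.g. genome codes AAA, AAB, AA, BB, ABB, or
#' wild/subspecies/cultivar categories), the number of sequences `n`,
#' analysed `sites`, segregating sites `S`, haplotypes `H`, `pi`,
#' `theta_w` and Tajima's `D`.  Each group is analysed over its own
#' indel-free site set.  Optionally, groups can be assigned to families
#' (e.g. A genome vs B genome); an `"Overall"` row over the union of each
#' family's samples is then appended.
#'
#' @param aln An `aligned_set`.
#' @param groups Sample-to-group map: named character vector (names =
#'   sample ids) or vector in `aln` record order.
#' @param families Optional group-to-family map (named character vector).
#' @return Data frame with columns `group`, `family`, `n`, `sites`, `S`,
#'   `H`, `pi`, `theta_w`, `tajima_d`.  Groups with `n < 2` have `NA`
#'   diversity.
#' @export
group_summaries <- function(aln, groups, families = NULL) {
  aln <- validate_alignment(aln)
  if (!is.null(names(groups))) {
    groups <- groups[aln$meta$sample_id]
  } else stopifnot(length(groups) == nrow(aln$meta))
  groups <- unname(groups)

  one <- function(label, family, idx) {
    if (length(idx) < 2L) {
      return(data.frame(group = label, family = family, n = length(idx),
                        sites = NA_integer_, S = NA_integer_,
                        H = if (length(idx)) 1L else 0L,
                        pi = NA_real_, theta_w = NA_real_,
                        tajima_d = NA_real_, stringsAsFactors = FALSE))
    }
    sub <- subset_aln(aln, idx)
    div <- diversity(sub)
    data.frame(group = label, family = family, n = div$n, sites = div$L,
               S = div$S, H = haplotypes(sub)$H, pi = div$pi,
               theta_w = div$theta_w,
               tajima_d = as.numeric(tajima_d(sub)),
               stringsAsFactors = FALSE)
  }

  fam_of <- function(g) {
    if (!is.null(families) && g %in% names(families)) families[[g]]
    else NA_character_
  }
  lv <- unique(groups[!is.na(groups)])
  out <- do.call(rbind, lapply(lv, function(g)
    one(g, fam_of(g), which(groups == g))))
  if (!is.null(families)) {
    for (f in unique(families)) {
      idx <- which(groups %in% names(families)[families == f])
      if (length(idx)) {
        out <- rbind(out, one(paste("Overall", f), f, idx))
      }
    }
  }
  rownames(out) <- NULL
  out
}
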