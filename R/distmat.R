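# Kimura 2-parameter distances with pairwise deletion.

# Integer coding: A=1, C=2, G=3, T=4; gaps and ambiguity codes -> NA.
# Ambiguity codes are never partially matched: any non-ACGT symbol drops
# the site from the comparison (pairwise deletion).
.encode_nt <- function(chars) {
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  unname(code[chars])
}

.k2p_from_counts <- function(n_sites, n_ts, n_tv) {
  if (n_sites == 0L) {
    return(list(distance = NA_real_, P = NA_real_, Q = NA_real_,
                sites_compared = 0L, status = "no_sites"))
  }
  P <- n_ts / n_sites
  Q <- n_tv / n_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(distance = NA_real_, P = P, Q = Q,
                sites_compared = n_sites, status = "saturated"))
  }
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  list(distance = d, P = P, Q = Q, sites_compared = n_sites, status = "ok")
}

.k2p_codes <- function(ca, cb) {
  ok <- !is.na(ca) & !is.na(cb)
  n <- sum(ok)
  if (n == 0L) return(.k2p_from_counts(0L, 0L, 0L))
  a <- ca[ok]; b <- cb[ok]
  diff <- a != b
  # transitions: A<->G (1,3) and C<->T (2,4); both pairs differ by 2
  ts <- diff & (abs(a - b) == 2L)
  .k2p_from_counts(n, sum(ts), sum(diff) - sum(ts))
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites where either residue is a gap or an ambiguity code are excluded
#' (pairwise deletion).  With transition proportion `P` and transversion
#' proportion `Q` over the compared sites, the distance is
#' `d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))` substitutions/site.
#'
#' @param a,b Residue strings of equal length (or character vectors of
#'   single residues).
#' @param details If `TRUE`, return a list with `distance`, `P`, `Q`,
#'   `sites_compared` and `status`; otherwise the bare distance.
#' @return The distance, or `NA` when undefined.  Undefined comparisons
#'   are flagged via `status`: `"no_sites"` (zero comparable sites) or
#'   `"saturated"` (the log argument is non-positive); these are distinct
#'   from a genuine zero distance.
#' @export
#' @examples
#' k2p("ACGTACGTAC", "GCGTACGTAA")  # 1 transition + 1 transversion in 10
k2p <- function(a, b, details = FALSE) {
  if (length(a) == 1L) a <- strsplit(a, "")[[1L]]
  if (length(b) == 1L) b <- strsplit(b, "")[[1L]]
  if (length(a) != length(b)) {
    stop("sequences must be aligned to equal length")
  }
  res <- .k2p_codes(.encode_nt(toupper(a)), .encode_nt(toupper(b)))
  if (details) res else res$distance
}

#' All pairwise K2P distances of an aligned set
#'
#' @param aln An `aligned_set` (see [validate_alignment()]).
#' @param quiet Suppress the message summarising undefined pairs.
#' @return A symmetric numeric matrix (substitutions/site) with zero
#'   diagonal, sample ids as dimnames and `NA` for undefined pairs.
#'   Attribute `"status"` holds the per-pair status matrix (`"ok"`,
#'   `"no_sites"`, `"saturated"`) and attribute `"n_undefined"` the count
#'   of undefined off-diagonal pairs.
#' @export
k2p_matrix <- function(aln, quiet = FALSE) {
  aln <- validate_alignment(aln)
  n <- nrow(aln$mat)
  codes <- matrix(.encode_nt(aln$mat), nrow = n)
  d <- matrix(0, n, n, dimnames = list(aln$meta$sample_id, aln$meta$sample_id))
  status <- matrix("ok", n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    ci <- codes[i, ]
    for (j in seq.int(i + 1L, n)) {
      res <- .k2p_codes(ci, codes[j, ])
      d[i, j] <- d[j, i] <- res$distance
      status[i, j] <- status[j, i] <- res$status
    }
  }
  n_undef <- sum(is.na(d[upper.tri(d)]))
  if (n_undef > 0L && !quiet) {
    message(n_undef, " of ", n * (n - 1L) / 2L,
            " pairs have undefined K2P distance (",
            sum(status[upper.tri(status)] == "saturated"), " saturated, ",
            sum(status[upper.tri(status)] == "no_sites"), " without sites)")
  }
  attr(d, "status") <- status
  attr(d, "n_undefined") <- n_undef
  d
}

#' Write a distance matrix as square TSV
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#'
#' Labels longer than 10 characters are written in relaxed PHYLIP style
#' (label, whitespace, values).  `NA` entries are written as `-1.0`,
#' the conventional marker for undefined distances.
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_phylip <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  vals <- ifelse(is.na(d), -1, d)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(rownames(d)[i],
                       sprintf("%.8f", vals[i, ])), collapse = "  "), con)
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' Accepts the relaxed (whitespace-separated) square format written by
#' [write_dist_phylip()]; `-1` entries become `NA`.
#'
#' @param path Input path.
#' @return Symmetric numeric matrix with labels as dimnames.
#' @export
read_dist_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  toks <- strsplit(trimws(lines[2L:(n + 1L)]), "\\s+")
  labels <- vapply(toks, `[`, "", 1L)
  d <- t(vapply(toks, function(tk) as.numeric(tk[-1L]), numeric(n)))
  dimnames(d) <- list(labels, labels)
  d[d < 0] <- NA_real_
  d
}
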