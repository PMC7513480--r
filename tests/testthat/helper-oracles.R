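# Independent oracles, deliberately naive and separate from the package's
# implementation paths.

# character-by-character transition/transversion recount + closed form
oracle_k2p <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  pur <- c("A", "G"); pyr <- c("C", "T")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(ca)) {
    x <- ca[i]; y <- cb[i]
    if (!(x %in% c(pur, pyr)) || !(y %in% c(pur, pyr))) next
    n <- n + 1L
    if (x == y) next
    same_class <- (x %in% pur && y %in% pur) || (x %in% pyr && y %in% pyr)
    if (same_class) ts <- ts + 1L else tv <- tv + 1L
  }
  if (n == 0L) return(NA_real_)
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# brute-force Smith-Waterman with affine gaps; a length-k gap costs
# open + k * ext (same convention as the package's aligner)
oracle_sw <- function(a, b, match = 1, mismatch = -2, open = 5, ext = 2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consume a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consume b)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                              Iy[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# exact two-sided rank-sum p-value by full enumeration of assignments
oracle_ranksum_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combs <- combn(nx + ny, nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- nx * (nx + ny + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# naive scanning digest: expand IUPAC pattern per position, check every
# window character by character (strict: sequence letter must be ACGT)
oracle_digest <- function(seq, pattern, cut_offset) {
  expand <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                 B = c("C", "G", "T"), D = c("A", "G", "T"),
                 H = c("A", "C", "T"), V = c("A", "C", "G"),
                 N = c("A", "C", "G", "T"))
  s <- strsplit(gsub("-", "", toupper(seq)), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  L <- length(s); m <- length(p)
  sites <- integer()
  if (L >= m) {
    for (st in seq_len(L - m + 1)) {
      hit <- TRUE
      for (k in seq_len(m)) {
        if (!(s[st + k - 1] %in% c("A", "C", "G", "T")) ||
            !(s[st + k - 1] %in% expand[[p[k]]])) { hit <- FALSE; break }
      }
      if (hit) sites <- c(sites, st)
    }
  }
  cuts <- sort(unique(sites + cut_offset - 1))
  cuts <- cuts[cuts >= 1 & cuts < L]
  list(sites = sites, cuts = cuts,
       fragments = sort(diff(c(0, cuts, L))))
}

# random ACGT string, optionally with gaps/ambiguities sprinkled in
random_seq <- function(L, p_gap = 0, p_amb = 0) {
  pool <- c("A", "C", "G", "T")
  s <- sample(pool, L, replace = TRUE)
  if (p_gap > 0) s[runif(L) < p_gap] <- "-"
  if (p_amb > 0) {
    amb <- runif(L) < p_amb
    s[amb] <- sample(c("N", "R", "Y", "W"), sum(amb), replace = TRUE)
  }
  paste(s, collapse = "")
}

# small labelled record set builder
make_records <- function(residues, species, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%d", seq_along(residues))
  data.frame(sample_id = ids, species = species, genome_code = NA_character_,
             residues = residues, stringsAsFactors = FALSE)
}

# the worked 4 x 16 polymorphism toy: S = 3 (columns 14-16),
# pairwise differences 1,2,3,1,2,1
tajima_toy <- function() {
  validate_alignment(make_records(
    c(paste0(strrep("A", 13), "AAA"),
      paste0(strrep("A", 13), "AAG"),
      paste0(strrep("A", 13), "ACG"),
      paste0(strrep("A", 13), "CCG")),
    species = "toy"))
}
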