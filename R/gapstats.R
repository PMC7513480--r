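# Barcoding-gap statistics: six divergence metrics, distance histograms,
# threshold proportions, Wilcoxon two-sample comparison.

#' Pairwise distances annotated as intra- or inter-specific
#'
#' @param d Distance matrix from [k2p_matrix()].
#' @param species Named character vector mapping sample id to species, or
#'   unnamed in matrix row order.
#' @return Data frame with one row per unordered pair and defined
#'   distance: `id_a`, `id_b`, `sp_a`, `sp_b`, `distance`, `type`
#'   (`"intra"`/`"inter"`).  Attribute `"n_excluded"` counts pairs dropped
#'   for undefined distance.
#' @export
pair_distances <- function(d, species) {
  species <- .species_vector(d, species)
  n <- nrow(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  out <- data.frame(
    id_a = rownames(d)[idx[, 1L]], id_b = rownames(d)[idx[, 2L]],
    sp_a = species[idx[, 1L]], sp_b = species[idx[, 2L]],
    distance = d[idx], stringsAsFactors = FALSE)
  out$type <- ifelse(out$sp_a == out$sp_b, "intra", "inter")
  keep <- !is.na(out$distance)
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_excluded") <- sum(!keep)
  res
}

.species_vector <- function(d, species) {
  if (!is.null(names(species))) {
    miss <- setdiff(rownames(d), names(species))
    if (length(miss)) stop("no species for samples: ",
                           paste(miss, collapse = ", "))
    species <- species[rownames(d)]
  } else if (length(species) != nrow(d)) {
    stop("'species' must be named by sample id or match matrix order")
  }
  unname(species)
}

#' Six divergence metrics for barcoding-gap assessment
#'
#' Computes the standard suite of intra-/inter-specific K2P divergence
#' metrics over a species-labelled distance matrix:
#' \describe{
#'   \item{all_inter}{mean over all between-species sample pairs.}
#'   \item{theta_prime}{species-pair weighted inter-specific divergence:
#'     the between-species distances are first averaged within each
#'     species pair, then over species pairs.}
#'   \item{min_inter}{each species' nearest-neighbor distance (minimum
#'     distance from any of its samples to any heterospecific sample),
#'     averaged over species.}
#'   \item{all_intra}{mean over all within-species sample pairs.}
#'   \item{theta}{per-species mean intra-specific distance, averaged over
#'     species with >= 2 samples.}
#'   \item{coalescent_depth}{per-species maximum intra-specific distance
#'     (deepest within-species split), averaged over species with >= 2
#'     samples.}
#' }
#' The `sd` column is the standard deviation over the per-unit values each
#' mean averages (sample pairs, species pairs, or species, as listed in
#' `unit`), and `n` the number of such units.  Undefined (`NA`) distances
#' are excluded throughout.  Metrics with no eligible unit (e.g. intra
#' metrics when no species has two samples) are `NA` with `n = 0`.
#'
#' @param d Distance matrix from [k2p_matrix()].
#' @param species Sample-to-species map (see [pair_distances()]).
#' @return Data frame with columns `metric`, `mean`, `sd`, `n`, `unit`.
#' @export
divergence_summary <- function(d, species) {
  species <- .species_vector(d, species)
  pd <- pair_distances(d, setNames(species, rownames(d)))
  inter <- pd$distance[pd$type == "inter"]
  intra <- pd$distance[pd$type == "intra"]

  # species-pair averages (theta_prime units)
  inter_pd <- pd[pd$type == "inter", , drop = FALSE]
  if (nrow(inter_pd)) {
    key <- paste(pmin(inter_pd$sp_a, inter_pd$sp_b),
                 pmax(inter_pd$sp_a, inter_pd$sp_b), sep = "\r")
    sp_pair_means <- tapply(inter_pd$distance, key, mean)
  } else sp_pair_means <- numeric()

  # per-species nearest heterospecific neighbor
  sp_levels <- unique(species)
  min_inter <- vapply(sp_levels, function(s) {
    rows <- inter_pd$sp_a == s | inter_pd$sp_b == s
    if (!any(rows)) NA_real_ else min(inter_pd$distance[rows])
  }, 0)
  min_inter <- min_inter[!is.na(min_inter)]

  # per-species intra mean and max over species with >=2 samples
  intra_pd <- pd[pd$type == "intra", , drop = FALSE]
  if (nrow(intra_pd)) {
    sp_intra_mean <- tapply(intra_pd$distance, intra_pd$sp_a, mean)
    sp_intra_max <- tapply(intra_pd$distance, intra_pd$sp_a, max)
  } else sp_intra_mean <- sp_intra_max <- numeric()

  row <- function(metric, v, unit) {
    data.frame(metric = metric,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) sd(v) else NA_real_,
               n = length(v), unit = unit, stringsAsFactors = FALSE)
  }
  rbind(row("all_inter", inter, "sample pair"),
        row("theta_prime", as.numeric(sp_pair_means), "species pair"),
        row("min_inter", as.numeric(min_inter), "species"),
        row("all_intra", intra, "sample pair"),
        row("theta", as.numeric(sp_intra_mean), "species"),
        row("coalescent_depth", as.numeric(sp_intra_max), "species"))
}

#' Barcoding-gap histogram
#'
#' Bins intra- and inter-specific distances into half-open bins
#' `[lo, hi)` anchored at 0 (default width 0.008 distance units) and
#' reports the ranges and the overlap between the two distributions.
#'
#' @param d Distance matrix from [k2p_matrix()].
#' @param species Sample-to-species map.
#' @param bin_width Bin width in substitutions/site.
#' @return Object of class `gap_histogram`: list with `bins` (data frame
#'   `bin_lo`, `bin_hi`, `intra_count`, `inter_count`, `intra_freq`,
#'   `inter_freq`), `intra_range`, `inter_range`, `overlap_fraction`
#'   (proportion of inter-specific distances less than or equal to the
#'   maximum intra-specific distance; `NA` when a class is empty) and
#'   `bin_width`.  An empty class triggers a warning.
#' @export
gap_histogram <- function(d, species, bin_width = 0.008) {
  stopifnot(bin_width > 0)
  pd <- pair_distances(d, .species_named(d, species))
  intra <- pd$distance[pd$type == "intra"]
  inter <- pd$distance[pd$type == "inter"]
  if (!length(intra)) warning("no defined intra-specific distances")
  if (!length(inter)) warning("no defined inter-specific distances")
  hi <- max(c(intra, inter, 0))
  n_bins <- max(1L, floor(hi / bin_width) + 1L)
  lo_edges <- (seq_len(n_bins) - 1L) * bin_width
  bin_of <- function(v) pmin(floor(v / bin_width) + 1L, n_bins)
  count_in <- function(v) tabulate(bin_of(v), nbins = n_bins)
  intra_count <- count_in(intra)
  inter_count <- count_in(inter)
  bins <- data.frame(
    bin_lo = lo_edges, bin_hi = lo_edges + bin_width,
    intra_count = intra_count, inter_count = inter_count,
    intra_freq = if (length(intra)) intra_count / length(intra) else 0,
    inter_freq = if (length(inter)) inter_count / length(inter) else 0)
  structure(list(
    bins = bins,
    intra_range = if (length(intra)) range(intra) else c(NA_real_, NA_real_),
    inter_range = if (length(inter)) range(inter) else c(NA_real_, NA_real_),
    overlap_fraction = if (length(intra) && length(inter))
      mean(inter <= max(intra)) else NA_real_,
    bin_width = bin_width), class = "gap_histogram")
}

.species_named <- function(d, species) {
  setNames(.species_vector(d, species), rownames(d))
}

#' @export
print.gap_histogram <- function(x, ...) {
  cat("gap_histogram (bin width ", x$bin_width, ")\n", sep = "")
  cat(sprintf("  intra: n=%d range [%.4f, %.4f]\n",
              sum(x$bins$intra_count), x$intra_range[1L], x$intra_range[2L]))
  cat(sprintf("  inter: n=%d range [%.4f, %.4f]\n",
              sum(x$bins$inter_count), x$inter_range[1L], x$inter_range[2L]))
  cat(sprintf("  overlap fraction: %.4f\n", x$overlap_fraction))
  invisible(x)
}

#' Plot a barcoding-gap histogram
#'
#' Side-by-side relative-frequency bars of intra- vs inter-specific
#' distances, in base graphics.
#'
#' @param x A `gap_histogram`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.gap_histogram <- function(x, ...) {
  h <- rbind(intra = x$bins$intra_freq, inter = x$bins$inter_freq)
  colnames(h) <- sprintf("%.3f", x$bins$bin_lo)
  graphics::barplot(h, beside = TRUE, legend.text = c("intra", "inter"),
                    xlab = "K2P distance (bin lower edge)",
                    ylab = "relative frequency", ...)
  invisible(x)
}

#' Proportion of values below (or at) a threshold
#'
#' @param values Non-empty numeric vector (e.g. inter-specific distances).
#' @param threshold Threshold value.
#' @param strict If `TRUE` (default) count `values < threshold`, else
#'   `values <= threshold`.
#' @return The fraction in `[0, 1]`.
#' @export
proportion_below <- function(values, threshold, strict = TRUE) {
  if (!length(values)) stop("'values' is empty")
  if (anyNA(values)) stop("'values' contains NA")
  if (strict) mean(values < threshold) else mean(values <= threshold)
}

#' Wilcoxon rank-sum (Mann-Whitney) two-sample test
#'
#' Compares two distance samples, as used to contrast intra- and
#' inter-specific divergence distributions.  When both samples have at
#' most 10 observations and there are no ties, the exact two-sided p-value
#' is used; otherwise the normal approximation with midranks,
#' tie-corrected variance and continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `statistic` (the Mann-Whitney U for `x`), `p.value`
#'   and `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' wilcoxon_ranksum(c(1, 2), c(3, 4))  # exact p = 1/3
wilcoxon_ranksum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 10L && length(y) <= 10L && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE,
                alternative = "two.sided"))
  p <- ht$p.value
  if (is.na(p)) p <- 1  # degenerate: identical constant samples
  list(statistic = unname(ht$statistic), p.value = min(p, 1),
       method = if (exact) "exact" else "normal")
}
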