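# Synthetic barcode data: species-structured alignments under the Kimura
# (K80) model, neutral-coalescent samples, and planted restriction
# haplotypes.  All generators are deterministic given their seed.

#' Configuration for the species-structured sequence generator
#'
#' Defaults emulate an ITS2-like plant barcode reference set: alignment
#' length drawn from 325--375 bp, root GC content 0.60, mean
#' inter-specific K2P divergence 0.19 and intra-specific divergence 0.035.
#'
#' @param n_species Number of species.
#' @param samples_per_species Samples per species.
#' @param inter_divergence Expected substitutions/site between samples of
#'   different species.
#' @param intra_divergence Expected substitutions/site between conspecific
#'   samples (must not exceed `inter_divergence`).
#' @param kappa Transition/transversion rate ratio of the K80 model.
#' @param length_range Inclusive range the alignment length is drawn from.
#' @param gc_target Root GC fraction.
#' @param species_tree `"star"` (default; expected inter-divergence is
#'   uniform across species pairs) or `"bifurcating"` (a random species
#'   tree scaled so the mean root-to-species depth matches the star
#'   branch; for tree-reconstruction tests).
#' @param indel_rate Expected number of deletion events per sample
#'   (default 0 = no indels).  Each event gaps a run of 1--5 alignment
#'   columns, exercising pairwise-deletion and indel-exclusion paths.
#' @param seed Integer seed (`NULL` = leave the RNG state alone).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_species = 10L, samples_per_species = 5L,
                       inter_divergence = 0.19, intra_divergence = 0.035,
                       kappa = 2, length_range = c(325L, 375L),
                       gc_target = 0.60,
                       species_tree = c("star", "bifurcating"),
                       indel_rate = 0, seed = NULL) {
  species_tree <- match.arg(species_tree)
  stopifnot(n_species >= 1L, samples_per_species >= 1L,
            inter_divergence >= 0, intra_divergence >= 0,
            intra_divergence <= inter_divergence,
            kappa > 0, gc_target > 0, gc_target < 1, indel_rate >= 0,
            length_range[1L] >= 1L, length_range[2L] >= length_range[1L])
  structure(list(n_species = as.integer(n_species),
                 samples_per_species = as.integer(samples_per_species),
                 inter_divergence = inter_divergence,
                 intra_divergence = intra_divergence, kappa = kappa,
                 length_range = as.integer(length_range),
                 gc_target = gc_target, species_tree = species_tree,
                 indel_rate = indel_rate, seed = seed),
            class = "sim_config")
}

# K80 per-site substitution along a branch of expected length d
# (substitutions/site).  codes: 1=A, 2=C, 3=G, 4=T.
.evolve_k80 <- function(codes, d, kappa) {
  if (d <= 0) return(codes)
  beta <- 1 / (kappa + 2)
  alpha <- kappa / (kappa + 2)
  e4b <- exp(-4 * beta * d)
  e2ab <- exp(-2 * (alpha + beta) * d)
  p_ts <- 0.25 + 0.25 * e4b - 0.5 * e2ab
  p_tv <- 0.25 - 0.25 * e4b       # each of the two transversions
  p_same <- 1 - p_ts - 2 * p_tv
  partner <- c(3L, 4L, 1L, 2L)    # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  u <- runif(length(codes))
  out <- codes
  out[u >= p_same & u < p_same + p_ts] <-
    partner[codes[u >= p_same & u < p_same + p_ts]]
  sel <- u >= p_same + p_ts & u < p_same + p_ts + p_tv
  out[sel] <- tv1[codes[sel]]
  sel <- u >= p_same + p_ts + p_tv
  out[sel] <- tv2[codes[sel]]
  out
}

.codes_to_chars <- function(codes) c("A", "C", "G", "T")[codes]

#' Simulate a species-structured barcode alignment
#'
#' A root sequence is drawn i.i.d. with the target GC; each species
#' ancestor evolves from the root along a branch of
#' `(inter_divergence - intra_divergence) / 2`, and each sample from its
#' species ancestor along `intra_divergence / 2`, all under the K80 model
#' with ratio `kappa` (star phylogeny among species, no indels).  Branch
#' lengths are chosen so that the expected pairwise divergence is exactly
#' `intra_divergence` within species and `inter_divergence` between
#' species.  A fixed seed gives byte-identical output.
#'
#' Two optional modes depart from this default: `species_tree =
#' "bifurcating"` evolves the species ancestors along a random
#' bifurcating tree (returned in the truth table) instead of the star,
#' and `indel_rate > 0` gaps short runs of columns per sample to
#' exercise pairwise-deletion and indel-exclusion code paths.
#'
#' @param cfg A [sim_config()].
#' @return List with `aln` (an `aligned_set`; sample ids `spXX_sY`,
#'   species `spXX`) and `truth` (list: `config`, `length`,
#'   `species_ancestors`, `assignment` data frame, `species_branch`,
#'   `sample_branch`).
#' @export
simulate_barcode_set <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  L <- if (cfg$length_range[1L] == cfg$length_range[2L]) cfg$length_range[1L]
       else sample(seq.int(cfg$length_range[1L], cfg$length_range[2L]), 1L)
  p_gc <- cfg$gc_target
  root <- sample.int(4L, L, replace = TRUE,
                     prob = c((1 - p_gc) / 2, p_gc / 2, p_gc / 2,
                              (1 - p_gc) / 2))
  b_sp <- (cfg$inter_divergence - cfg$intra_divergence) / 2
  b_sm <- cfg$intra_divergence / 2
  sp_names <- sprintf("sp%02d", seq_len(cfg$n_species))
  sp_phylo <- NULL
  if (cfg$species_tree == "star" || cfg$n_species < 3L) {
    ancestors <- lapply(sp_names, function(s)
      .evolve_k80(root, b_sp, cfg$kappa))
    names(ancestors) <- sp_names
  } else {
    # random bifurcating species tree, rescaled so the mean
    # root-to-species depth equals the star branch length
    sp_phylo <- ape::rtree(cfg$n_species, tip.label = sp_names)
    depths <- ape::node.depth.edgelength(sp_phylo)[seq_len(cfg$n_species)]
    if (b_sp > 0 && mean(depths) > 0) {
      sp_phylo$edge.length <- sp_phylo$edge.length * b_sp / mean(depths)
    } else sp_phylo$edge.length[] <- 0
    n_tip <- cfg$n_species
    root_node <- n_tip + 1L
    node_seq <- vector("list", n_tip + sp_phylo$Nnode)
    node_seq[[root_node]] <- root
    # parents precede children in ape edge ordering from the root
    for (k in seq_len(nrow(sp_phylo$edge))) {
      par <- sp_phylo$edge[k, 1L]; chl <- sp_phylo$edge[k, 2L]
      node_seq[[chl]] <- .evolve_k80(node_seq[[par]],
                                     sp_phylo$edge.length[k], cfg$kappa)
    }
    ancestors <- setNames(node_seq[seq_len(n_tip)], sp_phylo$tip.label)
    ancestors <- ancestors[sp_names]
  }
  recs <- list()
  for (s in sp_names) {
    for (i in seq_len(cfg$samples_per_species)) {
      codes <- .evolve_k80(ancestors[[s]], b_sm, cfg$kappa)
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = sprintf("%s_s%d", s, i), species = s,
        genome_code = NA_character_,
        residues = paste(.codes_to_chars(codes), collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  if (cfg$indel_rate > 0) {
    for (i in seq_len(nrow(records))) {
      n_ev <- rpois(1L, cfg$indel_rate)
      if (n_ev == 0L) next
      ch <- strsplit(records$residues[i], "")[[1L]]
      for (ev in seq_len(n_ev)) {
        len <- sample.int(5L, 1L)
        st <- sample.int(max(1L, L - len + 1L), 1L)
        ch[seq.int(st, min(L, st + len - 1L))] <- "-"
      }
      records$residues[i] <- paste(ch, collapse = "")
    }
  }
  list(aln = validate_alignment(records),
       truth = list(config = cfg, length = L,
                    species_ancestors = vapply(ancestors, function(a)
                      paste(.codes_to_chars(a), collapse = ""), ""),
                    assignment = records[, c("sample_id", "species")],
                    species_branch = b_sp, sample_branch = b_sm,
                    species_phylogeny = sp_phylo))
}

#' Simulate sequences under the standard neutral coalescent
#'
#' A Kingman coalescent genealogy is drawn (time to merge `k` lineages
#' exponential with rate `k(k-1)/2`), mutations are Poisson with mean
#' `theta/2` per unit branch length and placed uniformly on distinct
#' sites (infinite sites approximated on `sites` positions; collisions
#' retried).  Haplotypes are binary variants embedded in an `A`
#' background, the derived allele being `G`, so the alignment feeds
#' directly into the polymorphism statistics
#' (`E[S] = theta * a1`, `E[mean pairwise differences] = theta`).
#'
#' @param n Number of sampled haplotypes (>= 2).
#' @param theta Population-scaled mutation rate for the whole locus.
#' @param sites Number of sites.
#' @param seed Optional integer seed.
#' @return An `aligned_set` (`n` records, species `"coalescent"`).
#' @export
simulate_coalescent <- function(n, theta, sites, seed = NULL) {
  stopifnot(n >= 2L, theta >= 0, sites >= 1L)
  if (!is.null(seed)) set.seed(seed)
  # active lineages: descendant tip sets + accumulated pending length
  active <- lapply(seq_len(n), function(i) i)
  pending <- numeric(n)
  branches <- list()  # closed branches: list(tips, length)
  k <- n
  while (k > 1L) {
    t_k <- rexp(1L, rate = k * (k - 1L) / 2)
    pending <- pending + t_k
    pick <- sample.int(k, 2L)
    for (p in pick) {
      branches[[length(branches) + 1L]] <-
        list(tips = active[[p]], length = pending[p])
    }
    merged <- c(active[[pick[1L]]], active[[pick[2L]]])
    active <- c(active[-pick], list(merged))
    pending <- c(pending[-pick], 0)
    k <- k - 1L
  }
  total_len <- sum(vapply(branches, `[[`, 0, "length"))
  n_mut <- rpois(1L, theta / 2 * total_len)
  if (n_mut > sites) {
    stop("drew ", n_mut, " mutations for ", sites,
         " sites; increase 'sites'")
  }
  mat <- matrix("A", n, sites)
  if (n_mut > 0L) {
    # pick the branch of each mutation by length, then a distinct site
    lens <- vapply(branches, `[[`, 0, "length")
    picked <- sample.int(length(branches), n_mut, replace = TRUE,
                         prob = lens)
    used <- integer()
    for (b in picked) {
      repeat {
        pos <- sample.int(sites, 1L)
        if (!(pos %in% used)) break
      }
      used <- c(used, pos)
      mat[branches[[b]]$tips, pos] <- "G"
    }
  }
  records <- data.frame(sample_id = sprintf("h%d", seq_len(n)),
                        species = "coalescent",
                        genome_code = NA_character_,
                        residues = apply(mat, 1L, paste, collapse = ""),
                        stringsAsFactors = FALSE)
  validate_alignment(records)
}

# first unambiguous base of an IUPAC letter, in A<C<G<T order
.iupac_first <- function(letter) {
  bits <- .IUPAC_BITS[[letter]]
  c("A", "C", "G", "T")[which(bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L)][1L]
}

# mutate sequences until no enzyme matches outside 'keep' windows;
# positions inside any keep window are never touched
.scrub_sites <- function(s, enzymes, keep = NULL, max_iter = 100L) {
  in_keep <- rep(FALSE, length(s))
  if (!is.null(keep)) {
    for (w in keep) in_keep[seq.int(w[1L], w[2L])] <- TRUE
  }
  alt <- c("C", "G", "A", "T")
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    for (enz in enzymes) {
      m <- nchar(enz$recognition)
      pat <- strsplit(enz$recognition, "")[[1L]]
      for (st in find_sites(paste(s, collapse = ""), enz)) {
        span <- seq.int(st, st + m - 1L)
        if (all(in_keep[span])) next  # planted site, leave alone
        # mutate the first free position of the site to break the match
        free <- span[!in_keep[span]]
        pos <- free[1L]
        allowed_bits <- .IUPAC_BITS[[pat[pos - st + 1L]]]
        for (b in alt) {
          if (bitwAnd(.IUPAC_BITS[[b]], allowed_bits) == 0L && b != s[pos]) {
            s[pos] <- b
            break
          }
        }
        dirty <- TRUE
      }
    }
    if (!dirty) return(s)
  }
  stop("could not scrub incidental recognition sites (pattern too dense)")
}

#' Plant restriction-site haplotypes with a known discrimination table
#'
#' Builds `n_haplotypes` variants of a base sequence whose restriction
#' profiles are known by construction: each haplotype receives a distinct
#' per-enzyme count of planted recognition sites (a mixed-radix code over
#' the enzymes), written into fixed non-overlapping windows; incidental
#' sites elsewhere are mutated away first.  Two haplotypes are separated
#' by an enzyme exactly when their planted counts for it differ, which is
#' the returned truth table -- an independent oracle for
#' [discriminate_haplotypes()].
#'
#' @param base Residue string (or record with `residues`); gaps stripped.
#' @param n_haplotypes Number of haplotypes to construct.
#' @param enzymes Named list of `enzyme` objects.
#' @param seed Optional seed (the construction itself is deterministic).
#' @return List with `records` (one per haplotype; species = haplotype
#'   id), `truth` (data frame `hap_a`, `hap_b`, `enzyme`, `separated`)
#'   and `site_counts` (haplotype x enzyme matrix of planted sites).
#' @export
plant_restriction_haplotypes <- function(base, n_haplotypes,
                                         enzymes = restriction_enzymes(),
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.list(base)) base <- base$residues[[1L]]
  s0 <- strsplit(toupper(.strip_gaps(base)), "")[[1L]]
  L <- length(s0)
  E <- length(enzymes)
  stopifnot(n_haplotypes >= 1L, E >= 1L)
  widths <- vapply(enzymes, function(e) nchar(e$recognition), 0L)
  spacer <- 5L

  # choose radices (max planted sites + 1 per enzyme) to cover n_haplotypes
  radix <- rep(1L, E)
  space_needed <- function(r) sum((r - 1L) * (widths + spacer))
  k <- 1L
  while (prod(radix) < n_haplotypes) {
    radix[k] <- radix[k] + 1L
    if (space_needed(radix) > L - 2L * spacer) {
      stop("sequence too short to host the requested haplotype sites")
    }
    k <- if (k == E) 1L else k + 1L
  }

  # fixed slot windows, left to right
  slots <- vector("list", E)
  p <- spacer + 1L
  for (e in seq_len(E)) {
    if (radix[e] > 1L) {
      for (m in seq_len(radix[e] - 1L)) {
        slots[[e]] <- c(slots[[e]], p)
        p <- p + widths[e] + spacer
      }
    }
  }

  s_clean <- .scrub_sites(s0, enzymes)

  counts <- matrix(0L, n_haplotypes, E,
                   dimnames = list(sprintf("hap%d", seq_len(n_haplotypes)),
                                   names(enzymes)))
  recs <- list()
  for (j in seq_len(n_haplotypes)) {
    code <- j - 1L
    s <- s_clean
    keep <- list()
    for (e in seq_len(E)) {
      c_e <- code %% radix[e]
      code <- code %/% radix[e]
      counts[j, e] <- c_e
      if (c_e > 0L) {
        pat <- strsplit(enzymes[[e]]$recognition, "")[[1L]]
        inst <- vapply(pat, .iupac_first, "")
        for (m in seq_len(c_e)) {
          st <- slots[[e]][m]
          s[seq.int(st, st + widths[e] - 1L)] <- inst
          keep[[length(keep) + 1L]] <- c(st, st + widths[e] - 1L)
        }
      }
    }
    # junction artifacts: scrub any site not fully inside a kept window
    s <- .scrub_sites(s, enzymes, keep = keep)
    # verify the realized site set is exactly the planted one per enzyme
    for (e in seq_len(E)) {
      expected <- sort(as.integer(slots[[e]][seq_len(counts[j, e])]))
      got <- as.integer(find_sites(paste(s, collapse = ""), enzymes[[e]]))
      if (!identical(got, expected)) {
        stop("site planting failed for enzyme ", names(enzymes)[e],
             " (a planted window of another enzyme contains its pattern)")
      }
    }
    recs[[j]] <- data.frame(sample_id = sprintf("hap%d", j),
                            species = sprintf("hap%d", j),
                            genome_code = NA_character_,
                            residues = paste(s, collapse = ""),
                            stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)

  truth <- NULL
  if (n_haplotypes >= 2L) {
    pr <- combn(n_haplotypes, 2L)
    truth <- do.call(rbind, lapply(seq_len(ncol(pr)), function(i) {
      a <- pr[1L, i]; b <- pr[2L, i]
      data.frame(hap_a = sprintf("hap%d", a), hap_b = sprintf("hap%d", b),
                 enzyme = names(enzymes),
                 separated = counts[a, ] != counts[b, ],
                 stringsAsFactors = FALSE)
    }))
    rownames(truth) <- NULL
  } else {
    truth <- data.frame(hap_a = character(), hap_b = character(),
                        enzyme = character(), separated = logical(),
                        stringsAsFactors = FALSE)
  }
  list(records = records, truth = truth, site_counts = counts)
}
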