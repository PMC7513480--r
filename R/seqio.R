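# Reading, validating and writing species-labelled barcode sequences.

IUPAC_NT <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-")

#' Read species-labelled barcode sequences from FASTA
#'
#' Parses a (plain or aligned) FASTA file into a data frame of labelled
#' records.  Residues are uppercased and `U` is mapped to `T`; every
#' character must then be an IUPAC nucleotide code or the gap `-` (the `.`
#' gap dialect is rejected).
#'
#' Two header schemes are supported.  The default `"pipe"` scheme expects
#' `>species|sample_id|genome_code` with the genome code optional
#' (e.g. `>Musa_acuminata|KY710753` or `>Robusta|KY710765|AAA`).  The
#' `"regex"` scheme applies a user regular expression with 2--3 capture
#' groups in the order species, sample id, genome code.  Alternatively a
#' tab-separated sample sheet (columns `sample_id`, `species`, optionally
#' `genome_code`) can supply the labels, in which case headers are taken
#' verbatim as sample ids.
#'
#' @param path Path to a FASTA file.
#' @param label_scheme `"pipe"` (default) or `"regex"`.
#' @param regex Regular expression with capture groups, used when
#'   `label_scheme = "regex"`.
#' @param sample_sheet Optional path to a TSV sample sheet; overrides
#'   header parsing.
#' @return A data frame with columns `sample_id`, `species`, `genome_code`
#'   (`NA` when absent) and `residues`, in file order.  An empty file
#'   yields a zero-row frame.
#' @seealso [validate_alignment()], [write_fasta()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">Musa_acuminata|S1|AA", "acgt"), fa)
#' read_fasta(fa)
read_fasta <- function(path, label_scheme = c("pipe", "regex"),
                       regex = NULL, sample_sheet = NULL) {
  label_scheme <- match.arg(label_scheme)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  residues <- toupper(as.character(set))
  residues <- gsub("U", "T", residues, fixed = TRUE)

  n <- length(residues)
  if (n == 0L) {
    return(data.frame(sample_id = character(), species = character(),
                      genome_code = character(), residues = character(),
                      stringsAsFactors = FALSE))
  }

  if (!is.null(sample_sheet)) {
    sheet <- read_sample_sheet(sample_sheet)
    idx <- match(headers, sheet$sample_id)
    if (anyNA(idx)) {
      stop("sample sheet is missing entries for: ",
           paste(headers[is.na(idx)], collapse = ", "))
    }
    rec <- data.frame(sample_id = headers,
                      species = sheet$species[idx],
                      genome_code = sheet$genome_code[idx],
                      residues = residues, stringsAsFactors = FALSE)
  } else if (label_scheme == "pipe") {
    parts <- strsplit(headers, "|", fixed = TRUE)
    nf <- lengths(parts)
    bad <- which(nf < 2L | nf > 3L)
    if (length(bad)) {
      stop("malformed header for record ", bad[1L], " ('", headers[bad[1L]],
           "'): expected 'species|sample_id' or 'species|sample_id|genome_code'")
    }
    rec <- data.frame(
      sample_id = vapply(parts, `[`, "", 2L),
      species = vapply(parts, `[`, "", 1L),
      genome_code = vapply(parts, function(p)
        if (length(p) >= 3L) p[3L] else NA_character_, ""),
      residues = residues, stringsAsFactors = FALSE)
  } else {
    if (is.null(regex)) stop("label_scheme = 'regex' requires a 'regex'")
    m <- regmatches(headers, regexec(regex, headers))
    ng <- lengths(m)
    bad <- which(ng < 3L)
    if (length(bad)) {
      stop("header for record ", bad[1L], " ('", headers[bad[1L]],
           "') does not match the label regex")
    }
    rec <- data.frame(
      sample_id = vapply(m, `[`, "", 3L),
      species = vapply(m, `[`, "", 2L),
      genome_code = vapply(m, function(p)
        if (length(p) >= 4L && nzchar(p[4L])) p[4L] else NA_character_, ""),
      residues = residues, stringsAsFactors = FALSE)
  }
  .validate_residues(rec)
  rec
}

.validate_residues <- function(rec) {
  for (i in seq_len(nrow(rec))) {
    ch <- strsplit(rec$residues[i], "")[[1L]]
    if (length(ch) == 0L) {
      stop("record '", rec$sample_id[i], "' has an empty sequence")
    }
    bad <- which(!(ch %in% IUPAC_NT))
    if (length(bad)) {
      stop("illegal character '", ch[bad[1L]], "' at position ", bad[1L],
           " in record '", rec$sample_id[i], "'")
    }
  }
  invisible(rec)
}

#' Read a tab-separated sample sheet
#'
#' @param path TSV with a header row and columns `sample_id`, `species`,
#'   optionally `genome_code`.
#' @return Data frame with the three columns (`genome_code` filled with
#'   `NA` when absent).
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "species")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns 'sample_id' and 'species'")
  }
  if (!"genome_code" %in% names(sheet)) sheet$genome_code <- NA_character_
  sheet[, c("sample_id", "species", "genome_code")]
}

#' Write labelled records to FASTA
#'
#' Headers use the pipe scheme `species|sample_id|genome_code` (the genome
#' code is omitted when `NA`), so that [read_fasta()] round-trips exactly.
#'
#' @param records Data frame as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- paste0(">", records$species[i], "|", records$sample_id[i])
    if (!is.na(records$genome_code[i])) {
      hdr <- paste0(hdr, "|", records$genome_code[i])
    }
    writeLines(hdr, con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Validate an alignment and build an aligned set
#'
#' Checks that all records have equal length and at least two sequences,
#' then packs them into an `aligned_set`: a character site matrix plus the
#' label metadata.  Idempotent on an existing `aligned_set`.
#'
#' @param records Data frame from [read_fasta()] (columns `sample_id`,
#'   `species`, `genome_code`, `residues`), or an `aligned_set`.
#' @return An object of class `aligned_set` with elements `mat` (samples x
#'   sites character matrix, rownames = sample ids), `meta` (label data
#'   frame) and `length` (number of columns).  Per-species sample counts
#'   are available via `species_counts()`.
#' @export
validate_alignment <- function(records) {
  if (inherits(records, "aligned_set")) return(records)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("'records' must be a non-empty data frame of labelled sequences")
  }
  len <- nchar(records$residues)
  if (length(unique(len)) > 1L) {
    mode_len <- as.integer(names(sort(table(len), decreasing = TRUE))[1L])
    off <- records$sample_id[len != mode_len]
    stop("alignment is ragged; records with deviating length: ",
         paste(off, collapse = ", "))
  }
  if (nrow(records) < 2L) stop("an alignment needs at least 2 records")
  if (anyDuplicated(records$sample_id)) {
    stop("duplicated sample ids: ",
         paste(unique(records$sample_id[duplicated(records$sample_id)]),
               collapse = ", "))
  }
  .validate_residues(records)
  mat <- do.call(rbind, strsplit(records$residues, ""))
  rownames(mat) <- records$sample_id
  structure(list(mat = mat,
                 meta = records[, c("sample_id", "species", "genome_code")],
                 length = ncol(mat)),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat("aligned_set:", nrow(x$mat), "sequences x", x$length, "sites;",
      length(unique(x$meta$species)), "species\n")
  invisible(x)
}

#' Per-species sample counts of an aligned set
#'
#' @param aln An `aligned_set`.
#' @return Named integer vector, species -> number of samples.
#' @export
species_counts <- function(aln) {
  stopifnot(inherits(aln, "aligned_set"))
  tab <- table(aln$meta$species)
  setNames(as.integer(tab), names(tab))
}

#' Subset an aligned set by sample
#'
#' @param aln An `aligned_set`.
#' @param idx Row indices, sample ids, or a logical vector.
#' @return The subset `aligned_set` (may have a single record; functions
#'   requiring >= 2 records check again downstream).
#' @export
subset_aln <- function(aln, idx) {
  stopifnot(inherits(aln, "aligned_set"))
  if (is.character(idx)) idx <- match(idx, aln$meta$sample_id)
  structure(list(mat = aln$mat[idx, , drop = FALSE],
                 meta = aln$meta[idx, , drop = FALSE],
                 length = aln$length),
            class = "aligned_set")
}

#' Convert an aligned set back to a record data frame
#'
#' @param aln An `aligned_set`.
#' @return Data frame with `sample_id`, `species`, `genome_code`, `residues`.
#' @export
aln_records <- function(aln) {
  stopifnot(inherits(aln, "aligned_set"))
  out <- aln$meta
  out$residues <- apply(aln$mat, 1L, paste, collapse = "")
  rownames(out) <- NULL
  out
}
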