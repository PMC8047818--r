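## Alignment containers and upstream utilities: FASTA I/O, column
## filtering, identity-based deduplication, random-sequence baselines.

#' Amino-acid alignment
#'
#' An `aa_alignment` holds equal-length, gapped amino-acid sequences with
#' unique identifiers. It is the shared substrate of the distance, clock and
#' ancestral-reconstruction stages.
#'
#' @param sequences Character vector of aligned sequences (equal length,
#'   residues among the 20 amino-acid one-letter codes plus `-`). Case is
#'   normalised to upper.
#' @param ids Character vector of unique, non-empty identifiers. Defaults to
#'   `names(sequences)`.
#' @return An object of class `aa_alignment` with elements `mat` (character
#'   matrix, one row per sequence) and attributes accessed via [n_sites()]
#'   and [n_seq()].
#' @examples
#' aln <- aa_alignment(c(s1 = "AC-A", s2 = "AGGA"))
#' n_sites(aln)
#' @export
aa_alignment <- function(sequences, ids = names(sequences)) {
  if (length(sequences) < 1L) stop("alignment needs at least one sequence")
  if (is.null(ids)) stop("sequence identifiers are required")
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate identifiers: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids))) stop("empty identifiers are not allowed")
  sequences <- toupper(as.character(sequences))
  lens <- nchar(sequences)
  if (lens[1] < 1L) stop("alignment must have at least one column")
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths (", paste(unique(lens), collapse = ", "),
         "); not a valid alignment")
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  rownames(mat) <- ids
  bad <- !(mat %in% c(AA_CODES, GAP_CHAR))
  if (any(bad)) {
    offending <- unique(mat[bad])
    stop("invalid residue character(s): ", paste(offending, collapse = " "))
  }
  structure(list(mat = mat), class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Amino-acid alignment:", n_seq(x), "sequences x", n_sites(x), "columns\n")
  ids <- alignment_ids(x)
  show <- head(ids, 5)
  cat("  ", paste(show, collapse = ", "),
      if (length(ids) > 5) sprintf(", ... (%d more)", length(ids) - 5) else "", "\n")
  invisible(x)
}

#' @rdname aa_alignment
#' @param x An `aa_alignment`.
#' @export
n_sites <- function(x) ncol(x$mat)

#' @rdname aa_alignment
#' @export
n_seq <- function(x) nrow(x$mat)

#' @rdname aa_alignment
#' @export
alignment_ids <- function(x) rownames(x$mat)

#' @export
#' @method as.matrix aa_alignment
as.matrix.aa_alignment <- function(x, ...) x$mat

#' Extract sequences as strings
#' @param x An `aa_alignment` or `sequence_set`.
#' @return Named character vector of sequences.
#' @export
alignment_strings <- function(x) {
  if (inherits(x, "sequence_set")) return(setNames(x$seqs, x$ids))
  setNames(apply(x$mat, 1, paste, collapse = ""), rownames(x$mat))
}

#' Unaligned sequence set
#'
#' Ordered collection of (identifier, ungapped sequence) records.
#'
#' @param sequences Character vector of ungapped sequences.
#' @param ids Unique identifiers; defaults to `names(sequences)`.
#' @return An object of class `sequence_set` with elements `ids` and `seqs`.
#' @export
sequence_set <- function(sequences, ids = names(sequences)) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) > 0) {
    if (is.null(ids)) stop("sequence identifiers are required")
    ids <- as.character(ids)
    if (anyDuplicated(ids))
      stop("duplicate identifiers: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (any(!nzchar(ids))) stop("empty identifiers are not allowed")
    if (any(!nzchar(sequences))) stop("empty sequences are not allowed")
  } else ids <- character(0)
  structure(list(ids = ids, seqs = unname(sequences)), class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("Sequence set:", length(x$ids), "records\n")
  invisible(x)
}

#' Read amino-acid FASTA
#'
#' @param path Path to a FASTA file.
#' @param aligned If `TRUE` (default) the records must be equal length and an
#'   [aa_alignment] is returned; otherwise gaps are stripped and a
#'   [sequence_set] is returned.
#' @return An [aa_alignment] or [sequence_set]; record order preserved, case
#'   normalised to upper.
#' @export
read_fasta <- function(path, aligned = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))  # first token of the header
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids))) stop("FASTA record with empty header")
  if (aligned) {
    if (length(unique(nchar(seqs))) > 1L)
      stop("records have unequal lengths; re-read with aligned = FALSE ",
           "or align the sequences first")
    aa_alignment(seqs, ids)
  } else {
    sequence_set(gsub(GAP_CHAR, "", seqs, fixed = TRUE), ids)
  }
}

#' Write amino-acid FASTA
#'
#' @param x An [aa_alignment], [sequence_set], or named character vector.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, wrap = 60) {
  seqs <- if (is.character(x)) setNames(toupper(x), names(x)) else alignment_strings(x)
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(wrap))
  invisible(path)
}

#' Filter alignment columns by gap occupancy
#'
#' Keeps a column iff its gap fraction is `<= max_gap_fraction`. This is a
#' deliberately simple occupancy filter used to strip sparsely occupied,
#' indel-dominated columns ahead of distance and clock analyses.
#'
#' @param alignment An [aa_alignment].
#' @param max_gap_fraction Maximum tolerated fraction of gaps per column, in
#'   \[0, 1\]. Default 0.5.
#' @return List with `alignment` (filtered [aa_alignment]) and `kept_columns`
#'   (1-based column indices in the input coordinate system).
#' @export
filter_columns <- function(alignment, max_gap_fraction = 0.5) {
  stopifnot(inherits(alignment, "aa_alignment"))
  if (!is.numeric(max_gap_fraction) || max_gap_fraction < 0 || max_gap_fraction > 1)
    stop("max_gap_fraction must be in [0, 1]")
  gap_frac <- colMeans(alignment$mat == GAP_CHAR)
  keep <- which(gap_frac <= max_gap_fraction)
  if (length(keep) == 0L)
    stop("no columns pass the gap filter (max_gap_fraction = ",
         max_gap_fraction, "); empty alignment")
  out <- alignment
  out$mat <- alignment$mat[, keep, drop = FALSE]
  list(alignment = out, kept_columns = keep)
}

#' Write a kept-columns report
#'
#' One 1-based column index per line, matching the coordinate convention of
#' all user-facing reports.
#' @param kept_columns Integer vector as returned by [filter_columns()].
#' @param path Output path.
#' @export
write_kept_columns <- function(kept_columns, path) {
  writeLines(as.character(as.integer(kept_columns)), path)
  invisible(path)
}

## Identity used for dedup: matches / columns, excluding only gap-gap
## columns (a column gapped in exactly one sequence counts as a mismatch).
dedup_identity <- function(a, b) {
  both_gap <- a == GAP_CHAR & b == GAP_CHAR
  denom <- sum(!both_gap)
  if (denom == 0L) return(NA_real_)
  sum(a == b & !both_gap) / denom
}

#' Remove near-identical sequences
#'
#' Greedy longest-first clustering: sequences are visited in decreasing order
#' of ungapped length and a sequence is dropped iff its identity to an
#' already-kept representative exceeds `threshold`. Identity is computed over
#' equal-length records excluding gap-gap columns, so inputs must be
#' pre-aligned (or ungapped and of identical length).
#'
#' @param x An [aa_alignment] or [sequence_set] with equal-length records.
#' @param threshold Identity above which a sequence is considered redundant;
#'   default 0.92.
#' @return A [sequence_set] of representatives in input order.
#' @export
dedup_by_identity <- function(x, threshold = 0.92) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  strs <- alignment_strings(x)
  if (length(strs) == 0L) return(sequence_set(character(0)))
  if (length(unique(nchar(strs))) > 1L)
    stop("dedup_by_identity requires equal-length (pre-aligned) records")
  rows <- strsplit(strs, "", fixed = TRUE)
  ungapped_len <- vapply(rows, function(r) sum(r != GAP_CHAR), integer(1))
  order_idx <- order(-ungapped_len, seq_along(rows))  # longest first, stable
  kept <- integer(0)
  for (i in order_idx) {
    redundant <- FALSE
    for (j in kept) {
      idt <- dedup_identity(rows[[i]], rows[[j]])
      if (!is.na(idt) && idt > threshold) { redundant <- TRUE; break }
    }
    if (!redundant) kept <- c(kept, i)
  }
  kept <- sort(kept)  # restore input order
  sequence_set(gsub(GAP_CHAR, "", strs[kept], fixed = TRUE), names(strs)[kept])
}

#' Random amino-acid sequences
#'
#' I.i.d. residues from a fixed frequency vector; used as a null baseline for
#' distance saturation (expected pairwise identity is `sum(frequencies^2)`).
#'
#' @param n Number of sequences (>= 1).
#' @param length Sequence length.
#' @param frequencies Numeric vector of 20 residue frequencies in the order
#'   of `AA_CODES`; must be non-negative and sum to 1 (default uniform).
#' @param seed Integer seed for reproducibility.
#' @return A [sequence_set] with identifiers `rand_1 ... rand_n`.
#' @export
random_sequences <- function(n, length, frequencies = rep(1 / 20, 20), seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (length < 1) stop("length must be >= 1")
  if (length(frequencies) != 20L) stop("frequencies must have length 20")
  if (any(frequencies < 0)) stop("frequencies must be non-negative")
  if (abs(sum(frequencies) - 1) > 1e-9) stop("frequencies must sum to 1")
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(AA_CODES, length, replace = TRUE, prob = frequencies),
            collapse = ""),
      character(1))
    sequence_set(seqs, paste0("rand_", seq_len(n)))
  })
}
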