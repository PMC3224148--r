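#' Drop hypervariable (masked-out) alignment columns
#'
#' Keeps only the columns marked `keep` in the alignment's column mask.
#' Probes designed in hypervariable regions would hybridize to only a few
#' taxonomic groups, so the preparation pipeline removes those columns before
#' probe enumeration.  The returned mask is all-`TRUE` at the new width.
#'
#' @param aln An `AlignmentSet` with a mask.
#' @return An `AlignmentSet` restricted to the kept columns.
#' @export
remove_hypervariable <- function(aln) {
  if (is.null(aln$mask))
    stop("alignment has no column mask; cannot remove hypervariable regions",
         call. = FALSE)
  out <- subset_columns(aln, which(aln$mask))
  out$mask <- rep(TRUE, n_columns(out))
  out
}

#' Locate a conserved primer region in an alignment
#'
#' Scans the degapped majority consensus for windows matching the primer
#' under IUPAC degeneracy, then requires that at least half of the sequences
#' match the window exactly (IUPAC-degenerate, no gaps inside the window).
#' For the reverse orientation the search pattern is the primer's reverse
#' complement (the primer's binding site on the forward strand).  Among
#' qualifying windows the one with the highest per-sequence match fraction
#' wins; ties go to the leftmost window for forward primers and the
#' rightmost for reverse primers.
#'
#' @param aln An `AlignmentSet`.
#' @param primer IUPAC primer string (e.g. `"AGAGTTTGATCMTGGCTCAG"`).
#' @param orientation `"forward"` or `"reverse"`.
#' @param min_fraction Minimum fraction of sequences that must match.
#' @return 0-based half-open alignment column interval `c(start, end)`
#'   covering the primer site.
#' @export
find_primer_region <- function(aln, primer,
                               orientation = c("forward", "reverse"),
                               min_fraction = 0.5) {
  orientation <- match.arg(orientation)
  pat <- if (orientation == "reverse") reverse_complement(primer) else primer
  pc <- iupac_chars(pat)
  k <- length(pc)
  cons <- consensus_sequence(aln, collapse = FALSE)
  colmap <- which(cons != "-")
  if (length(colmap) < k)
    stop("primer not found: consensus shorter than primer", call. = FALSE)
  m <- alignment_matrix(aln)
  nseq <- nrow(m)

  best_frac <- -1; best_start <- NULL
  starts <- seq_len(length(colmap) - k + 1L)
  for (s in starts) {
    cols <- colmap[s + seq_len(k) - 1L]
    if (!all(iupac_match(pc, cons[cols]))) next
    sub <- m[, cols, drop = FALSE]
    ok_rows <- rowSums(matrix(iupac_match(rep(pc, each = nseq),
                                          as.vector(sub)),
                              nrow = nseq)) == k
    frac <- mean(ok_rows)
    if (frac < min_fraction) next
    better <- if (orientation == "reverse") frac >= best_frac else frac > best_frac
    if (better) { best_frac <- frac; best_start <- s }
  }
  if (is.null(best_start))
    stop("primer not found: no window matches '", primer, "' (",
         orientation, ") in at least ", round(100 * min_fraction),
         "% of sequences", call. = FALSE)
  cols <- colmap[best_start + seq_len(k) - 1L]
  c(start = cols[1L] - 1L, end = cols[k])
}

# kept-column interval between the primers, after moving `inset` ungapped
# consensus positions inward from each primer; 1-based inclusive c(a, b)
inner_interval <- function(aln, fwd, rev, inset) {
  if (fwd[2] > rev[1])
    stop("forward primer region must end before the reverse region starts",
         call. = FALSE)
  cons <- consensus_sequence(aln, collapse = FALSE)
  ungapped <- which(cons != "-")
  after <- ungapped[ungapped > fwd[2]]       # 0-based end == 1-based first col after
  before <- ungapped[ungapped <= rev[1]]     # columns strictly before the reverse site
  if (length(after) < inset + 1L || length(before) < inset + 1L)
    stop("empty target: primer regions overlap after applying the inset",
         call. = FALSE)
  a <- after[inset + 1L]
  b <- before[length(before) - inset]
  if (a > b)
    stop("empty target: primer regions overlap after applying the inset",
         call. = FALSE)
  c(a, b)
}

#' Truncate an alignment to the region between two primer sites
#'
#' Removes the primer columns and everything outside them, then moves a
#' further `inset` *ungapped consensus positions* inward from each side
#' ("ten nucleotide positions inward" is counted on the degapped consensus
#' and mapped back to alignment columns).  Truncation makes training data
#' consistent when partial gene sequences are present.
#'
#' @param aln An `AlignmentSet`.
#' @param fwd,rev 0-based half-open column intervals from
#'   [find_primer_region()].
#' @param inset Ungapped positions to move inward from each primer
#'   (default 10).
#' @return The truncated `AlignmentSet`.
#' @export
truncate_to_primers <- function(aln, fwd, rev, inset = 10L) {
  ab <- inner_interval(aln, fwd, rev, inset)
  subset_columns(aln, seq.int(ab[1], ab[2]))
}

#' Quality-filter sequences against the primer-truncated region
#'
#' Applies, in order, the three sequence rejection rules of the training
#' pipeline, judged on the region that survives [truncate_to_primers()]:
#' \enumerate{
#'   \item *Too short*: the sequence has an end gap in the alignment after
#'     truncation and the truncated-away section on that same end contains
#'     only gaps (i.e. the read never reached the primer).
#'   \item *Ambiguous*: the kept region contains any character outside
#'     `A/C/G/T/-`.
#'   \item *Duplicate*: the degapped kept-region string equals that of an
#'     earlier sequence (first occurrence wins).
#' }
#' Sequences are removed but columns are untouched, so the result composes
#' with [truncate_to_primers()] in either order.  Removal counts per rule are
#' attached as attribute `"qc_counts"`; an empty result only warns.
#'
#' @inheritParams truncate_to_primers
#' @return The filtered `AlignmentSet` (all columns retained).
#' @export
qc_filter <- function(aln, fwd, rev, inset = 10L) {
  ab <- inner_interval(aln, fwd, rev, inset)
  m <- alignment_matrix(aln)
  lead <- seq_len(ab[1] - 1L)
  trail <- if (ab[2] < ncol(m)) seq.int(ab[2] + 1L, ncol(m)) else integer(0)
  kept_cols <- seq.int(ab[1], ab[2])

  all_gaps <- function(rows, cols) {
    if (length(cols) == 0L) rep(FALSE, length(rows))
    else rowSums(m[rows, cols, drop = FALSE] != "-") == 0L
  }
  n <- nrow(m)
  short <- (all_gaps(seq_len(n), lead) & m[, ab[1]] == "-") |
           (all_gaps(seq_len(n), trail) & m[, ab[2]] == "-")
  keep <- !short

  region <- m[, kept_cols, drop = FALSE]
  ambiguous <- keep &
    apply(region, 1L, function(ch) any(!ch %in% c("A", "C", "G", "T", "-")))
  keep <- keep & !ambiguous

  plain <- apply(region, 1L, function(ch) paste(ch[ch != "-"], collapse = ""))
  dup <- rep(FALSE, n)
  dup[keep] <- duplicated(plain[keep])
  keep <- keep & !dup

  counts <- c(too_short = sum(short), ambiguous = sum(ambiguous),
              duplicate = sum(dup), retained = sum(keep))
  if (!any(keep)) {
    warning("qc_filter removed every sequence", call. = FALSE)
    out <- aln
    out$seqs <- aln$seqs[0]
    out$taxonomy <- NULL
    attr(out, "qc_counts") <- counts
    return(out)
  }
  out <- subset_sequences(aln, names(aln$seqs)[keep])
  attr(out, "plant_region") <- attr(aln, "plant_region")
  attr(out, "qc_counts") <- counts
  out
}

#' Run the training-data preparation pipeline on an alignment
#'
#' Chains the sequence-level stages: optional hypervariable-region removal
#' via the column mask, primer localisation, quality filtering and
#' primer-anchored truncation.  With `original = TRUE` the mask step is
#' skipped, reproducing the legacy pipeline in which hypervariable regions
#' stay in the training data (used for pipeline comparisons).
#'
#' @param aln An `AlignmentSet` (mask required unless `original = TRUE`).
#' @param fwd_primer,rev_primer IUPAC primer strings; defaults are the
#'   universal bacterial primers 27F and 1392R.
#' @param inset Ungapped positions trimmed inward of each primer.
#' @param original Skip hypervariable-region removal (legacy pipeline mode).
#' @param verbose Print per-rule removal counts.
#' @return The processed `AlignmentSet` (QC'd, truncated, mask applied
#'   unless `original`).
#' @export
prep_pipeline <- function(aln,
                          fwd_primer = "AGAGTTTGATCMTGGCTCAG",
                          rev_primer = "ACGGGCGGTGTGTRC",
                          inset = 10L, original = FALSE, verbose = FALSE) {
  if (!original) aln <- remove_hypervariable(aln)
  fwd <- find_primer_region(aln, fwd_primer, "forward")
  rev <- find_primer_region(aln, rev_primer, "reverse")
  ab <- inner_interval(aln, fwd, rev, inset)
  filtered <- qc_filter(aln, fwd, rev, inset)
  if (verbose) {
    qc <- attr(filtered, "qc_counts")
    message("qc_filter: ", paste(names(qc), qc, sep = "=", collapse = ", "))
  }
  out <- subset_columns(filtered, seq.int(ab[1], ab[2]))
  attr(out, "qc_counts") <- attr(filtered, "qc_counts")
  out
}
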