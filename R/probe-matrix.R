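#' Enumerate candidate probes
#'
#' All distinct ungapped `probe_length`-mers occurring at least once in the
#' training sequences, in sorted order.  Sequences shorter than the probe
#' length after degapping are skipped with a warning.
#'
#' @param aln An `AlignmentSet` (post-QC: no ambiguity codes).
#' @param probe_length Probe length in bases (default 10).
#' @return Sorted character vector of candidate probe strings.
#' @export
enumerate_candidates <- function(aln, probe_length = 10L) {
  plain <- degap(aln$seqs)
  short <- nchar(plain) < probe_length
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than the probe length skipped",
            call. = FALSE)
    plain <- plain[!short]
  }
  if (length(plain) == 0L) return(character(0))
  kmers <- unlist(lapply(plain, seq_kmers, k = probe_length),
                  use.names = FALSE)
  sort(unique(kmers))
}

# distinct k-mers of one degapped sequence
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), seq.int(k, n)))
}

# incidence of probes (rows) across sequences (columns), integer 0/1
probe_incidence <- function(probes, aln, probe_length = NULL) {
  plain <- degap(aln$seqs)
  k <- probe_length %||% nchar(probes[1L])
  inc <- vapply(plain, function(s) as.integer(probes %in% seq_kmers(s, k)),
                integer(length(probes)))
  inc <- matrix(inc, nrow = length(probes),
                dimnames = list(probes, names(aln$seqs)))
  inc
}

#' Rank candidate probes by OTU-level conservation
#'
#' For each candidate, the number of distinct OTUs containing at least one
#' sequence in which the probe occurs.  Highly conserved probes (present in
#' many OTUs) are the informative ones for fingerprinting, because their
#' *absence* patterns discriminate groups.
#'
#' @param candidates Character vector of probe strings.
#' @param aln An `AlignmentSet` with full taxonomy (including `otu`).
#' @return Named integer vector: probe -> OTU count.
#' @export
conservation_rank <- function(candidates, aln) {
  tax <- aln$taxonomy
  if (is.null(tax) || is.null(tax$otu))
    stop("taxonomy with OTU labels required", call. = FALSE)
  inc <- probe_incidence(candidates, aln)
  otu <- factor(paste(tax$genus, tax$otu))
  membership <- stats::model.matrix(~ otu - 1)
  hits <- (inc %*% membership) > 0
  counts <- as.integer(rowSums(hits))
  names(counts) <- candidates
  counts
}

#' Keep the most conserved probes
#'
#' The `n` probes with the highest OTU counts; ties at the boundary are
#' broken lexicographically by probe string.  If fewer than `n` candidates
#' exist, all are kept.
#'
#' @param ranked Named integer vector from [conservation_rank()].
#' @param n Number of probes to keep (default 1000).
#' @return Character vector of probe strings, sorted by decreasing
#'   conservation then probe string.
#' @export
filter_top <- function(ranked, n = 1000L) {
  stopifnot(n >= 1L)
  ord <- order(-ranked, names(ranked))
  names(ranked)[ord][seq_len(min(n, length(ranked)))]
}

#' Build the binary probe-by-sequence incidence matrix
#'
#' Entry `[p, s]` is 1 iff probe `p` is an exact forward-strand substring of
#' the degapped processed sequence `s` (the hybridization model: an exact
#' substring is assumed to hybridize).  Taxonomy is encoded to dense integer
#' codes per sequence at the three levels OTU (scoped by genus), genus and
#' phylum.
#'
#' @param probes Character vector of probe strings.
#' @param aln An `AlignmentSet` with full taxonomy.
#' @param revcomp Also count a match when the probe's reverse complement
#'   occurs (off by default: the hybridization model is forward-strand
#'   substring matching).
#' @return An object of class `ProbeMatrix`: list with `probes`, integer
#'   `incidence` (probes x sequences), `seq_ids`, taxonomy table `tax` with
#'   code columns, and `level_sizes`.
#' @export
build_matrix <- function(probes, aln, revcomp = FALSE) {
  if (length(probes) == 0L) stop("no probes supplied", call. = FALSE)
  tax <- aln$taxonomy
  if (is.null(tax) || is.null(tax$otu))
    stop("taxonomy with OTU labels required", call. = FALSE)
  inc <- probe_incidence(probes, aln)
  if (revcomp) {
    rc <- vapply(probes, reverse_complement, character(1))
    inc_rc <- probe_incidence(rc, aln)
    inc <- pmax(inc, matrix(inc_rc, nrow = length(probes),
                            dimnames = dimnames(inc)))
  }
  probe_matrix_from_incidence(inc, tax)
}

# assemble a ProbeMatrix from an incidence matrix and a taxonomy table
probe_matrix_from_incidence <- function(inc, tax) {
  tax <- tax[match(colnames(inc), tax$id), , drop = FALSE]
  rownames(tax) <- NULL
  tax$otu_code <- as.integer(factor(paste(tax$genus, tax$otu)))
  tax$genus_code <- as.integer(factor(tax$genus))
  tax$phylum_code <- as.integer(factor(tax$phylum))
  structure(list(probes = rownames(inc),
                 incidence = inc,
                 seq_ids = colnames(inc),
                 tax = tax,
                 level_sizes = c(otu = max(tax$otu_code),
                                 genus = max(tax$genus_code),
                                 phylum = max(tax$phylum_code))),
            class = "ProbeMatrix")
}

#' @export
print.ProbeMatrix <- function(x, ...) {
  cat("ProbeMatrix:", length(x$probes), "probes x", length(x$seq_ids),
      "sequences\n")
  cat("  groups:", x$level_sizes["otu"], "OTUs,", x$level_sizes["genus"],
      "genera,", x$level_sizes["phylum"], "phyla\n")
  invisible(x)
}

#' Full probe-matrix construction from a processed alignment
#'
#' Enumerate candidates, rank by OTU conservation, keep the top `top_n` and
#' build the incidence matrix.  `top_n = Inf` keeps every candidate.
#'
#' @inheritParams build_matrix
#' @param probe_length Probe length (default 10).
#' @param top_n Number of most-conserved probes to keep (default 1000).
#' @return A `ProbeMatrix`.
#' @export
probe_matrix <- function(aln, probe_length = 10L, top_n = 1000L,
                         revcomp = FALSE) {
  candidates <- enumerate_candidates(aln, probe_length)
  ranked <- conservation_rank(candidates, aln)
  kept <- if (is.finite(top_n)) filter_top(ranked, top_n) else sort(candidates)
  build_matrix(kept, aln, revcomp = revcomp)
}

# restrict a ProbeMatrix to a subset of sequences (training subsets);
# group codes are preserved so evaluations stay comparable
subset_matrix <- function(pm, seq_idx) {
  structure(list(probes = pm$probes,
                 incidence = pm$incidence[, seq_idx, drop = FALSE],
                 seq_ids = pm$seq_ids[seq_idx],
                 tax = pm$tax[seq_idx, , drop = FALSE],
                 level_sizes = pm$level_sizes),
            class = "ProbeMatrix")
}

#' Write / read a `ProbeMatrix` as plain text
#'
#' Serialized as a tab-separated file: a `#level_sizes` header line, the
#' taxonomy code table, a blank line, then the incidence matrix with probe
#' rownames and sequence-id header.  Round-trips bit-exactly.
#'
#' @param pm A `ProbeMatrix`.
#' @param path File path.
#' @export
write_probe_matrix <- function(pm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("#level_sizes\t", paste(names(pm$level_sizes), pm$level_sizes,
                              sep = "=", collapse = "\t"),
      "\n", file = con, sep = "")
  utils::write.table(pm$tax, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat("\n", file = con)
  utils::write.table(cbind(probe = pm$probes,
                           as.data.frame(pm$incidence, check.names = FALSE)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_matrix
#' @export
read_probe_matrix <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#level_sizes"))
    stop("not a probe matrix file: ", path, call. = FALSE)
  blank <- which(lines == "")[1L]
  tax <- utils::read.delim(text = lines[2:(blank - 1L)],
                           stringsAsFactors = FALSE,
                           colClasses = c(id = "character",
                                          phylum = "character",
                                          genus = "character",
                                          otu = "character"))
  incdf <- utils::read.delim(text = lines[(blank + 1L):length(lines)],
                             check.names = FALSE,
                             stringsAsFactors = FALSE)
  probes <- incdf$probe
  inc <- as.matrix(incdf[, -1L, drop = FALSE])
  mode(inc) <- "integer"
  rownames(inc) <- probes
  probe_matrix_from_incidence(inc, tax)
}
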