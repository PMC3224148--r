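#' Aligned sequence sets
#'
#' An `AlignmentSet` holds a gapped multiple sequence alignment as a named
#' character vector of equal-length strings over `A/C/G/T/-` (ambiguity codes
#' may be present before quality filtering), an optional per-column keep/drop
#' mask marking conserved versus hypervariable columns, and an optional
#' taxonomy table with one row per sequence (`id`, `phylum`, `genus`, `otu`).
#'
#' @param seqs Named character vector of gapped, equal-length sequences.
#' @param mask Optional logical vector, one element per alignment column;
#'   `TRUE` marks a column to keep (conserved), `FALSE` a hypervariable
#'   column to drop.
#' @param taxonomy Optional `data.frame` with columns `id`, `phylum`,
#'   `genus` and optionally `otu`.
#' @return An object of class `AlignmentSet`.
#' @export
alignment_set <- function(seqs, mask = NULL, taxonomy = NULL) {
  if (length(seqs) == 0L) stop("alignment contains no sequences", call. = FALSE)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("ragged alignment: sequence lengths differ", call. = FALSE)
  seqs <- toupper(seqs)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != w)
      stop("mask length (", length(mask), ") != alignment width (", w, ")",
           call. = FALSE)
  }
  if (!is.null(taxonomy)) taxonomy <- validate_taxonomy(taxonomy, names(seqs))
  structure(list(seqs = seqs, mask = mask, taxonomy = taxonomy),
            class = "AlignmentSet")
}

validate_taxonomy <- function(tax, ids) {
  need <- c("id", "phylum", "genus")
  if (!all(need %in% names(tax)))
    stop("taxonomy needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  missing_ids <- setdiff(ids, tax$id)
  if (length(missing_ids))
    stop("sequences missing from taxonomy: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "),
         if (length(missing_ids) > 5L) ", ...", call. = FALSE)
  tax <- tax[match(ids, tax$id), , drop = FALSE]
  rownames(tax) <- NULL
  tax
}

#' @export
print.AlignmentSet <- function(x, ...) {
  cat("AlignmentSet:", length(x$seqs), "sequences x", n_columns(x), "columns\n")
  cat("  mask:", if (is.null(x$mask)) "absent"
      else paste0(sum(x$mask), "/", length(x$mask), " columns kept"), "\n")
  cat("  taxonomy:", if (is.null(x$taxonomy)) "absent" else
    paste0(length(unique(x$taxonomy$phylum)), " phyla, ",
           length(unique(x$taxonomy$genus)), " genera",
           if (!is.null(x$taxonomy$otu))
             paste0(", ", nrow(unique(x$taxonomy[c("genus", "otu")])), " OTUs")),
    "\n")
  invisible(x)
}

#' @rdname alignment_set
#' @param x An `AlignmentSet`.
#' @export
n_columns <- function(x) nchar(x$seqs[[1L]])

#' @rdname alignment_set
#' @export
seq_ids <- function(x) names(x$seqs)

# character matrix view (sequences x columns)
alignment_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(aln$seqs), byrow = TRUE)
  rownames(m) <- names(aln$seqs)
  m
}

# keep a subset of alignment columns (1-based index vector), mask follows
subset_columns <- function(aln, cols) {
  m <- alignment_matrix(aln)[, cols, drop = FALSE]
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- names(aln$seqs)
  alignment_set(seqs,
                mask = if (is.null(aln$mask)) NULL else aln$mask[cols],
                taxonomy = aln$taxonomy)
}

# keep a subset of sequences by id
subset_sequences <- function(aln, ids) {
  stopifnot(all(ids %in% names(aln$seqs)))
  alignment_set(aln$seqs[ids], mask = aln$mask,
                taxonomy = if (is.null(aln$taxonomy)) NULL
                           else aln$taxonomy[aln$taxonomy$id %in% ids, , drop = FALSE])
}

#' Majority-rule consensus of an alignment
#'
#' Per column, the most frequent character (bases preferred over the gap on
#' ties, then alphabetical order).  Used to anchor primer search, truncation
#' insets and probe position reporting on one coordinate system.
#'
#' @param aln An `AlignmentSet`.
#' @param collapse Return a single string (`TRUE`) or a character vector per
#'   column (`FALSE`).
#' @return Consensus as string or character vector, gaps included.
#' @export
consensus_sequence <- function(aln, collapse = TRUE) {
  m <- alignment_matrix(aln)
  pref <- c("A", "C", "G", "T", "-")
  cons <- apply(m, 2L, function(col) {
    tab <- table(factor(col, levels = unique(c(pref, col))))
    names(tab)[which.max(tab)]  # which.max keeps the first (preferred) level
  })
  if (collapse) paste(cons, collapse = "") else cons
}

#' Read an aligned FASTA file, optionally extracting a column mask
#'
#' Reads a gapped FASTA alignment.  If `mask_id` is given, any record whose id
#' starts with that prefix is interpreted as the column mask and removed from
#' the sequence set: mask characters in `0`, `-` or `.` mean *drop the column*
#' (hypervariable); any other character means *keep*.
#'
#' @param path FASTA file path.
#' @param mask_id Optional id prefix identifying the mask record
#'   (e.g. `"mask"` or `"#=GC"`).
#' @return An `AlignmentSet`.
#' @export
read_aligned_fasta <- function(path, mask_id = NULL) {
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("empty or invalid FASTA file: ", path,
                                         " (", conditionMessage(e), ")",
                                         call. = FALSE))
  if (length(x) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  mask <- NULL
  if (!is.null(mask_id)) {
    is_mask <- startsWith(names(seqs), mask_id)
    if (any(is_mask)) {
      if (sum(is_mask) > 1L) stop("multiple mask records match '", mask_id, "'",
                                  call. = FALSE)
      mask <- parse_mask(seqs[[which(is_mask)]])
      seqs <- seqs[!is_mask]
      if (length(seqs) == 0L) stop("FASTA contains only the mask record",
                                   call. = FALSE)
    }
  }
  alignment_set(seqs, mask = mask)
}

parse_mask <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  !(ch %in% c("0", "-", "."))
}

#' Write an `AlignmentSet` as aligned FASTA
#'
#' The mask, when present, is written as a first record (`1` = keep,
#' `-` = drop) under `mask_id`.
#'
#' @inheritParams consensus_sequence
#' @param path Output file path.
#' @param mask_id Id used for the mask record.
#' @export
write_aligned_fasta <- function(aln, path, mask_id = "mask") {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(aln$mask)) {
    cat(">", mask_id, "\n", paste(ifelse(aln$mask, "1", "-"), collapse = ""),
        "\n", file = con, sep = "")
  }
  for (i in seq_along(aln$seqs))
    cat(">", names(aln$seqs)[i], "\n", aln$seqs[[i]], "\n", file = con, sep = "")
  invisible(path)
}

#' Read / write a taxonomy table
#'
#' Tab-separated with header columns `id`, `phylum`, `genus` and optionally
#' `otu` (OTU identifiers are scoped within their genus).
#'
#' @param path TSV file path.
#' @return A `data.frame`.
#' @export
read_taxonomy_tsv <- function(path) {
  tax <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "phylum", "genus")
  if (!all(need %in% names(tax)))
    stop("taxonomy TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tax
}

#' @rdname read_taxonomy_tsv
#' @param tax Taxonomy `data.frame`.
#' @export
write_taxonomy_tsv <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
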