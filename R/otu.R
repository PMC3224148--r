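#' Pairwise distances between aligned sequences
#'
#' Fraction of mismatched columns among comparable columns for every pair.
#' Gap policy: columns where *both* sequences are gapped are ignored; a gap
#' aligned against a base counts as one mismatch, and runs of adjacent gaps
#' count per column.  A pair with zero comparable columns is an error.
#'
#' @param aln An `AlignmentSet`.
#' @return An object of class `DistanceMatrix`: list with `ids` and the
#'   symmetric matrix `d` of distances in `[0, 1]`.
#' @export
pairwise_distances <- function(aln) {
  m <- alignment_matrix(aln)
  n <- nrow(m)
  gap <- m == "-"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        comp <- !(gap[i, ] & gap[j, ])
        nc <- sum(comp)
        if (nc == 0L)
          stop("no comparable columns between ", rownames(m)[i], " and ",
               rownames(m)[j], call. = FALSE)
        d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / nc
      }
    }
  }
  structure(list(ids = rownames(m), d = d), class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat("DistanceMatrix:", length(x$ids), "sequences, max distance",
      format(max(x$d), digits = 3), "\n")
  invisible(x)
}

#' Write a distance matrix as square phylip-style TSV
#'
#' @param dm A `DistanceMatrix`.
#' @param path Output path.
#' @export
write_distance_matrix <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(length(dm$ids), "\n", file = con, sep = "")
  for (i in seq_along(dm$ids))
    cat(dm$ids[i], "\t", paste(format(dm$d[i, ], trim = TRUE), collapse = "\t"),
        "\n", file = con, sep = "")
  invisible(path)
}

#' Cluster sequences into OTUs by complete-linkage agglomeration
#'
#' Agglomerative clustering with furthest-neighbour (complete) linkage, cut
#' at `threshold`: merging stops when no pair of clusters has *maximum*
#' cross-pair distance at or below the threshold.  Complete linkage is what
#' makes a "minimum similarity of 99%" OTU definition literal -- every
#' within-OTU pairwise distance is guaranteed `<= threshold`.  Ties during
#' agglomeration are broken toward the pair of clusters whose smallest
#' member indices are lexicographically least, and OTU numbers are assigned
#' by the input order of each cluster's first member, so results are
#' deterministic.
#'
#' @param dm A `DistanceMatrix` (typically per genus).
#' @param threshold Distance cut-off (default 0.01, i.e. 99% similarity).
#' @return Named character vector mapping sequence id to OTU id
#'   (`"otu01"`, `"otu02"`, ...).
#' @export
cluster_otus <- function(dm, threshold = 0.01) {
  stopifnot(inherits(dm, "DistanceMatrix"))
  d <- dm$d
  clusters <- as.list(seq_along(dm$ids))
  repeat {
    if (length(clusters) == 1L) break
    best <- NULL; best_d <- Inf
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in seq.int(a + 1L, length(clusters))) {
        link <- max(d[clusters[[a]], clusters[[b]]])
        if (link < best_d - 1e-15) { best_d <- link; best <- c(a, b) }
        # ties resolve to the earliest (a, b), i.e. smallest member indices
      }
    }
    if (best_d > threshold) break
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  first <- vapply(clusters, min, integer(1))
  clusters <- clusters[order(first)]
  otu <- character(length(dm$ids))
  for (i in seq_along(clusters))
    otu[clusters[[i]]] <- sprintf("otu%02d", i)
  names(otu) <- dm$ids
  otu
}

#' Per-genus OTU assignment
#'
#' Builds one distance matrix per genus from the processed alignment and
#' clusters each genus independently with [cluster_otus()]; OTUs are never
#' formed across genera.
#'
#' @param aln An `AlignmentSet`.
#' @param taxonomy `data.frame` with `id`, `phylum`, `genus` covering every
#'   sequence.
#' @param threshold Distance cut-off passed to [cluster_otus()].
#' @return Named character vector id -> OTU id (scoped within genus).
#' @export
assign_otus <- function(aln, taxonomy = aln$taxonomy, threshold = 0.01) {
  if (is.null(taxonomy)) stop("taxonomy required", call. = FALSE)
  taxonomy <- validate_taxonomy(taxonomy, names(aln$seqs))
  out <- character(0)
  for (g in unique(taxonomy$genus)) {
    ids <- taxonomy$id[taxonomy$genus == g]
    sub <- subset_sequences(aln, ids)
    out <- c(out, cluster_otus(pairwise_distances(sub), threshold))
  }
  out[names(aln$seqs)]
}

#' Attach full three-level taxonomy labels to an alignment
#'
#' Combines the externally supplied phylum/genus lineage with the pipeline's
#' per-genus OTU assignment into the alignment's taxonomy table.  OTU ids
#' stay scoped within their genus; the (genus, otu) pair identifies a group.
#'
#' @param aln An `AlignmentSet`.
#' @param taxonomy `data.frame` with `id`, `phylum`, `genus`.
#' @param otus Named character vector id -> OTU id, e.g. from
#'   [assign_otus()].
#' @return `aln` with `taxonomy` fully populated (columns `id`, `phylum`,
#'   `genus`, `otu`).
#' @export
label_set <- function(aln, taxonomy, otus) {
  taxonomy <- validate_taxonomy(taxonomy, names(aln$seqs))
  missing_otu <- setdiff(names(aln$seqs), names(otus))
  if (length(missing_otu))
    stop("sequences without an OTU assignment: ",
         paste(utils::head(missing_otu, 5L), collapse = ", "),
         if (length(missing_otu) > 5L) ", ...", call. = FALSE)
  taxonomy$otu <- unname(otus[taxonomy$id])
  aln$taxonomy <- taxonomy
  aln
}
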