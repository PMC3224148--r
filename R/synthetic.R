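#' Specification for a synthetic 16S-like training alignment
#'
#' Describes a taxonomically structured world from which gapped, aligned
#' sequence sets are simulated: a star phylogeny per level (root -> phylum ->
#' genus -> OTU -> sequence) with independent per-column substitutions on the
#' conserved columns, plus fast-evolving hypervariable blocks that also carry
#' all the gaps.  Two concrete primer sites (forward primer near the 5' end,
#' reverse-complemented reverse primer near the 3' end) are embedded verbatim
#' in every sequence and never mutated, so primer-anchored truncation can be
#' exercised on the output.
#'
#' Divergence parameters are per-branch substitution probabilities; the
#' expected pairwise divergence between two groups at a level is roughly
#' twice the branch rate of that level.  `within_otu_divergence` is a hard
#' per-pair bound: each sequence differs from its OTU ancestor in at most
#' `floor(within_otu_divergence * n_free / 2)` conserved columns, so any two
#' OTU members differ in at most `within_otu_divergence` of the compared
#' columns outside the hypervariable blocks -- generated OTUs always respect
#' a 99% similarity threshold when `within_otu_divergence <= 0.01`.
#'
#' @param n_phyla,genera_per_phylum,otus_per_genus,seqs_per_otu Counts
#'   (all >= 1) defining the nested taxonomy.
#' @param alignment_length Number of alignment columns.
#' @param hypervariable_blocks List of 0-based half-open column ranges
#'   `c(start, end)` treated as hypervariable (fast-evolving, gapped,
#'   masked out).
#' @param within_otu_divergence Maximum pairwise divergence within an OTU
#'   outside hypervariable blocks; must lie in `[0, 0.01]`.
#' @param between_group_divergence Named numeric vector with per-branch
#'   substitution rates `c(phylum=, genus=, otu=)`; must be ordered
#'   `otu <= genus <= phylum` and exceed `within_otu_divergence`.
#' @param hypervariable_divergence Per-column substitution probability inside
#'   hypervariable blocks (applied independently per sequence).
#' @param gap_rate Per-column gap probability inside hypervariable blocks.
#' @param fwd_primer,rev_primer Concrete (A/C/G/T) primer instances planted
#'   in all sequences; the reverse primer is planted as its reverse
#'   complement on the forward strand.
#' @param seed Integer seed; fully determines the generated set.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_phyla = 3, genera_per_phylum = 3,
                           otus_per_genus = 4, seqs_per_otu = 5,
                           alignment_length = 600,
                           hypervariable_blocks = list(c(260, 320)),
                           within_otu_divergence = 0.008,
                           between_group_divergence =
                             c(phylum = 0.06, genus = 0.03, otu = 0.015),
                           hypervariable_divergence = 0.25,
                           gap_rate = 0.10,
                           fwd_primer = "AGAGTTTGATCATGGCTCAG",
                           rev_primer = "ACGGGCGGTGTGTAC",
                           seed = 1L) {
  counts <- c(n_phyla = n_phyla, genera_per_phylum = genera_per_phylum,
              otus_per_genus = otus_per_genus, seqs_per_otu = seqs_per_otu)
  if (any(counts < 1) || any(counts != floor(counts)))
    stop("invalid spec: all counts must be integers >= 1", call. = FALSE)
  if (within_otu_divergence < 0 || within_otu_divergence > 0.01)
    stop("invalid spec: within_otu_divergence must lie in [0, 0.01]",
         call. = FALSE)
  bg <- between_group_divergence
  if (!all(c("phylum", "genus", "otu") %in% names(bg)))
    stop("between_group_divergence needs names phylum, genus, otu",
         call. = FALSE)
  if (!(bg["otu"] <= bg["genus"] && bg["genus"] <= bg["phylum"]))
    stop("invalid spec: divergences must be ordered otu <= genus <= phylum",
         call. = FALSE)
  if (within_otu_divergence > bg["genus"])
    stop("invalid spec: within-OTU divergence exceeds between-genus divergence",
         call. = FALSE)
  L <- alignment_length
  for (b in hypervariable_blocks)
    if (length(b) != 2L || b[1] < 0 || b[2] > L || b[1] >= b[2])
      stop("invalid spec: hypervariable block out of [0, alignment_length)",
           call. = FALSE)
  for (p in c(fwd_primer, rev_primer))
    if (!grepl("^[ACGT]+$", p))
      stop("planted primers must be concrete A/C/G/T strings", call. = FALSE)
  spec <- list(n_phyla = as.integer(n_phyla),
               genera_per_phylum = as.integer(genera_per_phylum),
               otus_per_genus = as.integer(otus_per_genus),
               seqs_per_otu = as.integer(seqs_per_otu),
               alignment_length = as.integer(L),
               hypervariable_blocks = hypervariable_blocks,
               within_otu_divergence = within_otu_divergence,
               between_group_divergence = bg,
               hypervariable_divergence = hypervariable_divergence,
               gap_rate = gap_rate,
               fwd_primer = fwd_primer, rev_primer = rev_primer,
               seed = as.integer(seed))
  spec <- structure(spec, class = "SyntheticSpec")
  # primer sites: forward at columns 11..(10+|fwd|), reverse-complement site
  # ending 10 columns before the 3' end (1-based, both inclusive)
  fw <- 10L + seq_len(nchar(fwd_primer))
  rvs <- reverse_complement(rev_primer)
  rv <- (L - 10L - nchar(rvs)) + seq_len(nchar(rvs))
  if (max(fw) >= min(rv))
    stop("alignment_length too short for the primer sites", call. = FALSE)
  hv <- hv_columns(spec)
  if (any(c(fw, rv) %in% hv))
    stop("invalid spec: hypervariable block overlaps a primer site",
         call. = FALSE)
  spec$fwd_cols <- fw
  spec$rev_cols <- rv
  spec$rev_site <- rvs
  spec
}

# 1-based column indices covered by the hypervariable blocks
hv_columns <- function(spec) {
  unique(unlist(lapply(spec$hypervariable_blocks,
                       function(b) seq.int(b[1] + 1L, b[2]))))
}

#' Enumerate the planted taxonomy of a synthetic spec
#'
#' @param spec A [synthetic_spec()].
#' @return A `data.frame` with one row per sequence: `id`, `phylum`, `genus`,
#'   `otu` (OTU ids are scoped within their genus).
#' @export
generate_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  g <- expand.grid(s = seq_len(spec$seqs_per_otu),
                   o = seq_len(spec$otus_per_genus),
                   ge = seq_len(spec$genera_per_phylum),
                   p = seq_len(spec$n_phyla))
  phylum <- sprintf("p%02d", g$p)
  genus <- sprintf("p%02dg%02d", g$p, g$ge)
  otu <- sprintf("otu%02d", g$o)
  data.frame(id = sprintf("%s_%s_s%02d", genus, otu, g$s),
             phylum = phylum, genus = genus, otu = otu,
             stringsAsFactors = FALSE)
}

# substitute each of `cols` with probability `rate` to a different base
mutate_cols <- function(chars, cols, rate) {
  if (length(cols) == 0L || rate <= 0) return(chars)
  hit <- cols[stats::runif(length(cols)) < rate]
  if (length(hit)) chars[hit] <- substitute_bases(chars[hit])
  chars
}

# draw a uniformly random *different* base for each input base
substitute_bases <- function(b) {
  bases <- c("A", "C", "G", "T")
  shift <- sample.int(3L, length(b), replace = TRUE)
  bases[(match(b, bases) - 1L + shift) %% 4L + 1L]
}

#' Simulate a taxonomically structured gapped alignment
#'
#' Runs the star-phylogeny substitution model of a [synthetic_spec()] and
#' returns an [alignment_set()] with the hypervariable column mask and the
#' planted taxonomy attached.  Identical spec and seed give byte-identical
#' output.
#'
#' @param spec A [synthetic_spec()].
#' @param labels Taxonomy as produced by [generate_taxonomy()] (regenerated
#'   when omitted).
#' @return An `AlignmentSet` with `mask` and `taxonomy` populated.  The
#'   attribute `"plant_region"` records the 1-based conserved columns safe
#'   for probe planting (inside the primer-truncated region, outside
#'   hypervariable blocks).
#' @export
generate_alignment <- function(spec, labels = generate_taxonomy(spec)) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  L <- spec$alignment_length
  hv <- hv_columns(spec)
  frozen <- c(spec$fwd_cols, spec$rev_cols)
  free <- setdiff(seq_len(L), c(hv, frozen))
  m_within <- floor(spec$within_otu_divergence * length(free) / 2)
  bg <- spec$between_group_divergence

  with_seed(spec$seed, {
    root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    root[spec$fwd_cols] <- strsplit(spec$fwd_primer, "")[[1]]
    root[spec$rev_cols] <- strsplit(spec$rev_site, "")[[1]]

    seqs <- character(nrow(labels))
    anc_ph <- list(); anc_ge <- list(); anc_otu <- list()
    for (i in seq_len(nrow(labels))) {
      ph <- labels$phylum[i]; ge <- labels$genus[i]
      ot <- paste(ge, labels$otu[i])
      if (is.null(anc_ph[[ph]]))
        anc_ph[[ph]] <- mutate_cols(root, free, bg["phylum"])
      if (is.null(anc_ge[[ge]]))
        anc_ge[[ge]] <- mutate_cols(anc_ph[[ph]], free, bg["genus"])
      if (is.null(anc_otu[[ot]]))
        anc_otu[[ot]] <- mutate_cols(anc_ge[[ge]], free, bg["otu"])
      s <- anc_otu[[ot]]
      if (m_within > 0) {
        cols <- sample(free, m_within)
        s[cols] <- substitute_bases(s[cols])
      }
      if (length(hv)) {
        s <- mutate_cols(s, hv, spec$hypervariable_divergence)
        gap <- hv[stats::runif(length(hv)) < spec$gap_rate]
        s[gap] <- "-"
      }
      seqs[i] <- paste(s, collapse = "")
    }
    names(seqs) <- labels$id
    mask <- rep(TRUE, L)
    mask[hv] <- FALSE
    aln <- alignment_set(seqs, mask = mask, taxonomy = labels)
    # columns that survive primer truncation with the default inset of 10
    lo <- max(spec$fwd_cols) + 10L + 1L
    hi <- min(spec$rev_cols) - 10L - 1L
    attr(aln, "plant_region") <- setdiff(seq.int(lo, hi), c(hv, frozen))
    aln
  })
}

#' Embed group-discriminative probes into a synthetic alignment
#'
#' Writes each probe verbatim into a dedicated, disjoint window of conserved
#' columns in *all* sequences of exactly one taxonomic group (probe `i` goes
#' to group `i` in label order) and verifies that no probe occurs in any
#' sequence outside its group.  Used to construct alignments where the ideal
#' probe set is known by design.
#'
#' @param aln An `AlignmentSet` with taxonomy (typically from
#'   [generate_alignment()]).
#' @param probes Character vector of equal-length A/C/G/T probe strings, at
#'   most one per group at `level`.
#' @param level Taxonomic level whose groups receive the probes.
#' @return A modified copy of `aln`.
#' @export
plant_discriminative_probes <- function(aln, probes,
                                        level = c("otu", "genus", "phylum")) {
  level <- match.arg(level)
  if (length(probes) == 0L) return(aln)
  if (!all(grepl("^[ACGT]+$", probes)))
    stop("probes must contain only A/C/G/T", call. = FALSE)
  k <- unique(nchar(probes))
  if (length(k) != 1L) stop("probes must have equal length", call. = FALSE)
  if (anyDuplicated(probes)) stop("probes must be distinct", call. = FALSE)
  tax <- aln$taxonomy
  if (is.null(tax)) stop("alignment has no taxonomy", call. = FALSE)
  key <- switch(level, otu = paste(tax$genus, tax$otu),
                genus = tax$genus, phylum = tax$phylum)
  groups <- unique(key)
  if (length(probes) > length(groups))
    stop("more probes (", length(probes), ") than groups at level ", level,
         " (", length(groups), ")", call. = FALSE)

  region <- attr(aln, "plant_region")
  if (is.null(region)) {
    keep <- if (is.null(aln$mask)) rep(TRUE, n_columns(aln)) else aln$mask
    region <- setdiff(which(keep), c(seq_len(40L),
                                     n_columns(aln) - seq_len(40L) + 1L))
  }
  # disjoint runs of k consecutive usable columns
  runs <- split(region, cumsum(c(1L, diff(region) != 1L)))
  windows <- list()
  for (r in runs) {
    n_win <- length(r) %/% k
    for (w in seq_len(n_win))
      windows[[length(windows) + 1L]] <- r[(w - 1L) * k + seq_len(k)]
  }
  if (length(windows) < length(probes))
    stop("not enough conserved columns to plant ", length(probes), " probes",
         call. = FALSE)

  m <- alignment_matrix(aln)
  for (i in seq_along(probes)) {
    members <- key == groups[i]
    m[members, windows[[i]]] <- matrix(strsplit(probes[i], "")[[1]],
                                       nrow = sum(members), ncol = k,
                                       byrow = TRUE)
  }
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- names(aln$seqs)
  out <- alignment_set(seqs, mask = aln$mask, taxonomy = tax)
  attr(out, "plant_region") <- attr(aln, "plant_region")

  plain <- degap(out$seqs)
  for (i in seq_along(probes)) {
    hit <- grepl(probes[i], plain, fixed = TRUE)
    members <- key == groups[i]
    if (any(hit & !members))
      stop("probe collision: ", probes[i], " occurs outside its ", level,
           " group in ", paste(utils::head(names(out$seqs)[hit & !members], 3L),
                               collapse = ", "), call. = FALSE)
    if (!all(hit[members]))
      stop("internal planting failure for probe ", probes[i], call. = FALSE)
  }
  out
}

#' Deterministic distinct probe strings for planting
#'
#' Generates `n` distinct random A/C/G/T k-mers under a fixed seed,
#' convenient as input to [plant_discriminative_probes()].
#'
#' @param n Number of probes.
#' @param k Probe length.
#' @param seed Integer seed.
#' @param avoid Character vector of k-mers the probes must not equal
#'   (e.g. [enumerate_candidates()] of the target alignment, to rule out
#'   planting collisions with background sequence).
#' @return Character vector of `n` distinct probes.
#' @export
random_probes <- function(n, k = 10L, seed = 1L, avoid = character(0)) {
  with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      p <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                 collapse = "")
      if (!p %in% out && !p %in% avoid) out <- c(out, p)
    }
    out
  })
}
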