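# Independent, deliberately naive reference implementations used as oracles.
# They share no code with the package internals: everything is recomputed
# with explicit loops over sequences, groups and pairs.

# fingerprint of each sequence as a plain string key
naive_fingerprint_keys <- function(ps, pm) {
  apply(pm$incidence[ps, , drop = FALSE], 2L, paste, collapse = "")
}

# gamma recount: distinct groups per distinct fingerprint and level
naive_gamma <- function(ps, pm) {
  keys <- naive_fingerprint_keys(ps, pm)
  distinct <- unique(keys)
  out <- matrix(0L, nrow = length(distinct), ncol = 3,
                dimnames = list(NULL, c("otu", "genus", "phylum")))
  for (i in seq_along(distinct)) {
    sel <- keys == distinct[i]
    out[i, "otu"] <- length(unique(pm$tax$otu_code[sel]))
    out[i, "genus"] <- length(unique(pm$tax$genus_code[sel]))
    out[i, "phylum"] <- length(unique(pm$tax$phylum_code[sel]))
  }
  out
}

naive_mfps_cost <- function(ps, pm, pen) {
  g <- naive_gamma(ps, pm)
  p <- c(pen$otu, pen$genus, pen$phylum)
  total <- 0
  for (f in seq_len(nrow(g)))
    for (i in 1:3)
      total <- total + p[i] * g[f, i] * (g[f, i] - 1)
  unname(total / 2)
}

naive_mdps_cost <- function(ps, pm) {
  keys <- naive_fingerprint_keys(ps, pm)
  total <- 0
  for (f in unique(keys)) {
    nf <- sum(keys == f)
    total <- total + nf * (nf - 1)
  }
  total / 2
}

# exhaustive minimum cost over all k-subsets of probes
exhaustive_min_cost <- function(pm, k, cost = c("mfps", "mdps"),
                                pen = penalty_config()) {
  cost <- match.arg(cost)
  subsets <- utils::combn(length(pm$probes), k)
  best <- Inf
  for (j in seq_len(ncol(subsets))) {
    ps <- subsets[, j]
    val <- if (cost == "mfps") naive_mfps_cost(ps, pm, pen)
           else naive_mdps_cost(ps, pm)
    if (val < best) best <- val
  }
  best
}

# naive per-pair distance recount under the package's stated gap policy
naive_distance <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  mism <- 0L; comp <- 0L
  for (i in seq_along(a)) {
    if (a[i] == "-" && b[i] == "-") next
    comp <- comp + 1L
    if (a[i] != b[i]) mism <- mism + 1L
  }
  if (comp == 0L) stop("no comparable columns")
  mism / comp
}

# random ProbeMatrix instance with nested random taxonomy
random_instance <- function(seed, n_probes = 10L, n_seqs = 12L,
                            n_phyla = 2L, genera_per_phylum = 2L,
                            otus_per_genus = 2L) {
  set.seed(seed)
  inc <- matrix(rbinom(n_probes * n_seqs, 1L, 0.5), nrow = n_probes,
                dimnames = list(sprintf("probe%02d", seq_len(n_probes)),
                                sprintf("s%02d", seq_len(n_seqs))))
  phyla <- sprintf("P%d", sample.int(n_phyla, n_seqs, replace = TRUE))
  genera <- paste0(phyla, "G", sample.int(genera_per_phylum, n_seqs,
                                          replace = TRUE))
  otus <- paste0("otu", sample.int(otus_per_genus, n_seqs, replace = TRUE))
  tax <- data.frame(id = colnames(inc), phylum = phyla, genus = genera,
                    otu = otus, stringsAsFactors = FALSE)
  mfps:::probe_matrix_from_incidence(inc, tax)
}

# relabel a ProbeMatrix so every sequence is its own singleton OTU
singleton_otu_matrix <- function(pm) {
  tax <- pm$tax[c("id", "phylum", "genus")]
  tax$otu <- paste0("solo_", seq_len(nrow(tax)))
  tax$genus <- "g1"; tax$phylum <- "p1"
  mfps:::probe_matrix_from_incidence(pm$incidence, tax)
}

# canonical form of a partition for comparisons up to relabeling
partition_canonical <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

# small processed + labeled synthetic world shared across tests
small_world <- function(seed = 11L, ...) {
  spec <- synthetic_spec(n_phyla = 2, genera_per_phylum = 2,
                         otus_per_genus = 2, seqs_per_otu = 3,
                         alignment_length = 400,
                         hypervariable_blocks = list(c(180, 220)),
                         seed = seed, ...)
  aln <- generate_alignment(spec)
  proc <- prep_pipeline(aln)
  tax <- aln$taxonomy[aln$taxonomy$id %in% names(proc$seqs),
                      c("id", "phylum", "genus")]
  label_set(proc, tax, assign_otus(proc, tax))
}
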