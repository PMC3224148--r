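#' High Fidelity Ratio of a probe set
#'
#' A distinct fingerprint is *high-fidelity* at a taxonomic level iff it
#' occurs in exactly one group at that level (\eqn{\gamma_{i,f} = 1}).  The
#' HFR is the number of distinct high-fidelity fingerprints divided by the
#' total number of distinct fingerprints, at the given level -- a measure of
#' how closely the fingerprints of a probe set represent real OTUs, genera
#' or phyla.  Because groups nest, `HFR_otu <= HFR_genus <= HFR_phylum`.
#'
#' @param ps Integer vector of probe indices into `pm$probes`.
#' @param pm A `ProbeMatrix` (the validation data).
#' @param level `"otu"`, `"genus"` or `"phylum"`.
#' @return An object of class `HFRResult`: list with `level`, `n_distinct`,
#'   `n_high_fidelity` and `ratio`.
#' @export
hfr <- function(ps, pm, level = c("otu", "genus", "phylum")) {
  level <- match.arg(level)
  if (length(pm$seq_ids) == 0L)
    stop("undefined metric: no sequences", call. = FALSE)
  acct <- gamma_counts(ps, pm)
  g <- acct$gamma[, level]
  structure(list(level = level, n_distinct = acct$n_distinct,
                 n_high_fidelity = sum(g == 1L),
                 ratio = sum(g == 1L) / acct$n_distinct),
            class = "HFRResult")
}

#' @export
print.HFRResult <- function(x, ...) {
  cat(sprintf("HFR (%s): %d / %d distinct fingerprints high-fidelity = %.3f\n",
              x$level, x$n_high_fidelity, x$n_distinct, x$ratio))
  invisible(x)
}

# convenience: HFR ratios at all three levels as a named numeric vector
hfr_all_levels <- function(ps, pm) {
  acct <- gamma_counts(ps, pm)
  apply(acct$gamma, 2L, function(g) sum(g == 1L) / acct$n_distinct)
}

#' Low-fidelity average-pairwise-distance histogram
#'
#' For each *low-fidelity* distinct fingerprint of each probe set (judged at
#' `level`, OTU by default), takes all sequences bearing it, computes their
#' average pairwise sequence distance, and bins the averages at 1% width.
#' The histogram reports the per-bin mean and standard deviation of counts
#' across the supplied probe sets.  High-fidelity fingerprints are excluded:
#' at the OTU level their sequences all sit in one OTU and so can never
#' exceed the 1% OTU cut-off distance.
#'
#' @param probe_sets List of integer probe-index vectors.
#' @param pm A `ProbeMatrix`.
#' @param aln The processed `AlignmentSet` the matrix was built from
#'   (distance source); sequence ids must match `pm$seq_ids`.
#' @param level Level at which low fidelity is judged.
#' @param bin_width Bin width (default 0.01).
#' @param n_bins Number of half-open bins `[j*w, (j+1)*w)` starting at 0.
#' @return An object of class `DistanceHistogram`: list with `breaks`,
#'   `counts` (per-bin mean), `dispersion` (per-bin SD) and the per-set
#'   count matrix `per_set`.
#' @export
low_fidelity_distance_histogram <- function(probe_sets, pm, aln,
                                            level = c("otu", "genus"),
                                            bin_width = 0.01, n_bins = 100L) {
  level <- match.arg(level)
  stopifnot(length(probe_sets) >= 1L)
  if (!all(pm$seq_ids %in% names(aln$seqs)))
    stop("alignment does not cover the matrix's sequences", call. = FALSE)
  per_set <- matrix(0, nrow = length(probe_sets), ncol = n_bins)
  for (i in seq_along(probe_sets)) {
    avgs <- low_fidelity_avg_distances(probe_sets[[i]], pm, aln, level)
    if (length(avgs)) {
      bins <- pmin(floor(avgs / bin_width) + 1L, n_bins)
      per_set[i, ] <- tabulate(bins, nbins = n_bins)
    }
  }
  structure(list(bin_width = bin_width,
                 breaks = seq(0, by = bin_width, length.out = n_bins + 1L),
                 counts = colMeans(per_set),
                 dispersion = apply(per_set, 2L, stats::sd),
                 per_set = per_set),
            class = "DistanceHistogram")
}

# average pairwise distance of the sequences behind each low-fidelity
# distinct fingerprint of one probe set
low_fidelity_avg_distances <- function(ps, pm, aln, level = "otu") {
  fps <- fingerprint_all(ps, pm)
  f <- fingerprint_codes(fps)
  g <- switch(level, otu = pm$tax$otu_code, genus = pm$tax$genus_code,
              phylum = pm$tax$phylum_code)
  gam <- gamma_one_level(f, g)
  low <- which(gam > 1L)
  vapply(low, function(code) {
    ids <- pm$seq_ids[f == code]
    d <- pairwise_distances(subset_sequences(aln, ids))$d
    mean(d[upper.tri(d)])
  }, numeric(1))
}

#' Cross-validation plan
#'
#' The probe-design variant of 5-fold cross-validation: each fold trains on
#' a *disjoint* `train_fraction` sample of the sequences (20% by default)
#' and validates on `validate_fraction` of them (100% by default), which
#' keeps HFR values comparable with runs trained on the full data.
#'
#' @param folds Number of folds (>= 2).
#' @param train_fraction Fraction of sequences in each training sample.
#' @param validate_fraction Fraction of sequences used for validation.
#' @param seed Integer seed for the fold split.
#' @return An object of class `CrossValPlan`.
#' @export
crossval_plan <- function(folds = 5L, train_fraction = 0.20,
                          validate_fraction = 1.00, seed = 1L) {
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (train_fraction <= 0 || train_fraction > 1 ||
      validate_fraction <= 0 || validate_fraction > 1)
    stop("fractions must lie in (0, 1]", call. = FALSE)
  if (train_fraction < 1 && folds * train_fraction > 1 + 1e-9)
    stop("folds * train_fraction exceeds 1: training samples cannot be disjoint",
         call. = FALSE)
  structure(list(folds = as.integer(folds), train_fraction = train_fraction,
                 validate_fraction = validate_fraction,
                 seed = as.integer(seed)),
            class = "CrossValPlan")
}

#' Cross-validated probe selection and evaluation
#'
#' For each fold, selects a probe set on that fold's disjoint training
#' sample and evaluates HFR on the validation data (all sequences by
#' default).  With `train_fraction = 1` every fold trains on the full set,
#' which reproduces a plain (non-CV) run per fold seed.
#'
#' @param pm A `ProbeMatrix`.
#' @param k Probe set size.
#' @param plan A [crossval_plan()].
#' @param cost,pen,cfg Passed to [anneal()]; the annealing seed is offset
#'   per fold so folds are independent.
#' @return List with `per_fold` (data.frame: fold, level, ratio, n_distinct)
#'   and `mean` (named vector of mean HFR per level).
#' @export
crossval <- function(pm, k, plan = crossval_plan(), cost = "mfps",
                     pen = penalty_config(), cfg = annealing_config()) {
  n <- length(pm$seq_ids)
  m <- if (plan$train_fraction == 1) n else floor(plan$train_fraction * n)
  if (m < 1L) stop("training fraction leaves no sequences", call. = FALSE)
  perm <- with_seed(plan$seed, sample.int(n))
  rows <- list()
  for (f in seq_len(plan$folds)) {
    train_idx <- if (plan$train_fraction == 1) seq_len(n)
                 else perm[(f - 1L) * m + seq_len(m)]
    train_pm <- subset_matrix(pm, sort(train_idx))
    miss <- pm$level_sizes["otu"] - length(unique(train_pm$tax$otu_code))
    if (miss > 0)
      warning("fold ", f, ": ", miss, " OTU(s) absent from the training sample",
              call. = FALSE)
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + 1000L * (f - 1L)
    sel <- anneal(train_pm, k, cost = cost, pen = pen, cfg = fold_cfg)
    val_pm <- if (plan$validate_fraction == 1) pm else
      subset_matrix(pm, sort(with_seed(plan$seed + f,
        sample.int(n, floor(plan$validate_fraction * n)))))
    ratios <- hfr_all_levels(sel$probe_indices, val_pm)
    rows[[f]] <- data.frame(fold = f, level = names(ratios),
                            ratio = unname(ratios),
                            cost = sel$cost, row.names = NULL)
  }
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold,
       mean = tapply(per_fold$ratio, per_fold$level, mean)[
         c("otu", "genus", "phylum")])
}

#' Phylum-holdout robustness experiment
#'
#' Trains probe sets with one phylum's sequences entirely removed from the
#' training data and evaluates HFR on the *full* matrix (all phyla
#' included), next to a baseline trained on everything.  Measures how well
#' probe sets distinguish taxa never seen during training -- the proxy for
#' detecting novel microbes.
#'
#' @param pm A `ProbeMatrix`.
#' @param phylum Phylum name to hold out.
#' @param k Probe set size.
#' @param cost,pen,cfg Passed to [anneal()].
#' @return data.frame with one row per condition (`baseline`, `holdout`)
#'   and level: columns `condition`, `level`, `ratio`, `n_train`.
#' @export
phylum_holdout <- function(pm, phylum, k, cost = "mfps",
                           pen = penalty_config(), cfg = annealing_config()) {
  if (!phylum %in% pm$tax$phylum)
    stop("unknown phylum: ", phylum, call. = FALSE)
  keep <- which(pm$tax$phylum != phylum)
  train_pm <- subset_matrix(pm, keep)
  base_sel <- anneal(pm, k, cost = cost, pen = pen, cfg = cfg)
  hold_sel <- anneal(train_pm, k, cost = cost, pen = pen, cfg = cfg)
  res <- rbind(
    data.frame(condition = "baseline",
               level = c("otu", "genus", "phylum"),
               ratio = unname(hfr_all_levels(base_sel$probe_indices, pm)),
               n_train = length(pm$seq_ids)),
    data.frame(condition = "holdout",
               level = c("otu", "genus", "phylum"),
               ratio = unname(hfr_all_levels(hold_sel$probe_indices, pm)),
               n_train = length(keep)))
  rownames(res) <- NULL
  res
}

#' Random probe sets (control condition)
#'
#' Uniform samples of `k` distinct probe indices, used as the random control
#' against annealed probe sets.
#'
#' @param pm A `ProbeMatrix`.
#' @param k Probe set size.
#' @param n_sets Number of sets.
#' @param seed Integer seed.
#' @return List of `n_sets` integer vectors.
#' @export
random_probe_sets <- function(pm, k, n_sets, seed = 1L) {
  P <- length(pm$probes)
  stopifnot(k <= P)
  if (n_sets == 0L) return(list())
  with_seed(seed, lapply(seq_len(n_sets), function(i) sort(sample.int(P, k))))
}

#' Positional bias of selected probes
#'
#' Maps every probe of every supplied probe set to its first match position
#' on the degapped majority consensus of the processed alignment (0-based)
#' and tallies the frequency per position.  Probes absent from the consensus
#' are skipped with a warning.
#'
#' @param probe_sets List of integer probe-index vectors.
#' @param pm A `ProbeMatrix`.
#' @param aln The processed `AlignmentSet` (consensus source).
#' @return data.frame with columns `position` (0-based) and `count`;
#'   attribute `"n_skipped"` counts unmatched probes.
#' @export
positional_bias <- function(probe_sets, pm, aln) {
  cons <- degap(consensus_sequence(aln))
  probes <- pm$probes[unlist(probe_sets, use.names = FALSE)]
  pos <- vapply(probes, function(p) regexpr(p, cons, fixed = TRUE)[[1]],
                integer(1))
  skipped <- sum(pos < 0L)
  if (skipped > 0L)
    warning(skipped, " probe occurrence(s) not found on the consensus; skipped",
            call. = FALSE)
  tab <- table(pos[pos > 0L] - 1L)
  out <- data.frame(position = as.integer(names(tab)),
                    count = as.integer(tab))
  attr(out, "n_skipped") <- skipped
  out
}

#' Genus-penalty sweep
#'
#' Builds `n_sets` probe sets per genus-penalty value (holding the OTU
#' penalty at `p_otu` and the phylum penalty at 0) and records the mean and
#' standard deviation of OTU and genus HFR, mirroring the penalty
#' optimisation experiment.
#'
#' @param pm A `ProbeMatrix`.
#' @param genus_penalties Numeric vector of genus penalties to test.
#' @param k Probe set size.
#' @param n_sets Probe sets per penalty value.
#' @param p_otu OTU penalty (default 1).
#' @param cfg An [annealing_config()]; each probe set uses a distinct
#'   derived seed.
#' @return data.frame: `genus_penalty`, `level`, `mean`, `sd`, `n`.
#' @export
penalty_sweep <- function(pm, genus_penalties, k, n_sets = 20L, p_otu = 1,
                          cfg = annealing_config(restarts = 1L)) {
  stopifnot(all(genus_penalties >= 0))
  rows <- list()
  for (gp in genus_penalties) {
    pen <- penalty_config(p_otu = p_otu, p_genus = gp, p_phylum = 0)
    ratios <- vapply(seq_len(n_sets), function(i) {
      cfg_i <- cfg
      cfg_i$seed <- cfg$seed + 100L * (i - 1L)
      sel <- anneal(pm, k, cost = "mfps", pen = pen, cfg = cfg_i)
      hfr_all_levels(sel$probe_indices, pm)[c("otu", "genus")]
    }, numeric(2))
    for (lev in c("otu", "genus"))
      rows[[length(rows) + 1L]] <-
        data.frame(genus_penalty = gp, level = lev,
                   mean = mean(ratios[lev, ]), sd = stats::sd(ratios[lev, ]),
                   n = n_sets)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
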