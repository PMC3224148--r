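#' Penalty configuration for the MFPS cost
#'
#' Per-level penalties \eqn{P_i} applied to fingerprints occurring in more
#' than one taxonomic group at level \eqn{i}.  The defaults -- OTU penalty 1,
#' genus penalty 30, phylum penalty 0 -- are the settings found optimal for
#' probe design on large 16S training sets; the phylum penalty can stay at
#' zero because phylum fidelity rises automatically when OTU fidelity is
#' optimized (groups nest).
#'
#' @param p_otu,p_genus,p_phylum Nonnegative penalties.
#' @return An object of class `PenaltyConfig`.
#' @export
penalty_config <- function(p_otu = 1, p_genus = 30, p_phylum = 0) {
  p <- c(otu = p_otu, genus = p_genus, phylum = p_phylum)
  if (any(p < 0) || anyNA(p))
    stop("penalties must be nonnegative numbers", call. = FALSE)
  structure(as.list(p), class = "PenaltyConfig")
}

#' Simulated annealing configuration
#'
#' @param steps Moves per run; default `200 * k`, chosen at run time when
#'   `NULL`.
#' @param t_initial Initial temperature; when `NULL` it is calibrated so
#'   that roughly 80% of uphill moves sampled during a 200-move warm-up
#'   would be accepted.
#' @param cooling Geometric cooling factor per step, in (0, 1).
#' @param restarts Independent runs; the single best probe set of all
#'   restarts is returned (default 10).
#' @param seed Root seed; restart `r` runs under seed `seed + r - 1`.
#' @param retained Probe indices that must appear in every candidate set.
#' @param avoided Probe indices that may never appear.
#' @return An object of class `AnnealingConfig`.
#' @export
annealing_config <- function(steps = NULL, t_initial = NULL, cooling = 0.995,
                             restarts = 10L, seed = 1L,
                             retained = integer(0), avoided = integer(0)) {
  if (length(intersect(retained, avoided)))
    stop("retained and avoided probe sets overlap", call. = FALSE)
  if (cooling <= 0 || cooling >= 1)
    stop("cooling must lie in (0, 1)", call. = FALSE)
  structure(list(steps = steps, t_initial = t_initial, cooling = cooling,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 retained = as.integer(retained),
                 avoided = as.integer(avoided)),
            class = "AnnealingConfig")
}

#' Fingerprint every sequence under a probe set
#'
#' Bit `j` of a sequence's fingerprint is the incidence of probe `j`: 1 if
#' the probe's sequence occurs exactly in the (degapped) gene sequence and
#' would therefore be assumed to hybridize, else 0.
#'
#' @param ps Integer vector of probe indices into `pm$probes` (a probe set
#'   of size `k`; `k = 0` is allowed and yields one empty fingerprint).
#' @param pm A `ProbeMatrix`.
#' @return Integer matrix `k x n_sequences`; column `s` is sequence `s`'s
#'   fingerprint.
#' @export
fingerprint_all <- function(ps, pm) {
  ps <- as.integer(ps)
  if (anyDuplicated(ps) || any(ps < 1L | ps > length(pm$probes)))
    stop("probe indices must be distinct and within range", call. = FALSE)
  pm$incidence[ps, , drop = FALSE]
}

# collapse fingerprints (k x n integer matrix) to distinct-fingerprint codes
# 1..N in order of first appearance
fingerprint_codes <- function(fps) {
  n <- ncol(fps)
  k <- nrow(fps)
  if (k == 0L) return(rep(1L, n))
  chunks <- split(seq_len(k), (seq_len(k) - 1L) %/% 30L)
  keymat <- vapply(chunks, function(rows)
    as.vector(crossprod(fps[rows, , drop = FALSE],
                        2^(seq_along(rows) - 1L))),
    numeric(n))
  keymat <- matrix(keymat, nrow = n)
  key <- if (ncol(keymat) == 1L) keymat[, 1L]
         else do.call(paste, c(as.data.frame(keymat), sep = "_"))
  match(key, unique(key))
}

# distinct-group counts per distinct fingerprint and level
# f: fingerprint codes 1..N; g: group codes per sequence
gamma_one_level <- function(f, g) {
  u <- !duplicated(f * (max(g) + 1) + g)
  tabulate(f[u], nbins = max(f))
}

#' Fidelity accounting of a probe set
#'
#' For each distinct fingerprint `f` and taxonomic level `i` in
#' (OTU, genus, phylum), the number \eqn{\gamma_{i,f}} of groups at level
#' `i` containing at least one sequence bearing `f`.
#'
#' @inheritParams fingerprint_all
#' @param fps Fingerprint matrix from [fingerprint_all()] (computed from
#'   `ps` when omitted).
#' @return An object of class `FidelityAccounting`: list with `n_distinct`
#'   (N) and `gamma`, an `N x 3` matrix with columns `otu`, `genus`,
#'   `phylum`.
#' @export
gamma_counts <- function(ps, pm, fps = fingerprint_all(ps, pm)) {
  f <- fingerprint_codes(fps)
  gamma <- cbind(otu = gamma_one_level(f, pm$tax$otu_code),
                 genus = gamma_one_level(f, pm$tax$genus_code),
                 phylum = gamma_one_level(f, pm$tax$phylum_code))
  structure(list(n_distinct = max(f), gamma = gamma),
            class = "FidelityAccounting")
}

#' The MFPS cost of a fidelity accounting
#'
#' \deqn{C = \tfrac12 \sum_{f=1}^{N} \sum_{i=1}^{3}
#'       P_i\, \gamma_{i,f} (\gamma_{i,f} - 1)}
#' Each distinct fingerprint pays, per taxonomic level, the penalised number
#' of ordered group pairs it fails to separate; a fingerprint confined to a
#' single group at a level (\eqn{\gamma_{i,f} = 1}) accrues no penalty
#' there.
#'
#' @param acct A `FidelityAccounting` from [gamma_counts()].
#' @param pen A [penalty_config()].
#' @return The total cost `C` (nonnegative number).
#' @export
mfps_cost <- function(acct, pen = penalty_config()) {
  stopifnot(inherits(acct, "FidelityAccounting"))
  if (!inherits(pen, "PenaltyConfig")) pen <- do.call(penalty_config, as.list(pen))
  g <- acct$gamma
  0.5 * (pen$otu * sum(g[, "otu"] * (g[, "otu"] - 1)) +
         pen$genus * sum(g[, "genus"] * (g[, "genus"] - 1)) +
         pen$phylum * sum(g[, "phylum"] * (g[, "phylum"] - 1)))
}

#' The MDPS cost of a set of fingerprints
#'
#' The predecessor objective: every pair of sequences sharing a fingerprint
#' is equally undesirable, regardless of similarity or taxonomy, giving
#' \eqn{C = \tfrac12 \sum_f n_f (n_f - 1)} where \eqn{n_f} is the number of
#' sequences bearing distinct fingerprint \eqn{f}.  Equivalent to
#' [mfps_cost()] with every sequence in its own singleton "OTU" and
#' penalties (1, 0, 0).
#'
#' @param fps Fingerprint matrix from [fingerprint_all()].
#' @return The number of undistinguished sequence pairs.
#' @export
mdps_cost <- function(fps) {
  nf <- tabulate(fingerprint_codes(fps))
  0.5 * sum(nf * (nf - 1))
}

# fast path used inside the annealer
set_cost <- function(ps, pm, cost = c("mfps", "mdps"), pen = penalty_config()) {
  cost <- match.arg(cost)
  fps <- pm$incidence[ps, , drop = FALSE]
  if (cost == "mdps") return(mdps_cost(fps))
  mfps_cost(gamma_counts(ps, pm, fps = fps), pen)
}

#' Select a probe set by simulated annealing
#'
#' Minimizes the chosen cost over size-`k` probe subsets.  Each restart
#' draws a random initial set (always containing the `retained` probes and
#' never an `avoided` one), then repeatedly proposes to replace one
#' non-retained member with a uniformly random eligible non-member,
#' accepting by the Metropolis rule at a geometrically cooled temperature.
#' The best set across restarts is returned (ties: lowest restart index); a
#' restart stops early when it reaches cost 0, which is a global optimum.
#'
#' @param pm A `ProbeMatrix`.
#' @param k Probe set size.
#' @param cost `"mfps"` or `"mdps"`.
#' @param pen A [penalty_config()] (ignored for `"mdps"`).
#' @param cfg An [annealing_config()].
#' @return An object of class `ProbeSelection`: list with `probe_indices`,
#'   `probes`, `cost`, the final `accounting`, `restart_costs` and the
#'   per-restart `cost_trace` of best-so-far values.
#' @export
anneal <- function(pm, k, cost = c("mfps", "mdps"), pen = penalty_config(),
                   cfg = annealing_config()) {
  cost <- match.arg(cost)
  k <- as.integer(k)
  P <- length(pm$probes)
  eligible <- setdiff(seq_len(P), cfg$avoided)
  if (length(cfg$retained) > k)
    stop("more retained probes than the probe set size", call. = FALSE)
  if (!all(cfg$retained %in% eligible))
    stop("a retained probe is also avoided or out of range", call. = FALSE)
  if (k > length(eligible))
    stop("infeasible: k exceeds the number of eligible probes", call. = FALSE)
  steps <- cfg$steps %||% (200L * k)
  score <- function(idx) set_cost(idx, pm, cost, pen)

  best <- NULL
  restart_costs <- numeric(cfg$restarts)
  traces <- vector("list", cfg$restarts)
  r_done <- 0L
  for (r in seq_len(cfg$restarts)) {
    run <- with_seed(cfg$seed + r - 1L, {
      anneal_once(pm, k, score, eligible, cfg, steps)
    })
    r_done <- r
    restart_costs[r] <- run$cost
    traces[[r]] <- run$trace
    if (is.null(best) || run$cost < best$cost) { best <- run; best$restart <- r }
    if (best$cost == 0) break
  }
  idx <- sort(best$set)
  structure(list(probe_indices = idx,
                 probes = pm$probes[idx],
                 cost = best$cost,
                 accounting = gamma_counts(idx, pm),
                 cost_fn = cost,
                 penalties = pen,
                 k = k,
                 restart = best$restart,
                 restart_costs = restart_costs[seq_len(r_done)],
                 cost_trace = traces[seq_len(r_done)]),
            class = "ProbeSelection")
}

anneal_once <- function(pm, k, score, eligible, cfg, steps) {
  retained <- cfg$retained
  pool <- setdiff(eligible, retained)
  cur <- c(retained, if (k > length(retained))
    sample(pool, k - length(retained)))
  cur_cost <- score(cur)
  if (length(retained) == k || length(eligible) == k)
    return(list(set = cur, cost = cur_cost, trace = cur_cost))

  in_set <- logical(length(pm$probes))
  in_set[cur] <- TRUE
  swappable <- seq.int(length(retained) + 1L, k)  # positions free to change

  propose <- function() {
    pos <- if (length(swappable) == 1L) swappable
           else swappable[sample.int(length(swappable), 1L)]
    repeat {
      cand <- eligible[sample.int(length(eligible), 1L)]
      if (!in_set[cand]) return(c(pos, cand))
    }
  }

  t0 <- cfg$t_initial
  if (is.null(t0)) {
    # warm-up: typical uphill move size from the initial state
    deltas <- replicate(200L, {
      pr <- propose()
      trial <- cur; trial[pr[1L]] <- pr[2L]
      score(trial) - cur_cost
    })
    up <- deltas[deltas > 0]
    t0 <- if (length(up)) mean(up) / -log(0.8) else 1
  }

  temp <- t0
  best_set <- cur; best_cost <- cur_cost
  trace <- numeric(steps + 1L); trace[1L] <- cur_cost
  for (s in seq_len(steps)) {
    pr <- propose()
    old <- cur[pr[1L]]
    trial <- cur; trial[pr[1L]] <- pr[2L]
    trial_cost <- score(trial)
    delta <- trial_cost - cur_cost
    if (delta <= 0 || stats::runif(1L) < exp(-delta / temp)) {
      cur <- trial; cur_cost <- trial_cost
      in_set[old] <- FALSE; in_set[pr[2L]] <- TRUE
      if (cur_cost < best_cost) { best_cost <- cur_cost; best_set <- cur }
    }
    temp <- temp * cfg$cooling
    trace[s + 1L] <- best_cost
    if (best_cost == 0) { trace <- trace[seq_len(s + 1L)]; break }
  }
  list(set = best_set, cost = best_cost, trace = trace)
}

#' @export
print.ProbeSelection <- function(x, ...) {
  cat("ProbeSelection:", x$k, "probes,", x$cost_fn, "cost",
      format(x$cost, digits = 6), "(best of", length(x$restart_costs),
      "restart(s))\n")
  invisible(x)
}

#' Write a probe set as plain text, one probe per line
#'
#' @param sel A `ProbeSelection` (or character vector of probes).
#' @param path Output path.
#' @export
write_probe_set <- function(sel, path) {
  probes <- if (inherits(sel, "ProbeSelection")) sel$probes else sel
  writeLines(probes, path)
  invisible(path)
}
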