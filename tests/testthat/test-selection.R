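make_accounting <- function(gamma_rows) {
  g <- do.call(rbind, gamma_rows)
  colnames(g) <- c("otu", "genus", "phylum")
  structure(list(n_distinct = nrow(g), gamma = g),
            class = "FidelityAccounting")
}

test_that("mfps_cost evaluates the penalised gamma pairs formula", {
  pen <- penalty_config(1, 30, 0)
  # gamma = 1 everywhere: no penalty accrues
  expect_equal(mfps_cost(make_accounting(list(c(1, 1, 1), c(1, 1, 1))), pen), 0)
  # single fingerprint in 2 OTUs of one genus: C = 1/2 * 1 * 2 * 1 = 1
  expect_equal(mfps_cost(make_accounting(list(c(2, 1, 1))), pen), 1)
  # gamma = (3, 2, 1): C = 1/2 (1*3*2 + 30*2*1) = 33
  expect_equal(mfps_cost(make_accounting(list(c(3, 2, 1))), pen), 33)
  # additive over fingerprints
  expect_equal(mfps_cost(make_accounting(list(c(2, 1, 1), c(3, 2, 1))), pen),
               34)
  expect_error(penalty_config(-1, 0, 0), "nonnegative")
})

test_that("mfps_cost is monotone in each gamma and each penalty", {
  set.seed(53)
  for (i in 1:50) {
    g <- c(otu = sample(1:5, 1), genus = sample(1:4, 1),
           phylum = sample(1:3, 1))
    pen <- penalty_config(runif(1, 0, 5), runif(1, 0, 50), runif(1, 0, 2))
    base <- mfps_cost(make_accounting(list(g)), pen)
    lev <- sample(names(g), 1)
    g2 <- g; g2[lev] <- g2[lev] + 1L
    expect_gte(mfps_cost(make_accounting(list(g2)), pen), base)
    pen2 <- pen; pen2$otu <- pen2$otu + 1
    expect_gte(mfps_cost(make_accounting(list(g)), pen2), base)
  }
})

test_that("fingerprints are the probe-set rows of the incidence matrix", {
  pm <- random_instance(59)
  ps <- c(2L, 5L, 7L)
  fps <- fingerprint_all(ps, pm)
  expect_identical(fps, pm$incidence[ps, , drop = FALSE])

  # k = 0: every sequence shares the single empty fingerprint
  acct0 <- gamma_counts(integer(0), pm)
  expect_equal(acct0$n_distinct, 1L)

  # permuting probe order permutes the bits identically for all sequences
  perm <- c(7L, 2L, 5L)
  expect_identical(fingerprint_all(perm, pm),
                   fps[match(perm, ps), , drop = FALSE])

  expect_error(fingerprint_all(c(1L, 1L), pm), "distinct")
  expect_error(fingerprint_all(c(1L, 999L), pm), "range")
})

test_that("gamma_counts matches a naive group-by recount", {
  for (seed in 1:10) {
    pm <- random_instance(seed)
    ps <- sort(sample(length(pm$probes), 3L))
    acct <- gamma_counts(ps, pm)
    ref <- naive_gamma(ps, pm)
    expect_equal(acct$n_distinct, nrow(ref))
    expect_equal(unname(acct$gamma), unname(ref))
    expect_equal(mfps_cost(acct, penalty_config()),
                 naive_mfps_cost(ps, pm, penalty_config()))
  }
})

test_that("hand-constructed sharing patterns give the expected gammas", {
  # 2 sequences in different OTUs of the same genus share a fingerprint
  inc <- matrix(c(1L, 1L, 0L), nrow = 1,
                dimnames = list("p1", c("s1", "s2", "s3")))
  tax <- data.frame(id = c("s1", "s2", "s3"), phylum = "P",
                    genus = c("G1", "G1", "G2"),
                    otu = c("otu01", "otu02", "otu01"))
  pm <- mfps:::probe_matrix_from_incidence(inc, tax)
  acct <- gamma_counts(1L, pm)
  shared <- which(tabulate(mfps:::fingerprint_codes(
    fingerprint_all(1L, pm))) == 2L)
  expect_equal(unname(acct$gamma[shared, ]), c(2L, 1L, 1L))
})

test_that("mdps_cost counts undistinguished sequence pairs", {
  pm <- random_instance(61, n_probes = 6L, n_seqs = 8L)
  # all-zero probe set of size 0: all sequences share one fingerprint
  expect_equal(mdps_cost(fingerprint_all(integer(0), pm)), 8 * 7 / 2)

  inc <- diag(1L, 4)
  dimnames(inc) <- list(paste0("p", 1:4), paste0("s", 1:4))
  tax <- data.frame(id = paste0("s", 1:4), phylum = "P", genus = "G",
                    otu = paste0("otu", 1:4))
  pmu <- mfps:::probe_matrix_from_incidence(inc, tax)
  expect_equal(mdps_cost(fingerprint_all(1:4, pmu)), 0)  # all unique

  # one fingerprint shared by 3 sequences, others unique -> 3 pairs
  tax2 <- data.frame(id = paste0("s", 1:6), phylum = "P", genus = "G",
                     otu = paste0("otu", 1:6))
  inc3 <- matrix(c(0L, 0L, 0L, 1L, 1L, 0L,
                   0L, 0L, 0L, 0L, 1L, 1L), nrow = 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), paste0("s", 1:6)))
  pm3 <- mfps:::probe_matrix_from_incidence(inc3, tax2)
  # fingerprints: s1=s2=s3=00, s4=10, s5=11, s6=01 -> one triple: 3 pairs
  expect_equal(mdps_cost(fingerprint_all(1:2, pm3)), 3)
})

test_that("MDPS equals MFPS under singleton-OTU relabeling with pen (1,0,0)", {
  for (seed in 1:10) {
    pm <- random_instance(seed + 100)
    ps <- sort(sample(length(pm$probes), 4L))
    solo <- singleton_otu_matrix(pm)
    expect_equal(mdps_cost(fingerprint_all(ps, pm)),
                 mfps_cost(gamma_counts(ps, solo), penalty_config(1, 0, 0)))
  }
})

test_that("a fully retained probe set is returned verbatim without search", {
  pm <- random_instance(67)
  keep <- c(1L, 4L, 9L)
  sel <- anneal(pm, 3L, cost = "mfps",
                cfg = annealing_config(restarts = 2L, seed = 3L,
                                       retained = keep))
  expect_equal(sel$probe_indices, sort(keep))
  expect_equal(sel$cost, mfps_cost(gamma_counts(keep, pm), penalty_config()))
})

test_that("avoided probes never appear and infeasible requests error", {
  pm <- random_instance(71, n_probes = 12L)
  for (seed in 1:20) {
    sel <- anneal(pm, 3L, cost = "mdps",
                  cfg = annealing_config(steps = 100L, restarts = 2L,
                                         seed = seed, avoided = c(2L, 6L)))
    expect_length(intersect(sel$probe_indices, c(2L, 6L)), 0L)
  }
  expect_error(anneal(pm, 12L,
                      cfg = annealing_config(avoided = 1L)), "infeasible")
  expect_error(annealing_config(retained = 1L, avoided = 1L), "overlap")
  expect_error(anneal(pm, 2L,
                      cfg = annealing_config(retained = 1:3)), "retained")
})

test_that("annealing is reproducible and its best-so-far trace nonincreasing", {
  pm <- random_instance(73)
  cfg <- annealing_config(steps = 300L, restarts = 3L, seed = 11L)
  s1 <- anneal(pm, 3L, cost = "mfps", cfg = cfg)
  s2 <- anneal(pm, 3L, cost = "mfps", cfg = cfg)
  expect_identical(s1$probe_indices, s2$probe_indices)
  expect_identical(s1$cost, s2$cost)
  for (tr in s1$cost_trace)
    expect_true(all(diff(tr) <= 0))
  # reported cost equals an independent recomputation on the returned set
  expect_equal(s1$cost, naive_mfps_cost(s1$probe_indices, pm,
                                        penalty_config()))
})

test_that("annealing attains the exhaustive optimum on tiny instances", {
  for (seed in c(3, 14)) {
    pm <- random_instance(seed, n_probes = 9L, n_seqs = 10L)
    for (cost in c("mfps", "mdps")) {
      ref <- exhaustive_min_cost(pm, 3L, cost)
      sel <- anneal(pm, 3L, cost = cost,
                    cfg = annealing_config(steps = 800L, restarts = 4L,
                                           seed = seed))
      expect_equal(sel$cost, ref)
    }
  }
})

test_that("planted OTU probes are an exhaustive MFPS optimum at cost 0", {
  spec <- synthetic_spec(n_phyla = 1, genera_per_phylum = 1,
                         otus_per_genus = 3, seqs_per_otu = 2,
                         alignment_length = 400,
                         hypervariable_blocks = list(c(180, 220)),
                         seed = 83)
  aln <- generate_alignment(spec)
  probes <- random_probes(3, seed = 7)
  planted <- plant_discriminative_probes(aln, probes, level = "otu")
  proc <- prep_pipeline(planted)
  tax <- planted$taxonomy[planted$taxonomy$id %in% names(proc$seqs),
                          c("id", "phylum", "genus")]
  world <- label_set(proc, tax, assign_otus(proc, tax))

  # restrict candidates to the planted probes plus a few decoys
  decoys <- setdiff(enumerate_candidates(world), probes)[1:7]
  pm <- build_matrix(c(probes, decoys), world)
  k <- 3L
  subsets <- utils::combn(length(pm$probes), k)
  zero_sets <- list()
  for (j in seq_len(ncol(subsets))) {
    if (naive_mfps_cost(subsets[, j], pm, penalty_config()) == 0)
      zero_sets[[length(zero_sets) + 1L]] <- pm$probes[subsets[, j]]
  }
  expect_true(any(vapply(zero_sets, function(z) setequal(z, probes),
                         logical(1))))
})
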