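test_that("hfr follows the high-fidelity definition", {
  # every sequence its own fingerprint and OTU -> HFR 1 at all levels
  inc <- diag(1L, 4)
  dimnames(inc) <- list(paste0("p", 1:4), paste0("s", 1:4))
  tax <- data.frame(id = paste0("s", 1:4), phylum = "P", genus = "G",
                    otu = paste0("otu", 1:4))
  pm <- mfps:::probe_matrix_from_incidence(inc, tax)
  for (lev in c("otu", "genus", "phylum"))
    expect_equal(hfr(1:4, pm, lev)$ratio, 1)

  # 10 distinct fingerprints, 8 confined to one OTU -> OTU HFR 0.8
  n <- 12L
  inc2 <- matrix(0L, nrow = 4, ncol = n,
                 dimnames = list(paste0("p", 1:4), paste0("s", seq_len(n))))
  for (s in seq_len(10L)) inc2[, s] <- as.integer(intToBits(s)[1:4])
  inc2[, 11L] <- inc2[, 1L]   # s11 repeats fingerprint 1 from another OTU
  inc2[, 12L] <- inc2[, 2L]   # s12 repeats fingerprint 2 from another OTU
  tax2 <- data.frame(id = paste0("s", seq_len(n)), phylum = "P", genus = "G",
                     otu = c(paste0("otu", 1:10), "otu90", "otu91"))
  pm2 <- mfps:::probe_matrix_from_incidence(inc2, tax2)
  res <- hfr(1:4, pm2, "otu")
  expect_equal(res$n_distinct, 10L)
  expect_equal(res$n_high_fidelity, 8L)
  expect_equal(res$ratio, 0.8)
})

test_that("HFR nesting holds on randomized instances", {
  for (seed in 1:25) {
    pm <- random_instance(seed + 300, n_probes = 8L, n_seqs = 14L,
                          n_phyla = 3L, genera_per_phylum = 2L,
                          otus_per_genus = 3L)
    ps <- sort(sample(8L, 3L))
    r <- vapply(c("otu", "genus", "phylum"),
                function(lev) hfr(ps, pm, lev)$ratio, numeric(1))
    expect_lte(r["otu"], r["genus"] + 1e-12)
    expect_lte(r["genus"], r["phylum"] + 1e-12)
  }
})

test_that("distance histogram bins low-fidelity averages at 1%", {
  world <- small_world(seed = 101)
  pm <- probe_matrix(world, top_n = 200)

  # a probe set with perfect OTU fidelity contributes an all-zero histogram
  sel <- anneal(pm, 12L, cost = "mfps",
                cfg = annealing_config(steps = 3000L, restarts = 3L,
                                       seed = 5L))
  expect_equal(sel$cost, 0)
  h <- low_fidelity_distance_histogram(list(sel$probe_indices), pm, world)
  expect_true(all(h$counts == 0))

  # an empty probe set lumps everything into one low-fidelity fingerprint
  h1 <- low_fidelity_distance_histogram(list(integer(0)), pm, world)
  expect_equal(sum(h1$per_set[1, ]), 1)
  d <- pairwise_distances(world)$d
  avg <- mean(d[upper.tri(d)])
  expect_equal(which(h1$per_set[1, ] == 1), floor(avg / 0.01) + 1L)
})

test_that("a known two-sequence fingerprint lands in the right bin", {
  # construct two sequences at distance 0.034 sharing a fingerprint
  L <- 500L
  base <- strrep("ACGTG", 100L)
  s2 <- strsplit(base, "")[[1]]
  flip <- seq(13L, by = 29L, length.out = 17L)  # 17/500 = 0.034
  s2[flip] <- chartr("ACGT", "CGTA", s2[flip])
  seqs <- c(a = base, b = paste(s2, collapse = ""))
  tax <- data.frame(id = c("a", "b"), phylum = "P", genus = "G",
                    otu = c("otu01", "otu02"))
  aln <- alignment_set(seqs, taxonomy = tax)
  inc <- matrix(1L, nrow = 1, ncol = 2, dimnames = list("p1", c("a", "b")))
  pm <- mfps:::probe_matrix_from_incidence(inc, tax)
  h <- low_fidelity_distance_histogram(list(1L), pm, aln)
  expect_equal(h$per_set[1, 4], 1)       # bin [0.03, 0.04)
  expect_equal(sum(h$per_set), 1)
})

test_that("high-fidelity fingerprints never exceed the OTU cut-off distance", {
  world <- small_world(seed = 103)
  pm <- probe_matrix(world, top_n = 200)
  for (seed in 1:5) {
    ps <- random_probe_sets(pm, 6L, 1L, seed = seed)[[1]]
    fps <- fingerprint_all(ps, pm)
    f <- mfps:::fingerprint_codes(fps)
    gam <- mfps:::gamma_one_level(f, pm$tax$otu_code)
    for (code in which(gam == 1L)) {
      ids <- pm$seq_ids[f == code]
      if (length(ids) < 2L) next
      d <- pairwise_distances(mfps:::subset_sequences(world, ids))$d
      expect_lte(mean(d[upper.tri(d)]), 0.01 + 1e-12)
    }
  }
})

test_that("histogram mass equals the number of low-fidelity fingerprints", {
  world <- small_world(seed = 107)
  pm <- probe_matrix(world, top_n = 200)
  sets <- random_probe_sets(pm, 5L, 4L, seed = 9L)
  h <- low_fidelity_distance_histogram(sets, pm, world)
  for (i in seq_along(sets)) {
    acct <- gamma_counts(sets[[i]], pm)
    expect_equal(sum(h$per_set[i, ]), sum(acct$gamma[, "otu"] > 1L))
  }
})

test_that("cross-validation uses disjoint training folds and full validation", {
  world <- small_world(seed = 109)
  pm <- probe_matrix(world, top_n = 150)
  plan <- crossval_plan(folds = 5L, train_fraction = 0.2, seed = 31L)
  res <- suppressWarnings(  # tiny folds legitimately miss some OTUs
    crossval(pm, k = 8L, plan = plan, cost = "mfps",
             cfg = annealing_config(steps = 600L, restarts = 1L,
                                    seed = 1L)))
  expect_equal(nrow(res$per_fold), 15L)
  expect_true(all(res$per_fold$ratio >= 0 & res$per_fold$ratio <= 1))
  expect_true(all(c("otu", "genus", "phylum") %in% names(res$mean)))

  # training on 100% with the fold seed reproduces a plain run
  plan_full <- crossval_plan(folds = 2L, train_fraction = 1, seed = 31L)
  res_full <- crossval(pm, k = 5L, plan = plan_full,
                       cfg = annealing_config(steps = 300L, restarts = 1L,
                                              seed = 7L))
  direct <- anneal(pm, 5L, cost = "mfps",
                   cfg = annealing_config(steps = 300L, restarts = 1L,
                                          seed = 7L))
  otu_fold1 <- res_full$per_fold$ratio[res_full$per_fold$fold == 1 &
                                         res_full$per_fold$level == "otu"]
  expect_equal(otu_fold1, hfr(direct$probe_indices, pm, "otu")$ratio)
})

test_that("fold fractions that cannot be disjoint are rejected", {
  expect_error(crossval_plan(folds = 5L, train_fraction = 0.5), "disjoint")
  expect_error(crossval_plan(folds = 1L), "folds")
  expect_error(crossval_plan(train_fraction = 0), "fractions")
})

test_that("phylum holdout trains without the phylum, evaluates on all", {
  world <- small_world(seed = 113)
  pm <- probe_matrix(world, top_n = 150)
  ph <- pm$tax$phylum[1]
  res <- phylum_holdout(pm, ph, k = 8L, cost = "mfps",
                        cfg = annealing_config(steps = 800L, restarts = 1L,
                                               seed = 3L))
  expect_setequal(res$condition, c("baseline", "holdout"))
  n_ph <- sum(pm$tax$phylum == ph)
  expect_equal(unique(res$n_train[res$condition == "holdout"]),
               length(pm$seq_ids) - n_ph)
  # the held-out phylum's sequences still receive fingerprints at evaluation
  expect_true(all(res$ratio > 0))
  expect_error(phylum_holdout(pm, "no-such-phylum", k = 4L), "unknown")
})

test_that("random probe sets are seeded uniform samples without replacement", {
  world <- small_world(seed = 127)
  pm <- probe_matrix(world, top_n = 100)
  expect_length(random_probe_sets(pm, 5L, 0L), 0L)
  sets <- random_probe_sets(pm, 5L, 10L, seed = 2L)
  expect_length(sets, 10L)
  for (s in sets) expect_equal(anyDuplicated(s), 0L)
  expect_identical(sets, random_probe_sets(pm, 5L, 10L, seed = 2L))
})

test_that("positional bias peaks at planted probe offsets", {
  spec <- synthetic_spec(n_phyla = 1, genera_per_phylum = 1,
                         otus_per_genus = 2, seqs_per_otu = 3,
                         alignment_length = 400,
                         hypervariable_blocks = list(c(180, 220)),
                         within_otu_divergence = 0, seed = 131)
  aln <- generate_alignment(spec)
  probe <- random_probes(1, seed = 17)
  planted <- plant_discriminative_probes(aln, probe, level = "phylum")
  proc <- prep_pipeline(planted)
  tax <- planted$taxonomy[planted$taxonomy$id %in% names(proc$seqs),
                          c("id", "phylum", "genus")]
  world <- label_set(proc, tax, assign_otus(proc, tax))
  pm <- build_matrix(probe, world)

  bias <- positional_bias(list(1L), pm, world)
  expect_equal(nrow(bias), 1L)
  cons <- gsub("-", "", consensus_sequence(world), fixed = TRUE)
  expect_equal(bias$position,
               regexpr(probe, cons, fixed = TRUE)[[1]] - 1L)
  expect_equal(sum(bias$count), 1L)

  # total mass over many sets equals the number of matched probe occurrences
  pm2 <- probe_matrix(world, top_n = 50)
  sets <- random_probe_sets(pm2, 4L, 5L, seed = 3L)
  b2 <- positional_bias(sets, pm2, world)
  expect_equal(sum(b2$count) + attr(b2, "n_skipped"), 20L)
})

test_that("penalty_sweep returns tidy per-penalty summaries", {
  world <- small_world(seed = 137)
  pm <- probe_matrix(world, top_n = 100)
  tab <- penalty_sweep(pm, genus_penalties = 5, k = 6L, n_sets = 3L,
                       cfg = annealing_config(steps = 400L, restarts = 1L,
                                              seed = 1L))
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$level, c("otu", "genus"))
  expect_true(all(tab$n == 3L))
  expect_true(all(tab$mean >= 0 & tab$mean <= 1))
})
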