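test_that("mutation profiles hold per-sample AF vectors over the cohort", {
  samples <- sprintf("S%d", 1:4)
  v <- rbind(make_variant("S1", pos = 100L, tumor_af = 0.5),
             make_variant("S3", pos = 100L, tumor_af = 0.5))
  p <- build_mutation_profiles(v, samples)
  expect_equal(nrow(p), 1L)
  expect_equal(unname(p$af[[1]]), c(0.5, 0, 0.5, 0))
  expect_equal(p$mean_af, 0.25)

  # distinct alternate alleles at one position are distinct mutations
  v2 <- rbind(make_variant("S1", pos = 100L, alt = "T"),
              make_variant("S2", pos = 100L, alt = "G"))
  expect_equal(nrow(build_mutation_profiles(v2, samples)), 2L)

  # duplicate call of one mutation within a sample keeps the max VAF
  v3 <- rbind(make_variant("S1", pos = 100L, tumor_af = 0.2),
              make_variant("S1", pos = 100L, tumor_af = 0.6))
  expect_equal(unname(build_mutation_profiles(v3, samples)$af[[1]]),
               c(0.6, 0, 0, 0))

  expect_equal(unname(build_mutation_profiles(
    make_variant(tumor_af = 1), "S1")$af[[1]]), 1)
  expect_error(build_mutation_profiles(v, c("S1", "S2")),
               "not in cohort: S3")
  expect_error(build_mutation_profiles(v, c("S1", "S1", "S3")),
               "duplicates")
})

test_that("minimum neighbour distances follow the vicinity rule", {
  samples <- "S1"
  v <- rbind(make_variant(pos = 100L), make_variant(pos = 103L),
             make_variant(pos = 200L))
  p <- compute_dmin(build_mutation_profiles(v, samples))
  expect_equal(p$d_min, c(3, 3, 97))

  single <- compute_dmin(build_mutation_profiles(make_variant(), samples))
  expect_equal(single$d_min, Inf)

  colocated <- rbind(make_variant(pos = 50L, alt = "T"),
                     make_variant(pos = 50L, alt = "G"))
  expect_equal(compute_dmin(build_mutation_profiles(colocated,
                                                    samples))$d_min,
               c(0, 0))

  p_bad <- build_mutation_profiles(v, samples)
  expect_error(compute_dmin(p_bad[c(2, 1, 3)]), "sorted")
})

test_that("the accumulation formula evaluates to its closed forms", {
  # saturated VAF and co-located neighbour: 1 + 1/(log(1)+1) = 2 in any base
  for (base in c("natural", "10", "2")) {
    expect_identical(mutation_acc_score(rep(1, 5), d_min = 0,
                                        log_base = base), 2)
  }
  # frozen hand evaluation: 0.25 + 1/(ln(10) + 1)
  expect_equal(mutation_acc_score(c(0.5, 0.5, 0, 0), d_min = 9),
               0.5527931065641138, tolerance = 1e-15)
  # base 10 makes the same distance term exactly 1/2
  expect_equal(mutation_acc_score(c(0.5, 0.5, 0, 0), d_min = 9,
                                  log_base = "10"), 0.75)
  # isolated mutation: AF mean alone
  expect_equal(mutation_acc_score(0.3, d_min = Inf), 0.3)
  expect_error(mutation_acc_score(c(0.5, 0.5), d_min = 1, n = 3),
               "cohort size")
})

test_that("gene score is the maximum mutation score with fixed tie-breaks", {
  samples <- sprintf("S%d", 1:2)
  v <- rbind(make_variant("S1", pos = 10L, tumor_af = 0.9),
             make_variant("S2", pos = 10L, tumor_af = 0.9),
             make_variant("S1", pos = 5000L, tumor_af = 0.1))
  gs <- gene_acc_scores(v, samples, cohort_label = "c1")
  prof <- compute_dmin(build_mutation_profiles(v, samples))
  per_mut <- sapply(seq_len(nrow(prof)), function(i)
    mutation_acc_score(prof$af[[i]], prof$d_min[i]))
  expect_equal(gs$score, max(per_mut))
  expect_equal(gs$n_mutations, 2L)

  # exact tie: smallest position wins
  tie <- rbind(make_variant("S1", pos = 10L, tumor_af = 0.4),
               make_variant("S1", pos = 20L, tumor_af = 0.4))
  gs_tie <- gene_acc_scores(tie, samples)
  expect_match(gs_tie$best_mutation, ":10:")

  expect_equal(nrow(gene_acc_scores(make_variant()[0, ], samples)), 0L)
})

test_that("gene scores match the brute-force oracle on random micro-cohorts", {
  for (seed in 1:40) {
    mc <- random_micro_cohort(seed)
    base <- c("natural", "10", "2")[seed %% 3 + 1]
    got <- gene_acc_scores(mc$variants, mc$samples, log_base = base)
    want <- oracle_gene_acc_scores(mc$variants, mc$samples, base)
    expect_equal(got$score[match(names(want), got$gene_symbol)],
                 unname(want), tolerance = 1e-12)
  }
})

test_that("scores are invariant to sample order and cohort duplication", {
  for (seed in 1:10) {
    mc <- random_micro_cohort(seed)
    ref_scores <- gene_acc_scores(mc$variants, mc$samples)

    perm <- sample(mc$samples)
    relabel <- setNames(sprintf("P%02d", seq_along(perm)), perm)
    v2 <- mc$variants
    v2$sample_id <- unname(relabel[v2$sample_id])
    got <- gene_acc_scores(v2, unname(relabel[mc$samples]))
    expect_equal(got[order(got$gene_symbol)]$score,
                 ref_scores[order(ref_scores$gene_symbol)]$score,
                 tolerance = 1e-12)

    # duplicating every sample (identical calls) leaves scores unchanged
    v_dup <- mc$variants
    v_dup$sample_id <- paste0(v_dup$sample_id, "_dup")
    dup <- gene_acc_scores(rbind(mc$variants, v_dup),
                           c(mc$samples, paste0(mc$samples, "_dup")))
    expect_equal(dup[order(dup$gene_symbol)]$score,
                 ref_scores[order(ref_scores$gene_symbol)]$score,
                 tolerance = 1e-12)
  }
})

test_that("adding a mutation never decreases a gene's score", {
  for (seed in 1:15) {
    mc <- random_micro_cohort(seed)
    before <- gene_acc_scores(mc$variants, mc$samples)
    set.seed(seed + 500)
    g <- sample(unique(mc$variants$gene_symbol), 1)
    extra <- make_variant(sample(mc$samples, 1), gene = g,
                          pos = sample(1:600, 1), ref = "C", alt = "G",
                          tumor_af = round(runif(1), 4))
    after <- gene_acc_scores(rbind(mc$variants, extra), mc$samples)
    expect_true(after$score[after$gene_symbol == g] >=
                  before$score[before$gene_symbol == g] - 1e-12)
  }
})

test_that("score range and distance-term monotonicity hold", {
  for (seed in 1:10) {
    mc <- random_micro_cohort(seed)
    s <- gene_acc_scores(mc$variants, mc$samples)$score
    expect_true(all(s > 0 & s <= 2))
  }
  d <- c(0, 1, 2, 5, 10, 100, 1e4, 1e6, 1e8)
  for (base in c("natural", "10", "2")) {
    term <- sapply(d, function(x)
      mutation_acc_score(0, d_min = x, n = 1, log_base = base))
    expect_true(all(diff(term) < 0))
  }
})

test_that("gene-set aggregation zero-fills and summarises per cohort", {
  sa <- data.table::data.table(gene_symbol = c("A", "B"), cohort = "c1",
                               score = c(0.6, 0.8), n_mutations = 1L,
                               best_mutation = "x")
  sb <- data.table::data.table(gene_symbol = "A", cohort = "c2",
                               score = 0.3, n_mutations = 1L,
                               best_mutation = "x")
  res <- score_gene_sets(sa, sb, list(S1 = c("A", "B"), S2 = c("B", "C")))
  sm <- res$summary
  expect_equal(sm[sm$set == "S1" & sm$cohort == "c1", ]$mean, 0.7)
  # unmutated member contributes 0
  expect_equal(res$per_gene[gene_symbol == "C" & cohort == "c1"]$score, 0)
  expect_equal(sm[sm$set == "S2" & sm$cohort == "c2", ]$mean, 0)

  dropped <- score_gene_sets(sa, sb, list(S2 = c("B", "C")),
                             drop_both_zero = TRUE)
  expect_false("C" %in% dropped$per_gene$gene_symbol)
  expect_true("B" %in% dropped$per_gene$gene_symbol)

  both <- score_gene_sets(sa, sb, list(S1 = c("A", "B")), test = "wilcox")
  expect_true(is.numeric(both$tests$p_value))
  expect_error(score_gene_sets(sa, sa, list(S1 = "A")), "distinct")
})
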