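test_that("raw verdicts normalise to signed scores per the mapping", {
  m <- default_interpreter_mapping()
  expect_equal(normalize_call("ClinVar", "benign", m), -6.2)
  expect_equal(normalize_call("ClinVar", "Benign", m), -6.2)
  expect_equal(normalize_call("InterVar", "Likely pathogenic", m), 3.9)
  expect_equal(normalize_call("InterVar", NA, m), 0)
  expect_equal(normalize_call("ClinVar", "something_else", m), 0)
  expect_error(normalize_call("PolyPhen", "benign", m), "PolyPhen")

  # SIFT: damaging below 0.05, sign flips at the threshold
  expect_gt(normalize_call("SIFT", 0.01, m), 0)
  expect_equal(normalize_call("SIFT", 0.05, m), 0)
  expect_lt(normalize_call("SIFT", 0.5, m), 0)
  expect_equal(normalize_call("SIFT", 0, m), 6.1)  # maximal damaging
  # CADD: damaging above phred 20, clamped to +/- scale
  expect_equal(normalize_call("CADD", 20, m), 0)
  expect_gt(normalize_call("CADD", 30, m), 0)
  expect_lt(normalize_call("CADD", 5, m), 0)
  expect_equal(normalize_call("CADD", 100, m), 5)
})

test_that("the shipped YAML mapping equals the built-in default", {
  path <- system.file("extdata", "interpreter_mapping.yaml",
                      package = "accuscore")
  m <- read_interpreter_mapping(path)
  d <- default_interpreter_mapping()
  for (ch in names(d)) {
    for (f in setdiff(names(d[[ch]]), "map")) {
      expect_equal(m[[ch]][[f]], d[[ch]][[f]])
    }
    if (!is.null(d[[ch]]$map)) {
      expect_equal(unlist(m[[ch]]$map), unlist(d[[ch]]$map))
    }
  }
  expect_equal(mapping_hash(m), mapping_hash(m))  # hash is stable
  expect_false(mapping_hash(m) == mapping_hash(d[1:3]))
})

test_that("consensus is most-pathogenic-wins and order-insensitive", {
  expect_equal(consensus_mutation_score(c(-7.8, -6.2, 6.1, 5)), 6.1)
  expect_equal(consensus_mutation_score(c(-3, -1)), -1)
  expect_equal(consensus_mutation_score(0), 0)
  expect_error(consensus_mutation_score(numeric()), "at least one")
  for (seed in 1:10) {
    set.seed(seed)
    s <- round(runif(4, -10, 10), 3)
    expect_equal(consensus_mutation_score(sample(s)),
                 consensus_mutation_score(s))
    expect_equal(consensus_mutation_score(c(s, s)),  # duplicated calls
                 consensus_mutation_score(s))
  }
})

test_that("gene-sample aggregation follows sum-of-positives with bins", {
  r <- gene_sample_score(c(6.1, 5, -2))
  expect_equal(r$s, 11.1)
  expect_equal(r$klass, "pathogenic_mid")

  r <- gene_sample_score(c(-7.8, -6.2))  # all benign: least-benign wins
  expect_equal(r$s, -6.2)
  expect_equal(r$klass, "benign")

  r <- gene_sample_score(c(-1, 0))  # no pathogenic, a VUS present
  expect_equal(r$s, 0)
  expect_equal(r$klass, "VUS")

  expect_equal(gene_sample_score(c(6.1, 5, -2))$s,
               oracle_gene_sample_score(c(6.1, 5, -2)))
  expect_error(gene_sample_score(numeric()), "at least one")
})

test_that("pathogenicity bins partition the reals", {
  expect_equal(classify_pathogenicity(c(-0.001, 0, 0.001, 9.999, 10, 20,
                                        20.001)),
               c("benign", "VUS", "pathogenic_low", "pathogenic_low",
                 "pathogenic_mid", "pathogenic_mid", "pathogenic_high"))
  set.seed(42)
  s <- c(runif(500, -50, 50), 0, 10, 20, -10)
  k <- classify_pathogenicity(s)
  expect_true(all(nchar(k) > 0))  # exhaustive
  # mutually exclusive: each score lands in exactly the predicted bin
  manual <- ifelse(s < 0, "benign",
            ifelse(s == 0, "VUS",
            ifelse(s < 10, "pathogenic_low",
            ifelse(s <= 20, "pathogenic_mid", "pathogenic_high"))))
  expect_equal(k, manual)
})

test_that("adding mutations moves gene-sample scores monotonically", {
  for (seed in 1:15) {
    set.seed(seed)
    scores <- round(runif(sample(1:5, 1), -10, 10), 2)
    s0 <- gene_sample_score(scores)$s
    s_path <- gene_sample_score(c(scores, runif(1, 0.1, 10)))$s
    expect_true(s_path >= s0)          # pathogenic never decreases s
    if (s0 > 0) {
      s_ben <- gene_sample_score(c(scores, -runif(1, 0.1, 10)))$s
      expect_equal(s_ben, s0)          # benign cannot change a positive s
    }
  }
})

test_that("gene-by-sample scoring joins calls and flags unannotated", {
  v <- rbind(make_variant("S1", gene = "G1", pos = 100L),
             make_variant("S1", gene = "G1", pos = 200L, alt = "G"),
             make_variant("S2", gene = "G1", pos = 100L),
             make_variant("S1", gene = "G2", pos = 300L))
  calls <- data.frame(
    gene_symbol = c("G1", "G1", "G1", "G1"),
    chrom = "chr1", pos = c(100L, 100L, 200L, 200L),
    ref = "A", alt = c("T", "T", "G", "G"),
    channel = c("InterVar", "ClinVar", "InterVar", "ClinVar"),
    raw_value = c("Pathogenic", "Benign", "Benign", "Likely benign"))
  gss <- gene_sample_scores(v, normalize_calls(calls))
  expect_equal(nrow(gss), 2L)  # G2 has no calls at all
  expect_equal(nrow(attr(gss, "unannotated")), 1L)
  expect_equal(attr(gss, "unannotated")$gene_symbol, "G2")
  s1 <- gss[gss$gene_symbol == "G1" & gss$sample_id == "S1", ]
  expect_equal(s1$s, 7.8)  # one pathogenic (7.8) + one benign (max -3.1)
  s2 <- gss[gss$gene_symbol == "G1" & gss$sample_id == "S2", ]
  expect_equal(s2$s, 7.8)
})

test_that("recurrent pathogenic genes respect the sample threshold", {
  set.seed(7)
  mk <- function(gene, n_pos, n_neg) {
    rbind(
      if (n_pos) data.frame(gene_symbol = gene,
                            sample_id = sprintf("S%d", seq_len(n_pos)),
                            s = runif(n_pos, 1, 15),
                            klass = "pathogenic_low"),
      if (n_neg) data.frame(gene_symbol = gene,
                            sample_id = sprintf("S%d", n_pos + seq_len(n_neg)),
                            s = -runif(n_neg, 1, 5), klass = "benign"))
  }
  tab <- rbind(mk("G5", 5, 4), mk("G4", 4, 5), mk("G9", 9, 0))
  rec <- recurrent_pathogenic_genes(tab, min_samples = 5)
  expect_equal(rec$genes$gene_symbol, c("G9", "G5"))
  expect_equal(rec$genes$n_pathogenic, c(9L, 5L))
  expect_true(all(rec$matrix$gene_symbol %in% c("G9", "G5")))

  all_genes <- recurrent_pathogenic_genes(tab, min_samples = 1)
  expect_equal(sort(all_genes$genes$gene_symbol), c("G4", "G5", "G9"))

  other <- mk("G5", 2, 0)
  rec2 <- recurrent_pathogenic_genes(tab, 5, other_scores = other)
  expect_equal(rec2$genes$n_pathogenic_other,
               c(0L, 2L)[match(rec2$genes$gene_symbol, c("G9", "G5"))])

  counts <- oracle_pathogenic_counts(tab)
  expect_equal(sort(names(counts[counts >= 5])),
               sort(rec$genes$gene_symbol))
})

test_that("recurrent mutated genes flag SNV, indel or both per sample", {
  v <- rbind(
    make_variant("S1", gene = "G1", pos = 1L),
    make_variant("S2", gene = "G1", pos = 2L),
    make_variant("S3", gene = "G1", pos = 3L),
    make_variant("S4", gene = "G1", pos = 4L, alt = "TA",
                 variant_class = "insertion", consequence = "frameshift"),
    make_variant("S5", gene = "G1", pos = 5L, ref = "AG", alt = "A",
                 variant_class = "deletion", consequence = "frameshift"),
    make_variant("S1", gene = "G2", pos = 6L),
    make_variant("S1", gene = "G2", pos = 7L, ref = "AG", alt = "A",
                 variant_class = "deletion", consequence = "frameshift"))
  rec <- recurrent_mutated_genes(v, min_samples = 5)
  expect_equal(rec$genes$gene_symbol, "G1")  # SNVs in 3 + indels in 2
  expect_equal(rec$genes$n_samples, 5L)
  flags <- rec$matrix
  expect_equal(sort(flags$flag[flags$sample_id %in% c("S1", "S2", "S3")]),
               rep("SNV", 3))
  expect_equal(sort(flags$flag[flags$sample_id %in% c("S4", "S5")]),
               rep("indel", 2))

  both <- recurrent_mutated_genes(v, min_samples = 1)
  g2 <- both$matrix[both$matrix$gene_symbol == "G2", ]
  expect_equal(g2$flag, "both")

  empty <- recurrent_mutated_genes(make_variant()[0, ], 5)
  expect_equal(nrow(empty$genes), 0L)

  counts <- oracle_mutated_flag_counts(v)
  expect_equal(unname(counts["G1"]),
               both$genes$n_samples[both$genes$gene_symbol == "G1"])
})
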