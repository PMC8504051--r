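#' Specification for the two-cohort synthetic data generator
#'
#' Describes a pair of somatic-mutation cohorts with the statistical
#' structure the scoring exploits: a small cohort A (default 9 samples,
#' the effusion-like group) carrying planted "hot" genes with tightly
#' clustered, high-VAF, recurrent, pathogenic mutations, versus a larger
#' cohort B (default 22 samples, the nodal-like group) where the same
#' genes are sparse or absent; background genes mutate symmetrically in
#' both cohorts with widely spaced, low-VAF, mostly benign mutations. A
#' configurable fraction of decoy records carries population MAF above
#' 1 % or a synonymous consequence, with bookkeeping, to exercise the
#' pre-filter.
#'
#' @param n_cohort_a,n_cohort_b Cohort sizes (defaults 9 and 22).
#' @param n_genes Total genes in the synthetic universe (default 40).
#' @param hot_genes Symbols planted as cohort-A-associated; must be a
#'   subset of the universe `GENE001..GENE<n_genes>` (default the first
#'   five).
#' @param hot_cluster_span_bp Maximum intermutation span of a planted
#'   cluster (default 10 bp, kataegis-like).
#' @param hot_vaf,background_vaf Beta shape parameters `c(shape1,
#'   shape2)` for carrier VAFs; defaults mean 0.45 (hot) and 0.15
#'   (background).
#' @param background_spacing_bp Minimum intermutation distance within a
#'   background gene (default 10000 bp).
#' @param hot_recurrence Fraction of cohort-A samples carrying each hot
#'   gene's mutation (default 7/9).
#' @param interpreter_concordance Probability that all four interpreter
#'   channels agree on a planted-pathogenic mutation (default 0.9;
#'   discordant calls stay majority-pathogenic).
#' @param maf_contamination Fraction (relative to the core record count)
#'   of added decoy records with population MAF above 1 % (default
#'   0.05).
#' @param synonymous_fraction Fraction of added synonymous decoy records
#'   (default 0.05).
#' @param seed Integer seed; the generator is fully deterministic given
#'   the spec.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cohort_a = 9L, n_cohort_b = 22L,
                           n_genes = 40L,
                           hot_genes = sprintf("GENE%03d", 1:5),
                           hot_cluster_span_bp = 10L,
                           hot_vaf = c(9, 11),
                           background_vaf = c(3, 17),
                           background_spacing_bp = 10000L,
                           hot_recurrence = 7 / 9,
                           interpreter_concordance = 0.9,
                           maf_contamination = 0.05,
                           synonymous_fraction = 0.05,
                           seed = 1L) {
  spec <- list(n_cohort_a = as.integer(n_cohort_a),
               n_cohort_b = as.integer(n_cohort_b),
               n_genes = as.integer(n_genes),
               hot_genes = hot_genes,
               hot_cluster_span_bp = as.integer(hot_cluster_span_bp),
               hot_vaf = hot_vaf, background_vaf = background_vaf,
               background_spacing_bp = as.integer(background_spacing_bp),
               hot_recurrence = hot_recurrence,
               interpreter_concordance = interpreter_concordance,
               maf_contamination = maf_contamination,
               synonymous_fraction = synonymous_fraction,
               seed = as.integer(seed))
  universe <- sprintf("GENE%03d", seq_len(spec$n_genes))
  if (spec$n_cohort_a < 1L || spec$n_cohort_b < 1L) {
    stop("cohort sizes must be >= 1", call. = FALSE)
  }
  probs <- c(spec$hot_recurrence, spec$interpreter_concordance,
             spec$maf_contamination, spec$synonymous_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!all(spec$hot_genes %in% universe)) {
    stop("hot_genes must be a subset of the gene universe ",
         universe[1L], "..", universe[spec$n_genes], call. = FALSE)
  }
  if (spec$hot_recurrence * spec$n_cohort_a < 1) {
    stop("infeasible spec: hot_recurrence x n_cohort_a < 1 ",
         "(no sample would carry a hot-gene mutation)", call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

# synthetic gene intervals; scores only use relative positions
synthetic_gene_models <- function(spec) {
  i <- seq_len(spec$n_genes)
  len <- 4L * spec$background_spacing_bp + 10000L
  data.table(
    gene_symbol = sprintf("GENE%03d", i),
    chrom = paste0("chr", (i - 1L) %% 4L + 1L),
    start = 1000000L + ((i - 1L) %/% 4L) * (len + 1000000L),
    length = len)
}

BASES <- c("A", "C", "G", "T")

rand_snv <- function() {
  ref <- sample(BASES, 1L)
  list(ref = ref, alt = sample(setdiff(BASES, ref), 1L))
}

rand_indel <- function() {
  ref <- sample(BASES, 1L)
  if (runif(1) < 0.5) {
    list(ref = ref, alt = paste0(ref, paste(sample(BASES, 2L, TRUE),
                                            collapse = "")),
         class = "insertion")
  } else {
    list(ref = paste0(ref, paste(sample(BASES, 2L, TRUE), collapse = "")),
         alt = ref, class = "deletion")
  }
}

#' Generate a two-cohort synthetic data set
#'
#' Produces per-sample variant tables for cohorts A and B, a four-channel
#' interpreter-call table for every distinct mutation, and ground-truth
#' bookkeeping (hot genes, planted-pathogenic mutation keys, the record
#' ids of MAF-contaminated and synonymous decoys). Deterministic given
#' `spec$seed`: identical specs yield byte-identical tables.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `variants_a`, `variants_b` (variant tables with an
#'   extra `record_id` column), `interpreter_calls` (gene, chrom, pos,
#'   ref, alt, channel, raw_value), `truth` (hot_genes,
#'   planted_pathogenic, contaminated, synonymous, spec echo),
#'   `gene_models`, `samples_a`, `samples_b`.
#' @export
generate_cohorts <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  models <- synthetic_gene_models(spec)
  samples_a <- sprintf("A%02d", seq_len(spec$n_cohort_a))
  samples_b <- sprintf("B%02d", seq_len(spec$n_cohort_b))
  set.seed(spec$seed)
  gene_seeds <- sample.int(999999937L, spec$n_genes)

  rec <- function(sample_id, gene, chrom, pos, ref, alt, class, conseq,
                  af, pmaf = NA_real_) {
    data.table(sample_id = sample_id, gene_symbol = gene, chrom = chrom,
               pos = as.integer(pos), ref = ref, alt = alt,
               variant_class = class, consequence = conseq,
               tumor_af = af, population_maf = pmaf)
  }

  variants <- list(A = list(), B = list())
  calls_intent <- list()   # per distinct mutation: key + verdict intent

  for (g in seq_len(spec$n_genes)) {
    gm <- models[g]
    gene <- gm$gene_symbol
    hot <- gene %in% spec$hot_genes
    set.seed(gene_seeds[g])

    if (hot) {
      # cohort A: one tight cluster, recurrent high-VAF pathogenic SNVs
      n_car <- ceiling(spec$hot_recurrence * spec$n_cohort_a)
      carriers <- sort(sample(samples_a, n_car))
      span <- spec$hot_cluster_span_bp
      anchor <- gm$start + sample.int(gm$length - span - 2000L, 1L) + 1000L
      offs <- sample(0:span, n_car, replace = n_car > span + 1L)
      alleles <- lapply(sort(unique(offs)), function(o) rand_snv())
      names(alleles) <- as.character(sort(unique(offs)))
      for (j in seq_len(n_car)) {
        al <- alleles[[as.character(offs[j])]]
        conseq <- if (runif(1) < 0.8) "missense" else "stop_gain"
        variants$A[[length(variants$A) + 1L]] <- rec(
          carriers[j], gene, gm$chrom, anchor + offs[j], al$ref, al$alt,
          "SNV", conseq, rbeta(1, spec$hot_vaf[1], spec$hot_vaf[2]))
      }
      for (o in sort(unique(offs))) {
        al <- alleles[[as.character(o)]]
        calls_intent[[length(calls_intent) + 1L]] <- list(
          gene = gene, chrom = gm$chrom, pos = anchor + o,
          ref = al$ref, alt = al$alt, intent = "pathogenic",
          planted = TRUE)
      }
      # cohort B: the hot gene is sparse — at most one isolated benign call
      if (runif(1) < 0.5) {
        al <- rand_snv()
        pos_b <- gm$start + sample.int(gm$length - 2000L, 1L) + 1000L
        variants$B[[length(variants$B) + 1L]] <- rec(
          sample(samples_b, 1L), gene, gm$chrom, pos_b, al$ref, al$alt,
          "SNV", "missense",
          rbeta(1, spec$background_vaf[1], spec$background_vaf[2]))
        calls_intent[[length(calls_intent) + 1L]] <- list(
          gene = gene, chrom = gm$chrom, pos = pos_b, ref = al$ref,
          alt = al$alt, intent = "benign", planted = FALSE)
      }
    } else {
      # background gene: symmetric sparse process in each cohort, widely
      # spaced mutations, <= 4 distinct carrier samples per cohort so no
      # background gene can reach a 5-sample recurrence threshold
      for (coh in c("A", "B")) {
        samples <- if (coh == "A") samples_a else samples_b
        n_mut <- sample(1:3, 1L)
        pool <- sample(samples, min(4L, length(samples)))
        gaps <- spec$background_spacing_bp + sample.int(5000L, n_mut)
        positions <- gm$start + 1000L + cumsum(gaps)
        for (k in seq_len(n_mut)) {
          is_indel <- runif(1) < 0.15
          al <- if (is_indel) rand_indel() else rand_snv()
          class <- if (is_indel) al$class else "SNV"
          conseq <- if (is_indel) {
            sample(c("frameshift", "inframe_indel"), 1L)
          } else {
            sample(c("missense", "splice", "stop_gain"), 1L,
                   prob = c(0.8, 0.15, 0.05))
          }
          n_car <- sample(1:2, 1L)
          carriers <- sample(pool, n_car)
          pmaf <- if (runif(1) < 0.3) runif(1, 0, 0.01) else NA_real_
          for (s in carriers) {
            variants[[coh]][[length(variants[[coh]]) + 1L]] <- rec(
              s, gene, gm$chrom, positions[k], al$ref, al$alt, class,
              conseq,
              rbeta(1, spec$background_vaf[1], spec$background_vaf[2]),
              pmaf)
          }
          intent <- sample(c("benign", "vus", "noise_pathogenic",
                             "unannotated"), 1L,
                           prob = c(0.6, 0.15, 0.15, 0.1))
          calls_intent[[length(calls_intent) + 1L]] <- list(
            gene = gene, chrom = gm$chrom, pos = positions[k],
            ref = al$ref, alt = al$alt, intent = intent, planted = FALSE)
        }
      }
    }
  }

  va <- rbindlist(variants$A)
  vb <- rbindlist(variants$B)

  # decoy records: population-MAF contamination and synonymous calls,
  # placed in a reserved band of each gene so they never perturb the
  # planted positional structure once filtered out
  decoys <- function(v, samples, n, kind, seed_shift) {
    set.seed((spec$seed + seed_shift) %% 999999937L)
    if (n < 1L) return(NULL)
    bg <- models[!gene_symbol %in% spec$hot_genes]
    idx <- sample.int(nrow(bg), n, replace = TRUE)
    rbindlist(lapply(seq_len(n), function(k) {
      gm <- bg[idx[k]]
      al <- rand_snv()
      rec(sample(samples, 1L), gm$gene_symbol, gm$chrom,
          gm$start + gm$length + 5000L + sample.int(4000L, 1L),
          al$ref, al$alt, "SNV",
          if (kind == "synonymous") "synonymous" else "missense",
          rbeta(1, spec$background_vaf[1], spec$background_vaf[2]),
          if (kind == "maf") runif(1, 0.02, 0.4) else NA_real_)
    }))
  }
  truth_ids <- list(contaminated = list(), synonymous = list())
  out_tabs <- list()
  for (coh in c("A", "B")) {
    core <- if (coh == "A") va else vb
    samples <- if (coh == "A") samples_a else samples_b
    n_maf <- round(spec$maf_contamination * nrow(core))
    n_syn <- round(spec$synonymous_fraction * nrow(core))
    d_maf <- decoys(core, samples, n_maf, "maf", if (coh == "A") 101L else 102L)
    d_syn <- decoys(core, samples, n_syn, "synonymous",
                    if (coh == "A") 201L else 202L)
    tab <- rbindlist(list(core, d_maf, d_syn))
    setorder(tab, gene_symbol, chrom, pos, ref, alt, sample_id)
    tab[, record_id := sprintf("%s-%05d", coh, seq_len(.N))]
    flag_ids <- function(d) {
      if (is.null(d) || !nrow(d)) return(character())
      tab$record_id[match(paste(d$sample_id, mutation_id(d)),
                          paste(tab$sample_id, mutation_id(tab)))]
    }
    truth_ids$contaminated[[coh]] <- sort(flag_ids(d_maf))
    truth_ids$synonymous[[coh]] <- sort(flag_ids(d_syn))
    out_tabs[[coh]] <- tab
  }

  intents <- rbindlist(lapply(calls_intent, function(x)
    data.table(gene_symbol = x$gene, chrom = x$chrom, pos = x$pos,
               ref = x$ref, alt = x$alt, intent = x$intent,
               planted = x$planted)))
  setorder(intents, gene_symbol, chrom, pos, ref, alt)
  set.seed((spec$seed + 301L) %% 999999937L)
  calls <- rbindlist(lapply(seq_len(nrow(intents)), function(i)
    synth_interpreter_calls(intents[i], spec$interpreter_concordance)))

  list(variants_a = out_tabs$A, variants_b = out_tabs$B,
       interpreter_calls = calls,
       truth = list(
         hot_genes = spec$hot_genes,
         planted_pathogenic = intents[planted == TRUE,
                                      mutation_key_cols(), with = FALSE],
         contaminated = truth_ids$contaminated,
         synonymous = truth_ids$synonymous,
         spec = unclass(spec)),
       gene_models = models, samples_a = samples_a, samples_b = samples_b)
}

# raw verdicts for one mutation under a given intent; pathogenic intents
# always keep a majority-pathogenic (consensus > 0) panel
synth_interpreter_calls <- function(key, concordance) {
  raw_path <- function(ch) switch(ch,
    InterVar = sample(c("Pathogenic", "Likely pathogenic"), 1L),
    ClinVar = sample(c("Pathogenic", "Likely pathogenic"), 1L),
    SIFT = sprintf("%.4f", runif(1, 0, 0.04)),
    CADD = sprintf("%.1f", runif(1, 25, 40)))
  raw_benign <- function(ch) switch(ch,
    InterVar = sample(c("Benign", "Likely benign"), 1L),
    ClinVar = sample(c("Benign", "Likely benign"), 1L),
    SIFT = sprintf("%.4f", runif(1, 0.3, 1)),
    CADD = sprintf("%.1f", runif(1, 1, 10)))
  channels <- INTERPRETER_CHANNELS
  raw <- switch(key$intent,
    pathogenic = {
      if (runif(1) < concordance) {
        vapply(channels, raw_path, character(1))
      } else {  # discordant but majority-pathogenic
        benign_ch <- sample(channels, 2L)
        vapply(channels, function(ch)
          if (ch %in% benign_ch) raw_benign(ch) else raw_path(ch),
          character(1))
      }
    },
    benign = vapply(channels, raw_benign, character(1)),
    noise_pathogenic = {  # one weakly pathogenic channel, rest benign
      vapply(channels, function(ch)
        if (ch == "CADD") sprintf("%.1f", runif(1, 21, 25))
        else raw_benign(ch), character(1))
    },
    vus = {
      channels <- c("InterVar", "ClinVar")
      c(InterVar = "Uncertain significance",
        ClinVar = "Uncertain significance")
    },
    unannotated = return(NULL))
  data.table(gene_symbol = key$gene_symbol, chrom = key$chrom,
             pos = key$pos, ref = key$ref, alt = key$alt,
             channel = channels, raw_value = unname(raw))
}

#' Write a synthetic data set to disk
#'
#' Writes `variants_a.tsv`, `variants_b.tsv`, `interpreter_calls.tsv`,
#' `gene_sets.gmt` (two sets: the planted hot genes and the background
#' genes) and `truth.json` under `dir`.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
simulate_to_dir <- function(spec = synthetic_spec(), dir) {
  sim <- generate_cohorts(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(variants_a = file.path(dir, "variants_a.tsv"),
             variants_b = file.path(dir, "variants_b.tsv"),
             interpreter_calls = file.path(dir, "interpreter_calls.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.json"))
  fwrite(sim$variants_a, paths["variants_a"], sep = "\t", na = ".",
         quote = FALSE)
  fwrite(sim$variants_b, paths["variants_b"], sep = "\t", na = ".",
         quote = FALSE)
  fwrite(sim$interpreter_calls, paths["interpreter_calls"], sep = "\t",
         na = ".", quote = FALSE)
  universe <- sim$gene_models$gene_symbol
  write_gene_sets(list(planted_hot = sim$truth$hot_genes,
                       background = setdiff(universe, sim$truth$hot_genes)),
                  paths["gene_sets"],
                  descriptions = c("planted cohort-A-associated genes",
                                   "background genes"))
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}
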