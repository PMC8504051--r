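# Independent brute-force reimplementations used as oracles. Plain loops
# over data frames, no shared code with the package internals.

oracle_log <- function(x, log_base) {
  b <- switch(as.character(log_base), natural = exp(1), "10" = 10, "2" = 2)
  log(x, base = b)
}

# per-gene accumulation scores by exhaustive enumeration: for every
# distinct mutation, sum per-sample max VAFs, find the minimum pairwise
# distance to any other distinct mutation of the gene, score, take max
oracle_gene_acc_scores <- function(variants, samples, log_base = "natural") {
  v <- as.data.frame(variants)
  n <- length(samples)
  out <- list()
  for (g in sort(unique(v$gene_symbol))) {
    vg <- v[v$gene_symbol == g, , drop = FALSE]
    key <- paste(vg$chrom, vg$pos, vg$ref, vg$alt)
    best <- -Inf
    for (k in unique(key)) {
      sel <- vg[key == k, , drop = FALSE]
      af_sum <- 0
      for (s in samples) {
        afs <- sel$tumor_af[sel$sample_id == s]
        if (length(afs)) af_sum <- af_sum + max(afs)
      }
      other_pos <- vg$pos[key != k]
      dmin <- if (length(other_pos)) min(abs(sel$pos[1] - other_pos)) else Inf
      dist_term <- if (is.infinite(dmin)) 0 else
        1 / (oracle_log(dmin + 1, log_base) + 1)
      best <- max(best, af_sum / n + dist_term)
    }
    out[[g]] <- best
  }
  unlist(out)
}

# gene-per-sample pathogenicity: sum of positives, else 0 if any VUS,
# else the least-negative benign score
oracle_gene_sample_score <- function(scores) {
  total <- 0
  n_pos <- 0
  has_vus <- FALSE
  best_neg <- -Inf
  for (x in scores) {
    if (x > 0) { total <- total + x; n_pos <- n_pos + 1 }
    else if (x == 0) has_vus <- TRUE
    else best_neg <- max(best_neg, x)
  }
  if (n_pos > 0) total else if (has_vus) 0 else best_neg
}

oracle_pathogenic_counts <- function(gene_sample_tab) {
  tab <- as.data.frame(gene_sample_tab)
  counts <- list()
  for (i in seq_len(nrow(tab))) {
    g <- tab$gene_symbol[i]
    if (is.null(counts[[g]])) counts[[g]] <- 0
    if (tab$s[i] > 0) counts[[g]] <- counts[[g]] + 1
  }
  unlist(counts)
}

oracle_mutated_flag_counts <- function(variants) {
  v <- as.data.frame(variants)
  pair <- unique(paste(v$gene_symbol, v$sample_id, sep = "\r"))
  counts <- list()
  for (p in pair) {
    g <- strsplit(p, "\r", fixed = TRUE)[[1]][1]
    counts[[g]] <- (counts[[g]] %||% 0) + 1
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random micro-cohort: <= 5 genes, <= 12 distinct mutations, <= 6 samples
random_micro_cohort <- function(seed) {
  set.seed(seed)
  n_samples <- sample(1:6, 1)
  samples <- sprintf("S%02d", seq_len(n_samples))
  n_genes <- sample(1:5, 1)
  genes <- sprintf("G%d", seq_len(n_genes))
  n_mut <- sample(1:12, 1)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (m in seq_len(n_mut)) {
    g <- sample(genes, 1)
    pos <- sample(1:500, 1)   # small range so position collisions happen
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    carriers <- sample(samples, sample(1:n_samples, 1))
    for (s in carriers) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, gene_symbol = g, chrom = "chr1", pos = pos,
        ref = ref, alt = alt, variant_class = "SNV",
        consequence = "missense", tumor_af = round(runif(1), 4),
        population_maf = NA_real_)
    }
  }
  v <- do.call(rbind, rows)
  # collapse accidental duplicate (sample, mutation) rows to max VAF to
  # keep the oracle's per-sample max rule exercised but unambiguous
  list(variants = v, samples = samples)
}

make_variant <- function(sample_id = "S1", gene = "G1", chrom = "chr1",
                         pos = 100L, ref = "A", alt = "T",
                         variant_class = "SNV", consequence = "missense",
                         tumor_af = 0.5, population_maf = NA_real_) {
  data.frame(sample_id = sample_id, gene_symbol = gene, chrom = chrom,
             pos = pos, ref = ref, alt = alt,
             variant_class = variant_class, consequence = consequence,
             tumor_af = tumor_af, population_maf = population_maf,
             stringsAsFactors = FALSE)
}
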