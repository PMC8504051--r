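#' Build per-mutation allele-frequency profiles for a cohort
#'
#' For each distinct mutation (gene, chrom, pos, ref, alt) the profile
#' holds a length-n vector over the cohort's samples: entry j is the
#' variant allele fraction of the mutation in sample j, or 0 when the
#' sample does not carry it. A sample with the same mutation called more
#' than once keeps the maximum VAF. Profiles are returned position-sorted
#' within each gene, ready for [compute_dmin()].
#'
#' @param variants A variant table for one cohort.
#' @param cohort_samples Ordered character vector of all sample ids in
#'   the cohort (including samples with no calls); no duplicates.
#' @return A `data.table` with one row per distinct mutation: the
#'   mutation key columns, `af` (list column: named numeric length-n
#'   vector), `mean_af` and `n_carriers`.
#' @export
build_mutation_profiles <- function(variants, cohort_samples) {
  dt <- validate_variants(variants)
  if (anyDuplicated(cohort_samples)) {
    stop("cohort_samples contains duplicates", call. = FALSE)
  }
  outside <- setdiff(unique(dt$sample_id), cohort_samples)
  if (length(outside)) {
    stop("sample(s) not in cohort: ", paste(outside, collapse = ", "),
         call. = FALSE)
  }
  n <- length(cohort_samples)
  if (!nrow(dt)) {
    return(data.table(gene_symbol = character(), chrom = character(),
                      pos = integer(), ref = character(),
                      alt = character(), af = list(),
                      mean_af = numeric(), n_carriers = integer()))
  }
  # duplicate calls of one mutation in one sample: keep max VAF
  dt <- dt[, .(tumor_af = max(tumor_af)),
           by = c(mutation_key_cols(), "sample_id")]
  key_cols <- mutation_key_cols()
  profiles <- dt[, {
    v <- numeric(n)
    names(v) <- cohort_samples
    v[match(sample_id, cohort_samples)] <- tumor_af
    .(af = list(v), mean_af = sum(tumor_af) / n, n_carriers = .N)
  }, by = key_cols]
  setorder(profiles, gene_symbol, chrom, pos, ref, alt)
  profiles[]
}

#' Minimum intermutation distance per mutation within each gene
#'
#' For every mutation of a gene (positions pooled across the whole
#' cohort), computes the distance in base pairs to its nearest vicinity
#' mutation: interior mutations take the minimum of the distances to the
#' previous and next mutation, terminal mutations the distance to their
#' single neighbour, and a gene's only mutation gets `Inf` (no
#' neighbour). Distinct alleles at the same position are 0 bp apart.
#'
#' @param profiles Mutation profiles from [build_mutation_profiles()],
#'   position-sorted within each gene (an error otherwise).
#' @return The profiles with a `d_min` column added.
#' @export
#' @examples
#' \dontrun{
#' prof <- build_mutation_profiles(variants, samples)
#' prof <- compute_dmin(prof)
#' }
compute_dmin <- function(profiles) {
  dt <- as.data.table(copy(profiles))
  if (dt[, any(chrom != chrom[1L]), by = gene_symbol][, any(V1)]) {
    stop("a gene's mutations span more than one chromosome", call. = FALSE)
  }
  if (dt[, is.unsorted(pos), by = gene_symbol][, any(V1)]) {
    stop("profiles must be position-sorted within each gene", call. = FALSE)
  }
  dt[, d_min := {
    if (.N == 1L) Inf else {
      gaps <- diff(pos)                      # gap k: pos[k+1] - pos[k]
      pmin(c(Inf, gaps), c(gaps, Inf))
    }
  }, by = gene_symbol]
  dt[]
}

# 1 / (log(d + 1) + 1); 0 for an isolated mutation (d = Inf limit)
distance_term <- function(d_min, log_base = c("natural", "10", "2")) {
  log_base <- match.arg(as.character(log_base), c("natural", "10", "2"))
  b <- switch(log_base, natural = exp(1), "10" = 10, "2" = 2)
  ifelse(is.infinite(d_min), 0, 1 / (log(d_min + 1, base = b) + 1))
}

#' Accumulation score of a single mutation
#'
#' The score is the cohort-mean allele fraction of the mutation plus an
#' intermutation-distance bonus:
#' \deqn{\mathrm{Acc}^{(i)} = \frac{1}{n}\sum_{k=1}^{n} AF_{k,i} +
#'   \frac{1}{\log(d_{\min}(i)+1)+1}}
#' where `n` is the cohort size and `d_min` the minimum distance in bp to
#' a vicinity mutation of the same gene. Tight clusters (small `d_min`)
#' push the second term toward its maximum of 1 (kataegis-like local
#' hypermutation); an isolated mutation (`d_min = Inf`) is scored by its
#' mean allele fraction alone.
#'
#' @param af_vector Numeric length-n vector of per-sample allele
#'   fractions (0 for non-carriers).
#' @param d_min Minimum neighbour distance in bp, or `Inf`.
#' @param n Cohort size; must equal `length(af_vector)`.
#' @param log_base Logarithm base for the distance term: `"natural"`
#'   (default), `"10"` or `"2"`.
#' @return The accumulation score, a real in (0, 2] for a carrier.
#' @export
#' @examples
#' mutation_acc_score(c(0.5, 0.5, 0, 0), d_min = 9)  # 0.25 + 1/(log(10)+1)
mutation_acc_score <- function(af_vector, d_min, n = length(af_vector),
                               log_base = "natural") {
  if (length(af_vector) != n) {
    stop("af_vector length (", length(af_vector),
         ") does not match cohort size n (", n, ")", call. = FALSE)
  }
  stopifnot(n >= 1L, all(af_vector >= 0 & af_vector <= 1))
  sum(af_vector) / n + distance_term(d_min, log_base)
}

#' Per-gene accumulation scores for a cohort
#'
#' Scores every mutation of every gene and takes each gene's maximum as
#' the gene score. Ties are broken toward the smallest position, then the
#' lexicographically smallest alternate allele.
#'
#' @param variants A (filtered) variant table for one cohort, or mutation
#'   profiles already carrying `d_min` (from [compute_dmin()]).
#' @param cohort_samples Ordered sample ids of the cohort (ignored when
#'   `variants` is already a profile table with `d_min`).
#' @param log_base Passed to the distance term; recorded in the result's
#'   `log_base` attribute.
#' @param cohort_label Label stored in the `cohort` column.
#' @return A `data.table` with one row per gene: `gene_symbol`, `cohort`,
#'   `score`, `n_mutations`, `best_mutation` (key of the arg-max
#'   mutation, `chrom:pos:ref:alt`).
#' @export
gene_acc_scores <- function(variants, cohort_samples = NULL,
                            log_base = "natural", cohort_label = "cohort") {
  if (is.data.frame(variants) && "d_min" %in% names(variants)) {
    prof <- as.data.table(copy(variants))
    n <- length(prof$af[[1L]])
  } else {
    if (is.null(cohort_samples)) {
      stop("cohort_samples is required when passing raw variant records",
           call. = FALSE)
    }
    prof <- compute_dmin(build_mutation_profiles(variants, cohort_samples))
    n <- length(cohort_samples)
  }
  if (!nrow(prof)) {
    return(data.table(gene_symbol = character(), cohort = character(),
                      score = numeric(), n_mutations = integer(),
                      best_mutation = character()))
  }
  prof[, acc_score := mean_af + distance_term(d_min, log_base)]
  out <- prof[order(-acc_score, pos, alt), .(
    cohort = cohort_label,
    score = acc_score[1L],
    n_mutations = .N,
    best_mutation = paste(chrom[1L], pos[1L], ref[1L], alt[1L], sep = ":")
  ), by = gene_symbol]
  setorder(out, -score, gene_symbol)
  data.table::setattr(out, "log_base", log_base)
  data.table::setattr(out, "n_samples", n)
  out[]
}

#' Aggregate gene accumulation scores over gene sets for two cohorts
#'
#' For each gene set and each cohort, collects the member genes' scores
#' (0 for a gene with no retained mutation in that cohort) and summary
#' statistics — the numbers behind a per-pathway boxplot pair comparing
#' the cohorts. Optionally drops genes whose score is 0 in both cohorts,
#' and can attach a Mann-Whitney U comparison of the two cohorts' score
#' distributions per set (an optional extra, not part of the scoring
#' method itself).
#'
#' @param scores_a,scores_b Per-gene score tables from
#'   [gene_acc_scores()] for the two cohorts (distinct `cohort` labels).
#' @param sets Named list of gene sets (see [read_gene_sets()]).
#' @param drop_both_zero Drop genes scoring 0 in both cohorts (default
#'   `FALSE`).
#' @param test `"none"` (default) or `"wilcox"` for a per-set
#'   Mann-Whitney U test between the cohorts' per-gene scores.
#' @return A list with `per_gene` (set, gene_symbol, cohort, score) and
#'   `summary` (set, cohort, n_genes, mean, median, q1, q3), plus
#'   `tests` when requested.
#' @export
score_gene_sets <- function(scores_a, scores_b, sets,
                            drop_both_zero = FALSE,
                            test = c("none", "wilcox")) {
  test <- match.arg(test)
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  lab_a <- if (nrow(scores_a)) scores_a$cohort[1L] else "cohortA"
  lab_b <- if (nrow(scores_b)) scores_b$cohort[1L] else "cohortB"
  if (identical(lab_a, lab_b)) {
    stop("the two cohorts must carry distinct labels", call. = FALSE)
  }
  lookup <- function(genes, tab) {
    s <- tab$score[match(genes, tab$gene_symbol)]
    s[is.na(s)] <- 0
    s
  }
  per_gene <- rbindlist(lapply(names(sets), function(nm) {
    genes <- unique(sets[[nm]])
    sa <- lookup(genes, scores_a)
    sb <- lookup(genes, scores_b)
    if (drop_both_zero) {
      keep <- sa != 0 | sb != 0
      genes <- genes[keep]; sa <- sa[keep]; sb <- sb[keep]
    }
    rbind(data.table(set = nm, gene_symbol = genes, cohort = lab_a,
                     score = sa),
          data.table(set = nm, gene_symbol = genes, cohort = lab_b,
                     score = sb))
  }))
  summary <- per_gene[, .(
    n_genes = .N,
    mean = mean(score),
    median = as.numeric(median(score)),
    q1 = as.numeric(quantile(score, 0.25, names = FALSE)),
    q3 = as.numeric(quantile(score, 0.75, names = FALSE))
  ), by = .(set, cohort)]
  out <- list(per_gene = per_gene, summary = summary)
  if (test == "wilcox") {
    out$tests <- per_gene[, {
      x <- score[cohort == lab_a]
      y <- score[cohort == lab_b]
      p <- if (length(x) && length(y))
        suppressWarnings(wilcox.test(x, y)$p.value) else NA_real_
      .(p_value = p, note = "Mann-Whitney U, exploratory extra")
    }, by = set]
  }
  out
}
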