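#' Default interpreter-to-score mapping
#'
#' Turns each interpreter channel's raw verdict into a signed score:
#' positive means pathogenic, negative benign, 0 a variant of uncertain
#' significance (VUS) or an unannotated call. InterVar and ClinVar use
#' the standard five-tier categorical scale; SIFT and CADD are numeric
#' and transformed around their conventional damaging thresholds (SIFT
#' < 0.05 deleterious, CADD phred >= 20 damaging), scaled so pathogenic
#' scores land in roughly (0, 10] per channel. The mapping is a plain
#' list and fully user-overridable ([read_interpreter_mapping()]); every
#' pipeline output records [mapping_hash()] so the transformation in
#' force is always reproducible.
#'
#' @return A named list, one entry per channel. Categorical channels have
#'   `type = "categorical"` and a `map` of verdict -> score; numeric
#'   channels have `type = "numeric"` with `threshold`, `scale` and
#'   `direction` (`"lower_damaging"` or `"higher_damaging"`), mapped as
#'   `scale * (threshold - x) / threshold` (or its mirror image), clamped
#'   to `[-scale, scale]`.
#' @export
#' @examples
#' m <- default_interpreter_mapping()
#' normalize_call("ClinVar", "benign", m)       # -6.2
#' normalize_call("SIFT", 0.01, m)              # deleterious: positive
default_interpreter_mapping <- function() {
  list(
    InterVar = list(
      type = "categorical",
      map = list(pathogenic = 7.8, likely_pathogenic = 3.9,
                 uncertain_significance = 0,
                 likely_benign = -3.9, benign = -7.8)),
    ClinVar = list(
      type = "categorical",
      map = list(pathogenic = 6.2, likely_pathogenic = 3.1,
                 uncertain_significance = 0,
                 likely_benign = -3.1, benign = -6.2)),
    SIFT = list(  # score in [0,1], smaller = more damaging
      type = "numeric", threshold = 0.05, scale = 6.1,
      direction = "lower_damaging"),
    CADD = list(  # phred-scaled, larger = more damaging
      type = "numeric", threshold = 20, scale = 5,
      direction = "higher_damaging")
  )
}

#' Read an interpreter mapping config from YAML
#'
#' @param path YAML file with the structure of
#'   [default_interpreter_mapping()].
#' @return The mapping list, validated.
#' @export
read_interpreter_mapping <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  mapping <- yaml::read_yaml(path)
  validate_mapping(mapping)
}

validate_mapping <- function(mapping) {
  stopifnot(is.list(mapping), !is.null(names(mapping)))
  for (ch in names(mapping)) {
    m <- mapping[[ch]]
    if (is.null(m$type) || !m$type %in% c("categorical", "numeric")) {
      stop("mapping for channel ", ch,
           " must declare type 'categorical' or 'numeric'", call. = FALSE)
    }
    if (m$type == "categorical" && !is.list(m$map)) {
      stop("categorical mapping for ", ch, " needs a 'map' table",
           call. = FALSE)
    }
    if (m$type == "numeric" &&
        (is.null(m$threshold) || is.null(m$scale) ||
         !m$direction %in% c("lower_damaging", "higher_damaging"))) {
      stop("numeric mapping for ", ch,
           " needs threshold, scale and direction", call. = FALSE)
    }
  }
  mapping
}

#' Hash of a mapping config
#'
#' MD5 of the mapping's canonical JSON serialisation; recorded in run
#' manifests so downstream scores are traceable to the exact raw-to-score
#' transformation used.
#'
#' @param mapping A mapping list.
#' @return A character MD5 digest.
#' @export
mapping_hash <- function(mapping) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(mapping, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

canon_category <- function(x) gsub("[ /-]+", "_", tolower(trimws(x)))

#' Normalise one interpreter verdict to a signed score
#'
#' @param channel Channel name (must be present in `mapping`).
#' @param raw_value The channel's raw verdict: a category string for
#'   categorical channels, a number for numeric ones. `NA` or an unknown
#'   category maps to 0 (VUS convention).
#' @param mapping A mapping list; default [default_interpreter_mapping()].
#' @return A signed numeric score (> 0 pathogenic, < 0 benign, 0 VUS).
#' @export
normalize_call <- function(channel, raw_value,
                           mapping = default_interpreter_mapping()) {
  if (!channel %in% names(mapping)) {
    stop("channel '", channel, "' is not defined in the mapping config",
         call. = FALSE)
  }
  m <- mapping[[channel]]
  if (length(raw_value) != 1L || is.na(raw_value)) return(0)
  if (m$type == "categorical") {
    s <- m$map[[canon_category(as.character(raw_value))]]
    return(if (is.null(s)) 0 else as.numeric(s))
  }
  x <- suppressWarnings(as.numeric(raw_value))
  if (is.na(x)) return(0)
  rel <- if (m$direction == "lower_damaging") {
    (m$threshold - x) / m$threshold
  } else {
    (x - m$threshold) / m$threshold
  }
  max(min(rel * m$scale, m$scale), -m$scale)
}

#' Normalise a table of interpreter calls
#'
#' @param calls A data frame with columns `gene_symbol`, `chrom`, `pos`,
#'   `ref`, `alt`, `channel`, `raw_value` (one row per mutation-channel
#'   verdict).
#' @param mapping A mapping list or path to a YAML mapping file.
#' @return The calls as a `data.table` with a `norm_score` column; the
#'   mapping's hash is attached as attribute `mapping_hash`.
#' @export
normalize_calls <- function(calls, mapping = default_interpreter_mapping()) {
  if (is.character(mapping)) mapping <- read_interpreter_mapping(mapping)
  mapping <- validate_mapping(mapping)
  dt <- as.data.table(copy(calls))
  required <- c(mutation_key_cols(), "channel", "raw_value")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("interpreter-call table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(dt$channel), names(mapping))
  if (length(unknown)) {
    stop("channel '", unknown[1L], "' is not defined in the mapping config",
         call. = FALSE)
  }
  dt[, norm_score := vapply(seq_len(.N), function(i)
    normalize_call(channel[i], raw_value[i], mapping), numeric(1))]
  data.table::setattr(dt, "mapping_hash", mapping_hash(mapping))
  dt[]
}

#' Consensus pathogenicity score of one mutation
#'
#' Most-pathogenic-wins: the consensus is the maximum of the channels'
#' signed scores. With verdicts (-7.8, -6.2, 6.1, 5) from four channels
#' the consensus is 6.1.
#'
#' @param norm_scores Numeric vector of 1-4 signed channel scores for a
#'   single mutation.
#' @return The maximum score.
#' @export
#' @examples
#' consensus_mutation_score(c(-7.8, -6.2, 6.1, 5))  # 6.1
consensus_mutation_score <- function(norm_scores) {
  if (!length(norm_scores)) {
    stop("a mutation needs at least one interpreter call", call. = FALSE)
  }
  stopifnot(is.numeric(norm_scores), !anyNA(norm_scores))
  max(norm_scores)
}

#' Consensus scores for all mutations in a call table
#'
#' @param calls Normalised calls from [normalize_calls()].
#' @return A `data.table` with the mutation key columns, `n_channels`
#'   and `consensus`.
#' @export
consensus_scores <- function(calls) {
  dt <- as.data.table(calls)
  if (!"norm_score" %in% names(dt)) {
    stop("calls must be normalised first (see normalize_calls)",
         call. = FALSE)
  }
  key_cols <- mutation_key_cols()
  out <- dt[, .(n_channels = length(unique(channel)),
                consensus = consensus_mutation_score(norm_score)),
            by = key_cols]
  setorder(out, gene_symbol, chrom, pos, ref, alt)
  out[]
}

#' Classify a gene-sample pathogenicity score
#'
#' Bins: `benign` (s < 0), `VUS` (s = 0), `pathogenic_low`
#' (0 < s < 10), `pathogenic_mid` (10 <= s <= 20), `pathogenic_high`
#' (s > 20). The partition is exhaustive and mutually exclusive over the
#' reals.
#'
#' @param s Numeric vector of gene-sample scores.
#' @return Character vector of class labels.
#' @export
classify_pathogenicity <- function(s) {
  stopifnot(is.numeric(s))
  out <- character(length(s))
  out[s < 0] <- "benign"
  out[s == 0] <- "VUS"
  out[s > 0 & s < 10] <- "pathogenic_low"
  out[s >= 10 & s <= 20] <- "pathogenic_mid"
  out[s > 20] <- "pathogenic_high"
  out
}

#' Pathogenicity score of one gene in one sample
#'
#' Aggregates the consensus scores of the gene's mutations in the
#' sample: if any mutation is pathogenic (score > 0) the gene score is
#' the sum of the positive scores; otherwise, if any mutation is a VUS
#' (score 0) the gene score is 0; otherwise all mutations are benign and
#' the gene score is the maximum (least-benign) of the negative scores,
#' keeping it below 0.
#'
#' @param mutation_scores Numeric vector of per-mutation consensus
#'   scores (>= 1 of them).
#' @return A list with `s` (the score) and `klass` (see
#'   [classify_pathogenicity()]).
#' @export
#' @examples
#' gene_sample_score(c(6.1, 5, -2))   # s = 11.1, pathogenic_mid
#' gene_sample_score(c(-7.8, -6.2))   # s = -6.2, benign
gene_sample_score <- function(mutation_scores) {
  if (!length(mutation_scores)) {
    stop("a gene-sample needs at least one mutation score", call. = FALSE)
  }
  stopifnot(is.numeric(mutation_scores), !anyNA(mutation_scores))
  pos_scores <- mutation_scores[mutation_scores > 0]
  s <- if (length(pos_scores)) {
    sum(pos_scores)
  } else if (any(mutation_scores == 0)) {
    0
  } else {
    max(mutation_scores)
  }
  list(s = s, klass = classify_pathogenicity(s))
}

#' Gene-by-sample pathogenicity scores for a cohort
#'
#' Joins a cohort's variant records with per-mutation consensus scores
#' and aggregates per gene and sample with [gene_sample_score()].
#' Mutations with no interpreter call are excluded from scoring and
#' reported via the `unannotated` attribute (a table of their keys).
#'
#' @param variants A (filtered) variant table for the cohort.
#' @param consensus A consensus table from [consensus_scores()], or a
#'   normalised call table (consensus is then computed).
#' @return A `data.table` with `gene_symbol`, `sample_id`, `s`, `klass`,
#'   and `n_mutations` (scored mutations in the gene-sample); attribute
#'   `unannotated` holds mutation keys present in `variants` but absent
#'   from `consensus`.
#' @export
gene_sample_scores <- function(variants, consensus) {
  dt <- validate_variants(variants)
  cons <- as.data.table(copy(consensus))
  if (!"consensus" %in% names(cons)) cons <- consensus_scores(cons)
  dt[, mutation_id := mutation_id(dt)]
  cons[, mutation_id := mutation_id(cons)]
  matched <- match(dt$mutation_id, cons$mutation_id)
  unannotated <- unique(dt[is.na(matched), mutation_key_cols(), with = FALSE])
  scored <- dt[!is.na(matched)]
  scored[, score := cons$consensus[matched[!is.na(matched)]]]
  out <- scored[, {
    gs <- gene_sample_score(score)
    .(s = gs$s, klass = gs$klass, n_mutations = .N)
  }, by = .(gene_symbol, sample_id)]
  setorder(out, gene_symbol, sample_id)
  data.table::setattr(out, "unannotated", unannotated)
  out[]
}

#' Recurrently pathogenic genes and the gene-by-sample class matrix
#'
#' Selects genes scored pathogenic (s > 0) in at least `min_samples`
#' samples of the cohort and returns the full gene-by-sample class
#' matrix for them. When the other cohort's gene-sample scores are
#' supplied, each selected gene's pathogenic-sample count there is
#' reported alongside (the cross-cohort bars under a recurrence matrix).
#'
#' @param scores Gene-sample scores from [gene_sample_scores()].
#' @param min_samples Minimum number of pathogenic samples (default 5).
#' @param other_scores Optional gene-sample scores of the other cohort.
#' @return A list with `genes` (gene_symbol, n_pathogenic, and
#'   `n_pathogenic_other` when supplied, ordered by decreasing count)
#'   and `matrix` (long table gene_symbol, sample_id, s, klass for the
#'   selected genes).
#' @export
recurrent_pathogenic_genes <- function(scores, min_samples = 5L,
                                       other_scores = NULL) {
  stopifnot(min_samples >= 1L)
  dt <- as.data.table(scores)
  counts <- dt[, .(n_pathogenic = sum(s > 0)), by = gene_symbol]
  genes <- counts[n_pathogenic >= min_samples]
  if (!is.null(other_scores)) {
    other <- as.data.table(other_scores)[, .(n = sum(s > 0)), by = gene_symbol]
    genes[, n_pathogenic_other :=
            ifelse(is.na(match(gene_symbol, other$gene_symbol)), 0L,
                   other$n[match(gene_symbol, other$gene_symbol)])]
  }
  setorder(genes, -n_pathogenic, gene_symbol)
  list(genes = genes[],
       matrix = dt[gene_symbol %in% genes$gene_symbol][])
}

#' Recurrently mutated genes with per-sample SNV/indel flags
#'
#' Flags each gene-sample as `SNV`, `indel` or `both` according to the
#' variant classes observed, and returns genes altered in at least
#' `min_samples` samples.
#'
#' @param variants A (filtered) variant table for the cohort.
#' @param min_samples Minimum number of altered samples (default 5).
#' @return A list with `genes` (gene_symbol, n_samples) and `matrix`
#'   (gene_symbol, sample_id, flag) restricted to the selected genes.
#' @export
recurrent_mutated_genes <- function(variants, min_samples = 5L) {
  stopifnot(min_samples >= 1L)
  dt <- validate_variants(variants)
  if (!nrow(dt)) {
    return(list(genes = data.table(gene_symbol = character(),
                                   n_samples = integer()),
                matrix = data.table(gene_symbol = character(),
                                    sample_id = character(),
                                    flag = character())))
  }
  flags <- dt[, {
    has_snv <- any(variant_class == "SNV")
    has_indel <- any(variant_class != "SNV")
    .(flag = if (has_snv && has_indel) "both" else if (has_snv) "SNV"
      else "indel")
  }, by = .(gene_symbol, sample_id)]
  counts <- flags[, .(n_samples = .N), by = gene_symbol]
  genes <- counts[n_samples >= min_samples]
  setorder(genes, -n_samples, gene_symbol)
  list(genes = genes[],
       matrix = flags[gene_symbol %in% genes$gene_symbol][])
}
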