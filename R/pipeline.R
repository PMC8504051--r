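#' Assemble a pipeline run configuration
#'
#' @param variants_a,variants_b Paths to the two cohorts' variant tables.
#' @param interpreter_calls Path to the interpreter-call TSV (mutation
#'   key, channel, raw_value).
#' @param out_dir Output directory for the report bundle.
#' @param gene_sets Optional path to a GMT file for per-set aggregation.
#' @param format Variant input format (`"auto"`, `"tsv"`, `"vcf"`).
#' @param maf_threshold Population-MAF filter cutoff (default 0.01).
#' @param keep_consequences Consequence terms retained by the filter.
#' @param log_base Log base of the accumulation distance term.
#' @param mapping Interpreter mapping: a list, a YAML path, or `NULL`
#'   for [default_interpreter_mapping()].
#' @param min_samples Recurrence threshold in samples (default 5).
#' @param cohort_labels Labels for cohorts A and B.
#' @param drop_both_zero Drop genes with zero score in both cohorts from
#'   the per-set tables.
#' @param seed Optional integer recorded in the manifest (the scoring
#'   itself is deterministic).
#' @return A validated `run_config` list.
#' @export
run_config <- function(variants_a, variants_b, interpreter_calls, out_dir,
                       gene_sets = NULL, format = "auto",
                       maf_threshold = 0.01,
                       keep_consequences = default_keep_consequences(),
                       log_base = "natural", mapping = NULL,
                       min_samples = 5L,
                       cohort_labels = c("cohortA", "cohortB"),
                       drop_both_zero = FALSE, seed = NULL) {
  cfg <- list(variants_a = variants_a, variants_b = variants_b,
              interpreter_calls = interpreter_calls, out_dir = out_dir,
              gene_sets = gene_sets, format = format,
              maf_threshold = maf_threshold,
              keep_consequences = keep_consequences,
              log_base = as.character(log_base), mapping = mapping,
              min_samples = as.integer(min_samples),
              cohort_labels = cohort_labels,
              drop_both_zero = isTRUE(drop_both_zero), seed = seed)
  for (p in c(cfg$variants_a, cfg$variants_b, cfg$interpreter_calls,
              cfg$gene_sets, if (is.character(cfg$mapping)) cfg$mapping)) {
    if (!file.exists(p)) stop("input path does not exist: ", p,
                              call. = FALSE)
  }
  stopifnot(cfg$maf_threshold >= 0, cfg$maf_threshold <= 1,
            cfg$min_samples >= 1L,
            length(cfg$cohort_labels) == 2L,
            cfg$cohort_labels[1] != cfg$cohort_labels[2])
  structure(cfg, class = "run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%OS2"),
                  stage, paste0(...)))
}

#' Run the full two-cohort scoring pipeline
#'
#' Orchestrates filter -> accumulation scoring -> pathogenicity scoring
#' -> recurrence -> gene-set comparison, writing a report bundle under
#' `config$out_dir`: filtered variant tables, per-gene accumulation
#' scores per cohort, the per-set comparison tables, the gene-by-sample
#' pathogenicity class matrix, recurrence lists, count summaries, and a
#' machine-readable `manifest.json` (config echo, mapping hash, output
#' list, stage timings). Identical config and inputs yield identical
#' numeric outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`filtered_a`,
#'   `filtered_b`, `acc_a`, `acc_b`, `set_scores`, `path_a`, `path_b`,
#'   `recurrent_pathogenic`, `recurrent_mutated`, `counts_a`,
#'   `counts_b`, `manifest`) and `paths` of all written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  timings <- list()
  tick <- function(stage, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[stage]] <<- round(as.numeric(Sys.time() - st, units = "secs"), 3)
    stage_log(stage, "done in ", timings[[stage]], "s")
    res
  }
  labs <- config$cohort_labels
  mapping <- if (is.null(config$mapping)) default_interpreter_mapping()
  else if (is.character(config$mapping))
    read_interpreter_mapping(config$mapping)
  else validate_mapping(config$mapping)

  raw_a <- tick("read_a", read_variant_table(config$variants_a, config$format))
  raw_b <- tick("read_b", read_variant_table(config$variants_b, config$format))
  filt_a <- tick("filter_a", filter_variants(raw_a, config$maf_threshold,
                                             config$keep_consequences))
  filt_b <- tick("filter_b", filter_variants(raw_b, config$maf_threshold,
                                             config$keep_consequences))
  samples_a <- sort(unique(raw_a$sample_id))
  samples_b <- sort(unique(raw_b$sample_id))

  acc_a <- tick("acc_score_a", gene_acc_scores(
    filt_a, samples_a, config$log_base, labs[1]))
  acc_b <- tick("acc_score_b", gene_acc_scores(
    filt_b, samples_b, config$log_base, labs[2]))

  calls <- tick("normalize_calls", normalize_calls(
    fread(config$interpreter_calls, sep = "\t",
          na.strings = c(".", "", "NA"),
          colClasses = list(character = "raw_value")), mapping))
  cons <- consensus_scores(calls)
  path_a <- tick("pathogenicity_a", gene_sample_scores(filt_a, cons))
  path_b <- tick("pathogenicity_b", gene_sample_scores(filt_b, cons))
  rec_path <- tick("recurrent_pathogenic", recurrent_pathogenic_genes(
    path_a, config$min_samples, other_scores = path_b))
  rec_mut <- tick("recurrent_mutated", recurrent_mutated_genes(
    filt_a, config$min_samples))

  set_scores <- NULL
  if (!is.null(config$gene_sets)) {
    sets <- read_gene_sets(config$gene_sets)
    set_scores <- tick("score_gene_sets", score_gene_sets(
      acc_a, acc_b, sets, drop_both_zero = config$drop_both_zero))
  }
  counts_a <- summarize_counts(filt_a)
  counts_b <- summarize_counts(filt_b)

  out <- function(name) file.path(config$out_dir, name)
  paths <- c(filtered_a = out("filtered_a.tsv"),
             filtered_b = out("filtered_b.tsv"),
             acc_scores_a = out("gene_acc_scores_a.tsv"),
             acc_scores_b = out("gene_acc_scores_b.tsv"),
             pathogenicity_matrix = out("pathogenicity_matrix.tsv"),
             recurrent_pathogenic = out("recurrent_pathogenic.tsv"),
             recurrent_mutated = out("recurrent_mutated.tsv"),
             count_summary = out("count_summary.tsv"))
  write_variant_table(filt_a, paths["filtered_a"])
  write_variant_table(filt_b, paths["filtered_b"])
  fwrite(acc_a, paths["acc_scores_a"], sep = "\t")
  fwrite(acc_b, paths["acc_scores_b"], sep = "\t")
  fwrite(path_a, paths["pathogenicity_matrix"], sep = "\t")
  fwrite(rec_path$genes, paths["recurrent_pathogenic"], sep = "\t")
  fwrite(rec_mut$genes, paths["recurrent_mutated"], sep = "\t")
  fwrite(rbind(cbind(cohort = labs[1], counts_a$summary),
               cbind(cohort = labs[2], counts_b$summary)),
         paths["count_summary"], sep = "\t")
  if (!is.null(set_scores)) {
    paths <- c(paths, gene_set_scores = out("gene_set_scores.tsv"),
               gene_set_summary = out("gene_set_summary.tsv"))
    fwrite(set_scores$per_gene, paths["gene_set_scores"], sep = "\t")
    fwrite(set_scores$summary, paths["gene_set_summary"], sep = "\t")
  }

  manifest <- list(
    package = "accuscore",
    version = as.character(utils::packageVersion("accuscore")),
    r_version = as.character(getRversion()),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config[c("variants_a", "variants_b", "interpreter_calls",
                      "gene_sets", "format", "maf_threshold",
                      "keep_consequences", "log_base", "min_samples",
                      "cohort_labels", "drop_both_zero")],
    mapping_hash = mapping_hash(mapping),
    n_samples = list(setNames(length(samples_a), labs[1]),
                     setNames(length(samples_b), labs[2])),
    unannotated_mutations = list(
      cohort_a = nrow(attr(path_a, "unannotated")),
      cohort_b = nrow(attr(path_b, "unannotated"))),
    outputs = as.list(paths),
    timings_sec = timings)
  manifest_path <- out("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  paths <- c(paths, manifest = manifest_path)
  stage_log("pipeline", "complete; ", length(paths), " files under ",
            config$out_dir)

  invisible(list(filtered_a = filt_a, filtered_b = filt_b,
                 acc_a = acc_a, acc_b = acc_b, set_scores = set_scores,
                 path_a = path_a, path_b = path_b,
                 recurrent_pathogenic = rec_path,
                 recurrent_mutated = rec_mut,
                 counts_a = counts_a, counts_b = counts_b,
                 manifest = manifest, paths = paths))
}
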