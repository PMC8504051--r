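#' Validate a variant table
#'
#' Checks that a data frame conforms to the variant-record contract: all
#' required columns present, `pos >= 1`, `tumor_af` and `population_maf`
#' in `[0, 1]`, `ref != alt`, and `variant_class` consistent with the
#' ref/alt allele lengths (`SNV` iff both are single bases; longer alt is
#' an `insertion`, longer ref a `deletion`).
#'
#' @param variants A data frame of variant records, one row per
#'   sample-variant pair, with columns `sample_id`, `gene_symbol`,
#'   `chrom`, `pos`, `ref`, `alt`, `variant_class`, `consequence`,
#'   `tumor_af` and optionally `population_maf` (`NA` = unannotated).
#' @return The validated table as a `data.table` (invisibly usable),
#'   with `population_maf` added as `NA` if absent.
#' @export
validate_variants <- function(variants) {
  dt <- as.data.table(copy(variants))
  required <- c("sample_id", "gene_symbol", "chrom", "pos", "ref", "alt",
                "variant_class", "consequence", "tumor_af")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"population_maf" %in% names(dt)) dt[, population_maf := NA_real_]
  dt[, pos := as.integer(pos)]
  dt[, tumor_af := as.numeric(tumor_af)]
  dt[, population_maf := as.numeric(population_maf)]

  fail <- function(rows, what) {
    stop("invalid variant record(s) [row ", paste(head(rows, 5L), collapse = ", "),
         if (length(rows) > 5L) ", ..." else "", "]: ", what, call. = FALSE)
  }
  req_na <- which(!stats::complete.cases(dt[, required, with = FALSE]))
  if (length(req_na)) fail(req_na, "missing value in a required field")
  bad <- which(dt$pos < 1L)
  if (length(bad)) fail(bad, "pos must be >= 1")
  bad <- which(dt$tumor_af < 0 | dt$tumor_af > 1)
  if (length(bad)) fail(bad, "tumor_af outside [0, 1]")
  bad <- which(!is.na(dt$population_maf) &
                 (dt$population_maf < 0 | dt$population_maf > 1))
  if (length(bad)) fail(bad, "population_maf outside [0, 1]")
  bad <- which(dt$ref == dt$alt)
  if (length(bad)) fail(bad, "ref equals alt")
  bad <- which(!dt$variant_class %in% VARIANT_CLASSES)
  if (length(bad)) fail(bad, paste("variant_class not one of",
                                   paste(VARIANT_CLASSES, collapse = "/")))
  bad <- which(!dt$consequence %in% CONSEQUENCES)
  if (length(bad)) fail(bad, paste("consequence not one of",
                                   paste(CONSEQUENCES, collapse = "/")))
  expected <- infer_variant_class(dt$ref, dt$alt)
  bad <- which(dt$variant_class != expected)
  if (length(bad)) fail(bad, "variant_class inconsistent with ref/alt lengths")
  dt[]
}

infer_variant_class <- function(ref, alt) {
  data.table::fifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
                      data.table::fifelse(nchar(alt) > nchar(ref),
                                          "insertion", "deletion"))
}

#' Read a variant table (TSV dialect or annotated VCF)
#'
#' The TSV dialect is UTF-8, tab-separated, with a mandatory header naming
#' the variant-record fields (see [validate_variants()]); `.` or an empty
#' field denotes a missing `population_maf`. The VCF path expects VCF 4.x
#' with per-record annotations in INFO keys `GENE` (gene symbol), `CONSEQ`
#' (consequence term, per alternate allele) and optionally `PMAF`
#' (population minor-allele frequency, per alternate allele), and
#' per-sample FORMAT `AF` (variant allele fraction) or `AD` (allelic
#' depths, from which VAF is derived as alt / (ref + alt)). Multi-allelic
#' sites are split into one record per alternate allele; a sample is
#' included as a carrier of a variant when its VAF is greater than zero.
#'
#' @param path Path to the file.
#' @param format `"tsv"`, `"vcf"`, or `"auto"` (by file extension).
#' @return A validated variant `data.table`, one row per sample-variant
#'   pair (see [validate_variants()] for columns).
#' @seealso [write_variant_table()], [filter_variants()]
#' @export
read_variant_table <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (format == "tsv") read_variant_tsv(path) else read_variant_vcf(path)
}

read_variant_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t",
                     fixed = TRUE)[[1L]]
  required <- c("sample_id", "gene_symbol", "chrom", "pos", "ref", "alt",
                "variant_class", "consequence", "tumor_af")
  if (!all(required %in% header)) {
    stop("malformed TSV '", path, "': header lacks column(s) ",
         paste(setdiff(required, header), collapse = ", "), call. = FALSE)
  }
  dt <- tryCatch(
    fread(path, sep = "\t", header = TRUE, na.strings = c(".", "", "NA"),
          colClasses = list(character = c("sample_id", "gene_symbol",
                                          "chrom", "ref", "alt",
                                          "variant_class", "consequence"))),
    error = function(e) stop("malformed TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  validate_variants(dt)
}

read_variant_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- tryCatch(
    VariantAnnotation::expand(VariantAnnotation::readVcf(path)),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  n_rec <- length(vcf)
  if (n_rec == 0L) {
    return(validate_variants(data.table(
      sample_id = character(), gene_symbol = character(),
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), variant_class = character(),
      consequence = character(), tumor_af = numeric(),
      population_maf = numeric())))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  for (key in c("GENE", "CONSEQ")) {
    if (is.null(info[[key]])) {
      stop("VCF '", path, "' lacks required INFO key ", key, call. = FALSE)
    }
  }
  site <- data.table(
    gene_symbol = as.character(unlist(info$GENE)),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    consequence = as.character(unlist(info$CONSEQ)),
    population_maf = if (is.null(info$PMAF)) NA_real_ else
      as.numeric(unlist(info$PMAF)))
  samples <- colnames(vcf)
  geno <- VariantAnnotation::geno(vcf)
  af_mat <- vcf_af_matrix(geno, n_rec, samples, path)

  out <- rbindlist(lapply(seq_along(samples), function(j) {
    af_j <- af_mat[, j]
    carrier <- !is.na(af_j) & af_j > 0
    if (!any(carrier)) return(NULL)
    cbind(data.table(sample_id = samples[j]), site[carrier],
          data.table(tumor_af = af_j[carrier]))
  }))
  if (!nrow(out)) {
    return(validate_variants(data.table(
      sample_id = character(), gene_symbol = character(),
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), variant_class = character(),
      consequence = character(), tumor_af = numeric(),
      population_maf = numeric())))
  }
  out[, variant_class := infer_variant_class(ref, alt)]
  setcolorder(out, c("sample_id", "gene_symbol", "chrom", "pos", "ref",
                     "alt", "variant_class", "consequence", "tumor_af",
                     "population_maf"))
  validate_variants(out)
}

# per-sample VAF matrix from FORMAT AF, falling back to AD = alt/(ref+alt)
vcf_af_matrix <- function(geno, n_rec, samples, path) {
  if (!is.null(geno$AF)) {
    af <- geno$AF
    if (is.list(af) || is.list(af[1, 1])) {
      af <- matrix(vapply(af, function(x) as.numeric(x)[1L], numeric(1)),
                   nrow = n_rec)
    }
    return(matrix(as.numeric(af), nrow = n_rec,
                  dimnames = list(NULL, samples)))
  }
  if (is.null(geno$AD)) {
    stop("VCF '", path, "' has neither FORMAT AF nor AD; ",
         "VAF cannot be derived", call. = FALSE)
  }
  ad <- geno$AD  # after expand(): ref and alt depth per record
  out <- matrix(NA_real_, nrow = n_rec, ncol = length(samples),
                dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    for (i in seq_len(n_rec)) {
      d <- if (length(dim(ad)) == 3L) ad[i, j, ] else ad[i, j]
      if (is.list(d)) d <- d[[1L]]
      d <- as.numeric(d)
      if (length(d) < 2L || anyNA(d)) {
        stop("VCF '", path, "': VAF underivable from AD for record ", i,
             ", sample ", samples[j], call. = FALSE)
      }
      tot <- d[1L] + d[2L]
      out[i, j] <- if (tot > 0) d[2L] / tot else 0
    }
  }
  out
}

#' Write a variant table in the package's TSV dialect
#'
#' @param variants A variant table (validated on the way out).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  dt <- validate_variants(variants)
  fwrite(dt, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' Filter variants by population frequency and consequence
#'
#' Applies the analysis pre-filter: records whose population minor-allele
#' frequency exceeds `maf_threshold` are removed (likely germline
#' polymorphisms); records with no population annotation are retained.
#' Only the consequences in `keep_consequences` are kept — by default the
#' exonic/splicing protein-changing terms, so synonymous SNVs are removed.
#' The boundary is strict: a record with `population_maf` exactly equal to
#' the threshold is retained. Input order is preserved and the operation
#' is idempotent.
#'
#' @param variants A variant table.
#' @param maf_threshold Population MAF cutoff in `[0, 1]`; default `0.01`
#'   (variants above 1 % population frequency are dropped).
#' @param keep_consequences Consequence terms to retain; default
#'   [default_keep_consequences()].
#' @return The filtered variant `data.table` (possibly empty).
#' @export
#' @examples
#' v <- data.frame(sample_id = "S1", gene_symbol = "TP53", chrom = "17",
#'                 pos = 7675088L, ref = "C", alt = "T",
#'                 variant_class = "SNV", consequence = "missense",
#'                 tumor_af = 0.41, population_maf = 0.02)
#' nrow(filter_variants(v))  # removed: population MAF above 1 %
filter_variants <- function(variants, maf_threshold = 0.01,
                            keep_consequences = default_keep_consequences()) {
  stopifnot(is.numeric(maf_threshold), length(maf_threshold) == 1L,
            maf_threshold >= 0, maf_threshold <= 1)
  if (!length(keep_consequences)) {
    stop("keep_consequences must be non-empty", call. = FALSE)
  }
  dt <- validate_variants(variants)
  keep <- (is.na(dt$population_maf) | dt$population_maf <= maf_threshold) &
    dt$consequence %in% keep_consequences
  dt[keep]
}

#' Read gene sets from a GMT file
#'
#' One set per line: set name, description, then member gene symbols, all
#' tab-separated. Duplicate symbols within a set are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (one per set).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character()))
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("malformed GMT '", path, "' at line ", i,
           ": expected at least 3 tab-separated fields", call. = FALSE)
    }
    genes <- unique(fields[-(1:2)])
    genes[nzchar(genes)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1),
    USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names in '", path, "'", call. = FALSE)
  }
  if (any(!lengths(sets))) {
    stop("empty gene set(s) in '", path, "': ",
         paste(names(sets)[!lengths(sets)], collapse = ", "), call. = FALSE)
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], unique(sets[[i]])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-sample and cohort-level mutation counts
#'
#' Counts SNVs and indels (insertions + deletions) per sample and
#' summarises the cohort: total, median, min and max per-sample count for
#' each class — the summary typically reported alongside a cohort's call
#' set (e.g. total SNVs with per-sample median and range).
#'
#' @param variants A variant table.
#' @return A list with `per_sample` (sample_id, n_snv, n_indel) and
#'   `summary` (class, total, median, min, max); medians are `NA` for an
#'   empty cohort.
#' @export
summarize_counts <- function(variants) {
  dt <- validate_variants(variants)
  if (nrow(dt) == 0L) {
    return(list(
      per_sample = data.table(sample_id = character(), n_snv = integer(),
                              n_indel = integer()),
      summary = data.table(class = c("SNV", "indel"), total = 0L,
                           median = NA_real_, min = NA_integer_,
                           max = NA_integer_)))
  }
  per_sample <- dt[, .(n_snv = sum(variant_class == "SNV"),
                       n_indel = sum(variant_class != "SNV")),
                   by = sample_id]
  setorder(per_sample, sample_id)
  summ <- function(x, cls) data.table(
    class = cls, total = sum(x), median = as.numeric(median(x)),
    min = min(x), max = max(x))
  list(per_sample = per_sample,
       summary = rbind(summ(per_sample$n_snv, "SNV"),
                       summ(per_sample$n_indel, "indel")))
}
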