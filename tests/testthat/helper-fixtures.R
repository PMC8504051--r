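# text fixtures written to tempfiles at test time

write_test_vcf_af <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CONSEQ,Number=A,Type=String,Description="Consequence">',
    '##INFO=<ID=PMAF,Number=A,Type=Float,Description="Population MAF">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Allele fraction">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    paste("chr1\t100\t.\tA\tT\t.\tPASS",
          "GENE=TP53;CONSEQ=missense;PMAF=0.005",
          "GT:AF\t0/1:0.5\t0/0:0", sep = "\t"),
    paste("chr1\t200\t.\tG\tC,T\t.\tPASS",
          "GENE=TP53;CONSEQ=missense,stop_gain;PMAF=0.001,0.02",
          "GT:AF\t0/1:0.25,0\t0/1:0,0.4", sep = "\t"),
    paste("chr2\t300\t.\tT\tTAG\t.\tPASS",
          "GENE=EGFR;CONSEQ=frameshift",
          "GT:AF\t0/1:0.1\t0/0:0", sep = "\t")
  ), path)
  path
}

# the same calls in the TSV dialect (carrier rows only)
write_test_tsv_twin <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    paste("sample_id", "gene_symbol", "chrom", "pos", "ref", "alt",
          "variant_class", "consequence", "tumor_af", "population_maf",
          sep = "\t"),
    "S1\tTP53\tchr1\t100\tA\tT\tSNV\tmissense\t0.5\t0.005",
    "S1\tTP53\tchr1\t200\tG\tC\tSNV\tmissense\t0.25\t0.001",
    "S2\tTP53\tchr1\t200\tG\tT\tSNV\tstop_gain\t0.4\t0.02",
    "S1\tEGFR\tchr2\t300\tT\tTAG\tinsertion\tframeshift\t0.1\t."
  ), path)
  path
}

write_test_vcf_ad <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CONSEQ,Number=A,Type=String,Description="Consequence">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\t.\tA\tT\t.\tPASS\tGENE=KRAS;CONSEQ=missense\tGT:AD\t0/1:6,4\t0/0:10,0"
  ), path)
  path
}

canon_records <- function(dt) {
  d <- as.data.frame(dt)[, c("sample_id", "gene_symbol", "chrom", "pos",
                             "ref", "alt", "variant_class", "consequence",
                             "tumor_af", "population_maf")]
  d <- d[order(d$sample_id, d$chrom, d$pos, d$alt), ]
  rownames(d) <- NULL
  d
}
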