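#!/usr/bin/env Rscript
# Thin shell entry point over strdose::run_pipeline().
#
#   strdose run --config pipeline.yaml
#   strdose run --vcf calls.vcf --pheno pheno.tsv --ped ped.tsv [--out-dir d]

suppressPackageStartupMessages(library(strdose))

args <- commandArgs(trailingOnly = TRUE)
usage <- function() {
  cat("usage: strdose run --config <yaml>\n",
      "       strdose run --vcf <vcf> --pheno <tsv> --ped <tsv>",
      "[--out-dir <dir>]\n")
  quit(status = 2)
}
if (length(args) < 1L || args[1L] != "run") usage()
args <- args[-1L]
opt <- function(flag) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else NULL
}
cfg_path <- opt("--config")
if (!is.null(cfg_path)) {
  run_pipeline(cfg_path)
} else {
  vcf <- opt("--vcf"); pheno <- opt("--pheno"); ped <- opt("--ped")
  if (is.null(vcf) || is.null(pheno) || is.null(ped)) usage()
  out_dir <- opt("--out-dir")
  if (is.null(out_dir)) out_dir <- "strdose_out"
  run_pipeline(pipeline_config(vcf = vcf, pheno = pheno, ped = ped,
                               out_dir = out_dir))
}
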