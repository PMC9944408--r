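#!/usr/bin/env Rscript
# Thin shell wrapper over rileqtl::run_ril_pipeline() for TSV inputs.
#
# Usage:
#   Rscript scripts/run_pipeline.R --snps snps.tsv --counts counts.tsv \
#     --metadata samples.tsv --annotation genes.tsv --out results_dir \
#     [--seed 1] [--bin-size 100] [--n-perm-arch 1000] [--n-perm-eqtl 10] \
#     [--q 0.05] [--p-cut 1e-4] [--no-harmonize]

suppressPackageStartupMessages(library(rileqtl))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, `bin-size` = 100L, `n-perm-arch` = 1000L,
            `n-perm-eqtl` = 10L, q = 0.05, `p-cut` = 1e-4, harmonize = TRUE)
i <- 1
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (key == "no-harmonize") { opt$harmonize <- FALSE; i <- i + 1 }
  else { opt[[key]] <- args[i + 1]; i <- i + 2 }
}
for (req in c("snps", "counts", "metadata", "annotation", "out"))
  if (is.null(opt[[req]])) stop("missing required argument --", req)

snps <- read_snp_table(opt$snps)
em <- read_expr_tsv(opt$counts, opt$metadata, opt$annotation)
res <- run_ril_pipeline(
  snps, em,
  bin_size = as.integer(opt$`bin-size`),
  n_perm_arch = as.integer(opt$`n-perm-arch`),
  n_perm_eqtl = as.integer(opt$`n-perm-eqtl`),
  q = as.numeric(opt$q),
  p_cut = as.numeric(opt$`p-cut`),
  harmonize = isTRUE(opt$harmonize),
  seed = as.integer(opt$seed),
  output_dir = opt$out)
print(res)
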