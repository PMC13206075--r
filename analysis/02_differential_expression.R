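#!/usr/bin/env Rscript
# Stage 2: per-dataset differential expression — low-count filter
# (group-total >= 10 in either group), median-of-ratios normalization,
# moderated log2 fold changes, BH-adjusted Welch tests, DEG calls at
# |log2FC| > 1 and padj < 0.05.

suppressPackageStartupMessages(library(dedtarget))

indir <- "results/01_inputs"
outdir <- "results/02_de"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

count_files <- list.files(indir, pattern = "_counts\\.tsv$")
for (cf in count_files) {
  ds <- sub("_counts\\.tsv$", "", cf)
  dataset <- read_count_dataset(file.path(indir, cf),
                                file.path(indir, paste0(ds, "_groups.tsv")))
  filt <- filter_low_counts(dataset, 10)
  res <- differential_expression(filt)
  write_de_table(res, file.path(outdir, paste0(ds, "_de.tsv")))
  degs <- call_degs(res, lfc_thresh = 1, alpha = 0.05)
  cat(sprintf("%s: %d genes after filter, %d DEGs (%d up, %d down)\n",
              ds, nrow(res), length(degs),
              sum(res$log2FoldChange[match(degs, res$gene)] > 0),
              sum(res$log2FoldChange[match(degs, res$gene)] < 0)))
}
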