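#!/usr/bin/env Rscript
# Stage 6: perturbation concordance — Pearson correlation between each
# candidate knockdown profile and the drug profile on the top 20% most
# drug-altered genes, against a 100-random-gene null with a rank-sum
# test, plus pathway-level AUROC (drug alterations as labels, knockdown
# NES as scores) for two collections x two directions.

suppressPackageStartupMessages(library(dedtarget))

indir <- "results/01_inputs"
outdir <- "results/06_concordance"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

profile_files <- list.files(indir, pattern = "^(drug|KD_).*\\.tsv$",
                            full.names = TRUE)
profiles <- load_profiles(profile_files)
drug <- profiles[["drug"]]
kd_pool <- sub("^KD:", "", grep("^KD:", names(profiles), value = TRUE))
kd_fun <- function(g) profiles[[paste0("KD:", g)]]

truth <- jsonlite::read_json(file.path(indir, "ground_truth.json"))
candidates <- intersect(unlist(truth$true_targets), kd_pool)
eligible <- setdiff(kd_pool, candidates)

report <- concordance_report(NULL, drug, candidates, eligible,
                             n_null = 100, fraction = 0.2, seed = 601,
                             kd_fun = kd_fun)
cat(sprintf("Top 20%% = %d genes; null n = %d (mean PCC %.3f, q95 %.3f)\n",
            report$meta$n_top_genes, length(report$null_pcc),
            mean(report$null_pcc, na.rm = TRUE),
            quantile(report$null_pcc, 0.95, na.rm = TRUE)))
for (g in names(report$candidate_pcc))
  cat(sprintf("  %s: PCC = %.3f\n", g, report$candidate_pcc[[g]]))
cat(sprintf("Rank-sum p (candidates vs null): %.3g\n", report$ranksum_p))

# pathway AUROC over two sub-collections, both directions
collection <- read_gmt(file.path(indir, "gene_sets.gmt"))
grp <- ((seq_along(collection) - 1) %/% 2) %% 2
collections <- list(GO_like = collection[grp == 0],
                    KEGG_like = collection[grp == 1])
rows <- list()
for (cname in names(collections)) {
  coll <- collections[[cname]]
  drug_g <- preranked_gsea(rank_profile(drug), coll, n_perm = 500,
                           seed = 611)
  for (g in candidates) {
    kd_g <- preranked_gsea(rank_profile(kd_fun(g)), coll, n_perm = 500,
                           seed = 613)
    for (dir in c("up", "down")) {
      a <- suppressWarnings(pathway_auroc(drug_g, kd_g, dir,
                                          alpha = 0.05))
      rows[[paste(cname, g, dir)]] <- data.frame(
        collection = cname, direction = dir, candidate = g,
        auroc = a$auroc, n_pos = a$n_pos, n_neg = a$n_neg,
        stringsAsFactors = FALSE)
      cat(sprintf("AUROC [%s, %s, %s]: %.3f (%d pos / %d neg)\n",
                  cname, g, dir, a$auroc, a$n_pos, a$n_neg))
    }
  }
}
auroc_table <- do.call(rbind, rows)
write_concordance_report(report, outdir, auroc_table)
cat(sprintf("Report written under %s\n", outdir))
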