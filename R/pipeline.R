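#' Rank a perturbation profile for enrichment analysis
#'
#' Turns a genome-wide log2FC profile into a [rank_genes()]-style ranked
#' list (descending log2FC, ties by gene identifier).
#'
#' @param profile named log2FC vector.
#' @return A `ranked_gene_list`.
#' @export
rank_profile <- function(profile) {
  rank_genes(data.frame(gene = names(profile),
                        log2FoldChange = as.numeric(profile),
                        stringsAsFactors = FALSE))
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: the simulator
#' settings (when inputs are synthetic), the file paths (when inputs are
#' external), the thresholds of each stage, the stage toggles, and one
#' global seed from which per-stage child seeds are derived
#' deterministically (so toggling a stage does not shift the randomness
#' of later stages).
#'
#' @param sim a [simulation_config()] used when `counts_paths` is NULL.
#' @param counts_paths,groups_paths optional external count/group TSVs
#'   (parallel vectors, one per dataset).
#' @param gmt_path optional external GMT collection.
#' @param target_list_path optional predicted drug-target list.
#' @param docking_table_path optional docking-affinity TSV.
#' @param outdir output directory.
#' @param min_count low-count filter threshold (default 10).
#' @param lfc DEG |log2FC| threshold (default 1).
#' @param alpha significance threshold for DEGs and enrichment (default
#'   0.05).
#' @param consensus_frac minimum supporting dataset fraction (default
#'   0.5).
#' @param core_freq strict core-gene frequency threshold (default 0.5).
#' @param affinity strict docking-affinity threshold in kcal/mol
#'   (default -6.5).
#' @param top_fraction top-altered fraction for concordance (default
#'   0.2).
#' @param n_null random-gene null size (default 100).
#' @param n_perm GSEA permutations (default 1000).
#' @param seed global seed.
#' @param stages character vector of stages to run (subset of the
#'   default).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            counts_paths = NULL, groups_paths = NULL,
                            gmt_path = NULL, target_list_path = NULL,
                            docking_table_path = NULL,
                            outdir = tempfile("dedtarget_run_"),
                            min_count = 10, lfc = 1, alpha = 0.05,
                            consensus_frac = 0.5, core_freq = 0.5,
                            affinity = -6.5, top_fraction = 0.2,
                            n_null = 100, n_perm = 1000, seed = 1L,
                            stages = c("simulate", "de", "gsea",
                                       "consensus", "intersect",
                                       "affinity", "perturb",
                                       "validate")) {
  stopifnot(all(stages %in% c("simulate", "de", "gsea", "consensus",
                              "intersect", "affinity", "perturb",
                              "validate")))
  check_scalar(alpha, "alpha", positive = TRUE)
  if (alpha >= 1) stop_field("alpha", "must be < 1")
  check_scalar(top_fraction, "top_fraction", positive = TRUE)
  if (top_fraction > 1) stop_field("top_fraction", "must be <= 1")
  structure(list(sim = sim, counts_paths = counts_paths,
                 groups_paths = groups_paths, gmt_path = gmt_path,
                 target_list_path = target_list_path,
                 docking_table_path = docking_table_path,
                 outdir = outdir,
                 thresholds = list(min_count = min_count, lfc = lfc,
                                   alpha = alpha,
                                   consensus_frac = consensus_frac,
                                   core_freq = core_freq,
                                   affinity = affinity,
                                   top_fraction = top_fraction,
                                   n_null = n_null, n_perm = n_perm),
                 seed = as.integer(seed), stages = stages),
            class = "pipeline_config")
}

#' Run the end-to-end target-discovery pipeline
#'
#' Stages: simulate (or load) the K count datasets and gene sets;
#' per-dataset differential expression and pre-ranked enrichment;
#' cross-dataset consensus pathways and core leading-edge genes;
#' intersection with the predicted drug-target list; docking-affinity
#' triage; knockdown/drug perturbation profiles; and concordance
#' validation (top-fraction PCC vs a random-gene null with rank-sum
#' test, plus pathway AUROC per direction). Every output table is
#' written under `config$outdir` and hashed into the run manifest, so a
#' rerun with the same config and seed reproduces identical hashes.
#'
#' @param config a [pipeline_config()].
#' @return The run manifest (list), invisibly written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = list(thresholds = th, seed = config$seed,
                                 stages = config$stages),
                   stages = list())
  outputs <- character(0)

  ## ---- inputs ----------------------------------------------------------
  truth <- NULL; profiles <- NULL
  if ("simulate" %in% config$stages || is.null(config$counts_paths)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- child_seed(config$seed, "simulate")
    sim <- simulate_study(sim_cfg)
    datasets <- sim$datasets
    collection <- sim$gene_sets
    truth <- sim$truth
    profiles <- sim$profiles
    sim_dir <- file.path(outdir, "inputs")
    dir.create(sim_dir, showWarnings = FALSE)
    for (ds in names(datasets))
      write_count_dataset(datasets[[ds]],
                          file.path(sim_dir, paste0(ds, "_counts.tsv")),
                          file.path(sim_dir, paste0(ds, "_groups.tsv")))
    write_gmt(collection, file.path(sim_dir, "gene_sets.gmt"))
    outputs <- c(outputs, list.files(sim_dir, full.names = TRUE))
    manifest$stages$simulate <- list(n_datasets = length(datasets),
                                     n_genes = sim_cfg$n_genes,
                                     true_targets = truth$true_targets)
  } else {
    datasets <- mapply(read_count_dataset, config$counts_paths,
                       config$groups_paths, SIMPLIFY = FALSE)
    names(datasets) <- sprintf("DS%02d", seq_along(datasets))
    collection <- read_gmt(config$gmt_path)
  }

  ## ---- differential expression ----------------------------------------
  ranked <- list(); de_tables <- list()
  if ("de" %in% config$stages) {
    de_dir <- file.path(outdir, "de")
    dir.create(de_dir, showWarnings = FALSE)
    for (ds in names(datasets)) {
      filt <- filter_low_counts(datasets[[ds]], th$min_count)
      res <- differential_expression(filt)
      de_tables[[ds]] <- res
      ranked[[ds]] <- rank_genes(res)
      write_de_table(res, file.path(de_dir, paste0(ds, "_de.tsv")))
    }
    outputs <- c(outputs, list.files(de_dir, full.names = TRUE))
    manifest$stages$de <- list(
      n_deg = vapply(de_tables, function(r)
        length(call_degs(r, th$lfc, th$alpha)), integer(1)))
  }

  ## ---- enrichment ------------------------------------------------------
  gsea <- list()
  if ("gsea" %in% config$stages && length(ranked)) {
    gsea_dir <- file.path(outdir, "gsea")
    dir.create(gsea_dir, showWarnings = FALSE)
    for (ds in names(ranked)) {
      gsea[[ds]] <- preranked_gsea(ranked[[ds]], collection,
                                   n_perm = th$n_perm,
                                   seed = child_seed(config$seed,
                                                     paste0("gsea_", ds)))
      write_tsv(gsea[[ds]], file.path(gsea_dir, paste0(ds, "_gsea.tsv")))
    }
    outputs <- c(outputs, list.files(gsea_dir, full.names = TRUE))
    manifest$stages$gsea <- list(
      n_significant = vapply(gsea, function(g)
        sum(g$pval < th$alpha), integer(1)))
  }

  ## ---- consensus -------------------------------------------------------
  core <- character(0); consensus <- NULL
  if ("consensus" %in% config$stages && length(gsea) >= 2) {
    consensus <- consensus_pathways(gsea, alpha = th$alpha,
                                    min_frac = th$consensus_frac)
    write_tsv(consensus, file.path(outdir, "consensus_pathways.tsv"))
    if (nrow(consensus) > 0) {
      freq <- leading_edge_frequency(consensus, gsea)
      write_tsv(freq, file.path(outdir, "core_gene_frequency.tsv"))
      core <- core_leading_edge_genes(freq, th$core_freq)
      outputs <- c(outputs, file.path(outdir, "core_gene_frequency.tsv"))
    }
    outputs <- c(outputs, file.path(outdir, "consensus_pathways.tsv"))
    manifest$stages$consensus <- list(n_pathways = nrow(consensus),
                                      n_core_genes = length(core))
  }

  ## ---- target intersection --------------------------------------------
  key_genes <- character(0)
  if ("intersect" %in% config$stages) {
    if (!is.null(config$target_list_path)) {
      targets <- read_target_list(config$target_list_path)
    } else if (!is.null(truth)) {
      # synthetic predicted-target list: true targets plus random genes
      pool <- setdiff(rownames(datasets[[1]]$counts), truth$true_targets)
      targets <- with_seed(child_seed(config$seed, "targets"),
                           c(truth$true_targets, sample(pool, 30)))
    } else targets <- character(0)
    key_genes <- intersect_targets(harmonize_symbols(targets),
                                   harmonize_symbols(core))
    writeLines(key_genes, file.path(outdir, "key_genes.txt"))
    outputs <- c(outputs, file.path(outdir, "key_genes.txt"))
    manifest$stages$intersect <- list(n_targets = length(targets),
                                      n_key_genes = length(key_genes),
                                      key_genes = key_genes)
  }

  ## ---- affinity triage -------------------------------------------------
  if ("affinity" %in% config$stages &&
      !is.null(config$docking_table_path)) {
    dock <- read_docking_table(config$docking_table_path)
    prioritized <- filter_by_affinity(dock, th$affinity)
    write_tsv(prioritized, file.path(outdir, "prioritized_targets.tsv"))
    outputs <- c(outputs, file.path(outdir, "prioritized_targets.tsv"))
    manifest$stages$affinity <- list(n_docked = nrow(dock),
                                     n_prioritized = nrow(prioritized),
                                     prioritized = prioritized$target)
  }

  ## ---- perturbation + concordance -------------------------------------
  if ("perturb" %in% config$stages && "validate" %in% config$stages) {
    if (!is.null(profiles)) {
      drug <- profiles[["drug"]]
      kd_fun <- function(g) profiles[[paste0("KD:", g)]]
      kd_pool <- sub("^KD:", "",
                     grep("^KD:", names(profiles), value = TRUE))
      model <- NULL
    } else {
      model <- fit_reference_model(datasets)
      stop("external drug profiles must be supplied via load_profiles()",
           call. = FALSE)
    }
    candidates <- if (length(key_genes)) intersect(key_genes, kd_pool)
                  else intersect(truth$true_targets, kd_pool)
    eligible <- setdiff(kd_pool, candidates)
    report <- concordance_report(model, drug, candidates, eligible,
                                 n_null = min(th$n_null, length(eligible)),
                                 fraction = th$top_fraction,
                                 seed = child_seed(config$seed, "null"),
                                 kd_fun = kd_fun)
    auroc_rows <- list()
    drug_gsea <- preranked_gsea(rank_profile(drug), collection,
                                n_perm = th$n_perm,
                                seed = child_seed(config$seed, "gsea_drug"))
    for (g in candidates) {
      kd_gsea <- preranked_gsea(rank_profile(kd_fun(g)), collection,
                                n_perm = th$n_perm,
                                seed = child_seed(config$seed,
                                                  paste0("gsea_kd_", g)))
      for (dir in c("up", "down")) {
        a <- suppressWarnings(pathway_auroc(drug_gsea, kd_gsea, dir,
                                            th$alpha))
        auroc_rows[[paste(g, dir)]] <-
          data.frame(collection = "sets", direction = dir, candidate = g,
                     auroc = a$auroc, n_pos = a$n_pos, n_neg = a$n_neg,
                     stringsAsFactors = FALSE)
      }
    }
    auroc_table <- do.call(rbind, auroc_rows)
    write_concordance_report(report, file.path(outdir, "concordance"),
                             auroc_table)
    outputs <- c(outputs,
                 list.files(file.path(outdir, "concordance"),
                            full.names = TRUE))
    manifest$stages$validate <- list(
      candidates = candidates,
      candidate_pcc = as.list(report$candidate_pcc),
      ranksum_p = report$ranksum_p,
      null_mean = mean(report$null_pcc, na.rm = TRUE))
  }

  ## ---- manifest --------------------------------------------------------
  hashes <- tools::md5sum(sort(outputs))
  manifest$hashes <- stats::setNames(as.character(hashes),
                                     sub(paste0("^", outdir, "/?"), "",
                                         names(hashes)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Render a human-readable run report
#'
#' Markdown summary of a pipeline run: thresholds echoed, consensus
#' pathways, core genes, key-gene intersection, prioritized docking
#' targets, and concordance statistics. Stages without outputs are
#' marked "not run".
#'
#' @param manifest the list returned by [run_pipeline()].
#' @param path output markdown path.
#' @return The path, invisibly.
#' @export
write_report <- function(manifest, path) {
  th <- manifest$config$thresholds
  lines <- c(
    "# Target-discovery run report", "",
    sprintf("Seed: %s", manifest$config$seed),
    sprintf(paste("Thresholds: min_count=%s, |log2FC|>%s, alpha=%s,",
                  "consensus_frac=%s, core_freq=%s, affinity<%s kcal/mol,",
                  "top_fraction=%s, n_null=%s, n_perm=%s"),
            th$min_count, th$lfc, th$alpha, th$consensus_frac,
            th$core_freq, th$affinity, th$top_fraction, th$n_null,
            th$n_perm),
    "")
  sec <- function(name, body) c(sprintf("## %s", name), "", body, "")
  st <- manifest$stages
  lines <- c(lines, sec("Datasets",
    if (is.null(st$simulate)) "not run"
    else sprintf("%d synthetic datasets over %d genes (true targets: %s)",
                 st$simulate$n_datasets, st$simulate$n_genes,
                 paste(st$simulate$true_targets, collapse = ", "))))
  lines <- c(lines, sec("Differential expression",
    if (is.null(st$de)) "not run"
    else sprintf("DEGs per dataset: %s",
                 paste(sprintf("%s=%d", names(st$de$n_deg), st$de$n_deg),
                       collapse = ", "))))
  lines <- c(lines, sec("Consensus pathways",
    if (is.null(st$consensus)) "not run"
    else if (st$consensus$n_pathways == 0) "zero consensus pathways"
    else sprintf("%d consensus pathways; %d core leading-edge genes",
                 st$consensus$n_pathways, st$consensus$n_core_genes)))
  lines <- c(lines, sec("Key genes",
    if (is.null(st$intersect)) "not run"
    else sprintf("%d predicted targets intersected to %d key genes: %s",
                 st$intersect$n_targets, st$intersect$n_key_genes,
                 paste(st$intersect$key_genes, collapse = ", "))))
  lines <- c(lines, sec("Prioritized docking targets",
    if (is.null(st$affinity)) "not run"
    else sprintf("%d of %d docked targets below threshold: %s",
                 st$affinity$n_prioritized, st$affinity$n_docked,
                 paste(st$affinity$prioritized, collapse = ", "))))
  lines <- c(lines, sec("Concordance validation",
    if (is.null(st$validate)) "not run"
    else c(sprintf("candidates: %s",
                   paste(st$validate$candidates, collapse = ", ")),
           sprintf("candidate PCC: %s",
                   paste(sprintf("%s=%.3f", names(st$validate$candidate_pcc),
                                 unlist(st$validate$candidate_pcc)),
                         collapse = ", ")),
           sprintf("rank-sum p vs %s-gene null: %.3g (null mean %.3f)",
                   th$n_null, st$validate$ranksum_p,
                   st$validate$null_mean))))
  writeLines(lines, path)
  invisible(path)
}
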