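#' Configuration for the multi-dataset transcriptomic simulator
#'
#' Defines the study conditions emulated by the generator: `n_datasets`
#' independent negative-binomial count datasets (default 7, mirroring an
#' integration of seven disease-model studies) that share planted pathway
#' signals, a gene-set collection in which `n_active_sets` sets carry a
#' planted differential-expression signal of size `de_log2fc` in exactly
#' `consensus_support` of the datasets, and perturbation profiles in which
#' the drug profile is the mean of the true targets' knockdown profiles
#' plus Gaussian noise.
#'
#' @param n_datasets number of independent count datasets (K).
#' @param n_genes size of the gene universe.
#' @param n_samples_per_group samples per group (control/treatment) in each
#'   dataset.
#' @param nb_dispersion negative-binomial dispersion (gamma-Poisson; the
#'   `size` parameter is `1/nb_dispersion`).
#' @param baseline_log_mean_range range (log2 scale) from which per-gene
#'   baseline mean expression is drawn uniformly.
#' @param n_gene_sets number of gene sets in the simulated collection.
#' @param set_size_range inclusive range of gene-set sizes.
#' @param n_active_sets number of sets carrying a planted signal.
#' @param consensus_support number of datasets (out of `n_datasets`) in
#'   which each planted set's signal is present.
#' @param de_log2fc planted log2 fold change for member genes of active
#'   sets (sign set per-set by the planted direction).
#' @param true_targets gene identifiers acting as the drug's true targets;
#'   `NULL` picks the first two members of the first active set.
#' @param kd_primary_log2fc log2 fold change applied to the knocked-down
#'   gene itself in simulated knockdown profiles.
#' @param drug_noise_sd standard deviation of the per-gene Gaussian noise
#'   added when combining target knockdown profiles into the drug profile.
#' @param n_decoys number of decoy genes receiving independent knockdown
#'   profiles (the random-gene null pool).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_datasets = 7L,
                              n_genes = 2000L,
                              n_samples_per_group = 6L,
                              nb_dispersion = 0.1,
                              baseline_log_mean_range = c(3, 9),
                              n_gene_sets = 50L,
                              set_size_range = c(10L, 40L),
                              n_active_sets = 10L,
                              consensus_support = 5L,
                              de_log2fc = 2,
                              true_targets = NULL,
                              kd_primary_log2fc = -2,
                              drug_noise_sd = 0.2,
                              n_decoys = 150L,
                              seed = 1L) {
  check_scalar(n_datasets, "n_datasets", positive = TRUE, integer = TRUE)
  check_scalar(n_genes, "n_genes", positive = TRUE, integer = TRUE)
  check_scalar(n_samples_per_group, "n_samples_per_group",
               positive = TRUE, integer = TRUE)
  check_scalar(nb_dispersion, "nb_dispersion", positive = TRUE)
  if (!is.numeric(baseline_log_mean_range) ||
      length(baseline_log_mean_range) != 2L ||
      diff(baseline_log_mean_range) < 0)
    stop_field("baseline_log_mean_range", "must be an increasing pair")
  check_scalar(n_gene_sets, "n_gene_sets", positive = TRUE, integer = TRUE)
  if (!is.numeric(set_size_range) || length(set_size_range) != 2L ||
      set_size_range[1] < 2 || set_size_range[2] > n_genes ||
      set_size_range[1] > set_size_range[2])
    stop_field("set_size_range", "must lie within [2, n_genes]")
  check_scalar(n_active_sets, "n_active_sets", integer = TRUE, nonneg = TRUE)
  if (n_active_sets > n_gene_sets)
    stop_field("n_active_sets", "must be <= n_gene_sets")
  check_scalar(consensus_support, "consensus_support",
               positive = TRUE, integer = TRUE)
  if (consensus_support > n_datasets)
    stop_field("consensus_support", "must be <= n_datasets")
  check_scalar(de_log2fc, "de_log2fc")
  check_scalar(kd_primary_log2fc, "kd_primary_log2fc")
  check_scalar(drug_noise_sd, "drug_noise_sd", nonneg = TRUE)
  check_scalar(n_decoys, "n_decoys", positive = TRUE, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  universe <- gene_ids(n_genes)
  if (!is.null(true_targets)) {
    true_targets <- as.character(true_targets)
    if (!all(true_targets %in% universe))
      stop_field("true_targets", "all targets must exist in the gene universe")
  }
  structure(list(
    n_datasets = as.integer(n_datasets),
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    nb_dispersion = nb_dispersion,
    baseline_log_mean_range = baseline_log_mean_range,
    n_gene_sets = as.integer(n_gene_sets),
    set_size_range = as.integer(set_size_range),
    n_active_sets = as.integer(n_active_sets),
    consensus_support = as.integer(consensus_support),
    de_log2fc = de_log2fc,
    true_targets = true_targets,
    kd_primary_log2fc = kd_primary_log2fc,
    drug_noise_sd = drug_noise_sd,
    n_decoys = as.integer(n_decoys),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

gene_ids <- function(n) sprintf("G%06d", seq_len(n))

#' Simulate a full synthetic study
#'
#' Joint generator behind [generate_counts()], [generate_gene_sets()] and
#' [generate_perturbation_profiles()]: one call draws the gene-set
#' collection, plants the consensus differential-expression signal in
#' `consensus_support` datasets per active set, simulates negative-binomial
#' counts with log-uniform size factors in [0.5, 2], and builds knockdown
#' and drug perturbation profiles. All three public generators re-run this
#' function from the config seed, so their outputs are mutually consistent
#' and deterministic.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `datasets` (list of [count_dataset()]),
#'   `gene_sets` (named list of member vectors), `profiles` (named list of
#'   log2FC vectors: `"drug"`, `"KD:<gene>"`), and `truth` (ground-truth
#'   record of every planted value).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    genes <- gene_ids(config$n_genes)
    K <- config$n_datasets

    ## --- gene sets ------------------------------------------------------
    sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                    config$n_gene_sets, replace = TRUE)
    set_names <- sprintf("SET%03d", seq_len(config$n_gene_sets))
    active_idx <- seq_len(config$n_active_sets)
    gene_sets <- vector("list", config$n_gene_sets)
    names(gene_sets) <- set_names
    # active sets get disjoint members so planted directions never clash
    pool <- sample(genes)
    used <- 0L
    directions <- rep_len(c("up", "down"), config$n_active_sets)
    support_sets <- vector("list", config$n_active_sets)
    for (i in active_idx) {
      gene_sets[[i]] <- sort(pool[used + seq_len(sizes[i])])
      used <- used + sizes[i]
      support_sets[[i]] <- sort(sample.int(K, config$consensus_support))
    }
    for (i in setdiff(seq_len(config$n_gene_sets), active_idx))
      gene_sets[[i]] <- sort(sample(genes, sizes[i]))

    ## --- planted per-dataset DE truth -----------------------------------
    de_genes <- replicate(K, numeric(0), simplify = FALSE)
    for (i in active_idx) {
      lfc <- config$de_log2fc * if (directions[i] == "up") 1 else -1
      for (d in support_sets[[i]]) {
        v <- rep(lfc, length(gene_sets[[i]]))
        names(v) <- gene_sets[[i]]
        de_genes[[d]] <- c(de_genes[[d]], v)
      }
    }

    ## --- counts ---------------------------------------------------------
    n <- config$n_samples_per_group
    datasets <- vector("list", K)
    names(datasets) <- sprintf("DS%02d", seq_len(K))
    size_factors_truth <- vector("list", K)
    for (d in seq_len(K)) {
      base_log2 <- stats::runif(config$n_genes,
                                config$baseline_log_mean_range[1],
                                config$baseline_log_mean_range[2])
      sf <- 2^stats::runif(2L * n, -1, 1)         # log-uniform in [0.5, 2]
      lfc <- rep(0, config$n_genes)
      names(lfc) <- genes
      if (length(de_genes[[d]])) lfc[names(de_genes[[d]])] <- de_genes[[d]]
      mu <- outer(2^base_log2, sf)                # genes x samples
      trt_cols <- n + seq_len(n)
      mu[, trt_cols] <- mu[, trt_cols] * 2^lfc
      counts <- matrix(
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
        nrow = config$n_genes,
        dimnames = list(genes, c(sprintf("ctl_%02d", seq_len(n)),
                                 sprintf("trt_%02d", seq_len(n)))))
      groups <- factor(rep(c("control", "treatment"), each = n),
                       levels = c("control", "treatment"))
      names(groups) <- colnames(counts)
      datasets[[d]] <- count_dataset(counts, groups)
      size_factors_truth[[d]] <- stats::setNames(sf, colnames(counts))
    }

    ## --- perturbation profiles ------------------------------------------
    targets <- config$true_targets
    if (is.null(targets)) {
      targets <- if (config$n_active_sets > 0)
        gene_sets[[1]][1:2] else genes[1:2]
    }
    dir_sign <- ifelse(directions == "up", 1, -1)
    make_kd <- function(g, coherent) {
      v <- rep(0, config$n_genes)
      names(v) <- genes
      hit <- stats::runif(config$n_genes) < 0.2   # sparse downstream response
      v[hit] <- stats::rnorm(sum(hit), 0, 0.8)
      if (coherent && config$n_active_sets > 0) {
        # pathway-coherent response: true-target knockdowns counteract the
        # planted disease direction of every active set; decoy knockdowns
        # have only diffuse, pathway-incoherent effects
        coeffs <- -dir_sign * abs(stats::rnorm(config$n_active_sets, 1, 0.3))
        for (i in seq_along(active_idx)) {
          s <- gene_sets[[active_idx[i]]]
          v[s] <- v[s] + coeffs[i]
        }
      }
      v[g] <- config$kd_primary_log2fc
      v
    }
    true_kd <- lapply(targets, make_kd, coherent = TRUE)
    names(true_kd) <- targets
    drug <- Reduce(`+`, true_kd) / length(true_kd) +
      stats::rnorm(config$n_genes, 0, config$drug_noise_sd)
    names(drug) <- genes
    decoy_pool <- setdiff(genes, targets)
    decoys <- sort(sample(decoy_pool, min(config$n_decoys,
                                          length(decoy_pool))))
    decoy_kd <- lapply(decoys, make_kd, coherent = FALSE)
    names(decoy_kd) <- decoys

    profiles <- c(list(drug = drug),
                  stats::setNames(true_kd, paste0("KD:", targets)),
                  stats::setNames(decoy_kd, paste0("KD:", decoys)))

    truth <- list(
      active_sets = data.frame(
        set = set_names[active_idx],
        direction = directions[seq_along(active_idx)],
        datasets = vapply(support_sets, function(s)
          paste(names(datasets)[s], collapse = ";"), character(1)),
        stringsAsFactors = FALSE),
      de_genes = stats::setNames(de_genes, names(datasets)),
      size_factors = stats::setNames(size_factors_truth, names(datasets)),
      true_targets = targets,
      decoy_genes = decoys,
      true_kd_profiles = true_kd,
      drug_profile_truth = drug
    )
    list(datasets = datasets, gene_sets = gene_sets,
         profiles = profiles, truth = truth)
  })
}

#' Generate synthetic count datasets with planted consensus signal
#'
#' @param config a [simulation_config()].
#' @return List with `datasets` (list of [count_dataset()]) and `truth`
#'   (the planted ground truth).
#' @export
generate_counts <- function(config) {
  sim <- simulate_study(config)
  list(datasets = sim$datasets, truth = sim$truth)
}

#' Generate the synthetic gene-set collection
#'
#' Active sets are composed of the planted differentially expressed genes;
#' the rest are drawn at random from the universe. Serializable with
#' [write_gmt()].
#'
#' @param config a [simulation_config()].
#' @return Named list of member-gene character vectors.
#' @export
generate_gene_sets <- function(config) {
  simulate_study(config)$gene_sets
}

#' Generate knockdown and drug perturbation profiles
#'
#' The `"drug"` profile is the arithmetic mean of the true targets'
#' knockdown profiles plus per-gene Gaussian noise with sd
#' `drug_noise_sd`; one independent `"KD:<gene>"` profile is produced per
#' true target and per decoy gene.
#'
#' @param config a [simulation_config()].
#' @param ground_truth optional truth record from [generate_counts()];
#'   used only for consistency checking.
#' @return Named list of log2 fold-change vectors over the gene universe.
#' @export
generate_perturbation_profiles <- function(config, ground_truth = NULL) {
  sim <- simulate_study(config)
  if (!is.null(ground_truth) &&
      !identical(ground_truth$true_targets, sim$truth$true_targets))
    stop("ground_truth does not match this configuration", call. = FALSE)
  sim$profiles
}

#' Write a count dataset as TSV plus a group-label sidecar
#'
#' @param dataset a [count_dataset()].
#' @param counts_path output path for the gene x sample count TSV.
#' @param groups_path output path for the two-column (sample, group) TSV.
#' @export
write_count_dataset <- function(dataset, counts_path, groups_path) {
  stopifnot(inherits(dataset, "count_dataset"))
  df <- data.frame(gene = rownames(dataset$counts), dataset$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(data.frame(sample = names(dataset$groups),
                       group = as.character(dataset$groups),
                       stringsAsFactors = FALSE), groups_path)
  invisible(counts_path)
}

#' Read a count dataset written by [write_count_dataset()]
#'
#' @param counts_path path to the count TSV (first column `gene`).
#' @param groups_path path to the sample/group sidecar TSV.
#' @return A [count_dataset()].
#' @export
read_count_dataset <- function(counts_path, groups_path) {
  df <- read_tsv(counts_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "integer"
  g <- read_tsv(groups_path)
  groups <- factor(g$group, levels = c("control", "treatment"))
  names(groups) <- g$sample
  count_dataset(m, groups[colnames(m)])
}

#' Serialize the ground-truth record to JSON
#'
#' @param truth truth record from [generate_counts()].
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  out$de_genes <- lapply(out$de_genes, as.list)
  out$true_kd_profiles <- lapply(out$true_kd_profiles, as.list)
  out$drug_profile_truth <- as.list(out$drug_profile_truth)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
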