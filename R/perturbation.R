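#' Fit the baseline co-expression model for knockdown simulation
#'
#' A deliberately simple surrogate perturbation engine: per-dataset
#' Pearson correlations of log2(normalized + 1) expression between genes
#' are averaged across datasets, shrunk toward zero by the factor
#' `(1 - shrinkage)`, and hard-thresholded at `sparsity` so weak
#' associations do not propagate. Self-weights are 1. Any richer engine
#' can replace it via [load_profiles()].
#'
#' @param baselines list of [count_dataset()] objects sharing one gene
#'   universe (the baseline expression matrices).
#' @param shrinkage shrinkage intensity in `[0, 1]` (default 0.5).
#' @param sparsity absolute-weight threshold below which associations
#'   are zeroed (default 0.2).
#' @return Object of class `coexpression_model`: list with `genes`, the
#'   weight matrix `W`, and the two tuning parameters.
#' @export
fit_reference_model <- function(baselines, shrinkage = 0.5, sparsity = 0.2) {
  if (inherits(baselines, "count_dataset")) baselines <- list(baselines)
  stopifnot(length(baselines) >= 1)
  genes <- rownames(baselines[[1]]$counts)
  for (b in baselines) {
    stopifnot(inherits(b, "count_dataset"))
    if (!identical(rownames(b$counts), genes))
      stop("baseline datasets must share one gene universe", call. = FALSE)
  }
  n_total <- sum(vapply(baselines, function(b) ncol(b$counts), integer(1)))
  if (n_total < 4)
    stop("need >= 4 total samples; correlation is unstable below that",
         call. = FALSE)
  if (shrinkage < 0 || shrinkage > 1)
    stop_field("shrinkage", "must lie in [0, 1]")
  acc <- matrix(0, length(genes), length(genes))
  for (b in baselines) {
    sf <- estimate_size_factors(b)
    logn <- log2(sweep(b$counts, 2, sf, "/") + 1)
    C <- suppressWarnings(stats::cor(t(logn)))
    C[!is.finite(C)] <- 0             # zero-variance genes contribute nothing
    acc <- acc + C
  }
  W <- (1 - shrinkage) * acc / length(baselines)
  W[abs(W) < sparsity] <- 0
  diag(W) <- 1
  dimnames(W) <- list(genes, genes)
  structure(list(genes = genes, W = W, shrinkage = shrinkage,
                 sparsity = sparsity),
            class = "coexpression_model")
}

#' @export
print.coexpression_model <- function(x, ...) {
  nz <- sum(x$W != 0) - length(x$genes)
  cat(sprintf(
    "coexpression_model: %d genes, %d nonzero off-diagonal weights (shrinkage %.2f, sparsity %.2f)\n",
    length(x$genes), nz, x$shrinkage, x$sparsity))
  invisible(x)
}

#' Simulate a single-gene knockdown profile
#'
#' First-order linear propagation: the knocked-down gene receives
#' `primary_log2fc`, and every other gene `j` receives
#' `w[gene, j] * primary_log2fc`. Deterministic.
#'
#' @param model a [fit_reference_model()] result.
#' @param gene gene to knock down (must be in the model universe).
#' @param primary_log2fc log2 fold change at the target (default -2).
#' @return Named numeric log2FC vector over the model universe, with a
#'   `label` attribute `"KD:<gene>"`.
#' @export
simulate_knockdown <- function(model, gene, primary_log2fc = -2) {
  stopifnot(inherits(model, "coexpression_model"))
  if (!gene %in% model$genes) {
    near <- model$genes[utils::head(order(utils::adist(gene, model$genes)), 3)]
    stop(sprintf("gene '%s' not in model universe; nearest: %s",
                 gene, paste(near, collapse = ", ")), call. = FALSE)
  }
  profile <- model$W[gene, ] * primary_log2fc
  profile[gene] <- primary_log2fc
  attr(profile, "label") <- paste0("KD:", gene)
  profile
}

#' Write a perturbation profile as two-column TSV
#'
#' @param profile named log2FC vector.
#' @param path output path.
#' @param label profile label written as a `# label:` header comment.
#' @export
write_profile <- function(profile, path, label = attr(profile, "label")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(label)) writeLines(sprintf("# label: %s", label), con)
  writeLines("gene\tlog2FC", con)
  writeLines(sprintf("%s\t%.17g", names(profile), as.numeric(profile)), con)
  invisible(path)
}

#' Load perturbation profiles from TSV files
#'
#' Each file is a two-column TSV (`gene`, `log2FC`), optionally with a
#' `# label: <label>` header; otherwise the file name (without
#' extension) is the label. Profiles are aligned to a common universe:
#' genes missing from a file are imputed as 0 (with a warning count),
#' and genes absent from `universe` are dropped or the universe is
#' extended, per `unknown`.
#'
#' @param paths character vector of file paths.
#' @param universe optional gene universe to align to (default: union
#'   of all genes seen).
#' @param unknown `"drop"` (default) or `"extend"`: what to do with
#'   genes not in `universe`.
#' @return Named list of aligned log2FC vectors.
#' @export
load_profiles <- function(paths, universe = NULL,
                          unknown = c("drop", "extend")) {
  unknown <- match.arg(unknown)
  raw <- lapply(paths, function(path) {
    lines <- readLines(path)
    label <- NULL
    lab <- grep("^# label:", lines, value = TRUE)
    if (length(lab)) label <- trimws(sub("^# label:", "", lab[1]))
    body <- grep("^#", lines, invert = TRUE)
    fields <- strsplit(lines[body], "\t", fixed = TRUE)
    header <- fields[[1]]
    if (length(header) < 2 || header[1] != "gene")
      stop(sprintf("%s: expected header 'gene\tlog2FC'", path), call. = FALSE)
    rows <- fields[-1]
    bad <- which(lengths(rows) != 2 |
                   is.na(suppressWarnings(
                     as.numeric(vapply(rows, function(r)
                       if (length(r) >= 2) r[2] else NA_character_,
                       character(1))))))
    if (length(bad))
      stop(sprintf("%s: malformed rows at lines %s", path,
                   paste(body[-1][bad], collapse = ", ")), call. = FALSE)
    v <- stats::setNames(
      as.numeric(vapply(rows, `[[`, character(1), 2)),
      vapply(rows, `[[`, character(1), 1))
    if (is.null(label))
      label <- tools::file_path_sans_ext(basename(path))
    list(label = label, profile = v)
  })
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(raw, function(r)
      names(r$profile)))))
  out <- lapply(raw, function(r) {
    extra <- setdiff(names(r$profile), universe)
    if (length(extra)) {
      if (unknown == "extend") universe <<- c(universe, extra)
      else warning(sprintf("%s: dropped %d gene(s) outside the universe",
                           r$label, length(extra)))
    }
    r
  })
  out <- lapply(out, function(r) {
    missing <- sum(!universe %in% names(r$profile))
    if (missing > 0)
      warning(sprintf("%s: %d universe gene(s) missing; imputed as 0",
                      r$label, missing))
    v <- stats::setNames(rep(0, length(universe)), universe)
    shared <- intersect(names(r$profile), universe)
    v[shared] <- r$profile[shared]
    attr(v, "label") <- r$label
    v
  })
  stats::setNames(out, vapply(out, attr, character(1), "label"))
}

#' Serialize a co-expression model as triplet TSV
#'
#' Writes the nonzero weights as rows (gene_i, gene_j, weight); the unit
#' diagonal is implicit and restored on read.
#'
#' @param model a [fit_reference_model()] result.
#' @param path output path.
#' @export
write_coexpression_model <- function(model, path) {
  stopifnot(inherits(model, "coexpression_model"))
  nz <- which(model$W != 0 & row(model$W) != col(model$W), arr.ind = TRUE)
  df <- data.frame(gene_i = model$genes[nz[, 1]],
                   gene_j = model$genes[nz[, 2]],
                   weight = model$W[nz],
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# genes: %s", paste(model$genes, collapse = ",")), con)
  writeLines(sprintf("# shrinkage: %.17g sparsity: %.17g",
                     model$shrinkage, model$sparsity), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a co-expression model written by [write_coexpression_model()]
#'
#' @param path path to the triplet TSV.
#' @return A `coexpression_model`.
#' @export
read_coexpression_model <- function(path) {
  lines <- readLines(path)
  genes <- strsplit(sub("^# genes: ", "", lines[1]), ",", fixed = TRUE)[[1]]
  pars <- as.numeric(regmatches(lines[2],
                                gregexpr("[0-9.]+", lines[2]))[[1]])
  df <- utils::read.table(text = lines[-(1:2)], sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  W <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  if (nrow(df)) W[cbind(df$gene_i, df$gene_j)] <- df$weight
  diag(W) <- 1
  structure(list(genes = genes, W = W, shrinkage = pars[1],
                 sparsity = pars[2]),
            class = "coexpression_model")
}
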