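#' Harmonize gene symbols across species casing conventions
#'
#' Maps symbols to an uppercase canonical form (mouse `Ctss` and human
#' `CTSS` collapse to `CTSS`); duplicates after harmonization collapse
#' to the first occurrence with a warning. The original spellings are
#' kept in an `original` attribute (canonical -> first original form).
#' No orthology mapping is attempted.
#'
#' @param genes character vector of gene symbols.
#' @return Character vector of unique canonical symbols with attribute
#'   `original`.
#' @export
harmonize_symbols <- function(genes) {
  genes <- as.character(genes)
  genes <- genes[nzchar(trimws(genes))]
  if (length(genes) == 0) {
    out <- character(0)
    attr(out, "original") <- stats::setNames(character(0), character(0))
    return(out)
  }
  canon <- toupper(trimws(genes))
  dup <- duplicated(canon)
  if (any(dup))
    warning(sprintf("%d symbol(s) collapsed after case harmonization: %s",
                    sum(dup), paste(unique(canon[dup]), collapse = ", ")))
  keep <- !dup
  out <- canon[keep]
  attr(out, "original") <- stats::setNames(genes[keep], out)
  out
}

#' Intersect predicted drug targets with core leading-edge genes
#'
#' Both inputs are expected in harmonized (uppercase canonical) form;
#' the result is reported in deterministic lexicographic order. An empty
#' intersection is a valid result, not an error.
#'
#' @param targets character vector of predicted drug-target symbols.
#' @param core_genes character vector of core leading-edge genes.
#' @return Sorted character vector of shared (key) genes.
#' @export
intersect_targets <- function(targets, core_genes) {
  out <- sort(intersect(targets, core_genes))
  if (length(out) == 0)
    message("target/core-gene intersection is empty")
  out
}

#' Triage docked targets by binding affinity
#'
#' Retains targets with predicted binding energy strictly below the
#' threshold (default -6.5 kcal/mol; more negative = stronger binding),
#' sorted ascending by affinity so the strongest binder comes first.
#'
#' @param table data.frame with columns `target` and `affinity`
#'   (kcal/mol), one row per target.
#' @param threshold strict upper bound on affinity (default -6.5).
#' @return data.frame of retained rows, ascending affinity.
#' @export
filter_by_affinity <- function(table, threshold = -6.5) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("docking table must be a non-empty data.frame", call. = FALSE)
  if (!all(c("target", "affinity") %in% names(table)))
    stop("docking table needs columns `target` and `affinity`", call. = FALSE)
  if (any(!is.finite(table$affinity)))
    stop("affinities must be finite", call. = FALSE)
  if (anyDuplicated(table$target))
    stop("one row per target required", call. = FALSE)
  out <- table[table$affinity < threshold, , drop = FALSE]
  out <- out[order(out$affinity, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a docking-affinity table
#'
#' TSV with columns `target` and `affinity` (kcal/mol), as produced by a
#' docking engine's summary.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `target`, `affinity`.
#' @export
read_docking_table <- function(path) {
  df <- read_tsv(path)
  names(df)[names(df) == "affinity_kcal_mol"] <- "affinity"
  if (!all(c("target", "affinity") %in% names(df)))
    stop("docking table needs columns `target` and `affinity` (kcal/mol)",
         call. = FALSE)
  df$affinity <- as.numeric(df$affinity)
  df
}

#' Read a predicted drug-target list
#'
#' One symbol per line (plain text) or a TSV whose first column holds
#' the symbols, as produced by a reverse-docking target-prediction
#' server.
#'
#' @param path path to the file.
#' @param harmonize apply [harmonize_symbols()] (default TRUE).
#' @return Character vector of target symbols; attributes `n_raw` and
#'   `n_harmonized` record pre-/post-harmonization counts.
#' @export
read_target_list <- function(path, harmonize = TRUE) {
  lines <- readLines(path)
  lines <- trimws(vapply(strsplit(lines, "\t", fixed = TRUE),
                         function(x) if (length(x)) x[[1]] else "",
                         character(1)))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  n_raw <- length(lines)
  out <- if (harmonize) harmonize_symbols(lines) else unique(lines)
  attr(out, "n_raw") <- n_raw
  attr(out, "n_harmonized") <- length(out)
  out
}
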