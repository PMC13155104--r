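#' ASV read-count matrix indexed by (treatment, replicate, fraction)
#'
#' @param counts Non-negative integer matrix, ASVs in rows (rownames = ASV
#'   ids), samples in columns.
#' @param samples data.frame with one row per column of `counts` and columns
#'   `treatment`, `replicate`, `fraction`. A `sample` column (the sample key)
#'   is derived as `"treatment:replicate:fraction"` if absent.
#'
#' @return An object of class `fcm` (list with elements `counts`, `samples`).
#' @export
feature_count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("`counts` must have ASV ids as rownames")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("treatment", "replicate", "fraction")
  if (!all(need %in% names(samples)))
    stop("`samples` needs columns: ", paste(need, collapse = ", "))
  if (nrow(samples) != ncol(counts))
    stop("`samples` must have one row per counts column")
  samples$replicate <- as.integer(samples$replicate)
  samples$fraction <- as.character(samples$fraction)
  if (!"sample" %in% names(samples))
    samples$sample <- paste(samples$treatment, samples$replicate,
                            samples$fraction, sep = ":")
  if (anyDuplicated(samples$sample))
    stop("duplicated sample keys: ",
         paste(unique(samples$sample[duplicated(samples$sample)]), collapse = ", "))
  colnames(counts) <- samples$sample
  structure(list(counts = counts, samples = samples), class = "fcm")
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("Feature count matrix: %d ASVs x %d samples (%d treatment(s)), %s reads\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$treatment)),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.fcm <- function(x) dim(x$counts)

taxonomy_ranks <- c("domain", "phylum", "class", "order", "family", "genus",
                    "species")

#' Parse a taxonomy table
#'
#' Accepts either QIIME-style lineage strings
#' (`"d__Bacteria; p__Bacteroidota; ..."`) in a single column, or one column
#' per rank. Flags eukaryotic organelles (mitochondria, chloroplasts) whose
#' 16S reads do not represent prokaryotic taxa.
#'
#' @param tab data.frame with an ASV id column (`asv`, or the first column)
#'   and either a lineage-string column (`taxon`/`taxonomy`/`lineage`) or
#'   per-rank columns (`domain` ... `species`).
#' @return data.frame with columns `asv`, the seven ranks, `lineage` (the
#'   collapsed string) and `organelle` (logical).
#' @export
parse_taxonomy <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!"asv" %in% names(tab)) names(tab)[1L] <- "asv"
  lin_col <- intersect(c("taxon", "taxonomy", "lineage"), names(tab))
  ranks <- matrix("", nrow(tab), length(taxonomy_ranks),
                  dimnames = list(NULL, taxonomy_ranks))
  if (length(lin_col)) {
    parts <- strsplit(as.character(tab[[lin_col[1L]]]), ";", fixed = TRUE)
    for (i in seq_along(parts)) {
      p <- trimws(parts[[i]])
      p <- sub("^[a-z]__", "", p)       # strip QIIME rank prefixes
      k <- min(length(p), length(taxonomy_ranks))
      if (k > 0) ranks[i, seq_len(k)] <- p[seq_len(k)]
    }
  } else {
    have <- intersect(taxonomy_ranks, names(tab))
    if (!length(have))
      stop("taxonomy needs a lineage column or per-rank columns")
    for (r in have) ranks[, r] <- as.character(tab[[r]])
  }
  ranks[is.na(ranks)] <- ""
  out <- data.frame(asv = as.character(tab$asv), ranks,
                    stringsAsFactors = FALSE)
  out$lineage <- apply(ranks, 1L, function(r)
    paste(r[r != ""], collapse = ";"))
  out$organelle <- grepl("chloroplast|mitochondri",
                         out$lineage, ignore.case = TRUE)
  out
}

unassigned_taxonomy <- function(asv) {
  ranks <- matrix("unassigned", length(asv), length(taxonomy_ranks),
                  dimnames = list(NULL, taxonomy_ranks))
  data.frame(asv = asv, ranks, lineage = "unassigned", organelle = FALSE,
             stringsAsFactors = FALSE)
}

#' Read an ASV count matrix and its taxonomy
#'
#' The counts file is a TSV/CSV with ASV ids in the first column and one
#' column per sample, named `"treatment:replicate:fraction"` (separator
#' configurable). The taxonomy file is parsed with [parse_taxonomy()]. ASVs
#' present in the counts but absent from the taxonomy receive an explicit
#' "unassigned" lineage with a warning, so the two tables always share one
#' ASV universe.
#'
#' @param counts_path,taxonomy_path File paths.
#' @param key_sep Separator inside sample column names.
#' @return A list with elements `counts` (an [feature_count_matrix()]) and
#'   `taxonomy` (a data.frame).
#' @export
read_counts_and_taxonomy <- function(counts_path, taxonomy_path,
                                     key_sep = ":") {
  tab <- read_table_auto(counts_path)
  asv <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- asv
  keys <- strsplit(colnames(mat), key_sep, fixed = TRUE)
  bad <- colnames(mat)[lengths(keys) != 3L]
  if (length(bad))
    stop("count column(s) unresolvable to (treatment, replicate, fraction): ",
         paste(bad, collapse = ", "))
  samples <- data.frame(
    treatment = vapply(keys, `[[`, "", 1L),
    replicate = as.integer(vapply(keys, `[[`, "", 2L)),
    fraction = vapply(keys, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  m <- feature_count_matrix(mat, samples)

  tax <- parse_taxonomy(read_table_auto(taxonomy_path))
  missing <- setdiff(asv, tax$asv)
  if (length(missing)) {
    warning(length(missing), " ASV(s) missing from taxonomy; recorded as unassigned")
    tax <- rbind(tax, unassigned_taxonomy(missing))
  }
  tax <- tax[match(asv, tax$asv), , drop = FALSE]
  rownames(tax) <- NULL
  list(counts = m, taxonomy = tax)
}

# subset an fcm to a set of ASV rows and/or sample columns
fcm_subset <- function(m, asvs = NULL, cols = NULL) {
  counts <- m$counts
  samples <- m$samples
  if (!is.null(asvs)) counts <- counts[asvs, , drop = FALSE]
  if (!is.null(cols)) {
    counts <- counts[, cols, drop = FALSE]
    samples <- samples[cols, , drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(list(counts = counts, samples = samples), class = "fcm")
}
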