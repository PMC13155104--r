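#' Default contaminant blocklist
#'
#' Genera commonly introduced by reagents and lab handling in 16S amplicon
#' datasets. The shipped default covers the usual suspects
#' (*Ralstonia*, *Variovorax*, *Streptococcus*, ...); extend it with your
#' facility's own list via `extra` or a one-name-per-line file.
#'
#' @param extra Character vector of additional taxon names.
#' @param file Optional path to a plain-text file, one taxon name per line
#'   (`#` comments allowed).
#' @return Character vector of taxon names (matched case-insensitively as
#'   substrings at any rank).
#' @export
qsip_blocklist <- function(extra = character(), file = NULL) {
  base <- c("Ralstonia", "Variovorax", "Streptococcus")
  shipped <- system.file("extdata", "contaminant_blocklist.txt",
                         package = "fjordsip")
  if (nzchar(shipped)) {
    ln <- readLines(shipped, warn = FALSE)
    ln <- trimws(sub("#.*$", "", ln))
    base <- union(base, ln[nzchar(ln)])
  }
  if (!is.null(file)) {
    ln <- readLines(file, warn = FALSE)
    ln <- trimws(sub("#.*$", "", ln))
    base <- union(base, ln[nzchar(ln)])
  }
  union(base, extra)
}

ledger_entry <- function(stage, asv_ids, reads_removed_fraction, detail = "") {
  structure(
    data.frame(stage = stage, n_removed = length(asv_ids),
               reads_removed_fraction = reads_removed_fraction,
               detail = detail, stringsAsFactors = FALSE,
               asv_ids = I(list(asv_ids))),
    class = c("filter_ledger", "data.frame"))
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("ASV filtering ledger:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-16s removed %4d ASV(s), %5.1f%% of reads  %s\n",
                x$stage[i], x$n_removed[i],
                100 * x$reads_removed_fraction[i],
                x$detail[i]))
  invisible(x)
}

#' Remove contaminant and organelle ASVs
#'
#' Drops ASVs whose lineage contains any blocklisted taxon name at any rank
#' (case-insensitive substring match) plus all organelle-flagged ASVs
#' (mitochondria, chloroplasts). Counts themselves are never modified; only
#' ASV membership changes.
#'
#' @param m A [feature_count_matrix()].
#' @param tax Taxonomy data.frame from [parse_taxonomy()].
#' @param blocklist Character vector of taxon names; see [qsip_blocklist()].
#'   An empty blocklist removes organelles only.
#' @return List with elements `counts` (filtered matrix) and `ledger`
#'   (one-row [ledger][print.filter_ledger] entry recording ids and the
#'   fraction of this call's reads removed).
#' @export
remove_contaminants <- function(m, tax, blocklist = qsip_blocklist()) {
  stopifnot(inherits(m, "fcm"))
  if (nrow(m$counts) == 0L) stop("empty count matrix")
  tax <- tax[match(rownames(m$counts), tax$asv), , drop = FALSE]
  hit <- rep(FALSE, nrow(m$counts))
  for (b in blocklist)
    hit <- hit | grepl(b, tax$lineage, ignore.case = TRUE, fixed = FALSE)
  hit <- hit | tax$organelle %in% TRUE
  removed <- rownames(m$counts)[hit]
  total <- sum(m$counts)
  frac <- if (total > 0) sum(m$counts[hit, , drop = FALSE]) / total else 0
  list(counts = fcm_subset(m, asvs = rownames(m$counts)[!hit]),
       ledger = ledger_entry("contaminants", removed, frac,
                             sprintf("%d blocklisted name(s)", length(blocklist))))
}

#' Remove globally low-abundant ASVs
#'
#' Keeps ASVs with at least `min_total` reads summed over all samples
#' (i.e. removes those with `< min_total` reads across whole fractions).
#'
#' @inheritParams remove_contaminants
#' @param min_total Minimum total read count to keep an ASV.
#' @return List with `counts` and `ledger` as in [remove_contaminants()].
#' @export
filter_low_abundance <- function(m, min_total = 10) {
  stopifnot(inherits(m, "fcm"), min_total >= 0)
  if (nrow(m$counts) == 0L) stop("empty count matrix")
  tot <- rowSums(m$counts)
  keep <- tot >= min_total
  removed <- rownames(m$counts)[!keep]
  total <- sum(m$counts)
  frac <- if (total > 0) sum(tot[!keep]) / total else 0
  list(counts = fcm_subset(m, asvs = rownames(m$counts)[keep]),
       ledger = ledger_entry("low_abundance", removed, frac,
                             sprintf("< %g reads overall", min_total)))
}

#' Per-treatment, per-replicate abundance filter
#'
#' Within each treatment, an ASV enters that treatment's qSIP analysis set
#' only if its reads summed over fractions exceed `min_reads` in *every*
#' replicate of that treatment (strict `>`). The matrix itself is untouched;
#' the result is per-treatment inclusion metadata.
#'
#' @inheritParams remove_contaminants
#' @param min_reads Per-replicate read total an ASV must exceed.
#' @return List with `inclusion` (named list: treatment -> character vector
#'   of retained ASV ids) and `ledger`.
#' @export
filter_per_replicate <- function(m, min_reads = 10) {
  stopifnot(inherits(m, "fcm"))
  treatments <- unique(m$samples$treatment)
  inclusion <- list()
  for (tr in treatments) {
    sam <- m$samples[m$samples$treatment == tr, , drop = FALSE]
    reps <- unique(sam$replicate)
    if (length(reps) == 0L) stop("treatment with zero replicates: ", tr)
    ok <- rep(TRUE, nrow(m$counts))
    for (r in reps) {
      cols <- sam$sample[sam$replicate == r]
      ok <- ok & rowSums(m$counts[, cols, drop = FALSE]) > min_reads
    }
    inclusion[[tr]] <- rownames(m$counts)[ok]
  }
  detail <- paste(sprintf("%s: %d", names(inclusion), lengths(inclusion)),
                  collapse = "; ")
  list(inclusion = inclusion,
       ledger = ledger_entry("per_replicate", character(), 0,
                             paste0("retained per treatment - ", detail)))
}

#' The full ASV quality-filtering cascade
#'
#' Applies, in order: (1) contaminant + organelle removal, (2) the global
#' low-abundance threshold, (3) the per-treatment per-replicate threshold.
#' Stage order matters and the removed sets are disjoint; the ledger records
#' each stage's removals so the cascade is auditable.
#'
#' @inheritParams remove_contaminants
#' @param min_total Global threshold: keep ASVs with `>= min_total` reads.
#' @param min_per_replicate Per-replicate threshold: keep (per treatment)
#'   ASVs with `> min_per_replicate` reads in every replicate.
#' @return List with `counts` (post stage 1-2), `inclusion` (stage 3
#'   per-treatment sets), and `ledger` (stacked entries).
#' @export
filter_features <- function(m, tax, blocklist = qsip_blocklist(),
                            min_total = 10, min_per_replicate = 10) {
  s1 <- remove_contaminants(m, tax, blocklist)
  s2 <- filter_low_abundance(s1$counts, min_total)
  s3 <- filter_per_replicate(s2$counts, min_per_replicate)
  ledger <- rbind(s1$ledger, s2$ledger, s3$ledger)
  class(ledger) <- c("filter_ledger", "data.frame")
  list(counts = s2$counts, inclusion = s3$inclusion, ledger = ledger)
}
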