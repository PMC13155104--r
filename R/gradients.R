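#' A single ultracentrifugation gradient replicate
#'
#' Holds the ordered density fractions of one technical SIP replicate: buoyant
#' densities (g/mL) and the qPCR-derived 16S rRNA gene copy total (SQ) of each
#' fraction. Fractions are stored in canonical ascending-density order; the
#' order in which they were supplied (typically collection order, densest
#' first) is kept as provenance.
#'
#' @param treatment Treatment identifier (no `":"` characters).
#' @param replicate Replicate number (typically 1--3).
#' @param density Buoyant densities, g/mL; must be unique and within
#'   \[1.60, 1.80\].
#' @param copies qPCR SQ per fraction (>= 0). `NA` is allowed only for
#'   fractions with `sequenced = FALSE` (density must always be present).
#' @param fraction Fraction labels; defaults to the supplied order.
#' @param sequenced Logical flag per fraction: selected for sequencing.
#'   Defaults to `!is.na(copies)`.
#'
#' @return An object of class `gradient_replicate`.
#' @seealso [read_gradient_table()], [validate_gradient()],
#'   [bulk_weighted_density()]
#' @export
gradient_replicate <- function(treatment, replicate, density, copies,
                               fraction = seq_along(density),
                               sequenced = NULL) {
  treatment <- as.character(treatment)[1L]
  if (grepl(":", treatment, fixed = TRUE))
    stop("treatment id must not contain ':' (reserved as sample-key separator)")
  replicate <- as.integer(replicate)[1L]
  density <- as.numeric(density)
  copies <- as.numeric(copies)
  fraction <- as.character(fraction)
  n <- length(density)
  if (n == 0L) stop("a gradient replicate needs at least one fraction")
  if (length(copies) != n || length(fraction) != n)
    stop("`density`, `copies` and `fraction` must have equal length")
  if (anyNA(density)) stop("density must be present for every fraction")
  if (any(density < 1.60 | density > 1.80))
    stop("buoyant densities must lie within [1.60, 1.80] g/mL")
  if (anyDuplicated(density))
    stop("duplicated buoyant densities; fractions must be strictly monotonic")
  if (anyDuplicated(fraction))
    stop("duplicated fraction labels: ",
         paste(unique(fraction[duplicated(fraction)]), collapse = ", "))
  if (is.null(sequenced)) sequenced <- !is.na(copies)
  sequenced <- as.logical(sequenced)
  if (length(sequenced) != n) stop("`sequenced` must match the fraction count")
  bad <- !is.na(copies) & (!is.finite(copies) | copies < 0)
  if (any(bad)) stop("copies must be finite and >= 0")
  if (any(is.na(copies) & sequenced))
    stop("sequenced fractions must have a copy (SQ) value")

  ord <- order(density)
  structure(
    list(treatment = treatment,
         replicate = replicate,
         fractions = data.frame(fraction = fraction[ord],
                                density = density[ord],
                                copies = copies[ord],
                                sequenced = sequenced[ord],
                                stringsAsFactors = FALSE),
         source_order = fraction),   # provenance: order as supplied
    class = "gradient_replicate"
  )
}

#' @export
print.gradient_replicate <- function(x, ...) {
  fr <- x$fractions
  cat(sprintf("Gradient replicate %s (treatment '%s'): %d fractions, %d sequenced\n",
              x$replicate, x$treatment, nrow(fr), sum(fr$sequenced)))
  cat(sprintf("  density %0.4f-%0.4f g/mL, total SQ %.4g\n",
              min(fr$density), max(fr$density), sum(fr$copies, na.rm = TRUE)))
  invisible(x)
}

default_gradient_schema <- function() {
  list(treatment = "treatment", replicate = "replicate", fraction = "fraction",
       density = "density", copies = "copies", sequenced = "sequenced")
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

check_numeric_column <- function(x, name, path) {
  suppressWarnings(num <- as.numeric(x))
  bad <- which(is.na(num) & !is.na(x) & trimws(as.character(x)) != "")
  if (length(bad))
    stop(sprintf("non-numeric %s in %s at line(s) %s", name, basename(path),
                 paste(bad + 1L, collapse = ", ")))  # +1 for the header line
  num
}

#' Read a per-fraction gradient table
#'
#' Reads a TSV/CSV with one row per (treatment, replicate, fraction) holding
#' buoyant density and qPCR SQ, and groups rows into [gradient_replicate()]
#' objects in canonical ascending-density order. Parsing is lossless: the
#' writer reproduces the table cell for cell (canonical column order).
#'
#' @param path Path to a `.tsv`/`.csv` file.
#' @param schema Named list mapping the required roles (`treatment`,
#'   `replicate`, `fraction`, `density`, `copies`, optionally `sequenced`) to
#'   column names. `copies` may name two columns (duplicate qPCR wells), which
#'   are averaged at read time.
#'
#' @return A named list of `gradient_replicate` objects
#'   (`"treatment:replicate"`).
#' @export
read_gradient_table <- function(path, schema = default_gradient_schema()) {
  schema <- utils::modifyList(default_gradient_schema(), schema)
  tab <- read_table_auto(path)
  need <- c("treatment", "replicate", "fraction", "density")
  for (role in need) {
    if (!schema[[role]] %in% names(tab))
      stop(sprintf("schema error: missing column '%s' (role '%s')",
                   schema[[role]], role))
  }
  copy_cols <- schema$copies
  if (!all(copy_cols %in% names(tab)))
    stop(sprintf("schema error: missing column '%s' (role 'copies')",
                 paste(setdiff(copy_cols, names(tab)), collapse = "', '")))

  density <- check_numeric_column(tab[[schema$density]], "density", path)
  copies <- rowMeans(vapply(copy_cols, function(cc)
    check_numeric_column(tab[[cc]], "copies", path), numeric(nrow(tab))))
  sequenced <- if (schema$sequenced %in% names(tab))
    as.logical(tab[[schema$sequenced]]) else NULL

  key <- paste(tab[[schema$treatment]], tab[[schema$replicate]],
               tab[[schema$fraction]], sep = ":")
  if (anyDuplicated(key))
    stop("duplicated (treatment, replicate, fraction) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))

  grp <- paste(tab[[schema$treatment]], tab[[schema$replicate]], sep = ":")
  reps <- lapply(split(seq_len(nrow(tab)), factor(grp, levels = unique(grp))),
                 function(i) {
                   gradient_replicate(
                     treatment = tab[[schema$treatment]][i][1L],
                     replicate = tab[[schema$replicate]][i][1L],
                     density = density[i], copies = copies[i],
                     fraction = tab[[schema$fraction]][i],
                     sequenced = if (is.null(sequenced)) NULL else sequenced[i])
                 })
  reps
}

#' Write gradient replicates back to a table
#'
#' Inverse of [read_gradient_table()] under the canonical column order
#' (`treatment`, `replicate`, `fraction`, `density`, `copies`, `sequenced`);
#' rows are emitted in canonical ascending-density order within each replicate.
#'
#' @param reps A `gradient_replicate` or list of them.
#' @param path Output path (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_gradient_table <- function(reps, path) {
  if (inherits(reps, "gradient_replicate")) reps <- list(reps)
  rows <- do.call(rbind, lapply(reps, function(r)
    cbind(data.frame(treatment = r$treatment, replicate = r$replicate,
                     stringsAsFactors = FALSE),
          r$fractions)))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(rows, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality-control report for a gradient replicate
#'
#' Evaluates the fractionation conventions used for density-gradient SIP:
#' adjacent fraction spacing within \[`min_spacing`, `max_spacing`\] g/mL,
#' between 7 and 14 sequenced fractions, sequenced fractions spanning the
#' SQ-vs-density peak (the peak fraction plus at least one sequenced fraction
#' on each flank), at least 5 fractions overall, and strictly monotonic
#' densities in the order collected. The report is pure: repeated calls give
#' identical results.
#'
#' @param rep A [gradient_replicate()].
#' @param min_spacing,max_spacing Acceptable adjacent density interval, g/mL.
#' @param seq_count Acceptable range for the number of sequenced fractions.
#'
#' @return A data.frame with columns `check`, `status`
#'   (`"pass"`/`"warn"`/`"fail"`) and `detail`.
#' @export
validate_gradient <- function(rep, min_spacing = 0.005, max_spacing = 0.007,
                              seq_count = c(7L, 14L)) {
  stopifnot(inherits(rep, "gradient_replicate"))
  fr <- rep$fractions
  if (nrow(fr) == 0L) stop("empty fraction list")
  out <- list()
  add <- function(check, status, detail)
    out[[length(out) + 1L]] <<- data.frame(check = check, status = status,
                                           detail = detail,
                                           stringsAsFactors = FALSE)

  # fraction count
  if (nrow(fr) < 5L)
    add("n_fractions", "fail", sprintf("only %d fractions (< 5)", nrow(fr)))
  else add("n_fractions", "pass", sprintf("%d fractions", nrow(fr)))

  # spacing between adjacent fractions (canonical order)
  dd <- diff(fr$density)
  bad <- which(dd < min_spacing - 1e-12 | dd > max_spacing + 1e-12)
  if (length(bad))
    add("spacing", "warn",
        sprintf("%d adjacent interval(s) outside [%g, %g] g/mL (e.g. %.4f)",
                length(bad), min_spacing, max_spacing, dd[bad[1L]]))
  else add("spacing", "pass", sprintf("all intervals within [%g, %g] g/mL",
                                      min_spacing, max_spacing))

  # number of sequenced fractions
  nseq <- sum(fr$sequenced)
  if (nseq < seq_count[1L] || nseq > seq_count[2L])
    add("sequenced_count", "warn",
        sprintf("%d sequenced fractions outside [%d, %d]", nseq,
                seq_count[1L], seq_count[2L]))
  else add("sequenced_count", "pass", sprintf("%d sequenced fractions", nseq))

  # peak coverage: peak = max copies, ties broken toward lower density
  cp <- fr$copies
  cp[is.na(cp)] <- -Inf
  peak <- which.max(cp)  # which.max takes the first (lowest-density) tie
  seq_idx <- which(fr$sequenced)
  spans <- length(seq_idx) > 0L && peak %in% seq_idx &&
    any(seq_idx < peak) && any(seq_idx > peak)
  if (spans)
    add("peak_span", "pass",
        sprintf("peak fraction '%s' sequenced with both flanks", fr$fraction[peak]))
  else
    add("peak_span", "warn",
        sprintf("sequenced fractions do not span the SQ peak (fraction '%s')",
                fr$fraction[peak]))

  # monotonic collection order: source order must be a monotone density sweep
  src <- match(rep$source_order, fr$fraction)
  src_density <- fr$density[src]
  monotone <- all(diff(src_density) > 0) || all(diff(src_density) < 0)
  if (monotone)
    add("monotonic", "pass", "densities monotonic in collection order")
  else
    add("monotonic", "fail", "densities not monotonic in collection order")

  do.call(rbind, out)
}
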