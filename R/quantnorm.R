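#' Construct a raw protein quantification table
#'
#' A `quant_table` holds one cell line's protein-level peak areas: one row per
#' protein, one column per biological replicate. A cell is `NA` when the
#' protein was not identified in that replicate run (search-engine exports
#' leave unidentified proteins blank, not zero, so literal zeros are coerced
#' to `NA` on construction).
#'
#' @param accession character vector of unique protein accessions.
#' @param areas numeric matrix of raw precursor peak areas (proteins x
#'   replicates), `NA` = not identified. Values must be non-negative.
#' @param gene,description optional per-protein annotation vectors.
#' @param cell_line label for the cell line the table belongs to.
#' @param normalized logical; `TRUE` if `areas` are already in
#'   parts-per-10^6 normalized units.
#' @return An object of class `quant_table`.
#' @export
quant_table <- function(accession, areas, gene = NULL, description = NULL,
                        cell_line = "unknown", normalized = FALSE) {
  areas <- as.matrix(areas)
  if (!is.numeric(areas)) stop("'areas' must be a numeric matrix")
  if (length(accession) != nrow(areas)) {
    stop("length(accession) must equal nrow(areas)")
  }
  if (anyDuplicated(accession)) {
    dups <- unique(accession[duplicated(accession)])
    stop("duplicate accessions: ", paste(dups, collapse = ", "))
  }
  if (ncol(areas) < 1L) stop("need at least one replicate column")
  neg <- which(areas < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(sprintf("negative area at protein '%s', replicate %d",
                 accession[neg[1L, 1L]], neg[1L, 2L]))
  }
  # zero means "not identified" in these exports
  areas[!is.na(areas) & areas == 0] <- NA_real_
  all_missing <- rowSums(!is.na(areas)) == 0L
  if (any(all_missing)) {
    stop("protein(s) with no identified replicate: ",
         paste(utils::head(accession[all_missing], 5L), collapse = ", "))
  }
  if (is.null(colnames(areas))) {
    colnames(areas) <- paste0(if (isTRUE(normalized)) "NormArea_rep"
                              else "Area_rep",
                              seq_len(ncol(areas)))
  }
  rownames(areas) <- accession
  structure(
    list(cell_line = cell_line,
         proteins = data.frame(
           accession = as.character(accession),
           gene = if (is.null(gene)) NA_character_ else as.character(gene),
           description = if (is.null(description)) NA_character_
                         else as.character(description),
           stringsAsFactors = FALSE),
         areas = areas,
         normalized = isTRUE(normalized)),
    class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("<quant_table> cell line '%s': %d proteins x %d replicates (%s)\n",
              x$cell_line, nrow(x$areas), ncol(x$areas),
              if (x$normalized) "normalized, parts-per-1e6" else "raw areas"))
  cat(sprintf("  missing cells: %d\n", sum(is.na(x$areas))))
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$areas)

#' Normalize one replicate's peak areas to parts-per-10^6
#'
#' Each identified protein's area is divided by the replicate run's total
#' identified area and scaled by 10^6, so a replicate column always sums to
#' 10^6 over its identified proteins. Missing (`NA`) entries stay missing and
#' do not contribute to the total.
#'
#' @param raw_areas numeric vector of raw peak areas; `NA` = not identified.
#' @return Numeric vector of the same length in parts-per-10^6 units.
#' @examples
#' normalize_replicate(c(2, 3, 5))          # 2e5, 3e5, 5e5
#' normalize_replicate(c(10, NA, 30))       # 2.5e5, NA, 7.5e5
#' @export
normalize_replicate <- function(raw_areas) {
  if (!is.numeric(raw_areas)) stop("'raw_areas' must be numeric")
  present <- !is.na(raw_areas)
  if (!any(present)) stop("empty replicate: all values missing")
  if (any(raw_areas[present] < 0)) {
    stop("negative area at position ",
         which(present & raw_areas < 0)[1L])
  }
  total <- sum(raw_areas[present])
  if (total <= 0) stop("empty replicate: total identified area is zero")
  raw_areas / total * 1e6
}

#' Normalize a quantification table to parts-per-10^6
#'
#' Applies [normalize_replicate()] independently to every replicate column.
#' Protein order and the missingness pattern are preserved; normalization is
#' per LC-MS/MS run (column), since the total-ion denominator is run-specific.
#'
#' @param table a [quant_table()].
#' @return A `quant_table` with `normalized = TRUE`.
#' @export
normalize_table <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  norm <- table$areas
  for (j in seq_len(ncol(norm))) {
    norm[, j] <- tryCatch(
      normalize_replicate(table$areas[, j]),
      error = function(e) stop(sprintf("replicate %d (%s): %s", j,
                                       colnames(norm)[j], conditionMessage(e)),
                               call. = FALSE))
  }
  colnames(norm) <- sub("^Area_", "NormArea_", colnames(norm))
  out <- table
  out$areas <- norm
  out$normalized <- TRUE
  out
}

#' Summarize one protein's normalized areas over replicates
#'
#' Computes the per-protein row model of a candidate table: detection count at
#' an inclusive normalized-area threshold, mean and sample SD (n-1
#' denominator) over identified replicates, and the percent coefficient of
#' variation. CV is `NA` (flagged undefined) with fewer than two identified
#' replicates or zero mean.
#'
#' @param norm_values numeric vector of normalized areas over replicates,
#'   `NA` = not identified.
#' @param detection_threshold normalized-area floor for calling a replicate
#'   detection; comparison is inclusive (`>=`). Default 70.
#' @return A one-row data.frame with columns `n_replicates_total`,
#'   `n_detected`, `mean_norm_area`, `sd_norm_area`, `cv_percent`.
#' @examples
#' summarize_protein(c(100, 200, 300, 400))  # mean 250, CV ~51.6%
#' @export
summarize_protein <- function(norm_values, detection_threshold = 70) {
  stopifnot(length(norm_values) >= 1L, detection_threshold > 0)
  present <- norm_values[!is.na(norm_values)]
  n_det <- sum(present >= detection_threshold)
  m <- if (length(present)) mean(present) else NA_real_
  s <- if (length(present) >= 2L) stats::sd(present) else NA_real_
  cv <- if (!is.na(s) && !is.na(m) && m > 0) 100 * s / m else NA_real_
  data.frame(n_replicates_total = length(norm_values),
             n_detected = n_det,
             mean_norm_area = m,
             sd_norm_area = s,
             cv_percent = cv)
}

#' Per-protein replicate summaries for a normalized table
#'
#' @param table a normalized [quant_table()].
#' @param detection_threshold inclusive normalized-area detection floor.
#' @return A data.frame (class `protein_summary`) with one row per protein:
#'   accession, gene, description, n_replicates_total, n_detected,
#'   mean_norm_area, sd_norm_area, cv_percent. Carries the cell line and
#'   threshold as attributes.
#' @export
summarize_quant_table <- function(table, detection_threshold = 70) {
  stopifnot(inherits(table, "quant_table"))
  if (!table$normalized) {
    warning("summarizing a non-normalized table; detection threshold is on ",
            "the parts-per-1e6 scale")
  }
  rows <- lapply(seq_len(nrow(table$areas)), function(i)
    summarize_protein(table$areas[i, ], detection_threshold))
  out <- cbind(table$proteins, do.call(rbind, rows))
  rownames(out) <- NULL
  attr(out, "cell_line") <- table$cell_line
  attr(out, "detection_threshold") <- detection_threshold
  class(out) <- c("protein_summary", "data.frame")
  out
}
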