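#' Default membrane-localization vocabulary
#'
#' Lowercased subcellular-location terms that count as membrane-associated
#' when refining a protein list against an annotation table.
#' @export
membrane_terms_default <- function() {
  c("membrane", "cell membrane", "plasma membrane",
    "mitochondrion membrane", "endoplasmic reticulum membrane",
    "golgi membrane")
}

#' Screening configuration
#'
#' Thresholds of the candidate-selection cascade. Defaults reflect a
#' four-replicate label-free design: a protein is detected in a cancer line
#' when it reaches the normalized-area floor in at least 75% of replicates
#' (3 of 4); it counts as expressed in the control line when it reaches the
#' floor in at least three replicates; candidates must keep replicate CV at
#' or below 40% and the table reports the 30 most abundant.
#'
#' @param detection_threshold normalized-area detection floor (inclusive).
#' @param presence_fraction fraction of cancer replicates that must reach the
#'   floor (inclusive comparison, so 3/4 passes at 0.75).
#' @param control_min_detected_reps replicate count defining expression in
#'   the control line.
#' @param cv_max_percent percent-CV ceiling (inclusive).
#' @param top_n number of candidates reported.
#' @param membrane_terms lowercase vocabulary of membrane localization terms.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(detection_threshold = 70,
                          presence_fraction = 0.75,
                          control_min_detected_reps = 3L,
                          cv_max_percent = 40,
                          top_n = 30L,
                          membrane_terms = membrane_terms_default()) {
  stopifnot(detection_threshold > 0,
            presence_fraction > 0, presence_fraction <= 1,
            control_min_detected_reps >= 1,
            cv_max_percent > 0,
            top_n >= 1)
  structure(list(detection_threshold = detection_threshold,
                 presence_fraction = presence_fraction,
                 control_min_detected_reps = as.integer(control_min_detected_reps),
                 cv_max_percent = cv_max_percent,
                 top_n = as.integer(top_n),
                 membrane_terms = tolower(membrane_terms)),
            class = "screen_config")
}

#' Call per-line detection for one protein
#'
#' Cancer rule: detected iff the protein reached the normalized-area floor in
#' at least `presence_fraction` of replicates. Control rule: detected iff it
#' reached the floor in at least `control_min_detected_reps` replicates.
#'
#' @param n_detected replicates at or above the detection floor.
#' @param n_replicates_total total replicates for the line.
#' @param role `"cancer"` or `"control"`.
#' @param config a [screen_config()].
#' @return A list with `detected`, `n_detected`, `rule_applied`.
#' @export
call_detection <- function(n_detected, n_replicates_total,
                           role = c("cancer", "control"),
                           config = screen_config()) {
  role <- match.arg(role)
  stopifnot(n_replicates_total >= 1L, n_detected >= 0L,
            n_detected <= n_replicates_total)
  detected <- if (role == "cancer") {
    n_detected / n_replicates_total >= config$presence_fraction
  } else {
    n_detected >= config$control_min_detected_reps
  }
  list(detected = detected, n_detected = as.integer(n_detected),
       rule_applied = paste0(role, "-rule"))
}

detected_accessions <- function(summaries, role, config) {
  keep <- vapply(seq_len(nrow(summaries)), function(i)
    call_detection(summaries$n_detected[i], summaries$n_replicates_total[i],
                   role, config)$detected, logical(1L))
  summaries$accession[keep]
}

#' Build an annotation table from accession/localization pairs
#'
#' @param accession character vector (unique).
#' @param localization character vector; multiple terms separated by `;`.
#' @param membrane_terms vocabulary used to derive the `membrane_associated`
#'   flag (a protein is membrane-associated iff any of its terms is in the
#'   vocabulary).
#' @return data.frame with columns `accession`, `localization` (list of
#'   lowercased terms), `membrane_associated`.
#' @export
annotation_table <- function(accession, localization,
                             membrane_terms = membrane_terms_default()) {
  stopifnot(length(accession) == length(localization))
  if (anyDuplicated(accession)) stop("duplicate accessions in annotation")
  terms <- lapply(strsplit(as.character(localization), ";", fixed = TRUE),
                  function(x) tolower(trimws(x)))
  memb <- vapply(terms, function(t) any(t %in% tolower(membrane_terms)),
                 logical(1L))
  out <- data.frame(accession = as.character(accession),
                    membrane_associated = memb,
                    stringsAsFactors = FALSE)
  out$localization <- terms
  out
}

#' Refine protein summaries to membrane-associated proteins
#'
#' Retains proteins whose annotation carries a membrane localization term.
#' Proteins absent from the annotation are dropped and counted.
#'
#' @param summaries a `protein_summary` data.frame.
#' @param annotation an [annotation_table()].
#' @return The membrane-associated subset, with attributes `n_unannotated`
#'   and `n_non_membrane` recording what was dropped.
#' @export
filter_membrane <- function(summaries, annotation) {
  idx <- match(summaries$accession, annotation$accession)
  unannotated <- is.na(idx)
  memb <- !unannotated & annotation$membrane_associated[idx]
  if (any(unannotated)) {
    warning(sum(unannotated), " unannotated protein(s) dropped from ",
            "membrane refinement")
  }
  out <- summaries[which(memb), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unannotated") <- sum(unannotated)
  attr(out, "n_non_membrane") <- sum(!memb & !unannotated)
  out
}

#' Venn partition of two detected-protein sets
#'
#' @param detected_a,detected_b character vectors of accessions.
#' @return A list of class `venn_partition` with `common`, `unique_a`,
#'   `unique_b` member vectors and their counts.
#' @export
compute_venn <- function(detected_a, detected_b) {
  a <- unique(as.character(detected_a))
  b <- unique(as.character(detected_b))
  common <- sort(intersect(a, b))
  ua <- sort(setdiff(a, b))
  ub <- sort(setdiff(b, a))
  structure(list(common = common, unique_a = ua, unique_b = ub,
                 n_common = length(common), n_unique_a = length(ua),
                 n_unique_b = length(ub)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> common: %d | unique A: %d | unique B: %d\n",
              x$n_common, x$n_unique_a, x$n_unique_b))
  invisible(x)
}

#' Select ranked candidate proteins exclusive to a cancer line
#'
#' The full screening cascade: membrane refinement, detection under the
#' cancer rule, exclusion of proteins expressed in the control line (control
#' rule), CV ceiling, then ranking by mean normalized area (descending, ties
#' broken by accession) and truncation to the top N.
#'
#' "Only detected in the cancerous cell line" is operationalized as failure
#' of the control detection rule (fewer than `control_min_detected_reps`
#' control replicates at the floor), not as total absence from control
#' identifications.
#'
#' @param cancer_summaries,control_summaries `protein_summary` data.frames
#'   computed from normalized tables at the same detection threshold.
#' @param annotation an [annotation_table()].
#' @param config a [screen_config()].
#' @return A data.frame of class `candidate_table` with columns `rank`,
#'   `accession`, `gene`, `description`, `mean_norm_area`, `sd_norm_area`,
#'   `cv_percent`; the config used is attached as attribute `config`.
#' @export
select_candidates <- function(cancer_summaries, control_summaries,
                              annotation, config = screen_config()) {
  memb <- filter_membrane(cancer_summaries, annotation)
  cancer_ok <- vapply(seq_len(nrow(memb)), function(i)
    call_detection(memb$n_detected[i], memb$n_replicates_total[i],
                   "cancer", config)$detected, logical(1L))
  if (length(cancer_ok) == 0L) cancer_ok <- logical(0L)
  control_detected <- detected_accessions(control_summaries, "control", config)
  exclusive <- !(memb$accession %in% control_detected)
  cv_ok <- !is.na(memb$cv_percent) & memb$cv_percent <= config$cv_max_percent
  pass <- which(cancer_ok & exclusive & cv_ok)
  out <- memb[pass, c("accession", "gene", "description",
                      "mean_norm_area", "sd_norm_area", "cv_percent"),
              drop = FALSE]
  ord <- order(-out$mean_norm_area, out$accession)
  out <- out[ord, , drop = FALSE]
  out <- utils::head(out, config$top_n)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "n_pool") <- length(pass)
  class(out) <- c("candidate_table", "data.frame")
  out
}
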