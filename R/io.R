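#' Read a tab-separated protein quantification export
#'
#' Expected header: `Accession  Gene  Description  Area_<rep1> ...` (any
#' number of area columns; for already-normalized tables the columns are
#' named `NormArea_<rep>`). Empty cells, `"NA"` and literal zeros parse as
#' missing (a search engine reports no area for an unidentified protein).
#'
#' @param path file path.
#' @param cell_line label stored on the table (defaults to the file name).
#' @return A [quant_table()].
#' @export
read_quant_table <- function(path, cell_line = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  required <- c("Accession", "Gene", "Description")
  miss <- setdiff(required, names(d))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  area_cols <- grep("^(Norm)?Area_", names(d), value = TRUE)
  if (!length(area_cols)) stop("no Area_* replicate columns found")
  areas <- as.matrix(d[area_cols])
  if (!is.numeric(areas)) {
    bad <- which(!vapply(d[area_cols], is.numeric, logical(1L)))
    stop("non-numeric area column(s): ",
         paste(area_cols[bad], collapse = ", "))
  }
  normalized <- all(startsWith(area_cols, "NormArea_"))
  quant_table(d$Accession, areas, gene = d$Gene,
              description = d$Description,
              cell_line = if (is.null(cell_line)) basename(path) else cell_line,
              normalized = normalized)
}

#' Write a quantification table as tab-separated text
#'
#' Inverse of [read_quant_table()]: missing cells are written empty.
#'
#' @param table a [quant_table()].
#' @param path output path.
#' @export
write_quant_table <- function(table, path) {
  stopifnot(inherits(table, "quant_table"))
  d <- cbind(data.frame(Accession = table$proteins$accession,
                        Gene = table$proteins$gene,
                        Description = table$proteins$description,
                        stringsAsFactors = FALSE),
             as.data.frame(table$areas))
  utils::write.table(d, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write per-protein replicate summaries as tab-separated text
#'
#' @param summaries a `protein_summary` data.frame.
#' @param path output path.
#' @export
write_summary_table <- function(summaries, path) {
  d <- data.frame(Accession = summaries$accession,
                  Gene = summaries$gene,
                  Description = summaries$description,
                  N_Detected = summaries$n_detected,
                  Mean_NormArea = summaries$mean_norm_area,
                  SD = summaries$sd_norm_area,
                  CV_Percent = summaries$cv_percent)
  utils::write.table(d, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein localization annotation table
#'
#' Tab-separated with header `Accession  Localization`; multiple terms per
#' protein are separated by semicolons.
#'
#' @param path file path.
#' @param membrane_terms vocabulary for the membrane flag.
#' @return An [annotation_table()].
#' @export
read_annotation_table <- function(path,
                                  membrane_terms = membrane_terms_default()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("Accession", "Localization") %in% names(d))) {
    stop("annotation file needs 'Accession' and 'Localization' columns")
  }
  annotation_table(d$Accession, d$Localization, membrane_terms)
}

#' Write an annotation table
#' @param annotation an [annotation_table()].
#' @param path output path.
#' @export
write_annotation_table <- function(annotation, path) {
  d <- data.frame(Accession = annotation$accession,
                  Localization = vapply(annotation$localization,
                                        paste, character(1L),
                                        collapse = ";"))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a candidate table in the published two-table layout
#' @param candidates a `candidate_table` from [select_candidates()].
#' @param path output path.
#' @export
write_candidate_table <- function(candidates, path) {
  d <- data.frame(Accession = candidates$accession,
                  Gene = candidates$gene,
                  Protein = candidates$description,
                  Mean_NormArea = candidates$mean_norm_area,
                  SD = candidates$sd_norm_area,
                  CV_Percent = candidates$cv_percent)
  utils::write.table(d, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a Venn partition as JSON
#' @param venn a [compute_venn()] result.
#' @param path output path.
#' @export
write_venn_json <- function(venn, path) {
  jsonlite::write_json(
    list(common = venn$n_common, unique_a = venn$n_unique_a,
         unique_b = venn$n_unique_b,
         members = list(common = venn$common, unique_a = venn$unique_a,
                        unique_b = venn$unique_b)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a TMA cohort CSV
#'
#' Comma-separated with header
#' `case_id,tissue_class,ihc_score,age_group,pt_status,grade,ln_metastasis,stage,her2_status`;
#' empty cells are missing.
#'
#' @param path file path.
#' @return A data.frame of cases.
#' @export
read_tma_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"), fileEncoding = "UTF-8")
  required <- c("case_id", "tissue_class", "ihc_score")
  miss <- setdiff(required, names(d))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  d$ihc_score <- as.integer(d$ihc_score)
  d
}

#' Write a TMA cohort CSV
#' @param cases cohort data.frame.
#' @param path output path.
#' @export
write_tma_cohort <- function(cases, path) {
  utils::write.csv(cases, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a plate-layout dose-response CSV into dose-response datasets
#'
#' Expected header:
#' `drug,cotreatment_drug,cotreatment_dose_uM,concentration_uM,experiment,replicate,od570,od650`.
#' Rows with `concentration_uM == 0` are vehicle wells; viability of treated
#' wells is their background-corrected OD divided by the vehicle mean of the
#' same drug/cotreatment/experiment.
#'
#' @param path file path.
#' @return Named list of [dose_response()] objects, one per
#'   drug/cotreatment combination.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"), fileEncoding = "UTF-8")
  required <- c("drug", "concentration_uM", "experiment", "od570", "od650")
  miss <- setdiff(required, names(d))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(d$cotreatment_drug)) d$cotreatment_drug <- NA_character_
  if (is.null(d$cotreatment_dose_uM)) d$cotreatment_dose_uM <- NA_real_
  if (is.null(d$replicate)) d$replicate <- NA_integer_
  key <- paste(d$drug,
               ifelse(is.na(d$cotreatment_drug), "",
                      paste0("+", d$cotreatment_drug, "_",
                             d$cotreatment_dose_uM)),
               sep = "")
  out <- lapply(split(d, key), function(g) {
    vehicle <- g[g$concentration_uM == 0, , drop = FALSE]
    treated <- g[g$concentration_uM > 0, , drop = FALSE]
    if (nrow(vehicle) == 0L) stop("no vehicle (concentration 0) wells for '",
                                  g$drug[1L], "'")
    viab <- numeric(nrow(treated))
    for (ex in unique(treated$experiment)) {
      vm <- mean(vehicle$od570[vehicle$experiment == ex] -
                   vehicle$od650[vehicle$experiment == ex])
      sel <- treated$experiment == ex
      viab[sel] <- viability_from_od(treated$od570[sel], treated$od650[sel],
                                     vm)
    }
    cot <- if (!is.na(treated$cotreatment_drug[1L])) {
      list(drug = treated$cotreatment_drug[1L],
           dose_uM = treated$cotreatment_dose_uM[1L])
    } else NULL
    dose_response(treated$drug[1L], treated$concentration_uM, viab,
                  treated$experiment, treated$replicate, cotreatment = cot)
  })
  out
}

new_run_log <- function(seed = NA_integer_) {
  env <- new.env(parent = emptyenv())
  env$events <- list()
  env$seed <- seed
  env$started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  env
}

log_event <- function(log, stage, message, ...) {
  log$events[[length(log$events) + 1L]] <-
    list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         stage = stage, message = message, detail = list(...))
  invisible(log)
}

run_log_as_list <- function(log) {
  list(started = log$started, seed = log$seed,
       package_version = as.character(utils::packageVersion("memscreen")),
       events = log$events)
}

#' Run the full screening pipeline on two cancer lines and a control line
#'
#' Orchestrates the analysis in its natural order: normalize each table,
#' summarize replicates, refine to membrane-associated proteins, compare
#' each cancer line's detected membrane proteins with the control line
#' (Venn partition), and select ranked candidate tables. When `out_dir` is
#' given, all artifacts (normalized tables, summaries, Venn JSONs,
#' candidate TSVs, run log) are written there.
#'
#' @param cancer_tables named list of raw [quant_table()]s for the cancer
#'   lines.
#' @param control_table raw [quant_table()] for the benign control line.
#' @param annotation an [annotation_table()].
#' @param config a [screen_config()].
#' @param out_dir optional output directory.
#' @param seed seed recorded in the run log (the screen itself is
#'   deterministic).
#' @return A list of class `pipeline_result`: `normalized`, `summaries`,
#'   `venn`, `candidates` (per cancer line), `control_summaries`, `log`.
#' @export
run_pipeline <- function(cancer_tables, control_table, annotation,
                         config = screen_config(), out_dir = NULL,
                         seed = NA_integer_) {
  stopifnot(is.list(cancer_tables), length(cancer_tables) >= 1L,
            inherits(control_table, "quant_table"))
  if (is.null(names(cancer_tables))) {
    names(cancer_tables) <- paste0("cancer_", seq_along(cancer_tables))
  }
  log <- new_run_log(seed)
  log_event(log, "config", "screen configuration",
            config = unclass(config)[setdiff(names(config), "membrane_terms")])

  norm_control <- normalize_table(control_table)
  control_sum <- summarize_quant_table(norm_control, config$detection_threshold)
  log_event(log, "normalize", "control line normalized",
            n_proteins = nrow(norm_control$areas))
  control_membrane <- suppressWarnings(filter_membrane(control_sum, annotation))
  control_detected <- detected_accessions(control_membrane, "control", config)

  normalized <- list(); summaries <- list()
  venn <- list(); candidates <- list()
  for (nm in names(cancer_tables)) {
    norm <- normalize_table(cancer_tables[[nm]])
    summ <- summarize_quant_table(norm, config$detection_threshold)
    log_event(log, "normalize", paste0("cancer line '", nm, "' normalized"),
              n_proteins = nrow(norm$areas))
    memb <- suppressWarnings(filter_membrane(summ, annotation))
    log_event(log, "membrane_filter", nm,
              n_membrane = nrow(memb),
              n_unannotated = attr(memb, "n_unannotated"),
              n_non_membrane = attr(memb, "n_non_membrane"))
    detected <- detected_accessions(memb, "cancer", config)
    venn[[nm]] <- compute_venn(detected, control_detected)
    candidates[[nm]] <- select_candidates(summ, control_sum, annotation,
                                          config)
    log_event(log, "screen", nm,
              n_detected = length(detected),
              n_candidates = nrow(candidates[[nm]]))
    normalized[[nm]] <- norm
    summaries[[nm]] <- summ
  }

  result <- structure(list(normalized = normalized, summaries = summaries,
                           control_normalized = norm_control,
                           control_summaries = control_sum,
                           venn = venn, candidates = candidates,
                           config = config, log = run_log_as_list(log)),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_quant_table(norm_control, file.path(out_dir, "control_normalized.tsv"))
    write_summary_table(control_sum, file.path(out_dir, "control_summary.tsv"))
    for (nm in names(cancer_tables)) {
      write_quant_table(normalized[[nm]],
                        file.path(out_dir, paste0(nm, "_normalized.tsv")))
      write_summary_table(summaries[[nm]],
                          file.path(out_dir, paste0(nm, "_summary.tsv")))
      write_venn_json(venn[[nm]], file.path(out_dir, paste0(nm, "_venn.json")))
      write_candidate_table(candidates[[nm]],
                            file.path(out_dir, paste0(nm, "_candidates.tsv")))
    }
    jsonlite::write_json(result$log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in names(x$candidates)) {
    cat(sprintf("  %s: venn %d/%d/%d (common/unique cancer/unique control), %d candidates\n",
                nm, x$venn[[nm]]$n_common, x$venn[[nm]]$n_unique_a,
                x$venn[[nm]]$n_unique_b, nrow(x$candidates[[nm]])))
  }
  invisible(x)
}
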