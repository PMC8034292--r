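#' Configuration for the synthetic quantification experiment
#'
#' Emulates a four-replicate label-free membrane-proteomics design: roughly
#' 2300 proteins identified per cell line of which about a quarter are
#' membrane-associated, log-normal raw peak areas, multiplicative replicate
#' noise at a target CV, abundance-dependent dropout, and a planted set of
#' cancer-exclusive membrane proteins per cancer line.
#'
#' @param n_proteins shared protein universe size.
#' @param membrane_fraction fraction of the universe annotated to membrane
#'   localizations.
#' @param n_replicates biological replicates per cell line.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of true
#'   raw peak areas (arbitrary intensity units).
#' @param replicate_cv target coefficient of variation of the multiplicative
#'   log-normal replicate noise (0 = noise-free).
#' @param dropout either a single probability in `[0, 1)` (uniform dropout)
#'   or a `list(max =, midpoint_log =, slope =)` for abundance-dependent
#'   dropout `p(a) = max * plogis(-(log(a) - midpoint_log) * slope)`
#'   (low-abundance proteins are missed preferentially, as in
#'   data-dependent acquisition). Default: logistic with max 0.5 centred
#'   2.75 log units below the abundance mean.
#' @param n_exclusive_cancer planted cancer-only membrane proteins per
#'   cancer line (disjoint between lines).
#' @param exclusive_abundance_boost multiplicative abundance boost of the
#'   planted proteins; their base abundance is drawn from the upper half of
#'   the abundance distribution so the planted targets emulate abundant,
#'   reliably detected candidates.
#' @param exclusive_control_mode `"absent"` (planted proteins have no signal
#'   at all in the control line) or `"trace"` (present at a low abundance
#'   that normalizes below a typical detection floor).
#' @return A list of class `synth_quant_config`.
#' @export
synth_quant_config <- function(n_proteins = 2300L,
                               membrane_fraction = 0.26,
                               n_replicates = 4L,
                               abundance_meanlog = 13,
                               abundance_sdlog = 1.5,
                               replicate_cv = 0.20,
                               dropout = list(max = 0.5,
                                              midpoint_log = 10.25,
                                              slope = 1.2),
                               n_exclusive_cancer = 30L,
                               exclusive_abundance_boost = 8,
                               exclusive_control_mode = c("absent", "trace")) {
  stopifnot(n_proteins >= 10L, membrane_fraction > 0, membrane_fraction <= 1,
            n_replicates >= 1L, replicate_cv >= 0,
            n_exclusive_cancer >= 0L, exclusive_abundance_boost >= 1)
  n_membrane <- round(n_proteins * membrane_fraction)
  if (2L * n_exclusive_cancer > n_membrane) {
    stop("n_exclusive_cancer too large for the membrane protein count")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 membrane_fraction = membrane_fraction,
                 n_replicates = as.integer(n_replicates),
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 replicate_cv = replicate_cv,
                 dropout = dropout,
                 n_exclusive_cancer = as.integer(n_exclusive_cancer),
                 exclusive_abundance_boost = exclusive_abundance_boost,
                 exclusive_control_mode = match.arg(exclusive_control_mode)),
            class = "synth_quant_config")
}

dropout_prob <- function(abundance, dropout) {
  if (is.numeric(dropout) && length(dropout) == 1L) {
    rep(dropout, length(abundance))
  } else {
    dropout$max * stats::plogis(-(log(abundance) - dropout$midpoint_log) *
                                  dropout$slope)
  }
}

sim_cell_line_table <- function(cell_line, accession, gene, description,
                                abundance, config) {
  n <- length(abundance)
  sdlog_rep <- if (config$replicate_cv > 0) {
    sqrt(log(1 + config$replicate_cv^2))
  } else 0
  areas <- matrix(NA_real_, n, config$n_replicates,
                  dimnames = list(accession,
                                  paste0("Area_rep", seq_len(config$n_replicates))))
  p_drop <- dropout_prob(abundance, config$dropout)
  for (j in seq_len(config$n_replicates)) {
    noise <- if (sdlog_rep > 0) {
      stats::rlnorm(n, meanlog = -sdlog_rep^2 / 2, sdlog = sdlog_rep)
    } else rep(1, n)
    vals <- abundance * noise
    vals[stats::runif(n) < p_drop] <- NA_real_
    areas[, j] <- vals
  }
  keep <- !is.na(abundance) & abundance > 0
  # a protein absent in the line (zero abundance) contributes no rows;
  # proteins dropped out in every replicate are also removed, as an
  # identification engine would never report them
  observed <- keep & rowSums(!is.na(areas)) > 0L
  quant_table(accession[observed], areas[observed, , drop = FALSE],
              gene = gene[observed], description = description[observed],
              cell_line = cell_line)
}

#' Simulate a three-cell-line quantification experiment with ground truth
#'
#' Generates raw quantification tables for two cancer lines and one benign
#' control line sharing a protein universe, an annotation table, and the
#' ground truth needed for recovery testing. Planted cancer-exclusive
#' membrane proteins carry abundant, consistent signal in their cancer line
#' and (by default) no signal at all in the control line.
#'
#' @param config a [synth_quant_config()].
#' @param seed integer seed; the simulation is fully deterministic given it.
#' @return A list: `tables` (named `cancer_a`, `cancer_b`, `control`
#'   [quant_table()]s), `annotation` ([annotation_table()]), `ground_truth`
#'   (planted exclusive accessions per line, true abundances, config echo,
#'   seed).
#' @export
sim_quant_experiment <- function(config = synth_quant_config(), seed) {
  stopifnot(inherits(config, "synth_quant_config"))
  if (missing(seed)) stop("'seed' is required for reproducibility")
  set.seed(seed)
  n <- config$n_proteins
  accession <- sprintf("SYN%05d", seq_len(n))
  gene <- sprintf("GENE%04d", seq_len(n))
  description <- sprintf("synthetic protein %d", seq_len(n))
  n_membrane <- round(n * config$membrane_fraction)
  membrane <- seq_len(n_membrane)  # first block is membrane-annotated
  k <- config$n_exclusive_cancer
  excl_a <- membrane[seq_len(k)]
  excl_b <- membrane[k + seq_len(k)]

  base <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  # planted exclusives: upper-half abundance draw times the boost, so the
  # planted targets are reliably above any sensible detection floor
  upper_half <- function(m) exp(config$abundance_meanlog +
                                  abs(stats::rnorm(m)) * config$abundance_sdlog)
  base[excl_a] <- upper_half(k) * config$exclusive_abundance_boost
  base[excl_b] <- upper_half(k) * config$exclusive_abundance_boost

  ab_a <- base; ab_a[excl_b] <- 0
  ab_b <- base; ab_b[excl_a] <- 0
  ab_c <- base
  trace_level <- exp(config$abundance_meanlog - 3 * config$abundance_sdlog)
  ab_c[c(excl_a, excl_b)] <- if (config$exclusive_control_mode == "trace") {
    trace_level
  } else 0

  tables <- list(
    cancer_a = sim_cell_line_table("cancer_a", accession, gene, description,
                                   ab_a, config),
    cancer_b = sim_cell_line_table("cancer_b", accession, gene, description,
                                   ab_b, config),
    control = sim_cell_line_table("control", accession, gene, description,
                                  ab_c, config))

  non_membrane_terms <- c("cytoplasm", "nucleus", "cytosol", "secreted")
  memb_terms <- membrane_terms_default()
  loc <- character(n)
  loc[membrane] <- sample(memb_terms, n_membrane, replace = TRUE)
  loc[-membrane] <- sample(non_membrane_terms, n - n_membrane, replace = TRUE)
  annotation <- annotation_table(accession, loc)

  list(tables = tables,
       annotation = annotation,
       ground_truth = list(exclusive_cancer_a = accession[excl_a],
                           exclusive_cancer_b = accession[excl_b],
                           membrane_accessions = accession[membrane],
                           true_abundance = list(cancer_a = ab_a,
                                                 cancer_b = ab_b,
                                                 control = ab_c),
                           accession = accession,
                           config = config, seed = seed))
}

#' Configuration for the synthetic TMA cohort
#'
#' Emulates a two-group tissue-microarray cohort: benign and carcinoma
#' cases, group-dependent IHC positivity probability (defaults 0 and 0.49),
#' covariates sampled from stated level frequencies, and a logistic
#' positivity model so per-covariate odds ratios can be planted.
#'
#' @param n_benign,n_cancer group sizes.
#' @param positivity_prob_benign,positivity_prob_cancer baseline probability
#'   that a case is IHC-positive (score >= 2).
#' @param positive_score_weights sampling weights of scores 2, 3, 4 within
#'   positive cases.
#' @param covariate_levels named list of named frequency vectors for the
#'   carcinoma covariates.
#' @param covariate_log_or named list (same names) of per-level log odds
#'   ratios added to the positivity logit (first level is reference);
#'   `NULL` = no covariate effects.
#' @param missing_covariate_rate named list or single rate of per-covariate
#'   missingness.
#' @param prob_missing_score probability a case's core is unevaluable.
#' @return A list of class `synth_tma_config`.
#' @export
synth_tma_config <- function(n_benign = 18L, n_cancer = 42L,
                             positivity_prob_benign = 0,
                             positivity_prob_cancer = 0.49,
                             positive_score_weights = c(0.4, 0.35, 0.25),
                             covariate_levels = list(
                               age_group = c(">40" = 0.59, "<=40" = 0.41),
                               pt_status = c(T2 = 0.7, T3 = 0.3),
                               grade = c("II" = 0.33, "II~III" = 0.27,
                                         "III" = 0.40),
                               ln_metastasis = c(negative = 0.5,
                                                 positive = 0.5),
                               stage = c(IIA = 0.29, IIB = 0.57, IIIA = 0.14),
                               her2_status = c(negative = 0.51,
                                               positive = 0.49)),
                             covariate_log_or = NULL,
                             missing_covariate_rate = 0.1,
                             prob_missing_score = 0) {
  stopifnot(n_benign >= 1L, n_cancer >= 1L,
            positivity_prob_benign >= 0, positivity_prob_benign <= 1,
            positivity_prob_cancer >= 0, positivity_prob_cancer <= 1)
  structure(list(n_benign = as.integer(n_benign),
                 n_cancer = as.integer(n_cancer),
                 positivity_prob_benign = positivity_prob_benign,
                 positivity_prob_cancer = positivity_prob_cancer,
                 positive_score_weights = positive_score_weights,
                 covariate_levels = covariate_levels,
                 covariate_log_or = covariate_log_or,
                 missing_covariate_rate = missing_covariate_rate,
                 prob_missing_score = prob_missing_score),
            class = "synth_tma_config")
}

#' Simulate a TMA cohort with ground truth
#'
#' Benign cases are positive with `positivity_prob_benign`; carcinoma
#' positivity follows a logistic model whose intercept reproduces
#' `positivity_prob_cancer` at the covariate reference levels and whose
#' slopes are the configured per-level log odds ratios. Positive cases get
#' scores 2-4 (configured weights), negative cases score 1.
#'
#' @param config a [synth_tma_config()].
#' @param seed integer seed.
#' @return A list: `cases` (data.frame in the layout of
#'   [steap4_tma_cohort()]) and `ground_truth`.
#' @export
sim_tma_cohort <- function(config = synth_tma_config(), seed) {
  stopifnot(inherits(config, "synth_tma_config"))
  if (missing(seed)) stop("'seed' is required for reproducibility")
  set.seed(seed)
  nb <- config$n_benign; nc <- config$n_cancer
  covs <- names(config$covariate_levels)
  miss_rate <- config$missing_covariate_rate
  if (!is.list(miss_rate)) {
    miss_rate <- stats::setNames(as.list(rep(miss_rate, length(covs))), covs)
  }
  cancer_cov <- lapply(covs, function(cv) {
    freq <- config$covariate_levels[[cv]]
    v <- sample(names(freq), nc, replace = TRUE, prob = freq)
    v[stats::runif(nc) < miss_rate[[cv]]] <- NA_character_
    v
  })
  names(cancer_cov) <- covs
  # logistic positivity: intercept at the configured baseline probability,
  # per-level log odds ratios added for non-reference observed levels
  eta <- rep(stats::qlogis(min(max(config$positivity_prob_cancer, 1e-9),
                               1 - 1e-9)), nc)
  if (!is.null(config$covariate_log_or)) {
    for (cv in names(config$covariate_log_or)) {
      lor <- config$covariate_log_or[[cv]]
      v <- cancer_cov[[cv]]
      for (lev in names(lor)) eta <- eta + ifelse(!is.na(v) & v == lev,
                                                  lor[[lev]], 0)
    }
  }
  p_cancer <- stats::plogis(eta)
  cancer_pos <- stats::runif(nc) < p_cancer
  benign_pos <- stats::runif(nb) < config$positivity_prob_benign
  draw_score <- function(pos) {
    ifelse(pos,
           sample(2:4, length(pos), replace = TRUE,
                  prob = config$positive_score_weights),
           1L)
  }
  cases <- rbind(
    data.frame(case_id = sprintf("SB%03d", seq_len(nb)),
               tissue_class = "normal_benign",
               ihc_score = draw_score(benign_pos),
               age_group = NA_character_, pt_status = NA_character_,
               grade = NA_character_, ln_metastasis = NA_character_,
               stage = NA_character_, her2_status = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(case_id = sprintf("SC%03d", seq_len(nc)),
               tissue_class = "carcinoma",
               ihc_score = draw_score(cancer_pos),
               age_group = cancer_cov$age_group,
               pt_status = cancer_cov$pt_status,
               grade = cancer_cov$grade,
               ln_metastasis = cancer_cov$ln_metastasis,
               stage = cancer_cov$stage,
               her2_status = cancer_cov$her2_status,
               stringsAsFactors = FALSE))
  cases$ihc_score[stats::runif(nrow(cases)) < config$prob_missing_score] <-
    NA_integer_
  rownames(cases) <- NULL
  list(cases = cases,
       ground_truth = list(positive = c(benign_pos, cancer_pos),
                           positivity_prob = p_cancer,
                           config = config, seed = seed))
}

#' Configuration for synthetic dose-response experiments
#'
#' Emulates the MTT viability design: an 8-point log-spaced dose grid from
#' 0.01 to 30 uM, three independent experiments in triplicate, Gaussian
#' noise on the viability fraction (truncated at 0). Conditions are named
#' 4PL parameter sets; the defaults mirror a monotherapy curve (IC50 2.3
#' uM) and a fixed-dose combination curve (IC50 1.0 uM with a deeper
#' bottom, i.e. ~60% maximal inhibition).
#'
#' @param conditions named list; each element is
#'   `list(bottom =, top =, hill =, ic50 =)`.
#' @param doses_uM dose grid in micromolar.
#' @param n_experiments,n_replicates independent experiments and
#'   within-experiment replicates.
#' @param noise_sd additive Gaussian SD on the viability fraction.
#' @return A list of class `synth_dose_config`.
#' @export
synth_dose_config <- function(conditions = list(
                                mono = list(bottom = 0.50, top = 1,
                                            hill = 1, ic50 = 2.3),
                                combo = list(bottom = 0.40, top = 1,
                                             hill = 1, ic50 = 1.0)),
                              doses_uM = 10^seq(log10(0.01), log10(30),
                                                length.out = 8),
                              n_experiments = 3L, n_replicates = 3L,
                              noise_sd = 0.05) {
  stopifnot(all(doses_uM > 0), noise_sd >= 0,
            n_experiments >= 1L, n_replicates >= 1L)
  structure(list(conditions = conditions, doses_uM = sort(doses_uM),
                 n_experiments = as.integer(n_experiments),
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd),
            class = "synth_dose_config")
}

#' Simulate dose-response datasets with ground truth
#'
#' @param config a [synth_dose_config()].
#' @param seed integer seed.
#' @return A list: `datasets` (named list of [dose_response()] objects, one
#'   per condition) and `ground_truth` (true 4PL parameters, config, seed).
#' @export
sim_dose_response <- function(config = synth_dose_config(), seed) {
  stopifnot(inherits(config, "synth_dose_config"))
  if (missing(seed)) stop("'seed' is required for reproducibility")
  set.seed(seed)
  grid <- expand.grid(concentration_uM = config$doses_uM,
                      experiment = seq_len(config$n_experiments),
                      replicate = seq_len(config$n_replicates))
  datasets <- lapply(names(config$conditions), function(nm) {
    p <- config$conditions[[nm]]
    mu <- fourpl(grid$concentration_uM, p$bottom, p$top, p$hill, p$ic50)
    y <- pmax(mu + stats::rnorm(nrow(grid), sd = config$noise_sd), 0)
    dose_response(drug = nm, concentration_uM = grid$concentration_uM,
                  viability = y, experiment = grid$experiment,
                  replicate = grid$replicate)
  })
  names(datasets) <- names(config$conditions)
  list(datasets = datasets,
       ground_truth = list(conditions = config$conditions,
                           config = config, seed = seed))
}
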