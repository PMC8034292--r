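#' Binarize an IHC staining score
#'
#' IHC cores are graded on an ordinal 1-4 scale: negative (1), weak (2),
#' moderate (3), strong (4). Two dichotomizations are supported:
#' `"intensity"` maps 1-2 to `"low"` and 3-4 to `"high"`; `"positivity"`
#' (the default used for positive-versus-negative association tables) maps
#' 1 to `"negative"` and 2-4 to `"positive"`.
#'
#' @param score integer vector of scores in 1..4 (`NA` allowed).
#' @param rule `"positivity"` or `"intensity"`.
#' @return Character vector of labels (`NA` preserved).
#' @export
binarize_score <- function(score, rule = c("positivity", "intensity")) {
  rule <- match.arg(rule)
  bad <- !is.na(score) & !(score %in% 1:4)
  if (any(bad)) {
    stop("IHC score out of 1..4 scale: ",
         paste(unique(score[bad]), collapse = ", "))
  }
  if (rule == "positivity") {
    ifelse(is.na(score), NA_character_,
           ifelse(score >= 2, "positive", "negative"))
  } else {
    ifelse(is.na(score), NA_character_,
           ifelse(score >= 3, "high", "low"))
  }
}

#' Build a covariate-by-expression contingency table from TMA cases
#'
#' Cases missing the IHC score or the requested covariate are dropped (their
#' count is reported as an attribute); remaining cases are cross-tabulated
#' as covariate level x binarized expression.
#'
#' @param cases data.frame of TMA cases; must contain `ihc_score` and the
#'   requested covariate column.
#' @param covariate name of the covariate column.
#' @param rule dichotomization rule passed to [binarize_score()].
#' @return An integer matrix (levels x c("positive","negative") or
#'   ("high","low")) with attribute `n_dropped`.
#' @export
build_contingency <- function(cases, covariate, rule = "positivity") {
  stopifnot(is.data.frame(cases), "ihc_score" %in% names(cases))
  if (!covariate %in% names(cases)) {
    stop("covariate '", covariate, "' not found in cases")
  }
  lab <- binarize_score(cases$ihc_score, rule)
  lev <- as.character(cases[[covariate]])
  keep <- !is.na(lab) & !is.na(lev) & nzchar(lev)
  n_dropped <- sum(!keep)
  lab <- lab[keep]; lev <- lev[keep]
  if (length(unique(lev)) < 2L) {
    stop("degenerate table: fewer than 2 observed levels of '",
         covariate, "' after dropping incomplete cases")
  }
  cols <- if (rule == "positivity") c("positive", "negative")
          else c("high", "low")
  tab <- table(factor(lev, levels = sort(unique(lev))),
               factor(lab, levels = cols))
  out <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Classic Pearson statistic sum((O-E)^2/E) with expected counts from the
#' product of the margins, no continuity correction, p-value from the
#' upper tail of the chi-square distribution at (r-1)(c-1) degrees of
#' freedom. A warning flag is set when any expected count is below 5 (the
#' test is still performed).
#'
#' @param table non-negative integer matrix, at least 2x2, with positive
#'   row and column totals.
#' @return A list of class `chisq_result`: `statistic`, `df`, `p_value`,
#'   `expected`, `low_expected_warning`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("table must be at least 2x2")
  if (any(table < 0)) stop("negative counts")
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (n <= 0) stop("empty table")
  if (any(rs == 0)) stop("zero row margin: ",
                         paste(rownames(table)[rs == 0], collapse = ", "))
  if (any(cs == 0)) stop("zero column margin: ",
                         paste(colnames(table)[cs == 0], collapse = ", "))
  expected <- outer(rs, cs) / n
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  structure(list(statistic = stat,
                 df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = expected,
                 low_expected_warning = any(expected < 5)),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.4f, df = %d, p = %.4f%s\n",
              x$statistic, x$df, x$p_value,
              if (x$low_expected_warning) "  [expected count < 5]" else ""))
  invisible(x)
}

#' Monte-Carlo permutation p-value for a contingency table
#'
#' Independent oracle for [pearson_chi_square()]: samples tables from the
#' independence null with both margins fixed (multivariate hypergeometric,
#' via [stats::r2dtable()]) and reports the fraction with a Pearson
#' statistic at least as large as observed.
#'
#' The fixed-margin null is discrete, so ties with the observed statistic
#' carry non-negligible probability mass; `p_value` counts the whole tie
#' mass (the usual conservative MC p) while `mid_p` counts half of it,
#' which is the quantity a continuous approximation targets.
#'
#' @param table contingency matrix.
#' @param n_draws number of null tables.
#' @return List with `p_value`, `mid_p`, `mc_se` (binomial standard
#'   error), `n_draws`.
#' @export
chi_square_permutation_p <- function(table, n_draws = 100000L) {
  table <- as.matrix(table)
  obs <- pearson_chi_square(table)$statistic
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  expected <- outer(rs, cs) / n
  draws <- stats::r2dtable(n_draws, rs, cs)
  stats_null <- vapply(draws, function(m) sum((m - expected)^2 / expected),
                       numeric(1L))
  # tolerance guards ties against floating-point noise
  p <- mean(stats_null >= obs - 1e-9)
  tie <- mean(abs(stats_null - obs) <= 1e-9)
  list(p_value = p, mid_p = p - tie / 2,
       mc_se = sqrt(p * (1 - p) / n_draws), n_draws = n_draws)
}

tma_covariates <- c("age_group", "pt_status", "grade", "ln_metastasis",
                    "stage", "her2_status")

#' Chi-square association report for a TMA cohort
#'
#' Runs the benign-versus-carcinoma expression comparison on all evaluable
#' cases, then one chi-square test per clinicopathological covariate on the
#' carcinoma cases only (cases missing a covariate are dropped per
#' comparison, never imputed). Significance is flagged at p < 0.05.
#'
#' @param cases data.frame with columns `case_id`, `tissue_class`
#'   (`"normal_benign"` / `"carcinoma"`), `ihc_score` (1-4 or `NA`), and any
#'   of the covariate columns `age_group`, `pt_status`, `grade`,
#'   `ln_metastasis`, `stage`, `her2_status`.
#' @param rule dichotomization rule for scores (default `"positivity"`:
#'   score 1 = negative, 2-4 = positive).
#' @param alpha significance level for the `significant` flag.
#' @return A list of class `tma_report`: `summary` (one row per comparison
#'   with statistic, df, p_value, n_used, n_dropped, low-expected flag,
#'   significance), `tables` (the contingency matrices), `results` (full
#'   `chisq_result` objects), `positivity` (positive / evaluable carcinoma
#'   counts and percent), and the rule used.
#' @export
association_report <- function(cases, rule = "positivity", alpha = 0.05) {
  stopifnot(all(c("tissue_class", "ihc_score") %in% names(cases)))
  comparisons <- c("tissue_class",
                   intersect(tma_covariates, names(cases)))
  carcinoma <- cases[cases$tissue_class == "carcinoma", , drop = FALSE]
  tables <- list(); results <- list(); rows <- list()
  for (cov in comparisons) {
    input <- if (cov == "tissue_class") cases else carcinoma
    res <- tryCatch({
      tab <- build_contingency(input, cov, rule)
      list(tab = tab, test = pearson_chi_square(tab))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[cov]] <- data.frame(comparison = cov, statistic = NA_real_,
                                df = NA_integer_, p_value = NA_real_,
                                n_used = 0L, n_dropped = nrow(input),
                                low_expected = NA, significant = NA,
                                note = conditionMessage(res))
      next
    }
    tables[[cov]] <- res$tab
    results[[cov]] <- res$test
    rows[[cov]] <- data.frame(
      comparison = cov,
      statistic = res$test$statistic,
      df = res$test$df,
      p_value = res$test$p_value,
      n_used = sum(res$tab),
      n_dropped = attr(res$tab, "n_dropped"),
      low_expected = res$test$low_expected_warning,
      significant = res$test$p_value < alpha,
      note = "")
  }
  lab <- binarize_score(carcinoma$ihc_score, rule)
  n_eval <- sum(!is.na(lab))
  n_pos <- sum(lab == "positive", na.rm = TRUE)
  structure(list(summary = do.call(rbind, c(rows,
                                            list(make.row.names = FALSE))),
                 tables = tables,
                 results = results,
                 positivity = list(n_positive = n_pos, n_evaluable = n_eval,
                                   percent = if (n_eval > 0)
                                     100 * n_pos / n_eval else NA_real_),
                 rule = rule, alpha = alpha),
            class = "tma_report")
}

#' @export
print.tma_report <- function(x, ...) {
  cat("<tma_report> dichotomization rule:", x$rule, "\n")
  s <- x$summary
  s$p_value <- sprintf("%.4f", s$p_value)
  print(s[, c("comparison", "statistic", "df", "p_value", "n_used",
              "n_dropped", "significant")], row.names = FALSE)
  cat(sprintf("carcinoma positivity: %d/%d (%.0f%%)\n",
              x$positivity$n_positive, x$positivity$n_evaluable,
              x$positivity$percent))
  invisible(x)
}
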