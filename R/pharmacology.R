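#' Background-corrected viability fraction from MTT optical densities
#'
#' MTT absorbance is read at 570 nm with a 650 nm reference; the corrected
#' signal (OD570 - OD650) is expressed as a fraction of the vehicle-control
#' mean and floored at zero (a negative background-corrected signal carries
#' no biological meaning; stimulation above 1 is kept).
#'
#' @param od570,od650 optical densities (vectorized).
#' @param vehicle_mean mean background-corrected OD of the vehicle wells.
#' @return Viability fraction(s), >= 0.
#' @export
viability_from_od <- function(od570, od650, vehicle_mean) {
  if (any(vehicle_mean <= 0)) stop("vehicle mean must be positive")
  pmax((od570 - od650) / vehicle_mean, 0)
}

#' Assemble a dose-response dataset
#'
#' @param drug drug label.
#' @param concentration_uM dose in micromolar for each well (vehicle wells
#'   excluded; all doses must be positive).
#' @param viability fraction-of-vehicle viability for each well.
#' @param experiment independent-experiment index for each well.
#' @param replicate within-experiment replicate index (optional).
#' @param cotreatment optional `list(drug =, dose_uM =)` describing a fixed
#'   co-administered dose.
#' @param max_tested_uM highest dose actually tested (defaults to the
#'   largest concentration); IC50 estimates beyond it are flagged as
#'   extrapolated.
#' @return A list of class `dose_response` with a long-format `data` table.
#' @export
dose_response <- function(drug, concentration_uM, viability, experiment,
                          replicate = NULL, cotreatment = NULL,
                          max_tested_uM = NULL) {
  stopifnot(length(concentration_uM) == length(viability),
            length(experiment) == length(viability))
  if (any(concentration_uM <= 0)) stop("concentrations must be positive")
  if (any(viability < 0)) stop("viability fractions must be >= 0")
  d <- data.frame(concentration_uM = concentration_uM,
                  viability = viability,
                  experiment = experiment,
                  replicate = if (is.null(replicate)) NA_integer_
                              else replicate)
  d <- d[order(d$concentration_uM, d$experiment), , drop = FALSE]
  rownames(d) <- NULL
  structure(list(drug = drug, cotreatment = cotreatment, data = d,
                 n_experiments = length(unique(experiment)),
                 max_tested_uM = if (is.null(max_tested_uM))
                   max(concentration_uM) else max_tested_uM),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> %s%s: %d doses (%g-%g uM), %d experiments, %d wells\n",
              x$drug,
              if (!is.null(x$cotreatment))
                sprintf(" + %s %g uM", x$cotreatment$drug,
                        x$cotreatment$dose_uM) else "",
              length(unique(x$data$concentration_uM)),
              min(x$data$concentration_uM), max(x$data$concentration_uM),
              x$n_experiments, nrow(x$data)))
  invisible(x)
}

#' Evaluate the four-parameter logistic dose-response model
#'
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)`. With `hill > 0`
#' and `top > bottom` the curve decreases from `top` (low dose) to `bottom`
#' (high dose) and equals the exact midpoint `(top + bottom) / 2` at
#' `x = ic50`.
#'
#' @param x dose (same units as `ic50`).
#' @param bottom,top asymptotic responses.
#' @param hill Hill slope (> 0 for a decreasing viability curve).
#' @param ic50 dose of half-maximal response.
#' @export
fourpl <- function(x, bottom, top, hill, ic50) {
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

# global fit: bottom/top/hill shared across experiments, one log10(IC50)
# per experiment; shrinks per-experiment IC50 variance by borrowing the
# curve shape across the whole dataset
fit_4pl_shared <- function(d, conc_range, start_shape) {
  exps <- sort(unique(d$experiment))
  ne <- length(exps)
  dd <- data.frame(lx = log10(d$concentration_uM), y = d$viability,
                   ei = match(d$experiment, exps))
  lterm <- paste(sprintf("l%d * (ei == %d)", seq_len(ne), seq_len(ne)),
                 collapse = " + ")
  fml <- stats::as.formula(paste0(
    "y ~ bottom + (top - bottom) / (1 + 10^(hill * (lx - (", lterm, "))))"))
  lo_l <- log10(min(conc_range) / 100); hi_l <- log10(max(conc_range) * 100)
  lic0 <- min(max(log10(start_shape$ic50), lo_l), hi_l)
  start <- c(list(bottom = start_shape$bottom, top = start_shape$top,
                  hill = start_shape$hill_slope),
             stats::setNames(as.list(rep(lic0, ne)),
                             paste0("l", seq_len(ne))))
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = dd, start = start,
                      lower = c(-Inf, -Inf, 0.1, rep(lo_l, ne)),
                      upper = c(Inf, Inf, 10, rep(hi_l, ne)),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  10^unname(cf[paste0("l", seq_len(ne))])
}

fit_4pl_once <- function(conc, viab, conc_range) {
  means <- tapply(viab, conc, mean)
  doses <- as.numeric(names(means))
  top0 <- max(means); bot0 <- min(means)
  half <- (top0 + bot0) / 2
  lic0 <- log10(doses[which.min(abs(means - half))])
  lo_l <- log10(min(conc_range) / 100); hi_l <- log10(max(conc_range) * 100)
  df <- data.frame(lx = log10(conc), y = viab)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (lx - lic50))),
      data = df,
      start = list(bottom = bot0, top = top0, hill = 1,
                   lic50 = min(max(lic0, lo_l), hi_l)),
      lower = c(bottom = -Inf, top = -Inf, hill = 0.1, lic50 = lo_l),
      upper = c(bottom = Inf, top = Inf, hill = 10, lic50 = hi_l),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
       hill_slope = unname(cf["hill"]), ic50 = 10^unname(cf["lic50"]),
       rss = sum(stats::resid(fit)^2))
}

#' Fit a four-parameter logistic curve and estimate the IC50
#'
#' Least-squares 4PL fit on the log10-dose scale (doses span several orders
#' of magnitude). Initialization: top and bottom at the extreme mean
#' responses, IC50 at the dose nearest half-maximal response, Hill slope 1;
#' bounds keep the IC50 within two orders of magnitude of the tested dose
#' range and the Hill slope in [0.1, 10]. With multiple independent
#' experiments, per-experiment IC50s are also estimated and pooled as mean
#' +/- SD; by default they come from a global fit that shares bottom, top
#' and Hill slope across experiments while letting log10(IC50) vary per
#' experiment (the shared-parameter fit standard dose-response software
#' offers), which stabilizes per-experiment estimates from small designs.
#' Set `share_shape = FALSE` for fully independent per-experiment fits.
#'
#' @param dataset a [dose_response()].
#' @param per_experiment estimate per-experiment IC50s (default `TRUE`);
#'   set `FALSE` for pooled-points-only fitting.
#' @param share_shape share bottom/top/Hill across experiments in the
#'   per-experiment fit (default `TRUE`).
#' @return A list of class `fourpl_fit`: `bottom`, `top`, `hill_slope`,
#'   `ic50`, `converged`, `rss`, `per_experiment_ic50s`, `ic50_mean`,
#'   `ic50_sd`, `min_mean_response`, and flags `ic50_unidentifiable`
#'   (near-flat curve) and `ic50_extrapolated` (estimate beyond the tested
#'   dose ceiling).
#' @export
fit_4pl <- function(dataset, per_experiment = TRUE, share_shape = TRUE) {
  stopifnot(inherits(dataset, "dose_response"))
  d <- dataset$data
  if (length(unique(d$concentration_uM)) < 4L) {
    stop("need at least 4 distinct concentrations")
  }
  rng <- range(d$concentration_uM)
  pooled <- fit_4pl_once(d$concentration_uM, d$viability, rng)
  if (is.null(pooled)) {
    return(structure(list(converged = FALSE, ic50 = NA_real_,
                          per_experiment_ic50s = numeric(0)),
                     class = "fourpl_fit"))
  }
  per_ic50 <- numeric(0)
  if (per_experiment && dataset$n_experiments >= 2L) {
    if (share_shape) {
      per_ic50 <- fit_4pl_shared(d, rng, pooled)
    }
    if (is.null(per_ic50) || length(per_ic50) == 0L) {
      per_ic50 <- vapply(split(d, d$experiment), function(dd) {
        f <- fit_4pl_once(dd$concentration_uM, dd$viability, rng)
        if (is.null(f)) NA_real_ else f$ic50
      }, numeric(1L))
      per_ic50 <- per_ic50[!is.na(per_ic50)]
    }
  }
  # canonical orientation: top is the low-dose asymptote
  span <- abs(pooled$top - pooled$bottom)
  means <- tapply(d$viability, d$concentration_uM, mean)
  structure(list(
    bottom = min(pooled$bottom, pooled$top),
    top = max(pooled$bottom, pooled$top),
    hill_slope = pooled$hill_slope,
    ic50 = pooled$ic50,
    converged = TRUE,
    rss = pooled$rss,
    per_experiment_ic50s = per_ic50,
    ic50_mean = if (length(per_ic50)) mean(per_ic50) else pooled$ic50,
    ic50_sd = if (length(per_ic50) >= 2L) stats::sd(per_ic50) else NA_real_,
    min_mean_response = min(means),
    ic50_unidentifiable = span < 0.05,
    ic50_extrapolated = pooled$ic50 > dataset$max_tested_uM),
    class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<fourpl_fit> did not converge\n"); return(invisible(x))
  }
  cat(sprintf("<fourpl_fit> IC50 = %.3g uM (bottom %.3f, top %.3f, hill %.2f)\n",
              x$ic50, x$bottom, x$top, x$hill_slope))
  if (length(x$per_experiment_ic50s) >= 2L) {
    cat(sprintf("  per-experiment IC50: %.3g +/- %.3g uM (n = %d)\n",
                x$ic50_mean, x$ic50_sd, length(x$per_experiment_ic50s)))
  }
  if (x$ic50_unidentifiable) cat("  WARNING: near-flat curve, IC50 unidentifiable\n")
  if (x$ic50_extrapolated) cat("  NOTE: IC50 beyond the tested dose ceiling\n")
  invisible(x)
}

#' Compare monotherapy and combination IC50s
#'
#' Reports the IC50 fold shift (mono / combo), the maximal growth inhibition
#' of the combination curve (100 x (1 - lowest mean viability)), and an
#' equal-variance two-sided Student's t-test on the per-experiment IC50s.
#' The test is performed on log10(IC50): IC50 estimates are log-normally
#' distributed, so the log scale is where their spread is symmetric.
#'
#' @param mono,combo converged [fit_4pl()] results with at least two
#'   per-experiment IC50s each (for the t-test).
#' @return A list of class `combination_result`: `ic50_mono`, `ic50_combo`
#'   (each mean and SD), `fold_shift`, `max_inhibition_percent`, `p_value`,
#'   and an `unidentifiable` flag (no p-value is computed when either IC50
#'   is unidentifiable).
#' @export
compare_ic50 <- function(mono, combo) {
  stopifnot(inherits(mono, "fourpl_fit"), inherits(combo, "fourpl_fit"))
  if (!mono$converged || !combo$converged) stop("both fits must have converged")
  unident <- isTRUE(mono$ic50_unidentifiable) || isTRUE(combo$ic50_unidentifiable)
  p <- NA_real_
  if (!unident && length(mono$per_experiment_ic50s) >= 2L &&
      length(combo$per_experiment_ic50s) >= 2L) {
    p <- stats::t.test(log10(mono$per_experiment_ic50s),
                       log10(combo$per_experiment_ic50s),
                       var.equal = TRUE)$p.value
  }
  structure(list(
    ic50_mono = c(mean = mono$ic50_mean, sd = mono$ic50_sd),
    ic50_combo = c(mean = combo$ic50_mean, sd = combo$ic50_sd),
    fold_shift = mono$ic50_mean / combo$ic50_mean,
    max_inhibition_percent = 100 * (1 - combo$min_mean_response),
    p_value = p,
    unidentifiable = unident),
    class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("<combination_result> IC50 %.3g -> %.3g uM (fold shift %.2f)\n",
              x$ic50_mono["mean"], x$ic50_combo["mean"], x$fold_shift))
  cat(sprintf("  max inhibition %.1f%%; t-test p = %s\n",
              x$max_inhibition_percent,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3)))
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' Compare siRNA growth curves against a reference group
#'
#' Two-sided Student's t-tests of each treatment group's optical densities
#' against the reference (typically the non-silencing control) at one
#' timepoint.
#'
#' @param curves data.frame with columns `treatment`, `time_h`, `od`.
#' @param reference reference treatment label.
#' @param timepoint hour at which to compare (e.g. 72).
#' @return data.frame with one row per non-reference group: mean OD of
#'   group and reference, percent change, `p_value` and significance stars
#'   (groups with fewer than 2 replicates get `NA` with a warning).
#' @export
compare_growth_curves <- function(curves, reference = "NC-siRNA",
                                  timepoint = 72) {
  stopifnot(all(c("treatment", "time_h", "od") %in% names(curves)))
  at <- curves[curves$time_h == timepoint, , drop = FALSE]
  if (!reference %in% at$treatment) {
    stop("reference group '", reference, "' absent at timepoint ", timepoint)
  }
  ref_od <- at$od[at$treatment == reference]
  groups <- setdiff(unique(at$treatment), reference)
  rows <- lapply(groups, function(g) {
    g_od <- at$od[at$treatment == g]
    p <- if (length(g_od) < 2L || length(ref_od) < 2L) {
      warning("group '", g, "' or reference has < 2 replicates; no test")
      NA_real_
    } else {
      stats::t.test(g_od, ref_od, var.equal = TRUE)$p.value
    }
    data.frame(treatment = g, time_h = timepoint,
               mean_od = mean(g_od), reference_mean_od = mean(ref_od),
               percent_change = 100 * (mean(g_od) / mean(ref_od) - 1),
               p_value = p, stars = significance_stars(p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
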