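# Small builders used across test files.

toy_quant <- function(areas, cell_line = "toy", accession = NULL) {
  areas <- as.matrix(areas)
  if (is.null(accession)) accession <- sprintf("P%02d", seq_len(nrow(areas)))
  quant_table(accession, areas, gene = paste0("G", seq_len(nrow(areas))),
              description = paste("protein", seq_len(nrow(areas))),
              cell_line = cell_line)
}

random_raw_table <- function(n_proteins, n_replicates, missing_frac = 0.1) {
  m <- matrix(rlnorm(n_proteins * n_replicates, 8, 1.2),
              n_proteins, n_replicates)
  m[runif(length(m)) < missing_frac] <- NA
  # keep at least one value per row and at least one per column
  for (i in which(rowSums(!is.na(m)) == 0L)) m[i, 1L] <- rlnorm(1, 8, 1.2)
  toy_quant(m)
}

# minimal converged fit object for testing comparisons in isolation
fake_fit <- function(per_exp, min_mean_response = 0.4) {
  structure(list(bottom = 0.1, top = 1, hill_slope = 1,
                 ic50 = mean(per_exp), converged = TRUE, rss = 0,
                 per_experiment_ic50s = per_exp,
                 ic50_mean = mean(per_exp),
                 ic50_sd = sd(per_exp),
                 min_mean_response = min_mean_response,
                 ic50_unidentifiable = FALSE, ic50_extrapolated = FALSE),
            class = "fourpl_fit")
}
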