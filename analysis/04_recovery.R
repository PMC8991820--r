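#!/usr/bin/env Rscript
# Repeated-trial recovery experiment: simulate independent trials under the
# default MAR conditions (true 3-year incremental QALY 0.07, zero cost
# effect), run each estimator, and summarise bias against the known truth.
# Then rerun complete-case analysis and PMM imputation under an
# outcome-history-dependent mechanism to exhibit the selection bias that
# imputation removes. Writes results/recovery.csv and results/cca_bias.csv.

suppressMessages(library(ceamiss))

seed <- 20260929L %% 2147483647L
n_rep <- 10
truth_q <- 0.07

rows <- list()
for (r in seq_len(n_rep)) {
  dat <- simulate_trial(trial_config(seed = seed + r))
  for (imp in c("linreg", "pmm")) {
    mi <- mi_fit(dat, 3, mice_config(M = 8, cycles = 5, imputer = imp,
                                     seed = seed + 50 + r),
                 rate = 0, qaly_rate = 0)
    rows[[length(rows) + 1]] <- data.frame(
      rep = r, method = if (imp == "pmm") "mipmm" else "milr",
      dqaly = mi$delta["qaly"], dcost = mi$delta["cost"])
  }
  for (m in c("rmm", "rmfe")) {
    fitter <- if (m == "rmm") fit_rmm else fit_rmfe
    rows[[length(rows) + 1]] <- data.frame(
      rep = r, method = m,
      dqaly = incremental_qaly_total(fitter(dat, "eq5d"), 3, rate = 0)$est,
      dcost = incremental_cost_total(fitter(dat, "cost"), 3, rate = 0)$est)
  }
  b <- bpa_fit(dat, 3, bpa_config(iterations = 2000, burnin = 500,
                                  seed = seed + r), rate = 0, qaly_rate = 0)
  rows[[length(rows) + 1]] <- data.frame(
    rep = r, method = "bpa", dqaly = b$delta["qaly"],
    dcost = b$delta["cost"])
  cat("trial", r, "done\n")
}
rec <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(rec, "results/recovery.csv", row.names = FALSE)

cat("\nMean estimates over", n_rep, "trials (truth: dQALY 0.07, dCost 0):\n")
print(aggregate(cbind(dqaly, dcost) ~ method, rec, mean), digits = 3)

## selection bias demonstration --------------------------------------------
ml <- list(intercept_cost = -6, intercept_eq5d = -2.3,
           prev_utility_treat = -12)
truth_1y <- truth_q * 49 / 153
bias <- list()
for (r in seq_len(n_rep)) {
  dat <- simulate_trial(trial_config(missing_logit = ml,
                                     seed = seed + 500 + r))
  bias[[length(bias) + 1]] <- data.frame(
    rep = r,
    cca = cca_fit(dat, 1, rate = 0, qaly_rate = 0)$delta["qaly"],
    mipmm = mi_fit(dat, 1, mice_config(M = 6, cycles = 4, imputer = "pmm",
                                       seed = seed + 600 + r),
                   rate = 0, qaly_rate = 0)$delta["qaly"])
}
bias <- do.call(rbind, bias)
write.csv(bias, "results/cca_bias.csv", row.names = FALSE)
cat("\nUnder missingness driven by the last observed utility in the treated\n")
cat("arm (truth ", round(truth_1y, 4), " at 1 year):\n", sep = "")
cat("  CCA mean:  ", round(mean(bias$cca), 4),
    "  (selection inflates the treated complete-case mean)\n")
cat("  MIPMM mean:", round(mean(bias$mipmm), 4),
    "  (imputation conditions on the observed history)\n")
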