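#!/usr/bin/env Rscript
# The six-way comparison on the simulated trial: complete-case analysis,
# multiple imputation (linear-regression and predictive-mean-matching
# imputers, Rubin-pooled), repeated-measures mixed and within estimators
# with cluster bootstrap, and the Bayesian selection model — each at 1, 3
# and 5 years. Costs discounted at 3.5%/year, QALYs reported undiscounted.
# Writes results/report.csv, results/ceac_long.csv, results/run_manifest.json.
# Full-scale settings (M = 40, B = 500, 10k MCMC iterations): allow roughly
# half an hour.

suppressMessages(library(ceamiss))
suppressMessages(library(jsonlite))

seed <- 20260929L %% 2147483647L
dat <- read_trial("results/data")

res <- compare_methods(dat, horizons = c(1, 3, 5),
                       methods = c("rmm", "rmfe", "cca", "milr", "mipmm",
                                   "bpa"),
                       seed = seed, rate = 0.035, qaly_rate = 0,
                       B = 500, mice_M = 40, mice_cycles = 20,
                       bpa_iterations = 10000, bpa_burnin = 2000)

dir.create("results", showWarnings = FALSE)
write.csv(res$summary, "results/report.csv", row.names = FALSE)
write.csv(res$ceac, "results/ceac_long.csv", row.names = FALSE)
write_json(res$config, "results/run_manifest.json", auto_unbox = TRUE)

fmt <- res$summary
fmt$delta_cost <- round(fmt$delta_cost)
fmt$delta_qaly <- round(fmt$delta_qaly, 3)
fmt$ceac_30k <- round(fmt$ceac_30k, 2)
print(fmt[, c("method", "horizon", "n_used", "delta_cost", "cost_se",
              "delta_qaly", "qaly_se", "icer", "ceac_30k")], digits = 3)

cat("\nReading the table: the generating truth is a zero cost effect and a\n")
cat("positive utility effect, so a well-behaved method shows delta cost\n")
cat("near 0, delta QALY near 0.022/0.070/0.117 at 1/3/5 years, and a high\n")
cat("probability of cost-effectiveness at £30,000/QALY. Complete-case\n")
cat("analysis runs on a shrinking subset (n_used) at later horizons and is\n")
cat("correspondingly noisier; the panel and imputation methods keep all\n")
cat("patients.\n")
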