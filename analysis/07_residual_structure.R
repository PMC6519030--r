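#!/usr/bin/env Rscript
# Stage 7: how the residual structure biases slope-variance estimates.
#
# Populations are simulated with ZERO individual slope variance but
# residual standard deviations that increase with temperature. The same
# random-regression model is then fitted with residual-variance groups
# defined three ways: calendar decades, equal-count temperature groups,
# and a single homogeneous group. Only the temperature grouping matches
# the generating process; the others must push environment-linked variance
# into the individual slopes.

library(rnevo)

cfg <- sim_config(n_founders = 26, n_years = 30, sigma2_B = 0, cov_AB = 0,
                  sigma2_PE_slope = 0, cov_PE = 0)
res <- run_residual_experiment(
  cfg, schemes = c("decade", "temperature", "homogeneous"),
  n_reps = 100, seed = 20260701)

print(res$summary, digits = 3, row.names = FALSE)
utils::write.csv(res$per_rep, file.path("results", "residual_experiment.csv"),
                 row.names = FALSE)
utils::write.csv(res$summary,
                 file.path("results", "residual_experiment_summary.csv"),
                 row.names = FALSE)

m <- setNames(res$summary$mean_slope_var, res$summary$scheme)
cat(sprintf("\nMean estimated slope variance (true value 0): decade %.3f, homogeneous %.3f, temperature %.3f.\n",
            m[["decade"]], m[["homogeneous"]], m[["temperature"]]))
cat("Misspecifying the residual structure inflates apparent variance in\n")
cat("plasticity; grouping residuals by temperature removes the artefact.\n")
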