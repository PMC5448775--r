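#!/usr/bin/env Rscript
# Duplicate-tracing method comparison on a synthetic kidney cohort.
#
# Thirty phantoms with ground-truth volumes spread over 600-6600 ml are
# "traced" twice by two virtual raters (an expert and a beginner, the
# beginner with larger boundary jitter and caliper error). Each tracing is
# measured by all five methods: polyline planimetry (reference),
# stereology point counting, the mid-slice shortcut, the ellipsoid caliper
# formula, and kidney length. The script emits the three summary tables a
# method-comparison study reports: per-method volumes, intra-/inter-rater
# reproducibility (repeated-measures CV), and agreement with the reference
# (mean % difference, Bland-Altman limits, RMSE).
#
# Typical findings on this cohort: planimetry CV under 1.5%, stereology
# unbiased with ~1% RMSE against planimetry, the mid-slice and ellipsoid
# shortcuts off by roughly -14% and -10% with the ellipsoid method both
# underestimating and far less repeatable (CV ~8% expert, ~14% beginner),
# and kidney length correlating with true volume at r > 0.9 while
# remaining far too coarse for volumetry.

suppressPackageStartupMessages(library(nephrovol))

config <- run_config(seed = 1L, n_kidneys = 30,
                     volume_range = c(600, 6600),
                     out_dir = "results/experiment")
res <- run_experiment_emulation(config)

cat("\nPer-method SKV (expert, session 1):\n")
m1 <- subset(res$measurements, rater == "expert" & session == 1 &
               method != "length_only")
agg <- aggregate(skv_ml ~ method, m1, function(x)
  c(mean = mean(x), sd = sd(x)))
print(cbind(method = agg$method, round(agg$skv_ml, 0)), quote = FALSE)

cat("\nReproducibility (repeated-measures CV, %):\n")
print(transform(res$reproducibility, cv_pct = round(cv_pct, 2),
                mean_diff_ml = round(mean_diff_ml, 1)), row.names = FALSE)

cat("\nAgreement with polyline planimetry (expert, session 1):\n")
print(transform(res$agreement,
                rmse_ml = round(rmse_ml, 0),
                mean_diff_pct = round(mean_diff_pct, 1),
                rmse_pct = round(rmse_pct, 1)), row.names = FALSE)

cat(sprintf("\nKidney length vs true volume: r = %.3f (p = %.2g)\n",
            res$length_correlation$r, res$length_correlation$p))
cat("written: results/experiment/{measurements,reproducibility,agreement}.csv\n")
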