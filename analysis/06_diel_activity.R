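#!/usr/bin/env Rscript
# Diel calling analysis: classify each counted file by solar light regime
# (light / nautical twilight / dark at the site, local time UTC-3h40) and
# test call-abundance differences across regimes with a Kruskal-Wallis
# test at alpha = 0.05.

source("analysis/00_config.R")
cfg <- analysis_config

intervals <- read.csv("results/count_intervals.csv")
intervals$start_utc <- as.POSIXct(intervals$start_utc, tz = "UTC")
iv <- assign_light_period(intervals, cfg$site[1], cfg$site[2])
write.csv(iv, "results/count_intervals_light.csv", row.names = FALSE)

use <- !iv$censored & !iv$excluded & !is.na(iv$n_calls)
grp <- droplevels(iv$light_period[use])
tab <- tapply(iv$n_calls[use], grp, median)
cat("median calls per file by light regime:\n")
print(tab)

if (nlevels(grp) >= 2) {
  kw <- kruskal_wallis(iv$n_calls[use], grp)
  cat(sprintf("Kruskal-Wallis H = %.2f, df = %d, p = %.2f (critical value %.2f at alpha = %.2f)\n",
              kw$H, kw$df, kw$p, kw$critical_value, kw$alpha))
  verdict <- if (kw$H < kw$critical_value)
    "no significant diel difference in call abundance" else
      "call abundance differs significantly between light regimes"
  cat(verdict, "\n")
  writeLines(jsonlite::toJSON(kw, auto_unbox = TRUE, digits = NA),
             "results/diel_test.json")
} else {
  cat("fewer than two light regimes in the analysed window; no test run\n")
}
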