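#!/usr/bin/env Rscript

# Ultra-fast drug release kinetics with aliquot-replacement correction.
#
# Simulates five replicate aliquot-sampled release series per formulation
# (14 mL chamber, 1 mL aliquots, 3 % measurement CV, sampling every 10 min
# to 60 min then 120/240/480/1440 min), corrects for the withdrawn drug,
# normalizes to the 24 h cumulative release, fits the saturating
# ultra-fast model, and reports the burst release rate over the first
# 120 min.

suppressPackageStartupMessages(library(mnswell))
dir.create("results", showWarnings = FALSE)
seed0 <- 200

formulations <- list(
  P15 = list(k = 0.060, a = 0.0550, C_max = 1.6),
  P20 = list(k = 0.056, a = 0.0514, C_max = 2.0)
)

rows <- lapply(names(formulations), function(nm) {
  tr <- formulations[[nm]]
  fits <- lapply(1:5, function(i) {
    g <- gen_release_series(k = tr$k, a = tr$a, C_max = tr$C_max,
                            noise_cv = 0.03, seed = seed0 + i)
    C_cum <- cumulative_correct(g)
    C_pct <- cumulative_percent(C_cum, C_cum[length(C_cum)])
    fit <- taolu_fit(g$t, C_cum / C_cum[length(C_cum)])
    c(k = fit$k, a = fit$a, r2 = fit$r2,
      pct_120min = C_pct[g$t == 120],
      rate_120 = release_rate(c(0, C_pct), c(0, g$t), window_end = 120))
  })
  m <- do.call(rbind, fits)
  stats <- lapply(colnames(m), function(cn) summarize_replicates(m[, cn]))
  names(stats) <- colnames(m)
  data.frame(
    formulation = nm, n = 5, k_true = tr$k,
    k = stats$k$mean, k_sem = stats$k$sem,
    a = stats$a$mean, a_sem = stats$a$sem,
    r2 = stats$r2$mean,
    released_120min_pct = stats$pct_120min$mean,
    released_120min_sem = stats$pct_120min$sem,
    rate_120min_pct_per_min = stats$rate_120$mean
  )
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/release_parameters.csv", row.names = FALSE)

cat("Ultra-fast release parameters (mean +/- SEM, n = 5):\n\n")
print(tab[, c("formulation", "k", "k_sem", "a", "a_sem", "r2",
              "released_120min_pct")],
      row.names = FALSE, digits = 3)
cat(sprintf(
  "\nBoth formulations release >%.0f%% of their 24 h total within 120 min —\nthe burst that motivates the saturating (ultra-fast) model over\ndiffusion-limited alternatives.\n",
  min(tab$released_120min_pct) %/% 1
))
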