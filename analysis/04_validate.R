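#!/usr/bin/env Rscript
# Step 4: validation summary and figures.
#
# Summarises the study bundle: season-averaged percentile grids per method
# against the 28-day truth (percentage difference from the 1st to the 99th
# percentile), the headline group statistics, and individual-level MAE /
# MAPE per method and season.  Writes summary tables and simple figures
# under results/.

suppressMessages(library(usualintake))

ds <- read_recalls("results/synthetic_recalls.csv")
grids <- utils::read.csv("results/study/percentile_grids.csv")
indiv <- utils::read.csv("results/study/individual_comparison.csv")

components <- unique(grids$component)
methods <- unique(grids$method)

# season-averaged Diff% per percentile rank
rows <- list()
for (comp in components) {
  truth <- true_usual_intake(ds, comp)
  for (meth in methods) {
    per_season <- lapply(c("winter", "spring", "summer", "autumn"), function(s) {
      g <- grids[grids$component == comp & grids$method == meth &
                   grids$season == s & grepl("^p", grids$stat), ]
      g <- g[order(as.integer(sub("p", "", g$stat))), ]
      structure(list(method = meth, component = comp, season = s,
                     mean = grids$estimate[grids$component == comp &
                                             grids$method == meth &
                                             grids$season == s &
                                             grids$stat == "mean"],
                     percentiles = stats::setNames(g$estimate, g$stat),
                     n = NA, seed = NA),
                class = "usual_intake_distribution")
    })
    avg <- average_percentiles_over_seasons(per_season)
    cmp <- compare_group(avg, truth)
    cmp$component <- comp; cmp$method <- meth
    rows[[paste(comp, meth)]] <- cmp
  }
}
avg_tab <- do.call(rbind, rows)
utils::write.csv(avg_tab, "results/season_averaged_diff.csv", row.names = FALSE)

key <- avg_tab[avg_tab$stat %in% c("mean", "p10", "p50", "p90"), ]
key$diff_pct <- round_half_up(key$diff_pct, 2)
cat("season-averaged percentage differences vs 28-day truth:\n")
print(stats::reshape(key[, c("component", "method", "stat", "diff_pct")],
                     idvar = c("component", "method"), timevar = "stat",
                     direction = "wide"), row.names = FALSE)

# per-percentile bias curves, one panel per component
grDevices::pdf("results/percentile_bias.pdf", width = 9, height = 3.2)
graphics::par(mfrow = c(1, length(components)), mar = c(4, 4, 2, 1))
for (comp in components) {
  plot(NULL, xlim = c(1, 99), ylim = c(-60, 60), xlab = "percentile rank",
       ylab = "Diff%", main = comp)
  graphics::abline(h = 0, lty = 2)
  cols <- c(`3day` = "grey40", MSM = "steelblue", NCI = "firebrick")
  for (meth in methods) {
    a <- avg_tab[avg_tab$component == comp & avg_tab$method == meth &
                   grepl("^p", avg_tab$stat), ]
    r <- as.integer(sub("p", "", a$stat))
    graphics::lines(r[order(r)], a$diff_pct[order(r)], col = cols[[meth]], lwd = 2)
  }
  graphics::legend("topright", names(cols), col = cols, lwd = 2, bty = "n", cex = 0.8)
}
grDevices::dev.off()

cat("\nMAE / MAPE by method (averaged over seasons):\n")
agg <- stats::aggregate(cbind(mae, mape) ~ component + method, indiv, mean)
agg$mae <- round_half_up(agg$mae, 2); agg$mape <- round_half_up(agg$mape, 2)
print(agg[order(agg$component, agg$mae), ], row.names = FALSE)
cat("\nwrote results/season_averaged_diff.csv and results/percentile_bias.pdf\n")
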