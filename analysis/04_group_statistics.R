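#!/usr/bin/env Rscript
# Step 4: group-level statistics — equalization (PAIR vs SINGLE), balanced
# partner correlations, synchrony-behavior correlations, top/bottom-40%
# splits. Coupled cohorts should show their own strategy's count correlating
# with synchrony; uncoupled cohorts should show neither.

library(fearsync)

in_dir <- file.path("results", "cohorts")
out_dir <- file.path("results", "analysis")
layout <- session_layout()

eths <- read_bout_table(file.path(in_dir, "bouts.csv"), layout)
meta <- utils::read.csv(file.path(in_dir, "metadata.csv"),
                        colClasses = "character")
syn <- utils::read.csv(file.path(out_dir, "synchrony.csv"))
beh <- utils::read.csv(file.path(out_dir, "behavior_counts.csv"))
syn <- merge(syn, beh, by = "dyad_id")

freeze_table <- function(config) {
  mm <- meta[meta$configuration == config, ]
  do.call(rbind, lapply(split(mm, mm$dyad_id), function(rows) {
    data.frame(dyad_id = rows$dyad_id[1L], group = rows$group[1L],
               subject_a = rows$subject_id[1L], subject_b = rows$subject_id[2L],
               freeze_a = freezing_level(bouts_to_trace(eths[[rows$subject_id[1L]]])),
               freeze_b = freezing_level(bouts_to_trace(eths[[rows$subject_id[2L]]])))
  }))
}
pair_fr <- freeze_table("PAIR")
single_fr <- freeze_table("SINGLE")

cat("Freezing equalization |freeze_a - freeze_b| (percent points):\n")
eq_rows <- list()
for (g in unique(pair_fr$group)) {
  eq <- equalization_metrics(pair_fr[pair_fr$group == g, ],
                             single_fr[single_fr$group == g, ])
  p <- if (!is.null(attr(eq, "test"))) attr(eq, "test")$p.value else NA
  cat(sprintf("  %-13s PAIR %5.2f vs SINGLE %5.2f (Wilcoxon p = %.3g)\n",
              g, mean(eq$diff_pair), mean(eq$diff_single), p))
  eq_rows[[g]] <- data.frame(group = g, mean_diff_pair = mean(eq$diff_pair),
                             mean_diff_single = mean(eq$diff_single), p = p)
}
utils::write.csv(do.call(rbind, eq_rows),
                 file.path(out_dir, "equalization.csv"), row.names = FALSE)

cat("\nBalanced partner correlations (PAIR):\n")
for (g in unique(pair_fr$group)) {
  asg <- balanced_partner_assignment(pair_fr[pair_fr$group == g, ])
  pc <- partner_correlation(asg)
  cat(sprintf("  %-13s r = %+.3f, p = %.3g (n = %d)\n", g, pc$r, pc$p, pc$n))
}

cat("\nSynchrony-behavior correlations and top/bottom-40% splits:\n")
for (g in unique(syn$group)) {
  sg <- syn[syn$group == g & !is.na(syn$corrected), ]
  for (b in c("follow_total", "r2f", "r2m")) {
    sc <- synchrony_behavior_correlation(sg, b)
    star <- if (sc$p < 0.05) " *" else ""
    cat(sprintf("  %-13s %-12s r = %+.3f, p = %.3g%s\n", g, b, sc$r, sc$p, star))
  }
  sp <- split_top_bottom(sg, 0.40)
  cat(sprintf("  %-13s top/bottom-%d follow: %.1f vs %.1f; r2f: %.1f vs %.1f\n",
              g, sp$k, mean(sp$top$follow_total), mean(sp$bottom$follow_total),
              mean(sp$top$r2f), mean(sp$bottom$r2f)))
}
cat("\nequalization table written to", file.path(out_dir, "equalization.csv"), "\n")
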