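#!/usr/bin/env Rscript
# Step 3: four-state decomposition of the dyad dynamics.
#
# Summarises the transition structure and the follow / retroact motif counts
# per group, and reports the follow-to-freeze vs follow-to-move imbalance:
# the two are halves of one alternating process and can only drift apart
# when both animals switch within the same frame (coarse 4-fps sampling).

library(fearsync)

out_dir <- file.path("results", "analysis")
syn <- utils::read.csv(file.path(out_dir, "synchrony.csv"))
beh <- utils::read.csv(file.path(out_dir, "behavior_counts.csv"))
trans <- utils::read.csv(file.path(out_dir, "transition_counts.csv"))
groups <- syn$group[match(beh$dyad_id, syn$dyad_id)]

cat("Behavior counts by group (mean per dyad):\n")
agg <- stats::aggregate(beh[c("follow_total", "r2f", "r2m")],
                        by = list(group = groups), FUN = mean)
print(agg, row.names = FALSE)

imbalance <- abs(beh$f2f - beh$f2m)
cat(sprintf("\nmax |follow_to_freeze - follow_to_move| across %d dyads: %d\n",
            nrow(beh), max(imbalance)))

tcols <- grep("^t_", names(trans), value = TRUE)
stopifnot(length(tcols) == 16L)
self_loops <- trans[, c("t_00", "t_11", "t_22", "t_33")]
cat(sprintf("transition totals: every dyad sums to %d; self-loops occupy %.1f%% of transitions\n",
            unique(rowSums(trans[tcols])),
            100 * mean(rowSums(self_loops) / rowSums(trans[tcols]))))
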