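#!/usr/bin/env Rscript
# Trial segmentation, lick metrics, k-means engagement classification and
# streak/transition statistics with the 1,000-permutation shuffle control.

suppressPackageStartupMessages(library(placegate))

gen <- read_session_h5("results/session.h5")
truth_states <- read.csv("results/truth_trials.csv")$state

trials <- build_trial_table(gen$session)
write.csv(trials, "results/trials.csv", row.names = FALSE)

acc <- mean(trials$engagement == truth_states)
cat(sprintf("engagement labels: %d engaged, %d disengaged (truth recovery %.2f)\n",
            sum(trials$engagement == "engaged"),
            sum(trials$engagement == "disengaged"), acc))
cat(sprintf("excluded trials: %d (%s)\n", sum(trials$excluded),
            paste(na.omit(unique(trials$exclude_reason)), collapse = ", ")))

set.seed(1)
st <- streak_stats(trials$engagement, n_shuffles = 1000)
cat("disengaged streak lengths:",
    paste(names(st$streak_hist), st$streak_hist, sep = "x", collapse = " "),
    "\n")
cat(sprintf("P(D->D) = %.2f (shuffle control %.2f)\n",
            st$transition_matrix["disengaged", "disengaged"],
            st$shuffle_transition_matrix["disengaged", "disengaged"]))

tm <- as.data.frame(as.table(st$transition_matrix))
names(tm) <- c("from", "to", "p")
tm$shuffle_p <- as.vector(st$shuffle_transition_matrix)
write.csv(tm, "results/transition_matrix.csv", row.names = FALSE)
write.csv(data.frame(length = as.integer(names(st$streak_hist)),
                     count = as.vector(st$streak_hist)),
          "results/streak_hist.csv", row.names = FALSE)
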