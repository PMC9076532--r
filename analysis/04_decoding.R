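#!/usr/bin/env Rscript
# Poisson naive-Bayes position decoding: sliding-window baseline and
# session inclusion, the four train/test engagement conditions, the
# speed-matched control, the template-matching control, and the
# streak-onset timecourse.

suppressPackageStartupMessages(library(placegate))

gen <- read_session_h5("results/session.h5")
trials <- read.csv("results/trials.csv")
usable <- trials$trial[!trials$excluded]
lab <- trials$engagement[!trials$excluded]

sl <- sliding_decoder(gen$session, usable)
write.csv(sl, "results/sliding_decoder.csv", row.names = FALSE)
cat(sprintf("sliding decoder: %d/%d tested trials below 10 cm\n",
            sum(sl$error_cm < 10, na.rm = TRUE), sum(!is.na(sl$error_cm))))

inc <- session_inclusion(trials[!trials$excluded, ], sl$error_cm)
cat(sprintf("session inclusion: %s%s\n",
            ifelse(inc$included, "included", "excluded"),
            ifelse(length(inc$reasons),
                   paste0(" (", paste(inc$reasons, collapse = ", "), ")"),
                   "")))

ed <- engagement_decoder(gen$session, usable, lab)
cat("condition-wise mean decoding error (cm), chance = 50:\n")
print(round(ed$errors, 1))

tm <- engagement_decoder(gen$session, usable, lab, decoder = "template")
cat("template-matching control:\n")
print(round(tm$errors, 1))

set.seed(4)
sm <- speed_matched_decoding(gen$session, usable, lab)
cat(sprintf("speed-matched decoding (%d unusable pairs):\n",
            sm$n_unusable_pairs))
print(round(sm$errors, 1))

cond_tbl <- data.frame(condition = names(ed$errors),
                       bayes_cm = as.vector(ed$errors),
                       template_cm = as.vector(tm$errors[names(ed$errors)]),
                       speed_matched_cm = as.vector(sm$errors[names(ed$errors)]))
write.csv(cond_tbl, "results/decoding_conditions.csv", row.names = FALSE)

so <- streak_onset_decoder(gen$session, trials$engagement)
write.csv(so, "results/streak_onset_error.csv", row.names = FALSE)
if (nrow(so)) {
  cat(sprintf("streak-onset error: pre %.1f cm -> first 5 disengaged %.1f cm\n",
              mean(so$error_cm[so$align < 0]),
              mean(so$error_cm[so$align >= 0 & so$align < 5])))
}
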