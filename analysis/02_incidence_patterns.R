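#!/usr/bin/env Rscript

# Stage 2: diurnal incidence patterns.
#
# Bins detected gait and LM frames by hour of day, per class, averaging
# over subjects -- the behavioural-volume view of the cohort. Writes
# results/hourly_incidence.csv and prints the peak activity hours.

library(wristpd)
feats <- readRDS("results/features.rds")

hourly <- cohort_hourly_incidence(feats)
write.csv(hourly, "results/hourly_incidence.csv", row.names = FALSE)

for (kind in c("gait", "LM")) {
  for (cl in c("control", "PD")) {
    h <- hourly[hourly$kind == kind & hourly$label == cl, ]
    message(sprintf("%-7s %-8s peak at %02d:00 (%.2f frames/h), daytime total %.0f frames/day",
                    kind, cl, h$hour[which.max(h$frames_per_hour)],
                    max(h$frames_per_hour), sum(h$frames_per_hour)))
  }
}
message("wrote results/hourly_incidence.csv")
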