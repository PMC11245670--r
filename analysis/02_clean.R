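#!/usr/bin/env Rscript
# Stage 2: the record-cleaning cascade. Cow-level rules (unique identifier,
# born on farm, no pre-entry lactation, study birth window, realistic age at
# first calving), then milk-record rules (lactation bracketing by calving
# dates, implausible yields) and free-text treatment matching against the
# product reference list.
library(resilherd)

herd <- read_herd_csvs("results/herd")

cc <- clean_cows(herd$cows, herd$calvings)
cm <- clean_milk(herd$milk, cc$cows, herd$calvings)
events <- match_treatments(herd$events, herd$products)
herd_years <- filter_recording_herd_years(events, cm$cows)

dir.create("results", showWarnings = FALSE)
write.csv(cm$cows, "results/cows_clean.csv", row.names = FALSE)
write.csv(cm$milk, "results/milk_clean.csv", row.names = FALSE)
write.csv(events, "results/events_categorized.csv", row.names = FALSE)
write.csv(herd_years, "results/herd_years.csv", row.names = FALSE)
write.csv(cc$report, "results/cleaning_report_cows.csv", row.names = FALSE)
write.csv(cm$report, "results/cleaning_report_milk.csv", row.names = FALSE)

cat("Cow cascade:\n")
print(as.data.frame(cc$report), row.names = FALSE)
cat(sprintf("Milk records retained: %d of %d\n", nrow(cm$milk),
            nrow(herd$milk)))
cat(sprintf("Treatment records matched: %d of %d (%.0f%% of treatments)\n",
            sum(events$kind == "treatment" & events$category != "unmatched"),
            sum(events$kind == "treatment"),
            100 * mean(events$category[events$kind == "treatment"] !=
                         "unmatched")))
cat(sprintf("Recording herd-years: %d\n", nrow(herd_years)))
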