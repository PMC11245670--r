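#!/usr/bin/env Rscript
# Stage 6: assemble the modelling features. Mother-daughter pairs are matched
# through the pedigree (first pregnancies excluded), restricted to recording
# herd-years, and each retained pair gets its gestation-window exposures
# (trimester THI means, stressor flags, milk-quality bands), pregnancy-number
# category, centered mother LRS, season of birth and farm-level context.
library(resilherd)

herd <- read_herd_csvs("results/herd")
cows <- dplyr::as_tibble(read.csv(
  "results/cows_clean.csv",
  colClasses = c(birth_date = "Date", entry_date = "Date",
                 exit_date = "Date")))
milk <- dplyr::as_tibble(read.csv("results/milk_clean.csv"))
milk$date <- as.Date(milk$date)
fits <- dplyr::as_tibble(read.csv("results/lactations.csv"))
lrs <- dplyr::as_tibble(read.csv("results/lrs.csv"))
events <- dplyr::as_tibble(read.csv("results/events_categorized.csv"))
events$date <- as.Date(events$date)
herd_years <- read.csv("results/herd_years.csv")
weather <- dplyr::as_tibble(read.csv("results/weather_thi.csv"))
weather$date <- as.Date(weather$date)
farm_stations <- read.csv("results/farm_stations.csv")
calvings <- herd$calvings[herd$calvings$cow_id %in% cows$cow_id, ]

pairs <- match_pairs(cows, calvings, generation_gap = 1)
pair_farm <- cows$farm_id[match(pairs$offspring_id, cows$cow_id)]
pair_year <- as.integer(format(pairs$calving_date, "%Y"))
pairs <- pairs[paste(pair_farm, pair_year) %in%
                 paste(herd_years$farm_id, herd_years$year), ]

features <- build_features(pairs, cows, calvings, events, milk, weather,
                           farm_stations, lrs, fits, mode = "daughter")
write.csv(features, "results/features.csv", row.names = FALSE)

cat(sprintf("Mother-daughter pairs in recording herd-years: %d\n",
            nrow(pairs)))
cat(sprintf("Feature rows (pairs with a scored daughter): %d (%d dropped)\n",
            nrow(features), attr(features, "n_dropped")))
cat("Pregnancy-number categories:\n")
print(table(features$pregnancy))
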