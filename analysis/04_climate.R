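#!/usr/bin/env Rscript
# Stage 4: thermal-discomfort exposure. Derive minimum relative humidity and
# THI_max from the daily station summaries, drop station-years missing more
# than 10% of observations, and match each farm to its nearest retained
# station by haversine distance.
library(resilherd)

herd <- read_herd_csvs("results/herd")

weather <- add_thi(herd$weather)
qc <- qc_stations(weather, "multi")
ok <- unique(qc$station_id[qc$retained])
farm_stations <- match_nearest_station(
  herd$farms, herd$stations[herd$stations$station_id %in% ok, ])

write.csv(weather, "results/weather_thi.csv", row.names = FALSE)
write.csv(qc, "results/station_qc.csv", row.names = FALSE)
write.csv(farm_stations, "results/farm_stations.csv", row.names = FALSE)

cat(sprintf("Station-years passing QC: %d of %d\n", sum(qc$retained),
            nrow(qc)))
cat(sprintf("Farm-station distances: mean %.1f km (range %.1f-%.1f)\n",
            mean(farm_stations$distance_km), min(farm_stations$distance_km),
            max(farm_stations$distance_km)))
cat(sprintf("THI_max: July mean %.1f, January mean %.1f\n",
            mean(weather$thi_max[format(weather$date, "%m") == "07"]),
            mean(weather$thi_max[format(weather$date, "%m") == "01"])))
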