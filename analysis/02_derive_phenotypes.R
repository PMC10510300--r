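#!/usr/bin/env Rscript
# Stage 2 — derive the analysis traits from the raw records.
#
# From the 10-min vaginal-temperature series this builds the trait family
# (T_Vall, T_V4days, the four fixed-hour traits and their single-record
# versions), computes respiration efficiency as the per-sow slope of T_V on
# RR at 8:00/16:00, applies the 3.5-SD outlier rule and the 12-172 bpm
# respiration band, and attaches the hourly climate covariates.

suppressPackageStartupMessages(library(sowtherm))

tv10 <- read_phenotypes("results/data/tv_10min.csv")
rr <- read_phenotypes("results/data/rr.csv")
bcs <- read_phenotypes("results/data/bcs.csv")
clim <- read_climate("results/data/climate_5min.csv")

message("deriving the vaginal-temperature trait family ...")
tv_traits <- derive_tv_traits(tv10)
tab <- table(tv_traits$trait)
message("  records per trait: ",
        paste(names(tab), tab, sep = "=", collapse = ", "))

message("deriving respiration efficiency ...")
tv_hourly <- tv_traits[tv_traits$trait == "T_V4days", ]
reff <- respiration_efficiency(rr, tv_hourly, hours = c(8, 16))
message("  estimable slopes: ", sum(!is.na(reff$value)), "/", nrow(reff))

message("filtering ...")
all_ph <- rbind(tv_traits[, c("trait", "animal_id", "day", "time", "value",
                              "parity", "location", "recorder",
                              "days_in_lactation", "week", "date")],
                rr[, c("trait", "animal_id", "day", "time", "value",
                       "parity", "location", "recorder",
                       "days_in_lactation", "week", "date")],
                bcs[, c("trait", "animal_id", "day", "time", "value",
                        "parity", "location", "recorder",
                        "days_in_lactation", "week", "date")])
fr <- filter_outliers(all_ph, k = 3.5, rr_trait = "RR")
message("  removed ", nrow(fr$report), " records (",
        sum(fr$report$reason == "sd_outlier"), " SD outliers, ",
        sum(fr$report$reason == "rr_bounds"), " outside the RR band)")
write.csv(fr$report, "results/filter_report.csv", row.names = FALSE)

message("attaching hourly climate covariates ...")
hourly <- hourly_average(clim)
write.csv(hourly, "results/climate_hourly.csv", row.names = FALSE)
ph <- attach_climate_all(fr$data, hourly)
write_phenotypes(ph, "results/phenotypes_analysis.csv")

reff_out <- data.frame(trait = "R_eff", animal_id = reff$animal_id,
                       value = reff$value, n_pairs = reff$n_pairs)
write.csv(reff_out, "results/respiration_efficiency.csv", row.names = FALSE)
message("stage 2 done: ", nrow(ph), " analysis records")
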