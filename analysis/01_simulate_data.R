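#!/usr/bin/env Rscript
# Stage 1 — simulate the study data.
#
# Builds a scaled-down analogue of a 46-day lactating-sow heat-stress trial:
# SNP genotypes for a herd organised in paternal half-sib families (with a
# sprinkling of QC-failing SNPs/animals), 5-min in-barn climate logger
# records over a 4-day collection window, raw 10-min vaginal-temperature
# series, 4x/day respiration-rate counts, and a single-record body-condition
# score. Everything downstream reads the CSV/PLINK files written here.

suppressPackageStartupMessages(library(sowtherm))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 20210609L
n_animals <- 300
n_days <- 4

message("simulating genotypes (", n_animals, " sows x 1,200 SNPs) ...")
gm <- simulate_genotypes(n_animals, 1200, seed = seed,
                         n_sires = n_animals %/% 25,
                         missing_rate = 0.01,
                         frac_low_maf = 0.03, frac_low_call = 0.02,
                         frac_excess_het = 0.01, frac_bad_animals = 0.02)
write_plink(gm, "results/data/genotypes")
write_geno_matrix(gm, "results/data/genotypes.tsv")

message("simulating in-barn climate (4 loggers x 2 rooms, 5-min records) ...")
cp <- climate_params(daily_mean_c = 28, amplitude_c = 4, phase_h = 16,
                     noise_sd_c = 0.5, rh_mean_pct = 70, rh_sd_pct = 8)
clim <- simulate_climate(n_days, n_loggers = 4, params = cp,
                         seed = seed + 1, n_rooms = 2)
write_climate(clim, "results/data/climate_5min.csv")

message("simulating phenotypes ...")
grm_all <- vanraden_grm(qc_genotypes(gm))
ids <- rownames(grm_all$G)

# variance components follow the reference magnitudes for T_Vall, RR and
# BCS_Cal; vaginal temperature carries a diurnal climate signal
tv <- reference_truth("T_Vall")
rr <- reference_truth("RR")
bc <- reference_truth("BCS_Cal")
Sigma_a <- diag(c(tv$sigma_a, rr$sigma_a, bc$sigma_a))
# modest genetic associations: T_V with RR 0.3; BCS with neither
Sigma_a[1, 2] <- Sigma_a[2, 1] <- 0.3 * sqrt(tv$sigma_a * rr$sigma_a)
bv <- simulate_breeding_values(grm_all, Sigma_a, seed = seed + 2)
colnames(bv) <- c("T_V10min", "RR", "BCS_Cal")

params <- true_params(
  sigma_a = c(T_V10min = tv$sigma_a, RR = rr$sigma_a, BCS_Cal = bc$sigma_a),
  sigma_pe = c(T_V10min = tv$sigma_pe, RR = rr$sigma_pe, BCS_Cal = 0),
  sigma_e = c(T_V10min = tv$sigma_e, RR = rr$sigma_e, BCS_Cal = bc$sigma_e),
  Sigma_a = Sigma_a,
  mean_value = c(T_V10min = 39.5, RR = 73, BCS_Cal = 10),
  parity_effects = c(0, 0.05, 0.08, 0.08, 0.05, 0),
  climate_slope = c(T_V10min = 0.05, RR = 2.0, BCS_Cal = 0),
  climate = cp)

# 10-min vaginal temperature: 6 records/hour at the four target hours
# (the analysis only uses those hours, so off-target hours are not simulated)
lay_tv <- do.call(rbind, lapply(seq(0, 50, 10) / 60, function(frac) {
  l <- study_layout(ids, n_days = n_days, hours = c(8, 12, 16, 20),
                    seed = seed + 3)
  l$time <- l$time + frac
  l
}))
ph_tv <- simulate_phenotypes(lay_tv, bv[, 1, drop = FALSE],
                             params_subset(params, "T_V10min"),
                             climate = clim, seed = seed + 4)

# respiration rate, 4x/day as breaths/min (counted 15 s, x4 -> multiples of 4)
lay_rr <- study_layout(ids, n_days = n_days, hours = c(8, 12, 16, 20),
                       seed = seed + 3)
ph_rr <- simulate_phenotypes(lay_rr, bv[, 2, drop = FALSE],
                             params_subset(params, "RR"),
                             climate = clim, seed = seed + 5)
ph_rr$value <- rr_from_counts(round(pmax(ph_rr$value, 0) / 4))

# caliper body-condition score, one record per sow
lay_bc <- study_layout(ids, n_days = 1, hours = 8, seed = seed + 3)
ph_bc <- simulate_phenotypes(lay_bc, bv[, 3, drop = FALSE],
                             params_subset(params, "BCS_Cal"),
                             seed = seed + 6)

write_phenotypes(ph_tv, "results/data/tv_10min.csv")
write_phenotypes(ph_rr, "results/data/rr.csv")
write_phenotypes(ph_bc, "results/data/bcs.csv")
write.csv(data.frame(animal_id = rownames(bv), bv),
          "results/data/true_breeding_values.csv", row.names = FALSE)

message("stage 1 done: ", nrow(ph_tv), " T_V records, ", nrow(ph_rr),
        " RR records, ", nrow(ph_bc), " BCS records")
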