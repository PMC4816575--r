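#!/usr/bin/env Rscript
# Step 1 — simulate the observational world with known ground truth.
#
# Builds everything the downstream steps consume: smooth monthly
# cloud-probability surfaces, twice-daily cloud-flag stacks from two sensors
# with orbital stripe artifacts, a monthly station archive, and the species
# data for both distribution models. Large arrays go to scratch/ as RDS
# working files; small tables and the truth parameters go to results/.

suppressPackageStartupMessages(library(cloudclim))
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch/inputs", recursive = TRUE, showWarnings = FALSE)

seed <- 20160901

## Ground truth: a single-peak seasonal climatology over a 60 x 60 domain.
## The correlation length (smoothness 8 cells) is set well above the 16-km
## station footprint so footprint averaging preserves the spatial signal,
## as synoptic-scale cloud structure does in reality.
truth <- generate_truth_climatology(60, 60, "sinusoid",
                                    p_range = c(0.2, 0.8), amplitude = 0.18,
                                    peak_month = 7, smoothness = 8,
                                    seed = seed)
saveRDS(truth, "scratch/truth_climatology.rds")

## Two sensors (morning/afternoon) with +-15 degree stripe bias
sim <- generate_cloud_stack(truth, years = 2000:2004, days_per_month = 30,
                            sensors = default_sensors(stripe_amplitude = 0.15),
                            seed = seed)
saveRDS(sim, "scratch/cloud_stack.rds")

## Station archive: 120 stations, 5% of sky noise, 20% sparse reporters
stations <- generate_station_records(truth, n_stations = 120, noise_sd = 5,
                                     years = 2000:2009, frac_low = 0.2,
                                     seed = seed)
write.csv(stations$stations, "scratch/inputs/stations.csv",
          row.names = FALSE)
write.csv(stations$obs_counts, "scratch/inputs/station_obs_counts.csv",
          row.names = FALSE)
saveRDS(stations, "scratch/stations.rds")

## Occupancy data: detections of a virtual montane species whose
## suitability tracks mean annual cloudiness (x1) and an independent smooth
## habitat axis (x2), sampled at 2000 surveyed cells of the same grid so
## the predictions carry spatial structure.
set.seed(seed %% 100000)
cells <- sort(sample.int(3600, 2000))
truth_annual <- Reduce(`+`, lapply(truth$grids, `[[`, "values")) / 12
habitat <- cloudclim:::gaussian_smooth(matrix(rnorm(3600), 60, 60), 6)
std <- function(v) (v - mean(v)) / sd(v)
X <- cbind(1, x1 = std(truth_annual[cells]), x2 = std(habitat[cells]))
occ <- generate_occupancy_data(c(-1, 2, -0.8), 0.5, X = X, seed = seed)
cc <- cell_centers(truth$grids[[1L]])
occ$data$lon <- cc$lon[(cells - 1L) %/% 60 + 1L]
occ$data$lat <- cc$lat[(cells - 1L) %% 60 + 1L]
occ$cells <- cells
write.csv(occ$data, "scratch/inputs/occurrence_cells.csv", row.names = FALSE)
saveRDS(occ, "scratch/occupancy.rds")

truth_params <- attr(truth, "truth")
jsonlite::write_json(
  list(seed = seed, grid = c(60, 60),
       seasonal_mode = truth_params$seasonal_mode,
       p_range = truth_params$p_range,
       amplitude = truth_params$amplitude,
       peak_month = truth_params$peak_month,
       sensors = "am/pm, stripes +-15 deg, bias 0.15, gap every 16 d",
       stations = list(n = 120, noise_sd = 5, frac_low = 0.2),
       occupancy = list(beta = occ$beta, delta = occ$delta, n_cells = 2000)),
  "results/inputs/truth_parameters.json", auto_unbox = TRUE, pretty = TRUE)

cat("Simulated: 60x60 truth, 2 sensors x 5 y x 360 d,",
    "120 stations, 2000 occupancy cells.\n")
cat("Ground truth recorded in results/inputs/truth_parameters.json\n")
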