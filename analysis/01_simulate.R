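#!/usr/bin/env Rscript
# Generate the synthetic study data: two arms of 8 Langendorff-perfused
# hearts (mononuclear cells vs stromal cells, 1e6 cells each), written in
# the CSV schemas the analysis steps read. Ground truth goes alongside so
# later steps can be checked against it.

suppressPackageStartupMessages(library(icretention))

seed <- 20160705
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (type in c("BMMNC", "MSC")) {
  params <- simulator_params(type)
  set.seed(seed + (type == "MSC"))
  runs <- list(); sizes <- list(); hist <- list(); truth <- list()
  for (i in 1:8) {
    sim <- simulate_run(params, dose = 1e6)
    id <- sprintf("%s_h%d", type, i)
    runs[[id]] <- sim$run
    sizes[[id]] <- rbind(
      data.frame(sample_id = id, population = "pre",
                 bin_lower_um = sim$truth$pre_histogram$bin_lower,
                 count = sim$truth$pre_histogram$count),
      data.frame(sample_id = id, population = "effluent",
                 bin_lower_um = sim$truth$effluent_histogram$bin_lower,
                 count = sim$truth$effluent_histogram$count))
    truth[[id]] <- list(retained_fraction = sim$truth$retained_fraction,
                        retained_count = sim$truth$retained_count)
    if (i <= 4) {  # four hearts per arm go to histology
      h <- simulate_sections(params, sim$truth$retained_count,
                             injected_dose = 1e6)
      df <- as.data.frame(h$sections)
      df$heart_id <- id
      df$heart_mass_mg <- h$heart_mass_mg
      df$injected_dose <- h$injected_dose
      hist[[id]] <- df
    }
  }
  write_effluent_csv(runs, file.path(out_dir, paste0(type, "_effluent.csv")))
  write_sizes_csv(do.call(rbind, sizes),
                  file.path(out_dir, paste0(type, "_sizes.csv")))
  write_histology_csv(do.call(rbind, hist),
                      file.path(out_dir, paste0(type, "_histology.csv")))
  jsonlite::write_json(truth, file.path(out_dir, paste0(type, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s: wrote 8 effluent runs, size histograms, 4 histology hearts\n",
              type))
}
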