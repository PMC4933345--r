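# Schema-validated CSV/JSON/YAML input-output and the end-to-end report.

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

fail_rows <- function(path, bad, what) {
  if (any(bad)) {
    # +1 for the header line, so numbers match the file as viewed
    stop(path, ": ", what, " at line(s) ",
         paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  }
}

#' Read a per-minute effluent table
#'
#' Expected columns: `run_id`, `cell_type`, `injected_dose`, `minute`,
#' `flow_ml_min`, `conc_cells_ml`, `replicate` (one row per replicate read).
#' Malformed rows are reported with their file line numbers; duplicate
#' `(run_id, minute, replicate)` keys and negative quantities are hard
#' errors.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_effluent_csv <- function(path) {
  df <- read_checked_csv(path, c("run_id", "cell_type", "injected_dose",
                                 "minute", "flow_ml_min", "conc_cells_ml",
                                 "replicate"))
  fail_rows(path, is.na(df$minute) | df$minute < 1, "invalid minute index")
  fail_rows(path, is.na(df$conc_cells_ml) | df$conc_cells_ml < 0,
            "negative or missing concentration")
  fail_rows(path, is.na(df$flow_ml_min) | df$flow_ml_min < 0,
            "negative or missing flow")
  fail_rows(path, is.na(df$injected_dose) | df$injected_dose <= 0,
            "non-positive injected dose")
  key <- paste(df$run_id, df$minute, df$replicate, sep = "|")
  if (anyDuplicated(key)) {
    stop(path, ": duplicate (run_id, minute, replicate) key: ",
         key[anyDuplicated(key)], call. = FALSE)
  }
  df
}

#' Turn a long effluent table into perfusion runs
#'
#' @param df data frame in the [read_effluent_csv()] schema.
#' @return named list of [perfusion_run()] objects, one per `run_id`.
#' @export
as_perfusion_runs <- function(df) {
  lapply(split(df, df$run_id), function(g) {
    perfusion_run(
      injected_dose = g$injected_dose[1L],
      cell_type = g$cell_type[1L],
      effluent = effluent_series(g$minute, g$flow_ml_min, g$conc_cells_ml)
    )
  })
}

#' Write an effluent table for a set of simulated runs
#'
#' @param runs named list of [perfusion_run()] objects.
#' @param path output CSV path.
#' @export
write_effluent_csv <- function(runs, path) {
  rows <- lapply(names(runs), function(id) {
    r <- runs[[id]]
    e <- r$effluent
    rep_idx <- stats::ave(seq_len(nrow(e)), e$minute, FUN = seq_along)
    data.frame(run_id = id, cell_type = r$cell_type,
               injected_dose = r$injected_dose,
               minute = e$minute, flow_ml_min = e$flow_ml_min,
               conc_cells_ml = e$conc_cells_ml, replicate = rep_idx)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read size-histogram tables
#'
#' Expected columns: `sample_id`, `population` (`pre` or `effluent`),
#' `bin_lower_um`, `count`.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_sizes_csv <- function(path) {
  df <- read_checked_csv(path, c("sample_id", "population", "bin_lower_um",
                                 "count"))
  fail_rows(path, is.na(df$count) | df$count < 0, "negative or missing count")
  fail_rows(path, !df$population %in% c("pre", "effluent"),
            "population must be 'pre' or 'effluent'")
  key <- paste(df$sample_id, df$population, df$bin_lower_um, sep = "|")
  if (anyDuplicated(key)) {
    stop(path, ": duplicate (sample_id, population, bin) key: ",
         key[anyDuplicated(key)], call. = FALSE)
  }
  df
}

#' @rdname read_sizes_csv
#' @param df data frame in the sizes schema.
#' @export
write_sizes_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a histology section-count table
#'
#' Expected columns: `heart_id`, `level`, `layer`, `labeled_cells`,
#' `area_mm2`, `heart_mass_mg`, `injected_dose`.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_histology_csv <- function(path) {
  df <- read_checked_csv(path, c("heart_id", "level", "layer",
                                 "labeled_cells", "area_mm2",
                                 "heart_mass_mg", "injected_dose"))
  fail_rows(path, is.na(df$labeled_cells) | df$labeled_cells < 0,
            "negative or missing labeled_cells")
  fail_rows(path, is.na(df$area_mm2) | df$area_mm2 <= 0,
            "non-positive examined area")
  fail_rows(path, is.na(df$heart_mass_mg) | df$heart_mass_mg <= 0,
            "non-positive heart mass")
  df
}

#' @rdname read_histology_csv
#' @param df data frame in the histology schema.
#' @export
write_histology_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save / load simulator parameters as YAML
#'
#' Round-trips every field of a [simulator_params()] object, including a
#' per-bin retention table if present.
#'
#' @param params a [simulator_params()] object.
#' @param path YAML file path.
#' @return `write_params` the path, invisibly; `read_params` the
#'   reconstructed `simulator_params`.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  if (!is.null(x$retention_table)) {
    x$retention_table <- as.list(as.data.frame(x$retention_table))
  }
  x$transmural_weights <- as.list(x$transmural_weights)
  if (!is.null(x$marker_fractions)) {
    x$marker_fractions <- as.list(x$marker_fractions)
  }
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  rt <- if (!is.null(x$retention_table)) {
    as.data.frame(x$retention_table)
  } else NULL
  simulator_params(
    cell_type = x$cell_type,
    size_median_um = x$size_median_um,
    size_sigma = x$size_sigma,
    entrap_d50_um = x$entrap_d50_um,
    entrap_k = x$entrap_k,
    entrap_pmax = x$entrap_pmax,
    target_retention = x$target_retention,
    retention_table = rt,
    transit_tau_s = x$transit_tau_s,
    injection_duration_s = x$injection_duration_s,
    injection_volume_ml = x$injection_volume_ml,
    baseline_flow_ml_min = x$baseline_flow_ml_min,
    obstruction_fraction = x$obstruction_fraction,
    flow_recovery_min = x$flow_recovery_min,
    counter_cv = x$counter_cv,
    n_reads = x$n_reads,
    transmural_weights = unlist(x$transmural_weights),
    dead_cell_fraction = x$dead_cell_fraction,
    marker_fractions = if (!is.null(x$marker_fractions))
      unlist(x$marker_fractions),
    window_minutes = x$window_minutes,
    n_minutes = x$n_minutes
  )
}

#' Run the full pipeline end to end on simulated hearts
#'
#' Simulates `n_hearts` injections, runs the effluent retention pipeline on
#' each, pools pre-injection and effluent size histograms for per-bin
#' retention, simulates histological sections for `n_histology` hearts and
#' applies the stereological estimator, and summarises both arms side by
#' side. All randomness flows from `seed`.
#'
#' @param cell_type `"BMMNC"` or `"MSC"`.
#' @param dose cells injected per heart.
#' @param n_hearts number of simulated hearts (>= 1).
#' @param seed integer seed for the whole report.
#' @param params optional [simulator_params()] override.
#' @param n_histology hearts carried into the histology arm (default 4).
#' @param window_minutes retention window, minutes.
#' @return list of class `retention_report` with elements `per_run` (data
#'   frame), `retention_mean_pct`, `retention_sem_pct`,
#'   `first_minute_mean_pct`, `per_bin` (pooled per-bin retention table),
#'   `histology` (per-heart estimates plus transmural summary),
#'   `effluent_vs_histology_pct` (difference of arm means), `expected_pct`
#'   (analytic oracle), `config`.
#' @export
run_report <- function(cell_type = "BMMNC", dose = 1e6, n_hearts = 8,
                       seed = 1, params = NULL, n_histology = 4,
                       window_minutes = 5L) {
  if (n_hearts < 1) stop("'n_hearts' must be >= 1", call. = FALSE)
  if (is.null(params)) params <- simulator_params(cell_type)
  params$window_minutes <- as.integer(window_minutes)
  set.seed(seed)

  per_run <- vector("list", n_hearts)
  pre_pool <- NULL
  eff_pool <- NULL
  truths <- vector("list", n_hearts)
  for (i in seq_len(n_hearts)) {
    sim <- simulate_run(params, dose)
    res <- analyze_run(sim$run, window_minutes = window_minutes)
    per_run[[i]] <- data.frame(
      heart = i,
      retention_pct = res$retention_pct,
      first_minute_pct = res$first_minute_pct,
      total_effluent = res$total_effluent,
      true_retained_fraction = sim$truth$retained_fraction
    )
    truths[[i]] <- sim$truth
    if (is.null(pre_pool)) {
      pre_pool <- sim$truth$pre_histogram
      eff_pool <- sim$truth$effluent_histogram
    } else {
      al <- align_histograms(pre_pool, sim$truth$pre_histogram)
      pre_pool <- size_histogram(al[[1]]$bin_lower,
                                 al[[1]]$count + al[[2]]$count)
      al <- align_histograms(eff_pool, sim$truth$effluent_histogram)
      eff_pool <- size_histogram(al[[1]]$bin_lower,
                                 al[[1]]$count + al[[2]]$count)
    }
  }
  per_run <- do.call(rbind, per_run)
  al <- align_histograms(pre_pool, eff_pool)
  per_bin <- per_bin_retention(al[[1]], al[[2]])

  n_hist <- min(n_histology, n_hearts)
  hist_rows <- lapply(seq_len(n_hist), function(i) {
    h <- simulate_sections(params, truths[[i]]$retained_count,
                           injected_dose = dose)
    est <- whole_heart_estimate(h)
    list(est = data.frame(heart = i,
                          retained_cells = est$retained_cells,
                          retention_pct = est$retention_pct),
         sections = transform(as.data.frame(h$sections), heart_id = paste0("h", i)))
  })
  hist_est <- do.call(rbind, lapply(hist_rows, `[[`, "est"))
  all_sections <- do.call(rbind, lapply(hist_rows, `[[`, "sections"))
  grad <- transmural_gradient(all_sections)

  sem <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(
    per_run = per_run,
    retention_mean_pct = mean(per_run$retention_pct),
    retention_sem_pct = sem(per_run$retention_pct),
    first_minute_mean_pct = mean(per_run$first_minute_pct),
    per_bin = per_bin,
    histology = list(per_heart = hist_est,
                     mean_pct = mean(hist_est$retention_pct),
                     sem_pct = sem(hist_est$retention_pct),
                     layer_density = grad$layer_density,
                     endo_epi_ratio = as.numeric(grad$endo_epi_ratio)),
    effluent_vs_histology_pct =
      mean(per_run$retention_pct) - mean(hist_est$retention_pct),
    expected_pct = 100 * expected_retention(params),
    config = list(cell_type = cell_type, dose = dose, n_hearts = n_hearts,
                  seed = seed, window_minutes = window_minutes)
  ), class = "retention_report")
}

#' @export
print.retention_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Retention report: %s, dose %.3g, %d heart(s), seed %d\n",
              cfg$cell_type, cfg$dose, cfg$n_hearts, cfg$seed))
  cat(sprintf("  effluent arm : %.1f +/- %.1f %% (mean +/- SEM)\n",
              x$retention_mean_pct, x$retention_sem_pct))
  cat(sprintf("  analytic     : %.1f %%\n", x$expected_pct))
  cat(sprintf("  first minute : %.1f %% of exited cells\n",
              x$first_minute_mean_pct))
  cat(sprintf("  histology arm: %.1f +/- %.1f %% (endo:epi %.2f)\n",
              x$histology$mean_pct, x$histology$sem_pct,
              x$histology$endo_epi_ratio))
  invisible(x)
}

#' Write a report as JSON
#'
#' Numbers are serialised at full precision; rounding is a display concern.
#'
#' @param report a `retention_report` from [run_report()].
#' @param path output JSON path.
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  x$histology$layer_density <- as.list(x$histology$layer_density)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
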