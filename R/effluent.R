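# Effluent-based retention: per-minute coronary effluent cell numbers,
# windowed totals, retention rate, first-minute washout fraction, and
# clinical-to-animal dose conversion.

#' Coronary effluent cell number for one minute
#'
#' Converts replicate cell-concentration reads (cells/ml) and the effluent
#' flow volume for one minute (ml/min) into a cell exit rate (cells/min).
#' Replicates are aggregated with the arithmetic mean by default (automated
#' counters report at least three reads per sample); the median is available
#' for robustness against a single aberrant read. An optional constant
#' red-blood-cell background rate (cells/min) can be subtracted; the result
#' is floored at zero.
#'
#' @param reads numeric vector of >= 1 concentration reads, cells/ml.
#' @param flow_ml_min effluent volume collected in the minute, ml.
#' @param background background cell rate to subtract, cells/min. Default 0:
#'   hearts are perfused until residual red-cell washout is negligible
#'   (< 1e5 cells/min) before injection.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return cells/min, a single non-negative number.
#' @examples
#' effluent_cell_number(c(900, 1000, 1100), flow_ml_min = 10)
#' @export
effluent_cell_number <- function(reads, flow_ml_min, background = 0,
                                 aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (length(reads) < 1L || anyNA(reads)) {
    stop("'reads' must contain at least one non-missing concentration", call. = FALSE)
  }
  if (any(reads < 0)) stop("concentration reads must be >= 0", call. = FALSE)
  if (length(flow_ml_min) != 1L || is.na(flow_ml_min) || flow_ml_min < 0) {
    stop("'flow_ml_min' must be a single non-negative number", call. = FALSE)
  }
  conc <- if (aggregate == "mean") mean(reads) else stats::median(reads)
  if (background > 0) {
    warning(sprintf("subtracting background of %g cells/min", background),
            call. = FALSE)
  }
  max(conc * flow_ml_min - background, 0)
}

#' Construct a per-minute effluent series
#'
#' An effluent series is a data frame in long replicate format with columns
#' `minute` (1-based; minute 1 is the first minute after injection start),
#' `flow_ml_min` and `conc_cells_ml` (one row per replicate read). This
#' constructor validates the invariants shared by all downstream functions.
#'
#' @param minute integer minute index per row, >= 1.
#' @param flow_ml_min effluent volume per minute, ml; constant within a minute.
#' @param conc_cells_ml concentration read, cells/ml.
#' @return validated `data.frame` with class `effluent_series`.
#' @export
effluent_series <- function(minute, flow_ml_min, conc_cells_ml) {
  df <- data.frame(minute = as.integer(minute),
                   flow_ml_min = as.numeric(flow_ml_min),
                   conc_cells_ml = as.numeric(conc_cells_ml))
  validate_effluent_series(df)
}

validate_effluent_series <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("minute", "flow_ml_min", "conc_cells_ml")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("effluent series missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$minute < 1L)) stop("minute indices must be >= 1", call. = FALSE)
  if (any(df$conc_cells_ml < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(df$flow_ml_min < 0)) stop("flow volumes must be >= 0", call. = FALSE)
  fl <- tapply(df$flow_ml_min, df$minute, function(x) length(unique(x)))
  if (any(fl > 1L)) {
    stop("flow_ml_min must be constant within a minute (minute ",
         names(fl)[which(fl > 1L)[1L]], " differs)", call. = FALSE)
  }
  class(df) <- union("effluent_series", class(df))
  df
}

#' Per-minute effluent cell numbers for a series
#'
#' @param series an [effluent_series()] data frame.
#' @inheritParams effluent_cell_number
#' @return data frame with one row per minute: `minute`, `flow_ml_min`,
#'   `cells_per_min`.
#' @export
per_minute_cells <- function(series, background = 0,
                             aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  series <- validate_effluent_series(as.data.frame(series))
  sp <- split(series, series$minute)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(minute = g$minute[1L],
               flow_ml_min = g$flow_ml_min[1L],
               cells_per_min = effluent_cell_number(
                 g$conc_cells_ml, g$flow_ml_min[1L],
                 background = background, aggregate = aggregate))
  }))
  rownames(out) <- NULL
  out[order(out$minute), ]
}

#' Total donor cell number in coronary effluent over a window
#'
#' Sums per-minute effluent cell numbers over minutes `1..window_minutes`.
#' Every minute in the window must be present; a gap is an error naming the
#' missing minute.
#'
#' @param per_minute data frame with columns `minute` and `cells_per_min`
#'   (as returned by [per_minute_cells()]).
#' @param window_minutes collection window in minutes (default 5; effluent
#'   cell exit is essentially complete within 5 minutes of injection).
#' @return total cells exited over the window.
#' @export
total_effluent <- function(per_minute, window_minutes = 5L) {
  stopifnot(is.data.frame(per_minute),
            all(c("minute", "cells_per_min") %in% names(per_minute)))
  window_minutes <- as.integer(window_minutes)
  if (window_minutes < 1L) stop("'window_minutes' must be >= 1", call. = FALSE)
  want <- seq_len(window_minutes)
  gap <- setdiff(want, per_minute$minute)
  if (length(gap)) {
    stop("effluent series is missing minute(s) ",
         paste(gap, collapse = ", "), " within the window", call. = FALSE)
  }
  if (anyDuplicated(per_minute$minute)) {
    stop("duplicate minute index in per-minute series: minute ",
         per_minute$minute[anyDuplicated(per_minute$minute)], call. = FALSE)
  }
  sum(per_minute$cells_per_min[per_minute$minute %in% want])
}

#' Donor cell retention rate
#'
#' `(injected - total_effluent) / injected * 100`. When counting noise makes
#' the effluent total exceed the injected dose, the raw value is negative; by
#' default it is clamped to 0% with a warning, and the unclamped value is kept
#' in the `"raw"` attribute of the result.
#'
#' @param injected_dose cells injected, > 0.
#' @param total_effluent total cells in the effluent window, >= 0.
#' @param clamp clamp negative rates to 0 (default TRUE).
#' @return retention in percent; attribute `raw` holds the unclamped value and
#'   attribute `clamped` whether clamping occurred.
#' @examples
#' retention_rate(8e6, 6.392e6)   # 20.1
#' @export
retention_rate <- function(injected_dose, total_effluent, clamp = TRUE) {
  if (length(injected_dose) != 1L || is.na(injected_dose) || injected_dose <= 0) {
    stop("'injected_dose' must be a single positive number", call. = FALSE)
  }
  if (total_effluent < 0) stop("'total_effluent' must be >= 0", call. = FALSE)
  raw <- (injected_dose - total_effluent) / injected_dose * 100
  val <- raw
  clamped <- FALSE
  if (raw < 0 && clamp) {
    warning(sprintf(
      "effluent total (%.4g) exceeds injected dose (%.4g); retention clamped to 0%%",
      total_effluent, injected_dose), call. = FALSE)
    val <- 0
    clamped <- TRUE
  }
  structure(val, raw = raw, clamped = clamped)
}

#' Fraction of exiting cells that leave within the first minute
#'
#' @param per_minute per-minute cell numbers (see [per_minute_cells()]).
#' @param window_minutes window over which the total is taken.
#' @return percent of the windowed effluent total that exited in minute 1.
#'   When the total is zero the fraction is undefined and `NA` is returned
#'   with attribute `undefined = TRUE` (no error).
#' @export
first_minute_fraction <- function(per_minute, window_minutes = 5L) {
  tot <- total_effluent(per_minute, window_minutes)
  if (tot == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  m1 <- per_minute$cells_per_min[per_minute$minute == 1L]
  structure(m1 / tot * 100, undefined = FALSE)
}

#' Analyse one perfusion run
#'
#' Runs the full effluent pipeline for one heart: per-minute cell numbers,
#' windowed effluent total, retention rate (with clamping policy) and
#' first-minute washout fraction.
#'
#' @param run a [perfusion_run()] object.
#' @param window_minutes retention window (default 5 minutes).
#' @param clamp clamp negative retention to 0 (default TRUE).
#' @inheritParams effluent_cell_number
#' @return object of class `retention_result`: list with `per_minute`,
#'   `total_effluent`, `retention_pct`, `retention_pct_raw`, `clamped`,
#'   `first_minute_pct`, `window_minutes`, `injected_dose`, `cell_type`.
#' @export
analyze_run <- function(run, window_minutes = 5L, clamp = TRUE,
                        background = 0, aggregate = c("mean", "median")) {
  stopifnot(inherits(run, "perfusion_run"))
  aggregate <- match.arg(aggregate)
  pm <- per_minute_cells(run$effluent, background = background,
                         aggregate = aggregate)
  tot <- total_effluent(pm, window_minutes)
  rr <- retention_rate(run$injected_dose, tot, clamp = clamp)
  structure(list(
    per_minute = pm,
    total_effluent = tot,
    retention_pct = as.numeric(rr),
    retention_pct_raw = attr(rr, "raw"),
    clamped = attr(rr, "clamped"),
    first_minute_pct = as.numeric(first_minute_fraction(pm, window_minutes)),
    window_minutes = as.integer(window_minutes),
    injected_dose = run$injected_dose,
    cell_type = run$cell_type
  ), class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  cat(sprintf("Retention result (%s, dose %.3g cells, %d-min window)\n",
              x$cell_type, x$injected_dose, x$window_minutes))
  cat(sprintf("  total effluent : %.4g cells\n", x$total_effluent))
  cat(sprintf("  retention      : %.1f %%%s\n", x$retention_pct,
              if (isTRUE(x$clamped)) " (clamped)" else ""))
  cat(sprintf("  first-minute   : %.1f %% of exited cells\n",
              x$first_minute_pct))
  invisible(x)
}

#' One heart perfusion experiment
#'
#' Bundles the injected dose, cell type, per-minute effluent series and the
#' injection protocol metadata (3 ml suspension over 20 s by default) for a
#' single ex-vivo perfused heart.
#'
#' @param injected_dose cells injected, > 0.
#' @param cell_type label, e.g. `"BMMNC"` or `"MSC"`.
#' @param effluent an [effluent_series()] covering at least minutes 1..5.
#' @param pre_population optional [cell_population()] measured before injection.
#' @param baseline_flow pre-injection coronary flow, ml/min.
#' @param injection_volume injectate volume, ml.
#' @param injection_duration injection duration, seconds.
#' @return object of class `perfusion_run`.
#' @export
perfusion_run <- function(injected_dose, cell_type, effluent,
                          pre_population = NULL, baseline_flow = NA_real_,
                          injection_volume = 3, injection_duration = 20) {
  if (injected_dose <= 0) stop("'injected_dose' must be > 0", call. = FALSE)
  effluent <- validate_effluent_series(as.data.frame(effluent))
  structure(list(injected_dose = injected_dose,
                 cell_type = cell_type,
                 effluent = effluent,
                 pre_population = pre_population,
                 baseline_flow = baseline_flow,
                 injection_volume = injection_volume,
                 injection_duration = injection_duration),
            class = "perfusion_run")
}

#' Scale a clinical intracoronary dose to an animal model
#'
#' Allometric (body-mass proportional) conversion of a human single-artery
#' cell dose to the equivalent dose for one animal coronary artery, and the
#' total over all injected arteries. Reported values follow the convention of
#' rounding the per-artery dose to 2 significant figures and the total to 1
#' significant figure; raw unrounded values are returned alongside.
#'
#' @param human_dose cells injected into a single human coronary artery.
#' @param human_mass_kg human body mass, kg (reference 75 kg).
#' @param animal_mass_kg animal body mass, kg (e.g. 0.2 for a 200 g rat).
#' @param n_arteries number of arteries injected in the animal model
#'   (3 for the rat: right, left anterior descending, left circumflex).
#' @return list with `per_artery`, `total` (rounded for reporting) and
#'   `per_artery_raw`, `total_raw`.
#' @examples
#' convert_clinical_dose(1e9, 75, 0.2, 3)  # 2.7e6 per artery, 8e6 total
#' @export
convert_clinical_dose <- function(human_dose, human_mass_kg, animal_mass_kg,
                                  n_arteries = 3L) {
  if (human_dose <= 0) stop("'human_dose' must be > 0", call. = FALSE)
  if (human_mass_kg <= 0 || animal_mass_kg <= 0) {
    stop("body masses must be > 0", call. = FALSE)
  }
  n_arteries <- as.integer(n_arteries)
  if (n_arteries < 1L) stop("'n_arteries' must be >= 1", call. = FALSE)
  per_raw <- human_dose * animal_mass_kg / human_mass_kg
  per <- signif(per_raw, 2)
  list(per_artery = per,
       total = signif(per * n_arteries, 1),
       per_artery_raw = per_raw,
       total_raw = per_raw * n_arteries)
}
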