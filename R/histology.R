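# Stereological whole-heart retention estimate from thin sections, and the
# transmural (epicardium -> endocardium) gradient of labelled-cell density.

#' Section-count table for one or more hearts
#'
#' One row per counted section (or per wall layer within a section):
#' `heart_id`, `level` (`base`, `mid`, `apex`), `layer` (`whole`,
#' `epicardial`, `mid-myocardial`, `endocardial`), `labeled_cells`
#' (fluorescently labelled donor cells counted in the section) and
#' `area_mm2` (myocardial area examined).
#'
#' @param heart_id heart identifier.
#' @param level section level along the long axis.
#' @param layer wall layer, or `"whole"` for the full cross-section.
#' @param labeled_cells labelled donor cells counted, >= 0.
#' @param area_mm2 examined myocardial area, mm^2, > 0.
#' @return validated data frame with class `section_counts`.
#' @export
section_counts <- function(heart_id, level, layer, labeled_cells, area_mm2) {
  df <- data.frame(heart_id = as.character(heart_id),
                   level = as.character(level),
                   layer = as.character(layer),
                   labeled_cells = as.numeric(labeled_cells),
                   area_mm2 = as.numeric(area_mm2))
  validate_section_counts(df)
}

validate_section_counts <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("heart_id", "level", "layer", "labeled_cells", "area_mm2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("section table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$labeled_cells < 0)) stop("labeled_cells must be >= 0", call. = FALSE)
  if (any(df$area_mm2 <= 0)) stop("area_mm2 must be > 0", call. = FALSE)
  class(df) <- union("section_counts", class(df))
  df
}

#' Stereology inputs for one heart
#'
#' @param heart_mass_mg heart wet mass, mg; under the tissue-density
#'   assumption 1 mg of myocardium occupies 1 mm^3, so mass doubles as the
#'   myocardial volume in mm^3.
#' @param sections a [section_counts()] table for this heart.
#' @param injected_dose cells injected, > 0.
#' @param section_thickness_mm cryosection thickness, mm (default 0.0075,
#'   i.e. 7.5 um).
#' @return object of class `heart_stereology`.
#' @export
heart_stereology <- function(heart_mass_mg, sections, injected_dose,
                             section_thickness_mm = 0.0075) {
  if (heart_mass_mg <= 0) stop("'heart_mass_mg' must be > 0", call. = FALSE)
  if (section_thickness_mm <= 0) {
    stop("'section_thickness_mm' must be > 0", call. = FALSE)
  }
  if (injected_dose <= 0) stop("'injected_dose' must be > 0", call. = FALSE)
  sections <- validate_section_counts(as.data.frame(sections))
  structure(list(heart_mass_mg = heart_mass_mg,
                 sections = sections,
                 injected_dose = injected_dose,
                 section_thickness_mm = section_thickness_mm),
            class = "heart_stereology")
}

#' Whole-heart retained-cell estimate from thin sections
#'
#' Areal labelled-cell densities (cells/mm^2) of the whole-cross-section
#' counts are averaged over the heart's sections, converted to a volumetric
#' density by dividing by the section thickness (mm), and scaled by the
#' myocardial volume (heart mass in mg, taken as mm^3):
#'
#' `retained = mean(labeled_cells / area_mm2) / thickness_mm * heart_mass_mg`
#'
#' @param h a [heart_stereology()] object.
#' @param weighting `"equal"` (default) averages section densities with equal
#'   weight; `"area"` weights each section by its examined area (i.e. pooled
#'   counts over pooled area).
#' @return list with `mean_density` (cells/mm^2), `retained_cells` and
#'   `retention_pct`.
#' @examples
#' sec <- section_counts("h1", c("base", "mid", "apex"), "whole",
#'                       labeled_cells = c(804.6, 894, 983.4),
#'                       area_mm2 = c(90, 100, 110))
#' whole_heart_estimate(heart_stereology(1242, sec, 8e6))
#' @export
whole_heart_estimate <- function(h, weighting = c("equal", "area")) {
  stopifnot(inherits(h, "heart_stereology"))
  weighting <- match.arg(weighting)
  sec <- h$sections[h$sections$layer == "whole", , drop = FALSE]
  if (nrow(sec) == 0L) {
    stop("no whole-section counts available for the stereological estimate",
         call. = FALSE)
  }
  dens <- if (weighting == "equal") {
    mean(sec$labeled_cells / sec$area_mm2)
  } else {
    sum(sec$labeled_cells) / sum(sec$area_mm2)
  }
  retained <- dens / h$section_thickness_mm * h$heart_mass_mg
  list(mean_density = dens,
       retained_cells = retained,
       retention_pct = retained / h$injected_dose * 100)
}

#' Transmural gradient of labelled-cell density
#'
#' Two-stage averaging that mirrors how layer densities are reported: the
#' density of each wall layer is first averaged within each heart across its
#' section levels (base/mid/apex), then across hearts; the gradient is
#' summarised as the endocardial:epicardial density ratio.
#'
#' @param sections a [section_counts()] table covering >= 2 distinct wall
#'   layers (rows with `layer == "whole"` are ignored).
#' @return list with `layer_density` (named mean densities, cells/mm^2),
#'   `per_heart` (heart x layer density matrix) and `endo_epi_ratio`
#'   (`NA` with attribute `undefined = TRUE` if the mean epicardial density
#'   is zero).
#' @export
transmural_gradient <- function(sections) {
  sections <- validate_section_counts(as.data.frame(sections))
  lay <- sections[sections$layer != "whole", , drop = FALSE]
  if (length(unique(lay$layer)) < 2L) {
    stop("need counts for at least two distinct wall layers", call. = FALSE)
  }
  lay$density <- lay$labeled_cells / lay$area_mm2
  # stage 1: mean density per heart and layer (across levels)
  per_heart <- tapply(lay$density, list(lay$heart_id, lay$layer), mean)
  # stage 2: mean across hearts
  layer_density <- colMeans(per_heart, na.rm = TRUE)
  epi <- if ("epicardial" %in% names(layer_density))
    layer_density[["epicardial"]] else NA_real_
  endo <- if ("endocardial" %in% names(layer_density))
    layer_density[["endocardial"]] else NA_real_
  ratio <- if (is.na(epi) || is.na(endo) || epi == 0) {
    structure(NA_real_, undefined = TRUE)
  } else {
    structure(endo / epi, undefined = FALSE)
  }
  list(layer_density = layer_density,
       per_heart = per_heart,
       endo_epi_ratio = ratio)
}
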