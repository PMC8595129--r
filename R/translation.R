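# Monkey-to-human translation: single-species allometric clearance
# scaling, BSA-based human-equivalent dose with a safety factor, and the
# ultrafiltration plasma-protein-binding calculation.

#' Body-surface-area dose-conversion factors
#'
#' The standard regulatory Km table (body weight / body surface area) used
#' for animal-to-human dose conversion, bundled as a plain-text file.
#'
#' @param path Optional path to a user CSV with columns
#'   `species, km, reference_bw_kg`.
#' @return A data.frame.
#' @export
bsa_km_factors <- function(path = NULL) {
  read.csv(path %||% .extdata("dose_conversion_constants.csv"),
           comment.char = "#")
}

#' Single-species allometric clearance scaling
#'
#' `CL_human = CL_animal * (BW_human / BW_animal)^exponent`, with the fixed
#' exponent 0.8 conventionally used for macromolecules.
#'
#' @param cl_animal Animal clearance (L/h), > 0.
#' @param bw_animal,bw_human Body weights (kg), > 0.
#' @param exponent Allometric exponent (default 0.8).
#' @return Predicted human clearance (L/h).
#' @export
#' @examples
#' allometric_cl(0.611, 6, 60)  # ~3.86 L/h
allometric_cl <- function(cl_animal, bw_animal, bw_human, exponent = 0.8) {
  if (any(!is.finite(c(cl_animal, bw_animal, bw_human))) ||
      cl_animal <= 0 || bw_animal <= 0 || bw_human <= 0) {
    stop("clearance and body weights must be positive", call. = FALSE)
  }
  cl_animal * (bw_human / bw_animal)^exponent
}

#' First-in-human dose from an animal dose
#'
#' Converts an animal dose to the human-equivalent dose (HED) by the
#' body-surface-area rule `HED = dose_animal * Km_animal / Km_human`, then
#' to an absolute starting dose `HED * BW_human / safety_factor`. The
#' reported dose is the raw value rounded to the nearest 10 mg.
#'
#' @param animal_dose_mg_kg Animal dose (mg/kg), > 0.
#' @param km_animal,km_human BSA conversion factors (see
#'   [bsa_km_factors()]); defaults are the monkey (12) and human (37)
#'   standards.
#' @param human_bw Human body weight (kg), default 60.
#' @param safety_factor Divisor applied to the full HED (default 10).
#' @return List with `hed_mg_kg`, `raw_mg` and `reported_mg`.
#' @export
#' @examples
#' hed_dose(46)  # raw 89.5 mg, reported 90 mg
hed_dose <- function(animal_dose_mg_kg, km_animal = 12, km_human = 37,
                     human_bw = 60, safety_factor = 10) {
  vals <- c(animal_dose_mg_kg, km_animal, km_human, human_bw, safety_factor)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("dose, Km factors, body weight and safety factor must be positive",
         call. = FALSE)
  }
  hed <- animal_dose_mg_kg * km_animal / km_human
  raw <- hed * human_bw / safety_factor
  list(hed_mg_kg = hed, raw_mg = raw, reported_mg = round(raw / 10) * 10)
}

#' Fraction unbound from an ultrafiltration measurement
#'
#' `fu% = 100 * C_buffer / C_plasma` (buffer = ultrafiltrate chamber),
#' `bound% = 100 - fu%`. A buffer concentration above the plasma-chamber
#' concentration is nonphysical; the values are still returned with a
#' warning flag set.
#'
#' @param c_buffer Concentration in the buffer/ultrafiltrate chamber
#'   (ug/ml), >= 0.
#' @param c_plasma Concentration in the plasma chamber (ug/ml), > 0.
#' @return List with `fu_percent`, `bound_percent`, `nonphysical`
#'   (logical). Vectorised over measurements.
#' @export
#' @examples
#' fraction_unbound(1, 100)  # fu 1%, bound 99%
fraction_unbound <- function(c_buffer, c_plasma) {
  if (any(!is.finite(c_plasma) | c_plasma <= 0)) {
    stop("plasma-chamber concentration must be > 0", call. = FALSE)
  }
  if (any(!is.finite(c_buffer) | c_buffer < 0)) {
    stop("buffer-chamber concentration must be >= 0", call. = FALSE)
  }
  fu <- 100 * c_buffer / c_plasma
  nonphys <- c_buffer > c_plasma
  if (any(nonphys)) {
    warning("buffer concentration exceeds plasma-chamber concentration ",
            "(nonphysical measurement)", call. = FALSE)
  }
  list(fu_percent = fu, bound_percent = 100 - fu, nonphysical = nonphys)
}

#' Summarise a binding-study dataset
#'
#' Applies [fraction_unbound()] per measurement and reports mean +/- SD of
#' fu% and bound% per matrix and nominal concentration.
#'
#' @param data A data.frame with columns `matrix`, `nominal_conc`,
#'   `c_buffer`, `c_plasma` (as generated by [generate_binding_study()]).
#' @return A data.frame, one row per matrix x nominal concentration.
#' @export
binding_table <- function(data) {
  req <- c("matrix", "nominal_conc", "c_buffer", "c_plasma")
  missing <- setdiff(req, names(data))
  if (length(missing)) {
    stop("binding data missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fu <- fraction_unbound(data$c_buffer, data$c_plasma)
  data$fu_percent <- fu$fu_percent
  data$bound_percent <- fu$bound_percent
  agg <- function(x) c(mean = mean(x), sd = sd(x))
  out <- do.call(rbind, lapply(
    split(data, list(data$matrix, data$nominal_conc), drop = TRUE),
    function(d) data.frame(
      matrix = d$matrix[1], nominal_conc = d$nominal_conc[1], n = nrow(d),
      fu_mean = mean(d$fu_percent), fu_sd = sd(d$fu_percent),
      bound_mean = mean(d$bound_percent), bound_sd = sd(d$bound_percent),
      stringsAsFactors = FALSE)))
  out <- out[order(out$matrix, out$nominal_conc), ]
  rownames(out) <- NULL
  out
}
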