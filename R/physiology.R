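#' Load a bundled species physiology
#'
#' Returns the whole-body physiology used by the PBPK engine: body weight,
#' cardiac output, hematocrit, plasma volume, and the volume and blood flow
#' of each of the 14 perfused tissue compartments plus the arterial and
#' venous blood pools. Values are compiled from standard compendia of organ
#' weights and regional blood flows and are bundled as plain-text CSV files;
#' any entry can be overridden.
#'
#' @param species One of `"monkey"` (6 kg macaque), `"rat"` (0.25 kg
#'   Sprague-Dawley) or `"human_chinese_male"` (60 kg adult).
#' @param overrides Optional named list. Top-level entries
#'   `body_weight_kg`, `cardiac_output_L_h`, `hematocrit` or
#'   `blood_volume_L` replace the species defaults; an entry named after a
#'   tissue must be a list with elements `volume_L` and/or `flow_L_per_h`.
#'
#' @return An object of class `physiology_spec`: a list with elements
#'   `species`, `body_weight` (kg), `cardiac_output` (L/h), `hematocrit`,
#'   `blood_volume` (L), `plasma_volume` (L), `arterial_volume`,
#'   `venous_volume` (L, blood) and `tissues` (data.frame with columns
#'   `tissue`, `volume_L`, `flow_L_per_h` for the 14 perfused compartments).
#' @seealso [validate_physiology()]
#' @export
#' @examples
#' phys <- load_physiology("monkey")
#' phys$body_weight
#' validate_physiology(phys)$pass
load_physiology <- function(species = c("monkey", "rat", "human_chinese_male"),
                            overrides = NULL) {
  if (!is.character(species) || length(species) != 1 ||
      !species %in% c("monkey", "rat", "human_chinese_male")) {
    stop("unsupported species: ", paste(species, collapse = ", "),
         " (supported: monkey, rat, human_chinese_male)", call. = FALSE)
  }
  meta <- read.csv(.extdata("species_reference.csv"))
  m <- meta[meta$species == species, ]
  tab <- read.csv(.extdata(sprintf("physiology_%s.csv", species)),
                  comment.char = "#")

  bw <- m$body_weight_kg
  co <- m$cardiac_output_L_h
  hct <- m$hematocrit
  blood <- m$blood_volume_L

  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    for (key in names(overrides)) {
      val <- overrides[[key]]
      if (key == "body_weight_kg") bw <- val
      else if (key == "cardiac_output_L_h") co <- val
      else if (key == "hematocrit") hct <- val
      else if (key == "blood_volume_L") blood <- val
      else if (key %in% tab$tissue) {
        if (!is.null(val$volume_L)) {
          tab$volume_L[tab$tissue == key] <- val$volume_L
        }
        if (!is.null(val$flow_L_per_h)) {
          tab$flow_L_per_h[tab$tissue == key] <- val$flow_L_per_h
        }
      } else {
        stop("unknown physiology override: ", key, call. = FALSE)
      }
    }
  }

  art <- tab[tab$tissue == "arterial_blood", ]
  ven <- tab[tab$tissue == "venous_blood", ]
  tissues <- tab[tab$tissue %in% .perfused_tissues, ]
  rownames(tissues) <- NULL

  spec <- structure(list(
    species = species,
    body_weight = bw,
    cardiac_output = co,
    hematocrit = hct,
    blood_volume = blood,
    plasma_volume = blood * (1 - hct),
    arterial_volume = art$volume_L,
    venous_volume = ven$volume_L,
    tissues = tissues
  ), class = "physiology_spec")
  spec
}

#' Validate a physiology specification
#'
#' Checks the structural invariants the PBPK engine relies on: all 14
#' perfused compartments present with positive volumes and non-negative
#' flows, lung flow equal to cardiac output, systemic (non-lung) flows
#' summing to cardiac output within 1%, and total volume consistent with
#' body weight at unit density.
#'
#' @param spec A `physiology_spec`, as returned by [load_physiology()].
#' @return A list of class `physiology_validation` with elements `pass`
#'   (logical) and `violations` (character vector; empty when `pass`).
#'   Violations name the offending tissue and quantity; nothing is raised.
#' @export
validate_physiology <- function(spec) {
  v <- character()
  t <- spec$tissues

  missing <- setdiff(.perfused_tissues, t$tissue)
  if (length(missing)) {
    v <- c(v, paste0("missing tissue compartment(s): ",
                     paste(missing, collapse = ", ")))
  }
  for (i in seq_len(nrow(t))) {
    if (!is.finite(t$volume_L[i]) || t$volume_L[i] <= 0) {
      v <- c(v, paste0(t$tissue[i], ": volume must be > 0 (got ",
                       t$volume_L[i], " L)"))
    }
    if (!is.finite(t$flow_L_per_h[i]) || t$flow_L_per_h[i] < 0) {
      v <- c(v, paste0(t$tissue[i], ": blood flow must be >= 0 (got ",
                       t$flow_L_per_h[i], " L/h)"))
    }
  }
  for (nm in c("arterial_volume", "venous_volume", "plasma_volume")) {
    if (!is.finite(spec[[nm]]) || spec[[nm]] <= 0) {
      v <- c(v, paste0(nm, " must be > 0"))
    }
  }

  lung <- t$flow_L_per_h[t$tissue == "lung"]
  if (length(lung) == 1 && is.finite(lung) &&
      abs(lung - spec$cardiac_output) > 1e-6 * spec$cardiac_output) {
    v <- c(v, paste0("lung: blood flow (", signif(lung, 6),
                     " L/h) must equal cardiac output (",
                     signif(spec$cardiac_output, 6), " L/h)"))
  }

  sys <- t$flow_L_per_h[t$tissue %in% .systemic_tissues]
  if (length(sys) && all(is.finite(sys))) {
    ratio <- sum(sys) / spec$cardiac_output
    if (ratio < 0.99 || ratio > 1.01) {
      v <- c(v, paste0("flow balance: systemic tissue flows sum to ",
                       signif(sum(sys), 6), " L/h, ", signif(ratio, 4),
                       "x cardiac output (must be within 1%)"))
    }
  }

  vol_tot <- sum(t$volume_L) + spec$arterial_volume + spec$venous_volume
  if (is.finite(vol_tot) && vol_tot > 1.05 * spec$body_weight) {
    v <- c(v, paste0("total volume ", signif(vol_tot, 5),
                     " L exceeds 1.05 x body weight (",
                     signif(1.05 * spec$body_weight, 5), " L)"))
  }

  structure(list(pass = length(v) == 0, violations = v),
            class = "physiology_validation")
}

#' @export
print.physiology_spec <- function(x, ...) {
  cat(sprintf("<physiology_spec> %s: BW %.3g kg, CO %.4g L/h, Hct %.2f\n",
              x$species, x$body_weight, x$cardiac_output, x$hematocrit))
  cat(sprintf("  plasma %.3g L, arterial blood %.3g L, venous blood %.3g L\n",
              x$plasma_volume, x$arterial_volume, x$venous_volume))
  cat(sprintf("  %d perfused tissue compartments, total tissue volume %.4g L\n",
              nrow(x$tissues), sum(x$tissues$volume_L)))
  invisible(x)
}

#' @export
print.physiology_validation <- function(x, ...) {
  if (x$pass) {
    cat("physiology: PASS\n")
  } else {
    cat("physiology: FAIL\n")
    for (v in x$violations) cat(" -", v, "\n")
  }
  invisible(x)
}
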