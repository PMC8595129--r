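# Tissue:plasma partition coefficient (Kp) prediction from drug
# physicochemistry and tissue composition, Rodgers-Single equation family.
#
# Conventions: Kpu is the tissue:unbound-plasma concentration ratio; the
# reported Kp is tissue:total plasma, Kp = fup * Kpu. As in the published
# equations, unbound plasma drug is treated as residing in plasma water,
# with plasma taken as an effectively aqueous reference (no plasma-water
# normalisation term).

# Plasma and red-blood-cell composition constants used by the equations.
.plasma_comp <- list(f_nl = 0.0023, f_np = 0.0013, ph = 7.4)
.blood_cell_comp <- list(f_iw = 0.603, f_nl = 0.0017, f_np = 0.0029,
                         ap_mg_g = 0.5, ph = 7.22)

#' Describe a drug for Kp prediction
#'
#' Bundles the physicochemical descriptors the partition equations need.
#'
#' @param molecular_weight Molecular weight (Da), > 0.
#' @param ionization_class One of `"neutral"`, `"monoprotic_acid"`,
#'   `"monoprotic_base"`, `"zwitterion"`, `"polyanion"`. A polyanion (such
#'   as a phosphorothioate/phosphodiester oligonucleotide backbone) is
#'   treated as fully ionized at physiological pH.
#' @param pka Numeric vector of pKa values. Required: one value for
#'   monoprotic acids/bases, two (acidic then basic) for zwitterions;
#'   ignored for neutrals and optional for polyanions.
#' @param logp Octanol-water log partition coefficient of the neutral
#'   species.
#' @param fup Fraction unbound in plasma, in (0, 1].
#' @param blood_plasma_ratio Blood:plasma total concentration ratio, > 0.
#'
#' @return An object of class `physchem_profile`.
#' @export
#' @examples
#' physchem_profile(6044.4, "polyanion", logp = -2, fup = 0.02)
physchem_profile <- function(molecular_weight,
                             ionization_class = c("neutral",
                                                  "monoprotic_acid",
                                                  "monoprotic_base",
                                                  "zwitterion",
                                                  "polyanion"),
                             pka = numeric(),
                             logp = 0,
                             fup = 1,
                             blood_plasma_ratio = 1) {
  ionization_class <- match.arg(ionization_class)
  if (!is.finite(molecular_weight) || molecular_weight <= 0) {
    stop("molecular_weight must be > 0", call. = FALSE)
  }
  if (!is.finite(fup) || fup <= 0 || fup > 1) {
    stop("fup must be in (0, 1]", call. = FALSE)
  }
  if (!is.finite(blood_plasma_ratio) || blood_plasma_ratio <= 0) {
    stop("blood_plasma_ratio must be > 0", call. = FALSE)
  }
  need <- switch(ionization_class,
                 neutral = 0, monoprotic_acid = 1, monoprotic_base = 1,
                 zwitterion = 2, polyanion = 0)
  if (length(pka) < need) {
    stop("ionization class '", ionization_class, "' requires ", need,
         " pKa value(s), got ", length(pka), call. = FALSE)
  }
  structure(list(
    molecular_weight = molecular_weight,
    ionization_class = ionization_class,
    pka = pka,
    logp = logp,
    fup = fup,
    blood_plasma_ratio = blood_plasma_ratio
  ), class = "physchem_profile")
}

#' @export
print.physchem_profile <- function(x, ...) {
  cat(sprintf(
    "<physchem_profile> MW %.1f Da, %s, logP %.2f, fup %.3g, B:P %.2f\n",
    x$molecular_weight, x$ionization_class, x$logp, x$fup,
    x$blood_plasma_ratio))
  if (length(x$pka)) cat("  pKa:", paste(signif(x$pka, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Load the bundled tissue-composition table
#'
#' Fractional tissue water, neutral lipid and neutral phospholipid,
#' acidic-phospholipid concentration, binding-protein tissue:plasma ratio
#' and intracellular pH for each perfused compartment. These are the
#' rat-derived reference values conventionally applied across species in
#' tissue-composition Kp models.
#'
#' @param path Optional path to a user CSV with the same columns
#'   (`tissue, f_ew, f_iw, f_nl, f_np, ap_mg_g, protein_ratio, ph_iw`).
#' @return A data.frame, one row per tissue.
#' @export
load_tissue_composition <- function(path = NULL) {
  path <- path %||% .extdata("tissue_composition.csv")
  tab <- read.csv(path, comment.char = "#")
  req <- c("tissue", "f_ew", "f_iw", "f_nl", "f_np", "ap_mg_g",
           "protein_ratio", "ph_iw")
  missing <- setdiff(req, names(tab))
  if (length(missing)) {
    stop("tissue composition table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- with(tab, f_ew < 0 | f_ew > 1 | f_iw < 0 | f_iw > 1 |
                f_nl < 0 | f_nl > 1 | f_np < 0 | f_np > 1 |
                (f_ew + f_iw + f_nl + f_np) > 1)
  if (any(bad)) {
    stop("invalid tissue composition for: ",
         paste(tab$tissue[bad], collapse = ", "), call. = FALSE)
  }
  tab
}

# ionized:neutral concentration ratios at a given pH
.ionization_ratio <- function(drug, ph) {
  switch(drug$ionization_class,
    neutral = 0,
    monoprotic_acid = 10^(ph - drug$pka[1]),
    monoprotic_base = 10^(drug$pka[1] - ph),
    zwitterion = 10^(ph - drug$pka[1]) + 10^(drug$pka[2] - ph),
    # the fully ionized limit of the acid branch: an effective pKa far
    # below physiological pH (default 0) keeps the neutral fraction
    # numerically nil while preserving the pH-partitioning of the ion
    polyanion = 10^(ph - (if (length(drug$pka)) drug$pka[1] else 0))
  )
}

.one_tissue_row <- function(tissue) {
  if (is.data.frame(tissue)) {
    if (nrow(tissue) != 1) {
      stop("expected a single tissue-composition row", call. = FALSE)
    }
    as.list(tissue)
  } else {
    as.list(tissue)
  }
}

#' Rodgers-Single tissue:plasma partition coefficient
#'
#' Tissue-composition prediction of Kp for acids, neutrals, weak bases and
#' permanently ionized anions: partitioning into extracellular and
#' intracellular water (pH-corrected by the Henderson-Hasselbalch ionized
#' ratios), into neutral lipid and neutral phospholipid (via the neutral
#' species), plus binding-protein association inferred from the plasma
#' fraction unbound. Moderate-to-strong monoprotic bases (pKa >= 7) are
#' handled by the companion electrostatic acidic-phospholipid form; use
#' [kp_lukacova()] for class-based dispatch.
#'
#' @param drug A [physchem_profile()].
#' @param tissue One row of the tissue-composition table (data.frame row or
#'   named list), as from [load_tissue_composition()].
#' @param plasma_ph Plasma pH (default 7.4).
#' @param reference `"total_plasma"` (default) returns Kp =
#'   tissue:total-plasma; `"unbound_plasma"` returns the
#'   binding-corrected coefficient Kpu = Kp / fup, which grows as plasma
#'   binding tightens.
#' @return Kp (dimensionless, >= 0).
#' @export
#' @examples
#' drug <- physchem_profile(6044.4, "polyanion", logp = -2, fup = 0.02)
#' comp <- load_tissue_composition()
#' kp_rodgers_single(drug, comp[comp$tissue == "liver", ])
kp_rodgers_single <- function(drug, tissue, plasma_ph = 7.4,
                              reference = c("total_plasma",
                                            "unbound_plasma")) {
  reference <- match.arg(reference)
  stopifnot(inherits(drug, "physchem_profile"))
  tis <- .one_tissue_row(tissue)

  p <- 10^drug$logp
  x_iw <- .ionization_ratio(drug, tis$ph_iw)     # intracellular
  y_p <- .ionization_ratio(drug, plasma_ph)      # plasma

  lipid_t <- (p * tis$f_nl + (0.3 * p + 0.7) * tis$f_np) / (1 + y_p)
  lipid_p <- (p * .plasma_comp$f_nl + (0.3 * p + 0.7) * .plasma_comp$f_np) /
    (1 + y_p)

  # protein association constant x plasma protein conc, back-calculated
  # from fup; scaled to tissue by the binding-protein tissue:plasma ratio
  ka_pr <- max(0, 1 / drug$fup - 1 - lipid_p)
  prot_t <- tis$protein_ratio * ka_pr

  kpu <- tis$f_ew + (1 + x_iw) / (1 + y_p) * tis$f_iw + lipid_t + prot_t
  max(0, if (reference == "unbound_plasma") kpu else drug$fup * kpu)
}

# Electrostatic acidic-phospholipid form for moderate-to-strong bases; the
# association constant is inferred from red-blood-cell partitioning, itself
# derived from the blood:plasma ratio and hematocrit.
.kp_strong_base <- function(drug, tis, plasma_ph, hematocrit = 0.45) {
  p <- 10^drug$logp
  bc <- .blood_cell_comp
  x_iw <- .ionization_ratio(drug, tis$ph_iw)
  x_bc <- .ionization_ratio(drug, bc$ph)
  y_p <- .ionization_ratio(drug, plasma_ph)

  lipid <- function(f_nl, f_np) (p * f_nl + (0.3 * p + 0.7) * f_np) / (1 + y_p)

  kpu_bc <- (drug$blood_plasma_ratio - (1 - hematocrit)) /
    (hematocrit * drug$fup)
  ka_ap <- max(0, kpu_bc - (1 + x_bc) / (1 + y_p) * bc$f_iw -
                 lipid(bc$f_nl, bc$f_np)) *
    (1 + y_p) / (bc$ap_mg_g * x_bc)

  kpu <- tis$f_ew + (1 + x_iw) / (1 + y_p) * tis$f_iw +
    lipid(tis$f_nl, tis$f_np) +
    ka_ap * tis$ap_mg_g * x_iw / (1 + y_p)
  max(0, drug$fup * kpu)
}

#' Lukacova (class-dispatched Rodgers-Single) partition coefficient
#'
#' Dispatches over the Rodgers-Single equation family by ionization class:
#' moderate-to-strong monoprotic bases (pKa >= 7) use the electrostatic
#' acidic-phospholipid form; acids, neutrals, weak bases, zwitterions
#' without a strong basic group, and permanently ionized polyanions use the
#' protein-binding form of [kp_rodgers_single()] (a polyanion enters it
#' fully ionized at any pH).
#'
#' @inheritParams kp_rodgers_single
#' @param hematocrit Hematocrit used when red-cell partitioning has to be
#'   back-calculated for the strong-base branch.
#' @return Kp (dimensionless, >= 0).
#' @export
kp_lukacova <- function(drug, tissue, plasma_ph = 7.4, hematocrit = 0.45) {
  stopifnot(inherits(drug, "physchem_profile"))
  tis <- .one_tissue_row(tissue)
  strong_base <- (drug$ionization_class == "monoprotic_base" &&
                    drug$pka[1] >= 7) ||
    (drug$ionization_class == "zwitterion" && max(drug$pka) >= 7)
  if (strong_base) {
    .kp_strong_base(drug, tis, plasma_ph, hematocrit)
  } else {
    kp_rodgers_single(drug, tis, plasma_ph)
  }
}

#' Predict Kp for every perfused tissue
#'
#' @param drug A [physchem_profile()].
#' @param composition Tissue-composition table
#'   (default [load_tissue_composition()]).
#' @param method `"lukacova"` (class dispatch, default) or
#'   `"rodgers_single"`.
#' @param plasma_ph Plasma pH.
#' @param overrides Optional named numeric vector/list of Kp values that
#'   replace the predictions for those tissues (e.g. fitted or literature
#'   Kps supplied via configuration).
#' @return Named numeric vector of Kp, one per tissue in `composition`.
#' @export
predict_kps <- function(drug, composition = load_tissue_composition(),
                        method = c("lukacova", "rodgers_single"),
                        plasma_ph = 7.4, overrides = NULL) {
  method <- match.arg(method)
  f <- if (method == "lukacova") kp_lukacova else kp_rodgers_single
  kps <- vapply(seq_len(nrow(composition)), function(i) {
    f(drug, composition[i, ], plasma_ph)
  }, numeric(1))
  names(kps) <- composition$tissue
  if (!is.null(overrides)) {
    ov <- unlist(overrides)
    unknown <- setdiff(names(ov), names(kps))
    if (length(unknown)) {
      stop("Kp override for unknown tissue(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    kps[names(ov)] <- ov
  }
  kps
}

#' Steady-state volume of distribution from partition coefficients
#'
#' `Vss = plasma volume + sum over perfused tissues of Kp_t * V_t`.
#'
#' @param kps Named numeric vector of tissue:plasma Kp values covering every
#'   perfused tissue of `physiology`.
#' @param physiology A [load_physiology()] spec.
#' @return Vss in litres (plasma-referenced).
#' @export
#' @examples
#' phys <- load_physiology("human_chinese_male")
#' kps <- setNames(rep(1, nrow(phys$tissues)), phys$tissues$tissue)
#' vss_from_kps(kps, phys)  # plasma volume + total tissue volume
vss_from_kps <- function(kps, physiology) {
  stopifnot(inherits(physiology, "physiology_spec"))
  t <- physiology$tissues
  missing <- setdiff(t$tissue, names(kps))
  if (length(missing)) {
    stop("missing Kp for tissue(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(unlist(kps[t$tissue])) | unlist(kps[t$tissue]) < 0)) {
    stop("Kp values must be finite and >= 0", call. = FALSE)
  }
  physiology$plasma_volume + sum(unlist(kps[t$tissue]) * t$volume_L)
}
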