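#' Run the full analysis pipeline
#'
#' Orchestrates the whole chain on one configuration: generates the
#' synthetic animal study (or reads a profiles CSV), runs per-subject
#' noncompartmental analysis and the dose-group summary, fits the
#' power-model dose-proportionality analysis, simulates the PBPK model at
#' every study dose, translates the animal clearance to a human prediction
#' (allometric scaling, BSA-based first-in-human dose) and simulates the
#' predicted human profile. Deterministic given the configuration and
#' seed.
#'
#' @param config A config list or YAML path (see [read_config()],
#'   [default_config()]).
#' @param output_dir Optional directory; when given, the NCA table and
#'   summary, the dose-proportionality table, the PBPK prediction table,
#'   the translation summary and a run log are written there as CSV/text.
#' @param profiles Optional profiles data.frame replacing the synthetic
#'   study.
#' @return A list of class `pipeline_result` with elements `profiles`,
#'   `nca`, `nca_summary`, `doseprop`, `pbpk_predictions`, `translation`,
#'   `config`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(default_config())
#' res$doseprop
#' }
run_pipeline <- function(config = default_config(), output_dir = NULL,
                         profiles = NULL) {
  cfg <- read_config(config)
  output_dir <- output_dir %||% cfg$output_dir

  phys <- load_physiology(cfg$species, overrides = cfg$physiology_overrides)
  drug <- physchem_profile(
    molecular_weight = cfg$drug$molecular_weight,
    ionization_class = cfg$drug$ionization_class,
    pka = cfg$drug$pka %||% numeric(),
    logp = cfg$drug$logp, fup = cfg$drug$fup,
    blood_plasma_ratio = cfg$drug$blood_plasma_ratio)
  kps <- predict_kps(drug, method = cfg$kp_method,
                     overrides = cfg$kp_overrides)

  # 1. study data
  if (is.null(profiles)) {
    design <- study_design(cfg$species, cfg$doses_mg_kg, cfg$n_per_dose,
                           cfg$times_h, matrices = c("plasma", "urine",
                                                     "feces"),
                           lloq = cfg$lloq)
    truth <- list(physiology = phys, kps = kps,
                  cl_ml_kg_h = cfg$cl_ml_kg_h,
                  blood_plasma_ratio = cfg$drug$blood_plasma_ratio)
    vm <- variability_model(cfg$variability$cv_cl, cfg$variability$cv_kp,
                            cfg$variability$cv_residual)
    profiles <- generate_plasma_study(design, truth, vm, seed = cfg$seed)
  }

  # 2. NCA
  nca <- nca_table(profiles)
  nca_sum <- summarize_nca(nca)

  # 3. dose proportionality
  dp <- doseprop_table(nca, alpha = cfg$analysis$alpha,
                       bounds = cfg$analysis$rdnm_bounds)

  # 4. PBPK predictions at the study doses (observed-CL-driven model)
  cl_animal <- mean(nca$cl, na.rm = TRUE) / 1000 * phys$body_weight  # L/h
  model <- build_model(phys, kps, cl_animal,
                       blood_plasma_ratio = cfg$drug$blood_plasma_ratio)
  pred <- do.call(rbind, lapply(cfg$doses_mg_kg, function(d) {
    sim <- simulate_until_eliminated(
      model, dosing = list(dose_event(d * phys$body_weight)),
      t_start = max(cfg$times_h) * 4)
    em <- exposure_metrics(sim)
    data.frame(species = cfg$species, dose = d, dose_units = "mg/kg",
               cmax_ug_ml = em$cmax, auc_inf_ug_h_ml = em$auc_inf,
               stringsAsFactors = FALSE)
  }))

  # 5. translation and human prediction
  tr <- cfg$translation
  cl_human <- tr$human_cl_L_h %||%
    allometric_cl(cl_animal, phys$body_weight, tr$human_bw,
                  exponent = tr$exponent)
  fih <- hed_dose(max(cfg$doses_mg_kg), tr$km_animal, tr$km_human,
                  tr$human_bw, tr$safety_factor)
  human_dose <- tr$human_dose_mg %||% fih$reported_mg
  hphys <- load_physiology("human_chinese_male",
                           overrides = list(body_weight_kg = tr$human_bw))
  hmodel <- build_model(hphys, kps, cl_human,
                        blood_plasma_ratio = cfg$drug$blood_plasma_ratio)
  hsim <- simulate_until_eliminated(
    hmodel, dosing = list(dose_event(human_dose)))
  hem <- exposure_metrics(hsim)
  pred <- rbind(pred, data.frame(
    species = "human", dose = human_dose, dose_units = "mg",
    cmax_ug_ml = hem$cmax, auc_inf_ug_h_ml = hem$auc_inf,
    stringsAsFactors = FALSE))

  translation <- data.frame(
    quantity = c("animal_cl_L_h", "human_cl_L_h", "human_vss_L",
                 "hed_mg_kg", "fih_raw_mg", "fih_reported_mg"),
    value = c(cl_animal, cl_human, vss_from_kps(kps, hphys),
              fih$hed_mg_kg, fih$raw_mg, fih$reported_mg),
    stringsAsFactors = FALSE)

  result <- structure(list(
    profiles = profiles, nca = nca, nca_summary = nca_sum, doseprop = dp,
    pbpk_predictions = pred, translation = translation, config = cfg
  ), class = "pipeline_result")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_profiles(profiles, file.path(output_dir, "profiles.csv"))
    write.csv(nca, file.path(output_dir, "nca.csv"), row.names = FALSE)
    write.csv(nca_sum, file.path(output_dir, "nca_summary.csv"),
              row.names = FALSE)
    write.csv(dp, file.path(output_dir, "dose_proportionality.csv"),
              row.names = FALSE)
    write.csv(pred, file.path(output_dir, "pbpk_predictions.csv"),
              row.names = FALSE)
    write.csv(translation, file.path(output_dir, "translation.csv"),
              row.names = FALSE)
    log <- c(
      sprintf("oligopbpk %s | R %s",
              as.character(utils::packageVersion("oligopbpk")),
              paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("seed: %d", cfg$seed),
      sprintf("species: %s; doses (mg/kg): %s; n/dose: %d", cfg$species,
              paste(cfg$doses_mg_kg, collapse = ", "), cfg$n_per_dose),
      sprintf("sampling (h): %s; LLOQ %g ug/ml",
              paste(cfg$times_h, collapse = ", "), cfg$lloq),
      sprintf("truth CL: %g ml/kg/h; Kp method: %s", cfg$cl_ml_kg_h,
              cfg$kp_method),
      sprintf("variability CVs (CL/Kp/residual): %g/%g/%g",
              cfg$variability$cv_cl, cfg$variability$cv_kp,
              cfg$variability$cv_residual),
      sprintf("alpha %g; Rdnm bounds (%g, %g)", cfg$analysis$alpha,
              cfg$analysis$rdnm_bounds[1], cfg$analysis$rdnm_bounds[2]),
      sprintf(paste0("translation: exponent %g, Km %g/%g, human BW %g kg, ",
                     "safety factor %g"),
              tr$exponent, tr$km_animal, tr$km_human, tr$human_bw,
              tr$safety_factor))
    writeLines(log, file.path(output_dir, "run_log.txt"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d profiles, %d NCA rows\n",
              length(unique(x$profiles$subject)), nrow(x$nca)))
  cat("  dose proportionality:\n")
  for (i in seq_len(nrow(x$doseprop))) {
    d <- x$doseprop[i, ]
    cat(sprintf("    %s: slope %.2f (%.2f, %.2f), Rdnm %.2f -> %s\n",
                d$parameter, d$slope, d$slope_ci_low, d$slope_ci_high,
                d$rdnm, d$conclusion))
  }
  cat("  translation:\n")
  for (i in seq_len(nrow(x$translation))) {
    cat(sprintf("    %s = %.4g\n", x$translation$quantity[i],
                x$translation$value[i]))
  }
  invisible(x)
}
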