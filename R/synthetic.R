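# Synthetic-study generator: emulates the monkey IV plasma study (3 doses x
# 3 animals, 10 samples over 0.08-6 h), the rat tissue-distribution study
# (single 25 mg/kg dose, kills at 0.17/0.5/2/6 h, 9 tissues + plasma) and
# ultrafiltration protein-binding measurements, using the PBPK engine as
# the data-generating truth. Lognormal between-subject variability on CL
# and on the Kp scale, proportional lognormal residual error, BLQ flagging
# at the assay LLOQ.

#' Describe a study design
#'
#' @param species Species label.
#' @param doses_mg_kg Dose levels (mg/kg), > 0.
#' @param n_per_dose Subjects per dose level, >= 1.
#' @param times_h Sampling (or kill) times (h), strictly increasing.
#' @param matrices Matrices sampled.
#' @param lloq Assay lower limit of quantification (ug/ml).
#' @return An object of class `study_design`.
#' @export
study_design <- function(species, doses_mg_kg, n_per_dose, times_h,
                         matrices = "plasma", lloq = 0.18) {
  if (any(doses_mg_kg <= 0)) stop("doses must be > 0", call. = FALSE)
  if (any(diff(times_h) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (n_per_dose < 1) stop("need at least one subject per dose", call. = FALSE)
  structure(list(species = species, doses_mg_kg = doses_mg_kg,
                 n_per_dose = n_per_dose, times_h = times_h,
                 matrices = matrices, lloq = lloq),
            class = "study_design")
}

#' Monkey single-dose IV study design
#'
#' Three dose levels (11.5, 23, 46 mg/kg), three animals per level,
#' sampling at 0.08, 0.17, 0.33, 0.5, 0.75, 1, 1.5, 2, 4 and 6 h, plasma
#' plus (BLQ) urine and feces, LLOQ 0.18 ug/ml.
#'
#' @return A [study_design()].
#' @export
monkey_iv_design <- function() {
  study_design("monkey", c(11.5, 23, 46), 3,
               c(0.08, 0.17, 0.33, 0.5, 0.75, 1, 1.5, 2, 4, 6),
               matrices = c("plasma", "urine", "feces"), lloq = 0.18)
}

#' Rat tissue-distribution study design
#'
#' Single 25 mg/kg IV dose, groups killed at 0.17, 0.5, 2 and 6 h, nine
#' tissues plus plasma.
#'
#' @return A [study_design()].
#' @export
rat_tissue_design <- function() {
  study_design("rat", 25, 5, c(0.17, 0.5, 2, 6),
               matrices = c("plasma", "heart", "lung", "kidney", "jejunum",
                            "stomach", "fat", "liver", "spleen", "muscle"),
               lloq = 0.18)
}

#' Between-subject and residual variability model
#'
#' Lognormal between-subject variability on clearance and on the common Kp
#' scale, and proportional lognormal residual error, parameterised by
#' coefficients of variation.
#'
#' @param cv_cl Between-subject CV on CL (default 0.15).
#' @param cv_kp Between-subject CV on the Kp scale (default 0.15).
#' @param cv_residual Proportional residual CV (default 0.10).
#' @return An object of class `variability_model`.
#' @export
variability_model <- function(cv_cl = 0.15, cv_kp = 0.15,
                              cv_residual = 0.10) {
  if (any(c(cv_cl, cv_kp, cv_residual) < 0)) {
    stop("CVs must be >= 0", call. = FALSE)
  }
  structure(list(cv_cl = cv_cl, cv_kp = cv_kp, cv_residual = cv_residual),
            class = "variability_model")
}

# sdlog of a lognormal with the given CV
.sdlog <- function(cv) sqrt(log(1 + cv^2))

# draw exp(N(0, sdlog)) with mean-1 correction on the log scale
.ln_draw <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- .sdlog(cv)
  exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Generate a synthetic plasma PK study
#'
#' One profile per subject: subject-level CL and a common Kp scale are
#' drawn lognormally around the truth model, the whole-body model is
#' simulated per subject, sampled at the design times, and proportional
#' lognormal residual error is applied. Values below the LLOQ are flagged
#' BLQ (concentration set missing). Urine and feces matrices, when
#' designed, are emitted all-BLQ (no prototype drug in excreta). The same
#' seed always reproduces the same dataset.
#'
#' @param design A [study_design()].
#' @param truth List describing the data-generating truth: `physiology`
#'   (a [load_physiology()] spec), `kps` (named Kp vector),
#'   `cl_ml_kg_h` (per-kg clearance, ml/kg/h) and optionally
#'   `blood_plasma_ratio`.
#' @param variability A [variability_model()].
#' @param seed Integer seed (default 20211103).
#' @return A data.frame with columns `subject, species, dose_mg_kg, matrix,
#'   time_h, conc_ug_ml, blq`, with the seed and LLOQ as attributes.
#' @export
generate_plasma_study <- function(design, truth,
                                  variability = variability_model(),
                                  seed = 20211103) {
  stopifnot(inherits(design, "study_design"),
            inherits(variability, "variability_model"))
  phys <- truth$physiology
  stopifnot(inherits(phys, "physiology_spec"))
  rbp <- truth$blood_plasma_ratio %||% 1
  cl_total <- truth$cl_ml_kg_h / 1000 * phys$body_weight   # L/h

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  rows <- list()
  subj_id <- 0
  for (dose in design$doses_mg_kg) {
    for (k in seq_len(design$n_per_dose)) {
      subj_id <- subj_id + 1
      subject <- sprintf("%s%02d", substr(design$species, 1, 1), subj_id)
      cl_i <- cl_total * .ln_draw(1, variability$cv_cl)
      kp_i <- truth$kps * .ln_draw(1, variability$cv_kp)
      model <- build_model(phys, kp_i, cl_i, blood_plasma_ratio = rbp)
      amount <- dose * phys$body_weight                    # mg
      sim <- simulate_pbpk(model, t_end = max(design$times_h),
                           dosing = list(dose_event(amount)))
      conc <- approx(sim$time, sim$conc_plasma,
                     xout = design$times_h)$y
      eps <- .ln_draw(length(conc), variability$cv_residual)
      obs <- conc * eps
      blq <- obs < design$lloq
      obs[blq] <- NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject, species = design$species, dose_mg_kg = dose,
        matrix = "plasma", time_h = design$times_h, conc_ug_ml = obs,
        blq = blq, stringsAsFactors = FALSE)
      for (m in intersect(design$matrices, c("urine", "feces"))) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = subject, species = design$species, dose_mg_kg = dose,
          matrix = m, time_h = design$times_h,
          conc_ug_ml = NA_real_, blq = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "lloq") <- design$lloq
  out
}

# Default truth Kps for the rat tissue study. These are configuration
# values chosen to honor the observed tissue AUC rank order
# (kidney > spleen > liver > fat > jejunum > stomach > lung > heart >
# muscle > plasma), not estimates from data; see the methods vignette.
#' @export
#' @rdname generate_tissue_study
rat_tissue_truth_kps <- function() {
  c(kidney = 300, spleen = 200, liver = 140, fat = 40, jejunum = 25,
    stomach = 15, lung = 8, heart = 5, muscle = 3)
}

#' Generate a synthetic rat tissue-distribution study
#'
#' Simulates the whole-body rat model with the supplied truth Kps for the
#' sampled tissues (the gut compartment is split evenly into stomach and
#' jejunum so both designed matrices exist; adipose serves as "fat"),
#' records tissue and plasma concentrations at the kill times, applies the
#' 1 g + 10 ml homogenate dilution (factor 11) and inverts it in the
#' reported concentration, and reports percent of injected dose per gram.
#'
#' @param design A [rat_tissue_design()]-style [study_design()].
#' @param kps Named truth Kp vector covering every designed tissue (see
#'   `rat_tissue_truth_kps()` for the bundled default).
#' @param dose_mg_kg Dose (default the design's single dose).
#' @param cl_ml_kg_h Per-kg clearance of the rat truth model (ml/kg/h).
#' @param noise_cv Proportional lognormal residual CV (default 0).
#' @param seed Integer seed.
#' @return A data.frame with columns `matrix, time_h, conc_ug_ml,
#'   homogenate_conc_ug_ml, id_pct_per_g, dose_mg_kg`.
#' @export
generate_tissue_study <- function(design = rat_tissue_design(),
                                  kps = rat_tissue_truth_kps(),
                                  dose_mg_kg = NULL,
                                  cl_ml_kg_h = 100,
                                  noise_cv = 0,
                                  seed = 20211103) {
  stopifnot(inherits(design, "study_design"))
  dose_mg_kg <- dose_mg_kg %||% design$doses_mg_kg[1]
  tissues <- setdiff(design$matrices, "plasma")
  missing <- setdiff(tissues, names(kps))
  if (length(missing)) {
    stop("missing truth Kp for tissue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  # map designed matrices onto model compartments, splitting gut
  phys <- load_physiology(design$species)
  tab <- phys$tissues
  gut <- tab[tab$tissue == "gut", ]
  tab <- tab[tab$tissue != "gut", ]
  tab <- rbind(tab,
               data.frame(tissue = "stomach", volume_L = gut$volume_L / 2,
                          flow_L_per_h = gut$flow_L_per_h / 2),
               data.frame(tissue = "jejunum", volume_L = gut$volume_L / 2,
                          flow_L_per_h = gut$flow_L_per_h / 2))
  tab$tissue[tab$tissue == "adipose"] <- "fat"
  phys$tissues <- tab

  model_kps <- setNames(rep(1, nrow(tab)), tab$tissue)
  model_kps[names(kps)] <- kps
  cl <- cl_ml_kg_h / 1000 * phys$body_weight

  # bypass the 14-compartment name validation: same topology, renamed rows
  model <- structure(list(physiology = phys, kps = model_kps,
                          clearance = cl, blood_plasma_ratio = 1,
                          dosing = list()), class = "pbpk_model")
  amount <- dose_mg_kg * phys$body_weight
  sim <- simulate_pbpk(model, t_end = max(design$times_h),
                       dosing = list(dose_event(amount)))

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  dose_ug <- amount * 1000
  rows <- list()
  for (tm in design$times_h) {
    i <- which.min(abs(sim$time - tm))
    for (m in design$matrices) {
      conc <- if (m == "plasma") sim$conc_plasma[i]
              else sim$conc_tissue[i, m]                  # ug per ml ~ ug/g
      conc <- conc * .ln_draw(1, noise_cv)
      homog <- conc / 11                                  # 1 g + 10 ml
      rows[[length(rows) + 1]] <- data.frame(
        matrix = m, time_h = tm,
        conc_ug_ml = homog * 11,                          # dilution inverted
        homogenate_conc_ug_ml = homog,
        id_pct_per_g = if (m == "plasma") NA_real_
                       else 1000 * conc / dose_ug * 100,  # ug/g over ug x100
        dose_mg_kg = dose_mg_kg, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Rank matrices by AUC over the sampled interval
#'
#' Linear trapezoidal AUC of each matrix over its sampled times, sorted
#' smallest to largest — the ordering used to summarise tissue
#' distribution.
#'
#' @param data A [generate_tissue_study()] data.frame (or any data.frame
#'   with `matrix`, `time_h`, `conc_ug_ml`).
#' @return A data.frame with `matrix` and `auc`, ascending.
#' @export
tissue_auc_ranking <- function(data) {
  aucs <- vapply(split(data, data$matrix), function(d) {
    d <- d[order(d$time_h), ]
    sum(diff(d$time_h) * (d$conc_ug_ml[-1] + d$conc_ug_ml[-nrow(d)]) / 2)
  }, numeric(1))
  out <- data.frame(matrix = names(aucs), auc = unname(aucs),
                    stringsAsFactors = FALSE)
  out <- out[order(out$auc), ]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic ultrafiltration binding study
#'
#' Buffer/plasma chamber concentration pairs consistent with a per-matrix
#' true fraction unbound plus multiplicative lognormal noise on the buffer
#' chamber.
#'
#' @param fu_truth Named vector of true fractions unbound (0, 1], one per
#'   matrix.
#' @param nominal_concs Nominal spiked concentrations (ug/ml), default the
#'   0.25 / 2.5 / 25 QC levels.
#' @param n_rep Replicates per matrix x concentration (default 3).
#' @param noise_cv Multiplicative noise CV on the buffer chamber.
#' @param seed Integer seed.
#' @return A data.frame with columns `matrix, nominal_conc, replicate,
#'   c_buffer, c_plasma`.
#' @export
generate_binding_study <- function(fu_truth = c(human_plasma = 0.02,
                                                human_albumin = 0.08,
                                                rat_plasma = 0.035,
                                                monkey_plasma = 0.045),
                                   nominal_concs = c(0.25, 2.5, 25),
                                   n_rep = 3, noise_cv = 0.05,
                                   seed = 20211103) {
  if (any(fu_truth <= 0 | fu_truth > 1)) {
    stop("fu_truth values must be in (0, 1]", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  rows <- list()
  for (m in names(fu_truth)) {
    for (conc in nominal_concs) {
      for (r in seq_len(n_rep)) {
        c_plasma <- conc
        c_buffer <- fu_truth[[m]] * c_plasma * .ln_draw(1, noise_cv)
        rows[[length(rows) + 1]] <- data.frame(
          matrix = m, nominal_conc = conc, replicate = r,
          c_buffer = c_buffer, c_plasma = c_plasma,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}
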