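# Noncompartmental analysis of individual concentration-time profiles.
#
# Conventions (stated because the source software's defaults are not
# portable): AUC by linear-up/log-down trapezoid; terminal slope by best
# adjusted-r2 search over terminal windows of >= 3 points excluding Tmax;
# AUC extrapolation from the last *observed* concentration; IV-bolus C(0)
# back-extrapolated log-linearly from the first two positive points; BLQ
# handling: pre-dose -> 0, embedded -> missing, trailing -> dropped.

#' Construct a concentration-time profile
#'
#' @param subject Subject identifier.
#' @param species Species label.
#' @param dose Administered dose: ug/kg for per-kg dosing (animals), mg for
#'   absolute dosing (human). Units only affect the units of CL and Vss.
#' @param matrix Sampled matrix (`"plasma"`, a tissue name, `"urine"`,
#'   `"feces"`).
#' @param time Sampling times (h), strictly increasing.
#' @param conc Concentrations (ug/ml); `NA` marks a BLQ/missing sample.
#' @param blq Optional logical vector flagging BLQ samples.
#' @param lloq Assay lower limit of quantification (ug/ml), optional.
#' @param route Dosing route (affects C(0) handling), default `"iv_bolus"`.
#' @return An object of class `conc_time_profile`.
#' @export
conc_time_profile <- function(subject, species, dose, matrix = "plasma",
                              time, conc, blq = NULL, lloq = NA_real_,
                              route = "iv_bolus") {
  if (length(time) != length(conc)) {
    stop("time and conc must have equal length", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(conc < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0 or missing", call. = FALSE)
  }
  blq <- blq %||% (is.na(conc) | (!is.na(lloq) & !is.na(conc) & conc < lloq))
  structure(list(subject = subject, species = species, dose = dose,
                 matrix = matrix, time = time, conc = conc,
                 blq = as.logical(blq), lloq = lloq, route = route),
            class = "conc_time_profile")
}

#' @export
print.conc_time_profile <- function(x, ...) {
  cat(sprintf("<conc_time_profile> subject %s (%s, %s), dose %g, %d samples\n",
              x$subject, x$species, x$matrix, x$dose, length(x$time)))
  invisible(x)
}

# Apply the BLQ rules; returns time/conc vectors ready for analysis.
.clean_profile <- function(profile) {
  time <- profile$time
  conc <- profile$conc
  blq <- profile$blq
  conc[blq & time <= 0] <- 0                 # pre-dose BLQ -> 0
  drop_trailing <- rev(cumprod(rev(blq & time > 0))) == 1
  keep <- !drop_trailing                     # trailing BLQ dropped
  time <- time[keep]; conc <- conc[keep]; blq <- blq[keep]
  conc[blq & time > 0] <- NA_real_           # embedded BLQ -> missing
  ok <- !is.na(conc)
  list(time = time[ok], conc = conc[ok])
}

#' Estimate the terminal elimination rate constant
#'
#' Fits log-linear regressions over every candidate terminal window of at
#' least three points after (and excluding) Tmax and keeps the window with
#' the best adjusted r-squared; a longer window wins ties within 1e-4.
#' Windows with a non-negative slope are rejected.
#'
#' @param profile A [conc_time_profile()], or a numeric time vector when
#'   `conc` is given.
#' @param conc Concentrations, if `profile` is a time vector.
#' @return List with `lambda_z` (1/h), `n_points`, `adj_r2`, `intercept`
#'   (log scale) and `points` (indices into the cleaned profile), or a
#'   `lambda_z` of `NA` with `reason` when not estimable.
#' @export
#' @examples
#' t <- c(0.08, 0.17, 0.33, 0.5, 0.75, 1, 1.5, 2, 4, 6)
#' estimate_lambda_z(t, 100 * exp(-0.6931 * t))$lambda_z
estimate_lambda_z <- function(profile, conc = NULL) {
  if (inherits(profile, "conc_time_profile")) {
    cl <- .clean_profile(profile)
    time <- cl$time; cvec <- cl$conc
  } else {
    time <- profile; cvec <- conc
  }
  pos <- cvec > 0
  time <- time[pos]; cvec <- cvec[pos]
  n <- length(time)
  not_estimable <- function(reason) {
    list(lambda_z = NA_real_, n_points = NA_integer_, adj_r2 = NA_real_,
         intercept = NA_real_, points = integer(), reason = reason)
  }
  if (n < 3) return(not_estimable("fewer than 3 positive concentrations"))

  imax <- which.max(cvec)
  cand_start <- seq(imax + 1, n - 2)
  if (imax + 1 > n - 2) {
    return(not_estimable("fewer than 3 positive post-Tmax concentrations"))
  }

  best <- NULL
  for (s in cand_start) {
    idx <- s:n
    fit <- lm(log(cvec[idx]) ~ time[idx])
    slope <- coef(fit)[[2]]
    if (!is.finite(slope) || slope >= 0) next
    # adjusted r2 computed directly (summary.lm warns on noise-free fits)
    y <- log(cvec[idx])
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    m <- length(idx)
    ar2 <- 1 - (1 - r2) * (m - 1) / (m - 2)
    if (is.null(best) || ar2 > best$adj_r2 + 1e-4 ||
        (abs(ar2 - best$adj_r2) <= 1e-4 && length(idx) > best$n_points)) {
      best <- list(lambda_z = -slope, n_points = length(idx), adj_r2 = ar2,
                   intercept = coef(fit)[[1]], points = idx, reason = NULL)
    }
  }
  if (is.null(best)) return(not_estimable("no declining terminal window"))
  best
}

# Linear-up/log-down trapezoid for AUC and AUMC over observed points.
.auc_aumc <- function(time, conc) {
  auc <- 0
  aumc <- 0
  for (i in seq_len(length(time) - 1)) {
    t1 <- time[i]; t2 <- time[i + 1]
    c1 <- conc[i]; c2 <- conc[i + 1]
    dt <- t2 - t1
    if (c2 < c1 && c1 > 0 && c2 > 0) {
      k <- log(c1 / c2) / dt
      auc <- auc + (c1 - c2) / k
      aumc <- aumc + (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
    } else {
      auc <- auc + dt * (c1 + c2) / 2
      aumc <- aumc + dt * (t1 * c1 + t2 * c2) / 2
    }
  }
  list(auc = auc, aumc = aumc)
}

#' Noncompartmental analysis of one profile
#'
#' Computes the standard IV parameter set: Cmax, Tmax, AUC to the last
#' quantifiable sample, AUC and AUMC extrapolated to infinity, terminal
#' rate constant and half-life, MRT, clearance and steady-state volume.
#' `CL = dose / AUCinf`, `Vss = CL * MRT` and `t1/2 = ln 2 / lambda_z`
#' hold exactly by construction. With per-kg dosing (ug/kg) CL is
#' ml/kg/h and Vss ml/kg; with absolute dosing (mg, concentrations ug/ml)
#' CL is L/h and Vss L.
#'
#' @param profile A [conc_time_profile()].
#' @param dose Dose override; defaults to the profile's.
#' @param back_extrapolate For IV bolus profiles, prepend a log-linearly
#'   back-extrapolated C(0) before computing AUC/AUMC (default TRUE).
#' @return An object of class `nca_result` (also a named list).
#' @export
#' @examples
#' t <- c(0.08, 0.17, 0.33, 0.5, 0.75, 1, 1.5, 2, 4, 6)
#' p <- conc_time_profile("m1", "monkey", dose = 1000, time = t,
#'                        conc = 100 * exp(-0.6931 * t))
#' run_nca(p)$cl   # ~ dose * k / C0 = 6.93 ml/kg/h
run_nca <- function(profile, dose = NULL, back_extrapolate = TRUE) {
  stopifnot(inherits(profile, "conc_time_profile"))
  dose <- dose %||% profile$dose
  cl_prof <- .clean_profile(profile)
  time <- cl_prof$time
  conc <- cl_prof$conc
  if (!length(time) || all(conc <= 0)) {
    stop("profile has no positive quantifiable concentrations",
         call. = FALSE)
  }

  imax <- which.max(conc)
  cmax <- conc[imax]
  tmax <- time[imax]

  # IV bolus C(0): log-linear back-extrapolation from the first two
  # positive samples (first value reused when not declining).
  at <- time
  ac <- conc
  if (back_extrapolate && identical(profile$route, "iv_bolus") &&
      time[1] > 0) {
    pos <- which(conc > 0)
    if (length(pos) >= 2 && conc[pos[1]] > conc[pos[2]]) {
      k0 <- log(conc[pos[1]] / conc[pos[2]]) / (time[pos[2]] - time[pos[1]])
      c0 <- conc[pos[1]] * exp(k0 * time[pos[1]])
    } else {
      c0 <- conc[pos[1]]
    }
    at <- c(0, time)
    ac <- c(c0, conc)
  }

  area <- .auc_aumc(at, ac)
  lam <- estimate_lambda_z(time, conc)

  t_last <- at[length(at)]
  c_last <- ac[length(ac)]
  res <- list(
    subject = profile$subject, species = profile$species,
    matrix = profile$matrix, dose = dose,
    cmax = cmax, tmax = tmax,
    auc_last = area$auc,
    auc_inf = NA_real_, aumc_inf = NA_real_,
    lambda_z = lam$lambda_z, lambda_z_points = lam$n_points,
    adj_r2 = lam$adj_r2,
    t_half = NA_real_, mrt = NA_real_, cl = NA_real_, vss = NA_real_
  )
  if (is.finite(lam$lambda_z)) {
    res$auc_inf <- area$auc + c_last / lam$lambda_z
    res$aumc_inf <- area$aumc + t_last * c_last / lam$lambda_z +
      c_last / lam$lambda_z^2
    res$t_half <- log(2) / lam$lambda_z
    res$mrt <- res$aumc_inf / res$auc_inf
    res$cl <- dose / res$auc_inf
    res$vss <- res$cl * res$mrt
  }
  structure(res, class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> subject %s (%s), dose %g\n",
              x$subject, x$matrix, x$dose))
  cat(sprintf("  Cmax %.4g at %g h; AUClast %.4g; AUCinf %.4g ug.h/ml\n",
              x$cmax, x$tmax, x$auc_last, x$auc_inf))
  cat(sprintf(
    "  lambda_z %.4g /h (%s pts, adj r2 %.4f); t1/2 %.3g h; MRT %.3g h\n",
    x$lambda_z, x$lambda_z_points, x$adj_r2, x$t_half, x$mrt))
  cat(sprintf("  CL %.4g; Vss %.4g (per dose units)\n", x$cl, x$vss))
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  data.frame(subject = x$subject, species = x$species, matrix = x$matrix,
             dose = x$dose, cmax = x$cmax, tmax = x$tmax,
             auc_last = x$auc_last, auc_inf = x$auc_inf,
             lambda_z = x$lambda_z, lambda_z_points = x$lambda_z_points,
             adj_r2 = x$adj_r2, t_half = x$t_half, mrt = x$mrt,
             cl = x$cl, vss = x$vss, stringsAsFactors = FALSE)
}

#' NCA of every plasma profile in a dataset
#'
#' @param data A profiles data.frame with the documented columns
#'   (`subject, species, dose_mg_kg, matrix, time_h, conc_ug_ml`, optional
#'   `blq`), as produced by [generate_plasma_study()] or [read_profiles()].
#' @param matrix Which matrix to analyse (default `"plasma"`).
#' @param dose_scale Multiplier converting the dataset's dose column to the
#'   dose units used for CL (default 1000: mg/kg -> ug/kg, so CL is
#'   ml/kg/h).
#' @param ... Passed to [run_nca()].
#' @return A data.frame with one row per subject.
#' @export
nca_table <- function(data, matrix = "plasma", dose_scale = 1000, ...) {
  data <- data[data$matrix == matrix, ]
  if (!nrow(data)) stop("no rows for matrix '", matrix, "'", call. = FALSE)
  out <- lapply(split(data, data$subject), function(d) {
    d <- d[order(d$time_h), ]
    p <- conc_time_profile(
      subject = d$subject[1], species = d$species[1],
      dose = d$dose_mg_kg[1] * dose_scale, matrix = matrix,
      time = d$time_h, conc = d$conc_ug_ml,
      blq = if ("blq" %in% names(d)) d$blq else NULL)
    cbind(as.data.frame(run_nca(p, ...)), dose_mg_kg = d$dose_mg_kg[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$dose_mg_kg, res$subject), ]
}

#' Group summary of an NCA table
#'
#' Mean and SD of each parameter by dose group, in the layout of a standard
#' preclinical PK summary table.
#'
#' @param tab Output of [nca_table()].
#' @param params Parameters to summarise.
#' @return A data.frame: one row per parameter, `mean (sd)` per dose.
#' @export
summarize_nca <- function(tab, params = c("auc_inf", "cmax", "mrt", "cl",
                                          "vss", "t_half")) {
  doses <- sort(unique(tab$dose_mg_kg))
  rows <- lapply(params, function(p) {
    cells <- vapply(doses, function(d) {
      x <- tab[[p]][tab$dose_mg_kg == d]
      sprintf("%.2f ± %.2f", mean(x, na.rm = TRUE),
              sd(x, na.rm = TRUE))
    }, character(1))
    c(parameter = p, setNames(cells, paste0("dose_", doses, "_mg_kg")))
  })
  as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
}
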