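# Equilibrium binding models and fitters for fluorescent-probe titrations
# (protein titrated into a fixed probe concentration) and for competitive
# back-titrations, plus the coupled-assay rate conversion.

#' Bound probe fraction under ligand depletion
#'
#' Exact single-site solution of the binding quadratic for a probe at
#' concentration `L` titrated with protein `P`: the probe is NOT assumed to
#' be negligible relative to KD, so bound fraction is
#' `fb = ((P + L + KD) - sqrt((P + L + KD)^2 - 4 P L)) / (2 L)`.
#' Reduces to the simple hyperbola `P / (KD + P)` as `L -> 0`.
#'
#' @param P Total titrant (protein) concentration, μM (vectorised).
#' @param L Total probe concentration, μM.
#' @param KD Dissociation constant, μM.
#' @return Bound fraction in `[0, 1)`.
#' @export
bound_fraction_depletion <- function(P, L, KD) {
  s <- P + L + KD
  (s - sqrt(s^2 - 4 * P * L)) / (2 * L)
}

single_site_signal <- function(P, KD, f_min, f_max, L) {
  f_min + (f_max - f_min) * bound_fraction_depletion(P, L, KD)
}

hill_signal <- function(P, K_half, n, f_min, f_max) {
  f_min + (f_max - f_min) * P^n / (K_half^n + P^n)
}

#' Bound probe concentration in a competitive equilibrium
#'
#' Solves the coupled mass balances for a probe (total `L`, dissociation
#' constant `kd_probe`) and a competitor (total `C`, dissociation constant
#' `kd_comp`) both binding the same site of a protein (total `P`). The free
#' protein concentration is found numerically per point (bisection via
#' [stats::uniroot()] to 1e-9 μM) and the bound-probe concentration
#' `[PL] = L * p / (kd_probe + p)` is returned.
#'
#' @param C Total competitor concentration, μM (vectorised).
#' @param P Total protein, μM.
#' @param L Total probe, μM.
#' @param kd_probe,kd_comp Dissociation constants, μM.
#' @return Bound probe concentration, μM.
#' @export
bound_probe_competitive <- function(C, P, L, kd_probe, kd_comp) {
  vapply(C, function(ci) {
    bal <- function(p) p + L * p / (kd_probe + p) + ci * p / (kd_comp + p) - P
    p <- uniroot(bal, c(0, P), tol = 1e-9)$root
    L * p / (kd_probe + p)
  }, numeric(1))
}

#' Construct a titration curve
#'
#' @param conc Titrant concentrations, μM; non-negative, strictly increasing.
#' @param signal Observed signal (arbitrary units), same length.
#' @param probe_conc Probe concentration, μM (> 0).
#' @param protein_conc Fixed protein concentration, μM, for back-titrations
#'   (optional).
#' @return A tibble of class `iface_titration` with columns `conc`, `signal`
#'   and attributes `probe_conc`, `protein_conc`.
#' @export
titration_curve <- function(conc, signal, probe_conc, protein_conc = NA_real_) {
  if (length(conc) != length(signal)) {
    abort("conc and signal lengths differ.", class = "iface_input_error")
  }
  if (any(conc < 0) || any(diff(conc) <= 0)) {
    abort("conc must be non-negative and strictly increasing.",
          class = "iface_input_error")
  }
  if (probe_conc <= 0) abort("probe_conc must be > 0.", class = "iface_input_error")
  out <- tibble(conc = as.numeric(conc), signal = as.numeric(signal))
  attr(out, "probe_conc") <- probe_conc
  attr(out, "protein_conc") <- protein_conc
  class(out) <- c("iface_titration", class(out))
  out
}

check_curve <- function(curve, min_points = 6) {
  if (!all(c("conc", "signal") %in% names(curve))) {
    abort("curve needs `conc` and `signal` columns.", class = "iface_input_error")
  }
  if (nrow(curve) < min_points) {
    abort(sprintf("need >= %d titration points (got %d).", min_points, nrow(curve)),
          class = "iface_input_error")
  }
  rho <- suppressWarnings(cor(curve$conc, curve$signal, method = "spearman"))
  if (!is.na(rho) && abs(rho) < 0.5) {
    warn("titration signal is not monotone beyond noise (|spearman rho| < 0.5).",
         class = "iface_data_quality_warning")
  }
  invisible(curve)
}

# deterministic midpoint estimate of the half-saturation concentration
midpoint_conc <- function(curve) {
  y <- curve$signal
  target <- (min(y) + max(y)) / 2
  i <- which.min(abs(y - target))
  max(curve$conc[i], min(curve$conc[curve$conc > 0]))
}

# run nlsLM from several deterministic starts, keep the best-RSS fit
multistart_nls <- function(formula, data, make_start, kd_inits, lower, upper) {
  best <- NULL
  for (k0 in kd_inits) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = make_start(k0),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    abort("nonlinear fit failed from all starting points.",
          class = "iface_fit_error")
  }
  best
}

new_binding_fit <- function(model, fit, rss, curve, extra = list()) {
  sm <- summary(fit$fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  out <- c(list(model = model, estimate = est, std_error = se, rss = rss,
                n = nrow(curve),
                data = as_tibble(curve[, c("conc", "signal")]),
                fitted = as.numeric(fitted(fit$fit))),
           extra)
  class(out) <- "iface_binding_fit"
  out
}

#' @export
print.iface_binding_fit <- function(x, ...) {
  cat(sprintf("<iface_binding_fit> model = %s, n = %d, RSS = %.4g\n",
              x$model, x$n, x$rss))
  for (nm in names(x$estimate)) {
    cat(sprintf("  %-8s %10.4g +/- %.3g\n", nm, x$estimate[nm], x$std_error[nm]))
  }
  invisible(x)
}

#' Fit a single-site (ligand-depletion) binding curve
#'
#' Fits `y = F_min + (F_max - F_min) * fb(P; KD, L)` with the exact
#' ligand-depletion bound fraction (see [bound_fraction_depletion()]); the
#' quadratic model is the default because fluorescent-probe concentrations
#' of ~1 μM are not negligible against KD values in the 10-25 μM range.
#' Nonlinear least squares is started from three deterministic KD
#' initializations (the curve midpoint and x0.1 / x10 of it) and the
#' best-RSS solution is kept; standard errors come from the local curvature
#' of the objective at the optimum.
#'
#' @param curve An [titration_curve()] (or data frame with `conc`, `signal`
#'   and `probe_conc` supplied).
#' @param probe_conc Probe concentration, μM; defaults to the curve
#'   attribute.
#' @return An `iface_binding_fit` with estimates `KD`, `F_min`, `F_max`
#'   (plus [tidy()]/[glance()]/[autoplot()] methods).
#' @export
fit_single_site <- function(curve, probe_conc = NULL) {
  check_curve(curve)
  L <- probe_conc %||% attr(curve, "probe_conc")
  if (is.null(L) || is.na(L)) {
    abort("probe_conc not supplied.", class = "iface_configuration_error")
  }
  mid <- midpoint_conc(curve)
  dat <- as_tibble(curve[, c("conc", "signal")])
  span <- diff(range(dat$signal))
  best <- multistart_nls(
    signal ~ single_site_signal(conc, KD, f_min, f_max, L = L),
    data = dat,
    make_start = function(k0) list(KD = k0, f_min = min(dat$signal),
                                   f_max = max(dat$signal) + 0.05 * span),
    kd_inits = mid * c(1, 0.1, 10),
    lower = c(KD = 1e-6, f_min = -Inf, f_max = -Inf),
    upper = c(KD = Inf, f_min = Inf, f_max = Inf)
  )
  est <- coef(best$fit)
  names(est) <- c("KD", "F_min", "F_max")
  fit <- new_binding_fit("single_site", best, best$rss, dat,
                         extra = list(probe_conc = L, hill_n = 1))
  names(fit$estimate) <- c("KD", "F_min", "F_max")
  names(fit$std_error) <- c("KD", "F_min", "F_max")
  fit
}

#' Fit the Hill equation to a titration curve
#'
#' Fits `y = F_min + (F_max - F_min) * P^n / (K_half^n + P^n)` with the
#' same deterministic multi-start protocol as [fit_single_site()]. The Hill
#' coefficient is constrained to `[0.2, 5]`; an estimate pinned at either
#' bound raises a boundary warning.
#'
#' @inheritParams fit_single_site
#' @return An `iface_binding_fit` with estimates `K_half`, `hill_n`,
#'   `F_min`, `F_max`.
#' @export
fit_hill <- function(curve) {
  check_curve(curve)
  mid <- midpoint_conc(curve)
  dat <- as_tibble(curve[, c("conc", "signal")])
  span <- diff(range(dat$signal))
  best <- multistart_nls(
    signal ~ hill_signal(conc, K_half, n, f_min, f_max),
    data = dat,
    make_start = function(k0) list(K_half = k0, n = 1,
                                   f_min = min(dat$signal),
                                   f_max = max(dat$signal) + 0.05 * span),
    kd_inits = mid * c(1, 0.1, 10),
    lower = c(K_half = 1e-6, n = 0.2, f_min = -Inf, f_max = -Inf),
    upper = c(K_half = Inf, n = 5, f_min = Inf, f_max = Inf)
  )
  est <- coef(best$fit)
  if (est["n"] <= 0.2 + 1e-6 || est["n"] >= 5 - 1e-6) {
    warn("Hill coefficient pinned at its bound [0.2, 5].",
         class = "iface_boundary_warning")
  }
  fit <- new_binding_fit("hill", best, best$rss, dat)
  names(fit$estimate) <- c("K_half", "hill_n", "F_min", "F_max")
  names(fit$std_error) <- c("K_half", "hill_n", "F_min", "F_max")
  fit
}

#' Fit a competitive displacement (back-titration) curve
#'
#' Default model: exact competitive equilibrium. The probe KD is fixed (from
#' a prior single-site fit of the direct titration); the competitor KD is
#' fitted, with the coupled mass balance solved numerically per point (see
#' [bound_probe_competitive()]). EC50 is reported as the competitor
#' concentration at half-maximal reduction of bound probe, obtained by
#' bisection on the fitted model. A descending-logistic fallback
#' (`model = "logistic"`) is available for curves where the equilibrium
#' model is not appropriate.
#'
#' @param curve Back-titration curve: competitor concentration vs signal,
#'   with `probe_conc` and `protein_conc` attributes (or arguments).
#' @param probe_kd Probe dissociation constant, μM (required for the
#'   equilibrium model).
#' @param probe_conc,protein_conc Probe / fixed protein concentrations, μM.
#' @param model `"equilibrium"` (default) or `"logistic"`.
#' @return An `iface_binding_fit`; for the equilibrium model the estimates
#'   are `KD_comp`, `top`, `bottom` with the derived `EC50` stored in the
#'   fit object.
#' @export
fit_displacement <- function(curve, probe_kd = NULL, probe_conc = NULL,
                             protein_conc = NULL,
                             model = c("equilibrium", "logistic")) {
  model <- match.arg(model)
  check_curve(curve)
  L <- probe_conc %||% attr(curve, "probe_conc")
  P <- protein_conc %||% attr(curve, "protein_conc")
  if (is.null(P) || is.na(P)) {
    abort("protein_conc not supplied for a back-titration.",
          class = "iface_configuration_error")
  }
  y <- curve$signal
  rho <- suppressWarnings(cor(curve$conc, y, method = "spearman"))
  if (is.na(rho) || rho >= 0 || diff(range(y)) == 0) {
    abort("back-titration signal is not descending; no displacement to fit.",
          class = "iface_data_quality_error")
  }
  dat <- as_tibble(curve[, c("conc", "signal")])
  mid <- midpoint_conc(curve)
  if (model == "logistic") {
    best <- multistart_nls(
      signal ~ bottom + (top - bottom) / (1 + (conc / ec50)^slope),
      data = dat,
      make_start = function(k0) list(ec50 = k0, slope = 1,
                                     top = max(y), bottom = min(y)),
      kd_inits = mid * c(1, 0.1, 10),
      lower = c(ec50 = 1e-6, slope = 0.2, top = -Inf, bottom = -Inf),
      upper = c(ec50 = Inf, slope = 5, top = Inf, bottom = Inf)
    )
    fit <- new_binding_fit("displacement_logistic", best, best$rss, dat)
    names(fit$estimate) <- c("EC50", "slope", "top", "bottom")
    names(fit$std_error) <- c("EC50", "slope", "top", "bottom")
    fit$EC50 <- unname(fit$estimate["EC50"])
    return(fit)
  }
  if (is.null(probe_kd)) {
    abort("probe_kd is required for the equilibrium displacement model.",
          class = "iface_configuration_error")
  }
  pl0 <- bound_probe_competitive(0, P, L, probe_kd, 1)  # kd_comp irrelevant at C=0
  best <- multistart_nls(
    signal ~ bottom + (top - bottom) *
      bound_probe_competitive(conc, P = P, L = L, kd_probe = probe_kd,
                              kd_comp = kd_comp) / pl0,
    data = dat,
    make_start = function(k0) list(kd_comp = k0, top = max(y), bottom = min(y)),
    kd_inits = mid * c(1, 0.1, 10),
    lower = c(kd_comp = 1e-6, top = -Inf, bottom = -Inf),
    upper = c(kd_comp = Inf, top = Inf, bottom = Inf)
  )
  kd_comp <- coef(best$fit)[["kd_comp"]]
  # EC50: competitor concentration halving the bound probe, by bisection
  target <- pl0 / 2
  g <- function(C) bound_probe_competitive(C, P, L, probe_kd, kd_comp) - target
  hi <- max(dat$conc[dat$conc > 0], 1)
  while (g(hi) > 0) hi <- hi * 10
  ec50 <- uniroot(g, c(1e-9, hi), tol = 1e-9)$root
  fit <- new_binding_fit("displacement_equilibrium", best, best$rss, dat,
                         extra = list(probe_kd = probe_kd, probe_conc = L,
                                      protein_conc = P, EC50 = ec50))
  names(fit$estimate) <- c("KD_comp", "top", "bottom")
  names(fit$std_error) <- c("KD_comp", "top", "bottom")
  fit
}

#' Convert a coupled-assay absorbance trace to a specific activity
#'
#' For an enzyme assay in which product formation is linked stoichiometrically
#' to NADH consumption and followed as absorbance at 340 nm: the slope of the
#' linear window (ordinary least squares) is converted to a molar rate with
#' the NADH extinction coefficient and the cuvette volume, then normalised by
#' enzyme mass.
#'
#' @param trace Data frame with columns `time_min` and `a340`.
#' @param volume_ml Reaction volume, mL.
#' @param enzyme_mg Enzyme mass in the reaction, mg (> 0).
#' @param extinction Molar extinction coefficient at 340 nm
#'   (default 6220 M^-1 cm^-1 for NADH).
#' @param path_cm Optical path length, cm (default 1).
#' @param stoichiometry Product molecules per NADH consumed (default 1).
#' @param window Optional integer indices of the linear window (default: all
#'   points).
#' @return One-row tibble of class `iface_rate`: `slope` (ΔA340/min),
#'   `rate_nmol_min`, `specific_activity` (nmol min^-1 mg^-1).
#' @export
coupled_assay_rate <- function(trace, volume_ml, enzyme_mg,
                               extinction = 6220, path_cm = 1,
                               stoichiometry = 1, window = NULL) {
  if (!all(c("time_min", "a340") %in% names(trace))) {
    abort("trace needs `time_min` and `a340` columns.", class = "iface_input_error")
  }
  if (enzyme_mg <= 0) abort("enzyme_mg must be > 0.", class = "iface_input_error")
  if (!is.null(window)) trace <- trace[window, , drop = FALSE]
  if (nrow(trace) < 5) {
    abort("need >= 5 points in the linear window.", class = "iface_input_error")
  }
  slope <- unname(coef(lm(a340 ~ time_min, data = trace))[2])
  if (slope > 1e-12) {
    warn("positive A340 slope: NADH consumption should decrease absorbance.",
         class = "iface_sign_warning")
  }
  # A/min -> M/min -> mol/min in the cuvette -> nmol/min
  rate <- abs(slope) / (extinction * path_cm) * (volume_ml / 1000) * 1e9 /
    stoichiometry
  out <- tibble(slope = slope, rate_nmol_min = rate,
                specific_activity = rate / enzyme_mg)
  class(out) <- c("iface_rate", class(out))
  out
}
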