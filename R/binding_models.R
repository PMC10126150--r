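#' Fraction bound under the two-site independent binding model
#'
#' For an aptamer with two independent target binding sites, the fraction of
#' constructs in the bound state at target concentration `c` is
#' `fr = (K1*c + K1*K2*c^2) / (1 + K1*c + K1*K2*c^2)`, where `K1` and `K2`
#' act multiplicatively as association constants (units 1/concentration);
#' the corresponding dissociation constants are their reciprocals, `1/K1`
#' and `1/K2`. The curve is 0 at zero concentration, monotone nondecreasing,
#' and saturates at 1.
#'
#' @param conc Target concentration(s), `>= 0`.
#' @param K1,K2 Association constants for the first and second binding
#'   event, `> 0` (1/concentration, in the units of `conc`).
#' @return Fraction bound in `[0, 1]`.
#' @export
fraction_bound_two_site <- function(conc, K1, K2) {
  check_conc(conc)
  stopifnot(K1 > 0, K2 > 0)
  t1 <- K1 * conc
  t2 <- K1 * K2 * conc^2
  (t1 + t2) / (1 + t1 + t2)
}

#' Plate-reader signal under the two-site model
#'
#' Maps fraction bound onto the fluorescence scale:
#' `y = y0 + (Bmax - y0) * fr`, equal to `y0` at zero concentration and
#' approaching `Bmax` at saturation. `Bmax < y0` describes a signal-off
#' switch (fluorescence decreases on binding).
#'
#' @inheritParams fraction_bound_two_site
#' @param Bmax Signal at 100% binding (RFU).
#' @param y0 Signal in the absence of target (RFU).
#' @return Predicted signal (RFU).
#' @export
signal_two_site <- function(conc, K1, K2, Bmax, y0) {
  y0 + (Bmax - y0) * fraction_bound_two_site(conc, K1, K2)
}

#' Fraction bound under the single-site binding model
#'
#' `fr = c / (c + KD_eff)`: the standard one-site isotherm with effective
#' dissociation constant `KD_eff` (concentration at half-saturation).
#'
#' @param conc Target concentration(s), `>= 0`.
#' @param KD_eff Effective dissociation constant, `> 0`, same units as
#'   `conc`.
#' @return Fraction bound in `[0, 1]`.
#' @export
fraction_bound_one_site <- function(conc, KD_eff) {
  check_conc(conc)
  stopifnot(KD_eff > 0)
  conc / (conc + KD_eff)
}

#' Plate-reader signal under the single-site model
#'
#' `y = y0 + (Bmax - y0) * c / (c + KD_eff)`.
#'
#' @inheritParams fraction_bound_one_site
#' @param Bmax Signal at 100% binding (RFU).
#' @param y0 Signal in the absence of target (RFU).
#' @return Predicted signal (RFU).
#' @export
signal_one_site <- function(conc, KD_eff, Bmax, y0) {
  y0 + (Bmax - y0) * fraction_bound_one_site(conc, KD_eff)
}

check_conc <- function(conc) {
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  invisible(conc)
}

#' Titration dataset
#'
#' Replicate fluorescence measurements of a fixed construct concentration
#' across a target titration, as produced by a plate reader.
#'
#' @param concentrations Strictly increasing, non-negative target
#'   concentrations.
#' @param replicates Numeric matrix `n_conc x n_rep` of fluorescence (RFU).
#' @param unit Concentration unit label (recorded, not converted).
#' @param construct_name Construct identifier.
#' @return A `binding_dataset` object.
#' @export
binding_dataset <- function(concentrations, replicates, unit = "uM",
                            construct_name = "") {
  check_conc(concentrations)
  if (is.null(dim(replicates))) replicates <- cbind(replicates)
  replicates <- as.matrix(replicates)
  stopifnot(nrow(replicates) == length(concentrations))
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be strictly increasing", call. = FALSE)
  structure(list(concentrations = as.numeric(concentrations),
                 replicates = replicates, unit = unit,
                 construct_name = construct_name),
            class = "binding_dataset")
}

#' Read a titration table
#'
#' Expects tab- or comma-separated text with a header
#' `concentration  rep1  rep2 ...`.
#'
#' @param path Path to the table.
#' @param unit Concentration unit label.
#' @param construct_name Construct identifier.
#' @return A [binding_dataset()].
#' @export
read_titration <- function(path, unit = "uM", construct_name = "") {
  tab <- utils::read.delim(path, sep = "", check.names = FALSE)
  if (ncol(tab) < 2L) tab <- utils::read.csv(path, check.names = FALSE)
  binding_dataset(tab[[1]], as.matrix(tab[, -1, drop = FALSE]), unit,
                  construct_name)
}

#' Fit a binding isotherm to a titration
#'
#' Least-squares fit of the single-site or two-site independent binding
#' model to a titration, on replicate means by default. Association/
#' dissociation parameters are optimized on the log scale (guaranteeing
#' positivity); the fit is started from the best point of a deterministic
#' logarithmic grid spanning `[min positive conc / 10, max conc * 10]`, with
#' `Bmax` and `y0` profiled linearly at each grid point, so the result is
#' reproducible for a given dataset. Final refinement uses
#' Levenberg-Marquardt least squares.
#'
#' @param data A [binding_dataset()].
#' @param model `"one_site"` or `"two_site"`.
#' @param use_means Fit replicate means (default) or all replicate points.
#' @param grid_size Number of grid points per log-spaced parameter axis.
#' @return A `binding_fit` object: list with `model`, `parameters` (named
#'   vector; `KD_eff`, or `K1`/`K2` with derived `KD1 = 1/K1`,
#'   `KD2 = 1/K2`), `se` (standard errors on the same scale), `Bmax`, `y0`,
#'   `residual_norm`, `fitted`, `fraction_bound` (observed means normalized
#'   to `[0, 1]` via `(y - y0)/(Bmax - y0)`), and flags `degenerate` (no
#'   resolvable signal change) and `kd_outside_range` (fitted KD more than
#'   100x outside the tested concentrations).
#' @export
fit_binding <- function(data, model = c("one_site", "two_site"),
                        use_means = TRUE, grid_size = 15L) {
  stopifnot(inherits(data, "binding_dataset"))
  model <- match.arg(model)
  n_distinct <- length(unique(data$concentrations))
  if (model == "one_site" && n_distinct < 4L)
    stop("one-site fit needs >= 4 distinct concentrations", call. = FALSE)
  if (model == "two_site" && n_distinct < 5L)
    stop("two-site fit needs >= 5 distinct concentrations", call. = FALSE)

  means <- rowMeans(data$replicates)
  if (use_means) {
    conc <- data$concentrations
    y <- means
  } else {
    conc <- rep(data$concentrations, ncol(data$replicates))
    y <- as.vector(data$replicates)
  }

  pos <- data$concentrations[data$concentrations > 0]
  kgrid <- exp(seq(log(min(pos) / 10), log(max(pos) * 10),
                   length.out = grid_size))

  # A flat titration has no identifiable binding parameters: report it as a
  # degenerate fit rather than chasing a singular least-squares problem.
  if (stats::sd(y) <= sqrt(.Machine$double.eps) * max(abs(y), 1)) {
    params <- if (model == "one_site") c(KD_eff = NA_real_)
              else c(K1 = NA_real_, K2 = NA_real_, KD1 = NA_real_,
                     KD2 = NA_real_)
    return(structure(list(model = model,
                          construct_name = data$construct_name,
                          unit = data$unit, parameters = params,
                          se = params, Bmax = mean(y), y0 = mean(y),
                          residual_norm = 0,
                          concentrations = data$concentrations,
                          observed = means,
                          fitted = rep(mean(y), length(data$concentrations)),
                          fraction_bound = rep(NA_real_,
                                               length(data$concentrations)),
                          fraction_bound_fitted =
                            rep(NA_real_, length(data$concentrations)),
                          degenerate = TRUE, kd_outside_range = FALSE),
                     class = "binding_fit"))
  }

  # At fixed binding parameters the model is linear in (y0, Bmax - y0):
  # profile them by simple linear regression on the fraction-bound curve.
  profile_rss <- function(fr) {
    X <- cbind(1, fr)
    coef <- tryCatch(qr.coef(qr(X), y), error = function(e) c(NA, NA))
    if (anyNA(coef)) return(list(rss = Inf, y0 = NA, Bmax = NA))
    r <- y - X %*% coef
    list(rss = sum(r^2), y0 = coef[1], Bmax = coef[1] + coef[2])
  }

  if (model == "one_site") {
    grid <- lapply(kgrid, function(kd)
      c(rss = profile_rss(fraction_bound_one_site(conc, kd))$rss, kd = kd))
    best <- grid[[which.min(vapply(grid, `[[`, numeric(1), "rss"))]]
    prof <- profile_rss(fraction_bound_one_site(conc, best[["kd"]]))
    start <- list(lkd = log(best[["kd"]]), Bmax = prof$Bmax, y0 = prof$y0)
    form1 <- y ~ y0 + (Bmax - y0) * conc / (conc + exp(lkd))
    fit <- with_fit_error(minpack.lm::nlsLM(
      form1, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)))
    fit <- reweight_fit(fit, form1)
    cf <- stats::coef(fit)
    se <- fit_se(fit)
    KD <- exp(cf[["lkd"]])
    params <- c(KD_eff = KD)
    pse <- c(KD_eff = KD * se[["lkd"]])  # delta method from the log scale
    Bmax <- cf[["Bmax"]]; y0 <- cf[["y0"]]
    fr_hat <- fraction_bound_one_site(data$concentrations, KD)
    kd_vals <- KD
  } else {
    kg <- expand.grid(k1 = 1 / kgrid, k2 = 1 / kgrid)
    rss <- mapply(function(k1, k2)
      profile_rss(fraction_bound_two_site(conc, k1, k2))$rss, kg$k1, kg$k2)
    bi <- which.min(rss)
    prof <- profile_rss(fraction_bound_two_site(conc, kg$k1[bi], kg$k2[bi]))
    start <- list(lk1 = log(kg$k1[bi]), lk2 = log(kg$k2[bi]),
                  Bmax = prof$Bmax, y0 = prof$y0)
    form2 <- y ~ y0 + (Bmax - y0) *
      (exp(lk1) * conc + exp(lk1) * exp(lk2) * conc^2) /
      (1 + exp(lk1) * conc + exp(lk1) * exp(lk2) * conc^2)
    fit <- with_fit_error(minpack.lm::nlsLM(
      form2, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)))
    fit <- reweight_fit(fit, form2)
    cf <- stats::coef(fit)
    se <- fit_se(fit)
    K1 <- exp(cf[["lk1"]]); K2 <- exp(cf[["lk2"]])
    params <- c(K1 = K1, K2 = K2, KD1 = 1 / K1, KD2 = 1 / K2)
    pse <- c(K1 = K1 * se[["lk1"]], K2 = K2 * se[["lk2"]],
             KD1 = se[["lk1"]] / K1, KD2 = se[["lk2"]] / K2)
    Bmax <- cf[["Bmax"]]; y0 <- cf[["y0"]]
    fr_hat <- fraction_bound_two_site(data$concentrations, K1, K2)
    kd_vals <- c(1 / K1, 1 / K2)
  }

  resid <- stats::resid(fit)
  resid_norm <- sqrt(sum(resid^2))
  span <- abs(Bmax - y0)
  degenerate <- span < 2 * stats::sd(resid) || span < 1e-8 * max(abs(y), 1)
  rng <- range(pos)
  outside <- any(kd_vals < rng[1] / 100 | kd_vals > rng[2] * 100)
  if (outside)
    warning("fitted KD more than 100x outside the tested concentration range",
            call. = FALSE)

  structure(list(model = model, construct_name = data$construct_name,
                 unit = data$unit, parameters = params, se = pse,
                 Bmax = Bmax, y0 = y0, residual_norm = resid_norm,
                 concentrations = data$concentrations,
                 observed = means, fitted = y0 + (Bmax - y0) * fr_hat,
                 fraction_bound = (means - y0) / (Bmax - y0),
                 fraction_bound_fitted = fr_hat,
                 degenerate = degenerate, kd_outside_range = outside),
            class = "binding_fit")
}

# Fluorescence errors scale with the signal (multiplicative noise), so the
# least-squares fit is reweighted once with inverse-squared fitted values --
# the standard variance model for plate-reader intensities. Falls back to
# the unweighted fit if the reweighted problem fails.
reweight_fit <- function(fit, formula) {
  pars <- names(stats::coef(fit))
  vars <- setdiff(all.vars(formula), pars)
  df <- mget(vars, envir = environment(formula))
  df$.w <- 1 / pmax(abs(stats::fitted(fit)), 1e-12)^2
  tryCatch(
    minpack.lm::nlsLM(formula, data = df, start = as.list(stats::coef(fit)),
                      weights = .w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) fit)
}

with_fit_error <- function(expr) {
  tryCatch(expr, error = function(e)
    stop("binding fit did not converge: ", conditionMessage(e),
         call. = FALSE))
}

fit_se <- function(fit) {
  out <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) NULL)
  if (is.null(out)) {
    out <- rep(NA_real_, length(stats::coef(fit)))
    names(out) <- names(stats::coef(fit))
  }
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("binding_fit (", x$model, ")",
      if (nzchar(x$construct_name)) paste0(" for ", x$construct_name), "\n",
      sep = "")
  p <- format(signif(x$parameters, 4))
  cat(paste0("  ", names(x$parameters), " = ", p, " ",
             ifelse(grepl("^K[12]$", names(x$parameters)),
                    paste0("1/", x$unit), x$unit), collapse = "\n"), "\n")
  cat("  Bmax =", signif(x$Bmax, 4), " y0 =", signif(x$y0, 4),
      " residual norm =", signif(x$residual_norm, 4), "\n")
  if (x$degenerate) cat("  flag: degenerate (no resolvable signal change)\n")
  if (x$kd_outside_range) cat("  flag: KD far outside tested range\n")
  invisible(x)
}

#' Time-course of a switch after target addition
#'
#' @param times Strictly increasing times (seconds).
#' @param signal Fluorescence (RFU), same length.
#' @param spike_time Time at which the target was spiked in (seconds).
#' @return A `time_course` object.
#' @export
time_course <- function(times, signal, spike_time = 0) {
  stopifnot(length(times) == length(signal))
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 spike_time = spike_time), class = "time_course")
}

#' Summarize switch binding kinetics from a time course
#'
#' Fits a mono-exponential relaxation
#' `S(t) = S_inf + (S_0 - S_inf) * exp(-k_obs * (t - spike_time))` to the
#' post-spike samples and reports the observed rate together with
#' `t_eq95 = ln(20) / k_obs`, the time to cover 95% of the signal step
#' (a practical "time to equilibrium"). The mono-exponential form is a
#' deliberate summary model -- it measures time-to-equilibrium, not
#' mechanism.
#'
#' @param tc A [time_course()].
#' @return A list `k_obs` (1/s), `t_eq95` (s), `S0`, `S_inf`, `degenerate`
#'   (TRUE when no resolvable step is present, in which case the rate
#'   estimates are `NA`).
#' @export
summarize_kinetics <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  keep <- tc$times >= tc$spike_time
  if (sum(keep) < 10L)
    stop("need at least 10 post-spike samples", call. = FALSE)
  t <- tc$times[keep] - tc$spike_time
  s <- tc$signal[keep]
  s0 <- s[1]
  sinf <- mean(s[t >= stats::quantile(t, 0.8)])
  step <- sinf - s0
  noise <- stats::sd(diff(s)) / sqrt(2)
  if (!is.finite(step) || abs(step) < 4 * max(noise, 1e-12))
    return(list(k_obs = NA_real_, t_eq95 = NA_real_, S0 = s0, S_inf = sinf,
                degenerate = TRUE))
  # initial rate from the time at which half the step is covered
  half_idx <- which(abs(s - s0) >= abs(step) / 2)[1]
  k0 <- if (is.na(half_idx) || t[half_idx] <= 0) 1 else log(2) / t[half_idx]
  fit <- minpack.lm::nlsLM(
    s ~ Sinf + (S0 - Sinf) * exp(-k * t),
    start = list(Sinf = sinf, S0 = s0, k = k0),
    lower = c(-Inf, -Inf, 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  k <- cf[["k"]]
  list(k_obs = k, t_eq95 = log(20) / k, S0 = cf[["S0"]],
       S_inf = cf[["Sinf"]], degenerate = FALSE)
}
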