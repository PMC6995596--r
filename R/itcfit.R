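# Weighted least-squares fitting of binding models to isotherms.
#
# Kd parameters are optimized on the log scale (they span nM to mM, and
# positivity is then free); enthalpies are linear. A deterministic
# multistart (perturbed starting points, seeded) replaces the manual
# iterate-until-stable loop of interactive fitting software. Residual
# minimization uses Levenberg-Marquardt (minpack.lm).

#' Construct a fit specification
#'
#' Declares the model to fit, initial values, optional box bounds, which
#' parameters are held fixed, and the fitting conventions. Parameter
#' names are `Kd1..Kdk` and `dH1..dHk` for sequential models; `n`, `Kd`,
#' `dH` for one-set.
#'
#' @param model a `binding_model` holding the initial parameter values.
#' @param fixed character vector of parameter names held at their initial
#'   values.
#' @param exclude_first_injection drop the first (priming) injection from
#'   the residuals? Standard ITC practice; default TRUE.
#' @param weights `"unit"` (default) or `"noise"` (1/sd^2 from the
#'   isotherm's noise metadata, when present).
#' @param lower,upper optional named numeric vectors of box bounds on the
#'   natural scale (Kd bounds positive).
#' @param n_starts number of multistart points (first start is
#'   unperturbed).
#' @param seed seed for the deterministic start perturbations.
#' @return an object of class `fit_spec`.
#' @export
fit_spec <- function(model, fixed = character(0),
                     exclude_first_injection = TRUE,
                     weights = c("unit", "noise"),
                     lower = NULL, upper = NULL, n_starts = 8, seed = 1) {
  stopifnot(inherits(model, "binding_model"))
  weights <- match.arg(weights)
  nm <- param_names(model)
  bad <- setdiff(fixed, nm)
  if (length(bad) > 0) stop("unknown fixed parameter(s): ",
                            paste(bad, collapse = ", "))
  if (length(setdiff(nm, fixed)) == 0) {
    stop("at least one parameter must be free")
  }
  init <- param_values(model)
  check_bounds <- function(b, side) {
    if (is.null(b)) return(invisible())
    bad <- setdiff(names(b), nm)
    if (length(bad) > 0) stop("unknown ", side, " bound(s): ",
                              paste(bad, collapse = ", "))
  }
  check_bounds(lower, "lower"); check_bounds(upper, "upper")
  for (p in names(lower)) if (init[p] < lower[p]) {
    stop("initial value of ", p, " below its lower bound")
  }
  for (p in names(upper)) if (init[p] > upper[p]) {
    stop("initial value of ", p, " above its upper bound")
  }
  structure(list(model = model, fixed = fixed,
                 exclude_first_injection = exclude_first_injection,
                 weights = weights, lower = lower, upper = upper,
                 n_starts = n_starts, seed = seed), class = "fit_spec")
}

param_names <- function(model) {
  if (model$kind == "one_set") c("n", "Kd", "dH")
  else {
    k <- length(model$Kd)
    c(paste0("Kd", seq_len(k)), paste0("dH", seq_len(k)))
  }
}

param_values <- function(model) {
  if (model$kind == "one_set") {
    c(n = model$n_sites, Kd = model$Kd, dH = model$dH)
  } else {
    k <- length(model$Kd)
    stats::setNames(c(model$Kd, model$dH), param_names(model))
  }
}

model_with_params <- function(model, values) {
  if (model$kind == "one_set") {
    binding_model("one_set", Kd = values[["Kd"]], dH = values[["dH"]],
                  n_sites = values[["n"]])
  } else {
    k <- length(model$Kd)
    binding_model("sequential",
                  Kd = unname(values[paste0("Kd", seq_len(k))]),
                  dH = unname(values[paste0("dH", seq_len(k))]))
  }
}

# log scale for positive parameters (Kd, n), natural for dH
is_log_param <- function(names) grepl("^Kd|^n$", names)

to_internal <- function(values) {
  lg <- is_log_param(names(values))
  values[lg] <- log(values[lg])
  values
}

from_internal <- function(theta) {
  lg <- is_log_param(names(theta))
  theta[lg] <- exp(theta[lg])
  theta
}

#' Fit a binding model to an isotherm
#'
#' Minimizes the weighted sum of squared differences between observed and
#' model per-injection normalized heats, honoring fixed parameters and
#' bounds, by Levenberg-Marquardt from `n_starts` deterministically
#' perturbed starting points; the best-RSS start wins. Per-step c-values
#' (cell concentration / Kd) are reported, and steps with c > 1000 are
#' flagged: on such steep steps the data bound Kd from above but do not
#' point-identify it under noise.
#'
#' @param iso an `isotherm` (observed heats).
#' @param scheme the `titration_scheme` the data were collected under.
#' @param spec a `fit_spec`.
#' @return an object of class `itc_fit`: `parameters` (data.frame with
#'   `name`, `estimate`, `fixed`), `model` (fitted `binding_model`),
#'   `rss`, `residuals`, `fitted`, `used` (logical per injection),
#'   `converged`, `n_starts_converged`, `c_values`, `kd_bounded_flags`,
#'   `thermo` (decomposition at the scheme temperature).
#' @export
fit_isotherm <- function(iso, scheme, spec) {
  stopifnot(inherits(scheme, "titration_scheme"),
            inherits(spec, "fit_spec"))
  iso <- as.data.frame(iso)
  iso <- iso[order(iso$injection), ]
  q_obs <- iso$q_norm
  n_inj <- length(q_obs)
  used <- rep(TRUE, n_inj)
  if (spec$exclude_first_injection) used[1] <- FALSE
  w <- rep(1, n_inj)
  if (spec$weights == "noise") {
    sd <- attr(iso, "noise_sd")
    if (!is.null(sd) && is.finite(sd) && sd > 0) w <- rep(1 / sd^2, n_inj)
  }
  init <- param_values(spec$model)
  free_names <- setdiff(names(init), spec$fixed)
  n_free <- length(free_names)
  if (sum(used) < n_free + 1) {
    stop("need at least ", n_free + 1, " usable injections")
  }

  predict_q <- function(values) {
    m <- model_with_params(spec$model, values)
    simulate_q_norm(scheme, m)$q_norm
  }

  resid_fn <- function(theta_free) {
    values <- init
    values[free_names] <- from_internal(
      stats::setNames(theta_free, free_names))
    q_hat <- tryCatch(predict_q(values), error = function(e) NULL)
    if (is.null(q_hat)) return(rep(1e6, sum(used)))
    (sqrt(w) * (q_obs - q_hat))[used]
  }

  bounds_internal <- function(b, default) {
    out <- stats::setNames(rep(default, n_free), free_names)
    for (p in intersect(names(b), free_names)) {
      out[p] <- if (is_log_param(p)) log(b[[p]]) else b[[p]]
    }
    out
  }
  lower_i <- bounds_internal(spec$lower, -Inf)
  upper_i <- bounds_internal(spec$upper, Inf)

  theta0 <- to_internal(init)[free_names]
  set.seed(spec$seed)
  starts <- list(theta0)
  if (spec$n_starts > 1) {
    for (s in seq_len(spec$n_starts - 1)) {
      pert <- theta0
      lg <- is_log_param(free_names)
      pert[lg] <- pert[lg] + stats::rnorm(sum(lg), 0, log(3))
      pert[!lg] <- pert[!lg] * (1 + stats::rnorm(sum(!lg), 0, 0.3))
      pert <- pmin(pmax(pert, lower_i), upper_i)
      starts[[s + 1]] <- pert
    }
  }

  best <- NULL
  n_conv <- 0L
  for (th in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = th, lower = lower_i, upper = upper_i,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$info %in% 1:4
    if (ok) n_conv <- n_conv + 1L
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = res$par, rss = rss, info = res$info,
                   message = res$message)
    }
  }
  if (is.null(best) || n_conv == 0L) {
    stop("no start converged; best diagnostics: ",
         if (is.null(best)) "none" else best$message)
  }

  est <- init
  est[free_names] <- from_internal(
    stats::setNames(best$par, free_names))
  fitted_model <- model_with_params(spec$model, est)
  q_fit <- predict_q(est)
  residuals <- q_obs - q_fit
  rss <- sum((sqrt(w) * residuals)[used]^2)

  Kds <- fitted_model$Kd
  c_values <- scheme$cell_conc_M / Kds
  thermo <- thermo_decompose(Kds, fitted_model$dH, scheme$temperature_K)
  structure(list(
    parameters = data.frame(name = names(est), estimate = unname(est),
                            fixed = names(est) %in% spec$fixed,
                            stringsAsFactors = FALSE),
    model = fitted_model, rss = rss, residuals = residuals, fitted = q_fit,
    used = used, converged = TRUE, n_starts_converged = n_conv,
    c_values = c_values, kd_bounded_flags = c_values > 1000,
    thermo = thermo, scheme = scheme, spec = spec
  ), class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("itc_fit:", x$model$kind, "model,", sum(!x$parameters$fixed),
      "free parameters, RSS =", format(x$rss, digits = 4), "\n")
  p <- x$parameters
  p$estimate <- signif(p$estimate, 6)
  print(p, row.names = FALSE)
  cat("thermodynamic decomposition at",
      x$scheme$temperature_K, "K (kJ/mol):\n")
  t <- x$thermo
  t$Kd <- signif(t$Kd, 4)
  t[c("dG", "dH", "mTdS")] <- lapply(t[c("dG", "dH", "mTdS")], round, 2)
  print(t, row.names = FALSE)
  if (any(x$kd_bounded_flags)) {
    cat("note: step(s)", paste(which(x$kd_bounded_flags), collapse = ","),
        "have c > 1000; Kd is bounded, not point-identified, under noise\n")
  }
  invisible(x)
}

#' Bootstrap parameter uncertainty
#'
#' Residual-resampling bootstrap around a successful fit: fitted heats
#' plus resampled (used-injection) residuals are refit, and per-parameter
#' 2.5/97.5 percentile intervals are reported. Seed-reproducible.
#'
#' @param fit an `itc_fit`.
#' @param n_resamples number of bootstrap resamples (>= 20).
#' @param seed RNG seed.
#' @return data.frame with `name`, `lower`, `upper`, `median` per free
#'   parameter.
#' @export
bootstrap_uncertainty <- function(fit, n_resamples = 200, seed = 1) {
  stopifnot(inherits(fit, "itc_fit"))
  if (n_resamples < 20) stop("n_resamples must be >= 20")
  spec <- fit$spec
  # restart each refit from the fitted values, single start
  refit_spec <- fit_spec(fit$model, fixed = spec$fixed,
                         exclude_first_injection =
                           spec$exclude_first_injection,
                         weights = spec$weights, lower = spec$lower,
                         upper = spec$upper, n_starts = 1, seed = spec$seed)
  base <- as.data.frame(fit$scheme$injection_volumes_uL)
  free_names <- fit$parameters$name[!fit$parameters$fixed]
  pool <- fit$residuals[fit$used]
  set.seed(seed)
  draws <- matrix(NA_real_, n_resamples, length(free_names),
                  dimnames = list(NULL, free_names))
  iso0 <- data.frame(injection = seq_along(fit$fitted),
                     volume_uL = fit$scheme$injection_volumes_uL,
                     molar_ratio = NA_real_, q_norm = fit$fitted)
  for (b in seq_len(n_resamples)) {
    iso_b <- iso0
    pick <- sample(length(pool), sum(fit$used), replace = TRUE)
    iso_b$q_norm[fit$used] <- fit$fitted[fit$used] + pool[pick]
    f <- tryCatch(fit_isotherm(iso_b, fit$scheme, refit_spec),
                  error = function(e) NULL)
    if (is.null(f)) next
    est <- stats::setNames(f$parameters$estimate, f$parameters$name)
    draws[b, ] <- est[free_names]
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  data.frame(
    name = free_names,
    lower = apply(draws, 2, stats::quantile, 0.025),
    upper = apply(draws, 2, stats::quantile, 0.975),
    median = apply(draws, 2, stats::median),
    row.names = NULL
  )
}

#' Compare candidate binding models by small-sample AIC
#'
#' Fits each candidate specification to the same data and ranks them by
#' AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1), with n the number of used
#' injections and k the number of free parameters plus one (the noise
#' variance). Ties preserve input order.
#'
#' @param iso an `isotherm`.
#' @param scheme a `titration_scheme`.
#' @param specs list of `fit_spec`s.
#' @return data.frame ranked by ascending AICc with columns `spec`,
#'   `kind`, `k_free`, `rss`, `aicc`, `delta_aicc`.
#' @export
model_compare <- function(iso, scheme, specs) {
  if (length(specs) < 2) stop("need at least two candidate specifications")
  rows <- lapply(seq_along(specs), function(i) {
    f <- fit_isotherm(iso, scheme, specs[[i]])
    n <- sum(f$used)
    k <- sum(!f$parameters$fixed) + 1
    aicc <- n * log(f$rss / n) + 2 * k +
      if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
    data.frame(spec = i, kind = f$model$kind, k_free = k - 1,
               rss = f$rss, aicc = aicc)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aicc, out$spec), ]
  out$delta_aicc <- out$aicc - out$aicc[1]
  rownames(out) <- NULL
  out
}
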