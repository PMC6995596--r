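# Stepwise binding equilibria and isothermal titration calorimetry
# forward models.
#
# The sequential (stepwise) scheme connects ligation states
# M, MA, ..., MA_n by stepwise dissociation constants Kd_i, with the
# binding polynomial Phi(a) = 1 + sum_j beta_j a^j, beta_j = prod_{i<=j}
# 1/Kd_i, as the partition function over ligation states. The one-set
# scheme is the classic n-identical-independent-sites model. All
# concentrations are molar, volumes litres internally, enthalpies kJ/mol.

R_GAS <- 8.314  # J/(mol K)

#' Construct a titration scheme
#'
#' Describes one ITC experiment: macromolecule M in the cell, ligand A in
#' the syringe, and the injection schedule. Defaults reflect a
#' MicroCal-class instrument: a 200 uL cell and a 0.4 uL priming
#' injection followed by 19 x 2 uL injections.
#'
#' @param cell_conc_M cell (macromolecule) concentration, molar.
#' @param syringe_conc_M syringe (ligand/injectant) concentration, molar.
#' @param cell_volume_uL working cell volume, microlitres.
#' @param injection_volumes_uL per-injection volumes, microlitres (>= 2).
#' @param temperature_K experiment temperature, kelvin.
#' @return an object of class `titration_scheme`.
#' @export
titration_scheme <- function(cell_conc_M, syringe_conc_M,
                             cell_volume_uL = 200,
                             injection_volumes_uL = c(0.4, rep(2, 19)),
                             temperature_K = 298.15) {
  stopifnot(cell_conc_M > 0, syringe_conc_M > 0, cell_volume_uL > 0,
            all(injection_volumes_uL > 0),
            length(injection_volumes_uL) >= 2, temperature_K > 0)
  structure(list(cell_conc_M = cell_conc_M, syringe_conc_M = syringe_conc_M,
                 cell_volume_uL = cell_volume_uL,
                 injection_volumes_uL = injection_volumes_uL,
                 temperature_K = temperature_K),
            class = "titration_scheme")
}

#' Construct a binding model
#'
#' Either `"one_set"` (n identical independent sites with one Kd and one
#' per-site dH) or `"sequential"` (1-3 ordered steps, each with its own
#' stepwise Kd and step enthalpy).
#'
#' @param kind `"one_set"` or `"sequential"`.
#' @param Kd dissociation constant(s), molar; one per step for sequential.
#' @param dH enthalpy change(s), kJ/mol; per site (one_set) or per step.
#' @param n_sites number of sites (one_set only).
#' @return an object of class `binding_model`.
#' @export
binding_model <- function(kind = c("sequential", "one_set"), Kd, dH,
                          n_sites = 1) {
  kind <- match.arg(kind)
  if (any(Kd <= 0)) stop("Kd must be > 0")
  if (kind == "one_set") {
    stopifnot(length(Kd) == 1, length(dH) == 1, n_sites > 0)
  } else {
    if (length(Kd) < 1 || length(Kd) > 3) {
      stop("sequential models support 1 to 3 steps")
    }
    stopifnot(length(dH) == length(Kd))
  }
  structure(list(kind = kind, Kd = as.numeric(Kd), dH = as.numeric(dH),
                 n_sites = n_sites), class = "binding_model")
}

n_steps <- function(model) {
  if (model$kind == "one_set") 1L else length(model$Kd)
}

# beta_j = prod_{i<=j} 1/Kd_i (overall association constants)
beta_coefs <- function(model) cumprod(1 / model$Kd)

# Average ligand bound per macromolecule at free ligand a, and its
# derivative d<nu>/da (sequential), or the one-set occupancy.
occupancy <- function(a, M_ignored, model) {
  if (model$kind == "one_set") {
    nu <- model$n_sites * a / (model$Kd + a)
    dnu <- model$n_sites * model$Kd / (model$Kd + a)^2
  } else {
    b <- beta_coefs(model)
    j <- seq_along(b)
    aj1 <- a^(j - 1)             # a^(j-1), scalar a
    aj <- aj1 * a
    phi <- 1 + sum(b * aj)
    num <- sum(j * b * aj)       # sum j beta_j a^j
    dphi <- sum(j * b * aj1)
    dnum <- sum(j^2 * b * aj1)
    nu <- num / phi
    dnu <- (dnum * phi - num * dphi) / phi^2
  }
  list(nu = nu, dnu = dnu)
}

#' Free ligand concentration from mass balance
#'
#' Solves A_total = [A] + M_total * nu([A]) for the free ligand
#' concentration, where nu is the binding-polynomial-weighted average
#' occupancy. The left side is strictly increasing in [A], so the root is
#' unique; it is bracketed on [0, A_total] and polished with Newton steps
#' to a relative tolerance of 1e-12.
#'
#' @param A_total total ligand, molar.
#' @param M_total total macromolecule, molar.
#' @param model a `binding_model`.
#' @return free ligand concentration, molar.
#' @export
free_ligand <- function(A_total, M_total, model) {
  stopifnot(A_total >= 0, M_total >= 0)
  if (A_total == 0) return(0)
  if (M_total == 0) return(A_total)
  f <- function(a) a + M_total * occupancy(a, M_total, model)$nu - A_total
  lo <- 0; hi <- A_total
  for (iter in 1:25) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  a <- (lo + hi) / 2
  # Newton polish (f' >= 1 always, so steps are stable)
  for (iter in 1:12) {
    occ <- occupancy(a, M_total, model)
    fa <- a + M_total * occ$nu - A_total
    a_new <- a - fa / (1 + M_total * occ$dnu)
    if (a_new < 0) a_new <- a / 2
    if (abs(a_new - a) <= 1e-14 * max(a, .Machine$double.xmin)) {
      a <- a_new; break
    }
    a <- a_new
  }
  if (!is.finite(a) || a < 0 || a > A_total * (1 + 1e-9)) {
    stop(sprintf(
      "mass-balance solve failed to converge (A_tot=%g, M_tot=%g, a=%g)",
      A_total, M_total, a))
  }
  a
}

#' Equilibrium species concentrations
#'
#' For the sequential scheme, ligation-state concentrations follow
#' [MA_j] = [M] * prod_{i<=j}([A]/Kd_i), with [M] fixed by conservation
#' of the macromolecule. For one-set, the `bound` entry is the total
#' concentration of occupied sites.
#'
#' @param A_free free ligand concentration, molar.
#' @param M_total total macromolecule, molar.
#' @param model a `binding_model`.
#' @return named numeric vector: `M`, then `MA`, `MA2`, ... (sequential)
#'   or `bound` (one_set).
#' @export
species <- function(A_free, M_total, model) {
  stopifnot(A_free >= 0)
  if (model$kind == "one_set") {
    bound <- M_total * model$n_sites * A_free / (model$Kd + A_free)
    return(c(M = M_total - bound / model$n_sites, bound = bound))
  }
  b <- beta_coefs(model)
  terms <- b * A_free^seq_along(b)
  phi <- 1 + sum(terms)
  M_free <- M_total / phi
  out <- c(M_free, M_free * terms)
  names(out) <- c("M", paste0("MA", c("", if (length(b) > 1) 2:length(b))))
  out
}

# Lean inner loop shared by simulate_isotherm and the fitter: per-injection
# normalized heats and molar ratios, no container construction.
simulate_q_norm <- function(scheme, model, dilution = "displacement",
                            dilution_heat = 0) {
  V0 <- scheme$cell_volume_uL * 1e-6      # L
  vols <- scheme$injection_volumes_uL * 1e-6
  M_tot <- scheme$cell_conc_M
  A_tot <- 0
  H_prev <- V0 * heat_content_per_L(A_tot, M_tot, model)  # kJ
  n <- length(vols)
  q_norm <- numeric(n)
  ratio <- numeric(n)
  for (i in seq_len(n)) {
    d <- if (dilution == "displacement") 1 - vols[i] / V0 else 1
    M_tot <- M_tot * d
    A_tot <- A_tot * d + scheme$syringe_conc_M * vols[i] / V0
    H_i <- V0 * heat_content_per_L(A_tot, M_tot, model)
    q <- H_i - H_prev * d
    mol_injected <- scheme$syringe_conc_M * vols[i]
    q_norm[i] <- q / mol_injected + dilution_heat
    ratio[i] <- A_tot / M_tot
    H_prev <- H_i
  }
  list(q_norm = q_norm, molar_ratio = ratio)
}

# Enthalpy content of the cell (kJ per litre of cell volume): each step i
# contributes dH_i for every complex at ligation level >= i, i.e.
# H/V0 = sum_j (cumsum(dH))_j [MA_j].
heat_content_per_L <- function(A_total, M_total, model) {
  a <- free_ligand(A_total, M_total, model)
  if (model$kind == "one_set") {
    return(model$dH * M_total * model$n_sites * a / (model$Kd + a))
  }
  b <- beta_coefs(model)
  terms <- b * a^seq_along(b)
  M_free <- M_total / (1 + sum(terms))
  sum(cumsum(model$dH) * M_free * terms)
}

#' Simulate a titration isotherm
#'
#' Forward-simulates the per-injection normalized heats for a binding
#' model under a titration scheme. The displacement (perfusion) dilution
#' model is used by default: each injection of volume v displaces an
#' equal volume of cell contents, so prior totals are scaled by
#' (1 - v/V0) while the injectant accumulates. The differential heat of
#' injection i is q_i = H_i - H_{i-1} (1 - v_i/V0), reported per mole of
#' injected ligand (kJ/mol), plus an optional constant dilution-heat
#' offset.
#'
#' @param scheme a `titration_scheme`.
#' @param model a `binding_model`.
#' @param dilution `"displacement"` (default) or `"none"` (totals updated
#'   with no volume displacement; cross-check mode).
#' @param dilution_heat constant per-injection offset added to `q_norm`,
#'   kJ/mol of injectant (emulates the blank-corrected heat of dilution).
#' @return an object of class `isotherm`: data.frame with columns
#'   `injection`, `volume_uL`, `molar_ratio` (cumulative A/M in cell),
#'   `q_norm` (kJ per mol injectant); the scheme, model and provenance in
#'   attributes.
#' @export
simulate_isotherm <- function(scheme, model,
                              dilution = c("displacement", "none"),
                              dilution_heat = 0) {
  stopifnot(inherits(scheme, "titration_scheme"),
            inherits(model, "binding_model"))
  dilution <- match.arg(dilution)
  sim <- simulate_q_norm(scheme, model, dilution, dilution_heat)
  iso <- data.frame(injection = seq_along(sim$q_norm),
                    volume_uL = scheme$injection_volumes_uL,
                    molar_ratio = sim$molar_ratio, q_norm = sim$q_norm)
  structure(iso, class = c("isotherm", "data.frame"),
            scheme = scheme, model = model, noise_sd = 0, seed = NA_integer_)
}

#' Write / read an isotherm as CSV
#'
#' @param iso an `isotherm`.
#' @param path output path.
#' @return `path` (write) or an `isotherm` without scheme metadata (read).
#' @export
write_isotherm <- function(iso, path) {
  utils::write.csv(as.data.frame(iso), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_isotherm
#' @export
read_isotherm <- function(path) {
  d <- utils::read.csv(path)
  need <- c("injection", "volume_uL", "molar_ratio", "q_norm")
  if (!all(need %in% names(d))) {
    stop("isotherm CSV must have columns: ", paste(need, collapse = ", "))
  }
  d <- d[order(d$injection), need]
  rownames(d) <- NULL
  structure(d, class = c("isotherm", "data.frame"))
}

#' Thermodynamic decomposition of a binding step
#'
#' Computes dG = R T ln(Kd / 1 M) (standard state 1 M) and the entropic
#' term -T dS = dG - dH, so that dG = dH + (-T dS) holds identically.
#' A positive -T dS denotes entropically unfavorable binding.
#'
#' @param Kd dissociation constant(s), molar.
#' @param dH enthalpy change(s), kJ/mol.
#' @param temperature_K temperature, kelvin.
#' @return data.frame of class `thermo_steps` with columns `Kd`, `dG`,
#'   `dH`, `mTdS` (all kJ/mol except `Kd`), and `temperature_K`.
#' @export
thermo_decompose <- function(Kd, dH, temperature_K) {
  stopifnot(all(Kd > 0), temperature_K > 0, length(dH) == length(Kd))
  dG <- R_GAS * temperature_K * log(Kd) / 1000  # kJ/mol
  out <- data.frame(Kd = Kd, dG = dG, dH = dH, mTdS = dG - dH,
                    temperature_K = temperature_K)
  class(out) <- c("thermo_steps", "data.frame")
  out
}
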