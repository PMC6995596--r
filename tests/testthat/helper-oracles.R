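# Independent oracles used across the suite. These deliberately
# re-derive quantities by brute force or closed form, separate from the
# package's own code paths.

# Direct Kabsch solve: minimal RMSD between two point sets after optimal
# superposition (rotation minimizing ||A - B R||_F after centering).
kabsch_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  s <- svd(t(Bc) %*% Ac)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((Ac - Bc %*% R)^2)))
}

# Brute-force anchor distances: Cbeta (Calpha for glycine) per residue,
# straight off the atom table.
brute_anchor_distance <- function(model, chain1, res1, chain2, res2) {
  pick <- function(ch, rn) {
    tab <- model$atoms[model$atoms$chain == ch & model$atoms$resno == rn, ]
    row <- if (any(tab$resid == "GLY")) tab[tab$elety == "CA", ]
    else if (any(tab$elety == "CB")) tab[tab$elety == "CB", ]
    else tab[tab$elety == "CA", ]
    as.numeric(row[1, c("x", "y", "z")])
  }
  sqrt(sum((pick(chain1, res1) - pick(chain2, res2))^2))
}

# Brute-force favorable-layer enumeration at identity rotation: every
# whole-pixel placement of the grounded, grid-centered model, scored by
# counting atoms inside the favorable layer; protruding poses dropped.
brute_dock_energies <- function(model, topo, layer_thickness,
                                clash_tolerance = 0.3) {
  xyz <- coords(model) / 10
  xyz[, 3] <- xyz[, 3] - min(xyz[, 3])
  nx <- ncol(topo$heights); ny <- nrow(topo$heights); ps <- topo$pixel_size
  cx <- topo$origin[1] + (nx - 1) / 2 * ps
  cy <- topo$origin[2] + (ny - 1) / 2 * ps
  xyz[, 1] <- xyz[, 1] - mean(xyz[, 1]) + cx
  xyz[, 2] <- xyz[, 2] - mean(xyz[, 2]) + cy
  energies <- c()
  for (dx in -floor((nx - 1) / 2):floor((nx - 1) / 2)) {
    for (dy in -floor((ny - 1) / 2):floor((ny - 1) / 2)) {
      px <- round((xyz[, 1] + dx * ps - topo$origin[1]) / ps) + 1
      py <- round((xyz[, 2] + dy * ps - topo$origin[2]) / ps) + 1
      if (any(px < 1 | px > nx | py < 1 | py > ny)) next
      henv <- topo$heights[cbind(py, px)]
      if (any(xyz[, 3] > henv + clash_tolerance)) next
      nf <- sum(xyz[, 3] >= henv - layer_thickness & xyz[, 3] <= henv)
      energies <- c(energies, -nf)
    }
  }
  sort(energies)
}

# Refining grid scan of the sequential mass balance
# A_tot = a + M_tot * (sum_j j beta_j a^j) / (1 + sum_j beta_j a^j),
# written out independently of the package solver.
grid_scan_free_ligand <- function(A_tot, M_tot, Kd) {
  beta <- cumprod(1 / Kd)
  f <- function(a) {
    aj <- outer(a, seq_along(beta), "^")
    phi <- 1 + as.numeric(aj %*% beta)
    bound <- as.numeric(aj %*% (seq_along(beta) * beta)) / phi
    a + M_tot * bound - A_tot
  }
  lo <- 0; hi <- A_tot
  for (round in 1:6) {
    a <- seq(lo, hi, length.out = 1e4)
    v <- f(a)
    i <- which(v >= 0)[1]
    hi <- a[i]; lo <- a[max(1, i - 1)]
  }
  (lo + hi) / 2
}

# Published stepwise parameters for the two titration experiments and
# the schemes they were collected under; shared by the itcfit tests and
# the acceptance suite.
assembly_truth <- function() {
  binding_model("sequential", Kd = c(1.5e-9, 4.3e-6),
                dH = c(-226.25, -360))
}
assembly_scheme <- function() {
  titration_scheme(cell_conc_M = 2.5e-6, syringe_conc_M = 25e-6,
                   temperature_K = 298.15)
}
calcium_truth <- function() {
  binding_model("sequential", Kd = c(100e-6, 1e-3, 1.94e-6),
                dH = c(4.78, 150.70, -154.42))
}
calcium_scheme <- function() {
  titration_scheme(cell_conc_M = 1.25e-3, syringe_conc_M = 25e-3,
                   temperature_K = 303.15)
}

# A model/spec pair with all initial guesses perturbed tenfold.
perturbed_spec <- function(truth, fixed = character(0), seed = 1,
                           n_starts = 8) {
  init <- binding_model(truth$kind, Kd = truth$Kd * 10, dH = truth$dH * 10,
                        n_sites = truth$n_sites)
  if (length(fixed) > 0) {
    # fixed parameters keep their true values
    vals <- init
    for (p in fixed) {
      i <- as.integer(sub("^Kd|^dH", "", p))
      if (grepl("^Kd", p)) vals$Kd[i] <- truth$Kd[i]
      else vals$dH[i] <- truth$dH[i]
    }
    init <- binding_model(truth$kind, Kd = vals$Kd, dH = vals$dH,
                          n_sites = truth$n_sites)
  }
  fit_spec(init, fixed = fixed, seed = seed, n_starts = n_starts)
}
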