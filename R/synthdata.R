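# Synthetic-data generators: geometric stand-in structures, planted
# cross-link sets, and noise models for topographs and isotherms.
#
# Every generator is a pure function of (parameters, seed): the same call
# yields byte-identical output. The structures are geometric stand-ins,
# not attempts to mimic real FXIII sequence or sushi-domain topology.

#' Generate a toy multi-chain model
#'
#' Self-avoiding poly-alanine chains (minimum inter-atom distance
#' 2.0 Angstrom) with one C-alpha and one C-beta per residue, laid out as
#' ideal alpha-helices or as straight bead strings. Every seventh residue
#' is planted as glycine and carries no C-beta, exercising the
#' glycine fallback of the restraint anchor rule.
#'
#' @param n_chains number of chains (>= 1).
#' @param residues_per_chain residues per chain (>= 1).
#' @param geometry `"helix"` or `"beads"`.
#' @param seed RNG seed for the coordinate jitter.
#' @param jitter uniform jitter half-width, Angstrom.
#' @return an `atomic_model` (chains "A", "B", ...).
#' @export
toy_model <- function(n_chains = 2, residues_per_chain = 20,
                      geometry = c("helix", "beads"), seed = 1,
                      jitter = 0.1) {
  geometry <- match.arg(geometry)
  stopifnot(n_chains >= 1, residues_per_chain >= 1)
  set.seed(seed)
  for (attempt in 1:20) {
    rows <- list()
    for (c_i in seq_len(n_chains)) {
      chain <- LETTERS[c_i]
      offset <- c(0, (c_i - 1) * 14, 0)  # chains laterally separated
      for (r in seq_len(residues_per_chain)) {
        gly <- r %% 7 == 0
        if (geometry == "helix") {
          ang <- r * 100 * pi / 180
          ca <- c(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * r)
          cb <- c(4.8 * cos(ang), 4.8 * sin(ang), 1.5 * r + 0.4)
        } else {
          ca <- c(3.8 * r, 0, 0)
          cb <- c(3.8 * r, 0, 2.5)
        }
        ca <- ca + offset + stats::runif(3, -jitter, jitter)
        rows[[length(rows) + 1L]] <- data.frame(
          chain = chain, resno = r, resid = if (gly) "GLY" else "ALA",
          elety = "CA", x = ca[1], y = ca[2], z = ca[3],
          stringsAsFactors = FALSE)
        if (!gly) {
          cb <- cb + offset + stats::runif(3, -jitter, jitter)
          rows[[length(rows) + 1L]] <- data.frame(
            chain = chain, resno = r, resid = "ALA", elety = "CB",
            x = cb[1], y = cb[2], z = cb[3], stringsAsFactors = FALSE)
        }
      }
    }
    at <- do.call(rbind, rows)
    xyz <- as.matrix(at[, c("x", "y", "z")])
    if (nrow(xyz) < 2 || min(stats::dist(xyz)) >= 2.0) {
      m <- atomic_model(at, title = sprintf("toy_model(%s, seed=%d)",
                                            geometry, seed))
      attr(m, "n_atoms_generated") <- nrow(at)
      return(m)
    }
  }
  stop("could not pack a self-avoiding toy model after 20 attempts")
}

#' Generate a bipartite model: compact core plus filamentous arm
#'
#' Emulates the bi-partite appearance of a globular subunit with an
#' extended filamentous partner adsorbed flat on the substrate: a compact
#' ball of atoms (chain "A") next to a thin low-lying arm (chain "B").
#' The arm's maximum z lies below the core's by construction, so the
#' simulated topograph shows two height regimes.
#'
#' @param core_radius core radius, nm.
#' @param arm_length arm length, nm (must exceed `core_radius`).
#' @param seed RNG seed.
#' @return an `atomic_model` with `core_atoms` / `arm_atoms` counts in
#'   attributes.
#' @export
bipartite_model <- function(core_radius = 2, arm_length = 6, seed = 1) {
  if (!(arm_length > core_radius)) {
    stop("arm_length must exceed core_radius (degenerate arm rejected)")
  }
  set.seed(seed)
  Rc <- core_radius * 10   # nm -> A
  La <- arm_length * 10
  # core: spherical lattice, spacing 3 A
  sp <- 3
  g <- seq(-Rc, Rc, by = sp)
  grid <- expand.grid(x = g, y = g, z = g)
  grid <- grid[grid$x^2 + grid$y^2 + grid$z^2 <= Rc^2, ]
  core <- data.frame(chain = "A", resno = seq_len(nrow(grid)), resid = "GLY",
                     elety = "CA", x = grid$x, y = grid$y,
                     z = grid$z + Rc, stringsAsFactors = FALSE)
  # arm: thin line hugging the substrate, z ~ 4 A (< core top 2*Rc)
  n_arm <- max(2L, floor(La / 3.8))
  ax <- Rc + 3.8 * seq_len(n_arm)
  arm <- data.frame(chain = "B", resno = seq_len(n_arm), resid = "GLY",
                    elety = "CA",
                    x = ax + stats::runif(n_arm, -0.3, 0.3),
                    y = stats::runif(n_arm, -1, 1),
                    z = 4 + stats::runif(n_arm, -0.5, 0.5),
                    stringsAsFactors = FALSE)
  m <- atomic_model(rbind(core, arm),
                    title = sprintf("bipartite_model(seed=%d)", seed))
  attr(m, "core_atoms") <- nrow(core)
  attr(m, "arm_atoms") <- nrow(arm)
  m
}

#' Plant a cross-link set with a controlled satisfaction fraction
#'
#' Samples residue pairs from a model such that exactly
#' `round(n * satisfied_fraction)` pairs have anchor-atom distance inside
#' the given band (default the 3-24 Angstrom DSS window) and the rest lie
#' outside it. Chains double as protein identifiers, so the identity
#' chain assignment reproduces the planted fraction exactly under
#' [evaluate_restraints()]. Ground-truth labels travel in the
#' `"ground_truth"` attribute.
#'
#' @param model an `atomic_model`.
#' @param n number of cross-links.
#' @param satisfied_fraction fraction in `[0, 1]` planted inside the band.
#' @param seed RNG seed.
#' @param band distance band, Angstrom.
#' @param anchor anchor rule, as in [build_restraints()].
#' @return a `crosslink_set` with attribute `ground_truth` (data.frame
#'   `planted_satisfied`, `distance`).
#' @export
sample_crosslinks <- function(model, n = 40, satisfied_fraction = 0.75,
                              seed = 1, band = c(3, 24), anchor = "cb") {
  stopifnot(satisfied_fraction >= 0, satisfied_fraction <= 1, n >= 1)
  anc <- anchor_coords(model, anchor)
  anc <- anc[stats::complete.cases(anc), ]
  if (nrow(anc) < 2) stop("model has too few anchorable residues")
  pairs <- utils::combn(nrow(anc), 2)
  d <- sqrt(colSums((t(anc[pairs[1, ], c("ax", "ay", "az")]) -
                     t(anc[pairs[2, ], c("ax", "ay", "az")]))^2))
  inside <- which(d >= band[1] & d <= band[2])
  outside <- which(d < band[1] | d > band[2])
  n_in <- round(n * satisfied_fraction)
  n_out <- n - n_in
  if (length(inside) < n_in || length(outside) < n_out) {
    stop(sprintf(
      "infeasible demand: need %d in-band / %d out-of-band pairs, have %d / %d",
      n_in, n_out, length(inside), length(outside)))
  }
  set.seed(seed)
  pick <- c(sample(inside, n_in), sample(outside, n_out))
  planted <- c(rep(TRUE, n_in), rep(FALSE, n_out))
  i1 <- pairs[1, pick]; i2 <- pairs[2, pick]
  xls <- crosslink_set(protein_1 = anc$chain[i1], residue_1 = anc$resno[i1],
                       protein_2 = anc$chain[i2], residue_2 = anc$resno[i2])
  attr(xls, "ground_truth") <- data.frame(planted_satisfied = planted,
                                          distance = d[pick])
  attr(xls, "band") <- band
  xls
}

#' Add Gaussian noise to an isotherm
#'
#' Independent zero-mean Gaussian noise on the normalized heats; the
#' noise level and seed are recorded in the metadata attributes.
#'
#' @param iso an `isotherm`.
#' @param sd noise standard deviation, kJ/mol (>= 0).
#' @param seed RNG seed.
#' @return a noisy `isotherm`.
#' @export
noisy_isotherm <- function(iso, sd, seed = 1) {
  stopifnot(sd >= 0)
  if (sd == 0) return(iso)
  set.seed(seed)
  iso$q_norm <- iso$q_norm + stats::rnorm(nrow(iso), 0, sd)
  attr(iso, "noise_sd") <- sd
  attr(iso, "seed") <- seed
  iso
}

#' Add Gaussian noise to a topograph
#'
#' Independent zero-mean Gaussian noise per pixel, clipped at the
#' substrate plane (heights cannot be negative); the number of clipped
#' pixels is recorded in the `"n_clipped"` attribute.
#'
#' @param topo a `topograph`.
#' @param sd noise standard deviation, nm (>= 0).
#' @param seed RNG seed.
#' @return a noisy `topograph`.
#' @export
noisy_topograph <- function(topo, sd, seed = 1) {
  stopifnot(inherits(topo, "topograph"), sd >= 0)
  if (sd == 0) return(topo)
  set.seed(seed)
  h <- topo$heights + matrix(stats::rnorm(length(topo$heights), 0, sd),
                             nrow(topo$heights))
  n_clip <- sum(h < 0)
  h[h < 0] <- 0
  out <- topograph(h, topo$pixel_size, topo$origin)
  attr(out, "noise_sd") <- sd
  attr(out, "seed") <- seed
  attr(out, "n_clipped") <- n_clip
  out
}
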