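# AFM topographs and rigid envelope docking.
#
# Heights are in nm throughout this module; atomic coordinates arrive in
# Angstrom and are converted (1 nm = 10 A) at this boundary. A topograph
# is a height field h(x, y) above the substrate plane z = 0.

#' Construct a topograph
#'
#' @param heights numeric matrix of heights in nm; rows index y, columns
#'   index x. Must be finite, non-negative, at least 2x2.
#' @param pixel_size lateral pixel size in nm.
#' @param origin (x0, y0) of the first pixel center, nm.
#' @return an object of class `topograph`.
#' @export
topograph <- function(heights, pixel_size, origin = c(0, 0)) {
  heights <- as.matrix(heights)
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (nrow(heights) < 2 || ncol(heights) < 2) stop("grid must be >= 2x2")
  if (any(!is.finite(heights))) stop("heights must be finite")
  if (any(heights < 0)) stop("heights must be >= 0 (substrate plane is 0)")
  structure(list(heights = heights, pixel_size = pixel_size,
                 origin = as.numeric(origin)), class = "topograph")
}

#' @export
print.topograph <- function(x, ...) {
  cat(sprintf("topograph: %d x %d pixels, %.3g nm/pixel, max height %.3g nm\n",
              ncol(x$heights), nrow(x$heights), x$pixel_size,
              max(x$heights)))
  invisible(x)
}

#' Whole-field maximum height
#'
#' @param topo a `topograph`.
#' @return maximum height in nm.
#' @export
max_height <- function(topo) {
  stopifnot(inherits(topo, "topograph"))
  max(topo$heights)
}

#' Write / read a topograph as plain text
#'
#' The height grid is stored as a whitespace-delimited matrix with a JSON
#' sidecar (`<path>.json`) carrying pixel size, origin and units.
#'
#' @param topo a `topograph`.
#' @param path matrix file path.
#' @return `path`, invisibly.
#' @export
write_topograph <- function(topo, path) {
  utils::write.table(topo$heights, path, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(pixel_size = topo$pixel_size,
                            origin = topo$origin, units = "nm"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_topograph
#' @export
read_topograph <- function(path) {
  h <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(h) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  topograph(h, meta$pixel_size, meta$origin)
}

# Ground a coordinate matrix (nm): shift z so the lowest sphere bottom
# (atom center minus atom radius) touches the substrate plane.
ground_nm <- function(xyz_nm, atom_radius_nm = 0) {
  xyz_nm[, 3] <- xyz_nm[, 3] - min(xyz_nm[, 3]) + atom_radius_nm
  xyz_nm
}

#' Simulate an AFM topograph from an atomic model
#'
#' Hard-sphere tip dilation: the model is grounded so its lowest atom
#' sphere touches the substrate, and each pixel records the highest point
#' the tip apex can reach, h(x,y) = max over atoms of
#' z_a + sqrt((r_atom + r_tip)^2 - d^2) - r_tip, where d is the lateral
#' distance from the pixel to the atom center and terms with imaginary
#' root contribute nothing. A zero-radius tip reproduces the van der
#' Waals upper envelope of the model itself.
#'
#' @param model an `atomic_model` (coordinates in Angstrom).
#' @param pixel_size lateral pixel size, nm.
#' @param tip_radius tip apex radius, nm (>= 0).
#' @param atom_radius effective atom radius, nm.
#' @param pad grid padding beyond the model footprint, nm.
#' @param grid_dim optional (ny, nx) to force grid dimensions.
#' @return a `topograph`.
#' @export
simulate_topograph <- function(model, pixel_size = 0.5, tip_radius = 1,
                               atom_radius = 0.2, pad = 2, grid_dim = NULL) {
  stopifnot(inherits(model, "atomic_model"))
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (tip_radius < 0) stop("tip_radius must be >= 0")
  xyz <- coords(model) / 10  # A -> nm
  xyz <- ground_nm(xyz, atom_radius)
  if (is.null(grid_dim)) {
    x0 <- min(xyz[, 1]) - pad
    y0 <- min(xyz[, 2]) - pad
    nx <- ceiling((max(xyz[, 1]) + pad - x0) / pixel_size) + 1L
    ny <- ceiling((max(xyz[, 2]) + pad - y0) / pixel_size) + 1L
  } else {
    ny <- grid_dim[1]; nx <- grid_dim[2]
    x0 <- mean(range(xyz[, 1])) - (nx - 1) / 2 * pixel_size
    y0 <- mean(range(xyz[, 2])) - (ny - 1) / 2 * pixel_size
  }
  gx <- x0 + (seq_len(nx) - 1L) * pixel_size
  gy <- y0 + (seq_len(ny) - 1L) * pixel_size
  R <- atom_radius + tip_radius
  h <- matrix(0, ny, nx)
  for (a in seq_len(nrow(xyz))) {
    dx2 <- (gx - xyz[a, 1])^2
    dy2 <- (gy - xyz[a, 2])^2
    near <- which(dx2 <= R^2)
    if (length(near) == 0L) next
    for (j in near) {
      d2 <- dy2 + dx2[j]
      ok <- d2 <= R^2
      if (!any(ok)) next
      contrib <- xyz[a, 3] + sqrt(R^2 - d2[ok]) - tip_radius
      h[ok, j] <- pmax(h[ok, j], pmax(contrib, 0))
    }
  }
  topograph(h, pixel_size, c(x0, y0))
}

# Favorable-layer score of one placement: xyz_nm already grounded and in
# the topograph frame. Returns n_favorable, or NA when any atom protrudes
# above envelope + clash_tolerance (pose invalid), plus protrusion count.
score_placement <- function(xyz_nm, topo, layer_thickness, clash_tolerance,
                            soft_penalty = FALSE) {
  px <- round((xyz_nm[, 1] - topo$origin[1]) / topo$pixel_size) + 1L
  py <- round((xyz_nm[, 2] - topo$origin[2]) / topo$pixel_size) + 1L
  inside <- px >= 1L & px <= ncol(topo$heights) &
    py >= 1L & py <= nrow(topo$heights)
  if (!all(inside)) return(list(n_favorable = NA_integer_, n_protruding = NA_integer_))
  henv <- topo$heights[cbind(py, px)]
  z <- xyz_nm[, 3]
  n_prot <- sum(z > henv + clash_tolerance)
  if (n_prot > 0 && !soft_penalty) {
    return(list(n_favorable = NA_integer_, n_protruding = n_prot))
  }
  n_fav <- sum(z >= henv - layer_thickness & z <= henv)
  if (n_prot > 0) n_fav <- n_fav - n_prot  # soft mode: penalize protrusions
  list(n_favorable = n_fav, n_protruding = n_prot)
}

#' Dock an atomic model into an AFM topograph
#'
#' Exhaustive rigid search over a grid of in-plane rotations and all
#' whole-pixel lateral translations that keep the model on the grid. Each
#' placement is grounded (lowest atom center at z = 0); an atom is in the
#' favorable layer when it lies within `layer_thickness` below the local
#' envelope height, and the pseudo-energy of a pose is minus its
#' favorable-atom count, so the best score is the lowest energy. Atoms
#' protruding above the envelope by more than `clash_tolerance`
#' invalidate the pose (the envelope is a physical upper bound on
#' matter), unless `soft_penalty = TRUE`, in which case they subtract
#' from the score instead.
#'
#' Reported statistics follow the convention for envelope docking: the
#' minimum energy, the mean energy of the top 10 solutions, the mean
#' pairwise C-alpha RMSD of the top 3 solutions (no superposition), and
#' the lateral offset of the best pose's centroid from the grid center.
#'
#' @param model an `atomic_model` (Angstrom).
#' @param topo a `topograph`.
#' @param rotation_step in-plane rotation step, degrees.
#' @param layer_thickness favorable-layer thickness, nm.
#' @param keep maximum number of poses retained.
#' @param clash_tolerance protrusion tolerance, nm.
#' @param soft_penalty penalize protrusions instead of rejecting.
#' @return an object of class `dock_result`: `poses` (data.frame ranked by
#'   ascending energy: `rot_deg`, `dx_px`, `dy_px`, `n_favorable`,
#'   `n_protruding`, `energy`), `min_energy`, `mean_energy_top10`,
#'   `rmsd_top3` (Angstrom), `xy_offset_best` (nm), and the search
#'   parameters. Empty pose table with a `diagnostic` when no placement
#'   is valid.
#' @export
dock <- function(model, topo, rotation_step = 30, layer_thickness = 1,
                 keep = 1e5, clash_tolerance = 0.3, soft_penalty = FALSE) {
  stopifnot(inherits(model, "atomic_model"), inherits(topo, "topograph"))
  xyz0 <- coords(model) / 10
  angles <- seq(0, 360 - rotation_step, by = rotation_step)
  nx <- ncol(topo$heights); ny <- nrow(topo$heights)
  px_sz <- topo$pixel_size
  grid_cx <- topo$origin[1] + (nx - 1) / 2 * px_sz
  grid_cy <- topo$origin[2] + (ny - 1) / 2 * px_sz
  rows <- list()
  for (ai in seq_along(angles)) {
    a <- angles[ai] * pi / 180
    Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    # rotate about the model centroid, then ground
    ctr <- colMeans(xyz0)
    xyz <- sweep(xyz0, 2, ctr) %*% t(Rz)
    xyz[, 3] <- xyz[, 3] - min(xyz[, 3])
    # place model centroid at grid center, then scan whole-pixel offsets
    xyz[, 1] <- xyz[, 1] - mean(xyz[, 1]) + grid_cx
    xyz[, 2] <- xyz[, 2] - mean(xyz[, 2]) + grid_cy
    half_x <- floor((nx - 1) / 2); half_y <- floor((ny - 1) / 2)
    for (dx in -half_x:half_x) {
      for (dy in -half_y:half_y) {
        sh <- xyz
        sh[, 1] <- sh[, 1] + dx * px_sz
        sh[, 2] <- sh[, 2] + dy * px_sz
        sc <- score_placement(sh, topo, layer_thickness, clash_tolerance,
                              soft_penalty)
        if (is.na(sc$n_favorable)) next
        rows[[length(rows) + 1L]] <- c(angles[ai], dx, dy,
                                       sc$n_favorable, sc$n_protruding)
      }
    }
  }
  if (length(rows) == 0L) {
    empty <- data.frame(rot_deg = numeric(0), dx_px = integer(0),
                        dy_px = integer(0), n_favorable = integer(0),
                        n_protruding = integer(0), energy = numeric(0))
    return(structure(list(poses = empty, min_energy = NA_real_,
                          mean_energy_top10 = NA_real_, rmsd_top3 = NA_real_,
                          xy_offset_best = NA_real_,
                          diagnostic = "no valid placement on grid",
                          params = list(rotation_step = rotation_step,
                                        layer_thickness = layer_thickness,
                                        clash_tolerance = clash_tolerance)),
                     class = "dock_result"))
  }
  poses <- as.data.frame(do.call(rbind, rows))
  names(poses) <- c("rot_deg", "dx_px", "dy_px", "n_favorable", "n_protruding")
  poses$energy <- -poses$n_favorable
  # deterministic ranking: energy, then smallest lateral offset (ties go
  # to the most centered placement), then rotation, then offsets
  poses <- poses[order(poses$energy, poses$dx_px^2 + poses$dy_px^2,
                       poses$rot_deg, poses$dx_px, poses$dy_px), ]
  rownames(poses) <- NULL
  if (nrow(poses) > keep) poses <- poses[seq_len(keep), ]

  place_ca <- function(rot_deg, dx, dy) {
    ca <- model$atoms$elety == "CA"
    a <- rot_deg * pi / 180
    Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    ctr <- colMeans(xyz0)
    xyz <- sweep(xyz0, 2, ctr) %*% t(Rz)
    xyz[, 3] <- xyz[, 3] - min(xyz[, 3])
    xyz[, 1] <- xyz[, 1] - mean(xyz[, 1]) + grid_cx + dx * px_sz
    xyz[, 2] <- xyz[, 2] - mean(xyz[, 2]) + grid_cy + dy * px_sz
    if (any(ca)) xyz[ca, , drop = FALSE] else xyz
  }
  top3 <- poses[seq_len(min(3, nrow(poses))), ]
  rmsd_top3 <- if (nrow(top3) < 2) 0 else {
    pl <- lapply(seq_len(nrow(top3)),
                 function(i) place_ca(top3$rot_deg[i], top3$dx_px[i],
                                      top3$dy_px[i]))
    pr <- utils::combn(length(pl), 2)
    mean(apply(pr, 2, function(ij) {
      sqrt(mean(rowSums((pl[[ij[1]]] - pl[[ij[2]]])^2))) * 10  # nm -> A
    }))
  }
  best_xyz <- place_ca(poses$rot_deg[1], poses$dx_px[1], poses$dy_px[1])
  ctr_best <- colMeans(best_xyz)
  xy_offset <- sqrt((ctr_best[1] - grid_cx)^2 + (ctr_best[2] - grid_cy)^2)
  top10 <- poses$energy[seq_len(min(10, nrow(poses)))]
  structure(list(poses = poses, min_energy = poses$energy[1],
                 mean_energy_top10 = mean(top10), rmsd_top3 = rmsd_top3,
                 xy_offset_best = xy_offset, diagnostic = NULL,
                 params = list(rotation_step = rotation_step,
                               layer_thickness = layer_thickness,
                               clash_tolerance = clash_tolerance)),
            class = "dock_result")
}

#' @export
print.dock_result <- function(x, ...) {
  if (nrow(x$poses) == 0L) {
    cat("dock_result: no valid pose (", x$diagnostic, ")\n")
    return(invisible(x))
  }
  cat("dock_result:", nrow(x$poses), "poses\n")
  cat(sprintf("  min energy        : %.1f\n", x$min_energy))
  cat(sprintf("  mean energy top10 : %.2f\n", x$mean_energy_top10))
  cat(sprintf("  RMSD top3         : %.2f A\n", x$rmsd_top3))
  cat(sprintf("  xy offset (best)  : %.2f nm\n", x$xy_offset_best))
  invisible(x)
}
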