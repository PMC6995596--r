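#' Construct an atomic model
#'
#' An atomic model is the package's common container for protein coordinates:
#' an ordered atom table with one row per atom, holding chain identifier,
#' 1-based residue number, 3-letter residue name, atom name and Cartesian
#' coordinates in Angstrom.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @param title optional free-text title.
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, title = "") {
  required <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[required]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resid <- as.character(atoms$resid)
  atoms$elety <- as.character(atoms$elety)
  if (nrow(atoms) == 0L) stop("atomic model must contain at least one atom")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite")
  }
  if (any(atoms$resno < 1L)) stop("residue numbers must be >= 1")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (chain, residue, atom) triple: ", dup)
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat("atomic_model:", if (nzchar(x$title)) x$title else "<untitled>", "\n")
  cat("  atoms:", nrow(x$atoms),
      " chains:", paste(unique(x$atoms$chain), collapse = ","),
      " residues:", length(unique(paste(x$atoms$chain, x$atoms$resno))), "\n")
  invisible(x)
}

#' Coordinate matrix of a model
#'
#' @param model an `atomic_model`.
#' @return n x 3 numeric matrix of Angstrom coordinates.
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "atomic_model"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Construct a rigid transform
#'
#' A proper rotation (determinant +1 orthonormal 3x3 matrix) followed by a
#' translation. Units of the translation are those of the coordinates the
#' transform is applied to (Angstrom for models, nm at the topograph
#' boundary).
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation matrix is not orthonormal")
  }
  if (abs(det(rotation) - 1) > 1e-6) {
    stop("rotation matrix must be a proper rotation (det = +1)")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Rotation about the z axis
#'
#' @param angle_deg rotation angle in degrees (counter-clockwise about +z).
#' @param translation optional translation.
#' @return a `rigid_transform`.
#' @export
rot_z <- function(angle_deg, translation = c(0, 0, 0)) {
  a <- angle_deg * pi / 180
  rigid_transform(matrix(c(cos(a), sin(a), 0,
                           -sin(a), cos(a), 0,
                           0, 0, 1), 3, 3), translation)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is the transform that applies `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Apply a rigid transform to an atomic model
#'
#' @param model an `atomic_model`.
#' @param tf a `rigid_transform` (translation in Angstrom).
#' @return the transformed `atomic_model`.
#' @export
apply_transform <- function(model, tf) {
  stopifnot(inherits(model, "atomic_model"), inherits(tf, "rigid_transform"))
  xyz <- coords(model) %*% t(tf$rotation)
  xyz <- sweep(xyz, 2, tf$translation, "+")
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}
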