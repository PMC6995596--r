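# Structure I/O and FXIII-A domain bookkeeping.
#
# PDB reading and writing delegate to bio3d; this layer enforces the
# package's invariants (no insertion codes, unique atom triples, single
# altloc kept by occupancy) and converts to the atomic_model container.

#' Read an atomic model from a PDB file
#'
#' Parses ATOM/HETATM records (wwPDB v3.3 fixed-width columns, via bio3d).
#' Alternate locations are reduced to one atom per (chain, residue, atom
#' name): the highest-occupancy altloc wins, first on ties. Files with
#' insertion codes are rejected; the intended inputs (e.g. the FXIII-A2
#' zymogen crystal structure) carry none, and silent renumbering would
#' corrupt residue-level restraints.
#'
#' @param path path to a PDB file.
#' @return an `atomic_model`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no ATOM/HETATM records in ", path)
  if (any(!is.na(at$insert) & nzchar(as.character(at$insert)))) {
    stop("insertion codes are not supported: ", path)
  }
  at$chain[is.na(at$chain)] <- " "
  # altloc reduction: highest occupancy, first on tie
  alt <- !is.na(at$alt) & nzchar(as.character(at$alt))
  if (any(alt)) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$chain, at$resno, at$elety)
    ord <- order(key, -occ, seq_len(nrow(at)))
    at <- at[ord, ]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), ]
    at <- at[order(as.integer(rownames(at))), ]
  }
  atomic_model(
    data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
               elety = at$elety, x = at$x, y = at$y, z = at$z,
               stringsAsFactors = FALSE),
    title = basename(path)
  )
}

#' Write an atomic model to a PDB file
#'
#' Coordinates are written to 3 decimals (PDB fixed width), so a
#' read/write round trip preserves them exactly at that precision.
#'
#' @param model an `atomic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  at <- model$atoms
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = ifelse(at$chain == " ", "", at$chain),
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}

#' FXIII-A domain architecture
#'
#' The catalytic FXIII-A subunit comprises the activation peptide followed
#' by four structural domains; the residue ranges below are the standard
#' crystallographic assignment used to annotate cross-link interface maps.
#'
#' @param chains chain identifiers carrying FXIII-A monomers.
#' @return a `domain_map` data.frame with columns `domain`, `chain`,
#'   `start`, `end` (1-based, inclusive).
#' @export
fxiii_a_domains <- function(chains = "A") {
  per <- data.frame(
    domain = c("activation peptide", "beta-sandwich", "catalytic core",
               "beta-barrel-1", "beta-barrel-2"),
    start = c(1L, 38L, 184L, 516L, 628L),
    end = c(37L, 183L, 515L, 627L, 731L),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(chains, function(ch) {
    cbind(per[1], chain = ch, per[2:3])
  }))
  domain_map(out)
}

#' Construct a domain map
#'
#' @param entries data.frame with columns `domain`, `chain`, `start`, `end`.
#' @return a `domain_map`.
#' @export
domain_map <- function(entries) {
  entries <- as.data.frame(entries)[c("domain", "chain", "start", "end")]
  if (any(entries$start > entries$end)) stop("domain start must be <= end")
  for (ch in unique(entries$chain)) {
    e <- entries[entries$chain == ch, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)])) {
      stop("overlapping domain ranges in chain ", ch)
    }
  }
  class(entries) <- c("domain_map", "data.frame")
  entries
}

#' Look up the domain containing a residue
#'
#' @param domains a `domain_map`.
#' @param chain chain identifier.
#' @param resno residue number.
#' @return domain name, or `"unassigned"` when no range covers the residue.
#' @export
domain_lookup <- function(domains, chain, resno) {
  hit <- domains$chain == chain & domains$start <= resno & domains$end >= resno
  if (!any(hit)) return("unassigned")
  domains$domain[which(hit)[1]]
}

#' Renumber chains into one continuous chain
#'
#' Concatenates the named chains into a single chain whose residue numbers
#' run in continuum: residues of chain k are offset by the cumulative
#' maximum residue number of the preceding chains. This is the standard
#' trick for presenting a homodimer to a bi-molecular docking engine as a
#' single molecule.
#'
#' @param model an `atomic_model`.
#' @param chain_order character vector of chain ids, in concatenation order.
#' @param new_chain chain id of the output chain.
#' @return list with `model` (renumbered single-chain `atomic_model`) and
#'   `index_map` (data.frame `chain`, `resno`, `new_resno`; a bijection).
#' @export
renumber_continuum <- function(model, chain_order, new_chain = "A") {
  stopifnot(inherits(model, "atomic_model"))
  have <- unique(model$atoms$chain)
  unknown <- setdiff(chain_order, have)
  if (length(unknown) > 0) {
    stop("chain(s) not present in model: ", paste(unknown, collapse = ", "))
  }
  offset <- 0L
  pieces <- list()
  maps <- list()
  for (ch in chain_order) {
    at <- model$atoms[model$atoms$chain == ch, ]
    res <- sort(unique(at$resno))
    maps[[ch]] <- data.frame(chain = ch, resno = res, new_resno = res + offset,
                             stringsAsFactors = FALSE)
    at$resno <- at$resno + offset
    at$chain <- new_chain
    pieces[[ch]] <- at
    offset <- offset + max(res)
  }
  index_map <- do.call(rbind, maps)
  rownames(index_map) <- NULL
  out <- atomic_model(do.call(rbind, pieces), title = model$title)
  list(model = out, index_map = index_map)
}

# Extract matched C-alpha coordinate matrices from two models.
matched_ca <- function(model_a, model_b) {
  pick <- function(m) {
    ca <- m$atoms[m$atoms$elety == "CA", ]
    ca[order(ca$chain, ca$resno), ]
  }
  a <- pick(model_a)
  b <- pick(model_b)
  if (nrow(a) == 0L) stop("no C-alpha atoms in model")
  if (nrow(a) != nrow(b) ||
      !all(a$chain == b$chain) || !all(a$resno == b$resno)) {
    stop("models do not share the same C-alpha atom set")
  }
  list(a = as.matrix(a[, c("x", "y", "z")]),
       b = as.matrix(b[, c("x", "y", "z")]))
}

#' C-alpha RMSD between two models
#'
#' Root-mean-square deviation over the shared C-alpha set. For docked poses
#' the deviation is taken in the common frame (`superpose = FALSE`, the
#' default); with `superpose = TRUE` the optimal-rotation (Kabsch) minimum
#' is returned instead.
#'
#' @param model_a,model_b `atomic_model`s with identical C-alpha sets.
#' @param superpose superpose before measuring?
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(model_a, model_b, superpose = FALSE) {
  m <- matched_ca(model_a, model_b)
  b <- m$b
  if (superpose) {
    fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(m$a)),
                                              mobile = as.numeric(t(b))))
    b <- matrix(fitted, ncol = 3, byrow = TRUE)
  }
  sqrt(mean(rowSums((m$a - b)^2)))
}
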