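# Cross-link restraints: construction, evaluation, interface summaries,
# and export for external docking engines.
#
# DSS bridges lysine side chains; the residue-level bounds used throughout
# are the conventional 3-24 Angstrom window on the Cbeta-Cbeta distance
# (Calpha for glycine). The anchor rule is configurable to Calpha-Calpha.

#' Load a cross-link table
#'
#' Reads a delimited text table with header columns `protein_1`,
#' `residue_1`, `protein_2`, `residue_2` and optionally `linker` (default
#' `"DSS"`). The `kind` of each link (inter/intra) is derived from the
#' protein identifiers. Malformed rows (non-numeric or < 1 residue
#' indices, missing fields) are dropped and collected into an error
#' summary attached as attribute `"errors"`.
#'
#' @param path path to a comma- or tab-delimited UTF-8 file.
#' @return data.frame of class `crosslink_set` with columns `protein_1`,
#'   `residue_1`, `protein_2`, `residue_2`, `linker`, `kind`.
#' @export
load_crosslinks <- function(path) {
  if (!file.exists(path)) stop("cross-link file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("protein_1", "residue_1", "protein_2", "residue_2")
  if (!all(need %in% names(raw))) {
    stop("cross-link table must name columns: ", paste(need, collapse = ", "))
  }
  if (!"linker" %in% names(raw)) raw$linker <- "DSS"
  raw$linker[is.na(raw$linker) | !nzchar(raw$linker)] <- "DSS"
  r1 <- suppressWarnings(as.integer(raw$residue_1))
  r2 <- suppressWarnings(as.integer(raw$residue_2))
  bad <- is.na(r1) | is.na(r2) | r1 < 1L | r2 < 1L |
    is.na(raw$protein_1) | is.na(raw$protein_2) |
    !nzchar(as.character(raw$protein_1)) | !nzchar(as.character(raw$protein_2))
  errors <- if (any(bad)) {
    data.frame(row = which(bad),
               reason = "missing field or residue index < 1",
               stringsAsFactors = FALSE)
  } else {
    data.frame(row = integer(0), reason = character(0))
  }
  keep <- raw[!bad, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no parseable cross-link rows in ", path)
  out <- crosslink_set(
    protein_1 = as.character(keep$protein_1), residue_1 = r1[!bad],
    protein_2 = as.character(keep$protein_2), residue_2 = r2[!bad],
    linker = as.character(keep$linker)
  )
  attr(out, "errors") <- errors
  out
}

#' Construct a cross-link set
#'
#' @param protein_1,protein_2 protein identifiers.
#' @param residue_1,residue_2 1-based residue indices.
#' @param linker linker name(s), recycled; default DSS.
#' @return data.frame of class `crosslink_set`.
#' @export
crosslink_set <- function(protein_1, residue_1, protein_2, residue_2,
                          linker = "DSS") {
  residue_1 <- as.integer(residue_1)
  residue_2 <- as.integer(residue_2)
  if (any(residue_1 < 1L) || any(residue_2 < 1L)) {
    stop("residue indices must be >= 1")
  }
  out <- data.frame(protein_1 = as.character(protein_1), residue_1 = residue_1,
                    protein_2 = as.character(protein_2), residue_2 = residue_2,
                    linker = rep_len(as.character(linker), length(residue_1)),
                    stringsAsFactors = FALSE)
  out$kind <- ifelse(out$protein_1 == out$protein_2, "intra", "inter")
  class(out) <- c("crosslink_set", "data.frame")
  out
}

#' Write a cross-link set to CSV
#'
#' @param xls a `crosslink_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crosslinks <- function(xls, path) {
  utils::write.csv(as.data.frame(xls)[c("protein_1", "residue_1", "protein_2",
                                        "residue_2", "linker")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand cross-links into distance restraints
#'
#' Each cross-link becomes one restraint per chain-pair expansion of its
#' two proteins, with constant lower/upper distance bounds (default 3 and
#' 24 Angstrom, the DSS window). When a protein maps to several chains
#' (homodimers), the expanded restraints share a parent `group` and are
#' treated as ambiguous: the group is satisfied if ANY member is, the
#' ambiguous-restraint convention of docking engines.
#'
#' @param xls a `crosslink_set`.
#' @param chain_assignment named list mapping each protein id to one or
#'   more chain ids.
#' @param bounds length-2 numeric, lower/upper distance bounds in Angstrom.
#' @param anchor `"cb"` (Cbeta, Calpha for glycine; default) or `"ca"`.
#' @return data.frame of class `restraint_set` with one row per expanded
#'   restraint: `group`, `chain_1`, `resno_1`, `chain_2`, `resno_2`,
#'   `lower`, `upper`.
#' @export
build_restraints <- function(xls, chain_assignment, bounds = c(3, 24),
                             anchor = c("cb", "ca")) {
  anchor <- match.arg(anchor)
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[1] < bounds[2])
  xls <- as.data.frame(xls)
  unmapped <- setdiff(unique(c(xls$protein_1, xls$protein_2)),
                      names(chain_assignment))
  if (length(unmapped) > 0) {
    stop("no chain assignment for protein(s): ",
         paste(unmapped, collapse = ", "))
  }
  rows <- list()
  for (i in seq_len(nrow(xls))) {
    ch1 <- chain_assignment[[xls$protein_1[i]]]
    ch2 <- chain_assignment[[xls$protein_2[i]]]
    grid <- expand.grid(chain_1 = ch1, chain_2 = ch2,
                        stringsAsFactors = FALSE)
    # drop degenerate self-pairings (same chain, same residue)
    self <- grid$chain_1 == grid$chain_2 &
      xls$residue_1[i] == xls$residue_2[i]
    grid <- grid[!self, , drop = FALSE]
    if (nrow(grid) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      group = i, chain_1 = grid$chain_1, resno_1 = xls$residue_1[i],
      chain_2 = grid$chain_2, resno_2 = xls$residue_2[i],
      lower = bounds[1], upper = bounds[2], stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0L) {
    data.frame(group = integer(0), chain_1 = character(0),
               resno_1 = integer(0), chain_2 = character(0),
               resno_2 = integer(0), lower = numeric(0), upper = numeric(0))
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  attr(out, "anchor") <- anchor
  class(out) <- c("restraint_set", "data.frame")
  out
}

# Anchor-atom coordinates per residue: Cbeta, falling back to Calpha for
# glycine (rule "cb"), or Calpha throughout (rule "ca"). NA rows for
# residues that cannot be anchored.
anchor_coords <- function(model, anchor = "cb") {
  at <- model$atoms
  res <- unique(at[, c("chain", "resno")])
  pick_one <- function(tab, name) {
    hit <- tab[tab$elety == name, , drop = FALSE]
    if (nrow(hit) == 0L) NULL else hit[1, c("x", "y", "z")]
  }
  xyz <- matrix(NA_real_, nrow(res), 3)
  for (i in seq_len(nrow(res))) {
    tab <- at[at$chain == res$chain[i] & at$resno == res$resno[i], ,
              drop = FALSE]
    p <- if (anchor == "ca") {
      pick_one(tab, "CA")
    } else if (any(tab$resid == "GLY")) {
      pick_one(tab, "CA")
    } else {
      hit <- pick_one(tab, "CB")
      if (is.null(hit)) pick_one(tab, "CA") else hit
    }
    if (!is.null(p)) xyz[i, ] <- as.numeric(p)
  }
  cbind(res, data.frame(ax = xyz[, 1], ay = xyz[, 2], az = xyz[, 3]))
}

#' Evaluate distance restraints on a model
#'
#' Measures the anchor-atom Euclidean distance for every expanded
#' restraint. A restraint is satisfied when lower <= d <= upper; an
#' ambiguous group is satisfied when any member is. Restraints whose
#' anchor atoms cannot be resolved in the model are flagged unmappable and
#' excluded from the satisfaction fraction.
#'
#' @param model an `atomic_model`.
#' @param restraints a `restraint_set` from [build_restraints()].
#' @return list of class `restraint_report`: `per_restraint` (measured
#'   distance, status per expanded restraint), `per_group` (group status,
#'   best distance), `n_total`, `n_satisfied`, `n_violated`,
#'   `n_unmappable`, `satisfaction_fraction` (NA when no mappable group).
#' @export
evaluate_restraints <- function(model, restraints) {
  stopifnot(inherits(model, "atomic_model"))
  anchor <- attr(restraints, "anchor")
  if (is.null(anchor)) anchor <- "cb"
  anc <- anchor_coords(model, anchor)
  key <- paste(anc$chain, anc$resno)
  look <- function(ch, rn) {
    i <- match(paste(ch, rn), key)
    if (is.na(i)) c(NA_real_, NA_real_, NA_real_)
    else as.numeric(anc[i, c("ax", "ay", "az")])
  }
  n <- nrow(restraints)
  d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p1 <- look(restraints$chain_1[i], restraints$resno_1[i])
    p2 <- look(restraints$chain_2[i], restraints$resno_2[i])
    d[i] <- sqrt(sum((p1 - p2)^2))
  }
  status <- ifelse(is.na(d), "unmappable",
                   ifelse(d >= restraints$lower & d <= restraints$upper,
                          "satisfied", "violated"))
  per <- cbind(as.data.frame(restraints),
               data.frame(distance = d, status = status,
                          excess = pmax(0, d - restraints$upper),
                          stringsAsFactors = FALSE))
  groups <- unique(restraints$group)
  gstat <- character(length(groups))
  gbest <- numeric(length(groups))
  for (j in seq_along(groups)) {
    s <- status[restraints$group == groups[j]]
    dd <- d[restraints$group == groups[j]]
    gstat[j] <- if (all(s == "unmappable")) "unmappable"
    else if (any(s == "satisfied")) "satisfied" else "violated"
    gbest[j] <- if (all(is.na(dd))) NA_real_ else min(dd, na.rm = TRUE)
  }
  n_unmap <- sum(gstat == "unmappable")
  n_sat <- sum(gstat == "satisfied")
  n_vio <- sum(gstat == "violated")
  n_eff <- n_sat + n_vio
  structure(list(
    per_restraint = per,
    per_group = data.frame(group = groups, status = gstat,
                           best_distance = gbest, stringsAsFactors = FALSE),
    n_total = n_eff, n_satisfied = n_sat, n_violated = n_vio,
    n_unmappable = n_unmap,
    satisfaction_fraction = if (n_eff > 0) n_sat / n_eff else NA_real_
  ), class = "restraint_report")
}

#' @export
print.restraint_report <- function(x, ...) {
  cat("restraint_report:", x$n_total, "groups (",
      x$n_satisfied, "satisfied,", x$n_violated, "violated,",
      x$n_unmappable, "unmappable )\n")
  cat("  satisfaction fraction:",
      if (is.na(x$satisfaction_fraction)) "undefined"
      else sprintf("%.3f", x$satisfaction_fraction), "\n")
  invisible(x)
}

#' Domain-pair contact matrix of a cross-link set
#'
#' Counts cross-links by the domain pair they bridge, the domain-wise
#' interface map used to summarize where two subunits touch. Residues not
#' covered by any domain range fall into an `"unassigned"` bucket. Each
#' cross-link increments exactly one cell (domain pair in canonical
#' order), so the matrix total equals the number of cross-links.
#'
#' @param xls a `crosslink_set`.
#' @param domains named list mapping each protein id to a `domain_map`
#'   (the map's `chain` column is ignored here; ranges apply to that
#'   protein's residue numbering).
#' @return integer matrix, rows/columns named `protein:domain`.
#' @export
domain_contact_matrix <- function(xls, domains) {
  xls <- as.data.frame(xls)
  lab <- function(protein, resno) {
    dm <- domains[[protein]]
    d <- if (is.null(dm)) "unassigned" else {
      hit <- dm$start <= resno & dm$end >= resno
      if (any(hit)) dm$domain[which(hit)[1]] else "unassigned"
    }
    paste0(protein, ":", d)
  }
  all_labels <- character(0)
  for (p in names(domains)) {
    all_labels <- c(all_labels, paste0(p, ":", domains[[p]]$domain))
  }
  l1 <- character(nrow(xls))
  l2 <- character(nrow(xls))
  for (i in seq_len(nrow(xls))) {
    l1[i] <- lab(xls$protein_1[i], xls$residue_1[i])
    l2[i] <- lab(xls$protein_2[i], xls$residue_2[i])
  }
  labels <- unique(c(all_labels, l1, l2))
  m <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_along(l1)) {
    # canonical order so intra pairs are accounted once, symmetrically
    a <- min(l1[i], l2[i])
    b <- max(l1[i], l2[i])
    m[a, b] <- m[a, b] + 1L
  }
  m
}

#' Export restraints for an external docking engine
#'
#' Writes either an ambiguous-interaction restraint table in the
#' `assign`-statement text dialect used by HADDOCK-class engines
#' (`haddock_tbl`; the 3-24 Angstrom window renders as distance 3.0 with
#' +21.0 upper correction) or a flat CSV. Output is deterministic:
#' restraints are sorted by chain and residue, so identical input yields
#' byte-identical files.
#'
#' @param restraints a non-empty `restraint_set`.
#' @param path output file path.
#' @param dialect `"haddock_tbl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_restraints <- function(restraints, path,
                              dialect = c("haddock_tbl", "csv")) {
  if (nrow(restraints) == 0L) stop("no restraints to export")
  dialect <- match.arg(dialect)
  anchor <- attr(restraints, "anchor")
  if (is.null(anchor)) anchor <- "cb"
  rs <- as.data.frame(restraints)
  rs <- rs[order(rs$chain_1, rs$resno_1, rs$chain_2, rs$resno_2), ]
  if (dialect == "csv") {
    utils::write.csv(rs, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  sel <- function(ch, rn) {
    name <- if (anchor == "ca") "CA" else "CB"
    sprintf("(segid %s and resid %d and name %s)", ch, rn, name)
  }
  blocks <- character(0)
  for (g in unique(rs$group)) {
    mem <- rs[rs$group == g, , drop = FALSE]
    stmts <- sprintf("assign %s %s %.1f %.1f %.1f",
                     sel(mem$chain_1, mem$resno_1),
                     sel(mem$chain_2, mem$resno_2),
                     mem$lower, 0, mem$upper - mem$lower)
    blocks <- c(blocks, paste(stmts, collapse = "\nor\n"))
  }
  writeLines(c("! ambiguous distance restraints (DSS cross-links)", "",
               paste(blocks, collapse = "\n\n")), path)
  invisible(path)
}
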