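#' Read a protein structure from a PDB file
#'
#' Parses a (possibly multi-model) PDB file into a `protein_structure`
#' object: an ordered residue table plus one Calpha coordinate set per
#' model and, when present, the full heavy-atom records needed for
#' hydrogen-bond analysis. Alternate locations are resolved to the
#' highest-occupancy copy; residues lacking a Calpha are dropped with a
#' warning. HETATM records are ignored unless `include_het = TRUE`.
#'
#' @param path Path to a PDB file.
#' @param model_policy `"first"` keeps only the first MODEL; `"all"`
#'   keeps every model (all models must share the residue list).
#' @param include_het Keep HETATM records as well as ATOM records.
#' @return An object of class `protein_structure` with elements
#'   `residues` (data.frame: `chain`, `resno`, `insert`, `resid`),
#'   `ca` (list of N x 3 coordinate matrices, one per model, in
#'   Angstrom), `atoms` (data.frame of heavy-atom records or `NULL`)
#'   and `axyz` (list of per-model atom coordinate matrices).
#' @export
read_structure <- function(path, model_policy = c("first", "all"),
                           include_het = FALSE) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atom <- pdb$atom
  row0 <- seq_len(nrow(atom))      # xyz columns follow the unfiltered table
  if (!include_het) {
    sel <- atom$type == "ATOM"
    atom <- atom[sel, , drop = FALSE]
    row0 <- row0[sel]
  }
  if (nrow(atom) == 0L) stop("no usable ATOM records in ", path)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  if (model_policy == "first") n_models <- 1L

  keep <- .resolve_altloc(atom)
  orig_row <- row0[keep]
  atom <- atom[keep, , drop = FALSE]
  atom$insert[is.na(atom$insert)] <- ""
  atom$chain[is.na(atom$chain)] <- " "

  rkey <- paste(atom$chain, atom$resno, atom$insert, sep = "|")
  is_ca <- atom$elety == "CA"
  res_order <- unique(rkey)
  ca_rows <- match(res_order, rkey[is_ca])
  missing_ca <- is.na(ca_rows)
  if (any(missing_ca)) {
    warning(sum(missing_ca), " residue(s) without a CA atom dropped: ",
            paste(utils::head(res_order[missing_ca], 5L), collapse = ", "))
    res_order <- res_order[!missing_ca]
    ca_rows <- ca_rows[!missing_ca]
  }
  if (length(res_order) == 0L) stop("no residues with CA atoms in ", path)
  ca_idx <- which(is_ca)[ca_rows]  # row in `atom` of each residue's CA

  residues <- data.frame(
    chain  = atom$chain[ca_idx],
    resno  = atom$resno[ca_idx],
    insert = atom$insert[ca_idx],
    resid  = atom$resid[ca_idx],
    stringsAsFactors = FALSE
  )

  atom_keep <- rkey %in% res_order
  col_idx <- function(rows) as.vector(t(outer(rows, 0:2, function(r, k) 3L * (r - 1L) + 1L + k)))
  ca_cols <- col_idx(orig_row[ca_idx])
  at_cols <- col_idx(orig_row[which(atom_keep)])

  ca <- vector("list", n_models)
  axyz <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    ca[[m]] <- matrix(xyz[m, ca_cols], ncol = 3L, byrow = TRUE)
    axyz[[m]] <- matrix(xyz[m, at_cols], ncol = 3L, byrow = TRUE)
    if (!all(is.finite(ca[[m]]))) stop("non-finite CA coordinates in model ", m)
  }

  atoms <- atom[atom_keep, c("chain", "resno", "insert", "resid", "elety", "elesy")]
  rownames(atoms) <- NULL
  atoms$res_index <- match(rkey[atom_keep], res_order)
  if (is.null(atoms$elesy) || anyNA(atoms$elesy) || any(atoms$elesy == "")) {
    atoms$elesy <- .element_from_name(atoms$elety, atoms$elesy)
  }

  out <- list(residues = residues, ca = ca, atoms = atoms, axyz = axyz,
              source = path)
  class(out) <- "protein_structure"
  out
}

# Highest-occupancy altloc resolution: one row per (residue, atom name).
.resolve_altloc <- function(atom) {
  akey <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  occ <- atom$o
  occ[is.na(occ)] <- 1
  ord <- order(factor(akey, levels = unique(akey)), -occ)
  !duplicated(akey[ord])[order(ord)]
}

.element_from_name <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    elesy <- toupper(trimws(elesy))
    bad <- is.na(elesy) | elesy == ""
  } else {
    elesy <- character(length(elety))
    bad <- rep(TRUE, length(elety))
  }
  guess <- toupper(substr(gsub("^[0-9]+", "", trimws(elety)), 1L, 1L))
  elesy[bad] <- guess[bad]
  elesy
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: %d residues, %d model(s)\n",
              nrow(x$residues), length(x$ca)))
  if (!is.null(x$atoms))
    cat(sprintf("  %d heavy-atom records per model\n", nrow(x$atoms)))
  invisible(x)
}

#' Number of residues of a structure
#' @param structure A `protein_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(structure) nrow(structure$residues)

#' Resolve residue keys to residue indices
#'
#' Residue keys are `chain:resno` tokens, optionally with an insertion
#' code appended (`A:41`, `A:41A`). A plain integer vector is taken as
#' residue indices and returned unchanged (after range checking).
#'
#' @param structure A `protein_structure`.
#' @param keys Character vector of `chain:resno` tokens, or integer
#'   indices into the residue table.
#' @return Integer vector of residue indices.
#' @export
resolve_residues <- function(structure, keys) {
  if (is.numeric(keys)) {
    idx <- as.integer(keys)
    if (any(idx < 1L | idx > n_residues(structure)))
      stop("residue index out of range")
    return(idx)
  }
  res <- structure$residues
  have <- paste0(res$chain, ":", res$resno, res$insert)
  idx <- match(trimws(keys), have)
  if (anyNA(idx))
    stop("residue key(s) not in structure: ",
         paste(keys[is.na(idx)], collapse = ", "))
  idx
}

#' Format residue indices as chain:resno keys
#' @param structure A `protein_structure`.
#' @param idx Integer residue indices (default: all).
#' @return Character vector of `chain:resno[insert]` tokens.
#' @export
residue_keys <- function(structure, idx = seq_len(n_residues(structure))) {
  res <- structure$residues
  paste0(res$chain[idx], ":", res$resno[idx], res$insert[idx])
}
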