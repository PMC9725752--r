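# Donor / acceptor heavy-atom templates per residue type. Backbone N
# donates (except proline) and backbone O / OXT accept for every
# residue; side-chain entries follow standard amino-acid chemistry.
.HB_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG"
)
.HB_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
  GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2"), MET = "SD", CYS = "SG"
)

.hb_roles <- function(atoms) {
  donor <- atoms$elety == "N" & atoms$resid != "PRO"
  acceptor <- atoms$elety %in% c("O", "OXT")
  for (res in names(.HB_DONORS))
    donor <- donor | (atoms$resid == res & atoms$elety %in% .HB_DONORS[[res]])
  for (res in names(.HB_ACCEPTORS))
    acceptor <- acceptor |
      (atoms$resid == res & atoms$elety %in% .HB_ACCEPTORS[[res]])
  heavy <- atoms$elesy %in% c("N", "O", "S")
  list(donor = donor & heavy, acceptor = acceptor & heavy)
}

#' Detect hydrogen bonds in one model
#'
#' A residue pair is bonded when any donor heavy atom (N/O/S per
#' residue-template chemistry) of one residue and acceptor of the other
#' lie within `d_max`. When the file contains hydrogens bonded to the
#' donor (within 1.25 Angstrom), the donor-H...acceptor angle must also
#' reach `angle_min`. Covalently adjacent backbone pairs (same chain,
#' residue numbers differing by at most 1) are excluded by default.
#'
#' @param structure A `protein_structure` with heavy-atom records.
#' @param model Model index.
#' @param d_max Donor-acceptor distance cutoff in Angstrom
#'   (default 3.5).
#' @param angle_min Minimum donor-H...acceptor angle in degrees
#'   (default 120), applied only where hydrogens are present.
#' @param exclude_adjacent Drop same-chain pairs with |delta resno| <= 1.
#' @return Data.frame with columns `i`, `j` (residue indices, `i < j`)
#'   and `witness` (semicolon-joined atom-pair labels).
#' @export
detect_hbonds <- function(structure, model = 1L, d_max = 3.5,
                          angle_min = 120, exclude_adjacent = TRUE) {
  atoms <- structure$atoms
  if (is.null(atoms)) stop("structure has no atom records")
  xyz <- structure$axyz[[model]]
  if (!any(atoms$elesy %in% c("N", "O")))
    stop("model has no N/O atoms; cannot detect hydrogen bonds")
  roles <- .hb_roles(atoms)
  don <- which(roles$donor)
  acc <- which(roles$acceptor)
  if (length(don) == 0L || length(acc) == 0L)
    return(data.frame(i = integer(), j = integer(), witness = character()))

  hyd <- which(atoms$elesy == "H")
  # attach each hydrogen to the nearest donor heavy atom within 1.25 A
  h_of <- vector("list", nrow(atoms))
  if (length(hyd)) {
    for (h in hyd) {
      dd <- sqrt(colSums((t(xyz[don, , drop = FALSE]) - xyz[h, ])^2))
      k <- which.min(dd)
      if (dd[k] <= 1.25) h_of[[don[k]]] <- c(h_of[[don[k]]], h)
    }
  }

  dmat <- sqrt(outer(rowSums(xyz[don, , drop = FALSE]^2), rep(1, length(acc))) +
               outer(rep(1, length(don)), rowSums(xyz[acc, , drop = FALSE]^2)) -
               2 * xyz[don, , drop = FALSE] %*% t(xyz[acc, , drop = FALSE]))
  hits <- which(dmat <= d_max, arr.ind = TRUE)
  out <- list()
  for (r in seq_len(nrow(hits))) {
    da <- don[hits[r, 1]]
    aa <- acc[hits[r, 2]]
    ri <- atoms$res_index[da]
    rj <- atoms$res_index[aa]
    if (ri == rj) next
    if (exclude_adjacent &&
        atoms$chain[da] == atoms$chain[aa] &&
        abs(atoms$resno[da] - atoms$resno[aa]) <= 1L) next
    hs <- h_of[[da]]
    if (length(hs)) {
      ang <- vapply(hs, function(h) {
        v1 <- xyz[da, ] - xyz[h, ]
        v2 <- xyz[aa, ] - xyz[h, ]
        acos(pmin(1, pmax(-1, sum(v1 * v2) /
                          (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      }, numeric(1))
      if (all(ang < angle_min)) next
    }
    key <- paste0(atoms$resno[da], ":", atoms$elety[da], "-",
                  atoms$resno[aa], ":", atoms$elety[aa])
    pi_ <- min(ri, rj); pj <- max(ri, rj)
    out[[length(out) + 1L]] <- data.frame(i = pi_, j = pj, witness = key,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), witness = character()))
  df <- do.call(rbind, out)
  agg <- stats::aggregate(witness ~ i + j, df,
                          function(w) paste(sort(unique(w)), collapse = ";"))
  agg[order(agg$i, agg$j), , drop = FALSE]
}

#' Aggregate hydrogen bonds over an ensemble
#'
#' Runs [detect_hbonds()] on every model and records, per residue pair,
#' the occupancy: the fraction of models in which the pair shares at
#' least one hydrogen bond.
#'
#' @param structure A multi-model `protein_structure`.
#' @inheritParams detect_hbonds
#' @return An object of class `hbond_graph`: list with `n_models`,
#'   `edges` (data.frame `i`, `j`, `occupancy`, `witness`),
#'   `per_model` (list of 2-column edge matrices) and `structure`.
#' @export
aggregate_hbonds <- function(structure, d_max = 3.5, angle_min = 120,
                             exclude_adjacent = TRUE) {
  n_models <- length(structure$axyz)
  per_model <- vector("list", n_models)
  tall <- list()
  for (m in seq_len(n_models)) {
    e <- detect_hbonds(structure, model = m, d_max = d_max,
                       angle_min = angle_min,
                       exclude_adjacent = exclude_adjacent)
    per_model[[m]] <- as.matrix(e[, c("i", "j"), drop = FALSE])
    if (nrow(e)) tall[[length(tall) + 1L]] <- e
  }
  if (length(tall)) {
    allp <- do.call(rbind, tall)
    cnt <- stats::aggregate(list(count = allp$i),
                            by = list(i = allp$i, j = allp$j), FUN = length)
    wit <- stats::aggregate(witness ~ i + j, allp,
                            function(w) paste(sort(unique(unlist(
                              strsplit(w, ";")))), collapse = ";"))
    edges <- merge(cnt, wit, by = c("i", "j"))
    edges$occupancy <- edges$count / n_models
    edges <- edges[order(edges$i, edges$j),
                   c("i", "j", "occupancy", "witness")]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(i = integer(), j = integer(),
                        occupancy = numeric(), witness = character())
  }
  out <- list(n_models = n_models, edges = edges, per_model = per_model,
              structure = structure)
  class(out) <- "hbond_graph"
  out
}

#' @export
print.hbond_graph <- function(x, ...) {
  cat(sprintf("hbond_graph: %d edges over %d model(s)\n",
              nrow(x$edges), x$n_models))
  invisible(x)
}

#' Enumerate hydrogen-bond pathways between two residues
#'
#' Finds every simple path of at most `max_length` edges from `source`
#' to `target` through edges with occupancy at least `min_occupancy`.
#' For each path two frequencies are reported: the bottleneck (minimum
#' edge occupancy along the path) and the support (fraction of models
#' in which every edge of the path is present simultaneously); joint
#' co-occurrence can only lower the latter, so support <= bottleneck.
#' Paths are sorted by descending support, then ascending length, then
#' lexicographic residue order.
#'
#' @param graph An `hbond_graph`.
#' @param source,target Residue indices (or `chain:resno` keys when the
#'   graph retains its structure).
#' @param min_occupancy Minimum edge occupancy (default 0.1).
#' @param max_length Maximum number of edges per path (default 6).
#' @return A data.frame of class `hbond_pathways` with columns `path`
#'   (dash-joined residue indices), `n_edges`, `support`, `bottleneck`.
#' @export
find_pathways <- function(graph, source, target, min_occupancy = 0.1,
                          max_length = 6L) {
  if (is.character(source)) source <- resolve_residues(graph$structure, source)
  if (is.character(target)) target <- resolve_residues(graph$structure, target)
  n_res <- nrow(graph$structure$residues)
  if (!all(c(source, target) %in% seq_len(n_res)))
    stop("source or target residue absent from the hydrogen-bond graph")
  e <- graph$edges[graph$edges$occupancy >= min_occupancy, , drop = FALSE]
  nodes <- sort(unique(c(e$i, e$j, source, target)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$i), to = as.character(e$j)),
    directed = FALSE, vertices = data.frame(name = as.character(nodes)))
  paths <- igraph::all_simple_paths(g, from = as.character(source),
                                    to = as.character(target),
                                    cutoff = max_length)
  if (length(paths) == 0L)
    return(structure(data.frame(path = character(), n_edges = integer(),
                                support = numeric(), bottleneck = numeric()),
                     class = c("hbond_pathways", "data.frame")))

  occ_of <- function(i, j) {
    hit <- e$occupancy[(e$i == min(i, j)) & (e$j == max(i, j))]
    hit[1]
  }
  model_sets <- lapply(graph$per_model, function(m)
    paste(m[, 1], m[, 2], sep = "-"))
  rows <- lapply(paths, function(p) {
    v <- as.integer(names(p))
    pairs <- cbind(utils::head(v, -1), v[-1])
    keys <- paste(pmin(pairs[, 1], pairs[, 2]),
                  pmax(pairs[, 1], pairs[, 2]), sep = "-")
    supp <- mean(vapply(model_sets, function(s) all(keys %in% s), logical(1)))
    bott <- min(mapply(occ_of, pairs[, 1], pairs[, 2]))
    data.frame(path = paste(v, collapse = "-"), n_edges = nrow(pairs),
               support = supp, bottleneck = bott, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$support, df$n_edges, df$path), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hbond_pathways", "data.frame")
  df
}
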