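# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own code paths.

# Dense Hessian assembled by plain double loops over residue pairs.
oracle_hessian <- function(xyz, cutoff, gamma = 1) {
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- xyz[j, ] - xyz[i, ]
      d <- sqrt(sum(r^2))
      if (d > cutoff) next
      blk <- -(gamma / d^2) * outer(r, r)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- blk
      H[ii, ii] <- H[ii, ii] - blk
    }
  }
  H
}

# Minimum-norm solve of H x = F via SVD, one force at a time; returns
# the direction-averaged per-residue response norms (mean of norms).
oracle_prs <- function(H, directions, rank_tol = 1e-8) {
  n <- nrow(H) / 3
  sv <- svd(H)
  keep <- sv$d > rank_tol * max(sv$d)
  out <- matrix(0, n, n)
  for (j in seq_len(n)) {
    acc <- numeric(n)
    for (k in seq_len(nrow(directions))) {
      F <- numeric(3 * n)
      F[(3 * j - 2):(3 * j)] <- directions[k, ]
      x <- sv$v[, keep, drop = FALSE] %*%
        ((t(sv$u[, keep, drop = FALSE]) %*% F) / sv$d[keep])
      acc <- acc + sqrt(rowSums(matrix(x, ncol = 3, byrow = TRUE)^2))
    }
    out[, j] <- acc / nrow(directions)
  }
  out
}

# Exhaustive simple-path enumeration by depth-first recursion over an
# undirected edge list (rows i, j), capped at max_edges edges.
oracle_paths <- function(edges, source, target, max_edges) {
  adj <- list()
  for (r in seq_len(nrow(edges))) {
    i <- as.character(edges$i[r]); j <- as.character(edges$j[r])
    adj[[i]] <- c(adj[[i]], edges$j[r])
    adj[[j]] <- c(adj[[j]], edges$i[r])
  }
  found <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == target) {
      found[[length(found) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) - 1L >= max_edges) return(invisible())
    for (nb in adj[[as.character(v)]])
      if (!nb %in% path) walk(c(path, nb))
  }
  walk(source)
  found
}

# Direct-sum mutual information (bits) of a weighted joint table given
# as parallel symbol vectors; pseudocount lambda spread over 20x20.
oracle_mi <- function(xa, xb, w, lambda = 0) {
  keep <- xa != 0 & xb != 0
  xa <- xa[keep]; xb <- xb[keep]; w <- w[keep]
  W <- sum(w)
  mi <- 0
  f <- matrix(lambda / 400, 20, 20)
  for (r in seq_along(xa)) f[xa[r], xb[r]] <- f[xa[r], xb[r]] + w[r]
  f <- f / (W + lambda)
  fa <- rowSums(f); fb <- colSums(f)
  for (x in 1:20) for (y in 1:20)
    if (f[x, y] > 0) mi <- mi + f[x, y] * log2(f[x, y] / (fa[x] * fb[y]))
  mi
}

# Hand-built minimal protein_structure from an atom table and one or
# more coordinate sets (used by the hydrogen-bond geometry tests).
hand_structure <- function(atoms, coords) {
  if (!is.list(coords)) coords <- list(coords)
  res_rows <- !duplicated(atoms$res_index)
  out <- list(
    residues = data.frame(chain = atoms$chain[res_rows],
                          resno = atoms$resno[res_rows],
                          insert = "", resid = atoms$resid[res_rows],
                          stringsAsFactors = FALSE),
    ca = lapply(coords, function(x) x[atoms$elety == "CA", , drop = FALSE]),
    atoms = atoms, axyz = coords, source = "hand")
  class(out) <- "protein_structure"
  out
}

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
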