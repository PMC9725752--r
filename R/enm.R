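#' Build an anisotropic elastic-network Hessian
#'
#' Constructs the 3N x 3N second-derivative matrix of a distance-weighted
#' anisotropic network model on the Calpha trace: residue pairs within
#' `cutoff` are joined by a Hookean spring, and the off-diagonal 3x3
#' superblock for a contacting pair (i, j) is
#' `-(gamma / d_ij^2) (r_j - r_i)(r_j - r_i)^T`, i.e. a uniform spring
#' constant acting along the unit inter-residue vector. Diagonal
#' superblocks enforce translation invariance (every row sums to zero).
#'
#' @param structure A `protein_structure`.
#' @param cutoff Contact cutoff in Angstrom. Default 13, a typical
#'   Calpha anisotropic-network radius that captures second-shell
#'   contacts.
#' @param gamma Spring constant (arbitrary units); scales the spectrum
#'   but none of the normalized DFI/DCI profiles.
#' @param model Which coordinate model to use.
#' @return An object of class `enm_hessian`: list with `n`, `matrix`
#'   (3N x 3N), `cutoff`, `gamma`.
#' @export
build_hessian <- function(structure, cutoff = 13, gamma = 1, model = 1L) {
  stopifnot(cutoff > 0, gamma > 0)
  xyz <- structure$ca[[model]]
  n <- nrow(xyz)
  if (n < 2L) stop("need at least 2 residues")
  d <- as.matrix(stats::dist(xyz))
  off <- d[upper.tri(d)]
  if (any(off == 0))
    stop("coincident CA atoms (zero inter-residue distance)")
  contact <- d <= cutoff
  diag(contact) <- FALSE
  if (any(rowSums(contact) == 0L))
    warning("disconnected network: ", sum(rowSums(contact) == 0L),
            " residue(s) with no neighbor within ", cutoff, " A")

  H <- matrix(0, 3L * n, 3L * n)
  for (i in seq_len(n - 1L)) {
    js <- which(contact[i, ] & seq_len(n) > i)
    for (j in js) {
      rij <- xyz[j, ] - xyz[i, ]
      blk <- -(gamma / d[i, j]^2) * tcrossprod(rij)
      ii <- (3L * i - 2L):(3L * i)
      jj <- (3L * j - 2L):(3L * j)
      H[ii, jj] <- blk
      H[jj, ii] <- blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  out <- list(n = n, matrix = H, cutoff = cutoff, gamma = gamma)
  class(out) <- "enm_hessian"
  out
}

#' Pseudo-invert a Hessian into a linear-response kernel
#'
#' Moore-Penrose pseudo-inverse by eigendecomposition, discarding the
#' `null_modes` smallest-magnitude eigenvalues (the six rigid-body modes
#' of a well-formed 3D structure). The inverse Hessian plays the role of
#' a covariance matrix in linear response theory.
#'
#' @param hessian An `enm_hessian`.
#' @param null_modes Number of null modes to discard (default 6).
#' @return An object of class `response_kernel`: list with `n`, `matrix`
#'   (3N x 3N), `source = "hessian-pseudoinverse"`.
#' @export
invert_kernel <- function(hessian, null_modes = 6L) {
  H <- hessian$matrix
  eig <- eigen(H, symmetric = TRUE)
  lam <- eig$values
  ord <- order(abs(lam))            # smallest magnitude first
  drop_idx <- ord[seq_len(null_modes)]
  keep <- setdiff(seq_along(lam), drop_idx)
  lmax <- max(abs(lam))
  bad <- abs(lam[keep]) < 1e-10 * lmax
  if (any(bad))
    stop(sum(bad), " near-singular mode(s) beyond the discarded ",
         null_modes, "; structure likely collinear or disconnected")
  V <- eig$vectors[, keep, drop = FALSE]
  K <- V %*% (t(V) / lam[keep])
  K <- (K + t(K)) / 2
  out <- list(n = hessian$n, matrix = K, source = "hessian-pseudoinverse")
  class(out) <- "response_kernel"
  out
}

#' Load an externally computed covariance matrix as a response kernel
#'
#' Reads a dense 3N x 3N text matrix (e.g. a Cartesian covariance matrix
#' from molecular dynamics) to use in place of the Hessian
#' pseudo-inverse. The matrix is symmetrized as `(C + t(C))/2` provided
#' its relative asymmetry is at most 1e-6.
#'
#' @param path Text file: one row per line, whitespace- or
#'   comma-delimited, `#` comment lines allowed.
#' @param n_residues Expected residue count N.
#' @return A `response_kernel` with `source = "supplied-covariance"`.
#' @export
load_covariance <- function(path, n_residues) {
  C <- read_dense_matrix(path)
  want <- 3L * n_residues
  if (!all(dim(C) == want))
    stop("covariance matrix is ", nrow(C), "x", ncol(C),
         "; expected ", want, "x", want, " for N = ", n_residues)
  scale <- max(abs(C))
  if (scale == 0) scale <- 1
  asym <- max(abs(C - t(C))) / scale
  if (asym > 1e-6)
    stop("matrix asymmetry ", format(asym), " exceeds tolerance 1e-6")
  out <- list(n = n_residues, matrix = (C + t(C)) / 2,
              source = "supplied-covariance")
  class(out) <- "response_kernel"
  out
}

#' Read a dense numeric matrix from text
#'
#' One row per line; fields separated by whitespace and/or commas;
#' lines starting with `#` are ignored.
#' @param path Input file.
#' @return A numeric matrix.
#' @export
read_dense_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("no data rows in ", path)
  rows <- lapply(strsplit(trimws(lines), "[,[:space:]]+"), as.numeric)
  len <- lengths(rows)
  if (length(unique(len)) != 1L) stop("ragged matrix in ", path)
  m <- do.call(rbind, rows)
  if (anyNA(m)) stop("non-numeric entries in ", path)
  m
}

#' Write a dense numeric matrix as text
#' @param m Numeric matrix.
#' @param path Output file.
#' @param header Optional character vector written as `#` comments.
#' @export
write_dense_matrix <- function(m, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE,
                     sep = " ")
  invisible(path)
}

#' @export
print.enm_hessian <- function(x, ...) {
  cat(sprintf("enm_hessian: N = %d, cutoff = %g A, gamma = %g\n",
              x$n, x$cutoff, x$gamma))
  invisible(x)
}

#' @export
print.response_kernel <- function(x, ...) {
  cat(sprintf("response_kernel: N = %d, source = %s\n", x$n, x$source))
  invisible(x)
}
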