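#' Force direction sets for perturbation response scanning
#'
#' The default deterministic set contains seven unit vectors: the three
#' Cartesian axes plus the normalized diagonals (1,1,0), (1,0,1),
#' (0,1,1) and (1,1,1), giving near-isotropic coverage without random
#' sampling. Alternatively, `k` seeded random unit directions can be
#' drawn.
#'
#' @param k Number of random unit vectors; `NULL` (default) returns the
#'   deterministic 7-direction set.
#' @param seed Seed used when `k` is given.
#' @return A matrix with one unit 3-vector per row.
#' @export
force_directions <- function(k = NULL, seed = 1L) {
  if (is.null(k)) {
    d <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  } else {
    stopifnot(k >= 1)
    d <- withr::with_seed(seed, matrix(stats::rnorm(3 * k), ncol = 3))
  }
  d / sqrt(rowSums(d^2))
}

#' Perturbation response scanning
#'
#' Applies a unit force along each direction at each residue in turn and
#' records, per responding residue, the Euclidean norm of its 3-vector
#' displacement response `Delta R = H^-1 F` under linear response
#' theory. Entry (i, j) of the result is the mean response magnitude of
#' residue i to perturbation at residue j, averaged over directions.
#'
#' @param kernel A `response_kernel` (Hessian pseudo-inverse or supplied
#'   covariance).
#' @param directions Matrix of unit force directions (rows); default
#'   [force_directions()].
#' @param average `"norm"` (default): arithmetic mean of the response
#'   norms over the directions. `"rms"`: root-mean-square of the norms;
#'   with a direction set forming a tight frame (`sum(d d^T)`
#'   proportional to the identity, e.g. the three Cartesian axes) the
#'   RMS average is exactly rotation-invariant, which makes profiles of
#'   symmetric structures exactly symmetric.
#' @return An object of class `response_matrix`: list with `n` and
#'   `values` (N x N, nonnegative).
#' @export
scan_responses <- function(kernel, directions = force_directions(),
                           average = c("norm", "rms")) {
  average <- match.arg(average)
  stopifnot(inherits(kernel, "response_kernel"))
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L || nrow(directions) < 1L)
    stop("directions must be a k x 3 matrix with k >= 1")
  norms <- sqrt(rowSums(directions^2))
  if (any(abs(norms - 1) > 1e-12))
    stop("force directions must be unit vectors")
  n <- kernel$n
  K <- kernel$matrix
  nd <- nrow(directions)
  vals <- matrix(0, n, n)
  for (j in seq_len(n)) {
    cols <- (3L * j - 2L):(3L * j)
    resp <- K[, cols] %*% t(directions)        # 3N x nd
    # per-direction per-residue norms, then average over directions
    sq <- resp^2
    sq_norm <- sq[seq(1, 3 * n, 3), , drop = FALSE] +
               sq[seq(2, 3 * n, 3), , drop = FALSE] +
               sq[seq(3, 3 * n, 3), , drop = FALSE]
    vals[, j] <- if (average == "norm") rowMeans(sqrt(sq_norm))
                 else sqrt(rowMeans(sq_norm))
  }
  out <- list(n = n, values = vals)
  class(out) <- "response_matrix"
  out
}

#' Percentile rank with mid-rank ties
#'
#' Maps each value to `(#smaller + 0.5 * #equal-excluding-self + 1) / N`,
#' so strictly increasing inputs map to `(1/N, 2/N, ..., 1)` and tied
#' values share a rank.
#'
#' @param values Numeric vector, finite, non-empty.
#' @return Numeric vector of ranks in (0, 1].
#' @export
percentile_rank <- function(values) {
  if (length(values) == 0L) stop("empty input")
  if (any(!is.finite(values))) stop("non-finite values in percentile_rank")
  rank(values, ties.method = "average") / length(values)
}

#' Dynamic flexibility index profile
#'
#' DFI of residue i is its total response across all perturbation sites,
#' normalized by the grand total over all residues:
#' `dfi_i = sum_j |dR_j|_i / sum_i sum_j |dR_j|_i`. Low-DFI positions
#' are hinges: rigid communication hubs whose perturbation propagates
#' broadly. `%DFI` is the within-protein percentile rank.
#'
#' @param responses A `response_matrix`.
#' @return A data.frame of class `dfi_profile` with columns `dfi`
#'   (sums to 1) and `pct_dfi`.
#' @export
compute_dfi <- function(responses) {
  stopifnot(inherits(responses, "response_matrix"))
  row_tot <- rowSums(responses$values)
  total <- sum(row_tot)
  if (total <= 0) stop("degenerate kernel: zero total response")
  dfi <- row_tot / total
  out <- data.frame(dfi = dfi, pct_dfi = percentile_rank(dfi))
  class(out) <- c("dfi_profile", "data.frame")
  out
}

#' Dynamic coupling index profile
#'
#' DCI of residue i is its mean response to perturbations at a
#' functional-site set, relative to its mean response to perturbations
#' anywhere:
#' `dci_i = (sum_{j in F} |dR_j|_i / |F|) / (sum_j |dR_j|_i / N)`.
#' Values above 1 mark above-average coupling to the functional site.
#'
#' @param responses A `response_matrix`.
#' @param functional_set Integer residue indices of the functional
#'   (e.g. binding-site) residues.
#' @return A data.frame of class `dci_profile` with columns `dci` and
#'   `pct_dci`; the functional set is kept in
#'   `attr(, "functional_set")`.
#' @export
compute_dci <- function(responses, functional_set) {
  stopifnot(inherits(responses, "response_matrix"))
  n <- responses$n
  f <- unique(as.integer(functional_set))
  if (length(f) == 0L) stop("functional_set is empty")
  if (any(f < 1L | f > n))
    stop("functional residue index out of range: ",
         paste(f[f < 1L | f > n], collapse = ", "))
  v <- responses$values
  num <- rowMeans(v[, f, drop = FALSE])
  den <- rowMeans(v)
  if (any(den <= 0)) stop("degenerate kernel: residue with zero response")
  dci <- num / den
  out <- data.frame(dci = dci, pct_dci = percentile_rank(dci))
  attr(out, "functional_set") <- f
  class(out) <- c("dci_profile", "data.frame")
  out
}

#' Flag hinge sites on a DFI profile
#'
#' Hinges are positions in the low tail of the flexibility ranking
#' (`%DFI` strictly below the threshold, default 0.2).
#'
#' @param profile A `dfi_profile`.
#' @param threshold `%DFI` threshold.
#' @return Logical vector, `TRUE` at hinge positions.
#' @export
hinge_sites <- function(profile, threshold = 0.2) {
  stopifnot(inherits(profile, "dfi_profile"))
  profile$pct_dfi < threshold
}

#' Write a per-residue profile as CSV
#'
#' Joins a DFI (and optionally DCI) profile to a structure's residue
#' table and writes a CSV with a `#` metadata header.
#'
#' @param structure A `protein_structure`.
#' @param dfi A `dfi_profile`.
#' @param path Output CSV path.
#' @param dci Optional `dci_profile` over the same residues.
#' @param meta Optional named character vector written as header lines.
#' @return The joined data.frame, invisibly.
#' @export
write_profile_csv <- function(structure, dfi, path, dci = NULL, meta = NULL) {
  df <- cbind(structure$residues, dfi)
  if (!is.null(dci)) {
    df <- cbind(df, dci)
    fs <- attr(dci, "functional_set")
    meta <- c(meta, functional_set = paste(residue_keys(structure, fs),
                                           collapse = ";"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), " = ", meta), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(df)
}
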