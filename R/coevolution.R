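AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Encode aligned sequences as an integer matrix: 1..20 for the standard
# amino acids, 0 for gaps and ambiguity characters.
.encode_msa <- function(seqs) {
  M <- length(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("ragged alignment: sequences differ in length")
  m <- matrix(match(toupper(unlist(strsplit(seqs, ""))), AA20, nomatch = 0L),
              nrow = M, ncol = L, byrow = TRUE)
  m
}

#' Construct an MSA object from aligned sequences
#'
#' @param seqs Named character vector of aligned sequences (one string
#'   per sequence; 20 amino acids plus `-`/`.` gaps).
#' @param reference_id Identifier of the reference row used to map
#'   alignment columns to structure residue numbers.
#' @param offset Residue number of the first non-gap reference column
#'   minus one (default 0: first mapped column is residue 1).
#' @return An object of class `msa`: list with `ids`, `seqs`, `mat`
#'   (integer-encoded M x L matrix), `L`, `ref` (reference row index)
#'   and `column_map` (alignment column -> residue number, NA where the
#'   reference is gapped).
#' @export
msa_from_sequences <- function(seqs, reference_id = names(seqs)[1],
                               offset = 0L) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ref <- match(reference_id, names(seqs))
  if (is.na(ref))
    stop("reference '", reference_id, "' not in alignment; available: ",
         paste(utils::head(names(seqs), 10L), collapse = ", "))
  mat <- .encode_msa(seqs)
  ref_chars <- strsplit(toupper(seqs[[ref]]), "")[[1]]
  non_gap <- !(ref_chars %in% c("-", "."))
  if (any(non_gap & mat[ref, ] == 0L))
    stop("reference row contains ambiguity characters")
  column_map <- rep(NA_integer_, ncol(mat))
  column_map[non_gap] <- offset + seq_len(sum(non_gap))
  out <- list(ids = names(seqs), seqs = unname(seqs), mat = mat,
              L = ncol(mat), ref = ref, column_map = column_map)
  class(out) <- "msa"
  out
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA or Stockholm alignments and builds the column-to-residue
#' map by walking the reference row: non-gap reference columns map to
#' successive residue numbers starting at `offset + 1`.
#'
#' @param path Alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @param reference_id Identifier of the reference sequence.
#' @param offset Residue-numbering offset (see [msa_from_sequences()]).
#' @return An `msa` object.
#' @export
read_msa <- function(path, format = c("fasta", "stockholm"),
                     reference_id = NULL, offset = 0L) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(Biostrings::unmasked(aln))
  if (is.null(reference_id)) reference_id <- names(seqs)[1]
  msa_from_sequences(seqs, reference_id = reference_id, offset = offset)
}

#' Write an MSA as aligned FASTA
#' @param msa An `msa` object.
#' @param path Output file.
#' @export
write_msa_fasta <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", msa$ids, "\n", msa$seqs), con)
  invisible(path)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns, reference '%s' (%d mapped)\n",
              length(x$ids), x$L, x$ids[x$ref], sum(!is.na(x$column_map))))
  invisible(x)
}

#' Redundancy-correcting sequence weights
#'
#' Each sequence is weighted by the reciprocal of the number of
#' sequences (itself included) within `identity_threshold` pairwise
#' identity, computed over columns where both rows are non-gap. The sum
#' of the weights is the effective sequence count Meff.
#'
#' @param msa An `msa` object with at least 2 sequences.
#' @param identity_threshold Fractional identity above which two
#'   sequences count as neighbors (default 0.8).
#' @return An object of class `sequence_weights`: list with `weights`
#'   (one per sequence, in (0, 1]) and `meff`.
#' @export
compute_weights <- function(msa, identity_threshold = 0.8) {
  m <- msa$mat
  M <- nrow(m)
  if (M < 2L) stop("need at least 2 sequences")
  neighbors <- integer(M)
  ng <- m != 0L
  for (i in seq_len(M)) {
    both <- ng & rep(ng[i, ], each = M)       # M x L: both rows non-gap
    eq <- m == rep(m[i, ], each = M)
    denom <- rowSums(both)
    ident <- ifelse(denom > 0, rowSums(eq & both) / denom, 0)
    neighbors[i] <- sum(ident >= identity_threshold)
  }
  w <- 1 / neighbors
  out <- list(weights = w, meff = sum(w))
  class(out) <- "sequence_weights"
  out
}

#' Weighted mutual information between alignment columns
#'
#' For each column pair, joint amino-acid frequencies are accumulated
#' over sequences that are non-gap at both columns, using the sequence
#' weights, with a symmetric additive pseudocount `lambda/400` per cell
#' before normalization. Marginals come from the joint, and
#' `MI(a,b) = sum f(x,y) log2(f(x,y) / (f(x) f(y)))` in bits. Pairs
#' whose retained effective weight falls below `min_effective` are
#' flagged invalid, as is the diagonal.
#'
#' @param msa An `msa` object.
#' @param weights A `sequence_weights` (default: computed at 0.8
#'   identity).
#' @param pseudocount Total pseudocount lambda (default 0.5).
#' @param min_effective Minimum effective sequence weight per pair
#'   (default 5).
#' @return An object of class `coupling_matrix`: list with `L`,
#'   `raw_mi`, `corrected`, `normalized` (L x L, NA where not yet
#'   filled) and `valid` (logical L x L).
#' @export
compute_mi <- function(msa, weights = compute_weights(msa),
                       pseudocount = 0.5, min_effective = 5) {
  m <- msa$mat
  L <- ncol(m)
  w <- weights$weights
  raw <- matrix(NA_real_, L, L)
  valid <- matrix(FALSE, L, L)
  for (a in seq_len(L - 1L)) {
    xa <- m[, a]
    for (b in (a + 1L):L) {
      xb <- m[, b]
      keep <- xa != 0L & xb != 0L
      W <- sum(w[keep])
      if (W < min_effective) next
      idx <- (xa[keep] - 1L) * 20L + xb[keep]
      tab <- numeric(400L)
      agg <- rowsum(w[keep], idx)
      tab[as.integer(rownames(agg))] <- agg
      f <- (tab + pseudocount / 400) / (W + pseudocount)
      fj <- matrix(f, 20L, 20L, byrow = TRUE)   # row = symbol at a
      fa <- rowSums(fj)
      fb <- colSums(fj)
      nz <- fj > 0
      mi <- sum(fj[nz] * log2(fj[nz] / outer(fa, fb)[nz]))
      raw[a, b] <- raw[b, a] <- mi
      valid[a, b] <- valid[b, a] <- TRUE
    }
  }
  if (!any(valid))
    stop("no valid column pairs: alignment too gapped or too small")
  out <- list(L = L, raw_mi = raw,
              corrected = matrix(NA_real_, L, L),
              normalized = matrix(NA_real_, L, L),
              valid = valid)
  class(out) <- "coupling_matrix"
  out
}

#' Average-product correction of mutual information
#'
#' Subtracts the background term `mean_a * mean_b / mean_all` from each
#' pair's MI, where `mean_a` is column a's mean MI over its valid
#' partners and `mean_all` the mean over all valid pairs. This removes
#' the shared phylogenetic/entropic signal that inflates MI in small
#' alignments.
#'
#' @param coupling A `coupling_matrix` with `raw_mi` filled.
#' @return The `coupling_matrix` with `corrected` filled.
#' @export
apc_correct <- function(coupling) {
  raw <- coupling$raw_mi
  valid <- coupling$valid
  vals <- raw[upper.tri(raw)][valid[upper.tri(valid)]]
  mean_all <- mean(vals)
  if (mean_all == 0) {
    warning("mean MI is zero; corrected scores set equal to raw MI")
    coupling$corrected <- raw
    return(coupling)
  }
  col_mean <- vapply(seq_len(coupling$L), function(a) {
    p <- valid[a, ]
    if (any(p)) mean(raw[a, p]) else NA_real_
  }, numeric(1))
  corr <- raw - outer(col_mean, col_mean) / mean_all
  corr[!valid] <- NA_real_
  coupling$corrected <- corr
  coupling
}

#' Rank-normalize corrected co-evolution scores
#'
#' Percentile-ranks the corrected scores over all valid upper-triangle
#' pairs (mid-rank ties) and writes the result symmetrically, yielding
#' scores in (0, 1] on which the co-evolution threshold is defined.
#'
#' @param coupling A `coupling_matrix` with `corrected` filled.
#' @return The `coupling_matrix` with `normalized` filled.
#' @export
normalize_coupling <- function(coupling) {
  corr <- coupling$corrected
  valid <- coupling$valid
  ut <- upper.tri(corr)
  sel <- ut & valid
  norm <- matrix(NA_real_, coupling$L, coupling$L)
  norm[sel] <- percentile_rank(corr[sel])
  norm[lower.tri(norm)] <- t(norm)[lower.tri(norm)]
  coupling$normalized <- norm
  coupling
}

#' Per-column coupling to a set of site columns
#'
#' Collapses the normalized coupling matrix to one score per column:
#' the maximum (default) or mean normalized score between that column
#' and any site column. A single strong co-evolutionary link to the
#' site suffices under the max convention.
#'
#' @param coupling A `coupling_matrix` with `normalized` filled.
#' @param site_columns Alignment column indices of the site.
#' @param method `"max"` or `"mean"`.
#' @return Numeric vector of length L (NA where no valid pair links the
#'   column to the site).
#' @export
coupling_to_site <- function(coupling, site_columns,
                             method = c("max", "mean")) {
  method <- match.arg(method)
  if (length(site_columns) == 0L) stop("site_columns is empty")
  norm <- coupling$normalized[, site_columns, drop = FALSE]
  apply(norm, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0L) return(NA_real_)
    if (method == "max") max(r) else mean(r)
  })
}

#' Export a coupling matrix as a pair table
#' @param coupling A `coupling_matrix`.
#' @param path Output CSV file.
#' @return The pair table, invisibly.
#' @export
write_coupling_csv <- function(coupling, path) {
  ut <- which(upper.tri(coupling$raw_mi), arr.ind = TRUE)
  df <- data.frame(col_a = ut[, 1], col_b = ut[, 2],
                   raw_mi = coupling$raw_mi[ut],
                   corrected = coupling$corrected[ut],
                   normalized = coupling$normalized[ut],
                   valid = coupling$valid[ut])
  df <- df[order(df$col_a, df$col_b), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
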