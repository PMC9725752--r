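#' Classify positions into the four dynamics/co-evolution categories
#'
#' Each non-binding-site position receives a dynamics bit and a
#' co-evolution bit. The dynamics bit is 1 for rigid, strongly coupled
#' sites (`%DFI <= dfi_rigid` and `%DCI >= dci`), 0 for flexible,
#' weakly coupled sites (`%DFI >= dfi_flex` and `%DCI < dci`), and
#' undefined otherwise — intermediate positions are reported as
#' `unclassified` rather than forced into a bin (a nearest-extreme mode
#' is available). The co-evolution bit is 1 when the position's
#' coupling score with the binding site reaches the `coevo` threshold.
#' Binding-site positions are excluded from the table.
#'
#' @param dfi A `dfi_profile` over all N residues.
#' @param dci A `dci_profile` over the same residues.
#' @param coevo_scores Numeric vector of length N: each position's
#'   normalized co-evolution score with the binding site (NA allowed
#'   for unmapped positions; treated as 0 with a note).
#' @param binding_set Integer residue indices of the binding site.
#' @param thresholds Named list: `dfi_rigid` (default 0.2), `dfi_flex`
#'   (0.7), `dci` (0.7), `coevo` (0.6). Rigidity and coupling cuts are
#'   inclusive ("0.2 or lower", "0.7 or higher").
#' @param mode `"strict"` keeps the `unclassified` label;
#'   `"nearest"` assigns intermediate positions the dynamics bit of the
#'   nearer extreme (1 when `%DCI >= dci`, else 0).
#' @return A data.frame of class `icdc_table` with one row per
#'   non-binding-site position: `residue` (index), `pct_dfi`,
#'   `pct_dci`, `coevo_score`, `dyn_bit`, `coevo_bit`, `category`.
#' @export
classify_icdc <- function(dfi, dci, coevo_scores, binding_set,
                          thresholds = list(dfi_rigid = 0.2,
                                            dfi_flex = 0.7,
                                            dci = 0.7, coevo = 0.6),
                          mode = c("strict", "nearest")) {
  mode <- match.arg(mode)
  th <- utils::modifyList(list(dfi_rigid = 0.2, dfi_flex = 0.7,
                               dci = 0.7, coevo = 0.6), thresholds)
  n <- nrow(dfi)
  stopifnot(nrow(dci) == n, length(coevo_scores) == n)
  binding_set <- unique(as.integer(binding_set))
  if (length(binding_set) == 0L) stop("binding_set is empty")
  keep <- setdiff(seq_len(n), binding_set)
  if (length(keep) == 0L) stop("no positions left after excluding binding set")

  cs <- coevo_scores
  if (anyNA(cs[keep]))
    message(sum(is.na(cs[keep])),
            " position(s) without a mapped MSA column; coupling score set to 0")
  cs[is.na(cs)] <- 0

  pdfi <- dfi$pct_dfi[keep]
  pdci <- dci$pct_dci[keep]
  dyn <- rep(NA_integer_, length(keep))
  dyn[pdfi <= th$dfi_rigid & pdci >= th$dci] <- 1L
  dyn[pdfi >= th$dfi_flex & pdci < th$dci] <- 0L
  if (mode == "nearest") {
    und <- is.na(dyn)
    dyn[und] <- ifelse(pdci[und] >= th$dci, 1L, 0L)
  }
  coevo_bit <- as.integer(cs[keep] >= th$coevo)
  category <- ifelse(is.na(dyn), "unclassified",
                     paste0("(", dyn, ",", coevo_bit, ")"))

  out <- data.frame(residue = keep, pct_dfi = pdfi, pct_dci = pdci,
                    coevo_score = cs[keep], dyn_bit = dyn,
                    coevo_bit = coevo_bit, category = category,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- th
  attr(out, "binding_set") <- binding_set
  class(out) <- c("icdc_table", "data.frame")
  out
}

#' Restrict an MSA to sequences with a compatible binding site
#'
#' Keeps sequences whose amino acids at the binding-site columns match
#' the reference composition at a fraction of positions of at least
#' `min_identity`. Matching is exact by default; `mode = "class"`
#' also accepts substitutions within the classes {ILVM}, {FYW}, {KR},
#' {DE}, {ST}, {NQ}. The reference sequence is always retained.
#'
#' @param msa An `msa` object.
#' @param binding_columns Alignment column indices of the binding site.
#' @param min_identity Minimum matching fraction in \[0, 1\].
#' @param mode `"exact"` or `"class"`.
#' @return The filtered `msa` (column map unchanged).
#' @export
filter_msa_by_binding_site <- function(msa, binding_columns,
                                       min_identity = 0.75,
                                       mode = c("exact", "class")) {
  mode <- match.arg(mode)
  if (length(binding_columns) == 0L) stop("binding_columns is empty")
  m <- msa$mat[, binding_columns, drop = FALSE]
  ref <- m[msa$ref, ]
  if (any(ref == 0L)) stop("reference is gapped at a binding column")
  same <- m == rep(ref, each = nrow(m))
  if (mode == "class") {
    classes <- list(c("I", "L", "V", "M"), c("F", "Y", "W"),
                    c("K", "R"), c("D", "E"), c("S", "T"), c("N", "Q"))
    cls <- rep(NA_integer_, 20L)
    for (k in seq_along(classes)) cls[match(classes[[k]], AA20)] <- k
    mc <- matrix(cls[m], nrow(m))         # NA where gap or unclassed
    rc <- cls[ref]
    same <- same | (!is.na(mc) & mc == rep(rc, each = nrow(m)))
  }
  frac <- rowSums(same) / length(binding_columns)
  keep <- frac >= min_identity
  keep[msa$ref] <- TRUE                 # reference always retained
  if (sum(keep) == 1L)
    message("only the reference passes the binding-site filter; ",
            "consider lowering min_identity")
  sub <- msa$seqs[keep]
  names(sub) <- msa$ids[keep]
  msa_from_sequences(sub, reference_id = msa$ids[msa$ref],
                     offset = min(msa$column_map, na.rm = TRUE) - 1L)
}

#' Propose substitutions observed in the alignment at a position
#'
#' Computes the weighted frequency of every non-gap, non-wild-type
#' amino acid at the alignment column mapped to `position`, and returns
#' those at or above `min_weighted_freq`, sorted by descending
#' frequency with alphabetical tie-break. The wild type is the
#' reference row's amino acid.
#'
#' @param msa An `msa` object (typically the binding-site-filtered
#'   subset).
#' @param weights A `sequence_weights` for `msa`.
#' @param position Structure residue number (matched against the
#'   column map).
#' @param min_weighted_freq Minimum weighted frequency (default 0.05).
#' @return A data.frame of class `mutation_proposals` with columns
#'   `position`, `wild_type`, `substitution`, `weighted_frequency`,
#'   `supporting_sequences`.
#' @export
propose_substitutions <- function(msa, weights, position,
                                  min_weighted_freq = 0.05) {
  col <- match(position, msa$column_map)
  if (is.na(col))
    stop("position ", position, " is not mapped to an alignment column")
  x <- msa$mat[, col]
  wt_code <- x[msa$ref]
  wt <- AA20[wt_code]
  w <- weights$weights
  keep <- x != 0L
  tot <- sum(w[keep])
  freq <- numeric(20L)
  agg <- rowsum(w[keep], x[keep])
  freq[as.integer(rownames(agg))] <- agg / tot
  count <- tabulate(x[keep], nbins = 20L)
  cand <- setdiff(which(freq >= min_weighted_freq & freq > 0), wt_code)
  out <- data.frame(position = rep(position, length(cand)),
                    wild_type = rep(wt, length(cand)),
                    substitution = AA20[cand],
                    weighted_frequency = freq[cand],
                    supporting_sequences = count[cand],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weighted_frequency, out$substitution), ]
  rownames(out) <- NULL
  class(out) <- c("mutation_proposals", "data.frame")
  out
}

#' Write an ICDC table as CSV
#'
#' @param icdc An `icdc_table`.
#' @param path Output CSV path.
#' @param structure Optional `protein_structure` used to annotate rows
#'   with chain/resno/resname.
#' @return The written data.frame, invisibly.
#' @export
write_icdc_csv <- function(icdc, path, structure = NULL) {
  df <- icdc
  if (!is.null(structure))
    df <- cbind(structure$residues[icdc$residue, , drop = FALSE], icdc)
  th <- attr(icdc, "thresholds")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# thresholds: dfi_rigid=", th$dfi_rigid,
                    " dfi_flex=", th$dfi_flex, " dci=", th$dci,
                    " coevo=", th$coevo), con)
  writeLines(paste0("# binding_set: ",
                    paste(attr(icdc, "binding_set"), collapse = ";")), con)
  utils::write.csv(df, con, row.names = FALSE)   # categories contain commas
  invisible(df)
}
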