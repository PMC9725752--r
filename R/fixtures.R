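#' Generate a synthetic Calpha structure
#'
#' Deterministic, seeded toy structures used throughout the test suite
#' and demos:
#' * `chain`: `n` residues along x at 3.8 Angstrom spacing (the typical
#'   Calpha-Calpha distance of a real trace) with small off-axis jitter
#'   to avoid collinearity;
#' * `ring`: a regular n-gon whose neighbor spacing is 3.8 Angstrom
#'   (exactly symmetric, no jitter);
#' * `square`: four residues on a unit square (a tiny closed-form
#'   Hessian fixture);
#' * `dumbbell`: two dense lobes of `n` residues each joined by a
#'   2-residue linker (residues `n+1`, `n+2`), the canonical
#'   hinge-localization fixture.
#'
#' @param kind One of `"chain"`, `"ring"`, `"square"`, `"dumbbell"`.
#' @param n Residue count (`chain`, `ring`) or lobe size (`dumbbell`);
#'   ignored for `square`.
#' @param seed Integer seed; identical inputs give identical output.
#' @param noise Off-axis jitter standard deviation in Angstrom
#'   (chain and dumbbell only).
#' @return A `protein_structure` with a single model and no atom
#'   records (Calpha only).
#' @export
make_structure <- function(kind = c("chain", "ring", "square", "dumbbell"),
                           n = 6L, seed = 1L, noise = 0.3) {
  kind <- match.arg(kind)
  xyz <- switch(kind,
    chain = {
      if (n < 2L) stop("chain needs n >= 2")
      jitter <- withr::with_seed(seed,
        matrix(stats::rnorm(2L * n, sd = noise), ncol = 2L))
      cbind(3.8 * (seq_len(n) - 1L), jitter)
    },
    ring = {
      if (n < 3L) stop("ring needs n >= 3")
      R <- 3.8 / (2 * sin(pi / n))
      th <- 2 * pi * (seq_len(n) - 1L) / n
      cbind(R * cos(th), R * sin(th), 0)
    },
    square = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
    dumbbell = {
      if (n < 4L) stop("dumbbell needs lobe size >= 4")
      grid <- as.matrix(expand.grid(x = 0:3, y = 0:3, z = 0:3)) * 3.8
      if (n > nrow(grid)) stop("lobe size at most ", nrow(grid))
      ord <- order(rowSums(grid^2))    # compact lobe: fill from corner
      lobe <- grid[ord[seq_len(n)], , drop = FALSE]
      ax <- max(lobe[, 1])
      linker <- rbind(c(ax + 3.8, 1.9, 1.9), c(ax + 7.6, 1.9, 1.9))
      lobe_b <- lobe
      lobe_b[, 1] <- ax + 11.4 + lobe_b[, 1]
      jitter <- withr::with_seed(seed,
        matrix(stats::rnorm(3L * (2L * n + 2L), sd = noise), ncol = 3L))
      rbind(lobe, linker, lobe_b) + jitter
    })
  n_res <- nrow(xyz)
  out <- list(
    residues = data.frame(chain = "A", resno = seq_len(n_res),
                          insert = "", resid = "ALA",
                          stringsAsFactors = FALSE),
    ca = list(unname(as.matrix(xyz))), atoms = NULL, axyz = NULL,
    source = sprintf("synthetic:%s(n=%d,seed=%d)", kind, n, seed))
  class(out) <- "protein_structure"
  out
}

#' Generate a synthetic MSA with planted covarying column pairs
#'
#' Background columns draw each symbol independently: the column's
#' consensus amino acid with probability `conservation`, otherwise
#' uniformly one of the remaining 19. Each planted pair instead draws
#' jointly: with probability `strength` the two columns take one of two
#' fixed covarying symbol combinations (picked 50/50), otherwise both
#' fall back to independent background draws. At strength 1 the pair is
#' perfectly correlated and its mutual information approaches 1 bit.
#' The first row is the consensus sequence (id `"ref"`) and serves as
#' the reference.
#'
#' @param n_seqs Number of sequences (including the reference row).
#' @param n_cols Number of alignment columns.
#' @param planted_pairs Data.frame with columns `col_a`, `col_b`,
#'   `strength` (in \[0, 1\]); planted columns must be disjoint.
#' @param conservation Per-column probability of the consensus symbol
#'   (default 0.7).
#' @param seed Integer seed.
#' @return An `msa` object.
#' @export
make_msa <- function(n_seqs, n_cols, planted_pairs = NULL,
                     conservation = 0.7, seed = 1L) {
  stopifnot(n_seqs >= 2L, n_cols >= 2L)
  if (!is.null(planted_pairs) && nrow(planted_pairs) > 0L) {
    pcols <- c(planted_pairs$col_a, planted_pairs$col_b)
    if (anyDuplicated(pcols)) stop("planted pairs must use disjoint columns")
    if (any(pcols < 1L | pcols > n_cols)) stop("planted column out of range")
  }
  withr::with_seed(seed, {
    consensus <- sample(20L, n_cols, replace = TRUE)
    draw_background <- function(col, m) {
      hit <- stats::runif(m) < conservation
      other <- sample(20L, m, replace = TRUE)
      # resample collisions with the consensus onto the other 19 symbols
      coll <- !hit & other == consensus[col]
      while (any(coll)) {
        other[coll] <- sample(20L, sum(coll), replace = TRUE)
        coll <- !hit & other == consensus[col]
      }
      ifelse(hit, consensus[col], other)
    }
    m <- matrix(0L, n_seqs - 1L, n_cols)
    for (col in seq_len(n_cols)) m[, col] <- draw_background(col, n_seqs - 1L)
    if (!is.null(planted_pairs) && nrow(planted_pairs) > 0L) {
      for (r in seq_len(nrow(planted_pairs))) {
        a <- planted_pairs$col_a[r]
        b <- planted_pairs$col_b[r]
        s <- planted_pairs$strength[r]
        xa <- consensus[a]
        xb <- consensus[b]
        # second combo: different symbol at both columns
        ya <- sample(setdiff(seq_len(20L), xa), 1L)
        yb <- sample(setdiff(seq_len(20L), xb), 1L)
        co <- stats::runif(n_seqs - 1L) < s
        pick1 <- stats::runif(n_seqs - 1L) < 0.5
        m[co & pick1, a] <- xa; m[co & pick1, b] <- xb
        m[co & !pick1, a] <- ya; m[co & !pick1, b] <- yb
      }
    }
    m <- rbind(consensus, m)
    seqs <- apply(m, 1L, function(row) paste(AA20[row], collapse = ""))
    names(seqs) <- c("ref", paste0("seq", seq_len(n_seqs - 1L)))
    msa_from_sequences(seqs, reference_id = "ref")
  })
}

#' Generate a synthetic per-mutation fitness table
#'
#' For every classified position of an ICDC table, draws
#' `n_subs_per_position` fitness records from the Gaussian configured
#' for that position's category; categories flagged `two_tailed` flip
#' the sign of the mean per record, yielding a widened, symmetric
#' distribution with unmoved center (the signature expected of
#' function-altering sites).
#'
#' @param icdc An `icdc_table`.
#' @param effects Named list over the four categories `"(1,1)"`,
#'   `"(1,0)"`, `"(0,1)"`, `"(0,0)"`, each a list with `mean`, `sd`
#'   and optional `two_tailed` flag.
#' @param n_subs_per_position Records per position.
#' @param seed Integer seed.
#' @return A `fitness_table`.
#' @export
make_fitness_table <- function(icdc, effects, n_subs_per_position = 5L,
                               seed = 1L) {
  cats <- c("(1,1)", "(1,0)", "(0,1)", "(0,0)")
  if (!all(cats %in% names(effects)))
    stop("effects must be given for all four categories")
  if (n_subs_per_position > 19L)
    stop("at most 19 substitutions per position (20 amino acids minus wt)")
  rows <- icdc[icdc$category %in% cats, , drop = FALSE]
  withr::with_seed(seed, {
    recs <- lapply(seq_len(nrow(rows)), function(k) {
      eff <- effects[[rows$category[k]]]
      nn <- n_subs_per_position
      mu <- rep(eff$mean, nn)
      if (isTRUE(eff$two_tailed))
        mu <- mu * sample(c(-1, 1), nn, replace = TRUE)
      subs <- sample(setdiff(AA20, "A"), nn)
      data.frame(position = rows$residue[k], wt = "A", sub = subs,
                 value = stats::rnorm(nn, mean = mu, sd = eff$sd),
                 source = "dms", stringsAsFactors = FALSE)
    })
    as_fitness_table(do.call(rbind, recs))
  })
}

#' Generate a multi-model ensemble with planted hydrogen-bond edges
#'
#' Builds a minimal heavy-atom ensemble in which each requested residue
#' pair shares a donor-acceptor contact (N...O at 2.9 Angstrom) in
#' exactly `round(occupancy * n_models)` models (seeded selection) and
#' sits far beyond bonding distance otherwise. Every residue carries
#' backbone N, CA, O and OXT atoms; residues are numbered 10, 20, 30,
#' ... so that planted edges are never covalently adjacent. Each
#' residue can accept at most two planted edges per side (its O and
#' OXT slots).
#'
#' @param n_models Number of models.
#' @param planted_edges Data.frame with columns `i`, `j` (residue
#'   indices, `i != j`) and `occupancy` in (0, 1].
#' @param n_residues Total residue count (default: largest index used).
#' @param seed Integer seed.
#' @return A multi-model `protein_structure` with heavy atoms.
#' @export
make_hbond_ensemble <- function(n_models, planted_edges, n_residues = NULL,
                                seed = 1L) {
  stopifnot(n_models >= 1L, nrow(planted_edges) >= 1L)
  if (any(planted_edges$occupancy <= 0 | planted_edges$occupancy > 1))
    stop("occupancies must lie in (0, 1]")
  if (is.null(n_residues))
    n_residues <- max(planted_edges$i, planted_edges$j)

  # atom layout: N, CA, O, OXT per residue; residue r based at x = 25(r-1)
  base <- function(r) c(25 * (r - 1L), 0, 0)
  offs <- rbind(N = c(0, 0, 0), CA = c(1.0, 1.2, 0),
                O = c(2.0, 0, 0), OXT = c(2.0, -1.2, 0))
  atoms <- data.frame(
    chain = "A", resno = rep(10L * seq_len(n_residues), each = 4L),
    insert = "", resid = "ALA",
    elety = rep(rownames(offs), n_residues),
    elesy = rep(c("N", "C", "O", "O"), n_residues),
    res_index = rep(seq_len(n_residues), each = 4L),
    stringsAsFactors = FALSE)
  base_xyz <- do.call(rbind, lapply(seq_len(n_residues), function(r)
    sweep(offs, 2L, base(r), "+")))
  rownames(base_xyz) <- NULL

  # assign each edge a donor N and a free acceptor slot (O, then OXT)
  slot_used <- matrix(FALSE, n_residues, 2L)  # columns: O, OXT
  alloc <- lapply(seq_len(nrow(planted_edges)), function(k) {
    i <- planted_edges$i[k]; j <- planted_edges$j[k]
    if (i == j) stop("self-edge planted at residue ", i)
    for (cand in list(c(i, j), c(j, i))) {
      free <- which(!slot_used[cand[2], ])
      if (length(free)) {
        slot_used[cand[2], free[1]] <<- TRUE
        return(list(donor = cand[1], acceptor = cand[2],
                    slot = c("O", "OXT")[free[1]]))
      }
    }
    stop("acceptor slots exhausted for edge ", i, "-", j)
  })

  active <- withr::with_seed(seed, lapply(seq_len(nrow(planted_edges)),
    function(k) {
      n_on <- round(planted_edges$occupancy[k] * n_models)
      sort(sample.int(n_models, n_on))
    }))

  axyz <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    xyz <- base_xyz
    for (k in seq_len(nrow(planted_edges))) {
      if (!(m %in% active[[k]])) next
      a <- alloc[[k]]
      th <- 2 * pi * k / max(8L, nrow(planted_edges) + 1L)
      dir <- c(0.2, cos(th), sin(th))
      dir <- dir / sqrt(sum(dir^2))
      arow <- which(atoms$res_index == a$acceptor & atoms$elety == a$slot)
      drow <- which(atoms$res_index == a$donor & atoms$elety == "N")
      xyz[arow, ] <- xyz[drow, ] + 2.9 * dir
    }
    axyz[[m]] <- xyz
  }
  ca_rows <- which(atoms$elety == "CA")
  out <- list(
    residues = data.frame(chain = "A", resno = 10L * seq_len(n_residues),
                          insert = "", resid = "ALA",
                          stringsAsFactors = FALSE),
    ca = lapply(axyz, function(x) x[ca_rows, , drop = FALSE]),
    atoms = atoms, axyz = axyz,
    source = sprintf("synthetic:hbond-ensemble(models=%d,seed=%d)",
                     n_models, seed))
  class(out) <- "protein_structure"
  out
}

#' Write a structure (synthetic or parsed) as a PDB file
#'
#' Emits fixed-width ATOM records, wrapping multi-model ensembles in
#' MODEL/ENDMDL blocks, so that generated fixtures round-trip through
#' [read_structure()]. Calpha-only structures are written as CA traces.
#'
#' @param structure A `protein_structure`.
#' @param path Output PDB path.
#' @export
write_structure_pdb <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  multi <- (if (is.null(structure$atoms)) length(structure$ca)
            else length(structure$axyz)) > 1L
  n_models <- if (is.null(structure$atoms)) length(structure$ca)
              else length(structure$axyz)
  for (m in seq_len(n_models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    if (is.null(structure$atoms)) {
      res <- structure$residues
      xyz <- structure$ca[[m]]
      lines <- sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        seq_len(nrow(res)), "CA", res$resid, res$chain, res$resno,
        ifelse(res$insert == "", " ", res$insert),
        xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, "C")
    } else {
      at <- structure$atoms
      xyz <- structure$axyz[[m]]
      lines <- sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        seq_len(nrow(at)), at$elety, at$resid, at$chain, at$resno,
        ifelse(at$insert == "", " ", at$insert),
        xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$elesy)
    }
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a fitness table as CSV
#' @param table A `fitness_table`.
#' @param path Output CSV path.
#' @export
write_fitness_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
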