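#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults. Unknown
#' keys in a supplied configuration are rejected.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    cutoff = 13, gamma = 1, null_modes = 6L, directions = "default",
    dfi_rigid = 0.2, dfi_flex = 0.7, dci = 0.7, coevo = 0.6,
    classify_mode = "strict",
    pseudocount = 0.5, identity_threshold = 0.8, min_effective = 5,
    coupling_method = "max", msa_offset = 0L,
    min_weighted_freq = 0.05, binding_min_identity = 0.75,
    neutral_lo = -0.1, neutral_hi = 0.1, direction_mode = "higher",
    d_max = 3.5, angle_min = 120, min_occupancy = 0.1, max_length = 6L,
    seed = 1L
  )
}

#' Merge a user configuration into the defaults
#' @param config Named list (possibly partial).
#' @return Full configuration list.
#' @export
resolve_config <- function(config = list()) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(base, config)
}

#' Read a plain-text key = value configuration file
#' @param path File with `key = value` lines; `#` comments allowed.
#' @return Named list (values parsed as numbers where possible).
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  parsed <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(parsed) <- keys
  parsed
}

#' Write a fully resolved configuration
#' @param config Full configuration list.
#' @param path Output file.
#' @param extra Optional named character vector appended as comments
#'   (e.g. input checksums).
#' @export
write_config_file <- function(config, path, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(extra)) writeLines(paste0("# ", names(extra), ": ", extra), con)
  writeLines(paste(names(config), "=",
                   vapply(config, function(v) paste(format(v), collapse = ","),
                          "")), con)
  invisible(path)
}

#' Run the full classification pipeline
#'
#' Chains the dynamics arm (kernel, perturbation response scanning,
#' DFI, DCI) and the co-evolution arm (sequence weights, mutual
#' information, average-product correction, rank normalization) and
#' classifies every non-binding-site position. Alignment columns are
#' tied to residues through the MSA column map and the structure's
#' author residue numbering.
#'
#' @param structure A `protein_structure`.
#' @param msa An `msa` whose column map uses the structure's residue
#'   numbers.
#' @param binding_keys Binding-site residues: `chain:resno` tokens or
#'   residue indices.
#' @param kernel Optional precomputed `response_kernel` (e.g. from
#'   [load_covariance()]); built from the structure's elastic network
#'   when `NULL`.
#' @param config Partial configuration list (see [default_config()]).
#' @return List with `dfi`, `dci`, `responses`, `coupling`,
#'   `coevo_scores`, `icdc`, `binding`, `config`.
#' @export
icdc_pipeline <- function(structure, msa, binding_keys, kernel = NULL,
                          config = list()) {
  cfg <- resolve_config(config)
  binding <- resolve_residues(structure, binding_keys)

  if (is.null(kernel)) {
    hess <- build_hessian(structure, cutoff = cfg$cutoff, gamma = cfg$gamma)
    kernel <- invert_kernel(hess, null_modes = cfg$null_modes)
  }
  dirs <- if (identical(cfg$directions, "default")) force_directions()
          else force_directions(k = as.integer(cfg$directions),
                                seed = cfg$seed)
  responses <- scan_responses(kernel, dirs)
  dfi <- compute_dfi(responses)
  dci <- compute_dci(responses, binding)

  weights <- compute_weights(msa, identity_threshold = cfg$identity_threshold)
  coupling <- compute_mi(msa, weights, pseudocount = cfg$pseudocount,
                         min_effective = cfg$min_effective)
  coupling <- normalize_coupling(apc_correct(coupling))

  resno <- structure$residues$resno
  col_of_res <- match(resno, msa$column_map)
  site_cols <- col_of_res[binding]
  if (anyNA(site_cols)) {
    warning(sum(is.na(site_cols)),
            " binding residue(s) without a mapped MSA column")
    site_cols <- site_cols[!is.na(site_cols)]
  }
  if (length(site_cols) == 0L)
    stop("no binding residue maps to an alignment column")
  per_col <- coupling_to_site(coupling, site_cols,
                              method = cfg$coupling_method)
  coevo_scores <- ifelse(is.na(col_of_res), NA_real_, per_col[col_of_res])

  icdc <- classify_icdc(dfi, dci, coevo_scores, binding,
                        thresholds = list(dfi_rigid = cfg$dfi_rigid,
                                          dfi_flex = cfg$dfi_flex,
                                          dci = cfg$dci,
                                          coevo = cfg$coevo),
                        mode = cfg$classify_mode)
  list(dfi = dfi, dci = dci, responses = responses, coupling = coupling,
       coevo_scores = coevo_scores, icdc = icdc, binding = binding,
       config = cfg)
}
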