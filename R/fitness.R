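#' Read a per-mutation fitness table
#'
#' CSV with columns `position`, `wt`, `sub`, `value` and optionally
#' `source` (`dms`, `docking`, `other`). Duplicate
#' (position, substitution) records and non-finite values are rejected.
#'
#' @param path CSV file.
#' @return A data.frame of class `fitness_table`.
#' @export
read_fitness_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("position", "wt", "sub", "value")
  if (!all(need %in% names(df)))
    stop("fitness table must have columns: ", paste(need, collapse = ", "))
  if (!"source" %in% names(df)) df$source <- "other"
  as_fitness_table(df)
}

#' Validate a data.frame as a fitness table
#' @param df Data.frame with `position`, `wt`, `sub`, `value`
#'   (and optional `source`) columns.
#' @return The validated `fitness_table`.
#' @export
as_fitness_table <- function(df) {
  if (!"source" %in% names(df)) df$source <- "other"
  if (any(!is.finite(df$value))) stop("non-finite fitness values")
  key <- paste(df$position, df$sub)
  if (anyDuplicated(key))
    stop("duplicate (position, substitution) records: ",
         paste(utils::head(unique(key[duplicated(key)]), 5L), collapse = ", "))
  class(df) <- c("fitness_table", "data.frame")
  df
}

#' Stratify fitness records by ICDC category
#'
#' Assigns each mutation record the category of its position and
#' summarizes the per-category value distributions. Records at
#' binding-site or unclassified positions are skipped with a logged
#' count. The neutral band brackets values considered
#' functionally silent.
#'
#' @param table A `fitness_table`.
#' @param icdc An `icdc_table` whose `residue` indices are position
#'   numbers matching `table$position` (pass `positions` to remap).
#' @param neutral_band Length-2 numeric `c(lo, hi)` (default
#'   `c(-0.1, 0.1)` on a relative-fitness scale).
#' @param per_position_mean Average records within a position before
#'   pooling (default FALSE: one value per substitution).
#' @param positions Optional vector mapping `icdc$residue` indices to
#'   the position numbering used in `table` (default: identity).
#' @return An object of class `category_distributions`: list with
#'   `values` (named list per category), `summary` (data.frame: `n`,
#'   `median`, `mean`, `iqr`, `frac_above`, `frac_below`),
#'   `neutral_band` and `skipped` counts.
#' @export
stratify <- function(table, icdc, neutral_band = c(-0.1, 0.1),
                     per_position_mean = FALSE, positions = NULL) {
  stopifnot(length(neutral_band) == 2L, neutral_band[1] <= neutral_band[2])
  pos <- if (is.null(positions)) icdc$residue else positions
  cat_of <- icdc$category[match(table$position, pos)]
  known <- !is.na(cat_of) & cat_of != "unclassified"
  n_skip_missing <- sum(is.na(cat_of))
  n_skip_uncl <- sum(!is.na(cat_of) & cat_of == "unclassified")
  if (!any(known))
    stop("no fitness records at classified positions")
  if (n_skip_missing + n_skip_uncl > 0L)
    message("skipped ", n_skip_missing, " record(s) at positions absent ",
            "from the table and ", n_skip_uncl, " at unclassified positions")

  df <- table[known, , drop = FALSE]
  df$category <- cat_of[known]
  if (per_position_mean) {
    agg <- stats::aggregate(value ~ position + category, df, mean)
    df <- agg
  }
  cats <- c("(1,1)", "(1,0)", "(0,1)", "(0,0)")
  cats <- c(cats[cats %in% df$category],
            setdiff(sort(unique(df$category)), cats))
  values <- lapply(cats, function(cc) df$value[df$category == cc])
  names(values) <- cats
  summary <- do.call(rbind, lapply(cats, function(cc) {
    v <- values[[cc]]
    data.frame(category = cc, n = length(v), median = stats::median(v),
               mean = mean(v), iqr = stats::IQR(v),
               frac_above = mean(v > neutral_band[2]),
               frac_below = mean(v < neutral_band[1]),
               stringsAsFactors = FALSE)
  }))
  out <- list(values = values, summary = summary,
              neutral_band = neutral_band,
              skipped = c(missing = n_skip_missing,
                          unclassified = n_skip_uncl))
  class(out) <- "category_distributions"
  out
}

#' @export
print.category_distributions <- function(x, ...) {
  cat("category_distributions (neutral band [",
      x$neutral_band[1], ", ", x$neutral_band[2], "])\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare two category distributions
#'
#' Two-sided Mann-Whitney U test between the value distributions of
#' two categories: exact enumeration for small tie-free samples (both
#' groups at most 20), tie-corrected normal approximation otherwise.
#' The effect size is the rank-biserial correlation
#' `2U/(n1 n2) - 1`.
#'
#' @param dist A `category_distributions`.
#' @param pair Character vector of two category labels, e.g.
#'   `c("(1,1)", "(0,0)")`.
#' @param on `"values"` compares the raw values; `"dispersion"`
#'   compares absolute deviations from the neutral-band midpoint
#'   (detects two-tailed effects that leave the median unmoved).
#' @return List with `statistic` (U), `p_value`, `effect`.
#' @export
compare_categories <- function(dist, pair, on = c("values", "dispersion")) {
  on <- match.arg(on)
  stopifnot(length(pair) == 2L)
  miss <- setdiff(pair, names(dist$values))
  if (length(miss)) stop("category not present: ", paste(miss, collapse = ", "))
  x <- dist$values[[pair[1]]]
  y <- dist$values[[pair[2]]]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 records in each category")
  if (on == "dispersion") {
    mid <- mean(dist$neutral_band)
    x <- abs(x - mid)
    y <- abs(y - mid)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 20L && length(y) <= 20L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = !exact))
  U <- unname(ht$statistic)
  list(statistic = U, p_value = ht$p.value,
       effect = 2 * U / (length(x) * length(y)) - 1)
}

#' Fraction of mutations beyond the neutral band
#'
#' Fraction of a category's records strictly better than the edge of
#' the neutral band: above `neutral_hi` when higher values mean better
#' function (fitness convention), below it when lower values are
#' better (docking-score convention).
#'
#' @param dist A `category_distributions`.
#' @param category Category label.
#' @param neutral_hi Edge of the neutral band in the favorable
#'   direction (default: the stored band's favorable edge).
#' @param direction `"higher"` (fitness) or `"lower"` (docking).
#' @return Fraction in \[0, 1\].
#' @export
enhancing_fraction <- function(dist, category, neutral_hi = NULL,
                               direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (!category %in% names(dist$values))
    stop("category not present: ", category)
  v <- dist$values[[category]]
  if (is.null(neutral_hi))
    neutral_hi <- if (direction == "higher") dist$neutral_band[2] else
      dist$neutral_band[1]
  if (direction == "higher") mean(v > neutral_hi) else mean(v < neutral_hi)
}
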