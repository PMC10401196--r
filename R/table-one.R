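#' Chi-square test with Yates continuity correction for 2x2 tables
#'
#' The correction subtracts 0.5 from each |O - E| but is floored so it never
#' exceeds |O - E| (the statistic can therefore reach exactly 0 for tables
#' with proportional margins). This is the convention used for the 2x2 rows
#' of conventional baseline-characteristics tables.
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @return list with \code{statistic}, \code{df} (= 1), \code{p},
#'   \code{statistic_printed} (rounded as conventionally tabulated:
#'   successive half-up rounding to two decimals and then one; values below
#'   0.05 keep two decimals).
#' @export
yates_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop_fmt("yates_chi_square needs a 2x2 table")
  if (any(tab < 0)) stop_fmt("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_fmt("zero row/column margin")
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  adj <- pmax(abs(tab - e) - 0.5, 0)   # floored correction
  stat <- sum(adj^2 / e)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, df = 1L, p = p,
       statistic_printed = print_chisq(stat))
}

#' Pearson chi-square test for r x c tables (no correction)
#'
#' @param tab r x c matrix of nonnegative counts; all expected counts must be
#'   positive.
#' @return list with \code{statistic}, \code{df}, \code{p},
#'   \code{statistic_printed}.
#' @export
pearson_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(dim(tab) < 2L)) stop_fmt("need at least a 2x2 table")
  if (any(tab < 0)) stop_fmt("counts must be nonnegative")
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(e <= 0)) stop_fmt("zero expected cell count")
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p, statistic_printed = print_chisq(stat))
}

## Reported precision convention of clinical baseline tables: successive
## half-up rounding — two decimals first, then one (so 5.2467 -> 5.25 -> 5.3);
## values below 0.05 keep two decimals.
round_half_up <- function(x, digits) floor(x * 10^digits + 0.5) / 10^digits
print_chisq <- function(stat) {
  two <- round_half_up(stat, 2)
  if (stat < 0.05) two else round_half_up(two, 1)
}

#' Baseline-characteristics table with chi-square tests
#'
#' Pools persons across sites, cross-tabulates each characteristic against
#' the binary outcome, and tests each row: binary (single-covariate)
#' characteristics with the continuity-corrected 2x2 chi-square, multi-level
#' characteristics (a set of mutually exclusive indicator covariates) with
#' the uncorrected Pearson test. Percentages are within-group (column)
#' percentages, as conventional for a "table one".
#'
#' @param site_data list of \code{site_dataset} objects (pooled), or one.
#' @param characteristics named list; each element is either a single
#'   covariate id (binary row) or a character vector of covariate ids
#'   (levels of one multi-level row). A bare character vector is treated as
#'   all-binary.
#' @param alpha significance threshold for the flag column (default .05).
#' @return data.frame with one row per characteristic (or per level):
#'   counts and percentages per outcome group, chi-square statistic, df,
#'   p-value and significance flag.
#' @export
build_table_one <- function(site_data, characteristics, alpha = 0.05) {
  if (inherits(site_data, "site_dataset")) site_data <- list(site_data)
  stopifnot(length(site_data) >= 1)
  if (is.character(characteristics))
    characteristics <- stats::setNames(as.list(characteristics), characteristics)
  empty <- data.frame(characteristic = character(), level = character(),
                      control_n = numeric(), control_pct = numeric(),
                      case_n = numeric(), case_pct = numeric(),
                      statistic = numeric(), df = integer(), p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (!length(characteristics)) return(empty)
  all_cols <- unique(unlist(characteristics, use.names = FALSE))
  for (ch in all_cols) {
    found <- any(vapply(site_data, function(s) ch %in% colnames(s$features), TRUE))
    if (!found) stop_fmt("characteristic covariate '%s' not found in any site", ch)
  }
  ## pooled carrier counts per group
  n1 <- sum(vapply(site_data, function(s) sum(s$labels == 1), 0))
  n0 <- sum(vapply(site_data, function(s) sum(s$labels == 0), 0))
  carriers <- function(col) {
    v1 <- 0; v0 <- 0
    for (s in site_data) {
      if (!(col %in% colnames(s$features))) next
      x <- as.numeric(s$features[, col]) != 0
      v1 <- v1 + sum(x & s$labels == 1)
      v0 <- v0 + sum(x & s$labels == 0)
    }
    c(case = v1, control = v0)
  }
  rows <- list()
  for (nm in names(characteristics)) {
    ids <- characteristics[[nm]]
    if (length(ids) == 1L) {
      cc <- carriers(ids)
      tab <- matrix(c(cc["control"], n0 - cc["control"],
                      cc["case"], n1 - cc["case"]), nrow = 2,
                    dimnames = list(c("with", "without"), c("control", "case")))
      ts <- yates_chi_square(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = nm, level = nm,
        control_n = unname(cc["control"]),
        control_pct = 100 * cc[["control"]] / n0,
        case_n = unname(cc["case"]),
        case_pct = 100 * cc[["case"]] / n1,
        statistic = ts$statistic, df = ts$df, p = ts$p,
        significant = ts$p < alpha, stringsAsFactors = FALSE)
    } else {
      cc <- vapply(ids, carriers, c(case = 0, control = 0))
      tab <- t(cc)[, c("control", "case"), drop = FALSE]
      ts <- pearson_chi_square(tab)
      for (k in seq_along(ids)) {
        rows[[length(rows) + 1L]] <- data.frame(
          characteristic = nm, level = ids[k],
          control_n = tab[k, "control"],
          control_pct = 100 * tab[k, "control"] / n0,
          case_n = tab[k, "case"],
          case_pct = 100 * tab[k, "case"] / n1,
          statistic = if (k == 1) ts$statistic else NA_real_,
          df = if (k == 1) ts$df else NA_integer_,
          p = if (k == 1) ts$p else NA_real_,
          significant = if (k == 1) ts$p < alpha else NA, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a baseline table to TSV
#'
#' @param table_one output of \code{\link{build_table_one}}.
#' @param path file path.
#' @export
write_table_one <- function(table_one, path) {
  utils::write.table(table_one, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
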