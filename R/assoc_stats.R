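# Exact and asymptotic tests for carrier count tables: two-tailed Fisher
# exact test via hypergeometric probability mass, and Pearson chi-square
# for r x c category tables.

#' Two-tailed Fisher exact test (probability-mass convention)
#'
#' Conditional on both margins of a 2x2 table, the top-left cell follows a
#' hypergeometric distribution. The two-tailed p-value is the sum of the
#' point probabilities of all tables with the same margins whose point
#' probability does not exceed that of the observed table (with a relative
#' tolerance of `1 + 1e-7` for floating-point ties). Point probabilities
#' are computed in log space via `lchoose`, so margins in the thousands do
#' not overflow.
#'
#' Degenerate tables with an empty row or column admit only one table and
#' give p = 1.
#'
#' @param x A 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(a, b, c, d)` read row-wise.
#' @return An object of class `htest` with `p.value`, plus
#'   `p.value.one.sided` (the smaller one-tailed p) as an extra element.
#' @examples
#' fisher_exact_two_tailed(build_burden_table(10, 916, 1, 973))$p.value
#' @export
fisher_exact_two_tailed <- function(x) {
  m <- as_2x2(x)
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  if (n < 1) stop("table total must be >= 1")
  ks <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  l_obs <- lp[ks == a]
  p <- sum(exp(lp[lp <= l_obs + log1p(1e-7)]))
  p <- min(1, p)
  lower <- sum(exp(lp[ks <= a]))
  upper <- sum(exp(lp[ks >= a]))
  structure(list(
    statistic = NULL, parameter = NULL,
    p.value = p,
    p.value.one.sided = min(1, lower, upper),
    method = "Two-tailed Fisher exact test (hypergeometric probability mass)",
    data.name = deparse(substitute(x)),
    observed = m
  ), class = "htest")
}

as_2x2 <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) stop("x must be a 2x2 table")
    m <- x
  } else if (is.numeric(x) && length(x) == 4L) {
    m <- matrix(x, nrow = 2L, byrow = TRUE)
  } else {
    stop("x must be a 2x2 matrix or a length-4 count vector")
  }
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("all cells must be non-negative integers")
  }
  storage.mode(m) <- "double"
  m
}

#' Pearson chi-square test for an r x c category table
#'
#' Statistic `sum((obs - exp)^2 / exp)` with expected counts from the
#' margin products over the grand total; `df = (r - 1)(c - 1)`; p-value
#' from the upper tail of the chi-square distribution. No continuity
#' correction is applied.
#'
#' @param x Matrix of non-negative counts with at least 2 rows and 2
#'   columns. All-zero rows/columns (which make an expected count zero)
#'   raise an error advising a category merge.
#' @return An object of class `htest` with `statistic`, `parameter` (df)
#'   and `p.value`.
#' @examples
#' chi_square_pearson(rbind(c(12, 5), c(3, 14)))
#' @export
chi_square_pearson <- function(x) {
  m <- as.matrix(x)
  if (any(is.na(m)) || any(m < 0)) stop("all cells must be non-negative")
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need at least a 2x2 table")
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) {
    stop("expected cell count of zero (all-zero row or column); ",
         "merge sparse categories before testing")
  }
  expected <- outer(rs, cs) / n
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  structure(list(
    statistic = c("X-squared" = stat),
    parameter = c(df = df),
    p.value = stats::pchisq(stat, df, lower.tail = FALSE),
    method = "Pearson chi-square test (no continuity correction)",
    data.name = deparse(substitute(x)),
    observed = m, expected = expected
  ), class = "htest")
}

#' Parse a semicolon/comma table string into a count matrix
#'
#' `"10,906;1,972"` becomes `rbind(c(10, 906), c(1, 972))`. Used by the
#' command-line `stats` subcommand.
#'
#' @param s Table string; `;` separates rows, `,` separates cells.
#' @return Numeric matrix.
#' @export
parse_table_string <- function(s) {
  rows <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  cells <- lapply(rows, function(r) {
    suppressWarnings(as.numeric(strsplit(r, ",")[[1]]))
  })
  len <- unique(lengths(cells))
  if (length(len) != 1L) stop("ragged table string: rows differ in length")
  if (anyNA(unlist(cells))) stop("non-numeric cell in table string")
  do.call(rbind, cells)
}

#' JSON-ready representation of a test result
#'
#' @param res An `htest` from [fisher_exact_two_tailed()] or
#'   [chi_square_pearson()].
#' @return Named list with `test`, `statistic`, `df`, `p_value`.
#' @export
test_result_json <- function(res) {
  list(
    test = res$method,
    statistic = if (is.null(res$statistic)) NULL else unname(res$statistic),
    df = if (is.null(res$parameter)) NULL else unname(res$parameter),
    p_value = res$p.value
  )
}
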