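#' Build a 2x2 exposure-by-outcome table for a before/after comparison
#'
#' Group 1 is the post period and group 2 the pre period within one site
#' (and an optional stratum such as "HA-AKI cases only"); cells are exact
#' tallies of a binary outcome.
#'
#' @param rows Cohort rows (need `period` plus the outcome column).
#' @param outcome Name of a logical column on `rows`.
#' @param site Optional site value to filter on (`rows$site`).
#' @param stratum Optional logical vector (aligned with `rows` *before* site
#'   filtering) or a function of the data returning one.
#' @return Object of class `two_by_two`: list with counts `a` (post events),
#'   `b` (post non-events), `c` (pre events), `d` (pre non-events) and
#'   labels. An all-empty selection is flagged via `empty = TRUE`.
#' @examples
#' rows <- data.frame(period = rep(c("pre", "post"), c(4, 4)),
#'                    died = c(TRUE, TRUE, FALSE, FALSE,
#'                             TRUE, FALSE, FALSE, FALSE))
#' build_two_by_two(rows, "died")
#' @export
build_two_by_two <- function(rows, outcome, site = NULL, stratum = NULL) {
  d <- as.data.frame(rows)
  if (is.function(stratum)) stratum <- stratum(d)
  if (!is.null(stratum)) d <- d[which(stratum), , drop = FALSE]
  if (!is.null(site)) d <- d[d$site == site, , drop = FALSE]
  y <- d[[outcome]]
  if (!is.logical(y)) stop("outcome must be a logical column", call. = FALSE)
  post <- d$period == "post"
  t <- list(a = sum(y & post, na.rm = TRUE),
            b = sum(!y & post, na.rm = TRUE),
            c = sum(y & !post, na.rm = TRUE),
            d = sum(!y & !post, na.rm = TRUE),
            outcome = outcome, site = if (is.null(site)) "all" else site,
            group1 = "post", group2 = "pre")
  t$empty <- (t$a + t$b + t$c + t$d) == 0
  structure(t, class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c(x$group1, x$group2),
                              c("event", "no event")))
  cat(sprintf("%s, site %s:\n", x$outcome, x$site))
  print(m)
  invisible(x)
}

.cells <- function(t, correct = FALSE) {
  cells <- c(t$a, t$b, t$c, t$d)
  if (all(cells == 0)) stop("all-zero 2x2 table", call. = FALSE)
  if (correct && any(cells == 0)) cells <- cells + 0.5  # Haldane-Anscombe
  cells
}

#' Odds ratio of a 2x2 table
#'
#' `(a/b) / (c/d)`. When any cell is zero the Haldane-Anscombe correction
#' (0.5 added to every cell) is applied and flagged via the
#' `"corrected"` attribute.
#'
#' @param t A [build_two_by_two()] table (or list with `a`,`b`,`c`,`d`).
#' @return Positive numeric odds ratio.
#' @examples
#' odds_ratio(list(a = 132, b = 477, c = 156, d = 412))  # 0.731
#' @export
odds_ratio <- function(t) {
  cells <- .cells(t, correct = TRUE)
  structure((cells[1] / cells[2]) / (cells[3] / cells[4]),
            corrected = any(c(t$a, t$b, t$c, t$d) == 0))
}

#' Woolf confidence interval for a 2x2 odds ratio
#'
#' The asymptotic log-odds-ratio interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, which always contains
#' the point estimate and shrinks as the cells scale up.
#'
#' @param t A 2x2 table as for [odds_ratio()].
#' @param level Confidence level (default 0.95).
#' @return Numeric length 2: lower and upper bound.
#' @examples
#' woolf_ci(list(a = 132, b = 477, c = 156, d = 412))  # 0.560 0.954
#' @export
woolf_ci <- function(t, level = 0.95) {
  cells <- .cells(t, correct = TRUE)
  lo <- log((cells[1] / cells[2]) / (cells[3] / cells[4]))
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - level) / 2)
  exp(lo + c(-1, 1) * z * se)
}

#' Pearson chi-square p-value for a 2x2 table
#'
#' Without continuity correction by default (the study cells are large
#' throughout); set `correct = TRUE` for Yates.
#'
#' @param t A 2x2 table.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return Two-sided p-value, or `NA` with a message for degenerate margins.
#' @export
chi2_p <- function(t, correct = FALSE) {
  m <- matrix(c(t$a, t$b, t$c, t$d), 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(NA_real_)
  suppressWarnings(stats::chisq.test(m, correct = correct)$p.value)
}

#' Cochran-Mantel-Haenszel test across 2x2 strata
#'
#' Common-odds-ratio chi-square over a list of 2x2 tables without continuity
#' correction: with per-stratum cells (a, b, c, d) and total n, the statistic
#' is `(sum a - sum E)^2 / sum V` with hypergeometric mean
#' `E = (a+b)(a+c)/n` and variance `V = (a+b)(c+d)(a+c)(b+d)/(n^2 (n-1))` on
#' one degree of freedom, and the Mantel-Haenszel common odds ratio is
#' `sum(ad/n) / sum(bc/n)`. With a single stratum this is that table's
#' Mantel-Haenszel chi-square (base `mantelhaen.test` agrees for two or more
#' strata but rejects single-stratum arrays, so the statistic is computed in
#' closed form here).
#'
#' @param strata List of 2x2 tables ([build_two_by_two()] or `a`-`d` lists);
#'   strata with a zero margin are dropped.
#' @return List with `statistic`, `p_value`, `common_or`, `n_strata`.
#' @export
cmh_test <- function(strata) {
  usable <- Filter(function(t) {
    m <- matrix(c(t$a, t$b, t$c, t$d), 2, byrow = TRUE)
    !any(rowSums(m) == 0) && !any(colSums(m) == 0)
  }, strata)
  if (!length(usable)) stop("no stratum with non-zero margins", call. = FALSE)
  cells <- vapply(usable, function(t) as.numeric(c(t$a, t$b, t$c, t$d)),
                  numeric(4))
  a <- cells[1, ]; b <- cells[2, ]; cc <- cells[3, ]; d <- cells[4, ]
  n <- a + b + cc + d
  ex <- (a + b) * (a + cc) / n
  v <- (a + b) * (cc + d) * (a + cc) * (b + d) / (n^2 * (n - 1))
  stat <- (sum(a) - sum(ex))^2 / sum(v)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       common_or = sum(a * d / n) / sum(b * cc / n),
       n_strata = length(usable))
}

#' Compare two continuous samples
#'
#' Two-sided t-test or Mann-Whitney U (Wilcoxon rank-sum with the normal
#' approximation and no continuity correction, so identical samples give
#' p = 1 under ties).
#'
#' @param x,y Numeric samples (non-empty; t-test needs n >= 2 in each).
#' @param method "t" or "mann_whitney".
#' @return Two-sided p-value.
#' @export
compare_continuous <- function(x, y, method = c("t", "mann_whitney")) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("samples must be non-empty", call. = FALSE)
  if (method == "t") {
    if (length(x) < 2 || length(y) < 2) {
      stop("t-test needs at least two observations per sample", call. = FALSE)
    }
    stats::t.test(x, y)$p.value
  } else {
    suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
  }
}
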