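## Group comparison: Mann-Whitney U with exact small-sample p-values,
## significance stars, and mean +/- SD group summaries.

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The U statistic is
#' computed from midranks; the p-value is exact (doubling the smaller
#' tail mass, capped at 1) whenever the combined sample size is at most
#' 16 and there are no ties, and otherwise uses the normal approximation
#' with tie and continuity corrections (via [stats::wilcox.test()]). A
#' degenerate comparison with zero rank variance reports p = 1.
#'
#' @param a,b numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exactLimit largest combined sample size for which the exact
#'   p-value is enumerated.
#' @return a `GroupComparison` list: `U`, `p`, `method` (`"exact"` or
#'   `"normal_approx"`), `n1`, `n2`, `alternative`, `stars`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(a, b, alternative = c("two.sided", "less",
                                               "greater"),
                         exactLimit = 16) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("samples must be finite")
  n1 <- length(a); n2 <- length(b)
  rk <- rank(c(a, b))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (n1 + n2) <= exactLimit
  p <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE)$p.value)
  if (!is.finite(p)) p <- 1
  structure(list(U = U, p = p,
                 method = if (exact) "exact" else "normal_approx",
                 n1 = n1, n2 = n2, alternative = alternative,
                 stars = starAnnotation(p)),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s, %s): U = %g, n = (%d, %d), p = %.4g %s\n",
              x$method, x$alternative, x$U, x$n1, x$n2, x$p, x$stars))
  invisible(x)
}

#' Significance star annotation
#'
#' The printed convention: `***` for p < 0.001, `**` for
#' 0.001 <= p < 0.01, otherwise `ns`. A `*` band for
#' 0.01 <= p < 0.05 is available via `includeSingleStar`.
#'
#' @param p p-value(s) in (0, 1].
#' @param includeSingleStar add the `*` band.
#' @return character vector of annotations.
#' @examples
#' starAnnotation(c(0.0005, 0.005, 0.5))
#' @export
starAnnotation <- function(p, includeSingleStar = FALSE) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("'p' must lie in (0, 1]")
  out <- ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(includeSingleStar & p < 0.05, "*", "ns")))
  out
}

#' Mean and standard deviation per group
#'
#' @param groups named list of numeric per-embryo value vectors.
#' @return `data.frame`: `group`, `n`, `mean`, `sd` (sample SD, n - 1
#'   denominator; `NA` for single-value groups).
#' @examples
#' summarizeGroups(list(DMSO = c(2, 4), treated = c(1, 1, 1)))
#' @export
summarizeGroups <- function(groups) {
  if (!is.list(groups) || length(groups) == 0 || is.null(names(groups)))
    stop("'groups' must be a non-empty named list")
  if (any(vapply(groups, length, integer(1)) < 1))
    stop("every group needs at least one value")
  data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, function(v)
      if (length(v) > 1) stats::sd(v) else NA_real_, numeric(1)),
    row.names = NULL)
}
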