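#' Kruskal-Wallis rank test across groups
#'
#' Omnibus comparison of two or more groups on mid-ranks with the standard
#' tie correction `1 - sum(t^3 - t) / (N^3 - N)` and a chi-square
#' approximation for the p-value with `k - 1` degrees of freedom. The H
#' statistic and p-value are computed by [stats::kruskal.test()]; the tie
#' correction factor, which that function applies but does not report, is
#' returned alongside.
#'
#' @param groups A list of two or more non-empty numeric vectors.
#' @return A list of class `kruskal_wallis`: `h_statistic`, `df`,
#'   `p_value`, `tie_correction`, `n`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("kruskal_wallis needs at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1L)) == 0L))
    stop("every group must be non-empty", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups),
                  vapply(groups, length, integer(1L))))
  n <- length(x)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (length(unique(x)) == 1L) {
    # fully tied data carry no rank information: no separation
    return(structure(
      list(h_statistic = 0, df = length(groups) - 1L, p_value = 1,
           tie_correction = tie_corr, n = n),
      class = "kruskal_wallis"))
  }
  kt <- stats::kruskal.test(x, g)
  structure(
    list(h_statistic = unname(kt$statistic),
         df = unname(kt$parameter),
         p_value = unname(kt$p.value),
         tie_correction = tie_corr,
         n = n),
    class = "kruskal_wallis"
  )
}

#' @export
print.kruskal_wallis <- function(x, ...) {
  cat("Kruskal-Wallis rank test\n")
  cat(sprintf("  H = %.4f, df = %d, p = %.4g (tie correction %.4f, N = %d)\n",
              x$h_statistic, x$df, x$p_value, x$tie_correction, x$n))
  invisible(x)
}

#' Least significant delta (confidence-interval half-width)
#'
#' The half-width of the normal-approximation confidence interval of a
#' group's mean daily iron intake, `z * sd / sqrt(n)`. A scenario-induced
#' increase of the group mean larger than this half-width is significant
#' at one-sided p < 0.025 for the default `z = 1.96`.
#'
#' @param sd Sample standard deviation of the group's intake, mg/day.
#' @param n Group size (>= 2).
#' @param z Normal quantile; default 1.96 (95% two-sided interval). A t
#'   quantile may be substituted.
#' @return Half-width in mg/day (vectorised over `sd`/`n`).
#' @export
#' @examples
#' least_significant_delta(4.1, 346)  # ~0.43
least_significant_delta <- function(sd, n, z = 1.96) {
  if (any(n < 2))
    stop("least_significant_delta needs n >= 2", call. = FALSE)
  if (any(sd < 0))
    stop("sd must be >= 0", call. = FALSE)
  z * sd / sqrt(n)
}

#' Is an intake increase significant?
#'
#' Strict rule: a delta is significant if and only if it is larger than
#' the group's confidence-interval half-width.
#'
#' @param delta Mean intake increase, mg/day.
#' @param half_width The group's [least_significant_delta()], mg/day.
#' @return Logical (vectorised).
#' @export
flag_significant <- function(delta, half_width) {
  if (any(!is.finite(delta)) || any(!is.finite(half_width)))
    stop("delta and half_width must be finite", call. = FALSE)
  delta > half_width
}
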