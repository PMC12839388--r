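## Irradiated-vs-control group comparisons.  Default: two-sided rank-sum
## test, with exact small-sample p-values by full enumeration of group
## assignments when both groups have at most 10 values, and the normal
## approximation otherwise.  Stars follow the strict-inequality map
## p < 0.05 -> *, p < 0.01 -> **, p < 0.001 -> ****, else n.s.

#' Map a p-value to a significance annotation
#'
#' Boundary values map to the weaker category (strict inequalities).
#'
#' @param p p-value in [0, 1]
#' @return one of `"****"`, `"**"`, `"*"`, `"n.s."`
#' @export
significance_annotation <- function(p) {
  check_num(p, "p", lower = 0, upper = 1)
  if (p < 0.001) "****" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "n.s."
}

#' @noRd
ranksum_exact_p <- function(a, b) {
  # two-sided exact permutation p for the rank-sum statistic (midranks)
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  sel <- utils::combn(n1 + n2, n1)
  w_all <- colSums(matrix(r[sel], nrow = n1))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

#' Compare two groups of per-nucleus summary values
#'
#' @param values_a,values_b numeric vectors (>= 3 values each for the
#'   default method)
#' @param method `"ranksum"` (two-sided; exact enumeration when both
#'   groups have <= 10 values, normal approximation otherwise) or
#'   `"t"` (Welch)
#' @param labels length-2 character vector of group names
#' @return a `group_comparison`: list with `labels`, `n`, `medians`,
#'   `statistic`, `p_value`, `annotation`, `method`
#' @export
compare_groups <- function(values_a, values_b,
                           method = c("ranksum", "t"),
                           labels = c("A", "B")) {
  method <- match.arg(method)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 3L || length(values_b) < 3L)
    stopf("need at least 3 finite values per group (got %d and %d)",
          length(values_a), length(values_b))
  if (method == "ranksum") {
    r <- rank(c(values_a, values_b))
    w <- sum(r[seq_along(values_a)])
    if (max(length(values_a), length(values_b)) <= 10L) {
      p <- ranksum_exact_p(values_a, values_b)
      flavor <- "exact permutation"
    } else {
      wt <- suppressWarnings(
        wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE))
      p <- wt$p.value
      flavor <- "normal approximation"
    }
    stat <- w
  } else {
    tt <- stats::t.test(values_a, values_b)
    stat <- unname(tt$statistic)
    p <- tt$p.value
    flavor <- "Welch"
  }
  structure(list(labels = labels,
                 n = c(length(values_a), length(values_b)),
                 medians = c(median(values_a), median(values_b)),
                 statistic = stat, p_value = p,
                 annotation = significance_annotation(p),
                 method = paste0(method, " (", flavor, ")")),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "%s (n=%d, median %.3g) vs %s (n=%d, median %.3g): p = %.4g [%s], %s\n",
    x$labels[1L], x$n[1L], x$medians[1L], x$labels[2L], x$n[2L],
    x$medians[2L], x$p_value, x$method, x$annotation))
  invisible(x)
}
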