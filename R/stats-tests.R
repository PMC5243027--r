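#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on paired differences, reported with the
#' convention `W = min(W+, W-)` so smaller statistics mean stronger
#' evidence. Zero differences are dropped. The p value is exact (full
#' enumeration over sign patterns) for n up to 12 without ties among the
#' absolute differences, and a continuity-corrected normal approximation
#' otherwise.
#'
#' @param x,y paired numeric vectors.
#' @return List of class `attractor_test` with `statistic` (W), `p_value`,
#'   `n` (non-zero pairs) and `test_name`.
#' @examples
#' wilcoxon_signed_rank(c(1.2, 2.1, 3.3, 2.8, 4.4), c(1.0, 1.5, 2.0, 2.2, 3.0))
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("samples must be paired", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero", call. = FALSE)
  if (n < 5) stop("need at least 5 non-zero paired differences", call. = FALSE)
  ranks <- rank(abs(d))
  w_plus <- sum(ranks[d > 0])
  w <- min(w_plus, n * (n + 1) / 2 - w_plus)
  ties <- any(duplicated(abs(d)))
  res <- suppressWarnings(
    wilcox.test(x = d, mu = 0, exact = n <= 12 && !ties, correct = TRUE))
  structure(list(statistic = w, p_value = res$p.value, n = n,
                 test_name = "wilcoxon_signed_rank"),
            class = c("attractor_test", "list"))
}

#' Mann-Whitney U test for two independent samples
#'
#' Two-sided rank-sum test reported as the U statistic for the first sample
#' (number of pairwise wins, midranks for ties). Exact for small untied
#' samples, tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric samples.
#' @return List of class `attractor_test` with `statistic` (U), `p_value`,
#'   `n` (the two sample sizes) and `test_name`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty", call. = FALSE)
  res <- suppressWarnings(wilcox.test(a, b, exact = NULL, correct = TRUE))
  structure(list(statistic = unname(res$statistic), p_value = res$p.value,
                 n = c(length(a), length(b)),
                 test_name = "mann_whitney_u"),
            class = c("attractor_test", "list"))
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way F test across independent groups.
#'
#' @param groups list of numeric samples, one per group.
#' @return List of class `attractor_test` with `statistic` (F), `df`
#'   (between, within), `p_value`, `n` (group sizes) and `test_name`.
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 values", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (var(values) == 0) stop("zero total variance", call. = FALSE)
  labels <- factor(rep(seq_along(groups), sizes))
  fit <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  structure(list(statistic = unname(fit$statistic),
                 df = unname(c(fit$parameter[1], fit$parameter[2])),
                 p_value = fit$p.value,
                 n = as.integer(sizes),
                 test_name = "anova_oneway"),
            class = c("attractor_test", "list"))
}

#' @export
print.attractor_test <- function(x, ...) {
  cat("<", x$test_name, "> statistic = ", format(x$statistic),
      if (!is.null(x$df)) paste0(", df = (", paste(x$df, collapse = ", "), ")"),
      ", p = ", format.pval(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}
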