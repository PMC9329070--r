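#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Two-sided rank-sum test between two independent samples. For small pooled
#' sizes (`n1 + n2 <= exact_threshold`, default 12) the null distribution is
#' enumerated completely over all `choose(n1+n2, n1)` group assignments of
#' the observed (possibly tied) data, using mid-ranks; the p-value is the
#' proportion of assignments whose U statistic is at least as far from its
#' null mean `n1*n2/2` as the observed one. This is exact under the
#' permutation null even with ties, where the classical normal approximation
#' is poor. Larger samples use the normal approximation with tie correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param mode `"auto"` (exact when small, default), `"exact"` (force
#'   enumeration), or `"normal"`.
#' @param exact_threshold Maximum pooled size for enumeration in auto mode.
#' @return A `pah_htest` list: `statistic` (U for `x`), `p_value`, `n1`,
#'   `n2`, `method` (`"MANN_WHITNEY_EXACT"` or `"MANN_WHITNEY_NORMAL"`).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p_value  # 2/6
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal"),
                         exact_threshold = 12) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)  # mid-ranks for ties
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  exact <- switch(mode, exact = TRUE, normal = FALSE,
                  auto = (n1 + n2) <= exact_threshold)
  if (exact) {
    mu <- n1 * n2 / 2
    offset <- n1 * (n1 + 1) / 2
    assignments <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[assignments], nrow = n1)) - offset
    # ranks are multiples of 1/2, so these comparisons are exact in binary
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu))
    method <- "MANN_WHITNEY_EXACT"
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    p <- wt$p.value
    method <- "MANN_WHITNEY_NORMAL"
  }
  structure(list(statistic = u_obs, p_value = p, n1 = n1, n2 = n2,
                 method = method),
            class = "pah_htest")
}

#' Two-sample t test (paired or Welch)
#'
#' Thin wrapper around [stats::t.test()] with explicit degenerate-input
#' handling: paired comparisons whose differences have zero variance (and
#' unpaired comparisons where both samples are constant) raise an error
#' rather than returning an undefined statistic.
#'
#' @param x,y Numeric samples. Paired tests require equal lengths >= 2;
#'   unpaired (Welch, unequal variances) requires each length >= 2.
#' @param paired Logical (default `FALSE`).
#' @return A `pah_htest` list with `statistic` (t), `p_value`, `df`, `n1`,
#'   `n2` and `method` (`"T_PAIRED"` or `"T_WELCH"`).
#' @export
t_test <- function(x, y, paired = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (paired) {
    if (length(x) != length(y)) {
      stop("paired test requires equal sample sizes", call. = FALSE)
    }
    if (length(x) < 2L) stop("need >= 2 pairs", call. = FALSE)
    if (stats::sd(x - y) == 0) {
      stop("degenerate input: paired differences have zero variance",
           call. = FALSE)
    }
  } else {
    if (length(x) < 2L || length(y) < 2L) {
      stop("need >= 2 observations per group", call. = FALSE)
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      stop("degenerate input: both samples are constant", call. = FALSE)
    }
  }
  tt <- stats::t.test(x, y, paired = paired, var.equal = FALSE)
  structure(list(statistic = unname(tt$statistic),
                 p_value = tt$p.value, df = unname(tt$parameter),
                 n1 = length(x), n2 = length(y),
                 method = if (paired) "T_PAIRED" else "T_WELCH"),
            class = "pah_htest")
}

#' @export
print.pah_htest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Signed fold change
#'
#' Symmetric fold-change convention (as popularised by gtools): `num/denom`
#' when `num >= denom`, otherwise `-denom/num`, so the magnitude is always
#' >= 1 and `fold_change(a, b) == -fold_change(b, a)` whenever `a != b`.
#'
#' @param num,denom Strictly positive values (vectorised).
#' @return Signed fold change(s).
#' @examples
#' fold_change(25.6, 3.7)  # ~6.92
#' fold_change(2, 4)       # -2
#' @export
fold_change <- function(num, denom) {
  if (any(num <= 0) || any(denom <= 0)) {
    stop("fold change undefined for non-positive values", call. = FALSE)
  }
  ifelse(num >= denom, num / denom, -denom / num)
}
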