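## The paired comparison framework: Shapiro-Wilk normality gate,
## Kruskal-Wallis omnibus, one-sided Wilcoxon signed-rank post hoc with
## Benjamini-Hochberg adjustment, and median-of-differences tables.
##
## The normality gate is advisory only: the nonparametric tests always
## run. The signed-rank test is implemented here (exact tail by dynamic
## programming over sign assignments for small n, normal approximation
## with tie correction and continuity correction otherwise) because the
## exact one-sided branch is part of the benchmark's contract; the gate
## and omnibus wrap the standard stats:: implementations.

#' Shapiro-Wilk normality gate for paired differences
#'
#' @param differences numeric vector, `n >= 3`, not all identical.
#' @return list with `W`, `p`, and `is_normal` (`p >= 0.05`).
#' @export
normality_gate <- function(differences) {
  if (length(differences) < 3L) stop("normality gate needs n >= 3")
  if (length(unique(differences)) == 1L) stop("zero-variance differences")
  sw <- shapiro.test(differences)
  list(W = unname(sw$statistic), p = sw$p.value,
       is_normal = sw$p.value >= 0.05)
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H with a chi-square reference on `k - 1` degrees of
#' freedom.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("kruskal_wallis needs at least two groups")
  }
  if (any(lengths(groups) == 0L)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kw <- suppressWarnings(stats::kruskal.test(x, g))
  list(H = unname(kw$statistic), p = kw$p.value,
       df = unname(kw$parameter))
}

# Exact tail P(W+ >= w) of the signed-rank statistic for the given
# absolute-value ranks (average ranks under ties), by convolution over
# the 2^n sign assignments. Ranks are doubled to keep the distribution
# support integral in the presence of .5 ties.
signed_rank_exact_tail <- function(ranks, w_obs) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1L)  # index i-1 = doubled statistic value
  dist[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), dist[seq_len(total + 1L - r)])
    dist <- (dist + shifted) / 2
  }
  w2 <- 2 * w_obs
  # >= with a small epsilon so half-integer observed values round safely
  sum(dist[(seq_along(dist) - 1L) >= w2 - 1e-9])
}

#' One-sided Wilcoxon signed-rank test for paired samples
#'
#' Tests `median(x - y) > 0` (`alternative = "greater"`). Zero
#' differences are discarded before ranking (the classic treatment).
#' The p value is exact — full enumeration of sign assignments via
#' dynamic programming — when the number of non-zero pairs is at most
#' `exact_max`; otherwise a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param x,y numeric vectors of equal length.
#' @param alternative only `"greater"` is provided; flip arguments for
#'   the other direction.
#' @param exact_max largest n for the exact branch (default 25).
#' @return list with `W` (sum of positive-difference ranks), `p`, `n`
#'   (non-zero pairs), `exact` (logical), `all_zero` (logical).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, alternative = "greater",
                                 exact_max = 25L) {
  alternative <- match.arg(alternative, "greater")
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("x and y must have equal length")
    x - y
  }
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(W = 0, p = 1, n = 0L, exact = TRUE, all_zero = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_tail(r, W)
    return(list(W = W, p = p, n = n, exact = TRUE, all_zero = FALSE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - 0.5) / sqrt(sigma2)  # continuity correction
  list(W = W, p = pnorm(z, lower.tail = FALSE), n = n,
       exact = FALSE, all_zero = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; the output is in
#' the input order.
#'
#' @param p_values numeric vector of raw p values in `[0, 1]`.
#' @return adjusted p values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' All pairwise method comparisons for one metric
#'
#' The benchmark's Table-style comparison: a Kruskal-Wallis omnibus over
#' methods, then for each unordered method pair the per-sample paired
#' differences, their median (reported in percentage points), a
#' one-sided Wilcoxon signed-rank test in the direction of the median,
#' and Benjamini-Hochberg adjustment across all pairs of the metric
#' (one FDR family per metric table). A Shapiro-Wilk gate on each
#' pair's differences is logged in the output but does not alter the
#' testing path.
#'
#' @param metric_table data.frame with columns `sample_id`, `method`,
#'   and the metric column named by `metric_name`; every (sample,
#'   method) cell must be present.
#' @param metric_name name of the metric column (e.g. `"mcc"`).
#' @return list with `omnibus` (from [kruskal_wallis()]) and `pairs`, a
#'   data.frame with `metric_name`, `method_a`, `method_b`, `n_pairs`,
#'   `median_difference` (pp., a minus b), `direction`, `shapiro_p`,
#'   `p_raw`, `p_adjusted`.
#' @export
compare_all <- function(metric_table, metric_name) {
  req <- c("sample_id", "method", metric_name)
  if (!all(req %in% names(metric_table))) {
    stop("metric table needs columns: ", paste(req, collapse = ", "))
  }
  methods <- sort(unique(metric_table$method))
  samples <- sort(unique(metric_table$sample_id))
  wide <- matrix(NA_real_, length(samples), length(methods),
                 dimnames = list(samples, methods))
  wide[cbind(match(metric_table$sample_id, samples),
             match(metric_table$method, methods))] <-
    metric_table[[metric_name]]
  if (anyNA(wide)) {
    holes <- which(is.na(wide), arr.ind = TRUE)
    stop("missing (sample, method) cells: ",
         paste(paste(samples[holes[, 1]], methods[holes[, 2]], sep = "/"),
               collapse = ", "))
  }
  omnibus <- kruskal_wallis(lapply(methods, function(m) wide[, m]))
  pr <- combn(methods, 2, simplify = FALSE)
  rows <- lapply(pr, function(p) {
    d <- wide[, p[1]] - wide[, p[2]]
    med <- median(d)
    test <- if (med >= 0) wilcoxon_signed_rank(wide[, p[1]], wide[, p[2]])
            else wilcoxon_signed_rank(wide[, p[2]], wide[, p[1]])
    sw_p <- if (length(d) >= 3 && length(unique(d)) > 1) {
      normality_gate(d)$p
    } else NA_real_
    data.frame(
      metric_name = metric_name, method_a = p[1], method_b = p[2],
      n_pairs = length(d), median_difference = med * 100,
      direction = if (med >= 0) "a-greater" else "b-greater",
      shapiro_p = sw_p, p_raw = test$p,
      stringsAsFactors = FALSE
    )
  })
  pairs <- do.call(rbind, rows)
  pairs$p_adjusted <- bh_adjust(pairs$p_raw)
  list(omnibus = omnibus, pairs = pairs)
}
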