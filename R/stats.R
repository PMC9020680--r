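#' Reconstruct a count from a published rate and group size
#'
#' Published summary tables often print a complication rate in percent
#' together with the group size but not the underlying count. The count is
#' recovered as `round(rate_percent/100 * n)`. When the product is farther
#' than `tol` from an integer the reconstruction is ambiguous (two counts
#' round to the same printed rate) and a warning is raised.
#'
#' @param rate_percent published rate(s) in percent, in `[0, 100]`.
#' @param n group size(s), positive integers.
#' @param tol ambiguity tolerance on the distance to the nearest integer.
#' @return integer vector of reconstructed counts.
#' @export
#' @examples
#' reconstruct_count(2.37, 1011)  # 24
#' reconstruct_count(c(3.61, 0.76), c(83, 1316))  # 3, 10
reconstruct_count <- function(rate_percent, n, tol = 0.1) {
  stopifnot(all(rate_percent >= 0), all(rate_percent <= 100), all(n >= 1))
  x <- rate_percent / 100 * n
  k <- as.integer(round(x))
  off <- abs(x - k)
  if (any(off > tol))
    warning("ambiguous count reconstruction (off by ",
            paste(signif(off[off > tol], 3), collapse = ", "),
            " from an integer)", call. = FALSE)
  k
}

#' Construct a 2x2 complication table
#'
#' Counts for one stratum comparison: `x1` complications among `n1`
#' procedures in group 1 versus `x2` among `n2` in group 2. Group 1 is the
#' group whose proportion enters the signed difference first (e.g. the
#' prophylaxis or the infected stratum).
#'
#' @param x1,n1 complications and procedures in group 1.
#' @param x2,n2 complications and procedures in group 2.
#' @param labels character pair naming the two groups.
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(x1, n1, x2, n2,
                       labels = c("group1", "group2")) {
  x1 <- as.integer(x1); n1 <- as.integer(n1)
  x2 <- as.integer(x2); n2 <- as.integer(n2)
  stopifnot(length(labels) == 2, n1 >= 1, n2 >= 1,
            x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  structure(list(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
                 labels = as.character(labels)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("2x2 complication table: %s vs %s\n",
              x$labels[1], x$labels[2]))
  cat(sprintf("  %-12s %d/%d (%.2f%%)\n", x$labels[1], x$x1, x$n1,
              100 * x$x1 / x$n1))
  cat(sprintf("  %-12s %d/%d (%.2f%%)\n", x$labels[2], x$x2, x$n2,
              100 * x$x2 / x$n2))
  invisible(x)
}

#' Observed difference in complication proportions
#'
#' The test statistic: `x1/n1 - x2/n2`, signed, group 1 minus group 2.
#'
#' @param t a [two_by_two()] table.
#' @return numeric scalar.
#' @export
observed_diff <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  t$x1 / t$n1 - t$x2 / t$n2
}

#' Exact upper-tail p-value of the permutation null
#'
#' Under permutation of the pooled complication labels across the two
#' groups with group sizes fixed, the group-1 complication count follows a
#' hypergeometric distribution with population `n1 + n2`, `x1 + x2`
#' successes, and `n1` draws. The permutation p-value of the signed
#' difference, upper tail with ties included, is therefore
#' `P(X >= k*)` where `k*` is the smallest count in group 1 whose implied
#' difference is at least the observed difference. The tail is computed by
#' direct summation of the hypergeometric mass over the support.
#'
#' @param t a [two_by_two()] table.
#' @return exact p-value in `[0, 1]`.
#' @export
exact_p <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  K <- t$x1 + t$x2
  N <- t$n1 + t$n2
  support <- max(0L, K - t$n2):min(K, t$n1)
  d_obs <- observed_diff(t)
  diffs <- support / t$n1 - (K - support) / t$n2
  in_tail <- diffs >= d_obs - 1e-12
  if (!any(in_tail)) return(0)
  kstar <- min(support[in_tail])
  sum(dhyper(kstar:max(support), K, N - K, t$n1))
}

#' One-sided Monte-Carlo randomization test for two proportions
#'
#' Tests whether the complication proportion in group 1 exceeds that in
#' group 2 by permuting the pooled complication outcomes across the two
#' groups. The test statistic is the signed difference in proportions,
#' `x1/n1 - x2/n2`. The empirical null is built from `B` independent
#' permutations of the `x1 + x2` complications among the `n1 + n2`
#' procedures (group sizes fixed), and the p-value is the proportion of
#' permuted differences as large as or larger than the observed
#' difference (upper tail, ties included).
#'
#' Two permutation mechanics are provided. `"count"` (default) draws the
#' group-1 complication count per replicate from the hypergeometric null —
#' exactly the permutation distribution, at a fraction of the cost.
#' `"shuffle"` literally permutes the 0/1 outcome vector and is retained
#' as an audit mode; both agree in distribution. The raw proportion `b/B`
#' is the default p-value estimator; `estimator = "add_one"` uses
#' `(b + 1)/(B + 1)`, which cannot be exactly zero.
#'
#' @param t a [two_by_two()] table.
#' @param B number of permutations (default 50000).
#' @param seed integer seed recorded in the result; when `NULL` one is
#'   drawn and recorded. The global RNG state is restored on exit.
#' @param method permutation mechanics, `"count"` or `"shuffle"`.
#' @param estimator `"raw"` for `b/B`, `"add_one"` for `(b+1)/(B+1)`.
#' @param alpha significance level annotated on the result.
#' @param keep_null keep the vector of permuted differences (needed by the
#'   plot method).
#' @return object of class `rand_test`: observed difference `d_obs`, the
#'   Monte-Carlo p-value `p_mc` with standard error `mc_se`
#'   (`sqrt(p_mc (1 - p_mc)/B)`), the exact hypergeometric tail `p_exact`,
#'   `B`, `seed`, `alpha`, group proportions, and (optionally) the null
#'   sample.
#' @seealso [exact_p()] for the analytic oracle, [run_comparisons()] to
#'   apply a comparison plan to a tally.
#' @export
#' @examples
#' t <- two_by_two(3, 83, 10, 1316, c("prophylaxis", "none"))
#' randomization_test(t, B = 10000, seed = 1)
randomization_test <- function(t, B = 50000L, seed = NULL,
                               method = c("count", "shuffle"),
                               estimator = c("raw", "add_one"),
                               alpha = 0.05, keep_null = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  B <- as.integer(B)
  if (is.na(B) || B < 1) stop("B must be a positive integer", call. = FALSE)
  method <- match.arg(method)
  estimator <- match.arg(estimator)

  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(list = ".Random.seed", envir = globalenv())))
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  set.seed(seed)

  K <- t$x1 + t$x2
  N <- t$n1 + t$n2
  d_obs <- observed_diff(t)

  if (method == "count") {
    a <- rhyper(B, K, N - K, t$n1)
  } else {
    pool <- c(rep(1L, K), rep(0L, N - K))
    a <- vapply(seq_len(B), function(i) sum(sample(pool, t$n1)), integer(1))
  }
  d_perm <- a / t$n1 - (K - a) / t$n2
  b <- sum(d_perm >= d_obs - 1e-12)
  p_mc <- if (estimator == "raw") b / B else (b + 1) / (B + 1)

  res <- list(
    table = t,
    d_obs = d_obs,
    p1 = t$x1 / t$n1,
    p2 = t$x2 / t$n2,
    B = B,
    p_mc = p_mc,
    mc_se = sqrt(p_mc * (1 - p_mc) / B),
    p_exact = exact_p(t),
    seed = as.integer(seed),
    alpha = alpha,
    method = method,
    estimator = estimator,
    null_dist = if (keep_null) d_perm else NULL
  )
  class(res) <- "rand_test"
  res
}

#' @export
print.rand_test <- function(x, digits = 3, ...) {
  cat("One-sided randomization test for two proportions\n")
  cat(sprintf("  %s: %.2f%% (%d/%d)   %s: %.2f%% (%d/%d)\n",
              x$table$labels[1], 100 * x$p1, x$table$x1, x$table$n1,
              x$table$labels[2], 100 * x$p2, x$table$x2, x$table$n2))
  star <- if (x$p_mc < x$alpha) " *" else ""
  cat(sprintf("  observed difference = %.5f\n", x$d_obs))
  cat(sprintf("  p = %.*f (B = %s permutations, MC se = %.2g)%s\n",
              digits, x$p_mc, format(x$B, big.mark = ","), x$mc_se, star))
  invisible(x)
}

#' @export
summary.rand_test <- function(object, ...) {
  out <- data.frame(
    group1 = object$table$labels[1],
    group2 = object$table$labels[2],
    x1 = object$table$x1, n1 = object$table$n1,
    x2 = object$table$x2, n2 = object$table$n2,
    d_obs = object$d_obs,
    B = object$B,
    p_mc = object$p_mc,
    mc_se = object$mc_se,
    p_exact = object$p_exact,
    seed = object$seed,
    significant = object$p_mc < object$alpha,
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary.rand_test", "data.frame")
  out
}

#' @export
coef.rand_test <- function(object, ...) {
  c(p1 = object$p1, p2 = object$p2, diff = object$d_obs)
}

#' Draw from the permutation null of a fitted randomization test
#'
#' @param object a `rand_test` object.
#' @param nsim number of null differences to draw.
#' @param seed optional seed.
#' @param ... unused.
#' @return numeric vector of `nsim` permuted differences.
#' @export
simulate.rand_test <- function(object, nsim = 1, seed = NULL, ...) {
  t <- object$table
  K <- t$x1 + t$x2
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(seed)
  }
  a <- rhyper(nsim, K, t$n1 + t$n2 - K, t$n1)
  a / t$n1 - (K - a) / t$n2
}

#' Plot the empirical null of a randomization test
#'
#' Histogram of the permuted differences with the observed difference
#' marked; the shaded tail is the Monte-Carlo p-value. Requires the test
#' to have been run with `keep_null = TRUE` (otherwise a fresh null sample
#' is drawn with the recorded seed).
#'
#' @param x a `rand_test` object.
#' @param ... passed to [graphics::hist()].
#' @export
plot.rand_test <- function(x, ...) {
  d <- x$null_dist
  if (is.null(d)) d <- simulate(x, nsim = x$B, seed = x$seed)
  h <- graphics::hist(d, breaks = 50, plot = FALSE)
  graphics::plot(h, freq = FALSE, col = "grey85", border = "grey60",
                 main = "Permutation null of difference in proportions",
                 xlab = sprintf("difference (%s - %s)",
                                x$table$labels[1], x$table$labels[2]), ...)
  graphics::abline(v = x$d_obs, col = "firebrick", lwd = 2)
  graphics::mtext(sprintf("observed = %.4f, p = %.3f", x$d_obs, x$p_mc),
                  side = 3, line = 0.2, cex = 0.9)
  invisible(x)
}

#' Run a plan of stratum comparisons against a tally
#'
#' Resolves each planned comparison to two strata of a tally table and
#' runs the randomization test, group 1 first. Each comparison's seed is
#' derived deterministically from `seed` so results are reproducible and
#' comparisons are independent.
#'
#' @param tallies tally data.frame from [tally_complications()].
#' @param plan list of comparisons, each a list with `name`, `stratum_a`
#'   and `stratum_b`; a stratum is a named list of column = value filters
#'   that must select exactly one tally row (group a is group 1).
#' @param B permutations per comparison.
#' @param seed master seed.
#' @param alpha significance level.
#' @return object of class `comparison_set`: a list of `rand_test` objects
#'   with a results data.frame attached.
#' @export
run_comparisons <- function(tallies, plan, B = 50000L, seed = NULL,
                            alpha = 0.05) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  pick <- function(stratum, name) {
    keep <- rep(TRUE, nrow(tallies))
    for (col in names(stratum)) {
      if (!col %in% names(tallies))
        stop("comparison '", name, "': no stratifier column '", col, "'",
             call. = FALSE)
      keep <- keep & tallies[[col]] == stratum[[col]]
    }
    row <- which(keep)
    if (length(row) != 1)
      stop("comparison '", name, "': stratum filter matches ",
           length(row), " tally rows (need exactly 1)", call. = FALSE)
    row
  }
  tests <- vector("list", length(plan))
  names(tests) <- vapply(plan, `[[`, "", "name")
  for (i in seq_along(plan)) {
    cmp <- plan[[i]]
    ra <- pick(cmp$stratum_a, cmp$name)
    rb <- pick(cmp$stratum_b, cmp$name)
    t <- two_by_two(tallies$complications[ra], tallies$procedures[ra],
                    tallies$complications[rb], tallies$procedures[rb],
                    labels = c(cmp$label_a %||% "group1",
                               cmp$label_b %||% "group2"))
    tests[[i]] <- randomization_test(t, B = B, seed = seed + i,
                                     alpha = alpha)
  }
  structure(tests, class = "comparison_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
as.data.frame.comparison_set <- function(x, ...) {
  out <- do.call(rbind, lapply(unclass(x), summary))
  out <- cbind(comparison = names(x), out)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' @export
print.comparison_set <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  cat(sprintf("%d stratum comparison(s), B = %s permutations each\n\n",
              nrow(df), format(x[[1]]$B, big.mark = ",")))
  fmt <- sprintf(
    "  %-34s %8s %8s %9s %7s\n", "comparison", "rate1", "rate2", "p", "")
  cat(fmt)
  for (i in seq_len(nrow(df))) {
    star <- if (df$significant[i]) "*" else ""
    cat(sprintf("  %-34s %7.2f%% %7.2f%% %9.*f %7s\n",
                df$comparison[i], 100 * df$x1[i] / df$n1[i],
                100 * df$x2[i] / df$n2[i], digits, df$p_mc[i], star))
  }
  invisible(x)
}
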