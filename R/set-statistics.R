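#' Exact upper-tail hypergeometric test for set overlap
#'
#' Computes the probability of observing at least `k` shared elements between
#' a draw of size `n` and a marked class of size `K` from a universe of size
#' `N`. This is the one-sided "Fisher exact test" in its enrichment
#' orientation, the convention used throughout the chaperone overlap
#' analysis: a depleted table yields a p-value near 1 rather than a small
#' two-sided p.
#'
#' The tail sum is evaluated from log-gamma binomial coefficients; whichever
#' of the two tails has fewer terms is summed and complemented, so the result
#' is accurate to near machine precision without arbitrary-precision
#' arithmetic.
#'
#' @param k observed overlap count.
#' @param n size of set A (the draw).
#' @param K size of set B (the marked class).
#' @param N universe size.
#' @return A `chap_test` object with elements `p_value`, `statistic` (the
#'   observed overlap), `tail` (always `"upper"`) and `method`.
#' @examples
#' hypergeom_upper_tail(17, 24, 46, 97)$p_value  # ~0.0076
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (any(c(k, n, K, N) < 0) || any(c(k, n, K, N) != floor(c(k, n, K, N))))
    stop("k, n, K, N must be non-negative integers")
  if (n > N || K > N) stop("set sizes n and K cannot exceed the universe N")
  if (k > min(n, K)) stop("overlap k cannot exceed min(n, K)")
  if (N - n - K + k < 0) stop("overlap k below the feasible minimum n + K - N")

  k_min <- max(0, n + K - N)
  k_max <- min(n, K)
  lden <- lchoose(N, n)
  lpmf <- function(i) lchoose(K, i) + lchoose(N - K, n - i) - lden
  logsumexp <- function(lx) {
    m <- max(lx)
    m + log(sum(exp(lx - m)))
  }
  if (k <= k_min) {
    p <- 1
  } else {
    n_upper <- k_max - k + 1
    n_lower <- k - k_min
    if (n_upper <= n_lower) {
      p <- exp(logsumexp(lpmf(k:k_max)))
    } else {
      p <- 1 - exp(logsumexp(lpmf(k_min:(k - 1))))
    }
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  chap_test(p, statistic = k, tail = "upper",
            method = "hypergeometric upper tail (one-sided Fisher)")
}

#' One-sided Fisher overlap test between two gene sets
#'
#' Builds the 2x2 contingency table for two sets over a common universe and
#' delegates to [hypergeom_upper_tail()].
#'
#' @param set_a,set_b character vectors of element ids; must be subsets of
#'   `universe`.
#' @param universe character vector, the reference universe.
#' @return list with `table` (a `chap_contingency`) and `test` (a `chap_test`).
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  universe <- unique(universe)
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stop("set elements outside the universe: ",
         paste(utils::head(c(out_a, out_b), 5), collapse = ", "))
  k <- length(intersect(set_a, set_b))
  tab <- chap_contingency(k, length(set_a), length(set_b), length(universe))
  list(table = tab, test = hypergeom_upper_tail(k, tab$n, tab$K, tab$N))
}

#' 2x2 overlap contingency table
#'
#' @param k overlap count; @param n size of set A; @param K size of set B;
#' @param N universe size.
#' @return `chap_contingency` with the four cells a = k, b = n-k, c = K-k,
#'   d = N-n-K+k.
#' @export
chap_contingency <- function(k, n, K, N) {
  cells <- c(a = k, b = n - k, c = K - k, d = N - n - K + k)
  if (any(cells < 0)) stop("invalid contingency table: negative cell count")
  structure(list(k = k, n = n, K = K, N = N, cells = cells),
            class = "chap_contingency")
}

#' @export
print.chap_contingency <- function(x, ...) {
  cat(sprintf("overlap k = %d of n = %d vs K = %d in N = %d\n",
              x$k, x$n, x$K, x$N))
  print(matrix(x$cells, 2, 2, byrow = TRUE,
               dimnames = list(c("in A", "not A"), c("in B", "not B"))))
  invisible(x)
}

chap_test <- function(p_value, statistic, tail, method, stars = NULL) {
  structure(list(p_value = p_value, statistic = statistic, tail = tail,
                 method = method, stars = stars), class = "chap_test")
}

#' @export
print.chap_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %.4g%s\n", x$method, x$statistic,
              x$p_value, if (is.null(x$stars)) "" else paste0(" ", x$stars)))
  invisible(x)
}

#' Mann-Whitney U test (exact by enumeration for small samples)
#'
#' Two-sided rank-sum test. When the combined sample size is at most
#' `exact_limit` the exact permutation null of the U statistic is computed by
#' full enumeration of rank splits (valid under ties); larger samples use the
#' normal approximation with tie and continuity corrections. Replicate counts
#' in qPCR comparisons (3-6 per arm) always take the exact route.
#'
#' @param x,y numeric vectors, each with at least 2 finite values.
#' @param exact_limit combined-size cutoff for exact enumeration (default 12).
#' @return `chap_test` with the U statistic of sample `x`.
#' @export
mann_whitney <- function(x, y, exact_limit = 12L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 finite values")
  nx <- length(x); ny <- length(y); n <- nx + ny
  comb <- c(x, y)
  r <- rank(comb)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (length(unique(comb)) == 1L) {
    warning("all values tied across both samples; p = 1")
    return(chap_test(1, statistic = u_obs, tail = "two-sided",
                     method = "Mann-Whitney (degenerate)"))
  }
  if (n <= exact_limit) {
    splits <- utils::combn(n, nx)
    u_all <- colSums(matrix(r[splits], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "Mann-Whitney exact (full enumeration)"
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "Mann-Whitney normal approximation (tie-corrected)"
  }
  chap_test(p, statistic = u_obs, tail = "two-sided", method = method,
            stars = significance_stars(p))
}

#' Significance stars as used in the figure annotations
#'
#' `*` for p < 0.05, `**` for p < 0.01, empty string otherwise.
#' @param p p-value.
#' @return character scalar.
#' @export
significance_stars <- function(p) {
  if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Venn region counts for 2 or 3 sets over a universe
#'
#' @param sets named list of 2 or 3 character vectors, all subsets of
#'   `universe`.
#' @param universe character vector.
#' @return data.frame with one row per membership pattern (including the
#'   all-outside region); `count` sums to `length(universe)`.
#' @export
venn_counts <- function(sets, universe) {
  m <- length(sets)
  if (m < 2 || m > 3) stop("venn_counts supports 2 or 3 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  universe <- unique(universe)
  bad <- unlist(lapply(sets, setdiff, y = universe))
  if (length(bad)) stop("set elements outside the universe: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  memb <- matrix(memb, ncol = m)
  patt <- expand.grid(rep(list(c(TRUE, FALSE)), m))[, m:1, drop = FALSE]
  names(patt) <- names(sets)
  patt <- patt[order(-rowSums(patt)), , drop = FALSE]
  counts <- apply(patt, 1, function(p)
    sum(colSums(t(memb) == as.logical(p)) == m))
  out <- cbind(patt, count = counts)
  rownames(out) <- NULL
  out
}
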