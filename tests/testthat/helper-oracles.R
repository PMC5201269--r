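# Independent brute-force oracles. These deliberately avoid the package's
# algorithms: subset enumeration for the hypergeometric tail, 4^w word
# enumeration for PWM p-values, pair-counting U over label assignments for
# Mann-Whitney, and plain regex for consensus scanning.

# P(overlap >= k) by enumerating all C(N, n) draws against a fixed set B.
oracle_hyper_tail <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)   # B = {1..K}
  mean(overlaps >= k)
}

# PWM score upper tail by enumerating all 4^w words. With discretize =
# TRUE column scores are rounded to the model grid exactly as the DP does,
# so the result must match the convolution to machine precision; with
# discretize = FALSE the exact (unrounded) word scores are used, which can
# differ from the DP by at most the accumulated per-column rounding, i.e.
# within one discretization bin per column.
oracle_pwm_tail <- function(model, score, bin = 1e-3, discretize = TRUE) {
  w <- model$width
  lo <- if (discretize) round(model$logodds / bin) * bin else model$logodds
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(words))
  pr <- rep(1, nrow(words))
  for (j in seq_len(w)) {
    sc <- sc + lo[cbind(words[, j], j)]
    pr <- pr * model$background[words[, j]]
  }
  sum(pr[sc >= score - bin / 2])
}

# Exact two-sided Mann-Whitney p by enumerating group assignments, with U
# computed by pair counting (not rank sums).
oracle_mw_p <- function(x, y) {
  comb <- c(x, y)
  nx <- length(x)
  n <- length(comb)
  u_of <- function(xs, ys)
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  mu <- nx * (n - nx) / 2
  u_obs <- u_of(x, y)
  splits <- utils::combn(n, nx)
  u_all <- apply(splits, 2, function(ix) u_of(comb[ix], comb[-ix]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# All consensus CANNTG start positions (0-based) by regex, one strand of a
# palindromic pattern class.
oracle_ebox_starts <- function(seq) {
  m <- gregexpr("(?=CA[ACGT][ACGT]TG)", seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m) - 1L
}

# Tiny catalog + evidence builders for unit tests.
tiny_catalog <- function(n = 6)
  chap_catalog(paste0("g", seq_len(n)))

ev <- function(name, category, genes)
  chap_evidence(name, category, genes)
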