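# Brute-force enumeration oracles for the exact rank tests. These stay
# deliberately naive (combn over rank assignments, expand.grid over sign
# patterns) and independent of the package's shift-algorithm code path.

brute_mann_whitney_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  combs <- utils::combn(length(r), n1)
  sums <- apply(combs, 2, function(i) sum(r[i]))
  robs <- sum(r[seq_len(n1)])
  lower <- mean(sums <= robs + 1e-9)
  upper <- mean(sums >= robs - 1e-9)
  min(1, 2 * min(lower, upper))
}

brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  sums <- as.numeric(signs %*% r)
  wobs <- sum(r[d > 0])
  lower <- mean(sums <= wobs + 1e-9)
  upper <- mean(sums >= wobs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# smooth positive random profile for fuzzing the overlapping index
random_profile <- function(n) {
  raw <- stats::runif(n + 4, 0.05, 1)
  as.numeric(stats::filter(raw, rep(1 / 5, 5), sides = 2))[3:(n + 2)]
}
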