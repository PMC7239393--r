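# Independent oracles, kept deliberately separate from the package's own
# code paths: direct evaluation of log-likelihood terms, exhaustive
# enumerations, and hand-rolled sums of squares.

# two-binomial likelihood-ratio statistic by direct term-by-term evaluation
oracle_lrt <- function(a1, n1, a2, n2) {
  term <- function(a, n, p) {
    out <- 0
    if (a > 0) out <- out + a * log(p)
    if (n - a > 0) out <- out + (n - a) * log(1 - p)
    out
  }
  p1 <- a1 / n1; p2 <- a2 / n2; p0 <- (a1 + a2) / (n1 + n2)
  G <- 2 * (term(a1, n1, p1) + term(a2, n2, p2) -
              term(a1, n1, p0) - term(a2, n2, p0))
  list(G = G, p = pchisq(G, 1, lower.tail = FALSE))
}

# exact two-sided rank-sum p-value by full enumeration over group labels,
# midranks for ties
oracle_wilcox <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  mu <- n1 * n2 / 2
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- combn(n1 + n2, n1)
  us <- apply(sets, 2, function(s) sum(rk[s]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# one-way ANOVA F and p from explicit sums of squares
oracle_anova <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(unlist(tapply(values, groups, function(v) (v - mean(v))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, p = pf(f, dfb, dfw, lower.tail = FALSE))
}

# junction-type counts by walking the explicit arrangement string
oracle_junctions <- function(o, r) {
  arr <- rep(c("S1", rep("S2", r), "S3"), o)
  pair <- paste(arr[-length(arr)], arr[-1], sep = "/")
  c(j12 = sum(pair == "S1/S2"), j22 = sum(pair == "S2/S2"),
    j23 = sum(pair == "S2/S3"), j31 = sum(pair == "S3/S1"))
}

# small fast config shared across tests (study-scale CNV on a 400-kb scaffold)
test_config <- function(...) sim_config(seed = 1L, ...)

# the paper-scale paralog subcohort: 10 hemizygous case females, 14 controls
paralog_config <- function(...) sim_config(seed = 1L, n_case_female = 10L,
                                           n_case_male = 0L,
                                           n_control_female = 7L,
                                           n_control_male = 7L, ...)

control_interval <- function(config)
  genomic_interval(config$scaffold, 1, config$outer$start - 1)
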