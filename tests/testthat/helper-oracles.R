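# Independent oracles used to pin expected values.

# Tail probability P(sum of independent Bernoulli >= threshold) by full
# 2^m enumeration of attendance subsets.
enum_tail <- function(beliefs, threshold) {
  m <- length(beliefs)
  if (m == 0L) return(as.numeric(threshold <= 0))
  subsets <- expand.grid(rep(list(0:1), m))
  total <- 0
  for (r in seq_len(nrow(subsets))) {
    a <- as.numeric(subsets[r, ])
    if (sum(a) >= threshold)
      total <- total + prod(ifelse(a == 1, beliefs, 1 - beliefs))
  }
  total
}

# Brute-force pure-Nash scan of the binary bar game, with the payoff rule
# written out inline (attendee gets H when total <= cap, -L otherwise;
# non-attendee gets 0).
brute_nash_binary <- function(n, cap, H, L) {
  profiles <- as.matrix(expand.grid(rep(list(0:1), n)))
  pay <- function(a_i, total) {
    if (a_i == 0) 0 else if (total <= cap) H else -L
  }
  keep <- apply(profiles, 1, function(a) {
    total <- sum(a)
    for (i in seq_len(n)) {
      flipped <- 1 - a[i]
      if (pay(flipped, total - a[i] + flipped) > pay(a[i], total)) return(FALSE)
    }
    TRUE
  })
  profiles[keep, , drop = FALSE]
}

# Short visit series for belief tests.
toy_series <- function(counts, start = "2020-01-01") {
  visit_series(as.Date(start) + seq_along(counts) - 1, counts)
}
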