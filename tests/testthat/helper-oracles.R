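# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the hypergeometric tail is an explicit lchoose()
# summation, not phyper().

# P(X >= a) for X ~ Hypergeometric(N, K, n)
hyper_tail_oracle <- function(a, K, n, N) {
  lo <- max(0L, n - (N - K))
  hi <- min(n, K)
  x <- max(a, lo):hi
  if (a > hi) return(0)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# Max |fisher_p - oracle| over every valid (N, K, n, a) with N <= n_max.
# Chunked by (N, K) so grouped cumulative sums stay small (no cancellation).
fisher_sweep_max_diff <- function(n_max = 60) {
  max_diff <- 0
  n_tables <- 0L
  for (N in 2:n_max) for (K in 0:N) {
    n <- rep(0:N, each = 1L)
    lo <- pmax(0L, n - (N - K))
    hi <- pmin(n, K)
    len <- hi - lo + 1L
    g <- rep(seq_along(n), len)
    x <- sequence(len) - 1L + lo[g]
    nn <- n[g]
    terms <- choose(K, x) * choose(N - K, nn - x) / choose(N, nn)
    # reverse-cumulative sum within contiguous groups gives P(X >= x)
    ord <- order(g, -x)
    gs <- g[ord]
    cs <- cumsum(terms[ord])
    grp_index <- cumsum(!duplicated(gs))
    grp_start <- which(!duplicated(gs))
    prefix <- c(0, cs[grp_start[-1L] - 1L])
    tail_p <- cs - prefix[grp_index]
    ours <- stats::phyper(x[ord] - 1, K, N - K, nn[ord],
                          lower.tail = FALSE)
    max_diff <- max(max_diff, abs(tail_p - ours))
    n_tables <- n_tables + length(x)
  }
  list(max_diff = max_diff, n_tables = n_tables)
}

# tiny fixed library used in several tests
tiny_library <- function() {
  microbe_set_library(list(
    microbe_set("T1", c("m1", "m2", "m3", "m4")),
    microbe_set("T2", c("m3", "m4", "m5")),
    microbe_set("T3", c("m6", "m7"))
  ), name = "tiny")
}

universe_of <- function(members, size = length(members)) {
  structure(list(members = members, size = as.integer(size)),
            class = "msea_universe")
}
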