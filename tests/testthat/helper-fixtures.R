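# Fixtures are built in code; no stored data files.

# Tiny registry from a named list of protein vectors; condition types are
# recycled unless given explicitly.
make_registry <- function(sets, types = NULL) {
  if (is.null(types)) {
    types <- rep(c("normoxia", "hypoxia", "OGD", "stroke"),
                 length.out = length(sets))
  }
  registry(tibble::tibble(
    id = names(sets),
    condition_type = types,
    proteins = unname(sets)
  ))
}

# Four datasets realizing the worked redundancy example: the intersection of
# any tuple containing ds4 (or all of ds1..ds3) is exactly {P0001}.
worked_example_registry <- function() {
  make_registry(list(
    ds1 = c("P0001", "A0001", "B0001"),
    ds2 = c("P0001", "A0001", "C0001"),
    ds3 = c("P0001", "B0001", "C0001"),
    ds4 = c("P0001", "D0001")
  ))
}

# Independent brute-force BH step-up rule: q_(i) = min_{j>=i} p_(j)*m/j,
# capped at 1, mapped back to input order. Deliberately naive (O(m^2)).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Independent brute-force upper-tail hypergeometric: enumerate every draw of
# n from M (K annotated) and count draws with overlap >= k.
hyper_oracle <- function(k, K, n, M) {
  items <- c(rep(1, K), rep(0, M - K))
  draws <- utils::combn(M, n)
  hits <- apply(draws, 2, function(ix) sum(items[ix]) >= k)
  mean(hits)
}

# Independent subset counter over the full bitmask lattice.
count_subsets <- function(n, min_size = 2, contains = integer(),
                          intersects = integer()) {
  count <- 0L
  for (mask in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < min_size) next
    if (length(contains) > 0 && !all(contains %in% members)) next
    if (length(intersects) > 0 && !any(intersects %in% members)) next
    count <- count + 1L
  }
  count
}
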