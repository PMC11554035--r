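# Brute-force matching oracle: exhaustive enumeration of maximum-cardinality
# unique (injective) annotation->detection assignments, minimising the total
# absolute sample difference. Independent of the greedy matcher: it never
# looks at nearest neighbours, it tries every assignment. Counts the optima
# so callers can restrict comparisons to instances with a unique optimum.
oracle_match <- function(a, d) {
  na <- length(a); nd <- length(d); k <- min(na, nd)
  best <- Inf; count <- 0L
  used <- rep(FALSE, nd)
  rec <- function(i, matched, cost) {
    if (cost > best) return()           # extensions only add cost
    if (i > na) {
      if (matched == k) {
        if (cost < best) { best <<- cost; count <<- 1L }
        else count <<- count + 1L       # cost == best: another optimum
      }
      return()
    }
    if (na - i >= k - matched) rec(i + 1L, matched, cost)
    for (j in seq_len(nd)) {
      if (!used[j]) {
        used[j] <<- TRUE
        rec(i + 1L, matched + 1L, cost + abs(a[i] - d[j]))
        used[j] <<- FALSE
      }
    }
  }
  rec(1L, 0L, 0)
  list(tp = k, cost = best, n_optima = count)
}

# Beat-like random matching instance: quasi-periodic annotations corrupted
# with deletions, insertions and timing jitter (jitter SD in samples).
random_instance <- function(jitter_sd_samples, insertions = TRUE) {
  na <- sample(2:8, 1)
  a <- 500 + cumsum(round(stats::rnorm(na, 250, 30)))
  keep <- stats::runif(na) >= 0.1
  d <- a[keep] + round(stats::rnorm(sum(keep), 0, jitter_sd_samples))
  if (insertions) {
    n_ins <- stats::rpois(1, 0.05 * na)
    if (n_ins > 0) {
      d <- c(d, round(stats::runif(n_ins, min(a) - 100, max(a) + 100)))
    }
  }
  list(a = a, d = sort(unique(d)))
}
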