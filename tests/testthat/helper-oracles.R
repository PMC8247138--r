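## Independent oracles and small fixtures shared across tests.

## tiny 3 ASV x 4 sample table (2 subjects x 2 days)
tinyTable <- function() {
  counts <- matrix(c(10, 5, 0,
                     8, 6, 1,
                     0, 12, 3,
                     2, 9, 4), nrow = 3,
                   dimnames = list(c("a1", "a2", "a3"),
                                   c("s1_d1", "s1_d2", "s2_d1", "s2_d2")))
  meta <- data.frame(sample_id = colnames(counts),
                     subject = c("s1", "s1", "s2", "s2"),
                     day = c(1, 100, 1, 100),
                     diet = c("FV", "FV", "FV", "FV"),
                     phase = rep("outbound", 4))
  LongitudinalASVTable(counts, meta)
}

## small synthetic design for fast tests; dots override the reduced
## defaults
smallDesign <- function(...) {
  args <- utils::modifyList(
    list(n_stable_asvs = 60, n_transient_asvs = 150,
         depth_range = c(15000, 40000)),
    list(...))
  do.call(syntheticDesign, args)
}

## unpruned optimal-partitioning oracle over the same cost/penalty as
## peltChangepoints: exhaustive over all admissible segmentations via
## dynamic programming (considers every last-changepoint position)
oracleSegmentation <- function(values, nQuantiles = NULL, minSegLen = 2) {
  n <- length(values)
  cd <- microdyn:::npCostData(values, nQuantiles)
  beta <- 4 * log(n)
  segCost <- function(s, t)
    microdyn:::npSegmentCost(cd, s, t) + log(t - s)
  F <- c(-beta, rep(Inf, n))
  prev <- integer(n + 1)
  for (t in seq_len(n)) {
    if (t < minSegLen) next
    for (s in c(0, seq_len(t - minSegLen))) {
      if (s > 0 && s < minSegLen) next
      v <- F[s + 1] + segCost(s, t) + beta
      if (v < F[t + 1]) { F[t + 1] <- v; prev[t + 1] <- s }
    }
  }
  cps <- integer(); t <- n
  while (t > 0) { s <- prev[t + 1]; if (s > 0) cps <- c(s, cps); t <- s }
  structure(as.integer(cps), objective = F[n + 1])
}

## brute-force enumeration of every changepoint subset (tiny n only)
enumSegmentation <- function(values, nQuantiles = NULL, minSegLen = 2) {
  n <- length(values)
  cd <- microdyn:::npCostData(values, nQuantiles)
  beta <- 4 * log(n)
  segCost <- function(s, t)
    microdyn:::npSegmentCost(cd, s, t) + log(t - s)
  best <- Inf; bestCps <- integer()
  positions <- seq_len(n - 1)
  for (m in 0:length(positions)) {
    combos <- if (m == 0) list(integer()) else
      asplit(combn(positions, m), 2)
    for (cps in combos) {
      bounds <- c(0, cps, n)
      if (any(diff(bounds) < minSegLen)) next
      obj <- m * beta
      for (j in seq_len(length(bounds) - 1))
        obj <- obj + segCost(bounds[j], bounds[j + 1])
      if (obj < best) { best <- obj; bestCps <- as.integer(cps) }
    }
  }
  structure(bestCps, objective = best)
}

## exact hypergeometric pmf by enumerating all C(N, n) draws
enumHypergeomUpper <- function(k, N, K, n) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)   # items 1..K are the "successes"
  mean(hits >= k)
}

## recovery helper: detected day within +-1 grid position of the grid
## point nearest to the true changepoint day
recoveredWithin1 <- function(detected, trueDay, grid) {
  if (!length(detected)) return(FALSE)
  pos <- which.min(abs(grid - trueDay))
  any(abs(match(detected, grid) - pos) <= 1, na.rm = TRUE)
}
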