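# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops, textbook formulas) so they share no
# code path with the implementation they check.

# ACI by explicit triple loop over bands, adjacent frame pairs.
naiveAci <- function(m) {
  total <- 0
  for (f in seq_len(nrow(m))) {
    for (i in 2:ncol(m)) {
      s <- m[f, i] + m[f, i - 1]
      if (s > 0) total <- total + abs(m[f, i] - m[f, i - 1]) / s
    }
  }
  total
}

# Event boundaries by scanning the sorted gap sequence.
gapScanEvents <- function(times, gap = 5) {
  t <- sort(as.numeric(times))
  if (length(t) == 0) return(list(n = 0L, starts = numeric()))
  starts <- t[1]
  for (i in seq_along(t)[-1]) {
    if (t[i] - t[i - 1] >= gap) starts <- c(starts, t[i])
  }
  list(n = length(starts), starts = starts)
}

# Exact 1-D k-means by exhaustive search over contiguous partitions of
# the sorted values (optimal 1-D clusters are contiguous in sort order).
kmeans1dOracle <- function(x, k = 3) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  ss <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  best <- NULL; bestCost <- Inf
  # cut points c1 < c2 split sorted values into 3 non-empty runs
  for (c1 in 1:(n - 2)) for (c2 in (c1 + 1):(n - 1)) {
    cost <- ss(xs[1:c1]) + ss(xs[(c1 + 1):c2]) + ss(xs[(c2 + 1):n])
    if (cost < bestCost) { bestCost <- cost; best <- c(c1, c2) }
  }
  grp <- c(rep(3L, best[1]), rep(2L, best[2] - best[1]),
           rep(1L, n - best[2]))  # sorted ascending: last run = top tier
  labs <- c("high", "medium", "low")[grp]
  out <- character(n)
  out[o] <- labs
  out
}

# Quartiles by hand-written linear interpolation of order statistics.
quartileOracle <- function(values) {
  xs <- sort(values)
  n <- length(xs)
  qq <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
  }
  q1 <- qq(0.25); q3 <- qq(0.75)
  ifelse(values > q3, "peak", ifelse(values < q1, "trough", "normal"))
}

# Spearman rho as Pearson correlation of average ranks.
spearmanOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Friedman statistic from the rank-sum formula (no tie correction), and
# an exhaustive within-block permutation p-value for small tables.
friedmanStatOracle <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  R <- colSums(t(apply(tab, 1, rank)))
  12 / (n * k * (k + 1)) * sum((R - n * (k + 1) / 2)^2)
}

friedmanPermOracle <- function(tab) {
  k <- ncol(tab); n <- nrow(tab)
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == k), ,
                 drop = FALSE]
  obs <- friedmanStatOracle(tab)
  combos <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), n)))
  stats <- apply(combos, 1, function(ix) {
    permuted <- t(vapply(seq_len(n), function(b) tab[b, perms[ix[b], ]],
                         numeric(k)))
    friedmanStatOracle(permuted)
  })
  mean(stats >= obs - 1e-12)
}

# Leading eigenvector of a symmetric matrix via dense eigendecomposition.
eigenOracle <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- abs(v)
  v / max(v)
}
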