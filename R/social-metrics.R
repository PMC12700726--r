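# Social-metric stage: dyadic association index, eigenvector centrality,
# David's Scores with K-means rank tiers, kinship counts.

#' Dyadic association index
#'
#' The simple-ratio association index
#' \deqn{DAI = D_{ab} / (D_a + D_b - D_{ab})}
#' where `dAb` is the time two individuals spent in proximity (within 1 m)
#' and `dA`, `dB` are their focal observation times. Lies in `[0, 1]`:
#' 0 for never-associated dyads, 1 when all observation time was joint.
#'
#' @param dAb joint proximity time (seconds); vectorized.
#' @param dA,dB focal sampling times of the two individuals (seconds).
#' @return numeric in `[0, 1]`.
#' @export
#' @examples
#' dai(10, 30, 20)  # 10 / (30 + 20 - 10) = 0.25
dai <- function(dAb, dA, dB) {
  denom <- dA + dB - dAb
  if (any(denom <= 0))
    stop("undefined dyad: focal times minus joint time must be positive")
  if (any(dAb < 0)) stop("joint time must be nonnegative")
  dAb / denom
}

#' DAI matrix over all dyads
#'
#' @param dyadSeconds symmetric matrix of joint proximity times (seconds),
#'   zero diagonal.
#' @param focalSeconds named (or positionally matched) vector of focal
#'   observation times per individual.
#' @return symmetric matrix of DAI values in `[0, 1]`, zero diagonal,
#'   dimnames from `focalSeconds` names or `dyadSeconds` dimnames.
#' @export
daiMatrix <- function(dyadSeconds, focalSeconds) {
  d <- as.matrix(dyadSeconds)
  n <- length(focalSeconds)
  stopifnot(nrow(d) == n, ncol(d) == n)
  if (n < 2) stop("need at least 2 individuals")
  if (any(abs(d - t(d)) > 1e-9)) stop("dyadSeconds must be symmetric")
  if (any(diag(d) != 0)) stop("dyadSeconds must have a zero diagonal")
  if (any(d < 0)) stop("dyadSeconds must be nonnegative")
  fa <- matrix(focalSeconds, n, n)
  over <- d > t(fa) + fa
  if (any(over)) {
    bad <- which(over, arr.ind = TRUE)[1, ]
    stop("dyad (", bad[1], ", ", bad[2],
         ") has joint time exceeding combined focal time")
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- dai(d[i, j], focalSeconds[i], focalSeconds[j])
    out[i, j] <- v
    out[j, i] <- v
  }
  ids <- names(focalSeconds)
  if (is.null(ids)) ids <- rownames(d)
  dimnames(out) <- list(ids, ids)
  out
}

#' Eigenvector centrality of a weighted association matrix
#'
#' Leading-eigenvector weights of a symmetric nonnegative association
#' matrix, computed by shifted power iteration from a uniform start (the
#' shift keeps the iteration convergent on bipartite-like graphs; it does
#' not change the eigenvectors). On a disconnected matrix each component's
#' leading eigenvector is computed separately, scaled by the component's
#' leading eigenvalue, and the combined vector is normalized to maximum 1;
#' a warning reports the disconnection.
#'
#' @param m symmetric nonnegative matrix, not all zero (e.g. a DAI
#'   matrix).
#' @param tol convergence tolerance on the iterate (default 1e-12).
#' @param maxIter iteration cap (default 10000).
#' @return named nonnegative vector with maximum 1.
#' @export
#' @examples
#' star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
#' eigenvectorCentrality(star)  # hub 1, leaves 1/sqrt(3)
eigenvectorCentrality <- function(m, tol = 1e-12, maxIter = 10000) {
  m <- as.matrix(m)
  n <- nrow(m)
  stopifnot(ncol(m) == n)
  if (any(m < 0)) stop("association matrix must be nonnegative")
  if (any(abs(m - t(m)) > 1e-9)) stop("association matrix must be symmetric")
  if (all(m == 0)) stop("association matrix is all zero")

  g <- igraph::graph_from_adjacency_matrix((m > 0) * 1, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1)
    warning("association matrix is disconnected (", comp$no,
            " components); centrality computed per component and scaled ",
            "by component eigenvalue")

  shift <- max(m)
  res <- numeric(n)
  for (k in seq_len(comp$no)) {
    idx <- which(comp$membership == k)
    sub <- m[idx, idx, drop = FALSE]
    if (length(idx) == 1 || all(sub == 0)) next  # isolated: centrality 0
    v <- rep(1 / sqrt(length(idx)), length(idx))
    A <- sub + diag(shift, length(idx))
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      w <- as.numeric(A %*% v)
      w <- w / sqrt(sum(w^2))
      if (max(abs(w - v)) < tol) { v <- w; converged <- TRUE; break }
      v <- w
    }
    if (!converged) {
      resid <- max(abs(as.numeric(A %*% v) / sqrt(sum((A %*% v)^2)) - v))
      stop("power iteration did not converge in ", maxIter,
           " iterations (residual ", signif(resid, 3), ")")
    }
    v <- abs(v)  # Perron vector of a nonnegative matrix
    lambda <- as.numeric(t(v) %*% sub %*% v)  # Rayleigh quotient, unshifted
    res[idx] <- v / max(v) * lambda
  }
  if (all(res == 0)) stop("association matrix has no connected structure")
  res <- res / max(res)
  names(res) <- rownames(m)
  res
}

#' David's Scores from a win/loss matrix
#'
#' Dominance scores from dyadic agonistic outcomes. With `W[i, j]` the
#' number of times `i` defeated `j`, the dyadic win proportion is
#' `P[i, j] = W[i, j] / (W[i, j] + W[j, i])` for dyads that interacted and
#' 0 otherwise (raw-proportion variant). Then
#' `DS_i = w_i + w2_i - l_i - l2_i` with `w_i = sum_j P[i, j]`,
#' `l_i = sum_j P[j, i]`, `w2_i = sum_j P[i, j] w_j`, and
#' `l2_i = sum_j P[j, i] l_j`. Scores always sum to zero.
#'
#' `dyadCorrected = TRUE` uses the dyad-frequency-corrected proportion
#' `Dij = Pij - (Pij - 0.5) / (nij + 1)` in place of `Pij`.
#'
#' @param w square integer matrix of win counts, zero diagonal.
#' @param dyadCorrected use the frequency-corrected variant (default
#'   `FALSE`).
#' @return named numeric vector of David's Scores.
#' @export
#' @examples
#' w <- matrix(c(0, 4, 0, 0), 2, 2, byrow = TRUE)
#' davidsScore(w)  # +1, -1
davidsScore <- function(w, dyadCorrected = FALSE) {
  w <- as.matrix(w)
  n <- nrow(w)
  stopifnot(ncol(w) == n)
  if (n < 2) stop("need at least 2 individuals")
  if (any(w < 0)) stop("win counts must be nonnegative")
  if (any(diag(w) != 0)) stop("diagonal of the win matrix must be zero")
  tot <- w + t(w)
  P <- ifelse(tot > 0, w / ifelse(tot > 0, tot, 1), 0)
  if (dyadCorrected) P <- ifelse(tot > 0, P - (P - 0.5) / (tot + 1), 0)
  w1 <- rowSums(P)
  l1 <- colSums(P)
  w2 <- as.numeric(P %*% w1)
  l2 <- as.numeric(t(P) %*% l1)
  ds <- w1 + w2 - l1 - l2
  names(ds) <- rownames(w)
  ds
}

#' Rank tiers from David's Scores by 1-D K-means
#'
#' Clusters scores into `k = 3` groups with [stats::kmeans()] (50 restarts
#' under a fixed seed for reproducibility) and labels the clusters
#' `high` / `medium` / `low` by descending cluster mean.
#'
#' @param ds numeric vector of David's Scores (named by individual).
#' @param k number of tiers (default 3).
#' @param seed RNG seed for the K-means restarts (default 1).
#' @param nstart number of random restarts (default 50).
#' @return factor with levels `high`, `medium`, `low` (for `k = 3`), named
#'   as `ds`.
#' @export
#' @examples
#' rankTiers(c(a = 10, b = 9, c = 0.5, d = 0, e = -9, f = -10))
rankTiers <- function(ds, k = 3, seed = 1, nstart = 50) {
  if (length(unique(ds)) < k)
    stop("need at least ", k, " distinct score values for ", k, " tiers")
  km <- withSeed(seed, kmeans(ds, centers = k, nstart = nstart))
  ord <- order(km$centers, decreasing = TRUE)
  labs <- if (k == 3) c("high", "medium", "low")
          else paste0("tier", seq_len(k))
  tier <- labs[match(km$cluster, ord)]
  out <- factor(tier, levels = labs)
  names(out) <- names(ds)
  out
}

#' Kinship counts from a pedigree
#'
#' Counts, for each roster member, the number of direct relatives also in
#' the roster. The default relation set is parents, offspring, and
#' siblings sharing at least one known parent; relations through
#' individuals absent from the roster still link roster members (two
#' roster siblings of an unlisted mother count each other).
#'
#' @param pedigree data.frame with columns `parent`, `offspring`
#'   (identifiers; parents outside the roster allowed).
#' @param roster character vector of group members to count within.
#' @param relations subset of `c("parent", "offspring", "sibling")` to
#'   count as direct (default all three).
#' @return named integer vector over `roster`.
#' @export
#' @examples
#' ped <- data.frame(parent = c("m", "m"), offspring = c("a", "b"))
#' kinshipCounts(ped, c("m", "a", "b"))  # 2, 2, 2
kinshipCounts <- function(pedigree, roster,
                          relations = c("parent", "offspring", "sibling")) {
  relations <- match.arg(relations, several.ok = TRUE)
  stopifnot(all(c("parent", "offspring") %in% names(pedigree)))
  par <- as.character(pedigree$parent)
  off <- as.character(pedigree$offspring)
  if (any(par == off)) stop("cyclic pedigree: individual is its own parent")
  # Kahn's algorithm over parent -> offspring links to reject cycles
  nodes <- unique(c(par, off))
  edges <- data.frame(from = par, to = off)
  indeg <- table(factor(edges$to, levels = nodes))
  queue <- nodes[indeg == 0]
  seen <- 0L
  indeg <- as.integer(indeg); names(indeg) <- nodes
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    kids <- edges$to[edges$from == v]
    for (kd in kids) {
      indeg[kd] <- indeg[kd] - 1L
      if (indeg[kd] == 0L) queue <- c(queue, kd)
    }
  }
  if (seen < length(nodes)) stop("cyclic pedigree")

  roster <- as.character(roster)
  relOf <- function(id) {
    rel <- character()
    if ("parent" %in% relations) rel <- c(rel, par[off == id])
    if ("offspring" %in% relations) rel <- c(rel, off[par == id])
    if ("sibling" %in% relations) {
      myPar <- par[off == id]
      sibs <- off[par %in% myPar]
      rel <- c(rel, setdiff(sibs, id))
    }
    unique(rel)
  }
  out <- vapply(roster, function(id)
    length(intersect(relOf(id), roster)), integer(1))
  names(out) <- roster
  out
}
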