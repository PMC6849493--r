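# Independent pure-R oracles for the attack engine: Floyd-Warshall paths,
# label-propagation-free component counting, and exhaustive enumeration of
# removal orders. Deliberately naive and separate from the package's
# compiled path.

oracle_metrics <- function(adj) {
  n <- nrow(adj)
  A <- adj != 0
  conn <- sum(A[upper.tri(A)])
  if (n == 0) return(list(conn = 0, ncomp = 0, apl = NA_real_))
  D <- ifelse(A, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  comp <- integer(n)
  cc <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cc <- cc + 1
      comp[is.finite(D[i, ])] <- cc
    }
  }
  off <- D[row(D) != col(D)]
  off <- off[is.finite(off)]
  apl <- if (length(off) > 0) mean(off) else NA_real_
  list(conn = conn, ncomp = cc, apl = apl)
}

# metrics after each removal in `order_idx` (indices into adj), including
# the initial state
oracle_trajectory <- function(adj, order_idx) {
  keep <- seq_len(nrow(adj))
  states <- list(oracle_metrics(adj))
  for (v in order_idx) {
    keep <- setdiff(keep, v)
    states[[length(states) + 1]] <- oracle_metrics(adj[keep, keep, drop = FALSE])
  }
  list(conn = vapply(states, `[[`, numeric(1), "conn"),
       ncomp = vapply(states, `[[`, numeric(1), "ncomp"),
       apl = vapply(states, `[[`, numeric(1), "apl"))
}

# five outcomes from an oracle trajectory (direct restatement of the
# definitions: peak minus initial, first-attainment step over N)
oracle_outcomes <- function(tr, N) {
  cmp <- tr$ncomp; pl <- tr$apl; cn <- tr$conn
  out <- c(components_magnitude = max(cmp) - cmp[1],
           components_extent = (which(cmp == max(cmp))[1] - 1) / N,
           pathlength_magnitude = NA_real_, pathlength_extent = NA_real_,
           connectivity_extent = NA_real_)
  if (!is.na(pl[1])) {
    pk <- max(pl, na.rm = TRUE)
    out["pathlength_magnitude"] <- pk - pl[1]
    out["pathlength_extent"] <- (which(!is.na(pl) & pl == pk)[1] - 1) / N
  }
  if (cn[1] > 0)
    out["connectivity_extent"] <- (which(cn <= 0.5 * cn[1])[1] - 1) / N
  out
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (q in all_permutations(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1]] <- c(i, rest[q])
    }
  }
  out
}

# expected outcomes of the random attack by enumerating every removal order
oracle_random_expected <- function(adj) {
  n <- nrow(adj)
  perms <- all_permutations(n)
  vals <- vapply(perms, function(p) {
    oracle_outcomes(oracle_trajectory(adj, p[seq_len(n - 1)]), n)
  }, numeric(5))
  list(mean = rowMeans(vals), sd = apply(vals, 1, stats::sd),
       n_orders = length(perms))
}

# exact Boltzmann distribution of a 2-node 0/1 Ising model over its 4 states
boltzmann_2node <- function(t1, t2, w) {
  states <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  e <- apply(states, 1, function(s) t1 * s[1] + t2 * s[2] + w * s[1] * s[2])
  p <- exp(e)
  p / sum(p)
}
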