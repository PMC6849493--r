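# Sequential node-removal (symptom deactivation) simulation. State metrics
# come from a single compiled routine so one-shot measurements and full
# trajectories share a code path.

state_metrics_cpp <- function(network, order_idx = integer(0),
                              weighted = FALSE, distance = "hops") {
  attack_trajectory_cpp(network$adjacency, as.integer(order_idx),
                        isTRUE(weighted), identical(distance, "inverse_weight"))
}

#' Network connectivity
#'
#' The total number of interactions present in the network: the count of
#' nonzero edges (default) or the sum of absolute edge weights
#' (`weighted = TRUE`).
#'
#' @param network A `symptom_network`.
#' @param weighted Sum absolute weights instead of counting edges.
#' @return Nonnegative scalar.
#' @export
connectivity <- function(network, weighted = FALSE) {
  if (weighted) sum(abs(network$adjacency[upper.tri(network$adjacency)]))
  else n_edges(network)
}

#' Number of components
#'
#' Count of maximal connected subgraphs; isolated symptoms count as
#' components.
#'
#' @param network A `symptom_network` with at least one node.
#' @return Integer count in \[1, number of nodes\].
#' @export
n_components <- function(network) {
  if (n_nodes(network) == 0) stop("empty network has no components")
  state_metrics_cpp(network)$n_components[1]
}

#' Average path length
#'
#' Mean shortest-path distance over all ordered pairs of symptoms joined
#' by a finite path (pairs in different components are excluded). `hops`
#' counts edges; `inverse_weight` uses `1/|w|` edge lengths. Returns `NA`
#' when the network has no edges.
#'
#' @param network A `symptom_network` with at least 2 nodes.
#' @param distance `"hops"` (default) or `"inverse_weight"`.
#' @return Scalar of at least 1 (in hops mode), or `NA` if edgeless.
#' @export
avg_path_length <- function(network, distance = c("hops", "inverse_weight")) {
  distance <- match.arg(distance)
  if (n_nodes(network) < 2) stop("need at least 2 nodes")
  state_metrics_cpp(network, distance = distance)$avg_path_length[1]
}

build_trajectory <- function(network, removal_labels, condition, mode,
                             weighted, distance, seed = NULL) {
  sm <- state_metrics_cpp(network, match(removal_labels, network$labels) - 1L,
                          weighted = weighted, distance = distance)
  nstate <- length(sm$n_components)
  states <- structure(list(step = seq_len(nstate) - 1L,
                           connectivity = sm$connectivity,
                           n_components = sm$n_components,
                           avg_path_length = sm$avg_path_length),
                      class = "data.frame", row.names = seq_len(nstate))
  structure(list(condition = condition,
                 removal_order = removal_labels,
                 states = states,
                 mode = mode,
                 n_initial = n_nodes(network),
                 seed = seed),
            class = "attack_trajectory")
}

#' @export
print.attack_trajectory <- function(x, ...) {
  cat("attack_trajectory: condition ", x$condition, " (", x$mode, " mode), ",
      x$n_initial, " -> 1 nodes in ", length(x$removal_order), " removals\n",
      sep = "")
  invisible(x)
}

#' Simulate a targeted attack
#'
#' Removes symptoms one at a time until a single symptom remains,
#' recording connectivity, number of components and average path length
#' initially and after every removal. In `initial` mode (the default
#' protocol) the pre-computed ranking fixes the whole removal order; in
#' `recalculated` (cascading) mode the measure is re-computed on the
#' surviving subnetwork before each removal.
#'
#' @param network A `symptom_network` with at least 2 nodes.
#' @param order A `ranked_order` from [rank_nodes()] (initial mode), or the
#'   measure name for recalculated mode.
#' @param mode `"initial"` or `"recalculated"`.
#' @param weighted Connectivity as summed absolute weight instead of edge
#'   count.
#' @param distance Path-length mode, see [avg_path_length()].
#' @return An `attack_trajectory`.
#' @export
targeted_attack <- function(network, order, mode = c("initial", "recalculated"),
                            weighted = FALSE, distance = c("hops", "inverse_weight")) {
  mode <- match.arg(mode)
  distance <- match.arg(distance)
  N <- n_nodes(network)
  if (N < 2) stop("need at least 2 nodes to attack")
  if (mode == "initial") {
    if (!inherits(order, "ranked_order"))
      stop("initial mode requires a ranked_order from rank_nodes()")
    if (!setequal(order$order, network$labels) ||
        length(order$order) != N)
      stop("ranking is not a permutation of the network's symptoms")
    removal <- order$order[seq_len(N - 1)]
    return(build_trajectory(network, removal, order$measure, mode,
                            weighted, distance))
  }
  measure <- if (inherits(order, "ranked_order")) order$measure
             else match.arg(order, c("degree", "strength", "bridgeness", "overlap"))
  current <- network
  removal <- character(N - 1)
  for (k in seq_len(N - 1)) {
    needs_modules <- measure %in% c("bridgeness", "overlap")
    top <- if (needs_modules && n_edges(current) == 0) {
      sort(current$labels)[1]  # edgeless remainder: all measures tie
    } else {
      asg <- if (needs_modules) detect_modules(current) else NULL
      rank_nodes(current, measure, assignment = asg)$order[1]
    }
    removal[k] <- top
    current <- remove_nodes(current, top)
  }
  build_trajectory(network, removal, measure, mode, weighted, distance)
}

#' Simulate random attacks
#'
#' Draws `n_sims` uniformly random removal orders and simulates each as a
#' full attack. Replicate `r` uses the seed `seed + r`, so enlarging
#' `n_sims` extends the replicate set without changing earlier replicates.
#'
#' @param network A `symptom_network` with at least 2 nodes.
#' @param n_sims Number of replicates (the study default is 2000).
#' @param seed Integer base seed.
#' @inheritParams targeted_attack
#' @return List of `attack_trajectory` objects, one per replicate.
#' @export
random_attack <- function(network, n_sims = 2000, seed = 1,
                          weighted = FALSE, distance = c("hops", "inverse_weight")) {
  distance <- match.arg(distance)
  stopifnot(n_sims >= 1)
  N <- n_nodes(network)
  if (N < 2) stop("need at least 2 nodes to attack")
  lapply(seq_len(n_sims), function(r) {
    rs <- as.integer((seed + r) %% 2147483647L)
    perm <- with_seed(rs, sample(network$labels))
    tr <- build_trajectory(network, perm[seq_len(N - 1)], "random", "initial",
                           weighted, distance, seed = rs)
    tr
  })
}
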