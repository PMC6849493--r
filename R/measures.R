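# Ranking measures: two centrality measures (degree, strength) and two
# bridge measures derived from an overlapping-module assignment.

check_node <- function(network, node) {
  if (!node %in% network$labels)
    stop("unknown symptom: ", node)
  match(node, network$labels)
}

#' Degree of a symptom
#'
#' Number of connections (nonzero-weight edges) a symptom has with the
#' other symptoms.
#'
#' @param network A `symptom_network`.
#' @param node Symptom label; omit for all symptoms.
#' @return Named integer vector (or scalar for a single node).
#' @export
node_degree <- function(network, node = NULL) {
  d <- colSums(network$adjacency != 0)
  if (is.null(node)) return(d)
  d[[check_node(network, node)]]
}

#' Strength of a symptom
#'
#' Sum of the absolute weights of a symptom's connections.
#'
#' @inheritParams node_degree
#' @return Named numeric vector (or scalar for a single node).
#' @export
node_strength <- function(network, node = NULL) {
  s <- colSums(abs(network$adjacency))
  if (is.null(node)) return(s)
  s[[check_node(network, node)]]
}

#' Detect overlapping modules
#'
#' Produces the two ingredients of the bridge measures: a fuzzy membership
#' matrix (how much each symptom belongs to each module) and a connection
#' profile (how each symptom's edge weight is distributed over modules).
#' The backend is deliberately simple and deterministic: (1) a base
#' partition by greedy modularity maximization on absolute weights;
#' (2) membership smoothing
#' `q(i,.) <- (1 - alpha) * onehot(base(i)) + alpha * sum_j P(i,j) q(j,.)`
#' with `P` the |w| row-normalized transition matrix, iterated to a fixed
#' point; (3) connection profile `c(i,m)` proportional to
#' `sum_j |w_ij| q(j,m)`, row-normalized.
#'
#' @param network A `symptom_network` with at least one edge.
#' @param alpha Smoothing weight in \[0, 1\]; 0 keeps the hard partition.
#' @param max_iter Maximum smoothing iterations.
#' @param tol Convergence tolerance on the membership update.
#' @return A `module_assignment`: `membership` (node x module,
#'   row-stochastic), `connection_profile` (row-stochastic where the node
#'   has edges), `base_partition` (module id per node), `n_modules`,
#'   `params`.
#' @export
detect_modules <- function(network, alpha = 0.5, max_iter = 50, tol = 1e-6) {
  stopifnot(alpha >= 0, alpha <= 1, max_iter >= 1, tol > 0)
  if (n_edges(network) == 0)
    stop("network has no edges; treat all nodes as singleton modules instead")
  p <- n_nodes(network)
  absw <- abs(network$adjacency)
  g <- igraph::graph_from_adjacency_matrix(absw, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  base <- as.integer(igraph::membership(igraph::cluster_fast_greedy(g)))
  M <- max(base)
  anchor <- matrix(0, p, M)
  anchor[cbind(seq_len(p), base)] <- 1
  rs <- rowSums(absw)
  P <- absw / ifelse(rs > 0, rs, 1)
  # isolated nodes keep their anchor row fixed
  iso <- rs == 0
  if (any(iso)) P[iso, ] <- 0
  q <- anchor
  for (t in seq_len(max_iter)) {
    q_new <- (1 - alpha) * anchor + alpha * (P %*% q)
    if (any(iso)) q_new[iso, ] <- anchor[iso, , drop = FALSE]
    if (max(abs(q_new - q)) < tol) { q <- q_new; break }
    q <- q_new
  }
  prof <- absw %*% q
  pr <- rowSums(prof)
  prof <- prof / ifelse(pr > 0, pr, 1)
  if (any(iso)) prof[iso, ] <- q[iso, , drop = FALSE]
  rownames(q) <- rownames(prof) <- network$labels
  structure(list(membership = q, connection_profile = prof,
                 base_partition = stats::setNames(base, network$labels),
                 n_modules = M,
                 params = list(alpha = alpha, max_iter = max_iter, tol = tol)),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("module_assignment: ", nrow(x$membership), " symptoms, ",
      x$n_modules, " modules (alpha = ", x$params$alpha, ")\n", sep = "")
  invisible(x)
}

#' Effective number of a probability vector
#'
#' Inverse participation ratio `1 / sum(p^2)`: 1 for a one-hot vector, the
#' vector length when mass is spread evenly.
#'
#' @param distribution Nonnegative vector summing to 1.
#' @return A real number of at least 1.
#' @export
effective_number <- function(distribution) {
  if (any(distribution < -1e-12) || abs(sum(distribution) - 1) > 1e-6)
    stop("`distribution` must be a nonnegative vector summing to 1")
  1 / sum(distribution^2)
}

#' Modular overlap of a symptom
#'
#' Effective number of modules to which the symptom is assigned (the
#' trans-modular role), computed from its fuzzy membership row.
#'
#' @param assignment A `module_assignment`.
#' @param node Symptom label.
#' @return Overlap value in \[1, number of modules\].
#' @export
modular_overlap <- function(assignment, node) {
  if (!node %in% rownames(assignment$membership))
    stop("unknown symptom: ", node)
  effective_number(assignment$membership[node, ])
}

#' Modular bridgeness of a symptom
#'
#' Effective number of modules to which the symptom is connected (the
#' inter-modular role), computed from its connection-profile row. Isolated
#' symptoms are assigned bridgeness 1.
#'
#' @inheritParams modular_overlap
#' @return Bridgeness value in \[1, number of modules\].
#' @export
modular_bridgeness <- function(assignment, node) {
  if (!node %in% rownames(assignment$connection_profile))
    stop("unknown symptom: ", node)
  effective_number(assignment$connection_profile[node, ])
}

#' Rank symptoms for a targeted attack
#'
#' Orders symptoms by descending measure value. Ties are broken by
#' ascending label (deterministic default) or uniformly at random under a
#' seed.
#'
#' @param network A `symptom_network`.
#' @param measure One of `"degree"`, `"strength"`, `"bridgeness"`,
#'   `"overlap"`.
#' @param assignment A `module_assignment`; required for the module
#'   measures.
#' @param seed Optional integer seed for random tie-breaking.
#' @return A `ranked_order`: `measure`, `order` (labels, descending),
#'   `values` (measure values along the order), `tie_rule`.
#' @export
rank_nodes <- function(network, measure = c("degree", "strength", "bridgeness", "overlap"),
                       assignment = NULL, seed = NULL) {
  measure <- match.arg(measure)
  vals <- switch(measure,
    degree = node_degree(network),
    strength = node_strength(network),
    bridgeness = ,
    overlap = {
      if (is.null(assignment))
        stop("`assignment` is required for measure '", measure, "'")
      fn <- if (measure == "overlap") modular_overlap else modular_bridgeness
      stats::setNames(vapply(network$labels, fn, numeric(1),
                             assignment = assignment), network$labels)
    })
  labels <- network$labels
  if (is.null(seed)) {
    ord <- order(-vals, labels)
    tie_rule <- "ascending label"
  } else {
    jitter_rank <- with_seed(seed, sample.int(length(labels)))
    ord <- order(-vals, jitter_rank)
    tie_rule <- sprintf("uniform random (seed %d)", as.integer(seed))
  }
  structure(list(measure = measure, order = labels[ord],
                 values = unname(vals[ord]), tie_rule = tie_rule),
            class = "ranked_order")
}

#' @export
print.ranked_order <- function(x, ...) {
  cat("ranked_order (", x$measure, ", ties: ", x$tie_rule, "): ",
      paste(utils::head(x$order, 8), collapse = " > "),
      if (length(x$order) > 8) " > ..." else "", "\n", sep = "")
  invisible(x)
}

#' Per-symptom measure table
#'
#' Convenience wrapper computing all four ranking measures at once.
#'
#' @param network A `symptom_network` (needs at least one edge for the
#'   module measures).
#' @param assignment Optional precomputed `module_assignment`.
#' @return Data frame with columns symptom, degree, strength, overlap,
#'   bridgeness, module.
#' @export
symptom_measures <- function(network, assignment = NULL) {
  if (is.null(assignment)) assignment <- detect_modules(network)
  data.frame(
    symptom = network$labels,
    degree = unname(node_degree(network)),
    strength = unname(node_strength(network)),
    overlap = vapply(network$labels, modular_overlap, numeric(1),
                     assignment = assignment),
    bridgeness = vapply(network$labels, modular_bridgeness, numeric(1),
                        assignment = assignment),
    module = unname(assignment$base_partition),
    row.names = NULL, stringsAsFactors = FALSE)
}
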