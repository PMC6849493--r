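# Synthetic ground-truth models and networks. Every generator takes an
# explicit integer seed and leaves the caller's RNG state untouched.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Uniformly drawn off-diagonal support of m pairs on p nodes.
draw_support <- function(p, m) {
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  if (m > nrow(pairs)) stop("requested support larger than the number of pairs")
  if (m == 0) return(pairs[0, , drop = FALSE])
  pairs[sample.int(nrow(pairs), m), , drop = FALSE]
}

#' Generate a ground-truth Gaussian precision model
#'
#' Draws a sparse symmetric precision matrix whose support is uniform among
#' off-diagonal pairs at the target density, then enforces positive
#' definiteness by diagonal loading until the condition number is at most
#' 1e4. The implied partial correlations are
#' `rho_ij = -kappa_ij / sqrt(kappa_ii * kappa_jj)`.
#'
#' @param p Number of variables (at least 3).
#' @param density Target fraction of nonzero off-diagonal pairs in (0, 1\];
#'   0 yields the empty model.
#' @param seed Integer seed.
#' @param magnitude_range Range of absolute off-diagonal precision entries.
#' @param pos_prob Probability that an implied partial correlation is
#'   positive (precision entry negative).
#' @return A `precision_model` with elements `precision`, `partials`
#'   (zero-diagonal partial-correlation matrix) and `support` (two-column
#'   index matrix of the nonzero pairs).
#' @export
gen_precision_model <- function(p, density, seed,
                                magnitude_range = c(0.3, 0.6),
                                pos_prob = 0.9) {
  stopifnot(p >= 3, density >= 0, density <= 1)
  with_seed(seed, {
    m <- round(density * p * (p - 1) / 2)
    support <- draw_support(p, m)
    K <- matrix(0, p, p)
    if (m > 0) {
      mag <- stats::runif(m, magnitude_range[1], magnitude_range[2])
      # positive partial correlation <=> negative precision entry
      sgn <- ifelse(stats::runif(m) < pos_prob, -1, 1)
      K[support] <- sgn * mag
      K <- K + t(K)
    }
    diag(K) <- 1
    # deterministic loading ladder: condition number <= 1e4
    for (attempt in 0:40) {
      ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) > 0 && max(ev) / min(ev) <= 1e4) break
      delta <- max(max(ev) / 1e4 - min(ev), 0.05 * 2^attempt)
      diag(K) <- diag(K) + delta
      if (attempt == 40) stop("failed to reach positive definiteness by diagonal loading")
    }
    structure(list(precision = K,
                   partials = partial_correlations(K),
                   support = support),
              class = "precision_model")
  })
}

#' Sample multivariate Gaussian data from a precision model
#'
#' @param model A `precision_model`.
#' @param n Number of observations.
#' @param seed Integer seed.
#' @return An `n x p` numeric matrix drawn from the zero-mean normal with
#'   covariance equal to the inverse precision.
#' @export
sample_gaussian <- function(model, n, seed) {
  stopifnot(inherits(model, "precision_model"), n >= 1)
  sigma <- tryCatch(solve(model$precision),
                    error = function(e) stop("singular precision matrix"))
  sigma <- (sigma + t(sigma)) / 2
  with_seed(seed, {
    x <- MASS::mvrnorm(n, mu = rep(0, nrow(sigma)), Sigma = sigma)
    if (n == 1) x <- matrix(x, nrow = 1)
    x
  })
}

#' Generate a ground-truth Ising model
#'
#' Couplings sit on a uniformly random support at the target density with
#' magnitudes scaled by `coupling_scale`; thresholds are drawn negative and
#' offset against each node's total positive coupling so that marginal
#' activation probabilities stay away from 0 and 1.
#'
#' @param p Number of binary variables (at least 3).
#' @param density Target edge fraction.
#' @param coupling_scale Multiplier on coupling magnitudes (base range
#'   0.5 to 1).
#' @param seed Integer seed.
#' @param pos_prob Probability of a positive coupling.
#' @return An `ising_model` with `thresholds` (length p) and `couplings`
#'   (symmetric, zero diagonal).
#' @export
gen_ising_model <- function(p, density, coupling_scale = 1, seed = 1,
                            pos_prob = 0.9) {
  stopifnot(p >= 3, density >= 0, density <= 1)
  with_seed(seed, {
    m <- round(density * p * (p - 1) / 2)
    support <- draw_support(p, m)
    W <- matrix(0, p, p)
    if (m > 0) {
      mag <- stats::runif(m, 0.5, 1) * coupling_scale
      sgn <- ifelse(stats::runif(m) < pos_prob, 1, -1)
      W[support] <- sgn * mag
      W <- W + t(W)
    }
    thresholds <- -0.5 * rowSums(pmax(W, 0)) + stats::runif(p, -0.5, 0)
    structure(list(thresholds = thresholds, couplings = W),
              class = "ising_model")
  })
}

#' Sample binary data from an Ising model by Gibbs sampling
#'
#' Full-conditional updates follow the logistic probability
#' `P(x_i = 1 | x_-i) = plogis(threshold_i + sum_j w_ij x_j)` over 0/1
#' states. Rows are recorded every `thin` sweeps after `burnin` sweeps.
#'
#' @param model An `ising_model`.
#' @param n Number of rows to record.
#' @param burnin Burn-in sweeps.
#' @param thin Sweeps between recorded rows.
#' @param seed Integer seed.
#' @return An `n x p` 0/1 matrix.
#' @export
sample_ising <- function(model, n, burnin = 200, thin = 5, seed = 1) {
  stopifnot(inherits(model, "ising_model"), n >= 1, burnin >= 0, thin >= 1)
  p <- length(model$thresholds)
  with_seed(seed, {
    init <- as.numeric(stats::runif(p) < 0.5)
    u <- stats::runif((burnin + n * thin) * p)
    sample_ising_cpp(model$thresholds, model$couplings, init,
                     as.integer(n), as.integer(burnin), as.integer(thin), u)
  })
}

#' Build a network with planted overlapping and bridging nodes
#'
#' Modules are fully connected cliques at a common edge weight. A shared
#' (overlapping) node belongs to two modules and carries all within-module
#' edges of both; a bridge edge is a single edge between two modules whose
#' endpoints each belong to exactly one module. Ground truth is recorded so
#' module-detection output can be scored.
#'
#' @param clique_sizes Integer vector of module sizes (each at least 3).
#' @param shared_nodes Number of nodes belonging to two modules.
#' @param bridge_edges Number of single inter-module edges.
#' @param weight Common positive edge weight.
#' @param seed Integer seed (reserved; the construction is deterministic).
#' @return A `planted_modular_network` with elements `network`,
#'   `true_modules` (list of label vectors), `true_overlap_nodes`,
#'   `true_bridge_nodes`.
#' @export
gen_planted_modules <- function(clique_sizes, shared_nodes = 0, bridge_edges = 0,
                                weight = 1, seed = 1) {
  stopifnot(all(clique_sizes >= 3), shared_nodes >= 0, bridge_edges >= 0, weight > 0)
  K <- length(clique_sizes)
  if ((shared_nodes > 0 || bridge_edges > 0) && K < 2)
    stop("sharing or bridging requires at least two modules")
  total <- sum(clique_sizes) - shared_nodes
  if (shared_nodes > 0 && total < max(clique_sizes))
    stop("too many shared nodes for the given clique sizes")
  labels <- sprintf("S%02d", seq_len(total))
  modules <- vector("list", K)
  nxt <- 1
  for (k in seq_len(K)) {
    modules[[k]] <- integer(0)
  }
  # allocate shared nodes to pairs (1,2), (2,3), ... cycling
  share_pair <- if (shared_nodes > 0)
    (seq_len(shared_nodes) - 1) %% (K - 1) + 1 else integer(0)
  shared_ids <- integer(0)
  for (s in seq_len(shared_nodes)) {
    id <- nxt; nxt <- nxt + 1
    shared_ids <- c(shared_ids, id)
    a <- share_pair[s]; b <- a + 1
    modules[[a]] <- c(modules[[a]], id)
    modules[[b]] <- c(modules[[b]], id)
  }
  for (k in seq_len(K)) {
    need <- clique_sizes[k] - length(modules[[k]])
    if (need < 0) stop("too many shared nodes for module ", k)
    if (need > 0) {
      ids <- seq.int(nxt, nxt + need - 1)
      nxt <- nxt + need
      modules[[k]] <- c(modules[[k]], ids)
    }
  }
  adj <- matrix(0, total, total)
  for (k in seq_len(K)) {
    idx <- modules[[k]]
    adj[idx, idx] <- weight
  }
  diag(adj) <- 0
  # bridge edges between exclusive members of distinct modules
  exclusive <- lapply(seq_len(K), function(k)
    setdiff(modules[[k]], shared_ids))
  bridge_ids <- integer(0)
  if (bridge_edges > 0) {
    pairs <- utils::combn(K, 2)
    used <- replicate(K, integer(0), simplify = FALSE)
    for (b in seq_len(bridge_edges)) {
      pr <- pairs[, (b - 1) %% ncol(pairs) + 1]
      ea <- setdiff(exclusive[[pr[1]]], used[[pr[1]]])
      eb <- setdiff(exclusive[[pr[2]]], used[[pr[2]]])
      if (length(ea) == 0 || length(eb) == 0)
        stop("not enough exclusive nodes for ", bridge_edges, " bridge edges")
      i <- ea[1]; j <- eb[1]
      if (adj[i, j] != 0) stop("bridge edge would duplicate an existing edge")
      adj[i, j] <- adj[j, i] <- weight
      used[[pr[1]]] <- c(used[[pr[1]]], i)
      used[[pr[2]]] <- c(used[[pr[2]]], j)
      bridge_ids <- c(bridge_ids, i, j)
    }
  }
  net <- symptom_network(adj, labels = labels)
  structure(list(network = net,
                 true_modules = lapply(modules, function(ix) labels[sort(ix)]),
                 true_overlap_nodes = labels[shared_ids],
                 true_bridge_nodes = unique(labels[bridge_ids])),
            class = "planted_modular_network")
}

#' Specification of a synthetic network ensemble
#'
#' Defaults emulate the descriptive profile of published cross-sectional
#' symptom networks: node counts from a right-skewed (log-normal)
#' distribution with mean about 23 and SD about 21 truncated to 5..120,
#' densities uniform on 0.067..0.861, signed weights with magnitudes in
#' (0, 1\] and about 90 percent positive edges.
#'
#' @param k Number of networks.
#' @param node_range Inclusive node-count range.
#' @param density_range Density range in (0, 1\].
#' @param pos_prob Probability of a positive edge weight.
#' @param weight_shape1,weight_shape2 Beta parameters for weight magnitudes.
#' @param seed Integer seed.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(k, node_range = c(5, 120),
                          density_range = c(0.067, 0.861),
                          pos_prob = 0.9,
                          weight_shape1 = 2, weight_shape2 = 5,
                          seed = 1) {
  stopifnot(k >= 1, length(node_range) == 2, node_range[1] <= node_range[2],
            length(density_range) == 2, density_range[1] <= density_range[2],
            density_range[1] > 0, density_range[2] <= 1,
            pos_prob >= 0, pos_prob <= 1)
  structure(list(k = as.integer(k), node_range = as.integer(node_range),
                 density_range = density_range, pos_prob = pos_prob,
                 weight_shape1 = weight_shape1, weight_shape2 = weight_shape2,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

# log-normal truncated to [lo, hi]; meanlog/sdlog matched to mean 23, sd 21
draw_node_counts <- function(k, lo, hi) {
  cv2 <- (21 / 23)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(23) - sdlog^2 / 2
  out <- integer(0)
  while (length(out) < k) {
    x <- round(stats::rlnorm(2 * k + 10, meanlog, sdlog))
    x <- x[x >= lo & x <= hi]
    out <- c(out, x)
  }
  out[seq_len(k)]
}

#' Generate an ensemble of synthetic symptom networks
#'
#' @param spec An [ensemble_spec()].
#' @return List of `symptom_network` objects of length `spec$k`.
#' @export
gen_network_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  with_seed(spec$seed, {
    sizes <- draw_node_counts(spec$k, spec$node_range[1], spec$node_range[2])
    lapply(seq_len(spec$k), function(i) {
      p <- sizes[i]
      dens <- stats::runif(1, spec$density_range[1], spec$density_range[2])
      m <- max(1L, round(dens * p * (p - 1) / 2))
      support <- draw_support(p, m)
      mag <- pmax(stats::rbeta(m, spec$weight_shape1, spec$weight_shape2), 0.01)
      sgn <- ifelse(stats::runif(m) < spec$pos_prob, 1, -1)
      adj <- matrix(0, p, p)
      adj[support] <- sgn * mag
      adj <- adj + t(adj)
      symptom_network(adj, labels = sprintf("S%03d", seq_len(p)))
    })
  })
}

#' Write planted ground truth as a JSON sidecar
#'
#' @param planted A `planted_modular_network`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(planted, path) {
  stopifnot(inherits(planted, "planted_modular_network"))
  jsonlite::write_json(list(true_modules = planted$true_modules,
                            true_overlap_nodes = planted$true_overlap_nodes,
                            true_bridge_nodes = planted$true_bridge_nodes),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
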