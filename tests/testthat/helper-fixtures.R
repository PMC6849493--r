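# Small graph fixtures built in code.

star_network <- function(n_leaves, weight = 1) {
  p <- n_leaves + 1
  adj <- matrix(0, p, p)
  adj[1, 2:p] <- adj[2:p, 1] <- weight
  symptom_network(adj, labels = c("hub", sprintf("leaf%02d", seq_len(n_leaves))))
}

path_network <- function(n, weight = 1) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- weight
  symptom_network(adj, labels = letters[seq_len(n)])
}

complete_network <- function(n, weight = 1) {
  adj <- matrix(weight, n, n)
  diag(adj) <- 0
  symptom_network(adj, labels = LETTERS[seq_len(n)])
}

# two cliques of size `m` joined by a single bridge edge
barbell_network <- function(m = 4, weight = 1) {
  gen_planted_modules(c(m, m), shared_nodes = 0, bridge_edges = 1,
                      weight = weight)$network
}

# Erdos-Renyi-style weighted network (uses the caller-visible RNG contract)
er_network <- function(p, density, seed, pos_prob = 0.9) {
  gen_network_ensemble(ensemble_spec(1, node_range = c(p, p),
                                     density_range = c(density, density),
                                     pos_prob = pos_prob, seed = seed))[[1]]
}
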