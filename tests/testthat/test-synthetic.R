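test_that("precision models hit the requested support and stay PD", {
  # empty support: no partial correlations
  m0 <- gen_precision_model(3, 0, seed = 1)
  expect_true(all(m0$partials[upper.tri(m0$partials)] == 0))

  m1 <- gen_precision_model(10, 0.2, seed = 7)
  expect_equal(nrow(m1$support), 9)  # round(0.2 * 45)

  m2 <- gen_precision_model(15, 0.2, seed = 3)
  ev <- eigen(m2$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # partials follow the definition entrywise
  i <- m2$support[1, 1]; j <- m2$support[1, 2]
  expect_equal(m2$partials[i, j],
               -m2$precision[i, j] /
                 sqrt(m2$precision[i, i] * m2$precision[j, j]))
  expect_identical(gen_precision_model(8, 0.3, seed = 5)$precision,
                   gen_precision_model(8, 0.3, seed = 5)$precision)
})

test_that("realized density matches the request within one edge", {
  for (s in 1:25) {
    p <- 5 + (s %% 14)
    dens <- 0.1 + 0.8 * (s / 25)
    m <- gen_precision_model(p, dens, seed = s)
    expect_equal(nrow(m$support), round(dens * p * (p - 1) / 2),
                 tolerance = 0, info = paste("seed", s))
    expect_true(isSymmetric(m$precision))
    net <- gen_network_ensemble(ensemble_spec(1, node_range = c(p, p),
                                              density_range = c(dens, dens),
                                              seed = s))[[1]]
    target <- max(1, round(dens * p * (p - 1) / 2))
    got <- sum(net$adjacency[upper.tri(net$adjacency)] != 0)
    expect_lte(abs(got - target), 1)
    expect_true(isSymmetric(net$adjacency))
    expect_true(all(diag(net$adjacency) == 0))
  }
})

test_that("gaussian sampler matches its model", {
  m0 <- gen_precision_model(5, 0, seed = 1)
  x <- sample_gaussian(m0, 5000, seed = 1)
  cors <- cor(x)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)

  # 2-variable model: sample correlation matches the covariance implied by
  # inverting the precision
  K <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  m2 <- structure(list(precision = K, partials = partial_correlations(K),
                       support = cbind(1L, 2L)), class = "precision_model")
  sig <- solve(K)
  rho <- sig[1, 2] / sqrt(sig[1, 1] * sig[2, 2])
  x2 <- sample_gaussian(m2, 10000, seed = 2)
  expect_lt(abs(cor(x2)[1, 2] - rho), 0.03)

  expect_equal(dim(sample_gaussian(m0, 1, seed = 3)), c(1L, 5L))
  expect_identical(sample_gaussian(m0, 10, seed = 4),
                   sample_gaussian(m0, 10, seed = 4))
})

test_that("gaussian sampler preserves conditional independence on a chain", {
  # chain a-b-c: partial correlation of (a, c) given b tends to 0
  K <- diag(3)
  K[1, 2] <- K[2, 1] <- K[2, 3] <- K[3, 2] <- -0.4
  m <- structure(list(precision = K, partials = partial_correlations(K),
                      support = rbind(c(1L, 2L), c(2L, 3L))),
                 class = "precision_model")
  n <- 20000
  x <- sample_gaussian(m, n, seed = 11)
  pc <- partial_correlations(solve(cor(x)))
  expect_lt(abs(pc[1, 3]), 3 / sqrt(n))
  expect_gt(pc[1, 2], 0.2)
})

test_that("ising models and Gibbs samples behave", {
  m0 <- gen_ising_model(5, 0, seed = 1)
  expect_true(all(m0$couplings == 0))
  m1 <- gen_ising_model(10, 0.3, seed = 1)
  k <- sum(m1$couplings[upper.tri(m1$couplings)] != 0)
  expect_lte(abs(k - round(0.3 * 45)), 1)
  expect_identical(gen_ising_model(10, 0.3, seed = 2),
                   gen_ising_model(10, 0.3, seed = 2))

  # independent, zero-threshold nodes activate half the time
  free <- structure(list(thresholds = rep(0, 4),
                         couplings = matrix(0, 4, 4)), class = "ising_model")
  x <- sample_ising(free, 4000, seed = 5)
  expect_true(all(abs(colMeans(x) - 0.5) < 0.03))
  expect_equal(dim(sample_ising(free, 1, seed = 6)), c(1L, 4L))
})

test_that("2-node Gibbs matches the exact Boltzmann distribution", {
  w <- 2
  m <- structure(list(thresholds = c(-1, -1),
                      couplings = matrix(c(0, w, w, 0), 2, 2)),
                 class = "ising_model")
  x <- sample_ising(m, 20000, burnin = 500, thin = 5, seed = 9)
  exact <- boltzmann_2node(-1, -1, w)
  emp <- table(factor(paste0(x[, 1], x[, 2]),
                      levels = c("00", "01", "10", "11"))) / nrow(x)
  # Monte-Carlo bound: 4 SEs of a binomial proportion (thinned chain)
  expect_true(all(abs(as.numeric(emp) - exact) <
                    4 * sqrt(exact * (1 - exact) / nrow(x)) + 0.01))
  # positive coupling raises agreement above the zero-coupling value
  free <- structure(list(thresholds = c(-1, -1), couplings = matrix(0, 2, 2)),
                    class = "ising_model")
  x0 <- sample_ising(free, 20000, burnin = 500, thin = 5, seed = 10)
  expect_gt(mean(x[, 1] == x[, 2]), mean(x0[, 1] == x0[, 2]))
})

test_that("planted modular networks record correct ground truth", {
  pm <- gen_planted_modules(c(6, 6), shared_nodes = 1)
  expect_equal(length(pm$network$labels), 11)
  expect_equal(unname(node_degree(pm$network, pm$true_overlap_nodes)), 10)

  pb <- gen_planted_modules(c(5, 5), bridge_edges = 1)
  inter <- pb$network$adjacency[pb$true_modules[[1]], pb$true_modules[[2]]]
  expect_equal(sum(inter != 0), 1)
  expect_equal(length(pb$true_bridge_nodes), 2)

  p3 <- gen_planted_modules(c(4, 4, 4))
  expect_equal(n_components(p3$network), 3)

  expect_error(gen_planted_modules(c(3, 3), shared_nodes = 10), "shared")
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(pm, f)
  gt <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(gt$true_overlap_nodes, pm$true_overlap_nodes)
})

test_that("ensembles respect node and density ranges", {
  nets <- gen_network_ensemble(ensemble_spec(51, seed = 11))
  sizes <- vapply(nets, function(n) length(n$labels), numeric(1))
  dens <- vapply(nets, network_density, numeric(1))
  expect_true(all(sizes >= 5 & sizes <= 120))
  expect_true(all(dens >= 0.067 - 0.01 & dens <= 0.861 + 0.01))
  expect_equal(length(nets), 51)

  k5 <- gen_network_ensemble(ensemble_spec(1, node_range = c(5, 5),
                                           density_range = c(1, 1), seed = 2))[[1]]
  expect_equal(connectivity(k5), 10)

  expect_identical(gen_network_ensemble(ensemble_spec(5, seed = 3)),
                   gen_network_ensemble(ensemble_spec(5, seed = 3)))
})
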