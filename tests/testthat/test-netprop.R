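edge_net <- function(from, to, weight = 1, nodes = NULL) {
  as_ppi_network(tibble::tibble(from = from, to = to, weight = weight),
                 threshold = 0, extra_nodes = nodes)
}

test_that("Laplacian normalization matches hand calculations and is contractive", {
  two <- edge_net("A", "B")
  W2 <- normalize_adjacency(two)
  expect_equal(as.matrix(W2), matrix(c(0, 1, 1, 0), 2,
                                     dimnames = list(c("A", "B"), c("A", "B"))))
  star <- edge_net(rep("hub", 3), c("l1", "l2", "l3"))
  Ws <- as.matrix(normalize_adjacency(star))
  expect_equal(Ws["hub", "l1"], 1 / sqrt(3), tolerance = 1e-12)

  set.seed(5)
  for (i in 1:5) {
    n <- 30
    pairs <- t(combn(paste0("n", 1:n), 2))
    keep <- runif(nrow(pairs)) < 0.1
    net <- edge_net(pairs[keep, 1], pairs[keep, 2],
                    weight = runif(sum(keep), 0.7, 1),
                    nodes = paste0("n", 1:n))
    ev <- eigen(as.matrix(normalize_adjacency(net)), only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-10)
  }
})

test_that("propagation matches the closed-form solve", {
  two <- edge_net("A", "B")
  W <- normalize_adjacency(two)
  f <- propagate(c(A = 1, B = 0), W, alpha = 0.5, iters = 30)
  expect_equal(unname(f), c(2 / 3, 1 / 3), tolerance = 1e-6)

  # alpha = 0 returns the input
  expect_equal(propagate(c(A = 1, B = 0), W, alpha = 0, iters = 30),
               c(A = 1, B = 0))

  # isolated nodes keep (1 - alpha) * f0, as the closed form dictates
  iso <- edge_net("A", "B", nodes = c("A", "B", "C"))
  Wi <- normalize_adjacency(iso)
  f0 <- c(A = 1, B = 0, C = 2)
  fi <- propagate(f0, Wi, 0.5, 30)
  expect_equal(unname(fi["C"]), 0.5 * 2, tolerance = 1e-12)
  expect_equal(fi, propagate_closed_form(f0, Wi, 0.5), tolerance = 1e-6)

  # random graph with <= 200 nodes: 30 iterations are within 1e-6 of the solve
  set.seed(12)
  n <- 150
  pairs <- t(combn(paste0("n", 1:n), 2))
  keep <- runif(nrow(pairs)) < 0.05
  net <- edge_net(pairs[keep, 1], pairs[keep, 2],
                  weight = runif(sum(keep), 0.7, 1), nodes = paste0("n", 1:n))
  W <- normalize_adjacency(net)
  f0 <- setNames(rexp(n), paste0("n", 1:n))
  expect_lt(max(abs(propagate(f0, W, 0.5, 30) -
                    propagate_closed_form(f0, W, 0.5))), 1e-6)
})

test_that("topology-bias correction nulls constants and removes hub excess", {
  set.seed(13)
  n <- 60
  pairs <- t(combn(paste0("n", 1:n), 2))
  keep <- runif(nrow(pairs)) < 0.08
  net <- edge_net(pairs[keep, 1], pairs[keep, 2], nodes = paste0("n", 1:n))
  W <- normalize_adjacency(net)

  const <- setNames(rep(3, n), paste0("n", 1:n))
  res <- topology_bias_correct(const, W)
  expect_lt(max(abs(res$f_corr)), 1e-12)

  # hub with many leaves, equal initial scores: correction removes the
  # uncorrected hub excess
  star <- edge_net(rep("hub", 20), paste0("leaf", 1:20))
  Ws <- normalize_adjacency(star)
  f0 <- setNames(rep(1, 21), rownames(Ws))
  rs <- topology_bias_correct(f0, Ws)
  hub_raw_excess <- rs$f[rs$node == "hub"] - mean(rs$f[rs$node != "hub"])
  hub_corr_excess <- rs$f_corr[rs$node == "hub"] - mean(rs$f_corr[rs$node != "hub"])
  expect_lt(abs(hub_corr_excess), abs(hub_raw_excess))

  # ring (regular graph): the bias term is constant across nodes
  ring <- edge_net(paste0("r", 1:12), paste0("r", c(2:12, 1)))
  rr <- topology_bias_correct(setNames(rnorm(12), paste0("r", 1:12)),
                              normalize_adjacency(ring))
  expect_lt(diff(range(rr$bias)), 1e-10)
})

test_that("top-fraction selection uses floor and deterministic tie-breaks", {
  res <- tibble::tibble(node = sprintf("n%03d", 1:100), f_corr = rep(1, 100))
  expect_equal(select_top(res, 0.02), c("n001", "n002"))   # ties -> id order
  res50 <- tibble::tibble(node = sprintf("n%02d", 1:50), f_corr = 50:1)
  expect_equal(select_top(res50, 0.02), "n01")
  expect_warning(out <- select_top(res50[1:10, ], 0.02), "empty")
  expect_length(out, 0)
  expect_error(select_top(res50, 0), "fraction")
})

test_that("induced-subgraph components partition the node set and find planted complexes", {
  cfg <- tiny_config(n_proteins = 120, n_complexes = 3, complex_size = 5,
                     p_in = 1, p_out = 0)
  tr <- simulate_truth(cfg, 2)
  net <- simulate_network(tr, cfg, 2)
  members <- tr$complexes[[1]]
  singletons <- setdiff(tr$proteins, unlist(tr$complexes))[1:4]
  res <- extract_subnetworks(c(members, singletons), net)
  expect_setequal(res$node, c(members, singletons))
  expect_equal(anyDuplicated(res$node), 0L)
  # the complex is one component of size 5 and density 1
  comp_of <- res$component[match(members, res$node)]
  expect_length(unique(comp_of), 1)
  summ <- attr(res, "summary")
  expect_equal(summ$n_nodes[summ$component == comp_of[1]], 5L)
  expect_equal(summ$density[summ$component == comp_of[1]], 1)
  # disconnected nodes are singleton components
  expect_equal(sum(summ$n_nodes == 1), 4L)

  expect_error(extract_subnetworks(c(members, "nope"), net), "not in the network")
})
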