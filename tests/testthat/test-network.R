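test_that("condensate graph edges come from inter-chain sticker contacts only", {
  # two chains with one Y-Y adjacency -> one edge
  cfg <- toy_config(list(line_chain(3, c(0, 0, 0)), line_chain(3, c(0, 1, 0))),
                    20, residues = list(c("Y", "G", "G"), c("Y", "G", "G")))
  g <- build_condensate_graph(cfg)
  expect_equal(igraph::ecount(g), 1)

  # adjacency only between a sticker and a spacer -> no edge
  cfg <- toy_config(list(line_chain(3, c(0, 0, 0)), line_chain(3, c(2, 1, 0))),
                    20, residues = list(c("Y", "G", "G"), c("G", "G", "Y")))
  # chain 1 bead Y at (0,0,0); chain 2 beads at (2,1,0),(3,1,0),(4,1,0) with Y
  # at (4,1,0): only spacer-sticker or spacer-spacer adjacencies exist
  g <- build_condensate_graph(cfg, restrict = FALSE)
  expect_equal(igraph::ecount(g), 0)

  # planted 5-chain toy config: edge set equals a brute-force audit
  set.seed(31)
  seqs <- replicate(5, generate_sequence(6, 0.34, "random", seed = 17),
                    simplify = FALSE)
  cfg <- build_lattice_config(seqs, 1, 7)
  g <- build_condensate_graph(cfg, restrict = FALSE)
  # brute force over all inter-chain sticker pairs
  expected <- matrix(0L, 5, 5)
  st <- which(cfg$sticker)
  for (i in st) for (j in st) {
    ci <- cfg$chain_id[i]; cj <- cfg$chain_id[j]
    if (ci < cj && mi_dist(cfg$coords[i, ], cfg$coords[j, ], 7) <= sqrt(3) + 1e-9) {
      expected[ci, cj] <- 1L
    }
  }
  got <- igraph_to_adj(g)
  expect_equal(got[upper.tri(got)] * 1L, expected[upper.tri(expected)])
})

test_that("betweenness matches closed forms and brute-force enumeration", {
  path3 <- igraph::make_graph(~ a - b, b - c)
  expect_equal(betweenness_centrality(path3), c(0, 1, 0))
  expect_equal(betweenness_centrality(path3, ordered = TRUE), c(0, 2, 0))
  expect_equal(betweenness_centrality(igraph::make_full_graph(6)), rep(0, 6))

  set.seed(7)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    g <- random_connected_graph(n, runif(1, 0.25, 0.6))
    expect_equal(betweenness_centrality(g), brute_betweenness(igraph_to_adj(g)),
                 tolerance = 1e-10)
  }
})

test_that("small-world summary matches hand enumeration and brute force", {
  tri <- igraph::make_full_graph(3)
  sw <- small_world_summary(tri)
  expect_equal(sw$L, 1)
  expect_equal(sw$C, 1)

  star5 <- igraph::make_star(5, mode = "undirected")
  sw <- small_world_summary(star5)
  expect_equal(sw$L, (4 * 1 + 6 * 2) * 2 / (5 * 4))  # = 1.6
  expect_equal(sw$C, 0)

  set.seed(19)
  for (rep in 1:6) {
    g <- random_connected_graph(sample(6:12, 1), runif(1, 0.3, 0.6))
    adj <- igraph_to_adj(g)
    sw <- small_world_summary(g)
    expect_equal(sw$L, brute_mean_path_length(adj), tolerance = 1e-12)
    expect_equal(sw$C, brute_clustering(adj), tolerance = 1e-12)
    expect_equal(sw$L_ER, log(igraph::vcount(g)) / log(mean(igraph::degree(g))))
    expect_equal(sw$C_ER, mean(igraph::degree(g)) / igraph::vcount(g))
  }
})

test_that("betweenness sums relate to path lengths via the combinatorial identity", {
  # sum of unordered-pair betweenness over nodes = sum over pairs of
  # (path length - 1) for connected unit-weight graphs
  set.seed(23)
  for (rep in 1:5) {
    g <- random_connected_graph(sample(7:12, 1), runif(1, 0.3, 0.5))
    D <- brute_distances(igraph_to_adj(g))
    expect_equal(sum(betweenness_centrality(g)),
                 sum(D[upper.tri(D)] - 1), tolerance = 1e-9)
  }
})

test_that("Watts-Strogatz fixtures reproduce the canonical small-world regime", {
  # p = 0 ring lattice: closed-form clustering, no rewiring randomness
  g0 <- make_ws_graph(60, 6, 0, seed = 1)
  sw0 <- small_world_summary(g0)
  expect_equal(sw0$C, 3 * (6 - 2) / (4 * (6 - 1)), tolerance = 1e-12)

  # small rewiring: clustering far above random, path length near random
  g <- make_ws_graph(500, 10, 0.1, seed = 2)
  sw <- small_world_summary(g)
  expect_gt(sw$C_ratio, 5)
  expect_lt(sw$L_ratio, 2)

  # p = 1: clustering close to the Erdos-Renyi value
  g1 <- make_ws_graph(500, 10, 1, seed = 3)
  sw1 <- small_world_summary(g1)
  expect_lt(sw1$C_ratio, 2.5)
})

test_that("planted hubs take the top betweenness ranks", {
  ph <- make_planted_hub_graph(80, n_hubs = 2, seed = 5)
  b <- betweenness_centrality(ph$graph)
  top <- order(-b)[1:2]
  expect_setequal(top, ph$hubs)
  sel <- condensr:::top_centrality_chains(ph$graph, top_fraction = 0.05)
  expect_true(all(ph$hubs %in% sel) || length(sel) < 2)
})

test_that("centrality distance distribution handles fixtures and ties", {
  # two hubs at a known separation: median distance equals the separation
  ph <- make_planted_hub_graph(40, n_hubs = 2, seed = 8)
  # build a fake single-bead-chain configuration: hubs at distance 7
  n <- igraph::vcount(ph$graph)
  coords <- cbind(seq_len(n) %% 20, (seq_len(n) %/% 20) * 3L, 0L)
  coords[ph$hubs[1], ] <- c(0L, 10L, 0L)
  coords[ph$hubs[2], ] <- c(7L, 10L, 0L)
  seqs <- replicate(n, encode_sequence("Y"), simplify = FALSE)
  cfg <- lattice_config(coords, seq_len(n), seqs, 40L)
  cd <- centrality_distance_distribution(cfg, ph$graph, top_fraction = 2 / n)
  expect_equal(cd$median, 7)
  expect_setequal(cd$chains, ph$hubs)

  # deterministic tie rule: identical betweenness resolved by chain id
  ring <- igraph::make_ring(20)
  igraph::V(ring)$chain <- 1:20
  expect_identical(condensr:::top_centrality_chains(ring, 0.1), 1:2)
})

test_that("centrality persistence is 1 for frozen dynamics and ~5% under the null", {
  seqs <- replicate(30, generate_sequence(4, 0.5, "uniform"), simplify = FALSE)
  cfg <- build_lattice_config(seqs, 1, 10)
  tr <- run_simulation(cfg, default_contact_model(), 45, n_sweeps = 40,
                       seed = 3, snapshot_interval = 10,
                       moves = move_set(local_only = TRUE))
  frozen <- tr
  frozen$frames <- rep(tr$frames[1], 6)
  frozen$steps <- seq(0L, 50L, 10L)
  frozen$energies <- rep(tr$energies[1], 6)
  p <- centrality_persistence(frozen, 10, top_fraction = 0.1,
                              equilibrated_only = FALSE)
  expect_equal(p$probability, 1)

  # random relabeling null: probability ~ top_fraction
  set.seed(77)
  n <- 200
  null_sets <- replicate(60, sort(sample.int(n, 10)), simplify = FALSE)
  hits <- vapply(seq_len(59), function(i) {
    mean(null_sets[[i]] %in% null_sets[[i + 1]])
  }, numeric(1))
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("ratio of association follows its arithmetic and invariances", {
  # hand-built: sequence config with n_st = 6, n_sp = 18 vs reference 8/16
  # -> (6/24)/(8/24) = 0.75; emulate via direct census on constructed triads
  seq_y <- encode_sequence("YGY", id = "s")
  # reference vs itself -> exactly 1
  cfg <- toy_config(list(line_chain(3, c(0, 0, 0)), line_chain(3, c(0, 1, 0))),
                    12, residues = list(c("Y", "G", "Y"), c("Y", "G", "Y")))
  res <- ratio_of_association(cfg, cfg, dense_only = FALSE)
  expect_equal(res$g_a, 1)

  # translation invariance of g_a
  cfg2 <- set_coords(cfg, sweep(cfg$coords, 2, c(4L, 2L, 7L),
                                function(a, s) (a + s) %% 12L))
  seq_cfg <- toy_config(list(line_chain(3, c(0, 0, 0)), line_chain(3, c(1, 1, 1))),
                        12, residues = list(c("Y", "Y", "G"), c("G", "Y", "Y")))
  r1 <- ratio_of_association(seq_cfg, cfg, dense_only = FALSE)
  r2 <- ratio_of_association(seq_cfg, cfg2, dense_only = FALSE)
  expect_equal(r1$g_a, r2$g_a)

  # direct arithmetic on the census
  a <- condensr:::association_probability(seq_cfg, dense_only = FALSE)
  b <- condensr:::association_probability(cfg, dense_only = FALSE)
  expect_equal(r1$g_a, a$p_a / b$p_a)
  expect_error(ratio_of_association(
    toy_config(list(line_chain(2)), 10,
               residues = list(c("G", "G"))), cfg), "sticker")
})

test_that("sticker-depleted sequences associate less at matched conditions", {
  # same condensate geometry, fewer stickers: g_a < 1 against the full-
  # sticker reference under identical coordinates
  set.seed(55)
  seqs_full <- replicate(40, generate_sequence(6, 0.5, "uniform"),
                         simplify = FALSE)
  cfg_full <- build_lattice_config(seqs_full, 1, 10)
  seqs_dep <- replicate(40, generate_sequence(6, 1 / 6, "uniform"),
                        simplify = FALSE)
  cfg_dep <- cfg_full
  cfg_dep$sequences <- seqs_dep
  cfg_dep$sticker <- unlist(lapply(seqs_dep, `[[`, "sticker_mask"))
  r <- ratio_of_association(cfg_dep, cfg_full, dense_only = FALSE)
  expect_lt(r$g_a, 1)
})

test_that("Weibull cluster machinery: closed form, exact linearisation, recovery", {
  # closed form: P(lambda - 1) = 1 - 1/e
  expect_equal(weibull_cluster_cdf(10 - 1, 10, 1.5), 1 - exp(-1))

  # regression on exact CDF points reproduces (lambda, k) to 1e-9:
  # construct per-size probabilities exactly from the CDF
  lambda <- 7; k <- 1.3
  s <- 1:40
  P <- weibull_cluster_cdf(s, lambda, k)
  x <- log(s + 1); y <- log(-log(1 - P))
  fit <- lm(y ~ x)
  expect_equal(unname(coef(fit)[2]), k, tolerance = 1e-9)
  expect_equal(exp(-unname(coef(fit)[1]) / k), lambda, tolerance = 1e-9)

  # sampling recovery within 5% at n = 1e5
  sizes <- sample_weibull_clusters(10, 1.5, 1e5, seed = 3)
  tab <- table(sizes)
  s <- as.integer(names(tab)); w <- as.numeric(tab)
  Pemp <- cumsum(w) / sum(w)
  use <- Pemp < 1 - 1e-12
  fit <- lm(log(-log(1 - Pemp[use])) ~ log(s[use] + 1), weights = w[use])
  k_hat <- unname(coef(fit)[2]); l_hat <- exp(-unname(coef(fit)[1]) / k_hat)
  expect_equal(k_hat, 1.5, tolerance = 0.05)
  expect_equal(l_hat, 10, tolerance = 10 * 0.05)

  # empirical CDF vs the closed form: KS distance < 0.01 at n = 1e5
  ks <- max(abs(Pemp - weibull_cluster_cdf(s, 10, 1.5)))
  expect_lt(ks, 0.01)

  # all-isolated stickers: degenerate, rejected
  cfg <- toy_config(list(line_chain(1, c(0, 0, 0)), line_chain(1, c(5, 5, 5))),
                    20)
  expect_error(sticker_cluster_weibull(cfg), "fewer than 3")
})

test_that("per-sticker cluster probabilities sum to one per configuration", {
  set.seed(12)
  seqs <- replicate(8, generate_sequence(6, 0.5, "random", seed = 2),
                    simplify = FALSE)
  cfg <- build_lattice_config(seqs, 1, 8)
  sizes <- condensr:::sticker_cluster_sizes(cfg)
  expect_equal(sum(sizes), sum(cfg$sticker))  # every sticker in one cluster
  tab <- table(sizes)
  p <- as.numeric(tab) * as.integer(names(tab))
  expect_equal(sum(p / sum(p)), 1)
})

test_that("conditional betweenness and contact lifetimes behave on fixtures", {
  # regular ring: all nodes share degree and betweenness
  ring <- igraph::make_ring(12)
  b <- betweenness_by_degree(ring, 2)
  expect_length(b, 12)
  expect_equal(max(b) - min(b), 0)
  expect_message(betweenness_by_degree(ring, 5), "no nodes")

  # contact formed and broken after exactly 7 recorded sweeps -> lifetime 7
  base <- toy_config(list(line_chain(1, c(0, 0, 0)), line_chain(1, c(5, 5, 5))),
                     16)
  near <- toy_config(list(line_chain(1, c(0, 0, 0)), line_chain(1, c(1, 1, 0))),
                     16)
  frames <- c(list(base$coords), rep(list(near$coords), 7),
              list(base$coords), list(base$coords))
  fake <- list(config = base, frames = frames,
               steps = seq(0L, by = 1L, length.out = length(frames)),
               energies = rep(0, length(frames)), temperature = 10, seed = 1,
               moves = move_set(local_only = TRUE), acceptance = NULL,
               energy_drift = 0)
  class(fake) <- "lattice_trajectory"
  lt <- sticker_contact_lifetime(fake, equilibrated_only = FALSE)
  expect_equal(lt$mean_lifetime, 7)
  expect_equal(lt$n_episodes, 1)
})

test_that("shuffled-centrality null shows no RMSD-centrality trend", {
  # permutation null: random per-chain displacements are independent of an
  # arbitrary centrality labelling, so the binned means are flat within noise
  set.seed(99)
  rmsd <- abs(rnorm(500, 5, 0.5))
  cent <- sample(500)
  bins <- cut(cent, 5)
  mns <- tapply(rmsd, bins, mean)
  fit <- lm(mns ~ seq_along(mns))
  expect_gt(summary(fit)$coefficients[2, 4], 0.01)  # slope not significant
})
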