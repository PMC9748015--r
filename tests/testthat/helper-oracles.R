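# Brute-force oracles and small construction helpers shared across tests.
# Everything here is deliberately independent of the package internals: the
# oracles enumerate pairs/paths directly so they can certify the optimised
# implementations.

# minimum-image euclidean distance between two coordinate rows
mi_dist <- function(a, b, L) {
  d <- abs(a - b)
  d <- pmin(d, L - d)
  sqrt(sum(d^2))
}

# O(n^2) contact-energy oracle: all unordered nonbonded pairs within sqrt(3)
brute_energy <- function(config, model) {
  xyz <- config$coords
  n <- nrow(xyz)
  L <- config$box_side
  types <- MODEL_ALPHABET[config$bead_type]
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      bonded <- config$chain_id[i] == config$chain_id[j] && abs(i - j) == 1
      if (bonded) next
      if (mi_dist(xyz[i, ], xyz[j, ], L) <= sqrt(3) + 1e-12) {
        e <- e + model$energies[types[i], types[j]]
      }
    }
  }
  e
}

# build a lattice_config from explicit per-chain coordinate matrices
toy_config <- function(chains_xyz, box_side, residues = NULL) {
  lens <- vapply(chains_xyz, nrow, integer(1))
  if (is.null(residues)) residues <- lapply(lens, function(l) rep("Y", l))
  seqs <- Map(function(res, i) {
    encode_sequence(paste(res, collapse = ""), id = paste0("c", i))
  }, residues, seq_along(residues))
  lattice_config(do.call(rbind, chains_xyz),
                 rep(seq_along(lens), lens), seqs, box_side)
}

# straight-line chain along x starting at `at`
line_chain <- function(n, at = c(0, 0, 0)) {
  cbind(at[1] + seq_len(n) - 1, at[2], at[3])
}

# all-pairs shortest-path matrix by breadth-first search (unit weights)
brute_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] > 0))))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# brute-force unordered-pair betweenness: enumerate every shortest path via
# path counting over the BFS DAG
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- brute_distances(adj)
  # sigma[s, t]: number of shortest paths
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (d in sort(unique(D[s, D[s, ] < Inf]))) {
      if (d == 0) next
      for (v in which(D[s, ] == d)) {
        preds <- which(adj[v, ] > 0 & D[s, ] == d - 1)
        sigma[s, v] <- sum(sigma[s, preds])
      }
    }
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || D[s, t] == Inf) next
        if (D[s, v] + D[v, t] == D[s, t]) {
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  b
}

brute_mean_path_length <- function(adj) {
  D <- brute_distances(adj)
  mean(D[upper.tri(D)])
}

brute_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  mean(ci)
}

igraph_to_adj <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
}

random_connected_graph <- function(n, p) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) >= n - 1) return(g)
  }
}
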