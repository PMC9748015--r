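# Synthetic-fixture generators with known ground truth, so every analysis
# stage can be tested without running simulations. All generators are
# deterministic given their seed and return their ground-truth parameters
# alongside the data.

#' Generate a sticker-and-spacer test sequence
#'
#' Builds a PLCD-like sequence with an exact sticker count and a chosen
#' placement pattern: `"uniform"` spreads the stickers evenly along the
#' chain (the natural aromatic patterning of prion-like domains), `"blocky"`
#' packs them into one contiguous block, `"random"` places them uniformly at
#' random.
#'
#' @param length chain length (>= 1).
#' @param sticker_fraction fraction of sticker residues, in (0, 1).
#' @param patterning `"uniform"`, `"blocky"` or `"random"`.
#' @param seed RNG seed (used by `"random"`).
#' @param sticker,spacer one-letter codes used for the two classes.
#' @param id sequence label.
#' @return An `encoded_sequence` with attribute `sticker_positions`.
#' @export
generate_sequence <- function(length, sticker_fraction = 0.2,
                              patterning = c("uniform", "blocky", "random"),
                              seed = 1L, sticker = "Y", spacer = "G",
                              id = NULL) {
  patterning <- match.arg(patterning)
  if (sticker_fraction <= 0 || sticker_fraction >= 1) {
    stop("sticker_fraction must be in (0, 1)")
  }
  n_st <- round(length * sticker_fraction)
  if (n_st < 1) stop("sticker_fraction too small for this length")
  pos <- switch(patterning,
    uniform = round(seq(1, length, length.out = n_st + 2L))[-c(1L, n_st + 2L)],
    blocky = seq_len(n_st) + (length - n_st) %/% 2L,
    random = { set.seed(seed); sort(sample.int(length, n_st)) })
  pos <- unique(pmin(length, pmax(1L, pos)))
  while (length(pos) < n_st) {  # uniform rounding can collide on short chains
    pos <- sort(union(pos, setdiff(seq_len(length), pos)[1]))
  }
  chars <- rep(spacer, length)
  chars[pos] <- sticker
  if (is.null(id)) {
    id <- sprintf("synth_%s_N%d_f%.2f", patterning, length, sticker_fraction)
  }
  out <- encode_sequence(paste(chars, collapse = ""), id = id)
  attr(out, "sticker_positions") <- pos
  out
}

#' Planted-droplet lattice configuration
#'
#' Places chains so that the expected shell density follows the
#' hyperbolic-tangent interface profile with the given parameters:
#' `log10 phi(r)` interpolates between the dense plateau `phi_dense` inside
#' `r_mid` and the dilute plateau `phi_dilute` outside, over a width
#' `delta`. Chains are grown site-by-site with per-site acceptance
#' probability equal to the target profile, which yields a legal
#' configuration by construction (this is a statistical fixture, not
#' simulation physics). Ground-truth parameters are attached.
#'
#' @param box_side box side (l.u.).
#' @param phi_dilute,phi_dense dilute/dense target volume fractions
#'   (`phi_dilute < phi_dense`).
#' @param r_mid interface midpoint (l.u.); droplet must fit in the box.
#' @param delta interface width (l.u.).
#' @param chain_length beads per chain.
#' @param seed RNG seed.
#' @param sequence optional `encoded_sequence` template for all chains
#'   (default an all-sticker chain, convenient for crosslink tests).
#' @return A `lattice_config` with attribute `ground_truth`
#'   (list phi_dilute, phi_dense, r_mid, delta, seed).
#' @export
make_droplet_config <- function(box_side, phi_dilute, phi_dense, r_mid, delta,
                                chain_length = 8L, seed = 1L,
                                sequence = NULL) {
  if (phi_dilute >= phi_dense) stop("phi_dilute must be below phi_dense")
  if (phi_dilute <= 0 || phi_dense > 0.9) stop("infeasible target densities")
  if (r_mid + delta / 2 > box_side / 2) stop("droplet does not fit in the box")
  L <- as.integer(box_side)
  ctr <- rep((L - 1) / 2, 3)
  g <- seq_len(L) - 1
  d1 <- pmin(abs(g - ctr[1]), L - abs(g - ctr[1]))
  r <- sqrt(outer(outer(d1^2, d1^2, `+`), d1^2, `+`))  # x fastest: site order
  lphi <- (log10(phi_dense) + log10(phi_dilute)) / 2 -
    (log10(phi_dense) - log10(phi_dilute)) / 2 * tanh(2 * (r - r_mid) / delta)
  w <- as.numeric(10^lphi)
  n_target <- sum(w)
  n_chains <- max(1L, round(n_target / chain_length))
  set.seed(seed)
  coords <- cpp_grow_chains(rep(as.integer(chain_length), n_chains), L, w,
                            max_restarts = 20000L)
  if (is.null(sequence)) {
    sequence <- encode_sequence(paste(rep("Y", chain_length), collapse = ""),
                                id = "droplet_chain")
  }
  stopifnot(length(sequence) == chain_length)
  cfg <- lattice_config(coords, rep(seq_len(n_chains), each = chain_length),
                        rep(list(sequence), n_chains), L)
  attr(cfg, "ground_truth") <- list(phi_dilute = phi_dilute,
                                    phi_dense = phi_dense,
                                    r_mid = r_mid, delta = delta, seed = seed)
  cfg
}

#' Planted-hub graph
#'
#' Builds `n_hubs` dense communities connected in a ring exclusively through
#' bridge nodes (the hubs): every shortest path between communities passes
#' through a hub, guaranteeing the hubs the top betweenness centralities.
#'
#' @param n total number of nodes.
#' @param n_hubs number of planted hubs (>= 2).
#' @param seed RNG seed.
#' @param p_within edge probability inside a community.
#' @return list with `graph` (igraph) and `hubs` (vertex ids).
#' @export
make_planted_hub_graph <- function(n, n_hubs = 2L, seed = 1L, p_within = 0.8) {
  if (n_hubs >= n / 4) stop("n must comfortably exceed n_hubs")
  set.seed(seed)
  n_comm <- n - n_hubs
  sizes <- rep(n_comm %/% n_hubs, n_hubs)
  sizes[seq_len(n_comm %% n_hubs)] <- sizes[seq_len(n_comm %% n_hubs)] + 1L
  comm_of <- rep(seq_len(n_hubs), sizes)
  members <- split(seq_len(n_comm), comm_of)
  edges <- NULL
  for (m in members) {  # dense within-community wiring, kept connected
    pairs <- t(utils::combn(m, 2))
    take <- runif(nrow(pairs)) < p_within
    ring <- cbind(m, c(m[-1], m[1]))[seq_len(length(m) - 1), , drop = FALSE]
    edges <- rbind(edges, pairs[take, , drop = FALSE], ring)
  }
  hubs <- n_comm + seq_len(n_hubs)
  for (h in seq_len(n_hubs)) {  # hub h bridges communities h and h+1
    a <- members[[h]]
    b <- members[[(h %% n_hubs) + 1L]]
    edges <- rbind(edges,
                   cbind(hubs[h], sample(a, max(2L, length(a) %/% 2L))),
                   cbind(hubs[h], sample(b, max(2L, length(b) %/% 2L))))
  }
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  igraph::V(g)$chain <- seq_len(n)
  list(graph = g, hubs = hubs)
}

#' Watts-Strogatz small-world test graph
#'
#' Ring lattice of `n` nodes with `k` neighbours each, rewired with
#' probability `p`. At `p = 0` the local clustering coefficient has the
#' closed form `3 (k - 2) / (4 (k - 1))`; at small `p` the graph shows the
#' canonical small-world signature (clustering far above, path length close
#' to, the Erdos-Renyi reference).
#'
#' @param n nodes.
#' @param k even neighbourhood size (`k < n`).
#' @param p rewiring probability.
#' @param seed RNG seed.
#' @return An igraph graph.
#' @export
make_ws_graph <- function(n, k, p, seed = 1L) {
  if (k %% 2 != 0 || k >= n) stop("k must be even and below n")
  set.seed(seed)
  g <- igraph::sample_smallworld(1, n, k / 2, p)
  igraph::V(g)$chain <- seq_len(n)
  igraph::simplify(g)
}

#' Sample sticker-cluster sizes from a discrete Weibull distribution
#'
#' Draws cluster sizes on the physical support `s >= 1` with cumulative
#' probability `P(S <= s) = 1 - exp(-((s+1)/lambda)^k)` for every `s >= 1`
#' (the nominal mass of the continuous-form CDF below s = 1 is absorbed into
#' s = 1), via inverse-CDF sampling.
#'
#' @param lambda scale parameter (> 0).
#' @param k shape parameter (> 0).
#' @param n_samples number of clusters to draw.
#' @param seed RNG seed.
#' @return Integer vector of sizes with attribute `ground_truth`.
#' @export
sample_weibull_clusters <- function(lambda, k, n_samples, seed = 1L) {
  stopifnot(lambda > 0, k > 0, n_samples >= 1)
  set.seed(seed)
  u <- runif(n_samples)
  s <- ceiling(lambda * (-log(1 - u))^(1 / k) - 1)
  s <- as.integer(pmax(1L, s))
  attr(s, "ground_truth") <- list(lambda = lambda, k = k, seed = seed)
  s
}

#' Binodal-arm pair with a known log offset
#'
#' Returns a (simulated, experimental) pair of dilute arms whose true ERMSL
#' is `10^|log10_offset|` by construction: the simulated arm is the base arm
#' with every concentration multiplied by `10^log10_offset`, optionally with
#' deterministic log-normal jitter (which makes the ERMSL a known function
#' of the jitter draws, returned as ground truth).
#'
#' @param base_arm data.frame with columns `T` and `c`; a default UCST-like
#'   dilute arm over T = 40..60 is used when omitted.
#' @param log10_offset log10 multiplicative offset of the simulated arm.
#' @param jitter_sd standard deviation of log10 jitter (default 0).
#' @param seed RNG seed for the jitter.
#' @return list with `sim`, `exp` (data.frames) and `true_ermsl`.
#' @export
make_binodal_pair <- function(base_arm = NULL, log10_offset = 0,
                              jitter_sd = 0, seed = 1L) {
  if (is.null(base_arm)) {
    temps <- seq(40, 60, by = 2.5)
    base_arm <- data.frame(T = temps,
                           c = 10^(-4 + 0.12 * (temps - min(temps))))
  }
  stopifnot(all(c("T", "c") %in% names(base_arm)), all(base_arm$c > 0))
  set.seed(seed)
  eps <- if (jitter_sd > 0) rnorm(nrow(base_arm), 0, jitter_sd) else
    rep(0, nrow(base_arm))
  sim <- base_arm
  sim$c <- base_arm$c * 10^(log10_offset + eps)
  list(sim = sim, exp = base_arm,
       true_ermsl = 10^sqrt(mean((log10_offset + eps)^2)))
}
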