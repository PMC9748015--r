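# Condensate graph construction and topology/dynamics statistics:
# betweenness, small-world summaries vs Erdos-Renyi references, centrality
# dynamics, ratio of association, sticker-cluster Weibull statistics.

#' Build the condensate contact graph
#'
#' Nodes are chains; an undirected edge joins two chains when any pair of
#' stickers between them is within the contact range (sqrt(3) l.u., minimum
#' image). Bonded pairs cannot be inter-chain, so all inter-chain sticker
#' adjacencies count. The graph is restricted to the largest connected
#' component, which is identified with the condensate.
#'
#' @param config a `lattice_config` with sticker flags.
#' @param model unused placeholder (contact range fixed at sqrt(3)).
#' @param restrict restrict to the largest connected component (default TRUE).
#' @return An `igraph` graph whose vertex attribute `chain` holds the
#'   original chain indices.
#' @export
build_condensate_graph <- function(config, model = NULL, restrict = TRUE) {
  if (length(config$sequences) == 0) stop("configuration has no chains")
  cp <- cpp_contact_pairs(config$coords, config$chain_id, config$box_side)
  st <- config$sticker
  keep <- cp[, "same_chain"] == 0L & st[cp[, "i"]] & st[cp[, "j"]]
  e <- cp[keep, c("i", "j"), drop = FALSE]
  edges <- unique(cbind(config$chain_id[e[, 1]], config$chain_id[e[, 2]]))
  n <- length(config$sequences)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$chain <- seq_len(n)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  g <- igraph::simplify(g)
  if (restrict) {
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  }
  g
}

#' Betweenness centrality of every node
#'
#' Unnormalised betweenness `g(n) = sum over pairs s != n != t of
#' sigma_st(n) / sigma_st`, where `sigma_st` counts shortest paths between s
#' and t and `sigma_st(n)` those passing through n. The default counts each
#' unordered pair once (the standard undirected convention);
#' `ordered = TRUE` doubles the values to the ordered-pair reading of the sum.
#'
#' @param graph an igraph graph.
#' @param ordered count ordered pairs (doubles the unordered values).
#' @return Numeric vector of betweenness values, one per node.
#' @export
betweenness_centrality <- function(graph, ordered = FALSE) {
  b <- igraph::betweenness(graph, directed = FALSE, weights = NA)
  if (ordered) b <- 2 * b
  unname(b)
}

#' Small-world summary of a graph
#'
#' Mean shortest path length `L = 2/(n(n-1)) * sum d(vi, vj)`, mean local
#' clustering coefficient `C` (average of per-node `C_i = 2 |e_jk| /
#' (k_i (k_i - 1))`, nodes with degree < 2 contributing 0), and the
#' Erdos-Renyi references `L_ER = log(n) / log(<k>)`, `C_ER = <k> / n`
#' together with the normalised ratios used to judge small-world structure.
#'
#' @param graph an igraph graph (n >= 3). Disconnected input is restricted
#'   to its giant component with a warning.
#' @return list with `n`, `mean_degree`, `L`, `C`, `L_ER`, `C_ER`,
#'   `L_ratio`, `C_ratio`.
#' @export
small_world_summary <- function(graph) {
  if (!igraph::is_connected(graph)) {
    warning("graph is disconnected; restricting to the giant component")
    comp <- igraph::components(graph)
    graph <- igraph::induced_subgraph(
      graph, which(comp$membership == which.max(comp$csize)))
  }
  n <- igraph::vcount(graph)
  if (n < 3) stop("need at least 3 nodes")
  k <- mean(igraph::degree(graph))
  L <- igraph::mean_distance(graph, directed = FALSE)
  ci <- igraph::transitivity(graph, type = "local", isolates = "zero")
  C <- mean(ci)
  L_ER <- log(n) / log(k)
  C_ER <- k / n
  list(n = n, mean_degree = k, L = L, C = C, L_ER = L_ER, C_ER = C_ER,
       L_ratio = L / L_ER, C_ratio = C / C_ER)
}

# chains in the top `fraction` of betweenness; ties at the cutoff broken by
# chain id (deterministic)
top_centrality_chains <- function(graph, top_fraction = 0.05) {
  b <- betweenness_centrality(graph)
  chains <- igraph::V(graph)$chain
  if (is.null(chains)) chains <- seq_along(b)
  n_top <- max(1L, floor(length(b) * top_fraction))
  ord <- order(-b, chains)
  sort(chains[ord[seq_len(n_top)]])
}

#' Pairwise distances among the most central chains
#'
#' Selects the `top_fraction` of chains by betweenness centrality (ties at
#' the cutoff broken by chain id) and returns the minimum-image pairwise
#' distances between their centres of mass.
#'
#' @param config a `lattice_config`.
#' @param graph condensate graph from [build_condensate_graph()].
#' @param top_fraction fraction of chains selected (default 0.05).
#' @return list with `distances` (l.u.), `median`, `quantiles` and the
#'   selected `chains`.
#' @export
centrality_distance_distribution <- function(config, graph, top_fraction = 0.05) {
  sel <- top_centrality_chains(graph, top_fraction)
  if (length(sel) < 2) stop("fewer than 2 chains selected; increase top_fraction")
  com <- chain_geometry(config)$com[sel, , drop = FALSE] %% config$box_side
  L <- config$box_side
  idx <- utils::combn(length(sel), 2)
  d <- (com[idx[1, ], , drop = FALSE] - com[idx[2, ], , drop = FALSE] +
          L / 2) %% L - L / 2
  dist <- sqrt(rowSums(d^2))
  list(distances = dist, median = median(dist),
       quantiles = quantile(dist, c(0.05, 0.25, 0.5, 0.75, 0.95)),
       chains = sel)
}

#' Persistence of top-centrality membership over Monte Carlo steps
#'
#' Probability that a chain in the top `top_fraction` of betweenness
#' centralities is still in the top set after `lag` Monte Carlo sweeps,
#' averaged over all frame pairs at that lag. Under a completely uncorrelated
#' null the probability equals `top_fraction`.
#'
#' @param traj a local-only `lattice_trajectory`.
#' @param lag lag in sweeps (must match stored frame spacings).
#' @param top_fraction fraction defining the top set.
#' @param equilibrated_only restrict to the equilibrated window.
#' @return list with `probability` and `n_pairs`.
#' @export
centrality_persistence <- function(traj, lag, top_fraction = 0.05,
                                   equilibrated_only = TRUE) {
  if (!traj$moves$local_only) {
    stop("centrality dynamics require a local-only move set")
  }
  idx <- if (equilibrated_only) as.integer(equilibrated_frames(traj)) else
    seq_along(traj$frames)
  steps <- traj$steps[idx]
  pairs <- which(outer(steps, steps, function(a, b) b - a) == lag, arr.ind = TRUE)
  if (nrow(pairs) == 0) stop("lag does not match any stored frame spacing")
  tops <- lapply(idx, function(f) {
    top_centrality_chains(build_condensate_graph(frame_config(traj, f)),
                          top_fraction)
  })
  frac <- vapply(seq_len(nrow(pairs)), function(p) {
    t1 <- tops[[pairs[p, 1]]]; t2 <- tops[[pairs[p, 2]]]
    mean(t1 %in% t2)
  }, numeric(1))
  list(probability = mean(frac), n_pairs = nrow(pairs))
}

# p_a: relative probability of sticker-sticker vs sticker-spacer contacts,
# over dense-phase stickers (bonded neighbours excluded).
association_probability <- function(config, dense_only = TRUE) {
  cen <- cpp_neighbor_census(config$coords, config$chain_id, config$sticker,
                             config$box_side)
  sel <- config$sticker
  if (dense_only) {
    ph <- assign_phases(config)
    sel <- sel & (ph[config$chain_id] == "dense")
  }
  n_st <- sum(cen[sel, "st_intra"] + cen[sel, "st_inter"])
  n_sp <- sum(cen[sel, "sp_intra"] + cen[sel, "sp_inter"])
  list(p_a = n_st / (n_st + n_sp), n_st = n_st, n_sp = n_sp)
}

#' Ratio of association
#'
#' `g_a = p_a,seq / p_a,ref`, where `p_a` is the probability that a
#' dense-phase sticker's occupied, nonbonded neighbours are stickers rather
#' than spacers, and the reference is the equivalent homopolymer carrying the
#' wild-type sticker-and-spacer architecture.
#'
#' @param config_seq configuration of the sequence of interest.
#' @param config_ref configuration of the homopolymer reference (sticker
#'   architecture imposed).
#' @param dense_only restrict the census to dense-phase stickers.
#' @return list of class `association_result` with `g_a`, `p_a_seq`,
#'   `p_a_ref` and the raw tallies.
#' @export
ratio_of_association <- function(config_seq, config_ref, dense_only = TRUE) {
  if (!any(config_seq$sticker) || !any(config_ref$sticker)) {
    stop("both configurations need sticker flags")
  }
  a <- association_probability(config_seq, dense_only)
  b <- association_probability(config_ref, dense_only)
  if (!is.finite(b$p_a) || b$p_a == 0) {
    stop("reference has no sticker neighbours; ratio undefined")
  }
  structure(list(g_a = a$p_a / b$p_a, p_a_seq = a$p_a, p_a_ref = b$p_a,
                 tallies_seq = a, tallies_ref = b),
            class = "association_result")
}

# connected clusters of stickers under nonbonded sticker-sticker adjacency
# (intra- and inter-chain); returns integer cluster sizes (in stickers)
sticker_cluster_sizes <- function(config) {
  st <- which(config$sticker)
  if (!length(st)) return(integer(0))
  cp <- cpp_contact_pairs(config$coords, config$chain_id, config$box_side)
  keep <- cp[, "bonded"] == 0L & config$sticker[cp[, "i"]] & config$sticker[cp[, "j"]]
  e <- cp[keep, c("i", "j"), drop = FALSE]
  idx <- match(seq_len(nrow(config$coords)), st)  # bead -> sticker index
  g <- igraph::make_empty_graph(length(st), directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, rbind(idx[e[, 1]], idx[e[, 2]]))
  igraph::components(g)$csize
}

#' Sticker-cluster size distribution with a discrete Weibull fit
#'
#' Stickers connected by nonbonded sticker-sticker contacts (within sqrt(3),
#' intra- and inter-chain) form clusters. The probability that a sticker
#' belongs to a cluster of size `s` is the relative cluster frequency
#' multiplied by `s` and normalised; the cumulative probability `P(s)` is fit
#' to the discrete Weibull form `P(s) = 1 - exp(-((s+1)/lambda)^k)` by
#' weighted least squares on the linearisation `ln(-ln(1 - P(s)))` vs
#' `ln(s + 1)`, after removing outliers more than 3 scaled median absolute
#' deviations from the median residual.
#'
#' @param configs a `lattice_config`, a list of them, or a
#'   `lattice_trajectory` (equilibrated frames are used).
#' @param size_range optional integer range of sizes to fit (the "linear
#'   region"); default uses all sizes below the largest observed.
#' @param mad_multiplier outlier cut in scaled MADs (default 3).
#' @return list of class `sticker_cluster_fit`: `table` (size, per-sticker
#'   probability, cumulative `P`), `lambda`, `k`, standard errors, and the
#'   points used.
#' @export
sticker_cluster_weibull <- function(configs, size_range = NULL,
                                    mad_multiplier = 3) {
  if (inherits(configs, "lattice_trajectory")) {
    keep <- equilibrated_frames(configs)
    configs <- lapply(keep, function(f) frame_config(configs, f))
  }
  if (inherits(configs, "lattice_config")) configs <- list(configs)
  sizes <- unlist(lapply(configs, sticker_cluster_sizes))
  if (!length(sizes)) stop("no stickers present")
  tab <- table(sizes)
  s <- as.integer(names(tab))
  w <- as.numeric(tab) * s              # frequency times size: sticker-weighted
  p <- w / sum(w)
  P <- cumsum(p)
  table_out <- data.frame(size = s, prob = p, P = P, n_clusters = as.numeric(tab))
  if (length(s) < 3 || max(s) < 2) {
    stop("fewer than 3 usable cluster sizes; Weibull fit rejected")
  }
  fit <- weibull_linear_fit(s, P, weights = w, size_range = size_range,
                            mad_multiplier = mad_multiplier)
  structure(c(list(table = table_out), fit), class = "sticker_cluster_fit")
}

#' Linearised discrete-Weibull fit of a cumulative size distribution
#'
#' Weighted least squares of `ln(-ln(1 - P(s)))` against `ln(s + 1)`, with
#' optional restriction to a size range and removal of outliers more than
#' `mad_multiplier` scaled median absolute deviations from the median
#' residual. The slope is the shape `k`; the scale is
#' `lambda = exp(-intercept / k)`.
#'
#' @param s integer sizes (ascending).
#' @param P cumulative per-sticker probabilities at `s`.
#' @param weights fit weights (e.g. counts or inverse variances).
#' @param size_range optional fitting range (the "linear region").
#' @param mad_multiplier outlier cut in scaled MADs.
#' @return list with `lambda`, `k`, standard errors, the points used and the
#'   outlier count.
#' @export
weibull_linear_fit <- function(s, P, weights = NULL, size_range = NULL,
                               mad_multiplier = 3) {
  if (is.null(weights)) weights <- rep(1, length(s))
  use <- P < 1 - 1e-12 & P > 0
  if (!is.null(size_range)) use <- use & s >= min(size_range) & s <= max(size_range)
  if (sum(use) < 3) stop("fewer than 3 usable points after filtering; fit rejected")
  x <- log(s[use] + 1)
  y <- log(-log(1 - P[use]))
  wt <- weights[use]
  fit0 <- lm(y ~ x, weights = wt)
  res <- stats::resid(fit0)
  keep_pt <- abs(res - median(res)) <= mad_multiplier * mad(res) | mad(res) == 0
  if (sum(keep_pt) < 3) keep_pt <- rep(TRUE, length(res))
  fit <- lm(y[keep_pt] ~ x[keep_pt], weights = wt[keep_pt])
  k_hat <- unname(coef(fit)[2])
  lambda_hat <- exp(-unname(coef(fit)[1]) / k_hat)
  se <- suppressWarnings(summary(fit)$coefficients[, 2])
  list(lambda = lambda_hat, k = k_hat,
       se_slope = unname(se[2]), se_intercept = unname(se[1]),
       points_used = data.frame(log_s1 = x[keep_pt], lin = y[keep_pt],
                                weight = wt[keep_pt]),
       n_outliers = sum(!keep_pt))
}

#' Fit a discrete Weibull to a per-sticker cluster-size sample
#'
#' Convenience wrapper over [weibull_linear_fit()] for samples already drawn
#' per sticker (e.g. from [sample_weibull_clusters()]): the empirical
#' cumulative distribution of the sizes is fit directly.
#'
#' @param sizes integer size sample.
#' @inheritParams weibull_linear_fit
#' @return As [weibull_linear_fit()].
#' @export
fit_weibull_sample <- function(sizes, size_range = NULL, mad_multiplier = 3) {
  tab <- table(sizes)
  s <- as.integer(names(tab))
  w <- as.numeric(tab)
  P <- cumsum(w) / sum(w)
  weibull_linear_fit(s, P, weights = w, size_range = size_range,
                     mad_multiplier = mad_multiplier)
}

#' Discrete Weibull cumulative probability
#'
#' `P(s) = 1 - exp(-((s+1)/lambda)^k)`.
#'
#' @param s cluster sizes.
#' @param lambda scale parameter (> 0).
#' @param k shape parameter (> 0).
#' @return Cumulative probabilities.
#' @export
weibull_cluster_cdf <- function(s, lambda, k) {
  stopifnot(lambda > 0, k > 0)
  1 - exp(-((s + 1) / lambda)^k)
}

#' Betweenness distribution conditioned on degree
#'
#' Returns the betweenness centralities of all nodes with the given degree,
#' disentangling the degree-betweenness correlation.
#'
#' @param graph an igraph graph.
#' @param degree node degree selecting the conditional class.
#' @return Numeric vector (possibly empty, with a message).
#' @export
betweenness_by_degree <- function(graph, degree) {
  b <- betweenness_centrality(graph)
  sel <- igraph::degree(graph) == degree
  if (!any(sel)) message(sprintf("no nodes with degree %d", degree))
  b[sel]
}

#' Chain mobility binned by betweenness centrality
#'
#' Computes per-chain RMS displacement over `lag` sweeps and bins it by the
#' chain's betweenness centrality in the first equilibrated frame.
#'
#' @param traj a local-only `lattice_trajectory`.
#' @param lag lag in sweeps.
#' @param n_bins number of centrality bins.
#' @return data.frame with bin bounds, mean RMSD and counts.
#' @export
rmsd_by_centrality <- function(traj, lag, n_bins = 5) {
  rmsd <- chain_rmsd_over_steps(traj, lag)
  f0 <- as.integer(equilibrated_frames(traj))[1]
  g <- build_condensate_graph(frame_config(traj, f0))
  b <- setNames(betweenness_centrality(g), igraph::V(g)$chain)
  cent <- b[as.character(rmsd$chain)]
  ok <- !is.na(cent)
  bins <- cut(cent[ok], breaks = n_bins, include.lowest = TRUE)
  data.frame(bin = levels(bins),
             mean_rmsd = as.numeric(tapply(rmsd$rmsd[ok], bins, mean)),
             mean_centrality = as.numeric(tapply(cent[ok], bins, mean)),
             n = as.integer(table(bins)))
}

#' Mean sticker-sticker contact lifetime
#'
#' Tracks specific nonbonded sticker-sticker contacts across stored frames
#' and reports the mean number of Monte Carlo sweeps a contact persists
#' (runs of consecutive frames in which the same bead pair stays in
#' contact).
#'
#' @param traj a local-only `lattice_trajectory`.
#' @param equilibrated_only restrict to the equilibrated window.
#' @return list with `mean_lifetime` (sweeps) and the number of contact
#'   episodes observed.
#' @export
sticker_contact_lifetime <- function(traj, equilibrated_only = TRUE) {
  if (!traj$moves$local_only) stop("contact lifetimes require a local-only move set")
  idx <- if (equilibrated_only) as.integer(equilibrated_frames(traj)) else
    seq_along(traj$frames)
  if (length(idx) < 2) stop("need at least two frames")
  dt <- diff(traj$steps[idx])
  if (length(unique(dt)) != 1) stop("frames must be evenly spaced")
  key_sets <- lapply(idx, function(f) {
    cfg <- frame_config(traj, f)
    cp <- cpp_contact_pairs(cfg$coords, cfg$chain_id, cfg$box_side)
    keep <- cp[, "bonded"] == 0L & cfg$sticker[cp[, "i"]] & cfg$sticker[cp[, "j"]]
    paste(cp[keep, "i"], cp[keep, "j"])
  })
  active <- list()
  lifetimes <- numeric(0)
  prev <- character(0)
  run <- integer(0)
  for (f in seq_along(key_sets)) {
    cur <- key_sets[[f]]
    cont <- intersect(prev, cur)
    ended <- setdiff(prev, cur)
    if (length(ended)) lifetimes <- c(lifetimes, run[ended])
    run_new <- setNames(rep(1L, length(cur)), cur)
    run_new[cont] <- run[cont] + 1L
    run <- run_new
    prev <- cur
  }
  if (length(run)) lifetimes <- c(lifetimes, run)  # right-censored tail runs
  list(mean_lifetime = mean(lifetimes) * dt[1], n_episodes = length(lifetimes))
}
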