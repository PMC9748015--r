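#' Lattice configuration container
#'
#' Holds per-bead integer coordinates of all chains on a periodic cubic
#' lattice, with beads of each chain stored contiguously and in chain order.
#'
#' @param coords integer matrix (n_beads x 3) of coordinates in `[0, box_side)`.
#' @param chain_id integer vector mapping each bead to its chain (1-based,
#'   contiguous blocks).
#' @param sequences list of `encoded_sequence`, one per chain, in chain order.
#' @param box_side lattice box side length (l.u.).
#' @return Object of class `lattice_config`.
#' @export
lattice_config <- function(coords, chain_id, sequences, box_side) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  chain_id <- as.integer(chain_id)
  if (inherits(sequences, "encoded_sequence")) sequences <- list(sequences)
  n_chain <- max(chain_id)
  stopifnot(length(sequences) == n_chain, nrow(coords) == length(chain_id))
  residues <- unlist(lapply(sequences, `[[`, "residues"))
  stopifnot(length(residues) == nrow(coords))
  cfg <- structure(
    list(
      box_side = as.integer(box_side),
      coords = coords,
      chain_id = chain_id,
      bead_type = match(residues, MODEL_ALPHABET),
      sticker = unlist(lapply(sequences, `[[`, "sticker_mask")),
      sequences = sequences,
      sequence_ids = vapply(sequences, `[[`, character(1), "id")
    ),
    class = "lattice_config"
  )
  validate_config(cfg)
  cfg
}

#' Audit the legality of a lattice configuration
#'
#' Checks excluded volume (one bead per site), coordinate ranges and the bond
#' constraint (consecutive beads of a chain within sqrt(3) l.u. under
#' minimum image).
#'
#' @param config a `lattice_config`.
#' @return Invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_config <- function(config) {
  L <- config$box_side
  xyz <- config$coords
  if (any(xyz < 0L) || any(xyz >= L)) stop("coordinates outside [0, box_side)")
  site <- xyz[, 1] + L * (xyz[, 2] + L * xyz[, 3])
  if (anyDuplicated(site)) stop("excluded volume violated: duplicate lattice site")
  same <- diff(config$chain_id) == 0L
  if (any(same)) {
    d <- abs(xyz[-1, , drop = FALSE][same, , drop = FALSE] -
             xyz[-nrow(xyz), , drop = FALSE][same, , drop = FALSE])
    d <- pmin(d, L - d)
    if (any(d > 1L)) stop("bond constraint violated: bonded beads farther than sqrt(3)")
  }
  invisible(TRUE)
}

#' @export
print.lattice_config <- function(x, ...) {
  cat(sprintf("<lattice_config> box %d^3, %d chains, %d beads (occupancy %.4f)\n",
              x$box_side, length(x$sequences), nrow(x$coords),
              nrow(x$coords) / x$box_side^3))
  invisible(x)
}

n_chains <- function(config) length(config$sequences)

chain_lengths <- function(config) tabulate(config$chain_id, n_chains(config))

#' Replace the coordinates of a configuration
#'
#' @param config a `lattice_config`.
#' @param coords new integer coordinate matrix of identical shape.
#' @return The updated configuration (validated).
#' @export
set_coords <- function(config, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  stopifnot(all(dim(coords) == dim(config$coords)))
  config$coords <- coords
  validate_config(config)
  config
}

#' Total contact energy of a configuration
#'
#' Sums the pairwise contact energy over all unordered nonbonded bead pairs
#' within the contact range (the 26-site neighbourhood for the default
#' sqrt(3)), using minimum-image distances under periodic boundaries; bonded
#' consecutive pairs are excluded.
#'
#' @param config a `lattice_config`.
#' @param model a `contact_model`.
#' @return Scalar energy in simulation units.
#' @export
total_energy <- function(config, model) {
  cpp_total_energy(config$coords, config$chain_id, config$bead_type,
                   config$box_side, model$energies)
}

#' Build an initial multi-chain configuration
#'
#' Chains are grown as random walks on vacant sites. `init = "random"`
#' disperses them uniformly through the box; `init = "droplet"` confines the
#' growth to a central ball of radius `init_radius`, giving a pre-formed
#' droplet starting condition for condensate analyses.
#'
#' @param sequences an `encoded_sequence` or list thereof.
#' @param counts number of copies of each sequence.
#' @param box_side box side length (l.u.).
#' @param init `"random"` or `"droplet"`.
#' @param init_radius droplet radius; default packs the chains at ~50%
#'   occupancy.
#' @return A `lattice_config`.
#' @export
build_lattice_config <- function(sequences, counts, box_side,
                                 init = c("random", "droplet"),
                                 init_radius = NULL) {
  init <- match.arg(init)
  if (inherits(sequences, "encoded_sequence")) sequences <- list(sequences)
  counts <- rep_len(as.integer(counts), length(sequences))
  seqs <- rep(sequences, counts)
  lens <- vapply(seqs, length, integer(1))
  L <- as.integer(box_side)
  if (sum(lens) >= L^3) stop("infeasible packing: more beads than lattice sites")
  if (init == "random") {
    w <- rep(1, L^3)
  } else {
    if (is.null(init_radius)) {
      init_radius <- (sum(lens) / 0.5 / (4 / 3 * pi))^(1 / 3)
    }
    if (2 * init_radius > L) stop("droplet does not fit in the box")
    ctr <- (L - 1) / 2
    g <- seq_len(L) - 1
    d1 <- pmin(abs(g - ctr), L - abs(g - ctr))
    r2 <- outer(outer(d1^2, d1^2, `+`), d1^2, `+`)  # x fastest, matches site index
    w <- as.numeric(r2 <= init_radius^2)
    if (sum(w) <= sum(lens)) stop("droplet radius too small for the bead count")
  }
  coords <- cpp_grow_chains(lens, L, w, max_restarts = 5000L)
  lattice_config(coords, rep(seq_along(seqs), lens), seqs, L)
}

default_moveset_weights <- function(moves) {
  c(local = moves$local, colocal = moves$colocal, reptation = moves$reptation,
    chain_translate = moves$chain_translate,
    cluster_translate = moves$cluster_translate)
}

#' Monte Carlo move set
#'
#' Relative attempt frequencies of the five move kinds: local single-bead
#' displacement, co-local two-bead displacement, reptation, whole-chain
#' translation and single-cluster translation. `local_only = TRUE` keeps only
#' the single-bead and co-local moves, the mode used for all
#' dynamics-as-move-count analyses (translations would corrupt the
#' moves-as-time proxy).
#'
#' @param local,colocal,reptation,chain_translate,cluster_translate
#'   nonnegative relative frequencies.
#' @param local_only logical; zero out the non-local moves.
#' @return Object of class `move_set`.
#' @export
move_set <- function(local = 10, colocal = 4, reptation = 2,
                     chain_translate = 1, cluster_translate = 0.2,
                     local_only = FALSE) {
  if (local_only) {
    reptation <- 0; chain_translate <- 0; cluster_translate <- 0
  }
  w <- c(local = local, colocal = colocal, reptation = reptation,
         chain_translate = chain_translate,
         cluster_translate = cluster_translate)
  if (any(w < 0) || sum(w) <= 0) stop("move frequencies must be nonnegative, not all zero")
  structure(list(weights = w, local_only = local_only), class = "move_set")
}

#' Run a Metropolis Monte Carlo simulation
#'
#' Samples configurations with acceptance probability `min(1, exp(-dE/T))`
#' (kB = 1, dimensionless temperature). A sweep attempts one move per bead.
#' Energies are tracked incrementally; the drift against a full recomputation
#' is returned for auditing. Reproducible given `seed`.
#'
#' @param config a `lattice_config` (use [build_lattice_config()] or a
#'   fixture generator), or a list of `encoded_sequence` if `counts` and
#'   `box_side` are supplied.
#' @param model a `contact_model` (or `adjusted_model`).
#' @param temperature dimensionless temperature (> 0).
#' @param n_sweeps number of Monte Carlo sweeps.
#' @param moves a [move_set()].
#' @param seed integer RNG seed.
#' @param snapshot_interval sweeps between stored frames.
#' @param counts,box_side,init used only when `config` is a sequence list;
#'   passed to [build_lattice_config()].
#' @return Object of class `lattice_trajectory`: fields `config` (static
#'   metadata and final coordinates), `frames` (list of coordinate matrices;
#'   frame 1 is the initial configuration at step 0), `steps`, `energies`,
#'   `temperature`, `seed`, `moves`, `acceptance` (per-kind attempt /
#'   accepted / illegal tallies), and `energy_drift`.
#' @export
run_simulation <- function(config, model, temperature, n_sweeps,
                           moves = move_set(), seed = 1L,
                           snapshot_interval = max(1L, n_sweeps %/% 50L),
                           counts = NULL, box_side = NULL,
                           init = "random") {
  if (inherits(model, "adjusted_model")) model <- model$model
  if (!inherits(config, "lattice_config")) {
    set.seed(seed)
    config <- build_lattice_config(config, counts, box_side, init = init)
  }
  stopifnot(inherits(moves, "move_set"), temperature > 0)
  set.seed(seed + 1L)
  res <- cpp_run_mc(config$coords, config$chain_id, config$bead_type,
                    config$box_side, model$energies, temperature,
                    as.integer(n_sweeps), nrow(config$coords),
                    as.integer(snapshot_interval), unname(moves$weights))
  e0 <- total_energy(config, model)
  frames <- c(list(config$coords), res$frames)
  steps <- c(0L, res$frame_steps)
  energies <- c(e0, res$frame_energies)
  acc <- data.frame(kind = names(moves$weights),
                    attempts = res$attempts, accepted = res$accepts,
                    illegal = res$illegal)
  final <- set_coords(config, res$final_coords)
  structure(
    list(
      config = final,
      frames = frames,
      steps = steps,
      energies = energies,
      temperature = temperature,
      seed = seed,
      moves = moves,
      acceptance = acc,
      energy_drift = abs(res$energy_incremental - res$energy_recomputed)
    ),
    class = "lattice_trajectory"
  )
}

#' @export
print.lattice_trajectory <- function(x, ...) {
  cat(sprintf(
    "<lattice_trajectory> %d frames to step %d, T = %g, %d chains, drift %.2e\n",
    length(x$frames), max(x$steps), x$temperature,
    length(x$config$sequences), x$energy_drift))
  invisible(x)
}

#' Perform a single Metropolis sweep
#'
#' Convenience wrapper over [run_simulation()] for one sweep; returns the
#' updated configuration and the acceptance tallies.
#'
#' @inheritParams run_simulation
#' @return list with `config` and `acceptance`.
#' @export
metropolis_sweep <- function(config, model, temperature, moves = move_set(),
                             seed = 1L) {
  tr <- run_simulation(config, model, temperature, n_sweeps = 1L,
                       moves = moves, seed = seed, snapshot_interval = 1L)
  list(config = tr$config, acceptance = tr$acceptance)
}

#' Extract one frame of a trajectory as a configuration
#'
#' @param traj a `lattice_trajectory`.
#' @param i frame index (1 = initial configuration).
#' @return A `lattice_config`.
#' @export
frame_config <- function(traj, i) {
  set_coords(traj$config, traj$frames[[i]])
}

#' Indices of equilibrated frames
#'
#' By default the first half of the stored frames is discarded. A
#' stationarity flag compares the energy means of the two halves of the
#' retained window: they should agree within `n_se` standard errors.
#'
#' @param traj a `lattice_trajectory`.
#' @param discard_fraction fraction of frames discarded from the start.
#' @param n_se stationarity tolerance in standard errors.
#' @return Integer frame indices with attribute `stationary` (logical).
#' @export
equilibrated_frames <- function(traj, discard_fraction = 0.5, n_se = 2) {
  n <- length(traj$frames)
  keep <- seq.int(floor(n * discard_fraction) + 1L, n)
  stationary <- TRUE
  if (length(keep) >= 4) {
    e <- traj$energies[keep]
    h1 <- e[seq_len(length(e) %/% 2)]
    h2 <- e[-seq_len(length(e) %/% 2)]
    se <- sqrt(sd(h1)^2 / length(h1) + sd(h2)^2 / length(h2))
    if (is.finite(se) && se > 0) {
      stationary <- abs(mean(h1) - mean(h2)) < n_se * se
    }
  }
  structure(keep, stationary = stationary)
}

# Unwrap the beads of each chain by accumulating minimum-image bond vectors
# from the first bead; returns a numeric matrix aligned with config$coords.
unwrap_chains <- function(config) {
  L <- config$box_side
  xyz <- config$coords
  d <- apply(xyz, 2, function(v) c(0, diff(v)))
  same <- c(FALSE, diff(config$chain_id) == 0L)
  d[!same, ] <- 0
  d <- ((d + L / 2) %% L) - L / 2  # minimum-image bond steps
  first <- !same
  out <- apply(d, 2, cumsum)
  # reset each chain to start at its wrapped first-bead coordinate
  base <- xyz[first, , drop = FALSE] - out[first, , drop = FALSE]
  out + base[cumsum(first), , drop = FALSE]
}

# Per-chain centres of mass and radii of gyration from unwrapped coordinates.
chain_geometry <- function(config) {
  u <- unwrap_chains(config)
  cid <- config$chain_id
  com <- cbind(tapply(u[, 1], cid, mean),
               tapply(u[, 2], cid, mean),
               tapply(u[, 3], cid, mean))
  dev <- u - com[cid, , drop = FALSE]
  rg2 <- as.numeric(tapply(rowSums(dev^2), cid, mean))
  list(com = com, rg2 = rg2, unwrapped = u)
}

#' Per-chain radius of gyration
#'
#' @param config a `lattice_config`.
#' @return Numeric vector of Rg (l.u.), one per chain, computed from
#'   unwrapped chain coordinates.
#' @export
chain_rg <- function(config) {
  sqrt(chain_geometry(config)$rg2)
}

#' Apparent single-chain scaling exponent
#'
#' Estimates the Flory-type exponent nu from the scaling of mean internal
#' distances with sequence separation, `<R_ij^2>^(1/2) ~ |i-j|^nu`, by
#' log-log regression over a separation window, averaged over the
#' equilibrated frames of a single-chain trajectory.
#'
#' @param traj single-chain `lattice_trajectory`.
#' @param window integer range of sequence separations used in the fit.
#' @param min_frames minimum number of equilibrated frames required.
#' @return list with `nu`, `se` (regression standard error), and the
#'   separation/`msd` table.
#' @export
single_chain_nu <- function(traj, window = NULL, min_frames = 10) {
  if (length(traj$config$sequences) != 1) stop("trajectory must contain a single chain")
  keep <- equilibrated_frames(traj)
  if (length(keep) < min_frames) {
    stop(sprintf("too few equilibrated frames (%d < %d)", length(keep), min_frames))
  }
  N <- nrow(traj$config$coords)
  if (is.null(window)) window <- seq(max(2L, round(N * 0.1)), round(N * 0.5))
  msd <- matrix(0, nrow = length(window), ncol = length(keep))
  for (f in seq_along(keep)) {
    u <- unwrap_chains(frame_config(traj, keep[f]))
    for (w in seq_along(window)) {
      s <- window[w]
      d <- u[seq_len(N - s) + s, , drop = FALSE] - u[seq_len(N - s), , drop = FALSE]
      msd[w, f] <- mean(rowSums(d^2))
    }
  }
  mmsd <- rowMeans(msd)
  fit <- lm(I(0.5 * log(mmsd)) ~ log(window))
  se_fit <- suppressWarnings(summary(fit)$coefficients[2, 2])
  list(nu = unname(coef(fit)[2]), se = se_fit,
       table = data.frame(separation = window, msd = mmsd))
}

#' Chain centre-of-mass displacement over a Monte Carlo step lag
#'
#' Root-mean-square displacement of chain centres of mass between stored
#' frames separated by `step_lag` Monte Carlo sweeps (move count as the time
#' proxy; requires a local-only move set so that translations do not corrupt
#' it). Displacements are taken under minimum image.
#'
#' @param traj a `lattice_trajectory` run with `move_set(local_only = TRUE)`.
#' @param step_lag lag in sweeps; must be a multiple of the frame spacing.
#' @param equilibrated_only restrict to the equilibrated window.
#' @return data.frame with one row per chain: `chain`, `rmsd` (l.u.) and the
#'   number of frame pairs averaged.
#' @export
chain_rmsd_over_steps <- function(traj, step_lag, equilibrated_only = TRUE) {
  if (!traj$moves$local_only) {
    stop("RMSD over MC steps requires a local-only move set")
  }
  idx <- if (equilibrated_only) as.integer(equilibrated_frames(traj)) else
    seq_along(traj$frames)
  steps <- traj$steps[idx]
  pairs <- which(outer(steps, steps, FUN = function(a, b) b - a) == step_lag,
                 arr.ind = TRUE)
  if (nrow(pairs) == 0) stop("step_lag does not match any stored frame spacing")
  L <- traj$config$box_side
  nc <- length(traj$config$sequences)
  acc <- matrix(0, nrow = nc, ncol = nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    c1 <- chain_geometry(frame_config(traj, idx[pairs[p, 1]]))$com
    c2 <- chain_geometry(frame_config(traj, idx[pairs[p, 2]]))$com
    d <- (c2 - c1 + L / 2) %% L - L / 2
    acc[, p] <- rowSums(d^2)
  }
  data.frame(chain = seq_len(nc), rmsd = sqrt(rowMeans(acc)),
             n_pairs = nrow(pairs))
}
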