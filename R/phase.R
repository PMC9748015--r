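# Phase assignment, binodals, two-phase width, ERMSL, swelling ratio and
# master curve, ternary contact fractions, overlap concentration.

chain_contact_graph <- function(config) {
  cp <- cpp_contact_pairs(config$coords, config$chain_id, config$box_side)
  inter <- cp[cp[, "same_chain"] == 0L, , drop = FALSE]
  edges <- unique(cbind(config$chain_id[inter[, "i"]],
                        config$chain_id[inter[, "j"]]))
  igraph::graph_from_edgelist(edges[edges[, 1] != edges[, 2], , drop = FALSE],
                              directed = FALSE) |>
    igraph::simplify() |>
    (\(g) igraph::add_vertices(g, max(0L, length(config$sequences) -
                                        igraph::vcount(g))))()
}

#' Assign chains to the dense or dilute phase
#'
#' Chains are clustered by inter-chain contact (any bead pair within the
#' contact range); the largest connected cluster of chains -- together with
#' anything within interacting range of it, which by construction is part of
#' the same cluster -- is the dense phase, the remainder the dilute phase.
#'
#' @param config a `lattice_config`.
#' @param model a `contact_model` (contact range; the default sqrt(3)
#'   26-neighbourhood is used for any range in `[1, sqrt(3)]`).
#' @return factor of length n_chains with levels `dense`, `dilute`; attribute
#'   `degenerate` is `TRUE` when the "largest cluster" is a single chain.
#' @export
assign_phases <- function(config, model = NULL) {
  g <- chain_contact_graph(config)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  lab <- ifelse(comp$membership == big, "dense", "dilute")
  structure(factor(lab, levels = c("dense", "dilute")),
            degenerate = max(comp$csize) <= 1L)
}

# Dense-region volume: occupied sites of dense-phase chains dilated by the
# 26-neighbourhood ("envelope" estimator).
dense_region_sites <- function(config, dense_chains) {
  L <- config$box_side
  xyz <- config$coords[config$chain_id %in% dense_chains, , drop = FALSE]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  sites <- unique(unlist(lapply(seq_len(nrow(offs)), function(k) {
    p <- sweep(xyz, 2, offs[k, ], `+`) %% L
    p[, 1] + L * (p[, 2] + L * p[, 3])
  })))
  sites
}

measure_phase_point <- function(config, model, estimator = "envelope") {
  phase <- assign_phases(config, model)
  dense_chains <- which(phase == "dense")
  L <- config$box_side
  n_dense <- sum(config$chain_id %in% dense_chains)
  n_dilute <- nrow(config$coords) - n_dense
  if (estimator == "envelope") {
    v_dense <- length(dense_region_sites(config, dense_chains))
    c_dense <- n_dense / v_dense
    c_dilute <- n_dilute / (L^3 - v_dense)
  } else {
    prof <- radial_density_profile(config, model)
    fit <- fit_interface(prof)
    c_dense <- fit$phi_dense
    c_dilute <- fit$phi_dilute
  }
  list(c_dilute = c_dilute, c_dense = c_dense,
       dense_fraction = length(dense_chains) / length(phase),
       degenerate = attr(phase, "degenerate"))
}

#' Compute a binodal from trajectories at several temperatures
#'
#' For each temperature the coexisting concentrations are measured on every
#' equilibrated frame of every replicate: `c_dense` is the bead volume
#' fraction inside the dense-phase region and `c_dilute` the volume fraction
#' of the remainder of the box. Two dense-region estimators are available:
#' `"envelope"` (occupied sites of dense chains dilated by one lattice unit)
#' and `"profile"` (plateaus of the fitted radial density profile). Points
#' whose trajectories do not show stable phase separation (dilute
#' concentration not below the dense one, or a degenerate largest cluster)
#' are excluded with a warning.
#'
#' @param trajectories named list: one `lattice_trajectory` or a list of
#'   replicate trajectories per temperature (names are the temperatures).
#' @param model a `contact_model`.
#' @param estimator `"envelope"` or `"profile"`.
#' @return Object of class `binodal`: data.frame with columns `T`,
#'   `c_dilute`, `c_dense`, `se_dilute`, `se_dense`, `omega`, `n_replicates`.
#' @export
compute_binodal <- function(trajectories, model, estimator = c("envelope", "profile")) {
  estimator <- match.arg(estimator)
  temps <- as.numeric(names(trajectories))
  if (anyNA(temps)) stop("trajectories must be named by temperature")
  rows <- lapply(seq_along(trajectories), function(i) {
    reps <- trajectories[[i]]
    if (inherits(reps, "lattice_trajectory")) reps <- list(reps)
    per_rep <- lapply(reps, function(tr) {
      keep <- equilibrated_frames(tr)
      ms <- lapply(keep, function(f) {
        measure_phase_point(frame_config(tr, f), model, estimator)
      })
      c(c_dilute = mean(vapply(ms, `[[`, numeric(1), "c_dilute")),
        c_dense = mean(vapply(ms, `[[`, numeric(1), "c_dense")),
        degenerate = mean(vapply(ms, `[[`, numeric(1), "degenerate")))
    })
    m <- do.call(rbind, per_rep)
    ok <- m[, "degenerate"] < 0.5 & m[, "c_dilute"] < m[, "c_dense"]
    if (!any(ok)) {
      warning(sprintf("T = %g: no stable phase separation; point excluded",
                      temps[i]))
      return(NULL)
    }
    m <- m[ok, , drop = FALSE]
    n <- nrow(m)
    data.frame(
      T = temps[i],
      c_dilute = mean(m[, "c_dilute"]), c_dense = mean(m[, "c_dense"]),
      se_dilute = if (n > 1) sd(m[, "c_dilute"]) / sqrt(n) else NA_real_,
      se_dense = if (n > 1) sd(m[, "c_dense"]) / sqrt(n) else NA_real_,
      n_replicates = n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no usable phase points")
  out <- out[order(out$T), ]
  out$omega <- two_phase_width(out$c_dilute, out$c_dense)
  class(out) <- c("binodal", "data.frame")
  out
}

#' Width of the two-phase regime
#'
#' `omega(T) = log10(c_dilute(T) / c_dense(T))`; negative below criticality
#' and approaching zero as the binodal arms merge.
#'
#' @param c_dilute,c_dense coexisting concentrations (volume fractions, > 0).
#' @return Numeric omega (vectorised).
#' @export
two_phase_width <- function(c_dilute, c_dense) {
  if (any(c_dilute <= 0) || any(c_dense <= 0)) {
    stop("two_phase_width undefined for non-positive concentrations")
  }
  log10(c_dilute / c_dense)
}

#' ERMSL between two binodal arms
#'
#' The exponential root-mean-square log compares the low-concentration arms
#' of a computed and a measured binodal:
#' `ERMSL = 10 ^ sqrt(mean(log10(c_sim / c_exp)^2))` over temperature-matched
#' points. A value of 1 means the arms overlay perfectly; 10 means the
#' concentrations differ by an order of magnitude on average. Exact
#' temperature matches are used where available; otherwise the experimental
#' arm is interpolated log-linearly in temperature onto the simulated grid.
#'
#' @param sim_arm,exp_arm data.frames with columns `T` and `c` (temperatures
#'   and concentrations, `c > 0`).
#' @return ERMSL (scalar >= 1).
#' @export
ermsl <- function(sim_arm, exp_arm) {
  sim_arm <- as.data.frame(sim_arm); exp_arm <- as.data.frame(exp_arm)
  if (!all(c("T", "c") %in% names(sim_arm)) ||
      !all(c("T", "c") %in% names(exp_arm))) {
    stop("arms must have columns 'T' and 'c'")
  }
  if (any(sim_arm$c <= 0) || any(exp_arm$c <= 0)) {
    stop("concentrations must be positive")
  }
  exp_arm <- exp_arm[order(exp_arm$T), ]
  exact <- match(sim_arm$T, exp_arm$T)
  logc_exp <- rep(NA_real_, nrow(sim_arm))
  logc_exp[!is.na(exact)] <- log10(exp_arm$c[exact[!is.na(exact)]])
  need <- is.na(logc_exp)
  in_range <- sim_arm$T >= min(exp_arm$T) & sim_arm$T <= max(exp_arm$T)
  interp <- need & in_range
  if (any(interp) && nrow(exp_arm) >= 2) {
    logc_exp[interp] <- approx(exp_arm$T, log10(exp_arm$c),
                               xout = sim_arm$T[interp])$y
  }
  use <- !is.na(logc_exp)
  if (!any(use)) stop("no overlapping temperature range between arms")
  d <- log10(sim_arm$c[use]) - logc_exp[use]
  10^sqrt(mean(d^2))
}

#' Swelling ratio
#'
#' `alpha = sqrt(mean(Rg2_dense)) / sqrt(mean(Rg2_dilute))`: the root-mean-
#' square radius of gyration of dense-phase chains relative to dilute-phase
#' chains at the same state point.
#'
#' @param rg2_dense,rg2_dilute samples of squared radii of gyration (l.u.^2).
#' @return alpha (scalar > 0).
#' @export
swelling_ratio <- function(rg2_dense, rg2_dilute) {
  if (!length(rg2_dense) || !length(rg2_dilute)) {
    stop("both phases need a nonempty Rg^2 sample")
  }
  sqrt(mean(rg2_dense)) / sqrt(mean(rg2_dilute))
}

#' Swelling ratio of a configuration
#'
#' Splits chains into phases with [assign_phases()] and applies
#' [swelling_ratio()]. Returns `NA` with a warning when the dilute phase is
#' empty (deep in the two-phase regime every chain can be part of the dense
#' cluster).
#'
#' @param config a `lattice_config`.
#' @param model a `contact_model`.
#' @return list with `alpha`, per-phase RMS Rg and chain counts.
#' @export
config_swelling <- function(config, model = NULL) {
  ph <- assign_phases(config, model)
  rg2 <- chain_geometry(config)$rg2
  if (!any(ph == "dilute")) {
    warning("no dilute-phase chains; swelling ratio undefined")
    return(list(alpha = NA_real_, rms_rg_dense = sqrt(mean(rg2[ph == "dense"])),
                rms_rg_dilute = NA_real_, n_dense = sum(ph == "dense"),
                n_dilute = 0L))
  }
  list(alpha = swelling_ratio(rg2[ph == "dense"], rg2[ph == "dilute"]),
       rms_rg_dense = sqrt(mean(rg2[ph == "dense"])),
       rms_rg_dilute = sqrt(mean(rg2[ph == "dilute"])),
       n_dense = sum(ph == "dense"), n_dilute = sum(ph == "dilute"))
}

#' Fit the swelling-ratio master curve
#'
#' Least-squares fit of `alpha = 1 + exp(-a * (omega - b))` to (omega, alpha)
#' points; across sequence variants the swelling ratios collapse onto this
#' single exponential master curve.
#'
#' @param omega,alpha numeric vectors (>= 4 points).
#' @return list with `a`, `b`, `residuals` and the `nls` fit object.
#' @export
fit_master_curve <- function(omega, alpha) {
  stopifnot(length(omega) == length(alpha))
  if (length(omega) < 4) stop("need at least 4 (omega, alpha) points")
  if (all(alpha <= 1)) warning("alpha <= 1 everywhere; fit is ill-conditioned")
  df <- data.frame(omega = omega, alpha = alpha)
  excess <- pmax(alpha - 1, 1e-12)
  sl <- coef(lm(log(excess) ~ omega))
  start <- list(a = max(1e-3, -unname(sl[2])),
                b = unname(sl[1]) / max(1e-3, -unname(sl[2])))
  fit <- minpack.lm::nlsLM(alpha ~ 1 + exp(-a * (omega - b)), data = df,
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  co <- coef(fit)
  list(a = unname(co["a"]), b = unname(co["b"]),
       residuals = stats::resid(fit), fit = fit)
}

#' Ternary contact fractions of dense-phase chains
#'
#' For every bead the 26-site neighbourhood is classified as solvated
#' (empty), same-chain, or other-chain; per-chain sums are normalised to the
#' fractions `f_sol`, `f_intra`, `f_inter`, which add to 1 exactly. Bonded
#' neighbours count toward `f_intra` (the census is a pure occupancy count).
#'
#' @param config a `lattice_config`.
#' @param model unused placeholder for interface consistency.
#' @param phase optional phase factor from [assign_phases()]; computed when
#'   missing. Fractions are returned for every chain, with the phase label
#'   attached.
#' @return data.frame with one row per chain: `chain`, `phase`, `f_intra`,
#'   `f_inter`, `f_sol`, `rg`.
#' @export
contact_fractions <- function(config, model = NULL, phase = NULL) {
  cen <- cpp_neighbor_census(config$coords, config$chain_id, config$sticker,
                             config$box_side)
  cid <- config$chain_id
  tot <- cbind(sol = tapply(cen[, "empty"], cid, sum),
               intra = tapply(cen[, "same_chain"], cid, sum),
               inter = tapply(cen[, "other_chain"], cid, sum))
  den <- rowSums(tot)
  if (is.null(phase)) phase <- assign_phases(config, model)
  data.frame(chain = seq_len(nrow(tot)), phase = phase,
             f_intra = tot[, "intra"] / den,
             f_inter = tot[, "inter"] / den,
             f_sol = tot[, "sol"] / den,
             rg = chain_rg(config))
}

#' Bin ternary fractions and average a chain property
#'
#' Assigns each chain to a ternary bin of resolution `nbins` on
#' (f_intra, f_inter, f_sol) and averages `value` (chain Rg by default) per
#' bin, mirroring how ternary contact plots are coloured.
#'
#' @param fractions output of [contact_fractions()].
#' @param nbins bins per ternary axis.
#' @param value chain values to average (defaults to `fractions$rg`).
#' @return data.frame keyed by the bin indices with the bin mean and count.
#' @export
ternary_bins <- function(fractions, nbins = 20, value = fractions$rg) {
  i1 <- pmin(nbins - 1L, floor(fractions$f_intra * nbins))
  i2 <- pmin(nbins - 1L, floor(fractions$f_inter * nbins))
  key <- interaction(i1, i2, drop = TRUE)
  out <- data.frame(
    bin_intra = as.integer(tapply(i1, key, `[`, 1)),
    bin_inter = as.integer(tapply(i2, key, `[`, 1)),
    mean_value = as.numeric(tapply(value, key, mean)),
    n = as.integer(table(key)))
  out[order(out$bin_intra, out$bin_inter), ]
}

#' Overlap volume fraction
#'
#' `phi_star = N * r^3 / Re^3` with `N` beads per chain, bead radius `r`
#' (0.5 l.u. by default) and `Re` the root-mean-square end-to-end distance
#' of dilute-phase chains. The regime comparison labels a saturation
#' concentration `phi_sat` as `dilute` when `phi_sat < phi_star`, else
#' `semi-dilute`.
#'
#' @param N beads per chain.
#' @param r bead radius (l.u.).
#' @param Re RMS end-to-end distance (l.u.).
#' @return phi_star (scalar).
#' @export
overlap_fraction <- function(N, r = 0.5, Re) {
  stopifnot(N > 0, r > 0, Re > 0)
  N * r^3 / Re^3
}

#' @rdname overlap_fraction
#' @param phi_sat saturation (dilute-arm) volume fraction.
#' @param phi_star overlap volume fraction.
#' @param tie label assigned when `phi_sat == phi_star` exactly.
#' @export
overlap_regime <- function(phi_sat, phi_star, tie = "semi-dilute") {
  ifelse(phi_sat < phi_star, "dilute",
         ifelse(phi_sat > phi_star, "semi-dilute", tie))
}

#' RMS end-to-end distance of a set of chains
#'
#' @param config a `lattice_config`.
#' @param chains chain indices (default all).
#' @return Root-mean-square end-to-end distance (l.u.).
#' @export
rms_end_to_end <- function(config, chains = NULL) {
  u <- unwrap_chains(config)
  cid <- config$chain_id
  first <- !duplicated(cid)
  last <- !duplicated(cid, fromLast = TRUE)
  d2 <- rowSums((u[last, , drop = FALSE] - u[first, , drop = FALSE])^2)
  if (!is.null(chains)) d2 <- d2[chains]
  sqrt(mean(d2))
}
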