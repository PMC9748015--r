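# Radial density profiles, hyperbolic-tangent interface fits, and radially
# resolved conformational/orientational statistics. All profiles use shells
# of width 1/4 lattice unit around the condensate centre of mass, with the
# exact lattice-site count per shell of the periodic cube as the volume
# prior.

SHELL_WIDTH <- 0.25

#' Condensate centre of mass
#'
#' Centre of mass of the dense-phase beads, computed per axis with circular
#' means (so a droplet wrapped across the periodic boundary is handled
#' correctly).
#'
#' @param config a `lattice_config`.
#' @param phase optional phase factor from [assign_phases()].
#' @return Numeric length-3 centre in `[0, box_side)`.
#' @export
condensate_center <- function(config, phase = NULL) {
  if (is.null(phase)) phase <- assign_phases(config)
  xyz <- config$coords[phase[config$chain_id] == "dense", , drop = FALSE]
  if (!nrow(xyz)) xyz <- config$coords
  L <- config$box_side
  theta <- xyz * (2 * pi / L)
  ang <- atan2(colMeans(sin(theta)), colMeans(cos(theta)))
  (ang / (2 * pi) * L) %% L
}

check_single_droplet <- function(config, min_chains = 5) {
  g <- chain_contact_graph(config)
  cs <- sort(igraph::components(g)$csize, decreasing = TRUE)
  if (length(cs) >= 2 && cs[2] >= max(min_chains, 0.1 * length(config$sequences))) {
    stop("multiple droplets detected; radial profiles need a single condensate ",
         "(split the system or analyse components separately)")
  }
  invisible(TRUE)
}

# minimum-image radial distance of each bead from `center`
bead_radii <- function(config, center) {
  L <- config$box_side
  d <- abs(sweep(config$coords, 2, center))
  d <- pmin(d, L - d)
  sqrt(rowSums(d^2))
}

shell_scaffold <- function(box_side, center, r_max = NULL) {
  if (is.null(r_max)) r_max <- sqrt(3) * box_side / 2
  nshell <- ceiling(r_max / SHELL_WIDTH)
  sites <- cpp_shell_site_counts(box_side, center, SHELL_WIDTH, nshell)
  data.frame(shell = seq_len(nshell),
             r_lo = (seq_len(nshell) - 1) * SHELL_WIDTH,
             r_mid = (seq_len(nshell) - 0.5) * SHELL_WIDTH,
             sites = sites)
}

radial_profile_obj <- function(df, center, box_side, kind) {
  structure(df, center = center, box_side = box_side, kind = kind,
            shell_width = SHELL_WIDTH, class = c("radial_profile", "data.frame"))
}

#' Radial density profile of a condensate
#'
#' Bead volume fraction per radial shell of width 1/4 l.u. around the
#' condensate centre: bead count divided by the exact number of lattice
#' sites in the shell (periodic cube geometry). Rejects configurations with
#' more than one droplet.
#'
#' @param config a `lattice_config` containing a single droplet.
#' @param model unused placeholder.
#' @param center optional centre override (length-3 numeric).
#' @return A `radial_profile` data.frame with columns `shell`, `r_lo`,
#'   `r_mid`, `sites`, `count`, `density`.
#' @export
radial_density_profile <- function(config, model = NULL, center = NULL) {
  check_single_droplet(config)
  if (is.null(center)) center <- condensate_center(config)
  sc <- shell_scaffold(config$box_side, center)
  r <- bead_radii(config, center)
  idx <- pmin(nrow(sc), floor(r / SHELL_WIDTH) + 1L)
  sc$count <- tabulate(idx, nbins = nrow(sc))
  sc$density <- ifelse(sc$sites > 0, sc$count / sc$sites, NA_real_)
  radial_profile_obj(sc, center, config$box_side, "density")
}

#' Fit a hyperbolic-tangent interface profile
#'
#' Nonlinear least squares of
#' `log10 phi(r) = (log10 phi'' + log10 phi')/2 -
#'  (log10 phi'' - log10 phi')/2 * tanh(2 (r - r_mid) / Delta)`
#' to a radial density profile, in log10 density. `phi'` and `phi''` are the
#' dilute- and dense-phase plateau densities, `r_mid` the midpoint, `Delta`
#' the interfacial width. Initial values come from the profile endpoints and
#' the half-log-density crossing.
#'
#' @param profile a `radial_profile` from [radial_density_profile()], or any
#'   data.frame with `r_mid` and `density` columns (positive densities are
#'   used).
#' @param weights optional per-shell fit weights (defaults to shell site
#'   counts when present, else 1).
#' @param min_sites shells whose exact site count is below this are dropped
#'   before fitting (the innermost shells of a radial grid hold only a
#'   handful of lattice sites, so their densities are 0-or-1 noise with
#'   enormous leverage in log space). Ignored when the profile carries no
#'   `sites` column.
#' @return list of class `interface_fit` with `phi_dilute`, `phi_dense`,
#'   `r_mid`, `delta`, `interface` (`r_mid` +/- `delta/2`), `residuals`,
#'   and the underlying `nls` object.
#' @export
fit_interface <- function(profile, weights = NULL, min_sites = 10) {
  df <- as.data.frame(profile)
  ok <- is.finite(df$density) & df$density > 0
  if ("sites" %in% names(df)) ok <- ok & df$sites >= min_sites
  df <- df[ok, ]
  if (nrow(df) < 6) stop("too few shells with positive density for an interface fit")
  if (is.null(weights)) {
    weights <- if ("sites" %in% names(df)) df$sites else rep(1, nrow(df))
  } else {
    weights <- weights[ok]
  }
  y <- log10(df$density)
  r <- df$r_mid
  n_edge <- max(2L, nrow(df) %/% 10L)
  l_dense <- mean(head(y, n_edge))
  l_dilute <- mean(tail(y, n_edge))
  if (l_dense - l_dilute < 0.2) {
    stop("profile is not sigmoidal (no separated plateaus); interface fit rejected")
  }
  mid_level <- (l_dense + l_dilute) / 2
  below <- which(y < mid_level)
  r_mid0 <- if (length(below)) r[min(below)] else median(r)
  q25 <- (3 * l_dense + l_dilute) / 4
  q75 <- (l_dense + 3 * l_dilute) / 4
  r25 <- r[which(y < q25)[1]]; r75 <- r[which(y < q75)[1]]
  delta0 <- max(2 * SHELL_WIDTH, if (!is.na(r75) && !is.na(r25)) r75 - r25 else 2)
  dat <- data.frame(r = r, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ (ld + lc) / 2 - (ld - lc) / 2 * tanh(2 * (r - rm) / dl),
    data = dat,
    start = list(ld = min(l_dense, -1e-6), lc = min(l_dilute, -1e-6),
                 rm = r_mid0, dl = delta0),
    weights = weights,
    # plateaus are volume fractions, so their log10 cannot exceed 0
    lower = c(ld = -Inf, lc = -Inf, rm = 0, dl = 2 * SHELL_WIDTH),
    upper = c(ld = 0, lc = 0, rm = max(r), dl = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                         ptol = 1e-12))
  co <- coef(fit)
  if (co[["dl"]] < 0) {  # tanh(-x) symmetry: fold the sign into the plateaus
    co[c("ld", "lc")] <- co[c("lc", "ld")]
    co[["dl"]] <- -co[["dl"]]
  }
  if (co[["ld"]] <= co[["lc"]]) stop("fit degenerate: dense plateau below dilute plateau")
  structure(
    list(phi_dilute = 10^co[["lc"]], phi_dense = 10^co[["ld"]],
         r_mid = co[["rm"]], delta = co[["dl"]],
         interface = c(co[["rm"]] - co[["dl"]] / 2, co[["rm"]] + co[["dl"]] / 2),
         residuals = stats::resid(fit), fit = fit),
    class = "interface_fit")
}

#' @export
print.interface_fit <- function(x, ...) {
  cat(sprintf(
    "<interface_fit> phi' = %.3g, phi'' = %.3g, r_mid = %.2f l.u., Delta = %.2f l.u.\n",
    x$phi_dilute, x$phi_dense, x$r_mid, x$delta))
  invisible(x)
}

#' Sticker-sticker crosslinks per sticker, radially resolved
#'
#' For every sticker, counts its nonbonded neighbours within sqrt(3) that
#' are also stickers, split into intramolecular and intermolecular
#' crosslinks, and bins the per-sticker counts by the sticker's radial
#' shell. Total = intra + inter exactly.
#'
#' @param config a `lattice_config`.
#' @param model unused placeholder.
#' @param center optional centre override.
#' @return A `radial_profile` data.frame with per-shell mean `total`,
#'   `intra`, `inter` crosslinks per sticker and the sticker `count`.
#' @export
crosslinks_per_sticker_profile <- function(config, model = NULL, center = NULL) {
  if (is.null(center)) center <- condensate_center(config)
  cen <- cpp_neighbor_census(config$coords, config$chain_id, config$sticker,
                             config$box_side)
  st <- config$sticker
  sc <- shell_scaffold(config$box_side, center)
  r <- bead_radii(config, center)[st]
  idx <- pmin(nrow(sc), floor(r / SHELL_WIDTH) + 1L)
  intra <- cen[st, "st_intra"]; inter <- cen[st, "st_inter"]
  sc$count <- tabulate(idx, nbins = nrow(sc))
  sums_i <- tapply(intra, factor(idx, levels = seq_len(nrow(sc))), sum)
  sums_e <- tapply(inter, factor(idx, levels = seq_len(nrow(sc))), sum)
  sc$intra <- as.numeric(sums_i) / sc$count
  sc$inter <- as.numeric(sums_e) / sc$count
  sc$total <- sc$intra + sc$inter
  radial_profile_obj(sc, center, config$box_side, "crosslinks_per_sticker")
}

# gyration tensor eigenvalues (descending) for one chain's unwrapped coords
gyration_eigenvalues <- function(u) {
  d <- sweep(u, 2, colMeans(u))
  ev <- eigen(crossprod(d) / nrow(u), symmetric = TRUE, only.values = TRUE)$values
  sort(ev, decreasing = TRUE)
}

#' Asphericity of a chain
#'
#' Normalised gyration-tensor asphericity
#' `[(l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2] / (2 (l1+l2+l3)^2)` with eigenvalues
#' `l1 >= l2 >= l3`; ranges from 0 (sphere) to 1 (rod), values above 0.4
#' indicating cigar-shaped conformations.
#'
#' @param u numeric matrix of (unwrapped) bead coordinates of one chain.
#' @return Scalar in `[0, 1]`.
#' @export
asphericity <- function(u) {
  ev <- gyration_eigenvalues(u)
  s <- sum(ev)
  if (s == 0) return(0)
  ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 + (ev[3] - ev[1])^2) / (2 * s^2)
}

#' Radially resolved chain properties
#'
#' Bins a per-chain conformational property into radial shells. For `Rg` and
#' `asphericity` every bead contributes its chain's value to the bead's own
#' shell (bead-weighted binning, so a chain spanning several shells is
#' weighted by how many beads it has in each). For `local_extension` the
#' distance between residue pairs separated by exactly `delta_seq` residues
#' is binned by the first residue's shell; chains shorter than
#' `delta_seq + 1` are skipped.
#'
#' @param config a `lattice_config` containing a single droplet.
#' @param property `"rg"`, `"asphericity"` or `"local_extension"`.
#' @param delta_seq sequence separation for local extension (default 5).
#' @param center optional centre override.
#' @return A `radial_profile` data.frame with per-shell `value` and `count`.
#' @export
chain_property_profile <- function(config,
                                   property = c("rg", "asphericity",
                                                "local_extension"),
                                   delta_seq = 5, center = NULL) {
  property <- match.arg(property)
  if (is.null(center)) center <- condensate_center(config)
  sc <- shell_scaffold(config$box_side, center)
  r <- bead_radii(config, center)
  geo <- chain_geometry(config)
  cid <- config$chain_id
  if (property %in% c("rg", "asphericity")) {
    cval <- if (property == "rg") sqrt(geo$rg2) else
      vapply(split(seq_len(nrow(config$coords)), cid),
             function(ix) asphericity(geo$unwrapped[ix, , drop = FALSE]),
             numeric(1))
    val <- cval[cid]
    idx <- pmin(nrow(sc), floor(r / SHELL_WIDTH) + 1L)
  } else {
    u <- geo$unwrapped
    lens <- tabulate(cid)
    starts <- cumsum(c(1L, head(lens, -1)))
    pairs_i <- unlist(lapply(seq_along(lens), function(c) {
      if (lens[c] <= delta_seq) return(integer(0))
      starts[c] + seq_len(lens[c] - delta_seq) - 1L
    }))
    if (!length(pairs_i)) stop("all chains shorter than delta_seq + 1")
    pairs_j <- pairs_i + as.integer(delta_seq)
    val <- sqrt(rowSums((u[pairs_j, , drop = FALSE] -
                           u[pairs_i, , drop = FALSE])^2))
    idx <- pmin(nrow(sc), floor(r[pairs_i] / SHELL_WIDTH) + 1L)
  }
  f <- factor(idx, levels = seq_len(nrow(sc)))
  sc$count <- as.integer(table(f))
  sc$value <- as.numeric(tapply(val, f, mean))
  radial_profile_obj(sc, center, config$box_side, property)
}

#' Distinct chains per residue, radially resolved
#'
#' For each radial shell: the number of distinct chains with at least one
#' bead in the shell divided by the number of beads in the shell. Values lie
#' in (0, 1]; low values indicate chains wrapped around a shell, high values
#' chains crossing it perpendicularly. Empty shells are masked (`NA`).
#'
#' @param config a `lattice_config`.
#' @param center optional centre override.
#' @return A `radial_profile` data.frame with `n_chains`, `count` (beads)
#'   and `value` = n_chains / beads.
#' @export
distinct_chains_per_residue <- function(config, center = NULL) {
  if (is.null(center)) center <- condensate_center(config)
  sc <- shell_scaffold(config$box_side, center)
  r <- bead_radii(config, center)
  idx <- pmin(nrow(sc), floor(r / SHELL_WIDTH) + 1L)
  f <- factor(idx, levels = seq_len(nrow(sc)))
  sc$count <- as.integer(table(f))
  sc$n_chains <- as.integer(tapply(config$chain_id, f,
                                   function(x) length(unique(x))))
  sc$n_chains[is.na(sc$n_chains)] <- 0L
  sc$value <- ifelse(sc$count > 0, sc$n_chains / sc$count, NA_real_)
  radial_profile_obj(sc, center, config$box_side, "distinct_chains_per_residue")
}

#' Chain orientation relative to the condensate centre
#'
#' For each chain with distinct end beads a and b, theta is the angle
#' between the end-to-end segment and the segment from an end bead to the
#' condensate centre; `cos^2 theta` is evaluated twice per chain (once per
#' end, binned by that end bead's shell) and averaged per shell. Values are
#' 1 for chains collinear with the radius vector, ~0 for chains tangent to
#' their shell, and average 1/3 for isotropic orientations.
#'
#' @param config a `lattice_config`.
#' @param center optional centre override.
#' @return A `radial_profile` data.frame with per-shell mean `value`
#'   (cos^2 theta) and evaluation `count`; attribute `n_excluded` counts
#'   chains with zero end-to-end vectors.
#' @export
orientation_profile <- function(config, center = NULL) {
  if (is.null(center)) center <- condensate_center(config)
  L <- config$box_side
  sc <- shell_scaffold(config$box_side, center)
  u <- unwrap_chains(config)
  cid <- config$chain_id
  first <- which(!duplicated(cid))
  last <- which(!duplicated(cid, fromLast = TRUE))
  multi <- last > first
  first <- first[multi]; last <- last[multi]
  ee <- u[last, , drop = FALSE] - u[first, , drop = FALSE]
  deg <- rowSums(ee^2)
  nz <- deg > 0
  n_excluded <- sum(!nz)
  first <- first[nz]; last <- last[nz]; ee <- ee[nz, , drop = FALSE]
  cos2 <- function(end_idx, vec) {
    # segment from end bead to centre, minimum image on wrapped coordinates
    d <- sweep(config$coords[end_idx, , drop = FALSE], 2, center)
    d <- ((d + L / 2) %% L) - L / 2
    num <- rowSums(vec * d)^2
    den <- rowSums(vec^2) * rowSums(d^2)
    ifelse(den > 0, num / den, NA_real_)
  }
  vals <- c(cos2(first, ee), cos2(last, -ee))
  r_ends <- bead_radii(config, center)[c(first, last)]
  ok <- !is.na(vals)
  idx <- pmin(nrow(sc), floor(r_ends[ok] / SHELL_WIDTH) + 1L)
  f <- factor(idx, levels = seq_len(nrow(sc)))
  sc$count <- as.integer(table(f))
  sc$value <- as.numeric(tapply(vals[ok], f, mean))
  out <- radial_profile_obj(sc, center, config$box_side, "orientation")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Average radial profiles across frames
#'
#' Pools a list of `radial_profile`s (same box and shell grid) into one
#' profile: per-shell values are count-weighted means, counts and site
#' priors are summed, and a standard error about the per-frame mean is
#' attached where at least two frames populate a shell.
#'
#' @param profiles list of `radial_profile`s of the same kind.
#' @param value name of the value column to pool (default `"value"`, or
#'   `"density"` for density profiles).
#' @return A pooled `radial_profile`.
#' @export
average_profiles <- function(profiles, value = NULL) {
  stopifnot(length(profiles) >= 1)
  if (is.null(value)) {
    value <- if ("density" %in% names(profiles[[1]])) "density" else "value"
  }
  ns <- max(vapply(profiles, nrow, integer(1)))
  get <- function(p, col) c(p[[col]], rep(NA_real_, ns - nrow(p)))
  counts <- sapply(profiles, get, col = "count")
  vals <- sapply(profiles, get, col = value)
  counts[is.na(counts)] <- 0
  wsum <- rowSums(counts)
  vsum <- rowSums(vals * counts, na.rm = TRUE)
  base <- profiles[[which.max(vapply(profiles, nrow, integer(1)))]]
  out <- as.data.frame(base)
  out$count <- as.integer(wsum)
  out[[value]] <- ifelse(wsum > 0, vsum / wsum, NA_real_)
  if ("sites" %in% names(out) && value == "density") {
    sites <- sapply(profiles, get, col = "sites")
    out$sites <- rowSums(sites, na.rm = TRUE)
    out$density <- ifelse(out$sites > 0,
                          rowSums(vals * sites, na.rm = TRUE) / out$sites,
                          NA_real_)
  }
  out$se <- apply(vals, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  })
  radial_profile_obj(out, attr(base, "center"), attr(base, "box_side"),
                     attr(base, "kind"))
}

#' Interface-width scaling with chain length
#'
#' Away from the critical temperature the interfacial width plateaus at a
#' length-specific value `Delta_p`; across chain lengths `Delta_p ~ N^x`.
#' The plateau for each length is the longest low-temperature run over which
#' `|dDelta/dT|` stays below `slope_threshold`; the exponent comes from a
#' log-log regression of `Delta_p` against `N`.
#'
#' @param fits data.frame with columns `N`, `T`, `delta`.
#' @param slope_threshold plateau slope tolerance (l.u. per temperature
#'   unit).
#' @return list with `plateaus` (data.frame `N`, `delta_p`, `n_T`),
#'   `exponent`, `se` and the regression fit.
#' @export
interface_width_scaling <- function(fits, slope_threshold = 0.1) {
  stopifnot(all(c("N", "T", "delta") %in% names(fits)))
  if (length(unique(fits$N)) < 3) stop("need at least 3 chain lengths")
  plateaus <- lapply(split(fits, fits$N), function(df) {
    df <- df[order(df$T), ]
    if (nrow(df) < 2) stop("need at least 2 temperatures per chain length")
    slopes <- abs(diff(df$delta) / diff(df$T))
    flat <- slopes < slope_threshold
    if (!any(flat)) return(NULL)
    # longest run of flat segments starting from the lowest temperatures
    runs <- rle(flat)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    best <- which(runs$values)[which.max(runs$lengths[runs$values])]
    seg <- starts[best]:(ends[best] + 1L)   # segment i spans points i, i+1
    data.frame(N = df$N[1], delta_p = mean(df$delta[seg]), n_T = length(seg))
  })
  plateaus <- do.call(rbind, plateaus)
  if (is.null(plateaus) || nrow(plateaus) < 3) {
    stop("no plateau detected for enough chain lengths; ",
         "inspect the Delta(T) series")
  }
  fit <- lm(log(delta_p) ~ log(N), data = plateaus)
  se_fit <- suppressWarnings(summary(fit)$coefficients[2, 2])
  list(plateaus = plateaus, exponent = unname(coef(fit)[2]),
       se = se_fit, fit = fit)
}
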