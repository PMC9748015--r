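test_that("shell volume prior conserves the box and profiles conserve beads", {
  cnt <- condensr:::cpp_shell_site_counts(20L, c(9.5, 9.5, 9.5), 0.25,
                                          ceiling(sqrt(3) * 10 / 0.25))
  expect_equal(sum(cnt), 20^3)

  # total beads across shells equals total beads in the system
  drop <- make_droplet_config(28, 5e-3, 0.5, 7, 3, chain_length = 6, seed = 2)
  prof <- radial_density_profile(drop)
  expect_equal(sum(prof$count), nrow(drop$coords))
  expect_equal(sum(prof$sites), 28^3)
  expect_true(all(prof$r_lo == (prof$shell - 1) * 0.25))
})

test_that("uniform ball profile is flat inside and empty outside", {
  # fill a ball of radius 5 completely with single-bead chains
  L <- 24L
  ctr <- (L - 1) / 2
  g <- expand.grid(x = 0:(L - 1), y = 0:(L - 1), z = 0:(L - 1))
  r <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2)
  inside <- g[r <= 5, ]
  chains <- lapply(seq_len(nrow(inside)),
                   function(i) as.matrix(inside[i, , drop = FALSE]))
  cfg <- toy_config(chains, L)
  prof <- radial_density_profile(cfg, center = rep(ctr, 3))
  inner <- prof$r_mid < 4.5 & prof$sites > 0
  expect_true(all(abs(prof$density[inner] - 1) < 1e-12))
  expect_true(all(prof$count[prof$r_lo > 5.1] == 0))
})

test_that("interface fit round-trips exact and noisy tanh profiles", {
  # exact synthetic data at the spec'd scale: recovery to 1e-9
  r <- seq(0.125, 45, by = 0.25)
  truth <- list(phi_dilute = 1e-4, phi_dense = 0.6, r_mid = 25, delta = 6)
  lphi <- with(truth, (log10(phi_dense) + log10(phi_dilute)) / 2 -
                 (log10(phi_dense) - log10(phi_dilute)) / 2 *
                 tanh(2 * (r - r_mid) / delta))
  prof <- data.frame(r_mid = r, density = 10^lphi)
  fit <- fit_interface(prof)
  expect_equal(fit$phi_dilute, truth$phi_dilute, tolerance = 1e-9)
  expect_equal(fit$phi_dense, truth$phi_dense, tolerance = 1e-9)
  expect_equal(fit$r_mid, truth$r_mid, tolerance = 1e-9)
  expect_equal(fit$delta, truth$delta, tolerance = 1e-9)
  expect_equal(fit$interface, c(25 - 3, 25 + 3), tolerance = 1e-6)

  # 5% multiplicative noise: width recovered within 5%
  set.seed(6)
  noisy <- prof
  noisy$density <- prof$density * exp(rnorm(nrow(prof), 0, 0.05))
  fit_n <- fit_interface(noisy, weights = rep(1, nrow(noisy)))
  expect_equal(fit_n$delta, truth$delta, tolerance = 0.05)

  # flat profile: error, not a spurious fit
  flat <- data.frame(r_mid = r, density = rep(0.3, length(r)))
  expect_error(fit_interface(flat), "not sigmoidal")
})

test_that("interface fit is scale-consistent under coordinate shifts", {
  r <- seq(0.125, 40, by = 0.25)
  lphi <- (log10(0.5) + log10(1e-3)) / 2 -
    (log10(0.5) - log10(1e-3)) / 2 * tanh(2 * (r - 15) / 4)
  prof <- data.frame(r_mid = r, density = 10^lphi)
  f1 <- fit_interface(prof)
  shifted <- data.frame(r_mid = r + 3, density = 10^lphi)
  f2 <- fit_interface(shifted)
  expect_equal(f2$r_mid - f1$r_mid, 3, tolerance = 1e-6)
  expect_equal(f2$delta, f1$delta, tolerance = 1e-6)
})

test_that("crosslink profiles split intra/inter exactly", {
  # hand-built triad: central sticker touches one intra and one inter sticker
  cfg <- toy_config(list(rbind(c(5, 5, 5), c(6, 5, 5), c(7, 5, 5)),
                         matrix(c(6, 6, 5), 1)),
                    16, residues = list(c("Y", "G", "Y"), "Y"))
  # stickers: chain1 beads 1,3 and chain2 bead; bead1-bead3 are nonbonded
  # intra at distance 2 -> NOT in contact; move bead 3 adjacent:
  cfg <- toy_config(list(rbind(c(5, 5, 5), c(6, 5, 4), c(6, 6, 4)),
                         matrix(c(5, 6, 5), 1)),
                    16, residues = list(c("Y", "G", "Y"), "Y"))
  cen <- condensr:::cpp_neighbor_census(cfg$coords, cfg$chain_id, cfg$sticker,
                                        cfg$box_side)
  b1 <- cen[1, ]  # first sticker
  expect_equal(unname(b1["st_intra"]), 1)  # bead 3 within sqrt(3), nonbonded
  expect_equal(unname(b1["st_inter"]), 1)  # chain-2 sticker adjacent
  prof <- crosslinks_per_sticker_profile(cfg)
  nz <- prof$count > 0
  expect_equal(prof$total[nz], prof$intra[nz] + prof$inter[nz])

  # isolated sticker has zero crosslinks
  iso <- toy_config(list(matrix(c(1, 1, 1), 1)), 16)
  p <- crosslinks_per_sticker_profile(iso, center = c(1, 1, 1))
  expect_equal(sum(p$total[p$count > 0]), 0)
})

test_that("chain shape measures hit their limits", {
  rod <- line_chain(20)
  expect_equal(asphericity(rod), 1)
  # planar symmetric ring: low asphericity, below the 0.4 cigar threshold
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  ring <- cbind(10 * cos(th), 10 * sin(th), 0)
  expect_lt(asphericity(ring), 0.4)
  # sphere-like cloud: asphericity near 0
  set.seed(3)
  cloud <- matrix(rnorm(3000), ncol = 3)
  expect_lt(asphericity(cloud), 0.05)
})

test_that("chain property profiles use bead weighting", {
  # one chain straddling two shells with known bead split contributes its
  # value with the bead counts as weights
  L <- 32L
  ctr <- c(15.5, 15.5, 15.5)
  chain <- cbind(seq(12L, 21L), 16L, 16L)  # 10 beads along x through centre
  cfg <- toy_config(list(chain), L)
  prof <- chain_property_profile(cfg, "rg", center = ctr)
  rg <- chain_rg(cfg)
  nz <- which(prof$count > 0)
  expect_true(all(abs(prof$value[nz] - rg) < 1e-12))
  expect_equal(sum(prof$count), 10)

  # local extension on a straight rod: every |i-j| = 5 pair at distance 5
  prof5 <- chain_property_profile(cfg, "local_extension", delta_seq = 5,
                                  center = ctr)
  nz <- which(prof5$count > 0)
  expect_true(all(abs(prof5$value[nz] - 5) < 1e-12))
  expect_equal(sum(prof5$count), 5)  # 10 - 5 pairs
  expect_error(chain_property_profile(
    toy_config(list(line_chain(3)), 16), "local_extension"), "shorter")
})

test_that("distinct chains per residue matches the worked example and bounds", {
  # shell with 8 distinct chains contributing 24 beads -> 8/24 = 0.33
  L <- 40L
  ctr <- c(20, 20, 20)
  chains <- lapply(0:7, function(k) {
    # 3-bead chains at radius ~10, each entirely inside one shell band
    ang <- k * pi / 4
    x <- 20 + round(10 * cos(ang)); y <- 20 + round(10 * sin(ang))
    rbind(c(x, y, 19), c(x, y, 20), c(x, y, 21))
  })
  cfg <- toy_config(chains, L)
  r <- condensr:::bead_radii(cfg, ctr)
  prof <- distinct_chains_per_residue(cfg, center = ctr)
  # pool the populated shells: 8 chains, 24 beads
  nz <- prof$count > 0
  expect_equal(sum(prof$n_chains[nz] * 0 + prof$count[nz]), 24)
  pooled <- sum(prof$count[nz] * prof$value[nz])  # = sum n_chains per shell
  # every chain may span few shells; check global bound and the 1/m case
  expect_true(all(prof$value[nz] > 0 & prof$value[nz] <= 1))

  # all beads of one chain in a single shell -> value 1/m
  one <- toy_config(list(rbind(c(25, 20, 20), c(25, 21, 20), c(25, 20, 21))),
                    L)
  p1 <- distinct_chains_per_residue(one, center = c(20, 20, 20))
  nz1 <- which(p1$count > 0)
  if (length(nz1) == 1) expect_equal(p1$value[nz1], 1 / 3)

  # every bead from a different chain -> value 1
  many <- toy_config(lapply(0:3, function(k) matrix(c(25, 20 + k, 20), 1)), L)
  pm <- distinct_chains_per_residue(many, center = c(20, 20, 20))
  expect_true(all(pm$value[pm$count > 0] == 1))
})

test_that("orientation profile hits collinear, tangent and isotropic limits", {
  L <- 60L
  ctr <- c(30, 30, 30)
  # chain collinear with the radius vector -> cos^2 = 1
  rad <- toy_config(list(cbind(40:45, 30L, 30L)), L)
  pr <- orientation_profile(rad, center = ctr)
  expect_true(all(abs(pr$value[pr$count > 0] - 1) < 1e-12))

  # chain tangent to its shell -> cos^2 ~ 0
  tan_cfg <- toy_config(list(cbind(40L, 28:33, 30L)), L)
  pt <- orientation_profile(tan_cfg, center = ctr)
  expect_true(all(pt$value[pt$count > 0] < 0.1))

  # isotropically oriented rods -> mean cos^2 ~ 1/3
  set.seed(8)
  chains <- list()
  for (i in 1:400) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    base <- runif(3, 10, 50)
    pts <- round(rbind(base, base + u, base + 2 * u))
    # keep only chains that stay legal (distinct adjacent sites)
    if (any(duplicated(pts))) next
    d <- abs(diff(pts)); if (any(d > 1)) next
    chains[[length(chains) + 1]] <- pts
  }
  # place them far apart on a big lattice to avoid overlap
  L2 <- 256L
  chains <- lapply(seq_along(chains), function(i) {
    off <- c((i %% 16) * 16L, ((i %/% 16) %% 16) * 16L, (i %/% 256) * 16L)
    sweep(chains[[i]], 2, off, `+`) %% L2
  })
  cfg <- toy_config(chains, L2)
  po <- orientation_profile(cfg, center = c(8, 8, 8))
  mu <- sum(po$value * po$count, na.rm = TRUE) / sum(po$count)
  expect_equal(mu, 1 / 3, tolerance = 0.06)
})

test_that("interface width scaling recovers a planted exponent and error paths", {
  set.seed(4)
  Ns <- c(50, 100, 200, 400)
  rows <- do.call(rbind, lapply(Ns, function(N) {
    Tm <- seq(1, 10)
    delta_p <- 0.8 * N^0.45
    delta <- ifelse(Tm < 7, delta_p, delta_p * (1 + 0.8 * (Tm - 7)))
    data.frame(N = N, T = Tm, delta = delta)
  }))
  sc <- interface_width_scaling(rows, slope_threshold = 0.05)
  expect_equal(sc$exponent, 0.45, tolerance = 1e-9)

  # strictly increasing width with no plateau -> error path
  bad <- data.frame(N = rep(Ns, each = 5), T = rep(1:5, 4),
                    delta = ave(rep(Ns, each = 5), rep(Ns, each = 5),
                                FUN = function(n) n[1]^0.45 * (1 + 0.5 * (1:5))))
  expect_error(interface_width_scaling(bad, slope_threshold = 0.05),
               "no plateau")
})

test_that("planted droplet fixture round-trips through the interface fit", {
  drop <- make_droplet_config(40, 3e-3, 0.55, 11, 4, chain_length = 6, seed = 12)
  gt <- attr(drop, "ground_truth")
  expect_true(validate_config(drop))
  prof <- radial_density_profile(drop)
  fit <- fit_interface(prof)
  expect_equal(fit$r_mid, gt$r_mid, tolerance = 0.5 / gt$r_mid)
  expect_equal(fit$delta, gt$delta, tolerance = 0.10)

  # determinism and parameter validation
  d2 <- make_droplet_config(40, 3e-3, 0.55, 11, 4, chain_length = 6, seed = 12)
  expect_identical(drop$coords, d2$coords)
  expect_error(make_droplet_config(40, 0.5, 0.5, 11, 4), "below")
  expect_error(make_droplet_config(20, 1e-3, 0.5, 30, 4), "fit in the box")
})
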