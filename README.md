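# condensr

Lattice sticker-and-spacer simulation and analysis of biomolecular
condensates formed by prion-like low-complexity domains (PLCDs).

PLCDs are intrinsically disordered protein regions that phase separate into
condensates by a process coupled to percolation: aromatic *stickers*
(Tyr/Phe) form reversible crosslinks that network chains together, while
*spacers* set solubility. `condensr` implements a single-bead-per-residue
model of this process — Metropolis Monte Carlo over a ten-letter residue
alphabet on a periodic cubic lattice, contacts within √3 lattice units,
`kB = 1` — together with the analysis suite used to characterise the
resulting condensates:

* **Phase diagrams** — dense/dilute phase assignment by connectivity,
  binodals with replicate standard errors, the two-phase width
  `ω = log10(c_dilute/c_dense)`, and the ERMSL
  (`10^RMS(log10 c_sim/c_exp)`) for comparing dilute arms against
  measurements (1 = perfect overlay, 10 = an order of magnitude apart).
* **Conformations** — radius-of-gyration statistics per phase, the swelling
  ratio `α = √⟨R²g,dense⟩ / √⟨R²g,dilute⟩` and its master curve
  `α = 1 + exp[−a(ω − b)]`, apparent scaling exponents ν from internal
  distances, overlap concentration `φ* = N r³/⟨R²e⟩^{3/2}`, and ternary
  intra/inter/solvent contact fractions.
* **Network topology** — condensate graphs (chains as nodes, inter-chain
  sticker contacts as edges), betweenness centrality
  `g(n) = Σ σst(n)/σst`, mean path length and clustering against
  Erdős–Rényi references, centrality dynamics, the ratio of association
  `g_a`, and discrete-Weibull fits
  `P(s) = 1 − exp[−((s+1)/λ)^k]` to sticker-cluster sizes.
* **Interfaces** — exact-prior radial density profiles in 1/4-l.u. shells,
  hyperbolic-tangent interface fits for `(φ′, φ″, r_mid, Δ)`,
  crosslinks-per-sticker, radially resolved Rg/asphericity/local extension,
  distinct-chains-per-residue, `cos²θ` chain orientation, and the
  interface-width scaling `Δp ~ N^x`.
* **Fixtures** — deterministic generators with known ground truth (planted
  tanh droplets, planted-hub and Watts–Strogatz graphs, Weibull samples,
  offset binodal pairs, patterned sequences) so every stage is testable
  without simulation.

The Monte Carlo core is C++ (Rcpp); analyses are plain R on top of igraph
and minpack.lm.

## Worked example

Condense 250 short sticker-and-spacer chains into a droplet and ask whether
the condensate network is small-world:

```r
library(condensr)

seq <- generate_sequence(8, sticker_fraction = 0.25, patterning = "uniform")
hp  <- make_homopolymer_equivalent(8, epsilon = -3.3, template = seq)

traj <- run_simulation(list(hp$sequence), hp$model, temperature = 10,
                       n_sweeps = 2000, counts = 250, box_side = 40,
                       seed = 9, snapshot_interval = 200, init = "droplet")

g  <- build_condensate_graph(traj$config)
sw <- small_world_summary(g)
cat(sprintf("n=%d <k>=%.2f C=%.3f C_ER=%.4f C/C_ER=%.2f L/L_ER=%.2f\n",
            sw$n, sw$mean_degree, sw$C, sw$C_ER, sw$C_ratio, sw$L_ratio))
#> n=250 <k>=7.29 C=0.366 C_ER=0.0292 C/C_ER=12.56 L/L_ER=1.49
```

All 250 chains belong to one connected condensate. Its mean clustering
coefficient is ~13× the Erdős–Rényi value for a random graph of the same
size and mean degree, while the mean path length is within ~1.5× of random
— the small-world signature: crosslinking is locally dense around hub
chains, yet every chain is a short path from every other.

Fitting an interface, on a planted droplet with known ground truth:

```r
drop <- make_droplet_config(40, phi_dilute = 3e-3, phi_dense = 0.55,
                            r_mid = 11, delta = 4, chain_length = 6, seed = 12)
fit <- fit_interface(radial_density_profile(drop))
fit
#> <interface_fit> phi' = 0.00118, phi'' = 0.567, r_mid = 11.26 l.u., Delta = 3.73 l.u.
```

The four parameters of the planted tanh profile are recovered from the
realised lattice configuration; `fit$interface` gives the interfacial band
`r_mid ± Δ/2` used to localise interfacial statistics.

See `vignettes/condensate-methods.Rmd` for the model, every estimator's
definition and the numerical choices.

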