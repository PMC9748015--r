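---
title: "Lattice sticker-and-spacer condensates: models, statistics and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice sticker-and-spacer condensates: models, statistics and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensr)
```

# The model

`condensr` simulates and analyses coarse-grained models of prion-like
low-complexity domains (PLCDs), intrinsically disordered protein regions that
drive the formation of biomolecular condensates by phase separation coupled
to percolation. Each residue is one bead on a periodic cubic lattice. Nine
residue types are kept explicitly — tyrosine (Y), phenylalanine (F), arginine
(R), lysine (K), glycine (G), serine (S), threonine (T), glutamine (Q),
asparagine (N) — and all other amino acids collapse into a generic type X.
Tyrosine and phenylalanine are the *stickers*, the aromatic residues whose
reversible contacts crosslink chains into condensate-spanning networks;
arginine acts as an auxiliary sticker through its contact energies only, and
everything else is a *spacer* that modulates solubility.

Two beads are in contact when they sit within $\sqrt{3}$ lattice units of
each other (the 26-site neighbourhood), under minimum-image periodic
boundaries. Bonded neighbours along a chain are excluded from the energy;
bonds themselves fluctuate over the same $\sqrt 3$ range, a convention
inspired by bond-fluctuation lattice models. The configurational energy is
the sum of type-pair contact energies $\varepsilon(a,b)$ over all nonbonded
contacts; $k_B = 1$ and temperature is dimensionless.

## The contact-energy table

The published model's exact energy table is distributed as source data of
the original study and is not redistributed here. The packaged defaults
(`inst/extdata/contact_energies_synthetic.tsv`, loaded by
`default_contact_model()`) are a *synthetic* table constructed to satisfy
every printed constraint of that model:

* the sticker hierarchy of attraction strengths,
  $|\varepsilon_{YY}| > |\varepsilon_{YF}| > |\varepsilon_{FF}| >
  |\varepsilon_{R\text{-aromatic}}|$;
* replacing a Y–Y contact with a Y–K contact is the largest possible change
  in pair energy, and its magnitude is $0.47\,k_BT$ at $T = 40$ and
  $0.32\,k_BT$ at $T = 60$ — which pins $|\varepsilon_{YY} -
  \varepsilon_{YK}| = 18.95$ in simulation units over the working
  temperature grid $40 \le T \le 60$;
* lysine is repulsive toward the aromatics, spacer–spacer interactions are
  weakly attractive.

Any user-supplied table in the same TSV layout replaces the defaults via
`read_energy_table()`; symmetry is verified to $10^{-9}$ on load.

Variants whose net charge per residue (NCPR) deviates from the reference
sequence couple differently in multi-chain simulations than their
single-chain dimensions suggest. The adjustment implemented in
`adjust_model_for_ncpr()` adds a penalty $\kappa\,|\Delta\mathrm{NCPR}|$ to
every attractive entry. The published constant lives in supplementary
material we do not reproduce, so $\kappa$ defaults to 0 (adjustment off) and
both $\kappa$ and the functional form are overridable; this is a documented
stand-in, not a fitted value. Histidine and cysteine are treated as neutral
for NCPR (standard at pH 7).

## The Monte Carlo engine

`run_simulation()` performs Metropolis Monte Carlo: a proposed move is
accepted with probability $\min\{1, e^{-\Delta E / T}\}$. The move inventory
is

* **local**: one bead to a random vacant site of its 26-neighbourhood,
  subject to both bond constraints;
* **co-local**: two consecutive beads displaced by one common offset;
* **reptation**: the chain slides one step along its own contour, the
  freed end re-growing at a random bond-compatible site (types stay in
  sequence order);
* **chain translation**: a rigid displacement of one chain by up to 2 l.u.
  per axis;
* **cluster translation**: a rigid displacement of one connected cluster of
  chains, rejected if the displaced cluster would touch any outside chain
  (the standard no-merge rule, which preserves detailed balance; internal
  energy is unchanged, so legal proposals always accept).

All proposals are symmetric, so plain Metropolis acceptance satisfies
detailed balance for each kind. `move_set(local_only = TRUE)` restricts the
inventory to the local and co-local moves; every analysis that uses the
move count as a proxy for time (chain RMSD, centrality persistence, contact
lifetimes) refuses trajectories generated with non-local moves, because one
accepted translation teleports a chain without physical meaning on that
clock. The engine tracks the energy incrementally and reports the drift
against a full recomputation with every trajectory; the test suite holds
this below $10^{-9}$ over $10^6$ moves.

A *sweep* is one attempted move per bead. Equilibration is handled by
discarding the first half of the stored frames
(`equilibrated_frames()`), plus a split-half stationarity flag that
compares the energy means of the retained halves at two standard errors.
Both choices are configurable.

# The statistics

**Phases and binodals.** Chains are clustered by inter-chain contact; the
largest connected cluster is the dense phase (`assign_phases()`). The dense
concentration is the bead volume fraction inside the dense region; two
region estimators are shipped because the exact convention is a genuine
design freedom: the default *envelope* estimator dilates the occupied sites
of dense chains by one lattice unit (a morphological dilation rather than a
convex hull, which is ill-defined under periodic boundaries), and the
*profile* estimator takes the plateaus of the fitted radial density
profile. The two-phase width is $\omega(T) = \log_{10}(c_{\rm dilute} /
c_{\rm dense})$, the package's only closeness-to-criticality coordinate:
critical temperatures are never extrapolated from binodal fits, since the
functional forms used for such fits are only valid asymptotically close to
criticality.

**ERMSL.** Two dilute arms are compared by the exponential
root-mean-square log, $\mathrm{ERMSL} =
10^{\sqrt{\langle(\log_{10} c_{\rm sim}/c_{\rm exp})^2\rangle}}$, which is 1
for perfect overlap and 10 when concentrations differ by an order of
magnitude on average — those two printed anchors fix the base-10
antilog-of-RMS-log form. Arms on different temperature grids are matched by
exact temperature where possible and otherwise by log-linear interpolation
in temperature.

**Swelling.** $\alpha = \sqrt{\langle R_{g,\rm dense}^2\rangle} \big/
\sqrt{\langle R_{g,\rm dilute}^2\rangle}$ uses root-mean-square $R_g$, not
the mean of $R_g$. Across variants the $(\omega, \alpha)$ points collapse
onto the master curve $\alpha = 1 + e^{-a(\omega - b)}$, fit by
`fit_master_curve()`; on synthetic data generated at the published
constants $(a, b) = (0.33, -9.5)$ the fit recovers them to $10^{-6}$.

**Contact fractions and overlap.** For every bead the 26 neighbour sites
are classified as solvated, same-chain or other-chain; per-chain sums give
$f_{\rm sol} + f_{\rm intra} + f_{\rm inter} = 1$ exactly. This census is a
pure occupancy count, so bonded neighbours count toward $f_{\rm intra}$. By
contrast, the crosslink and association tallies (crosslinks per sticker,
ratio of association, sticker clusters) exclude bonded neighbours, because
a covalent bond is not a reversible crosslink. The overlap volume fraction
is $\phi^* = N r^3 / \langle R_e^2\rangle^{3/2}$ with bead radius $r = 0.5$
l.u., evaluated on dilute-phase chains.

**Condensate graphs.** Chains are nodes; an undirected edge joins two
chains when any inter-chain sticker pair is within $\sqrt 3$; the graph is
restricted to its largest component. Betweenness
$g(n) = \sum_{s \ne n \ne t} \sigma_{st}(n)/\sigma_{st}$ is computed in the
standard undirected convention (each unordered pair once); the printed sum
reads as ordered pairs, which exactly doubles every value, so
`betweenness_centrality(ordered = TRUE)` is provided and the convention is
flagged wherever it matters. Mean path length
$L = \tfrac{2}{n(n-1)}\sum_{i<j} d(v_i, v_j)$ and the mean of local
clustering coefficients $C_i = 2|e_{jk}|/(k_i(k_i - 1))$ (nodes of degree
$< 2$ contributing 0) are referenced to the Erdős–Rényi values
$L_{ER} = \log n / \log\langle k\rangle$ and $C_{ER} = \langle k\rangle/n$;
finite-size corrections are not applied because $\langle k \rangle \ll n$
in all intended regimes. These primitives are computed through igraph; the
test suite certifies them against an independent brute-force all-pairs
enumeration on every random graph up to $n = 12$ it generates. Top-5%
centrality sets break ties at the cutoff by chain id, deterministically.

**Sticker clusters.** Connected sets of stickers under nonbonded
sticker–sticker adjacency (intra- and inter-chain alike) have sizes $s$;
each cluster-size frequency is multiplied by $s$ to give the probability
that a *sticker* sits in a cluster of size $s$. The cumulative distribution
is fit to the discrete Weibull form $P(s) = 1 - e^{-((s+1)/\lambda)^k}$ by
weighted least squares on $\ln[-\ln(1-P)]$ vs $\ln(s+1)$, removing points
more than 3 scaled median absolute deviations from the median residual.
The MAD filter doubles as the "linear region" restriction: on our fixtures
it removes exactly the exponentially-bounded head and starved tail that
motivated restricting the fit, so no separate run-detection heuristic is
layered on top; an explicit `size_range` is accepted for manual control.

**Interface profiles.** All radial statistics use shells of width 1/4 l.u.
around the condensate centre of mass, which is computed per axis with
circular means so droplets wrapped across the periodic boundary are handled
exactly. Shell volumes are exact lattice-site counts per shell (cached per
box and centre), not continuum approximations; summed over shells they
reproduce the box volume exactly. The density profile is fit in
$\log_{10}$ to
$$\log_{10}\phi(r) = \tfrac12[\log_{10}\phi'' + \log_{10}\phi'] -
  \tfrac12[\log_{10}\phi'' - \log_{10}\phi']
  \tanh\!\left[\frac{2(r - r_{\rm mid})}{\Delta}\right],$$
initialised from the profile endpoints, the half-log-density crossing and
the 25–75% span. Shells holding fewer than `min_sites = 10` lattice sites
are excluded from the fit: the innermost shells of any radial grid contain
a handful of sites, so their densities are 0-or-1 noise with enormous
leverage in log space. The interface band is reported as
$r_{\rm mid} \pm \Delta/2$. Radially resolved chain properties ($R_g$,
asphericity) use bead-weighted binning — every bead contributes its chain's
value to its own shell — and the local extension is the distance between
residues exactly 5 apart, binned by the first residue's shell. The
asphericity is the normalised gyration-tensor form
$[(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 +
(\lambda_3-\lambda_1)^2] / [2(\lambda_1+\lambda_2+\lambda_3)^2] \in [0,1]$,
chosen because the conventional 0.4 "cigar" threshold is consistent with
this normalisation; the function is exported separately so another
convention can be swapped in. Chain orientation evaluates
$\cos^2\theta$ between the end-to-end segment and the end-to-centre
segment, once per end, each binned by that end's shell; an isotropic
ensemble averages 1/3.

# The synthetic-fixture generators

Every analysis stage is testable without simulation through deterministic
generators that return their ground truth alongside the data:
sticker-and-spacer sequences with exact sticker counts and uniform, blocky
or random patterning (uniform spacing mirrors the aromatic patterning of
natural PLCDs); planted-droplet configurations grown site-by-site with
acceptance probability equal to a target tanh profile (a statistical
fixture, not simulation physics — but always a legal configuration);
planted-hub graphs whose bridge construction guarantees the hubs the top
betweenness; Watts–Strogatz graphs for small-world calibration, with the
closed-form ring-lattice clustering $3(k-2)/(4(k-1))$ at $p = 0$; discrete
Weibull samples on the physical support $s \ge 1$ (the nominal mass of the
continuous-form CDF below $s = 1$ is absorbed into $s = 1$, so the
empirical CDF matches the closed form exactly at every observed size); and
binodal-arm pairs with a known log offset, whose true ERMSL is
$10^{|{\rm offset}|}$ by construction.

What the fixtures do *not* emulate: experimental noise beyond log-normal
jitter, capillary fluctuations of real interfaces, and any sequence
chemistry beyond the sticker/spacer dichotomy. A passing fixture test
certifies the estimator, not the field realism of the generator.

# Study conditions and problem sizes

The published campaigns simulate chains of 137 residues, $10^4$-chain
droplets and $120^3$ boxes on cluster hardware. The package reproduces the
*machinery* of those campaigns and exercises it at desk scale; the shipped
tests and the acceptance script use the following conditions, chosen once
as the smallest systems in which each phenomenon is cleanly expressed:

* single-chain scaling: an 80-bead athermal chain in a $64^3$ box,
  internal-distance window $8 \dots 40$ — the self-avoiding-walk regime
  ($\nu \approx 0.588$);
* collapse: a 40-bead chain at $\varepsilon = -3.3$, $T = 6$, whose
  internal-distance exponent drops far below the ideal value;
* phase coexistence and swelling: 60 chains of 25 beads at
  $\varepsilon = -3.3$ in a $32^3$ box, started from a pre-formed droplet.
  For 25-bead chains the two-phase window sits near $T \approx 30$–$37$
  (shorter chains condense at lower temperatures than the 137-residue
  systems simulated at $40 \le T \le 60$); $T = 33$ and $T = 36$ bracket a
  populated dilute phase with $\omega \approx -2.9$ and $-1.9$;
* interface structure: 700 sticker-and-spacer 30-mers (20% tyrosine,
  uniformly patterned) at $T = 12$ in a $52^3$ box — a droplet of radius
  ~20 l.u., large enough for a well-conditioned tanh fit;
* condensate graphs: 250 chains of 8 beads (2 uniformly placed stickers)
  at $T = 10$, pre-formed droplet.

Scaling down changes which signatures are expressible. The orientational
interface signature (mean $\cos^2\theta$ above 1/3 inside the fitted band)
is robust at every scale we probed. The interfacial $R_g$ *maximum* of the
full-scale campaigns is not: across homopolymer and sticker systems with
chains of 25–100 beads and droplet radii of 10–23 l.u., at quench depths
from deep to near-critical, the band-mean $R_g$ sits between the dense and
dilute values rather than above both. Chains comparable in size to the
interfacial width have no room to dangle the long tails that drive the
full-scale expansion, so the corresponding check in the test suite records
this limitation as a failure rather than masking it. The published
campaign-scale quantities —
the master-curve constants $(0.33, -9.5)$, the interface-width exponent
$\Delta_p \sim N^{0.45}$, the homopolymer-equivalent energy $-3.3$ — are
consumed as inputs and verified as machinery round-trips on synthetic data
at those constants, not re-derived from desk-scale simulation.

# Known limitations

* The packaged energy table is synthetic (anchored to printed constraints,
  not the published source data); quantitative binodal positions will
  differ from the published ones even at matched sizes.
* The NCPR adjustment constant is not published in the main text; with the
  default $\kappa = 0$ charged variants are under-penalised.
* The move inventory is a documented stand-in for the original engine's
  (whose exact inventory and frequencies are supplementary material);
  equilibrium distributions agree by detailed balance, kinetic quantities
  (lifetimes, RMSD per move) are convention-dependent.
* `temperature_scale` / `concentration_scale` config constants are
  pass-through factors for unit conversion; the package never computes
  Kelvin or molar units itself.
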