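// Metropolis Monte Carlo engine for sticker-and-spacer polymers on a
// periodic cubic lattice. Beads occupy single sites; bonded beads must stay
// within sqrt(3) lattice units (chebyshev distance 1 under minimum image),
// and nonbonded beads in the 26-site neighbourhood contribute the pairwise
// contact energy of their residue types. kB = 1; temperature dimensionless.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

namespace {

struct Sim {
  int L, L2, L3, nb, nchain;
  std::vector<int> px, py, pz;     // bead coords in [0, L)
  std::vector<int> occ;            // site -> bead index or -1
  std::vector<int> type;           // bead -> 0..9
  std::vector<int> chain;          // bead -> chain index
  std::vector<int> cstart, clen;   // chain -> first bead, length
  std::vector<double> eps;         // 10x10 row-major
  int offs[26][3];

  int wrap(int v) const { int m = v % L; return m < 0 ? m + L : m; }
  int site(int x, int y, int z) const { return x + L * (y + L * z); }
  int bead_site(int b) const { return site(px[b], py[b], pz[b]); }
  double pair_eps(int a, int b) const { return eps[type[a] * 10 + type[b]]; }
  bool bonded(int a, int b) const {
    return chain[a] == chain[b] && (a - b == 1 || b - a == 1);
  }
  // minimum-image chebyshev distance between two coordinate triples
  int cheb(int x1, int y1, int z1, int x2, int y2, int z2) const {
    int dx = std::abs(x1 - x2); if (dx > L - dx) dx = L - dx;
    int dy = std::abs(y1 - y2); if (dy > L - dy) dy = L - dy;
    int dz = std::abs(z1 - z2); if (dz > L - dz) dz = L - dz;
    return std::max(dx, std::max(dy, dz));
  }
  bool in_contact(int a, int b) const {
    return cheb(px[a], py[a], pz[a], px[b], py[b], pz[b]) == 1;
  }

  void init_offsets() {
    int k = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          offs[k][0] = dx; offs[k][1] = dy; offs[k][2] = dz; ++k;
        }
  }

  void build_occ() {
    occ.assign(L3, -1);
    for (int b = 0; b < nb; ++b) {
      int s = bead_site(b);
      if (occ[s] >= 0) stop("two beads occupy one lattice site");
      occ[s] = b;
    }
  }

  // energy of bead b against current occupancy, excluding bonded neighbours
  double bead_env_energy(int b, int x, int y, int z) const {
    double e = 0.0;
    for (int k = 0; k < 26; ++k) {
      int s = site(wrap(x + offs[k][0]), wrap(y + offs[k][1]), wrap(z + offs[k][2]));
      int o = occ[s];
      if (o >= 0 && o != b && !bonded(b, o)) e += pair_eps(b, o);
    }
    return e;
  }

  double total_energy() const {
    double e = 0.0;
    for (int b = 0; b < nb; ++b) e += bead_env_energy(b, px[b], py[b], pz[b]);
    return e / 2.0;
  }

  // --- move machinery -----------------------------------------------------
  // Each proposal removes the moved beads from occ, evaluates the energy of
  // the moved set at old and new positions (external contacts plus internal
  // nonbonded contacts, each once), applies Metropolis, and restores or
  // commits.

  double set_energy(const std::vector<int> &beads,
                    const std::vector<int> &xs, const std::vector<int> &ys,
                    const std::vector<int> &zs) const {
    // beads must already be removed from occ
    double e = 0.0;
    size_t m = beads.size();
    for (size_t i = 0; i < m; ++i) {
      int b = beads[i];
      for (int k = 0; k < 26; ++k) {
        int s = site(wrap(xs[i] + offs[k][0]), wrap(ys[i] + offs[k][1]),
                     wrap(zs[i] + offs[k][2]));
        int o = occ[s];
        if (o >= 0 && !bonded(b, o)) e += pair_eps(b, o);
      }
      for (size_t j = i + 1; j < m; ++j) {
        int o = beads[j];
        if (bonded(b, o)) continue;
        if (cheb(xs[i], ys[i], zs[i], xs[j], ys[j], zs[j]) == 1)
          e += pair_eps(b, o);
      }
    }
    return e;
  }

  bool metropolis(double dE, double temperature) {
    if (dE <= 0) return true;
    return unif_rand() < std::exp(-dE / temperature);
  }

  int rand_int(int n) {  // uniform on 0..n-1
    int v = (int)(unif_rand() * n);
    return v >= n ? n - 1 : v;
  }

  // returns: 0 rejected-illegal, 1 rejected-metropolis, 2 accepted
  int move_local(double T) {
    int b = rand_int(nb);
    int k = rand_int(26);
    int nx = wrap(px[b] + offs[k][0]), ny = wrap(py[b] + offs[k][1]),
        nz = wrap(pz[b] + offs[k][2]);
    if (occ[site(nx, ny, nz)] >= 0) return 0;
    // bond constraints to chain neighbours
    int c = chain[b];
    if (b > cstart[c] && cheb(nx, ny, nz, px[b-1], py[b-1], pz[b-1]) > 1) return 0;
    if (b < cstart[c] + clen[c] - 1 &&
        cheb(nx, ny, nz, px[b+1], py[b+1], pz[b+1]) > 1) return 0;
    std::vector<int> beads{b}, ox{px[b]}, oy{py[b]}, oz{pz[b]},
                     nxs{nx}, nys{ny}, nzs{nz};
    occ[bead_site(b)] = -1;
    double e0 = set_energy(beads, ox, oy, oz);
    double e1 = set_energy(beads, nxs, nys, nzs);
    if (metropolis(e1 - e0, T)) {
      px[b] = nx; py[b] = ny; pz[b] = nz;
      occ[site(nx, ny, nz)] = b;
      lastDE = e1 - e0;
      return 2;
    }
    occ[site(ox[0], oy[0], oz[0])] = b;
    return 1;
  }

  int move_colocal(double T) {
    int b = rand_int(nb);
    int c = chain[b];
    if (b >= cstart[c] + clen[c] - 1) return 0;  // need successor in chain
    int b2 = b + 1;
    int k = rand_int(26);
    int dx = offs[k][0], dy = offs[k][1], dz = offs[k][2];
    int nx1 = wrap(px[b] + dx), ny1 = wrap(py[b] + dy), nz1 = wrap(pz[b] + dz);
    int nx2 = wrap(px[b2] + dx), ny2 = wrap(py[b2] + dy), nz2 = wrap(pz[b2] + dz);
    occ[bead_site(b)] = -1;
    occ[bead_site(b2)] = -1;
    bool legal = occ[site(nx1, ny1, nz1)] < 0 && occ[site(nx2, ny2, nz2)] < 0;
    if (legal && b > cstart[c] &&
        cheb(nx1, ny1, nz1, px[b-1], py[b-1], pz[b-1]) > 1) legal = false;
    if (legal && b2 < cstart[c] + clen[c] - 1 &&
        cheb(nx2, ny2, nz2, px[b2+1], py[b2+1], pz[b2+1]) > 1) legal = false;
    if (!legal) {
      occ[bead_site(b)] = b; occ[bead_site(b2)] = b2;
      return 0;
    }
    std::vector<int> beads{b, b2}, ox{px[b], px[b2]}, oy{py[b], py[b2]},
                     oz{pz[b], pz[b2]}, nxs{nx1, nx2}, nys{ny1, ny2}, nzs{nz1, nz2};
    double e0 = set_energy(beads, ox, oy, oz);
    double e1 = set_energy(beads, nxs, nys, nzs);
    if (metropolis(e1 - e0, T)) {
      px[b] = nx1; py[b] = ny1; pz[b] = nz1;
      px[b2] = nx2; py[b2] = ny2; pz[b2] = nz2;
      occ[bead_site(b)] = b; occ[bead_site(b2)] = b2;
      lastDE = e1 - e0;
      return 2;
    }
    occ[site(ox[0], oy[0], oz[0])] = b;
    occ[site(ox[1], oy[1], oz[1])] = b2;
    return 1;
  }

  int move_reptation(double T) {
    int c = rand_int(nchain);
    int s0 = cstart[c], len = clen[c];
    if (len < 2) return 0;
    bool toward_head = unif_rand() < 0.5;  // grow at last bead, vacate first
    int grow = toward_head ? s0 + len - 1 : s0;
    int k = rand_int(26);
    int nx = wrap(px[grow] + offs[k][0]), ny = wrap(py[grow] + offs[k][1]),
        nz = wrap(pz[grow] + offs[k][2]);
    std::vector<int> beads(len), ox(len), oy(len), oz(len),
                     nxs(len), nys(len), nzs(len);
    for (int i = 0; i < len; ++i) {
      int b = s0 + i;
      beads[i] = b; ox[i] = px[b]; oy[i] = py[b]; oz[i] = pz[b];
      occ[bead_site(b)] = -1;
    }
    // shift coordinates along the chain; bead types stay with indices
    for (int i = 0; i < len; ++i) {
      int src;  // index (within chain) of the old position bead i inherits
      if (toward_head) src = i + 1; else src = i - 1;
      if (src >= 0 && src < len) {
        nxs[i] = ox[src]; nys[i] = oy[src]; nzs[i] = oz[src];
      } else {
        nxs[i] = nx; nys[i] = ny; nzs[i] = nz;
      }
    }
    // legality: new site vacant (old chain sites are free now)
    bool legal = occ[site(nx, ny, nz)] < 0;
    // the new end site must not collide with the shifted chain itself
    if (legal) {
      for (int i = 0; i < len; ++i) {
        int shifted = toward_head ? (i == len - 1) : (i == 0);
        if (!shifted && nxs[i] == nx && nys[i] == ny && nzs[i] == nz) {
          legal = false; break;
        }
      }
    }
    if (!legal) {
      for (int i = 0; i < len; ++i) occ[site(ox[i], oy[i], oz[i])] = beads[i];
      return 0;
    }
    double e0 = set_energy(beads, ox, oy, oz);
    double e1 = set_energy(beads, nxs, nys, nzs);
    if (metropolis(e1 - e0, T)) {
      for (int i = 0; i < len; ++i) {
        int b = beads[i];
        px[b] = nxs[i]; py[b] = nys[i]; pz[b] = nzs[i];
        occ[bead_site(b)] = b;
      }
      lastDE = e1 - e0;
      return 2;
    }
    for (int i = 0; i < len; ++i) occ[site(ox[i], oy[i], oz[i])] = beads[i];
    return 1;
  }

  int rand_shift() { return rand_int(5) - 2; }  // uniform on -2..2

  int move_chain_translate(double T) {
    int c = rand_int(nchain);
    int s0 = cstart[c], len = clen[c];
    int dx = rand_shift(), dy = rand_shift(), dz = rand_shift();
    if (dx == 0 && dy == 0 && dz == 0) return 0;
    std::vector<int> beads(len), ox(len), oy(len), oz(len),
                     nxs(len), nys(len), nzs(len);
    for (int i = 0; i < len; ++i) {
      int b = s0 + i;
      beads[i] = b; ox[i] = px[b]; oy[i] = py[b]; oz[i] = pz[b];
      nxs[i] = wrap(px[b] + dx); nys[i] = wrap(py[b] + dy); nzs[i] = wrap(pz[b] + dz);
      occ[bead_site(b)] = -1;
    }
    bool legal = true;
    for (int i = 0; i < len && legal; ++i)
      if (occ[site(nxs[i], nys[i], nzs[i])] >= 0) legal = false;
    if (!legal) {
      for (int i = 0; i < len; ++i) occ[site(ox[i], oy[i], oz[i])] = beads[i];
      return 0;
    }
    double e0 = set_energy(beads, ox, oy, oz);
    double e1 = set_energy(beads, nxs, nys, nzs);
    if (metropolis(e1 - e0, T)) {
      for (int i = 0; i < len; ++i) {
        int b = beads[i];
        px[b] = nxs[i]; py[b] = nys[i]; pz[b] = nzs[i];
        occ[bead_site(b)] = b;
      }
      lastDE = e1 - e0;
      return 2;
    }
    for (int i = 0; i < len; ++i) occ[site(ox[i], oy[i], oz[i])] = beads[i];
    return 1;
  }

  // chains connected to chain c via inter-chain contacts (BFS)
  void chain_cluster(int c, std::vector<int> &members) const {
    std::vector<char> seen(nchain, 0);
    std::queue<int> q;
    q.push(c); seen[c] = 1;
    while (!q.empty()) {
      int cc = q.front(); q.pop();
      members.push_back(cc);
      for (int i = 0; i < clen[cc]; ++i) {
        int b = cstart[cc] + i;
        for (int k = 0; k < 26; ++k) {
          int s = site(wrap(px[b] + offs[k][0]), wrap(py[b] + offs[k][1]),
                       wrap(pz[b] + offs[k][2]));
          int o = occ[s];
          if (o >= 0 && !seen[chain[o]]) {
            seen[chain[o]] = 1;
            q.push(chain[o]);
          }
        }
      }
    }
  }

  // Translate the whole contact cluster containing a random chain. The move
  // is rejected if the displaced cluster would overlap or newly touch any
  // outside chain (standard no-merge rule), which preserves detailed
  // balance; the internal energy is unchanged so legal moves always accept.
  int move_cluster_translate(double) {
    int c = rand_int(nchain);
    std::vector<int> members;
    chain_cluster(c, members);
    if ((int)members.size() == nchain) return 0;  // nothing to move against
    int dx = rand_shift(), dy = rand_shift(), dz = rand_shift();
    if (dx == 0 && dy == 0 && dz == 0) return 0;
    std::vector<char> inset(nb, 0);
    std::vector<int> beads;
    for (int cc : members)
      for (int i = 0; i < clen[cc]; ++i) {
        beads.push_back(cstart[cc] + i);
        inset[cstart[cc] + i] = 1;
      }
    for (int b : beads) occ[bead_site(b)] = -1;
    bool legal = true;
    for (size_t i = 0; i < beads.size() && legal; ++i) {
      int b = beads[i];
      int nx = wrap(px[b] + dx), ny = wrap(py[b] + dy), nz = wrap(pz[b] + dz);
      if (occ[site(nx, ny, nz)] >= 0) { legal = false; break; }
      for (int k = 0; k < 26; ++k) {
        int s = site(wrap(nx + offs[k][0]), wrap(ny + offs[k][1]),
                     wrap(nz + offs[k][2]));
        int o = occ[s];
        if (o >= 0 && !inset[o]) { legal = false; break; }  // no-merge rule
      }
    }
    if (!legal) {
      for (int b : beads) occ[bead_site(b)] = b;
      return 0;
    }
    for (int b : beads) {
      px[b] = wrap(px[b] + dx); py[b] = wrap(py[b] + dy); pz[b] = wrap(pz[b] + dz);
    }
    for (int b : beads) occ[bead_site(b)] = b;
    lastDE = 0.0;
    return 2;
  }

  double lastDE = 0.0;
};

void sim_from_args(Sim &S, const IntegerMatrix &coords,
                   const IntegerVector &chain_id, const IntegerVector &type,
                   int box, const NumericMatrix &eps) {
  S.L = box; S.L2 = box * box; S.L3 = S.L2 * box;
  S.nb = coords.nrow();
  if (chain_id.size() != S.nb || type.size() != S.nb)
    stop("coords, chain_id and type disagree in length");
  S.px.resize(S.nb); S.py.resize(S.nb); S.pz.resize(S.nb);
  S.type.resize(S.nb); S.chain.resize(S.nb);
  for (int b = 0; b < S.nb; ++b) {
    S.px[b] = coords(b, 0); S.py[b] = coords(b, 1); S.pz[b] = coords(b, 2);
    if (S.px[b] < 0 || S.px[b] >= box || S.py[b] < 0 || S.py[b] >= box ||
        S.pz[b] < 0 || S.pz[b] >= box)
      stop("bead coordinate outside [0, box)");
    S.type[b] = type[b] - 1;
    if (S.type[b] < 0 || S.type[b] > 9) stop("bead type out of range 1..10");
    S.chain[b] = chain_id[b] - 1;
  }
  // chains must be contiguous blocks in bead order
  S.nchain = 0;
  for (int b = 0; b < S.nb; ++b) S.nchain = std::max(S.nchain, S.chain[b] + 1);
  S.cstart.assign(S.nchain, -1);
  S.clen.assign(S.nchain, 0);
  for (int b = 0; b < S.nb; ++b) {
    int c = S.chain[b];
    if (S.cstart[c] < 0) S.cstart[c] = b;
    else if (S.cstart[c] + S.clen[c] != b)
      stop("beads of a chain must be contiguous and ordered");
    S.clen[c]++;
  }
  S.eps.resize(100);
  for (int i = 0; i < 10; ++i)
    for (int j = 0; j < 10; ++j) S.eps[i * 10 + j] = eps(i, j);
  S.init_offsets();
  S.build_occ();
  // bond audit
  for (int c = 0; c < S.nchain; ++c)
    for (int i = 1; i < S.clen[c]; ++i) {
      int b = S.cstart[c] + i;
      if (S.cheb(S.px[b], S.py[b], S.pz[b], S.px[b-1], S.py[b-1], S.pz[b-1]) > 1)
        stop("bonded beads farther apart than sqrt(3)");
    }
}

}  // namespace

// [[Rcpp::export]]
double cpp_total_energy(IntegerMatrix coords, IntegerVector chain_id,
                        IntegerVector type, int box, NumericMatrix eps) {
  Sim S;
  sim_from_args(S, coords, chain_id, type, box, eps);
  return S.total_energy();
}

// [[Rcpp::export]]
List cpp_run_mc(IntegerMatrix coords, IntegerVector chain_id,
                IntegerVector type, int box, NumericMatrix eps,
                double temperature, int n_sweeps, int moves_per_sweep,
                int snapshot_interval, NumericVector move_weights) {
  if (temperature <= 0) stop("temperature must be positive");
  if (move_weights.size() != 5) stop("move_weights must have length 5");
  Sim S;
  sim_from_args(S, coords, chain_id, type, box, eps);
  RNGScope scope;

  double wsum = 0.0;
  for (int i = 0; i < 5; ++i) {
    if (move_weights[i] < 0) stop("move weights must be nonnegative");
    wsum += move_weights[i];
  }
  if (wsum <= 0) stop("at least one move weight must be positive");
  double cum[5];
  double acc = 0.0;
  for (int i = 0; i < 5; ++i) { acc += move_weights[i] / wsum; cum[i] = acc; }

  double E = S.total_energy();
  std::vector<IntegerMatrix> frames;
  std::vector<int> frame_steps;
  std::vector<double> frame_E;
  IntegerVector attempts(5), accepts(5), illegal(5);

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int m = 0; m < moves_per_sweep; ++m) {
      double u = unif_rand();
      int kind = 0;
      while (kind < 4 && u > cum[kind]) ++kind;
      attempts[kind]++;
      S.lastDE = 0.0;
      int res;
      switch (kind) {
        case 0: res = S.move_local(temperature); break;
        case 1: res = S.move_colocal(temperature); break;
        case 2: res = S.move_reptation(temperature); break;
        case 3: res = S.move_chain_translate(temperature); break;
        default: res = S.move_cluster_translate(temperature); break;
      }
      if (res == 2) { accepts[kind]++; E += S.lastDE; }
      else if (res == 0) illegal[kind]++;
    }
    if (snapshot_interval > 0 &&
        (sweep % snapshot_interval == 0 || sweep == n_sweeps)) {
      if (frame_steps.empty() || frame_steps.back() != sweep) {
        IntegerMatrix fr(S.nb, 3);
        for (int b = 0; b < S.nb; ++b) {
          fr(b, 0) = S.px[b]; fr(b, 1) = S.py[b]; fr(b, 2) = S.pz[b];
        }
        frames.push_back(fr);
        frame_steps.push_back(sweep);
        frame_E.push_back(E);
      }
    }
    if (sweep % 256 == 0) Rcpp::checkUserInterrupt();
  }

  double E_recomputed = S.total_energy();
  IntegerMatrix final_coords(S.nb, 3);
  for (int b = 0; b < S.nb; ++b) {
    final_coords(b, 0) = S.px[b]; final_coords(b, 1) = S.py[b];
    final_coords(b, 2) = S.pz[b];
  }
  return List::create(
    _["frames"] = wrap(frames),
    _["frame_steps"] = wrap(frame_steps),
    _["frame_energies"] = wrap(frame_E),
    _["final_coords"] = final_coords,
    _["energy_incremental"] = E,
    _["energy_recomputed"] = E_recomputed,
    _["attempts"] = attempts,
    _["accepts"] = accepts,
    _["illegal"] = illegal);
}

// All contacting bead pairs (chebyshev distance 1 under minimum image).
// Returns a 4-column matrix: bead i, bead j (1-based, i < j), same_chain,
// bonded.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(IntegerMatrix coords, IntegerVector chain_id,
                                int box) {
  Sim S;
  IntegerVector type(coords.nrow(), 1);
  sim_from_args(S, coords, chain_id, type, box,
                NumericMatrix(10, 10));
  std::vector<int> vi, vj, vsame, vbond;
  for (int b = 0; b < S.nb; ++b) {
    for (int k = 0; k < 26; ++k) {
      int s = S.site(S.wrap(S.px[b] + S.offs[k][0]),
                     S.wrap(S.py[b] + S.offs[k][1]),
                     S.wrap(S.pz[b] + S.offs[k][2]));
      int o = S.occ[s];
      if (o > b) {
        vi.push_back(b + 1); vj.push_back(o + 1);
        vsame.push_back(S.chain[b] == S.chain[o]);
        vbond.push_back(S.bonded(b, o));
      }
    }
  }
  IntegerMatrix out(vi.size(), 4);
  for (size_t r = 0; r < vi.size(); ++r) {
    out(r, 0) = vi[r]; out(r, 1) = vj[r]; out(r, 2) = vsame[r]; out(r, 3) = vbond[r];
  }
  colnames(out) = CharacterVector::create("i", "j", "same_chain", "bonded");
  return out;
}

// Per-bead census of the 26-site neighbourhood. Columns: empty, same_chain,
// other_chain (site occupancy, bonded neighbours included in same_chain),
// st_intra, st_inter, sp_intra, sp_inter (nonbonded neighbours that are
// stickers/spacers, split by chain identity).
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_census(IntegerMatrix coords, IntegerVector chain_id,
                                  LogicalVector sticker, int box) {
  Sim S;
  IntegerVector type(coords.nrow(), 1);
  sim_from_args(S, coords, chain_id, type, box, NumericMatrix(10, 10));
  if (sticker.size() != S.nb) stop("sticker flag length mismatch");
  IntegerMatrix out(S.nb, 7);
  for (int b = 0; b < S.nb; ++b) {
    int empty = 0, same = 0, other = 0, sti = 0, ste = 0, spi = 0, spe = 0;
    for (int k = 0; k < 26; ++k) {
      int s = S.site(S.wrap(S.px[b] + S.offs[k][0]),
                     S.wrap(S.py[b] + S.offs[k][1]),
                     S.wrap(S.pz[b] + S.offs[k][2]));
      int o = S.occ[s];
      if (o < 0) { ++empty; continue; }
      bool samec = S.chain[o] == S.chain[b];
      if (samec) ++same; else ++other;
      if (S.bonded(b, o)) continue;
      if (sticker[o]) { if (samec) ++sti; else ++ste; }
      else            { if (samec) ++spi; else ++spe; }
    }
    out(b, 0) = empty; out(b, 1) = same; out(b, 2) = other;
    out(b, 3) = sti; out(b, 4) = ste; out(b, 5) = spi; out(b, 6) = spe;
  }
  colnames(out) = CharacterVector::create(
    "empty", "same_chain", "other_chain",
    "st_intra", "st_inter", "sp_intra", "sp_inter");
  return out;
}

// Exact lattice-site counts per radial shell of width `width` around a
// (generally non-integer) centre, distances under minimum image in a
// periodic cube. Shell i covers [i*width, (i+1)*width).
// [[Rcpp::export]]
NumericVector cpp_shell_site_counts(int box, NumericVector center,
                                    double width, int nshell) {
  if (center.size() != 3) stop("center must have length 3");
  NumericVector counts(nshell);
  double hw = box / 2.0;
  for (int x = 0; x < box; ++x) {
    double dx = std::abs(x - center[0]);
    if (dx > hw) dx = box - dx;
    for (int y = 0; y < box; ++y) {
      double dy = std::abs(y - center[1]);
      if (dy > hw) dy = box - dy;
      for (int z = 0; z < box; ++z) {
        double dz = std::abs(z - center[2]);
        if (dz > hw) dz = box - dz;
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        int i = (int)(r / width);
        if (i < nshell) counts[i] += 1;
      }
    }
  }
  return counts;
}

// Grow chains site-by-site with per-site acceptance weights in [0, 1]
// (rejection sampling against the maximum weight). Used by the fixture
// generators and the initial-condition builders; always produces a legal
// configuration (vacant sites, bonds within sqrt(3)). weight has length
// box^3 indexed site = x + box*(y + box*z).
// [[Rcpp::export]]
IntegerMatrix cpp_grow_chains(IntegerVector chain_lengths, int box,
                              NumericVector weight, int max_restarts) {
  int L = box, L2 = L * L, L3 = L2 * L;
  if (weight.size() != L3) stop("weight must have length box^3");
  double wmax = 0.0;
  for (int s = 0; s < L3; ++s) {
    if (weight[s] < 0) stop("weights must be nonnegative");
    wmax = std::max(wmax, (double)weight[s]);
  }
  if (wmax <= 0) stop("all placement weights are zero");
  int nchain = chain_lengths.size();
  int nb = 0;
  for (int c = 0; c < nchain; ++c) nb += chain_lengths[c];
  if (nb >= L3) stop("more beads than lattice sites");
  RNGScope scope;
  std::vector<int> occ(L3, -1);
  IntegerMatrix out(nb, 3);
  int offs[26][3];
  {
    int k = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (dx || dy || dz) { offs[k][0]=dx; offs[k][1]=dy; offs[k][2]=dz; ++k; }
        }
  }
  auto wrap = [L](int v) { int m = v % L; return m < 0 ? m + L : m; };
  int b0 = 0;
  long long restarts = 0;
  for (int c = 0; c < nchain; ++c) {
    int len = chain_lengths[c];
    bool placed = false;
    while (!placed) {
      if (restarts > (long long)max_restarts)
        stop("could not place chains at the requested density");
      // start site: rejection sample against weight
      int sx = -1, sy = -1, sz = -1, ssite = -1;
      for (int tries = 0; tries < 100000; ++tries) {
        int x = (int)(unif_rand() * L), y = (int)(unif_rand() * L),
            z = (int)(unif_rand() * L);
        if (x >= L) x = L - 1; if (y >= L) y = L - 1; if (z >= L) z = L - 1;
        int s = x + L * (y + L * z);
        if (occ[s] >= 0) continue;
        if (unif_rand() * wmax < weight[s]) { sx = x; sy = y; sz = z; ssite = s; break; }
      }
      if (ssite < 0) { ++restarts; continue; }
      std::vector<int> cx{sx}, cy{sy}, cz{sz}, cs{ssite};
      occ[ssite] = b0;
      bool dead = false;
      while ((int)cx.size() < len) {
        bool grew = false;
        for (int tries = 0; tries < 200 && !grew; ++tries) {
          int k = (int)(unif_rand() * 26); if (k >= 26) k = 25;
          int x = wrap(cx.back() + offs[k][0]);
          int y = wrap(cy.back() + offs[k][1]);
          int z = wrap(cz.back() + offs[k][2]);
          int s = x + L * (y + L * z);
          if (occ[s] >= 0) continue;
          if (unif_rand() * wmax >= weight[s]) continue;
          occ[s] = b0;
          cx.push_back(x); cy.push_back(y); cz.push_back(z); cs.push_back(s);
          grew = true;
        }
        if (!grew) { dead = true; break; }
      }
      if (dead) {
        for (int s : cs) occ[s] = -1;
        ++restarts;
        continue;
      }
      for (int i = 0; i < len; ++i) {
        out(b0 + i, 0) = cx[i]; out(b0 + i, 1) = cy[i]; out(b0 + i, 2) = cz[i];
      }
      b0 += len;
      placed = true;
    }
  }
  return out;
}
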