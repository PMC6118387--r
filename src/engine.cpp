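// Discrete-time agent-based engine for oral drug absorption.
//
// World model: a fixed set of 3-D lattice spaces (stomach, gut lumen segments,
// enterocytes, portal vein, sinusoid, hepatocyte, systemic blood, other
// organs, egested colon). Drug molecules are individual agents that perform a
// biased random walk (flow axis = X), cross membranes probabilistically
// (membrane plane normal = Y: a membrane joins the +Y face of its `from`
// space to the -Y face, y = 0, of its `to` space), are advected between
// connected spaces from a downstream flow zone, and interact with static
// site objects (metabolic enzymes, efflux transporters, nonspecific binders)
// via probabilistic bind / convert / release rules.
//
// Event order within one step (fixed for reproducibility):
//   1. bound drugs: metabolize (cyp only, parents only), then release
//   2. unbound drugs move (uniform 6-neighbour step + flow drift)
//   3. membrane permeation attempts
//   4. inter-space flow transfers
//   5. binding attempts
//   6. step counter increment, systemic measurement
//
// All randomness comes from one std::mt19937_64 stream seeded from R, so a
// given (parameterization, seed) pair is bit-reproducible.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  // uniform double in [0,1) with 53-bit resolution, implementation-independent
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(gen() % static_cast<uint64_t>(n)); }
};

struct SpaceP {
  int dx, dy, dz;
  double flowRate;   // mean +X drift in grid points per step (0 = no flow)
  bool terminal;     // egested space: agents never leave, dynamics skipped
};

struct FlowP {
  int from, to;
  double depth;      // fraction of X width forming the downstream flow zone
  double frac;       // per-step transfer probability within the zone
  int zoneMin;       // first x index inside the flow zone (precomputed)
};

struct MemP {
  int a, b;          // membrane joins a's +Y face to b's -Y face
  double pab, pba;   // effective crossing probabilities (precomputed in R)
  double uptake;     // carrier-mediated a->b uptake rate, position-independent
  int zoneMinA;      // a-side interface zone: y >= zoneMinA
  int zoneMaxB;      // b-side adjacency zone: y <= zoneMaxB (single plane)
};

struct SiteP {
  int kind;          // 0 = cyp, 1 = pgp, 2 = binder
  int space;
  int x, y, z;
  int cap, occ;
};

struct KindP {
  double affinity, releaseProb, metabolizeProb;
  int substrate;     // drug is a substrate of this site kind
};

inline int zone_min(int d, double depth) {
  // cells x with x >= d*(1-depth); depth 0.5 on d=20 -> x >= 10
  int zm = static_cast<int>(std::ceil(d * (1.0 - depth) - 1e-9));
  if (zm < 0) zm = 0;
  if (zm > d) zm = d;
  return zm;
}

} // namespace

// [[Rcpp::export]]
List cpp_run_sim(List world, int steps, int doseSpace, int numSolutes,
                 double moveProb, int measureSpace, double seed,
                 bool returnState) {
  // ---- unpack world ----
  IntegerMatrix spDims = world["space_dims"];        // n_spaces x 3
  NumericVector spFlow = world["space_flow"];        // flowRate per space
  LogicalVector spTerm = world["space_terminal"];
  IntegerVector effluxTarget = world["efflux_target"]; // per space: lumen space for pgp efflux, or -1

  NumericMatrix fl = world["flows"];     // cols: from,to,depth,frac
  NumericMatrix mem = world["membranes"];// cols: a,b,pab,pba,depthA,depthB
  NumericMatrix st = world["sites"];     // cols: kind,space,cap,nbcode (positions drawn here)
  NumericMatrix kindPar = world["kind_params"]; // 3 x (affinity,release,metab,substrate)

  const int nSpace = spDims.nrow();
  std::vector<SpaceP> spaces(nSpace);
  for (int i = 0; i < nSpace; ++i) {
    spaces[i] = {spDims(i, 0), spDims(i, 1), spDims(i, 2), spFlow[i],
                 static_cast<bool>(spTerm[i])};
  }

  std::vector<FlowP> flows(fl.nrow());
  std::vector<std::vector<int>> spaceFlows(nSpace);
  for (int i = 0; i < fl.nrow(); ++i) {
    int from = static_cast<int>(fl(i, 0));
    flows[i] = {from, static_cast<int>(fl(i, 1)), fl(i, 2), fl(i, 3), 0};
    flows[i].zoneMin = zone_min(spaces[from].dx, flows[i].depth);
    spaceFlows[from].push_back(i);
  }

  std::vector<MemP> mems(mem.nrow());
  // membranes a drug in space s may attempt, in declaration order
  std::vector<std::vector<std::pair<int, int>>> spaceMems(nSpace); // (mem idx, side 0=a,1=b)
  for (int i = 0; i < mem.nrow(); ++i) {
    int a = static_cast<int>(mem(i, 0)), b = static_cast<int>(mem(i, 1));
    MemP m = {a, b, mem(i, 2), mem(i, 3), mem(i, 5), 0, 0};
    // Polarized epithelia (no carrier uptake): the configured interface
    // depth is the unstirred zone on the upstream (a) side and the
    // downstream side is a single adjacency plane at y = 0, which makes net
    // transport directional. Exchange interfaces (carrier uptake > 0, e.g.
    // the sinusoid/hepatocyte interface) are symmetric: the interface depth
    // applies on both sides.
    m.zoneMinA = zone_min(spaces[a].dy, mem(i, 4));
    if (m.uptake > 0.0) {
      int zb = static_cast<int>(std::floor(spaces[b].dy * mem(i, 4) - 1e-9));
      if (zb < 0) zb = 0;
      m.zoneMaxB = zb;
    } else {
      m.zoneMaxB = 0;
    }
    mems[i] = m;
    spaceMems[a].push_back({i, 0});
    spaceMems[b].push_back({i, 1});
  }

  KindP kinds[3];
  for (int k = 0; k < 3; ++k) {
    kinds[k] = {kindPar(k, 0), kindPar(k, 1), kindPar(k, 2),
                static_cast<int>(kindPar(k, 3))};
  }

  Rng rng(static_cast<uint64_t>(seed));

  // ---- place sites ----
  std::vector<SiteP> sites;
  std::vector<int> nbcode; // 0: self, 1: 3-point X line, 2: 3x3 XY block, 3: 3^3 cube
  for (int i = 0; i < st.nrow(); ++i) {
    int kind = static_cast<int>(st(i, 0));
    int sp = static_cast<int>(st(i, 1));
    int cap = static_cast<int>(st(i, 2));
    int nb = static_cast<int>(st(i, 3));
    const SpaceP& S = spaces[sp];
    int x = rng.below(S.dx), y = rng.below(S.dy), z = rng.below(S.dz);
    if (kind == 1) y = 0; // efflux transporters sit on the apical membrane plane
    if (kind == 0) {
      // metabolic enzymes are zonated in the membrane-facing
      // (periportal / apical) third of their space
      y = rng.below(S.dy / 3 > 0 ? S.dy / 3 : 1);
    }
    sites.push_back({kind, sp, x, y, z, cap, 0});
    nbcode.push_back(nb);
  }

  // per-space CSR map: lattice cell -> indices of sites whose neighbourhood
  // covers that cell (site coverage is static, so build once)
  std::vector<std::vector<std::vector<uint16_t>>> cover(nSpace);
  for (int sp = 0; sp < nSpace; ++sp) {
    bool any = false;
    for (size_t i = 0; i < sites.size(); ++i) if (sites[i].space == sp) { any = true; break; }
    if (!any) continue;
    const SpaceP& S = spaces[sp];
    cover[sp].assign(static_cast<size_t>(S.dx) * S.dy * S.dz, {});
    for (size_t i = 0; i < sites.size(); ++i) {
      if (sites[i].space != sp) continue;
      int rx = 0, ry = 0, rz = 0;
      switch (nbcode[i]) {
        case 1: rx = 1; break;
        case 2: rx = 1; ry = 1; break;
        case 3: rx = 1; ry = 1; rz = 1; break;
        default: break;
      }
      for (int ddz = -rz; ddz <= rz; ++ddz)
        for (int ddy = -ry; ddy <= ry; ++ddy)
          for (int ddx = -rx; ddx <= rx; ++ddx) {
            int cx = sites[i].x + ddx, cy = sites[i].y + ddy, cz = sites[i].z + ddz;
            if (cx < 0 || cx >= S.dx || cy < 0 || cy >= S.dy || cz < 0 || cz >= S.dz)
              continue;
            cover[sp][cx + S.dx * (cy + static_cast<size_t>(S.dy) * cz)]
                .push_back(static_cast<uint16_t>(i));
          }
    }
  }

  // ---- dose ----
  const int n = numSolutes;
  std::vector<int8_t> dSpace(n), dSpecies(n, 0);
  std::vector<int16_t> dx(n), dy(n), dz(n);
  std::vector<int32_t> dBound(n, -1);
  {
    const SpaceP& S = spaces[doseSpace];
    for (int i = 0; i < n; ++i) {
      dSpace[i] = static_cast<int8_t>(doseSpace);
      dx[i] = static_cast<int16_t>(rng.below(S.dx));
      dy[i] = static_cast<int16_t>(rng.below(S.dy));
      dz[i] = static_cast<int16_t>(rng.below(S.dz));
    }
  }

  IntegerVector amounts(steps + 1);
  long metabolizedCount = 0;

  auto measure = [&](int /*step*/) {
    int c = 0;
    for (int i = 0; i < n; ++i)
      if (dSpecies[i] == 0 && dSpace[i] == measureSpace) ++c;
    return c;
  };
  amounts[0] = measure(0);

  const bool doMove = moveProb > 0.0;

  for (int step = 1; step <= steps; ++step) {
    // 1. bound drugs: metabolize then release
    for (int i = 0; i < n; ++i) {
      int b = dBound[i];
      if (b < 0) continue;
      SiteP& s = sites[b];
      const KindP& K = kinds[s.kind];
      if (s.kind == 0 && dSpecies[i] == 0 && K.metabolizeProb > 0.0 &&
          rng.unif() < K.metabolizeProb) {
        dSpecies[i] = 1;
        ++metabolizedCount;
      }
      if (rng.unif() < K.releaseProb) {
        dBound[i] = -1;
        --s.occ;
        if (s.kind == 1) {
          // efflux: released on the luminal side of the apical membrane
          int lum = effluxTarget[s.space];
          if (lum >= 0) {
            dSpace[i] = static_cast<int8_t>(lum);
            dy[i] = static_cast<int16_t>(spaces[lum].dy - 1);
            if (dx[i] >= spaces[lum].dx) dx[i] = static_cast<int16_t>(spaces[lum].dx - 1);
            if (dz[i] >= spaces[lum].dz) dz[i] = static_cast<int16_t>(spaces[lum].dz - 1);
          }
        }
      }
    }

    // 2. movement
    for (int i = 0; i < n; ++i) {
      if (dBound[i] >= 0) continue;
      const SpaceP& S = spaces[dSpace[i]];
      if (S.terminal) continue;
      if (doMove && (moveProb >= 1.0 || rng.unif() < moveProb)) {
        int dir = rng.below(6);
        int nx = dx[i], ny = dy[i], nz = dz[i];
        switch (dir) {
          case 0: ++nx; break; case 1: --nx; break;
          case 2: ++ny; break; case 3: --ny; break;
          case 4: ++nz; break; default: --nz; break;
        }
        // reflecting boundaries: a step off the lattice is rejected
        if (nx >= 0 && nx < S.dx && ny >= 0 && ny < S.dy && nz >= 0 && nz < S.dz) {
          dx[i] = static_cast<int16_t>(nx);
          dy[i] = static_cast<int16_t>(ny);
          dz[i] = static_cast<int16_t>(nz);
        }
      }
      if (S.flowRate > 0.0) {
        int drift = static_cast<int>(S.flowRate);
        double fracPart = S.flowRate - drift;
        if (fracPart > 0.0 && rng.unif() < fracPart) ++drift;
        if (drift > 0) {
          int nx = dx[i] + drift;
          if (nx > S.dx - 1) nx = S.dx - 1;
          dx[i] = static_cast<int16_t>(nx);
        }
      }
    }

    // 3. membrane permeation
    for (int i = 0; i < n; ++i) {
      if (dBound[i] >= 0) continue;
      int sp = dSpace[i];
      if (spaces[sp].terminal || spaceMems[sp].empty()) continue;
      for (auto& ms : spaceMems[sp]) {
        const MemP& m = mems[ms.first];
        if (ms.second == 0) {
          // carrier-mediated uptake clears the whole upstream space
          if (m.uptake > 0.0 && rng.unif() < m.uptake) {
            dSpace[i] = static_cast<int8_t>(m.b);
            dy[i] = 0;
            const SpaceP& T = spaces[m.b];
            if (dx[i] >= T.dx) dx[i] = static_cast<int16_t>(T.dx - 1);
            if (dz[i] >= T.dz) dz[i] = static_cast<int16_t>(T.dz - 1);
            break;
          }
          if (dy[i] < m.zoneMinA) continue;
          if (m.pab > 0.0 && rng.unif() < m.pab) {
            dSpace[i] = static_cast<int8_t>(m.b);
            dy[i] = 0;
            const SpaceP& T = spaces[m.b];
            if (dx[i] >= T.dx) dx[i] = static_cast<int16_t>(T.dx - 1);
            if (dz[i] >= T.dz) dz[i] = static_cast<int16_t>(T.dz - 1);
            break;
          }
        } else {
          if (dy[i] > m.zoneMaxB) continue;
          if (m.pba > 0.0 && rng.unif() < m.pba) {
            dSpace[i] = static_cast<int8_t>(m.a);
            const SpaceP& T = spaces[m.a];
            dy[i] = static_cast<int16_t>(T.dy - 1);
            if (dx[i] >= T.dx) dx[i] = static_cast<int16_t>(T.dx - 1);
            if (dz[i] >= T.dz) dz[i] = static_cast<int16_t>(T.dz - 1);
            break;
          }
        }
      }
    }

    // 4. inter-space flow
    for (int i = 0; i < n; ++i) {
      if (dBound[i] >= 0) continue;
      int sp = dSpace[i];
      if (spaces[sp].terminal || spaceFlows[sp].empty()) continue;
      for (int fi : spaceFlows[sp]) {
        const FlowP& F = flows[fi];
        if (dx[i] < F.zoneMin) continue;
        if (F.frac > 0.0 && (F.frac >= 1.0 || rng.unif() < F.frac)) {
          dSpace[i] = static_cast<int8_t>(F.to);
          dx[i] = 0; // enter at the upstream face, transverse coords preserved
          const SpaceP& T = spaces[F.to];
          if (dy[i] >= T.dy) dy[i] = static_cast<int16_t>(T.dy - 1);
          if (dz[i] >= T.dz) dz[i] = static_cast<int16_t>(T.dz - 1);
          break;
        }
      }
    }

    // 5. binding attempts
    for (int i = 0; i < n; ++i) {
      if (dBound[i] >= 0) continue;
      int sp = dSpace[i];
      if (cover[sp].empty()) continue;
      const SpaceP& S = spaces[sp];
      auto& cand = cover[sp][dx[i] + S.dx * (dy[i] + static_cast<size_t>(S.dy) * dz[i])];
      for (uint16_t si : cand) {
        SiteP& s = sites[si];
        if (s.occ >= s.cap) continue;
        // metabolites are not substrates of the enzymes / transporters that
        // act on the parent; they only undergo nonspecific binding
        if (dSpecies[i] == 1 && s.kind != 2) continue;
        const KindP& K = kinds[s.kind];
        if (!K.substrate) continue;
        if (K.affinity > 0.0 && (K.affinity >= 1.0 || rng.unif() < K.affinity)) {
          dBound[i] = si;
          ++s.occ;
          break;
        }
      }
    }

    amounts[step] = measure(step);
  }

  List out = List::create(_["amounts"] = amounts,
                          _["metabolized"] = static_cast<double>(metabolizedCount));
  if (returnState) {
    IntegerVector oSpace(n), oSpecies(n), oX(n), oY(n), oZ(n), oBound(n);
    for (int i = 0; i < n; ++i) {
      oSpace[i] = dSpace[i]; oSpecies[i] = dSpecies[i];
      oX[i] = dx[i]; oY[i] = dy[i]; oZ[i] = dz[i]; oBound[i] = dBound[i];
    }
    IntegerVector sKind(sites.size()), sSpace(sites.size()), sOcc(sites.size()),
        sCap(sites.size()), sX(sites.size()), sY(sites.size()), sZ(sites.size());
    for (size_t i = 0; i < sites.size(); ++i) {
      sKind[i] = sites[i].kind; sSpace[i] = sites[i].space; sOcc[i] = sites[i].occ;
      sCap[i] = sites[i].cap; sX[i] = sites[i].x; sY[i] = sites[i].y; sZ[i] = sites[i].z;
    }
    out["state"] = List::create(
        _["space"] = oSpace, _["species"] = oSpecies, _["x"] = oX, _["y"] = oY,
        _["z"] = oZ, _["bound"] = oBound);
    out["sites"] = List::create(
        _["kind"] = sKind, _["space"] = sSpace, _["x"] = sX, _["y"] = sY,
        _["z"] = sZ, _["occ"] = sOcc, _["cap"] = sCap);
  }
  return out;
}
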