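// 2D Langevin dynamics core for synapsin-decorated vesicles.
//
// Species codes: 0 = vesicle, 1 = synapsin (mono), 2 = syn_N, 3 = syn_C.
// Models: 0 = mono-domain, 1 = bi-domain (N+C rigid dimers).
// Pair kinds: 0 = none, 1 = WCA repulsive, 2 = cosine-squared attractive.
//
// Lengths are reduced units (1 = 10 nm), energies kBT. Interaction
// geometry per pair: sigma = 2^{1/6}(r_i + r_j); WCA acts for r < sigma,
// the attractive well out to r_c = sigma + 0.25. Neighbor lists use a
// per-pair cutoff plus a 0.3 skin and are rebuilt when any particle has
// moved 0.15 or more since the last build.

#include <Rcpp.h>
#include <chrono>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double SIGFAC = 1.122462048309373; // 2^{1/6}
static const double SKIN = 0.3;
static const double REBUILD_DISP = 0.15;
static const double SQRT6 = 2.449489742783178;

// Deterministic, seedable generator (PCG32), independent of R's RNG so
// million-step runs do not touch the R API per draw.
struct Pcg32 {
  uint64_t state, inc;
  explicit Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    nextInt();
    state += seed;
    nextInt();
  }
  uint32_t nextInt() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  // uniform on [0, 1)
  double unif() { return nextInt() * (1.0 / 4294967296.0); }
  // uniform on [-sqrt(6), sqrt(6)]: mean 0, variance 2, so that
  // F_r = sqrt(kBT m / (dt gamma)) * eta satisfies fluctuation-dissipation.
  double eta() { return (2.0 * unif() - 1.0) * SQRT6; }
};

inline int pairKind(int si, int sj, bool sameV, bool sameD, int model,
                    bool ccSame) {
  if (sameD) return 0;
  if (si > sj) std::swap(si, sj);
  if (si == 0 && sj == 0) return 1;            // vesicle-vesicle
  if (model == 0) {
    if (si == 0 && sj == 1) return sameV ? 0 : 1; // tether handles same-ves
    return sameV ? 1 : 2;                      // synapsin-synapsin
  }
  if (si == 0 && sj == 2) return sameV ? 0 : 1; // vesicle-N
  if (si == 0 && sj == 3) return 1;             // vesicle-C
  if (si == 2 && sj == 2) return 1;             // N-N
  if (si == 2 && sj == 3) return 1;             // N-C (other dimers)
  if (si == 3 && sj == 3) return (sameV && !ccSame) ? 1 : 2; // C-C
  return 0;
}

struct Sim {
  int n = 0, model = 0;
  double box = 0, half = 0;
  double eps = 0, bondK = 0, ccSep = 0;
  bool ccSame = true;
  double dt = 0, gamma_ = 1, kBT = 1, mass = 1;
  bool thermostat = true;

  std::vector<double> x, y, vx, vy, radius;
  std::vector<int> species, ves, dimid;
  // tether bonds
  std::vector<int> bondA, bondB;
  std::vector<double> bondR0;
  // rigid dimers
  std::vector<int> dN, dC;
  std::vector<double> dX, dY, dVX, dVY, dOmega, dUx, dUy;
  double halfSep = 0.5, inertia = 0.5, dimerMass = 2.0;
  std::vector<int> points; // particles integrated as free points

  // forces
  std::vector<double> fx, fy;   // conservative, per bead
  std::vector<double> gfx, gfy; // generalized (point beads)
  std::vector<double> dFx, dFy, dTau; // generalized (dimers)
  double pe = 0;

  // neighbor list (squared cutoffs cached per pair)
  std::vector<int> nlI, nlJ, nlKind;
  std::vector<double> nlSig2, nlRc2;
  std::vector<double> xRef, yRef;
  long nRebuilds = 0;

  // persistent cell-list scaffolding (geometry is static: radii fixed)
  std::vector<int> beadsIdx, vesIdx;
  std::vector<int> cellHead, cellNext; // head per cell, chain per bead
  int nc = 0, walkR = 0;
  double csz = 0, maxBB2 = 0;
  bool useGrid = false;
  double dispBound = 1e9; // accumulated upper bound on max displacement

  // note: plain floor-based wrap (std::fmod would pull a glibc-2.38
  // versioned symbol that the runtime loader cannot resolve here)
  inline double wrap(double a) const {
    a -= box * std::floor(a / box);
    if (a >= box) a = 0.0;
    return a;
  }
  inline void minImage(double &dx, double &dy) const {
    if (dx > half) dx -= box; else if (dx < -half) dx += box;
    if (dy > half) dy -= box; else if (dy < -half) dy += box;
  }

  void init(NumericVector x_, NumericVector y_, NumericVector vx_,
            NumericVector vy_, IntegerVector sp, NumericVector rad,
            IntegerVector ves_, IntegerVector dim_, IntegerVector ba,
            IntegerVector bb, NumericVector br0, IntegerVector dn,
            IntegerVector dc, double box_, int model_, double eps_,
            double bondK_, bool ccSame_, double dimerSep, double dt_,
            double gamma__, double kBT_, double mass_, bool thermo) {
    n = x_.size();
    box = box_; half = box / 2; model = model_;
    eps = eps_; bondK = bondK_; ccSame = ccSame_;
    dt = dt_; gamma_ = gamma__; kBT = kBT_; mass = mass_;
    thermostat = thermo;
    x.assign(x_.begin(), x_.end());
    y.assign(y_.begin(), y_.end());
    vx.assign(vx_.begin(), vx_.end());
    vy.assign(vy_.begin(), vy_.end());
    species.assign(sp.begin(), sp.end());
    radius.assign(rad.begin(), rad.end());
    ves.assign(ves_.begin(), ves_.end());
    dimid.assign(dim_.begin(), dim_.end());
    bondA.assign(ba.begin(), ba.end());
    bondB.assign(bb.begin(), bb.end());
    bondR0.assign(br0.begin(), br0.end());
    dN.assign(dn.begin(), dn.end());
    dC.assign(dc.begin(), dc.end());
    halfSep = dimerSep / 2;
    dimerMass = 2 * mass;
    inertia = 2 * mass * halfSep * halfSep;
    fx.assign(n, 0); fy.assign(n, 0);
    gfx.assign(n, 0); gfy.assign(n, 0);

    std::vector<bool> inDimer(n, false);
    for (size_t k = 0; k < dN.size(); ++k) {
      inDimer[dN[k]] = true;
      inDimer[dC[k]] = true;
    }
    for (int i = 0; i < n; ++i) if (!inDimer[i]) points.push_back(i);

    size_t nd = dN.size();
    dX.assign(nd, 0); dY.assign(nd, 0); dVX.assign(nd, 0); dVY.assign(nd, 0);
    dOmega.assign(nd, 0);
    dUx.assign(nd, 1); dUy.assign(nd, 0);
    dFx.assign(nd, 0); dFy.assign(nd, 0); dTau.assign(nd, 0);
    for (size_t k = 0; k < nd; ++k) {
      int a = dN[k], b = dC[k];
      double rx = x[b] - x[a], ry = y[b] - y[a];
      minImage(rx, ry);
      double len = std::sqrt(rx * rx + ry * ry);
      if (len > 0) { dUx[k] = rx / len; dUy[k] = ry / len; }
      dX[k] = wrap(x[a] + rx / 2);
      dY[k] = wrap(y[a] + ry / 2);
      dVX[k] = (vx[a] + vx[b]) / 2;
      dVY[k] = (vy[a] + vy[b]) / 2;
      // omega from relative bead velocities (zero for standard init)
      double relvx = vx[b] - vx[a], relvy = vy[b] - vy[a];
      double len2 = rx * rx + ry * ry;
      dOmega[k] = len2 > 0 ? (rx * relvy - ry * relvx) / len2 : 0.0;
    }
    setupGrid();
    updateDimerBeads();
  }

  // fast wrap for values at most one box length out of range
  inline double wrap1(double a) const {
    if (a >= box) a -= box; else if (a < 0) a += box;
    if (a >= box || a < 0) return wrap(a);
    return a;
  }

  void updateDimerBeads() {
    for (size_t k = 0; k < dN.size(); ++k) {
      double ux = dUx[k], uy = dUy[k];
      int a = dN[k], b = dC[k];
      double hx = halfSep * ux, hy = halfSep * uy;
      x[a] = wrap1(dX[k] - hx);
      y[a] = wrap1(dY[k] - hy);
      x[b] = wrap1(dX[k] + hx);
      y[b] = wrap1(dY[k] + hy);
      double whx = dOmega[k] * hx, why = dOmega[k] * hy;
      vx[a] = dVX[k] + why;
      vy[a] = dVY[k] - whx;
      vx[b] = dVX[k] - why;
      vy[b] = dVY[k] + whx;
    }
  }

  inline double pairCutoff(int kind, double sig) const {
    return kind == 2 ? sig + 0.25 : sig;
  }

  void addIfClose(int i, int j, double r2) {
    bool sameV = ves[i] == ves[j];
    bool sameD = dimid[i] >= 0 && dimid[i] == dimid[j];
    int kind = pairKind(species[i], species[j], sameV, sameD, model, ccSame);
    if (kind == 0) return;
    double sig = SIGFAC * (radius[i] + radius[j]);
    double cut = pairCutoff(kind, sig) + SKIN;
    if (r2 < cut * cut) {
      nlI.push_back(i); nlJ.push_back(j);
      nlKind.push_back(kind);
      nlSig2.push_back(sig * sig);
      double rc = pairCutoff(kind, sig);
      nlRc2.push_back(rc * rc);
    }
  }

  void tryAddPair(int i, int j) {
    double dx = x[i] - x[j], dy = y[i] - y[j];
    minImage(dx, dy);
    addIfClose(i, j, dx * dx + dy * dy);
  }

  void setupGrid() {
    beadsIdx.clear(); vesIdx.clear();
    for (int i = 0; i < n; ++i) {
      if (species[i] == 0) vesIdx.push_back(i); else beadsIdx.push_back(i);
    }
    double maxBeadR = 0, maxVesR = 0;
    for (size_t b = 0; b < beadsIdx.size(); ++b)
      maxBeadR = std::max(maxBeadR, radius[beadsIdx[b]]);
    for (size_t a = 0; a < vesIdx.size(); ++a)
      maxVesR = std::max(maxVesR, radius[vesIdx[a]]);
    double cell = SIGFAC * 2 * maxBeadR + 0.25 + SKIN;
    double bb = cell;
    maxBB2 = bb * bb;
    nc = cell > 0 ? (int)std::floor(box / cell) : 0;
    double vbCut = SIGFAC * (maxVesR + maxBeadR) + 0.25 + SKIN;
    useGrid = nc >= 3;
    walkR = useGrid ? (int)std::ceil(vbCut / (box / nc)) : 0;
    if (useGrid && 2 * walkR + 1 > nc) useGrid = false;
    if (useGrid) {
      csz = box / nc;
      cellHead.assign((size_t)nc * nc, -1);
      cellNext.assign(n, -1);
    }
  }

  inline int cellOf(double xi, double yi) const {
    int cx = (int)(xi / csz), cy = (int)(yi / csz);
    if (cx >= nc) cx = nc - 1; if (cx < 0) cx = 0;
    if (cy >= nc) cy = nc - 1; if (cy < 0) cy = 0;
    return cy * nc + cx;
  }

  void buildNeighbors() {
    size_t keep = nlI.size() + 64;
    nlI.clear(); nlJ.clear(); nlKind.clear(); nlSig2.clear(); nlRc2.clear();
    nlI.reserve(keep); nlJ.reserve(keep); nlKind.reserve(keep);
    nlSig2.reserve(keep); nlRc2.reserve(keep);
    if (!useGrid) {
      for (size_t a = 0; a < beadsIdx.size(); ++a)
        for (size_t b = a + 1; b < beadsIdx.size(); ++b)
          tryAddPair(beadsIdx[a], beadsIdx[b]);
      for (size_t a = 0; a < vesIdx.size(); ++a) {
        int i = vesIdx[a];
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          if (species[j] == 0 && j < i) continue;
          tryAddPair(i, j);
        }
      }
    } else {
      // re-bin beads into the persistent head/next cell list
      std::fill(cellHead.begin(), cellHead.end(), -1);
      for (size_t b = 0; b < beadsIdx.size(); ++b) {
        int i = beadsIdx[b];
        int c = cellOf(x[i], y[i]);
        cellNext[i] = cellHead[c];
        cellHead[c] = i;
      }
      // half stencil: own chain tail + E, N, NE, SE cells; the base cell
      // must be computed exactly as in the binning pass above
      const int OX[4] = {1, 0, 1, 1};
      const int OY[4] = {0, 1, 1, -1};
      for (size_t b = 0; b < beadsIdx.size(); ++b) {
        int i = beadsIdx[b];
        double xi = x[i], yi = y[i];
        int c0 = cellOf(xi, yi);
        int cx0 = c0 % nc, cy0 = c0 / nc;
        for (int j = cellNext[i]; j >= 0; j = cellNext[j]) {
          double dx = xi - x[j], dy = yi - y[j];
          minImage(dx, dy);
          { double r2 = dx * dx + dy * dy; if (r2 < maxBB2) addIfClose(i, j, r2); }
        }
        for (int s = 0; s < 4; ++s) {
          int cx = cx0 + OX[s], cy = cy0 + OY[s];
          if (cx >= nc) cx -= nc;
          if (cy >= nc) cy -= nc; else if (cy < 0) cy += nc;
          for (int j = cellHead[(size_t)cy * nc + cx]; j >= 0;
               j = cellNext[j]) {
            double dx = xi - x[j], dy = yi - y[j];
            minImage(dx, dy);
            { double r2 = dx * dx + dy * dy; if (r2 < maxBB2) addIfClose(i, j, r2); }
          }
        }
      }
      for (size_t a = 0; a < vesIdx.size(); ++a) {
        int i = vesIdx[a];
        int cx0 = (int)(x[i] / csz), cy0 = (int)(y[i] / csz);
        if (cx0 >= nc) cx0 = nc - 1; if (cx0 < 0) cx0 = 0;
        if (cy0 >= nc) cy0 = nc - 1; if (cy0 < 0) cy0 = 0;
        for (int oy = -walkR; oy <= walkR; ++oy)
          for (int ox = -walkR; ox <= walkR; ++ox) {
            int cx = (cx0 + ox + nc) % nc;
            int cy = (cy0 + oy + nc) % nc;
            for (int j = cellHead[(size_t)cy * nc + cx]; j >= 0;
                 j = cellNext[j])
              tryAddPair(i, j);
          }
        for (size_t b = a + 1; b < vesIdx.size(); ++b)
          tryAddPair(i, vesIdx[b]);
      }
    }
    xRef = x; yRef = y;
    dispBound = 0;
  }

  bool needRebuild() {
    if (dispBound < REBUILD_DISP) return false;
    double lim = REBUILD_DISP * REBUILD_DISP;
    double worst = 0;
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - xRef[i], dy = y[i] - yRef[i];
      if (dx > half) dx -= box; else if (dx < -half) dx += box;
      if (dy > half) dy -= box; else if (dy < -half) dy += box;
      double d2 = dx * dx + dy * dy;
      if (d2 >= lim) return true;
      if (d2 > worst) worst = d2;
    }
    dispBound = std::sqrt(worst); // true max; keep accumulating from here
    return false;
  }

  void computeConservative(bool withEnergy = true) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    pe = 0;
    const size_t m = nlI.size();
    for (size_t k = 0; k < m; ++k) {
      int i = nlI[k], j = nlJ[k];
      double dx = x[i] - x[j], dy = y[i] - y[j];
      minImage(dx, dy);
      double r2 = dx * dx + dy * dy;
      double sig2 = nlSig2[k];
      if (nlKind[k] == 1) {
        if (r2 < sig2 && r2 > 0) {
          double s2 = sig2 / r2;
          double s6 = s2 * s2 * s2;
          if (withEnergy) pe += eps * (s6 * s6 - 2 * s6 + 1);
          double fscal = 12 * eps * (s6 * s6 - s6) / r2;
          fx[i] += fscal * dx; fy[i] += fscal * dy;
          fx[j] -= fscal * dx; fy[j] -= fscal * dy;
        }
      } else {
        if (r2 < sig2) {
          if (withEnergy) pe += -eps; // flat well: no force
        } else if (r2 < nlRc2[k]) {
          double sig = std::sqrt(sig2);
          double r = std::sqrt(r2);
          const double d = 0.25; // shoulder width r_c - sigma
          // w = pi (r - sigma) / d; E = -eps (1 + cos w)/2, dE/dr = ...
          double w = M_PI * (r - sig) / d;
          if (withEnergy) pe += -eps * 0.5 * (1 + std::cos(w));
          // F = -dE/dr = -eps * sin(w) * pi/(2d): attractive
          double F = -eps * std::sin(w) * M_PI / (2 * d);
          double fscal = F / r;
          fx[i] += fscal * dx; fy[i] += fscal * dy;
          fx[j] -= fscal * dx; fy[j] -= fscal * dy;
        }
      }
    }
    for (size_t k = 0; k < bondA.size(); ++k) {
      int a = bondA[k], b = bondB[k];
      double dx = x[a] - x[b], dy = y[a] - y[b];
      minImage(dx, dy);
      double r = std::sqrt(dx * dx + dy * dy);
      double dr = r - bondR0[k];
      if (withEnergy) pe += 0.5 * bondK * dr * dr;
      if (r > 0) {
        double fscal = -bondK * dr / r;
        fx[a] += fscal * dx; fy[a] += fscal * dy;
        fx[b] -= fscal * dx; fy[b] -= fscal * dy;
      }
    }
  }

  // friction + random forces per bead, reduced to generalized coordinates
  void assembleGeneralized(Pcg32 &rng) {
    const double c = thermostat ? std::sqrt(kBT * mass / (dt * gamma_)) : 0.0;
    const double fric = -mass / gamma_;
    if (thermostat) {
      for (size_t q = 0; q < points.size(); ++q) {
        int i = points[q];
        gfx[i] = fx[i] + fric * vx[i] + c * rng.eta();
        gfy[i] = fy[i] + fric * vy[i] + c * rng.eta();
      }
    } else {
      for (size_t q = 0; q < points.size(); ++q) {
        int i = points[q];
        gfx[i] = fx[i];
        gfy[i] = fy[i];
      }
    }
    for (size_t k = 0; k < dN.size(); ++k) {
      double Fx = 0, Fy = 0, Tau = 0;
      int idx[2] = {dN[k], dC[k]};
      double sgn[2] = {-1.0, 1.0};
      for (int q = 0; q < 2; ++q) {
        int i = idx[q];
        double rx = sgn[q] * halfSep * dUx[k], ry = sgn[q] * halfSep * dUy[k];
        double bfx = fx[i], bfy = fy[i];
        if (thermostat) {
          // bead velocity = COM velocity + omega x r
          bfx += fric * (dVX[k] - dOmega[k] * ry) + c * rng.eta();
          bfy += fric * (dVY[k] + dOmega[k] * rx) + c * rng.eta();
        }
        Fx += bfx; Fy += bfy;
        Tau += rx * bfy - ry * bfx;
      }
      dFx[k] = Fx; dFy[k] = Fy; dTau[k] = Tau;
    }
  }

  void halfKick() {
    const double hm = 0.5 * dt / mass;
    const double hM = 0.5 * dt / dimerMass;
    const double hI = 0.5 * dt / inertia;
    for (size_t q = 0; q < points.size(); ++q) {
      int i = points[q];
      vx[i] += hm * gfx[i];
      vy[i] += hm * gfy[i];
    }
    for (size_t k = 0; k < dN.size(); ++k) {
      dVX[k] += hM * dFx[k];
      dVY[k] += hM * dFy[k];
      dOmega[k] += hI * dTau[k];
    }
  }

  void drift() {
    double vmax = 0;
    for (size_t q = 0; q < points.size(); ++q) {
      int i = points[q];
      x[i] = wrap1(x[i] + dt * vx[i]);
      y[i] = wrap1(y[i] + dt * vy[i]);
      double a = std::fabs(vx[i]), b = std::fabs(vy[i]);
      if (a > vmax) vmax = a;
      if (b > vmax) vmax = b;
    }
    double bmax = 0;
    for (size_t k = 0; k < dN.size(); ++k) {
      dX[k] = wrap1(dX[k] + dt * dVX[k]);
      dY[k] = wrap1(dY[k] + dt * dVY[k]);
      // incremental rotation by delta = omega*dt: series for sin/cos with
      // one Newton renormalization keeps |u| = 1 to machine precision and
      // avoids per-step trig (delta is O(1e-2) at the default time step)
      double d = dt * dOmega[k];
      double d2 = d * d;
      double cs = 1 - d2 * (0.5 - d2 / 24.0);
      double sn = d * (1 - d2 * (1.0 / 6.0 - d2 / 120.0));
      double ux = cs * dUx[k] - sn * dUy[k];
      double uy = sn * dUx[k] + cs * dUy[k];
      double n2 = ux * ux + uy * uy;
      double inv = 0.5 * (3.0 - n2);
      dUx[k] = ux * inv;
      dUy[k] = uy * inv;
      double a = std::fabs(dVX[k]), b = std::fabs(dVY[k]);
      double s = (a > b ? a : b) * 1.4142135623730951 +
                 std::fabs(dOmega[k]) * halfSep;
      if (s > bmax) bmax = s;
    }
    // conservative upper bound on any bead displacement this step
    double stepDisp = vmax * 1.4142135623730951;
    if (bmax > stepDisp) stepDisp = bmax;
    dispBound += dt * stepDisp;
    updateDimerBeads();
  }

  double kineticEnergy() const {
    double ke = 0;
    for (size_t q = 0; q < points.size(); ++q) {
      int i = points[q];
      ke += 0.5 * mass * (vx[i] * vx[i] + vy[i] * vy[i]);
    }
    for (size_t k = 0; k < dN.size(); ++k) {
      ke += 0.5 * dimerMass * (dVX[k] * dVX[k] + dVY[k] * dVY[k]);
      ke += 0.5 * inertia * dOmega[k] * dOmega[k];
    }
    return ke;
  }

  void checkFinite(int step) const {
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
          !std::isfinite(vx[i]) || !std::isfinite(vy[i]))
        stop("simulation blow-up: non-finite coordinates at step %d "
             "(particle %d)", step, i + 1);
  }
};

static Sim makeSim(NumericVector x, NumericVector y, NumericVector vx,
                   NumericVector vy, IntegerVector species,
                   NumericVector radius, IntegerVector ves,
                   IntegerVector dimid, IntegerVector bond_a,
                   IntegerVector bond_b, NumericVector bond_r0,
                   IntegerVector dimer_n, IntegerVector dimer_c,
                   double box, int model, double eps, double bondK,
                   bool cc_same_attract, double dimer_sep, double dt,
                   double gamma, double kBT, double mass, bool thermostat) {
  Sim s;
  s.init(x, y, vx, vy, species, radius, ves, dimid, bond_a, bond_b, bond_r0,
         dimer_n, dimer_c, box, model, eps, bondK, cc_same_attract,
         dimer_sep, dt, gamma, kBT, mass, thermostat);
  return s;
}

// [[Rcpp::export]]
List compute_forces_cpp(NumericVector x, NumericVector y, NumericVector vx,
                        NumericVector vy, IntegerVector species,
                        NumericVector radius, IntegerVector ves,
                        IntegerVector dimid, IntegerVector bond_a,
                        IntegerVector bond_b, NumericVector bond_r0,
                        IntegerVector dimer_n, IntegerVector dimer_c,
                        double box, int model, double eps, double bondK,
                        bool cc_same_attract, double dimer_sep) {
  Sim s = makeSim(x, y, vx, vy, species, radius, ves, dimid, bond_a, bond_b,
                  bond_r0, dimer_n, dimer_c, box, model, eps, bondK,
                  cc_same_attract, dimer_sep, 1e-3, 1, 1, 1, false);
  s.buildNeighbors();
  s.computeConservative();
  return List::create(_["fx"] = NumericVector(s.fx.begin(), s.fx.end()),
                      _["fy"] = NumericVector(s.fy.begin(), s.fy.end()),
                      _["pe"] = s.pe);
}

// [[Rcpp::export]]
List run_sim_cpp(NumericVector x, NumericVector y, NumericVector vx,
                 NumericVector vy, IntegerVector species,
                 NumericVector radius, IntegerVector ves,
                 IntegerVector dimid, IntegerVector bond_a,
                 IntegerVector bond_b, NumericVector bond_r0,
                 IntegerVector dimer_n, IntegerVector dimer_c, double box,
                 int model, double eps, double bondK, bool cc_same_attract,
                 double dimer_sep, double dt, double gamma, double kBT,
                 double mass, bool thermostat, int n_steps,
                 int snapshot_interval, int seed) {
  Sim s = makeSim(x, y, vx, vy, species, radius, ves, dimid, bond_a, bond_b,
                  bond_r0, dimer_n, dimer_c, box, model, eps, bondK,
                  cc_same_attract, dimer_sep, dt, gamma, kBT, mass,
                  thermostat);
  Pcg32 rng((uint64_t)(uint32_t)seed);
  int nsnap = n_steps / snapshot_interval + 1;
  int n = s.n;
  NumericMatrix sx(n, nsnap), sy(n, nsnap), svx(n, nsnap), svy(n, nsnap);
  NumericVector spe(nsnap), ske(nsnap);
  IntegerVector ssteps(nsnap);

  s.buildNeighbors();
  s.computeConservative();
  s.assembleGeneralized(rng);
  int isnap = 0;
  auto record = [&](int step) {
    for (int i = 0; i < n; ++i) {
      sx(i, isnap) = s.x[i]; sy(i, isnap) = s.y[i];
      svx(i, isnap) = s.vx[i]; svy(i, isnap) = s.vy[i];
    }
    spe[isnap] = s.pe;
    ske[isnap] = s.kineticEnergy();
    ssteps[isnap] = step;
    ++isnap;
  };
  record(0);
  double tKick = 0, tDrift = 0, tBuild = 0, tForce = 0, tGen = 0;
  using clk = std::chrono::steady_clock;
  auto el = [](clk::time_point a, clk::time_point b) {
    return std::chrono::duration<double>(b - a).count();
  };
  for (int step = 1; step <= n_steps; ++step) {
    auto t0 = clk::now();
    s.halfKick();
    auto t1 = clk::now();
    s.drift();
    auto t2 = clk::now();
    if (s.needRebuild()) { s.buildNeighbors(); ++s.nRebuilds; }
    auto t3 = clk::now();
    s.computeConservative(step % snapshot_interval == 0);
    auto t4 = clk::now();
    s.assembleGeneralized(rng);
    s.halfKick();
    auto t5 = clk::now();
    tKick += el(t0, t1); tDrift += el(t1, t2); tBuild += el(t2, t3);
    tForce += el(t3, t4); tGen += el(t4, t5);
    if (step % snapshot_interval == 0) {
      s.checkFinite(step);
      record(step);
      Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["x"] = sx, _["y"] = sy, _["vx"] = svx,
                      _["vy"] = svy, _["pe"] = spe, _["ke"] = ske,
                      _["steps"] = ssteps,
                      _["n_rebuilds"] = s.nRebuilds,
                      _["n_pairs"] = (int)s.nlI.size(),
                      _["timing"] = NumericVector::create(
                          _["kick"] = tKick, _["drift"] = tDrift,
                          _["build"] = tBuild, _["force"] = tForce,
                          _["langevin"] = tGen));
}

// Pairs of points closer than `cutoff` under the minimum-image
// convention, found with a periodic cell grid. 1-based indices.
// [[Rcpp::export]]
IntegerMatrix neighbor_pairs_cpp(NumericVector x, NumericVector y,
                                 double box, double cutoff) {
  int n = x.size();
  double half = box / 2;
  std::vector<int> pi_, pj_;
  double c2 = cutoff * cutoff;
  auto check = [&](int i, int j) {
    double dx = x[i] - x[j], dy = y[i] - y[j];
    if (dx > half) dx -= box; else if (dx < -half) dx += box;
    if (dy > half) dy -= box; else if (dy < -half) dy += box;
    if (dx * dx + dy * dy <= c2) { pi_.push_back(i + 1); pj_.push_back(j + 1); }
  };
  int nc = (int)std::floor(box / cutoff);
  if (nc < 3) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) check(i, j);
  } else {
    double csz = box / nc;
    std::vector<std::vector<int> > grid((size_t)nc * nc);
    std::vector<int> cxv(n), cyv(n);
    for (int i = 0; i < n; ++i) {
      double xi = x[i] - box * std::floor(x[i] / box);
      double yi = y[i] - box * std::floor(y[i] / box);
      if (xi >= box) xi = 0.0;
      if (yi >= box) yi = 0.0;
      int cx = (int)(xi / csz), cy = (int)(yi / csz);
      if (cx >= nc) cx = nc - 1; if (cy >= nc) cy = nc - 1;
      cxv[i] = cx; cyv[i] = cy;
      grid[(size_t)cy * nc + cx].push_back(i);
    }
    for (int i = 0; i < n; ++i)
      for (int oy = -1; oy <= 1; ++oy)
        for (int ox = -1; ox <= 1; ++ox) {
          int cx = (cxv[i] + ox + nc) % nc;
          int cy = (cyv[i] + oy + nc) % nc;
          const std::vector<int> &cl = grid[(size_t)cy * nc + cx];
          for (size_t q = 0; q < cl.size(); ++q)
            if (cl[q] > i) check(i, cl[q]);
        }
  }
  IntegerMatrix out(pi_.size(), 2);
  for (size_t k = 0; k < pi_.size(); ++k) {
    out(k, 0) = pi_[k];
    out(k, 1) = pj_[k];
  }
  return out;
}
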