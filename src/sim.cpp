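// Forward-time lattice simulator core.
//
// Layout of an allele buffer: a + 2*(l + L*(x + W*y)), a in {0,1}, matching
// an R array with dim c(2, L, W, H).  Cells are 0-based; x = column,
// y = row.  All randomness comes from a self-contained xoshiro256++
// generator seeded explicitly, so identical seeds give byte-identical
// output on every platform.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----

static inline uint64_t splitmix64_next(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];

  void seed(uint64_t sd) {
    uint64_t sm = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(sm);
    // avoid the (astronomically unlikely) all-zero state
    if ((s[0] | s[1] | s[2] | s[3]) == 0) s[0] = 0x1ULL;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on [0, 1)
  inline double unif() {
    return (next() >> 11) * 0x1.0p-53;
  }

  // uniform on (0, 1]
  inline double unif_pos() {
    return ((next() >> 11) + 1) * 0x1.0p-53;
  }
};

// Deterministic seed derivation (stream splitting).  Returns a value in
// [1, 2^53) so it survives an R double round trip exactly.
// [[Rcpp::export(name = ".bb_derive_seed")]]
double bb_derive_seed(double seed, double key) {
  uint64_t st = (uint64_t)seed * 0x9E3779B97F4A7C15ULL + (uint64_t)key;
  uint64_t v = splitmix64_next(st);
  v = splitmix64_next(st) ^ v;
  v >>= 11;                      // 53 bits
  if (v == 0) v = 1;
  return (double)v;
}

// ------------------------------------------- discretized normal kernel ----

// Alias sampler for round(Normal(0, sigma)) restricted to [-R, R] with
// R = ceil(8*sigma); the truncated tail mass is < 1e-15.
struct DiscNormal {
  int R;
  int n;
  std::vector<double> prob;
  std::vector<int> alias;

  void build(double sigma) {
    if (sigma <= 0.0) {
      R = 0; n = 1;
      prob.assign(1, 1.0);
      alias.assign(1, 0);
      return;
    }
    R = (int)std::ceil(8.0 * sigma);
    n = 2 * R + 1;
    std::vector<double> w((size_t)n);
    const double inv = 1.0 / (sigma * std::sqrt(2.0));
    double tot = 0.0;
    for (int k = -R; k <= R; ++k) {
      double hi = 0.5 * std::erfc(-(k + 0.5) * inv);
      double lo = 0.5 * std::erfc(-(k - 0.5) * inv);
      double p = hi - lo;
      if (p < 0) p = 0;
      w[(size_t)(k + R)] = p;
      tot += p;
    }
    // Vose alias construction
    prob.assign((size_t)n, 0.0);
    alias.assign((size_t)n, 0);
    std::vector<double> scaled((size_t)n);
    std::vector<int> small, large;
    small.reserve((size_t)n); large.reserve((size_t)n);
    for (int i = 0; i < n; ++i) {
      scaled[(size_t)i] = w[(size_t)i] * n / tot;
      if (scaled[(size_t)i] < 1.0) small.push_back(i); else large.push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int g = large.back(); large.pop_back();
      prob[(size_t)s] = scaled[(size_t)s];
      alias[(size_t)s] = g;
      scaled[(size_t)g] = (scaled[(size_t)g] + scaled[(size_t)s]) - 1.0;
      if (scaled[(size_t)g] < 1.0) small.push_back(g); else large.push_back(g);
    }
    while (!large.empty()) { prob[(size_t)large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { prob[(size_t)small.back()] = 1.0; small.pop_back(); }
  }

  inline int draw(Xoshiro256pp &rng) {
    if (n == 1) return 0;
    uint64_t r = rng.next();
    int i = (int)(((__uint128_t)r * (uint64_t)n) >> 64);
    double u = (rng.next() >> 11) * 0x1.0p-53;
    int k = (u < prob[(size_t)i]) ? i : alias[(size_t)i];
    return k - R;
  }
};

// ------------------------------------------------------- parent drawing ---

static inline int quadrant_cpp(int x, int y, int sx, int sy) {
  return (x >= sx ? 1 : 0) + (y >= sy ? 2 : 0);
}

// Rejection draw of one parent cell for offspring cell (x, y): offsets from
// the discretized bivariate normal; draws landing off-grid are redrawn; with
// an active barrier, a draw in a foreign quadrant is kept with probability b,
// otherwise the whole draw is repeated.  Always terminates: the focal cell
// itself is acceptable.
static inline void draw_parent_one(int x, int y, DiscNormal &dn, int W, int H,
                                   bool barrier, double b, int sx, int sy,
                                   Xoshiro256pp &rng, int &px, int &py) {
  const int q0 = barrier ? quadrant_cpp(x, y, sx, sy) : 0;
  for (;;) {
    px = x + dn.draw(rng);
    py = y + dn.draw(rng);
    if (px < 0 || px >= W || py < 0 || py >= H) continue;
    if (barrier && quadrant_cpp(px, py, sx, sy) != q0) {
      if (b <= 0.0 || rng.unif() >= b) continue;
    }
    return;
  }
}

// [[Rcpp::export(name = ".bb_draw_parents")]]
IntegerMatrix bb_draw_parents(int n, int x, int y, double sigma,
                              int W, int H, bool barrier, double b,
                              int sx, int sy, double seed) {
  Xoshiro256pp rng; rng.seed((uint64_t)seed);
  DiscNormal dn; dn.build(sigma);
  IntegerMatrix out(n, 2);
  int px, py;
  for (int i = 0; i < n; ++i) {
    draw_parent_one(x, y, dn, W, H, barrier, b, sx, sy, rng, px, py);
    out(i, 0) = px;
    out(i, 1) = py;
  }
  return out;
}

// ------------------------------------------------------------ evolution ---

// Mean number of distinct alleles and mean gene diversity (1 - sum p^2)
// per locus over the whole lattice.
static void lattice_diag(const std::vector<int> &al, int W, int H, int L,
                         double &mean_na, double &mean_h) {
  const size_t N2 = (size_t)W * H * 2;
  double na_tot = 0.0, h_tot = 0.0;
  std::vector<int> copies(N2);
  for (int l = 0; l < L; ++l) {
    size_t m = 0;
    for (size_t c = 0; c < (size_t)W * H; ++c) {
      copies[m++] = al[2 * (l + (size_t)L * c)];
      copies[m++] = al[2 * (l + (size_t)L * c) + 1];
    }
    std::sort(copies.begin(), copies.end());
    double sump2 = 0.0;
    int na = 0;
    size_t i = 0;
    while (i < N2) {
      size_t j = i;
      while (j < N2 && copies[j] == copies[i]) ++j;
      double p = (double)(j - i) / (double)N2;
      sump2 += p * p;
      ++na;
      i = j;
    }
    na_tot += na;
    h_tot += 1.0 - sump2;
  }
  mean_na = na_tot / L;
  mean_h = h_tot / L;
}

// Advance the lattice `ngen` synchronous generations.  snapshot_gens are
// 1-based generation indices (relative to this call) at which a copy of the
// lattice is kept; diag_every > 0 records mean Na / H at that cadence (and
// always at generation ngen).
// [[Rcpp::export(name = ".bb_sim_run")]]
List bb_sim_run(IntegerVector alleles, int W, int H, int L,
                IntegerVector next_allele_id, double sigma, double mu,
                int ngen, bool barrier, double b, int sx, int sy,
                double seed, IntegerVector snapshot_gens, int diag_every) {
  const size_t SZ = (size_t)2 * L * W * H;
  if ((size_t)alleles.size() != SZ)
    stop("allele buffer has wrong length");
  Xoshiro256pp rng; rng.seed((uint64_t)seed);
  DiscNormal dn; dn.build(sigma);

  std::vector<int> cur(alleles.begin(), alleles.end());
  std::vector<int> nxt(SZ);
  std::vector<int> nid(next_allele_id.begin(), next_allele_id.end());

  std::unordered_set<int> snap_set(snapshot_gens.begin(), snapshot_gens.end());
  List snapshots;
  std::vector<double> diag_gen, diag_na, diag_h;

  // geometric countdown over the transmission stream: number of further
  // transmissions until (and including) the next mutating one
  const bool mutating = mu > 0.0;
  long long until_mut = 0;
  if (mutating) {
    if (mu >= 1.0) until_mut = 1;
    else until_mut = 1 + (long long)std::floor(std::log(rng.unif_pos()) /
                                               std::log1p(-mu));
  }

  int p1x, p1y, p2x, p2y;
  for (int g = 1; g <= ngen; ++g) {
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        draw_parent_one(x, y, dn, W, H, barrier, b, sx, sy, rng, p1x, p1y);
        draw_parent_one(x, y, dn, W, H, barrier, b, sx, sy, rng, p2x, p2y);
        uint64_t bits1 = rng.next();
        uint64_t bits2 = rng.next();
        const size_t base1 = (size_t)2 * L * (p1x + (size_t)W * p1y);
        const size_t base2 = (size_t)2 * L * (p2x + (size_t)W * p2y);
        const size_t basec = (size_t)2 * L * (x + (size_t)W * y);
        for (int l = 0; l < L; ++l) {
          int a1 = cur[base1 + 2 * l + ((bits1 >> l) & 1ULL)];
          if (mutating && --until_mut == 0) {
            a1 = nid[(size_t)l]++;
            until_mut = (mu >= 1.0) ? 1
              : 1 + (long long)std::floor(std::log(rng.unif_pos()) /
                                          std::log1p(-mu));
          }
          int a2 = cur[base2 + 2 * l + ((bits2 >> l) & 1ULL)];
          if (mutating && --until_mut == 0) {
            a2 = nid[(size_t)l]++;
            until_mut = (mu >= 1.0) ? 1
              : 1 + (long long)std::floor(std::log(rng.unif_pos()) /
                                          std::log1p(-mu));
          }
          nxt[basec + 2 * l] = a1;
          nxt[basec + 2 * l + 1] = a2;
        }
      }
    }
    cur.swap(nxt);
    if (snap_set.count(g)) {
      IntegerVector sc((R_xlen_t)SZ);
      std::copy(cur.begin(), cur.end(), sc.begin());
      snapshots.push_back(sc);
    }
    if (diag_every > 0 && (g % diag_every == 0 || g == ngen)) {
      double mna, mh;
      lattice_diag(cur, W, H, L, mna, mh);
      diag_gen.push_back(g);
      diag_na.push_back(mna);
      diag_h.push_back(mh);
    }
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector out((R_xlen_t)SZ);
  std::copy(cur.begin(), cur.end(), out.begin());
  IntegerVector nid_out(L);
  std::copy(nid.begin(), nid.end(), nid_out.begin());
  NumericMatrix diag((int)diag_gen.size(), 3);
  for (size_t i = 0; i < diag_gen.size(); ++i) {
    diag((int)i, 0) = diag_gen[i];
    diag((int)i, 1) = diag_na[i];
    diag((int)i, 2) = diag_h[i];
  }
  colnames(diag) = CharacterVector::create("generation", "mean_na", "mean_h");
  return List::create(_["alleles"] = out,
                      _["next_allele_id"] = nid_out,
                      _["snapshots"] = snapshots,
                      _["diagnostics"] = diag);
}

// ------------------------------------------------- pairwise genotype dist --

// geno: n x 2L integer matrix, columns (locus1.a, locus1.b, locus2.a, ...).
// metric "dps": 1 - (shared alleles / 2) averaged over loci (shared counted
// by the best pairing of the two allele pairs, i.e. sum of min allele counts).
// metric "rousset": identity-based analogue of FST/(1-FST) for individual
// pairs, a_hat_ij = (Qw - Qij) / (1 - Qw) with Qw the mean within-individual
// allele identity and Qij the mean cross-individual identity over the four
// allele comparisons per locus.
// [[Rcpp::export(name = ".bb_pairwise_dist")]]
NumericMatrix bb_pairwise_dist(IntegerMatrix geno, int L, std::string metric) {
  const int n = geno.nrow();
  if (geno.ncol() != 2 * L) stop("genotype matrix has wrong width");
  NumericMatrix D(n, n);
  const bool rousset = (metric == "rousset");

  // copy to row-major flat buffer for locality
  std::vector<int> g((size_t)n * 2 * L);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 2 * L; ++c) g[(size_t)i * 2 * L + c] = geno(i, c);

  double qw = 0.0;
  if (rousset) {
    long hits = 0;
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l)
        if (g[(size_t)i * 2 * L + 2 * l] == g[(size_t)i * 2 * L + 2 * l + 1])
          ++hits;
    qw = (double)hits / ((double)n * L);
  }

  for (int i = 0; i < n; ++i) {
    const int *gi = &g[(size_t)i * 2 * L];
    for (int j = i + 1; j < n; ++j) {
      const int *gj = &g[(size_t)j * 2 * L];
      double acc = 0.0;
      for (int l = 0; l < L; ++l) {
        int a1 = gi[2 * l], a2 = gi[2 * l + 1];
        int b1 = gj[2 * l], b2 = gj[2 * l + 1];
        if (rousset) {
          acc += (double)((a1 == b1) + (a1 == b2) + (a2 == b1) + (a2 == b2));
        } else {
          int pair1 = (a1 == b1) + (a2 == b2);
          int pair2 = (a1 == b2) + (a2 == b1);
          acc += (double)(pair1 > pair2 ? pair1 : pair2);
        }
      }
      double d;
      if (rousset) {
        double qij = acc / (4.0 * L);
        double denom = 1.0 - qw;
        d = (denom > 1e-12) ? (qw - qij) / denom : 0.0;
      } else {
        d = 1.0 - acc / (2.0 * L);
      }
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
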