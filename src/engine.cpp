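#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Per-walker counter-free RNG: xoshiro256+ seeded through splitmix64 so that
// every walker owns an independent, reproducible stream derived from
// (master seed, stream index).  Streams survive phase boundaries by passing a
// distinct stream offset per phase.

static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t rotl64(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct Xoshiro256p {
  uint64_t s[4];
  void seed_from(uint64_t master, uint64_t stream) {
    uint64_t x = master ^ (0xD1B54A32D192ED03ULL * (stream + 1ULL));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(x);
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl64(s[3], 45);
    return result;
  }
  // uniform on [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Site codes: 0 = free, 1 = obstacle, 2 = bindable obstacle.
//
// Per-step rule, unbound walker (RNG draw order: axis, direction, release):
//   draw axis (x/y), draw direction (-1/+1); target site free -> move;
//   target bindable -> bind (walker sits on the binding site);
//   target plain obstacle -> elastic collision, stay put.
// Bound walker: one draw u; u < p_unbind(site) -> release isotropically to a
//   uniformly chosen unoccupied 4-neighbour (extra draw); if all four
//   neighbours are occupied the walker stays at the binding site, unbound.
//
// [[Rcpp::export]]
List sim_ensemble_cpp(RawMatrix sites, NumericMatrix p_unbind, bool has_binding,
                      IntegerVector si, IntegerVector sj,
                      IntegerVector swi, IntegerVector swj,
                      LogicalVector sbound,
                      int n_steps, int record_every,
                      double master_seed, double stream_offset) {
  const int nx = sites.nrow(), ny = sites.ncol();
  const int n_walkers = si.size();
  if (n_steps % record_every != 0)
    stop("n_steps must be a multiple of record_every");
  const int n_rec = n_steps / record_every;

  NumericMatrix IU(n_rec, n_walkers), JU(n_rec, n_walkers);
  IntegerMatrix IW(n_rec, n_walkers), JW(n_rec, n_walkers);
  LogicalMatrix BND(n_rec, n_walkers);
  IntegerVector fi(n_walkers), fj(n_walkers), fwi(n_walkers), fwj(n_walkers);
  LogicalVector fbound(n_walkers);

  const uint64_t mseed = (uint64_t)master_seed;
  const uint64_t soff  = (uint64_t)stream_offset;
  const Rbyte *S = &sites[0];

  for (int w = 0; w < n_walkers; ++w) {
    Xoshiro256p rng;
    rng.seed_from(mseed, soff + (uint64_t)w);
    int i = si[w], j = sj[w];
    int wi = swi[w], wj = swj[w];
    bool bound = sbound[w];
    double pu = 0.0;
    if (bound && has_binding) pu = p_unbind(i, j);

    int rec = 0;
    for (int step = 0; step < n_steps; ++step) {
      if (bound) {
        double u = rng.unif();
        if (u < pu) {
          // isotropic release among unoccupied 4-neighbours
          int ci[4], cj[4], cwi[4], cwj[4];
          int cnt = 0;
          for (int d = 0; d < 4; ++d) {
            int ti = i, tj = j, twi = wi, twj = wj;
            if (d == 0)      { ti = i + 1; if (ti == nx) { ti = 0;      ++twi; } }
            else if (d == 1) { ti = i - 1; if (ti < 0)   { ti = nx - 1; --twi; } }
            else if (d == 2) { tj = j + 1; if (tj == ny) { tj = 0;      ++twj; } }
            else             { tj = j - 1; if (tj < 0)   { tj = ny - 1; --twj; } }
            if (S[(size_t)tj * nx + ti] == 0) {
              ci[cnt] = ti; cj[cnt] = tj; cwi[cnt] = twi; cwj[cnt] = twj;
              ++cnt;
            }
          }
          bound = false;
          if (cnt > 0) {
            int k = (int)(rng.unif() * cnt);
            if (k == cnt) k = cnt - 1;
            i = ci[k]; j = cj[k]; wi = cwi[k]; wj = cwj[k];
          }
          // else: remain at the binding site this step, unbound
        }
      } else {
        double u1 = rng.unif();
        double u2 = rng.unif();
        int ti = i, tj = j, twi = wi, twj = wj;
        if (u1 < 0.5) {
          if (u2 < 0.5) { ti = i - 1; if (ti < 0)   { ti = nx - 1; --twi; } }
          else          { ti = i + 1; if (ti == nx) { ti = 0;      ++twi; } }
        } else {
          if (u2 < 0.5) { tj = j - 1; if (tj < 0)   { tj = ny - 1; --twj; } }
          else          { tj = j + 1; if (tj == ny) { tj = 0;      ++twj; } }
        }
        Rbyte code = S[(size_t)tj * nx + ti];
        if (code == 0) {
          i = ti; j = tj; wi = twi; wj = twj;
        } else if (code == 2 && has_binding) {
          // binding succeeds on contact; walker occupies the binding site
          i = ti; j = tj; wi = twi; wj = twj;
          bound = true;
          pu = p_unbind(ti, tj);
        }
        // plain obstacle (or bindable without binding enabled): stay
      }
      if ((step + 1) % record_every == 0) {
        IU(rec, w) = (double)i + (double)wi * (double)nx;
        JU(rec, w) = (double)j + (double)wj * (double)ny;
        IW(rec, w) = i; JW(rec, w) = j;
        BND(rec, w) = bound;
        ++rec;
      }
    }
    fi[w] = i; fj[w] = j; fwi[w] = wi; fwj[w] = wj; fbound[w] = bound;
  }

  return List::create(_["iu"] = IU, _["ju"] = JU,
                      _["iw"] = IW, _["jw"] = JW,
                      _["bound"] = BND,
                      _["final_i"] = fi, _["final_j"] = fj,
                      _["final_wi"] = fwi, _["final_wj"] = fwj,
                      _["final_bound"] = fbound);
}
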