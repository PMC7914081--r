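#include <Rcpp.h>
using namespace Rcpp;

// Lattice encoding shared with the R side:
//   sp    : integer matrix, 0 = vacant, otherwise species id in 1..N
//   lag   : integer matrix, 1 = individual in lag phase
//   timer : integer matrix, steps spent in the current lag episode
// Species vectors are indexed by species id - 1.

static inline int wrapi(int a, int n) {
  int r = a % n;
  return r < 0 ? r + n : r;
}

// Neighbourhood statistic for an occupied focal site.  Default semantics:
// count of occupied Moore neighbours whose role is OPPOSITE to the focal
// cell's role.  literal = TRUE switches to the plain sum of the role flag
// over occupied neighbours (i.e. a collaborator count for every focal cell).
static int mll_at(const IntegerMatrix& sp, const IntegerVector& role,
                  int i, int j, bool literal) {
  int R = sp.nrow(), C = sp.ncol();
  int focal_role = role[sp(i, j) - 1];
  int cnt = 0;
  for (int di = -1; di <= 1; ++di) {
    for (int dj = -1; dj <= 1; ++dj) {
      if (di == 0 && dj == 0) continue;
      int s = sp(wrapi(i + di, R), wrapi(j + dj, C));
      if (s == 0) continue;
      int r = role[s - 1];
      if (literal) cnt += r;
      else if (r != focal_role) ++cnt;
    }
  }
  return cnt;
}

// [[Rcpp::export]]
IntegerMatrix cpp_mll_matrix(const IntegerMatrix& sp, const IntegerVector& role,
                             bool literal) {
  int R = sp.nrow(), C = sp.ncol();
  IntegerMatrix out(R, C);
  for (int i = 0; i < R; ++i)
    for (int j = 0; j < C; ++j)
      out(i, j) = sp(i, j) == 0 ? NA_INTEGER : mll_at(sp, role, i, j, literal);
  return out;
}

// Lag-entry decisions for every active occupied cell, taken from the
// pre-phase snapshot (MLL depends only on sp/role, which this phase never
// modifies, so reading the input matrices IS the snapshot).
static int lag_phase(IntegerMatrix& sp, IntegerMatrix& lag, IntegerMatrix& timer,
                     const IntegerVector& role,
                     const NumericMatrix& aprob, const NumericMatrix& bprob,
                     bool literal) {
  int R = sp.nrow(), C = sp.ncol();
  int entries = 0;
  for (int j = 0; j < C; ++j) {
    for (int i = 0; i < R; ++i) {
      int s = sp(i, j);
      if (s == 0 || lag(i, j) == 1) continue;
      int mll = mll_at(sp, role, i, j, literal);
      int tier = mll >= 6 ? 0 : (mll >= 3 ? 1 : 2);
      double pr = role[s - 1] == 1 ? aprob(s - 1, tier) : bprob(s - 1, tier);
      if (pr > 0.0 && unif_rand() < pr) {
        lag(i, j) = 1;
        timer(i, j) = 0;
        ++entries;
      }
    }
  }
  return entries;
}

// Per cell, in order: lagged cells age; overrun (timer > Lat*n) risks death
// with probability p; survivors recover with probability 1/Lat; every
// occupied cell then faces natural death with probability d.
static void death_phase(IntegerMatrix& sp, IntegerMatrix& lag, IntegerMatrix& timer,
                        const NumericVector& p, const NumericVector& d,
                        const IntegerVector& Lat, const IntegerVector& nfac,
                        int* recoveries, int* overrun_deaths, int* natural_deaths) {
  int R = sp.nrow(), C = sp.ncol();
  for (int j = 0; j < C; ++j) {
    for (int i = 0; i < R; ++i) {
      int s = sp(i, j);
      if (s == 0) continue;
      bool dead = false;
      if (lag(i, j) == 1) {
        timer(i, j) += 1;
        if (timer(i, j) > Lat[s - 1] * nfac[s - 1] && unif_rand() < p[s - 1]) {
          dead = true;
          ++*overrun_deaths;
        }
        if (!dead && unif_rand() < 1.0 / Lat[s - 1]) {
          lag(i, j) = 0;
          timer(i, j) = 0;
          ++*recoveries;
        }
      }
      if (!dead && d[s - 1] > 0.0 && unif_rand() < d[s - 1]) {
        dead = true;
        ++*natural_deaths;
      }
      if (dead) {
        sp(i, j) = 0;
        lag(i, j) = 0;
        timer(i, j) = 0;
      }
    }
  }
}

// Proliferation into vacancies.  Vacancies are visited in uniformly random
// order; candidates are the occupied, non-lagged cells of the radius-3 Moore
// shell (7x7 minus centre, 48 sites, torus wrapped) as of the phase-start
// snapshot, each volunteering independently with its species' probability m.
// One uniform pick among volunteers parents an offspring copy; a parent may
// parent at most once per step, and offspring are not candidates this step.
static int move_phase(IntegerMatrix& sp, IntegerMatrix& lag, IntegerMatrix& timer,
                      const NumericVector& m) {
  int R = sp.nrow(), C = sp.ncol();
  IntegerMatrix sp0 = clone(sp);
  IntegerMatrix lag0 = clone(lag);
  LogicalMatrix parented(R, C);

  std::vector<int> vac;
  vac.reserve(R * C);
  for (int j = 0; j < C; ++j)
    for (int i = 0; i < R; ++i)
      if (sp(i, j) == 0) vac.push_back(j * R + i);

  // Fisher-Yates on R's RNG stream
  for (int k = (int)vac.size() - 1; k > 0; --k) {
    int idx = (int)std::floor(unif_rand() * (k + 1));
    if (idx > k) idx = k;
    std::swap(vac[k], vac[idx]);
  }

  int births = 0;
  std::vector<int> cand;
  cand.reserve(48);
  for (size_t v = 0; v < vac.size(); ++v) {
    int i = vac[v] % R, j = vac[v] / R;
    cand.clear();
    for (int dj = -3; dj <= 3; ++dj) {
      for (int di = -3; di <= 3; ++di) {
        if (di == 0 && dj == 0) continue;
        int pi = wrapi(i + di, R), pj = wrapi(j + dj, C);
        int s = sp0(pi, pj);
        if (s == 0 || lag0(pi, pj) == 1 || parented(pi, pj)) continue;
        if (unif_rand() < m[s - 1]) cand.push_back(pj * R + pi);
      }
    }
    if (!cand.empty()) {
      int pick = (int)std::floor(unif_rand() * cand.size());
      if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
      int pi = cand[pick] % R, pj = cand[pick] / R;
      sp(i, j) = sp0(pi, pj);
      lag(i, j) = 0;
      timer(i, j) = 0;
      parented(pi, pj) = true;
      ++births;
    }
  }
  return births;
}

// [[Rcpp::export]]
List cpp_lag_phase(const IntegerMatrix& sp_in, const IntegerMatrix& lag_in,
                   const IntegerMatrix& timer_in, const IntegerVector& role,
                   const NumericMatrix& aprob, const NumericMatrix& bprob,
                   bool literal) {
  IntegerMatrix sp = clone(sp_in), lag = clone(lag_in), timer = clone(timer_in);
  int entries = lag_phase(sp, lag, timer, role, aprob, bprob, literal);
  return List::create(_["species"] = sp, _["is_lag"] = lag,
                      _["lag_timer"] = timer, _["lag_entries"] = entries);
}

// [[Rcpp::export]]
List cpp_death_phase(const IntegerMatrix& sp_in, const IntegerMatrix& lag_in,
                     const IntegerMatrix& timer_in,
                     const NumericVector& p, const NumericVector& d,
                     const IntegerVector& Lat, const IntegerVector& nfac) {
  IntegerMatrix sp = clone(sp_in), lag = clone(lag_in), timer = clone(timer_in);
  int rec = 0, od = 0, nd = 0;
  death_phase(sp, lag, timer, p, d, Lat, nfac, &rec, &od, &nd);
  return List::create(_["species"] = sp, _["is_lag"] = lag,
                      _["lag_timer"] = timer, _["recoveries"] = rec,
                      _["overrun_deaths"] = od, _["natural_deaths"] = nd);
}

// [[Rcpp::export]]
List cpp_move_phase(const IntegerMatrix& sp_in, const IntegerMatrix& lag_in,
                    const IntegerMatrix& timer_in, const NumericVector& m) {
  IntegerMatrix sp = clone(sp_in), lag = clone(lag_in), timer = clone(timer_in);
  int births = move_phase(sp, lag, timer, m);
  return List::create(_["species"] = sp, _["is_lag"] = lag,
                      _["lag_timer"] = timer, _["births"] = births);
}

// One synchronous step: lag induction, lag bookkeeping + deaths, move rule.
// Consumes the same RNG draws as calling the three phase wrappers in order.
// [[Rcpp::export]]
List cpp_ca_step(const IntegerMatrix& sp_in, const IntegerMatrix& lag_in,
                 const IntegerMatrix& timer_in, const IntegerVector& role,
                 const NumericMatrix& aprob, const NumericMatrix& bprob,
                 const NumericVector& m, const NumericVector& p,
                 const NumericVector& d, const IntegerVector& Lat,
                 const IntegerVector& nfac, bool literal, bool lag_enabled) {
  IntegerMatrix sp = clone(sp_in), lag = clone(lag_in), timer = clone(timer_in);
  int entries = 0, rec = 0, od = 0, nd = 0;
  if (lag_enabled)
    entries = lag_phase(sp, lag, timer, role, aprob, bprob, literal);
  death_phase(sp, lag, timer, p, d, Lat, nfac, &rec, &od, &nd);
  int births = move_phase(sp, lag, timer, m);
  return List::create(_["species"] = sp, _["is_lag"] = lag,
                      _["lag_timer"] = timer,
                      _["lag_entries"] = entries, _["recoveries"] = rec,
                      _["overrun_deaths"] = od, _["natural_deaths"] = nd,
                      _["births"] = births);
}

// Species counts at a snapshot (tabulate species ids 1..n_species).
// [[Rcpp::export]]
IntegerVector cpp_species_counts(const IntegerMatrix& sp, int n_species) {
  IntegerVector out(n_species);
  int n = sp.nrow() * sp.ncol();
  for (int k = 0; k < n; ++k) {
    int s = sp[k];
    if (s > 0 && s <= n_species) out[s - 1] += 1;
  }
  return out;
}
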