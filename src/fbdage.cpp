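// Lewis-Mk pruning likelihood and the Metropolis-Hastings kernel for
// fixed-topology tip dating under the fossilized birth-death tree prior.
//
// Node indexing follows the R side: tips 1..ntip, internal nodes
// (ntip+1)..(2 ntip - 1) with the root at ntip+1 (0-based internally).
// A sampled ancestor is a fossil tip whose age is tied to its parent's.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
using namespace Rcpp;

// ---------------------------------------------------------------- topology

struct Topo {
  int ntip, nnode;
  std::vector<int> parent;                 // -1 for root
  std::vector<std::array<int, 2> > kids;   // internal nodes only (by node id)
  std::vector<int> postorder;              // internal nodes, children first
  int root;
};

static Topo build_topo(const IntegerMatrix& edge, int ntip) {
  Topo tp;
  tp.ntip = ntip;
  tp.nnode = 2 * ntip - 1;
  tp.root = ntip;  // 0-based
  tp.parent.assign(tp.nnode, -1);
  tp.kids.assign(tp.nnode, std::array<int, 2>{{-1, -1}});
  for (int e = 0; e < edge.nrow(); e++) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    tp.parent[c] = p;
    if (tp.kids[p][0] < 0) tp.kids[p][0] = c; else tp.kids[p][1] = c;
  }
  // iterative postorder over internal nodes
  tp.postorder.clear();
  std::vector<int> stack, out;
  stack.push_back(tp.root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    out.push_back(v);
    for (int i = 0; i < 2; i++) {
      int c = tp.kids[v][i];
      if (c >= ntip) stack.push_back(c);
    }
  }
  for (int i = (int)out.size() - 1; i >= 0; i--) tp.postorder.push_back(out[i]);
  return tp;
}

// ------------------------------------------------------- pruning likelihood

// log-likelihood of one character (bitmask-coded tip states) for one
// gamma-category rate multiplier; rate[v] is the clock rate on the branch
// above node v
static double prune_char(const Topo& tp, const std::vector<double>& age,
                         const int* bits, int k,
                         const std::vector<double>& rate, double g,
                         std::vector<double>& buf) {
  const int K = k;
  double scaler = 0.0;
  // buf holds partials for all nodes: nnode x K
  for (int t = 0; t < tp.ntip; t++) {
    for (int s = 0; s < K; s++)
      buf[t * K + s] = (bits[t] >> s) & 1 ? 1.0 : 0.0;
  }
  for (size_t i = 0; i < tp.postorder.size(); i++) {
    int v = tp.postorder[i];
    double* Lv = &buf[v * K];
    for (int s = 0; s < K; s++) Lv[s] = 1.0;
    for (int ci = 0; ci < 2; ci++) {
      int c = tp.kids[v][ci];
      double dur = age[v] - age[c];
      double m = rate[c] * g * dur;
      double e = std::exp(-(double)K / (K - 1) * m);
      double psame = 1.0 / K + (double)(K - 1) / K * e;
      double pdiff = (1.0 - e) / K;
      const double* Lc = &buf[c * K];
      double sum = 0.0;
      for (int s = 0; s < K; s++) sum += Lc[s];
      for (int s = 0; s < K; s++)
        Lv[s] *= pdiff * sum + (psame - pdiff) * Lc[s];
    }
    double mx = 0.0;
    for (int s = 0; s < K; s++) if (Lv[s] > mx) mx = Lv[s];
    if (mx <= 0.0) return R_NegInf;
    for (int s = 0; s < K; s++) Lv[s] /= mx;
    scaler += std::log(mx);
  }
  double tot = 0.0;
  const double* Lr = &buf[tp.root * K];
  for (int s = 0; s < K; s++) tot += Lr[s];
  if (tot <= 0.0) return R_NegInf;
  return std::log(tot / K) + scaler;
}

// gamma-category average in log space
static double logmeanexp(const std::vector<double>& x) {
  double mx = R_NegInf;
  for (size_t i = 0; i < x.size(); i++) if (x[i] > mx) mx = x[i];
  if (!R_FINITE(mx)) return mx;
  double s = 0.0;
  for (size_t i = 0; i < x.size(); i++) s += std::exp(x[i] - mx);
  return mx + std::log(s / x.size());
}

// full matrix log-likelihood; rate[] is per-node (branch above node),
// grates are the gamma multipliers, mkv applies the variable-characters
// ascertainment correction
static double mk_loglik_all(const Topo& tp, const std::vector<double>& age,
                            const IntegerMatrix& bits, const IntegerVector& kvec,
                            const std::vector<double>& rate,
                            const std::vector<double>& grates, bool mkv) {
  int nchar = bits.ncol();
  int kmax = 0;
  for (int j = 0; j < nchar; j++) if (kvec[j] > kmax) kmax = kvec[j];
  std::vector<double> buf((size_t)tp.nnode * std::max(kmax, 2));
  std::vector<int> col(tp.ntip);
  std::vector<double> percat(grates.size());
  // Mkv: probability of a constant character, cached per state count k
  // (all-same-state pattern; by symmetry each of the k states is equal)
  std::vector<double> log_pvar(kmax + 1, NA_REAL);
  double ll = 0.0;
  for (int j = 0; j < nchar; j++) {
    int k = kvec[j];
    for (int t = 0; t < tp.ntip; t++) col[t] = bits(t, j);
    for (size_t g = 0; g < grates.size(); g++)
      percat[g] = prune_char(tp, age, col.data(), k, rate, grates[g], buf);
    double lc = logmeanexp(percat);
    if (!R_FINITE(lc)) return R_NegInf;
    if (mkv) {
      if (!R_FINITE(log_pvar[k])) {
        std::vector<int> cc(tp.ntip, 1);  // every tip in state 0
        for (size_t g = 0; g < grates.size(); g++)
          percat[g] = prune_char(tp, age, cc.data(), k, rate, grates[g], buf);
        double pconst = (double)k * std::exp(logmeanexp(percat));
        log_pvar[k] = std::log1p(-std::min(pconst, 1.0 - 1e-12));
      }
      lc -= log_pvar[k];
    }
    ll += lc;
  }
  return ll;
}

// [[Rcpp::export]]
double mk_loglik_cpp(IntegerMatrix edge, NumericVector age, int ntip,
                     IntegerMatrix bits, IntegerVector kvec,
                     NumericVector edge_rates, NumericVector gamma_rates,
                     bool mkv) {
  Topo tp = build_topo(edge, ntip);
  std::vector<double> a(age.begin(), age.end());
  // per-edge rates to per-node (branch above child node)
  std::vector<double> rate(tp.nnode, 0.0);
  for (int e = 0; e < edge.nrow(); e++) rate[edge(e, 1) - 1] = edge_rates[e];
  std::vector<double> gr(gamma_rates.begin(), gamma_rates.end());
  return mk_loglik_all(tp, a, bits, kvec, rate, gr, mkv);
}

// ------------------------------------------------------ FBD tree density

struct FbdRates { double lambda, mu, psi, d, r, T; };

// Kendall extinction probability (no fossil sampling), for the
// survival conditioning term
static double p0_bd(double t, double d, double r) {
  double e = std::exp(-d * t);
  return r * (1.0 - e) / (1.0 - r * e);
}

// log q(t) and p0(t) of the birth-death-sampling process with rho = 1
struct QP { double c1, c2; };
static QP qp_const(const FbdRates& fr) {
  QP z;
  double x = fr.lambda - fr.mu - fr.psi;
  z.c1 = std::sqrt(x * x + 4.0 * fr.lambda * fr.psi);
  z.c2 = (fr.lambda + fr.mu + fr.psi) / z.c1;
  return z;
}
static double log_q(double t, const QP& z) {
  double e = std::exp(-z.c1 * t);
  double den = e * (1.0 - z.c2) + (1.0 + z.c2);
  return std::log(4.0) - z.c1 * t - 2.0 * std::log(den);
}
static double p0_full(double t, const FbdRates& fr, const QP& z) {
  double e = std::exp(-z.c1 * t);
  double frac = (e * (1.0 - z.c2) - (1.0 + z.c2)) /
                (e * (1.0 - z.c2) + (1.0 + z.c2));
  return (fr.lambda + fr.mu + fr.psi + z.c1 * frac) / (2.0 * fr.lambda);
}

// log density of the sampled-ancestor tree under the FBD process,
// conditioned on survival of the process for time T
static double fbd_log_density(const Topo& tp, const std::vector<double>& age,
                              const std::vector<bool>& is_fossil,
                              const std::vector<bool>& sa,
                              const FbdRates& fr) {
  if (fr.T < age[tp.root] - 1e-12) return R_NegInf;
  int nfossil = 0;
  for (int t = 0; t < tp.ntip; t++) if (is_fossil[t]) nfossil++;
  if (nfossil > 0 && fr.psi <= 0.0) return R_NegInf;
  QP z = qp_const(fr);
  double surv = 1.0 - p0_bd(fr.T, fr.d, fr.r);
  double lp = log_q(fr.T, z) - std::log(surv);
  // labeled-tree convention: each bifurcation contributes 2 lambda
  // (two orientations of its children per labeled topology)
  double log_lambda = std::log(2.0 * fr.lambda);
  double log_psi = fr.psi > 0 ? std::log(fr.psi) : R_NegInf;
  for (size_t i = 0; i < tp.postorder.size(); i++) {
    int v = tp.postorder[i];
    // a node is a sampled-ancestor attachment when one of its children is
    // a fossil tip flagged SA (zero-length branch)
    bool is_sa_node = false;
    for (int ci = 0; ci < 2; ci++) {
      int c = tp.kids[v][ci];
      if (c < tp.ntip && is_fossil[c] && sa[c]) is_sa_node = true;
    }
    if (!is_sa_node) lp += log_lambda + log_q(age[v], z);
  }
  for (int t = 0; t < tp.ntip; t++) {
    if (!is_fossil[t]) continue;  // extant tips contribute rho = 1
    if (age[t] <= 0.0 || age[t] >= fr.T) return R_NegInf;
    if (sa[t]) {
      lp += log_psi;
    } else {
      double p0y = p0_full(age[t], fr, z);
      if (p0y <= 0.0) return R_NegInf;
      lp += log_psi + std::log(p0y) - log_q(age[t], z);
    }
  }
  return lp;
}

// ----------------------------------------------------------- prior handling

// family codes: 0 lognormal(meanlog, sdlog), 1 uniform(min, max),
// 2 gamma(shape, rate), 3 fixed(value)
static double prior_logdens(int fam, double a, double b, double x) {
  switch (fam) {
    case 0: return R::dlnorm(x, a, b, 1);
    case 1: return R::dunif(x, a, b, 1);
    case 2: return R::dgamma(x, a, 1.0 / b, 1);
    case 3: return (x == a) ? 0.0 : R_NegInf;
  }
  return R_NegInf;
}

// --------------------------------------------------------------- the kernel

// parameter slots in the state vector
enum { P_D = 0, P_R, P_SPSI, P_MU, P_S, P_ALPHA, NPAR };

struct Kernel {
  Topo tp;
  std::vector<bool> is_fossil;
  std::vector<double> lower, upper;   // per tip (fossils)
  int focal;                          // tip index or -1
  // data
  IntegerMatrix bits; IntegerVector kvec;
  bool have_chars;
  int clock_kind;                     // 0 strict, 1 ucln
  bool use_gamma; int gamma_ncat;
  bool use_fbd, use_lik;
  // priors
  IntegerVector pfam; NumericMatrix ppar;  // NPAR rows (+T row at NPAR)
  bool implicit_s, implicit_T; double Nmin, Nmax;
  // state
  std::vector<double> age;   // nnode
  std::vector<bool> sa;      // per tip
  double T;
  std::vector<double> par;   // NPAR
  std::vector<double> mult;  // ucln per-node multipliers (branch above node)
  // caches
  double cur_lik, cur_fbd, cur_pprior;

  FbdRates rates() const {
    FbdRates fr;
    fr.d = par[P_D]; fr.r = par[P_R];
    fr.lambda = fr.d / (1.0 - fr.r);
    fr.mu = fr.r * fr.d / (1.0 - fr.r);
    if (implicit_s) fr.psi = par[P_SPSI];
    else fr.psi = par[P_SPSI] * fr.mu / (1.0 - par[P_SPSI]);
    fr.T = T;
    return fr;
  }

  double param_logprior() const {
    double lp = 0.0;
    lp += prior_logdens(pfam[P_D], ppar(P_D, 0), ppar(P_D, 1), par[P_D]);
    lp += prior_logdens(pfam[P_R], ppar(P_R, 0), ppar(P_R, 1), par[P_R]);
    lp += prior_logdens(pfam[P_SPSI], ppar(P_SPSI, 0), ppar(P_SPSI, 1),
                        par[P_SPSI]);
    lp += prior_logdens(pfam[P_MU], ppar(P_MU, 0), ppar(P_MU, 1), par[P_MU]);
    if (clock_kind == 1) {
      lp += prior_logdens(pfam[P_S], ppar(P_S, 0), ppar(P_S, 1), par[P_S]);
      double S = par[P_S];
      if (S <= 0) return R_NegInf;
      for (int v = 0; v < tp.nnode; v++) {
        if (v == tp.root) continue;
        lp += R::dlnorm(mult[v], -S * S / 2.0, S, 1);
      }
    }
    if (use_gamma)
      lp += prior_logdens(pfam[P_ALPHA], ppar(P_ALPHA, 0), ppar(P_ALPHA, 1),
                          par[P_ALPHA]);
    if (implicit_T) {
      double d = par[P_D];
      double lo = std::log(std::max(Nmin, 1.0)) / d;
      double hi = std::log(Nmax) / d;
      if (T < lo || T > hi) return R_NegInf;
      lp += std::log(d) + d * T - std::log(Nmax - Nmin);
    } else {
      lp += prior_logdens(pfam[NPAR], ppar(NPAR, 0), ppar(NPAR, 1), T);
    }
    // fossil age range indicator (moves respect bounds; guards state)
    for (int t = 0; t < tp.ntip; t++) {
      if (!is_fossil[t]) continue;
      double lo = lower[t], hi = (t == focal) ? T : upper[t];
      if (age[t] < lo - 1e-12 || age[t] > hi + 1e-12) return R_NegInf;
    }
    return lp;
  }

  double fbd_logdens() const {
    if (!use_fbd) return 0.0;
    return fbd_log_density(tp, age, is_fossil, sa, rates());
  }

  double loglik() {
    if (!use_lik || !have_chars) return 0.0;
    std::vector<double> rate(tp.nnode, par[P_MU]);
    if (clock_kind == 1)
      for (int v = 0; v < tp.nnode; v++) rate[v] = par[P_MU] * mult[v];
    std::vector<double> gr;
    if (use_gamma) {
      gr.resize(gamma_ncat);
      double a = par[P_ALPHA];
      if (a <= 0) return R_NegInf;
      // equal-probability category means via the shape+1 identity
      std::vector<double> cum(gamma_ncat + 1);
      for (int i = 0; i <= gamma_ncat; i++) {
        double q = (double)i / gamma_ncat;
        double bnd = (i == 0) ? 0.0 :
          (i == gamma_ncat ? R_PosInf : R::qgamma(q, a, 1.0 / a, 1, 0));
        cum[i] = (i == gamma_ncat) ? 1.0 : R::pgamma(bnd, a + 1.0, 1.0 / a, 1, 0);
      }
      for (int i = 0; i < gamma_ncat; i++)
        gr[i] = gamma_ncat * (cum[i + 1] - cum[i]);
    } else {
      gr.assign(1, 1.0);
    }
    return mk_loglik_all(tp, age, bits, kvec, rate, gr, false);
  }

  double logpost() { return cur_lik + cur_fbd + cur_pprior; }
};

// uniform slide with reflection into [lo, hi]
static double reflect(double x, double lo, double hi) {
  double w = hi - lo;
  if (w <= 0) return lo;
  double period = 2.0 * w;
  double y = x - lo;
  y -= std::floor(y / period) * period;
  return lo + (y <= w ? y : period - y);
}

// [[Rcpp::export]]
List fbd_mcmc_cpp(IntegerMatrix edge, NumericVector age0, int ntip,
                  LogicalVector is_fossil, LogicalVector sa0, int focal,
                  NumericVector lower, NumericVector upper, double T0,
                  IntegerMatrix bits, IntegerVector kvec,
                  NumericVector par0, NumericVector mult0,
                  IntegerVector prior_fam, NumericMatrix prior_par,
                  bool implicit_s, bool implicit_T, double Nmin, double Nmax,
                  int clock_kind, bool use_gamma, int gamma_ncat,
                  bool use_fbd, bool use_lik,
                  double niter_d, int thin, double burnin_frac) {
  long niter = (long)niter_d;
  Kernel K;
  K.tp = build_topo(edge, ntip);
  K.is_fossil.assign(is_fossil.begin(), is_fossil.end());
  K.sa.assign(sa0.begin(), sa0.end());
  K.lower.assign(lower.begin(), lower.end());
  K.upper.assign(upper.begin(), upper.end());
  K.focal = focal;
  K.bits = bits; K.kvec = kvec;
  K.have_chars = bits.ncol() > 0;
  K.clock_kind = clock_kind; K.use_gamma = use_gamma;
  K.gamma_ncat = gamma_ncat;
  K.use_fbd = use_fbd; K.use_lik = use_lik;
  K.pfam = prior_fam; K.ppar = prior_par;
  K.implicit_s = implicit_s; K.implicit_T = implicit_T;
  K.Nmin = Nmin; K.Nmax = Nmax;
  K.age.assign(age0.begin(), age0.end());
  K.T = T0;
  K.par.assign(par0.begin(), par0.end());
  K.mult.assign(mult0.begin(), mult0.end());
  K.cur_pprior = K.param_logprior();
  K.cur_fbd = K.fbd_logdens();
  K.cur_lik = K.loglik();
  if (!R_FINITE(K.cur_pprior) || !R_FINITE(K.cur_fbd) || !R_FINITE(K.cur_lik))
    stop("zero-probability initial state (prior %f, tree %f, likelihood %f)",
         K.cur_pprior, K.cur_fbd, K.cur_lik);

  std::vector<int> fossils, internals;
  for (int t = 0; t < ntip; t++) if (is_fossil[t]) fossils.push_back(t);
  for (int v = ntip; v < K.tp.nnode; v++) internals.push_back(v);
  bool fixed_params[NPAR + 1];
  for (int i = 0; i <= NPAR; i++) fixed_params[i] = (prior_fam[i] == 3);

  // move types: 0 d, 1 r, 2 s/psi, 3 T, 4 mu, 5 S, 6 alpha, 7 node age,
  // 8 fossil age, 9 sa toggle, 10 tree scale, 11 ucln multiplier
  const int NMOVE = 12;
  std::vector<double> w(NMOVE, 0.0);
  if (!fixed_params[P_D]) w[0] = 2;
  if (!fixed_params[P_R]) w[1] = 2;
  if (!fixed_params[P_SPSI]) w[2] = 2;
  if (!implicit_T && !fixed_params[NPAR]) w[3] = 2;
  if (implicit_T) w[3] = 2;
  if (!fixed_params[P_MU]) w[4] = 2;   // harmless prior draw without data
  if (clock_kind == 1 && !fixed_params[P_S]) w[5] = 1;
  if (use_gamma && !fixed_params[P_ALPHA]) w[6] = 1;
  if (use_fbd) {
    w[7] = std::max(1, (int)internals.size());
    w[8] = std::max(1, (int)fossils.size());
    w[9] = fossils.empty() ? 0 : std::max(1, (int)fossils.size() / 2);
    w[10] = 1;
  }
  if (clock_kind == 1) w[11] = std::max(1, K.tp.nnode / 4);
  double wtot = 0.0;
  for (int i = 0; i < NMOVE; i++) wtot += w[i];
  if (wtot <= 0) stop("no free parameters to sample");
  std::vector<double> wcum(NMOVE);
  double acc0 = 0;
  for (int i = 0; i < NMOVE; i++) { acc0 += w[i] / wtot; wcum[i] = acc0; }

  // tuning parameters per move type (step sizes), adapted during burn-in
  std::vector<double> step(NMOVE, 0.5);
  step[1] = 0.2; step[3] = 0.3; step[10] = 0.1;
  // adaptation caps: slides bounded by their support width, scale moves
  // by a generous log-range (unbounded growth breaks the proposals when
  // a move is always accepted, e.g. a flat prior with no data)
  double step_max[NMOVE] = {4, 1, 4, 4, 4, 4, 1, 0, 0, 0, 2, 4};
  std::vector<long> nprop(NMOVE, 0), nacc(NMOVE, 0), bprop(NMOVE, 0),
      bacc(NMOVE, 0);
  long nburn = (long)(burnin_frac * niter);
  const int tune_interval = 200;

  long nsamp = niter / thin + 1;
  int ncol_extra = 0;
  NumericMatrix trace(nsamp, 15 + ncol_extra);
  long isamp = 0;

  for (long it = 0; it <= niter; it++) {
    if (it > 0) {
      double u = R::runif(0, 1);
      int mv = 0;
      while (mv < NMOVE - 1 && u > wcum[mv]) mv++;
      nprop[mv]++;
      bool in_burn = it <= nburn;
      if (in_burn) bprop[mv]++;

      double logA = 0.0;           // Hastings correction
      bool valid = true, need_lik = false;
      // save state pieces
      double old_par[NPAR]; for (int i = 0; i < NPAR; i++) old_par[i] = K.par[i];
      double oldT = K.T;
      double old_age_v = 0; int touched_node = -1;
      double old_age_f = 0; int touched_tip = -1;
      bool old_sa = false; int touched_sa = -1;
      std::vector<double> old_ages;  // tree scale
      double old_mult = 0; int touched_mult = -1;

      switch (mv) {
        case 0: case 2: case 4: {   // scale moves on d, s/psi, mu
          int pi = (mv == 0) ? P_D : (mv == 2 ? P_SPSI : P_MU);
          double c = std::exp(step[mv] * (R::runif(0, 1) - 0.5));
          K.par[pi] *= c;
          logA += std::log(c);
          if (pi == P_MU) need_lik = true;
          if (pi == P_SPSI && !implicit_s && K.par[pi] >= 1.0) valid = false;
          break;
        }
        case 1: {                    // reflect slide on r in (0,1)
          K.par[P_R] = reflect(K.par[P_R] + step[1] * (R::runif(0, 1) - 0.5),
                               1e-10, 1.0 - 1e-10);
          break;
        }
        case 3: {                    // scale T
          double c = std::exp(step[3] * (R::runif(0, 1) - 0.5));
          K.T *= c;
          logA += std::log(c);
          if (K.T < K.age[K.tp.root]) valid = false;
          break;
        }
        case 5: {                    // scale S
          double c = std::exp(step[5] * (R::runif(0, 1) - 0.5));
          K.par[P_S] *= c;
          logA += std::log(c);
          break;
        }
        case 6: {                    // reflect slide on alpha
          double lo = prior_par(P_ALPHA, 0), hi = prior_par(P_ALPHA, 1);
          if (prior_fam[P_ALPHA] != 1) { lo = 1e-6; hi = 100; }
          K.par[P_ALPHA] = reflect(K.par[P_ALPHA] +
                                   step[6] * (R::runif(0, 1) - 0.5) * (hi - lo),
                                   lo + 1e-9, hi - 1e-9);
          need_lik = true;
          break;
        }
        case 7: {                    // node age: uniform within bounds
          int v = internals[std::min((int)(R::runif(0, 1) * internals.size()),
                                     (int)internals.size() - 1)];
          // SA-tied node ages move via the fossil-age move
          bool tied = false;
          for (int ci = 0; ci < 2; ci++) {
            int c = K.tp.kids[v][ci];
            if (c < ntip && K.is_fossil[c] && K.sa[c]) tied = true;
          }
          if (tied) { valid = false; break; }
          double lo = 0.0;
          for (int ci = 0; ci < 2; ci++)
            lo = std::max(lo, K.age[K.tp.kids[v][ci]]);
          double hi = (v == K.tp.root) ? K.T : K.age[K.tp.parent[v]];
          if (hi <= lo) { valid = false; break; }
          touched_node = v; old_age_v = K.age[v];
          K.age[v] = lo + R::runif(0, 1) * (hi - lo);
          need_lik = true;
          break;
        }
        case 8: {                    // fossil age: uniform within bounds
          int f = fossils[std::min((int)(R::runif(0, 1) * fossils.size()),
                                   (int)fossils.size() - 1)];
          int p = K.tp.parent[f];
          double lo = std::max(K.lower[f], 1e-9);
          double hi;
          if (K.sa[f]) {
            int sib = (K.tp.kids[p][0] == f) ? K.tp.kids[p][1] : K.tp.kids[p][0];
            lo = std::max(lo, K.age[sib]);
            hi = (p == K.tp.root) ? K.T : K.age[K.tp.parent[p]];
          } else {
            hi = K.age[p];
          }
          double cap = (f == K.focal) ? K.T : K.upper[f];
          hi = std::min(hi, cap);
          if (hi <= lo) { valid = false; break; }
          touched_tip = f; old_age_f = K.age[f];
          double y = lo + R::runif(0, 1) * (hi - lo);
          K.age[f] = y;
          if (K.sa[f]) { touched_node = p; old_age_v = K.age[p]; K.age[p] = y; }
          need_lik = true;
          break;
        }
        case 9: {                    // sampled-ancestor toggle
          int f = fossils[std::min((int)(R::runif(0, 1) * fossils.size()),
                                   (int)fossils.size() - 1)];
          int p = K.tp.parent[f];
          int sib = (K.tp.kids[p][0] == f) ? K.tp.kids[p][1] : K.tp.kids[p][0];
          double hi = (p == K.tp.root) ? K.T : K.age[K.tp.parent[p]];
          double lo = std::max(K.age[f], K.age[sib]);
          if (hi <= lo) { valid = false; break; }
          touched_sa = f; old_sa = K.sa[f];
          touched_node = p; old_age_v = K.age[p];
          if (!K.sa[f]) {            // collapse to sampled ancestor
            if (K.age[f] < K.age[sib]) { valid = false; break; }
            K.age[p] = K.age[f]; K.sa[f] = true;
            logA -= std::log(hi - lo);   // reverse move draws age[p]
          } else {                   // expand to fossil tip
            K.age[p] = lo + R::runif(0, 1) * (hi - lo);
            K.sa[f] = false;
            logA += std::log(hi - lo);
          }
          need_lik = true;
          break;
        }
        case 10: {                   // scale internal ages and T
          double c = std::exp(step[10] * (R::runif(0, 1) - 0.5));
          old_ages = K.age;
          for (size_t i = 0; i < internals.size(); i++)
            K.age[internals[i]] *= c;
          K.T *= c;
          // SA fossils follow their attachment
          int nfree = (int)internals.size() + 1;
          for (size_t i = 0; i < fossils.size(); i++) {
            int f = fossils[i];
            if (K.sa[f]) K.age[f] = K.age[K.tp.parent[f]];
          }
          // check ordering for non-SA fossils
          for (size_t i = 0; i < fossils.size(); i++) {
            int f = fossils[i];
            if (!K.sa[f] && K.age[K.tp.parent[f]] < K.age[f]) valid = false;
          }
          logA += nfree * std::log(c);
          need_lik = true;
          break;
        }
        case 11: {                   // ucln branch-rate multiplier
          int v = std::min((int)(R::runif(0, 1) * K.tp.nnode), K.tp.nnode - 1);
          if (v == K.tp.root) { valid = false; break; }
          double c = std::exp(step[11] * (R::runif(0, 1) - 0.5));
          touched_mult = v; old_mult = K.mult[v];
          K.mult[v] *= c;
          logA += std::log(c);
          need_lik = true;
          break;
        }
      }

      bool accept = false;
      if (valid) {
        double new_pprior = K.param_logprior();
        if (R_FINITE(new_pprior)) {
          double new_fbd = K.fbd_logdens();
          if (R_FINITE(new_fbd)) {
            double new_lik = need_lik ? K.loglik() : K.cur_lik;
            double dlp = (new_pprior + new_fbd + new_lik) -
                         (K.cur_pprior + K.cur_fbd + K.cur_lik);
            if (R_FINITE(new_lik) &&
                std::log(R::runif(0, 1)) < dlp + logA) {
              accept = true;
              K.cur_pprior = new_pprior; K.cur_fbd = new_fbd;
              K.cur_lik = new_lik;
            }
          }
        }
      }
      if (!accept) {                  // restore
        for (int i = 0; i < NPAR; i++) K.par[i] = old_par[i];
        K.T = oldT;
        if (mv == 10 && !old_ages.empty()) K.age = old_ages;
        if (touched_node >= 0 && mv != 10) K.age[touched_node] = old_age_v;
        if (touched_tip >= 0) K.age[touched_tip] = old_age_f;
        if (touched_sa >= 0) K.sa[touched_sa] = old_sa;
        if (touched_mult >= 0) K.mult[touched_mult] = old_mult;
      } else {
        nacc[mv]++;
        if (in_burn) bacc[mv]++;
      }
      // step-size adaptation, frozen after burn-in
      if (in_burn && it % tune_interval == 0) {
        for (int m = 0; m < NMOVE; m++) {
          if (bprop[m] < 20) continue;
          double ar = (double)bacc[m] / bprop[m];
          if (ar > 0.35 && (step_max[m] <= 0 || step[m] < step_max[m]))
            step[m] *= 1.2;
          else if (ar < 0.15) step[m] *= 0.8;
          bprop[m] = bacc[m] = 0;
        }
      }
    }

    if (it % thin == 0 && isamp < nsamp) {
      FbdRates fr = K.rates();
      double s_now = K.implicit_s ?
        (fr.mu + fr.psi > 0 ? fr.psi / (fr.mu + fr.psi) : 0.0) : K.par[P_SPSI];
      int nsa = 0;
      for (size_t i = 0; i < fossils.size(); i++) if (K.sa[fossils[i]]) nsa++;
      trace(isamp, 0) = it;
      trace(isamp, 1) = K.logpost();
      trace(isamp, 2) = K.cur_lik;
      trace(isamp, 3) = K.cur_pprior + K.cur_fbd;
      trace(isamp, 4) = K.par[P_D];
      trace(isamp, 5) = K.par[P_R];
      trace(isamp, 6) = s_now;
      trace(isamp, 7) = fr.psi;
      trace(isamp, 8) = K.T;
      trace(isamp, 9) = K.par[P_MU];
      trace(isamp, 10) = K.par[P_S];
      trace(isamp, 11) = K.par[P_ALPHA];
      trace(isamp, 12) = (K.focal >= 0) ? K.age[K.focal] : NA_REAL;
      trace(isamp, 13) = K.age[K.tp.root];
      trace(isamp, 14) = nsa;
      isamp++;
    }
  }

  NumericVector final_ages(K.age.begin(), K.age.end());
  LogicalVector final_sa(K.sa.begin(), K.sa.end());
  IntegerVector np(nprop.begin(), nprop.end());
  IntegerVector na(nacc.begin(), nacc.end());
  return List::create(_["trace"] = trace, _["n_proposed"] = np,
                      _["n_accepted"] = na, _["final_age"] = final_ages,
                      _["final_sa"] = final_sa,
                      _["step"] = NumericVector(step.begin(), step.end()));
}

// [[Rcpp::export]]
double fbd_tree_logdens_cpp(IntegerMatrix edge, NumericVector age, int ntip,
                            LogicalVector is_fossil, LogicalVector sa,
                            double origin_T, double lambda, double mu,
                            double psi, double d, double r) {
  Topo tp = build_topo(edge, ntip);
  std::vector<double> a(age.begin(), age.end());
  std::vector<bool> foss(is_fossil.begin(), is_fossil.end());
  std::vector<bool> s(sa.begin(), sa.end());
  FbdRates fr; fr.lambda = lambda; fr.mu = mu; fr.psi = psi;
  fr.d = d; fr.r = r; fr.T = origin_T;
  return fbd_log_density(tp, a, foss, s, fr);
}
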