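#include <Rcpp.h>
using namespace Rcpp;

// Length-based selectivity.
// form 0: logistic with par (L50, log(L95 - L50)).
// form 1: double normal with par (peak, log ascending sd, log descending sd).
static inline double sel_len(double L, int form, const double *sp) {
  if (form == 0) {
    double d = std::exp(sp[1]);
    return 1.0 / (1.0 + std::exp(-std::log(19.0) * (L - sp[0]) / d));
  }
  double w = (L < sp[0]) ? std::exp(sp[1]) : std::exp(sp[2]);
  double z = (L - sp[0]) / w;
  return std::exp(-0.5 * z * z);
}

// Baranov catch biomass predicted at apical F given start-of-year state.
static double baranov_catch(double F, int A, const double *N, const double *w,
                            const double *sel, const double *M) {
  double c = 0.0;
  for (int a = 0; a < A; ++a) {
    double Fa = F * sel[a];
    double Z = Fa + M[a];
    if (Z <= 0.0) continue;
    c += w[a] * N[a] * (Fa / Z) * (1.0 - std::exp(-Z));
  }
  return c;
}

// Solve apical F on [0, fmax] so predicted catch matches cobs. Fixed-count
// bisection keeps the objective smooth to finite-difference resolution.
// Returns fmax (flagged) when the catch is unattainable.
static double solve_f(double cobs, int A, const double *N, const double *w,
                      const double *sel, const double *M, double fmax,
                      bool *attainable) {
  *attainable = true;
  if (cobs <= 0.0) return 0.0;
  if (baranov_catch(fmax, A, N, w, sel, M) < cobs) {
    *attainable = false;
    return fmax;
  }
  double lo = 0.0, hi = fmax;
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    if (baranov_catch(mid, A, N, w, sel, M) < cobs) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// Extracted model data (one extraction per fit, shared across FD evals).
struct AsmData {
  int A, L, T, form, nsel;
  double h, sigma_r, ess, q_trend, fmax;
  NumericVector M, w, mat, mids, cobs, iobs, isig;
  NumericMatrix alk, lobs;
  IntegerVector ipos, lpos, dpos;
  std::vector<int> dev_year;  // length T, 1 where a deviate is estimated

  explicit AsmData(List dat)
      : A(as<int>(dat["n_ages"])), L(as<int>(dat["n_len"])),
        T(as<int>(dat["n_years"])), form(as<int>(dat["sel_form"])),
        nsel(as<int>(dat["n_sel"])), h(as<double>(dat["h"])),
        sigma_r(as<double>(dat["sigma_r"])), ess(as<double>(dat["ess"])),
        q_trend(as<double>(dat["q_trend"])), fmax(as<double>(dat["f_max"])),
        M(dat["m"]), w(dat["waa"]), mat(dat["mat"]), mids(dat["mids"]),
        cobs(dat["catch_obs"]), iobs(dat["idx_obs"]), isig(dat["idx_sigma"]),
        alk(dat["alk"]), lobs(dat["lc_obs"]), ipos(dat["idx_pos"]),
        lpos(dat["lc_pos"]), dpos(dat["dev_pos"]), dev_year(T, 0) {
    for (int i = 0; i < dpos.size(); ++i) dev_year[dpos[i]] = 1;
  }
};

// Optional per-fit report filled when rep != nullptr.
struct AsmReport {
  std::vector<double> ssb, f, rec, eb, cpred, ipred, iresid, nterm,
      selA, selL, lcpred, Nmat;
  std::vector<int> fok;
  double logq, nll_idx, nll_len, nll_pen, S0;
  bool all_attainable;
};

static double asm_core(const double *par, const AsmData &d,
                       AsmReport *rep) {
  const int A = d.A, L = d.L, T = d.T;
  const double R0 = std::exp(par[0]);
  const double *sp = par + 1;
  const double *devp = par + 1 + d.nsel;
  const double bias = 0.5 * d.sigma_r * d.sigma_r;

  std::vector<double> selL(L), selA(A, 0.0), alkc(A * L, 0.0);
  for (int l = 0; l < L; ++l) selL[l] = sel_len(d.mids[l], d.form, sp);
  for (int a = 0; a < A; ++a) {
    double s = 0.0;
    for (int l = 0; l < L; ++l) s += d.alk(a, l) * selL[l];
    selA[a] = s;
    if (s > 1e-12)
      for (int l = 0; l < L; ++l) alkc[a * L + l] = d.alk(a, l) * selL[l] / s;
  }

  std::vector<double> N(A, 0.0);
  N[0] = R0;
  for (int a = 1; a < A; ++a) N[a] = N[a - 1] * std::exp(-d.M[a - 1]);
  N[A - 1] /= (1.0 - std::exp(-d.M[A - 1]));
  double S0 = 0.0;
  for (int a = 1; a < A; ++a) S0 += N[a] * d.w[a] * d.mat[a];

  std::vector<double> eb(T), lp(L);
  double nll_len = 0.0;
  int lc_i = 0, dev_i = 0;
  bool all_ok = true;

  if (rep) {
    rep->ssb.resize(T); rep->f.resize(T); rep->rec.resize(T);
    rep->eb.resize(T); rep->cpred.resize(T); rep->fok.resize(T);
    rep->lcpred.assign((size_t)d.lpos.size() * L, 0.0);
    rep->Nmat.assign((size_t)(T + 1) * A, 0.0);
    rep->selA.assign(selA.begin(), selA.end());
    rep->selL.assign(selL.begin(), selL.end());
    rep->S0 = S0;
  }

  for (int t = 0; t < T; ++t) {
    // spawning (ages 1+) precedes recruitment within the year
    double s = 0.0;
    for (int a = 1; a < A; ++a) s += N[a] * d.w[a] * d.mat[a];
    double bh = 4.0 * d.h * R0 * s /
                (S0 * (1.0 - d.h) + (5.0 * d.h - 1.0) * s);
    // mean-bias-corrected lognormal deviate, matching the generating model
    double dv = 0.0;
    if (d.dev_year[t]) dv = devp[dev_i++] - bias;
    N[0] = bh * std::exp(dv);

    double e = 0.0;
    for (int a = 0; a < A; ++a) e += N[a] * d.w[a] * selA[a];
    eb[t] = e;

    bool ok;
    double F = solve_f(d.cobs[t], A, N.data(), d.w.begin(), selA.data(),
                       d.M.begin(), d.fmax, &ok);
    if (!ok) all_ok = false;

    if (rep) {
      rep->ssb[t] = s; rep->rec[t] = N[0]; rep->eb[t] = e;
      rep->f[t] = F; rep->fok[t] = ok;
      rep->cpred[t] = baranov_catch(F, A, N.data(), d.w.begin(),
                                    selA.data(), d.M.begin());
      for (int a = 0; a < A; ++a) rep->Nmat[(size_t)t * A + a] = N[a];
    }

    // predicted catch length composition and multinomial NLL
    if (lc_i < d.lpos.size() && d.lpos[lc_i] == t) {
      std::fill(lp.begin(), lp.end(), 0.0);
      double tot = 0.0;
      for (int a = 0; a < A; ++a) {
        double Fa = F * selA[a], Z = Fa + d.M[a];
        if (Z <= 0.0) continue;
        double cn = N[a] * (Fa / Z) * (1.0 - std::exp(-Z));
        if (cn <= 0.0) continue;
        for (int l = 0; l < L; ++l) lp[l] += cn * alkc[a * L + l];
      }
      for (int l = 0; l < L; ++l) tot += lp[l];
      if (tot > 0.0) for (int l = 0; l < L; ++l) lp[l] /= tot;
      double nll_y = 0.0;
      for (int l = 0; l < L; ++l)
        if (d.lobs(lc_i, l) > 0.0)
          nll_y -= d.lobs(lc_i, l) * std::log(lp[l] + 1e-12);
      nll_len += d.ess * nll_y;
      if (rep)
        for (int l = 0; l < L; ++l) rep->lcpred[(size_t)lc_i * L + l] = lp[l];
      ++lc_i;
    }

    // annual survival update with plus-group accumulation
    double carry = N[A - 1] * std::exp(-(d.M[A - 1] + F * selA[A - 1]));
    for (int a = A - 1; a >= 1; --a) {
      double Z = d.M[a - 1] + F * selA[a - 1];
      N[a] = N[a - 1] * std::exp(-Z);
    }
    N[A - 1] += carry;
    N[0] = 0.0;
  }

  // conditional analytic MLE for log q (inverse-variance weighted)
  double num = 0.0, den = 0.0;
  for (int i = 0; i < d.ipos.size(); ++i) {
    int t = d.ipos[i];
    double pr = std::log1p(d.q_trend) * t + std::log(eb[t]);
    double wgt = 1.0 / (d.isig[i] * d.isig[i]);
    num += wgt * (std::log(d.iobs[i]) - pr);
    den += wgt;
  }
  double logq = (den > 0.0) ? num / den : 0.0;

  double nll_idx = 0.0;
  if (rep) rep->iresid.resize(d.ipos.size());
  for (int i = 0; i < d.ipos.size(); ++i) {
    int t = d.ipos[i];
    double r = std::log(d.iobs[i]) - logq - std::log1p(d.q_trend) * t -
               std::log(eb[t]);
    if (rep) rep->iresid[i] = r;
    nll_idx += 0.5 * r * r / (d.isig[i] * d.isig[i]) + std::log(d.isig[i]);
  }

  double nll_pen = 0.0;
  if (d.sigma_r > 0.0)
    for (int i = 0; i < d.dpos.size(); ++i) {
      double dvp = devp[i];
      nll_pen += 0.5 * dvp * dvp / (d.sigma_r * d.sigma_r);
    }

  double nll = nll_idx + nll_len + nll_pen;
  if (!std::isfinite(nll)) nll = 1e12;

  if (rep) {
    rep->logq = logq;
    rep->nll_idx = nll_idx; rep->nll_len = nll_len; rep->nll_pen = nll_pen;
    rep->all_attainable = all_ok;
    rep->ipred.resize(T);
    for (int t = 0; t < T; ++t)
      rep->ipred[t] = std::exp(logq + std::log1p(d.q_trend) * t) * eb[t];
    rep->nterm.assign(N.begin(), N.end());
    for (int a = 0; a < A; ++a) rep->Nmat[(size_t)T * A + a] = N[a];
  }
  return nll;
}

// Objective (report = FALSE) or full report (report = TRUE).
// [[Rcpp::export]]
List asm_kernel(NumericVector par, List dat, bool report) {
  AsmData d(dat);
  if (!report) {
    double nll = asm_core(par.begin(), d, nullptr);
    return List::create(_["nll"] = nll);
  }
  AsmReport rep;
  double nll = asm_core(par.begin(), d, &rep);
  NumericMatrix lcpred(d.lpos.size(), d.L), Nmat(d.T + 1, d.A);
  for (int i = 0; i < d.lpos.size(); ++i)
    for (int l = 0; l < d.L; ++l) lcpred(i, l) = rep.lcpred[(size_t)i * d.L + l];
  for (int t = 0; t <= d.T; ++t)
    for (int a = 0; a < d.A; ++a) Nmat(t, a) = rep.Nmat[(size_t)t * d.A + a];
  return List::create(
      _["nll"] = nll, _["nll_index"] = rep.nll_idx,
      _["nll_length"] = rep.nll_len, _["nll_penalty"] = rep.nll_pen,
      _["logq"] = rep.logq, _["ssb"] = wrap(rep.ssb), _["f"] = wrap(rep.f),
      _["rec"] = wrap(rep.rec), _["eb"] = wrap(rep.eb),
      _["catch_pred"] = wrap(rep.cpred), _["index_pred"] = wrap(rep.ipred),
      _["index_resid"] = wrap(rep.iresid), _["lencomp_pred"] = lcpred,
      _["numbers"] = Nmat, _["terminal_n"] = wrap(rep.nterm),
      _["sel_age"] = wrap(rep.selA), _["sel_len"] = wrap(rep.selL),
      _["ssb0"] = rep.S0, _["f_attainable"] = wrap(rep.fok),
      _["all_attainable"] = rep.all_attainable);
}

// Objective value and central-difference gradient in one call.
// [[Rcpp::export]]
List asm_nll_grad(NumericVector par, List dat) {
  AsmData d(dat);
  const int p = par.size();
  std::vector<double> x(par.begin(), par.end());
  double f0 = asm_core(x.data(), d, nullptr);
  NumericVector g(p);
  for (int i = 0; i < p; ++i) {
    double hstep = 1e-6 * std::max(1.0, std::fabs(x[i]));
    double xi = x[i];
    x[i] = xi + hstep;
    double fu = asm_core(x.data(), d, nullptr);
    x[i] = xi - hstep;
    double fd = asm_core(x.data(), d, nullptr);
    x[i] = xi;
    g[i] = (fu - fd) / (2.0 * hstep);
  }
  return List::create(_["nll"] = f0, _["grad"] = g);
}
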