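// Core numerics: kinetic-law flux evaluation, analytic Jacobian, and a
// stiff integrator (linearly implicit Bader-Deuflhard midpoint rule with
// polynomial extrapolation and adaptive macro-step control).
//
// The networks integrated here span pM..mM concentrations and ms..hour
// timescales; an implicit, L-stable-by-construction scheme with the exact
// Jacobian is required.  Error control is per-component WRMS with
// scale atol + rtol*|y|, so small species are resolved relative to their
// own magnitude.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

enum LawKind { MA_IRREV = 0, MA_REV = 1, MM = 2, MM_ACT = 3 };

struct Reac {
  int kind;
  std::vector<int> ridx; std::vector<double> rst;   // reactants
  std::vector<int> pidx; std::vector<double> pst;   // products
  std::vector<int> nidx; std::vector<double> nst;   // net stoichiometry
  int enz = -1, act = -1;
  double k = 0, kon = 0, koff = 0, kcat = 0, Km = 0, actF = 1, actKm = 1;
};

static std::vector<Reac> parse_reactions(const List& creac) {
  std::vector<Reac> out;
  out.reserve(creac.size());
  for (int i = 0; i < creac.size(); ++i) {
    List rl = creac[i];
    Reac r;
    r.kind = as<int>(rl["kind"]);
    IntegerVector ri = rl["ridx"]; NumericVector rs = rl["rst"];
    IntegerVector pi = rl["pidx"]; NumericVector ps = rl["pst"];
    for (int j = 0; j < ri.size(); ++j) { r.ridx.push_back(ri[j]); r.rst.push_back(rs[j]); }
    for (int j = 0; j < pi.size(); ++j) { r.pidx.push_back(pi[j]); r.pst.push_back(ps[j]); }
    std::map<int, double> net;
    for (size_t j = 0; j < r.ridx.size(); ++j) net[r.ridx[j]] -= r.rst[j];
    for (size_t j = 0; j < r.pidx.size(); ++j) net[r.pidx[j]] += r.pst[j];
    for (auto& kv : net) if (kv.second != 0.0) { r.nidx.push_back(kv.first); r.nst.push_back(kv.second); }
    r.enz = as<int>(rl["enz"]);
    r.act = as<int>(rl["act"]);
    NumericVector pr = rl["par"];  // k, kon, koff, kcat, Km, actF, actKm
    r.k = pr[0]; r.kon = pr[1]; r.koff = pr[2];
    r.kcat = pr[3]; r.Km = pr[4]; r.actF = pr[5]; r.actKm = pr[6];
    out.push_back(std::move(r));
  }
  return out;
}

static inline double side_product(const std::vector<int>& idx,
                                  const std::vector<double>& st,
                                  const double* y) {
  double p = 1.0;
  for (size_t j = 0; j < idx.size(); ++j) {
    double c = y[idx[j]];
    p *= (st[j] == 1.0) ? c : std::pow(c, st[j]);
  }
  return p;
}

// d/dy_m of the side product, computed without dividing by y_m so that
// zero concentrations are handled exactly (stoichiometries are small ints).
static inline double side_product_partial(const std::vector<int>& idx,
                                          const std::vector<double>& st,
                                          const double* y, size_t m) {
  double p = (st[m] == 1.0) ? 1.0 : st[m] * std::pow(y[idx[m]], st[m] - 1.0);
  for (size_t j = 0; j < idx.size(); ++j) {
    if (j == m) continue;
    double c = y[idx[j]];
    p *= (st[j] == 1.0) ? c : std::pow(c, st[j]);
  }
  return p;
}

static double reaction_flux(const Reac& r, const double* y) {
  switch (r.kind) {
  case MA_IRREV:
    return r.k * side_product(r.ridx, r.rst, y);
  case MA_REV:
    return r.kon * side_product(r.ridx, r.rst, y)
         - r.koff * side_product(r.pidx, r.pst, y);
  case MM: case MM_ACT: {
    double S = y[r.ridx[0]], E = y[r.enz];
    double v = r.kcat * E * S / (r.Km + S);
    if (r.kind == MM_ACT) {
      double A = y[r.act];
      v *= 1.0 + (r.actF - 1.0) * A / (A + r.actKm);
    }
    return v;
  }
  }
  return 0.0;
}

static void rhs(const std::vector<Reac>& reac, const double* y, double* dy, int n) {
  std::fill(dy, dy + n, 0.0);
  for (const Reac& r : reac) {
    double v = reaction_flux(r, y);
    for (size_t j = 0; j < r.nidx.size(); ++j) dy[r.nidx[j]] += r.nst[j] * v;
  }
}

static void jacobian(const std::vector<Reac>& reac, const double* y,
                     arma::mat& J) {
  J.zeros();
  std::vector<std::pair<int, double>> dep;  // (species, dv/dy_species)
  for (const Reac& r : reac) {
    dep.clear();
    switch (r.kind) {
    case MA_IRREV:
      for (size_t m = 0; m < r.ridx.size(); ++m)
        dep.emplace_back(r.ridx[m], r.k * side_product_partial(r.ridx, r.rst, y, m));
      break;
    case MA_REV:
      for (size_t m = 0; m < r.ridx.size(); ++m)
        dep.emplace_back(r.ridx[m], r.kon * side_product_partial(r.ridx, r.rst, y, m));
      for (size_t m = 0; m < r.pidx.size(); ++m)
        dep.emplace_back(r.pidx[m], -r.koff * side_product_partial(r.pidx, r.pst, y, m));
      break;
    case MM: case MM_ACT: {
      double S = y[r.ridx[0]], E = y[r.enz];
      double den = r.Km + S;
      double g = 1.0;
      if (r.kind == MM_ACT) {
        double A = y[r.act];
        g = 1.0 + (r.actF - 1.0) * A / (A + r.actKm);
        double base = r.kcat * E * S / den;
        double dgdA = (r.actF - 1.0) * r.actKm /
                      ((A + r.actKm) * (A + r.actKm));
        dep.emplace_back(r.act, base * dgdA);
      }
      dep.emplace_back(r.enz, g * r.kcat * S / den);
      dep.emplace_back(r.ridx[0], g * r.kcat * E * r.Km / (den * den));
      break;
    }
    }
    for (const auto& d : dep)
      for (size_t j = 0; j < r.nidx.size(); ++j)
        J(r.nidx[j], d.first) += r.nst[j] * d.second;
  }
}

// [[Rcpp::export]]
NumericVector cpp_fluxes(List creac, NumericVector y) {
  std::vector<Reac> reac = parse_reactions(creac);
  NumericVector out(reac.size());
  for (size_t i = 0; i < reac.size(); ++i) out[i] = reaction_flux(reac[i], y.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rhs(List creac, NumericVector y) {
  std::vector<Reac> reac = parse_reactions(creac);
  NumericVector dy(y.size());
  rhs(reac, y.begin(), dy.begin(), y.size());
  return dy;
}

// [[Rcpp::export]]
NumericMatrix cpp_jacobian(List creac, NumericVector y) {
  std::vector<Reac> reac = parse_reactions(creac);
  int n = y.size();
  arma::mat J(n, n);
  jacobian(reac, y.begin(), J);
  NumericMatrix out(n, n);
  std::copy(J.begin(), J.end(), out.begin());
  return out;
}

// One Bader-Deuflhard semi-implicit midpoint traversal of macro step H with
// m substeps, starting from y with f0 = f(y) and Jacobian J already known.
// Returns false if the linear solve failed or produced non-finite values.
static bool simd_step(const std::vector<Reac>& reac, const arma::vec& y,
                      const arma::vec& f0, const arma::mat& J, double H,
                      int m, arma::vec& out, long& nfev) {
  const int n = y.n_elem;
  const double h = H / m;
  arma::mat A = arma::eye<arma::mat>(n, n) - h * J;
  arma::mat L, U, P;
  if (!arma::lu(L, U, P, A)) return false;
  auto lusolve = [&](const arma::vec& b, arma::vec& x) -> bool {
    arma::vec pb = P * b;
    arma::vec z;
    if (!arma::solve(z, arma::trimatl(L), pb)) return false;
    if (!arma::solve(x, arma::trimatu(U), z)) return false;
    return x.is_finite();
  };
  arma::vec del(n), ym(n), fy(n), tmp(n);
  if (!lusolve(h * f0, del)) return false;
  ym = y + del;
  for (int k = 1; k < m; ++k) {
    rhs(reac, ym.memptr(), fy.memptr(), n); ++nfev;
    if (!fy.is_finite()) return false;
    if (!lusolve(h * fy - del, tmp)) return false;
    del += 2.0 * tmp;       // del_new = del_old + 2*tmp
    ym += del;              // y_{k+1} = y_k + del_new
  }
  rhs(reac, ym.memptr(), fy.memptr(), n); ++nfev;
  if (!fy.is_finite()) return false;
  if (!lusolve(h * fy - del, tmp)) return false;
  out = ym + tmp;
  return out.is_finite();
}

// [[Rcpp::export]]
List cpp_simulate(List creac, NumericVector y0, NumericVector times,
                  double rtol, double atol, double max_step, double h_init) {
  std::vector<Reac> reac = parse_reactions(creac);
  const int n = y0.size();
  const int nt = times.size();
  const int KMAX = 5;
  const int nseq[KMAX + 1] = {0, 2, 6, 10, 14, 22};

  NumericMatrix Y(nt, n);
  arma::vec y(n);
  for (int i = 0; i < n; ++i) y[i] = y0[i];
  for (int i = 0; i < n; ++i) Y(0, i) = y[i];

  double t = times[0];
  double span = times[nt - 1] - t;
  double H = h_init > 0 ? h_init : std::min(span * 1e-6, 1e-2);
  if (max_step > 0) H = std::min(H, max_step);

  long nfev = 0, njac = 0, nstep = 0, nreject = 0;
  std::string err_msg;
  bool failed = false;
  int filled = 1;

  arma::vec f0(n), scale(n);
  arma::mat J(n, n);
  std::vector<std::vector<arma::vec>> tab(KMAX + 1,
      std::vector<arma::vec>(KMAX + 1, arma::vec(n)));

  for (int iout = 1; iout < nt && !failed; ++iout) {
    double tgoal = times[iout];
    while (t < tgoal * (1 - 1e-14) - 1e-300) {
      if (nstep > 2000000L) { err_msg = "step limit exceeded"; failed = true; break; }
      double Hs = std::min(H, tgoal - t);
      if (max_step > 0) Hs = std::min(Hs, max_step);
      rhs(reac, y.memptr(), f0.memptr(), n); ++nfev;
      jacobian(reac, y.memptr(), J); ++njac;
      if (!f0.is_finite() || !J.is_finite()) {
        err_msg = "non-finite derivative or Jacobian"; failed = true; break;
      }
      for (int i = 0; i < n; ++i) scale[i] = atol + rtol * std::fabs(y[i]);

      bool accepted = false;
      double err = -1.0;
      int jacc = 0;
      while (!accepted) {
        bool broke = false;
        err = -1.0;
        for (int j = 1; j <= KMAX; ++j) {
          if (!simd_step(reac, y, f0, J, Hs, nseq[j], tab[j][1], nfev)) {
            broke = true; break;
          }
          // polynomial extrapolation in (H/nseq)^2 (Aitken-Neville)
          for (int l = 2; l <= j; ++l) {
            double r = double(nseq[j]) / double(nseq[j - l + 1]);
            double fac = r * r - 1.0;
            tab[j][l] = tab[j][l - 1]
                      + (tab[j][l - 1] - tab[j - 1][l - 1]) / fac;
          }
          if (j >= 2) {
            arma::vec d = tab[j][j] - tab[j][j - 1];
            double s = 0;
            for (int i = 0; i < n; ++i) { double e = d[i] / scale[i]; s += e * e; }
            err = std::sqrt(s / n);
            if (!std::isfinite(err)) { broke = true; break; }
            if (err <= 1.0) { accepted = true; jacc = j; break; }
          }
          for (int l = 1; l <= j; ++l) tab[j - 1][l] = tab[j][l];
          // keep previous diagonal for the next column's error estimate
        }
        if (accepted) break;
        ++nreject;
        double fac = (broke || err <= 0) ? 0.25
                   : std::max(0.1, 0.9 * std::pow(err, -1.0 / (2.0 * KMAX - 1.0)));
        Hs *= fac;
        H = Hs;
        if (Hs < 1e-12 * std::max(1.0, std::fabs(t)) || Hs <= 0) {
          err_msg = "step size underflow (stiff solver failure)";
          failed = true; break;
        }
      }
      if (failed) break;

      arma::vec ynew = tab[jacc][jacc];
      // negativity policy: excursions comparable to the local error are
      // tolerated during integration; anything clearly larger is a failure.
      double floor_fail = -(1e6 * atol + 1e-3 * rtol * arma::abs(ynew).max());
      for (int i = 0; i < n; ++i) {
        if (ynew[i] < floor_fail) {
          err_msg = "negative concentration beyond tolerance (species index "
                    + std::to_string(i + 1) + ")";
          failed = true;
        }
      }
      if (failed) break;
      y = ynew;
      t += Hs;
      ++nstep;
      double fac = 0.9 * std::pow(std::max(err, 1e-10),
                                  -1.0 / (2.0 * jacc - 1.0));
      fac = std::min(5.0, std::max(0.2, fac));
      double Hnat = Hs * fac;
      H = (Hs < H) ? std::max(H, Hnat) : Hnat;
    }
    if (failed) break;
    for (int i = 0; i < n; ++i) {
      double v = y[i];
      if (v < 0 && v >= -(100.0 * atol)) v = 0;  // output clipping only
      Y(iout, i) = v;
    }
    filled = iout + 1;
  }

  return List::create(
    _["status"] = failed ? "error" : "ok",
    _["message"] = err_msg,
    _["Y"] = Y,
    _["filled"] = filled,
    _["t_reached"] = t,
    _["last_state"] = NumericVector(y.begin(), y.end()),
    _["n_steps"] = (double)nstep,
    _["n_fev"] = (double)nfev,
    _["n_jac"] = (double)njac,
    _["n_reject"] = (double)nreject);
}
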