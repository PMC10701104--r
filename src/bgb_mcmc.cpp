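// Block Gibbs / Metropolis-within-Gibbs engine for the graph-guided sparse
// factor model.  One sweep updates, in order:
//   rho (Polya-Gamma / per-feature Gaussian precision), m, rows of W,
//   tau_w, alpha (MH), columns of Z, (tau_z, delta), columns of Omega
//   (graph-constrained Wishart, block Gibbs per connected component with a
//   rank-one-maintained Sigma = Omega^-1 cache).
//
// All randomness uses R's RNG (seed-reproducible from set.seed()).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

double bgb_rpg(double b, double c);       // polyagamma.cpp
double bgb_rinvgauss(double mu, double lambda);

namespace {

struct BGBData {
  arma::mat psi, kappa, bmat, x;
  arma::ivec type;       // 0 gaussian, 1 binomial, 2 negative binomial
  arma::vec zeta;        // gaussian precision-prior df, per feature
  arma::vec trials;      // n_j (binomial rows)
  arma::vec fails;       // r_j (negative-binomial rows)
  double lconst;         // data-dependent log-likelihood constant
  int p, n;
};

struct BGBState {
  arma::vec m;
  arma::mat W, Z, alpha, tau_w_sq, tau_z_sq, delta, rho, Omega, Sigma;
  int p, n, L;
};

struct BGBGraph {
  std::vector<arma::uvec> comp;                    // global member indices
  std::vector<std::vector<arma::uvec>> nb_local;   // per comp, per member
  std::vector<arma::uvec> nb_global;               // per feature
};

struct BGBHyper {
  double nu1, nu2, nu3, nu4, eta, epsilon, sigma_m_sq, q;
};

BGBData data_from_list(const List& d) {
  BGBData out;
  out.psi = as<arma::mat>(d["psi"]);
  out.kappa = as<arma::mat>(d["kappa"]);
  out.bmat = as<arma::mat>(d["b"]);
  out.x = as<arma::mat>(d["x"]);
  out.type = as<arma::ivec>(d["type"]);
  out.zeta = as<arma::vec>(d["zeta"]);
  out.trials = as<arma::vec>(d["trials"]);
  out.fails = as<arma::vec>(d["fails"]);
  out.lconst = d.containsElementNamed("lconst") ? as<double>(d["lconst"])
                                                : 0.0;
  out.p = out.psi.n_rows;
  out.n = out.psi.n_cols;
  return out;
}

BGBState state_from_list(const List& s) {
  BGBState st;
  st.m = as<arma::vec>(s["m"]);
  st.W = as<arma::mat>(s["W"]);
  st.Z = as<arma::mat>(s["Z"]);
  st.alpha = as<arma::mat>(s["alpha"]);
  st.tau_w_sq = as<arma::mat>(s["tau_w_sq"]);
  st.tau_z_sq = as<arma::mat>(s["tau_z_sq"]);
  st.delta = as<arma::mat>(s["delta"]);
  st.rho = as<arma::mat>(s["rho"]);
  st.Omega = as<arma::mat>(s["Omega"]);
  st.Sigma = as<arma::mat>(s["Sigma"]);
  st.p = st.W.n_rows;
  st.L = st.W.n_cols;
  st.n = st.Z.n_cols;
  return st;
}

List state_to_list(const BGBState& st) {
  return List::create(
      _["m"] = st.m, _["W"] = st.W, _["Z"] = st.Z, _["alpha"] = st.alpha,
      _["tau_w_sq"] = st.tau_w_sq, _["tau_z_sq"] = st.tau_z_sq,
      _["delta"] = st.delta, _["rho"] = st.rho, _["Omega"] = st.Omega,
      _["Sigma"] = st.Sigma);
}

BGBGraph graph_from_list(const List& g, int p) {
  BGBGraph gr;
  List comps = g["comps"]; // 0-based member indices, one per component
  List nb = g["nb"];       // 0-based neighbor lists, length p
  gr.nb_global.resize(p);
  for (int j = 0; j < p; ++j) gr.nb_global[j] = as<arma::uvec>(nb[j]);
  int nc = comps.size();
  gr.comp.resize(nc);
  gr.nb_local.resize(nc);
  for (int c = 0; c < nc; ++c) {
    gr.comp[c] = as<arma::uvec>(comps[c]);
    const arma::uvec& mem = gr.comp[c];
    std::map<arma::uword, arma::uword> glob2loc;
    for (arma::uword k = 0; k < mem.n_elem; ++k) glob2loc[mem[k]] = k;
    gr.nb_local[c].resize(mem.n_elem);
    for (arma::uword k = 0; k < mem.n_elem; ++k) {
      const arma::uvec& nbj = gr.nb_global[mem[k]];
      arma::uvec loc(nbj.n_elem);
      for (arma::uword t = 0; t < nbj.n_elem; ++t) loc[t] = glob2loc.at(nbj[t]);
      gr.nb_local[c][k] = loc;
    }
  }
  return gr;
}

BGBHyper hyper_from_list(const List& h) {
  BGBHyper hp;
  hp.nu1 = as<double>(h["nu1"]);
  hp.nu2 = as<double>(h["nu2"]);
  hp.nu3 = as<double>(h["nu3"]);
  hp.nu4 = as<double>(h["nu4"]);
  hp.eta = as<double>(h["eta"]);
  hp.epsilon = as<double>(h["epsilon"]);
  hp.sigma_m_sq = as<double>(h["sigma_m_sq"]);
  hp.q = as<double>(h["mh_proposal_var"]);
  return hp;
}

arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z[i] = R::norm_rand();
  return z;
}

double log1pexp(double x) {
  if (x > 30.0) return x + std::log1p(std::exp(-x));
  return std::log1p(std::exp(x));
}

// ---------------------------------------------------------------- rho --

void step_rho(BGBState& st, const BGBData& dat, const arma::mat& WZ) {
  for (int j = 0; j < dat.p; ++j) {
    if (dat.type[j] == 0) {
      double ss = 0.0;
      for (int i = 0; i < dat.n; ++i) {
        double r = dat.x(j, i) - (st.m[j] + WZ(j, i));
        ss += r * r;
      }
      double shape = 0.5 * (dat.zeta[j] + dat.n);
      double rate = 0.5 * (dat.zeta[j] + ss);
      double rj = R::rgamma(shape, 1.0 / rate);
      st.rho.row(j).fill(rj);
    } else {
      for (int i = 0; i < dat.n; ++i)
        st.rho(j, i) = bgb_rpg(dat.bmat(j, i), st.m[j] + WZ(j, i));
    }
  }
}

// ------------------------------------------------------------------ m --

void step_m(BGBState& st, const BGBData& dat, const BGBHyper& hp,
            const arma::mat& WZ) {
  for (int j = 0; j < dat.p; ++j) {
    double sr = 0.0, s = 0.0;
    for (int i = 0; i < dat.n; ++i) {
      sr += st.rho(j, i);
      s += dat.kappa(j, i) - st.rho(j, i) * (WZ(j, i) - dat.psi(j, i));
    }
    double vm = 1.0 / (1.0 / hp.sigma_m_sq + sr);
    st.m[j] = vm * s + std::sqrt(vm) * R::norm_rand();
  }
}

// ------------------------------------------------------- W rows, tau_w --

// posterior precision and linear term for row j of W
void w_row_system(const BGBState& st, const BGBData& dat, int j,
                  arma::mat& Prec, arma::vec& rhs) {
  arma::rowvec rho_j = st.rho.row(j);
  arma::mat Zr = st.Z.each_row() % rho_j;
  Prec = Zr * st.Z.t();
  Prec.diag() += 1.0 / arma::conv_to<arma::vec>::from(st.tau_w_sq.row(j));
  arma::vec t(dat.n);
  for (int i = 0; i < dat.n; ++i)
    t[i] = rho_j[i] * (dat.psi(j, i) - st.m[j]) + dat.kappa(j, i);
  rhs = st.Z * t;
}

arma::vec sample_mvn_from_system(arma::mat Prec, const arma::vec& rhs,
                                 arma::vec* mean_out = nullptr,
                                 bool draw = true) {
  arma::mat R;
  if (!arma::chol(R, Prec)) {
    Prec.diag() += 1e-8;
    if (!arma::chol(R, Prec))
      stop("posterior precision matrix is numerically singular");
  }
  arma::vec y = arma::solve(arma::trimatl(R.t()), rhs);
  arma::vec a = arma::solve(arma::trimatu(R), y);
  if (mean_out) *mean_out = a;
  if (!draw) return a;
  return a + arma::solve(arma::trimatu(R), rnorm_vec(rhs.n_elem));
}

void step_w(BGBState& st, const BGBData& dat) {
  arma::mat Prec;
  arma::vec rhs;
  for (int j = 0; j < st.p; ++j) {
    w_row_system(st, dat, j, Prec, rhs);
    st.W.row(j) = sample_mvn_from_system(Prec, rhs).t();
  }
}

void step_tau_w(BGBState& st) {
  for (int j = 0; j < st.p; ++j)
    for (int l = 0; l < st.L; ++l) {
      double lam = std::exp(st.alpha(j, l));
      double w = st.W(j, l);
      if (w == 0.0) {
        // prior fallback: tau^2 ~ Exp(lambda^2 / 2)
        st.tau_w_sq(j, l) = R::exp_rand() * 2.0 / (lam * lam);
      } else {
        double inv = bgb_rinvgauss(std::fabs(lam / w), lam * lam);
        st.tau_w_sq(j, l) = 1.0 / inv;
      }
    }
}

// ------------------------------------------------------------- alpha --

// log target for alpha_jl up to additive constant:
//   2*alpha - exp(2 alpha) tau^2 / 2 - (omega_jj atil^2 + 2 atil g)/(2 nu2)
int step_alpha(BGBState& st, const BGBGraph& gr, const BGBHyper& hp,
               double q) {
  int nacc = 0;
  double sq = std::sqrt(q);
  for (int l = 0; l < st.L; ++l) {
    for (int j = 0; j < st.p; ++j) {
      double cur = st.alpha(j, l);
      double tau2 = st.tau_w_sq(j, l);
      const arma::uvec& nb = gr.nb_global[j];
      double g = 0.0;
      for (arma::uword t = 0; t < nb.n_elem; ++t)
        g += st.Omega(j, nb[t]) * (st.alpha(nb[t], l) - hp.nu1);
      double ojj = st.Omega(j, j);
      double at = cur - hp.nu1;
      double lt_cur = 2.0 * cur - 0.5 * std::exp(2.0 * cur) * tau2 -
                      (ojj * at * at + 2.0 * at * g) / (2.0 * hp.nu2);
      double cand = cur + sq * R::norm_rand();
      double atc = cand - hp.nu1;
      double lt_cand = 2.0 * cand - 0.5 * std::exp(2.0 * cand) * tau2 -
                       (ojj * atc * atc + 2.0 * atc * g) / (2.0 * hp.nu2);
      double lr = lt_cand - lt_cur;
      if (std::isfinite(lr) && std::log(R::unif_rand()) < lr) {
        st.alpha(j, l) = cand;
        ++nacc;
      }
    }
  }
  return nacc;
}

// ------------------------------------------------- Z cols, tau_z, delta --

void z_col_system(const BGBState& st, const BGBData& dat, int i,
                  arma::mat& Prec, arma::vec& rhs) {
  arma::vec rho_i = st.rho.col(i);
  arma::mat Wr = st.W.each_col() % rho_i;
  Prec = st.W.t() * Wr;
  // prior precision of z_li is delta_li / tau_li^2 (normal scale mixture of
  // the Laplace with per-entry rate delta_li)
  Prec.diag() += st.delta.col(i) / st.tau_z_sq.col(i);
  arma::vec t(dat.p);
  for (int j = 0; j < dat.p; ++j)
    t[j] = rho_i[j] * (dat.psi(j, i) - st.m[j]) + dat.kappa(j, i);
  rhs = st.W.t() * t;
}

void step_z(BGBState& st, const BGBData& dat) {
  arma::mat Prec;
  arma::vec rhs;
  for (int i = 0; i < st.n; ++i) {
    z_col_system(st, dat, i, Prec, rhs);
    st.Z.col(i) = sample_mvn_from_system(Prec, rhs);
  }
}

void step_tau_z_delta(BGBState& st, const BGBHyper& hp) {
  for (int l = 0; l < st.L; ++l)
    for (int i = 0; i < st.n; ++i) {
      double z = st.Z(l, i);
      double del = st.delta(l, i);
      double tau2;
      if (z == 0.0) {
        tau2 = R::exp_rand() * 2.0 / del; // prior Exp(delta/2)
      } else {
        double inv = bgb_rinvgauss(std::fabs(1.0 / z), del);
        tau2 = 1.0 / inv;
      }
      st.tau_z_sq(l, i) = tau2;
      double rate = hp.nu3 + 0.5 * tau2 + 0.5 * z * z / tau2;
      st.delta(l, i) = R::rgamma(hp.nu4 + 1.5, 1.0 / rate);
    }
}

// ------------------------------------------------------------- Omega --

// One Gibbs pass over the columns of one graph component.  Omega_c and
// Sigma_c are the component-local precision and its cached inverse; A_c is
// the component-local posterior scale matrix.
void omega_component_sweep(arma::mat& Omega_c, arma::mat& Sigma_c,
                           const arma::mat& A_c,
                           const std::vector<arma::uvec>& nb_local,
                           double shape) {
  arma::uword pc = Omega_c.n_rows;
  if (pc == 1) {
    double xi = R::rgamma(shape, 2.0 / A_c(0, 0));
    Omega_c(0, 0) = xi;
    Sigma_c(0, 0) = 1.0 / xi;
    return;
  }
  for (arma::uword j = 0; j < pc; ++j) {
    const arma::uvec& nb = nb_local[j];
    arma::uword d = nb.n_elem;
    double ajj = A_c(j, j);
    double xi = R::rgamma(shape, 2.0 / ajj);
    arma::vec sj = Sigma_c.col(j);
    double sjj = sj[j];
    // Omega_bar^{-1} = Sigma~11 - sigma1 sigma1^T / sigma_jj
    arma::vec s1 = sj.elem(nb);
    arma::mat M = Sigma_c.submat(nb, nb) - s1 * s1.t() / sjj;
    M = 0.5 * (M + M.t());
    arma::mat R;
    if (!arma::chol(R, M)) {
      // cache drift: rebuild Sigma from scratch and retry once
      if (!arma::inv_sympd(Sigma_c, Omega_c))
        stop("Omega update: precision matrix lost positive definiteness");
      sj = Sigma_c.col(j);
      sjj = sj[j];
      s1 = sj.elem(nb);
      M = Sigma_c.submat(nb, nb) - s1 * s1.t() / sjj;
      M = 0.5 * (M + M.t());
      if (!arma::chol(R, M))
        stop("Omega update: conditional covariance not positive definite");
    }
    arma::vec a1 = A_c.col(j);
    a1 = a1.elem(nb);
    // mean  = -Omega_bar a1 / ajj = -M^{-1} a1 / ajj,  cov = M^{-1}/ajj
    arma::vec y = arma::solve(arma::trimatl(R.t()), a1);
    arma::vec mu = -arma::solve(arma::trimatu(R), y) / ajj;
    arma::vec w1 =
        mu + arma::solve(arma::trimatu(R), rnorm_vec(d)) / std::sqrt(ajj);
    double ojj = xi + arma::as_scalar(w1.t() * M * w1);
    // write column/row j of Omega (structural zeros untouched)
    for (arma::uword t = 0; t < d; ++t) {
      Omega_c(nb[t], j) = w1[t];
      Omega_c(j, nb[t]) = w1[t];
    }
    Omega_c(j, j) = ojj;
    // rank-one update of Sigma:
    //   Oinv = Omega_{-j,-j}^{-1} = Sigma_{-j,-j} - s s^T / sjj
    //   Sigma_{-j,-j} <- Oinv + (Oinv w)(Oinv w)^T / xi
    //   sigma_{-j,j}  <- -(Oinv w)/xi,  sigma_jj <- 1/xi
    arma::vec u = Sigma_c.cols(nb) * w1 - sj * (arma::dot(s1, w1) / sjj);
    // fused rank-2 update: Sigma += u u^T / xi - sj sj^T / sjj (one pass)
    {
      const double* up = u.memptr();
      const double* sp = sj.memptr();
      for (arma::uword cidx = 0; cidx < pc; ++cidx) {
        double cu = up[cidx] / xi;
        double cs = sp[cidx] / sjj;
        double* col = Sigma_c.colptr(cidx);
        for (arma::uword ridx = 0; ridx < pc; ++ridx)
          col[ridx] += up[ridx] * cu - sp[ridx] * cs;
      }
    }
    Sigma_c.col(j) = -u / xi;
    Sigma_c.row(j) = Sigma_c.col(j).t();
    Sigma_c(j, j) = 1.0 / xi;
  }
}

// Full Omega sweep over all components; returns max cache drift observed
// when `check` is true (drift measured before any rebuild).
double step_omega(BGBState& st, const BGBGraph& gr, const BGBHyper& hp,
                  bool rebuild) {
  double shape = 0.5 * (hp.eta * (1.0 + hp.epsilon) + st.L) + 1.0;
  double drift = 0.0;
  for (size_t c = 0; c < gr.comp.size(); ++c) {
    const arma::uvec& mem = gr.comp[c];
    arma::uword pc = mem.n_elem;
    arma::mat Omega_c = st.Omega.submat(mem, mem);
    arma::mat Sigma_c = st.Sigma.submat(mem, mem);
    if (rebuild && pc > 1) {
      double d = arma::abs(Sigma_c * Omega_c -
                           arma::eye(pc, pc)).max();
      if (d > drift) drift = d;
      if (!arma::inv_sympd(Sigma_c, Omega_c))
        stop("Omega rebuild: matrix not positive definite");
    }
    // component-local A = eta(11^T + eps I) + (1/nu2) sum_l atil atil^T
    arma::mat At = st.alpha.rows(mem);
    At -= hp.nu1;
    arma::mat A_c = hp.eta * arma::ones(pc, pc);
    A_c.diag() += hp.eta * hp.epsilon;
    A_c += (At * At.t()) / hp.nu2;
    omega_component_sweep(Omega_c, Sigma_c, A_c, gr.nb_local[c], shape);
    st.Omega.submat(mem, mem) = Omega_c;
    st.Sigma.submat(mem, mem) = Sigma_c;
  }
  return drift;
}

// ------------------------------------------------------------ loglik --

// Original (non-augmented) log likelihood of the data at mu; gaussian rows
// use precision rho_gauss[j].
double loglik_all(const BGBData& dat, const arma::mat& mu,
                  const arma::vec& rho_gauss) {
  double ll = dat.lconst;
  for (int j = 0; j < dat.p; ++j) {
    int ty = dat.type[j];
    for (int i = 0; i < dat.n; ++i) {
      double x = dat.x(j, i), u = mu(j, i);
      if (ty == 0) {
        double r = rho_gauss[j];
        ll += 0.5 * (std::log(r) - std::log(2.0 * M_PI)) -
              0.5 * r * (x - u) * (x - u);
      } else if (ty == 1) {
        ll += x * u - dat.trials[j] * log1pexp(u);
      } else {
        ll += x * u - (x + dat.fails[j]) * log1pexp(u);
      }
    }
  }
  return ll;
}

void full_sweep(BGBState& st, const BGBData& dat, const BGBGraph& gr,
                const BGBHyper& hp, double q, bool rebuild, int& nacc,
                double& drift) {
  arma::mat WZ = st.W * st.Z;
  step_rho(st, dat, WZ);
  step_m(st, dat, hp, WZ);
  step_w(st, dat);
  step_tau_w(st);
  nacc = step_alpha(st, gr, hp, q);
  step_z(st, dat);
  step_tau_z_delta(st, hp);
  drift = step_omega(st, gr, hp, rebuild);
}

} // namespace

// ----------------------------------------------------------------------
// Exports: granular conditional updates (used by the unit tests and the
// R-level wrappers) and the full chain runner.
// ----------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_step_rho(List state, List data) {
  BGBState st = state_from_list(state);
  BGBData dat = data_from_list(data);
  arma::mat WZ = st.W * st.Z;
  step_rho(st, dat, WZ);
  return List::create(_["rho"] = st.rho);
}

// [[Rcpp::export]]
List cpp_step_m(List state, List data, List hyper) {
  BGBState st = state_from_list(state);
  BGBData dat = data_from_list(data);
  BGBHyper hp = hyper_from_list(hyper);
  arma::mat WZ = st.W * st.Z;
  step_m(st, dat, hp, WZ);
  return List::create(_["m"] = st.m);
}

// [[Rcpp::export]]
List cpp_step_w(List state, List data) {
  BGBState st = state_from_list(state);
  BGBData dat = data_from_list(data);
  step_w(st, dat);
  return List::create(_["W"] = st.W);
}

// [[Rcpp::export]]
List cpp_w_row_moments(int j, List state, List data) {
  BGBState st = state_from_list(state);
  BGBData dat = data_from_list(data);
  arma::mat Prec;
  arma::vec rhs, mean;
  w_row_system(st, dat, j - 1, Prec, rhs);
  sample_mvn_from_system(Prec, rhs, &mean, false);
  return List::create(_["mean"] = mean, _["cov"] = arma::inv_sympd(Prec));
}

// [[Rcpp::export]]
List cpp_step_tau_w(List state) {
  BGBState st = state_from_list(state);
  step_tau_w(st);
  return List::create(_["tau_w_sq"] = st.tau_w_sq);
}

// [[Rcpp::export]]
List cpp_step_alpha(List state, List graph, List hyper, double q) {
  BGBState st = state_from_list(state);
  BGBGraph gr = graph_from_list(graph, st.p);
  BGBHyper hp = hyper_from_list(hyper);
  int nacc = step_alpha(st, gr, hp, q);
  return List::create(_["alpha"] = st.alpha, _["naccept"] = nacc);
}

// [[Rcpp::export]]
List cpp_step_z(List state, List data) {
  BGBState st = state_from_list(state);
  BGBData dat = data_from_list(data);
  step_z(st, dat);
  return List::create(_["Z"] = st.Z);
}

// [[Rcpp::export]]
List cpp_z_col_moments(int i, List state, List data) {
  BGBState st = state_from_list(state);
  BGBData dat = data_from_list(data);
  arma::mat Prec;
  arma::vec rhs, mean;
  z_col_system(st, dat, i - 1, Prec, rhs);
  sample_mvn_from_system(Prec, rhs, &mean, false);
  return List::create(_["mean"] = mean, _["cov"] = arma::inv_sympd(Prec));
}

// [[Rcpp::export]]
List cpp_step_tau_z_delta(List state, List hyper) {
  BGBState st = state_from_list(state);
  BGBHyper hp = hyper_from_list(hyper);
  step_tau_z_delta(st, hp);
  return List::create(_["tau_z_sq"] = st.tau_z_sq, _["delta"] = st.delta);
}

// [[Rcpp::export]]
List cpp_step_omega(List state, List graph, List hyper, bool rebuild) {
  BGBState st = state_from_list(state);
  BGBGraph gr = graph_from_list(graph, st.p);
  BGBHyper hp = hyper_from_list(hyper);
  double drift = step_omega(st, gr, hp, rebuild);
  return List::create(_["Omega"] = st.Omega, _["Sigma"] = st.Sigma,
                      _["drift"] = drift);
}

// [[Rcpp::export]]
List cpp_sweep(List state, List data, List graph, List hyper, bool rebuild) {
  BGBState st = state_from_list(state);
  BGBData dat = data_from_list(data);
  BGBGraph gr = graph_from_list(graph, st.p);
  BGBHyper hp = hyper_from_list(hyper);
  int nacc = 0;
  double drift = 0.0;
  full_sweep(st, dat, gr, hp, hp.q, rebuild, nacc, drift);
  List out = state_to_list(st);
  out["naccept"] = nacc;
  out["drift"] = drift;
  return out;
}

// [[Rcpp::export]]
double cpp_loglik(List data, arma::mat mu, arma::vec rho_gauss) {
  BGBData dat = data_from_list(data);
  return loglik_all(dat, mu, rho_gauss);
}

// Full chain: burn-in with optional Robbins-Monro adaptation of the MH
// proposal variance, then thinned archiving of (m, W, Z), the original-data
// log likelihood, a running mean of mu, and a running mean of the gaussian
// precisions (used for the DIC plug-in likelihood).
// [[Rcpp::export]]
List cpp_run(List state, List data, List graph, List hyper, int n_burnin,
             int n_iter, int thin, int rebuild_every, bool adapt,
             double target_accept) {
  BGBState st = state_from_list(state);
  BGBData dat = data_from_list(data);
  BGBGraph gr = graph_from_list(graph, st.p);
  BGBHyper hp = hyper_from_list(hyper);
  double q = hp.q;
  int nacc = 0;
  double drift = 0.0, max_drift = 0.0;
  int T = (thin > 0) ? n_iter / thin : 0;
  arma::mat m_draws(st.p, std::max(T, 1));
  arma::cube W_draws(st.p, st.L, std::max(T, 1));
  arma::cube Z_draws(st.L, st.n, std::max(T, 1));
  arma::vec loglik(std::max(T, 1), arma::fill::zeros);
  arma::mat mu_sum(st.p, st.n, arma::fill::zeros);
  arma::vec rho_sum(st.p, arma::fill::zeros);
  arma::vec acc_trace(n_burnin + n_iter, arma::fill::zeros);
  int kept = 0;
  double acc_after_burn = 0.0;
  int nsweep_after = 0;
  for (int it = 0; it < n_burnin + n_iter; ++it) {
    bool rebuild = rebuild_every > 0 && (it + 1) % rebuild_every == 0;
    full_sweep(st, dat, gr, hp, q, rebuild, nacc, drift);
    if (drift > max_drift) max_drift = drift;
    double arate = (st.p * st.L > 0) ? (double)nacc / (st.p * st.L) : 0.0;
    acc_trace[it] = arate;
    if (adapt && it < n_burnin) {
      double gam = 1.0 / std::pow(it + 1.0, 0.6);
      q = std::exp(std::log(q) + gam * (arate - target_accept));
      q = std::min(std::max(q, 1e-4), 100.0);
    }
    if (it >= n_burnin) {
      acc_after_burn += arate;
      ++nsweep_after;
      int post = it - n_burnin + 1;
      if (thin > 0 && post % thin == 0 && kept < T) {
        arma::mat mu = st.W * st.Z;
        mu.each_col() += st.m;
        m_draws.col(kept) = st.m;
        W_draws.slice(kept) = st.W;
        Z_draws.slice(kept) = st.Z;
        loglik[kept] = loglik_all(dat, mu, st.rho.col(0));
        mu_sum += mu;
        rho_sum += st.rho.col(0);
        ++kept;
      }
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }
  if (kept > 0) {
    mu_sum /= kept;
    rho_sum /= kept;
  }
  arma::mat m_out = (kept > 0) ? m_draws.cols(0, kept - 1)
                               : arma::mat(st.p, 0);
  arma::cube W_out = (kept > 0) ? W_draws.slices(0, kept - 1)
                                : arma::cube(st.p, st.L, 0);
  arma::cube Z_out = (kept > 0) ? Z_draws.slices(0, kept - 1)
                                : arma::cube(st.L, st.n, 0);
  arma::vec ll_out = (kept > 0) ? loglik.subvec(0, kept - 1) : arma::vec();
  return List::create(
      _["m_draws"] = m_out, _["W_draws"] = W_out, _["Z_draws"] = Z_out,
      _["loglik"] = ll_out,
      _["mu_hat"] = mu_sum, _["rho_bar"] = rho_sum, _["n_kept"] = kept,
      _["accept_rate"] = (nsweep_after > 0 ? acc_after_burn / nsweep_after
                                           : NA_REAL),
      _["q_final"] = q, _["max_drift"] = max_drift,
      _["state"] = state_to_list(st));
}
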