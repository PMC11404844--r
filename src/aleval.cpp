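// Augmented-Lagrangian objective and gradient of the direct-collocation
// muscle redundancy problem. Mirrors the reference R implementation
// (al_eval in R/solver.R); the R version is retained and the two are
// cross-checked in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// characteristic-curve constants (must match R/muscle-curves.R)
static const double FL_B1[3] = {0.814483478343008, 0.433004984392647, 0.1};
static const double FL_B2[3] = {1.055033428970575, 0.716775413397760, 1.0};
static const double FL_B3[3] = {0.162384573599574, -0.029947116970696,
                                0.353553390593273762};  // 0.5*sqrt(0.5)
static const double FL_B4[3] = {0.063303448465465, 0.200356847296188, 0.0};
static const double FV_D1 = -0.318323436899127, FV_D2 = -8.149156043475250,
                    FV_D3 = -0.374121508647863, FV_D4 = 0.885644059915004;
static const double PAS_KPE = 4.0, PAS_E0 = 0.6, LM_MIN = 0.2;
static const double TEN_C1 = 0.2, TEN_C2 = 0.995;
static const double FIBER_DAMPING = 0.01, VEL_SCALE = 10.0;

static mat shift_up(const mat& X) { return arma::shift(X, 1, 0); }
static mat shift_down(const mat& X) { return arma::shift(X, -1, 0); }

static void fl_curve(const mat& lm, mat& f, mat& df) {
  f.zeros(size(lm)); df.zeros(size(lm));
  for (int k = 0; k < 3; ++k) {
    mat den = FL_B3[k] + FL_B4[k] * lm;
    mat z = (lm - FL_B2[k]) / den;
    mat g = FL_B1[k] * exp(-0.5 * square(z));
    f += g;
    mat dz = (den - (lm - FL_B2[k]) * FL_B4[k]) / square(den);
    df += g % (-z % dz);
  }
}

static void fv_curve(const mat& v, mat& f, mat& df) {
  mat z = FV_D2 * v + FV_D3;
  mat s = sqrt(square(z) + 1.0);
  f = FV_D1 * log(z + s) + FV_D4;
  df = FV_D1 * FV_D2 / s;
}

static void fpas_curve(const mat& lm, const mat& scale, const mat& shift,
                       mat& f, mat& df) {
  mat l = lm - shift;
  double denom = std::expm1(PAS_KPE);
  double base = std::expm1(PAS_KPE * (LM_MIN - 1.0) / PAS_E0) / denom;
  mat raw = (exp(PAS_KPE * (l - 1.0) / PAS_E0) - 1.0) / denom;
  f = scale % (raw - base);
  df = scale % ((PAS_KPE / PAS_E0) * exp(PAS_KPE * (l - 1.0) / PAS_E0) / denom);
}

static void ften_curve(const mat& lt, const mat& kt, mat& f, mat& df) {
  mat e1 = exp(kt % (lt - TEN_C2));
  mat e0 = exp(kt * (1.0 - TEN_C2));
  f = TEN_C1 * (e1 - e0);
  df = TEN_C1 * kt % e1;
}

// [[Rcpp::export]]
Rcpp::List aleval_cpp(const arma::vec& x,
                      int N, int nm, int nj, double h, bool rigid,
                      const arma::mat& l_mt, const arma::mat& tau_id,
                      const arma::mat& tau_exo_fixed, const arma::cube& R,
                      const arma::mat& f_max, const arma::mat& l_opt,
                      const arma::mat& l_slk, const arma::mat& k_t,
                      const arma::mat& p_scale, const arma::mat& p_shift,
                      const arma::mat& height,
                      double w_a, double w_r, double w_v, double T_R,
                      double tau_act, double tau_deact, double blend,
                      int motor_joint,  // 0-based, -1 if none
                      const arma::mat& rt_gain, const arma::mat& rt_offset,
                      const arma::mat& rt_vt,
                      const arma::mat& lam_H, const arma::mat& lam_A,
                      double rho_H, double rho_A, bool want_grad) {
  const int n_mat = N * nm;
  int off = 0;
  mat a(const_cast<double*>(x.memptr()) + off, N, nm, false, true); off += n_mat;
  mat lm;
  if (!rigid) { lm = mat(const_cast<double*>(x.memptr()) + off, N, nm, false, true); off += n_mat; }
  mat e(const_cast<double*>(x.memptr()) + off, N, nm, false, true); off += n_mat;
  vec tau_dev;
  if (motor_joint >= 0) { tau_dev = x.subvec(off, off + N - 1); }

  mat am = 0.5 * (a + shift_down(a));
  mat vt, F_t, cH, lmm;
  mat fact, dfact, fv, dfv, fpas, dfpas, cosA, dcos, lt, dlt, ftn, dftn, fib;
  mat along;
  if (!rigid) {
    lmm = 0.5 * (lm + shift_down(lm));
    vt = (shift_down(lm) - lm) / (h * VEL_SCALE);
    fl_curve(lmm, fact, dfact);
    fv_curve(vt, fv, dfv);
    fpas_curve(lmm, p_scale, p_shift, fpas, dfpas);
    mat lm_abs = lmm % l_opt;
    along = sqrt(square(lm_abs) - square(height));
    cosA = along / lm_abs;
    dcos = square(height) / (square(l_opt) % pow(lmm, 3) % cosA);
    lt = (l_mt - along) / l_slk;
    dlt = -l_opt / (l_slk % cosA);
    ften_curve(lt, k_t, ftn, dftn);
    fib = am % fact % fv + fpas + FIBER_DAMPING * vt;
    cH = fib % cosA - ftn;
    F_t = f_max % ftn;
  } else {
    vt = rt_vt;
    F_t = rt_gain % am + rt_offset;
  }

  mat tau_mus(N, nj, fill::zeros);
  for (int j = 0; j < nj; ++j)
    tau_mus.col(j) = sum(R.slice(j) % F_t, 1);
  mat tau_exo = tau_exo_fixed;
  if (motor_joint >= 0) tau_exo.col(motor_joint) += tau_dev;
  mat eR = (tau_id - tau_mus - tau_exo) / T_R;

  // activation dynamics: tanh-blended Winters rate at the midpoint
  mat d = e - am;
  mat th = tanh(blend * d);
  mat f_sw = 0.5 * th;
  mat r_act = 1.0 / (tau_act * (0.5 + 1.5 * am));
  mat r_deact = (0.5 + 1.5 * am) / tau_deact;
  mat mix = r_act % (f_sw + 0.5) + r_deact % (0.5 - f_sw);
  mat g = mix % d;
  mat cA = (shift_down(a) - a) - h * g;

  double J_a = h * w_a * accu(square(am));
  double J_r = h * w_r * accu(square(eR));
  double J_v = h * w_v * accu(square(vt));
  double J = J_a + J_r + J_v;
  double L = J + accu(lam_A % cA) + 0.5 * rho_A * accu(square(cA));
  if (!rigid) L += accu(lam_H % cH) + 0.5 * rho_H * accu(square(cH));

  if (!want_grad)
    return Rcpp::List::create(Rcpp::Named("L") = L, Rcpp::Named("J") = J,
                              Rcpp::Named("J_a") = J_a,
                              Rcpp::Named("J_r") = J_r,
                              Rcpp::Named("J_v") = J_v);

  mat sA = lam_A + rho_A * cA;
  // activation-rate partials
  mat sech2 = 1.0 - square(th);
  mat df_dd = 0.5 * blend * sech2;
  mat dmix_dd = (r_act - r_deact) % df_dd;
  mat dr_act_da = -1.5 / (tau_act * square(0.5 + 1.5 * am));
  mat dr_deact_da = (1.5 / tau_deact) * ones(N, nm);
  mat dmix_da = dr_act_da % (f_sw + 0.5) + dr_deact_da % (0.5 - f_sw) - dmix_dd;
  mat g_e = dmix_dd % d + mix;
  mat g_a = dmix_da % d - mix;

  mat eR_R(N, nm, fill::zeros);
  for (int j = 0; j < nj; ++j)
    eR_R += R.slice(j).each_col() % eR.col(j);

  mat G_am = 2.0 * h * w_a * am - h * (sA % g_a);
  mat sH;
  if (!rigid) {
    sH = lam_H + rho_H * cH;
    G_am += sH % (fact % fv % cosA);
  } else {
    G_am += 2.0 * h * w_r * (-1.0 / T_R) * (eR_R % rt_gain);
  }
  mat grad_a = 0.5 * (G_am + shift_up(G_am)) + (shift_up(sA) - sA);
  mat grad_e = -h * (sA % g_e);

  vec grad;
  if (!rigid) {
    mat G_lmm = sH % ((am % dfact % fv + dfpas) % cosA + fib % dcos -
                      dftn % dlt) +
      2.0 * h * w_r * (-1.0 / T_R) * (eR_R % f_max % dftn % dlt);
    mat G_vt = sH % ((am % fact % dfv + FIBER_DAMPING) % cosA) +
      2.0 * h * w_v * vt;
    mat grad_lm = 0.5 * (G_lmm + shift_up(G_lmm)) +
      (shift_up(G_vt) - G_vt) / (h * VEL_SCALE);
    grad = join_cols(vectorise(grad_a), vectorise(grad_lm), vectorise(grad_e));
  } else {
    grad = join_cols(vectorise(grad_a), vectorise(grad_e));
  }
  if (motor_joint >= 0) {
    vec grad_tau = -2.0 * h * w_r / T_R * eR.col(motor_joint);
    grad = join_cols(grad, grad_tau);
  }
  return Rcpp::List::create(Rcpp::Named("L") = L, Rcpp::Named("grad") = grad,
                            Rcpp::Named("J") = J);
}

// Persistent evaluation context: constants are copied once per solve,
// multipliers updated once per outer iteration, and the evaluation runs as
// fused scalar loops over a preallocated workspace.
struct AlCtx {
  int N, nm, nj;
  double h;
  bool rigid;
  mat l_mt, tau_id, tau_exo_fixed;
  cube R;
  mat f_max, l_opt, l_slk, k_t, p_scale, p_shift, height;
  double w_a, w_r, w_v, T_R;
  double tau_act, tau_deact, blend;
  int motor_joint;
  mat rt_gain, rt_offset, rt_vt;
  mat lam_H, lam_A;
  double rho_H, rho_A;
  // workspace
  mat am, vt, fib, cosA, cH, cA, sA, sH, g_e, g_a, eR, eR_R,
      G_am, G_lmm, G_vt, fact, dfact, fv, dfv, dfpas, dcos, dlt, dftn;
  vec grad;
};

static inline void fl_scalar(double lm, double& f, double& df) {
  f = 0.0; df = 0.0;
  for (int k = 0; k < 3; ++k) {
    double den = FL_B3[k] + FL_B4[k] * lm;
    double z = (lm - FL_B2[k]) / den;
    double g = FL_B1[k] * std::exp(-0.5 * z * z);
    f += g;
    double dz = (den - (lm - FL_B2[k]) * FL_B4[k]) / (den * den);
    df += g * (-z * dz);
  }
}

static inline void fv_scalar(double v, double& f, double& df) {
  double z = FV_D2 * v + FV_D3;
  double s = std::sqrt(z * z + 1.0);
  f = FV_D1 * std::log(z + s) + FV_D4;
  df = FV_D1 * FV_D2 / s;
}

// [[Rcpp::export]]
SEXP alctx_new(int N, int nm, int nj, double h, bool rigid,
               const arma::mat& l_mt, const arma::mat& tau_id,
               const arma::mat& tau_exo_fixed, const arma::cube& R,
               const arma::mat& f_max, const arma::mat& l_opt,
               const arma::mat& l_slk, const arma::mat& k_t,
               const arma::mat& p_scale, const arma::mat& p_shift,
               const arma::mat& height,
               double w_a, double w_r, double w_v, double T_R,
               double tau_act, double tau_deact, double blend,
               int motor_joint,
               const arma::mat& rt_gain, const arma::mat& rt_offset,
               const arma::mat& rt_vt) {
  AlCtx* c = new AlCtx;
  c->N = N; c->nm = nm; c->nj = nj; c->h = h; c->rigid = rigid;
  c->l_mt = l_mt; c->tau_id = tau_id; c->tau_exo_fixed = tau_exo_fixed;
  c->R = R; c->f_max = f_max; c->l_opt = l_opt; c->l_slk = l_slk;
  c->k_t = k_t; c->p_scale = p_scale; c->p_shift = p_shift;
  c->height = height;
  c->w_a = w_a; c->w_r = w_r; c->w_v = w_v; c->T_R = T_R;
  c->tau_act = tau_act; c->tau_deact = tau_deact; c->blend = blend;
  c->motor_joint = motor_joint;
  c->rt_gain = rt_gain; c->rt_offset = rt_offset; c->rt_vt = rt_vt;
  c->lam_H = mat(N, nm, fill::zeros);
  c->lam_A = mat(N, nm, fill::zeros);
  c->rho_H = 0.0; c->rho_A = 0.0;
  for (mat* w : {&c->am, &c->vt, &c->fib, &c->cosA, &c->cH, &c->cA, &c->sA,
                 &c->sH, &c->g_e, &c->g_a, &c->eR_R, &c->G_am, &c->G_lmm,
                 &c->G_vt, &c->fact, &c->dfact, &c->fv, &c->dfv, &c->dfpas,
                 &c->dcos, &c->dlt, &c->dftn})
    w->set_size(N, nm);
  c->eR.set_size(N, nj);
  int nvar = (rigid ? 2 : 3) * N * nm + (motor_joint >= 0 ? N : 0);
  c->grad.set_size(nvar);
  return Rcpp::XPtr<AlCtx>(c, true);
}

// [[Rcpp::export]]
void alctx_update(SEXP ptr, const arma::mat& lam_H, const arma::mat& lam_A,
                  double rho_H, double rho_A, double w_r) {
  Rcpp::XPtr<AlCtx> c(ptr);
  if (!c->rigid) c->lam_H = lam_H;
  c->lam_A = lam_A;
  c->rho_H = rho_H; c->rho_A = rho_A;
  c->w_r = w_r;
}

// Core evaluation: returns L, fills grad (if non-null) and J terms.
static double eval_core(AlCtx& c, const double* x_ptr, double* grad_out,
                        double* Jterms) {
  const int N = c.N, nm = c.nm, nj = c.nj;
  const double h = c.h;
  const int n_mat = N * nm;
  const double* a_p = x_ptr;
  const double* lm_p = c.rigid ? nullptr : a_p + n_mat;
  const double* e_p = a_p + (c.rigid ? 1 : 2) * n_mat;
  const double* tau_p = (c.motor_joint >= 0)
    ? a_p + (c.rigid ? 2 : 3) * n_mat : nullptr;

  const double pas_denom = std::expm1(PAS_KPE);
  const double pas_base = std::expm1(PAS_KPE * (LM_MIN - 1.0) / PAS_E0) / pas_denom;

  double J_a = 0.0, J_r = 0.0, J_v = 0.0, pen = 0.0;
  // pass A: midpoint quantities, forces, constraint residuals
  for (int m = 0; m < nm; ++m) {
    const double* a_c = a_p + m * N;
    const double* e_c = e_p + m * N;
    const double* lm_c = c.rigid ? nullptr : lm_p + m * N;
    for (int i = 0; i < N; ++i) {
      int inext = (i + 1 < N) ? i + 1 : 0;
      double am = 0.5 * (a_c[i] + a_c[inext]);
      c.am(i, m) = am;
      double Ft, vt;
      if (!c.rigid) {
        double lmm = 0.5 * (lm_c[i] + lm_c[inext]);
        vt = (lm_c[inext] - lm_c[i]) / (h * VEL_SCALE);
        double fl, dfl, fvv, dfv;
        fl_scalar(lmm, fl, dfl);
        fv_scalar(vt, fvv, dfv);
        double lsh = lmm - c.p_shift(i, m);
        double pexp = std::exp(PAS_KPE * (lsh - 1.0) / PAS_E0);
        double fpas = c.p_scale(i, m) * ((pexp - 1.0) / pas_denom - pas_base);
        double dfpas = c.p_scale(i, m) * (PAS_KPE / PAS_E0) * pexp / pas_denom;
        double lo = c.l_opt(i, m), hg = c.height(i, m), ls = c.l_slk(i, m);
        double lm_abs = lmm * lo;
        double along = std::sqrt(lm_abs * lm_abs - hg * hg);
        double cosA = along / lm_abs;
        double dcos = hg * hg / (lo * lo * lmm * lmm * lmm * cosA);
        double lt = (c.l_mt(i, m) - along) / ls;
        double dlt = -lo / (ls * cosA);
        double kt = c.k_t(i, m);
        double e1 = std::exp(kt * (lt - TEN_C2));
        double e0 = std::exp(kt * (1.0 - TEN_C2));
        double ftn = TEN_C1 * (e1 - e0);
        double dftn = TEN_C1 * kt * e1;
        double fib = am * fl * fvv + fpas + FIBER_DAMPING * vt;
        c.cH(i, m) = fib * cosA - ftn;
        Ft = c.f_max(i, m) * ftn;
        c.vt(i, m) = vt; c.fib(i, m) = fib; c.cosA(i, m) = cosA;
        c.fact(i, m) = fl; c.dfact(i, m) = dfl;
        c.fv(i, m) = fvv; c.dfv(i, m) = dfv;
        c.dfpas(i, m) = dfpas; c.dcos(i, m) = dcos;
        c.dlt(i, m) = dlt; c.dftn(i, m) = dftn;
      } else {
        vt = c.rt_vt(i, m);
        c.vt(i, m) = vt;
        Ft = c.rt_gain(i, m) * am + c.rt_offset(i, m);
      }
      c.fib(i, m) = c.rigid ? 0.0 : c.fib(i, m);
      c.G_vt(i, m) = Ft;  // reuse G_vt as temporary F_t storage
      // activation dynamics
      double d = e_c[i] - am;
      double th = std::tanh(c.blend * d);
      double f_sw = 0.5 * th;
      double r_act = 1.0 / (c.tau_act * (0.5 + 1.5 * am));
      double r_deact = (0.5 + 1.5 * am) / c.tau_deact;
      double mix = r_act * (f_sw + 0.5) + r_deact * (0.5 - f_sw);
      double g = mix * d;
      double cA = (a_c[inext] - a_c[i]) - h * g;
      c.cA(i, m) = cA;
      double sA = c.lam_A(i, m) + c.rho_A * cA;
      c.sA(i, m) = sA;
      pen += c.lam_A(i, m) * cA + 0.5 * c.rho_A * cA * cA;
      if (!c.rigid) {
        double cH = c.cH(i, m);
        pen += c.lam_H(i, m) * cH + 0.5 * c.rho_H * cH * cH;
        c.sH(i, m) = c.lam_H(i, m) + c.rho_H * cH;
      }
      J_a += am * am;
      J_v += vt * vt;
      if (grad_out) {
        double sech2 = 1.0 - th * th;
        double df_dd = 0.5 * c.blend * sech2;
        double dmix_dd = (r_act - r_deact) * df_dd;
        double dr_act_da = -1.5 / (c.tau_act * (0.5 + 1.5 * am) * (0.5 + 1.5 * am));
        double dmix_da = dr_act_da * (f_sw + 0.5) +
          (1.5 / c.tau_deact) * (0.5 - f_sw) - dmix_dd;
        c.g_e(i, m) = dmix_dd * d + mix;
        c.g_a(i, m) = dmix_da * d - mix;
      }
    }
  }
  // moment balance -> reserves
  for (int j = 0; j < nj; ++j) {
    const mat& Rj = c.R.slice(j);
    for (int i = 0; i < N; ++i) {
      double tm = 0.0;
      for (int m = 0; m < nm; ++m) tm += Rj(i, m) * c.G_vt(i, m);
      double exo = c.tau_exo_fixed(i, j);
      if (j == c.motor_joint) exo += tau_p[i];
      double eR = (c.tau_id(i, j) - tm - exo) / c.T_R;
      c.eR(i, j) = eR;
      J_r += eR * eR;
    }
  }
  J_a *= h * c.w_a; J_r *= h * c.w_r; J_v *= h * c.w_v;
  double J = J_a + J_r + J_v;
  double L = J + pen;
  if (Jterms) { Jterms[0] = J; Jterms[1] = J_a; Jterms[2] = J_r; Jterms[3] = J_v; }
  if (!grad_out) return L;

  // pass B: gradients
  for (int m = 0; m < nm; ++m)
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int j = 0; j < nj; ++j) s += c.R.slice(j)(i, m) * c.eR(i, j);
      c.eR_R(i, m) = s;
    }
  double* gp = grad_out;
  const double wrT = 2.0 * h * c.w_r * (-1.0 / c.T_R);
  for (int m = 0; m < nm; ++m) {
    for (int i = 0; i < N; ++i) {
      double G = 2.0 * h * c.w_a * c.am(i, m) - h * c.sA(i, m) * c.g_a(i, m);
      if (!c.rigid)
        G += c.sH(i, m) * (c.fact(i, m) * c.fv(i, m) * c.cosA(i, m));
      else
        G += wrT * c.eR_R(i, m) * c.rt_gain(i, m);
      c.G_am(i, m) = G;
      if (!c.rigid) {
        c.G_lmm(i, m) = c.sH(i, m) *
          ((c.am(i, m) * c.dfact(i, m) * c.fv(i, m) + c.dfpas(i, m)) * c.cosA(i, m) +
           c.fib(i, m) * c.dcos(i, m) - c.dftn(i, m) * c.dlt(i, m)) +
          wrT * c.eR_R(i, m) * c.f_max(i, m) * c.dftn(i, m) * c.dlt(i, m);
        c.G_vt(i, m) = c.sH(i, m) *
          ((c.am(i, m) * c.fact(i, m) * c.dfv(i, m) + FIBER_DAMPING) * c.cosA(i, m)) +
          2.0 * h * c.w_v * c.vt(i, m);
      }
    }
  }
  for (int m = 0; m < nm; ++m)
    for (int i = 0; i < N; ++i) {
      int iprev = (i > 0) ? i - 1 : N - 1;
      gp[m * N + i] = 0.5 * (c.G_am(i, m) + c.G_am(iprev, m)) +
        (c.sA(iprev, m) - c.sA(i, m));
    }
  int off = n_mat;
  if (!c.rigid) {
    for (int m = 0; m < nm; ++m)
      for (int i = 0; i < N; ++i) {
        int iprev = (i > 0) ? i - 1 : N - 1;
        gp[off + m * N + i] = 0.5 * (c.G_lmm(i, m) + c.G_lmm(iprev, m)) +
          (c.G_vt(iprev, m) - c.G_vt(i, m)) / (h * VEL_SCALE);
      }
    off += n_mat;
  }
  for (int m = 0; m < nm; ++m)
    for (int i = 0; i < N; ++i)
      gp[off + m * N + i] = -h * c.sA(i, m) * c.g_e(i, m);
  off += n_mat;
  if (c.motor_joint >= 0)
    for (int i = 0; i < N; ++i)
      gp[off + i] = (2.0 * h * c.w_r / c.T_R) * (-c.eR(i, c.motor_joint));
  return L;
}

// [[Rcpp::export]]
Rcpp::List aleval_ptr(SEXP ptr, const arma::vec& x, bool want_grad) {
  Rcpp::XPtr<AlCtx> cp(ptr);
  AlCtx& c = *cp;
  double Jt[4];
  if (!want_grad) {
    double L = eval_core(c, x.memptr(), nullptr, Jt);
    return Rcpp::List::create(Rcpp::Named("L") = L, Rcpp::Named("J") = Jt[0],
                              Rcpp::Named("J_a") = Jt[1],
                              Rcpp::Named("J_r") = Jt[2],
                              Rcpp::Named("J_v") = Jt[3]);
  }
  double L = eval_core(c, x.memptr(), c.grad.memptr(), Jt);
  return Rcpp::List::create(Rcpp::Named("L") = L,
                            Rcpp::Named("grad") = c.grad,
                            Rcpp::Named("J") = Jt[0]);
}

// Native bound-constrained inner solve: drives R'"'"'s L-BFGS-B
// implementation directly over the C++ objective, with the variable
// scaling applied inside (the optimizer works in z-space, x = z * scl).
#include <R_ext/Applic.h>

struct InnerEx {
  AlCtx* c;
  const double* scl;
  int n;
  std::vector<double> xbuf;
  std::vector<double> gbuf;
  std::vector<double> zlast;
  bool have_g;
};

static double inner_fn(int n, double* z, void* ex_) {
  InnerEx* ex = static_cast<InnerEx*>(ex_);
  for (int i = 0; i < n; ++i) ex->xbuf[i] = z[i] * ex->scl[i];
  double L = eval_core(*ex->c, ex->xbuf.data(), ex->gbuf.data(), nullptr);
  for (int i = 0; i < n; ++i) ex->gbuf[i] *= ex->scl[i];
  std::copy(z, z + n, ex->zlast.begin());
  ex->have_g = true;
  return L;
}

static void inner_gr(int n, double* z, double* g, void* ex_) {
  InnerEx* ex = static_cast<InnerEx*>(ex_);
  bool same = ex->have_g && std::equal(z, z + n, ex->zlast.begin());
  if (!same) inner_fn(n, z, ex_);
  std::copy(ex->gbuf.begin(), ex->gbuf.end(), g);
}

// [[Rcpp::export]]
Rcpp::List al_inner_solve(SEXP ptr, const arma::vec& x0,
                          const arma::vec& lower, const arma::vec& upper,
                          const arma::vec& scl, int maxit, double factr,
                          double pgtol, int lmm) {
  Rcpp::XPtr<AlCtx> cp(ptr);
  int n = x0.n_elem;
  std::vector<double> z(n), lo(n), hi(n);
  std::vector<int> nbd(n, 2);
  for (int i = 0; i < n; ++i) {
    z[i] = x0[i] / scl[i];
    lo[i] = lower[i] / scl[i];
    hi[i] = upper[i] / scl[i];
    if (z[i] < lo[i]) z[i] = lo[i];
    if (z[i] > hi[i]) z[i] = hi[i];
  }
  InnerEx ex;
  ex.c = cp.get(); ex.scl = scl.memptr(); ex.n = n;
  ex.xbuf.resize(n); ex.gbuf.resize(n); ex.zlast.resize(n);
  ex.have_g = false;
  double Fmin = 0.0;
  int fail = 0, fncount = 0, grcount = 0;
  char msg[128];
  lbfgsb(n, lmm, z.data(), lo.data(), hi.data(), nbd.data(), &Fmin,
         inner_fn, inner_gr, &fail, &ex, factr, pgtol, &fncount, &grcount,
         maxit, msg, 0, 1000000);
  arma::vec x_out(n);
  for (int i = 0; i < n; ++i) x_out[i] = z[i] * scl[i];
  return Rcpp::List::create(Rcpp::Named("par") = x_out,
                            Rcpp::Named("value") = Fmin,
                            Rcpp::Named("fncount") = fncount,
                            Rcpp::Named("fail") = fail,
                            Rcpp::Named("msg") = std::string(msg));
}
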