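// Joint PK + TAG marginal likelihood for the OLTT turnover model.
//
// Structural model (per subject, free-concentration scale):
//   drug:  1- or 2-compartment first-order absorption, closed form,
//          superposed over dosing events;
//   TAG:   depot A' = -ka_tag * A loaded at challenge time + tlag;
//          C' = r0*kout + (A/V_tag)*ka_tag*Inh(C_free) - kout*C,
//          Inh(c) = ic50 / (c + ic50).
// Because the TAG equation is linear given the inhibition input, each
// challenge contributes the convolution
//   (ka_tag * m / V_tag) * int_0^{t-L} exp(-kout (t-L-u)) exp(-ka_tag u)
//                                       * Inh(L+u) du,   L = t_chal + tlag,
// on top of the steady-state baseline r0. The integral is evaluated by
// composite Simpson quadrature on a fixed number of nodes in u, which is
// smooth in every parameter (the hard lag keeps its genuine kink where
// t crosses L). Random effects are log-normal; residual errors are
// proportional.
#include <TMB.hpp>

template <class Type>
Type posp(Type x) { return CppAD::CondExpGt(x, Type(0), x, Type(0)); }

// smooth positive part: w * log(1 + exp(x/w)); coincides with max(x, 0)
// away from |x| ~ w and keeps the objective differentiable in the lag.
// The exponent argument is clamped so the unselected branch can never
// overflow (an Inf there poisons reverse-mode derivatives).
template <class Type>
Type softpos(Type x, Type w) {
  Type z = CppAD::CondExpGt(x, w * Type(30), Type(30), x / w);
  return CppAD::CondExpGt(x, w * Type(30), x,
                          w * log(Type(1) + exp(z)));
}

template <class Type>
Type objective_function<Type>::operator()() {
  DATA_INTEGER(n_cmt);        // 1 or 2 PK compartments
  DATA_INTEGER(n_subj);
  DATA_INTEGER(n_quad);       // Simpson panels per challenge integral (even)
  DATA_SCALAR(lag_smooth);    // softplus width (h) of event-time onsets

  // observations, sorted by subject (0 = PK free conc, 1 = TAG)
  DATA_IVECTOR(obs_start);    // per subject, 0-based offsets
  DATA_IVECTOR(obs_len);
  DATA_IVECTOR(obs_type);
  DATA_VECTOR(obs_time);
  DATA_VECTOR(obs_y);

  // dosing events (amounts already in umol, per kg for rodent templates)
  DATA_IVECTOR(dose_start);
  DATA_IVECTOR(dose_len);
  DATA_VECTOR(dose_time);
  DATA_VECTOR(dose_umol);

  // lipid challenges (mg TAG per subject); a challenge flagged drug-free
  // (placebo subjects, or meals completed well before the first dose) uses
  // the analytic double-exponential solution instead of quadrature
  DATA_IVECTOR(chal_start);
  DATA_IVECTOR(chal_len);
  DATA_VECTOR(chal_time);
  DATA_VECTOR(chal_mg);
  DATA_IVECTOR(chal_drugfree);

  // covariates, as ratios to reference
  DATA_VECTOR(bw_frac);
  DATA_VECTOR(bmi_frac);

  DATA_IVECTOR(eta_par);      // structural slot index modified by each eta

  // slots: 0 ka, 1 v, 2 cl, 3 v2, 4 cl2, 5 r0, 6 kout, 7 ka_tag,
  //        8 v_tag, 9 tlag_tag, 10 ic50
  PARAMETER_VECTOR(logtheta);
  PARAMETER(theta_bmi);
  PARAMETER(theta_allo_cl);
  PARAMETER(theta_allo_v);
  PARAMETER_VECTOR(log_omega);
  PARAMETER(log_sig_pk);
  PARAMETER(log_sig_tag);
  PARAMETER_MATRIX(eta);      // n_subj x n_eta

  int n_eta = eta_par.size();
  Type sig_pk = exp(log_sig_pk);
  Type sig_tag = exp(log_sig_tag);
  Type nll = Type(0);

  for (int j = 0; j < n_eta; j++) {
    Type om = exp(log_omega(j));
    for (int i = 0; i < n_subj; i++)
      nll -= dnorm(eta(i, j), Type(0), om, true);
  }

  int n_obs = obs_y.size();
  vector<Type> pred(n_obs);
  pred.setZero();

  for (int i = 0; i < n_subj; i++) {
    vector<Type> th(11);
    for (int s = 0; s < 11; s++) th(s) = exp(logtheta(s));
    th(1) *= pow(bw_frac(i), theta_allo_v);
    th(2) *= pow(bw_frac(i), theta_allo_cl);
    th(5) *= pow(bmi_frac(i), theta_bmi);
    for (int j = 0; j < n_eta; j++) th(eta_par(j)) *= exp(eta(i, j));
    Type ka = th(0), V = th(1), Cl = th(2), V2 = th(3), Cl2 = th(4);
    Type r0 = th(5), kout = th(6), katag = th(7), vtag = th(8);
    Type tlag = th(9), ic50 = th(10);

    // macro constants of the disposition model
    Type k10 = Cl / V;
    Type al = k10, be = k10, ca = Type(0), cb = Type(0), ck = Type(0);
    if (n_cmt == 2) {
      Type k12 = Cl2 / V, k21 = Cl2 / V2;
      Type sum = k10 + k12 + k21;
      Type disc = sqrt(sum * sum - Type(4) * k10 * k21);
      al = (sum + disc) / Type(2);
      be = (sum - disc) / Type(2);
      ca = (k21 - al) / ((ka - al) * (be - al));
      cb = (k21 - be) / ((ka - be) * (al - be));
      ck = (k21 - ka) / ((al - ka) * (be - ka));
    }

    int d0 = dose_start(i), dl = dose_len(i);
    // free concentration at time t (zero before dosing)
    auto conc = [&](Type t) -> Type {
      Type c = Type(0);
      for (int d = 0; d < dl; d++) {
        Type tau = softpos(t - dose_time(d0 + d), lag_smooth);
        Type D = dose_umol(d0 + d);
        Type u;
        if (n_cmt == 1) {
          u = ka / (V * (ka - k10)) * (exp(-k10 * tau) - exp(-ka * tau));
        } else {
          u = ka / V * (ca * exp(-al * tau) + cb * exp(-be * tau) +
                        ck * exp(-ka * tau));
        }
        c += D * u;
      }
      return c;
    };

    int c0i = chal_start(i), cli = chal_len(i);
    // plasma TAG at time t: baseline plus one convolution per challenge
    auto c_tag_at = [&](Type t) -> Type {
      Type C = r0;
      for (int c = 0; c < cli; c++) {
        // a positive lag makes the contribution identically zero at or
        // before the challenge time (data-level skip)
        if (asDouble(t) <= asDouble(chal_time(c0i + c)) + 1e-12) continue;
        Type L = chal_time(c0i + c) + tlag;
        Type m = chal_mg(c0i + c);
        Type tau = softpos(t - L, lag_smooth);
        if (chal_drugfree(c0i + c)) {
          // Inh == 1: exact convolution of the two exponentials
          Type mu = kout - katag;
          Type x = mu * tau;
          Type e0 = exp(-kout * tau);
          Type exact = (exp(-katag * tau) - e0) / mu;
          Type ser = tau * e0 * (Type(1) + x / Type(2) + x * x / Type(6) +
                                 x * x * x / Type(24));
          Type J = CppAD::CondExpGt(fabs(x), Type(1e-3), exact, ser);
          C += (katag * m / vtag) * J;
        } else {
          Type du = tau / Type(n_quad);
          Type s = Type(0);
          for (int k = 0; k <= n_quad; k++) {
            Type w = (k == 0 || k == n_quad) ? Type(1)
                     : (k % 2 == 1 ? Type(4) : Type(2));
            Type u = du * Type(k);
            Type inh = ic50 / (conc(L + u) + ic50);
            s += w * exp(-kout * (tau - u) - katag * u) * inh;
          }
          C += (katag * m / vtag) * s * du / Type(3);
        }
      }
      return C;
    };

    int o0 = obs_start(i), ol = obs_len(i);
    for (int o = 0; o < ol; o++) {
      Type f;
      if (obs_type(o0 + o) == 0) {
        f = conc(obs_time(o0 + o));
        nll -= dnorm(obs_y(o0 + o), f, sig_pk * f, true);
      } else {
        f = c_tag_at(obs_time(o0 + o));
        nll -= dnorm(obs_y(o0 + o), f, sig_tag * f, true);
      }
      pred(o0 + o) = f;
    }
  }

  REPORT(pred);
  return nll;
}
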