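#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Generative observer engine.
//
// z: n x 18 matrix of standard-normal draws; for event j (0..2) columns
//    6*j + {0..5} hold (sA, tA, iA, sV, tV, iV). The same draws are reused
//    across parameter values (common random numbers) so the Monte-Carlo
//    fit objective is deterministic.
// distal: 3 x 6 matrix, columns (S_A, T_A, I_A, S_V, T_V, I_V).
// params: the 11 observer parameters in canonical order
//    (p_common, sigma_S_P, sigma_T_P, sigma_I_P, sigma_sA, sigma_tA,
//     sigma_iA, sigma_sV, sigma_tV, sigma_iV, phi_I).
// variant: 0 = BCI, 1 = BCI_NP (causal evidence from pairs 1-2 only),
//          2 = FF (p_c1 = 1), 3 = FS (p_c1 = 0).
// visual_only: unisensory (0-beep) condition; segregation path only.

static const double LOG2PI = 1.8378770664093454836;

struct Obs {
  double pc, phi;
  double a_s2, a_t2, a_i2, vv_s2, vv_t2, vv_i2;
  double p_s2, p_t2, p_i2;
  double wsA, wsV, wsP, wiA, wiV, wiP;
  // per cue dimension (0 = space, 1 = time, 2 = intensity):
  // log-ratio constant and quadratic-form coefficients of
  // log p(.|C=1) - log p(.|C=2) for centred cues
  double dconst[3];           // c1 const - c2 const
  double q1_diff[3], q1_v[3], q1_a[3];   // C1: (v-a)^2, v^2, a^2 / D
  double q2_v[3], q2_a[3];               // C2: v^2/(vv+vp), a^2/(va+vp)
  int variant;
};

static void cue_constants(Obs& o, int c, double va, double vv, double vp) {
  double D = vv * va + vv * vp + va * vp;
  double mv = vv + vp, ma = va + vp;
  o.dconst[c] = -0.5 * std::log(D) + 0.5 * std::log(mv * ma);
  o.q1_diff[c] = vp / D; o.q1_v[c] = va / D; o.q1_a[c] = vv / D;
  o.q2_v[c] = 1.0 / mv; o.q2_a[c] = 1.0 / ma;
}

static Obs make_obs(const NumericVector& par) {
  Obs o;
  o.pc = par[0]; o.phi = par[10];
  double sp_s = par[1], sp_t = par[2], sp_i = par[3];
  double sa_s = par[4], sa_t = par[5], sa_i = par[6];
  double sv_s = par[7], sv_t = par[8], sv_i = par[9];
  o.a_s2 = sa_s * sa_s; o.a_t2 = sa_t * sa_t; o.a_i2 = sa_i * sa_i;
  o.vv_s2 = sv_s * sv_s; o.vv_t2 = sv_t * sv_t; o.vv_i2 = sv_i * sv_i;
  o.p_s2 = sp_s * sp_s; o.p_t2 = sp_t * sp_t; o.p_i2 = sp_i * sp_i;
  o.wsA = 1.0 / o.a_s2; o.wsV = 1.0 / o.vv_s2; o.wsP = 1.0 / o.p_s2;
  o.wiA = 1.0 / o.a_i2; o.wiV = 1.0 / o.vv_i2; o.wiP = 1.0 / o.p_i2;
  cue_constants(o, 0, o.a_s2, o.vv_s2, o.p_s2);
  cue_constants(o, 1, o.a_t2, o.vv_t2, o.p_t2);
  cue_constants(o, 2, o.a_i2, o.vv_i2, o.p_i2);
  return o;
}

// log p(a,v|C=1) - log p(a,v|C=2) for one centred cue pair
static inline double log_lr_pair(const Obs& o, int c, double a, double v) {
  double d = v - a;
  double q1 = d * d * o.q1_diff[c] + v * v * o.q1_v[c] + a * a * o.q1_a[c];
  double q2 = v * v * o.q2_v[c] + a * a * o.q2_a[c];
  return o.dconst[c] - 0.5 * (q1 - q2);
}

// simulate one condition; fills counts (3 x 6, column-major as R matrix)
// and optionally per-trial outcomes (n x 3, bins 1..6)
// align a trial's raw event outcomes the way observed press sequences are
// aligned to events: the ordered presses (non-absent bins) map to events
// (1,2,3) / (1,3) / (1) depending on their number
static inline void align_outcomes(const int raw[3], int aligned[3]) {
  int presses[3], np = 0;
  for (int j = 0; j < 3; ++j) if (raw[j] < 6) presses[np++] = raw[j];
  aligned[0] = aligned[1] = aligned[2] = 6;
  if (np == 3) { aligned[0] = presses[0]; aligned[1] = presses[1];
                 aligned[2] = presses[2]; }
  else if (np == 2) { aligned[0] = presses[0]; aligned[2] = presses[1]; }
  else if (np == 1) { aligned[0] = presses[0]; }
}

static void run_condition(const NumericMatrix& z, const NumericMatrix& distal,
                          const NumericVector& par,
                          const NumericVector& muT,
                          const NumericVector& muIV,
                          const NumericVector& muIA,
                          const NumericVector& buttons,
                          int variant, bool visual_only, bool align,
                          NumericMatrix* counts, IntegerMatrix* outcomes) {
  Obs o = make_obs(par);
  o.variant = variant;
  int n = z.nrow();
  int nb = buttons.size();
  double sa_s = std::sqrt(o.a_s2), sa_t = std::sqrt(o.a_t2),
         sa_i = std::sqrt(o.a_i2);
  double sv_s = std::sqrt(o.vv_s2), sv_t = std::sqrt(o.vv_t2),
         sv_i = std::sqrt(o.vv_i2);

  double log_prior_odds = 0.0;
  bool w_fixed = false; double w_fix = 0.0;
  if (visual_only) { w_fixed = true; w_fix = 0.0; }
  else if (variant == 2 || o.pc >= 1.0) { w_fixed = true; w_fix = 1.0; }
  else if (variant == 3 || o.pc <= 0.0) { w_fixed = true; w_fix = 0.0; }
  else log_prior_odds = std::log(o.pc) - std::log1p(-o.pc);

  int npairs = (variant == 1) ? 2 : 3;

  for (int i = 0; i < n; ++i) {
    double sA[3], tA[3], iA[3], sV[3], tV[3], iV[3];
    for (int j = 0; j < 3; ++j) {
      int b = 6 * j;
      sA[j] = distal(j, 0) + sa_s * z(i, b + 0);
      tA[j] = distal(j, 1) + sa_t * z(i, b + 1);
      iA[j] = distal(j, 2) + sa_i * z(i, b + 2);
      sV[j] = distal(j, 3) + sv_s * z(i, b + 3);
      tV[j] = distal(j, 4) + sv_t * z(i, b + 4);
      iV[j] = distal(j, 5) + sv_i * z(i, b + 5);
    }
    double w;
    if (w_fixed) {
      w = w_fix;
    } else {
      double lr = 0.0;
      for (int j = 0; j < npairs; ++j) {
        // spatial (prior mean 0); temporal centred on the event's prior
        // mean; intensity centred on modality-specific prior means
        lr += log_lr_pair(o, 0, sA[j], sV[j]);
        lr += log_lr_pair(o, 1, tA[j] - muT[j], tV[j] - muT[j]);
        lr += log_lr_pair(o, 2, iA[j] - muIA[j], iV[j] - muIV[j]);
      }
      double lo = log_prior_odds + lr;
      w = 1.0 / (1.0 + std::exp(-lo));
    }
    int raw[3];
    for (int j = 0; j < 3; ++j) {
      double segS = (sV[j] * o.wsV) / (o.wsV + o.wsP);
      double segI = (iV[j] * o.wiV + muIV[j] * o.wiP) / (o.wiV + o.wiP);
      double S, I;
      if (visual_only) {
        S = segS; I = segI;
      } else {
        double fusS = (sV[j] * o.wsV + sA[j] * o.wsA) /
                      (o.wsV + o.wsA + o.wsP);
        double fusI = (iV[j] * o.wiV + iA[j] * o.wiA + muIV[j] * o.wiP) /
                      (o.wiV + o.wiA + o.wiP);
        S = w * fusS + (1.0 - w) * segS;
        I = w * fusI + (1.0 - w) * segI;
      }
      int bin;
      if (I <= o.phi) {
        bin = 5;                       // sixth bin: no flash perceived
      } else {
        bin = 0;
        double best = std::fabs(S - buttons[0]);
        for (int k = 1; k < nb; ++k) {
          double d = std::fabs(S - buttons[k]);
          if (d < best) { best = d; bin = k; }  // ties -> lower index
        }
      }
      raw[j] = bin + 1;
      if (outcomes) (*outcomes)(i, j) = bin + 1;
    }
    if (counts) {
      int use[3];
      if (align) align_outcomes(raw, use);
      else { use[0] = raw[0]; use[1] = raw[1]; use[2] = raw[2]; }
      for (int j = 0; j < 3; ++j) (*counts)(j, use[j] - 1) += 1.0;
    }
  }
}

// [[Rcpp::export(name = ".engine_condition")]]
SEXP engine_condition(NumericMatrix z, NumericMatrix distal,
                      NumericVector params, NumericVector muT,
                      NumericVector muIV, NumericVector muIA,
                      NumericVector buttons, int variant, bool visual_only,
                      bool return_outcomes, bool align) {
  if (return_outcomes) {
    IntegerMatrix outc(z.nrow(), 3);
    run_condition(z, distal, params, muT, muIV, muIA, buttons, variant,
                  visual_only, align, nullptr, &outc);
    return outc;
  }
  NumericMatrix counts(3, 6);
  run_condition(z, distal, params, muT, muIV, muIA, buttons, variant,
                visual_only, align, &counts, nullptr);
  return counts;
}

// Multinomial log likelihood of observed outcome counts across conditions.
// z_list / distal_list / obs_list are parallel lists over conditions;
// obs_list entries are 3 x 6 observed outcome-count matrices.
// Predicted bin probabilities are pseudocount-floored:
// (count + pseudocount) / (n + 6 * pseudocount).
// [[Rcpp::export(name = ".engine_loglik")]]
double engine_loglik(List z_list, List distal_list, List obs_list,
                     LogicalVector visual_only, NumericVector params,
                     NumericVector muT, NumericVector muIV,
                     NumericVector muIA, NumericVector buttons,
                     int variant, double pseudocount) {
  int ncond = z_list.size();
  double ll = 0.0;
  for (int c = 0; c < ncond; ++c) {
    NumericMatrix z = z_list[c];
    NumericMatrix distal = distal_list[c];
    NumericMatrix obs = obs_list[c];
    NumericMatrix counts(3, 6);
    run_condition(z, distal, params, muT, muIV, muIA, buttons, variant,
                  visual_only[c], true, &counts, nullptr);
    double denom = z.nrow() + 6.0 * pseudocount;
    for (int j = 0; j < 3; ++j) {
      for (int b = 0; b < 6; ++b) {
        double oc = obs(j, b);
        if (oc > 0.0) {
          double p = (counts(j, b) + pseudocount) / denom;
          ll += oc * std::log(p);
        }
      }
    }
  }
  return ll;
}
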