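// Fast mirror of the R reference dynamics (R/dynamics.R): full coupled
// right-hand side of the planar 7-link body, 18 Hill muscles, MLR, CPG
// and motoneurons, with fixed-step RK4 and stick ground contact.
// Tested against the R composition to tight tolerance.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const int NQ = 9;
static const int NSTATE = 45;

struct Model {
  // segments
  double m_hat, I_hat, c_hat;
  double m_th, L_th, c_th, I_th;
  double m_sh, L_sh, c_sh, I_sh;
  double m_ft, I_ft;
  double h_ank, a_heel, b_toe, cfx, cfy;
  double b_hip, b_knee, b_ank;
  double knee_lo, knee_hi, knee_k, knee_c;
  double ank_lo, ank_hi, ank_k, ank_c;
  double kx, cx, ky, cy;
  double grav, M_tot;
  // muscles (9 per leg)
  double fmax[9], lopt[9], vmax[9], cpd[9], kpe[9];
  double rhip[9], rknee[9], rankle[9];
  double met_c0, met_c1, met_c2;
  // mlr
  double tau_ppn, tau_cnf, w_ppn_cnf, w_cnf_ppn, beta_ppn, beta_cnf,
         w_hc, switch_time, post_switch;
  // cpg
  double cpg_tau, cpg_taup, cpg_beta;
  // motoneuron
  double mn_gain, mn_floor, wp, ws, wt;
  // posture refs
  double hat_ref, hip_ref, knee_ref, ankle_ref;
  // controller parameters
  double u0, wfeed[16], Wcpg[12][12], wpos[23];
  double Wa[18][12];
};

static Model parse_model(const List& config, const NumericVector& theta) {
  Model md;
  List body = config["body"];
  List seg = body["segments"];
  List hat = seg["hat"], th = seg["thigh"], sh = seg["shank"], ft = seg["foot"];
  md.m_hat = as<double>(hat["mass"]); md.I_hat = as<double>(hat["inertia"]);
  md.c_hat = as<double>(hat["com"]);
  md.m_th = as<double>(th["mass"]); md.L_th = as<double>(th["length"]);
  md.c_th = as<double>(th["com"]); md.I_th = as<double>(th["inertia"]);
  md.m_sh = as<double>(sh["mass"]); md.L_sh = as<double>(sh["length"]);
  md.c_sh = as<double>(sh["com"]); md.I_sh = as<double>(sh["inertia"]);
  md.m_ft = as<double>(ft["mass"]); md.I_ft = as<double>(ft["inertia"]);
  List fg = body["foot_geom"];
  md.h_ank = as<double>(fg["ankle_height"]);
  md.a_heel = as<double>(fg["heel_back"]);
  md.b_toe = as<double>(fg["toe_front"]);
  md.cfx = as<double>(fg["com_x"]); md.cfy = as<double>(fg["com_y"]);
  NumericVector bv = body["joint_viscosity"];
  md.b_hip = bv[0]; md.b_knee = bv[1]; md.b_ank = bv[2];
  List jl = body["joint_limits"];
  List kl = jl["knee"], al = jl["ankle"];
  NumericVector kr = kl["range"], ar = al["range"];
  md.knee_lo = kr[0]; md.knee_hi = kr[1];
  md.knee_k = as<double>(kl["stiffness"]); md.knee_c = as<double>(kl["damping"]);
  md.ank_lo = ar[0]; md.ank_hi = ar[1];
  md.ank_k = as<double>(al["stiffness"]); md.ank_c = as<double>(al["damping"]);
  List cc = body["contact"];
  md.kx = as<double>(cc["kx"]); md.cx = as<double>(cc["cx"]);
  md.ky = as<double>(cc["ky"]); md.cy = as<double>(cc["cy"]);
  md.grav = as<double>(body["gravity"]);
  md.M_tot = as<double>(body["total_mass"]);

  DataFrame mt = as<DataFrame>(config["muscles"]);
  NumericVector fmax = mt["f_max"], lopt = mt["l_opt"], vmax = mt["v_max"],
    cpd = mt["c_pd"], kpe = mt["k_pe"], rh = mt["r_hip"], rk = mt["r_knee"],
    ra = mt["r_ankle"];
  for (int i = 0; i < 9; i++) {
    md.fmax[i] = fmax[i]; md.lopt[i] = lopt[i]; md.vmax[i] = vmax[i];
    md.cpd[i] = cpd[i]; md.kpe[i] = kpe[i];
    md.rhip[i] = rh[i]; md.rknee[i] = rk[i]; md.rankle[i] = ra[i];
  }
  List met = config["metabolic"];
  md.met_c0 = as<double>(met["c0"]); md.met_c1 = as<double>(met["c1"]);
  md.met_c2 = as<double>(met["c2"]);

  List mlr = config["mlr"];
  md.tau_ppn = as<double>(mlr["tau_ppn"]); md.tau_cnf = as<double>(mlr["tau_cnf"]);
  md.w_ppn_cnf = as<double>(mlr["w_ppn_cnf"]);
  md.w_cnf_ppn = as<double>(mlr["w_cnf_ppn"]);
  md.beta_ppn = as<double>(mlr["beta_ppn"]); md.beta_cnf = as<double>(mlr["beta_cnf"]);
  md.w_hc = as<double>(mlr["w_hc"]);
  md.switch_time = as<double>(mlr["switch_time"]);
  md.post_switch = as<double>(mlr["post_switch"]);

  List cpg = config["cpg"];
  md.cpg_tau = as<double>(cpg["tau"]); md.cpg_taup = as<double>(cpg["tau_prime"]);
  md.cpg_beta = as<double>(cpg["beta"]);

  List mn = config["motoneuron"];
  md.mn_gain = as<double>(mn["gain"]); md.mn_floor = as<double>(mn["u_ppn_floor"]);
  md.wp = as<double>(mn["w_primary"]); md.ws = as<double>(mn["w_secondary"]);
  md.wt = as<double>(mn["w_tertiary"]);

  List ps = config["posture"];
  md.hat_ref = as<double>(ps["hat_ref"]); md.hip_ref = as<double>(ps["hip_ref"]);
  md.knee_ref = as<double>(ps["knee_ref"]);
  md.ankle_ref = as<double>(ps["ankle_ref"]);

  // free parameters: u0 | feed(16) | cpg gains(9) | pos(23)
  if (theta.size() != 49) stop("expected 49 free parameters");
  md.u0 = theta[0];
  for (int i = 0; i < 16; i++) md.wfeed[i] = theta[1 + i];
  double g9[9];
  for (int i = 0; i < 9; i++) g9[i] = theta[17 + i];
  std::memset(md.Wcpg, 0, sizeof(md.Wcpg));
  for (int off = 0; off <= 6; off += 6) {
    int hf = off, he = off + 1, kf = off + 2, ke = off + 3,
        af = off + 4, ae = off + 5;
    md.Wcpg[hf][he] = md.Wcpg[he][hf] = -g9[0];
    md.Wcpg[kf][ke] = md.Wcpg[ke][kf] = -g9[1];
    md.Wcpg[af][ae] = md.Wcpg[ae][af] = -g9[2];
    md.Wcpg[ke][hf] = -g9[3];
    md.Wcpg[kf][he] = -g9[4];
    md.Wcpg[ae][hf] = -g9[5];
    md.Wcpg[af][he] = -g9[6];
  }
  md.Wcpg[0][6] = md.Wcpg[6][0] = md.Wcpg[1][7] = md.Wcpg[7][1] = -g9[7];
  md.Wcpg[2][8] = md.Wcpg[8][2] = md.Wcpg[3][9] = md.Wcpg[9][3] = -g9[8];
  for (int i = 0; i < 23; i++) md.wpos[i] = theta[26 + i];

  std::memset(md.Wa, 0, sizeof(md.Wa));
  for (int s = 0; s < 2; s++) {
    int mo = 9 * s, co = 6 * s;
    int hf = co, he = co + 1, kf = co + 2, ke = co + 3, af = co + 4,
        ae = co + 5;
    md.Wa[mo + 0][he] = -md.wp;
    md.Wa[mo + 1][hf] = -md.wp;
    md.Wa[mo + 2][he] = -md.ws; md.Wa[mo + 2][kf] = -md.wt;
    md.Wa[mo + 3][hf] = -md.ws; md.Wa[mo + 3][ke] = -md.wt;
    md.Wa[mo + 4][kf] = -md.wp;
    md.Wa[mo + 5][ke] = -md.wp;
    md.Wa[mo + 6][ae] = -md.ws; md.Wa[mo + 6][kf] = -md.wt;
    md.Wa[mo + 7][ae] = -md.wp;
    md.Wa[mo + 8][af] = -md.wp;
  }
  return md;
}

struct Contact {
  double ax[4];   // anchors: heel_l, toe_l, heel_r, toe_r
  bool active[4];
};

// 9x9 symmetric positive-definite solve via Cholesky
static bool chol_solve(double A[NQ][NQ], const double* b, double* x) {
  double L[NQ][NQ];
  for (int i = 0; i < NQ; i++)
    for (int j = 0; j <= i; j++) {
      double s = A[i][j];
      for (int k = 0; k < j; k++) s -= L[i][k] * L[j][k];
      if (i == j) {
        if (s <= 0) return false;
        L[i][i] = std::sqrt(s);
      } else L[i][j] = s / L[j][j];
    }
  double y[NQ];
  for (int i = 0; i < NQ; i++) {
    double s = b[i];
    for (int k = 0; k < i; k++) s -= L[i][k] * y[k];
    y[i] = s / L[i][i];
  }
  for (int i = NQ - 1; i >= 0; i--) {
    double s = y[i];
    for (int k = i + 1; k < NQ; k++) s -= L[k][i] * x[k];
    x[i] = s / L[i][i];
  }
  return true;
}

struct RhsOut {
  double d[NSTATE];
  double grf[2];
  double alpha[18];
  double tension[18];
  double torques[6];
  bool ok;
};

static void rhs(const Model& md, double t, const double* x,
                double s_ppn, double s_cnf, const Contact& ct, RhsOut& out) {
  const double* q = x;
  const double* qd = x + 9;
  double u_ppn = x[18], u_cnf = x[19];
  const double* ucpg = x + 20;
  const double* vcpg = x + 32;

  // ---- kinematics -------------------------------------------------------
  // body list: 0 hat, then per side (L=0,R=1): thigh, shank, foot
  // J stored dense 2x9 per body; angle index per body
  double J[7][2][NQ], bias[7][2], mass[7], inert[7];
  int iang[7];
  double posy[7];
  std::memset(J, 0, sizeof(J));
  double X = q[0], Y = q[1], hat = q[2];
  double sh_hat = std::sin(hat), ch_hat = std::cos(hat);
  // hat
  mass[0] = md.m_hat; inert[0] = md.I_hat; iang[0] = 2;
  J[0][0][0] = 1; J[0][1][1] = 1;
  J[0][0][2] = md.c_hat * (-ch_hat); J[0][1][2] = md.c_hat * (-sh_hat);
  bias[0][0] = -md.c_hat * (-sh_hat) * qd[2] * qd[2];
  bias[0][1] = -md.c_hat * (ch_hat) * qd[2] * qd[2];
  posy[0] = Y + md.c_hat * ch_hat;

  double heel[2][2], toe[2][2], heelv[2][2], toev[2][2];
  double Jheel[2][NQ][2], Jtoe[2][NQ][2];  // [side][coord][xy]
  std::memset(Jheel, 0, sizeof(Jheel));
  std::memset(Jtoe, 0, sizeof(Jtoe));
  double shank_ang[2];

  for (int s = 0; s < 2; s++) {
    int it = 3 + 3 * s, isH = 4 + 3 * s, ifo = 5 + 3 * s;
    double tht = q[it], ths = q[isH], thf = q[ifo];
    shank_ang[s] = ths;
    double et[2] = {std::sin(tht), -std::cos(tht)};
    double ept[2] = {std::cos(tht), std::sin(tht)};
    double es[2] = {std::sin(ths), -std::cos(ths)};
    double eps_[2] = {std::cos(ths), std::sin(ths)};
    double cf_ = std::cos(thf), sf = std::sin(thf);
    int bt = 1 + 3 * s, bs = 2 + 3 * s, bf = 3 + 3 * s;
    mass[bt] = md.m_th; inert[bt] = md.I_th; iang[bt] = it;
    mass[bs] = md.m_sh; inert[bs] = md.I_sh; iang[bs] = isH;
    mass[bf] = md.m_ft; inert[bf] = md.I_ft; iang[bf] = ifo;
    // thigh com
    J[bt][0][0] = 1; J[bt][1][1] = 1;
    J[bt][0][it] = md.c_th * ept[0]; J[bt][1][it] = md.c_th * ept[1];
    bias[bt][0] = -md.c_th * et[0] * qd[it] * qd[it];
    bias[bt][1] = -md.c_th * et[1] * qd[it] * qd[it];
    posy[bt] = Y + md.c_th * et[1];
    // shank com
    J[bs][0][0] = 1; J[bs][1][1] = 1;
    J[bs][0][it] = md.L_th * ept[0]; J[bs][1][it] = md.L_th * ept[1];
    J[bs][0][isH] = md.c_sh * eps_[0]; J[bs][1][isH] = md.c_sh * eps_[1];
    bias[bs][0] = -md.L_th * et[0] * qd[it] * qd[it]
                  - md.c_sh * es[0] * qd[isH] * qd[isH];
    bias[bs][1] = -md.L_th * et[1] * qd[it] * qd[it]
                  - md.c_sh * es[1] * qd[isH] * qd[isH];
    posy[bs] = Y + md.L_th * et[1] + md.c_sh * es[1];
    // foot com: local (cfx, -cfy)
    double lx = md.cfx, ly = -md.cfy;
    double rx = cf_ * lx - sf * ly, ry = sf * lx + cf_ * ly;
    double rpx = -sf * lx - cf_ * ly, rpy = cf_ * lx - sf * ly;
    J[bf][0][0] = 1; J[bf][1][1] = 1;
    J[bf][0][it] = md.L_th * ept[0]; J[bf][1][it] = md.L_th * ept[1];
    J[bf][0][isH] = md.L_sh * eps_[0]; J[bf][1][isH] = md.L_sh * eps_[1];
    J[bf][0][ifo] = rpx; J[bf][1][ifo] = rpy;
    bias[bf][0] = -md.L_th * et[0] * qd[it] * qd[it]
                  - md.L_sh * es[0] * qd[isH] * qd[isH]
                  - rx * qd[ifo] * qd[ifo];
    bias[bf][1] = -md.L_th * et[1] * qd[it] * qd[it]
                  - md.L_sh * es[1] * qd[isH] * qd[isH]
                  - ry * qd[ifo] * qd[ifo];
    posy[bf] = Y + md.L_th * et[1] + md.L_sh * es[1] + ry;
    // ankle and contact points
    double ank[2] = {X + md.L_th * et[0] + md.L_sh * es[0],
                     Y + md.L_th * et[1] + md.L_sh * es[1]};
    double locs[2][2] = {{-md.a_heel, -md.h_ank}, {md.b_toe, -md.h_ank}};
    for (int pt = 0; pt < 2; pt++) {
      double px = locs[pt][0], py = locs[pt][1];
      double rx2 = cf_ * px - sf * py, ry2 = sf * px + cf_ * py;
      double rpx2 = -sf * px - cf_ * py, rpy2 = cf_ * px - sf * py;
      double (*Jp)[2] = pt == 0 ? Jheel[s] : Jtoe[s];
      Jp[0][0] = 1; Jp[1][1] = 1;
      Jp[it][0] = md.L_th * ept[0]; Jp[it][1] = md.L_th * ept[1];
      Jp[isH][0] = md.L_sh * eps_[0]; Jp[isH][1] = md.L_sh * eps_[1];
      Jp[ifo][0] = rpx2; Jp[ifo][1] = rpy2;
      double px2 = ank[0] + rx2, py2 = ank[1] + ry2;
      double vx = 0, vy = 0;
      for (int k = 0; k < NQ; k++) { vx += Jp[k][0] * qd[k]; vy += Jp[k][1] * qd[k]; }
      if (pt == 0) { heel[s][0] = px2; heel[s][1] = py2;
                     heelv[s][0] = vx; heelv[s][1] = vy; }
      else { toe[s][0] = px2; toe[s][1] = py2; toev[s][0] = vx; toev[s][1] = vy; }
    }
  }

  // ---- contact forces ---------------------------------------------------
  double cfrc[4][2];
  double grf[2] = {0, 0};
  for (int i = 0; i < 4; i++) {
    int s = i / 2, pt = i % 2;
    const double* p = pt == 0 ? heel[s] : toe[s];
    const double* v = pt == 0 ? heelv[s] : toev[s];
    cfrc[i][0] = cfrc[i][1] = 0;
    if (p[1] < 0) {
      double fy = md.ky * (-p[1]) - md.cy * v[1];
      if (fy > 0) {
        double ax = ct.active[i] ? ct.ax[i] : p[0];
        cfrc[i][0] = md.kx * (ax - p[0]) - md.cx * v[0];
        cfrc[i][1] = fy;
      }
    }
    grf[s] += cfrc[i][1];
  }
  out.grf[0] = grf[0]; out.grf[1] = grf[1];

  // ---- joint angles -----------------------------------------------------
  double ja[6] = {q[3] - q[2], q[4] - q[3], q[5] - q[4],
                  q[6] - q[2], q[7] - q[6], q[8] - q[7]};
  double jv[6] = {qd[3] - qd[2], qd[4] - qd[3], qd[5] - qd[4],
                  qd[6] - qd[2], qd[7] - qd[6], qd[8] - qd[7]};

  // ---- neural -----------------------------------------------------------
  double hc = (t <= md.switch_time) ? 1.0 : 0.0;
  double hcp = hc ? s_ppn : md.post_switch;
  double hcc = hc ? s_cnf : md.post_switch;
  double du_ppn = (-u_ppn + md.w_ppn_cnf * std::max(0.0, u_cnf)
                   - md.beta_ppn * u_ppn + md.w_hc * hcp) / md.tau_ppn;
  double du_cnf = (-u_cnf + md.w_cnf_ppn * std::max(0.0, u_ppn)
                   - md.beta_cnf * u_cnf + md.w_hc * hcc) / md.tau_cnf;

  double gn[2] = {grf[0] / (0.5 * md.M_tot * md.grav),
                  grf[1] / (0.5 * md.M_tot * md.grav)};
  double thseg[2] = {q[3], q[6]}, shseg[2] = {q[4], q[7]},
         ftseg[2] = {q[5], q[8]};
  const double* w = md.wfeed;
  double feed[12];
  for (int s = 0; s < 2; s++) {
    int o = 1 - s, off = 6 * s;
    feed[off + 0] = -w[0] * thseg[s] + w[1] * gn[o] - w[2] * gn[s]
                    - w[3] * hat;
    feed[off + 1] = w[4] * thseg[s] + w[5] * gn[s] + w[6] * thseg[o];
    feed[off + 2] = -w[7] * shseg[s] - w[8] * gn[s] + w[9] * gn[o];
    feed[off + 3] = w[10] * shseg[s] + w[11] * gn[s];
    feed[off + 4] = -w[12] * gn[s] - w[13] * ftseg[s];
    feed[off + 5] = w[14] * gn[s] + w[15] * shseg[s];
  }
  double y[12], du[12], dv[12];
  for (int i = 0; i < 12; i++) y[i] = std::max(0.0, ucpg[i]);
  double drive = md.u0 * u_cnf;
  for (int i = 0; i < 12; i++) {
    double syn = 0;
    for (int j = 0; j < 12; j++) syn += md.Wcpg[i][j] * y[j];
    du[i] = (-ucpg[i] + syn - md.cpg_beta * vcpg[i] + drive + feed[i])
            / md.cpg_tau;
    dv[i] = (-vcpg[i] + y[i]) / md.cpg_taup;
  }

  // posture control
  double P[18];
  const double* wq = md.wpos;
  double pp = hat - md.hat_ref, pd = qd[2];
  for (int s = 0; s < 2; s++) {
    int o = 1 - s, off = 9 * s;
    double g = std::min(1.0, std::max(0.0, gn[s]));
    double go = std::min(1.0, std::max(0.0, gn[o]));
    double hipdev = ja[3 * s] - md.hip_ref;
    double kneedev = ja[3 * s + 1] - md.knee_ref;
    // ankle strategy: absolute shank sway angle/rate from the standing
    // reference (positive = backward sway)
    double shank_ref = md.hat_ref + md.hip_ref + md.knee_ref;
    double swaydev = q[4 + 3 * s] - shank_ref;
    double swayvel = qd[4 + 3 * s];
    P[off + 0] = -wq[0] * g + wq[5] * g * pp + wq[7] * g * pd
                 - wq[16] * g * hipdev - wq[21] * (g - go);
    P[off + 1] = -wq[6] * g * pp - wq[8] * g * pd - wq[13] * (1 - g)
                 + wq[17] * g * hipdev;
    P[off + 2] = -wq[3] * g;
    P[off + 3] = 0.0;
    P[off + 4] = -wq[15] * (1 - g);
    P[off + 5] = -wq[1] * g + wq[11] * g * kneedev;
    P[off + 6] = -wq[4] * g + wq[12] * g * kneedev;
    P[off + 7] = -wq[2] * g + wq[9] * g * pp + wq[18] * g * swaydev
                 + wq[20] * g * swayvel;
    P[off + 8] = -wq[10] * g * pp - wq[14] * (1 - g) - wq[19] * g * swaydev
                 - wq[20] * g * swayvel - wq[22] * g;
  }
  double uf = std::max(u_ppn, md.mn_floor);
  double alpha[18];
  for (int m = 0; m < 18; m++) {
    double arg = P[m] / uf;
    for (int i = 0; i < 12; i++) arg += md.Wa[m][i] * y[i];
    double raw = 2.0 / (1.0 + std::exp(md.mn_gain * arg)) - 1.0;
    alpha[m] = std::min(1.0, std::max(0.0, raw));
    out.alpha[m] = alpha[m];
  }

  // ---- muscles ----------------------------------------------------------
  double tau[6] = {0, 0, 0, 0, 0, 0};
  double edot = 0;
  for (int m = 0; m < 18; m++) {
    int i = m % 9, s = m / 9;
    double arm[3] = {md.rhip[i], md.rknee[i], md.rankle[i]};
    double ref[3] = {md.hip_ref, md.knee_ref, md.ankle_ref};
    double L = md.lopt[i], Ld = 0;
    for (int jj = 0; jj < 3; jj++) {
      L += arm[jj] * (ja[3 * s + jj] - ref[jj]);
      Ld += arm[jj] * jv[3 * s + jj];
    }
    double xi = L / md.lopt[i], eta = Ld / md.vmax[i];
    double kfl = 0.32 + 0.71 * std::exp(-1.112 * (xi - 1.0))
                 * std::sin(3.722 * (xi - 0.656));
    double hfv = 1.0 + std::tanh(3.0 * eta);
    double F = md.fmax[i] * kfl * hfv * alpha[m] + md.cpd[i] * Ld
               + md.kpe[i] * (std::exp(15.0 * (L - md.lopt[i])) - 1.0);
    if (F < 0) F = 0;
    out.tension[m] = F;
    for (int jj = 0; jj < 3; jj++) tau[3 * s + jj] -= F * arm[jj];
    edot += md.fmax[i] * md.vmax[i] *
            (md.met_c0 + md.met_c1 * alpha[m]
             + md.met_c2 * alpha[m] * std::max(0.0, -eta));
  }
  for (int jj = 0; jj < 6; jj++) out.torques[jj] = tau[jj];

  // passive joint torques: viscosity + limits
  double taujoint[6];
  double bvis[3] = {md.b_hip, md.b_knee, md.b_ank};
  for (int jj = 0; jj < 6; jj++)
    taujoint[jj] = tau[jj] - bvis[jj % 3] * jv[jj];
  for (int s = 0; s < 2; s++) {
    double a = ja[3 * s + 1], vv = jv[3 * s + 1];
    if (a < md.knee_lo) taujoint[3 * s + 1] += md.knee_k * (md.knee_lo - a) - md.knee_c * vv;
    else if (a > md.knee_hi) taujoint[3 * s + 1] += -md.knee_k * (a - md.knee_hi) - md.knee_c * vv;
    a = ja[3 * s + 2]; vv = jv[3 * s + 2];
    if (a < md.ank_lo) taujoint[3 * s + 2] += md.ank_k * (md.ank_lo - a) - md.ank_c * vv;
    else if (a > md.ank_hi) taujoint[3 * s + 2] += -md.ank_k * (a - md.ank_hi) - md.ank_c * vv;
  }

  // ---- generalized forces and mass matrix -------------------------------
  double M[NQ][NQ], Q[NQ], Cv[NQ];
  std::memset(M, 0, sizeof(M));
  std::memset(Q, 0, sizeof(Q));
  std::memset(Cv, 0, sizeof(Cv));
  for (int b = 0; b < 7; b++) {
    for (int i2 = 0; i2 < NQ; i2++) {
      double jx = J[b][0][i2], jy = J[b][1][i2];
      if (jx == 0 && jy == 0) continue;
      for (int j2 = i2; j2 < NQ; j2++)
        M[i2][j2] += mass[b] * (jx * J[b][0][j2] + jy * J[b][1][j2]);
      Cv[i2] += mass[b] * (jx * bias[b][0] + jy * bias[b][1]);
      Q[i2] += jy * (-mass[b] * md.grav);
    }
    M[iang[b]][iang[b]] += inert[b];
  }
  for (int i2 = 0; i2 < NQ; i2++)
    for (int j2 = 0; j2 < i2; j2++) M[i2][j2] = M[j2][i2];
  // contact
  for (int i = 0; i < 4; i++) {
    if (cfrc[i][0] == 0 && cfrc[i][1] == 0) continue;
    int s = i / 2;
    double (*Jp)[2] = (i % 2 == 0) ? Jheel[s] : Jtoe[s];
    for (int k = 0; k < NQ; k++)
      Q[k] += Jp[k][0] * cfrc[i][0] + Jp[k][1] * cfrc[i][1];
  }
  // joint torques onto the absolute-angle coordinates
  Q[3] += taujoint[0]; Q[2] -= taujoint[0];
  Q[4] += taujoint[1]; Q[3] -= taujoint[1];
  Q[5] += taujoint[2]; Q[4] -= taujoint[2];
  Q[6] += taujoint[3]; Q[2] -= taujoint[3];
  Q[7] += taujoint[4]; Q[6] -= taujoint[4];
  Q[8] += taujoint[5]; Q[7] -= taujoint[5];

  double rhsv[NQ], qdd[NQ];
  for (int i = 0; i < NQ; i++) rhsv[i] = Q[i] - Cv[i];
  out.ok = chol_solve(M, rhsv, qdd);
  if (!out.ok) return;

  for (int i = 0; i < NQ; i++) out.d[i] = qd[i];
  for (int i = 0; i < NQ; i++) out.d[9 + i] = qdd[i];
  out.d[18] = du_ppn; out.d[19] = du_cnf;
  for (int i = 0; i < 12; i++) { out.d[20 + i] = du[i]; out.d[32 + i] = dv[i]; }
  out.d[44] = edot;
  (void)shank_ang;
}

// update stick-contact anchors from the (new) state
static void update_contact(const Model& md, const double* x, Contact& ct) {
  const double* q = x;
  const double* qd = x + 9;
  double X = q[0], Y = q[1];
  for (int s = 0; s < 2; s++) {
    int it = 3 + 3 * s, isH = 4 + 3 * s, ifo = 5 + 3 * s;
    double et[2] = {std::sin(q[it]), -std::cos(q[it])};
    double ept[2] = {std::cos(q[it]), std::sin(q[it])};
    double es[2] = {std::sin(q[isH]), -std::cos(q[isH])};
    double eps_[2] = {std::cos(q[isH]), std::sin(q[isH])};
    double cf_ = std::cos(q[ifo]), sf = std::sin(q[ifo]);
    double ank[2] = {X + md.L_th * et[0] + md.L_sh * es[0],
                     Y + md.L_th * et[1] + md.L_sh * es[1]};
    double locs[2][2] = {{-md.a_heel, -md.h_ank}, {md.b_toe, -md.h_ank}};
    for (int pt = 0; pt < 2; pt++) {
      int i = 2 * s + pt;
      double px = locs[pt][0], py = locs[pt][1];
      double rx = cf_ * px - sf * py, ry = sf * px + cf_ * py;
      double rpx = -sf * px - cf_ * py, rpy = cf_ * px - sf * py;
      double X2 = ank[0] + rx, Y2 = ank[1] + ry;
      double vx = qd[0] + md.L_th * ept[0] * qd[it] + md.L_sh * eps_[0] * qd[isH]
                  + rpx * qd[ifo];
      double vy = qd[1] + md.L_th * ept[1] * qd[it] + md.L_sh * eps_[1] * qd[isH]
                  + rpy * qd[ifo];
      (void)vx;
      double fy = 0;
      if (Y2 < 0) fy = std::max(0.0, md.ky * (-Y2) - md.cy * vy);
      if (fy > 0 && !ct.active[i]) { ct.active[i] = true; ct.ax[i] = X2; }
      else if (fy <= 0) ct.active[i] = false;
    }
  }
}

// [[Rcpp::export(name = ".full_derivatives_cpp")]]
List full_derivatives_cpp(double t, NumericVector state, NumericVector theta,
                          double s_ppn, double s_cnf,
                          NumericVector anchor_x, LogicalVector anchor_active,
                          List config) {
  Model md = parse_model(config, theta);
  Contact ct;
  for (int i = 0; i < 4; i++) { ct.ax[i] = anchor_x[i]; ct.active[i] = anchor_active[i]; }
  RhsOut out;
  rhs(md, t, REAL(state), s_ppn, s_cnf, ct, out);
  if (!out.ok) stop("singular mass matrix");
  return List::create(
    _["dstate"] = NumericVector(out.d, out.d + NSTATE),
    _["grf"] = NumericVector::create(out.grf[0], out.grf[1]),
    _["alpha"] = NumericVector(out.alpha, out.alpha + 18),
    _["tension"] = NumericVector(out.tension, out.tension + 18),
    _["torques"] = NumericVector(out.torques, out.torques + 6));
}

// [[Rcpp::export(name = ".run_gait_cpp")]]
List run_gait_cpp(NumericVector state0, NumericVector theta,
                  double s_ppn, double s_cnf, double dt, double duration,
                  int decimation, double fall_height, double fall_pitch,
                  List config) {
  Model md = parse_model(config, theta);
  Contact ct;
  for (int i = 0; i < 4; i++) { ct.ax[i] = 0; ct.active[i] = false; }
  int nstep = (int)std::floor(duration / dt + 0.5);
  int nrec = nstep / decimation + 1;
  NumericMatrix rec_state(nrec, NSTATE);
  NumericMatrix rec_grf(nrec, 2);
  NumericMatrix rec_alpha(nrec, 18);
  NumericVector rec_t(nrec);

  double x[NSTATE], xs[NSTATE];
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE];
  for (int i = 0; i < NSTATE; i++) x[i] = state0[i];
  update_contact(md, x, ct);

  RhsOut o1, o2, o3, o4;
  double fall_time = NA_REAL;
  int irec = 0;
  bool aborted = false;

  // record initial sample
  rhs(md, 0.0, x, s_ppn, s_cnf, ct, o1);
  rec_t[0] = 0;
  for (int i = 0; i < NSTATE; i++) rec_state(0, i) = x[i];
  rec_grf(0, 0) = o1.grf[0]; rec_grf(0, 1) = o1.grf[1];
  for (int i = 0; i < 18; i++) rec_alpha(0, i) = o1.alpha[i];
  irec = 1;

  int step;
  for (step = 0; step < nstep; step++) {
    double t = step * dt;
    rhs(md, t, x, s_ppn, s_cnf, ct, o1);
    if (!o1.ok) { aborted = true; break; }
    for (int i = 0; i < NSTATE; i++) xs[i] = x[i] + 0.5 * dt * o1.d[i];
    rhs(md, t + 0.5 * dt, xs, s_ppn, s_cnf, ct, o2);
    if (!o2.ok) { aborted = true; break; }
    for (int i = 0; i < NSTATE; i++) xs[i] = x[i] + 0.5 * dt * o2.d[i];
    rhs(md, t + 0.5 * dt, xs, s_ppn, s_cnf, ct, o3);
    if (!o3.ok) { aborted = true; break; }
    for (int i = 0; i < NSTATE; i++) xs[i] = x[i] + dt * o3.d[i];
    rhs(md, t + dt, xs, s_ppn, s_cnf, ct, o4);
    if (!o4.ok) { aborted = true; break; }
    for (int i = 0; i < NSTATE; i++) {
      k1[i] = o1.d[i]; k2[i] = o2.d[i]; k3[i] = o3.d[i]; k4[i] = o4.d[i];
      x[i] += dt / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
    }
    update_contact(md, x, ct);

    bool finite = true;
    for (int i = 0; i < NSTATE && finite; i++)
      if (!std::isfinite(x[i])) finite = false;
    if (!finite) { aborted = true; break; }

    double tnew = (step + 1) * dt;
    if ((step + 1) % decimation == 0 && irec < nrec) {
      rhs(md, tnew, x, s_ppn, s_cnf, ct, o1);
      rec_t[irec] = tnew;
      for (int i = 0; i < NSTATE; i++) rec_state(irec, i) = x[i];
      rec_grf(irec, 0) = o1.grf[0]; rec_grf(irec, 1) = o1.grf[1];
      for (int i = 0; i < 18; i++) rec_alpha(irec, i) = o1.alpha[i];
      irec++;
    }
    // fall detection
    if (x[1] < fall_height || std::fabs(x[2]) > fall_pitch) {
      fall_time = tnew;
      break;
    }
  }
  if (aborted && ISNA(fall_time)) fall_time = step * dt;

  return List::create(
    _["t"] = rec_t[Range(0, irec - 1)],
    _["state"] = rec_state(Range(0, irec - 1), _),
    _["grf"] = rec_grf(Range(0, irec - 1), _),
    _["alpha"] = rec_alpha(Range(0, irec - 1), _),
    _["fall_time"] = fall_time,
    _["aborted"] = aborted,
    _["n_steps_integrated"] = step);
}
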