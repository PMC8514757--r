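#ifndef VTGRAD_TT06_H
#define VTGRAD_TT06_H

#include <cmath>
#include <vector>
#include <string>
#include <stdexcept>

// ten Tusscher & Panfilov (2006) human ventricular myocyte, epicardial
// parameter set. State layout (19 variables):
//   0 V (mV), 1 m, 2 h, 3 j, 4 xr1, 5 xr2, 6 xs, 7 r, 8 s, 9 d, 10 f,
//   11 f2, 12 fcass, 13 rbar (RyR adaptation), 14 Cai, 15 CaSR, 16 CaSS,
//   17 Nai, 18 Ki   (concentrations mM)
// Voltage-dependent gate steady states / Rush-Larsen decay factors and the
// voltage-only current coefficients are tabulated over [-120, 80] mV at
// 0.05 mV with linear interpolation; the table is rebuilt when dt changes.

namespace tt06 {

const int N_STATE = 19;

const double Rgas = 8314.472;
const double Temp = 310.0;
const double Frdy = 96485.3415;
const double RTONF = Rgas * Temp / Frdy;   // ~26.713 mV
const double Cm = 0.185;
const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
const double Ko = 5.4, Nao = 140.0, Cao = 2.0;
const double pKNa = 0.03;

// maximal conductances / rates (epi)
const double gNa0 = 14.838, gK10 = 5.405, gto0 = 0.294, gKr0 = 0.153,
             gKs0 = 0.392, gCaL0 = 0.0000398, kNaCa0 = 1000.0,
             pNaK0 = 2.724, gpK0 = 0.0146, gpCa0 = 0.1238,
             gbNa0 = 0.00029, gbCa0 = 0.000592;
const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35, alp = 2.5;
const double KmK = 1.0, KmNa = 40.0, KpCa = 0.0005;
const double Vmaxup = 0.006375, Kup = 0.00025, Vrel = 0.102, Vleak = 0.00036,
             Vxfer = 0.0038;
const double k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005, EC = 1.5,
             maxsr = 2.5, minsr = 1.0;
const double Bufc = 0.2, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3,
             Bufss = 0.4, Kbufss = 0.00025;

const double VMIN = -120.0, VMAX = 100.0, VSTEP = 0.05;
// hard instability bounds: a strong stimulus can transiently drive a
// plateau-phase cell above +80 mV, so the runaway check sits higher
const double VERR_LO = -120.0, VERR_HI = 95.0;
const int NTAB = (int)((VMAX - VMIN) / VSTEP) + 1;  // 4001

// multiplicative conductance factors (tissue-class remodeling, I_Ks hook)
struct Mult {
  double gNa, gCaL, gKr, gKs, gto, gK1, gpCa, gpK, gbNa, gbCa, pNaK, kNaCa;
  Mult() : gNa(1), gCaL(1), gKr(1), gKs(1), gto(1), gK1(1), gpCa(1), gpK(1),
           gbNa(1), gbCa(1), pNaK(1), kNaCa(1) {}
};

// index helpers for the 12 tabulated gates (all but fcass, rbar)
enum { G_M = 0, G_H, G_J, G_XR1, G_XR2, G_XS, G_R, G_S, G_D, G_F, G_F2,
       NGATE_TAB };

struct Tables {
  double dt;
  // [gate][vindex]
  std::vector<double> inf[NGATE_TAB], rl[NGATE_TAB];
  std::vector<double> nak_rec;    // voltage factor of INaK
  std::vector<double> naca_e1;    // exp(gam V F/RT)
  std::vector<double> naca_e2;    // exp((gam-1) V F/RT)
  std::vector<double> cal_fac;    // 4 (V-15) F^2/(RT) / (exp(2(V-15)F/RT)-1)
  std::vector<double> cal_exp;    // exp(2 (V-15) F/RT)
  std::vector<double> ipk_rec;    // 1/(1+exp((25-V)/5.98))

  void build(double dt_) {
    dt = dt_;
    for (int g = 0; g < NGATE_TAB; ++g) { inf[g].resize(NTAB); rl[g].resize(NTAB); }
    nak_rec.resize(NTAB); naca_e1.resize(NTAB); naca_e2.resize(NTAB);
    cal_fac.resize(NTAB); cal_exp.resize(NTAB); ipk_rec.resize(NTAB);
    for (int i = 0; i < NTAB; ++i) {
      double V = VMIN + i * VSTEP;
      double a, b, tau, xinf;
      // m
      xinf = 1.0 / ((1.0 + std::exp((-56.86 - V) / 9.03)) *
                    (1.0 + std::exp((-56.86 - V) / 9.03)));
      a = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
      b = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
          0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
      tau = a * b;
      inf[G_M][i] = xinf; rl[G_M][i] = std::exp(-dt / tau);
      // h
      xinf = 1.0 / ((1.0 + std::exp((V + 71.55) / 7.43)) *
                    (1.0 + std::exp((V + 71.55) / 7.43)));
      if (V >= -40.0) {
        a = 0.0;
        b = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
      } else {
        a = 0.057 * std::exp(-(V + 80.0) / 6.8);
        b = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
      }
      tau = 1.0 / (a + b);
      inf[G_H][i] = xinf; rl[G_H][i] = std::exp(-dt / tau);
      // j (same steady state as h)
      inf[G_J][i] = xinf;
      if (V >= -40.0) {
        a = 0.0;
        b = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
      } else {
        a = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
            (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
        b = 0.02424 * std::exp(-0.01052 * V) /
            (1.0 + std::exp(-0.1378 * (V + 40.14)));
      }
      tau = 1.0 / (a + b);
      rl[G_J][i] = std::exp(-dt / tau);
      // xr1
      xinf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
      a = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
      b = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
      tau = a * b;
      inf[G_XR1][i] = xinf; rl[G_XR1][i] = std::exp(-dt / tau);
      // xr2
      xinf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
      a = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
      b = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
      tau = a * b;
      inf[G_XR2][i] = xinf; rl[G_XR2][i] = std::exp(-dt / tau);
      // xs
      xinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
      a = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
      b = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
      tau = a * b + 80.0;
      inf[G_XS][i] = xinf; rl[G_XS][i] = std::exp(-dt / tau);
      // r (epi)
      xinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
      tau = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
      inf[G_R][i] = xinf; rl[G_R][i] = std::exp(-dt / tau);
      // s (epi)
      xinf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
      tau = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
            5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
      inf[G_S][i] = xinf; rl[G_S][i] = std::exp(-dt / tau);
      // d
      xinf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
      a = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
      b = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
      double c = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
      tau = a * b + c;
      inf[G_D][i] = xinf; rl[G_D][i] = std::exp(-dt / tau);
      // f
      xinf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
      tau = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
            200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
            180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
      inf[G_F][i] = xinf; rl[G_F][i] = std::exp(-dt / tau);
      // f2
      xinf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
      tau = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
            31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
            80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
      inf[G_F2][i] = xinf; rl[G_F2][i] = std::exp(-dt / tau);
      // voltage-only current coefficients
      nak_rec[i] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTONF) +
                          0.0353 * std::exp(-V / RTONF));
      naca_e1[i] = std::exp(gam * V / RTONF);
      naca_e2[i] = std::exp((gam - 1.0) * V / RTONF);
      double Vs = (std::fabs(V - 15.0) < 1e-6) ? V + 1e-6 : V;
      double e2 = std::exp(2.0 * (Vs - 15.0) / RTONF);
      cal_exp[i] = e2;
      cal_fac[i] = 4.0 * (Vs - 15.0) * (Frdy / RTONF) / (e2 - 1.0);
      ipk_rec[i] = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));
    }
  }
};

inline Tables &tables_for(double dt) {
  static Tables tab;
  if (tab.nak_rec.empty() || tab.dt != dt) tab.build(dt);
  return tab;
}

// one reaction step: Rush-Larsen gates, forward Euler for V and
// concentrations. i_stim in uA/uF (cathodal stimulus negative by convention;
// it depolarizes: dV/dt includes -i_stim). Returns false if V left
// [-120, 80] (caller reports instability).
inline bool step(double *s, const Mult &mm, double i_stim, double dt,
                 const Tables &tab) {
  double V = s[0];
  if (!(V > VERR_LO && V < VERR_HI)) return false;
  double x = (V - VMIN) / VSTEP;
  int i0 = (int)x;
  if (i0 >= NTAB - 1) i0 = NTAB - 2;
  double w = x - i0;
#define LK(v) ((v)[i0] + w * ((v)[i0 + 1] - (v)[i0]))

  double Cai = s[14], CaSR = s[15], CaSS = s[16], Nai = s[17], Ki = s[18];

  double EK = RTONF * std::log(Ko / Ki);
  double ENa = RTONF * std::log(Nao / Nai);
  double EKs = RTONF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  double ECa = 0.5 * RTONF * std::log(Cao / Cai);

  double INa = gNa0 * mm.gNa * s[1] * s[1] * s[1] * s[2] * s[3] * (V - ENa);
  double ICaL = gCaL0 * mm.gCaL * s[9] * s[10] * s[11] * s[12] *
                LK(tab.cal_fac) * (0.25 * LK(tab.cal_exp) * CaSS - Cao);
  double Ito = gto0 * mm.gto * s[7] * s[8] * (V - EK);
  double IKr = gKr0 * mm.gKr * std::sqrt(Ko / 5.4) * s[4] * s[5] * (V - EK);
  double IKs = gKs0 * mm.gKs * s[6] * s[6] * (V - EKs);
  double vk = V - EK;
  double aK1 = 0.1 / (1.0 + std::exp(0.06 * (vk - 200.0)));
  double bK1 = (3.0 * std::exp(0.0002 * (vk + 100.0)) +
                std::exp(0.1 * (vk - 10.0))) /
               (1.0 + std::exp(-0.5 * vk));
  double IK1 = gK10 * mm.gK1 * (aK1 / (aK1 + bK1)) * vk;
  double e1 = LK(tab.naca_e1), e2 = LK(tab.naca_e2);
  double INaCa = kNaCa0 * mm.kNaCa *
                 (e1 * Nai * Nai * Nai * Cao -
                  e2 * Nao * Nao * Nao * Cai * alp) /
                 ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
                  (1.0 + ksat * e2));
  double INaK = pNaK0 * mm.pNaK * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) *
                LK(tab.nak_rec);
  double IpCa = gpCa0 * mm.gpCa * Cai / (Cai + KpCa);
  double IpK = gpK0 * mm.gpK * LK(tab.ipk_rec) * vk;
  double IbNa = gbNa0 * mm.gbNa * (V - ENa);
  double IbCa = gbCa0 * mm.gbCa * (V - ECa);

  double Iion = INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK + IpCa +
                IpK + IbNa + IbCa;

  // calcium subsystem (rates per SR volume where applicable)
  double kCaSR = maxsr - (maxsr - minsr) / (1.0 + (EC / CaSR) * (EC / CaSR));
  double kk1 = k1p / kCaSR, kk2 = k2p * kCaSR;
  double rbar = s[13];
  double O = kk1 * CaSS * CaSS * rbar / (k3 + kk1 * CaSS * CaSS);
  double Irel = Vrel * O * (CaSR - CaSS);
  double Ileak = Vleak * (CaSR - Cai);
  double Iup = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  double Ixfer = Vxfer * (CaSS - Cai);

  // rbar: linear ODE, exact exponential update
  double tau_r = 1.0 / (k4 + kk2 * CaSS);
  double rinf = k4 * tau_r;
  s[13] = rinf + (rbar - rinf) * std::exp(-dt / tau_r);

  double bc = 1.0 / (1.0 + Bufc * Kbufc / ((Cai + Kbufc) * (Cai + Kbufc)));
  double bsr = 1.0 / (1.0 + Bufsr * Kbufsr / ((CaSR + Kbufsr) * (CaSR + Kbufsr)));
  double bss = 1.0 / (1.0 + Bufss * Kbufss / ((CaSS + Kbufss) * (CaSS + Kbufss)));

  s[14] = Cai + dt * bc * (-(IbCa + IpCa - 2.0 * INaCa) * Cm /
                               (2.0 * Vc * Frdy) -
                           (Iup - Ileak) * (Vsr / Vc) + Ixfer);
  s[15] = CaSR + dt * bsr * (Iup - Irel - Ileak);
  s[16] = CaSS + dt * bss * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) -
                             ICaL * Cm / (2.0 * Vss * Frdy));
  s[17] = Nai + dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * Cm /
                      (Vc * Frdy));
  s[18] = Ki + dt * (-(i_stim + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) *
                     Cm / (Vc * Frdy));

  // tabulated gates (Rush-Larsen)
  for (int g = 0; g < NGATE_TAB; ++g) {
    double gi = LK(tab.inf[g]);
    double gv = gi + (s[1 + g] - gi) * LK(tab.rl[g]);
    if (gv < 0.0) gv = 0.0; else if (gv > 1.0) gv = 1.0;
    s[1 + g] = gv;
  }
  // fcass (CaSS-dependent)
  double fi = 0.6 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 0.4;
  double ft = 80.0 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 2.0;
  double fc = fi + (s[12] - fi) * std::exp(-dt / ft);
  if (fc < 0.0) fc = 0.0; else if (fc > 1.0) fc = 1.0;
  s[12] = fc;
  if (s[13] < 0.0) s[13] = 0.0; else if (s[13] > 1.0) s[13] = 1.0;

  s[0] = V + dt * (-Iion - i_stim);
#undef LK
  return true;
}

// published epicardial initial conditions
inline void default_state(double *s) {
  s[0] = -85.23;  s[1] = 0.00172; s[2] = 0.7444;  s[3] = 0.7045;
  s[4] = 0.00621; s[5] = 0.4712;  s[6] = 0.00303; s[7] = 2.42e-8;
  s[8] = 0.999998; s[9] = 3.373e-5; s[10] = 0.7888; s[11] = 0.9755;
  s[12] = 0.9953; s[13] = 0.9073; s[14] = 0.000126; s[15] = 3.64;
  s[16] = 0.00036; s[17] = 8.604; s[18] = 136.89;
}

inline const char *state_name(int i) {
  static const char *nm[N_STATE] = {
      "vm", "m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d",
      "f", "f2", "fcass", "rbar", "cai", "casr", "cass", "nai", "ki"};
  return nm[i];
}

}  // namespace tt06

#endif
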