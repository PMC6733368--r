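/* Compiled right-hand side of the two-compartment fluid-bed granulation
 * heat- and mass-balance model, in the form expected by deSolve's
 * compiled-code interface.  Must stay numerically identical to the R
 * reference implementation fbg_rhs() in R/simulator.R (tested).
 *
 * State vector (8):
 *   y[0] m_bed_w   liquid water in bed              [kg]
 *   y[1] m_bed_b   binder solids in bed             [kg]
 *   y[2] m_air_w   water vapor in chamber air       [kg]
 *   y[3] T_bed     bed temperature                  [degC]
 *   y[4] T_air     chamber air temperature          [degC]
 *   y[5] T_wall    wall temperature                 [degC]
 *   y[6] cum water leaving with exhaust air         [kg]      (diagnostic)
 *   y[7] cum enthalpy out (exhaust + wall loss)     [J]       (diagnostic)
 *
 * Parameter vector p (31), filled by fbg_init via odeparms; the order is
 * fixed and mirrored by .fbg_parms_vector() in R/simulator.R.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static double p[31];

void fbg_init(void (*odeparms)(int *, double *))
{
    int n = 31;
    odeparms(&n, p);
}

void fbg_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double ws = p[0], Fspray = p[1], Fair = p[2], Tin = p[3],
                 xin = p[4], Tspray = p[5];
    const double thp = p[6], the = p[7];
    const double cps = p[8], cpwl = p[9], cpwg = p[10], cpb = p[11],
                 cpa = p[12], cpsteel = p[13], lam0 = p[14], T0 = p[15],
                 rhop = p[16], Dw = p[17], mua = p[18], rhoa = p[19];
    const double mair = p[20], V = p[21], mwall = p[22], UAbw = p[23],
                 UAaw = p[24], UAwe = p[25], UAba = p[26], Abed = p[27],
                 Tenv = p[28];
    const double mbs = p[30];

    /* clamp tiny solver undershoots; derivatives below keep masses >= 0 */
    const double mbw = y[0] > 0 ? y[0] : 0;
    const double mbb = y[1] > 0 ? y[1] : 0;
    const double maw = y[2] > 0 ? y[2] : 0;
    const double Tb = y[3], Ta = y[4], Tw = y[5];

    /* evaporation closure: eta(LOD) * Ranz-Marshall k0 * area * (csat - cw) */
    const double lod = 100.0 * mbw / (mbw + mbs + mbb);
    double eta = expm1(lod / the);
    if (eta > 1.0) eta = 1.0;
    if (eta < 0.0) eta = 0.0;
    const double Ap = 6.0 * (mbs + mbb) / (rhop * thp);
    const double u = Fair / (rhoa * Abed);
    const double Re = rhoa * u * thp / mua;
    const double Sc = mua / (rhoa * Dw);
    const double Sh = 2.0 + 0.6 * sqrt(Re) * cbrt(Sc);
    const double k = (Sh * Dw / thp) * eta;
    /* Arden Buck saturation curve at the bed surface, ideal-gas conversion */
    const double psat =
        611.21 * exp((18.678 - Tb / 234.5) * Tb / (257.14 + Tb));
    const double csat = psat * 0.018015 / (8.314462618 * (Tb + 273.15));
    const double cw = maw / V;
    double drive = csat - cw;
    if (drive < 0.0) drive = 0.0;          /* no condensation */
    double mevap = k * Ap * drive;
    if (y[0] <= 0.0) mevap = 0.0;          /* bed water exhausted */

    const double x = maw / mair;           /* well-mixed outlet humidity */

    ydot[0] = (1.0 - ws) * Fspray - mevap;
    ydot[1] = ws * Fspray;
    ydot[2] = Fair * (xin - x) + mevap;

    const double Hspray =
        Fspray * ((1.0 - ws) * cpwl + ws * cpb) * (Tspray - T0);
    const double Hairin = Fair * (cpa + xin * cpwg) * (Tin - T0);
    const double Hairout = Fair * (cpa + x * cpwg) * (Ta - T0);
    const double Hevap = mevap * (lam0 + cpwg * (Tb - T0));
    const double Qbw = UAbw * (Tb - Tw);
    const double Qba = UAba * (Tb - Ta);
    const double Qaw = UAaw * (Ta - Tw);
    const double Qwe = UAwe * (Tw - Tenv);

    const double Cbed = mbs * cps + mbw * cpwl + mbb * cpb;
    ydot[3] = (Hspray - Hevap - Qbw - Qba -
               (Tb - T0) * (ydot[0] * cpwl + ydot[1] * cpb)) / Cbed;
    const double Cair = mair * cpa + maw * cpwg;
    ydot[4] = (Hairin - Hairout + Hevap + Qba - Qaw -
               (Ta - T0) * ydot[2] * cpwg) / Cair;
    ydot[5] = (Qbw + Qaw - Qwe) / (mwall * cpsteel);

    ydot[6] = Fair * x;
    ydot[7] = Hairout + Qwe;
}

static const R_CMethodDef cMethods[] = {
    {"fbg_init",   (DL_FUNC) &fbg_init,   1},
    {"fbg_derivs", (DL_FUNC) &fbg_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_fbgtwin(DllInfo *info)
{
    R_registerRoutines(info, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);
}
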