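/* Coupled beta-cell clock / glucose-insulin model.
 *
 * State (15):
 *   y[0]  bmal1_mRNA      y[1]  BMAL1_prot
 *   y[2]  per_mRNA        y[3]  PER_prot
 *   y[4]  cry_mRNA        y[5]  CRY_prot
 *   y[6]  percry_complex
 *   y[7]  rev_mRNA        y[8]  REV_prot
 *   y[9]  glucose         y[10] insulin
 *   y[11] exo_mRNA        y[12] exo_prot
 *   y[13] food_act (fast eating activity)
 *   y[14] food_sat (slow satiety pool)
 *
 * The nutrient signal driving glucose is max(food_act - food_sat, 0):
 * a front-loaded intake pulse peaking shortly after the feeding window
 * opens, mirroring the burst of pellet intake at dark onset.
 *
 * Parameter order must match .bc_param_order in R/params.R.
 */

#include <R.h>
#include <math.h>

#define N_PARMS 59

static double p[N_PARMS];

/* named accessors, 0-based into the parameter vector */
#define v_mb      p[0]
#define d_mb      p[1]
#define k_pb      p[2]
#define d_pb      p[3]
#define v_mp      p[4]
#define K_bp      p[5]
#define n_bp      p[6]
#define c_glu     p[7]
#define K_gp      p[8]
#define n_gp      p[9]
#define d_mp      p[10]
#define k_pp      p[11]
#define d_pp      p[12]
#define v_mc      p[13]
#define K_bc      p[14]
#define n_bc      p[15]
#define d_mc      p[16]
#define k_pcr     p[17]
#define d_pcr     p[18]
#define k_ass     p[19]
#define k_dis     p[20]
#define d_cp      p[21]
#define K_pc      p[22]
#define n_pc      p[23]
#define v_mr      p[24]
#define K_br      p[25]
#define n_br      p[26]
#define d_mr      p[27]
#define cneur     p[28]
#define k_pr      p[29]
#define d_pr      p[30]
#define K_rb      p[31]
#define n_rb      p[32]
#define v_gb      p[33]
#define k_fg      p[34]
#define d_g       p[35]
#define k_gi      p[36]
#define k_i       p[37]
#define K_ig      p[38]
#define n_ig      p[39]
#define K_ie      p[40]
#define n_ie      p[41]
#define d_i       p[42]
#define v_me      p[43]
#define K_be      p[44]
#define n_be      p[45]
#define d_me      p[46]
#define k_pe      p[47]
#define d_pe      p[48]
#define k_fa      p[49]
#define k_fo      p[50]
#define scn_peak  p[51]
#define food_edge p[52]
#define food_onset p[53]
#define food_dur  p[54]
#define scn_mode  p[55]   /* 0 rhythmic, 1 replaced by temporal mean     */
#define exo_mode  p[56]   /* 0 clock-driven, 1 transcription = exo_const */
#define exo_const p[57]
#define food_mode p[58]   /* 0 scheduled pulse, 1 drive = temporal mean  */

static double hillA(double x, double K, double n)
{
    double xn, Kn;
    if (x <= 0.0) return 0.0;
    xn = pow(x, n);
    Kn = pow(K, n);
    return xn / (Kn + xn);
}

static double hillR(double x, double K, double n)
{
    double xn, Kn;
    Kn = pow(K, n);
    if (x <= 0.0) return 1.0;
    xn = pow(x, n);
    return Kn / (Kn + xn);
}

/* smooth periodic feeding pulse: ~1 inside the window, ~0 outside */
static double food_drive_c(double t)
{
    double center, phi, delta;
    if (food_mode > 0.5) return food_dur / 24.0;   /* temporal mean */
    center = food_onset + food_dur / 2.0;
    phi = fmod(t - center, 24.0);
    if (phi < -12.0) phi += 24.0;
    if (phi >  12.0) phi -= 24.0;
    delta = fabs(phi);
    return 1.0 / (1.0 + exp(-(food_dur / 2.0 - delta) / food_edge));
}

/* clipped-cosine SCN waveform: unit peak at scn_peak, zero through the
 * dark half-cycle; temporal mean 1/pi */
static double scn_wave_c(double t)
{
    double w = cos(2.0 * M_PI * (t - scn_peak) / 24.0);
    return (w > 0.0) ? w : 0.0;
}

void bc_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

void bc_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double MB = y[0], PB = y[1], MP = y[2], PP = y[3], MC = y[4],
           PC = y[5], CP = y[6], MR = y[7], PR = y[8], G = y[9],
           I = y[10], ME = y[11], PE = y[12], FA = y[13], FO = y[14];
    double rep_cp, scn_in, fglu, fexo, exo_tx, drive, intake;

    rep_cp = hillR(CP, K_pc, n_pc);   /* PER-CRY blocks BMAL1 action */
    scn_in = (scn_mode > 0.5) ? cneur / M_PI : cneur * scn_wave_c(*t);

    ydot[0] = v_mb * hillR(PR, K_rb, n_rb) - d_mb * MB;
    ydot[1] = k_pb * MB - d_pb * PB;
    ydot[2] = v_mp * hillA(PB, K_bp, n_bp) * rep_cp
              + c_glu * hillA(G, K_gp, n_gp) - d_mp * MP;
    ydot[3] = k_pp * MP - k_ass * PP * PC + k_dis * CP - d_pp * PP;
    ydot[4] = v_mc * hillA(PB, K_bc, n_bc) * rep_cp - d_mc * MC;
    ydot[5] = k_pcr * MC - k_ass * PP * PC + k_dis * CP - d_pcr * PC;
    ydot[6] = k_ass * PP * PC - k_dis * CP - d_cp * CP;
    ydot[7] = v_mr * hillA(PB, K_br, n_br) * rep_cp + scn_in - d_mr * MR;
    ydot[8] = k_pr * MR - d_pr * PR;

    drive = food_drive_c(*t);
    ydot[13] = k_fa * (drive - FA);
    ydot[14] = k_fo * (FA - FO);

    intake = FA - FO;
    if (intake < 0.0) intake = 0.0;
    ydot[9] = v_gb + k_fg * intake - d_g * G - k_gi * I * G;

    fglu = hillA(G, K_ig, n_ig);
    fexo = hillA(PE, K_ie, n_ie);
    ydot[10] = k_i * fglu * fexo - d_i * I;

    exo_tx = (exo_mode > 0.5) ? exo_const : v_me * hillA(PB, K_be, n_be);
    ydot[11] = exo_tx - d_me * ME;
    ydot[12] = k_pe * ME - d_pe * PE;

    if (ip[0] >= 3) {
        yout[0] = fglu;
        yout[1] = fexo;
        yout[2] = intake;
    }
}
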