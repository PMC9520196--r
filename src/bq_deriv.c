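/* Right-hand side of the consumer-resource model, in deSolve's
 * compiled-model convention (initfunc + derivs).
 *
 * State vector y (length 3 + 2N):
 *   y[0] = C  cellulose (mM glucose-equivalents)
 *   y[1] = G  glucose (mM)
 *   y[2] = A  amino acids (mM)
 *   y[3 + i]       = B_i  biomass of species i (ng)
 *   y[3 + N + i]   = P_i  cumulative gross production of species i (ng)
 *
 * Parameter vector (doubles), padded to BQ_NPAR on the R side:
 *   p[0] = N (number of species)
 *   p[1] = mode: 0 = bulk_soil, 1 = rhizosphere (amino acids non-limiting,
 *          dA/dt not evaluated)
 *   p[2] = G_death (mM): below this glucose level the growth term is zeroed
 *   p[3] = y_CG: glucose yield per unit cellulose degraded
 *   then 12 doubles per species:
 *   [0] mu_eff  = mu_max * eps_rel         (1/generation)
 *   [1] Km_G    glucose transporter half-saturation (mM)
 *   [2] Km_A    amino-acid transporter half-saturation (mM)
 *   [3] uT      = Vmax_T   * v_conv        (mM per ng per generation)
 *   [4] ucel    = Vmax_cel * v_conv        (mM per ng per generation)
 *   [5] Km_cel  cellulase half-saturation (mM)
 *   [6] uleak   = leak_max * v_conv        (mM per ng per generation)
 *   [7] K_leak  leakage half-saturation on glucose (mM)
 *   [8] m       maintenance burden (1/generation)
 *   [9] cellulolytic flag (0/1)
 *   [10] prototrophic flag (0/1)
 *   [11] alive flag (0/1)
 */

#include <R.h>

#define BQ_MAXN 128
#define BQ_HEAD 4
#define BQ_SPP 12
#define BQ_NPAR (BQ_HEAD + BQ_SPP * BQ_MAXN)

static double parms[BQ_NPAR];

void bq_init(void (*odeparms)(int *, double *))
{
    int n = BQ_NPAR;
    odeparms(&n, parms);
}

void bq_deriv(int *neq, double *t, double *y, double *ydot,
              double *yout, int *ip)
{
    const int N = (int) parms[0];
    const int rhizo = parms[1] > 0.5;
    const double G_death = parms[2];
    const double y_CG = parms[3];

    const double C = y[0] > 0 ? y[0] : 0;
    const double G = y[1] > 0 ? y[1] : 0;
    const double A = y[2] > 0 ? y[2] : 0;

    double cel_flux = 0, uptake_G = 0, leak_A = 0, uptake_A = 0;
    /* dormancy switch: steep smooth gate around the death threshold
     * (Hill exponent 6), so the RHS stays solver-friendly */
    double act = 0;
    if (G > 0) {
        const double r = G_death / G;
        const double r2 = r * r;
        act = 1.0 / (1.0 + r2 * r2 * r2);
    }

    for (int i = 0; i < N; i++) {
        const double *p = parms + BQ_HEAD + BQ_SPP * i;
        const double B = y[3 + i];
        ydot[3 + i] = 0;
        ydot[3 + N + i] = 0;
        if (p[11] < 0.5 || B <= 0)
            continue;

        const double fG = G / (p[1] + G);
        double flim = fG;

        if (p[9] > 0.5)  /* cellulolytic: degrade C into G */
            cel_flux += p[4] * B * C / (p[5] + C);

        /* below the death threshold cells go dormant: growth, transport
         * and leakage stop together (extracellular cellulase keeps
         * working); `act` is the smooth dormancy switch */
        uptake_G += act * p[3] * fG * B;
        if (p[10] > 0.5) {           /* prototroph: leak amino acids */
            if (!rhizo)
                leak_A += act * p[6] * B * G / (p[7] + G);
        } else if (!rhizo) {         /* auxotroph in bulk soil: Liebig */
            const double fA = A / (p[2] + A);
            uptake_A += act * p[3] * fA * B;
            if (fA < flim)
                flim = fA;
        }

        const double gross = act * p[0] * flim;
        ydot[3 + i] = (gross - p[8]) * B;
        ydot[3 + N + i] = gross * B;
    }

    ydot[0] = -cel_flux;
    ydot[1] = y_CG * cel_flux - uptake_G;
    ydot[2] = rhizo ? 0 : (leak_A - uptake_A);
}
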