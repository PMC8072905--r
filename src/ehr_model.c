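/* Right-hand side of the EHR compartmental models, in the deSolve
 * compiled-function convention (initfunc + derivs looked up by name).
 *
 * Uniform internal state layout, 1 depot + nt transit + 4 disposition
 * compartments (unused slots stay identically zero):
 *   y[0]        depot
 *   y[1..nt]    transit chain
 *   y[nt+1]     central
 *   y[nt+2]     peripheral
 *   y[nt+3]     bile
 *   y[nt+4]     gut
 *
 * Amounts are ng per kg body weight; rate constants 1/h.
 */
#include <R.h>

static double parms[13];

#define NT        ((int) parms[0])   /* transit compartments (0 for IV)   */
#define HAS_PER   ((int) parms[1])   /* peripheral compartment present    */
#define K10       parms[2]           /* CL/V                              */
#define K12       parms[3]           /* CL2/V                             */
#define K21       parms[4]           /* CL2/V2                            */
#define KCB       parms[5]           /* central -> bile                   */
#define KGC       parms[6]           /* gut -> central re-absorption      */
#define BILECOEF  parms[7]           /* 1/Tau (continuous bile emptying)  */
#define KA1       parms[8]           /* depot -> central (fast path)      */
#define KA2       parms[9]           /* depot -> transit[1] (slow path)   */
#define KTR       parms[10]          /* transit chain rate                */
#define RELRATE   parms[11]          /* zero-order release into depot     */
#define WINRATE   parms[12]          /* windowed bile emptying rate       */

void ehr_init(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, parms);
}

void ehr_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int nt = NT, k;
    double depot   = y[0];
    double central = y[nt + 1];
    double periph  = y[nt + 2];
    double bile    = y[nt + 3];
    double gut     = y[nt + 4];
    double into_central = 0.0;
    double bile_out;

    ydot[0] = RELRATE - (KA1 + KA2) * depot;
    if (nt > 0) {
        ydot[1] = KA2 * depot - KTR * y[1];
        for (k = 2; k <= nt; k++)
            ydot[k] = KTR * (y[k - 1] - y[k]);
        into_central = KA1 * depot + KTR * y[nt];
    }

    bile_out = BILECOEF * bile;
    if (WINRATE > 0.0 && bile > 0.0)
        bile_out += WINRATE;

    ydot[nt + 1] = into_central - (K10 + K12 + KCB) * central
                   + K21 * periph + KGC * gut;
    ydot[nt + 2] = HAS_PER ? (K12 * central - K21 * periph) : 0.0;
    ydot[nt + 3] = KCB * central - bile_out;
    ydot[nt + 4] = bile_out - KGC * gut;
}
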