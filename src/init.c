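#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_ssa_propensities(SEXP, SEXP, SEXP, SEXP);
SEXP C_ssa_stoich(void);
SEXP C_ssa_lineage(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                   SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_ssa_propensities", (DL_FUNC) &C_ssa_propensities, 4},
    {"C_ssa_stoich", (DL_FUNC) &C_ssa_stoich, 0},
    {"C_ssa_lineage", (DL_FUNC) &C_ssa_lineage, 10},
    {NULL, NULL, 0}
};

void R_init_mcncycle(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    /* deSolve looks up cdk_derivs / cdk_initmod / cdk_root_m by name */
    R_useDynamicSymbols(dll, TRUE);
}
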