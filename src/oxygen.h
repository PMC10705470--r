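#ifndef RSSPHEROID_OXYGEN_H
#define RSSPHEROID_OXYGEN_H

#include <vector>

// Steady-state radial oxygen profile on shells of width dr (conservative
// finite volumes, free anoxic boundary by monotone fixed point).
//
// cons   consuming concentration (c_p + c_d) per shell
// i0     surface shell (0-based); Dirichlet rho[i0] = rho0; if i0 < 0 the
//        spheroid is below the detection threshold and rho = rho0 everywhere
// a      consumption rate in mmHg per hour (per unit packed cell volume)
// rho    output, length cons.size(); shells beyond i0 are set to rho0
// chi    output, 1 where the shell consumes, 0 in the anoxic core
//
// Returns the number of fixed-point iterations, or -1 on non-convergence.
int rs_oxygen_core(const std::vector<double>& cons, int i0, double dr,
                   double D, double rho0, double rho_an, double a,
                   int max_iter, std::vector<double>& rho,
                   std::vector<char>& chi);

// Outer edge of the outermost non-consuming shell (0 if the whole spheroid
// consumes).
double rs_anoxic_radius(const std::vector<char>& chi, int i0, double dr);

#endif
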