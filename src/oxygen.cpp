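#include "oxygen.h"
#include <cmath>

// Tridiagonal solve (Thomas); a = sub, b = diag, c = super, d = rhs.
static void thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& d,
                   std::vector<double>& x) {
  const int n = (int)b.size();
  if (n == 0) return;
  for (int i = 1; i < n; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  x[n - 1] = d[n - 1] / b[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = (d[i] - c[i] * x[i + 1]) / b[i];
}

int rs_oxygen_core(const std::vector<double>& cons, int i0, double dr,
                   double D, double rho0, double rho_an, double a,
                   int max_iter, std::vector<double>& rho,
                   std::vector<char>& chi) {
  const int n = (int)cons.size();
  const double pi = 3.14159265358979323846;
  rho.assign(n, rho0);
  chi.assign(n, 0);
  if (i0 < 0) return 0;
  for (int i = 0; i <= i0 && i < n; ++i) chi[i] = 1;  // start all consuming
  const int m = i0;  // unknowns 0..m-1, Dirichlet at shell i0
  if (m <= 0) return 0;

  // face conductance g_i = D * A_i / dr across face at radius i*dr
  std::vector<double> g(m + 1), vol(m);
  for (int i = 0; i <= m; ++i) {
    double rf = i * dr;
    g[i] = D * 4.0 * pi * rf * rf / dr;
  }
  for (int i = 0; i < m; ++i)
    vol[i] = 4.0 / 3.0 * pi * dr * dr * dr *
             (std::pow(i + 1.0, 3) - std::pow((double)i, 3));

  std::vector<double> sub(m), dia(m), sup(m), rhs(m), x(m);
  // one shell can be disabled per iteration, so n iterations always suffice
  const int cap = std::max(max_iter, m + 2);
  for (int iter = 1; iter <= cap; ++iter) {
    for (int i = 0; i < m; ++i) {
      sub[i] = (i > 0) ? g[i] : 0.0;
      sup[i] = (i < m - 1) ? g[i + 1] : 0.0;
      dia[i] = -(g[i] + g[i + 1]);
      rhs[i] = chi[i] ? a * cons[i] * vol[i] : 0.0;
      if (i == m - 1) rhs[i] -= g[m] * rho0;  // Dirichlet neighbor
    }
    thomas(sub, dia, sup, rhs, x);
    for (int i = 0; i < m; ++i) rho[i] = x[i];
    // disable the innermost consuming shell at or below the threshold
    // (one per iteration: the consuming set shrinks monotonically to the
    // smallest self-consistent anoxic core; disabling the whole
    // sub-threshold region at once would overshoot, because the profile of
    // the over-consuming iterate lies below the free-boundary solution)
    bool changed = false;
    for (int i = 0; i < m; ++i) {
      if (chi[i] && rho[i] <= rho_an) {
        chi[i] = 0;
        changed = true;
        break;
      }
    }
    if (!changed) {
      // anoxic core sits exactly at the threshold pressure
      for (int i = 0; i < m; ++i)
        if (!chi[i]) rho[i] = rho_an;
      for (int i = m; i < n; ++i) rho[i] = rho0;
      return iter;
    }
  }
  return -1;
}

// The zero-flux core boundary sits on the first shell face above the true
// free boundary, so the face position overestimates r_an by up to one shell;
// the center of the outermost anoxic shell is the unbiased estimate (error
// within +/- dr/2 of the analytic free boundary).
double rs_anoxic_radius(const std::vector<char>& chi, int i0, double dr) {
  int last = -1;
  for (int i = 0; i <= i0 && i < (int)chi.size(); ++i)
    if (!chi[i]) last = i;
  return last < 0 ? 0.0 : (last + 0.5) * dr;
}
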