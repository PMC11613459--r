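#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Explicit forward-Euler integration of the five-species Min reaction-diffusion
// system on a 1D cell-centered grid with no-flux (mirrored ghost) boundaries.
//
// Species order (rows of c0): c_DD, c_DT, c_E, c_d, c_de.
// k = (k_D, k_dD, k_dE, k_de, k_ADP_ATP); D = per-species diffusion in the
// same species order.  Frames are stored every `frame_every` steps (plus the
// initial state), giving nsteps/frame_every + 1 frames.
//
// [[Rcpp::export]]
List min_integrate_cpp(NumericMatrix c0, double dx, double dt,
                       int nsteps, int frame_every,
                       NumericVector k, NumericVector D) {
  const int n = c0.ncol();
  if (c0.nrow() != 5) stop("c0 must have 5 rows (species)");
  if (nsteps % frame_every != 0) stop("nsteps must be a multiple of frame_every");

  const double kD = k[0], kdD = k[1], kdE = k[2], kde = k[3], kAA = k[4];
  const double idx2 = 1.0 / (dx * dx);

  std::vector<std::vector<double> > c(5, std::vector<double>(n));
  std::vector<std::vector<double> > cn(5, std::vector<double>(n));
  for (int s = 0; s < 5; ++s)
    for (int i = 0; i < n; ++i) c[s][i] = c0(s, i);

  const int nframes = nsteps / frame_every + 1;
  std::vector<NumericMatrix> out;
  for (int s = 0; s < 5; ++s) out.push_back(NumericMatrix(nframes, n));
  for (int s = 0; s < 5; ++s)
    for (int i = 0; i < n; ++i) out[s](0, i) = c[s][i];

  // relative step-change monitor: the largest single-step density change of
  // any species, relative to the current overall maximum density, maximized
  // over steps (species starting from zero make a per-species denominator
  // meaningless)
  double max_rel_change = 0.0;

  int frame = 1;
  for (int step = 1; step <= nsteps; ++step) {
    double dmax[5] = {0, 0, 0, 0, 0};
    double cmax[5] = {0, 0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      const int il = (i == 0) ? 0 : i - 1;
      const int ir = (i == n - 1) ? n - 1 : i + 1;
      const double cDD = c[0][i], cDT = c[1][i], cE = c[2][i],
                   cd = c[3][i], cde = c[4][i];

      const double flux = kdE * cd * cE;       // MinE recruitment
      const double rec  = kdD * cd * cDT;      // MinD self-recruitment
      const double rel  = kde * cde;           // MinDE dissociation
      const double exch = kAA * cDD;           // nucleotide exchange
      const double att  = kD * cDT;            // spontaneous attachment

      const double r0 = -exch + rel;
      const double r1 = exch - att - rec;
      const double r2 = rel - flux;
      const double r3 = att + rec - flux;
      const double r4 = flux - rel;

      const double l0 = (c[0][il] - 2.0 * cDD + c[0][ir]) * idx2;
      const double l1 = (c[1][il] - 2.0 * cDT + c[1][ir]) * idx2;
      const double l2 = (c[2][il] - 2.0 * cE  + c[2][ir]) * idx2;
      const double l3 = (c[3][il] - 2.0 * cd  + c[3][ir]) * idx2;
      const double l4 = (c[4][il] - 2.0 * cde + c[4][ir]) * idx2;

      cn[0][i] = cDD + dt * (D[0] * l0 + r0);
      cn[1][i] = cDT + dt * (D[1] * l1 + r1);
      cn[2][i] = cE  + dt * (D[2] * l2 + r2);
      cn[3][i] = cd  + dt * (D[3] * l3 + r3);
      cn[4][i] = cde + dt * (D[4] * l4 + r4);

      const double oldv[5] = {cDD, cDT, cE, cd, cde};
      for (int s = 0; s < 5; ++s) {
        const double d = std::fabs(cn[s][i] - oldv[s]);
        if (d > dmax[s]) dmax[s] = d;
        if (oldv[s] > cmax[s]) cmax[s] = oldv[s];
      }
    }
    double dall = 0.0, call = 0.0;
    for (int s = 0; s < 5; ++s) {
      if (dmax[s] > dall) dall = dmax[s];
      if (cmax[s] > call) call = cmax[s];
    }
    if (call > 0.0 && dall / call > max_rel_change)
      max_rel_change = dall / call;
    c.swap(cn);

    if (step % frame_every == 0) {
      bool bad = false;
      for (int s = 0; s < 5 && !bad; ++s)
        for (int i = 0; i < n; ++i)
          if (!std::isfinite(c[s][i])) { bad = true; break; }
      if (bad)
        stop("non-finite concentration at t = %g s; integration aborted",
             step * dt);
      for (int s = 0; s < 5; ++s)
        for (int i = 0; i < n; ++i) out[s](frame, i) = c[s][i];
      ++frame;
      Rcpp::checkUserInterrupt();
    }
  }

  return List::create(_["c_DD"] = out[0], _["c_DT"] = out[1],
                      _["c_E"] = out[2], _["c_d"] = out[3],
                      _["c_de"] = out[4],
                      _["max_rel_change"] = max_rel_change);
}
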