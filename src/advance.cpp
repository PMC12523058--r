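#include <Rcpp.h>
using namespace Rcpp;

// Explicit Euler integration of the coupled auxin / PD / PIN system with
// the wall flux frozen at the start of every (sub)step. With adaptive =
// true the substep length is chosen from a Gershgorin row bound on the
// auxin-transport Jacobian (|lambda| <= auxdec_i + outflow_i + inflow_i)
// so that stiff canalized states (high PD area / membrane PIN) remain
// stable; with adaptive = false exactly one Euler step of length dt is
// taken.
// [[Rcpp::export(name = ".advanceCpp")]]
List advanceCpp(NumericVector A0, NumericVector Aprec0, NumericVector P0,
                NumericVector D0, NumericVector Pab0, NumericVector Pba0,
                IntegerVector wa, IntegerVector wb, NumericVector Tfac,
                NumericVector auxdec, LogicalVector z1, LogicalVector z2,
                List par, double t0, double dt, bool adaptive) {
  const double auxpr = par["auxpr"], Dperm = par["Dperm"],
    alpha = par["alpha"], beta = par["beta"], gamma_ = par["gamma"],
    kU = par["kU"], kWl = par["kWl"], kWq = par["kWq"], kOff = par["kOff"],
    pinpr = par["pinpr"], pindec = par["pindec"], fSat = par["fSat"],
    aprecRamp = par["aprecRamp"], z1Init = par["z1Init"],
    z2Start = par["z2Start"];
  const int n = A0.size(), nw = wa.size();

  NumericVector A = clone(A0), Aprec = clone(Aprec0), P = clone(P0),
    D = clone(D0), Pab = clone(Pab0), Pba = clone(Pba0), phi(nw);
  std::vector<double> dA(n), dP(n), fa(n), fU(n), satP(n), inv2(n), row(n);
  std::vector<int> ia(nw), ib(nw);
  for (int w = 0; w < nw; ++w) { ia[w] = wa[w] - 1; ib[w] = wb[w] - 1; }

  double t = t0;
  const double tEnd = t0 + dt;
  long nsub = 0;
  while (t < tEnd - 1e-12) {
    // per-cell saturation factors (division-heavy, hoisted out of the
    // wall loops)
    for (int i = 0; i < n; ++i) {
      const double a1 = 1 + A[i];
      fa[i] = A[i] / a1;
      inv2[i] = 1 / (a1 * a1);
      fU[i] = fSat * A[i] / (fSat + A[i]);
      satP[i] = P[i] / (1 + P[i]);
    }
    double h = tEnd - t;
    if (adaptive) {
      for (int i = 0; i < n; ++i) row[i] = auxdec[i];
      for (int w = 0; w < nw; ++w) {
        const int a = ia[w], b = ib[w];
        const double pd2 = 2 * Dperm * D[w];
        const double pinA = Tfac[w] * Pab[w] * inv2[a];
        const double pinB = Tfac[w] * Pba[w] * inv2[b];
        row[a] += pd2 + pinA + pinB;
        row[b] += pd2 + pinA + pinB;
      }
      double rmax = gamma_;
      if (kOff > rmax) rmax = kOff;
      if (pindec > rmax) rmax = pindec;
      for (int i = 0; i < n; ++i) if (row[i] > rmax) rmax = row[i];
      // 0.9: keeps the Euler amplification factor of every mode positive
      // (no sign-alternating transients for the phi^2 terms to rectify)
      if (rmax > 0 && 0.9 / rmax < h) h = 0.9 / rmax;
    }
    // freeze flux, evaluate and apply wall equations
    std::fill(dA.begin(), dA.end(), 0.0);
    std::fill(dP.begin(), dP.end(), 0.0);
    for (int w = 0; w < nw; ++w) {
      const int a = ia[w], b = ib[w];
      const double f = Tfac[w] * (Pab[w] * fa[a] - Pba[w] * fa[b]) +
        Dperm * D[w] * (A[a] - A[b]);
      phi[w] = f;
      dA[a] -= f; dA[b] += f;
      const double dD = alpha * f * f + beta - gamma_ * D[w];
      const double phiA = f > 0 ? f : 0.0;
      const double phiB = f < 0 ? -f : 0.0;
      const double dPab = kU * satP[a] * fU[b] +
        satP[a] * (kWq * phiA * phiA + kWl * phiA) - kOff * Pab[w];
      const double dPba = kU * satP[b] * fU[a] +
        satP[b] * (kWq * phiB * phiB + kWl * phiB) - kOff * Pba[w];
      dP[a] -= dPab; dP[b] -= dPba;
      D[w] += h * dD; if (D[w] < 0) D[w] = 0;
      Pab[w] += h * dPab; if (Pab[w] < 0) Pab[w] = 0;
      Pba[w] += h * dPba; if (Pba[w] < 0) Pba[w] = 0;
    }
    // cell equations
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      const double Anew = A[i] + h * (auxpr * Aprec[i] - auxdec[i] * A[i] + dA[i]);
      const double Pnew = P[i] + h * (pinpr * A[i] - pindec * P[i] + dP[i]);
      A[i] = Anew < 0 ? 0 : Anew;
      P[i] = Pnew < 0 ? 0 : Pnew;
      bad = bad || !std::isfinite(A[i]) || !std::isfinite(P[i]);
    }
    t += h;
    ++nsub;
    if (bad) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(A[i]))
          stop("non-finite auxin in cell %d at t = %g (auxin equation)",
               i + 1, t);
    }
    // production-zone schedule
    for (int i = 0; i < n; ++i) {
      if (z1[i]) Aprec[i] = z1Init + aprecRamp * t;
      else if (z2[i]) Aprec[i] = t >= z2Start ? aprecRamp * (t - z2Start) : 0.0;
      else Aprec[i] = 0.0;
    }
    if (nsub > 200000000L) stop("step subdivision exploded at t = %g", t);
  }
  for (int w = 0; w < nw; ++w)
    if (!std::isfinite(D[w]) || !std::isfinite(Pab[w]) || !std::isfinite(Pba[w]))
      stop("non-finite wall state on wall %d at t = %g", w + 1, t);
  return List::create(_["A"] = A, _["Aprec"] = Aprec, _["Pcyto"] = P,
                      _["D"] = D, _["Pab"] = Pab, _["Pba"] = Pba,
                      _["phi"] = phi, _["nsub"] = nsub);
}
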