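#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Shared helpers
// ---------------------------------------------------------------------------

static inline double wrap_pi_c(double x) {
  // wrap to [-pi, pi)
  double y = x + M_PI;
  y -= std::floor(y / (2.0 * M_PI)) * (2.0 * M_PI);
  if (y >= 2.0 * M_PI) y = 0.0;  // guard against rounding at the seam
  return y - M_PI;
}

// Periodic model potential: a sum of product von Mises wells
//   U(z) = -sum_i d_i * exp(c_i * (cos(phi-phi_i) + cos(psi-psi_i) - 2))
// plus optional explicit Fourier terms coef * f1(k1*phi) * f2(k2*psi),
// where type 1 = cos*cos, 2 = cos*sin, 3 = sin*cos, 4 = sin*sin,
// plus a constant offset (set in R so that min U = 0).
struct PotC {
  const double *wells; int nw;   // rows: phi, psi, depth, conc (column-major)
  const double *ft;    int nf;   // rows: k1, k2, type, coef
  double offset;
};

static inline void pot_eval(const PotC &P, double phi, double psi,
                            double *U, double *gphi, double *gpsi) {
  double u = 0.0, gp = 0.0, gs = 0.0;
  for (int i = 0; i < P.nw; i++) {
    double dphi = phi - P.wells[i];
    double dpsi = psi - P.wells[P.nw + i];
    double d = P.wells[2 * P.nw + i];
    double c = P.wells[3 * P.nw + i];
    double e = d * std::exp(c * (std::cos(dphi) + std::cos(dpsi) - 2.0));
    u -= e;
    gp += e * c * std::sin(dphi);
    gs += e * c * std::sin(dpsi);
  }
  for (int i = 0; i < P.nf; i++) {
    double k1 = P.ft[i];
    double k2 = P.ft[P.nf + i];
    int ty = (int)P.ft[2 * P.nf + i];
    double a = P.ft[3 * P.nf + i];
    double f1, df1, f2, df2;
    if (ty == 1 || ty == 2) { f1 = std::cos(k1 * phi); df1 = -k1 * std::sin(k1 * phi); }
    else                    { f1 = std::sin(k1 * phi); df1 =  k1 * std::cos(k1 * phi); }
    if (ty == 1 || ty == 3) { f2 = std::cos(k2 * psi); df2 = -k2 * std::sin(k2 * psi); }
    else                    { f2 = std::sin(k2 * psi); df2 =  k2 * std::cos(k2 * psi); }
    u  += a * f1 * f2;
    gp += a * df1 * f2;
    gs += a * f1 * df2;
  }
  *U = u + P.offset;
  *gphi = gp;
  *gpsi = gs;
}

static inline PotC make_pot(const NumericMatrix &wells, const NumericMatrix &fterms,
                            double offset) {
  PotC P;
  P.wells = wells.nrow() > 0 ? &wells(0, 0) : NULL;
  P.nw = wells.nrow();
  P.ft = fterms.nrow() > 0 ? &fterms(0, 0) : NULL;
  P.nf = fterms.nrow();
  P.offset = offset;
  return P;
}

// Per-dimension basis vector of length M = 2N+1 in the fixed order
// [1, cos(x), sin(x), cos(2x), sin(2x), ..., cos(Nx), sin(Nx)]
// with derivatives; cos/sin of multiples via angle-addition recurrence.
static inline void basis_dim(double x, int N, double *f, double *df) {
  f[0] = 1.0; df[0] = 0.0;
  double c1 = std::cos(x), s1 = std::sin(x);
  double ck = 1.0, sk = 0.0;
  for (int k = 1; k <= N; k++) {
    double cn = ck * c1 - sk * s1;
    double sn = sk * c1 + ck * s1;
    ck = cn; sk = sn;
    f[2 * k - 1] = ck; df[2 * k - 1] = -k * sk;
    f[2 * k]     = sk; df[2 * k]     =  k * ck;
  }
}

// ---------------------------------------------------------------------------
// Exported: potential evaluation on a set of points
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".pot_eval_core")]]
NumericMatrix pot_eval_core(NumericMatrix z, NumericMatrix wells,
                            NumericMatrix fterms, double offset) {
  PotC P = make_pot(wells, fterms, offset);
  int n = z.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) {
    double U, gp, gs;
    pot_eval(P, wrap_pi_c(z(i, 0)), wrap_pi_c(z(i, 1)), &U, &gp, &gs);
    out(i, 0) = U; out(i, 1) = gp; out(i, 2) = gs;
  }
  return out;
}

// [[Rcpp::export(name = ".basis_core")]]
NumericMatrix basis_core(NumericMatrix z, int N) {
  int M = 2 * N + 1;
  int n = z.nrow();
  std::vector<double> f(M), df(M), g(M), dg(M);
  NumericMatrix out(n, M * M);
  for (int i = 0; i < n; i++) {
    basis_dim(wrap_pi_c(z(i, 0)), N, f.data(), df.data());
    basis_dim(wrap_pi_c(z(i, 1)), N, g.data(), dg.data());
    for (int b = 0; b < M; b++)
      for (int a = 0; a < M; a++)
        out(i, a + M * b) = f[a] * g[b];
  }
  return out;
}

// [[Rcpp::export(name = ".bias_eval_core")]]
NumericVector bias_eval_core(NumericMatrix z, NumericMatrix A) {
  int M = A.nrow();
  int N = (M - 1) / 2;
  int n = z.nrow();
  std::vector<double> f(M), df(M), g(M), dg(M);
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    basis_dim(wrap_pi_c(z(i, 0)), N, f.data(), df.data());
    basis_dim(wrap_pi_c(z(i, 1)), N, g.data(), dg.data());
    double v = 0.0;
    for (int b = 0; b < M; b++) {
      double gb = g[b];
      if (gb == 0.0) continue;
      double acc = 0.0;
      for (int a = 0; a < M; a++) acc += A(a, b) * f[a];
      v += acc * gb;
    }
    out[i] = v;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Langevin propagator (overdamped Euler-Maruyama on the torus)
// ---------------------------------------------------------------------------

// Shared stepping kernel. A is the (possibly empty) bias coefficient matrix.
// Records (step, phi, psi, bias) every record_stride steps. Uses R's RNG so
// set.seed() governs reproducibility.

// [[Rcpp::export(name = ".langevin_core")]]
NumericMatrix langevin_core(NumericMatrix wells, NumericMatrix fterms, double offset,
                            NumericMatrix A, bool has_bias,
                            double beta, double D, double dt,
                            int n_steps, int record_stride,
                            double phi0, double psi0) {
  PotC P = make_pot(wells, fterms, offset);
  int M = A.nrow();
  int N = has_bias ? (M - 1) / 2 : 0;
  std::vector<double> f(M > 0 ? M : 1), df(M > 0 ? M : 1);
  std::vector<double> g(M > 0 ? M : 1), dg(M > 0 ? M : 1);

  int nrec = n_steps / record_stride;
  NumericMatrix out(nrec, 4);
  double phi = wrap_pi_c(phi0), psi = wrap_pi_c(psi0);
  double pref = beta * D * dt;
  double sig = std::sqrt(2.0 * D * dt);
  int irec = 0;
  RNGScope scope;
  for (int s = 1; s <= n_steps; s++) {
    double U, gp, gs;
    pot_eval(P, phi, psi, &U, &gp, &gs);
    double V = 0.0;
    if (has_bias) {
      basis_dim(phi, N, f.data(), df.data());
      basis_dim(psi, N, g.data(), dg.data());
      for (int b = 0; b < M; b++) {
        double acc = 0.0;
        for (int a = 0; a < M; a++) acc += A(a, b) * f[a];
        double dacc = 0.0;
        for (int a = 0; a < M; a++) dacc += A(a, b) * df[a];
        V += acc * g[b];
        gp += dacc * g[b];
        gs += acc * dg[b];
      }
    }
    phi = wrap_pi_c(phi - pref * gp + sig * norm_rand());
    psi = wrap_pi_c(psi - pref * gs + sig * norm_rand());
    if (s % record_stride == 0 && irec < nrec) {
      if (has_bias) {
        // bias at the *recorded* position
        basis_dim(phi, N, f.data(), df.data());
        basis_dim(psi, N, g.data(), dg.data());
        V = 0.0;
        for (int b = 0; b < M; b++) {
          double acc = 0.0;
          for (int a = 0; a < M; a++) acc += A(a, b) * f[a];
          V += acc * g[b];
        }
      } else V = 0.0;
      out(irec, 0) = (double)s * dt;
      out(irec, 1) = phi;
      out(irec, 2) = psi;
      out(irec, 3) = V;
      irec++;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// VES driver: alternates `stride` Langevin steps under the acting bias with
// one stochastic-gradient coefficient update. The acting bias is the running
// mean of the instantaneous coefficient iterates when average_bias is true
// (averaged SGD), otherwise the instantaneous iterates (plain SGD).
// Functional gradient for the uniform target:
//   dOmega/dalpha_k = -<f_k>_biased-batch + <f_k>_uniform
// where <f_k>_uniform is 1 for the constant basis function and 0 otherwise.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".ves_core")]]
List ves_core(NumericMatrix wells, NumericMatrix fterms, double offset,
              int N, double mu, int stride, int n_iter,
              double beta, double D, double dt, int record_stride,
              double phi0, double psi0, bool average_bias, int history_stride,
              bool curvature, int avg_start) {
  PotC P = make_pot(wells, fterms, offset);
  int M = 2 * N + 1;
  int K = M * M;
  std::vector<double> f(M), df(M), g(M), dg(M);
  std::vector<double> a_inst(K, 0.0), a_bar(K, 0.0), S(K, 0.0);
  std::vector<double> S2(K, 0.0), v(K, 0.0);

  long total_steps = (long)stride * n_iter;
  int nrec = (int)(total_steps / record_stride);
  NumericMatrix traj(nrec, 4);
  int nhist = n_iter / history_stride;
  NumericMatrix hist(nhist, K);
  IntegerVector hist_iter(nhist);

  double phi = wrap_pi_c(phi0), psi = wrap_pi_c(psi0);
  double pref = beta * D * dt;
  double sig = std::sqrt(2.0 * D * dt);
  int irec = 0, ihist = 0;
  long step = 0;
  RNGScope scope;

  for (int it = 1; it <= n_iter; it++) {
    std::fill(S.begin(), S.end(), 0.0);
    std::fill(S2.begin(), S2.end(), 0.0);
    // curvature direction: the instantaneous iterate's offset from the
    // average, fixed over the stride
    for (int k = 0; k < K; k++) v[k] = a_inst[k] - a_bar[k];
    const double *Aact = average_bias ? a_bar.data() : a_inst.data();
    for (int s = 0; s < stride; s++) {
      step++;
      double U, gp, gs;
      pot_eval(P, phi, psi, &U, &gp, &gs);
      basis_dim(phi, N, f.data(), df.data());
      basis_dim(psi, N, g.data(), dg.data());
      for (int b = 0; b < M; b++) {
        double acc = 0.0, dacc = 0.0;
        const double *col = Aact + (size_t)b * M;
        for (int a = 0; a < M; a++) { acc += col[a] * f[a]; dacc += col[a] * df[a]; }
        gp += dacc * g[b];
        gs += acc * dg[b];
      }
      // accumulate basis means of the configuration *before* the step
      double fv = 0.0;
      if (curvature) {
        for (int b = 0; b < M; b++) {
          double gb = g[b];
          const double *vcol = v.data() + (size_t)b * M;
          double acc = 0.0;
          for (int a = 0; a < M; a++) acc += vcol[a] * f[a];
          fv += acc * gb;
        }
      }
      for (int b = 0; b < M; b++) {
        double gb = g[b];
        double *Srow = S.data() + (size_t)b * M;
        double *S2row = S2.data() + (size_t)b * M;
        for (int a = 0; a < M; a++) {
          double fk = f[a] * gb;
          Srow[a] += fk;
          if (curvature) S2row[a] += fk * fv;
        }
      }
      phi = wrap_pi_c(phi - pref * gp + sig * norm_rand());
      psi = wrap_pi_c(psi - pref * gs + sig * norm_rand());
      if (step % record_stride == 0 && irec < nrec) {
        basis_dim(phi, N, f.data(), df.data());
        basis_dim(psi, N, g.data(), dg.data());
        double Vr = 0.0;
        for (int b = 0; b < M; b++) {
          double acc = 0.0;
          const double *col = Aact + (size_t)b * M;
          for (int a = 0; a < M; a++) acc += col[a] * f[a];
          Vr += acc * g[b];
        }
        traj(irec, 0) = (double)step * dt;
        traj(irec, 1) = phi;
        traj(irec, 2) = psi;
        traj(irec, 3) = Vr;
        irec++;
      }
    }
    // gradient (at the averaged iterate) plus the curvature correction
    //   H v ~ beta * ( <f (f.v)> - <f><f.v> )
    // of Bach-Moulines averaged stochastic gradient descent
    double fbar_dot_v = 0.0;
    if (curvature)
      for (int k = 0; k < K; k++) fbar_dot_v += (S[k] / stride) * v[k];
    for (int k = 0; k < K; k++) {
      double fbar = S[k] / stride;
      double grad = -fbar;
      if (k == 0) grad += 1.0;  // uniform-target term on the constant function
      if (curvature)
        grad += beta * (S2[k] / stride - fbar * fbar_dot_v);
      a_inst[k] -= mu * grad;
      // Iterate averaging begins at avg_start; before that the acting bias
      // is the instantaneous iterate (fill stage).
      if (it < avg_start)
        a_bar[k] = a_inst[k];
      else
        a_bar[k] += (a_inst[k] - a_bar[k]) / (it - avg_start + 1);
    }
    if (it % history_stride == 0 && ihist < nhist) {
      const double *rep = average_bias ? a_bar.data() : a_inst.data();
      for (int k = 0; k < K; k++) hist(ihist, k) = rep[k];
      hist_iter[ihist] = it;
      ihist++;
    }
  }

  NumericMatrix Ainst(M, M), Abar(M, M);
  for (int b = 0; b < M; b++)
    for (int a = 0; a < M; a++) {
      Ainst(a, b) = a_inst[a + (size_t)b * M];
      Abar(a, b) = a_bar[a + (size_t)b * M];
    }
  return List::create(_["traj"] = traj, _["alpha_inst"] = Ainst,
                      _["alpha_bar"] = Abar, _["history"] = hist,
                      _["history_iter"] = hist_iter);
}

// ---------------------------------------------------------------------------
// Minimax ("widest path" dual) barrier on a periodic grid with 4-connectivity.
// Returns the minimum over paths of the maximum F along the path (including
// both endpoints). NA bins are impassable. Returns NA if end is unreachable.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".minimax_core")]]
double minimax_core(NumericMatrix F, int si, int sj, int ei, int ej) {
  int nr = F.nrow(), nc = F.ncol();
  int n = nr * nc;
  std::vector<double> dist((size_t)n, R_PosInf);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  int start = si + nr * sj, end = ei + nr * ej;
  if (NumericVector::is_na(F[start]) || NumericVector::is_na(F[end]))
    return NA_REAL;
  dist[start] = F[start];
  pq.push(Node(dist[start], start));
  int di[4] = {1, -1, 0, 0};
  int dj[4] = {0, 0, 1, -1};
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = top.first;
    int u = top.second;
    if (d > dist[u]) continue;
    if (u == end) return d;
    int ui = u % nr, uj = u / nr;
    for (int t = 0; t < 4; t++) {
      int vi = (ui + di[t] + nr) % nr;
      int vj = (uj + dj[t] + nc) % nc;
      int v = vi + nr * vj;
      double Fv = F[v];
      if (NumericVector::is_na(Fv)) continue;
      double nd = d > Fv ? d : Fv;
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(Node(nd, v));
      }
    }
  }
  return NA_REAL;
}
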