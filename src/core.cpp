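// Compiled core of the polarimetric tomography forward model and its
// analytic gradient.
//
// Conventions shared with the R layer:
//  * lab frame (k, j, p): k = (1,0,0) transverse, j = (0,1,0) vertical
//    rotation axis, p = (0,0,1) beam direction;
//  * R_s = R_k(beta) * R_j(alpha) maps object-frame vectors to the lab;
//  * rays are sampled at a fixed step of one voxel size along p with
//    nearest-neighbour lookup in the object frame; every in-grid sample
//    contributes one retarder matrix with path length d;
//  * Mueller matrices are stored column-major (R layout), and the chain
//    along a ray composes left-multiplicatively: the voxel nearest the
//    sensor is the leftmost factor;
//  * intensities are normalised so that the co-polarized empty-path
//    maximum equals 1 (the `norm` factor supplied by the R layer).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void mat_mult(const double* A, const double* B, double* C) {
  for (int c = 0; c < 4; ++c)
    for (int r = 0; r < 4; ++r) {
      double s = 0;
      for (int k = 0; k < 4; ++k) s += A[k * 4 + r] * B[c * 4 + k];
      C[c * 4 + r] = s;
    }
}

static inline void row_mat(const double* q, const double* M, double* out) {
  for (int c = 0; c < 4; ++c) {
    double s = 0;
    for (int r = 0; r < 4; ++r) s += q[r] * M[c * 4 + r];
    out[c] = s;
  }
}

static inline void mat_col(const double* M, const double* v, double* out) {
  for (int r = 0; r < 4; ++r) {
    double s = 0;
    for (int c = 0; c < 4; ++c) s += M[c * 4 + r] * v[c];
    out[r] = s;
  }
}

static inline double row_mat_col(const double* q, const double* M,
                                 const double* v) {
  double s = 0;
  for (int c = 0; c < 4; ++c) {
    double mc = 0;
    for (int r = 0; r < 4; ++r) mc += q[r] * M[c * 4 + r];
    s += mc * v[c];
  }
  return s;
}

static inline void set_identity(double* M) {
  for (int i = 0; i < 16; ++i) M[i] = 0;
  M[0] = M[5] = M[10] = M[15] = 1;
}

// R_s, row-major 3x3 (R[r*3+c]); object -> lab.
static void rot_rs(double alpha, double beta, double* R) {
  double ca = std::cos(alpha), sa = std::sin(alpha);
  double cb = std::cos(beta), sb = std::sin(beta);
  R[0] = ca;       R[1] = 0;   R[2] = sa;
  R[3] = sb * sa;  R[4] = cb;  R[5] = -sb * ca;
  R[6] = -cb * sa; R[7] = sb;  R[8] = cb * ca;
}

// Per-voxel retarder matrix and (optionally) every derivative factor the
// analytic gradient of the intensity loss needs.
struct VoxOpt {
  double M[16];
  double dMdth[16], dMddel[16];
  double ddel_dphi, ddel_dpsi, ddel_dne, dth_dphi, dth_dpsi;
  bool identity;  // delta == 0 and no absorption: M is the identity
};

static void voxel_matrices(double phi, double psi, double ne, double A,
                           const double* R, double n_o, double fac,
                           bool want_grad, VoxOpt& o) {
  const double sp = std::sin(phi), cp = std::cos(phi);
  const double sps = std::sin(psi), cps = std::cos(psi);
  const double c0 = sp * cps, c1 = sp * sps, c2v = cp;
  // lab-frame c-axis and its transverse components
  const double clx = R[0] * c0 + R[1] * c1 + R[2] * c2v;
  const double cly = R[3] * c0 + R[4] * c1 + R[5] * c2v;
  const double clz = R[6] * c0 + R[7] * c1 + R[8] * c2v;

  const double g = clz;                       // cos(angle to beam)
  const double dn2 = ne * ne - n_o * n_o;
  const double D = n_o * n_o + dn2 * g * g;
  const double sqrtD = std::sqrt(D);
  const double nE = n_o * ne / sqrtD;
  const double delta = fac * (nE - n_o);

  const double rho2 = clx * clx + cly * cly;
  const double theta = (rho2 < 1e-24) ? 0.0 : std::atan2(cly, clx);

  const double t = std::exp(-A);
  const double co2 = std::cos(2 * theta), si2 = std::sin(2 * theta);
  const double cd = std::cos(delta), sd = std::sin(delta);

  double* M = o.M;
  for (int i = 0; i < 16; ++i) M[i] = 0;
  M[0 * 4 + 0] = t;
  M[1 * 4 + 1] = t * (co2 * co2 + cd * si2 * si2);
  M[2 * 4 + 1] = t * (1 - cd) * co2 * si2;
  M[3 * 4 + 1] = -t * sd * si2;
  M[1 * 4 + 2] = t * (1 - cd) * co2 * si2;
  M[2 * 4 + 2] = t * (cd * co2 * co2 + si2 * si2);
  M[3 * 4 + 2] = t * co2 * sd;
  M[1 * 4 + 3] = t * sd * si2;
  M[2 * 4 + 3] = -t * co2 * sd;
  M[3 * 4 + 3] = t * cd;
  // physical per-voxel retardances are >~1e-3 rad; anything at rounding
  // level comes from ne == n_o background voxels
  o.identity = (std::fabs(delta) < 1e-12 && A == 0.0);

  if (!want_grad) return;

  // dM/ddelta, dM/dtheta: element-wise derivatives of the closed form
  double* Dd = o.dMddel;
  double* Dt = o.dMdth;
  for (int i = 0; i < 16; ++i) { Dd[i] = 0; Dt[i] = 0; }
  Dd[1 * 4 + 1] = -t * sd * si2 * si2;
  Dd[2 * 4 + 1] = t * sd * co2 * si2;
  Dd[3 * 4 + 1] = -t * cd * si2;
  Dd[1 * 4 + 2] = t * sd * co2 * si2;
  Dd[2 * 4 + 2] = -t * sd * co2 * co2;
  Dd[3 * 4 + 2] = t * co2 * cd;
  Dd[1 * 4 + 3] = t * cd * si2;
  Dd[2 * 4 + 3] = -t * co2 * cd;
  Dd[3 * 4 + 3] = -t * sd;

  const double c4 = co2 * co2 - si2 * si2;  // cos(4 theta)
  Dt[1 * 4 + 1] = -4 * t * co2 * si2 * (1 - cd);
  Dt[2 * 4 + 1] = 2 * t * (1 - cd) * c4;
  Dt[3 * 4 + 1] = -2 * t * sd * co2;
  Dt[1 * 4 + 2] = 2 * t * (1 - cd) * c4;
  Dt[2 * 4 + 2] = 4 * t * co2 * si2 * (1 - cd);
  Dt[3 * 4 + 2] = -2 * t * si2 * sd;
  Dt[1 * 4 + 3] = 2 * t * sd * co2;
  Dt[2 * 4 + 3] = 2 * t * si2 * sd;

  // chain factors: derivatives of delta and theta w.r.t. (phi, psi, n_e).
  // d c / d phi and d c / d psi in the object frame, rotated to the lab.
  const double dphi0 = cp * cps, dphi1 = cp * sps, dphi2 = -sp;
  const double dpsi0 = -sp * sps, dpsi1 = sp * cps, dpsi2 = 0.0;
  const double dclx_p = R[0] * dphi0 + R[1] * dphi1 + R[2] * dphi2;
  const double dcly_p = R[3] * dphi0 + R[4] * dphi1 + R[5] * dphi2;
  const double dclz_p = R[6] * dphi0 + R[7] * dphi1 + R[8] * dphi2;
  const double dclx_s = R[0] * dpsi0 + R[1] * dpsi1 + R[2] * dpsi2;
  const double dcly_s = R[3] * dpsi0 + R[4] * dpsi1 + R[5] * dpsi2;
  const double dclz_s = R[6] * dpsi0 + R[7] * dpsi1 + R[8] * dpsi2;

  // n_E as a function of g = cos(phi_angle): the 1/sin(phi_angle)
  // singularity of d(arccos) cancels analytically, so differentiate in g.
  const double D32 = sqrtD * D;
  const double ddel_dg = -fac * n_o * ne * dn2 * g / D32;
  double s2g = 1 - g * g;
  if (s2g < 0) s2g = 0;
  o.ddel_dne = fac * n_o * n_o * n_o * s2g / D32;
  o.ddel_dphi = ddel_dg * dclz_p;
  o.ddel_dpsi = ddel_dg * dclz_s;

  if (rho2 < 1e-24) {
    // c parallel to the beam: theta is irrelevant (delta -> 0 there) and
    // dM/dtheta vanishes at the same rate; drop the singular factor.
    o.dth_dphi = 0;
    o.dth_dpsi = 0;
  } else {
    o.dth_dphi = (clx * dcly_p - cly * dclx_p) / rho2;
    o.dth_dpsi = (clx * dcly_s - cly * dclx_s) / rho2;
  }
}

// Geometry of one scan: shared nearest-neighbour ray sampler.
struct Sampler {
  int nx, ny, nz, nk, nj, nsteps;
  double R[9];
  double cxk, cxj, cxt, ox, oy, oz;
  void init(int nx_, int ny_, int nz_, int nk_, int nj_, double alpha,
            double beta) {
    nx = nx_; ny = ny_; nz = nz_; nk = nk_; nj = nj_;
    nsteps = (int)std::ceil(std::sqrt((double)nx * nx + (double)ny * ny +
                                      (double)nz * nz)) + 3;
    // keep (nsteps - nz) even so that axis-aligned samples coincide with
    // voxel centers (no half-voxel offset at alpha = beta = 0)
    if ((nsteps - nz) % 2 != 0) ++nsteps;
    rot_rs(alpha, beta, R);
    cxk = (nk - 1) / 2.0; cxj = (nj - 1) / 2.0; cxt = (nsteps - 1) / 2.0;
    ox = (nx - 1) / 2.0; oy = (ny - 1) / 2.0; oz = (nz - 1) / 2.0;
  }
  // voxel linear index for sample m of pixel (ik, ij), or -1 if outside
  inline int sample(int ik, int ij, int m) const {
    const double lx = ik - cxk, ly = ij - cxj, lz = m - cxt;
    // object = R_s^T * lab
    const double x = R[0] * lx + R[3] * ly + R[6] * lz + ox;
    const double y = R[1] * lx + R[4] * ly + R[7] * lz + oy;
    const double z = R[2] * lx + R[5] * ly + R[8] * lz + oz;
    const int ix = (int)std::lround(x);
    const int iy = (int)std::lround(y);
    const int iz = (int)std::lround(z);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
      return -1;
    return ix + nx * (iy + ny * iz);
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_ray_path(IntegerVector dims, double alpha, double beta,
                           int ik, int ij, int nk, int nj) {
  Sampler s;
  s.init(dims[0], dims[1], dims[2], nk, nj, alpha, beta);
  std::vector<int> hits;
  for (int m = 0; m < s.nsteps; ++m) {
    int v = s.sample(ik - 1, ij - 1, m);
    if (v >= 0) hits.push_back(v);
  }
  IntegerMatrix out(hits.size(), 3);
  for (size_t i = 0; i < hits.size(); ++i) {
    int v = hits[i];
    out(i, 0) = v % dims[0] + 1;
    out(i, 1) = (v / dims[0]) % dims[1] + 1;
    out(i, 2) = v / (dims[0] * dims[1]) + 1;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_project_mueller(NumericVector phi, NumericVector psi,
                                  NumericVector ne, NumericVector A,
                                  IntegerVector dims, double n_o, double fac,
                                  double alpha, double beta, int nk, int nj) {
  Sampler s;
  s.init(dims[0], dims[1], dims[2], nk, nj, alpha, beta);
  NumericVector out(16 * nk * nj);
  out.attr("dim") = IntegerVector::create(4, 4, nk, nj);
  VoxOpt vo;
  double P[16], T[16];
  for (int ij = 0; ij < nj; ++ij)
    for (int ik = 0; ik < nk; ++ik) {
      set_identity(P);
      for (int m = 0; m < s.nsteps; ++m) {
        int v = s.sample(ik, ij, m);
        if (v < 0) continue;
        voxel_matrices(phi[v], psi[v], ne[v], A[v], s.R, n_o, fac, false, vo);
        if (vo.identity) continue;
        mat_mult(vo.M, P, T);  // later voxels multiply on the left
        std::copy(T, T + 16, P);
      }
      std::copy(P, P + 16, out.begin() + 16 * (ik + nk * ij));
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_forward(NumericVector phi, NumericVector psi,
                          NumericVector ne, NumericVector A,
                          IntegerVector dims, double n_o, double fac,
                          NumericVector alphas, NumericVector betas, int nk,
                          int nj, NumericVector gen, NumericVector ana,
                          double norm) {
  const int nproj = alphas.size();
  NumericVector out((R_xlen_t)nk * nj * 16 * nproj);
  out.attr("dim") = IntegerVector::create(nk, nj, 16, nproj);
  // analyzer rows S^T M_PSA and generator columns M_PSG S
  double arow[16][4], gcol[16][4];
  for (int l = 0; l < 16; ++l)
    for (int i = 0; i < 4; ++i) {
      arow[l][i] = ana[16 * l + 4 * i + 0];  // row 0 of analyzer matrix
      gcol[l][i] = gen[16 * l + 4 * 0 + i];  // col 0 of generator matrix
    }
  VoxOpt vo;
  double P[16], T[16], b[4];
  for (int ip = 0; ip < nproj; ++ip) {
    Sampler s;
    s.init(dims[0], dims[1], dims[2], nk, nj, alphas[ip], betas[ip]);
    for (int ij = 0; ij < nj; ++ij)
      for (int ik = 0; ik < nk; ++ik) {
        set_identity(P);
        for (int m = 0; m < s.nsteps; ++m) {
          int v = s.sample(ik, ij, m);
          if (v < 0) continue;
          voxel_matrices(phi[v], psi[v], ne[v], A[v], s.R, n_o, fac, false,
                         vo);
          if (vo.identity) continue;
          mat_mult(vo.M, P, T);
          std::copy(T, T + 16, P);
        }
        for (int l = 0; l < 16; ++l) {
          mat_col(P, gcol[l], b);
          double I = 0;
          for (int i = 0; i < 4; ++i) I += arow[l][i] * b[i];
          out[ik + (R_xlen_t)nk * (ij + (R_xlen_t)nj * (l + 16 * ip))] =
              norm * I;
        }
      }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_gradient(NumericVector phi, NumericVector psi, NumericVector ne,
                  NumericVector A, IntegerVector dims, double n_o, double fac,
                  NumericVector alphas, NumericVector betas, int nk, int nj,
                  NumericVector gen, NumericVector ana, double norm,
                  NumericVector measured, IntegerVector proj_idx) {
  const int nvox = dims[0] * dims[1] * dims[2];
  NumericVector gphi(nvox), gpsi(nvox), gne(nvox);
  double arow[16][4], gcol[16][4];
  for (int l = 0; l < 16; ++l)
    for (int i = 0; i < 4; ++i) {
      arow[l][i] = ana[16 * l + 4 * i + 0];
      gcol[l][i] = gen[16 * l + 4 * 0 + i];
    }
  double eps = 0;
  std::vector<int> vox;
  std::vector<VoxOpt> ops;
  std::vector<double> qs, vs;  // per-sample 4-vectors for one pol set
  for (int s_i = 0; s_i < proj_idx.size(); ++s_i) {
    const int ip = proj_idx[s_i];
    Sampler s;
    s.init(dims[0], dims[1], dims[2], nk, nj, alphas[ip], betas[ip]);
    for (int ij = 0; ij < nj; ++ij)
      for (int ik = 0; ik < nk; ++ik) {
        vox.clear();
        for (int m = 0; m < s.nsteps; ++m) {
          int v = s.sample(ik, ij, m);
          if (v >= 0) vox.push_back(v);
        }
        const int N = (int)vox.size();
        if (ops.size() < (size_t)N) ops.resize(N);
        for (int p = 0; p < N; ++p)
          voxel_matrices(phi[vox[p]], psi[vox[p]], ne[vox[p]], A[vox[p]], s.R,
                         n_o, fac, true, ops[p]);
        qs.assign((size_t)4 * std::max(N, 1), 0.0);
        vs.assign((size_t)4 * std::max(N, 1), 0.0);
        for (int l = 0; l < 16; ++l) {
          double Ihat;
          if (N == 0) {
            double I0 = 0;
            for (int i = 0; i < 4; ++i) I0 += arow[l][i] * gcol[l][i];
            Ihat = I0;
          } else {
            // q_p = S^T M_PSA M_N ... M_{p+1};  v_p = M_{p-1} ... M_1 M_PSG S
            std::copy(arow[l], arow[l] + 4, &qs[4 * (N - 1)]);
            for (int p = N - 2; p >= 0; --p)
              row_mat(&qs[4 * (p + 1)], ops[p + 1].M, &qs[4 * p]);
            std::copy(gcol[l], gcol[l] + 4, &vs[0]);
            for (int p = 1; p < N; ++p)
              mat_col(ops[p - 1].M, &vs[4 * (p - 1)], &vs[4 * p]);
            Ihat = row_mat_col(&qs[4 * (N - 1)], ops[N - 1].M,
                               &vs[4 * (N - 1)]);
          }
          const double Imeas =
              measured[ik +
                       (R_xlen_t)nk * (ij + (R_xlen_t)nj * (l + 16 * ip))];
          const double diff = norm * Ihat - Imeas;
          eps += diff * diff;
          const double coeff = 2.0 * diff * norm;
          for (int p = 0; p < N; ++p) {
            const VoxOpt& o = ops[p];
            const double st = row_mat_col(&qs[4 * p], o.dMdth, &vs[4 * p]);
            const double sdl = row_mat_col(&qs[4 * p], o.dMddel, &vs[4 * p]);
            const int v = vox[p];
            gphi[v] += coeff * (st * o.dth_dphi + sdl * o.ddel_dphi);
            gpsi[v] += coeff * (st * o.dth_dpsi + sdl * o.ddel_dpsi);
            gne[v] += coeff * sdl * o.ddel_dne;
          }
        }
      }
  }
  gphi.attr("dim") = dims;
  gpsi.attr("dim") = dims;
  gne.attr("dim") = dims;
  return List::create(_["eps_i"] = eps, _["phi"] = gphi, _["psi"] = gpsi,
                      _["n_e"] = gne);
}

// Straight-ray line integrals (unit sample length) of a scalar volume,
// used by the absorption tomography.
// [[Rcpp::export]]
NumericVector cpp_project_lines(NumericVector vol, IntegerVector dims,
                                NumericVector alphas, NumericVector betas,
                                int nk, int nj) {
  const int nproj = alphas.size();
  NumericVector out((R_xlen_t)nk * nj * nproj);
  out.attr("dim") = IntegerVector::create(nk, nj, nproj);
  for (int ip = 0; ip < nproj; ++ip) {
    Sampler s;
    s.init(dims[0], dims[1], dims[2], nk, nj, alphas[ip], betas[ip]);
    for (int ij = 0; ij < nj; ++ij)
      for (int ik = 0; ik < nk; ++ik) {
        double acc = 0;
        for (int m = 0; m < s.nsteps; ++m) {
          int v = s.sample(ik, ij, m);
          if (v >= 0) acc += vol[v];
        }
        out[ik + (R_xlen_t)nk * (ij + (R_xlen_t)nj * ip)] = acc;
      }
  }
  return out;
}

// Adjoint of cpp_project_lines.
// [[Rcpp::export]]
NumericVector cpp_backproject_lines(NumericVector img, IntegerVector dims,
                                    NumericVector alphas, NumericVector betas,
                                    int nk, int nj) {
  const int nproj = alphas.size();
  NumericVector vol(dims[0] * dims[1] * dims[2]);
  for (int ip = 0; ip < nproj; ++ip) {
    Sampler s;
    s.init(dims[0], dims[1], dims[2], nk, nj, alphas[ip], betas[ip]);
    for (int ij = 0; ij < nj; ++ij)
      for (int ik = 0; ik < nk; ++ik) {
        const double w =
            img[ik + (R_xlen_t)nk * (ij + (R_xlen_t)nj * ip)];
        if (w == 0) continue;
        for (int m = 0; m < s.nsteps; ++m) {
          int v = s.sample(ik, ij, m);
          if (v >= 0) vol[v] += w;
        }
      }
  }
  vol.attr("dim") = dims;
  return vol;
}
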