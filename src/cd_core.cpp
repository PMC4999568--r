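#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Coordinate descent on the Gram formulation of
//   min_theta ||y - A theta||^2 + lam * ||theta||_1
// with G = A'A, g = A'y.  theta is updated in place (warm start).
// Columns with G(j,j) == 0 (all-zero columns) are pinned at zero.
// Convergence: a full sweep changes no coefficient by tol or more;
// between full sweeps, iteration is restricted to the active set.
// Returns the number of sweeps used.
static int cd_solve(const mat& G, const vec& g, double lam, vec& theta,
                    double tol, int max_iter, bool& converged,
                    std::vector<double>* obj_trace = nullptr,
                    double yty = 0.0) {
  const uword m = G.n_cols;
  const double thr = lam / 2.0;
  vec Gt = G * theta;

  auto sweep_over = [&](const uvec& idx) -> double {
    double maxdel = 0.0;
    for (uword t = 0; t < idx.n_elem; ++t) {
      const uword j = idx[t];
      const double gjj = G(j, j);
      if (gjj <= 0.0) { theta[j] = 0.0; continue; }
      const double cj = g[j] - Gt[j] + gjj * theta[j];
      double bj = 0.0;
      if (cj > thr) bj = (cj - thr) / gjj;
      else if (cj < -thr) bj = (cj + thr) / gjj;
      const double del = bj - theta[j];
      if (del != 0.0) {
        Gt += del * G.col(j);
        theta[j] = bj;
        const double adel = std::fabs(del);
        if (adel > maxdel) maxdel = adel;
      }
    }
    return maxdel;
  };

  const uvec all = regspace<uvec>(0, m - 1);
  converged = false;
  int it = 0;
  while (it < max_iter) {
    const double maxdel = sweep_over(all);
    ++it;
    if (obj_trace) {
      obj_trace->push_back(yty - 2.0 * dot(g, theta) +
                           dot(theta, G * theta) + lam * norm(theta, 1));
    }
    if (maxdel < tol) { converged = true; break; }
    // iterate on the current active set until stable, then re-check all
    uvec act = find(theta != 0.0);
    if (act.n_elem > 0 && act.n_elem < m) {
      while (it < max_iter) {
        const double d = sweep_over(act);
        ++it;
        if (obj_trace) {
          obj_trace->push_back(yty - 2.0 * dot(g, theta) +
                               dot(theta, G * theta) + lam * norm(theta, 1));
        }
        if (d < tol) break;
      }
    }
  }
  return it;
}

// Solve the lasso along a (descending) lambda sequence with warm starts.
// [[Rcpp::export]]
Rcpp::List cpp_cd_path(const arma::mat& G, const arma::vec& g,
                       const arma::vec& lambdas, double tol, int max_iter,
                       const arma::vec& theta0) {
  const uword m = G.n_cols, L = lambdas.n_elem;
  mat thetas(m, L);
  ivec iters(L);
  uvec conv(L);
  vec theta = theta0;
  for (uword l = 0; l < L; ++l) {
    bool ok = false;
    iters[l] = cd_solve(G, g, lambdas[l], theta, tol, max_iter, ok);
    conv[l] = ok ? 1u : 0u;
    thetas.col(l) = theta;
  }
  return Rcpp::List::create(Rcpp::Named("theta") = thetas,
                            Rcpp::Named("iters") = iters,
                            Rcpp::Named("converged") = conv);
}

// Per-sweep objective values for a single lambda (cold start).
// [[Rcpp::export]]
arma::vec cpp_cd_obj_trace(const arma::mat& G, const arma::vec& g, double yty,
                           double lambda, double tol, int max_iter) {
  vec theta(G.n_cols, fill::zeros);
  std::vector<double> trace;
  bool ok = false;
  cd_solve(G, g, lambda, theta, tol, max_iter, ok, &trace, yty);
  return vec(trace);
}

// Penalty-free generalized-lasso blocks in the Gram formulation.
// The design is augmented with an intercept column; idx_b indexes the free
// block (intercept + penalty-free features), idx_a the penalized block
// (0-based into the augmented p+1 columns).  Reduction: project the
// penalized columns onto the orthogonal complement of the free block
// (P = X_b (X_b'X_b)^+ X_b'), solve a standard lasso for theta_a on the
// projected problem, then back-solve beta_b = (X_b'X_b)^+ X_b'(y - X_a theta_a).
static void pf_blocks(const mat& G, const vec& g, const uvec& idx_b,
                      const uvec& idx_a, mat& Mb, mat& Gba, mat& Gat,
                      vec& gat, vec& gb, bool& rank_deficient) {
  mat Gbb = G.submat(idx_b, idx_b);
  gb = g(idx_b);
  rank_deficient = (arma::rank(Gbb) < Gbb.n_rows);
  if (!pinv(Mb, Gbb)) Rcpp::stop("pseudoinverse of the free block failed");
  if (idx_a.n_elem > 0) {
    Gba = G.submat(idx_b, idx_a);     // nb x na
    mat W = Mb * Gba;                 // nb x na
    Gat = G.submat(idx_a, idx_a) - Gba.t() * W;
    Gat = 0.5 * (Gat + Gat.t());
    gat = g(idx_a) - W.t() * gb;
  } else {
    Gba.reset(); Gat.reset(); gat.reset();
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_fit_pf(const arma::mat& G, const arma::vec& g,
                      const arma::uvec& idx_b, const arma::uvec& idx_a,
                      const arma::vec& lambdas, double tol, int max_iter) {
  mat Mb, Gba, Gat;
  vec gat, gb;
  bool rank_def = false;
  pf_blocks(G, g, idx_b, idx_a, Mb, Gba, Gat, gat, gb, rank_def);
  const uword L = lambdas.n_elem, na = idx_a.n_elem, nb = idx_b.n_elem;
  mat thetas(na, L, fill::zeros), betab(nb, L);
  ivec iters(L, fill::zeros);
  uvec conv(L, fill::ones);
  vec theta(na, fill::zeros);
  for (uword l = 0; l < L; ++l) {
    if (na > 0) {
      bool ok = false;
      iters[l] = cd_solve(Gat, gat, lambdas[l], theta, tol, max_iter, ok);
      conv[l] = ok ? 1u : 0u;
      thetas.col(l) = theta;
      betab.col(l) = Mb * (gb - Gba * theta);
    } else {
      betab.col(l) = Mb * gb;
    }
  }
  return Rcpp::List::create(Rcpp::Named("theta") = thetas,
                            Rcpp::Named("beta_b") = betab,
                            Rcpp::Named("iters") = iters,
                            Rcpp::Named("converged") = conv,
                            Rcpp::Named("rank_deficient") = rank_def);
}

// Exact piecewise-linear lasso path (LARS-lasso homotopy) on the Gram
// formulation, evaluated at a descending lambda grid.  On the active set A
// with signs s, theta_A(lam) = v - (lam/2) u with u = G_AA^{-1} s,
// v = G_AA^{-1} g_A; events are coefficient sign changes (drops) and
// inactive gradients hitting the boundary |2(g - G theta)_j| = lam (adds).
// Scores for a held-out sample are linear in lambda within a segment.
// Returns false on numerical breakdown (caller falls back to coordinate
// descent).
// Incremental Cholesky of the active-set Gram: R is upper triangular with
// R'R = Gat(A, A), maintained under feature additions (rank-1 extension)
// and removals (column deletion + Givens re-triangularization).
struct ActiveChol {
  mat R;                 // capacity x capacity, upper triangular in use
  uword m = 0;           // current active count
  explicit ActiveChol(uword cap) : R(cap, cap, fill::zeros) {}

  // append variable with Gram column c (length m) and diagonal gjj
  bool add(const vec& c, double gjj) {
    // solve R' w = c by forward substitution on the transposed factor
    for (uword i = 0; i < m; ++i) {
      double s = c[i];
      for (uword k = 0; k < i; ++k) s -= R(k, i) * R(k, m);
      R(i, m) = s / R(i, i);
    }
    double d2 = gjj;
    for (uword k = 0; k < m; ++k) d2 -= R(k, m) * R(k, m);
    if (d2 <= 1e-12 * (gjj + 1.0)) return false;
    R(m, m) = std::sqrt(d2);
    ++m;
    return true;
  }

  // remove variable at active position t
  void drop(uword t) {
    for (uword j = t; j + 1 < m; ++j) R.col(j) = R.col(j + 1);
    --m;
    for (uword j = t; j < m; ++j) {   // re-triangularize rows j, j+1
      const double a = R(j, j), b = R(j + 1, j);
      double r = std::hypot(a, b);
      if (r == 0.0) continue;
      const double cth = a / r, sth = b / r;
      for (uword k = j; k < m; ++k) {
        const double x = R(j, k), y = R(j + 1, k);
        R(j, k) = cth * x + sth * y;
        R(j + 1, k) = -sth * x + cth * y;
      }
      R(j, j) = std::fabs(R(j, j));
    }
  }

  // solve (R'R) x = b
  void solve_sym(const double* b, double* x) const {
    for (uword i = 0; i < m; ++i) {           // forward: R' z = b
      double s = b[i];
      for (uword k = 0; k < i; ++k) s -= R(k, i) * x[k];
      x[i] = s / R(i, i);
    }
    for (uword ii = m; ii-- > 0;) {           // backward: R x = z
      double s = x[ii];
      for (uword k = ii + 1; k < m; ++k) s -= R(ii, k) * x[k];
      x[ii] = s / R(ii, ii);
    }
  }
};

static bool homotopy_scores(const mat& Gat, const vec& gat, const mat& Mb,
                            const mat& Gba, const vec& gb, const vec& xb,
                            const vec& xa, const vec& lambdas, rowvec& out) {
  const uword na = gat.n_elem, L = lambdas.n_elem;
  const double lam_max = 2.0 * std::max(abs(gat).max(), 0.0);
  const double s0 = dot(xb, Mb * gb);
  uword gi = 0;
  while (gi < L && lambdas[gi] >= lam_max) out[gi++] = s0;
  if (gi >= L) return true;
  if (!(lam_max > 0)) { while (gi < L) out[gi++] = s0; return true; }

  const uword cap = std::min<uword>(na, Gat.n_rows) + 1;
  ActiveChol ch(cap);
  std::vector<uword> A;  A.reserve(cap);
  std::vector<double> sg; sg.reserve(cap);
  std::vector<char> inA(na, 0);
  std::vector<double> u(cap), v(cap), gA(cap), sv(cap);
  vec w1(na), w2(na);
  // score(lam) = sc0 + sc1*lam; precompute Mb-dependent pieces per event
  const vec Mbxb = Mb.t() * xb;        // for dot(xb, Mb * z) = dot(Mbxb, z)
  const double xbMgb = dot(Mbxb, gb);

  {
    const uword j0 = index_max(abs(gat));
    if (!ch.add(vec(), Gat(j0, j0))) return false;
    A.push_back(j0);
    sg.push_back(gat[j0] > 0 ? 1.0 : -1.0);
    inA[j0] = 1;
  }
  double lam_hi = lam_max;
  const double lam_floor = lambdas[L - 1];
  const int max_events = 40 * static_cast<int>(na) + 200;
  for (int ev = 0; ev < max_events; ++ev) {
    const uword m = A.size();
    double sc0 = s0, sc1 = 0.0;
    if (m > 0) {
      for (uword t = 0; t < m; ++t) { gA[t] = gat[A[t]]; sv[t] = sg[t]; }
      ch.solve_sym(sv.data(), u.data());
      ch.solve_sym(gA.data(), v.data());
      // w1 = Gat(:,A) v, w2 = Gat(:,A) u as column accumulations
      w1.zeros(); w2.zeros();
      for (uword t = 0; t < m; ++t) {
        const double* col = Gat.colptr(A[t]);
        const double vt = v[t], ut = u[t];
        for (uword j = 0; j < na; ++j) {
          w1[j] += vt * col[j];
          w2[j] += ut * col[j];
        }
      }
      // score pieces with theta_A(lam) = v - (lam/2) u:
      //   score = xb'Mb gb - sum_t q_t theta_t + sum_t xa_t theta_t,
      //   q_t = (Mb' xb)' Gba(:, A[t])
      double xav = 0.0, xau = 0.0, qv = 0.0, qu = 0.0;
      for (uword t = 0; t < m; ++t) {
        const uword j = A[t];
        xav += xa[j] * v[t];
        xau += xa[j] * u[t];
        double q = 0.0;
        for (uword r = 0; r < Gba.n_rows; ++r) q += Mbxb[r] * Gba(r, j);
        qv += q * v[t];
        qu += q * u[t];
      }
      sc0 = xbMgb - qv + xav;
      sc1 = 0.5 * qu - 0.5 * xau;
    }
    // next event below lam_hi (strict decrease guards against cycling)
    const double guard = lam_hi * (1.0 - 1e-9);
    double lam_ev = -1.0;
    int ev_kind = 0;            // 1 = drop, 2 = add
    uword ev_j = 0;
    double ev_sign = 0.0;
    for (uword t = 0; t < m; ++t) {
      if (u[t] != 0.0) {
        const double lam = 2.0 * v[t] / u[t];
        if (lam > 0 && lam < guard && lam > lam_ev) {
          lam_ev = lam; ev_kind = 1; ev_j = t;
        }
      }
    }
    for (uword j = 0; j < na; ++j) {
      if (inA[j]) continue;
      const double a = 2.0 * (gat[j] - (m ? w1[j] : 0.0));
      const double b = m ? w2[j] : 0.0;
      const double den_p = 1.0 - b, den_m = 1.0 + b;
      if (den_p != 0.0) {
        const double lam = a / den_p;
        if (lam > 0 && lam < guard && lam > lam_ev) {
          lam_ev = lam; ev_kind = 2; ev_j = j; ev_sign = 1.0;
        }
      }
      if (den_m != 0.0) {
        const double lam = -a / den_m;
        if (lam > 0 && lam < guard && lam > lam_ev) {
          lam_ev = lam; ev_kind = 2; ev_j = j; ev_sign = -1.0;
        }
      }
    }
    // emit grid scores inside (lam_ev, lam_hi]
    const double seg_lo = (ev_kind == 0) ? (lam_floor - 1.0) : lam_ev;
    while (gi < L && lambdas[gi] > seg_lo) {
      out[gi] = sc0 + sc1 * lambdas[gi];
      ++gi;
    }
    if (gi >= L) return true;
    if (ev_kind == 0) return true;   // no further events; grid exhausted above
    if (ev_kind == 1) {
      inA[A[ev_j]] = 0;
      A.erase(A.begin() + ev_j);
      sg.erase(sg.begin() + ev_j);
      ch.drop(ev_j);
    } else {
      vec c(A.size());
      for (uword t = 0; t < A.size(); ++t) c[t] = Gat(A[t], ev_j);
      if (!ch.add(c, Gat(ev_j, ev_j))) return false;
      A.push_back(ev_j);
      sg.push_back(ev_sign);
      inA[ev_j] = 1;
    }
    lam_hi = lam_ev;
  }
  return false;
}

// Leave-one-out scores for a fixed free set across a lambda path.
// G: (p+1, p+1, n) cube of per-fold Grams of the augmented training design;
// gmat: (p+1, n) per-fold X'y; xh: (n, p+1) held-out augmented rows (scaled
// with the training fold's statistics).  Returns an (n, L) matrix of
// linear scores for the held-out samples.
//
// The first fold runs the path with warm starts along lambda; every later
// fold warm-starts each lambda from the previous fold's solution at the
// same lambda, which is typically 1-2 sweeps away.
// [[Rcpp::export]]
Rcpp::List cpp_loocv_scores(const arma::cube& G, const arma::mat& gmat,
                            const arma::mat& xh, const arma::uvec& idx_b,
                            const arma::uvec& idx_a, const arma::vec& lambdas,
                            double tol, int max_iter) {
  const uword n = G.n_slices, L = lambdas.n_elem, na = idx_a.n_elem;
  mat scores(n, L);
  bool all_conv = true;
  long total_iter = 0;
  for (uword f = 0; f < n; ++f) {
    mat Mb, Gba, Gat;
    vec gat, gb;
    bool rank_def = false;
    pf_blocks(G.slice(f), gmat.col(f), idx_b, idx_a, Mb, Gba, Gat, gat, gb,
              rank_def);
    vec xrow = xh.row(f).t();
    vec xb = xrow(idx_b);
    if (na > 0) {
      vec xa = xrow(idx_a);
      rowvec srow(L);
      bool done = homotopy_scores(Gat, gat, Mb, Gba, gb, xb, xa, lambdas, srow);
      if (!done) {
        // event cycling at a degenerate crossing: retry on a slightly
        // ridged Gram, which separates the tied events (score error is
        // of the order of the ridge)
        mat Gat_r = Gat;
        Gat_r.diag() += 1e-8 * (trace(Gat) / na + 1.0);
        done = homotopy_scores(Gat_r, gat, Mb, Gba, gb, xb, xa, lambdas, srow);
      }
      if (done) {
        scores.row(f) = srow;
      } else {
        // last resort: coordinate descent with warm starts along the
        // lambda sequence, at a scoring-grade tolerance
        const double tol_cv = std::max(tol, 1e-6);
        vec theta(na, fill::zeros);
        for (uword l = 0; l < L; ++l) {
          bool ok = false;
          total_iter += cd_solve(Gat, gat, lambdas[l], theta, tol_cv,
                                 max_iter, ok);
          if (!ok) all_conv = false;
          vec bb = Mb * (gb - Gba * theta);
          scores(f, l) = dot(xb, bb) + dot(xa, theta);
        }
      }
    } else {
      const double s = dot(xb, Mb * gb);
      scores.row(f).fill(s);
    }
  }
  return Rcpp::List::create(Rcpp::Named("scores") = scores,
                            Rcpp::Named("converged") = all_conv,
                            Rcpp::Named("total_iter") = total_iter);
}
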