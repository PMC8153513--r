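// Time integration of M theta'' + D theta' + K theta = F with Bernoulli
// surface loading and midline contact.
//
// Scheme: implicit Newmark (average acceleration, beta = 1/4, gamma = 1/2)
// written as a three-term recurrence,
//   M (t+ - 2 t0 + t-)/h^2 + D (t+ - t-)/(2h)
//     + K (t+ + 2 t0 + t-)/4 = F(t0),
// so the iteration matrix A = M/h^2 + D/(2h) + K/4 is constant and is
// factorized once per simulation.  The aerodynamic load is evaluated
// explicitly at the current state.  Contact follows the projection rule:
// any node whose x-position would cross the midline is forced onto it; the
// force required is the residual of the discrete momentum balance at that
// dof, and nodes whose residual turns tensile are released.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List integrate_fe(const arma::mat& M, const arma::mat& D,
                        const arma::mat& K, double h, int nsteps,
                        const arma::vec& theta0, const arma::vec& v0,
                        const arma::ivec& surf_x_dof,
                        const arma::ivec& surf_z_dof,
                        const arma::vec& surf_X, const arma::vec& surf_Z,
                        const arma::ivec& all_x_dof, const arma::vec& all_X,
                        double midline_mm, double l_gl_mm, double p_sub,
                        double p_sup, double a_floor, double rho_air,
                        bool contact_on, bool store_traj, int sep_mode,
                        bool follower_loads, double n_beta, double n_gamma) {
  const uword n = M.n_rows;
  const uword ns = surf_x_dof.n_elem;
  const int nsamp = nsteps + 1;

  // Newmark (beta, gamma) in three-term form; (1/4, 1/2) is the
  // energy-conserving average-acceleration member, gamma > 1/2 adds
  // high-frequency numerical dissipation (useful under contact impacts).
  // The load is evaluated at the current state (explicit aerodynamics).
  const double bb = n_beta, gg = n_gamma;
  mat A = M / (h * h) + gg * D / h + bb * K;
  mat B1 = 2.0 * M / (h * h) - (1.0 - 2.0 * gg) * D / h -
    (0.5 + gg - 2.0 * bb) * K;
  mat B2 = -M / (h * h) - (gg - 1.0) * D / h - (0.5 - gg + bb) * K;
  mat Ainv;
  if (!inv_sympd(Ainv, A))
    Rcpp::stop("iteration matrix not positive definite");

  // unique surface dofs (force vector support), for the fused update
  uvec sdof;
  if (ns > 0) {
    std::vector<uword> sd;
    for (uword i = 0; i < ns; ++i) {
      sd.push_back((uword)surf_x_dof(i));
      sd.push_back((uword)surf_z_dof(i));
    }
    std::sort(sd.begin(), sd.end());
    sd.erase(std::unique(sd.begin(), sd.end()), sd.end());
    sdof = uvec(sd);
  }
  const uword nsd = sdof.n_elem;
  // one fused operator: thp = CC * [th0; thm; F(sdof)]
  mat CC(n, 2 * n + nsd);
  CC.cols(0, n - 1) = Ainv * B1;
  CC.cols(n, 2 * n - 1) = Ainv * B2;
  if (nsd > 0) CC.cols(2 * n, 2 * n + nsd - 1) = Ainv.cols(sdof);

  vec th0 = theta0, thm(n), thp(n);

  vec gaw(nsamp, fill::zeros), amin(nsamp, fill::zeros), q(nsamp, fill::zeros);
  mat cforce(ns, nsamp, fill::zeros);  // N per metre depth, compressive >= 0
  mat traj, fstore;
  if (store_traj) {
    traj.zeros(n, nsamp);
    fstore.zeros(n, nsamp);
  }

  // surface state -> area profile, pressures, nodal force vector
  // (F is touched only on the ~2*ns surface dofs; callers pre-zero it once)
  vec xs(ns), zs(ns), Ap(ns), ps(ns), Araw(ns);
  auto aero = [&](const vec& th, vec& F, double& amin_out, double& qa_out) {
    if (ns < 2) { amin_out = datum::nan; qa_out = 0.0; return; }
    for (uword i = 0; i < ns; ++i) {
      F(surf_x_dof(i)) = 0.0;
      F(surf_z_dof(i)) = 0.0;
    }
    for (uword i = 0; i < ns; ++i) {
      xs(i) = surf_X(i) + 1e3 * th(surf_x_dof(i));
      zs(i) = surf_Z(i) + 1e3 * th(surf_z_dof(i));
      double a = 2.0 * (midline_mm - xs(i)) * l_gl_mm;
      Araw(i) = a > 0.0 ? a : 0.0;
      Ap(i) = a > a_floor ? a : a_floor;  // floored profile (diagnostics)
    }
    // Separation area from the true minimum (zero during contact): at full
    // closure A_sep = 0, every station is on the A >= A_sep branch and the
    // whole surface feels p_sub (no flow, stagnation); while open, stations
    // in the first branch have A in [A_min, 1.3 A_min) so the area ratio is
    // bounded by 1.69 and no division blow-up is possible.
    double Amin = Araw.min();
    double Asep = 1.3 * Amin;
    if (sep_mode == 1) {
      // variant: closed phase assigns p_sup strictly above the seal
      sword first_contact = -1;
      for (uword i = 0; i < ns; ++i)
        if (Araw(i) <= 0.0) { first_contact = i; break; }
      if (first_contact >= 0) {
        for (uword i = 0; i < ns; ++i)
          ps(i) = ((sword)i <= first_contact) ? p_sub : p_sup;
      } else {
        for (uword i = 0; i < ns; ++i)
          ps(i) = (Araw(i) < Asep)
            ? p_sub - (p_sub - p_sup) * (Asep / Araw(i)) * (Asep / Araw(i))
            : p_sub;
      }
    } else if (sep_mode == 3) {
      // smooth attached/separated channel law: Bernoulli pressure
      // p_sub - dp (A_sep/A)^2 upstream of the separation point (where the
      // divergent-channel area first reaches A_sep past the minimum) and
      // p_sup in the separated jet beyond it.  The attached value equals
      // p_sup exactly at A = A_sep, so the profile is continuous in the
      // areas; at full closure A_sep = 0 gives stagnation p_sub up to the
      // seal and p_sup beyond it.
      uword im = Araw.index_min();
      bool separated = false;
      double dp = p_sub - p_sup;
      for (uword i = 0; i < ns; ++i) {
        if (separated) { ps(i) = p_sup; continue; }
        if (Araw(i) <= 0.0) {
          ps(i) = (i <= im) ? p_sub : p_sup;
          if (i >= im) separated = true;
          continue;
        }
        if (i > im && Araw(i) >= Asep) {
          ps(i) = p_sup;
          separated = true;
          continue;
        }
        double r = Asep / Araw(i);
        ps(i) = p_sub - dp * r * r;
      }
    } else if (sep_mode == 2) {
      // jet variant: the flow detaches at the minimum section; stations
      // superior to it sit in the separated jet at p_sup, stations at and
      // below it follow the branch rule
      uword im = Araw.index_min();
      for (uword i = 0; i < ns; ++i) {
        if (i > im) { ps(i) = p_sup; continue; }
        ps(i) = (Araw(i) < Asep)
          ? p_sub - (p_sub - p_sup) * (Asep / Araw(i)) * (Asep / Araw(i))
          : p_sub;
      }
    } else {
      for (uword i = 0; i < ns; ++i)
        ps(i) = (Araw(i) < Asep)
          ? p_sub - (p_sub - p_sup) * (Asep / Araw(i)) * (Asep / Araw(i))
          : p_sub;
    }
    for (uword i = 0; i + 1 < ns; ++i) {
      double pe = 0.5 * (ps(i) + ps(i + 1));
      // surface tractions integrate over the reference edges by default
      // (consistent small-strain treatment; follower loads optional)
      double dx, dz;
      if (follower_loads) {
        dx = (xs(i + 1) - xs(i)) * 1e-3;
        dz = (zs(i + 1) - zs(i)) * 1e-3;
      } else {
        dx = (surf_X(i + 1) - surf_X(i)) * 1e-3;
        dz = (surf_Z(i + 1) - surf_Z(i)) * 1e-3;
      }
      double fx = pe * (-dz), fz = pe * dx;
      F(surf_x_dof(i)) += 0.5 * fx;
      F(surf_z_dof(i)) += 0.5 * fz;
      F(surf_x_dof(i + 1)) += 0.5 * fx;
      F(surf_z_dof(i + 1)) += 0.5 * fz;
    }
    amin_out = Amin;
    // flow rate uses the physical (unfloored, zero at contact) minimum area
    double amin_q = 2.0 * (midline_mm - xs.max()) * l_gl_mm;
    double dp = p_sub - p_sup;
    qa_out = (amin_q <= 0.0 || dp <= 0.0)
      ? 0.0 : 1.3 * amin_q * std::sqrt(2.0 * dp / rho_air);
  };

  auto gaw_of = [&](const vec& th) {
    if (ns == 0) return 0.0;
    double xmax = -datum::inf;
    for (uword i = 0; i < ns; ++i) {
      double x = surf_X(i) + 1e3 * th(surf_x_dof(i));
      if (x > xmax) xmax = x;
    }
    double w = midline_mm - xmax;
    return w > 0 ? 2.0 * w * l_gl_mm : 0.0;
  };

  // initial sample: aero state of theta0 is also the first step's load
  vec F(n, fill::zeros), u(2 * n + nsd);
  double am, qa;
  aero(th0, F, am, qa);
  gaw(0) = gaw_of(th0);
  amin(0) = am;
  q(0) = qa;
  if (store_traj) { traj.col(0) = th0; fstore.col(0) = F; }

  // back-difference start: theta_{-1} = th0 - h v0 + h^2/2 a0
  vec a0 = solve(M, F - D * v0 - K * th0, solve_opts::likely_sympd);
  thm = th0 - h * v0 + 0.5 * h * h * a0;

  bool failed = false;
  int fail_step = -1;

  for (int step = 1; step <= nsteps; ++step) {
    // F currently holds the load evaluated at th0
    u.subvec(0, n - 1) = th0;
    u.subvec(n, 2 * n - 1) = thm;
    for (uword k = 0; k < nsd; ++k) u(2 * n + k) = F(sdof(k));
    thp = CC * u;

    if (contact_on) {
      // clamp penetrating nodes, then release any with tensile residual.
      // The constraint force at a clamped dof is the residual of the
      // discrete balance, A thp - b = A (thp - thp_unconstrained), which
      // only involves the clamped entries of the difference.
      std::vector<uword> act;
      std::vector<double> dstar;  // thp_clamped - thp_unconstrained
      for (uword k = 0; k < all_x_dof.n_elem; ++k) {
        uword d = all_x_dof(k);
        if (all_X(k) + 1e3 * thp(d) > midline_mm) {
          double clamped = (midline_mm - all_X(k)) * 1e-3;
          dstar.push_back(clamped - thp(d));
          thp(d) = clamped;
          act.push_back(d);
        }
      }
      if (!act.empty()) {
        auto resid = [&](size_t k) {
          double r = 0.0;
          for (size_t j = 0; j < act.size(); ++j)
            r += A(act[k], act[j]) * dstar[j];
          return r;
        };
        for (int pass = 0; pass < 10 && !act.empty(); ++pass) {
          bool released = false;
          for (size_t k = 0; k < act.size(); ++k) {
            double r = resid(k);
            if (r > 0) {  // tensile hold: release, restore prediction
              double akk = A(act[k], act[k]);
              thp(act[k]) += -r / akk;
              dstar[k] += -r / akk;
              act.erase(act.begin() + k);
              dstar.erase(dstar.begin() + k);
              released = true;
              break;
            }
          }
          if (!released) break;
        }
        // record compressive contact force at surface stations
        for (size_t k = 0; k < act.size(); ++k) {
          for (uword i = 0; i < ns; ++i) {
            if (act[k] == (uword)surf_x_dof(i)) {
              cforce(i, step) = -resid(k);  // wall pushes in -x: r <= 0
            }
          }
        }
      }
    }

    if (!thp.is_finite()) {
      failed = true;
      fail_step = step;
      break;
    }

    gaw(step) = gaw_of(thp);
    if (store_traj) { traj.col(step) = thp; fstore.col(step) = F; }

    thm = th0;
    th0 = thp;
    // aero at the new state: diagnostics for this sample, load for the next
    aero(th0, F, am, qa);
    amin(step) = am;
    q(step) = qa;
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("gaw") = gaw, Rcpp::Named("a_min") = amin,
    Rcpp::Named("q") = q, Rcpp::Named("contact_force") = cforce,
    Rcpp::Named("failed") = failed, Rcpp::Named("fail_step") = fail_step);
  if (store_traj) {
    out["trajectories"] = traj;
    out["forces"] = fstore;
  }
  return out;
}

// Static pre-compression equilibrium: K theta = f_c subject to the node
// x-positions not exceeding x0, solved by active-set iteration on the
// complementarity conditions (clamped nodes carry compressive reactions
// only; violated nodes are added, tensile ones released).
// [[Rcpp::export]]
Rcpp::List prestress_cpp(const arma::mat& K, const arma::ivec& all_x_dof,
                         const arma::vec& all_X, double x0_mm,
                         int max_iter = 60) {
  const uword n = K.n_rows;
  vec th(n, fill::zeros);
  std::vector<uword> act;
  std::vector<double> target;
  for (int it = 0; it < max_iter; ++it) {
    // solve with active dofs pinned at (x0 - X)
    uvec fixed(act.size());
    vec val(act.size());
    for (size_t k = 0; k < act.size(); ++k) {
      fixed(k) = act[k];
      val(k) = target[k];
    }
    th.zeros();
    if (!act.empty()) th(fixed) = val;
    uvec all = regspace<uvec>(0, n - 1);
    std::vector<uword> fr;
    for (uword d = 0; d < n; ++d) {
      bool is_fixed = false;
      for (size_t k = 0; k < act.size(); ++k) if (act[k] == d) is_fixed = true;
      if (!is_fixed) fr.push_back(d);
    }
    uvec freeidx(fr.size());
    for (size_t k = 0; k < fr.size(); ++k) freeidx(k) = fr[k];
    if (!act.empty()) {
      vec rhs = -K.submat(freeidx, fixed) * val;
      th(freeidx) = solve(K.submat(freeidx, freeidx), rhs,
                          solve_opts::likely_sympd);
    }
    // check violations and reactions
    bool changed = false;
    for (uword k = 0; k < all_x_dof.n_elem; ++k) {
      uword d = all_x_dof(k);
      bool is_act = false;
      for (size_t j = 0; j < act.size(); ++j) if (act[j] == d) is_act = true;
      double pos = all_X(k) + 1e3 * th(d);
      if (!is_act && pos > x0_mm + 1e-10) {
        act.push_back(d);
        target.push_back((x0_mm - all_X(k)) * 1e-3);
        changed = true;
      }
    }
    if (!changed) {
      // release tensile reactions (reaction r = (K th)_d; wall force -x => r<0)
      vec r = K * th;
      for (size_t j = 0; j < act.size();) {
        if (r(act[j]) > 1e-12) {
          act.erase(act.begin() + j);
          target.erase(target.begin() + j);
          changed = true;
        } else ++j;
      }
    }
    if (!changed) {
      vec r = K * th;
      double energy = 0.5 * dot(th, r);
      return Rcpp::List::create(Rcpp::Named("theta0") = th,
                                Rcpp::Named("energy") = energy,
                                Rcpp::Named("converged") = true,
                                Rcpp::Named("n_active") = (int)act.size());
    }
  }
  return Rcpp::List::create(Rcpp::Named("theta0") = th,
                            Rcpp::Named("energy") = NA_REAL,
                            Rcpp::Named("converged") = false,
                            Rcpp::Named("n_active") = (int)act.size());
}
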