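#include <Rcpp.h>
using namespace Rcpp;

// Reduced-unit toy substrate: a frozen "protein" site marker (copy_id == 0)
// with a Gaussian funnel well at site_center, a soft-core excluded volume,
// a harmonic outer confinement, and compact-support pair repulsion between
// distinct ligand copies. All particles with copy_id >= 1 are mobile.

struct PotPars {
  double cx, cy, cz;
  double depth, width;
  double r_ex, r_conf;
  double k_wall, k_conf;
  double eps_rep, d_rep;
};

static PotPars unpack_spec(const List& spec) {
  PotPars p;
  NumericVector c = spec["site_center"];
  p.cx = c[0]; p.cy = c[1]; p.cz = c[2];
  p.depth = as<double>(spec["well_depth"]);
  p.width = as<double>(spec["well_width"]);
  p.r_ex = as<double>(spec["excluded_radius"]);
  p.r_conf = as<double>(spec["confinement_radius"]);
  p.k_wall = as<double>(spec["wall_stiffness"]);
  p.k_conf = as<double>(spec["confinement_stiffness"]);
  p.eps_rep = as<double>(spec["copy_repulsion_strength"]);
  p.d_rep = as<double>(spec["copy_repulsion_range"]);
  return p;
}

// potential energy of the full configuration
static double energy_impl(const NumericMatrix& pos, const IntegerVector& copy_id,
                          const PotPars& p) {
  const int n = pos.nrow();
  double U = 0.0;
  for (int i = 0; i < n; ++i) {
    if (copy_id[i] == 0) continue;
    double dx = pos(i, 0) - p.cx, dy = pos(i, 1) - p.cy, dz = pos(i, 2) - p.cz;
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    U += -p.depth * std::exp(-r2 / (2.0 * p.width * p.width));
    if (p.r_ex > 0.0 && r < p.r_ex) {
      double d = p.r_ex - r;
      U += 0.5 * p.k_wall * d * d;
    }
    if (r > p.r_conf) {
      double d = r - p.r_conf;
      U += 0.5 * p.k_conf * d * d;
    }
  }
  if (p.eps_rep > 0.0 && p.d_rep > 0.0) {
    for (int i = 0; i < n; ++i) {
      if (copy_id[i] == 0) continue;
      for (int j = i + 1; j < n; ++j) {
        if (copy_id[j] == 0 || copy_id[j] == copy_id[i]) continue;
        double dx = pos(i, 0) - pos(j, 0);
        double dy = pos(i, 1) - pos(j, 1);
        double dz = pos(i, 2) - pos(j, 2);
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < p.d_rep) {
          double u = 1.0 - d / p.d_rep;
          U += p.eps_rep * u * u;
        }
      }
    }
  }
  return U;
}

// -grad U; frozen rows (copy_id == 0) get zero force
static void force_impl(const NumericMatrix& pos, const IntegerVector& copy_id,
                       const PotPars& p, NumericMatrix& F) {
  const int n = pos.nrow();
  std::fill(F.begin(), F.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    if (copy_id[i] == 0) continue;
    double dx = pos(i, 0) - p.cx, dy = pos(i, 1) - p.cy, dz = pos(i, 2) - p.cz;
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    // well: dU/dr = depth * (r / w^2) * exp(-r^2/2w^2); radial F = -dU/dr
    double w2 = p.width * p.width;
    double fr = -p.depth * (r / w2) * std::exp(-r2 / (2.0 * w2));
    if (p.r_ex > 0.0 && r < p.r_ex) fr += p.k_wall * (p.r_ex - r);
    if (r > p.r_conf) fr -= p.k_conf * (r - p.r_conf);
    if (r > 1e-12) {
      F(i, 0) += fr * dx / r;
      F(i, 1) += fr * dy / r;
      F(i, 2) += fr * dz / r;
    }
  }
  if (p.eps_rep > 0.0 && p.d_rep > 0.0) {
    for (int i = 0; i < n; ++i) {
      if (copy_id[i] == 0) continue;
      for (int j = i + 1; j < n; ++j) {
        if (copy_id[j] == 0 || copy_id[j] == copy_id[i]) continue;
        double dx = pos(i, 0) - pos(j, 0);
        double dy = pos(i, 1) - pos(j, 1);
        double dz = pos(i, 2) - pos(j, 2);
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < p.d_rep && d > 1e-12) {
          double fmag = 2.0 * p.eps_rep * (1.0 - d / p.d_rep) / p.d_rep;
          double fx = fmag * dx / d, fy = fmag * dy / d, fz = fmag * dz / d;
          F(i, 0) += fx; F(i, 1) += fy; F(i, 2) += fz;
          F(j, 0) -= fx; F(j, 1) -= fy; F(j, 2) -= fz;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".toy_energy_cpp")]]
double toy_energy_cpp(NumericMatrix pos, IntegerVector copy_id, List spec) {
  PotPars p = unpack_spec(spec);
  return energy_impl(pos, copy_id, p);
}

// [[Rcpp::export(name = ".toy_force_cpp")]]
NumericMatrix toy_force_cpp(NumericMatrix pos, IntegerVector copy_id, List spec) {
  PotPars p = unpack_spec(spec);
  NumericMatrix F(pos.nrow(), 3);
  force_impl(pos, copy_id, p, F);
  return F;
}

// Long-run observable sampler: same BAOAB integration, but returns flat
// (n_frames x 3n) position/velocity matrices instead of per-frame R objects,
// so equilibrium statistics over 1e5+ frames stay cheap.
// [[Rcpp::export(name = ".run_trajectory_cpp")]]
List run_trajectory_cpp(NumericMatrix pos0, NumericMatrix vel0,
                        NumericVector masses, IntegerVector copy_id, List spec,
                        double dt, double temperature, double friction,
                        int n_steps_per_frame, int n_frames) {
  PotPars p = unpack_spec(spec);
  const int n = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel = clone(vel0);
  NumericMatrix F(n, 3);
  force_impl(pos, copy_id, p, F);
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  NumericMatrix out_pos(n_frames, 3 * n), out_vel(n_frames, 3 * n);
  for (int f = 0; f < n_frames; ++f) {
    for (int s = 0; s < n_steps_per_frame; ++s) {
      for (int i = 0; i < n; ++i) {
        if (copy_id[i] == 0) continue;
        double hdtm = 0.5 * dt / masses[i];
        double sig = c2 * std::sqrt(temperature / masses[i]);
        for (int d = 0; d < 3; ++d) {
          vel(i, d) += hdtm * F(i, d);
          pos(i, d) += 0.5 * dt * vel(i, d);
          vel(i, d) = c1 * vel(i, d) + sig * norm_rand();
          pos(i, d) += 0.5 * dt * vel(i, d);
        }
      }
      force_impl(pos, copy_id, p, F);
      for (int i = 0; i < n; ++i) {
        if (copy_id[i] == 0) continue;
        double hdtm = 0.5 * dt / masses[i];
        for (int d = 0; d < 3; ++d) vel(i, d) += hdtm * F(i, d);
      }
    }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        if (!std::isfinite(pos(i, d)))
          stop("integration blow-up at frame %d", f + 1);
        out_pos(f, 3 * i + d) = pos(i, d);
        out_vel(f, 3 * i + d) = vel(i, d);
      }
  }
  return List::create(_["positions"] = out_pos, _["velocities"] = out_vel);
}

// BAOAB Langevin splitting. Records one frame every n_steps_per_frame steps;
// uses R's RNG (norm_rand), so trajectories are reproducible under set.seed().
// [[Rcpp::export(name = ".run_segment_cpp")]]
List run_segment_cpp(NumericMatrix pos0, NumericMatrix vel0,
                     NumericVector masses, IntegerVector copy_id, List spec,
                     double dt, double temperature, double friction,
                     int n_steps_per_frame, int frames_per_segment) {
  PotPars p = unpack_spec(spec);
  const int n = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel = clone(vel0);
  NumericMatrix F(n, 3);
  force_impl(pos, copy_id, p, F);

  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  List frames_pos(frames_per_segment), frames_vel(frames_per_segment);

  long step = 0;
  for (int f = 0; f < frames_per_segment; ++f) {
    for (int s = 0; s < n_steps_per_frame; ++s, ++step) {
      for (int i = 0; i < n; ++i) {
        if (copy_id[i] == 0) continue;
        double hdtm = 0.5 * dt / masses[i];
        double sig = c2 * std::sqrt(temperature / masses[i]);
        for (int d = 0; d < 3; ++d) {
          vel(i, d) += hdtm * F(i, d);             // B
          pos(i, d) += 0.5 * dt * vel(i, d);       // A
          vel(i, d) = c1 * vel(i, d) + sig * norm_rand();  // O
          pos(i, d) += 0.5 * dt * vel(i, d);       // A
        }
      }
      force_impl(pos, copy_id, p, F);
      for (int i = 0; i < n; ++i) {
        if (copy_id[i] == 0) continue;
        double hdtm = 0.5 * dt / masses[i];
        for (int d = 0; d < 3; ++d) vel(i, d) += hdtm * F(i, d);  // B
      }
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          if (!std::isfinite(pos(i, d)) || std::fabs(pos(i, d)) > 1e8)
            stop("integration blow-up: non-finite or runaway coordinate at step %d",
                 (int)(step + 1));
    }
    frames_pos[f] = clone(pos);
    frames_vel[f] = clone(vel);
  }
  return List::create(_["positions"] = frames_pos, _["velocities"] = frames_vel);
}
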