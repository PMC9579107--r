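// Event-driven stochastic simulation of the three-state jump process with
// drift and diffusion: movers run at +/- v with diffusivity D, tumble at
// lambda_e, settle at lambda_s and die at mu; settled cells double at
// lambda_d into one right- and one left-mover at the same position.
//
// Exact in distribution: event times are exponential; between events (and
// up to observation times, by memorylessness) mover positions advance by
// the ballistic drift plus a Gaussian diffusive increment.  Uses R's RNG,
// so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Walker {
  double t, x;
  int species;   // 0 = right-mover, 1 = settled, 2 = left-mover
  int ancestor;
};

// [[Rcpp::export(name = ".particles_cpp")]]
List particles_cpp(int n0, int init_species, NumericVector obs_times,
                   double lambda_s, double lambda_d, double lambda_e,
                   double mu, double v_plus, double v_minus, double D) {
  const int nobs = obs_times.size();
  const double sqrt2D = std::sqrt(2.0 * D);

  std::vector<std::vector<double>> xs(nobs);
  std::vector<std::vector<int>> sp(nobs), anc(nobs);

  std::vector<Walker> stack;
  stack.reserve(256);

  for (int a = 0; a < n0; ++a) {
    stack.push_back({0.0, 0.0, init_species, a});
    while (!stack.empty()) {
      Walker w = stack.back();
      stack.pop_back();
      // index of the first observation time not yet recorded for this walker
      int io = 0;
      while (io < nobs && obs_times[io] <= w.t) ++io;

      bool alive = true;
      while (alive) {
        const bool moving = (w.species != 1);
        const double rate = moving ? (lambda_s + lambda_e + mu) : lambda_d;
        const double v = (w.species == 0) ? v_plus :
                         (w.species == 2) ? -v_minus : 0.0;
        double tau = (rate > 0.0) ? R::rexp(1.0 / rate) : R_PosInf;
        double t_event = w.t + tau;

        // record at any observation times passed before the event
        while (io < nobs && obs_times[io] <= t_event) {
          const double h = obs_times[io] - w.t;
          if (moving && h > 0.0)
            w.x += v * h + sqrt2D * std::sqrt(h) * R::norm_rand();
          w.t = obs_times[io];
          xs[io].push_back(w.x);
          sp[io].push_back(w.species);
          anc[io].push_back(w.ancestor);
          ++io;
          // memorylessness: redraw the waiting time from the recorded time
          tau = (rate > 0.0) ? R::rexp(1.0 / rate) : R_PosInf;
          t_event = w.t + tau;
        }
        if (io >= nobs) break;  // walker survived past the last observation

        const double h = t_event - w.t;
        if (moving && h > 0.0)
          w.x += v * h + sqrt2D * std::sqrt(h) * R::norm_rand();
        w.t = t_event;

        if (!moving) {
          // doubling: the settled cell becomes a right- and a left-mover
          stack.push_back({w.t, w.x, 2, w.ancestor});
          w.species = 0;
        } else {
          const double u = R::unif_rand() * rate;
          if (u < lambda_s) {
            w.species = 1;
          } else if (u < lambda_s + lambda_e) {
            w.species = (w.species == 0) ? 2 : 0;
          } else {
            alive = false;  // death of a mover
          }
        }
      }
    }
  }

  List out(nobs);
  for (int io = 0; io < nobs; ++io) {
    out[io] = DataFrame::create(_["x"] = xs[io], _["species"] = sp[io],
                                _["ancestor"] = anc[io]);
  }
  return out;
}
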