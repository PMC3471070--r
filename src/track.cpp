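// Probabilistic streamline propagation.
//
// From each seed-voxel center, n_per_seed streamlines are launched
// bidirectionally (two legs with opposite initial signs).  At each step one
// orientation sample is drawn for the current voxel; between the two fiber
// populations the one most aligned with the previous step (absolute cosine)
// is taken, sign-flipped to keep the cosine positive.  A step whose cosine
// does not exceed the curvature threshold terminates the leg.  Legs also end
// on grid exit, on entering a voxel without orientation samples, on target
// entry, or after max_steps.  Streamlines entering the exclusion mask are
// discarded entirely; visited voxels of target-reaching streamlines are
// counted once per streamline per voxel.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  inline bool inside(int i, int j, int k) const {
    return i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz;
  }
  inline int lin(int i, int j, int k) const { return i + nx * (j + ny * k); }
};

}  // namespace

// [[Rcpp::export]]
List cpp_track(IntegerVector dims, IntegerVector index, NumericVector v1,
               NumericVector v2, LogicalVector has2, IntegerVector seed_vox,
               LogicalVector target, LogicalVector exclusion, int n_boot,
               int n_per_seed, double curv_thresh, double step_size,
               int max_steps, int seed) {
  Grid gr{dims[0], dims[1], dims[2]};
  const int nvox = gr.nx * gr.ny * gr.nz;
  const int nmask_rows = v1.size() / (3 * n_boot);
  IntegerVector counts(nvox);
  std::vector<int> stamp(nvox, -1);
  std::vector<int> visited;
  visited.reserve(4 * max_steps);

  auto sample_dir = [&](int row, int bi, int pop, double* out) {
    const NumericVector& v = (pop == 0) ? v1 : v2;
    for (int c = 0; c < 3; ++c)
      out[c] = v[row + (size_t)nmask_rows * (bi + (size_t)n_boot * c)];
  };

  long n_reached = 0;
  const int nseed = seed_vox.size();
  for (int s = 0; s < nseed; ++s) {
    int svox = seed_vox[s];
    int sk = svox / (gr.nx * gr.ny);
    int rem = svox % (gr.nx * gr.ny);
    int sj = rem / gr.nx;
    int si = rem % gr.nx;
    for (int rep = 0; rep < n_per_seed; ++rep) {
      uint32_t id = (uint32_t)(s * n_per_seed + rep);
      std::mt19937 rng((uint32_t)seed * 2654435761u + id + 1u);
      std::uniform_int_distribution<int> pick(0, n_boot - 1);
      visited.clear();
      bool excluded = false, reached = false;
      int srow = index[svox];
      if (srow >= 0) {
        // seed voxel is visited by construction
        stamp[svox] = (int)id;
        visited.push_back(svox);
        double dir0[3];
        sample_dir(srow, pick(rng), 0, dir0);
        for (int leg = 0; leg < 2 && !excluded; ++leg) {
          double pos[3] = {(double)si, (double)sj, (double)sk};
          double dir[3] = {dir0[0], dir0[1], dir0[2]};
          if (leg == 1) { dir[0] = -dir[0]; dir[1] = -dir[1]; dir[2] = -dir[2]; }
          for (int st = 0; st < max_steps; ++st) {
            pos[0] += step_size * dir[0];
            pos[1] += step_size * dir[1];
            pos[2] += step_size * dir[2];
            int i = (int)std::lround(pos[0]);
            int j = (int)std::lround(pos[1]);
            int k = (int)std::lround(pos[2]);
            if (!gr.inside(i, j, k)) break;
            int vox = gr.lin(i, j, k);
            if (stamp[vox] != (int)id) {
              stamp[vox] = (int)id;
              visited.push_back(vox);
            }
            if (exclusion[vox]) { excluded = true; break; }
            if (target[vox]) { reached = true; break; }
            int row = index[vox];
            if (row < 0) break;
            int bi = pick(rng);
            double cand[3], c1v[3], c2v[3];
            sample_dir(row, bi, 0, c1v);
            double c1 = c1v[0] * dir[0] + c1v[1] * dir[1] + c1v[2] * dir[2];
            double cbest = c1;
            cand[0] = c1v[0]; cand[1] = c1v[1]; cand[2] = c1v[2];
            if (has2[row]) {
              sample_dir(row, bi, 1, c2v);
              double c2 = c2v[0] * dir[0] + c2v[1] * dir[1] + c2v[2] * dir[2];
              if (std::fabs(c2) > std::fabs(cbest)) {
                cbest = c2;
                cand[0] = c2v[0]; cand[1] = c2v[1]; cand[2] = c2v[2];
              }
            }
            if (cbest < 0) {
              cbest = -cbest;
              cand[0] = -cand[0]; cand[1] = -cand[1]; cand[2] = -cand[2];
            }
            if (cbest <= curv_thresh) break;
            dir[0] = cand[0]; dir[1] = cand[1]; dir[2] = cand[2];
          }
        }
      }
      if (!excluded && reached) {
        ++n_reached;
        for (int v : visited) ++counts[v];
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["counts"] = counts, _["n_reached"] = (double)n_reached,
                      _["total"] = (double)nseed * (double)n_per_seed);
}
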