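#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Neighbour offsets for 6/18/26 connectivity on a 3-D grid.
static std::vector<std::array<int,3>> neighbour_offsets(int connectivity) {
    std::vector<std::array<int,3>> off;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (a == 0) continue;
                if (connectivity == 6 && a > 1) continue;
                if (connectivity == 18 && a > 2) continue;
                off.push_back({dx, dy, dz});
            }
    return off;
}

// Label connected components of a 3-D logical mask.
// Returns an integer vector (0 = background), labels in first-encounter order.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
    if (dims.size() != 3) stop("dims must have length 3");
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");
    IntegerVector labels(n, 0);
    std::vector<std::array<int,3>> off = neighbour_offsets(connectivity);
    std::vector<R_xlen_t> stack;
    int next_label = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || labels[s] != 0) continue;
        ++next_label;
        labels[s] = next_label;
        stack.clear();
        stack.push_back(s);
        while (!stack.empty()) {
            R_xlen_t v = stack.back(); stack.pop_back();
            int x = (int)(v % nx);
            int y = (int)((v / nx) % ny);
            int z = (int)(v / ((R_xlen_t)nx * ny));
            for (size_t k = 0; k < off.size(); ++k) {
                int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                    continue;
                R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
                if (mask[w] && labels[w] == 0) {
                    labels[w] = next_label;
                    stack.push_back(w);
                }
            }
        }
    }
    labels.attr("n_labels") = next_label;
    return labels;
}

// Threshold-free cluster enhancement of a non-negative statistic map:
//   TFCE(v) = sum over h = dh, 2dh, ... of extent(v, h)^E * h^H * dh,
// where extent(v, h) is the size of the connected component containing v in
// the supra-threshold set {stat >= h}. Negative input values are clamped to 0.
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims,
                       double E, double H, double dh, int connectivity) {
    if (dims.size() != 3) stop("dims must have length 3");
    if (!(dh > 0)) stop("dh must be positive");
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (stat.size() != n) stop("stat length does not match dims");

    NumericVector out(n, 0.0);
    // Active voxels: stat > 0 after clamping.
    std::vector<R_xlen_t> active;
    double smax = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
        double v = stat[i];
        if (v > 0) {
            active.push_back(i);
            if (v > smax) smax = v;
        }
    }
    if (active.empty()) return out;

    std::vector<std::array<int,3>> off = neighbour_offsets(connectivity);
    std::vector<int> comp(n, 0);        // component id at current threshold
    std::vector<R_xlen_t> touched;      // voxels labelled at current threshold
    std::vector<R_xlen_t> stack;

    int nsteps = (int)std::floor(smax / dh + 1e-12);
    for (int k = 1; k <= nsteps; ++k) {
        double h = k * dh;
        touched.clear();
        int ncomp = 0;
        std::vector<double> csize;
        // label supra-threshold components among active voxels
        for (size_t a = 0; a < active.size(); ++a) {
            R_xlen_t s = active[a];
            if (stat[s] < h || comp[s] != 0) continue;
            ++ncomp;
            double sz = 0;
            comp[s] = ncomp;
            touched.push_back(s);
            stack.clear();
            stack.push_back(s);
            while (!stack.empty()) {
                R_xlen_t v = stack.back(); stack.pop_back();
                sz += 1;
                int x = (int)(v % nx);
                int y = (int)((v / nx) % ny);
                int z = (int)(v / ((R_xlen_t)nx * ny));
                for (size_t q = 0; q < off.size(); ++q) {
                    int xx = x + off[q][0], yy = y + off[q][1], zz = z + off[q][2];
                    if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                        continue;
                    R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
                    if (stat[w] >= h && comp[w] == 0) {
                        comp[w] = ncomp;
                        touched.push_back(w);
                        stack.push_back(w);
                    }
                }
            }
            csize.push_back(sz);
        }
        double hH = std::pow(h, H) * dh;
        for (size_t t = 0; t < touched.size(); ++t) {
            R_xlen_t v = touched[t];
            out[v] += std::pow(csize[comp[v] - 1], E) * hH;
            comp[v] = 0; // reset for next threshold
        }
    }
    return out;
}
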