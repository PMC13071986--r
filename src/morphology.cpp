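#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

static const double DT_INF = 1e20;

// 1D squared-distance transform via the lower-envelope-of-parabolas
// algorithm (Felzenszwalb & Huttenlocher). f holds per-site seed costs
// (0 at sources, DT_INF elsewhere); d receives squared distances.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
    int k = 0;
    v[0] = 0;
    z[0] = -DT_INF;
    z[1] = DT_INF;
    for (int q = 1; q < n; q++) {
        double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                   (2.0 * q - 2.0 * v[k]);
        while (s <= z[k]) {
            k--;
            s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                (2.0 * q - 2.0 * v[k]);
        }
        k++;
        v[k] = q;
        z[k] = s;
        z[k + 1] = DT_INF;
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        while (z[k + 1] < q) k++;
        double dq = (double)(q - v[k]);
        d[q] = dq * dq + f[v[k]];
    }
}

// Exact squared Euclidean distance (in voxel units) from every voxel to the
// nearest TRUE voxel of a 3D mask stored in column-major order.
// Voxels with no TRUE voxel anywhere get a distance >= DT_INF.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims) {
    const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
    const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
    NumericVector d(n);
    for (R_xlen_t i = 0; i < n; i++) d[i] = mask[i] ? 0.0 : DT_INF;

    const int nmax = std::max(n1, std::max(n2, n3));
    std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // axis 1 (stride 1)
    for (int k = 0; k < n3; k++) {
        for (int j = 0; j < n2; j++) {
            const R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
            for (int i = 0; i < n1; i++) f[i] = d[base + i];
            dt1d(f, dd, v, z, n1);
            for (int i = 0; i < n1; i++) d[base + i] = dd[i];
        }
    }
    // axis 2 (stride n1)
    for (int k = 0; k < n3; k++) {
        for (int i = 0; i < n1; i++) {
            const R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
            for (int j = 0; j < n2; j++) f[j] = d[base + (R_xlen_t)n1 * j];
            dt1d(f, dd, v, z, n2);
            for (int j = 0; j < n2; j++) d[base + (R_xlen_t)n1 * j] = dd[j];
        }
    }
    // axis 3 (stride n1*n2)
    const R_xlen_t s3 = (R_xlen_t)n1 * n2;
    for (int j = 0; j < n2; j++) {
        for (int i = 0; i < n1; i++) {
            const R_xlen_t base = i + (R_xlen_t)n1 * j;
            for (int k = 0; k < n3; k++) f[k] = d[base + s3 * k];
            dt1d(f, dd, v, z, n3);
            for (int k = 0; k < n3; k++) d[base + s3 * k] = dd[k];
        }
    }
    return d;
}

// Connected-component labelling of a 3D mask (column-major), 6- or
// 26-connectivity. Labels are 1..n_components, background stays 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
    const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
    const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
    IntegerVector lab(n);

    std::vector<std::array<int, 3> > offs;
    for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
            for (int di = -1; di <= 1; di++) {
                if (di == 0 && dj == 0 && dk == 0) continue;
                const int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
                if (connectivity == 6 && manh != 1) continue;
                offs.push_back({{di, dj, dk}});
            }

    int cur = 0;
    std::vector<R_xlen_t> stack;
    for (R_xlen_t p = 0; p < n; p++) {
        if (!mask[p] || lab[p] != 0) continue;
        cur++;
        lab[p] = cur;
        stack.push_back(p);
        while (!stack.empty()) {
            const R_xlen_t q = stack.back();
            stack.pop_back();
            const int i = (int)(q % n1);
            const int j = (int)((q / n1) % n2);
            const int k = (int)(q / ((R_xlen_t)n1 * n2));
            for (size_t o = 0; o < offs.size(); o++) {
                const int ii = i + offs[o][0];
                const int jj = j + offs[o][1];
                const int kk = k + offs[o][2];
                if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                    kk < 0 || kk >= n3)
                    continue;
                const R_xlen_t qq =
                    ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
                if (mask[qq] && lab[qq] == 0) {
                    lab[qq] = cur;
                    stack.push_back(qq);
                }
            }
        }
    }
    return lab;
}

// Background voxels reachable from the volume border without crossing the
// mask. slicewise = TRUE restricts the flood to each axial (first-axis)
// slice with 4-connectivity in-plane; otherwise a 6-connected 3D flood is
// used. The complement of the result within the background is the set of
// enclosed holes.
// [[Rcpp::export]]
LogicalVector cpp_border_background(LogicalVector mask, IntegerVector dims,
                                    bool slicewise) {
    const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
    const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
    LogicalVector reached(n);
    std::vector<R_xlen_t> stack;

    if (slicewise) {
        // per-slice 4-connected flood in the (j, k) plane of each i-slice
        for (int i = 0; i < n1; i++) {
            for (int k = 0; k < n3; k++)
                for (int j = 0; j < n2; j++) {
                    if (j != 0 && j != n2 - 1 && k != 0 && k != n3 - 1)
                        continue;
                    const R_xlen_t p =
                        i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
                    if (!mask[p] && !reached[p]) {
                        reached[p] = TRUE;
                        stack.push_back(p);
                    }
                }
            while (!stack.empty()) {
                const R_xlen_t q = stack.back();
                stack.pop_back();
                const int j = (int)((q / n1) % n2);
                const int k = (int)(q / ((R_xlen_t)n1 * n2));
                const int dj[4] = {1, -1, 0, 0};
                const int dk[4] = {0, 0, 1, -1};
                for (int o = 0; o < 4; o++) {
                    const int jj = j + dj[o], kk = k + dk[o];
                    if (jj < 0 || jj >= n2 || kk < 0 || kk >= n3) continue;
                    const R_xlen_t qq =
                        i + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
                    if (!mask[qq] && !reached[qq]) {
                        reached[qq] = TRUE;
                        stack.push_back(qq);
                    }
                }
            }
        }
        return reached;
    }

    for (R_xlen_t p = 0; p < n; p++) {
        const int i = (int)(p % n1);
        const int j = (int)((p / n1) % n2);
        const int k = (int)(p / ((R_xlen_t)n1 * n2));
        const bool border = (i == 0 || i == n1 - 1 || j == 0 ||
                             j == n2 - 1 || k == 0 || k == n3 - 1);
        if (border && !mask[p] && !reached[p]) {
            reached[p] = TRUE;
            stack.push_back(p);
        }
    }
    const int di[6] = {1, -1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, 1, -1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, 1, -1};
    while (!stack.empty()) {
        const R_xlen_t q = stack.back();
        stack.pop_back();
        const int i = (int)(q % n1);
        const int j = (int)((q / n1) % n2);
        const int k = (int)(q / ((R_xlen_t)n1 * n2));
        for (int o = 0; o < 6; o++) {
            const int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                kk < 0 || kk >= n3)
                continue;
            const R_xlen_t qq = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
            if (!mask[qq] && !reached[qq]) {
                reached[qq] = TRUE;
                stack.push_back(qq);
            }
        }
    }
    return reached;
}
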