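#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Squared Euclidean distance transform on a regular anisotropic grid,
// lower-envelope-of-parabolas algorithm (Felzenszwalb & Huttenlocher 2012),
// one separable pass per axis. Exact for voxel-center seed sets.

static const double EDT_INF = 1e30; // finite sentinel; grid diameters are << 1e15 mm

// In-place 1D pass along a line of n samples with stride `stride`,
// sample spacing squared w2. f holds squared distances accumulated so far.
static void dt1d(double *f, int n, std::ptrdiff_t stride, double w2,
                 std::vector<double> &scratch, std::vector<int> &v,
                 std::vector<double> &z) {
    double *g = scratch.data();
    for (int i = 0; i < n; ++i) g[i] = f[(std::ptrdiff_t)i * stride];

    int k = 0;
    v[0] = 0;
    z[0] = -EDT_INF;
    z[1] = EDT_INF;
    for (int q = 1; q < n; ++q) {
        double fq = g[q] + w2 * (double)q * q;
        double s;
        while (true) {
            int vk = v[k];
            s = (fq - (g[vk] + w2 * (double)vk * vk)) / (2.0 * w2 * (q - vk));
            if (s <= z[k] && k > 0) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = EDT_INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        int vk = v[k];
        f[(std::ptrdiff_t)q * stride] = w2 * (double)(q - vk) * (q - vk) + g[vk];
    }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector seeds, IntegerVector dim,
                         NumericVector spacing) {
    if (dim.size() != 3 || spacing.size() != 3)
        stop("dim and spacing must have length 3");
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const std::ptrdiff_t nxy = (std::ptrdiff_t)nx * ny;
    if ((std::ptrdiff_t)seeds.size() != nxy * nz)
        stop("seed array length does not match dim");

    NumericVector out(seeds.size());
    double *d = REAL(out);
    for (std::ptrdiff_t i = 0; i < (std::ptrdiff_t)seeds.size(); ++i)
        d[i] = (seeds[i] == TRUE) ? 0.0 : EDT_INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> scratch(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // axis 1 (stride 1)
    double w2 = spacing[0] * spacing[0];
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            dt1d(d + k * nxy + (std::ptrdiff_t)j * nx, nx, 1, w2, scratch, v, z);
    // axis 2 (stride nx)
    w2 = spacing[1] * spacing[1];
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i)
            dt1d(d + k * nxy + i, ny, nx, w2, scratch, v, z);
    // axis 3 (stride nx*ny)
    w2 = spacing[2] * spacing[2];
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
            dt1d(d + (std::ptrdiff_t)j * nx + i, nz, nxy, w2, scratch, v, z);

    for (std::ptrdiff_t i = 0; i < (std::ptrdiff_t)out.size(); ++i)
        if (d[i] >= 1e29) d[i] = R_PosInf;
    out.attr("dim") = dim;
    return out;
}
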