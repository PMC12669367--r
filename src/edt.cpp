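#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact Euclidean distance transform on a regular grid with per-axis sample
// spacing (Felzenszwalb & Huttenlocher lower-envelope algorithm, applied
// separably along each axis on squared distances).

static const double INF = 1e30;

// 1D squared-distance transform; samples sit at x_i = i * w.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w) {
    const double NINF = -std::numeric_limits<double>::infinity();
    const double PINF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = NINF;
    z[1] = PINF;
    const double w2 = w * w;
    for (int q = 1; q < n; ++q) {
        double fq = f[q] + w2 * q * q;
        double s;
        while (true) {
            int p = v[k];
            s = (fq - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
            if (s > z[k]) break;
            --k;
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = PINF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        int p = v[k];
        double dx = w * (q - p);
        d[q] = dx * dx + f[p];
    }
}

// [[Rcpp::export]]
Rcpp::NumericVector edt3d(Rcpp::LogicalVector mask, Rcpp::IntegerVector dims,
                          Rcpp::NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    Rcpp::NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        out[i] = (mask[i] == TRUE) ? 0.0 : INF;
    }
    const int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // along x (stride 1)
    for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            for (int i = 0; i < nx; ++i) f[i] = out[base + i];
            dt1d(f, d, v, z, nx, spacing[0]);
            for (int i = 0; i < nx; ++i) out[base + i] = d[i];
        }
    }
    // along y (stride nx)
    for (int k = 0; k < nz; ++k) {
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = i + (R_xlen_t)nx * ny * k;
            for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
            dt1d(f, d, v, z, ny, spacing[1]);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
        }
    }
    // along z (stride nx*ny)
    const R_xlen_t sxy = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = i + (R_xlen_t)nx * j;
            for (int k = 0; k < nz; ++k) f[k] = out[base + sxy * k];
            dt1d(f, d, v, z, nz, spacing[2]);
            for (int k = 0; k < nz; ++k) out[base + sxy * k] = d[k];
        }
    }
    for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
    return out;
}
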