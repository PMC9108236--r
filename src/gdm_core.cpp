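#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Absent sites carry this cost instead of infinity so the lower-envelope
// intersections below stay well defined; finite distances are unaffected
// because LARGE dwarfs any attainable squared grid distance.
static const double LARGE = 1e20;

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) on samples at
// positions i*step, i = 0..n-1. Exact for squared Euclidean cost.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double step) {
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; q++) {
        double xq = q * step;
        double s;
        while (true) {
            double xv = v[k] * step;
            s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
            if (s <= z[k] && k > 0) k--;
            else break;
        }
        if (s <= z[k]) { // k == 0 and new parabola dominates everywhere
            v[0] = q;
        } else {
            k++;
            v[k] = q;
        }
        z[k] = (k == 0) ? -INF : s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        double xq = q * step;
        while (z[k + 1] < xq) k++;
        double xv = v[k] * step;
        d[q] = (xq - xv) * (xq - xv) + f[v[k]];
    }
}

// Exact squared Euclidean distance (mm^2) from every voxel to the nearest
// true voxel of `mask`, on an anisotropic grid. Infinite when mask is empty.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    std::vector<double> g(n);
    for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] ? 0.0 : LARGE;

    // pass along x
    {
        std::vector<double> f(nx), d(nx);
        for (int z = 0; z < nz; z++)
            for (int y = 0; y < ny; y++) {
                R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
                for (int x = 0; x < nx; x++) f[x] = g[base + x];
                dt1d(f, d, nx, spacing[0]);
                for (int x = 0; x < nx; x++) g[base + x] = d[x];
            }
    }
    // pass along y
    {
        std::vector<double> f(ny), d(ny);
        for (int z = 0; z < nz; z++)
            for (int x = 0; x < nx; x++) {
                R_xlen_t base = (R_xlen_t)z * nx * ny + x;
                for (int y = 0; y < ny; y++) f[y] = g[base + (R_xlen_t)y * nx];
                dt1d(f, d, ny, spacing[1]);
                for (int y = 0; y < ny; y++) g[base + (R_xlen_t)y * nx] = d[y];
            }
    }
    // pass along z
    {
        std::vector<double> f(nz), d(nz);
        R_xlen_t nxy = (R_xlen_t)nx * ny;
        for (int y = 0; y < ny; y++)
            for (int x = 0; x < nx; x++) {
                R_xlen_t base = (R_xlen_t)y * nx + x;
                for (int z = 0; z < nz; z++) f[z] = g[base + (R_xlen_t)z * nxy];
                dt1d(f, d, nz, spacing[2]);
                for (int z = 0; z < nz; z++) g[base + (R_xlen_t)z * nxy] = d[z];
            }
    }
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; i++) out[i] = g[i];
    return out;
}

static inline double sample_trilinear(const double* vol, int nx, int ny, int nz,
                                      double x, double y, double z, bool& ok) {
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
        ok = false;
        return NA_REAL;
    }
    ok = true;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (z0 < 0) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    R_xlen_t nxy = (R_xlen_t)nx * ny;
    const double* p = vol + (R_xlen_t)z0 * nxy + (R_xlen_t)y0 * nx + x0;
    double c00 = p[0] * (1 - fx) + p[1] * fx;
    double c10 = p[nx] * (1 - fx) + p[nx + 1] * fx;
    double c01 = p[nxy] * (1 - fx) + p[nxy + 1] * fx;
    double c11 = p[nxy + nx] * (1 - fx) + p[nxy + nx + 1] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
}

// Trilinear interpolation at continuous 0-based voxel coordinates (one row
// per point). Points outside the grid yield NA.
// [[Rcpp::export(name = ".interp_trilinear_cpp")]]
NumericVector interp_trilinear_cpp(NumericVector vol, IntegerVector dim,
                                   NumericMatrix pts) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    R_xlen_t np = pts.nrow();
    NumericVector out(np);
    const double* v = REAL(vol);
    bool ok;
    for (R_xlen_t i = 0; i < np; i++) {
        out[i] = sample_trilinear(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2), ok);
    }
    return out;
}

// Normalized cross-correlation between fixed-ROI intensities and the moving
// volume sampled at base points + each candidate offset (all in 0-based voxel
// coordinates of the moving grid). Offsets with < 50% of points inside the
// moving grid score -2 (worse than any attainable correlation).
// [[Rcpp::export(name = ".ncc_search_cpp")]]
NumericVector ncc_search_cpp(NumericVector fvals, NumericMatrix base_pts,
                             NumericVector vol, IntegerVector dim,
                             NumericMatrix offsets) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    R_xlen_t np = base_pts.nrow(), no = offsets.nrow();
    const double* v = REAL(vol);
    NumericVector out(no);
    bool ok;
    for (R_xlen_t o = 0; o < no; o++) {
        double ox = offsets(o, 0), oy = offsets(o, 1), oz = offsets(o, 2);
        double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
        R_xlen_t nvalid = 0;
        for (R_xlen_t i = 0; i < np; i++) {
            double m = sample_trilinear(v, nx, ny, nz, base_pts(i, 0) + ox,
                                        base_pts(i, 1) + oy, base_pts(i, 2) + oz, ok);
            if (!ok) continue;
            double f = fvals[i];
            sf += f; sm += m; sff += f * f; smm += m * m; sfm += f * m;
            nvalid++;
        }
        if (nvalid < np / 2 || nvalid < 2) { out[o] = -2.0; continue; }
        double n = (double)nvalid;
        double cov = sfm - sf * sm / n;
        double vf = sff - sf * sf / n;
        double vm = smm - sm * sm / n;
        out[o] = (vf <= 0 || vm <= 0) ? -2.0 : cov / std::sqrt(vf * vm);
    }
    return out;
}

// 6-connected component labelling of a 3D logical mask (iterative flood fill).
// [[Rcpp::export(name = ".label_components6_cpp")]]
IntegerVector label_components6_cpp(LogicalVector mask, IntegerVector dim) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz, nxy = (R_xlen_t)nx * ny;
    IntegerVector lab(n, 0);
    int next = 0;
    std::vector<R_xlen_t> stack;
    for (R_xlen_t s = 0; s < n; s++) {
        if (!mask[s] || lab[s] != 0) continue;
        next++;
        stack.push_back(s);
        lab[s] = next;
        while (!stack.empty()) {
            R_xlen_t i = stack.back();
            stack.pop_back();
            int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / nxy);
            const int dx[6] = {-1, 1, 0, 0, 0, 0};
            const int dy[6] = {0, 0, -1, 1, 0, 0};
            const int dz[6] = {0, 0, 0, 0, -1, 1};
            for (int k = 0; k < 6; k++) {
                int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
                if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                    continue;
                R_xlen_t j = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
                if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
            }
        }
    }
    return lab;
}
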