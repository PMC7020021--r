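#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Low-level mesh geometry: closest point on a triangulated surface (for ICP
// correspondences and RMS deviation) and +y ray casting of a surface as a
// height field (for volumetric subtraction). Both use a uniform grid over
// triangle bounding boxes so queries stay fast at cohort scale.

static inline double dot3(const double* a, const double* b) {
    return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Closest point on triangle abc to point p (Ericson, Real-Time Collision
// Detection, 5.1.5). Writes the closest point into out.
static void closest_pt_triangle(const double* p, const double* a,
                                const double* b, const double* c,
                                double* out) {
    double ab[3], ac[3], ap[3];
    for (int i = 0; i < 3; ++i) {
        ab[i] = b[i] - a[i];
        ac[i] = c[i] - a[i];
        ap[i] = p[i] - a[i];
    }
    double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
    if (d1 <= 0.0 && d2 <= 0.0) {
        for (int i = 0; i < 3; ++i) out[i] = a[i];
        return;
    }
    double bp[3];
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
    if (d3 >= 0.0 && d4 <= d3) {
        for (int i = 0; i < 3; ++i) out[i] = b[i];
        return;
    }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
        return;
    }
    double cp[3];
    for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
    double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
    if (d6 >= 0.0 && d5 <= d6) {
        for (int i = 0; i < 3; ++i) out[i] = c[i];
        return;
    }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
        double w = d2 / (d2 - d6);
        for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
        return;
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
        double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
        return;
    }
    double denom = 1.0 / (va + vb + vc);
    double v = vb * denom, w = vc * denom;
    for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

struct TriGrid3 {
    double origin[3];
    double cell;
    int n[3];
    std::vector<std::vector<int> > bins;

    int clampi(int v, int hi) const {
        return std::max(0, std::min(v, hi - 1));
    }
    int index(int ix, int iy, int iz) const {
        return (iz * n[1] + iy) * n[0] + ix;
    }
};

static void build_grid3(const NumericMatrix& V, const IntegerMatrix& F,
                        TriGrid3& g) {
    const int nt = F.nrow();
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
        lo[k] = R_PosInf;
        hi[k] = R_NegInf;
    }
    double mean_ext = 0.0;
    for (int t = 0; t < nt; ++t) {
        double tlo[3], thi[3];
        for (int k = 0; k < 3; ++k) {
            tlo[k] = R_PosInf;
            thi[k] = R_NegInf;
        }
        for (int j = 0; j < 3; ++j) {
            int vi = F(t, j) - 1;
            for (int k = 0; k < 3; ++k) {
                double x = V(vi, k);
                if (x < tlo[k]) tlo[k] = x;
                if (x > thi[k]) thi[k] = x;
                if (x < lo[k]) lo[k] = x;
                if (x > hi[k]) hi[k] = x;
            }
        }
        double e = 0.0;
        for (int k = 0; k < 3; ++k) e = std::max(e, thi[k] - tlo[k]);
        mean_ext += e;
    }
    mean_ext /= std::max(1, nt);
    double cell = std::max(mean_ext * 1.5, 1e-6);
    for (int k = 0; k < 3; ++k) {
        double ext = hi[k] - lo[k];
        int nk = (int)std::ceil(ext / cell) + 1;
        nk = std::max(1, std::min(nk, 128));
        g.n[k] = nk;
        g.origin[k] = lo[k];
        // recompute cell so the capped grid still covers the bbox
        if (nk > 1) cell = std::max(cell, ext / nk + 1e-9);
    }
    g.cell = cell;
    g.bins.assign((size_t)g.n[0] * g.n[1] * g.n[2], std::vector<int>());
    for (int t = 0; t < nt; ++t) {
        double tlo[3], thi[3];
        for (int k = 0; k < 3; ++k) {
            tlo[k] = R_PosInf;
            thi[k] = R_NegInf;
        }
        for (int j = 0; j < 3; ++j) {
            int vi = F(t, j) - 1;
            for (int k = 0; k < 3; ++k) {
                double x = V(vi, k);
                if (x < tlo[k]) tlo[k] = x;
                if (x > thi[k]) thi[k] = x;
            }
        }
        int ilo[3], ihi[3];
        for (int k = 0; k < 3; ++k) {
            ilo[k] = g.clampi((int)std::floor((tlo[k] - g.origin[k]) / g.cell), g.n[k]);
            ihi[k] = g.clampi((int)std::floor((thi[k] - g.origin[k]) / g.cell), g.n[k]);
        }
        for (int iz = ilo[2]; iz <= ihi[2]; ++iz)
            for (int iy = ilo[1]; iy <= ihi[1]; ++iy)
                for (int ix = ilo[0]; ix <= ihi[0]; ++ix)
                    g.bins[g.index(ix, iy, iz)].push_back(t);
    }
}

//' @noRd
// [[Rcpp::export(name = "cpp_closest_points")]]
List cpp_closest_points(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
    const int np = P.nrow(), nt = F.nrow();
    NumericVector dist(np);
    NumericMatrix cp(np, 3);
    if (nt == 0) stop("mesh has no faces");

    TriGrid3 g;
    build_grid3(V, F, g);
    std::vector<int> stamp((size_t)nt, -1);

    for (int ip = 0; ip < np; ++ip) {
        double p[3] = {P(ip, 0), P(ip, 1), P(ip, 2)};
        int ic[3];
        for (int k = 0; k < 3; ++k)
            ic[k] = (int)std::floor((p[k] - g.origin[k]) / g.cell);
        double best = R_PosInf;
        double bestpt[3] = {0, 0, 0};
        int maxr = std::max(g.n[0], std::max(g.n[1], g.n[2])) +
                   (int)(std::abs(ic[0]) + std::abs(ic[1]) + std::abs(ic[2])) + 2;
        for (int r = 0;; ++r) {
            // any triangle in a cell at Chebyshev index-distance r is at
            // least (r-1)*cell away from p, so stop once that exceeds best
            if (r > 0 && (double)(r - 1) * g.cell > std::sqrt(best)) break;
            if (r > maxr) break;
            bool any_cell = false;
            for (int dz = -r; dz <= r; ++dz) {
                int iz = ic[2] + dz;
                if (iz < 0 || iz >= g.n[2]) continue;
                for (int dy = -r; dy <= r; ++dy) {
                    int iy = ic[1] + dy;
                    if (iy < 0 || iy >= g.n[1]) continue;
                    for (int dx = -r; dx <= r; ++dx) {
                        // only the shell, not the full block
                        if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
                            continue;
                        int ix = ic[0] + dx;
                        if (ix < 0 || ix >= g.n[0]) continue;
                        any_cell = true;
                        const std::vector<int>& bin = g.bins[g.index(ix, iy, iz)];
                        for (size_t bi = 0; bi < bin.size(); ++bi) {
                            int t = bin[bi];
                            if (stamp[t] == ip) continue;
                            stamp[t] = ip;
                            int i0 = F(t, 0) - 1, i1 = F(t, 1) - 1, i2 = F(t, 2) - 1;
                            double a[3] = {V(i0, 0), V(i0, 1), V(i0, 2)};
                            double b[3] = {V(i1, 0), V(i1, 1), V(i1, 2)};
                            double c[3] = {V(i2, 0), V(i2, 1), V(i2, 2)};
                            double q[3];
                            closest_pt_triangle(p, a, b, c, q);
                            double d2 = 0.0;
                            for (int k = 0; k < 3; ++k) {
                                double dd = p[k] - q[k];
                                d2 += dd * dd;
                            }
                            if (d2 < best) {
                                best = d2;
                                for (int k = 0; k < 3; ++k) bestpt[k] = q[k];
                            }
                        }
                    }
                }
            }
            (void)any_cell;
        }
        dist[ip] = std::sqrt(best);
        for (int k = 0; k < 3; ++k) cp(ip, k) = bestpt[k];
    }
    return List::create(_["distance"] = dist, _["point"] = cp);
}

//' @noRd
// [[Rcpp::export(name = "cpp_raycast_y")]]
NumericVector cpp_raycast_y(NumericMatrix XZ, NumericMatrix V, IntegerMatrix F) {
    // Rays parallel to +y at (x, z); returns the outermost (maximum)
    // interpolated y over all triangles hit, NA when the ray misses.
    const int nq = XZ.nrow(), nt = F.nrow();
    NumericVector out(nq, NA_REAL);
    if (nt == 0) return out;

    // 2D uniform grid on the x-z projection
    double lo[2] = {R_PosInf, R_PosInf}, hi[2] = {R_NegInf, R_NegInf};
    double mean_ext = 0.0;
    for (int t = 0; t < nt; ++t) {
        double tlo[2] = {R_PosInf, R_PosInf}, thi[2] = {R_NegInf, R_NegInf};
        for (int j = 0; j < 3; ++j) {
            int vi = F(t, j) - 1;
            double xx = V(vi, 0), zz = V(vi, 2);
            tlo[0] = std::min(tlo[0], xx); thi[0] = std::max(thi[0], xx);
            tlo[1] = std::min(tlo[1], zz); thi[1] = std::max(thi[1], zz);
        }
        lo[0] = std::min(lo[0], tlo[0]); hi[0] = std::max(hi[0], thi[0]);
        lo[1] = std::min(lo[1], tlo[1]); hi[1] = std::max(hi[1], thi[1]);
        mean_ext += std::max(thi[0] - tlo[0], thi[1] - tlo[1]);
    }
    mean_ext /= nt;
    double cell = std::max(mean_ext * 1.5, 1e-6);
    int n0 = std::max(1, std::min((int)std::ceil((hi[0] - lo[0]) / cell) + 1, 512));
    int n1 = std::max(1, std::min((int)std::ceil((hi[1] - lo[1]) / cell) + 1, 512));
    if (n0 > 1) cell = std::max(cell, (hi[0] - lo[0]) / n0 + 1e-9);
    if (n1 > 1) cell = std::max(cell, (hi[1] - lo[1]) / n1 + 1e-9);
    std::vector<std::vector<int> > bins((size_t)n0 * n1);
    for (int t = 0; t < nt; ++t) {
        double tlo[2] = {R_PosInf, R_PosInf}, thi[2] = {R_NegInf, R_NegInf};
        for (int j = 0; j < 3; ++j) {
            int vi = F(t, j) - 1;
            double xx = V(vi, 0), zz = V(vi, 2);
            tlo[0] = std::min(tlo[0], xx); thi[0] = std::max(thi[0], xx);
            tlo[1] = std::min(tlo[1], zz); thi[1] = std::max(thi[1], zz);
        }
        int ix0 = std::max(0, std::min((int)std::floor((tlo[0] - lo[0]) / cell), n0 - 1));
        int ix1 = std::max(0, std::min((int)std::floor((thi[0] - lo[0]) / cell), n0 - 1));
        int iz0 = std::max(0, std::min((int)std::floor((tlo[1] - lo[1]) / cell), n1 - 1));
        int iz1 = std::max(0, std::min((int)std::floor((thi[1] - lo[1]) / cell), n1 - 1));
        for (int iz = iz0; iz <= iz1; ++iz)
            for (int ix = ix0; ix <= ix1; ++ix)
                bins[(size_t)iz * n0 + ix].push_back(t);
    }

    const double eps = 1e-9;
    for (int q = 0; q < nq; ++q) {
        double x = XZ(q, 0), z = XZ(q, 1);
        int ix = (int)std::floor((x - lo[0]) / cell);
        int iz = (int)std::floor((z - lo[1]) / cell);
        if (ix < 0 || ix >= n0 || iz < 0 || iz >= n1) continue;
        const std::vector<int>& bin = bins[(size_t)iz * n0 + ix];
        double besty = R_NegInf;
        bool hit = false;
        for (size_t bi = 0; bi < bin.size(); ++bi) {
            int t = bin[bi];
            int i0 = F(t, 0) - 1, i1 = F(t, 1) - 1, i2 = F(t, 2) - 1;
            double x0 = V(i0, 0), z0 = V(i0, 2);
            double x1 = V(i1, 0), z1 = V(i1, 2);
            double x2 = V(i2, 0), z2 = V(i2, 2);
            double det = (x1 - x0) * (z2 - z0) - (x2 - x0) * (z1 - z0);
            if (std::abs(det) < 1e-12) continue;  // edge-on triangle
            double l1 = ((x - x0) * (z2 - z0) - (z - z0) * (x2 - x0)) / det;
            double l2 = ((z - z0) * (x1 - x0) - (x - x0) * (z1 - z0)) / det;
            double l0 = 1.0 - l1 - l2;
            if (l0 < -eps || l1 < -eps || l2 < -eps) continue;
            double y = l0 * V(i0, 1) + l1 * V(i1, 1) + l2 * V(i2, 1);
            if (y > besty) besty = y;
            hit = true;
        }
        if (hit) out[q] = besty;
    }
    return out;
}
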