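// Spatial queries against triangle meshes: closest point on surface and
// first-hit ray casting, both accelerated by a uniform grid over triangle
// bounding boxes. Distances are exact (point-to-triangle by the standard
// region decomposition; ray-triangle by Moller-Trumbore); the grid only
// prunes candidates.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Vec3 {
    double x, y, z;
};
inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(Vec3 a, Vec3 b) {
    return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm2(Vec3 a) { return dot(a, a); }

// Closest point on triangle (a,b,c) to p; also returns barycentric (u,v,w).
// Ericson, Real-Time Collision Detection, 5.1.5.
Vec3 closestPointTriangle(Vec3 p, Vec3 a, Vec3 b, Vec3 c,
                          double& u, double& v, double& w) {
    Vec3 ab = b - a, ac = c - a, ap = p - a;
    double d1 = dot(ab, ap), d2 = dot(ac, ap);
    if (d1 <= 0.0 && d2 <= 0.0) { u = 1; v = 0; w = 0; return a; }
    Vec3 bp = p - b;
    double d3 = dot(ab, bp), d4 = dot(ac, bp);
    if (d3 >= 0.0 && d4 <= d3) { u = 0; v = 1; w = 0; return b; }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double t = d1 / (d1 - d3);
        u = 1 - t; v = t; w = 0;
        return a + t * ab;
    }
    Vec3 cp = p - c;
    double d5 = dot(ab, cp), d6 = dot(ac, cp);
    if (d6 >= 0.0 && d5 <= d6) { u = 0; v = 0; w = 1; return c; }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
        double t = d2 / (d2 - d6);
        u = 1 - t; v = 0; w = t;
        return a + t * ac;
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
        double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        u = 0; v = 1 - t; w = t;
        return b + t * (c - b);
    }
    double denom = 1.0 / (va + vb + vc);
    double vv = vb * denom, ww = vc * denom;
    u = 1 - vv - ww; v = vv; w = ww;
    return a + vv * ab + ww * ac;
}

// Moller-Trumbore; returns t >= 0 on hit (front or back face), NA on miss.
bool rayTriangle(Vec3 orig, Vec3 dir, Vec3 a, Vec3 b, Vec3 c, double& t) {
    const double EPS = 1e-12;
    Vec3 e1 = b - a, e2 = c - a;
    Vec3 pvec = cross(dir, e2);
    double det = dot(e1, pvec);
    if (std::fabs(det) < EPS) return false;
    double inv = 1.0 / det;
    Vec3 tvec = orig - a;
    double u = dot(tvec, pvec) * inv;
    if (u < -1e-9 || u > 1 + 1e-9) return false;
    Vec3 qvec = cross(tvec, e1);
    double v = dot(dir, qvec) * inv;
    if (v < -1e-9 || u + v > 1 + 1e-9) return false;
    t = dot(e2, qvec) * inv;
    return t >= 0.0;
}

struct TriGrid {
    std::vector<Vec3> A, B, C;           // triangle corners
    double x0, y0, z0, h;                // grid origin and cell size
    int nx, ny, nz;
    std::vector<std::vector<int>> cells; // triangle ids per cell
    std::vector<int> stamp;              // visited marker per triangle
    int stampVal = 0;

    int cellIndex(int ci, int cj, int ck) const {
        return ci + nx * (cj + ny * ck);
    }

    void build(const NumericMatrix& V, const IntegerMatrix& F) {
        int nf = F.nrow();
        A.resize(nf); B.resize(nf); C.resize(nf);
        double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
        double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
        double edgeSum = 0.0;
        for (int f = 0; f < nf; ++f) {
            int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
            A[f] = {V(ia, 0), V(ia, 1), V(ia, 2)};
            B[f] = {V(ib, 0), V(ib, 1), V(ib, 2)};
            C[f] = {V(ic, 0), V(ic, 1), V(ic, 2)};
            edgeSum += std::sqrt(norm2(B[f] - A[f]));
        }
        for (int v = 0; v < V.nrow(); ++v) {
            lo[0] = std::min(lo[0], V(v, 0)); hi[0] = std::max(hi[0], V(v, 0));
            lo[1] = std::min(lo[1], V(v, 1)); hi[1] = std::max(hi[1], V(v, 1));
            lo[2] = std::min(lo[2], V(v, 2)); hi[2] = std::max(hi[2], V(v, 2));
        }
        double meanEdge = nf > 0 ? edgeSum / nf : 1.0;
        h = std::max(meanEdge * 2.0, 1e-9);
        x0 = lo[0] - 0.5 * h; y0 = lo[1] - 0.5 * h; z0 = lo[2] - 0.5 * h;
        nx = std::max(1, (int)std::ceil((hi[0] - x0) / h) + 1);
        ny = std::max(1, (int)std::ceil((hi[1] - y0) / h) + 1);
        nz = std::max(1, (int)std::ceil((hi[2] - z0) / h) + 1);
        // Cap total cells to keep memory bounded for degenerate aspect ratios.
        while ((double)nx * ny * nz > 2e7) {
            h *= 2.0;
            nx = std::max(1, (nx + 1) / 2);
            ny = std::max(1, (ny + 1) / 2);
            nz = std::max(1, (nz + 1) / 2);
        }
        cells.assign((std::size_t)nx * ny * nz, {});
        for (int f = 0; f < nf; ++f) {
            double tlo[3] = {std::min({A[f].x, B[f].x, C[f].x}),
                             std::min({A[f].y, B[f].y, C[f].y}),
                             std::min({A[f].z, B[f].z, C[f].z})};
            double thi[3] = {std::max({A[f].x, B[f].x, C[f].x}),
                             std::max({A[f].y, B[f].y, C[f].y}),
                             std::max({A[f].z, B[f].z, C[f].z})};
            int i0 = clampi((int)((tlo[0] - x0) / h), 0, nx - 1);
            int i1 = clampi((int)((thi[0] - x0) / h), 0, nx - 1);
            int j0 = clampi((int)((tlo[1] - y0) / h), 0, ny - 1);
            int j1 = clampi((int)((thi[1] - y0) / h), 0, ny - 1);
            int k0 = clampi((int)((tlo[2] - z0) / h), 0, nz - 1);
            int k1 = clampi((int)((thi[2] - z0) / h), 0, nz - 1);
            for (int ck = k0; ck <= k1; ++ck)
                for (int cj = j0; cj <= j1; ++cj)
                    for (int ci = i0; ci <= i1; ++ci)
                        cells[cellIndex(ci, cj, ck)].push_back(f);
        }
        stamp.assign(nf, -1);
    }

    static int clampi(int v, int lo, int hi) {
        return v < lo ? lo : (v > hi ? hi : v);
    }

    // Closest point on the mesh to p. Expanding-shell search: a triangle in a
    // cell at Chebyshev ring r is at least (r-1)*h away from p's (clamped)
    // cell, so the search stops once that bound exceeds the best distance.
    void closest(Vec3 p, double& bestD2, int& bestF, Vec3& bestQ,
                 double& bu, double& bv, double& bw) {
        ++stampVal;
        int ci = clampi((int)((p.x - x0) / h), 0, nx - 1);
        int cj = clampi((int)((p.y - y0) / h), 0, ny - 1);
        int ck = clampi((int)((p.z - z0) / h), 0, nz - 1);
        bestD2 = R_PosInf; bestF = -1;
        int rmax = std::max({nx, ny, nz});
        for (int r = 0; r <= rmax; ++r) {
            if (bestF >= 0) {
                double bound = (double)(r - 1) * h;
                if (bound > 0 && bound * bound > bestD2) break;
            }
            int i0 = std::max(0, ci - r), i1 = std::min(nx - 1, ci + r);
            int j0 = std::max(0, cj - r), j1 = std::min(ny - 1, cj + r);
            int k0 = std::max(0, ck - r), k1 = std::min(nz - 1, ck + r);
            for (int k = k0; k <= k1; ++k)
            for (int j = j0; j <= j1; ++j)
            for (int i = i0; i <= i1; ++i) {
                // only the shell surface of the expanding box
                if (r > 0 && std::max({std::abs(i - ci), std::abs(j - cj),
                                       std::abs(k - ck)}) != r)
                    continue;
                for (int f : cells[cellIndex(i, j, k)]) {
                    if (stamp[f] == stampVal) continue;
                    stamp[f] = stampVal;
                    double u, v, w;
                    Vec3 q = closestPointTriangle(p, A[f], B[f], C[f], u, v, w);
                    double d2 = norm2(q - p);
                    if (d2 < bestD2) {
                        bestD2 = d2; bestF = f; bestQ = q;
                        bu = u; bv = v; bw = w;
                    }
                }
            }
        }
    }

    // First ray hit with t in (tmin, tmax]; 3D-DDA traversal of the grid.
    double firstHit(Vec3 orig, Vec3 dir, double tmin, double tmax, int& hitF) {
        hitF = -1;
        double best = R_PosInf;
        ++stampVal;
        // Clip the ray to the grid's bounding box.
        double gx1 = x0 + nx * h, gy1 = y0 + ny * h, gz1 = z0 + nz * h;
        double t0 = 0.0, t1 = tmax;
        const double lo[3] = {x0, y0, z0}, hi[3] = {gx1, gy1, gz1};
        const double o[3] = {orig.x, orig.y, orig.z};
        const double d[3] = {dir.x, dir.y, dir.z};
        for (int ax = 0; ax < 3; ++ax) {
            if (std::fabs(d[ax]) < 1e-15) {
                if (o[ax] < lo[ax] || o[ax] > hi[ax]) return NA_REAL;
            } else {
                double ta = (lo[ax] - o[ax]) / d[ax];
                double tb = (hi[ax] - o[ax]) / d[ax];
                if (ta > tb) std::swap(ta, tb);
                t0 = std::max(t0, ta);
                t1 = std::min(t1, tb);
            }
        }
        if (t0 > t1) return NA_REAL;
        Vec3 start = orig + (t0 + 1e-9) * dir;
        int ci = clampi((int)((start.x - x0) / h), 0, nx - 1);
        int cj = clampi((int)((start.y - y0) / h), 0, ny - 1);
        int ck = clampi((int)((start.z - z0) / h), 0, nz - 1);
        int stepi = d[0] > 0 ? 1 : -1, stepj = d[1] > 0 ? 1 : -1,
            stepk = d[2] > 0 ? 1 : -1;
        auto boundary = [&](int c, double org, double dd, double orig0) {
            // ray parameter at which the ray leaves cell c along this axis
            if (std::fabs(dd) < 1e-15) return R_PosInf;
            double edge = orig0 + (dd > 0 ? (c + 1) : c) * h;
            return (edge - org) / dd;
        };
        double tx = boundary(ci, o[0], d[0], x0);
        double ty = boundary(cj, o[1], d[1], y0);
        double tz = boundary(ck, o[2], d[2], z0);
        double dtx = std::fabs(d[0]) < 1e-15 ? R_PosInf : h / std::fabs(d[0]);
        double dty = std::fabs(d[1]) < 1e-15 ? R_PosInf : h / std::fabs(d[1]);
        double dtz = std::fabs(d[2]) < 1e-15 ? R_PosInf : h / std::fabs(d[2]);
        double tcell = t0;
        while (true) {
            for (int f : cells[cellIndex(ci, cj, ck)]) {
                if (stamp[f] == stampVal) continue;
                stamp[f] = stampVal;
                double t;
                if (rayTriangle(orig, dir, A[f], B[f], C[f], t) &&
                    t > tmin && t <= tmax && t < best) {
                    best = t; hitF = f;
                }
            }
            double tnext = std::min({tx, ty, tz});
            if (best <= tnext || tcell > t1) break;  // hit before leaving cell
            if (tx <= ty && tx <= tz) { ci += stepi; tx += dtx; }
            else if (ty <= tz)        { cj += stepj; ty += dty; }
            else                      { ck += stepk; tz += dtz; }
            if (ci < 0 || ci >= nx || cj < 0 || cj >= ny || ck < 0 || ck >= nz)
                break;
            tcell = tnext;
        }
        return hitF >= 0 ? best : NA_REAL;
    }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_closest_on_mesh")]]
List closest_on_mesh(NumericMatrix points, NumericMatrix V, IntegerMatrix F) {
    TriGrid grid;
    grid.build(V, F);
    int n = points.nrow();
    NumericVector dist(n);
    NumericMatrix closest(n, 3);
    IntegerVector face(n);
    NumericMatrix bary(n, 3);
    for (int i = 0; i < n; ++i) {
        Vec3 p = {points(i, 0), points(i, 1), points(i, 2)};
        double d2, u, v, w;
        int f;
        Vec3 q;
        grid.closest(p, d2, f, q, u, v, w);
        dist[i] = std::sqrt(d2);
        closest(i, 0) = q.x; closest(i, 1) = q.y; closest(i, 2) = q.z;
        face[i] = f + 1;
        bary(i, 0) = u; bary(i, 1) = v; bary(i, 2) = w;
    }
    return List::create(_["distance"] = dist, _["point"] = closest,
                        _["face"] = face, _["bary"] = bary);
}

// [[Rcpp::export(name = ".cpp_ray_first_hit")]]
List ray_first_hit(NumericMatrix origins, NumericMatrix dirs,
                   NumericMatrix V, IntegerMatrix F,
                   double tmin, double tmax) {
    TriGrid grid;
    grid.build(V, F);
    int n = origins.nrow();
    NumericVector tout(n);
    IntegerVector face(n);
    for (int i = 0; i < n; ++i) {
        Vec3 o = {origins(i, 0), origins(i, 1), origins(i, 2)};
        Vec3 d = {dirs(i, 0), dirs(i, 1), dirs(i, 2)};
        int f;
        tout[i] = grid.firstHit(o, d, tmin, tmax, f);
        face[i] = f + 1;  // 0 means no hit
    }
    return List::create(_["t"] = tout, _["face"] = face);
}

// 6-connected component labelling of a binary 3D mask (iterative BFS).
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector label_components(IntegerVector mask, IntegerVector dims) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const std::size_t n = (std::size_t)nx * ny * nz;
    IntegerVector labels(n, 0);
    std::vector<std::size_t> queue;
    int next = 0;
    for (std::size_t s = 0; s < n; ++s) {
        if (mask[s] == 0 || labels[s] != 0) continue;
        ++next;
        labels[s] = next;
        queue.clear();
        queue.push_back(s);
        while (!queue.empty()) {
            std::size_t cur = queue.back();
            queue.pop_back();
            int i = cur % nx, j = (cur / nx) % ny, k = cur / ((std::size_t)nx * ny);
            const int di[6] = {-1, 1, 0, 0, 0, 0};
            const int dj[6] = {0, 0, -1, 1, 0, 0};
            const int dk[6] = {0, 0, 0, 0, -1, 1};
            for (int m = 0; m < 6; ++m) {
                int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                    continue;
                std::size_t t = (std::size_t)ii + nx * (jj + (std::size_t)ny * kk);
                if (mask[t] != 0 && labels[t] == 0) {
                    labels[t] = next;
                    queue.push_back(t);
                }
            }
        }
    }
    labels.attr("n_components") = next;
    return labels;
}
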