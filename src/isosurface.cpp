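// Isosurface extraction from a scalar 3D field by marching tetrahedra.
//
// Each grid cube is split into the six Kuhn (Freudenthal) tetrahedra that
// share the main diagonal; this decomposition tiles the lattice consistently,
// so shared cube faces carry matching diagonals and the extracted surface is
// watertight. Surface vertices live on lattice edges and are welded through a
// hash on the (sorted) pair of global node indices, so triangles from
// neighbouring tetrahedra share vertices exactly.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct EdgeKey {
    std::uint64_t k;
    EdgeKey(std::uint64_t a, std::uint64_t b) {
        if (a > b) std::swap(a, b);
        k = (a << 32) | b;
    }
    bool operator==(const EdgeKey& o) const { return k == o.k; }
};

struct EdgeKeyHash {
    std::size_t operator()(const EdgeKey& e) const {
        return std::hash<std::uint64_t>()(e.k);
    }
};

// Cube corner offsets, corner index c in 0..7 encodes (dx, dy, dz) bits.
inline int cornerDx(int c) { return c & 1; }
inline int cornerDy(int c) { return (c >> 1) & 1; }
inline int cornerDz(int c) { return (c >> 2) & 1; }

// Six Kuhn tetrahedra of the unit cube: walk from corner 0 to corner 7
// adding one axis at a time, in each of the 6 axis orders.
static const int TETS[6][4] = {
    {0, 1, 3, 7},  // x, y, z
    {0, 1, 5, 7},  // x, z, y
    {0, 2, 3, 7},  // y, x, z
    {0, 2, 6, 7},  // y, z, x
    {0, 4, 5, 7},  // z, x, y
    {0, 4, 6, 7}   // z, y, x
};

struct MeshBuilder {
    std::unordered_map<EdgeKey, int, EdgeKeyHash> edgeVertex;
    std::vector<double> vx, vy, vz;   // vertex positions (voxel index space)
    std::vector<int> tri;             // flat triangle index list (0-based)

    int vertexOnEdge(std::uint64_t ga, std::uint64_t gb,
                     const double pa[3], const double pb[3],
                     double va, double vb, double iso) {
        EdgeKey key(ga, gb);
        auto it = edgeVertex.find(key);
        if (it != edgeVertex.end()) return it->second;
        double t = (iso - va) / (vb - va);
        if (t < 1e-6) t = 1e-6;
        if (t > 1.0 - 1e-6) t = 1.0 - 1e-6;
        int id = (int)vx.size();
        vx.push_back(pa[0] + t * (pb[0] - pa[0]));
        vy.push_back(pa[1] + t * (pb[1] - pa[1]));
        vz.push_back(pa[2] + t * (pb[2] - pa[2]));
        edgeVertex.emplace(key, id);
        return id;
    }

    // Add triangle (a,b,c) as given, or with b/c swapped when flip is true.
    void addTri(int a, int b, int c, bool flip) {
        if (flip) std::swap(b, c);
        tri.push_back(a); tri.push_back(b); tri.push_back(c);
    }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_marching_tets")]]
List marching_tets(NumericVector field, IntegerVector dims, double iso) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double* f = REAL(field);
    auto at = [&](int i, int j, int k) -> double {
        return f[(std::size_t)i + (std::size_t)nx * (j + (std::size_t)ny * k)];
    };
    auto gid = [&](int i, int j, int k) -> std::uint64_t {
        return (std::uint64_t)i + (std::uint64_t)nx * (j + (std::uint64_t)ny * k);
    };

    MeshBuilder mb;
    double cpos[8][3];
    double cval[8];
    std::uint64_t cgid[8];

    for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
    for (int i = 0; i + 1 < nx; ++i) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
            int ci = i + cornerDx(c), cj = j + cornerDy(c), ck = k + cornerDz(c);
            cval[c] = at(ci, cj, ck);
            (cval[c] > iso ? anyIn : anyOut) = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int c = 0; c < 8; ++c) {
            cpos[c][0] = i + cornerDx(c);
            cpos[c][1] = j + cornerDy(c);
            cpos[c][2] = k + cornerDz(c);
            cgid[c] = gid(i + cornerDx(c), j + cornerDy(c), k + cornerDz(c));
        }

        for (int t = 0; t < 6; ++t) {
            const int* T = TETS[t];
            int in[4], nin = 0, out[4], nout = 0;
            for (int v = 0; v < 4; ++v) {
                if (cval[T[v]] > iso) in[nin++] = T[v]; else out[nout++] = T[v];
            }
            if (nin == 0 || nin == 4) continue;

            auto ev = [&](int a, int b) {
                return mb.vertexOnEdge(cgid[a], cgid[b], cpos[a], cpos[b],
                                       cval[a], cval[b], iso);
            };
            // Signed volume of tet (p,q,r,s): exact on lattice coordinates.
            // Orientation of each emitted triangle follows from its sign, so
            // winding is robust even for sliver triangles.
            auto det3 = [&](int p, int q, int r, int s) -> double {
                double ax = cpos[q][0] - cpos[p][0], ay = cpos[q][1] - cpos[p][1],
                       az = cpos[q][2] - cpos[p][2];
                double bx = cpos[r][0] - cpos[p][0], by = cpos[r][1] - cpos[p][1],
                       bz = cpos[r][2] - cpos[p][2];
                double cx = cpos[s][0] - cpos[p][0], cy = cpos[s][1] - cpos[p][1],
                       cz = cpos[s][2] - cpos[p][2];
                return ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
                       az * (bx * cy - by * cx);
            };

            if (nin == 1) {
                // Normal away from the single inside corner iff the outside
                // corners are positively oriented around it.
                bool flip = det3(in[0], out[0], out[1], out[2]) < 0.0;
                mb.addTri(ev(in[0], out[0]), ev(in[0], out[1]), ev(in[0], out[2]),
                          flip);
            } else if (nin == 3) {
                // Mirror case: normal must point toward the outside corner.
                bool flip = det3(out[0], in[0], in[1], in[2]) > 0.0;
                mb.addTri(ev(out[0], in[0]), ev(out[0], in[1]), ev(out[0], in[2]),
                          flip);
            } else {  // nin == 2: quad split into two triangles
                bool flip = det3(in[0], in[1], out[0], out[1]) < 0.0;
                int q0 = ev(in[0], out[0]);
                int q1 = ev(in[0], out[1]);
                int q2 = ev(in[1], out[1]);
                int q3 = ev(in[1], out[0]);
                mb.addTri(q0, q1, q2, flip);
                mb.addTri(q0, q2, q3, flip);
            }
        }
    }

    const int nv = (int)mb.vx.size();
    const int nf = (int)mb.tri.size() / 3;
    NumericMatrix V(nv, 3);
    for (int v = 0; v < nv; ++v) {
        V(v, 0) = mb.vx[v]; V(v, 1) = mb.vy[v]; V(v, 2) = mb.vz[v];
    }
    IntegerMatrix F(nf, 3);
    for (int q = 0; q < nf; ++q) {
        F(q, 0) = mb.tri[3 * q] + 1;      // 1-based for R
        F(q, 1) = mb.tri[3 * q + 1] + 1;
        F(q, 2) = mb.tri[3 * q + 2] + 1;
    }
    return List::create(_["vertices"] = V, _["faces"] = F);
}
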