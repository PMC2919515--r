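#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// squared distance from p to segment [a, b]
static inline double seg_dist2(double px, double py,
                               double ax, double ay,
                               double bx, double by) {
    double dx = bx - ax, dy = by - ay;
    double L2 = dx * dx + dy * dy;
    double t = 0.0;
    if (L2 > 0.0) {
        t = ((px - ax) * dx + (py - ay) * dy) / L2;
        if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
    }
    double qx = ax + t * dx - px;
    double qy = ay + t * dy - py;
    return qx * qx + qy * qy;
}

// even-odd crossing rule; vertices form a ring (closing edge implied)
static inline bool point_in_ring(double px, double py,
                                 const double* vx, const double* vy, int n) {
    bool inside = false;
    for (int i = 0, j = n - 1; i < n; j = i++) {
        if ((vy[i] > py) != (vy[j] > py)) {
            double xint = vx[j] + (py - vy[j]) * (vx[i] - vx[j]) / (vy[i] - vy[j]);
            if (px < xint) inside = !inside;
        }
    }
    return inside;
}

// signed distance from one point to one object.
// n == 1: Euclidean distance to a point object (always >= 0).
// n >= 3: minimum distance to the polygon boundary, negative inside,
//         0 within `tol` of the boundary.
static double signed_obj_dist(double px, double py,
                              const double* vx, const double* vy,
                              int n, double tol) {
    if (n == 1) {
        double dx = px - vx[0], dy = py - vy[0];
        return std::sqrt(dx * dx + dy * dy);
    }
    double b2 = R_PosInf;
    for (int i = 0, j = n - 1; i < n; j = i++) {
        double d2 = seg_dist2(px, py, vx[j], vy[j], vx[i], vy[i]);
        if (d2 < b2) b2 = d2;
    }
    double b = std::sqrt(b2);
    if (b < tol) return 0.0;
    return point_in_ring(px, py, vx, vy, n) ? -b : b;
}

// Signed nearest-neighbour distances from query points to a set of
// reference objects. Objects are passed flattened: vertices (vx, vy),
// per-object offsets `start` (0-based) and lengths `len`. Pruning uses
// per-object bounding circles (centre cx, cy; radius rmax): for any point,
// dist(p, centre) - rmax is a lower bound on the signed distance.
// [[Rcpp::export]]
NumericVector cpp_nn_signed(NumericVector px, NumericVector py,
                            NumericVector vx, NumericVector vy,
                            IntegerVector start, IntegerVector len,
                            NumericVector cx, NumericVector cy,
                            NumericVector rmax, double tol) {
    int n = px.size(), M = start.size();
    NumericVector out(n);
    std::vector<double> lb(M);
    const double* vxp = REAL(vx);
    const double* vyp = REAL(vy);
    for (int q = 0; q < n; q++) {
        double x = px[q], y = py[q];
        int jbest = 0;
        double lbmin = R_PosInf;
        for (int j = 0; j < M; j++) {
            double dx = x - cx[j], dy = y - cy[j];
            double l = std::sqrt(dx * dx + dy * dy) - rmax[j];
            lb[j] = l;
            if (l < lbmin) { lbmin = l; jbest = j; }
        }
        double best = signed_obj_dist(x, y, vxp + start[jbest], vyp + start[jbest],
                                      len[jbest], tol);
        for (int j = 0; j < M; j++) {
            if (j == jbest || lb[j] >= best) continue;
            double d = signed_obj_dist(x, y, vxp + start[j], vyp + start[j],
                                       len[j], tol);
            if (d < best) best = d;
        }
        out[q] = best;
    }
    return out;
}

// Batch even-odd point-in-polygon test (boundary counts as inside when
// within tol of an edge).
// [[Rcpp::export]]
LogicalVector cpp_in_polygon(NumericVector px, NumericVector py,
                             NumericVector vx, NumericVector vy, double tol) {
    int n = px.size(), m = vx.size();
    LogicalVector out(n);
    const double* vxp = REAL(vx);
    const double* vyp = REAL(vy);
    for (int q = 0; q < n; q++) {
        bool inside = point_in_ring(px[q], py[q], vxp, vyp, m);
        if (!inside && tol > 0.0) {
            double t2 = tol * tol;
            for (int i = 0, j = m - 1; i < m; j = i++) {
                if (seg_dist2(px[q], py[q], vxp[j], vyp[j], vxp[i], vyp[i]) < t2) {
                    inside = true;
                    break;
                }
            }
        }
        out[q] = inside;
    }
    return out;
}
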