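#include <Rcpp.h>
#include <vector>
#include <queue>
#include <set>
#include <cmath>
#include <algorithm>

// Quadric edge-collapse mesh decimation (Garland-Heckbert error quadrics,
// area-weighted plane accumulation, optimal collapse placement with midpoint
// fallback, link-condition and normal-flip guards).

namespace {

struct Quadric {
  double q[10]; // symmetric 4x4: stored as upper triangle row-major
  Quadric() { for (int i = 0; i < 10; ++i) q[i] = 0.0; }
  void addPlane(double a, double b, double c, double d, double w) {
    q[0] += w * a * a; q[1] += w * a * b; q[2] += w * a * c; q[3] += w * a * d;
    q[4] += w * b * b; q[5] += w * b * c; q[6] += w * b * d;
    q[7] += w * c * c; q[8] += w * c * d;
    q[9] += w * d * d;
  }
  void add(const Quadric& o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(double x, double y, double z) const {
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
         + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
         + q[7]*z*z + 2*q[8]*z + q[9];
  }
  // minimize: solve [q0 q1 q2; q1 q4 q5; q2 q5 q7] v = -[q3; q6; q8]
  bool minimize(double& x, double& y, double& z) const {
    double a11 = q[0], a12 = q[1], a13 = q[2];
    double a22 = q[4], a23 = q[5], a33 = q[7];
    double det = a11*(a22*a33 - a23*a23) - a12*(a12*a33 - a23*a13)
               + a13*(a12*a23 - a22*a13);
    if (std::fabs(det) < 1e-12) return false;
    double b1 = -q[3], b2 = -q[6], b3 = -q[8];
    x = ( b1*(a22*a33 - a23*a23) - a12*(b2*a33 - a23*b3) + a13*(b2*a23 - a22*b3)) / det;
    y = ( a11*(b2*a33 - a23*b3) - b1*(a12*a33 - a13*a23) + a13*(a12*b3 - b2*a13)) / det;
    z = ( a11*(a22*b3 - b2*a23) - a12*(a12*b3 - b2*a13) + b1*(a12*a23 - a22*a13)) / det;
    return std::isfinite(x) && std::isfinite(y) && std::isfinite(z);
  }
};

struct Cand {
  double cost;
  int u, v;
  long stamp;
  double x, y, z;
  bool operator<(const Cand& o) const { return cost > o.cost; } // min-heap
};

} // namespace

// [[Rcpp::export(name = ".cpp_qem_decimate")]]
Rcpp::List cpp_qem_decimate(Rcpp::NumericMatrix Vin, Rcpp::IntegerMatrix Fin,
                            int targetFaces) {
  int nv = Vin.nrow(), nf = Fin.nrow();
  std::vector<double> VX(nv), VY(nv), VZ(nv);
  for (int i = 0; i < nv; ++i) { VX[i] = Vin(i,0); VY[i] = Vin(i,1); VZ[i] = Vin(i,2); }
  std::vector<int> FA(nf), FB(nf), FC(nf);
  std::vector<bool> faceAlive(nf, true), vertAlive(nv, true);
  for (int f = 0; f < nf; ++f) { FA[f] = Fin(f,0); FB[f] = Fin(f,1); FC[f] = Fin(f,2); }

  std::vector<std::vector<int> > vfaces(nv);
  for (int f = 0; f < nf; ++f) {
    vfaces[FA[f]].push_back(f); vfaces[FB[f]].push_back(f); vfaces[FC[f]].push_back(f);
  }

  std::vector<Quadric> Q(nv);
  for (int f = 0; f < nf; ++f) {
    double ux = VX[FB[f]]-VX[FA[f]], uy = VY[FB[f]]-VY[FA[f]], uz = VZ[FB[f]]-VZ[FA[f]];
    double vx = VX[FC[f]]-VX[FA[f]], vy = VY[FC[f]]-VY[FA[f]], vz = VZ[FC[f]]-VZ[FA[f]];
    double nx = uy*vz - uz*vy, ny = uz*vx - ux*vz, nz = ux*vy - uy*vx;
    double len = std::sqrt(nx*nx + ny*ny + nz*nz);
    if (len < 1e-300) continue;
    double area = 0.5 * len;
    nx /= len; ny /= len; nz /= len;
    double d = -(nx*VX[FA[f]] + ny*VY[FA[f]] + nz*VZ[FA[f]]);
    Q[FA[f]].addPlane(nx, ny, nz, d, area);
    Q[FB[f]].addPlane(nx, ny, nz, d, area);
    Q[FC[f]].addPlane(nx, ny, nz, d, area);
  }

  // boundary constraint quadrics (Garland-Heckbert): for each open-boundary
  // edge add a heavily weighted plane through the edge, perpendicular to the
  // adjacent face, so the boundary does not drift inwards.
  {
    std::map<std::pair<int,int>, std::pair<int,int> > edgeUse; // edge -> (count, face)
    for (int f = 0; f < nf; ++f) {
      int e[3][2] = { {FA[f], FB[f]}, {FB[f], FC[f]}, {FC[f], FA[f]} };
      for (int j = 0; j < 3; ++j) {
        std::pair<int,int> key(std::min(e[j][0], e[j][1]),
                               std::max(e[j][0], e[j][1]));
        std::map<std::pair<int,int>, std::pair<int,int> >::iterator it =
          edgeUse.find(key);
        if (it == edgeUse.end()) edgeUse[key] = std::make_pair(1, f);
        else it->second.first += 1;
      }
    }
    for (std::map<std::pair<int,int>, std::pair<int,int> >::iterator it =
           edgeUse.begin(); it != edgeUse.end(); ++it) {
      if (it->second.first != 1) continue;
      int a = it->first.first, b = it->first.second, f = it->second.second;
      double ex = VX[b]-VX[a], ey = VY[b]-VY[a], ez = VZ[b]-VZ[a];
      double ux = VX[FB[f]]-VX[FA[f]], uy = VY[FB[f]]-VY[FA[f]], uz = VZ[FB[f]]-VZ[FA[f]];
      double vx = VX[FC[f]]-VX[FA[f]], vy = VY[FC[f]]-VY[FA[f]], vz = VZ[FC[f]]-VZ[FA[f]];
      double fnx = uy*vz - uz*vy, fny = uz*vx - ux*vz, fnz = ux*vy - uy*vx;
      // plane normal = edge x face normal
      double nx = ey*fnz - ez*fny, ny = ez*fnx - ex*fnz, nz = ex*fny - ey*fnx;
      double len = std::sqrt(nx*nx + ny*ny + nz*nz);
      if (len < 1e-300) continue;
      nx /= len; ny /= len; nz /= len;
      double d = -(nx*VX[a] + ny*VY[a] + nz*VZ[a]);
      double elen2 = ex*ex + ey*ey + ez*ez;
      double w = 1000.0 * elen2;
      Quadric bq;
      bq.addPlane(nx, ny, nz, d, w);
      Q[a].add(bq);
      Q[b].add(bq);
    }
  }

  std::vector<long> version(nv, 0);
  std::priority_queue<Cand> heap;

  // neighbour vertex sets derived from live faces
  struct Helper {
    std::vector<std::vector<int> >& vfaces;
    std::vector<bool>& faceAlive;
    std::vector<int>& FA; std::vector<int>& FB; std::vector<int>& FC;
    Helper(std::vector<std::vector<int> >& vf, std::vector<bool>& fa,
           std::vector<int>& A, std::vector<int>& B, std::vector<int>& C)
      : vfaces(vf), faceAlive(fa), FA(A), FB(B), FC(C) {}
    void neighbours(int v, std::set<int>& out) {
      out.clear();
      for (size_t k = 0; k < vfaces[v].size(); ++k) {
        int f = vfaces[v][k];
        if (!faceAlive[f]) continue;
        if (FA[f] != v) out.insert(FA[f]);
        if (FB[f] != v) out.insert(FB[f]);
        if (FC[f] != v) out.insert(FC[f]);
      }
    }
  } H(vfaces, faceAlive, FA, FB, FC);

  Quadric Qsum;
  int liveFaces = 0;
  for (int f = 0; f < nf; ++f) if (faceAlive[f]) ++liveFaces;

  // seed heap with all edges
  {
    std::set<std::pair<int,int> > seen;
    for (int f = 0; f < nf; ++f) {
      int e[3][2] = { {FA[f], FB[f]}, {FB[f], FC[f]}, {FC[f], FA[f]} };
      for (int j = 0; j < 3; ++j) {
        int u = std::min(e[j][0], e[j][1]), v = std::max(e[j][0], e[j][1]);
        if (!seen.insert(std::make_pair(u, v)).second) continue;
        Cand c; c.u = u; c.v = v; c.stamp = 0;
        Qsum = Q[u]; Qsum.add(Q[v]);
        if (!Qsum.minimize(c.x, c.y, c.z)) {
          c.x = 0.5*(VX[u]+VX[v]); c.y = 0.5*(VY[u]+VY[v]); c.z = 0.5*(VZ[u]+VZ[v]);
        }
        c.cost = Qsum.eval(c.x, c.y, c.z);
        heap.push(c);
      }
    }
  }

  std::set<int> nu, nv2, common;
  long guard = 0, guardMax = 40L * (long)nf + 100000L;

  while (liveFaces > targetFaces && !heap.empty() && ++guard < guardMax) {
    Cand c = heap.top(); heap.pop();
    int u = c.u, v = c.v;
    if (!vertAlive[u] || !vertAlive[v]) continue;
    if (c.stamp != version[u] + version[v]) continue; // stale
    // still an edge?
    bool isEdge = false;
    for (size_t k = 0; k < vfaces[u].size() && !isEdge; ++k) {
      int f = vfaces[u][k];
      if (!faceAlive[f]) continue;
      if (FA[f]==v || FB[f]==v || FC[f]==v) isEdge = true;
    }
    if (!isEdge) continue;

    // link condition: shared neighbours must be <= 2
    H.neighbours(u, nu); H.neighbours(v, nv2);
    common.clear();
    std::set_intersection(nu.begin(), nu.end(), nv2.begin(), nv2.end(),
                          std::inserter(common, common.begin()));
    if (common.size() > 2) continue;

    // normal-flip guard on surviving faces
    bool flip = false;
    for (int pass = 0; pass < 2 && !flip; ++pass) {
      const std::vector<int>& fl = (pass == 0) ? vfaces[u] : vfaces[v];
      for (size_t k = 0; k < fl.size(); ++k) {
        int f = fl[k];
        if (!faceAlive[f]) continue;
        int a = FA[f], b = FB[f], cc = FC[f];
        bool hasU = (a==u||b==u||cc==u), hasV = (a==v||b==v||cc==v);
        if (hasU && hasV) continue; // face will be removed
        double ax = VX[a], ay = VY[a], az = VZ[a];
        double bx = VX[b], by = VY[b], bz = VZ[b];
        double cx = VX[cc], cy = VY[cc], cz = VZ[cc];
        double n0x = (by-ay)*(cz-az)-(bz-az)*(cy-ay);
        double n0y = (bz-az)*(cx-ax)-(bx-ax)*(cz-az);
        double n0z = (bx-ax)*(cy-ay)-(by-ay)*(cx-ax);
        // move the collapsing endpoint to the new position
        if (a==u||a==v) { ax=c.x; ay=c.y; az=c.z; }
        if (b==u||b==v) { bx=c.x; by=c.y; bz=c.z; }
        if (cc==u||cc==v){ cx=c.x; cy=c.y; cz=c.z; }
        double n1x = (by-ay)*(cz-az)-(bz-az)*(cy-ay);
        double n1y = (bz-az)*(cx-ax)-(bx-ax)*(cz-az);
        double n1z = (bx-ax)*(cy-ay)-(by-ay)*(cx-ax);
        if (n0x*n1x + n0y*n1y + n0z*n1z <= 0) { flip = true; break; }
      }
    }
    if (flip) continue;

    // collapse v into u at new position
    VX[u] = c.x; VY[u] = c.y; VZ[u] = c.z;
    Q[u].add(Q[v]);
    vertAlive[v] = false;
    for (size_t k = 0; k < vfaces[v].size(); ++k) {
      int f = vfaces[v][k];
      if (!faceAlive[f]) continue;
      bool hasU = (FA[f]==u||FB[f]==u||FC[f]==u);
      if (hasU) { faceAlive[f] = false; --liveFaces; continue; }
      if (FA[f]==v) FA[f]=u;
      if (FB[f]==v) FB[f]=u;
      if (FC[f]==v) FC[f]=u;
      vfaces[u].push_back(f);
    }
    version[u] += 1;

    // re-evaluate edges incident to u
    H.neighbours(u, nu);
    for (std::set<int>::iterator it = nu.begin(); it != nu.end(); ++it) {
      int w = *it;
      Cand nc; nc.u = std::min(u, w); nc.v = std::max(u, w);
      nc.stamp = version[nc.u] + version[nc.v];
      Qsum = Q[nc.u]; Qsum.add(Q[nc.v]);
      if (!Qsum.minimize(nc.x, nc.y, nc.z)) {
        nc.x = 0.5*(VX[nc.u]+VX[nc.v]); nc.y = 0.5*(VY[nc.u]+VY[nc.v]);
        nc.z = 0.5*(VZ[nc.u]+VZ[nc.v]);
      }
      nc.cost = Qsum.eval(nc.x, nc.y, nc.z);
      heap.push(nc);
    }
  }

  // compact
  std::vector<int> remap(nv, -1);
  int nvOut = 0;
  for (int i = 0; i < nv; ++i) if (vertAlive[i]) remap[i] = nvOut++;
  int nfOut = 0;
  for (int f = 0; f < nf; ++f) if (faceAlive[f]) ++nfOut;
  Rcpp::NumericMatrix Vout(nvOut, 3);
  for (int i = 0; i < nv; ++i) {
    if (remap[i] < 0) continue;
    Vout(remap[i], 0) = VX[i]; Vout(remap[i], 1) = VY[i]; Vout(remap[i], 2) = VZ[i];
  }
  Rcpp::IntegerMatrix Fout(nfOut, 3);
  int r = 0;
  for (int f = 0; f < nf; ++f) {
    if (!faceAlive[f]) continue;
    Fout(r, 0) = remap[FA[f]]; Fout(r, 1) = remap[FB[f]]; Fout(r, 2) = remap[FC[f]];
    ++r;
  }
  return Rcpp::List::create(Rcpp::Named("vertices") = Vout,
                            Rcpp::Named("faces") = Fout);
}
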