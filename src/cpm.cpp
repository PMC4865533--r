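// Cellular Potts engine for a quasi-2D section of the blastocoel roof.
//
// Lattice labels: 0 external medium, 1 blastocoel cavity, 2 immutable basal
// separator, 3 immutable anchor, >=10 cell ids.  The grid is stored as an
// R integer matrix with nrow = width (x), ncol = height (y); y increases
// toward the external side (the SL sits at large y, the cavity at small y).
//
// One Monte Carlo sweep = N copy attempts (N = mutable sites); after the
// lattice attempts the chemoattractant field is sub-stepped, elastic DC-SC
// links and SC neighbor bonds are updated, and the open lateral boundary
// rules (release / removal / DC replenishment) are applied.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>
#include <algorithm>
using namespace Rcpp;

static const int L_EXT = 0, L_CAV = 1, L_SEP = 2, L_ANC = 3, L_CELL0 = 10;
static const int K_DC = 0, K_SC = 1, K_CAV = 2, K_EXT = 3, K_SEP = 4, K_ANC = 5;

// 4th-order contact neighborhood (20 sites)
static const int NB20[20][2] = {
  {1,0},{-1,0},{0,1},{0,-1},
  {1,1},{1,-1},{-1,1},{-1,-1},
  {2,0},{-2,0},{0,2},{0,-2},
  {1,2},{2,1},{1,-2},{2,-1},{-1,2},{-2,1},{-1,-2},{-2,-1}};
// half set: each unordered pair counted once in the Hamiltonian
static const int NB10[10][2] = {
  {1,0},{0,1},{1,1},{1,-1},{2,0},{0,2},{1,2},{2,1},{1,-2},{2,-1}};
static const int NB8[8][2] = {
  {1,0},{1,1},{0,1},{-1,1},{-1,0},{-1,-1},{0,-1},{1,-1}};

struct CellRec {
  int id, kind;
  double tvol;
  bool frozen, alive;
  double c0;
  long vol;
  double sumx, sumy;
  int sep_contact;      // # of own sites 4-adjacent to the separator
};

struct Bond { int a, b; bool active; double d0; };
struct Link { int dc, sc; double rest; int age; };

struct Params {
  double J[6][6];
  double lambda_v, temperature, lambda_chem;
  double D, k_decay, dt_chem, level_multiplier;
  double p_form, p_break, k_spring, k_coh;
  int contact_threshold, sc_min_contact;
  bool boundary, replenish;
  int replenish_w;
  double dc_c0;
  double mcs_min;        // simulated minutes per Monte Carlo sweep
  double tick_min;       // housekeeping interval (chemo, links, boundary)
  int record_every_min;
  std::vector<int> clamp_sites;
  double clamp_value;
};

class Engine {
public:
  int w, h;
  std::vector<int> lab;
  std::vector<double> conc, conc2;
  std::vector<CellRec> cells;
  std::vector<int> idmap;            // id -> index, -1 absent
  std::vector<Bond> bonds;
  std::vector<Link> links;
  Params P;
  int sep_row, anc_lx, anc_rx;       // 0-based; -1 when absent
  double spacing;
  double anc_l_cx, anc_l_cy, anc_r_cx, anc_r_cy;
  std::mt19937_64 gen;
  double time_min;
  long n_immutable;
  // event log
  std::vector<int> inserted_ids, frozen_ids, removed_ids;
  int replenish_skipped = 0;
  long accepted = 0, attempts = 0;
  long guard_checked = 0, guard_rejected = 0;

  // Active-site bookkeeping: a copy attempt can only change the lattice at
  // a mutable site with at least one differently-labeled 8-neighbor, so
  // attempts elsewhere are exact no-ops and are counted without work.
  std::vector<int> active;       // linear indices of active sites
  std::vector<int> active_pos;   // site -> position in `active`, -1 if not

  inline int at(int x, int y) const { return lab[x + w * y]; }
  inline void setlab(int x, int y, int v) { lab[x + w * y] = v; }
  inline bool inside(int x, int y) const { return x >= 0 && x < w && y >= 0 && y < h; }
  inline double runif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  inline int rint(int n) { return (int)(gen() % (uint64_t)n); }

  // flat label -> kind lookup for the hot loop
  std::vector<int> kind_by_label;
  void rebuild_kinds() {
    int maxid = L_CELL0;
    for (auto& c : cells) if (c.id > maxid) maxid = c.id;
    kind_by_label.assign(maxid + 1, -1);
    kind_by_label[L_EXT] = K_EXT; kind_by_label[L_CAV] = K_CAV;
    kind_by_label[L_SEP] = K_SEP; kind_by_label[L_ANC] = K_ANC;
    for (auto& c : cells) if (c.alive) kind_by_label[c.id] = c.kind;
  }

  inline int kind_of(int label) const {
    int k = kind_by_label[label];
    if (k < 0) stop("unknown cell label %d", label);
    return k;
  }

  CellRec* cellp(int label) {
    if (label < L_CELL0) return nullptr;
    int ix = idmap[label];
    if (ix < 0) stop("label %d missing from registry", label);
    return &cells[ix];
  }

  void endpoint_pos(int id, double& x, double& y) {
    if (id == -1) { x = anc_l_cx; y = anc_l_cy; return; }
    if (id == -2) { x = anc_r_cx; y = anc_r_cy; return; }
    CellRec* c = cellp(id);
    x = c->sumx / c->vol; y = c->sumy / c->vol;
  }

  bool sep_adjacent(int x, int y) const {
    if (sep_row < 0) return false;
    static const int d4[4][2] = {{1,0},{-1,0},{0,1},{0,-1}};
    for (auto& d : d4) {
      int nx = x + d[0], ny = y + d[1];
      if (inside(nx, ny) && at(nx, ny) == L_SEP) return true;
    }
    return false;
  }

  // Rebuild volumes, centroid sums, separator contacts, anchor centroids
  void census() {
    rebuild_kinds();
    for (auto& c : cells) { c.vol = 0; c.sumx = 0; c.sumy = 0; c.sep_contact = 0; }
    n_immutable = 0;
    double lsx = 0, lsy = 0, rsx = 0, rsy = 0; long ln = 0, rn = 0;
    for (int y = 0; y < h; ++y) for (int x = 0; x < w; ++x) {
      int l = at(x, y);
      if (l == L_SEP) { ++n_immutable; continue; }
      if (l == L_ANC) {
        ++n_immutable;
        if (x < w / 2) { lsx += x; lsy += y; ++ln; } else { rsx += x; rsy += y; ++rn; }
        continue;
      }
      if (l >= L_CELL0) {
        CellRec* c = cellp(l);
        c->vol++; c->sumx += x; c->sumy += y;
        if (sep_adjacent(x, y)) c->sep_contact++;
      }
    }
    if (ln > 0) { anc_l_cx = lsx / ln; anc_l_cy = lsy / ln; }
    if (rn > 0) { anc_r_cx = rsx / rn; anc_r_cy = rsy / rn; }
    for (auto& c : cells)
      if (c.alive && c.vol == 0) stop("registry cell %d has no lattice sites", c.id);
    rebuild_active();
    rebuild_mech_index();
  }

  bool site_is_active(int i) const {
    int l = lab[i];
    if (l == L_SEP || l == L_ANC) return false;
    int x = i % w, y = i / w;
    bool lcell = l >= L_CELL0;
    for (auto& d : NB8) {
      int nx = x + d[0], ny = y + d[1];
      if (!inside(nx, ny)) continue;
      int ln = at(nx, ny);
      if (ln != l && (lcell || ln >= L_CELL0)) return true;
    }
    return false;
  }

  void active_set(int i, bool want) {
    int pos = active_pos[i];
    if (want && pos < 0) {
      active_pos[i] = (int)active.size();
      active.push_back(i);
    } else if (!want && pos >= 0) {
      int last = active.back();
      active[pos] = last;
      active_pos[last] = pos;
      active.pop_back();
      active_pos[i] = -1;
    }
  }

  void rebuild_active() {
    active.clear();
    active_pos.assign((size_t)w * h, -1);
    for (int i = 0; i < w * h; ++i)
      if (site_is_active(i)) active_set(i, true);
  }

  void touch_neighborhood(int x, int y) {
    active_set(x + w * y, site_is_active(x + w * y));
    for (auto& d : NB8) {
      int nx = x + d[0], ny = y + d[1];
      if (inside(nx, ny)) active_set(nx + w * ny, site_is_active(nx + w * ny));
    }
  }

  // ---- energy terms -------------------------------------------------------

  double contact_delta(int x, int y, int lnew) {
    int lold = at(x, y);
    int kn = kind_of(lnew), ko = kind_of(lold);
    const double* Jn = P.J[kn];
    const double* Jo = P.J[ko];
    double dE = 0;
    if (x >= 2 && x < w - 2 && y >= 2 && y < h - 2) {
      // interior fast path: no bounds checks
      const int i0 = x + w * y;
      const int* L = lab.data();
      const int* K = kind_by_label.data();
      static const int noff[20] = {0};   // filled lazily below
      (void)noff;
      const int offs[20] = {
        1, -1, w, -w, 1 + w, 1 - w, -1 + w, -1 - w,
        2, -2, 2 * w, -2 * w,
        1 + 2 * w, 2 + w, 1 - 2 * w, 2 - w, -1 + 2 * w, -2 + w,
        -1 - 2 * w, -2 - w};
      for (int k = 0; k < 20; ++k) {
        int lt = L[i0 + offs[k]];
        if (lt != lnew) dE += Jn[K[lt]];
        if (lt != lold) dE -= Jo[K[lt]];
      }
      return dE;
    }
    for (auto& d : NB20) {
      int nx = x + d[0], ny = y + d[1];
      if (!inside(nx, ny)) continue;
      int lt = at(nx, ny);
      if (lt != lnew) dE += Jn[kind_of(lt)];
      if (lt != lold) dE -= Jo[kind_of(lt)];
    }
    return dE;
  }

  // Frozen (released) cells lose their target-volume constraint and are
  // driven to shrink instead (target 0), so they leave the simulation.
  double volume_delta(int lgain, int llose) {
    double dE = 0;
    CellRec* g = (lgain >= L_CELL0) ? cellp(lgain) : nullptr;
    CellRec* l = (llose >= L_CELL0) ? cellp(llose) : nullptr;
    if (g) {
      double v = g->vol, t = g->frozen ? 0.0 : g->tvol;
      dE += P.lambda_v * ((v + 1 - t) * (v + 1 - t) - (v - t) * (v - t));
    }
    if (l) {
      double v = l->vol, t = l->frozen ? 0.0 : l->tvol;
      dE += P.lambda_v * ((v - 1 - t) * (v - 1 - t) - (v - t) * (v - t));
    }
    return dE;
  }

  // per-cell indices into `links` and (active) `bonds`, rebuilt whenever
  // either table changes; keeps the per-attempt energy work O(per-cell)
  std::vector<std::vector<int>> links_of, abonds_of;
  void rebuild_mech_index() {
    links_of.assign(cells.size(), {});
    abonds_of.assign(cells.size(), {});
    for (size_t i = 0; i < links.size(); ++i) {
      links_of[idmap[links[i].dc]].push_back((int)i);
      links_of[idmap[links[i].sc]].push_back((int)i);
    }
    for (size_t i = 0; i < bonds.size(); ++i) {
      if (!bonds[i].active) continue;
      if (bonds[i].a >= L_CELL0) abonds_of[idmap[bonds[i].a]].push_back((int)i);
      if (bonds[i].b >= L_CELL0) abonds_of[idmap[bonds[i].b]].push_back((int)i);
    }
  }

  // spring + cohesion energy change if site (x,y) moves from llose to lgain
  double mech_delta(int x, int y, int lgain, int llose) {
    bool gmov = lgain >= L_CELL0, lmov = llose >= L_CELL0;
    if (!gmov && !lmov) return 0.0;
    if (links.empty() && bonds.empty()) return 0.0;
    // centroids before/after for the two movers
    double gx0 = 0, gy0 = 0, gx1 = 0, gy1 = 0, lx0 = 0, ly0 = 0, lx1 = 0, ly1 = 0;
    bool l_ok = false;
    CellRec* g = gmov ? cellp(lgain) : nullptr;
    CellRec* l = lmov ? cellp(llose) : nullptr;
    if (g) {
      gx0 = g->sumx / g->vol; gy0 = g->sumy / g->vol;
      gx1 = (g->sumx + x) / (g->vol + 1.0); gy1 = (g->sumy + y) / (g->vol + 1.0);
    }
    if (l && l->vol > 1) {
      l_ok = true;
      lx0 = l->sumx / l->vol; ly0 = l->sumy / l->vol;
      lx1 = (l->sumx - x) / (l->vol - 1.0); ly1 = (l->sumy - y) / (l->vol - 1.0);
    }
    auto pos_after = [&](int id, double& px, double& py) {
      if (g && id == lgain) { px = gx1; py = gy1; }
      else if (l_ok && id == llose) { px = lx1; py = ly1; }
      else endpoint_pos(id, px, py);
    };
    auto pos_before = [&](int id, double& px, double& py) {
      if (g && id == lgain) { px = gx0; py = gy0; }
      else if (l_ok && id == llose) { px = lx0; py = ly0; }
      else endpoint_pos(id, px, py);
    };
    double dE = 0;
    int gi = g ? idmap[lgain] : -1;
    int li = (l_ok) ? idmap[llose] : -1;
    auto link_term = [&](int i) {
      const Link& lk = links[i];
      double ax, ay, bx, by;
      pos_before(lk.dc, ax, ay); pos_before(lk.sc, bx, by);
      double d0 = std::hypot(ax - bx, ay - by) - lk.rest;
      pos_after(lk.dc, ax, ay); pos_after(lk.sc, bx, by);
      double d1 = std::hypot(ax - bx, ay - by) - lk.rest;
      dE += P.k_spring * (d1 * d1 - d0 * d0);
    };
    auto bond_term = [&](int i) {
      const Bond& bd = bonds[i];
      double ax, ay, bx, by;
      pos_before(bd.a, ax, ay); pos_before(bd.b, bx, by);
      double s0 = std::max(0.0, std::hypot(ax - bx, ay - by) - bd.d0);
      pos_after(bd.a, ax, ay); pos_after(bd.b, bx, by);
      double s1 = std::max(0.0, std::hypot(ax - bx, ay - by) - bd.d0);
      dE += P.k_coh * (s1 * s1 - s0 * s0);
    };
    auto in_list = [](const std::vector<int>& v, int i) {
      for (int x : v) if (x == i) return true;
      return false;
    };
    if (gi >= 0) {
      for (int i : links_of[gi]) link_term(i);
      for (int i : abonds_of[gi]) bond_term(i);
    }
    if (li >= 0) {
      for (int i : links_of[li])
        if (gi < 0 || !in_list(links_of[gi], i)) link_term(i);
      for (int i : abonds_of[li])
        if (gi < 0 || !in_list(abonds_of[gi], i)) bond_term(i);
    }
    return dE;
  }

  // Chemotaxis bias on deep-cell membrane moves: the copy attempt gets
  // -lambda * (c_target - c_source) when either the extending (gaining) or
  // the retracting (losing) cell is a live deep cell. Up-gradient
  // extensions and retractions of the down-gradient rear are both favored;
  // at the cavity edge this suppresses extensions into the cavity and
  // lets the cavity reclaim the rear - the ratchet that directs cells
  // toward the chemoattractant source.
  // Chemotaxis bias on membrane extensions: applied when the extending
  // (gaining) cell is a live deep cell; up-gradient extensions are favored,
  // extensions against the gradient suppressed.
  double chemo_delta(int x, int y, int sx, int sy, int lgain, int llose) {
    (void)llose;
    if (P.lambda_chem == 0.0 || lgain < L_CELL0) return 0.0;
    CellRec* g = cellp(lgain);
    if (g->kind != K_DC || g->frozen) return 0.0;
    return -P.lambda_chem * (conc[x + w * y] - conc[sx + w * sy]);
  }

  // local simple-point test: does removing (x,y) keep its label's sites
  // 8-connected within the 3x3 neighborhood?
  bool connectivity_ok(int x, int y) {
    int l0 = at(x, y);
    int fg[8]; int nfg = 0, idx[8];
    for (int i = 0; i < 8; ++i) {
      int nx = x + NB8[i][0], ny = y + NB8[i][1];
      fg[i] = (inside(nx, ny) && at(nx, ny) == l0) ? 1 : 0;
      if (fg[i]) idx[nfg++] = i;
    }
    if (nfg == 0) return true;       // lone site; vanish guard decides
    // BFS over foreground ring cells, adjacency = Chebyshev distance <= 1
    bool seen[8] = {false};
    int stack[8], sp = 0;
    stack[sp++] = idx[0]; seen[idx[0]] = true;
    int cnt = 1;
    while (sp > 0) {
      int i = stack[--sp];
      for (int k = 0; k < nfg; ++k) {
        int j = idx[k];
        if (seen[j]) continue;
        int dx = std::abs(NB8[i][0] - NB8[j][0]);
        int dy = std::abs(NB8[i][1] - NB8[j][1]);
        if (dx <= 1 && dy <= 1) { seen[j] = true; stack[sp++] = j; ++cnt; }
      }
    }
    return cnt == nfg;
  }

  // When the 3x3 test fails, check whether the site's same-label neighbors
  // reconnect without it through cell sites inside a 7x7 window. Rough,
  // interdigitated interfaces fail the local test constantly while the cell
  // body reconnects a site or two away; without this rescue those
  // configurations are absorbing and the dynamics ratchets into them.
  bool connectivity_ok_window(int x, int y) {
    if (connectivity_ok(x, y)) return true;
    const int l0 = at(x, y), R = 3;
    // seed BFS from one same-label 8-neighbor, must reach all others
    int seeds[8]; int ns = 0;
    for (auto& d : NB8) {
      int nx = x + d[0], ny = y + d[1];
      if (inside(nx, ny) && at(nx, ny) == l0) seeds[ns++] = nx + w * ny;
    }
    if (ns <= 1) return true;
    bool seen[49] = {false};
    auto widx = [&](int i) {
      int dx = i % w - x, dy = i / w - y;
      return (dx + R) + 7 * (dy + R);
    };
    std::vector<int> stack;
    stack.push_back(seeds[0]);
    seen[widx(seeds[0])] = true;
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      int cx = i % w, cy = i / w;
      for (auto& d : NB8) {
        int nx = cx + d[0], ny = cy + d[1];
        if (!inside(nx, ny)) continue;
        if (std::abs(nx - x) > R || std::abs(ny - y) > R) continue;
        if (nx == x && ny == y) continue;
        if (at(nx, ny) != l0) continue;
        int j = nx + w * ny;
        if (!seen[widx(j)]) { seen[widx(j)] = true; stack.push_back(j); }
      }
    }
    for (int k = 1; k < ns; ++k)
      if (!seen[widx(seeds[k])]) return false;
    return true;
  }

  // ---- single copy attempt ------------------------------------------------

  void attempt() {
    ++attempts;
    // uniform over all w*h sites; attempts at inactive sites are no-ops
    int r = rint(w * h);
    if (r >= (int)active.size()) return;
    int i = active[r];
    int x = i % w, y = i / w;
    int ls = lab[i];
    int di = rint(8);
    int sx = x + NB8[di][0], sy = y + NB8[di][1];
    if (!inside(sx, sy)) return;
    int ln = at(sx, sy);
    if (ln == ls) return;
    if (ln == L_SEP || ln == L_ANC) return;       // immutable labels never spread
    // cell-free regions only rearrange where cells move; cavity <-> external
    // exchange is not a physical move
    if (ls < L_CELL0 && ln < L_CELL0) return;

    CellRec* losing = (ls >= L_CELL0) ? cellp(ls) : nullptr;
    CellRec* gaining = (ln >= L_CELL0) ? cellp(ln) : nullptr;

    if (losing) {
      if (losing->vol <= 1 && !losing->frozen) return;   // cell-vanishing guard
      // released (frozen) cells are shrinking out of the simulation and may
      // fragment; everything else stays a connected domain
      if (!losing->frozen && losing->vol > 1) {
        ++guard_checked;
        if (!connectivity_ok_window(x, y)) { ++guard_rejected; return; }
      }
      // SC minimal basal contact
      if (losing->kind == K_SC && !losing->frozen && sep_row >= 0 &&
          sep_adjacent(x, y) && losing->sep_contact - 1 < P.sc_min_contact)
        return;
    }
    // DCs never invade the SL compartment above the separator
    if (gaining && gaining->kind == K_DC && sep_row >= 0 && y > sep_row) return;

    double dH = contact_delta(x, y, ln) + volume_delta(ln, ls) +
                chemo_delta(x, y, sx, sy, ln, ls) + mech_delta(x, y, ln, ls);
    if (dH > 0 && runif() >= std::exp(-dH / P.temperature)) return;

    // accept
    setlab(x, y, ln);
    ++accepted;
    touch_neighborhood(x, y);
    bool sepadj = sep_adjacent(x, y);
    if (losing) {
      losing->vol--; losing->sumx -= x; losing->sumy -= y;
      if (sepadj) losing->sep_contact--;
      if (losing->vol == 0) kill_cell(ls);
    }
    if (gaining) {
      gaining->vol++; gaining->sumx += x; gaining->sumy += y;
      if (sepadj) gaining->sep_contact++;
    }
  }

  void kill_cell(int id) {
    CellRec* c = cellp(id);
    c->alive = false;
    removed_ids.push_back(id);
    bonds.erase(std::remove_if(bonds.begin(), bonds.end(),
      [&](const Bond& b) { return b.a == id || b.b == id; }), bonds.end());
    links.erase(std::remove_if(links.begin(), links.end(),
      [&](const Link& l) { return l.dc == id || l.sc == id; }), links.end());
    idmap[id] = -1;
    rebuild_mech_index();
  }

  // ---- chemoattractant field ---------------------------------------------

  // Per-label secretion rates (0 = not a producer), rebuilt before
  // stepping. Producers secrete at rate k_decay * c0 * multiplier, so the
  // steady concentration level inside a wide producing region is
  // c0 * multiplier; a boundary-layer gradient of width sqrt(D/k) forms
  // where producing tissue meets cell-free space.
  std::vector<double> rate_by_label;
  void rebuild_rates() {
    int maxid = L_CELL0;
    for (auto& c : cells) if (c.alive && c.id > maxid) maxid = c.id;
    rate_by_label.assign(maxid + 1, 0.0);
    for (auto& c : cells)
      if (c.alive && c.c0 > 0)
        rate_by_label[c.id] = P.k_decay * c.c0 * P.level_multiplier;
  }

  void chemo_substep() {
    const double a = P.D * P.dt_chem, keep = 1.0 - 4.0 * a - P.k_decay * P.dt_chem;
    const double dt = P.dt_chem;
    const int nlab = (int)rate_by_label.size();
    const double* c = conc.data();
    double* o = conc2.data();
    const int* L = lab.data();
    for (int y = 0; y < h; ++y) {
      const int row = w * y;
      const bool ytop = (y == h - 1), ybot = (y == 0);
      for (int x = 0; x < w; ++x) {
        const int i = x + row;
        const int l = L[i];
        const double ci = c[i];
        const double cl = (x > 0) ? c[i - 1] : ci;
        const double cr = (x < w - 1) ? c[i + 1] : ci;
        const double cd = ybot ? ci : c[i - w];
        const double cu = ytop ? ci : c[i + w];
        double v = keep * ci + a * (cl + cr + cd + cu);
        if (l < nlab && rate_by_label[l] > 0) v += rate_by_label[l] * dt;
        o[i] = (v > 0) ? v : 0;
      }
    }
    conc.swap(conc2);
    // fixed sources (purified-attractant disc) are reservoirs: Dirichlet
    for (size_t i = 0; i < P.clamp_sites.size(); ++i)
      conc[P.clamp_sites[i]] = P.clamp_value * P.level_multiplier;
  }

  void step_chemo(double minutes) {
    int n = (int)std::lround(minutes / P.dt_chem);
    if (n <= 0) return;
    rebuild_rates();
    for (size_t i = 0; i < P.clamp_sites.size(); ++i)
      conc[P.clamp_sites[i]] = P.clamp_value * P.level_multiplier;
    for (int i = 0; i < n; ++i) chemo_substep();
  }

  // ---- per-sweep housekeeping --------------------------------------------

  // contact area (adjacent 4-neighbor site pairs) between SC/anchor labels,
  // restricted to rows near and above the separator
  void update_bond_state() {
    if (bonds.empty()) return;
    std::vector<long> area(bonds.size(), 0);
    auto bond_index = [&](int ida, int idb) -> int {
      for (size_t i = 0; i < bonds.size(); ++i)
        if ((bonds[i].a == ida && bonds[i].b == idb) ||
            (bonds[i].a == idb && bonds[i].b == ida)) return (int)i;
      return -1;
    };
    int ylo = (sep_row >= 0) ? std::max(0, sep_row - 2) : 0;
    auto bond_id_of_site = [&](int x, int y) -> int {
      int l = at(x, y);
      if (l == L_ANC) return (x < w / 2) ? -1 : -2;
      if (l >= L_CELL0 && cellp(l)->kind == K_SC) return l;
      return 0;   // not a bond endpoint
    };
    for (int y = ylo; y < h; ++y) for (int x = 0; x < w; ++x) {
      int a = bond_id_of_site(x, y);
      if (a == 0) continue;
      if (x + 1 < w) {
        int b = bond_id_of_site(x + 1, y);
        if (b != 0 && b != a) { int bi = bond_index(a, b); if (bi >= 0) area[bi]++; }
      }
      if (y + 1 < h) {
        int b = bond_id_of_site(x, y + 1);
        if (b != 0 && b != a) { int bi = bond_index(a, b); if (bi >= 0) area[bi]++; }
      }
    }
    for (size_t i = 0; i < bonds.size(); ++i) {
      if (area[i] < P.contact_threshold) {
        if (!bonds[i].active) {
          double ax, ay, bx, by;
          endpoint_pos(bonds[i].a, ax, ay); endpoint_pos(bonds[i].b, bx, by);
          bonds[i].active = true;
          bonds[i].d0 = std::hypot(ax - bx, ay - by);
        }
      } else bonds[i].active = false;
    }
    // SCs establish a neighbor connection with an anchor upon contact
    if (anc_lx >= 0) {
      std::vector<long> anc_contact_l(idmap.size(), 0), anc_contact_r(idmap.size(), 0);
      for (int y = ylo; y < h; ++y) for (int x = 0; x < w; ++x) {
        if (at(x, y) != L_ANC) continue;
        int aid = (x < w / 2) ? -1 : -2;
        static const int d4[4][2] = {{1,0},{-1,0},{0,1},{0,-1}};
        for (auto& d : d4) {
          int nx = x + d[0], ny = y + d[1];
          if (!inside(nx, ny)) continue;
          int l = at(nx, ny);
          if (l >= L_CELL0 && cellp(l)->kind == K_SC && !cellp(l)->frozen) {
            if (aid == -1) anc_contact_l[l]++; else anc_contact_r[l]++;
          }
        }
      }
      for (auto& c : cells) {
        if (!c.alive || c.kind != K_SC || c.frozen) continue;
        if (anc_contact_l[c.id] > 0 && bond_index(c.id, -1) < 0)
          bonds.push_back({c.id, -1, false, 0.0});
        if (anc_contact_r[c.id] > 0 && bond_index(c.id, -2) < 0)
          bonds.push_back({c.id, -2, false, 0.0});
      }
    }
  }

  void update_links() {
    // removals
    links.erase(std::remove_if(links.begin(), links.end(), [&](const Link& lk) {
      CellRec* d = cellp(lk.dc); CellRec* s = cellp(lk.sc);
      if (!d->alive || !s->alive || d->frozen || s->frozen) return true;
      if (d->sep_contact == 0) return true;
      double ax, ay, bx, by;
      endpoint_pos(lk.dc, ax, ay); endpoint_pos(lk.sc, bx, by);
      if (std::hypot(ax - bx, ay - by) >= 2.0 * lk.rest) return true;
      return runif() < P.p_break;
    }), links.end());
    for (auto& lk : links) lk.age++;
    // formation: unlinked DC touching the separator links to the SC above
    if (sep_row < 0) return;
    for (auto& c : cells) {
      if (!c.alive || c.frozen || c.kind != K_DC || c.sep_contact == 0) continue;
      bool linked = false;
      for (auto& lk : links) if (lk.dc == c.id) { linked = true; break; }
      if (linked) continue;
      if (runif() >= P.p_form) continue;
      double cx = c.sumx / c.vol, cy = c.sumy / c.vol;
      int col = std::min(w - 1, std::max(0, (int)std::lround(cx)));
      int scid = 0;
      if (sep_row + 1 < h) {
        int l = at(col, sep_row + 1);
        if (l >= L_CELL0 && cellp(l)->kind == K_SC && !cellp(l)->frozen) scid = l;
      }
      if (scid == 0) {
        double best = 1e18;
        for (auto& s : cells) {
          if (!s.alive || s.frozen || s.kind != K_SC) continue;
          double d = std::fabs(s.sumx / s.vol - cx);
          if (d < best - 1e-12 || (std::fabs(d - best) <= 1e-12 && (scid == 0 || s.id < scid))) {
            best = d; scid = s.id;
          }
        }
      }
      if (scid == 0) continue;     // no SC available, logged upstream
      double ax, ay;
      endpoint_pos(scid, ax, ay);
      double rest = std::hypot(ax - cx, ay - cy);
      links.push_back({c.id, scid, rest, 0});
    }
  }

  bool bonded_to_anchor(int id) {
    for (auto& b : bonds)
      if ((b.a == id && b.b < 0) || (b.b == id && b.a < 0)) return true;
    return false;
  }

  void freeze_cell(CellRec& c) {
    c.frozen = true;
    frozen_ids.push_back(c.id);
    bonds.erase(std::remove_if(bonds.begin(), bonds.end(),
      [&](const Bond& b) { return b.a == c.id || b.b == c.id; }), bonds.end());
    links.erase(std::remove_if(links.begin(), links.end(),
      [&](const Link& l) { return l.dc == c.id || l.sc == c.id; }), links.end());
  }

  void boundary_release() {
    if (anc_lx < 0) return;
    for (auto& c : cells) {
      if (!c.alive || c.frozen) continue;
      double cx = c.sumx / c.vol;
      bool outside = (cx < anc_lx || cx > anc_rx);
      if (!outside) continue;
      if (c.kind == K_SC) {
        if (!bonded_to_anchor(c.id)) { freeze_cell(c); continue; }
        bool all_anchored = true, any = false;
        for (auto& b : bonds) {
          int other = (b.a == c.id) ? b.b : (b.b == c.id ? b.a : 0);
          if (other == 0 || other < 0) continue;
          any = true;
          if (!bonded_to_anchor(other)) { all_anchored = false; break; }
        }
        if (any && all_anchored) freeze_cell(c);
      } else {
        bool linked = false;
        for (auto& lk : links) if (lk.dc == c.id) { linked = true; break; }
        if (!linked) freeze_cell(c);
      }
    }
  }

  int next_id() {
    int m = L_CELL0;
    for (auto& c : cells) if (c.id >= m) m = c.id + 1;
    return m;
  }

  void replenish_side(int ax) {
    if (ax < 0 || sep_row < 0) return;
    int x0 = std::max(0, ax - P.replenish_w / 2);
    int x1 = std::min(w - 1, ax + P.replenish_w / 2 - 1);
    int y1 = sep_row - 2, y0 = std::max(0, y1 - P.replenish_w + 1);
    for (int y = y0; y <= y1; ++y) for (int x = x0; x <= x1; ++x) {
      int l = at(x, y);
      if (l >= L_CELL0 && cellp(l)->kind == K_DC) return;   // DC present
    }
    // seed a new DC on free (cavity / external) sites in an 8x8 patch
    int px0 = std::max(0, ax - 4), py0 = std::max(0, sep_row - 10);
    std::vector<int> taken;
    for (int y = py0; y < std::min(h, py0 + 8); ++y)
      for (int x = px0; x < std::min(w, px0 + 8); ++x) {
        int l = at(x, y);
        if (l == L_CAV || l == L_EXT) taken.push_back(x + w * y);
      }
    if ((int)taken.size() < 32) { ++replenish_skipped; return; }
    int id = next_id();
    if ((int)idmap.size() <= id) idmap.resize(id + 1, -1);
    if ((int)kind_by_label.size() <= id) kind_by_label.resize(id + 1, -1);
    kind_by_label[id] = K_DC;
    CellRec c; c.id = id; c.kind = K_DC; c.tvol = 64; c.frozen = false;
    c.alive = true; c.c0 = P.dc_c0; c.vol = 0; c.sumx = 0; c.sumy = 0; c.sep_contact = 0;
    for (int i : taken) {
      lab[i] = id;
      int x = i % w, y = i / w;
      c.vol++; c.sumx += x; c.sumy += y;
      if (sep_adjacent(x, y)) c.sep_contact++;
    }
    idmap[id] = (int)cells.size();
    cells.push_back(c);
    inserted_ids.push_back(id);
  }

  // ---- driver -------------------------------------------------------------

  void housekeeping() {
    step_chemo(P.tick_min);
    update_bond_state();
    update_links();
    if (P.boundary) {
      boundary_release();
      if (P.replenish) {
        size_t before = inserted_ids.size();
        replenish_side(anc_lx); replenish_side(anc_rx);
        if (inserted_ids.size() != before)
          rebuild_active();   // replenishment painted new sites
      }
    }
    rebuild_mech_index();
  }

  void sweep() {
    long N = (long)w * h - n_immutable;
    for (long i = 0; i < N; ++i) attempt();
    time_min += P.mcs_min;
  }
};

static void parse_params(List params, Params& P) {
  NumericMatrix J = params["J"];
  for (int i = 0; i < 6; ++i) for (int j = 0; j < 6; ++j) P.J[i][j] = J(i, j);
  P.lambda_v = as<double>(params["lambda_v"]);
  P.temperature = as<double>(params["temperature"]);
  P.lambda_chem = as<double>(params["lambda_chem"]);
  P.D = as<double>(params["D"]);
  P.k_decay = as<double>(params["k_decay"]);
  P.dt_chem = as<double>(params["dt_chem"]);
  P.level_multiplier = as<double>(params["level_multiplier"]);
  P.p_form = as<double>(params["p_form"]);
  P.p_break = as<double>(params["p_break"]);
  P.k_spring = as<double>(params["k_spring"]);
  P.k_coh = as<double>(params["k_coh"]);
  P.contact_threshold = as<int>(params["contact_threshold"]);
  P.sc_min_contact = as<int>(params["sc_min_contact"]);
  P.boundary = as<bool>(params["boundary"]);
  P.replenish = as<bool>(params["replenish"]);
  P.replenish_w = as<int>(params["replenish_w"]);
  P.dc_c0 = as<double>(params["dc_c0"]);
  P.mcs_min = as<double>(params["mcs_min"]);
  P.tick_min = as<double>(params["tick_min"]);
  P.record_every_min = as<int>(params["record_every_min"]);
  if (params.containsElementNamed("clamp_sites")) {
    IntegerVector cs = params["clamp_sites"];
    P.clamp_sites.assign(cs.begin(), cs.end());
    P.clamp_value = as<double>(params["clamp_value"]);
  } else P.clamp_value = 0;
}

static void build_engine(Engine& E, IntegerMatrix labels, NumericMatrix conc,
                         List cells, List bonds, List links,
                         List params, List geom) {
  E.w = labels.nrow(); E.h = labels.ncol();
  E.lab.assign(labels.begin(), labels.end());
  E.conc.assign(conc.begin(), conc.end());
  E.conc2.resize(E.conc.size());
  parse_params(params, E.P);
  E.spacing = as<double>(geom["spacing"]);
  E.sep_row = as<int>(geom["sep_row"]) - 1;        // 1-based from R, -1 => absent => -2
  if (as<int>(geom["sep_row"]) < 0) E.sep_row = -1;
  E.anc_lx = as<int>(geom["anchor_lx"]) - 1;
  E.anc_rx = as<int>(geom["anchor_rx"]) - 1;
  if (as<int>(geom["anchor_lx"]) < 0) { E.anc_lx = -1; E.anc_rx = -1; }

  IntegerVector id = cells["id"], kind = cells["kind"];
  NumericVector tvol = cells["target_volume"], c0 = cells["c0"];
  LogicalVector frozen = cells["frozen"];
  int maxid = L_CELL0;
  for (int i = 0; i < id.size(); ++i) maxid = std::max(maxid, id[i]);
  E.idmap.assign(maxid + 1, -1);
  for (int i = 0; i < id.size(); ++i) {
    CellRec c;
    c.id = id[i]; c.kind = kind[i]; c.tvol = tvol[i];
    c.frozen = frozen[i]; c.alive = true; c.c0 = c0[i];
    c.vol = 0; c.sumx = 0; c.sumy = 0; c.sep_contact = 0;
    E.idmap[c.id] = (int)E.cells.size();
    E.cells.push_back(c);
  }
  IntegerVector ba = bonds["a"], bb = bonds["b"];
  LogicalVector bact = bonds["active"];
  NumericVector bd0 = bonds["d0"];
  for (int i = 0; i < ba.size(); ++i)
    E.bonds.push_back({ba[i], bb[i], (bool)bact[i], bd0[i]});
  IntegerVector ld = links["dc"], ls = links["sc"], lage = links["age"];
  NumericVector lrest = links["rest"];
  for (int i = 0; i < ld.size(); ++i)
    E.links.push_back({ld[i], ls[i], lrest[i], lage[i]});
  E.census();
}

static List export_state(Engine& E) {
  IntegerMatrix labels(E.w, E.h);
  std::copy(E.lab.begin(), E.lab.end(), labels.begin());
  NumericMatrix conc(E.w, E.h);
  std::copy(E.conc.begin(), E.conc.end(), conc.begin());
  int n = 0;
  for (auto& c : E.cells) if (c.alive) ++n;
  IntegerVector id(n), kind(n), vol(n), sepc(n);
  NumericVector tvol(n), c0(n), cx(n), cy(n);
  LogicalVector frozen(n);
  int i = 0;
  for (auto& c : E.cells) {
    if (!c.alive) continue;
    id[i] = c.id; kind[i] = c.kind; vol[i] = (int)c.vol; tvol[i] = c.tvol;
    c0[i] = c.c0; frozen[i] = c.frozen; sepc[i] = c.sep_contact;
    cx[i] = c.sumx / c.vol + 1;  // back to 1-based site coords
    cy[i] = c.sumy / c.vol + 1;
    ++i;
  }
  int nb = (int)E.bonds.size();
  IntegerVector ba(nb), bb(nb); LogicalVector bact(nb); NumericVector bd0(nb);
  for (int k = 0; k < nb; ++k) {
    ba[k] = E.bonds[k].a; bb[k] = E.bonds[k].b;
    bact[k] = E.bonds[k].active; bd0[k] = E.bonds[k].d0;
  }
  int nl = (int)E.links.size();
  IntegerVector ld(nl), lsc(nl), lage(nl); NumericVector lrest(nl), llen(nl);
  for (int k = 0; k < nl; ++k) {
    ld[k] = E.links[k].dc; lsc[k] = E.links[k].sc;
    lrest[k] = E.links[k].rest; lage[k] = E.links[k].age;
    double ax, ay, bx, by;
    E.endpoint_pos(E.links[k].dc, ax, ay); E.endpoint_pos(E.links[k].sc, bx, by);
    llen[k] = std::hypot(ax - bx, ay - by);
  }
  return List::create(
    _["labels"] = labels, _["conc"] = conc,
    _["cells"] = List::create(_["id"] = id, _["kind"] = kind, _["volume"] = vol,
                              _["target_volume"] = tvol, _["frozen"] = frozen,
                              _["c0"] = c0, _["sep_contact"] = sepc,
                              _["cx"] = cx, _["cy"] = cy),
    _["bonds"] = List::create(_["a"] = ba, _["b"] = bb, _["active"] = bact, _["d0"] = bd0),
    _["links"] = List::create(_["dc"] = ld, _["sc"] = lsc, _["rest"] = lrest,
                              _["age"] = lage, _["length"] = llen));
}

// [[Rcpp::export]]
List cpm_advance_cpp(IntegerMatrix labels, NumericMatrix conc,
                     List cells, List bonds, List links,
                     List params, List geom,
                     int n_sweeps, double seed, double time0) {
  Engine E;
  build_engine(E, labels, conc, cells, bonds, links, params, geom);
  E.gen.seed((uint64_t)seed);
  E.time_min = time0;

  std::vector<double> trk;   // minute, id, kind, x, y, volume
  int per_tick = std::max(1, (int)std::lround(E.P.tick_min / E.P.mcs_min));
  long prev_minute = (long)std::floor(time0 + 1e-9);
  for (int s = 0; s < n_sweeps; ++s) {
    E.sweep();
    if ((s + 1) % per_tick == 0) E.housekeeping();
    long minute = (long)std::floor(E.time_min + 1e-9);
    if (minute > prev_minute && minute % E.P.record_every_min == 0) {
      for (auto& c : E.cells) {
        if (!c.alive) continue;
        trk.push_back((double)minute);
        trk.push_back(c.id); trk.push_back(c.kind);
        trk.push_back(c.sumx / c.vol + 1); trk.push_back(c.sumy / c.vol + 1);
        trk.push_back((double)c.vol);
      }
    }
    if (minute > prev_minute) prev_minute = minute;
  }
  int nr = (int)trk.size() / 6;
  NumericMatrix tracks(nr, 6);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < 6; ++j) tracks(i, j) = trk[i * 6 + j];

  List st = export_state(E);
  st["tracks"] = tracks;
  st["time_min"] = E.time_min;
  st["accepted"] = (double)E.accepted;
  st["attempts"] = (double)E.attempts;
  st["inserted"] = wrap(E.inserted_ids);
  st["frozen_events"] = wrap(E.frozen_ids);
  st["removed"] = wrap(E.removed_ids);
  st["replenish_skipped"] = E.replenish_skipped;
  st["guard_checked"] = (double)E.guard_checked;
  st["guard_rejected"] = (double)E.guard_rejected;
  return st;
}

// [[Rcpp::export]]
List cpm_hamiltonian_cpp(IntegerMatrix labels, List cells, List bonds, List links,
                         List params, List geom) {
  Engine E;
  NumericMatrix conc(labels.nrow(), labels.ncol());
  build_engine(E, labels, conc, cells, bonds, links, params, geom);
  double Hc = 0;
  for (int y = 0; y < E.h; ++y) for (int x = 0; x < E.w; ++x) {
    int la = E.at(x, y);
    for (auto& d : NB10) {
      int nx = x + d[0], ny = y + d[1];
      if (!E.inside(nx, ny)) continue;
      int lb = E.at(nx, ny);
      if (lb != la) Hc += E.P.J[E.kind_of(la)][E.kind_of(lb)];
    }
  }
  double Hv = 0;
  for (auto& c : E.cells) {
    if (!c.alive) continue;
    double d = c.vol - (c.frozen ? 0.0 : c.tvol);
    Hv += E.P.lambda_v * d * d;
  }
  double Hl = 0;
  for (auto& lk : E.links) {
    double ax, ay, bx, by;
    E.endpoint_pos(lk.dc, ax, ay); E.endpoint_pos(lk.sc, bx, by);
    double d = std::hypot(ax - bx, ay - by) - lk.rest;
    Hl += E.P.k_spring * d * d;
  }
  double Hb = 0;
  for (auto& bd : E.bonds) {
    if (!bd.active) continue;
    double ax, ay, bx, by;
    E.endpoint_pos(bd.a, ax, ay); E.endpoint_pos(bd.b, bx, by);
    double s = std::max(0.0, std::hypot(ax - bx, ay - by) - bd.d0);
    Hb += E.P.k_coh * s * s;
  }
  return List::create(_["contact"] = Hc, _["volume"] = Hv,
                      _["link"] = Hl, _["cohesion"] = Hb,
                      _["total"] = Hc + Hv + Hl + Hb);
}

// [[Rcpp::export]]
List cpm_delta_cpp(IntegerMatrix labels, NumericMatrix conc,
                   List cells, List bonds, List links,
                   List params, List geom,
                   int x, int y, int new_label, int sx, int sy) {
  Engine E;
  build_engine(E, labels, conc, cells, bonds, links, params, geom);
  --x; --y; --sx; --sy;
  if (!E.inside(x, y)) stop("site outside grid");
  int ls = E.at(x, y);
  double dc = E.contact_delta(x, y, new_label);
  double dv = E.volume_delta(new_label, ls);
  double dch = (E.inside(sx, sy)) ? E.chemo_delta(x, y, sx, sy, new_label, E.at(x, y)) : 0.0;
  double dm = E.mech_delta(x, y, new_label, ls);
  return List::create(_["contact"] = dc, _["volume"] = dv, _["chemo"] = dch,
                      _["mech"] = dm, _["total"] = dc + dv + dch + dm);
}

// Repeatedly apply the Metropolis acceptance rule to one fixed proposal;
// used to verify the acceptance frequency against exp(-dH/T).
// [[Rcpp::export]]
int cpm_accept_probe_cpp(IntegerMatrix labels, NumericMatrix conc,
                         List cells, List bonds, List links,
                         List params, List geom,
                         int x, int y, int new_label, int sx, int sy,
                         int n_trials, double seed) {
  Engine E;
  build_engine(E, labels, conc, cells, bonds, links, params, geom);
  E.gen.seed((uint64_t)seed);
  --x; --y; --sx; --sy;
  int ls = E.at(x, y);
  double dH = E.contact_delta(x, y, new_label) + E.volume_delta(new_label, ls) +
              (E.inside(sx, sy) ? E.chemo_delta(x, y, sx, sy, new_label, ls) : 0.0) +
              E.mech_delta(x, y, new_label, ls);
  int acc = 0;
  double p = (dH <= 0) ? 1.0 : std::exp(-dH / E.P.temperature);
  for (int i = 0; i < n_trials; ++i)
    if (dH <= 0 || E.runif() < p) ++acc;
  return acc;
}

// [[Rcpp::export]]
bool connectivity_guard_cpp(IntegerMatrix labels, int x, int y) {
  Engine E;
  E.w = labels.nrow(); E.h = labels.ncol();
  E.lab.assign(labels.begin(), labels.end());
  return E.connectivity_ok(x - 1, y - 1);
}

// [[Rcpp::export]]
NumericMatrix chemo_step_cpp(NumericMatrix conc, IntegerMatrix labels,
                             IntegerVector ids, NumericVector c0,
                             double D, double k_decay, double dt, int n_steps,
                             double level_multiplier,
                             IntegerVector clamp_sites, double clamp_value) {
  int w = conc.nrow(), h = conc.ncol();
  std::vector<double> c(conc.begin(), conc.end()), c2(c.size());
  int maxid = 10;
  for (int i = 0; i < ids.size(); ++i) maxid = std::max(maxid, ids[i]);
  std::vector<double> rate(maxid + 1, 0.0);
  for (int i = 0; i < ids.size(); ++i)
    rate[ids[i]] = k_decay * c0[i] * level_multiplier;
  auto apply_dirichlet = [&]() {
    for (int i = 0; i < clamp_sites.size(); ++i)
      c[clamp_sites[i]] = clamp_value * level_multiplier;
  };
  apply_dirichlet();
  for (int s = 0; s < n_steps; ++s) {
    double a = D * dt, dec = k_decay * dt;
    for (int y = 0; y < h; ++y) for (int x = 0; x < w; ++x) {
      int i = x + w * y;
      double v = c[i];
      double cl = (x > 0) ? c[i - 1] : v;
      double cr = (x < w - 1) ? c[i + 1] : v;
      double cd = (y > 0) ? c[i - w] : v;
      double cu = (y < h - 1) ? c[i + w] : v;
      int l = labels[i];
      double nv = v + a * (cl + cr + cd + cu - 4 * v) - dec * v;
      if (l >= 10 && l <= maxid && rate[l] > 0) nv += rate[l] * dt;
      c2[i] = (nv > 0) ? nv : 0;
    }
    c.swap(c2);
    apply_dirichlet();
  }
  NumericMatrix out(w, h);
  std::copy(c.begin(), c.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
int contact_area_cpp(IntegerMatrix labels, int label_a, int label_b) {
  int w = labels.nrow(), h = labels.ncol();
  int n = 0;
  for (int y = 0; y < h; ++y) for (int x = 0; x < w; ++x) {
    int l = labels(x, y);
    if (l != label_a && l != label_b) continue;
    if (x + 1 < w) {
      int m = labels(x + 1, y);
      if ((l == label_a && m == label_b) || (l == label_b && m == label_a)) ++n;
    }
    if (y + 1 < h) {
      int m = labels(x, y + 1);
      if ((l == label_a && m == label_b) || (l == label_b && m == label_a)) ++n;
    }
  }
  return n;
}
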