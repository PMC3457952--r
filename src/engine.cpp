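// Daily-step individual-based vole model on a 1 m raster.
//
// The engine advances the whole world one day at a time: vegetation first,
// then every vole in freshly shuffled order (mortality, aging, territory
// assessment/eviction, mating and reproduction, male restlessness,
// dispersal), then predators, then output recording.  All stochastic draws
// come from two self-contained splitmix64 streams (voles+vegetation vs
// predators) so that toggling the predator layer does not perturb the vole
// draw sequence.  Same seed + same configuration => bit-identical runs.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

// ---------------------------------------------------------------- RNG ----
// splitmix64: tiny, portable, fully deterministic across platforms.
struct Rng {
  uint64_t s;
  bool have_norm;
  double cached_norm;
  explicit Rng(uint64_t seed) : s(seed), have_norm(false), cached_norm(0.0) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  bool bern(double p) { return unif() < p; }
  int below(int n) { return (int)(unif() * n); }  // 0..n-1
  double norm() {
    if (have_norm) { have_norm = false; return cached_norm; }
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    double r = std::sqrt(-2.0 * std::log(u1));
    cached_norm = r * std::sin(2.0 * M_PI * u2);
    have_norm = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
  int pois(double lambda) {  // inversion; lambda small (litter sizes)
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
  template <typename T>
  void shuffle(std::vector<T>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = below(i + 1);
      std::swap(v[i], v[j]);
    }
  }
};

// ------------------------------------------------------------- agents ----
struct Vole {
  int id;
  int sex;        // 0 = male, 1 = female
  int age;        // days
  double lifespan;
  int x, y;       // daily foraging position
  int natal_x, natal_y;
  int mother;     // id of the dam, 0 for founders
  bool has_terr;
  int tx, ty, tr;
  bool has_orig;  // males: bounds of the territory held before moving
  int ox, oy, orr;
  bool dispersing;
  double heading;  // dispersal direction (radians), persistent per bout
  int gest_left;   // days until birth; -1 = not pregnant
  int litter_age;  // -1 = no unweaned litter
  int litter_size;
  bool dead;
};

struct Predator {
  int x, y;
  int days_unsucc;
  int age;
  bool reproduced_this_year;
  bool dead;
};

// --------------------------------------------------------- parameters ----
struct Params {
  double V1, V2, V3, V4, V5, V6, V7, V8, V9, V10, V11, V12, V13, V14, V15,
      V16, V17;
  double weaning_age, lifespan_mean_m, lifespan_sd_m, month_days;
  double gestation, litter_mean;
  int disp_steps;
  double disp_step_m, juv_range;
  double winter_decay, growth_increment;
  double encounter_radius;
  int vole_immigration;
};

struct PredParams {
  bool enabled;
  double home_range;
  int kill_cap;
  int survive_thr;
  int repro_thr;
  int disp_days;
  int starve_days;
  double disp_dist;
  int repro_day_start, repro_day_end;
  int n_offspring;
  int max_pred;
  int init_n;
  int max_age;
  int start_day;
  int immigration_n;
  int immigration_doy;
  double catch_p;
};

double getd(const List& l, const char* n) { return as<double>(l[n]); }

// -------------------------------------------------------- bucket grid ----
// Coarse spatial index over vole positions, rebuilt each day.
struct Buckets {
  int bs, bw, bh;
  std::vector<std::vector<int>> cells;
  void init(int W, int H, int bucket) {
    bs = bucket;
    bw = (W + bs - 1) / bs;
    bh = (H + bs - 1) / bs;
    cells.assign((size_t)bw * bh, {});
  }
  void clear() {
    for (auto& c : cells) c.clear();
  }
  void add(int x, int y, int idx) {
    cells[(size_t)(y / bs) * bw + (x / bs)].push_back(idx);
  }
  template <typename F>
  void for_near(double cx, double cy, double r, F f) const {
    int bx0 = std::max(0, (int)((cx - r) / bs));
    int bx1 = std::min(bw - 1, (int)((cx + r) / bs));
    int by0 = std::max(0, (int)((cy - r) / bs));
    int by1 = std::min(bh - 1, (int)((cy + r) / bs));
    for (int by = by0; by <= by1; ++by)
      for (int bx = bx0; bx <= bx1; ++bx)
        for (int idx : cells[(size_t)by * bw + bx]) f(idx);
  }
};

double dist2(double ax, double ay, double bx, double by) {
  double dx = ax - bx, dy = ay - by;
  return dx * dx + dy * dy;
}

// Area of intersection of two circles (lens), radii r1 r2, centre dist d.
double lens_area(double r1, double r2, double d) {
  if (d >= r1 + r2) return 0.0;
  double rmin = std::min(r1, r2), rmax = std::max(r1, r2);
  if (d <= rmax - rmin) return M_PI * rmin * rmin;
  double a1 = r1 * r1 * std::acos((d * d + r1 * r1 - r2 * r2) / (2 * d * r1));
  double a2 = r2 * r2 * std::acos((d * d + r2 * r2 - r1 * r1) / (2 * d * r2));
  double a3 = 0.5 * std::sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) *
                              (d + r1 + r2));
  return a1 + a2 - a3;
}

// ------------------------------------------------------------- engine ----
struct Engine {
  int W, H, n_days;
  const int* codes;   // H rows x W cols, column-major from R: codes[x*H+y]
  const int* patch;   // patch ids, 0 = unlabelled
  int n_class;
  std::vector<double> baseq, growth;
  std::vector<int> passable;
  std::vector<double> temp;
  std::vector<int> breed_start;  // per year, -1 = none
  Params P;
  PredParams PP;
  Rng rng, prng;

  // vegetation per habitat class: ring of <14 d cohorts + mature pool
  std::vector<std::array<double, 14>> newg;
  std::vector<double> mature;
  std::vector<double> quality;  // baseq * digestibility

  std::vector<int> bdist;  // Chebyshev distance to nearest different-code cell
  std::vector<std::vector<int>> halfw;  // disk row half-widths per radius

  std::vector<Vole> voles;
  std::vector<Predator> preds;
  int next_id;
  Buckets vb, tb_m;  // vole positions; settled-male territory centres

  // outputs
  std::vector<double> counts;      // n_days x 13
  std::vector<double> events;      // n_days x 10
  std::vector<double> patch_sum;   // n_patch x 4
  std::vector<double> patch_days;  // 4
  int n_patch, patch_rec_start;
  NumericMatrix traps;
  int cap_start, cap_end;
  std::vector<int> trap_of_cell;  // -1 or trap index
  std::vector<int> cap_day, cap_id, cap_trap, cap_nx, cap_ny, cap_age, cap_sex;
  std::vector<int> snap_days;
  std::vector<double> age_edges;
  std::vector<double> snaps;  // n_snap x (2*n_ageclass)

  Engine(uint64_t seed) : rng(seed), prng(seed ^ 0x5DEECE66DULL), next_id(1) {}

  int code_at(int x, int y) const { return codes[(size_t)x * H + y]; }
  int patch_at(int x, int y) const { return patch[(size_t)x * H + y]; }
  bool in_grid(int x, int y) const { return x >= 0 && x < W && y >= 0 && y < H; }

  void build_bdist() {
    // two-pass chamfer for L-inf distance to nearest cell of different code
    bdist.assign((size_t)W * H, 1 << 28);
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        int c = code_at(x, y);
        bool border = (x == 0 || y == 0 || x == W - 1 || y == H - 1);
        if (!border) {
          for (int dx = -1; dx <= 1 && !border; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              if (code_at(x + dx, y + dy) != c) { border = true; break; }
        }
        if (border) bdist[(size_t)x * H + y] = 0;
      }
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        size_t i = (size_t)x * H + y;
        if (x > 0) {
          bdist[i] = std::min(bdist[i], bdist[i - H] + 1);
          if (y > 0) bdist[i] = std::min(bdist[i], bdist[i - H - 1] + 1);
          if (y < H - 1) bdist[i] = std::min(bdist[i], bdist[i - H + 1] + 1);
        }
        if (y > 0) bdist[i] = std::min(bdist[i], bdist[i - 1] + 1);
      }
    for (int x = W - 1; x >= 0; --x)
      for (int y = H - 1; y >= 0; --y) {
        size_t i = (size_t)x * H + y;
        if (x < W - 1) {
          bdist[i] = std::min(bdist[i], bdist[i + H] + 1);
          if (y > 0) bdist[i] = std::min(bdist[i], bdist[i + H - 1] + 1);
          if (y < H - 1) bdist[i] = std::min(bdist[i], bdist[i + H + 1] + 1);
        }
        if (y < H - 1) bdist[i] = std::min(bdist[i], bdist[i + 1] + 1);
      }
  }

  void build_disks(int rmax) {
    halfw.assign(rmax + 1, {});
    for (int r = 0; r <= rmax; ++r) {
      halfw[r].assign(2 * r + 1, 0);
      for (int dy = -r; dy <= r; ++dy)
        halfw[r][dy + r] = (int)std::floor(std::sqrt((double)r * r - dy * dy));
    }
  }

  // mean habitat quality over the disk of radius r centred on (cx, cy);
  // cells outside the grid count as quality 0.
  double mean_quality(int cx, int cy, int r) {
    if (in_grid(cx, cy) && bdist[(size_t)cx * H + cy] > r + 1 && cx - r >= 0 &&
        cx + r < W && cy - r >= 0 && cy + r < H)
      return quality[code_at(cx, cy)];
    double s = 0.0;
    long n = 0;
    const std::vector<int>& hw = halfw[r];
    for (int dy = -r; dy <= r; ++dy) {
      int w = hw[dy + r];
      n += 2 * w + 1;
      int y = cy + dy;
      if (y < 0 || y >= H) continue;
      int x0 = std::max(0, cx - w), x1 = std::min(W - 1, cx + w);
      for (int x = x0; x <= x1; ++x) s += quality[code_at(x, y)];
    }
    return s / (double)n;
  }

  // is o a pre-territorial offspring of the focal vole?
  bool own_young(const Vole& o, int focal_id) const {
    return o.mother == focal_id &&
           o.age < (o.sex == 0 ? P.V1 : P.V2);
  }

  // voles (any stage/sex) within radius r of (cx, cy), excluding self
  // and the focal vole's own pre-territorial offspring
  int local_count(double cx, double cy, double r, int self_idx) {
    int n = 0;
    double r2 = r * r;
    int fid = self_idx >= 0 ? voles[self_idx].id : -1;
    vb.for_near(cx, cy, r, [&](int j) {
      if (j == self_idx) return;
      const Vole& o = voles[j];
      if (o.dead || own_young(o, fid)) return;
      if (dist2(o.x, o.y, cx, cy) <= r2) ++n;
    });
    return n;
  }

  double density_threshold(int sex) const {
    double rmin = sex == 0 ? P.V6 : P.V4;
    return P.V13 * (rmin * rmin) / (P.V4 * P.V4);
  }

  bool density_ok(int cx, int cy, int r, int sex, int self_idx) {
    return local_count(cx, cy, r, self_idx) + 1 < density_threshold(sex);
  }

  // would a same-sex resident older by the eviction gap immediately
  // force this vole off a territory of radius r at (cx, cy)?
  bool would_be_evicted(int cx, int cy, int r, int sex, int age,
                        int self_idx) {
    bool ev = false;
    double my_area = M_PI * r * r;
    double reach = 2.0 * (r + (sex == 0 ? P.V7 : P.V5));
    vb.for_near(cx, cy, reach, [&](int j) {
      if (ev || j == self_idx) return;
      const Vole& o = voles[j];
      if (o.dead || !o.has_terr || o.sex != sex) return;
      if (o.age - age < P.V8) return;
      double d = std::sqrt(dist2(o.tx, o.ty, cx, cy));
      if (lens_area(o.tr, r, d) / my_area > 0.5) ev = true;
    });
    return ev;
  }

  // scratch buffers for the radius scan (avoid per-call allocation)
  std::vector<double> d2_all, d2_fem;

  // acceptable territory radius at (cx, cy); -1 if none.  Acceptability
  // = mean quality x V3 reaches 1.0 and, when check_density, the local
  // vole count within the radius stays below the sex-scaled threshold.
  // Females take the smallest acceptable radius, as do males outside
  // the breeding season; a breeding-season male takes the largest
  // acceptable radius (mate access expands male ranges at low density,
  // while the density rule shrinks them back as abundance rises).
  // female_mode 2 (breeding-season male settlement) additionally
  // requires at least one adult female inside the chosen circle.
  int scan_radius(int cx, int cy, int sex, int self_idx, bool check_density,
                  int female_mode) {
    int rmin = (int)(sex == 0 ? P.V6 : P.V4);
    int rmax = (int)(sex == 0 ? P.V7 : P.V5);
    // one neighbour gather serves every candidate radius
    d2_all.clear();
    d2_fem.clear();
    double rmax2 = (double)rmax * rmax;
    int fid = self_idx >= 0 ? voles[self_idx].id : -1;
    vb.for_near(cx, cy, rmax, [&](int j) {
      if (j == self_idx) return;
      const Vole& o = voles[j];
      if (o.dead) return;
      double dd = dist2(o.x, o.y, cx, cy);
      if (dd > rmax2) return;
      if (check_density && !own_young(o, fid)) d2_all.push_back(dd);
      if (female_mode && o.sex == 1 && o.age >= P.V2) d2_fem.push_back(dd);
    });
    double thr = density_threshold(sex);
    bool expand = sex == 0 && female_mode > 0;  // breeding-season male
    if (expand) {
      // crowding gates tenure at the minimum radius; the claimed range
      // is then the largest radius of sufficient quality (mate access
      // and male-male exclusion extend over the patrolled area)
      if (check_density) {
        double rm2 = (double)rmin * rmin;
        int n = 1;  // the resident itself
        for (double dd : d2_all)
          if (dd <= rm2) ++n;
        if (n >= thr) return -1;
      }
      int best = -1;
      for (int r = rmin; r <= rmax; ++r)
        if (mean_quality(cx, cy, r) * P.V3 >= 1.0) best = r;
      if (best < 0) return -1;
      if (female_mode == 2) {
        double r2 = (double)best * best;
        bool has_fem = false;
        for (double dd : d2_fem)
          if (dd <= r2) { has_fem = true; break; }
        if (!has_fem) return -1;
      }
      return best;
    }
    for (int r = rmin; r <= rmax; ++r) {
      if (mean_quality(cx, cy, r) * P.V3 < 1.0) continue;
      double r2 = (double)r * r;
      if (check_density) {
        int n = 1;  // the resident itself
        for (double dd : d2_all)
          if (dd <= r2) ++n;
        if (n >= thr) continue;
      }
      return r;
    }
    return -1;
  }

  bool in_breeding_window(int day_idx) const {
    int year = day_idx / 365, doy = day_idx % 365 + 1;
    int bs = breed_start[year];
    return bs >= 0 && doy >= bs && doy < (int)P.V11;
  }

  double draw_lifespan() {
    double ls = (P.lifespan_mean_m + P.lifespan_sd_m * rng.norm()) * P.month_days;
    return std::max(1.0, ls);
  }

  void spawn_vole(int sex, int age, int x, int y, int nx, int ny,
                  int mother_id, std::vector<Vole>& out) {
    Vole v;
    v.id = next_id++;
    v.mother = mother_id;
    v.sex = sex;
    v.age = age;
    v.lifespan = draw_lifespan();
    v.x = x; v.y = y;
    v.natal_x = nx; v.natal_y = ny;
    v.has_terr = false; v.tx = v.ty = 0; v.tr = 0;
    v.has_orig = false; v.ox = v.oy = v.orr = 0;
    v.dispersing = true;
    v.heading = 2.0 * M_PI * rng.unif();
    v.gest_left = -1;
    v.litter_age = -1; v.litter_size = 0;
    v.dead = false;
    out.push_back(v);
  }

  void settle(Vole& v, int r) {
    v.has_terr = true;
    v.tx = v.x; v.ty = v.y; v.tr = r;
    v.dispersing = false;
    if (v.sex == 0) { v.has_orig = true; v.ox = v.tx; v.oy = v.ty; v.orr = r; }
  }

  void release_territory(Vole& v) {
    v.has_terr = false;
    v.dispersing = true;
    v.heading = 2.0 * M_PI * rng.unif();
  }

  // correlated random walk: a disperser keeps a persistent heading with
  // small turning noise, re-orienting only when blocked by impassable
  // habitat or the grid edge.
  bool disperse_move(Vole& v) {
    double step = P.disp_step_m;
    for (int attempt = 0; attempt < 8; ++attempt) {
      double h = v.heading + (rng.unif() - 0.5) * (M_PI / 2.0);
      int nx = v.x + (int)std::lround(std::cos(h) * step);
      int ny = v.y + (int)std::lround(std::sin(h) * step);
      if (in_grid(nx, ny) && passable[code_at(nx, ny)]) {
        v.heading = h;
        v.x = nx;
        v.y = ny;
        return true;
      }
      v.heading = 2.0 * M_PI * rng.unif();  // blocked: re-orient
    }
    return false;
  }

  void try_infanticide(Vole& male, int& n_inf) {
    double er = P.encounter_radius, er2 = er * er;
    vb.for_near(male.x, male.y, er, [&](int j) {
      Vole& f = voles[j];
      if (f.dead || f.sex != 1 || f.litter_age < 0) return;
      if (f.litter_age >= (int)P.weaning_age) return;
      double nest_x = f.has_terr ? f.tx : f.x, nest_y = f.has_terr ? f.ty : f.y;
      if (dist2(nest_x, nest_y, male.x, male.y) > er2) return;
      if (!rng.bern(P.V17)) return;  // attempt
      double succ = std::max(0.0, 1.0 - f.litter_age / P.weaning_age);
      if (rng.bern(succ)) {
        f.litter_age = -1;
        f.litter_size = 0;
        ++n_inf;
      }
    });
  }

  void run() {
    int n_age_class = (int)age_edges.size();
    snaps.assign(snap_days.size() * 2 * n_age_class, 0.0);
    counts.assign((size_t)n_days * 13, 0.0);
    events.assign((size_t)n_days * 10, 0.0);
    patch_sum.assign((size_t)n_patch * 4, 0.0);
    patch_days.assign(4, 0.0);

    std::vector<int> order;
    std::vector<Vole> newborns;

    for (int day = 0; day < n_days; ++day) {
      int doy = day % 365 + 1;
      double T = temp[day];

      // ---- vegetation (per habitat class) ----
      for (int c = 0; c < n_class; ++c) {
        // age cohorts by one day; oldest cohort matures
        mature[c] += newg[c][13];
        for (int k = 13; k > 0; --k) newg[c][k] = newg[c][k - 1];
        newg[c][0] = 0.0;
        if (growth[c] > 0 && T >= P.V14)
          newg[c][0] = P.growth_increment * growth[c];
        else
          mature[c] *= (1.0 - P.winter_decay);
        double ng = 0.0;
        for (int k = 0; k < 14; ++k) ng += newg[c][k];
        double tot = ng + mature[c];
        double frac = tot > 0 ? ng / tot : 0.0;
        double dig = std::min(1.0, 0.7 + std::sqrt(frac));
        quality[c] = baseq[c] * dig;
      }

      // ---- spatial indices (day-start snapshot) ----
      vb.clear();
      tb_m.clear();
      for (int i = 0; i < (int)voles.size(); ++i) {
        vb.add(voles[i].x, voles[i].y, i);
        if (voles[i].sex == 0 && voles[i].has_terr)
          tb_m.add(voles[i].tx, voles[i].ty, i);
      }

      bool window = in_breeding_window(day);

      // annual vole immigration into the open landscape, arriving at
      // the start of the breeding season
      if (P.vole_immigration > 0) {
        int year = day / 365;
        int bs = breed_start[year];
        if (bs >= 0 && doy == bs) {
          for (int i = 0; i < P.vole_immigration; ++i) {
            int tries = 0, px = 0, py = 0;
            do {
              px = rng.below(W);
              py = rng.below(H);
            } while (baseq[code_at(px, py)] <= 0 && ++tries < 1000);
            if (baseq[code_at(px, py)] > 0)
              spawn_vole(rng.bern(0.5) ? 1 : 0, 60 + rng.below(60), px, py,
                         px, py, 0, voles);
          }
        }
      }
      int e_births_m = 0, e_births_f = 0, e_bg = 0, e_disp_m = 0,
          e_disp_f = 0, e_life = 0, e_pred = 0, e_inf = 0, e_evict_m = 0,
          e_evict_f = 0;

      order.resize(voles.size());
      for (int i = 0; i < (int)order.size(); ++i) order[i] = i;
      rng.shuffle(order);
      newborns.clear();

      for (int oi : order) {
        Vole& v = voles[oi];
        if (v.dead) continue;

        // -- mortality --
        if (rng.bern(P.V10)) { v.dead = true; ++e_bg; continue; }
        if (v.age > v.lifespan) { v.dead = true; ++e_life; continue; }

        // -- aging (maturation is implicit via age thresholds) --
        v.age += 1;
        double mat_age = v.sex == 0 ? P.V1 : P.V2;
        bool adult = v.age >= mat_age;

        // -- daily position --
        // Settled voles forage over their whole territory each day;
        // pre-territorial juveniles range around the natal nest.
        // Adult dispersers move in the dispersal phase below.
        if (v.has_terr || !adult) {
          double cx = v.has_terr ? v.tx : v.natal_x;
          double cy = v.has_terr ? v.ty : v.natal_y;
          double rr = v.has_terr ? v.tr : P.juv_range;
          double a = 2.0 * M_PI * rng.unif();
          double d = rr * std::sqrt(rng.unif());
          int nx = (int)std::lround(cx + d * std::cos(a));
          int ny = (int)std::lround(cy + d * std::sin(a));
          if (in_grid(nx, ny) && passable[code_at(nx, ny)]) {
            v.x = nx;
            v.y = ny;
          }
        }

        // -- territory assessment / eviction --
        // Territorial competition is a breeding-season phenomenon:
        // inside the window every vole re-justifies its territory
        // daily against the full acceptability rule, density included
        // (a female with an active pregnancy or unweaned litter
        // defends her nest site and is exempt from the crowding
        // displacement), and older same-sex residents evict younger
        // ones.  Outside the window territories lapse into loose
        // winter ranges held on habitat quality alone.
        if (v.has_terr) {
          bool nesting = v.sex == 1 && (v.gest_left > 0 || v.litter_age >= 0);
          int r = scan_radius(v.tx, v.ty, v.sex, oi, window && !nesting,
                              (v.sex == 0 && window && adult) ? 2 : 0);
          if (r < 0) {
            release_territory(v);
          } else {
            v.tr = r;
            if (window) {
              // eviction by an older same-sex territory holder
              double my_area = M_PI * v.tr * v.tr;
              bool evicted = false;
              double reach = v.tr + (v.sex == 0 ? P.V7 : P.V5);
              vb.for_near(v.tx, v.ty, 2.0 * reach, [&](int j) {
                if (evicted || j == oi) return;
                const Vole& o = voles[j];
                if (o.dead || !o.has_terr || o.sex != v.sex) return;
                if (o.age - v.age < P.V8) return;
                double d = std::sqrt(dist2(o.tx, o.ty, v.tx, v.ty));
                if (lens_area(o.tr, v.tr, d) / my_area > 0.5) evicted = true;
              });
              if (evicted) {
                release_territory(v);
                if (v.sex == 0) ++e_evict_m; else ++e_evict_f;
              }
            }
          }
        }

        // -- reproduction (females) --
        if (v.sex == 1) {
          if (v.gest_left > 0) {
            if (--v.gest_left == 0) {
              v.gest_left = -1;
              v.litter_size = std::max(1, rng.pois(P.litter_mean));
              v.litter_age = 0;
            }
          } else if (v.litter_age >= 0) {
            if (++v.litter_age >= (int)P.weaning_age) {
              int nx = v.has_terr ? v.tx : v.x, ny = v.has_terr ? v.ty : v.y;
              for (int k = 0; k < v.litter_size; ++k) {
                int sx = rng.bern(0.5) ? 1 : 0;
                spawn_vole(sx, (int)P.weaning_age, nx, ny, nx, ny, v.id,
                           newborns);
                if (sx == 0) ++e_births_m; else ++e_births_f;
              }
              v.litter_age = -1;
              v.litter_size = 0;
            }
          } else if (adult && v.has_terr && window &&
                     density_ok(v.tx, v.ty, v.tr, 1, oi)) {
            // choose the nearest settled adult male whose territory
            // contains her position; ties by lowest id
            int best = -1;
            double bd = 1e30;
            tb_m.for_near(v.x, v.y, P.V7, [&](int j) {
              const Vole& m = voles[j];
              if (m.dead || !m.has_terr || m.age < P.V1) return;
              double d2v = dist2(m.tx, m.ty, v.x, v.y);
              if (d2v > (double)m.tr * m.tr) return;
              if (d2v < bd - 1e-9 ||
                  (std::fabs(d2v - bd) <= 1e-9 &&
                   (best < 0 || m.id < voles[best].id))) {
                bd = d2v;
                best = j;
              }
            });
            if (best >= 0) v.gest_left = (int)P.gestation;
          }
        }

        // -- male restlessness --
        if (v.sex == 0 && adult && v.has_terr && window) {
          int nf = 0;
          double r2 = (double)v.tr * v.tr;
          vb.for_near(v.tx, v.ty, v.tr, [&](int j) {
            const Vole& f = voles[j];
            if (!f.dead && f.sex == 1 && f.age >= P.V2 &&
                dist2(f.x, f.y, v.tx, v.ty) <= r2)
              ++nf;
          });
          if (nf == 0 && rng.bern(P.V12)) release_territory(v);
        }

        // -- dispersal --
        // Juveniles are pre-territorial (tethered to the natal nest
        // above) and can first claim a territory at the sex-specific
        // maturation age.  Adults without a territory are dispersing
        // proper: the per-day dispersal mortality V9 applies, and they
        // move by a correlated random walk, attempting settlement
        // before each step.
        if (!v.has_terr && adult) {
          if (rng.bern(P.V9)) {
            v.dead = true;
            if (v.sex == 0) ++e_disp_m; else ++e_disp_f;
            continue;
          }
          for (int s = 0; s <= P.disp_steps; ++s) {
            if (quality[code_at(v.x, v.y)] > 0) {
              int r = scan_radius(v.x, v.y, v.sex, oi, true,
                                  (v.sex == 0 && window) ? 2 : 0);
              if (r >= 0 &&
                  (!window ||
                   !would_be_evicted(v.x, v.y, r, v.sex, v.age, oi))) {
                settle(v, r);
                break;
              }
            }
            if (s == P.disp_steps) break;
            disperse_move(v);
          }
          // a mature male beyond his original bounds encounters nests
          // over his assessment range while moving, settled or not
          if (v.sex == 0) try_infanticide(v, e_inf);
        }
      }

      // integrate newborns (act from tomorrow)
      for (Vole& nb : newborns) voles.push_back(nb);

      // ---- predators ----
      if (PP.enabled) {
        // founders arrive once the prey base is established, plus a
        // trickle of annual immigrants (the landscape is open)
        bool founders = day == PP.start_day;
        bool immigrants = day > PP.start_day && doy == PP.immigration_doy;
        if (founders || immigrants) {
          int n_arrive = founders ? PP.init_n : PP.immigration_n;
          std::vector<std::pair<int, int>> cells;
          for (int x = 0; x < W; ++x)
            for (int y = 0; y < H; ++y)
              if (baseq[code_at(x, y)] > 0) cells.push_back({x, y});
          for (int i = 0; i < n_arrive && !cells.empty(); ++i) {
            auto [px, py] = cells[prng.below((int)cells.size())];
            Predator p;
            p.x = px; p.y = py;
            p.days_unsucc = 0;
            p.age = prng.below(PP.max_age / 2);
            p.reproduced_this_year = false;
            p.dead = false;
            preds.push_back(p);
          }
        }
        // rebuild vole bucket including newborns, excluding dead
        vb.clear();
        for (int i = 0; i < (int)voles.size(); ++i)
          if (!voles[i].dead) vb.add(voles[i].x, voles[i].y, i);
        if (doy == 1)
          for (Predator& p : preds) p.reproduced_this_year = false;
        std::vector<int> porder(preds.size());
        for (int i = 0; i < (int)porder.size(); ++i) porder[i] = i;
        prng.shuffle(porder);
        std::vector<int> local;
        std::vector<Predator> pred_newborns;
        int n_alive_pred = 0;
        for (Predator& q : preds)
          if (!q.dead) ++n_alive_pred;
        for (int pi : porder) {
          Predator& p = preds[pi];
          if (p.dead) continue;
          p.age += 1;
          if (p.age > PP.max_age) { p.dead = true; --n_alive_pred; continue; }
          local.clear();
          double hr2 = PP.home_range * PP.home_range;
          vb.for_near(p.x, p.y, PP.home_range, [&](int j) {
            if (!voles[j].dead && dist2(voles[j].x, voles[j].y, p.x, p.y) <= hr2)
              local.push_back(j);
          });
          int n_local = (int)local.size();
          // imperfect capture: each local vole is caught with a small
          // daily probability, up to the daily cap -- prey escape
          // hunting pressure at low density
          int kills = 0;
          for (int k = 0; k < n_local && kills < PP.kill_cap; ++k)
            if (prng.bern(PP.catch_p)) ++kills;
          for (int k = 0; k < kills; ++k) {
            int pick = prng.below((int)local.size());
            voles[local[pick]].dead = true;
            ++e_pred;
            local[pick] = local.back();
            local.pop_back();
          }
          if (n_local < PP.survive_thr) {
            if (++p.days_unsucc > PP.starve_days) {
              p.dead = true;
              --n_alive_pred;
              continue;
            }
            if (p.days_unsucc >= PP.disp_days) {
              double ang = 2 * M_PI * prng.unif();
              int nx = p.x + (int)std::round(std::cos(ang) * PP.disp_dist);
              int ny = p.y + (int)std::round(std::sin(ang) * PP.disp_dist);
              p.x = std::min(W - 1, std::max(0, nx));
              p.y = std::min(H - 1, std::max(0, ny));
            }
          } else {
            p.days_unsucc = 0;
          }
          if (!p.reproduced_this_year && doy >= PP.repro_day_start &&
              doy <= PP.repro_day_end && n_local >= PP.repro_thr &&
              n_alive_pred < PP.max_pred) {
            p.reproduced_this_year = true;
            for (int k = 0; k < PP.n_offspring && n_alive_pred < PP.max_pred;
                 ++k) {
              Predator c;
              c.x = p.x; c.y = p.y;
              c.days_unsucc = 0; c.age = 0;
              c.reproduced_this_year = true;
              c.dead = false;
              pred_newborns.push_back(c);  // appended after the loop
              ++n_alive_pred;
            }
          }
        }
        for (Predator& c : pred_newborns) preds.push_back(c);
        preds.erase(std::remove_if(preds.begin(), preds.end(),
                                   [](const Predator& p) { return p.dead; }),
                    preds.end());
      }

      // ---- recording ----
      // grid-wide counts plus a census restricted to cells of
      // food-bearing habitat (base quality > 0), mirroring field
      // sampling of the high-quality areas
      int am = 0, af = 0, jm = 0, jf = 0;
      int cam = 0, caf = 0, cjm = 0, cjf = 0;
      int settf = 0, pregf = 0, settm = 0;
      int season = (doy >= 60 && doy < 152)    ? 0   // Mar-May
                   : (doy >= 152 && doy < 244) ? 1   // Jun-Aug
                   : (doy >= 244 && doy < 335) ? 2   // Sep-Nov
                                               : 3;  // Dec-Feb
      bool rec_patch = day >= patch_rec_start;
      if (rec_patch) patch_days[season] += 1.0;
      for (const Vole& v : voles) {
        if (v.dead) continue;
        bool adult = v.age >= (v.sex == 0 ? P.V1 : P.V2);
        if (v.sex == 0) adult ? ++am : ++jm;
        else            adult ? ++af : ++jf;
        if (v.sex == 1 && adult && v.has_terr) ++settf;
        if (v.sex == 1 && (v.gest_left > 0 || v.litter_age >= 0)) ++pregf;
        if (v.sex == 0 && adult && v.has_terr) ++settm;
        if (baseq[code_at(v.x, v.y)] > 0) {
          if (v.sex == 0) adult ? ++cam : ++cjm;
          else            adult ? ++caf : ++cjf;
        }
        if (rec_patch) {
          int pid = patch_at(v.x, v.y);
          if (pid > 0)
            patch_sum[(size_t)(pid - 1) * 4 + season] += 1.0;
        }
      }
      counts[(size_t)day * 13 + 0] = am;
      counts[(size_t)day * 13 + 1] = af;
      counts[(size_t)day * 13 + 2] = jm;
      counts[(size_t)day * 13 + 3] = jf;
      counts[(size_t)day * 13 + 4] = am + af + jm + jf;
      counts[(size_t)day * 13 + 5] = (double)preds.size();
      counts[(size_t)day * 13 + 6] = cam;
      counts[(size_t)day * 13 + 7] = caf;
      counts[(size_t)day * 13 + 8] = cjm;
      counts[(size_t)day * 13 + 9] = cjf;
      counts[(size_t)day * 13 + 10] = settf;
      counts[(size_t)day * 13 + 11] = pregf;
      counts[(size_t)day * 13 + 12] = settm;
      events[(size_t)day * 10 + 0] = e_births_m;
      events[(size_t)day * 10 + 1] = e_births_f;
      events[(size_t)day * 10 + 2] = e_bg;
      events[(size_t)day * 10 + 3] = e_disp_m;
      events[(size_t)day * 10 + 4] = e_disp_f;
      events[(size_t)day * 10 + 5] = e_life;
      events[(size_t)day * 10 + 6] = e_pred;
      events[(size_t)day * 10 + 7] = e_inf;
      events[(size_t)day * 10 + 8] = e_evict_m;
      events[(size_t)day * 10 + 9] = e_evict_f;

      // capture records
      if (day >= cap_start && day <= cap_end && !trap_of_cell.empty()) {
        for (const Vole& v : voles) {
          if (v.dead) continue;
          int t = trap_of_cell[(size_t)v.x * H + v.y];
          if (t >= 0) {
            cap_day.push_back(day);
            cap_id.push_back(v.id);
            cap_trap.push_back(t);
            cap_nx.push_back(v.natal_x);
            cap_ny.push_back(v.natal_y);
            cap_age.push_back(v.age);
            cap_sex.push_back(v.sex);
          }
        }
      }

      // mid-month age-structure snapshots
      for (int si = 0; si < (int)snap_days.size(); ++si) {
        if (snap_days[si] != day) continue;
        for (const Vole& v : voles) {
          if (v.dead) continue;
          int cls = (int)age_edges.size() - 1;
          for (int k = 0; k < (int)age_edges.size(); ++k)
            if (v.age <= age_edges[k]) { cls = k; break; }
          snaps[(size_t)si * 2 * n_age_class + (size_t)v.sex * n_age_class +
                cls] += 1.0;
        }
      }

      // compact the dead
      voles.erase(std::remove_if(voles.begin(), voles.end(),
                                 [](const Vole& v) { return v.dead; }),
                  voles.end());
    }
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_label_patches(IntegerMatrix codes) {
  int H = codes.nrow(), W = codes.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      if (lab(y, x) != 0) continue;
      int c = codes(y, x);
      ++next;
      stack.clear();
      stack.push_back({x, y});
      lab(y, x) = next;
      while (!stack.empty()) {
        auto [cx, cy] = stack.back();
        stack.pop_back();
        const int DX[4] = {1, -1, 0, 0}, DY[4] = {0, 0, 1, -1};
        for (int d = 0; d < 4; ++d) {
          int nx = cx + DX[d], ny = cy + DY[d];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          if (lab(ny, nx) == 0 && codes(ny, nx) == c) {
            lab(ny, nx) = next;
            stack.push_back({nx, ny});
          }
        }
      }
    }
  return lab;
}

// [[Rcpp::export]]
List cpp_run_sim(IntegerMatrix codes, IntegerMatrix patch,
                 NumericVector base_quality, NumericVector growth_rate,
                 LogicalVector passable_cls, NumericVector temp,
                 IntegerVector breed_start, List par, List pred,
                 NumericMatrix traps, int capture_start, int capture_end,
                 IntegerVector snapshot_days, NumericVector age_edges,
                 int patch_record_start, int n_patches, int init_n, int seed) {
  Engine E((uint64_t)(uint32_t)seed * 2654435761ULL + 1ULL);
  E.H = codes.nrow();
  E.W = codes.ncol();
  // column-major: codes(y, x) at x*H + y, matching Engine::code_at
  E.codes = codes.begin();
  E.patch = patch.begin();
  E.n_class = base_quality.size();
  E.baseq = as<std::vector<double>>(base_quality);
  E.growth = as<std::vector<double>>(growth_rate);
  E.passable.resize(E.n_class);
  for (int i = 0; i < E.n_class; ++i) E.passable[i] = passable_cls[i] ? 1 : 0;
  E.temp = as<std::vector<double>>(temp);
  E.n_days = temp.size();
  E.breed_start = as<std::vector<int>>(breed_start);

  Params& P = E.P;
  P.V1 = getd(par, "V1");   P.V2 = getd(par, "V2");   P.V3 = getd(par, "V3");
  P.V4 = getd(par, "V4");   P.V5 = getd(par, "V5");   P.V6 = getd(par, "V6");
  P.V7 = getd(par, "V7");   P.V8 = getd(par, "V8");   P.V9 = getd(par, "V9");
  P.V10 = getd(par, "V10"); P.V11 = getd(par, "V11"); P.V12 = getd(par, "V12");
  P.V13 = getd(par, "V13"); P.V14 = getd(par, "V14"); P.V15 = getd(par, "V15");
  P.V16 = getd(par, "V16"); P.V17 = getd(par, "V17");
  P.weaning_age = getd(par, "weaning_age");
  P.lifespan_mean_m = getd(par, "lifespan_mean_months");
  P.lifespan_sd_m = getd(par, "lifespan_sd_months");
  P.month_days = getd(par, "month_days");
  P.gestation = getd(par, "gestation_days");
  P.litter_mean = getd(par, "litter_mean");
  P.disp_steps = (int)getd(par, "dispersal_steps");
  P.juv_range = getd(par, "juvenile_range_m");
  P.disp_step_m = getd(par, "dispersal_step_m");
  P.winter_decay = getd(par, "winter_decay");
  P.growth_increment = getd(par, "growth_increment");
  P.encounter_radius = getd(par, "encounter_radius");
  P.vole_immigration = (int)getd(par, "vole_immigration_n");

  PredParams& PP = E.PP;
  PP.enabled = as<bool>(pred["enabled"]);
  if (PP.enabled) {
    PP.home_range = getd(pred, "home_range");
    PP.kill_cap = (int)getd(pred, "kill_cap");
    PP.survive_thr = (int)getd(pred, "survive_threshold");
    PP.repro_thr = (int)getd(pred, "reproduce_threshold");
    PP.disp_days = (int)getd(pred, "dispersal_days");
    PP.starve_days = (int)getd(pred, "starvation_days");
    PP.disp_dist = getd(pred, "dispersal_distance");
    PP.repro_day_start = (int)getd(pred, "repro_day_start");
    PP.repro_day_end = (int)getd(pred, "repro_day_end");
    PP.n_offspring = (int)getd(pred, "n_offspring");
    PP.max_pred = (int)getd(pred, "max_predators");
    PP.init_n = (int)getd(pred, "init_n");
    PP.max_age = (int)getd(pred, "max_age_days");
    PP.start_day = (int)getd(pred, "start_day");
    PP.immigration_n = (int)getd(pred, "immigration_n");
    PP.immigration_doy = (int)getd(pred, "immigration_doy");
    PP.catch_p = getd(pred, "catch_p");
  }

  E.newg.assign(E.n_class, {});
  for (auto& a : E.newg) a.fill(0.0);
  E.mature.assign(E.n_class, 1.0);  // start with mature standing biomass
  E.quality.assign(E.n_class, 0.0);
  for (int c = 0; c < E.n_class; ++c) E.quality[c] = 0.7 * E.baseq[c];

  E.build_bdist();
  int rmax = (int)std::max(P.V5, P.V7);
  E.build_disks(std::max(1, rmax));
  E.vb.init(E.W, E.H, 32);
  E.tb_m.init(E.W, E.H, 32);

  // trap cell map: cells whose centre lies within 1 m of a trap
  E.traps = traps;
  E.cap_start = capture_start;
  E.cap_end = capture_end;
  if (traps.nrow() > 0) {
    E.trap_of_cell.assign((size_t)E.W * E.H, -1);
    for (int t = 0; t < traps.nrow(); ++t) {
      double txc = traps(t, 0), tyc = traps(t, 1);
      for (int x = (int)txc - 2; x <= (int)txc + 2; ++x)
        for (int y = (int)tyc - 2; y <= (int)tyc + 2; ++y) {
          if (!E.in_grid(x, y)) continue;
          double d2v = dist2(x + 0.5, y + 0.5, txc, tyc);
          if (d2v > 1.0) continue;
          size_t i = (size_t)x * E.H + y;
          int cur = E.trap_of_cell[i];
          if (cur < 0 ||
              d2v < dist2(x + 0.5, y + 0.5, traps(cur, 0), traps(cur, 1)))
            E.trap_of_cell[i] = t;
        }
    }
  }

  E.snap_days = as<std::vector<int>>(snapshot_days);
  E.age_edges = as<std::vector<double>>(age_edges);
  E.n_patch = n_patches;
  E.patch_rec_start = patch_record_start;

  // initial population scattered over settleable habitat
  std::vector<std::pair<int, int>> settleable;
  for (int x = 0; x < E.W; ++x)
    for (int y = 0; y < E.H; ++y)
      if (E.baseq[E.code_at(x, y)] > 0) settleable.push_back({x, y});
  if (!settleable.empty()) {
    for (int i = 0; i < init_n; ++i) {
      auto [x, y] = settleable[E.rng.below((int)settleable.size())];
      int age = 60 + E.rng.below(180);
      E.spawn_vole(E.rng.bern(0.5) ? 1 : 0, age, x, y, x, y, 0, E.voles);
    }
  }

  E.run();

  int nd = E.n_days;
  NumericMatrix counts(nd, 13), events(nd, 10);
  for (int d = 0; d < nd; ++d) {
    for (int k = 0; k < 13; ++k) counts(d, k) = E.counts[(size_t)d * 13 + k];
    for (int k = 0; k < 10; ++k) events(d, k) = E.events[(size_t)d * 10 + k];
  }
  colnames(counts) = CharacterVector::create(
      "adult_m", "adult_f", "juv_m", "juv_f", "total", "predators",
      "census_adult_m", "census_adult_f", "census_juv_m", "census_juv_f",
      "settled_f", "repro_f", "settled_m");
  colnames(events) = CharacterVector::create(
      "births_m", "births_f", "deaths_background", "deaths_dispersal_m",
      "deaths_dispersal_f", "deaths_lifespan", "deaths_predation",
      "infanticides", "evictions_m", "evictions_f");

  NumericMatrix psum(n_patches, 4);
  for (int p = 0; p < n_patches; ++p)
    for (int s = 0; s < 4; ++s) psum(p, s) = E.patch_sum[(size_t)p * 4 + s];
  colnames(psum) = CharacterVector::create("spring", "summer", "autumn",
                                           "winter");

  int n_age_class = age_edges.size();
  NumericMatrix snapm((int)E.snap_days.size(), 2 * n_age_class);
  for (int i = 0; i < (int)E.snap_days.size(); ++i)
    for (int k = 0; k < 2 * n_age_class; ++k)
      snapm(i, k) = E.snaps[(size_t)i * 2 * n_age_class + k];

  DataFrame caps = DataFrame::create(
      _["day"] = wrap(E.cap_day), _["vole_id"] = wrap(E.cap_id),
      _["trap"] = wrap(E.cap_trap), _["natal_x"] = wrap(E.cap_nx),
      _["natal_y"] = wrap(E.cap_ny), _["age_days"] = wrap(E.cap_age),
      _["sex"] = wrap(E.cap_sex));

  return List::create(
      _["counts"] = counts, _["events"] = events, _["patch_sums"] = psum,
      _["patch_days"] = wrap(E.patch_days), _["captures"] = caps,
      _["age_snapshots"] = snapm, _["snapshot_days"] = wrap(E.snap_days));
}
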