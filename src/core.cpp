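// Fixed-time-step stochastic core for the mitochondrial quality-control
// simulator: damage, persistent-random-walk transport, contact detection,
// selective fusion, fission with discrete health-unit exchange, selective
// autophagy, and population-limited replication, for hard-disk mitochondria
// in a square 2D cell.
//
// All randomness is drawn from R's RNG so that simulations are reproducible
// from set.seed() and the R-level sub-step wrappers consume the stream in
// exactly the same order as the full compiled run loop.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <set>
#include <map>
#include <unordered_map>
#include <utility>
#include <algorithm>

using namespace Rcpp;

static const double WINDOW_MIN = 180.0; // trailing cap window, minutes

// ---------------------------------------------------------------------------
// parameters and state

struct Pars {
  double dt, L, r, k_damage, k_fus, k_fis, k_aut, k_rep, N0, sigma_N,
      h_aut, h_fus, v, k_on, k_off, alpha, beta, cap_aut, cap_rep, tol;
  int n_HU, n_exchange, max_place_attempts;
};

static Pars pars_from_list(const List& p) {
  Pars q;
  q.dt = as<double>(p["dt"]);
  q.L = as<double>(p["L"]);
  q.r = as<double>(p["r"]);
  q.k_damage = as<double>(p["k_damage"]);
  q.k_fus = as<double>(p["k_fus"]);
  q.k_fis = as<double>(p["k_fis"]);
  q.k_aut = as<double>(p["k_aut"]);
  q.k_rep = as<double>(p["k_rep"]);
  q.N0 = as<double>(p["N0"]);
  q.sigma_N = as<double>(p["sigma_N"]);
  q.h_aut = as<double>(p["h_aut"]);
  q.h_fus = as<double>(p["h_fus"]);
  q.v = as<double>(p["v"]);
  q.k_on = as<double>(p["k_on"]);
  q.k_off = as<double>(p["k_off"]);
  q.alpha = as<double>(p["alpha"]);
  q.beta = as<double>(p["beta"]);
  q.cap_aut = as<double>(p["cap_autophagy"]);
  q.cap_rep = as<double>(p["cap_replication"]);
  q.tol = as<double>(p["tol"]);
  q.n_HU = as<int>(p["n_HU"]);
  q.n_exchange = as<int>(p["n_exchange"]);
  q.max_place_attempts = as<int>(p["max_place_attempts"]);
  return q;
}

struct EventLog {
  std::vector<double> time;
  std::vector<int> kind, id1, id2;
  std::vector<double> d1, d2, d3, d4;
  void add(double t, int k, int a, int b, double x1 = NA_REAL,
           double x2 = NA_REAL, double x3 = NA_REAL, double x4 = NA_REAL) {
    time.push_back(t);
    kind.push_back(k);
    id1.push_back(a);
    id2.push_back(b);
    d1.push_back(x1);
    d2.push_back(x2);
    d3.push_back(x3);
    d4.push_back(x4);
  }
};

// kind codes
enum { EV_DAMAGE = 1, EV_FUSION = 2, EV_FISSION = 3, EV_AUTOPHAGY = 4,
       EV_REPLICATION = 5, EV_REPLICATION_BLOCKED = 6 };

struct Cell {
  double time = 0.0;
  int nHU = 10, next_id = 1;
  std::vector<double> x, y, theta;
  std::vector<int> id, motion, moved, deg;
  std::vector<int> hu; // n * nHU, row block per mitochondrion
  std::vector<std::pair<int, int> > bonds; // index pairs, first < second
  std::vector<double> aut_times, rep_times;
  int cum_aut = 0, cum_rep = 0;

  int n() const { return (int)x.size(); }
  int hsum(int i) const {
    int s = 0;
    for (int u = 0; u < nHU; ++u) s += hu[(size_t)i * nHU + u];
    return s;
  }
  double health(int i) const { return (double)hsum(i) / nHU; }
};

// ---------------------------------------------------------------------------
// list <-> struct conversion (R-facing state is keyed by persistent ids)

static Cell cell_from_list(const List& st) {
  Cell c;
  c.time = as<double>(st["time"]);
  NumericMatrix pos = st["pos"];
  IntegerMatrix hum = st["hu"];
  IntegerVector mo = st["motion"], mv = st["moved"], ids = st["id"];
  NumericVector th = st["theta"];
  int n = pos.nrow();
  c.nHU = hum.ncol();
  c.x.resize(n); c.y.resize(n); c.theta.resize(n);
  c.id.resize(n); c.motion.resize(n); c.moved.resize(n);
  c.deg.assign(n, 0);
  c.hu.resize((size_t)n * c.nHU);
  std::unordered_map<int, int> idx;
  for (int i = 0; i < n; ++i) {
    c.x[i] = pos(i, 0);
    c.y[i] = pos(i, 1);
    c.theta[i] = th[i];
    c.id[i] = ids[i];
    c.motion[i] = mo[i];
    c.moved[i] = mv[i];
    for (int u = 0; u < c.nHU; ++u) c.hu[(size_t)i * c.nHU + u] = hum(i, u);
    idx[ids[i]] = i;
  }
  IntegerMatrix bm = st["bonds"];
  for (int b = 0; b < bm.nrow(); ++b) {
    std::unordered_map<int, int>::iterator ii = idx.find(bm(b, 0));
    std::unordered_map<int, int>::iterator jj = idx.find(bm(b, 1));
    if (ii == idx.end() || jj == idx.end())
      stop("bond references a mitochondrion id that does not exist");
    int i = ii->second, j = jj->second;
    if (i > j) std::swap(i, j);
    c.bonds.push_back(std::make_pair(i, j));
    c.deg[i]++; c.deg[j]++;
  }
  c.next_id = as<int>(st["next_id"]);
  c.aut_times = as<std::vector<double> >(st["aut_times"]);
  c.rep_times = as<std::vector<double> >(st["rep_times"]);
  c.cum_aut = as<int>(st["cum_autophagy"]);
  c.cum_rep = as<int>(st["cum_replication"]);
  return c;
}

static List cell_to_list(const Cell& c) {
  int n = c.n();
  NumericMatrix pos(n, 2);
  IntegerMatrix hum(n, c.nHU);
  IntegerVector mo(n), mv(n), ids(n);
  NumericVector th(n);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = c.x[i];
    pos(i, 1) = c.y[i];
    th[i] = c.theta[i];
    ids[i] = c.id[i];
    mo[i] = c.motion[i];
    mv[i] = c.moved[i];
    for (int u = 0; u < c.nHU; ++u) hum(i, u) = c.hu[(size_t)i * c.nHU + u];
  }
  colnames(pos) = CharacterVector::create("x", "y");
  IntegerMatrix bm(c.bonds.size(), 2);
  for (size_t b = 0; b < c.bonds.size(); ++b) {
    bm(b, 0) = c.id[c.bonds[b].first];
    bm(b, 1) = c.id[c.bonds[b].second];
  }
  List st = List::create(
      _["time"] = c.time, _["pos"] = pos, _["hu"] = hum, _["motion"] = mo,
      _["theta"] = th, _["moved"] = mv, _["id"] = ids,
      _["next_id"] = c.next_id, _["bonds"] = bm,
      _["aut_times"] = wrap(c.aut_times), _["rep_times"] = wrap(c.rep_times),
      _["cum_autophagy"] = c.cum_aut, _["cum_replication"] = c.cum_rep);
  st.attr("class") = "cell_state";
  return st;
}

static DataFrame events_to_df(const EventLog& e) {
  return DataFrame::create(
      _["time"] = wrap(e.time), _["kind"] = wrap(e.kind),
      _["id1"] = wrap(e.id1), _["id2"] = wrap(e.id2),
      _["d1"] = wrap(e.d1), _["d2"] = wrap(e.d2), _["d3"] = wrap(e.d3),
      _["d4"] = wrap(e.d4));
}

// ---------------------------------------------------------------------------
// sub-steps

static void do_damage(Cell& c, const Pars& p, EventLog* log) {
  double prob = 1.0 - std::exp(-p.k_damage * p.dt);
  if (prob <= 0.0) return;
  int n = c.n();
  for (int i = 0; i < n; ++i) {
    int flipped = 0;
    for (int u = 0; u < c.nHU; ++u) {
      size_t k = (size_t)i * c.nHU + u;
      if (c.hu[k] == 1 && unif_rand() < prob) {
        c.hu[k] = 0;
        ++flipped;
      }
    }
    if (flipped > 0 && log)
      log->add(c.time, EV_DAMAGE, c.id[i], NA_INTEGER, (double)flipped);
  }
}

// advance mover i along theta by at most v*dt, truncated at first contact
// (center distance 2r) or at the cell wall; truncation detaches the filament
static void advance_one(Cell& c, int i, const Pars& p) {
  double step = p.v * p.dt;
  if (step <= 0.0) return;
  double dx = std::cos(c.theta[i]), dy = std::sin(c.theta[i]);
  double s = step;
  bool blocked = false;
  // wall truncation
  if (dx > 0) {
    double sw = (p.L - p.r - c.x[i]) / dx;
    if (sw < s) { s = std::max(0.0, sw); blocked = true; }
  } else if (dx < 0) {
    double sw = (p.r - c.x[i]) / dx;
    if (sw < s) { s = std::max(0.0, sw); blocked = true; }
  }
  if (dy > 0) {
    double sw = (p.L - p.r - c.y[i]) / dy;
    if (sw < s) { s = std::max(0.0, sw); blocked = true; }
  } else if (dy < 0) {
    double sw = (p.r - c.y[i]) / dy;
    if (sw < s) { s = std::max(0.0, sw); blocked = true; }
  }
  // contact truncation against every other mitochondrion (current positions)
  double two_r = 2.0 * p.r, two_r2 = two_r * two_r;
  int n = c.n();
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double qx = c.x[j] - c.x[i], qy = c.y[j] - c.y[i];
    double b = dx * qx + dy * qy;
    double c2 = qx * qx + qy * qy - two_r2;
    if (c2 <= 0.0) { // already touching/overlapping within float error
      if (b > 0.0) { s = 0.0; blocked = true; break; }
      continue;
    }
    if (b <= 0.0) continue; // moving away
    double disc = b * b - c2;
    if (disc < 0.0) continue; // ray misses the disk
    double sc = b - std::sqrt(disc);
    if (sc < s) { s = sc; blocked = true; }
  }
  c.x[i] += s * dx;
  c.y[i] += s * dy;
  // clamp against accumulated floating error
  c.x[i] = std::min(std::max(c.x[i], p.r), p.L - p.r);
  c.y[i] = std::min(std::max(c.y[i], p.r), p.L - p.r);
  if (blocked || s < step) c.motion[i] = 0;
}

static void do_transport(Cell& c, const Pars& p) {
  double pon = 1.0 - std::exp(-p.k_on * p.dt);
  double poff = 1.0 - std::exp(-p.k_off * p.dt);
  int n = c.n();
  std::vector<int> movers;
  for (int i = 0; i < n; ++i) {
    c.moved[i] = 0;
    if (c.deg[i] > 0) { c.motion[i] = 0; continue; } // fused: never moves
    if (c.motion[i] == 0) {
      if (pon > 0.0 && unif_rand() < pon) {
        c.motion[i] = 1;
        c.theta[i] = unif_rand() * 2.0 * M_PI;
      }
    } else {
      if (poff > 0.0 && unif_rand() < poff) c.motion[i] = 0;
    }
    if (c.motion[i] == 1) {
      c.moved[i] = 1; // in motion during this sub-step
      movers.push_back(i);
    }
  }
  // random order: earlier movers are obstacles for later ones
  for (int k = (int)movers.size() - 1; k > 0; --k) {
    int j = (int)(unif_rand() * (k + 1));
    if (j > k) j = k;
    std::swap(movers[k], movers[j]);
  }
  for (size_t m = 0; m < movers.size(); ++m) advance_one(c, movers[m], p);
}

// all unordered pairs with center distance <= 2r + tol (O(n^2) pair scan),
// annotated with the motility class from the transport sub-step just
// completed (fused network members are never in motion)
// class codes: 0 = both moving, 1 = one moving, 2 = neither moving
static void find_contacts(const Cell& c, const Pars& p,
                          std::vector<std::pair<int, int> >& pairs,
                          std::vector<int>& cls) {
  pairs.clear();
  cls.clear();
  int n = c.n();
  double cut = 2.0 * p.r + p.tol, cut2 = cut * cut;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double qx = c.x[j] - c.x[i], qy = c.y[j] - c.y[i];
      if (qx * qx + qy * qy <= cut2) {
        pairs.push_back(std::make_pair(i, j));
        cls.push_back(2 - c.moved[i] - c.moved[j]);
      }
    }
  }
}

static void do_fusion(Cell& c, const Pars& p,
                      const std::vector<std::pair<int, int> >& pairs,
                      const std::vector<int>& cls, EventLog* log) {
  double pbase = 1.0 - std::exp(-p.k_fus * p.dt);
  if (pbase <= 0.0) return;
  std::set<std::pair<int, int> > bonded(c.bonds.begin(), c.bonds.end());
  for (size_t k = 0; k < pairs.size(); ++k) {
    int i = pairs[k].first, j = pairs[k].second;
    if (bonded.count(std::make_pair(i, j))) continue;
    if (c.health(i) < p.h_fus || c.health(j) < p.h_fus) continue;
    double scale = cls[k] == 0 ? 1.0 : (cls[k] == 1 ? p.alpha : p.beta);
    if (scale <= 0.0) continue;
    if (unif_rand() < scale * pbase) {
      c.bonds.push_back(std::make_pair(i, j));
      bonded.insert(std::make_pair(i, j));
      c.deg[i]++; c.deg[j]++;
      c.motion[i] = 0; c.motion[j] = 0;
      if (log) log->add(c.time, EV_FUSION, c.id[i], c.id[j], (double)cls[k]);
    }
  }
}

// swap n randomly chosen unit states between mitochondria i and j
static void exchange_units_core(Cell& c, int i, int j, int n_ex) {
  int N = c.nHU;
  std::vector<int> ia(N), ib(N);
  for (int u = 0; u < N; ++u) { ia[u] = u; ib[u] = u; }
  for (int k = 0; k < n_ex; ++k) {
    int ra = k + (int)(unif_rand() * (N - k));
    if (ra >= N) ra = N - 1;
    std::swap(ia[k], ia[ra]);
  }
  for (int k = 0; k < n_ex; ++k) {
    int rb = k + (int)(unif_rand() * (N - k));
    if (rb >= N) rb = N - 1;
    std::swap(ib[k], ib[rb]);
  }
  for (int k = 0; k < n_ex; ++k) {
    size_t ka = (size_t)i * N + ia[k], kb = (size_t)j * N + ib[k];
    std::swap(c.hu[ka], c.hu[kb]);
  }
}

static void do_fission(Cell& c, const Pars& p, EventLog* log) {
  double prob = 1.0 - std::exp(-p.k_fis * p.dt);
  if (prob <= 0.0 || c.bonds.empty()) return;
  std::vector<char> broken(c.bonds.size(), 0);
  for (size_t b = 0; b < c.bonds.size(); ++b) {
    if (unif_rand() < prob) {
      int i = c.bonds[b].first, j = c.bonds[b].second;
      double hi = c.health(i), hj = c.health(j);
      exchange_units_core(c, i, j, p.n_exchange);
      broken[b] = 1;
      if (log)
        log->add(c.time, EV_FISSION, c.id[i], c.id[j], hi, hj, c.health(i),
                 c.health(j));
    }
  }
  std::vector<std::pair<int, int> > keep;
  keep.reserve(c.bonds.size());
  for (size_t b = 0; b < c.bonds.size(); ++b) {
    if (broken[b]) {
      c.deg[c.bonds[b].first]--;
      c.deg[c.bonds[b].second]--;
    } else {
      keep.push_back(c.bonds[b]);
    }
  }
  c.bonds.swap(keep);
  // fission products with no remaining bonds are independent and unbound
}

static bool window_allows_core(const std::vector<double>& times, double cap,
                               double now) {
  if (!R_finite(cap)) return true;
  if (cap <= 0) return false;
  int count = 0;
  for (size_t k = times.size(); k-- > 0;) {
    if (times[k] <= now - WINDOW_MIN) break; // sorted ascending
    if (times[k] <= now) ++count;
  }
  return count < cap;
}

static void remove_at(Cell& c, int i) {
  int last = c.n() - 1;
  if (i != last) {
    c.x[i] = c.x[last]; c.y[i] = c.y[last];
    c.theta[i] = c.theta[last];
    c.id[i] = c.id[last];
    c.motion[i] = c.motion[last];
    c.moved[i] = c.moved[last];
    c.deg[i] = c.deg[last];
    for (int u = 0; u < c.nHU; ++u)
      c.hu[(size_t)i * c.nHU + u] = c.hu[(size_t)last * c.nHU + u];
    for (size_t b = 0; b < c.bonds.size(); ++b) {
      if (c.bonds[b].first == last) c.bonds[b].first = i;
      if (c.bonds[b].second == last) c.bonds[b].second = i;
      if (c.bonds[b].first > c.bonds[b].second)
        std::swap(c.bonds[b].first, c.bonds[b].second);
    }
  }
  c.x.pop_back(); c.y.pop_back(); c.theta.pop_back();
  c.id.pop_back(); c.motion.pop_back(); c.moved.pop_back(); c.deg.pop_back();
  c.hu.resize((size_t)(c.n()) * c.nHU);
}

static void do_autophagy(Cell& c, const Pars& p, EventLog* log) {
  double prob = 1.0 - std::exp(-p.k_aut * p.dt);
  if (prob <= 0.0) return;
  std::vector<int> marked;
  int n = c.n();
  for (int i = 0; i < n; ++i) {
    if (c.deg[i] > 0) continue;              // fused: protected
    double h = c.health(i);
    if (h >= p.h_aut) continue;              // strictly below the threshold
    if (!window_allows_core(c.aut_times, p.cap_aut, c.time)) continue;
    if (unif_rand() < prob) {
      marked.push_back(i);
      c.aut_times.push_back(c.time);
      c.cum_aut++;
      if (log) log->add(c.time, EV_AUTOPHAGY, c.id[i], NA_INTEGER, h);
    }
  }
  for (size_t k = marked.size(); k-- > 0;) remove_at(c, marked[k]);
}

static double replication_g(double N, const Pars& p) {
  double z = (N - p.N0) / p.sigma_N;
  if (z > 700.0) return 0.0;
  return 1.0 / (1.0 + std::exp(z));
}

static void do_replicate(Cell& c, const Pars& p, EventLog* log) {
  int N = c.n();
  if (N == 0) return;
  double rate = N * p.k_rep * replication_g((double)N, p);
  double prob = 1.0 - std::exp(-rate * p.dt);
  if (prob <= 0.0) return;
  if (!window_allows_core(c.rep_times, p.cap_rep, c.time)) return;
  if (unif_rand() >= prob) return;
  int prog = (int)(unif_rand() * N);
  if (prog >= N) prog = N - 1;
  double two_r2 = 4.0 * p.r * p.r;
  // near-jammed cells reject almost every candidate; a modest budget keeps
  // the step cost bounded (the event is skipped and logged on failure)
  int budget = std::min(p.max_place_attempts, 200);
  for (int attempt = 0; attempt < budget; ++attempt) {
    double px = p.r + unif_rand() * (p.L - 2.0 * p.r);
    double py = p.r + unif_rand() * (p.L - 2.0 * p.r);
    bool ok = true;
    for (int j = 0; j < N; ++j) {
      double qx = c.x[j] - px, qy = c.y[j] - py;
      if (qx * qx + qy * qy < two_r2) { ok = false; break; }
    }
    if (ok) {
      c.x.push_back(px); c.y.push_back(py); c.theta.push_back(0.0);
      c.id.push_back(c.next_id);
      c.motion.push_back(0); c.moved.push_back(0); c.deg.push_back(0);
      for (int u = 0; u < c.nHU; ++u)
        c.hu.push_back(c.hu[(size_t)prog * c.nHU + u]);
      c.rep_times.push_back(c.time);
      c.cum_rep++;
      if (log)
        log->add(c.time, EV_REPLICATION, c.id[prog], c.next_id,
                 c.health(prog));
      c.next_id++;
      return;
    }
  }
  if (log)
    log->add(c.time, EV_REPLICATION_BLOCKED, c.id[prog], NA_INTEGER,
             c.health(prog));
}

static void do_step(Cell& c, const Pars& p, EventLog* log) {
  do_damage(c, p, log);
  do_transport(c, p);
  std::vector<std::pair<int, int> > pairs;
  std::vector<int> cls;
  find_contacts(c, p, pairs, cls);
  do_fusion(c, p, pairs, cls, log);
  do_fission(c, p, log);
  do_autophagy(c, p, log);
  do_replicate(c, p, log);
  c.time += p.dt;
}

// ---------------------------------------------------------------------------
// exported sub-step wrappers (used by the R-level module functions)

// [[Rcpp::export]]
List cpp_damage_step(List state, List params) {
  Cell c = cell_from_list(state);
  Pars p = pars_from_list(params);
  EventLog e;
  do_damage(c, p, &e);
  return List::create(_["state"] = cell_to_list(c),
                      _["events"] = events_to_df(e));
}

// [[Rcpp::export]]
List cpp_transport_step(List state, List params) {
  Cell c = cell_from_list(state);
  Pars p = pars_from_list(params);
  do_transport(c, p);
  return cell_to_list(c);
}

// [[Rcpp::export]]
DataFrame cpp_contacts(List state, List params) {
  Cell c = cell_from_list(state);
  Pars p = pars_from_list(params);
  std::vector<std::pair<int, int> > pairs;
  std::vector<int> cls;
  find_contacts(c, p, pairs, cls);
  IntegerVector i1(pairs.size()), i2(pairs.size()), cl(pairs.size());
  for (size_t k = 0; k < pairs.size(); ++k) {
    i1[k] = c.id[pairs[k].first];
    i2[k] = c.id[pairs[k].second];
    cl[k] = cls[k];
  }
  return DataFrame::create(_["id1"] = i1, _["id2"] = i2, _["class"] = cl);
}

// [[Rcpp::export]]
List cpp_fusion_step(List state, List params, IntegerVector pair_id1,
                     IntegerVector pair_id2, IntegerVector pair_class) {
  Cell c = cell_from_list(state);
  Pars p = pars_from_list(params);
  std::unordered_map<int, int> idx;
  for (int i = 0; i < c.n(); ++i) idx[c.id[i]] = i;
  std::vector<std::pair<int, int> > pairs;
  std::vector<int> cls;
  for (int k = 0; k < pair_id1.size(); ++k) {
    std::unordered_map<int, int>::iterator a = idx.find(pair_id1[k]);
    std::unordered_map<int, int>::iterator b = idx.find(pair_id2[k]);
    if (a == idx.end() || b == idx.end())
      stop("contact pair references unknown mitochondrion id");
    int i = a->second, j = b->second;
    if (i > j) std::swap(i, j);
    pairs.push_back(std::make_pair(i, j));
    cls.push_back(pair_class[k]);
  }
  EventLog e;
  do_fusion(c, p, pairs, cls, &e);
  return List::create(_["state"] = cell_to_list(c),
                      _["events"] = events_to_df(e));
}

// [[Rcpp::export]]
List cpp_fission_step(List state, List params) {
  Cell c = cell_from_list(state);
  Pars p = pars_from_list(params);
  EventLog e;
  do_fission(c, p, &e);
  return List::create(_["state"] = cell_to_list(c),
                      _["events"] = events_to_df(e));
}

// [[Rcpp::export]]
List cpp_autophagy_step(List state, List params) {
  Cell c = cell_from_list(state);
  Pars p = pars_from_list(params);
  EventLog e;
  do_autophagy(c, p, &e);
  return List::create(_["state"] = cell_to_list(c),
                      _["events"] = events_to_df(e));
}

// [[Rcpp::export]]
List cpp_replicate_step(List state, List params) {
  Cell c = cell_from_list(state);
  Pars p = pars_from_list(params);
  EventLog e;
  do_replicate(c, p, &e);
  return List::create(_["state"] = cell_to_list(c),
                      _["events"] = events_to_df(e));
}

// [[Rcpp::export]]
List cpp_step(List state, List params) {
  Cell c = cell_from_list(state);
  Pars p = pars_from_list(params);
  EventLog e;
  do_step(c, p, &e);
  return List::create(_["state"] = cell_to_list(c),
                      _["events"] = events_to_df(e));
}

// [[Rcpp::export]]
List cpp_exchange_units(IntegerVector a, IntegerVector b, int n_ex) {
  int N = a.size();
  Cell c;
  c.nHU = N;
  c.x.assign(2, 0.0); c.y.assign(2, 0.0); c.theta.assign(2, 0.0);
  c.id.assign(2, 0); c.motion.assign(2, 0); c.moved.assign(2, 0);
  c.deg.assign(2, 0);
  c.hu.resize(2 * (size_t)N);
  for (int u = 0; u < N; ++u) { c.hu[u] = a[u]; c.hu[N + u] = b[u]; }
  exchange_units_core(c, 0, 1, n_ex);
  IntegerVector a2(N), b2(N);
  for (int u = 0; u < N; ++u) { a2[u] = c.hu[u]; b2[u] = c.hu[N + u]; }
  return List::create(_["a"] = a2, _["b"] = b2);
}

// [[Rcpp::export]]
double cpp_replication_g(double N, double N0, double sigma_N) {
  Pars p;
  p.N0 = N0;
  p.sigma_N = sigma_N;
  return replication_g(N, p);
}

// [[Rcpp::export]]
bool cpp_window_allows(NumericVector times, double cap, double now) {
  std::vector<double> t = as<std::vector<double> >(times);
  return window_allows_core(t, cap, now);
}

// ---------------------------------------------------------------------------
// placement

// [[Rcpp::export]]
NumericMatrix cpp_place(int n, double L, double r, int max_attempts) {
  NumericMatrix pos(n, 2);
  double two_r2 = 4.0 * r * r;
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int attempt = 0; attempt < max_attempts; ++attempt) {
      double px = r + unif_rand() * (L - 2.0 * r);
      double py = r + unif_rand() * (L - 2.0 * r);
      bool ok = true;
      for (int j = 0; j < i; ++j) {
        double qx = pos(j, 0) - px, qy = pos(j, 1) - py;
        if (qx * qx + qy * qy < two_r2) { ok = false; break; }
      }
      if (ok) {
        pos(i, 0) = px;
        pos(i, 1) = py;
        placed = true;
        break;
      }
    }
    if (!placed) {
      double phi = n * M_PI * r * r / (L * L);
      stop("infeasible packing: could not place mitochondrion %d of %d "
           "(filling fraction %.3f) within the attempt budget",
           i + 1, n, phi);
    }
  }
  colnames(pos) = CharacterVector::create("x", "y");
  return pos;
}

// ---------------------------------------------------------------------------
// full run loop (identical sub-step composition and RNG order as cpp_step)

// [[Rcpp::export]]
List cpp_run_cell(List state, List params, int n_steps, int record_every,
                  bool log_events) {
  Cell c = cell_from_list(state);
  Pars p = pars_from_list(params);
  EventLog e;
  EventLog* log = log_events ? &e : 0;

  std::vector<double> rec_time;
  std::vector<int> rec_n, rec_bonds, rec_aut, rec_rep;
  std::vector<double> healths;
  std::vector<int> offsets; // start index (0-based) of each sample's healths

  // record a sample (including the initial state)
  struct Rec {
    static void take(const Cell& c, std::vector<double>& rec_time,
                     std::vector<int>& rec_n, std::vector<int>& rec_bonds,
                     std::vector<int>& rec_aut, std::vector<int>& rec_rep,
                     std::vector<double>& healths, std::vector<int>& offsets) {
      rec_time.push_back(c.time);
      rec_n.push_back(c.n());
      rec_bonds.push_back((int)c.bonds.size());
      rec_aut.push_back(c.cum_aut);
      rec_rep.push_back(c.cum_rep);
      offsets.push_back((int)healths.size());
      for (int i = 0; i < c.n(); ++i) healths.push_back(c.health(i));
    }
  };

  Rec::take(c, rec_time, rec_n, rec_bonds, rec_aut, rec_rep, healths, offsets);
  for (int s = 1; s <= n_steps; ++s) {
    do_step(c, p, log);
    if (record_every > 0 && (s % record_every == 0 || s == n_steps)) {
      if (rec_time.empty() || rec_time.back() != c.time)
        Rec::take(c, rec_time, rec_n, rec_bonds, rec_aut, rec_rep, healths,
                  offsets);
    }
    if (s % 512 == 0) Rcpp::checkUserInterrupt();
  }
  offsets.push_back((int)healths.size()); // sentinel

  return List::create(
      _["state"] = cell_to_list(c), _["events"] = events_to_df(e),
      _["rec_time"] = wrap(rec_time), _["rec_n"] = wrap(rec_n),
      _["rec_bonds"] = wrap(rec_bonds), _["rec_cum_aut"] = wrap(rec_aut),
      _["rec_cum_rep"] = wrap(rec_rep), _["healths"] = wrap(healths),
      _["offsets"] = wrap(offsets));
}
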