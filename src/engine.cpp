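// Discrete-time stochastic engine for CTL surveillance of a 2-D tissue.
//
// The tissue is a toroidal lattice of immobile cells (non-susceptible,
// susceptible, infected, dead). CTL and virions are off-lattice agents with
// floating-point positions, coarse-grained to 1 um for contact detection.
// All randomness is drawn from R's RNG so that set.seed() in R makes whole
// runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

const int ST_NONSUSC = 0, ST_SUSC = 1, ST_INF = 2, ST_DEAD = 3;
const int CTL_SEARCH = 0, CTL_SCAN = 1, CTL_CONJ = 2;
const int MAX_CONTACT = 32;
const double TWO_PI = 6.283185307179586;
const double DEG = 0.017453292519943295;

struct Ctl {
  double x, y, heading, rem;   // position um, heading rad, segment left um
  int st;                      // behavioural state
  double elapsed;              // seconds in current scanning/conjugated spell
  int engaged;                 // lattice site index or -1
  int prev[MAX_CONTACT];       // contact set at last check while searching
  int nprev;
  double cgx_last, cgy_last;   // coarse-grained position at last check
  double scans, kills;
};

struct Virion { double x, y, heading; };

struct Engine {
  // geometry
  int nr, nc, N;
  double d, ex, ey;            // cell diameter, extents (um)
  // timing
  double dt;                   // seconds per step
  double clock_min;
  long sample_every_steps;
  // event probabilities per step
  double p_cyto, p_diffuse, p_clear, p_prod;
  double vir_step;             // um per step
  // CTL parameters
  double ctl_v, scan_s, handling_s, persist, chemo, contact;
  bool discrete_turn, conj_produce;
  int mode;                    // 0 diffuse, 1 clustered

  std::vector<int> state;
  std::vector<int> susc, suscPos, inf, infPos;
  std::vector<double> inf_since;
  std::vector<int> firstCtl, nAttach;
  int nConjSites;              // infected sites with at least one CTL bound
  std::vector<Ctl> ctls;
  std::vector<Virion> virions;
  std::vector<int> ord;        // per-step CTL update order

  // samples
  std::vector<double> s_t;
  std::vector<double> s_susc, s_inf, s_dead, s_free, s_conj, s_vir;

  double wrapx(double v) const { v -= ex * std::floor(v / ex); return v >= ex ? 0.0 : v; }
  double wrapy(double v) const { v -= ey * std::floor(v / ey); return v >= ey ? 0.0 : v; }
  static double mindiff(double a, double e) {
    a -= e * std::nearbyint(a / e);
    return a;
  }
  int siteOf(double x, double y) const {
    int col = (int)(x / d); if (col >= nc) col = nc - 1; if (col < 0) col = 0;
    int row = (int)(y / d); if (row >= nr) row = nr - 1; if (row < 0) row = 0;
    return row * nc + col;
  }
  double centerX(int s) const { return (s % nc + 0.5) * d; }
  double centerY(int s) const { return (s / nc + 0.5) * d; }

  static void removeFrom(std::vector<int>& lst, std::vector<int>& pos, int site) {
    int p = pos[site], last = lst.back();
    lst[p] = last; pos[last] = p; lst.pop_back(); pos[site] = -1;
  }
  static void addTo(std::vector<int>& lst, std::vector<int>& pos, int site) {
    pos[site] = (int)lst.size(); lst.push_back(site);
  }

  void infect(int s) {
    state[s] = ST_INF;
    removeFrom(susc, suscPos, s);
    addTo(inf, infPos, s);
    inf_since[s] = clock_min;
  }

  // site leaves the infected pool (CTL lysis or cytopathic death);
  // all conjugated CTL are released with a fresh turn event
  void killSite(int s) {
    state[s] = ST_DEAD;
    ++deadCount;
    removeFrom(inf, infPos, s);
    if (nAttach[s] > 0) {
      --nConjSites;
      for (size_t i = 0; i < ctls.size(); ++i) {
        Ctl& c = ctls[i];
        if (c.st == CTL_CONJ && c.engaged == s) {
          c.st = CTL_SEARCH; c.engaged = -1; c.elapsed = 0.0;
          turnEvent(c);
        }
      }
    }
    firstCtl[s] = -1; nAttach[s] = 0;
  }

  // directed turns head at the nearest living infected cell (conjugated or
  // not); ties broken on the smaller (row, col), i.e. smaller site index
  void turnEvent(Ctl& c) {
    bool directed = false;
    if (chemo > 0 && !inf.empty() && unif_rand() < chemo) {
      double best = 1e300; int bs = -1;
      for (size_t j = 0; j < inf.size(); ++j) {
        int s = inf[j];
        double dx = mindiff(centerX(s) - c.x, ex);
        double dy = mindiff(centerY(s) - c.y, ey);
        double dd = dx * dx + dy * dy;
        if (dd < best || (dd == best && s < bs)) { best = dd; bs = s; }
      }
      if (bs >= 0) {
        double dx = mindiff(centerX(bs) - c.x, ex);
        double dy = mindiff(centerY(bs) - c.y, ey);
        if (dx != 0.0 || dy != 0.0) { c.heading = std::atan2(dy, dx); directed = true; }
      }
    }
    if (!directed) {
      double turn = discrete_turn ? (unif_rand() < 0.5 ? -45.0 : 45.0)
                                  : (unif_rand() * 90.0 - 45.0);
      c.heading += turn * DEG;
    }
    c.rem = persist;
  }

  // Contact detection: position coarse-grained to the nearest 1 um; every
  // living site whose centre lies within contact_radius is "in contact".
  // A scan or conjugation is triggered only by sites newly entering the set.
  bool contactCheck(Ctl& c) {
    double cgx = wrapx(std::nearbyint(c.x));
    double cgy = wrapy(std::nearbyint(c.y));
    c.cgx_last = cgx; c.cgy_last = cgy;
    int col0 = (int)(cgx / d); if (col0 >= nc) col0 = nc - 1;
    int row0 = (int)(cgy / d); if (row0 >= nr) row0 = nr - 1;
    int range = (int)(contact / d) + 1;
    int cur[MAX_CONTACT]; double curD[MAX_CONTACT]; int ncur = 0;
    double c2 = contact * contact;
    for (int dr = -range; dr <= range; ++dr) {
      for (int dc = -range; dc <= range; ++dc) {
        int row = ((row0 + dr) % nr + nr) % nr;
        int col = ((col0 + dc) % nc + nc) % nc;
        int s = row * nc + col;
        if (state[s] == ST_DEAD) continue;
        bool dup = false;
        for (int j = 0; j < ncur; ++j) if (cur[j] == s) { dup = true; break; }
        if (dup) continue;
        double dx = mindiff(centerX(s) - cgx, ex);
        double dy = mindiff(centerY(s) - cgy, ey);
        double dd = dx * dx + dy * dy;
        if (dd <= c2 && ncur < MAX_CONTACT) { cur[ncur] = s; curD[ncur] = dd; ++ncur; }
      }
    }
    int bestInf = -1, bestLiv = -1; double dInf = 1e300, dLiv = 1e300;
    for (int j = 0; j < ncur; ++j) {
      int s = cur[j];
      bool seen = false;
      for (int q = 0; q < c.nprev; ++q) if (c.prev[q] == s) { seen = true; break; }
      if (seen) continue;
      if (state[s] == ST_INF) {
        if (curD[j] < dInf || (curD[j] == dInf && s < bestInf)) { dInf = curD[j]; bestInf = s; }
      } else {
        if (curD[j] < dLiv || (curD[j] == dLiv && s < bestLiv)) { dLiv = curD[j]; bestLiv = s; }
      }
    }
    for (int j = 0; j < ncur; ++j) c.prev[j] = cur[j];
    c.nprev = ncur;
    if (bestInf >= 0) {
      c.st = CTL_CONJ; c.engaged = bestInf; c.elapsed = 0.0;
      if (nAttach[bestInf] == 0) ++nConjSites;
      ++nAttach[bestInf];
      if (firstCtl[bestInf] < 0) firstCtl[bestInf] = (int)(&c - &ctls[0]);
      return true;
    }
    if (bestLiv >= 0) {
      c.st = CTL_SCAN; c.engaged = bestLiv; c.elapsed = 0.0;
      c.scans += 1;
      return true;
    }
    return false;
  }

  // fill the contact set without triggering scanning/conjugation; used at
  // CTL placement so that landing on a cell does not count as surveying it
  void preloadContacts(Ctl& c) {
    double cgx = wrapx(std::nearbyint(c.x));
    double cgy = wrapy(std::nearbyint(c.y));
    c.cgx_last = cgx; c.cgy_last = cgy;
    int col0 = (int)(cgx / d); if (col0 >= nc) col0 = nc - 1;
    int row0 = (int)(cgy / d); if (row0 >= nr) row0 = nr - 1;
    int range = (int)(contact / d) + 1;
    double c2 = contact * contact;
    c.nprev = 0;
    for (int dr = -range; dr <= range; ++dr) {
      for (int dc = -range; dc <= range; ++dc) {
        int row = ((row0 + dr) % nr + nr) % nr;
        int col = ((col0 + dc) % nc + nc) % nc;
        int s = row * nc + col;
        if (state[s] == ST_DEAD) continue;
        bool dup = false;
        for (int j = 0; j < c.nprev; ++j) if (c.prev[j] == s) { dup = true; break; }
        if (dup) continue;
        double dx = mindiff(centerX(s) - cgx, ex);
        double dy = mindiff(centerY(s) - cgy, ey);
        if (dx * dx + dy * dy <= c2 && c.nprev < MAX_CONTACT) c.prev[c.nprev++] = s;
      }
    }
  }

  void updateCtl(int i) {
    Ctl& c = ctls[i];
    double budget = dt;
    int guard = 0;
    while (budget > 1e-9 && ++guard < 10000) {
      if (c.st == CTL_SEARCH) {
        double vps = ctl_v / 60.0;
        if (vps <= 0) break;
        double dmove = vps * budget;
        bool segEnd = false;
        if (dmove >= c.rem) { dmove = c.rem; segEnd = true; }
        double tused = dmove / vps;
        c.x = wrapx(c.x + std::cos(c.heading) * dmove);
        c.y = wrapy(c.y + std::sin(c.heading) * dmove);
        c.rem -= dmove;
        budget -= tused;
        // the contact set can only change when the coarse-grained (1 um)
        // position moves; skip the neighbourhood scan otherwise
        bool changed = false;
        if (wrapx(std::nearbyint(c.x)) != c.cgx_last ||
            wrapy(std::nearbyint(c.y)) != c.cgy_last)
          changed = contactCheck(c);
        if (!changed && segEnd) turnEvent(c);
      } else if (c.st == CTL_SCAN) {
        double need = scan_s - c.elapsed;
        double use = need < budget ? need : budget;
        c.elapsed += use; budget -= use;
        if (c.elapsed >= scan_s - 1e-9) {
          c.st = CTL_SEARCH; c.engaged = -1; c.elapsed = 0.0;
          turnEvent(c);
        }
      } else {  // conjugated: only the first-attached CTL's clock kills
        int s = c.engaged;
        if (firstCtl[s] == i) {
          double need = handling_s - c.elapsed;
          double use = need < budget ? need : budget;
          c.elapsed += use; budget -= use;
          if (c.elapsed >= handling_s - 1e-9) {
            c.kills += 1;
            killSite(s);  // releases this CTL (state -> SEARCH) and others
          }
        } else {
          c.elapsed += budget; budget = 0.0;
        }
      }
    }
  }

  void virionPhase() {
    size_t i = 0;
    while (i < virions.size()) {
      if (p_clear > 0 && unif_rand() < p_clear) {
        virions[i] = virions.back(); virions.pop_back(); continue;
      }
      Virion& v = virions[i];
      v.x = wrapx(v.x + std::cos(v.heading) * vir_step);
      v.y = wrapy(v.y + std::sin(v.heading) * vir_step);
      int s = siteOf(v.x, v.y);
      if (state[s] == ST_SUSC) {
        infect(s);
        virions[i] = virions.back(); virions.pop_back(); continue;
      }
      ++i;
    }
  }

  // pick a uniformly random infected site that may act (conjugated sites
  // are excluded when conj_produce is off); -1 if none qualifies
  int randomActiveInfected() {
    if (inf.empty()) return -1;
    if (conj_produce || nConjSites == 0) {
      int j = (int)(unif_rand() * inf.size());
      if (j >= (int)inf.size()) j = (int)inf.size() - 1;
      return inf[j];
    }
    if (nConjSites >= (int)inf.size()) return -1;
    for (int tries = 0; tries < 1000; ++tries) {
      int j = (int)(unif_rand() * inf.size());
      if (j >= (int)inf.size()) j = (int)inf.size() - 1;
      if (nAttach[inf[j]] == 0) return inf[j];
    }
    for (size_t j = 0; j < inf.size(); ++j)
      if (nAttach[inf[j]] == 0) return inf[j];
    return -1;
  }

  // Per-cell events are independent Bernoulli trials with small per-step
  // probabilities; the number of events per step is drawn as a binomial
  // and assigned to uniformly chosen cells, avoiding one RNG draw per cell
  // per step.
  void infectedPhase() {
    int nInf = (int)inf.size();
    if (nInf == 0) return;
    if (mode == 1 && p_prod > 0) {
      int nActive = conj_produce ? nInf : nInf - nConjSites;
      if (nActive > 0) {
        int nv = (int)R::rbinom((double)nActive, p_prod);
        for (int j = 0; j < nv; ++j) {
          int s = randomActiveInfected();
          if (s < 0) break;
          Virion v; v.x = centerX(s); v.y = centerY(s);
          v.heading = unif_rand() * TWO_PI;
          virions.push_back(v);
        }
      }
    }
    if (p_cyto > 0) {
      int ndie = (int)R::rbinom((double)inf.size(), p_cyto);
      for (int j = 0; j < ndie && !inf.empty(); ++j) {
        int idx = (int)(unif_rand() * inf.size());
        if (idx >= (int)inf.size()) idx = (int)inf.size() - 1;
        killSite(inf[idx]);
      }
    }
    if (mode == 0 && p_diffuse > 0 && !susc.empty()) {
      int nActive = conj_produce ? (int)inf.size() : (int)inf.size() - nConjSites;
      if (nActive > 0) {
        int nNew = (int)R::rbinom((double)nActive, p_diffuse);
        for (int j = 0; j < nNew && !susc.empty(); ++j) {
          int t = (int)(unif_rand() * susc.size());
          if (t >= (int)susc.size()) t = (int)susc.size() - 1;
          infect(susc[t]);
        }
      }
    }
  }

  void ctlPhase() {
    int n = (int)ctls.size();
    for (int i = n - 1; i > 0; --i) {   // Fisher-Yates reshuffle each step
      int j = (int)(unif_rand() * (i + 1)); if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    for (int i = 0; i < n; ++i) updateCtl(ord[i]);
  }

  void record() {
    int nfree = 0, nconj = 0;
    for (size_t i = 0; i < ctls.size(); ++i)
      (ctls[i].st == CTL_CONJ ? nconj : nfree)++;
    s_t.push_back(clock_min);
    s_susc.push_back((double)susc.size());
    s_inf.push_back((double)inf.size());
    s_dead.push_back((double)deadCount);
    s_free.push_back((double)nfree);
    s_conj.push_back((double)nconj);
    s_vir.push_back((double)virions.size());
  }
  int deadCount;
};

}  // namespace

// [[Rcpp::export]]
List abm_run_cpp(List cfg) {
  Engine E;
  E.nr = as<int>(cfg["n_rows"]); E.nc = as<int>(cfg["n_cols"]);
  E.N = E.nr * E.nc;
  E.d = as<double>(cfg["cell_d"]);
  E.ex = E.nc * E.d; E.ey = E.nr * E.d;
  E.dt = as<double>(cfg["dt_s"]);
  double dt_min = E.dt / 60.0;
  E.mode = as<int>(cfg["mode"]);
  E.p_cyto = 1.0 - std::exp(-as<double>(cfg["cyto_per_min"]) * dt_min);
  E.p_diffuse = 1.0 - std::exp(-as<double>(cfg["diffuse_per_min"]) * dt_min);
  E.p_clear = 1.0 - std::exp(-as<double>(cfg["clear_per_min"]) * dt_min);
  E.p_prod = 1.0 - std::exp(-as<double>(cfg["prod_per_min"]) * dt_min);
  E.vir_step = as<double>(cfg["vir_speed_um_min"]) * dt_min;
  E.ctl_v = as<double>(cfg["ctl_v_um_min"]);
  E.scan_s = as<double>(cfg["scan_s"]);
  E.handling_s = as<double>(cfg["handling_min"]) * 60.0;
  E.persist = as<double>(cfg["persist_um"]);
  E.chemo = as<double>(cfg["chemo_p"]);
  E.contact = as<double>(cfg["contact_um"]);
  E.discrete_turn = as<int>(cfg["discrete_turn"]) != 0;
  E.conj_produce = as<int>(cfg["conj_produce"]) != 0;
  double sat_frac = as<double>(cfg["saturation_frac"]);
  double t_max_min = as<double>(cfg["t_max_min"]);
  double t_grow_max_min = as<double>(cfg["t_grow_max_min"]);
  double sample_every_min = as<double>(cfg["sample_every_min"]);
  int I_C = as<int>(cfg["I_C"]);
  int n_ctl = as<int>(cfg["n_ctl"]);
  int substrate = as<int>(cfg["substrate"]);  // 1 susceptible, 0 non-susceptible

  E.state.assign(E.N, substrate ? ST_SUSC : ST_NONSUSC);
  E.inf_since.assign(E.N, -1.0);
  E.firstCtl.assign(E.N, -1);
  E.nAttach.assign(E.N, 0);
  E.suscPos.assign(E.N, -1); E.infPos.assign(E.N, -1);
  if (substrate) {
    E.susc.reserve(E.N);
    for (int s = 0; s < E.N; ++s) Engine::addTo(E.susc, E.suscPos, s);
  }
  E.clock_min = 0.0; E.deadCount = 0; E.nConjSites = 0;

  long sample_every_steps = (long)std::lround(sample_every_min * 60.0 / E.dt);
  if (sample_every_steps < 1) sample_every_steps = 1;

  RNGScope rng;

  // --- initial infection -------------------------------------------------
  IntegerVector init_inf = cfg["init_infected_sites"];  // 0-based, may be empty
  int status = 0;  // 0 ok, 1 died out during growth, 2 growth timed out
  double t_intro = 0.0;
  long step = 0;

  if (init_inf.size() > 0) {
    for (int j = 0; j < init_inf.size(); ++j) {
      int s = init_inf[j];
      if (E.state[s] == ST_SUSC) E.infect(s);
      else { E.state[s] = ST_INF; Engine::addTo(E.inf, E.infPos, s); }
    }
  } else if (I_C > 0) {
    int s0 = (int)(unif_rand() * E.N); if (s0 >= E.N) s0 = E.N - 1;
    if (E.state[s0] == ST_SUSC) E.infect(s0);
    else { E.state[s0] = ST_INF; Engine::addTo(E.inf, E.infPos, s0); }
    E.record();
    while ((int)E.inf.size() < I_C) {
      E.virionPhase();
      E.infectedPhase();
      E.clock_min += dt_min; ++step;
      if (step % sample_every_steps == 0) E.record();
      if (E.inf.empty()) { status = 1; break; }
      if (E.clock_min > t_grow_max_min) { status = 2; break; }
      if (step % 100000 == 0) Rcpp::checkUserInterrupt();
    }
  }

  // --- CTL introduction and main loop ------------------------------------
  if (status == 0) {
    t_intro = E.clock_min;
    NumericMatrix ctl_xy = cfg["ctl_xy"];  // 0 rows -> random placement
    E.ctls.resize(n_ctl);
    for (int i = 0; i < n_ctl; ++i) {
      Ctl& c = E.ctls[i];
      if (ctl_xy.nrow() == n_ctl && n_ctl > 0) {
        c.x = E.wrapx(ctl_xy(i, 0)); c.y = E.wrapy(ctl_xy(i, 1));
      } else {
        c.x = unif_rand() * E.ex; c.y = unif_rand() * E.ey;
      }
      c.heading = unif_rand() * TWO_PI;
      c.rem = E.persist;
      c.st = CTL_SEARCH; c.elapsed = 0.0; c.engaged = -1;
      c.scans = 0.0; c.kills = 0.0;
      E.preloadContacts(c);
    }
    E.ord.resize(n_ctl);
    for (int i = 0; i < n_ctl; ++i) E.ord[i] = i;

    bool had_infection = !E.inf.empty();
    E.record();
    double t_end = t_intro + t_max_min;
    while (true) {
      E.virionPhase();
      E.infectedPhase();
      E.ctlPhase();
      E.clock_min += dt_min; ++step;
      if (step % sample_every_steps == 0) E.record();
      if (had_infection && E.inf.empty()) { E.record(); break; }
      // control has clearly failed once the cumulative epidemic (every site
      // ever infected: currently infected plus dead) covers sat_frac of the
      // tissue; stopping there keeps small lattices away from target-cell
      // burnout, which is not part of the modelled dynamics
      if (had_infection && substrate &&
          (double)(E.N - (int)E.susc.size()) >= sat_frac * E.N) { E.record(); break; }
      if (E.clock_min >= t_end - 1e-9) { E.record(); break; }
      if (step % 50000 == 0) Rcpp::checkUserInterrupt();
    }
  }

  int n_ctl_out = (int)E.ctls.size();
  NumericVector scans(n_ctl_out), kills(n_ctl_out);
  for (int i = 0; i < n_ctl_out; ++i) { scans[i] = E.ctls[i].scans; kills[i] = E.ctls[i].kills; }
  IntegerVector inf_sites(E.inf.begin(), E.inf.end());
  std::sort(inf_sites.begin(), inf_sites.end());

  return List::create(
    _["status"] = status,
    _["t_intro_min"] = t_intro,
    _["time_min"] = wrap(E.s_t),
    _["susceptible"] = wrap(E.s_susc),
    _["infected"] = wrap(E.s_inf),
    _["dead"] = wrap(E.s_dead),
    _["ctl_free"] = wrap(E.s_free),
    _["ctl_conjugated"] = wrap(E.s_conj),
    _["virions"] = wrap(E.s_vir),
    _["scans"] = scans,
    _["kills"] = kills,
    _["infected_sites"] = inf_sites,
    _["t_end_min"] = E.clock_min);
}

// Monte-Carlo estimate of the probability that a simple symmetric random
// walk on the d-dimensional cubic lattice returns to its origin within
// max_steps steps (a lower bound on the eventual-return probability).
// [[Rcpp::export]]
double polya_return_cpp(int dimension, int n_walks, int max_steps) {
  RNGScope rng;
  long returned = 0;
  std::vector<int> pos(dimension);
  int ndir = 2 * dimension;
  for (int w = 0; w < n_walks; ++w) {
    std::fill(pos.begin(), pos.end(), 0);
    for (int s = 0; s < max_steps; ++s) {
      int mv = (int)(unif_rand() * ndir); if (mv >= ndir) mv = ndir - 1;
      pos[mv >> 1] += (mv & 1) ? 1 : -1;
      bool origin = true;
      for (int k = 0; k < dimension; ++k) if (pos[k] != 0) { origin = false; break; }
      if (origin) { ++returned; break; }
    }
    if ((w & 8191) == 0) Rcpp::checkUserInterrupt();
  }
  return (double)returned / (double)n_walks;
}

// Age-structured conjugate model, first-order upwind with dt = dtau
// (exact age advection). Time in minutes; r, k per minute; T, C fractions.
// Conservation C_free + sum(m) = C0 holds to machine precision.
// [[Rcpp::export]]
List solve_extended_cpp(double r, double k, double h, double C0, double T0,
                        double dtau, double t_end, int sample_every) {
  int B = (int)std::lround(h / dtau);
  if (B < 1) stop("dtau must divide h with at least one age bin");
  std::vector<double> m(B, 0.0);
  double T = T0, Cf = C0;
  long n_steps = (long)std::ceil(t_end / dtau - 1e-9);
  std::vector<double> o_t, o_T, o_C, o_X;
  o_t.push_back(0.0); o_T.push_back(T); o_C.push_back(Cf); o_X.push_back(0.0);
  for (long s = 1; s <= n_steps; ++s) {
    double out = m[B - 1];
    for (int i = B - 1; i > 0; --i) m[i] = m[i - 1];
    // exact within-step integration of dT/dt = (r - k Cf) T at frozen Cf;
    // the bound mass k Cf int(T) keeps CTL conservation exact while
    // removing the first-order Euler bias at practical dtau
    double g = r - k * Cf;
    double grow = std::exp(g * dtau);
    double inflow = (std::abs(g) > 1e-14)
      ? k * Cf * T * (grow - 1.0) / g
      : k * Cf * T * dtau;
    double Tnew = T * grow;
    if (inflow > Cf) {  // handling-saturated far outside the model's domain
      inflow = Cf;
      Tnew = T * std::exp(r * dtau) - inflow;
    }
    T = Tnew;
    Cf += out - inflow;
    m[0] = inflow;
    if (T < 0) T = 0;
    if (Cf < 0) Cf = 0;
    if (s % sample_every == 0 || s == n_steps) {
      double tot = 0.0; for (int i = 0; i < B; ++i) tot += m[i];
      o_t.push_back(s * dtau); o_T.push_back(T); o_C.push_back(Cf); o_X.push_back(tot);
    }
    if (s % 1000000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["time_min"] = wrap(o_t), _["T"] = wrap(o_T),
                      _["C_free"] = wrap(o_C), _["conjugates"] = wrap(o_X));
}
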