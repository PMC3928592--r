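// Lymph node agent-based compartment.
//
// State lives in an external pointer so repeated stepping does not copy the
// agent registries. All randomness is drawn from R's RNG (unif_rand /
// norm_rand / R::rpois), so set.seed() in R makes whole simulations
// reproducible bit-for-bit.
//
// Geometry: truncated-cone mask over a cubic lattice, 10 um per site
// (about one T cell diameter); the wide base (z = 0) carries the efferent
// lymphatic (EL) exit sites, the mid-cone band carries the HEV entry sites.
// The per-site capacity is a parameter; mean steady-state occupancy is set
// by the target cell count and density.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// state codes
enum { ST_N = 0, ST_A = 1, ST_E = 2, ST_CM = 3, ST_EM = 4 };
// lineage codes
enum { L_CD4 = 0, L_CD8 = 1 };
// DC kinds
enum { DC_AG = 0, DC_LDC = 1 };

struct Pars {
  double dt;                 // s
  double bind_time_s, cm_bind_time_s;
  double priming_thr, effector_thr, em_thr, aicd_thr;
  bool aicd_enabled;
  double cd8_thr_scale, cd8_eff_scale, cd8_aicd_scale;
  double prob_em, prob_cm;
  double cm_eff;
  double lic_prob_per_min, lic_boost;
  double extra_recruitment;
  int div_act[2];            // CD4, CD8
  int div_cm;                // rounds for a re-activated CM program
  int div_eff[2];
  double div_slope;          // extra rounds per log2 of signal excess
  int div_max_extra;
  double cycle_s;
  double cognate_freq;
  double cm_refract_s;       // maturation delay before a new CM can rebind
  bool cd8_requires_ldc;
  double k_bind;
  double pmhc_sdlog;
  int dc_max_bound;
  double dc_lifespan_s;
  double p_move;
  int site_cap;
  double transit_s;
  double recruit_coeff;      // cells per (mm^-3 * s)
  double p_exit;
};

// Fast internal RNG for the per-agent loops (xoshiro256+, seeded once from
// R's RNG at core creation, so set.seed() still governs every draw).
struct FastRng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t x) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  int below(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

struct LnCore {
  // lattice
  int nx, ny, nz, nsites;
  std::vector<char> ok, el;       // in-cone mask, EL membership
  std::vector<int> hev;           // HEV site indices
  std::vector<unsigned char> occ; // T cells per site
  std::vector<int> dc_at;         // site -> dc index, -1 if none
  double f_el;
  // T cell registry (structure of arrays, freelist-recycled)
  std::vector<char> alive, lin, st, cog, mem_ok, from_cm;
  std::vector<int> site, bdc, divs, clone;
  std::vector<double> belapsed, sig, age, cyc;
  std::vector<int> freelist;
  std::vector<int> ids_buf;
  int n_alive;
  // DC registry
  std::vector<char> dalive, dkind;
  std::vector<int> dsite, dnbound;
  std::vector<double> dp1, dp2, dlife;
  int nd_alive;
  // bookkeeping
  long next_clone;
  bool tracing, signal_log_on;
  std::vector<int> exit_clone, exit_lin, exit_st;
  std::vector<int> ev_type, ev_id;       // signal log: 0 acc, 1 reset, 2 set
  std::vector<double> ev_amt;
  double cum_exit[2][5];
  double cum_recruit[2][5];
  Pars P;
  FastRng rng;

  int idx(int x, int y, int z) const { return x + nx * (y + ny * z); }
};

typedef XPtr<LnCore> LnPtr;

static void shuffle(std::vector<int>& v, FastRng& rng) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = rng.below(i + 1);
    std::swap(v[i], v[j]);
  }
}

static Pars make_pars(List p, double scale) {
  Pars P;
  double dt = as<double>(p["abm_dt"]);
  P.dt = dt;
  P.bind_time_s = as<double>(p["bind_time"]) * 60.0;
  P.cm_bind_time_s = as<double>(p["cm_bind_time"]) * 60.0;
  P.priming_thr = as<double>(p["priming_threshold"]);
  P.effector_thr = as<double>(p["effector_threshold"]);
  P.em_thr = as<double>(p["em_threshold"]);
  P.aicd_thr = as<double>(p["aicd_threshold"]);
  P.aicd_enabled = as<double>(p["aicd_enabled"]) != 0;
  P.cd8_thr_scale = as<double>(p["cd8_threshold_scale"]);
  P.cd8_eff_scale = as<double>(p["cd8_effector_scale"]);
  P.cd8_aicd_scale = as<double>(p["cd8_aicd_scale"]);
  P.prob_em = as<double>(p["prob_em"]);
  P.prob_cm = as<double>(p["prob_cm"]);
  P.cm_eff = as<double>(p["cm_signal_efficiency"]);
  P.lic_prob_per_min = as<double>(p["dc_licensing_prob"]);
  P.lic_boost = as<double>(p["licensing_boost"]);
  P.extra_recruitment = as<double>(p["extra_recruitment"]);
  P.div_act[L_CD4] = (int)as<double>(p["divisions_activated_cd4"]);
  P.div_act[L_CD8] = (int)as<double>(p["divisions_activated_cd8"]);
  P.div_cm = (int)as<double>(p["divisions_activated_cm"]);
  P.div_slope = as<double>(p["div_signal_slope"]);
  P.div_max_extra = (int)as<double>(p["div_max_extra"]);
  P.div_eff[L_CD4] = (int)as<double>(p["divisions_effector"]);
  P.div_eff[L_CD8] = (int)as<double>(p["divisions_effector_cd8"]);
  P.cycle_s = as<double>(p["cell_cycle_h"]) * 3600.0;
  P.cognate_freq = as<double>(p["cognate_frequency"]);
  P.cm_refract_s = as<double>(p["cm_refractory_days"]) * 86400.0;
  P.cd8_requires_ldc = as<double>(p["cd8_requires_ldc"]) != 0;
  P.k_bind = as<double>(p["k_bind"]);
  P.pmhc_sdlog = as<double>(p["dc_pmhc_sdlog"]);
  P.dc_max_bound = (int)as<double>(p["dc_max_bound"]);
  P.dc_lifespan_s = as<double>(p["dc_lifespan_days"]) * 86400.0;
  P.p_move = std::min(1.0, dt * (as<double>(p["t_speed"]) / 60.0) / 10.0);
  P.site_cap = (int)as<double>(p["site_capacity"]);
  P.transit_s = as<double>(p["ln_transit_h"]) * 3600.0;
  double target = as<double>(p["ln_target_cells"]) * scale;
  double n40 = as<double>(p["n4_0"]), n80 = as<double>(p["n8_0"]);
  P.recruit_coeff = (target / P.transit_s) / (n40 + n80);
  P.p_exit = 0.0; // set after geometry
  return P;
}

// [[Rcpp::export(name = ".ln_create_cpp")]]
SEXP ln_create_cpp(List params, double scale) {
  LnCore* c = new LnCore();
  c->P = make_pars(params, scale);
  double target = as<double>(params["ln_target_cells"]) * scale;
  double dens_per_site = as<double>(params["ln_density"]) * 1e-6; // cells/site
  double n_sites = target / dens_per_site;
  // truncated cone with top radius R/2, height 2R: V = 7*pi*R^3/6
  double R = std::cbrt(6.0 * n_sites / (7.0 * M_PI));
  int hz = std::max(4, (int)std::lround(2.0 * R));
  int nr = std::max(2, (int)std::ceil(R));
  c->nx = c->ny = 2 * nr + 3;
  c->nz = hz;
  c->nsites = c->nx * c->ny * c->nz;
  c->ok.assign(c->nsites, 0);
  c->el.assign(c->nsites, 0);
  c->occ.assign(c->nsites, 0);
  c->dc_at.assign(c->nsites, -1);
  double cx = (c->nx - 1) / 2.0, cy = (c->ny - 1) / 2.0;
  int n_in = 0, n_el = 0;
  int z_lo = (int)std::floor(0.40 * hz), z_hi = (int)std::ceil(0.60 * hz);
  for (int z = 0; z < c->nz; ++z) {
    double rz = R * (1.0 - 0.5 * (double)z / hz);
    for (int y = 0; y < c->ny; ++y)
      for (int x = 0; x < c->nx; ++x) {
        double d2 = (x - cx) * (x - cx) + (y - cy) * (y - cy);
        if (d2 <= rz * rz) {
          int s = c->idx(x, y, z);
          c->ok[s] = 1;
          ++n_in;
          // efferent sinus access is distributed through the paracortex:
          // every in-cone site can attempt egress (uniform hazard), so the
          // realized mean transit equals the calibrated target at any scale
          c->el[s] = 1;
          ++n_el;
          if (z >= z_lo && z <= z_hi) c->hev.push_back(s);
        }
      }
  }
  c->f_el = (double)n_el / (double)n_in;
  c->P.p_exit = std::min(1.0, c->P.dt / (c->P.transit_s * c->f_el));
  uint64_t sd = (uint64_t)(unif_rand() * 4294967296.0) << 32;
  sd |= (uint64_t)(unif_rand() * 4294967296.0);
  c->rng.seed(sd);
  c->n_alive = 0;
  c->nd_alive = 0;
  c->next_clone = 1;
  c->tracing = false;
  c->signal_log_on = false;
  for (int l = 0; l < 2; ++l)
    for (int s = 0; s < 5; ++s) { c->cum_exit[l][s] = 0; c->cum_recruit[l][s] = 0; }
  return LnPtr(c, true);
}

static int new_tc(LnCore* c) {
  int id;
  if (!c->freelist.empty()) {
    id = c->freelist.back();
    c->freelist.pop_back();
  } else {
    id = (int)c->alive.size();
    c->alive.push_back(0); c->lin.push_back(0); c->st.push_back(0);
    c->cog.push_back(0); c->mem_ok.push_back(0); c->from_cm.push_back(0);
    c->site.push_back(-1); c->bdc.push_back(-1);
    c->divs.push_back(0); c->clone.push_back(-1);
    c->belapsed.push_back(0); c->sig.push_back(0);
    c->age.push_back(0); c->cyc.push_back(0);
  }
  c->alive[id] = 1;
  c->lin[id] = 0; c->st[id] = ST_N; c->cog[id] = 0; c->mem_ok[id] = 0;
  c->from_cm[id] = 0;
  c->site[id] = -1; c->bdc[id] = -1; c->divs[id] = 0; c->clone[id] = -1;
  c->belapsed[id] = 0; c->sig[id] = 0; c->age[id] = 0; c->cyc[id] = 0;
  if (c->signal_log_on) {
    c->ev_type.push_back(1); c->ev_id.push_back(id); c->ev_amt.push_back(0);
  }
  ++c->n_alive;
  return id;
}

static void kill_tc(LnCore* c, int id) {
  if (c->bdc[id] >= 0) {
    c->dnbound[c->bdc[id]]--;
    c->bdc[id] = -1;
  }
  if (c->site[id] >= 0) c->occ[c->site[id]]--;
  c->alive[id] = 0;
  c->freelist.push_back(id);
  --c->n_alive;
}

static int random_free_site(LnCore* c, const std::vector<int>& pool) {
  for (int tries = 0; tries < 40; ++tries) {
    int s = pool[c->rng.below((int)pool.size())];
    if (c->occ[s] < c->P.site_cap) return s;
  }
  return -1;
}

static int place_anywhere(LnCore* c) {
  for (int tries = 0; tries < 200; ++tries) {
    int s = c->rng.below(c->nsites);
    if (c->ok[s] && c->occ[s] < c->P.site_cap) return s;
  }
  return -1;
}

// [[Rcpp::export(name = ".ln_seed_cpp")]]
void ln_seed_cpp(SEXP xp, double n_total, double n4, double cm4, double n8,
                 double cm8) {
  LnPtr c(xp);
  double tot = n4 + cm4 + n8 + cm8;
  if (tot <= 0) return;
  int counts[4];
  counts[0] = (int)std::lround(n_total * n4 / tot);
  counts[1] = (int)std::lround(n_total * cm4 / tot);
  counts[2] = (int)std::lround(n_total * n8 / tot);
  counts[3] = (int)std::lround(n_total * cm8 / tot);
  char lins[4] = {L_CD4, L_CD4, L_CD8, L_CD8};
  char sts[4] = {ST_N, ST_CM, ST_N, ST_CM};
  for (int k = 0; k < 4; ++k)
    for (int i = 0; i < counts[k]; ++i) {
      int s = place_anywhere(c);
      if (s < 0) return; // lattice full
      int id = new_tc(c);
      c->lin[id] = lins[k];
      c->st[id] = sts[k];
      c->site[id] = s;
      c->occ[s]++;
      if (sts[k] == ST_CM) c->cog[id] = 1;
      else if (c->rng.unif() < c->P.cognate_freq) {
        c->cog[id] = 1;
        if (c->tracing) c->clone[id] = (int)(c->next_clone++);
      }
    }
}

// [[Rcpp::export(name = ".ln_set_tracing_cpp")]]
void ln_set_tracing_cpp(SEXP xp, bool on, bool signal_log) {
  LnPtr c(xp);
  c->tracing = on;
  c->signal_log_on = signal_log;
}

// [[Rcpp::export(name = ".ln_add_dcs_cpp")]]
int ln_add_dcs_cpp(SEXP xp, int n, double pmhc1, double pmhc2) {
  LnPtr c(xp);
  int added = 0;
  for (int i = 0; i < n; ++i) {
    int s = -1;
    for (int tries = 0; tries < 200; ++tries) {
      int cand = c->rng.below(c->nsites);
      if (c->ok[cand] && c->dc_at[cand] < 0) { s = cand; break; }
    }
    if (s < 0) break;
    double j = std::exp(c->P.pmhc_sdlog * norm_rand());
    int d = (int)c->dalive.size();
    c->dalive.push_back(1);
    c->dkind.push_back(DC_AG);
    c->dsite.push_back(s);
    c->dnbound.push_back(0);
    c->dp1.push_back(pmhc1 * j);
    c->dp2.push_back(pmhc2 * j);
    c->dlife.push_back(c->P.dc_lifespan_s);
    c->dc_at[s] = d;
    c->nd_alive++;
    ++added;
  }
  return added;
}

static void unbind_checkpoint(LnCore* c, int id, int& deaths) {
  // clear the bond, then decide fate from the accumulated signal
  int d = c->bdc[id];
  if (d >= 0) c->dnbound[d]--;
  c->bdc[id] = -1;
  c->belapsed[id] = 0;
  bool cd8 = c->lin[id] == L_CD8;
  double thr = c->P.priming_thr * (cd8 ? c->P.cd8_thr_scale : 1.0);
  double aicd = c->P.aicd_thr * (cd8 ? c->P.cd8_aicd_scale : 1.0);
  if (c->P.aicd_enabled && c->sig[id] >= aicd) {
    kill_tc(c, id);
    ++deaths;
    return;
  }
  if (c->sig[id] >= thr) {
    c->from_cm[id] = (c->st[id] == ST_CM);
    c->st[id] = ST_A;
    c->divs[id] = 0;
    c->cyc[id] = c->P.cycle_s;
  } else {
    // revert (Naive stays Naive, CM stays CM), stimulation forgotten
    c->sig[id] = 0;
    if (c->signal_log_on) {
      c->ev_type.push_back(1); c->ev_id.push_back(id); c->ev_amt.push_back(0);
    }
  }
}

// Activation rounds follow the signal-strength model: a base number of
// rounds plus extra rounds proportional to the log2 excess of accumulated
// signal over the priming threshold (slope 0 recovers a fixed program).
// Re-activated CM programs are a short fixed recall burst.
static inline int act_rounds(const LnCore* c, int id) {
  int base = c->from_cm[id] ? c->P.div_cm : c->P.div_act[(int)c->lin[id]];
  if (c->P.div_slope <= 0) return base;
  double thr = c->P.priming_thr *
    (c->lin[id] == L_CD8 ? c->P.cd8_thr_scale : 1.0);
  double ratio = c->sig[id] / thr;
  if (ratio <= 1.0) return base;
  int extra = (int)std::floor(c->P.div_slope * std::log2(ratio));
  if (extra < 0) extra = 0;
  if (extra > c->P.div_max_extra) extra = c->P.div_max_extra;
  return base + extra;
}

static void differentiation_checkpoint(LnCore* c, int id) {
  // called when an Activated cell completes its division program
  bool cd8 = c->lin[id] == L_CD8;
  double eff_thr = c->P.effector_thr *
    (cd8 ? c->P.cd8_eff_scale : 1.0);
  if (c->sig[id] >= eff_thr) {
    c->st[id] = ST_E;
    c->cyc[id] = c->P.cycle_s;
  } else if (c->mem_ok[id] && c->rng.unif() < c->P.prob_cm) {
    c->st[id] = ST_CM;
    c->sig[id] = 0;
    c->divs[id] = 0;
    c->cyc[id] = c->P.cm_refract_s;  // refractory until matured
    if (c->signal_log_on) {
      c->ev_type.push_back(1); c->ev_id.push_back(id); c->ev_amt.push_back(0);
    }
  } else {
    // stays on the effector track (fate: short-lived effector)
    c->st[id] = ST_E;
    c->cyc[id] = c->P.cycle_s;
  }
}

static void em_checkpoint(LnCore* c, int id) {
  bool cd8 = c->lin[id] == L_CD8;
  double em_thr = c->P.em_thr * (cd8 ? c->P.cd8_thr_scale : 1.0);
  if (c->mem_ok[id] && c->sig[id] >= em_thr && c->rng.unif() < c->P.prob_em)
    c->st[id] = ST_EM;
  c->cyc[id] = 1e18; // expansion finished
}

// [[Rcpp::export(name = ".ln_step_cpp")]]
List ln_step_cpp(SEXP xp, NumericVector blood, int phases) {
  // blood: c(n4, cm4, n8, cm8) concentrations in cells/mm3
  LnPtr c(xp);
  const Pars& P = c->P;
  double dt = P.dt;
  int recruited[2][2] = {{0, 0}, {0, 0}}; // [lin][0=N,1=CM]
  int exited[2][5] = {{0}, {0}};
  int births = 0, deaths = 0, dc_deaths = 0;
  double naive_exit_age = 0.0;
  int naive_exit_n = 0;

  // ---- 1. recruitment ------------------------------------------------
  if (phases & 1) {
    bool dc_present = c->nd_alive > 0;
    double boost = dc_present ? P.extra_recruitment : 1.0;
    double lam[4] = {blood[0], blood[1], blood[2], blood[3]};
    char lins[4] = {L_CD4, L_CD4, L_CD8, L_CD8};
    char sts[4] = {ST_N, ST_CM, ST_N, ST_CM};
    for (int k = 0; k < 4; ++k) {
      double l = P.recruit_coeff * lam[k] * dt * boost;
      if (l <= 0) continue;
      int n = (int)R::rpois(l);
      for (int i = 0; i < n; ++i) {
        int s = random_free_site(c, c->hev);
        if (s < 0) continue;
        int id = new_tc(c);
        c->lin[id] = lins[k];
        c->st[id] = sts[k];
        c->site[id] = s;
        c->occ[s]++;
        if (sts[k] == ST_CM) c->cog[id] = 1;
        else if (c->rng.unif() < P.cognate_freq) {
          c->cog[id] = 1;
          if (c->tracing) c->clone[id] = (int)(c->next_clone++);
        }
        recruited[(int)lins[k]][sts[k] == ST_CM ? 1 : 0]++;
        c->cum_recruit[(int)lins[k]][(int)sts[k]] += 1;
      }
    }
  }

  // shared shuffled index of currently alive cells
  std::vector<int>& ids = c->ids_buf;
  ids.clear();
  ids.reserve(c->n_alive);
  for (int i = 0; i < (int)c->alive.size(); ++i)
    if (c->alive[i]) ids.push_back(i);
  shuffle(ids, c->rng);

  // ---- 2. motility ---------------------------------------------------
  if (phases & 2) {
    static const int DX[6] = {1, -1, 0, 0, 0, 0};
    static const int DY[6] = {0, 0, 1, -1, 0, 0};
    static const int DZ[6] = {0, 0, 0, 0, 1, -1};
    for (int id : ids) {
      if (!c->alive[id] || c->bdc[id] >= 0) continue;
      double u = c->rng.unif();
      if (u >= P.p_move) continue;
      int s = c->site[id];
      int z = s / (c->nx * c->ny);
      int rem = s % (c->nx * c->ny);
      int y = rem / c->nx, x = rem % c->nx;
      int k = (int)(u / P.p_move * 6);
      if (k > 5) k = 5;
      int nxp = x + DX[k], nyp = y + DY[k], nzp = z + DZ[k];
      if (nxp < 0 || nyp < 0 || nzp < 0 ||
          nxp >= c->nx || nyp >= c->ny || nzp >= c->nz) continue;
      int t = c->idx(nxp, nyp, nzp);
      if (!c->ok[t] || c->occ[t] >= P.site_cap) continue;
      c->occ[s]--; c->occ[t]++;
      c->site[id] = t;
    }
  }

  // ---- 3. binding, signal accumulation, unbinding --------------------
  if (phases & 4) {
    for (int id : ids) {
      if (!c->alive[id]) continue;
      int d = c->bdc[id];
      if (d >= 0) {
        // accumulate signal only before the first division of the program
        if (c->divs[id] == 0) {
          double pm = (c->lin[id] == L_CD4) ? c->dp2[d] : c->dp1[d];
          double eff = (c->st[id] == ST_CM) ? P.cm_eff : 1.0;
          double inc = pm * (dt / 60.0) * eff;
          c->sig[id] += inc;
          if (c->signal_log_on) {
            c->ev_type.push_back(0); c->ev_id.push_back(id);
            c->ev_amt.push_back(inc);
          }
        }
        c->belapsed[id] += dt;
        double bt = (c->st[id] == ST_CM) ? P.cm_bind_time_s : P.bind_time_s;
        if (c->belapsed[id] >= bt) unbind_checkpoint(c, id, deaths);
      } else if (c->cog[id] && (c->st[id] == ST_N || c->st[id] == ST_CM)) {
        if (c->st[id] == ST_CM && c->cyc[id] > 0) {
          c->cyc[id] -= dt;  // maturing memory cannot re-engage yet
          continue;
        }
        // scan the 27-site Chebyshev neighborhood for a DC with a free slot
        int s = c->site[id];
        int z = s / (c->nx * c->ny);
        int rem = s % (c->nx * c->ny);
        int y = rem / c->nx, x = rem % c->nx;
        for (int dz = -1; dz <= 1 && c->bdc[id] < 0; ++dz)
          for (int dy = -1; dy <= 1 && c->bdc[id] < 0; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int ax = x + dx, ay = y + dy, az = z + dz;
              if (ax < 0 || ay < 0 || az < 0 ||
                  ax >= c->nx || ay >= c->ny || az >= c->nz) continue;
              int dcd = c->dc_at[c->idx(ax, ay, az)];
              if (dcd < 0 || !c->dalive[dcd]) continue;
              if (c->dnbound[dcd] >= P.dc_max_bound) continue;
              double pm = (c->lin[id] == L_CD4) ? c->dp2[dcd] : c->dp1[dcd];
              double pb = pm / (pm + P.k_bind);
              if (c->rng.unif() < pb) {
                c->bdc[id] = dcd;
                c->belapsed[id] = 0;
                c->dnbound[dcd]++;
                c->mem_ok[id] =
                  (c->lin[id] == L_CD4) || !P.cd8_requires_ldc ||
                  (c->dkind[dcd] == DC_LDC);
                break;
              }
            }
      }
    }
  }

  // ---- 4. checkpoints and proliferation ------------------------------
  if (phases & 8) {
    for (int id : ids) {
      if (!c->alive[id]) continue;
      char s0 = c->st[id];
      if (s0 != ST_A && s0 != ST_E) continue;
      // Activated cells stop at the activation rounds and then take the
      // differentiation check; effector-track cells finish the full program.
      if (c->cyc[id] > 1e17) continue;
      c->cyc[id] -= dt;
      if (c->cyc[id] > 0) continue;
      // attempt division into a free von-Neumann neighbor (or own site)
      int s = c->site[id];
      int z = s / (c->nx * c->ny);
      int rem = s % (c->nx * c->ny);
      int y = rem / c->nx, x = rem % c->nx;
      static const int DX[7] = {0, 1, -1, 0, 0, 0, 0};
      static const int DY[7] = {0, 0, 0, 1, -1, 0, 0};
      static const int DZ[7] = {0, 0, 0, 0, 0, 1, -1};
      int target = -1;
      int start = c->rng.below(7);
      for (int k = 0; k < 7; ++k) {
        int kk = (start + k) % 7;
        int ax = x + DX[kk], ay = y + DY[kk], az = z + DZ[kk];
        if (ax < 0 || ay < 0 || az < 0 ||
            ax >= c->nx || ay >= c->ny || az >= c->nz) continue;
        int t = c->idx(ax, ay, az);
        if (!c->ok[t]) continue;
        if (c->occ[t] < P.site_cap) { target = t; break; }
      }
      if (target < 0) { c->cyc[id] = 0; continue; } // defer until space frees
      int dghtr = new_tc(c);
      c->lin[dghtr] = c->lin[id];
      c->st[dghtr] = c->st[id];
      c->cog[dghtr] = c->cog[id];
      c->mem_ok[dghtr] = c->mem_ok[id];
      c->from_cm[dghtr] = c->from_cm[id];
      c->clone[dghtr] = c->clone[id];
      c->sig[dghtr] = c->sig[id];
      c->site[dghtr] = target;
      c->occ[target]++;
      c->divs[id]++;
      c->divs[dghtr] = c->divs[id];
      c->cyc[id] = P.cycle_s;
      c->cyc[dghtr] = P.cycle_s;
      ++births;
      if (c->signal_log_on) {
        c->ev_type.push_back(2); c->ev_id.push_back(dghtr);
        c->ev_amt.push_back(c->sig[id]);
      }
      char sNow = c->st[id];
      int done = c->divs[id];
      if (sNow == ST_A && done >= act_rounds(c, id)) {
        differentiation_checkpoint(c, id);
        differentiation_checkpoint(c, dghtr);
      }
      // cells that just became (or already were) effectors finish the
      // additional effector rounds, then take the EM check once
      if (c->st[id] == ST_E &&
          c->divs[id] >= act_rounds(c, id) + P.div_eff[(int)c->lin[id]])
        em_checkpoint(c, id);
      if (c->alive[dghtr] && c->st[dghtr] == ST_E &&
          c->divs[dghtr] >= act_rounds(c, dghtr) + P.div_eff[(int)c->lin[dghtr]])
        em_checkpoint(c, dghtr);
    }
  }

  // ---- 5. DC licensing by CD4 effectors ------------------------------
  if (phases & 16) {
    double p_lic = std::min(1.0, P.lic_prob_per_min * dt / 60.0);
    for (int id : ids) {
      if (!c->alive[id] || c->lin[id] != L_CD4 || c->st[id] != ST_E) continue;
      int s = c->site[id];
      int z = s / (c->nx * c->ny);
      int rem = s % (c->nx * c->ny);
      int y = rem / c->nx, x = rem % c->nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int ax = x + dx, ay = y + dy, az = z + dz;
            if (ax < 0 || ay < 0 || az < 0 ||
                ax >= c->nx || ay >= c->ny || az >= c->nz) continue;
            int d = c->dc_at[c->idx(ax, ay, az)];
            if (d < 0 || !c->dalive[d] || c->dkind[d] != DC_AG) continue;
            if (c->rng.unif() < p_lic) {
              c->dkind[d] = DC_LDC;
              c->dp1[d] *= P.lic_boost;
              c->dp2[d] *= P.lic_boost;
            }
          }
    }
  }

  // ---- 6. egress and death -------------------------------------------
  if (phases & 32) {
    for (int id : ids) {
      if (!c->alive[id] || c->bdc[id] >= 0) continue;
      char s0 = c->st[id];
      if (s0 == ST_A) continue; // early activation markers retain the cell
      if (!c->el[c->site[id]]) continue;
      if (c->rng.unif() < P.p_exit) {
        exited[(int)c->lin[id]][(int)s0]++;
        c->cum_exit[(int)c->lin[id]][(int)s0] += 1;
        if (s0 == ST_N) { naive_exit_age += c->age[id]; ++naive_exit_n; }
        if (c->tracing && c->clone[id] > 0) {
          c->exit_clone.push_back(c->clone[id]);
          c->exit_lin.push_back((int)c->lin[id]);
          c->exit_st.push_back((int)s0);
        }
        kill_tc(c, id);
      }
    }
    // DC ageing and death; bonds to dying DCs end with a checkpoint
    for (int d = 0; d < (int)c->dalive.size(); ++d) {
      if (!c->dalive[d]) continue;
      c->dlife[d] -= dt;
      if (c->dlife[d] <= 0) {
        c->dalive[d] = 0;
        c->dc_at[c->dsite[d]] = -1;
        c->nd_alive--;
        ++dc_deaths;
      }
    }
    for (int id : ids) {
      if (!c->alive[id]) continue;
      int d = c->bdc[id];
      // a bond cut short by DC death ends with the usual checkpoint
      if (d >= 0 && !c->dalive[d]) unbind_checkpoint(c, id, deaths);
    }
  }

  // ---- ageing + consolidated report ----------------------------------
  IntegerMatrix ex(2, 5), cnt(2, 5);
  int n_bound = 0;
  int cnt_l[2][5] = {{0}, {0}};
  for (int i = 0; i < (int)c->alive.size(); ++i)
    if (c->alive[i]) {
      c->age[i] += dt;
      cnt_l[(int)c->lin[i]][(int)c->st[i]]++;
      if (c->bdc[i] >= 0) ++n_bound;
    }
  for (int l = 0; l < 2; ++l)
    for (int s = 0; s < 5; ++s) {
      ex(l, s) = exited[l][s];
      cnt(l, s) = cnt_l[l][s];
    }
  int agdc = 0, ldc = 0;
  for (int d = 0; d < (int)c->dalive.size(); ++d)
    if (c->dalive[d]) (c->dkind[d] == DC_AG ? agdc : ldc)++;
  CharacterVector lnames = CharacterVector::create("CD4", "CD8");
  CharacterVector snames = CharacterVector::create("N", "A", "E", "CM", "EM");
  ex.attr("dimnames") = List::create(lnames, snames);
  cnt.attr("dimnames") = List::create(lnames, snames);
  return List::create(
    _["recruited"] = NumericVector::create(
      _["n4"] = recruited[0][0], _["cm4"] = recruited[0][1],
      _["n8"] = recruited[1][0], _["cm8"] = recruited[1][1]),
    _["exited"] = ex,
    _["births"] = births,
    _["deaths"] = deaths,
    _["dc_deaths"] = dc_deaths,
    _["agdc"] = agdc,
    _["ldc"] = ldc,
    _["counts"] = cnt,
    _["n_bound"] = n_bound,
    _["total"] = c->n_alive,
    _["naive_exit_age_s"] = naive_exit_age,
    _["naive_exit_n"] = naive_exit_n);
}

// [[Rcpp::export(name = ".ln_ablate_dcs_cpp")]]
int ln_ablate_dcs_cpp(SEXP xp) {
  // instant removal of every DC (diphtheria-toxin style); bound T cells
  // unbind and face the usual checkpoint with their partial signal
  LnPtr c(xp);
  int removed = 0;
  for (int d = 0; d < (int)c->dalive.size(); ++d)
    if (c->dalive[d]) {
      c->dalive[d] = 0;
      c->dc_at[c->dsite[d]] = -1;
      ++removed;
    }
  c->nd_alive = 0;
  int deaths = 0;
  for (int id = 0; id < (int)c->alive.size(); ++id)
    if (c->alive[id] && c->bdc[id] >= 0) {
      c->bdc[id] = -1;
      unbind_checkpoint(c, id, deaths);
    }
  return removed;
}

// [[Rcpp::export(name = ".ln_counts_cpp")]]
List ln_counts_cpp(SEXP xp) {
  LnPtr c(xp);
  IntegerMatrix cnt(2, 5);
  int n_bound = 0;
  for (int i = 0; i < (int)c->alive.size(); ++i)
    if (c->alive[i]) {
      cnt((int)c->lin[i], (int)c->st[i])++;
      if (c->bdc[i] >= 0) ++n_bound;
    }
  int agdc = 0, ldc = 0;
  for (int d = 0; d < (int)c->dalive.size(); ++d)
    if (c->dalive[d]) (c->dkind[d] == DC_AG ? agdc : ldc)++;
  cnt.attr("dimnames") = List::create(
    CharacterVector::create("CD4", "CD8"),
    CharacterVector::create("N", "A", "E", "CM", "EM"));
  return List::create(_["counts"] = cnt, _["n_bound"] = n_bound,
                      _["agdc"] = agdc, _["ldc"] = ldc,
                      _["total"] = c->n_alive);
}

// [[Rcpp::export(name = ".ln_cumulative_cpp")]]
List ln_cumulative_cpp(SEXP xp) {
  LnPtr c(xp);
  NumericMatrix ex(2, 5), rec(2, 5);
  for (int l = 0; l < 2; ++l)
    for (int s = 0; s < 5; ++s) {
      ex(l, s) = c->cum_exit[l][s];
      rec(l, s) = c->cum_recruit[l][s];
    }
  List dn = List::create(CharacterVector::create("CD4", "CD8"),
                         CharacterVector::create("N", "A", "E", "CM", "EM"));
  ex.attr("dimnames") = dn;
  rec.attr("dimnames") = dn;
  return List::create(_["exited"] = ex, _["recruited"] = rec);
}

// [[Rcpp::export(name = ".ln_tcells_cpp")]]
DataFrame ln_tcells_cpp(SEXP xp) {
  LnPtr c(xp);
  std::vector<int> id, site_x, site_y, site_z, divs, clone, bdc;
  std::vector<std::string> lin, st;
  std::vector<bool> cog, memk;
  std::vector<double> sig, bel, age;
  const char* SN[5] = {"N", "A", "E", "CM", "EM"};
  for (int i = 0; i < (int)c->alive.size(); ++i) {
    if (!c->alive[i]) continue;
    id.push_back(i);
    lin.push_back(c->lin[i] == L_CD4 ? "CD4" : "CD8");
    st.push_back(SN[(int)c->st[i]]);
    cog.push_back(c->cog[i] != 0);
    memk.push_back(c->mem_ok[i] != 0);
    bdc.push_back(c->bdc[i]);
    sig.push_back(c->sig[i]);
    bel.push_back(c->belapsed[i]);
    divs.push_back(c->divs[i]);
    clone.push_back(c->clone[i]);
    age.push_back(c->age[i]);
    int s = c->site[i];
    int z = s / (c->nx * c->ny);
    int rem = s % (c->nx * c->ny);
    site_z.push_back(z);
    site_y.push_back(rem / c->nx);
    site_x.push_back(rem % c->nx);
  }
  return DataFrame::create(
    _["id"] = id, _["lineage"] = lin, _["state"] = st, _["cognate"] = cog,
    _["mem_allowed"] = memk, _["bound_dc"] = bdc, _["bind_elapsed"] = bel,
    _["signal"] = sig, _["divisions"] = divs, _["clone"] = clone,
    _["age_s"] = age, _["x"] = site_x, _["y"] = site_y, _["z"] = site_z);
}

// [[Rcpp::export(name = ".ln_dcs_cpp")]]
DataFrame ln_dcs_cpp(SEXP xp) {
  LnPtr c(xp);
  std::vector<int> id, nb, sx, sy, sz;
  std::vector<std::string> kind;
  std::vector<double> p1, p2, life;
  for (int d = 0; d < (int)c->dalive.size(); ++d) {
    if (!c->dalive[d]) continue;
    id.push_back(d);
    kind.push_back(c->dkind[d] == DC_AG ? "AgDC" : "LDC");
    p1.push_back(c->dp1[d]);
    p2.push_back(c->dp2[d]);
    nb.push_back(c->dnbound[d]);
    life.push_back(c->dlife[d] / 86400.0);
    int s = c->dsite[d];
    int z = s / (c->nx * c->ny);
    int rem = s % (c->nx * c->ny);
    sz.push_back(z);
    sy.push_back(rem / c->nx);
    sx.push_back(rem % c->nx);
  }
  return DataFrame::create(
    _["id"] = id, _["kind"] = kind, _["pmhc1"] = p1, _["pmhc2"] = p2,
    _["n_bound"] = nb, _["lifespan_days"] = life,
    _["x"] = sx, _["y"] = sy, _["z"] = sz);
}

// [[Rcpp::export(name = ".ln_exit_log_cpp")]]
DataFrame ln_exit_log_cpp(SEXP xp, bool clear) {
  LnPtr c(xp);
  const char* SN[5] = {"N", "A", "E", "CM", "EM"};
  int n = (int)c->exit_clone.size();
  std::vector<std::string> lin(n), st(n);
  for (int i = 0; i < n; ++i) {
    lin[i] = c->exit_lin[i] == L_CD4 ? "CD4" : "CD8";
    st[i] = SN[c->exit_st[i]];
  }
  DataFrame out = DataFrame::create(
    _["clone"] = c->exit_clone, _["lineage"] = lin, _["state"] = st);
  if (clear) {
    c->exit_clone.clear(); c->exit_lin.clear(); c->exit_st.clear();
  }
  return out;
}

// [[Rcpp::export(name = ".ln_signal_log_cpp")]]
DataFrame ln_signal_log_cpp(SEXP xp, bool clear) {
  LnPtr c(xp);
  DataFrame out = DataFrame::create(
    _["event"] = c->ev_type, _["id"] = c->ev_id, _["amount"] = c->ev_amt);
  if (clear) { c->ev_type.clear(); c->ev_id.clear(); c->ev_amt.clear(); }
  return out;
}

// [[Rcpp::export(name = ".ln_info_cpp")]]
List ln_info_cpp(SEXP xp) {
  LnPtr c(xp);
  int n_in = 0, n_el = 0;
  for (int s = 0; s < c->nsites; ++s) {
    if (c->ok[s]) ++n_in;
    if (c->el[s]) ++n_el;
  }
  return List::create(
    _["dims"] = IntegerVector::create(c->nx, c->ny, c->nz),
    _["n_sites"] = n_in, _["n_el_sites"] = n_el,
    _["n_hev_sites"] = (int)c->hev.size(),
    _["f_el"] = c->f_el, _["p_exit"] = c->P.p_exit,
    _["p_move"] = c->P.p_move,
    _["recruit_coeff"] = c->P.recruit_coeff,
    _["site_capacity"] = c->P.site_cap,
    _["next_clone"] = (double)c->next_clone);
}

// Forward-Euler kernel for the eight blood pools; rates packs
// (s40, s80, lf, dn4, dec4, dcm4, aem4, dem4, dn8, dec8, dcm8, aem8, dem8)
// with lf the continuous-compounding log factor of the thymic decline.
// [[Rcpp::export(name = ".euler_cpp")]]
List euler_cpp(NumericVector conc, double t_days, double h_day, int m,
               NumericVector rates) {
  double n4 = conc[0], e4 = conc[1], cm4 = conc[2], em4 = conc[3];
  double n8 = conc[4], e8 = conc[5], cm8 = conc[6], em8 = conc[7];
  const double s40 = rates[0], s80 = rates[1], lf = rates[2];
  const double dn4 = rates[3], dec4 = rates[4], dcm4 = rates[5];
  const double aem4 = rates[6], dem4 = rates[7];
  const double dn8 = rates[8], dec8 = rates[9], dcm8 = rates[10];
  const double aem8 = rates[11], dem8 = rates[12];
  double t = t_days;
  for (int i = 0; i < m; ++i) {
    double s4 = s40 * std::exp(lf * t);
    double s8 = s80 * std::exp(lf * t);
    n4 += h_day * (s4 - dn4 * n4);
    e4 += h_day * (-dec4 * e4);
    cm4 += h_day * (-dcm4 * cm4 + aem4 * em4);
    em4 += h_day * (-dem4 * em4);
    n8 += h_day * (s8 - dn8 * n8);
    e8 += h_day * (-dec8 * e8);
    cm8 += h_day * (-dcm8 * cm8 + aem8 * em8);
    em8 += h_day * (-dem8 * em8);
    t += h_day;
  }
  return List::create(
    _["conc"] = NumericVector::create(n4, e4, cm4, em4, n8, e8, cm8, em8),
    _["t"] = t);
}
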