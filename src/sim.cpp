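// Compiled simulation core: the four per-step sub-models (environmental
// disruption, ageing and death, reproduction, mating) plus the run loop.
// The R-level phase functions and the run loop call the same internal
// routines, so stepping a population from R and running it here consume the
// RNG identically and produce bit-identical trajectories.
//
// All randomness comes from R's RNG (unif_rand / R::rpois), so set.seed()
// in R fully determines a run.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <set>
using namespace Rcpp;

// Column layout of the population matrix (shared with R via pop_columns()).
enum Col {
  SEX = 0,   // 1 = male, 0 = female
  AGE,       // integer-valued steps
  VA_M, VA_P,        // viability alleles, maternal / paternal slot
  PR_M, PR_P,        // preference alleles, maternal / paternal slot
  VIAB, PREF,        // expressed traits (allele means, cached at birth)
  SIG,               // male signal, fixed at birth; NA for females
  PREG, GEST,        // pregnancy flag and gestation counter (females)
  S_VA_M, S_VA_P,    // stored mate alleles (viability pair); NA unless pregnant
  S_PR_M, S_PR_P,    // stored mate alleles (preference pair)
  ID,
  NCOL
};

static const char *COLNAMES[NCOL] = {
  "sex", "age", "viab_allele_mat", "viab_allele_pat",
  "pref_allele_mat", "pref_allele_pat", "viability", "preference",
  "signal", "pregnant", "gestation",
  "mate_viab_mat", "mate_viab_pat", "mate_pref_mat", "mate_pref_pat", "id"
};

struct Pop {
  std::vector<double> c[NCOL];
  size_t n;
  Pop() : n(0) {}
  void resize(size_t m) { for (int k = 0; k < NCOL; k++) c[k].resize(m); n = m; }
  void copy_row(size_t from, size_t to) {
    if (from != to) for (int k = 0; k < NCOL; k++) c[k][to] = c[k][from];
  }
  void push_row(const double *row) {
    for (int k = 0; k < NCOL; k++) c[k].push_back(row[k]);
    n++;
  }
};

struct Par {
  double gest_len, lambda, senescence, maturity, K, ve, pm, vm;
};

static Par par_from_list(List p) {
  Par q;
  q.gest_len   = as<double>(p["gestation_length"]);
  q.lambda     = as<double>(p["fecundity_lambda"]);
  q.senescence = as<double>(p["senescence"]);
  q.maturity   = as<double>(p["maturity_age"]);
  q.K          = as<double>(p["carrying_capacity"]);
  q.ve         = as<double>(p["viability_effect"]);
  q.pm         = as<double>(p["preference_mutation"]);
  q.vm         = as<double>(p["viability_mutation"]);
  return q;
}

static Pop pop_from_mat(NumericMatrix m) {
  if (m.ncol() != NCOL) stop("population matrix must have %d columns", NCOL);
  Pop P;
  size_t n = m.nrow();
  P.resize(n);
  for (int k = 0; k < NCOL; k++)
    for (size_t i = 0; i < n; i++) P.c[k][i] = m(i, k);
  return P;
}

static NumericMatrix pop_to_mat(const Pop &P) {
  NumericMatrix m(P.n, NCOL);
  for (int k = 0; k < NCOL; k++)
    for (size_t i = 0; i < P.n; i++) m(i, k) = P.c[k][i];
  CharacterVector cn(NCOL);
  for (int k = 0; k < NCOL; k++) cn[k] = COLNAMES[k];
  colnames(m) = cn;
  return m;
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Ageing and death. The juvenile count is snapshotted once at phase start;
// survivors age by one step; a pregnant female's brood dies with her
// (the stored mate alleles are simply discarded with her row).
static void ageing_death(Pop &P, const Par &par) {
  size_t J = 0;
  for (size_t i = 0; i < P.n; i++)
    if (P.c[AGE][i] < par.maturity) J++;
  double pj = 1.0 - (double)J / par.K;
  if (pj < 0.0) pj = 0.0;
  size_t w = 0;
  for (size_t i = 0; i < P.n; i++) {
    double p;
    if (P.c[AGE][i] < par.maturity) {
      p = pj;
    } else {
      double a = P.c[AGE][i];
      p = 1.0 - clamp01(a * a / par.senescence - par.ve * P.c[VIAB][i]);
    }
    if (unif_rand() < p) {
      P.copy_row(i, w);
      P.c[AGE][w] += 1.0;
      w++;
    }
  }
  P.resize(w);
}

static inline double gamete(double a, double b) {
  return unif_rand() < 0.5 ? a : b;
}

// Choice-then-mutate: the transmitted copy may be replaced by a fresh
// Uniform(0,1) draw with the per-allele mutation probability.
static inline double mutate(double a, double rate) {
  if (unif_rand() < rate) return unif_rand();
  return a;
}

// Reproduction. Birth check precedes the gestation increment, so a litter is
// delivered on the step when gestation == gestation_length. Newborn males fix
// their signal with the disruption value current at birth; broods in utero
// are sheltered from disruption until then.
static void reproduction(Pop &P, const Par &par, double disruption,
                         double &next_id, int t,
                         std::vector<double> *log_t,
                         std::vector<double> *log_age) {
  size_t n0 = P.n;  // newborns appended past n0 are not scanned this phase
  double row[NCOL];
  for (size_t i = 0; i < n0; i++) {
    if (P.c[PREG][i] != 1.0) continue;
    if (P.c[GEST][i] >= par.gest_len) {
      int litter = (int)R::rpois(par.lambda);
      for (int k = 0; k < litter; k++) {
        double sex = unif_rand() < 0.5 ? 1.0 : 0.0;
        double vam = mutate(gamete(P.c[VA_M][i], P.c[VA_P][i]), par.vm);
        double vap = mutate(gamete(P.c[S_VA_M][i], P.c[S_VA_P][i]), par.vm);
        double prm = mutate(gamete(P.c[PR_M][i], P.c[PR_P][i]), par.pm);
        double prp = mutate(gamete(P.c[S_PR_M][i], P.c[S_PR_P][i]), par.pm);
        double viab = 0.5 * (vam + vap), pref = 0.5 * (prm + prp);
        row[SEX] = sex; row[AGE] = 0.0;
        row[VA_M] = vam; row[VA_P] = vap;
        row[PR_M] = prm; row[PR_P] = prp;
        row[VIAB] = viab; row[PREF] = pref;
        row[SIG] = sex == 1.0 ? viab * (1.0 - disruption) : NA_REAL;
        row[PREG] = 0.0; row[GEST] = 0.0;
        row[S_VA_M] = NA_REAL; row[S_VA_P] = NA_REAL;
        row[S_PR_M] = NA_REAL; row[S_PR_P] = NA_REAL;
        row[ID] = next_id; next_id += 1.0;
        P.push_row(row);
      }
      if (log_t) {
        log_t->push_back((double)t);
        log_age->push_back(P.c[AGE][i]);
      }
      P.c[PREG][i] = 0.0; P.c[GEST][i] = 0.0;
      P.c[S_VA_M][i] = NA_REAL; P.c[S_VA_P][i] = NA_REAL;
      P.c[S_PR_M][i] = NA_REAL; P.c[S_PR_P][i] = NA_REAL;
    } else {
      P.c[GEST][i] += 1.0;
    }
  }
}

// Mating. Each mature non-pregnant female picks uniformly among the mature
// males whose signal is at least her preference (ties in signal included).
// Males are not depleted: several females may pick the same male in a step.
static void mating(Pop &P, const Par &par) {
  std::vector<std::pair<double, size_t> > males;
  for (size_t i = 0; i < P.n; i++)
    if (P.c[SEX][i] == 1.0 && P.c[AGE][i] >= par.maturity)
      males.push_back(std::make_pair(P.c[SIG][i], i));
  std::sort(males.begin(), males.end());
  size_t m = males.size();
  if (m == 0) return;
  for (size_t i = 0; i < P.n; i++) {
    if (P.c[SEX][i] != 0.0 || P.c[AGE][i] < par.maturity ||
        P.c[PREG][i] != 0.0)
      continue;
    double pref = P.c[PREF][i];
    size_t lo = std::lower_bound(males.begin(), males.end(),
                                 std::make_pair(pref, (size_t)0)) -
                males.begin();
    size_t k = m - lo;
    if (k == 0) continue;  // wallflower: no acceptable male this step
    size_t pick = lo + (size_t)(unif_rand() * (double)k);
    if (pick >= m) pick = m - 1;
    size_t j = males[pick].second;
    P.c[PREG][i] = 1.0;
    P.c[GEST][i] = 1.0;
    P.c[S_VA_M][i] = P.c[VA_M][j];
    P.c[S_VA_P][i] = P.c[VA_P][j];
    P.c[S_PR_M][i] = P.c[PR_M][j];
    P.c[S_PR_P][i] = P.c[PR_P][j];
  }
}

// One observer record: counts and allele means over all living individuals
// plus the mean signal over males. 11 values per row.
static void capture(const Pop &P, const Par &par, double t,
                    std::vector<double> &recs) {
  size_t nm = 0, nf = 0, nj = 0;
  double spp = 0, spm = 0, svp = 0, svm = 0, ssig = 0;
  for (size_t i = 0; i < P.n; i++) {
    if (P.c[SEX][i] == 1.0) { nm++; ssig += P.c[SIG][i]; } else nf++;
    if (P.c[AGE][i] < par.maturity) nj++;
    spp += P.c[PR_P][i]; spm += P.c[PR_M][i];
    svp += P.c[VA_P][i]; svm += P.c[VA_M][i];
  }
  double n = (double)P.n;
  recs.push_back(t);
  recs.push_back(n);
  recs.push_back((double)nm);
  recs.push_back((double)nf);
  recs.push_back((double)nj);
  recs.push_back(spp / n);
  recs.push_back(spm / n);
  recs.push_back(svp / n);
  recs.push_back(svm / n);
  recs.push_back(nm > 0 ? ssig / (double)nm : NA_REAL);
}

static inline double disruption_value(int t, double burn_in, double level,
                                      double duration) {
  return (t >= burn_in && t < burn_in + duration) ? level : 0.0;
}

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(NumericMatrix pop0, List params, double next_id,
                 int t0, int t_end, double burn_in, double disr_level,
                 double disr_duration, IntegerVector capture_at,
                 bool log_births) {
  Par par = par_from_list(params);
  Pop P = pop_from_mat(pop0);
  std::set<int> caps(capture_at.begin(), capture_at.end());
  std::vector<double> recs, log_t, log_age;
  bool extinct = false;
  int ext_time = NA_INTEGER;
  int t = t0;
  double last_d = 0.0;
  for (; t < t_end; t++) {
    if (P.n > 0 && caps.count(t)) capture(P, par, (double)t, recs);
    double d = disruption_value(t, burn_in, disr_level, disr_duration);
    last_d = d;
    ageing_death(P, par);
    reproduction(P, par, d, next_id, t,
                 log_births ? &log_t : (std::vector<double> *)0,
                 log_births ? &log_age : (std::vector<double> *)0);
    mating(P, par);
    if (P.n == 0) { extinct = true; ext_time = t; break; }
  }
  if (!extinct && caps.count(t_end)) capture(P, par, (double)t_end, recs);
  size_t nrec = recs.size() / 10;
  NumericMatrix recmat(nrec, 10);
  for (size_t r = 0; r < nrec; r++)
    for (int k = 0; k < 10; k++) recmat(r, k) = recs[r * 10 + k];
  colnames(recmat) = CharacterVector::create(
      "t", "n", "n_males", "n_females", "n_juveniles",
      "mean_pref_pat", "mean_pref_mat", "mean_viab_pat", "mean_viab_mat",
      "mean_signal_males");
  return List::create(
      _["pop"] = pop_to_mat(P), _["t"] = extinct ? ext_time : t_end,
      _["next_id"] = next_id, _["extinct"] = extinct,
      _["extinction_time"] = extinct ? IntegerVector::create(ext_time)
                                     : IntegerVector::create(NA_INTEGER),
      _["disruption"] = last_d,
      _["records"] = recmat,
      _["birth_t"] = NumericVector(log_t.begin(), log_t.end()),
      _["birth_age"] = NumericVector(log_age.begin(), log_age.end()));
}

// [[Rcpp::export(name = ".phase_ageing_death_cpp")]]
NumericMatrix phase_ageing_death_cpp(NumericMatrix pop, List params) {
  Par par = par_from_list(params);
  Pop P = pop_from_mat(pop);
  ageing_death(P, par);
  return pop_to_mat(P);
}

// [[Rcpp::export(name = ".phase_reproduction_cpp")]]
List phase_reproduction_cpp(NumericMatrix pop, List params, double disruption,
                            double next_id, bool log_births, int t) {
  Par par = par_from_list(params);
  Pop P = pop_from_mat(pop);
  std::vector<double> log_t, log_age;
  reproduction(P, par, disruption, next_id, t,
               log_births ? &log_t : (std::vector<double> *)0,
               log_births ? &log_age : (std::vector<double> *)0);
  return List::create(_["pop"] = pop_to_mat(P), _["next_id"] = next_id,
                      _["birth_t"] = NumericVector(log_t.begin(), log_t.end()),
                      _["birth_age"] =
                          NumericVector(log_age.begin(), log_age.end()));
}

// [[Rcpp::export(name = ".phase_mating_cpp")]]
NumericMatrix phase_mating_cpp(NumericMatrix pop, List params) {
  Par par = par_from_list(params);
  Pop P = pop_from_mat(pop);
  mating(P, par);
  return pop_to_mat(P);
}
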