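#include "core.h"
#include <chrono>

using namespace Rcpp;
using namespace cellmet;

namespace {

struct Config {
  int capacity, initial_pop, init_cell, cfn, interval, prof_n;
  bool energy_unlimited;
  int energy_parcels;
  double parcel_size;
  bool food_replenished;
  int food_rate, food_cap, food_stock0;
  double r_ins, r_del, r_ptr;
  double gene_coeff, energy_coeff, food_coeff;
  double gene_override, energy_override, food_override;  // -1 = none
  bool extra_cost, consume, rewards, replication;
  int feeding_period;
  double break_weight;
  int record_first, record_every;
  double max_hours;
};

Config read_config(const List& cfg) {
  Config c;
  c.capacity = as<int>(cfg["capacity"]);
  c.initial_pop = as<int>(cfg["initial_pop"]);
  c.init_cell = as<int>(cfg["initial_cellularity_genes"]);
  c.cfn = as<int>(cfg["cellularity_fn"]);
  c.interval = as<int>(cfg["interval"]);
  c.prof_n = as<int>(cfg["proficiency_n_puzzles"]);
  c.energy_unlimited = as<bool>(cfg["energy_unlimited"]);
  c.energy_parcels = as<int>(cfg["energy_parcels"]);
  c.parcel_size = as<double>(cfg["parcel_size"]);
  c.food_replenished = as<bool>(cfg["food_replenished"]);
  c.food_rate = as<int>(cfg["food_replenish_rate"]);
  c.food_cap = as<int>(cfg["food_cap"]);
  c.food_stock0 = as<int>(cfg["food_initial_stock"]);
  c.r_ins = as<double>(cfg["rate_insertion"]);
  c.r_del = as<double>(cfg["rate_deletion"]);
  c.r_ptr = as<double>(cfg["rate_pointer"]);
  c.gene_coeff = as<double>(cfg["gene_coefficient"]);
  c.energy_coeff = as<double>(cfg["energy_coefficient"]);
  c.food_coeff = as<double>(cfg["food_coefficient"]);
  c.gene_override = as<double>(cfg["gene_transfer_override"]);
  c.energy_override = as<double>(cfg["energy_transfer_override"]);
  c.food_override = as<double>(cfg["food_transfer_override"]);
  c.extra_cost = as<bool>(cfg["replication_extra_cost"]);
  c.consume = as<bool>(cfg["consume_energy"]);
  c.rewards = as<bool>(cfg["rewards_enabled"]);
  c.feeding_period = as<int>(cfg["feeding_period"]);
  c.replication = as<bool>(cfg["replication_enabled"]);
  c.break_weight = as<double>(cfg["break_weight"]);
  c.record_first = as<int>(cfg["record_first"]);
  c.record_every = as<int>(cfg["record_every"]);
  c.max_hours = as<double>(cfg["max_hours"]);
  return c;
}

struct Org {
  long id;
  Genome g;
  double energy, imp, prof;
  bool has_puzzle;
  int puz[8];
  int head;
  std::vector<int> slots;
  int out[8];
  int out_written[8];
  int stockpile;
  long fed;  // index of the last feeding window in which a puzzle was taken
};

struct Counters {
  double reward = 0, consumed = 0, death_energy = 0, cull_energy = 0,
         discarded_energy = 0, extra_cost_paid = 0;
  long births = 0, deaths = 0, culled = 0;
  long gene_fired = 0, gene_gain = 0, gene_loss = 0;
  long energy_fired = 0, energy_gain = 0, energy_loss = 0;
  long food_fired = 0, food_gain = 0, food_loss = 0;
};

struct Engine {
  Config c;
  long t = 0, x = 0, next_id = 1;
  std::vector<Org> orgs;
  std::vector<double> parcels;  // finite energy pool
  Genome gpool;
  int food_stock = 0;
  Counters n;
  std::vector<double> tr_step, tr_pop, tr_imp, tr_prof, tr_len, tr_etot,
      tr_pcount, tr_gpool, tr_x;
};

double event_prob(double imp, double coeff, double override_) {
  return override_ >= 0 ? override_ : coeff * (1.0 - imp);
}

void reset_exec(Org& o) {
  o.head = 0;
  o.slots.assign(o.g.size(), 0);
  for (int k = 0; k < 8; ++k) {
    o.out[k] = 0;
    o.out_written[k] = 0;
  }
}

void give_puzzle(Org& o) {
  for (int k = 0; k < 8; ++k) o.puz[k] = coin(0.5) ? 1 : 0;
  o.has_puzzle = true;
}

void exec_one(Org& o) {
  const Gene& gn = o.g[o.head];
  int v = 0;
  switch (gn.kind) {
  case GENE_INPUT:
    v = o.puz[gn.a];
    break;
  case GENE_OUTPUT:
    v = gn.b >= 0 ? o.slots[gn.b] : 0;
    o.out[gn.a] = v;
    o.out_written[gn.a] = 1;
    break;
  case GENE_NAND: {
    int va = gn.a >= 0 ? o.slots[gn.a] : 0;
    int vb = gn.b >= 0 ? o.slots[gn.b] : 0;
    v = (va && vb) ? 0 : 1;
    break;
  }
  default:
    v = o.head > 0 ? o.slots[o.head - 1] : 0;
  }
  o.slots[o.head] = v;
  ++o.head;
}

void energy_transfer(Org& o, Engine& e) {
  double p = event_prob(o.imp, e.c.energy_coeff, e.c.energy_override);
  if (!coin(p)) return;
  ++e.n.energy_fired;
  if (coin(0.5)) {  // loss: a uniform fraction of the store leaves as a parcel
    ++e.n.energy_loss;
    double amt = unif_rand() * o.energy;
    o.energy -= amt;
    if (e.c.energy_unlimited) e.n.discarded_energy += amt;
    else e.parcels.push_back(amt);
  } else {  // gain: one parcel drawn uniformly from the pool
    ++e.n.energy_gain;
    if (e.c.energy_unlimited) {
      o.energy += e.c.parcel_size;
    } else if (!e.parcels.empty()) {
      int k = runif_int(static_cast<int>(e.parcels.size()));
      o.energy += e.parcels[k];
      e.parcels[k] = e.parcels.back();
      e.parcels.pop_back();
    }
  }
}

void init_engine(Engine& e) {
  const Config& c = e.c;
  for (int i = 0; i < c.initial_pop; ++i) {
    Org o;
    o.id = e.next_id++;
    o.g = founder_genome(c.init_cell);
    o.energy = 2.0 * o.g.size();
    o.imp = impermeability_value(count_cellularity(o.g), c.cfn);
    o.prof = proficiency(o.g, c.prof_n);
    o.has_puzzle = false;
    o.stockpile = 0;
    o.fed = -1;
    reset_exec(o);
    e.orgs.push_back(o);
  }
  if (!c.energy_unlimited)
    e.parcels.assign(c.energy_parcels, c.parcel_size);
  e.food_stock = c.food_stock0;
}

void record(Engine& e, long s) {
  double mi = 0, mp = 0, ml = 0;
  for (const Org& o : e.orgs) {
    mi += o.imp;
    mp += o.prof;
    ml += static_cast<double>(o.g.size());
  }
  double np = static_cast<double>(e.orgs.size());
  e.tr_step.push_back(static_cast<double>(s));
  e.tr_pop.push_back(np);
  e.tr_imp.push_back(mi / np);
  e.tr_prof.push_back(mp / np);
  e.tr_len.push_back(ml / np);
  if (e.c.energy_unlimited) {
    e.tr_etot.push_back(R_PosInf);
    e.tr_pcount.push_back(R_PosInf);
  } else {
    double tot = 0;
    for (double a : e.parcels) tot += a;
    e.tr_etot.push_back(tot);
    e.tr_pcount.push_back(static_cast<double>(e.parcels.size()));
  }
  e.tr_gpool.push_back(static_cast<double>(e.gpool.size()));
  e.tr_x.push_back(static_cast<double>(e.x));
}

std::string run_steps(Engine& e, long n_steps) {
  const Config& c = e.c;
  auto start = std::chrono::steady_clock::now();
  for (long k = 0; k < n_steps; ++k) {
    if (e.orgs.empty()) return "extinct";
    long s = e.t + 1;

    // (1) food acquisition, capped at one puzzle per organism per
    // feeding period; organisms with an empty genome cannot process food
    // and never acquire a puzzle.
    long window = (s - 1) / c.feeding_period;
    for (Org& o : e.orgs) {
      if (o.has_puzzle || o.g.empty() || o.fed >= window) continue;
      if (!c.food_replenished) {
        give_puzzle(o);
        o.fed = window;
      } else if (o.stockpile > 0) {
        --o.stockpile;
        give_puzzle(o);
        o.fed = window;
      }
    }

    // (2) one instruction per organism holding a puzzle; everyone consumes
    // one unit of processing energy.
    for (Org& o : e.orgs) {
      if (o.has_puzzle && o.head < static_cast<int>(o.g.size())) exec_one(o);
      if (c.consume) {
        o.energy -= 1.0;
        e.n.consumed += 1.0;
      }
    }

    // (3) completed executions earn the density-adjusted reward.
    for (Org& o : e.orgs) {
      if (o.has_puzzle && o.head >= static_cast<int>(o.g.size())) {
        // Only register positions actually written by an OUTPUT gene can
        // count as correct.
        int ncorr = 0;
        for (int i = 0; i < 8; ++i)
          if (o.out_written[i] && o.out[i] == 1 - o.puz[i]) ++ncorr;
        if (c.rewards) {
          double r = static_cast<double>(ncorr) * ncorr * ncorr -
                     0.1 * static_cast<double>(e.x);
          if (r > 0) {
            o.energy += r;
            e.n.reward += r;
          }
        }
        o.has_puzzle = false;
        reset_exec(o);
      }
    }

    // (4) death at zero or negative energy.
    {
      std::vector<Org> alive;
      alive.reserve(e.orgs.size());
      for (Org& o : e.orgs) {
        if (o.energy > 0) {
          alive.push_back(std::move(o));
        } else {
          ++e.n.deaths;
          e.n.death_energy += o.energy;
        }
      }
      e.orgs.swap(alive);
    }

    // (5) replication at 4L stored energy.
    if (c.replication) {
      size_t n0 = e.orgs.size();
      for (size_t i = 0; i < n0; ++i) {
        int L = static_cast<int>(e.orgs[i].g.size());
        if (L < 1) continue;
        if (e.orgs[i].energy < 4.0 * L) continue;
        double extra = c.extra_cost ? 2.0 * L : 0.0;
        double E = e.orgs[i].energy - extra;
        e.n.extra_cost_paid += extra;
        Org child = e.orgs[i];  // copies genome and cached proficiency
        child.id = e.next_id++;
        child.energy = E / 2.0;
        child.has_puzzle = false;
        reset_exec(child);
        child.stockpile = e.orgs[i].stockpile / 2;
        e.orgs.push_back(child);  // may invalidate references, not indices
        Org& p = e.orgs[i];
        p.id = e.next_id++;
        p.energy = E / 2.0;
        p.has_puzzle = false;
        reset_exec(p);
        p.stockpile -= child.stockpile;
        e.n.births += 2;
      }
    }

    // (6) interval events: mutation, gene / energy / food transfers, then a
    // proficiency retest and impermeability update if the genome changed.
    if (s % c.interval == 0) {
      for (Org& o : e.orgs) {
        bool changed = mutate_genome(o.g, c.r_ins, c.r_del, c.r_ptr);
        int fired, dir;
        double pg = event_prob(o.imp, c.gene_coeff, c.gene_override);
        if (gene_transfer(o.g, e.gpool, pg, c.break_weight, &fired, &dir))
          changed = true;
        if (fired) {
          ++e.n.gene_fired;
          if (dir < 0) ++e.n.gene_loss; else ++e.n.gene_gain;
        }
        energy_transfer(o, e);
        if (c.food_replenished) {
          double pf = event_prob(o.imp, c.food_coeff, c.food_override);
          if (coin(pf)) {
            ++e.n.food_fired;
            if (coin(0.5)) {  // loss: one stockpiled puzzle back to the pool
              if (o.stockpile > 0) {
                --o.stockpile;
                ++e.n.food_loss;
                if (e.food_stock < c.food_cap) ++e.food_stock;
              }
            } else {  // gain
              if (e.food_stock > 0) {
                --e.food_stock;
                ++o.stockpile;
                ++e.n.food_gain;
              }
            }
          }
        }
        if (changed) {
          o.imp = impermeability_value(count_cellularity(o.g), c.cfn);
          o.prof = proficiency(o.g, c.prof_n);
          reset_exec(o);  // the current puzzle, if any, is retained
        }
      }
      if (c.food_replenished)
        e.food_stock = std::min(c.food_cap, e.food_stock + c.food_rate);
    }

    // (7) cull uniformly at random down to capacity.
    while (static_cast<int>(e.orgs.size()) > c.capacity) {
      int j = runif_int(static_cast<int>(e.orgs.size()));
      ++e.n.culled;
      e.n.cull_energy += e.orgs[j].energy;
      e.orgs[j] = std::move(e.orgs.back());
      e.orgs.pop_back();
    }

    // (8) density-dependent reward reduction factor.
    {
      double pop = static_cast<double>(e.orgs.size());
      if (pop > 0.85 * c.capacity) ++e.x;
      else if (pop < 0.25 * c.capacity && e.x > 0) --e.x;
    }

    e.t = s;

    // (9) recording schedule: first at record_first, then every record_every.
    if (!e.orgs.empty() &&
        (s == c.record_first ||
         (s > c.record_first && (s - c.record_first) % c.record_every == 0)))
      record(e, s);

    if (e.orgs.empty()) return "extinct";
    if ((k & 255) == 0) {
      double hours = std::chrono::duration<double>(
                         std::chrono::steady_clock::now() - start).count() /
                     3600.0;
      if (hours > c.max_hours) return "wallclock";
    }
  }
  return "done";
}

List export_state(const Engine& e) {
  List orgs(e.orgs.size());
  for (size_t i = 0; i < e.orgs.size(); ++i) {
    const Org& o = e.orgs[i];
    IntegerVector puz(8), out(8);
    LogicalVector wr(8);
    for (int k = 0; k < 8; ++k) {
      puz[k] = o.puz[k];
      out[k] = o.out[k];
      wr[k] = o.out_written[k] == 1;
    }
    orgs[i] = List::create(
        _["id"] = static_cast<double>(o.id), _["genome"] = genome_to_R(o.g),
        _["energy"] = o.energy, _["impermeability"] = o.imp,
        _["proficiency"] = o.prof, _["has_puzzle"] = o.has_puzzle,
        _["puzzle"] = puz, _["read_head"] = o.head, _["slots"] = wrap(o.slots),
        _["output_register"] = out, _["output_written"] = wr,
        _["food_stockpile"] = o.stockpile,
        _["fed_window"] = static_cast<double>(o.fed));
  }
  return List::create(
      _["t"] = static_cast<double>(e.t), _["x"] = static_cast<double>(e.x),
      _["next_id"] = static_cast<double>(e.next_id), _["organisms"] = orgs,
      _["energy_parcels"] = wrap(e.parcels),
      _["gene_pool"] = genome_to_R(e.gpool), _["food_stock"] = e.food_stock);
}

void import_state(Engine& e, const List& st) {
  e.t = static_cast<long>(as<double>(st["t"]));
  e.x = static_cast<long>(as<double>(st["x"]));
  e.next_id = static_cast<long>(as<double>(st["next_id"]));
  List orgs = st["organisms"];
  for (int i = 0; i < orgs.size(); ++i) {
    List ol = orgs[i];
    Org o;
    o.id = static_cast<long>(as<double>(ol["id"]));
    o.g = genome_from_R(as<IntegerMatrix>(ol["genome"]));
    o.energy = as<double>(ol["energy"]);
    o.imp = impermeability_value(count_cellularity(o.g), e.c.cfn);
    o.prof = as<double>(ol["proficiency"]);
    o.has_puzzle = as<bool>(ol["has_puzzle"]);
    IntegerVector puz = ol["puzzle"], out = ol["output_register"];
    LogicalVector wr = ol["output_written"];
    for (int k = 0; k < 8; ++k) {
      o.puz[k] = puz[k];
      o.out[k] = out[k];
      o.out_written[k] = wr[k] ? 1 : 0;
    }
    o.head = as<int>(ol["read_head"]);
    o.slots = as<std::vector<int> >(ol["slots"]);
    o.slots.resize(o.g.size(), 0);
    o.stockpile = as<int>(ol["food_stockpile"]);
    o.fed = static_cast<long>(as<double>(ol["fed_window"]));
    e.orgs.push_back(o);
  }
  e.parcels = as<std::vector<double> >(st["energy_parcels"]);
  e.gpool = genome_from_R(as<IntegerMatrix>(st["gene_pool"]));
  e.food_stock = as<int>(st["food_stock"]);
}

List export_counters(const Counters& n) {
  return List::create(
      _["reward"] = n.reward, _["consumed"] = n.consumed,
      _["death_energy"] = n.death_energy, _["cull_energy"] = n.cull_energy,
      _["discarded_energy"] = n.discarded_energy,
      _["extra_cost_paid"] = n.extra_cost_paid,
      _["births"] = static_cast<double>(n.births),
      _["deaths"] = static_cast<double>(n.deaths),
      _["culled"] = static_cast<double>(n.culled),
      _["gene_events"] = static_cast<double>(n.gene_fired),
      _["gene_gain"] = static_cast<double>(n.gene_gain),
      _["gene_loss"] = static_cast<double>(n.gene_loss),
      _["energy_events"] = static_cast<double>(n.energy_fired),
      _["energy_gain"] = static_cast<double>(n.energy_gain),
      _["energy_loss"] = static_cast<double>(n.energy_loss),
      _["food_events"] = static_cast<double>(n.food_fired),
      _["food_gain"] = static_cast<double>(n.food_gain),
      _["food_loss"] = static_cast<double>(n.food_loss));
}

}  // namespace

// [[Rcpp::export]]
List cpp_run(List config, double n_steps, Nullable<List> state) {
  Engine e;
  e.c = read_config(config);
  if (state.isNotNull())
    import_state(e, List(state));
  else
    init_engine(e);
  std::string status = run_steps(e, static_cast<long>(n_steps));
  DataFrame trace = DataFrame::create(
      _["step"] = wrap(e.tr_step), _["population_size"] = wrap(e.tr_pop),
      _["mean_impermeability"] = wrap(e.tr_imp),
      _["mean_proficiency"] = wrap(e.tr_prof),
      _["mean_genome_length"] = wrap(e.tr_len),
      _["env_energy_total"] = wrap(e.tr_etot),
      _["env_parcel_count"] = wrap(e.tr_pcount),
      _["gene_pool_size"] = wrap(e.tr_gpool),
      _["reduction_factor"] = wrap(e.tr_x));
  return List::create(_["state"] = export_state(e), _["trace"] = trace,
                      _["counters"] = export_counters(e.n),
                      _["status"] = status);
}

// [[Rcpp::export]]
List cpp_energy_transfer_event(double energy, NumericVector parcels,
                               bool unlimited, double parcel_size,
                               double prob) {
  Engine e;
  e.c.energy_unlimited = unlimited;
  e.c.parcel_size = parcel_size;
  e.c.energy_coeff = 1.0;
  e.c.energy_override = prob;
  e.parcels = as<std::vector<double> >(parcels);
  Org o;
  o.energy = energy;
  o.imp = 0;
  long fired0 = 0;
  energy_transfer(o, e);
  fired0 = e.n.energy_fired;
  return List::create(_["energy"] = o.energy, _["parcels"] = wrap(e.parcels),
                      _["fired"] = fired0 > 0,
                      _["direction"] = e.n.energy_loss > 0
                                           ? -1
                                           : (e.n.energy_gain > 0 ? 1 : 0),
                      _["discarded"] = e.n.discarded_energy);
}
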