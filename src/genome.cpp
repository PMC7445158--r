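#include "core.h"

using namespace Rcpp;

namespace cellmet {

Genome founder_genome(int n_cell) {
  Genome g;
  g.reserve(32 + n_cell);
  // 8 input genes reading puzzle bits 0..7, one each.
  for (int k = 0; k < 8; ++k) g.push_back(Gene{GENE_INPUT, k, -1});
  // 16 NAND genes with operands drawn uniformly from preceding positions:
  // the founder network is a random Boolean circuit.
  for (int i = 0; i < 16; ++i) {
    int p = static_cast<int>(g.size());
    g.push_back(Gene{GENE_NAND, runif_int(p), runif_int(p)});
  }
  // 8 output genes writing registers 0..7, source initialized to the
  // immediately preceding position.
  for (int k = 0; k < 8; ++k) {
    int p = static_cast<int>(g.size());
    g.push_back(Gene{GENE_OUTPUT, k, p - 1});
  }
  for (int c = 0; c < n_cell; ++c) g.push_back(Gene{GENE_CELL, -1, -1});
  return g;
}

void evaluate_genome(const Genome& g, const int* input, int* out,
                     int* written) {
  const int L = static_cast<int>(g.size());
  std::vector<int> slots(L, 0);
  for (int k = 0; k < 8; ++k) {
    out[k] = 0;
    written[k] = 0;
  }
  for (int i = 0; i < L; ++i) {
    const Gene& gn = g[i];
    int v = 0;
    switch (gn.kind) {
    case GENE_INPUT:
      v = input[gn.a];
      break;
    case GENE_OUTPUT:
      v = gn.b >= 0 ? slots[gn.b] : 0;
      out[gn.a] = v;
      written[gn.a] = 1;
      break;
    case GENE_NAND: {
      int va = gn.a >= 0 ? slots[gn.a] : 0;
      int vb = gn.b >= 0 ? slots[gn.b] : 0;
      v = (va && vb) ? 0 : 1;
      break;
    }
    default:  // CELLULARITY passes through the preceding value
      v = i > 0 ? slots[i - 1] : 0;
    }
    slots[i] = v;
  }
}

int count_cellularity(const Genome& g) {
  int n = 0;
  for (const Gene& gn : g)
    if (gn.kind == GENE_CELL) ++n;
  return n;
}

double impermeability_value(int n_cell, int fn) {
  switch (fn) {
  case 0: return 1.0 - std::pow(0.5, n_cell);              // standard
  case 1: return std::pow(0.5, n_cell);                    // reverse
  default: return std::min(1.0, 0.25 * n_cell);            // linear
  }
}

double proficiency(const Genome& g, int n_puzzles) {
  double total = 0.0;
  int in[8], out[8], written[8];
  for (int t = 0; t < n_puzzles; ++t) {
    for (int k = 0; k < 8; ++k) in[k] = coin(0.5) ? 1 : 0;
    evaluate_genome(g, in, out, written);
    int n = 0;
    // A register position never written by an OUTPUT gene is not a solved
    // bit: accuracy counts written, matching positions only.
    for (int k = 0; k < 8; ++k)
      if (written[k] && out[k] == 1 - in[k]) ++n;
    total += n;
  }
  return total / n_puzzles;
}

void remap_field(int& field, int self_pos, const std::vector<int>& posmap) {
  if (field < 0) return;
  int t = field < static_cast<int>(posmap.size()) ? posmap[field] : -1;
  if (t >= 0 && t < self_pos) {
    field = t;
  } else {
    // Target deleted or no longer preceding: redraw uniformly over the valid
    // range, or unset for a gene at position 0.
    field = self_pos == 0 ? -1 : runif_int(self_pos);
  }
}

void revalidate_gene(Gene& gn, int pos) {
  switch (gn.kind) {
  case GENE_INPUT:
    if (gn.a < 0 || gn.a > 7) gn.a = runif_int(8);
    gn.b = -1;
    break;
  case GENE_OUTPUT:
    if (gn.a < 0 || gn.a > 7) gn.a = runif_int(8);
    if (gn.b >= pos) gn.b = pos == 0 ? -1 : runif_int(pos);
    break;
  case GENE_NAND:
    if (gn.a >= pos) gn.a = pos == 0 ? -1 : runif_int(pos);
    if (gn.b >= pos) gn.b = pos == 0 ? -1 : runif_int(pos);
    break;
  default:
    gn.a = gn.b = -1;
  }
}

bool mutate_genome(Genome& g, double r_ins, double r_del, double r_ptr) {
  const int L = static_cast<int>(g.size());
  if (L == 0) return false;
  // Three independent per-site draws, one per mutation type.
  std::vector<char> del(L), ins(L), ptr(L);
  for (int i = 0; i < L; ++i) {
    ins[i] = coin(r_ins);
    del[i] = coin(r_del);
    ptr[i] = coin(r_ptr);
  }
  Genome ng;
  std::vector<int> posmap(L, -1);     // old position -> new position
  std::vector<int> src;               // old index per new gene; -1 = fresh insert
  std::vector<char> ptr_new;          // pointer-mutation flag at new position
  for (int i = 0; i < L; ++i) {
    if (ins[i]) {  // fresh random gene inserted immediately before site i
      ng.push_back(Gene{0, 0, 0});
      src.push_back(-1);
      ptr_new.push_back(0);
    }
    if (!del[i]) {
      posmap[i] = static_cast<int>(ng.size());
      ng.push_back(g[i]);
      src.push_back(i);
      ptr_new.push_back(ptr[i]);
    }
  }
  // Pointer maintenance after the structural edits.
  for (int j = 0; j < static_cast<int>(ng.size()); ++j) {
    Gene& gn = ng[j];
    if (src[j] < 0) {  // draw the inserted gene de novo at its final position
      gn.kind = runif_int(4);
      gn.a = gn.b = -1;
      if (gn.kind == GENE_INPUT) {
        gn.a = runif_int(8);
      } else if (gn.kind == GENE_OUTPUT) {
        gn.a = runif_int(8);
        gn.b = j == 0 ? -1 : runif_int(j);
      } else if (gn.kind == GENE_NAND) {
        gn.a = j == 0 ? -1 : runif_int(j);
        gn.b = j == 0 ? -1 : runif_int(j);
      }
    } else {
      if (gn.kind == GENE_OUTPUT) {
        remap_field(gn.b, j, posmap);
      } else if (gn.kind == GENE_NAND) {
        remap_field(gn.a, j, posmap);
        remap_field(gn.b, j, posmap);
      }
    }
  }
  // Pointer reassignment, applied in the new coordinates: re-draw one
  // uniformly chosen pointer-like field of the mutated gene.
  for (int j = 0; j < static_cast<int>(ng.size()); ++j) {
    if (!ptr_new[j]) continue;
    Gene& gn = ng[j];
    switch (gn.kind) {
    case GENE_INPUT:
      gn.a = runif_int(8);
      break;
    case GENE_OUTPUT:
      if (coin(0.5)) gn.a = runif_int(8);
      else gn.b = j == 0 ? -1 : runif_int(j);
      break;
    case GENE_NAND: {
      int& f = coin(0.5) ? gn.a : gn.b;
      f = j == 0 ? -1 : runif_int(j);
      break;
    }
    default:
      break;  // cellularity genes carry no pointer-like fields
    }
  }
  bool changed = ng.size() != g.size();
  if (!changed) {
    for (size_t i = 0; i < ng.size(); ++i) {
      if (!(ng[i] == g[i])) { changed = true; break; }
    }
  }
  g.swap(ng);
  return changed;
}

std::vector<int> fragment_ids(const Genome& g, double break_weight) {
  std::vector<int> id(g.size(), 0);
  int cur = 0;
  for (size_t i = 1; i < g.size(); ++i) {
    if (coin(break_weight)) ++cur;
    id[i] = cur;
  }
  return id;
}

bool gene_transfer(Genome& g, Genome& pool, double prob, double break_weight,
                   int* fired, int* direction) {
  *fired = 0;
  *direction = 0;
  if (!coin(prob)) return false;
  *fired = 1;
  bool loss = coin(0.5);
  *direction = loss ? -1 : 1;
  if (loss) {
    if (g.empty()) return false;
    std::vector<int> id = fragment_ids(g, break_weight);
    int nseg = id.back() + 1;
    int k = runif_int(nseg);
    Genome ng;
    std::vector<int> posmap(g.size(), -1);
    for (size_t i = 0; i < g.size(); ++i) {
      if (id[i] == k) {
        pool.push_back(g[i]);
      } else {
        posmap[i] = static_cast<int>(ng.size());
        ng.push_back(g[i]);
      }
    }
    for (int j = 0; j < static_cast<int>(ng.size()); ++j) {
      Gene& gn = ng[j];
      if (gn.kind == GENE_OUTPUT) {
        remap_field(gn.b, j, posmap);
      } else if (gn.kind == GENE_NAND) {
        remap_field(gn.a, j, posmap);
        remap_field(gn.b, j, posmap);
      }
    }
    g.swap(ng);
    return true;
  }
  // Gain: insert one pool gene at a uniformly chosen fragmentation break point.
  if (pool.empty()) return false;
  int pos;
  if (g.empty()) {
    pos = 0;
  } else {
    std::vector<int> id = fragment_ids(g, break_weight);
    std::vector<int> breaks;
    for (size_t i = 1; i < g.size(); ++i)
      if (id[i] != id[i - 1]) breaks.push_back(static_cast<int>(i));
    if (breaks.empty()) return false;  // genome did not break: no insertion site
    pos = breaks[runif_int(static_cast<int>(breaks.size()))];
  }
  int pi = runif_int(static_cast<int>(pool.size()));
  Gene gn = pool[pi];
  pool[pi] = pool.back();
  pool.pop_back();
  revalidate_gene(gn, pos);
  g.insert(g.begin() + pos, gn);
  for (int j = pos + 1; j < static_cast<int>(g.size()); ++j) {
    Gene& gg = g[j];
    if (gg.kind == GENE_OUTPUT) {
      if (gg.b >= pos) ++gg.b;
    } else if (gg.kind == GENE_NAND) {
      if (gg.a >= pos) ++gg.a;
      if (gg.b >= pos) ++gg.b;
    }
  }
  return true;
}

Genome genome_from_R(const IntegerMatrix& m) {
  Genome g;
  g.reserve(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) {
    Gene gn;
    gn.kind = m(i, 0) - 1;
    gn.a = m(i, 1) == NA_INTEGER ? -1 : m(i, 1);
    gn.b = m(i, 2) == NA_INTEGER ? -1 : m(i, 2);
    g.push_back(gn);
  }
  return g;
}

IntegerMatrix genome_to_R(const Genome& g) {
  IntegerMatrix m(static_cast<int>(g.size()), 3);
  for (int i = 0; i < static_cast<int>(g.size()); ++i) {
    m(i, 0) = g[i].kind + 1;
    m(i, 1) = g[i].a < 0 ? NA_INTEGER : g[i].a;
    m(i, 2) = g[i].b < 0 ? NA_INTEGER : g[i].b;
  }
  colnames(m) = CharacterVector::create("kind", "a", "b");
  return m;
}

}  // namespace cellmet

using namespace cellmet;

// [[Rcpp::export]]
IntegerMatrix cpp_founder_genome(int n_cellularity) {
  return genome_to_R(founder_genome(n_cellularity));
}

// [[Rcpp::export]]
IntegerVector cpp_evaluate(IntegerMatrix genome, IntegerVector input) {
  Genome g = genome_from_R(genome);
  int in[8], out[8], written[8];
  for (int k = 0; k < 8; ++k) in[k] = input[k];
  evaluate_genome(g, in, out, written);
  IntegerVector res(8);
  LogicalVector wr(8);
  for (int k = 0; k < 8; ++k) {
    res[k] = out[k];
    wr[k] = written[k] == 1;
  }
  res.attr("written") = wr;
  return res;
}

// [[Rcpp::export]]
double cpp_measure_proficiency(IntegerMatrix genome, int n_puzzles) {
  Genome g = genome_from_R(genome);
  return proficiency(g, n_puzzles);
}

// [[Rcpp::export]]
List cpp_mutate(IntegerMatrix genome, double r_ins, double r_del, double r_ptr) {
  Genome g = genome_from_R(genome);
  bool changed = mutate_genome(g, r_ins, r_del, r_ptr);
  return List::create(_["genome"] = genome_to_R(g), _["changed"] = changed);
}

// [[Rcpp::export]]
IntegerVector cpp_fragment_ids(IntegerMatrix genome, double break_weight) {
  Genome g = genome_from_R(genome);
  std::vector<int> id = fragment_ids(g, break_weight);
  return wrap(id);
}

// [[Rcpp::export]]
List cpp_gene_transfer_event(IntegerMatrix genome, IntegerMatrix pool,
                             double prob, double break_weight) {
  Genome g = genome_from_R(genome);
  Genome p = genome_from_R(pool);
  int fired, dir;
  bool changed = gene_transfer(g, p, prob, break_weight, &fired, &dir);
  return List::create(_["genome"] = genome_to_R(g), _["pool"] = genome_to_R(p),
                      _["fired"] = fired == 1, _["direction"] = dir,
                      _["changed"] = changed);
}

// [[Rcpp::export]]
double cpp_impermeability(int n_cellularity, int fn) {
  return impermeability_value(n_cellularity, fn);
}
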