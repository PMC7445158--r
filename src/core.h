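#ifndef CELLMET_CORE_H
#define CELLMET_CORE_H

#include <Rcpp.h>
#include <vector>

namespace cellmet {

// Gene kinds (0-based here; the R side uses 1-based codes).
enum GeneKind { GENE_INPUT = 0, GENE_OUTPUT = 1, GENE_NAND = 2, GENE_CELL = 3 };

// a/b meaning by kind:
//   INPUT:       a = puzzle input index (0..7),  b unused (-1)
//   OUTPUT:      a = output register index,      b = source pointer (-1 unset)
//   NAND:        a = operand position,           b = operand position (-1 unset)
//   CELLULARITY: both unused (-1)
// Pointer-valued fields hold absolute 0-based genome positions and must be
// strictly smaller than the gene's own position; -1 reads as value 0.
struct Gene {
  int kind, a, b;
};

inline bool operator==(const Gene& x, const Gene& y) {
  return x.kind == y.kind && x.a == y.a && x.b == y.b;
}

typedef std::vector<Gene> Genome;

// All randomness flows through R's RNG so that set.seed() in R makes every
// simulation reproducible end to end.
inline int runif_int(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}
inline bool coin(double p) { return unif_rand() < p; }

Genome founder_genome(int n_cell);
// out: the 8-bit output register (zero-initialized); written: 1 where an
// OUTPUT gene actually wrote the position during this execution.
void evaluate_genome(const Genome& g, const int* input, int* out,
                     int* written);
int count_cellularity(const Genome& g);
double impermeability_value(int n_cell, int fn);  // fn: 0 standard, 1 reverse, 2 linear
double proficiency(const Genome& g, int n_puzzles);
bool mutate_genome(Genome& g, double r_ins, double r_del, double r_ptr);
std::vector<int> fragment_ids(const Genome& g, double break_weight);
void remap_field(int& field, int self_pos, const std::vector<int>& posmap);
void revalidate_gene(Gene& gn, int pos);
bool gene_transfer(Genome& g, Genome& pool, double prob, double break_weight,
                   int* fired, int* direction);

Genome genome_from_R(const Rcpp::IntegerMatrix& m);
Rcpp::IntegerMatrix genome_to_R(const Genome& g);

}  // namespace cellmet

#endif
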