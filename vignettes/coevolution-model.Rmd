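---
title: "The coevolution model: organisms, energy economy and drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coevolution model: organisms, energy economy and drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmet)
```

# The model

`cellmet` simulates populations of digital organisms in which two traits
coevolve: **cellular impermeability** — a membrane-like property that gates
stochastic exchange of genes and energy with a shared environment — and
**metabolic proficiency** — the accuracy with which an organism's Boolean
logic-gate genome converts food into processing energy.  The package also
contains a standalone **directional-drift** model of a trait that lowers its
own mutation rate.

## Genomes and metabolism

A genome is an ordered list of genes of four kinds.  INPUT genes read one of
the eight bits of the current food puzzle; NAND genes compute NOT-AND of the
stored values of two strictly earlier genes; OUTPUT genes copy the stored
value of an earlier gene into one of eight output-register positions;
CELLULARITY genes have no metabolic function — their count $n$ sets the
organism's impermeability through a configurable cellularity function
(`impermeability()`):

* standard: $1 - 0.5^n$,
* reverse: $0.5^n$ (cellularity imposed by the environment; genes open the
  cell),
* linear: $\min(1, 0.25\,n)$ (clamped at 1 from $n = 4$; the function is
  never evaluated above $n = 3$ in the standard scenarios).

A food puzzle is a random 8-bit register whose solution is its bitwise
complement.  Execution is sequential: a read head executes one gene per time
step, storing each gene's value in its own slot.  Pointers are absolute
0-based genome positions constrained to strictly preceding positions; a
pointer whose target is unset reads the value 0, which gives total,
crash-free execution semantics under arbitrary mutation.

When the read head reaches the end of the genome, the output register is
scored against the puzzle solution and the organism receives
$\max(0,\, n_c^3 - 0.1 x)$ energy units, where $n_c$ is the number of
correct bits and $x$ a population-level reduction factor that increments by
one on every step in which the population exceeds 85% of capacity and
decrements (floored at 0) below 25%.  The cubic makes accuracy
disproportionately valuable; the reduction factor tightens competition as
the population saturates.

**Scoring rule.**  A register position counts as correct only if an OUTPUT
gene actually wrote it during that execution.  The zero-initialized register
would otherwise credit genomes that write nothing with about four "correct"
bits per execution; under selection this is fatal — single-gene organisms
earn the expected cubic reward of a half-random register at every step and
take over any population within a few hundred steps, which is incompatible
with the sustained 20–50-gene genomes and rising proficiency the model is
meant to produce.  `evaluate_genome()` still returns the raw register (with
a `"written"` attribute), and `count_correct()` remains a plain register
comparison; `measure_proficiency()` and the engine's rewards use the
written-bit rule.

**Feeding cadence.**  An organism may *start* at most one food puzzle per
feeding window (`feeding_period`, default 30 steps).  The window is just
below the founder's 32-instruction metabolic program, so founder-length and
longer genomes metabolize continuously, exactly one instruction per step,
and are never rate-limited.  The cap binds only on genomes shorter than the
window.  Without it, per-step income scales inversely with genome length and
selection collapses every population onto minimal "write-zeros" genomes
(length ~8, proficiency pinned at 4) regardless of the energy regime —
again incompatible with the coevolutionary dynamics the model exists to
study.  With the cap, completion *rate* is equalized and metabolic
*accuracy* is the margin of selection.

## Energy economy, replication and death

Every organism consumes one energy unit per step and dies at zero.  Founders
start with twice their genome length in energy; an organism replicates when
its store reaches four genome lengths, being replaced by two offspring with
identical genomes and half the store each (an optional variant charges an
extra two genome lengths at replication, not passed down).  When the
population exceeds capacity, organisms are removed uniformly at random.

The environment holds three pools.  The **energy pool** is either unlimited
(every gain event yields a 500-unit parcel; deposits are discarded) or
seeded once at step 0 — with 25% of capacity in 500-unit parcels in the
limited-energy scenarios, or a 10,000-parcel burst in the
reversal-of-selection scenario — and never replenished except by organism
losses.  The **free-gene pool** starts empty and collects genes shed by
gene-loss events.  The **food pool** is effectively infinite except in the
cellularity-gated-food variant, where organisms draw from personal
stockpiles replenished only by transfer events.

## Cellularity-gated exchange

Every 100 steps (the interval), each organism is mutated (per-site
insertion, deletion and pointer-reassignment draws, 0.005 each by default)
and exposed to one potential transfer event per channel.  A channel fires
with probability $c\,(1 - \text{impermeability})$ with $c = 0.5$, or with a
constant override of 0 or 1 in the control scenarios; the direction of a
fired event is a fair coin.

* **Gene loss** fragments the genome at inter-gene boundaries (break
  probability 0.1), deposits one uniformly chosen segment — possibly the
  whole genome — into the free-gene pool and re-concatenates the rest,
  remapping pointers.
* **Gene gain** fragments identically and inserts one gene drawn from the
  pool at a uniformly chosen break point, revalidating its pointers.  If
  the pool is empty or the genome happens not to break, the event is a
  no-op.
* **Energy loss** moves a uniform fraction of the current store into a new
  parcel in the pool; **energy gain** draws one parcel.

After any genome change the organism's proficiency is re-measured (1000
random puzzles by default; a smaller sample only adds measurement noise) and
its impermeability recomputed.  Proficiency values are cached per genome
content and inherited by offspring.

## Scheduling details

Each step applies, in order: food acquisition; execution (one instruction
per organism holding a puzzle) and consumption; reward crediting for
completed executions; death; replication; interval events (on every 100th
step, per organism: mutation, gene transfer, energy transfer, food transfer
in the gated variant, then a single retest covering all edits); culling;
the reduction-factor update; and metrics recording.  Metrics are recorded at
step 250 and every 1000 steps thereafter (250, 1250, ...).  Runs terminate
at 100,000 steps, on extinction, or at a wall-clock limit.

Degenerate inputs have defined behaviour: an organism whose genome becomes
empty cannot acquire or process food and does not replicate (the
four-genome-lengths threshold degenerates to zero); it starves on its
remaining store.  Simulations are bit-reproducible given `seed`: all
randomness, including the compiled engine's, flows through R's RNG, and
`advance_step()` resumes a run to the identical trace.

# What the scenarios show

With the published parameters (capacity 500–1000, mutation rates 0.005,
transfer coefficient 0.5) the engine reproduces the qualitative
coevolutionary outcomes: seeded (limited) energy drives mean impermeability
above 80–90% and proficiency toward 5–6.5 from either starting condition,
while unlimited energy drives impermeability toward 0 and holds proficiency
in the random-genome band, and a one-off energy burst produces the
down-then-up impermeability trajectory with partial population survival.
Two caveats: written-bit scoring raises the proficiency floor of drifting
genomes to about 4 (rather than 2–3), slightly compressing proficiency's
dynamic range; and because impermeability saturates faster than proficiency
at moderate capacity, the pooled impermeability–proficiency correlation
across replicate limited-energy runs is strongly positive but typically
0.5–0.7 rather than above 0.8.

# The directional-drift model

The standalone drift model strips away genomes, metabolism and death: a
non-negative integer fidelity value takes a lazy ±1 walk clamped at 0.  A
first mutation channel fires with probability $0.5^x$ (test mode), 0 (min
control) or 1 (max control); a constant second channel (0.1) mimics
insertion/deletion mutations.  Initial fidelity is 0; a decrement at 0
clamps rather than resampling; the state-dependent channel is applied before
the constant one.  `drift_exact_distribution()` propagates the transition
kernel exactly and is the oracle against which the Monte-Carlo ensembles are
chi-square tested.  At step 1000 both control distributions have mode 0 but
are nearly flat near zero (min control: 0.0797 vs 0.0789 at fidelity 0
vs 1), so `modal_fidelity()` can read the mode from a binned histogram — the
raw sample mode of even a $10^6$-walker ensemble is noise-dominated.

```{r drift, eval = FALSE}
set.seed(1)
ens <- run_drift_ensemble("test", n_runs = 1e5, n_steps = 1000)
exact <- drift_exact_distribution("test", n_steps = 1000)
plot(as.integer(names(exact)), exact, type = "h",
     xlab = "fidelity value", ylab = "probability", xlim = c(0, 120))
```

# Problem sizes used by the test suite

The packaged checks run scaled-down versions of the published experiments:
scenario regressions use capacity 500, 20,000 steps and 100–200-puzzle
proficiency measurements with three seeds per condition; the burst scenario
uses ten replicates at capacity 200 with a 2,000-parcel burst; drift
ensembles use $10^5$–$3\times10^5$ walkers.  These sizes preserve the
qualitative regimes (the transitions stabilize well before 20,000 steps at
these capacities) while each run completes in about a second of CPU time.

# Limitations

The model is aspatial by construction.  The feeding cadence and the
written-bit scoring rule are this package's own modelling commitments,
chosen because the literal per-step/raw-register alternatives are
evolutionarily degenerate (see above); both are configurable or inspectable.
The gene-exchange process is asymmetric (segment-sized losses, single-gene
gains), so genomes at zero impermeability erode over long horizons; in the
limited-energy regimes this erosion is precisely the fidelity cost that
selects for cellularity, but it makes very long fully-permeable runs
decline in genome length.  The replenished-food variant's replenishment
rate and stockpile exchange cadence are free parameters with no published
values; defaults are capacity/4 puzzles per interval and a cap equal to
capacity.
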