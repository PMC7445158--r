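#' Simulation configuration
#'
#' Collects every tunable parameter of a population run and fills in the
#' published defaults.  Deviations from the defaults define the scenario
#' presets (see [preset()]).
#'
#' @param capacity maximum population capacity; random culling keeps the
#'   population at or below it.
#' @param initial_pop founding population size; defaults to half the
#'   capacity, between the 25% and 85% reduction-factor thresholds so the
#'   reward factor starts neutral.
#' @param initial_cellularity_genes cellularity genes in each founder genome
#'   (0 or 3 in the standard scenarios).
#' @param cellularity_function one of \code{"standard"}, \code{"reverse"},
#'   \code{"linear"} (see [impermeability()]).
#' @param energy_mode \code{"unlimited"} or \code{"seeded"} (a finite pool
#'   seeded once at step 0 and never replenished except by organism losses).
#' @param energy_parcels number of parcels to seed (seeded mode); defaults to
#'   25% of capacity.
#' @param parcel_size energy units per seeded parcel (500).
#' @param food_mode \code{"unlimited"} or \code{"replenished"}
#'   (cellularity-gated food acquisition through personal stockpiles).
#' @param food_replenish_rate puzzles added to the environmental food pool
#'   per interval (replenished mode); defaults to capacity / 4.
#' @param food_cap,food_initial_stock food-pool cap and initial stock; both
#'   default to the capacity.
#' @param mutation_rates per-site insertion, deletion and pointer rates
#'   (published value 0.005 each).
#' @param gene_coefficient,energy_coefficient,food_coefficient transfer
#'   coefficients multiplied by one minus impermeability (published value
#'   0.5).
#' @param gene_transfer_override,energy_transfer_override,food_transfer_override
#'   optional constants in [0, 1] replacing the cellularity-derived event
#'   probability for that channel; \code{NULL} for no override.
#' @param replication_extra_cost if TRUE, replication additionally costs two
#'   genome lengths of energy, not passed to offspring.
#' @param interval steps between mutation/transfer/retest events (100).
#' @param feeding_period steps per feeding window: an organism starts at
#'   most one food puzzle per window.  The default (30) sits just below the
#'   founder's 32-instruction metabolic program, so founder-length and
#'   longer genomes metabolize continuously, one instruction per step, while
#'   genomes shorter than the window cannot convert food faster than one
#'   puzzle per window -- metabolic accuracy, not genome-completion speed,
#'   is the margin of selection.  See the methods vignette.
#' @param max_steps termination step count (100000).
#' @param max_hours wall-clock termination (100 h).
#' @param proficiency_n_puzzles puzzles per proficiency measurement (1000;
#'   reduce for scaled-down runs).
#' @param break_weight per-boundary fragmentation probability (0.1).
#' @param record_first,record_every metrics recording schedule: first at
#'   step 250, then every 1000 steps (250, 1250, 2250, ...).
#' @param consume_energy,rewards_enabled,replication_enabled diagnostic
#'   switches used by the closed-economy and gene-count conservation checks;
#'   leave TRUE for real simulations.
#' @param seed optional RNG seed applied by [run_sim()].
#' @return A validated \code{cm_config} list.
#' @examples
#' cfg <- sim_config(capacity = 200, max_steps = 500, seed = 1,
#'                   proficiency_n_puzzles = 50)
#' @export
sim_config <- function(capacity = 1000,
                       initial_pop = NULL,
                       initial_cellularity_genes = 0,
                       cellularity_function = "standard",
                       energy_mode = c("unlimited", "seeded"),
                       energy_parcels = NULL,
                       parcel_size = 500,
                       food_mode = c("unlimited", "replenished"),
                       food_replenish_rate = NULL,
                       food_cap = NULL,
                       food_initial_stock = NULL,
                       mutation_rates = c(insertion = 0.005,
                                          deletion = 0.005,
                                          pointer = 0.005),
                       gene_coefficient = 0.5,
                       energy_coefficient = 0.5,
                       food_coefficient = 0.5,
                       gene_transfer_override = NULL,
                       energy_transfer_override = NULL,
                       food_transfer_override = NULL,
                       replication_extra_cost = FALSE,
                       interval = 100,
                       feeding_period = 30,
                       max_steps = 100000,
                       max_hours = 100,
                       proficiency_n_puzzles = 1000,
                       break_weight = 0.1,
                       record_first = 250,
                       record_every = 1000,
                       consume_energy = TRUE,
                       rewards_enabled = TRUE,
                       replication_enabled = TRUE,
                       seed = NULL) {
  energy_mode <- match.arg(energy_mode)
  food_mode <- match.arg(food_mode)
  if (is.null(initial_pop)) initial_pop <- max(1L, capacity %/% 2L)
  if (is.null(energy_parcels)) energy_parcels <- round(0.25 * capacity)
  if (is.null(food_replenish_rate)) food_replenish_rate <- capacity %/% 4L
  if (is.null(food_cap)) food_cap <- capacity
  if (is.null(food_initial_stock)) food_initial_stock <- food_cap
  mutation_rates <- rep_len(as.numeric(mutation_rates), 3L)
  stopifnot(capacity >= 1, initial_pop >= 1, initial_pop <= capacity,
            initial_cellularity_genes >= 0, interval >= 1, max_steps >= 0,
            all(mutation_rates >= 0 & mutation_rates <= 1),
            proficiency_n_puzzles >= 1, feeding_period >= 1,
            break_weight >= 0, break_weight <= 1,
            energy_parcels >= 0, parcel_size >= 0,
            food_initial_stock <= food_cap)
  ovr <- function(v) {
    if (is.null(v) || is.na(v)) return(NULL)
    stopifnot(v %in% c(0, 1))
    v
  }
  cfg <- list(capacity = as.integer(capacity),
              initial_pop = as.integer(initial_pop),
              initial_cellularity_genes = as.integer(initial_cellularity_genes),
              cellularity_function = match.arg(cellularity_function,
                                               c("standard", "reverse",
                                                 "linear")),
              energy_mode = energy_mode,
              energy_parcels = as.integer(energy_parcels),
              parcel_size = as.numeric(parcel_size),
              food_mode = food_mode,
              food_replenish_rate = as.integer(food_replenish_rate),
              food_cap = as.integer(food_cap),
              food_initial_stock = as.integer(food_initial_stock),
              mutation_rates = mutation_rates,
              gene_coefficient = gene_coefficient,
              energy_coefficient = energy_coefficient,
              food_coefficient = food_coefficient,
              gene_transfer_override = ovr(gene_transfer_override),
              energy_transfer_override = ovr(energy_transfer_override),
              food_transfer_override = ovr(food_transfer_override),
              replication_extra_cost = isTRUE(replication_extra_cost),
              interval = as.integer(interval),
              feeding_period = as.integer(feeding_period),
              max_steps = as.integer(max_steps),
              max_hours = as.numeric(max_hours),
              proficiency_n_puzzles = as.integer(proficiency_n_puzzles),
              break_weight = as.numeric(break_weight),
              record_first = as.integer(record_first),
              record_every = as.integer(record_every),
              consume_energy = isTRUE(consume_energy),
              rewards_enabled = isTRUE(rewards_enabled),
              replication_enabled = isTRUE(replication_enabled),
              seed = seed)
  class(cfg) <- "cm_config"
  cfg
}

as_cpp_config <- function(config) {
  ovr <- function(v) if (is.null(v)) -1 else as.numeric(v)
  list(capacity = config$capacity,
       initial_pop = config$initial_pop,
       initial_cellularity_genes = config$initial_cellularity_genes,
       cellularity_fn = cellularity_fn_code(config$cellularity_function),
       interval = config$interval,
       proficiency_n_puzzles = config$proficiency_n_puzzles,
       energy_unlimited = config$energy_mode == "unlimited",
       energy_parcels = config$energy_parcels,
       parcel_size = config$parcel_size,
       food_replenished = config$food_mode == "replenished",
       food_replenish_rate = config$food_replenish_rate,
       food_cap = config$food_cap,
       food_initial_stock = config$food_initial_stock,
       rate_insertion = config$mutation_rates[1L],
       rate_deletion = config$mutation_rates[2L],
       rate_pointer = config$mutation_rates[3L],
       gene_coefficient = config$gene_coefficient,
       energy_coefficient = config$energy_coefficient,
       food_coefficient = config$food_coefficient,
       gene_transfer_override = ovr(config$gene_transfer_override),
       energy_transfer_override = ovr(config$energy_transfer_override),
       food_transfer_override = ovr(config$food_transfer_override),
       replication_extra_cost = config$replication_extra_cost,
       consume_energy = config$consume_energy,
       rewards_enabled = config$rewards_enabled,
       replication_enabled = config$replication_enabled,
       feeding_period = config$feeding_period,
       break_weight = config$break_weight,
       record_first = config$record_first,
       record_every = config$record_every,
       max_hours = config$max_hours)
}

wrap_state <- function(state) {
  state$organisms <- lapply(state$organisms, function(o) {
    o$genome <- as_genome(o$genome)
    o
  })
  class(state) <- "cm_state"
  state
}

unwrap_state <- function(state) {
  state$organisms <- lapply(state$organisms, function(o) {
    o$genome <- unclass(o$genome)
    o
  })
  unclass(state)
}

#' Initialize a simulation population
#'
#' Creates the founding population: \code{initial_pop} organisms, each with
#' an independent founder genome, an energy allocation of twice its genome
#' length, and a metabolic proficiency measured at inception; seeds the
#' environmental pools; sets the reduction factor and step counter to 0.
#'
#' @param config a \code{cm_config} from [sim_config()].
#' @return A \code{cm_state}: list with step counter \code{t}, reduction
#'   factor \code{x}, \code{organisms}, \code{energy_parcels},
#'   \code{gene_pool} and \code{food_stock}.
#' @examples
#' st <- init_population(sim_config(capacity = 20,
#'                                  proficiency_n_puzzles = 20, seed = 1))
#' length(st$organisms)
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "cm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- cpp_run(as_cpp_config(config), 0, NULL)
  wrap_state(res$state)
}

#' Advance a simulation by one or more steps
#'
#' Executes the per-step schedule: food acquisition; one genome instruction
#' per organism holding a puzzle plus one unit of energy consumption each;
#' reward crediting for completed executions; death at zero energy;
#' replication at four genome lengths of stored energy; on every 100th step
#' the interval events (mutation, gene/energy/food transfers, proficiency
#' retest); culling to capacity; the reduction-factor update; and metrics
#' recording on the recording schedule.
#'
#' @param state a \code{cm_state}.
#' @param config the \code{cm_config} the state was created under.
#' @param n_steps number of steps to advance.
#' @return List with the updated \code{state}, the \code{trace} records
#'   produced during these steps, event \code{counters}, and \code{status}
#'   (\code{"done"} or \code{"extinct"}).
#' @export
advance_step <- function(state, config, n_steps = 1) {
  stopifnot(inherits(config, "cm_config"), n_steps >= 0)
  res <- cpp_run(as_cpp_config(config), n_steps, unwrap_state(state))
  list(state = wrap_state(res$state), trace = res$trace,
       counters = res$counters, status = res$status)
}

#' Run a full simulation
#'
#' Iterates the per-step schedule until \code{max_steps} is reached, the
#' population goes extinct, or the wall-clock limit is hit.  Fully
#' reproducible given \code{config$seed}.
#'
#' @param config a \code{cm_config} (see [sim_config()] and [preset()]).
#' @return A \code{cm_sim}: list with the metrics \code{trace} (data frame,
#'   see [write_trace()] for the columns), the \code{final_state}, event
#'   \code{counters}, the termination \code{status} (\code{"max_steps"},
#'   \code{"extinct"} or \code{"wallclock"}), and the \code{config}.
#' @examples
#' sim <- run_sim(sim_config(capacity = 50, max_steps = 300,
#'                           proficiency_n_puzzles = 20, seed = 1))
#' sim$trace
#' @export
run_sim <- function(config) {
  stopifnot(inherits(config, "cm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- cpp_run(as_cpp_config(config), config$max_steps, NULL)
  status <- if (res$status == "done") "max_steps" else res$status
  structure(list(trace = res$trace, final_state = wrap_state(res$state),
                 counters = res$counters, status = status, config = config),
            class = "cm_sim")
}

#' @export
print.cm_sim <- function(x, ...) {
  st <- x$final_state
  cat(sprintf("<simulation: %s at step %d, %d organisms, %d records>\n",
              x$status, as.integer(st$t), length(st$organisms),
              nrow(x$trace)))
  invisible(x)
}

#' Construct an organism
#'
#' @param genome a \code{cm_genome}.
#' @param config a \code{cm_config} providing the cellularity function and
#'   proficiency sample size.
#' @return An organism list: genome, energy (twice the genome length),
#'   impermeability, proficiency, food stockpile.
#' @export
new_organism <- function(genome, config = sim_config()) {
  list(genome = genome,
       energy = 2 * genome_length(genome),
       impermeability = impermeability(n_cellularity_genes(genome),
                                       config$cellularity_function),
       proficiency = measure_proficiency(genome,
                                         config$proficiency_n_puzzles),
       food_stockpile = 0L)
}

#' Replicate an organism
#'
#' Triggered once the parent's store reaches four genome lengths of energy.
#' The parent is replaced by two offspring with genomes identical to the
#' parent's; each receives half of the parent's stored energy (after the
#' optional extra replication cost of two genome lengths, which is not
#' passed down).  Offspring inherit the parent's cached proficiency.
#'
#' @param organism an organism list with at least \code{genome} and
#'   \code{energy}.
#' @param config a \code{cm_config} (for \code{replication_extra_cost}).
#' @return List of the two offspring.
#' @examples
#' org <- list(genome = not_network_genome(), energy = 140, proficiency = 8,
#'             food_stockpile = 0L)
#' sapply(replicate_organism(org, sim_config()), `[[`, "energy")
#' @export
replicate_organism <- function(organism, config = sim_config()) {
  L <- genome_length(organism$genome)
  stopifnot(L >= 1, organism$energy >= 4 * L)
  extra <- if (isTRUE(config$replication_extra_cost)) 2 * L else 0
  E <- organism$energy - extra
  child <- organism
  child$energy <- E / 2
  organism$energy <- E / 2
  sp <- organism$food_stockpile %||% 0L
  child$food_stockpile <- sp %/% 2L
  organism$food_stockpile <- sp - child$food_stockpile
  list(organism, child)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cull a population to capacity
#'
#' Uniformly random organisms are removed until exactly \code{capacity}
#' remain; a population at or below capacity is unchanged.
#'
#' @param organisms list of organisms.
#' @param capacity maximum population capacity.
#' @return The culled list.
#' @export
cull_population <- function(organisms, capacity) {
  n <- length(organisms)
  if (n <= capacity) return(organisms)
  organisms[sort(sample.int(n, capacity))]
}

#' Cellularity-gated gene-transfer event
#'
#' Fires with [event_probability()]; the direction is a fair coin.  A loss
#' fragments the genome ([fragment_genome()]), removes one uniformly chosen
#' segment into the free-gene pool and remaps the remainder's pointers.  A
#' gain draws one gene from the pool (a no-op when the pool is empty or the
#' genome does not fragment) and inserts it at a uniformly chosen break
#' point, revalidating its pointers.
#'
#' @param organism an organism list with \code{genome} and
#'   \code{impermeability}.
#' @param pool an \code{cm_gene_pool}.
#' @param coefficient,override see [event_probability()].
#' @param break_weight fragmentation probability (0.1).
#' @return List with the updated \code{organism} and \code{pool}, plus
#'   \code{fired}, \code{direction} (-1 loss, +1 gain, 0 none) and
#'   \code{changed}.
#' @export
gene_transfer_event <- function(organism, pool, coefficient = 0.5,
                                override = NULL, break_weight = 0.1) {
  p <- event_probability(organism$impermeability, coefficient, override)
  res <- cpp_gene_transfer_event(unclass(organism$genome),
                                 unclass(pool$genes), p, break_weight)
  organism$genome <- as_genome(res$genome)
  pool$genes <- as_genome(res$pool)
  list(organism = organism, pool = pool, fired = res$fired,
       direction = res$direction, changed = res$changed)
}

#' Cellularity-gated energy-transfer event
#'
#' Fires with [event_probability()]; the direction is a fair coin.  A loss
#' moves a uniform fraction of the organism's current store into a new
#' parcel deposited to the pool; a gain draws one parcel from the pool (a
#' no-op on an empty finite pool) and adds its amount to the store.
#'
#' @param organism an organism list with \code{energy} and
#'   \code{impermeability}.
#' @param pool an \code{cm_energy_pool}.
#' @param coefficient,override see [event_probability()].
#' @return List with the updated \code{organism} and \code{pool}, plus
#'   \code{fired} and \code{direction}.
#' @export
energy_transfer_event <- function(organism, pool, coefficient = 0.5,
                                  override = NULL) {
  p <- event_probability(organism$impermeability, coefficient, override)
  res <- cpp_energy_transfer_event(organism$energy, pool$parcels,
                                   pool$mode == "unlimited",
                                   pool$parcel_size, p)
  organism$energy <- res$energy
  if (pool$mode == "finite") pool$parcels <- res$parcels
  list(organism = organism, pool = pool, fired = res$fired,
       direction = res$direction)
}
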