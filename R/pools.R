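#' Environmental energy pool
#'
#' A finite pool is a multiset of energy parcels; an unlimited pool never
#' exhausts and yields parcels of \code{parcel_size} (500 units by default,
#' the only parcel size used when seeding) on every draw, discarding
#' deposits.  The limited-energy scenarios seed the pool once, at step 0,
#' with parcels equivalent to 25% of the population capacity, and never
#' replenish it except through organism losses.
#'
#' @param mode \code{"unlimited"} or \code{"finite"}.
#' @param parcels numeric vector of parcel amounts (finite mode).
#' @param parcel_size parcel size yielded by unlimited-mode draws.
#' @return An \code{cm_energy_pool} list.
#' @export
energy_pool <- function(mode = c("unlimited", "finite"), parcels = numeric(),
                        parcel_size = 500) {
  mode <- match.arg(mode)
  stopifnot(all(parcels >= 0), parcel_size >= 0)
  structure(list(mode = mode, parcels = as.numeric(parcels),
                 parcel_size = parcel_size),
            class = "cm_energy_pool")
}

#' @rdname energy_pool
#' @param n_parcels number of parcels to seed.
#' @export
seed_energy <- function(n_parcels, parcel_size = 500) {
  stopifnot(n_parcels >= 0)
  energy_pool("finite", rep(parcel_size, n_parcels), parcel_size)
}

#' Draw or deposit energy parcels
#'
#' \code{draw_energy()} removes and returns one uniformly chosen parcel from
#' a finite pool (\code{NULL} when the pool is empty), or a fresh parcel of
#' the configured size from an unlimited pool.  \code{deposit_energy()} adds
#' a parcel to a finite pool; unlimited pools discard deposits.
#'
#' @param pool an \code{cm_energy_pool}.
#' @param amount parcel amount to deposit.
#' @return \code{draw_energy()}: list with \code{parcel} (amount or
#'   \code{NULL}) and the updated \code{pool}.  \code{deposit_energy()}: the
#'   updated pool.
#' @export
draw_energy <- function(pool) {
  if (pool$mode == "unlimited")
    return(list(parcel = pool$parcel_size, pool = pool))
  if (length(pool$parcels) == 0L)
    return(list(parcel = NULL, pool = pool))
  k <- sample.int(length(pool$parcels), 1L)
  parcel <- pool$parcels[k]
  pool$parcels <- pool$parcels[-k]
  list(parcel = parcel, pool = pool)
}

#' @rdname draw_energy
#' @export
deposit_energy <- function(pool, amount) {
  stopifnot(amount >= 0)
  if (pool$mode == "finite") pool$parcels <- c(pool$parcels, amount)
  pool
}

#' @rdname draw_energy
#' @export
total_energy <- function(pool) {
  if (pool$mode == "unlimited") Inf else sum(pool$parcels)
}

#' Environmental free-gene pool
#'
#' The multiset of genes shed by organisms through gene-loss events, from
#' which gain events draw.  It starts empty.  Genes retain their kind and
#' index fields; pointer fields are revalidated when a gene is inserted into
#' a genome.
#'
#' @param genes a \code{cm_genome}-shaped matrix of pooled genes.
#' @return An \code{cm_gene_pool}.
#' @export
gene_pool <- function(genes = NULL) {
  if (is.null(genes)) genes <- new_genome(integer(0))
  structure(list(genes = as_genome(unclass(genes))), class = "cm_gene_pool")
}

#' @rdname gene_pool
#' @param pool an \code{cm_gene_pool}.
#' @param segment a \code{cm_genome} segment to deposit.
#' @export
deposit_genes <- function(pool, segment) {
  pool$genes <- as_genome(rbind(unclass(pool$genes), unclass(segment)))
  pool
}

#' @rdname gene_pool
#' @return \code{draw_gene()}: list with \code{gene} (a 1-gene
#'   \code{cm_genome} or \code{NULL} when the pool is empty) and the updated
#'   \code{pool}.
#' @export
draw_gene <- function(pool) {
  n <- nrow(pool$genes)
  if (n == 0L) return(list(gene = NULL, pool = pool))
  k <- sample.int(n, 1L)
  gene <- as_genome(pool$genes[k, , drop = FALSE])
  pool$genes <- as_genome(pool$genes[-k, , drop = FALSE])
  list(gene = gene, pool = pool)
}

#' Environmental food pool
#'
#' In unlimited mode (the default for all but the cellularity-gated food
#' scenarios) organisms always receive a fresh random puzzle on demand.  In
#' replenished mode the environment holds a finite stock of puzzles topped
#' up by \code{replenish_rate} per 100-step interval (capped at \code{cap});
#' organisms draw from a personal stockpile that exchanges puzzles with the
#' pool only through cellularity-gated transfer events.
#'
#' @param mode \code{"unlimited"} or \code{"replenished"}.
#' @param stock current puzzle stock (replenished mode).
#' @param replenish_rate puzzles added per 100-step interval.
#' @param cap maximum stock.
#' @return An \code{cm_food_pool}.
#' @export
food_pool <- function(mode = c("unlimited", "replenished"), stock = 0,
                      replenish_rate = 0, cap = Inf) {
  mode <- match.arg(mode)
  stopifnot(stock >= 0, replenish_rate >= 0, stock <= cap)
  structure(list(mode = mode, stock = stock,
                 replenish_rate = replenish_rate, cap = cap),
            class = "cm_food_pool")
}

#' @rdname food_pool
#' @param pool an \code{cm_food_pool}.
#' @export
replenish_food <- function(pool) {
  stopifnot(pool$mode == "replenished")
  pool$stock <- min(pool$cap, pool$stock + pool$replenish_rate)
  pool
}

#' Acquire a food puzzle for an organism
#'
#' Unlimited mode always yields a fresh random puzzle.  In replenished mode
#' the puzzle comes from the organism's internal stockpile, or \code{NULL}
#' when the stockpile is empty (the organism tries again next step).
#'
#' @param organism a list with a \code{food_stockpile} count (replenished
#'   mode).
#' @param pool an \code{cm_food_pool}.
#' @return List with \code{puzzle} (a \code{cm_puzzle} or \code{NULL}) and
#'   the updated \code{organism}.
#' @export
acquire_food <- function(organism, pool) {
  if (pool$mode == "unlimited")
    return(list(puzzle = new_puzzle(), organism = organism))
  if (organism$food_stockpile > 0) {
    organism$food_stockpile <- organism$food_stockpile - 1L
    return(list(puzzle = new_puzzle(), organism = organism))
  }
  list(puzzle = NULL, organism = organism)
}
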