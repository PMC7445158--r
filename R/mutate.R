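#' Mutate a genome
#'
#' Applies per-site insertion, deletion and pointer-reassignment mutations.
#' For each site three independent draws are made, one per mutation type.
#' A deletion removes the gene; an insertion places one freshly generated
#' random gene (kind uniform over the four kinds, pointer fields uniform
#' over their valid ranges) immediately before the site; a pointer
#' reassignment re-draws one uniformly chosen pointer-like field of the gene
#' over its valid range.  Pointer maintenance runs after the structural
#' edits, so the returned genome always satisfies the gene invariants.
#'
#' @param genome a \code{cm_genome}.
#' @param rates numeric vector of per-site probabilities, in the order
#'   insertion, deletion, pointer (names optional); a single value is
#'   recycled.  The published default is 0.005 for all three.
#' @return A list with elements \code{genome} and \code{changed} (TRUE iff
#'   the genome differs from the input).
#' @examples
#' set.seed(1)
#' res <- mutate_genome(founder_genome(3))
#' res$changed
#' @export
mutate_genome <- function(genome,
                          rates = c(insertion = 0.005, deletion = 0.005,
                                    pointer = 0.005)) {
  rates <- rep_len(as.numeric(rates), 3L)
  stopifnot(all(rates >= 0 & rates <= 1))
  res <- cpp_mutate(unclass(genome), rates[1L], rates[2L], rates[3L])
  list(genome = as_genome(res$genome), changed = res$changed)
}

#' Remap pointers after a structural genome edit
#'
#' Given a genome whose pointer fields still refer to positions in the
#' pre-edit coordinate system and a map from old to new positions, updates
#' every pointer whose target survived.  A pointer whose target was removed,
#' or which would no longer strictly precede its gene, is re-drawn uniformly
#' over the gene's valid preceding positions (or set to unset for a gene at
#' position 0).
#'
#' @param genome a \code{cm_genome} in its new gene order, fields in old
#'   coordinates.
#' @param position_map integer vector over old 0-based positions giving each
#'   position's new 0-based position, \code{NA} for removed positions.
#' @return A \code{cm_genome} satisfying all gene invariants.
#' @export
remap_pointers <- function(genome, position_map) {
  L <- genome_length(genome)
  remap1 <- function(field, self_pos) {
    if (is.na(field)) return(NA_integer_)
    t <- if (field + 1L <= length(position_map)) position_map[field + 1L]
         else NA_integer_
    if (!is.na(t) && t < self_pos) return(as.integer(t))
    if (self_pos == 0L) NA_integer_
    else as.integer(sample.int(self_pos, 1L) - 1L)
  }
  for (j in seq_len(L)) {
    self <- j - 1L
    kind <- genome[j, 1L]
    if (kind == 2L) {
      genome[j, 3L] <- remap1(genome[j, 3L], self)
    } else if (kind == 3L) {
      genome[j, 2L] <- remap1(genome[j, 2L], self)
      genome[j, 3L] <- remap1(genome[j, 3L], self)
    }
  }
  genome
}

#' Fragment a genome into contiguous segments
#'
#' Each of the L - 1 inter-gene boundaries breaks independently with
#' probability \code{break_weight}; the genome splits into the resulting
#' runs.  Concatenating the segments in order always reproduces the input
#' genome.  Fragmentation underlies gene-transfer events: a loss removes one
#' uniformly chosen segment, a gain inserts a pool gene at one of the break
#' points.
#'
#' @param genome a \code{cm_genome}.
#' @param break_weight per-boundary break probability (published value 0.1).
#' @return A list of \code{cm_genome} segments (empty list for an empty
#'   genome).
#' @examples
#' set.seed(1)
#' segs <- fragment_genome(founder_genome(0))
#' do.call(rbind, lapply(segs, unclass))  # reassembles the genome
#' @export
fragment_genome <- function(genome, break_weight = 0.1) {
  stopifnot(break_weight >= 0, break_weight <= 1)
  if (genome_length(genome) == 0L) return(list())
  ids <- cpp_fragment_ids(unclass(genome), break_weight)
  lapply(split(seq_along(ids), ids),
         function(ix) as_genome(genome[ix, , drop = FALSE]))
}
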