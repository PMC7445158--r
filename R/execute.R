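#' Step-wise genome execution
#'
#' A fresh execution state has the read head at position 0, all value slots
#' unset, and an all-zero output register.  \code{execute_next()} executes
#' the single gene under the read head: INPUT copies the addressed puzzle
#' bit; NAND computes NOT-AND of the two addressed value slots (unset
#' operands read 0); OUTPUT copies the addressed slot (unset reads 0) into
#' its output register index; CELLULARITY passes through the value of the
#' immediately preceding position (0 at position 0).  The result is stored
#' in the gene's own value slot and the read head advances by one.
#'
#' @param genome a \code{cm_genome}.
#' @param state an execution state from \code{new_exec_state()}.
#' @param puzzle a \code{cm_puzzle} (see [new_puzzle()]).
#' @return \code{new_exec_state()}/\code{execute_next()}: an execution state
#'   (list with \code{read_head}, \code{value_slots}, \code{output_register},
#'   and \code{output_written}, which flags the register positions an OUTPUT
#'   gene has actually written -- the positions that can count as solved
#'   bits when the execution is scored).
#' @examples
#' g <- copy_through_genome()
#' p <- puzzle(c(1, 0, 1, 0, 1, 1, 0, 0))
#' s <- new_exec_state(g)
#' s <- execute_next(g, s, p)
#' s$read_head
#' @export
new_exec_state <- function(genome) {
  list(read_head = 0L,
       value_slots = rep(NA_integer_, genome_length(genome)),
       output_register = integer(8),
       output_written = logical(8))
}

#' @rdname new_exec_state
#' @export
execute_next <- function(genome, state, puzzle) {
  h <- state$read_head
  L <- genome_length(genome)
  if (h >= L) stop("execution already completed: read head at end of genome")
  kind <- genome[h + 1L, 1L]; a <- genome[h + 1L, 2L]; b <- genome[h + 1L, 3L]
  slot <- function(p) {
    if (is.na(p)) 0L else state$value_slots[p + 1L]
  }
  v <- if (kind == 1L) {
    puzzle$input_bits[a + 1L]
  } else if (kind == 2L) {
    v <- slot(b)
    state$output_register[a + 1L] <- v
    state$output_written[a + 1L] <- TRUE
    v
  } else if (kind == 3L) {
    as.integer(!(slot(a) & slot(b)))
  } else {
    if (h == 0L) 0L else state$value_slots[h]
  }
  state$value_slots[h + 1L] <- v
  state$read_head <- h + 1L
  state
}

#' Evaluate a genome against a food puzzle
#'
#' Runs the genome from a fresh execution state until the read head reaches
#' the end and returns the final 8-bit output register.  Deterministic given
#' genome and puzzle; an empty genome returns the all-zero register.  The
#' \code{"written"} attribute flags the positions an OUTPUT gene wrote;
#' positions never written stay 0 in the register but are not solved bits
#' (see [measure_proficiency()]).
#'
#' @inheritParams new_exec_state
#' @return Integer vector of 8 bits, with a logical \code{"written"}
#'   attribute of length 8.
#' @examples
#' evaluate_genome(not_network_genome(), puzzle(c(1, 0, 1, 0, 1, 1, 0, 0)))
#' @export
evaluate_genome <- function(genome, puzzle) {
  cpp_evaluate(unclass(genome), as.integer(puzzle$input_bits))
}
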