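#' Food puzzles
#'
#' A food puzzle is a randomly generated 8-bit input register whose solution
#' register is the bitwise complement (a Boolean NOT at every index).
#' \code{new_puzzle()} draws 8 independent fair bits; \code{puzzle()} wraps
#' given input bits; \code{parse_puzzle()} parses the bracketed literal form
#' \code{"[1,0,1,0,1,1,0,0]"}.
#'
#' @param input_bits integer/numeric vector of 8 bits.
#' @param text a puzzle literal such as \code{"[1,0,1,0,1,1,0,0]"}.
#' @return A \code{cm_puzzle}: list with \code{input_bits} and
#'   \code{solution_bits}.
#' @examples
#' p <- parse_puzzle("[1,0,1,0,1,1,0,0]")
#' p$solution_bits  # 0 1 0 1 0 0 1 1
#' @export
new_puzzle <- function() {
  puzzle(as.integer(runif(8) < 0.5))
}

#' @rdname new_puzzle
#' @export
puzzle <- function(input_bits) {
  input_bits <- as.integer(input_bits)
  stopifnot(length(input_bits) == 8L, all(input_bits %in% 0:1))
  structure(list(input_bits = input_bits, solution_bits = 1L - input_bits),
            class = "cm_puzzle")
}

#' @rdname new_puzzle
#' @export
parse_puzzle <- function(text) {
  text <- trimws(text)
  if (!grepl("^\\[([01],){7}[01]\\]$", text))
    stop("malformed puzzle literal: ", text)
  puzzle(as.integer(strsplit(gsub("\\[|\\]", "", text), ",")[[1]]))
}

#' Count correct output bits
#'
#' @param output_register,solution_bits integer vectors of 8 bits.
#' @return The number of positions where the two registers agree (0..8).
#' @export
count_correct <- function(output_register, solution_bits) {
  stopifnot(length(output_register) == 8L, length(solution_bits) == 8L)
  sum(output_register == solution_bits)
}

#' Processing-energy reward for a solved puzzle
#'
#' The reward is \code{n_correct^3 - 0.1 * x}, clamped at zero, where
#' \code{x} is the population-level reduction factor.  The cubic term makes
#' accurate metabolism disproportionately valuable; the reduction term
#' tightens competition as the population fills its capacity.
#'
#' @param n_correct number of correct output bits (0..8).
#' @param x reduction factor (non-negative integer).
#' @return Non-negative reward in processing-energy units.
#' @examples
#' energy_reward(8, 0)   # 512
#' energy_reward(5, 100) # 115
#' @export
energy_reward <- function(n_correct, x) {
  stopifnot(n_correct >= 0, n_correct <= 8, x >= 0)
  max(0, n_correct^3 - 0.1 * x)
}

#' Update the population-level reward reduction factor
#'
#' Increments by one on any step in which the population exceeds 85% of
#' capacity, decrements by one (floored at 0) when it drops below 25% of
#' capacity, and is unchanged in between.  Comparisons are strict.
#'
#' @param x current reduction factor.
#' @param pop_size current population size.
#' @param capacity maximum population capacity.
#' @return The updated factor.
#' @export
update_reduction_factor <- function(x, pop_size, capacity) {
  stopifnot(capacity > 0, x >= 0)
  if (pop_size > 0.85 * capacity) x + 1
  else if (pop_size < 0.25 * capacity) max(0, x - 1)
  else x
}

#' Measure metabolic proficiency
#'
#' The mean number of correctly solved puzzle bits over \code{n_puzzles}
#' fresh random food puzzles.  A bit is solved when an OUTPUT gene wrote the
#' register position during execution and the written value matches the
#' solution; positions left unwritten never count (otherwise genomes with no
#' outputs would be credited for the zero-initialized register).  The same
#' scoring drives the engine's energy rewards.  An optimal network scores 8;
#' a random founder genome typically scores between 2 and 4.  This is a
#' measurement only: it consumes no organism energy and does not advance
#' simulation time.
#'
#' @param genome a \code{cm_genome}.
#' @param n_puzzles number of random puzzles to average over (published
#'   value 1000; reduce for scaled-down runs, which only adds measurement
#'   noise).
#' @return A value in [0, 8].
#' @examples
#' measure_proficiency(not_network_genome(), 100) # 8
#' @export
measure_proficiency <- function(genome, n_puzzles = 1000) {
  stopifnot(n_puzzles >= 1)
  cpp_measure_proficiency(unclass(genome), as.integer(n_puzzles))
}
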