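#' Directional-drift walker
#'
#' A standalone model of genetic drift over a trait ("fidelity value") that
#' lowers its own mutation rate.  A non-negative integer fidelity value x
#' takes a lazy +/-1 random walk clamped at 0.  At each step a first
#' mutation channel fires with probability \code{0.5^x} (test mode), 0 (min
#' control, mimicking an always-closed cell) or 1 (max control, an
#' always-open cell); when it fires, x moves +/-1 with equal probability,
#' floored at 0.  A second channel then fires with a constant probability
#' \code{base_prob} (0.1, mimicking insertion/deletion mutations) and
#' applies the same update.
#'
#' @param fidelity initial non-negative fidelity value.
#' @param mode \code{"test"}, \code{"min_control"} or \code{"max_control"}.
#' @param base_prob constant second-channel probability.
#' @return \code{drift_walker()}: a walker list; \code{drift_step()}: the
#'   walker after one step.
#' @examples
#' set.seed(1)
#' w <- drift_walker()
#' w <- drift_step(w)
#' w$fidelity
#' @export
drift_walker <- function(fidelity = 0,
                         mode = c("test", "min_control", "max_control"),
                         base_prob = 0.1) {
  mode <- match.arg(mode)
  stopifnot(fidelity >= 0, base_prob >= 0, base_prob <= 1)
  list(fidelity = as.integer(fidelity), mode = mode, base_prob = base_prob)
}

#' @rdname drift_walker
#' @param walker a walker from \code{drift_walker()}.
#' @export
drift_step <- function(walker) {
  p1 <- switch(walker$mode,
               test = 0.5^walker$fidelity,
               min_control = 0,
               max_control = 1)
  bump <- function(x) max(0L, x + sample(c(-1L, 1L), 1L))
  if (runif(1) < p1) walker$fidelity <- bump(walker$fidelity)
  if (runif(1) < walker$base_prob) walker$fidelity <- bump(walker$fidelity)
  walker
}

drift_mode_code <- function(mode) {
  match(match.arg(mode, c("test", "min_control", "max_control")),
        c("test", "min_control", "max_control")) - 1L
}

#' Run an ensemble of independent drift walkers
#'
#' @param mode walker mode (see [drift_walker()]).
#' @param n_runs number of independent walkers.
#' @param n_steps steps per walker.
#' @param initial_fidelity starting fidelity value.
#' @param base_prob constant second-channel probability.
#' @return A \code{cm_drift} list: \code{histogram} (named counts of final
#'   fidelity values), \code{n_runs}, \code{n_steps}, \code{mode}.
#' @examples
#' set.seed(1)
#' d <- run_drift_ensemble("min_control", n_runs = 1000, n_steps = 100)
#' modal_fidelity(d)
#' @export
run_drift_ensemble <- function(mode, n_runs, n_steps, initial_fidelity = 0,
                               base_prob = 0.1) {
  stopifnot(n_runs >= 1, n_steps >= 0, initial_fidelity >= 0)
  h <- cpp_drift_ensemble(drift_mode_code(mode), as.integer(n_runs),
                          as.integer(n_steps), as.integer(initial_fidelity),
                          base_prob)
  structure(list(histogram = h, n_runs = n_runs, n_steps = n_steps,
                 mode = mode), class = "cm_drift")
}

#' @rdname run_drift_ensemble
#' @param dist a \code{cm_drift} ensemble or a probability vector from
#'   [drift_exact_distribution()].
#' @param bin_width histogram bin width used to locate the mode.  The control
#'   distributions are nearly flat near zero, so the raw sample mode of a
#'   finite ensemble is noise-dominated; estimating the mode from a binned
#'   histogram (as one would read it off a plotted histogram) is robust.  The
#'   default 1 returns the raw mode.
#' @return \code{modal_fidelity()}: the fidelity value (lower edge of the
#'   modal bin) with the largest mass.
#' @export
modal_fidelity <- function(dist, bin_width = 1) {
  h <- if (inherits(dist, "cm_drift")) dist$histogram else dist
  vals <- as.integer(names(h))
  bins <- (vals %/% bin_width) * bin_width
  mass <- tapply(as.numeric(h), bins, sum)
  as.integer(names(mass)[which.max(mass)])
}

#' Exact distribution of the drift walker
#'
#' Propagates the walker's two-channel transition kernel exactly over the
#' states \code{0..truncation}, serving as an oracle for the Monte-Carlo
#' ensemble.  The truncation must be large enough that no probability mass
#' escapes (the default, \code{initial_fidelity + 2 * n_steps}, bounds the
#' support exactly since each step moves at most +2).
#'
#' @inheritParams run_drift_ensemble
#' @param truncation largest fidelity state tracked.
#' @return Named probability vector over fidelity values 0..truncation,
#'   summing to 1 within numerical tolerance.
#' @examples
#' p <- drift_exact_distribution("max_control", n_steps = 1)
#' p[p > 0]
#' @export
drift_exact_distribution <- function(mode, n_steps, initial_fidelity = 0,
                                     base_prob = 0.1, truncation = NULL) {
  mode <- match.arg(mode, c("test", "min_control", "max_control"))
  if (is.null(truncation)) truncation <- initial_fidelity + 2L * n_steps
  K <- as.integer(truncation)
  stopifnot(initial_fidelity <= K)
  p <- numeric(K + 1L)
  p[initial_fidelity + 1L] <- 1
  q1 <- switch(mode,
               test = 0.5^(0:K),
               min_control = rep(0, K + 1L),
               max_control = rep(1, K + 1L))
  propagate <- function(p, q) {
    up <- p * q / 2
    down <- p * q / 2
    np <- p * (1 - q)
    np[1L] <- np[1L] + down[1L]                 # decrement at 0 clamps to 0
    np[1:K] <- np[1:K] + down[2:(K + 1L)]
    np[2:(K + 1L)] <- np[2:(K + 1L)] + up[1:K]
    if (up[K + 1L] > 0)
      stop("insufficient truncation: probability mass beyond state ", K)
    np
  }
  for (s in seq_len(n_steps)) {
    p <- propagate(p, q1)
    p <- propagate(p, rep(base_prob, K + 1L))
  }
  if (abs(sum(p) - 1) > 1e-9)
    stop("insufficient truncation: total mass ", sum(p))
  names(p) <- 0:K
  p
}
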