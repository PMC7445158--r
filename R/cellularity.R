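#' Cellular impermeability from cellularity-gene count
#'
#' Maps the number of cellularity genes n to an impermeability value in
#' [0, 1] under one of three functions:
#' \describe{
#'   \item{standard}{\code{1 - 0.5^n}: impermeability grows with n
#'     (endogenously produced cellularity).}
#'   \item{reverse}{\code{0.5^n}: organisms start fully closed and acquire
#'     genes to open up (environmentally imposed cellularity).}
#'   \item{linear}{\code{min(1, 0.25 * n)}: linear growth, clamped at 1 for
#'     n >= 4.}
#' }
#' Impermeability 0 means maximal probability of gene/energy exchange with
#' the environment; 1 means the organism is completely closed.
#'
#' @param n_cellularity non-negative integer count of cellularity genes.
#' @param fn cellularity function name.
#' @return Impermeability in [0, 1].
#' @examples
#' impermeability(3, "standard") # 0.875
#' impermeability(3, "linear")   # 0.75
#' impermeability(3, "reverse")  # 0.125
#' @export
impermeability <- function(n_cellularity,
                           fn = c("standard", "reverse", "linear")) {
  fn <- match.arg(fn)
  stopifnot(all(n_cellularity >= 0))
  switch(fn,
         standard = 1 - 0.5^n_cellularity,
         reverse = 0.5^n_cellularity,
         linear = pmin(1, 0.25 * n_cellularity))
}

cellularity_fn_code <- function(fn) {
  match(match.arg(fn, c("standard", "reverse", "linear")),
        c("standard", "reverse", "linear")) - 1L
}

#' Per-interval exchange-event probability
#'
#' The probability that a gene, energy or food transfer event fires for an
#' organism in one 100-step interval: \code{coefficient * (1 - imp)}, or the
#' override constant when one is set (the constant-probability control
#' scenarios fix a channel at 0 or 1 regardless of impermeability).
#'
#' @param imp the organism's cellular impermeability in [0, 1].
#' @param coefficient channel coefficient (published value 0.5).
#' @param override optional constant in [0, 1] replacing the computed
#'   probability; \code{NULL} (default) for no override.
#' @return Probability in [0, 1].
#' @examples
#' event_probability(0.875, 0.5)  # 0.0625
#' event_probability(0.2, 0.5, override = 1)
#' @export
event_probability <- function(imp, coefficient = 0.5, override = NULL) {
  stopifnot(imp >= 0, imp <= 1, coefficient >= 0, coefficient <= 1)
  if (!is.null(override) && !is.na(override)) {
    stopifnot(override >= 0, override <= 1)
    return(override)
  }
  coefficient * (1 - imp)
}
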