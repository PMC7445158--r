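#' Scenario presets
#'
#' Named configurations reproducing the published experiments.  The fig2
#' family crosses the founder cellularity-gene count (0 or 3, suffixes
#' a/c = unlimited energy, b/d = an energy pool seeded once with parcels
#' equivalent to 25% of capacity at 500 units each):
#' \describe{
#'   \item{fig2a}{0 cellularity genes, unlimited energy.}
#'   \item{fig2b}{0 cellularity genes, seeded (limited) energy.}
#'   \item{fig2c}{3 cellularity genes, unlimited energy.}
#'   \item{fig2d}{3 cellularity genes, seeded energy.}
#'   \item{fig3}{3 cellularity genes, a one-off burst of 10,000 parcels of
#'     500 units, capacity 1000: the reversal-of-selection scenario.}
#'   \item{fig6lin_a..d / fig6rev_a..d}{the fig2 family under the linear or
#'     reverse cellularity function.}
#'   \item{fig8_a..d}{the fig2 family with cellularity-gated food
#'     acquisition (replenished food pool and personal stockpiles).}
#'   \item{fig9_gene0 / fig9_gene100}{gene-transfer probability fixed at 0%
#'     or 100%; fig9_energy0 / fig9_energy100 likewise for energy transfer.
#'     These bind the limited-energy, 0-cellularity-gene base scenario; pass
#'     other bases through [sim_config()] directly.}
#'   \item{figS11}{the limited-energy base with the extra replication cost
#'     of two genome lengths.}
#' }
#'
#' All presets use mutation rates 0.005, transfer coefficients 0.5, interval
#' 100 and 100,000 max steps; capacity defaults to 1000.
#'
#' @param name preset name.
#' @param capacity optional capacity override (the published runs used 500,
#'   1000 and 10,000).
#' @param ... further [sim_config()] arguments (e.g. \code{seed},
#'   \code{max_steps}, \code{proficiency_n_puzzles}) overriding the preset.
#' @return A \code{cm_config}.
#' @examples
#' cfg <- preset("fig2b", capacity = 500, seed = 1)
#' cfg$energy_parcels  # 125
#' @export
preset <- function(name, capacity = 1000, ...) {
  base <- list(
    fig2a = list(initial_cellularity_genes = 0, energy_mode = "unlimited"),
    fig2b = list(initial_cellularity_genes = 0, energy_mode = "seeded"),
    fig2c = list(initial_cellularity_genes = 3, energy_mode = "unlimited"),
    fig2d = list(initial_cellularity_genes = 3, energy_mode = "seeded"),
    fig3 = list(initial_cellularity_genes = 3, energy_mode = "seeded",
                energy_parcels = 10000L)
  )
  for (s in c("a", "b", "c", "d")) {
    base[[paste0("fig6lin_", s)]] <-
      c(base[[paste0("fig2", s)]], list(cellularity_function = "linear"))
    base[[paste0("fig6rev_", s)]] <-
      c(base[[paste0("fig2", s)]], list(cellularity_function = "reverse"))
    base[[paste0("fig8_", s)]] <-
      c(base[[paste0("fig2", s)]], list(food_mode = "replenished"))
  }
  base$fig9_gene0 <- c(base$fig2b, list(gene_transfer_override = 0))
  base$fig9_gene100 <- c(base$fig2b, list(gene_transfer_override = 1))
  base$fig9_energy0 <- c(base$fig2b, list(energy_transfer_override = 0))
  base$fig9_energy100 <- c(base$fig2b, list(energy_transfer_override = 1))
  base$figS11 <- c(base$fig2b, list(replication_extra_cost = TRUE))
  if (!name %in% names(base))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(base), collapse = ", "))
  args <- modifyList(c(list(capacity = capacity), base[[name]]), list(...))
  do.call(sim_config, args)
}
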