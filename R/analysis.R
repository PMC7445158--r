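TRACE_COLUMNS <- c("step", "population_size", "mean_impermeability",
                   "mean_proficiency", "mean_genome_length",
                   "env_energy_total", "env_parcel_count", "gene_pool_size",
                   "reduction_factor")

#' Pearson correlation with p-value
#'
#' Standard Pearson product-moment correlation; the two-sided p-value comes
#' from the t-distribution with n - 2 degrees of freedom.
#'
#' @param xs,ys numeric vectors of equal length (at least 3), each with
#'   non-zero variance.
#' @return List with \code{r} and \code{p}.
#' @examples
#' pearson(c(1, 2, 3), c(2, 4, 7))
#' @export
pearson <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 3) stop("need at least 3 observations")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("correlation undefined: zero variance")
  ct <- cor.test(xs, ys, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Pooled impermeability-proficiency correlation across traces
#'
#' Pools the (mean impermeability, mean proficiency) pairs from every record
#' of every trace into a single Pearson correlation, the statistic used to
#' quantify the coevolution of the two traits.
#'
#' @param traces a list of trace data frames (or \code{cm_sim} objects).
#' @return List with \code{r}, \code{p} and the number of pooled pairs
#'   \code{n}.
#' @export
trace_correlation <- function(traces) {
  if (inherits(traces, "cm_sim") || is.data.frame(traces))
    traces <- list(traces)
  tr <- lapply(traces, function(t) if (inherits(t, "cm_sim")) t$trace else t)
  imp <- unlist(lapply(tr, `[[`, "mean_impermeability"))
  prof <- unlist(lapply(tr, `[[`, "mean_proficiency"))
  c(pearson(imp, prof), list(n = length(imp)))
}

#' Run replicate simulations of one scenario
#'
#' Independent runs with distinct seeds.  A replicate survives when its
#' population is still alive at \code{max_steps}.
#'
#' @param config a \code{cm_config}, or a preset name passed to [preset()].
#' @param n_replicates number of replicates.
#' @param seeds integer seeds, one per replicate (defaults to
#'   \code{1:n_replicates}).
#' @param ... further arguments to [preset()] when \code{config} is a name.
#' @return List with per-replicate \code{runs}, logical \code{survived},
#'   \code{survival_count}, and \code{min_impermeability} (the per-replicate
#'   minimum population-averaged impermeability, the quantity used to
#'   colour-code the burst-energy runs).
#' @examples
#' ens <- run_sim_ensemble(sim_config(capacity = 30, max_steps = 300,
#'                                    proficiency_n_puzzles = 20),
#'                         n_replicates = 2)
#' ens$survival_count
#' @export
run_sim_ensemble <- function(config, n_replicates, seeds = NULL, ...) {
  if (is.character(config)) config <- preset(config, ...)
  if (is.null(seeds)) seeds <- seq_len(n_replicates)
  stopifnot(length(seeds) == n_replicates)
  runs <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    run_sim(cfg)
  })
  survived <- vapply(runs, function(r) r$status == "max_steps", logical(1))
  min_imp <- vapply(runs, function(r) {
    if (nrow(r$trace) == 0) NA_real_ else min(r$trace$mean_impermeability)
  }, numeric(1))
  list(runs = runs, survived = survived,
       survival_count = sum(survived), min_impermeability = min_imp,
       seeds = seeds)
}

#' Write and read metrics traces
#'
#' Traces are CSV files with a fixed header (step, population_size,
#' mean_impermeability, mean_proficiency, mean_genome_length,
#' env_energy_total, env_parcel_count, gene_pool_size, reduction_factor).
#' Values are written with 17 significant digits so that a round trip is
#' bit-exact.
#'
#' @param trace a trace data frame (or a \code{cm_sim}).
#' @param path file path.
#' @return \code{read_trace()}: the trace data frame.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "cm_sim")) trace <- trace$trace
  stopifnot(identical(names(trace), TRACE_COLUMNS))
  rows <- vapply(seq_len(nrow(trace)), function(i) {
    paste(vapply(trace[i, ], function(v) formatC(v, digits = 17,
                                                 format = "g"), ""),
          collapse = ",")
  }, "")
  writeLines(c(paste(TRACE_COLUMNS, collapse = ","), rows), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0)
    stop("trace parse error at line 1: empty file")
  if (!identical(lines[1], paste(TRACE_COLUMNS, collapse = ",")))
    stop("trace parse error at line 1: bad header")
  n <- length(lines) - 1L
  m <- matrix(NA_real_, nrow = n, ncol = length(TRACE_COLUMNS))
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    if (length(fields) != length(TRACE_COLUMNS))
      stop(sprintf("trace parse error at line %d: %d fields, expected %d",
                   i + 1L, length(fields), length(TRACE_COLUMNS)))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("trace parse error at line %d: non-numeric field", i + 1L))
    m[i, ] <- vals
  }
  df <- as.data.frame(m)
  names(df) <- TRACE_COLUMNS
  df
}

#' Plot population-averaged trajectories
#'
#' Base-graphics time series of mean impermeability and mean proficiency
#' (rescaled to [0, 1]) against the recording steps.
#'
#' @param trace a trace data frame or \code{cm_sim}.
#' @param ... passed to [plot()].
#' @export
plot_trace <- function(trace, ...) {
  if (inherits(trace, "cm_sim")) trace <- trace$trace
  plot(trace$step, trace$mean_impermeability, type = "l", ylim = c(0, 1),
       xlab = "time step", ylab = "population mean", col = "black", ...)
  graphics::lines(trace$step, trace$mean_proficiency / 8, col = "red3")
  graphics::legend("bottomright",
                   legend = c("impermeability", "proficiency / 8"),
                   col = c("black", "red3"), lty = 1, bty = "n")
  invisible(trace)
}
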