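test_that("presets encode the published parameter combinations", {
  cfg <- preset("fig2b", capacity = 500)
  expect_equal(cfg$initial_cellularity_genes, 0)
  expect_equal(cfg$energy_mode, "seeded")
  expect_equal(cfg$energy_parcels, 125)          # 25% of capacity
  expect_equal(cfg$parcel_size, 500)
  expect_equal(cfg$mutation_rates, rep(0.005, 3))
  expect_equal(cfg$gene_coefficient, 0.5)
  expect_equal(cfg$max_steps, 100000)

  cfg <- preset("fig3")
  expect_equal(cfg$capacity, 1000)
  expect_equal(cfg$initial_cellularity_genes, 3)
  expect_equal(cfg$energy_parcels, 10000)        # the burst seeding

  expect_equal(preset("fig6rev_c")$cellularity_function, "reverse")
  expect_equal(preset("fig6lin_b")$cellularity_function, "linear")
  expect_equal(preset("fig8_b")$food_mode, "replenished")
  expect_equal(preset("fig9_gene100")$gene_transfer_override, 1)
  expect_equal(preset("fig9_energy0")$energy_transfer_override, 0)
  expect_true(preset("figS11")$replication_extra_cost)
  expect_error(preset("nope"), "valid presets")
})

test_that("pearson matches a direct textbook computation", {
  p <- pearson(c(1, 2, 3), c(2, 4, 6))
  expect_equal(p$r, 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1))$r, -1)
  set.seed(2)
  x <- runif(50); y <- 0.4 * x + runif(50)
  ref_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- ref_r * sqrt(48 / (1 - ref_r^2))
  ref_p <- 2 * stats::pt(-abs(tstat), df = 48)
  got <- pearson(x, y)
  expect_equal(got$r, ref_r, tolerance = 1e-12)
  expect_equal(got$p, ref_p, tolerance = 1e-12)
  expect_error(pearson(1:5, 1:4), "equal length")
  expect_error(pearson(c(1, 2), c(2, 1)), "at least 3")
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
})

test_that("traces round-trip bit-exactly through CSV", {
  cfg <- tiny_config(energy_mode = "seeded", max_steps = 2300, seed = 71)
  sim <- run_sim(cfg)
  path <- tempfile(fileext = ".csv")
  write_trace(sim$trace, path)
  back <- read_trace(path)
  expect_identical(back, sim$trace)
  # empty trace: header only
  empty <- sim$trace[0, ]
  write_trace(empty, path)
  expect_equal(nrow(read_trace(path)), 0)
  # malformed inputs report the offending line
  writeLines(c("step,foo", "1,2"), path)
  expect_error(read_trace(path), "line 1")
  lines <- readLines({ write_trace(sim$trace, path); path })
  writeLines(c(lines, "1,2,3"), path)
  expect_error(read_trace(path), sprintf("line %d", length(lines) + 1))
})

test_that("population means are recorded over living organisms", {
  # a uniform founder population with frozen genomes keeps its founder mean
  cfg <- sim_config(capacity = 20, initial_cellularity_genes = 3,
                    mutation_rates = c(0, 0, 0), gene_transfer_override = 0,
                    energy_transfer_override = 0, proficiency_n_puzzles = 20,
                    max_steps = 300, seed = 72)
  sim <- run_sim(cfg)
  expect_equal(sim$trace$step[1], 250)
  expect_equal(sim$trace$mean_impermeability[1], 0.875)
  expect_equal(sim$trace$mean_genome_length[1], 35)
})

test_that("replicate ensembles report survival and are reproducible", {
  cfg <- tiny_config(max_steps = 2600)  # unlimited energy: trivially survivable
  ens <- run_sim_ensemble(cfg, n_replicates = 2, seeds = c(5, 6))
  expect_equal(ens$survival_count, 2)
  expect_length(ens$min_impermeability, 2)
  ens2 <- run_sim_ensemble(cfg, n_replicates = 2, seeds = c(5, 6))
  expect_identical(lapply(ens$runs, `[[`, "trace"),
                   lapply(ens2$runs, `[[`, "trace"))
  # pooled correlation plumbing
  tc <- trace_correlation(lapply(ens$runs, `[[`, "trace"))
  expect_equal(tc$n, sum(vapply(ens$runs, function(r) nrow(r$trace),
                                numeric(1))))
})
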