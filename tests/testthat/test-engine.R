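test_that("init_population allocates energy, proficiency and pools", {
  cfg <- sim_config(capacity = 30, initial_pop = 12, energy_mode = "seeded",
                    initial_cellularity_genes = 3,
                    proficiency_n_puzzles = 30, seed = 1)
  st <- init_population(cfg)
  expect_length(st$organisms, 12)
  expect_equal(st$t, 0)
  expect_equal(st$x, 0)
  expect_length(st$energy_parcels, round(0.25 * 30))
  for (o in st$organisms) {
    expect_equal(o$energy, 2 * nrow(o$genome))       # two times genome length
    expect_true(o$proficiency >= 0 && o$proficiency <= 8)
    expect_equal(o$impermeability, 0.875)
    expect_false(o$has_puzzle)
  }
  st2 <- init_population(cfg)  # same configured seed
  expect_identical(st, st2)
})

test_that("an organism earning nothing dies after exactly 2L steps", {
  cfg <- sim_config(capacity = 4, initial_pop = 1, rewards_enabled = FALSE,
                    energy_transfer_override = 0, gene_transfer_override = 0,
                    mutation_rates = c(0, 0, 0), proficiency_n_puzzles = 10,
                    seed = 5)
  st <- init_population(cfg)  # L = 32, energy 64
  res <- advance_step(st, cfg, 63)
  expect_equal(res$status, "done")
  expect_length(res$state$organisms, 1)
  expect_equal(res$state$organisms[[1]]$energy, 1)
  res <- advance_step(res$state, cfg, 1)
  expect_equal(res$status, "extinct")
  expect_length(res$state$organisms, 0)
})

test_that("replication halves energy and duplicates the genome", {
  g <- founder_genome(3)  # L = 35
  org <- list(genome = g, energy = 140, proficiency = 3.2, food_stockpile = 5L)
  kids <- replicate_organism(org, sim_config())
  expect_equal(vapply(kids, `[[`, numeric(1), "energy"), c(70, 70))
  expect_identical(kids[[1]]$genome, g)
  expect_identical(kids[[2]]$genome, g)
  expect_equal(vapply(kids, `[[`, numeric(1), "proficiency"), c(3.2, 3.2))
  expect_equal(sum(vapply(kids, `[[`, integer(1), "food_stockpile")), 5L)
  # extra-cost variant: two genome lengths deducted, not passed down
  kids <- replicate_organism(org, sim_config(replication_extra_cost = TRUE))
  expect_equal(vapply(kids, `[[`, numeric(1), "energy"), c(35, 35))
  expect_error(replicate_organism(list(genome = g, energy = 100)), "energy")
})

test_that("culling removes uniformly at random down to capacity", {
  orgs <- lapply(1:105, function(i) list(id = i))
  set.seed(8)
  kept <- cull_population(orgs, 100)
  expect_length(kept, 100)
  expect_identical(cull_population(orgs[1:50], 100), orgs[1:50])
  set.seed(11); a <- cull_population(orgs, 30)
  set.seed(11); b <- cull_population(orgs, 30)
  expect_identical(a, b)
})

test_that("gene transfer events respect impermeability, direction and pools", {
  set.seed(12)
  g <- founder_genome(0)
  org <- list(genome = g, impermeability = 1)
  pool <- gene_pool()
  for (i in 1:50) {
    res <- gene_transfer_event(org, pool)
    expect_false(res$fired)   # fully closed cell: probability 0
    expect_identical(res$organism$genome, g)
  }
  # a loss with break weight 0 sheds the entire genome (a single segment)
  org$impermeability <- 0
  repeat {
    res <- gene_transfer_event(org, pool, override = 1, break_weight = 0)
    if (res$direction == -1) break
  }
  expect_equal(genome_length(res$organism$genome), 0)
  expect_equal(nrow(res$pool$genes), 32)
  # a gain from an empty pool is a no-op
  repeat {
    res <- gene_transfer_event(org, gene_pool(), override = 1)
    if (res$direction == 1) break
  }
  expect_identical(res$organism$genome, g)
  expect_false(res$changed)
  # gains and losses leave only valid genomes behind
  pool <- gene_pool(founder_genome(0))
  for (i in 1:200) {
    res <- gene_transfer_event(org, pool, override = 1)
    org <- res$organism; pool <- res$pool
    expect_true(validate_genome(org$genome))
  }
})

test_that("energy transfer events conserve energy", {
  set.seed(13)
  org <- list(energy = 100, impermeability = 0)
  pool <- energy_pool("finite", parcels = c(500, 500))
  for (i in 1:100) {
    res <- energy_transfer_event(org, pool, override = 1)
    expect_true(res$fired)
    expect_equal(res$organism$energy + total_energy(res$pool), 1100)
    org <- res$organism; pool <- res$pool
    expect_gte(org$energy, 0)
  }
})

test_that("run_sim records on schedule, terminates and is seed-reproducible", {
  cfg <- tiny_config(energy_mode = "seeded", max_steps = 2300, seed = 31)
  sim <- run_sim(cfg)
  expect_identical(sim$trace$step, c(250, 1250, 2250))  # 250, then every 1000
  expect_true(all(sim$trace$population_size <= cfg$capacity))
  expect_identical(run_sim(cfg)$trace, sim$trace)
  cfg2 <- cfg; cfg2$seed <- 32
  expect_false(identical(run_sim(cfg2)$trace, sim$trace))
  # no food at all: extinction by starvation before max_steps
  cfg3 <- sim_config(capacity = 20, food_mode = "replenished",
                     food_replenish_rate = 0, food_initial_stock = 0,
                     energy_transfer_override = 0, proficiency_n_puzzles = 10,
                     max_steps = 5000, seed = 33)
  sim3 <- run_sim(cfg3)
  expect_equal(sim3$status, "extinct")
  expect_lt(sim3$final_state$t, 5000)
})

test_that("energy bookkeeping balances exactly over a full-featured run", {
  cfg <- tiny_config(energy_mode = "seeded", max_steps = 800, seed = 41)
  st0 <- init_population(cfg)
  total0 <- state_org_energy(st0) + sum(st0$energy_parcels)
  res <- advance_step(st0, cfg, 800)
  n <- res$counters
  total1 <- state_org_energy(res$state) + sum(res$state$energy_parcels)
  expect_equal(total1,
               total0 + n$reward - n$consumed - n$death_energy -
                 n$cull_energy - n$extra_cost_paid,
               tolerance = 1e-9)
})

test_that("impermeability cache always matches the genome after a run", {
  for (fn in c("standard", "reverse", "linear")) {
    cfg <- tiny_config(initial_cellularity_genes = 3,
                       cellularity_function = fn, energy_mode = "seeded",
                       max_steps = 700, seed = 51)
    sim <- run_sim(cfg)
    for (o in sim$final_state$organisms) {
      expect_equal(o$impermeability,
                   impermeability(n_cellularity_genes(o$genome), fn))
    }
  }
})

test_that("energy-transfer override 1 with a seeded pool fills the population", {
  cfg <- sim_config(capacity = 50, initial_pop = 25, energy_mode = "seeded",
                    energy_parcels = 1000, energy_transfer_override = 1,
                    proficiency_n_puzzles = 10, max_steps = 500, seed = 61)
  sim <- run_sim(cfg)
  expect_equal(length(sim$final_state$organisms), 50)
  expect_gt(sim$counters$energy_gain, 0)
})
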