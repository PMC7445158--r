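test_that("energy pool seeding, draws and deposits", {
  p <- seed_energy(250, 500)
  expect_length(p$parcels, 250)
  expect_equal(total_energy(p), 125000)
  expect_equal(total_energy(seed_energy(0)), 0)

  set.seed(1)
  p1 <- energy_pool("finite", parcels = 42)
  d <- draw_energy(p1)
  expect_equal(d$parcel, 42)
  expect_length(d$pool$parcels, 0)
  expect_null(draw_energy(d$pool)$parcel)

  u <- energy_pool("unlimited")
  expect_equal(draw_energy(u)$parcel, 500)
  expect_equal(draw_energy(u)$parcel, 500)
  expect_equal(total_energy(deposit_energy(u, 99)), Inf)  # deposits discarded

  p2 <- deposit_energy(energy_pool("finite", parcels = c(10, 20)), 30)
  expect_equal(total_energy(p2), 60)  # conservation of deposited amount
})

test_that("gene pool deposit and draw", {
  set.seed(2)
  gp <- gene_pool()
  expect_null(draw_gene(gp)$gene)
  seg <- new_genome(c("INPUT", "NAND"), a = c(3L, 0L), b = c(NA, 0L))
  gp <- deposit_genes(gp, seg)
  expect_equal(nrow(gp$genes), 2)
  d <- draw_gene(gp)
  expect_equal(nrow(d$gene), 1)
  expect_equal(nrow(d$pool$genes), 1)
  d2 <- draw_gene(d$pool)
  expect_equal(nrow(d2$pool$genes), 0)
  got <- rbind(unclass(d$gene), unclass(d2$gene))
  expect_setequal(got[, "kind"], unclass(seg)[, "kind"])
})

test_that("food pool replenishment and acquisition", {
  fp <- food_pool("replenished", stock = 0, replenish_rate = 250, cap = 1000)
  expect_equal(replenish_food(fp)$stock, 250)
  fp$stock <- 1000
  expect_equal(replenish_food(fp)$stock, 1000)      # capped
  fp$replenish_rate <- 0
  fp$stock <- 7
  expect_equal(replenish_food(fp)$stock, 7)          # rate 0: non-increasing

  org <- list(food_stockpile = 1L)
  res <- acquire_food(org, food_pool("unlimited"))
  expect_s3_class(res$puzzle, "cm_puzzle")
  res <- acquire_food(org, fp)
  expect_s3_class(res$puzzle, "cm_puzzle")
  expect_equal(res$organism$food_stockpile, 0L)
  res2 <- acquire_food(res$organism, fp)
  expect_null(res2$puzzle)                           # empty stockpile: idle
})

test_that("closed economy conserves energy when rewards and consumption are off", {
  cfg <- sim_config(capacity = 5000, initial_pop = 20, energy_mode = "seeded",
                    energy_parcels = 10, parcel_size = 500,
                    proficiency_n_puzzles = 10, consume_energy = FALSE,
                    rewards_enabled = FALSE, max_steps = 1500, seed = 21)
  st0 <- init_population(cfg)
  total0 <- state_org_energy(st0) + sum(st0$energy_parcels)
  res <- advance_step(st0, cfg, 1500)
  total1 <- state_org_energy(res$state) + sum(res$state$energy_parcels)
  expect_equal(total1, total0, tolerance = 1e-9)
  expect_equal(res$counters$deaths, 0)
  expect_equal(res$counters$culled, 0)
  expect_gt(res$counters$energy_events, 0)  # transfers did occur
})

test_that("gene count is conserved under pure gene transfer", {
  cfg <- sim_config(capacity = 5000, initial_pop = 25, energy_mode = "seeded",
                    energy_parcels = 0, mutation_rates = c(0, 0, 0),
                    gene_transfer_override = 1, energy_transfer_override = 0,
                    proficiency_n_puzzles = 10, consume_energy = FALSE,
                    rewards_enabled = FALSE, replication_enabled = FALSE,
                    max_steps = 1200, seed = 22)
  st0 <- init_population(cfg)
  n0 <- state_gene_count(st0)
  res <- advance_step(st0, cfg, 1200)
  expect_equal(state_gene_count(res$state), n0)
  expect_gt(res$counters$gene_events, 0)
  expect_equal(res$counters$deaths, 0)
})

test_that("an override of zero silences a transfer channel completely", {
  cfg <- tiny_config(energy_mode = "seeded",
                     gene_transfer_override = 0, energy_transfer_override = 0,
                     max_steps = 1000, seed = 23)
  sim <- run_sim(cfg)
  expect_equal(sim$counters$gene_events, 0)
  expect_equal(sim$counters$energy_events, 0)
})
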