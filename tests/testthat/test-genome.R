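test_that("founder genome has the designed composition and is seed-deterministic", {
  set.seed(1)
  g0 <- founder_genome(0)
  expect_equal(genome_length(g0), 32)
  g <- founder_genome(3)
  expect_equal(genome_length(g), 35)
  expect_equal(n_cellularity_genes(g), 3)
  expect_identical(gene_kinds(g),
                   c(rep("INPUT", 8), rep("NAND", 16), rep("OUTPUT", 8),
                     rep("CELLULARITY", 3)))
  expect_identical(g[1:8, "a"], 0:7)                      # each input bit once
  expect_identical(g[25:32, "a"], 0:7)                    # each register once
  expect_identical(g[25:32, "b"], 23:30)                  # immediate predecessor
  expect_true(all(g[9:24, "a"] < 8:23 & g[9:24, "b"] < 8:23))
  expect_true(validate_genome(g))
  set.seed(99); a <- founder_genome(3)
  set.seed(99); b <- founder_genome(3)
  expect_identical(a, b)
})

test_that("execute_next implements the four gene semantics", {
  # NAND truth table through two inputs feeding one NAND
  for (bits in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
    g <- new_genome(c("INPUT", "INPUT", "NAND"), a = c(0L, 1L, 0L),
                    b = c(NA, NA, 1L))
    pz <- puzzle(c(bits, rep(0, 6)))
    st <- evaluate_stepwise(g, pz)
    expect_equal(st$value_slots[3], as.integer(!(bits[1] && bits[2])))
  }
  # read head advances by exactly one per call
  g <- founder_genome(0)
  st <- new_exec_state(g)
  st <- execute_next(g, st, new_puzzle())
  expect_equal(st$read_head, 1L)
  # OUTPUT at position 0 has an unset source and writes 0, but marks written
  g <- new_genome("OUTPUT", a = 5L, b = NA_integer_)
  st <- evaluate_stepwise(g, puzzle(rep(1, 8)))
  expect_equal(st$output_register[6], 0L)
  expect_true(st$output_written[6])
  expect_false(any(st$output_written[-6]))
  # CELLULARITY passes through the preceding value; position 0 reads 0
  g <- new_genome(c("INPUT", "CELLULARITY", "CELLULARITY"), a = c(0L, NA, NA))
  st <- evaluate_stepwise(g, puzzle(c(1, rep(0, 7))))
  expect_equal(st$value_slots, c(1L, 1L, 1L))
  g <- new_genome("CELLULARITY")
  st <- evaluate_stepwise(g, puzzle(rep(1, 8)))
  expect_equal(st$value_slots, 0L)
  # unset NAND operands read 0 (NAND(0, 0) = 1)
  g <- new_genome("NAND", a = NA_integer_, b = NA_integer_)
  st <- evaluate_stepwise(g, puzzle(rep(1, 8)))
  expect_equal(st$value_slots, 1L)
  # calling past the end errors
  expect_error(execute_next(g, st, puzzle(rep(1, 8))), "completed")
})

test_that("evaluate_genome agrees with step-wise execution on random genomes", {
  set.seed(42)
  for (i in 1:20) {
    g <- founder_genome(sample(0:3, 1))
    for (j in 1:5) g <- mutate_genome(g, rates = 0.05)$genome
    pz <- new_puzzle()
    out <- evaluate_genome(g, pz)
    st <- evaluate_stepwise(g, pz)
    expect_identical(as.integer(out), st$output_register)
    expect_identical(attr(out, "written"), st$output_written)
  }
})

test_that("reference networks evaluate correctly on all 256 puzzles", {
  notg <- not_network_genome()
  copyg <- copy_through_genome()
  empty <- new_genome(integer(0))
  inputs <- all_puzzle_inputs()
  matches <- apply(inputs, 1, function(bits) {
    pz <- puzzle(as.integer(bits))
    expect_identical(as.integer(evaluate_genome(notg, pz)), pz$solution_bits)
    expect_identical(as.integer(evaluate_genome(copyg, pz)), pz$input_bits)
    out <- evaluate_genome(empty, pz)
    expect_identical(as.integer(out), rep(0L, 8))
    count_correct(out, pz$solution_bits)
  })
  # an all-zero register matches the solution wherever the input bit is 1
  expect_equal(mean(matches), 4.0)
})

test_that("mutation operator edge cases and per-site rates", {
  set.seed(7)
  g <- founder_genome(3)
  res <- mutate_genome(g, rates = c(0, 0, 0))
  expect_identical(res$genome, g)
  expect_false(res$changed)
  res <- mutate_genome(g, rates = c(insertion = 0, deletion = 1, pointer = 0))
  expect_equal(genome_length(res$genome), 0)
  expect_true(res$changed)
  # deletion count is Binomial(L, rate): mean 32 * 0.005 = 0.16
  g32 <- founder_genome(0)
  dels <- replicate(30000, {
    32 - genome_length(mutate_genome(g32, rates = c(0, 0.005, 0))$genome)
  })
  expect_equal(mean(dels), 0.16, tolerance = 0.08)  # ~3 SE relative
  # distributional check at a rate giving a usable spread
  dels <- replicate(20000, {
    32 - genome_length(mutate_genome(g32, rates = c(0, 0.05, 0))$genome)
  })
  obs <- tabulate(dels + 1L, nbins = 33)
  expect_gt(chisq_gof_p(obs, stats::dbinom(0:32, 32, 0.05)), 1e-3)
})

test_that("gene invariants hold after long random edit chains", {
  set.seed(123)
  for (chain in 1:100) {
    g <- founder_genome(sample(0:3, 1))
    for (edit in 1:50) {
      g <- mutate_genome(g, rates = runif(3, 0, 0.2))$genome
      expect_true(validate_genome(g))
    }
  }
})

test_that("fragmentation edge cases, concatenation identity and mean count", {
  set.seed(5)
  g <- founder_genome(0)
  expect_length(fragment_genome(g, 0), 1)
  expect_equal(genome_length(fragment_genome(g, 0)[[1]]), 32)
  expect_length(fragment_genome(g, 1), 32)
  expect_length(fragment_genome(new_genome(integer(0))), 0)
  for (i in 1:200) {
    gg <- founder_genome(sample(0:3, 1))
    segs <- fragment_genome(gg, runif(1))
    recon <- do.call(rbind, lapply(segs, unclass))
    expect_equal(unname(recon), unname(unclass(gg)))
  }
  # expected segment count 1 + 0.1 * (L - 1) = 4.4 at L = 35
  g35 <- founder_genome(3)
  counts <- replicate(20000, length(fragment_genome(g35, 0.1)))
  expect_equal(mean(counts), 4.4, tolerance = 0.01)
})

test_that("remap_pointers preserves surviving targets and restores invariants", {
  # I0 I1 N(0,0) O(2 -> reg 0): gene 1 (I1) is unreferenced; delete it
  g <- new_genome(c("INPUT", "INPUT", "NAND", "OUTPUT"),
                  a = c(0L, 1L, 0L, 0L), b = c(NA, NA, 0L, 2L))
  shifted <- as_genome(unclass(g)[-2, , drop = FALSE])
  remapped <- remap_pointers(shifted, position_map = c(0L, NA, 1L, 2L))
  expect_identical(unname(unclass(remapped)),
                   unname(unclass(new_genome(c("INPUT", "NAND", "OUTPUT"),
                                             a = c(0L, 0L, 0L),
                                             b = c(NA, 0L, 1L)))))
  # identity map leaves the genome untouched
  set.seed(1)
  gf <- founder_genome(0)
  expect_identical(remap_pointers(gf, 0:31), gf)
  # deleting a referenced gene still yields a valid genome
  set.seed(2)
  for (i in 1:50) {
    gf <- founder_genome(0)
    drop <- sample(32, 1)
    pm <- rep(NA_integer_, 32)
    pm[-drop] <- 0:30
    g2 <- remap_pointers(as_genome(unclass(gf)[-drop, , drop = FALSE]), pm)
    expect_true(validate_genome(g2))
  }
})

test_that("genome text format round-trips and rejects malformed tokens", {
  set.seed(9)
  g1 <- founder_genome(3)
  g2 <- mutate_genome(g1, rates = 0.2)$genome
  g3 <- new_genome(c("OUTPUT", "NAND"), a = c(3L, NA), b = c(NA, 0L))
  path <- tempfile(fileext = ".txt")
  write_genomes(list(g1, g2, g3), path)
  back <- read_genomes(path)
  expect_length(back, 3)
  expect_identical(unname(unclass(back[[1]])), unname(unclass(g1)))
  expect_identical(unname(unclass(back[[2]])), unname(unclass(g2)))
  expect_identical(unname(unclass(back[[3]])), unname(unclass(g3)))
  writeLines(c("# comment", "", "I0 N-,- O->5 C"), path)
  g <- read_genomes(path)
  expect_length(g, 1)
  expect_identical(gene_kinds(g[[1]]), c("INPUT", "NAND", "OUTPUT",
                                         "CELLULARITY"))
  writeLines("I0 X3", path)
  expect_error(read_genomes(path), "malformed gene token")
})
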