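test_that("zero intensities produce empty trajectories", {
  g <- mt_fixture("toy")
  tr <- run_trajectory(g, sim_params(c(PH = 0, PL = 0), t_end = 100), seed = 1)
  expect_true(all(tr$gene_counts == 0))
  expect_equal(tr$bindings, 0)
  expect_equal(tr$terminations, 0)
  expect_equal(tr$collisions, 0)
})

test_that("identical seeds reproduce identical trajectories", {
  g <- mt_fixture("toy")
  p <- sim_params(c(PH = 0.05, PL = 0.03), t_end = 150)
  a <- run_trajectory(g, p, seed = 77)
  b <- run_trajectory(g, p, seed = 77)
  expect_identical(a$gene_counts, b$gene_counts)
  expect_identical(a$terminator, b$terminator)
  expect_identical(a$bindings, b$bindings)
})

test_that("polymerases are conserved exactly in every trajectory", {
  g <- mt_fixture("toy")
  for (seed in 1:10) {
    p <- sim_params(c(PH = 0.08, PL = 0.05), t_end = 120)
    tr <- run_trajectory(g, p, seed = seed)
    expect_equal(tr$bindings, tr$terminations + tr$active_at_end)
  }
  # also with a hot terminator and quadruplex sites
  g2 <- make_toy_genome(
    3000,
    promoter_specs = list(list(name = "PH", tss = 101, strand = "heavy"),
                          list(name = "PL", tss = 2901, strand = "light")),
    gene_specs = list(list(name = "G", start = 301, end = 800, strand = "heavy")),
    factor_specs = list(list(name = "T1", start = 1001, p = 0.5, q = 0.5,
                             lambda = 2)),
    quadruplex_specs = list(list(name = "Q1", start = 1501, end = 1530,
                                 strand = "heavy", prob = 0.4)))
  for (seed in 1:5) {
    tr <- run_trajectory(g2, sim_params(c(PH = 0.1, PL = 0.1), t_end = 100),
                         seed = seed)
    expect_equal(tr$bindings, tr$terminations + tr$active_at_end)
  }
})

test_that("meeting times follow circle arithmetic", {
  # gap 1000 nt closing at 2v = 1000 nt/s
  expect_equal(next_meeting_time(0, +1, 1000, -1, v = 500, length = 2000), 1.0)
  # co-directional polymerases at equal speed never meet
  expect_true(is.na(next_meeting_time(0, +1, 1000, +1, v = 500, length = 2000)))
  # converging arc of 1800 nt
  expect_equal(next_meeting_time(100, +1, 1900, -1, v = 500, length = 2000), 1.8)
  # converging across the origin: heavy at 1900 meets light at 100 at the
  # origin after the 200-nt arc closes
  expect_equal(next_meeting_time(1900, +1, 100, -1, v = 500, length = 2000), 0.2)
})

test_that("terminator passage draws follow p and q", {
  site <- list(pass_prob_heavy = 1, pass_prob_light = 0)
  set.seed(1)
  expect_true(all(encounter_factor("heavy", site, n = 1000) == "pass"))
  expect_true(all(encounter_factor("light", site, n = 1000) == "terminate"))

  site <- list(pass_prob_heavy = 0.0164, pass_prob_light = 0.0056)
  set.seed(42)
  draws <- encounter_factor("heavy", site, n = 1e5)
  f <- mean(draws == "pass")
  sigma <- sqrt(0.0164 * (1 - 0.0164) / 1e5)
  expect_lt(abs(f - 0.0164), 3 * sigma)
})

test_that("promoter occupancy rejects even partial overlap", {
  g <- mt_fixture("toy")      # PH footprint spans 0-based [85, 102)
  expect_true(promoter_available(g, "PH"))
  # heavy polymerase body [pos-15, pos+2): pos 116 puts its trailing edge
  # at 101, overlapping the footprint by exactly one nucleotide
  expect_false(promoter_available(g, "PH", pol_pos = 116, pol_dir = 1L))
  expect_true(promoter_available(g, "PH", pol_pos = 118, pol_dir = 1L))
  # a bound factor overlapping the footprint blocks binding
  g2 <- make_toy_genome(
    2000,
    promoter_specs = list(list(name = "P", tss = 100, strand = "heavy")),
    factor_specs = list(list(name = "F", start = 95, p = 1, q = 1,
                             lambda = 1)))
  expect_false(promoter_available(g2, "P", bound_sites = "F"))
})

test_that("binding acceptance shows the footprint-clearance dead time", {
  # lambda = 10/s against a 17 nt / 500 nt/s clearance: renewal rate
  # lambda / (1 + lambda * D)
  g <- long_circle_toy(gene = FALSE)
  p <- sim_params(c(P = 10), t_end = 200)
  tr <- run_trajectory(g, p, seed = 9)
  expected_rate <- 10 / (1 + 10 * 17 / 500)
  n_expected <- expected_rate * 200
  # renewal count SD: sqrt(n) * (sd/mean of the renewal interval)
  sd_n <- sqrt(n_expected) * (0.1 / (0.034 + 0.1))
  expect_lt(abs(tr$bindings - n_expected), 4 * sd_n)
})

test_that("quadruplex sites terminate with the configured probability", {
  g <- make_toy_genome(
    5000,
    promoter_specs = list(list(name = "P", tss = 101, strand = "heavy")),
    gene_specs = list(
      list(name = "up", start = 201, end = 700, strand = "heavy"),
      list(name = "down", start = 1201, end = 1700, strand = "heavy")),
    quadruplex_specs = list(list(name = "Q", start = 1001, end = 1030,
                                 strand = "heavy", prob = 1)))
  tr <- run_trajectory(g, sim_params(c(P = 0.05), t_end = 400), seed = 3)
  expect_gt(tr$gene_counts[["up"]], 0)
  expect_equal(tr$gene_counts[["down"]], 0)
  expect_equal(tr$quadruplex_stops, tr$bindings)   # every polymerase stops

  # prob = 0 is transparent
  g0 <- make_toy_genome(
    5000,
    promoter_specs = list(list(name = "P", tss = 101, strand = "heavy")),
    gene_specs = list(list(name = "down", start = 1201, end = 1700,
                           strand = "heavy")),
    quadruplex_specs = list(list(name = "Q", start = 1001, end = 1030,
                                 strand = "heavy", prob = 0)))
  tr0 <- run_trajectory(g0, sim_params(c(P = 0.05), t_end = 400), seed = 3)
  expect_gt(tr0$gene_counts[["down"]], 0)
})

test_that("counting respects the run-up window", {
  g <- long_circle_toy()
  p_full <- sim_params(c(P = 0.05), t_end = 400)
  p_half <- sim_params(c(P = 0.05), t_end = 400, run_up = 200)
  a <- run_trajectory(g, p_full, seed = 5)
  b <- run_trajectory(g, p_half, seed = 5)
  expect_identical(a$bindings, b$bindings)  # same event stream
  expect_lt(b$gene_counts[["G"]], a$gene_counts[["G"]])
  expect_equal(b$bindings, b$terminations + b$active_at_end)
})

test_that("raising one strand's intensity does not boost opposing genes", {
  g <- two_strand_toy()
  n <- 150
  lo <- sim_params(c(PH = 0.02, PL = 0.005), t_end = 300)
  hi <- sim_params(c(PH = 0.02, PL = 0.05), t_end = 300)
  # common random numbers: paired trajectory seeds
  d <- vapply(seq_len(n), function(i) {
    a <- run_trajectory(g, lo, seed = 1000 + i)$gene_counts
    b <- run_trajectory(g, hi, seed = 1000 + i)$gene_counts
    (b[["gH1"]] + b[["gH2"]]) - (a[["gH1"]] + a[["gH2"]])
  }, 0)
  expect_lte(mean(d), 3 * stats::sd(d) / sqrt(n))
})

test_that("degenerate inputs are rejected", {
  g <- mt_fixture("toy")
  expect_error(sim_params(c(PH = -1)), ">= 0")
  expect_error(sim_params(c(PH = 1), t_end = 0), "positive")
  expect_error(sim_params(c(PH = 1), p = 1.5), "probabilities")
  expect_error(sim_params(c(PH = 1), t_end = 10, run_up = 10), "run_up")
})
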