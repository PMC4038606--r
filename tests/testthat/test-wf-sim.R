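test_that("the genic selection update matches its closed form", {
  # neutral identity
  expect_equal(selection_update(0.3, 0), 0.3)
  # direct evaluation: p = 0.5, s = -0.01 -> 0.495/0.995
  expect_equal(selection_update(0.5, -0.01), 0.495 / 0.995)
  expect_equal(selection_update(0.5, -0.01), 0.4974874, tolerance = 1e-6)
  # lethal limit
  expect_equal(selection_update(0.7, -1), 0)
  expect_equal(selection_update(0.7, -2), 0)
  # strict monotone reduction for deleterious s on the open interval
  p <- seq(0.01, 0.99, by = 0.01)
  for (s in c(-1e-4, -0.01, -0.5)) expect_true(all(selection_update(p, s) < p))
  expect_true(all(selection_update(p, -0.01) > 0))
})

test_that("mutational influx has the configured class ratio and structure", {
  st <- population_state(
    tibble::tibble(s = numeric(), klass = character(), count = integer()),
    twoN = 10000)
  rates <- mutation_rates(mu_site = 1e-8, L_syn = 7000)  # 2N mu L_syn = 0.7
  set.seed(11)
  ks <- kn <- numeric(400)
  for (i in seq_len(400)) {
    out <- draw_new_mutations(st, rates, dfe_config())
    ks[i] <- sum(out$sites$klass == "syn")
    kn[i] <- sum(out$sites$klass == "ns")
  }
  # Poisson means 0.7 and 1.75 (= 2.5x): 3-SE Monte Carlo bands
  expect_lt(abs(mean(ks) - 0.7), 3 * sqrt(0.7 / 400))
  expect_lt(abs(mean(kn) - 2.5 * 0.7), 3 * sqrt(1.75 / 400))
  # structure of entered mutations
  set.seed(4)
  out <- draw_new_mutations(st, mutation_rates(1e-8, 7e7), dfe_config())
  expect_true(all(out$sites$count == 1L))
  expect_true(all(out$sites$s[out$sites$klass == "syn"] == 0))
  expect_true(all(out$sites$s[out$sites$klass == "ns"] < 0))
  # zero-rate case leaves the state unchanged
  out0 <- draw_new_mutations(st, mutation_rates(0, 7000), dfe_config())
  expect_equal(nrow(out0$sites), 0)
})

test_that("neutral drift is a martingale and fixes with probability p", {
  # brute force at 2N = 20 with mutation off: evolve many independent neutral
  # trajectories through generation_step until absorption; the fixation
  # probability of a variant at frequency p equals p
  twoN <- 20L
  for (count0 in c(2L, 10L)) {
    set.seed(100 + count0)
    n_traj <- 3000L
    st <- population_state(
      tibble::tibble(s = 0, klass = "syn", count = rep(count0, n_traj)),
      twoN = twoN)
    n_fixed <- 0L
    while (nrow(st$sites) > 0) {
      st <- generation_step(st, twoN)
      n_fixed <- n_fixed + attr(st, "n_fixed")
    }
    p0 <- count0 / twoN
    expect_lt(abs(n_fixed / n_traj - p0), 3 * sqrt(p0 * (1 - p0) / n_traj))
  }
  # one-step conservation of the mean frequency (fixations count as 2N)
  st <- population_state(
    tibble::tibble(s = 0, klass = "syn", count = rep(50L, 4000)),
    twoN = 100L)
  set.seed(5)
  nxt <- generation_step(st, 100L)
  total <- sum(nxt$sites$count) + 100L * attr(nxt, "n_fixed")
  se <- sqrt(4000 * 100 * 0.5 * 0.5)  # binomial variance per site
  expect_lt(abs(total - 4000 * 50), 3 * se)
})

test_that("compiled and reference engines are stream-identical", {
  m <- rescale_model(
    canonical_model("BN_growth", N_ancestral = 200, burn_in = 400), 2)
  rates <- mutation_rates(mu_site = 1e-6, L_syn = 2000)
  dfe <- dfe_config(shape = 0.184, mean_s = 0.0257)
  a <- run_model(m, rates, dfe, seed = 99, snapshot_times = c(0, 100),
                 engine = "compiled")
  b <- run_model(m, rates, dfe, seed = 99, snapshot_times = c(0, 100),
                 engine = "r")
  for (nm in names(a$snapshots)) {
    expect_equal(as.data.frame(a$snapshots[[nm]]$sites),
                 as.data.frame(b$snapshots[[nm]]$sites))
    expect_equal(a$snapshots[[nm]]$twoN, b$snapshots[[nm]]$twoN)
  }
})

test_that("runs are reproducible from the seed and respect the timeline", {
  m <- demographic_model(data.frame(N = 50, duration = 40), burn_in = 200)
  rates <- mutation_rates(mu_site = 1e-6, L_syn = 2000)
  s1 <- run_model(m, rates, dfe_config(), seed = 7)
  s2 <- run_model(m, rates, dfe_config(), seed = 7)
  expect_identical(s1$snapshots, s2$snapshots)
  # zero mutation rate -> empty segregating set
  s0 <- run_model(m, mutation_rates(0, 2000), dfe_config(), seed = 7)
  expect_equal(nrow(present_state(s0)$sites), 0)
  # snapshot outside the timeline errors
  expect_error(run_model(m, rates, dfe_config(), seed = 1,
                         snapshot_times = 1e6), "timeline")
})

test_that("chromosome sampling is hypergeometric with a census limit", {
  st <- population_state(
    tibble::tibble(s = c(0, -0.001), klass = c("syn", "ns"),
                   count = c(100L, 1L)),
    twoN = 10000L)
  expect_error(sample_chromosomes(st, 20000), "more chromosomes")
  # census case returns the population counts
  smp <- sample_chromosomes(st, 10000L)
  expect_equal(smp$sample_count, c(100L, 1L))
  # singleton present in a 10% sample with probability 0.1
  set.seed(9)
  present <- replicate(4000, sample_chromosomes(st, 1000L)$sample_count[2] > 0)
  expect_lt(abs(mean(present) - 0.1), 3 * sqrt(0.1 * 0.9 / 4000))
  # mean sampled count of the common site = 10% of its population count
  set.seed(10)
  cnts <- replicate(2000, sample_chromosomes(st, 1000L)$sample_count[1])
  expect_lt(abs(mean(cnts) - 10), 3 * sd(cnts) / sqrt(2000))
})

test_that("sample summaries count classes and average selection correctly", {
  tab <- tibble::tibble(
    s = c(rep(0, 10), rep(c(-0.01, -0.03), 5)),
    klass = c(rep("syn", 10), rep("ns", 10)),
    count = 5L, origin = 0L,
    sample_count = c(rep(3L, 19), 0L),
    in_sample = c(rep(TRUE, 19), FALSE))
  ss <- summarize_sample(tab, 100)
  expect_equal(ss$S_syn, 10)
  expect_equal(ss$S_ns, 9)
  expect_equal(ss$prop_ns, 9 / 19)
  # mean |s| over ns sites in the sample: five at 0.01, four at 0.03
  expect_equal(ss$mean_abs_s, mean(c(rep(0.01, 5), rep(0.03, 4))))
  # empty sample is flagged with NA statistics
  empty <- tab[0, ]
  ss0 <- summarize_sample(empty, 100)
  expect_equal(ss0$S_syn + ss0$S_ns, 0)
  expect_true(is.na(ss0$prop_ns) && is.na(ss0$mean_abs_s))
  # two-class arithmetic example
  two <- tibble::tibble(s = c(-0.01, -0.03), klass = "ns", count = 5L,
                        origin = 0L, sample_count = 2L, in_sample = TRUE)
  expect_equal(summarize_sample(two, 100)$mean_abs_s, 0.02)
})

test_that("genetic load follows the multiplicative formula", {
  st <- population_state(
    tibble::tibble(s = c(-0.1, -0.5), klass = "ns", count = c(10L, 1L)),
    twoN = 1000L)
  expect_equal(genetic_load(st), 1 - (1 - 0.01 * 0.1) * (1 - 0.001 * 0.5))
  expect_equal(genetic_load(st), 0.0014995, tolerance = 1e-7)
  expect_equal(genetic_load(st, method = "additive"),
               0.01 * 0.1 + 0.001 * 0.5)
  # no deleterious segregating sites -> zero load
  neutral <- population_state(
    tibble::tibble(s = 0, klass = "syn", count = 100L), twoN = 1000L)
  expect_equal(genetic_load(neutral), 0)
  empty <- population_state(
    tibble::tibble(s = numeric(), klass = character(), count = integer()),
    twoN = 1000L)
  expect_equal(genetic_load(empty), 0)
})
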