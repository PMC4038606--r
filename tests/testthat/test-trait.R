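make_sites <- function(s, p = 0.1, twoN = 1000L, klass = "ns",
                       causal = TRUE) {
  tibble::tibble(s = s, klass = klass, count = round(p * twoN),
                 is_causal = causal)
}

test_that("causal thinning follows the target-to-locus ratio", {
  sites <- tibble::tibble(s = -0.01, klass = rep(c("ns", "syn"), each = 4000),
                          count = 5L)
  expect_error(select_causal(sites, 2e5, 1e5), "cannot exceed")
  all_in <- select_causal(sites, 1e5, 1e5)
  expect_true(all(all_in$is_causal[all_in$klass == "ns"]))
  expect_false(any(all_in$is_causal[all_in$klass == "syn"]))
  none <- select_causal(sites, 0, 1e5)
  expect_false(any(none$is_causal))
  set.seed(21)
  half <- select_causal(sites, 70000, 140000)
  frac <- mean(half$is_causal[half$klass == "ns"])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("effect sizes follow alpha = delta |s|^tau (1 + eps) C", {
  # deterministic case (eps_sd = 0): sqrt coupling
  cfg <- trait_config(tau = 0.5, eps_sd = 0)
  arch <- assign_effects(make_sites(-0.01), cfg, C = 1, twoN = 1000L)
  expect_equal(arch$sites$alpha, 0.1)
  # tau = 0 decouples effects from s, including s = 0
  cfg0 <- trait_config(tau = 0, eps_sd = 0)
  arch0 <- assign_effects(make_sites(c(-0.5, -1e-9, 0)), cfg0, C = 2,
                          twoN = 1000L)
  expect_equal(arch0$sites$alpha, rep(2, 3))
  # tau > 0 with a neutral causal site gives alpha = 0 (documented, no error)
  archz <- assign_effects(make_sites(0), cfg, C = 1, twoN = 1000L)
  expect_equal(archz$sites$alpha, 0)
  # noise scale: sd(alpha)/|mean(alpha)| = eps_sd at fixed s
  set.seed(31)
  cfgn <- trait_config(tau = 0.5, eps_sd = 0.5)
  archn <- assign_effects(make_sites(rep(-0.04, 20000)), cfgn, C = 1,
                          twoN = 1000L)
  expect_equal(sd(archn$sites$alpha) / mean(archn$sites$alpha), 0.5,
               tolerance = 0.03)
  # delta scales the sign/magnitude linearly
  cfgd <- trait_config(tau = 0.5, eps_sd = 0, delta = -2)
  expect_equal(assign_effects(make_sites(-0.01), cfgd, C = 1,
                              twoN = 1000L)$sites$alpha, -0.2)
})

test_that("C calibration inverts the heritability relation", {
  # closed-form oracle: C = sqrt((h2/(1-h2)) V_E / X); with eps_sd = 0 and
  # tau = 0, X = 2 p (1-p), so pick p with 2p(1-p) = 0.05 to hit the printed
  # example C = 2.9277
  p <- (1 - sqrt(1 - 2 * 0.05)) / 2
  cfg <- trait_config(tau = 0, h2_target = 0.3, eps_sd = 0, V_E = 1)
  sites <- list(tibble::tibble(s = -0.01, p = p))
  C <- calibrate_C(sites, cfg)
  expect_equal(as.numeric(C), sqrt((0.3 / 0.7) / 0.05), tolerance = 1e-12)
  expect_equal(as.numeric(C), 2.92770, tolerance = 1e-5)
  # independent check: the calibrated C actually yields h2_target
  X <- 2 * p * (1 - p)
  expect_equal(as.numeric(C)^2 * X / (as.numeric(C)^2 * X + 1), 0.3,
               tolerance = 1e-12)
  # X scaled by 4 halves C
  p4 <- (1 - sqrt(1 - 2 * 0.2)) / 2  # 2p(1-p) = 0.2
  C4 <- calibrate_C(list(tibble::tibble(s = -0.01, p = p4)), cfg)
  expect_equal(as.numeric(C4), as.numeric(C) / 2, tolerance = 1e-12)
  # h2 -> 0 drives C -> 0
  cfg_small <- trait_config(tau = 0, h2_target = 1e-8, eps_sd = 0)
  expect_lt(as.numeric(calibrate_C(sites, cfg_small)), 1e-3)
  # degenerate replicate (no causal variation) is skipped with a warning
  expect_warning(
    C2 <- calibrate_C(c(sites, list(tibble::tibble(s = numeric(),
                                                   p = numeric()))), cfg),
    "skipped")
  expect_equal(as.numeric(C2), as.numeric(C))
})

test_that("variance decompositions are exact and conserve V_A", {
  single <- make_fixture("single_common")
  vd <- variance_decomposition(single)
  expect_equal(vd$V_A, 0.5)  # 2 * 0.5 * 0.5 * 1
  expect_equal(vd$h2, 0.5 / 1.5)
  # term-by-term evaluation for two SNPs: (0.5, 1) and (0.1, 2)
  arch2 <- structure(list(
    sites = tibble::tibble(site = 1:2, s = c(-1e-4, -1e-3), p = c(0.5, 0.1),
                           age_gen = c(100, 10), alpha = c(1, 2)),
    C = 1, cfg = trait_config()), class = "trait_architecture")
  vd2 <- variance_decomposition(arch2)
  expect_equal(vd2$V_A, 0.5 + 2 * 0.1 * 0.9 * 4)
  expect_equal(vd2$V_A, 1.22)
  # partitions over exhaustive disjoint bins conserve V_A to 1e-9 relative
  set.seed(41)
  arch_big <- structure(list(
    sites = tibble::tibble(site = 1:500,
                           s = -rgamma(500, 0.2, rate = 10),
                           p = runif(500, 1e-4, 0.999),
                           age_gen = sample(1:4000, 500, TRUE),
                           alpha = rnorm(500)),
    C = 1, cfg = trait_config()), class = "trait_architecture")
  vdb <- variance_decomposition(arch_big)
  expect_equal(sum(vdb$by_age$V_A), vdb$V_A, tolerance = 1e-9)
  expect_equal(max(vdb$by_frequency$fraction), 1, tolerance = 1e-9)
  # top-k fractions are monotone and reach V_A at k = n_causal
  fr <- vdb$by_topk$frac_V_A
  expect_true(all(diff(fr) >= 0))
  vd_all <- variance_decomposition(arch_big, top_k = c(10, 500))
  expect_equal(vd_all$by_topk$frac_V_A[2], 1, tolerance = 1e-12)
})

test_that("phenotypes are additive in dosages with Gaussian noise", {
  arch <- structure(list(
    sites = tibble::tibble(site = 1, s = -0.01, p = 0.3, age_gen = 1,
                           alpha = 0.3),
    C = 1, cfg = trait_config(V_E = 0)), class = "trait_architecture")
  # single homozygote, no environment: Y = 2 * 0.3
  expect_equal(phenotypes(arch, matrix(2, 1, 1)), 0.6)
  expect_equal(phenotypes(arch, matrix(0, 5, 1)), rep(0, 5))
  expect_error(phenotypes(arch, matrix(0, 5, 3)), "causal sites")
  # pure environmental model: sample variance of Y approximately V_E
  arch0 <- structure(list(
    sites = tibble::tibble(site = 1, s = -0.01, p = 0.3, age_gen = 1,
                           alpha = 0),
    C = 1, cfg = trait_config(V_E = 1)), class = "trait_architecture")
  set.seed(51)
  Y <- phenotypes(arch0, matrix(1, 4000, 1))
  expect_equal(var(Y), 1, tolerance = 0.1)
})
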