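#' Trait-model configuration
#'
#' Parameters of the fitness-trait coupling model. A causal SNP's effect on
#' the trait is `alpha_i = delta * |s_i|^tau * (1 + eps_i) * C`, with
#' `eps_i ~ Normal(0, eps_sd^2)`. `tau = 0.5` couples trait effects to
#' selection (more deleterious mutations have larger effects); `tau = 0`
#' decouples them. `C` is a normalising constant calibrated once under a
#' constant-size history (see [calibrate_C()]) so that the mutational target
#' accounts for the requested heritability, and is then frozen across
#' demographies.
#'
#' @param tau Fitness-trait coupling exponent (0 or 0.5 in the study design).
#' @param h2_target Heritability attributable to the mutational target
#'   (0.05, 0.1 or 0.3 in the study design).
#' @param M Mutational target size in base pairs (70,000 or 140,000).
#' @param eps_sd Standard deviation of the per-SNP noise `eps_i` (0.5).
#' @param delta Sign constant (1: causal alleles increase the trait/liability).
#' @param V_E Environmental variance, in squared trait units. Fixed at 1 by
#'   default; any positive value only rescales the trait units.
#' @return An object of class `trait_config`.
#' @export
trait_config <- function(tau = 0.5, h2_target = 0.3, M = 70000,
                         eps_sd = 0.5, delta = 1, V_E = 1) {
  stopifnot(tau >= 0, h2_target > 0, h2_target < 1, eps_sd >= 0, V_E >= 0)
  structure(list(tau = tau, h2_target = h2_target, M = M, eps_sd = eps_sd,
                 delta = delta, V_E = V_E),
            class = "trait_config")
}

#' Flag causal sites within the nonsynonymous target
#'
#' The mutational target of `M` base pairs is a random subset of the
#' nonsynonymous target of `L_ns` base pairs: each nonsynonymous site is
#' causal independently with probability `M / L_ns` (a thinned subprocess).
#'
#' @param sites Site tibble (e.g. from a [population_state()]).
#' @param M Mutational target size (bp), `M <= L_ns`.
#' @param L_ns Nonsynonymous target size (bp).
#' @return `sites` with a logical `is_causal` column (always `FALSE` for
#'   synonymous sites).
#' @export
select_causal <- function(sites, M, L_ns) {
  if (M > L_ns) stop("mutational target M cannot exceed the nonsynonymous target L_ns")
  sites <- tibble::as_tibble(sites)
  sites$is_causal <- sites$klass == "ns" & runif(nrow(sites)) < M / L_ns
  sites
}

#' Assign trait effect sizes to causal sites
#'
#' Applies `alpha_i = delta * |s_i|^tau * (1 + eps_i) * C` independently per
#' causal site, `eps_i ~ Normal(0, eps_sd^2)`. For `tau = 0`, `|s|^0 == 1` for
#' every site including `s = 0`; for `tau > 0` a neutral causal site gets
#' `alpha = 0`. `(1 + eps_i)` is not truncated, so a small fraction of effects
#' flip sign.
#'
#' @param sites Site tibble with an `is_causal` column (see [select_causal()])
#'   and a frequency column `p` or `count` plus `twoN` attribute; frequencies
#'   are taken as `count / twoN` when `p` is absent.
#' @param cfg A [trait_config()].
#' @param C Normalising constant (> 0), from [calibrate_C()].
#' @param twoN Haploid population size used to convert counts to frequencies
#'   (required when `sites` has no `p` column).
#' @return An object of class `trait_architecture`: list with `sites` (tibble
#'   of causal sites: `site`, `s`, `p`, `age_gen`, `alpha`), `C`, `cfg`.
#' @export
#' @examples
#' sites <- data.frame(s = c(-0.01, -0.04), klass = "ns", count = c(5, 1),
#'                     is_causal = TRUE)
#' arch <- assign_effects(sites, trait_config(tau = 0.5), C = 1, twoN = 1000)
#' arch$sites
assign_effects <- function(sites, cfg, C, twoN = NULL) {
  stopifnot(inherits(cfg, "trait_config"), C > 0)
  sites <- tibble::as_tibble(sites)
  if (!"p" %in% names(sites)) {
    if (is.null(twoN)) stop("supply twoN to convert counts to frequencies")
    sites$p <- sites$count / twoN
  }
  causal <- sites[sites$is_causal, ]
  eps <- rnorm(nrow(causal), 0, cfg$eps_sd)
  raw <- if (cfg$tau == 0) rep(1, nrow(causal)) else abs(causal$s)^cfg$tau
  alpha <- cfg$delta * raw * (1 + eps) * C
  structure(
    list(sites = tibble::tibble(
           site = seq_len(nrow(causal)),
           s = causal$s, p = causal$p,
           age_gen = if ("age_gen" %in% names(causal)) causal$age_gen
                     else rep(NA_real_, nrow(causal)),
           alpha = alpha),
         C = C, cfg = cfg),
    class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("<trait_architecture> tau =", x$cfg$tau, " C =", signif(x$C, 5),
      " causal sites =", nrow(x$sites), "\n")
  invisible(x)
}

# Raw (un-normalised) genetic variance of one replicate's causal set:
# X = 2 sum p(1-p) (|s|^tau (1+eps))^2.
raw_target_variance <- function(causal, cfg) {
  eps <- rnorm(nrow(causal), 0, cfg$eps_sd)
  raw <- if (cfg$tau == 0) rep(1, nrow(causal)) else abs(causal$s)^cfg$tau
  2 * sum(causal$p * (1 - causal$p) * (raw * (1 + eps))^2)
}

#' Calibrate the effect-size normalising constant C
#'
#' For each constant-size reference replicate `r`, the raw target variance is
#' `X_r = 2 sum p_i (1 - p_i) (|s_i|^tau (1 + eps_i))^2` over its causal
#' sites, and `C_r = sqrt((h2 / (1 - h2)) * V_E / X_r)` is the constant that
#' would give exactly the target heritability in that replicate. The returned
#' `C` is the mean of `C_r` over replicates; it is then frozen and reused
#' under every demographic history, so that a SNP with a given trait effect
#' has that same effect regardless of the population's history. Realised
#' heritability per replicate is therefore stochastic.
#'
#' @param reference_sites A list of causal-site tibbles (columns `s`, `p`),
#'   one per constant-size replicate; conveniently produced by
#'   [simulate_causal_sites()].
#' @param cfg A [trait_config()].
#' @return The calibrated constant `C` (scalar), with attribute `C_r` giving
#'   the per-replicate values. Replicates with `X_r = 0` are skipped with a
#'   warning.
#' @export
calibrate_C <- function(reference_sites, cfg) {
  stopifnot(inherits(cfg, "trait_config"), cfg$V_E > 0)
  X <- vapply(reference_sites, raw_target_variance, numeric(1), cfg = cfg)
  if (any(X == 0)) {
    warning(sum(X == 0), " replicate(s) with zero raw variance skipped")
    X <- X[X > 0]
  }
  if (!length(X)) stop("no usable calibration replicates")
  Cr <- sqrt((cfg$h2_target / (1 - cfg$h2_target)) * cfg$V_E / X)
  structure(mean(Cr), C_r = Cr)
}

#' Additive-variance decomposition of a trait architecture
#'
#' Computes `V_A = 2 sum p_i (1 - p_i) alpha_i^2`, the phenotypic variance
#' `V_P = V_A + V_E`, the realised heritability `h2 = V_A / V_P`, and three
#' partitions of `V_A`:
#' * `by_frequency`: cumulative fraction of `V_A` from sites with population
#'   frequency below each threshold;
#' * `by_age`: disjoint mutation-age classes (older than `age_breaks[1]`
#'   generations; between the breaks; younger than `age_breaks[2]`), the
#'   age classes of the bottleneck / recovery / recent-growth timeline;
#' * `by_topk`: cumulative share of `V_A` and of `V_P` captured by the `k`
#'   sites with the largest per-site variance `2 p (1-p) alpha^2`.
#'
#' Disjoint partitions sum to `V_A` exactly (to numerical round-off).
#'
#' @param arch A [trait_architecture()].
#' @param freq_thresholds Frequency thresholds for the cumulative partition.
#' @param age_breaks Two age boundaries in generations before sampling
#'   (defaults 1960 and 80: before-bottleneck / after-bottleneck /
#'   after-growth).
#' @param top_k Values of `k` for the top-k partition.
#' @return An object of class `variance_decomposition`.
#' @export
variance_decomposition <- function(arch,
                                   freq_thresholds = c(0.0005, 0.001, 0.005,
                                                       0.01, 0.05, 0.1, 0.5, 1),
                                   age_breaks = c(1960, 80),
                                   top_k = c(1, 5, 10, 25, 50, 100)) {
  stopifnot(inherits(arch, "trait_architecture"))
  st <- arch$sites
  v <- 2 * st$p * (1 - st$p) * st$alpha^2
  V_A <- sum(v)
  V_E <- arch$cfg$V_E
  by_freq <- tibble::tibble(
    threshold = freq_thresholds,
    V_A_below = vapply(freq_thresholds, function(th) sum(v[st$p < th]),
                       numeric(1)))
  by_freq$fraction <- if (V_A > 0) by_freq$V_A_below / V_A else NA_real_
  age <- st$age_gen
  cls <- cut(-age, breaks = c(-Inf, -age_breaks, Inf),
             labels = c("before_bottleneck", "after_bottleneck", "after_growth"))
  by_age <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(class = cls, v = v), .data$class,
                    .drop = FALSE),
    n_sites = dplyr::n(), V_A = sum(.data$v), .groups = "drop")
  by_age$fraction <- if (V_A > 0) by_age$V_A / V_A else NA_real_
  vs <- sort(v, decreasing = TRUE)
  kk <- pmin(top_k, length(vs))
  topsum <- vapply(kk, function(k) sum(vs[seq_len(k)]), numeric(1))
  by_topk <- tibble::tibble(
    k = top_k,
    V_A_top = topsum,
    frac_V_A = if (V_A > 0) topsum / V_A else NA_real_,
    frac_V_P = topsum / (V_A + V_E))
  structure(list(V_A = V_A, V_P = V_A + V_E, h2 = V_A / (V_A + V_E),
                 by_frequency = by_freq, by_age = by_age, by_topk = by_topk,
                 per_site_variance = v),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("<variance_decomposition> V_A =", signif(x$V_A, 5),
      " h2 =", signif(x$h2, 4), "\n")
  invisible(x)
}

#' Additive phenotypes from genotype dosages
#'
#' `Y_j = sum_i z_ij alpha_i + eps_j`, `eps_j ~ Normal(0, V_E)`.
#'
#' @param arch A [trait_architecture()].
#' @param genotypes Integer matrix of dosages in `{0,1,2}`, individuals in
#'   rows, causal sites in columns (column order matching `arch$sites`).
#' @param cfg A [trait_config()] (defaults to the architecture's own).
#' @return Numeric phenotype vector, one entry per individual.
#' @export
phenotypes <- function(arch, genotypes, cfg = arch$cfg) {
  stopifnot(inherits(arch, "trait_architecture"))
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != nrow(arch$sites))
    stop("genotype matrix has ", ncol(genotypes),
         " columns but the architecture has ", nrow(arch$sites), " causal sites")
  drop(genotypes %*% arch$sites$alpha) +
    rnorm(nrow(genotypes), 0, sqrt(cfg$V_E))
}
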