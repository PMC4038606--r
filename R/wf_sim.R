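#' @useDynLib demarch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang %||% .data
#' @importFrom stats rbinom rpois rgamma rhyper rnorm runif qnorm quantile
#'   median cor dhyper setNames
NULL

new_population_state <- function(sites, twoN, generation = 0L) {
  structure(list(sites = tibble::as_tibble(sites), twoN = as.integer(twoN),
                 generation = as.integer(generation)),
            class = "population_state")
}

#' Create a population state from a site table
#'
#' A population state is the full set of segregating mutations at one
#' generation: per site a selection coefficient `s` (<= 0), a functional class
#' `klass` (`"syn"` or `"ns"`), a derived-allele copy number `count`
#' (0 < count < 2N), and the generation of origin `origin`.
#'
#' @param sites Data frame with columns `s`, `klass`, `count` and optionally
#'   `origin` (defaults to 0).
#' @param twoN Haploid population size (number of chromosomes).
#' @param generation Generation index of the state.
#' @return An object of class `population_state`.
#' @export
#' @examples
#' population_state(data.frame(s = c(0, -0.01), klass = c("syn", "ns"),
#'                             count = c(5, 1)), twoN = 100)
population_state <- function(sites, twoN, generation = 0L) {
  sites <- tibble::as_tibble(sites)
  if (!"origin" %in% names(sites)) sites$origin <- 0L
  stopifnot(all(c("s", "klass", "count") %in% names(sites)),
            all(sites$count > 0), all(sites$count < twoN),
            all(sites$klass %in% c("syn", "ns")),
            all(sites$s[sites$klass == "syn"] == 0))
  new_population_state(sites[c("s", "klass", "count", "origin")], twoN, generation)
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> 2N =", x$twoN, " generation =", x$generation,
      " segregating sites =", nrow(x$sites), "\n")
  invisible(x)
}

#' Add newly arising mutations to a population state
#'
#' A Poisson-distributed number of new mutations enters the population each
#' generation: `K_syn ~ Poisson(2N * mu_site * L_syn)` synonymous and
#' `K_ns ~ Poisson(2N * mu_site * L_ns)` nonsynonymous mutations, each as a
#' single copy. Nonsynonymous selection coefficients are drawn from the
#' (negated) gamma DFE; synonymous mutations are neutral.
#'
#' @param state A [population_state()].
#' @param rates A [mutation_rates()].
#' @param dfe A [dfe_config()] or [dfe_neutral()].
#' @return The updated `population_state`.
#' @export
draw_new_mutations <- function(state, rates, dfe) {
  stopifnot(inherits(state, "population_state"))
  k_syn <- rpois(1, state$twoN * rates$mu_site * rates$L_syn)
  k_ns <- rpois(1, state$twoN * rates$mu_site * rates$L_ns)
  s_new <- if (k_ns > 0 && !dfe$neutral)
    -rgamma(k_ns, shape = dfe$shape, scale = dfe$mean_s / dfe$shape)
  else rep(0, k_ns)
  add <- tibble::tibble(
    s = c(rep(0, k_syn), s_new),
    klass = c(rep("syn", k_syn), rep("ns", k_ns)),
    count = 1L,
    origin = state$generation)
  state$sites <- dplyr::bind_rows(state$sites, add)
  state
}

#' Advance a population state by one Wright-Fisher generation
#'
#' Each segregating site is updated independently: the derived-allele
#' frequency `p = count / 2N` first changes deterministically by genic
#' selection, `p* = p (1 + s) / (1 + p s)` (equivalent to additive diploid
#' selection with h = 1/2 to first order; `s <= -1` is lethal, `p* = 0`), and
#' the next generation's copy number is then drawn as
#' `Binomial(next_twoN, p*)`. Sites that are lost or fixed leave the
#' segregating set.
#'
#' @param state A [population_state()].
#' @param next_twoN Haploid size of the offspring generation (>= 4).
#' @return The `population_state` of the next generation.
#' @export
#' @examples
#' st <- population_state(data.frame(s = -0.01, klass = "ns", count = 50),
#'                        twoN = 100)
#' generation_step(st, 100)
generation_step <- function(state, next_twoN) {
  stopifnot(inherits(state, "population_state"), next_twoN >= 4)
  p <- state$sites$count / state$twoN
  s <- state$sites$s
  pstar <- ifelse(s <= -1, 0, p * (1 + s) / (1 + p * s))
  cnt <- rbinom(length(pstar), next_twoN, pstar)
  keep <- cnt > 0L & cnt < next_twoN
  sites <- state$sites[keep, ]
  sites$count <- cnt[keep]
  out <- new_population_state(sites, next_twoN, state$generation + 1L)
  # absorption log of this one step (fixations are dropped from the set)
  attr(out, "n_fixed") <- sum(cnt == next_twoN)
  attr(out, "n_lost") <- sum(cnt == 0L)
  out
}

#' Selection update of an allele frequency under genic selection
#'
#' @param p Derived-allele frequency in (0, 1).
#' @param s Selection coefficient (<= 0; `s <= -1` is lethal).
#' @return The post-selection frequency `p* = p(1+s)/(1+ps)`.
#' @export
selection_update <- function(p, s) ifelse(s <= -1, 0, p * (1 + s) / (1 + p * s))

# Pure-R engine mirroring wf_core_cpp draw-for-draw (reference implementation,
# used to validate the compiled core; identical RNG stream).
wf_engine_r <- function(sizes, muL_syn, muL_ns, shape, scale, neutral_ns,
                        snapshot_at) {
  st <- new_population_state(
    tibble::tibble(s = numeric(), klass = character(), count = integer(),
                   origin = integer()),
    twoN = sizes[1], generation = 0L)
  rates_unit <- structure(list(mu_site = 1, L_syn = muL_syn, L_ns = muL_ns),
                          class = "mutation_rates")
  dfe <- if (neutral_ns) dfe_neutral()
         else dfe_config(shape = shape, mean_s = shape * scale)
  snaps <- vector("list", length(snapshot_at))
  Tn <- length(sizes) - 1L
  for (t in seq_len(Tn)) {
    st <- generation_step(st, sizes[t + 1L])
    st$generation <- t  # mutations entering generation t carry origin t
    st <- draw_new_mutations(st, rates_unit, dfe)
    i <- match(t, snapshot_at)
    if (!is.na(i)) {
      snaps[[i]] <- tibble::tibble(
        s = st$sites$s,
        klass = ifelse(st$sites$klass == "syn", 0L, 1L),
        count = st$sites$count,
        origin = st$sites$origin)
    }
  }
  list(snapshots = snaps)
}

#' Run a forward Wright-Fisher simulation under a demographic model
#'
#' Iterates mutation and drift-with-selection through the burn-in (starting
#' from a mutation-free population) and every epoch of `model`, recording the
#' segregating set at the requested time points. If the model was produced by
#' [rescale_model()], the stored multipliers are applied internally (mutation
#' rate and selection coefficients multiplied by lambda) and all outputs are
#' reported back on the natural scale: selection coefficients are divided by
#' lambda and mutation ages multiplied by lambda.
#'
#' @param model A [demographic_model()] (possibly rescaled).
#' @param rates A [mutation_rates()] on the natural (unrescaled) scale.
#' @param dfe A [dfe_config()] on the natural scale.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param snapshot_times Generations before sampling (on the natural scale) at
#'   which to record the population; `0` is the present. Times are converted
#'   to the rescaled timeline and must fall inside it.
#' @param engine `"compiled"` (default) or `"r"` (reference implementation;
#'   identical output for identical seeds).
#' @return An object of class `wf_sim`: list with `snapshots` (one
#'   [population_state()] per snapshot time, sites carrying natural-scale `s`,
#'   `klass`, `count`, and `age_gen` = natural generations before sampling at
#'   which the mutation arose), `model`, `rates`, `dfe`, `seed`.
#' @export
#' @examples
#' m <- rescale_model(canonical_model("constant", N_ancestral = 500,
#'                                    burn_in = 2000), 2)
#' sim <- run_model(m, mutation_rates(1e-8, 5000), dfe_config(), seed = 1)
#' present_state(sim)
run_model <- function(model, rates, dfe, seed,
                      snapshot_times = 0, engine = c("compiled", "r")) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(rates, "mutation_rates"), inherits(dfe, "dfe_config"))
  engine <- match.arg(engine)
  lam <- model$lambda
  sizes <- model_size_series(model)
  Tn <- length(sizes) - 1L
  timeline <- model_timeline(model)
  snap_back <- as.integer(round(snapshot_times / lam))
  if (any(snap_back < 0) || any(snap_back > timeline + model$burn_in - 1L))
    stop("snapshot time outside the simulated timeline")
  snap_at <- sort(unique(Tn - snap_back))
  muL_syn <- rates$mu_site * model$mu_multiplier * rates$L_syn
  muL_ns <- rates$mu_site * model$mu_multiplier * rates$L_ns
  scale <- if (dfe$neutral) 1 else (dfe$mean_s / dfe$shape) * model$s_multiplier
  set.seed(seed)
  res <- if (engine == "compiled")
    wf_core_cpp(sizes, muL_syn, muL_ns, dfe$shape, scale, dfe$neutral, snap_at)
  else
    wf_engine_r(sizes, muL_syn, muL_ns, dfe$shape, scale, dfe$neutral, snap_at)
  snaps <- purrr::map2(res$snapshots, snap_at, function(df, t) {
    sites <- tibble::tibble(
      s = df$s / lam,
      klass = ifelse(df$klass == 0L, "syn", "ns"),
      count = df$count,
      origin = df$origin,
      age_gen = (t - df$origin) * lam)
    new_population_state(sites, twoN = sizes[t + 1L], generation = t)
  })
  # snap_at ascending corresponds to generations-before-present descending
  names(snaps) <- paste0("t_minus_", (Tn - snap_at) * lam)
  structure(list(snapshots = snaps, model = model, rates = rates, dfe = dfe,
                 seed = seed),
            class = "wf_sim")
}

#' Present-day population state of a simulation
#' @param sim A `wf_sim` object from [run_model()].
#' @return The final [population_state()] (sampling time), if recorded.
#' @export
present_state <- function(sim) {
  stopifnot(inherits(sim, "wf_sim"))
  sim$snapshots[["t_minus_0"]] %||%
    sim$snapshots[[length(sim$snapshots)]]
}

#' Sample chromosomes from a population state
#'
#' Draws `n_chrom` chromosomes without replacement; per site the sampled copy
#' number is hypergeometric with the site's population count. A site
#' "segregates in the sample" when its sampled count is strictly between 0 and
#' `n_chrom`.
#'
#' @param state A [population_state()].
#' @param n_chrom Number of chromosomes to sample (<= 2N).
#' @return The site tibble with columns `sample_count` and `in_sample` added.
#' @export
sample_chromosomes <- function(state, n_chrom) {
  stopifnot(inherits(state, "population_state"))
  if (n_chrom > state$twoN)
    stop("cannot sample more chromosomes than the population holds")
  sites <- state$sites
  sites$sample_count <- rhyper(nrow(sites), m = sites$count,
                               n = state$twoN - sites$count, k = n_chrom)
  sites$in_sample <- sites$sample_count > 0L & sites$sample_count < n_chrom
  sites
}

#' Summarise deleterious variation in a sample of chromosomes
#'
#' @param sample_sites Output of [sample_chromosomes()].
#' @param n_chrom The sample size used.
#' @return One-row tibble: `n_chrom`, segregating synonymous (`S_syn`) and
#'   nonsynonymous (`S_ns`) counts, `prop_ns = S_ns / (S_syn + S_ns)`, and
#'   `mean_abs_s`, the mean absolute selection coefficient of nonsynonymous
#'   sites segregating in the sample (`NA` when there are none).
#' @export
summarize_sample <- function(sample_sites, n_chrom) {
  seg <- sample_sites[sample_sites$in_sample, ]
  S_syn <- sum(seg$klass == "syn")
  S_ns <- sum(seg$klass == "ns")
  tibble::tibble(
    n_chrom = n_chrom, S_syn = S_syn, S_ns = S_ns,
    prop_ns = if (S_syn + S_ns > 0) S_ns / (S_syn + S_ns) else NA_real_,
    mean_abs_s = if (S_ns > 0) mean(abs(seg$s[seg$klass == "ns"])) else NA_real_)
}

#' Genetic load of a population
#'
#' The proportional reduction in population mean fitness caused by segregating
#' deleterious mutations. With genic selection the per-site mean fitness is
#' `1 + p * s`; combining sites multiplicatively,
#' `load = 1 - prod(1 + p_i * s_i)`. An additive variant `sum(p_i * |s_i|)` is
#' available. Optionally the load is computed over the sites segregating in a
#' sample of `n_individuals` diploids (using population frequencies), matching
#' the convention of summarising load in a finite sequencing sample.
#'
#' @param state A [population_state()] (with natural-scale `s`).
#' @param n_individuals If non-`NULL`, restrict to sites segregating in a
#'   random sample of this many diploid individuals.
#' @param method `"multiplicative"` (default) or `"additive"`.
#' @return Load in `[0, 1]` (multiplicative) or `sum(p|s|)` (additive).
#' @export
#' @examples
#' st <- population_state(data.frame(s = c(-0.1, -0.5), klass = "ns",
#'                                   count = c(10, 1)), twoN = 1000)
#' genetic_load(st)
genetic_load <- function(state, n_individuals = NULL,
                         method = c("multiplicative", "additive")) {
  stopifnot(inherits(state, "population_state"))
  method <- match.arg(method)
  sites <- state$sites
  if (!is.null(n_individuals)) {
    smp <- sample_chromosomes(state, min(2L * n_individuals, state$twoN))
    sites <- smp[smp$in_sample, ]
  }
  p <- sites$count / state$twoN
  if (method == "multiplicative") 1 - prod(1 + p * sites$s)
  else sum(p * abs(sites$s))
}

#' Watterson's expected number of segregating sites
#'
#' `E[S] = theta_locus * sum_{i=1}^{n-1} 1/i` for a sample of `n` chromosomes
#' from a neutral, constant-size, equilibrium population, where
#' `theta_locus = 4 N mu L`.
#'
#' @param theta_locus Population-scaled mutation rate of the locus.
#' @param n_chrom Sample size in chromosomes.
#' @return Expected segregating-site count.
#' @export
watterson_expected_S <- function(theta_locus, n_chrom) {
  theta_locus * sum(1 / seq_len(n_chrom - 1))
}
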