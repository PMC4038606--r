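# Shared reduced-scale simulations, computed lazily and cached for the whole
# test run. Scale: lambda = 40 rescaling of the canonical histories, which
# keeps every property qualitative check to a few seconds while preserving
# the population-scaled parameters.

.sim_cache <- new.env(parent = emptyenv())

shared_rates <- function() mutation_rates(mu_site = 1e-8, L_syn = 56000)
shared_dfe <- function() dfe_config(shape = 0.184, mean_s = 0.0257)

shared_sims <- function(name, n = 30, lam = 40, seed = 20260927) {
  key <- paste(name, n, lam, seed, sep = "_")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  model <- rescale_model(canonical_model(name), lam)
  reps <- simulate_replicates(model, shared_rates(), shared_dfe(), n, seed,
                              stream = match(name, c("constant", "BN",
                                                     "BN_growth", "Old_growth")))
  .sim_cache[[key]] <- reps
  reps
}

# Per-replicate present-day summaries (sample of min(1000, 2N) chromosomes)
# plus genetic load, for one canonical history.
shared_summaries <- function(name, n = 30, lam = 40) {
  key <- paste("summ", name, n, lam, sep = "_")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  reps <- shared_sims(name, n = n, lam = lam)
  out <- purrr::map_dfr(seq_along(reps), function(r) {
    sites <- reps[[r]]
    twoN <- attr(sites, "twoN")
    st <- population_state(sites[c("s", "klass", "count", "origin")], twoN)
    set.seed(attr(sites, "seed") + 13L)
    k <- min(1000L, twoN)
    ss <- summarize_sample(sample_chromosomes(st, k), k)
    ss$load <- genetic_load(st)
    ss$replicate <- r
    ss
  })
  .sim_cache[[key]] <- out
  out
}
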