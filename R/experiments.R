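#' Derive a replicate seed from a master seed
#'
#' Deterministic, collision-free within a run: the replicate index (offset by
#' a stream id) is mixed into the master seed with a large prime multiplier,
#' modulo 2^31 - 1.
#'
#' @param master Master integer seed.
#' @param replicate Replicate index (1-based).
#' @param stream Optional stream offset separating independent stages
#'   (e.g. different demographies).
#' @return An integer seed.
#' @export
replicate_seed <- function(master, replicate, stream = 0) {
  as.integer((as.double(master) + (replicate + stream * 100003) * 1299709) %%
               2147483647)
}

#' Experiment configuration
#'
#' Bundles every knob of the replication pipeline: demographic models, DFE,
#' mutation rates, the grid of trait-model cells, replicate counts and sample
#' sizes. Defaults follow the study design: tau in \{0, 0.5\}, target
#' heritability in \{0.05, 0.1, 0.3\}, mutational target 70 or 140 kb,
#' samples of 1000 chromosomes for diversity summaries and 1000 cases / 1000
#' controls for association.
#'
#' @param demographies Named list of (rescaled) [demographic_model()]s to
#'   simulate. A `"constant"` model is added automatically for calibration if
#'   absent, built from the first model's ancestral size and rescaling.
#' @param rates A [mutation_rates()] (natural scale).
#' @param dfe A [dfe_config()] (natural scale).
#' @param cells Tibble with columns `tau`, `h2`, `M` and logical `assoc`
#'   (run the cohort + association stage for that cell). Default: the full
#'   study grid with association on.
#' @param n_replicates Replicates per demography (the full-scale study uses
#'   1000; desk scale 100-200).
#' @param n_calibration Constant-size replicates used to calibrate `C`.
#' @param n_chrom Chromosomes sampled for diversity summaries.
#' @param n_source,prevalence,n_cases,n_controls Cohort design.
#' @param thresholds Significance thresholds tracked in the outputs.
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(demographies, rates = mutation_rates(),
                              dfe = dfe_config(),
                              cells = NULL,
                              n_replicates = 100, n_calibration = 100,
                              n_chrom = 1000, n_source = 6000,
                              prevalence = 0.4, n_cases = 1000,
                              n_controls = 1000,
                              thresholds = c(5e-8, 1e-5, 1e-2),
                              seed = 1) {
  stopifnot(is.list(demographies), length(demographies) >= 1,
            !is.null(names(demographies)))
  if (is.null(cells))
    cells <- tidyr::expand_grid(tau = c(0, 0.5), h2 = c(0.05, 0.1, 0.3),
                                M = c(70000, 140000), assoc = TRUE)
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("tau", "h2", "M") %in% names(cells)))
  if (!"assoc" %in% names(cells)) cells$assoc <- TRUE
  structure(list(demographies = demographies, rates = rates, dfe = dfe,
                 cells = cells, n_replicates = n_replicates,
                 n_calibration = n_calibration, n_chrom = n_chrom,
                 n_source = n_source, prevalence = prevalence,
                 n_cases = n_cases, n_controls = n_controls,
                 thresholds = thresholds, seed = seed),
            class = "experiment_config")
}

#' Simulate replicate populations and return their causal-ready site tables
#'
#' Runs `n` independent replicates of `model` and returns, per replicate, the
#' present-day site tibble with frequencies (`p = count / twoN`), mutation
#' ages and natural-scale selection coefficients.
#'
#' @param model A (rescaled) [demographic_model()].
#' @param rates,dfe Natural-scale [mutation_rates()] and [dfe_config()].
#' @param n Number of replicates.
#' @param seed Master seed (replicate seeds derived with [replicate_seed()]).
#' @param stream Stream offset (see [replicate_seed()]).
#' @return List of `n` tibbles (columns `s`, `klass`, `count`, `p`,
#'   `age_gen`), each with attributes `twoN` and `seed`.
#' @export
simulate_replicates <- function(model, rates, dfe, n, seed, stream = 0) {
  purrr::map(seq_len(n), function(r) {
    sim <- run_model(model, rates, dfe,
                     seed = replicate_seed(seed, r, stream))
    st <- present_state(sim)
    sites <- st$sites
    sites$p <- sites$count / st$twoN
    attr(sites, "twoN") <- st$twoN
    attr(sites, "seed") <- replicate_seed(seed, r, stream)
    sites
  })
}

#' Causal-site tables for calibration
#'
#' Thins each replicate's nonsynonymous sites to the mutational target
#' (probability `M / L_ns`) and returns the causal subsets, the input
#' [calibrate_C()] expects.
#'
#' @param replicates Output of [simulate_replicates()].
#' @param M Mutational target (bp).
#' @param L_ns Nonsynonymous target (bp).
#' @return List of causal-site tibbles (columns include `s`, `p`).
#' @export
simulate_causal_sites <- function(replicates, M, L_ns) {
  purrr::map(replicates, function(sites) {
    flagged <- select_causal(sites, M, L_ns)
    flagged[flagged$is_causal, ]
  })
}

# One replicate of the trait -> cohort -> association pipeline for one cell.
analyze_replicate_cell <- function(sites, cell, C, cfg_base, run_assoc,
                                   n_source, prevalence, n_cases, n_controls,
                                   thresholds) {
  cfg <- trait_config(tau = cell$tau, h2_target = cell$h2, M = cell$M,
                      eps_sd = cfg_base$eps_sd, delta = cfg_base$delta,
                      V_E = cfg_base$V_E)
  flagged <- select_causal(sites, cell$M, attr(sites, "L_ns"))
  arch <- assign_effects(flagged, cfg, C, twoN = attr(sites, "twoN"))
  vd <- variance_decomposition(arch)
  out <- list(
    n_causal = nrow(arch$sites), V_A = vd$V_A, h2 = vd$h2,
    by_frequency = vd$by_frequency, by_age = vd$by_age, by_topk = vd$by_topk)
  if (run_assoc && nrow(arch$sites) > 0) {
    cohort <- make_cohort(arch, n_source = n_source, prevalence = prevalence,
                          n_cases = n_cases, n_controls = n_controls)
    res <- assoc_test(cohort)
    out$n_sig <- setNames(
      vapply(thresholds, function(th) count_significant(res, th), numeric(1)),
      paste0("p", thresholds))
    out$va_by_p <- va_explained_by_pvalue(res)
    out$n_causal_in_cases <- {
      case_rows <- cohort$phenotypes$label == "case"
      sum(colSums(cohort$dosages[case_rows, , drop = FALSE]) > 0)
    }
  }
  out
}

#' Run a full replication experiment
#'
#' Orchestrates the whole pipeline for every demography and trait cell of the
#' configuration: (1) constant-size calibration replicates and [calibrate_C()]
#' per cell; (2) per-demography replicate simulations; (3) per replicate,
#' diversity summaries, genetic load, trait architecture, variance
#' decompositions and (optionally) the case-control association stage.
#' Everything is reproducible from `cfg$seed` alone.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print progress.
#' @return A named list of tidy tables:
#'   `sample_summaries` (per demography x replicate: `S_syn`, `S_ns`,
#'   `prop_ns`, `mean_abs_s`, `load`);
#'   `C_values` (per cell);
#'   `replicate_stats` (per demography x cell x replicate: `n_causal`, `V_A`,
#'   `h2`, significant counts, causal-in-cases count);
#'   `va_by_frequency`, `va_by_age`, `topk`, `va_by_pvalue`
#'   (per demography x cell x replicate partitions).
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (verbose) message(...)
  L_ns <- cfg$rates$L_ns

  demos <- cfg$demographies
  if (!"constant" %in% names(demos)) {
    ref <- demos[[1]]
    demos$constant <- local({
      m <- canonical_model("constant",
                           N_ancestral = ref$epochs$N[1] * ref$lambda)
      rescale_model(m, ref$lambda)
    })
  }

  say("calibration replicates under the constant-size model")
  cal_reps <- simulate_replicates(demos$constant, cfg$rates, cfg$dfe,
                                  cfg$n_calibration, cfg$seed, stream = 999)
  cfg_base <- trait_config()  # carries eps_sd, delta, V_E defaults
  cells <- cfg$cells
  cells$C <- NA_real_
  for (i in seq_len(nrow(cells))) {
    cellcfg <- trait_config(tau = cells$tau[i], h2_target = cells$h2[i],
                            M = cells$M[i])
    set.seed(replicate_seed(cfg$seed, i, stream = 888))
    causal <- simulate_causal_sites(cal_reps, cells$M[i], L_ns)
    cells$C[i] <- as.numeric(calibrate_C(causal, cellcfg))
  }

  sim_demos <- demos[names(demos) %in% names(cfg$demographies)]
  summaries <- list(); rep_stats <- list()
  vaf <- list(); vaa <- list(); topk <- list(); vap <- list()
  for (d in names(sim_demos)) {
    say("simulating ", cfg$n_replicates, " replicates of ", d)
    stream <- match(d, names(sim_demos))
    reps <- simulate_replicates(sim_demos[[d]], cfg$rates, cfg$dfe,
                                cfg$n_replicates, cfg$seed, stream = stream)
    for (r in seq_along(reps)) {
      sites <- reps[[r]]
      attr(sites, "L_ns") <- L_ns
      twoN <- attr(sites, "twoN")
      st <- new_population_state(sites[c("s", "klass", "count", "origin")],
                                 twoN)
      set.seed(replicate_seed(cfg$seed, r, stream = stream + 40))
      smp <- sample_chromosomes(st, min(cfg$n_chrom, twoN))
      ss <- summarize_sample(smp, min(cfg$n_chrom, twoN))
      ss$load <- genetic_load(st)
      summaries[[length(summaries) + 1]] <-
        dplyr::bind_cols(tibble::tibble(demography = d, replicate = r), ss)
      for (i in seq_len(nrow(cells))) {
        set.seed(replicate_seed(cfg$seed, r, stream = stream + 50 + 7 * i))
        res <- analyze_replicate_cell(
          sites, cells[i, ], cells$C[i], cfg_base, cells$assoc[i],
          cfg$n_source, cfg$prevalence, cfg$n_cases, cfg$n_controls,
          cfg$thresholds)
        key <- tibble::tibble(demography = d, replicate = r,
                              tau = cells$tau[i], h2_target = cells$h2[i],
                              M = cells$M[i])
        stat <- dplyr::bind_cols(key, tibble::tibble(
          n_causal = res$n_causal, V_A = res$V_A, h2 = res$h2))
        if (!is.null(res$n_sig)) {
          stat <- dplyr::bind_cols(stat, tibble::as_tibble(as.list(res$n_sig)))
          stat$n_causal_in_cases <- res$n_causal_in_cases
          vap[[length(vap) + 1]] <- dplyr::bind_cols(key, res$va_by_p)
        }
        rep_stats[[length(rep_stats) + 1]] <- stat
        vaf[[length(vaf) + 1]] <- dplyr::bind_cols(key, res$by_frequency)
        vaa[[length(vaa) + 1]] <- dplyr::bind_cols(key, res$by_age)
        topk[[length(topk) + 1]] <- dplyr::bind_cols(key, res$by_topk)
      }
    }
  }
  list(sample_summaries = dplyr::bind_rows(summaries),
       C_values = cells,
       replicate_stats = dplyr::bind_rows(rep_stats),
       va_by_frequency = dplyr::bind_rows(vaf),
       va_by_age = dplyr::bind_rows(vaa),
       topk = dplyr::bind_rows(topk),
       va_by_pvalue = dplyr::bind_rows(vap))
}

#' Deterministic fixtures for downstream-stage testing
#'
#' Small hand-specified populations and architectures that exercise the
#' trait, cohort and association stages without any simulation.
#'
#' * `"five_sites"`: five causal sites with fixed `p`, `s`, `alpha`
#'   (hand-checkable `V_A`).
#' * `"null_trait"`: five sites with `alpha = 0` (type-I-error calibration).
#' * `"single_common"`: one site, `p = 0.5`, `alpha = 1` (`V_A = 0.5`).
#'
#' @param name Fixture name.
#' @return A `trait_architecture` built from the fixed table.
#' @export
#' @examples
#' variance_decomposition(make_fixture("single_common"))$V_A  # 0.5
make_fixture <- function(name = c("five_sites", "null_trait", "single_common")) {
  name <- match.arg(name)
  tab <- switch(name,
    five_sites = tibble::tibble(
      p = c(0.5, 0.1, 0.01, 0.001, 0.25),
      s = c(-1e-5, -1e-4, -0.001, -0.01, -1e-5),
      alpha = c(0.1, 0.2, 0.5, 1.0, -0.1),
      age_gen = c(3000, 2500, 1000, 50, 90)),
    null_trait = tibble::tibble(
      p = c(0.5, 0.3, 0.2, 0.1, 0.05),
      s = rep(-1e-4, 5),
      alpha = rep(0, 5),
      age_gen = rep(1000, 5)),
    single_common = tibble::tibble(p = 0.5, s = -1e-5, alpha = 1,
                                   age_gen = 1000))
  structure(list(sites = tibble::tibble(site = seq_len(nrow(tab)),
                                        s = tab$s, p = tab$p,
                                        age_gen = tab$age_gen,
                                        alpha = tab$alpha),
                 C = 1, cfg = trait_config()),
            class = "trait_architecture")
}
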