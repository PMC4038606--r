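#' Construct a step-wise demographic model
#'
#' A demographic model is an ordered sequence of constant-size epochs (oldest
#' first), preceded by a burn-in period at the first epoch's size that lets the
#' population reach mutation-selection-drift equilibrium before the first size
#' change. Sampling happens at the end of the last epoch.
#'
#' @param epochs A data frame with columns `N` (diploid population size,
#'   integer >= 2) and `duration` (generations, integer >= 1), oldest epoch
#'   first. The last epoch ends at sampling time.
#' @param burn_in Number of generations spent at the first epoch's size before
#'   epoch 1 starts, beginning from a mutation-free population. Defaults to
#'   `10 * 2 * epochs$N[1]`.
#' @param label Free-text label for the model.
#'
#' @return An object of class `demographic_model`: a list with elements
#'   `epochs` (tibble), `burn_in`, `label`, `lambda` (rescaling factor applied
#'   so far), and the scaling directives `s_multiplier` and `mu_multiplier`
#'   that [run_model()] applies to selection coefficients and mutation rates.
#' @seealso [canonical_model()], [rescale_model()]
#' @export
#' @examples
#' demographic_model(data.frame(N = c(1000, 2000), duration = c(100, 50)))
demographic_model <- function(epochs, burn_in = NULL, label = "custom") {
  epochs <- tibble::as_tibble(epochs)
  stopifnot(all(c("N", "duration") %in% names(epochs)), nrow(epochs) >= 1)
  if (any(epochs$N < 2)) stop("every epoch size N must be >= 2")
  if (any(epochs$duration < 1)) stop("every epoch duration must be >= 1")
  epochs$N <- as.integer(round(epochs$N))
  epochs$duration <- as.integer(round(epochs$duration))
  if (is.null(burn_in)) burn_in <- 10L * 2L * epochs$N[1]
  structure(
    list(epochs = epochs, burn_in = as.integer(burn_in), label = label,
         lambda = 1, s_multiplier = 1, mu_multiplier = 1),
    class = "demographic_model")
}

#' Canonical population-history models
#'
#' Builds one of three canonical human-like histories:
#' * `"BN"`: ancestral size, a brief severe bottleneck starting 2000
#'   generations before sampling, recovery to the ancestral size 1960
#'   generations before sampling.
#' * `"BN_growth"`: the same bottleneck plus an instantaneous 100-fold
#'   expansion 80 generations before sampling.
#' * `"Old_growth"`: a 2-fold instantaneous expansion 4000 generations before
#'   sampling (an African-like history).
#' * `"constant"`: constant ancestral size (the calibration model for trait
#'   effect sizes).
#'
#' The bottleneck severity is not pinned down by the sources this model family
#' emulates; `N_bottleneck = N_ancestral / 10` is the documented default
#' assumption and can be overridden.
#'
#' @param name One of `"BN"`, `"BN_growth"`, `"Old_growth"`, `"constant"`.
#' @param N_ancestral Ancestral diploid population size.
#' @param N_bottleneck Diploid size during the bottleneck.
#' @param growth_fold Fold-change of the recent instantaneous expansion
#'   (`BN_growth` only).
#' @param t_bottleneck_start,t_bottleneck_end Generations before sampling at
#'   which the bottleneck starts and ends.
#' @param t_growth Generations before sampling of the recent expansion.
#' @param t_old_growth Generations before sampling of the ancient 2-fold
#'   expansion (`Old_growth` only).
#' @param old_growth_fold Fold-change of the ancient expansion.
#' @param burn_in Burn-in generations (default `10 * 2 * N_ancestral`).
#' @param constant_duration Post-burn-in duration of the `"constant"` model,
#'   so that its timeline is comparable to the bottleneck models.
#'
#' @return A [demographic_model()].
#' @export
#' @examples
#' canonical_model("BN_growth", N_ancestral = 1000)
canonical_model <- function(name = c("BN", "BN_growth", "Old_growth", "constant"),
                            N_ancestral = 10000, N_bottleneck = N_ancestral / 10,
                            growth_fold = 100,
                            t_bottleneck_start = 2000, t_bottleneck_end = 1960,
                            t_growth = 80, t_old_growth = 4000,
                            old_growth_fold = 2,
                            burn_in = 10 * 2 * N_ancestral,
                            constant_duration = t_bottleneck_start) {
  name <- match.arg(name)
  if (N_ancestral <= 0 || N_bottleneck <= 0 || growth_fold <= 0)
    stop("population sizes and fold-changes must be positive")
  if (t_bottleneck_start <= t_bottleneck_end || t_bottleneck_end <= t_growth)
    stop("expected t_bottleneck_start > t_bottleneck_end > t_growth")
  epochs <- switch(
    name,
    constant = tibble::tibble(N = N_ancestral, duration = constant_duration),
    BN = tibble::tibble(
      N = c(N_ancestral, N_bottleneck, N_ancestral),
      duration = c(1, t_bottleneck_start - t_bottleneck_end, t_bottleneck_end)),
    BN_growth = tibble::tibble(
      N = c(N_ancestral, N_bottleneck, N_ancestral, N_ancestral * growth_fold),
      duration = c(1, t_bottleneck_start - t_bottleneck_end,
                   t_bottleneck_end - t_growth, t_growth)),
    Old_growth = tibble::tibble(
      N = c(N_ancestral, N_ancestral * old_growth_fold),
      duration = c(1, t_old_growth)))
  # The leading 1-generation ancestral epoch anchors the pre-change size; the
  # burn-in (at that size) supplies the equilibrium ancestral population.
  demographic_model(epochs, burn_in = burn_in - 1L, label = name)
}

#' Rescale a demographic model for faster simulation
#'
#' Divides every population size and every duration (burn-in included) by
#' `lambda`, and records directives to multiply selection coefficients and
#' mutation rates by `lambda`, so that the population-scaled parameters
#' `4*N*mu` and `4*N*s` -- and hence, in the diffusion limit, the patterns of
#' variation -- are preserved. Durations are rounded to the nearest integer,
#' minimum 1.
#'
#' @param model A [demographic_model()].
#' @param lambda Rescaling factor, >= 1.
#' @return The rescaled `demographic_model`, with `lambda`, `s_multiplier` and
#'   `mu_multiplier` updated. [run_model()] applies the multipliers and
#'   returns results on the natural (unrescaled) scale.
#' @export
#' @examples
#' m <- canonical_model("BN", N_ancestral = 10000)
#' rescale_model(m, 10)
rescale_model <- function(model, lambda) {
  stopifnot(inherits(model, "demographic_model"))
  if (lambda < 1) stop("lambda must be >= 1")
  if (lambda == 1) return(model)
  new_N <- as.integer(round(model$epochs$N / lambda))
  if (any(new_N < 2)) stop("rescaling by this lambda gives an epoch size < 2")
  model$epochs$N <- new_N
  model$epochs$duration <-
    pmax(1L, as.integer(round(model$epochs$duration / lambda)))
  model$burn_in <- max(1L, as.integer(round(model$burn_in / lambda)))
  model$lambda <- model$lambda * lambda
  model$s_multiplier <- model$s_multiplier * lambda
  model$mu_multiplier <- model$mu_multiplier * lambda
  model
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> ", x$label,
      "  (lambda = ", x$lambda, ")\n", sep = "")
  cat("burn-in:", x$burn_in, "generations at N =", x$epochs$N[1], "\n")
  print(x$epochs)
  invisible(x)
}

#' Total post-burn-in timeline length of a model, in generations
#' @param model A [demographic_model()].
#' @return Integer number of generations from the start of epoch 1 to sampling.
#' @export
model_timeline <- function(model) sum(model$epochs$duration)

# Haploid size (2N) for every transition 0..T of the simulated timeline.
model_size_series <- function(model) {
  sizes <- c(rep(model$epochs$N[1], model$burn_in),
             rep(model$epochs$N, model$epochs$duration))
  as.integer(c(sizes[1], sizes) * 2L)[seq_len(model$burn_in + model_timeline(model) + 1L)]
}

#' Read a demographic model from a YAML or JSON configuration file
#'
#' The schema is `epochs: [{N, duration}, ...]`, `burn_in`, `rescale_lambda`,
#' `label`; `rescale_lambda` (optional) is applied with [rescale_model()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [demographic_model()].
#' @export
read_demography_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  epochs <- dplyr::bind_rows(lapply(cfg$epochs, tibble::as_tibble))
  # YAML 1.1 reads a bare `N:` key as the boolean FALSE; undo that
  names(epochs)[names(epochs) %in% c("FALSE", "FALSE.")] <- "N"
  m <- demographic_model(epochs, burn_in = cfg$burn_in,
                         label = cfg$label %||% "config")
  if (!is.null(cfg$rescale_lambda)) m <- rescale_model(m, cfg$rescale_lambda)
  m
}
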