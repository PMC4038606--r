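#' Distribution of fitness effects for new nonsynonymous mutations
#'
#' Selection coefficients of new nonsynonymous mutations are drawn as
#' `-Gamma(shape, scale = mean_s / shape)`, i.e. all are deleterious with mean
#' absolute effect `mean_s`. Synonymous mutations are neutral (`s = 0`).
#' Defaults follow the gamma fit of Boyko et al. (2008) to human nonsynonymous
#' site-frequency data (shape 0.184, mean |s| 0.0257); both are configuration
#' entries, not constants of the method.
#'
#' @param shape Gamma shape parameter (> 0).
#' @param mean_s Mean absolute selection coefficient of new nonsynonymous
#'   mutations (> 0). Use [dfe_neutral()] for a fully neutral model.
#' @return An object of class `dfe_config`.
#' @export
dfe_config <- function(shape = 0.184, mean_s = 0.0257) {
  stopifnot(shape > 0, mean_s > 0)
  structure(list(shape = shape, mean_s = mean_s, neutral = FALSE),
            class = "dfe_config")
}

#' Neutral "DFE": every mutation has s = 0
#'
#' Used for calibration checks against neutral theory (e.g. Watterson's
#' estimator of the number of segregating sites).
#' @return A `dfe_config` with all selection coefficients fixed at 0.
#' @export
dfe_neutral <- function() {
  structure(list(shape = 1, mean_s = 0, neutral = TRUE), class = "dfe_config")
}

#' Mutation rates and target sizes
#'
#' The simulated locus has a synonymous target of `L_syn` base pairs and a
#' nonsynonymous target of `L_ns = 2.5 * L_syn` base pairs, reflecting the
#' larger number of coding sites whose mutation is nonsynonymous; the 2.5:1
#' ratio of mutational input is enforced exactly. The per-site, per-generation
#' mutation rate `mu_site` defaults to 1e-8.
#'
#' @param mu_site Per-site per-generation mutation rate.
#' @param L_syn Synonymous target length in base pairs.
#' @param ns_ratio Ratio of nonsynonymous to synonymous target length.
#' @return An object of class `mutation_rates` with fields `mu_site`, `L_syn`,
#'   `L_ns`.
#' @export
mutation_rates <- function(mu_site = 1e-8, L_syn = 56000, ns_ratio = 2.5) {
  stopifnot(mu_site >= 0, L_syn >= 0)
  structure(list(mu_site = mu_site, L_syn = L_syn, L_ns = ns_ratio * L_syn),
            class = "mutation_rates")
}
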