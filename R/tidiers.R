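#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a population state into its site table
#' @param x A [population_state()].
#' @param ... Unused.
#' @return Tibble of segregating sites with the derived-allele frequency `p`.
#' @export
tidy.population_state <- function(x, ...) {
  out <- x$sites
  out$p <- out$count / x$twoN
  out
}

#' One-row summary of a population state
#' @param x A [population_state()].
#' @param ... Unused.
#' @return Tibble: `twoN`, `S_syn`, `S_ns`, `prop_ns`, `mean_abs_s`, `load`.
#' @export
glance.population_state <- function(x, ...) {
  S_syn <- sum(x$sites$klass == "syn")
  S_ns <- sum(x$sites$klass == "ns")
  tibble::tibble(
    twoN = x$twoN, S_syn = S_syn, S_ns = S_ns,
    prop_ns = if (S_syn + S_ns > 0) S_ns / (S_syn + S_ns) else NA_real_,
    mean_abs_s = if (S_ns > 0) mean(abs(x$sites$s[x$sites$klass == "ns"]))
                 else NA_real_,
    load = genetic_load(x))
}

#' Tidy a trait architecture into its causal-site table
#' @param x A [trait_architecture()] (see [assign_effects()]).
#' @param ... Unused.
#' @return Tibble with `site`, `s`, `p`, `age_gen`, `alpha` and the per-site
#'   variance contribution `v = 2 p (1-p) alpha^2`.
#' @export
tidy.trait_architecture <- function(x, ...) {
  out <- x$sites
  out$v <- 2 * out$p * (1 - out$p) * out$alpha^2
  out
}

#' One-row summary of a trait architecture
#' @param x A [trait_architecture()].
#' @param ... Unused.
#' @return Tibble: `n_causal`, `C`, `tau`, `V_A`, `V_P`, `h2`.
#' @export
glance.trait_architecture <- function(x, ...) {
  vd <- variance_decomposition(x)
  tibble::tibble(n_causal = nrow(x$sites), C = x$C, tau = x$cfg$tau,
                 V_A = vd$V_A, V_P = vd$V_P, h2 = vd$h2)
}

#' Tidy an association result
#' @param x An [assoc_test()] result.
#' @param ... Unused.
#' @return The underlying tibble with significance flags at the three
#'   conventional thresholds.
#' @export
tidy.assoc_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$sig_1e5 <- out$p_value < 1e-5 & out$testable
  out$sig_1e2 <- out$p_value < 1e-2 & out$testable
  out$sig_5e8 <- out$p_value < 5e-8 & out$testable
  out
}

#' One-row summary of an association result
#' @param x An [assoc_test()] result.
#' @param ... Unused.
#' @return Tibble with testable-site count and significant counts at the
#'   three conventional thresholds.
#' @export
glance.assoc_result <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x), n_testable = sum(x$testable),
    n_sig_1e5 = count_significant(x, 1e-5),
    n_sig_1e2 = count_significant(x, 1e-2),
    n_sig_5e8 = count_significant(x, 5e-8))
}
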