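#' Draw genotype dosages under Hardy-Weinberg and linkage equilibrium
#'
#' Sites are independent (no linkage), so each individual's dosage at site `i`
#' is `Binomial(2, p_i)`, independently across sites and individuals.
#'
#' @param frequencies Population derived-allele frequencies, in `[0, 1]`.
#' @param n_individuals Number of diploid individuals (>= 1).
#' @return Integer matrix, individuals x sites, entries in `{0, 1, 2}`.
#' @export
#' @examples
#' g <- draw_genotypes(c(0.5, 0.01), 100)
#' colMeans(g)
draw_genotypes <- function(frequencies, n_individuals) {
  stopifnot(n_individuals >= 1, all(frequencies >= 0), all(frequencies <= 1))
  m <- length(frequencies)
  matrix(rbinom(n_individuals * m, 2L, rep(frequencies, each = n_individuals)),
         nrow = n_individuals, ncol = m)
}

#' Liability-threshold case-control ascertainment
#'
#' Phenotypes are rank-transformed to the standard normal scale (Blom offsets,
#' `qnorm((rank - 3/8) / (n + 1/4))`, ties broken at random), giving the
#' liability. The threshold `L` is the `1 - prevalence` standard-normal
#' quantile, so that a fraction `prevalence` of individuals have liability
#' above `L` (the cases' stratum). `n_cases` cases are sampled uniformly
#' without replacement from above `L` and `n_controls` controls from at or
#' below `L`.
#'
#' @param Y Numeric phenotype vector for the source cohort.
#' @param prevalence Disease prevalence (fraction of liabilities above `L`).
#' @param n_cases,n_controls Numbers of cases and controls to sample.
#' @return A tibble with one row per source individual: `id`, `Y`,
#'   `liability`, `stratum` (`"case_pool"`/`"control_pool"`) and `label`
#'   (`"case"`, `"control"`, or `NA` for unsampled individuals), with the
#'   threshold `L` as an attribute.
#' @export
#' @examples
#' asc <- ascertain(rnorm(5000), prevalence = 0.4, n_cases = 100,
#'                  n_controls = 100)
#' attr(asc, "L")
ascertain <- function(Y, prevalence = 0.4, n_cases = 1000, n_controls = 1000) {
  stopifnot(prevalence > 0, prevalence <= 1)
  n <- length(Y)
  r <- rank(Y, ties.method = "random")
  liab <- qnorm((r - 3 / 8) / (n + 1 / 4))
  L <- if (prevalence >= 1) -Inf else qnorm(1 - prevalence)
  upper <- which(liab > L)
  lower <- which(liab <= L)
  if (length(upper) < n_cases)
    stop("only ", length(upper), " individuals above the liability threshold; ",
         "use a larger source cohort")
  if (length(lower) < n_controls)
    stop("only ", length(lower), " individuals below the liability threshold; ",
         "use a larger source cohort")
  label <- rep(NA_character_, n)
  label[sample(upper, n_cases)] <- "case"
  label[sample(lower, n_controls)] <- "control"
  out <- tibble::tibble(
    id = seq_len(n), Y = Y, liability = liab,
    stratum = ifelse(liab > L, "case_pool", "control_pool"),
    label = label)
  attr(out, "L") <- L
  out
}

# Two-stage equivalent of draw_genotypes() that exploits rarity: per site the
# cohort-wide copy number is Binomial(2n, p), and the copies are then placed
# uniformly without replacement among the 2n chromosomes (exchangeability
# makes the per-individual dosages iid Binomial(2, p)). Sites with zero copies
# are monomorphic-absent and carried by index only, so the dense matrix holds
# just the polymorphic columns.
draw_cohort_alleles <- function(frequencies, n_individuals) {
  m <- length(frequencies)
  K <- rbinom(m, 2L * n_individuals, frequencies)
  keep <- which(K > 0L)
  Z <- matrix(0L, n_individuals, length(keep))
  for (j in seq_along(keep)) {
    slots <- sample.int(2L * n_individuals, K[keep[j]])
    Z[, j] <- tabulate((slots + 1L) %/% 2L, nbins = n_individuals)
  }
  list(dosages = Z, site_index = keep, n_sites = m)
}

#' Simulate a case-control cohort from a trait architecture
#'
#' Draws a source cohort of `n_source` individuals with Hardy-Weinberg
#' genotypes at the causal sites, additive phenotypes with environmental
#' noise, and liability-threshold ascertainment of `n_cases` cases and
#' `n_controls` controls.
#'
#' @param arch A [trait_architecture()].
#' @param n_source Source-cohort size before ascertainment (default 6000,
#'   comfortably enough for 1000 cases from the top 40% and 1000 controls
#'   from the bottom 60%).
#' @param prevalence Disease prevalence (default 0.40).
#' @param n_cases,n_controls Sample sizes (default 1000 each).
#' @return An object of class `cohort_data`: list with `dosages` (sampled
#'   individuals x polymorphic causal sites), `site_index` (mapping of dosage
#'   columns to rows of `arch$sites`; causal sites absent from the source
#'   cohort carry no column), `phenotypes` (tibble: `id`, `Y`, `liability`,
#'   `label` for the sampled individuals), `L`, `arch`, and the design
#'   parameters.
#' @export
make_cohort <- function(arch, n_source = 6000, prevalence = 0.4,
                        n_cases = 1000, n_controls = 1000) {
  stopifnot(inherits(arch, "trait_architecture"))
  drawn <- draw_cohort_alleles(arch$sites$p, n_source)
  Y <- drop(drawn$dosages %*% arch$sites$alpha[drawn$site_index]) +
    rnorm(n_source, 0, sqrt(arch$cfg$V_E))
  asc <- ascertain(Y, prevalence, n_cases, n_controls)
  keep <- !is.na(asc$label)
  structure(
    list(dosages = drawn$dosages[keep, , drop = FALSE],
         site_index = drawn$site_index,
         phenotypes = asc[keep, ],
         L = attr(asc, "L"), arch = arch,
         n_cases = n_cases, n_controls = n_controls, prevalence = prevalence),
    class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("<cohort_data>", x$n_cases, "cases /", x$n_controls, "controls;",
      ncol(x$dosages), "of", nrow(x$arch$sites),
      "causal sites polymorphic in the source cohort (prevalence",
      x$prevalence, ")\n")
  invisible(x)
}

#' Export a cohort as plain-text tables
#'
#' Writes `genotypes.tsv` (site by individual dosages, long format) and
#' `phenotypes.tsv` (`id`, `Y`, `liability`, `label`) under `dir`.
#'
#' @param cohort A [make_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_cohort_tsv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno <- tibble::as_tibble(cohort$dosages, .name_repair = ~ paste0("site_", seq_along(.x)))
  geno <- dplyr::bind_cols(tibble::tibble(id = cohort$phenotypes$id), geno)
  geno_long <- tidyr::pivot_longer(geno, -"id", names_to = "site",
                                   values_to = "dosage")
  p_geno <- file.path(dir, "genotypes.tsv")
  p_phen <- file.path(dir, "phenotypes.tsv")
  utils::write.table(geno_long, p_geno, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$phenotypes, p_phen, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p_geno, p_phen))
}
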