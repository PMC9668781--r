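#' Broad-sense heritability
#'
#' Fraction of the plot-level phenotypic variance attributable to
#' genotypes:
#' \deqn{h^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge} + \sigma^2_e}}
#'
#' @param sigma2_g genotypic variance, >= 0.
#' @param sigma2_ge genotype-by-trial interaction variance, >= 0.
#' @param sigma2_e residual variance, >= 0. The three must not all be
#'   zero.
#' @return heritability in \[0, 1\].
#' @examples
#' broad_sense_h2(5.44, 0, 2.16) # 0.72, the carotenoid-content example
#' @export
broad_sense_h2 <- function(sigma2_g, sigma2_ge, sigma2_e) {
  if (any(c(sigma2_g, sigma2_ge, sigma2_e) < 0)) {
    stop("variance components must be >= 0")
  }
  tot <- sigma2_g + sigma2_ge + sigma2_e
  if (any(tot == 0)) stop("all components zero: heritability undefined")
  sigma2_g / tot
}

#' Clonal-mean heritability
#'
#' Heritability on the scale of genotype means across `e` trials with
#' effective replication `r`:
#' \deqn{h^2_m = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/e +
#'   \sigma^2_e/(re)}}
#'
#' @inheritParams broad_sense_h2
#' @param e number of trials, >= 1.
#' @param r effective replication per trial, > 0.
#' @return heritability in \[0, 1\].
#' @export
clonal_mean_h2 <- function(sigma2_g, sigma2_ge, sigma2_e, e, r) {
  if (any(c(sigma2_g, sigma2_ge, sigma2_e) < 0)) {
    stop("variance components must be >= 0")
  }
  if (any(e < 1) || any(r <= 0)) stop("need e >= 1 and r > 0")
  den <- sigma2_g + sigma2_ge / e + sigma2_e / (r * e)
  if (any(den == 0)) stop("all components zero: heritability undefined")
  sigma2_g / den
}

#' Heritability estimates from a fitted model
#'
#' Extracts the genotype, genotype-by-trial and residual components of a
#' [fit_trait_blup()] fit and returns both heritabilities. Dropped
#' components count as zero.
#'
#' @param object a `cassava_fit`.
#' @param e,r override the number of trials and effective replication
#'   recorded in the fit.
#' @return data frame with columns `trait`, `h2`, `h2m`, `e`, `r`,
#'   `sigma2_g`, `sigma2_ge`, `sigma2_e`.
#' @export
heritability <- function(object, e = NULL, r = NULL) {
  stopifnot(inherits(object, "cassava_fit"))
  vc <- object$varcomp
  z <- function(v) if (is.na(v)) 0 else v
  sg <- z(vc["genotype"]); sge <- z(vc["ge"]); se <- z(vc["residual"])
  if (is.null(e)) e <- object$e
  if (is.null(r)) r <- object$r
  data.frame(trait = object$trait,
             h2 = broad_sense_h2(sg, sge, se),
             h2m = clonal_mean_h2(sg, sge, se, e, r),
             e = e, r = r,
             sigma2_g = unname(sg), sigma2_ge = unname(sge),
             sigma2_e = unname(se),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Predicted genetic gain from selection
#'
#' Gain predicted from the selection differential on the BLUP scale,
#' \eqn{G = h^2_m S}, where S is the deviation of the selected genotypes'
#' mean from the population mean of the BLUP + intercept values. The
#' percent gain is reported relative to the population mean.
#'
#' @param blups named numeric vector of BLUP + intercept values (one per
#'   genotype).
#' @param selected character vector of selected genotype ids (non-empty
#'   subset of `names(blups)`).
#' @param h2m clonal-mean heritability in \[0, 1\] used to shrink the
#'   differential.
#' @param population_mean overrides the population mean (defaults to
#'   `mean(blups)`).
#' @return list with `selected_mean`, `population_mean`, `S`, `G`,
#'   `G_pct`.
#' @export
genetic_gain <- function(blups, selected, h2m,
                         population_mean = mean(blups, na.rm = TRUE)) {
  if (length(selected) == 0) stop("empty selection")
  if (!all(selected %in% names(blups))) {
    stop("selected genotypes absent from blups: ",
         paste(setdiff(selected, names(blups)), collapse = ", "))
  }
  if (h2m < 0 || h2m > 1) stop("h2m must lie in [0, 1]")
  sel_mean <- mean(blups[selected], na.rm = TRUE)
  S <- sel_mean - population_mean
  G <- h2m * S
  G_pct <- if (population_mean == 0) NA_real_ else 100 * G / population_mean
  list(selected_mean = sel_mean, population_mean = population_mean,
       S = S, G = G, G_pct = G_pct)
}
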