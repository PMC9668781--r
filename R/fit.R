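#' @importFrom stats coef logLik predict residuals setNames var
NULL

# Normalise input to a plot-level data frame carrying is_check.
plot_frame <- function(data) {
  if (inherits(data, "cassava_dataset")) {
    pl <- data$plots
    pl$is_check <- data$germplasm$is_check[match(pl$genotype_id,
                                                 data$germplasm$genotype_id)]
    return(pl)
  }
  stopifnot(is.data.frame(data))
  if (!"is_check" %in% names(data)) {
    stop("a plain plot table must carry an 'is_check' column")
  }
  data
}

#' Build the augmented-design model frame for one trait
#'
#' Prepares the response and the fixed/random design factors of the
#' per-trait mixed model
#' \deqn{Y_{ijk} = \mu + E_i + B_{(i)j} + G_k + GE_{ik} + \epsilon_{ijk}}
#' in which the genotype effect splits into a fixed check part and a
#' random test-clone part. Trials in which the trait was not measured are
#' excluded. Random terms that cannot be estimated are dropped with a
#' warning: the trial term needs at least two trials, the block term more
#' blocks than trials, the genotype term at least two test clones, and
#' the genotype-by-trial term at least one genotype observed in two or
#' more trials.
#'
#' @param data a `cassava_dataset` or a plot-level data frame with columns
#'   `trial_id`, `block_id`, `genotype_id`, `is_check` and the trait.
#' @param trait trait column name.
#' @return list with the model frame (`frame`), the included random
#'   `terms`, the fixed-effect formula part, the number of trials used
#'   (`e`) and the effective replication (`r`).
#' @export
build_design <- function(data, trait) {
  pl <- plot_frame(data)
  if (!trait %in% names(pl)) {
    stop("trait '", trait, "' absent from the plot table")
  }
  pl <- pl[!is.na(pl[[trait]]), , drop = FALSE]
  if (nrow(pl) == 0) stop("trait '", trait, "' has no non-missing records")
  fr <- data.frame(
    y = pl[[trait]],
    trial = factor(pl$trial_id),
    geno = factor(pl$genotype_id),
    tind = as.numeric(!pl$is_check),
    stringsAsFactors = FALSE
  )
  fr$block <- factor(paste(pl$trial_id, pl$block_id, sep = ":"))
  fr$checkf <- factor(ifelse(pl$is_check, pl$genotype_id, "test"))
  fr$checkf <- stats::relevel(fr$checkf, ref = "test")
  fr$ge <- factor(paste(pl$genotype_id, pl$trial_id, sep = ":"))

  terms <- character(0)
  dropped <- character(0)
  e <- nlevels(fr$trial)
  if (e >= 2) terms <- c(terms, "trial") else dropped <- c(dropped, "trial")
  if (nlevels(fr$block) >= 2 &&
      nlevels(fr$block) > ifelse(e >= 2, e, 1)) {
    terms <- c(terms, "block")
  } else {
    dropped <- c(dropped, "block")
  }
  n_test <- length(unique(pl$genotype_id[!pl$is_check]))
  if (n_test >= 2) {
    terms <- c(terms, "genotype")
  } else {
    dropped <- c(dropped, "genotype")
  }
  multi_trial_geno <- any(rowSums(table(fr$geno, fr$trial) > 0) >= 2)
  if ("trial" %in% terms && "genotype" %in% terms && multi_trial_geno) {
    terms <- c(terms, "ge")
  } else {
    dropped <- c(dropped, "ge")
  }
  if (length(dropped)) {
    warning("dropping unestimable term(s) for ", trait, ": ",
            paste(dropped, collapse = ", "))
  }
  if (!length(terms)) stop("no estimable random term for trait ", trait)
  fixed <- if (nlevels(fr$checkf) >= 2) "checkf" else "1"
  # effective replication: harmonic mean of test-clone plot counts over
  # the included trials, divided by the number of trials
  cnt <- table(fr$geno[fr$tind == 1])
  cnt <- cnt[cnt > 0]
  r <- if (length(cnt)) (length(cnt) / sum(1 / as.numeric(cnt))) / e else NA
  list(frame = fr, terms = terms, fixed = fixed, e = e, r = r,
       trait = trait, dropped = dropped)
}

reml_formula <- function(design, terms = design$terms) {
  rand <- c(trial = "(1 | trial)", block = "(1 | block)",
            genotype = "(0 + tind | geno)", ge = "(1 | ge)")[terms]
  stats::as.formula(paste("y ~", design$fixed, "+",
                          paste(rand, collapse = " + ")))
}

fit_lmer <- function(design, terms = design$terms) {
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE,
                            optCtrl = list(xtol_abs = 1e-10,
                                           ftol_abs = 1e-12))
  lme4::lmer(reml_formula(design, terms), data = design$frame,
             REML = TRUE, control = ctrl)
}

#' Fit the augmented-design mixed model for one trait
#'
#' Fits, by REML, the per-trait linear mixed model of a multi-environment
#' augmented block design: fixed intercept and check effects (treatment
#' contrasts against the test-clone baseline, so the intercept estimates
#' the overall constant \eqn{\mu}), random trial, block-within-trial,
#' test-clone and genotype-by-trial effects, Gaussian residuals. Variance
#' components are constrained non-negative by the profiled-REML
#' parameterisation. BLUPs of the test-clone effects are returned both on
#' the deviation scale and added to the intercept, the scale on which
#' genotype means are reported and selected.
#'
#' @param data a `cassava_dataset` or plot-level data frame (see
#'   [build_design()]).
#' @param trait trait column name.
#' @param intercept how to centre reported BLUPs: `"mu"` (default) adds
#'   the fitted intercept alone; `"mu_plus_mean_check"` also adds the mean
#'   fixed check effect.
#' @return object of class `cassava_fit` with components `varcomp`
#'   (named: trial, block, genotype, ge, residual; `NA` for dropped
#'   terms), `mu`, `check_effects`, `blups` (data frame: genotype, blup,
#'   blup_plus_intercept), `loglik`, `converged`, `e` (trials used), `r`
#'   (effective replication), and the underlying `lme4` fit in `$model`.
#' @examples
#' sim <- simulate_trials(generator_config(n_genotypes = 40, n_checks = 3,
#'   n_trials = 2, blocks_per_trial = 2, traits = "TCC",
#'   missingness = list()), seed = 42)
#' fit <- fit_trait_blup(sim$data, "TCC")
#' fit
#' @export
fit_trait_blup <- function(data, trait,
                           intercept = c("mu", "mu_plus_mean_check")) {
  intercept <- match.arg(intercept)
  design <- build_design(data, trait)
  mod <- fit_lmer(design)
  out <- collect_fit(mod, design, intercept)
  out
}

collect_fit <- function(mod, design, intercept = "mu") {
  vc <- as.data.frame(lme4::VarCorr(mod))
  get_vc <- function(grp) {
    i <- match(grp, vc$grp)
    if (is.na(i)) NA_real_ else vc$vcov[i]
  }
  varcomp <- c(trial = get_vc("trial"), block = get_vc("block"),
               genotype = get_vc("geno"), ge = get_vc("ge"),
               residual = get_vc("Residual"))
  fe <- lme4::fixef(mod)
  mu <- unname(fe["(Intercept)"])
  check_effects <- fe[setdiff(names(fe), "(Intercept)")]
  names(check_effects) <- sub("^checkf", "", names(check_effects))
  shift <- mu
  if (intercept == "mu_plus_mean_check" && length(check_effects)) {
    shift <- mu + mean(check_effects)
  }
  blups <- data.frame(genotype = character(0), blup = numeric(0))
  if ("genotype" %in% design$terms) {
    re <- lme4::ranef(mod)$geno
    b <- setNames(re[["tind"]], rownames(re))
    test_ids <- unique(as.character(
      design$frame$geno[design$frame$tind == 1]))
    b <- b[test_ids]
    blups <- data.frame(genotype = names(b), blup = unname(b),
                        blup_plus_intercept = shift + unname(b),
                        stringsAsFactors = FALSE)
    blups <- blups[order(blups$genotype), , drop = FALSE]
    rownames(blups) <- NULL
  }
  msgs <- mod@optinfo$conv$lme4$messages
  # a variance component estimated at its boundary is a valid optimum
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  structure(list(
    trait = design$trait, design = design, model = mod,
    varcomp = varcomp, mu = mu, check_effects = check_effects,
    blups = blups, loglik = as.numeric(logLik(mod)),
    converged = is.null(msgs) || length(msgs) == 0,
    e = design$e, r = design$r, n_obs = nrow(design$frame),
    intercept_rule = intercept
  ), class = "cassava_fit")
}

#' @export
print.cassava_fit <- function(x, digits = 4, ...) {
  cat("Augmented-design REML fit - trait:", x$trait, "\n")
  cat(sprintf("  %d plots, %d trials, %d test clones; REML logLik %.2f%s\n",
              x$n_obs, x$e, nrow(x$blups), x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  cat("  variance components:\n")
  print(round(x$varcomp, digits))
  h <- heritability(x)
  cat(sprintf("  h2 = %.3f, h2m = %.3f (e = %d, r = %.2f)\n",
              h$h2, h$h2m, h$e, h$r))
  invisible(x)
}

#' @export
summary.cassava_fit <- function(object, ...) {
  print(object)
  if (length(object$check_effects)) {
    cat("  fixed check effects (vs. test baseline):\n")
    print(round(object$check_effects, 4))
  }
  invisible(object)
}

#' @export
coef.cassava_fit <- function(object, ...) {
  c("(Intercept)" = object$mu, object$check_effects)
}

#' @export
logLik.cassava_fit <- function(object, ...) logLik(object$model)

#' @export
residuals.cassava_fit <- function(object, ...) residuals(object$model)

#' Predicted genotype means (BLUP plus intercept)
#'
#' @param object a `cassava_fit`.
#' @param genotypes optional character vector restricting the output.
#' @param ... unused.
#' @return named numeric vector of BLUP + intercept values for the test
#'   clones.
#' @export
predict.cassava_fit <- function(object, genotypes = NULL, ...) {
  v <- setNames(object$blups$blup_plus_intercept, object$blups$genotype)
  if (!is.null(genotypes)) v <- v[genotypes]
  v
}

#' Fit several traits and collect the fits
#'
#' @param data a `cassava_dataset` or plot-level data frame.
#' @param traits trait names; defaults to every canonical trait present.
#' @param ... passed to [fit_trait_blup()].
#' @return named list of `cassava_fit` objects.
#' @export
fit_all_traits <- function(data, traits = NULL, ...) {
  pl <- plot_frame(data)
  if (is.null(traits)) traits <- intersect(trait_names(), names(pl))
  if (!length(traits)) stop("no trait columns found")
  setNames(lapply(traits, function(tr) fit_trait_blup(data, tr, ...)),
           traits)
}

#' Likelihood-ratio deviance test for one random term
#'
#' Refits the model without the stated random term and forms the deviance
#' statistic `2 * (logLik_full - logLik_reduced)`, referred to the
#' chi-squared distribution with one degree of freedom; significance is
#' declared at the 1 % level. Testing a variance component on the
#' boundary of its parameter space this way is conservative (the
#' rejection rate under the null falls below the nominal level); no
#' mixture correction is applied.
#'
#' @param object a `cassava_fit`.
#' @param term one of `"genotype"`, `"ge"`, `"trial"`, `"block"`.
#' @return list with `term`, `chi_square`, `df`, `p_value`,
#'   `significant_at_1pct`.
#' @export
lrt_term <- function(object, term = c("genotype", "ge", "trial", "block")) {
  stopifnot(inherits(object, "cassava_fit"))
  term <- match.arg(term)
  if (!term %in% object$design$terms) {
    stop("term '", term, "' is not part of the fitted model")
  }
  reduced_terms <- setdiff(object$design$terms, term)
  if (!length(reduced_terms)) {
    stop("cannot drop the only random term of the model")
  }
  red <- fit_lmer(object$design, reduced_terms)
  chi2 <- max(0, 2 * (object$loglik - as.numeric(logLik(red))))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(term = term, chi_square = chi2, df = 1L, p_value = p,
       significant_at_1pct = p < 0.01)
}

#' Genotype-by-trait table of BLUP + intercept values
#'
#' @param fits named list of `cassava_fit` objects (one per trait), as
#'   returned by [fit_all_traits()].
#' @return data frame with a `genotype` column and one column per trait;
#'   genotypes absent from a trait's fit get `NA` in that column.
#' @export
blup_table <- function(fits) {
  if (inherits(fits, "cassava_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  genos <- sort(unique(unlist(lapply(fits, function(f) f$blups$genotype))))
  out <- data.frame(genotype = genos, stringsAsFactors = FALSE)
  for (f in fits) {
    out[[f$trait]] <- f$blups$blup_plus_intercept[
      match(genos, f$blups$genotype)]
  }
  out
}
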