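#' Reference trait means and variance components
#'
#' Per-trait overall means and REML variance components (genotype,
#' genotype-by-trial, residual) typical of a large multi-environment
#' evaluation of a cream/yellow-root cassava panel, together with the
#' broad-sense and clonal-mean heritabilities they imply. These values
#' parameterise the default synthetic-data preset and serve as worked
#' examples for the heritability formulas.
#'
#' @return data frame with columns `trait`, `mean`, `h2`, `h2m`,
#'   `sigma2_g`, `sigma2_ge`, `sigma2_e`.
#' @export
reference_components <- function() {
  data.frame(
    trait = c("TCC", "DMC.Grav", "DMC.OD", "FRY", "ShY", "HI", "DRY",
              "NRP", "StC", "PulpColor", "HCN"),
    mean = c(4.09, 34.22, 39.99, 16.49, 18.57, 45.40, 5.06, 4.15, 25.36,
             2.11, 6.80),
    h2 = c(0.72, 0.45, 0.54, 0.21, 0.22, 0.32, 0.21, 0.32, 0.48, 0.42,
           0.60),
    h2m = c(1.00, 0.92, 0.98, 0.83, 0.81, 0.89, 0.80, 0.89, 1.00, 0.99,
            0.96),
    sigma2_g = c(5.44, 5.26, 13.15, 17.28, 19.12, 49.42, 1.78, 0.81,
                 5.17, 0.18, 1.60),
    sigma2_ge = c(0.00, 3.87, 1.68, 28.06, 35.14, 46.83, 3.49, 0.80,
                  0.00, 0.00, 0.53),
    sigma2_e = c(2.16, 2.59, 9.44, 37.56, 32.50, 56.40, 3.22, 0.89,
                 5.59, 0.25, 0.52),
    stringsAsFactors = FALSE
  )
}

#' Default genetic correlation matrix between traits
#'
#' Signed correlation structure used by the synthetic-data preset: a
#' strong positive carotenoid/pulp-colour association, a near-zero
#' carotenoid/dry-matter association, a mutually correlated agronomic
#' block (fresh, dry and shoot yield, harvest index, root number) and a
#' dry-matter/starch quality block. The hand-specified matrix is projected
#' to the nearest positive-semidefinite correlation matrix (eigenvalue
#' clipping followed by renormalisation of the diagonal), so the returned
#' matrix is always a valid MVN parameter.
#'
#' @param traits trait names (subset of [trait_names()]).
#' @return symmetric PSD correlation matrix with unit diagonal.
#' @export
default_genetic_correlation <- function(traits = trait_names()) {
  tn <- trait_names()
  R <- diag(length(tn))
  dimnames(R) <- list(tn, tn)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("TCC", "PulpColor", 0.70)
  set_r("TCC", "HCN", 0.20)
  set_r("PulpColor", "HCN", 0.15)
  set_r("DMC.Grav", "DMC.OD", 0.60)
  set_r("DMC.Grav", "StC", 0.80)
  set_r("DMC.OD", "StC", 0.50)
  set_r("DMC.Grav", "DRY", 0.30)
  set_r("FRY", "DRY", 0.85)
  set_r("FRY", "ShY", 0.55)
  set_r("FRY", "HI", 0.45)
  set_r("DRY", "ShY", 0.45)
  set_r("DRY", "HI", 0.40)
  set_r("ShY", "HI", -0.35)
  set_r("NRP", "FRY", 0.40)
  set_r("NRP", "DRY", 0.35)
  set_r("NRP", "ShY", 0.30)
  set_r("NRP", "HI", 0.10)
  set_r("NRP", "StC", -0.15)
  R <- nearest_psd_correlation(R)
  miss <- setdiff(traits, tn)
  if (length(miss)) stop("unknown trait(s): ", paste(miss, collapse = ", "))
  R[traits, traits, drop = FALSE]
}

# Project a symmetric matrix to the nearest PSD correlation matrix by
# eigenvalue clipping at `floor`, then rescale to unit diagonal.
nearest_psd_correlation <- function(R, floor = 1e-6) {
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vals <- pmax(ev$values, floor)
  M <- ev$vectors %*% (vals * t(ev$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  dimnames(M) <- dimnames(R)
  (M + t(M)) / 2
}

#' Configuration for the synthetic trial generator
#'
#' Builds a validated generator configuration. The defaults emulate a
#' large germplasm evaluation: 265 test genotypes plus 10 common checks
#' over 21 trials with between 5 and 22 augmented blocks each, trait means
#' and genotype/GE/error variance components from
#' [reference_components()], the signed genetic correlation structure of
#' [default_genetic_correlation()], and carotenoid content measured in
#' only the last two trials. Trial- and block-level variances are not part
#' of the reference table; they default to `2 * sigma2_e` and
#' `0.25 * sigma2_e` per trait.
#'
#' @param n_genotypes number of unreplicated test genotypes.
#' @param n_checks number of common checks (replicated in every block).
#' @param n_trials number of trials (environments).
#' @param blocks_per_trial single count or length-2 range from which each
#'   trial's block count is drawn.
#' @param traits trait names to simulate.
#' @param means named numeric vector of per-trait overall means.
#' @param sigma2_g,sigma2_ge,sigma2_e named per-trait variance components
#'   (genotype, genotype-by-trial, residual).
#' @param sigma2_env,sigma2_block named per-trait trial-level and
#'   block-level variances.
#' @param genetic_correlation PSD correlation matrix (unit diagonal) of
#'   genotype effects across traits.
#' @param missingness named list: trait -> integer indices of the trials
#'   in which the trait is measured. Traits absent from the list are
#'   measured everywhere.
#' @param discretize_scores if `TRUE`, pulp colour is thresholded to the
#'   1-3 scale and the cyanogenic score rounded to 1-9; if `FALSE`
#'   (default) the latent continuous values are kept, which is the scale
#'   on which the linear mixed model operates.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_genotypes = 265,
                             n_checks = 10,
                             n_trials = 21,
                             blocks_per_trial = c(5, 22),
                             traits = trait_names(),
                             means = NULL,
                             sigma2_g = NULL,
                             sigma2_ge = NULL,
                             sigma2_e = NULL,
                             sigma2_env = NULL,
                             sigma2_block = NULL,
                             genetic_correlation = NULL,
                             missingness = NULL,
                             discretize_scores = FALSE) {
  ref <- reference_components()
  pick <- function(user, col) {
    v <- stats::setNames(ref[[col]], ref$trait)[traits]
    if (!is.null(user)) {
      if (is.null(names(user))) {
        stopifnot(length(user) == length(traits))
        names(user) <- traits
      }
      v[names(user)] <- user
    }
    if (anyNA(v)) stop("no default ", col, " for trait(s): ",
                       paste(traits[is.na(v)], collapse = ", "))
    v
  }
  means <- pick(means, "mean")
  sigma2_g <- pick(sigma2_g, "sigma2_g")
  sigma2_ge <- pick(sigma2_ge, "sigma2_ge")
  sigma2_e <- pick(sigma2_e, "sigma2_e")
  if (is.null(sigma2_env)) sigma2_env <- 2 * sigma2_e
  if (is.null(sigma2_block)) sigma2_block <- 0.25 * sigma2_e
  if (is.null(genetic_correlation)) {
    genetic_correlation <- default_genetic_correlation(traits)
  }
  R <- genetic_correlation
  stopifnot(is.matrix(R), nrow(R) == length(traits),
            ncol(R) == length(traits))
  if (max(abs(diag(R) - 1)) > 1e-8) stop("correlation diagonal must be 1")
  if (max(abs(R - t(R))) > 1e-8) stop("correlation matrix must be symmetric")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("genetic_correlation is not positive semidefinite")
  }
  if (any(c(sigma2_g, sigma2_ge, sigma2_e, sigma2_env, sigma2_block) < 0)) {
    stop("variance components must be >= 0")
  }
  if (n_checks < 1) stop("need at least one check")
  if (n_checks > n_genotypes) stop("more checks than test genotypes")
  if (is.null(missingness)) {
    if ("TCC" %in% traits && n_trials > 2) {
      missingness <- list(TCC = (n_trials - 1):n_trials)
    } else {
      missingness <- list()
    }
  }
  for (tr in names(missingness)) {
    if (!tr %in% traits) stop("missingness names unknown trait: ", tr)
    if (any(!missingness[[tr]] %in% seq_len(n_trials))) {
      stop("missingness indices out of trial range for ", tr)
    }
  }
  structure(list(n_genotypes = n_genotypes, n_checks = n_checks,
                 n_trials = n_trials, blocks_per_trial = blocks_per_trial,
                 traits = traits, means = means, sigma2_g = sigma2_g,
                 sigma2_ge = sigma2_ge, sigma2_e = sigma2_e,
                 sigma2_env = sigma2_env, sigma2_block = sigma2_block,
                 genetic_correlation = R, missingness = missingness,
                 discretize_scores = discretize_scores),
            class = "generator_config")
}

#' Simulate a multi-environment augmented-design trial set
#'
#' Draws a complete plot-level dataset from the additive model
#' \deqn{Y_{ijk} = \mu + E_i + B_{(i)j} + G_k + GE_{ik} + \epsilon_{ijk}}
#' with independent Gaussian trial, block-within-trial, genotype-by-trial
#' and error effects, and genotype effects drawn across traits from a
#' zero-mean multivariate normal with covariance
#' `diag(sd_g) %*% R %*% diag(sd_g)`. Checks appear in every block of
#' every trial; each test genotype appears once per trial in a randomly
#' assigned block (the repeated-evaluation structure of a germplasm
#' collection, which makes the genotype-by-trial variance estimable).
#' Traits restricted by the missingness map are `NA` outside their
#' measured trials. Percent-scale traits (HI, StC) are truncated into
#' \[0, 100\].
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed governing every draw.
#' @return list with elements `data` (a `cassava_dataset`) and `truth`
#'   (generating parameters, true effect draws and realized components).
#' @export
simulate_trials <- function(cfg = generator_config(), seed = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(as.integer(seed))
  p <- length(cfg$traits)
  n_all <- cfg$n_genotypes + cfg$n_checks
  check_ids <- sprintf("CHK-%02d", seq_len(cfg$n_checks))
  test_ids <- sprintf("G%04d", seq_len(cfg$n_genotypes))
  geno_ids <- c(check_ids, test_ids)

  # genotype effects: MVN across traits
  Sg <- diag(sqrt(cfg$sigma2_g), p) %*% cfg$genetic_correlation %*%
    diag(sqrt(cfg$sigma2_g), p)
  ev <- eigen(Sg, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  G <- matrix(stats::rnorm(n_all * p), n_all, p) %*% t(A)
  dimnames(G) <- list(geno_ids, cfg$traits)

  bpt <- cfg$blocks_per_trial
  n_blocks <- if (length(bpt) == 2) {
    sample(bpt[1]:bpt[2], cfg$n_trials, replace = TRUE)
  } else {
    rep(bpt, cfg$n_trials)
  }
  trial_ids <- sprintf("T%02d", seq_len(cfg$n_trials))
  trials <- data.frame(trial_id = trial_ids,
                       year = 2000 + seq_len(cfg$n_trials),
                       location = "synthetic",
                       n_blocks = n_blocks, stringsAsFactors = FALSE)

  env_eff <- sapply(cfg$sigma2_env, function(v) {
    stats::rnorm(cfg$n_trials, 0, sqrt(v))
  })
  env_eff <- matrix(env_eff, cfg$n_trials, p,
                    dimnames = list(trial_ids, cfg$traits))
  ge_eff <- array(stats::rnorm(n_all * cfg$n_trials * p),
                  dim = c(n_all, cfg$n_trials, p),
                  dimnames = list(geno_ids, trial_ids, cfg$traits))
  for (t in seq_len(p)) {
    ge_eff[, , t] <- ge_eff[, , t] * sqrt(cfg$sigma2_ge[t])
  }

  plot_list <- vector("list", cfg$n_trials)
  block_eff <- list()
  for (i in seq_len(cfg$n_trials)) {
    nb <- n_blocks[i]
    be <- sapply(cfg$sigma2_block, function(v) stats::rnorm(nb, 0, sqrt(v)))
    be <- matrix(be, nb, p)
    block_eff[[trial_ids[i]]] <- be
    test_block <- sample(rep_len(seq_len(nb), cfg$n_genotypes))
    rows <- rbind(
      expand.grid(block = seq_len(nb), genotype = check_ids,
                  stringsAsFactors = FALSE),
      data.frame(block = test_block, genotype = test_ids,
                 stringsAsFactors = FALSE)
    )
    vals <- matrix(NA_real_, nrow(rows), p,
                   dimnames = list(NULL, cfg$traits))
    for (t in seq_len(p)) {
      tr <- cfg$traits[t]
      measured <- if (tr %in% names(cfg$missingness)) {
        i %in% cfg$missingness[[tr]]
      } else {
        TRUE
      }
      if (!measured) next
      gidx <- match(rows$genotype, geno_ids)
      vals[, t] <- cfg$means[t] + env_eff[i, t] + be[rows$block, t] +
        G[gidx, t] + ge_eff[cbind(gidx, i, t)] +
        stats::rnorm(nrow(rows), 0, sqrt(cfg$sigma2_e[t]))
    }
    for (tr in intersect(c("HI", "StC"), cfg$traits)) {
      vals[, tr] <- pmin(pmax(vals[, tr], 0), 100)
    }
    if ("NRP" %in% cfg$traits) { # root counts cannot go negative
      vals[, "NRP"] <- pmax(vals[, "NRP"], 0)
    }
    if (cfg$discretize_scores) {
      if ("PulpColor" %in% cfg$traits) {
        vals[, "PulpColor"] <- pmin(pmax(round(vals[, "PulpColor"]), 1), 3)
      }
      if ("HCN" %in% cfg$traits) {
        vals[, "HCN"] <- pmin(pmax(round(vals[, "HCN"]), 1), 9)
      }
    }
    plot_list[[i]] <- data.frame(trial_id = trial_ids[i],
                                 block_id = sprintf("B%02d", rows$block),
                                 genotype_id = rows$genotype,
                                 vals, check.names = FALSE,
                                 stringsAsFactors = FALSE)
  }
  plots <- do.call(rbind, plot_list)
  rownames(plots) <- NULL
  germplasm <- data.frame(genotype_id = geno_ids,
                          is_check = geno_ids %in% check_ids,
                          stringsAsFactors = FALSE)
  ds <- cassava_dataset(trials, germplasm, plots)
  truth <- list(
    config = cfg, seed = as.integer(seed),
    genotype_effects = G, env_effects = env_eff,
    block_effects = block_eff, ge_effects = ge_eff,
    realized = data.frame(
      trait = cfg$traits,
      sigma2_g = apply(G[test_ids, , drop = FALSE], 2, stats::var),
      sigma2_ge = apply(ge_eff, 3, function(m) stats::var(as.vector(m))),
      row.names = NULL, stringsAsFactors = FALSE
    )
  )
  list(data = ds, truth = truth)
}

#' Back-fill raw measurements from trait values
#'
#' Inverts the trait-derivation formulas so that a simulated dataset can be
#' pushed through the raw-measurement path end to end: for each plot,
#' chooses raw field/laboratory values (weights in air and water, percent
#' humidity, plot root/shoot weights, absorbance/volume/mass, root and
#' plant counts) such that [derive_traits()] reproduces the plot's trait
#' values to within 1e-9 relative error. The composite traits HI and DRY
#' are recomputed from the back-filled FRY, ShY and DMC.Grav so the
#' resulting dataset is internally consistent. Root counts are stored at
#' fractional precision to keep the inversion exact.
#'
#' @param ds a `cassava_dataset` whose plots carry trait columns.
#' @param seed integer seed for the arbitrary auxiliary choices (sample
#'   mass class, extract volume).
#' @param plot_area_m2 plot area used for the yield inversion.
#' @return the dataset with raw measurement columns added and HI/DRY made
#'   consistent.
#' @export
backfill_raw_measurements <- function(ds, seed = 1, plot_area_m2 = 14.4) {
  stopifnot(inherits(ds, "cassava_dataset"))
  set.seed(as.integer(seed))
  pl <- ds$plots
  n <- nrow(pl)
  pl$plot_area <- plot_area_m2
  if ("DMC.Grav" %in% names(pl)) {
    d <- pl$DMC.Grav
    if (any(!is.na(d) & d < 16.3)) {
      stop("DMC.Grav below 16.3 cannot be represented with a non-negative ",
           "weight in water")
    }
    pl$weight_air <- ifelse(is.na(d), NA_real_, 5)
    pl$weight_water <- 5 * (1 - 158.3 / (d + 142))
  }
  if ("DMC.OD" %in% names(pl)) pl$humidity <- 100 - pl$DMC.OD
  if ("FRY" %in% names(pl)) {
    pl$plot_root_weight <- pl$FRY * plot_area_m2 / 10
  }
  if ("ShY" %in% names(pl)) {
    pl$plot_shoot_weight <- pl$ShY * plot_area_m2 / 10
  }
  if ("NRP" %in% names(pl)) {
    pl$n_plants_harvested <- ifelse(is.na(pl$NRP), NA_real_, 16)
    pl$n_roots <- pl$NRP * 16
  }
  if ("TCC" %in% names(pl)) {
    pl$sample_mass <- sample(c(10, 15, 25), n, replace = TRUE)
    pl$sample_mass[is.na(pl$TCC)] <- NA_real_
    pl$extract_volume <- ifelse(is.na(pl$TCC), NA_real_, 50)
    pl$absorbance <- pl$TCC * 2592 * pl$sample_mass / (50 * 1e4)
    neg <- !is.na(pl$absorbance) & pl$absorbance < 0
    if (any(neg)) {
      stop("negative TCC cannot be represented as an absorbance")
    }
  }
  if ("StC" %in% names(pl)) pl$starch_content <- pl$StC
  if ("PulpColor" %in% names(pl)) pl$pulp_color <- pl$PulpColor
  if ("HCN" %in% names(pl)) pl$hcn_score <- pl$HCN
  # make composite traits consistent with the raw inputs
  if (all(c("FRY", "ShY") %in% names(pl))) {
    ok <- !is.na(pl$FRY) & !is.na(pl$ShY) & (pl$FRY + pl$ShY > 0)
    pl$HI <- NA_real_
    pl$HI[ok] <- harvest_index(pl$FRY[ok], pl$ShY[ok])
  }
  if (all(c("FRY", "DMC.Grav") %in% names(pl))) {
    pl$DRY <- dry_root_yield(pl$FRY, pl$DMC.Grav)
  }
  ds$plots <- pl
  ds
}
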