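#' Default economic weights of the selection index
#'
#' Weights favouring carotenoid content and yellow pulp (30 each), root
#' and dry yield and root number (10), dry matter, shoot yield, harvest
#' index and starch (5), and penalising cyanogenic compounds (-30).
#'
#' @return named numeric vector over the eleven canonical traits.
#' @export
default_selection_weights <- function() {
  c(DMC.Grav = 5, DMC.OD = 5, TCC = 30, FRY = 10, ShY = 5, HI = 5,
    DRY = 10, NRP = 10, StC = 5, PulpColor = 30, HCN = -30)
}

#' Weighted selection index over trait BLUPs
#'
#' Index of each genotype as the weighted sum of its BLUP + intercept
#' values, \eqn{SI_g = \sum_t w_t b_{gt}}. Two variants: `mode = "blup"`
#' (default) weights the BLUP values directly, exactly as the index is
#' defined; `mode = "rank"` is the rank-summation variant, weighting the
#' within-trait ascending ranks instead (a negatively weighted trait such
#' as the cyanogenic score is thereby penalised for high ranks).
#' Optionally each trait is z-scored first, removing the unit dependence
#' of the raw weighted sum. Genotypes missing any weighted trait are
#' excluded with a warning: an index over unequal trait sets is not
#' comparable.
#'
#' @param blups genotype-by-trait table of BLUP + intercept values with a
#'   `genotype` column.
#' @param weights named numeric vector of economic weights; defaults to
#'   [default_selection_weights()] restricted to the traits present.
#' @param standardize z-score each weighted trait before summing
#'   (default `FALSE`).
#' @param mode `"blup"` or `"rank"`.
#' @return named numeric vector of index scores.
#' @export
compute_index <- function(blups, weights = NULL, standardize = FALSE,
                          mode = c("blup", "rank")) {
  mode <- match.arg(mode)
  stopifnot("genotype" %in% colnames(blups))
  if (is.null(weights)) {
    weights <- default_selection_weights()
    weights <- weights[names(weights) %in% colnames(blups)]
  }
  if (!length(weights)) stop("no applicable weights")
  unknown <- setdiff(names(weights), colnames(blups))
  if (length(unknown)) {
    stop("weight(s) on unknown trait(s): ", paste(unknown, collapse = ", "))
  }
  X <- as.matrix(blups[, names(weights), drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- blups$genotype
  incomplete <- !stats::complete.cases(X)
  if (any(incomplete)) {
    warning("excluding ", sum(incomplete),
            " genotype(s) with missing weighted trait(s): ",
            paste(utils::head(blups$genotype[incomplete], 5),
                  collapse = ", "),
            if (sum(incomplete) > 5) ", ..." else "")
    X <- X[!incomplete, , drop = FALSE]
  }
  if (mode == "rank") {
    X <- apply(X, 2, rank, ties.method = "average")
  } else if (standardize) {
    X <- scale(X)
  }
  drop(X %*% weights)[]
}

#' Select the top-ranked parents
#'
#' Top `n` genotypes by index score, descending; ties at the selection
#' boundary break by genotype identifier (lexicographic), which is logged.
#'
#' @param scores named numeric vector from [compute_index()].
#' @param n number of parents to select (default 30).
#' @return character vector of selected genotype ids, in rank order.
#' @export
select_parents <- function(scores, n = 30) {
  if (n < 1) stop("n must be >= 1")
  if (n > length(scores)) {
    warning("n exceeds population size; selecting everyone")
    n <- length(scores)
  }
  ord <- order(-scores, names(scores))
  ranked <- names(scores)[ord]
  if (n < length(scores) &&
      scores[ranked[n]] == scores[ranked[n + 1]]) {
    message("tie at the selection boundary broken by genotype id")
  }
  ranked[seq_len(n)]
}

#' Selected-parent gain report
#'
#' Per-trait report of the selected genotypes: mean of the selected set,
#' general (population) mean, selection differential S, predicted gain
#' G = h2m * S and percent gain, all on the BLUP + intercept scale.
#' Traits without a heritability entry keep their means but omit the
#' gain.
#'
#' @param blups genotype-by-trait BLUP table with a `genotype` column.
#' @param selected character vector of selected genotype ids.
#' @param heritabilities named numeric vector of clonal-mean
#'   heritabilities per trait (or a data frame with `trait` and `h2m`
#'   columns, as stacked [heritability()] rows).
#' @return data frame with one row per trait: `trait`, `selected_mean`,
#'   `general_mean`, `S`, `G`, `G_pct`.
#' @export
gain_report <- function(blups, selected, heritabilities) {
  stopifnot("genotype" %in% colnames(blups), length(selected) >= 1)
  if (is.data.frame(heritabilities)) {
    heritabilities <- stats::setNames(heritabilities$h2m,
                                      heritabilities$trait)
  }
  traits <- setdiff(colnames(blups), c("genotype", "cluster"))
  out <- do.call(rbind, lapply(traits, function(tr) {
    v <- stats::setNames(blups[[tr]], blups$genotype)
    pop_mean <- mean(v, na.rm = TRUE)
    sel_mean <- mean(v[selected], na.rm = TRUE)
    S <- sel_mean - pop_mean
    if (tr %in% names(heritabilities) && !is.na(heritabilities[tr])) {
      g <- genetic_gain(v, selected, heritabilities[[tr]], pop_mean)
      data.frame(trait = tr, selected_mean = sel_mean,
                 general_mean = pop_mean, S = S, G = g$G,
                 G_pct = g$G_pct, stringsAsFactors = FALSE)
    } else {
      data.frame(trait = tr, selected_mean = sel_mean,
                 general_mean = pop_mean, S = S, G = NA_real_,
                 G_pct = NA_real_, stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Worked-example table of 30 selected genotypes
#'
#' Genotype-by-trait BLUP + intercept values of a published-style set of
#' 30 cassava genotypes selected for recombination, shipped as a
#' plain-text fixture. Useful as a small worked example for the selection
#' and gain machinery.
#'
#' @return data frame with `genotype`, `cluster` and the eleven trait
#'   columns.
#' @export
selected_parents_example <- function() {
  utils::read.csv(system.file("extdata", "selected_parents_blups.csv",
                              package = "biofortqg", mustWork = TRUE),
                  check.names = FALSE, stringsAsFactors = FALSE)
}
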