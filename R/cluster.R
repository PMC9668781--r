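#' Principal-component scores of the BLUP table
#'
#' Centres (and by default unit-variance scales) the trait columns and
#' projects the genotypes onto the principal axes. Missing cells are
#' mean-imputed per trait first (the imputed fraction is reported via a
#' message), since K-means requires complete vectors. Component signs are
#' fixed by making the largest-magnitude loading of each axis positive,
#' so the decomposition is fully deterministic.
#'
#' @param blups genotype-by-trait BLUP table (data frame with `genotype`
#'   column, or numeric matrix).
#' @param standardize scale traits to unit variance before the
#'   decomposition (default `TRUE`; traits carry incommensurable units).
#' @param n_components number of components to retain (default: all).
#' @return matrix of scores, genotypes in rows (named), components in
#'   columns, with the explained-variance proportions in attribute
#'   `"var_explained"` and the loadings in `"rotation"`.
#' @export
pca_scores <- function(blups, standardize = TRUE, n_components = NULL) {
  gn <- if ("genotype" %in% colnames(blups)) blups$genotype else
    rownames(blups)
  X <- as.matrix(blups[, setdiff(colnames(blups), c("genotype", "cluster")),
                       drop = FALSE])
  storage.mode(X) <- "double"
  if (ncol(X) < 2) stop("need at least 2 traits")
  n_imp <- sum(is.na(X))
  if (n_imp > 0) {
    message(sprintf("mean-imputing %d missing cell(s) (%.1f%%)",
                    n_imp, 100 * n_imp / length(X)))
    for (j in seq_len(ncol(X))) {
      X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = standardize)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  rotation <- sweep(pc$rotation, 2, flip, `*`)
  if (!is.null(n_components)) {
    n_components <- min(n_components, ncol(scores))
    scores <- scores[, seq_len(n_components), drop = FALSE]
    rotation <- rotation[, seq_len(n_components), drop = FALSE]
  }
  rownames(scores) <- gn
  attr(scores, "var_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  attr(scores, "rotation") <- rotation
  scores
}

#' Successive K-means with BIC model selection
#'
#' Runs K-means for each candidate number of groups, each with multiple
#' random restarts keeping the best within-cluster sum of squares, and
#' scores each solution by the parameter-counting BIC
#' \deqn{BIC(k) = n \ln(WSS_k/n) + k\,p \ln n,}
#' where p is the score dimensionality, so each fitted centre is charged
#' its p coordinates (the X-means convention; charging one parameter per
#' cluster systematically over-splits Gaussian groups). The selected k
#' minimises the BIC; ties break toward the smaller k.
#'
#' @param scores numeric matrix (genotypes in rows), e.g. from
#'   [pca_scores()].
#' @param k_range candidate cluster counts (default 2:15), all below the
#'   number of rows.
#' @param nstart random restarts per k (default 25).
#' @param seed integer seed making the scan reproducible.
#' @return object of class `cluster_solution`: list with `k_selected`,
#'   `assignments` (named integer vector), `bic_curve` (data frame k,
#'   wss, bic), `cluster_sizes`, `centers` and the input `scores`.
#' @export
kmeans_bic_scan <- function(scores, k_range = 2:15, nstart = 25,
                            seed = 1) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stop("k_range must lie within 2 .. n-1")
  }
  if (all(apply(scores, 2, stats::sd) == 0)) {
    stop("degenerate input: all points identical")
  }
  set.seed(as.integer(seed))
  fits <- vector("list", length(k_range))
  wss <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- stats::kmeans(scores, centers = k_range[i],
                               nstart = nstart, iter.max = 100)
    wss[i] <- fits[[i]]$tot.withinss
  }
  bic <- n * log(wss / n) + k_range * ncol(scores) * log(n)
  best <- which(bic == min(bic))[1] # tie -> smaller k (range is sorted)
  sol <- fits[[best]]
  assignments <- stats::setNames(sol$cluster, rownames(scores))
  structure(list(k_selected = k_range[best], assignments = assignments,
                 bic_curve = data.frame(k = k_range, wss = wss, bic = bic),
                 cluster_sizes = as.integer(table(sol$cluster)),
                 centers = sol$centers, scores = scores),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("K-means/BIC clustering: k =", x$k_selected, "selected from",
      paste(range(x$bic_curve$k), collapse = ".."), "\n")
  cat("cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Per-cluster trait summaries with Holm-adjusted comparisons
#'
#' Descriptive statistics (mean, median, quartiles) per cluster and
#' trait, plus all pairwise Welch two-sample comparisons of cluster means
#' per trait with step-down Holm adjustment within each trait family and
#' significance stars at 0.05 / 0.01 / 0.001. Clusters with fewer than
#' two members are excluded from the tests with a warning.
#'
#' @param solution a `cluster_solution`.
#' @param blups the genotype-by-trait BLUP table the clustering was
#'   derived from (`genotype` column required).
#' @return list with data frames `summary` (cluster, trait, n, mean,
#'   median, q1, q3) and `comparisons` (trait, cluster_a, cluster_b,
#'   p_raw, p_holm, stars).
#' @export
summarize_clusters <- function(solution, blups) {
  stopifnot(inherits(solution, "cluster_solution"),
            "genotype" %in% colnames(blups))
  cl <- solution$assignments[blups$genotype]
  traits <- setdiff(colnames(blups), c("genotype", "cluster"))
  summ <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    do.call(rbind, lapply(traits, function(tr) {
      v <- blups[[tr]][cl == k]
      v <- v[!is.na(v)]
      data.frame(cluster = k, trait = tr, n = length(v),
                 mean = mean(v), median = stats::median(v),
                 q1 = unname(stats::quantile(v, 0.25)),
                 q3 = unname(stats::quantile(v, 0.75)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  sizes <- table(cl)
  testable <- as.integer(names(sizes)[sizes >= 2])
  if (length(testable) < length(sizes)) {
    warning("excluding cluster(s) of size < 2 from comparisons: ",
            paste(setdiff(names(sizes), as.character(testable)),
                  collapse = ", "))
  }
  comp <- NULL
  if (length(testable) >= 2) {
    pairs <- utils::combn(sort(testable), 2)
    comp <- do.call(rbind, lapply(traits, function(tr) {
      praw <- apply(pairs, 2, function(pr) {
        a <- blups[[tr]][cl == pr[1]]
        b <- blups[[tr]][cl == pr[2]]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2 || length(b) < 2 ||
            (stats::sd(a) == 0 && stats::sd(b) == 0)) {
          return(NA_real_)
        }
        stats::t.test(a, b)$p.value
      })
      ph <- stats::p.adjust(praw, method = "holm")
      data.frame(trait = tr, cluster_a = pairs[1, ],
                 cluster_b = pairs[2, ], p_raw = praw, p_holm = ph,
                 stars = ifelse(is.na(ph), "",
                         ifelse(ph < 0.001, "***",
                         ifelse(ph < 0.01, "**",
                         ifelse(ph < 0.05, "*", "")))),
                 stringsAsFactors = FALSE)
    }))
    rownames(comp) <- NULL
  }
  list(summary = summ, comparisons = comp)
}
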