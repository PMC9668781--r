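#' Pairwise Pearson correlations among trait BLUPs
#'
#' Pairwise-complete Pearson correlations between trait columns of a
#' genotype-by-trait BLUP table, with two-sided significance from the
#' t statistic \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n - 2 degrees of
#' freedom. Cells with p above the significance level are flagged
#' non-significant. Constant traits yield `NA` with a warning.
#'
#' @param blups data frame with a `genotype` column (optional) and one
#'   numeric column per trait, or a numeric matrix.
#' @param alpha significance level for the non-significance flag
#'   (default 0.05).
#' @return object of class `trait_cor`: list with matrices `r`, `p`,
#'   `n` (complete pairs) and logical `significant`.
#' @export
pearson_matrix <- function(blups, alpha = 0.05) {
  X <- as.matrix(blups[, setdiff(colnames(blups), c("genotype", "cluster")),
                       drop = FALSE])
  storage.mode(X) <- "double"
  p <- ncol(X)
  traits <- colnames(X)
  r <- diag(1, p); pv <- matrix(1, p, p); n <- matrix(0L, p, p)
  dimnames(r) <- dimnames(pv) <- dimnames(n) <- list(traits, traits)
  diag(n) <- colSums(!is.na(X))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j <= i) next
      ok <- stats::complete.cases(X[, c(i, j)])
      m <- sum(ok)
      n[i, j] <- n[j, i] <- m
      if (m < 3) {
        warning("fewer than 3 complete pairs for ", traits[i], " vs ",
                traits[j])
        r[i, j] <- r[j, i] <- NA_real_
        pv[i, j] <- pv[j, i] <- NA_real_
        next
      }
      if (stats::sd(X[ok, i]) == 0 || stats::sd(X[ok, j]) == 0) {
        warning("constant trait in pair ", traits[i], " vs ", traits[j],
                "; correlation undefined")
        r[i, j] <- r[j, i] <- NA_real_
        pv[i, j] <- pv[j, i] <- NA_real_
        next
      }
      rij <- stats::cor(X[ok, i], X[ok, j])
      r[i, j] <- r[j, i] <- rij
      if (abs(rij) >= 1) {
        pij <- 0
      } else {
        tstat <- rij * sqrt((m - 2) / (1 - rij^2))
        pij <- 2 * stats::pt(abs(tstat), df = m - 2, lower.tail = FALSE)
      }
      pv[i, j] <- pv[j, i] <- pij
    }
  }
  sig <- !is.na(pv) & pv < alpha
  diag(sig) <- TRUE
  structure(list(traits = traits, r = r, p = pv, n = n,
                 significant = sig, alpha = alpha),
            class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, digits = 2, ...) {
  cat("Pearson correlation matrix (", length(x$traits), " traits; 'x' = ",
      "not significant at ", x$alpha, "):\n", sep = "")
  m <- format(round(x$r, digits))
  m[!x$significant] <- paste0(m[!x$significant], "x")
  print(m, quote = FALSE)
  invisible(x)
}

#' Hierarchically clustered trait ordering for a correlogram
#'
#' Orders traits by average-linkage agglomerative clustering on the
#' dissimilarity `1 - r`, so that mutually correlated traits appear
#' contiguously. Deterministic for a given matrix.
#'
#' @param cm a `trait_cor` object or a correlation matrix.
#' @return character vector of trait names in display order.
#' @export
order_correlogram <- function(cm) {
  r <- if (inherits(cm, "trait_cor")) cm$r else as.matrix(cm)
  if (ncol(r) <= 2) return(colnames(r))
  d <- 1 - r
  d[is.na(d)] <- 1
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  colnames(r)[hc$order]
}

# ---- graphical lasso -------------------------------------------------
# Sparse inverse-covariance estimation by block coordinate descent
# (lasso regression of each variable on the rest, applied to the working
# covariance), the classical algorithm for the L1-penalised Gaussian
# likelihood. Written here because no sparse precision estimator ships
# with the environment's R packages.

# coordinate-descent lasso for: min 1/2 b' V b - s' b + rho * |b|_1
lasso_cd <- function(V, s, rho, b0 = NULL, tol = 1e-8, max_iter = 1000) {
  p <- length(s)
  b <- if (is.null(b0)) numeric(p) else b0
  d <- diag(V)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      resid <- s[j] - sum(V[j, ] * b) + d[j] * b[j]
      bj <- sign(resid) * max(abs(resid) - rho, 0) / d[j]
      delta <- max(delta, abs(bj - b[j]))
      b[j] <- bj
    }
    if (delta < tol) break
  }
  b
}

#' Graphical lasso estimate of a sparse precision matrix
#'
#' Maximises the L1-penalised Gaussian log-likelihood
#' `log det(Theta) - tr(S Theta) - rho * ||Theta||_1` (off-diagonal
#' penalty) by block coordinate descent over the columns of the working
#' covariance. At `rho = 0` (and nonsingular `S`) the result equals
#' `solve(S)`.
#'
#' @param S sample covariance (or correlation) matrix.
#' @param rho non-negative L1 penalty.
#' @param tol convergence tolerance on the working covariance.
#' @param max_iter maximum outer sweeps.
#' @return list with `Theta` (precision), `W` (fitted covariance) and the
#'   penalised log-likelihood `loglik` (up to constants, for n = 1).
#' @export
graphical_lasso <- function(S, rho, tol = 1e-6, max_iter = 200) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), rho >= 0)
  p <- ncol(S)
  if (p == 1) {
    Theta <- matrix(1 / S[1, 1], 1, 1)
    return(list(Theta = Theta, W = S, loglik = log(Theta[1, 1]) - 1))
  }
  W <- S + rho * diag(p)
  B <- matrix(0, p - 1, p) # lasso coefficients per column
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      V <- W[idx, idx, drop = FALSE]
      s <- S[idx, j]
      B[, j] <- lasso_cd(V, s, rho, b0 = B[, j])
      w12 <- V %*% B[, j]
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (max(abs(W - W_old)) < tol) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    Theta[j, j] <- theta_jj
    Theta[idx, j] <- -B[, j] * theta_jj
  }
  Theta <- (Theta + t(Theta)) / 2
  Theta[abs(Theta) < 1e-8] <- 0 # symmetrisation leaves numeric dust
  dimnames(Theta) <- dimnames(W) <- dimnames(S)
  ld <- determinant(Theta, logarithm = TRUE)
  loglik <- as.numeric(ld$modulus) - sum(S * Theta)
  list(Theta = Theta, W = W, loglik = loglik)
}

#' Constrained Gaussian MLE for a fixed graph
#'
#' Covariance-selection maximum likelihood: maximises
#' `log det(Theta) - tr(S Theta)` subject to `Theta[i, j] = 0` off the
#' given support, by the classical block algorithm (each column solved as
#' an unpenalised regression restricted to its neighbours). Used to score
#' candidate graphs without the shrinkage bias of the lasso estimate.
#'
#' @param S covariance/correlation matrix.
#' @param support logical or 0/1 adjacency matrix (diagonal ignored).
#' @param tol,max_iter convergence controls.
#' @return list with `Theta` and unpenalised per-observation `loglik`.
#' @export
ggm_constrained_mle <- function(S, support, tol = 1e-8, max_iter = 200) {
  p <- ncol(S)
  A <- support | t(support)
  diag(A) <- FALSE
  W <- S
  B <- matrix(0, p - 1, p)
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      nb <- which(A[idx, j])
      b <- numeric(p - 1)
      if (length(nb)) {
        V <- W[idx[nb], idx[nb], drop = FALSE]
        b[nb] <- solve(V, S[idx[nb], j])
      }
      B[, j] <- b
      w12 <- W[idx, idx, drop = FALSE] %*% b
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (max(abs(W - W_old)) < tol) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    Theta[j, j] <- theta_jj
    Theta[idx, j] <- -B[, j] * theta_jj
  }
  Theta <- (Theta + t(Theta)) / 2
  Theta[!A & row(A) != col(A)] <- 0
  dimnames(Theta) <- dimnames(S)
  ld <- determinant(Theta, logarithm = TRUE)
  list(Theta = Theta,
       loglik = as.numeric(ld$modulus) - sum(S * Theta))
}

# Extended BIC of a support, scored at its constrained MLE so that lasso
# shrinkage bias does not leak into model selection.
ebic_score <- function(S, support, n, gamma) {
  fit <- ggm_constrained_mle(S, support)
  nedges <- sum(support[upper.tri(support)])
  -n * fit$loglik + nedges * log(n) + 4 * gamma * nedges * log(ncol(S))
}

#' Regularised partial-correlation trait network
#'
#' Estimates a sparse Gaussian graphical model over the trait columns of
#' a BLUP table: traits are standardised, the correlation matrix is fed
#' to the graphical lasso over a log-spaced penalty grid, and the penalty
#' is selected by the extended BIC
#' \eqn{-2 \ell + E \log n + 4 \gamma E \log p} (E = edge count), each
#' candidate support scored at its constrained maximum likelihood
#' ([ggm_constrained_mle()]) so that lasso shrinkage does not bias the
#' model choice. Edge
#' weights are the partial correlations
#' \eqn{-\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}}; exactly-zero entries
#' mean no edge.
#'
#' @param blups genotype-by-trait BLUP table (data frame or matrix).
#' @param rho optional fixed penalty; if `NULL` the EBIC-selected value
#'   from the grid is used.
#' @param n_rho grid size (log-spaced from `rho_max`, the largest
#'   off-diagonal absolute correlation, down by three decades).
#' @param gamma EBIC tuning parameter (0 = plain BIC; default 0.5).
#' @return object of class `trait_network`: list with the
#'   partial-correlation `weights` matrix (zero diagonal), `edges` data
#'   frame (trait_a, trait_b, weight, sign), selected `rho`, and the
#'   `path` of penalties with their EBIC scores.
#' @export
partial_correlation_network <- function(blups, rho = NULL, n_rho = 50,
                                        gamma = 0.5) {
  X <- as.matrix(blups[, setdiff(colnames(blups), c("genotype", "cluster")),
                       drop = FALSE])
  storage.mode(X) <- "double"
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("need at least 3 complete genotype rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  S <- stats::cor(X)
  if (is.null(rho)) {
    rho_max <- max(abs(S[upper.tri(S)]))
    grid <- exp(seq(log(rho_max), log(rho_max * 1e-3),
                    length.out = n_rho))
    supports <- lapply(grid, function(rh) {
      Th <- graphical_lasso(S, rh)$Theta
      abs(Th) > 1e-10 & row(Th) != col(Th)
    })
    scores <- vapply(supports, ebic_score, numeric(1),
                     S = S, n = n, gamma = gamma)
    rho <- grid[which.min(scores)]
    path <- data.frame(rho = grid, ebic = scores)
  } else {
    if (rho == 0 && abs(det(S)) < 1e-12) {
      stop("covariance is singular; use a nonzero penalty")
    }
    path <- NULL
  }
  g <- graphical_lasso(S, rho)
  Th <- g$Theta
  W <- -Th / sqrt(tcrossprod(diag(Th)))
  diag(W) <- 0
  W[abs(W) < 1e-10] <- 0
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  edges <- data.frame(
    trait_a = colnames(W)[ut[, 1]], trait_b = colnames(W)[ut[, 2]],
    weight = W[ut],
    sign = ifelse(W[ut] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  structure(list(traits = colnames(W), weights = W, edges = edges,
                 rho = rho, gamma = gamma, n = n, path = path),
            class = "trait_network")
}

#' @export
print.trait_network <- function(x, ...) {
  cat("Regularised partial-correlation network:", length(x$traits),
      "traits,", nrow(x$edges), "edges (rho =",
      signif(x$rho, 3), ", EBIC gamma =", x$gamma, ")\n")
  if (nrow(x$edges)) {
    ord <- order(-abs(x$edges$weight))
    print(transform(x$edges[ord, ], weight = round(weight, 3)),
          row.names = FALSE)
  }
  invisible(x)
}
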