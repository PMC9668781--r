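# Shared fixtures and independent oracles, built in code at test time.

# Tiny hand-checkable dataset: 1 trial, 2 blocks, 2 checks + 2 test clones.
tiny_dataset <- function() {
  trials <- data.frame(trial_id = "T01", year = 2020L, location = "A",
                       n_blocks = 2L, stringsAsFactors = FALSE)
  germplasm <- data.frame(
    genotype_id = c("CHK-01", "CHK-02", "G0001", "G0002"),
    is_check = c(TRUE, TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  plots <- data.frame(
    trial_id = "T01",
    block_id = c("B1", "B1", "B1", "B2", "B2", "B2"),
    genotype_id = c("CHK-01", "CHK-02", "G0001",
                    "CHK-01", "CHK-02", "G0002"),
    TCC = c(4.0, 5.0, 8.0, 4.5, 5.5, 2.0),
    stringsAsFactors = FALSE)
  cassava_dataset(trials, germplasm, plots)
}

# Balanced one-way random-effects data: g genotypes x r replicates, no
# checks, single trial and block so only the genotype term survives.
balanced_oneway <- function(g, r, mu, sigma2_g, sigma2_e, seed) {
  set.seed(seed)
  geno <- rep(sprintf("G%03d", seq_len(g)), each = r)
  y <- mu + rep(stats::rnorm(g, 0, sqrt(sigma2_g)), each = r) +
    stats::rnorm(g * r, 0, sqrt(sigma2_e))
  data.frame(trial_id = "T01", block_id = "B1", genotype_id = geno,
             is_check = FALSE, y = y, stringsAsFactors = FALSE)
}

# Closed-form ANOVA estimators and shrunken means for the balanced
# one-way design: the independent oracle for the REML fit.
oneway_anova_oracle <- function(df) {
  means <- c(tapply(df$y, df$genotype_id, mean))
  g <- length(means)
  r <- nrow(df) / g
  grand <- mean(df$y)
  msb <- r * sum((means - grand)^2) / (g - 1)
  msw <- sum((df$y - means[df$genotype_id])^2) / (g * (r - 1))
  sigma2_e <- msw
  sigma2_g <- max(0, (msb - msw) / r)
  shrink <- sigma2_g / (sigma2_g + sigma2_e / r)
  blup <- shrink * (means - grand)
  list(sigma2_g = sigma2_g, sigma2_e = sigma2_e, mu = grand,
       blup = blup, shrunken_mean = grand + blup)
}

# Sample n rows from the Gaussian graphical model with precision Omega.
rmvn_precision <- function(n, Omega, seed) {
  set.seed(seed)
  Sigma <- solve(Omega)
  L <- chol(Sigma)
  X <- matrix(stats::rnorm(n * ncol(Omega)), n) %*% L
  colnames(X) <- paste0("t", seq_len(ncol(Omega)))
  as.data.frame(X)
}

# Tridiagonal (chain) precision matrix with off-diagonal weight w.
chain_precision <- function(p, w = 0.3) {
  Om <- diag(p)
  for (i in seq_len(p - 1)) Om[i, i + 1] <- Om[i + 1, i] <- w
  dimnames(Om) <- list(paste0("t", 1:p), paste0("t", 1:p))
  Om
}

# Six well-separated Gaussian clusters in `p` dimensions.
make_clusters <- function(n_per = 20, p = 11, k = 6, sep = 8, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(k * p, 0, sep / 2), k, p)
  X <- do.call(rbind, lapply(seq_len(k), function(j) {
    sweep(matrix(stats::rnorm(n_per * p), n_per, p), 2, centers[j, ], `+`)
  }))
  colnames(X) <- paste0("t", seq_len(p))
  rownames(X) <- sprintf("G%03d", seq_len(nrow(X)))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

quiet_fit <- function(...) {
  suppressWarnings(suppressMessages(fit_trait_blup(...)))
}
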