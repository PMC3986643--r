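#' SNP-BLUP (ridge) estimates of additive SNP effects
#'
#' Solves the ridge system with shrinkage `lambda = m * (1 - h2) / h2`
#' (`m` = SNP count), the SNP-BLUP value when each SNP carries an equal share
#' of the genetic variance. Genotypes and phenotypes are centered internally;
#' for `m >> n` the animal-dimension dual `b = X'(XX' + lambda I)^{-1} y` is
#' used. Deterministic.
#'
#' @param X genotype dosage matrix, animals x SNPs (0/1/2).
#' @param y phenotypes, one per animal.
#' @param h2 assumed trait heritability in (0, 1).
#' @return An `effect_estimates` object: list with `effect` (one beta-hat per
#'   SNP), `model = "ridge"`, `h2`.
#' @export
fit_ridge <- function(X, y, h2) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  stopifnot(length(y) == n)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  lambda <- m * (1 - h2) / h2
  if (n <= m) {
    alpha <- solve(tcrossprod(Xc) + diag(lambda, n), yc)
    b <- drop(crossprod(Xc, alpha))
  } else {
    b <- drop(solve(crossprod(Xc) + diag(lambda, m), crossprod(Xc, yc)))
  }
  structure(list(effect = b, model = "ridge", h2 = h2), class = "effect_estimates")
}

#' BayesR-style mixture estimates of additive SNP effects
#'
#' Gibbs sampler with a 4-component normal mixture prior on SNP effects:
#' component variances are `mixture * sigma2_g` with
#' `mixture = (0, 1e-4, 1e-3, 1e-2)` by default and
#' `sigma2_g = h2 * var(y)`. Samples per-SNP component indicators and effects,
#' Dirichlet mixture proportions and the residual variance; beta-hat is the
#' posterior mean averaged over `chains` independent chains. No
#' pedigree/polygenic term is fitted. Desk-scale defaults (5,000 iterations,
#' 2,000 burn-in, 3 chains) are deliberately smaller than the reference
#' analysis scale (50,000 / 30,000 / 5), which remains available through the
#' arguments.
#'
#' @inheritParams fit_ridge
#' @param mixture strictly increasing variance ladder as fractions of
#'   `sigma2_g`; first entry must be 0 (the null component); length >= 2.
#' @param n_iter,burn_in,chains Gibbs sampler controls.
#' @param seed optional integer; the whole fit is bit-reproducible given the
#'   seed (chains advance one RNG stream).
#' @return An `effect_estimates` object with additionally `pip` (posterior
#'   probability of a nonzero effect per SNP) and `pi` (mean mixture
#'   proportions).
#' @export
fit_bayesr <- function(X, y, h2, mixture = c(0, 1e-4, 1e-3, 1e-2),
                       n_iter = 5000L, burn_in = 2000L, chains = 3L,
                       seed = NULL) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  if (length(mixture) < 2L) stop("mixture needs at least 2 components")
  if (mixture[1] != 0) stop("first mixture component must have variance 0")
  if (any(diff(mixture) <= 0)) stop("mixture variance ladder must be strictly increasing")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot(length(y) == nrow(X))
  if (!is.null(seed)) set.seed(seed)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  comp_var <- mixture * h2 * var(y)
  m <- ncol(X)
  b <- numeric(m); pip <- numeric(m); pi_mean <- numeric(length(mixture))
  for (ch in seq_len(chains)) {
    fit <- bayesr_gibbs_cpp(Xc, yc, comp_var, as.integer(n_iter), as.integer(burn_in))
    b <- b + fit$beta / chains
    pip <- pip + fit$pip / chains
    pi_mean <- pi_mean + fit$pi / chains
  }
  structure(list(effect = b, model = "bayesr", h2 = h2, pip = pip,
                 pi = pi_mean, mixture = mixture,
                 n_iter = n_iter, burn_in = burn_in, chains = chains),
            class = "effect_estimates")
}

#' Total GEBV per animal
#'
#' @param X genotype dosage matrix (animals x SNPs).
#' @param effects an `effect_estimates` object (or a numeric effect vector).
#' @return Numeric vector: `X %*% beta_hat` per animal.
#' @export
total_gebv <- function(X, effects) {
  b <- if (inherits(effects, "effect_estimates")) effects$effect else effects
  drop(as.matrix(X) %*% b)
}

#' Local GEBV variance per window
#'
#' For window `w` and animal `a`, the local GEBV is
#' `g_aw = sum_{j in w} X_aj * beta_hat_j` over the SNPs assigned to the
#' window; the window value is the variance of `g_aw` across animals (n-1
#' denominator) - the window's contribution to genetic variance. The top
#' fraction are flagged as putative QTL windows. Over any non-overlapping
#' window subset the per-animal local GEBVs sum exactly to the total GEBV of
#' the SNPs those windows cover.
#'
#' @param X genotype dosage matrix (animals x SNPs), columns aligned to `map`.
#' @param effects an `effect_estimates` object or numeric effect vector.
#' @param map the [genome_map] the columns of `X` follow.
#' @param grid a `window_grid`.
#' @param top_q flagged fraction (default 0.05).
#' @return Data frame per window: `chrom`, `start`, `end`, `n_snps`, `raw`
#'   (variance), `std`, `flag`; attribute `local_gebv` holds the animals x
#'   windows local-GEBV matrix.
#' @export
window_gebv_variance <- function(X, effects, map, grid, top_q = 0.05) {
  b <- if (inherits(effects, "effect_estimates")) effects$effect else effects
  X <- as.matrix(X)
  stopifnot(ncol(X) == nrow(map), length(b) == ncol(X))
  asg <- assign_points(grid, map$chrom, map$pos)
  G <- matrix(0, nrow(X), nrow(grid))
  v <- rep(NA_real_, nrow(grid))
  for (w in seq_along(asg)) {
    idx <- asg[[w]]
    if (!length(idx)) next
    g <- drop(X[, idx, drop = FALSE] %*% b[idx])
    G[, w] <- g
    v[w] <- var(g)
  }
  std <- tryCatch(standardize_windows(v),
                  error = function(e) rep(NA_real_, length(v)))  # all-zero effects
  out <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                    n_snps = vapply(asg, length, integer(1)),
                    raw = v, std = std, stringsAsFactors = FALSE)
  out$flag <- flag_top_fraction(out$raw, q = top_q)
  attr(out, "local_gebv") <- G
  out
}
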