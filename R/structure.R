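## Population structure: genotype PCA and frequentist admixture by EM.

#' PCA of a genotype matrix
#'
#' Standard genotype principal components: per site, missing dosages are
#' mean-imputed, values centered, and scaled by `sqrt(p (1 - p))` with
#' `p` the site's allele frequency (dosage mean / 2); sites with zero
#' variance are dropped. The eigendecomposition of the sample covariance
#' of the scaled matrix gives per-sample coordinates and per-component
#' explained-variance fractions (non-increasing).
#'
#' @param ge a [GenotypeExperiment-class]; apply [selectStructureSnps()]
#'   first for low-coverage data.
#' @param nComponents number of components to return.
#' @return list with `coords` (samples x components, scaled by the
#'   singular values), `varExplained` (fractions), and `nSitesUsed`.
#' @export
pcaGenotypes <- function(ge, nComponents = 4) {
  g <- dosage(ge)
  p <- rowMeans(g, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  g <- g[keep, , drop = FALSE]
  p <- p[keep]
  mu <- 2 * p
  x <- (g - mu) / sqrt(2 * p * (1 - p))
  x[is.na(x)] <- 0                       # mean imputation after centering
  v <- apply(x, 1, var)
  x <- x[v > 0, , drop = FALSE]
  cv <- crossprod(x) / nrow(x)           # samples x samples
  eig <- eigen(cv, symmetric = TRUE)
  k <- min(nComponents, ncol(cv) - 1)
  ev <- pmax(eig$values, 0)
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  rownames(coords) <- colnames(ge)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords,
       varExplained = ev[seq_len(k)] / sum(ev),
       nSitesUsed = nrow(x))
}

## One EM run from a given starting point; returns fit components.
.admixtureEmRun <- function(G, K, maxIter, tol, Q, F) {
  M <- !is.na(G)
  G0 <- G; G0[!M] <- 0
  G2 <- 2 - G; G2[!M] <- 0
  Ji <- rowSums(M)
  eps <- 1e-9
  loglik <- numeric(0)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    P <- Q %*% F
    P <- pmin(pmax(P, eps), 1 - eps)
    llNew <- sum(G0 * log(P) + G2 * log1p(-P))
    loglik <- c(loglik, llNew)
    if (it > 1 && (llNew - ll) < tol * abs(ll)) {
      ll <- llNew
      return(list(Q = Q, F = F, loglik = loglik, iterations = it,
                  converged = TRUE))
    }
    ll <- llNew
    A <- G0 / P                      # N x J, zero where missing
    B <- G2 / (1 - P)
    QtA <- crossprod(Q, A)           # K x J
    QtB <- crossprod(Q, B)
    Fnew <- (F * QtA) / (F * QtA + (1 - F) * QtB + eps)
    Snum <- A %*% t(F) + B %*% t(1 - F)   # N x K
    Qnew <- Q * Snum / (2 * Ji)
    Qnew <- Qnew / rowSums(Qnew)
    Q <- Qnew
    F <- pmin(pmax(Fnew, eps), 1 - eps)
  }
  list(Q = Q, F = F, loglik = loglik, iterations = maxIter,
       converged = FALSE)
}

#' Frequentist admixture estimation by EM
#'
#' Maximizes the binomial admixture composite log-likelihood
#' `sum_ij [ g_ij log(sum_k q_ik f_kj) + (2 - g_ij) log(sum_k q_ik (1 - f_kj)) ]`
#' over ancestry proportions `Q` (rows on the simplex) and ancestral
#' allele frequencies `F` by expectation-maximization; missing genotypes
#' are skipped. The log-likelihood is non-decreasing at every iteration.
#' Several random starts are run and the best final likelihood kept;
#' iteration stops at `maxIter` or when the relative log-likelihood
#' change drops below `tol`.
#'
#' For `K = 1` the optimum is analytic: `Q` is a column of ones and
#' `f_1j` is the mean dosage at site j divided by 2.
#'
#' @param ge a [GenotypeExperiment-class] (or a sites-by-samples dosage
#'   matrix in the layout of the `dosage` assay).
#' @param K number of ancestral populations (`1 <= K <=` sample count).
#' @param maxIter maximum EM iterations (default 10000).
#' @param tol relative log-likelihood convergence tolerance.
#' @param nStarts number of random restarts.
#' @param seed integer seed for the starts.
#' @return an [AdmixtureFit-class].
#' @export
admixtureEM <- function(ge, K, maxIter = 10000, tol = 1e-6, nStarts = 5,
                        seed = 1) {
  G <- t(if (is(ge, "GenotypeExperiment")) dosage(ge) else as.matrix(ge))
  N <- nrow(G); J <- ncol(G)
  if (K > N) stop("K must not exceed the number of samples")
  if (K == 1) {
    f <- colMeans(G, na.rm = TRUE) / 2
    Q <- matrix(1, N, 1)
    F <- matrix(pmin(pmax(f, 1e-9), 1 - 1e-9), 1, J)
    M <- !is.na(G); G0 <- G; G0[!M] <- 0; G2 <- 2 - G; G2[!M] <- 0
    P <- Q %*% F
    ll <- sum(G0 * log(P) + G2 * log1p(-P))
    return(new("AdmixtureFit", Q = Q, F = matrix(f, 1, J), loglik = ll,
               iterations = 1L, converged = TRUE))
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(nStarts)) {
    Q0 <- matrix(stats::rgamma(N * K, 1), N, K)
    Q0 <- Q0 / rowSums(Q0)
    F0 <- matrix(runif(K * J, 0.05, 0.95), K, J)
    fit <- .admixtureEmRun(G, K, maxIter, tol, Q0, F0)
    if (is.null(best) || tail(fit$loglik, 1) > tail(best$loglik, 1))
      best <- fit
  }
  rownames(best$Q) <- rownames(G)
  new("AdmixtureFit", Q = best$Q, F = best$F, loglik = best$loglik,
      iterations = as.integer(best$iterations),
      converged = best$converged)
}

#' Align admixture components to a reference by greedy matching
#'
#' Resolves label switching: permutes the columns of an estimated `Q` to
#' best match a reference `Q` (greedy minimal column-wise absolute
#' error).
#'
#' @param Q estimated ancestry matrix.
#' @param Qref reference ancestry matrix of the same shape.
#' @return the column-permuted `Q`.
#' @export
alignAncestry <- function(Q, Qref) {
  K <- ncol(Q)
  stopifnot(ncol(Qref) == K)
  perm <- integer(K)
  free <- seq_len(K)
  for (k in seq_len(K)) {
    errs <- vapply(free, function(j) mean(abs(Q[, j] - Qref[, k])),
                   numeric(1))
    perm[k] <- free[which.min(errs)]
    free <- setdiff(free, perm[k])
  }
  Q[, perm, drop = FALSE]
}
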