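# models: the two fitted models — the logistic model of SRE overlap on
# per-SNP features, and the two-variance-component mixed model partitioning
# trait variance into SRE and non-SRE SNP contributions (GREML).

#' Logistic model of SRE overlap
#'
#' Fits p_i = 1 / (1 + exp(-(b0 + b . Delta))) by iteratively reweighted least
#' squares, where Delta are per-SNP features (typically derived allele
#' frequency, F_ST, B-value and LD extent). Features are z-scored internally
#' for conditioning; coefficients, standard errors and Wald tests are reported
#' on the original scale. The intercept captures the genome-wide (global)
#' effect, the feature coefficients locus-specific effects.
#'
#' @param overlap binary response (0/1 or logical): SRE membership per SNP.
#' @param features numeric matrix or data.frame of per-SNP features (columns
#'   named).
#' @param max_iter IRLS iteration cap (default 100).
#' @param tol convergence tolerance on max |delta beta| (default 1e-8).
#' @return object of class `sre_logistic`: coefficients, se, z, p (Wald),
#'   vcov, converged, n, n_iter, fitted.
#' @export
fit_sre_logistic <- function(overlap, features, max_iter = 100L, tol = 1e-8) {
  y <- as.numeric(overlap)
  stopifnot(all(y %in% c(0, 1)))
  X0 <- as.matrix(features)
  if (is.null(colnames(X0))) colnames(X0) <- paste0("x", seq_len(ncol(X0)))
  ok <- complete.cases(X0) & !is.na(y)
  y <- y[ok]; X0 <- X0[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X0)
  if (n < 10L * (p + 1L)) {
    warning("fewer than 10 observations per parameter; estimates may be unstable")
  }
  mu_x <- colMeans(X0); sd_x <- apply(X0, 2L, sd)
  if (any(sd_x == 0)) {
    stop_sre(paste("constant feature column(s):",
                   paste(colnames(X0)[sd_x == 0], collapse = ", ")),
             "sre_config_error")
  }
  Z <- cbind(`(Intercept)` = 1, sweep(sweep(X0, 2L, mu_x), 2L, sd_x, "/"))
  if (qr(Z)$rank < ncol(Z)) {
    stop_sre("rank-deficient design (collinear features)", "sre_config_error")
  }
  beta <- rep(0, p + 1L)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-12)) w <- pmax(w, 1e-12)
    # weighted least squares step on the working response
    zw <- eta + (y - mu) / w
    WZ <- Z * w
    XtWX <- crossprod(Z, WZ)
    beta_new <- solve(XtWX, crossprod(WZ, zw))
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  mu <- plogis(drop(Z %*% beta))
  if (max(abs(beta[-1L])) > 30) {
    j <- which.max(abs(beta[-1L]))
    stop_sre(paste("apparent perfect separation on feature", colnames(X0)[j]),
             "sre_separation_error")
  }
  if (!converged) {
    return(structure(list(converged = FALSE, n = n, n_iter = iter),
                     class = "sre_logistic"))
  }
  w <- pmax(mu * (1 - mu), 1e-12)
  vcov_z <- solve(crossprod(Z, Z * w))
  # back-transform: beta_j = beta_zj / sd_j ; beta_0 = beta_z0 - sum beta_zj mu_j/sd_j
  Tm <- diag(p + 1L)
  Tm[1L, -1L] <- -mu_x / sd_x
  Tm[cbind(2:(p + 1L), 2:(p + 1L))] <- 1 / sd_x
  coef <- drop(Tm %*% beta)
  vc <- Tm %*% vcov_z %*% t(Tm)
  se <- sqrt(diag(vc))
  z <- coef / se
  names(coef) <- names(se) <- names(z) <- c("(Intercept)", colnames(X0))
  structure(list(
    coefficients = coef, se = se, z = z, p = 2 * pnorm(-abs(z)),
    vcov = vc, converged = TRUE, n = n, n_iter = iter, fitted = mu
  ), class = "sre_logistic")
}

#' @export
print.sre_logistic <- function(x, ...) {
  if (!x$converged) {
    cat("<sre_logistic> IRLS did not converge; no estimates reported\n")
    return(invisible(x))
  }
  cat(sprintf("<sre_logistic> n = %d, converged in %d iterations\n", x$n, x$n_iter))
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$z, p = x$p))
  invisible(x)
}

#' Genetic relatedness matrix from genotype dosages
#'
#' A = (1/m) sum_k (g_k - 2 p_k)(g_k - 2 p_k)' / (2 p_k (1 - p_k)), the
#' standard normalized GRM. Monomorphic SNPs are excluded (count reported as
#' an attribute).
#'
#' @param G n_individuals x m_snps dosage matrix, entries in \{0,1,2\}.
#' @return n x n symmetric matrix with attribute `n_excluded`.
#' @export
compute_grm <- function(G) {
  G <- as.matrix(G)
  p <- colMeans(G) / 2
  keep <- p > 0 & p < 1
  n_excluded <- sum(!keep)
  if (n_excluded > 0L) {
    message(sprintf("compute_grm: excluded %d monomorphic SNPs", n_excluded))
  }
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  Zs <- sweep(sweep(G, 2L, 2 * p), 2L, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(Zs) / ncol(G)
  attr(A, "n_excluded") <- n_excluded
  A
}

#' Two-variance-component GREML (average-information REML)
#'
#' Fits y = X b + g_SRE + g_nonSRE + e with var(y) = A_SRE s2_1 +
#' A_nonSRE s2_2 + I s2_e by AI-REML with EM fallback steps when an AI update
#' would decrease the restricted likelihood or leave the parameter space.
#' Components are constrained non-negative (projected to a small floor at the
#' boundary). The SRE heritability is s2_1 / (s2_1 + s2_2 + s2_e) with a
#' delta-method standard error from the inverse AI matrix.
#'
#' @param y phenotype vector (length n).
#' @param X fixed-effect design matrix (default intercept only).
#' @param A_sre,A_nonsre n x n genetic relatedness matrices.
#' @param max_iter iteration cap (default 200).
#' @param tol convergence tolerance on the change in restricted log-likelihood.
#' @return object of class `sre_greml`: varcomp (s2_sre, s2_nonsre, s2_e),
#'   h2_sre, h2_se, logLik, n_iter, converged.
#' @export
reml_two_vc <- function(y, A_sre, A_nonsre, X = NULL, max_iter = 200L,
                        tol = 1e-6) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  if (n < 200L) warning("n < 200: variance-component estimates may be unstable")
  K <- list(A_sre, A_nonsre, diag(n))
  # non-identifiability guard: identical (up to scale) relatedness structures
  if (sqrt(sum((A_sre - A_nonsre)^2)) / n < 1e-10) {
    stop_sre("A_SRE and A_nonSRE are numerically identical: components not identifiable",
             "sre_config_error")
  }
  vp <- var(y)
  sig <- rep(vp / 3, 3L)
  floor_v <- vp * 1e-8

  loglik <- function(sig) {
    V <- sig[1L] * K[[1L]] + sig[2L] * K[[2L]] + sig[3L] * K[[3L]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    Vi <- chol2inv(ch)
    XtViX <- crossprod(X, Vi %*% X)
    ch2 <- chol(XtViX)
    B <- Vi %*% X %*% chol2inv(ch2) %*% crossprod(X, Vi)
    P <- Vi - B
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) +
                    drop(crossprod(y, Py)))
    list(ll = ll, P = P, Py = Py)
  }

  st <- loglik(sig)
  ll_old <- st$ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    P <- st$P; Py <- st$Py
    KPy <- lapply(K, function(Kk) Kk %*% Py)
    score <- vapply(seq_len(3L), function(k)
      -0.5 * (sum(P * K[[k]]) - drop(crossprod(Py, KPy[[k]]))), numeric(1L))
    AI <- matrix(0, 3L, 3L)
    PKPy <- lapply(KPy, function(v) P %*% v)
    for (a in 1:3) for (b in a:3) {
      AI[a, b] <- AI[b, a] <- 0.5 * drop(crossprod(KPy[[a]], PKPy[[b]]))
    }
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    sig_new <- if (!is.null(step)) pmax(sig + step, floor_v) else NULL
    st_new <- if (!is.null(sig_new)) loglik(sig_new) else list(ll = -Inf)
    if (st_new$ll < ll_old - 1e-10) {
      # EM fallback step (always increases the restricted likelihood)
      sig_new <- vapply(seq_len(3L), function(k)
        max(floor_v,
            sig[k] + sig[k]^2 *
              (drop(crossprod(Py, KPy[[k]])) - sum(P * K[[k]])) / n),
        numeric(1L))
      st_new <- loglik(sig_new)
    }
    dll <- st_new$ll - ll_old
    sig <- sig_new
    st <- st_new
    ll_old <- st_new$ll
    if (abs(dll) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    return(structure(list(converged = FALSE, n_iter = iter),
                     class = "sre_greml"))
  }
  # SE of h2 by delta method from the inverse AI at the optimum
  P <- st$P; Py <- st$Py
  KPy <- lapply(K, function(Kk) Kk %*% Py)
  PKPy <- lapply(KPy, function(v) P %*% v)
  AI <- matrix(0, 3L, 3L)
  for (a in 1:3) for (b in a:3) {
    AI[a, b] <- AI[b, a] <- 0.5 * drop(crossprod(KPy[[a]], PKPy[[b]]))
  }
  Sv <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 3L, 3L))
  S <- sum(sig)
  grad <- c(S - sig[1L], -sig[1L], -sig[1L]) / S^2
  h2_se <- sqrt(drop(t(grad) %*% Sv %*% grad))
  structure(list(
    varcomp = c(s2_sre = sig[1L], s2_nonsre = sig[2L], s2_e = sig[3L]),
    h2_sre = sig[1L] / S, h2_se = h2_se, logLik = ll_old,
    n_iter = iter, converged = TRUE
  ), class = "sre_greml")
}

#' @export
print.sre_greml <- function(x, ...) {
  if (!x$converged) {
    cat("<sre_greml> REML did not converge; estimates withheld\n")
    return(invisible(x))
  }
  cat(sprintf("<sre_greml> converged in %d iterations, logLik = %.3f\n",
              x$n_iter, x$logLik))
  print(round(x$varcomp, 4))
  cat(sprintf("h2_SRE = %.4f (SE %.4f)\n", x$h2_sre, x$h2_se))
  invisible(x)
}

#' Simulate genotypes and a phenotype under the two-component model
#'
#' Utility for calibration tests: unrelated individuals with binomial
#' genotypes, SRE and non-SRE SNP sets, and y = g_SRE + g_nonSRE + e with the
#' requested variance components.
#'
#' @param n individuals; @param m_sre,m_nonsre SNP counts per component.
#' @param s2_sre,s2_nonsre,s2_e generating variance components.
#' @param seed RNG seed.
#' @return list: y, G_sre, G_nonsre, A_sre, A_nonsre.
#' @export
simulate_greml <- function(n, m_sre, m_nonsre, s2_sre, s2_nonsre, s2_e, seed = 1L) {
  set.seed(seed)
  simG <- function(m) {
    p <- runif(m, 0.05, 0.95)
    matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  }
  G1 <- simG(m_sre); G2 <- simG(m_nonsre)
  A1 <- compute_grm(G1); A2 <- compute_grm(G2)
  std <- function(G) {
    p <- colMeans(G) / 2
    keep <- p > 0 & p < 1
    sweep(sweep(G[, keep, drop = FALSE], 2L, 2 * p[keep]), 2L,
          sqrt(2 * p[keep] * (1 - p[keep])), "/")
  }
  Z1 <- std(G1); Z2 <- std(G2)
  g1 <- drop(Z1 %*% rnorm(ncol(Z1), 0, sqrt(s2_sre / ncol(Z1))))
  g2 <- drop(Z2 %*% rnorm(ncol(Z2), 0, sqrt(s2_nonsre / ncol(Z2))))
  y <- g1 + g2 + rnorm(n, 0, sqrt(s2_e))
  list(y = y, G_sre = G1, G_nonsre = G2, A_sre = A1, A_nonsre = A2)
}
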