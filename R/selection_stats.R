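# selection_stats: per-variant cross-population differentiation and selection
# statistics.
#
# F_ST is the Weir-Cockerham (1984) two-population per-locus estimator
# computed from haplotype (haploid) counts, heterozygosity component zero
# under the haploid convention. iHS follows the orientation with the
# ancestral-allele integral in the numerator: extended homozygosity on the
# derived background yields negative raw iHS. EHH curves stop at EHH < 0.05
# or the chromosome end; integrals use the trapezoid rule on genetic distance.

#' Weir-Cockerham per-locus F_ST from haploid allele counts
#'
#' @param n1,n2 haplotypes sampled in each population (>= 2).
#' @param x1,x2 ALT allele counts.
#' @return list with `theta` (per-locus estimate, may be negative, NA when the
#'   locus is monomorphic in both populations or a sample is too small, with a
#'   `reason` attribute), and the variance components `a` and `b` (so loci can
#'   be combined with [wc_fst_multilocus()]). Vectorized over loci.
#' @export
wc_fst <- function(n1, x1, n2, x2) {
  r <- 2
  p1 <- x1 / n1; p2 <- x2 / n2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  theta <- a / (a + b)
  bad_n <- n1 < 2 | n2 < 2
  mono <- pbar == 0 | pbar == 1
  theta[bad_n | mono] <- NA_real_
  a[bad_n | mono] <- NA_real_
  b[bad_n | mono] <- NA_real_
  reason <- rep(NA_character_, length(theta))
  reason[mono] <- "monomorphic"
  reason[bad_n] <- "sample_too_small"
  list(theta = theta, a = a, b = b, reason = reason)
}

#' Multi-locus Weir-Cockerham F_ST (ratio of summed variance components)
#'
#' Combines per-locus components as theta = sum(a) / sum(a + b); this is the
#' estimator's own multi-locus form and, unlike the arithmetic mean of
#' per-locus ratios, is unbiased for the Balding-Nichols divergence parameter.
#'
#' @param fst result of [wc_fst()] over many loci.
#' @return single F_ST estimate.
#' @export
wc_fst_multilocus <- function(fst) {
  ok <- !is.na(fst$a)
  sum(fst$a[ok]) / sum(fst$a[ok] + fst$b[ok])
}

#' Derived allele frequency per population
#'
#' @param panel a [haplotype_panel()] (entries 1 = ALT).
#' @param site site index.
#' @param ref,alt,ancestral alleles; ancestral must equal ref or alt, else NA
#'   is returned.
#' @return derived (non-ancestral) allele frequency in \[0,1\], or NA.
#' @export
derived_allele_freq <- function(panel, site, ref, alt, ancestral) {
  p_alt <- mean(panel$H[, site])
  if (is.na(ancestral)) return(NA_real_)
  if (ancestral == ref) p_alt
  else if (ancestral == alt) 1 - p_alt
  else NA_real_
}

#' Extended haplotype homozygosity curve from a core site
#'
#' EHH at distance d is the probability that two random distinct haplotypes
#' carrying `core_allele` at the core are identical over all sites between the
#' core and d. Computed site by site outward until EHH < 0.05 or the
#' chromosome end; EHH(0) = 1 and the curve is non-increasing.
#'
#' @param panel a [haplotype_panel()].
#' @param core_site column index of the core.
#' @param core_allele 0 or 1.
#' @param direction "left" or "right".
#' @param ehh_floor stopping threshold (default 0.05).
#' @return data.table with columns `dist_cM` (genetic distance from the core,
#'   starting at 0) and `ehh`; attribute `truncated` is TRUE when the curve
#'   hit the chromosome end before dropping below the floor. NULL when fewer
#'   than two haplotypes carry the core allele.
#' @export
ehh_curve <- function(panel, core_site, core_allele, direction = c("right", "left"),
                      ehh_floor = 0.05) {
  direction <- match.arg(direction)
  carriers <- panel$H[, core_site] == core_allele
  n <- sum(carriers)
  if (n < 2L) return(NULL)
  H <- panel$H[carriers, , drop = FALSE]
  m <- ncol(H)
  idx <- if (direction == "right") {
    if (core_site == m) integer(0) else (core_site + 1L):m
  } else {
    if (core_site == 1L) integer(0) else (core_site - 1L):1L
  }
  denom <- n * (n - 1)
  grp <- rep(1L, n)                      # haplotype grouping by shared prefix
  dist <- 0
  out_d <- 0; out_e <- 1
  truncated <- TRUE
  for (j in idx) {
    grp <- as.integer(factor(paste(grp, H[, j])))
    cnt <- tabulate(grp)
    ehh <- sum(cnt * (cnt - 1)) / denom
    d <- abs(panel$pos_cM[j] - panel$pos_cM[core_site])
    out_d <- c(out_d, d); out_e <- c(out_e, ehh)
    if (ehh < ehh_floor) { truncated <- FALSE; break }
  }
  res <- data.table(dist_cM = out_d, ehh = out_e)
  attr(res, "truncated") <- truncated
  res
}

# Trapezoid integral of an EHH curve over genetic distance.
.ehh_integral <- function(curve) {
  if (is.null(curve) || nrow(curve) < 2L) return(0)
  x <- curve$dist_cM; y <- curve$ehh
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# Both-direction integrated EHH for one allele at a site.
.ihh <- function(panel, site, allele, ehh_floor = 0.05) {
  l <- ehh_curve(panel, site, allele, "left", ehh_floor)
  r <- ehh_curve(panel, site, allele, "right", ehh_floor)
  if (is.null(l) || is.null(r)) return(NA_real_)
  .ehh_integral(l) + .ehh_integral(r)
}

#' Raw integrated haplotype score (iHS) at a site
#'
#' log of the ratio of the integrated EHH on the ancestral background to that
#' on the derived background. Undefined (NA with reason) when either allele
#' has fewer than two carriers, the ancestral state is unknown, or an integral
#' is zero.
#'
#' @param panel a [haplotype_panel()] (1 = ALT).
#' @param site site index.
#' @param ref,alt,ancestral alleles.
#' @param ehh_floor EHH stopping threshold.
#' @return raw iHS (numeric, possibly NA with attribute `reason`).
#' @export
ihs <- function(panel, site, ref, alt, ancestral, ehh_floor = 0.05) {
  na_with <- function(reason) structure(NA_real_, reason = reason)
  if (is.na(ancestral) || !ancestral %in% c(ref, alt)) {
    return(na_with("ancestral_unknown"))
  }
  anc_code <- if (ancestral == ref) 0L else 1L
  der_code <- 1L - anc_code
  if (sum(panel$H[, site] == anc_code) < 2L ||
      sum(panel$H[, site] == der_code) < 2L) {
    return(na_with("too_few_carriers"))
  }
  ia <- .ihh(panel, site, anc_code, ehh_floor)
  id <- .ihh(panel, site, der_code, ehh_floor)
  if (is.na(ia) || is.na(id) || ia == 0 || id == 0) return(na_with("zero_integral"))
  log(ia / id)
}

#' Raw cross-population EHH score (XP-EHH) at a site
#'
#' log of the ratio of the integrated EHH in population 1 to that in
#' population 2 for a designated allele (default the derived allele; falls
#' back to ALT when the ancestral state is unknown). Positive values indicate
#' longer haplotypes (a sweep signal) in population 1.
#'
#' @param panel_P1,panel_P2 [haplotype_panel()] objects over the same sites.
#' @param site site index.
#' @param ref,alt,ancestral alleles (optional; used to designate the derived
#'   allele).
#' @param ehh_floor EHH stopping threshold.
#' @return raw XP-EHH (numeric, possibly NA with attribute `reason`).
#' @export
xp_ehh <- function(panel_P1, panel_P2, site, ref = NULL, alt = NULL,
                   ancestral = NA, ehh_floor = 0.05) {
  na_with <- function(reason) structure(NA_real_, reason = reason)
  allele <- if (!is.na(ancestral) && !is.null(ref) && ancestral == alt) 0L else 1L
  if (sum(panel_P1$H[, site] == allele) +
      sum(panel_P2$H[, site] == allele) == 0L) {
    return(na_with("allele_absent"))
  }
  i1 <- .ihh(panel_P1, site, allele, ehh_floor)
  i2 <- .ihh(panel_P2, site, allele, ehh_floor)
  if (is.na(i1) || is.na(i2)) return(na_with("too_few_carriers"))
  if (i2 == 0 || i1 == 0) return(na_with("zero_integral"))
  log(i1 / i2)
}

#' Standardize raw scores to mean 0, variance 1 within bins
#'
#' Bins with fewer than `min_per_bin` defined scores are merged with their
#' left neighbor (the first bin merges right). With a single global bin this
#' is plain z-scoring.
#'
#' @param raw numeric scores (NA allowed).
#' @param bin_variable values binned to define standardization strata (e.g.
#'   DAF for iHS); NULL for a single global bin.
#' @param bin_width width of the bins (default 0.05).
#' @param min_per_bin minimum defined scores per bin (default 20).
#' @return list: `std` (standardized scores), `bin` (bin id per score).
#' @export
standardize_scores <- function(raw, bin_variable = NULL, bin_width = 0.05,
                               min_per_bin = 20L) {
  n <- length(raw)
  if (is.null(bin_variable)) {
    bin <- rep(1L, n)
  } else {
    stopifnot(length(bin_variable) == n)
    bin <- as.integer(floor(pmin(bin_variable, 1 - 1e-12) / bin_width)) + 1L
    bin[is.na(bin_variable)] <- NA_integer_
    # merge sparse bins leftward
    repeat {
      cnt <- table(bin[!is.na(raw) & !is.na(bin)])
      small <- names(cnt)[cnt < min_per_bin]
      if (!length(small) || length(cnt) <= 1L) break
      b <- as.integer(small[1L])
      others <- as.integer(names(cnt))[as.integer(names(cnt)) != b]
      tgt <- if (any(others < b)) max(others[others < b]) else min(others[others > b])
      bin[bin == b & !is.na(bin)] <- tgt
    }
  }
  std <- rep(NA_real_, n)
  for (b in unique(bin[!is.na(bin)])) {
    i <- which(bin == b & !is.na(raw))
    if (length(i) < 2L) next
    s <- sd(raw[i])
    if (s == 0) next  # all-constant bin: undefined
    std[i] <- (raw[i] - mean(raw[i])) / s
  }
  list(std = std, bin = bin)
}

#' Calibrate the drift scale omega from putatively neutral SNPs
#'
#' Method-of-moments: the mean over SNPs of (p2 - p1)^2 / (pbar (1 - pbar)),
#' minus the binomial sampling contribution 1/n1 + 1/n2; floored at 1e-6.
#'
#' @param panel_P1,panel_P2 [haplotype_panel()] objects over the same sites.
#' @return omega estimate (> 0).
#' @export
calibrate_omega <- function(panel_P1, panel_P2) {
  p1 <- colMeans(panel_P1$H); p2 <- colMeans(panel_P2$H)
  n1 <- nrow(panel_P1$H); n2 <- nrow(panel_P2$H)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  ok <- pbar > 0 & pbar < 1
  w <- mean((p2[ok] - p1[ok])^2 / (pbar[ok] * (1 - pbar[ok]))) - (1 / n1 + 1 / n2)
  if (w <= 0) {
    warning("calibrate_omega: non-positive estimate, flooring at 1e-6")
    w <- 1e-6
  }
  w
}

# Truncated-normal log-density of x on [0,1] with mean mu, variance v.
.log_dtnorm01 <- function(x, mu, v) {
  s <- sqrt(v)
  z <- pnorm((1 - mu) / s) - pnorm((0 - mu) / s)
  dnorm(x, mu, s, log = TRUE) - log(z)
}

#' XP-CLR-style composite likelihood ratio over sliding windows
#'
#' At each grid point, the null likelihood of the observed P2 frequencies at
#' the k SNPs in the window is the truncated-normal Wiener drift model
#' N(p0, omega pbar (1 - pbar)) on \[0,1\], with p0 the P1 sample frequency;
#' the variance scale uses the pooled frequency pbar so that sites monomorphic
#' in the reference but polymorphic in the test population do not collapse the
#' modeled variance. The alternative shifts each SNP's expected frequency
#' toward fixation by a sweep effect s decayed with genetic distance from the
#' grid point, exp(-d/delta), with the shift direction free per SNP (a swept
#' haplotype drags linked alleles toward whichever allele it carries) but s
#' and delta shared across the window, maximized over a fixed grid.
#' CLR = 2 (max log alt - log null) >= 0.
#'
#' @param panel_P1,panel_P2 [haplotype_panel()] objects over the same sites;
#'   P1 is the neutral reference, P2 the tested population.
#' @param omega drift scale, e.g. from [calibrate_omega()].
#' @param k SNPs per window (default 50).
#' @param step grid spacing in SNPs (default 10).
#' @param s_grid sweep-effect grid (must contain 0).
#' @param delta_grid decay-scale grid in cM.
#' @return data.table: window_center (site index), clr; per-variant scores via
#'   [xpclr_per_site()].
#' @export
xpclr <- function(panel_P1, panel_P2, omega, k = 50L, step = 10L,
                  s_grid = seq(0, 0.5, by = 0.05), delta_grid = c(0.01, 0.1, 1)) {
  stopifnot(0 %in% s_grid)
  p1 <- colMeans(panel_P1$H); p2 <- colMeans(panel_P2$H)
  n1 <- nrow(panel_P1$H); n2 <- nrow(panel_P2$H)
  m <- length(p1)
  if (m < k) stop_sre("fewer SNPs than window size", "sre_config_error")
  # monomorphic frequencies nudged off the boundary to keep densities finite
  x_all <- pmin(pmax(p2, 1 / (2 * n2)), 1 - 1 / (2 * n2))
  p0_all <- pmin(pmax(p1, 1 / (2 * n1)), 1 - 1 / (2 * n1))
  pbar_all <- (n1 * p0_all + n2 * x_all) / (n1 + n2)
  poly <- p1 > 0 & p1 < 1 | p2 > 0 & p2 < 1

  centers <- seq(ceiling(k / 2), m - floor(k / 2), by = step)
  clr <- numeric(length(centers))
  for (ci in seq_along(centers)) {
    cen <- centers[ci]
    win <- (cen - ceiling(k / 2) + 1L):(cen - ceiling(k / 2) + k)
    win <- win[poly[win]]
    if (length(win) == 0L) { clr[ci] <- 0; next }
    mu0 <- p0_all[win]
    v <- omega * pbar_all[win] * (1 - pbar_all[win])
    x <- x_all[win]
    ll_null <- sum(.log_dtnorm01(x, mu0, v))
    d <- abs(panel_P1$pos_cM[win] - panel_P1$pos_cM[cen])
    best <- ll_null
    for (delta in delta_grid) {
      decay <- exp(-d / delta)
      for (s in s_grid[s_grid > 0]) {
        up <- .log_dtnorm01(x, pmin(mu0 + s * decay * (1 - mu0), 1 - 1e-9), v)
        dn <- .log_dtnorm01(x, pmax(mu0 - s * decay * mu0, 1e-9), v)
        best <- max(best, sum(pmax(up, dn)))
      }
    }
    clr[ci] <- 2 * (best - ll_null)
  }
  data.table(window_center = centers, clr = clr)
}

#' Per-variant XP-CLR score: maximum over covering windows
#'
#' @param clr_table output of [xpclr()].
#' @param m number of sites.
#' @param k window size used.
#' @return numeric vector of length m (NA where no window covers the site).
#' @export
xpclr_per_site <- function(clr_table, m, k = 50L) {
  out <- rep(NA_real_, m)
  half <- floor(k / 2)
  for (i in seq_len(nrow(clr_table))) {
    cen <- clr_table$window_center[i]
    lo <- max(1L, cen - half); hi <- min(m, cen + half)
    idx <- lo:hi
    out[idx] <- pmax(out[idx], clr_table$clr[i], na.rm = TRUE)
  }
  out
}

#' Composite likelihood over cross-population metrics
#'
#' L(x) = f_FST(x)^alpha * f_XPEHH(x)^beta * f_XPCLR(x)^gamma with the
#' component densities estimated from the panel-wide empirical distributions
#' (histogram with `bins` bins and add-one smoothing). Reported as log L.
#'
#' @param fst,xpehh,xpclr_scores per-variant metric vectors.
#' @param alpha,beta,gamma exponents (defaults 1).
#' @param bins histogram bins (default 50).
#' @return list: `logL` per variant (NA when any component is undefined),
#'   and the three density functions.
#' @export
composite_likelihood <- function(fst, xpehh, xpclr_scores,
                                 alpha = 1, beta = 1, gamma = 1, bins = 50L) {
  dens <- function(x) {
    ok <- !is.na(x)
    rng <- range(x[ok])
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1L], rng[2L], length.out = bins + 1L)
    cnt <- tabulate(findInterval(x[ok], edges, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = bins)
    p <- (cnt + 1) / (sum(cnt) + bins)       # add-one smoothing
    width <- diff(edges)[1L]
    function(q) {
      i <- findInterval(q, edges, rightmost.closed = TRUE, all.inside = TRUE)
      out <- p[i] / width
      out[is.na(q)] <- NA_real_
      out
    }
  }
  f_fst <- dens(fst); f_xpehh <- dens(xpehh); f_xpclr <- dens(xpclr_scores)
  logL <- alpha * log(f_fst(fst)) + beta * log(f_xpehh(xpehh)) +
    gamma * log(f_xpclr(xpclr_scores))
  list(logL = logL, f_fst = f_fst, f_xpehh = f_xpehh, f_xpclr = f_xpclr)
}

#' Run the full per-variant selection scan on a two-population fixture
#'
#' Convenience wrapper: per-SNP Weir-Cockerham F_ST, per-population DAF, raw
#' and standardized iHS (DAF bins of width 0.05) and XP-EHH (single global
#' bin), windowed XP-CLR with method-of-moments omega, and the log composite
#' likelihood.
#'
#' @param panels named list of two [haplotype_panel()] objects.
#' @param variants data.table with variant_id, ref, alt and (optionally)
#'   merged `ancestral`.
#' @param k,step XP-CLR window parameters.
#' @return data.table of per-variant scores with reason codes.
#' @export
selection_scan <- function(panels, variants, k = 50L, step = 10L) {
  stopifnot(length(panels) == 2L)
  P1 <- panels[[1L]]; P2 <- panels[[2L]]
  m <- ncol(P1$H)
  x1 <- colSums(P1$H); x2 <- colSums(P2$H)
  fst <- wc_fst(nrow(P1$H), x1, nrow(P2$H), x2)
  anc <- if ("ancestral" %in% names(variants)) variants$ancestral
         else rep(NA_character_, m)
  daf1 <- daf2 <- ihs_raw <- xpehh_raw <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    daf1[i] <- derived_allele_freq(P1, i, variants$ref[i], variants$alt[i], anc[i])
    daf2[i] <- derived_allele_freq(P2, i, variants$ref[i], variants$alt[i], anc[i])
    ihs_raw[i] <- ihs(P1, i, variants$ref[i], variants$alt[i], anc[i])
    xpehh_raw[i] <- xp_ehh(P1, P2, i, variants$ref[i], variants$alt[i], anc[i])
  }
  ihs_std <- standardize_scores(ihs_raw, daf1, bin_width = 0.05)$std
  xpehh_std <- standardize_scores(xpehh_raw)$std
  omega <- calibrate_omega(P1, P2)
  # XP-CLR tests the focal population (first panel) against the second as the
  # neutral reference, matching XP-EHH's sign convention (positive = sweep in P1)
  clr_t <- xpclr(P2, P1, omega, k = k, step = step)
  clr_site <- xpclr_per_site(clr_t, m, k = k)
  comp <- composite_likelihood(fst$theta, xpehh_std, clr_site)
  data.table(
    variant_id = variants$variant_id, fst = fst$theta, fst_reason = fst$reason,
    daf_P1 = daf1, daf_P2 = daf2, ihs_raw = ihs_raw, ihs_std = ihs_std,
    xpehh_raw = xpehh_raw, xpehh_std = xpehh_std, xpclr = clr_site,
    log_composite = comp$logL
  )
}
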