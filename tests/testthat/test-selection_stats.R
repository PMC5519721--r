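# Independent oracle for the two-population haploid Weir-Cockerham estimator,
# written in the ANOVA (mean-squares) form rather than the a/b components:
# theta = (MSP - MSG) / (MSP + (nc - 1) MSG).
wc_oracle <- function(n1, x1, n2, x2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  MSP <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / 1
  MSG <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 - 1 + n2 - 1)
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  (MSP - MSG) / (MSP + (nc - 1) * MSG)
}

test_that("Weir-Cockerham F_ST matches its definition and oracle", {
  # reciprocal fixation: complete differentiation
  expect_equal(wc_fst(100, 100, 100, 0)$theta, 1)
  # identical counts: estimator is <= 0 in finite samples
  expect_lte(wc_fst(20, 10, 20, 10)$theta, 0)
  # the spec's concrete instance against the independent ANOVA-form oracle
  expect_equal(wc_fst(20, 15, 20, 5)$theta, wc_oracle(20, 15, 20, 5),
               tolerance = 1e-12)
  # 100 random instances, unequal sample sizes, machine precision
  set.seed(41)
  for (i in 1:100) {
    n1 <- sample(4:200, 1); n2 <- sample(4:200, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    if (x1 == 0 && x2 == 0) x1 <- 1
    if (x1 == n1 && x2 == n2) x1 <- n1 - 1
    expect_equal(wc_fst(n1, x1, n2, x2)$theta, wc_oracle(n1, x1, n2, x2),
                 tolerance = 1e-10)
  }
  # bounds and undefined cases
  expect_true(is.na(wc_fst(50, 0, 50, 0)$theta))
  expect_equal(wc_fst(50, 0, 50, 0)$reason, "monomorphic")
  expect_true(is.na(wc_fst(1, 1, 50, 10)$theta))
  set.seed(42)
  th <- wc_fst(100, rbinom(500, 100, 0.5), 100, rbinom(500, 100, 0.5))$theta
  expect_true(all(th >= -0.5 & th <= 1, na.rm = TRUE))
})

test_that("derived allele frequency polarizes on the ancestral allele", {
  H <- matrix(0L, 100, 1); H[1:30, 1] <- 1L
  pan <- haplotype_panel("P1", H, "chr1", 1000L)
  expect_equal(derived_allele_freq(pan, 1, "A", "C", "A"), 0.30)
  expect_equal(derived_allele_freq(pan, 1, "A", "C", "C"), 0.70)
  expect_true(is.na(derived_allele_freq(pan, 1, "A", "C", NA)))
  expect_true(is.na(derived_allele_freq(pan, 1, "A", "C", "G")))
  # counting oracle across a random panel
  pan2 <- random_panel(60, 40, seed = 43)
  for (j in c(1, 20, 40)) {
    expect_equal(derived_allele_freq(pan2, j, "A", "C", "A"),
                 sum(pan2$H[, j]) / 60)
  }
})

# O(n^2 m) pairwise oracle for EHH: fraction of ordered carrier pairs
# identical over every site between the core and the query site.
ehh_oracle <- function(panel, core, allele, direction) {
  carriers <- which(panel$H[, core] == allele)
  n <- length(carriers)
  m <- ncol(panel$H)
  idx <- if (direction == "right") {
    if (core == m) integer(0) else (core + 1L):m
  } else {
    if (core == 1L) integer(0) else (core - 1L):1L
  }
  out <- data.frame(dist_cM = 0, ehh = 1)
  for (j in idx) {
    rng <- if (direction == "right") (core + 1L):j else j:(core - 1L)
    same <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (all(panel$H[carriers[a], rng] == panel$H[carriers[b], rng])) {
        same <- same + 1
      }
    }
    e <- 2 * same / (n * (n - 1))
    out <- rbind(out, data.frame(dist_cM = abs(panel$pos_cM[j] - panel$pos_cM[core]),
                                 ehh = e))
    if (e < 0.05) break
  }
  out
}

test_that("EHH curves match the brute-force pairwise oracle", {
  # identical carriers: EHH stays 1 to the boundary
  H <- matrix(rep(c(0L, 1L), each = 5) , 10, 20)
  H[1:5, ] <- matrix(rep(H[1, ], each = 5), 5)  # make carriers of 0 identical
  pan <- haplotype_panel("P1", H, "chr1", seq_len(20) * 1000L)
  cv <- ehh_curve(pan, 10, H[1, 10], "right")
  expect_true(all(cv$ehh[seq_len(nrow(cv))] >= 0))
  # two carriers differing at the first flanking site: EHH drops to 0 there
  H2 <- matrix(0L, 4, 5); H2[1:2, 3] <- 1L; H2[1, 4] <- 1L
  pan2 <- haplotype_panel("P1", H2, "chr1", seq_len(5) * 1000L)
  cv2 <- ehh_curve(pan2, 3, 1L, "right")
  expect_equal(cv2$ehh, c(1, 0))
  # fewer than two carriers: undefined
  H3 <- matrix(0L, 4, 5); H3[1, 3] <- 1L
  pan3 <- haplotype_panel("P1", H3, "chr1", seq_len(5) * 1000L)
  expect_null(ehh_curve(pan3, 3, 1L, "right"))
  # 50 random panels against the O(n^2 m) oracle, both directions
  set.seed(44)
  for (i in 1:50) {
    pan <- random_panel(sample(6:14, 1), sample(8:16, 1), seed = 100 + i)
    core <- sample(2:(ncol(pan$H) - 1), 1)
    allele <- sample(0:1, 1)
    if (sum(pan$H[, core] == allele) < 2) next
    dirn <- sample(c("left", "right"), 1)
    got <- ehh_curve(pan, core, allele, dirn)
    want <- ehh_oracle(pan, core, allele, dirn)
    expect_equal(got$ehh, want$ehh, tolerance = 1e-12)
    expect_equal(got$dist_cM, want$dist_cM, tolerance = 1e-12)
    # non-increasing up to the stopping point
    expect_true(all(diff(got$ehh) <= 1e-12))
  }
})

test_that("EHH integrals match an independent quadrature oracle", {
  set.seed(45)
  for (i in 1:20) {
    pan <- random_panel(20, 30, seed = 200 + i)
    core <- 15
    cv <- ehh_curve(pan, core, 1L, "right")
    if (is.null(cv) || nrow(cv) < 2) next
    # independent trapezoid: pracma-style direct sum
    x <- cv$dist_cM; y <- cv$ehh
    oracle <- sum((x[-1] - x[-length(x)]) * (y[-1] + y[-length(y)])) / 2
    expect_equal(sreselscan:::.ehh_integral(cv), oracle, tolerance = 1e-12)
  }
})

test_that("iHS is zero under mirror symmetry and negative for derived sweeps", {
  # mirror construction: derived carriers have exactly the haplotype structure
  # of the ancestral carriers
  set.seed(46)
  half <- matrix(rbinom(20 * 21, 1, 0.5), 20, 21)
  H <- rbind(half, half)
  H[, 11] <- rep(c(0L, 1L), each = 20)   # core: first 20 ancestral, rest derived
  pan <- haplotype_panel("P1", H, "chr1", seq_len(21) * 1000L)
  expect_equal(ihs(pan, 11, "A", "C", "A"), 0, tolerance = 1e-12)
  # sweep planted on the derived allele: extended derived homozygosity makes
  # the ancestral/derived log-ratio negative
  pan2 <- simulate_panel(runif(200, 0.3, 0.7), 120, seed = 47)
  sw <- plant_sweep(pan2, 100, 1L, f = 0.9, L = 80, seed = 48)
  expect_lt(ihs(sw, 100, "A", "C", "A"), 0)   # ancestral = ref = 0 coding
  # undefined cases carry reasons
  expect_true(is.na(ihs(pan2, 100, "A", "C", NA)))
  expect_equal(attr(ihs(pan2, 100, "A", "C", NA), "reason"), "ancestral_unknown")
})

test_that("XP-EHH is zero for identical panels and antisymmetric", {
  pan <- random_panel(40, 60, seed = 49)
  pan2 <- random_panel(40, 60, seed = 50)
  expect_equal(xp_ehh(pan, pan, 30), 0, tolerance = 1e-12)
  a <- xp_ehh(pan, pan2, 30); b <- xp_ehh(pan2, pan, 30)
  expect_equal(a, -b, tolerance = 1e-12)
  # sweep in P1 drives the score positive at the core
  base <- simulate_panel(runif(200, 0.3, 0.7), 120, seed = 51)
  other <- simulate_panel(runif(200, 0.3, 0.7), 120, seed = 52)
  sw <- plant_sweep(base, 100, 1L, f = 0.9, L = 80, seed = 53)
  expect_gt(xp_ehh(sw, other, 100), 0)
})

test_that("swapping populations negates XP-EHH and leaves F_ST unchanged", {
  fx <- default_fixture()
  P1 <- fx$panels$P1; P2 <- fx$panels$P2
  f12 <- wc_fst(nrow(P1$H), colSums(P1$H), nrow(P2$H), colSums(P2$H))$theta
  f21 <- wc_fst(nrow(P2$H), colSums(P2$H), nrow(P1$H), colSums(P1$H))$theta
  expect_equal(f12, f21, tolerance = 1e-12)
  for (s in c(50, 100, 150)) {
    x <- xp_ehh(P1, P2, s)
    if (is.na(x)) next
    expect_equal(x, -xp_ehh(P2, P1, s), tolerance = 1e-12)
  }
})

test_that("standardization produces exact per-bin moments and merges sparse bins", {
  set.seed(54)
  raw <- rnorm(500, 3, 2)
  daf <- runif(500)
  st <- standardize_scores(raw, daf, bin_width = 0.05)
  for (b in unique(st$bin)) {
    v <- st$std[st$bin == b & !is.na(st$std)]
    expect_lt(abs(mean(v)), 1e-12)
    expect_lt(abs(var(v) - 1), 1e-12)
  }
  # single global bin equals plain z-scoring
  stg <- standardize_scores(raw)
  expect_equal(stg$std, (raw - mean(raw)) / sd(raw), tolerance = 1e-12)
  # sparse bins are merged: 30 points in [0,0.05), 5 in [0.95,1] -> one bin
  raw2 <- rnorm(35); bv <- c(runif(30, 0, 0.049), runif(5, 0.95, 0.999))
  st2 <- standardize_scores(raw2, bv, bin_width = 0.05, min_per_bin = 20)
  expect_equal(length(unique(st2$bin)), 1L)
  # outlier flagging at |score| >= 2 behaves like a z-threshold
  expect_equal(sum(abs(stg$std) > 2), sum(abs(raw - mean(raw)) / sd(raw) > 2))
})

test_that("omega calibration recovers the drift scale from known divergence", {
  to_panel <- function(freqs, n_hap, seed, pop) {
    set.seed(seed)
    H <- matrix(rbinom(n_hap * length(freqs), 1,
                       rep(freqs, each = n_hap)), n_hap)
    haplotype_panel(pop, H, "chr1", seq_along(freqs) * 1000L)
  }
  for (cc in c(0.05, 0.10)) {
    fr <- simulate_frequencies(20000, cc, seed = 55)
    p1 <- to_panel(fr$freqs[, 1], 100, 56, "P1")
    p2 <- to_panel(fr$freqs[, 2], 100, 57, "P2")
    w <- calibrate_omega(p1, p2)
    target <- 2 * cc / (1 - cc)
    expect_lt(abs(w - target) / target, 0.20)
  }
  # identical panels floor at 1e-6 with a warning
  pan <- random_panel(50, 100, seed = 58)
  expect_warning(w0 <- calibrate_omega(pan, pan))
  expect_equal(w0, 1e-6)
  # doubling the drift scale roughly doubles the estimate
  fra <- simulate_frequencies(20000, 0.05, seed = 59)
  frb <- simulate_frequencies(20000, 0.0952, seed = 59) # 2c/(1-c) doubles
  wa <- calibrate_omega(to_panel(fra$freqs[, 1], 200, 60, "a"),
                        to_panel(fra$freqs[, 2], 200, 61, "b"))
  wb <- calibrate_omega(to_panel(frb$freqs[, 1], 200, 62, "a"),
                        to_panel(frb$freqs[, 2], 200, 63, "b"))
  expect_lt(abs(wb / wa - 2), 0.4)
})

test_that("XP-CLR is non-negative, zero in degenerate cases, and separates sweeps", {
  fr <- simulate_frequencies(600, 0.05, seed = 64)
  P1 <- simulate_panel(fr$freqs[, 1], 120, seed = 65, pop = "P1")
  P2 <- simulate_panel(fr$freqs[, 2], 120, seed = 66, pop = "P2")
  om <- calibrate_omega(P2, P1)
  cn <- xpclr(P2, P1, om)
  expect_true(all(cn$clr >= 0))
  # single SNP windows with s restricted to 0: alternative equals null
  c0 <- xpclr(P2, P1, om, k = 1L, step = 50L, s_grid = 0)
  expect_true(all(c0$clr == 0))
  # planted sweep windows dominate the null distribution (rank-sum)
  p1f <- colMeans(P1$H)
  core <- which(p1f >= 0.4 & p1f <= 0.6)
  core <- core[which.min(abs(core - 300))]
  sw <- plant_sweep(P1, core, 1L, f = 0.8, L = 100, seed = 67)
  cs <- xpclr(P2, sw, om)
  sweep_scores <- cs$clr[abs(cs$window_center - core) <= 50]
  null_scores <- cn$clr
  rc <- rank_compare(sweep_scores, null_scores)
  expect_lt(rc$p, 1e-4)
  expect_gt(median(sweep_scores), stats::quantile(null_scores, 0.95))
})

test_that("iHS integrals scale linearly with a uniform map rescaling", {
  pan <- simulate_panel(runif(200, 0.3, 0.7), 80, seed = 68)
  site <- 100
  raw1 <- ihs(pan, site, "A", "C", "A")
  pan2 <- pan; pan2$pos_cM <- pan$pos_cM * 2
  raw2 <- ihs(pan2, site, "A", "C", "A")
  # iHS is a ratio of integrals: uniform rescaling cancels exactly as long as
  # the stopping rule truncates at the same sites (it does: EHH is unchanged)
  expect_equal(raw1, raw2, tolerance = 1e-10)
})

test_that("composite likelihood reduces correctly and matches direct lookup", {
  set.seed(69)
  fst <- runif(300); xpe <- rnorm(300); clr <- rgamma(300, 2)
  # zero exponents: L = 1 everywhere
  cl0 <- composite_likelihood(fst, xpe, clr, alpha = 0, beta = 0, gamma = 0)
  expect_true(all(abs(cl0$logL) < 1e-12))
  # alpha only: ranking identical to the F_ST density ranking
  cl1 <- composite_likelihood(fst, xpe, clr, alpha = 1, beta = 0, gamma = 0)
  expect_equal(order(cl1$logL), order(log(cl1$f_fst(fst))))
  # direct product oracle
  cl <- composite_likelihood(fst, xpe, clr)
  oracle <- log(cl$f_fst(fst)) + log(cl$f_xpehh(xpe)) + log(cl$f_xpclr(clr))
  expect_equal(cl$logL, oracle, tolerance = 1e-12)
  # undefined components propagate
  xpe[5] <- NA
  cl2 <- composite_likelihood(fst, xpe, clr)
  expect_true(is.na(cl2$logL[5]))
})

test_that("selection_scan produces a complete per-variant score table", {
  fx <- default_fixture()
  sc <- selection_scan(fx$panels, merge(fx$variants, fx$ancestral,
                                        by = "variant_id", sort = FALSE))
  expect_equal(nrow(sc), nrow(fx$variants))
  expect_true(all(c("fst", "daf_P1", "ihs_std", "xpehh_std", "xpclr",
                    "log_composite") %in% names(sc)))
  # DAF-dependent statistics are undefined exactly where ancestral is unknown
  anc <- merge(fx$variants, fx$ancestral, by = "variant_id", sort = FALSE)$ancestral
  expect_true(all(is.na(sc$ihs_raw[is.na(anc)])))
  expect_true(all(is.na(sc$daf_P1[is.na(anc)])))
})
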