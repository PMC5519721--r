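# enrichment: the statistical-comparison engine — F_ST binning, SRE vs
# non-SRE odds ratios, CMH common odds ratio over background-selection strata,
# feature-matched empirical null sets, and rank/KS comparisons.

#' Assign F_ST bins
#'
#' Bins of width `bin_width` over \[0,1\] (half-open, last bin closed);
#' negative estimates are clipped to 0 for bin assignment. Extreme flags at
#' F_ST > 0.70 and F_ST < 0.05 are carried as separate columns.
#'
#' @param fst per-variant F_ST values (NA allowed).
#' @param bin_width default 0.1.
#' @return data.table with columns bin (integer, 1-based), bin_label,
#'   extreme_high (fst > 0.70), extreme_low (fst < 0.05).
#' @export
fst_bins <- function(fst, bin_width = 0.1) {
  f <- pmax(fst, 0)
  nb <- as.integer(round(1 / bin_width))
  bin <- pmin(as.integer(floor(f / bin_width)) + 1L, nb)
  lab <- sprintf("[%.1f,%.1f%s", (bin - 1L) * bin_width, bin * bin_width,
                 ifelse(bin == nb, "]", ")"))
  data.table(bin = bin, bin_label = lab,
             extreme_high = fst > 0.70, extreme_low = fst < 0.05)
}

#' LD extent of a focal variant: L = sum of r^2 with neighbors
#'
#' r is the haplotype (0/1 vector) correlation between the focal site and
#' every other biallelic site within `window_bp` of it.
#'
#' @param panel a [haplotype_panel()].
#' @param site focal site index.
#' @param window_bp neighbor window (default +/- 200 kb).
#' @return L >= 0, or NA when the focal variant is monomorphic.
#' @export
ld_extent <- function(panel, site, window_bp = 2e5) {
  g <- panel$H[, site]
  if (var(g) == 0) return(NA_real_)
  nb <- which(abs(panel$pos_bp - panel$pos_bp[site]) <= window_bp)
  nb <- nb[nb != site]
  if (!length(nb)) return(0)
  r <- suppressWarnings(cor(g, panel$H[, nb, drop = FALSE]))
  sum(r^2, na.rm = TRUE)  # monomorphic neighbors contribute 0 (r = NA)
}

#' LD extent for every site of a panel
#' @inheritParams ld_extent
#' @return numeric vector of L values.
#' @export
ld_extent_all <- function(panel, window_bp = 2e5) {
  vapply(seq_len(ncol(panel$H)), function(i) ld_extent(panel, i, window_bp),
         numeric(1L))
}

#' Odds ratio of a flag against set membership (2x2)
#'
#' OR = \[P(F|S)/(1-P(F|S))\] / \[P(F|S^c)/(1-P(F|S^c))\] = ad/bc from the
#' 2x2 table (a = |F & S|, b = |!F & S|, c = |F & S^c|, d = |!F & S^c|), with
#' a two-sided Fisher exact p-value and a Haldane-Anscombe 0.5 correction
#' (flagged) when any cell is zero.
#'
#' @param in_set logical: membership in S.
#' @param flag logical: the F_ST bin / extreme flag.
#' @return list: or, p (Fisher exact, from the uncorrected table), table
#'   (a,b,c,d), corrected (TRUE when the 0.5 correction was applied).
#' @export
odds_ratio <- function(in_set, flag) {
  ok <- !is.na(in_set) & !is.na(flag)
  in_set <- in_set[ok]; flag <- flag[ok]
  if (!any(in_set) || all(in_set)) {
    return(list(or = NA_real_, p = NA_real_, table = c(a = NA, b = NA, c = NA, d = NA),
                corrected = FALSE, reason = "empty_set_or_complement"))
  }
  a <- sum(in_set & flag); b <- sum(in_set & !flag)
  cc <- sum(!in_set & flag); d <- sum(!in_set & !flag)
  corrected <- any(c(a, b, cc, d) == 0L)
  or <- if (corrected) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  p <- fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE))$p.value
  list(or = or, p = p, table = c(a = a, b = b, c = cc, d = d),
       corrected = corrected, reason = NA_character_)
}

#' Conditional odds ratio within feature strata
#'
#' The same 2x2 odds ratio computed within the subset of the universe whose
#' feature-bin assignment falls in `delta_keep`.
#'
#' @param in_set,flag as in [odds_ratio()].
#' @param delta_bins per-variant feature-bin labels.
#' @param delta_keep bin labels defining the stratum.
#' @return as [odds_ratio()], or reason "degenerate_stratum".
#' @export
conditional_odds_ratio <- function(in_set, flag, delta_bins, delta_keep) {
  sel <- delta_bins %in% delta_keep
  if (!any(sel & in_set, na.rm = TRUE) || !any(sel & !in_set, na.rm = TRUE)) {
    return(list(or = NA_real_, p = NA_real_, table = NULL, corrected = FALSE,
                reason = "degenerate_stratum"))
  }
  odds_ratio(in_set[sel], flag[sel])
}

#' Per-bin odds-ratio table of SRE vs non-SRE membership across F_ST bins
#'
#' @param fst per-variant F_ST.
#' @param in_set logical SRE membership within the universe.
#' @param bin_width F_ST bin width (default 0.1).
#' @return data.table, one row per occupied bin plus the two extreme flags:
#'   bin_label, or, p, a, b, c, d.
#' @export
fst_bin_or_table <- function(fst, in_set, bin_width = 0.1) {
  fb <- fst_bins(fst, bin_width)
  rows <- list()
  for (b in sort(unique(fb$bin[!is.na(fb$bin)]))) {
    o <- odds_ratio(in_set, fb$bin == b)
    rows[[length(rows) + 1L]] <- data.table(
      bin_label = fb$bin_label[match(b, fb$bin)], or = o$or, p = o$p,
      a = o$table["a"], b = o$table["b"], c = o$table["c"], d = o$table["d"]
    )
  }
  for (fl in c("extreme_high", "extreme_low")) {
    o <- odds_ratio(in_set, fb[[fl]])
    rows[[length(rows) + 1L]] <- data.table(
      bin_label = if (fl == "extreme_high") "FST>0.70" else "FST<0.05",
      or = o$or, p = o$p,
      a = o$table["a"], b = o$table["b"], c = o$table["c"], d = o$table["d"]
    )
  }
  rbindlist(rows)
}

#' Cochran-Mantel-Haenszel common odds ratio over strata
#'
#' Mantel-Haenszel estimator sum(a_i d_i / n_i) / sum(b_i c_i / n_i) with the
#' CMH chi-square (continuity-corrected) p-value; also reports the crude
#' (pooled) odds ratio so confounding inflation is visible. Strata with an
#' empty margin are excluded (flagged in `n_excluded`).
#'
#' @param strata stratum id per observation.
#' @param in_set logical SRE membership.
#' @param flag logical high-F_ST flag.
#' @return list: common_or, p, chisq, crude_or, n_strata_used, n_excluded.
#' @export
cmh_common_or <- function(strata, in_set, flag) {
  ok <- !is.na(strata) & !is.na(in_set) & !is.na(flag)
  strata <- strata[ok]; in_set <- in_set[ok]; flag <- flag[ok]
  num <- den <- 0
  sum_a <- sum_ea <- sum_va <- 0
  used <- 0L; excluded <- 0L
  for (s in unique(strata)) {
    i <- strata == s
    a <- as.numeric(sum(in_set[i] & flag[i]))
    b <- as.numeric(sum(in_set[i] & !flag[i]))
    cc <- as.numeric(sum(!in_set[i] & flag[i]))
    d <- as.numeric(sum(!in_set[i] & !flag[i]))
    n <- a + b + cc + d
    r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
    if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) { excluded <- excluded + 1L; next }
    used <- used + 1L
    num <- num + a * d / n
    den <- den + b * cc / n
    sum_a <- sum_a + a
    sum_ea <- sum_ea + r1 * c1 / n
    sum_va <- sum_va + r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  }
  if (used == 0L) {
    return(list(common_or = NA_real_, p = NA_real_, chisq = NA_real_,
                crude_or = NA_real_, n_strata_used = 0L, n_excluded = excluded))
  }
  chisq <- (abs(sum_a - sum_ea) - 0.5)^2 / sum_va
  crude <- odds_ratio(in_set, flag)$or
  list(common_or = num / den, p = pchisq(chisq, 1L, lower.tail = FALSE),
       chisq = chisq, crude_or = crude, n_strata_used = used,
       n_excluded = excluded)
}

#' Matching-feature bin assignments
#'
#' Bin widths follow the analysis conventions: B-value width 100, DAF width
#' 0.05, LD extent in the fixed intervals \[0,50), \[50,85), \[85,110),
#' \[110,140), >=140; optional MAF (width 0.05), gene size (pool quintiles)
#' and junction distance (pool quartiles).
#'
#' @param b_value,daf,ld per-variant features (required).
#' @param maf,gene_size,junction_distance optional extra features.
#' @return character vector of composite bin labels (NA when any required
#'   feature is missing).
#' @export
match_feature_bins <- function(b_value, daf, ld, maf = NULL, gene_size = NULL,
                               junction_distance = NULL) {
  b_bin <- floor(b_value / 100)
  d_bin <- floor(pmin(daf, 1 - 1e-12) / 0.05)
  l_bin <- findInterval(ld, c(0, 50, 85, 110, 140))
  lab <- paste(b_bin, d_bin, l_bin, sep = "|")
  if (!is.null(maf)) lab <- paste(lab, floor(pmin(maf, 0.5 - 1e-12) / 0.05), sep = "|")
  if (!is.null(gene_size)) {
    q <- stats::quantile(gene_size, seq(0.2, 0.8, 0.2), na.rm = TRUE)
    lab <- paste(lab, findInterval(gene_size, unique(q)), sep = "|")
  }
  if (!is.null(junction_distance)) {
    q <- stats::quantile(junction_distance, c(0.25, 0.5, 0.75), na.rm = TRUE)
    lab <- paste(lab, findInterval(junction_distance, unique(q)), sep = "|")
  }
  lab[is.na(b_value) | is.na(daf) | is.na(ld)] <- NA_character_
  lab
}

#' Empirical p-value against feature-matched null sets
#'
#' Draws `n_sets` random sets from the pool matching the target set's per-bin
#' composition exactly, evaluates `statistic` on each, and reports
#' p = (#\{null >= observed\} + 1) / (n_sets + 1). Sampling is without
#' replacement within each bin cell unless a cell has too few pool candidates,
#' in which case it falls back to replacement (flagged).
#'
#' @param target_idx indices (into `values`) of the target set.
#' @param pool_idx indices of the candidate pool (disjoint from target).
#' @param bins per-variant feature-bin labels (see [match_feature_bins()]).
#' @param statistic function mapping a vector of indices to a scalar (e.g.
#'   number of high-F_ST members).
#' @param n_sets number of null sets (analysis convention: 1000).
#' @param seed RNG seed.
#' @return list: p, observed, null (vector of null statistics),
#'   with_replacement (TRUE when any cell fell back to replacement).
#' @export
matched_null_pvalue <- function(target_idx, pool_idx, bins, statistic,
                                n_sets = 1000L, seed = 1L) {
  set.seed(seed)
  tb <- table(bins[target_idx])
  pool_by_bin <- split(pool_idx, bins[pool_idx])
  missing_cells <- setdiff(names(tb), names(pool_by_bin))
  if (length(missing_cells)) {
    stop_sre(paste("no pool candidates in feature cells:",
                   paste(missing_cells, collapse = "; ")), "sre_config_error")
  }
  with_repl <- FALSE
  draws <- matrix(0L, n_sets, sum(tb))
  col <- 1L
  for (cell in names(tb)) {
    k <- tb[[cell]]
    cand <- pool_by_bin[[cell]]
    repl <- length(cand) < k
    with_repl <- with_repl || repl
    block <- vapply(seq_len(n_sets), function(j)
      cand[sample.int(length(cand), k, replace = repl)], integer(k))
    draws[, col:(col + k - 1L)] <- if (k == 1L) matrix(block, ncol = 1L) else t(block)
    col <- col + k
  }
  observed <- statistic(target_idx)
  null_stats <- apply(draws, 1L, statistic)
  p <- (sum(null_stats >= observed) + 1) / (n_sets + 1)
  list(p = p, observed = observed, null = null_stats,
       with_replacement = with_repl)
}

#' Mann-Whitney U rank comparison
#'
#' Exact two-sided p by enumeration of the U distribution (no-ties recursion)
#' when both samples have at most 12 observations and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction. All-tied data give p = 1 with a flag.
#'
#' @param a,b numeric samples (non-empty).
#' @return list: U (for sample a), p (two-sided), method, all_tied flag.
#' @export
rank_compare <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (var(c(a, b)) == 0) {
    return(list(U = U, p = 1, method = "degenerate", all_tied = TRUE))
  }
  if (!ties && n1 <= 12L && n2 <= 12L) {
    cdf <- .mw_exact_cdf(n1, n2)          # P(U <= u), u = 0..n1*n2
    mu <- n1 * n2 / 2
    p <- if (U > mu) 2 * (1 - if (U >= 1) cdf[U] else 0)   # P(U >= u) = 1 - P(U <= u-1)
         else 2 * cdf[U + 1L]
    return(list(U = U, p = min(1, p), method = "exact", all_tied = FALSE))
  }
  # normal approximation, tie + continuity correction (two-sided)
  tie_tab <- table(r)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- U - n1 * n2 / 2
  corr <- sign(z) * 0.5
  z <- (z - corr) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  list(U = U, p = min(1, p), method = "normal", all_tied = FALSE)
}

# Exact CDF of the Mann-Whitney U statistic under H0 (no ties):
# returns vector c[u+1] = P(U <= u) for u = 0..n1*n2.
.mw_exact_cdf <- function(n1, n2) {
  g <- .mw_count(n1, n2)
  cumsum(g) / sum(g)
}

# Number of arrangements with U = u, via the recursion
# N(n1, n2, u) = N(n1-1, n2, u-n2) + N(n1, n2-1, u).
.mw_count <- function(n1, n2) {
  maxu <- n1 * n2
  memo <- new.env()
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i == 0L || j == 0L) {
      out <- c(1, rep(0, maxu))
    } else {
      a <- rec(i - 1L, j)   # counts over u for (i-1, j), shift by j
      b <- rec(i, j - 1L)
      out <- c(rep(0, j), head(a, maxu + 1L - j)) + b
    }
    memo[[key]] <- out
    out
  }
  rec(n1, n2)
}

#' Kolmogorov-Smirnov comparison of p-value distributions
#'
#' Two-sample KS, or one-sample KS against Uniform(0,1) when `b` is NULL.
#' Also emits a Q-Q table (expected vs observed -log10 p) for plotting.
#'
#' @param a numeric sample (p-values in \[0,1\] for the uniform-null mode).
#' @param b second sample or NULL.
#' @return list: statistic, p, qq (data.table expected/observed -log10 p).
#' @export
distribution_compare_ks <- function(a, b = NULL) {
  stopifnot(length(a) > 0L)
  kt <- if (is.null(b)) suppressWarnings(ks.test(a, "punif"))
        else suppressWarnings(ks.test(a, b))
  s <- sort(a)
  qq <- data.table(expected = -log10(stats::ppoints(length(s))),
                   observed = -log10(pmax(s, .Machine$double.xmin)))
  list(statistic = unname(kt$statistic), p = kt$p.value, qq = qq)
}
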