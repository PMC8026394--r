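#' Per-population allele frequencies
#'
#' Computes derived(alt)-allele frequencies and observed chromosome counts
#' per population per SNP. Diploid samples contribute 2 chromosomes where
#' non-missing; pseudo-haploid samples contribute 1 (their 0/2 dosage codes
#' a single sampled allele).
#'
#' @param data a [GenotypeData-class].
#' @param pop_spec optional named list mapping population name to sample
#'   ids; defaults to the `population` column of the sample table.
#' @return A list with elements `p` (SNP x population frequency matrix,
#'   NA = missing), `n` (chromosome counts), `chrom`, `pos_bp` (SNP
#'   coordinates). This is the frequency-table input of all f-statistics.
#' @export
alleleFreqs <- function(data, pop_spec = NULL) {
  g <- genoMatrix(data)
  sa <- sampleInfo(data)
  if (is.null(pop_spec)) {
    pop_spec <- split(sa$sample_id, sa$population)
  }
  unknown <- setdiff(unlist(pop_spec), sa$sample_id)
  if (length(unknown)) .stopf("unknown sample(s): %s", paste(unknown, collapse = ", "))
  pops <- names(pop_spec)
  p <- matrix(NA_real_, nrow(g), length(pops), dimnames = list(NULL, pops))
  n <- matrix(0, nrow(g), length(pops), dimnames = list(NULL, pops))
  for (k in seq_along(pops)) {
    idx <- match(pop_spec[[k]], sa$sample_id)
    ph <- sa$ploidy[idx] == "pseudohaploid"
    sub <- g[, idx, drop = FALSE]
    obs <- !is.na(sub)
    chroms <- sweep(obs * 1, 2, ifelse(ph, 1, 2), "*")
    derived <- sub
    derived[is.na(derived)] <- 0L
    derived <- sweep(derived, 2, ifelse(ph, 0.5, 1), "*")
    ntot <- rowSums(chroms)
    dtot <- rowSums(derived)
    n[, k] <- ntot
    p[, k] <- ifelse(ntot > 0, dtot / ntot, NA_real_)
  }
  si <- snpInfo(data)
  list(p = p, n = n, chrom = si$chrom, pos_bp = si$pos_bp, cm = si$cm)
}

#' Frequency table from bare frequency matrices
#'
#' Convenience constructor used by frequency-level simulations where
#' population frequencies are known exactly (infinite sample). `n` defaults
#' to `Inf`, which disables finite-sample heterozygosity corrections.
#'
#' @param p SNP x population frequency matrix (named columns).
#' @param chrom,pos_bp SNP coordinates.
#' @param n optional matrix of chromosome counts.
#' @export
freqTable <- function(p, chrom, pos_bp, n = NULL) {
  if (is.null(n)) n <- matrix(Inf, nrow(p), ncol(p), dimnames = dimnames(p))
  list(p = p, n = n, chrom = chrom, pos_bp = pos_bp, cm = NULL)
}

.het_corr <- function(p, n) {
  # unbiased heterozygosity correction term p(1-p)/(n-1); dropped (0) when
  # n <= 1 (and vanishing as n -> Inf)
  out <- p * (1 - p) / (n - 1)
  bad <- !(n > 1)
  if (any(bad, na.rm = TRUE)) out[which(bad)] <- 0
  out
}

#' Per-SNP f-statistic contributions
#'
#' `f2PerSNP` returns per-SNP (p_i - p_j)^2, minus finite-sample
#' heterozygosity terms when `corrected` (dropped, with no substitute, for a
#' population observed on a single chromosome). `f3PerSNP` returns
#' (p_c - p_a)(p_c - p_b) with the target-population correction.
#' `f4PerSNP` returns (p_a - p_b)(p_c - p_d) (no correction needed).
#' `dPerSNP` returns the per-SNP numerator and the ABBA-BABA denominator
#' (p_a + p_b - 2 p_a p_b)(p_c + p_d - 2 p_c p_d).
#' SNPs missing in any involved population yield NA (listwise per statistic).
#'
#' @param freqs a frequency table from [alleleFreqs()] or [freqTable()].
#' @param i,j,a,b,c,d population names.
#' @param corrected apply the heterozygosity correction (default TRUE for
#'   f2/f3; f4 and D are unbiased without it).
#' @return numeric vector (f2/f3/f4) or list(num, den) (D).
#' @export
f2PerSNP <- function(freqs, i, j, corrected = TRUE) {
  pi <- freqs$p[, i]; pj <- freqs$p[, j]
  out <- (pi - pj)^2
  if (corrected)
    out <- out - .het_corr(pi, freqs$n[, i]) - .het_corr(pj, freqs$n[, j])
  out
}

#' @rdname f2PerSNP
#' @export
f3PerSNP <- function(freqs, c, a, b, corrected = TRUE) {
  pc <- freqs$p[, c]; pa <- freqs$p[, a]; pb <- freqs$p[, b]
  out <- (pc - pa) * (pc - pb)
  if (corrected) out <- out - .het_corr(pc, freqs$n[, c])
  out
}

#' @rdname f2PerSNP
#' @export
f4PerSNP <- function(freqs, a, b, c, d) {
  (freqs$p[, a] - freqs$p[, b]) * (freqs$p[, c] - freqs$p[, d])
}

#' @rdname f2PerSNP
#' @export
dPerSNP <- function(freqs, a, b, c, d) {
  pa <- freqs$p[, a]; pb <- freqs$p[, b]
  pc <- freqs$p[, c]; pd <- freqs$p[, d]
  list(num = (pa - pb) * (pc - pd),
       den = (pa + pb - 2 * pa * pb) * (pc + pd - 2 * pc * pd))
}

#' Weighted block jackknife for ratio statistics
#'
#' Blocks are fixed physical windows of `block_mb` megabases anchored at
#' position 0 on each chromosome (5 Mb by default, the conventional choice
#' for linked SNP data). The point estimate is the ratio of sums
#' sum(num)/sum(den); the standard error is the weighted delete-one-block
#' jackknife with block weights equal to their SNP counts (Busing-style
#' weighted jackknife, which reduces to the unweighted formula for equal
#' blocks).
#'
#' @param num,den per-SNP numerator and denominator contributions (use
#'   `den = rep(1, n)` for mean-type statistics such as f2/f3/f4). SNPs with
#'   NA in either are dropped.
#' @param chrom,pos_bp SNP coordinates.
#' @param block_mb block size in Mb.
#' @param statistic,pops labels stored on the result.
#' @return An [FStatResult-class].
#' @export
blockJackknife <- function(num, den, chrom, pos_bp, block_mb = 5,
                           statistic = "ratio", pops = character()) {
  keep <- !is.na(num) & !is.na(den)
  num <- num[keep]; den <- den[keep]
  chrom <- chrom[keep]; pos_bp <- pos_bp[keep]
  block <- paste0(chrom, ":", floor(pos_bp / (block_mb * 1e6)))
  ub <- unique(block)
  B <- length(ub)
  if (B < 2) .stopf("block jackknife needs >= 2 non-empty blocks (got %d)", B)
  bi <- match(block, ub)
  num_b <- rowsum(num, bi)[, 1]
  den_b <- rowsum(den, bi)[, 1]
  m_b <- tabulate(bi, nbins = B)
  Sn <- sum(num_b); Sd <- sum(den_b)
  theta <- Sn / Sd
  theta_j <- (Sn - num_b) / (Sd - den_b)
  n <- sum(m_b)
  h <- n / m_b
  theta_J <- B * theta - sum((1 - m_b / n) * theta_j)
  var_j <- sum((h * theta - (h - 1) * theta_j - theta_J)^2 / (h - 1)) / B
  se <- sqrt(var_j)
  methods::new("FStatResult", statistic = statistic, pops = as.character(pops),
               estimate = theta, se = se,
               z = if (se > 0) theta / se else ifelse(theta == 0, 0, sign(theta) * Inf),
               n_blocks = as.integer(B), n_snps = as.integer(n))
}

#' Compute an f-statistic with jackknife uncertainty
#'
#' High-level wrapper: computes per-SNP contributions for the requested
#' statistic and runs the weighted block jackknife.
#'
#' @param freqs frequency table ([alleleFreqs()] / [freqTable()]).
#' @param statistic one of "f2", "f3", "f4", "D".
#' @param pops character vector of population names, in the statistic's
#'   canonical order: (i, j), (c; a, b), (a, b; c, d).
#' @param block_mb jackknife block size in Mb.
#' @param corrected heterozygosity correction for f2/f3.
#' @return An [FStatResult-class].
#' @export
fStat <- function(freqs, statistic, pops, block_mb = 5, corrected = TRUE) {
  per <- switch(statistic,
    f2 = list(num = f2PerSNP(freqs, pops[1], pops[2], corrected), den = NULL),
    f3 = list(num = f3PerSNP(freqs, pops[1], pops[2], pops[3], corrected), den = NULL),
    f4 = list(num = f4PerSNP(freqs, pops[1], pops[2], pops[3], pops[4]), den = NULL),
    D  = dPerSNP(freqs, pops[1], pops[2], pops[3], pops[4]),
    .stopf("unknown statistic: %s", statistic))
  den <- if (is.null(per$den)) rep(1, length(per$num)) else per$den
  blockJackknife(per$num, den, freqs$chrom, freqs$pos_bp, block_mb,
                 statistic = statistic, pops = pops)
}

setMethod("show", "FStatResult", function(object) {
  cat(sprintf("%s(%s) = %.6g +/- %.3g (Z = %.2f; %d SNPs, %d blocks)\n",
              object@statistic, paste(object@pops, collapse = ", "),
              object@estimate, object@se, object@z,
              object@n_snps, object@n_blocks))
})

#' Direct f4-ratio ancestry proportion
#'
#' Estimates the admixture proportion alpha = f4(A, O; X, C) /
#' f4(A, O; B, C), both sums taken over the SNPs shared by all five
#' populations, with the jackknife run on the ratio of ratios. In the
#' `nean`-style design A and B are the two high-quality archaic genomes
#' (A in the Altai role, B in the Vindija role), O and C are two African
#' populations and X is the test individual; alpha is then the proportion
#' of the genome deriving from the B-related (Neanderthal) source. The
#' result is flagged unreliable when the denominator f4 has |Z| < 3.
#'
#' @param freqs frequency table.
#' @param A,O,X,C,B population names (see above for roles).
#' @param block_mb jackknife block size.
#' @return An [F4RatioResult-class] with a 95% CI (alpha +/- 1.96 se).
#' @export
f4Ratio <- function(freqs, A, O, X, C, B, block_mb = 5) {
  pops <- c(A, O, X, C, B)
  ok <- rowSums(is.na(freqs$p[, pops, drop = FALSE])) == 0
  num <- ifelse(ok, f4PerSNP(freqs, A, O, X, C), NA)
  den <- ifelse(ok, f4PerSNP(freqs, A, O, B, C), NA)
  ratio <- blockJackknife(num, den, freqs$chrom, freqs$pos_bp, block_mb,
                          statistic = "f4ratio", pops = pops)
  ones <- rep(1, length(num))
  numr <- blockJackknife(num, ones, freqs$chrom, freqs$pos_bp, block_mb,
                         statistic = "f4num", pops = c(A, O, X, C))
  denr <- blockJackknife(den, ones, freqs$chrom, freqs$pos_bp, block_mb,
                         statistic = "f4den", pops = c(A, O, B, C))
  alpha <- ratio@estimate; se <- ratio@se
  methods::new("F4RatioResult", alpha = alpha, se = se,
               ci95 = c(alpha - 1.96 * se, alpha + 1.96 * se),
               numerator = numr, denominator = denr,
               reliable = abs(denr@z) >= 3)
}

setMethod("show", "F4RatioResult", function(object) {
  cat(sprintf("f4-ratio alpha = %.4f (95%% CI %.4f-%.4f)%s\n",
              object@alpha, object@ci95[1], object@ci95[2],
              if (object@reliable) "" else " [unreliable: denominator |Z| < 3]"))
})

#' Block-jackknife covariance of several ratio statistics
#'
#' Delete-one-block estimates for a set of statistics defined by per-SNP
#' numerator columns (shared denominator of ones), returning the jackknife
#' covariance matrix. Used for the admixture-graph GLS objective.
#'
#' @param num_mat SNP x statistic matrix of per-SNP contributions (rows
#'   with any NA are dropped).
#' @param chrom,pos_bp SNP coordinates.
#' @param block_mb block size in Mb.
#' @return list(est, cov, n_blocks, n_snps).
#' @export
jackknifeCovariance <- function(num_mat, chrom, pos_bp, block_mb = 5) {
  keep <- rowSums(is.na(num_mat)) == 0
  num_mat <- num_mat[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos_bp <- pos_bp[keep]
  block <- paste0(chrom, ":", floor(pos_bp / (block_mb * 1e6)))
  ub <- unique(block)
  B <- length(ub)
  if (B < 2) .stopf("need >= 2 blocks")
  bi <- match(block, ub)
  sums_b <- rowsum(num_mat, bi)
  m_b <- tabulate(bi, nbins = B)
  tot <- colSums(sums_b)
  n <- sum(m_b)
  est <- tot / n
  # leave-one-out estimates (means over remaining SNPs)
  loo <- sweep(-sums_b, 2, tot, "+") / (n - m_b)
  center <- colMeans(loo)
  dev <- sweep(loo, 2, center, "-")
  covm <- crossprod(dev) * (B - 1) / B
  list(est = est, cov = covm, n_blocks = B, n_snps = n)
}
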