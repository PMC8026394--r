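#' Fixed-width window registry
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param window_bp window width (default 100 kb).
#' @return `GRanges` tiling of all chromosomes (terminal window clipped).
#' @export
windowRegistry <- function(chrom_lengths, window_bp = 1e5) {
  parts <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq(1, chrom_lengths[[ch]], by = window_bp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_bp - 1, chrom_lengths[[ch]]))
  })
  df <- do.call(rbind, parts)
  GRanges(df$chrom, IRanges(df$start, df$end))
}

#' Binary window ancestry vector
#'
#' 1 if any Neanderthal segment overlaps the window, else 0. The window
#' registry is shared across samples so vectors are comparable.
#'
#' @param segments `GRanges` of ancestry segments.
#' @param windows window registry `GRanges`.
#' @return integer vector over windows.
#' @export
ancestryVector <- function(segments, windows) {
  as.integer(GenomicRanges::countOverlaps(windows, segments) > 0)
}

#' Segment-sharing correlation between two genomes
#'
#' Pearson correlation of two binary window vectors with a block-bootstrap
#' percentile CI: windows are grouped into contiguous blocks of
#' `block_kb` kb (5 Mb default, matching the jackknife scale used for
#' f-statistics) and blocks are resampled with replacement.
#'
#' @param vecA,vecB equal-length binary vectors from [ancestryVector()].
#' @param window_bp width of the underlying windows (for block grouping).
#' @param block_kb bootstrap block size in kb.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return An [OverlapTest-class]; r is NA with flag "zero_variance" when
#'   either vector is constant.
#' @export
overlapCorrelation <- function(vecA, vecB, window_bp = 1e5, block_kb = 5000,
                               n_boot = 1000L, seed = 1L) {
  if (length(vecA) != length(vecB)) .stopf("vectors must have equal length")
  n <- length(vecA)
  per_block <- max(1L, round(block_kb * 1000 / window_bp))
  block <- (seq_len(n) - 1L) %/% per_block
  if (length(unique(block)) < 2) .stopf("need >= 2 blocks")
  if (sd(vecA) == 0 || sd(vecB) == 0)
    return(methods::new("OverlapTest", r = NA_real_,
                        ci95 = c(NA_real_, NA_real_), n_windows = as.integer(n),
                        flags = "zero_variance"))
  r <- cor(vecA, vecB)
  ub <- unique(block)
  idx_by_block <- split(seq_len(n), block)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    bs <- sample(ub, length(ub), replace = TRUE)
    ix <- unlist(idx_by_block[as.character(bs)], use.names = FALSE)
    a <- vecA[ix]; b <- vecB[ix]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, 0)
  ci <- unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE))
  methods::new("OverlapTest", r = r, ci95 = ci, n_windows = as.integer(n),
               flags = character())
}

setMethod("show", "OverlapTest", function(object) {
  cat(sprintf("Overlap correlation r = %.3f (95%% CI %.3f-%.3f, %d windows)%s\n",
              object@r, object@ci95[1], object@ci95[2], object@n_windows,
              if (length(object@flags)) paste0(" [", object@flags, "]") else ""))
})

#' Rank-sum comparison of two groups of correlations
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test: exact when both groups
#' are small without ties, otherwise the normal approximation with
#' continuity and tie correction (the stats::wilcox.test policy).
#'
#' @param group1,group2 numeric vectors (non-empty).
#' @return list(statistic = U for group1, p_value).
#' @export
compareGroups <- function(group1, group2) {
  if (length(group1) == 0 || length(group2) == 0)
    .stopf("both groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(group1, group2, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

# map genomic intervals into the concatenated coordinate space of a merged
# callable set on one chromosome; callable is a matrix [start,end) 0-based
.concat_coords <- function(iv, callable) {
  # cumulative callable bp before each callable interval
  off <- cumsum(c(0, callable[, 2] - callable[, 1]))
  pieces <- .intersect_intervals(iv, callable)
  if (nrow(pieces) == 0) return(pieces)
  k <- findInterval(pieces[, 1], callable[, 1])
  cbind(start = off[k] + (pieces[, 1] - callable[k, 1]),
        end = off[k] + (pieces[, 2] - callable[k, 1]))
}

#' Permutation test of segment depletion in introgression deserts
#'
#' Observed statistic: total bp of overlap between ancestry segments and
#' desert regions. Null: every segment is independently re-placed uniformly
#' at random within the callable portion of its own chromosome (in
#' concatenated callable coordinates, so total segment bp is preserved
#' exactly and fragmented callable regions pose no placement problem);
#' overlaps among placed segments are permitted. The one-sided depletion
#' p-value is (1 + #\{null <= observed\}) / (1 + n_perm).
#'
#' @param segments `GRanges` of ancestry segments (within callable).
#' @param deserts `GRanges` of desert regions.
#' @param callable `GRanges` of callable regions.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return A [DesertTest-class].
#' @export
desertOverlapTest <- function(segments, deserts, callable, n_perm = 10000L,
                              seed = 1L) {
  deserts <- normalizeRegions(deserts)
  callable <- normalizeRegions(callable)
  obs <- sum(as.numeric(width(GenomicRanges::intersect(
    GenomicRanges::reduce(segments, ignore.strand = TRUE), deserts,
    ignore.strand = TRUE))))
  total <- sum(as.numeric(width(segments)))
  seg_chrom <- as.character(seqnames(segments))
  set.seed(seed)
  null_tot <- numeric(n_perm)
  for (ch in unique(seg_chrom)) {
    cal <- callable[seqnames(callable) == ch]
    if (length(cal) == 0) .stopf("no callable region on chromosome %s", ch)
    cal_iv <- cbind(start(cal) - 1, end(cal))
    S <- sum(cal_iv[, 2] - cal_iv[, 1])
    des <- deserts[seqnames(deserts) == ch]
    des_cc <- if (length(des) > 0)
      .concat_coords(cbind(start(des) - 1, end(des)), cal_iv)
    else matrix(numeric(0), ncol = 2)
    # cumulative desert bp below x in concatenated space
    if (nrow(des_cc) > 0) {
      kx <- c(0, as.numeric(t(des_cc)), S)
      cumdes <- cumsum(c(0, des_cc[, 2] - des_cc[, 1]))
      ky <- c(0, as.numeric(t(cbind(cumdes[-length(cumdes)], cumdes[-1]))), cumdes[length(cumdes)])
      Dfun <- stats::approxfun(kx, ky, rule = 2, ties = "ordered")
    } else {
      Dfun <- function(x) rep(0, length(x))
    }
    lens <- as.numeric(width(segments[seg_chrom == ch]))
    if (any(lens > S))
      .stopf("segment longer than callable span on chromosome %s", ch)
    for (li in seq_along(lens)) {
      L <- lens[li]
      starts <- runif(n_perm, 0, S - L)
      null_tot <- null_tot + (Dfun(starts + L) - Dfun(starts))
    }
  }
  p <- (1 + sum(null_tot <= obs + 1e-6)) / (1 + n_perm)
  methods::new("DesertTest", observed_bp = obs, total_bp = total,
               n_permutations = as.integer(n_perm), p_depletion = p,
               null_summary = quantile(null_tot, c(0, 0.25, 0.5, 0.75, 1)),
               seed = as.integer(seed))
}

setMethod("show", "DesertTest", function(object) {
  cat(sprintf("Desert overlap: %.0f bp of %.0f bp in deserts; depletion p = %.4g (%d permutations)\n",
              object@observed_bp, object@total_bp, object@p_depletion,
              object@n_permutations))
})
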