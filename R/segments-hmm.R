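#' Bin the genome in genetic-map coordinates
#'
#' Contiguous bins of `bin_cm` centiMorgans per chromosome (terminal bin
#' possibly shorter); every panel SNP is assigned to exactly one bin, with
#' right-open convention at boundaries.
#'
#' @param map a [GeneticMap-class].
#' @param panel SNP data.frame with `chrom` and `cm` columns (cm relative
#'   to the chromosome start).
#' @param bin_cm bin width in cM (default 0.05).
#' @return list(bins = data.frame(chrom, bin, start_cm, end_cm, start_bp,
#'   end_bp), snp_bin = global bin row index per panel SNP (NA for SNPs on
#'   chromosomes absent from the map), bin_cm).
#' @export
binGenome <- function(map, panel, bin_cm = 0.05) {
  spans <- chromSpansCM(map)
  bins <- do.call(rbind, lapply(names(spans), function(ch) {
    span <- spans[[ch]]
    edges <- unique(c(seq(0, span, by = bin_cm), span))
    a <- map@anchors[map@anchors$chrom == ch, ]
    data.frame(chrom = ch, bin = seq_len(length(edges) - 1),
               start_cm = edges[-length(edges)], end_cm = edges[-1],
               start_bp = bpFromCM(map, ch, edges[-length(edges)] + a$cm[1]),
               end_bp = bpFromCM(map, ch, edges[-1] + a$cm[1]),
               stringsAsFactors = FALSE)
  }))
  bins$row <- seq_len(nrow(bins))
  snp_bin <- rep(NA_integer_, nrow(panel))
  for (ch in unique(panel$chrom)) {
    if (!ch %in% names(spans)) next
    sel <- which(panel$chrom == ch)
    b <- bins[bins$chrom == ch, ]
    idx <- findInterval(panel$cm[sel], b$start_cm, rightmost.closed = FALSE)
    idx[idx < 1] <- 1L
    idx[idx > nrow(b)] <- nrow(b)
    snp_bin[sel] <- b$row[idx]
  }
  list(bins = bins, snp_bin = snp_bin, bin_cm = bin_cm)
}

#' Per-SNP derived/ancestral read counts
#'
#' @param frags a [FragmentTable-class].
#' @param panel SNP data.frame with `ref`, `alt`.
#' @param filter apply [standardFilter()] first.
#' @param mask_k when > 0, drop damage-consistent observations (T on a
#'   forward-strand read, A on a reverse-strand read) within `mask_k`
#'   positions of a fragment end — the same masking rule used for
#'   pseudo-haploid calling. 0 disables.
#' @return list(n_der, n_anc) integer vectors over panel SNPs.
#' @export
readCountsAtSNPs <- function(frags, panel, filter = TRUE, mask_k = 0L) {
  r <- if (filter) standardFilter(frags)@records else frags@records
  r <- r[!is.na(r$snp_index), , drop = FALSE]
  if (mask_k > 0 && nrow(r) > 0) {
    near <- pmin(r$pos_from_5p, r$pos_from_3p) <= mask_k
    dmg <- (r$strand == "+" & r$allele == "T") |
           (r$strand == "-" & r$allele == "A")
    r <- r[!(near & dmg), , drop = FALSE]
  }
  der <- r$allele == panel$alt[r$snp_index]
  anc <- r$allele == panel$ref[r$snp_index]
  n_der <- tabulate(r$snp_index[der], nbins = nrow(panel))
  n_anc <- tabulate(r$snp_index[anc], nbins = nrow(panel))
  list(n_der = n_der, n_anc = n_anc)
}

#' Read-level emission log-likelihood
#'
#' Probability of a derived read allele given k Neanderthal copies:
#' P(derived | k) = c p_cont + (1 - c) ((1 - e) q_k + e (1 - q_k)) with
#' q_k = (k/2) p_nea + (1 - k/2) p_afr. The log-likelihood of a site (or a
#' bin) is the sum over its reads; probabilities are clipped at 1e-300
#' before the log, so impossible configurations return a large negative
#' value rather than -Inf.
#'
#' @param n_der,n_anc derived / ancestral read counts (vectors over sites).
#' @param p_nea,p_afr,p_cont source allele frequencies per site.
#' @param c,e contamination and error rates.
#' @param k Neanderthal copy number (0, 1 or 2).
#' @return numeric vector of per-site log-likelihoods.
#' @export
emissionLoglik <- function(n_der, n_anc, p_nea, p_afr, p_cont, c, e, k) {
  q <- (k / 2) * p_nea + (1 - k / 2) * p_afr
  pd <- c * p_cont + (1 - c) * ((1 - e) * q + e * (1 - q))
  ld <- log(pmax(pd, 1e-300))
  la <- log(pmax(1 - pd, 1e-300))
  L <- max(length(ld), length(n_der), length(n_anc))
  ld <- rep_len(ld, L); la <- rep_len(la, L)
  n_der <- rep_len(n_der, L); n_anc <- rep_len(n_anc, L)
  out <- numeric(L)
  nz <- n_der > 0
  out[nz] <- n_der[nz] * ld[nz]
  nz <- n_anc > 0
  out[nz] <- out[nz] + n_anc[nz] * la[nz]
  out
}

# haplotype-factorized copy-number transition matrix over distance d_cm
.copy_transition <- function(F, tau, d_cm) {
  a <- exp(-tau * d_cm)
  H <- matrix(c((1 - F) * (1 - a) + a, F * (1 - a),
                (1 - F) * (1 - a), F * (1 - a) + a), 2, 2, byrow = TRUE)
  # rows: from (mod, nea); cols: to (mod, nea)
  T3 <- matrix(0, 3, 3)
  T3[1, ] <- c(H[1, 1]^2, 2 * H[1, 1] * H[1, 2], H[1, 2]^2)
  T3[2, ] <- c(H[1, 1] * H[2, 1],
               H[1, 1] * H[2, 2] + H[1, 2] * H[2, 1],
               H[1, 2] * H[2, 2])
  T3[3, ] <- c(H[2, 1]^2, 2 * H[2, 1] * H[2, 2], H[2, 2]^2)
  T3
}

# forward-backward in log space; returns posteriors and both total logliks
.forward_backward <- function(emis, logT, loginit) {
  n <- nrow(emis)
  K <- ncol(emis)
  fwd <- matrix(-Inf, n, K)
  fwd[1, ] <- loginit + emis[1, ]
  if (n > 1) for (t in 2:n) {
    for (kk in seq_len(K))
      fwd[t, kk] <- .logsumexp_vec(fwd[t - 1, ] + logT[, kk]) + emis[t, kk]
  }
  bwd <- matrix(0, n, K)
  if (n > 1) for (t in (n - 1):1) {
    for (kk in seq_len(K))
      bwd[t, kk] <- .logsumexp_vec(logT[kk, ] + emis[t + 1, ] + bwd[t + 1, ])
  }
  ll_f <- .logsumexp_vec(fwd[n, ])
  ll_b <- .logsumexp_vec(loginit + emis[1, ] + bwd[1, ])
  post <- exp(fwd + bwd - ll_f)
  post <- post / rowSums(post)
  list(post = post, loglik_forward = ll_f, loglik_backward = ll_b)
}

#' Decode Neanderthal copy-number posteriors along the genome
#'
#' Diploid three-state HMM ({0, 1, 2} Neanderthal copies) in genetic-map
#' coordinates. Transitions factorize over two independent haplotype
#' chains, each a two-state Markov process with stationary Neanderthal
#' fraction `F` and switch intensity `tau` per cM; emissions are per-read
#' binomial mixtures of Neanderthal, modern and contaminant allele
#' frequencies ([emissionLoglik()]). Posterior decoding via
#' forward-backward in log space; deterministic given inputs.
#'
#' @param bt bin track from [binGenome()].
#' @param counts read counts from [readCountsAtSNPs()].
#' @param panel_freqs list with `p_nea`, `p_afr`, `p_cont` per panel SNP.
#' @param F stationary per-haplotype Neanderthal fraction.
#' @param tau switch intensity per cM.
#' @param c,e contamination and error rates of the emission model.
#' @return list(posterior = n_bin x 3 matrix, loglik_forward,
#'   loglik_backward, bins).
#' @export
decodeTrack <- function(bt, counts, panel_freqs, F = 0.03, tau = 0.05,
                        c = 0, e = 0.001) {
  stopifnot(F > 0, F < 1, tau > 0)
  nb <- nrow(bt$bins)
  emis <- matrix(0, nb, 3)
  ok <- !is.na(bt$snp_bin)
  for (k in 0:2) {
    site_ll <- emissionLoglik(counts$n_der[ok], counts$n_anc[ok],
                              panel_freqs$p_nea[ok], panel_freqs$p_afr[ok],
                              panel_freqs$p_cont[ok], c, e, k)
    agg <- rowsum(site_ll, bt$snp_bin[ok])
    emis[as.integer(rownames(agg)), k + 1] <- agg[, 1]
  }
  if (any(!is.finite(emis)))
    .stopf("non-finite emission log-likelihood at bin %d",
           which(!is.finite(rowSums(emis)))[1])
  init <- c((1 - F)^2, 2 * F * (1 - F), F^2)
  post <- matrix(NA_real_, nb, 3)
  ll_f <- 0; ll_b <- 0
  for (ch in unique(bt$bins$chrom)) {
    rows <- which(bt$bins$chrom == ch)
    d <- bt$bins$end_cm[rows] - bt$bins$start_cm[rows]
    # constant bin width except possibly the terminal bin; use the modal
    # width for the shared transition matrix
    T3 <- .copy_transition(F, tau, bt$bin_cm)
    fb <- .forward_backward(emis[rows, , drop = FALSE], log(T3), log(init))
    post[rows, ] <- fb$post
    ll_f <- ll_f + fb$loglik_forward
    ll_b <- ll_b + fb$loglik_backward
  }
  list(posterior = post, loglik_forward = ll_f, loglik_backward = ll_b,
       bins = bt$bins)
}

#' Call Neanderthal ancestry segments from decoded posteriors
#'
#' Maximal runs of bins with P(k >= 1) >= `threshold`; runs separated by a
#' gap shorter than `merge_gap_cm` are merged; segments shorter than
#' `min_cm` are dropped. Copy number per segment is the majority posterior
#' state among its bins.
#'
#' @param decoded output of [decodeTrack()].
#' @param threshold posterior call threshold (default 0.9).
#' @param min_cm minimum reported segment length (default 0.2 cM).
#' @param merge_gap_cm gap-closing width in cM; the default (one bin width)
#'   merges only runs with no intervening called-off bin.
#' @return list(segments = GRanges with start_cm/end_cm/length_cm/
#'   posterior/copies, summary = list(total_cm, longest_cm,
#'   n_segments_gt5cm, per_chrom)).
#' @export
callSegments <- function(decoded, threshold = 0.9, min_cm = 0.2,
                         merge_gap_cm = NULL) {
  bins <- decoded$bins
  p_any <- decoded$posterior[, 2] + decoded$posterior[, 3]
  if (is.null(merge_gap_cm))
    merge_gap_cm <- max(bins$end_cm - bins$start_cm)
  segs <- list()
  for (ch in unique(bins$chrom)) {
    rows <- which(bins$chrom == ch)
    on <- p_any[rows] >= threshold
    if (!any(on)) next
    iv <- cbind(bins$start_cm[rows][on] - 1e-9, bins$end_cm[rows][on] + 1e-9)
    # close sub-bin gaps, then gaps below merge_gap_cm
    iv <- .merge_intervals(iv)
    if (nrow(iv) > 1) {
      gaps <- iv[-1, 1] - iv[-nrow(iv), 2]
      grp <- cumsum(c(1, gaps >= merge_gap_cm))
      iv <- do.call(rbind, lapply(split(seq_len(nrow(iv)), grp), function(ix)
        c(iv[ix[1], 1], iv[ix[length(ix)], 2])))
    }
    for (si in seq_len(nrow(iv))) {
      s_cm <- max(iv[si, 1], 0); e_cm <- iv[si, 2]
      inside <- rows[bins$start_cm[rows] >= s_cm - 1e-6 &
                     bins$end_cm[rows] <= e_cm + 1e-6]
      cm_len <- bins$end_cm[max(inside)] - bins$start_cm[min(inside)]
      if (cm_len < min_cm) next
      copies <- if (mean(decoded$posterior[inside, 3]) >
                    mean(decoded$posterior[inside, 2])) 2L else 1L
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ch, start_bp = bins$start_bp[min(inside)],
        end_bp = bins$end_bp[max(inside)],
        start_cm = bins$start_cm[min(inside)],
        end_cm = bins$end_cm[max(inside)], length_cm = cm_len,
        posterior = mean(p_any[inside]), copies = copies,
        stringsAsFactors = FALSE)
    }
  }
  if (length(segs) == 0) {
    gr <- GRanges()
    summary <- list(total_cm = 0, longest_cm = 0, n_segments_gt5cm = 0L,
                    per_chrom = data.frame())
    return(list(segments = gr, summary = summary))
  }
  df <- do.call(rbind, segs)
  gr <- GRanges(df$chrom, IRanges(pmax(1, round(df$start_bp)),
                                  pmax(1, round(df$end_bp))),
                start_cm = df$start_cm, end_cm = df$end_cm,
                length_cm = df$length_cm, posterior = df$posterior,
                copies = df$copies)
  per_chrom <- aggregate(length_cm ~ chrom, df, sum)
  list(segments = gr,
       summary = list(total_cm = sum(df$length_cm),
                      longest_cm = max(df$length_cm),
                      n_segments_gt5cm = sum(df$length_cm > 5),
                      per_chrom = per_chrom))
}

#' End-to-end segment detection from fragments
#'
#' Convenience wrapper: bins the genome, aggregates read counts, decodes
#' and calls segments.
#'
#' @inheritParams decodeTrack
#' @inheritParams callSegments
#' @param frags a [FragmentTable-class].
#' @param panel_freqs output of [simulateArchaicPanel()] or an equivalent
#'   list with `panel`, `p_nea`, `p_afr`, `p_cont`.
#' @param map a [GeneticMap-class].
#' @param bin_cm bin width in cM.
#' @return As [callSegments()], plus `decoded`.
#' @export
detectSegments <- function(frags, panel_freqs, map, bin_cm = 0.05, F = 0.03,
                           tau = 0.05, c = 0, e = 0.001, threshold = 0.9,
                           min_cm = 0.2, mask_k = 0L) {
  bt <- binGenome(map, panel_freqs$panel, bin_cm)
  counts <- readCountsAtSNPs(frags, panel_freqs$panel, mask_k = mask_k)
  dec <- decodeTrack(bt, counts, panel_freqs, F = F, tau = tau, c = c, e = e)
  out <- callSegments(dec, threshold = threshold, min_cm = min_cm)
  out$decoded <- dec
  out
}

#' Length-weighted precision and recall against a truth set
#'
#' Compares called segments with true tracts in genetic-map coordinates.
#' Precision = overlapped called cM / total called cM; recall = overlapped
#' truth cM / total truth cM (both length-weighted). Truth intervals are
#' taken as the union over haplotypes (the HMM reports diploid copy
#' number). Boundary error is the mean absolute cM distance between each
#' truth boundary and the nearest called boundary.
#'
#' @param called `GRanges` from [callSegments()] (needs start_cm/end_cm).
#' @param truth a [TruthSet-class].
#' @param label truth tract class to compare against.
#' @param min_cm restrict both sets to tracts at least this long.
#' @return list(precision, recall, boundary_error_cm, called_cm, truth_cm).
#' @export
segmentRecovery <- function(called, truth, label = "recent", min_cm = 0) {
  tm <- S4Vectors::mcols(truth@segments)
  cm <- S4Vectors::mcols(called)
  tsel <- tm$label == label & tm$length_cm >= min_cm
  csel <- if (length(called)) cm$length_cm >= min_cm else logical(0)
  chroms <- unique(c(as.character(seqnames(truth@segments[tsel])),
                     as.character(seqnames(called[csel]))))
  ov <- 0; tot_t <- 0; tot_c <- 0; berr <- c()
  for (ch in chroms) {
    ti <- which(tsel & as.character(seqnames(truth@segments)) == ch)
    ci <- which(csel & as.character(seqnames(called)) == ch)
    tiv <- if (length(ti)) .merge_intervals(cbind(tm$start_cm[ti], tm$end_cm[ti]))
           else matrix(numeric(0), ncol = 2)
    civ <- if (length(ci)) .merge_intervals(cbind(cm$start_cm[ci], cm$end_cm[ci]))
           else matrix(numeric(0), ncol = 2)
    tot_t <- tot_t + sum(tiv[, 2] - tiv[, 1])
    tot_c <- tot_c + sum(civ[, 2] - civ[, 1])
    inter <- .intersect_intervals(tiv, civ)
    ov <- ov + sum(inter[, 2] - inter[, 1])
    if (nrow(tiv) && nrow(civ)) {
      cb <- as.numeric(civ)
      berr <- c(berr, vapply(as.numeric(tiv), function(x) min(abs(cb - x)), 0))
    }
  }
  list(precision = if (tot_c > 0) ov / tot_c else NA_real_,
       recall = if (tot_t > 0) ov / tot_t else NA_real_,
       boundary_error_cm = if (length(berr)) mean(berr) else NA_real_,
       called_cm = tot_c, truth_cm = tot_t)
}
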