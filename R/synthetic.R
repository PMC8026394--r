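#' Simulate allele frequencies down an admixture graph
#'
#' Root frequencies are drawn uniformly on \\[0.05, 0.95\\]; every drift
#' edge of length f resamples the child frequency from a Beta distribution
#' with mean p and variance f — the edge length is therefore the edge's
#' realized f2 (mean squared frequency difference), and by the law of
#' total variance f2 is additive along drift paths. The Beta variance is
#' capped at 0.9 p (1 - p) (a proper Beta needs variance below p (1 - p)),
#' which slightly compresses drift at frequencies near 0 or 1. Admixture
#' nodes mix their parents linearly: alpha p1 + (1 - alpha) p2.
#'
#' @param graph an [AdmixtureGraph-class] with all values set; drift
#'   lengths must satisfy f < 1.
#' @param n_snps number of SNPs.
#' @param seed RNG seed (simulations are bit-reproducible given the seed).
#' @return matrix of frequencies, one column per graph node.
#' @export
simulateGraphFrequencies <- function(graph, n_snps, seed) {
  e <- graph@edges
  if (any(is.na(e$value[e$type == "drift"])))
    .stopf("all drift lengths must be set")
  if (any(e$value[e$type == "drift"] >= 1))
    .stopf("drift length must be < 1")
  prop <- .admix_props(e)
  set.seed(seed)
  ord <- rev(.topo_up(e))  # parents before children
  p <- matrix(NA_real_, n_snps, length(ord), dimnames = list(NULL, ord))
  root <- .graph_root(graph)
  p[, root] <- runif(n_snps, 0.05, 0.95)
  for (nd in ord) {
    if (nd == root) next
    ein <- which(e$child == nd)
    if (length(ein) == 1) {
      f <- e$value[ein]
      pp <- p[, e$parent[ein]]
      if (f == 0) {
        p[, nd] <- pp
      } else {
        v <- pmin(f, 0.9 * pp * (1 - pp))
        scale <- pp * (1 - pp) / v - 1
        p[, nd] <- pmin(pmax(rbeta(n_snps, pp * scale, (1 - pp) * scale),
                             1e-9), 1 - 1e-9)
      }
    } else {
      p[, nd] <- prop[ein[1]] * p[, e$parent[ein[1]]] +
                 prop[ein[2]] * p[, e$parent[ein[2]]]
    }
  }
  p
}

#' Evenly spaced SNP coordinates for simulated panels
#'
#' @param n_snps total SNPs, spread evenly over `n_chrom` chromosomes.
#' @param n_chrom number of chromosomes.
#' @param spacing_bp distance between adjacent SNPs.
#' @param cm_per_mb constant recombination rate used for the cm column.
#' @return data.frame chrom/pos_bp/cm.
#' @export
snpGrid <- function(n_snps, n_chrom = 22L, spacing_bp = 2.5e4,
                    cm_per_mb = 1) {
  per <- ceiling(n_snps / n_chrom)
  chrom <- rep(paste0("chr", seq_len(n_chrom)), each = per)[seq_len(n_snps)]
  idx <- sequence(rle(chrom)$lengths)
  pos <- as.integer(idx * spacing_bp)
  data.frame(chrom = chrom, pos_bp = pos,
             cm = pos / 1e6 * cm_per_mb, stringsAsFactors = FALSE)
}

#' Simulate a null genotype panel (star phylogeny)
#'
#' All populations diverge independently from a common root with equal
#' drift, so every D statistic has expectation 0 — the calibration null for
#' jackknife Z scores.
#'
#' @param n_pops number of populations (>= 4 so D is defined).
#' @param n_snps SNPs (placed on an even grid over 22 chromosomes).
#' @param seed RNG seed.
#' @param drift per-branch drift in f2 units.
#' @param n_ind diploid individuals sampled per population.
#' @return A [GenotypeData-class].
#' @export
simulateNullPanel <- function(n_pops, n_snps, seed, drift = 0.02, n_ind = 10L) {
  if (n_pops < 4) .stopf("n_pops must be >= 4")
  pops <- paste0("pop", seq_len(n_pops))
  edges <- data.frame(child = pops, parent = "root", type = "drift",
                      value = drift, stringsAsFactors = FALSE)
  g <- admixtureGraph(edges)
  p <- simulateGraphFrequencies(g, n_snps, seed)
  grid <- snpGrid(n_snps)
  geno <- matrix(NA_integer_, n_snps, n_pops * n_ind)
  for (k in seq_len(n_pops)) {
    cols <- (k - 1) * n_ind + seq_len(n_ind)
    geno[, cols] <- rbinom(n_snps * n_ind, 2L, rep(p[, pops[k]], n_ind))
  }
  samples <- data.frame(
    sample_id = paste0(rep(pops, each = n_ind), "_", seq_len(n_ind)),
    population = rep(pops, each = n_ind), ploidy = "diploid",
    stringsAsFactors = FALSE)
  snp <- data.frame(snp_id = paste0("snp", seq_len(n_snps)),
                    chrom = grid$chrom, pos_bp = grid$pos_bp, cm = grid$cm,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  GenotypeData(snp, samples, geno)
}

#' A human-scale uniform genetic map for simulations
#'
#' 22 chromosomes with cM spans shrinking linearly from the largest to the
#' smallest (~3,500 cM genome total at the default), constant 1 cM/Mb.
#'
#' @param n_chrom chromosomes.
#' @param total_cm genome-wide map length.
#' @return A [GeneticMap-class] with two anchors per chromosome.
#' @export
uniformMap <- function(n_chrom = 22L, total_cm = 3500) {
  raw <- seq(2, 1, length.out = n_chrom)
  spans <- raw / sum(raw) * total_cm
  anchors <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    data.frame(chrom = paste0("chr", i), pos_bp = c(1, round(spans[i] * 1e6)),
               cm = c(0, spans[i]), stringsAsFactors = FALSE)
  }))
  GeneticMap(anchors)
}

# one Haldane meiosis on a carrier whose haplotype A holds the interval set
# H (list of start/end matrices in cM per chromosome); homolog B is blank.
# Returns the gamete's retained interval set.
.meiosis <- function(H, spans) {
  out <- H
  for (ci in seq_along(spans)) {
    L <- spans[ci]
    n_x <- rpois(1, L / 100)
    breaks <- sort(runif(n_x, 0, L))
    phase <- runif(1) < 0.5  # TRUE: start on haplotype A
    edges <- c(0, breaks, L)
    starts <- edges[-length(edges)]
    ends <- edges[-1]
    onA <- rep(c(phase, !phase), length.out = length(starts))
    Aseg <- cbind(start = starts[onA], end = ends[onA])
    out[[ci]] <- .intersect_intervals(H[[ci]], .merge_intervals(Aseg))
  }
  out
}

#' Simulate Neanderthal-ancestry tracts for one diploid individual
#'
#' One haplotype descends from a single Neanderthal ancestor `g`
#' generations back: the ancestral genome passes through `g` successive
#' Haldane meioses (crossovers a Poisson process at 1 per 100 cM, uniform
#' start phase, no interference); the first meiosis acts on a fully
#' Neanderthal diploid and so creates no ancestry boundaries. Both
#' haplotypes additionally carry old "background" introgression from a
#' stationary two-state Markov process with stationary Neanderthal fraction
#' `alpha_bg` and mean Neanderthal tract length 100 / T_bg cM,
#' corresponding to a pulse roughly `T_bg` generations ago.
#'
#' @param map a [GeneticMap-class]; defines the simulated chromosomes.
#' @param g generations to the Neanderthal ancestor (integer >= 1).
#' @param alpha_bg stationary background Neanderthal fraction in \\[0, 1).
#' @param T_bg background age in generations (default 2000, i.e. ~50 kyr at
#'   25 yr/generation; background tracts then essentially never reach the
#'   5 cM dating threshold).
#' @param sex "male" or "female" (carried through to read simulation; males
#'   have a single X).
#' @param seed RNG seed.
#' @return A [TruthSet-class]; recent tracts are labelled "recent" on
#'   haplotype 1, background tracts "background" on both haplotypes.
#' @export
simulatePedigreeTracts <- function(map, g, alpha_bg = 0.02, T_bg = 2000,
                                   sex = "male", seed = 1L) {
  if (g < 1) .stopf("g must be >= 1")
  spans <- chromSpansCM(map)
  if (length(spans) == 0) .stopf("empty map")
  chroms <- names(spans)
  set.seed(seed)
  # recent tracts: start fully Neanderthal, then g - 1 boundary-forming meioses
  H <- lapply(spans, function(L) cbind(start = 0, end = L))
  if (g > 1) for (k in seq_len(g - 1)) H <- .meiosis(H, spans)
  segs <- list()
  emit <- function(ci, iv, hap, label) {
    if (nrow(iv) == 0) return()
    a <- map@anchors[map@anchors$chrom == chroms[ci], ]
    s_bp <- bpFromCM(map, chroms[ci], iv[, 1] + a$cm[1])
    e_bp <- bpFromCM(map, chroms[ci], iv[, 2] + a$cm[1])
    segs[[length(segs) + 1]] <<- data.frame(
      chrom = chroms[ci], start_bp = s_bp, end_bp = e_bp, hap = hap,
      label = label, start_cm = iv[, 1], end_cm = iv[, 2],
      length_cm = iv[, 2] - iv[, 1], stringsAsFactors = FALSE)
  }
  for (ci in seq_along(spans)) emit(ci, H[[ci]], 1L, "recent")
  # background: alternating-exponential two-state process per haplotype
  if (alpha_bg > 0) {
    mean_nea <- 100 / T_bg
    mean_mod <- mean_nea * (1 - alpha_bg) / alpha_bg
    for (hap in 1:2) for (ci in seq_along(spans)) {
      L <- spans[ci]
      pos <- 0; state <- runif(1) < alpha_bg
      iv <- NULL
      while (pos < L) {
        len <- rexp(1, 1 / if (state) mean_nea else mean_mod)
        nxt <- min(pos + len, L)
        if (state) iv <- rbind(iv, c(pos, nxt))
        pos <- nxt; state <- !state
      }
      if (!is.null(iv)) emit(ci, .merge_intervals(iv), hap, "background")
    }
  }
  df <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start_bp = numeric(), end_bp = numeric(),
               hap = integer(), label = character(), start_cm = numeric(),
               end_cm = numeric(), length_cm = numeric())
  gr <- GRanges(df$chrom, IRanges(pmax(1, round(df$start_bp)),
                                  pmax(1, round(df$end_bp))),
                hap = df$hap, label = df$label, start_cm = df$start_cm,
                end_cm = df$end_cm, length_cm = df$length_cm)
  methods::new("TruthSet", segments = gr,
               params = list(g = g, alpha_bg = alpha_bg, T_bg = T_bg,
                             sex = sex, seed = seed),
               map = map)
}

setMethod("show", "TruthSet", function(object) {
  s <- object@segments
  rec <- S4Vectors::mcols(s)$label == "recent"
  cat(sprintf("TruthSet (g = %s, %s): %d recent tracts (%.1f cM), %d background tracts (%.1f cM)\n",
              object@params$g, object@params$sex, sum(rec),
              sum(S4Vectors::mcols(s)$length_cm[rec]), sum(!rec),
              sum(S4Vectors::mcols(s)$length_cm[!rec])))
})

#' True tract lengths above a threshold
#'
#' @param truth a [TruthSet-class].
#' @param label tract class to extract.
#' @param min_cm length threshold.
#' @return numeric vector of tract lengths in cM.
#' @export
truthLengths <- function(truth, label = "recent", min_cm = 0) {
  m <- S4Vectors::mcols(truth@segments)
  len <- m$length_cm[m$label == label]
  len[len >= min_cm]
}

#' Simulate an archaic-ascertainment frequency panel
#'
#' Emulates a panel of SNPs ascertained where archaic genomes differ from
#' Africans: the African/modern frequency is low (Beta(0.5, 9)) and the
#' Neanderthal frequency high (Beta(9, 0.5)); the contaminant (present-day)
#' frequency equals the modern frequency. All frequencies are clipped to
#' \\[0.001, 0.999\\] to avoid degenerate read likelihoods.
#'
#' With `ascertainment = "modern"` the panel instead emulates a common-
#' polymorphism capture set (frequencies Beta(0.7, 0.7), shared by the
#' modern and contaminant populations) — the appropriate substrate for
#' identity and contamination work, where heterozygosity drives the
#' signal.
#'
#' @param map a [GeneticMap-class] giving the chromosomes.
#' @param snps_per_cm marker density (default 50).
#' @param seed RNG seed.
#' @param x_snps optional number of extra SNPs on an "X" chromosome of
#'   `x_cm` cM appended to the panel (for sex / X-contamination work).
#' @param x_cm genetic length of the X chromosome.
#' @param ascertainment "archaic" (sites where Neanderthals differ from
#'   Africans) or "modern" (common modern-human polymorphisms).
#' @return list(panel = SNP data.frame (snp_id, chrom, pos_bp, cm, ref,
#'   alt), p_nea, p_afr, p_cont = frequency vectors).
#' @export
simulateArchaicPanel <- function(map, snps_per_cm = 50, seed = 1L,
                                 x_snps = 0L, x_cm = 180,
                                 ascertainment = c("archaic", "modern")) {
  ascertainment <- match.arg(ascertainment)
  set.seed(seed)
  spans <- chromSpansCM(map)
  rows <- lapply(names(spans), function(ch) {
    n <- max(2L, round(spans[[ch]] * snps_per_cm))
    a <- map@anchors[map@anchors$chrom == ch, ]
    cm <- sort(runif(n, 0, spans[[ch]]))
    data.frame(chrom = ch, pos_bp = round(bpFromCM(map, ch, cm + a$cm[1])),
               cm = cm, stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  if (x_snps > 0) {
    cm <- sort(runif(x_snps, 0, x_cm))
    panel <- rbind(panel, data.frame(chrom = "X", pos_bp = round(cm * 1e6),
                                     cm = cm, stringsAsFactors = FALSE))
  }
  # de-duplicate positions within chromosome to keep pos strictly increasing
  panel <- panel[!duplicated(panel[c("chrom", "pos_bp")]), ]
  n <- nrow(panel)
  panel$snp_id <- paste0("s", seq_len(n))
  # alternate C/T and G/A sites so both deamination-susceptible strand
  # classes (T on +, A on -) occur
  ct <- seq_len(n) %% 2 == 1
  panel$ref <- ifelse(ct, "C", "G")
  panel$alt <- ifelse(ct, "T", "A")
  clip <- function(x) pmin(pmax(x, 0.001), 0.999)
  if (ascertainment == "archaic") {
    p_nea <- clip(rbeta(n, 9, 0.5))
    p_afr <- clip(rbeta(n, 0.5, 9))
    p_cont <- clip(rbeta(n, 0.5, 9))
  } else {
    p_afr <- p_cont <- clip(rbeta(n, 0.7, 0.7))
    p_nea <- clip(rbeta(n, 9, 0.5))
  }
  list(panel = panel[c("snp_id", "chrom", "pos_bp", "cm", "ref", "alt")],
       p_nea = p_nea, p_afr = p_afr, p_cont = p_cont)
}

#' Read-simulation settings
#'
#' @param coverage mean per-SNP read depth (Poisson).
#' @param contamination probability a read is a present-day contaminant.
#' @param error per-read allele error rate.
#' @param deam_prob terminal C-to-T deamination probability at position 1
#'   (`delta`), decaying geometrically with rate `deam_decay` (`rho`) per
#'   position inward.
#' @param deam_decay geometric decay of the deamination probability.
#' @param ref_c_prob probability a terminal position carries a reference C
#'   (the substrate for deamination).
#' @param mean_length mean fragment length (min 35; shifted geometric).
#' @param base_quality constant reported base quality.
#' @param mapq constant reported mapping quality.
#' @return list of validated settings.
#' @export
readSimSpec <- function(coverage = 2, contamination = 0.05, error = 0.001,
                        deam_prob = 0.3, deam_decay = 0.5, ref_c_prob = 0.25,
                        mean_length = 55, base_quality = 40L, mapq = 37L) {
  if (coverage < 0) .stopf("coverage must be >= 0")
  for (v in c(contamination, error, deam_prob, deam_decay, ref_c_prob))
    if (v < 0 || v >= 1) .stopf("probabilities must lie in [0, 1)")
  if (mean_length < 35) .stopf("mean_length must be >= 35")
  as.list(environment())
}

#' True haplotype alleles of a simulated individual
#'
#' Draws one derived(1)/ancestral(0) allele per haplotype per panel SNP
#' from the frequency of the haplotype's ancestry source (Neanderthal
#' inside truth tracts, modern outside). Seeded from the truth set's own
#' seed, so repeated read simulations ("libraries") of the same individual
#' share one genome.
#'
#' @param truth a [TruthSet-class].
#' @param panel_freqs output of [simulateArchaicPanel()].
#' @return integer matrix (SNPs x 2 haplotypes) of derived-allele
#'   indicators.
#' @export
simulateGenotypes <- function(truth, panel_freqs) {
  panel <- panel_freqs$panel
  n_snp <- nrow(panel)
  hap_src <- matrix("mod", n_snp, 2)
  segs <- truth@segments
  if (length(segs)) {
    snp_gr <- GRanges(panel$chrom, IRanges(panel$pos_bp, width = 1L))
    for (hap in 1:2) {
      sel <- segs[S4Vectors::mcols(segs)$hap == hap]
      if (length(sel)) {
        ov <- GenomicRanges::findOverlaps(snp_gr, sel)
        hap_src[unique(S4Vectors::queryHits(ov)), hap] <- "nea"
      }
    }
  }
  p_src <- function(hap) ifelse(hap_src[, hap] == "nea",
                                panel_freqs$p_nea, panel_freqs$p_afr)
  set.seed(.seed_stream(truth@params$seed, 104729L))
  cbind(rbinom(n_snp, 1L, p_src(1)), rbinom(n_snp, 1L, p_src(2)))
}

#' Simulate an ancient-DNA fragment table over a SNP panel
#'
#' Per panel SNP, read depth is Poisson with the spec's coverage (halved on
#' the X for males). Each read is a contaminant with probability c (allele
#' drawn from the contaminant-population frequency, no deamination) or
#' endogenous from a uniformly chosen haplotype; haplotype alleles are
#' drawn once per SNP from the frequency of the haplotype's ancestry source
#' (Neanderthal inside truth tracts, modern outside). Sequencing error
#' flips the read allele with probability e. Endogenous reads acquire
#' terminal C-to-T marks at distance k from either end with probability
#' delta * rho^(k-1) * P(reference C); a C (on +) / G-read-as-A (on -)
#' allele at the SNP itself is damage-flipped with the positional
#' probability, providing the substrate for damage masking.
#'
#' @param truth a [TruthSet-class] (its map supplies chromosome spans).
#' @param panel_freqs output of [simulateArchaicPanel()] (panel plus
#'   p_nea/p_afr/p_cont).
#' @param spec a [readSimSpec()].
#' @param seed RNG seed.
#' @param specimen_id specimen label.
#' @return A [FragmentTable-class]; one row per read (every read overlaps
#'   exactly one panel SNP).
#' @export
simulateReads <- function(truth, panel_freqs, spec = readSimSpec(),
                          seed = 1L, specimen_id = "sim1",
                          genotypes = NULL) {
  panel <- panel_freqs$panel
  n_snp <- nrow(panel)
  male <- identical(truth@params$sex, "male")
  on_x <- panel$chrom == "X"
  if (is.null(genotypes)) genotypes <- simulateGenotypes(truth, panel_freqs)
  hap_allele <- genotypes
  set.seed(seed)
  lambda <- rep(spec$coverage, n_snp)
  if (male) lambda[on_x] <- lambda[on_x] / 2
  depth <- rpois(n_snp, lambda)
  snp_of_read <- rep.int(seq_len(n_snp), depth)
  n_read <- length(snp_of_read)
  if (n_read == 0) return(FragmentTable(
    stats::setNames(data.frame(matrix(ncol = length(.fragment_cols), nrow = 0)),
                    .fragment_cols)))
  contam <- runif(n_read) < spec$contamination
  hap_pick <- sample.int(2L, n_read, replace = TRUE)
  if (male) hap_pick[on_x[snp_of_read]] <- 1L  # single X
  allele <- integer(n_read)
  allele[contam] <- rbinom(sum(contam), 1L,
                           panel_freqs$p_cont[snp_of_read[contam]])
  idx_end <- which(!contam)
  allele[idx_end] <- hap_allele[cbind(snp_of_read[idx_end], hap_pick[idx_end])]
  err <- runif(n_read) < spec$error
  allele[err] <- 1L - allele[err]
  # fragment geometry
  len <- 35L + rgeom(n_read, 1 / (spec$mean_length - 34))
  offset <- floor(runif(n_read) * len)
  pos5 <- offset + 1L
  pos3 <- len - offset
  strand <- ifelse(runif(n_read) < 0.5, "+", "-")
  start_bp <- panel$pos_bp[snp_of_read] - 1L - offset
  # terminal deamination marks (endogenous only), window of 10 positions
  kwin <- 10L
  deam_end <- function() {
    pos <- rep(NA_integer_, n_read)
    prob <- spec$deam_prob * spec$deam_decay^(seq_len(kwin) - 1) * spec$ref_c_prob
    hit <- matrix(runif(n_read * kwin) < rep(prob, each = n_read), n_read)
    hit[contam, ] <- FALSE
    any_hit <- rowSums(hit) > 0
    pos[any_hit] <- apply(hit[any_hit, , drop = FALSE], 1, which.max)
    pos
  }
  ct5 <- deam_end()
  ct3 <- deam_end()
  # damage at the SNP base itself: ref C -> T observed on + strand (alt
  # direction), i.e. an apparent alt 'T' on +, apparent 'A' on -
  dist_end <- pmin(pos5, pos3)
  p_dmg <- spec$deam_prob * spec$deam_decay^(dist_end - 1)
  dmg <- !contam & runif(n_read) < p_dmg
  base <- ifelse(allele == 1L, panel$alt[snp_of_read], panel$ref[snp_of_read])
  base[dmg & strand == "+" & base == "C"] <- "T"
  base[dmg & strand == "-" & base == "G"] <- "A"
  rec <- data.frame(
    fragment_id = paste0(specimen_id, "_f", seq_len(n_read)),
    specimen_id = specimen_id,
    chrom = panel$chrom[snp_of_read],
    start_bp = pmax(0L, as.integer(start_bp)),
    length_bp = as.integer(len),
    strand = strand,
    mapq = spec$mapq,
    ct_5p = .ct_flags(ct5), ct_3p = .ct_flags(ct3),
    ct5_pos = ct5, ct3_pos = ct3,
    snp_index = snp_of_read,
    allele = base,
    base_quality = spec$base_quality,
    pos_from_5p = as.integer(pos5), pos_from_3p = as.integer(pos3),
    stringsAsFactors = FALSE)
  FragmentTable(rec)
}
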