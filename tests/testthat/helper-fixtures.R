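# Shared fixtures for the test suite; everything is generated in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# a small genotype set built by hand
tiny_genotypes <- function() {
  snp <- data.frame(
    snp_id = paste0("rs", 1:4),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    pos_bp = c(100L, 200L, 150L, 400L),
    cm = c(0.01, 0.02, 0.015, 0.04),
    ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3"),
    population = c("popA", "popA", "popB"),
    ploidy = c("diploid", "diploid", "pseudohaploid"),
    stringsAsFactors = FALSE)
  geno <- matrix(c(0L, 1L, 2L,
                   2L, 2L, 0L,
                   NA, 1L, 2L,
                   1L, 0L, NA), nrow = 4, byrow = TRUE)
  GenotypeData(snp, samples, geno)
}

# two-anchor-per-chromosome test map
toy_map <- function(n_chrom = 2, total_cm = 200) uniformMap(n_chrom, total_cm)

# hand-built fragment record rows
frag_row <- function(fragment_id = "f1", chrom = "chr1", start_bp = 1000L,
                     length_bp = 50L, strand = "+", mapq = 37L,
                     ct5_pos = NA_integer_, ct3_pos = NA_integer_,
                     snp_index = 1L, allele = "T", base_quality = 40L,
                     pos_from_5p = 10L, pos_from_3p = NA) {
  if (is.na(pos_from_3p)) pos_from_3p <- length_bp - pos_from_5p + 1L
  data.frame(fragment_id = fragment_id, specimen_id = "spec1", chrom = chrom,
             start_bp = start_bp, length_bp = length_bp, strand = strand,
             mapq = mapq,
             ct_5p = !is.na(ct5_pos) & ct5_pos <= 3,
             ct_3p = !is.na(ct3_pos) & ct3_pos <= 3,
             ct5_pos = ct5_pos, ct3_pos = ct3_pos,
             snp_index = snp_index, allele = allele,
             base_quality = base_quality,
             pos_from_5p = pos_from_5p, pos_from_3p = pos_from_3p,
             stringsAsFactors = FALSE)
}

# random frequency table over an even SNP grid
random_freq_table <- function(n_snps, pops, seed, n_chrom = 10) {
  set.seed(seed)
  grid <- snpGrid(n_snps, n_chrom = n_chrom)
  p <- matrix(runif(n_snps * length(pops), 0.02, 0.98), n_snps,
              dimnames = list(NULL, pops))
  n <- matrix(sample(c(2, 10, 40), n_snps * length(pops), replace = TRUE),
              n_snps, dimnames = list(NULL, pops))
  freqTable(p, grid$chrom, grid$pos_bp, n = n)
}

# 5-leaf one-admixture truth graph shared by graph-fit tests; the
# root->outgroup edge is 0 by the fitting convention
admix_graph_5leaf <- function(alpha = 0.3) {
  e <- data.frame(
    child  = c("O", "N0", "N1", "N3", "P1", "P2", "P3", "Xm", "X"),
    parent = c("root", "root", "N0", "N0", "N1", "N3", "N3", "N1", "Xm"),
    type = c(rep("drift", 7), "admix", "drift"),
    value = c(0, 0.01, 0.01, 0.015, 0.02, 0.02, 0.025, alpha, 0.005))
  e <- rbind(e, data.frame(child = "Xm", parent = "N3", type = "admix",
                           value = NA))
  admixtureGraph(e, leaves = c("O", "P1", "P2", "P3", "X"))
}

free_graph <- function(graph) {
  e <- graph@edges
  e$value[!(e$child == "O" & e$type == "drift")] <- NA
  admixtureGraph(e, leaves = graph@leaves)
}

# simulate a genotype-sampled frequency table from a graph
sampled_freqs <- function(graph, pops, n_snps, seed, n_dip = 20) {
  p <- simulateGraphFrequencies(graph, n_snps, seed = seed)
  set.seed(seed + 5e5)
  grid <- snpGrid(n_snps)
  pm <- vapply(pops, function(pp) rbinom(n_snps, 2 * n_dip, p[, pp]) /
                 (2 * n_dip), numeric(n_snps))
  nm <- matrix(2 * n_dip, n_snps, length(pops),
               dimnames = list(NULL, pops))
  freqTable(pm, grid$chrom, grid$pos_bp, n = nm)
}

# archaic-ancestry admixture design for the direct f4-ratio: A/B are the
# two archaic genomes, O/C two modern outgroup populations, X the test
# individual carrying `alpha` archaic ancestry from the B-side source
f4_ratio_graph <- function(alpha = 0.03) {
  e <- data.frame(
    child  = c("ARC", "MOD", "A", "B0", "B", "O", "M0", "C", "X"),
    parent = c("root", "root", "ARC", "ARC", "B0", "MOD", "MOD", "M0", "Xm"),
    type = "drift",
    value = c(0.1, 0.02, 0.03, 0.02, 0.01, 0.01, 0.01, 0.01, 0.005))
  e <- rbind(e,
             data.frame(child = "Xm", parent = "B0", type = "admix",
                        value = alpha),
             data.frame(child = "Xm", parent = "M0", type = "admix",
                        value = NA))
  admixtureGraph(e, leaves = c("A", "B", "O", "C", "X"))
}

# frequency table for one f4-ratio replicate: archaics as single diploids,
# moderns as 20 diploids, X as one pseudo-haploid ancient
f4_ratio_freqs <- function(alpha, n_snps, seed) {
  g <- f4_ratio_graph(alpha)
  p <- simulateGraphFrequencies(g, n_snps, seed = seed)
  set.seed(seed + 7e5)
  grid <- snpGrid(n_snps)
  pm <- cbind(A = rbinom(n_snps, 2, p[, "A"]) / 2,
              B = rbinom(n_snps, 2, p[, "B"]) / 2,
              O = rbinom(n_snps, 40, p[, "O"]) / 40,
              C = rbinom(n_snps, 40, p[, "C"]) / 40,
              X = rbinom(n_snps, 1, p[, "X"]))
  nm <- matrix(rep(c(2, 2, 40, 40, 1), each = n_snps), n_snps, 5,
               dimnames = list(NULL, colnames(pm)))
  freqTable(pm, grid$chrom, grid$pos_bp, n = nm)
}

# naive direct f-statistic oracles (independent of the package internals)
naive_f2 <- function(pa, pb, na_, nb, corrected = TRUE) {
  out <- (pa - pb)^2
  if (corrected) {
    ca <- ifelse(na_ > 1, pa * (1 - pa) / (na_ - 1), 0)
    cb <- ifelse(nb > 1, pb * (1 - pb) / (nb - 1), 0)
    out <- out - ca - cb
  }
  out
}
naive_jackknife <- function(num, den, block) {
  ub <- unique(block)
  theta <- sum(num) / sum(den)
  tj <- vapply(ub, function(b) sum(num[block != b]) / sum(den[block != b]), 0)
  m <- vapply(ub, function(b) sum(block == b), 0)
  n <- sum(m); h <- n / m; B <- length(ub)
  tJ <- B * theta - sum((1 - m / n) * tj)
  se <- sqrt(sum((h * theta - (h - 1) * tj - tJ)^2 / (h - 1)) / B)
  list(est = theta, se = se)
}
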