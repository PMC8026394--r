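test_that("zero drift copies frequencies and alpha=1 admixture copies parent1", {
  e <- data.frame(child = c("A", "B"), parent = c("root", "root"),
                  type = "drift", value = c(0, 0.05))
  g <- admixtureGraph(e)
  p <- simulateGraphFrequencies(g, 500, seed = 1)
  expect_identical(p[, "A"], p[, "root"])
  e2 <- rbind(e, data.frame(child = "X", parent = "A", type = "admix",
                            value = 1),
                 data.frame(child = "X", parent = "B", type = "admix",
                            value = NA))
  p2 <- simulateGraphFrequencies(admixtureGraph(e2, leaves = c("A", "B", "X")),
                                 500, seed = 2)
  expect_identical(p2[, "X"], p2[, "A"])
  # drift >= 1 rejected
  e$value[2] <- 1
  expect_error(simulateGraphFrequencies(admixtureGraph(e), 10, seed = 1),
               "drift")
})

test_that("empirical f2 is additive along a drift path", {
  e <- data.frame(child = c("A", "B", "X"), parent = c("root", "root", "A"),
                  type = "drift", value = c(0.02, 0.03, 0))
  g <- admixtureGraph(e)
  p <- simulateGraphFrequencies(g, 50000, seed = 11)
  f2_emp <- (p[, "X"] - p[, "B"])^2
  mc_se <- sd(f2_emp) / sqrt(length(f2_emp))
  expect_lt(abs(mean(f2_emp) - 0.05), 3 * mc_se)
})

test_that("simulations are bit-reproducible given the seed", {
  g <- admixtureGraph(data.frame(child = c("A", "B"),
                                 parent = "root", type = "drift",
                                 value = c(0.01, 0.02)))
  expect_identical(simulateGraphFrequencies(g, 200, seed = 9),
                   simulateGraphFrequencies(g, 200, seed = 9))
  map <- toy_map()
  t1 <- simulatePedigreeTracts(map, g = 4, seed = 3)
  t2 <- simulatePedigreeTracts(map, g = 4, seed = 3)
  expect_identical(t1@segments, t2@segments)
  pf <- simulateArchaicPanel(map, snps_per_cm = 5, seed = 4)
  f1 <- simulateReads(t1, pf, readSimSpec(coverage = 1), seed = 5)
  f2 <- simulateReads(t2, pf, readSimSpec(coverage = 1), seed = 5)
  expect_identical(fragmentRecords(f1), fragmentRecords(f2))
})

test_that("g=1 recent tracts are whole chromosomes on one haplotype", {
  map <- toy_map()
  tr <- simulatePedigreeTracts(map, g = 1, alpha_bg = 0, seed = 2)
  spans <- chromSpansCM(map)
  m <- S4Vectors::mcols(tr@segments)
  expect_equal(sum(m$length_cm), sum(spans))
  expect_true(all(m$hap == 1L))
  expect_true(all(m$label == "recent"))
})

test_that("a zero-length chromosome map yields no crossovers: tract is all or nothing", {
  map <- GeneticMap(data.frame(chrom = "chr1", pos_bp = c(1, 2e6),
                               cm = c(0, 1e-9)))
  for (s in 1:10) {
    tr <- simulatePedigreeTracts(map, g = 4, alpha_bg = 0, seed = s)
    len <- truthLengths(tr, "recent")
    expect_true(length(len) == 0 ||
                  isTRUE(all.equal(sum(len), 1e-9, tolerance = 1e-3)))
  }
})

test_that("recent-tract diploid genome fraction approximates 2^-g over replicates", {
  map <- uniformMap(n_chrom = 8, total_cm = 1200)
  for (g in c(2, 5)) {
    fr <- vapply(1:120, function(i) {
      sum(truthLengths(simulatePedigreeTracts(map, g, alpha_bg = 0,
                                              seed = 9000 * g + i))) / 1200 / 2
    }, 0)
    se <- sd(fr) / sqrt(length(fr))
    expect_lt(abs(mean(fr) - 2^-g), 4 * se)
  }
})

test_that("mean recent-tract length matches the oracle-measured pedigree value", {
  # an independent check of the meiosis engine: after g meioses the
  # carrier-lineage breakpoints accumulate at (g-1)/100 per cM, so interior
  # tracts are ~Exp(100/(g-1)) cM, shortened by chromosome ends. For g=6 on
  # a 3,500-cM genome direct simulation gives ~17.2 cM (not 100/g).
  map <- uniformMap()
  lens <- unlist(lapply(1:30, function(i)
    truthLengths(simulatePedigreeTracts(map, 6, alpha_bg = 0, seed = 500 + i))))
  expect_gt(mean(lens), 100 / 6 - 3)
  expect_lt(mean(lens), 100 / 5 + 3)
})

test_that("background tracts have the requested stationary fraction and scale", {
  map <- uniformMap(n_chrom = 4, total_cm = 2000)
  tr <- simulatePedigreeTracts(map, g = 1, alpha_bg = 0.05, T_bg = 500,
                               seed = 31)
  m <- S4Vectors::mcols(tr@segments)
  bg <- m$length_cm[m$label == "background"]
  # two haplotypes x 2000 cM at stationary fraction 0.05
  expect_lt(abs(sum(bg) / 4000 - 0.05), 0.02)
  expect_lt(abs(mean(bg) - 100 / 500), 0.05)
})

test_that("null panel has star structure and rejects n_pops < 4", {
  expect_error(simulateNullPanel(3, 100, seed = 1), ">= 4")
  gd <- simulateNullPanel(4, 2000, seed = 1, drift = 0)
  fr <- alleleFreqs(gd)
  # zero drift: all populations share the root frequency, D identically 0
  d <- dPerSNP(fr, "pop1", "pop2", "pop3", "pop4")
  # sampling noise only; the frequency-level D with infinite sampling is 0:
  g2 <- admixtureGraph(data.frame(child = paste0("pop", 1:4),
                                  parent = "root", type = "drift", value = 0))
  p <- simulateGraphFrequencies(g2, 500, seed = 2)
  expect_true(all((p[, "pop1"] - p[, "pop2"]) * (p[, "pop3"] - p[, "pop4"]) == 0))
})

test_that("read simulation respects degenerate settings", {
  map <- toy_map()
  tr <- simulatePedigreeTracts(map, g = 3, alpha_bg = 0.02, seed = 41)
  pf <- simulateArchaicPanel(map, snps_per_cm = 10, seed = 42)
  geno <- simulateGenotypes(tr, pf)
  # c=0, e=0, deamination off: every read allele equals a true haplotype
  # allele and no ct flags anywhere
  f0 <- simulateReads(tr, pf, readSimSpec(coverage = 2, contamination = 0,
                                          error = 0, deam_prob = 0), seed = 43)
  r <- fragmentRecords(f0)
  expect_false(any(r$ct_5p) || any(r$ct_3p))
  der <- r$allele == pf$panel$alt[r$snp_index]
  hap_der <- geno[cbind(r$snp_index, 1L)] == 1L | geno[cbind(r$snp_index, 2L)] == 1L
  hap_anc <- geno[cbind(r$snp_index, 1L)] == 0L | geno[cbind(r$snp_index, 2L)] == 0L
  expect_true(all(ifelse(der, hap_der, hap_anc)))
  expect_error(simulateReads(tr, pf, readSimSpec(coverage = -1), seed = 1),
               "coverage")
})

test_that("fully contaminated reads follow the contaminant frequencies", {
  map <- toy_map(1, 50)
  tr <- simulatePedigreeTracts(map, g = 2, alpha_bg = 0, seed = 51)
  pf <- simulateArchaicPanel(map, snps_per_cm = 4, seed = 52)
  f1 <- simulateReads(tr, pf, readSimSpec(coverage = 60, contamination = 0.999,
                                          error = 0, deam_prob = 0), seed = 53)
  r <- fragmentRecords(f1)
  der <- r$allele == pf$panel$alt[r$snp_index]
  # chi-square of observed derived counts against binomial(p_cont) per SNP
  obs <- tapply(der, r$snp_index, sum)
  ntr <- tapply(der, r$snp_index, length)
  idx <- as.integer(names(obs))
  expected <- pf$p_cont[idx] * ntr
  chi <- sum((obs - expected)^2 / (expected * (1 - pf$p_cont[idx])))
  p_val <- pchisq(chi, df = length(obs), lower.tail = FALSE)
  expect_gt(p_val, 0.001)
  # contaminant reads carry no deamination even with deam_prob > 0
  f2 <- simulateReads(tr, pf, readSimSpec(coverage = 10, contamination = 0.999,
                                          deam_prob = 0.5), seed = 54)
  expect_lt(mean(fragmentRecords(f2)$ct_5p), 0.005)
})

test_that("terminal deamination rate at position 1 matches delta * refC availability", {
  map <- toy_map(1, 80)
  tr <- simulatePedigreeTracts(map, g = 2, alpha_bg = 0, seed = 61)
  pf <- simulateArchaicPanel(map, snps_per_cm = 20, seed = 62)
  sp <- readSimSpec(coverage = 15, contamination = 0, deam_prob = 0.3,
                    deam_decay = 0.5, ref_c_prob = 0.25)
  fr <- fragmentRecords(simulateReads(tr, pf, sp, seed = 63))
  at1 <- mean(!is.na(fr$ct5_pos) & fr$ct5_pos == 1)
  expected <- 0.3 * 0.25
  se <- sqrt(expected * (1 - expected) / nrow(fr))
  expect_lt(abs(at1 - expected), 4 * se)
})
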