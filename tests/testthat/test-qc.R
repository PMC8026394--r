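test_that("deamination filter implements inclusive OR and is idempotent", {
  r <- rbind(frag_row("f1", ct5_pos = 1L),               # 5' only
             frag_row("f2", ct3_pos = 3L),               # 3' only
             frag_row("f3", ct5_pos = 2L, ct3_pos = 1L), # both
             frag_row("f4"),                             # neither
             frag_row("f5", ct5_pos = 4L))               # outside window 3
  ft <- FragmentTable(r)
  out <- filterDeaminated(ft, k = 3)
  expect_identical(fragmentRecords(out)$fragment_id, c("f1", "f2", "f3"))
  expect_equal(attr(out, "retained_fraction"), 3 / 5)
  again <- filterDeaminated(out, k = 3)
  expect_identical(fragmentRecords(again), fragmentRecords(out))
  # wider window picks up f5
  expect_identical(fragmentRecords(filterDeaminated(ft, k = 4))$fragment_id,
                   c("f1", "f2", "f3", "f5"))
  expect_error(filterDeaminated(ft, k = 0), "k")
})

test_that("deamination filter output counts match flag counts", {
  set.seed(8)
  n <- 10
  flags <- c(rep(TRUE, 4), rep(FALSE, 6))
  r <- do.call(rbind, lapply(1:n, function(i)
    frag_row(paste0("f", i), ct5_pos = if (flags[i]) 1L else NA_integer_)))
  expect_equal(nFragments(filterDeaminated(FragmentTable(r))), 4L)
})

test_that("pseudo-haploid calling enforces quality and damage masks", {
  panel <- data.frame(snp_id = "s1", chrom = "chr1", pos_bp = 1000L, cm = 0.1,
                      ref = "C", alt = "T", stringsAsFactors = FALSE)
  # low base quality -> missing
  low <- FragmentTable(frag_row("f1", base_quality = 29L, pos_from_5p = 20L,
                                allele = "T"))
  expect_true(is.na(pseudohaploidCall(low, panel, seed = 1)[1]))
  # boundary quality retained
  ok <- FragmentTable(frag_row("f1", base_quality = 30L, pos_from_5p = 20L,
                               allele = "T"))
  expect_equal(pseudohaploidCall(ok, panel, seed = 1)[1], 2L)
  # damage-consistent T on + strand at distance 3 from the 5' end -> masked
  dmg <- FragmentTable(frag_row("f1", allele = "T", strand = "+",
                                pos_from_5p = 3L))
  expect_true(is.na(pseudohaploidCall(dmg, panel, seed = 1)[1]))
  # same position but a C allele is not damage-consistent
  cle <- FragmentTable(frag_row("f1", allele = "C", strand = "+",
                                pos_from_5p = 3L))
  expect_equal(pseudohaploidCall(cle, panel, seed = 1)[1], 0L)
  # A on - strand near the 3' end masked; A on + strand kept
  panelGA <- transform(panel, ref = "G", alt = "A")
  mneg <- FragmentTable(frag_row("f1", allele = "A", strand = "-",
                                 pos_from_5p = 25L, length_bp = 28L,
                                 mapq = 37L))
  mneg@records$length_bp <- 50L; mneg@records$pos_from_3p <- 4L
  expect_true(is.na(pseudohaploidCall(mneg, panelGA, seed = 1)[1]))
  mpos <- FragmentTable(frag_row("f1", allele = "A", strand = "+",
                                 pos_from_5p = 25L))
  expect_equal(pseudohaploidCall(mpos, panelGA, seed = 1)[1], 2L)
})

test_that("pseudo-haploid calls are deterministic, never heterozygous, and true to haplotypes", {
  map <- toy_map()
  tr <- simulatePedigreeTracts(map, g = 4, alpha_bg = 0.02, seed = 71)
  pf <- simulateArchaicPanel(map, snps_per_cm = 10, seed = 72)
  f0 <- simulateReads(tr, pf, readSimSpec(coverage = 2, contamination = 0,
                                          error = 0, deam_prob = 0), seed = 73)
  c1 <- pseudohaploidCall(f0, pf$panel, seed = 5)
  c2 <- pseudohaploidCall(f0, pf$panel, seed = 5)
  expect_identical(c1, c2)
  expect_true(all(c1 %in% c(0L, 2L, NA)))
  geno <- simulateGenotypes(tr, pf)
  called <- which(!is.na(c1))
  ok <- (c1[called] / 2 == geno[called, 1]) | (c1[called] / 2 == geno[called, 2])
  expect_true(all(ok))
})

test_that("conditional deamination contamination estimator has the closed-form limits", {
  # all fragments deaminated at both ends: r_u = r_c = 1 -> c = 0
  r <- do.call(rbind, lapply(1:50, function(i)
    frag_row(paste0("f", i), ct5_pos = 1L, ct3_pos = 1L)))
  est <- estimateContaminationDeam(FragmentTable(r))
  expect_equal(est@c_hat, 0)
  # no conditioning fragments: flagged undefined
  r2 <- do.call(rbind, lapply(1:50, function(i) frag_row(paste0("f", i))))
  est2 <- estimateContaminationDeam(FragmentTable(r2))
  expect_true("undefined_rc" %in% est2@flags)
})

test_that("contamination estimators converge on simulations as data grow", {
  map <- toy_map(2, 150)
  pf <- simulateArchaicPanel(map, snps_per_cm = 20, seed = 81)
  tr <- simulatePedigreeTracts(map, g = 3, alpha_bg = 0.02, seed = 82)
  bias <- vapply(c(1, 4, 16), function(cov) {
    sp <- readSimSpec(coverage = cov, contamination = 0.2, deam_prob = 0.4,
                      ref_c_prob = 0.4)
    fs <- simulateReads(tr, pf, sp, seed = 83)
    abs(estimateContaminationDeam(fs)@c_hat - 0.2)
  }, 0)
  expect_lt(bias[3], 0.05)
  expect_lt(bias[3], bias[1] + 0.02)
})

test_that("X-polymorphism estimator recovers contamination in males and refuses females", {
  map <- toy_map(2, 100)
  pf <- simulateArchaicPanel(map, snps_per_cm = 5, seed = 91, x_snps = 800,
                             x_cm = 180, ascertainment = "modern")
  tr <- simulatePedigreeTracts(map, g = 4, alpha_bg = 0.02, sex = "male",
                               seed = 92)
  sp <- readSimSpec(coverage = 12, contamination = 0.03, deam_prob = 0)
  fs <- simulateReads(tr, pf, sp, seed = 93)
  xp <- data.frame(snp_index = which(pf$panel$chrom == "X"),
                   ref = pf$panel$ref[pf$panel$chrom == "X"],
                   alt = pf$panel$alt[pf$panel$chrom == "X"],
                   p_cont = pf$p_cont[pf$panel$chrom == "X"])
  est <- estimateContaminationX(fs, xp)
  expect_gte(est@c_hat, 0.01)
  expect_lte(est@c_hat, 0.05)
  expect_error(estimateContaminationX(fs, xp, sex = "female"), "male")
  # all reads matching consensus -> c_hat ~ 0
  r0 <- do.call(rbind, lapply(1:200, function(i)
    frag_row(paste0("f", i), allele = "C", pos_from_5p = 20L,
             snp_index = (i %% 60) + 1L)))
  xp0 <- data.frame(snp_index = 1:60, ref = "C", alt = "T", p_cont = 0.5)
  est0 <- estimateContaminationX(FragmentTable(r0), xp0)
  expect_lt(est0@c_hat, 0.01)
})

test_that("sex determination separates simulated males and females", {
  map <- toy_map(4, 400)
  pf <- simulateArchaicPanel(map, snps_per_cm = 10, seed = 101, x_snps = 2000,
                             x_cm = 180)
  sp <- readSimSpec(coverage = 1, contamination = 0.02, deam_prob = 0.3)
  trm <- simulatePedigreeTracts(map, g = 5, sex = "male", seed = 102)
  trf <- simulatePedigreeTracts(map, g = 5, sex = "female", seed = 103)
  sm <- determineSex(simulateReads(trm, pf, sp, seed = 104), pf$panel)
  sf <- determineSex(simulateReads(trf, pf, sp, seed = 105), pf$panel)
  expect_identical(sm@call, "male")
  expect_identical(sf@call, "female")
  expect_lt(abs(sm@x_auto_ratio - 0.5), 0.1)
  expect_lt(abs(sf@x_auto_ratio - 1.0), 0.15)
  # tiny sample -> wide CI -> unresolved
  few <- fragmentRecords(simulateReads(trm, pf, readSimSpec(coverage = 0.002),
                                       seed = 106))
  expect_identical(determineSex(FragmentTable(few), pf$panel)@call,
                   "unresolved")
})

test_that("pairwise mismatch rate arithmetic, thresholds and small-overlap rule", {
  a <- rep(c(0L, 2L), 300)
  expect_equal(pairwiseMismatchRate(a, a)@pmr, 0)
  expect_identical(pairwiseMismatchRate(a, a)@verdict, "same_individual")
  # 13 mismatches over 100 sites: pmr 0.13 but inconclusive below 500 sites
  b <- a[1:100]
  b2 <- b; b2[1:13] <- 2L - b2[1:13]
  r <- pairwiseMismatchRate(b, b2)
  expect_equal(r@pmr, 0.13)
  expect_identical(r@verdict, "inconclusive")
  expect_error(pairwiseMismatchRate(c(0L, NA), c(NA, 0L)), "overlap")
})
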