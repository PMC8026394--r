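test_that("graph construction validates structure", {
  # cycle
  e <- data.frame(child = c("A", "B", "root"), parent = c("root", "A", "B"),
                  type = "drift", value = 0.1)
  expect_error(admixtureGraph(e), "acyclic|root")
  # two roots
  e2 <- data.frame(child = c("A", "B"), parent = c("r1", "r2"),
                   type = "drift", value = 0.1)
  expect_error(admixtureGraph(e2), "root")
  # negative drift
  e3 <- data.frame(child = "A", parent = "root", type = "drift", value = -1)
  expect_error(admixtureGraph(e3), ">= 0")
  # proportion out of range
  e4 <- data.frame(child = c("A", "B", "X", "X"),
                   parent = c("root", "root", "A", "B"),
                   type = c("drift", "drift", "admix", "admix"),
                   value = c(0.1, 0.1, 1.5, NA))
  expect_error(admixtureGraph(e4), "\\[0, 1\\]")
})

test_that("lineage weights: trees give 0/1 path indicators, admixture splits flow", {
  e <- data.frame(child = c("A", "B", "N", "C"),
                  parent = c("N", "N", "root", "root"),
                  type = "drift", value = 0.1)
  g <- admixtureGraph(e)
  w <- lineageWeights(g, "A")
  expect_equal(w, c(1, 0, 1, 0))
  # 50/50 admixture: each parent branch carries 0.5
  e2 <- data.frame(child = c("A", "B", "X", "X", "L"),
                   parent = c("root", "root", "A", "B", "X"),
                   type = c("drift", "drift", "admix", "admix", "drift"),
                   value = c(0.1, 0.1, 0.5, NA, 0.05))
  g2 <- admixtureGraph(e2, leaves = c("A", "B", "L"))
  w2 <- lineageWeights(g2, "L")
  expect_equal(w2[1:2], c(0.5, 0.5))
  # conservation: flow into the root sums to 1
  root_edges <- which(g2@edges$parent == "root")
  expect_equal(sum(w2[root_edges]), 1)
})

test_that("lineage weights agree with explicit path enumeration on a multi-admixture graph", {
  # two stacked admixtures; enumerate the four root paths by hand
  e <- data.frame(
    child  = c("A", "B", "C", "M1", "M1", "M2", "M2", "L"),
    parent = c("root", "root", "root", "A", "B", "M1", "C", "M2"),
    type = c("drift", "drift", "drift", "admix", "admix", "admix", "admix",
             "drift"),
    value = c(0.1, 0.1, 0.1, 0.6, NA, 0.7, NA, 0.05))
  g <- admixtureGraph(e, leaves = c("A", "B", "C", "L"))
  w <- lineageWeights(g, "L")
  # path probabilities: via M2->M1 (0.7) then A (0.6) or B (0.4); via C 0.3
  expect_equal(unname(w[1]), 0.7 * 0.6)   # edge A
  expect_equal(unname(w[2]), 0.7 * 0.4)   # edge B
  expect_equal(unname(w[3]), 0.3)         # edge C
  expect_equal(unname(w[8]), 1)           # leaf edge
})

test_that("expected f2/f3/f4 follow the path formalism and its identities", {
  e <- data.frame(
    child  = c("O", "N0", "N1", "C", "A", "B"),
    parent = c("root", "root", "N0", "N0", "N1", "N1"),
    type = "drift", value = c(0.005, 0.02, 0.03, 0.01, 0.012, 0.018))
  g <- admixtureGraph(e)
  expect_equal(expectedF2(g, "A", "A"), 0)
  # simple tree: sum of path edges
  expect_equal(expectedF2(g, "A", "B"), 0.012 + 0.018)
  expect_equal(expectedF2(g, "A", "C"), 0.012 + 0.03 + 0.01)
  # identities on a random admixture graph
  g2 <- admix_graph_5leaf(0.37)
  lv <- g2@leaves
  for (q in list(c("O", "P1", "P2", "X"), c("P1", "P2", "P3", "X"))) {
    lhs <- expectedF4(g2, q[1], q[2], q[3], q[4])
    rhs <- (expectedF2(g2, q[1], q[4]) + expectedF2(g2, q[2], q[3]) -
            expectedF2(g2, q[1], q[3]) - expectedF2(g2, q[2], q[4])) / 2
    expect_equal(lhs, rhs)
  }
  # expected f4 equals the edge-sum form by direct enumeration
  w <- lapply(setNames(lv, lv), function(l) lineageWeights(g2, l))
  d <- g2@edges$type == "drift"
  len <- g2@edges$value[d]
  direct <- sum(len * (w[["P1"]][d] - w[["P2"]][d]) *
                      (w[["P3"]][d] - w[["X"]][d]))
  expect_equal(expectedF4(g2, "P1", "P2", "P3", "X"), direct)
})

test_that("a noiseless tree is inverted exactly with zero residuals", {
  e <- data.frame(
    child  = c("O", "N0", "N1", "P3", "P1", "P2"),
    parent = c("root", "root", "N0", "N0", "N1", "N1"),
    type = "drift", value = c(0, 0.02, 0.015, 0.04, 0.02, 0.03))
  g <- admixtureGraph(e)
  ing <- setdiff(g@leaves, "O")
  prs <- list()
  for (i in seq_along(ing)) for (j in i:length(ing))
    prs[[length(prs) + 1]] <- c(ing[i], ing[j])
  f3o <- setNames(vapply(prs, function(pr)
    expectedF3(g, "O", pr[1], pr[2]), 0),
    vapply(prs, paste, "", collapse = ","))
  free <- e; free$value[free$child != "O"] <- NA
  fit <- fitGraph(admixtureGraph(free), "O", f3o, diag(length(f3o)))
  expect_true(fit$identifiable)
  expect_lt(max(abs(fit$graph@edges$value - e$value)), 1e-6)
  expect_lt(fit$objective, 1e-12)
})

test_that("objective never increases across refinement of admixture proportions", {
  gt <- admix_graph_5leaf(0.3)
  fr <- sampled_freqs(gt, gt@leaves, 20000, seed = 23)
  # trace the outer objective on a coarse then fine grid around the optimum
  ing <- setdiff(gt@leaves, "O")
  prs <- list()
  for (i in seq_along(ing)) for (j in i:length(ing))
    prs[[length(prs) + 1]] <- c(ing[i], ing[j])
  labs <- vapply(prs, paste, "", collapse = ",")
  num_mat <- vapply(prs, function(pr) {
    if (pr[1] == pr[2]) f2PerSNP(fr, "O", pr[1])
    else f3PerSNP(fr, "O", pr[1], pr[2])
  }, numeric(nrow(fr$p)))
  jk <- jackknifeCovariance(num_mat, fr$chrom, fr$pos_bp)
  free <- free_graph(gt)
  fit <- fitGraph(free, "O", setNames(jk$est, labs), jk$cov)
  # the returned optimum is at least as good as every grid evaluation
  covr <- jk$cov + diag(1e-6 * mean(diag(jk$cov)), nrow(jk$cov))
  U <- chol(solve(covr))
  objs <- vapply(seq(0, 1, 0.1), function(a) {
    gg <- ntracts:::.set_alphas(free, setNames(a, "Xm"))
    ntracts:::.fit_lengths(gg, "O", prs, jk$est, U)$objective
  }, 0)
  expect_lte(fit$objective, min(objs) + 1e-9)
})

test_that("fitGraphData recovers a simulated admixture and flags misspecification", {
  gt <- admix_graph_5leaf(0.3)
  fr <- sampled_freqs(gt, gt@leaves, 50000, seed = 29)
  fit <- fitGraphData(fr, free_graph(gt), "O")
  am <- fit@graph@edges$type == "admix"
  expect_gt(fit@graph@edges$value[am][1], 0.2)
  expect_lt(fit@graph@edges$value[am][1], 0.4)
  expect_lt(fit@worst_abs_z, 3.5)
  # admixture edge removed: X forced to be sister of P2
  e2 <- data.frame(
    child  = c("O", "N0", "N3", "P1", "N4", "X", "P2", "P3"),
    parent = c("root", "root", "N0", "N0", "N3", "N4", "N4", "N3"),
    type = "drift", value = c(0, rep(NA, 7)))
  fit2 <- fitGraphData(fr, admixtureGraph(e2, leaves = gt@leaves), "O")
  expect_gt(fit2@worst_abs_z, 3)
})

test_that("topology comparison ranks the generating model first", {
  gt <- admix_graph_5leaf(0.3)
  fr <- sampled_freqs(gt, gt@leaves, 30000, seed = 31)
  e2 <- data.frame(
    child  = c("O", "N0", "N3", "P1", "N4", "X", "P2", "P3"),
    parent = c("root", "root", "N0", "N0", "N3", "N4", "N4", "N3"),
    type = "drift", value = c(0, rep(NA, 7)))
  cmp <- compareTopologies(list(free_graph(gt),
                                admixtureGraph(e2, leaves = gt@leaves)),
                           fr, "O")
  expect_equal(cmp$topology[cmp$rank == 1], 1)
  # single topology: identity ranking
  one <- compareTopologies(list(free_graph(gt)), fr, "O")
  expect_equal(one$rank, 1)
  # mismatched leaf sets rejected
  e3 <- data.frame(child = c("O", "A", "B", "Q"),
                   parent = c("root", "root", "N", "N"), type = "drift",
                   value = NA)
  e3 <- rbind(e3, data.frame(child = "N", parent = "root", type = "drift",
                             value = NA))
  expect_error(compareTopologies(list(free_graph(gt), admixtureGraph(e3)),
                                 fr, "O"), "leaf set")
})

test_that("graph files with free parameters round trip through the edge-list TSV", {
  d <- withr::local_tempdir()
  writeLines(c("child\tparent\ttype\tvalue",
               "A\troot\tdrift\t0.02",
               "B\troot\tdrift\tfree",
               "X\tA\tadmix\t0.3",
               "X\tB\tadmix\tfree",
               "L\tX\tdrift\t0.01"), file.path(d, "g.tsv"))
  g <- readGraph(file.path(d, "g.tsv"))
  expect_true(is.na(g@edges$value[g@edges$child == "B"]))
  expect_equal(g@edges$value[g@edges$type == "admix"][1], 0.3)
  expect_setequal(g@leaves, "L")
})
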