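#' Construct an admixture graph
#'
#' @param edges data.frame with columns `child`, `parent`, `type`
#'   ("drift"/"admix"), `value`. Drift values are branch lengths in f2
#'   units (>= 0); admix values are the proportion assigned to the *first
#'   listed* admix edge of each admixture node (the second is its
#'   complement and its `value` is ignored and may be NA). `NA` drift
#'   lengths / proportions are free parameters for [fitGraph()].
#' @param leaves designated leaf set; defaults to nodes that are never
#'   parents.
#' @return An [AdmixtureGraph-class].
#' @export
admixtureGraph <- function(edges, leaves = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("child", "parent", "type", "value")
  if (!all(need %in% names(edges)))
    .stopf("edges must have columns %s", paste(need, collapse = ", "))
  if (!all(edges$type %in% c("drift", "admix")))
    .stopf("edge type must be 'drift' or 'admix'")
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")])
  if (!igraph::is_dag(g)) .stopf("graph must be acyclic")
  nodes <- unique(c(edges$child, edges$parent))
  roots <- setdiff(edges$parent, edges$child)
  if (length(roots) != 1) .stopf("graph must have exactly one root (found %d)",
                                 length(roots))
  for (nd in nodes) {
    ein <- which(edges$child == nd)
    if (length(ein) == 0) next
    types <- edges$type[ein]
    if (length(ein) == 1 && types != "drift")
      .stopf("node %s: a single incoming edge must be drift", nd)
    if (length(ein) == 2 && !all(types == "admix"))
      .stopf("node %s: two incoming edges must both be admix", nd)
    if (length(ein) > 2) .stopf("node %s: more than two incoming edges", nd)
  }
  dv <- edges$value[edges$type == "drift"]
  if (any(!is.na(dv) & dv < 0)) .stopf("drift lengths must be >= 0")
  av <- edges$value[edges$type == "admix"]
  if (any(!is.na(av) & (av < 0 | av > 1)))
    .stopf("admixture proportions must lie in [0, 1]")
  if (is.null(leaves)) leaves <- setdiff(edges$child, edges$parent)
  miss <- setdiff(leaves, nodes)
  if (length(miss)) .stopf("leaves not in graph: %s", paste(miss, collapse = ", "))
  methods::new("AdmixtureGraph", edges = edges, leaves = leaves)
}

#' @rdname admixtureGraph
#' @param path edge-list TSV with header child/parent/type/value ("free"
#'   or empty value = free parameter).
#' @export
readGraph <- function(path) {
  e <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = c("NA", "free", ""))
  e$value <- as.numeric(e$value)
  admixtureGraph(e)
}

setMethod("show", "AdmixtureGraph", function(object) {
  e <- object@edges
  cat(sprintf("AdmixtureGraph: %d nodes, %d drift edges, %d admixture nodes, leaves: %s\n",
              length(unique(c(e$child, e$parent))), sum(e$type == "drift"),
              sum(e$type == "admix") / 2,
              paste(object@leaves, collapse = ", ")))
})

.graph_root <- function(graph) setdiff(graph@edges$parent, graph@edges$child)

# nodes in child-before-parent order (flow direction leaf -> root)
.topo_up <- function(edges) {
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")])
  names(igraph::topo_sort(g, mode = "out"))
}

# lineage weights with precomputed topological order (hot path)
.lw <- function(edges, leaf, ord, prop) {
  flow <- setNames(numeric(length(ord)), ord)
  flow[leaf] <- 1
  w <- numeric(nrow(edges))
  for (nd in ord) {
    phi <- flow[[nd]]
    if (phi == 0) next
    ein <- which(edges$child == nd)
    if (length(ein) == 0) next
    pr <- if (length(ein) == 1) 1 else prop[ein]
    w[ein] <- w[ein] + phi * pr
    for (k in seq_along(ein)) {
      pn <- edges$parent[ein[k]]
      flow[[pn]] <- flow[[pn]] + phi * pr[k]
    }
  }
  w
}

# leaves x leaves matrix of expected f2 under a fully parameterized graph
.expected_f2_matrix <- function(graph) {
  e <- graph@edges
  ord <- .topo_up(e)
  prop <- .admix_props(e)
  leaves <- graph@leaves
  W <- vapply(leaves, function(l) .lw(e, l, ord, prop), numeric(nrow(e)))
  d <- e$type == "drift"
  len <- e$value[d]
  M <- matrix(0, length(leaves), length(leaves),
              dimnames = list(leaves, leaves))
  for (i in seq_along(leaves)) for (j in seq_len(i - 1)) {
    M[i, j] <- M[j, i] <- sum(len * (W[d, i] - W[d, j])^2)
  }
  M
}

# admixture proportion on each edge row (NA for drift edges); the second
# admix edge of a node gets 1 - alpha of the first
.admix_props <- function(edges) {
  prop <- rep(NA_real_, nrow(edges))
  for (nd in unique(edges$child[edges$type == "admix"])) {
    ein <- which(edges$child == nd)
    prop[ein[1]] <- edges$value[ein[1]]
    prop[ein[2]] <- 1 - edges$value[ein[1]]
  }
  prop
}

#' Lineage traversal probabilities
#'
#' For a lineage sampled in `leaf` and traced back to the root, returns the
#' probability that it traverses each edge. Admixture nodes split the flow
#' according to their proportions; at the root all flow is conserved
#' (weights on the root's incoming side sum to 1).
#'
#' @param graph an [AdmixtureGraph-class] with all admixture proportions set.
#' @param leaf leaf name.
#' @return numeric vector, one entry per row of `graph@edges`.
#' @export
lineageWeights <- function(graph, leaf) {
  edges <- graph@edges
  if (!leaf %in% unique(c(edges$child, edges$parent)))
    .stopf("unknown leaf: %s", leaf)
  prop <- .admix_props(edges)
  if (any(edges$type == "admix" & is.na(prop)))
    .stopf("admixture proportions must be set to compute lineage weights")
  ord <- .topo_up(edges)
  flow <- setNames(numeric(length(ord)), ord)
  flow[leaf] <- 1
  w <- numeric(nrow(edges))
  for (nd in ord) {
    phi <- flow[nd]
    if (phi == 0) next
    ein <- which(edges$child == nd)
    if (length(ein) == 0) next
    pr <- if (length(ein) == 1) 1 else prop[ein]
    w[ein] <- w[ein] + phi * pr
    for (k in seq_along(ein))
      flow[edges$parent[ein[k]]] <- flow[edges$parent[ein[k]]] + phi * pr[k]
  }
  w
}

#' Expected f-statistics under an admixture graph
#'
#' `expectedF2(graph, i, j)` evaluates sum over drift edges of
#' length * (w_i - w_j)^2, with w the [lineageWeights()]. f3 and f4 follow
#' from the f2 identities: f3(c; a, b) = (f2(c,a) + f2(c,b) - f2(a,b)) / 2
#' and f4(a, b; c, d) = (f2(a,d) + f2(b,c) - f2(a,c) - f2(b,d)) / 2.
#'
#' @param graph a fully parameterized [AdmixtureGraph-class].
#' @param i,j,a,b,c,d leaf names.
#' @return expected statistic value (f2 units).
#' @export
expectedF2 <- function(graph, i, j) {
  e <- graph@edges
  if (any(is.na(e$value[e$type == "drift"])))
    .stopf("all drift lengths must be set")
  wi <- lineageWeights(graph, i); wj <- lineageWeights(graph, j)
  d <- e$type == "drift"
  sum(e$value[d] * (wi[d] - wj[d])^2)
}

#' @rdname expectedF2
#' @export
expectedF3 <- function(graph, c, a, b) {
  (expectedF2(graph, c, a) + expectedF2(graph, c, b) - expectedF2(graph, a, b)) / 2
}

#' @rdname expectedF2
#' @export
expectedF4 <- function(graph, a, b, c, d) {
  (expectedF2(graph, a, d) + expectedF2(graph, b, c) -
   expectedF2(graph, a, c) - expectedF2(graph, b, d)) / 2
}

# per-edge coefficients of f3(O; i, j) as a linear function of drift-edge
# lengths, for a fixed admixture parameterization: (wO - wi) * (wO - wj)
.f3_design <- function(graph, outgroup, pairs, ord = NULL) {
  e <- graph@edges
  if (is.null(ord)) ord <- .topo_up(e)
  prop <- .admix_props(e)
  drift <- which(e$type == "drift")
  leaves <- unique(c(outgroup, unlist(pairs)))
  W <- vapply(leaves, function(l) .lw(e, l, ord, prop), numeric(nrow(e)))
  X <- t(vapply(pairs, function(pr) {
    ((W[, outgroup] - W[, pr[1]]) * (W[, outgroup] - W[, pr[2]]))[drift]
  }, numeric(length(drift))))
  colnames(X) <- paste(e$child[drift], e$parent[drift], sep = "<-")
  list(X = X, drift = drift)
}

.set_alphas <- function(graph, alphas) {
  # alphas: named by admixture node
  e <- graph@edges
  for (nd in names(alphas)) {
    ein <- which(e$child == nd & e$type == "admix")
    e$value[ein[1]] <- alphas[[nd]]
    e$value[ein[2]] <- NA  # complement, by convention
  }
  graph@edges <- e
  graph
}

.free_alpha_nodes <- function(graph) {
  e <- graph@edges
  out <- character()
  for (nd in unique(e$child[e$type == "admix"])) {
    ein <- which(e$child == nd & e$type == "admix")
    if (is.na(e$value[ein[1]])) out <- c(out, nd)
  }
  out
}

# inner solver: non-negative GLS over free drift lengths, fixed alphas
.fit_lengths <- function(graph, outgroup, pairs, obs, U, ord = NULL) {
  des <- .f3_design(graph, outgroup, pairs, ord)
  e <- graph@edges
  len <- e$value[des$drift]
  free <- is.na(len)
  fixed_part <- if (any(!free))
    des$X[, !free, drop = FALSE] %*% len[!free] else 0
  y <- obs - as.numeric(fixed_part)
  Cmat <- U %*% des$X[, free, drop = FALSE]
  d <- as.numeric(U %*% y)
  identifiable <- qr(Cmat)$rank == ncol(Cmat)
  sol <- tryCatch(pracma::lsqnonneg(Cmat, d), error = function(err) NULL)
  if (is.null(sol)) {
    # rank-deficient design (e.g. a grid endpoint collapsing two paths):
    # fall back to a ridge-stabilized solve, clipped to non-negative
    ridge <- crossprod(Cmat) + diag(1e-6 * max(diag(crossprod(Cmat)), 1),
                                    ncol(Cmat))
    x <- pmax(solve(ridge, crossprod(Cmat, d)), 0)
    sol <- list(x = as.numeric(x))
  }
  lenfit <- len
  lenfit[free] <- sol$x
  resid <- d - as.numeric(Cmat %*% sol$x)
  list(lengths = lenfit, objective = sum(resid^2), identifiable = identifiable,
       drift = des$drift)
}

#' Fit an admixture graph to outgroup-f3 statistics
#'
#' The basis is the set of outgroup-f3 statistics f3(O; i, j) over all
#' (unordered, including i = j) pairs of non-outgroup leaves. Free drift
#' lengths are fitted by non-negative generalized least squares (inner
#' solver); free admixture proportions by an outer deterministic grid over
#' \\[0, 1\\] in steps of 0.02 followed by golden-section refinement
#' (coordinate descent when several are free). The root-to-outgroup edge is
#' not identifiable from this basis (only its sum with the root's other
#' child edge is); fix it to 0 in the topology by convention.
#'
#' @param graph topology with free parameters as NA values.
#' @param outgroup leaf used as outgroup O.
#' @param f3_obs named numeric vector of observed f3(O; i, j), names
#'   "i,j".
#' @param f3_cov covariance matrix of `f3_obs` (e.g. from
#'   [jackknifeCovariance()]); regularized by adding 1e-6 * mean(diag) to
#'   the diagonal.
#' @param grid_step outer grid step for admixture proportions.
#' @return list(graph, objective, identifiable, alphas) with fitted values
#'   filled into the graph.
#' @export
fitGraph <- function(graph, outgroup, f3_obs, f3_cov, grid_step = 0.02) {
  pairs <- lapply(strsplit(names(f3_obs), ",", fixed = TRUE), trimws)
  covr <- f3_cov + diag(1e-6 * mean(diag(f3_cov)), nrow(f3_cov))
  U <- chol(solve(covr))
  free_a <- .free_alpha_nodes(graph)
  ord <- .topo_up(graph@edges)
  inner <- function(alphas) {
    gg <- if (length(alphas)) .set_alphas(graph, alphas) else graph
    .fit_lengths(gg, outgroup, pairs, as.numeric(f3_obs), U, ord)
  }
  alphas <- setNames(rep(0.5, length(free_a)), free_a)
  if (length(free_a) == 0) {
    best <- inner(alphas)
  } else {
    agrid <- seq(0, 1, by = grid_step)
    for (pass in seq_len(max(1L, length(free_a)))) {
      for (nd in free_a) {
        objs <- vapply(agrid, function(a) {
          alphas[nd] <- a; inner(alphas)$objective
        }, 0)
        a0 <- agrid[which.min(objs)]
        opt <- stats::optimize(function(a) {
          alphas[nd] <- a; inner(alphas)$objective
        }, lower = max(0, a0 - grid_step), upper = min(1, a0 + grid_step),
        tol = 1e-8)
        alphas[nd] <- opt$minimum
      }
    }
    best <- inner(alphas)
  }
  gg <- if (length(free_a)) .set_alphas(graph, alphas) else graph
  gg@edges$value[best$drift] <- best$lengths
  # fill complement admix values for readability
  pr <- .admix_props(gg@edges)
  am <- gg@edges$type == "admix"
  gg@edges$value[am] <- pr[am]
  list(graph = gg, objective = best$objective,
       identifiable = best$identifiable, alphas = alphas)
}

#' Fit an admixture graph to genotype/frequency data with full diagnostics
#'
#' Computes the outgroup-f3 basis and its block-jackknife covariance from a
#' frequency table, fits the graph with [fitGraph()], and evaluates the
#' residual Z of every f2, f3 and f4 combination of the graph's leaves
#' (observed minus fitted, divided by the observed statistic's jackknife
#' SE). The worst |Z| is the model diagnostic: a well-fitting graph has all
#' residuals within ~3 SE.
#'
#' @param freqs frequency table covering all graph leaves.
#' @param graph topology (free parameters NA).
#' @param outgroup outgroup leaf name.
#' @param block_mb jackknife block size.
#' @return A [GraphFit-class].
#' @export
fitGraphData <- function(freqs, graph, outgroup, block_mb = 5) {
  leaves <- graph@leaves
  ing <- setdiff(leaves, outgroup)
  prs <- list()
  for (i in seq_along(ing)) for (j in i:length(ing))
    prs[[length(prs) + 1]] <- c(ing[i], ing[j])
  labs <- vapply(prs, paste, "", collapse = ",")
  # diagonal entries f3(O; i, i) are f2(O, i) and need the i-population
  # sampling correction as well; off-diagonal pairs only the outgroup's
  num_mat <- vapply(prs, function(pr) {
    if (pr[1] == pr[2]) f2PerSNP(freqs, outgroup, pr[1], corrected = TRUE)
    else f3PerSNP(freqs, outgroup, pr[1], pr[2], corrected = TRUE)
  }, numeric(nrow(freqs$p)))
  jk <- jackknifeCovariance(num_mat, freqs$chrom, freqs$pos_bp, block_mb)
  f3_obs <- setNames(jk$est, labs)
  fit <- fitGraph(graph, outgroup, f3_obs, jk$cov)
  res <- .graph_residuals(freqs, fit$graph, block_mb)
  methods::new("GraphFit", graph = fit$graph, objective = fit$objective,
               residuals = res, worst_abs_z = max(abs(res$z), na.rm = TRUE),
               n_snps_used = as.integer(jk$n_snps),
               identifiable = fit$identifiable)
}

.graph_residuals <- function(freqs, graph, block_mb) {
  leaves <- graph@leaves
  F2 <- .expected_f2_matrix(graph)
  ef3 <- function(cc, a, b) (F2[cc, a] + F2[cc, b] - F2[a, b]) / 2
  ef4 <- function(a, b, cc, d) (F2[a, d] + F2[b, cc] - F2[a, cc] - F2[b, d]) / 2
  n <- length(leaves)
  # hoist per-leaf columns and correction terms out of the stat loop
  P <- lapply(setNames(leaves, leaves), function(l) freqs$p[, l])
  H <- lapply(setNames(leaves, leaves),
              function(l) .het_corr(freqs$p[, l], freqs$n[, l]))
  stats <- list(); fitted <- numeric()
  add <- function(stat, pops, per_snp, fit_val) {
    stats[[length(stats) + 1]] <<- list(stat = stat, pops = pops,
                                        num = per_snp)
    fitted[length(fitted) + 1] <<- fit_val
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- leaves[i]; b <- leaves[j]
    add("f2", c(a, b), (P[[a]] - P[[b]])^2 - H[[a]] - H[[b]], F2[a, b])
  }
  for (ci in seq_len(n)) {
    rest <- leaves[-ci]
    for (i in seq_len(length(rest) - 1)) for (j in (i + 1):length(rest)) {
      cc <- leaves[ci]; a <- rest[i]; b <- rest[j]
      add("f3", c(cc, a, b),
          (P[[cc]] - P[[a]]) * (P[[cc]] - P[[b]]) - H[[cc]], ef3(cc, a, b))
    }
  }
  if (n >= 4) {
    quads <- utils::combn(leaves, 4, simplify = FALSE)
    for (q in quads) {
      for (p in list(q, q[c(1, 3, 2, 4)], q[c(1, 4, 2, 3)]))
        add("f4", p, (P[[p[1]]] - P[[p[2]]]) * (P[[p[3]]] - P[[p[4]]]),
            ef4(p[1], p[2], p[3], p[4]))
    }
  }
  # single shared block layout, vectorized delete-one-block jackknife
  bi_key <- paste0(freqs$chrom, ":", floor(freqs$pos_bp / (block_mb * 1e6)))
  bi <- match(bi_key, unique(bi_key))
  B <- max(bi)
  num_mat <- vapply(stats, `[[`, numeric(length(bi)), "num")
  ok_mat <- !is.na(num_mat)
  num_mat[!ok_mat] <- 0
  sums_b <- rowsum(num_mat, bi)
  cnt_b <- rowsum(ok_mat * 1, bi)
  tot <- colSums(sums_b); ntot <- colSums(cnt_b)
  est <- tot / ntot
  rows <- lapply(seq_along(stats), function(s) {
    nb <- cnt_b[, s] > 0
    Bk <- sum(nb)
    loo <- (tot[s] - sums_b[nb, s]) / (ntot[s] - cnt_b[nb, s])
    m <- cnt_b[nb, s]; h <- ntot[s] / m
    tJ <- Bk * est[s] - sum((1 - m / ntot[s]) * loo)
    se <- sqrt(sum((h * est[s] - (h - 1) * loo - tJ)^2 / (h - 1)) / Bk)
    resid <- est[s] - fitted[s]
    z <- if (se > 0) resid / se else if (abs(resid) < 1e-12) 0 else Inf
    data.frame(statistic = stats[[s]]$stat,
               pops = paste(stats[[s]]$pops, collapse = ","),
               observed = est[s], fitted = fitted[s], se = se, z = z)
  })
  do.call(rbind, rows)
}

setMethod("show", "GraphFit", function(object) {
  cat(sprintf("GraphFit: objective %.4g, worst |Z| = %.2f over %d statistics (%d SNPs)%s\n",
              object@objective, object@worst_abs_z, nrow(object@residuals),
              object@n_snps_used,
              if (object@identifiable) "" else " [WARNING: non-identifiable]"))
})

#' Compare candidate topologies on the same data
#'
#' Fits each topology with [fitGraphData()] and ranks by worst |Z|, then by
#' objective. Ties (identical rounded keys) share a rank and are reported,
#' not broken.
#'
#' @param topologies list of [AdmixtureGraph-class] objects over the same
#'   leaf set.
#' @param freqs frequency table.
#' @param outgroup outgroup leaf.
#' @param block_mb jackknife block size.
#' @return data.frame ranking with columns topology, worst_abs_z,
#'   objective, rank; attribute "fits" holds the GraphFit objects.
#' @export
compareTopologies <- function(topologies, freqs, outgroup, block_mb = 5) {
  leafsets <- lapply(topologies, function(g) sort(g@leaves))
  if (length(unique(vapply(leafsets, paste, "", collapse = ","))) != 1)
    .stopf("all topologies must share one leaf set")
  fits <- lapply(topologies, fitGraphData, freqs = freqs, outgroup = outgroup,
                 block_mb = block_mb)
  wz <- vapply(fits, function(f) f@worst_abs_z, 0)
  ob <- vapply(fits, function(f) f@objective, 0)
  key <- order(wz, ob)
  rk <- integer(length(fits)); rk[key] <- seq_along(fits)
  # tie detection on rounded keys
  tied <- duplicated(round(wz, 6)) & duplicated(round(ob, 6))
  out <- data.frame(topology = seq_along(fits), worst_abs_z = wz,
                    objective = ob, rank = rk, tied = tied)
  out <- out[order(out$rank), ]
  attr(out, "fits") <- fits
  out
}
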