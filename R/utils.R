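#' @importFrom stats approx rbeta rbinom rpois runif rexp rgeom optim
#'   wilcox.test cor quantile qgamma qchisq pnorm setNames aggregate
#'   binom.test median sd
#' @importFrom utils head tail read.table write.table
NULL

# log-sum-exp along rows of a matrix
.logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- mx[bad]
  out
}

.logsumexp_vec <- function(v) {
  mx <- max(v)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(v - mx)))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Merge and sort a two-column matrix of [start, end) intervals (numeric,
# half-open, on a single sequence). Returns matrix with columns start, end.
.merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  s <- iv[, 1]; e <- iv[, 2]
  keep_s <- s[1]; out_s <- c(); out_e <- c()
  cur_s <- s[1]; cur_e <- e[1]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (s[i] <= cur_e) {
        cur_e <- max(cur_e, e[i])
      } else {
        out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
        cur_s <- s[i]; cur_e <- e[i]
      }
    }
  }
  out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
  m <- cbind(start = out_s, end = out_e)
  m[m[, 2] > m[, 1], , drop = FALSE]
}

# Intersection of two merged half-open interval sets (matrices start/end).
.intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  out <- vector("list", nrow(a))
  j <- 1L
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1], b[, 1]); e <- pmin(a[i, 2], b[, 2])
    keep <- e > s
    if (any(keep)) out[[i]] <- cbind(start = s[keep], end = e[keep])
  }
  m <- do.call(rbind, out)
  if (is.null(m))
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  m[order(m[, 1]), , drop = FALSE]
}

# Complement of a merged interval set within [0, span).
.complement_intervals <- function(iv, span) {
  if (nrow(iv) == 0) return(cbind(start = 0, end = span))
  s <- c(0, iv[, 2]); e <- c(iv[, 1], span)
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

.seed_stream <- function(seed, k) as.integer((seed + 7919 * k) %% .Machine$integer.max)
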