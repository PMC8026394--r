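#' Retain putatively deaminated fragments
#'
#' Keeps fragments showing a C-to-T substitution within the first `k`
#' and/or ("and/or" is inclusive OR) last `k` aligned positions — the
#' standard authentication filter for ancient DNA. Idempotent; the output
#' is always a subset of the input.
#'
#' @param frags a [FragmentTable-class].
#' @param k terminal window in bp (default 3).
#' @return Filtered `FragmentTable`; attribute `"retained_fraction"` holds
#'   the retained fragment fraction.
#' @export
filterDeaminated <- function(frags, k = 3L) {
  if (k < 1) .stopf("k must be >= 1")
  r <- frags@records
  keep <- .ct_flags(r$ct5_pos, k) | .ct_flags(r$ct3_pos, k)
  out <- FragmentTable(r[keep, , drop = FALSE])
  n_in <- length(unique(r$fragment_id))
  attr(out, "retained_fraction") <-
    if (n_in > 0) length(unique(r$fragment_id[keep])) / n_in else NA_real_
  out
}

#' Pseudo-haploid genotype calling with damage masking
#'
#' At each covered panel SNP one eligible read is chosen uniformly at
#' random (seeded, hence deterministic). Ineligible reads: base quality
#' below `min_bq`; failure of the standard length/mapping-quality filter;
#' or a damage-consistent allele — a T on a forward-strand read or an A on
#' a reverse-strand read within `mask_k` positions of either fragment end
#' (default 5, wider than the window-3 authentication filter). SNPs with no
#' eligible read are missing.
#'
#' @param frags a [FragmentTable-class].
#' @param panel SNP data.frame with columns `ref`, `alt` (row order defines
#'   `snp_index`).
#' @param min_bq minimum base quality (default 30).
#' @param mask_k damage-mask window in bp from either end.
#' @param seed RNG seed for the read draw.
#' @return integer vector over panel SNPs: derived dosage on the diploid
#'   scale (0 or 2; never heterozygous) or NA.
#' @export
pseudohaploidCall <- function(frags, panel, min_bq = 30L, mask_k = 5L,
                              seed = 1L) {
  r <- standardFilter(frags)@records
  r <- r[!is.na(r$snp_index), , drop = FALSE]
  calls <- rep(NA_integer_, nrow(panel))
  if (nrow(r) == 0) return(calls)
  near_end <- pmin(r$pos_from_5p, r$pos_from_3p) <= mask_k
  damage_like <- (r$strand == "+" & r$allele == "T") |
                 (r$strand == "-" & r$allele == "A")
  ok <- r$base_quality >= min_bq & !(near_end & damage_like)
  r <- r[ok, , drop = FALSE]
  if (nrow(r) == 0) return(calls)
  set.seed(seed)
  pick <- order(r$snp_index, runif(nrow(r)))
  r <- r[pick, , drop = FALSE]
  first <- !duplicated(r$snp_index)
  chosen <- r[first, , drop = FALSE]
  derived <- chosen$allele == panel$alt[chosen$snp_index]
  ancestral <- chosen$allele == panel$ref[chosen$snp_index]
  val <- ifelse(derived, 2L, ifelse(ancestral, 0L, NA_integer_))
  calls[chosen$snp_index] <- val
  calls
}

#' Contamination from conditional deamination
#'
#' Present-day contaminant DNA carries no terminal deamination, so the
#' unconditional rate of 5' C-to-T (r_u, over all fragments) is depressed
#' relative to the rate among fragments already deaminated at the 3' end
#' (r_c, which are all endogenous): c = 1 - r_u / r_c. The estimate
#' averages both end orderings; the SE combines binomial delta-method
#' errors of the two ratios (end-independence of deamination within
#' endogenous molecules is assumed).
#'
#' @param frags a [FragmentTable-class] (fragment-level flags are used; SNP
#'   overlap rows are deduplicated by fragment_id).
#' @return A [ContaminationEstimate-class]; flagged "undefined_rc" when no
#'   conditioning fragments exist.
#' @export
estimateContaminationDeam <- function(frags) {
  r <- frags@records
  r <- r[!duplicated(r$fragment_id), , drop = FALSE]
  n <- nrow(r)
  if (n == 0) .stopf("no fragments")
  one_dir <- function(u_flag, c_flag) {
    r_u <- mean(u_flag)
    nc <- sum(c_flag)
    if (nc == 0 || r_u == 0) return(list(c = NA_real_, var = NA_real_))
    r_c <- mean(u_flag[c_flag])
    if (r_c == 0) return(list(c = NA_real_, var = NA_real_))
    chat <- 1 - r_u / r_c
    v <- (r_u / r_c)^2 * (r_u * (1 - r_u) / n / r_u^2 +
                          r_c * (1 - r_c) / nc / r_c^2)
    list(c = chat, var = v)
  }
  d1 <- one_dir(r$ct_5p, r$ct_3p)
  d2 <- one_dir(r$ct_3p, r$ct_5p)
  ests <- c(d1$c, d2$c)
  vars <- c(d1$var, d2$var)
  okv <- !is.na(ests)
  if (!any(okv))
    return(methods::new("ContaminationEstimate", c_hat = NA_real_,
                        se = NA_real_, method = "conditional_deamination",
                        n_informative = as.integer(n), flags = "undefined_rc"))
  chat <- mean(ests[okv])
  se <- sqrt(sum(vars[okv]) / sum(okv)^2)
  methods::new("ContaminationEstimate",
               c_hat = min(max(chat, 0), 1), se = se,
               method = "conditional_deamination",
               n_informative = as.integer(n), flags = character())
}

#' Contamination from X-chromosome polymorphisms (males)
#'
#' A male carries a single X, so every endogenous X read should match the
#' site consensus up to sequencing error; mismatches in excess of the error
#' rate indicate contamination. Maximizes over (c, e) the likelihood
#' whose per-read term is c q + (1 - c) ((1 - e) m + e (1 - m)), with q the
#' contaminant-population frequency of the read's allele and m the
#' indicator that the read matches the majority consensus at its site.
#' The SE is curvature-based (observed information at the optimum).
#'
#' @param frags a [FragmentTable-class].
#' @param x_panel_freqs data.frame for X-panel SNPs with columns
#'   `snp_index` (matching the fragment table), `ref`, `alt`, `p_cont`
#'   (contaminant alt-allele frequency).
#' @param sex must be "male" — the single-X model is invalid for females.
#' @param min_sites flag "low_confidence" below this many informative
#'   polymorphic sites (default 50).
#' @return A [ContaminationEstimate-class].
#' @export
estimateContaminationX <- function(frags, x_panel_freqs, sex = "male",
                                   min_sites = 50L) {
  if (!identical(sex, "male"))
    .stopf("X-polymorphism contamination model requires a male (single X)")
  r <- standardFilter(frags)@records
  r <- r[!is.na(r$snp_index) & r$snp_index %in% x_panel_freqs$snp_index, ,
         drop = FALSE]
  if (nrow(r) == 0) .stopf("no X-chromosome reads")
  xi <- match(r$snp_index, x_panel_freqs$snp_index)
  is_alt <- r$allele == x_panel_freqs$alt[xi]
  is_ref <- r$allele == x_panel_freqs$ref[xi]
  keep <- is_alt | is_ref
  r <- r[keep, , drop = FALSE]; xi <- xi[keep]; is_alt <- is_alt[keep]
  # majority consensus per site
  alt_n <- rowsum(as.numeric(is_alt), xi)
  tot_n <- rowsum(rep(1, length(xi)), xi)
  cons_alt <- setNames(alt_n[, 1] * 2 >= tot_n[, 1], rownames(alt_n))
  m <- as.numeric(is_alt == cons_alt[as.character(xi)])
  pa <- x_panel_freqs$p_cont[xi]
  q <- ifelse(is_alt, pa, 1 - pa)
  nll <- function(par) {
    cc <- par[1]; ee <- par[2]
    -sum(log(pmax(cc * q + (1 - cc) * ((1 - ee) * m + ee * (1 - m)), 1e-12)))
  }
  fit <- optim(c(0.05, 0.005), nll, method = "L-BFGS-B",
               lower = c(0, 1e-6), upper = c(0.95, 0.2), hessian = TRUE)
  se <- tryCatch(suppressWarnings(sqrt(solve(fit$hessian)[1, 1])),
                 error = function(e) NA_real_)
  if (!is.na(se) && !is.finite(se)) se <- NA_real_
  n_sites <- length(unique(xi))
  flags <- if (n_sites < min_sites) "low_confidence" else character()
  methods::new("ContaminationEstimate",
               c_hat = min(max(fit$par[1], 0), 1), se = se,
               method = "x_polymorphism", n_informative = as.integer(nrow(r)),
               flags = flags)
}

setMethod("show", "ContaminationEstimate", function(object) {
  cat(sprintf("Contamination (%s): %.3f +/- %.3f (n = %d)%s\n",
              object@method, object@c_hat, object@se, object@n_informative,
              if (length(object@flags)) paste0(" [", paste(object@flags,
                collapse = ","), "]") else ""))
})

#' Genetic sex from X-to-autosome coverage
#'
#' rho = (X fragments / X target sites) / (autosomal fragments / autosomal
#' target sites): ~0.5 for males (one X vs two autosomal copies), ~1 for
#' females. The binomial CI on the X-fragment share of all fragments is
#' transformed to rho; male is called when the whole CI lies below 0.6,
#' female when it lies above 0.8, else unresolved.
#'
#' @param frags a [FragmentTable-class].
#' @param panel SNP data.frame with a `chrom` column; X sites are those
#'   with `chrom == x_chrom`.
#' @param x_chrom name of the X chromosome in the panel.
#' @return A [SexCall-class].
#' @export
determineSex <- function(frags, panel, x_chrom = "X") {
  r <- frags@records
  r <- r[!duplicated(r$fragment_id) & !is.na(r$snp_index), , drop = FALSE]
  s_x <- sum(panel$chrom == x_chrom)
  s_a <- sum(panel$chrom != x_chrom)
  if (s_x == 0 || s_a == 0) .stopf("panel must include X and autosomal sites")
  n_x <- sum(r$chrom == x_chrom)
  n_a <- sum(r$chrom != x_chrom)
  if (n_a == 0) .stopf("no autosomal fragments")
  rho_of <- function(p) (p / (1 - p)) * (s_a / s_x)
  bt <- binom.test(n_x, n_x + n_a)
  rho <- rho_of(n_x / (n_x + n_a))
  lo <- rho_of(bt$conf.int[1]); hi <- rho_of(bt$conf.int[2])
  call <- if (hi < 0.6) "male" else if (lo > 0.8) "female" else "unresolved"
  methods::new("SexCall", x_auto_ratio = rho, ci_low = lo, ci_high = hi,
               call = call)
}

setMethod("show", "SexCall", function(object) {
  cat(sprintf("SexCall: %s (X/autosome ratio %.3f, CI %.3f-%.3f)\n",
              object@call, object@x_auto_ratio, object@ci_low, object@ci_high))
})

#' Pairwise mismatch rate between pseudo-haploid call sets
#'
#' The fraction of jointly called panel SNPs at which two call sets
#' disagree: low for two samplings of one individual (mismatches only at
#' heterozygous sites), about twice as high for unrelated individuals. The
#' verdict threshold is a configurable midpoint between the same-individual
#' and unrelated cohort baselines; with fewer than `min_sites` overlapping
#' sites the comparison is inconclusive.
#'
#' @param callsA,callsB integer vectors from [pseudohaploidCall()] on the
#'   same panel.
#' @param threshold verdict threshold on the mismatch rate (default 0.18).
#' @param min_sites minimum overlap for a verdict (default 500).
#' @return A [PmrResult-class].
#' @export
pairwiseMismatchRate <- function(callsA, callsB, threshold = 0.18,
                                 min_sites = 500L) {
  if (length(callsA) != length(callsB))
    .stopf("call sets must be on the same panel")
  both <- !is.na(callsA) & !is.na(callsB)
  n <- sum(both)
  if (n == 0) .stopf("no overlapping called sites")
  pmr <- mean(callsA[both] != callsB[both])
  verdict <- if (n < min_sites) "inconclusive"
             else if (pmr < threshold) "same_individual"
             else "different_individuals"
  methods::new("PmrResult", pmr = pmr, n_overlapping_sites = as.integer(n),
               verdict = verdict)
}

setMethod("show", "PmrResult", function(object) {
  cat(sprintf("PMR: %.4f over %d sites -> %s\n", object@pmr,
              object@n_overlapping_sites, object@verdict))
})
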