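#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand reduce
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData assay
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' GeneticMap: piecewise-linear recombination map
#'
#' Stores per-chromosome anchor pairs (physical position in bp, genetic
#' position in cM). Physical and genetic coordinates must both be strictly
#' increasing within each chromosome; the first anchor's cM must be
#' non-negative. Queries between anchors are linearly interpolated and
#' queries beyond the terminal anchors are held constant (see
#' [interpolateCM()]).
#'
#' @slot anchors data.frame with columns `chrom`, `pos_bp`, `cm`.
#' @seealso [readGeneticMap()], [interpolateCM()], [bpFromCM()]
#' @export
setClass("GeneticMap", representation(anchors = "data.frame"))

setValidity("GeneticMap", function(object) {
  a <- object@anchors
  if (!all(c("chrom", "pos_bp", "cm") %in% names(a)))
    return("anchors must have columns chrom, pos_bp, cm")
  for (ch in unique(a$chrom)) {
    x <- a[a$chrom == ch, ]
    if (is.unsorted(x$pos_bp, strictly = TRUE))
      return(sprintf("pos_bp not strictly increasing on chromosome %s", ch))
    if (is.unsorted(x$cm, strictly = TRUE))
      return(sprintf("cm not strictly increasing on chromosome %s", ch))
    if (x$cm[1] < 0) return("cm of first anchor must be >= 0")
  }
  TRUE
})

#' GenotypeData: SNP panel with per-sample allele counts
#'
#' Extends `RangedSummarizedExperiment`. Rows are SNPs (a `GRanges` with
#' metadata columns `snp_id`, `cm`, `ref`, `alt`), columns are samples
#' (`colData` columns `sample_id`, `population`, `ploidy`). The single assay
#' `"geno"` holds derived(alt)-allele dosages on the diploid scale: 0, 1, 2
#' or `NA` for missing. Pseudo-haploid samples (ploidy `"pseudohaploid"`)
#' carry a single sampled allele coded 0/2 and are never heterozygous.
#'
#' @seealso [readEigenstrat()], [writeEigenstrat()], [alleleFreqs()]
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!"geno" %in% SummarizedExperiment::assayNames(object))
    return("assay 'geno' is required")
  g <- SummarizedExperiment::assay(object, "geno")
  if (!all(g %in% c(0L, 1L, 2L, NA)))
    return("geno entries must be 0, 1, 2 or NA")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "population", "ploidy")
  if (!all(need %in% names(cd)))
    return("colData must have sample_id, population, ploidy")
  if (!all(cd$ploidy %in% c("diploid", "pseudohaploid")))
    return("ploidy must be 'diploid' or 'pseudohaploid'")
  ph <- cd$ploidy == "pseudohaploid"
  if (any(ph) && any(g[, ph, drop = FALSE] == 1L, na.rm = TRUE))
    return("pseudo-haploid samples cannot be heterozygous (geno == 1)")
  mc <- names(S4Vectors::mcols(SummarizedExperiment::rowRanges(object)))
  if (!all(c("snp_id", "cm", "ref", "alt") %in% mc))
    return("rowRanges must carry snp_id, cm, ref, alt")
  TRUE
})

#' FragmentTable: per-read ancient-DNA fragment records
#'
#' One row per (fragment, overlapped SNP); fragments overlapping no panel
#' SNP have `snp_index = NA`. Fragment-level fields are repeated across a
#' fragment's SNP rows. Terminal C-to-T evidence is stored as `ct5_pos` /
#' `ct3_pos`, the 1-based distance of the nearest C-to-T substitution from
#' the 5' / 3' end (NA if none observed within the recorded window), from
#' which the conventional window-3 flags `ct_5p` / `ct_3p` are derived.
#'
#' @slot records data.frame, see [readFragments()] for the column contract.
#' @export
setClass("FragmentTable", representation(records = "data.frame"))

.fragment_cols <- c("fragment_id", "specimen_id", "chrom", "start_bp",
                    "length_bp", "strand", "mapq", "ct_5p", "ct_3p",
                    "ct5_pos", "ct3_pos", "snp_index", "allele",
                    "base_quality", "pos_from_5p", "pos_from_3p")

setValidity("FragmentTable", function(object) {
  r <- object@records
  if (!all(.fragment_cols %in% names(r)))
    return(paste("missing fragment columns:",
                 paste(setdiff(.fragment_cols, names(r)), collapse = ", ")))
  if (nrow(r) > 0) {
    if (!all(r$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
    p5 <- r$pos_from_5p[!is.na(r$pos_from_5p)]
    if (length(p5) && (any(p5 < 1) ||
        any(p5 > r$length_bp[!is.na(r$pos_from_5p)])))
      return("pos_from_5p out of [1, length_bp]")
  }
  TRUE
})

#' FStatResult: an f-statistic with block-jackknife uncertainty
#'
#' @slot statistic character, one of "f2", "f3", "f4", "D", "f4num",
#'   "f4den" or a label set by the caller.
#' @slot pops character vector of population labels in statistic order.
#' @slot estimate numeric point estimate (ratio of sums over SNPs).
#' @slot se weighted block-jackknife standard error.
#' @slot z estimate / se.
#' @slot n_blocks,n_snps integer counts entering the jackknife.
#' @export
setClass("FStatResult",
  representation(statistic = "character", pops = "character",
                 estimate = "numeric", se = "numeric", z = "numeric",
                 n_blocks = "integer", n_snps = "integer"))

setValidity("FStatResult", function(object) {
  if (length(object@se) && !is.na(object@se) && object@se < 0)
    return("se must be >= 0")
  TRUE
})

#' F4RatioResult: admixture proportion from a ratio of f4 statistics
#'
#' @slot alpha point estimate of the ancestry proportion.
#' @slot se jackknife standard error of the ratio.
#' @slot ci95 numeric(2), alpha +/- 1.96 se.
#' @slot numerator,denominator the two [FStatResult-class] components.
#' @slot reliable FALSE when the denominator f4 has |Z| < 3.
#' @export
setClass("F4RatioResult",
  representation(alpha = "numeric", se = "numeric", ci95 = "numeric",
                 numerator = "FStatResult", denominator = "FStatResult",
                 reliable = "logical"))

setValidity("F4RatioResult", function(object) {
  if (length(object@ci95) == 2 && object@ci95[1] > object@ci95[2])
    return("ci95 must be ordered")
  TRUE
})

#' AdmixtureGraph: phylogenetic network with drift and admixture edges
#'
#' Directed acyclic graph with a single root. Drift edges carry non-negative
#' lengths in f2 units (squared allele-frequency difference); admixture
#' nodes have exactly two incoming edges of type "admix" whose proportions
#' sum to 1. `NA` values mark free parameters to be fitted. Each admixture
#' node stores its proportion on the first listed admix edge; the second is
#' its complement.
#'
#' @slot edges data.frame with columns `child`, `parent`,
#'   `type` (`"drift"`/`"admix"`), `value` (length, proportion or NA).
#' @slot leaves character vector of designated leaf nodes.
#' @export
setClass("AdmixtureGraph",
  representation(edges = "data.frame", leaves = "character"))

#' GraphFit: fitted admixture graph with residual diagnostics
#'
#' @slot graph the [AdmixtureGraph-class] with fitted values filled in.
#' @slot objective generalized-least-squares objective at the optimum.
#' @slot residuals data.frame with one row per f2/f3/f4 leaf combination:
#'   `statistic`, `pops`, `observed`, `fitted`, `se`, `z`.
#' @slot worst_abs_z max |z| over the residual table.
#' @slot n_snps_used SNPs entering the fitted basis.
#' @slot identifiable FALSE when the design matrix is rank-deficient.
#' @export
setClass("GraphFit",
  representation(graph = "AdmixtureGraph", objective = "numeric",
                 residuals = "data.frame", worst_abs_z = "numeric",
                 n_snps_used = "integer", identifiable = "logical"))

#' ContaminationEstimate
#'
#' @slot c_hat estimated present-day contamination fraction in [0, 1].
#' @slot se delta-method or curvature-based standard error.
#' @slot method "conditional_deamination" or "x_polymorphism".
#' @slot n_informative fragments or reads informing the estimate.
#' @slot flags character vector of caveats (e.g. "low_confidence").
#' @export
setClass("ContaminationEstimate",
  representation(c_hat = "numeric", se = "numeric", method = "character",
                 n_informative = "integer", flags = "character"))

setValidity("ContaminationEstimate", function(object) {
  if (!is.na(object@c_hat) && (object@c_hat < 0 || object@c_hat > 1))
    return("c_hat must lie in [0, 1]")
  if (!is.na(object@se) && object@se < 0) return("se must be >= 0")
  TRUE
})

#' SexCall: genetic sex from the X/autosome coverage ratio
#'
#' @slot x_auto_ratio per-site X coverage divided by per-site autosomal
#'   coverage (about 0.5 for males, 1 for females).
#' @slot ci_low,ci_high binomial confidence bounds on the ratio.
#' @slot call "male", "female" or "unresolved".
#' @export
setClass("SexCall",
  representation(x_auto_ratio = "numeric", ci_low = "numeric",
                 ci_high = "numeric", call = "character"))

#' PmrResult: pairwise mismatch rate between two pseudo-haploid call sets
#'
#' @slot pmr mismatch fraction over jointly called sites.
#' @slot n_overlapping_sites sites called in both samples.
#' @slot verdict "same_individual", "different_individuals" or
#'   "inconclusive" (fewer than `min_sites` overlapping sites).
#' @export
setClass("PmrResult",
  representation(pmr = "numeric", n_overlapping_sites = "integer",
                 verdict = "character"))

#' DatingResult: generations to the most recent Neanderthal ancestor
#'
#' @slot g_hat maximum-likelihood estimate (generations, >= such that the
#'   truncated-exponential model applies).
#' @slot ci95 numeric(2); may hit the grid edges (see `flags`).
#' @slot n_segments_used segments above the length threshold.
#' @slot threshold_cm truncation threshold in cM.
#' @slot loglik data.frame with columns `g` and `loglik` (profile grid).
#' @slot method "profile" or "bootstrap".
#' @slot flags caveats such as "open_upper" or "degenerate".
#' @export
setClass("DatingResult",
  representation(g_hat = "numeric", ci95 = "numeric",
                 n_segments_used = "integer", threshold_cm = "numeric",
                 loglik = "data.frame", method = "character",
                 flags = "character"))

#' OverlapTest: segment-sharing correlation between two genomes
#'
#' @slot r Pearson correlation of binary window-ancestry vectors.
#' @slot ci95 block-bootstrap percentile interval.
#' @slot n_windows vector length.
#' @slot flags e.g. "zero_variance".
#' @export
setClass("OverlapTest",
  representation(r = "numeric", ci95 = "numeric", n_windows = "integer",
                 flags = "character"))

#' DesertTest: permutation test of segment depletion in deserts
#'
#' @slot observed_bp observed overlap of segments with deserts (bp).
#' @slot total_bp total segment length (bp).
#' @slot n_permutations number of random re-placements.
#' @slot p_depletion one-sided permutation p-value,
#'   (1 + #\{perm <= obs\}) / (1 + n_perm).
#' @slot null_summary numeric summary (quantiles) of the null overlaps.
#' @slot seed RNG seed used.
#' @export
setClass("DesertTest",
  representation(observed_bp = "numeric", total_bp = "numeric",
                 n_permutations = "integer", p_depletion = "numeric",
                 null_summary = "numeric", seed = "integer"))

#' TruthSet: simulated ancestry ground truth
#'
#' @slot segments `GRanges` of true Neanderthal-ancestry intervals with
#'   metadata columns `hap` (1/2), `label` ("recent"/"background"),
#'   `start_cm`, `end_cm`, `length_cm`.
#' @slot params list of the generating parameters (g, alpha_bg, T_bg, sex,
#'   contamination, error, seed, ...).
#' @slot map the [GeneticMap-class] the simulation ran on.
#' @export
setClass("TruthSet",
  representation(segments = "GRanges", params = "list", map = "GeneticMap"))
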