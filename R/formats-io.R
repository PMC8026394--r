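#' Construct a GenotypeData object
#'
#' @param snp data.frame with columns `snp_id`, `chrom`, `pos_bp` (1-based),
#'   `cm`, `ref`, `alt`. Positions must be strictly increasing within each
#'   chromosome.
#' @param samples data.frame with columns `sample_id`, `population`,
#'   `ploidy` ("diploid" or "pseudohaploid").
#' @param geno integer matrix (SNPs x samples) of derived-allele dosages
#'   0/1/2/NA on the diploid scale.
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(snp, samples, geno) {
  need <- c("snp_id", "chrom", "pos_bp", "cm", "ref", "alt")
  if (!all(need %in% names(snp)))
    .stopf("snp table must have columns %s", paste(need, collapse = ", "))
  if (!all(snp$ref %in% c("A", "C", "G", "T")) ||
      !all(snp$alt %in% c("A", "C", "G", "T")))
    .stopf("alleles must be one of A, C, G, T")
  for (ch in unique(snp$chrom)) {
    p <- snp$pos_bp[snp$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      .stopf("pos_bp must be strictly increasing within chromosome %s", ch)
    if (is.unsorted(snp$cm[snp$chrom == ch]))
      .stopf("cm must be non-decreasing within chromosome %s", ch)
  }
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(snp) || ncol(geno) != nrow(samples))
    .stopf("geno dimensions (%d x %d) do not match panel (%d) and samples (%d)",
           nrow(geno), ncol(geno), nrow(snp), nrow(samples))
  rr <- GRanges(snp$chrom, IRanges(snp$pos_bp, width = 1L),
                snp_id = snp$snp_id, cm = snp$cm, ref = snp$ref, alt = snp$alt)
  names(rr) <- snp$snp_id
  colnames(geno) <- samples$sample_id
  se <- SummarizedExperiment(assays = list(geno = geno), rowRanges = rr,
                             colData = DataFrame(samples, row.names = samples$sample_id))
  methods::new("GenotypeData", se)
}

#' @describeIn GenotypeData SNP panel metadata as a data.frame.
#' @param x A `GenotypeData` object.
#' @export
snpInfo <- function(x) {
  rr <- rowRanges(x)
  data.frame(snp_id = S4Vectors::mcols(rr)$snp_id,
             chrom = as.character(seqnames(rr)),
             pos_bp = start(rr), cm = S4Vectors::mcols(rr)$cm,
             ref = S4Vectors::mcols(rr)$ref, alt = S4Vectors::mcols(rr)$alt,
             row.names = NULL)
}

#' @describeIn GenotypeData the dosage matrix (SNPs x samples).
#' @export
genoMatrix <- function(x) assay(x, "geno")

#' @describeIn GenotypeData the sample table as a data.frame.
#' @export
sampleInfo <- function(x) as.data.frame(colData(x))

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d SNPs x %d samples (%d populations)\n",
              nrow(object), ncol(object),
              length(unique(colData(object)$population))))
})

## ---------------------------------------------------------------- EIGENSTRAT

#' Read an EIGENSTRAT genotype set
#'
#' Reads the ASCII 0/1/2/9 dialect: `geno` has one line per SNP and one
#' character per sample (9 = missing); `snp` is whitespace-separated with
#' columns snp_id, chrom, genetic position (Morgans), physical position,
#' ref, alt; `ind` has sample_id, sex, population. Ploidy is read from an
#' optional 4th `ind` column, defaulting to "diploid".
#'
#' @param geno_path,snp_path,ind_path paths to the three files.
#' @return A [GenotypeData-class] object; SNP order is preserved.
#' @export
readEigenstrat <- function(geno_path, snp_path, ind_path) {
  for (p in c(geno_path, snp_path, ind_path))
    if (!file.exists(p)) .stopf("file not found: %s", p)
  snp <- read.table(snp_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("snp_id", "chrom", "morgans", "pos_bp",
                                  "ref", "alt"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  ind <- read.table(ind_path, header = FALSE, stringsAsFactors = FALSE)
  names(ind)[1:3] <- c("sample_id", "sex", "population")
  ind$ploidy <- if (ncol(ind) >= 4) ind[[4]] else "diploid"
  lines <- readLines(geno_path)
  if (length(lines) != nrow(snp))
    .stopf("geno has %d lines but snp has %d records", length(lines), nrow(snp))
  widths <- nchar(lines)
  if (any(widths != nrow(ind)))
    .stopf("geno line width (%d) does not match ind count (%d)",
           widths[which(widths != nrow(ind))[1]], nrow(ind))
  codes <- matrix(utf8ToInt("0"), nrow = length(lines), ncol = nrow(ind))
  split <- strsplit(lines, "", fixed = TRUE)
  geno <- do.call(rbind, lapply(split, function(ch) {
    v <- match(ch, c("0", "1", "2", "9"))
    if (anyNA(v)) .stopf("invalid geno character")
    c(0L, 1L, 2L, NA)[v]
  }))
  samples <- data.frame(sample_id = ind$sample_id, population = ind$population,
                        ploidy = ind$ploidy, sex = ind$sex,
                        stringsAsFactors = FALSE)
  snp_df <- data.frame(snp_id = snp$snp_id, chrom = snp$chrom,
                       pos_bp = snp$pos_bp, cm = snp$morgans * 100,
                       ref = snp$ref, alt = snp$alt, stringsAsFactors = FALSE)
  GenotypeData(snp_df, samples, geno)
}

#' Write an EIGENSTRAT genotype set
#'
#' Inverse of [readEigenstrat()]; round-trips losslessly.
#'
#' @param data a [GenotypeData-class] object.
#' @param prefix output path prefix; writes `<prefix>.geno`, `.snp`, `.ind`.
#' @return Invisibly, the three file paths.
#' @export
writeEigenstrat <- function(data, prefix) {
  if (ncol(data) == 0) .stopf("cannot write an empty sample set")
  g <- genoMatrix(data)
  if (!all(g %in% c(0L, 1L, 2L, NA)))
    .stopf("unencodable allele count in geno matrix")
  chars <- matrix("9", nrow(g), ncol(g))
  chars[!is.na(g)] <- as.character(g[!is.na(g)])
  lines <- apply(chars, 1L, paste0, collapse = "")
  writeLines(lines, paste0(prefix, ".geno"))
  si <- snpInfo(data)
  write.table(data.frame(si$snp_id, si$chrom, format(si$cm / 100, digits = 10),
                         si$pos_bp, si$ref, si$alt),
              paste0(prefix, ".snp"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  sa <- sampleInfo(data)
  sex <- if ("sex" %in% names(sa)) sa$sex else "U"
  write.table(data.frame(sa$sample_id, sex, sa$population, sa$ploidy),
              paste0(prefix, ".ind"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".geno", ".snp", ".ind")))
}

## --------------------------------------------------------------- genetic map

#' Construct / read a genetic map
#'
#' The map file is a 3-column TSV (`chrom`, `pos_bp`, `cm`) with one header
#' line. Both coordinates must be strictly increasing within a chromosome.
#'
#' @param anchors data.frame with columns `chrom`, `pos_bp`, `cm`.
#' @return A [GeneticMap-class] object.
#' @export
GeneticMap <- function(anchors) methods::new("GeneticMap", anchors = anchors)

#' @rdname GeneticMap
#' @param path path to the TSV map file.
#' @export
readGeneticMap <- function(path) {
  a <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(a)[1:3] <- c("chrom", "pos_bp", "cm")
  GeneticMap(a)
}

#' @rdname GeneticMap
#' @param map a `GeneticMap`.
#' @export
writeGeneticMap <- function(map, path) {
  write.table(map@anchors, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "GeneticMap", function(object) {
  a <- object@anchors
  spans <- vapply(split(a$cm, a$chrom), function(x) diff(range(x)), 0)
  cat(sprintf("GeneticMap: %d chromosomes, %.1f cM total, %d anchors\n",
              length(spans), sum(spans), nrow(a)))
})

#' Interpolate genetic position
#'
#' Piecewise-linear interpolation of cM between anchors; constant
#' extrapolation beyond the terminal anchors. Monotone non-decreasing in
#' `pos_bp`.
#'
#' @param map a [GeneticMap-class].
#' @param chrom chromosome name (scalar).
#' @param pos_bp numeric vector of physical positions.
#' @return numeric vector of genetic positions in cM.
#' @export
interpolateCM <- function(map, chrom, pos_bp) {
  a <- map@anchors[map@anchors$chrom == chrom, ]
  if (nrow(a) == 0) .stopf("unknown chromosome: %s", chrom)
  if (nrow(a) == 1) return(rep(a$cm, length(pos_bp)))
  approx(a$pos_bp, a$cm, xout = pos_bp, rule = 2, ties = "ordered")$y
}

#' @rdname interpolateCM
#' @param cm numeric vector of genetic positions; the inverse mapping
#'   (bp from cM), constant-extrapolated beyond terminal anchors.
#' @export
bpFromCM <- function(map, chrom, cm) {
  a <- map@anchors[map@anchors$chrom == chrom, ]
  if (nrow(a) == 0) .stopf("unknown chromosome: %s", chrom)
  if (nrow(a) == 1) return(rep(a$pos_bp, length(cm)))
  approx(a$cm, a$pos_bp, xout = cm, rule = 2, ties = "ordered")$y
}

#' @rdname interpolateCM
#' @export
chromSpansCM <- function(map) {
  a <- map@anchors
  vapply(split(a, a$chrom), function(x) diff(range(x$cm)), 0)
}

## ---------------------------------------------------------------- region set

#' Read, write and normalize BED region sets
#'
#' Regions are held as `GRanges` (1-based closed, the Bioconductor
#' convention); BED files on disk are 0-based half-open and converted at the
#' boundary by rtracklayer. `readRegions` normalizes (sorts and merges
#' overlapping or bookended intervals).
#'
#' @param bed_path path to a BED3+ file.
#' @return A normalized `GRanges`.
#' @export
readRegions <- function(bed_path) {
  info <- file.info(bed_path)
  if (is.na(info$size)) .stopf("file not found: %s", bed_path)
  if (info$size == 0) return(GRanges())
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (any(width(gr) < 1)) .stopf("malformed interval: start >= end")
  normalizeRegions(gr)
}

#' @rdname readRegions
#' @param rs a `GRanges` region set.
#' @param path output path.
#' @export
writeRegions <- function(rs, path) {
  rtracklayer::export(rs, path, format = "BED")
  invisible(path)
}

#' @rdname readRegions
#' @export
normalizeRegions <- function(rs) {
  GenomicRanges::reduce(GenomicRanges::sort(rs), ignore.strand = TRUE)
}

#' @rdname readRegions
#' @export
totalBp <- function(rs) sum(as.numeric(width(rs)))

## ----------------------------------------------------------------- fragments

#' Construct, read and write fragment tables
#'
#' The fragment TSV is this package's own interchange format for per-read
#' ancient-DNA evidence (alignment ingestion is out of scope). Columns:
#' `fragment_id`, `specimen_id`, `chrom`, `start_bp` (0-based), `length_bp`,
#' `strand`, `mapq`, `ct_5p`, `ct_3p` (logical: C-to-T within the first /
#' last 3 aligned positions), `ct5_pos`, `ct3_pos` (distance of the nearest
#' terminal C-to-T from each end, NA if none), `snp_index` (1-based index
#' into the SNP panel, NA if the fragment overlaps no panel SNP), `allele`,
#' `base_quality`, `pos_from_5p`, `pos_from_3p`.
#'
#' @param records data.frame with the columns above.
#' @return A [FragmentTable-class].
#' @export
FragmentTable <- function(records) {
  methods::new("FragmentTable", records = as.data.frame(records))
}

#' @rdname FragmentTable
#' @param tsv_path path to a fragment TSV with a header line.
#' @export
readFragments <- function(tsv_path) {
  r <- data.table::fread(tsv_path, sep = "\t", header = TRUE,
                         na.strings = "NA", data.table = FALSE)
  miss <- setdiff(.fragment_cols, names(r))
  if (length(miss)) .stopf("missing fragment columns: %s",
                           paste(miss, collapse = ", "))
  r$chrom <- as.character(r$chrom)
  r$allele <- as.character(r$allele)
  r$strand <- as.character(r$strand)
  FragmentTable(r)
}

#' @rdname FragmentTable
#' @param frags a `FragmentTable`.
#' @param path output path.
#' @export
writeFragments <- function(frags, path) {
  data.table::fwrite(frags@records, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname FragmentTable
#' @export
fragmentRecords <- function(frags) frags@records

#' @rdname FragmentTable
#' @details `nFragments` counts distinct fragments (not SNP-overlap rows).
#' @export
nFragments <- function(frags) length(unique(frags@records$fragment_id))

#' Standard length / mapping-quality filter
#'
#' Retains fragments at least `min_length` bp long with mapping quality
#' greater than or equal to `min_mapq` (defaults 35 bp and 25, the
#' conventional ancient-DNA processing thresholds). Applied explicitly, not
#' silently, so callers can report filter counts.
#'
#' @param frags a [FragmentTable-class].
#' @param min_length,min_mapq thresholds (boundary values are retained).
#' @return Filtered `FragmentTable`.
#' @export
standardFilter <- function(frags, min_length = 35L, min_mapq = 25L) {
  r <- frags@records
  FragmentTable(r[r$length_bp >= min_length & r$mapq >= min_mapq, , drop = FALSE])
}

setMethod("show", "FragmentTable", function(object) {
  r <- object@records
  cat(sprintf("FragmentTable: %d fragments, %d SNP overlaps, %d specimens\n",
              length(unique(r$fragment_id)), sum(!is.na(r$snp_index)),
              length(unique(r$specimen_id))))
})

# derive window-3 boolean flags from damage positions
.ct_flags <- function(pos, k = 3L) !is.na(pos) & pos <= k
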