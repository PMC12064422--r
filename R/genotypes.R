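#' Genotype matrix for an inbred diversity panel
#'
#' A `geno_matrix` holds biallelic SNP dosages (alt-allele counts in
#' `{0, 1, 2, NA}`) for a panel of lines, together with per-variant
#' metadata.  Coordinates are 1-based and inclusive, as in VCF; variants
#' are kept strictly sorted by `(chrom, pos)` and all downstream windows
#' are defined on that convention.
#'
#' @param dosages numeric matrix, lines x variants, values in
#'   `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`; one row per column of `dosages`.
#' @param lines character vector of accession names, one per row of
#'   `dosages`.
#'
#' @return An object of class `geno_matrix`: a list with elements
#'   `lines`, `variants` (with a recomputed `maf` column) and `dosages`.
#' @export
geno_matrix <- function(dosages, variants, lines) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  lines <- as.character(lines)
  stopifnot(
    nrow(dosages) == length(lines),
    ncol(dosages) == nrow(variants),
    all(c("id", "chrom", "pos") %in% names(variants))
  )
  if (nrow(dosages) < 2L || ncol(dosages) < 1L)
    stop("a geno_matrix needs at least 2 lines and 1 variant", call. = FALSE)
  if (anyDuplicated(lines))
    stop("duplicated line names", call. = FALSE)
  if (anyDuplicated(variants$id))
    stop("duplicated variant ids", call. = FALSE)
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  if (any(variants$pos < 1))
    stop("positions must be >= 1", call. = FALSE)
  if (is.null(variants$ref)) variants$ref <- "A"
  if (is.null(variants$alt)) variants$alt <- "G"

  ## canonical order: (chrom, pos), chromosomes in order of first appearance
  chrom <- as.character(variants$chrom)
  chrom_lvl <- unique(chrom[order(suppressWarnings(as_chrom_rank(chrom)))])
  ord <- order(match(chrom, chrom_lvl), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  key <- paste(variants$chrom, variants$pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos) among variants", call. = FALSE)

  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$maf <- compute_maf(dosages)
  rownames(variants) <- NULL
  rownames(dosages) <- lines
  colnames(dosages) <- variants$id
  structure(list(lines = lines, variants = variants, dosages = dosages),
            class = "geno_matrix")
}

## natural chromosome ranking: numeric part if present, else lexicographic
as_chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(gsub("^[Cc]hr", "", chrom)))
  ifelse(is.na(num), rank(chrom), num)
}

## minor allele frequency per SNP column from non-missing dosages
compute_maf <- function(dosages) {
  f <- colMeans(dosages, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' @exportS3Method
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d lines x %d variants on %d chromosome(s)\n",
              length(x$lines), nrow(x$variants),
              length(unique(x$variants$chrom))))
  cat(sprintf("  missing dosages: %.2f%%; median MAF: %.3f\n",
              100 * mean(is.na(x$dosages)),
              stats::median(x$variants$maf, na.rm = TRUE)))
  invisible(x)
}

#' @exportS3Method
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by variant index or by region
#'
#' @param g a `geno_matrix`.
#' @param keep integer or logical index over variants.
#' @return a `geno_matrix` restricted to the kept variants.
#' @export
subset_variants <- function(g, keep) {
  geno_matrix(g$dosages[, keep, drop = FALSE],
              g$variants[keep, c("id", "chrom", "pos", "ref", "alt"),
                         drop = FALSE],
              g$lines)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF records are parsed with \pkg{vcfR}; only biallelic SNVs are kept
#' and the number of skipped multi-allelic records is reported as a
#' message.  The dosage TSV dialect has a `line` column followed by one
#' column per SNP named `chrom:pos` (ref/alt default to A/G, which is
#' what the simulator writes).
#'
#' @param path file to read.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return a `geno_matrix`.
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read genotype file: ", path, call. = FALSE)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !is.na(alt)
  n_skip <- sum(!biallelic)
  if (n_skip > 0)
    message(n_skip, " non-biallelic-SNV record(s) skipped")
  if (!any(biallelic))
    stop("no usable biallelic SNVs in ", path, call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  ## dosage = alt allele count; any missing allele -> NA
  dos <- gt_to_dosage(gt)
  id <- fix[, "ID"]
  no_id <- is.na(id) | id == "." | id == ""
  id[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  variants <- data.frame(id = id,
                         chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = ref[biallelic],
                         alt = alt[biallelic],
                         stringsAsFactors = FALSE)
  geno_matrix(t(dos), variants, colnames(gt))
}

gt_to_dosage <- function(gt) {
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0", "0")] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean %in% c("1/1", "1")] <- 2
  dos
}

read_genotypes_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "line")
    stop("dosage TSV must start with a 'line' column", call. = FALSE)
  snp_cols <- names(d)[-1]
  if (length(snp_cols) == 0)
    stop("no SNP columns in ", path, call. = FALSE)
  parts <- strsplit(snp_cols, ":", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("SNP columns must be named chrom:pos", call. = FALSE)
  variants <- data.frame(
    id = gsub(":", "_", snp_cols, fixed = TRUE),
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  dos <- as.matrix(d[, -1, drop = FALSE])
  geno_matrix(dos, variants, d$line)
}

#' Write genotypes to VCF or dosage TSV
#'
#' Both formats round-trip through [read_genotypes()]: the written file
#' re-reads to an equal `geno_matrix`.  The VCF carries genotypes only
#' (GT field; dosage 1 becomes `0/1`, missing becomes `./.`).
#'
#' @param g a `geno_matrix`.
#' @inheritParams read_genotypes
#' @export
write_genotypes <- function(g, path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "dosage_tsv") {
    d <- as.data.frame(g$dosages)
    names(d) <- paste0(g$variants$chrom, ":", g$variants$pos)
    d <- cbind(line = g$lines, d)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(g$variants), length(g$lines))
  for (v in c(0, 1, 2))
    gt[t(g$dosages) == v] <- gt_code[[as.character(v)]]
  header <- c("##fileformat=VCFv4.2",
              paste0("##source=salicoloc_", utils::packageVersion("salicoloc")),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$lines), collapse = "\t"))
  body <- paste(g$variants$chrom, g$variants$pos, g$variants$id,
                g$variants$ref, g$variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
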