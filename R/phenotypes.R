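#' Long-format phenotype table
#'
#' Replicated phenotype records for a two-treatment (control/saline)
#' trial: one row per `(line, trait, treatment, replicate)`.  The key
#' must be unique and `treatment` is restricted to the two-level set.
#'
#' @param records data.frame with columns `line`, `trait`, `treatment`,
#'   `replicate`, `value`.
#' @return the validated data.frame with class `pheno_table` prepended.
#' @export
pheno_table <- function(records) {
  d <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("line", "trait", "treatment", "replicate", "value")
  if (!all(need %in% names(d)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d <- d[, need]
  d$line <- as.character(d$line)
  d$trait <- as.character(d$trait)
  d$treatment <- as.character(d$treatment)
  d$replicate <- as.integer(d$replicate)
  d$value <- as.numeric(d$value)
  if (!all(d$treatment %in% c("control", "saline")))
    stop("treatment must be 'control' or 'saline'", call. = FALSE)
  if (any(d$replicate < 1L))
    stop("replicate must be >= 1", call. = FALSE)
  key <- paste(d$line, d$trait, d$treatment, d$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (line, trait, treatment, replicate) records",
         call. = FALSE)
  class(d) <- c("pheno_table", "data.frame")
  d
}

#' Read / write phenotype TSV
#'
#' Columns: `line trait treatment replicate value`.
#' @param path TSV file.
#' @return a `pheno_table`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path))
    stop("cannot read phenotype file: ", path, call. = FALSE)
  pheno_table(utils::read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
}

#' @rdname read_phenotypes
#' @param p a `pheno_table`.
#' @export
write_phenotypes <- function(p, path) {
  utils::write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-trait GWAS summary-statistic table
#'
#' One row per tested SNP, sorted by `(chrom, pos)`, with `p` in (0, 1]
#' and `neg_log10_p` consistent with it.  `trait` and `experiment`
#' label the scan the table came from.
#'
#' @param d data.frame with columns `trait`, `experiment`, `snp`,
#'   `chrom`, `pos`, `p`, and optionally `neg_log10_p`, `beta`, `maf`.
#' @return the validated data.frame with class `sumstat_table`.
#' @export
sumstat_table <- function(d) {
  d <- as.data.frame(d, stringsAsFactors = FALSE)
  need <- c("trait", "experiment", "snp", "chrom", "pos", "p")
  if (!all(need %in% names(d)))
    stop("sumstat table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d$chrom <- as.character(d$chrom)
  d$pos <- as.integer(d$pos)
  d$p <- as.numeric(d$p)
  if (any(!is.finite(d$p)) || any(d$p <= 0) || any(d$p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (is.null(d$neg_log10_p)) {
    d$neg_log10_p <- -log10(d$p)
  } else if (any(abs(d$neg_log10_p + log10(d$p)) > 1e-4)) {
    stop("neg_log10_p inconsistent with p", call. = FALSE)
  }
  if (is.null(d$beta)) d$beta <- NA_real_
  if (is.null(d$maf)) d$maf <- NA_real_
  ord <- order(match(d$chrom, unique(d$chrom[order(as_chrom_rank(d$chrom))])),
               d$pos)
  d <- d[ord, c("trait", "experiment", "snp", "chrom", "pos", "p",
                "neg_log10_p", "beta", "maf")]
  rownames(d) <- NULL
  class(d) <- c("sumstat_table", "data.frame")
  d
}

#' Read / write summary-statistic TSV
#'
#' Columns: `trait experiment snp chrom pos p neg_log10_p beta maf`.
#' @param path TSV file.
#' @return a `sumstat_table`.
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path))
    stop("cannot read sumstats file: ", path, call. = FALSE)
  sumstat_table(utils::read.table(path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE))
}

#' @rdname read_sumstats
#' @param s a `sumstat_table`.
#' @export
write_sumstats <- function(s, path) {
  utils::write.table(as.data.frame(s), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
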