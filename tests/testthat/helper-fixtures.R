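# fixtures built in code: tiny genotype matrices, VCF text, phenotypes

# deterministic little panel: n lines x m SNPs with given dosage matrix
tiny_geno <- function(dosages, pos = NULL, chrom = "chr1") {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  geno_matrix(dosages,
              data.frame(id = paste0("s", seq_len(m)), chrom = chrom,
                         pos = pos, ref = "A", alt = "G"),
              sprintf("L%02d", seq_len(nrow(dosages))))
}

# random valid dosage panel for property tests
random_geno <- function(n, m, seed, chrom = "chr1", span = 10000L) {
  set.seed(seed)
  pos <- sort(sample.int(span, m))
  dos <- matrix(sample(c(0, 2), n * m, replace = TRUE), n, m)
  ## make sure no column is constant
  for (j in seq_len(m))
    if (length(unique(dos[, j])) == 1) dos[1, j] <- 2 - dos[1, j]
  tiny_geno(dos, pos = pos, chrom = chrom)
}

# write a small VCF by hand (for reader tests independent of the writer)
write_test_vcf <- function(path, records, samples) {
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples),
                    collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

# phenotype table with given per-(line, treatment) means, sd 0
flat_pheno <- function(lines, trait, control, saline, n_reps = 2) {
  do.call(rbind, lapply(seq_along(lines), function(i) {
    data.frame(line = lines[i], trait = trait,
               treatment = rep(c("control", "saline"), each = n_reps),
               replicate = rep(seq_len(n_reps), 2),
               value = rep(c(control[i], saline[i]), each = n_reps))
  })) |> pheno_table()
}

# independent LD-pruning oracle: exhaustive greedy pass over all pairs
oracle_prune <- function(g, window_bp, r2_max) {
  m <- ncol(g$dosages)
  kept <- integer(0)
  for (k in seq_len(m)) {
    ok <- TRUE
    for (j in kept) {
      if (g$variants$pos[k] - g$variants$pos[j] <= window_bp) {
        r <- suppressWarnings(stats::cor(g$dosages[, k], g$dosages[, j],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2_max) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- c(kept, k)
  }
  g$variants$id[kept]
}

# sumstat table from explicit positions and -log10 p values
tiny_sumstats <- function(pos, nlp, chrom = "chr1", trait = "t",
                          experiment = "e1") {
  sumstat_table(data.frame(
    trait = trait, experiment = experiment,
    snp = paste0(chrom, "_", pos), chrom = chrom, pos = pos,
    p = 10^(-nlp)))
}
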