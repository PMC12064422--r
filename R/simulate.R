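#' QTL specification for the phenotype simulator
#'
#' A QTL sits on an existing simulated SNP and adds `effect` trait
#' units per alt allele.  Effects are given per trait and per
#' treatment, so a saline-only QTL (the salinity-tolerance situation of
#' interest) has a zero control entry.  Listing the same QTL for two or
#' more traits plants a true colocation.
#'
#' @param chrom,pos SNP coordinates (must match a simulated SNP).
#' @param effects named list: trait name -> numeric
#'   `c(control = ..., saline = ...)`.
#' @return an object of class `qtl_spec`.
#' @export
qtl_spec <- function(chrom, pos, effects) {
  stopifnot(is.list(effects), length(effects) >= 1, !is.null(names(effects)))
  effects <- lapply(effects, function(e) {
    e <- unlist(e)
    if (!all(c("control", "saline") %in% names(e)))
      stop("each QTL effect needs 'control' and 'saline' entries",
           call. = FALSE)
    if (!all(is.finite(e))) stop("QTL effects must be finite", call. = FALSE)
    e[c("control", "saline")]
  })
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 effects = effects), class = "qtl_spec")
}

#' Simulation configuration
#'
#' Defaults describe the panel the analysis is designed around: 300
#' inbred lines genotyped at ~2 SNPs/kb across five 2-Mb chromosomes,
#' founder-mosaic block LD, a MAF spectrum on \[0.05, 0.5\], and
#' split-plot-like phenotypes with three replicates per treatment.
#' `n_founders` and `ld_block_scale` are calibrated so that the all-null
#' per-window GWAS peak probability at the default colocation settings
#' (threshold 3, 100-kb windows) falls in the low-percent range
#' observed for real diversity panels of this kind.
#'
#' @param n_lines number of inbred lines.
#' @param chromosomes named numeric vector: chromosome name -> length bp.
#' @param snp_density expected SNPs per bp.
#' @param n_founders founder haplotypes per panel.
#' @param ld_block_scale bp scale of founder-mosaic switching; the
#'   founder label changes between SNPs `d` bp apart with probability
#'   `1 - exp(-d / ld_block_scale)`.
#' @param maf_range range the per-SNP alt-allele design frequency is
#'   drawn from, uniformly.
#' @param het_rate per-site heterozygosity rate (0 for fully inbred).
#' @param qtls list of [qtl_spec()] objects.
#' @param traits trait names to simulate.
#' @param treatment_means named list: trait -> `c(control=, saline=)`
#'   baseline means; defaults to 10/6 for every trait.
#' @param line_variance variance of the line-level random effect
#'   (shared across treatments and replicates within a line x trait).
#' @param residual_variance replicate-level residual variance.
#' @param n_reps replicates per (line, treatment); the trial layout
#'   uses three.
#' @param n_subpop number of subpopulations (1 = none; 2 splits the
#'   founder pool between two line groups to create population
#'   structure for exercising PC covariates).
#' @param seed integer seed fixing all randomness.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 300,
                       chromosomes = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6,
                                       chr4 = 2e6, chr5 = 2e6),
                       snp_density = 0.002,
                       n_founders = 8,
                       ld_block_scale = 50000,
                       maf_range = c(0.05, 0.5),
                       het_rate = 0,
                       qtls = list(),
                       traits = c("grain_yield", "filled_grains",
                                  "panicle_length", "shoot_biomass"),
                       treatment_means = NULL,
                       line_variance = 1,
                       residual_variance = 1,
                       n_reps = 3,
                       n_subpop = 1,
                       seed = 1) {
  if (is.null(names(chromosomes)) || any(names(chromosomes) == ""))
    stop("chromosomes must be a named vector of lengths", call. = FALSE)
  if (is.null(treatment_means))
    treatment_means <- stats::setNames(
      rep(list(c(control = 10, saline = 6)), length(traits)), traits)
  stopifnot(
    n_lines >= 2, snp_density > 0, n_founders >= 2, ld_block_scale > 0,
    length(maf_range) == 2, maf_range[1] >= 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2], het_rate >= 0, het_rate <= 1,
    line_variance >= 0, residual_variance >= 0, n_reps >= 1,
    n_subpop %in% c(1, 2), length(traits) >= 1
  )
  if (!all(traits %in% names(treatment_means)))
    stop("treatment_means must cover every trait", call. = FALSE)
  if (!all(vapply(qtls, inherits, TRUE, "qtl_spec")))
    stop("qtls must be a list of qtl_spec objects", call. = FALSE)
  for (q in qtls) {
    if (!all(names(q$effects) %in% traits))
      stop("QTL effect trait not in `traits`: ",
           paste(setdiff(names(q$effects), traits), collapse = ", "),
           call. = FALSE)
    if (!q$chrom %in% names(chromosomes))
      stop("QTL chromosome not simulated: ", q$chrom, call. = FALSE)
  }
  structure(list(
    n_lines = as.integer(n_lines), chromosomes = chromosomes,
    snp_density = snp_density, n_founders = as.integer(n_founders),
    ld_block_scale = ld_block_scale, maf_range = maf_range,
    het_rate = het_rate, qtls = qtls, traits = traits,
    treatment_means = treatment_means, line_variance = line_variance,
    residual_variance = residual_variance, n_reps = as.integer(n_reps),
    n_subpop = as.integer(n_subpop), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a block-LD genotype panel
#'
#' Founder-mosaic model: SNP positions are a homogeneous point process
#' at `snp_density` per chromosome; each SNP gets a design alt
#' frequency drawn uniformly from `maf_range` and `n_founders` founder
#' haplotypes carry Bernoulli(frequency) alleles.  Each inbred line is
#' a founder mosaic (switch probability `1 - exp(-d / ld_block_scale)`
#' between adjacent SNPs), doubled to a dosage in `{0, 2}`, with each
#' site then made heterozygous (dosage 1) with probability `het_rate`.
#' With `n_subpop = 2`, founders are split into two pools and each half
#' of the panel draws from its own pool, creating population structure.
#'
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a `geno_matrix`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_lines
  nf <- cfg$n_founders
  lines <- sprintf("L%04d", seq_len(n))
  ## founder pool per line (subpopulation mode splits the pool)
  if (cfg$n_subpop == 2) {
    if (nf < 4) stop("n_subpop = 2 needs n_founders >= 4", call. = FALSE)
    half <- nf %/% 2
    pool <- list(seq_len(half), seq(half + 1, nf))
    line_pool <- c(rep(1L, ceiling(n / 2)), rep(2L, floor(n / 2)))
  } else {
    pool <- list(seq_len(nf))
    line_pool <- rep(1L, n)
  }

  chrom_blocks <- vector("list", length(cfg$chromosomes))
  variant_blocks <- vector("list", length(cfg$chromosomes))
  for (ci in seq_along(cfg$chromosomes)) {
    cname <- names(cfg$chromosomes)[ci]
    len <- cfg$chromosomes[ci]
    m <- stats::rpois(1, len * cfg$snp_density)
    pos <- ceiling(stats::runif(m) * len)
    ## configured QTL positions are guaranteed to be SNPs
    qtl_pos <- vapply(Filter(function(q) q$chrom == cname, cfg$qtls),
                      `[[`, 0L, "pos")
    if (any(qtl_pos > len | qtl_pos < 1))
      stop("QTL position outside chromosome ", cname, call. = FALSE)
    pos <- sort(unique(c(pos, qtl_pos)))
    m <- length(pos)
    if (m == 0)
      stop("zero SNPs simulated on chromosome ", cname,
           "; raise snp_density", call. = FALSE)
    freq <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    founders <- matrix(stats::rbinom(nf * m, 1, rep(freq, each = nf)),
                       nrow = nf, ncol = m)
    switch_p <- 1 - exp(-diff(pos) / cfg$ld_block_scale)
    dos <- matrix(0, n, m)
    for (i in seq_len(n)) {
      seg <- cumsum(c(1L, stats::runif(m - 1) < switch_p))
      fidx <- pool[[line_pool[i]]][
        sample.int(length(pool[[line_pool[i]]]), seg[m], replace = TRUE)]
      dos[i, ] <- 2 * founders[cbind(fidx[seg], seq_len(m))]
    }
    if (cfg$het_rate > 0) {
      het <- matrix(stats::runif(n * m) < cfg$het_rate, n, m)
      dos[het] <- 1
    }
    chrom_blocks[[ci]] <- dos
    variant_blocks[[ci]] <- data.frame(
      id = paste0(cname, "_", pos), chrom = cname, pos = pos,
      ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  geno_matrix(do.call(cbind, chrom_blocks),
              do.call(rbind, variant_blocks), lines)
}

#' Simulate replicated control/saline phenotypes
#'
#' Model: `value(i, t, j, k) = mu_tj + sum_q a_qtj * x_iq + g_it +
#' e_itjk`, with line effects `g_it ~ N(0, line_variance)` shared
#' across treatments and replicates, and residuals
#' `e ~ N(0, residual_variance)` independent per record.  Deterministic
#' for fixed `cfg$seed` (a seed offset separates the phenotype stream
#' from the genotype stream).
#'
#' @param g a `geno_matrix` produced from the same configuration.
#' @param cfg a [sim_config()].
#' @return a `pheno_table`.
#' @export
simulate_phenotypes <- function(g, cfg) {
  stopifnot(inherits(g, "geno_matrix"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- length(g$lines)
  key <- paste(g$variants$chrom, g$variants$pos)
  ## genetic value per (line, trait, treatment) from planted QTLs
  gv <- array(0, dim = c(n, length(cfg$traits), 2),
              dimnames = list(NULL, cfg$traits, c("control", "saline")))
  for (q in cfg$qtls) {
    idx <- match(paste(q$chrom, q$pos), key)
    if (is.na(idx))
      stop("QTL position ", q$chrom, ":", q$pos,
           " absent from the genotype matrix", call. = FALSE)
    x <- g$dosages[, idx]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    for (tr in names(q$effects)) {
      gv[, tr, "control"] <- gv[, tr, "control"] + q$effects[[tr]]["control"] * x
      gv[, tr, "saline"] <- gv[, tr, "saline"] + q$effects[[tr]]["saline"] * x
    }
  }
  recs <- vector("list", length(cfg$traits))
  for (ti in seq_along(cfg$traits)) {
    tr <- cfg$traits[ti]
    line_eff <- stats::rnorm(n, 0, sqrt(cfg$line_variance))
    block <- expand.grid(replicate = seq_len(cfg$n_reps),
                         treatment = c("control", "saline"),
                         line_i = seq_len(n),
                         KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
    mu <- cfg$treatment_means[[tr]][block$treatment]
    value <- mu + gv[cbind(block$line_i, ti, match(block$treatment,
                                                  c("control", "saline")))] +
      line_eff[block$line_i] +
      stats::rnorm(nrow(block), 0, sqrt(cfg$residual_variance))
    recs[[ti]] <- data.frame(line = g$lines[block$line_i], trait = tr,
                             treatment = block$treatment,
                             replicate = block$replicate,
                             value = value, stringsAsFactors = FALSE)
  }
  pheno_table(do.call(rbind, recs))
}
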