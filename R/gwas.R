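#' GWAS scan configuration
#'
#' Defaults follow standard diversity-panel practice for this kind of
#' study: SNPs kept at MAF strictly > 0.05, LD pruning in 2-kb windows
#' at r^2 = 0.85, three principal-component covariates (or
#' BIC-selected), and a genome-wide significance level of 0.1 spread
#' over the effective number of independent tests.
#'
#' @param min_maf keep SNPs with MAF strictly greater than this.
#' @param prune_window_bp LD-pruning window in bp.
#' @param prune_r2 r^2 above which the later SNP of a pair is dropped.
#' @param n_pcs number of PC covariates, or `"bic"` for automatic
#'   selection up to `k_max`.
#' @param k_max upper bound for BIC selection.
#' @param alpha_gw genome-wide significance level before correction.
#' @param meff_block_bp block size (bp, by position) for block-wise
#'   effective-test-number computation.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(min_maf = 0.05, prune_window_bp = 2000,
                        prune_r2 = 0.85, n_pcs = 3, k_max = 10,
                        alpha_gw = 0.1, meff_block_bp = 5e5) {
  stopifnot(min_maf >= 0, min_maf < 0.5,
            prune_r2 > 0, prune_r2 <= 1,
            alpha_gw > 0, alpha_gw < 1,
            prune_window_bp > 0)
  if (!identical(n_pcs, "bic")) stopifnot(n_pcs >= 0)
  structure(list(min_maf = min_maf, prune_window_bp = prune_window_bp,
                 prune_r2 = prune_r2, n_pcs = n_pcs, k_max = k_max,
                 alpha_gw = alpha_gw, meff_block_bp = meff_block_bp),
            class = "scan_config")
}

#' Filter SNPs by minor allele frequency
#'
#' Keeps SNPs whose MAF (computed from non-missing dosages) is strictly
#' greater than `min_maf`; reports the removed count as a message.
#'
#' @param g a `geno_matrix`.
#' @param min_maf threshold (strict inequality).
#' @return the filtered `geno_matrix`.
#' @export
maf_filter <- function(g, min_maf = 0.05) {
  stopifnot(inherits(g, "geno_matrix"))
  maf <- g$variants$maf
  keep <- !is.na(maf) & maf > min_maf
  if (!any(keep))
    stop("all SNPs removed by the MAF filter", call. = FALSE)
  message(sum(!keep), " SNP(s) removed at MAF <= ", min_maf)
  subset_variants(g, keep)
}

## r^2 between two dosage columns; pairwise-complete, with mean
## imputation fallback when fewer than 3 lines are shared
dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    y[is.na(y)] <- mean(y, na.rm = TRUE)
    ok <- rep(TRUE, length(x))
  }
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(0)
  stats::cor(x[ok], y[ok])^2
}

#' Greedy LD pruning
#'
#' Forward pass per chromosome in position order: a SNP is dropped iff
#' its squared dosage correlation with any already-kept SNP within
#' `window_bp` upstream exceeds `r2_max`.  The later SNP of an
#' offending pair is always the one dropped, which makes the kept set
#' deterministic for sorted input.
#'
#' @param g a `geno_matrix` (sorted, as the class guarantees).
#' @param window_bp window in bp.
#' @param r2_max r^2 threshold (strict: drop iff r^2 > r2_max).
#' @return the pruned `geno_matrix`.
#' @export
ld_prune <- function(g, window_bp = 2000, r2_max = 0.85) {
  stopifnot(inherits(g, "geno_matrix"))
  keep <- logical(nrow(g$variants))
  for (chrom in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == chrom)
    pos <- g$variants$pos[idx]
    kept_local <- integer(0)
    for (k in seq_along(idx)) {
      inside <- kept_local[pos[kept_local] >= pos[k] - window_bp]
      drop <- FALSE
      for (j in rev(inside)) {   # nearest kept first
        if (dosage_r2(g$dosages[, idx[k]], g$dosages[, idx[j]]) > r2_max) {
          drop <- TRUE
          break
        }
      }
      if (!drop) {
        kept_local <- c(kept_local, k)
        keep[idx[k]] <- TRUE
      }
    }
  }
  subset_variants(g, keep)
}

## line x SNP dosage matrix with missing imputed to the SNP mean,
## columns mean-centred
centred_dosages <- function(g) {
  x <- g$dosages
  mu <- colMeans(x, na.rm = TRUE)
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) x[nas] <- mu[nas[, 2]]
  sweep(x, 2, colMeans(x))
}

#' Principal-component covariates for population structure
#'
#' PCs of the line x SNP dosage matrix (mean-imputed, column-centred),
#' computed from the line-by-line cross-product.  With `n_pcs = "bic"`
#' the number of PCs K is chosen in `0..k_max` to minimize
#' `n * ln(RSS/n) + (K + 1) * ln(n)` for the regression of the trait on
#' the first K PCs.
#'
#' @param g a `geno_matrix`.
#' @param n_pcs integer K, or `"bic"`.
#' @param y per-line trait values (required for `"bic"`).
#' @param k_max search bound for BIC selection.
#' @return lines x K matrix of PC scores (0 columns when K = 0), with
#'   attribute `"K"`.
#' @export
pca_covariates <- function(g, n_pcs = 3, y = NULL, k_max = 10) {
  stopifnot(inherits(g, "geno_matrix"))
  n <- length(g$lines)
  if (!identical(n_pcs, "bic") && n_pcs >= n)
    stop("K must be smaller than the number of lines", call. = FALSE)
  kmax_need <- if (identical(n_pcs, "bic")) k_max else n_pcs
  if (kmax_need == 0) {
    out <- matrix(0, n, 0, dimnames = list(g$lines, NULL))
    attr(out, "K") <- 0L
    return(out)
  }
  xc <- centred_dosages(g)
  eg <- eigen(tcrossprod(xc), symmetric = TRUE)
  nev <- min(kmax_need, n - 1)
  scores <- eg$vectors[, seq_len(nev), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(nev)], 0)), nev)
  rownames(scores) <- g$lines
  colnames(scores) <- paste0("PC", seq_len(nev))
  K <- if (identical(n_pcs, "bic")) {
    if (is.null(y)) stop("BIC selection needs trait values y", call. = FALSE)
    yv <- y[g$lines]
    ok <- !is.na(yv)
    bic <- vapply(0:nev, function(k) {
      X <- cbind(1, scores[ok, seq_len(k), drop = FALSE])
      rss <- sum(stats::lm.fit(X, yv[ok])$residuals^2)
      sum(ok) * log(rss / sum(ok)) + (k + 1) * log(sum(ok))
    }, 0)
    which.min(bic) - 1L
  } else min(n_pcs, nev)
  out <- scores[, seq_len(K), drop = FALSE]
  attr(out, "K") <- as.integer(K)
  out
}

#' Marginal association scan (OLS with covariates)
#'
#' Per SNP, ordinary least squares of the trait on dosage + covariates
#' + intercept; the reported p-value is the two-sided t-test on the
#' dosage coefficient.  Lines with missing trait values are dropped for
#' the whole scan; missing dosages are handled per SNP on complete
#' cases.  SNPs that are monomorphic among the used lines get p = 1
#' (keeping window occupancy stable downstream).
#'
#' @param g a `geno_matrix`.
#' @param y named per-line trait vector (names matched to `g$lines`).
#' @param covariates lines x K matrix (may have 0 columns).
#' @param trait,experiment labels written into the output table.
#' @return a `sumstat_table`.
#' @export
association_scan <- function(g, y, covariates = NULL,
                             trait = "trait", experiment = "exp1") {
  stopifnot(inherits(g, "geno_matrix"))
  if (is.null(names(y))) {
    if (length(y) != length(g$lines))
      stop("unnamed y must have one value per line", call. = FALSE)
    names(y) <- g$lines
  }
  yv <- y[g$lines]
  if (is.null(covariates)) covariates <- matrix(0, length(g$lines), 0)
  use <- !is.na(yv)
  n_use <- sum(use)
  p_par <- 1L + ncol(covariates)   # intercept + covariates
  if (n_use < p_par + 2L)
    stop("fewer usable lines than model parameters", call. = FALSE)
  yu <- yv[use]
  X0 <- cbind(`(Intercept)` = 1, covariates[use, , drop = FALSE])
  qr0 <- qr(X0)
  ey <- as.vector(qr.resid(qr0, yu))
  G <- g$dosages[use, , drop = FALSE]
  m <- ncol(G)
  has_na <- colSums(is.na(G)) > 0
  beta <- pval <- rep(NA_real_, m)

  fit_cols <- function(cols, Gc) {
    ## Gc: complete dosage submatrix for these columns
    E <- Gc - X0 %*% qr.coef(qr0, Gc)
    see <- colSums(E^2)
    mono <- see < 1e-12
    sy <- colSums(E * ey)
    b <- ifelse(mono, 0, sy / see)
    df <- n_use - p_par - 1L
    rss <- sum(ey^2) - b^2 * see
    se <- sqrt(pmax(rss, 0) / df / pmax(see, 1e-300))
    tt <- b / se
    pv <- 2 * stats::pt(-abs(tt), df)
    pv[mono] <- 1
    pv <- pmax(pv, .Machine$double.xmin)
    list(beta = b, p = pv, cols = cols)
  }

  if (any(!has_na)) {
    r <- fit_cols(which(!has_na), G[, !has_na, drop = FALSE])
    beta[r$cols] <- r$beta
    pval[r$cols] <- r$p
  }
  for (jj in which(has_na)) {
    x <- G[, jj]
    ok <- !is.na(x)
    nn <- sum(ok)
    if (nn < p_par + 2L || stats::sd(x[ok]) == 0) {
      beta[jj] <- 0
      pval[jj] <- 1
      next
    }
    X <- cbind(X0[ok, , drop = FALSE], x[ok])
    fit <- stats::lm.fit(X, yu[ok])
    rss <- sum(fit$residuals^2)
    df <- nn - ncol(X)
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(rss / df * XtXinv[ncol(X), ncol(X)])
    beta[jj] <- fit$coefficients[ncol(X)]
    pval[jj] <- max(2 * stats::pt(-abs(beta[jj] / se), df),
                    .Machine$double.xmin)
  }

  sumstat_table(data.frame(
    trait = trait, experiment = experiment,
    snp = g$variants$id, chrom = g$variants$chrom, pos = g$variants$pos,
    p = pval, beta = beta, maf = g$variants$maf,
    stringsAsFactors = FALSE))
}

## effective number of tests for one correlation spectrum:
## f(lambda) = 1{lambda >= 1} + (lambda - floor(lambda))
meff_from_eigen <- function(lambda) {
  lambda <- pmax(lambda, 0)
  ## f is discontinuous at integers; snap eigenvalues within numerical
  ## error of an integer so e.g. 5.999999999997 counts as 6, not 5 + 1
  near <- abs(lambda - round(lambda)) < 1e-8 * pmax(lambda, 1)
  lambda[near] <- round(lambda[near])
  sum((lambda >= 1) + (lambda - floor(lambda)))
}

#' Effective number of independent tests and genome-wide threshold
#'
#' Per chromosome, the eigenvalues of the SNP dosage correlation matrix
#' are mapped through `f(lambda) = 1{lambda >= 1} + (lambda -
#' floor(lambda))` and summed; chromosome contributions add up to Meff
#' and the genome-wide -log10 threshold is `-log10(alpha_gw / Meff)`.
#' For chromosomes longer than `block_bp` the spectrum is computed in
#' adjacent position blocks and summed, which bounds the matrix sizes
#' while slightly over-counting across block edges.  Constant SNP
#' columns are excluded from the correlation with a warning.
#'
#' @param g a `geno_matrix` (post MAF filter / pruning).
#' @param alpha_gw genome-wide significance level.
#' @param block_bp block size in bp.
#' @return list of class `meff_threshold`: `M`, `Meff`, `threshold`
#'   (in -log10 p units) and `alpha_gw`.
#' @export
meff_threshold <- function(g, alpha_gw = 0.1, block_bp = 5e5) {
  stopifnot(inherits(g, "geno_matrix"))
  xc <- centred_dosages(g)
  sds <- apply(xc, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant SNP column(s) excluded from Meff")
  }
  meff <- 0
  M <- 0L
  for (chrom in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == chrom & sds > 0)
    if (!length(idx)) next
    pos <- g$variants$pos[idx]
    block <- (pos - 1) %/% block_bp
    for (b in unique(block)) {
      cols <- idx[block == b]
      M <- M + length(cols)
      if (length(cols) == 1) {
        meff <- meff + 1
        next
      }
      cc <- stats::cor(xc[, cols, drop = FALSE])
      ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
      meff <- meff + meff_from_eigen(ev)
    }
  }
  if (M == 0) stop("no polymorphic SNPs for Meff", call. = FALSE)
  structure(list(M = M, Meff = meff,
                 threshold = -log10(alpha_gw / meff),
                 alpha_gw = alpha_gw),
            class = "meff_threshold")
}

#' @exportS3Method
print.meff_threshold <- function(x, ...) {
  cat(sprintf("M = %d SNPs, Meff = %.1f independent tests\n", x$M, x$Meff))
  cat(sprintf("genome-wide -log10(p) threshold at alpha = %g: %.3f\n",
              x$alpha_gw, x$threshold))
  invisible(x)
}

#' Full GWAS stage: filter, prune, covariates, scan
#'
#' Convenience wrapper chaining [maf_filter()], [ld_prune()],
#' [pca_covariates()] and [association_scan()] under one
#' [scan_config()].
#'
#' @param g a `geno_matrix`.
#' @param y named per-line trait vector.
#' @param cfg a [scan_config()].
#' @param trait,experiment labels for the output table.
#' @param threshold if `TRUE`, also compute [meff_threshold()].
#' @return list of class `gwas_fit`: `sumstats` (a `sumstat_table`),
#'   `genotypes` (the filtered/pruned `geno_matrix`), `covariates`, and
#'   optionally `threshold`.
#' @export
gwas_scan <- function(g, y, cfg = scan_config(), trait = "trait",
                      experiment = "exp1", threshold = FALSE) {
  g2 <- suppressMessages(maf_filter(g, cfg$min_maf))
  g2 <- ld_prune(g2, cfg$prune_window_bp, cfg$prune_r2)
  pcs <- pca_covariates(g2, cfg$n_pcs, y = y, k_max = cfg$k_max)
  ss <- association_scan(g2, y, pcs, trait = trait, experiment = experiment)
  out <- list(sumstats = ss, genotypes = g2, covariates = pcs)
  if (threshold)
    out$threshold <- meff_threshold(g2, cfg$alpha_gw, cfg$meff_block_bp)
  class(out) <- "gwas_fit"
  out
}

#' @exportS3Method
print.gwas_fit <- function(x, ...) {
  cat(sprintf("GWAS scan of '%s' (%s): %d SNPs after filtering/pruning, K = %d PCs\n",
              x$sumstats$trait[1], x$sumstats$experiment[1],
              nrow(x$sumstats), attr(x$covariates, "K")))
  top <- x$sumstats[which.max(x$sumstats$neg_log10_p), ]
  cat(sprintf("top SNP: %s (%s:%d), -log10 p = %.2f\n",
              top$snp, top$chrom, top$pos, top$neg_log10_p))
  if (!is.null(x$threshold)) print(x$threshold)
  invisible(x)
}
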