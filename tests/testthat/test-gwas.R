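test_that("MAF filtering uses a strict boundary on non-missing dosages", {
  g <- tiny_geno(cbind(c(0, 0, 2, 2), c(0, 0, 0, 0), c(0, 0, 0, 2)))
  expect_message(kept <- maf_filter(g, 0.05), "1 SNP")
  expect_equal(kept$variants$id, c("s1", "s3"))   # maf 0.5 and 0.25
  kept2 <- suppressMessages(maf_filter(g, 0.25))  # 0.25 not > 0.25
  expect_equal(kept2$variants$id, "s1")
  expect_error(suppressMessages(maf_filter(g, 0.5)), "all SNPs")
})

test_that("LD pruning drops the later SNP of correlated nearby pairs", {
  x <- c(0, 2, 0, 2, 2, 0)
  g <- tiny_geno(cbind(x, x), pos = c(1000L, 1500L))
  pruned <- ld_prune(g, window_bp = 2000, r2_max = 0.85)
  expect_equal(pruned$variants$id, "s1")
  ## same pair but outside the window survives
  g2 <- tiny_geno(cbind(x, x), pos = c(1000L, 6000L))
  expect_equal(nrow(ld_prune(g2, 2000, 0.85)$variants), 2L)
})

test_that("pruned sets agree with an exhaustive pairwise oracle", {
  for (seed in 1:20) {
    g <- random_geno(n = 30, m = sample(10:40, 1), seed = seed,
                     span = 8000L)
    pruned <- ld_prune(g, 2000, 0.5)
    expect_equal(pruned$variants$id, oracle_prune(g, 2000, 0.5),
                 info = paste("seed", seed))
    ## no kept pair within the window exceeds the bound
    pos <- pruned$variants$pos
    for (a in seq_along(pos)) for (b in seq_len(a - 1)) {
      if (pos[a] - pos[b] <= 2000) {
        r2 <- stats::cor(pruned$dosages[, a], pruned$dosages[, b])^2
        expect_lte(r2, 0.5 + 1e-12)
      }
    }
  }
})

test_that("maf_filter then ld_prune is idempotent", {
  g <- random_geno(40, 60, seed = 77, span = 20000L)
  once <- ld_prune(suppressMessages(maf_filter(g, 0.05)), 2000, 0.6)
  twice <- ld_prune(suppressMessages(maf_filter(once, 0.05)), 2000, 0.6)
  expect_identical(once$variants$id, twice$variants$id)
  expect_identical(once$dosages, twice$dosages)
})

test_that("PC covariates are orthogonal and optional", {
  g <- random_geno(40, 80, seed = 12, span = 50000L)
  pcs <- pca_covariates(g, 4)
  gram <- crossprod(pcs)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-6)
  p0 <- pca_covariates(g, 0)
  expect_equal(ncol(p0), 0L)
  expect_error(pca_covariates(g, 40), "smaller")
})

test_that("BIC selection finds structure when it matters", {
  cfg <- sim_config(n_lines = 100, chromosomes = c(chr1 = 3e5),
                    snp_density = 0.002, n_subpop = 2, seed = 15)
  g <- simulate_genotypes(cfg)
  pcs1 <- pca_covariates(g, 1)
  ## trait driven by the structure axis: BIC should keep >= 1 PC
  y <- stats::setNames(pcs1[, 1] + stats::rnorm(100, 0, 0.5 * stats::sd(pcs1[, 1])),
                       g$lines)
  pcs <- pca_covariates(g, "bic", y = y, k_max = 5)
  expect_gte(attr(pcs, "K"), 1L)
  ## pure noise trait: BIC should keep none
  set.seed(1)
  y0 <- stats::setNames(stats::rnorm(100), g$lines)
  pcs0 <- pca_covariates(g, "bic", y = y0, k_max = 5)
  expect_equal(attr(pcs0, "K"), 0L)
})

test_that("association scan matches the closed-form OLS oracle", {
  ## 6-line, 1-SNP worked case via the normal equations
  x <- c(0, 0, 2, 2, 0, 2)
  y <- c(1.0, 1.3, 2.9, 3.3, 0.8, 3.0)
  g <- tiny_geno(cbind(x, c(0, 2, 0, 2, 0, 2)))
  ss <- association_scan(g, stats::setNames(y, g$lines))
  xc <- x - mean(x)
  beta_hand <- sum(xc * y) / sum(xc^2)
  res <- y - mean(y) - beta_hand * xc
  se_hand <- sqrt(sum(res^2) / 4 / sum(xc^2))
  p_hand <- 2 * stats::pt(-abs(beta_hand / se_hand), 4)
  expect_equal(ss$beta[ss$snp == "s1"], beta_hand)
  expect_equal(ss$p[ss$snp == "s1"], p_hand)
})

test_that("a perfectly fitting SNP floors the p-value; monomorphic gives 1", {
  g <- tiny_geno(cbind(c(0, 2, 0, 2, 2, 0), c(2, 2, 2, 2, 2, 2)))
  y <- stats::setNames(g$dosages[, 1], g$lines)
  ss <- association_scan(g, y)
  expect_equal(ss$beta[1], 1)
  expect_lt(ss$p[1], 1e-200)
  expect_equal(ss$p[2], 1)   # constant dosage
})

test_that("p-values are invariant to affine transforms of the trait", {
  g <- random_geno(50, 30, seed = 8, span = 30000L)
  set.seed(99)
  y <- stats::setNames(rnorm(50), g$lines)
  s1 <- association_scan(g, y)
  s2 <- association_scan(g, 3.7 * y - 11)
  expect_equal(s1$p, s2$p, tolerance = 1e-9)
})

test_that("null scans produce approximately uniform p-values", {
  g <- random_geno(80, 200, seed = 42, span = 2000000L)
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed + 1000)
    y <- stats::setNames(rnorm(80), g$lines)
    ss <- association_scan(g, y)
    if (suppressWarnings(stats::ks.test(ss$p, "punif"))$p.value > 0.01)
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("Meff maps the correlation spectrum as specified", {
  ## mutually independent SNPs: Meff = M
  set.seed(3)
  n <- 400
  dos <- matrix(sample(c(0, 2), n * 10, replace = TRUE), n)
  g <- tiny_geno(dos)
  mt <- meff_threshold(g, alpha_gw = 0.1)
  expect_equal(mt$M, 10L)
  expect_lt(abs(mt$Meff - 10), 1.0)   # sampling noise off exact identity
  ## five copies of one SNP: spectrum (5,0,0,0,0) -> Meff = 1
  x <- sample(c(0, 2), n, replace = TRUE)
  g2 <- tiny_geno(matrix(x, n, 5))
  mt2 <- meff_threshold(g2)
  expect_equal(mt2$Meff, 1)
  expect_equal(mt2$threshold, -log10(0.1 / 1))
  ## exact on a hand-built spectrum: f(5)=1, f(0)=0
  expect_equal(salicoloc:::meff_from_eigen(c(5, 0, 0, 0, 0)), 1)
  expect_equal(salicoloc:::meff_from_eigen(c(1.4, 0.6)), 2)
})

test_that("Meff never exceeds M and the threshold orders accordingly", {
  for (seed in 1:15) {
    g <- random_geno(30, sample(5:25, 1), seed = seed + 500, span = 5000L)
    mt <- meff_threshold(g)
    expect_lte(mt$Meff, mt$M + 1e-9)
    expect_gte(mt$Meff, 1)
    expect_lte(mt$threshold, -log10(0.1 / mt$M))
  }
})
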