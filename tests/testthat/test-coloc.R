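test_that("window assignment uses inclusive 1-based tiling", {
  v <- data.frame(chrom = "chr1", pos = c(1, 100000, 100001, 300001))
  grid <- assign_windows(v, 100000)
  expect_equal(grid$Nwind, 3L)   # windows 1, 2 and 4
  expect_setequal(grid$occupied, c("chr1:1", "chr1:2", "chr1:4"))
  w <- grid$windows[grid$windows$window == "chr1:2", ]
  expect_equal(w$start, 100001)
  expect_equal(w$end, 200000)
  expect_error(assign_windows(v, 0), "positive")
})

test_that("significant windows honour the >= threshold boundary", {
  s <- tiny_sumstats(c(5000, 150000, 260000, 310000),
                     c(3.0, 2.999, 5.2, 0.1))
  grid <- assign_windows(s, 100000)
  pk <- significant_windows(s, grid, 3)
  expect_setequal(pk$significant, c("chr1:1", "chr1:3"))
  expect_equal(pk$p_trait, 2 / 4)
  ## all null -> none significant
  s0 <- tiny_sumstats(c(5000, 150000), c(0, 0))
  pk0 <- significant_windows(s0, assign_windows(s0, 100000), 3)
  expect_equal(length(pk0$significant), 0L)
  expect_equal(pk0$p_trait, 0)
})

test_that("pair counts equal the brute-force window intersection", {
  set.seed(17)
  for (i in 1:10) {
    pos <- sort(sample.int(2e6, 150))
    nlp_a <- stats::rexp(150); nlp_b <- stats::rexp(150)
    sa <- tiny_sumstats(pos, nlp_a, trait = "a")
    sb <- tiny_sumstats(pos, nlp_b, trait = "b")
    grid <- assign_windows(sa, 100000)
    pa <- significant_windows(sa, grid, 1.5)
    pb <- significant_windows(sb, grid, 1.5)
    ## oracle: enumerate windows and intersect explicitly
    wa <- unique(ceiling(pos[nlp_a >= 1.5] / 1e5))
    wb <- unique(ceiling(pos[nlp_b >= 1.5] / 1e5))
    expect_equal(coloc_pair_count(pa, pb), length(intersect(wa, wb)))
  }
  ## grid mismatch is an error
  s1 <- tiny_sumstats(c(100, 200), c(1, 1))
  g1 <- assign_windows(s1, 1000)
  g2 <- assign_windows(s1, 2000)
  p1 <- significant_windows(s1, g1, 1)
  p2 <- significant_windows(s1, g2, 1)
  expect_error(coloc_pair_count(p1, p2), "grids")
})

test_that("the colocation z test follows its defining formulas", {
  ## obs equal to expectation: z = 0, P = 0.5
  tst <- coloc_z_test(5, sqrt(0.05), sqrt(0.05), 100)
  expect_equal(tst$expected, 5)
  expect_equal(tst$z, 0)
  expect_equal(tst$p.value, 0.5)
  ## full formula check
  t2 <- coloc_z_test(7, 0.2, 0.1, 200)
  expect_equal(t2$expected, 200 * 0.02)
  expect_equal(t2$sigma, sqrt(200 * 0.02 * 0.98))
  expect_equal(t2$p.value, stats::pnorm((7 - 4) / sqrt(200 * 0.02 * 0.98),
                                        lower.tail = FALSE))
  ## degenerate p_coloc = 0
  expect_equal(coloc_z_test(0, 0, 0.3, 50)$p.value, 1)
  d <- coloc_z_test(2, 0, 0.3, 50)
  expect_equal(d$p.value, 0)
  expect_true(d$degenerate)
  expect_error(coloc_z_test(60, 0.5, 0.5, 50), "exceed")
})

test_that("the normal tail is calibrated against binomial simulation", {
  set.seed(123)
  obs <- stats::rbinom(10000, 2000, 0.005)
  pv <- vapply(obs, function(o)
    coloc_z_test(o, 0.05, 0.1, 2000)$p.value, 0)
  frac <- mean(pv < 0.05)
  ## Monte-Carlo error around the nominal level for exp = 10
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("raising the threshold never increases peaks or colocations", {
  set.seed(29)
  pos <- sort(sample.int(1e6, 300))
  sa <- tiny_sumstats(pos, stats::rexp(300, 1 / 1.5), trait = "a")
  sb <- tiny_sumstats(pos, stats::rexp(300, 1 / 1.5), trait = "b")
  grid <- assign_windows(sa, 50000)
  prev_sig <- Inf; prev_obs <- Inf
  for (T in c(1, 2, 3, 4)) {
    pa <- significant_windows(sa, grid, T)
    pb <- significant_windows(sb, grid, T)
    expect_lte(length(pa$significant), prev_sig)
    obs <- coloc_pair_count(pa, pb)
    expect_lte(obs, prev_obs)
    prev_sig <- length(pa$significant); prev_obs <- obs
  }
})

test_that("colocations at a fine window imply colocations at a coarser one", {
  set.seed(37)
  pos <- sort(sample.int(1e6, 300))
  sa <- tiny_sumstats(pos, stats::rexp(300, 1 / 1.5), trait = "a")
  sb <- tiny_sumstats(pos, stats::rexp(300, 1 / 1.5), trait = "b")
  ga <- assign_windows(sa, 20000)
  gc_ <- assign_windows(sa, 100000)   # 20 kb divides 100 kb
  fine_a <- significant_windows(sa, ga, 2)$significant
  fine_b <- significant_windows(sb, ga, 2)$significant
  coarse_a <- significant_windows(sa, gc_, 2)$significant
  coarse_b <- significant_windows(sb, gc_, 2)$significant
  lift <- function(w) {
    k <- as.integer(sub(".*:", "", w))
    paste0(sub(":[0-9]+$", "", w), ":", ceiling(k * 20000 / 100000))
  }
  expect_true(all(lift(intersect(fine_a, fine_b)) %in%
                    intersect(coarse_a, coarse_b)))
})

test_that("coloc_scan ties the pieces together per experiment", {
  ## construct two experiments with a shared peak for anchor and t2 in e1
  pos <- seq(10000, 990000, by = 10000)
  nlp0 <- rep(0.1, length(pos))
  mk <- function(trait, expt, hot) {
    nl <- nlp0; nl[hot] <- 5
    tiny_sumstats(pos, nl, trait = trait, experiment = expt)
  }
  tabs <- list(mk("rgy", "e1", c(5, 50)), mk("t2", "e1", c(5, 80)),
               mk("rgy", "e2", 20), mk("t2", "e2", 70))
  cs <- coloc_scan(tabs, "rgy", threshold = 3, window_kb = 100)
  expect_equal(nrow(cs$pairs), 2L)
  e1 <- cs$pairs[cs$pairs$experiment == "e1", ]
  expect_equal(e1$obs, 1L)             # SNP 5 shared (window chr1:1)
  e2 <- cs$pairs[cs$pairs$experiment == "e2", ]
  expect_equal(e2$obs, 0L)
  expect_error(coloc_scan(tabs[1:3], "t2"), "missing from experiment")
})

test_that("sweep selects the densest cell with the stated tie rule", {
  pos <- seq(10000, 990000, by = 10000)
  mk <- function(trait, hot) {
    nl <- rep(0.1, length(pos)); nl[hot] <- 5
    tiny_sumstats(pos, nl, trait = trait, experiment = "e1")
  }
  ## peaks 30 kb apart: colocate at 100 kb, not at 1 kb
  tabs <- list(mk("rgy", 11), mk("t2", 14))
  sw <- sweep_configs(tabs, "rgy", thresholds = 3,
                      window_sizes_kb = c(1, 100))
  tab <- sw$table
  n1 <- tab$n_significant[tab$window_kb == 1]
  n100 <- tab$n_significant[tab$window_kb == 100]
  expect_gte(n100, n1)
  expect_equal(sw$selected$window_kb, 100)
  ## single cell degenerates to that cell
  sw1 <- sweep_configs(tabs, "rgy", thresholds = 3.5, window_sizes_kb = 20)
  expect_equal(sw1$selected, list(threshold = 3.5, window_kb = 20))
  ## equal counts everywhere: larger window then lower threshold wins
  tabs0 <- list(mk("rgy", integer(0)), mk("t2", integer(0)))
  sw0 <- sweep_configs(tabs0, "rgy", thresholds = c(3, 4),
                       window_sizes_kb = c(1, 100))
  expect_equal(sw0$selected, list(threshold = 3, window_kb = 100))
})

test_that("locus summaries count distinct non-anchor traits per window", {
  pos <- seq(10000, 990000, by = 10000)
  mk <- function(trait, expt, hot) {
    nl <- rep(0.1, length(pos)); nl[hot] <- 5
    tiny_sumstats(pos, nl, trait = trait, experiment = expt)
  }
  ## window chr1:1 carries anchor + t2 + t3 (t2 in both experiments
  ## counts once); window chr1:5 carries t2+t3 but no anchor
  tabs <- list(mk("rgy", "e1", 3), mk("t2", "e1", c(4, 45)),
               mk("t3", "e1", 5), mk("rgy", "e2", 8), mk("t2", "e2", c(2, 44)))
  cs <- coloc_scan(tabs, "rgy", threshold = 3, window_kb = 100)
  loci <- multi_trait_locus_summary(cs, min_traits = 2)
  expect_equal(nrow(as.data.frame(loci)), 1L)
  expect_equal(loci$window, "chr1:1")
  expect_equal(loci$n_traits, 2L)
  expect_equal(loci$traits, "t2,t3")
  expect_true(loci$qualifies)
  ## anchor-free windows never appear
  expect_false("chr1:5" %in% loci$window)
})

test_that("locus counting equals a brute-force per-window tally", {
  set.seed(41)
  pos <- sort(sample.int(2e6, 400))
  traits <- c("rgy", "t2", "t3", "t4")
  tabs <- lapply(traits, function(tr)
    tiny_sumstats(pos, stats::rexp(400, 1 / 1.2), trait = tr,
                  experiment = "e1"))
  cs <- coloc_scan(tabs, "rgy", threshold = 2, window_kb = 100)
  loci <- multi_trait_locus_summary(cs, min_traits = 1)
  ## oracle: recount from the raw tables
  sig_windows <- function(s, T) unique(ceiling(s$pos[s$neg_log10_p >= T] / 1e5))
  wa <- sig_windows(tabs[[1]], 2)
  for (w in wa) {
    n_oracle <- sum(vapply(tabs[2:4], function(s) w %in% sig_windows(s, 2),
                           TRUE))
    row <- loci[loci$window == paste0("chr1:", w), ]
    expect_equal(row$n_traits, n_oracle)
  }
})
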