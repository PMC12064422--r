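test_that("window haplotypes are dosage strings with major-dosage imputation", {
  g <- tiny_geno(rbind(c(0, 2, 2), c(0, 0, 2), c(NA, 0, 2), c(0, 0, 0)),
                 pos = c(100L, 200L, 300L))
  haps <- extract_window_haplotypes(g, "chr1", 100, 300)
  expect_equal(unname(haps["L01"]), "022")
  ## missing at s1 imputed to major dosage 0
  expect_equal(unname(haps["L03"]), "002")
  ## inclusive boundaries: SNP at pos = end included, 99 excludes s1
  expect_equal(nchar(extract_window_haplotypes(g, "chr1", 100, 299)[[1]]), 2L)
  expect_error(extract_window_haplotypes(g, "chr1", 400, 500), "no SNPs")
})

test_that("exact-match grouping labels by descending group size", {
  haps <- c(a = "00", b = "22", c = "00", d = "02", e = "00")
  lab <- group_haplotypes(haps, max_groups = 15)
  expect_equal(attr(lab, "n_groups"), 3L)
  expect_equal(unname(lab[c("a", "c", "e")]), c(1L, 1L, 1L))  # largest
  expect_length(unique(lab[c("b", "d")]), 2L)
})

test_that("clustering caps the number of groups at max_groups", {
  set.seed(53)
  g <- random_geno(60, 10, seed = 53, span = 5000L)
  haps <- extract_window_haplotypes(g, "chr1", 1, 5000)
  expect_gt(length(unique(haps)), 15)
  lab <- group_haplotypes(haps, max_groups = 15)
  expect_equal(length(unique(lab)), 15L)
  ## exact-match partition refines the clustered partition
  split_by_string <- split(names(haps), haps)
  for (grp in split_by_string)
    expect_length(unique(lab[grp]), 1L)
})

test_that("clustered partitions match a naive all-pairs UPGMA oracle", {
  naive_upgma <- function(haps, max_groups) {
    uniq <- sort(unique(haps))
    dd <- salicoloc:::hap_distance(stats::setNames(uniq, uniq))
    members <- as.list(uniq)
    repr <- uniq
    while (length(members) > max_groups) {
      best <- NULL; best_d <- Inf
      for (i in seq_len(length(members) - 1))
        for (j in seq(i + 1, length(members))) {
          dij <- mean(dd[members[[i]], members[[j]]])
          r <- sort(c(repr[i], repr[j]))
          if (dij < best_d - 1e-12 ||
              (abs(dij - best_d) <= 1e-12 &&
               paste(r[1], r[2]) < paste(best_r[1], best_r[2]))) {
            best <- c(i, j); best_d <- dij; best_r <- sort(c(repr[i], repr[j]))
          }
        }
      members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
      repr[best[1]] <- min(repr[best[1]], repr[best[2]])
      members[[best[2]]] <- NULL
      repr <- repr[-best[2]]
    }
    members
  }
  for (seed in 1:8) {
    g <- random_geno(25, 6, seed = seed + 200, span = 4000L)
    haps <- extract_window_haplotypes(g, "chr1", 1, 4000)
    k <- 4
    if (length(unique(haps)) <= k) next
    lab <- group_haplotypes(haps, max_groups = k)
    oracle <- naive_upgma(haps, k)
    ## same partition of distinct strings
    part_impl <- split(names(haps), lab)
    to_strings <- function(p) sort(vapply(p, function(g_) paste(sort(unique(haps[g_])), collapse = "|"), ""))
    oracle_strings <- sort(vapply(oracle, function(m) paste(sort(m), collapse = "|"), ""))
    expect_setequal(unname(to_strings(part_impl)), unname(oracle_strings))
  }
})

test_that("grouping is invariant to permuting line order", {
  g <- random_geno(40, 8, seed = 300, span = 6000L)
  haps <- extract_window_haplotypes(g, "chr1", 1, 6000)
  lab1 <- group_haplotypes(haps, max_groups = 5)
  perm <- sample(length(haps))
  lab2 <- group_haplotypes(haps[perm], max_groups = 5)
  expect_equal(lab1[names(haps)], lab2[names(haps)])
})

test_that("group summaries call the highest-mean qualifying group favourable", {
  lab <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L, 3L),
                         sprintf("l%d", 1:7))
  vals <- stats::setNames(c(40, 42, 38, 88, 92, 90, 200), sprintf("l%d", 1:7))
  gs <- summarize_groups(lab, vals, min_n = 3)
  expect_equal(gs$favourable, 2L)       # group 3 is a singleton
  expect_false(gs$groups$qualifies[gs$groups$group == 3])
  expect_true(gs$distinct)
  ## all equal values: F = 0, tie broken by larger n
  lab2 <- stats::setNames(c(1L, 1L, 1L, 1L, 2L, 2L, 2L), sprintf("l%d", 1:7))
  vals2 <- stats::setNames(rep(5, 7), sprintf("l%d", 1:7))
  gs2 <- summarize_groups(lab2, vals2, min_n = 3)
  expect_equal(gs2$F, 0)
  expect_equal(gs2$favourable, 1L)
})

test_that("sub-window choice scores match an independent F computation", {
  cfg <- sim_config(n_lines = 150, chromosomes = c(chr1 = 1e5),
                    snp_density = 0.0008, traits = "gy", seed = 61)
  g <- simulate_genotypes(cfg)
  set.seed(62)
  vals <- stats::setNames(rnorm(150, 60, 10), g$lines)
  ch <- choose_subwindow(g, "chr1", 1, 1e5, vals,
                         sizes_bp = c(20000, 40000), step_bp = 20000)
  for (i in seq_len(nrow(ch$scores))) {
    row <- ch$scores[i, ]
    haps <- extract_window_haplotypes(g, row$chrom, row$start, row$end)
    grp <- summarize_groups(group_haplotypes(haps, 15), vals, min_n = 3)
    if (grp$distinct) expect_equal(row$F, grp$F)
  }
  ## argmax consistency with the declared tie rules
  Fv <- ifelse(is.na(ch$scores$F), -Inf, ch$scores$F)
  ord <- order(-Fv, ch$scores$size, ch$scores$start)
  expect_equal(ch$best$start, ch$scores$start[ord[1]])
  expect_equal(ch$best$size, ch$scores$size[ord[1]])
})

test_that("a locus with one polymorphic SNP ties to the smallest leftmost window", {
  dos <- cbind(rep(c(0, 2), 10))
  g <- tiny_geno(dos, pos = 50000L)
  set.seed(63)
  vals <- stats::setNames(rnorm(20, 60, 5) + 10 * dos[, 1], g$lines)
  ch <- choose_subwindow(g, "chr1", 1, 1e5, vals,
                         sizes_bp = c(20000, 40000), step_bp = 20000)
  ## sub-windows not containing pos 50000 are skipped (no SNPs); among
  ## those containing it all Fs are equal -> smallest size, leftmost
  expect_equal(ch$best$size, 20000)
  expect_equal(ch$best$start, 40001)
})
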