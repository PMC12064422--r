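#' Fixed genomic window grid and occupancy
#'
#' Tiles each chromosome into fixed windows of `window_bp` from
#' position 1 (window k covers `[(k-1)*W + 1, k*W]`) and records which
#' windows contain at least one tested SNP.  `Nwind`, the number of
#' occupied windows, is the denominator of the empirical peak
#' probability.
#'
#' @param variants data.frame with `chrom` and `pos` columns (a
#'   `sumstat_table` or a `geno_matrix$variants` slot both work).
#' @param window_bp window size in bp (> 0).
#' @return list of class `window_grid`: `window_bp`, `occupied`
#'   (character keys `"chrom:k"`), `Nwind`, and a `windows` data.frame
#'   with chrom/start/end per occupied window.
#' @export
assign_windows <- function(variants, window_bp) {
  if (window_bp <= 0) stop("window_bp must be positive", call. = FALSE)
  stopifnot(all(c("chrom", "pos") %in% names(variants)))
  k <- ceiling(variants$pos / window_bp)
  key <- paste0(variants$chrom, ":", k)
  occ <- unique(key)
  kk <- as.integer(sub(".*:", "", occ))
  windows <- data.frame(window = occ,
                        chrom = sub(":[0-9]+$", "", occ),
                        start = (kk - 1L) * as.integer(window_bp) + 1L,
                        end = kk * as.integer(window_bp),
                        stringsAsFactors = FALSE)
  windows <- windows[order(match(windows$chrom,
                                 unique(windows$chrom[order(as_chrom_rank(windows$chrom))])),
                           windows$start), ]
  rownames(windows) <- NULL
  structure(list(window_bp = window_bp, occupied = windows$window,
                 Nwind = nrow(windows), windows = windows),
            class = "window_grid")
}

## window key per row of a (chrom, pos) table
window_key <- function(d, window_bp) {
  paste0(d$chrom, ":", ceiling(d$pos / window_bp))
}

#' Significant windows for one trait
#'
#' A window is significant when its best SNP reaches `-log10 p >=
#' threshold`.  The empirical peak probability `p_trait` is the number
#' of significant windows divided by `Nwind`, the number of occupied
#' windows in the grid.
#'
#' @param s a `sumstat_table`.
#' @param grid a [assign_windows()] grid built from the experiment's
#'   tested SNP set (must cover `s`).
#' @param threshold significance threshold in `-log10 p` units
#'   (boundary inclusive).
#' @return list of class `trait_peaks`: `trait`, `experiment`,
#'   `threshold`, `window_bp`, `significant` (window keys), `Nwind`,
#'   `p_trait`.
#' @export
significant_windows <- function(s, grid, threshold) {
  stopifnot(inherits(grid, "window_grid"))
  key <- window_key(s, grid$window_bp)
  if (!all(key %in% grid$occupied))
    stop("summary-stat SNPs fall outside the grid's occupied windows",
         call. = FALSE)
  if (nrow(s) == 0) {
    warning("empty summary-stat table: p_trait = 0")
    sig <- character(0)
  } else {
    best <- tapply(s$neg_log10_p, key, max)
    sig <- names(best)[best >= threshold]
  }
  structure(list(trait = if (nrow(s)) s$trait[1] else NA_character_,
                 experiment = if (nrow(s)) s$experiment[1] else NA_character_,
                 threshold = threshold, window_bp = grid$window_bp,
                 occupied = grid$occupied,
                 significant = sig, Nwind = grid$Nwind,
                 p_trait = length(sig) / grid$Nwind),
            class = "trait_peaks")
}

#' Number of shared significant windows for a trait pair
#'
#' @param a,b `trait_peaks` on the same grid (same window size and
#'   occupancy) and experiment.
#' @return integer count of windows significant for both.
#' @export
coloc_pair_count <- function(a, b) {
  stopifnot(inherits(a, "trait_peaks"), inherits(b, "trait_peaks"))
  if (a$window_bp != b$window_bp ||
      !identical(sort(a$occupied), sort(b$occupied)))
    stop("trait peaks come from different window grids", call. = FALSE)
  if (!identical(a$experiment, b$experiment))
    stop("trait peaks come from different experiments", call. = FALSE)
  length(intersect(a$significant, b$significant))
}

#' Colocation enrichment test (binomial z with normal tail)
#'
#' The observed number of windows jointly significant for two traits
#' is modelled as Binomial(`Nwind`, `p_coloc`) under independence, with
#' `p_coloc = p_anchor * p_other`, `expNcoloc = Nwind * p_coloc`,
#' `sigma = sqrt(Nwind * p_coloc * (1 - p_coloc))`, `z = (obs -
#' expNcoloc) / sigma`, and a one-sided upper-tail standard-normal
#' P-value.  A pair is flagged significant at P < 0.05.
#'
#' Two calling modes:
#' \itemize{
#'   \item probability mode: give `p_anchor`, `p_other` and `Nwind`;
#'   \item expected-count mode: give `expected` only, which applies the
#'     rare-peak limit `sigma = sqrt(expected)` (the binomial's Poisson
#'     limit, appropriate when `p_coloc` is vanishingly small).
#' }
#'
#' Degenerate rule: when `p_coloc = 0`, P = 1 if `obs = 0` and P = 0
#' otherwise, with `degenerate = TRUE`.
#'
#' @param obs observed colocation count (integer >= 0).
#' @param p_anchor,p_other per-trait empirical peak probabilities in
#'   \[0, 1\].
#' @param Nwind number of occupied windows (>= 1).
#' @param expected expected colocation count (expected-count mode).
#' @param anchor,trait,experiment optional labels carried through.
#' @return list of class `coloc_test` with fields `obs`, `p_coloc`,
#'   `expected`, `sigma`, `z`, `p.value`, `significant`, `degenerate`.
#' @export
coloc_z_test <- function(obs, p_anchor = NULL, p_other = NULL, Nwind = NULL,
                         expected = NULL, anchor = NULL, trait = NULL,
                         experiment = NULL) {
  stopifnot(obs >= 0)
  if (is.null(expected)) {
    stopifnot(!is.null(p_anchor), !is.null(p_other), !is.null(Nwind),
              Nwind >= 1, p_anchor >= 0, p_anchor <= 1,
              p_other >= 0, p_other <= 1)
    if (obs > Nwind)
      stop("observed colocations exceed the number of windows",
           call. = FALSE)
    p_coloc <- p_anchor * p_other
    expected <- Nwind * p_coloc
    sigma <- sqrt(Nwind * p_coloc * (1 - p_coloc))
  } else {
    stopifnot(expected >= 0)
    p_coloc <- NA_real_
    sigma <- sqrt(expected)
  }
  degenerate <- FALSE
  if (sigma == 0) {
    degenerate <- TRUE
    p_val <- if (obs == 0) 1 else 0
    z <- if (obs == 0) 0 else Inf
  } else {
    z <- (obs - expected) / sigma
    p_val <- stats::pnorm(z, lower.tail = FALSE)
  }
  structure(list(obs = obs, p_coloc = p_coloc, expected = expected,
                 sigma = sigma, z = z, p.value = p_val,
                 significant = p_val < 0.05, degenerate = degenerate,
                 anchor = anchor, trait = trait, experiment = experiment),
            class = "coloc_test")
}

#' @exportS3Method
print.coloc_test <- function(x, ...) {
  cat("windowed colocation enrichment test\n")
  if (!is.null(x$anchor))
    cat(sprintf("  %s vs %s (%s)\n", x$anchor, x$trait,
                x$experiment %||% ""))
  cat(sprintf("  obs = %d, expected = %.3f, sigma = %.3f, z = %.3f\n",
              x$obs, x$expected, x$sigma, x$z))
  cat(sprintf("  one-sided P = %.3g%s%s\n", x$p.value,
              if (x$significant) "  (significant at 0.05)" else "",
              if (x$degenerate) "  [degenerate: p_coloc = 0]" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-trait colocation scan
#'
#' The central fit: from per-(trait, experiment) GWAS summary
#' statistics, tiles the genome into `window_kb` windows, finds each
#' trait's significant windows at `threshold`, and tests every
#' non-anchor trait against the anchor trait within its experiment
#' using [coloc_z_test()].  Each experiment gets its own grid built
#' from the union of its tables' SNPs.
#'
#' @param sumstats list of `sumstat_table`s (one per trait x
#'   experiment), or a single data.frame carrying `trait` and
#'   `experiment` columns.
#' @param anchor anchor trait name (must be present in every
#'   experiment).
#' @param threshold peak threshold in `-log10 p` units.
#' @param window_kb window size in kb.
#' @return object of class `coloc_scan`: `pairs` (data.frame of pair
#'   tests), `peaks` (list of `trait_peaks`), `grids` (per experiment),
#'   plus the settings.
#' @export
coloc_scan <- function(sumstats, anchor, threshold = 3, window_kb = 100) {
  tabs <- split_sumstats(sumstats)
  window_bp <- window_kb * 1000
  expts <- unique(vapply(tabs, function(s) s$experiment[1], ""))
  grids <- list()
  peaks <- list()
  pairs <- list()
  for (ex in expts) {
    in_ex <- Filter(function(s) s$experiment[1] == ex, tabs)
    traits <- vapply(in_ex, function(s) s$trait[1], "")
    if (!anchor %in% traits)
      stop("anchor trait '", anchor, "' missing from experiment ", ex,
           call. = FALSE)
    all_snps <- unique(do.call(rbind,
      lapply(in_ex, function(s) s[, c("chrom", "pos")])))
    grid <- assign_windows(all_snps, window_bp)
    grids[[ex]] <- grid
    pk <- lapply(in_ex, significant_windows, grid = grid,
                 threshold = threshold)
    names(pk) <- paste(traits, ex, sep = "|")
    peaks <- c(peaks, pk)
    a <- pk[[paste(anchor, ex, sep = "|")]]
    for (tr in setdiff(traits, anchor)) {
      b <- pk[[paste(tr, ex, sep = "|")]]
      obs <- coloc_pair_count(a, b)
      tst <- coloc_z_test(obs, a$p_trait, b$p_trait, grid$Nwind,
                          anchor = anchor, trait = tr, experiment = ex)
      pairs[[length(pairs) + 1L]] <- data.frame(
        experiment = ex, trait = tr, obs = obs,
        expected = tst$expected, sigma = tst$sigma, z = tst$z,
        p = tst$p.value, significant = tst$significant,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(pairs = do.call(rbind, pairs), peaks = peaks,
                 grids = grids, anchor = anchor, threshold = threshold,
                 window_bp = window_bp),
            class = "coloc_scan")
}

## normalize sumstats input to a list of single-(trait, experiment)
## tables
split_sumstats <- function(sumstats) {
  if (is.data.frame(sumstats))
    sumstats <- lapply(
      split(as.data.frame(sumstats),
            paste(sumstats$trait, sumstats$experiment, sep = "|")),
      sumstat_table)
  stopifnot(length(sumstats) >= 2)
  for (s in sumstats) {
    stopifnot(inherits(s, "sumstat_table"))
    if (length(unique(s$trait)) != 1 || length(unique(s$experiment)) != 1)
      stop("each sumstat table must carry one (trait, experiment)",
           call. = FALSE)
  }
  sumstats
}

#' @exportS3Method
print.coloc_scan <- function(x, ...) {
  cat(sprintf("colocation scan: anchor '%s', threshold %.1f, window %d kb\n",
              x$anchor, x$threshold, x$window_bp / 1000))
  for (ex in names(x$grids))
    cat(sprintf("  %s: Nwind = %d occupied windows\n", ex,
                x$grids[[ex]]$Nwind))
  cat(sprintf("  %d pair test(s), %d significant at P < 0.05\n",
              nrow(x$pairs), sum(x$pairs$significant)))
  invisible(x)
}

#' @exportS3Method
summary.coloc_scan <- function(object, ...) {
  d <- object$pairs[order(object$pairs$p), ]
  rownames(d) <- NULL
  cat(sprintf("pair tests vs anchor '%s' (T = %.1f, W = %d kb):\n",
              object$anchor, object$threshold, object$window_bp / 1000))
  print(transform(d, expected = round(expected, 3), sigma = round(sigma, 3),
                  z = round(z, 2), p = signif(p, 3)), row.names = FALSE)
  invisible(d)
}

#' @exportS3Method
plot.coloc_scan <- function(x, ...) {
  d <- x$pairs
  lab <- paste(d$trait, d$experiment, sep = "\n")
  graphics::barplot(d$z, names.arg = lab, las = 2, cex.names = 0.7,
                    ylab = "colocation z", ...)
  graphics::abline(h = stats::qnorm(0.95), lty = 2)
  invisible(x)
}

#' Threshold / window-size sweep
#'
#' Runs [coloc_scan()] over a grid of peak thresholds and window
#' sizes, counting the (trait, experiment) pairs significantly
#' colocated with the anchor in each cell.  The selected cell
#' maximizes that count, with ties broken toward larger windows and
#' then lower thresholds.
#'
#' @inheritParams coloc_scan
#' @param thresholds vector of `-log10 p` thresholds.
#' @param window_sizes_kb vector of window sizes in kb.
#' @return list of class `coloc_sweep`: `table` (one row per cell) and
#'   `selected` (threshold, window_kb).
#' @export
sweep_configs <- function(sumstats, anchor, thresholds = c(3, 3.5, 4),
                          window_sizes_kb = c(1, 2, 5, 20, 100)) {
  tabs <- split_sumstats(sumstats)
  cells <- expand.grid(threshold = thresholds, window_kb = window_sizes_kb,
                       KEEP.OUT.ATTRS = FALSE)
  cells$n_significant <- vapply(seq_len(nrow(cells)), function(i) {
    cs <- coloc_scan(tabs, anchor, cells$threshold[i], cells$window_kb[i])
    sum(cs$pairs$significant)
  }, 0L)
  ord <- order(-cells$n_significant, -cells$window_kb, cells$threshold)
  sel <- cells[ord[1], c("threshold", "window_kb")]
  structure(list(table = cells, selected = as.list(sel)),
            class = "coloc_sweep")
}

#' @exportS3Method
print.coloc_sweep <- function(x, ...) {
  cat("colocation sweep (significant pairs per cell):\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("selected: threshold %.1f, window %d kb\n",
              x$selected$threshold, x$selected$window_kb))
  invisible(x)
}

#' Multi-trait locus summary
#'
#' Pools the per-trait significant windows across experiments: for
#' every window where the anchor is significant in at least one
#' experiment, counts the distinct non-anchor trait names significant
#' in that window.  Windows reaching `min_traits` distinct co-occurring
#' traits qualify as multi-trait loci.
#'
#' @param cs a `coloc_scan` (all experiments share the window size by
#'   construction), or a plain list of `trait_peaks` on a common window
#'   size (then `anchor` must be given).
#' @param min_traits qualification threshold (default 7).
#' @param anchor anchor trait name when `cs` is a list of peaks.
#' @return data.frame of class `locus_summary`: window, chrom, start,
#'   end, n_traits, traits (comma-joined), qualifies; sorted by
#'   descending count then position.
#' @export
multi_trait_locus_summary <- function(cs, min_traits = 7, anchor = NULL) {
  if (inherits(cs, "coloc_scan")) {
    peaks <- cs$peaks
    anchor <- cs$anchor
    window_bp <- cs$window_bp
  } else {
    peaks <- cs
    if (is.null(anchor))
      stop("anchor must be given for a plain list of peaks", call. = FALSE)
    window_bp <- unique(vapply(peaks, `[[`, 0, "window_bp"))
    if (length(window_bp) != 1)
      stop("peaks must share one window size", call. = FALSE)
  }
  anchor_windows <- unique(unlist(lapply(
    Filter(function(p) p$trait == anchor, peaks), `[[`, "significant")))
  if (!length(anchor_windows))
    return(structure(data.frame(window = character(0)),
                     class = c("locus_summary", "data.frame")))
  rows <- lapply(anchor_windows, function(w) {
    others <- unique(vapply(
      Filter(function(p) p$trait != anchor && w %in% p$significant, peaks),
      `[[`, "", "trait"))
    k <- as.integer(sub(".*:", "", w))
    data.frame(window = w, chrom = sub(":[0-9]+$", "", w),
               start = (k - 1L) * window_bp + 1L, end = k * window_bp,
               n_traits = length(others),
               traits = paste(sort(others), collapse = ","),
               qualifies = length(others) >= min_traits,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_traits,
                   match(out$chrom,
                         unique(out$chrom[order(as_chrom_rank(out$chrom))])),
                   out$start), ]
  rownames(out) <- NULL
  class(out) <- c("locus_summary", "data.frame")
  out
}
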