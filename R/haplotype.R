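#' Per-line haplotype (dosage) strings over a region
#'
#' Collapses the dosages of all SNPs inside `[start, end]` (boundaries
#' inclusive) into one string per line.  Missing dosages are imputed to
#' the SNP's major (most frequent) dosage; heterozygous calls are
#' retained as 1.
#'
#' @param g a `geno_matrix`.
#' @param chrom,start,end region coordinates (1-based, inclusive).
#' @return named character vector of dosage strings, one per line,
#'   with attribute `"snps"` (variant ids used).
#' @export
extract_window_haplotypes <- function(g, chrom, start, end) {
  stopifnot(inherits(g, "geno_matrix"))
  idx <- which(g$variants$chrom == chrom & g$variants$pos >= start &
                 g$variants$pos <= end)
  if (!length(idx))
    stop("no SNPs in region ", chrom, ":", start, "-", end, call. = FALSE)
  dos <- g$dosages[, idx, drop = FALSE]
  for (j in seq_len(ncol(dos))) {
    nas <- is.na(dos[, j])
    if (any(nas)) {
      tab <- table(dos[!nas, j])
      major <- as.numeric(names(tab)[which.max(tab)])
      dos[nas, j] <- major
    }
  }
  haps <- apply(dos, 1, paste, collapse = "")
  names(haps) <- g$lines
  attr(haps, "snps") <- g$variants$id[idx]
  haps
}

## normalized Hamming distance between dosage strings: per-SNP mismatch
## contributes |d1 - d2| / 2, averaged over SNPs
hap_distance <- function(haps) {
  m <- do.call(rbind, lapply(strsplit(haps, ""), as.numeric))
  d <- as.matrix(stats::dist(m, method = "manhattan")) / (2 * ncol(m))
  dimnames(d) <- list(names(haps), names(haps))
  d
}

#' Group lines by haplotype
#'
#' Identical strings always share a group.  When the number of distinct
#' strings exceeds `max_groups`, average-linkage agglomerative
#' clustering on the normalized Hamming distance (dosage mismatch
#' contributes `|d1 - d2| / 2` per SNP) merges haplotypes until
#' `max_groups` clusters remain; at equal merge distance the
#' lexicographically smallest pair of cluster representatives merges
#' first, which makes the partition independent of input order.
#' Groups are numbered 1..G by descending size (ties by the
#' lexicographically smallest member string).
#'
#' @param haps named character vector from
#'   [extract_window_haplotypes()].
#' @param max_groups maximum number of groups (the variety-group
#'   setting; default 15).
#' @return named integer vector of group labels per line, with
#'   attribute `"n_groups"`.
#' @export
group_haplotypes <- function(haps, max_groups = 15) {
  stopifnot(length(haps) >= 2)
  uniq <- sort(unique(haps))
  ## cluster distinct strings; start from exact-match partition
  members <- as.list(uniq)            # cluster -> haplotype strings
  if (length(uniq) > max_groups) {
    dd <- hap_distance(stats::setNames(uniq, uniq))
    repr <- uniq                       # lexicographically smallest member
    sizes <- rep(1L, length(uniq))    # distinct strings per cluster
    active <- rep(TRUE, length(uniq))
    diag(dd) <- Inf
    n_active <- length(uniq)
    while (n_active > max_groups) {
      dmin <- min(dd[active, active])
      cand <- which(dd == dmin & outer(active, active, `&`), arr.ind = TRUE)
      cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
      ## lexicographically smallest representative pair merges first
      r1 <- pmin(repr[cand[, 1]], repr[cand[, 2]])
      r2 <- pmax(repr[cand[, 1]], repr[cand[, 2]])
      pick <- order(r1, r2)[1]
      i <- cand[pick, 1]
      j <- cand[pick, 2]
      ## average-linkage (UPGMA) update over distinct strings
      newd <- (sizes[i] * dd[i, ] + sizes[j] * dd[j, ]) /
        (sizes[i] + sizes[j])
      dd[i, ] <- newd
      dd[, i] <- newd
      dd[i, i] <- Inf
      active[j] <- FALSE
      dd[j, ] <- Inf
      dd[, j] <- Inf
      members[[i]] <- c(members[[i]], members[[j]])
      sizes[i] <- sizes[i] + sizes[j]
      repr[i] <- min(repr[i], repr[j])
      n_active <- n_active - 1L
    }
    members <- members[active]
  }
  ## label lines; order groups by descending size then smallest member
  cluster_of <- stats::setNames(
    rep(seq_along(members), lengths(members)), unlist(members))
  line_cluster <- cluster_of[haps]
  sizes <- tabulate(line_cluster, nbins = length(members))
  first <- vapply(members, min, "")
  ord <- order(-sizes, first)
  relabel <- match(seq_along(members), ord)
  labels <- stats::setNames(as.integer(relabel[line_cluster]), names(haps))
  attr(labels, "n_groups") <- length(members)
  labels
}

#' Summarize haplotype groups against the anchor trait
#'
#' Computes per-group n, mean and median of the anchor trait (over
#' non-missing values), scores the phenotypic distinction among groups
#' with `n >= min_n` by one-way ANOVA ([anova_lsd()]), and calls the
#' favourable group: the qualifying group with the highest mean (ties
#' broken toward the larger group).
#'
#' @param labels group labels from [group_haplotypes()].
#' @param values anchor trait values: a [relative_trait()] object or a
#'   named numeric vector.
#' @param min_n minimum group size to qualify (default 3, so singleton
#'   haplotypes cannot be called favourable).
#' @param alpha significance level passed to [anova_lsd()].
#' @return list of class `hap_grouping`: `groups` (data.frame),
#'   `favourable` (group id or NA), `F`, `p`, `distinct` (logical:
#'   ANOVA computable), `labels`, `boxplot_data`.
#' @export
summarize_groups <- function(labels, values, min_n = 3, alpha = 0.05) {
  if (inherits(values, "relative_trait")) values <- values$values
  stopifnot(!is.null(names(labels)), !is.null(names(values)))
  lines <- intersect(names(labels), names(values))
  lab <- labels[lines]
  val <- values[lines]
  ok <- !is.na(val)
  gstat <- data.frame(
    group = sort(unique(as.integer(lab))),
    stringsAsFactors = FALSE)
  gstat$n <- vapply(gstat$group, function(g) sum(lab == g & ok), 0L)
  gstat$mean <- vapply(gstat$group, function(g)
    if (any(lab == g & ok)) mean(val[lab == g & ok]) else NA_real_, 0)
  gstat$median <- vapply(gstat$group, function(g)
    if (any(lab == g & ok)) stats::median(val[lab == g & ok]) else NA_real_, 0)
  gstat$qualifies <- gstat$n >= min_n

  qual <- gstat[gstat$qualifies & !is.na(gstat$mean), ]
  F_stat <- p_val <- NA_real_
  distinct <- FALSE
  if (nrow(qual) >= 2) {
    in_q <- ok & lab %in% qual$group
    fit <- tryCatch(
      anova_lsd(val[in_q], lab[in_q], alpha = alpha, min_n = min_n),
      error = function(e) NULL)
    if (!is.null(fit)) {
      F_stat <- fit$F
      p_val <- fit$p
      distinct <- TRUE
    }
  }
  favourable <- if (nrow(qual) >= 1) {
    qual$group[order(-qual$mean, -qual$n)][1]
  } else NA_integer_
  boxplot_data <- data.frame(line = lines[ok], group = lab[ok],
                             value = val[ok], stringsAsFactors = FALSE)
  structure(list(groups = gstat, favourable = favourable,
                 F = F_stat, p = p_val, distinct = distinct,
                 min_n = min_n, labels = labels,
                 boxplot_data = boxplot_data),
            class = "hap_grouping")
}

#' @exportS3Method
print.hap_grouping <- function(x, ...) {
  cat(sprintf("haplotype grouping: %d group(s), favourable = %s\n",
              nrow(x$groups),
              ifelse(is.na(x$favourable), "none", x$favourable)))
  if (x$distinct)
    cat(sprintf("distinction among groups with n >= %d: F = %.3g, p = %.3g\n",
                x$min_n, x$F, x$p))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method
plot.hap_grouping <- function(x, ...) {
  graphics::boxplot(value ~ group, data = x$boxplot_data,
                    xlab = "haplotype group", ylab = "anchor trait", ...)
  invisible(x)
}

#' Choose the best sub-window within a colocating locus
#'
#' Enumerates sub-windows of each candidate size (default 20, 40 and
#' 60 kb) at `step_bp` offsets inside the locus, groups haplotypes in
#' each, and scores the phenotypic distinction by the one-way ANOVA F
#' statistic over qualifying groups.  Returns the argmax; ties break
#' toward the smaller sub-window, then the leftmost.
#'
#' @param g a `geno_matrix`.
#' @param chrom,start,end the locus (one grid window, e.g. 100 kb).
#' @param values anchor trait values (see [summarize_groups()]).
#' @param sizes_bp candidate sub-window sizes in bp.
#' @param step_bp enumeration step in bp.
#' @param max_groups,min_n,alpha passed through to grouping/summary.
#' @return list of class `subwindow_choice`: `best` (chrom, start,
#'   end, size), `grouping` (its `hap_grouping`), and `scores` (one
#'   row per evaluated sub-window).
#' @export
choose_subwindow <- function(g, chrom, start, end, values,
                             sizes_bp = c(20000, 40000, 60000),
                             step_bp = 20000, max_groups = 15,
                             min_n = 3, alpha = 0.05) {
  rows <- list()
  groupings <- list()
  for (size in sizes_bp) {
    offs <- seq(start, max(start, end - size + 1), by = step_bp)
    for (s0 in offs) {
      e0 <- min(s0 + size - 1, end)
      haps <- tryCatch(extract_window_haplotypes(g, chrom, s0, e0),
                       error = function(e) NULL)
      if (is.null(haps)) next
      grp <- summarize_groups(group_haplotypes(haps, max_groups),
                              values, min_n = min_n, alpha = alpha)
      key <- paste0(chrom, ":", s0, "-", e0)
      groupings[[key]] <- grp
      rows[[key]] <- data.frame(chrom = chrom, start = s0, end = e0,
                                size = size,
                                F = ifelse(grp$distinct, grp$F, NA_real_),
                                n_groups = nrow(grp$groups),
                                stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no SNPs in any sub-window of the locus", call. = FALSE)
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  Fv <- ifelse(is.na(scores$F), -Inf, scores$F)
  ord <- order(-Fv, scores$size, scores$start)
  best <- scores[ord[1], ]
  structure(list(best = best,
                 grouping = groupings[[paste0(best$chrom, ":", best$start,
                                              "-", best$end)]],
                 scores = scores),
            class = "subwindow_choice")
}

#' @exportS3Method
print.subwindow_choice <- function(x, ...) {
  cat(sprintf("selected sub-window %s:%d-%d (%d kb), distinction F = %.3g\n",
              x$best$chrom, x$best$start, x$best$end, x$best$size / 1000,
              x$best$F))
  print(x$grouping)
  invisible(x)
}
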