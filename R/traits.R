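#' Relative trait: saline as a percentage of control
#'
#' The standard salinity-tolerance measure: per line, 100 x (mean over
#' saline replicates) / (mean over control replicates).  Means are
#' taken over non-missing replicates; a line is excluded (with a
#' counted reason) if either treatment mean is missing or the control
#' mean is <= 0.  Values are not capped at 100.
#'
#' @param p a `pheno_table`.
#' @param trait trait to use.
#' @param numerator_treatment,denominator_treatment treatment labels
#'   forming the ratio (defaults: saline over control).
#' @return a list of class `relative_trait`: `trait`, named numeric
#'   `values` (percent, per line), and `excluded`, a named count of
#'   exclusion reasons.
#' @export
relative_trait <- function(p, trait,
                           numerator_treatment = "saline",
                           denominator_treatment = "control") {
  stopifnot(inherits(p, "pheno_table"))
  d <- p[p$trait == trait, , drop = FALSE]
  if (nrow(d) == 0)
    stop("trait not present in phenotype table: ", trait, call. = FALSE)
  mean_by <- function(treat) {
    dd <- d[d$treatment == treat & !is.na(d$value), ]
    tapply(dd$value, dd$line, mean)
  }
  num <- mean_by(numerator_treatment)
  den <- mean_by(denominator_treatment)
  lines <- union(names(num), names(den))
  num <- num[lines]
  den <- den[lines]
  missing_mean <- is.na(num) | is.na(den)
  bad_control <- !missing_mean & den <= 0
  keep <- !missing_mean & !bad_control
  values <- as.numeric(100 * num[keep] / den[keep])
  names(values) <- lines[keep]
  structure(list(trait = trait, values = values,
                 excluded = c(missing_mean = sum(missing_mean),
                              nonpositive_control = sum(bad_control))),
            class = "relative_trait")
}

#' @exportS3Method
print.relative_trait <- function(x, ...) {
  cat(sprintf("relative %s: %d lines (excluded: %d missing, %d non-positive control)\n",
              x$trait, length(x$values), x$excluded[["missing_mean"]],
              x$excluded[["nonpositive_control"]]))
  print(summary(unname(x$values)))
  invisible(x)
}

#' Pairwise-complete Pearson correlation matrix
#'
#' For a set of per-line trait vectors, computes pairwise-complete
#' Pearson r with a two-sided p-value from the t transform on n - 2
#' degrees of freedom.  Cells with fewer than 3 complete pairs are
#' flagged missing (NA), and star codes follow the usual
#' 0.05 / 0.01 / 0.001 levels.
#'
#' @param vectors named list of named numeric vectors (names = lines).
#' @return list of class `trait_cor`: matrices `r`, `p`, `n` and a
#'   character matrix `stars`.
#' @export
correlation_matrix <- function(vectors) {
  stopifnot(is.list(vectors), length(vectors) >= 2, !is.null(names(vectors)))
  lines <- sort(unique(unlist(lapply(vectors, names))))
  m <- sapply(vectors, function(v) v[lines])
  rownames(m) <- lines
  k <- ncol(m)
  r <- p <- n <- matrix(NA_real_, k, k,
                        dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) for (j in i:k) {
    ok <- stats::complete.cases(m[, i], m[, j])
    nn <- sum(ok)
    n[i, j] <- n[j, i] <- nn
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (nn < 3) next
    rr <- stats::cor(m[ok, i], m[ok, j])
    r[i, j] <- r[j, i] <- rr
    tt <- rr * sqrt((nn - 2) / max(1 - rr^2, .Machine$double.eps))
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), nn - 2)
  }
  stars <- ifelse(is.na(p), "", ifelse(p < 0.001, "***",
           ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
  structure(list(r = r, p = p, n = n, stars = stars), class = "trait_cor")
}

#' @exportS3Method
print.trait_cor <- function(x, digits = 3, ...) {
  cat("pairwise-complete Pearson correlations\n")
  disp <- matrix(paste0(format(round(x$r, digits)), x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  print(disp, quote = FALSE)
  invisible(x)
}

#' One-way ANOVA with Fisher's LSD pairwise comparisons
#'
#' Fits a one-way ANOVA, then compares group means with the least
#' significant difference test at `alpha` using the pooled error mean
#' square, and assigns a compact letter display (groups sharing a
#' letter are not significantly different).  Groups with fewer than
#' `min_n` members are excluded with a warning.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length.
#' @param alpha significance level for the pairwise comparisons.
#' @param min_n minimum group size (default 2).
#' @return list of class `anova_lsd`: `F`, `p`, `df`, `groups`
#'   (data.frame with n, mean, letters) and `pairs` (data.frame of
#'   pairwise differences, LSD and significance).
#' @export
anova_lsd <- function(values, groups, alpha = 0.05, min_n = 2) {
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups[ok])
  sizes <- table(groups)
  small <- names(sizes)[sizes < min_n]
  if (length(small) > 0) {
    warning("excluding group(s) with n < ", min_n, ": ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- groups[keep]
    sizes <- table(groups)
  }
  if (length(sizes) < 2)
    stop("need at least 2 usable groups", call. = FALSE)
  fit <- stats::lm(values ~ factor(groups))
  ## anova() warns on zero-residual fits; those degenerate layouts are
  ## handled explicitly below
  av <- suppressWarnings(stats::anova(fit))
  mse <- av[["Mean Sq"]][2]
  df_err <- av[["Df"]][2]
  F_stat <- av[["F value"]][1]
  p_val <- av[["Pr(>F)"]][1]
  ## degenerate layouts: no between-group signal (possibly no variance
  ## at all) gives F = 0 rather than 0/0 noise
  tot <- sum((values - mean(values))^2)
  if (!is.finite(F_stat) || av[["Sum Sq"]][1] <= 1e-10 * (tot + 1)) {
    F_stat <- 0
    p_val <- 1
    mse <- max(mse, 0)
  }
  means <- tapply(values, groups, mean)
  ord <- order(-means)
  gname <- names(means)[ord]
  gmean <- means[ord]
  gn <- as.integer(sizes[gname])

  tcrit <- stats::qt(1 - alpha / 2, df_err)
  k <- length(gname)
  cmp <- utils::combn(k, 2)
  lsd <- tcrit * sqrt(mse * (1 / gn[cmp[1, ]] + 1 / gn[cmp[2, ]]))
  diffm <- abs(gmean[cmp[1, ]] - gmean[cmp[2, ]])
  pairs <- data.frame(group1 = gname[cmp[1, ]], group2 = gname[cmp[2, ]],
                      diff = diffm, lsd = lsd,
                      significant = diffm > lsd,
                      stringsAsFactors = FALSE)
  sig <- matrix(FALSE, k, k)
  sig[t(cmp)] <- pairs$significant
  sig <- sig | t(sig)

  letters_out <- cld_letters(sig)
  grp <- data.frame(group = gname, n = gn, mean = unname(gmean),
                    letters = letters_out, stringsAsFactors = FALSE)
  structure(list(F = F_stat, p = p_val, df = c(av[["Df"]][1], df_err),
                 mse = mse, alpha = alpha, groups = grp, pairs = pairs),
            class = "anova_lsd")
}

## compact letter display from a pairwise significance matrix whose
## rows/cols are ordered by descending mean: assign one letter per
## maximal run of mutually non-significant groups
cld_letters <- function(sig) {
  k <- nrow(sig)
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    runs[[i]] <- i:j
  }
  ## keep maximal runs only
  maximal <- Filter(function(r) {
    !any(vapply(runs, function(s)
      !identical(s, r) && all(r %in% s), TRUE))
  }, runs)
  maximal <- unique(maximal)
  out <- character(k)
  for (li in seq_along(maximal))
    out[maximal[[li]]] <- paste0(out[maximal[[li]]], letters[li])
  out
}

#' @exportS3Method
print.anova_lsd <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat(sprintf("Fisher's LSD at alpha = %g:\n", x$alpha))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
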