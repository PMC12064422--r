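#' Read a pipeline run configuration
#'
#' The run configuration is a flat YAML file of stage settings; every
#' key has a default, so a minimal config can be empty.  `qtls` is the
#' one nested key: a list of `{chrom, pos, trait(s), control, saline}`
#' entries planting additive QTLs (the same entry listed for several
#' traits plants a true colocation).
#'
#' @param path YAML file, or a named list already in memory.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(raw)) raw <- list()
  defaults <- list(
    seed = 1, n_lines = 300,
    n_chrom = 5, chrom_length_bp = 2e6,
    snp_density = 0.002, n_founders = 8, ld_block_scale = 50000,
    maf_min = 0.05, maf_max = 0.5, het_rate = 0,
    traits = c("grain_yield", "filled_grains", "panicle_length",
               "shoot_biomass"),
    anchor_trait = "grain_yield",
    control_mean = 10, saline_mean = 6,
    line_variance = 1, residual_variance = 1, n_reps = 3,
    n_subpop = 1,
    qtls = list(),
    experiment = "sim1",
    min_maf = 0.05, prune_window_bp = 2000, prune_r2 = 0.85, n_pcs = 3,
    alpha_gw = 0.1,
    coloc_threshold = 3, coloc_window_kb = 100, sweep = FALSE,
    min_traits = 7,
    hap_sub_sizes_kb = c(20, 40, 60), hap_max_groups = 15, hap_min_n = 3,
    stages = c("simulate", "traits", "gwas", "coloc", "haplo")
  )
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, raw)
  ## modifyList merges nested lists element-wise and drops unnamed
  ## entries; qtls is a plain list of entries, so take it verbatim
  if ("qtls" %in% names(raw)) cfg$qtls <- raw$qtls
  ## YAML renders some numeric spellings (e.g. 2.0e6) as strings
  num_keys <- c("seed", "n_lines", "n_chrom", "chrom_length_bp",
                "snp_density", "n_founders", "ld_block_scale", "maf_min",
                "maf_max", "het_rate", "control_mean", "saline_mean",
                "line_variance", "residual_variance", "n_reps", "n_subpop",
                "min_maf", "prune_window_bp", "prune_r2", "alpha_gw",
                "coloc_threshold", "coloc_window_kb", "min_traits",
                "hap_sub_sizes_kb", "hap_max_groups", "hap_min_n")
  for (k in num_keys) cfg[[k]] <- as.numeric(cfg[[k]])
  if (!cfg$anchor_trait %in% cfg$traits)
    stop("anchor_trait '", cfg$anchor_trait, "' not among traits",
         call. = FALSE)
  for (q in cfg$qtls) {
    need <- c("chrom", "pos", "traits", "saline")
    if (!all(need %in% names(q)))
      stop("each qtl needs keys: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (!all(q$traits %in% cfg$traits))
      stop("qtl trait not among configured traits", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

run_config_sim <- function(cfg) {
  chroms <- stats::setNames(rep(cfg$chrom_length_bp, cfg$n_chrom),
                            paste0("chr", seq_len(cfg$n_chrom)))
  qtls <- lapply(cfg$qtls, function(q) {
    eff <- rep(list(c(control = q$control %||% 0, saline = q$saline)),
               length(q$traits))
    names(eff) <- q$traits
    qtl_spec(q$chrom, q$pos, eff)
  })
  sim_config(
    n_lines = cfg$n_lines, chromosomes = chroms,
    snp_density = cfg$snp_density, n_founders = cfg$n_founders,
    ld_block_scale = cfg$ld_block_scale,
    maf_range = c(cfg$maf_min, cfg$maf_max), het_rate = cfg$het_rate,
    qtls = qtls, traits = cfg$traits,
    treatment_means = stats::setNames(
      rep(list(c(control = cfg$control_mean, saline = cfg$saline_mean)),
          length(cfg$traits)), cfg$traits),
    line_variance = cfg$line_variance,
    residual_variance = cfg$residual_variance,
    n_reps = cfg$n_reps, n_subpop = cfg$n_subpop, seed = cfg$seed)
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> relative traits -> GWAS -> colocation ->
#' haplotype favourability, writing every stage's tabular output as
#' TSV under `out_dir` plus a `manifest.yaml` of file checksums.  When
#' a manifest from a previous run with an identical configuration is
#' found and all its outputs are intact, stages are skipped unless
#' `force = TRUE`.  The whole run is deterministic for a fixed seed.
#'
#' @param config path to a YAML run configuration, or a `run_config`.
#' @param out_dir output directory (created if needed).
#' @param force rerun even when existing outputs match.
#' @return the manifest, invisibly: a list with `seed`, `config_md5`,
#'   `outputs` (named md5 vector) and `versions`.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config_md5 <- config_digest(cfg)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  if (!force && file.exists(manifest_path)) {
    prev <- yaml::read_yaml(manifest_path)
    outs <- file.path(out_dir, names(prev$outputs))
    if (identical(prev$config_md5, config_md5) && all(file.exists(outs)) &&
        identical(unname(tools::md5sum(outs)),
                  unname(unlist(prev$outputs)))) {
      message("outputs up to date; skipping all stages (force = TRUE to rerun)")
      return(invisible(prev))
    }
  }
  stage <- function(name) name %in% cfg$stages
  paths <- character(0)
  note <- function(p) paths <<- union(paths, p)

  sim <- run_config_sim(cfg)
  g <- pheno <- NULL
  if (stage("simulate")) {
    g <- simulate_genotypes(sim)
    pheno <- simulate_phenotypes(g, sim)
    note(write_genotypes(g, file.path(out_dir, "genotypes.vcf"), "vcf"))
    note(write_genotypes(g, file.path(out_dir, "genotypes.tsv"),
                         "dosage_tsv"))
    note(write_phenotypes(pheno, file.path(out_dir, "phenotypes.tsv")))
  } else {
    g <- read_genotypes(file.path(out_dir, "genotypes.tsv"), "dosage_tsv")
    pheno <- read_phenotypes(file.path(out_dir, "phenotypes.tsv"))
  }

  rel <- lapply(cfg$traits, function(tr) relative_trait(pheno, tr))
  names(rel) <- cfg$traits
  if (stage("traits")) {
    lines <- sort(unique(unlist(lapply(rel, function(r) names(r$values)))))
    tab <- data.frame(line = lines, stringsAsFactors = FALSE)
    for (tr in cfg$traits) tab[[tr]] <- rel[[tr]]$values[lines]
    f <- file.path(out_dir, "relative_traits.tsv")
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f)
    cm <- correlation_matrix(lapply(rel, `[[`, "values"))
    ctab <- data.frame(trait1 = rep(rownames(cm$r), ncol(cm$r)),
                       trait2 = rep(colnames(cm$r), each = nrow(cm$r)),
                       r = as.vector(cm$r), p = as.vector(cm$p),
                       n = as.vector(cm$n), stars = as.vector(cm$stars))
    f <- file.path(out_dir, "trait_correlations.tsv")
    utils::write.table(ctab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f)
  }

  sumstats <- NULL
  if (stage("gwas")) {
    scfg <- scan_config(min_maf = cfg$min_maf,
                        prune_window_bp = cfg$prune_window_bp,
                        prune_r2 = cfg$prune_r2, n_pcs = cfg$n_pcs,
                        alpha_gw = cfg$alpha_gw)
    g2 <- suppressMessages(maf_filter(g, scfg$min_maf))
    g2 <- ld_prune(g2, scfg$prune_window_bp, scfg$prune_r2)
    sumstats <- lapply(cfg$traits, function(tr) {
      pcs <- pca_covariates(g2, scfg$n_pcs, y = rel[[tr]]$values)
      ss <- association_scan(g2, rel[[tr]]$values, pcs,
                             trait = tr, experiment = cfg$experiment)
      f <- file.path(out_dir, paste0("sumstats_", tr, ".tsv"))
      write_sumstats(ss, f)
      note(f)
      ss
    })
    names(sumstats) <- cfg$traits
  } else if (stage("coloc") || stage("haplo")) {
    files <- list.files(out_dir, "^sumstats_.*\\.tsv$", full.names = TRUE)
    sumstats <- lapply(files, read_sumstats)
  }

  cs <- NULL
  if (stage("coloc")) {
    cs <- coloc_scan(sumstats, cfg$anchor_trait,
                     threshold = cfg$coloc_threshold,
                     window_kb = cfg$coloc_window_kb)
    f <- file.path(out_dir, "coloc_pairs.tsv")
    utils::write.table(cs$pairs, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(f)
    if (isTRUE(cfg$sweep)) {
      sw <- sweep_configs(sumstats, cfg$anchor_trait)
      f <- file.path(out_dir, "coloc_sweep.tsv")
      utils::write.table(sw$table, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note(f)
    }
    loci <- multi_trait_locus_summary(cs, min_traits = cfg$min_traits)
    f <- file.path(out_dir, "coloc_loci.tsv")
    utils::write.table(as.data.frame(loci), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(f)
  }

  if (stage("haplo")) {
    if (is.null(cs)) stop("haplo stage needs the coloc stage", call. = FALSE)
    loci <- multi_trait_locus_summary(cs, min_traits = cfg$min_traits)
    if (nrow(loci) > 0 && any(loci$qualifies)) {
      top <- loci[loci$qualifies, ][1, ]
      anchor_vals <- rel[[cfg$anchor_trait]]$values
      ch <- choose_subwindow(g, top$chrom, top$start, top$end, anchor_vals,
                             sizes_bp = cfg$hap_sub_sizes_kb * 1000,
                             max_groups = cfg$hap_max_groups,
                             min_n = cfg$hap_min_n)
      f <- file.path(out_dir, "hap_subwindow_scores.tsv")
      utils::write.table(ch$scores, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note(f)
      grp <- ch$grouping
      f <- file.path(out_dir, "hap_groups.tsv")
      utils::write.table(grp$groups, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note(f)
      assign_tab <- data.frame(line = names(grp$labels),
                               group = as.integer(grp$labels))
      f <- file.path(out_dir, "hap_assignments.tsv")
      utils::write.table(assign_tab, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note(f)
      f <- file.path(out_dir, "hap_boxplot_data.tsv")
      utils::write.table(grp$boxplot_data, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note(f)
    } else {
      message("no qualifying multi-trait locus; haplotype stage skipped")
    }
  }

  outputs <- as.list(tools::md5sum(paths))
  names(outputs) <- basename(paths)
  manifest <- list(seed = cfg$seed, config_md5 = config_md5,
                   outputs = outputs,
                   versions = list(
                     salicoloc = as.character(utils::packageVersion("salicoloc")),
                     R = paste(R.version$major, R.version$minor, sep = ".")))
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest)
}

## stable digest of a run configuration (md5 of its deparsed,
## name-sorted form)
config_digest <- function(cfg) {
  x <- unclass(cfg)
  x <- x[order(names(x))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x), tmp)
  unname(tools::md5sum(tmp))
}
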