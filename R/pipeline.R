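## Configuration-driven orchestration: simulate-or-ingest -> MAF filter ->
## kinship/PCA -> phenotype LMM -> GBLUP prediction + CV -> GWAS -> selection
## scan -> LD decay -> variant density.  Every stage writes TSV outputs plus
## a JSON manifest (parameters, seed, input checksums, row counts); manifests
## carry no timestamps so a rerun with the same config is byte-identical.

.pipeline_defaults <- function() list(
  maf = 0.05,
  window_sites = 500, step_sites = 100,
  subset_min_year = 1990, percentile = 0.95,
  cv_folds = 2, cv_replicates = 100,
  fdr_q = 0.05, fdr_method = "bh",
  ld_max_dist_bp = 3e6, ld_bin_bp = 1e4,
  density_block_bp = 1e5,
  n_pcs = 2)

.all_stages <- c("data", "maf", "kinship", "pheno", "prediction", "gwas",
                 "sweep", "ld", "density")

.stage_deps <- list(
  data = character(0),
  maf = "data",
  kinship = "maf",
  pheno = "data",
  prediction = c("kinship", "pheno"),
  gwas = c("kinship", "pheno"),
  sweep = "maf",
  ld = "maf",
  density = "data")

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.manifest <- function(dir, stage, params, inputs = character(0),
                      outputs = character(0), counts = list(), seed = NULL) {
  man <- list(stage = stage, seed = seed, parameters = params,
              inputs = lapply(inputs, function(f)
                list(path = basename(f),
                     md5 = unname(tools::md5sum(f)))),
              outputs = lapply(outputs, function(f)
                list(path = basename(f),
                     md5 = unname(tools::md5sum(f)))),
              counts = counts)
  path <- file.path(dir, paste0(stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the full panel analysis pipeline from a configuration
#'
#' Executes the enabled stages in dependency order on either a simulated
#' panel (a `simulation` block holding [sim_config()] arguments plus a
#' `traits` list of [trait_config()] argument lists) or real inputs (an
#' `inputs` block with `vcf`, `metadata` and optionally `phenotypes` paths).
#' Exactly one of the two blocks must be present.  Each stage writes its
#' tables as TSV plus a JSON manifest under `manifests/`; a failing stage
#' aborts with its name.  All randomness derives from `config$seed`, and
#' manifests contain no timestamps, so reruns of an unchanged config are
#' byte-identical.
#'
#' @param config A list, or path to a YAML file, with elements `simulation`
#'   or `inputs`, optional `stages` (subset of `data, maf, kinship, pheno,
#'   prediction, gwas, sweep, ld, density`), optional `parameters`
#'   overriding stage defaults
#'   (MAF 0.05, windows 500/100, 2-fold x 100 CV, FDR 0.05, 95th percentile,
#'   LD to 3 Mb), `seed`, and optionally `output_dir`.
#' @param output_dir Output directory; overrides `config$output_dir`.
#' @return Invisibly, the output directory.  Side effect: TSVs and
#'   manifests under it.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  has_sim <- !is.null(config$simulation)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp)
    stop("config needs exactly one of 'simulation' or 'inputs'")
  out <- output_dir %||% config$output_dir
  if (is.null(out)) stop("no output directory given")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  man_dir <- file.path(out, "manifests")
  dir.create(man_dir, showWarnings = FALSE)

  stages <- config$stages %||% .all_stages
  bad <- setdiff(stages, .all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .all_stages[.all_stages %in% stages]
  for (s in stages) {
    missing_dep <- setdiff(.stage_deps[[s]], stages)
    if (length(missing_dep))
      stop("stage '", s, "' requires disabled stage(s): ",
           paste(missing_dep, collapse = ", "))
  }
  par <- utils::modifyList(.pipeline_defaults(), config$parameters %||% list())
  seed <- as.integer(config$seed %||% 1L)
  manifests <- character(0)
  gd <- records <- NULL

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("data" %in% stages) run_stage("data", function() {
    if (has_sim) {
      sim <- config$simulation
      traits <- sim$traits
      cfgargs <- sim[setdiff(names(sim), c("traits", "n_seasons", "n_years"))]
      cfgargs$seed <- seed
      if (!is.null(cfgargs$introgressions))
        cfgargs$introgressions <- lapply(cfgargs$introgressions,
                                         function(a) do.call(introgression_spec, a))
      cfg <- do.call(sim_config, cfgargs)
      gd <<- simulate_panel(cfg)
      if (is.null(traits)) traits <- list(list(name = "trait1"))
      recs <- lapply(seq_along(traits), function(i) {
        tc <- do.call(trait_config, traits[[i]])
        simulate_phenotypes(gd, tc,
                            n_seasons = config$simulation$n_seasons %||% 2,
                            n_years = config$simulation$n_years %||% 2,
                            seed = seed + i)
      })
      records <<- do.call(rbind, lapply(recs, as.data.frame))
      paths <- write_fixture(gd, structure(records,
                                           class = c("phenotype_records",
                                                     "data.frame")),
                             out, prefix = "panel")
      manifests <<- c(manifests, .manifest(
        man_dir, "data", list(source = "simulation"), outputs = paths,
        counts = list(n_samples = nrow(gd$samples),
                      n_variants = nrow(gd$variants),
                      n_phenotype_records = nrow(records)),
        seed = seed))
    } else {
      gd <<- read_vcf(config$inputs$vcf, config$inputs$metadata)
      if (!is.null(config$inputs$phenotypes))
        records <<- utils::read.delim(config$inputs$phenotypes,
                                      stringsAsFactors = FALSE)
      manifests <<- c(manifests, .manifest(
        man_dir, "data", list(source = "inputs"),
        inputs = unlist(config$inputs),
        counts = list(n_samples = nrow(gd$samples),
                      n_variants = nrow(gd$variants)),
        seed = seed))
    }
  })

  gdf <- NULL
  if ("maf" %in% stages) run_stage("maf", function() {
    n0 <- nrow(gd$variants)
    gdf <<- filter_maf(gd, par$maf)
    manifests <<- c(manifests, .manifest(
      man_dir, "maf", list(min_maf = par$maf),
      counts = list(n_before = n0, n_after = nrow(gdf$variants)),
      seed = seed))
  })

  K_add <- K_dom <- pcs <- NULL
  if ("kinship" %in% stages) run_stage("kinship", function() {
    chroms <- unique(gdf$variants$chromosome)
    lens <- vapply(chroms, function(ch)
      max(gdf$variants$position[gdf$variants$chromosome == ch]), 0)
    A_c <- lapply(chroms, function(ch) additive_kinship(gdf, ch))
    D_c <- lapply(chroms, function(ch) dominance_kinship(gdf, ch))
    K_add <<- integrate_kinship(A_c, lens)
    K_dom <<- integrate_kinship(D_c, lens)
    pcs <<- pca_structure(K_add, k = par$n_pcs)
    a_path <- .write_tsv(data.frame(sample_id = K_add$sample_ids,
                                    K_add$values, check.names = FALSE),
                         file.path(out, "kinship_additive.tsv"))
    d_path <- .write_tsv(data.frame(sample_id = K_dom$sample_ids,
                                    K_dom$values, check.names = FALSE),
                         file.path(out, "kinship_dominance.tsv"))
    pca_df <- data.frame(sample_id = pcs$sample_ids, pcs$scores,
                         release_year = gdf$samples$release_year)
    p_path <- .write_tsv(pca_df, file.path(out, "pca.tsv"))
    manifests <<- c(manifests, .manifest(
      man_dir, "kinship", list(n_pcs = par$n_pcs,
                               chrom_lengths = as.list(lens)),
      outputs = c(a_path, d_path, p_path),
      counts = list(n_chromosomes = length(chroms)),
      seed = seed))
  })

  cv_list <- list()
  if ("pheno" %in% stages) run_stage("pheno", function() {
    if (is.null(records)) stop("no phenotype records available")
    traits <- unique(records$trait)
    cv_list <<- lapply(traits, function(tr)
      fit_cultivar_values(records, tr))
    names(cv_list) <<- traits
    vals <- do.call(rbind, lapply(cv_list, function(cv)
      data.frame(trait = cv$trait, sample_id = names(cv$values),
                 value = unname(cv$values))))
    vc <- do.call(rbind, lapply(cv_list, function(cv)
      data.frame(trait = cv$trait, component = names(cv$varcomp),
                 variance = unname(cv$varcomp))))
    v_path <- .write_tsv(vals, file.path(out, "cultivar_values.tsv"))
    vc_path <- .write_tsv(vc, file.path(out, "variance_components.tsv"))
    manifests <<- c(manifests, .manifest(
      man_dir, "pheno", list(), outputs = c(v_path, vc_path),
      counts = list(n_traits = length(traits)), seed = seed))
  })

  if ("prediction" %in% stages) run_stage("prediction", function() {
    kernels <- list(additive = K_add)
    if (!is.null(K_dom)) kernels$dominance <- K_dom
    gebv_rows <- list(); cv_rows <- list()
    for (tr in names(cv_list)) {
      yv <- cv_list[[tr]]
      fit <- fit_gblup(yv, list(additive = K_add))
      gebv <- predict_gebv(fit)
      gebv_rows[[tr]] <- data.frame(
        sample_id = names(gebv), trait = tr, gebv = unname(gebv),
        phenotyped = names(gebv) %in% names(yv$values))
      cvres <- cross_validate(yv, kernels,
                              n_folds = par$cv_folds,
                              n_replicates = par$cv_replicates,
                              seed = seed + 17)
      cv_rows[[tr]] <- cbind(trait = tr, cvres$summary)
    }
    g_path <- .write_tsv(do.call(rbind, gebv_rows),
                         file.path(out, "gebv.tsv"))
    c_path <- .write_tsv(do.call(rbind, cv_rows), file.path(out, "cv.tsv"))
    manifests <<- c(manifests, .manifest(
      man_dir, "prediction",
      list(cv_folds = par$cv_folds, cv_replicates = par$cv_replicates),
      outputs = c(g_path, c_path), counts = list(n_traits = length(cv_list)),
      seed = seed))
  })

  if ("gwas" %in% stages) run_stage("gwas", function() {
    paths <- character(0)
    n_sig <- 0
    for (tr in names(cv_list)) {
      scan <- association_scan(cv_list[[tr]], gdf, covariates = pcs,
                               K = K_add)
      dec <- fdr_threshold(scan$p, q = par$fdr_q, method = par$fdr_method)
      scan$significant <- dec$significant
      n_sig <- n_sig + dec$n_significant
      paths <- c(paths, .write_tsv(
        as.data.frame(scan),
        file.path(out, paste0("gwas_", tr, ".tsv"))))
    }
    manifests <<- c(manifests, .manifest(
      man_dir, "gwas",
      list(pcs = par$n_pcs, fdr_q = par$fdr_q, method = par$fdr_method),
      outputs = paths, counts = list(n_significant = n_sig), seed = seed))
  })

  if ("sweep" %in% stages) run_stage("sweep", function() {
    sub <- gdf$samples$sample_id[gdf$samples$release_year >=
                                   par$subset_min_year]
    if (length(sub) < 2) stop("subpanel (release_year >= ",
                              par$subset_min_year, ") has < 2 samples")
    pi_all <- nucleotide_diversity(gdf, NULL, par$window_sites,
                                   par$step_sites)
    pi_sub <- nucleotide_diversity(gdf, sub, par$window_sites,
                                   par$step_sites)
    rod_t <- percentile_flag(rod(pi_all, pi_sub), par$percentile)
    h_all <- heterozygosity_windows(gdf, NULL, par$window_sites,
                                    par$step_sites)
    h_sub <- heterozygosity_windows(gdf, sub, par$window_sites,
                                    par$step_sites)
    ind <- percentile_flag(het_excess_indicator(h_all, h_sub),
                           par$percentile)
    cols <- c("chromosome", "window_index", "start_bp", "end_bp",
              "n_sites", "value", "partial", "flagged")
    r_path <- .write_tsv(as.data.frame(rod_t)[, cols],
                         file.path(out, "rod.tsv"))
    h_path <- .write_tsv(as.data.frame(ind)[, cols],
                         file.path(out, "het_indicator.tsv"))
    manifests <<- c(manifests, .manifest(
      man_dir, "sweep",
      list(window_sites = par$window_sites, step_sites = par$step_sites,
           subset_min_year = par$subset_min_year,
           percentile = par$percentile),
      outputs = c(r_path, h_path),
      counts = list(n_subpanel = length(sub),
                    n_rod_flagged = sum(rod_t$flagged),
                    n_het_flagged = sum(ind$flagged)),
      seed = seed))
  })

  if ("ld" %in% stages) run_stage("ld", function() {
    curves <- list(genotype = ld_decay(gdf, "genotype",
                                       par$ld_max_dist_bp, par$ld_bin_bp))
    if (gdf$phased)
      curves$haplotype <- ld_decay(gdf, "haplotype",
                                   par$ld_max_dist_bp, par$ld_bin_bp)
    paths <- character(0)
    hd <- list()
    for (mode in names(curves)) {
      paths <- c(paths, .write_tsv(
        curves[[mode]]$bins, file.path(out, paste0("ld_", mode, ".tsv"))))
      hd[[paste0("half_decay_bp_", mode)]] <- curves[[mode]]$half_decay_bp
    }
    manifests <<- c(manifests, .manifest(
      man_dir, "ld",
      list(max_dist_bp = par$ld_max_dist_bp, bin_bp = par$ld_bin_bp),
      outputs = paths, counts = hd, seed = seed))
  })

  if ("density" %in% stages) run_stage("density", function() {
    dens <- variant_density(gd, par$density_block_bp)
    d_path <- .write_tsv(
      as.data.frame(dens)[, c("chromosome", "window_index", "start_bp",
                              "end_bp", "value")],
      file.path(out, "variant_density.tsv"))
    manifests <<- c(manifests, .manifest(
      man_dir, "density", list(block_bp = par$density_block_bp),
      outputs = d_path, counts = list(n_blocks = nrow(dens)), seed = seed))
  })

  jsonlite::write_json(
    list(seed = seed, stages = as.list(stages),
         parameters = par,
         manifests = as.list(basename(manifests))),
    file.path(out, "run.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a completed pipeline run
#'
#' Reads the manifests and stage tables under `output_dir` and assembles a
#' one-page text summary: variant counts, the PC1-release-year correlation,
#' the cross-validation accuracy table, top association hits (or "none"),
#' counts of flagged selection windows and LD half-decay distances.  Stages
#' that did not run are marked as missing rather than failing.
#'
#' @param output_dir Directory written by [run_pipeline()].
#' @return Invisibly, a list of the summary pieces; prints the text summary.
#' @export
report_summary <- function(output_dir) {
  run_path <- file.path(output_dir, "run.json")
  if (!file.exists(run_path)) stop("no run.json in ", output_dir)
  run <- jsonlite::read_json(run_path, simplifyVector = TRUE)
  lines <- c("== pipeline summary ==",
             paste("stages run:", if (length(run$stages))
               paste(run$stages, collapse = ", ") else "(none)"),
             paste("seed:", run$seed))
  out <- list(stages = run$stages, seed = run$seed)

  rd <- function(f) {
    p <- file.path(output_dir, f)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE)
    else NULL
  }
  man <- function(stage) {
    p <- file.path(output_dir, "manifests", paste0(stage, ".json"))
    if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE)
    else NULL
  }

  m <- man("maf")
  lines <- c(lines, if (!is.null(m))
    paste0("variants: ", m$counts$n_before, " -> ", m$counts$n_after,
           " after MAF filter") else "variants: (missing)")

  pca <- rd("pca.tsv")
  if (!is.null(pca) && "release_year" %in% names(pca)) {
    r <- stats::cor(pca$PC1, pca$release_year)
    out$pc1_year_correlation <- r
    lines <- c(lines, sprintf("PC1 ~ release year correlation: %.3f", r))
  } else lines <- c(lines, "PC1 ~ release year: (missing)")

  cv <- rd("cv.tsv")
  if (!is.null(cv)) {
    out$cv <- cv
    lines <- c(lines, "cross-validation accuracy (mean +/- sd):",
               sprintf("  %s / %s: %.3f +/- %.3f", cv$trait, cv$model,
                       cv$accuracy_mean, cv$accuracy_sd))
  } else lines <- c(lines, "cross-validation: (missing)")

  gwas_files <- list.files(output_dir, pattern = "^gwas_.*\\.tsv$")
  if (length(gwas_files)) {
    for (f in gwas_files) {
      gw <- rd(f)
      sig <- gw[gw$significant, , drop = FALSE]
      tr <- sub("^gwas_(.*)\\.tsv$", "\\1", f)
      if (nrow(sig)) {
        top <- sig[order(sig$p), ][1, ]
        lines <- c(lines, sprintf(
          "GWAS %s: %d significant; top %s:%d (-log10p = %.2f)",
          tr, nrow(sig), top$chromosome, top$position, top$neglog10p))
      } else lines <- c(lines, sprintf("GWAS %s: none significant", tr))
    }
  } else lines <- c(lines, "GWAS: (missing)")

  sw <- man("sweep")
  lines <- c(lines, if (!is.null(sw))
    sprintf("selection scan: %d ROD and %d het-indicator windows flagged",
            sw$counts$n_rod_flagged, sw$counts$n_het_flagged)
    else "selection scan: (missing)")

  ldm <- man("ld")
  if (!is.null(ldm)) {
    for (nm in names(ldm$counts)) {
      v <- suppressWarnings(as.numeric(ldm$counts[[nm]]))
      lines <- c(lines, sprintf("LD %s: %s", nm,
                                if (!length(v) || is.na(v)) "NA"
                                else sprintf("%.0f bp", v)))
    }
  } else lines <- c(lines, "LD decay: (missing)")

  cat(lines, sep = "\n")
  out$lines <- lines
  invisible(out)
}
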