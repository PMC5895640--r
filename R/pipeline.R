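# Pipeline orchestration: ordered stages (select-genes -> network ->
# stats -> preserve -> ppi -> qtl -> neo) driven by a validated config,
# with per-stage seeds derived from one global seed, cached stage outputs,
# and a JSON run manifest (config echo, file hashes, timings, warnings).

PIPELINE_DEFAULTS <- list(
  seed = 1L,
  out_dir = "pipeline_out",
  simulate = TRUE,
  expression = NULL,          # named list of per-condition TSV paths
  genotypes = NULL,
  phenotypes = NULL,
  ppi = NULL,
  gene_sets = NULL,
  mean_floor = 8,
  resp_cutoff = 0.5,
  powers = 1:20,
  r2_target = 0.8,
  min_module_size = 30,
  cut_height_frac = 0.99,
  delta_min = 0.1,
  ppi_min_score = 700,
  preserve_alpha = 0.01,
  enrich_alpha = 0.05,
  leo_threshold = 0.5,
  lrs_min = 15,
  cis_window = 10,
  per_condition_networks = TRUE
)

#' Build a validated pipeline configuration
#'
#' Unknown keys are rejected (typo safety); thresholds are range-checked.
#' The global `seed` is fanned out to per-stage seeds as `seed + stage
#' offset` (offsets 101-404 for the generator stages, documented in the
#' generator functions), so each stage is independently reproducible.
#'
#' @param ... Overrides of the documented defaults.
#' @param config_file Optional YAML file whose keys are merged in (file
#'   values are overridden by `...`).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(..., config_file = NULL) {
  cfg <- PIPELINE_DEFAULTS
  from_file <- if (!is.null(config_file)) yaml::read_yaml(config_file) else list()
  overrides <- c(from_file, list(...))
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  stopifnot(cfg$mean_floor > 0, cfg$resp_cutoff > 0, cfg$resp_cutoff < 1,
            cfg$r2_target > 0, cfg$r2_target <= 1,
            cfg$ppi_min_score >= 0, cfg$ppi_min_score <= 1000,
            cfg$preserve_alpha > 0, cfg$preserve_alpha < 1,
            cfg$leo_threshold >= 0, cfg$cis_window > 0)
  if (!cfg$simulate) {
    paths <- unlist(cfg[c("expression", "genotypes", "phenotypes")])
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(cfg, class = "PipelineConfig")
}

stage_files <- function(dir) {
  fs <- list.files(dir, recursive = TRUE, full.names = TRUE)
  if (!length(fs)) return(data.frame(file = character(), md5 = character()))
  data.frame(file = fs, md5 = unname(tools::md5sum(fs)),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load-or-simulate inputs; per-condition variable-gene
#' selection and merge; combined (and optionally per-condition)
#' co-expression networks; module condition patterns, trait correlations
#' and gene-set enrichment; cross-condition preservation and specificity;
#' PPI overlay and subnetwork extraction; phenotype QTL scans; causal
#' screening of the top-QTL marker against module genes. Each stage writes
#' its outputs under `out_dir/<stage>/`; a stage whose outputs already
#' exist is skipped unless `force` is set, so deleting one stage directory
#' re-runs only that stage and its dependents downstream of the cache.
#'
#' @param config A [pipeline_config()].
#' @param force Re-run stages even when their outputs exist.
#' @return A `RunManifest` list (also written as `manifest.json` under
#'   `out_dir`): config echo, package version, per-stage files with md5
#'   hashes, timings, collected warnings.
#' @export
run_pipeline <- function(config = pipeline_config(), force = FALSE) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config),
                  version = as.character(utils::packageVersion("stressnet")),
                  stages = list(), warnings = character())
  note <- function(w) manifest$warnings <<- c(manifest$warnings, w)
  timed <- function(name, fun) {
    dir <- file.path(out, name)
    if (!force && dir.exists(dir) && length(list.files(dir))) {
      manifest$stages[[name]] <<- list(cached = TRUE, files = stage_files(dir))
      return(invisible(NULL))
    }
    dir.create(dir, showWarnings = FALSE)
    t0 <- proc.time()[["elapsed"]]
    withCallingHandlers(
      fun(dir),
      warning = function(w) { note(conditionMessage(w))
        invokeRestart("muffleWarning") })
    manifest$stages[[name]] <<- list(cached = FALSE,
                                     seconds = proc.time()[["elapsed"]] - t0,
                                     files = stage_files(dir))
    invisible(NULL)
  }

  # --- inputs ---------------------------------------------------------
  if (config$simulate) {
    study <- simulate_study(synthetic_design(seed = config$seed))
  } else {
    exprs <- lapply(stats::setNames(nm = names(config$expression)), function(cond)
      read_expression(config$expression[[cond]], cond))
    study <- list(
      expression = exprs,
      genotypes = read_genotypes(config$genotypes),
      phenotypes = read_phenotypes(config$phenotypes),
      ppi = if (!is.null(config$ppi)) read_ppi(config$ppi),
      truth = NULL)
  }

  # --- variable genes -------------------------------------------------
  vgs <- NULL
  timed("select_genes", function(dir) {
    sets <- lapply(names(study$expression), function(cond) {
      prof <- compute_cv(study$expression[[cond]])
      fit <- fit_cv_mixture(prof$cv, seed = config$seed + 11L)
      s <- select_variable_genes(prof, fit, mean_floor = config$mean_floor,
                                 resp_cutoff = config$resp_cutoff,
                                 condition = cond)
      utils::write.table(s$table, file.path(dir, paste0(cond, "_cv.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(weights = fit$weights, means = fit$means,
                                sds = fit$sds),
                           file.path(dir, paste0(cond, "_mixture.json")),
                           auto_unbox = TRUE, digits = NA)
      s
    })
    merged <- merge_conditions(sets)
    writeLines(merged$genes, file.path(dir, "merged_genes.txt"))
    vgs <<- merged
  })
  if (is.null(vgs))
    vgs <- list(genes = readLines(file.path(out, "select_genes", "merged_genes.txt")))

  # --- networks -------------------------------------------------------
  nets <- list()
  combined <- combine_conditions(study$expression, vgs$genes)
  net_stage <- function(dir) {
    build_and_write <- function(expr, tag) {
      nw <- build_network(expr, powers = config$powers,
                          r2_target = config$r2_target,
                          min_size = config$min_module_size,
                          cut_height_frac = config$cut_height_frac)
      utils::write.table(nw$scan, file.path(dir, paste0(tag, "_powerscan.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      asg <- data.frame(gene = names(nw$modules$assignment),
                        module = unname(nw$modules$assignment),
                        k_in = unname(nw$modules$k_in),
                        stringsAsFactors = FALSE)
      utils::write.table(asg, file.path(dir, paste0(tag, "_modules.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(nw$modules$eigengenes))
        utils::write.table(
          data.frame(strain = rownames(nw$modules$eigengenes),
                     nw$modules$eigengenes, check.names = FALSE),
          file.path(dir, paste0(tag, "_eigengenes.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      nw
    }
    nets$combined <<- build_and_write(combined, "combined")
    if (config$per_condition_networks) {
      for (cond in names(study$expression)) {
        expr_c <- study$expression[[cond]]
        expr_c <- expr_c[intersect(vgs$genes, rownames(expr_c)), ]
        nets[[cond]] <<- build_and_write(expr_c, cond)
      }
    }
  }
  timed("network", net_stage)
  if (is.null(nets$combined)) {   # cached: rebuild in memory (cheap relative to IO)
    net_stage(file.path(out, "network"))
  }

  # --- module statistics ----------------------------------------------
  timed("stats", function(dir) {
    asg <- nets$combined$modules$assignment
    pat <- pattern_summary(study$expression, asg, delta_min = config$delta_min)
    utils::write.table(pat, file.path(dir, "patterns.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mes <- nets$combined$modules$eigengenes
    if (!is.null(mes) && !is.null(study$phenotypes)) {
      # eigengene rows are condition-tagged strain columns; average per strain
      strain <- sub("^[A-Z]+\\.", "", rownames(mes))
      mes_s <- apply(mes, 2, function(v) tapply(v, strain, mean))
      tc <- module_trait_correlation(mes_s, study$phenotypes)
      utils::write.table(
        data.frame(module = rownames(tc$r), r = tc$r, p = tc$p,
                   check.names = FALSE),
        file.path(dir, "module_trait.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(config$gene_sets)) {
      gsc <- read_gmt(config$gene_sets)
      enr <- module_enrichment(asg, gsc, alpha = config$enrich_alpha)
      utils::write.table(enr, file.path(dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })

  # --- preservation ----------------------------------------------------
  if (config$per_condition_networks) timed("preserve", function(dir) {
    conds <- names(study$expression)
    all_rows <- list()
    spec_rows <- list()
    for (a in conds) {
      ovs <- list()
      for (b in setdiff(conds, a)) {
        ov <- module_overlap(nets[[a]]$modules$assignment,
                             nets[[b]]$modules$assignment,
                             alpha = config$preserve_alpha)
        ov$condA <- rep(a, nrow(ov)); ov$condB <- rep(b, nrow(ov))
        ovs[[b]] <- ov
        all_rows[[paste(a, b)]] <- ov
      }
      sp <- call_specific_modules(ovs, alpha = config$preserve_alpha)
      if (nrow(sp)) { sp$condition <- a; spec_rows[[a]] <- sp }
    }
    utils::write.table(do.call(rbind, all_rows), file.path(dir, "overlaps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(spec_rows))
      utils::write.table(do.call(rbind, lapply(spec_rows, function(d)
        d[, c("module", "specific", "condition")])),
        file.path(dir, "specificity.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # --- PPI overlay -----------------------------------------------------
  if (!is.null(study$ppi)) timed("ppi", function(dir) {
    hi <- filter_ppi(study$ppi, min_score = config$ppi_min_score)
    common <- intersect_with_modules(hi, nets$combined$modules$assignment)
    utils::write.table(common, file.path(dir, "common_interactions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    subs <- extract_subnetworks(common)
    export_subnetworks(subs, dir, format = "SIF",
                       modules = nets$combined$modules)
  })

  # --- QTL + causal screen --------------------------------------------
  timed("qtl", function(dir) {
    traits <- colnames(study$phenotypes)
    scans <- lapply(traits, function(tr) {
      s <- qtl_scan(study$phenotypes[, tr], study$genotypes)
      s$trait <- tr
      s
    })
    utils::write.table(do.call(rbind, scans), file.path(dir, "qtl.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  timed("neo", function(dir) {
    qtl <- utils::read.delim(file.path(out, "qtl", "qtl.tsv"))
    asg <- nets$combined$modules$assignment
    mes <- nets$combined$modules$eigengenes
    strain <- sub("^[A-Z]+\\.", "", rownames(mes))
    mes_s <- apply(mes, 2, function(v) tapply(v, strain, mean))
    tc <- module_trait_correlation(mes_s, study$phenotypes)
    rows <- list()
    for (tr in unique(qtl$trait)) {
      sub <- qtl[qtl$trait == tr & !qtl$skipped, ]
      if (!nrow(sub) || all(is.na(sub$LRS))) next
      top <- sub[which.max(sub$LRS), ]
      marker <- study$genotypes$codes[top$marker, ]
      # pick the trait's own condition matrix when the trait name carries a
      # condition tag; screen only modules associated with the trait
      cond <- regmatches(tr, regexpr("(NOS|RSS|NOE|RSE)$", tr))
      expr_cond <- if (length(cond) && cond %in% names(study$expression))
        study$expression[[cond]] else study$expression[[1]]
      assoc <- rownames(tc$r)[!is.na(tc$p[, tr]) & tc$p[, tr] < 0.1]
      for (mod in intersect(setdiff(unique(asg), GREY), assoc)) {
        genes <- names(asg)[asg == mod]
        sub_expr <- expr_cond[intersect(genes, rownames(expr_cond)), ]
        res <- screen_causal_genes(marker, sub_expr,
                                   study$phenotypes[, tr, drop = FALSE],
                                   threshold = config$leo_threshold)
        if (nrow(res)) { res$module <- mod; res$marker <- top$marker
          rows[[paste(tr, mod)]] <- res }
      }
    }
    if (length(rows))
      utils::write.table(do.call(rbind, rows), file.path(dir, "leo.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  })

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  class(manifest) <- "RunManifest"
  invisible(manifest)
}
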