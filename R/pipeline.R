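#' Default pipeline run configuration
#'
#' Collects every stage parameter of the atlas pipeline in one list.
#' Input paths may be NULL when \code{simulate} is TRUE, in which case a
#' synthetic fixture with planted ground truth is generated first.
#'
#' @param expression,counts,design,ppi input file paths (TSV; see the
#'   reader functions). Ignored when \code{simulate} is TRUE.
#' @param label_files named character vector of one-gene-per-line label
#'   files (optional).
#' @param simulate generate a synthetic fixture instead of reading inputs.
#' @param sim arguments passed to \code{\link{sim_config}} when
#'   simulating.
#' @param min_mean,detect_tpm,tau_specific,tau_group,fold classification
#'   parameters (see \code{\link{filter_genes}},
#'   \code{\link{classify_genes}}).
#' @param lfc_cutoff,p_cutoff DEG thresholds (see \code{\link{call_degs}}).
#' @param n_top,beta_candidates,min_module_size,n_perm co-expression
#'   parameters.
#' @param min_score,activity_p,min_component network parameters.
#' @param seed mandatory integer seed for all stochastic stages.
#' @return a \code{run_config} list.
#' @export
run_config <- function(expression = NULL, counts = NULL, design = NULL,
                       ppi = NULL, label_files = NULL, simulate = is.null(expression),
                       sim = list(), min_mean = 1.0, detect_tpm = 1.0,
                       tau_specific = 0.85, tau_group = 0.5, fold = 5,
                       lfc_cutoff = 3, p_cutoff = 0.05, n_top = 500,
                       beta_candidates = 6:20, min_module_size = 10,
                       n_perm = 1000, min_score = 0.7, activity_p = 0.05,
                       min_component = 3, seed = 1L) {
  stopifnot(length(seed) == 1, is.finite(seed))
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{run_config}}; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @param ... overrides applied after reading.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  overrides <- list(...)
  y[names(overrides)] <- overrides
  bad <- setdiff(names(y), names(formals(run_config)))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full atlas pipeline
#'
#' Executes, in order: simulate (optional), atlas (filtering, tau,
#' classification, tissue correlations), de (one-vs-all NB LRT), modules
#' (co-expression detection, activity, hubs), networks (tissue-specific
#' PPI subnetworks) and labels (label-set association, when label files
#' are given). Every stage writes its outputs under \code{outdir} and the
#' run ends with a \code{manifest.json} recording parameters, stages and
#' input checksums. Identical config and seed reproduce identical outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @param outdir output directory (created).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- character()
  truth <- NULL

  if (isTRUE(config$simulate)) {
    sim <- .stage("simulate", {
      sc <- do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                                  config$sim))
      s <- simulate_atlas(sc)
      s$ppi <- simulate_ppi(s$truth, sc)
      fx <- file.path(outdir, "fixture")
      write_fixture(fx, s$atlas, s$counts, s$truth, s$ppi)
      s
    })
    atlas <- sim$atlas
    counts <- sim$counts
    ppi_path <- file.path(outdir, "fixture", "ppi.tsv")
    truth <- sim$truth
    stages <- c(stages, "simulate")
  } else {
    atlas <- .stage("read", expression_atlas(
      read_matrix_tsv(config$expression), read_design_tsv(config$design)))
    counts <- if (!is.null(config$counts))
      .stage("read", read_matrix_tsv(config$counts, integer_counts = TRUE))
    ppi_path <- config$ppi
    stages <- c(stages, "read")
  }

  res_atlas <- .stage("atlas", {
    profile <- average_replicates(atlas)
    profile <- filter_genes(profile, min_mean = config$min_mean)
    tau <- compute_tau(profile)
    tau <- classify_genes(profile, tau, detect_tpm = config$detect_tpm,
                          tau_specific = config$tau_specific,
                          tau_group = config$tau_group, fold = config$fold)
    write_tau_table(tau, file.path(outdir, "tau_classification.tsv"))
    ts <- tau$gene_id[tau$category == "TissueSpecific"]
    tc <- if (length(ts) >= 3) tissue_correlation(profile, ts) else NULL
    if (!is.null(tc))
      utils::write.table(tc, file.path(outdir, "tissue_correlation.tsv"),
                         sep = "\t", quote = FALSE)
    fc <- tryCatch(foldchange_tau_correlation(tau), error = function(e) NULL)
    list(profile = profile, tau = tau, tissue_cor = tc, fc_tau = fc)
  })
  stages <- c(stages, "atlas")

  res_de <- NULL
  if (!is.null(counts)) {
    res_de <- .stage("de", {
      de <- de_all_tissues(counts, atlas$design,
                           lfc_cutoff = config$lfc_cutoff,
                           p_cutoff = config$p_cutoff)
      utils::write.table(de, file.path(outdir, "de_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      de
    })
    stages <- c(stages, "de")
  }

  res_mod <- .stage("modules", {
    # modules are sought among tissue-specific genes (the most variable
    # n_top of them), mirroring the differential-co-expression design
    ts <- res_atlas$tau$gene_id[res_atlas$tau$category == "TissueSpecific"]
    if (length(ts) < 30) ts <- res_atlas$tau$gene_id
    sub <- atlas
    sub$tpm <- atlas$tpm[ts, , drop = FALSE]
    sel <- select_genes(sub, min(config$n_top, length(ts)))
    expr <- t(log2(atlas$tpm[sel, , drop = FALSE] + 1))
    cc <- suppressWarnings(stats::cor(expr)); cc[is.na(cc)] <- 0
    beta <- tryCatch(
      select_soft_power(cc, candidates = config$beta_candidates),
      warning = function(w) 6L)
    mods <- detect_modules(expr, beta,
                           min_module_size = config$min_module_size)
    activity <- do.call(rbind, lapply(seq_along(mods$modules), function(i) {
      a <- module_activity(mods$modules[[i]], atlas, n_perm = config$n_perm,
                           seed = config$seed + i)
      cbind(module = mods$modules[[i]]$id, a)
    }))
    hubs <- do.call(rbind, lapply(mods$modules, function(m) {
      h <- find_hubs(m, mods$adjacency, k = min(5, length(m$genes)))
      cbind(module = m$id, h)
    }))
    write_gmt(mods, file.path(outdir, "modules.gmt"))
    if (!is.null(activity))
      utils::write.table(activity, file.path(outdir, "module_activity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(hubs))
      utils::write.table(hubs, file.path(outdir, "hubs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    list(mods = mods, activity = activity, hubs = hubs)
  })
  stages <- c(stages, "modules")

  res_net <- NULL
  if (!is.null(ppi_path)) {
    res_net <- .stage("networks", {
      if (!is.data.frame(ppi_path) && !file.exists(ppi_path))
        stop("ppi file not found: ", ppi_path)
      ppi <- load_ppi(ppi_path, min_score = config$min_score)
      tissues <- sort(unique(atlas$design$tissue))
      nets <- lapply(tissues, function(t)
        extract_tissue_network(ppi, res_atlas$tau, res_mod$mods,
                               res_mod$activity, t,
                               activity_p = config$activity_p,
                               min_component = config$min_component))
      names(nets) <- tissues
      for (nt in nets) if (length(nt$nodes))
        write_tissue_network(nt, file.path(outdir, "networks"))
      nets
    })
    stages <- c(stages, "networks")
  }

  res_lab <- NULL
  if (!is.null(config$label_files)) {
    res_lab <- .stage("labels", {
      labs <- lapply(seq_along(config$label_files), function(i)
        read_label_set(config$label_files[i],
                       name = names(config$label_files)[i]))
      rep <- compare_label_sets(res_atlas$tau, res_atlas$profile, labs)
      utils::write.table(rep$tau_summary,
                         file.path(outdir, "label_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(rep$crosstab,
                         file.path(outdir, "label_crosstab.tsv"),
                         sep = "\t", quote = FALSE)
      rep
    })
    stages <- c(stages, "labels")
  }

  inputs <- c(expression = config$expression, counts = config$counts,
              design = config$design,
              ppi = if (is.character(ppi_path)) ppi_path else NULL)
  manifest <- list(
    stages = stages,
    parameters = config[setdiff(names(config),
                                c("expression", "counts", "design", "ppi",
                                  "label_files"))],
    input_checksums = if (length(inputs))
      as.list(stats::setNames(unname(tools::md5sum(unlist(inputs))),
                              names(inputs))) else list())
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(atlas = atlas, counts = counts, truth = truth,
                 atlas_results = res_atlas, de = res_de,
                 modules = res_mod, networks = res_net, labels = res_lab,
                 manifest = manifest, outdir = outdir))
}

#' Summarize a completed pipeline run
#'
#' Reads the run directory and produces the headline tables: gene counts
#' and fractions per tissue-specificity category, per-tissue
#' tissue-specific gene counts, the module table (module, size,
#' significantly active tissues, hubs), and the tissue-network table.
#'
#' @param outdir a completed \code{\link{run_pipeline}} directory.
#' @param activity_p significance cutoff used for the module table's
#'   active-tissue column (default 0.05).
#' @return list with \code{categories}, \code{ts_per_tissue},
#'   \code{modules}, \code{networks}.
#' @export
summarize_run <- function(outdir, activity_p = 0.05) {
  p_tau <- file.path(outdir, "tau_classification.tsv")
  if (!file.exists(p_tau)) stop("incomplete run: missing tau_classification.tsv")
  tau <- utils::read.delim(p_tau, stringsAsFactors = FALSE)
  lev <- c("TissueSpecific", "GroupEnriched", "ExpressedInAll", "Mixed")
  n <- table(factor(tau$category, levels = lev))
  categories <- data.frame(category = lev, n = as.integer(n),
                           fraction_pct = round(100 * as.integer(n) /
                                                  nrow(tau), 2))
  ts <- tau[tau$category == "TissueSpecific", ]
  ts_per_tissue <- as.data.frame(table(max_tissue = ts$max_tissue),
                                 stringsAsFactors = FALSE)
  names(ts_per_tissue)[2] <- "n_tissue_specific"

  modules <- NULL
  p_gmt <- file.path(outdir, "modules.gmt")
  if (file.exists(p_gmt) && length(readLines(p_gmt))) {
    gmt <- strsplit(readLines(p_gmt), "\t")
    act <- utils::read.delim(file.path(outdir, "module_activity.tsv"),
                             stringsAsFactors = FALSE)
    hubs <- utils::read.delim(file.path(outdir, "hubs.tsv"),
                              stringsAsFactors = FALSE)
    modules <- do.call(rbind, lapply(gmt, function(row) {
      id <- row[1]
      up <- act$tissue[act$module == id & act$nes > 0 & act$p < activity_p]
      data.frame(module = id, size = length(row) - 2,
                 up_tissues = paste(up, collapse = ";"),
                 hubs = paste(hubs$gene_id[hubs$module == id],
                              collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  }

  networks <- NULL
  net_dir <- file.path(outdir, "networks")
  if (dir.exists(net_dir)) {
    fs <- list.files(net_dir, pattern = "_network\\.tsv$", full.names = TRUE)
    networks <- do.call(rbind, lapply(fs, function(f) {
      ed <- utils::read.delim(f, stringsAsFactors = FALSE)
      data.frame(tissue = sub("^tissue_(.*)_network\\.tsv$", "\\1",
                              basename(f)),
                 n_nodes = length(unique(c(ed$protein1, ed$protein2))),
                 n_edges = nrow(ed), stringsAsFactors = FALSE)
    }))
  }
  list(categories = categories, ts_per_tissue = ts_per_tissue,
       modules = modules, networks = networks)
}
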