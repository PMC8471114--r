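#' Configuration for the synthetic atlas generator
#'
#' Defines the study design emulated by \code{\link{simulate_atlas}}: a
#' multi-tissue bulk RNA-seq atlas with a small number of pooled replicate
#' libraries per tissue, genes planted in four tissue-specificity
#' categories, latent-factor co-expression modules among tissue-specific
#' genes, and a scored interactome with planted cliques.
#'
#' Category fractions default to the proportions observed in published
#' multi-tissue fish atlases (15\% tissue-specific, 19.5\% group-enriched,
#' 29.8\% expressed-in-all, 35.7\% mixed). Tissue-specific genes are planted
#' at folds drawn from [\code{specific_fold}, 4 x \code{specific_fold}];
#' group-enriched genes at folds 16--64 over the non-group tissues; mixed
#' genes at 2.4--3.5-fold enrichment in 2--4 tissues over a sub-detection
#' baseline, so that they pass the grand-mean filter yet fall below the
#' per-tissue detection threshold somewhere.
#'
#' @param n_tissues number of tissues (default 10).
#' @param n_replicates replicate libraries per tissue (default 2).
#' @param n_genes total genes (default 5000).
#' @param category_fractions named fractions for TissueSpecific,
#'   GroupEnriched, ExpressedInAll, Mixed; must sum to 1.
#' @param specific_fold minimum planted fold of a tissue-specific gene's
#'   target tissue over every other tissue (>= 5; default 8). \code{Inf}
#'   plants single-tissue genes with zero off-target expression.
#' @param group_size_range integer pair: range of enriched-group sizes,
#'   within [2, n_tissues - 3] (default c(2, 5)).
#' @param baseline_log2_mean,baseline_log2_sd log2-TPM baseline expression
#'   distribution (defaults 3 and 2).
#' @param noise_log2_sd per-sample log2 noise sd (default 0.2; 0 = no
#'   sample noise).
#' @param nb_dispersion negative-binomial dispersion phi of the counts,
#'   variance mu + phi mu^2 (default 0.1; 0 = deterministic expected
#'   counts).
#' @param library_size_mean mean sequencing depth per library (default
#'   2e7).
#' @param n_modules number of planted co-expression modules (default 7).
#' @param module_size_range integer pair of module sizes (default
#'   c(14, 55)).
#' @param ppi_background_edges number of random background interactions
#'   (default 2000).
#' @param ppi_clique_fraction fraction of modules that receive a planted
#'   high-score clique (default 0.5).
#' @param ppi_clique_size clique size (>= 3, default 5).
#' @param seed integer seed; the same config is bit-reproducible.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_tissues = 10L, n_replicates = 2L, n_genes = 5000L,
                       category_fractions = c(TissueSpecific = 0.15,
                                              GroupEnriched = 0.195,
                                              ExpressedInAll = 0.298,
                                              Mixed = 0.357),
                       specific_fold = 8, group_size_range = c(2L, 5L),
                       baseline_log2_mean = 3, baseline_log2_sd = 2,
                       noise_log2_sd = 0.2, nb_dispersion = 0.1,
                       library_size_mean = 2e7, n_modules = 7L,
                       module_size_range = c(14L, 55L),
                       ppi_background_edges = 2000L,
                       ppi_clique_fraction = 0.5, ppi_clique_size = 5L,
                       seed = 1L) {
  if (abs(sum(category_fractions) - 1) > 1e-9)
    stop("category_fractions must sum to 1")
  need <- c("TissueSpecific", "GroupEnriched", "ExpressedInAll", "Mixed")
  if (!all(need %in% names(category_fractions)))
    stop("category_fractions must name all four categories")
  if (group_size_range[1] < 2 || group_size_range[2] > n_tissues - 3)
    stop("group_size_range must lie within [2, n_tissues - 3]")
  if (specific_fold < 5) stop("specific_fold must be >= 5")
  if (baseline_log2_sd <= 0) stop("baseline_log2_sd must be > 0")
  if (noise_log2_sd < 0 || nb_dispersion < 0)
    stop("noise_log2_sd and nb_dispersion must be >= 0")
  if (ppi_clique_size < 3) stop("cliques need >= 3 nodes")
  if (ppi_clique_size > module_size_range[1])
    stop("clique size exceeds smallest module size")
  structure(list(
    n_tissues = as.integer(n_tissues), n_replicates = as.integer(n_replicates),
    n_genes = as.integer(n_genes),
    category_fractions = category_fractions[need],
    specific_fold = specific_fold,
    group_size_range = as.integer(group_size_range),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    noise_log2_sd = noise_log2_sd, nb_dispersion = nb_dispersion,
    library_size_mean = library_size_mean, n_modules = as.integer(n_modules),
    module_size_range = as.integer(module_size_range),
    ppi_background_edges = as.integer(ppi_background_edges),
    ppi_clique_fraction = ppi_clique_fraction,
    ppi_clique_size = as.integer(ppi_clique_size),
    seed = as.integer(seed)), class = "sim_config")
}

# deterministic integer allocation of n genes to category fractions
.allocate_categories <- function(fractions, n) {
  cum <- round(cumsum(fractions) * n)
  counts <- diff(c(0L, cum))
  names(counts) <- names(fractions)
  counts
}

#' Simulate a multi-tissue expression atlas with planted ground truth
#'
#' Draws per-gene per-tissue mean expression according to planted
#' categories, adds latent-factor co-expression modules among
#' tissue-specific genes, then samples sequencing counts per library with a
#' negative-binomial model (variance mu + phi mu^2) at the planted relative
#' abundances. The TPM matrix is the per-sample counts-per-million rescale
#' of the counts (gene lengths fixed at 1).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{atlas} (an \code{\link{expression_atlas}}),
#'   \code{counts} (integer matrix with the same dimnames), and
#'   \code{truth}: list with \code{genes} (data.frame gene_id, category,
#'   target, true_fold, module) and \code{modules} (list of id, genes,
#'   tissue).
#' @export
simulate_atlas <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nt <- config$n_tissues
  nr <- config$n_replicates
  ng <- config$n_genes
  tissues <- sprintf("tissue%02d", seq_len(nt))
  samples <- as.vector(outer(seq_len(nr), tissues,
                             function(r, t) paste0(t, "_rep", r)))
  design <- data.frame(sample_id = samples,
                       tissue = rep(tissues, each = nr),
                       stringsAsFactors = FALSE)
  counts_per_cat <- .allocate_categories(config$category_fractions, ng)
  category <- rep(names(counts_per_cat), counts_per_cat)
  category <- sample(category)  # shuffle gene order
  gene_ids <- sprintf("gene%05d", seq_len(ng))

  log2mu <- matrix(NA_real_, ng, nt, dimnames = list(gene_ids, tissues))
  target <- character(ng)
  true_fold <- rep(NA_real_, ng)

  for (i in seq_len(ng)) {
    b <- stats::rnorm(1, config$baseline_log2_mean, config$baseline_log2_sd)
    cat_i <- category[i]
    if (cat_i == "TissueSpecific") {
      b <- max(b, 5)                       # target >= 32 TPM, survives filter
      t0 <- sample(nt, 1)
      f <- config$specific_fold * 2^stats::runif(1, 0, 2)
      log2mu[i, ] <- if (is.finite(f)) b - log2(f) else -Inf
      log2mu[i, t0] <- b
      target[i] <- tissues[t0]
      true_fold[i] <- f
    } else if (cat_i == "GroupEnriched") {
      b <- max(b, 5)
      k <- sample(seq(config$group_size_range[1], config$group_size_range[2]), 1)
      grp <- sort(sample(nt, k))
      f <- 2^stats::runif(1, 4, 6)          # 16--64 fold over non-group
      log2mu[i, ] <- b - log2(f)
      log2mu[i, grp] <- b
      target[i] <- paste(tissues[grp], collapse = ";")
      true_fold[i] <- f
    } else if (cat_i == "ExpressedInAll") {
      b <- max(b, 2)                        # >= 4 TPM everywhere
      log2mu[i, ] <- b
      target[i] <- ""
      true_fold[i] <- 1
    } else {                                # Mixed: moderate enrichment
      ke <- sample(3:4, 1)
      f <- 2^stats::runif(1, log2(2.6), log2(3.5))
      lmin <- 1.25 * nt / (nt - ke + ke * f)
      L <- stats::runif(1, lmin, 0.88)      # sub-detection baseline TPM
      grp <- sort(sample(nt, ke))
      log2mu[i, ] <- log2(L)
      log2mu[i, grp] <- log2(L * f)
      target[i] <- paste(tissues[grp], collapse = ";")
      true_fold[i] <- f
    }
  }

  # Planted values are meant as absolute TPM, so per-tissue totals must come
  # out near 1e6 after the counts-per-million rescale. Mixed genes are pinned
  # to their sub-detection baselines; the other categories absorb the scale.
  mixed <- category == "Mixed"
  tot <- colSums(2^log2mu)
  tot_mixed <- colSums(2^log2mu[mixed, , drop = FALSE])
  cal <- (1e6 - mean(tot_mixed)) / mean(tot - tot_mixed)
  log2mu[!mixed, ] <- log2mu[!mixed, ] + log2(cal)

  # planted co-expression modules: blocks of tissue-specific genes sharing a
  # latent per-sample factor that is shifted upward in the module's tissue
  module_of <- character(ng)
  modules <- list()
  mod_tissues <- sample(tissues, min(config$n_modules, nt))
  loading <- matrix(0, ng, length(mod_tissues))
  for (mi in seq_along(mod_tissues)) {
    tt <- mod_tissues[mi]
    pool <- which(category == "TissueSpecific" & target == tt &
                  module_of == "")
    sz <- sample(seq(config$module_size_range[1],
                     config$module_size_range[2]), 1)
    sz <- min(sz, length(pool))
    if (sz < 3) next
    members <- sample(pool, sz)
    module_of[members] <- sprintf("M%d", mi)
    loading[members, mi] <- stats::runif(sz, 0.8, 1.2)
    modules[[length(modules) + 1]] <-
      list(id = sprintf("M%d", mi), genes = gene_ids[members], tissue = tt)
  }

  # per-sample expression in log2 space: tissue mean + module factor + noise
  ns <- length(samples)
  latent <- matrix(stats::rnorm(length(mod_tissues) * ns, 0, 0.5),
                   length(mod_tissues), ns)
  for (mi in seq_along(mod_tissues))
    latent[mi, design$tissue == mod_tissues[mi]] <-
      latent[mi, design$tissue == mod_tissues[mi]] + 1.5
  log2expr <- log2mu[, design$tissue, drop = FALSE]
  colnames(log2expr) <- samples
  if (length(mod_tissues)) log2expr <- log2expr + loading %*% latent
  if (config$noise_log2_sd > 0)
    log2expr <- log2expr + matrix(stats::rnorm(ng * ns, 0,
                                               config$noise_log2_sd), ng, ns)
  expr <- 2^log2expr                        # -Inf -> 0
  rel <- sweep(expr, 2L, colSums(expr), "/")

  libsize <- round(config$library_size_mean * 2^stats::runif(ns, -0.25, 0.25))
  mu <- sweep(rel, 2L, libsize, "*")
  counts <- if (config$nb_dispersion > 0) {
    matrix(stats::rnbinom(ng * ns, size = 1 / config$nb_dispersion, mu = mu),
           ng, ns)
  } else {
    round(mu)                               # noiseless limit
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, samples)

  tpm <- sweep(counts, 2L, colSums(counts), "/") * 1e6
  atlas <- expression_atlas(tpm, design)
  truth <- list(
    genes = data.frame(gene_id = gene_ids, category = category,
                       target = target, true_fold = true_fold,
                       module = module_of, stringsAsFactors = FALSE),
    modules = modules)
  list(atlas = atlas, counts = counts, truth = truth)
}

#' Simulate a scored protein-protein interaction edge list
#'
#' Background edges are drawn uniformly over gene pairs with combined
#' scores Uniform(0, 1); in a subset of the planted co-expression modules a
#' complete clique of high-scoring edges (scores Uniform(0.75, 1)) is
#' planted among module genes, recorded in the returned truth. Duplicate
#' undirected pairs are collapsed keeping the maximal score; no self-loops.
#'
#' @param truth the \code{truth} element of \code{\link{simulate_atlas}}.
#' @param config the same \code{\link{sim_config}}.
#' @return list with \code{edges} (data.frame protein1, protein2,
#'   combined_score) and \code{cliques} (list of id, genes, tissue; empty
#'   when \code{ppi_clique_fraction} is 0).
#' @export
simulate_ppi <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(truth$modules) && config$ppi_clique_fraction > 0)
    stop("truth contains no modules to plant cliques into")
  set.seed(config$seed + 1L)
  genes <- truth$genes$gene_id
  ng <- length(genes)
  i <- sample(ng, config$ppi_background_edges, replace = TRUE)
  j <- sample(ng, config$ppi_background_edges, replace = TRUE)
  keep <- i != j
  a <- pmin(i[keep], j[keep]); b <- pmax(i[keep], j[keep])
  edges <- data.frame(protein1 = genes[a], protein2 = genes[b],
                      combined_score = stats::runif(length(a)),
                      stringsAsFactors = FALSE)

  cliques <- list()
  n_cl <- round(config$ppi_clique_fraction * length(truth$modules))
  if (n_cl > 0) {
    # plant into the largest modules for stable recovery fixtures
    ord <- order(-vapply(truth$modules, function(m) length(m$genes), 1L))
    for (mi in ord[seq_len(min(n_cl, length(truth$modules)))]) {
      mod <- truth$modules[[mi]]
      if (length(mod$genes) < config$ppi_clique_size)
        stop("clique size exceeds module size")
      cg <- sort(sample(mod$genes, config$ppi_clique_size))
      pairs <- utils::combn(cg, 2)
      edges <- rbind(edges, data.frame(
        protein1 = pairs[1, ], protein2 = pairs[2, ],
        combined_score = stats::runif(ncol(pairs), 0.75, 1),
        stringsAsFactors = FALSE))
      cliques[[length(cliques) + 1]] <-
        list(id = paste0("clique_", mod$id), genes = cg, tissue = mod$tissue)
    }
  }
  # dedupe unordered pairs, keep max score
  key <- paste(edges$protein1, edges$protein2, sep = "\r")
  ord <- order(key, -edges$combined_score)
  edges <- edges[ord, ][!duplicated(key[ord]), ]
  rownames(edges) <- NULL
  list(edges = edges, cliques = cliques)
}

#' Write a synthetic fixture to disk
#'
#' Emits \code{expression.tsv}, \code{counts.tsv} (first column gene_id,
#' then sample columns), \code{design.tsv} (sample_id, tissue),
#' \code{ppi.tsv} (protein1, protein2, combined_score) and
#' \code{truth.json}. Numeric TPM values are written with 17 significant
#' digits so the files round-trip bit-exactly through the readers.
#'
#' @param dir_path output directory (created if missing).
#' @param atlas,counts,truth,ppi outputs of \code{\link{simulate_atlas}}
#'   and \code{\link{simulate_ppi}}; \code{ppi} may be NULL.
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(dir_path, atlas, counts, truth, ppi = NULL) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir_path)) stop("cannot create directory: ", dir_path)
  p_expr <- file.path(dir_path, "expression.tsv")
  p_cnt <- file.path(dir_path, "counts.tsv")
  p_des <- file.path(dir_path, "design.tsv")
  p_truth <- file.path(dir_path, "truth.json")
  .write_matrix_tsv(atlas$tpm, p_expr, digits17 = TRUE)
  .write_matrix_tsv(counts, p_cnt, digits17 = FALSE)
  utils::write.table(atlas$design, p_des, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(truth, p_truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(expression = p_expr, counts = p_cnt, design = p_des,
             truth = p_truth)
  if (!is.null(ppi)) {
    p_ppi <- file.path(dir_path, "ppi.tsv")
    pe <- ppi$edges
    pe$combined_score <- sprintf("%.17g", pe$combined_score)
    utils::write.table(pe, p_ppi, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, ppi = p_ppi)
  }
  invisible(paths)
}

.write_matrix_tsv <- function(m, path, digits17 = FALSE) {
  vals <- if (digits17) {
    matrix(sprintf("%.17g", m), nrow(m))
  } else {
    matrix(format(m, scientific = FALSE, trim = TRUE), nrow(m))
  }
  df <- data.frame(gene_id = rownames(m), vals, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c("gene_id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an expression or count matrix written by \code{write_fixture}
#'
#' @param path TSV with first column gene_id and one column per sample.
#' @param integer_counts coerce values to integer (for counts.tsv).
#' @return numeric (or integer) matrix with gene ids as rownames.
#' @export
read_matrix_tsv <- function(path, integer_counts = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- if (integer_counts) "integer" else "double"
  m
}

#' Read a sample design table (sample_id, tissue)
#' @param path TSV path.
#' @return data.frame with columns sample_id and tissue.
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue") %in% names(df)))
    stop("design file needs columns sample_id, tissue")
  df
}

#' Read a fixture truth file
#' @param path truth.json path.
#' @return the truth list (genes data.frame, modules list).
#' @export
read_truth_json <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(tr$modules)) {
    tr$modules <- lapply(seq_len(nrow(tr$modules)), function(i)
      list(id = tr$modules$id[i], genes = tr$modules$genes[[i]],
           tissue = tr$modules$tissue[i]))
  }
  tr
}
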