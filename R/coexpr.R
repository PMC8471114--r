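#' Select the most variable genes for network construction
#'
#' Ranks genes by variance of log2(TPM + 1) across samples and keeps the
#' top \code{n_top}. Ties are broken by gene id for determinism.
#'
#' @param atlas an \code{\link{expression_atlas}} (variance is taken over
#'   samples).
#' @param n_top number of genes to keep.
#' @return character vector of selected gene ids.
#' @export
select_genes <- function(atlas, n_top) {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (n_top > nrow(atlas$tpm)) stop("n_top exceeds gene count")
  lg <- log2(atlas$tpm + 1)
  v <- apply(lg, 1L, stats::var)
  ord <- order(-v, rownames(atlas$tpm))
  rownames(atlas$tpm)[ord[seq_len(n_top)]]
}

# scale-free topology fit index: R^2 of log10 p(k) ~ log10 k over degree
# bins, zeroed when the slope is positive (not scale-free-like).
.scale_free_r2 <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(0)
  bin <- cut(k, n_bins, include.lowest = TRUE)   # equal-width bins
  dk <- tapply(k, bin, mean)
  pk <- as.vector(table(bin)) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(0)
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] > 0) 0 else r2
}

#' Choose the soft-thresholding power for the co-expression network
#'
#' Evaluates candidate powers beta on the weighted adjacency
#' |r|^beta and returns the smallest beta whose connectivity distribution
#' fits a scale-free topology with R^2 >= \code{r2_cutoff}; if none
#' qualifies, the candidate maximizing R^2. A degenerate (identity)
#' correlation matrix falls back to \code{default_beta} = 6 with a
#' warning. Strongly blocked correlation structures never look scale-free
#' at low powers, so when calling this on a tissue-blocked gene subset
#' restrict \code{candidates} to the conventional range (>= 6); the
#' pipeline does this by default.
#'
#' @param corr gene x gene Pearson correlation matrix (>= 30 genes).
#' @param candidates candidate powers (default 1:20).
#' @param r2_cutoff scale-free fit threshold (default 0.8).
#' @param default_beta fallback power when no candidate fits (default 6).
#' @return integer beta.
#' @export
select_soft_power <- function(corr, candidates = 1:20, r2_cutoff = 0.8,
                              default_beta = 6L) {
  if (nrow(corr) < 30) stop("need >= 30 genes")
  off <- abs(corr); diag(off) <- 0
  if (max(off) < 1e-12) {
    warning("degenerate correlation matrix; falling back to beta = ",
            default_beta)
    return(as.integer(default_beta))
  }
  r2 <- vapply(candidates, function(b) {
    a <- off^b
    .scale_free_r2(rowSums(a))
  }, numeric(1))
  hit <- which(r2 >= r2_cutoff)
  as.integer(if (length(hit)) candidates[hit[1]] else
    candidates[which.max(r2)])
}

# unsigned topological overlap matrix from a weighted adjacency
.tom <- function(a) {
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules
#'
#' Builds the weighted adjacency |Pearson r|^beta over the supplied genes,
#' converts it to topological-overlap dissimilarity, clusters with
#' average-linkage hierarchical clustering and applies a static tree cut
#' at height \code{cut_height}. Clusters of at least
#' \code{min_module_size} genes become modules, labelled M1, M2, ... by
#' descending size; remaining genes form the not-correlated bin.
#'
#' @param expr samples x genes matrix of log2 expression (e.g.
#'   t(log2(tpm + 1)) over selected genes).
#' @param beta soft-thresholding power from
#'   \code{\link{select_soft_power}}.
#' @param min_module_size smallest reported module (default 10).
#' @param cut_height static cut height on the TOM-dissimilarity dendrogram
#'   (default 0.995).
#' @return object of class \code{coexpr_modules}: list with
#'   \code{modules} (list of id, genes), \code{unassigned} (gene ids),
#'   \code{adjacency} (gene x gene matrix), \code{beta}.
#' @export
detect_modules <- function(expr, beta, min_module_size = 10,
                           cut_height = 0.995) {
  genes <- colnames(expr)
  cc <- suppressWarnings(stats::cor(expr))
  cc[is.na(cc)] <- 0
  adj <- abs(cc)^beta
  diss <- 1 - .tom(adj)
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # order surviving clusters by descending size, ties by smallest member id
  ord <- order(-sizes[keep],
               vapply(keep, function(g) min(genes[cl == g]), ""))
  modules <- lapply(seq_along(ord), function(i) {
    g <- sort(genes[cl == keep[ord[i]]])
    list(id = sprintf("M%d", i), genes = g)
  })
  assigned <- unlist(lapply(modules, `[[`, "genes"))
  structure(list(modules = modules,
                 unassigned = sort(setdiff(genes, assigned)),
                 adjacency = adj, beta = beta),
            class = "coexpr_modules")
}

#' @export
print.coexpr_modules <- function(x, ...) {
  cat(sprintf("coexpr_modules: %d modules (beta = %d), %d unassigned genes\n",
              length(x$modules), x$beta, length(x$unassigned)))
  for (m in x$modules) cat(sprintf("  %s: %d genes\n", m$id, length(m$genes)))
  invisible(x)
}

#' Per-tissue module activity (normalized enrichment score)
#'
#' Scores how strongly a module's genes are jointly up- or down-regulated
#' in each tissue. The observed statistic is the mean gene-standardized
#' log2(TPM + 1) of module genes over the tissue's samples; the null is
#' built from \code{n_perm} random gene sets of equal size drawn from the
#' atlas, giving NES = (obs - mean(null)) / sd(null) and an upper-tail
#' permutation p with +1 smoothing.
#'
#' @param module a module (list with \code{genes}) or character vector of
#'   gene ids.
#' @param atlas an \code{\link{expression_atlas}} providing the gene
#'   universe.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutation draw.
#' @return data.frame with columns tissue, nes, p.
#' @export
module_activity <- function(module, atlas, n_perm = 1000, seed = 1L) {
  genes <- if (is.list(module)) module$genes else module
  stopifnot(inherits(atlas, "expression_atlas"))
  genes <- intersect(genes, rownames(atlas$tpm))
  if (!length(genes)) stop("module genes absent from atlas")
  if (length(genes) > nrow(atlas$tpm)) stop("module larger than gene universe")
  lg <- log2(atlas$tpm + 1)
  z <- t(scale(t(lg)))                       # gene-wise standardization
  z[is.na(z)] <- 0                           # constant genes contribute 0
  tissues <- sort(unique(atlas$design$tissue))
  # per-gene per-tissue mean z
  gt <- vapply(tissues, function(t)
    rowMeans(z[, atlas$design$tissue == t, drop = FALSE]),
    numeric(nrow(z)))
  obs <- colMeans(gt[genes, , drop = FALSE])
  set.seed(seed)
  null <- t(vapply(seq_len(n_perm), function(b)
    colMeans(gt[sample(nrow(gt), length(genes)), , drop = FALSE]),
    numeric(length(tissues))))
  nes <- (obs - colMeans(null)) / apply(null, 2L, stats::sd)
  p <- vapply(seq_along(tissues), function(j)
    (1 + sum(null[, j] >= obs[j])) / (n_perm + 1), numeric(1))
  data.frame(tissue = tissues, nes = nes, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Rank intramodule hub genes by connectivity
#'
#' Intramodule connectivity of a gene is the row sum of the weighted
#' adjacency restricted to the module's genes. Returns the top k genes;
#' ties broken by gene id.
#'
#' @param module a module (list with \code{genes}) or gene id vector.
#' @param adjacency gene x gene weighted adjacency (from
#'   \code{\link{detect_modules}}).
#' @param k number of hubs (default 5); if k exceeds the module size all
#'   genes are returned with a warning.
#' @return data.frame with columns gene_id and connectivity, in rank
#'   order.
#' @export
find_hubs <- function(module, adjacency, k = 5) {
  genes <- if (is.list(module)) module$genes else module
  genes <- intersect(genes, rownames(adjacency))
  if (k > length(genes)) {
    warning("k exceeds module size; returning all genes")
    k <- length(genes)
  }
  a <- adjacency[genes, genes, drop = FALSE]
  diag(a) <- 0
  conn <- rowSums(a)
  ord <- order(-conn, genes)
  data.frame(gene_id = genes[ord[seq_len(k)]],
             connectivity = unname(conn[ord[seq_len(k)]]),
             stringsAsFactors = FALSE)
}

#' Write modules as a GMT gene-set file
#' @param mods a \code{coexpr_modules} object.
#' @param path output path.
#' @export
write_gmt <- function(mods, path) {
  lines <- vapply(mods$modules, function(m)
    paste(c(m$id, sprintf("coexpression module (%d genes)", length(m$genes)),
            m$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
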