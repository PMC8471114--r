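#' Construct a multi-tissue expression atlas
#'
#' Bundles a genes x samples TPM matrix with its sample-to-tissue design.
#' The atlas is the entry point of the pipeline: replicate averaging, gene
#' filtering, tau computation and classification all start from it.
#'
#' @param tpm numeric matrix, genes x samples, non-negative TPM values with
#'   gene ids as rownames and sample ids as colnames.
#' @param design data.frame with columns \code{sample_id} and \code{tissue};
#'   every column of \code{tpm} must appear exactly once in
#'   \code{design$sample_id}.
#' @return An object of class \code{expression_atlas} with elements
#'   \code{tpm} and \code{design}.
#' @export
expression_atlas <- function(tpm, design) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm))) stop("tpm must have gene ids as rownames")
  if (is.null(colnames(tpm))) stop("tpm must have sample ids as colnames")
  if (anyDuplicated(rownames(tpm))) stop("duplicate gene ids")
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue") %in% names(design)))
    stop("design needs columns sample_id, tissue")
  design$sample_id <- as.character(design$sample_id)
  design$tissue <- as.character(design$tissue)
  missing <- setdiff(colnames(tpm), design$sample_id)
  if (length(missing))
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  design <- design[match(colnames(tpm), design$sample_id), , drop = FALSE]
  if (length(unique(design$tissue)) < 2) stop("need at least 2 tissues")
  structure(list(tpm = tpm, design = design), class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("expression_atlas: %d genes x %d samples, %d tissues\n",
              nrow(x$tpm), ncol(x$tpm), length(unique(x$design$tissue))))
  invisible(x)
}

#' Average replicate samples into a per-tissue profile
#'
#' Collapses a sample-level atlas to tissue-level expression by taking the
#' arithmetic mean of each tissue's replicate TPM columns. All downstream
#' tissue-specificity statistics (tau, classification) operate on this
#' profile.
#'
#' @param atlas an \code{\link{expression_atlas}}.
#' @return An object of class \code{tissue_profile}: list with \code{means}
#'   (genes x tissues matrix, tissue columns in sorted order) and
#'   \code{n_tissues}.
#' @export
average_replicates <- function(atlas) {
  stopifnot(inherits(atlas, "expression_atlas"))
  tissues <- sort(unique(atlas$design$tissue))
  means <- vapply(tissues, function(t) {
    cols <- atlas$design$sample_id[atlas$design$tissue == t]
    if (!length(cols)) stop("tissue with zero samples: ", t)
    rowMeans(atlas$tpm[, cols, drop = FALSE])
  }, numeric(nrow(atlas$tpm)))
  means <- matrix(means, nrow = nrow(atlas$tpm))
  dimnames(means) <- list(rownames(atlas$tpm), tissues)
  structure(list(means = means, n_tissues = length(tissues)),
            class = "tissue_profile")
}

#' @export
print.tissue_profile <- function(x, ...) {
  cat(sprintf("tissue_profile: %d genes x %d tissues\n",
              nrow(x$means), x$n_tissues))
  invisible(x)
}

#' Filter lowly expressed and annotated non-coding genes
#'
#' Removes genes whose mean expression over all tissues is at or below
#' \code{min_mean} TPM (inclusive removal: a grand mean of exactly
#' \code{min_mean} is dropped), and genes listed in \code{ncRNA_ids}.
#'
#' @param profile a \code{tissue_profile}.
#' @param ncRNA_ids character vector of gene ids to drop regardless of
#'   expression (e.g. annotated non-coding RNAs). Default none.
#' @param min_mean removal threshold on the grand mean TPM; genes with
#'   grand mean strictly greater than this are retained. Default 1.
#' @return The filtered \code{tissue_profile}; attribute \code{"removed"}
#'   carries a named count of genes dropped for low expression and by the
#'   ncRNA list.
#' @export
filter_genes <- function(profile, ncRNA_ids = character(), min_mean = 1.0) {
  stopifnot(inherits(profile, "tissue_profile"), min_mean >= 0)
  gm <- rowMeans(profile$means)
  low <- gm <= min_mean
  nc <- rownames(profile$means) %in% ncRNA_ids
  keep <- !low & !nc
  if (!any(keep)) stop("no genes retained after filtering")
  out <- profile
  out$means <- profile$means[keep, , drop = FALSE]
  attr(out, "removed") <- c(low_expression = sum(low & !nc), ncRNA = sum(nc))
  out
}

#' Tissue-specificity index tau
#'
#' For each gene g with per-tissue mean expression x_i over N tissues,
#' tau = sum_i (1 - x_i / max_i x_i) / (N - 1). tau is 0 for perfectly
#' uniform expression and 1 when a gene is expressed in a single tissue.
#'
#' @param profile a filtered \code{tissue_profile}; every gene must have a
#'   positive maximum (guaranteed after \code{\link{filter_genes}}).
#' @return data.frame with columns \code{gene_id}, \code{tau},
#'   \code{max_tissue} (tissue of maximal mean expression, ties broken by
#'   tissue name), \code{max_tpm}, and \code{fold_over_rest} (max tissue
#'   mean divided by the largest other tissue mean; \code{Inf} when all
#'   other tissues are zero).
#' @export
compute_tau <- function(profile) {
  stopifnot(inherits(profile, "tissue_profile"))
  m <- profile$means
  mx <- apply(m, 1L, max)
  if (any(mx <= 0))
    stop("gene(s) with all-zero profile: tau undefined; filter first")
  N <- ncol(m)
  tau <- rowSums(1 - m / mx) / (N - 1)
  # ties on the max resolved by tissue (column) name order: columns are sorted
  imax <- apply(m, 1L, which.max)
  second <- vapply(seq_len(nrow(m)), function(i) max(m[i, -imax[i]]),
                   numeric(1))
  data.frame(gene_id = rownames(m),
             tau = tau,
             max_tissue = colnames(m)[imax],
             max_tpm = mx,
             fold_over_rest = ifelse(second > 0, mx / second, Inf),
             stringsAsFactors = FALSE)
}

#' Classify genes into tissue-specificity categories
#'
#' Assigns every retained gene to exactly one of four categories, evaluated
#' in precedence order:
#' \describe{
#'   \item{TissueSpecific}{tau > 0.85 and the top tissue mean is at least
#'     5-fold higher than the mean of every other tissue (i.e. 5 x the
#'     maximum of the others).}
#'   \item{GroupEnriched}{tau > 0.5 and there is a group of k tissues
#'     (2 <= k <= 7) such that, with tissues sorted by descending mean,
#'     the smallest of the top-k means is at least 5 x the largest of the
#'     remaining means; the smallest qualifying k defines the group.}
#'   \item{ExpressedInAll}{mean >= \code{detect_tpm} in every tissue.}
#'   \item{Mixed}{everything else.}
#' }
#'
#' @param profile the filtered \code{tissue_profile} used for
#'   \code{\link{compute_tau}}.
#' @param tau data.frame from \code{\link{compute_tau}} on the same genes.
#' @param detect_tpm detection threshold per tissue for ExpressedInAll
#'   (default 1 TPM).
#' @param tau_specific,tau_group tau thresholds for the TissueSpecific and
#'   GroupEnriched rules (defaults 0.85 and 0.5).
#' @param fold enrichment fold required by the TissueSpecific and
#'   GroupEnriched rules (default 5).
#' @param max_group_size largest allowed enriched-group size (default 7).
#' @return \code{tau} with added columns \code{category} (factor with
#'   levels TissueSpecific, GroupEnriched, ExpressedInAll, Mixed) and
#'   \code{group} (semicolon-joined tissues; the target tissue for
#'   TissueSpecific genes, empty otherwise).
#' @export
classify_genes <- function(profile, tau, detect_tpm = 1.0,
                           tau_specific = 0.85, tau_group = 0.5,
                           fold = 5, max_group_size = 7) {
  stopifnot(inherits(profile, "tissue_profile"))
  m <- profile$means
  if (!identical(rownames(m), tau$gene_id))
    stop("tau table and profile cover different genes")
  N <- ncol(m)
  lev <- c("TissueSpecific", "GroupEnriched", "ExpressedInAll", "Mixed")
  category <- character(nrow(m))
  group <- character(nrow(m))
  kmax <- min(max_group_size, N - 1L)
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    ord <- order(-x, names(x))  # descending, ties by tissue name
    xs <- x[ord]
    if (tau$tau[i] > tau_specific && xs[1] >= fold * xs[2]) {
      category[i] <- "TissueSpecific"
      group[i] <- names(xs)[1]
    } else if (tau$tau[i] > tau_group) {
      k <- 0L
      for (kk in 2:kmax) {
        if (xs[kk] >= fold * max(xs[(kk + 1):N])) { k <- kk; break }
      }
      if (k > 0L) {
        category[i] <- "GroupEnriched"
        group[i] <- paste(sort(names(xs)[seq_len(k)]), collapse = ";")
      }
    }
    if (category[i] == "") {
      category[i] <- if (all(x >= detect_tpm)) "ExpressedInAll" else "Mixed"
    }
  }
  tau$category <- factor(category, levels = lev)
  tau$group <- group
  tau
}

#' Pairwise tissue correlation on a gene subset
#'
#' Pearson correlation between tissue expression profiles, computed on
#' log2(TPM + 1) over a chosen gene subset (typically the tissue-specific
#' genes). A tissue with constant expression over the subset yields NA
#' correlations, with a warning.
#'
#' @param profile a \code{tissue_profile}.
#' @param gene_subset character vector of gene ids (>= 3).
#' @return Symmetric tissues x tissues correlation matrix with unit
#'   diagonal.
#' @export
tissue_correlation <- function(profile, gene_subset = rownames(profile$means)) {
  stopifnot(inherits(profile, "tissue_profile"))
  gene_subset <- intersect(gene_subset, rownames(profile$means))
  if (length(gene_subset) < 3) stop("need at least 3 genes")
  lg <- log2(profile$means[gene_subset, , drop = FALSE] + 1)
  sds <- apply(lg, 2L, stats::sd)
  if (any(sds == 0))
    warning("constant tissue column(s): correlations undefined (NA)")
  cc <- suppressWarnings(stats::cor(lg))
  diag(cc) <- 1
  cc
}

#' Correlation between enrichment fold-change and tau
#'
#' Spearman rank correlation (tie-corrected) between log2 fold-change of a
#' gene's top tissue over the rest and its tau index, across genes with a
#' finite fold. By construction of both statistics the association is
#' expected to be strongly positive in a real atlas.
#'
#' @param tau data.frame from \code{\link{compute_tau}} (or
#'   \code{\link{classify_genes}}).
#' @return list with elements \code{rho} and \code{p}.
#' @export
foldchange_tau_correlation <- function(tau) {
  ok <- is.finite(tau$fold_over_rest) & tau$fold_over_rest > 0
  x <- log2(tau$fold_over_rest[ok])
  y <- tau$tau[ok]
  if (length(x) < 10) stop("need at least 10 genes with finite fold")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("all-tied ranks: rank correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Write a tau classification table to TSV
#'
#' @param tau classified tau table from \code{\link{classify_genes}}.
#' @param path output file path.
#' @export
write_tau_table <- function(tau, path) {
  utils::write.table(tau, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
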