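#' Method-of-moments dispersion estimation with shrinkage
#'
#' Estimates the negative-binomial dispersion phi (variance mu + phi mu^2)
#' per gene on library-size-normalized counts by method of moments,
#' phi_g = max(0, (s^2 - mu) / mu^2), then shrinks each estimate toward the
#' trimmed-mean common dispersion with weight
#' w = n_common / (n_common + n_samples). Estimates are floored at 1e-6.
#'
#' @param counts genes x samples integer matrix (gene ids as rownames).
#' @param n_common prior weight of the common dispersion (default 10).
#' @param trim trim fraction for the common-dispersion trimmed mean
#'   (default 0.1).
#' @return numeric vector of dispersions, named by gene; NA for all-zero
#'   genes (flagged with a warning).
#' @export
estimate_dispersions <- function(counts, n_common = 10, trim = 0.1) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  lib <- colSums(counts)
  norm <- sweep(counts, 2L, lib / mean(lib), "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  phi <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), NA_real_)
  zero <- is.na(phi)
  if (any(zero)) warning(sum(zero), " all-zero gene(s): dispersion NA")
  common <- mean(phi[!zero], trim = trim)
  w <- n_common / (n_common + ncol(counts))
  out <- pmax(w * common + (1 - w) * phi, 1e-6)
  names(out) <- rownames(counts)
  out
}

# Maximize the NB log-likelihood over a single log-rate beta, with
# mu_j = exp(beta + offset_j) and size = 1/phi, vectorized over genes.
# counts: genes x samples, offs: per-sample log offsets, phi: per-gene.
# Returns list(beta, loglik); beta = -Inf (loglik 0 contribution) for
# all-zero rows.
.nb_fit_rate <- function(counts, offs, phi, max_iter = 50L, tol = 1e-10) {
  size <- 1 / phi
  tot <- rowSums(counts)
  eo <- exp(offs)
  beta <- log(pmax(tot, 0.5) / sum(eo))
  sz <- matrix(size, nrow(counts), ncol(counts))
  for (it in seq_len(max_iter)) {
    mu <- exp(beta) %o% eo                       # genes x samples
    r <- mu / (sz + mu)
    score <- tot - rowSums((counts + sz) * r)
    info <- rowSums((counts + sz) * r * (1 - r))
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta[tot == 0] <- -Inf
  mu <- exp(beta) %o% eo
  ll <- rowSums(stats::dnbinom(counts, size = sz, mu = mu, log = TRUE))
  ll[tot == 0] <- 0                              # lim mu->0: all mass at 0
  list(beta = beta, loglik = ll)
}

#' One-vs-all negative-binomial likelihood-ratio test
#'
#' For each gene, contrasts the focal tissue's libraries against all
#' remaining libraries under an NB log-linear model with log library-size
#' offsets. The null model fits a single rate; the full model adds a focal
#' group indicator (equivalently, separate rates per group). The statistic
#' is 2(l_full - l_null), compared to chi-squared with 1 df; log2fc is the
#' focal-group coefficient divided by ln 2 (positive = upregulated in the
#' focal tissue).
#'
#' @param counts genes x samples integer matrix.
#' @param design data.frame with \code{sample_id}, \code{tissue} matching
#'   the columns of \code{counts}.
#' @param focal_tissue tissue id contrasted against the rest.
#' @param dispersions per-gene dispersion vector (from
#'   \code{\link{estimate_dispersions}}); estimated if NULL.
#' @return data.frame with columns gene_id, tissue, log2fc, lrt_stat, p,
#'   q (BH-adjusted, reported but unused by the DEG rule), is_deg.
#'   Genes with zero counts everywhere are skipped (NA statistics, not DEG).
#' @export
one_vs_all_lrt <- function(counts, design, focal_tissue, dispersions = NULL) {
  counts <- as.matrix(counts)
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  if (anyNA(design$tissue)) stop("samples missing from design")
  if (!focal_tissue %in% design$tissue)
    stop("unknown focal tissue: ", focal_tissue)
  focal <- design$tissue == focal_tissue
  if (all(focal)) stop("no non-focal samples")
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts)
  dispersions <- dispersions[rownames(counts)]
  phi <- ifelse(is.na(dispersions), 1e-6, dispersions)
  offs <- log(colSums(counts))

  null_fit <- .nb_fit_rate(counts, offs, phi)
  fit_f <- .nb_fit_rate(counts[, focal, drop = FALSE], offs[focal], phi)
  fit_r <- .nb_fit_rate(counts[, !focal, drop = FALSE], offs[!focal], phi)

  lrt <- pmax(0, 2 * (fit_f$loglik + fit_r$loglik - null_fit$loglik))
  log2fc <- (fit_f$beta - fit_r$beta) / log(2)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  allzero <- rowSums(counts) == 0
  lrt[allzero] <- NA_real_
  p[allzero] <- NA_real_
  log2fc[allzero] <- NA_real_
  res <- data.frame(gene_id = rownames(counts), tissue = focal_tissue,
                    log2fc = log2fc, lrt_stat = lrt, p = p,
                    q = stats::p.adjust(p, "BH"),
                    dispersion = dispersions,
                    stringsAsFactors = FALSE, row.names = NULL)
  call_degs(res)
}

#' Apply the differential-expression calling rule
#'
#' A gene is a DEG for its focal tissue when log2fc > \code{lfc_cutoff}
#' (strict) and p < \code{p_cutoff} (strict, unadjusted). By default the
#' rule is signed: only upregulation in the focal tissue qualifies; set
#' \code{absolute = TRUE} to call on |log2fc|.
#'
#' @param results data.frame with columns log2fc and p.
#' @param lfc_cutoff log2 fold-change cutoff (default 3).
#' @param p_cutoff p-value cutoff (default 0.05).
#' @param absolute call on absolute fold change (default FALSE).
#' @return \code{results} with a logical \code{is_deg} column.
#' @export
call_degs <- function(results, lfc_cutoff = 3, p_cutoff = 0.05,
                      absolute = FALSE) {
  fc <- if (absolute) abs(results$log2fc) else results$log2fc
  results$is_deg <- !is.na(results$p) & !is.na(fc) &
    fc > lfc_cutoff & results$p < p_cutoff
  results
}

#' Run the one-vs-all contrast for every tissue
#'
#' @inheritParams one_vs_all_lrt
#' @param ... passed to \code{\link{call_degs}}.
#' @return row-bound data.frame of per-tissue results.
#' @export
de_all_tissues <- function(counts, design, dispersions = NULL, ...) {
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts)
  res <- lapply(sort(unique(design$tissue)), function(t)
    call_degs(one_vs_all_lrt(counts, design, t, dispersions), ...))
  do.call(rbind, res)
}
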