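#' Kruskal-Wallis rank-sum test
#'
#' Rank-based k-sample test implemented directly from its definition:
#' with pooled mid-ranks R and group rank sums R_i over n_i values,
#' H = [12 / (n (n + 1)) * sum R_i^2 / n_i - 3 (n + 1)] / C where
#' C = 1 - sum(t^3 - t) / (n^3 - n) corrects for tied groups of size t.
#' p is from the chi-squared distribution with (k - 1) df.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @return list with \code{H}, \code{p}, \code{df}.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs >= 2 values")
  x <- unlist(groups)
  if (length(unique(x)) == 1)
    stop("all values identical across groups: H undefined")
  n <- length(x)
  r <- rank(x)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  rsum <- tapply(r, g, sum)
  ni <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / ni) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / correction
  df <- length(groups) - 1
  list(H = h, p = stats::pchisq(h, df, lower.tail = FALSE), df = df)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA computed from the between- and
#' within-group sums of squares: F = MS_between / MS_within with
#' (k - 1, n - k) degrees of freedom.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @return list with \code{F}, \code{p}, \code{df1}, \code{df2}.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  ni <- vapply(groups, length, 1L)
  if (any(ni < 2)) stop("each group needs >= 2 values")
  n <- sum(ni)
  k <- length(groups)
  means <- vapply(groups, mean, 1)
  grand <- sum(unlist(groups)) / n
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  if (ssw == 0) stop("zero within-group variance everywhere: F undefined")
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
       df1 = k - 1, df2 = n - k)
}

#' Read a one-gene-per-line label file
#' @param path text file, one gene id per line.
#' @param name label-set name (defaults to the file name without
#'   extension).
#' @return list with \code{name} and \code{genes} (unique ids).
#' @export
read_label_set <- function(path, name = NULL) {
  ids <- unique(trimws(readLines(path)))
  ids <- ids[nzchar(ids)]
  list(name = if (is.null(name))
    sub("\\.[^.]*$", "", basename(path)) else name, genes = ids)
}

#' Compare gene label sets against tau and expression
#'
#' For each supplied label set (e.g. genes under positive selection,
#' transcription factors, housekeeping genes), reports the distribution of
#' tau and of log2(TPM + 1) expression, the cross-tabulation of labels by
#' tissue-specificity categories, pairwise Kruskal-Wallis comparisons of
#' tau between each label set, the tissue-specific genes, and the
#' unlabelled complement (computed both including and excluding the
#' tissue-specific genes), and the per-tissue mean expression of each
#' label set.
#'
#' @param tau classified tau table from \code{\link{classify_genes}}.
#' @param profile the \code{tissue_profile} the classification was made on.
#' @param labels list of label sets (each a list with \code{name},
#'   \code{genes}); sets with no overlap with the atlas are skipped with a
#'   warning.
#' @return object of class \code{label_report}: list with
#'   \code{tau_summary} (per-group n, median/mean tau, median/mean log2
#'   expression), \code{crosstab} (labels x categories counts),
#'   \code{tests} (pairwise Kruskal-Wallis on tau), and
#'   \code{tissue_means} (label x tissue mean TPM).
#' @export
compare_label_sets <- function(tau, profile, labels) {
  stopifnot(inherits(profile, "tissue_profile"))
  universe <- tau$gene_id
  labels <- Filter(function(l) {
    ok <- length(intersect(l$genes, universe)) > 0
    if (!ok) warning("label set ", l$name, " has no genes in the atlas")
    ok
  }, labels)
  groups <- lapply(labels, function(l) intersect(l$genes, universe))
  names(groups) <- vapply(labels, `[[`, "", "name")
  labelled <- unique(unlist(groups))
  ts <- tau$gene_id[tau$category == "TissueSpecific"]
  groups$TS <- ts
  groups$other <- setdiff(universe, labelled)
  groups$other_nonTS <- setdiff(universe, union(labelled, ts))

  mean_expr <- rowMeans(profile$means)
  lg <- log2(mean_expr + 1)
  names(lg) <- universe
  tau_of <- stats::setNames(tau$tau, tau$gene_id)

  tau_summary <- do.call(rbind, lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    data.frame(group = nm, n = length(g),
               median_tau = stats::median(tau_of[g]),
               mean_tau = mean(tau_of[g]),
               median_log2_expr = stats::median(lg[g]),
               mean_log2_expr = mean(lg[g]),
               stringsAsFactors = FALSE)
  }))

  cats <- levels(tau$category)
  crosstab <- t(vapply(names(groups), function(nm) {
    tabulate(factor(tau$category[match(groups[[nm]], tau$gene_id)],
                    levels = cats), length(cats))
  }, integer(length(cats))))
  colnames(crosstab) <- cats

  pair <- utils::combn(names(groups), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pair)), function(j) {
    a <- groups[[pair[1, j]]]; b <- groups[[pair[2, j]]]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    kw <- tryCatch(kruskal_wallis(list(tau_of[a], tau_of[b])),
                   error = function(e) list(H = NA_real_, p = NA_real_))
    data.frame(group1 = pair[1, j], group2 = pair[2, j],
               H = kw$H, p = kw$p, stringsAsFactors = FALSE)
  }))

  tissue_means <- t(vapply(names(groups), function(nm)
    colMeans(profile$means[groups[[nm]], , drop = FALSE]),
    numeric(ncol(profile$means))))

  structure(list(tau_summary = tau_summary, crosstab = crosstab,
                 tests = tests, tissue_means = tissue_means,
                 groups = groups),
            class = "label_report")
}

#' @export
print.label_report <- function(x, ...) {
  cat("label_report\n")
  print(x$tau_summary, row.names = FALSE)
  invisible(x)
}
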