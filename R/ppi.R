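#' Load and filter a scored interaction edge list
#'
#' Reads a STRING-style tab-separated edge list (columns protein1,
#' protein2, combined_score). Scores on the 0--1000 integer scale are
#' auto-detected (any score > 1) and divided by 1000. Unordered duplicate
#' pairs are collapsed keeping the maximal score, self-loops dropped, and
#' only edges with score strictly greater than \code{min_score} are kept.
#'
#' @param path edge-list file, or a data.frame with the same columns.
#' @param min_score retention threshold; strict inequality (default 0.7).
#' @return object of class \code{ppi_graph}: list with \code{edges}
#'   (data.frame protein1, protein2, combined_score) and \code{nodes}.
#' @export
load_ppi <- function(path, min_score = 0.7) {
  df <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(df))) stop("ppi file needs columns ",
                                      paste(need, collapse = ", "))
  df$combined_score <- as.numeric(df$combined_score)
  if (anyNA(df$combined_score)) stop("malformed score values")
  if (any(df$combined_score < 0)) stop("negative interaction scores")
  if (any(df$combined_score > 1)) df$combined_score <- df$combined_score / 1000
  if (any(df$combined_score > 1)) stop("scores exceed 1 after rescaling")
  df <- df[df$protein1 != df$protein2, , drop = FALSE]
  a <- pmin(df$protein1, df$protein2)
  b <- pmax(df$protein1, df$protein2)
  df$protein1 <- a; df$protein2 <- b
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -df$combined_score)
  df <- df[ord, ][!duplicated(key[ord]), , drop = FALSE]
  df <- df[df$combined_score > min_score, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(edges = df,
                 nodes = sort(unique(c(df$protein1, df$protein2)))),
            class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("ppi_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Extract a tissue-specific PPI subnetwork
#'
#' Gates the global interactome to proteins that are (a) classified
#' TissueSpecific with this tissue as their top tissue and (b) members of
#' a co-expression module whose activity in this tissue is significantly
#' positive (NES > 0 and permutation p < \code{activity_p}). The induced
#' subgraph over gated nodes is decomposed into connected components and
#' only components with at least \code{min_component} nodes are reported.
#' A tissue whose gate yields no qualifying component produces a valid
#' empty network.
#'
#' @param ppi a \code{\link{load_ppi}} graph.
#' @param tau classified tau table from \code{\link{classify_genes}}.
#' @param mods a \code{coexpr_modules} object.
#' @param activity data.frame with columns module, tissue, nes, p (one row
#'   per module x tissue, e.g. row-bound \code{\link{module_activity}}
#'   results with a module column).
#' @param tissue tissue id.
#' @param activity_p module-activity significance cutoff (default 0.05).
#' @param min_component smallest reported connected component (default 3).
#' @return object of class \code{tissue_network}: list with \code{tissue},
#'   \code{nodes}, \code{edges}, \code{components} (list of node sets) and
#'   \code{hubs}.
#' @export
extract_tissue_network <- function(ppi, tau, mods, activity, tissue,
                                   activity_p = 0.05, min_component = 3) {
  if (!tissue %in% activity$tissue) stop("unknown tissue id: ", tissue)
  ts_genes <- tau$gene_id[tau$category == "TissueSpecific" &
                          tau$max_tissue == tissue]
  act <- activity[activity$tissue == tissue &
                  activity$nes > 0 & activity$p < activity_p, , drop = FALSE]
  mod_genes <- unlist(lapply(mods$modules, function(m)
    if (m$id %in% act$module) m$genes else character()))
  gate <- intersect(ts_genes, mod_genes)
  ed <- ppi$edges[ppi$edges$protein1 %in% gate &
                  ppi$edges$protein2 %in% gate, , drop = FALSE]
  comps <- list()
  nodes <- character()
  if (nrow(ed)) {
    g <- igraph::graph_from_data_frame(ed, directed = FALSE)
    cmp <- igraph::components(g)
    for (ci in seq_len(cmp$no)) {
      members <- sort(names(cmp$membership)[cmp$membership == ci])
      if (length(members) >= min_component)
        comps[[length(comps) + 1]] <- members
    }
    nodes <- sort(unlist(comps))
    ed <- ed[ed$protein1 %in% nodes & ed$protein2 %in% nodes, , drop = FALSE]
  } else {
    ed <- ed[0, , drop = FALSE]
  }
  rownames(ed) <- NULL
  net <- structure(list(tissue = tissue, nodes = nodes, edges = ed,
                        components = comps, hubs = NULL),
                   class = "tissue_network")
  net$hubs <- if (length(nodes)) network_hubs(net) else
    data.frame(gene_id = character(), degree = integer(),
               score_sum = numeric(), stringsAsFactors = FALSE)
  net
}

#' @export
print.tissue_network <- function(x, ...) {
  cat(sprintf("tissue_network [%s]: %d nodes, %d edges, %d component(s)\n",
              x$tissue, length(x$nodes), nrow(x$edges), length(x$components)))
  invisible(x)
}

#' Rank hub proteins of a tissue network by degree
#'
#' Degree ranking within the network; ties broken by the sum of incident
#' interaction scores, then by gene id.
#'
#' @param network a \code{tissue_network}.
#' @param k number of hubs (default 3); capped at the node count.
#' @return data.frame with columns gene_id, degree, score_sum, in rank
#'   order. Empty for an empty network.
#' @export
network_hubs <- function(network, k = 3) {
  if (!length(network$nodes))
    return(data.frame(gene_id = character(), degree = integer(),
                      score_sum = numeric(), stringsAsFactors = FALSE))
  ends <- c(network$edges$protein1, network$edges$protein2)
  sc <- c(network$edges$combined_score, network$edges$combined_score)
  deg <- vapply(network$nodes, function(n) sum(ends == n), 0L)
  ssum <- vapply(network$nodes, function(n) sum(sc[ends == n]), 0)
  ord <- order(-deg, -ssum, network$nodes)
  k <- min(k, length(network$nodes))
  data.frame(gene_id = network$nodes[ord[seq_len(k)]],
             degree = unname(deg[ord[seq_len(k)]]),
             score_sum = unname(ssum[ord[seq_len(k)]]),
             stringsAsFactors = FALSE)
}

#' Write a tissue network edge list and GraphML export
#' @param network a \code{tissue_network}.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_tissue_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_tsv <- file.path(dir, sprintf("tissue_%s_network.tsv", network$tissue))
  utils::write.table(network$edges, p_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_gml <- file.path(dir, sprintf("tissue_%s_network.graphml",
                                  network$tissue))
  if (nrow(network$edges)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE)
    igraph::write_graph(g, p_gml, format = "graphml")
  }
  invisible(c(p_tsv, p_gml))
}
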