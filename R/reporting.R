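#' Bipartite term-microbe graph of top enrichment results
#'
#' Takes the `top_k` first rows of a ranked result and draws one edge per
#' (term, shared member) pair, weighted by that term's combined score (falls
#' back to 0 when the run skipped the rank correction). Node size is degree.
#'
#' @param results An `msea_result` (already in the desired order).
#' @param top_k Number of leading terms to include.
#' @return An [igraph][igraph::igraph-package] bipartite graph; vertex
#'   attributes `type` (FALSE = term, TRUE = microbe) and `size` (degree),
#'   edge attribute `weight` (combined score).
#' @export
bipartite_graph <- function(results, top_k) {
  stopifnot(inherits(results, "msea_result"), top_k >= 1)
  if (nrow(results) == 0L) {
    msea_error("msea_empty_result_error", "no enrichment results")
  }
  top <- utils::head(results, top_k)
  edges <- do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
    shared <- top$shared_members[[i]]
    if (length(shared) == 0L) return(NULL)
    w <- top$combined_score[i]
    data.frame(term = top$term_id[i], microbe = shared,
               weight = if (is.na(w)) 0 else w,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) edges <- data.frame(term = character(0),
                                          microbe = character(0),
                                          weight = numeric(0))
  terms <- unique(top$term_id)
  microbes <- unique(edges$microbe)
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = c(terms, microbes),
                          type = c(rep(FALSE, length(terms)),
                                   rep(TRUE, length(microbes))))
  )
  igraph::V(g)$size <- igraph::degree(g)
  g
}

#' Overlap network among enriched terms
#'
#' For every unordered pair of term sets, tests the member overlap by the
#' one-sided Fisher's exact test over a background of `background_size`
#' entities, corrects over all pairs by Benjamini-Hochberg, and connects two
#' terms iff the corrected p-value is below `alpha`.
#'
#' @param term_sets Named list of member character vectors (at least 2).
#' @param background_size Size of the background universe the members are
#'   drawn from; must be at least the size of the member union.
#' @param alpha Corrected-p cutoff for an edge (default 0.01).
#' @return An undirected igraph graph over all terms; edge attributes
#'   `p_value` and `q_value`.
#' @export
overlap_network <- function(term_sets, background_size, alpha = 0.01) {
  stopifnot(is.list(term_sets), length(term_sets) >= 2L,
            !is.null(names(term_sets)))
  union_size <- length(unique(unlist(term_sets, use.names = FALSE)))
  stopifnot(background_size >= union_size)
  ids <- names(term_sets)
  pairs <- utils::combn(seq_along(ids), 2L)
  p <- apply(pairs, 2L, function(ij) {
    s1 <- unique(term_sets[[ij[1L]]]); s2 <- unique(term_sets[[ij[2L]]])
    a <- length(intersect(s1, s2))
    tab <- list(a = a, b = length(s1) - a, c = length(s2) - a,
                d = background_size - length(union(s1, s2)),
                N = background_size)
    fisher_p(tab)
  })
  q <- bh_qvalues(p)
  keep <- q < alpha
  edges <- data.frame(from = ids[pairs[1L, keep]],
                      to = ids[pairs[2L, keep]],
                      p_value = p[keep], q_value = q[keep],
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = ids))
}

#' Two-dimensional t-SNE embedding of a weighted entity matrix
#'
#' Exact (dense) t-distributed stochastic neighbor embedding of the rows of
#' a matrix — typically the TF-IDF-normalized microbe-by-gene matrix — into
#' 2-D coordinates. Input similarities use Gaussian kernels calibrated per
#' row to the target perplexity by bisection; the embedding is optimized by
#' gradient descent with momentum and early exaggeration. Deterministic
#' given `seed`; output is centered.
#'
#' @param mat Numeric matrix, one row per entity; needs at least
#'   `3 * perplexity` rows.
#' @param seed RNG seed for the random initialization.
#' @param perplexity Effective number of neighbors (default 30).
#' @param max_iter Gradient-descent iterations (default 500).
#' @return Data frame `entity`, `x`, `y` (one row per input row).
#' @export
embed_tsne <- function(mat, seed, perplexity = 30, max_iter = 500) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 3 * perplexity) {
    msea_error("msea_insufficient_data_error",
               sprintf("t-SNE needs at least 3*perplexity = %d rows, got %d",
                       ceiling(3 * perplexity), n))
  }
  P <- tsne_affinities(mat, perplexity)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  eta <- 200
  exaggeration <- 12
  stop_lying <- min(100L, max_iter %/% 4L)
  Pex <- P * exaggeration
  for (iter in seq_len(max_iter)) {
    Pi <- if (iter <= stop_lying) Pex else P
    # Student-t kernel in the embedding
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    L <- (Pi - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter < 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  data.frame(entity = rownames(mat) %||% as.character(seq_len(n)),
             x = Y[, 1L], y = Y[, 2L], stringsAsFactors = FALSE)
}

# symmetrized input affinities at a target perplexity (bisection on the
# per-row Gaussian precision)
tsne_affinities <- function(mat, perplexity, tol = 1e-5) {
  n <- nrow(mat)
  sq <- rowSums(mat^2)
  D <- outer(sq, sq, `+`) - 2 * tcrossprod(mat)
  D[D < 0] <- 0
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0; p <- w }
      else {
        p <- w / sw
        H <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else { beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.eps] <- .Machine$double.eps
  P / sum(P)
}

#' Write a graph as a flat TSV edge list
#'
#' Columns `from`, `to` plus every edge attribute; round-trips through
#' [read_edge_list()].
#'
#' @param graph An igraph graph.
#' @param path Output path.
#' @export
write_edge_list <- function(graph, path) {
  edges <- igraph::as_data_frame(graph, what = "edges")
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV edge list written by [write_edge_list()]
#' @param path File path.
#' @param directed Build a directed graph (default FALSE).
#' @export
read_edge_list <- function(path, directed = FALSE) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(edges))) {
    msea_error("msea_format_error", "edge list needs 'from' and 'to' columns")
  }
  igraph::graph_from_data_frame(edges, directed = directed)
}

#' Write a graph in GraphML format
#' @param graph An igraph graph.
#' @param path Output path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Write a t-SNE embedding as TSV, optionally with phylum labels
#'
#' When a taxonomy tree is supplied, each entity is annotated with the
#' phylum of its lineage (the coloring used for embedding plots); entities
#' absent from the tree get NA.
#'
#' @param coords Data frame from [embed_tsne()].
#' @param path Output path.
#' @param tree Optional `taxonomy_tree` providing phylum labels.
#' @export
write_embedding <- function(coords, path, tree = NULL) {
  if (!is.null(tree)) {
    nodes <- tree$nodes
    leaf_ids <- stats::setNames(
      tree$leaves, taxon_key(nodes$name[match(tree$leaves, nodes$node_id)]))
    coords$phylum <- vapply(coords$entity, function(e) {
      lf <- unname(leaf_ids[taxon_key(e)])
      if (is.na(lf)) return(NA_character_)
      anc <- taxonomy_ancestors(tree, lf)
      ph <- anc[nodes$rank[match(anc, nodes$node_id)] == "phylum"]
      if (length(ph)) nodes$name[match(ph[1L], nodes$node_id)]
      else NA_character_
    }, character(1))
  }
  utils::write.table(coords, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
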