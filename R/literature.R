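#' Construct a mention corpus
#'
#' A corpus of documents, each carrying the set of microbe names and the set
#' of gene symbols mentioned in it. Microbe names are normalized via
#' [normalize_taxon_name()] and deduplicated case-insensitively; gene symbols
#' are upper-cased.
#'
#' @param documents Named list; each element a list with character vectors
#'   `microbes` and `genes` (either may be empty).
#' @export
mention_corpus <- function(documents) {
  stopifnot(is.list(documents))
  if (length(documents) > 0L &&
      (is.null(names(documents)) || any(!nzchar(names(documents))))) {
    names(documents) <- paste0("doc", seq_along(documents))
  }
  documents <- lapply(documents, function(d) {
    m <- as.character(d$microbes %||% character(0))
    g <- as.character(d$genes %||% character(0))
    if (length(m)) m <- unique_taxa(normalize_taxon_name(m))
    list(microbes = m, genes = unique(toupper(g)))
  })
  structure(list(documents = documents), class = "mention_corpus")
}

#' @export
print.mention_corpus <- function(x, ...) {
  cat(sprintf("Mention corpus: %d documents\n", length(x$documents)))
  invisible(x)
}

#' Read a mention corpus from a (document_id, entity_type, entity_name) table
#'
#' Accepts the tagger-style long format as TSV with those three columns;
#' `entity_type` must be `"microbe"` or `"gene"`.
#'
#' @param path TSV file path.
#' @export
read_mention_corpus <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("document_id", "entity_type", "entity_name")
  if (!all(need %in% names(tab))) {
    msea_error("msea_format_error",
               sprintf("mention table needs columns %s",
                       paste(need, collapse = ", ")))
  }
  bad <- !tab$entity_type %in% c("microbe", "gene")
  if (any(bad)) {
    msea_error("msea_format_error",
               sprintf("unknown entity_type(s): %s",
                       paste(unique(tab$entity_type[bad]), collapse = ", ")))
  }
  docs <- lapply(split(tab, as.character(tab$document_id)), function(d) {
    list(microbes = d$entity_name[d$entity_type == "microbe"],
         genes = d$entity_name[d$entity_type == "gene"])
  })
  mention_corpus(docs)
}

#' Write a mention corpus to the long TSV format
#' @param corpus A `mention_corpus`.
#' @param path Output path.
#' @export
write_mention_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "mention_corpus"))
  rows <- lapply(names(corpus$documents), function(id) {
    d <- corpus$documents[[id]]
    n <- length(d$microbes) + length(d$genes)
    if (n == 0L) return(NULL)  # mentionless documents have no long-format row
    data.frame(
      document_id = rep(id, n),
      entity_type = c(rep("microbe", length(d$microbes)),
                      rep("gene", length(d$genes))),
      entity_name = c(d$microbes, d$genes),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count microbe-gene co-mentions across a corpus
#'
#' For every microbe i and gene j, counts the documents mentioning both, and
#' for every entity the documents mentioning it at all. Documents carrying
#' only one entity type contribute to marginals but not to co-counts.
#'
#' @param corpus A [mention_corpus()].
#' @return An `association_matrix`: ordered `microbes` and `genes`, the
#'   integer `co_counts` matrix (microbes x genes), and per-entity document
#'   counts `microbe_doc_counts`, `gene_doc_counts`.
#' @export
count_cooccurrence <- function(corpus) {
  stopifnot(inherits(corpus, "mention_corpus"))
  docs <- corpus$documents
  if (length(docs) == 0L) {
    msea_error("msea_empty_corpus_error", "corpus has no documents")
  }
  microbes <- unique_taxa(unlist(lapply(docs, `[[`, "microbes"),
                                 use.names = FALSE) %||% character(0))
  genes <- sort(unique(unlist(lapply(docs, `[[`, "genes"),
                              use.names = FALSE) %||% character(0)))
  microbes <- sort(microbes)
  nm <- length(microbes); ng <- length(genes); nd <- length(docs)
  Mm <- Matrix::sparseMatrix(dims = c(nd, max(nm, 1L)), i = {}, j = {})
  Mg <- Matrix::sparseMatrix(dims = c(nd, max(ng, 1L)), i = {}, j = {})
  mi <- unlist(lapply(seq_along(docs), function(k) {
    rep(k, length(docs[[k]]$microbes))
  }))
  mj <- match(taxon_key(unlist(lapply(docs, `[[`, "microbes"),
                               use.names = FALSE)), taxon_key(microbes))
  gi <- unlist(lapply(seq_along(docs), function(k) {
    rep(k, length(docs[[k]]$genes))
  }))
  gj <- match(unlist(lapply(docs, `[[`, "genes"), use.names = FALSE), genes)
  if (nm > 0L) Mm <- Matrix::sparseMatrix(i = mi, j = mj, x = 1,
                                          dims = c(nd, nm))
  if (ng > 0L) Mg <- Matrix::sparseMatrix(i = gi, j = gj, x = 1,
                                          dims = c(nd, ng))
  co <- if (nm > 0L && ng > 0L) {
    as.matrix(Matrix::t(Mm) %*% Mg)
  } else {
    matrix(0, nm, ng)
  }
  dimnames(co) <- list(microbes, genes)
  structure(list(
    microbes = microbes, genes = genes,
    co_counts = co,
    microbe_doc_counts = stats::setNames(
      if (nm) as.integer(Matrix::colSums(Mm)) else integer(0), microbes),
    gene_doc_counts = stats::setNames(
      if (ng) as.integer(Matrix::colSums(Mg)) else integer(0), genes),
    n_documents = nd
  ), class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("Association matrix: %d microbes x %d genes over %d documents\n",
              length(x$microbes), length(x$genes), x$n_documents))
  invisible(x)
}

#' Jaccard index of one microbe-gene pair
#'
#' The co-mentioning document count divided by the size of the union of the
#' two entities' mentioning-document sets:
#' `co / (microbe_docs + gene_docs - co)`. When both marginals are zero the
#' index is defined as 0.
#'
#' @param matrix An `association_matrix`.
#' @param microbe,gene Entity names present in the matrix.
#' @return A score in \[0, 1\].
#' @export
jaccard_index <- function(matrix, microbe, gene) {
  i <- match(taxon_key(microbe), taxon_key(matrix$microbes))
  j <- match(toupper(gene), matrix$genes)
  if (is.na(i)) msea_error("msea_key_error",
                           sprintf("unknown microbe %s", sQuote(microbe)))
  if (is.na(j)) msea_error("msea_key_error",
                           sprintf("unknown gene %s", sQuote(gene)))
  co <- matrix$co_counts[i, j]
  denom <- matrix$microbe_doc_counts[[i]] + matrix$gene_doc_counts[[j]] - co
  if (denom == 0) 0 else unname(co / denom)
}

# full microbes x genes Jaccard matrix (0/0 -> 0)
jaccard_matrix <- function(matrix) {
  co <- matrix$co_counts
  denom <- outer(as.numeric(matrix$microbe_doc_counts),
                 as.numeric(matrix$gene_doc_counts), `+`) - co
  out <- co / denom
  out[denom == 0] <- 0
  dimnames(out) <- dimnames(co)
  out
}

#' Binarize associations by keeping the top fraction of all pairs
#'
#' "All possible pairs" is the full microbes x genes grid including
#' zero-score pairs; the cut keeps the `ceiling(fraction * total)` highest
#' Jaccard scores, with all pairs tied at the cut retained (so the kept count
#' can exceed the nominal one) and zero-score pairs never retained.
#'
#' @param matrix An `association_matrix`.
#' @param fraction Top fraction to keep, in (0, 1]; default 0.001 (top 0.1%).
#' @return A `binary_associations`: a `pairs` data frame
#'   (`microbe`, `gene`, `jaccard`), the realized `threshold` (the minimum
#'   retained score) and the requested `fraction`.
#' @export
threshold_by_top_fraction <- function(matrix, fraction = 0.001) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    msea_error("msea_value_error", "fraction must lie in (0, 1]")
  }
  J <- jaccard_matrix(matrix)
  total <- length(J)
  k <- min(ceiling(fraction * total), total)
  scores <- as.vector(J)
  cut <- sort(scores, decreasing = TRUE)[k]
  keep <- which(J >= cut & J > 0, arr.ind = TRUE)
  pairs <- data.frame(
    microbe = matrix$microbes[keep[, 1L]],
    gene = matrix$genes[keep[, 2L]],
    jaccard = J[keep],
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(-pairs$jaccard, pairs$microbe, pairs$gene), ]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 threshold = if (nrow(pairs)) min(pairs$jaccard) else NA_real_,
                 fraction = fraction),
            class = "binary_associations")
}

#' @export
print.binary_associations <- function(x, ...) {
  cat(sprintf("Binary associations: %d pairs at Jaccard >= %.4g (top %.3g%%)\n",
              nrow(x$pairs), x$threshold, 100 * x$fraction))
  invisible(x)
}

#' Export retained associations as a 3-column TSV
#' @param assoc A `binary_associations`.
#' @param path Output path.
#' @export
write_associations <- function(assoc, path) {
  utils::write.table(assoc$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# taxonomic similarity between two leaves: depth of the deepest shared
# ancestor divided by the maximum node depth of the tree
taxonomic_similarity_matrix <- function(tree, names) {
  nodes <- tree$nodes
  leaf_by_key <- stats::setNames(tree$leaves,
                                 taxon_key(nodes$name[match(tree$leaves,
                                                            nodes$node_id)]))
  anc <- lapply(names, function(nm) {
    lf <- leaf_by_key[[taxon_key(nm)]]
    if (is.null(lf)) character(0) else taxonomy_ancestors(tree, lf)
  })
  depth <- function(id) match(nodes$rank[match(id, nodes$node_id)],
                              TAXON_RANKS)
  max_depth <- max(vapply(nodes$rank, function(r) match(r, TAXON_RANKS),
                          integer(1)))
  n <- length(names)
  sim <- matrix(0, n, n, dimnames = list(names, names))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    shared <- intersect(anc[[i]], anc[[j]])
    if (length(shared)) {
      sim[i, j] <- sim[j, i] <- max(vapply(shared, depth, integer(1))) /
        max_depth
    }
  }
  diag(sim) <- 1
  sim
}

#' Select a binarization threshold by correlation with the taxonomy
#'
#' For each candidate top fraction, binarizes the association matrix, builds
#' the per-microbe gene profile, and computes the Spearman rank correlation
#' over all microbe pairs between (a) the Jaccard similarity of their gene
#' profiles and (b) their taxonomic similarity (depth of deepest shared
#' ancestor over the tree's maximum depth). The candidate maximizing the
#' correlation wins; candidates whose binarization retains nothing are
#' skipped with a warning.
#'
#' @param matrix An `association_matrix`.
#' @param tree A `taxonomy_tree` whose leaves cover the matrix microbes.
#' @param candidates Numeric vector of at least two candidate fractions.
#' @param similarity_fun Optional replacement statistic: a function
#'   `(gene_sim_vector, taxo_sim_vector) -> scalar`; defaults to Spearman
#'   correlation.
#' @return List with `best_fraction` and a `statistics` data frame
#'   (`fraction`, `statistic`, `n_pairs`, `n_retained`).
#' @export
select_threshold_by_taxonomy <- function(matrix, tree, candidates,
                                         similarity_fun = NULL) {
  stopifnot(length(candidates) >= 2L)
  similarity_fun <- similarity_fun %||% function(g, t) {
    suppressWarnings(stats::cor(g, t, method = "spearman"))
  }
  microbes <- matrix$microbes
  taxo <- taxonomic_similarity_matrix(tree, microbes)
  ut <- upper.tri(taxo)
  stat <- rep(NA_real_, length(candidates))
  n_ret <- integer(length(candidates))
  for (ci in seq_along(candidates)) {
    assoc <- threshold_by_top_fraction(matrix, candidates[ci])
    n_ret[ci] <- nrow(assoc$pairs)
    if (n_ret[ci] == 0L) {
      msea_warning("msea_degenerate_candidate_warning",
                   sprintf("fraction %g retains no pairs; skipped",
                           candidates[ci]))
      next
    }
    profiles <- lapply(microbes, function(m) {
      assoc$pairs$gene[taxon_key(assoc$pairs$microbe) == taxon_key(m)]
    })
    n <- length(microbes)
    gsim <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      u <- length(union(profiles[[i]], profiles[[j]]))
      gsim[i, j] <- gsim[j, i] <-
        if (u == 0) 0 else length(intersect(profiles[[i]], profiles[[j]])) / u
    }
    stat[ci] <- similarity_fun(gsim[ut], taxo[ut])
  }
  if (all(is.na(stat))) {
    msea_error("msea_no_valid_threshold_error",
               "every candidate fraction produced a degenerate binarization")
  }
  list(
    best_fraction = candidates[which.max(stat)],
    statistics = data.frame(fraction = candidates, statistic = stat,
                            n_pairs = sum(ut), n_retained = n_ret)
  )
}

#' Convert binarized associations into a gene-centric microbe-set library
#'
#' One set per gene; members are the microbes retained for it. Genes with no
#' retained microbe do not appear.
#'
#' @param assoc A `binary_associations`.
#' @return A `microbe_set_library` with provenance `"literature"`.
#' @export
associations_to_library <- function(assoc) {
  stopifnot(inherits(assoc, "binary_associations"))
  if (nrow(assoc$pairs) == 0L) {
    msea_error("msea_empty_library_error", "no retained associations")
  }
  by_gene <- split(assoc$pairs$microbe, assoc$pairs$gene)
  sets <- Map(function(g, m) microbe_set(g, unique_taxa(m)),
              names(by_gene), by_gene)
  microbe_set_library(unname(sets), name = "literature",
                      provenance = "literature")
}

#' TF-IDF normalization of the microbe-by-gene count matrix
#'
#' Treats microbes as documents and genes as terms:
#' `tf[i, j] = co[i, j] / rowSums(co)[i]`, `idf[j] = log(N / df[j])` with
#' `df[j]` the number of microbes co-mentioned with gene j at least once, and
#' natural-log idf. Microbes with an all-zero row stay all-zero; a gene
#' co-mentioned with every microbe gets an all-zero column (idf = 0),
#' offsetting ubiquitous genes.
#'
#' @param matrix An `association_matrix`.
#' @return Numeric microbes x genes matrix of tf-idf weights.
#' @export
tfidf_normalize <- function(matrix) {
  co <- matrix$co_counts
  if (length(co) == 0L) {
    msea_error("msea_empty_corpus_error", "association matrix is empty")
  }
  rs <- rowSums(co)
  tf <- co / ifelse(rs == 0, 1, rs)
  df <- colSums(co > 0)
  idf <- ifelse(df == 0, 0, log(nrow(co) / df))
  out <- sweep(tf, 2L, idf, `*`)
  dimnames(out) <- dimnames(co)
  out
}
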