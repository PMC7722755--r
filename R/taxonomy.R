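# Taxonomic ranks recognized in lineage strings, shallow to deep. Tokens
# below species (strain level) are discarded during parsing.
TAXON_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                 "genus", "species")
RANK_PREFIX <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                 f = "family", g = "genus", s = "species")
EXCLUDED_KINGDOMS <- c("viruses", "viroids")

new_taxonomy_tree <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("node_id", "name", "rank", "parent_id") %in% names(nodes)))
  rownames(nodes) <- NULL
  leaves <- setdiff(nodes$node_id, nodes$parent_id)
  structure(list(nodes = nodes, leaves = leaves), class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("Taxonomy tree: %d nodes, %d leaves, ranks %s\n",
              nrow(x$nodes), length(x$leaves),
              paste(intersect(TAXON_RANKS, unique(x$nodes$rank)),
                    collapse = " > ")))
  invisible(x)
}

#' Parse Greengenes-style lineage strings into a taxonomy tree
#'
#' Each record is a semicolon-delimited lineage ordered kingdom to species,
#' with tokens carrying single-letter rank prefixes (`k__`, `p__`, ...,
#' `s__`). One node is created per distinct (rank, name, lineage-prefix), so
#' identically named clades under different parents stay distinct. Lineages
#' whose kingdom is Viruses or Viroids are dropped entirely, strain-level
#' tokens are discarded, empty tokens (e.g. `"s__"`) are skipped, and all
#' names are passed through [normalize_taxon_name()]. Species names are
#' formed as `"<genus> <epithet>"` when the epithet does not already repeat
#' the genus.
#'
#' @param records Character vector of lineage strings.
#' @return A `taxonomy_tree`: a node table (`node_id`, `name`, `rank`,
#'   `parent_id`) plus the leaf node ids.
#' @export
parse_greengenes_taxonomy <- function(records) {
  stopifnot(is.character(records))
  node_id <- character(0); name <- character(0)
  rank <- character(0); parent_id <- character(0)
  seen <- new.env(parent = emptyenv())

  for (rec in records) {
    tokens <- trimws(strsplit(rec, ";", fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0L) next

    ranks <- character(0); names_ <- character(0)
    for (tok in tokens) {
      pref <- sub("^([A-Za-z])__.*$", "\\1", tok)
      if (grepl("^[A-Za-z]__", tok)) {
        rk <- RANK_PREFIX[tolower(pref)]
        if (is.na(rk)) next  # strain or other sub-species token: discard
        nm <- sub("^[A-Za-z]__", "", tok)
      } else {
        # unprefixed token: infer rank by position after the last parsed one
        rk <- TAXON_RANKS[match(utils::tail(ranks, 1), TAXON_RANKS) + 1L]
        if (length(rk) == 0L || is.na(rk)) rk <- TAXON_RANKS[1L]
        nm <- tok
      }
      if (!nzchar(nm)) next  # unnamed level, e.g. "s__"
      ranks <- c(ranks, rk); names_ <- c(names_, nm)
    }
    if (length(ranks) == 0L) next
    depth <- match(ranks, TAXON_RANKS)
    if (any(diff(depth) <= 0L)) {
      msea_error("msea_malformed_lineage_error",
                 sprintf("rank order violated in lineage %s", sQuote(rec)))
    }
    if (ranks[1L] == "kingdom" &&
        tolower(names_[1L]) %in% EXCLUDED_KINGDOMS) next

    names_ <- normalize_taxon_name(names_)
    # species epithets become "<genus> <epithet>" unless already binomial
    is_sp <- ranks == "species"
    if (any(is_sp) && any(ranks == "genus")) {
      gen <- names_[ranks == "genus"][1L]
      sp <- names_[is_sp]
      needs_genus <- !startsWith(taxon_key(sp), paste0(taxon_key(gen), " ")) &
        taxon_key(sp) != taxon_key(gen)
      sp[needs_genus] <- paste(gen, sp[needs_genus])
      names_[is_sp] <- sp
    }

    ids <- vapply(seq_along(names_), function(i) {
      paste(paste0(substr(ranks[seq_len(i)], 1, 1), "__",
                   taxon_key(names_[seq_len(i)])), collapse = ";")
    }, character(1))
    parents <- c(NA_character_, ids[-length(ids)])
    for (i in seq_along(ids)) {
      if (!is.null(seen[[ids[i]]])) next
      assign(ids[i], TRUE, envir = seen)
      node_id <- c(node_id, ids[i]); name <- c(name, names_[i])
      rank <- c(rank, ranks[i]); parent_id <- c(parent_id, parents[i])
    }
  }
  new_taxonomy_tree(data.frame(
    node_id = node_id, name = name, rank = rank, parent_id = parent_id,
    stringsAsFactors = FALSE
  ))
}

# leaf names under each node, computed by walking parent pointers
taxonomy_leaf_table <- function(tree) {
  nodes <- tree$nodes
  if (nrow(nodes) == 0L) {
    return(data.frame(leaf_id = character(0), leaf_name = character(0)))
  }
  data.frame(leaf_id = tree$leaves,
             leaf_name = nodes$name[match(tree$leaves, nodes$node_id)],
             stringsAsFactors = FALSE)
}

# ancestor node_ids (inclusive) for one node
taxonomy_ancestors <- function(tree, node_id) {
  nodes <- tree$nodes
  out <- character(0)
  cur <- node_id
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- nodes$parent_id[match(cur, nodes$node_id)]
  }
  out
}

#' Convert a taxonomy tree into a microbe-set library at one rank
#'
#' Enumerates, for every node at the requested rank, the names of all leaf
#' descendants; each such node becomes one microbe-set. Nodes at the rank
#' with no leaf descendants below them cannot occur (every node lies on a
#' root-to-leaf path), but a node that is itself a leaf yields a singleton
#' set of its own name.
#'
#' @param tree A `taxonomy_tree` from [parse_greengenes_taxonomy()].
#' @param rank One of `"kingdom"`, ..., `"genus"`; `"species"` is rejected
#'   because every set would be a singleton of itself.
#' @return A [microbe_set_library()] with provenance `"taxonomy"`.
#' @export
taxonomy_library <- function(tree, rank) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  rank <- match.arg(rank, TAXON_RANKS)
  if (rank == "species") {
    msea_error("msea_invalid_rank_error",
               "rank 'species' would produce singleton sets of themselves")
  }
  nodes <- tree$nodes
  at_rank <- nodes$node_id[nodes$rank == rank]
  sets <- list()
  if (length(at_rank) > 0L && length(tree$leaves) > 0L) {
    # map every leaf to its ancestor at `rank`, if any
    anc_at_rank <- vapply(tree$leaves, function(lf) {
      anc <- taxonomy_ancestors(tree, lf)
      hit <- anc[anc %in% at_rank]
      if (length(hit)) hit[1L] else NA_character_
    }, character(1))
    leaf_names <- nodes$name[match(tree$leaves, nodes$node_id)]
    for (nid in at_rank) {
      members <- unique_taxa(leaf_names[!is.na(anc_at_rank) & anc_at_rank == nid])
      if (length(members) == 0L) next
      label <- nodes$name[match(nid, nodes$node_id)]
      sets[[nid]] <- microbe_set(nid, members, term_label = label)
    }
  }
  microbe_set_library(sets, name = paste0("taxonomy_", rank),
                      provenance = "taxonomy", allow_empty = TRUE)
}
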