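# Seeded generators for every input the tool consumes, with planted
# structure so the whole pipeline is testable without external downloads.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a mention corpus with planted microbe-gene co-mentions
#'
#' Every entity is mentioned in each document independently with probability
#' `background_rate`; each planted (microbe, gene) pair is additionally
#' co-mentioned (both inserted into the document) with its own `co_rate`.
#' Entity names are `"M0001"`-style for microbes and `"G0001"`-style for
#' genes, so name normalization is a no-op; `greengenes_style = TRUE`
#' instead emits microbes with `g__`/`_noname` decorations to exercise the
#' normalizer.
#'
#' @param n_docs,n_microbes,n_genes Corpus dimensions.
#' @param background_rate Per-document independent mention probability.
#' @param planted_pairs Data frame `microbe` (index), `gene` (index),
#'   `co_rate`; may be NULL/empty.
#' @param seed RNG seed (generation is a pure function of the arguments).
#' @param greengenes_style Decorate microbe names with rank prefixes and
#'   `_noname` suffixes.
#' @return A [mention_corpus()].
#' @export
make_mention_corpus <- function(n_docs, n_microbes, n_genes,
                                background_rate = 0.02,
                                planted_pairs = NULL, seed = 0,
                                greengenes_style = FALSE) {
  stopifnot(n_docs >= 1, n_microbes >= 1, n_genes >= 1,
            background_rate >= 0, background_rate <= 1)
  microbes <- sprintf("M%04d", seq_len(n_microbes))
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(planted_pairs) && nrow(planted_pairs) > 0L) {
    stopifnot(all(planted_pairs$microbe >= 1),
              all(planted_pairs$microbe <= n_microbes),
              all(planted_pairs$gene >= 1),
              all(planted_pairs$gene <= n_genes),
              all(planted_pairs$co_rate >= 0),
              all(planted_pairs$co_rate <= 1))
  }
  docs <- with_seed(seed, {
    lapply(seq_len(n_docs), function(d) {
      m <- microbes[stats::runif(n_microbes) < background_rate]
      g <- genes[stats::runif(n_genes) < background_rate]
      if (!is.null(planted_pairs) && nrow(planted_pairs) > 0L) {
        hit <- stats::runif(nrow(planted_pairs)) < planted_pairs$co_rate
        m <- c(m, microbes[planted_pairs$microbe[hit]])
        g <- c(g, genes[planted_pairs$gene[hit]])
      }
      list(microbes = unique(m), genes = unique(g))
    })
  })
  names(docs) <- sprintf("D%05d", seq_len(n_docs))
  if (greengenes_style) {
    docs <- lapply(docs, function(d) {
      if (length(d$microbes)) {
        d$microbes <- paste0("g__", d$microbes, "_noname")
      }
      d
    })
  }
  mention_corpus(docs)
}

#' Generate a library with one planted enriched term
#'
#' Draws `n_terms` member sets uniformly from a universe of `"M0001"`-style
#' names, then rebuilds one term (the planted one) to share exactly
#' `planted_overlap` members with an emitted input list. The other terms
#' overlap the input only by chance, so the planted term should surface at
#' rank 1 in an enrichment run.
#'
#' @param universe_size Universe size (members `"M0001"`...).
#' @param n_terms Number of sets.
#' @param set_size_range Length-2 integer range of set sizes.
#' @param input_size Size of the emitted input list.
#' @param planted_overlap Members shared between planted term and input;
#'   must be feasible under the other parameters.
#' @param seed RNG seed.
#' @return List: `library` (a `microbe_set_library`), `input` (character
#'   vector), `planted_term` (its term_id), `universe` (an `msea_universe`
#'   over the full generated universe).
#' @export
make_planted_library <- function(universe_size = 1000, n_terms = 30,
                                 set_size_range = c(10, 50),
                                 input_size = 20, planted_overlap = 10,
                                 seed = 0) {
  stopifnot(universe_size >= 2, n_terms >= 1, input_size >= 1,
            input_size <= universe_size)
  lo <- set_size_range[1L]; hi <- set_size_range[2L]
  if (planted_overlap > min(input_size, hi) ||
      (hi - planted_overlap) > (universe_size - input_size) ||
      planted_overlap > universe_size) {
    msea_error("msea_spec_error",
               "requested planted overlap is infeasible under the set sizes")
  }
  members <- sprintf("M%04d", seq_len(universe_size))
  out <- with_seed(seed, {
    input <- sample(members, input_size)
    sizes <- sample(lo:hi, n_terms, replace = TRUE)
    sets <- lapply(seq_len(n_terms), function(t) {
      microbe_set(sprintf("T%03d", t), sample(members, sizes[t]))
    })
    planted_id <- sprintf("T%03d", sample.int(n_terms, 1L))
    psize <- max(sizes[match(planted_id, sprintf("T%03d", seq_len(n_terms)))],
                 planted_overlap)
    in_part <- sample(input, planted_overlap)
    out_part <- sample(setdiff(members, input), psize - planted_overlap)
    sets[[match(planted_id, vapply(sets, `[[`, character(1), "term_id"))]] <-
      microbe_set(planted_id, c(in_part, out_part))
    list(input = input, sets = sets, planted = planted_id)
  })
  library <- microbe_set_library(out$sets, name = "planted",
                                 provenance = "user")
  universe <- structure(list(members = members,
                             size = as.integer(universe_size)),
                        class = "msea_universe")
  list(library = library, input = out$input, planted_term = out$planted,
       universe = universe)
}

#' Generate a balanced toy taxonomy
#'
#' A full tree with systematic names (`Phylum01`, `Genus01x02`,
#' `Genus01x02 sp03`, ...) under one Bacteria kingdom; class/order/family
#' levels are collapsed so the tree has kingdom, phylum, genus and species
#' ranks. Deterministic: the same arguments always give the same tree.
#'
#' @param n_phyla,genera_per_phylum,species_per_genus Positive counts.
#' @param seed Accepted for interface uniformity; the construction is
#'   deterministic regardless.
#' @return A `taxonomy_tree` with
#'   `n_phyla * genera_per_phylum * species_per_genus` species leaves.
#' @export
make_toy_taxonomy <- function(n_phyla, genera_per_phylum, species_per_genus,
                              seed = 0) {
  stopifnot(n_phyla >= 1, genera_per_phylum >= 1, species_per_genus >= 1)
  lineages <- character(0)
  for (p in seq_len(n_phyla)) {
    for (g in seq_len(genera_per_phylum)) {
      genus <- sprintf("Genus%02dx%02d", p, g)
      for (s in seq_len(species_per_genus)) {
        lineages <- c(lineages, sprintf(
          "k__Bacteria;p__Phylum%02d;g__%s;s__sp%02d", p, genus, s))
      }
    }
  }
  parse_greengenes_taxonomy(lineages)
}
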