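#' Determine the microbe universe for enrichment testing
#'
#' The universe is the population the Fisher test draws from: ideally the
#' union of everything the profiling pipeline can identify and every member
#' of the library. When neither a profiled-taxa list nor an explicit size is
#' supplied, a fixed default size of 1000 is used, with the library union as
#' the named portion and the remainder treated as unnamed profiling capacity.
#'
#' @param library A `microbe_set_library`.
#' @param profiled_taxa Optional character vector of taxa the profiling
#'   pipeline can identify.
#' @param size Optional explicit universe size; must accommodate the named
#'   members (and the input, when given).
#' @param input_set Optional input microbe list, used only to validate an
#'   explicit `size`.
#' @return An `msea_universe`: named `members` plus total `size`
#'   (`size >= length(members)`; the difference is unnamed capacity).
#' @export
determine_universe <- function(library, profiled_taxa = NULL, size = NULL,
                               input_set = NULL) {
  stopifnot(inherits(library, "microbe_set_library"))
  if (length(library$sets) == 0L) {
    msea_error("msea_empty_library_error", "library has no sets")
  }
  members <- library$member_union
  if (!is.null(profiled_taxa)) {
    members <- unique_taxa(c(members, normalize_taxon_name(profiled_taxa)))
  }
  if (is.null(size)) {
    size <- if (is.null(profiled_taxa)) max(1000L, length(members))
            else length(members)
  } else {
    needed <- unique_taxa(c(members, as.character(input_set %||% character(0))))
    if (size < length(needed)) {
      msea_error("msea_universe_too_small_error",
                 sprintf("explicit universe size %d < %d named members",
                         size, length(needed)))
    }
  }
  structure(list(members = members, size = as.integer(size)),
            class = "msea_universe")
}

#' @export
print.msea_universe <- function(x, ...) {
  cat(sprintf("Universe: size %d (%d named members, %d unnamed)\n",
              x$size, length(x$members), x$size - length(x$members)))
  invisible(x)
}

#' Build the 2x2 contingency table for one set against the input
#'
#' Cells: `a` = overlap, `b` = input-only, `c` = set-only, `d` = the
#' remainder of the universe, with `a + b + c + d = N`. When the universe is
#' fully enumerated, input members outside it are dropped with a warning;
#' when the universe carries unnamed capacity (size beyond the named
#' members), unknown input members are assumed to occupy it.
#'
#' @param input_set Character vector of input microbe names.
#' @param term_set Character vector, one library set's members.
#' @param universe An `msea_universe` from [determine_universe()].
#' @return A list `(a, b, c, d, N)`.
#' @export
build_contingency <- function(input_set, term_set, universe) {
  stopifnot(inherits(universe, "msea_universe"))
  input_set <- unique_taxa(as.character(input_set))
  term_set <- unique_taxa(as.character(term_set))
  N <- universe$size
  fully_named <- length(universe$members) >= N
  in_univ <- taxon_key(input_set) %in% taxon_key(universe$members)
  if (fully_named && any(!in_univ)) {
    msea_warning("msea_dropped_members_warning",
                 sprintf("dropped %d input member(s) outside the universe: %s",
                         sum(!in_univ),
                         paste(input_set[!in_univ], collapse = ", ")))
    input_set <- input_set[in_univ]
  }
  if (length(input_set) == 0L) {
    msea_error("msea_empty_input_error",
               "input is empty after universe filtering")
  }
  term_set <- term_set[taxon_key(term_set) %in% taxon_key(universe$members)]
  a <- sum(taxon_key(input_set) %in% taxon_key(term_set))
  b <- length(input_set) - a
  cc <- length(term_set) - a
  d <- N - a - b - cc
  stopifnot(d >= 0)
  list(a = a, b = b, c = cc, d = d, N = N)
}

#' One-sided Fisher's exact p-value for enrichment
#'
#' The upper-tail hypergeometric probability `P(X >= a)` for overlap `a`
#' between a draw of size `a + b` and a set of size `a + c` from a universe
#' of size `N`; always in (0, 1].
#'
#' @param table A contingency list from [build_contingency()] (fields
#'   `a`, `b`, `c`, `d`, `N`).
#' @export
fisher_p <- function(table) {
  with(table, {
    stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d == N)
    stats::phyper(a - 1, a + c, N - (a + c), a + b, lower.tail = FALSE)
  })
}

#' Odds ratio of a 2x2 table
#'
#' `(a * d) / (b * c)`; when any cell is zero, 0.5 is added to every cell
#' first (Haldane-Anscombe correction) so the ratio is always finite and
#' positive.
#'
#' @inheritParams fisher_p
#' @export
odds_ratio <- function(table) {
  with(table, {
    if (min(a, b, c, d) == 0) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    } else {
      (a * d) / (b * c)
    }
  })
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment across all tested terms of one
#' library run; q-values are monotone in p and never below p.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @export
bh_qvalues <- function(pvalues) {
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

# terms x universe sparse membership matrix; named members occupy universe
# positions 1..length(members), unnamed capacity fills the rest
membership_matrix <- function(library, universe) {
  keys <- taxon_key(universe$members)
  term_ids <- names(library$sets)
  ij <- lapply(seq_along(term_ids), function(t) {
    pos <- match(taxon_key(library$sets[[t]]$members), keys)
    pos <- pos[!is.na(pos)]
    cbind(t, pos)
  })
  ij <- do.call(rbind, ij)
  Matrix::sparseMatrix(i = ij[, 1L], j = ij[, 2L], x = 1,
                       dims = c(length(term_ids), universe$size),
                       dimnames = list(term_ids, NULL))
}

#' Monte-Carlo null model of expected per-term ranks
#'
#' Fisher's exact test is biased toward large sets. Following the
#' expected-rank correction used by gene-set enrichment servers, this draws
#' `reps` random inputs of the observed input's size uniformly without
#' replacement from the universe, scores every library term by its one-sided
#' Fisher p each time, ranks terms ascending by p (average ranks on ties),
#' and records each term's mean and standard deviation of rank. Observed
#' ranks are later standardized against these (see [zscore()]).
#'
#' @param library A `microbe_set_library`.
#' @param input_size Size of the random inputs (match the real input).
#' @param universe An `msea_universe`.
#' @param reps Number of Monte-Carlo repetitions (default 10000).
#' @param seed RNG seed; the model is reproducible given the seed.
#' @return A `null_rank_model` with per-term `mean_rank` and `sd_rank`.
#' @export
null_rank_model <- function(library, input_size, universe, reps = 10000,
                            seed = 0) {
  stopifnot(inherits(universe, "msea_universe"), reps >= 2,
            input_size >= 1, input_size <= universe$size)
  M <- membership_matrix(library, universe)
  K <- Matrix::rowSums(M)
  N <- universe$size
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- replicate(reps, sample.int(N, input_size))
  X <- Matrix::sparseMatrix(i = as.vector(draws),
                            j = rep(seq_len(reps), each = input_size),
                            x = 1, dims = c(N, reps))
  counts <- as.matrix(M %*% X)  # terms x reps overlap counts
  p <- stats::phyper(counts - 1, K, N - K, input_size, lower.tail = FALSE)
  ranks <- apply(p, 2L, rank, ties.method = "average")
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1L)
  mean_rank <- rowMeans(ranks)
  sd_rank <- apply(ranks, 1L, stats::sd)
  structure(list(
    term_ids = rownames(M),
    input_size = as.integer(input_size),
    universe_size = N, reps = as.integer(reps), seed = seed,
    mean_rank = stats::setNames(mean_rank, rownames(M)),
    sd_rank = stats::setNames(sd_rank, rownames(M))
  ), class = "null_rank_model")
}

#' @export
print.null_rank_model <- function(x, ...) {
  cat(sprintf(
    "Null rank model: %d terms, input size %d, universe %d, %d reps (seed %s)\n",
    length(x$term_ids), x$input_size, x$universe_size, x$reps,
    format(x$seed)))
  invisible(x)
}

#' Rank z-score against the null model
#'
#' `z = (observed_rank - mean_rank) / sd_rank`; better-than-expected
#' (smaller) ranks give negative z. A term whose null rank never varies
#' (`sd_rank == 0`) gets z = 0 with a degeneracy flag.
#'
#' @param observed_rank Observed rank of the term (ascending p).
#' @param model A [null_rank_model()].
#' @param term Term id present in the model.
#' @return List `(z, degenerate)`.
#' @export
zscore <- function(observed_rank, model, term) {
  stopifnot(inherits(model, "null_rank_model"))
  if (!term %in% model$term_ids) {
    msea_error("msea_key_error", sprintf("term %s not in null model",
                                         sQuote(term)))
  }
  m <- model$mean_rank[[term]]
  s <- model$sd_rank[[term]]
  if (s == 0) list(z = 0, degenerate = TRUE)
  else list(z = (observed_rank - m) / s, degenerate = FALSE)
}

#' Combined enrichment score
#'
#' `c = log10(p) * z` (base-10 logarithm). Since log10(p) <= 0, a negative z
#' (better-than-expected rank) yields a positive combined score; c = 0 when
#' p = 1 or z = 0.
#'
#' @param p Fisher p-value in (0, 1].
#' @param z Rank z-score.
#' @export
combined_score <- function(p, z) {
  if (any(p <= 0) || any(p > 1)) {
    msea_error("msea_domain_error", "p must lie in (0, 1]")
  }
  log10(p) * z
}

#' Microbe-set enrichment analysis
#'
#' Tests an input microbe list against every set of a library: one-sided
#' Fisher's exact test under a fixed universe, Benjamini-Hochberg q-values
#' across all terms, observed rank (ascending p, average ties), a rank
#' z-score against the Monte-Carlo null of [null_rank_model()], and the
#' combined score `log10(p) * z`.
#'
#' @param input_set Character vector of microbe names (the DA microbes).
#' @param library A `microbe_set_library` (or any set library, e.g. gene
#'   sets, when the input is a gene list — the statistic is generic).
#' @param universe Optional `msea_universe`; defaults to
#'   `determine_universe(library)` (fixed size 1000 when the library union
#'   is smaller).
#' @param reps Monte-Carlo repetitions for the null rank model; `reps = 0`
#'   skips the rank correction (z, combined score become NA).
#' @param seed RNG seed for the null model.
#' @param null_model Optional precomputed [null_rank_model()] (must match
#'   the library, universe size and filtered input size); overrides `reps`.
#' @param sort `"p"` (default) or `"combined"` ordering of the result.
#' @return Data frame of class `msea_result`, one row per term: `term_id`,
#'   `overlap`, `set_size`, `input_size`, `shared_members` (list column),
#'   `odds_ratio`, `p_value`, `q_value`, `rank`, `z_score`,
#'   `combined_score`, `z_degenerate`.
#' @export
msea <- function(input_set, library, universe = NULL, reps = 10000,
                 seed = 0, null_model = NULL, sort = c("p", "combined")) {
  sort <- match.arg(sort)
  stopifnot(inherits(library, "microbe_set_library"))
  input_set <- unique_taxa(normalize_taxon_name(as.character(input_set)))
  universe <- universe %||% determine_universe(library, input_set = input_set)

  # filter the input once, with the same drop rule as build_contingency
  fully_named <- length(universe$members) >= universe$size
  if (fully_named) {
    in_univ <- taxon_key(input_set) %in% taxon_key(universe$members)
    if (any(!in_univ)) {
      msea_warning("msea_dropped_members_warning",
                   sprintf("dropped %d input member(s) outside the universe",
                           sum(!in_univ)))
      input_set <- input_set[in_univ]
    }
  }
  if (length(input_set) == 0L) {
    msea_error("msea_empty_input_error",
               "input is empty after universe filtering")
  }

  term_ids <- names(library$sets)
  rows <- lapply(term_ids, function(tid) {
    s <- library$sets[[tid]]
    shared <- s$members[taxon_key(s$members) %in% taxon_key(input_set)]
    tab <- build_contingency(input_set, s$members, universe)
    list(term_id = tid, shared = shared, tab = tab)
  })
  p <- vapply(rows, function(r) fisher_p(r$tab), numeric(1))
  or <- vapply(rows, function(r) odds_ratio(r$tab), numeric(1))
  obs_rank <- rank(p, ties.method = "average")
  q <- bh_qvalues(p)

  if (is.null(null_model) && reps > 0) {
    null_model <- null_rank_model(library, length(input_set), universe,
                                  reps = reps, seed = seed)
  }
  if (!is.null(null_model)) {
    stopifnot(setequal(null_model$term_ids, term_ids))
    zs <- lapply(seq_along(term_ids), function(i) {
      zscore(obs_rank[i], null_model, term_ids[i])
    })
    z <- vapply(zs, `[[`, numeric(1), "z")
    degen <- vapply(zs, `[[`, logical(1), "degenerate")
    comb <- combined_score(p, z)
  } else {
    z <- rep(NA_real_, length(term_ids))
    degen <- rep(NA, length(term_ids))
    comb <- rep(NA_real_, length(term_ids))
  }

  out <- data.frame(
    term_id = term_ids,
    overlap = vapply(rows, function(r) length(r$shared), integer(1)),
    set_size = vapply(rows, function(r) r$tab$a + r$tab$c, integer(1)),
    input_size = length(input_set),
    odds_ratio = or, p_value = p, q_value = q,
    rank = obs_rank, z_score = z, combined_score = comb,
    z_degenerate = degen,
    stringsAsFactors = FALSE
  )
  out$shared_members <- lapply(rows, `[[`, "shared")
  ord <- if (sort == "p") {
    order(out$p_value, -out$overlap, out$term_id)
  } else {
    order(-out$combined_score, out$p_value, out$term_id)
  }
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "universe_size") <- universe$size
  attr(out, "seed") <- if (!is.null(null_model)) null_model$seed else seed
  attr(out, "reps") <- if (!is.null(null_model)) null_model$reps else reps
  class(out) <- c("msea_result", "data.frame")
  out
}

#' Write MSEA results as TSV
#'
#' Columns: term_id, overlap, set_size, input_size, shared_members
#' (semicolon-joined), odds_ratio, p_value, q_value, rank, z_score,
#' combined_score.
#'
#' @param results An `msea_result`.
#' @param path Output path.
#' @export
write_msea_results <- function(results, path) {
  tab <- as.data.frame(results)
  tab$shared_members <- vapply(tab$shared_members, paste, character(1),
                               collapse = ";")
  tab$z_degenerate <- NULL
  tab <- tab[c("term_id", "overlap", "set_size", "input_size",
               "shared_members", "odds_ratio", "p_value", "q_value",
               "rank", "z_score", "combined_score")]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(tab, format_tsv_field), sep = "\t")),
             con)
  invisible(path)
}

# stable, locale-independent number formatting for deterministic outputs
format_tsv_field <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    formatC(x, digits = 15, format = "g")
  } else {
    as.character(x)
  }
}
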