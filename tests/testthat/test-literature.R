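test_that("co-occurrence counts match a brute-force per-document loop", {
  corp <- make_mention_corpus(50, 6, 5, background_rate = 0.3, seed = 11)
  mat <- count_cooccurrence(corp)

  # oracle: exhaustive double loop over documents and entity pairs
  docs <- corp$documents
  for (m in mat$microbes) {
    in_m <- vapply(docs, function(d) m %in% d$microbes, logical(1))
    expect_equal(unname(mat$microbe_doc_counts[m]), sum(in_m))
    for (g in mat$genes) {
      in_g <- vapply(docs, function(d) g %in% d$genes, logical(1))
      expect_equal(unname(mat$co_counts[m, g]), sum(in_m & in_g))
    }
  }
  for (g in mat$genes) {
    expect_equal(unname(mat$gene_doc_counts[g]),
                 sum(vapply(docs, function(d) g %in% d$genes, logical(1))))
  }
  # count invariants
  expect_true(all(mat$co_counts <=
                    outer(mat$microbe_doc_counts, mat$gene_doc_counts, pmin)))
  expect_error(count_cooccurrence(mention_corpus(list())),
               class = "msea_empty_corpus_error")
})

test_that("documents with one entity type feed marginals, not co-counts", {
  corp <- mention_corpus(list(
    d1 = list(microbes = "m1", genes = "g1"),
    d2 = list(microbes = "m1", genes = character(0))))
  mat <- count_cooccurrence(corp)
  expect_equal(unname(mat$co_counts["m1", "G1"]), 1)
  expect_equal(unname(mat$microbe_doc_counts[["m1"]]), 2L)
})

test_that("jaccard index follows the co-mention equation", {
  # co=2, microbe docs=4, gene docs=3 -> 2/(4+3-2)
  corp <- mention_corpus(list(
    list(microbes = "m1", genes = "g1"),
    list(microbes = "m1", genes = "g1"),
    list(microbes = "m1", genes = character(0)),
    list(microbes = "m1", genes = character(0)),
    list(microbes = character(0), genes = "g1"),
    list(microbes = "m2", genes = "g2")))
  mat <- count_cooccurrence(corp)
  expect_equal(jaccard_index(mat, "m1", "g1"), 2 / (4 + 3 - 2))
  expect_equal(jaccard_index(mat, "m1", "g2"), 0)
  expect_equal(jaccard_index(mat, "m2", "g2"), 1)  # identical doc sets
  expect_error(jaccard_index(mat, "nope", "g1"), class = "msea_key_error")

  # bounded in [0,1] and symmetric in the two entities' document sets
  corp2 <- make_mention_corpus(80, 6, 6, background_rate = 0.2, seed = 5)
  m2 <- count_cooccurrence(corp2)
  J <- vapply(m2$microbes, function(mm) {
    vapply(m2$genes, function(gg) jaccard_index(m2, mm, gg), numeric(1))
  }, numeric(length(m2$genes)))
  expect_true(all(J >= 0 & J <= 1))
})

test_that("top-fraction binarization keeps the highest pairs with ties", {
  corp <- make_mention_corpus(200, 25, 40, background_rate = 0.05,
                              planted_pairs = data.frame(
                                microbe = 1, gene = 1, co_rate = 0.5),
                              seed = 21)
  mat <- count_cooccurrence(corp)
  # fraction 1/total keeps exactly the single top pair
  total <- length(mat$microbes) * length(mat$genes)
  top1 <- threshold_by_top_fraction(mat, 1 / total)
  expect_equal(nrow(top1$pairs), 1L)
  expect_equal(top1$pairs$microbe, "M0001")
  expect_equal(top1$pairs$gene, "G0001")
  expect_equal(top1$threshold, top1$pairs$jaccard)

  # fraction 1.0 keeps every positive-score pair, never zero-score ones
  all_pos <- threshold_by_top_fraction(mat, 1)
  J <- sapply(seq_along(mat$genes), function(j) {
    sapply(seq_along(mat$microbes), function(i) {
      jaccard_index(mat, mat$microbes[i], mat$genes[j])
    })
  })
  expect_equal(nrow(all_pos$pairs), sum(J > 0))
  expect_true(all(all_pos$pairs$jaccard > 0))

  # monotonicity: smaller fraction keeps a subset
  f1 <- threshold_by_top_fraction(mat, 0.005)
  f2 <- threshold_by_top_fraction(mat, 0.05)
  key <- function(a) paste(a$pairs$microbe, a$pairs$gene)
  expect_true(all(key(f1) %in% key(f2)))
  expect_true(all(f1$pairs$jaccard >= f1$threshold))

  expect_error(threshold_by_top_fraction(mat, 0), class = "msea_value_error")
  expect_error(threshold_by_top_fraction(mat, 1.5), class = "msea_value_error")
})

test_that("planted pair beats the off-pair score distribution", {
  # pair co-occurring at 20% with 1% background: its Jaccard should clear
  # the 99th percentile of the off-pair scores in nearly every replicate
  hits <- 0L
  n_seeds <- 30L
  for (s in seq_len(n_seeds)) {
    corp <- make_mention_corpus(200, 10, 10, background_rate = 0.01,
                                planted_pairs = data.frame(
                                  microbe = 1, gene = 1, co_rate = 0.2),
                                seed = 1000 + s)
    mat <- count_cooccurrence(corp)
    if (!"M0001" %in% mat$microbes || !"G0001" %in% mat$genes) next
    J <- msea:::jaccard_matrix(mat)
    planted <- J["M0001", "G0001"]
    off <- J[!(row(J) == which(rownames(J) == "M0001") &
                 col(J) == which(colnames(J) == "G0001"))]
    if (planted > stats::quantile(off, 0.99)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("threshold selection by taxonomy favors within-genus structure", {
  # 4 genera x 3 species; co-mentions planted only within genera: each genus
  # shares one gene among its species
  tree <- make_toy_taxonomy(2, 2, 3)
  species <- tree$nodes$name[tree$nodes$rank == "species"]
  genus_of <- rep(1:4, each = 3)
  docs <- list()
  set.seed(31)
  for (d in 1:300) {
    g <- sample(4, 1)
    sp <- sample(species[genus_of == g], 1)
    docs[[d]] <- list(microbes = sp, genes = sprintf("GENE%02d", g))
  }
  # noise documents pairing random species with random other genes
  for (d in 301:360) {
    docs[[d]] <- list(microbes = sample(species, 1),
                      genes = sprintf("NOISE%02d", sample(20, 1)))
  }
  corp <- mention_corpus(docs)
  mat <- count_cooccurrence(corp)
  n_planted <- length(species) * 1L  # one strong gene per species
  total <- length(mat$microbes) * length(mat$genes)
  sel <- select_threshold_by_taxonomy(
    mat, tree, candidates = c(n_planted / total, 0.5, 1.0))
  expect_equal(sel$best_fraction, n_planted / total)
  stats <- sel$statistics
  expect_true(stats$statistic[1] > stats$statistic[3])

  # identical candidates give identical statistics (determinism)
  sel2 <- select_threshold_by_taxonomy(mat, tree, candidates = c(0.5, 0.5))
  expect_equal(sel2$statistics$statistic[1], sel2$statistics$statistic[2])
})

test_that("gene-centric library construction is a bijection on pairs", {
  corp <- make_mention_corpus(100, 8, 8, background_rate = 0.15, seed = 9)
  assoc <- threshold_by_top_fraction(count_cooccurrence(corp), 0.2)
  lib <- associations_to_library(assoc)
  expect_equal(lib$provenance, "literature")
  rebuilt <- do.call(rbind, lapply(lib$sets, function(s) {
    data.frame(microbe = s$members, gene = s$term_id)
  }))
  expect_setequal(paste(rebuilt$microbe, rebuilt$gene),
                  paste(assoc$pairs$microbe, assoc$pairs$gene))
  # simple shapes
  a2 <- structure(list(pairs = data.frame(
    microbe = c("m1", "m2"), gene = c("g1", "g1"), jaccard = c(1, 1)),
    threshold = 1, fraction = 1), class = "binary_associations")
  l2 <- associations_to_library(a2)
  expect_length(l2$sets, 1L)
  expect_setequal(l2$sets$g1$members, c("m1", "m2"))
})

test_that("tf-idf weighting matches hand computation and zeroes ubiquity", {
  co <- matrix(c(2, 0, 1,
                 1, 1, 0), nrow = 3, ncol = 2,
               dimnames = list(c("m1", "m2", "m3"), c("g1", "g2")))
  mat <- structure(list(
    microbes = rownames(co), genes = colnames(co), co_counts = co,
    microbe_doc_counts = c(m1 = 5L, m2 = 2L, m3 = 2L),
    gene_doc_counts = c(g1 = 4L, g2 = 3L), n_documents = 10L),
    class = "association_matrix")
  w <- tfidf_normalize(mat)
  # hand-computed: tf rows (2/3,1/3),(0,1),(1/1,0); idf = log(3/2), log(3/2)
  expect_equal(w["m1", ], c(g1 = 2 / 3 * log(3 / 2), g2 = 1 / 3 * log(3 / 2)))
  expect_equal(w["m2", ], c(g1 = 0, g2 = log(3 / 2)))
  expect_equal(w["m3", ], c(g1 = log(3 / 2), g2 = 0))

  # a gene co-mentioned with every microbe has idf 0 -> zero column
  co2 <- co; co2[, "g1"] <- c(3, 1, 2)
  mat$co_counts <- co2
  w2 <- tfidf_normalize(mat)
  expect_equal(unname(w2[, "g1"]), c(0, 0, 0))
  # gene present in exactly 1 of N microbes gets idf log(N)
  co3 <- matrix(c(1, 1, 1, 1, 0, 0), 3, 2,
                dimnames = list(rownames(co), colnames(co)))
  mat$co_counts <- co3
  w3 <- tfidf_normalize(mat)
  expect_equal(unname(w3["m1", "g2"]), 1 / 2 * log(3))

  # identical count rows give identical tf-idf rows
  mat$co_counts <- matrix(c(2, 2, 0, 1, 1, 3), 3, 2,
                          dimnames = list(rownames(co), colnames(co)))
  w4 <- tfidf_normalize(mat)
  expect_equal(unname(w4["m1", ]), unname(w4["m2", ]))
})
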