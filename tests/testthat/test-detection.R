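# Tiny multi-gene fixtures are built through the public pipeline: records ->
# classify_set -> species_scores; two_gene_fixture() lives in the helper.

test_that("marker confidence reproduces the worked two-gene average", {
  fx <- two_gene_fixture()
  cls <- classify_genes(fx$psets)
  sc <- species_scores(cls, fx$presence)
  # c(g1, S) = mean(0.8, 0.6) = 0.7; c(g2, S) = 0; C_S = 0.7 / 2 = 0.35
  expect_equal(sc$confidence[sc$species_id == "S"], 0.35)
  # X: c(g1, X) = 1.0, c(g2, X) = 0.9 -> C_X = 0.95
  expect_equal(sc$confidence[sc$species_id == "X"], 0.95)
})

test_that("one certain read in a single-gene package gives C_S = 1", {
  tr <- chain_tax()
  ps <- make_pset(tr, list(make_record("a", "gx", edge_of(tr, "S"), 1.0)))
  presence <- build_presence_index(list(tr))
  sc <- species_scores(classify_genes(list(ps)), presence)
  expect_equal(sc$confidence, 1.0)
  expect_equal(sc$vote_fraction, 1.0)
  expect_equal(sc$m_s, 1L)
})

test_that("marker vote counts distinct voting genes over m_s", {
  # S in genes g1, g2, g3 (m_S = 3); voting reads only in g1 and g3
  mk <- function(g) build_taxonomy(data.frame(
    taxon_id = c("r", "G", "S", "X"), parent_id = c(NA, "r", "G", "G"),
    rank = c("superkingdom", "genus", "species", "species"),
    name = c("r", "G", "S", "X"), stringsAsFactors = FALSE), g)
  trees <- lapply(c("g1", "g2", "g3"), mk)
  psets <- list(
    make_pset(trees[[1]], list(make_record("a", "g1", edge_of(trees[[1]], "S"), 0.9),
                               make_record("b", "g1", edge_of(trees[[1]], "S"), 0.7))),
    make_pset(trees[[2]], list(make_record("c", "g2", edge_of(trees[[2]], "X"), 1.0))),
    make_pset(trees[[3]], list(make_record("d", "g3", edge_of(trees[[3]], "S"), 0.8))))
  presence <- build_presence_index(trees)
  sc <- species_scores(classify_genes(psets), presence)
  s_row <- sc[sc$species_id == "S", ]
  expect_equal(s_row$vote_count, 2L)
  expect_equal(s_row$vote_fraction, 2 / 3)
  expect_equal(s_row$supporting_genes[[1]], c("g1", "g3"))
  expect_equal(s_row$n_supporting_reads, 3L)
})

test_that("vote argmax ties break to the lexicographically smallest species", {
  tr <- binary_tax("g1")
  # equal support for sA and sB
  ps <- make_pset(tr, list(make_record("a", "g1",
                                       c(edge_of(tr, "sB"), edge_of(tr, "sA")),
                                       c(0.4, 0.4))))
  sc <- species_scores(classify_genes(list(ps)),
                       build_presence_index(list(tr)))
  expect_equal(sc$vote_count[sc$species_id == "sA"], 1L)
  expect_equal(sc$vote_count[sc$species_id == "sB"], 0L)
})

test_that("scores match the brute-force triple-loop oracle on random fixtures", {
  set.seed(53)
  for (i in 1:10) {
    genes <- sprintf("g%d", 1:sample(2:4, 1))
    trees <- lapply(genes, function(g) rand_tax(sample(4:15, 1), gene = g))
    psets <- lapply(trees, function(tr) {
      make_pset(tr, lapply(1:sample(3:10, 1),
                           function(j) rand_record(tr, sprintf("q%d", j))))
    })
    presence <- build_presence_index(trees)
    cls <- classify_genes(psets)
    sc <- species_scores(cls, presence)
    or <- oracle_scores(cls, presence)
    expect_equal(setNames(sc$vote_fraction, sc$species_id),
                 or$vote_fraction[sc$species_id], tolerance = 1e-12)
    expect_equal(setNames(sc$confidence, sc$species_id),
                 or$confidence[sc$species_id], tolerance = 1e-12)
  }
})

test_that("detection thresholds behave as stated and nest monotonically", {
  sc <- structure(data.frame(
    species_id = c("A", "B", "C"), m_s = 1L, vote_count = 0L,
    vote_fraction = c(0.5, 0.1, 0), confidence = c(0.35, 0.19, 0),
    n_supporting_reads = 0L, stringsAsFactors = FALSE),
    class = c("species_score_table", "data.frame"))
  expect_equal(detect_species(sc, "confidence", 0.2), "A")
  expect_equal(detect_species(sc, "confidence", 0.19), c("A", "B"))
  expect_equal(detect_species(sc, "confidence", 1.0), character(0))
  expect_error(detect_species(sc, "confidence", 0), "threshold")
  expect_error(detect_species(sc, "confidence", -1), "threshold")
  # monotone nesting over a grid, both methods
  for (method in c("confidence", "vote")) {
    prev <- NULL
    for (T in c(0.05, 0.15, 0.3, 0.6, 1)) {
      det <- detect_species(sc, method, T)
      if (!is.null(prev)) expect_true(all(det %in% prev))
      prev <- det
    }
  }
})

test_that("score tables are invariant to read and gene order and to batching", {
  set.seed(59)
  genes <- c("g1", "g2", "g3")
  trees <- lapply(genes, function(g) rand_tax(8, gene = g))
  psets <- lapply(trees, function(tr) {
    make_pset(tr, lapply(1:8, function(j) rand_record(tr, sprintf("q%d", j))))
  })
  presence <- build_presence_index(trees)
  base <- species_scores(classify_genes(psets), presence)

  # permute genes and reads
  psets_perm <- rev(lapply(psets, function(p) {
    p$records <- rev(p$records); p
  }))
  perm <- species_scores(classify_genes(psets_perm), presence)
  expect_equal(base$vote_fraction, perm$vote_fraction)
  expect_equal(base$confidence, perm$confidence)

  # split one gene's reads into two batches and merge classifications
  cls <- classify_genes(psets)
  g1a <- cls[[1]]; g1b <- cls[[1]]
  g1a$reads <- cls[[1]]$reads[1:4]
  g1b$reads <- cls[[1]]$reads[5:8]
  merged <- cls
  merged[[1]]$reads <- c(g1a$reads, g1b$reads)
  sc2 <- species_scores(merged, presence)
  expect_equal(base$confidence, sc2$confidence)
  expect_equal(base$vote_fraction, sc2$vote_fraction)
})

test_that("placement mass on a species outside G_s raises a reference error", {
  tr <- binary_tax("g1")
  ps <- make_pset(tr, list(make_record("a", "g1", edge_of(tr, "sA"), 0.9)))
  # presence index built from a pruned tree that lacks sA for g1
  t_pruned <- build_taxonomy(data.frame(
    taxon_id = c("r", "g2", "sC"), parent_id = c(NA, "r", "g2"),
    rank = c("superkingdom", "genus", "species"),
    name = c("r", "g2", "sC"), stringsAsFactors = FALSE), "g1")
  presence <- build_presence_index(list(t_pruned))
  expect_error(species_scores(classify_genes(list(ps)), presence),
               "absent")
})

test_that("abundance profile computes relative read frequencies at a rank", {
  tr <- binary_tax("g1")
  recs <- c(lapply(1:6, function(i) make_record(paste0("a", i), "g1",
                                                edge_of(tr, "sA"), 1.0)),
            lapply(1:3, function(i) make_record(paste0("b", i), "g1",
                                                edge_of(tr, "sB"), 1.0)),
            lapply(1:1, function(i) make_record(paste0("c", i), "g1",
                                                edge_of(tr, "sC"), 1.0)))
  cls <- classify_genes(list(make_pset(tr, recs)))
  prof <- abundance_profile(cls, "species")
  expect_equal(as.numeric(prof[c("sA", "sB", "sC")]), c(0.6, 0.3, 0.1))
  expect_equal(sum(prof), 1)
  gen <- abundance_profile(cls, "genus")
  expect_equal(as.numeric(gen[c("g1", "g2")]), c(0.9, 0.1))
  # strict > for the profiling baseline
  expect_equal(detect_by_abundance(prof, 0.1), c("sA", "sB"))
  expect_equal(detect_by_abundance(prof, 0.05), c("sA", "sB", "sC"))
  # single-species trivial case
  prof1 <- abundance_profile(classify_genes(list(make_pset(tr, recs[1:6]))),
                             "species")
  expect_equal(as.numeric(prof1), 1.0)
  # zero reads assigned at rank -> empty profile, not an error
  none <- classify_genes(list(make_pset(tr, list(
    make_record("x", "g1", c(edge_of(tr, "sA"), edge_of(tr, "sC")),
                c(0.5, 0.45))))), B = 0.99)
  expect_length(abundance_profile(none, "species"), 0)
})

test_that("profiles sum to one on random fixtures whenever a read is assigned", {
  set.seed(61)
  for (i in 1:10) {
    tr <- rand_tax(sample(4:15, 1), gene = "g1")
    ps <- make_pset(tr, lapply(1:10, function(j) rand_record(tr, paste0("q", j))))
    cls <- classify_genes(list(ps), B = 0.6)
    prof <- abundance_profile(cls, "species")
    if (length(prof) > 0) expect_equal(sum(prof), 1, tolerance = 1e-9)
  }
})
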