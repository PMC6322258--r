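fv_row <- function(tf = 1, idf = 1, cooc = 0, avg_tf = 1, title = 0,
                   a1 = 0, a2 = 0, a3 = 0, len = 100, entity = "E1") {
  tibble::tibble(article_id = "a", entity_id = entity, tf = tf, idf = idf,
                 cooc = cooc, avg_tf = avg_tf, title = title,
                 abstract_1 = a1, abstract_2 = a2, abstract_3 = a3,
                 article_len = len)
}

fake_stats <- function(avg_len = 100, df = c(E1 = 1L), tc = df, n = 10L) {
  structure(list(num_articles = n, df = df, total_count = tc,
                 avg_article_len = avg_len), class = "cae_corpus_stats")
}

test_that("TFIDF multiplies frequency and rareness", {
  expect_equal(tfidf_score(fv_row(tf = 2, idf = 1)), 2)
  expect_equal(tfidf_score(fv_row(tf = 5, idf = 0)), 0)
  expect_equal(tfidf_score(fv_row(tf = 3, idf = 2)), 6)
})

test_that("BM25e saturates in TF and normalises by article length", {
  st <- fake_stats(avg_len = 100)
  # tf = 1 at average length: score equals IDF for any k1, b
  for (k1 in c(0.5, 1.2, 2)) for (b in c(0, 0.4, 0.75, 1)) {
    expect_equal(bm25e_score(fv_row(tf = 1, idf = 1.7, len = 100), st, k1, b),
                 1.7, tolerance = 1e-12)
  }
  # large tf tends to (k1 + 1) * idf
  expect_equal(bm25e_score(fv_row(tf = 1e8, idf = 2, len = 100), st, 1.2, 0.75),
               2.2 * 2, tolerance = 1e-6)
  # worked value: tf = 2 at average length with default parameters
  expect_equal(bm25e_score(fv_row(tf = 2, idf = 3, len = 100), st, 1.2, 0.75),
               (2 * 2.2) / 3.2 * 3, tolerance = 1e-12)
  # b = 0 removes length dependence; monotone in tf
  s_short <- bm25e_score(fv_row(tf = 2, idf = 1, len = 10), st, 1.2, 0)
  s_long <- bm25e_score(fv_row(tf = 2, idf = 1, len = 500), st, 1.2, 0)
  expect_equal(s_short, s_long)
  tfs <- vapply(1:8, function(t)
    bm25e_score(fv_row(tf = t, idf = 1, len = 100), st, 1.2, 0.75), numeric(1))
  expect_true(all(diff(tfs) > 0))
})

test_that("ESe combines saturation with the concentration factor", {
  # tf = 1, |a| = avgdl, c = DF, N = DF: first factor 1/1.45, second 1
  st <- fake_stats(avg_len = 50, df = c(E1 = 10L), tc = c(E1 = 10L), n = 10L)
  expect_equal(ese_score(fv_row(tf = 1, len = 50), st), 1 / 1.45,
               tolerance = 1e-12)
  # c = DF (AvgTF = 1), N = 4 DF: second factor sqrt(4) = 2
  st2 <- fake_stats(avg_len = 50, df = c(E1 = 5L), tc = c(E1 = 5L), n = 20L)
  expect_equal(ese_score(fv_row(tf = 1, len = 50), st2), 2 / 1.45,
               tolerance = 1e-12)
  # monotone in tf and in concentration
  v <- vapply(1:6, function(t) ese_score(fv_row(tf = t, len = 50), st), numeric(1))
  expect_true(all(diff(v) > 0))
  st3 <- fake_stats(avg_len = 50, df = c(E1 = 5L), tc = c(E1 = 15L), n = 20L)
  expect_gt(ese_score(fv_row(tf = 1, len = 50), st3),
            ese_score(fv_row(tf = 1, len = 50), st2))
  expect_error(ese_score(fv_row(entity = "nope"), st), "unseen")
})

test_that("eGRABe adds one point per satisfied locality/frequency rule", {
  expect_equal(egrabe_score(fv_row(tf = 3, title = 1, a1 = 1), 1L), 3L)
  expect_equal(egrabe_score(fv_row(tf = 1), 1L), 0L)
  expect_equal(egrabe_score(fv_row(tf = 4), 2L), 1L)
  # monotone in X via the boundary flag
  fv <- fv_row(tf = 1, a1 = 0, a2 = 1, a3 = 1)
  v <- vapply(1:3, function(X) egrabe_score(fv, X), integer(1))
  expect_true(all(diff(v) >= 0))
})

test_that("CCSEe sums goal, background and conclusion position weights", {
  lex <- lexicon("E1", "gene", list("alphafactor"))
  seg <- segment_article("a1", "Role of alphafactor",
    "Background statement. Methods here. More methods. Results shown. Alphafactor rose.")
  ann <- match_entities(seg, lex)
  cfg <- scorer_config(ccse_goal_w = 1, ccse_conclusion = c(1, 0.5, 0.25))
  # title + last sentence
  expect_equal(ccsee_score(ann, "E1", cfg), 2.0)
  # absent from all zones -> 0
  seg2 <- segment_article("a2", "No mention here",
    "One. Two. Three alphafactor four. Five. Six. Seven. Eight.")
  ann2 <- match_entities(seg2, lex)
  expect_equal(ccsee_score(ann2, "E1",
                           scorer_config(ccse_background = c(1, 0.5),
                                         ccse_conclusion = c(1, 0.5))), 0)
  # title-only entity with goal weight 1
  seg3 <- segment_article("a3", "Alphafactor study", "Nothing else relevant.")
  ann3 <- match_entities(seg3, lex)
  expect_equal(ccsee_score(ann3, "E1", cfg), 1.0)
})

test_that("ranking sorts by score with deterministic entity-id tie-break", {
  a <- make_ann("1", sentences = list(c("A", "B", "C")))
  feat <- tibble::tibble(article_id = "1", entity_id = c("A", "B", "C"))
  sc <- list(A = 2, B = 5, C = 2)
  rk <- caerank:::new_ranked("1", names(sc), unlist(sc))
  expect_equal(rk$entity_id, c("B", "A", "C"))
  expect_equal(rk$rank, 1:3)
  # single candidate
  rk1 <- caerank:::new_ranked("1", "A", 3)
  expect_equal(rk1$rank, 1L)
})

test_that("random ranking is a seed-reproducible permutation", {
  fx <- fixture_sim(seed = 21, n_articles = 10)
  r1 <- rank_corpus(fx$ann, "random", seed = 5)
  r2 <- rank_corpus(fx$ann, "random", seed = 5)
  r3 <- rank_corpus(fx$ann, "random", seed = 6)
  expect_identical(lapply(r1, `[[`, "entity_id"),
                   lapply(r2, `[[`, "entity_id"))
  expect_false(identical(lapply(r1, `[[`, "entity_id"),
                         lapply(r3, `[[`, "entity_id")))
  # a permutation of the candidates
  for (aid in names(r1)[1:3]) {
    expect_setequal(r1[[aid]]$entity_id, fx$ann[[aid]]$candidates)
  }
  expect_error(rank_corpus(fx$ann, "random"), "seed")
})

test_that("pairwise training recovers a separating feature", {
  # synthetic features where avg_tf strictly separates CAEs
  set.seed(42)
  n_art <- 30
  rows <- list(); gold <- list()
  for (i in seq_len(n_art)) {
    aid <- as.character(i)
    ents <- paste0("E", i, "_", 1:5)
    cae <- ents[1:2]
    gold[[aid]] <- cae
    for (j in 1:5) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        article_id = aid, entity_id = ents[j],
        tf = sample(1:3, 1), idf = runif(1, 0, 3), cooc = runif(1, 0, 2),
        avg_tf = if (j <= 2) runif(1, 3, 5) else runif(1, 1, 2),
        title = sample(0:1, 1), abstract_1 = 0L,
        abstract_2 = sample(0:1, 1), abstract_3 = 1L, article_len = 100L)
    }
  }
  feat <- dplyr::bind_rows(rows)
  gold <- structure(gold, class = "cae_gold")
  m <- train_ranker(feat, gold, seed = 1)
  expect_gt(m$weights[["avg_tf"]], 0)
  expect_gt(m$weights[["avg_tf"]], abs(m$weights[["tf"]]))
  # perfect training MAP on separable data
  scores <- score_features(m, feat)
  aps <- vapply(unique(feat$article_id), function(aid) {
    ix <- feat$article_id == aid
    rk <- caerank:::new_ranked(aid, feat$entity_id[ix], scores[ix])
    average_precision(rk, gold[[aid]])
  }, numeric(1))
  expect_equal(mean(aps), 1.0)

  # determinism: same data and seed give identical weights
  m2 <- train_ranker(feat, gold, seed = 1)
  expect_identical(m$weights, m2$weights)

  # antisymmetry: swapping the class labels negates the weight vector
  gold_flip <- structure(lapply(unique(feat$article_id), function(aid) {
    setdiff(feat$entity_id[feat$article_id == aid], gold[[aid]])
  }), names = unique(feat$article_id), class = "cae_gold")
  m3 <- train_ranker(feat, gold_flip, seed = 1)
  expect_equal(unname(m3$weights), unname(-m$weights), tolerance = 1e-6)
})

test_that("training skips degenerate articles and models round-trip as JSON", {
  feat <- dplyr::bind_rows(
    fv_row(entity = "A", tf = 3, avg_tf = 4),
    fv_row(entity = "B", tf = 1, avg_tf = 1))
  feat$article_id <- "a"
  all_cae <- structure(list(a = c("A", "B")), class = "cae_gold")
  expect_error(train_ranker(feat, all_cae), "no training articles")

  fx <- fixture_sim(seed = 23, n_articles = 25)
  feat2 <- build_features(fx$ann, fx$stats)
  m <- train_ranker(feat2, fx$sim$gold)
  expect_equal(length(m$weights), 6L)
  f <- withr::local_tempfile(fileext = ".json")
  write_ranker(m, f)
  m2 <- read_ranker(f)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(score_features(m2, feat2), score_features(m, feat2),
               tolerance = 1e-12)
  # constant feature gets zero contribution, not NaN
  feat3 <- feat2
  feat3$title <- 1L
  m3 <- train_ranker(feat3, fx$sim$gold)
  expect_true(all(is.finite(score_features(m3, feat3))))
})

test_that("ablation sets drop exactly one member of ALL", {
  expect_setequal(feature_set_all(),
                  c("tf", "idf", "cooc", "avg_tf", "title", "abstract_2"))
  expect_setequal(feature_set_all_minus("abstract_2"),
                  c("tf", "idf", "cooc", "avg_tf", "title"))
  expect_error(feature_set_all_minus("abstract_9"), "unknown feature")
})
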