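test_that("average precision follows the seen-at-rank definition", {
  # [CAE, non, CAE, non] -> (1/1 + 2/3) / 2
  rk <- ranked_fixture(c("c1", "n1", "c2", "n2"))
  expect_equal(as.numeric(average_precision(rk, c("c1", "c2"))),
               (1 + 2/3) / 2)
  # all k CAEs on top
  rk2 <- ranked_fixture(c("c1", "c2", "n1", "n2"))
  expect_equal(as.numeric(average_precision(rk2, c("c1", "c2"))), 1.0)
  # single CAE ranked last of n
  rk3 <- ranked_fixture(c("n1", "n2", "n3", "c1"))
  expect_equal(as.numeric(average_precision(rk3, "c1")), 1/4)
  # gold CAEs missing from candidates are dropped from k
  a <- average_precision(rk2, c("c1", "c2", "ghost"))
  expect_equal(as.numeric(a), 1.0)
  expect_equal(attr(a, "n_missing"), 1L)
  expect_error(average_precision(rk3, "ghost"), "no gold CAE")
})

test_that("precision at X keeps the denominator at X for short lists", {
  rk <- ranked_fixture(c("c1", "n1", "c2", "n2"))
  expect_equal(precision_at_x(rk, c("c1", "c2"), 3L), 2/3)
  expect_equal(precision_at_x(rk, c("c1", "c2"), 1L), 1.0)
  short <- ranked_fixture(c("c1", "n1"))
  expect_equal(precision_at_x(short, "c1", 5L), 0.2)
})

test_that("AP and P@X match exhaustive enumeration for small candidate sets", {
  for (n in 2:4) {
    ids <- paste0("e", seq_len(n))
    subsets <- unlist(lapply(seq_len(n), function(k)
      utils::combn(n, k, simplify = FALSE)), recursive = FALSE)
    for (p in perms(n)) {
      rk <- ranked_fixture(ids[p])
      for (sub in subsets) {
        gold <- ids[sub]
        expect_equal(as.numeric(average_precision(rk, gold)),
                     ap_oracle(ids[p], gold))
        expect_equal(precision_at_x(rk, gold, 2L),
                     p_at_x_oracle(ids[p], gold, 2L))
      }
    }
  }
})

test_that("corpus evaluation pools articles and counts exclusions", {
  rks <- list("1" = ranked_fixture(c("c1", "n1"), "1"),
              "2" = ranked_fixture(c("n2", "c2"), "2"),
              "3" = ranked_fixture(c("n3", "n4"), "3"))
  gold <- structure(list("1" = "c1", "2" = "c2", "3" = "zz"),
                    class = "cae_gold")
  ev <- evaluate(rks, gold)
  expect_equal(ev$map, mean(c(1, 0.5)))
  expect_equal(ev$n_excluded, 1L)   # article 3 has no gold CAE in candidates
  expect_equal(ev$n_articles, 2L)
  expect_equal(unname(ev$avg_p_at["P@1"]), 0.5)
  # %P@1>0 equals 100 * Average P@1 (P@1 is 0/1 per article)
  expect_equal(unname(ev$pct_p_at_positive["P@1"]),
               100 * unname(ev$avg_p_at["P@1"]))
  expect_error(evaluate(list("9" = ranked_fixture("x", "9")), gold),
               "missing from gold")
})

test_that("%P@1>0 equals 100 x Average P@1 on generated corpora", {
  fx <- fixture_sim(seed = 41, n_articles = 30)
  rk <- rank_corpus(fx$ann, "tf", fx$stats)
  ev <- evaluate(rk, fx$sim$gold)
  expect_equal(unname(ev$pct_p_at_positive["P@1"]),
               100 * unname(ev$avg_p_at["P@1"]), tolerance = 1e-12)
})

test_that("fold plans are balanced, seed-stable and cover every article", {
  ids <- as.character(1:11)
  plan <- make_folds(ids, 5L, seed = 9)
  sizes <- table(plan$assignments)
  expect_setequal(as.integer(sizes), c(3L, 2L, 2L, 2L, 2L))
  expect_setequal(names(plan$assignments), ids)
  plan2 <- make_folds(ids, 5L, seed = 9)
  expect_identical(plan$assignments, plan2$assignments)
  plan3 <- make_folds(as.character(1:10), 5L, seed = 1)
  expect_true(all(table(plan3$assignments) == 2L))
  expect_error(make_folds(as.character(1:3), 5L, seed = 1), "smaller")
})

test_that("cross-validation pools held-out rankings with fold-local stats", {
  fx <- fixture_sim(seed = 43, n_articles = 25)
  plan <- make_folds(names(fx$ann), 5L, seed = 2)
  cv <- cross_validate(fx$ann, fx$sim$gold, "tf", plan)
  # manual reconstruction
  rankings <- list()
  for (fold in 0:4) {
    test_ids <- names(plan$assignments)[plan$assignments == fold]
    train <- structure(fx$ann[setdiff(names(fx$ann), test_ids)],
                       class = "cae_annotated_corpus")
    st <- compute_corpus_stats(train)
    rankings <- c(rankings, rank_corpus(
      structure(fx$ann[test_ids], class = "cae_annotated_corpus"), "tf", st))
  }
  manual <- evaluate(rankings, fx$sim$gold)
  expect_equal(cv$map, manual$map, tolerance = 1e-12)
  expect_equal(cv$n_articles, manual$n_articles)

  # a reused plan keeps test memberships identical across scorers
  cv2 <- cross_validate(fx$ann, fx$sim$gold, "avgtf", plan)
  expect_setequal(names(cv2$per_article_ap), names(cv$per_article_ap))
})

test_that("paired t-test flags certain and null differences correctly", {
  x <- runif(20)
  r <- paired_ttest(x, x)
  expect_equal(r$t, 0)
  expect_false(r$significant)
  r2 <- paired_ttest(rep(0.8, 50), rep(0.7, 50))
  expect_true(r2$significant)
  expect_equal(r2$mean_diff, 0.1)
  set.seed(1)
  a <- runif(40); b <- a + rnorm(40, 0.3, 0.05)
  r3 <- paired_ttest(b, a, alpha = 0.01)
  expect_true(r3$significant)
  expect_gt(r3$t, 0)
  expect_error(paired_ttest(setNames(runif(3), c("a", "b", "c")),
                            setNames(runif(3), c("a", "b", "d"))),
               "differ")
  expect_error(paired_ttest(1, 2), "at least two")
})

test_that("scorer comparison matrix marks directional significance", {
  set.seed(7)
  base <- runif(60, 0.2, 0.8)
  aps <- list(good = pmin(base + 0.15, 1), flat = base,
              noise = base + rnorm(60, 0, 1e-3))
  cmp <- compare_scorers(aps, alpha = 0.01)
  expect_true(cmp$significant["good", "flat"])
  expect_false(cmp$significant["flat", "good"])
  expect_true(is.na(cmp$p["flat", "flat"]))
})
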