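#' Average precision of one ranked candidate list
#'
#' AP for an article with k CAEs: the mean over the CAEs of j / Seen(j),
#' where Seen(j) is the rank of the j-th best-ranked CAE -- i.e. the
#' precision observed each time a CAE is encountered while walking down the
#' list. Gold CAEs that are not among the ranked candidates are dropped
#' from k (their count is available via `attr(, "n_missing")`).
#'
#' @param ranked A `cae_ranked` tibble.
#' @param gold_caes Character vector of gold CAE ids for the article.
#' @return AP in (0, 1], with attribute `n_missing`. Errors if no gold CAE
#'   is among the candidates.
#' @export
average_precision <- function(ranked, gold_caes) {
  present <- intersect(gold_caes, ranked$entity_id)
  n_missing <- length(setdiff(gold_caes, present))
  if (length(present) == 0L) {
    stop("no gold CAE among the ranked candidates of article ",
         ranked$article_id[1] %||% "?", call. = FALSE)
  }
  seen <- sort(ranked$rank[ranked$entity_id %in% present])
  ap <- mean(seq_along(seen) / seen)
  attr(ap, "n_missing") <- n_missing
  ap
}

#' Precision among the top-X ranked candidates
#'
#' `|top-X intersect gold| / X`; when fewer than X candidates exist the
#' denominator stays X (a short list cannot reach precision 1 for large X).
#'
#' @param ranked A `cae_ranked` tibble.
#' @param gold_caes Character vector of gold CAE ids.
#' @param X Positive cut-off.
#' @return Real in [0, 1].
#' @export
precision_at_x <- function(ranked, gold_caes, X) {
  stopifnot(X >= 1L)
  top <- ranked$entity_id[ranked$rank <= X]
  length(intersect(top, gold_caes)) / X
}

#' Evaluate rankings against the gold standard
#'
#' Computes MAP, the average precision at top-X, and the percentage of
#' articles with at least one CAE in the top X. Articles whose gold CAEs
#' are entirely absent from their candidates are excluded and counted.
#'
#' @param rankings Named list of `cae_ranked` (article_id -> ranking).
#' @param gold A `cae_gold`.
#' @param p_at_x Cut-offs for Average P@X (default 1, 2, 3, 5).
#' @param pct_at_x Cut-offs for the top-X hit percentage (default 1, 2, 3).
#' @return A `cae_eval` list: `map`, `avg_p_at` (named), `pct_p_at_positive`
#'   (named, in percent), `per_article_ap`, `n_articles`, `n_excluded`,
#'   `n_missing_caes`.
#' @export
evaluate <- function(rankings, gold, p_at_x = c(1L, 2L, 3L, 5L),
                     pct_at_x = c(1L, 2L, 3L)) {
  missing_gold <- setdiff(names(rankings), names(gold))
  if (length(missing_gold)) {
    stop("article(s) missing from gold standard: ",
         paste(utils::head(missing_gold, 5L), collapse = ", "), call. = FALSE)
  }
  xs <- sort(unique(c(p_at_x, pct_at_x)))
  ap <- numeric(); pax <- matrix(0, nrow = 0, ncol = length(xs))
  n_excluded <- 0L; n_missing <- 0L
  keep_ids <- character()
  for (aid in names(rankings)) {
    r <- rankings[[aid]]
    gc <- gold[[aid]]
    if (nrow(r) == 0L || length(intersect(gc, r$entity_id)) == 0L) {
      n_excluded <- n_excluded + 1L
      next
    }
    a <- average_precision(r, gc)
    n_missing <- n_missing + attr(a, "n_missing")
    ap[aid] <- as.numeric(a)
    pax <- rbind(pax, vapply(xs, function(X) precision_at_x(r, gc, X),
                             numeric(1)))
    keep_ids <- c(keep_ids, aid)
  }
  if (length(ap) == 0L) stop("no evaluable articles", call. = FALSE)
  colnames(pax) <- as.character(xs)
  avg_p <- setNames(colMeans(pax)[as.character(p_at_x)],
                    paste0("P@", p_at_x))
  pct <- setNames(vapply(pct_at_x, function(X)
    100 * mean(pax[, as.character(X)] > 0), numeric(1)),
    paste0("P@", pct_at_x))
  structure(list(map = mean(ap), avg_p_at = avg_p,
                 pct_p_at_positive = pct,
                 per_article_ap = ap, n_articles = length(ap),
                 n_excluded = n_excluded, n_missing_caes = n_missing),
            class = "cae_eval")
}

#' @export
print.cae_eval <- function(x, ...) {
  cat(sprintf("<cae_eval> %d articles (%d excluded)\n",
              x$n_articles, x$n_excluded))
  cat(sprintf("  MAP        %.4f\n", x$map))
  for (nm in names(x$avg_p_at)) {
    cat(sprintf("  Average %-5s %.4f\n", nm, x$avg_p_at[[nm]]))
  }
  for (nm in names(x$pct_p_at_positive)) {
    cat(sprintf("  %%%s>0     %.2f%%\n", nm, x$pct_p_at_positive[[nm]]))
  }
  invisible(x)
}

#' Serialize an evaluation report as JSON
#' @param report A `cae_eval`.
#' @param path Output path.
#' @param per_article Include per-article AP values (default TRUE).
#' @return `path`, invisibly.
#' @export
write_eval <- function(report, path, per_article = TRUE) {
  obj <- list(map = report$map,
              avg_p_at = as.list(report$avg_p_at),
              pct_p_at_positive = as.list(report$pct_p_at_positive),
              n_articles = report$n_articles,
              n_excluded = report$n_excluded,
              n_missing_caes = report$n_missing_caes)
  if (per_article) obj$per_article_ap <- as.list(report$per_article_ap)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assign articles to cross-validation folds
#'
#' Articles are shuffled by seed and dealt evenly into folds (sizes differ
#' by at most one), so a plan reused across scorers keeps test memberships
#' identical and paired comparisons valid.
#'
#' @param corpus A `cae_corpus`, `cae_annotated_corpus`, or character vector
#'   of article ids.
#' @param n_folds Number of folds (default 5).
#' @param seed Shuffle seed.
#' @return A `cae_folds` list: `assignments` (named integer, folds
#'   0..n_folds-1), `n_folds`, `seed`.
#' @export
make_folds <- function(corpus, n_folds = 5L, seed = 1L) {
  ids <- if (is.character(corpus)) corpus
         else if (inherits(corpus, "cae_annotated_corpus")) names(corpus)
         else corpus$article_id
  if (length(ids) < n_folds) {
    stop("corpus smaller than the number of folds", call. = FALSE)
  }
  shuffled <- with_seed(seed, sample(ids))
  assign <- setNames(rep(seq_len(n_folds) - 1L, length.out = length(ids)),
                     shuffled)
  structure(list(assignments = assign[ids], n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "cae_folds")
}

#' Cross-validated evaluation of a scorer
#'
#' For each fold, collection statistics (and the ranking model, for a
#' trainable scorer) are computed on the training articles only; the
#' held-out articles are then ranked with those statistics and all held-out
#' rankings are pooled into a single report.
#'
#' @param annotated A `cae_annotated_corpus`.
#' @param gold A `cae_gold` covering the articles.
#' @param scorer A scorer name (see [scorer_names()]) or a [ranker_spec()].
#' @param plan A [make_folds()] plan over the same articles.
#' @param cfg A [scorer_config()].
#' @param seed Seed for the `"random"` scorer.
#' @return A `cae_eval` over the pooled held-out rankings.
#' @export
cross_validate <- function(annotated, gold, scorer, plan,
                           cfg = scorer_config(), seed = NULL) {
  rankings <- list()
  for (fold in 0:(plan$n_folds - 1L)) {
    test_ids <- names(plan$assignments)[plan$assignments == fold]
    train_ids <- setdiff(names(annotated), test_ids)
    train <- structure(annotated[train_ids], class = "cae_annotated_corpus")
    test <- structure(annotated[intersect(names(annotated), test_ids)],
                      class = "cae_annotated_corpus")
    stats <- compute_corpus_stats(train)
    use_scorer <- scorer
    if (inherits(scorer, "cae_ranker_spec")) {
      tr_feat <- build_features(train, stats)
      use_scorer <- tryCatch(
        train_ranker(tr_feat, gold, scorer$feature_subset,
                     scorer$regularization, seed = plan$seed),
        error = function(e) stop(sprintf("training failed in fold %d: %s",
                                         fold, conditionMessage(e)),
                                 call. = FALSE))
    }
    fold_seed <- if (!is.null(seed)) seed + fold else NULL
    rk <- rank_corpus(test, use_scorer, stats, cfg = cfg, seed = fold_seed)
    rankings <- c(rankings, rk)
  }
  evaluate(rankings, gold)
}

#' Paired t-test between two per-article metric vectors
#'
#' Two-sided paired t-test on the per-article differences (AP values for
#' MAP comparisons, P@X values for P@X comparisons), judged at the given
#' alpha (default 0.01, i.e. 99% confidence).
#'
#' @param ap_a,ap_b Numeric vectors over the same articles; if named, they
#'   are matched by name.
#' @param alpha Significance level.
#' @return List: `t`, `p`, `significant`, `mean_diff`, `n`.
#' @export
paired_ttest <- function(ap_a, ap_b, alpha = 0.01) {
  if (!is.null(names(ap_a)) && !is.null(names(ap_b))) {
    if (!setequal(names(ap_a), names(ap_b))) {
      stop("article sets differ between the two metric vectors", call. = FALSE)
    }
    ap_b <- ap_b[names(ap_a)]
  } else if (length(ap_a) != length(ap_b)) {
    stop("metric vectors have different lengths", call. = FALSE)
  }
  n <- length(ap_a)
  if (n < 2L) stop("need at least two paired observations", call. = FALSE)
  d <- ap_a - ap_b
  if (sd(d) < 1e-12) {   # numerically constant differences
    if (abs(mean(d)) < 1e-12) {
      return(list(t = 0, p = 1, significant = FALSE, mean_diff = 0, n = n))
    }
    # constant non-zero difference: certainty
    return(list(t = sign(mean(d)) * Inf, p = 0, significant = TRUE,
                mean_diff = mean(d), n = n))
  }
  ht <- t.test(ap_a, ap_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alpha, mean_diff = mean(d), n = n)
}

#' Pairwise significance matrix across scorers
#'
#' Runs [paired_ttest()] on per-article AP vectors for every ordered scorer
#' pair.
#'
#' @param ap_list Named list of per-article AP vectors (one per scorer).
#' @param alpha Significance level.
#' @return List with matrices `p` and `significant` (rows beat columns when
#'   `mean_diff` > 0 and significant).
#' @export
compare_scorers <- function(ap_list, alpha = 0.01) {
  k <- length(ap_list)
  nm <- names(ap_list)
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  sig <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    r <- paired_ttest(ap_list[[i]], ap_list[[j]], alpha)
    p[i, j] <- r$p
    sig[i, j] <- r$significant && r$mean_diff > 0
  }
  list(p = p, significant = sig, alpha = alpha)
}
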