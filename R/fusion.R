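#' The default learned-fusion feature set
#'
#' TF, IDF, CoOcc, AvgTF, TITLE and Abstract2 (the best-performing X for the
#' boundary-sentence flag). Ablation configurations drop one member.
#'
#' @return Character vector of feature column names.
#' @export
feature_set_all <- function() {
  c("tf", "idf", "cooc", "avg_tf", "title", "abstract_2")
}

#' Ablated feature set (ALL minus one indicator)
#' @param drop Feature name to remove, e.g. `"abstract_2"`.
#' @return Character vector.
#' @export
feature_set_all_minus <- function(drop) {
  fs <- feature_set_all()
  if (!drop %in% fs) stop("unknown feature: ", drop, call. = FALSE)
  setdiff(fs, drop)
}

#' Configuration for the parametric fusion scorers
#'
#' @param k1,b BM25e parameters (defaults 1.2 and 0.75, the standard BM25
#'   settings).
#' @param egrab_x X for the eGRABe boundary rule, 1..3.
#' @param ccse_goal_w Weight for a title occurrence in CCSEe.
#' @param ccse_background Weights for abstract positions counted from the
#'   first sentence (element 1 = first sentence).
#' @param ccse_conclusion Weights counted from the last sentence (element 1
#'   = last sentence).
#' @return A `cae_scorer_config` list.
#' @export
scorer_config <- function(k1 = 1.2, b = 0.75, egrab_x = 2L,
                          ccse_goal_w = 1,
                          ccse_background = c(1, 2/3, 1/3),
                          ccse_conclusion = c(1, 2/3, 1/3)) {
  stopifnot(k1 >= 0, b >= 0, b <= 1, egrab_x %in% 1:3,
            all(ccse_background >= 0), all(ccse_conclusion >= 0))
  structure(list(k1 = k1, b = b, egrab_x = as.integer(egrab_x),
                 ccse_goal_w = ccse_goal_w,
                 ccse_background = ccse_background,
                 ccse_conclusion = ccse_conclusion),
            class = "cae_scorer_config")
}

#' TFIDF fusion score
#' @param fv Feature tibble rows (from [build_features()]).
#' @return Numeric vector `tf * idf`.
#' @export
tfidf_score <- function(fv) {
  fv$tf * fv$idf
}

#' BM25-style fusion score for entities
#'
#' `TF(k1+1) / (TF + k1 (1 - b + b |a|/avgal)) * IDF`, the classic
#' saturating term-frequency weight with article-length normalisation.
#' With TF = 1 and |a| = avgal the score reduces to IDF exactly.
#'
#' @param fv Feature tibble rows (uses `tf`, `idf`, `article_len`).
#' @param stats A `cae_corpus_stats` supplying avgal.
#' @param k1,b Parameters; see [scorer_config()].
#' @return Numeric vector.
#' @export
bm25e_score <- function(fv, stats, k1 = 1.2, b = 0.75) {
  sat <- fv$tf * (k1 + 1) /
    (fv$tf + k1 * (1 - b + b * fv$article_len / stats$avg_article_len))
  sat * fv$idf
}

#' ES-style fusion score (frequency + rareness + concentration)
#'
#' `TF / (TF + 0.45 sqrt(|a|/avgdl)) * sqrt((c(e,C)/DF(e))^3 * N/DF(e))`.
#' The second factor rewards entities that concentrate their occurrences in
#' few articles (high micro-average TF, low document frequency).
#'
#' @param fv Feature tibble rows (uses `tf`, `article_len`, `entity_id`).
#' @param stats A `cae_corpus_stats`.
#' @param smooth_unseen The concentration factor is undefined for an entity
#'   absent from the reference collection (DF = 0). With the default
#'   `FALSE` such entities raise an error; `TRUE` scores them as if seen
#'   exactly once (DF = 1, c = 1), which ranking under cross-validation
#'   uses so that held-out articles with novel entities remain scorable.
#' @return Numeric vector.
#' @export
ese_score <- function(fv, stats, smooth_unseen = FALSE) {
  d <- stats$df[fv$entity_id]
  cc <- stats$total_count[fv$entity_id]
  unseen <- is.na(d) | d == 0L
  if (any(unseen)) {
    if (!smooth_unseen) {
      bad <- unique(fv$entity_id[unseen])
      stop("ese_score undefined for entities unseen in collection: ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    d[unseen] <- 1L
    cc[unseen] <- 1L
  }
  n <- stats$num_articles
  first <- fv$tf / (fv$tf + 0.45 * sqrt(fv$article_len / stats$avg_article_len))
  unname(first * sqrt((cc / d)^3 * (n / d)))
}

#' eGRAB-style rule score
#'
#' One point each for: TF >= 3; a title occurrence; an occurrence in the
#' first X or last X abstract sentences.
#'
#' @param fv Feature tibble rows.
#' @param X Integer 1..3.
#' @return Integer vector in 0..3.
#' @export
egrabe_score <- function(fv, X) {
  stopifnot(X %in% 1:3)
  ax <- fv[[paste0("abstract_", X)]]
  as.integer(fv$tf >= 3) + as.integer(fv$title) + as.integer(ax)
}

#' CCSE-style positional score for one entity
#'
#' Sum of a goal factor (title occurrence), a background factor (weights
#' over the leading abstract sentences) and a conclusion factor (weights
#' over the trailing sentences). Every mention contributes, so an entity
#' occurring in several parts of the article is amplified.
#'
#' @param annotated A `cae_annotated` article.
#' @param entity Candidate entity id.
#' @param cfg A [scorer_config()].
#' @return Non-negative real.
#' @export
ccsee_score <- function(annotated, entity, cfg = scorer_config()) {
  m <- annotated$mentions[annotated$mentions$entity_id == entity, ]
  if (nrow(m) == 0L) return(0)
  score <- if (any(m$in_title)) cfg$ccse_goal_w else 0
  n <- annotated$segmented$n_sentences
  s <- m$sentence[!is.na(m$sentence)]
  for (si in s) {
    from_start <- si + 1L                  # 1-based index from first sentence
    from_end <- n - si                     # 1-based index from last sentence
    if (from_start <= length(cfg$ccse_background)) {
      score <- score + cfg$ccse_background[from_start]
    }
    if (from_end <= length(cfg$ccse_conclusion)) {
      score <- score + cfg$ccse_conclusion[from_end]
    }
  }
  score
}

.indicator_scorers <- c("tf", "idf", "cooc", "avgtf", "title",
                        "abstract1", "abstract2", "abstract3")
.fusion_scorers <- c("tfidf", "bm25e", "ese", "ccsee",
                     "egrabe1", "egrabe2", "egrabe3", "random")

#' Names of the built-in scorers
#' @return Character vector accepted by [rank_article()] and friends.
#' @export
scorer_names <- function() c(.indicator_scorers, .fusion_scorers)

# scores for the candidates of one article, aligned with `fv` rows
score_candidates <- function(fv, annotated, scorer, stats,
                             cfg = scorer_config(), model = NULL) {
  if (inherits(scorer, "cae_ranker")) {
    return(score_features(scorer, fv))
  }
  if (inherits(scorer, "cae_scorer_config")) {
    stop("a scorer_config must be paired with a scorer name; pass cfg=",
         call. = FALSE)
  }
  switch(scorer,
    tf = fv$tf, idf = fv$idf, cooc = fv$cooc, avgtf = fv$avg_tf,
    title = fv$title,
    abstract1 = fv$abstract_1, abstract2 = fv$abstract_2,
    abstract3 = fv$abstract_3,
    tfidf = tfidf_score(fv),
    bm25e = bm25e_score(fv, stats, cfg$k1, cfg$b),
    ese = ese_score(fv, stats, smooth_unseen = TRUE),
    egrabe1 = egrabe_score(fv, 1L), egrabe2 = egrabe_score(fv, 2L),
    egrabe3 = egrabe_score(fv, 3L),
    ccsee = vapply(fv$entity_id, function(e) ccsee_score(annotated, e, cfg),
                   numeric(1)),
    random = runif(nrow(fv)),
    stop("unknown scorer: ", scorer, call. = FALSE)
  )
}

#' Rank the candidate entities of one article
#'
#' Sorts candidates by the chosen score, descending; ties are broken by
#' entity id ascending so that every ranking is deterministic.
#'
#' @param annotated A `cae_annotated` article.
#' @param scorer A scorer name (see [scorer_names()]) or a trained
#'   `cae_ranker`.
#' @param stats A `cae_corpus_stats` (needed by collection-level scorers).
#' @param features Optional pre-built feature tibble (whole corpus or this
#'   article); computed on the fly when absent.
#' @param cfg A [scorer_config()] for the parametric scorers.
#' @param seed Seed for the `"random"` scorer (required there).
#' @return A `cae_ranked` tibble: `article_id`, `entity_id`, `score`,
#'   `rank`. Empty (with a warning) when the article has no candidates.
#' @export
rank_article <- function(annotated, scorer, stats = NULL, features = NULL,
                         cfg = scorer_config(), seed = NULL) {
  if (length(annotated$candidates) == 0L) {
    warning("article ", annotated$article_id, " has no candidate entities")
    return(new_ranked(annotated$article_id, character(), numeric()))
  }
  fv <- article_features(annotated, stats, features)
  scores <- if (identical(scorer, "random") && !is.null(seed)) {
    with_seed(seed, score_candidates(fv, annotated, scorer, stats, cfg))
  } else {
    score_candidates(fv, annotated, scorer, stats, cfg)
  }
  new_ranked(annotated$article_id, fv$entity_id, scores)
}

article_features <- function(annotated, stats, features) {
  if (!is.null(features)) {
    fv <- features[features$article_id == annotated$article_id, ]
    if (nrow(fv) != length(annotated$candidates)) {
      stop("feature table does not cover article ", annotated$article_id,
           call. = FALSE)
    }
    return(fv)
  }
  if (is.null(stats)) {
    # enough for the purely positional scorers (random, ccsee)
    return(tibble::tibble(article_id = annotated$article_id,
                          entity_id = annotated$candidates))
  }
  ac <- structure(list(annotated), names = annotated$article_id,
                  class = "cae_annotated_corpus")
  build_features(ac, stats)
}

new_ranked <- function(article_id, entity_id, score) {
  ord <- order(-score, entity_id)
  out <- tibble::tibble(article_id = rep(article_id, length(entity_id)),
                        entity_id = entity_id[ord],
                        score = as.numeric(score)[ord],
                        rank = seq_along(ord))
  structure(out, class = c("cae_ranked", class(out)))
}

#' Rank every article of an annotated corpus
#'
#' @inheritParams rank_article
#' @param annotated A `cae_annotated_corpus`.
#' @param seed Seed for the `"random"` scorer; one stream drives the whole
#'   corpus so a given (seed, corpus) pair always yields the same rankings.
#' @return Named list of `cae_ranked`, one per article with candidates.
#' @export
rank_corpus <- function(annotated, scorer, stats = NULL, features = NULL,
                        cfg = scorer_config(), seed = NULL) {
  if (is.null(features)) {
    features <- if (!is.null(stats)) {
      build_features(annotated, stats)
    } else {
      dplyr::bind_rows(lapply(annotated, function(a)
        tibble::tibble(article_id = a$article_id, entity_id = a$candidates)))
    }
  }
  run <- function() {
    out <- list()
    for (aid in names(annotated)) {
      a <- annotated[[aid]]
      if (length(a$candidates) == 0L) next
      fv <- features[features$article_id == aid, ]
      scores <- score_candidates(fv, a, scorer, stats, cfg)
      out[[aid]] <- new_ranked(aid, fv$entity_id, scores)
    }
    out
  }
  if (identical(scorer, "random")) {
    if (is.null(seed)) stop("the random scorer needs a seed", call. = FALSE)
    with_seed(seed, run())
  } else {
    run()
  }
}

# ---- learning-based fusion ---------------------------------------------

#' Train a pairwise linear ranking model
#'
#' Learned fusion of the indicators by pairwise ranking: within each
#' training article, every (CAE, non-CAE) candidate pair contributes the
#' difference of their z-scored feature vectors with label +1 and its
#' negation with label -1; a linear large-margin classifier (soft-margin
#' SVM) is fit on these differences. Ranking with the model scores each
#' candidate by the learned linear combination. Articles lacking either a
#' CAE or a non-CAE among their candidates provide no pairs and are
#' skipped (counted in the model metadata).
#'
#' @param features Feature tibble from [build_features()] (training
#'   articles).
#' @param gold A `cae_gold` with the training articles' CAE sets.
#' @param feature_subset Columns to learn on; default [feature_set_all()].
#' @param regularization Soft-margin cost parameter C (default 1).
#' @param seed Recorded in the model metadata; the fit itself is
#'   deterministic given the data.
#' @return A `cae_ranker`: feature names, weights, per-feature centring and
#'   scaling, and training metadata.
#' @export
train_ranker <- function(features, gold, feature_subset = feature_set_all(),
                         regularization = 1, seed = 0L) {
  stopifnot(all(feature_subset %in% names(features)))
  lab <- mapply(function(aid, eid) eid %in% (gold[[aid]] %||% character()),
                features$article_id, features$entity_id)
  usable <- split(seq_len(nrow(features)), features$article_id)
  usable <- Filter(function(ix) any(lab[ix]) && any(!lab[ix]), usable)
  skipped <- length(unique(features$article_id)) - length(usable)
  if (length(usable) == 0L) {
    stop("no training articles with both a CAE and a non-CAE candidate",
         call. = FALSE)
  }
  rows <- unlist(usable, use.names = FALSE)
  x <- as.matrix(features[rows, feature_subset])
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1   # constant feature -> scaled to 0
  xs <- sweep(sweep(as.matrix(features[, feature_subset]), 2L, ctr), 2L,
              scl, "/")

  diffs <- list()
  for (ix in usable) {
    pos <- ix[lab[ix]]
    neg <- ix[!lab[ix]]
    for (p in pos) {
      d <- xs[rep(p, length(neg)), , drop = FALSE] - xs[neg, , drop = FALSE]
      diffs[[length(diffs) + 1L]] <- d
    }
  }
  d <- do.call(rbind, diffs)
  mat <- rbind(d, -d)
  y <- factor(c(rep(1, nrow(d)), rep(-1, nrow(d))), levels = c(-1, 1))
  fit <- e1071::svm(x = mat, y = y, kernel = "linear",
                    cost = regularization, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  # orient so that +1-labelled differences score positively
  if (mean(sign(d %*% w)) < 0) w <- -w
  structure(list(feature_names = feature_subset,
                 weights = setNames(as.numeric(w), feature_subset),
                 center = setNames(as.numeric(ctr), feature_subset),
                 scale = setNames(as.numeric(scl), feature_subset),
                 regularization = regularization,
                 meta = list(seed = seed, n_articles = length(usable),
                             n_pairs = nrow(d), n_skipped = skipped)),
            class = "cae_ranker")
}

#' Score feature rows with a trained ranking model
#' @param model A `cae_ranker`.
#' @param features Feature tibble rows.
#' @return Numeric score vector.
#' @export
score_features <- function(model, features) {
  x <- as.matrix(features[, model$feature_names])
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  drop(xs %*% model$weights)
}

#' Write a ranking model as JSON
#' @param model A `cae_ranker`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranker <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ranking model written by [write_ranker()]
#' @param path Path to the JSON file.
#' @return A `cae_ranker`.
#' @export
read_ranker <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(list(feature_names = m$feature_names,
                 weights = setNames(as.numeric(m$weights), m$feature_names),
                 center = setNames(as.numeric(m$center), m$feature_names),
                 scale = setNames(as.numeric(m$scale), m$feature_names),
                 regularization = m$regularization,
                 meta = m$meta),
            class = "cae_ranker")
}

#' Specification of a trainable scorer for cross-validation
#'
#' @param feature_subset Feature columns; default [feature_set_all()].
#' @param regularization Soft-margin cost C.
#' @return A `cae_ranker_spec`.
#' @export
ranker_spec <- function(feature_subset = feature_set_all(),
                        regularization = 1) {
  structure(list(feature_subset = feature_subset,
                 regularization = regularization),
            class = "cae_ranker_spec")
}
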