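#' Collection-level statistics
#'
#' Computes, over an annotated collection C: the number of articles |A|, the
#' document frequency DF(e) (articles mentioning e), the total occurrence
#' count c(e, C), and the average article length in tokens (avgal, used by
#' the length-normalised fusion scores).
#'
#' @param annotated A `cae_annotated_corpus`.
#' @return A `cae_corpus_stats` list: `num_articles`, `df` (named integer),
#'   `total_count` (named integer), `avg_article_len`.
#' @export
compute_corpus_stats <- function(annotated) {
  if (length(annotated) == 0L) stop("empty annotated collection", call. = FALSE)
  df <- integer(); tc <- integer()
  toks <- numeric(length(annotated))
  for (i in seq_along(annotated)) {
    a <- annotated[[i]]
    toks[i] <- a$segmented$token_count
    if (nrow(a$mentions) == 0L) next
    cnt <- table(a$mentions$entity_id)
    ids <- names(cnt)
    new <- setdiff(ids, names(df))
    if (length(new)) {
      df[new] <- 0L
      tc[new] <- 0L
    }
    df[ids] <- df[ids] + 1L
    tc[ids] <- tc[ids] + as.integer(cnt)
  }
  ord <- order(names(df))
  structure(list(num_articles = length(annotated),
                 df = df[ord], total_count = tc[ord],
                 avg_article_len = mean(toks)),
            class = "cae_corpus_stats")
}

#' Term frequency of an entity in one article
#'
#' Number of mentions of the entity anywhere in the article (title counts).
#'
#' @param entity Entity id; must be a candidate of the article.
#' @param annotated A `cae_annotated` article.
#' @return Integer count, at least 1.
#' @export
tf <- function(entity, annotated) {
  if (!entity %in% annotated$candidates) {
    stop(sprintf("'%s' is not a candidate of article %s", entity,
                 annotated$article_id), call. = FALSE)
  }
  sum(annotated$mentions$entity_id == entity)
}

#' Inverse document frequency (rareness)
#'
#' `log2((|A| + 1) / (DF(e) + 1))`; an entity never seen in the collection
#' takes DF = 0, so the +1 smoothing keeps the value finite.
#'
#' @param entity Entity id.
#' @param stats A `cae_corpus_stats`.
#' @return Non-negative real.
#' @export
idf <- function(entity, stats) {
  d <- stats$df[entity]
  d <- ifelse(is.na(d), 0L, d)
  unname(log2((stats$num_articles + 1) / (d + 1)))
}

# sentence index sets S_e(a): abstract sentences only, title excluded
sentence_set <- function(annotated, entity) {
  s <- annotated$mentions$sentence[annotated$mentions$entity_id == entity]
  unique(s[!is.na(s)])
}

#' Sentence co-occurrence score of an entity within an article
#'
#' For entity e with abstract-sentence set S_e(a), sums over every other
#' candidate x the fraction |S_e intersect S_x| / |S_e|. A title-only entity
#' (empty S_e) or a sole candidate scores 0.
#'
#' @param entity Entity id; must be a candidate.
#' @param annotated A `cae_annotated` article.
#' @return Non-negative real, at most the number of other candidates.
#' @export
cooc <- function(entity, annotated) {
  if (!entity %in% annotated$candidates) {
    stop(sprintf("'%s' is not a candidate of article %s", entity,
                 annotated$article_id), call. = FALSE)
  }
  se <- sentence_set(annotated, entity)
  if (length(se) == 0L) return(0)
  others <- setdiff(annotated$candidates, entity)
  if (length(others) == 0L) return(0)
  tot <- 0
  for (x in others) {
    sx <- sentence_set(annotated, x)
    tot <- tot + length(intersect(se, sx)) / length(se)
  }
  tot
}

#' Concentration of an entity across the collection
#'
#' The micro-average term frequency c(e, C) / DF(e): how strongly the
#' entity's occurrences concentrate in the articles that mention it. Always
#' at least 1 for an observed entity.
#'
#' @param entity Entity id with DF(e) >= 1.
#' @param stats A `cae_corpus_stats`.
#' @return Real >= 1.
#' @export
avg_tf <- function(entity, stats) {
  d <- stats$df[entity]
  if (is.na(d) || d == 0L) {
    stop(sprintf("avg_tf undefined: entity '%s' unseen in collection", entity),
         call. = FALSE)
  }
  unname(stats$total_count[entity] / d)
}

#' Title presence flag
#' @param entity Entity id; must be a candidate.
#' @param annotated A `cae_annotated` article.
#' @return 1 if the entity has a title mention, else 0.
#' @export
title_flag <- function(entity, annotated) {
  if (!entity %in% annotated$candidates) {
    stop(sprintf("'%s' is not a candidate of article %s", entity,
                 annotated$article_id), call. = FALSE)
  }
  as.integer(any(annotated$mentions$in_title &
                 annotated$mentions$entity_id == entity))
}

#' Abstract-boundary presence flag
#'
#' 1 if the entity appears in the first X or last X sentences of the
#' abstract. Short abstracts (at most 2X sentences) make every
#' abstract-located entity eligible.
#'
#' @param entity Entity id; must be a candidate.
#' @param annotated A `cae_annotated` article.
#' @param X Integer in 1..3.
#' @return 0 or 1.
#' @export
abstract_x <- function(entity, annotated, X) {
  stopifnot(X >= 1L)
  if (!entity %in% annotated$candidates) {
    stop(sprintf("'%s' is not a candidate of article %s", entity,
                 annotated$article_id), call. = FALSE)
  }
  s <- sentence_set(annotated, entity)
  if (length(s) == 0L) return(0L)
  n <- annotated$segmented$n_sentences
  as.integer(any(s < X | s >= n - X))
}

#' Assemble per-(entity, article) feature vectors
#'
#' One row per candidate entity per article with all six indicators plus the
#' article length in tokens (needed by the length-normalised fusion scores).
#' Rows are ordered by (article_id, entity_id), making serialization
#' deterministic.
#'
#' @param annotated A `cae_annotated_corpus`.
#' @param stats A `cae_corpus_stats`, normally computed on the training
#'   collection (to avoid test leakage under cross-validation).
#' @return A tibble with columns `article_id`, `entity_id`, `tf`, `idf`,
#'   `cooc`, `avg_tf`, `title`, `abstract_1`, `abstract_2`, `abstract_3`,
#'   `article_len`.
#' @export
build_features <- function(annotated, stats) {
  total <- sum(vapply(annotated, function(a) length(a$candidates), integer(1)))
  aid_v <- character(total); eid_v <- character(total)
  tf_v <- integer(total); idf_v <- numeric(total); cooc_v <- numeric(total)
  at_v <- numeric(total); ttl_v <- integer(total)
  a1_v <- integer(total); a2_v <- integer(total); a3_v <- integer(total)
  len_v <- integer(total)
  k <- 0L
  for (aid in names(annotated)) {
    a <- annotated[[aid]]
    cands <- a$candidates
    if (length(cands) == 0L) next
    n_sent <- a$segmented$n_sentences
    # per-entity mention summaries, computed once per article
    ssets <- lapply(cands, function(e) sentence_set(a, e))
    names(ssets) <- cands
    counts <- table(a$mentions$entity_id)
    in_ttl <- tapply(a$mentions$in_title, a$mentions$entity_id, any)
    for (j in seq_along(cands)) {
      e <- cands[j]
      se <- ssets[[j]]
      cx <- if (length(se) == 0L || length(cands) == 1L) 0 else {
        sum(vapply(cands[-j], function(x)
          length(intersect(se, ssets[[x]])) / length(se), numeric(1)))
      }
      d <- stats$df[e]
      k <- k + 1L
      aid_v[k] <- aid; eid_v[k] <- e
      tf_v[k] <- as.integer(counts[[e]])
      idf_v[k] <- idf(e, stats)
      cooc_v[k] <- cx
      at_v[k] <- if (!is.na(d) && d >= 1L) avg_tf(e, stats) else 1
      ttl_v[k] <- as.integer(isTRUE(in_ttl[[e]]))
      a1_v[k] <- as.integer(length(se) > 0L && any(se < 1L | se >= n_sent - 1L))
      a2_v[k] <- as.integer(length(se) > 0L && any(se < 2L | se >= n_sent - 2L))
      a3_v[k] <- as.integer(length(se) > 0L && any(se < 3L | se >= n_sent - 3L))
      len_v[k] <- a$segmented$token_count
    }
  }
  out <- tibble::tibble(article_id = aid_v[seq_len(k)],
                        entity_id = eid_v[seq_len(k)],
                        tf = tf_v[seq_len(k)], idf = idf_v[seq_len(k)],
                        cooc = cooc_v[seq_len(k)], avg_tf = at_v[seq_len(k)],
                        title = ttl_v[seq_len(k)],
                        abstract_1 = a1_v[seq_len(k)],
                        abstract_2 = a2_v[seq_len(k)],
                        abstract_3 = a3_v[seq_len(k)],
                        article_len = len_v[seq_len(k)])
  dplyr::arrange(out, .data$article_id, .data$entity_id)
}

#' Write a feature table as TSV
#' @param features Tibble from [build_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#' @param path Path to the TSV file.
#' @return Feature tibble.
#' @export
read_features <- function(path) {
  tibble::as_tibble(utils::read.delim(path, colClasses = c(
    article_id = "character", entity_id = "character")))
}

#' @importFrom rlang .data
NULL
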