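# Independent brute-force oracles and small fixtures shared across tests.

# average precision by walking the ranked list and recording the running
# precision each time a CAE is encountered
ap_oracle <- function(ordered_ids, gold) {
  precs <- numeric()
  hits <- 0L
  for (r in seq_along(ordered_ids)) {
    if (ordered_ids[r] %in% gold) {
      hits <- hits + 1L
      precs <- c(precs, hits / r)
    }
  }
  mean(precs)
}

p_at_x_oracle <- function(ordered_ids, gold, X) {
  sum(head(ordered_ids, X) %in% gold) / X
}

# all permutations of 1..n as a list of integer vectors
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# brute-force dictionary scan over one article's segments: stage 1 tries
# every official name at every offset (longest match first, left to right),
# stage 2 tries synonyms of entities whose official names were not found,
# on the tokens stage 1 left unconsumed. Assumes an unambiguous lexicon
# and no priority ids. Returns the multiset of matched entity ids.
scan_oracle <- function(segments, official, synonyms) {
  build_tab <- function(surfaces) {
    tab <- list()
    for (id in names(surfaces)) {
      for (s in surfaces[[id]]) {
        toks <- caerank::tokenize(s)
        key <- tolower(paste(toks, collapse = " "))
        tab[[key]] <- list(id = id, len = length(toks))
      }
    }
    tab
  }
  scan_one <- function(tokens, consumed, tab) {
    lens <- sort(unique(vapply(tab, `[[`, integer(1), "len")),
                 decreasing = TRUE)
    ids <- character()
    i <- 1L
    while (i <= length(tokens)) {
      if (consumed[i]) { i <- i + 1L; next }
      matched <- FALSE
      for (len in lens) {
        if (i + len - 1L > length(tokens)) next
        jj <- i:(i + len - 1L)
        if (any(consumed[jj])) next
        hit <- tab[[tolower(paste(tokens[jj], collapse = " "))]]
        if (!is.null(hit)) {
          ids <- c(ids, hit$id)
          consumed[jj] <- TRUE
          i <- i + len
          matched <- TRUE
          break
        }
      }
      if (!matched) i <- i + 1L
    }
    list(ids = ids, consumed = consumed)
  }
  consumed <- lapply(segments, function(s) rep(FALSE, length(s)))
  tab1 <- build_tab(official)
  found <- character()
  for (si in seq_along(segments)) {
    r <- scan_one(segments[[si]], consumed[[si]], tab1)
    consumed[[si]] <- r$consumed
    found <- c(found, r$ids)
  }
  unseen <- setdiff(names(synonyms), unique(found))
  if (length(unseen)) {
    tab2 <- build_tab(synonyms[unseen])
    if (length(tab2)) {
      for (si in seq_along(segments)) {
        r <- scan_one(segments[[si]], consumed[[si]], tab2)
        consumed[[si]] <- r$consumed
        found <- c(found, r$ids)
      }
    }
  }
  found
}

# recompute all six indicators for one (entity, article) pair straight from
# the mention tuples, independently of build_features
indicator_oracle <- function(entity, ann, all_ann) {
  m <- ann$mentions
  mine <- m[m$entity_id == entity, ]
  tf_v <- nrow(mine)
  # collection stats by full recount
  n_art <- length(all_ann)
  df_v <- sum(vapply(all_ann, function(a) entity %in% a$mentions$entity_id,
                     logical(1)))
  c_v <- sum(vapply(all_ann, function(a) sum(a$mentions$entity_id == entity),
                    numeric(1)))
  idf_v <- log2((n_art + 1) / (df_v + 1))
  se <- unique(mine$sentence[!is.na(mine$sentence)])
  cooc_v <- 0
  for (x in setdiff(unique(m$entity_id), entity)) {
    sx <- unique(m$sentence[m$entity_id == x & !is.na(m$sentence)])
    if (length(se) > 0) cooc_v <- cooc_v + length(intersect(se, sx)) / length(se)
  }
  ns <- ann$segmented$n_sentences
  ax <- vapply(1:3, function(X)
    as.integer(length(se) > 0 && any(se < X | se >= ns - X)), integer(1))
  list(tf = tf_v, idf = idf_v, cooc = cooc_v,
       avg_tf = if (df_v > 0) c_v / df_v else NA_real_,
       title = as.integer(any(mine$in_title)),
       abstract_1 = ax[1], abstract_2 = ax[2], abstract_3 = ax[3])
}

# tiny pharmacology-flavoured lexicon used across recognition tests
tiny_lexicon <- function() {
  caerank::lexicon(
    entity_id = c("D003042", "D004298", "C016287", "23411", "D006966"),
    entity_type = c("chemical", "chemical", "chemical", "gene", "disease"),
    official_names = list("cocaine", "dopamine", "lisuride", "SIRT1",
                          "hyperprolactinaemia"),
    synonyms = list(character(), character(), "2-bromolisuride",
                    c("sirtuin 1"), character()))
}

# a ranked list object without going through a scorer
ranked_fixture <- function(ids, article_id = "a1") {
  tibble::tibble(article_id = article_id, entity_id = ids,
                 score = rev(seq_along(ids)), rank = seq_along(ids))
}

# small deterministic annotated corpus for indicator tests
fixture_sim <- function(seed = 101, n_articles = 20, ...) {
  cfg <- caerank::sim_config(n_articles = n_articles, vocab_size = 40,
                             seed = seed, ...)
  sim <- caerank::generate_corpus(cfg)
  ann <- caerank::annotate_corpus(sim$corpus, sim$lexicon, sim$gold)
  list(sim = sim, ann = ann,
       stats = caerank::compute_corpus_stats(ann))
}
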