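#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the statistical structure that separates
#' conclusive association entities (CAEs) from other candidates in curated
#' corpora: CAEs are mentioned somewhat more often (frequency), appear more
#' often in titles and boundary sentences (locality), and a pool of "focal"
#' entities -- the entities articles tend to conclude about -- concentrate
#' their occurrences in the articles mentioning them (concentration,
#' driving AvgTF). Entity popularity across articles is Zipf-distributed,
#' giving a realistic document-frequency (and hence IDF) spread.
#'
#' @param n_articles Number of articles.
#' @param vocab_size Number of lexicon entities.
#' @param candidates_per_article Integer range (min, max) of candidate
#'   entities per article.
#' @param caes_per_article Integer range of CAEs per article.
#' @param tf_rate_cae,tf_rate_noncae Poisson rates; a mention count is
#'   1 + Poisson(rate), so every candidate appears at least once.
#' @param p_title_cae,p_title_noncae Probability that a given mention is
#'   placed in the title.
#' @param p_boundary_cae,p_boundary_noncae Probability that an abstract
#'   mention lands in the first or last sentence.
#' @param concentration_boost Multiplier on the mention counts of focal
#'   entities (>= 1); raises their micro-average TF corpus-wide.
#' @param focal_fraction Fraction of the vocabulary designated focal.
#' @param p_cae_focal Probability that a CAE slot is filled from the focal
#'   candidates of the article when one is available.
#' @param df_zipf_exponent Zipf exponent for entity popularity.
#' @param sentences_per_abstract Integer range of abstract sentences.
#' @param year_range Publication year range (inclusive).
#' @param p_abbrev Probability that an article introduces an author-defined
#'   parenthesised abbreviation for one of its entities.
#' @param p_synonym_use Probability a mention is rendered with the synonym
#'   rather than the official name.
#' @param ambiguity Fraction of entities paired up to share a synonym
#'   (exercises ambiguous-surface handling); 0 disables.
#' @param seed Mandatory generation seed.
#' @return A validated `cae_sim_config` list.
#' @export
sim_config <- function(n_articles = 300L,
                       vocab_size = 200L,
                       candidates_per_article = c(4L, 10L),
                       caes_per_article = c(1L, 3L),
                       tf_rate_cae = 1.0,
                       tf_rate_noncae = 0.5,
                       p_title_cae = 0.35,
                       p_title_noncae = 0.15,
                       p_boundary_cae = 0.45,
                       p_boundary_noncae = 0.3,
                       concentration_boost = 3,
                       focal_fraction = 0.25,
                       p_cae_focal = 0.8,
                       df_zipf_exponent = 1.0,
                       sentences_per_abstract = c(5L, 10L),
                       year_range = c(2005L, 2016L),
                       p_abbrev = 0.2,
                       p_synonym_use = 0.3,
                       ambiguity = 0,
                       seed) {
  if (missing(seed)) stop("sim_config requires a seed", call. = FALSE)
  cfg <- list(n_articles = as.integer(n_articles),
              vocab_size = as.integer(vocab_size),
              candidates_per_article = as.integer(candidates_per_article),
              caes_per_article = as.integer(caes_per_article),
              tf_rate_cae = tf_rate_cae, tf_rate_noncae = tf_rate_noncae,
              p_title_cae = p_title_cae, p_title_noncae = p_title_noncae,
              p_boundary_cae = p_boundary_cae,
              p_boundary_noncae = p_boundary_noncae,
              concentration_boost = concentration_boost,
              focal_fraction = focal_fraction, p_cae_focal = p_cae_focal,
              df_zipf_exponent = df_zipf_exponent,
              sentences_per_abstract = as.integer(sentences_per_abstract),
              year_range = as.integer(year_range),
              p_abbrev = p_abbrev, p_synonym_use = p_synonym_use,
              ambiguity = ambiguity, seed = as.integer(seed))
  probs <- c(cfg$p_title_cae, cfg$p_title_noncae, cfg$p_boundary_cae,
             cfg$p_boundary_noncae, cfg$p_cae_focal, cfg$p_abbrev,
             cfg$p_synonym_use, cfg$ambiguity, cfg$focal_fraction)
  stopifnot(all(probs >= 0), all(probs <= 1),
            cfg$tf_rate_cae > 0, cfg$tf_rate_noncae > 0,
            cfg$concentration_boost >= 1,
            cfg$n_articles >= 1, cfg$vocab_size >= 2,
            length(cfg$candidates_per_article) == 2L,
            length(cfg$caes_per_article) == 2L,
            diff(cfg$candidates_per_article) >= 0,
            diff(cfg$caes_per_article) >= 0,
            cfg$caes_per_article[1] >= 1L,
            cfg$candidates_per_article[1] >= 1L,
            diff(cfg$sentences_per_abstract) >= 0,
            cfg$sentences_per_abstract[1] >= 2L)
  if (cfg$caes_per_article[1] > cfg$candidates_per_article[1]) {
    stop("caes_per_article exceeds candidates_per_article", call. = FALSE)
  }
  if (cfg$candidates_per_article[2] > cfg$vocab_size) {
    stop("candidates_per_article exceeds vocab_size", call. = FALSE)
  }
  structure(cfg, class = "cae_sim_config")
}

# filler vocabulary; never collides with entity surface forms
.filler_words <- paste0("flw", sprintf("%02d", 1:60))

#' Generate a synthetic corpus, lexicon and gold standard
#'
#' Draws articles per [sim_config()]: candidates are sampled with Zipf
#' popularity, CAEs drawn per article (preferring focal entities), mention
#' counts 1 + Poisson with class-specific rates (focal counts multiplied by
#' the concentration boost), and each mention placed in the title, a
#' boundary sentence or a middle sentence with class-specific
#' probabilities. Some articles introduce a parenthesised author
#' abbreviation on the first abstract mention of an entity and use the
#' short form afterwards, exercising abbreviation resolution end to end.
#' Fully reproducible from the config seed.
#'
#' @param cfg A `cae_sim_config`.
#' @return List: `corpus` (`cae_corpus`), `lexicon` (`cae_lexicon`), `gold`
#'   (`cae_gold`), `truth` (per-article CAE/candidate sets, focal ids, the
#'   drawn mention counts).
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "cae_sim_config"))
  with_seed(cfg$seed, generate_corpus_impl(cfg))
}

generate_corpus_impl <- function(cfg) {
  v <- cfg$vocab_size
  ids <- sprintf("E%05d", seq_len(v))
  types <- rep(c("gene", "disease", "chemical"), length.out = v)
  official <- paste0("entq", seq_len(v), "x")
  synonyms <- as.list(paste0("synq", seq_len(v), "x"))
  if (cfg$ambiguity > 0) {
    n_pairs <- floor(cfg$ambiguity * v / 2)
    if (n_pairs >= 1) {
      pick <- sample(v, 2L * n_pairs)
      for (p in seq_len(n_pairs)) {
        shared <- paste0("shsyn", p, "x")
        i1 <- pick[2L * p - 1L]; i2 <- pick[2L * p]
        synonyms[[i1]] <- c(synonyms[[i1]], shared)
        synonyms[[i2]] <- c(synonyms[[i2]], shared)
      }
    }
  }
  lex <- lexicon(ids, types, as.list(official), synonyms)
  abbrevs <- paste0("ZQ", seq_len(v))  # author short forms, not in lexicon

  focal <- sort(sample(v, max(1L, round(cfg$focal_fraction * v))))
  zipf_w <- (seq_len(v))^(-cfg$df_zipf_exponent)
  # popularity rank is independent of entity index (focal spread evenly)
  pop_order <- sample(v)
  zipf_w <- zipf_w[order(pop_order)]

  n <- cfg$n_articles
  art_title <- character(n); art_abs <- character(n)
  art_year <- integer(n)
  art_ids <- as.character(seq(1000001L, length.out = n))
  gold <- list(); truth_cand <- list(); truth_counts <- list()

  for (ai in seq_len(n)) {
    n_cand <- sample(cfg$candidates_per_article[1]:cfg$candidates_per_article[2], 1L)
    cand <- sample(v, n_cand, prob = zipf_w)
    k_max <- min(sample(cfg$caes_per_article[1]:cfg$caes_per_article[2], 1L),
                 n_cand)
    # fill CAE slots, preferring focal candidates
    cae <- integer()
    pool <- cand
    for (s in seq_len(k_max)) {
      pf <- intersect(pool, focal)
      pick_focal <- length(pf) > 0 && runif(1) < cfg$p_cae_focal
      from <- if (pick_focal) pf else pool
      ch <- if (length(from) == 1L) from else sample(from, 1L)
      cae <- c(cae, ch)
      pool <- setdiff(pool, ch)
    }
    n_sent <- sample(cfg$sentences_per_abstract[1]:cfg$sentences_per_abstract[2], 1L)
    sent_tokens <- rep(list(character()), n_sent)
    title_tokens <- character()

    # article-level abbreviation: one entity may get an author short form
    abbrev_ent <- if (runif(1) < cfg$p_abbrev) cand[sample(length(cand), 1L)]
                  else NA_integer_

    counts <- integer(length(cand))
    for (ci in seq_along(cand)) {
      e <- cand[ci]
      is_cae <- e %in% cae
      rate <- if (is_cae) cfg$tf_rate_cae else cfg$tf_rate_noncae
      cnt <- 1L + rpois(1L, rate)
      if (e %in% focal) cnt <- as.integer(ceiling(cnt * cfg$concentration_boost))
      counts[ci] <- cnt
      p_title <- if (is_cae) cfg$p_title_cae else cfg$p_title_noncae
      p_bound <- if (is_cae) cfg$p_boundary_cae else cfg$p_boundary_noncae
      use_abbrev <- identical(e, abbrev_ent)
      first_abstract_mention <- TRUE
      for (mi in seq_len(cnt)) {
        surf <- if (runif(1) < cfg$p_synonym_use) synonyms[[e]][1]
                else official[e]
        if (runif(1) < p_title) {
          title_tokens <- c(title_tokens, surf)
        } else {
          si <- if (runif(1) < p_bound) {
            if (runif(1) < 0.5) 1L else n_sent
          } else {
            sample(n_sent, 1L)
          }
          if (use_abbrev) {
            if (first_abstract_mention) {
              surf <- paste0(surf, " (", abbrevs[e], ")")
              first_abstract_mention <- FALSE
            } else {
              surf <- abbrevs[e]
            }
          }
          sent_tokens[[si]] <- c(sent_tokens[[si]], surf)
        }
      }
    }

    # pad with filler words and render
    render_sentence <- function(toks) {
      pad <- sample(.filler_words, sample(4:8, 1L), replace = TRUE)
      all_t <- sample(c(toks, pad))
      all_t[1] <- paste0(toupper(substring(all_t[1], 1, 1)),
                         substring(all_t[1], 2))
      paste(all_t, collapse = " ")
    }
    sents <- vapply(sent_tokens, render_sentence, character(1))
    art_abs[ai] <- paste0(paste(sents, collapse = ". "), ".")
    ttl <- c(title_tokens, sample(.filler_words, 3L, replace = TRUE))
    ttl <- sample(ttl)
    ttl[1] <- paste0(toupper(substring(ttl[1], 1, 1)), substring(ttl[1], 2))
    art_title[ai] <- paste(ttl, collapse = " ")
    art_year[ai] <- sample(cfg$year_range[1]:cfg$year_range[2], 1L)

    gold[[art_ids[ai]]] <- sort(ids[cae])
    truth_cand[[art_ids[ai]]] <- sort(ids[cand])
    truth_counts[[art_ids[ai]]] <- setNames(counts, ids[cand])
  }

  corp <- corpus(art_ids, art_title, art_abs, art_year,
                 provenance = sprintf("synthetic(seed=%d)", cfg$seed))
  list(corpus = corp, lexicon = lex,
       gold = structure(gold, class = "cae_gold"),
       truth = list(cae_sets = gold, candidate_sets = truth_cand,
                    mention_counts = truth_counts,
                    focal_ids = ids[focal], config = cfg))
}

#' Write a generated corpus to a run directory
#'
#' Emits `articles.jsonl`, `lexicon.tsv`, `gold.txt` and `manifest.json`
#' (config and seed) in the pipeline's canonical formats.
#'
#' @param sim Result of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_corpus <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_articles(sim$corpus, file.path(dir, "articles.jsonl"))
  write_lexicon(sim$lexicon, file.path(dir, "lexicon.tsv"))
  write_gold(sim$gold, file.path(dir, "gold.txt"))
  jsonlite::write_json(
    list(config = unclass(sim$truth$config),
         n_articles = nrow(sim$corpus),
         files = c("articles.jsonl", "lexicon.tsv", "gold.txt")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Analytic random-baseline top-X hit rate
#'
#' Under a uniformly random ranking of n candidates of which k are CAEs,
#' the chance that at least one CAE lands in the top X is
#' `1 - C(n-k, X) / C(n, X)` (1 when X > n - k). Returns the mean over
#' articles, in percent -- the expected %P\@X>0 of the random baseline.
#'
#' @param n_candidates Integer vector, candidates per article.
#' @param n_caes Integer vector, CAEs among those candidates.
#' @param X Top-list size.
#' @return Percentage in [0, 100].
#' @export
expected_random_pct_p_at_x <- function(n_candidates, n_caes, X) {
  stopifnot(length(n_candidates) == length(n_caes), X >= 1L,
            all(n_caes >= 1L), all(n_caes <= n_candidates))
  p <- mapply(function(n, k) {
    if (X > n - k) return(1)
    1 - choose(n - k, X) / choose(n, X)
  }, n_candidates, n_caes)
  100 * mean(p)
}

#' Per-article candidate and CAE counts of an annotated corpus
#'
#' Convenience extractor feeding [expected_random_pct_p_at_x()]: counts,
#' per article, the candidates and how many of them are gold CAEs. Articles
#' with no gold CAE among candidates are dropped (they cannot be evaluated).
#'
#' @param annotated A `cae_annotated_corpus`.
#' @param gold A `cae_gold`.
#' @return Tibble: `article_id`, `n_candidates`, `n_caes`.
#' @export
candidate_counts <- function(annotated, gold) {
  rows <- lapply(names(annotated), function(aid) {
    k <- length(intersect(annotated[[aid]]$candidates,
                          gold[[aid]] %||% character()))
    if (k == 0L) return(NULL)
    tibble::tibble(article_id = aid,
                   n_candidates = length(annotated[[aid]]$candidates),
                   n_caes = k)
  })
  dplyr::bind_rows(Filter(Negate(is.null), rows))
}
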