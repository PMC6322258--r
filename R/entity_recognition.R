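#' Tokenize text into alphanumeric tokens
#'
#' Tokens are maximal alphanumeric runs, with internal hyphens kept so that
#' chemical names like "2-bromolisuride" stay one token. Punctuation
#' delimits and is dropped.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  m <- gregexpr("[A-Za-z0-9]+(?:-[A-Za-z0-9]+)*", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character())
  regmatches(text, list(m))[[1]]
}

# words that commonly precede an abbreviating period mid-sentence
.abbrev_guards <- c("e.g", "i.e", "al", "fig", "figs", "ref", "refs", "vs",
                    "cf", "dr", "mr", "mrs", "ms", "st", "approx", "ca",
                    "resp", "spp", "subsp", "var", "no", "nr", "vol")

#' Split an abstract into sentences
#'
#' Rule-based splitter: a run of `.`, `?` or `!` followed by whitespace and
#' an uppercase letter or digit ends a sentence, unless the period belongs
#' to a decimal number, a single-letter initial, or a common abbreviation
#' ("e.g.", "et al.", "Fig." and the like).
#'
#' @param text Abstract text (may be empty).
#' @return Character vector of sentences in textual order; `character(0)`
#'   for empty input.
#' @export
split_sentences <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  m <- gregexpr("[.?!]+(?=\\s)", text, perl = TRUE)[[1]]
  cuts <- integer()
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in ends) {
      rest <- substring(text, e + 1L)
      nxt <- sub("^\\s*", "", rest)
      if (!nzchar(nxt) || !grepl("^[A-Z0-9]", nxt)) next
      # token immediately before the terminator
      before <- substring(text, 1L, e - 1L)
      last <- sub("^.*?([A-Za-z0-9.]*)$", "\\1", before)
      low <- tolower(sub("\\.$", "", last))
      if (low %in% .abbrev_guards) next
      if (grepl("^[A-Z]$", last)) next        # initials: "J. Smith"
      cuts <- c(cuts, e)
    }
  }
  starts <- c(1L, cuts + 1L)
  stops <- c(cuts, nchar(text))
  sents <- trimws(substring(text, starts, stops))
  sents[nzchar(sents)]
}

#' Segment an article into title tokens and abstract sentences
#'
#' @param article_id Article identifier.
#' @param title,abstract Raw texts.
#' @return A `cae_segmented` list: `article_id`, `title`, `title_tokens`,
#'   `sentence_texts`, `sentence_tokens` (list of token vectors, abstract
#'   only -- the title is not an abstract sentence), `n_sentences`, and
#'   `token_count` (title tokens plus all sentence tokens, the article
#'   length |a|).
#' @export
segment_article <- function(article_id, title, abstract) {
  sent_texts <- split_sentences(abstract)
  sent_tokens <- lapply(sent_texts, tokenize)
  ttl_tokens <- tokenize(title)
  structure(list(
    article_id = article_id,
    title = title,
    title_tokens = ttl_tokens,
    sentence_texts = sent_texts,
    sentence_tokens = sent_tokens,
    n_sentences = length(sent_texts),
    token_count = length(ttl_tokens) + sum(lengths(sent_tokens))
  ), class = "cae_segmented")
}

# --- lexicon surface index ----------------------------------------------
#
# Matching is case-insensitive for ordinary names but case-sensitive for
# short all-uppercase symbols (<= 4 chars), the usual dictionary-matching
# compromise that keeps gene symbols like "WAS" or "CAT" from firing on
# common words. Keys: "cs:<form>" for case-sensitive symbols,
# "ci:<lowercased tokens>" otherwise.

surface_key <- function(toks) {
  if (length(toks) == 1L && nchar(toks) <= 4L &&
      grepl("^[A-Z0-9-]+$", toks) && grepl("[A-Z]", toks)) {
    paste0("cs:", toks)
  } else {
    paste0("ci:", paste(tolower(toks), collapse = " "))
  }
}

# text-side lookup keys for an n-gram of tokens
query_keys <- function(toks) {
  keys <- paste0("ci:", paste(tolower(toks), collapse = " "))
  if (length(toks) == 1L && nchar(toks) <= 4L &&
      grepl("^[A-Z0-9-]+$", toks) && grepl("[A-Z]", toks)) {
    keys <- c(paste0("cs:", toks), keys)
  }
  keys
}

build_surface_index <- function(lex, field) {
  env <- new.env(parent = emptyenv(), size = max(64L, nrow(lex) * 2L))
  max_len <- 1L
  forms <- lex[[field]]
  for (i in seq_len(nrow(lex))) {
    id <- lex$entity_id[i]
    for (f in forms[[i]]) {
      toks <- tokenize(f)
      if (length(toks) == 0L) next
      max_len <- max(max_len, length(toks))
      key <- surface_key(toks)
      env[[key]] <- unique(c(env[[key]], id))
    }
  }
  list(env = env, max_len = max_len)
}

lexicon_index <- function(lex) {
  idx <- attr(lex, "surface_index")
  if (is.null(idx)) {
    idx <- list(official = build_surface_index(lex, "official_names"),
                synonym = build_surface_index(lex, "synonyms"))
  }
  idx
}

#' Pre-compute the surface-form index of a lexicon
#'
#' Annotation builds this index on the fly; attaching it once with this
#' function avoids rebuilding it per corpus.
#'
#' @param lex A `cae_lexicon`.
#' @return The lexicon with its surface index cached in an attribute.
#' @export
index_lexicon <- function(lex) {
  attr(lex, "surface_index") <- lexicon_index(lex)
  lex
}

all_surface_keys <- function(idx) {
  c(ls(idx$official$env), ls(idx$synonym$env))
}

#' Detect author-defined abbreviations
#'
#' Authors often introduce their own short forms in parentheses, e.g.
#' "dopamine (DA)". When the tokens immediately preceding a parenthesised
#' short form match a lexicon surface form, the short form is mapped to that
#' entity for the rest of the article. Short forms that are themselves
#' lexicon surface forms are left to ordinary matching; the first definition
#' of a short form wins.
#'
#' @param segmented A `cae_segmented` article.
#' @param lex A `cae_lexicon`.
#' @return Named character vector: short form -> entity_id (possibly
#'   empty), with attribute `defining` locating each defining occurrence
#'   (segment 1 = title, then abstract sentences; token index within the
#'   segment). The defining occurrence sits right next to the long form it
#'   abbreviates and is not counted as a separate mention downstream.
#' @export
detect_abbreviations <- function(segmented, lex) {
  idx <- lexicon_index(lex)
  known <- all_surface_keys(idx)
  tbl <- character()
  def_seg <- integer(); def_tok <- integer()
  segs <- c(segmented$title, segmented$sentence_texts)
  for (sgi in seq_along(segs)) {
    txt <- segs[[sgi]]
    m <- gregexpr("\\(\\s*([A-Za-z0-9][A-Za-z0-9-]{0,9})\\s*\\)", txt, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (j in seq_along(starts)) {
      short <- gsub("[()\\s]", "", substring(txt, starts[j], starts[j] + lens[j] - 1L),
                    perl = TRUE)
      if (!nzchar(short)) next
      if (!is.null(tbl[short]) && !is.na(tbl[short])) next  # first wins
      if (any(query_keys(short) %in% known)) next            # lexicon owns it
      pre_toks <- tokenize(substring(txt, 1L, starts[j] - 1L))
      if (length(pre_toks) == 0L) next
      max_len <- max(idx$official$max_len, idx$synonym$max_len)
      hit <- NULL
      for (len in seq(min(max_len, length(pre_toks)), 1L)) {
        span <- pre_toks[(length(pre_toks) - len + 1L):length(pre_toks)]
        keys <- query_keys(span)
        ids <- unique(c(
          unlist(lapply(keys, function(k) idx$official$env[[k]])),
          unlist(lapply(keys, function(k) idx$synonym$env[[k]]))
        ))
        if (length(ids)) { hit <- ids[order(ids)][1]; break }
      }
      if (!is.null(hit)) {
        tbl[short] <- hit
        def_seg <- c(def_seg, sgi)
        def_tok <- c(def_tok, length(pre_toks) + 1L)
      }
    }
  }
  attr(tbl, "defining") <- data.frame(segment = def_seg, token = def_tok)
  tbl
}

# scan one segment (vector of tokens) for surfaces in `lookup`, a function
# (token span) -> entity ids or NULL. Longest match first, left to right; a
# token consumed by a mention is unavailable to later passes.
scan_segment <- function(tokens, consumed, max_len, lookup) {
  hits <- list()
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    if (consumed[i]) { i <- i + 1L; next }
    matched <- FALSE
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      jj <- i:(i + len - 1L)
      if (any(consumed[jj])) next
      ids <- lookup(tokens[jj])
      if (!is.null(ids) && length(ids)) {
        hits[[length(hits) + 1L]] <- list(
          ids = ids, surface = paste(tokens[jj], collapse = " "),
          offset = i, length = len)
        consumed[jj] <- TRUE
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  list(hits = hits, consumed = consumed)
}

#' Detect candidate entities in a segmented article
#'
#' Dictionary-based matching in three passes, gold-first: (1) all surface
#' forms (official names and synonyms) of `priority_ids`, whose presence has
#' already been confirmed by curators; (2) official names and symbols of
#' every entity; (3) synonyms of entities not yet seen in the article.
#' Author-defined abbreviations detected in the article are matched after
#' pass 1. Matches are longest-first, left to right; a token span feeds at
#' most one mention per entity, so downstream term frequencies are not
#' double-counted. A surface form owned by several entities yields a mention
#' for each owner unless one owner is a priority id.
#'
#' @param segmented A `cae_segmented` article.
#' @param lex A `cae_lexicon`.
#' @param priority_ids Character vector of entity ids to match first
#'   (typically the article's gold CAEs); may be empty.
#' @return A `cae_annotated` list: `article_id`, `segmented`, `mentions`
#'   (tibble: `entity_id`, `surface`, `in_title`, `sentence` 0-based or
#'   `NA`, `token_offset` 1-based), `candidates` (sorted entity ids) and
#'   `no_candidates` flag.
#' @export
match_entities <- function(segmented, lex, priority_ids = character()) {
  idx <- lexicon_index(lex)
  abbrev <- detect_abbreviations(segmented, lex)
  segs <- c(list(segmented$title_tokens), segmented$sentence_tokens)
  consumed <- lapply(segs, function(t) rep(FALSE, length(t)))
  mentions <- list()

  add_hits <- function(hits, seg_i) {
    for (h in hits) {
      for (id in h$ids) {
        mentions[[length(mentions) + 1L]] <<- list(
          entity_id = id, surface = h$surface,
          in_title = seg_i == 1L,
          sentence = if (seg_i == 1L) NA_integer_ else seg_i - 2L,
          token_offset = h$offset)
      }
    }
  }

  run_pass <- function(lookup, max_len) {
    for (s in seq_along(segs)) {
      if (length(segs[[s]]) == 0L) next
      res <- scan_segment(segs[[s]], consumed[[s]], max_len, lookup)
      consumed[[s]] <<- res$consumed
      add_hits(res$hits, s)
    }
  }

  prio <- as.character(priority_ids)
  restrict <- function(ids) {
    ids <- sort(unique(ids))
    hitp <- intersect(ids, prio)
    if (length(hitp)) hitp else ids
  }

  # pass 1: surfaces of priority entities only
  if (length(prio)) {
    run_pass(function(toks) {
      ids <- unique(c(
        unlist(lapply(query_keys(toks), function(k) idx$official$env[[k]])),
        unlist(lapply(query_keys(toks), function(k) idx$synonym$env[[k]]))
      ))
      ids <- intersect(ids, prio)
      if (length(ids)) sort(ids) else NULL
    }, max(idx$official$max_len, idx$synonym$max_len))
  }

  # abbreviation pass: exact token equality with detected short forms; the
  # defining occurrence (the parenthesised token next to its long form) is
  # consumed without a mention so TF is not inflated by the definition
  if (length(abbrev)) {
    def <- attr(abbrev, "defining")
    if (!is.null(def)) {
      for (r in seq_len(nrow(def))) {
        sgi <- def$segment[r]; tk <- def$token[r]
        if (sgi <= length(consumed) && tk <= length(consumed[[sgi]])) {
          consumed[[sgi]][tk] <- TRUE
        }
      }
    }
    run_pass(function(toks) {
      if (length(toks) != 1L) return(NULL)
      id <- abbrev[toks]
      if (is.na(id)) NULL else unname(id)
    }, 1L)
  }

  # pass 2: official names of all entities
  run_pass(function(toks) {
    ids <- unique(unlist(lapply(query_keys(toks),
                                function(k) idx$official$env[[k]])))
    if (length(ids)) restrict(ids) else NULL
  }, idx$official$max_len)

  # pass 3: synonyms of entities not yet matched in this article
  seen <- unique(vapply(mentions, `[[`, character(1), "entity_id"))
  run_pass(function(toks) {
    ids <- unique(unlist(lapply(query_keys(toks),
                                function(k) idx$synonym$env[[k]])))
    ids <- setdiff(ids, seen)
    if (length(ids)) restrict(ids) else NULL
  }, idx$synonym$max_len)

  mt <- if (length(mentions)) {
    tibble::tibble(
      entity_id = vapply(mentions, `[[`, character(1), "entity_id"),
      surface = vapply(mentions, `[[`, character(1), "surface"),
      in_title = vapply(mentions, `[[`, logical(1), "in_title"),
      sentence = vapply(mentions, `[[`, integer(1), "sentence"),
      token_offset = vapply(mentions, `[[`, integer(1), "token_offset"))
  } else {
    tibble::tibble(entity_id = character(), surface = character(),
                   in_title = logical(), sentence = integer(),
                   token_offset = integer())
  }
  ord <- order(!mt$in_title, mt$sentence, mt$token_offset, mt$entity_id)
  mt <- mt[ord, ]
  structure(list(
    article_id = segmented$article_id,
    segmented = segmented,
    mentions = mt,
    candidates = sort(unique(mt$entity_id)),
    no_candidates = nrow(mt) == 0L
  ), class = "cae_annotated")
}

#' Annotate a whole corpus
#'
#' Segments every article and runs dictionary matching; when `gold` is
#' supplied, each article's curated CAEs are matched with priority
#' (gold-first mapping).
#'
#' @param corpus A `cae_corpus`.
#' @param lex A `cae_lexicon`.
#' @param gold Optional `cae_gold` supplying priority ids per article.
#' @return A `cae_annotated_corpus`: named list of `cae_annotated`, one per
#'   article, in corpus order; articles' `pub_year` carried in an attribute.
#' @export
annotate_corpus <- function(corpus, lex, gold = NULL) {
  lex <- index_lexicon(lex)
  out <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    seg <- segment_article(corpus$article_id[i], corpus$title[i],
                           corpus$abstract[i])
    prio <- if (!is.null(gold)) gold[[corpus$article_id[i]]] %||% character()
            else character()
    out[[i]] <- match_entities(seg, lex, priority_ids = prio)
  }
  names(out) <- corpus$article_id
  structure(out, pub_year = setNames(corpus$pub_year, corpus$article_id),
            class = "cae_annotated_corpus")
}

#' Serialize annotations as JSON-lines
#'
#' One record per article (`article_id`, candidate ids, mention tuples and
#' segment sizes), for caching between pipeline stages.
#'
#' @param annotated A `cae_annotated_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated <- function(annotated, path) {
  years <- attr(annotated, "pub_year")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (a in annotated) {
    rec <- list(
      article_id = a$article_id,
      pub_year = if (!is.na(years[[a$article_id]])) years[[a$article_id]],
      n_sentences = a$segmented$n_sentences,
      token_count = a$segmented$token_count,
      sentence_lengths = as.integer(lengths(a$segmented$sentence_tokens)),
      title_length = length(a$segmented$title_tokens),
      candidates = a$candidates,
      mentions = lapply(seq_len(nrow(a$mentions)), function(i) list(
        entity_id = a$mentions$entity_id[i],
        surface = a$mentions$surface[i],
        in_title = a$mentions$in_title[i],
        sentence = if (is.na(a$mentions$sentence[i])) NULL
                   else a$mentions$sentence[i],
        token_offset = a$mentions$token_offset[i]))
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Read cached annotations written by [write_annotated()]
#'
#' The raw texts are not stored; the reconstructed objects carry the segment
#' geometry (sentence counts, token counts) that all downstream indicator
#' computations need.
#'
#' @param path Path to the JSONL file.
#' @return A `cae_annotated_corpus`.
#' @export
read_annotated <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  years <- integer(length(lines))
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE)
    ms <- rec$mentions
    mt <- tibble::tibble(
      entity_id = vapply(ms, function(m) m$entity_id, character(1)),
      surface = vapply(ms, function(m) m$surface, character(1)),
      in_title = vapply(ms, function(m) isTRUE(m$in_title), logical(1)),
      sentence = vapply(ms, function(m) as.integer(m$sentence %||% NA), integer(1)),
      token_offset = vapply(ms, function(m) as.integer(m$token_offset), integer(1)))
    seg <- structure(list(
      article_id = rec$article_id, title = NULL,
      title_tokens = rep("", as.integer(rec$title_length)),
      sentence_texts = NULL,
      sentence_tokens = lapply(unlist(rec$sentence_lengths) %||% integer(),
                               function(n) rep("", n)),
      n_sentences = as.integer(rec$n_sentences),
      token_count = as.integer(rec$token_count)), class = "cae_segmented")
    out[[i]] <- structure(list(
      article_id = rec$article_id, segmented = seg, mentions = mt,
      candidates = as.character(unlist(rec$candidates) %||% character()),
      no_candidates = nrow(mt) == 0L), class = "cae_annotated")
    years[i] <- as.integer(rec$pub_year %||% NA)
  }
  names(out) <- vapply(out, `[[`, character(1), "article_id")
  structure(out, pub_year = setNames(years, names(out)),
            class = "cae_annotated_corpus")
}
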