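#' Read a corpus of article records
#'
#' Articles are title + abstract records, optionally carrying a publication
#' year used by the frequency-recency views. The canonical on-disk format is
#' JSON-lines with keys `id`, `title`, `abstract` and optional `year`;
#' MEDLINE-format files (PMID/TI/AB/DP fields) are read as a convenience.
#'
#' @param path Path to the article file.
#' @param format `"jsonl"` (default) or `"medline"`.
#' @param provenance Free-text label stored on the returned corpus.
#' @return A `cae_corpus`: a tibble with columns `article_id`, `title`,
#'   `abstract`, `pub_year` (integer, `NA` if absent), in file order.
#' @export
read_articles <- function(path, format = c("jsonl", "medline"),
                          provenance = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("article file not found: ", path, call. = FALSE)
  recs <- switch(format,
    jsonl   = parse_article_jsonl(path),
    medline = parse_article_medline(path)
  )
  new_corpus(recs, provenance)
}

parse_article_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) abort_line(
                      paste0("malformed JSON record: ", conditionMessage(e)), i))
    if (is.null(rec$id) || !nzchar(as.character(rec$id)[1])) {
      abort_line("article record lacks an 'id'", i)
    }
    title    <- as.character(rec$title %||% "")[1]
    abstract <- as.character(rec$abstract %||% "")[1]
    if (!nzchar(trimws(title)) && !nzchar(trimws(abstract))) {
      abort_line(sprintf("article '%s' has neither title nor abstract",
                         as.character(rec$id)[1]), i)
    }
    year <- rec$year %||% NA
    out[[i]] <- list(article_id = as.character(rec$id)[1],
                     title = title, abstract = abstract,
                     pub_year = suppressWarnings(as.integer(year)))
  }
  out
}

# Best-effort MEDLINE reader: PMID, TI, AB, DP tags with 6-space
# continuation lines; records separated by blank lines or the next PMID.
parse_article_medline <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  recs <- list()
  cur <- NULL
  field <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$PMID)) return(NULL)
    year <- NA_integer_
    if (!is.null(cur$DP)) {
      m <- regmatches(cur$DP, regexpr("[0-9]{4}", cur$DP))
      if (length(m)) year <- as.integer(m)
    }
    list(article_id = trimws(cur$PMID),
         title = squish(cur$TI %||% ""),
         abstract = squish(cur$AB %||% ""),
         pub_year = year)
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      r <- flush(cur); if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      cur <- NULL; field <- NULL
      next
    }
    if (grepl("^[A-Z]{1,4}\\s*-", ln)) {
      tag <- sub("^([A-Z]{1,4}).*$", "\\1", ln)
      val <- sub("^[A-Z]{1,4}\\s*-\\s*", "", ln)
      if (tag == "PMID" && !is.null(cur) && !is.null(cur$PMID)) {
        r <- flush(cur); if (!is.null(r)) recs[[length(recs) + 1L]] <- r
        cur <- NULL
      }
      if (is.null(cur)) cur <- list()
      cur[[tag]] <- val
      field <- tag
    } else if (grepl("^\\s{2,}", ln) && !is.null(field)) {
      cur[[field]] <- paste(cur[[field]], trimws(ln))
    }
  }
  r <- flush(cur); if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  keep <- vapply(recs, function(r) nzchar(r$title) || nzchar(r$abstract), logical(1))
  recs[keep]
}

new_corpus <- function(recs, provenance = "") {
  if (length(recs) == 0L) {
    out <- tibble::tibble(article_id = character(), title = character(),
                          abstract = character(), pub_year = integer())
  } else {
    out <- tibble::tibble(
      article_id = vapply(recs, `[[`, character(1), "article_id"),
      title      = vapply(recs, `[[`, character(1), "title"),
      abstract   = vapply(recs, `[[`, character(1), "abstract"),
      pub_year   = vapply(recs, function(r) r$pub_year %||% NA_integer_, integer(1))
    )
  }
  dup <- out$article_id[duplicated(out$article_id)]
  if (length(dup)) {
    stop("duplicate article id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  structure(out, provenance = provenance,
            class = c("cae_corpus", class(out)))
}

#' Construct a corpus from vectors (in-memory)
#'
#' @param article_id,title,abstract Character vectors of equal length.
#' @param pub_year Integer vector (`NA` allowed).
#' @param provenance Label recorded on the corpus.
#' @return A `cae_corpus` tibble.
#' @export
corpus <- function(article_id, title, abstract, pub_year = NA_integer_,
                   provenance = "in-memory") {
  n <- length(article_id)
  pub_year <- as.integer(rep_len(pub_year, n))
  recs <- lapply(seq_len(n), function(i) {
    list(article_id = as.character(article_id[i]), title = title[i],
         abstract = abstract[i], pub_year = pub_year[i])
  })
  new_corpus(recs, provenance)
}

#' Write a corpus as JSON-lines
#'
#' @param corpus A `cae_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_articles <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- list(id = corpus$article_id[i], title = corpus$title[i],
                abstract = corpus$abstract[i])
    if (!is.na(corpus$pub_year[i])) rec$year <- corpus$pub_year[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a CTD-style entity lexicon
#'
#' Tab-separated, four columns: `entity_id`, `entity_type` (one of `gene`,
#' `disease`, `chemical`), `official_names` and `synonyms`, the last two
#' `|`-separated lists (synonyms may be empty). A header row naming the
#' columns is tolerated. The same surface string may legitimately belong to
#' several entities; that ambiguity is preserved.
#'
#' @param path Path to the TSV file.
#' @return A `cae_lexicon`: tibble with columns `entity_id`, `entity_type`
#'   and list-columns `official_names`, `synonyms` (whitespace-normalised).
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^entity_id\\t", lines[[1]])) lines <- lines[-1]
  ids <- character(length(lines)); types <- character(length(lines))
  offs <- vector("list", length(lines)); syns <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    length(f) <- 4L
    f[is.na(f)] <- ""
    id <- trimws(f[1])
    if (!nzchar(id)) abort_line("blank entity_id", i)
    type <- trimws(f[2])
    if (!type %in% c("gene", "disease", "chemical")) {
      abort_line(sprintf("unknown entity_type '%s' for id %s", type, id), i)
    }
    split_forms <- function(s) {
      v <- squish(strsplit(s, "|", fixed = TRUE)[[1]])
      v[nzchar(v)]
    }
    ids[i] <- id; types[i] <- type
    offs[[i]] <- split_forms(f[3]); syns[[i]] <- split_forms(f[4])
    if (length(offs[[i]]) == 0L) {
      abort_line(sprintf("entity %s has no official name", id), i)
    }
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate entity id(s) in lexicon: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  new_lexicon(ids, types, offs, syns)
}

new_lexicon <- function(ids, types, official, synonyms) {
  out <- tibble::tibble(entity_id = as.character(ids),
                        entity_type = as.character(types),
                        official_names = official, synonyms = synonyms)
  structure(out, class = c("cae_lexicon", class(out)))
}

#' Construct a lexicon in memory
#'
#' @param entity_id,entity_type Character vectors.
#' @param official_names,synonyms Lists of character vectors (a bare
#'   character vector is treated as one name per entity).
#' @return A `cae_lexicon`.
#' @export
lexicon <- function(entity_id, entity_type, official_names, synonyms = NULL) {
  n <- length(entity_id)
  if (!is.list(official_names)) official_names <- as.list(official_names)
  if (is.null(synonyms)) synonyms <- rep(list(character()), n)
  if (!is.list(synonyms)) synonyms <- as.list(synonyms)
  stopifnot(length(official_names) == n, length(synonyms) == n,
            all(entity_type %in% c("gene", "disease", "chemical")))
  if (anyDuplicated(entity_id)) stop("duplicate entity id(s)", call. = FALSE)
  new_lexicon(entity_id, entity_type,
              lapply(official_names, squish), lapply(synonyms, squish))
}

#' Write a lexicon as TSV
#' @param lex A `cae_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  lines <- vapply(seq_len(nrow(lex)), function(i) {
    paste(lex$entity_id[i], lex$entity_type[i],
          paste(lex$official_names[[i]], collapse = "|"),
          paste(lex$synonyms[[i]], collapse = "|"), sep = "\t")
  }, character(1))
  writeLines(c("entity_id\tentity_type\tofficial_names\tsynonyms", lines),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read gold CAE annotations
#'
#' One line per article: the article id, whitespace, then the `|`-separated
#' entity ids of its curated conclusive association entities (CAEs).
#'
#' @param path Path to the annotation file.
#' @return A `cae_gold`: named list mapping article_id to a character vector
#'   of entity ids (each non-empty).
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("gold file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(parts) < 2L) {
      abort_line(sprintf("gold line for article '%s' lists no entity ids",
                         parts[1] %||% ""), i)
    }
    id <- parts[1]
    ents <- strsplit(paste(parts[-1], collapse = ""), "|", fixed = TRUE)[[1]]
    ents <- unique(ents[nzchar(ents)])
    if (length(ents) == 0L) abort_line("gold line lists no entity ids", i)
    if (!is.null(out[[id]])) abort_line(paste0("duplicate gold article id ", id), i)
    out[[id]] <- ents
  }
  structure(out, class = "cae_gold")
}

#' Write gold CAE annotations
#'
#' Entity ids are written sorted so that identical annotations always yield
#' byte-identical files.
#'
#' @param gold A `cae_gold` (or plain named list of character vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  if (length(gold) == 0L) stop("gold standard is empty", call. = FALSE)
  lines <- vapply(names(gold), function(id) {
    paste0(id, "\t", paste(sort(gold[[id]]), collapse = "|"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.cae_corpus <- function(x, ...) {
  cat(sprintf("<cae_corpus> %d articles (%s)\n", nrow(x),
              attr(x, "provenance") %||% ""))
  NextMethod()
}
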