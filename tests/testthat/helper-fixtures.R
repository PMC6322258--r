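# hand-built annotated articles with fully controlled entity placement;
# sentences is a list of character vectors of entity ids per sentence
make_ann <- function(article_id, title_ents = character(),
                     sentences = list(), n_filler = 5L) {
  ments <- list()
  for (e in title_ents) {
    ments[[length(ments) + 1L]] <- list(entity_id = e, in_title = TRUE,
                                        sentence = NA_integer_)
  }
  for (si in seq_along(sentences)) {
    for (e in sentences[[si]]) {
      ments[[length(ments) + 1L]] <- list(entity_id = e, in_title = FALSE,
                                          sentence = si - 1L)
    }
  }
  mt <- if (length(ments)) tibble::tibble(
    entity_id = vapply(ments, `[[`, character(1), "entity_id"),
    surface = vapply(ments, `[[`, character(1), "entity_id"),
    in_title = vapply(ments, `[[`, logical(1), "in_title"),
    sentence = vapply(ments, `[[`, integer(1), "sentence"),
    token_offset = seq_along(ments)
  ) else tibble::tibble(entity_id = character(), surface = character(),
                        in_title = logical(), sentence = integer(),
                        token_offset = integer())
  seg <- structure(list(article_id = article_id, title = "",
                        title_tokens = rep("w", length(title_ents) + 2L),
                        sentence_texts = rep("", length(sentences)),
                        sentence_tokens = lapply(sentences, function(s)
                          rep("w", length(s) + n_filler)),
                        n_sentences = length(sentences),
                        token_count = length(title_ents) + 2L +
                          sum(lengths(sentences)) + n_filler * length(sentences)),
                   class = "cae_segmented")
  structure(list(article_id = article_id, segmented = seg, mentions = mt,
                 candidates = sort(unique(mt$entity_id)),
                 no_candidates = nrow(mt) == 0L),
            class = "cae_annotated")
}

as_corpus <- function(anns) {
  ids <- vapply(anns, `[[`, character(1), "article_id")
  structure(setNames(anns, ids),
            pub_year = setNames(rep(NA_integer_, length(anns)), ids),
            class = "cae_annotated_corpus")
}
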