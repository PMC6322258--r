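test_that("sentence splitting honours terminators, decimals and abbreviations", {
  expect_equal(split_sentences("A b. C d."), c("A b.", "C d."))
  expect_equal(split_sentences(""), character())
  expect_equal(
    split_sentences("Rats received 2.5 mg/kg daily. Effects ceased."),
    c("Rats received 2.5 mg/kg daily.", "Effects ceased."))
  # guard words and initials do not split
  expect_length(split_sentences("Agonists (e.g. lisuride) were tested."), 1L)
  expect_length(split_sentences("Smith et al. Reported this effect."), 1L)
  expect_length(split_sentences("J. Smith reported it."), 1L)
  # question/exclamation marks split too
  expect_length(split_sentences("Does it work? It does! Final."), 3L)
})

test_that("concatenating split sentences reconstructs the abstract text", {
  texts <- c("One sentence only.",
             "First here. Second there. Third, with 3.5 mg. Fourth ends",
             "Numbers like 37 degrees C. 90 percent responded.")
  for (tx in texts) {
    s <- split_sentences(tx)
    expect_equal(gsub("\\s+", " ", paste(s, collapse = " ")),
                 gsub("\\s+", " ", trimws(tx)))
  }
})

test_that("tokenizer keeps hyphenated chemicals as one token", {
  expect_equal(tokenize("2-bromolisuride reduced binding"),
               c("2-bromolisuride", "reduced", "binding"))
  expect_equal(tokenize("(n = 12)"), c("n", "12"))
  expect_equal(tokenize(""), character())
})

test_that("author abbreviations resolve to the defining long form", {
  lex <- tiny_lexicon()
  seg <- segment_article("a1", "Lisuride and prolactin",
    "Rats received dopamine (DA) infusions. DA levels rose. A group (n = 12) served as control.")
  tbl <- detect_abbreviations(seg, lex)
  expect_equal(unname(tbl["DA"]), "D004298")
  expect_false("n" %in% names(tbl))   # (n = 12) has no lexicon long form

  # a short form that is itself a lexicon surface is not overridden
  lex2 <- lexicon(c("C016287", "X1"), c("chemical", "gene"),
                  list("lisuride", "LIS"), list(character(), character()))
  seg2 <- segment_article("a2", "", "Animals got lisuride (LIS) daily.")
  expect_false("LIS" %in% names(detect_abbreviations(seg2, lex2)))
})

test_that("dictionary matching locates every occurrence with its position", {
  lex <- lexicon("C016287", "chemical", list("lisuride"))
  seg <- segment_article("a1", "Lisuride effects",
    "Animals received lisuride (LIS) daily. Controls got saline. LIS reduced secretion.")
  ann <- match_entities(seg, lex)
  m <- ann$mentions[ann$mentions$entity_id == "C016287", ]
  # title, long form in sentence 0, author short form in sentence 2; the
  # defining "(LIS)" next to the long form is not a separate mention
  expect_equal(nrow(m), 3L)
  expect_true(any(m$in_title))
  expect_setequal(m$sentence[!m$in_title], c(0L, 2L))
  expect_equal(ann$candidates, "C016287")
})

test_that("priority ids are matched even when ordinary passes would miss them", {
  # surface appears only as a synonym shared with another entity; priority
  # resolution assigns it to the confirmed CAE alone
  lex <- lexicon(c("G1", "G2"), c("gene", "gene"),
                 list("alphaparin", "betaparin"),
                 list("parin shared", "parin shared"))
  seg <- segment_article("a1", "", "The parin shared complex was measured.")
  ann_plain <- match_entities(seg, lex)
  expect_setequal(ann_plain$candidates, c("G1", "G2"))  # ambiguous: both owners
  ann_prio <- match_entities(seg, lex, priority_ids = "G2")
  expect_equal(ann_prio$candidates, "G2")

  # gold CAE whose only surface form is present is always a candidate
  lex2 <- tiny_lexicon()
  seg2 <- segment_article("a2", "", "Severe hyperprolactinaemia was observed.")
  ann2 <- match_entities(seg2, lex2, priority_ids = "D006966")
  expect_true("D006966" %in% ann2$candidates)
})

test_that("short all-uppercase symbols match case-sensitively, names do not", {
  lex <- lexicon(c("G1", "D1"), c("gene", "disease"),
                 list("WAS", "anemia"), list(character(), character()))
  seg <- segment_article("a1", "", "The patient was anemic. WAS protein Anemia.")
  ann <- match_entities(seg, lex)
  m <- ann$mentions
  # lowercase "was" must not fire the gene symbol; uppercase "WAS" must
  expect_equal(sum(m$entity_id == "G1"), 1L)
  # "anemia"/"Anemia" match case-insensitively
  expect_equal(sum(m$entity_id == "D1"), 1L)
})

test_that("longest match wins and spans are not double-counted", {
  lex <- lexicon(c("D1", "D2"), c("disease", "disease"),
                 list("breast cancer", "cancer"), list(character(), character()))
  seg <- segment_article("a1", "", "Breast cancer incidence rose. Cancer rates too.")
  ann <- match_entities(seg, lex)
  expect_equal(sum(ann$mentions$entity_id == "D1"), 1L)
  expect_equal(sum(ann$mentions$entity_id == "D2"), 1L)  # only sentence 2
  expect_equal(ann$mentions$sentence[ann$mentions$entity_id == "D2"], 1L)
})

test_that("mention sets equal a brute-force scan over generated articles", {
  fx <- fixture_sim(seed = 7, n_articles = 15, p_abbrev = 0)
  lex <- fx$sim$lexicon
  official <- setNames(lex$official_names, lex$entity_id)
  synonyms <- setNames(lex$synonyms, lex$entity_id)
  # prediction-mode annotation (no priority ids), matching the oracle
  ann <- annotate_corpus(fx$sim$corpus, lex)
  for (aid in names(ann)[1:10]) {
    a <- ann[[aid]]
    segs <- c(list(a$segmented$title_tokens), a$segmented$sentence_tokens)
    oracle <- scan_oracle(segs, official, synonyms)
    expect_equal(sort(a$mentions$entity_id), sort(oracle), label = aid)
  }
})

test_that("annotation caching round-trips through JSONL", {
  fx <- fixture_sim(seed = 9, n_articles = 8)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_annotated(fx$ann, f)
  back <- read_annotated(f)
  expect_equal(names(back), names(fx$ann))
  for (aid in names(back)) {
    expect_equal(back[[aid]]$candidates, fx$ann[[aid]]$candidates)
    expect_equal(as.data.frame(back[[aid]]$mentions),
                 as.data.frame(fx$ann[[aid]]$mentions))
    expect_equal(back[[aid]]$segmented$token_count,
                 fx$ann[[aid]]$segmented$token_count)
  }
  # stats computed from cache equal stats from live annotation
  expect_equal(compute_corpus_stats(back), compute_corpus_stats(fx$ann))
})
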