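mk_rec <- function(id, abstract = "First point. Second point.",
                   language = "eng", keywords = character(),
                   year = 2001L) {
  medline_record(id, "A title.", abstract, year, keywords, language)
}

test_that("filtering keeps English records with a non-title sentence", {
  recs <- list(
    mk_rec("keep1"),
    mk_rec("keep2", keywords = character()),          # no keywords: kept
    mk_rec("drop_empty", abstract = ""),
    mk_rec("drop_lang", language = "fra"),
    mk_rec("keep3", abstract = "Single sentence only."))
  suppressMessages(out <- filter_records(recs))
  expect_identical(vapply(out, `[[`, "", "id"),
                   c("keep1", "keep2", "keep3"))
})

test_that("train/test split is deterministic, exhaustive and on-ratio", {
  recs <- lapply(sprintf("R%04d", 1:1000), mk_rec)
  sp1 <- split_train_test(recs, ratio = 0.7, seed = 13)
  sp2 <- split_train_test(recs, ratio = 0.7, seed = 13)
  expect_identical(vapply(sp1$train, `[[`, "", "id"),
                   vapply(sp2$train, `[[`, "", "id"))
  n_train <- length(sp1$train)
  expect_lte(abs(n_train - 700L), 10L)
  expect_identical(n_train + length(sp1$test), 1000L)
  expect_length(intersect(vapply(sp1$train, `[[`, "", "id"),
                          vapply(sp1$test, `[[`, "", "id")), 0L)
  sp3 <- split_train_test(recs, ratio = 0.7, seed = 14)
  expect_false(identical(vapply(sp1$train, `[[`, "", "id"),
                         vapply(sp3$train, `[[`, "", "id")))
  expect_error(split_train_test(list(), 0.7), "no records")
  expect_error(split_train_test(recs, 0), "strictly between")
})

test_that("condition index prunes rare keywords and counts years half-open", {
  recs <- c(lapply(1:10, function(i)
              mk_rec(paste0("a", i), keywords = "Alpha", year = 1999L)),
            lapply(1:9, function(i)
              mk_rec(paste0("b", i), keywords = "beta", year = 2005L)))
  ci <- build_condition_index(recs, min_count = 10L, cutoff_year = 2020L)
  expect_identical(names(ci$keywords), "alpha")
  expect_identical(ci$n_years, 2020L - 1999L)
  ci_all <- build_condition_index(recs, min_count = 1L,
                                  cutoff_year = 2020L)
  expect_identical(names(ci_all$keywords), c("alpha", "beta"))
  # keyword set is exactly the >= min_count set (recount oracle)
  counts <- table(tolower(unlist(lapply(recs, `[[`, "keywords"))))
  expect_setequal(names(ci$keywords), names(counts)[counts >= 10])
  # keyword and year indices disjoint and contiguous
  expect_identical(unname(ci_all$keywords),
                   ci_all$n_years + seq_along(ci_all$keywords))
})

test_that("year indices clamp at the range ends", {
  recs <- list(mk_rec("r1", year = 1990L), mk_rec("r2", year = 2010L))
  ci <- build_condition_index(recs, cutoff_year = 2020L)
  expect_identical(year_index(ci, 1990L), 1L)
  expect_identical(year_index(ci, 2019L), 30L)
  expect_identical(year_index(ci, 2035L), 30L)  # beyond cutoff: clamp
  expect_identical(year_index(ci, 1900L), 1L)   # before min: clamp
  ids <- condition_ids(ci, 2010L, c("unseen kw"))
  expect_identical(ids, year_index(ci, 2010L))
  expect_warning(condition_ids(ci, 2010L, "unseen kw", warn = TRUE),
                 "unindexed")
})

test_that("subwords inherit the labels of their covering word", {
  # word 'cisplatin' at chars 1..9 split into three subwords
  ann <- data.frame(start = c(1L, 11L), end = c(9L, 14L),
                    pos = c("NOUN", "VERB"), dep = c("nsubj", "ROOT"),
                    ent = c("simple_chemical", "not_an_entity"))
  lab <- align_labels(ann, starts = c(1L, 4L, 7L, 10L, 11L))
  expect_identical(lab$ent, c(rep("simple_chemical", 3),
                              "not_an_entity", "not_an_entity"))
  expect_identical(lab$pos, c(rep("NOUN", 3), "SPACE", "VERB"))
  expect_identical(lab$dep, c(rep("nsubj", 3), "dep", "ROOT"))
})

test_that("overlapping entity spans are rejected", {
  ann <- data.frame(start = c(1L, 3L), end = c(5L, 8L),
                    pos = "NOUN", dep = "nsubj",
                    ent = c("cancer", "organ"))
  expect_error(align_labels(ann, starts = 1L), "overlapping entity")
})

test_that("encoded documents have aligned tracks and sentence starts", {
  g <- synthetic_grammar(n_words = 30, n_keywords = 2, topic_size = 8,
                         seed = 2)
  recs <- sample_corpus(g, 5, seed = 6)
  v <- build_vocab(unlist(lapply(recs, function(r)
    split_sentences(paste(r$title, r$abstract)))), size = 60, seed = 1)
  ci <- build_condition_index(recs, min_count = 1L)
  for (r in recs) {
    doc <- encode_record(r, v, ci)
    n <- length(doc$tokens)
    expect_identical(length(doc$pos_ids), n)
    expect_identical(length(doc$dep_ids), n)
    expect_identical(length(doc$ent_ids), n)
    expect_identical(doc$tokens[1], v$bos_id)
    expect_identical(doc$tokens[n], v$eos_id)
    expect_identical(doc$sent_starts[1], 1L)
    expect_identical(length(doc$cond_ids), 1L + length(r$keywords))
    # sentence starts (beyond the start token) land on word-initial pieces
    txt <- tolower(paste(r$title, r$abstract))
    seg <- segment_text(txt, v)
    expect_true(all(doc$sent_starts <= n - 1L))
  }
})

test_that("windows start at sentence starts and shift all targets by one", {
  g <- synthetic_grammar(n_words = 30, n_keywords = 2, topic_size = 8,
                         seed = 2)
  recs <- sample_corpus(g, 6, seed = 7)
  v <- build_vocab(unlist(lapply(recs, function(r)
    split_sentences(paste(r$title, r$abstract)))), size = 60, seed = 1)
  ci <- build_condition_index(recs, min_count = 1L)
  for (r in recs) {
    doc <- encode_record(r, v, ci)
    for (s in 1:10) {
      w <- sample_window(doc, window = 32L, seed = s)
      n <- length(w$input_ids)
      expect_lte(n, 32L)
      start <- which(vapply(doc$sent_starts, function(st)
        identical(doc$tokens[st:(st + n - 1L)], w$input_ids),
        logical(1)))[1]
      expect_false(is.na(start))
      st <- doc$sent_starts[start]
      idx <- st:(st + n - 1L)
      expect_identical(w$token_targets, doc$tokens[idx + 1L])
      expect_identical(w$pos_targets, doc$pos_ids[idx + 1L])
      expect_identical(w$dep_targets, doc$dep_ids[idx + 1L])
      expect_identical(w$ent_targets, doc$ent_ids[idx + 1L])
    }
  }
})

test_that("short documents fit one window; tiny documents error", {
  doc <- structure(list(id = "d", tokens = c(1L, 6L, 7L, 8L, 2L),
                        pos_ids = rep(1L, 5), dep_ids = rep(1L, 5),
                        ent_ids = rep(1L, 5), sent_starts = c(1L, 3L),
                        cond_ids = 1L), class = "encoded_doc")
  w <- sample_window(doc, window = 128L, seed = 1)
  starts_seen <- unique(replicate(50, {
    w <- sample_window(doc, window = 128L)
    w$input_ids[1]
  }))
  expect_true(all(starts_seen %in% doc$tokens[c(1L, 3L)]))
  expect_identical(sample_window(doc, window = 128L, seed = 2)$token_targets,
                   doc$tokens[-1][seq_len(length(w$input_ids))] |>
                     utils::head(length(w$token_targets)))
  tiny <- doc; tiny$tokens <- 1L
  expect_error(sample_window(structure(list(tokens = 1L,
                                            sent_starts = 1L),
                                       class = "encoded_doc")),
               "fewer than 2")
})

test_that("window starts are uniform over eligible sentence starts", {
  doc <- structure(list(id = "d",
                        tokens = c(1L, rep(5:8, 5), 2L),
                        pos_ids = rep(1L, 22), dep_ids = rep(1L, 22),
                        ent_ids = rep(1L, 22),
                        sent_starts = c(1L, 8L, 15L), cond_ids = 1L),
                   class = "encoded_doc")
  with_seed_test(77, {
    starts <- replicate(10000, {
      # identify the start by matching window length (window truncates at
      # the document end, so each start yields a distinct length)
      length(sample_window(doc, window = 128L)$input_ids)
    })
  })
  counts <- table(starts)
  expect_identical(length(counts), 3L)
  p <- 1 / 3
  sigma <- sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - 10000 * p) < 3 * sigma))
})

test_that("JSON-lines records round-trip including annotations", {
  g <- synthetic_grammar(n_words = 24, n_keywords = 2, topic_size = 6,
                         seed = 4)
  recs <- sample_corpus(g, 4, seed = 9)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl_records(recs, path)
  back <- read_jsonl_records(path)
  expect_length(back, 4L)
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$id, recs[[i]]$id)
    expect_identical(back[[i]]$title, recs[[i]]$title)
    expect_identical(back[[i]]$abstract, recs[[i]]$abstract)
    expect_identical(back[[i]]$year, recs[[i]]$year)
    expect_identical(back[[i]]$keywords, recs[[i]]$keywords)
    expect_identical(back[[i]]$annotations$start,
                     recs[[i]]$annotations$start)
    expect_identical(back[[i]]$annotations$ent,
                     recs[[i]]$annotations$ent)
  }
})

test_that("MEDLINE XML maps into citation records", {
  xml <- '<?xml version="1.0"?>
<PubmedArticleSet>
 <PubmedArticle>
  <MedlineCitation>
   <PMID>123456</PMID>
   <Article>
    <Journal><JournalIssue><PubDate><Year>2017</Year></PubDate></JournalIssue></Journal>
    <ArticleTitle>Gene expression in tumors.</ArticleTitle>
    <Abstract><AbstractText>First part.</AbstractText>
      <AbstractText>Second part.</AbstractText></Abstract>
    <Language>eng</Language>
   </Article>
   <MeshHeadingList>
    <MeshHeading><DescriptorName>Neoplasms</DescriptorName></MeshHeading>
   </MeshHeadingList>
   <KeywordList><Keyword>RNA-seq</Keyword></KeywordList>
  </MedlineCitation>
 </PubmedArticle>
</PubmedArticleSet>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  recs <- read_medline_xml(path)
  expect_length(recs, 1L)
  r <- recs[[1]]
  expect_identical(r$id, "123456")
  expect_identical(r$year, 2017L)
  expect_identical(r$title, "Gene expression in tumors.")
  expect_identical(r$abstract, "First part. Second part.")
  expect_setequal(r$keywords, c("Neoplasms", "RNA-seq"))
  expect_identical(r$language, "eng")
})

test_that("sentence splitter honours the lookahead rule", {
  s <- split_sentences("Mean was 3.5 units. Next sentence here! Done?")
  expect_identical(length(s), 3L)
  expect_identical(s[1], "Mean was 3.5 units.")
})
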