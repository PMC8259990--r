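# Citation-record model, filtering, splitting, condition indexing,
# annotation alignment and training-window sampling.

#' Create a citation record
#'
#' The in-memory form of one MEDLINE-style citation: title, abstract,
#' publication year, an optional keyword set, a language tag and optional
#' word-level annotations.
#'
#' @param id record identifier (string).
#' @param title article title.
#' @param abstract abstract body (may be empty; such records are removed by
#'   [filter_records()]).
#' @param year integer publication year.
#' @param keywords character vector of author-supplied keywords (possibly
#'   empty).
#' @param language language tag; English is `"eng"`/`"en"`/`"english"`.
#' @param annotations optional data.frame with columns `start`, `end`
#'   (1-based character offsets into the document text, i.e.
#'   `paste(title, abstract)`), `pos`, `dep`, `ent`.
#' @return A list of class `medline_record`.
#' @export
medline_record <- function(id, title, abstract, year, keywords = character(),
                           language = "eng", annotations = NULL) {
  stopifnot(length(id) == 1L, length(title) == 1L, length(abstract) == 1L)
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations),
              all(c("start", "end", "pos", "dep", "ent") %in%
                    names(annotations)))
  }
  structure(list(id = as.character(id), title = as.character(title),
                 abstract = as.character(abstract),
                 year = as.integer(year),
                 keywords = as.character(keywords),
                 language = as.character(language),
                 annotations = annotations),
            class = "medline_record")
}

#' @export
print.medline_record <- function(x, ...) {
  cat(sprintf("<medline_record %s> (%s, %d) %s\n", x$id, x$language,
              x$year, substr(x$title, 1, 60)))
  invisible(x)
}

# Document text used for tokenization, alignment and window sampling:
# the title is the first sentence, followed by the abstract.
document_text <- function(record) {
  paste(record$title, record$abstract)
}

is_english <- function(language) {
  tolower(trimws(language)) %in% c("en", "eng", "english")
}

#' Split text into sentences
#'
#' Deterministic rule-based splitter: a sentence boundary is a run of
#' `.?!` followed by whitespace and an uppercase letter or digit.
#'
#' @param text single string.
#' @return Character vector of sentences (boundary punctuation retained).
#' @export
split_sentences <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  starts <- sentence_start_offsets(text)
  n <- nchar(text)
  ends <- c(starts[-1] - 1L, n)
  out <- substring(text, starts, ends)
  trimws(out[nzchar(trimws(out))])
}

# 1-based character offsets at which sentences begin.
sentence_start_offsets <- function(text) {
  if (!nzchar(text)) return(integer(0))
  m <- gregexpr("[.?!]+[ \t\r\n]+(?=[A-Z0-9])", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(1L)
  bound <- as.integer(m) + attr(m, "match.length")
  unique(c(1L, bound[bound <= nchar(text)]))
}

#' Filter citation records for training
#'
#' Keeps exactly the records that are in English and contain at least one
#' non-title sentence (a non-empty abstract). Records without keywords are
#' retained. Dropped records are counted in a message.
#'
#' @param records list of [medline_record()] objects.
#' @return Filtered list of records.
#' @export
filter_records <- function(records) {
  keep <- vapply(records, function(r) {
    is_english(r$language) &&
      length(split_sentences(r$abstract)) >= 1L &&
      !is.na(r$year)
  }, logical(1))
  if (any(!keep))
    message(sprintf("filter_records: dropped %d of %d records",
                    sum(!keep), length(records)))
  records[keep]
}

#' Deterministic train/test split
#'
#' Records are ranked by a seeded hash of their id and the top `ratio`
#' fraction is assigned to the training partition, so the split is
#' exhaustive, disjoint, reproducible for a given seed, and hits the
#' requested fraction to within one record.
#'
#' @param records non-empty list of [medline_record()] objects.
#' @param ratio training fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return List with elements `train` and `test` (original record order).
#' @export
split_train_test <- function(records, ratio = 0.7, seed = 13L) {
  if (length(records) == 0L) stopf("no records to split")
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stopf("`ratio` must lie strictly between 0 and 1")
  ids <- vapply(records, `[[`, "", "id")
  h <- vapply(ids, fnv1a32, numeric(1), seed = as.integer(seed))
  rk <- order(h, ids)
  n_train <- max(1L, min(length(records) - 1L,
                         as.integer(round(ratio * length(records)))))
  train_idx <- sort(rk[seq_len(n_train)])
  list(train = records[train_idx],
       test = records[setdiff(seq_along(records), train_idx)])
}

#' Build the condition index over keywords and years
#'
#' Indexes every training-partition keyword occurring at least `min_count`
#' times (case-insensitive after trimming), and one index per year in the
#' half-open range `[min_year, cutoff_year)` where `min_year` is the
#' earliest year observed. Year indices come first (1..n_years), keyword
#' indices follow contiguously. Years at or beyond the cutoff clamp to the
#' last year index; years before `min_year` clamp to the first.
#'
#' @param records non-empty list of training records.
#' @param min_count minimum keyword occurrence count (default 10).
#' @param cutoff_year exclusive upper bound of the year range.
#' @return An object of class `condition_index`.
#' @export
build_condition_index <- function(records, min_count = 10L,
                                  cutoff_year = 2020L) {
  if (length(records) == 0L) stopf("no records to index")
  years <- vapply(records, `[[`, integer(1), "year")
  min_year <- min(years)
  if (cutoff_year <= min_year)
    stopf("cutoff_year (%d) must exceed the earliest year (%d)",
          cutoff_year, min_year)
  n_years <- as.integer(cutoff_year - min_year)
  kws <- tolower(trimws(unlist(lapply(records, `[[`, "keywords"))))
  kws <- kws[nzchar(kws)]
  tab <- table(kws)
  kept <- sort(names(tab)[tab >= min_count])
  kw_ids <- if (length(kept)) stats::setNames(seq_along(kept) + n_years, kept)
            else stats::setNames(integer(0), character(0))
  structure(list(keywords = kw_ids,
                 min_year = as.integer(min_year),
                 cutoff_year = as.integer(cutoff_year),
                 n_years = n_years,
                 n_conditions = n_years + length(kept)),
            class = "condition_index")
}

#' @export
print.condition_index <- function(x, ...) {
  cat(sprintf(
    "<condition_index> %d year indices [%d, %d) + %d keywords = %d conditions\n",
    x$n_years, x$min_year, x$cutoff_year, length(x$keywords),
    x$n_conditions))
  invisible(x)
}

#' Map a year to its condition index
#'
#' @param index a [build_condition_index()] result.
#' @param year integer year(s); clamped into the indexed range.
#' @return Integer index in `1..n_years`.
#' @export
year_index <- function(index, year) {
  stopifnot(inherits(index, "condition_index"))
  y <- pmin(pmax(as.integer(year), index$min_year), index$cutoff_year - 1L)
  y - index$min_year + 1L
}

#' Condition ids for a record's metadata
#'
#' Every record carries its year index; indexed keywords follow. Unknown
#' (pruned) keywords are dropped with a warning when `warn` is TRUE.
#'
#' @param index a `condition_index`.
#' @param year publication year.
#' @param keywords character vector of keywords (possibly empty).
#' @param warn warn about unindexed keywords.
#' @return Integer vector of condition embedding indices (length >= 1).
#' @export
condition_ids <- function(index, year, keywords = character(), warn = FALSE) {
  stopifnot(inherits(index, "condition_index"))
  kw <- tolower(trimws(keywords))
  kw <- kw[nzchar(kw)]
  hit <- kw %in% names(index$keywords)
  if (warn && any(!hit))
    warning(sprintf("dropping unindexed keyword(s): %s",
                    paste(kw[!hit], collapse = ", ")), call. = FALSE)
  c(year_index(index, year), unname(index$keywords[kw[hit]]))
}

#' Align word-level annotations onto a subword segmentation
#'
#' Each subword inherits the POS/dependency/entity labels of the word whose
#' character span contains the subword's first character. Subwords outside
#' any annotated span receive the null labels (`SPACE`, `dep`,
#' `not_an_entity`).
#'
#' @param annotations data.frame with `start`, `end`, `pos`, `dep`, `ent`
#'   (1-based inclusive character offsets).
#' @param starts integer vector of each subword's first-character offset,
#'   e.g. `attr(segment_text(...), "starts")`.
#' @return List with character vectors `pos`, `dep`, `ent`, one entry per
#'   subword.
#' @export
align_labels <- function(annotations, starts) {
  n <- length(starts)
  pos <- rep(NULL_POS, n); dep <- rep(NULL_DEP, n); ent <- rep(NULL_ENT, n)
  if (is.null(annotations) || nrow(annotations) == 0L)
    return(list(pos = pos, dep = dep, ent = ent))
  ann <- annotations[order(annotations$start), , drop = FALSE]
  is_ent <- ann$ent != NULL_ENT
  if (sum(is_ent) > 1L) {
    es <- ann[is_ent, , drop = FALSE]
    if (any(es$start[-1] <= es$end[-nrow(es)]))
      stopf("overlapping entity spans in annotations")
  }
  word_of <- findInterval(starts, ann$start)
  for (i in seq_len(n)) {
    w <- word_of[i]
    if (w >= 1L && starts[i] <= ann$end[w]) {
      pos[i] <- ann$pos[w]; dep[i] <- ann$dep[w]; ent[i] <- ann$ent[w]
    }
  }
  list(pos = pos, dep = dep, ent = ent)
}

#' Encode a record into aligned token and label tracks
#'
#' Tokenizes the document text (title as first sentence, then abstract),
#' wraps it as start-of-abstract ... end-of-abstract, aligns any word-level
#' annotations onto the subwords, converts labels to ids, records
#' sentence-start token positions (eligible training-window starts) and the
#' record's condition ids.
#'
#' @param record a [medline_record()].
#' @param vocab a [subword_vocab()].
#' @param cond_index a `condition_index`.
#' @param mode segmentation mode passed to [segment_text()].
#' @param alpha sampling smoothing for `"sample"` mode.
#' @return List of class `encoded_doc` with `tokens`, `pos_ids`, `dep_ids`,
#'   `ent_ids` (equal length), `sent_starts`, `cond_ids`, `id`.
#' @export
encode_record <- function(record, vocab, cond_index,
                          mode = "viterbi", alpha = 1) {
  stopifnot(inherits(record, "medline_record"))
  text <- document_text(record)
  seg <- segment_text(text, vocab, mode = mode, alpha = alpha)
  lab <- align_labels(record$annotations, attr(seg, "starts"))
  tokens <- c(vocab$bos_id, as.integer(seg), vocab$eos_id)
  pos_ids <- c(label_to_id(NULL_POS, POS_TAGS, "pos"),
               label_to_id(lab$pos, POS_TAGS, "pos"),
               label_to_id(NULL_POS, POS_TAGS, "pos"))
  dep_ids <- c(label_to_id(NULL_DEP, DEP_TAGS, "dependency"),
               label_to_id(lab$dep, DEP_TAGS, "dependency"),
               label_to_id(NULL_DEP, DEP_TAGS, "dependency"))
  ent_ids <- c(label_to_id(NULL_ENT, ENTITY_CLASSES, "entity"),
               label_to_id(lab$ent, ENTITY_CLASSES, "entity"),
               label_to_id(NULL_ENT, ENTITY_CLASSES, "entity"))
  # sentence starts in token space: the start token, plus the first token
  # at or after each later sentence's character offset (+1 for the start
  # token prepended ahead of the segmentation)
  ch_starts <- sentence_start_offsets(text)
  tok_starts <- attr(seg, "starts")
  sent_tok <- vapply(ch_starts[-1],
                     function(s) which(tok_starts >= s)[1] + 1L,
                     integer(1))
  sent_starts <- unique(c(1L, sent_tok[!is.na(sent_tok)]))
  structure(list(id = record$id, tokens = tokens, pos_ids = pos_ids,
                 dep_ids = dep_ids, ent_ids = ent_ids,
                 sent_starts = sent_starts,
                 cond_ids = condition_ids(cond_index, record$year,
                                          record$keywords)),
            class = "encoded_doc")
}

#' Sample a training window from an encoded document
#'
#' The window start is drawn uniformly among sentence-start token positions;
#' all four target tracks are the corresponding source tracks shifted left
#' by one token (position `i` of the window predicts token `i + 1` of the
#' document along with its labels). Windows are truncated so that every
#' input position has a target; length never exceeds `window`.
#'
#' @param doc an [encode_record()] result.
#' @param window maximum window length in tokens (default 128).
#' @param seed optional seed for the start draw.
#' @return List of class `training_window` with `input_ids`,
#'   `token_targets`, `pos_targets`, `dep_targets`, `ent_targets`,
#'   `condition_ids`.
#' @export
sample_window <- function(doc, window = 128L, seed = NULL) {
  stopifnot(inherits(doc, "encoded_doc"))
  n <- length(doc$tokens)
  if (n < 2L) stopf("document has fewer than 2 tokens; cannot form targets")
  eligible <- doc$sent_starts[doc$sent_starts <= n - 1L]
  if (length(eligible) == 0L) stopf("no eligible sentence start")
  start <- with_seed(seed, eligible[sample.int(length(eligible), 1L)])
  end <- min(start + window - 1L, n - 1L)
  idx <- start:end
  structure(list(input_ids = doc$tokens[idx],
                 token_targets = doc$tokens[idx + 1L],
                 pos_targets = doc$pos_ids[idx + 1L],
                 dep_targets = doc$dep_ids[idx + 1L],
                 ent_targets = doc$ent_ids[idx + 1L],
                 condition_ids = doc$cond_ids),
            class = "training_window")
}

#' Read records from JSON-lines
#'
#' One JSON object per line with fields `id`, `title`, `abstract`, `year`,
#' `keywords`, `language` and optional `annotations` (array of objects with
#' `start`, `end`, `pos`, `dep`, `ent`).
#'
#' @param path file path.
#' @return List of [medline_record()] objects.
#' @export
read_jsonl_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyDataFrame = TRUE)
    ann <- x$annotations
    if (!is.null(ann) && !is.data.frame(ann)) ann <- as.data.frame(ann)
    if (!is.null(ann) && nrow(ann) == 0L) ann <- NULL
    medline_record(x$id, x$title, x$abstract, x$year,
                   keywords = unlist(x$keywords) %||% character(),
                   language = x$language %||% "eng",
                   annotations = ann)
  })
}

#' Write records as JSON-lines
#'
#' Inverse of [read_jsonl_records()].
#'
#' @param records list of [medline_record()] objects.
#' @param path output file path.
#' @export
write_jsonl_records <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in records) {
    x <- unclass(r)
    if (is.null(x$annotations)) x$annotations <- NULL
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read citation records from MEDLINE XML
#'
#' Maps `PubmedArticle` elements (ArticleTitle, AbstractText, PubDate/Year,
#' Language, MeSH descriptor names and author keywords) into
#' [medline_record()] objects. Records lacking a parseable year are
#' skipped.
#'
#' @param path path to a MEDLINE/PubMed XML file.
#' @return List of [medline_record()] objects.
#' @export
read_medline_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  out <- list()
  for (a in arts) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abst <- paste(vapply(xml2::xml_find_all(a, ".//Abstract/AbstractText"),
                         xml2::xml_text, ""), collapse = " ")
    lang <- xml2::xml_text(xml2::xml_find_first(a, ".//Language"))
    yr <- xml2::xml_text(xml2::xml_find_first(
      a, ".//JournalIssue/PubDate/Year"))
    if (is.na(yr) || !nzchar(yr)) {
      md <- xml2::xml_text(xml2::xml_find_first(
        a, ".//JournalIssue/PubDate/MedlineDate"))
      yr <- regmatches(md, regexpr("[0-9]{4}", md))
      if (length(yr) == 0L) next
    }
    mesh <- vapply(xml2::xml_find_all(a, ".//MeshHeading/DescriptorName"),
                   xml2::xml_text, "")
    kw <- vapply(xml2::xml_find_all(a, ".//KeywordList/Keyword"),
                 xml2::xml_text, "")
    out[[length(out) + 1L]] <- medline_record(
      pmid, title, abst, as.integer(yr),
      keywords = c(mesh, kw),
      language = if (is.na(lang)) "" else lang)
  }
  out
}
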