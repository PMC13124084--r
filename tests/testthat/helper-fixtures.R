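# Shared fixtures, built once per test run.

lex_builtin <- load_builtin_lexicon()
fillers_builtin <- build_filler_vocabulary(lex_builtin)

# Independent matching oracle: a naive loop over the individual compiled
# patterns, one stri_detect per pattern per message. The production path
# uses one combined alternation per category; the two must agree on
# every indicator and matched-id set.
oracle_match <- function(lex, texts) {
  txt <- cdsmark::normalize_text(texts)
  opts <- stringi::stri_opts_regex(case_insensitive = TRUE)
  codes <- distortion_types()$code
  lapply(txt, function(one) {
    hit <- vapply(lex$regex, function(rx)
      stringi::stri_detect_regex(one, rx, opts_regex = opts), logical(1))
    ids <- sort(lex$id[hit])
    flags <- vapply(codes, function(cc)
      as.integer(any(lex$category_code[hit] == cc)), integer(1))
    list(match = as.integer(any(hit)), matched_ids = ids, flags = flags)
  })
}

# A small handmade chat corpus: 2 sessions, mixed roles and months.
tiny_corpus <- function() {
  sessions <- data.frame(
    session_id = c("s1", "s2"),
    start_date = as.Date(c("2020-01-15", "2020-02-10")),
    stringsAsFactors = FALSE)
  messages <- data.frame(
    session_id = c("s1", "s1", "s1", "s1", "s2", "s2", "s2"),
    role = c("h", "o", "b", "h", "h", "o", "h"),
    t = c(0, 10, 15, 20, 0, 5, 30),
    text = c("dat zou kunnen",          # ss
             "vertel eens wat meer",    # no match
             "chat gestart",            # system
             "mooi weer vandaag",       # no match
             "het is allemaal mijn schuld",  # p (+ dr "allemaal")
             "hoe gaat het nu",         # no match
             "koffie en thee"),         # no match
    stringsAsFactors = FALSE)
  cds_corpus(sessions, messages, mode = "chat")
}

# Build an annotation table directly (bypassing the matcher) for the
# prevalence arithmetic tests: `spec` is a data.frame with columns
# session_id, role and any subset of category-code columns (0/1).
make_ann <- function(spec) {
  codes <- distortion_types()$code
  ann <- data.frame(session_id = spec$session_id,
                    msg_index = stats::ave(seq_len(nrow(spec)),
                                           spec$session_id,
                                           FUN = seq_along),
                    role = spec$role, stringsAsFactors = FALSE)
  for (cc in codes) {
    ann[[cc]] <- if (cc %in% names(spec)) as.integer(spec[[cc]])
      else 0L
  }
  flags <- as.matrix(ann[, codes])
  ann$any_cds <- as.integer(rowSums(flags) > 0)
  ann$matched_pattern_ids <- ""
  structure(ann, class = c("cds_annotations", "data.frame"))
}
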