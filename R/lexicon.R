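#' The 12 cognitive distortion types
#'
#' Returns the closed taxonomy of distortion types used throughout the
#' package, in canonical row order, with the short codes used as column
#' names in annotations and reports.
#'
#' @return a data.frame with columns \code{code} and \code{name}, 12 rows.
#' @export
#' @examples
#' distortion_types()
distortion_types <- function() {
  data.frame(
    code = c("c", "dr", "dtp", "er", "f", "lam",
             "mam", "mf", "m", "o", "p", "ss"),
    name = c("Catastrophizing", "Dichotomous reasoning",
             "Disqualifying the positive", "Emotional reasoning",
             "Fortune-telling", "Labeling and mislabeling",
             "Magnification and minimization", "Mental filtering",
             "Mindreading", "Overgeneralizing", "Personalizing",
             "Should statements"),
    stringsAsFactors = FALSE
  )
}

# Published per-category schema counts used for the side-by-side census.
.published_counts <- c(c = 25L, dr = 25L, dtp = 14L, er = 10L, f = 8L,
                       lam = 47L, mam = 9L, mf = 16L, m = 72L, o = 20L,
                       p = 15L, ss = 4L)

#' Matching options
#'
#' @param gap_cap maximum number of characters a gap construct
#'   (\code{"(.+ |)"} in the printed dialect) may span. Default
#'   \code{Inf}: unlimited within one message. Finite caps are exposed
#'   for sensitivity analysis.
#' @param case_insensitive logical; match case-insensitively (default).
#' @return a list of class \code{cds_match_options}.
#' @export
match_options <- function(gap_cap = Inf, case_insensitive = TRUE) {
  stopifnot(is.numeric(gap_cap), length(gap_cap) == 1L, gap_cap >= 1)
  structure(list(gap_cap = gap_cap,
                 case_insensitive = isTRUE(case_insensitive)),
            class = "cds_match_options")
}

# Rewrite the printed gap construct "(.+ |)" into a canonical form.
#
# The printed rows are inconsistent about spacing around the gap:
# "ik zal(.+ |) niet" (space after) would demand a double space when the
# empty branch applies, and "het zal(.+ |)niet" (no space) would glue
# words together.  Both are repaired by absorbing the adjacent spaces and
# emitting " (.+ )?": a single space, optionally followed by one or more
# characters and a further space.  With a finite cap the inner ".+"
# becomes ".{1,cap}".
.canonical_gap <- function(normalized, gap_cap = Inf) {
  gap <- if (is.finite(gap_cap)) {
    sprintf(" (.{1,%d} )?", as.integer(gap_cap))
  } else {
    " (.+ )?"
  }
  stringi::stri_replace_all_regex(normalized, " ?\\(\\.\\+ \\|\\) ?", gap)
}

#' Compile one lexicon pattern into a matcher regex
#'
#' Turns the cleaned (normalized) form of a printed pattern into the ICU
#' regular expression actually used for matching. The transformation:
#' canonicalizes gap constructs (see Details), then anchors a word
#' boundary at a pattern edge when -- and only when -- the edge character
#' is alphanumeric, so that 1-grams such as "zou" or "alleen" cannot fire
#' inside longer words while character-class or optional-suffix edges
#' ("zwart[-/]wit", "slechtste?") are left untouched.
#'
#' Matching with the compiled form is case-insensitive and operates on
#' NFC-normalized, whitespace-collapsed text (see
#' \code{\link{normalize_text}}); \code{.} never crosses a message
#' boundary because matching is strictly per message.
#'
#' @param p a single-row subset of a lexicon data.frame, or a length-1
#'   character vector holding a normalized pattern.
#' @param options a \code{\link{match_options}} object.
#' @return length-1 character: the compiled regex.
#' @export
#' @examples
#' compile_pattern("zou")
#' compile_pattern("ik zal(.+ |) niet")
compile_pattern <- function(p, options = match_options()) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1L)
    id <- p$id
    normalized <- p$normalized
  } else {
    id <- NA_integer_
    normalized <- as.character(p)
  }
  if (!nzchar(normalized)) {
    stop("empty pattern after cleaning (pattern id ", id, ")")
  }
  core <- .canonical_gap(normalize_text(normalized), options$gap_cap)
  alnum <- function(ch) stringi::stri_detect_regex(ch, "[\\p{L}\\p{N}]")
  first <- stringi::stri_sub(core, 1L, 1L)
  last <- stringi::stri_sub(core, -1L, -1L)
  if (alnum(first)) core <- paste0("\\b", core)
  if (alnum(last)) core <- paste0(core, "\\b")
  ok <- tryCatch({
    stringi::stri_detect_regex("probe", core)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop("pattern does not compile to a valid regex (pattern id ", id,
         "): ", normalized)
  }
  core
}

#' Parse printed lexicon text
#'
#' Parses the packaged (or a user-supplied) plain-text rendering of the
#' lexicon: one category per line, a tab between the category name and
#' its patterns, patterns separated by the two-character delimiter
#' comma-then-space. Commas inside patterns (e.g. \code{"top,? maar"})
#' are never followed by a space and therefore survive the split.
#' Typographic quote artifacts present in two printed rows are stripped
#' from the normalized pattern text but preserved byte-for-byte in the
#' \code{raw} column. Pattern ids are assigned in canonical category
#' order, then reading order within a row.
#'
#' @param text character: either one string with embedded newlines or a
#'   vector of lines.
#' @param options a \code{\link{match_options}} object.
#' @return a data.frame of class \code{cds_lexicon} with columns
#'   \code{id}, \code{category_code}, \code{category_name}, \code{raw},
#'   \code{normalized}, \code{is_regex}, \code{regex}.
#' @export
parse_lexicon_text <- function(text, options = match_options()) {
  if (length(text) == 1L && stringi::stri_detect_fixed(text, "\n")) {
    text <- stringi::stri_split_fixed(text, "\n")[[1]]
  }
  text <- text[nzchar(trimws(text))]
  if (length(text) == 0L) stop("lexicon text contains no rows")
  types <- distortion_types()

  rows <- lapply(text, function(line) {
    fields <- stringi::stri_split_fixed(line, "\t")[[1]]
    if (length(fields) != 2L) {
      stop("malformed lexicon row (expected '<category>\\t<patterns>'): ",
           substr(line, 1, 40))
    }
    name <- trimws(fields[1L])
    idx <- match(tolower(name), tolower(types$name))
    if (is.na(idx)) stop("unknown distortion category label: '", name, "'")
    raw <- stringi::stri_split_fixed(fields[2L], ", ")[[1]]
    if (length(raw) == 0L || all(!nzchar(trimws(raw)))) {
      stop("empty pattern row for category '", name, "'")
    }
    data.frame(category_code = types$code[idx],
               category_name = types$name[idx],
               order = idx, raw = raw, stringsAsFactors = FALSE)
  })
  lex <- do.call(rbind, rows)
  lex <- lex[order(lex$order), , drop = FALSE]
  lex$order <- NULL

  norm <- stringi::stri_replace_all_regex(lex$raw, .quote_chars, "")
  norm <- stringi::stri_trans_nfc(norm)
  norm <- trimws(stringi::stri_replace_all_regex(norm, "\\s+", " "))
  if (any(!nzchar(norm))) {
    stop("pattern empty after cleaning in category '",
         lex$category_name[!nzchar(norm)][1L], "'")
  }
  lex$normalized <- norm
  lex$is_regex <- stringi::stri_detect_regex(norm, "[()\\[\\]|?+.]")
  lex$id <- seq_len(nrow(lex))
  lex$regex <- vapply(seq_len(nrow(lex)), function(i)
    compile_pattern(lex[i, ], options), character(1))
  lex <- lex[, c("id", "category_code", "category_name", "raw",
                 "normalized", "is_regex", "regex")]
  structure(lex, class = c("cds_lexicon", "data.frame"),
            options = options)
}

#' Load the packaged Dutch lexicon
#'
#' Reads and parses the packaged copy of the printed 12-category Dutch
#' lexicon of cognitive distortion schemata (265 claimed n-grams/regexes).
#' Deterministic and idempotent: repeated calls yield identical lexicons.
#'
#' @inheritParams parse_lexicon_text
#' @return a \code{cds_lexicon} data.frame; see
#'   \code{\link{parse_lexicon_text}}.
#' @export
#' @examples
#' lex <- load_builtin_lexicon()
#' nrow(lex)
#' category_counts(lex)
load_builtin_lexicon <- function(options = match_options()) {
  path <- system.file("extdata", "cds_lexicon_nl.tsv", package = "cdsmark")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged lexicon resource is missing; reinstall the package")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lex <- parse_lexicon_text(lines, options)
  if (length(unique(lex$category_code)) != 12L) {
    stop("packaged lexicon resource is corrupt: expected 12 categories, ",
         "found ", length(unique(lex$category_code)))
  }
  lex
}

#' Per-category pattern counts
#'
#' @param lex a \code{cds_lexicon} (or an empty data.frame with the same
#'   columns).
#' @return named integer vector over the 12 category codes (zeros where a
#'   category has no parsed patterns), with attribute \code{total}.
#' @export
category_counts <- function(lex) {
  types <- distortion_types()
  n <- vapply(types$code, function(cc) sum(lex$category_code == cc),
              integer(1))
  names(n) <- types$code
  attr(n, "total") <- sum(n)
  n
}

#' Parsed versus published category counts
#'
#' The printed pattern rows do not split to the published per-category
#' totals for five categories (nor to the published overall total of 265);
#' the parsed rows are treated as canonical and both counts are reported
#' side by side rather than forced to agree.
#'
#' @param lex a \code{cds_lexicon}.
#' @return data.frame with columns \code{code}, \code{name},
#'   \code{n_parsed}, \code{n_published}, \code{agree}.
#' @export
lexicon_census <- function(lex) {
  types <- distortion_types()
  n <- category_counts(lex)
  data.frame(code = types$code, name = types$name,
             n_parsed = as.integer(n[types$code]),
             n_published = as.integer(.published_counts[types$code]),
             agree = as.integer(n[types$code]) ==
               as.integer(.published_counts[types$code]),
             stringsAsFactors = FALSE)
}

# One combined alternation regex per category: (?:p1)|(?:p2)|...
# Used by the production matcher; the per-pattern loop is the oracle.
.category_regexes <- function(lex) {
  types <- distortion_types()
  out <- vapply(types$code, function(cc) {
    pats <- lex$regex[lex$category_code == cc]
    if (length(pats) == 0L) return(NA_character_)
    paste0("(?:", pats, ")", collapse = "|")
  }, character(1))
  names(out) <- types$code
  out
}

#' Export a lexicon to a tabular file
#'
#' @param lex a \code{cds_lexicon}.
#' @param path output path; tab-separated UTF-8 with columns id,
#'   category_code, category_name, raw, normalized, is_regex.
#' @return invisibly, \code{path}.
#' @export
write_lexicon <- function(lex, path) {
  out <- lex[, c("id", "category_code", "category_name", "raw",
                 "normalized", "is_regex")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.cds_lexicon <- function(x, ...) {
  n <- category_counts(x)
  cat("CDS lexicon:", nrow(x), "patterns in",
      sum(n > 0), "categories\n")
  print(stats::setNames(as.integer(n), names(n)))
  invisible(x)
}
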