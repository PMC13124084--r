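# Per-category detection over a vector of already-normalized texts.
# Production path: one combined alternation regex per category.
.detect_matrix <- function(lex, texts_norm) {
  codes <- distortion_types()$code
  regs <- .category_regexes(lex)
  ci <- attr(lex, "options")$case_insensitive %||% TRUE
  out <- matrix(FALSE, nrow = length(texts_norm), ncol = length(codes),
                dimnames = list(NULL, codes))
  for (cc in codes) {
    if (is.na(regs[[cc]])) next
    out[, cc] <- stringi::stri_detect_regex(
      texts_norm, regs[[cc]],
      opts_regex = stringi::stri_opts_regex(case_insensitive = ci))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ids of the individual patterns (within the given categories) matching
# one normalized text, in pattern-id order
.matched_ids <- function(lex, text_norm, codes) {
  sub <- lex[lex$category_code %in% codes, , drop = FALSE]
  if (nrow(sub) == 0L) return(integer())
  ci <- attr(lex, "options")$case_insensitive %||% TRUE
  hit <- stringi::stri_detect_regex(
    text_norm, sub$regex,
    opts_regex = stringi::stri_opts_regex(case_insensitive = ci))
  sort(sub$id[hit])
}

#' Match one message against a set of patterns
#'
#' The message-level matching function: returns 1 when the normalized
#' message text contains at least one pattern of the chosen set,
#' regardless of topic or context, and 0 otherwise. Multiple hits still
#' yield 1 -- prevalence is the fraction of messages containing at least
#' one marker, not a hit count -- but the individual matching pattern ids
#' are reported for diagnostics.
#'
#' @param lex a \code{cds_lexicon}.
#' @param text a length-1 character string (may be empty).
#' @param categories category codes defining the pattern set C; default
#'   \code{NULL} = the whole lexicon.
#' @param ids optional explicit pattern ids further restricting C.
#' @return list with elements \code{match} (integer 0/1) and
#'   \code{matched_ids} (integer vector, ascending).
#' @export
#' @examples
#' lex <- load_builtin_lexicon()
#' match_message(lex, "dat zou kunnen", categories = "ss")$match
match_message <- function(lex, text, categories = NULL, ids = NULL) {
  stopifnot(length(text) == 1L)
  sub <- lex
  if (!is.null(categories)) {
    bad <- setdiff(categories, distortion_types()$code)
    if (length(bad)) stop("unknown category code: ", bad[1L])
    sub <- sub[sub$category_code %in% categories, , drop = FALSE]
  }
  if (!is.null(ids)) sub <- sub[sub$id %in% ids, , drop = FALSE]
  if (nrow(sub) == 0L || !nzchar(text)) {
    return(list(match = 0L, matched_ids = integer()))
  }
  txt <- normalize_text(text)
  ci <- attr(lex, "options")$case_insensitive %||% TRUE
  hit <- stringi::stri_detect_regex(
    txt, sub$regex,
    opts_regex = stringi::stri_opts_regex(case_insensitive = ci))
  list(match = as.integer(any(hit)), matched_ids = sort(sub$id[hit]))
}

#' Annotate every non-system message of a corpus
#'
#' Runs the matcher over the whole corpus and returns one annotation row
#' per non-system message, in corpus order: the 12 per-category binary
#' indicators, the overall indicator \code{any_cds}, and the ids of the
#' patterns that matched (semicolon-joined). Deterministic: annotating
#' the same corpus twice yields identical output.
#'
#' @param lex a \code{cds_lexicon}.
#' @param corpus a \code{\link{cds_corpus}}; role-\code{b} messages are
#'   skipped (equivalently, run \code{\link{exclude_system_messages}}
#'   first).
#' @return data.frame of class \code{cds_annotations} with columns
#'   \code{session_id}, \code{msg_index}, \code{role}, one 0/1 column per
#'   category code, \code{any_cds}, \code{matched_pattern_ids}.
#' @export
annotate_corpus <- function(lex, corpus) {
  stopifnot(inherits(corpus, "cds_corpus"))
  msgs <- corpus$messages[corpus$messages$role != "b", , drop = FALSE]
  codes <- distortion_types()$code
  if (nrow(msgs) == 0L) {
    ann <- data.frame(session_id = character(), msg_index = integer(),
                      role = character(), stringsAsFactors = FALSE)
    for (cc in codes) ann[[cc]] <- integer()
    ann$any_cds <- integer()
    ann$matched_pattern_ids <- character()
    return(structure(ann, class = c("cds_annotations", "data.frame")))
  }
  txt <- normalize_text(msgs$text)
  flags <- .detect_matrix(lex, txt)
  any_cds <- as.integer(rowSums(flags) > 0)
  ids <- character(nrow(msgs))
  hit_rows <- which(any_cds == 1L)
  for (i in hit_rows) {
    ids[i] <- paste(.matched_ids(lex, txt[i], codes[flags[i, ]]),
                    collapse = ";")
  }
  ann <- data.frame(session_id = msgs$session_id,
                    msg_index = msgs$msg_index,
                    role = msgs$role, stringsAsFactors = FALSE)
  for (cc in codes) ann[[cc]] <- as.integer(flags[, cc])
  ann$any_cds <- any_cds
  ann$matched_pattern_ids <- ids
  rownames(ann) <- NULL
  structure(ann, class = c("cds_annotations", "data.frame"))
}

#' Write annotations to a tab-separated file
#' @param ann a \code{cds_annotations} data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read annotations written by \code{\link{write_annotations}}
#' @param path file path.
#' @return a \code{cds_annotations} data.frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, colClasses = "character",
                           fileEncoding = "UTF-8")
  codes <- distortion_types()$code
  need <- c("session_id", "msg_index", "role", codes, "any_cds",
            "matched_pattern_ids")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation file is missing column(s): ",
                         paste(miss, collapse = ", "))
  ann$msg_index <- as.integer(ann$msg_index)
  for (cc in c(codes, "any_cds")) ann[[cc]] <- as.integer(ann[[cc]])
  ann$matched_pattern_ids[is.na(ann$matched_pattern_ids)] <- ""
  structure(ann[, need], class = c("cds_annotations", "data.frame"))
}
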