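#' Construct a chat corpus
#'
#' The corpus container used by every downstream operation. A corpus
#' holds a session table (one row per session: anonymous id and calendar
#' start date, the latter needed for monthly binning) and a message table
#' (session id, role, elapsed seconds \code{t}, text). Three modes share
#' the container: \code{chat} (helpline sessions of alternating help
#' seeker / counselor messages plus occasional system messages),
#' \code{timeline} (one "session" per individual whose messages are
#' posts), and \code{sentence_collection} (a single session whose
#' messages are sentences, role \code{h}, \code{t = 0}).
#'
#' Messages are sorted by \code{t} within session with a stable sort
#' (input order preserved among ties) and assigned a per-session
#' \code{msg_index}. Empty-text messages are retained: denominators count
#' messages posted, and an empty message trivially contains no marker.
#'
#' @param sessions data.frame with columns \code{session_id},
#'   \code{start_date} (Date, or coercible; NA allowed).
#' @param messages data.frame with columns \code{session_id}, \code{role}
#'   (one of \code{"h"}, \code{"o"}, \code{"b"}), \code{t} (seconds,
#'   non-negative), \code{text}.
#' @param mode one of \code{"chat"}, \code{"timeline"},
#'   \code{"sentence_collection"}.
#' @return a list of class \code{cds_corpus} with elements
#'   \code{sessions}, \code{messages}, \code{mode}.
#' @export
cds_corpus <- function(sessions, messages,
                       mode = c("chat", "timeline", "sentence_collection")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(sessions), is.data.frame(messages))
  need_s <- c("session_id", "start_date")
  need_m <- c("session_id", "role", "t", "text")
  miss <- setdiff(need_s, names(sessions))
  if (length(miss)) stop("sessions table is missing column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need_m, names(messages))
  if (length(miss)) stop("messages table is missing column(s): ",
                         paste(miss, collapse = ", "))
  sessions$session_id <- as.character(sessions$session_id)
  if (any(!nzchar(sessions$session_id))) stop("empty session_id")
  if (anyDuplicated(sessions$session_id)) stop("duplicate session_id")
  sessions$start_date <- as.Date(sessions$start_date)

  messages$session_id <- as.character(messages$session_id)
  bad <- setdiff(unique(messages$role), c("h", "o", "b"))
  if (length(bad)) stop("unknown role value: '", bad[1L],
                        "' (expected h, o or b)")
  messages$t <- as.numeric(messages$t)
  if (any(is.na(messages$t)) || any(messages$t < 0)) {
    stop("message times t must be non-negative numbers")
  }
  messages$text <- as.character(messages$text)
  messages$text[is.na(messages$text)] <- ""
  orphan <- setdiff(unique(messages$session_id), sessions$session_id)
  if (length(orphan)) stop("message references unknown session_id: ",
                           orphan[1L])

  # stable sort: session (in session-table order), then t, then input order
  skey <- match(messages$session_id, sessions$session_id)
  ord <- order(skey, messages$t, seq_len(nrow(messages)))
  messages <- messages[ord, c(need_m), drop = FALSE]
  messages$msg_index <- stats::ave(seq_len(nrow(messages)),
                                   messages$session_id,
                                   FUN = seq_along)
  rownames(messages) <- NULL
  rownames(sessions) <- NULL
  structure(list(sessions = sessions[, need_s, drop = FALSE],
                 messages = messages, mode = mode),
            class = "cds_corpus")
}

#' @export
print.cds_corpus <- function(x, ...) {
  cat(sprintf("<cds_corpus mode=%s: %d sessions, %d messages (%s)>\n",
              x$mode, nrow(x$sessions), nrow(x$messages),
              paste(sprintf("%s=%d", c("h", "o", "b"),
                            vapply(c("h", "o", "b"),
                                   function(r) sum(x$messages$role == r),
                                   integer(1))), collapse = " ")))
  invisible(x)
}

#' Read sessions from JSON lines
#'
#' One JSON object per line:
#' \code{{"session_id": ..., "start_date": "YYYY-MM-DD",
#' "messages": [{"role": "h", "t": 0, "text": "..."}, ...]}}.
#'
#' @param path file path.
#' @param mode corpus mode, default \code{"chat"}.
#' @return a \code{\link{cds_corpus}}.
#' @export
read_sessions_jsonl <- function(path, mode = "chat") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(cds_corpus(
      data.frame(session_id = character(), start_date = as.Date(character())),
      data.frame(session_id = character(), role = character(),
                 t = numeric(), text = character()),
      mode))
  }
  sess <- vector("list", length(lines))
  msgs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyDataFrame = TRUE),
      error = function(e) stop("malformed JSON on line ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    if (is.null(obj$session_id)) stop("line ", i, ": missing session_id")
    m <- obj$messages
    if (is.null(m) || NROW(m) == 0L) {
      m <- data.frame(role = character(), t = numeric(),
                      text = character())
    }
    bad <- setdiff(unique(m$role), c("h", "o", "b"))
    if (length(bad)) stop("line ", i, ": unknown role value '", bad[1L], "'")
    sess[[i]] <- data.frame(session_id = as.character(obj$session_id),
                            start_date = if (is.null(obj$start_date))
                              NA_character_ else obj$start_date,
                            stringsAsFactors = FALSE)
    if (nrow(m)) m$session_id <- as.character(obj$session_id)
    msgs[[i]] <- m
  }
  msgs <- msgs[vapply(msgs, nrow, integer(1)) > 0L]
  messages <- if (length(msgs)) do.call(rbind, msgs) else
    data.frame(session_id = character(), role = character(),
               t = numeric(), text = character())
  cds_corpus(do.call(rbind, sess), messages, mode)
}

#' Read sessions from long-format CSV
#'
#' Columns \code{session_id}, \code{start_date}, \code{role}, \code{t},
#' \code{text}; RFC-4180 quoting, so text fields may contain commas and
#' newlines. Produces the same corpus as the equivalent JSONL file.
#'
#' @inheritParams read_sessions_jsonl
#' @return a \code{\link{cds_corpus}}.
#' @export
read_sessions_csv <- function(path, mode = "chat") {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  need <- c("session_id", "start_date", "role", "t", "text")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("CSV is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    return(cds_corpus(
      data.frame(session_id = character(), start_date = as.Date(character())),
      data.frame(session_id = character(), role = character(),
                 t = numeric(), text = character()),
      mode))
  }
  first <- !duplicated(df$session_id)
  sessions <- data.frame(session_id = df$session_id[first],
                         start_date = df$start_date[first],
                         stringsAsFactors = FALSE)
  messages <- data.frame(session_id = df$session_id, role = df$role,
                         t = as.numeric(df$t), text = df$text,
                         stringsAsFactors = FALSE)
  cds_corpus(sessions, messages, mode)
}

#' Read a plain-text sentence corpus
#'
#' One sentence per line, UTF-8; blank and whitespace-only lines are
#' dropped. The result is a single-session corpus in
#' \code{sentence_collection} mode with every sentence a role-\code{h}
#' message at \code{t = 0}.
#'
#' @param path file path.
#' @param session_id label for the single session.
#' @return a \code{\link{cds_corpus}}.
#' @export
read_sentence_corpus <- function(path, session_id = "sentences") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sessions <- data.frame(session_id = session_id,
                         start_date = as.Date(NA),
                         stringsAsFactors = FALSE)
  messages <- data.frame(session_id = rep(session_id, length(lines)),
                         role = rep("h", length(lines)),
                         t = rep(0, length(lines)),
                         text = lines, stringsAsFactors = FALSE)
  cds_corpus(sessions, messages, mode = "sentence_collection")
}

#' Write a corpus as JSON lines
#' @param corpus a \code{\link{cds_corpus}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_sessions_jsonl <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus$sessions))) {
    sid <- corpus$sessions$session_id[i]
    m <- corpus$messages[corpus$messages$session_id == sid,
                         c("role", "t", "text"), drop = FALSE]
    rownames(m) <- NULL
    obj <- list(session_id = sid,
                start_date = format(corpus$sessions$start_date[i]),
                messages = m)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                na = "null", dataframe = "rows"), con)
  }
  invisible(path)
}

#' Write a corpus as long-format CSV
#' @inheritParams write_sessions_jsonl
#' @return invisibly, \code{path}.
#' @export
write_sessions_csv <- function(corpus, path) {
  m <- corpus$messages
  m$start_date <- format(
    corpus$sessions$start_date[match(m$session_id,
                                     corpus$sessions$session_id)])
  out <- m[, c("session_id", "start_date", "role", "t", "text")]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Drop system messages
#'
#' Removes all role-\code{b} (automated platform) messages from a corpus;
#' everything else, including sessions left empty by the removal, is
#' untouched. Help-seeker and counselor message counts are conserved.
#'
#' @param corpus a \code{\link{cds_corpus}}.
#' @return a \code{\link{cds_corpus}} without system messages; original
#'   per-session message indices are preserved.
#' @export
exclude_system_messages <- function(corpus) {
  keep <- corpus$messages$role != "b"
  out <- corpus
  out$messages <- corpus$messages[keep, , drop = FALSE]
  rownames(out$messages) <- NULL
  out
}
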