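# Run expr with a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# split s at top-level "|" (not inside parentheses / brackets)
.split_alternation <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  cuts <- integer()
  inclass <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (inclass) {
      if (ch == "]") inclass <- FALSE
    } else if (ch == "[") {
      inclass <- TRUE
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
    } else if (ch == "|" && depth == 0L) {
      cuts <- c(cuts, i)
    }
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts), function(k) {
    if (starts[k] > ends[k]) "" else
      paste(chars[starts[k]:ends[k]], collapse = "")
  }, character(1))
}

# Realize one string from the restricted regex dialect the lexicon uses:
# literals, (a|b|...) groups (possibly with an empty branch), postfix ?,
# [..] character classes, and ".+" (a gap) realized as one filler word.
.realize_core <- function(s, fillers) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      depth <- 1L
      j <- i
      while (depth > 0L) {
        j <- j + 1L
        if (j > n) stop("unbalanced parentheses in pattern: ", s)
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") depth <- depth - 1L
      }
      inner <- if (j - i > 1L)
        paste(chars[(i + 1L):(j - 1L)], collapse = "") else ""
      optional <- j < n && chars[j + 1L] == "?"
      if (optional && stats::runif(1) < 0.5) {
        piece <- ""
      } else {
        branches <- .split_alternation(inner)
        br <- branches[[sample.int(length(branches), 1L)]]
        piece <- .realize_core(br, fillers)
      }
      out <- c(out, piece)
      i <- j + 1L + as.integer(optional)
    } else if (ch == "[") {
      j <- i
      while (chars[j] != "]") {
        j <- j + 1L
        if (j > n) stop("unbalanced character class in pattern: ", s)
      }
      cls <- chars[(i + 1L):(j - 1L)]
      optional <- j < n && chars[j + 1L] == "?"
      if (!(optional && stats::runif(1) < 0.5)) {
        out <- c(out, cls[sample.int(length(cls), 1L)])
      }
      i <- j + 1L + as.integer(optional)
    } else if (ch == "." && i < n && chars[i + 1L] == "+") {
      out <- c(out, fillers[sample.int(length(fillers), 1L)])
      i <- i + 2L
    } else if (i < n && chars[i + 1L] == "?") {
      if (stats::runif(1) < 0.5) out <- c(out, ch)
      i <- i + 2L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

#' Realize a concrete string from a lexicon pattern
#'
#' The inverse of matching: draws, using the current RNG stream, a
#' concrete string that the pattern's own compiled matcher accepts.
#' Alternation branches are chosen uniformly, optional elements are
#' included with probability 1/2, and a gap construct is resolved to
#' either nothing or one filler word. Every returned string is verified
#' against the pattern's compiled matcher; a pattern whose realizations
#' cannot self-match (an empty language) raises an error.
#'
#' @param p a single-row subset of a \code{cds_lexicon}, or a length-1
#'   character pattern in the printed dialect.
#' @param fillers words used to fill gap constructs; must not themselves
#'   trigger the pattern (use \code{\link{build_filler_vocabulary}}).
#' @return length-1 character string.
#' @export
#' @examples
#' lex <- load_builtin_lexicon()
#' set.seed(1)
#' realize_pattern(lex[lex$category_code == "ss", ][1, ])
realize_pattern <- function(p, fillers = c("koffie", "fiets", "verhaal")) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1L)
    normalized <- p$normalized
    regex <- p$regex
    id <- p$id
  } else {
    normalized <- as.character(p)
    regex <- compile_pattern(normalized)
    id <- NA_integer_
  }
  core <- .canonical_gap(normalize_text(normalized), Inf)
  s <- .realize_core(core, fillers)
  s <- trimws(stringi::stri_replace_all_regex(s, " +", " "))
  ok <- stringi::stri_detect_regex(
    normalize_text(s), regex,
    opts_regex = stringi::stri_opts_regex(case_insensitive = TRUE))
  if (!ok) {
    stop("realization '", s, "' does not self-match pattern id ", id,
         " ('", normalized, "'): empty or inconsistent pattern language")
  }
  s
}

#' Candidate filler words
#'
#' A list of common, neutral Dutch words (objects, places, activities and
#' a few connectors) proposed as building blocks for non-matching filler
#' sentences. Candidates are only proposals: they must pass the
#' verification sweep in \code{\link{build_filler_vocabulary}}, which is
#' what actually guarantees that no filler sentence triggers the lexicon.
#'
#' @return character vector.
#' @export
filler_candidates <- function() {
  c("vandaag", "morgen", "gisteren", "samen", "rustig", "verhaal",
    "vraag", "antwoord", "tafel", "stoel", "fiets", "water", "koffie",
    "thee", "brood", "appel", "boom", "straat", "stad", "dorp",
    "muziek", "boek", "brief", "school", "tuin", "vogel", "bloem",
    "regen", "zon", "wolk", "trein", "reis", "huis", "kamer", "deur",
    "raam", "markt", "winkel", "brug", "rivier", "strand", "bos",
    "berg", "veld", "paard", "hond", "kat", "kaas", "melk", "suiker",
    "bord", "lepel", "vork", "wandelen", "praten", "luisteren",
    "schrijven", "lezen", "eten", "drinken", "slapen", "spelen",
    "werken", "de", "en", "we", "met", "voor", "naar", "ook", "dan",
    "hier", "daar")
}

#' Build a verified non-matching filler vocabulary
#'
#' Filler text for the synthetic generator must be guaranteed not to
#' trigger any lexicon pattern -- several patterns consist of extremely
#' common Dutch words ("alleen", "altijd", "nooit", "niets"), so a naive
#' neutral vocabulary would leak matches. The sweep is therefore
#' mandatory and runs at build time: (1) every candidate word alone is
#' matched against the full lexicon and matching words are removed;
#' (2) every ordered pair of surviving words is matched (this catches
#' bigram and empty-gap patterns) and offending words are removed
#' greedily; (3) a seeded set of random probe sentences is matched as a
#' final guard against longer-range gap patterns. The probe RNG is local:
#' the caller's RNG stream is untouched.
#'
#' @param lex a \code{cds_lexicon}.
#' @param candidates candidate words; default
#'   \code{\link{filler_candidates}}.
#' @param n_probe number of random probe sentences (default 200).
#' @param probe_len words per probe sentence (default 8).
#' @param probe_seed seed for the local probe RNG.
#' @param min_size minimum usable vocabulary size before the build fails.
#' @return character vector of verified filler words.
#' @export
build_filler_vocabulary <- function(lex, candidates = filler_candidates(),
                                    n_probe = 200, probe_len = 8,
                                    probe_seed = 20170701,
                                    min_size = 10) {
  vocab <- unique(normalize_text(candidates))
  ci <- stringi::stri_opts_regex(case_insensitive = TRUE)
  allrx <- paste0("(?:", lex$regex, ")", collapse = "|")
  hits <- function(x) stringi::stri_detect_regex(x, allrx, opts_regex = ci)

  vocab <- vocab[!hits(vocab)]

  repeat {
    if (length(vocab) < min_size) stop("filler vocabulary exhausted")
    pairs <- expand.grid(a = vocab, b = vocab, stringsAsFactors = FALSE)
    bad <- hits(paste(pairs$a, pairs$b))
    if (!any(bad)) break
    guilty <- sort(table(c(pairs$a[bad], pairs$b[bad])), decreasing = TRUE)
    vocab <- setdiff(vocab, names(guilty)[1L])
  }

  repeat {
    if (length(vocab) < min_size) stop("filler vocabulary exhausted")
    probes <- .with_seed(probe_seed, {
      vapply(seq_len(n_probe), function(i)
        paste(sample(vocab, probe_len, replace = TRUE), collapse = " "),
        character(1))
    })
    bad <- hits(probes)
    if (!any(bad)) break
    words <- unlist(strsplit(probes[bad], " ", fixed = TRUE))
    guilty <- sort(table(words), decreasing = TRUE)
    vocab <- setdiff(vocab, names(guilty)[1L])
  }
  vocab
}

#' Role- and category-specific injection rates
#'
#' Builds the per-message injection probability matrix used by
#' \code{\link{generate_corpus}}: rows are roles (h, o, b), columns the
#' 12 category codes; entry (r, C) is the probability that a role-r
#' message receives one embedded realization of a category-C pattern.
#' System messages are never injected. Defaults reproduce the observed
#' overall rates of the helpline study (22.19\% of help-seeker and
#' 13.78\% of counselor messages carrying a marker), distributed over
#' categories using the published per-category figures (dichotomous
#' reasoning 0.13/0.07, should statements 0.05/0.02, overgeneralizing
#' 0.03/0.02 for h/o) with the remainder spread uniformly over the other
#' nine categories.
#'
#' @param p_h,p_o overall per-message injection probability for help
#'   seekers and counselors; the category profile is rescaled to these
#'   totals.
#' @param weights_h,weights_o optional named non-negative weight vectors
#'   over the 12 codes replacing the default category profile.
#' @return 3 x 12 numeric matrix, rownames \code{c("h","o","b")}.
#' @export
injection_rates <- function(p_h = 0.2219, p_o = 0.1378,
                            weights_h = NULL, weights_o = NULL) {
  codes <- distortion_types()$code
  profile <- function(known) {
    w <- stats::setNames(rep(NA_real_, 12L), codes)
    w[names(known)] <- known
    w[is.na(w)] <- (1 - sum(known)) / sum(is.na(w))
    w
  }
  wh <- if (is.null(weights_h)) {
    profile(c(dr = 0.13, ss = 0.05, o = 0.03) / 0.2219)
  } else {
    stats::setNames(weights_h[codes], codes)
  }
  wo <- if (is.null(weights_o)) {
    profile(c(dr = 0.07, ss = 0.02, o = 0.02) / 0.1378)
  } else {
    stats::setNames(weights_o[codes], codes)
  }
  if (any(is.na(wh)) || any(is.na(wo)) || any(wh < 0) || any(wo < 0)) {
    stop("weights must be non-negative and cover all 12 category codes")
  }
  m <- rbind(h = p_h * wh / sum(wh),
             o = p_o * wo / sum(wo),
             b = rep(0, 12L))
  colnames(m) <- codes
  m
}

#' Simulation configuration
#'
#' The stated world of the generator: session counts, mean messages per
#' role (defaults match the helpline aggregates of roughly 47 help-seeker
#' and 43 counselor messages per session, plus a small system-message
#' rate to exercise the exclusion rule), per-role/category injection
#' probabilities, and a multi-year start-date window for monthly binning
#' (defaults to July 2017 - June 2021).
#'
#' @param n_sessions number of sessions to generate.
#' @param seed RNG seed (mandatory).
#' @param mean_messages named numeric: mean message count per session for
#'   roles h, o and b (Poisson draws).
#' @param injection 3 x 12 probability matrix, see
#'   \code{\link{injection_rates}}; at most one injection per message, so
#'   each role's probabilities must sum to at most 1.
#' @param months length-2 Date (or coercible) vector: start-date window.
#' @param sentence_length length-2 integer: min/max filler words per
#'   message.
#' @param independent_injection logical; if TRUE, categories are injected
#'   independently (multi-category co-occurrence possible) instead of the
#'   default at-most-one-injection scheme.
#' @return list of class \code{cds_sim_config}.
#' @export
simulation_config <- function(n_sessions, seed,
                              mean_messages = c(h = 47, o = 43, b = 2),
                              injection = injection_rates(),
                              months = as.Date(c("2017-07-01",
                                                 "2021-06-01")),
                              sentence_length = c(5L, 12L),
                              independent_injection = FALSE) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(is.numeric(n_sessions), n_sessions >= 1,
            all(c("h", "o", "b") %in% names(mean_messages)),
            all(mean_messages >= 0), mean_messages[["h"]] > 0,
            is.matrix(injection),
            identical(rownames(injection), c("h", "o", "b")),
            ncol(injection) == 12L,
            length(sentence_length) == 2L,
            sentence_length[1] >= 1,
            sentence_length[2] >= sentence_length[1])
  if (any(injection < 0) || any(injection > 1)) {
    stop("injection probabilities must lie in [0, 1]")
  }
  if (!independent_injection && any(rowSums(injection) > 1)) {
    stop("per-message total injection probability exceeds 1 for a role")
  }
  months <- as.Date(months)
  if (length(months) != 2L || any(is.na(months)) || months[2] < months[1]) {
    stop("months must be two ascending dates")
  }
  structure(list(n_sessions = as.integer(n_sessions),
                 seed = as.integer(seed),
                 mean_messages = mean_messages,
                 injection = injection, months = months,
                 sentence_length = as.integer(sentence_length),
                 independent_injection = isTRUE(independent_injection)),
            class = "cds_sim_config")
}

#' Generate a seeded synthetic chat corpus
#'
#' Produces a reproducible chat-mode corpus with known statistical
#' structure: sessions of roughly alternating help-seeker/counselor
#' filler messages (plus occasional system messages) with start dates
#' uniform over the configured window; each message is a random filler
#' sentence, and with the configured per-role/category probability a
#' realization of one uniformly chosen pattern of that category is
#' embedded at a random word position. Ground-truth injection labels are
#' returned alongside the corpus, so the matcher can be audited exactly:
#' filler never matches, realizations always self-match.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param lex a \code{cds_lexicon} (default: the builtin lexicon).
#' @param fillers verified filler vocabulary; built (and verified) from
#'   \code{lex} when NULL.
#' @return list of class \code{cds_simulation}: \code{corpus} (a
#'   \code{\link{cds_corpus}}), \code{truth} (data.frame session_id,
#'   msg_index, role, category, pattern_id; NA where nothing was
#'   injected), \code{config}.
#' @export
generate_corpus <- function(cfg, lex = load_builtin_lexicon(),
                            fillers = NULL) {
  stopifnot(inherits(cfg, "cds_sim_config"))
  if (is.null(fillers)) fillers <- build_filler_vocabulary(lex)
  codes <- distortion_types()$code
  set.seed(cfg$seed)

  n <- cfg$n_sessions
  sids <- sprintf("syn%06d", seq_len(n))
  days <- as.integer(cfg$months[2] - cfg$months[1])
  starts <- cfg$months[1] + sample.int(days + 1L, n, replace = TRUE) - 1L

  nh <- stats::rpois(n, cfg$mean_messages[["h"]])
  no <- stats::rpois(n, cfg$mean_messages[["o"]])
  nb <- if (cfg$mean_messages[["b"]] > 0)
    stats::rpois(n, cfg$mean_messages[["b"]]) else rep(0L, n)

  roles_of_session <- function(h, o, b) {
    ho <- character(h + o)
    # alternate h/o starting with the help seeker; leftovers trail
    k <- min(h, o)
    if (k > 0) ho[seq_len(2 * k)] <- rep(c("h", "o"), k)
    if (h > k) ho[(2 * k + 1):(h + o)] <- "h"
    if (o > k) ho[(2 * k + 1):(h + o)] <- "o"
    if (b > 0) {
      pos <- sort(sample.int(h + o + b, b))
      out <- character(h + o + b)
      out[pos] <- "b"
      out[-pos] <- ho
      out
    } else ho
  }
  roles <- unlist(lapply(seq_len(n), function(i)
    roles_of_session(nh[i], no[i], nb[i])), use.names = FALSE)
  k_all <- nh + no + nb
  sid_col <- rep(sids, k_all)

  tvals <- unlist(lapply(k_all, function(k) {
    if (k == 0L) return(numeric())
    cumsum(c(0, sample(5:120, max(k - 1L, 0L), replace = TRUE)))
  }), use.names = FALSE)

  total <- length(roles)
  lens <- sample(cfg$sentence_length[1]:cfg$sentence_length[2], total,
                 replace = TRUE)
  words <- sample(fillers, sum(lens), replace = TRUE)
  texts <- vapply(split(words, rep.int(seq_len(total), lens)),
                  paste, character(1), collapse = " ")
  names(texts) <- NULL

  truth_cat <- rep(NA_character_, total)
  truth_id <- rep(NA_integer_, total)
  p_by_role <- rowSums(cfg$injection)
  if (cfg$independent_injection) {
    for (cc in codes) {
      u <- stats::runif(total)
      sel <- u < cfg$injection[roles, cc]
      for (i in which(sel)) {
        cand <- lex[lex$category_code == cc, , drop = FALSE]
        pick <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
        real <- realize_pattern(pick, fillers)
        pos <- sample.int(lens[i] + 1L, 1L) - 1L
        w <- strsplit(texts[i], " ", fixed = TRUE)[[1]]
        texts[i] <- paste(append(w, real, after = pos), collapse = " ")
        truth_cat[i] <- if (is.na(truth_cat[i])) cc
          else paste(truth_cat[i], cc, sep = ";")
        truth_id[i] <- pick$id  # last one wins in the scalar column
      }
    }
  } else {
    u <- stats::runif(total)
    inject <- u < p_by_role[roles]
    for (i in which(inject)) {
      pr <- cfg$injection[roles[i], ]
      cc <- sample(codes, 1L, prob = pr / sum(pr))
      cand <- lex[lex$category_code == cc, , drop = FALSE]
      pick <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
      real <- realize_pattern(pick, fillers)
      pos <- sample.int(lens[i] + 1L, 1L) - 1L
      w <- strsplit(texts[i], " ", fixed = TRUE)[[1]]
      texts[i] <- paste(append(w, real, after = pos), collapse = " ")
      truth_cat[i] <- cc
      truth_id[i] <- pick$id
    }
  }

  sessions <- data.frame(session_id = sids, start_date = starts,
                         stringsAsFactors = FALSE)
  messages <- data.frame(session_id = sid_col, role = roles, t = tvals,
                         text = texts, stringsAsFactors = FALSE)
  corpus <- cds_corpus(sessions, messages, mode = "chat")
  truth <- data.frame(session_id = sid_col,
                      msg_index = corpus$messages$msg_index,
                      role = roles, category = truth_cat,
                      pattern_id = truth_id, stringsAsFactors = FALSE)
  structure(list(corpus = corpus, truth = truth, config = cfg),
            class = "cds_simulation")
}
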