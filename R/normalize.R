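#' Normalize text for matching
#'
#' Applies the package-wide normalization convention used on both message
#' text and lexicon patterns before any matching takes place: Unicode NFC
#' (so composed and decomposed accented characters compare equal),
#' lower-casing, and collapsing of whitespace runs (spaces, tabs, newlines)
#' to single spaces. Punctuation is left in place; gap constructs in
#' patterns may traverse it.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_text("Dat  ZOU\nkunnen")
normalize_text <- function(x) {
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- stringi::stri_trans_tolower(x)
  stringi::stri_replace_all_regex(x, "\\s+", " ")
}

# Typographic quote artifacts that occur in the printed lexicon rows.
# Stripped from normalized pattern text, preserved in the raw text.
.quote_chars <- "[\"“”„]"
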