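#' Tokenize a text string
#'
#' Lowercases, splits on whitespace, and strips punctuation from token
#' edges (interior apostrophes etc. are kept). Suited to short lowercase
#' social-media style text and to the synthetic word-like vocabulary.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize_text("I like to read, a lot!")
#' @export
tokenize_text <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "\\s+")[[1]]
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks[nzchar(toks)]
}

#' Read a JSONL corpus
#'
#' One JSON object per line, UTF-8. Recognized fields: `message_id` (required
#' in strict mode), `participant_id`, `text`, `tokens`, `scores_raw`,
#' `scores_std`. In lenient mode malformed lines are skipped with a warning
#' naming the line numbers; in strict mode they are fatal.
#'
#' @param path Path to a JSONL file.
#' @param strict Logical; if `TRUE` malformed lines abort the read.
#' @return List of corpus records (each a list), with attribute `n_skipped`.
#' @export
read_corpus <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty corpus file: ", path, call. = FALSE)
    out <- list()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  records <- vector("list", length(lines))
  bad <- integer(0)
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    ok <- is.list(rec) && (!strict || !is.null(rec$message_id))
    if (!ok) {
      if (strict) {
        stop(sprintf("malformed corpus line %d in %s", i, path), call. = FALSE)
      }
      bad <- c(bad, i)
      next
    }
    if (!is.null(rec$tokens)) rec$tokens <- as.character(rec$tokens)
    records[[i]] <- rec
  }
  if (length(bad) > 0) {
    warning(sprintf("skipped %d malformed line(s): %s", length(bad),
                    paste(utils::head(bad, 10), collapse = ", ")),
            call. = FALSE)
    records <- records[-bad]
  }
  records <- records[!vapply(records, is.null, logical(1))]
  ids <- vapply(records, function(r) as.character(r$message_id %||% NA),
                character(1))
  if (anyDuplicated(stats::na.omit(ids))) {
    warning("duplicate message_id values in ", path, call. = FALSE)
  }
  attr(records, "n_skipped") <- length(bad)
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSONL corpus
#'
#' @param records List of corpus records (lists with fields such as
#'   `message_id`, `participant_id`, `text`, `tokens`, `scores_raw`,
#'   `scores_std`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (rec in records) {
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(line, con, useBytes = TRUE)
  }
  invisible(path)
}

# default patterns for extraneous content
.link_pattern <- "(https?://|www\\.)\\S+"
.hashtag_pattern <- "#\\w+"
.emoji_code_pattern <- ":[a-z_]+:"

#' Preprocess a corpus of records
#'
#' Applies the study-style filters: drops records with fewer than
#' `min_words` tokens, drops records containing links, and strips hashtags
#' and emoji codes before tokenization. In `blog_mode`, each text is split
#' into sentences (on terminal punctuation) and truncated to the shortest
#' sentence prefix whose cumulative word count first reaches
#' `blog_target_words`.
#'
#' @param records List of corpus records (with `text` and/or `tokens`).
#' @param min_words Minimum surviving token count (default 5).
#' @param strip_patterns Character vector of regexes removed from the text
#'   before tokenization (defaults: hashtags, `:emoji_code:` sequences).
#' @param link_pattern Regex identifying links; a match drops the record.
#' @param blog_mode Logical; apply sentence-prefix truncation.
#' @param blog_target_words Cumulative word threshold for `blog_mode`
#'   (default 30).
#' @return Filtered list of records, each with refreshed `tokens`; attribute
#'   `n_dropped` counts removals.
#' @export
preprocess_corpus <- function(records, min_words = 5,
                              strip_patterns = c(.hashtag_pattern,
                                                 .emoji_code_pattern),
                              link_pattern = .link_pattern,
                              blog_mode = FALSE, blog_target_words = 30) {
  keep <- logical(length(records))
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    text <- rec$text %||% paste(rec$tokens %||% character(0), collapse = " ")
    if (grepl(link_pattern, text, ignore.case = TRUE)) next
    for (pat in strip_patterns) text <- gsub(pat, " ", text)
    if (blog_mode) text <- .truncate_blog(text, blog_target_words)
    toks <- tokenize_text(text)
    if (length(toks) < min_words) next
    rec$text <- text
    rec$tokens <- toks
    out[[i]] <- rec
    keep[i] <- TRUE
  }
  res <- out[keep]
  attr(res, "n_dropped") <- sum(!keep)
  res
}

# keep the shortest sentence prefix whose cumulative word count first
# reaches `target` words; if the whole text is shorter, keep everything
.truncate_blog <- function(text, target = 30) {
  sentences <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  if (length(sentences) <= 1L) return(text)
  counts <- vapply(sentences, function(s) length(tokenize_text(s)), integer(1))
  cum <- cumsum(counts)
  stop_at <- which(cum >= target)
  n_keep <- if (length(stop_at) == 0) length(sentences) else stop_at[1]
  paste(sentences[seq_len(n_keep)], collapse = " ")
}
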