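#' Partial-ratio string similarity
#'
#' Similarity between a pair of strings on a 0-100 scale: the shorter string
#' (length m) is slid across every length-m substring of the longer string,
#' Levenshtein distance is computed for each window, and the best window's
#' normalised similarity 100 * (1 - d/m) is returned. Exact matches and
#' substrings therefore score 100. Comparison is case-insensitive and ignores
#' leading/trailing whitespace.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Numeric vector of similarities in \[0, 100\].
#' @export
partial_ratio <- function(a, b) {
  a <- tolower(trimws(a)); b <- tolower(trimws(b))
  mapply(function(x, y) {
    if (nchar(x) > nchar(y)) { tmp <- x; x <- y; y <- tmp }
    m <- nchar(x); n <- nchar(y)
    if (m == 0) return(if (n == 0) 100 else 0)
    windows <- substring(y, seq_len(n - m + 1), seq_len(n - m + 1) + m - 1)
    d <- utils::adist(x, windows)
    100 * (1 - min(d) / m)
  }, a, b, USE.NAMES = FALSE)
}

#' Match free-text treatment records to a product reference list
#'
#' Each free-text treatment record is scored against every product name with
#' the partial-ratio measure; the best-scoring product at or above the
#' similarity threshold assigns its use category. Records below threshold are
#' retained with category `"unmatched"`. Matched products whose names contain
#' a dry-cow keyword set `dry_cow_flag`, so dry-cow therapies can be included
#' or excluded per analysis. Records whose `kind` is not `"treatment"`
#' (directly recorded mastitis/lameness cases) keep their category.
#'
#' @param events Event table with `cow_id`, `date`, `raw_text` and `kind`
#'   (`"mastitis"`, `"lameness"` or `"treatment"`).
#' @param products Product list with columns `name` and `category`
#'   (`"antimicrobial"`, `"anti_inflammatory"`, `"vaccine"`, ...).
#' @param threshold Minimum partial-ratio similarity (default 90) for a match.
#' @param dry_cow_keywords Keywords (regex fragments, case-insensitive) whose
#'   presence in the matched product name flags a dry-cow therapy.
#' @return The event table with `category`, `matched_product`, `match_score`
#'   and `dry_cow_flag` columns; the per-record audit of every match is the
#'   table itself, suitable for manual review.
#' @export
match_treatments <- function(events, products, threshold = 90,
                             dry_cow_keywords = c("dry cow", "\\bDC\\b")) {
  events$category <- ifelse(events$kind %in% c("mastitis", "lameness"),
                            events$kind, "unmatched")
  events$matched_product <- NA_character_
  events$match_score <- NA_real_
  events$dry_cow_flag <- FALSE
  is_trt <- events$kind == "treatment"
  if (!any(is_trt) || nrow(products) == 0) return(dplyr::as_tibble(events))

  txt <- unique(events$raw_text[is_trt])
  scores <- vapply(txt, function(x) partial_ratio(x, products$name),
                   numeric(nrow(products)))
  scores <- matrix(scores, nrow = nrow(products))
  best <- apply(scores, 2, which.max)
  best_score <- scores[cbind(best, seq_along(txt))]
  lut <- dplyr::tibble(
    raw_text = txt,
    matched_product = ifelse(best_score >= threshold, products$name[best], NA),
    match_score = best_score,
    category = ifelse(best_score >= threshold,
                      products$category[best], "unmatched"))
  dc_pattern <- paste(dry_cow_keywords, collapse = "|")
  lut$dry_cow_flag <- !is.na(lut$matched_product) &
    grepl(dc_pattern, lut$matched_product, ignore.case = TRUE)

  i <- match(events$raw_text[is_trt], lut$raw_text)
  events$category[is_trt] <- lut$category[i]
  events$matched_product[is_trt] <- lut$matched_product[i]
  events$match_score[is_trt] <- lut$match_score[i]
  events$dry_cow_flag[is_trt] <- lut$dry_cow_flag[i]
  dplyr::as_tibble(events)
}
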