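#' Boolean query construction
#'
#' A boolean search strategy is an AND/OR tree over terms. `bq_term()`
#' builds a leaf (optionally field-tagged), `bq_and()`/`bq_or()` build
#' connectives over one or more children. The tree serialises to the
#' PubMed dialect via [serialize_pubmed()] and runs against an in-memory
#' corpus via [evaluate_query()].
#'
#' @param text Non-empty term text; multiword terms are matched as phrases.
#' @param field `"title_abstract"` (rendered `[tiab]`) or `"all"`.
#' @param ... Child nodes (terms or connectives), or a single list of them.
#' @return A `bool_query` node.
#' @export
#' @examples
#' q <- bq_and(bq_term("atrial fibrillation"), bq_term("warfarin"))
#' serialize_pubmed(q)
bq_term <- function(text, field = c("title_abstract", "all")) {
  field <- match.arg(field)
  if (!is_nonempty_string(text)) {
    stop_litmine("bq_term: text must be a non-empty string", "config")
  }
  structure(list(op = "term", text = trimws(text), field = field),
            class = c("bq_term", "bool_query"))
}

.bq_children <- function(...) {
  children <- list(...)
  if (length(children) == 1L && is.list(children[[1L]]) &&
      !inherits(children[[1L]], "bool_query")) {
    children <- children[[1L]]
  }
  if (!length(children)) {
    stop_litmine("boolean connective needs at least one child", "config")
  }
  ok <- vapply(children, inherits, logical(1), what = "bool_query")
  if (!all(ok)) stop_litmine("all children must be bool_query nodes", "config")
  children
}

#' @rdname bq_term
#' @export
bq_and <- function(...) {
  structure(list(op = "and", children = .bq_children(...)),
            class = c("bq_and", "bool_query"))
}

#' @rdname bq_term
#' @export
bq_or <- function(...) {
  structure(list(op = "or", children = .bq_children(...)),
            class = c("bq_or", "bool_query"))
}

#' @export
print.bool_query <- function(x, ...) {
  cat("<bool_query> ", serialize_pubmed(x), "\n", sep = "")
  invisible(x)
}

#' Serialize a boolean query to the PubMed search dialect
#'
#' Terms render as `"term"[tiab]` (title/abstract field) or bare `"term"`
#' (all fields); connectives render as fully parenthesised infix with
#' upper-case `AND`/`OR`. [parse_pubmed()] inverts this, and
#' serialize-parse-serialize is a fixed point.
#'
#' @param query A `bool_query`.
#' @return A single string.
#' @export
serialize_pubmed <- function(query) {
  stopifnot(inherits(query, "bool_query"))
  if (query$op == "term") {
    tag <- if (query$field == "title_abstract") "[tiab]" else ""
    return(sprintf('"%s"%s', query$text, tag))
  }
  parts <- vapply(query$children, serialize_pubmed, character(1))
  if (length(parts) == 1L) return(parts)
  sprintf("(%s)", paste(parts, collapse = sprintf(" %s ", toupper(query$op))))
}

#' @rdname serialize_pubmed
#' @param text A serialized query string.
#' @export
parse_pubmed <- function(text) {
  toks <- .pq_lex(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  node <- .pq_expr(st)
  if (st$i <= length(st$toks)) {
    stop_litmine(sprintf("parse_pubmed: trailing input at token %d", st$i), "parse_error")
  }
  node
}

.pq_lex <- function(text) {
  pat <- '"[^"]*"(\\[[a-z]+\\])?|\\(|\\)|AND|OR|[^\\s()]+'
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) stop_litmine("parse_pubmed: empty query", "parse_error")
  regmatches(text, list(m))[[1]]
}

.pq_peek <- function(st) if (st$i <= length(st$toks)) st$toks[st$i] else NA_character_

.pq_next <- function(st) {
  t <- .pq_peek(st)
  st$i <- st$i + 1L
  t
}

# expr := atom ((AND|OR) atom)* ; a run of one operator folds into one node,
# mixing AND and OR at one level without parentheses is rejected.
.pq_expr <- function(st) {
  nodes <- list(.pq_atom(st))
  op <- NULL
  repeat {
    t <- .pq_peek(st)
    if (is.na(t) || t == ")") break
    if (!t %in% c("AND", "OR")) {
      stop_litmine(sprintf("parse_pubmed: expected AND/OR, saw '%s'", t), "parse_error")
    }
    if (!is.null(op) && t != op) {
      stop_litmine("parse_pubmed: mixed AND/OR without parentheses", "parse_error")
    }
    op <- t
    .pq_next(st)
    nodes <- c(nodes, list(.pq_atom(st)))
  }
  if (length(nodes) == 1L) return(nodes[[1L]])
  if (op == "AND") bq_and(nodes) else bq_or(nodes)
}

.pq_atom <- function(st) {
  t <- .pq_next(st)
  if (is.na(t)) stop_litmine("parse_pubmed: unexpected end of input", "parse_error")
  if (t == "(") {
    node <- .pq_expr(st)
    if (!identical(.pq_next(st), ")")) {
      stop_litmine("parse_pubmed: missing closing parenthesis", "parse_error")
    }
    return(node)
  }
  m <- regmatches(t, regexec('^"([^"]*)"(\\[([a-z]+)\\])?$', t))[[1]]
  if (length(m)) {
    field <- if (identical(m[4], "tiab")) "title_abstract" else "all"
    return(bq_term(m[2], field = field))
  }
  bq_term(t, field = "all")
}

# token-list cache for a corpus; computed lazily per evaluate() call
.corpus_tokens <- function(corpus, stem = FALSE) {
  lapply(corpus$studies, function(s) {
    toks <- tokenize(paste(s$title, s$abstract))
    if (stem) stem_tokens(toks) else toks
  })
}

#' Evaluate a boolean query against an in-memory corpus
#'
#' The offline stand-in for search-engine execution. A study matches a
#' term iff the term's tokens occur as a contiguous, case-insensitive
#' token subsequence of its title + abstract (phrase matching, so "art"
#' never matches "heart"); AND intersects and OR unions child match sets.
#' No stemming by default; `stem = TRUE` applies a light suffix stripper
#' to both document and query tokens.
#'
#' @param query A `bool_query`.
#' @param corpus A [linked_corpus()].
#' @param stem Apply light suffix stemming.
#' @return Character vector of matching `study_id`s (unordered set).
#' @export
evaluate_query <- function(query, corpus, stem = FALSE) {
  stopifnot(inherits(query, "bool_query"), inherits(corpus, "linked_corpus"))
  doc_tokens <- .corpus_tokens(corpus, stem = stem)
  ids <- names(doc_tokens)
  ids[.eval_node(query, doc_tokens, stem = stem)]
}

.eval_node <- function(node, doc_tokens, stem) {
  if (node$op == "term") {
    phrase <- tokenize(node$text)
    if (stem) phrase <- stem_tokens(phrase)
    return(vapply(doc_tokens, contains_phrase, logical(1), phrase = phrase))
  }
  masks <- lapply(node$children, .eval_node, doc_tokens = doc_tokens, stem = stem)
  Reduce(if (node$op == "and") `&` else `|`, masks)
}

#' Retrieve ranked search results for a query
#'
#' Orders the [evaluate_query()] match set by descending publication date
#' with ties broken by ascending `study_id` (a deterministic replacement
#' for a search engine's undocumented relevance order), truncated to
#' `limit`.
#'
#' @inheritParams evaluate_query
#' @param limit Maximum number of results (>= 1).
#' @return Character vector of `study_id`s, newest first.
#' @export
retrieve <- function(query, corpus, limit = 3000, stem = FALSE) {
  if (!is_count(limit)) stop_litmine("retrieve: limit must be a positive integer", "config")
  ids <- evaluate_query(query, corpus, stem = stem)
  if (!length(ids)) return(character())
  dates <- as.Date(vapply(ids, function(i) as.character(corpus$studies[[i]]$pub_date),
                          character(1)))
  ord <- order(dates, ids, decreasing = c(TRUE, FALSE), method = "radix")
  utils::head(ids[ord], limit)
}

#' All term texts appearing in a query tree
#'
#' @param query A `bool_query`.
#' @return Character vector of term texts (document order, duplicates kept).
#' @export
query_terms <- function(query) {
  if (query$op == "term") return(query$text)
  unlist(lapply(query$children, query_terms), use.names = FALSE)
}
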