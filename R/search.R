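#' Build a search index over gene features and annotations
#'
#' One entry per gene feature, with the searchable fields: locus tag, gene
#' name, product, genome name, and any annotation identifiers (KO/COG/Pfam)
#' joined per gene. All fields are case-folded at query time.
#'
#' @param genomes Named list of `genome_record`s.
#' @param annotations Optional data frame with columns `genome_id`,
#'   `locus_tag`, `annotation_id` (e.g. KO, COG or Pfam accessions; several
#'   rows per gene allowed).
#' @return A `search_index` data frame with columns `genome_id`, `locus_tag`,
#'   `gene`, `product`, `genome`, `annotations`, `kind`.
#' @export
build_search_index <- function(genomes, annotations = NULL) {
  rows <- lapply(genomes, function(g) {
    fs <- g$features
    if (!nrow(fs)) return(NULL)
    data.frame(genome_id = g$genome_id, locus_tag = fs$locus_tag,
               gene = ifelse(is.na(fs$gene_name), "", fs$gene_name),
               product = ifelse(is.na(fs$product), "", fs$product),
               genome = g$display_name, kind = fs$kind,
               stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, rows)
  idx$annotations <- ""
  if (!is.null(annotations) && nrow(annotations)) {
    key <- paste(annotations$genome_id, annotations$locus_tag)
    agg <- vapply(split(annotations$annotation_id, key),
                  paste, "", collapse = " ")
    m <- match(paste(idx$genome_id, idx$locus_tag), names(agg))
    idx$annotations[!is.na(m)] <- agg[m[!is.na(m)]]
  }
  rownames(idx) <- NULL
  class(idx) <- c("search_index", "data.frame")
  idx
}

#' Parse a search-bar query
#'
#' Grammar: terms are bare words (matched as case-insensitive substrings of
#' any field, `*` matching any run of characters) or `"quoted phrases"`,
#' optionally restricted to one field with a `field:` prefix (fields:
#' locus_tag, gene, product, genome, annotations, kind; field-restricted
#' terms match whole tokens). Operators, recognized case-insensitively, bind
#' NOT tightest, then AND, then OR; adjacency is implicit AND; parentheses
#' group.
#'
#' @param text Query string, e.g. `'trp* AND NOT pseudo'`.
#' @return A `query_ast`: nested list of `term`/`and`/`or`/`not` nodes.
#' @export
parse_query <- function(text) {
  if (!nzchar(trimws(text))) stop("empty query")
  toks <- query_tokenize(text)
  st <- new.env(); st$toks <- toks; st$i <- 1L
  ast <- query_parse_or(st, text)
  if (st$i <= length(st$toks))
    query_error(text, st$toks[[st$i]]$pos,
                paste0("unexpected '", st$toks[[st$i]]$text, "'"))
  structure(ast, class = "query_ast")
}

query_error <- function(text, pos, why) {
  stop(sprintf("query parse error at position %d: %s (in \"%s\")",
               pos, why, text), call. = FALSE)
}

query_tokenize <- function(text) {
  toks <- list()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { toks[[length(toks) + 1L]] <- list(type = "lp", text = "(", pos = i); i <- i + 1L; next }
    if (ch == ")") { toks[[length(toks) + 1L]] <- list(type = "rp", text = ")", pos = i); i <- i + 1L; next }
    if (ch == '"') {
      close <- regexpr('"', substr(text, i + 1L, n))
      if (close < 0) query_error(text, i, "unbalanced quote")
      phrase <- substr(text, i + 1L, i + close - 1L)
      toks[[length(toks) + 1L]] <- list(type = "word", text = phrase, pos = i,
                                        quoted = TRUE)
      i <- i + close + 1L
      next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr('^[^\\s()"]+', substr(text, i, n), perl = TRUE))
    up <- toupper(m)
    type <- if (up %in% c("AND", "OR", "NOT")) tolower(up) else "word"
    toks[[length(toks) + 1L]] <- list(type = type, text = m, pos = i,
                                      quoted = FALSE)
    i <- i + nchar(m)
  }
  toks
}

q_peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
q_next <- function(st) { t <- q_peek(st); st$i <- st$i + 1L; t }

query_parse_or <- function(st, text) {
  left <- query_parse_and(st, text)
  kids <- list(left)
  repeat {
    t <- q_peek(st)
    if (is.null(t) || t$type != "or") break
    op <- q_next(st)
    if (is.null(q_peek(st))) query_error(text, op$pos, "trailing OR")
    kids[[length(kids) + 1L]] <- query_parse_and(st, text)
  }
  if (length(kids) == 1L) kids[[1L]] else list(type = "or", children = kids)
}

query_parse_and <- function(st, text) {
  kids <- list(query_parse_not(st, text))
  repeat {
    t <- q_peek(st)
    if (is.null(t)) break
    if (t$type == "and") {
      op <- q_next(st)
      if (is.null(q_peek(st))) query_error(text, op$pos, "trailing AND")
      kids[[length(kids) + 1L]] <- query_parse_not(st, text)
    } else if (t$type %in% c("word", "not", "lp")) {
      kids[[length(kids) + 1L]] <- query_parse_not(st, text)  # implicit AND
    } else break
  }
  if (length(kids) == 1L) kids[[1L]] else list(type = "and", children = kids)
}

query_parse_not <- function(st, text) {
  t <- q_peek(st)
  if (!is.null(t) && t$type == "not") {
    op <- q_next(st)
    if (is.null(q_peek(st))) query_error(text, op$pos, "trailing NOT")
    return(list(type = "not", child = query_parse_not(st, text)))
  }
  query_parse_atom(st, text)
}

query_parse_atom <- function(st, text) {
  t <- q_peek(st)
  if (is.null(t)) query_error(text, nchar(text) + 1L, "unexpected end of query")
  if (t$type == "lp") {
    q_next(st)
    inner <- query_parse_or(st, text)
    cl <- q_peek(st)
    if (is.null(cl) || cl$type != "rp")
      query_error(text, t$pos, "unbalanced parenthesis")
    q_next(st)
    return(inner)
  }
  if (t$type != "word")
    query_error(text, t$pos, paste0("unexpected '", t$text, "'"))
  q_next(st)
  pat <- t$text
  field <- NA_character_
  if (!isTRUE(t$quoted) && grepl("^[A-Za-z_]+:", pat)) {
    field <- tolower(sub(":.*$", "", pat))
    pat <- sub("^[A-Za-z_]+:", "", pat)
  }
  if (!nzchar(pat)) query_error(text, t$pos, "empty search term")
  list(type = "term", pattern = pat, field = field)
}

#' Execute a parsed query against a search index
#'
#' Bare terms match case-insensitively as substrings of any searchable
#' field; `*` matches any run of characters; a `field:` prefix restricts the
#' term to one field and matches whole whitespace-delimited tokens of it.
#' Boolean operators apply set semantics over the record set. Hits are
#' sorted by genome id, then locus tag.
#'
#' @param ast A `query_ast` from [parse_query()].
#' @param index A `search_index` from [build_search_index()].
#' @return The matching rows of `index` (data frame, possibly empty).
#' @export
execute_query <- function(ast, index) {
  mask <- query_eval(ast, index)
  hits <- index[mask, , drop = FALSE]
  hits <- hits[order(hits$genome_id, hits$locus_tag), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

query_eval <- function(node, index) {
  switch(node$type,
    term = term_mask(node, index),
    and = Reduce(`&`, lapply(node$children, query_eval, index = index)),
    or = Reduce(`|`, lapply(node$children, query_eval, index = index)),
    not = !query_eval(node$child, index),
    stop("unknown query node: ", node$type))
}

search_fields <- c("locus_tag", "gene", "product", "genome", "annotations", "kind")

term_mask <- function(node, index) {
  esc <- gsub("([.^$|()\\[\\]{}+?\\\\])", "\\\\\\1", node$pattern, perl = TRUE)
  rx_body <- gsub("*", ".*", esc, fixed = TRUE)
  if (is.na(node$field)) {
    hit <- rep(FALSE, nrow(index))
    for (f in search_fields)  # substring semantics for bare terms
      hit <- hit | grepl(rx_body, index[[f]], ignore.case = TRUE, perl = TRUE)
    hit
  } else {
    f <- node$field
    if (f == "locus") f <- "locus_tag"
    if (!f %in% search_fields)
      stop("unknown search field: ", node$field,
           " (available: ", paste(search_fields, collapse = ", "), ")")
    rx <- paste0("^", rx_body, "$")  # whole-token semantics
    vapply(strsplit(index[[f]], "\\s+"), function(tokens)
      any(grepl(rx, tokens, ignore.case = TRUE, perl = TRUE)), TRUE)
  }
}
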