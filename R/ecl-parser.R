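# Recursive-descent parser for the implemented ECL subset.
#
# Grammar (whitespace-insensitive, /* */ comments stripped):
#   expression  := refined (connective refined)*        ; one connective kind
#                                                         per level, MINUS
#                                                         binary left-assoc
#   refined     := subexpr [":" refinement]
#   subexpr     := [op] (ID [TERM] | "*" | "(" expression ")")
#   op          := "<" | "<<" | ">" | ">>"
#   refinement  := item ((AND|OR|",") item)*            ; homogeneous
#   item        := [cardinality] ("{" attrs "}" | attr)
#   attrs       := attr ((AND|OR|",") attr)*            ; homogeneous
#   attr        := [cardinality] ["R"] subexpr ("="|"!=") value
#   value       := [op] (ID [TERM] | "*" | "(" expression ")")
#   cardinality := "[" INT ".." (INT|"*") "]"
# Comma is an input synonym for AND inside refinements; it is never emitted.

#' Tokenize ECL text
#'
#' Splits ECL text into typed tokens with 1-based character offsets.
#' Pipe-delimited terms become single `TERM` tokens; `/* ... */` comments
#' are dropped; `R` before an attribute is the reverse marker. Operators
#' must be contiguous (`< <` is not `<<`).
#'
#' @param text a single ECL string.
#' @return data.frame with columns `kind`, `text`, `offset`.
#' @examples
#' ecl_tokenize("<< 64572001 |Disease (disorder)|")
#' @export
ecl_tokenize <- function(text) {
  toks <- tokenize_internal(text)
  data.frame(kind = vapply(toks, `[[`, character(1), "kind"),
             text = vapply(toks, `[[`, character(1), "text"),
             offset = vapply(toks, `[[`, integer(1), "offset"),
             stringsAsFactors = FALSE)
}

parse_error <- function(text, offset, expected, found, code) {
  offset <- min(max(offset, 1L), nchar(text) + 1L)
  before <- substr(text, 1L, offset - 1L)
  line <- 1L + lengths(regmatches(before, gregexpr("\n", before, fixed = TRUE)))
  last_nl <- max(c(0L, gregexpr("\n", before, fixed = TRUE)[[1]]))
  col <- offset - last_nl
  stop(errorCondition(
    sprintf("ECL parse error at %d:%d [%s]: expected %s, found %s",
            line, col, code, expected, found),
    class = c("ecl_parse_error", "eclkit_error"),
    offset = as.integer(offset), expected = expected, found = found, code = code))
}

tokenize_internal <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  toks <- list()
  pos <- 1L
  push <- function(kind, lexeme, offset) {
    toks[[length(toks) + 1L]] <<- list(kind = kind, text = lexeme, offset = offset)
  }
  two <- c("<<" = "OP", ">>" = "OP", "!=" = "COMPARATOR", ".." = "CARD_SEP")
  one <- c("<" = "OP", ">" = "OP", "=" = "COMPARATOR", "{" = "LBRACE", "}" = "RBRACE",
           "(" = "LPAREN", ")" = "RPAREN", "[" = "LBRACKET", "]" = "RBRACKET",
           "*" = "STAR", ":" = "COLON", "," = "COMMA")
  while (pos <= n) {
    ch <- chars[pos]
    if (grepl("^[[:space:]]$", ch)) { pos <- pos + 1L; next }
    if (ch == "/" && pos < n && chars[pos + 1L] == "*") {
      rest <- substr(text, pos + 2L, n)
      end <- regexpr("*/", rest, fixed = TRUE)
      if (end == -1L) parse_error(text, pos, "'*/' closing the comment",
                                  "end of input", "UNTERMINATED_COMMENT")
      pos <- pos + 2L + end + 1L
      next
    }
    if (ch == "|") {
      rest <- substr(text, pos + 1L, n)
      end <- regexpr("|", rest, fixed = TRUE)
      if (end == -1L) parse_error(text, pos, "closing '|'", "end of input",
                                  "UNTERMINATED_TERM")
      push("TERM", substr(rest, 1L, end - 1L), pos)
      pos <- pos + 1L + end
      next
    }
    if (grepl("^[0-9]$", ch)) {
      m <- regexpr("^[0-9]+", substr(text, pos, n))
      lex <- regmatches(substr(text, pos, n), m)
      push("ID", lex, pos)
      pos <- pos + nchar(lex)
      next
    }
    if (grepl("^[A-Za-z]$", ch)) {
      m <- regexpr("^[A-Za-z]+", substr(text, pos, n))
      lex <- regmatches(substr(text, pos, n), m)
      up <- toupper(lex)
      if (up %in% c("AND", "OR", "MINUS")) push("KEYWORD", up, pos)
      else if (lex == "R") push("REVERSE", lex, pos)
      else parse_error(text, pos, "a keyword (AND, OR, MINUS) or 'R'", lex,
                       "UNKNOWN_TOKEN")
      pos <- pos + nchar(lex)
      next
    }
    pair <- substr(text, pos, pos + 1L)
    if (pair %in% names(two)) {
      push(two[[pair]], pair, pos)
      pos <- pos + 2L
      next
    }
    if (ch %in% names(one)) {
      push(one[[ch]], ch, pos)
      pos <- pos + 1L
      next
    }
    parse_error(text, pos, "a valid ECL token", ch, "UNKNOWN_TOKEN")
  }
  toks
}

# parser state: environment with the source text, token list and cursor
new_parser <- function(text) {
  st <- new.env(parent = emptyenv())
  st$text <- text
  st$toks <- tokenize_internal(text)
  st$i <- 1L
  st
}

peek <- function(st) {
  if (st$i > length(st$toks)) list(kind = "EOF", text = "end of input",
                                   offset = nchar(st$text) + 1L)
  else st$toks[[st$i]]
}

advance <- function(st) {
  tok <- peek(st)
  st$i <- st$i + 1L
  tok
}

expect <- function(st, kind, expected, code = "UNEXPECTED_TOKEN") {
  tok <- peek(st)
  if (tok$kind != kind) parse_error(st$text, tok$offset, expected, tok$text, code)
  advance(st)
}

#' Parse ECL text into an expression constraint
#'
#' On failure raises a condition of class `ecl_parse_error` carrying
#' `offset` (1-based character position), `expected`, `found` and an error
#' `code` such as `AMBIGUOUS_OPERATORS` (two different connectives at one
#' level without parentheses), `MALFORMED_CARDINALITY`,
#' `UNBALANCED_BRACES`, `UNTERMINATED_TERM` or `INVALID_SCTID`. Nothing is
#' silently repaired.
#'
#' @param text a single ECL string.
#' @return an `ecl_expression` satisfying the model invariants.
#' @examples
#' parse_ecl("<< 64572001 |Disease (disorder)|")
#' @export
parse_ecl <- function(text) {
  st <- new_parser(text)
  if (!length(st$toks)) {
    parse_error(text, 1L, "an expression constraint", "end of input", "EMPTY_INPUT")
  }
  e <- p_expression(st)
  tok <- peek(st)
  if (tok$kind != "EOF") {
    parse_error(st$text, tok$offset, "end of input", tok$text, "TRAILING_INPUT")
  }
  e
}

p_expression <- function(st) {
  first <- p_refined(st)
  tok <- peek(st)
  if (tok$kind != "KEYWORD") return(first)
  op <- tok$text
  if (op == "MINUS") {
    acc <- first
    while (peek(st)$kind == "KEYWORD") {
      tok <- peek(st)
      if (tok$text != "MINUS") {
        parse_error(st$text, tok$offset, "MINUS (parenthesize to mix operators)",
                    tok$text, "AMBIGUOUS_OPERATORS")
      }
      advance(st)
      rhs <- p_refined(st)
      acc <- normalize_expr(structure(list(kind = "compound", op = "MINUS",
                                           operands = list(acc, rhs)),
                                      class = "ecl_expression"))
    }
    return(acc)
  }
  operands <- list(first)
  while (peek(st)$kind == "KEYWORD") {
    tok <- peek(st)
    if (tok$text != op) {
      parse_error(st$text, tok$offset,
                  sprintf("%s (parenthesize to mix operators)", op),
                  tok$text, "AMBIGUOUS_OPERATORS")
    }
    advance(st)
    operands <- c(operands, list(p_refined(st)))
  }
  normalize_expr(structure(list(kind = "compound", op = op, operands = operands),
                           class = "ecl_expression"))
}

p_refined <- function(st) {
  sub <- p_subexpression(st)
  refinement <- NULL
  if (peek(st)$kind == "COLON") {
    advance(st)
    refinement <- p_refinement(st)
  }
  normalize_expr(structure(list(kind = "simple", op = sub$op, focus = sub$focus,
                                refinement = refinement),
                           class = "ecl_expression"))
}

p_subexpression <- function(st) {
  op <- "self"
  if (peek(st)$kind == "OP") op <- advance(st)$text
  tok <- peek(st)
  if (tok$kind == "ID") {
    advance(st)
    if (!is_sctid(tok$text)) {
      parse_error(st$text, tok$offset, "a SCTID (6-18 digits, no leading zero)",
                  tok$text, "INVALID_SCTID")
    }
    term <- NULL
    if (peek(st)$kind == "TERM") term <- advance(st)$text
    focus <- structure(list(kind = "concept", id = tok$text, term = term),
                       class = "ecl_focus")
  } else if (tok$kind == "STAR") {
    advance(st)
    focus <- structure(list(kind = "wildcard"), class = "ecl_focus")
  } else if (tok$kind == "LPAREN") {
    advance(st)
    inner <- p_expression(st)
    expect(st, "RPAREN", "')'")
    focus <- structure(list(kind = "nested", expr = inner), class = "ecl_focus")
  } else {
    parse_error(st$text, tok$offset, "a concept id, '*' or '('", tok$text,
                "UNEXPECTED_TOKEN")
  }
  list(op = op, focus = focus)
}

ref_connective <- function(st, current, context) {
  tok <- peek(st)
  if (tok$kind == "COMMA") k <- "AND"
  else if (tok$kind == "KEYWORD" && tok$text %in% c("AND", "OR")) k <- tok$text
  else return(NULL)
  if (!is.null(current) && k != current) {
    parse_error(st$text, tok$offset,
                sprintf("%s (parenthesize to mix operators in a %s)", current, context),
                tok$text, "AMBIGUOUS_OPERATORS")
  }
  advance(st)
  k
}

p_refinement <- function(st) {
  items <- list(p_ref_item(st))
  conn <- NULL
  repeat {
    k <- ref_connective(st, conn, "refinement")
    if (is.null(k)) break
    conn <- k
    items <- c(items, list(p_ref_item(st)))
  }
  structure(list(items = items, connective = conn %||% "AND"),
            class = "ecl_refinement")
}

p_ref_item <- function(st) {
  card <- NULL
  if (peek(st)$kind == "LBRACKET") card <- p_cardinality(st)
  if (peek(st)$kind == "LBRACE") return(p_group(st, card))
  p_attr_constraint(st, card)
}

p_group <- function(st, card) {
  open <- expect(st, "LBRACE", "'{'")
  constraints <- list(p_attr_constraint(st, NULL))
  conn <- NULL
  repeat {
    k <- ref_connective(st, conn, "role group")
    if (is.null(k)) break
    conn <- k
    constraints <- c(constraints, list(p_attr_constraint(st, NULL)))
  }
  tok <- peek(st)
  if (tok$kind != "RBRACE") {
    parse_error(st$text, tok$offset, "'}' closing the role group", tok$text,
                "UNBALANCED_BRACES")
  }
  advance(st)
  structure(list(cardinality = card %||% card_default(), constraints = constraints,
                 connective = conn %||% "AND"),
            class = "ecl_group")
}

p_attr_constraint <- function(st, card) {
  if (is.null(card) && peek(st)$kind == "LBRACKET") card <- p_cardinality(st)
  reverse <- FALSE
  if (peek(st)$kind == "REVERSE") {
    advance(st)
    reverse <- TRUE
  }
  sub <- p_subexpression(st)
  tok <- peek(st)
  if (tok$kind != "COMPARATOR") {
    parse_error(st$text, tok$offset, "'=' or '!='", tok$text, "UNEXPECTED_TOKEN")
  }
  comparator <- advance(st)$text
  value <- p_value(st)
  structure(list(cardinality = card %||% card_default(), reverse = reverse,
                 attr_op = sub$op, attr_focus = sub$focus,
                 comparator = comparator, value = value),
            class = "ecl_attribute")
}

p_value <- function(st) {
  sub <- p_subexpression(st)
  normalize_expr(structure(list(kind = "simple", op = sub$op, focus = sub$focus,
                                refinement = NULL),
                           class = "ecl_expression"))
}

p_cardinality <- function(st) {
  open <- expect(st, "LBRACKET", "'['")
  tok <- peek(st)
  if (tok$kind != "ID" || !grepl("^[0-9]+$", tok$text)) {
    parse_error(st$text, tok$offset, "a minimum cardinality integer", tok$text,
                "MALFORMED_CARDINALITY")
  }
  min_val <- as.numeric(advance(st)$text)
  tok <- peek(st)
  if (tok$kind != "CARD_SEP") {
    parse_error(st$text, tok$offset, "'..'", tok$text, "MALFORMED_CARDINALITY")
  }
  advance(st)
  tok <- peek(st)
  if (tok$kind == "STAR") {
    advance(st)
    max_val <- Inf
  } else if (tok$kind == "ID" && grepl("^[0-9]+$", tok$text)) {
    max_val <- as.numeric(advance(st)$text)
  } else {
    parse_error(st$text, tok$offset, "a maximum cardinality integer or '*'",
                tok$text, "MALFORMED_CARDINALITY")
  }
  tok <- peek(st)
  if (tok$kind != "RBRACKET") {
    parse_error(st$text, tok$offset, "']'", tok$text, "MALFORMED_CARDINALITY")
  }
  advance(st)
  if (is.finite(max_val) && max_val < min_val) {
    parse_error(st$text, open$offset, "min <= max in the cardinality",
                sprintf("[%d..%d]", min_val, max_val), "MALFORMED_CARDINALITY")
  }
  structure(list(min = min_val, max = max_val), class = "ecl_cardinality")
}
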