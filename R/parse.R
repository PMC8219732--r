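#' Parse a motif query written in the motif DSL
#'
#' The DSL is a line-oriented, whitespace-agnostic language for describing
#' query graphs (the grammar ships with the package in EBNF, see
#' `system.file("grammar", "motif.ebnf", package = "motifquery")`):
#'
#' \preformatted{
#' # comments run from a hash to end of line
#' A -> B                      # required directed edge
#' A -> B [weight >= 10]       # ... with edge-attribute constraints
#' A !> C                      # forbidden edge (non-edge)
#' A.size > 50                 # node-attribute constraint
#' A.radius > B.radius         # inter-node comparison
#' A === B                     # declared interchangeable nodes
#' dual(x, y) {                # macro with local arguments
#'   x -> y
#'   y -> x
#' }
#' dual(A, B)                  # macro call; macros may call macros
#' }
#'
#' Leading comment lines of the form `# key: value` are read as provenance
#' metadata; the keys `exact_match` and `ignore_direction` (values
#' true/false) set the corresponding match-mode flags.
#'
#' @param source DSL text (single string or character vector of lines), or a
#'   path to a `.motif` file when `is_file = TRUE`.
#' @param is_file treat `source` as a file path.
#' @param exact_match,ignore_direction optional overrides of the match-mode
#'   flags; default NULL defers to provenance directives (else FALSE).
#' @return a [motif()] object with all macros expanded.
#' @examples
#' m <- parse_motif("A -> B\nB -> C\nA !> C")
#' @export
parse_motif <- function(source, is_file = FALSE,
                        exact_match = NULL, ignore_direction = NULL) {
  if (is_file) source <- readLines(source, warn = FALSE)
  text <- paste(source, collapse = "\n")
  prov <- scrape_provenance(text)
  lines <- strip_comments(text)
  parsed <- read_statements(lines)
  stmts <- expand_macros(parsed$statements, parsed$macros)
  flags <- list(exact_match = exact_match, ignore_direction = ignore_direction)
  for (f in names(flags)) {
    if (is.null(flags[[f]])) {
      flags[[f]] <- identical(tolower(prov[[f]] %||% "false"), "true")
    }
    prov[[f]] <- NULL
  }
  build_motif(stmts, prov, flags$exact_match, flags$ignore_direction)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- lexical layer -------------------------------------------------------

IDENT_RE <- "[A-Za-z_][A-Za-z0-9_]*"

# Remove hash comments (respecting double-quoted strings); returns lines.
strip_comments <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  vapply(lines, function(ln) {
    chars <- strsplit(ln, "")[[1]]
    in_str <- FALSE
    for (i in seq_along(chars)) {
      if (chars[i] == '"') in_str <- !in_str
      if (chars[i] == "#" && !in_str) return(substr(ln, 1, i - 1))
    }
    ln
  }, "", USE.NAMES = FALSE)
}

scrape_provenance <- function(text) {
  prov <- list()
  for (ln in strsplit(text, "\n", fixed = TRUE)[[1]]) {
    t <- trimws(ln)
    if (t == "") next
    if (!startsWith(t, "#")) break  # provenance is the leading comment block
    m <- regmatches(t, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_ ]*?)\\s*:\\s*(.*)$", t))[[1]]
    if (length(m) == 3) prov[[m[2]]] <- m[3]
  }
  prov
}

# Split a string on `sep` at top level (outside quotes/brackets/parens).
split_top_level <- function(s, sep = ",") {
  chars <- strsplit(s, "")[[1]]
  depth <- 0; in_str <- FALSE; parts <- character(); cur <- character()
  for (ch in chars) {
    if (ch == '"') in_str <- !in_str
    if (!in_str) {
      if (ch %in% c("[", "(")) depth <- depth + 1
      if (ch %in% c("]", ")")) depth <- depth - 1
      if (ch == sep && depth == 0) {
        parts <- c(parts, paste(cur, collapse = ""))
        cur <- character()
        next
      }
    }
    cur <- c(cur, ch)
  }
  c(parts, paste(cur, collapse = ""))
}

parse_error <- function(lineno, line, why) {
  stop(sprintf("motif DSL syntax error at line %d: %s\n  >> %s",
               lineno, why, trimws(line)), call. = FALSE)
}

# ---- statement layer -----------------------------------------------------

# Reads comment-stripped lines into top-level statements and macro
# definitions. Braces are normalized onto their own logical lines so a macro
# body may open on the header line and close after its last statement.
read_statements <- function(lines) {
  raw <- data.frame(no = seq_along(lines), text = lines,
                    stringsAsFactors = FALSE)
  units <- list()
  for (i in seq_len(nrow(raw))) {
    txt <- gsub("\\{", "\n{\n", raw$text[i])
    txt <- gsub("\\}", "\n}\n", txt)
    for (piece in strsplit(txt, "\n", fixed = TRUE)[[1]]) {
      for (stmt in split_top_level(piece, ";")) {
        stmt <- trimws(stmt)
        if (nzchar(stmt)) units[[length(units) + 1]] <- list(no = raw$no[i], text = stmt)
      }
    }
  }
  macros <- list()
  statements <- list()
  i <- 1
  while (i <= length(units)) {
    u <- units[[i]]
    call_m <- regmatches(u$text, regexec(
      paste0("^(", IDENT_RE, ")\\s*\\((.*)\\)$"), u$text))[[1]]
    is_def <- length(call_m) == 3 && i < length(units) &&
      units[[i + 1]]$text == "{"
    if (is_def) {
      name <- call_m[2]
      params <- trimws(split_top_level(call_m[3]))
      params <- params[nzchar(params)]
      if (!all(grepl(paste0("^", IDENT_RE, "$"), params)) || anyDuplicated(params)) {
        parse_error(u$no, u$text, "macro parameters must be distinct identifiers")
      }
      body <- list()
      j <- i + 2
      while (j <= length(units) && units[[j]]$text != "}") {
        body[[length(body) + 1]] <- parse_statement(units[[j]]$text, units[[j]]$no)
        j <- j + 1
      }
      if (j > length(units)) parse_error(u$no, u$text, "unterminated macro body ('}' missing)")
      if (!is.null(macros[[name]])) parse_error(u$no, u$text, paste0("macro '", name, "' redefined"))
      check_macro_body(name, params, body, macros, u$no)
      macros[[name]] <- list(name = name, params = params, body = body)
      i <- j + 1
    } else if (u$text %in% c("{", "}")) {
      parse_error(u$no, u$text, "unexpected brace outside a macro definition")
    } else {
      statements[[length(statements) + 1]] <- parse_statement(u$text, u$no)
      i <- i + 1
    }
  }
  list(statements = statements, macros = macros)
}

# Node names referenced by a statement (for macro hygiene checks).
statement_names <- function(s) {
  switch(s$type,
         edge = ,
         nonedge = c(s$from, s$to),
         inter = c(s$a, s$b),
         constraint = c(s$subject, if (!is.null(s$rhs_ref)) s$rhs_ref[1]),
         call = s$args,
         character())
}

check_macro_body <- function(name, params, body, known_macros, lineno) {
  for (s in body) {
    if (s$type == "call" && !s$macro %in% c(names(known_macros), name)) {
      stop(sprintf("line %d: macro '%s' calls undefined macro '%s'",
                   s$line, name, s$macro), call. = FALSE)
    }
    bad <- setdiff(statement_names(s), params)
    if (s$type != "call" && length(bad)) {
      stop(sprintf(paste0("line %d: macro '%s' references '%s' which is not a ",
                          "macro parameter (macro locals may not leak into the motif)"),
                   s$line, name, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
}

parse_statement <- function(stmt, lineno) {
  # interchangeability: A === B
  m <- regmatches(stmt, regexec(
    paste0("^(", IDENT_RE, ")\\s*===\\s*(", IDENT_RE, ")$"), stmt))[[1]]
  if (length(m) == 3) return(list(type = "inter", a = m[2], b = m[3], line = lineno))

  # forbidden edge: A !> B   (also accepts !->)
  m <- regmatches(stmt, regexec(
    paste0("^(", IDENT_RE, ")\\s*!-?>\\s*(", IDENT_RE, ")\\s*$"), stmt))[[1]]
  if (length(m) == 3) return(list(type = "nonedge", from = m[2], to = m[3], line = lineno))

  # required edge: A -> B [attr op value, ...]
  m <- regmatches(stmt, regexec(
    paste0("^(", IDENT_RE, ")\\s*->\\s*(", IDENT_RE, ")\\s*(\\[(.*)\\])?\\s*$"), stmt))[[1]]
  if (length(m) >= 3) {
    attrs <- list()
    if (length(m) == 5 && nzchar(m[5])) {
      for (part in split_top_level(m[5])) {
        attrs[[length(attrs) + 1]] <- parse_predicate(part, lineno, stmt)
      }
    }
    return(list(type = "edge", from = m[2], to = m[3], attrs = attrs, line = lineno))
  }

  # node constraint: A.attr op value-or-ref
  m <- regmatches(stmt, regexec(
    paste0("^(", IDENT_RE, ")\\.(", IDENT_RE, ")\\s*(.+)$"), stmt))[[1]]
  if (length(m) == 4) {
    pred <- parse_predicate(paste0(m[3], " ", m[4]), lineno, stmt)
    return(list(type = "constraint", subject = m[2], attribute = pred$attribute,
                op = pred$op, rhs = pred$rhs, rhs_ref = pred$rhs_ref, line = lineno))
  }

  # macro call: name(A, B)
  m <- regmatches(stmt, regexec(
    paste0("^(", IDENT_RE, ")\\s*\\((.*)\\)$"), stmt))[[1]]
  if (length(m) == 3) {
    args <- trimws(split_top_level(m[3]))
    args <- args[nzchar(args)]
    if (!all(grepl(paste0("^", IDENT_RE, "$"), args))) {
      parse_error(lineno, stmt, "macro arguments must be node identifiers")
    }
    return(list(type = "call", macro = m[2], args = args, line = lineno))
  }

  parse_error(lineno, stmt, "unrecognized statement")
}

# "attr op rhs" (for edge attribute lists and the tail of node constraints).
parse_predicate <- function(s, lineno, ctx) {
  s <- trimws(s)
  m <- regmatches(s, regexec(paste0(
    "^(", IDENT_RE, ")\\s*(<=|>=|!=|==|=|<|>|\\bin\\b|\\bcontains\\b)\\s*(.+)$"), s))[[1]]
  if (length(m) != 4) parse_error(lineno, ctx, paste0("cannot parse predicate '", s, "'"))
  op <- if (m[3] == "==") "=" else m[3]
  rhs_txt <- trimws(m[4])
  ref <- regmatches(rhs_txt, regexec(
    paste0("^(", IDENT_RE, ")\\.(", IDENT_RE, ")$"), rhs_txt))[[1]]
  if (length(ref) == 3) {
    return(list(attribute = m[2], op = op, rhs = NULL, rhs_ref = c(ref[2], ref[3])))
  }
  list(attribute = m[2], op = op, rhs = parse_value(rhs_txt, lineno, ctx), rhs_ref = NULL)
}

parse_value <- function(s, lineno, ctx) {
  s <- trimws(s)
  if (startsWith(s, '"')) {
    if (!endsWith(s, '"') || nchar(s) < 2) parse_error(lineno, ctx, "unterminated string")
    return(substr(s, 2, nchar(s) - 1))
  }
  if (startsWith(s, "[")) {
    if (!endsWith(s, "]")) parse_error(lineno, ctx, "unterminated list")
    inner <- substr(s, 2, nchar(s) - 1)
    parts <- trimws(split_top_level(inner))
    parts <- parts[nzchar(parts)]
    return(lapply(parts, parse_value, lineno = lineno, ctx = ctx))
  }
  if (grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", s)) {
    return(as.numeric(s))
  }
  if (s %in% c("true", "false")) return(s == "true")
  parse_error(lineno, ctx, paste0("cannot parse value '", s, "'"))
}

# ---- macro expansion -----------------------------------------------------

#' Expand macro calls into flat statement lists
#'
#' Internal statement records (as produced by the parser) are flattened:
#' every macro call is replaced by its body with parameters substituted by
#' the call arguments, innermost calls first. Macro bodies may only
#' reference their own parameters (checked at definition time), so
#' substitution cannot capture motif node names. Recursive macro chains are
#' rejected with the offending cycle listed.
#'
#' @param statements list of statement records.
#' @param definitions named list of macro definitions
#'   (`list(name, params, body)`).
#' @return flat list of statement records with no `call` entries.
#' @keywords internal
#' @export
expand_macros <- function(statements, definitions) {
  expand_one <- function(stmt, stack) {
    if (stmt$type != "call") return(list(stmt))
    def <- definitions[[stmt$macro]]
    if (is.null(def)) {
      stop(sprintf("line %d: call to undefined macro '%s'", stmt$line, stmt$macro),
           call. = FALSE)
    }
    if (stmt$macro %in% stack) {
      stop("recursive macro expansion: ",
           paste(c(stack, stmt$macro), collapse = " -> "), call. = FALSE)
    }
    if (length(stmt$args) != length(def$params)) {
      stop(sprintf("line %d: macro '%s' expects %d argument(s), got %d",
                   stmt$line, stmt$macro, length(def$params), length(stmt$args)),
           call. = FALSE)
    }
    sub <- stats::setNames(stmt$args, def$params)
    rename <- function(x) ifelse(x %in% names(sub), sub[x], x)
    out <- list()
    for (b in def$body) {
      b2 <- b
      if (b$type %in% c("edge", "nonedge")) {
        b2$from <- unname(rename(b$from)); b2$to <- unname(rename(b$to))
      } else if (b$type == "inter") {
        b2$a <- unname(rename(b$a)); b2$b <- unname(rename(b$b))
      } else if (b$type == "constraint") {
        b2$subject <- unname(rename(b$subject))
        if (!is.null(b$rhs_ref)) b2$rhs_ref[1] <- unname(rename(b$rhs_ref[1]))
      } else if (b$type == "call") {
        b2$args <- unname(rename(b$args))
      }
      out <- c(out, expand_one(b2, c(stack, stmt$macro)))
    }
    out
  }
  flat <- list()
  for (s in statements) flat <- c(flat, expand_one(s, character()))
  flat
}

# ---- motif assembly ------------------------------------------------------

build_motif <- function(stmts, provenance, exact_match, ignore_direction) {
  edges <- matrix(character(), 0, 2)
  forbidden <- matrix(character(), 0, 2)
  node_constraints <- list()
  edge_constraints <- list()
  interchangeable <- list()
  order_seen <- character()
  note <- function(...) order_seen <<- unique(c(order_seen, ...))
  for (s in stmts) {
    if (s$type == "edge") {
      note(s$from, s$to)
      edges <- rbind(edges, c(s$from, s$to))
      for (p in s$attrs) {
        k <- edge_key(s$from, s$to)
        edge_constraints[[k]] <- c(edge_constraints[[k]], list(
          constraint(c(s$from, s$to), p$attribute, p$op, p$rhs, p$rhs_ref)))
      }
    } else if (s$type == "nonedge") {
      note(s$from, s$to)
      forbidden <- rbind(forbidden, c(s$from, s$to))
    } else if (s$type == "constraint") {
      note(s$subject, if (!is.null(s$rhs_ref)) s$rhs_ref[1])
      node_constraints <- c(node_constraints, list(
        constraint(s$subject, s$attribute, s$op, s$rhs, s$rhs_ref)))
    } else if (s$type == "inter") {
      note(s$a, s$b)
      interchangeable <- c(interchangeable, list(c(s$a, s$b)))
    }
  }
  if (nrow(edges) == 0 && nrow(forbidden) == 0) {
    stop("empty motif: the query declares no edges", call. = FALSE)
  }
  motif(edges, forbidden, nodes = order_seen,
        node_constraints = node_constraints,
        edge_constraints = edge_constraints,
        interchangeable = interchangeable,
        exact_match = exact_match,
        ignore_direction = ignore_direction,
        provenance = provenance)
}

# ---- serialization -------------------------------------------------------

#' Serialize a motif to DSL text
#'
#' Writes the expanded motif as a `.motif` file body: a provenance comment
#' header (author, date, match-mode flags, any other metadata) followed by
#' one DSL statement per edge, non-edge, constraint and interchangeability
#' declaration. `parse_motif(serialize_motif(m))` reproduces the motif
#' structure exactly (macros are expanded on parse, so round-trips compare
#' expanded forms).
#'
#' @param m a [motif()] object.
#' @param path optional file to write to.
#' @return the DSL text, invisibly when `path` is given.
#' @export
serialize_motif <- function(m, path = NULL) {
  hdr <- c("# .motif query file")
  prov <- m$provenance
  if (is.null(prov$date)) prov$date <- format(Sys.Date())
  for (k in names(prov)) hdr <- c(hdr, sprintf("# %s: %s", k, prov[[k]]))
  hdr <- c(hdr,
           sprintf("# exact_match: %s", tolower(m$exact_match)),
           sprintf("# ignore_direction: %s", tolower(m$ignore_direction)))
  body <- character()
  for (i in seq_len(nrow(m$edges))) {
    f <- m$edges[i, 1]; t <- m$edges[i, 2]
    cs <- constraints_of_edge(m, f, t)
    attr_txt <- if (length(cs)) {
      paste0(" [", paste(vapply(cs, function(cst) {
        paste(cst$attribute, cst$op, serialize_value(cst))
      }, ""), collapse = ", "), "]")
    } else ""
    body <- c(body, paste0(f, " -> ", t, attr_txt))
  }
  for (i in seq_len(nrow(m$forbidden))) {
    body <- c(body, paste0(m$forbidden[i, 1], " !> ", m$forbidden[i, 2]))
  }
  for (cst in m$node_constraints) {
    body <- c(body, paste0(cst$subject, ".", cst$attribute, " ", cst$op, " ",
                           serialize_value(cst)))
  }
  for (p in m$interchangeable) body <- c(body, paste0(p[1], " === ", p[2]))
  text <- paste(c(hdr, "", body, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

serialize_value <- function(cst) {
  if (!is.null(cst$rhs_ref)) return(paste0(cst$rhs_ref[1], ".", cst$rhs_ref[2]))
  fmt <- function(v) {
    if (is.character(v)) paste0('"', v, '"')
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 15)
  }
  if (is.list(cst$rhs)) {
    paste0("[", paste(vapply(cst$rhs, fmt, ""), collapse = ", "), "]")
  } else fmt(cst$rhs)
}
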