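#' Motif validation
#'
#' Pre-execution validators detect impossible (self-contradictory) queries
#' and optionally biologically implausible ones, so that a user is warned
#' quickly instead of running a long search that is destined to return
#' nothing. Violations are returned as data, never thrown; a motif that
#' fails validation still yields zero matches on every host graph.
#'
#' @name validation
NULL

violation <- function(severity, rule, subject, message) {
  structure(list(severity = severity, rule = rule,
                 subject = paste(subject, collapse = "->"),
                 message = message),
            class = "motif_violation")
}

#' @export
print.motif_violation <- function(x, ...) {
  cat(sprintf("[%s] %s (%s): %s\n", x$severity, x$rule, x$subject, x$message))
  invisible(x)
}

violation_df <- function(violations) {
  if (!length(violations)) {
    return(data.frame(severity = character(), rule = character(),
                      subject = character(), message = character()))
  }
  do.call(rbind, lapply(violations, function(v) {
    data.frame(severity = v$severity, rule = v$rule, subject = v$subject,
               message = v$message, stringsAsFactors = FALSE)
  }))
}

#' Structural validation of a motif
#'
#' Flags ordered node pairs declared both as required and as forbidden
#' edges (an unsatisfiable conflict), and motif nodes that participate in
#' no edge at all (isolated query nodes, typically introduced by a
#' constraint on a mistyped name).
#'
#' @param m a [motif()].
#' @return list of violations (empty when the motif is consistent).
#' @export
validate_structure <- function(m) {
  out <- list()
  if (nrow(m$edges) && nrow(m$forbidden)) {
    rk <- edge_key(m$edges[, 1], m$edges[, 2])
    fk <- edge_key(m$forbidden[, 1], m$forbidden[, 2])
    for (key in intersect(rk, fk)) {
      out <- c(out, list(violation(
        "error", "edge_conflict", key,
        sprintf("edge %s is required but also declared as a non-edge", key))))
    }
  }
  touched <- unique(c(t(m$edges), t(m$forbidden)))
  for (node in setdiff(m$nodes, touched)) {
    out <- c(out, list(violation(
      "error", "isolated_node", node,
      sprintf("node %s participates in no edge of the motif", node))))
  }
  out
}

#' Constraint-satisfiability validation of a motif
#'
#' For every node/edge and attribute, checks that the conjunction of its
#' constraints admits at least one value: numeric bounds must leave a
#' non-empty interval, equalities must not contradict each other, other
#' bounds, or inequalities (`x = "a" AND x != "a"`), and membership lists
#' must intersect. Directly contradictory inter-node comparisons
#' (`A.r > B.r AND B.r > A.r`) are also caught; full constraint-network
#' consistency is out of scope.
#'
#' @param m a [motif()].
#' @return list of violations.
#' @export
validate_constraints <- function(m) {
  out <- list()
  groups <- list()
  refs <- list()
  note <- function(cst) {
    if (!is.null(cst$rhs_ref)) {
      if (length(cst$subject) == 1) refs[[length(refs) + 1]] <<- cst
      return(invisible(NULL))
    }
    key <- paste0(paste(cst$subject, collapse = "->"), ".", cst$attribute)
    groups[[key]] <<- c(groups[[key]], list(cst))
  }
  for (cst in m$node_constraints) note(cst)
  for (k in names(m$edge_constraints)) for (cst in m$edge_constraints[[k]]) note(cst)

  for (key in names(groups)) {
    if (!cset_satisfiable(groups[[key]])) {
      out <- c(out, list(violation(
        "error", "unsatisfiable_constraints", key,
        sprintf("no value of %s can satisfy all of: %s", key,
                paste(vapply(groups[[key]], constraint_string, ""),
                      collapse = " AND ")))))
    }
  }

  # inter-node comparisons: intersect allowed order relations per pair+attr
  if (length(refs)) {
    rel_of <- function(op) switch(op, "<" = "l", "<=" = "le", "=" = "e",
                                  "!=" = "lg", ">" = "g", ">=" = "ge", NULL)
    allowed <- list(l = "l", le = c("l", "e"), e = "e", lg = c("l", "g"),
                    g = "g", ge = c("g", "e"))
    sets <- list()
    labels <- list()
    for (cst in refs) {
      r <- rel_of(cst$op)
      if (is.null(r)) next
      a <- cst$subject; b <- cst$rhs_ref[1]; attr2 <- cst$rhs_ref[2]
      if (cst$attribute != attr2 && a != b) next  # cross-attribute: skip
      flip <- a > b
      key <- paste(if (flip) c(b, a) else c(a, b), collapse = "|")
      key <- paste0(key, ".", cst$attribute)
      rel <- allowed[[r]]
      if (flip) rel <- chartr("lg", "gl", rel)
      sets[[key]] <- if (is.null(sets[[key]])) rel else intersect(sets[[key]], rel)
      labels[[key]] <- c(labels[[key]], constraint_string(cst))
    }
    for (key in names(sets)) {
      if (!length(sets[[key]])) {
        out <- c(out, list(violation(
          "error", "contradictory_comparison", key,
          paste("mutually exclusive inter-node comparisons:",
                paste(labels[[key]], collapse = " AND ")))))
      }
    }
  }
  out
}

# Does a conjunction of single-attribute literal constraints admit a value?
cset_satisfiable <- function(csts) {
  test <- function(v) all(vapply(csts, function(cst) eval_op(cst$op, v, cst$rhs),
                                 logical(1)))
  eqs <- Filter(function(cst) cst$op == "=", csts)
  ins <- Filter(function(cst) cst$op == "in", csts)
  if (length(eqs)) {
    return(any(vapply(eqs, function(cst) test(cst$rhs), logical(1))))
  }
  if (length(ins)) {
    cands <- unlist(lapply(ins, function(cst) as.list(cst$rhs)), recursive = FALSE)
    return(any(vapply(cands, test, logical(1))))
  }
  # numeric bounds: tightest interval, then probe candidate values
  lo <- -Inf; lo_strict <- FALSE; hi <- Inf; hi_strict <- FALSE
  numeric_seen <- FALSE
  str_forbidden <- character()
  for (cst in csts) {
    if (is.numeric(cst$rhs) && cst$op %in% c("<", "<=", ">", ">=")) {
      numeric_seen <- TRUE
      v <- cst$rhs
      if (cst$op %in% c(">", ">=")) {
        if (v > lo || (v == lo && cst$op == ">")) { lo <- v; lo_strict <- cst$op == ">" }
      } else {
        if (v < hi || (v == hi && cst$op == "<")) { hi <- v; hi_strict <- cst$op == "<" }
      }
    } else if (is.character(cst$rhs) && cst$op %in% c("<", "<=", ">", ">=")) {
      # string order bounds are rare; accept (satisfiable by some string)
    } else if (cst$op == "!=") {
      if (is.character(cst$rhs)) str_forbidden <- c(str_forbidden, cst$rhs)
    }
  }
  if (numeric_seen) {
    if (lo > hi || (lo == hi && (lo_strict || hi_strict))) return(FALSE)
    probes <- unique(c(if (is.finite(lo) && !lo_strict) lo,
                       if (is.finite(hi) && !hi_strict) hi,
                       if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2,
                       if (is.finite(lo)) lo + 1,
                       if (is.finite(hi)) hi - 1,
                       0))
    return(any(vapply(probes, test, logical(1))))
  }
  # only != / contains / string-order constraints: pick a fresh string
  probe <- paste0(c("zz", str_forbidden), collapse = "_")
  csts_nc <- Filter(function(cst) cst$op != "contains", csts)
  all(vapply(csts_nc, function(cst) eval_op(cst$op, probe, cst$rhs), logical(1)))
}

#' Biological-plausibility validation
#'
#' Optional validator for neuroscience priors such as Dale's principle: a
#' rule declares an edge attribute (for example synapse `type`) together
#' with groups of mutually exclusive values (e.g. inhibitory transmitters
#' versus excitatory ones). A warning is raised for any motif node whose
#' outgoing required edges carry equality constraints in two or more
#' exclusive groups — a single neuron required to both inhibit and excite.
#' Rules are optional and modifiable: an empty rule set validates anything.
#'
#' @param m a [motif()].
#' @param rules list of rules, each
#'   `list(attribute = "type", exclusive_groups = list(c("GABA"), c("glutamate")))`;
#'   or a path to a YAML/JSON-free key=value config read by
#'   [read_biology_rules()].
#' @return list of violations (severity "warning").
#' @export
validate_biology <- function(m, rules = list()) {
  if (is.character(rules) && length(rules) == 1) rules <- read_biology_rules(rules)
  if (!is.list(rules)) stop("malformed rule configuration: must be a list of rules")
  if (!is.null(rules$attribute)) rules <- list(rules)  # single rule shorthand
  out <- list()
  for (rule in rules) {
    if (is.null(rule$attribute) || is.null(rule$exclusive_groups)) {
      stop("malformed rule configuration: each rule needs $attribute and $exclusive_groups")
    }
    groups <- lapply(rule$exclusive_groups, as.character)
    for (node in m$nodes) {
      vals <- character()
      for (i in seq_len(nrow(m$edges))) {
        if (m$edges[i, 1] != node) next
        for (cst in constraints_of_edge(m, m$edges[i, 1], m$edges[i, 2])) {
          if (cst$attribute == rule$attribute && cst$op == "=" &&
              is.character(cst$rhs)) {
            vals <- c(vals, cst$rhs)
          }
        }
      }
      gidx <- unique(unlist(lapply(vals, function(v) {
        which(vapply(groups, function(g) v %in% g, logical(1)))
      })))
      if (length(gidx) > 1) {
        out <- c(out, list(violation(
          "warning", "exclusive_edge_types", node,
          sprintf("node %s has outgoing edges constrained to mutually exclusive %s values: %s",
                  node, rule$attribute, paste(unique(vals), collapse = ", ")))))
      }
    }
  }
  out
}

#' Read a biological-rule configuration file
#'
#' Plain-text key/value format: one rule per block,
#' \preformatted{
#' attribute: type
#' exclusive: GABA, glycine
#' exclusive: glutamate, acetylcholine
#' }
#' Blocks are separated by blank lines; each `exclusive:` line lists one
#' group of interchangeable values, and the groups of a rule are mutually
#' exclusive with each other.
#'
#' @param path file path.
#' @return list of rules for [validate_biology()].
#' @export
read_biology_rules <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!startsWith(lines, "#")]
  rules <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$attribute)) rules[[length(rules) + 1]] <<- cur
    cur <<- NULL
  }
  for (ln in lines) {
    if (ln == "") { flush(); next }
    kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("malformed rule configuration line: ", ln)
    if (kv[2] == "attribute") {
      flush()
      cur <- list(attribute = kv[3], exclusive_groups = list())
    } else if (kv[2] == "exclusive") {
      if (is.null(cur)) stop("malformed rule configuration: 'exclusive' before 'attribute'")
      cur$exclusive_groups <- c(cur$exclusive_groups,
                                list(trimws(strsplit(kv[3], ",")[[1]])))
    } else {
      stop("malformed rule configuration key: ", kv[2])
    }
  }
  flush()
  rules
}

#' Run all validators on a motif
#'
#' @param m a [motif()].
#' @param rules optional biological rules for [validate_biology()].
#' @return data.frame with columns severity, rule, subject, message
#'   (zero rows when the motif passes).
#' @export
validate_motif <- function(m, rules = list()) {
  violation_df(c(validate_structure(m), validate_constraints(m),
                 validate_biology(m, rules)))
}
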