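# Reader/writer for a small OBO 1.4 dialect.
#
# Supported: a `format-version` header line, `[Term]` stanzas with tags
# `id`, `name`, `namespace` (the term category), `is_a: <id>` and
# `relationship: has_part <id>`. Trailing `! comment` text is stripped.
# has_part is the only parthood relation of the dialect: part_of is not
# universally quantifiable over cell parts (a molecule is not confined to
# one whole), so a part_of tag is a hard parse error rather than being
# silently inverted.

strip_obo_comment <- function(x) {
  sub("\\s*!.*$", "", x)
}

#' Read an ontology from an OBO-subset file
#'
#' Parses the dialect described above and returns a validated
#' [ceq_ontology()]. Unknown tags inside a `[Term]` stanza are ignored
#' with a warning; a malformed stanza, a missing `id`, a `part_of` (or any
#' non-`has_part`) relationship type, or a result failing
#' [validate_ontology()] is an error carrying the offending line number.
#'
#' @param path File to read (UTF-8, LF line endings).
#' @param kind Ontology kind; if `NULL`, inferred from the term categories.
#' @return A valid [ceq_ontology()].
#' @export
read_obo <- function(path, kind = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parse_err <- function(i, msg) {
    abort(sprintf("%s (line %d): %s", path, i, msg))
  }

  term_rows <- list()
  edge_rows <- list()
  unknown_tags <- character()
  cur <- NULL          # list(id, name, namespace, edges = list of c(rel, obj))
  cur_line <- NA_integer_
  in_header <- TRUE
  in_skipped <- FALSE

  flush_term <- function() {
    if (is.null(cur)) return(invisible())
    if (is.null(cur$id)) parse_err(cur_line, "[Term] stanza without an id tag")
    term_rows[[length(term_rows) + 1]] <<- tibble(
      id = cur$id,
      label = if (is.null(cur$name)) "" else cur$name,
      category = if (is.null(cur$namespace)) NA_character_ else cur$namespace)
    for (e in cur$edges) {
      edge_rows[[length(edge_rows) + 1]] <<- tibble(
        subject = cur$id, relation = e[[1]], object = e[[2]])
    }
    cur <<- NULL
    invisible()
  }

  for (i in seq_along(lines)) {
    line <- strip_obo_comment(trimws(lines[[i]]))
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush_term()
      in_header <- FALSE
      if (line == "[Term]") {
        cur <- list(edges = list())
        cur_line <- i
        in_skipped <- FALSE
      } else {
        warn(sprintf("skipping unsupported stanza %s at line %d", line, i))
        in_skipped <- TRUE
      }
      next
    }
    if (in_skipped || in_header) {
      if (in_header && !grepl("^[A-Za-z_-]+:", line)) {
        parse_err(i, sprintf("cannot parse header line '%s'", line))
      }
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z_-]+):\\s*(.*)$", line))[[1]]
    if (length(m) == 0) parse_err(i, sprintf("cannot parse line '%s'", line))
    tag <- m[[2]]
    value <- trimws(m[[3]])
    if (tag == "id") {
      if (value == "") parse_err(i, "empty id")
      cur$id <- value
    } else if (tag == "name") {
      cur$name <- value
    } else if (tag == "namespace") {
      cur$namespace <- value
    } else if (tag == "is_a") {
      if (value == "") parse_err(i, "is_a without a target id")
      cur$edges[[length(cur$edges) + 1]] <- c("is_a", value)
    } else if (tag == "relationship") {
      parts <- strsplit(value, "\\s+")[[1]]
      if (length(parts) != 2) {
        parse_err(i, "relationship tag must be '<type> <id>'")
      }
      if (parts[[1]] != "has_part") {
        parse_err(i, sprintf(
          "relationship type '%s' is outside the dialect (only has_part)",
          parts[[1]]))
      }
      cur$edges[[length(cur$edges) + 1]] <- c("has_part", parts[[2]])
    } else {
      unknown_tags <- c(unknown_tags, tag)
    }
  }
  flush_term()

  if (length(unknown_tags) > 0) {
    warn(sprintf("ignored unknown tag(s): %s",
                 paste(sort(unique(unknown_tags)), collapse = ", ")))
  }

  terms <- if (length(term_rows) > 0) bind_rows(term_rows) else
    tibble(id = character(), label = character(), category = character())
  edges <- if (length(edge_rows) > 0) bind_rows(edge_rows) else NULL
  onto <- ceq_ontology(terms, edges, kind = kind)
  rep <- validate_ontology(onto)
  if (nrow(rep) > 0) {
    abort(c(sprintf("'%s' parsed but the ontology is invalid", path),
            stats::setNames(paste(rep$rule, rep$item, sep = ": "),
                            rep("x", nrow(rep)))))
  }
  onto
}

#' Write an ontology to an OBO-subset file
#'
#' Deterministic serialization: terms sorted by id; tags emitted in the
#' fixed order `id`, `name`, `namespace`, `is_a` (targets sorted),
#' `relationship: has_part` (targets sorted). [read_obo()] on the output
#' reproduces the ontology exactly, and two writes are byte-identical.
#' Refuses to write an invalid ontology, reporting its violations.
#'
#' @param ontology A valid [ceq_ontology()].
#' @param path Output file (UTF-8, LF line endings).
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  assert_valid_ontology(ontology)
  terms <- ontology$terms |> arrange(.data$id)
  edges <- ontology$edges
  out <- c("format-version: 1.4", "")
  for (k in seq_len(nrow(terms))) {
    t <- terms[k, ]
    isa <- sort(edges$object[edges$subject == t$id & edges$relation == "is_a"])
    hp <- sort(edges$object[edges$subject == t$id & edges$relation == "has_part"])
    out <- c(out,
             "[Term]",
             paste0("id: ", t$id),
             paste0("name: ", t$label),
             paste0("namespace: ", t$category),
             if (length(isa)) paste0("is_a: ", isa),
             if (length(hp)) paste0("relationship: has_part ", hp),
             "")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
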