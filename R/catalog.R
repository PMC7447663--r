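#' Term catalogs and group queries
#'
#' A `term_catalog` is a miniature stand-in for a licensed regulatory
#' event dictionary: a flat set of preferred terms (PTs) plus named group
#' queries, each group a set of member PTs. Every group member must be a
#' catalog term; a term may belong to several groups.
#'
#' @param terms Character vector of preferred terms.
#' @param groups Named list of character vectors; each element is one group
#'   query.
#' @return An object of class `term_catalog` with elements `terms` and
#'   `groups`.
#' @seealso [builtin_endocrine_catalog()] for the shipped endocrine catalog.
#' @export
term_catalog <- function(terms, groups = list()) {
  terms <- unique(as.character(terms))
  if (length(groups)) {
    if (is.null(names(groups)) || anyDuplicated(names(groups)) ||
        any(!nzchar(names(groups)))) {
      stop("groups must have unique non-empty names", call. = FALSE)
    }
    groups <- lapply(groups, function(g) unique(as.character(g)))
    if (any(lengths(groups) == 0L)) {
      stop("group queries must be non-empty", call. = FALSE)
    }
    stray <- setdiff(unlist(groups), terms)
    if (length(stray)) {
      stop("group members missing from the term list: ",
           paste(utils::head(stray, 5L), collapse = "; "), call. = FALSE)
    }
  }
  structure(list(terms = terms, groups = groups), class = "term_catalog")
}

#' @export
print.term_catalog <- function(x, ...) {
  cat("Term catalog:", length(x$terms), "preferred terms,",
      length(x$groups), "group queries\n")
  for (g in names(x$groups)) {
    cat("  ", g, " (", length(x$groups[[g]]), " terms)\n", sep = "")
  }
  invisible(x)
}

#' Built-in endocrine adverse-event catalog
#'
#' The open catalog of endocrine preferred terms used throughout the
#' package, covering thyroid, pituitary, adrenal, pancreatic, parathyroid,
#' gonadal and posterior-pituitary toxicity, with these group queries:
#'
#' * `ICI-DM` — insulin-deficient diabetes under checkpoint blockade:
#'   type 1 diabetes mellitus, diabetes mellitus, fulminant type 1 diabetes
#'   mellitus, diabetic ketoacidosis;
#' * `thyroid_dysfunction` — hypothyroidism, hyperthyroidism, thyroiditis;
#' * `hypophysitis_hypopituitarism` — anterior pituitary toxicity family;
#' * `adrenal_insufficiency_group` — adrenocortical insufficiency family;
#' * `endocrine_all` — union of every catalog term.
#'
#' @return A [term_catalog()].
#' @export
builtin_endocrine_catalog <- function() {
  thyroid <- c("hypothyroidism", "hyperthyroidism", "thyroiditis",
               "thyrotoxic crisis", "basedow's disease")
  pituitary <- c("hypophysitis", "hypopituitarism",
                 "lymphocytic hypophysitis", "pituitary enlargement")
  adrenal <- c("adrenal insufficiency",
               "primary adrenocortical insufficiency",
               "secondary adrenocortical insufficiency",
               "acute adrenocortical insufficiency")
  pancreas <- c("type 1 diabetes mellitus", "diabetes mellitus",
                "fulminant type 1 diabetes mellitus", "diabetic ketoacidosis")
  other <- c("diabetes insipidus", "hypoparathyroidism", "hypogonadism",
             "inappropriate antidiuretic hormone secretion")
  terms <- c(thyroid, pituitary, adrenal, pancreas, other)
  term_catalog(
    terms = terms,
    groups = list(
      `ICI-DM` = pancreas,
      thyroid_dysfunction = c("hypothyroidism", "hyperthyroidism",
                              "thyroiditis"),
      hypophysitis_hypopituitarism = pituitary,
      adrenal_insufficiency_group = adrenal,
      endocrine_all = terms
    )
  )
}

#' Resolve a group query
#'
#' @param catalog A [term_catalog()].
#' @param query Either the name of a catalog group, a single catalog term,
#'   or a character vector of preferred terms used as an ad-hoc query.
#' @return Named list with `name` and `members`.
#' @export
resolve_query <- function(catalog, query) {
  stopifnot(inherits(catalog, "term_catalog"))
  if (length(query) == 1L && query %in% names(catalog$groups)) {
    return(list(name = query, members = catalog$groups[[query]]))
  }
  members <- unique(as.character(query))
  if (length(members) == 0L) stop("empty query", call. = FALSE)
  list(name = paste(members, collapse = "+"), members = members)
}

#' Match reports against a group query
#'
#' A report matches when at least one of its event terms belongs to the
#' query; a report matching several member terms still counts once
#' (case-level counting).
#'
#' @param reports An [icsr_set()].
#' @inheritParams resolve_query
#' @return Logical vector, one element per report.
#' @export
match_query <- function(reports, catalog, query) {
  stopifnot(is_icsr_set(reports))
  members <- resolve_query(catalog, query)$members
  vapply(reports$events, function(e) any(e %in% members), logical(1))
}

#' Read or write a term catalog file
#'
#' Catalogs serialize to a human-editable YAML or JSON document of the form
#' `{terms: [...], groups: {name: [...], ...}}`.
#'
#' @param path File path; `.json` selects JSON, anything else YAML.
#' @return `read_term_catalog()` returns a [term_catalog()];
#'   `write_term_catalog()` returns `path` invisibly.
#' @export
read_term_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  term_catalog(terms = unlist(doc$terms), groups = lapply(doc$groups, unlist))
}

#' @rdname read_term_catalog
#' @param catalog A [term_catalog()] to serialize.
#' @export
write_term_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "term_catalog"))
  doc <- list(terms = catalog$terms, groups = catalog$groups)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(doc, path, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}
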