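#' Load a PAC concept lexicon
#'
#' Reads the lexicon configuration (YAML): the concept dictionary mapping each
#' PAC evidence concept to its case-insensitive surface patterns, the context
#' trigger lists (negation, hypothetical, family/experiencer, scope
#' terminators), the section-header dictionary, and the sentence-splitter
#' abbreviation guard list. The packaged default covers every concept the PAC
#' rule engine can credit; the file is user-replaceable so local phrase
#' inventories can be swapped in without touching code.
#'
#' @param path Path to a lexicon YAML file. Defaults to the lexicon shipped
#'   with the package.
#' @return An object of class `pac_lexicon`: a list with elements `concepts`
#'   (named list of character pattern vectors), `triggers`, `sections`,
#'   `abbreviations`, and precompiled per-concept regular expressions.
#' @examples
#' lex <- load_lexicon()
#' names(lex$concepts)[1:5]
#' @export
load_lexicon <- function(path = default_lexicon_path()) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (field in c("concepts", "triggers", "sections", "abbreviations")) {
    if (is.null(raw[[field]])) {
      stop("lexicon is missing the '", field, "' block", call. = FALSE)
    }
  }
  concepts <- lapply(raw$concepts, function(p) as.character(unlist(p)))
  if (length(concepts) == 0) stop("lexicon defines no concepts", call. = FALSE)
  for (cid in names(concepts)) {
    pats <- concepts[[cid]]
    if (length(pats) == 0 || any(!nzchar(trimws(pats)))) {
      stop("concept '", cid, "' has an empty pattern list or blank pattern",
           call. = FALSE)
    }
  }
  triggers <- lapply(raw$triggers, function(p) tolower(as.character(unlist(p))))
  for (t in c("negation", "hypothetical", "family", "scope_terminators")) {
    if (is.null(triggers[[t]])) {
      stop("lexicon trigger list '", t, "' is missing", call. = FALSE)
    }
  }
  sections <- lapply(raw$sections, function(p) tolower(as.character(unlist(p))))
  lex <- structure(
    list(
      concepts = concepts,
      triggers = triggers,
      sections = sections,
      abbreviations = tolower(as.character(unlist(raw$abbreviations))),
      regex = lapply(concepts, compile_concept_regex),
      section_lookup = build_section_lookup(sections)
    ),
    class = "pac_lexicon"
  )
  lex
}

#' Path to the packaged default lexicon
#' @return A file path.
#' @export
default_lexicon_path <- function() {
  system.file("extdata", "pac_lexicon.yaml", package = "asthmapac",
              mustWork = TRUE)
}

# One alternation regex per concept; alternatives ordered longest-first so the
# regex engine prefers the longest surface form at a position. Literal phrases
# are escaped and internal whitespace is matched flexibly.
compile_concept_regex <- function(patterns) {
  pats <- patterns[order(-nchar(patterns))]
  esc <- vapply(pats, function(p) {
    p <- gsub("([][{}()+*^$|\\\\?.#-])", "\\\\\\1", p, perl = TRUE)
    gsub("\\s+", "\\\\s+", p)
  }, character(1))
  paste0("(?i)\\b(?:", paste(esc, collapse = "|"), ")\\b")
}

build_section_lookup <- function(sections) {
  labels <- rep(names(sections), lengths(sections))
  variants <- tolower(unlist(sections, use.names = FALSE))
  stats::setNames(labels, variants)
}

#' @export
print.pac_lexicon <- function(x, ...) {
  cat("<pac_lexicon>\n")
  cat("  concepts:", length(x$concepts), "with",
      sum(lengths(x$concepts)), "surface patterns\n")
  cat("  sections:", length(x$sections), "canonical labels\n")
  cat("  negation triggers:", paste(x$triggers$negation, collapse = ", "), "\n")
  invisible(x)
}
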