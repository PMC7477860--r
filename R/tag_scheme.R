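#' IOB tag scheme over entity categories
#'
#' Defines the closed tag set used throughout the package: one `O` tag plus
#' `B-X`/`I-X` pairs for every entity category `X`.  The default categories are
#' the five Traditional Chinese Medicine clinical term types: medicines
#' (`MED`), formulas (`FOL`), symptoms (`SYM`), diseases (`DES`) and patterns
#' (`PAT`).
#'
#' @param categories Character vector of category codes. Codes must be unique,
#'   non-empty and must not contain a hyphen.
#' @return An object of class `tag_scheme` with elements `categories` and
#'   `tags` (the derived full tag list, `O` first).
#' @examples
#' sc <- tag_scheme()
#' sc$tags
#' @export
tag_scheme <- function(categories = c("MED", "FOL", "SYM", "DES", "PAT")) {
  categories <- as.character(categories)
  if (length(categories) == 0) {
    stop_validation("a tag scheme needs at least one category")
  }
  if (anyDuplicated(categories)) {
    stop_validation("category codes must be unique")
  }
  if (any(!nzchar(categories)) || any(grepl("-", categories, fixed = TRUE))) {
    stop_validation("category codes must be non-empty and contain no hyphen")
  }
  tags <- c("O", as.vector(rbind(paste0("B-", categories),
                                 paste0("I-", categories))))
  structure(list(categories = categories, tags = tags), class = "tag_scheme")
}

#' @export
print.tag_scheme <- function(x, ...) {
  cat("<tag_scheme> ", length(x$categories), " categories: ",
      paste(x$categories, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Map tag strings to 1-based indices into scheme$tags, erroring on unknowns.
tag_indices <- function(labels, scheme) {
  idx <- match(labels, scheme$tags)
  if (anyNA(idx)) {
    bad <- labels[which(is.na(idx))[1]]
    stop_validation(sprintf("unknown tag '%s' for this tag scheme", bad),
                    class = "tcmner_tag_error")
  }
  idx
}

is_tag_scheme <- function(x) inherits(x, "tag_scheme")
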