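#' Load the controlled allergen and lifestyle-preference vocabularies
#'
#' Reads the two one-tag-per-line vocabulary files that define every tag a
#' meal or user may carry. The bundled defaults are the catering
#' platform's 34 supported allergies and 31 lifestyle preferences,
#' lowercased; internal spaces are preserved (e.g. `"brazil nuts"`) and
#' matching everywhere in the package is exact after lowercasing.
#'
#' @param config_dir Directory containing `allergens.txt` and
#'   `preferences.txt`. Defaults to the copies shipped with the package.
#' @return List with character vectors `allergens` and `preferences`.
#' @examples
#' v <- load_vocabularies()
#' length(v$allergens)    # 34
#' length(v$preferences)  # 31
#' @export
load_vocabularies <- function(config_dir = system.file("extdata", "vocab",
                                                       package = "mealrec")) {
  list(
    allergens   = read_vocab_file(file.path(config_dir, "allergens.txt")),
    preferences = read_vocab_file(file.path(config_dir, "preferences.txt"))
  )
}

read_vocab_file <- function(path) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path, call. = FALSE)
  tags <- readLines(path, encoding = "UTF-8")
  tags <- normalize_tag(tags)
  tags <- tags[nzchar(tags)]
  if (length(tags) == 0) stop("empty vocabulary file: ", path, call. = FALSE)
  dup <- unique(tags[duplicated(tags)])
  if (length(dup) > 0) {
    stop("duplicate vocabulary tag(s) in ", basename(path), ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  tags
}

#' Normalize a tag for vocabulary matching
#'
#' Lowercases and trims; internal whitespace is collapsed to single
#' spaces. Matching against vocabularies is exact after this
#' normalization.
#'
#' @param tag Character vector of tags.
#' @return Normalized character vector.
#' @export
normalize_tag <- function(tag) {
  gsub("[[:space:]]+", " ", trimws(tolower(as.character(tag))))
}

assert_tags_in_vocab <- function(tags, vocab, what) {
  unknown <- setdiff(tags, vocab)
  if (length(unknown) > 0) {
    stop("unknown ", what, " tag(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(tags)
}

# Required-diet lifestyle tags are must-have meal tags; every other
# preference tag is an avoidance (must-not-have) tag.
required_diet_tags <- function() c("vegan", "vegetarian", "halal", "kosher")
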