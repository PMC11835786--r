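#' Scored nutrients
#'
#' The twelve nutrients that drive the knowledge-based scorer, in their
#' canonical order. Per-portion units: fiber, monounsaturated fat,
#' polyunsaturated fat, protein, total fat, saturated fat and carbohydrate
#' in g; vitamin A in ug RE; vitamin B12 in ug; vitamin C and calcium and
#' iron in mg (vitamin C mg, calcium mg, iron mg). Energy (kcal) may be
#' carried alongside for display but is never scored.
#'
#' @return Character vector of the twelve nutrient keys.
#' @export
scored_nutrients <- function() {
  c("fiber", "vitamin_a", "vitamin_b12", "vitamin_c",
    "monounsaturated_fat", "polyunsaturated_fat", "protein", "total_fat",
    "calcium", "iron", "saturated_fat", "carbohydrate")
}

#' Construct and validate a per-portion nutrient vector
#'
#' @param x Named numeric vector. Must contain every scored nutrient;
#'   an optional `energy` entry (kcal) is kept, other extra names are
#'   dropped with a warning.
#' @return Named numeric vector over the scored nutrients (plus `energy`
#'   when supplied), all values finite and non-negative.
#' @export
nutrient_vector <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("nutrient vector must be fully named", call. = FALSE)
  }
  x <- unlist(x)
  missing <- setdiff(scored_nutrients(), names(x))
  if (length(missing) > 0) {
    stop("missing scored nutrient(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(x), c(scored_nutrients(), "energy"))
  if (length(extra) > 0) {
    warning("ignoring unknown nutrient column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(c(scored_nutrients(), "energy"), names(x))
  x <- x[keep]
  vals <- as.numeric(x)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("nutrient values must be finite and >= 0", call. = FALSE)
  }
  stats::setNames(vals, keep)
}
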