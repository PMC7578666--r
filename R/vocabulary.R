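#' Controlled vocabularies for interaction records
#'
#' Chemical-use annotations are restricted to a fixed eleven-term vocabulary
#' (pharmaceutical, recreational drug, research, warfare, endobiotic,
#' agricultural, cosmetics, environment, food components, industrial,
#' pollutant); each chemical carries one to three of these terms. Taxa are
#' restricted to the three mammalian sources of high-throughput
#' toxicogenomic evidence, and action directions to increase ("+"),
#' decrease ("-") or unspecified ("1") expression change.
#'
#' @return `use_vocabulary()` returns the character vector of the 11 legal
#'   use terms; `allowed_taxa()` the three taxon labels; `direction_codes()`
#'   the three normalized direction codes.
#' @examples
#' use_vocabulary()
#' @export
use_vocabulary <- function() {
  c(
    "pharmaceutical", "recreational drug", "research", "warfare",
    "endobiotic", "agricultural", "cosmetics", "environment",
    "food components", "industrial", "pollutant"
  )
}

#' @rdname use_vocabulary
#' @export
allowed_taxa <- function() c("Homo", "Mus", "Rattus")

#' @rdname use_vocabulary
#' @export
direction_codes <- function() c("+", "-", "1")

# Case/whitespace-insensitive canonical form used for vocabulary membership.
normalize_term <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

# Normalize a direction string; ASCII hyphen and U+2212 both mean decrease.
normalize_direction <- function(x) {
  x <- trimws(x)
  x[x == "−"] <- "-"
  x
}
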