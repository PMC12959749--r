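#' The ten-vowel /hVt/ elicitation inventory
#'
#' The analysis is defined over a fixed inventory of ten American English
#' monophthong targets elicited in an /hVt/ frame (heat, hit, het, hate, hat,
#' hut, hoot, hood, hoed, hot). Vowels are identified by ASCII ARPABET-style
#' codes to avoid IPA encoding hazards in CSV files; the mapping to IPA is
#' bijective. The central unrounded STRUT vowel ("hut") is carried under code
#' `AH` and displayed as schwa, matching the transcription convention the
#' elicitation task uses.
#'
#' @return A tibble with one row per vowel, in fixed inventory order:
#'   \describe{
#'     \item{code}{ASCII vowel code (`IY`, `IH`, `EH`, `EY`, `AE`, `AH`,
#'       `UW`, `UH`, `OW`, `AA`).}
#'     \item{ipa}{IPA display string.}
#'     \item{word}{The /hVt/ elicitation word.}
#'     \item{corner}{Logical; `TRUE` for the four corner vowels
#'       IY (heat), UW (hoot), AE (hat), AA (hot) that define the
#'       quadrilateral vowel space.}
#'   }
#' @examples
#' vowel_inventory()
#' @export
vowel_inventory <- function() {
  tibble::tibble(
    code = c("IY", "IH", "EH", "EY", "AE", "AH", "UW", "UH", "OW", "AA"),
    ipa = c("i", "ɪ", "ɛ", "e", "æ", "ə",
            "u", "ʊ", "o", "ɑ"),
    word = c("heat", "hit", "het", "hate", "hat", "hut",
             "hoot", "hood", "hoed", "hot"),
    corner = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE,
               TRUE, FALSE, FALSE, TRUE)
  )
}

#' Corner vowels in quadrilateral traversal order
#'
#' Returns the codes of the four corner vowels in the fixed perimeter order
#' used for the quadrilateral vowel space area: IY (high front) to AE (low
#' front) to AA (low back) to UW (high back). This order traces the perimeter
#' of the traditional vowel chart so that, for typical formant
#' configurations, the quadrilateral is simple (non-self-intersecting).
#'
#' @return Character vector `c("IY", "AE", "AA", "UW")`.
#' @seealso [compute_qvsa()]
#' @export
corner_vowels <- function() c("IY", "AE", "AA", "UW")

#' Normalise vowel labels to inventory codes
#'
#' Accepts ARPABET-style codes in any case, or the IPA display characters,
#' and returns canonical codes. Unknown labels raise a validation error
#' listing the offending values.
#'
#' @param x Character vector of vowel labels.
#' @return Character vector of canonical vowel codes.
#' @export
normalize_vowel <- function(x) {
  inv <- vowel_inventory()
  up <- toupper(trimws(as.character(x)))
  code <- ifelse(up %in% inv$code, up, inv$code[match(trimws(x), inv$ipa)])
  if (anyNA(code)) {
    bad <- unique(x[is.na(code)])
    vs_abort(
      paste0("Unknown vowel label(s): ", paste(bad, collapse = ", "),
             ". Admissible codes: ", paste(inv$code, collapse = ", "), "."),
      "vowelspace_vowel_error"
    )
  }
  code
}

# session labels: the analysis is defined on exactly two timepoints
session_levels <- function() c("baseline", "post")
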