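#' ICD-10 chapter map
#'
#' The 22 chapters of ICD-10 as contiguous ranges of 3-character category
#' codes (WHO grouping). Chapters 1-14 (infectious through genitourinary)
#' are the analysis scope; chapters 15-22 (pregnancy, perinatal, congenital,
#' symptoms/signs, injury, external causes, factors influencing health
#' status, special purposes) are excluded by [applyFilters()].
#'
#' @return A data.frame with columns `chapter` (integer 1-22), `from` and
#'   `to` (inclusive 3-character code bounds), and `title`.
#' @examples
#' icdChapterMap()
#' @export
icdChapterMap <- function() {
  data.frame(
    chapter = 1:22,
    from = c("A00", "C00", "D50", "E00", "F00", "G00", "H00", "H60", "I00",
             "J00", "K00", "L00", "M00", "N00", "O00", "P00", "Q00", "R00",
             "S00", "V01", "Z00", "U00"),
    to   = c("B99", "D48", "D89", "E90", "F99", "G99", "H59", "H95", "I99",
             "J99", "K93", "L99", "M99", "N99", "O99", "P96", "Q99", "R99",
             "T98", "Y98", "Z99", "U99"),
    title = c(
      "Certain infectious and parasitic diseases",
      "Neoplasms",
      "Diseases of the blood and blood-forming organs",
      "Endocrine, nutritional and metabolic diseases",
      "Mental and behavioural disorders",
      "Diseases of the nervous system",
      "Diseases of the eye and adnexa",
      "Diseases of the ear and mastoid process",
      "Diseases of the circulatory system",
      "Diseases of the respiratory system",
      "Diseases of the digestive system",
      "Diseases of the skin and subcutaneous tissue",
      "Diseases of the musculoskeletal system and connective tissue",
      "Diseases of the genitourinary system",
      "Pregnancy, childbirth and the puerperium",
      "Certain conditions originating in the perinatal period",
      "Congenital malformations, deformations and chromosomal abnormalities",
      "Symptoms, signs and abnormal clinical and laboratory findings",
      "Injury, poisoning and certain other consequences of external causes",
      "External causes of morbidity and mortality",
      "Factors influencing health status and contact with health services",
      "Codes for special purposes"),
    stringsAsFactors = FALSE
  )
}

#' Chapter of a 3-character ICD-10 code
#'
#' Assigns each code its ICD-10 chapter (1-22) from the packaged chapter map.
#' Codes that fall in a gap of the classification (e.g. "D49") get `NA`.
#'
#' @param codes character vector of 3-character codes (letter + two digits).
#' @return integer vector of chapters, `NA` where unmapped.
#' @examples
#' icdChapter(c("I10", "E78", "O80", "D49"))
#' @export
icdChapter <- function(codes) {
  map <- icdChapterMap()
  out <- rep(NA_integer_, length(codes))
  ok <- !is.na(codes) & grepl("^[A-Z][0-9][0-9]$", codes)
  for (r in seq_len(nrow(map))) {
    in_range <- ok & codes >= map$from[r] & codes <= map$to[r]
    out[in_range] <- map$chapter[r]
  }
  out
}

#' Normalize a raw diagnosis code to its 3-character ICD-10 category
#'
#' Uppercases, strips dots, truncates to the first three characters (dropping
#' subcategory digits), and checks the `[A-Z][0-9][0-9]` pattern.
#'
#' @param raw character vector of raw codes (e.g. `"e78.5"`, `"I10"`).
#' @param strict if `TRUE` (default), invalid codes raise an error; if
#'   `FALSE`, they become `NA` (used during bulk file parsing, where rows
#'   without any parseable code are dropped and counted).
#' @return character vector of normalized 3-character codes.
#' @examples
#' normalizeCode(c("e78.5", "I10"))   # "E78" "I10"
#' normalizeCode("XX", strict = FALSE) # NA
#' @export
normalizeCode <- function(raw, strict = TRUE) {
  if (length(raw) == 0L) return(character(0))
  x <- toupper(gsub(".", "", trimws(as.character(raw)), fixed = TRUE))
  x <- substr(x, 1L, 3L)
  bad <- !grepl("^[A-Z][0-9][0-9]$", x)
  if (any(bad)) {
    if (strict) {
      stop("invalid ICD-10 code(s): ",
           paste(unique(raw[bad]), collapse = ", "))
    }
    x[bad] <- NA_character_
  }
  x
}
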