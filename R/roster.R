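#' Species roster for the simulated prairie songbird community
#'
#' Returns the default community: ten grassland- and sagebrush-associated
#' species commonly surveyed together on point counts in central Montana
#' prairie, identified by their four-letter alpha codes. This community
#' includes two similar-sounding pairs (McCown's Longspur / Horned Lark and
#' Killdeer / Long-billed Curlew) that make misidentification plausible.
#'
#' @return A data.frame with columns `code`, `common_name` and
#'   `scientific_name`, one row per species, ordered by code.
#' @examples
#' study_roster()
#' @export
study_roster <- function() {
  data.frame(
    code = c("BHCO", "BRSP", "HOLA", "KILL", "LARB",
             "LBCU", "MCLO", "SAVS", "VESP", "WEME"),
    common_name = c(
      "Brown-headed Cowbird", "Brewer's Sparrow", "Horned Lark",
      "Killdeer", "Lark Bunting", "Long-billed Curlew",
      "McCown's Longspur", "Savannah Sparrow", "Vesper Sparrow",
      "Western Meadowlark"),
    scientific_name = c(
      "Molothrus ater", "Spizella breweri", "Eremophila alpestris",
      "Charadrius vociferus", "Calamospiza melanocorys",
      "Numenius americanus", "Rhynchophanes mccownii",
      "Passerculus sandwichensis", "Pooecetes gramineus",
      "Sturnella neglecta"),
    stringsAsFactors = FALSE
  )
}

validate_roster <- function(roster) {
  stopifnot(is.data.frame(roster), all(c("code") %in% names(roster)))
  if (anyDuplicated(roster$code)) {
    stop("species codes in roster must be unique")
  }
  if (nrow(roster) < 1L) stop("roster must contain at least one species")
  invisible(roster)
}
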