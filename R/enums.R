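#' Canonical category labels
#'
#' The database distinguishes four recovery metrics, five submetrics, six
#' ecosystem categories and ten disturbance categories. Free-text labels found
#' in source files ("Oil spill", "invasive species", ...) are normalized to
#' these canonical labels; anything that cannot be matched is a reject, never
#' silently coerced.
#'
#' @format A named list of character vectors with elements `metric`,
#'   `submetric`, `ecosystem`, `disturbance`.
#' @export
debt_levels <- list(
  metric      = c("abundance", "diversity", "carbon", "nitrogen"),
  submetric   = c("richness", "diversity_index", "pool", "flux", "none"),
  ecosystem   = c("forest", "grassland", "wetland", "river", "lake", "marine"),
  disturbance = c("agriculture", "logging", "mining", "invasive",
                  "eutrophication", "hydrologic", "overfishing", "oil_spill",
                  "hurricane", "multiple")
)

# Synonym table: lower-cased, punctuation collapsed to a single space.
.enum_synonyms <- list(
  metric = c(
    "organism abundance" = "abundance",
    "species diversity"  = "diversity",
    "carbon cycling"     = "carbon",
    "nitrogen cycling"   = "nitrogen"
  ),
  submetric = c(
    "species richness" = "richness",
    "diversity index"  = "diversity_index",
    "diversity indexes" = "diversity_index",
    "stock"            = "pool",
    "pools"            = "pool",
    "fluxes"           = "flux"
  ),
  ecosystem = c(
    "forests"    = "forest",
    "grasslands" = "grassland",
    "wetlands"   = "wetland",
    "rivers"     = "river",
    "lakes"      = "lake",
    "marine ecosystems" = "marine"
  ),
  disturbance = c(
    "agricultural transformation" = "agriculture",
    "invasive species"     = "invasive",
    "hydrologic disruption" = "hydrologic",
    "hydrological disruption" = "hydrologic",
    "damming"              = "hydrologic",
    "oil spill"            = "oil_spill",
    "oil spills"           = "oil_spill",
    "hurricanes"           = "hurricane"
  )
)

# Normalize a character vector against one enum; unmatched entries become NA.
normalize_enum <- function(x, which) {
  canon <- debt_levels[[which]]
  syn <- .enum_synonyms[[which]]
  key <- tolower(trimws(gsub("\\s+", " ", gsub("[[:punct:]_]+", " ", as.character(x)))))
  key[is.na(x)] <- NA_character_
  canon_key <- tolower(gsub("[[:punct:]_]+", " ", canon))
  out <- canon[match(key, canon_key)]
  hit <- !is.na(match(key, names(syn)))
  out[is.na(out) & hit] <- unname(syn[key[is.na(out) & hit]])
  out
}
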