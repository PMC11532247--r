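# Digitized per-species citation table from a published survey of 145
# informants in the Rema-Kalenga Wildlife Sanctuary (Bangladesh): 51
# medicinal plant species with WFO identifier, citation count and the
# reported index values and ordinal index ranks.
#
# Digitization notes (data errata kept verbatim, not corrected):
#  * the same WFO id (wfo-0001296467) is assigned to both Terminalia
#    bellirica and Ocimum tenuiflorum in the source table;
#  * the Adhatoda vasica citation digits were garbled in extraction; the
#    reported RFC 0.317 and RFC rank 10 fix the count at 46 (46/145 = 0.3172).
# The reported CII/CVI/rank columns cannot be independently recomputed (the
# per-informant raw reports are not deposited); they are carried as reported
# values only. RFC is recomputable as citations / 145.

#' Load the packaged 51-species citation fixture
#'
#' Returns the digitized species citation table: scientific name, author
#' string, WFO identifier (carried as an opaque string, no taxonomic
#' resolution), the number of citing informants (FCs, out of N = 145), and
#' the reported RFC/RI/CVI/CII values with their ordinal ranks.
#'
#' @return data frame with 51 rows and columns `species`, `authority`,
#'   `wfo_id`, `citations`, `rfc_reported`, `ri_reported`, `cvi_reported`,
#'   `cii_reported`, `rank_rfc`, `rank_ri`, `rank_cii`, `rank_cvi`.
#' @export
load_citation_fixture <- function() {
  path <- system.file("extdata", "species_citations.csv",
                      package = "ethnoindices", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  stopifnot(nrow(d) == 51L)
  d
}

#' Number of informants for the fixture survey
#' @return 145, the informant count behind the packaged citation fixture.
#' @export
citation_fixture_n_informants <- function() 145L

#' Look up a fixture species by scientific name
#'
#' @param species scientific name (binomial, whitespace-insensitive).
#' @return One-row data frame for the species.
#' @export
citation_lookup <- function(species) {
  d <- load_citation_fixture()
  key <- normalize_species(species)
  hit <- d$species == key
  if (!any(hit)) {
    stop("species not in the citation fixture: '", key, "'", call. = FALSE)
  }
  d[hit, , drop = FALSE]
}

#' Citation count (FCs) for a fixture species
#' @param species scientific name.
#' @return Integer citation count.
#' @export
citation_count <- function(species) {
  citation_lookup(species)$citations
}
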