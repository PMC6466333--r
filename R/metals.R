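#' The seven assessed trace metals
#'
#' Fixed identity and ordering (Cr, Ni, Cu, Zn, As, Cd, Pb) used in every
#' tabular output of the package.  As is a metalloid but is treated
#' identically throughout.
#'
#' @return Character vector of the seven metal symbols, in canonical order.
#' @export
#' @examples
#' trace_metals()
trace_metals <- function() {
  c("Cr", "Ni", "Cu", "Zn", "As", "Cd", "Pb")
}

#' The four metals carrying a cancer slope factor
#'
#' @return Character vector: Cr, Ni, As, Cd (canonical order).
#' @export
carcinogens <- function() {
  c("Cr", "Ni", "As", "Cd")
}

# Check / normalize a vector of metal symbols; preserves canonical order
# when `sort = TRUE`.
match_metals <- function(metal, several.ok = TRUE) {
  m <- match.arg(metal, trace_metals(), several.ok = several.ok)
  m
}
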