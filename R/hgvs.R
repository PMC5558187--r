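#' Parse HGVS protein-level mutation notation
#'
#' Parses strings like `"p.Arg365Leu"` (missense), `"p.Gly105fs"`
#' (frameshift), `"p.Trp230del"` (deletion) or `"p.Arg333Ter"` / `"p.Arg333*"`
#' (nonsense) into their components. Splice-site changes have no protein-level
#' notation; they enter the pipeline through the `consequence` column of the
#' variant table instead.
#'
#' @param text Character vector of HGVS p. strings.
#' @return A tibble with one row per input: `hgvs_p`, `wild_type` and
#'   `mutant` (three-letter codes; `mutant` is `NA` for non-missense),
#'   `position` (1-based protein coordinate) and `consequence`.
#' @examples
#' parse_hgvs_p(c("p.Arg365Leu", "p.Val142Ala", "p.Gly105fs"))
#' @export
parse_hgvs_p <- function(text) {
  if (length(text) == 0) {
    return(tibble(hgvs_p = character(), wild_type = character(),
                  position = integer(), mutant = character(),
                  consequence = character()))
  }
  rx <- "^p\\.([A-Za-z]{3})([0-9]+)([A-Za-z]{3}|fs|del|\\*)$"
  m <- regmatches(text, regexec(rx, text))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    abort(paste0("Cannot parse HGVS p. notation: ",
                 paste(unique(text[bad]), collapse = ", "),
                 " (expected e.g. \"p.Arg365Leu\", \"p.Gly105fs\", \"p.Arg333Ter\")."))
  }
  wt <- vapply(m, `[`, character(1), 2)
  pos <- as.integer(vapply(m, `[`, character(1), 3))
  tail <- vapply(m, `[`, character(1), 4)

  # validate wild type codes
  aa_three_to_one(wt)

  is_token <- tail %in% names(CONSEQUENCE_TOKENS)
  consequence <- ifelse(is_token, CONSEQUENCE_TOKENS[tail], "MISSENSE")
  mutant <- ifelse(is_token, NA_character_, tail)
  if (any(!is_token)) {
    aa_three_to_one(mutant[!is_token])
  }
  same <- !is_token & mutant == wt
  if (any(same)) {
    abort(paste0("Wild-type equals mutant residue in: ",
                 paste(unique(text[same]), collapse = ", ")))
  }
  if (any(pos < 1L)) {
    abort("Protein positions must be >= 1.")
  }
  tibble(hgvs_p = text, wild_type = wt, position = pos,
         mutant = mutant, consequence = unname(consequence))
}

#' Format a parsed protein mutation back to HGVS p. notation
#'
#' Inverse of [parse_hgvs_p()]: `format_hgvs_p(parse_hgvs_p(x))` returns `x`
#' for every valid input.
#'
#' @param mutation A tibble as returned by [parse_hgvs_p()] (columns
#'   `wild_type`, `position`, `mutant`, `consequence`).
#' @return Character vector of HGVS p. strings.
#' @export
format_hgvs_p <- function(mutation) {
  suffix <- ifelse(
    mutation$consequence == "MISSENSE", mutation$mutant,
    c(FRAMESHIFT = "fs", DELETION = "del", NONSENSE = "Ter")[mutation$consequence]
  )
  if (anyNA(suffix)) {
    abort("Cannot format mutation: missing mutant residue or unsupported consequence.")
  }
  paste0("p.", mutation$wild_type, mutation$position, suffix)
}
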