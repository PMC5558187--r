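#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn inform
NULL

# Three-letter <-> one-letter codes for the 20 standard amino acids.
AA_TABLE <- data.frame(
  three = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
            "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
            "Tyr", "Val"),
  one   = c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
            "I", "L", "K", "M", "F", "P", "S", "T", "W",
            "Y", "V"),
  stringsAsFactors = FALSE
)

AA_CLASSES <- c("HYDROPHOBIC", "POLAR", "POSITIVE", "NEGATIVE")

#' Default amino-acid physicochemical class scheme
#'
#' Maps each one-letter amino-acid code to one of four classes:
#' hydrophobic, polar (uncharged), positively charged, negatively charged.
#' Glycine, cysteine and tyrosine are grouped with the hydrophobic residues
#' and histidine with the positive residues, matching the substitution-class
#' groupings used for the cystinuria transporter subunits. Alternative
#' schemes (e.g. histidine as polar) can be supplied to any function that
#' takes a `scheme` argument as a named character vector over the 20
#' one-letter codes.
#'
#' @return Named character vector: names are one-letter codes, values are
#'   one of `"HYDROPHOBIC"`, `"POLAR"`, `"POSITIVE"`, `"NEGATIVE"`.
#' @examples
#' default_aa_scheme()[["Y"]]  # "HYDROPHOBIC"
#' @export
default_aa_scheme <- function() {
  scheme <- c(
    G = "HYDROPHOBIC", A = "HYDROPHOBIC", V = "HYDROPHOBIC",
    L = "HYDROPHOBIC", I = "HYDROPHOBIC", P = "HYDROPHOBIC",
    F = "HYDROPHOBIC", M = "HYDROPHOBIC", W = "HYDROPHOBIC",
    C = "HYDROPHOBIC", Y = "HYDROPHOBIC",
    S = "POLAR", T = "POLAR", N = "POLAR", Q = "POLAR",
    K = "POSITIVE", R = "POSITIVE", H = "POSITIVE",
    D = "NEGATIVE", E = "NEGATIVE"
  )
  scheme
}

check_aa_scheme <- function(scheme) {
  if (!is.character(scheme) || is.null(names(scheme)) ||
      !setequal(names(scheme), AA_TABLE$one)) {
    abort("`scheme` must be a named character vector over the 20 one-letter amino-acid codes.")
  }
  bad <- setdiff(unique(scheme), AA_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("Unknown amino-acid class: ", paste(bad, collapse = ", ")))
  }
  invisible(scheme)
}

#' Convert between three-letter and one-letter residue codes
#'
#' @param x Character vector of residue codes.
#' @return Character vector of converted codes.
#' @examples
#' aa_three_to_one("Arg")
#' aa_one_to_three("R")
#' @export
aa_three_to_one <- function(x) {
  idx <- match(x, AA_TABLE$three)
  if (anyNA(idx)) {
    abort(paste0("Unknown residue code: ",
                 paste(unique(x[is.na(idx)]), collapse = ", ")))
  }
  AA_TABLE$one[idx]
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) {
  idx <- match(x, AA_TABLE$one)
  if (anyNA(idx)) {
    abort(paste0("Unknown residue code: ",
                 paste(unique(x[is.na(idx)]), collapse = ", ")))
  }
  AA_TABLE$three[idx]
}

#' Classify a residue into a physicochemical class
#'
#' @param residue Character vector of residue codes, one- or three-letter.
#' @param scheme Class scheme, see [default_aa_scheme()].
#' @return Factor with levels `HYDROPHOBIC`, `POLAR`, `POSITIVE`, `NEGATIVE`.
#' @examples
#' classify_residue(c("Tyr", "Ser", "Asp", "R"))
#' @export
classify_residue <- function(residue, scheme = default_aa_scheme()) {
  check_aa_scheme(scheme)
  one <- ifelse(nchar(residue) == 3, NA_character_, residue)
  is_three <- nchar(residue) == 3
  one[is_three] <- aa_three_to_one(residue[is_three])
  idx <- match(one, names(scheme))
  if (anyNA(idx)) {
    abort(paste0("Unknown residue code: ",
                 paste(unique(residue[is.na(idx)]), collapse = ", ")))
  }
  factor(unname(scheme[idx]), levels = AA_CLASSES)
}
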