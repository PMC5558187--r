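CONTRAST_ATTRIBUTES <- c("allele_frequency", "consurf", "ddg")

#' Contrast disease-associated and population-only variant sets
#'
#' Compares the two sets on one annotation — allele frequency, ConSurf
#' conservation grade (1-9), or predicted stability change (kcal/mol,
#' negative = destabilising) — reporting per-set sizes, medians, histograms
#' and a two-sided Wilcoxon rank-sum test. Missing values are dropped per
#' set; an allele frequency of exactly 0 (variant absent from the population
#' panel) is a real value, not missing.
#'
#' @param disease,population Variant tibbles (see [read_variant_table()]).
#' @param attribute One of `"allele_frequency"`, `"consurf"`, `"ddg"`.
#' @param mode Passed to [wilcoxon_rank_sum()].
#' @param freq_thresholds Bin edges for the frequency histogram (fractions).
#' @param ddg_binwidth Bin width (kcal/mol) for the stability histogram.
#' @return A list of class `contrast_report`: `attribute`, per-set `n`,
#'   `median`, `histogram`, `median_difference` (disease minus population),
#'   `test` (a `rank_test`).
#' @export
contrast_sets <- function(disease, population,
                          attribute = c("allele_frequency", "consurf", "ddg"),
                          mode = "auto",
                          freq_thresholds = c(1e-4, 1e-3, 1e-2, 1e-1),
                          ddg_binwidth = 0.5) {
  attribute <- match.arg(attribute)
  vd <- disease[[attribute]]
  vp <- population[[attribute]]
  vd <- vd[!is.na(vd)]
  vp <- vp[!is.na(vp)]
  if (length(vd) == 0 || length(vp) == 0) {
    abort(paste0("Attribute `", attribute, "` is absent from all members of one set."))
  }
  hist_fun <- switch(attribute,
    consurf = function(v) {
      counts <- tabulate(as.integer(v), nbins = 9)
      stats::setNames(counts, as.character(1:9))
    },
    allele_frequency = function(v) frequency_spectrum(v, freq_thresholds),
    ddg = function(v) {
      edges <- seq(floor(min(v) / ddg_binwidth) * ddg_binwidth,
                   ceiling(max(v) / ddg_binwidth) * ddg_binwidth + ddg_binwidth,
                   by = ddg_binwidth)
      counts <- tabulate(findInterval(v, edges), nbins = length(edges) - 1L)
      stats::setNames(counts, paste0("[", utils::head(edges, -1), ",",
                                     edges[-1], ")"))
    })
  structure(list(
    attribute = attribute,
    n = c(disease = length(vd), population = length(vp)),
    median = c(disease = stats::median(vd), population = stats::median(vp)),
    median_difference = stats::median(vd) - stats::median(vp),
    histogram = list(disease = hist_fun(vd), population = hist_fun(vp)),
    test = wilcoxon_rank_sum(vd, vp, mode = mode)
  ), class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat(sprintf("Contrast on %s: disease n = %d median = %g; population n = %d median = %g; p = %.4g\n",
              x$attribute, x$n[["disease"]], x$median[["disease"]],
              x$n[["population"]], x$median[["population"]],
              x$test$p_two_sided))
  invisible(x)
}

#' Allele-frequency spectrum
#'
#' Counts variants with frequency exactly 0 (absent from the population
#' panel), then per half-open frequency bin `[t_i, t_{i+1})` starting from
#' `(0, t_1)`, with a final overflow bin at or above the last threshold.
#'
#' @param frequencies Numeric allele-frequency fractions in `[0, 1]`
#'   (missing values dropped).
#' @param thresholds Strictly increasing bin edges.
#' @return Named integer vector of bin counts summing to the number of
#'   non-missing inputs.
#' @examples
#' frequency_spectrum(c(0, 5e-5, 0.31), thresholds = c(1e-4, 1e-2))
#' @export
frequency_spectrum <- function(frequencies, thresholds = c(1e-4, 1e-3, 1e-2, 1e-1)) {
  if (any(diff(thresholds) <= 0)) abort("`thresholds` must be strictly increasing.")
  f <- frequencies[!is.na(frequencies)]
  edges <- c(0, thresholds)
  labels <- c("0",
              paste0("(0,", thresholds[1], ")"),
              if (length(thresholds) > 1) {
                paste0("[", utils::head(thresholds, -1), ",",
                       thresholds[-1], ")")
              },
              paste0(">=", thresholds[length(thresholds)]))
  counts <- integer(length(labels))
  counts[1] <- sum(f == 0)
  nz <- f[f > 0]
  bin <- findInterval(nz, thresholds) + 1L   # 1 = below first threshold
  for (b in seq_len(length(thresholds) + 1L)) {
    counts[b + 1L] <- sum(bin == b)
  }
  stats::setNames(counts, labels)
}

#' Runs of mutated positions along the protein sequence
#'
#' Groups mutated residue positions into maximal runs where consecutive
#' members differ by at most `max_gap`, to describe sequence clustering of
#' mutations (e.g. the rBAT stretches 121-124, 253-256, 480-482, 552-568).
#'
#' @param positions Integer protein positions (>= 1); duplicates collapsed.
#' @param max_gap Maximum spacing between consecutive members of a run.
#' @return Tibble ordered by `start`: `start`, `end`, `n_positions`, `span`.
#' @examples
#' sequence_clustering_runs(c(121, 122, 123, 124, 300))
#' @export
sequence_clustering_runs <- function(positions, max_gap = 1L) {
  pos <- sort(unique(as.integer(positions)))
  if (length(pos) == 0) {
    return(tibble(start = integer(), end = integer(),
                  n_positions = integer(), span = integer()))
  }
  if (any(pos < 1L)) abort("Positions must be >= 1.")
  run <- cumsum(c(1L, diff(pos) > max_gap))
  starts <- tapply(pos, run, min)
  ends <- tapply(pos, run, max)
  tibble(start = as.integer(starts), end = as.integer(ends),
         n_positions = as.integer(tabulate(run)),
         span = as.integer(ends - starts + 1L))
}

#' Correlation between allele frequency and conservation
#'
#' Spearman rank correlation (mid-ranks; ConSurf grades are heavily tied)
#' between allele frequency and ConSurf score, dropping variants missing
#' either annotation.
#'
#' @param variants Variant tibble with `allele_frequency` and `consurf`.
#' @return A list with `rho`, `p_value`, `n` (see [spearman_correlation()]).
#' @export
af_conservation_correlation <- function(variants) {
  spearman_correlation(variants$allele_frequency, variants$consurf)
}
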