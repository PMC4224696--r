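#' Conservation of the mutated base(s)
#'
#' Substitutions report the per-base conservation score at the mutated
#' base (multi-base substitutions: the mean over substituted bases);
#' deletions report the mean over all deleted bases. Insertions have no
#' mutated reference base, so no value is reported. Bases absent from the
#' track are excluded from means; when every relevant base is uncovered the
#' value is `NA` with a warning.
#'
#' @param mutations Mutation tibble.
#' @param track Conservation tibble ([read_conservation()]).
#' @return Numeric vector of scores in `[0, 1]` (`NA` for insertions and
#'   uncovered sites).
#' @export
mutation_conservation <- function(mutations, track) {
  purrr::pmap_dbl(
    list(mutations$chrom, mutations$pos, mutations$ref, mutations$kind),
    function(chrom, pos, ref, kind) {
      if (kind == "insertion") return(NA_real_)
      span <- pos:(pos + nchar(ref) - 1L)
      scores <- conservation_at(track, rep(chrom, length(span)), span)
      if (all(is.na(scores))) {
        warn(sprintf("no conservation score covering %s:%d", chrom, pos))
        return(NA_real_)
      }
      mean(scores, na.rm = TRUE)
    }
  )
}

#' Local background conservation around each mutation
#'
#' Mean of the available per-base scores over the window `pad` bases either
#' side of the mutation position (the mutated base included). Uncovered
#' bases are excluded from the mean; a fully uncovered window yields `NA`
#' with a warning.
#'
#' @param mutations Mutation tibble.
#' @param track Conservation tibble.
#' @param pad Window half-width in bases (default 20).
#' @return Numeric vector of background scores.
#' @export
background_conservation <- function(mutations, track, pad = 20) {
  purrr::map2_dbl(mutations$chrom, mutations$pos, function(chrom, pos) {
    span <- max(1L, pos - pad):(pos + pad)
    scores <- conservation_at(track, rep(chrom, length(span)), span)
    if (all(is.na(scores))) {
      warn(sprintf("no conservation coverage within %d bp of %s:%d", pad, chrom, pos))
      return(NA_real_)
    }
    mean(scores, na.rm = TRUE)
  })
}
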