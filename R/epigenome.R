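#' DNase hypersensitive site containing each mutation
#'
#' A substitution or insertion hits a DHS when its anchor base lies inside
#' the peak; a deletion hits when any deleted base does. Book-ended or
#' duplicated peaks containing the same base are resolved in favour of the
#' peak with the smallest start (then smallest end).
#'
#' @param mutations Mutation tibble ([oc_mutations()]).
#' @param dhs DHS peak tibble ([read_bed()]).
#' @return `mutations` with added columns `in_dhs` (logical) and
#'   `dhs_start`/`dhs_end` (BED coordinates of the containing peak, `NA`
#'   outside any peak).
#' @export
dhs_hit <- function(mutations, dhs) {
  n <- nrow(mutations)
  out <- mutate(mutations, in_dhs = FALSE,
                dhs_start = NA_integer_, dhs_end = NA_integer_)
  if (n == 0 || nrow(dhs) == 0) return(out)
  span_end <- mutations$pos + pmax(nchar(mutations$ref), 1L) - 1L
  hits <- interval_hits(dhs, mutations$chrom, mutations$pos, span_end)
  if (nrow(hits) > 0) {
    hits <- hits |>
      mutate(start = dhs$start[.data$peak_row], end = dhs$end[.data$peak_row]) |>
      arrange(.data$query, .data$start, .data$end) |>
      distinct(.data$query, .keep_all = TRUE)
    out$in_dhs[hits$query] <- TRUE
    out$dhs_start[hits$query] <- hits$start
    out$dhs_end[hits$query] <- hits$end
  }
  out
}

#' Anchor coordinate for the flanking-histone-mark windows
#'
#' Mutations inside a DHS anchor the search at the DHS peak centre
#' (floor of the midpoint); mutations outside any DHS anchor it at the
#' mutation position itself.
#'
#' @param pos Mutation position(s), 1-based.
#' @param dhs_start,dhs_end BED coordinates of the containing DHS
#'   (`NA` when the mutation is outside any DHS).
#' @return Integer anchor coordinate(s).
#' @export
flank_anchor <- function(pos, dhs_start, dhs_end) {
  mid <- as.integer(floor((as.numeric(dhs_start) + as.numeric(dhs_end)) / 2))
  ifelse(is.na(dhs_start), as.integer(pos), mid)
}

# the two closed 1-based flanking windows [anchor-outer, anchor-inner] and
# [anchor+inner, anchor+outer], clipped at chromosome start
flank_windows <- function(anchor, inner = 150, outer = 500) {
  list(
    left = c(max(1L, anchor - outer), max(1L, anchor - inner)),
    right = c(anchor + inner, anchor + outer)
  )
}

#' Is a histone mark present in the flanking annulus?
#'
#' Flags anchors for which at least one peak of the mark overlaps (by one
#' base or more) the annulus `inner`..`outer` bp on either side of the
#' anchor. Peaks lying entirely within the inner core are not "flanking"
#' and do not count.
#'
#' @param anchor Anchor coordinate(s) from [flank_anchor()].
#' @param chrom Chromosome of each anchor.
#' @param peaks Histone mark peak tibble ([read_bed()]).
#' @param inner,outer Annulus bounds in bp (defaults 150 and 500).
#' @return Logical vector, one flag per anchor.
#' @export
histone_flanking <- function(anchor, chrom, peaks, inner = 150, outer = 500) {
  n <- length(anchor)
  if (n == 0) return(logical())
  if (nrow(peaks) == 0) return(rep(FALSE, n))
  stopifnot(inner <= outer)
  flag <- rep(FALSE, n)
  for (side in c("left", "right")) {
    qs <- if (side == "left") pmax(1L, anchor - outer) else anchor + inner
    qe <- if (side == "left") pmax(1L, anchor - inner) else anchor + outer
    ok <- qs <= qe & !(side == "left" & anchor - inner < 1)
    if (any(ok)) {
      hits <- interval_hits(peaks, chrom[ok], qs[ok], qe[ok])
      flag[which(ok)[unique(hits$query)]] <- TRUE
    }
  }
  flag
}
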