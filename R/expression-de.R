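#' Split expression samples into mutant and non-mutant groups for one DHS
#'
#' Every sample carrying at least one mutation inside the given DHS is a
#' mutant sample; every other sample in the expression matrix (flagged
#' normal samples included — they carry no mutations by definition) is
#' non-mutant. Mutant samples absent from the expression matrix are dropped
#' with a warning.
#'
#' @param dhs_start,dhs_end BED coordinates of the DHS.
#' @param chrom Chromosome of the DHS.
#' @param all_mutations Full mutation tibble for the cohort.
#' @param expr Expression tibble ([read_expression()]).
#' @return A list with character vectors `mutant` and `non_mutant`.
#' @export
classify_samples <- function(chrom, dhs_start, dhs_end, all_mutations, expr) {
  peaks <- tibble(chrom = chrom, start = as.integer(dhs_start), end = as.integer(dhs_end))
  span_end <- all_mutations$pos + pmax(nchar(all_mutations$ref), 1L) - 1L
  hits <- interval_hits(peaks, all_mutations$chrom, all_mutations$pos, span_end)
  mutant <- sort(unique(all_mutations$sample_id[hits$query]))
  samples <- expression_samples(expr)
  absent <- setdiff(mutant, samples)
  if (length(absent) > 0) {
    warn(sprintf("mutant sample(s) absent from expression matrix: %s",
                 paste(absent, collapse = ", ")))
  }
  list(mutant = intersect(mutant, samples), non_mutant = setdiff(samples, mutant))
}

#' Fold change of one mutant sample against the non-mutant median
#'
#' @param mutant_value Expression of the mutant sample.
#' @param non_mutant_values Expression of the non-mutant samples.
#' @return `mutant_value / median(non_mutant_values)`; `NA` when the median
#'   is 0 or no non-mutant value is available.
#' @export
fold_change <- function(mutant_value, non_mutant_values) {
  non_mutant_values <- non_mutant_values[!is.na(non_mutant_values)]
  if (length(non_mutant_values) == 0 || is.na(mutant_value)) return(NA_real_)
  med <- median(non_mutant_values)
  if (med == 0) {
    warn("non-mutant median expression is 0; fold change undefined")
    return(NA_real_)
  }
  mutant_value / med
}

#' Two-sided t-test of one mutant sample against the non-mutant samples
#'
#' With a single mutant sample a two-group test is undefined, so the test
#' asks whether the mutant value is plausible under the non-mutant
#' distribution: a one-sample t-test of the non-mutant values with the
#' mutant value as hypothesized mean,
#' `t = (mean(non) - mutant) / (sd(non) / sqrt(n))`, df `n - 1`, two-sided.
#'
#' Degenerate cases: fewer than 3 non-mutant values give `NA`; zero
#' variance gives p = 1 when the mutant equals the common non-mutant value
#' and p = 0 otherwise (a point-mass null).
#'
#' @inheritParams fold_change
#' @return Two-sided p-value.
#' @export
de_test <- function(mutant_value, non_mutant_values) {
  x <- non_mutant_values[!is.na(non_mutant_values)]
  if (length(x) < 3 || is.na(mutant_value)) return(NA_real_)
  s <- sd(x)
  if (s == 0) {
    return(if (mutant_value == x[1]) 1 else 0)
  }
  t_stat <- (mean(x) - mutant_value) / (s / sqrt(length(x)))
  2 * pt(-abs(t_stat), df = length(x) - 1)
}

#' Mutation-linked differential expression for annotated records
#'
#' For each record that falls in a DHS and has an assigned gene present in
#' the expression matrix, classifies samples by mutation status within that
#' DHS, computes the fold change of the record's sample against the
#' non-mutant median, the per-sample two-sided t-test p-value, and a
#' Bonferroni adjustment whose family size is the number of DHS-associated
#' (mutation, gene) records in the run.
#'
#' @param records Annotation record tibble carrying `chrom`, `pos`, `ref`,
#'   `sample_id`, `gene`, `in_dhs`, `dhs_start`, `dhs_end`.
#' @param all_mutations Full cohort mutation tibble (defines mutant groups).
#' @param expr Expression tibble ([read_expression()]).
#' @return `records` with columns `fold_change`, `p_value`, `adj_p_value`,
#'   `n_non_mutant` filled in (NA where not evaluated).
#' @export
add_expression_stats <- function(records, all_mutations, expr) {
  records <- mutate(records,
                    fold_change = NA_real_, p_value = NA_real_,
                    adj_p_value = NA_real_, n_non_mutant = NA_integer_)
  if (is.null(expr) || nrow(records) == 0) return(records)
  eligible <- which(records$in_dhs & !is.na(records$gene))
  n_tests <- length(eligible)  # DHS-associated record count = Bonferroni family
  for (i in eligible) {
    gene_expr <- expr[expr$gene == records$gene[i], , drop = FALSE]
    if (nrow(gene_expr) == 0) next
    grp <- classify_samples(records$chrom[i], records$dhs_start[i], records$dhs_end[i],
                            all_mutations, expr)
    if (!records$sample_id[i] %in% grp$mutant) next
    mut_val <- gene_expr$value[match(records$sample_id[i], gene_expr$sample_id)]
    non_vals <- gene_expr$value[gene_expr$sample_id %in% grp$non_mutant]
    non_vals <- non_vals[!is.na(non_vals)]
    records$n_non_mutant[i] <- length(non_vals)
    records$fold_change[i] <- fold_change(mut_val, non_vals)
    p <- de_test(mut_val, non_vals)
    records$p_value[i] <- p
    if (!is.na(p)) {
      records$adj_p_value[i] <- stats::p.adjust(p, method = "bonferroni", n = n_tests)
    }
  }
  records
}
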