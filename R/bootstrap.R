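#' Bootstrap test for interval-overlap enrichment
#'
#' Builds the null distribution of the overlap between a mutation subset
#' and an annotation set: each replicate draws `subset_size` mutations from
#' the universe without replacement and counts how many carry the
#' annotation. The observed overlap is compared to the replicates with a
#' two-sided one-sample t-test (plus an empirical rank p-value for
#' robustness). Replicate counts follow the hypergeometric distribution
#' with the universe's annotation fraction.
#'
#' @param universe Mutation tibble (or any tibble; only its row count and
#'   the `annotated` flags matter).
#' @param subset_size Number of mutations drawn per replicate.
#' @param annotated Logical vector, one flag per universe row (does this
#'   mutation carry the annotation?), or the name of a logical column of
#'   `universe`.
#' @param observed Observed overlap count of the real subset (optional; the
#'   p-values need it).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; identical seed and inputs give identical
#'   replicates.
#' @return An object of class `oncocis_bootstrap`: list with `observed`,
#'   `replicates`, `mean`, `sd`, `p_value` (t-test), `p_empirical`,
#'   `subset_size`, `n_universe`, `n_annotated`, `n_reps`, `seed`.
#' @examples
#' u <- tibble::tibble(annotated = rep(c(TRUE, FALSE), 500))
#' b <- bootstrap_overlap(u, 100, "annotated", observed = 80, seed = 1)
#' glance(b)
#' @export
bootstrap_overlap <- function(universe, subset_size, annotated,
                              observed = NULL, n_reps = 1000, seed = NULL) {
  if (is.character(annotated) && length(annotated) == 1) {
    annotated <- universe[[annotated]]
  }
  annotated <- as.logical(annotated)
  n <- nrow(universe)
  stopifnot(length(annotated) == n, n_reps >= 1)
  if (subset_size > n) {
    abort(sprintf("subset_size (%d) exceeds universe size (%d)", subset_size, n))
  }
  draw <- function() sum(annotated[sample.int(n, subset_size, replace = FALSE)])
  reps <- if (is.null(seed)) {
    purrr::map_int(seq_len(n_reps), function(i) draw())
  } else {
    withr::with_seed(as.integer(seed), purrr::map_int(seq_len(n_reps), function(i) draw()))
  }
  m <- mean(reps)
  s <- sd(reps)
  p_t <- p_emp <- NA_real_
  if (!is.null(observed)) {
    if (s == 0) {
      p_t <- if (observed == reps[1]) 1 else 0
    } else {
      t_stat <- (m - observed) / (s / sqrt(n_reps))
      p_t <- 2 * pt(-abs(t_stat), df = n_reps - 1)
    }
    p_emp <- (1 + min(sum(reps >= observed), sum(reps <= observed))) / (n_reps + 1) * 2
    p_emp <- min(1, p_emp)
  }
  structure(
    list(
      observed = observed, replicates = reps, mean = m, sd = s,
      p_value = p_t, p_empirical = p_emp, subset_size = subset_size,
      n_universe = n, n_annotated = sum(annotated), n_reps = n_reps, seed = seed
    ),
    class = "oncocis_bootstrap"
  )
}

#' @export
print.oncocis_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<oncocis_bootstrap> %d replicates of %d from %d (%d annotated)\n",
    x$n_reps, x$subset_size, x$n_universe, x$n_annotated
  ))
  cat(sprintf("  null overlap: mean %.1f, sd %.2f\n", x$mean, x$sd))
  if (!is.null(x$observed)) {
    cat(sprintf("  observed %d; one-sample t-test p %.3g (empirical %.3g)\n",
                x$observed, x$p_value, x$p_empirical))
  }
  invisible(x)
}

#' @rdname bootstrap_overlap
#' @param x An `oncocis_bootstrap` object.
#' @param ... Unused.
#' @method tidy oncocis_bootstrap
#' @export
tidy.oncocis_bootstrap <- function(x, ...) {
  tibble(replicate = seq_along(x$replicates), overlap = x$replicates)
}

#' @rdname bootstrap_overlap
#' @method glance oncocis_bootstrap
#' @export
glance.oncocis_bootstrap <- function(x, ...) {
  tibble(
    observed = x$observed %||% NA_integer_, mean = x$mean, sd = x$sd,
    p_value = x$p_value, p_empirical = x$p_empirical,
    subset_size = x$subset_size, n_universe = x$n_universe,
    n_annotated = x$n_annotated, n_reps = x$n_reps
  )
}

#' @rdname bootstrap_overlap
#' @param object An `oncocis_bootstrap` object.
#' @method autoplot oncocis_bootstrap
#' @export
autoplot.oncocis_bootstrap <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$overlap)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::labs(
      x = "bootstrap overlap count", y = "replicates",
      title = sprintf("Null overlap: mean %.1f, sd %.2f", object$mean, object$sd)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$observed)) {
    p <- p + ggplot2::geom_vline(xintercept = object$observed,
                                 colour = "firebrick", linewidth = 1)
  }
  p
}
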