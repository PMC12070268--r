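# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @rdname tidiers
#' @param x A result object.
#' @param ... Unused.
#' @name tidiers
#' @title Tidy and glance methods for nogowave results
#' @description
#' `tidy()` returns one row per estimated component (cluster, ANOVA effect,
#' comparison); `glance()` returns a one-row summary of the fit/test setup.
tidy.cluster_set <- function(x, ...) {
  out <- as_tibble(x[, setdiff(names(x), "members")])
  out$members <- vapply(x$members, function(m) paste(m, collapse = ","), character(1))
  out
}

#' @export
#' @rdname tidiers
glance.cluster_set <- function(x, ...) {
  tibble(
    n_clusters = nrow(x),
    n_significant = if ("significant" %in% names(x)) sum(x$significant) else NA_integer_,
    threshold = attr(x, "threshold") %||% NA_real_,
    R = attr(x, "R") %||% NA_integer_,
    alpha = attr(x, "alpha") %||% NA_real_,
    design = attr(x, "design") %||% NA_character_
  )
}

#' @export
#' @rdname tidiers
tidy.mixed_anova <- function(x, ...) x$table

#' @export
#' @rdname tidiers
glance.mixed_anova <- function(x, ...) {
  tibble(dv = x$dv, n_subjects = x$n_subjects)
}

#' @export
#' @rdname tidiers
tidy.posthoc_test <- function(x, ...) {
  tibble(
    test = x$test, statistic = x$statistic, df = x$df, Z = x$Z, p = x$p,
    effect = x$effect, effect_type = x$effect_type, degenerate = x$degenerate
  )
}

#' @export
#' @rdname tidiers
tidy.group_comparison <- function(x, ...) {
  tibble(
    band = x$band, statistic = x$statistic, handling = x$handling,
    n_a = x$n_a, n_b = x$n_b, U = x$U, Z = x$Z, p = x$p, r = x$r
  )
}
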