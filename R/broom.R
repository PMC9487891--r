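#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed ANOVA result
#'
#' One row per effect (group, condition, interaction) with the test route,
#' F, degrees of freedom, p and partial eta squared.
#'
#' @param x An [mixed_anova()] or [art_anova()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mst_anova
#' @export
tidy.mst_anova <- function(x, ...) {
  dplyr::select(x$table, "effect", "route", "F", "df1", "df2", "p", "eta2")
}

#' Glance at a mixed ANOVA result
#'
#' @param x An `mst_anova` object.
#' @param ... Unused.
#' @return One-row tibble with the route, subject count and the
#'   interaction test.
#' @method glance mst_anova
#' @export
glance.mst_anova <- function(x, ...) {
  inter <- x$table[x$table$effect == "group:condition", ]
  tibble::tibble(route = x$route, n_subjects = x$n_subjects,
                 interaction_F = inter$F, interaction_p = inter$p)
}

#' Tidy a permutation correlation
#'
#' @param x A [perm_correlation()] result.
#' @param ... Unused.
#' @return One-row tibble with `estimate` (Pearson r), `p.value`
#'   (permutation), `n` and `n_perm`.
#' @method tidy perm_cor
#' @export
tidy.perm_cor <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p, n = x$n, n_perm = x$n_perm)
}

#' Tidy a spanning tree into its edge list
#'
#' @param x A [build_mst()] result.
#' @param ... Unused.
#' @return Edge tibble (`i`, `j`, `pli`, `dist`).
#' @method tidy spanning_tree
#' @export
tidy.spanning_tree <- function(x, ...) x$edges

#' Glance at a spanning tree
#'
#' @param x A [build_mst()] result.
#' @param ... Unused.
#' @return The one-row metric panel of [tree_metrics()].
#' @method glance spanning_tree
#' @export
glance.spanning_tree <- function(x, ...) tree_metrics(x)
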