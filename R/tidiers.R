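#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy quantile-treatment-effect results
#'
#' @param x A `ud_qte` object from [quantile_effects()].
#' @param ... Unused.
#' @return The effect table as a plain tibble.
#' @export
tidy.ud_qte <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ud_qte")
  as_tibble(out)
}

#' @rdname tidy.ud_qte
#' @export
glance.ud_qte <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    bootstrap_B = attr(x, "B"),
    control = attr(x, "control"),
    alpha = attr(x, "alpha"),
    comparisons = attr(x, "comparisons")
  )
}

#' Tidy factorial ANOVA results
#'
#' @param x A `ud_anova` object from [group_anova()].
#' @param component `"anova"` for the term table or `"contrasts"` for the
#'   Tukey pairwise contrasts.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ud_anova <- function(x, component = c("anova", "contrasts"), ...) {
  component <- match.arg(component)
  x[[component]]
}

#' @rdname tidy.ud_anova
#' @export
glance.ud_anova <- function(x, ...) {
  tibble(n_bats = x$n_bats, interaction = x$interaction)
}
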