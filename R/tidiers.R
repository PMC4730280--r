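# broom-style tidiers for fitted result objects.

#' Tidy an expression result
#'
#' @param x An `expression_result`.
#' @param ... Unused.
#' @return The per gene x condition summary tibble.
#' @method tidy expression_result
#' @export
tidy.expression_result <- function(x, ...) {
  x$summary
}

#' One-row summary of an expression result
#'
#' @param x An `expression_result`.
#' @param ... Unused.
#' @return Tibble with counts and the reference/calibrator names.
#' @method glance expression_result
#' @export
glance.expression_result <- function(x, ...) {
  tibble(
    n_genes = length(unique(x$summary$gene)),
    n_conditions = length(unique(x$summary$condition)),
    reference_gene = x$reference_gene,
    calibrator = x$calibrator
  )
}

#' Tidy an LSD result
#'
#' @param x An `lsd_result`.
#' @param ... Unused.
#' @return The pairwise comparison tibble with group means and letters
#'   joined in.
#' @method tidy lsd_result
#' @export
tidy.lsd_result <- function(x, ...) {
  x$pairs
}

#' One-row summary of an LSD result
#'
#' @param x An `lsd_result`.
#' @param ... Unused.
#' @return Tibble with group count, error df, pooled MSE and alpha.
#' @method glance lsd_result
#' @export
glance.lsd_result <- function(x, ...) {
  tibble(
    n_groups = nrow(x$letters),
    df_error = x$anova["Residuals", "Df"],
    mse = x$anova["Residuals", "Mean Sq"],
    alpha = x$alpha
  )
}
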