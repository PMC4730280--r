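# RT-qPCR analysis: 2^-ddCt relative expression with a reference gene and
# calibrator condition, Fisher's LSD multiple comparisons with a compact
# letter display, and Pearson correlations between expression patterns and
# with stage-wise karyogamy efficiency.

#' Relative expression by the 2^-ddCt method
#'
#' Per condition and replicate, dCt = target Ct - reference Ct (replicate Ct
#' values are averaged within a sample first when technical replicates
#' share a replicate id); ddCt subtracts the calibrator's mean dCt; relative
#' expression is 2^-ddCt. Amplification efficiency is assumed to be exactly
#' 2. By construction the calibrator's relative expression is exactly 1 for
#' any noise realisation. Standard errors are propagated to the linear scale
#' by the delta method.
#'
#' @param ct_table Tibble with `condition`, `gene`, `replicate`, `ct`.
#' @param reference_gene Reference (housekeeping) gene name.
#' @param calibrator Calibrator condition.
#' @return An `expression_result`: list with `summary` (per gene x
#'   condition: `dct`, `ddct`, `fold`, `se`, `n`) and `replicates` (per
#'   replicate dCt), plus the reference/calibrator names.
#' @export
ddct_fold_change <- function(ct_table, reference_gene, calibrator) {
  ct_table <- as_tibble(ct_table)
  if (!reference_gene %in% ct_table$gene) {
    sod_error(paste0("reference gene '", reference_gene,
                     "' absent from the Ct table"), "sod_input_error")
  }
  if (!calibrator %in% ct_table$condition) {
    sod_error(paste0("calibrator condition '", calibrator,
                     "' absent from the Ct table"), "sod_input_error")
  }
  ref <- ct_table[ct_table$gene == reference_gene, ]
  ref <- dplyr::summarise(
    dplyr::group_by(ref, .data$condition, .data$replicate),
    ref_ct = mean(.data$ct), .groups = "drop"
  )
  missing_ref <- dplyr::anti_join(
    dplyr::distinct(ct_table[ct_table$gene != reference_gene,
                             c("condition", "replicate")]),
    ref, by = c("condition", "replicate")
  )
  if (nrow(missing_ref) > 0L) {
    sod_error(
      paste0("no reference measurement for sample ", missing_ref$condition[1],
             "/rep", missing_ref$replicate[1]),
      "sod_input_error"
    )
  }
  targets <- ct_table[ct_table$gene != reference_gene, ]
  per_rep <- dplyr::summarise(
    dplyr::group_by(targets, .data$gene, .data$condition, .data$replicate),
    ct = mean(.data$ct), .groups = "drop"
  )
  per_rep <- dplyr::left_join(per_rep, ref, by = c("condition", "replicate"))
  per_rep$dct <- per_rep$ct - per_rep$ref_ct
  summary <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$gene, .data$condition),
    dct_se = sd(.data$dct) / sqrt(dplyr::n()),
    dct = mean(.data$dct),
    n = dplyr::n(),
    .groups = "drop"
  )
  cal <- summary[summary$condition == calibrator, c("gene", "dct")]
  names(cal)[2] <- "dct_cal"
  summary <- dplyr::left_join(summary, cal, by = "gene")
  summary$ddct <- summary$dct - summary$dct_cal
  summary$fold <- 2^(-summary$ddct)
  summary$se <- summary$fold * log(2) * summary$dct_se
  summary <- summary[, c("gene", "condition", "dct", "ddct", "fold", "se",
                         "n")]
  structure(
    list(summary = summary, replicates = per_rep,
         reference_gene = reference_gene, calibrator = calibrator),
    class = "expression_result"
  )
}

#' @export
print.expression_result <- function(x, ...) {
  cat("<expression_result> 2^-ddCt relative expression\n")
  cat("  reference gene:", x$reference_gene, " calibrator:", x$calibrator,
      "\n")
  print(x$summary)
  invisible(x)
}

#' Fisher's LSD test with a compact letter display
#'
#' One-way ANOVA provides the pooled error; all pairs are compared with LSD
#' t-tests at `alpha`, and letters are assigned with the insert-and-absorb
#' algorithm over groups sorted by mean so that two groups share a letter
#' iff they are not significantly different.
#'
#' @param values Tibble with `group` and `value` columns (>= 2 groups, each
#'   >= 2 replicates).
#' @param alpha Significance level.
#' @return An `lsd_result`: list with `letters` (group, mean, letter),
#'   `pairs` (pairwise p-values), and the ANOVA table.
#' @export
lsd_letters <- function(values, alpha = 0.05) {
  values <- as_tibble(values)
  values$group <- as.character(values$group)
  groups <- sort(unique(values$group))
  if (length(groups) < 2L) {
    sod_error("LSD needs at least two groups", "sod_input_error")
  }
  sizes <- table(values$group)
  if (any(sizes < 2L)) {
    sod_error("every group needs at least two replicates", "sod_input_error")
  }
  fit <- aov(value ~ group, data = values)
  tab <- suppressWarnings(anova(fit))
  mse <- tab["Residuals", "Mean Sq"]
  dfe <- tab["Residuals", "Df"]
  if (!is.finite(mse) ||
        mse <= 1e-12 * max(var(values$value), .Machine$double.eps)) {
    sod_error("zero within-group variance: LSD is degenerate",
              "sod_variance_error")
  }
  means <- vapply(groups, function(g) mean(values$value[values$group == g]),
                  numeric(1), USE.NAMES = FALSE)
  ns <- as.numeric(sizes[groups])
  pairs <- dplyr::bind_rows(lapply(seq_along(groups), function(i) {
    if (i == length(groups)) return(NULL)
    dplyr::bind_rows(lapply((i + 1L):length(groups), function(j) {
      tstat <- abs(means[i] - means[j]) /
        sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      tibble(
        group1 = groups[i], group2 = groups[j],
        diff = means[i] - means[j], t = tstat,
        p = 2 * pt(tstat, dfe, lower.tail = FALSE)
      )
    }))
  }))
  sig <- function(a, b) {
    p <- pairs$p[(pairs$group1 == a & pairs$group2 == b) |
                   (pairs$group1 == b & pairs$group2 == a)]
    p < alpha
  }
  # Letters = maximal cliques of the non-significance graph (groups ordered
  # by decreasing mean, ties by label): two groups share a letter iff their
  # difference is not significant, and sharing is transitive-consistent by
  # construction.
  ord <- order(-means, groups)
  adj <- outer(groups[ord], groups[ord],
               Vectorize(function(a, b) a == b || !sig(a, b)))
  sets <- maximal_cliques(adj, groups[ord])
  letter_of <- vapply(groups, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
  structure(
    list(
      letters = tibble(group = groups[ord], mean = means[ord],
                       letter = letter_of[ord]),
      pairs = pairs, anova = tab, alpha = alpha
    ),
    class = "lsd_result"
  )
}

#' @export
print.lsd_result <- function(x, ...) {
  cat("<lsd_result> Fisher's LSD at alpha =", x$alpha, "\n")
  print(x$letters)
  invisible(x)
}

# All maximal cliques of an undirected graph given as a logical adjacency
# matrix, in first-vertex order (small n; simple Bron-Kerbosch).
maximal_cliques <- function(adj, labels) {
  n <- nrow(adj)
  out <- list()
  bk <- function(r, p, x) {
    if (length(p) == 0L && length(x) == 0L) {
      out[[length(out) + 1L]] <<- labels[sort(r)]
      return()
    }
    for (v in p) {
      nb <- setdiff(which(adj[v, ]), v)
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(), seq_len(n), integer())
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return The correlation coefficient r in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    sod_error("pearson_correlation needs equal lengths >= 3",
              "sod_input_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    sod_error("undefined correlation: zero variance", "sod_variance_error")
  }
  cor(x, y, method = "pearson")
}

#' Stage-wise karyogamy efficiency
#'
#' Percentage of basidia having proceeded to karyogamy at three
#' fruiting-body stages: 37.5 (egg, 3 h), 30 (elongation, 9 h) and 0.1
#' (maturation, 7 h).
#'
#' @return Tibble with `stage`, `efficiency`.
#' @export
karyogamy_efficiency <- function() {
  tibble(
    stage = c("egg", "elongation", "maturation"),
    efficiency = c(37.5, 30, 0.1)
  )
}

#' Correlate stage-wise expression with karyogamy efficiency
#'
#' @param expression_by_stage Tibble with `gene`, `stage`, `expression`.
#' @param karyogamy Tibble with `stage`, `efficiency` (defaults to the
#'   recorded stage table).
#' @return Tibble with `gene`, `r`.
#' @export
karyogamy_correlation <- function(expression_by_stage,
                                  karyogamy = karyogamy_efficiency()) {
  expression_by_stage <- as_tibble(expression_by_stage)
  out <- lapply(split(expression_by_stage, expression_by_stage$gene),
                function(sub) {
    hit <- match(karyogamy$stage, sub$stage)
    if (anyNA(hit)) {
      sod_error(
        paste0("stage mismatch for gene '", sub$gene[1], "': missing ",
               karyogamy$stage[is.na(hit)][1]),
        "sod_input_error"
      )
    }
    tibble(gene = sub$gene[1],
           r = pearson_correlation(sub$expression[hit],
                                   karyogamy$efficiency))
  })
  dplyr::bind_rows(out)
}
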