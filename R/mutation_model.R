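# De novo mutation probabilities, constraint restriction and the global
# rescaling that anchors expected ultra-rare variant totals to the
# observed total.

prob_column <- function(class) {
  switch(class, truncating = "p_lof", missense = "p_mis",
         stop("unknown variant class: ", class))
}

oe_column <- function(class) {
  switch(class, truncating = "oe_lof", missense = "oe_mis",
         stop("unknown variant class: ", class))
}

#' Gene universe of a probability table
#'
#' Genes with a defined mutation probability for the given class.
#'
#' @param table A `probability_table`.
#' @param class `"truncating"` or `"missense"`.
#' @return Character vector of gene symbols.
#' @export
probability_universe <- function(table,
                                 class = c("truncating", "missense")) {
  class <- match.arg(class)
  table$gene[!is.na(table[[prob_column(class)]])]
}

#' Restrict the gene universe to constrained genes
#'
#' Keeps genes with a defined mutation probability and a defined
#' observed/expected constraint ratio strictly below the class threshold
#' (defaults: pLoF o/e < 0.35 for truncating, missense o/e < 0.75 for
#' missense). Genes absent from the constraint table are excluded.
#'
#' @param table A `probability_table`.
#' @param constraint A `constraint_table`.
#' @param class `"truncating"` or `"missense"`.
#' @param threshold Strict upper bound on o/e; class-specific default.
#' @return A restricted `probability_table`.
#' @export
restrict_to_constrained <- function(table, constraint,
                                    class = c("truncating", "missense"),
                                    threshold = NULL) {
  class <- match.arg(class)
  if (is.null(threshold)) {
    threshold <- if (class == "truncating") 0.35 else 0.75
  }
  stopifnot(threshold > 0)
  oe <- constraint[[oe_column(class)]][match(table$gene, constraint$gene)]
  keep <- !is.na(table[[prob_column(class)]]) & !is.na(oe) & oe < threshold
  if (!any(keep)) stop("no genes remain after constraint restriction")
  probability_table(table[keep, , drop = FALSE])
}

#' Compute the global scaling factor and rescaled success probabilities
#'
#' The scaling factor is chosen so that the expected and observed totals
#' of ultra-rare variants match over the gene universe:
#' `SF = N_obs / (N_S * sum_g p_g)`, and each gene's per-subject success
#' probability becomes `P_success,g = p_g * SF` (clamped at 1 with a
#' warning for pathological inputs). With the default
#' `n_obs = "universe"`, the observed total is restricted to variants in
#' universe genes, so the conservation identity
#' `sum_g P_success,g * N_S == N_obs` holds exactly within the analysis
#' universe; `n_obs = "all"` anchors on the full observed total instead.
#'
#' @param matrix A `gene_subject_matrix` of observed carrier indicators.
#' @param table A `probability_table` (possibly constraint-restricted)
#'   defining the gene universe.
#' @param n_subjects Number of cohort subjects (binomial trials);
#'   defaults to the matrix roster size.
#' @param n_obs `"universe"` (default) or `"all"`: which observed total
#'   anchors the scaling factor.
#' @return A `rescaled_model`: list with `class`, `sf`, `n_obs`,
#'   `n_subjects` and `genes` (data frame `gene`, `p_exp`, `p_success`).
#' @export
compute_scaling_factor <- function(matrix, table,
                                   n_subjects = matrix$n_subjects,
                                   n_obs = c("universe", "all")) {
  n_obs <- match.arg(n_obs)
  class <- matrix$class
  universe <- probability_universe(table, class)
  if (length(universe) == 0) stop("empty gene universe")
  counts <- gene_counts(matrix)
  observed <- if (n_obs == "universe") {
    sum(counts[names(counts) %in% universe])
  } else {
    sum(counts)
  }
  if (observed == 0) stop("no observed variants of class ", class)
  p_exp <- table[[prob_column(class)]][match(universe, table$gene)]
  sum_p <- sum(p_exp)
  if (sum_p == 0) stop("summed mutation probabilities are zero")
  sf <- observed / (n_subjects * sum_p)
  p_success <- p_exp * sf
  if (any(p_success > 1)) {
    clamped <- universe[p_success > 1]
    warning("P_success clamped to 1 for gene(s): ",
            paste(utils::head(clamped, 5), collapse = ", "))
    p_success <- pmin(p_success, 1)
  }
  structure(list(class = class, sf = sf, n_obs = observed,
                 n_subjects = n_subjects,
                 genes = data.frame(gene = universe, p_exp = p_exp,
                                    p_success = p_success,
                                    stringsAsFactors = FALSE)),
            class = "rescaled_model")
}

#' @export
print.rescaled_model <- function(x, ...) {
  cat(sprintf(
    "rescaled_model (%s): SF = %.4g, N_obs = %d, N_S = %d, %d gene(s)\n",
    x$class, x$sf, x$n_obs, x$n_subjects, nrow(x$genes)))
  invisible(x)
}

#' Per-gene rescaled success probabilities
#'
#' @param model A `rescaled_model`.
#' @return Named numeric vector gene -> `P_success,g`.
#' @export
success_probabilities <- function(model) {
  stats::setNames(model$genes$p_success, model$genes$gene)
}
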