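# Gene-level burden: one-sided binomial test against rescaled success
# probabilities, multiple-test correction, reference-singleton
# comparison, and 2x2 exact-test enrichment machinery.

binom_tail_p <- function(k, n, p) {
  # P(X >= k), X ~ Binomial(n, p); k = 0 gives 1
  ifelse(k <= 0, 1, stats::pbinom(k - 1, n, p, lower.tail = FALSE))
}

#' One-sided binomial burden test for a single gene
#'
#' Tests whether the observed number of distinct carrier subjects exceeds
#' expectation under the rescaled mutation probability:
#' `p = P(X >= N_success)` for `X ~ Binomial(N_S, P_success,g)`. Genes
#' with no observed variant get `p = 1`.
#'
#' @param model A `rescaled_model`.
#' @param matrix A `gene_subject_matrix` of the same class.
#' @param gene Gene symbol; must lie in the model universe.
#' @return One-row data frame: `gene`, `class`, `n_success`, `n_trials`,
#'   `p_success`, `p_value`.
#' @export
gene_binomial_test <- function(model, matrix, gene) {
  res <- gene_burden_test(model, matrix)
  row <- res[res$gene == gene, , drop = FALSE]
  if (nrow(row) == 0) stop("gene not in model universe: ", gene)
  rownames(row) <- NULL
  row
}

#' Gene burden test over the whole universe
#'
#' Vectorized [gene_binomial_test()] over every gene with a defined
#' (rescaled) mutation probability; genes without observed variants enter
#' with `n_success = 0` and `p_value = 1`.
#'
#' @param model A `rescaled_model`.
#' @param matrix A `gene_subject_matrix` of the same class.
#' @return Data frame with one row per universe gene: `gene`, `class`,
#'   `n_success`, `n_trials`, `p_success`, `p_value`.
#' @export
gene_burden_test <- function(model, matrix) {
  if (!is.null(matrix$class) && matrix$class != model$class) {
    stop("matrix class does not match model class")
  }
  counts <- gene_counts(matrix)
  k <- counts[model$genes$gene]
  k[is.na(k)] <- 0L
  n <- model$n_subjects
  if (any(k > n)) stop("carrier count exceeds subject count")
  data.frame(gene = model$genes$gene, class = model$class,
             n_success = as.integer(k), n_trials = n,
             p_success = model$genes$p_success,
             p_value = binom_tail_p(k, n, model$genes$p_success),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Multiple-test correction for gene burden results
#'
#' BH-FDR is computed per variant class over that class's full
#' defined-probability universe (genes without observed variants enter at
#' `p = 1`, or can be omitted); the Bonferroni correction multiplies each
#' p-value by the joint number of tests across both classes,
#' `m_truncating + m_missense`, capped at 1.
#'
#' @param truncating,missense Gene burden data frames from
#'   [gene_burden_test()] (either may be `NULL`).
#' @param unobserved `"include"` (default; zero-carrier genes enter
#'   corrections at `p = 1` and the universe size counts them) or
#'   `"omit"` (only genes with observed variants are tested and counted).
#' @return List with elements `truncating` and `missense`: the inputs
#'   with `bh_fdr` and `bonferroni` columns appended.
#' @export
correct_multiple_tests <- function(truncating = NULL, missense = NULL,
                                   unobserved = c("include", "omit")) {
  unobserved <- match.arg(unobserved)
  if (unobserved == "omit") {
    keep_obs <- function(res) {
      if (is.null(res)) NULL else res[res$n_success > 0, , drop = FALSE]
    }
    truncating <- keep_obs(truncating)
    missense <- keep_obs(missense)
  }
  m_t <- if (is.null(truncating)) 0L else nrow(truncating)
  m_m <- if (is.null(missense)) 0L else nrow(missense)
  m_joint <- m_t + m_m
  adjust <- function(res) {
    if (is.null(res)) return(NULL)
    res$bh_fdr <- stats::p.adjust(res$p_value, method = "BH")
    res$bonferroni <- pmin(1, res$p_value * m_joint)
    res
  }
  list(truncating = adjust(truncating),
       missense = adjust(missense))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with the conditional maximum-likelihood
#' odds ratio (the odds parameter maximizing the noncentral
#' hypergeometric likelihood given the margins); the two-sided p-value
#' sums the probabilities of all tables no more likely than the observed
#' one (minimum-likelihood rule). A zero cell in the appropriate position
#' yields an infinite odds ratio. The sample odds ratio `ad/bc` is also
#' reported for transparency.
#'
#' @param a,b,c_,d Non-negative integer cell counts, rows = cohort vs
#'   reference (or in-class vs out-of-class).
#' @param alternative `"greater"` (one-sided) or `"two_sided"`.
#' @return An `exact_test_result`: list with `p_value`, `alternative`,
#'   `odds_ratio` (conditional MLE), `sample_odds_ratio` and `table`.
#' @export
fisher_exact <- function(a, b, c_, d,
                         alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c_, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("all-zero contingency table")
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = if (alternative == "greater")
    "greater" else "two.sided")
  structure(list(p_value = ft$p.value, alternative = alternative,
                 odds_ratio = unname(ft$estimate),
                 sample_odds_ratio = if (b * c_ == 0) Inf else a * d / (b * c_),
                 table = tab),
            class = "exact_test_result")
}

#' @export
print.exact_test_result <- function(x, ...) {
  cat(sprintf("Fisher exact (%s): p = %.4g, OR (CMLE) = %.4g\n",
              x$alternative, x$p_value, x$odds_ratio))
  invisible(x)
}

#' Compare cohort ultra-rare burden to reference singletons
#'
#' For each gene, builds the 2x2 table (cohort ultra-rare variants in the
#' gene vs in other genes; reference singletons in the gene vs in other
#' genes) and applies a two-sided Fisher exact test, with BH-FDR across
#' tested genes. The universe is restricted to genes with at least one
#' reference truncating AND at least one reference missense singleton,
#' to avoid genes masked out of the reference.
#'
#' @param matrix A `gene_subject_matrix` of cohort carrier indicators.
#' @param singletons A `singleton_table`.
#' @param class `"truncating"` or `"missense"`.
#' @return Data frame: `gene`, `a`, `b`, `c`, `d`, `p_value`,
#'   `odds_ratio`, `bh_fdr` over the restricted universe.
#' @export
singleton_comparison <- function(matrix, singletons,
                                 class = c("truncating", "missense")) {
  class <- match.arg(class)
  eligible <- !is.na(singletons$n_singleton_lof) &
    !is.na(singletons$n_singleton_mis) &
    singletons$n_singleton_lof >= 1 & singletons$n_singleton_mis >= 1
  universe <- singletons$gene[eligible]
  if (length(universe) == 0) stop("empty singleton comparison universe")
  col <- if (class == "truncating") "n_singleton_lof" else "n_singleton_mis"
  ref <- singletons[[col]][match(universe, singletons$gene)]
  counts <- gene_counts(matrix)
  obs <- counts[universe]
  obs[is.na(obs)] <- 0L
  total_obs <- sum(counts)
  total_ref <- sum(ref)
  res <- data.frame(gene = universe, a = as.integer(obs),
                    b = total_obs - as.integer(obs),
                    c = as.integer(ref), d = total_ref - as.integer(ref),
                    stringsAsFactors = FALSE)
  stats_ <- lapply(seq_len(nrow(res)), function(i) {
    ft <- fisher_exact(res$a[i], res$b[i], res$c[i], res$d[i],
                       alternative = "two_sided")
    c(p = ft$p_value, or = ft$odds_ratio)
  })
  res$p_value <- vapply(stats_, `[[`, numeric(1), "p")
  res$odds_ratio <- vapply(stats_, `[[`, numeric(1), "or")
  res$bh_fdr <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Singleton comparison for one gene
#'
#' @inheritParams singleton_comparison
#' @param gene Gene symbol; must lie in the restricted universe.
#' @return An `exact_test_result`.
#' @export
singleton_comparison_test <- function(matrix, singletons, gene,
                                      class = c("truncating", "missense")) {
  class <- match.arg(class)
  res <- singleton_comparison(matrix, singletons, class)
  row <- res[res$gene == gene, , drop = FALSE]
  if (nrow(row) == 0) {
    stop("gene outside the singleton comparison universe: ", gene)
  }
  fisher_exact(row$a, row$b, row$c, row$d, alternative = "two_sided")
}

#' Protein annotation for region/residue-class enrichment
#'
#' @param gene Gene symbol.
#' @param length Protein length in amino acids.
#' @param regions Named list of closed aa intervals `c(start, end)`,
#'   e.g. `list(extracellular = c(19, 1735))`.
#' @param residue_classes Named list of integer aa positions, e.g.
#'   disulfide-bond cysteines.
#' @return A `protein_annotation` object.
#' @export
protein_annotation <- function(gene, length, regions = list(),
                               residue_classes = list()) {
  stopifnot(length >= 1)
  for (r in regions) {
    if (r[1] < 1 || r[2] > length || r[1] > r[2]) {
      stop("region interval outside [1, length]")
    }
  }
  for (pos in residue_classes) {
    if (any(pos < 1 | pos > length)) stop("residue position outside protein")
  }
  structure(list(gene = gene, length = length, regions = regions,
                 residue_classes = residue_classes),
            class = "protein_annotation")
}

#' Protein-region enrichment of cohort missense variants
#'
#' One-sided (greater) Fisher exact test of in-region vs out-of-region
#' variant counts, cohort vs reference.
#'
#' @param cohort_positions Amino-acid positions of cohort variants.
#' @param reference_positions Amino-acid positions of reference variants.
#' @param annotation A [protein_annotation()].
#' @param region Region name in `annotation$regions`.
#' @return An `exact_test_result`.
#' @export
region_enrichment <- function(cohort_positions, reference_positions,
                              annotation, region) {
  if (!region %in% names(annotation$regions)) {
    stop("unknown region: ", region)
  }
  if (length(cohort_positions) == 0) stop("no cohort variants")
  iv <- annotation$regions[[region]]
  inside <- function(p) p >= iv[1] & p <= iv[2]
  fisher_exact(sum(inside(cohort_positions)),
               sum(!inside(cohort_positions)),
               sum(inside(reference_positions)),
               sum(!inside(reference_positions)),
               alternative = "greater")
}

#' Residue-class enrichment of cohort missense variants
#'
#' One-sided (greater) Fisher exact test of variants altering a named
#' residue class (e.g. disulfide-bond cysteines) vs not, cohort vs
#' reference; membership means the variant's reference residue position
#' lies in the class position set.
#'
#' @inheritParams region_enrichment
#' @param residue_class Residue-class name in
#'   `annotation$residue_classes`.
#' @return An `exact_test_result`.
#' @export
residue_class_enrichment <- function(cohort_positions, reference_positions,
                                     annotation, residue_class) {
  if (!residue_class %in% names(annotation$residue_classes)) {
    stop("unknown residue class: ", residue_class)
  }
  if (length(cohort_positions) == 0) stop("no cohort variants")
  cls <- annotation$residue_classes[[residue_class]]
  a <- sum(cohort_positions %in% cls)
  c_ <- sum(reference_positions %in% cls)
  if (a + c_ == 0) stop("degenerate margin: no in-class variants")
  fisher_exact(a, length(cohort_positions) - a,
               c_, length(reference_positions) - c_,
               alternative = "greater")
}

#' Fraction of subjects carrying a qualifying variant in listed genes
#'
#' Distinct subjects in the subset carrying at least one variant in at
#' least one listed gene, over the subset size. Subjects carrying
#' variants in several listed genes count once.
#'
#' @param matrices A `gene_subject_matrix` or list of them (e.g.
#'   truncating and missense).
#' @param genes Gene symbols of interest.
#' @param subjects Subject subset (defaults to the full roster of the
#'   first matrix).
#' @return Fraction in `[0, 1]`.
#' @export
carrier_fraction <- function(matrices, genes, subjects = NULL) {
  if (inherits(matrices, "gene_subject_matrix")) matrices <- list(matrices)
  if (is.null(subjects)) subjects <- matrices[[1]]$subject_ids
  subjects <- as.character(subjects)
  if (length(subjects) == 0) stop("empty subject subset")
  if (length(genes) == 0) return(0)
  carriers <- unique(unlist(lapply(matrices, function(m) {
    cc <- m$counts
    cc$subject_id[cc$gene %in% genes]
  })))
  length(intersect(carriers, subjects)) / length(subjects)
}

#' Restrict a carrier matrix to a subject subset
#'
#' Used for subset re-analyses (e.g. re-running burden tests on one
#' phenotype subgroup with its own multiple-test correction).
#'
#' @param matrix A `gene_subject_matrix`.
#' @param subjects Subject identifiers to keep.
#' @return A `gene_subject_matrix` over the subset roster.
#' @export
subset_matrix <- function(matrix, subjects) {
  subjects <- as.character(subjects)
  missing <- setdiff(subjects, matrix$subject_ids)
  if (length(missing) > 0) {
    stop("unknown subject(s): ", paste(utils::head(missing, 5),
                                       collapse = ", "))
  }
  counts <- matrix$counts[matrix$counts$subject_id %in% subjects, ,
                          drop = FALSE]
  gene_subject_matrix(counts, class = matrix$class, subject_ids = subjects)
}
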