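# Gene-set burden: capped binomial test, greedy step-down Jaccard
# clustering to de-correlate overlapping sets, and a resampling-based
# FDR under the rescaled multinomial null.

#' Filter a gene-set collection for burden testing
#'
#' Sets are first intersected with the gene universe (genes with a
#' defined mutation probability); a set is retained iff it then has more
#' than 5 and fewer than 100 genes. When a constrained universe is also
#' given, sets with fewer than two constrained genes are removed (their
#' member lists stay intersected with the full universe).
#'
#' @param collection A `gene_set_collection`.
#' @param universe Character vector: the probability universe.
#' @param constrained_universe Optional character vector of constrained
#'   genes.
#' @param min_genes,max_genes Exclusive size bounds (defaults 5 and 100:
#'   keep `min_genes < n < max_genes`).
#' @return A filtered `gene_set_collection`.
#' @export
filter_genesets <- function(collection, universe,
                            constrained_universe = NULL,
                            min_genes = 5, max_genes = 100) {
  sets <- lapply(collection$sets, function(g) intersect(g, universe))
  sizes <- vapply(sets, length, integer(1))
  keep <- sizes > min_genes & sizes < max_genes
  if (!is.null(constrained_universe)) {
    n_constrained <- vapply(sets, function(g) {
      length(intersect(g, constrained_universe))
    }, integer(1))
    keep <- keep & n_constrained >= 2
  }
  gene_set_collection(sets[keep],
                      descriptions = collection$descriptions[keep],
                      source = collection$source)
}

#' Capped binomial burden test for one gene-set
#'
#' The success probability pools the member genes' rescaled
#' probabilities, `P_success = sum_{g in set} P_success,g` (clamped at 1
#' with a warning); the observed count caps contributions per subject,
#' `N_success = sum_s min(sum_{g in set} N_obs,g,s, 1)`, so a subject
#' with variants in several member genes counts once. One-sided binomial
#' test with `N_trials = N_S`.
#'
#' @param model A `rescaled_model`.
#' @param matrix A `gene_subject_matrix` of the same class.
#' @param genes Member gene symbols (already intersected with the
#'   universe; members outside the universe are dropped here).
#' @param name Optional set name for the result row.
#' @return One-row data frame: `set_name`, `n_genes`, `n_success`,
#'   `n_trials`, `p_success`, `p_value`.
#' @export
geneset_binomial_test <- function(model, matrix, genes,
                                  name = NA_character_) {
  genes <- intersect(genes, model$genes$gene)
  if (length(genes) == 0) stop("gene-set empty after universe intersection")
  p_success <- sum(success_probabilities(model)[genes])
  if (p_success > 1) {
    warning(sprintf("pooled P_success %.3g clamped to 1 for set %s",
                    p_success, name))
    p_success <- 1
  }
  cc <- matrix$counts
  carriers <- unique(cc$subject_id[cc$gene %in% genes])
  n_success <- length(carriers)
  data.frame(set_name = name, n_genes = length(genes),
             n_success = n_success, n_trials = model$n_subjects,
             p_success = p_success,
             p_value = binom_tail_p(n_success, model$n_subjects, p_success),
             stringsAsFactors = FALSE)
}

#' Gene-set burden test over a filtered collection
#'
#' @param model A `rescaled_model`.
#' @param matrix A `gene_subject_matrix`.
#' @param collection A filtered `gene_set_collection`.
#' @return Data frame with one row per set, sorted by `p_value`
#'   (ties broken by set name for determinism).
#' @export
geneset_burden_test <- function(model, matrix, collection) {
  rows <- lapply(names(collection$sets), function(nm) {
    geneset_binomial_test(model, matrix, collection$sets[[nm]], name = nm)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$p_value, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Ultra-rare variant identifiers of a gene-set: the (gene, subject)
# indicator entries of member genes.
variant_ids <- function(genes, matrix) {
  cc <- matrix$counts
  rows <- cc$gene %in% genes
  unique(paste(cc$gene[rows], cc$subject_id[rows], sep = "\r"))
}

#' Jaccard similarity of two gene-sets' ultra-rare variant sets
#'
#' Similarity is computed on variant sets, not member gene lists: each
#' set maps to the (gene, subject) carrier entries of its member genes,
#' and the ratio is `|intersection| / |union|` (0 when the union is
#' empty). This makes the clustering data-dependent: two sets are
#' correlated only insofar as they share observed variants.
#'
#' @param genes_i,genes_j Member gene vectors of the two sets.
#' @param matrix A `gene_subject_matrix`.
#' @return Jaccard fraction in `[0, 1]`.
#' @export
jaccard_variant_similarity <- function(genes_i, genes_j, matrix) {
  vi <- variant_ids(genes_i, matrix)
  vj <- variant_ids(genes_j, matrix)
  u <- union(vi, vj)
  if (length(u) == 0) return(0)
  length(intersect(vi, vj)) / length(u)
}

#' Greedy step-down selection of gene-set representatives
#'
#' Iteratively selects the most significant remaining gene-set, absorbs
#' every remaining set whose variant-set Jaccard similarity with it
#' exceeds the threshold, removes selected and absorbed sets, and
#' repeats until none remain. Only representatives proceed to the
#' multiple-test correction; an absorbed set inherits its
#' representative's p-value. p-value ties are broken lexicographically
#' by set name.
#'
#' @param results Data frame from [geneset_burden_test()].
#' @param collection The matching filtered `gene_set_collection`.
#' @param matrix The `gene_subject_matrix` the tests were run on.
#' @param threshold Jaccard threshold (absorb when strictly greater;
#'   default 0.5).
#' @return A `cluster_selection`: list with `representatives` (data
#'   frame `set_name`, `p_value`, `n_members` in selection order) and
#'   `members` (data frame `representative`, `set_name`, `jaccard`,
#'   covering every input set exactly once).
#' @export
greedy_stepdown_select <- function(results, collection, matrix,
                                   threshold = 0.5) {
  res <- results[order(results$p_value, results$set_name), , drop = FALSE]
  remaining <- res$set_name
  pvals <- stats::setNames(res$p_value, res$set_name)
  vsets <- lapply(collection$sets, variant_ids, matrix = matrix)
  reps <- character(0)
  members <- list()
  while (length(remaining) > 0) {
    sel <- remaining[1]
    rest <- remaining[-1]
    jac <- vapply(rest, function(nm) {
      u <- union(vsets[[sel]], vsets[[nm]])
      if (length(u) == 0) 0 else
        length(intersect(vsets[[sel]], vsets[[nm]])) / length(u)
    }, numeric(1))
    absorbed <- rest[jac > threshold]
    reps <- c(reps, sel)
    members[[length(members) + 1L]] <- data.frame(
      representative = sel,
      set_name = c(sel, absorbed),
      jaccard = c(1, unname(jac[match(absorbed, rest)])),
      stringsAsFactors = FALSE)
    remaining <- setdiff(rest, absorbed)
  }
  representatives <- data.frame(
    set_name = reps, p_value = unname(pvals[reps]),
    n_members = vapply(members, nrow, integer(1)),
    stringsAsFactors = FALSE)
  structure(list(representatives = representatives,
                 members = do.call(rbind, members)),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("cluster_selection: %d representative(s) of %d set(s)\n",
              nrow(x$representatives), nrow(x$members)))
  invisible(x)
}

#' Resample a carrier matrix under the rescaled multinomial null
#'
#' The total number of observed ultra-rare variants is held fixed and
#' redistributed over genes multinomially with probabilities
#' proportional to the rescaled per-gene success probabilities; each
#' resampled variant is assigned to a uniformly random subject.
#' Duplicate (gene, subject) draws are retained as counts and only
#' capped downstream by the per-gene / per-set min(., 1) rules.
#'
#' @param model A `rescaled_model` (supplies `N_obs` and the gene
#'   probabilities).
#' @param n_subjects Number of subjects (default from the model).
#' @param seed Optional integer seed for reproducibility.
#' @return A `gene_subject_matrix` with synthetic subject labels
#'   `S1..Sn`.
#' @export
resample_counts <- function(model, n_subjects = model$n_subjects,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- model$genes$p_success
  gene_draw <- stats::rmultinom(1, model$n_obs, probs / sum(probs))[, 1]
  nz <- which(gene_draw > 0)
  gene <- rep(model$genes$gene[nz], gene_draw[nz])
  subj <- paste0("S", sample.int(n_subjects, length(gene), replace = TRUE))
  agg <- stats::aggregate(
    list(count = rep(1L, length(gene))),
    by = list(gene = gene, subject_id = subj), FUN = sum)
  gene_subject_matrix(agg, class = model$class,
                      subject_ids = paste0("S", seq_len(n_subjects)))
}

#' Resampling-based FDR for selected gene-set representatives
#'
#' For each permutation iteration, the observed variant total is
#' resampled over genes under the rescaled null ([resample_counts()]),
#' the gene-set burden tests are re-run, and (by default) the greedy
#' step-down selection is re-applied. For each real representative's
#' p-value threshold `p`, the FDR is the mean permutation count of
#' selected sets with p-value at or below `p`, divided by the real
#' count, clamped to `[0, 1]` and monotonized (cumulative minimum from
#' the least to the most significant threshold).
#'
#' @param selection A real-data `cluster_selection`.
#' @param collection The filtered `gene_set_collection` used for the real
#'   analysis.
#' @param model The `rescaled_model` of the class under test.
#' @param n_subjects Number of subjects (default from the model).
#' @param iterations Number of permutation iterations (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @param perm_selection `"rerun"` (default; greedy selection re-applied
#'   to each permutation) or `"fixed"` (all permuted sets counted).
#' @return A `resampling_fdr_result`: data frame `set_name`,
#'   `p_value`, `ngs_real`, `mean_ngs_perm`, `fdr` plus attributes
#'   `iterations` and `seed`.
#' @export
resampling_fdr <- function(selection, collection, model,
                           n_subjects = model$n_subjects,
                           iterations = 1000, seed = NULL,
                           perm_selection = c("rerun", "fixed")) {
  perm_selection <- match.arg(perm_selection)
  if (iterations < 1) stop("iterations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  reps <- selection$representatives
  if (nrow(reps) == 0) stop("empty cluster selection")
  thresholds <- reps$p_value
  ngs_real <- vapply(thresholds, function(t) sum(reps$p_value <= t),
                     numeric(1))
  perm_counts <- matrix(0, nrow = iterations, ncol = length(thresholds))
  for (i in seq_len(iterations)) {
    m_i <- resample_counts(model, n_subjects)
    res_i <- geneset_burden_test(model, m_i, collection)
    p_i <- if (perm_selection == "rerun") {
      greedy_stepdown_select(res_i, collection, m_i)$representatives$p_value
    } else {
      res_i$p_value
    }
    perm_counts[i, ] <- vapply(thresholds, function(t) sum(p_i <= t),
                               numeric(1))
  }
  mean_perm <- colMeans(perm_counts)
  fdr_raw <- pmin(1, mean_perm / ngs_real)
  # monotonize: FDR non-increasing with significance
  ord <- order(thresholds, decreasing = TRUE)
  fdr <- fdr_raw
  fdr[ord] <- cummin(fdr_raw[ord])
  out <- data.frame(set_name = reps$set_name, p_value = thresholds,
                    ngs_real = as.integer(ngs_real),
                    mean_ngs_perm = mean_perm, fdr = fdr,
                    stringsAsFactors = FALSE)
  attr(out, "iterations") <- iterations
  attr(out, "seed") <- seed
  class(out) <- c("resampling_fdr_result", "data.frame")
  out
}
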