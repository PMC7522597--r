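# Fixture builders and independent oracles shared across the suite.

# One fully-populated clean variant record; override any field.
make_record <- function(...) {
  rec <- data.frame(
    subject_id = "S1", chrom = "chr1", pos = 100L, ref = "C", alt = "T",
    gene = "GENE1", transcript = "TX_GENE1.1", effect = "stopgain",
    zygosity = "het", DP = 30L, GQ = 99L, alt_fraction = 0.5,
    af_1000g = NA_real_, af_exac = NA_real_, af_gnomad = NA_real_,
    cohort_allele_count = 1L, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

make_cohort <- function(..., subject_ids = NULL) {
  cohort_table(do.call(rbind, list(...)), subject_ids = subject_ids)
}

# Small probability table with round numbers.
tiny_prob_table <- function(genes = c("GENE1", "GENE2", "GENE3"),
                            p_lof = c(0.001, 0.002, 0.001),
                            p_mis = c(0.002, 0.004, 0.002)) {
  probability_table(data.frame(gene = genes, p_lof = p_lof, p_mis = p_mis,
                               stringsAsFactors = FALSE))
}

# Carrier matrix built directly from (gene, subject) pairs.
make_matrix <- function(gene, subject_id, class = "truncating",
                        subject_ids = unique(subject_id)) {
  gene_subject_matrix(
    data.frame(gene = gene, subject_id = subject_id,
               count = rep(1L, length(gene)), stringsAsFactors = FALSE),
    class = class, subject_ids = subject_ids)
}

# --- independent oracles -------------------------------------------------

# Brute-force upper binomial tail by direct summation of the pmf.
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(x) choose(n, x) * p^x * (1 - p)^(n - x),
             numeric(1)))
}

# Fisher exact by full enumeration of tables with the observed margins.
# Returns one-sided (greater in cell a) and two-sided
# (minimum-likelihood rule) p-values.
oracle_fisher <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(support, function(x) stats::dhyper(x, c1, n - c1, r1),
                  numeric(1))
  p_obs <- probs[match(a, support)]
  list(greater = sum(probs[support >= a]),
       two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Noncentral hypergeometric log-likelihood of cell a given margins.
nch_loglik <- function(psi, a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  logw <- lchoose(r1, support) + lchoose(n - r1, c1 - support) +
    support * log(psi)
  logw[match(a, support)] - log(sum(exp(logw - max(logw)))) - max(logw)
}

# Exhaustive reference for the greedy step-down procedure: a direct
# re-implementation with explicit set operations on (name, p) pairs.
oracle_greedy <- function(pvals, variant_sets, threshold = 0.5) {
  remaining <- names(sort(pvals))
  # stable tie-break by name
  ord <- order(pvals[remaining], remaining)
  remaining <- remaining[ord]
  reps <- character(0)
  while (length(remaining) > 0) {
    sel <- remaining[1]
    reps <- c(reps, sel)
    absorbed <- character(0)
    for (nm in remaining[-1]) {
      u <- union(variant_sets[[sel]], variant_sets[[nm]])
      j <- if (length(u) == 0) 0 else
        length(intersect(variant_sets[[sel]], variant_sets[[nm]])) /
        length(u)
      if (j > threshold) absorbed <- c(absorbed, nm)
    }
    remaining <- setdiff(remaining[-1], absorbed)
  }
  reps
}

# Write a canonical variant TSV fixture and return its path.
write_variant_fixture <- function(records, path = tempfile(fileext = ".tsv")) {
  write_variant_table(cohort_table(records), path)
  path
}
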