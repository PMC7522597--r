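# Synthetic cohorts with known ground truth: multinomial null over a
# per-gene mutation probability table, optional per-gene burden
# injection, and planted QC violations. Truth labels travel in a side
# channel, never in the variant table itself, so the pipeline cannot
# peek.

#' Simulate a per-gene mutation probability table
#'
#' Per-gene truncating and missense probabilities drawn log-uniformly
#' over `prob_range` (default 1e-7 to 1e-4), mimicking the dynamic range
#' of published sequence-context mutation probability tables.
#'
#' @param n_genes Number of genes.
#' @param prob_range Length-2 numeric range for the log-uniform draw.
#' @param seed Optional integer seed.
#' @return A `probability_table` with genes `G00001..`.
#' @export
simulate_probability_table <- function(n_genes = 18500,
                                       prob_range = c(1e-7, 1e-4),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_genes >= 1, prob_range[1] > 0, prob_range[2] < 1)
  lo <- log(prob_range[1]); hi <- log(prob_range[2])
  probability_table(data.frame(
    gene = sprintf("G%05d", seq_len(n_genes)),
    p_lof = exp(stats::runif(n_genes, lo, hi)),
    p_mis = exp(stats::runif(n_genes, lo, hi)),
    stringsAsFactors = FALSE))
}

#' Specification for a synthetic cohort
#'
#' Defaults reproduce the study conditions the package is calibrated
#' under: 231 subjects, 642 clean ultra-rare truncating and 3293 clean
#' ultra-rare missense variants distributed multinomially over a
#' log-uniform probability table.
#'
#' @param n_subjects Cohort size.
#' @param probability_table Optional `probability_table`; synthesized
#'   from `n_genes`/`prob_range` when `NULL`.
#' @param n_genes,prob_range Passed to [simulate_probability_table()]
#'   when no table is given.
#' @param n_truncating,n_missense Clean ultra-rare variant totals per
#'   class.
#' @param injections List of `list(gene =, class =, carriers =)` burden
#'   injections: `carriers` extra clean variants in distinct subjects.
#' @param qc_rates Named list of planted QC-violation rates in `[0, 1]`
#'   (fractions of the total clean variant count): `low_dp`, `low_af`,
#'   `ref_freq`, `non_principal`, `cohort_dup`, `multi_indel`.
#' @param seed Optional integer seed.
#' @return A `synthetic_cohort_spec` list.
#' @export
synthetic_cohort_spec <- function(n_subjects = 231,
                                  probability_table = NULL,
                                  n_genes = 18500,
                                  prob_range = c(1e-7, 1e-4),
                                  n_truncating = 642, n_missense = 3293,
                                  injections = list(),
                                  qc_rates = list(), seed = NULL) {
  defaults <- list(low_dp = 0, low_af = 0, ref_freq = 0,
                   non_principal = 0, cohort_dup = 0, multi_indel = 0)
  unknown <- setdiff(names(qc_rates), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown qc_rates name(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(qc_rates)] <- qc_rates
  if (any(unlist(defaults) < 0 | unlist(defaults) > 1)) {
    stop("qc rates must lie in [0, 1]")
  }
  for (inj in injections) {
    stopifnot(all(c("gene", "class", "carriers") %in% names(inj)))
    if (inj$carriers > n_subjects) {
      stop("injection exceeds n_subjects for gene ", inj$gene)
    }
  }
  structure(list(n_subjects = n_subjects,
                 probability_table = probability_table,
                 n_genes = n_genes, prob_range = prob_range,
                 n_truncating = n_truncating, n_missense = n_missense,
                 injections = injections, qc_rates = defaults,
                 seed = seed),
            class = "synthetic_cohort_spec")
}

principal_map_for <- function(genes) {
  stats::setNames(paste0("TX_", genes, ".1"), genes)
}

blank_record <- function(n) {
  data.frame(subject_id = character(n), chrom = character(n),
             pos = integer(n), ref = character(n), alt = character(n),
             gene = character(n), transcript = character(n),
             effect = character(n), zygosity = rep("het", n),
             DP = integer(n), GQ = rep(99L, n),
             alt_fraction = numeric(n),
             af_1000g = rep(NA_real_, n), af_exac = rep(NA_real_, n),
             af_gnomad = rep(NA_real_, n),
             cohort_allele_count = rep(1L, n), stringsAsFactors = FALSE)
}

fill_clean <- function(rec, genes, gene_index, subjects, effects,
                       pos_offset = 0L) {
  n <- nrow(rec)
  rec$subject_id <- subjects
  rec$gene <- genes
  rec$chrom <- paste0("chr", (gene_index %% 22L) + 1L)
  rec$pos <- gene_index * 10000L + pos_offset + seq_len(n)
  rec$transcript <- paste0("TX_", genes, ".1")
  rec$effect <- effects
  is_ins <- effects == "frameshift_insertion"
  is_del <- effects == "frameshift_deletion"
  rec$ref <- ifelse(is_del, "AT", ifelse(is_ins, "A", "C"))
  rec$alt <- ifelse(is_del, "A", ifelse(is_ins, "AT", "T"))
  rec$DP <- 20L + stats::rpois(n, 15)
  rec$alt_fraction <- stats::runif(n, 0.35, 0.65)
  rec
}

draw_class_records <- function(table, class, total, subject_pool,
                               effect_mix, pos_offset = 0L) {
  if (total < 1) return(blank_record(0L))
  p <- table[[prob_column(class)]]
  counts <- stats::rmultinom(1, total, p / sum(p))[, 1]
  nz <- which(counts > 0)
  ns <- length(subject_pool)
  k <- pmin(counts[nz], ns)
  gene_index <- rep(nz, k)
  # distinct subjects per gene so clean totals survive the per-gene
  # per-subject collapse exactly
  subj <- unlist(lapply(seq_along(nz), function(i) {
    if (k[i] == 1L) subject_pool[sample.int(ns, 1L)]
    else subject_pool[sample.int(ns, k[i])]
  }), use.names = FALSE)
  n <- length(gene_index)
  eff <- sample(names(effect_mix), n, replace = TRUE, prob = effect_mix)
  fill_clean(blank_record(n), table$gene[gene_index], gene_index, subj,
             eff, pos_offset = pos_offset)
}

#' Simulate a synthetic cohort
#'
#' Clean ultra-rare variants are drawn multinomially over genes in
#' proportion to the class mutation probability, with subjects assigned
#' uniformly (distinct within a gene); burden injections add clean
#' variants in distinct extra carriers; QC violations of each requested
#' type are planted as additional records that the filter cascade must
#' remove. Fixed seeds reproduce the output exactly.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return A list of class `synthetic_cohort`: `cohort` (the
#'   [cohort_table()]), `probability_table`, `principal_map`, and
#'   `truth` (data frame labelling planted violation and injection
#'   records; empty under the pure null).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  table <- spec$probability_table
  if (is.null(table)) {
    table <- simulate_probability_table(spec$n_genes, spec$prob_range)
  }
  subjects <- sprintf("SUBJ%04d", seq_len(spec$n_subjects))
  trunc_mix <- c(stopgain = 0.7, frameshift_insertion = 0.15,
                 frameshift_deletion = 0.15)
  recs <- rbind(
    draw_class_records(table, "truncating", spec$n_truncating, subjects,
                       trunc_mix),
    draw_class_records(table, "missense", spec$n_missense, subjects,
                       c(missense = 1), pos_offset = 4000L))
  truth <- list()
  mark <- function(rec, label) {
    data.frame(subject_id = rec$subject_id, gene = rec$gene,
               chrom = rec$chrom, pos = rec$pos, label = label,
               stringsAsFactors = FALSE)
  }
  # burden injections: distinct carriers, preferring subjects without a
  # variant already in that gene
  for (inj in spec$injections) {
    g <- inj$gene
    j <- match(g, table$gene)
    if (is.na(j)) stop("injection gene not in probability table: ", g)
    have <- unique(recs$subject_id[recs$gene == g])
    pool <- setdiff(subjects, have)
    if (length(pool) < inj$carriers) pool <- subjects
    subj <- sample(pool, inj$carriers)
    eff <- if (inj$class == "truncating") {
      sample(names(trunc_mix), inj$carriers, replace = TRUE,
             prob = trunc_mix)
    } else rep("missense", inj$carriers)
    rec <- fill_clean(blank_record(inj$carriers), rep(g, inj$carriers), j,
                      subj, eff, pos_offset = 5000L)
    truth[[length(truth) + 1L]] <- mark(rec, paste0("inject_", inj$class))
    recs <- rbind(recs, rec)
  }
  # planted QC violations, each violating exactly one filter
  n_clean <- spec$n_truncating + spec$n_missense
  plant <- function(n, build, label) {
    if (n < 1) return(invisible(NULL))
    j <- sample(nrow(table), n, replace = TRUE)
    subj <- sample(subjects, n, replace = TRUE)
    eff <- sample(c("stopgain", "missense"), n, replace = TRUE)
    rec <- fill_clean(blank_record(n), table$gene[j], j, subj, eff,
                      pos_offset = 7000L)
    rec <- build(rec)
    truth[[length(truth) + 1L]] <<- mark(rec, label)
    recs <<- rbind(recs, rec)
  }
  rates <- spec$qc_rates
  plant(round(rates$low_dp * n_clean), function(r) {
    r$DP <- sample(0:10, nrow(r), replace = TRUE); r
  }, "low_dp")
  plant(round(rates$low_af * n_clean), function(r) {
    r$alt_fraction <- stats::runif(nrow(r), 0.05, 0.25); r
  }, "low_af")
  plant(round(rates$ref_freq * n_clean), function(r) {
    r$af_gnomad <- 1e-5; r
  }, "ref_freq")
  plant(round(rates$non_principal * n_clean), function(r) {
    r$transcript <- paste0(r$transcript, "_alt"); r
  }, "non_principal")
  plant(round(rates$cohort_dup * n_clean), function(r) {
    r$cohort_allele_count <- 2L; r
  }, "cohort_dup")
  n_multi <- round(rates$multi_indel * n_clean)
  if (n_multi >= 1) {
    j <- sample(nrow(table), n_multi, replace = TRUE)
    subj <- sample(subjects, n_multi, replace = TRUE)
    for (i in seq_len(n_multi)) {
      # +1 and +2 insertions: cumulative size 3, removed by the
      # frameshift indel collapse
      pair <- fill_clean(blank_record(2L), rep(table$gene[j[i]], 2L), j[i],
                         rep(subj[i], 2L),
                         rep("frameshift_insertion", 2L),
                         pos_offset = 8000L + 2L * i)
      pair$alt <- c("AT", "ATT")
      truth[[length(truth) + 1L]] <- mark(pair, "multi_indel")
      recs <- rbind(recs, pair)
    }
  }
  truth <- if (length(truth) == 0) {
    data.frame(subject_id = character(0), gene = character(0),
               chrom = character(0), pos = integer(0),
               label = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, truth)
  structure(list(cohort = cohort_table(recs, subject_ids = subjects),
                 probability_table = table,
                 principal_map = principal_map_for(table$gene),
                 truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d record(s), %d subject(s), %d planted label(s)\n",
    nrow(x$cohort), n_subjects(x$cohort), nrow(x$truth)))
  invisible(x)
}

#' Simulate a reference singleton count table
#'
#' Per-gene singleton counts drawn multinomially in proportion to the
#' class mutation probabilities, with every gene guaranteed at least one
#' singleton of each class (matching the comparison-universe restriction
#' to genes not masked out of the reference).
#'
#' @param table A `probability_table`.
#' @param total_lof,total_mis Total singleton counts per class; each must
#'   be at least the number of genes.
#' @param seed Optional integer seed.
#' @return A `singleton_table`.
#' @export
simulate_singletons <- function(table, total_lof, total_mis, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(table)
  draw <- function(total, p) {
    if (total < n) stop("total singletons below gene count; cannot ",
                        "guarantee one per gene")
    1L + stats::rmultinom(1, total - n, p / sum(p))[, 1]
  }
  structure(data.frame(gene = table$gene,
                       n_singleton_lof = draw(total_lof, table$p_lof),
                       n_singleton_mis = draw(total_mis, table$p_mis),
                       stringsAsFactors = FALSE),
            class = c("singleton_table", "data.frame"))
}

#' Simulate a gene-set collection with optional planted clusters
#'
#' Generates gene-sets sampled from the universe, either mutually
#' independent (`overlap = "none"`) or with planted clusters of sets
#' sharing a fixed fraction of members (`overlap = "planted"`), for
#' exercising the Jaccard clustering. Ground-truth cluster labels are
#' attached as attribute `cluster` (0 for independent sets).
#'
#' @param universe Character vector of gene symbols.
#' @param n_sets Number of sets.
#' @param size_range Inclusive set-size range (default 6 to 99, within
#'   the burden filter bounds).
#' @param overlap `"none"` or `"planted"`.
#' @param n_clusters,sets_per_cluster Planted-cluster design.
#' @param share Fraction of members shared within a planted cluster
#'   (default 0.75, above the 0.5 Jaccard threshold under full
#'   carriage).
#' @param seed Optional integer seed.
#' @return A `gene_set_collection` with attribute `cluster`.
#' @export
simulate_genesets <- function(universe, n_sets = 20,
                              size_range = c(6, 99),
                              overlap = c("none", "planted"),
                              n_clusters = 2, sets_per_cluster = 3,
                              share = 0.75, seed = NULL) {
  overlap <- match.arg(overlap)
  if (!is.null(seed)) set.seed(seed)
  if (length(universe) < size_range[2]) {
    stop("universe smaller than the maximum set size")
  }
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  sets <- vector("list", n_sets)
  cluster <- integer(n_sets)
  i <- 1L
  if (overlap == "planted") {
    for (cl in seq_len(n_clusters)) {
      base_size <- sizes[i]
      base <- sample(universe, base_size)
      core <- base[seq_len(max(2L, round(share * base_size)))]
      for (s in seq_len(sets_per_cluster)) {
        if (i > n_sets) break
        fresh <- sample(setdiff(universe, core),
                        max(1L, base_size - length(core)))
        sets[[i]] <- unique(c(core, fresh))
        cluster[i] <- cl
        i <- i + 1L
      }
    }
  }
  while (i <= n_sets) {
    sets[[i]] <- sample(universe, sizes[i])
    cluster[i] <- 0L
    i <- i + 1L
  }
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  out <- gene_set_collection(sets, source = "synthetic")
  attr(out, "cluster") <- stats::setNames(cluster, names(sets))
  out
}
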