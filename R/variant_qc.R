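# Filter cascade: raw annotated calls -> per-gene per-subject ultra-rare
# carrier indicators. Every filter only removes (or reclassifies)
# records, so stage counts are non-increasing and each filter is
# idempotent.

.truncating_effects <- c("stopgain", "frameshift_insertion",
                         "frameshift_deletion", "splice_donor",
                         "splice_acceptor")

#' Classify effects into truncating / missense / other
#'
#' Truncating (LoF) comprises stop gains, frameshift indels and canonical
#' splice-site alterations; missense is the missense label; everything
#' else is "other".
#'
#' @param effect Character vector of controlled-vocabulary effect labels.
#' @return Character vector in `{truncating, missense, other}`.
#' @export
effect_class <- function(effect) {
  ifelse(effect %in% .truncating_effects, "truncating",
         ifelse(effect == "missense", "missense", "other"))
}

#' Select ultra-rare variants
#'
#' Keeps records seen exactly once in the cohort
#' (`cohort_allele_count == 1`) and absent from all population references
#' (1000 Genomes, ExAC, gnomAD frequencies missing or exactly zero).
#'
#' @param cohort A [cohort_table()].
#' @return Filtered [cohort_table()].
#' @export
select_ultra_rare <- function(cohort) {
  absent <- function(af) is.na(af) | af == 0
  keep <- cohort$cohort_allele_count == 1 &
    absent(cohort$af_1000g) & absent(cohort$af_exac) &
    absent(cohort$af_gnomad)
  rebuild_cohort(cohort[keep, , drop = FALSE], cohort)
}

#' Remove low-quality variant calls
#'
#' A record is removed iff any of: read depth `DP <= dp_max_remove`;
#' heterozygous with `alt_fraction < het_alt_min` or `GQ < het_gq_min`;
#' homozygous with `alt_fraction < hom_alt_min` or `GQ <= hom_gq_max`.
#' With the defaults, het calls are kept only at the GQ cap of 99 and hom
#' calls only with GQ above 25.
#'
#' @param cohort A [cohort_table()].
#' @param dp_max_remove Remove if `DP` at or below this (default 10).
#' @param het_alt_min,het_gq_min Het thresholds (defaults 0.3 and 99;
#'   removal is strict `<`).
#' @param hom_alt_min,hom_gq_max Hom thresholds (defaults 0.8, removal
#'   strict `<`; and 25, removal at or below).
#' @return Filtered [cohort_table()].
#' @export
filter_low_quality <- function(cohort, dp_max_remove = 10,
                               het_alt_min = 0.3, het_gq_min = 99,
                               hom_alt_min = 0.8, hom_gq_max = 25) {
  if (nrow(cohort) == 0) return(cohort)
  bad_zyg <- !cohort$zygosity %in% c("het", "hom")
  if (any(bad_zyg)) {
    stop("unknown zygosity for record(s): ",
         paste(utils::head(which(bad_zyg), 5), collapse = ", "))
  }
  het <- cohort$zygosity == "het"
  remove <- cohort$DP <= dp_max_remove |
    (het & (cohort$alt_fraction < het_alt_min | cohort$GQ < het_gq_min)) |
    (!het & (cohort$alt_fraction < hom_alt_min | cohort$GQ <= hom_gq_max))
  rebuild_cohort(cohort[!remove, , drop = FALSE], cohort)
}

# Signed indel size: insertions positive, deletions negative.
indel_size <- function(ref, alt) nchar(alt) - nchar(ref)

#' Collapse multiple frameshift indels per gene per subject
#'
#' Whenever one subject carries two or more frameshift indels in the same
#' gene, they are removed entirely if their cumulative size is a multiple
#' of 3 (the shifts cancel and the net effect is in-frame); otherwise a
#' single representative (smallest chrom, pos; deterministic) is kept.
#'
#' @param cohort A [cohort_table()].
#' @param size_mode `"signed"` (insertions +, deletions -; default) or
#'   `"absolute"` when accumulating indel sizes.
#' @return Filtered [cohort_table()].
#' @export
collapse_frameshift_indels <- function(cohort,
                                       size_mode = c("signed", "absolute")) {
  size_mode <- match.arg(size_mode)
  if (nrow(cohort) == 0) return(cohort)
  is_fs <- cohort$effect %in% c("frameshift_insertion", "frameshift_deletion")
  if (!any(is_fs)) return(cohort)
  fs <- cohort[is_fs, , drop = FALSE]
  sizes <- indel_size(fs$ref, fs$alt)
  if (size_mode == "absolute") sizes <- abs(sizes)
  grp <- paste(fs$subject_id, fs$gene, sep = "\r")
  drop_local <- logical(nrow(fs))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    if (sum(sizes[idx]) %% 3 == 0) {
      drop_local[idx] <- TRUE
    } else {
      ord <- order(fs$chrom[idx], fs$pos[idx])
      drop_local[idx[-ord[1]]] <- TRUE
    }
  }
  drop <- rep(FALSE, nrow(cohort))
  drop[which(is_fs)[drop_local]] <- TRUE
  rebuild_cohort(cohort[!drop, , drop = FALSE], cohort)
}

#' Rescue splice-site insertions that restore a canonical dinucleotide
#'
#' Insertions annotated as splice donor/acceptor alterations are kept as
#' truncating only if the alternate allele sequence no longer encodes a
#' canonical GT (donor) / AG (acceptor) intronic dinucleotide at the
#' annotated position. The local alternate sequence is reconstructed by
#' applying the insertion to the reference context; if the canonical
#' dinucleotide (on the annotated strand) is present at exactly the
#' annotated offset, the record is reclassified to effect `"other"`.
#' Records without splice annotation are retained as truncating with a
#' warning (conservative).
#'
#' @param cohort A [cohort_table()].
#' @param splice_annotation Data frame with columns `transcript`,
#'   `chrom`, `role` (`donor`/`acceptor`), `strand` (`+`/`-`),
#'   `dinuc_pos` (1-based genomic position of the first dinucleotide
#'   base), `context_start` (genomic position of the first base of
#'   `context`) and `context` (reference sequence around the site,
#'   typically +/- 10 bp).
#' @return A [cohort_table()] with rescued records reclassified.
#' @export
filter_splice_insertions <- function(cohort, splice_annotation) {
  if (nrow(cohort) == 0) return(cohort)
  is_target <- cohort$effect %in% c("splice_donor", "splice_acceptor") &
    nchar(cohort$alt) > nchar(cohort$ref)
  if (!any(is_target)) return(cohort)
  canonical <- c(`donor+` = "GT", `donor-` = "AC",
                 `acceptor+` = "AG", `acceptor-` = "CT")
  effects <- cohort$effect
  for (i in which(is_target)) {
    ann <- splice_annotation[
      splice_annotation$transcript == cohort$transcript[i] &
        splice_annotation$chrom == cohort$chrom[i], , drop = FALSE]
    if (nrow(ann) > 1) {
      # nearest annotated site for this transcript
      ann <- ann[which.min(abs(ann$dinuc_pos - cohort$pos[i])), , drop = FALSE]
    }
    if (nrow(ann) == 0) {
      warning(sprintf("no splice annotation for %s %s:%d; retained",
                      cohort$transcript[i], cohort$chrom[i], cohort$pos[i]))
      next
    }
    ctx <- ann$context[1]
    offset_dinuc <- ann$dinuc_pos[1] - ann$context_start[1] + 1L
    ins_after <- cohort$pos[i] - ann$context_start[1] + 1L
    inserted <- substr(cohort$alt[i], nchar(cohort$ref[i]) + 1L,
                       nchar(cohort$alt[i]))
    if (ins_after < 0 || ins_after > nchar(ctx)) next
    alt_seq <- paste0(substr(ctx, 1, ins_after), inserted,
                      substr(ctx, ins_after + 1L, nchar(ctx)))
    want <- canonical[paste0(ann$role[1], ann$strand[1])]
    if (substr(alt_seq, offset_dinuc, offset_dinuc + 1L) == want) {
      effects[i] <- "other"
    }
  }
  out <- cohort
  out$effect <- effects
  rebuild_cohort(as.data.frame(out), cohort)
}

#' Keep only variants affecting the principal transcript
#'
#' @param cohort A [cohort_table()].
#' @param principal_map Named character vector gene -> principal
#'   transcript (see [read_principal_map()]). Records whose gene has no
#'   principal transcript are removed and counted in attribute
#'   `n_unmapped`.
#' @return Filtered [cohort_table()].
#' @export
filter_principal_transcript <- function(cohort, principal_map) {
  if (nrow(cohort) == 0) return(cohort)
  principal <- unname(principal_map[cohort$gene])
  keep <- !is.na(principal) & cohort$transcript == principal
  out <- rebuild_cohort(cohort[keep, , drop = FALSE], cohort)
  attr(out, "n_unmapped") <- sum(is.na(principal))
  out
}

#' Collapse to per-gene per-subject carrier indicators
#'
#' At most one ultra-rare variant of a class is counted per gene per
#' subject, so the per-gene count equals the number of distinct carrier
#' subjects.
#'
#' @param cohort A filtered [cohort_table()].
#' @param class `"truncating"` or `"missense"`.
#' @return A `gene_subject_matrix`: list with `class`, `counts` (data
#'   frame `gene`, `subject_id`, `count` with `count = 1`), `subject_ids`
#'   and `n_subjects`.
#' @export
collapse_per_gene_per_subject <- function(cohort,
                                          class = c("truncating",
                                                    "missense")) {
  class <- match.arg(class)
  rows <- cohort[effect_class(cohort$effect) == class, , drop = FALSE]
  key <- unique(data.frame(gene = rows$gene,
                           subject_id = as.character(rows$subject_id),
                           stringsAsFactors = FALSE))
  key <- key[order(key$gene, key$subject_id), , drop = FALSE]
  rownames(key) <- NULL
  key$count <- if (nrow(key) > 0) 1L else integer(0)
  gene_subject_matrix(key, class = class,
                      subject_ids = subject_ids(cohort))
}

#' Construct a gene-by-subject carrier matrix
#'
#' Sparse representation of the 0/1 (or counted, for resampled data)
#' gene-by-subject variant matrix of one variant class.
#'
#' @param counts Data frame with columns `gene`, `subject_id`, `count`.
#' @param class Variant class label.
#' @param subject_ids Full subject roster.
#' @return A `gene_subject_matrix` object.
#' @export
gene_subject_matrix <- function(counts, class, subject_ids) {
  stopifnot(all(c("gene", "subject_id", "count") %in% names(counts)))
  if (any(counts$count < 1)) stop("counts must be >= 1")
  extra <- setdiff(unique(counts$subject_id), subject_ids)
  if (length(extra) > 0) stop("counts reference unknown subject(s)")
  structure(list(class = class,
                 counts = as.data.frame(counts, stringsAsFactors = FALSE),
                 subject_ids = as.character(subject_ids),
                 n_subjects = length(subject_ids)),
            class = "gene_subject_matrix")
}

#' @export
print.gene_subject_matrix <- function(x, ...) {
  cat(sprintf(
    "gene_subject_matrix (%s): %d gene(s), %d subject(s), total %d\n",
    x$class, length(unique(x$counts$gene)), x$n_subjects, matrix_total(x)))
  invisible(x)
}

#' Per-gene carrier counts
#'
#' Number of distinct carrier subjects per gene (indicator capping: a
#' subject counts at most once per gene).
#'
#' @param matrix A `gene_subject_matrix`.
#' @return Named integer vector gene -> carrier count.
#' @export
gene_counts <- function(matrix) {
  cc <- matrix$counts
  if (nrow(cc) == 0) return(stats::setNames(integer(0), character(0)))
  key <- unique(paste(cc$gene, cc$subject_id, sep = "\r"))
  genes <- sub("\r.*$", "", key)
  tab <- table(genes)
  stats::setNames(as.integer(tab), names(tab))
}

#' Total observed ultra-rare variants in a matrix
#'
#' Sum of per-gene carrier counts (the `N_Obs` anchoring the scaling
#' factor).
#'
#' @param matrix A `gene_subject_matrix`.
#' @return Integer total.
#' @export
matrix_total <- function(matrix) sum(gene_counts(matrix))

#' Run the full ultra-rare variant filter cascade
#'
#' Fixed stage order: ultra-rare selection, low-quality filter,
#' frameshift-indel collapse (truncating only), principal-transcript
#' filter, splice-insertion rescue (truncating only), per-gene
#' per-subject collapse. Per-stage surviving record counts (restricted to
#' the requested class, tracking reclassification) are attached as
#' attribute `stage_counts`.
#'
#' @param cohort A raw [cohort_table()].
#' @param class `"truncating"` or `"missense"`.
#' @param principal_map Named vector gene -> principal transcript.
#' @param splice_annotation Optional splice-site annotation (see
#'   [filter_splice_insertions()]); ignored for the missense class.
#' @param ... Passed to [filter_low_quality()] /
#'   [collapse_frameshift_indels()].
#' @return A `gene_subject_matrix` with attribute `stage_counts`.
#' @export
run_filter_cascade <- function(cohort, class = c("truncating", "missense"),
                               principal_map, splice_annotation = NULL,
                               ...) {
  class <- match.arg(class)
  dots <- list(...)
  lq_args <- dots[names(dots) %in% names(formals(filter_low_quality))]
  fs_args <- dots[names(dots) %in%
                    names(formals(collapse_frameshift_indels))]
  n_class <- function(x) sum(effect_class(x$effect) == class)
  stage <- c(initial = n_class(cohort))
  cur <- select_ultra_rare(cohort)
  stage["ultra_rare"] <- n_class(cur)
  cur <- do.call(filter_low_quality, c(list(cur), lq_args))
  stage["low_quality"] <- n_class(cur)
  if (class == "truncating") {
    cur <- do.call(collapse_frameshift_indels, c(list(cur), fs_args))
    stage["frameshift_indel"] <- n_class(cur)
  }
  cur <- filter_principal_transcript(cur, principal_map)
  stage["principal_transcript"] <- n_class(cur)
  if (class == "truncating" && !is.null(splice_annotation)) {
    cur <- filter_splice_insertions(cur, splice_annotation)
    stage["splice_rescue"] <- n_class(cur)
  }
  out <- collapse_per_gene_per_subject(cur, class)
  stage["collapsed"] <- matrix_total(out)
  attr(out, "stage_counts") <- stage
  out
}
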