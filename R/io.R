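# Tabular IO: everything downstream consumes only the in-memory types
# built here. All files are UTF-8, tab-separated, '#'-comment lines
# ignored, 1-based VCF-style coordinates.

.variant_columns <- c(
  "subject_id", "chrom", "pos", "ref", "alt", "gene", "transcript",
  "effect", "zygosity", "DP", "GQ", "alt_fraction",
  "af_1000g", "af_exac", "af_gnomad", "cohort_allele_count"
)

#' Controlled effect vocabulary
#'
#' The canonical effect labels used by the filter cascade. The mapping from
#' annotation-tool labels to this vocabulary is shipped as a data file
#' (`extdata/effect_map.tsv`) so that new dialects can be added without
#' code changes.
#'
#' @return Character vector of canonical effect labels.
#' @export
effect_vocabulary <- function() {
  c("stopgain", "frameshift_insertion", "frameshift_deletion",
    "nonframeshift_insertion", "nonframeshift_deletion",
    "splice_donor", "splice_acceptor", "missense", "synonymous", "other")
}

.effect_map_cache <- new.env(parent = emptyenv())

effect_map <- function() {
  if (is.null(.effect_map_cache$map)) {
    path <- system.file("extdata", "effect_map.tsv", package = "uraburden")
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    .effect_map_cache$map <- stats::setNames(tab$effect, tab$source_label)
  }
  .effect_map_cache$map
}

map_effect <- function(x) {
  vocab <- effect_vocabulary()
  out <- ifelse(x %in% vocab, x, unname(effect_map()[x]))
  out[is.na(out)] <- "other"
  out
}

#' Construct a cohort variant table
#'
#' A `cohort_table` is a data frame of one annotated variant call per
#' subject per row, with the subject roster carried as an attribute so
#' that subjects without any (remaining) variant still count as trials.
#'
#' @param records Data frame with the standard variant columns (see
#'   [read_variant_table()]).
#' @param subject_ids Ordered unique subject identifiers; defaults to the
#'   subjects present in `records`. Must cover every record's subject.
#' @return A `cohort_table` object (data frame subclass) with attributes
#'   `subject_ids` and `n_subjects`.
#' @export
cohort_table <- function(records, subject_ids = NULL) {
  missing_cols <- setdiff(.variant_columns, names(records))
  if (length(missing_cols) > 0) {
    stop("missing variant column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(subject_ids)) {
    subject_ids <- unique(as.character(records$subject_id))
  }
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("duplicated subject identifiers")
  if (length(subject_ids) == 0) stop("cohort must contain >= 1 subject")
  extra <- setdiff(unique(as.character(records$subject_id)), subject_ids)
  if (length(extra) > 0) {
    stop("record subject(s) not in subject roster: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  if (nrow(records) > 0) {
    if (any(records$pos < 1)) stop("variant pos must be >= 1")
    if (any(records$ref == records$alt)) stop("ref and alt must differ")
    af <- records$alt_fraction
    if (any(!is.na(af) & (af < 0 | af > 1))) {
      stop("alt_fraction must lie in [0, 1]")
    }
    if (any(records$DP < 0, na.rm = TRUE)) stop("DP must be >= 0")
    if (any(records$cohort_allele_count < 1, na.rm = TRUE)) {
      stop("cohort_allele_count must be >= 1")
    }
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  structure(records,
            subject_ids = subject_ids,
            n_subjects = length(subject_ids),
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d variant record(s), %d subject(s)\n",
              nrow(x), attr(x, "n_subjects")))
  NextMethod()
}

#' Subject roster of a cohort table
#' @param cohort A `cohort_table`.
#' @return Character vector of subject identifiers.
#' @export
subject_ids <- function(cohort) attr(cohort, "subject_ids")

#' Number of subjects in a cohort table
#' @param cohort A `cohort_table`.
#' @return Integer subject count (the binomial trial count `N_S`).
#' @export
n_subjects <- function(cohort) attr(cohort, "n_subjects")

# Rebuild a cohort_table after row filtering, preserving the roster.
rebuild_cohort <- function(records, cohort) {
  cohort_table(records, subject_ids = subject_ids(cohort))
}

#' Read an annotated per-subject variant table
#'
#' Reads the tab-separated variant contract used across the package:
#' columns `subject_id, chrom, pos, ref, alt, gene, transcript, effect,
#' zygosity, DP, GQ, alt_fraction, af_1000g, af_exac, af_gnomad,
#' cohort_allele_count`. Effect labels are mapped onto the controlled
#' vocabulary ([effect_vocabulary()]); empty allele-frequency fields are
#' read as `NA`, meaning "absent from that reference".
#'
#' @param path Path to a UTF-8 TSV file; `#`-prefixed lines are ignored.
#' @param subject_ids Optional full subject roster (subjects with no
#'   variants are otherwise invisible in the file).
#' @return A [cohort_table()].
#' @export
read_variant_table <- function(path, subject_ids = NULL) {
  tab <- utils::read.delim(path, comment.char = "#", na.strings = c("NA", ""),
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.variant_columns, names(tab))
  if (length(missing_cols) > 0) {
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(tab), .variant_columns)
  if (length(unknown) > 0) {
    stop("variant table has unknown column(s): ",
         paste(unknown, collapse = ", "))
  }
  tab <- tab[, .variant_columns]
  numify <- function(col, integer = FALSE) {
    raw <- tab[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value in column '%s' at data line %d: '%s'",
                   col, bad[1], raw[bad[1]]))
    }
    if (integer) as.integer(val) else val
  }
  tab$pos <- numify("pos", integer = TRUE)
  tab$DP <- numify("DP", integer = TRUE)
  tab$GQ <- numify("GQ", integer = TRUE)
  tab$alt_fraction <- numify("alt_fraction")
  tab$af_1000g <- numify("af_1000g")
  tab$af_exac <- numify("af_exac")
  tab$af_gnomad <- numify("af_gnomad")
  tab$cohort_allele_count <- numify("cohort_allele_count", integer = TRUE)
  bad_zyg <- !tab$zygosity %in% c("het", "hom")
  if (any(bad_zyg)) {
    stop(sprintf("unknown zygosity '%s' at data line %d",
                 tab$zygosity[which(bad_zyg)[1]], which(bad_zyg)[1]))
  }
  tab$effect <- map_effect(tab$effect)
  cohort_table(tab, subject_ids = subject_ids)
}

#' Write an annotated variant table
#'
#' Inverse of [read_variant_table()]; canonical files round-trip
#' byte-identically.
#'
#' @param cohort A [cohort_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(cohort, path) {
  out <- as.data.frame(cohort)[, .variant_columns]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read gene-sets in GMT format
#'
#' Standard GMT dialect: one tab-separated line per set with fields
#' name, description, then one or more gene symbols. Duplicate genes
#' within a line are stored once; empty lines are skipped.
#'
#' @param path Path to a GMT file.
#' @param source Free-text tag for the resource (e.g. "GO/pathways",
#'   "MPO").
#' @return A `gene_set_collection`: list with elements `sets` (named list
#'   of unique gene symbol vectors), `descriptions` (named character) and
#'   `source`.
#' @export
read_gmt <- function(path, source = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short) > 0) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  descriptions <- stats::setNames(vapply(fields, `[[`, character(1), 2),
                                  names_)
  sets <- stats::setNames(
    lapply(fields, function(f) unique(f[-(1:2)])), names_)
  gene_set_collection(sets, descriptions, source)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param descriptions Optional named character vector of descriptions.
#' @param source Free-text resource tag.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL,
                                source = NA_character_) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene-set names must be present and unique")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep(NA_character_, length(sets)),
                                    names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions, source = source),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d set(s)%s\n", length(x$sets),
              if (is.na(x$source)) "" else paste0(" [", x$source, "]")))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

read_gene_keyed <- function(path, value_cols) {
  tab <- utils::read.delim(path, comment.char = "#", na.strings = c("NA", ""),
                           stringsAsFactors = FALSE)
  need <- c("gene", value_cols)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$gene)) {
    stop("duplicate gene row(s): ",
         paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
  }
  tab[, need]
}

#' Read a per-gene de novo mutation probability table
#'
#' TSV with columns `gene`, `p_lof`, `p_mis`: per-gene, per-generation
#' de novo mutation probabilities for truncating (loss-of-function) and
#' missense variants, as distributed with sequence-context mutation
#' models. The genes present define the gene universe `G` of the burden
#' test.
#'
#' @param path Path to TSV.
#' @return A `probability_table` data frame.
#' @export
read_probability_table <- function(path) {
  tab <- read_gene_keyed(path, c("p_lof", "p_mis"))
  probability_table(tab)
}

#' Construct/validate a probability table
#' @param tab Data frame with columns `gene`, `p_lof`, `p_mis`.
#' @return A validated `probability_table`.
#' @export
probability_table <- function(tab) {
  for (col in c("p_lof", "p_mis")) {
    p <- tab[[col]]
    bad <- which(!is.na(p) & (p <= 0 | p >= 1))
    if (length(bad) > 0) {
      stop(sprintf("probability %s=%g for gene %s outside (0,1)",
                   col, p[bad[1]], tab$gene[bad[1]]))
    }
  }
  if (nrow(tab) < 1) stop("probability table must define >= 1 gene")
  structure(as.data.frame(tab, stringsAsFactors = FALSE),
            class = c("probability_table", "data.frame"))
}

#' Read a per-gene constraint table
#'
#' TSV with columns `gene`, `oe_lof`, `oe_mis`: observed/expected variant
#' ratios from a large reference population (low values indicate negative
#' selection). `NA` means no defined constraint for that gene/class.
#'
#' @param path Path to TSV.
#' @return A `constraint_table` data frame.
#' @export
read_constraint_table <- function(path) {
  tab <- read_gene_keyed(path, c("oe_lof", "oe_mis"))
  for (col in c("oe_lof", "oe_mis")) {
    oe <- tab[[col]]
    bad <- which(!is.na(oe) & oe < 0)
    if (length(bad) > 0) {
      stop(sprintf("constraint %s=%g for gene %s is negative",
                   col, oe[bad[1]], tab$gene[bad[1]]))
    }
  }
  structure(tab, class = c("constraint_table", "data.frame"))
}

#' Read a per-gene reference singleton count table
#'
#' TSV with columns `gene`, `n_singleton_lof`, `n_singleton_mis`: counts
#' of reference-database singleton variants (allele count 1) per gene and
#' variant class, used as the comparison class for cohort ultra-rare
#' variants.
#'
#' @param path Path to TSV.
#' @return A `singleton_table` data frame.
#' @export
read_singleton_table <- function(path) {
  tab <- read_gene_keyed(path, c("n_singleton_lof", "n_singleton_mis"))
  for (col in c("n_singleton_lof", "n_singleton_mis")) {
    n <- tab[[col]]
    bad <- which(!is.na(n) & n < 0)
    if (length(bad) > 0) {
      stop(sprintf("singleton count %s for gene %s is negative",
                   col, tab$gene[bad[1]]))
    }
  }
  structure(tab, class = c("singleton_table", "data.frame"))
}

#' Read a principal-transcript map
#'
#' TSV with columns `gene`, `principal_transcript`: the principal isoform
#' per gene (APPRIS-style); the cascade keeps only variants affecting it.
#'
#' @param path Path to TSV.
#' @return Named character vector gene -> principal transcript.
#' @export
read_principal_map <- function(path) {
  tab <- read_gene_keyed(path, "principal_transcript")
  stats::setNames(as.character(tab$principal_transcript), tab$gene)
}

#' Ingest a multi-sample VCF into a cohort table
#'
#' Builds one variant record per called non-reference genotype per sample
#' from a VCFv4.2 file with `GT`, `DP`, `GQ` and `AD` FORMAT fields, then
#' attaches gene/transcript/effect annotation from a per-variant map.
#' `alt_fraction` is the alternate AD over total AD; zygosity comes from
#' the genotype; the in-cohort allele count is recomputed across samples.
#' Sites lacking a required FORMAT value yield a warning and are dropped
#' (count reported via attribute `n_dropped`).
#'
#' @param path Path to a VCF file (plain or bgzip).
#' @param annotation Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `transcript`, `effect` keyed on the variant allele.
#' @return A [cohort_table()].
#' @export
ingest_vcf <- function(path, annotation) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF ingestion requires the 'vcfR' package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  samples <- colnames(gt)
  key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")
  ann_key <- key(annotation$chrom, annotation$pos, annotation$ref,
                 annotation$alt)
  rows <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(gt))) {
    for (s in samples) {
      g <- gt[i, s]
      if (is.na(g)) next
      alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)[[1]]
      if (!any(alleles == "1")) next
      adi <- ad[i, s]
      if (is.na(adi) || is.na(dp[i, s]) || is.na(gq[i, s])) {
        warning(sprintf("missing FORMAT value at %s:%s sample %s; dropped",
                        fix[i, "CHROM"], fix[i, "POS"], s))
        n_dropped <- n_dropped + 1L
        next
      }
      adv <- as.numeric(strsplit(adi, ",", fixed = TRUE)[[1]])
      alt_fraction <- if (sum(adv) > 0) adv[2] / sum(adv) else NA_real_
      zyg <- if (all(alleles == "1")) "hom" else "het"
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = fix[i, "ALT"],
        zygosity = zyg, DP = as.integer(dp[i, s]), GQ = as.integer(gq[i, s]),
        alt_fraction = alt_fraction, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    rec <- data.frame(subject_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), zygosity = character(0),
                      DP = integer(0), GQ = integer(0),
                      alt_fraction = numeric(0), stringsAsFactors = FALSE)
  } else {
    rec <- do.call(rbind, rows)
  }
  k <- key(rec$chrom, rec$pos, rec$ref, rec$alt)
  idx <- match(k, ann_key)
  rec$gene <- annotation$gene[idx]
  rec$transcript <- annotation$transcript[idx]
  rec$effect <- map_effect(annotation$effect[idx])
  rec$af_1000g <- NA_real_
  rec$af_exac <- NA_real_
  rec$af_gnomad <- NA_real_
  counts <- table(k)
  rec$cohort_allele_count <- as.integer(counts[k])
  out <- cohort_table(rec[, .variant_columns], subject_ids = samples)
  attr(out, "n_dropped") <- n_dropped
  out
}
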