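test_that("ultra-rare selection keeps cohort singletons absent from references", {
  co <- make_cohort(
    make_record(pos = 1L),                                  # clean singleton
    make_record(pos = 2L, cohort_allele_count = 2L),        # cohort-recurrent
    make_record(pos = 3L, af_gnomad = 1e-6),                # in reference
    make_record(pos = 4L, af_exac = 0))                     # zero counts as absent
  out <- select_ultra_rare(co)
  expect_equal(sort(out$pos), c(1L, 4L))
  expect_equal(n_subjects(out), n_subjects(co))
})

test_that("low-quality filter applies depth, fraction and GQ rules", {
  co <- make_cohort(
    make_record(pos = 1L, DP = 10L),                              # DP <= 10
    make_record(pos = 2L, DP = 11L),                              # kept
    make_record(pos = 3L, zygosity = "het", alt_fraction = 0.29), # low frac
    make_record(pos = 4L, zygosity = "het", GQ = 98L),            # het GQ < 99
    make_record(pos = 5L, zygosity = "hom", alt_fraction = 0.7,
                DP = 30L, GQ = 60L),                              # hom frac < .8
    make_record(pos = 6L, zygosity = "hom", alt_fraction = 0.85,
                GQ = 25L),                                        # hom GQ <= 25
    make_record(pos = 7L, zygosity = "hom", alt_fraction = 0.85,
                GQ = 26L),                                        # kept
    make_record(pos = 8L, zygosity = "het", alt_fraction = 0.5,
                DP = 30L, GQ = 99L))                              # kept
  out <- filter_low_quality(co)
  expect_equal(sort(out$pos), c(2L, 7L, 8L))
  bad <- make_record(zygosity = "unknown")
  co2 <- cohort_table(bad)
  expect_error(filter_low_quality(co2), "zygosity")
})

test_that("frameshift indel collapse removes in-frame combinations", {
  fs <- function(pos, ref, alt, effect, subject = "S1", gene = "GENE1") {
    make_record(pos = pos, ref = ref, alt = alt, effect = effect,
                subject_id = subject, gene = gene)
  }
  # +1 and +2 in one gene/subject: cumulative 3 -> both removed
  co <- make_cohort(fs(1L, "A", "AT", "frameshift_insertion"),
                    fs(2L, "A", "ATT", "frameshift_insertion"))
  expect_equal(nrow(collapse_frameshift_indels(co)), 0)
  # +1 and +1: representative with smallest position kept
  co <- make_cohort(fs(5L, "A", "AT", "frameshift_insertion"),
                    fs(2L, "A", "AG", "frameshift_insertion"))
  out <- collapse_frameshift_indels(co)
  expect_equal(out$pos, 2L)
  # single indel untouched
  co <- make_cohort(fs(1L, "A", "AT", "frameshift_insertion"))
  expect_equal(nrow(collapse_frameshift_indels(co)), 1)
  # signed sizes: +4 and -1 net +3 -> removed; absolute mode keeps one
  co <- make_cohort(fs(1L, "A", "ATTTT", "frameshift_insertion"),
                    fs(9L, "AT", "A", "frameshift_deletion"))
  expect_equal(nrow(collapse_frameshift_indels(co)), 0)
  expect_equal(nrow(collapse_frameshift_indels(co, size_mode = "absolute")), 1)
  # different subjects are independent
  co <- make_cohort(fs(1L, "A", "AT", "frameshift_insertion"),
                    fs(2L, "A", "ATT", "frameshift_insertion", subject = "S2"))
  expect_equal(nrow(collapse_frameshift_indels(co)), 2)
})

test_that("splice insertions restoring a canonical dinucleotide are rescued", {
  # donor GT at genomic positions 111-112 on +, context covers 101-122
  ann <- data.frame(transcript = "TX_GENE1.1", chrom = "chr1",
                    role = "donor", strand = "+", dinuc_pos = 111L,
                    context_start = 101L,
                    context = "AAAAAAAAAAGTAAAAAAAAAA",
                    stringsAsFactors = FALSE)
  # insertion of GT immediately 5' of the donor: canonical restored
  co <- make_cohort(make_record(pos = 110L, ref = "A", alt = "AGT",
                                effect = "splice_donor"))
  out <- filter_splice_insertions(co, ann)
  expect_equal(out$effect, "other")
  # insertion of AA inside the donor dinucleotide: stays truncating
  co <- make_cohort(make_record(pos = 111L, ref = "G", alt = "GAA",
                                effect = "splice_donor"))
  out <- filter_splice_insertions(co, ann)
  expect_equal(out$effect, "splice_donor")
  # SNVs at splice sites are out of scope for this filter
  co <- make_cohort(make_record(pos = 111L, ref = "G", alt = "A",
                                effect = "splice_donor"))
  out <- filter_splice_insertions(co, ann)
  expect_equal(out$effect, "splice_donor")
  # missing annotation: conservative, retained with a warning
  co <- make_cohort(make_record(pos = 110L, ref = "A", alt = "AGT",
                                effect = "splice_donor",
                                transcript = "TX_OTHER.1"))
  expect_warning(out <- filter_splice_insertions(co, ann), "no splice")
  expect_equal(out$effect, "splice_donor")
})

test_that("principal transcript filter keeps principal-isoform effects only", {
  pm <- c(GENE1 = "TX_GENE1.1")
  co <- make_cohort(
    make_record(pos = 1L),
    make_record(pos = 2L, transcript = "TX_GENE1.2"),
    make_record(pos = 3L, gene = "GENE9", transcript = "TX_GENE9.1"))
  out <- filter_principal_transcript(co, pm)
  expect_equal(out$pos, 1L)
  expect_equal(attr(out, "n_unmapped"), 1)
})

test_that("per-gene per-subject collapse counts distinct carriers", {
  co <- make_cohort(
    make_record(pos = 1L, effect = "missense"),
    make_record(pos = 2L, effect = "missense"),          # same gene+subject
    make_record(pos = 3L, effect = "missense", subject_id = "S2"),
    make_record(pos = 4L, effect = "stopgain", subject_id = "S2"))
  mm <- collapse_per_gene_per_subject(co, "missense")
  expect_equal(unname(gene_counts(mm)["GENE1"]), 2L)
  expect_equal(matrix_total(mm), 2L)
  mt <- collapse_per_gene_per_subject(co, "truncating")
  expect_equal(matrix_total(mt), 1L)
  # seven distinct carriers yield a count of seven
  co7 <- make_cohort(do.call(rbind, lapply(1:7, function(i) {
    make_record(subject_id = paste0("S", i), pos = i * 10L, gene = "FLT4")
  })))
  expect_equal(unname(gene_counts(
    collapse_per_gene_per_subject(co7, "truncating"))["FLT4"]), 7L)
  # empty cohort
  co0 <- cohort_table(make_record()[0, ], subject_ids = "S1")
  expect_equal(matrix_total(collapse_per_gene_per_subject(co0, "missense")), 0L)
})

test_that("cascade applies stages in order with non-increasing counts", {
  pm <- c(GENE1 = "TX_GENE1.1", GENE2 = "TX_GENE2.1")
  co <- make_cohort(
    make_record(pos = 1L),                                         # clean
    make_record(pos = 2L, gene = "GENE2", transcript = "TX_GENE2.1",
                subject_id = "S2"),                                # clean
    make_record(pos = 3L, cohort_allele_count = 2L),               # freq
    make_record(pos = 4L, DP = 5L),                                # low qual
    make_record(pos = 5L, ref = "A", alt = "AT",
                effect = "frameshift_insertion"),
    make_record(pos = 6L, ref = "A", alt = "ATT",
                effect = "frameshift_insertion"),                  # pair: removed
    make_record(pos = 7L, transcript = "TX_GENE1.9"))              # non-principal
  mat <- run_filter_cascade(co, "truncating", pm)
  stage <- attr(mat, "stage_counts")
  expect_true(all(diff(stage) <= 0))
  expect_equal(unname(stage["collapsed"]), 2)
  expect_equal(matrix_total(mat), 2L)
  # missense path has no indel or splice stages
  mat_m <- run_filter_cascade(co, "missense", pm)
  expect_false("frameshift_indel" %in% names(attr(mat_m, "stage_counts")))
  expect_false("splice_rescue" %in% names(attr(mat_m, "stage_counts")))
  # all-passing fixture: output total equals input record count
  co_clean <- make_cohort(make_record(pos = 1L),
                          make_record(pos = 2L, subject_id = "S2"))
  expect_equal(matrix_total(run_filter_cascade(co_clean, "truncating", pm)),
               2L)
})

test_that("filters are idempotent and only remove records", {
  spec <- synthetic_cohort_spec(
    n_subjects = 40, n_genes = 300, n_truncating = 60, n_missense = 120,
    qc_rates = list(low_dp = 0.05, low_af = 0.05, ref_freq = 0.05,
                    non_principal = 0.05, cohort_dup = 0.05,
                    multi_indel = 0.03),
    seed = 11)
  sim <- simulate_cohort(spec)
  co <- sim$cohort
  for (f in list(select_ultra_rare, filter_low_quality,
                 collapse_frameshift_indels)) {
    once <- f(co)
    expect_lte(nrow(once), nrow(co))
    expect_identical(as.data.frame(f(once)), as.data.frame(once))
  }
  once <- filter_principal_transcript(co, sim$principal_map)
  twice <- filter_principal_transcript(once, sim$principal_map)
  expect_identical(as.data.frame(twice), as.data.frame(once))
})

test_that("collapse matches a brute-force distinct-carrier count", {
  spec <- synthetic_cohort_spec(n_subjects = 50, n_genes = 200,
                                n_truncating = 150, n_missense = 0,
                                seed = 23)
  sim <- simulate_cohort(spec)
  mat <- collapse_per_gene_per_subject(sim$cohort, "truncating")
  counts <- gene_counts(mat)
  rows <- sim$cohort[effect_class(sim$cohort$effect) == "truncating", ]
  for (g in names(counts)) {
    expect_equal(unname(counts[g]),
                 length(unique(rows$subject_id[rows$gene == g])))
  }
})
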