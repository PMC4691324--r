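test_that("pipeline configuration validates and round-trips through YAML", {
  cfg <- mfhet_config()
  expect_equal(cfg$af_confirm_min, 0.05)
  expect_equal(cfg$af_rescue_min, 0.01)
  expect_equal(cfg$hotspot_window_aa, 3L)
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  expect_identical(read_config(f), cfg)
  expect_error(mfhet_config(af_rescue_min = 0.2, af_confirm_min = 0.05))
  expect_error(mfhet_config(scna_reciprocal_overlap_min = 0))
})

test_that("hierarchy invariants are enforced", {
  h <- make_hierarchy(lesions = 2L, samples = c(1L))
  expect_s3_class(h, "cohort_hierarchy")
  expect_equal(nrow(hierarchy_samples(h)), 2L)
  # multifocality requires >= 2 lesions
  expect_error(cohort_hierarchy(list(list(patient_id = "P1", covariates = list(),
    lesions = list(list(lesion_id = "L1", samples = "S1"))))),
    "fewer than 2 lesions")
  # duplicate sample ids
  expect_error(cohort_hierarchy(list(list(patient_id = "P1", covariates = list(),
    lesions = list(list(lesion_id = "L1", samples = "S1"),
                   list(lesion_id = "L2", samples = "S1"))))),
    "duplicate sample_id")
})

test_that("hierarchy YAML round-trips and validation is order-independent", {
  h <- make_hierarchy(n_patients = 3L, lesions = 2L, samples = 2L,
                      covariates = list(grade = "G3", subtype = "ER+/HER2-",
                                        max_inter_lesion_distance_cm = 2.5))
  f <- tempfile(fileext = ".yaml")
  write_hierarchy(h, f)
  h2 <- read_hierarchy(f)
  expect_identical(hierarchy_samples(h2), hierarchy_samples(h))
  # permuting patients yields the same model up to order
  h_rev <- cohort_hierarchy(rev(h$patients))
  ct <- covariate_table(h)
  ct_rev <- covariate_table(h_rev)
  ct_rev <- ct_rev[order(ct_rev$patient_id), ]
  rownames(ct_rev) <- NULL
  expect_identical(ct[order(ct$patient_id), ], ct_rev)
})

test_that("samples absent from variant tables warn but resolve", {
  h <- make_hierarchy(lesions = 2L, samples = 2L)
  calls <- make_call(sample = "P1_L1_S1")
  expect_warning(check_sample_resolution(calls, h), "no calls")
  expect_error(check_sample_resolution(make_call(sample = "NOPE"), h),
               "not in hierarchy")
})

test_that("variant TSV reading maps fields, flags bad rows, and round-trips", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("patient\tsample\tgene\tchrom\tpos\tref\talt\tvariant_class\tprotein_change\taf\tdepth",
               "P1\tS1\tTP53\t17\t7578265\tC\tT\tmissense\tR196*\t0.42\t180"), f)
  calls <- read_variant_table(f, "discovery")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$af_discovery, 0.42)
  expect_equal(calls$depth_discovery, 180L)
  expect_equal(calls$gene_symbol, "TP53")
  expect_equal(calls$pos, 7578265L)
  # empty file with a valid header
  writeLines("patient\tsample\tgene\tchrom\tpos\tref\talt\taf\tdepth", f)
  expect_equal(nrow(read_variant_table(f, "discovery")), 0L)
  # AF out of range names the row
  writeLines(c("patient\tsample\tgene\tchrom\tpos\tref\talt\taf\tdepth",
               "P1\tS1\tTP53\t17\t100\tC\tT\t1.2\t80"), f)
  expect_error(read_variant_table(f, "discovery"), "af_discovery outside")
  # missing mandatory column is named
  writeLines(c("patient\tsample\tgene\tchrom\tpos\tref\taf\tdepth",
               "P1\tS1\tTP53\t17\t100\tC\t0.2\t80"), f)
  expect_error(read_variant_table(f, "discovery"), "alt")
  # write -> read reproduces every field
  calls <- rbind(
    make_call(af_validation = 0.21, depth_validation = 1500L),
    make_call(sample = "P1_L2_S1", pos = 999L, protein_change = NA,
              variant_class = "silent", af_validation = 0.07,
              depth_validation = 900L))
  write_variant_table(calls, f, "validation")
  back <- read_variant_table(f, "validation")
  expect_equal(back$af_validation, calls$af_validation)
  expect_equal(back$depth_validation, calls$depth_validation)
  expect_equal(back$protein_change, calls$protein_change)
  expect_equal(back$variant_class, calls$variant_class)
})

test_that("VCF input with per-sample AD/DP yields allele fractions", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "17\t7578265\t.\tC\tT\t.\tPASS\tGENE=TP53;CLASS=missense;PCHG=R196*\tGT:AD:DP\t0/1:58:42:100\t0/1:90:10:100"),
    f)
  # AD written as ref,alt — fix the line to proper comma form
  lines <- readLines(f)
  lines[6] <- "17\t7578265\t.\tC\tT\t.\tPASS\tGENE=TP53;CLASS=missense;PCHG=R196*\tGT:AD:DP\t0/1:58,42:100\t0/1:90,10:100"
  writeLines(lines, f)
  calls <- read_variant_table(f, "discovery",
                              patient_of_sample = c(S1 = "P1", S2 = "P1"))
  expect_equal(nrow(calls), 2L)
  expect_equal(sort(calls$af_discovery), c(0.10, 0.42))
  expect_equal(calls$gene_symbol, c("TP53", "TP53"))
})

test_that("allele normalisation gives platform-independent variant identity", {
  # the same deletion written with different padding
  a <- normalize_alleles(100L, "CTT", "CT")
  b <- normalize_alleles(99L, "ACTT", "ACT")
  expect_equal(a$pos, 100L)
  expect_equal(b$pos, 100L)
  expect_equal(a$ref, b$ref)
  expect_equal(a$alt, b$alt)
  # SNV untouched
  s <- normalize_alleles(50L, "G", "A")
  expect_equal(s, list(pos = 50L, ref = "G", alt = "A"))
})

test_that("unique variant grouping matches a brute-force oracle", {
  # two samples of one patient with the identical variant
  calls <- rbind(make_call(sample = "S1"), make_call(sample = "S2"))
  uv <- unique_variants(calls)
  expect_equal(nrow(uv), 1L)
  expect_equal(uv$n_observations, 2L)
  # same variant in two patients: two per-patient entries, recurrence 2
  calls <- rbind(make_call(patient = "P1", sample = "S1"),
                 make_call(patient = "P2", sample = "S2"))
  uv <- unique_variants(calls)
  expect_equal(nrow(uv), 2L)
  expect_equal(unname(attr(uv, "cohort_recurrence")[uv$key[1]]), 2L)
  # random calls: group sizes sum to the number of non-silent calls
  set.seed(7)
  keys <- data.frame(pos = c(100L, 200L, 300L, 400L),
                     gene = c("A", "B", "C", "D"))
  pick <- sample(4L, 10L, replace = TRUE)
  calls <- do.call(rbind, lapply(seq_len(10L), function(i)
    make_call(sample = sprintf("S%d", i), pos = keys$pos[pick[i]],
              gene = keys$gene[pick[i]])))
  uv <- unique_variants(calls)
  expect_equal(nrow(uv), length(unique(pick)))
  expect_equal(sum(uv$n_observations), 10L)
  expect_equal(attr(uv, "n_nonsilent_calls"), 10L)
  # silent variants are excluded
  calls$variant_class[1] <- "silent"
  expect_equal(attr(unique_variants(calls), "n_nonsilent_calls"), 9L)
  # conflicting gene annotation for one genomic key
  calls <- rbind(make_call(gene = "TP53"), make_call(sample = "S2", gene = "EGFR"))
  expect_error(unique_variants(calls), "conflicting gene_symbol")
})

test_that("substitutions and indels are counted separately", {
  calls <- rbind(make_call(variant_class = "missense"),
                 make_call(sample = "S2", pos = 5L, ref = "CT", alt = "C",
                           variant_class = "frameshift_del"),
                 make_call(sample = "S3", pos = 9L, variant_class = "nonsense"))
  uv <- unique_variants(calls)
  expect_equal(attr(uv, "n_substitutions"), 2L)
  expect_equal(attr(uv, "n_indels"), 1L)
})

test_that("resource tables validate their schemas", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tprotein_change\tcosmic_confirmed_samples",
               "TP53\tR273H\t44", "PIK3CA\tE545K\t52"), f)
  rec <- read_recurrence_table(f)
  expect_equal(nrow(rec), 2L)
  writeLines(c("gene\tprotein_change\tcosmic_confirmed_samples",
               "TP53\tR273H\t44", "TP53\tR273H\t10"), f)
  expect_error(read_recurrence_table(f), "duplicate")
  writeLines(c("gene\trole", "TP53\ttumour_suppressor", "KRAS\toncogene"), f)
  roles <- read_gene_role_table(f)
  expect_equal(roles$role[roles$gene == "KRAS"], "oncogene")
  writeLines(c("gene\trole", "TP53\tbad_role"), f)
  expect_error(read_gene_role_table(f), "unknown role")
})
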