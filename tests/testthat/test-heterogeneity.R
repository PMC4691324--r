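cfg <- mfhet_config()

pm_of <- function(m, lesion_of) as_presence_matrix(m, lesion_of)

test_that("the three groups follow their defining set structure", {
  # two lesions, one sample each, one shared variant: homogeneous
  m <- pm_of(matrix(1L, 1, 2), c(S1 = "L1", S2 = "L2"))
  expect_equal(classify_patient(m, config = cfg)$group, "HOMOGENEOUS")
  # shared variant A plus a variant B private to lesion 2: intermediate
  m <- pm_of(rbind(A = c(1L, 1L), B = c(0L, 1L)), c(S1 = "L1", S2 = "L2"))
  res <- classify_patient(m, config = cfg)
  expect_equal(res$group, "INTERMEDIATE")
  expect_equal(res$common_variants, "A")
  expect_equal(res$private_variants, "B")
  # disjoint mutations between lesions: heterogeneous
  m <- pm_of(rbind(A = c(1L, 0L), B = c(0L, 1L)), c(S1 = "L1", S2 = "L2"))
  expect_equal(classify_patient(m, config = cfg)$group, "HETEROGENEOUS")
})

test_that("convergent-evolution pattern: same gene, different mutations, heterogeneous", {
  # lesion 1 (3 samples) all carry one TP53 mutation; lesion 2 carries another
  m <- pm_of(rbind(`TP53a` = c(1L, 1L, 1L, 0L), `TP53b` = c(0L, 0L, 0L, 1L)),
             c(S1 = "L1", S2 = "L1", S3 = "L1", S4 = "L2"))
  res <- classify_patient(m, config = cfg)
  expect_equal(res$group, "HETEROGENEOUS")
  expect_equal(length(res$common_variants), 0L)
})

test_that("grouping agrees with brute-force set logic on all small matrices", {
  shapes <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  for (shape in shapes) {
    lesion_of <- rep(c("L1", "L2"), shape)
    names(lesion_of) <- sprintf("S%d", seq_along(lesion_of))
    nc <- length(lesion_of)
    cells <- 2^nc - 1L  # rows need >= 1 present cell
    for (nr in 1:3) {
      grid <- expand.grid(rep(list(1:cells), nr))
      for (g in seq_len(nrow(grid))) {
        m <- t(vapply(seq_len(nr), function(r)
          as.integer(bitwAnd(grid[g, r], 2^(seq_len(nc) - 1L)) > 0),
          integer(nc)))
        rownames(m) <- sprintf("v%d", seq_len(nr))
        got <- classify_patient(pm_of(m, lesion_of), config = cfg)$group
        expect_equal(got, oracle_group(m, lesion_of, strict = TRUE),
                     info = paste(shape, collapse = "x"))
      }
    }
  }
})

test_that("group labels are invariant under sample and lesion relabeling", {
  set.seed(13)
  for (i in 1:25) {
    nles <- sample(2:3, 1L)
    spl <- sample(1:2, nles, replace = TRUE)
    lesion_of <- rep(sprintf("L%d", seq_len(nles)), spl)
    names(lesion_of) <- sprintf("S%d", seq_along(lesion_of))
    nr <- sample(1:4, 1L)
    repeat {
      m <- matrix(rbinom(nr * length(lesion_of), 1L, 0.5), nr)
      if (all(rowSums(m) >= 1L)) break
    }
    rownames(m) <- sprintf("v%d", seq_len(nr))
    perm <- sample(ncol(m))
    g1 <- classify_patient(pm_of(m, lesion_of), config = cfg)$group
    g2 <- classify_patient(pm_of(m[, perm, drop = FALSE], lesion_of[perm]),
                           config = cfg)$group
    expect_equal(g1, g2)
  }
})

test_that("adding a lesion-common variant removes heterogeneity", {
  m <- rbind(A = c(1L, 0L), B = c(0L, 1L))
  lesion_of <- c(S1 = "L1", S2 = "L2")
  expect_equal(classify_patient(pm_of(m, lesion_of), config = cfg)$group,
               "HETEROGENEOUS")
  m2 <- rbind(m, C = c(1L, 1L))
  expect_false(classify_patient(pm_of(m2, lesion_of), config = cfg)$group ==
                 "HETEROGENEOUS")
})

test_that("removing private variants from an intermediate patient yields
           homogeneous exactly when the rest is sample-complete", {
  lesion_of <- c(S1 = "L1", S2 = "L1", S3 = "L2")
  m <- rbind(A = c(1L, 1L, 1L), B = c(0L, 0L, 1L))
  res <- classify_patient(pm_of(m, lesion_of), config = cfg)
  expect_equal(res$group, "INTERMEDIATE")
  m2 <- m[setdiff(rownames(m), res$private_variants), , drop = FALSE]
  expect_equal(classify_patient(pm_of(m2, lesion_of), config = cfg)$group,
               "HOMOGENEOUS")
  # a lesion-common but sample-incomplete variant stays intermediate (strict)
  m3 <- rbind(A = c(1L, 0L, 1L))
  expect_equal(classify_patient(pm_of(m3, lesion_of), config = cfg)$group,
               "INTERMEDIATE")
  # and homogeneous under the lesion-level reading
  loose <- mfhet_config(strict_homogeneous = FALSE)
  expect_equal(classify_patient(pm_of(m3, lesion_of), config = loose)$group,
               "HOMOGENEOUS")
})

test_that("zero-variant patients are excluded with a warning", {
  m <- pm_of(matrix(integer(0), 0, 2), c(S1 = "L1", S2 = "L2"))
  expect_error(classify_patient(m, config = cfg), "zero confirmed")
})

test_that("cohort grouping partitions patients and counts shared oncogenic", {
  co <- generate_cohort(generator_config(n_patients = 12L, seed = 31L))
  fit <- mfhet(co$discovery, co$validation, co$hierarchy, co$recurrence,
               co$roles)
  g <- fit$heterogeneity$group_summary
  expect_equal(g$n_homogeneous + g$n_intermediate + g$n_heterogeneous,
               g$n_patients)
  expect_equal(g$shared_fraction,
               (g$n_homogeneous + g$n_intermediate) / g$n_patients)
  pats <- fit$heterogeneity$patients
  expect_true(all(pats$shares_oncogenic[pats$group == "HETEROGENEOUS"] == FALSE))
})

test_that("private/common AF comparison: zero shift gives p = 1", {
  mk_patient <- function(pid, priv, comm) {
    list(patient_id = pid, group = "INTERMEDIATE",
         af_private = priv, af_common = comm,
         median_af_private = stats::median(priv),
         median_af_common = stats::median(comm))
  }
  het <- list(per_patient = list(
    P1 = mk_patient("P1", 0.2, 0.2), P2 = mk_patient("P2", 0.3, 0.3),
    P3 = mk_patient("P3", 0.25, 0.25)))
  res <- private_vs_common_af(het)
  expect_equal(res$test$p_value, 1)
  expect_equal(res$median_af_private, res$median_af_common)
})

test_that("paired signed-rank statistic matches exhaustive enumeration", {
  het <- list(per_patient = list(
    P1 = list(patient_id = "P1", group = "INTERMEDIATE", af_private = 0.1,
              af_common = 0.3, median_af_private = 0.1, median_af_common = 0.3),
    P2 = list(patient_id = "P2", group = "INTERMEDIATE", af_private = 0.2,
              af_common = 0.25, median_af_private = 0.2, median_af_common = 0.25),
    P3 = list(patient_id = "P3", group = "INTERMEDIATE", af_private = 0.15,
              af_common = 0.3, median_af_private = 0.15, median_af_common = 0.3)))
  res <- private_vs_common_af(het)
  d <- c(0.1 - 0.3, 0.2 - 0.25, 0.15 - 0.3)
  expect_equal(res$test$p_value, oracle_signed_rank_p(d))
  expect_error(private_vs_common_af(list(per_patient = het$per_patient[1])),
               "insufficient")
})

test_that("planted subclonal private mutations have lower AF, detectably", {
  co <- generate_cohort(generator_config(
    n_patients = 60L, group_proportions = c(HOMOGENEOUS = 0, INTERMEDIATE = 1,
                                            HETEROGENEOUS = 0),
    seed = 17L))
  fit <- mfhet(co$discovery, co$validation, co$hierarchy, co$recurrence,
               co$roles)
  res <- fit$af_comparison
  expect_lt(res$median_af_private, res$median_af_common)
  expect_lt(res$test$p_value, 0.05)
})

test_that("covariate association chooses the documented test per covariate", {
  set.seed(41)
  groups <- rep(c("HOMOGENEOUS", "INTERMEDIATE", "HETEROGENEOUS"), each = 10L)
  pts <- lapply(seq_along(groups), function(i) {
    pid <- sprintf("P%02d", i)
    dist <- if (groups[i] == "HETEROGENEOUS") rnorm(1, 4, 1)
            else if (groups[i] == "HOMOGENEOUS") rnorm(1, 1.5, 1) else rnorm(1, 2.5, 1)
    list(patient_id = pid,
         covariates = list(grade = sample(c("G2", "G3"), 1L),
                           max_inter_lesion_distance_cm = max(0.1, dist)),
         lesions = list(list(lesion_id = paste0(pid, "_L1"),
                             samples = paste0(pid, "_L1_S1")),
                        list(lesion_id = paste0(pid, "_L2"),
                             samples = paste0(pid, "_L2_S1"))))
  })
  h <- cohort_hierarchy(pts)
  het <- list(patients = data.frame(
    patient_id = sprintf("P%02d", seq_along(groups)), group = groups,
    n_mutations_total = 3L, n_common = 1L, n_private = 1L,
    shares_oncogenic = groups != "HETEROGENEOUS",
    has_oncogenic = TRUE, median_af_common = 0.3, median_af_private = 0.15,
    stringsAsFactors = FALSE))
  tab <- covariate_association(het, h, cfg)
  dist3 <- tab[tab$covariate == "max_inter_lesion_distance_cm" &
                 tab$comparison == "3-group", ]
  expect_equal(dist3$test_used, "kruskal_wallis")
  hh <- tab[tab$covariate == "max_inter_lesion_distance_cm" &
              tab$comparison == "homogeneous-vs-heterogeneous", ]
  expect_equal(hh$test_used, "rank_sum")
  expect_lt(hh$p, 0.05)  # planted separation ~2.5 cm at n=10+10
  expect_equal(tab$test_used[tab$covariate == "grade"][1], "fisher_exact")
  # identical distributions: p near 1 (statistic ~ 0)
  # each group receives the same multiset of distances
  pts2 <- pts
  for (i in seq_along(pts2))
    pts2[[i]]$covariates$max_inter_lesion_distance_cm <-
      rep(c(1, 2, 3), length.out = 10L)[(i - 1L) %% 10L + 1L]
  tab2 <- covariate_association(het, cohort_hierarchy(pts2), cfg)
  p2 <- tab2$p[tab2$covariate == "max_inter_lesion_distance_cm" &
                 tab2$comparison == "3-group"]
  expect_gt(p2, 0.99)
})

test_that("single-level covariates are skipped with a note", {
  pts <- lapply(1:6, function(i) {
    pid <- sprintf("P%d", i)
    list(patient_id = pid, covariates = list(grade = "G3"),
         lesions = list(list(lesion_id = paste0(pid, "_L1"),
                             samples = paste0(pid, "_L1_S1")),
                        list(lesion_id = paste0(pid, "_L2"),
                             samples = paste0(pid, "_L2_S1"))))
  })
  het <- list(patients = data.frame(
    patient_id = sprintf("P%d", 1:6),
    group = rep(c("HOMOGENEOUS", "INTERMEDIATE", "HETEROGENEOUS"), 2L),
    n_mutations_total = 2L, n_common = 1L, n_private = 1L,
    shares_oncogenic = FALSE, has_oncogenic = FALSE,
    median_af_common = NA_real_, median_af_private = NA_real_,
    stringsAsFactors = FALSE))
  tab <- covariate_association(het, cohort_hierarchy(pts), cfg)
  gr <- tab[tab$covariate == "grade", ]
  expect_match(gr$note, "skipped")
})

test_that("presence-matrix export re-parses to the identical matrix", {
  set.seed(19)
  lesion_of <- c(S1 = "L1", S2 = "L1", S3 = "L2")
  m <- matrix(c(1L, 1L, 1L, 0L, 1L, 1L, 1L, 0L, NA), 3, 3,
              dimnames = list(c("k1", "k2", "k3"), names(lesion_of)))
  pm <- as_presence_matrix(m, lesion_of, validation_only = c(FALSE, TRUE, FALSE))
  onco <- data.frame(key = c("k1", "k3"), oncogenic = c(TRUE, TRUE))
  f <- tempfile(fileext = ".tsv")
  write_presence_matrix(pm, onco, f)
  back <- read_presence_matrix(f)
  expect_equal(unname(back$lesion_of), unname(lesion_of))
  expect_equal(unname(back$validation_only), c(FALSE, TRUE, FALSE))
  expect_equal(back$cells["k1", "S1"], "oncogenic-present")
  expect_equal(back$cells["k2", "S1"], "unknown-present")
  expect_equal(back$cells["k1", "S2"], "absent")
  expect_equal(back$cells["k3", "S3"], "no-assay")
  # round trip: write the parsed matrix again and compare bytes
  f2 <- tempfile(fileext = ".tsv")
  write_presence_matrix(pm, onco, f2)
  expect_identical(readLines(f), readLines(f2))
})
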