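#' Synthetic multifocal cohort generator
#'
#' Generates cohorts with the statistical structure the analysis assumes: a
#' planted clonal phylogeny per patient (truncal mutations in every lesion,
#' lesion-private subclonal mutations), two-platform read sampling at the
#' study depths (discovery ~178x, deep validation ~1344x), tumour purity,
#' rule-annotated driver mutations drawn from a built-in catalogue, clinical
#' covariates matching the study's marginal distributions, and (for a subset
#' of patients) planted copy-number and rearrangement events with
#' common/private labels. Every planted quantity is recorded as ground truth
#' so each downstream stage can be scored.
#'
#' @name synthetic_cohort
NULL

#' Generator configuration
#'
#' Defaults reproduce the study conditions: 36 patients; 2 lesions with
#' probability 22/36, otherwise 3 (10/36) or 4 (4/36); 1-3 samples per
#' lesion; group proportions 11:13:12
#' (homogeneous:intermediate:heterogeneous), allocated by largest-remainder
#' rounding so the planted composition matches the configured proportions at
#' any cohort size; mutation counts 1 + Geometric(0.25) capped at 27 (cohort
#' median 3, range 1-27); private subclones at half the cancer-cell fraction;
#' purity 0.4-0.9 (the study required > 40% cellularity); platform depths
#' 178x and 1344x; beta-binomial read noise with overdispersion 0.01;
#' roughly 7% of validation assays failing (mirroring the 35 unconfirmable
#' mutations: variant-level design failures plus sample-level DNA
#' exhaustion); a discovery caller that misses calls below its detection
#' limit (>= 3 reads and >= 5% observed AF) plus 2% artifact dropout — the
#' sources of validation-only "present" calls; driver probability 0.44 per
#' mutation;
#' inter-lesion distances increasing from the homogeneous to the
#' heterogeneous group; genome-wide (copy-number + rearrangement) data for 8
#' patients.
#'
#' @param n_patients Cohort size.
#' @param lesion_count_probs Named probabilities for 2/3/4 lesions.
#' @param samples_per_lesion_range Integer range.
#' @param group_proportions Named proportions (must sum to 1).
#' @param mutation_geom_prob Geometric parameter of the mutation-count
#'   sampler.
#' @param mutation_count_max Cap on mutations per patient.
#' @param private_subclone_ccf Cancer-cell fraction of private subclones.
#' @param purity_range Per-sample tumour purity range.
#' @param depth_discovery,depth_validation Mean platform depths.
#' @param af_noise `"beta-binomial"`, `"binomial"` or `"none"`.
#' @param overdispersion Beta-binomial overdispersion rho.
#' @param assay_fail_variant_rate Probability a patient-variant's validation
#'   assay design fails (all samples affected; the study lost 19/474 calls
#'   this way).
#' @param assay_fail_sample_rate Probability a sample's DNA is exhausted
#'   before validation (all variants of that sample affected; 4/171 samples
#'   in the study).
#' @param discovery_dropout Per-(variant, sample) probability that the
#'   discovery platform reports no call despite presence (FFPE/library
#'   artifacts). Independent of this, the discovery caller only reports a
#'   variant when it sees at least 3 supporting reads and an observed AF of
#'   at least 5%, so subclonal variants are also missed at the detection
#'   limit — the main source of validation-only `PRESENT` calls.
#' @param oncogenic_fraction Probability a planted mutation is a catalogue
#'   driver.
#' @param distance_means,distance_sd Normal model (cm) of the largest
#'   inter-lesion distance per group (truncated at 0.2 cm).
#' @param distance_missing_rate Probability the distance is missing.
#' @param lvi_missing_rate Probability lymphovascular invasion is missing.
#' @param plant_dataset_recurrent Plant one substitution shared by two
#'   patients (dataset-recurrence rule).
#' @param plant_cluster Plant a three-substitution cohort cluster.
#' @param silent_fraction Fraction of passenger mutations that are silent.
#' @param n_wgs_patients Patients receiving genome-wide data.
#' @param seed RNG seed.
#' @return An object of class `mfhet_generator_config`.
#' @export
generator_config <- function(n_patients = 36L,
                             lesion_count_probs = c(`2` = 22/36, `3` = 10/36, `4` = 4/36),
                             samples_per_lesion_range = c(1L, 3L),
                             group_proportions = c(HOMOGENEOUS = 11/36,
                                                   INTERMEDIATE = 13/36,
                                                   HETEROGENEOUS = 12/36),
                             mutation_geom_prob = 0.25,
                             mutation_count_max = 27L,
                             private_subclone_ccf = 0.5,
                             purity_range = c(0.4, 0.9),
                             depth_discovery = 178,
                             depth_validation = 1344,
                             af_noise = c("beta-binomial", "binomial", "none"),
                             overdispersion = 0.01,
                             assay_fail_variant_rate = 19 / 474,
                             assay_fail_sample_rate = 4 / 171,
                             discovery_dropout = 0.02,
                             oncogenic_fraction = 0.44,
                             distance_means = c(HOMOGENEOUS = 1.5,
                                                INTERMEDIATE = 2.5,
                                                HETEROGENEOUS = 4),
                             distance_sd = 1,
                             distance_missing_rate = 10/36,
                             lvi_missing_rate = 1/36,
                             plant_dataset_recurrent = TRUE,
                             plant_cluster = TRUE,
                             silent_fraction = 0.1,
                             n_wgs_patients = 8L,
                             seed = 1L) {
  af_noise <- match.arg(af_noise)
  cfg <- as.list(environment())
  stopifnot(
    abs(sum(group_proportions) - 1) < 1e-9,
    abs(sum(lesion_count_probs) - 1) < 1e-9,
    private_subclone_ccf > 0, private_subclone_ccf <= 1,
    purity_range[1] > 0, purity_range[2] <= 1,
    assay_fail_variant_rate >= 0, assay_fail_variant_rate < 1,
    assay_fail_sample_rate >= 0, assay_fail_sample_rate < 1,
    discovery_dropout >= 0, discovery_dropout < 1,
    oncogenic_fraction >= 0, oncogenic_fraction <= 1,
    silent_fraction >= 0, silent_fraction < 1)
  if (n_patients < sum(group_proportions > 0))
    stop("config error: n_patients smaller than the number of non-empty groups")
  class(cfg) <- "mfhet_generator_config"
  cfg
}

# built-in driver catalogue: gene, protein change, class, planted rule.
# Genomic coordinates are assigned deterministically (unique position per
# entry); counts for the recurrence table live in catalogue_resources().
driver_catalogue <- function() {
  df <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene protein_change variant_class rule
PIK3CA E545K missense R1
PIK3CA H1047R missense R1
PIK3CA N345K missense R1
PIK3CA C420R missense R1
AKT1 E17K missense R1
ERBB2 L755S missense R1
ERBB2 V777L missense R1
KRAS G12D missense R1
KRAS G13D missense R1
KRAS Q61H missense R1
NRAS Q61K missense R1
NRAS G12C missense R1
ESR1 Y537S missense R1
ESR1 D538G missense R1
EGFR L858R missense R1
GNAS R201C missense R1
EGFR E746_A750del inframe_del R1
TP53 R273H missense R2
TP53 R175H missense R2
TP53 Y220C missense R2
TP53 R282W missense R2
TP53 G245S missense R2
PTEN R130G missense R2
PTEN R173H missense R2
MAP2K4 R134W missense R2
CDH1 D254Y missense R2
SF3B1 R625C missense R2
TP53 R196* nonsense R4
TP53 R342* nonsense R4
PTEN K267fs frameshift_del R4
PTEN Y68* nonsense R4
PTEN T319fs frameshift_del R4
GATA3 P409fs frameshift_ins R4
GATA3 S408fs frameshift_ins R4
CDH1 Q23* nonsense R4
CDH1 W156* nonsense R4
CDH1 P373fs frameshift_del R4
MAP3K1 S939fs frameshift_del R4
MAP3K1 Q1227* nonsense R4
RB1 R358* nonsense R4
RB1 Q217* nonsense R4
RB1 S443fs frameshift_del R4
ARID1A Q586* nonsense R4
NF1 R461* nonsense R4
BRCA1 E111fs frameshift_ins R4
BRCA2 K437fs frameshift_del R4
NCOR1 S887* nonsense R4
TBX3 N212fs frameshift_del R4
CTCF R567* nonsense R4
PIK3CA E543Q missense R5
AKT1 E20D missense R5
KRAS G15S missense R5
EGFR A859T missense R5
ESR1 V534E missense R5
TP53 P275T missense R5
GATA3 M294K missense R7
SF3B1 K700R missense R7
PIK3R1 E160D missense R7
MAP2K4 S184L missense R7
RUNX1 R204Q missense R7
SMAD4 A118V missense R7
")
  chrom_of <- c(PIK3CA = "3", AKT1 = "14", ERBB2 = "17", KRAS = "12",
                NRAS = "1", ESR1 = "6", EGFR = "7", GNAS = "20", TP53 = "17",
                PTEN = "10", MAP2K4 = "17", CDH1 = "16", SF3B1 = "2",
                GATA3 = "10", MAP3K1 = "5", RB1 = "13", ARID1A = "1",
                NF1 = "17", BRCA1 = "17", BRCA2 = "13", NCOR1 = "17",
                TBX3 = "12", CTCF = "16", PIK3R1 = "5", RUNX1 = "21",
                SMAD4 = "18")
  df$chrom <- unname(chrom_of[df$gene])
  df$pos <- 1000000L + seq_len(nrow(df)) * 1000L
  df$ref <- "C"; df$alt <- "T"
  df$ref[df$variant_class == "frameshift_del"] <- "CA"
  df$alt[df$variant_class == "frameshift_del"] <- "C"
  df$ref[df$variant_class == "frameshift_ins"] <- "C"
  df$alt[df$variant_class == "frameshift_ins"] <- "CA"
  df$ref[df$variant_class == "inframe_del"] <- "CGGAATTAAGAGA"
  df$alt[df$variant_class == "inframe_del"] <- "C"
  df$category <- c(R1 = "ONCOGENIC", R2 = "ONCOGENIC", R4 = "ONCOGENIC",
                   R5 = "PUTATIVE", R7 = "POSSIBLE")[df$rule]
  df
}

#' Built-in annotation resources of the generator
#'
#' The COSMIC-like recurrence snapshot and gene-role table consistent with
#' the driver catalogue (plus decoy entries never planted).
#'
#' @return A list with `recurrence` and `roles` data.frames in the layouts
#'   [read_recurrence_table()] and [read_gene_role_table()] read.
#' @export
catalogue_resources <- function() {
  recurrence <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene protein_change cosmic_confirmed_samples
PIK3CA E545K 52
PIK3CA H1047R 83
PIK3CA N345K 13
PIK3CA C420R 11
PIK3CA E542K 31
AKT1 E17K 28
ERBB2 L755S 12
ERBB2 V777L 8
KRAS G12D 95
KRAS G13D 33
KRAS Q61H 21
NRAS Q61K 41
NRAS G12C 16
ESR1 Y537S 24
ESR1 D538G 38
EGFR L858R 72
GNAS R201C 30
EGFR E746_A750del 60
TP53 R273H 44
TP53 R175H 61
TP53 Y220C 26
TP53 R282W 29
TP53 G245S 27
PTEN R130G 21
PTEN R173H 9
MAP2K4 R134W 5
CDH1 D254Y 3
SF3B1 R625C 6
GATA3 M294K 1
SF3B1 K700R 1
PIK3R1 E160D 1
MAP2K4 S184L 1
RUNX1 R204Q 1
SMAD4 A118V 1
BRAF V600E 103
TP53 R248Q 49
")
  roles <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene role
PIK3CA oncogene
AKT1 oncogene
ERBB2 oncogene
KRAS oncogene
NRAS oncogene
ESR1 oncogene
EGFR oncogene
GNAS oncogene
MYC oncogene
BRAF oncogene
TP53 tumour_suppressor
PTEN tumour_suppressor
GATA3 tumour_suppressor
CDH1 tumour_suppressor
MAP3K1 tumour_suppressor
RB1 tumour_suppressor
ARID1A tumour_suppressor
NF1 tumour_suppressor
BRCA1 tumour_suppressor
BRCA2 tumour_suppressor
NCOR1 tumour_suppressor
TBX3 tumour_suppressor
CTCF tumour_suppressor
SF3B1 other_cancer_gene
MAP2K4 other_cancer_gene
PIK3R1 other_cancer_gene
RUNX1 other_cancer_gene
SMAD4 other_cancer_gene
")
  list(recurrence = recurrence, roles = roles)
}

largest_remainder <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

rbetabinom <- function(n, size, prob, rho) {
  out <- integer(n)
  pos <- prob > 0 & prob < 1
  if (any(pos)) {
    a <- prob[pos] * (1 - rho) / rho
    b <- (1 - prob[pos]) * (1 - rho) / rho
    p <- stats::rbeta(sum(pos), a, b)
    out[pos] <- stats::rbinom(sum(pos), size[pos], p)
  }
  out[prob >= 1] <- size[prob >= 1]
  out
}

sample_reads <- function(af_true, mean_depth, noise, rho) {
  n <- length(af_true)
  if (noise == "none") {
    depth <- rep(as.integer(round(mean_depth)), n)
    alt <- as.integer(round(af_true * depth))
  } else {
    depth <- pmax(1L, stats::rpois(n, mean_depth))
    alt <- if (noise == "binomial") stats::rbinom(n, depth, af_true)
           else rbetabinom(n, depth, af_true, rho)
  }
  list(depth = depth, alt = alt, af = alt / depth)
}

#' Generate a synthetic cohort
#'
#' @param config An [generator_config()].
#' @param outdir Optional directory; when given, the full analysis input file
#'   set is written: `discovery.tsv`, `validation.tsv`, `hierarchy.yaml`,
#'   `recurrence.tsv`, `roles.tsv`, and per-lesion `cn/*.tsv` and
#'   `rr/*.bedpe`.
#' @return A list of class `mfhet_cohort` with elements `discovery`,
#'   `validation` (mutation-call data.frames), `hierarchy`, `recurrence`,
#'   `roles`, `cn_profiles`, `rearrangements` (per-patient lists) and `truth`
#'   (ground-truth tables: `patients`, `variants`, `calls`, `scna_events`,
#'   `rearrangement_events`).
#' @export
generate_cohort <- function(config = generator_config(), outdir = NULL) {
  stopifnot(inherits(config, "mfhet_generator_config"))
  set.seed(config$seed)
  res <- catalogue_resources()
  cat_df <- driver_catalogue()
  groups <- rep(names(config$group_proportions),
                largest_remainder(config$n_patients, config$group_proportions))
  groups <- sample(groups)
  pids <- sprintf("P%03d", seq_len(config$n_patients))

  passenger_counter <- 0L
  psg_residue <- new.env(parent = emptyenv())
  new_passenger <- function(silent) {
    passenger_counter <<- passenger_counter + 1L
    gene <- sprintf("PSG%03d", (passenger_counter %% 300L) + 1L)
    k <- (get0(gene, envir = psg_residue) %||% 0L) + 1L
    assign(gene, k, envir = psg_residue)
    residue <- 11L + 17L * k
    list(gene = gene,
         protein_change = if (silent) sprintf("L%d=", residue)
                          else sprintf("A%dV", residue),
         variant_class = if (silent) "silent" else "missense",
         rule = NA_character_, category = if (silent) NA_character_ else "UNKNOWN",
         chrom = as.character(1L + (passenger_counter %% 22L)),
         pos = 10000L + passenger_counter * 37L, ref = "C", alt = "T")
  }
  driver_row <- function(i) {
    r <- cat_df[i, ]
    list(gene = r$gene, protein_change = r$protein_change,
         variant_class = r$variant_class, rule = r$rule, category = r$category,
         chrom = as.character(r$chrom), pos = r$pos, ref = r$ref, alt = r$alt)
  }

  patients <- list(); variant_rows <- list(); call_rows <- list()
  for (pi in seq_along(pids)) {
    pid <- pids[pi]; group <- groups[pi]
    nl <- as.integer(sample(names(config$lesion_count_probs), 1L,
                            prob = config$lesion_count_probs))
    ns_per_lesion <- sample(seq(config$samples_per_lesion_range[1L],
                                config$samples_per_lesion_range[2L]),
                            nl, replace = TRUE)
    lesions <- sprintf("%s_L%d", pid, seq_len(nl))
    samples <- unlist(lapply(seq_len(nl), function(li)
      sprintf("%s_S%d", lesions[li], seq_len(ns_per_lesion[li]))))
    lesion_of <- rep(lesions, ns_per_lesion)

    nm <- min(1L + stats::rgeom(1L, config$mutation_geom_prob),
              config$mutation_count_max)
    if (group == "INTERMEDIATE") nm <- max(nm, 2L)
    if (group == "HETEROGENEOUS") nm <- max(nm, nl)
    # lesion carriers and CCF per mutation
    driver_pool <- sample(nrow(cat_df))
    take_driver <- function() {
      if (!length(driver_pool)) return(NULL)
      i <- driver_pool[1L]; driver_pool <<- driver_pool[-1L]
      driver_row(i)
    }
    if (group == "HOMOGENEOUS") {
      truncal_idx <- seq_len(nm)
      carrier_sets <- rep(list(lesions), nm)
      ccfs <- rep(1, nm)
    } else if (group == "INTERMEDIATE") {
      n_truncal <- sample(seq_len(nm - 1L), 1L)
      truncal_idx <- seq_len(n_truncal)
      carrier_sets <- vector("list", nm); ccfs <- numeric(nm)
      for (mi in seq_len(nm)) {
        if (mi <= n_truncal) {
          carrier_sets[[mi]] <- lesions; ccfs[mi] <- 1
        } else {
          k <- sample(seq_len(nl - 1L), 1L)  # proper non-empty lesion subset
          carrier_sets[[mi]] <- sample(lesions, k)
          ccfs[mi] <- config$private_subclone_ccf
        }
      }
    } else {  # HETEROGENEOUS: disjoint lesion sets, each lesion >= 1 mutation
      truncal_idx <- integer(0)
      owner <- c(seq_len(nl), sample(nl, nm - nl, replace = TRUE))
      carrier_sets <- lapply(owner, function(o) lesions[o])
      ccfs <- rep(1, nm)
    }
    # identity: heterogeneous lesions get distinct forced drivers; the slots
    # that define the planted group (first truncal, first private) must be
    # non-silent, since silent variants are excluded from the grouping
    ids <- vector("list", nm)
    forced_driver <- if (group == "HETEROGENEOUS") seq_len(nl) else integer(0)
    forced_nonsilent <- c(1L, if (group == "INTERMEDIATE")
      length(truncal_idx) + 1L)
    for (mi in seq_len(nm)) {
      want_driver <- mi %in% forced_driver ||
        stats::runif(1L) < config$oncogenic_fraction
      d <- if (want_driver) take_driver() else NULL
      ids[[mi]] <- if (!is.null(d)) d
        else new_passenger(silent = !(mi %in% forced_nonsilent) &&
                             stats::runif(1L) < config$silent_fraction)
    }
    purity <- stats::runif(length(samples), config$purity_range[1L],
                           config$purity_range[2L])
    names(purity) <- samples
    dist_mean <- config$distance_means[[group]]
    distance <- if (stats::runif(1L) < config$distance_missing_rate) NA_real_
                else max(0.2, stats::rnorm(1L, dist_mean, config$distance_sd))
    covs <- list(
      age_group = sample(c("<40", "40-49", "50-69", ">70"), 1L,
                         prob = c(2, 11, 17, 6) / 36),
      tumour_size_cm = round(stats::runif(1L, 1, 5.5), 1),
      n_positive_nodes = sample(0:12, 1L, prob = c(16, rep(16/3, 3), rep(1/6, 6), rep(1, 3)) / 36),
      grade = sample(c("G1", "G2", "G3"), 1L, prob = c(8, 7, 21) / 36),
      subtype = sample(c("ER+/HER2-", "ER-/HER2-", "HER2+"), 1L,
                       prob = c(26, 4, 6) / 36),
      dcis_present = stats::runif(1L) < 30 / 36,
      lvi_present = if (stats::runif(1L) < config$lvi_missing_rate) NULL
                    else stats::runif(1L) < 14 / 35,
      max_inter_lesion_distance_cm = if (is.na(distance)) NULL else round(distance, 2))
    covs <- Filter(Negate(is.null), covs)
    patients[[pi]] <- list(
      patient_id = pid, covariates = covs,
      lesions = lapply(seq_len(nl), function(li)
        list(lesion_id = lesions[li],
             samples = samples[lesion_of == lesions[li]])))
    for (mi in seq_len(nm)) {
      id <- ids[[mi]]
      key <- paste(id$chrom, id$pos, id$ref, id$alt, sep = ":")
      variant_rows[[length(variant_rows) + 1L]] <- data.frame(
        patient_id = pid, key = key, gene_symbol = id$gene,
        protein_change = id$protein_change, variant_class = id$variant_class,
        chrom = id$chrom, pos = id$pos, ref_allele = id$ref, alt_allele = id$alt,
        rule = id$rule, category = id$category,
        truncal = mi %in% truncal_idx,
        silent = id$variant_class == "silent", stringsAsFactors = FALSE)
      for (s in samples) {
        les <- lesion_of[match(s, samples)]
        ccf_s <- if (les %in% carrier_sets[[mi]]) ccfs[mi] else 0
        call_rows[[length(call_rows) + 1L]] <- data.frame(
          patient_id = pid, key = key, sample_id = s, lesion_id = les,
          present = ccf_s > 0, ccf = ccf_s,
          af_true = purity[[s]] * ccf_s / 2, stringsAsFactors = FALSE)
      }
    }
  }

  truth_variants <- do.call(rbind, variant_rows)
  truth_calls <- do.call(rbind, call_rows)

  # cohort-level plantings: a dataset-recurrent substitution and a cluster
  plant_extra <- function(pid, gene, protein_change, chrom, pos, ref, alt,
                          rule, category) {
    p <- patients[[match(pid, pids)]]
    all_samples <- unlist(lapply(p$lesions, `[[`, "samples"))
    lesion_of <- rep(vapply(p$lesions, `[[`, "", "lesion_id"),
                     vapply(p$lesions, function(l) length(l$samples), 0L))
    grp <- groups[match(pid, pids)]
    carriers <- if (grp == "HETEROGENEOUS") lesion_of[1L] else unique(lesion_of)
    key <- paste(chrom, pos, ref, alt, sep = ":")
    truth_variants <<- rbind(truth_variants, data.frame(
      patient_id = pid, key = key, gene_symbol = gene,
      protein_change = protein_change, variant_class = "missense",
      chrom = chrom, pos = pos, ref_allele = ref, alt_allele = alt,
      rule = rule, category = category, truncal = grp != "HETEROGENEOUS",
      silent = FALSE, stringsAsFactors = FALSE))
    pur <- stats::runif(length(all_samples), config$purity_range[1L],
                        config$purity_range[2L])
    truth_calls <<- rbind(truth_calls, data.frame(
      patient_id = pid, key = key, sample_id = all_samples,
      lesion_id = lesion_of, present = lesion_of %in% carriers,
      ccf = as.numeric(lesion_of %in% carriers),
      af_true = pur * (lesion_of %in% carriers) / 2, stringsAsFactors = FALSE))
  }
  if (config$plant_dataset_recurrent && config$n_patients >= 2L)
    for (pid in pids[1:2])
      plant_extra(pid, "DSREC1", "G55R", "9", 5000000L, "C", "T", "R3", "ONCOGENIC")
  if (config$plant_cluster && config$n_patients >= 3L) {
    clst <- list(c("S100F", 6000000L), c("G101E", 6000100L), c("A103T", 6000200L))
    for (k in 1:3)
      plant_extra(pids[k %% config$n_patients + 1L], "CLST1", clst[[k]][1L],
                  "11", as.integer(clst[[k]][2L]), "G", "T", "R6", "PUTATIVE")
  }

  # dataset-recurrence adjustment: a substitution planted in >= 2 patients
  # fires the dataset-recurrence rule ahead of any weaker planted rule
  nonsilent <- truth_variants[!truth_variants$silent, , drop = FALSE]
  pat_count <- tapply(nonsilent$patient_id, nonsilent$key,
                      function(p) length(unique(p)))
  is_sub <- truth_variants$variant_class %in% SUBSTITUTION_CLASSES
  dup <- !truth_variants$silent & is_sub &
    pat_count[truth_variants$key] >= 2L
  weaker <- is.na(truth_variants$rule) |
    truth_variants$rule %in% c("R4", "R5", "R6", "R7")
  upgrade <- dup & weaker
  truth_variants$rule[upgrade] <- "R3"
  truth_variants$category[upgrade] <- "ONCOGENIC"

  # read sampling
  tc <- truth_calls
  val <- sample_reads(tc$af_true, config$depth_validation, config$af_noise,
                      config$overdispersion)
  disc <- sample_reads(tc$af_true, config$depth_discovery, config$af_noise,
                       config$overdispersion)
  # assay failures: variant-level design failures and sample-level DNA
  # exhaustion, matching the study's two failure modes
  pv <- unique(paste(tc$patient_id, tc$key))
  failed_pv <- pv[stats::runif(length(pv)) < config$assay_fail_variant_rate]
  all_s <- unique(tc$sample_id)
  failed_s <- all_s[stats::runif(length(all_s)) < config$assay_fail_sample_rate]
  assay_failed <- paste(tc$patient_id, tc$key) %in% failed_pv |
    tc$sample_id %in% failed_s
  dropped <- stats::runif(nrow(tc)) < config$discovery_dropout
  # the discovery caller needs >= 3 supporting reads and >= 5% observed AF
  detected <- !dropped & disc$alt >= 3L & disc$af >= 0.05
  # guarantee every variant is discovered somewhere (else it would never have
  # entered the validation assay)
  pk <- paste(tc$patient_id, tc$key)
  for (g in unique(pk[tc$present])) {
    idx <- which(pk == g & tc$present)
    if (!any(detected[idx])) {
      i <- idx[which.max(tc$af_true[idx])]
      tries <- 0L
      while ((disc$alt[i] < 3L || disc$af[i] < 0.05) && tries < 100L) {
        r <- sample_reads(tc$af_true[i], config$depth_discovery,
                          config$af_noise, config$overdispersion)
        disc$depth[i] <- r$depth; disc$alt[i] <- r$alt; disc$af[i] <- r$af
        tries <- tries + 1L
      }
      if (disc$alt[i] < 3L || disc$af[i] < 0.05) {
        disc$alt[i] <- max(3L, as.integer(ceiling(0.05 * disc$depth[i])))
        disc$af[i] <- disc$alt[i] / disc$depth[i]
      }
      detected[i] <- TRUE
    }
  }

  anno <- truth_variants[!duplicated(paste(truth_variants$patient_id,
                                           truth_variants$key)), , drop = FALSE]
  am <- match(pk, paste(anno$patient_id, anno$key))
  base_calls <- data.frame(
    patient_id = tc$patient_id, sample_id = tc$sample_id,
    gene_symbol = anno$gene_symbol[am], chrom = anno$chrom[am],
    pos = anno$pos[am], ref_allele = anno$ref_allele[am],
    alt_allele = anno$alt_allele[am], variant_class = anno$variant_class[am],
    protein_change = anno$protein_change[am], stringsAsFactors = FALSE)
  discovery <- base_calls[detected, , drop = FALSE]
  discovery$af_discovery <- disc$af[detected]
  discovery$depth_discovery <- disc$depth[detected]
  discovery$af_validation <- NA_real_; discovery$depth_validation <- NA_integer_
  discovery$assay_ok_validation <- TRUE
  validation <- base_calls
  validation$af_discovery <- NA_real_; validation$depth_discovery <- NA_integer_
  validation$af_validation <- ifelse(assay_failed, NA_real_, val$af)
  validation$depth_validation <- ifelse(assay_failed, NA_integer_, val$depth)
  validation$assay_ok_validation <- !assay_failed
  rownames(discovery) <- rownames(validation) <- NULL

  hierarchy <- cohort_hierarchy(patients)
  truth_patients <- data.frame(
    patient_id = pids, group = groups,
    n_lesions = vapply(patients, function(p) length(p$lesions), 0L),
    n_samples = vapply(patients, function(p)
      sum(vapply(p$lesions, function(l) length(l$samples), 0L)), 0L),
    stringsAsFactors = FALSE)

  wgs <- generate_wgs(pids, groups, patients, config)

  cohort <- structure(list(
    discovery = discovery, validation = validation, hierarchy = hierarchy,
    recurrence = res$recurrence, roles = res$roles,
    cn_profiles = wgs$cn_profiles, rearrangements = wgs$rearrangements,
    truth = list(patients = truth_patients, variants = truth_variants,
                 calls = truth_calls, scna_events = wgs$scna_events,
                 rearrangement_events = wgs$rearrangement_events),
    config = config), class = "mfhet_cohort")
  if (!is.null(outdir)) write_cohort(cohort, outdir)
  cohort
}

WGS_CHROMS <- as.character(1:6)
WGS_CHROM_LEN <- 150e6

# planted, non-overlapping copy-number events and rearrangements for the
# genome-wide subset: 2 homogeneous, 3 intermediate, 3 heterogeneous patients
# where available (mirroring the study's frozen-tissue subset)
generate_wgs <- function(pids, groups, patients, config) {
  n_wgs <- min(config$n_wgs_patients, length(pids))
  want <- c(HOMOGENEOUS = 2L, INTERMEDIATE = 3L, HETEROGENEOUS = 3L)
  sel <- character(0)
  for (g in names(want))
    sel <- c(sel, utils::head(pids[groups == g], want[[g]]))
  sel <- utils::head(unique(c(sel, pids)), n_wgs)
  cn_profiles <- list(); rearrangements <- list()
  scna_rows <- list(); rr_rows <- list()
  private_lambda <- c(HOMOGENEOUS = 0.5, INTERMEDIATE = 1.5, HETEROGENEOUS = 3)
  for (pid in sel) {
    p <- patients[[match(pid, pids)]]
    grp <- groups[match(pid, pids)]
    lesions <- vapply(p$lesions, `[[`, "", "lesion_id")
    # non-overlapping event intervals for the whole patient
    taken <- list()
    draw_interval <- function() {
      for (try in 1:200) {
        ch <- sample(WGS_CHROMS, 1L)
        len <- stats::runif(1L, 5e6, 3e7)
        start <- floor(stats::runif(1L, 0, WGS_CHROM_LEN - len))
        ok <- TRUE
        for (t in taken) if (t$ch == ch &&
            start < t$end + 1e6 && start + len + 1e6 > t$start) { ok <- FALSE; break }
        if (ok) {
          iv <- list(ch = ch, start = start, end = start + len)
          taken[[length(taken) + 1L]] <<- iv
          return(iv)
        }
      }
      NULL
    }
    n_common <- 2L + stats::rpois(1L, 1)
    events <- list()
    for (k in seq_len(n_common)) {
      iv <- draw_interval(); if (is.null(iv)) next
      events[[length(events) + 1L]] <- list(
        iv = iv, dir = sample(c("gain", "loss"), 1L), lesions = lesions,
        common = TRUE)
    }
    for (les in lesions) {
      n_priv <- stats::rpois(1L, private_lambda[[grp]])
      for (k in seq_len(n_priv)) {
        iv <- draw_interval(); if (is.null(iv)) next
        events[[length(events) + 1L]] <- list(
          iv = iv, dir = sample(c("gain", "loss"), 1L), lesions = les,
          common = FALSE)
      }
    }
    profs <- list()
    for (les in lesions) {
      segs <- list()
      for (ch in WGS_CHROMS) {
        evs <- Filter(function(e) e$iv$ch == ch && les %in% e$lesions, events)
        cuts <- sort(unique(c(0, WGS_CHROM_LEN,
                              unlist(lapply(evs, function(e) c(e$iv$start, e$iv$end))))))
        for (i in seq_len(length(cuts) - 1L)) {
          s <- cuts[i]; e <- cuts[i + 1L]
          cn <- 2L
          for (ev in evs) if (ev$iv$start <= s && ev$iv$end >= e)
            cn <- cn + if (ev$dir == "gain") 1L else -1L
          segs[[length(segs) + 1L]] <- data.frame(
            chrom = ch, start = s, end = e,
            absolute_copy_number = max(cn, 0L), stringsAsFactors = FALSE)
        }
      }
      profs[[les]] <- cn_profile(do.call(rbind, segs), les, ploidy = 2)
    }
    cn_profiles[[pid]] <- profs
    for (ev in events) for (les in ev$lesions)
      scna_rows[[length(scna_rows) + 1L]] <- data.frame(
        patient_id = pid, lesion_id = les, chrom = ev$iv$ch,
        start = ev$iv$start, end = ev$iv$end, direction = ev$dir,
        common = ev$common, stringsAsFactors = FALSE)
    # rearrangements
    rr_id <- 0L
    mk_event <- function(common_flag) {
      rr_id <<- rr_id + 1L
      inter <- stats::runif(1L) < 0.2
      ch1 <- sample(WGS_CHROMS, 1L)
      ch2 <- if (inter) sample(setdiff(WGS_CHROMS, ch1), 1L) else ch1
      p1 <- floor(stats::runif(1L, 1e6, WGS_CHROM_LEN - 1e6))
      p2 <- if (inter) floor(stats::runif(1L, 1e6, WGS_CHROM_LEN - 1e6))
            else min(p1 + floor(stats::runif(1L, 1e4, 5e6)), WGS_CHROM_LEN - 1e6)
      strands <- if (inter) sample(c("+", "-"), 2L, replace = TRUE)
                 else switch(sample(3L, 1L), c("+", "-"), c("-", "+"),
                             rep(sample(c("+", "-"), 1L), 2L))
      list(name = sprintf("%s_RR%03d", pid, rr_id), chrom1 = ch1, pos1 = p1,
           strand1 = strands[1L], chrom2 = ch2, pos2 = p2,
           strand2 = strands[2L], common = common_flag)
    }
    n_common_rr <- 4L + stats::rpois(1L, 2)
    common_events <- lapply(seq_len(n_common_rr), function(i) mk_event(TRUE))
    rr_list <- list()
    for (les in lesions) {
      rows <- lapply(common_events, function(e) data.frame(
        lesion_id = les, chrom1 = e$chrom1,
        pos1 = e$pos1 + floor(stats::runif(1L, -100, 100)),
        strand1 = e$strand1, chrom2 = e$chrom2,
        pos2 = e$pos2 + floor(stats::runif(1L, -100, 100)),
        strand2 = e$strand2, name = e$name, stringsAsFactors = FALSE))
      n_priv <- 1L + stats::rpois(1L, private_lambda[[grp]])
      priv <- lapply(seq_len(n_priv), function(i) {
        e <- mk_event(FALSE)
        data.frame(lesion_id = les, chrom1 = e$chrom1, pos1 = e$pos1,
                   strand1 = e$strand1, chrom2 = e$chrom2, pos2 = e$pos2,
                   strand2 = e$strand2, name = e$name, stringsAsFactors = FALSE)
      })
      ev <- do.call(rbind, c(rows, priv))
      rr_list[[les]] <- rearrangement_set(ev)
      for (i in seq_len(nrow(ev)))
        rr_rows[[length(rr_rows) + 1L]] <- data.frame(
          patient_id = pid, lesion_id = les, name = ev$name[i],
          common = ev$name[i] %in% vapply(common_events, `[[`, "", "name"),
          stringsAsFactors = FALSE)
    }
    rearrangements[[pid]] <- rr_list
  }
  list(cn_profiles = cn_profiles, rearrangements = rearrangements,
       scna_events = if (length(scna_rows)) do.call(rbind, scna_rows) else NULL,
       rearrangement_events = if (length(rr_rows)) do.call(rbind, rr_rows) else NULL)
}

#' Write a generated cohort to disk
#'
#' @param cohort An `mfhet_cohort`.
#' @param outdir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(cohort$discovery, file.path(outdir, "discovery.tsv"),
                      "discovery")
  write_variant_table(cohort$validation, file.path(outdir, "validation.tsv"),
                      "validation")
  write_hierarchy(cohort$hierarchy, file.path(outdir, "hierarchy.yaml"))
  utils::write.table(cohort$recurrence, file.path(outdir, "recurrence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$roles, file.path(outdir, "roles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(cohort$cn_profiles)) {
    dir.create(file.path(outdir, "cn"), showWarnings = FALSE)
    dir.create(file.path(outdir, "rr"), showWarnings = FALSE)
    for (pid in names(cohort$cn_profiles))
      for (prof in cohort$cn_profiles[[pid]])
        utils::write.table(prof$segments,
                           file.path(outdir, "cn", paste0(prof$lesion_id, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    for (pid in names(cohort$rearrangements))
      for (les in names(cohort$rearrangements[[pid]])) {
        ev <- cohort$rearrangements[[pid]][[les]]
        bedpe <- data.frame(ev$chrom1, ev$pos1, ev$pos1 + 1L, ev$chrom2,
                            ev$pos2, ev$pos2 + 1L, ev$name, 0L,
                            ev$strand1, ev$strand2)
        utils::write.table(bedpe, file.path(outdir, "rr", paste0(les, ".bedpe")),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
  }
  invisible(outdir)
}

#' @export
print.mfhet_cohort <- function(x, ...) {
  cat(sprintf("mfhet synthetic cohort: %d patients (seed %d)\n",
              x$config$n_patients, x$config$seed))
  print(table(x$truth$patients$group))
  invisible(x)
}

#' Score the pipeline against the planted truth
#'
#' @param cohort An `mfhet_cohort` (carries the ground truth).
#' @param confirmation An [confirm_cohort()] result on that cohort.
#' @param oncogenicity An [classify_variants()] result, or `NULL`.
#' @param heterogeneity An [classify_cohort()] result, or `NULL`.
#' @param cn An [compare_lesion_genomes()] result, or `NULL`.
#' @return A list with `confirmation` (sensitivity, specificity, counts),
#'   `oncogenicity` (`category_accuracy`, `rule_accuracy`), `group_confusion`
#'   (3 x 3 matrix) and `group_accuracy`, and `rearrangement_accuracy` /
#'   `scna_accuracy` when genome-wide results are supplied.
#' @export
truth_vs_pipeline_report <- function(cohort, confirmation,
                                     oncogenicity = NULL,
                                     heterogeneity = NULL, cn = NULL) {
  truth <- cohort$truth
  out <- list()
  tab <- confirmation$status_table
  tkey <- paste(truth$calls$patient_id, truth$calls$key, truth$calls$sample_id)
  skey <- paste(tab$patient_id, tab$key, tab$sample_id)
  m <- match(skey, tkey)
  if (anyNA(m))
    stop("integrity error: status rows do not match the cohort's truth identifiers")
  informative <- tab$status != "ASSAY_FAILED"
  called <- tab$status %in% c("CONFIRMED", "PRESENT")
  tp <- sum(informative & called & truth$calls$present[m])
  fn <- sum(informative & !called & truth$calls$present[m])
  tn <- sum(informative & !called & !truth$calls$present[m])
  fp <- sum(informative & called & !truth$calls$present[m])
  out$confirmation <- list(sensitivity = tp / (tp + fn),
                           specificity = tn / (tn + fp),
                           tp = tp, fp = fp, tn = tn, fn = fn)
  if (!is.null(oncogenicity)) {
    tv <- truth$variants[!truth$variants$silent, , drop = FALSE]
    tv <- tv[!duplicated(tv$key), , drop = FALSE]
    m2 <- match(oncogenicity$key, tv$key)
    if (anyNA(m2))
      stop("integrity error: classified variants missing from truth")
    truth_cat <- tv$category[m2]
    truth_rule <- tv$rule[m2]
    cat_ok <- oncogenicity$category == truth_cat
    rule_ok <- ifelse(is.na(truth_rule), is.na(oncogenicity$triggering_rule) |
                        oncogenicity$category == "UNKNOWN",
                      !is.na(oncogenicity$triggering_rule) &
                        oncogenicity$triggering_rule == truth_rule)
    out$oncogenicity <- list(category_accuracy = mean(cat_ok),
                             rule_accuracy = mean(cat_ok & rule_ok),
                             n = nrow(oncogenicity))
  }
  if (!is.null(heterogeneity)) {
    pred <- heterogeneity$patients
    m3 <- match(pred$patient_id, truth$patients$patient_id)
    lv <- c("HOMOGENEOUS", "INTERMEDIATE", "HETEROGENEOUS")
    cm <- table(truth = factor(truth$patients$group[m3], lv),
                predicted = factor(pred$group, lv))
    out$group_confusion <- cm
    out$group_accuracy <- sum(diag(cm)) / sum(cm)
  }
  if (!is.null(cn) && !is.null(truth$rearrangement_events)) {
    acc <- c()
    for (pid in names(cn$rearrangements)) {
      ev <- cn$rearrangements[[pid]]$events
      te <- truth$rearrangement_events
      te <- te[te$patient_id == pid, , drop = FALSE]
      m4 <- match(paste(ev$lesion_id, ev$name), paste(te$lesion_id, te$name))
      acc <- c(acc, ev$common == te$common[m4])
    }
    out$rearrangement_accuracy <- mean(acc)
    sacc <- c()
    for (pid in names(cn$scna)) {
      ab <- cn$scna[[pid]]$aberrations
      ts <- truth$scna_events
      ts <- ts[ts$patient_id == pid, , drop = FALSE]
      if (!nrow(ab)) next
      for (i in seq_len(nrow(ab))) {
        hit <- which(ts$lesion_id == ab$lesion_id[i] & ts$chrom == ab$chrom[i] &
                       ts$start < ab$end[i] & ts$end > ab$start[i])
        if (length(hit) == 1L) sacc <- c(sacc, ab$common[i] == ts$common[hit])
      }
    }
    out$scna_accuracy <- if (length(sacc)) mean(sacc) else NA_real_
  }
  out
}
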