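#' Rule-based oncogenicity classification
#'
#' Each unique non-silent variant is assigned one of four tiers by a fixed
#' rule cascade. Tier 1 (`ONCOGENIC`): R1 non-synonymous substitutions or
#' in-frame indels in canonical oncogenes at recurrent hotspots; R2
#' non-synonymous substitutions recurrent in two or more confirmed catalogue
#' samples; R3 variants recurrent in two or more patients of the cohort
#' itself; R4 nonsense or frameshifting indels in known tumour suppressors.
#' Tier 2 (`PUTATIVE`): R5 previously unreported non-synonymous substitutions
#' in a known cancer gene within +/-3 amino acids of a catalogue-recurrent
#' mutation; R6 membership in a cohort mutation cluster (more than two
#' substitutions within three amino acids of each other). Tier 3 (`POSSIBLE`):
#' R7 substitutions confirmed somatic in exactly one catalogue sample; R8
#' proximity to a catalogue mutation cluster (requires an `in_cluster` column
#' in the recurrence table; inert otherwise). Anything else is `UNKNOWN`.
#' Tiers are evaluated in order and the first tier that fires decides the
#' category; within a tier the lowest-numbered rule is recorded. Downstream
#' analyses collapse the three oncogenic tiers into a single binary
#' "oncogenic" flag (category != UNKNOWN).
#'
#' @name oncogenicity
NULL

ONCO_CATEGORIES <- c("ONCOGENIC", "PUTATIVE", "POSSIBLE", "UNKNOWN")

#' Residue position of a protein change
#'
#' Extracts the first residue number from notations such as `R196*`,
#' `p.H1047R`, `E545K`, `T256fs` or `S241del`. Returns `NA` (with no error)
#' when no position is parseable.
#'
#' @param protein_change Character vector.
#' @return Integer vector of residue positions.
#' @export
protein_position <- function(protein_change) {
  m <- regmatches(protein_change, regexpr("[0-9]+", protein_change))
  out <- rep(NA_integer_, length(protein_change))
  out[regexpr("[0-9]+", protein_change) > 0L & !is.na(protein_change)] <-
    as.integer(m)
  out
}

# residues of a gene's cohort substitutions that sit in a cluster:
# >= min_n distinct positions spanning <= window residues
cluster_positions <- function(positions, window = 3L, min_n = 3L) {
  p <- sort(unique(positions[!is.na(positions)]))
  if (length(p) < min_n) return(integer(0))
  in_cluster <- logical(length(p))
  for (i in seq_len(length(p) - min_n + 1L)) {
    j <- i + min_n - 1L
    if (p[j] - p[i] <= window) in_cluster[i:j] <- TRUE
  }
  p[in_cluster]
}

#' Classify one variant
#'
#' Low-level single-variant classifier; [classify_variants()] prepares the
#' cohort-level inputs (dataset recurrence, cohort substitution positions)
#' and is what most callers want.
#'
#' @param variant_class One of the standard variant classes.
#' @param protein_change Protein change string (may be `NA`; position rules
#'   are then skipped with a warning, but the truncation rule R4 still
#'   applies).
#' @param gene_role `oncogene`, `tumour_suppressor`, `other_cancer_gene` or
#'   `not_cancer_gene`.
#' @param cosmic_count Confirmed-sample count for the exact
#'   (gene, protein_change) in the recurrence table (0 when absent).
#' @param cosmic_recurrent_positions Residue positions in this gene whose
#'   catalogue count meets the recurrence minimum.
#' @param cosmic_cluster_positions Residue positions flagged `in_cluster` in
#'   the catalogue for this gene (empty when the column is absent; R8 inert).
#' @param dataset_recurrence_count Number of distinct cohort patients carrying
#'   this exact genomic variant.
#' @param cohort_cluster_positions Residues of this gene's cohort mutation
#'   clusters (from [cluster_positions()] over all cohort substitutions).
#' @param config An [mfhet_config()].
#' @return A list with `category`, `triggering_rule` (e.g. `"R4"`, `NA` for
#'   UNKNOWN) and `evidence`.
#' @export
classify_variant <- function(variant_class, protein_change, gene_role,
                             cosmic_count, cosmic_recurrent_positions,
                             cosmic_cluster_positions = integer(0),
                             dataset_recurrence_count = 1L,
                             cohort_cluster_positions = integer(0),
                             config = mfhet_config()) {
  w <- config$hotspot_window_aa
  is_sub <- variant_class %in% SUBSTITUTION_CLASSES
  is_inframe <- variant_class %in% c("inframe_ins", "inframe_del")
  is_truncating <- variant_class %in% c("nonsense", "frameshift_ins", "frameshift_del")
  pos <- protein_position(protein_change)
  if ((is_sub || is_inframe) && is.na(pos) && !is.na(protein_change))
    warning("unparseable protein_change '", protein_change,
            "': residue-position rules skipped")
  near <- function(targets) !is.na(pos) && length(targets) &&
    any(abs(targets - pos) <= w)
  rules <- c(
    R1 = (is_sub || is_inframe) && gene_role == "oncogene" &&
      cosmic_count >= config$cosmic_recurrent_min,
    R2 = is_sub && cosmic_count >= config$cosmic_recurrent_min,
    R3 = dataset_recurrence_count >= 2L && is_sub,
    R4 = is_truncating && gene_role == "tumour_suppressor",
    R5 = is_sub && cosmic_count == 0L && gene_role != "not_cancer_gene" &&
      near(cosmic_recurrent_positions),
    R6 = is_sub && !is.na(pos) && pos %in% cohort_cluster_positions,
    R7 = is_sub && cosmic_count == 1L,
    R8 = near(cosmic_cluster_positions)
  )
  tier_of <- c(R1 = 1L, R2 = 1L, R3 = 1L, R4 = 1L,
               R5 = 2L, R6 = 2L, R7 = 3L, R8 = 3L)
  fired <- names(rules)[rules]
  if (length(fired)) {
    tier <- min(tier_of[fired])
    rule <- fired[tier_of[fired] == tier][1L]  # lowest-numbered in the tier
    category <- ONCO_CATEGORIES[tier]
  } else {
    rule <- NA_character_
    category <- "UNKNOWN"
  }
  list(category = category, triggering_rule = rule,
       evidence = list(cosmic_count = cosmic_count,
                       dataset_recurrence_count = dataset_recurrence_count,
                       residue = pos, role = gene_role))
}

#' Classify all unique variants of a cohort
#'
#' Computes the cohort-level inputs (dataset recurrence across patients,
#' cohort substitution-cluster residues per gene) and classifies every unique
#' variant. Classification is independent of input order.
#'
#' @param uv An [unique_variants()] table.
#' @param recurrence Recurrence table ([read_recurrence_table()] layout).
#' @param roles Gene-role table ([read_gene_role_table()] layout); genes
#'   absent from it are `not_cancer_gene`.
#' @param config An [mfhet_config()].
#' @return A data.frame of class `mfhet_oncogenicity`, one row per distinct
#'   cohort variant key: `key, gene_symbol, variant_class, protein_change,
#'   category, triggering_rule, oncogenic` (collapsed flag), plus evidence
#'   columns; attribute `summary` holds `n_variants`, `n_oncogenic_tiered`
#'   and `fraction` (collapsed oncogenic fraction of unique variants).
#' @export
classify_variants <- function(uv, recurrence, roles, config = mfhet_config()) {
  # one row per distinct cohort variant key
  first <- !duplicated(uv$key)
  vars <- uv[first, c("key", "gene_symbol", "variant_class", "protein_change"),
             drop = FALSE]
  vars <- vars[order(vars$key), , drop = FALSE]
  rec_count <- attr(uv, "cohort_recurrence")
  role_of <- function(g) {
    i <- match(g, roles$gene)
    ifelse(is.na(i), "not_cancer_gene", roles$role[i])
  }
  cos_key <- paste(recurrence$gene, recurrence$protein_change, sep = "|")
  cos_pos_all <- protein_position(recurrence$protein_change)
  has_cluster_col <- "in_cluster" %in% names(recurrence)
  # cohort substitution residues per gene (distinct residues)
  subs <- uv[uv$variant_class %in% SUBSTITUTION_CLASSES, , drop = FALSE]
  sub_pos <- protein_position(subs$protein_change)
  cohort_clusters <- lapply(split(sub_pos, subs$gene_symbol), cluster_positions,
                            window = config$hotspot_window_aa,
                            min_n = config$cluster_min_mutations)
  n <- nrow(vars)
  category <- character(n); rule <- character(n)
  cosmic_count <- integer(n); ds_count <- integer(n)
  for (i in seq_len(n)) {
    g <- vars$gene_symbol[i]
    sel <- recurrence$gene == g
    cc <- recurrence$cosmic_confirmed_samples[sel &
            recurrence$protein_change == vars$protein_change[i]]
    cc <- if (length(cc)) cc[1L] else 0L
    rec_pos <- cos_pos_all[sel &
        recurrence$cosmic_confirmed_samples >= config$cosmic_recurrent_min]
    clu_pos <- if (has_cluster_col)
      cos_pos_all[sel & recurrence$in_cluster %in% TRUE] else integer(0)
    dsc <- as.integer(rec_count[[vars$key[i]]])
    res <- classify_variant(
      variant_class = vars$variant_class[i],
      protein_change = vars$protein_change[i],
      gene_role = role_of(g),
      cosmic_count = cc,
      cosmic_recurrent_positions = rec_pos[!is.na(rec_pos)],
      cosmic_cluster_positions = clu_pos[!is.na(clu_pos)],
      dataset_recurrence_count = dsc,
      cohort_cluster_positions = cohort_clusters[[g]] %||% integer(0),
      config = config)
    category[i] <- res$category; rule[i] <- res$triggering_rule
    cosmic_count[i] <- cc; ds_count[i] <- dsc
  }
  out <- data.frame(vars, category = category, triggering_rule = rule,
                    oncogenic = category != "UNKNOWN",
                    cosmic_count = cosmic_count,
                    dataset_recurrence = ds_count,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "summary") <- list(n_variants = n,
                               n_oncogenic_tiered = sum(out$oncogenic),
                               fraction = if (n) sum(out$oncogenic) / n else NA_real_)
  class(out) <- c("mfhet_oncogenicity", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
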