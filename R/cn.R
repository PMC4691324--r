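#' Copy-number profiles and rearrangements
#'
#' Per-lesion segmented absolute copy-number profiles (half-open
#' `[start, end)` segments with non-negative integer total copy number, plus a
#' ploidy estimate) and rearrangement breakpoint pairs (BEDPE) are compared
#' between the lesions of a patient to label events common (present in all
#' lesions) or private, and to compute a minimum-event inter-lesion
#' copy-number distance.
#'
#' @name cn_structural
NULL

RR_CLASSES <- c("deletion-type", "tandem-duplication-type", "inversion-type",
                "inter-chromosomal")

#' Construct / read a copy-number profile
#'
#' @param segments data.frame with `chrom`, `start`, `end`,
#'   `absolute_copy_number`.
#' @param lesion_id Lesion identifier.
#' @param ploidy Ploidy estimate; defaults to the length-weighted mean copy
#'   number.
#' @return A `cn_profile` object.
#' @export
cn_profile <- function(segments, lesion_id, ploidy = NULL) {
  seg <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  if (any(seg$end <= seg$start)) stop("integrity error: empty or reversed segment")
  cn <- seg$absolute_copy_number
  if (any(cn < 0) || any(cn != round(cn)))
    stop("integrity error: copy numbers must be non-negative integers")
  seg$absolute_copy_number <- as.integer(cn)
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
      stop("integrity error: overlapping segments on ", ch)
  }
  if (is.null(ploidy)) {
    w <- seg$end - seg$start
    ploidy <- sum(w * cn) / sum(w)
  }
  rownames(seg) <- NULL
  structure(list(lesion_id = lesion_id, segments = seg,
                 ploidy = as.numeric(ploidy)), class = "cn_profile")
}

#' @rdname cn_profile
#' @param path BED-like TSV with header `chrom, start, end,
#'   absolute_copy_number`.
#' @export
read_cn_profile <- function(path, lesion_id, ploidy = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "absolute_copy_number")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  cn_profile(df, lesion_id, ploidy)
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("cn_profile %s: %d segments on %d chromosomes, ploidy %.2f\n",
              x$lesion_id, nrow(x$segments), length(unique(x$segments$chrom)),
              x$ploidy))
  invisible(x)
}

#' Read a BEDPE rearrangement file
#'
#' Ten columns, no header: `chrom1 start1 end1 chrom2 start2 end2 name score
#' strand1 strand2`. Breakpoint positions are the interval starts (0-based
#' BEDPE convention; widths of 1 expected). The rearrangement class is
#' derived: different chromosomes give `inter-chromosomal`; equal strands
#' give `inversion-type`; `+/-` gives `deletion-type`; `-/+` gives
#' `tandem-duplication-type`.
#'
#' @param path BEDPE file.
#' @param lesion_id Lesion identifier.
#' @return data.frame with `lesion_id, chrom1, pos1, strand1, chrom2, pos2,
#'   strand2, rr_class, name`.
#' @export
read_bedpe <- function(path, lesion_id) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom1", "start1", "end1", "chrom2",
                                        "start2", "end2", "name", "score",
                                        "strand1", "strand2"))
  rearrangement_set(data.frame(
    lesion_id = lesion_id, chrom1 = as.character(df$chrom1), pos1 = df$start1,
    strand1 = df$strand1, chrom2 = as.character(df$chrom2), pos2 = df$start2,
    strand2 = df$strand2, name = df$name, stringsAsFactors = FALSE))
}

#' Build a validated rearrangement set
#'
#' Orders each event's two breakpoints canonically (lower chromosome/position
#' first) and derives `rr_class` from the chromosome pair and strands.
#'
#' @param df data.frame with `lesion_id, chrom1, pos1, strand1, chrom2, pos2,
#'   strand2`.
#' @return The validated data.frame with an `rr_class` column.
#' @export
rearrangement_set <- function(df) {
  if (any(df$pos1 < 0 | df$pos2 < 0)) stop("integrity error: negative position")
  if (any(!df$strand1 %in% c("+", "-")) || any(!df$strand2 %in% c("+", "-")))
    stop("integrity error: strands must be + or -")
  flip <- df$chrom1 > df$chrom2 | (df$chrom1 == df$chrom2 & df$pos1 > df$pos2)
  if (any(flip)) {
    tmp <- df[flip, c("chrom1", "pos1", "strand1")]
    df[flip, c("chrom1", "pos1", "strand1")] <- df[flip, c("chrom2", "pos2", "strand2")]
    df[flip, c("chrom2", "pos2", "strand2")] <- tmp
  }
  df$rr_class <- ifelse(df$chrom1 != df$chrom2, "inter-chromosomal",
                 ifelse(df$strand1 == df$strand2, "inversion-type",
                 ifelse(df$strand1 == "+", "deletion-type",
                        "tandem-duplication-type")))
  df
}

#' Match rearrangements across the lesions of a patient
#'
#' Two events match when they have the same class, chromosome pair and
#' strands, and both breakpoints lie within `tolerance_bp` of each other.
#' Within each lesion pair a deterministic greedy one-to-one matching is
#' taken (candidate pairs sorted by summed breakpoint distance, ties broken
#' by genomic order); matched events are clustered across lesions and a
#' cluster is *common* when it contains an event from every lesion. The
#' result is invariant under permuting lesion order.
#'
#' @param lesions List of rearrangement data.frames (one per lesion; see
#'   [rearrangement_set()]), >= 2 lesions.
#' @param tolerance_bp Breakpoint tolerance (default from [mfhet_config()]).
#' @return A list with `events` (all events with `common` flag and cluster
#'   id), `common_events`, `private_events` (split by lesion) and
#'   `fraction_common` (fraction of all events in common clusters).
#' @export
match_rearrangements <- function(lesions, tolerance_bp = 500L) {
  stopifnot(length(lesions) >= 2L)
  all_ev <- do.call(rbind, lesions)
  all_ev <- rearrangement_set(all_ev)
  n <- nrow(all_ev)
  if (n == 0L)
    return(list(events = all_ev, common_events = all_ev,
                private_events = list(), fraction_common = NA_real_))
  all_ev <- all_ev[order(all_ev$lesion_id, all_ev$chrom1, all_ev$pos1,
                         all_ev$chrom2, all_ev$pos2), , drop = FALSE]
  rownames(all_ev) <- NULL
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  lesion_ids <- sort(unique(all_ev$lesion_id))
  for (a in seq_along(lesion_ids)) for (b in seq_along(lesion_ids)) {
    if (a >= b) next
    ia <- which(all_ev$lesion_id == lesion_ids[a])
    ib <- which(all_ev$lesion_id == lesion_ids[b])
    cands <- list()
    for (i in ia) for (j in ib) {
      if (all_ev$rr_class[i] != all_ev$rr_class[j]) next
      if (all_ev$chrom1[i] != all_ev$chrom1[j] ||
          all_ev$chrom2[i] != all_ev$chrom2[j]) next
      if (all_ev$strand1[i] != all_ev$strand1[j] ||
          all_ev$strand2[i] != all_ev$strand2[j]) next
      d1 <- abs(all_ev$pos1[i] - all_ev$pos1[j])
      d2 <- abs(all_ev$pos2[i] - all_ev$pos2[j])
      if (d1 <= tolerance_bp && d2 <= tolerance_bp)
        cands[[length(cands) + 1L]] <- c(i = i, j = j, d = d1 + d2)
    }
    if (!length(cands)) next
    cm <- do.call(rbind, cands)
    cm <- cm[order(cm[, "d"], cm[, "i"], cm[, "j"]), , drop = FALSE]
    used_i <- integer(0); used_j <- integer(0)
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, "i"]; j <- cm[r, "j"]
      if (i %in% used_i || j %in% used_j) next
      used_i <- c(used_i, i); used_j <- c(used_j, j)
      union2(i, j)
    }
  }
  cluster <- vapply(seq_len(n), function(i) as.integer(find(i)), 0L)
  n_lesions <- length(lesion_ids)
  lesions_of_cluster <- tapply(all_ev$lesion_id, cluster,
                               function(l) length(unique(l)))
  all_ev$cluster <- cluster
  all_ev$common <- lesions_of_cluster[as.character(cluster)] == n_lesions
  list(events = all_ev,
       common_events = all_ev[all_ev$common, , drop = FALSE],
       private_events = split(all_ev[!all_ev$common, , drop = FALSE],
                              all_ev$lesion_id[!all_ev$common]),
       fraction_common = mean(all_ev$common))
}

# collapse a profile to maximal runs of same aberration direction
# relative to baseline = round(ploidy); returns per-chromosome runs
aberrant_runs <- function(profile) {
  base <- round(profile$ploidy)
  seg <- profile$segments
  dir <- ifelse(seg$absolute_copy_number > base, "gain",
         ifelse(seg$absolute_copy_number < base, "loss", "neutral"))
  runs <- list()
  for (ch in unique(seg$chrom)) {
    idx <- which(seg$chrom == ch)
    r <- rle(dir[idx])
    ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (k in seq_along(r$values)) {
      if (r$values[k] == "neutral") next
      i0 <- idx[starts[k]]; i1 <- idx[ends[k]]
      runs[[length(runs) + 1L]] <- data.frame(
        chrom = ch, start = seg$start[i0], end = seg$end[i1],
        direction = r$values[k], stringsAsFactors = FALSE)
    }
  }
  if (length(runs)) do.call(rbind, runs)
  else data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                  direction = character(0), stringsAsFactors = FALSE)
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Compare copy-number profiles across lesions
#'
#' An aberration is a maximal run of segments whose copy number departs from
#' the lesion's baseline (= rounded ploidy) in one direction; collapsing to
#' direction runs makes the comparison invariant to re-segmentation of the
#' same underlying profile. An aberration is *common* when every other lesion
#' carries an overlapping aberration of the same direction with reciprocal
#' overlap at least `overlap_min`. When a focal-region table is supplied, each
#' region is called `gain`, `loss` or `neutral` per lesion (direction of the
#' aberrant bases covering the region majority-wise).
#'
#' @param profiles List of `cn_profile` objects (>= 2).
#' @param focal_regions Optional data.frame `chrom, start, end, gene,
#'   expected_direction`.
#' @param overlap_min Minimum reciprocal overlap (default 0.5).
#' @return A list with `aberrations` (per lesion with `common` flag),
#'   `fraction_common`, and `focal_calls` (region x lesion status table with a
#'   `common` column) when regions were supplied.
#' @export
compare_scna <- function(profiles, focal_regions = NULL, overlap_min = 0.5) {
  stopifnot(length(profiles) >= 2L)
  runs <- lapply(profiles, aberrant_runs)
  ids <- vapply(profiles, function(p) p$lesion_id, "")
  names(runs) <- ids
  for (k in seq_along(runs))
    if (nrow(runs[[k]]))
      runs[[k]]$lesion_id <- ids[k]
  is_common <- function(r, others) {
    for (o in others) {
      hit <- FALSE
      if (nrow(o)) for (j in seq_len(nrow(o))) {
        if (o$chrom[j] != r$chrom || o$direction[j] != r$direction) next
        if (reciprocal_overlap(r$start, r$end, o$start[j], o$end[j]) >= overlap_min) {
          hit <- TRUE; break
        }
      }
      if (!hit) return(FALSE)
    }
    TRUE
  }
  all_runs <- list()
  for (k in seq_along(runs)) {
    rk <- runs[[k]]
    if (!nrow(rk)) next
    rk$common <- vapply(seq_len(nrow(rk)), function(i)
      is_common(rk[i, ], runs[-k]), TRUE)
    all_runs[[length(all_runs) + 1L]] <- rk
  }
  ab <- if (length(all_runs)) do.call(rbind, all_runs)
        else data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), direction = character(0),
                        lesion_id = character(0), common = logical(0))
  out <- list(aberrations = ab,
              fraction_common = if (nrow(ab)) mean(ab$common) else NA_real_)
  if (!is.null(focal_regions)) {
    calls <- list()
    for (i in seq_len(nrow(focal_regions))) {
      fr <- focal_regions[i, ]
      status <- vapply(seq_along(profiles), function(k) {
        rk <- runs[[k]]
        cov <- c(gain = 0, loss = 0)
        if (nrow(rk)) for (j in seq_len(nrow(rk))) {
          if (rk$chrom[j] != fr$chrom) next
          ov <- max(0, min(rk$end[j], fr$end) - max(rk$start[j], fr$start))
          cov[rk$direction[j]] <- cov[rk$direction[j]] + ov
        }
        if (sum(cov) == 0) "neutral" else names(cov)[which.max(cov)]
      }, "")
      calls[[i]] <- data.frame(gene = fr$gene, chrom = fr$chrom,
                               t(stats::setNames(status, ids)),
                               common = length(unique(status)) == 1L &&
                                 status[1L] != "neutral",
                               stringsAsFactors = FALSE)
    }
    out$focal_calls <- do.call(rbind, calls)
  }
  out
}

# intersect two profiles onto the union breakpoint grid of one chromosome
intersect_grid <- function(sa, sb) {
  bp <- sort(unique(c(sa$start, sa$end, sb$start, sb$end)))
  starts <- utils::head(bp, -1L); ends <- bp[-1L]
  copy_at <- function(seg, s) {
    i <- which(seg$start <= s & seg$end > s)
    if (length(i) != 1L) NA_integer_ else seg$absolute_copy_number[i]
  }
  a <- vapply(starts, function(s) copy_at(sa, s), 0L)
  b <- vapply(starts, function(s) copy_at(sb, s), 0L)
  if (anyNA(a) || anyNA(b))
    stop("integrity error: profiles do not cover the same territory; grids not alignable")
  list(a = a, b = b)
}

#' Minimum-event copy-number distance between two lesions
#'
#' The smallest number of events transforming one profile into the other,
#' where one event adds +1 or -1 to one contiguous run of segments on one
#' chromosome. Segments at copy number 0 are fixed: they can never be
#' amplified back nor included in any event, so they split runs. The distance
#' is computed per chromosome on the union breakpoint grid by the linear-scan
#' decomposition of the positive and negative parts of the difference profile
#' (with zero segments acting as barriers) and summed over chromosomes; on
#' small instances it equals the breadth-first-search shortest path in the
#' event graph.
#'
#' @param a,b `cn_profile` objects covering the same chromosomes and
#'   territory.
#' @return Non-negative integer count of events, or `NA` with a warning when
#'   the target is unreachable (a segment at 0 in `a` must gain copies in
#'   `b`).
#' @export
min_event_distance <- function(a, b) {
  ca <- unique(a$segments$chrom); cb <- unique(b$segments$chrom)
  if (!setequal(ca, cb))
    stop("integrity error: profiles cover different chromosomes")
  total <- 0L
  for (ch in sort(ca)) {
    g <- intersect_grid(a$segments[a$segments$chrom == ch, , drop = FALSE],
                        b$segments[b$segments$chrom == ch, , drop = FALSE])
    d <- event_distance_vec(g$a, g$b)
    if (is.na(d)) {
      warning("unreachable target on ", ch,
              ": a zero-copy segment cannot regain copies")
      return(NA_integer_)
    }
    total <- total + d
  }
  total
}

# linear-scan minimum events for one chromosome given aligned copy vectors
event_distance_vec <- function(a, b) {
  if (any(a == 0L & b > 0L)) return(NA_integer_)
  keep <- !(a == 0L & b == 0L)
  d <- b - a
  # zero segments (a == 0) are barriers: reset the carried level across them
  total <- 0L; prev_p <- 0L; prev_q <- 0L
  for (i in seq_along(a)) {
    if (a[i] == 0L) { prev_p <- 0L; prev_q <- 0L; next }
    p <- max(d[i], 0L); q <- max(-d[i], 0L)
    total <- total + max(p - prev_p, 0L) + max(q - prev_q, 0L)
    prev_p <- p; prev_q <- q
  }
  as.integer(total)
}

#' Read a focal-region table
#'
#' BED-like TSV with header `chrom, start, end, gene, expected_direction`
#' (`gain` or `loss`), naming the recurrent breast-cancer focal aberrations
#' whose status is called per lesion by [compare_scna()].
#'
#' @param path File path.
#' @return A validated data.frame.
#' @export
read_focal_regions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene", "expected_direction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("format error: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (any(!df$expected_direction %in% c("gain", "loss")))
    stop("value error: expected_direction must be gain or loss")
  df
}

#' Compare all genome-wide data of a patient set
#'
#' Convenience wrapper running [match_rearrangements()] and [compare_scna()]
#' for every patient with genome-wide inputs and averaging the common
#' fractions.
#'
#' @param rearrangements Named list (per patient) of lists of per-lesion
#'   rearrangement data.frames; may be `NULL`.
#' @param cn_profiles Named list (per patient) of lists of `cn_profile`s;
#'   may be `NULL`.
#' @param focal_regions Optional focal-region table (see [compare_scna()]).
#' @param config An [mfhet_config()].
#' @return A list with per-patient results and the mean common fractions.
#' @export
compare_lesion_genomes <- function(rearrangements = NULL, cn_profiles = NULL,
                                   focal_regions = NULL,
                                   config = mfhet_config()) {
  rr <- lapply(rearrangements, match_rearrangements,
               tolerance_bp = config$rearrangement_bp_tolerance)
  cn <- lapply(cn_profiles, compare_scna, focal_regions = focal_regions,
               overlap_min = config$scna_reciprocal_overlap_min)
  dist <- lapply(cn_profiles, function(ps) {
    n <- length(ps)
    m <- matrix(0L, n, n, dimnames = list(vapply(ps, `[[`, "", "lesion_id"),
                                          vapply(ps, `[[`, "", "lesion_id")))
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i < j) m[i, j] <- m[j, i] <-
          suppressWarnings(min_event_distance(ps[[i]], ps[[j]]))
    m
  })
  list(rearrangements = rr, scna = cn, min_event_distances = dist,
       mean_fraction_common_rearrangements =
         if (length(rr)) mean(vapply(rr, `[[`, 0, "fraction_common"), na.rm = TRUE) else NA_real_,
       mean_fraction_common_scna =
         if (length(cn)) mean(vapply(cn, `[[`, 0, "fraction_common"), na.rm = TRUE) else NA_real_)
}
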