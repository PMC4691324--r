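# Independent oracles used across the suite. These deliberately re-derive
# results by brute force (enumeration, BFS, pair counting) and never call the
# code paths they check.

# breadth-first search over the copy-number event graph: an event adds +1/-1
# to a contiguous run of segments; segments at 0 can never be part of a run
bfs_event_distance <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (any(a == 0L & b > 0L)) return(NA_integer_)
  n <- length(a)
  cap <- max(a, b) + 1L
  if (identical(a, b)) return(0L)
  runs <- list()
  for (i in seq_len(n)) for (j in i:n) runs[[length(runs) + 1L]] <- i:j
  enc <- function(x) paste(x, collapse = ",")
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(enc(a), TRUE, visited)
  frontier <- list(a)
  target <- enc(b)
  d <- 0L
  repeat {
    d <- d + 1L
    nxt <- list()
    for (x in frontier) {
      for (seg in runs) {
        if (any(x[seg] == 0L)) next
        for (s in c(1L, -1L)) {
          y <- x
          y[seg] <- y[seg] + s
          if (any(y < 0L) || any(y > cap)) next
          k <- enc(y)
          if (k == target) return(d)
          if (is.null(visited[[k]])) {
            visited[[k]] <- TRUE
            nxt[[length(nxt) + 1L]] <- y
          }
        }
      }
    }
    if (!length(nxt)) return(NA_integer_)
    frontier <- nxt
  }
}

# brute-force set-logic grouping of a complete 0/1 presence matrix
oracle_group <- function(m, lesion_of, strict = TRUE) {
  lesions <- unique(lesion_of)
  common <- apply(m, 1L, function(row)
    all(vapply(lesions, function(l) any(row[lesion_of == l] == 1L), TRUE)))
  if (!any(common)) return("HETEROGENEOUS")
  if (all(common) && (all(m == 1L) || !strict)) return("HOMOGENEOUS")
  "INTERMEDIATE"
}

# AUC by exhaustive pair counting (ties count half)
oracle_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive residue-cluster oracle: a position is clustered iff some window
# of span <= w containing it holds >= k distinct cohort positions
oracle_clustered <- function(positions, w = 3L, k = 3L) {
  u <- sort(unique(positions))
  vapply(u, function(p) {
    any(vapply((p - w):p, function(lo)
      sum(u >= lo & u <= lo + w) >= k && p >= lo && p <= lo + w, TRUE))
  }, TRUE)
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask)
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]), 0)
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (i in seq_len(n)) {
    q <- integer(n)
    q[i] <- n
    q[-i] <- p
    out[[length(out) + 1L]] <- q
  }
  out
}

# small builders -------------------------------------------------------------

make_hierarchy <- function(n_patients = 1L, lesions = 2L, samples = 1L,
                           covariates = list()) {
  pts <- lapply(seq_len(n_patients), function(i) {
    pid <- sprintf("P%d", i)
    list(patient_id = pid, covariates = covariates,
         lesions = lapply(seq_len(lesions), function(l)
           list(lesion_id = sprintf("%s_L%d", pid, l),
                samples = sprintf("%s_L%d_S%d", pid, l, seq_len(samples)))))
  })
  cohort_hierarchy(pts)
}

# one merged mutation-call row
make_call <- function(patient = "P1", sample = "P1_L1_S1", gene = "TP53",
                      chrom = "17", pos = 7578265L, ref = "C", alt = "T",
                      variant_class = "missense", protein_change = "R196*",
                      af_discovery = NA_real_, depth_discovery = NA_integer_,
                      af_validation = NA_real_, depth_validation = NA_integer_,
                      assay_ok = TRUE) {
  data.frame(patient_id = patient, sample_id = sample, gene_symbol = gene,
             chrom = chrom, pos = pos, ref_allele = ref, alt_allele = alt,
             variant_class = variant_class, protein_change = protein_change,
             af_discovery = af_discovery, depth_discovery = depth_discovery,
             af_validation = af_validation, depth_validation = depth_validation,
             assay_ok_validation = assay_ok, stringsAsFactors = FALSE)
}

make_profile <- function(copies, lesion_id = "L", chrom = "1", ploidy = 2) {
  n <- length(copies)
  cn_profile(data.frame(chrom = chrom, start = seq_len(n) - 1L,
                        end = seq_len(n), absolute_copy_number = copies),
             lesion_id, ploidy = ploidy)
}
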