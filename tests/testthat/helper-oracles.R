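# Independent oracles and tiny fixture builders used across the suite.
# Each oracle is deliberately naive (enumeration / per-base-pair scanning /
# hand-rolled BFS) and shares no code path with the implementation it checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Upper-tail hypergeometric probability by direct tail summation of
# binomial-coefficient terms (log scale for stability).
oracle_fisher_tail <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  x <- seq.int(max(0L, k - n2), min(n1, k))
  terms <- exp(lchoose(n1, x) + lchoose(n2, k - x) - lchoose(n1 + n2, k))
  sum(terms[x >= a])
}

# Per-base-pair carrier-profile segmentation: for every base in the covered
# footprint record the carrier set; regions are maximal runs of identical
# non-empty carrier sets. Works on one (chrom, type) track at a time.
oracle_segments <- function(calls) {
  out <- list()
  for (type in unique(calls$type)) {
    for (ch in unique(calls$chrom[calls$type == type])) {
      sub <- calls[calls$type == type & calls$chrom == ch, , drop = FALSE]
      lo <- min(sub$start); hi <- max(sub$end)
      profile <- lapply(lo:(hi - 1L), function(p) {
        sort(unique(sub$sample_id[sub$start <= p & p < sub$end]))
      })
      covered <- lengths(profile) > 0L
      key <- vapply(profile, paste, "", collapse = ",")
      runs <- rle(ifelse(covered, key, NA_character_))
      pos <- lo + cumsum(c(0L, runs$lengths))
      for (i in seq_along(runs$values)) {
        if (is.na(runs$values[i])) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, type = type, start = pos[i], end = pos[i + 1L],
          carriers = runs$values[i], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$type, res$chrom, res$start), , drop = FALSE]
}

# Naive O(n * m) call-vs-gene overlap check (half-open intervals).
oracle_carriers <- function(calls, genes) {
  sets <- list()
  for (j in seq_len(nrow(genes))) {
    hits <- calls$chrom == genes$chrom[j] &
      calls$start < genes$end[j] & genes$start[j] < calls$end
    sets[[genes$symbol[j]]] <- sort(unique(calls$sample_id[hits]))
  }
  sets
}

# Hand-rolled breadth-first expansion over a directed edge data.frame.
oracle_bfs <- function(edges, seeds, degree, mode = "out") {
  frontier <- seeds
  members <- seeds
  for (step in seq_len(degree)) {
    nxt <- character(0)
    for (v in frontier) {
      if (mode %in% c("out", "all")) nxt <- c(nxt, edges$target[edges$source == v])
      if (mode %in% c("in", "all")) nxt <- c(nxt, edges$source[edges$target == v])
    }
    frontier <- setdiff(unique(nxt), members)
    members <- union(members, frontier)
  }
  sort(members)
}

# Small random call table on a toy coordinate range, both CNV types.
random_toy_calls <- function(seed, n_samples = 5L, n_calls = 8L,
                             span = 400L) {
  gfinet:::with_seed(seed, {
    start <- sample.int(span, n_calls) - 1L
    len <- sample(5:80, n_calls, replace = TRUE)
    data.frame(
      sample_id = sample(sprintf("s%d", seq_len(n_samples)), n_calls,
                         replace = TRUE),
      chrom = sample(c("chr1", "chr2"), n_calls, replace = TRUE),
      start = start, end = start + len,
      type = sample(c("del", "dup"), n_calls, replace = TRUE),
      copy_number = 1L, n_snps = 10L, stringsAsFactors = FALSE)
  })
}

toy_samples <- function(ids, cohorts) {
  data.frame(sample_id = ids, cohort = cohorts, ancestry = "Europe",
             call_rate = 0.99, lrr_sd = 0.1, gcwf = 0, n_cnv = 1L,
             quality_score = seq_along(ids) / length(ids),
             stringsAsFactors = FALSE)
}

toy_interactome <- function() {
  interactome(data.frame(source = c("A", "B"), target = c("B", "C"),
                         stringsAsFactors = FALSE))
}

small_config <- function(...) {
  simulation_config(n_cases = 60L, n_controls = 60L, n_genes = 40L,
                    n_chromosomes = 2L, family_spec = c(FAM01 = 4L,
                                                        FAM02 = 2L),
                    background_carrier_rate = 0.01, qc_fail_fraction = 0.1,
                    duplicate_pairs = 1L, ...)
}
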