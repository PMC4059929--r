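#' Build copy-number variable regions (CNVRs) from call boundaries
#'
#' CNVRs are population-level regions derived from the genomic boundaries of
#' individual CNV calls. Deletions and duplications are segmented as
#' separate tracks and never merged across types. Within one (chromosome,
#' type) track:
#'
#' * `mode = "breakpoint"` (default): the union of call footprints is
#'   partitioned at every distinct call start/end into maximal disjoint
#'   segments, each segment's carrier set is the set of samples with at
#'   least one overlapping call, and adjacent segments with identical
#'   carrier sets are merged back together. This preserves carrier-frequency
#'   differences inside stacks of partially overlapping calls.
#' * `mode = "union"`: overlapping calls are simply merged into one region
#'   (interval union), the coarser alternative.
#'
#' @param calls CNV call data.frame (internal 0-based half-open
#'   coordinates, see [read_cnv_calls()]).
#' @param mode Segmentation mode, `"breakpoint"` or `"union"`.
#' @return A data.frame of class `cnvr_table`: `id, chrom, start, end, type,
#'   n_carriers` plus a list-column `carriers` of sorted sample-id vectors.
#' @examples
#' calls <- data.frame(sample_id = c("A", "B"), chrom = "chr1",
#'                     start = c(100L, 200L), end = c(300L, 400L),
#'                     type = "del", copy_number = 1L, n_snps = 10L)
#' build_cnvrs(calls)[, c("start", "end", "n_carriers")]
#' @export
build_cnvrs <- function(calls, mode = c("breakpoint", "union")) {
  mode <- match.arg(mode)
  validate_calls(calls)
  out <- list()
  for (type in c("del", "dup")) {
    sub_t <- calls[calls$type == type, , drop = FALSE]
    for (ch in sort(unique(sub_t$chrom))) {
      sub <- sub_t[sub_t$chrom == ch, , drop = FALSE]
      if (nrow(sub) == 0L) next
      # 1-based closed IRanges view of the half-open intervals
      ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
      pieces <- if (mode == "breakpoint") IRanges::disjoin(ir)
                else IRanges::reduce(ir)
      hits <- IRanges::findOverlaps(pieces, ir)
      carr <- lapply(seq_along(pieces), function(i) {
        sort(unique(sub$sample_id[S4Vectors::subjectHits(hits)[
          S4Vectors::queryHits(hits) == i]]))
      })
      seg <- data.frame(start = IRanges::start(pieces) - 1L,
                        end = IRanges::end(pieces))
      seg <- seg[order(seg$start), , drop = FALSE]
      carr <- carr[order(IRanges::start(pieces))]
      if (mode == "breakpoint" && nrow(seg) > 1L) {
        # merge adjacent segments with identical carrier sets
        grp <- cumsum(c(TRUE, vapply(2:nrow(seg), function(i) {
          !(seg$start[i] == seg$end[i - 1L] &&
              identical(carr[[i]], carr[[i - 1L]]))
        }, logical(1))))
        seg <- data.frame(
          start = tapply(seg$start, grp, min),
          end = tapply(seg$end, grp, max))
        carr <- carr[!duplicated(grp)]
      }
      out[[length(out) + 1L]] <- data.frame(
        id = sprintf("%s_%s_%d_%d", type, ch, seg$start, seg$end),
        chrom = ch, start = as.integer(seg$start), end = as.integer(seg$end),
        type = type, n_carriers = vapply(carr, length, 0L),
        stringsAsFactors = FALSE, row.names = NULL)
      out[[length(out)]]$carriers <- carr
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(id = character(0), chrom = character(0), start = integer(0),
               end = integer(0), type = character(0), n_carriers = integer(0),
               carriers = I(list()), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("cnvr_table", class(res))
  res
}

#' Case/control association at each CNVR
#'
#' Tests, at every CNVR, whether carriers concentrate in cases using the
#' one-sided (upper-tail) Fisher's exact test; annotates each region with
#' its nearest gene (interval distance 0 when overlapping) and, when exon
#' intervals are supplied, whether the region disrupts an exon of that gene.
#'
#' Cohort denominators default to the case/control counts in `samples` but
#' can be set explicitly, since published tables may use slightly different
#' post-QC totals.
#'
#' @param cnvrs A `cnvr_table` from [build_cnvrs()].
#' @param samples Sample data.frame mapping `sample_id` to `cohort`.
#' @param genes Optional gene data.frame for nearest-gene annotation.
#' @param exons Optional exon data.frame (`chrom, start, end, symbol`).
#' @param n_case,n_control Cohort denominators; default from `samples`.
#' @return A data.frame of class `cnv_assoc`: `id, chrom, start, end, type,
#'   a, c, p, or, nearest_gene, exonic`, where `a`/`c` are case/control
#'   carrier counts. Cohort sizes are attached as attributes.
#' @export
associate_cnvrs <- function(cnvrs, samples, genes = NULL, exons = NULL,
                            n_case = NULL, n_control = NULL) {
  check_columns(samples, c("sample_id", "cohort"), "sample table")
  cases <- samples$sample_id[samples$cohort == "case"]
  ctrls <- samples$sample_id[samples$cohort == "control"]
  if (is.null(n_case)) n_case <- length(cases)
  if (is.null(n_control)) n_control <- length(ctrls)
  check_that(n_case > 0 && n_control > 0, "both cohorts must be non-empty")
  unresolved <- setdiff(unique(unlist(cnvrs$carriers)), samples$sample_id)
  check_that(length(unresolved) == 0L, "carrier id(s) not in sample table: %s",
             paste(utils::head(unresolved, 3L), collapse = ", "))
  a <- vapply(cnvrs$carriers, function(s) sum(s %in% cases), 0L)
  cc <- vapply(cnvrs$carriers, function(s) sum(s %in% ctrls), 0L)
  ft <- fisher_one_sided(a, n_case - a, cc, n_control - cc)
  res <- data.frame(id = cnvrs$id, chrom = cnvrs$chrom, start = cnvrs$start,
                    end = cnvrs$end, type = cnvrs$type, a = a, c = cc,
                    p = ft$p_one_sided, or = ft$odds_ratio,
                    nearest_gene = NA_character_, exonic = NA,
                    stringsAsFactors = FALSE)
  if (!is.null(genes) && nrow(res) > 0L) {
    for (i in seq_len(nrow(res))) {
      g <- genes[genes$chrom == res$chrom[i], , drop = FALSE]
      if (nrow(g) == 0L) next
      # half-open interval distance: 0 when overlapping
      dist <- pmax(0L, pmax(g$start - res$end[i], res$start[i] - g$end))
      j <- which.min(dist)
      res$nearest_gene[i] <- g$symbol[j]
      if (!is.null(exons)) {
        ex <- exons[exons$symbol == g$symbol[j] &
                      exons$chrom == res$chrom[i], , drop = FALSE]
        res$exonic[i] <- any(ex$start < res$end[i] & res$start[i] < ex$end)
      }
    }
  }
  attr(res, "n_case") <- n_case
  attr(res, "n_control") <- n_control
  class(res) <- c("cnv_assoc", class(res))
  res
}

#' Discovery-replication filtering of CNVR associations
#'
#' Implements the two-stage design: regions significant in the discovery
#' cohort (p <= `p_disc`) are retained when an overlapping region of the
#' same CNV type is significant in the replication cohort (p <= `p_repl`)
#' with the same direction of enrichment (both case-enriched, odds ratio
#' > 1). Retained regions are annotated with pooled-count Fisher statistics
#' across both cohorts.
#'
#' @param disc,repl `cnv_assoc` tables from [associate_cnvrs()].
#' @param p_disc,p_repl Significance thresholds; defaults 1e-4 and 1e-3.
#' @return A data.frame with discovery coordinates, per-cohort statistics
#'   and pooled `a, c, p, or`. Empty (zero rows) when no region replicates.
#' @export
discovery_replication <- function(disc, repl, p_disc = 1e-4, p_repl = 1e-3) {
  stopifnot(inherits(disc, "cnv_assoc"), inherits(repl, "cnv_assoc"))
  cand <- disc[disc$p <= p_disc & disc$or > 1, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    m <- repl[repl$type == cand$type[i] & repl$chrom == cand$chrom[i] &
                repl$start < cand$end[i] & cand$start[i] < repl$end, ,
              drop = FALSE]
    m <- m[m$p <= p_repl & m$or > 1, , drop = FALSE]
    if (nrow(m) == 0L) next
    m <- m[which.min(m$p), , drop = FALSE]
    a_pool <- cand$a[i] + m$a
    c_pool <- cand$c[i] + m$c
    n_case <- attr(disc, "n_case") + attr(repl, "n_case")
    n_ctrl <- attr(disc, "n_control") + attr(repl, "n_control")
    ft <- fisher_one_sided(a_pool, n_case - a_pool, c_pool, n_ctrl - c_pool)
    rows[[length(rows) + 1L]] <- data.frame(
      id = cand$id[i], chrom = cand$chrom[i], start = cand$start[i],
      end = cand$end[i], type = cand$type[i],
      nearest_gene = cand$nearest_gene[i],
      p_disc = cand$p[i], or_disc = cand$or[i],
      p_repl = m$p, or_repl = m$or,
      a_pooled = a_pool, c_pooled = c_pool,
      p_pooled = ft$p_one_sided, or_pooled = ft$odds_ratio,
      stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame(
    id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), type = character(0), nearest_gene = character(0),
    p_disc = numeric(0), or_disc = numeric(0), p_repl = numeric(0),
    or_repl = numeric(0), a_pooled = integer(0), c_pooled = integer(0),
    p_pooled = numeric(0), or_pooled = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Genome-wide CNV burden permutation test
#'
#' Per-sample CNV burden is the total span of that sample's calls in
#' kilobases (0 for call-free samples); the test statistic is the absolute
#' difference of cohort mean burdens, assessed against `n_perm` random
#' case/control label permutations with the plus-one estimator
#' \eqn{(r + 1)/(n_{perm} + 1)}. Permutations are generated from
#' per-iteration seeds derived from `seed` by a counter scheme, so the
#' result does not depend on evaluation order.
#'
#' @param calls CNV call data.frame.
#' @param samples Sample data.frame (needs >= 1 case and >= 1 control).
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed.
#' @return An object of class `burden_test`: list with `mean_case_kb`,
#'   `mean_control_kb`, `difference_kb`, `p_perm`, `n_perm`.
#' @export
burden_test <- function(calls, samples, n_perm = 10000L, seed = 1L) {
  check_that(n_perm >= 1, "n_perm must be >= 1")
  check_columns(samples, c("sample_id", "cohort"), "sample table")
  is_case <- samples$cohort == "case"
  check_that(any(is_case) && any(!is_case),
             "need at least one case and one control")
  span_kb <- (calls$end - calls$start) / 1000
  burden <- stats::setNames(numeric(nrow(samples)), samples$sample_id)
  if (nrow(calls) > 0L) {
    per_sample <- rowsum(span_kb, calls$sample_id)
    burden[rownames(per_sample)] <- per_sample[, 1L]
  }
  obs_case <- mean(burden[is_case])
  obs_ctrl <- mean(burden[!is_case])
  obs <- abs(obs_case - obs_ctrl)
  n <- length(burden)
  k <- sum(is_case)
  r <- 0L
  for (i in seq_len(n_perm)) {
    idx <- with_seed(derive_seed(seed, paste0("perm", i)),
                     sample.int(n, k))
    perm_case <- mean(burden[idx])
    perm_ctrl <- (sum(burden) - sum(burden[idx])) / (n - k)
    if (abs(perm_case - perm_ctrl) >= obs) r <- r + 1L
  }
  structure(list(mean_case_kb = obs_case, mean_control_kb = obs_ctrl,
                 difference_kb = obs_case - obs_ctrl,
                 p_perm = (r + 1) / (n_perm + 1), n_perm = n_perm),
            class = "burden_test")
}

#' @export
print.burden_test <- function(x, ...) {
  cat(sprintf("CNV burden: cases %.1f kb, controls %.1f kb (diff %+.1f kb)\n",
              x$mean_case_kb, x$mean_control_kb, x$difference_kb))
  cat(sprintf("  label-permutation p = %.4g (%d permutations)\n",
              x$p_perm, x$n_perm))
  invisible(x)
}

#' @export
print.cnv_assoc <- function(x, ...) {
  cat(sprintf("CNVR association: %d regions, cohorts %d cases / %d controls\n",
              nrow(x), attr(x, "n_case"), attr(x, "n_control")))
  print.data.frame(utils::head(x[order(x$p), ], 10L), digits = 3)
  invisible(x)
}
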