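#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every parameter of the synthetic genome, interactome
#' and case/control CNV cohort. The defaults describe the reference
#' simulation used throughout the package's tests: 500 cases and 500
#' controls, 200 genes on 5 chromosomes, a sparse directed interactome
#' (mean out-degree 2), rare background CNV carriage (0.2% per gene per
#' sample) and an 8-fold carrier-rate excess planted, in cases only, on the
#' second-degree network of one 10-member gene family (`FAM01`).
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param n_genes Number of genes in the synthetic genome.
#' @param n_chromosomes Number of chromosomes the genes are laid on.
#' @param gene_length_bp Mean gene length in base pairs.
#' @param chromosome_length_bp Length of each synthetic chromosome; the
#'   generated gene footprint must fit inside it.
#' @param family_spec Named integer vector: family root symbol -> member
#'   count (each >= 2). Members are named `root1, root2, ...`.
#' @param mean_out_degree Mean directed out-degree of the interactome.
#' @param background_carrier_rate Per-gene per-sample probability of
#'   harbouring a CNV overlapping that gene, in [0, 1].
#' @param case_burden_multiplier Genome-wide carrier-rate multiplier applied
#'   to cases (>= 1); models an overall excess CNV burden.
#' @param effect_target Family root or single gene symbol receiving the
#'   planted effect, or `NULL` for none.
#' @param effect_multiplier Carrier-rate multiplier applied, in cases only,
#'   to every gene of the effect target's expanded network (>= 1).
#' @param fraction_del Proportion of calls that are deletions.
#' @param qc_fail_fraction Proportion of samples given failing QC metrics.
#' @param duplicate_pairs Number of near-identical sample pairs to inject.
#' @param n_interactome_sources 1 (default) or 3; with 3 sources ~20% of
#'   edges are duplicated across two sources to exercise merging.
#' @param seed Master RNG seed.
#' @return A validated list of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(n_cases = 50, n_controls = 50, n_genes = 40,
#'                          family_spec = c(FAM01 = 4), seed = 7)
#' @export
simulation_config <- function(n_cases = 500L,
                              n_controls = 500L,
                              n_genes = 200L,
                              n_chromosomes = 5L,
                              gene_length_bp = 20000,
                              chromosome_length_bp = 5e6,
                              family_spec = default_family_spec(),
                              mean_out_degree = 2,
                              background_carrier_rate = 0.002,
                              case_burden_multiplier = 1,
                              effect_target = "FAM01",
                              effect_multiplier = 8,
                              fraction_del = 0.5,
                              qc_fail_fraction = 0.05,
                              duplicate_pairs = 2L,
                              n_interactome_sources = 1L,
                              seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_genes = as.integer(n_genes), n_chromosomes = as.integer(n_chromosomes),
    gene_length_bp = gene_length_bp,
    chromosome_length_bp = chromosome_length_bp,
    family_spec = family_spec,
    mean_out_degree = mean_out_degree,
    background_carrier_rate = background_carrier_rate,
    case_burden_multiplier = case_burden_multiplier,
    effect_target = effect_target,
    effect_multiplier = effect_multiplier,
    fraction_del = fraction_del,
    qc_fail_fraction = qc_fail_fraction,
    duplicate_pairs = as.integer(duplicate_pairs),
    n_interactome_sources = as.integer(n_interactome_sources),
    seed = as.integer(seed)
  )
  counts <- c(cfg$n_cases, cfg$n_controls, cfg$n_genes, cfg$n_chromosomes)
  check_that(all(counts > 0L), "cohort, gene and chromosome counts must be > 0")
  check_that(cfg$gene_length_bp > 0 && cfg$chromosome_length_bp > 0,
             "lengths must be positive")
  probs <- c(cfg$background_carrier_rate, cfg$fraction_del,
             cfg$qc_fail_fraction)
  check_that(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  check_that(cfg$case_burden_multiplier >= 1 && cfg$effect_multiplier >= 1,
             "rate multipliers must be >= 1")
  check_that(cfg$mean_out_degree >= 0, "mean_out_degree must be >= 0")
  check_that(cfg$duplicate_pairs >= 0L, "duplicate_pairs must be >= 0")
  check_that(cfg$n_interactome_sources %in% c(1L, 3L),
             "n_interactome_sources must be 1 or 3")
  if (length(cfg$family_spec)) {
    check_that(!is.null(names(cfg$family_spec)) &&
                 all(nzchar(names(cfg$family_spec))),
               "family_spec must be a named vector of member counts")
    check_that(all(cfg$family_spec >= 2), "family member counts must be >= 2")
    check_that(sum(cfg$family_spec) <= cfg$n_genes,
               "family members (%d) exceed n_genes (%d)",
               sum(cfg$family_spec), cfg$n_genes)
  }
  class(cfg) <- "simulation_config"
  cfg
}

# Reference family catalogue: one 10-member target family plus 19 background
# families of mixed size, so family-level null calibration has material.
default_family_spec <- function() {
  sizes <- c(10L, rep(c(2L, 3L, 4L, 5L, 6L, 8L), length.out = 19L))
  stats::setNames(sizes, sprintf("FAM%02d", seq_along(sizes)))
}

#' Generate a synthetic genome with gene families
#'
#' Lays non-overlapping gene intervals across `n_chromosomes` chromosomes
#' (round-robin), with gamma-distributed lengths around `gene_length_bp` and
#' exponential intergenic gaps. Family members are named `root` followed by a
#' 1-based index (`GRM1 ... GRM8` style) and assigned to random gene slots;
#' the remaining genes get neutral `GENE####` symbols.
#'
#' @param config A [simulation_config()].
#' @return A list with `genes` (data.frame: chrom, start, end, symbol,
#'   strand; 0-based half-open) and `families` (data.frame: root, member).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, "genome"), {
    n <- config$n_genes
    chroms <- sprintf("chr%d", rep_len(seq_len(config$n_chromosomes), n))
    lens <- pmax(500, round(stats::rgamma(n, shape = 4,
                                          rate = 4 / config$gene_length_bp)))
    # intergenic gaps are kept >= 2 mean gene lengths so that call flanks
    # (at most one gene length) only rarely reach a neighbouring gene
    gaps <- round(2 * config$gene_length_bp +
                    stats::rexp(n, rate = 1 / config$gene_length_bp))
    start <- integer(n); end <- integer(n)
    for (ch in unique(chroms)) {
      idx <- which(chroms == ch)
      pos <- cumsum(gaps[idx] + lens[idx])
      end[idx] <- pos
      start[idx] <- pos - lens[idx]
      if (max(pos) > config$chromosome_length_bp) {
        stop(sprintf(
          "gene footprint (%d bp) exceeds chromosome length (%g bp) on %s",
          max(pos), config$chromosome_length_bp, ch), call. = FALSE)
      }
    }
    fam_roots <- rep(names(config$family_spec), config$family_spec)
    fam_members <- unlist(lapply(config$family_spec, seq_len), use.names = FALSE)
    fam_symbols <- paste0(fam_roots, fam_members)
    n_free <- n - length(fam_symbols)
    symbols <- character(n)
    slots <- sample.int(n) # random placement of family members among slots
    symbols[slots[seq_along(fam_symbols)]] <- fam_symbols
    if (n_free > 0) {
      symbols[slots[length(fam_symbols) + seq_len(n_free)]] <-
        sprintf("GENE%04d", seq_len(n_free))
    }
    genes <- data.frame(chrom = chroms, start = start, end = end,
                        symbol = symbols, strand = "+",
                        stringsAsFactors = FALSE)
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    families <- data.frame(root = fam_roots, member = fam_symbols,
                           stringsAsFactors = FALSE)
    list(genes = genes, families = families)
  })
}

#' Generate a synthetic directed interactome
#'
#' Each gene receives a Poisson(`mean_out_degree`) number of outgoing edges
#' to distinct other genes; no self-loops. With
#' `n_interactome_sources = 3`, edges are split across three source labels
#' and roughly 20% are duplicated into a second source, so downstream
#' merging is exercised.
#'
#' @param genes Gene models from [make_genome()].
#' @param config A [simulation_config()].
#' @return An [interactome()] object.
#' @export
make_interactome <- function(genes, config) {
  stopifnot(inherits(config, "simulation_config"))
  symbols <- genes$symbol
  check_that(length(symbols) >= 2, "an interactome needs at least 2 genes")
  check_that(config$mean_out_degree < length(symbols),
             "mean_out_degree (%g) must be smaller than the gene count (%d)",
             config$mean_out_degree, length(symbols))
  with_seed(derive_seed(config$seed, "interactome"), {
    deg <- pmin(stats::rpois(length(symbols), config$mean_out_degree),
                length(symbols) - 1L)
    src <- rep(symbols, deg)
    tgt <- unlist(lapply(seq_along(symbols), function(i) {
      if (deg[i] == 0L) return(character(0))
      sample(symbols[-i], deg[i])
    }), use.names = FALSE)
    if (length(src) == 0L) {
      edges <- data.frame(source = character(0), target = character(0),
                          dataset = character(0), stringsAsFactors = FALSE)
      return(interactome(edges, all_symbols = symbols))
    }
    if (config$n_interactome_sources == 3L) {
      ds <- sample(c("S1", "S2", "S3"), length(src), replace = TRUE)
      dup <- which(stats::runif(length(src)) < 0.2)
      ds2 <- vapply(ds[dup], function(s) sample(setdiff(c("S1", "S2", "S3"), s), 1L), "")
      edges <- data.frame(
        source = c(src, src[dup]), target = c(tgt, tgt[dup]),
        dataset = c(ds, ds2), stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(source = src, target = tgt, dataset = "S1",
                          stringsAsFactors = FALSE)
    }
    interactome(edges, all_symbols = symbols)
  })
}

#' Simulate a case/control CNV cohort with planted structure
#'
#' Draws, for every (sample, gene) pair, whether the sample carries a CNV
#' overlapping that gene. Control genes carry at the background rate; case
#' rates are `background * case_burden_multiplier`, further multiplied by
#' `effect_multiplier` on the expanded (second-degree, outgoing) network of
#' `effect_target`. Each carrier event becomes a del/dup call covering the
#' gene with random flanks of up to one gene length, clipped to the
#' chromosome. QC metrics are drawn inside the standard thresholds except
#' for exactly `ceiling(qc_fail_fraction * n)` samples, which each violate at
#' least one threshold. `duplicate_pairs` near-identical pairs get IBS drawn
#' on [0.9, 1]; background pairs on [0.6, 0.85].
#'
#' @param genes,families Output of [make_genome()].
#' @param inter An [interactome()] (used to expand the effect target).
#' @param config A [simulation_config()].
#' @return A list with `samples`, `calls`, `ibs_pairs` data.frames and
#'   `truth`, a list recording the planted structure: `target_network_genes`,
#'   `per_gene_case_rate`, `per_gene_control_rate`,
#'   `injected_duplicate_pairs`, `injected_qc_failures`.
#' @export
simulate_cohort <- function(genes, families, inter, config) {
  stopifnot(inherits(config, "simulation_config"))
  symbols <- genes$symbol
  target_genes <- character(0)
  if (!is.null(config$effect_target)) {
    tgt <- config$effect_target
    if (tgt %in% families$root) {
      seeds <- families$member[families$root == tgt]
    } else if (tgt %in% symbols) {
      seeds <- tgt
    } else {
      stop(sprintf("effect_target '%s' names no generated family or gene", tgt),
           call. = FALSE)
    }
    net <- expand_network(inter, seeds, degree = 2L, direction = "out")
    target_genes <- intersect(net$members, symbols)
  }

  base <- config$background_carrier_rate
  ctrl_rate <- stats::setNames(rep(base, length(symbols)), symbols)
  case_rate <- ctrl_rate * config$case_burden_multiplier
  case_rate[target_genes] <- case_rate[target_genes] * config$effect_multiplier
  case_rate <- pmin(case_rate, 1)

  n_case <- config$n_cases; n_ctrl <- config$n_controls
  n <- n_case + n_ctrl
  sample_id <- c(sprintf("case%04d", seq_len(n_case)),
                 sprintf("ctrl%04d", seq_len(n_ctrl)))
  cohort <- rep(c("case", "control"), c(n_case, n_ctrl))

  with_seed(derive_seed(config$seed, "cohort"), {
    # carrier draws, one gene at a time
    chrom_of <- stats::setNames(genes$chrom, symbols)
    gs <- stats::setNames(genes$start, symbols)
    ge <- stats::setNames(genes$end, symbols)
    call_rows <- vector("list", length(symbols))
    for (j in seq_along(symbols)) {
      g <- symbols[j]
      hit <- c(stats::rbinom(n_case, 1L, case_rate[g]),
               stats::rbinom(n_ctrl, 1L, ctrl_rate[g])) == 1L
      k <- sum(hit)
      if (k == 0L) next
      len <- ge[g] - gs[g]
      lf <- floor(stats::runif(k, 0, len))
      rf <- floor(stats::runif(k, 0, len))
      start <- pmax(0, gs[[g]] - lf)
      end <- pmin(config$chromosome_length_bp, ge[[g]] + rf)
      is_del <- stats::runif(k) < config$fraction_del
      cn <- ifelse(is_del, sample(0:1, k, replace = TRUE),
                   sample(3:4, k, replace = TRUE))
      call_rows[[j]] <- data.frame(
        sample_id = sample_id[hit], chrom = chrom_of[[g]],
        start = as.integer(start), end = as.integer(end),
        type = ifelse(is_del, "del", "dup"), copy_number = as.integer(cn),
        n_snps = 3L + stats::rpois(k, (end - start) / 5000),
        stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, call_rows)
    if (is.null(calls)) {
      calls <- data.frame(sample_id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          type = character(0), copy_number = integer(0),
                          n_snps = integer(0), stringsAsFactors = FALSE)
    }
    calls <- calls[order(calls$sample_id, calls$chrom, calls$start), ,
                   drop = FALSE]
    rownames(calls) <- NULL

    n_calls <- table(factor(calls$sample_id, levels = sample_id))
    samples <- data.frame(
      sample_id = sample_id, cohort = cohort,
      ancestry = sample(c("Europe", "Africa", "America"), n, replace = TRUE,
                        prob = c(0.7, 0.15, 0.15)),
      call_rate = stats::runif(n, 0.955, 0.999),
      lrr_sd = stats::runif(n, 0.05, 0.28),
      gcwf = stats::runif(n, -0.018, 0.018),
      n_cnv = as.integer(n_calls),
      quality_score = stats::runif(n),
      stringsAsFactors = FALSE)

    # forced QC failures: each violates at least one threshold
    n_fail <- ceiling(config$qc_fail_fraction * n)
    fail_idx <- if (n_fail > 0) sample.int(n, n_fail) else integer(0)
    for (i in fail_idx) {
      mode <- sample(1:3, 1L)
      if (mode == 1L) samples$call_rate[i] <- stats::runif(1, 0.80, 0.9499)
      if (mode == 2L) samples$lrr_sd[i] <- stats::runif(1, 0.31, 0.5)
      if (mode == 3L) samples$gcwf[i] <- sample(c(-1, 1), 1L) *
          stats::runif(1, 0.021, 0.05)
    }

    # IBS pairs: injected duplicates high, background pairs low
    n_dup <- config$duplicate_pairs
    dup_ids <- if (n_dup > 0) sample_id[sample.int(n, 2L * n_dup)] else character(0)
    dup_pairs <- if (n_dup > 0) {
      data.frame(id_a = dup_ids[seq_len(n_dup) * 2L - 1L],
                 id_b = dup_ids[seq_len(n_dup) * 2L],
                 ibs = stats::runif(n_dup, 0.9, 1.0),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id_a = character(0), id_b = character(0), ibs = numeric(0),
                 stringsAsFactors = FALSE)
    }
    n_bg <- min(5L * n, n * (n - 1L) / 2)
    ia <- sample.int(n, n_bg, replace = TRUE)
    ib <- sample.int(n - 1L, n_bg, replace = TRUE)
    ib <- ifelse(ib >= ia, ib + 1L, ib)
    bg <- data.frame(id_a = sample_id[pmin(ia, ib)],
                     id_b = sample_id[pmax(ia, ib)],
                     ibs = stats::runif(n_bg, 0.6, 0.85),
                     stringsAsFactors = FALSE)
    bg <- bg[!duplicated(paste(bg$id_a, bg$id_b)), , drop = FALSE]
    drop_bg <- paste(bg$id_a, bg$id_b) %in%
      c(paste(dup_pairs$id_a, dup_pairs$id_b),
        paste(dup_pairs$id_b, dup_pairs$id_a))
    ibs_pairs <- rbind(dup_pairs, bg[!drop_bg, , drop = FALSE])
    rownames(ibs_pairs) <- NULL

    truth <- list(
      target_network_genes = target_genes,
      per_gene_case_rate = case_rate,
      per_gene_control_rate = ctrl_rate,
      injected_duplicate_pairs = dup_pairs[, c("id_a", "id_b")],
      injected_qc_failures = samples$sample_id[fail_idx])
    list(samples = samples, calls = calls, ibs_pairs = ibs_pairs,
         truth = truth)
  })
}

#' Synthetic ancestry eigenvector fixture
#'
#' Emulates the supervised ancestry-classification setting without genotypes:
#' each continental label is an isotropic Gaussian cluster in `dim`
#' dimensions, with centroids placed `separation` apart along distinct axes.
#' Half the points per cluster are labelled (training), half unlabelled.
#'
#' @param n_train,n_test Labelled / unlabelled points per cluster.
#' @param labels Cluster labels.
#' @param separation Distance between cluster centroids.
#' @param sigma Within-cluster standard deviation.
#' @param dim Feature dimension (default 10, the first 10 eigenvectors).
#' @param seed RNG seed.
#' @return A list with `features` (data.frame: sample_id, ev1..evD, label,
#'   NA for test points) and `truth` (data.frame: sample_id, label for the
#'   unlabelled points).
#' @export
ancestry_fixture <- function(n_train = 50L, n_test = 50L,
                             labels = c("Africa", "America", "Europe"),
                             separation = 1, sigma = 0.01, dim = 10L,
                             seed = 1L) {
  check_that(dim >= length(labels), "dim must be >= number of labels")
  with_seed(seed, {
    centroids <- diag(separation, nrow = length(labels), ncol = dim)
    rows <- list(); truth <- list()
    for (i in seq_along(labels)) {
      m <- n_train + n_test
      pts <- matrix(stats::rnorm(m * dim, sd = sigma), m, dim, byrow = TRUE)
      pts <- sweep(pts, 2L, centroids[i, ], `+`)
      ids <- sprintf("%s_%03d", tolower(labels[i]), seq_len(m))
      lab <- c(rep(labels[i], n_train), rep(NA_character_, n_test))
      df <- data.frame(sample_id = ids, pts, label = lab,
                       stringsAsFactors = FALSE)
      names(df)[1 + seq_len(dim)] <- sprintf("ev%d", seq_len(dim))
      rows[[i]] <- df
      truth[[i]] <- data.frame(sample_id = ids[(n_train + 1):m],
                               label = labels[i], stringsAsFactors = FALSE)
    }
    list(features = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Print a simulation configuration
#' @param x A `simulation_config`.
#' @param ... Ignored.
#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort config: %d cases / %d controls, %d genes on %d chromosomes\n",
    x$n_cases, x$n_controls, x$n_genes, x$n_chromosomes))
  cat(sprintf("  background carrier rate %g, burden multiplier %g\n",
              x$background_carrier_rate, x$case_burden_multiplier))
  if (!is.null(x$effect_target)) {
    cat(sprintf("  planted effect: x%g on network of %s\n",
                x$effect_multiplier, x$effect_target))
  }
  cat(sprintf("  %d families, mean out-degree %g, seed %d\n",
              length(x$family_spec), x$mean_out_degree, x$seed))
  invisible(x)
}
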