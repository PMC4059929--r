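#' Construct an interactome from a directed edge table
#'
#' Normalises an edge data.frame (`source, target[, dataset]`) into the
#' package's interactome container: symbols are upper-cased, self-loops are
#' dropped (with a message reporting how many), and duplicate
#' (source, target) pairs are merged with their dataset ids concatenated.
#'
#' @param edges Data.frame with columns `source`, `target` and optionally
#'   `dataset` (defaults to `"S1"`).
#' @param all_symbols Optional character vector of additional vertex symbols
#'   to register even when they appear in no edge.
#' @return An object of class `interactome`: list with `edges` (merged edge
#'   data.frame with a `datasets` column), `symbols`, `graph` (directed
#'   igraph) and `n_self_dropped`.
#' @seealso [load_interactome()] to build one from files,
#'   [expand_network()] to grow gene networks on it.
#' @export
interactome <- function(edges, all_symbols = NULL) {
  check_columns(edges, c("source", "target"), "edge table")
  if (!"dataset" %in% names(edges)) edges$dataset <- "S1"
  edges$source <- toupper(as.character(edges$source))
  edges$target <- toupper(as.character(edges$target))
  self <- edges$source == edges$target
  if (any(self)) {
    message(sprintf("interactome: dropped %d self-loop(s)", sum(self)))
  }
  edges <- edges[!self, , drop = FALSE]
  key <- paste(edges$source, edges$target, sep = "\r")
  datasets <- vapply(split(edges$dataset, key), function(d) {
    paste(sort(unique(d)), collapse = ";")
  }, "")
  uniq <- edges[!duplicated(key), c("source", "target"), drop = FALSE]
  uniq$datasets <- datasets[paste(uniq$source, uniq$target, sep = "\r")]
  uniq <- uniq[order(uniq$source, uniq$target), , drop = FALSE]
  rownames(uniq) <- NULL
  symbols <- sort(unique(c(uniq$source, uniq$target,
                           toupper(as.character(all_symbols)))))
  graph <- igraph::graph_from_data_frame(uniq[, c("source", "target")],
                                         directed = TRUE,
                                         vertices = symbols)
  structure(list(edges = uniq, symbols = symbols, graph = graph,
                 n_self_dropped = sum(self)),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("Directed interactome: %d symbols, %d merged edges",
              length(x$symbols), nrow(x$edges)))
  if (x$n_self_dropped > 0) {
    cat(sprintf(" (%d self-loops dropped)", x$n_self_dropped))
  }
  cat("\n")
  invisible(x)
}

#' Load and merge interactome edge-list files
#'
#' Reads one or more headerless TSV edge lists (2 columns `source, target`
#' or 3 columns `source, target, dataset`; 2-column files use the file's
#' base name as dataset id) and merges them into a single [interactome()]:
#' union of edges, duplicate (source, target) pairs collapsed with dataset
#' ids concatenated, self-loops dropped with a reported count.
#'
#' @param paths Character vector of file paths.
#' @return An `interactome` object.
#' @export
load_interactome <- function(paths) {
  check_that(length(paths) >= 1L, "at least one edge file is required")
  parts <- lapply(paths, function(p) {
    check_that(file.exists(p), "edge file not found: %s", p)
    lines <- readLines(p)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < 2L | nf > 3L)
    if (length(bad)) {
      stop(sprintf("malformed edge line at %s:%d (need 2 or 3 columns)",
                   p, bad[1L]), call. = FALSE)
    }
    data.frame(
      source = vapply(fields, `[[`, "", 1L),
      target = vapply(fields, `[[`, "", 2L),
      dataset = vapply(fields, function(f) {
        if (length(f) >= 3L) f[[3L]] else sub("\\.[^.]*$", "", basename(p))
      }, ""),
      stringsAsFactors = FALSE)
  })
  interactome(do.call(rbind, parts))
}

#' Define gene families from a membership table or by symbol derivation
#'
#' In table mode (`derive = FALSE`), `x` is a data.frame (or 2-column TSV
#' path) with `root, member` rows; families with at least two distinct
#' members are retained. In derive mode, `x` is a character vector of gene
#' symbols, each symbol's family root is obtained by stripping its trailing
#' run of digits (`GRM1 -> GRM`), and roots claiming at least two symbols
#' become families; singleton roots are discarded. This mirrors how
#' nomenclature-root gene families are formed from official gene symbols.
#'
#' @param x Family table, TSV path, or (with `derive = TRUE`) symbol vector.
#' @param derive Derive families from symbol roots instead of a table.
#' @return Data.frame `root, member` containing only families with >= 2
#'   members; a warning is raised (and an empty table returned) when none
#'   remain.
#' @examples
#' define_families(c("GRM1", "GRM5", "CALM1"), derive = TRUE)
#' @export
define_families <- function(x, derive = FALSE) {
  if (derive) {
    syms <- unique(toupper(as.character(x)))
    root <- sub("[0-9]+$", "", syms)
    keep <- nzchar(root)
    fam <- data.frame(root = root[keep], member = syms[keep],
                      stringsAsFactors = FALSE)
  } else {
    fam <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
      read_families(x)
    } else {
      x
    }
    check_columns(fam, c("root", "member"), "gene family table")
    fam <- unique(fam[, c("root", "member")])
  }
  sizes <- table(fam$root)
  fam <- fam[fam$root %in% names(sizes)[sizes >= 2L], , drop = FALSE]
  fam <- fam[order(fam$root, fam$member), , drop = FALSE]
  rownames(fam) <- NULL
  if (nrow(fam) == 0L) warning("no gene family with >= 2 members")
  fam
}

#' Expand a gene network from seed genes
#'
#' Breadth-first expansion from the seed symbols along interactome edges:
#' `degree = 1` adds direct interaction partners, `degree = 2` additionally
#' adds their partners (the second-degree network). Traversal follows
#' outgoing edges by default; seeds absent from the interactome contribute
#' only themselves.
#'
#' @param inter An [interactome()].
#' @param seeds Non-empty character vector of seed gene symbols.
#' @param degree Expansion depth, 1 or 2.
#' @param direction Edge direction to follow: `"out"` (default), `"in"`, or
#'   `"all"` to ignore direction.
#' @return An object of class `gene_network`: list with `seed_set`,
#'   `degree`, `members` (seeds plus all reached symbols).
#' @examples
#' toy <- interactome(data.frame(source = c("A", "B"), target = c("B", "C")))
#' expand_network(toy, "A", degree = 2)$members
#' @export
expand_network <- function(inter, seeds, degree = 2L,
                           direction = c("out", "in", "all")) {
  stopifnot(inherits(inter, "interactome"))
  direction <- match.arg(direction)
  seeds <- unique(toupper(as.character(seeds)))
  check_that(length(seeds) >= 1L, "seeds must be non-empty")
  check_that(degree %in% c(1L, 2L), "degree must be 1 or 2")
  present <- intersect(seeds, inter$symbols)
  members <- seeds
  if (length(present)) {
    nb <- igraph::ego(inter$graph, order = degree, nodes = present,
                      mode = direction)
    members <- unique(c(seeds, unlist(lapply(nb, names), use.names = FALSE)))
  }
  structure(list(seed_set = seeds, degree = as.integer(degree),
                 members = sort(members)),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Gene network: %d seed(s), degree %d, %d members\n",
              length(x$seed_set), x$degree, length(x$members)))
  invisible(x)
}

#' Map CNV calls onto genes as per-gene carrier sets
#'
#' A sample carries a gene when at least one of its CNV calls overlaps the
#' gene interval by >= 1 bp (half-open intersection); deletions and
#' duplications both count. With `exons` supplied and `exonic = TRUE`,
#' overlap is instead required with an exon of the gene.
#'
#' @param calls CNV call data.frame (internal coordinates).
#' @param genes Gene data.frame (`chrom, start, end, symbol`).
#' @param samples Sample data.frame mapping ids to cohorts.
#' @param exons Optional exon data.frame (`chrom, start, end, symbol`).
#' @param exonic Restrict carrier status to exon-overlapping calls.
#' @return An object of class `carrier_sets`: list with `case` and
#'   `control` (named lists: symbol -> sorted sample-id vector), `genes`
#'   (all gene symbols), `n_case`, `n_control`.
#' @export
map_cnvs_to_genes <- function(calls, genes, samples, exons = NULL,
                              exonic = FALSE) {
  validate_calls(calls)
  check_columns(genes, c("chrom", "start", "end", "symbol"), "gene table")
  check_columns(samples, c("sample_id", "cohort"), "sample table")
  targets <- if (exonic) {
    check_that(!is.null(exons), "exonic mode requires an exon table")
    exons
  } else {
    genes
  }
  carrier <- list()
  for (ch in unique(targets$chrom)) {
    g <- targets[targets$chrom == ch, , drop = FALSE]
    cl <- calls[calls$chrom == ch, , drop = FALSE]
    if (nrow(cl) == 0L || nrow(g) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = g$start + 1L, end = g$end),
      IRanges::IRanges(start = cl$start + 1L, end = cl$end))
    if (length(hits) == 0L) next
    by_gene <- split(cl$sample_id[S4Vectors::subjectHits(hits)],
                     g$symbol[S4Vectors::queryHits(hits)])
    for (sym in names(by_gene)) {
      carrier[[sym]] <- unique(c(carrier[[sym]], by_gene[[sym]]))
    }
  }
  cases <- samples$sample_id[samples$cohort == "case"]
  ctrls <- samples$sample_id[samples$cohort == "control"]
  structure(list(
    case = lapply(carrier, function(s) sort(intersect(s, cases))),
    control = lapply(carrier, function(s) sort(intersect(s, ctrls))),
    genes = unique(genes$symbol),
    n_case = length(cases), n_control = length(ctrls)),
    class = "carrier_sets")
}

#' Cumulative CNV enrichment of a gene network
#'
#' Scores a gene network for cumulative case/control CNV enrichment: a
#' sample is a network carrier when it carries a CNV in any member gene
#' (counted once, however many member genes it hits). The carrier/
#' non-carrier 2x2 table is tested with the one-sided Fisher's exact test
#' and summarised by the cross-product odds ratio (the network's
#' "enrichment"). Member genes with at least one carrier in either cohort
#' are "informative"; informative genes whose case carrier frequency
#' exceeds their control carrier frequency are "enriched".
#'
#' @param network A [expand_network()] result, or a character vector of
#'   member symbols.
#' @param carriers A [map_cnvs_to_genes()] result, or a list with `case` /
#'   `control` named carrier lists.
#' @param n_case,n_control Cohort denominators; default from `carriers`.
#' @param name Network label for reporting.
#' @param family_size Seed-family size N recorded in the result.
#' @return An object of class `network_result`: list with fields `name`,
#'   `family_size`, `network_size`, `informative_genes`, `enriched_genes`,
#'   `case_carriers`, `control_carriers`, `case_freq`, `control_freq`,
#'   `p_fisher`, `enrichment`, `testable` (FALSE when no member gene is
#'   informative, in which case the Fisher fields are NA).
#' @examples
#' carr <- list(case = list(G1 = c("s1", "s2")), control = list(G1 = "t1"))
#' network_association(c("G1", "G2"), carr, n_case = 100, n_control = 100)
#' @export
network_association <- function(network, carriers, n_case = NULL,
                                n_control = NULL, name = NULL,
                                family_size = NA_integer_) {
  members <- if (inherits(network, "gene_network")) network$members
             else unique(as.character(network))
  if (is.null(n_case)) n_case <- carriers$n_case
  if (is.null(n_control)) n_control <- carriers$n_control
  check_that(!is.null(n_case) && !is.null(n_control) &&
               n_case > 0 && n_control > 0,
             "cohort sizes must be supplied and positive")
  case_l <- carriers$case[intersect(members, names(carriers$case))]
  ctrl_l <- carriers$control[intersect(members, names(carriers$control))]
  per_case <- vapply(members, function(g) {
    length(case_l[[g]] %||% character(0))
  }, 0L)
  per_ctrl <- vapply(members, function(g) {
    length(ctrl_l[[g]] %||% character(0))
  }, 0L)
  informative <- per_case + per_ctrl > 0L
  enriched <- informative & (per_case / n_case > per_ctrl / n_control)
  cc <- length(unique(unlist(case_l, use.names = FALSE)))
  ct <- length(unique(unlist(ctrl_l, use.names = FALSE)))
  res <- list(name = name %||% paste(utils::head(members, 1L), "network"),
              family_size = family_size,
              network_size = length(members),
              informative_genes = sum(informative),
              enriched_genes = sum(enriched),
              case_carriers = cc, control_carriers = ct,
              case_freq = cc / n_case, control_freq = ct / n_control,
              p_fisher = NA_real_, enrichment = NA_real_,
              n_case = n_case, n_control = n_control,
              testable = any(informative))
  if (res$testable) {
    ft <- fisher_one_sided(cc, n_case - cc, ct, n_control - ct)
    res$p_fisher <- ft$p_one_sided
    res$enrichment <- ft$odds_ratio
  }
  class(res) <- "network_result"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.network_result <- function(x, ...) {
  cat(sprintf("Network '%s' (N = %s): %d members, %d/%d enriched/informative\n",
              x$name, format(x$family_size), x$network_size,
              x$enriched_genes, x$informative_genes))
  cat(sprintf("  carriers %d/%d cases vs %d/%d controls",
              x$case_carriers, x$n_case, x$control_carriers, x$n_control))
  if (x$testable) {
    cat(sprintf("; OR %.3g, one-sided Fisher p %.3g", x$enrichment,
                x$p_fisher))
  } else {
    cat("; untestable (no informative gene)")
  }
  if (!is.null(x$p_perm)) cat(sprintf(", perm p %.4g", x$p_perm))
  cat("\n")
  invisible(x)
}

#' Random-gene-set network permutation test
#'
#' Calibrates an observed network enrichment against networks grown from
#' random seed sets of the same size: each of `n_perm` draws samples N
#' distinct seed symbols uniformly from `universe` (default: all interactome
#' symbols), expands them exactly as the observed network was expanded, and
#' recomputes the enrichment statistic. The reported p-value uses the
#' plus-one estimator \eqn{(r + 1)/(n_{perm} + 1)}, where r counts draws
#' whose statistic is at least the observed one; the uncorrected
#' \eqn{r/n_{perm}} is also returned. Draws whose network has no
#' informative gene count as non-exceeding. Per-draw seeds are derived from
#' `seed` by a counter scheme, so results are reproducible and independent
#' of evaluation order.
#'
#' This test controls for network size and topology: a large family spawns
#' a large network that accrues carriers by size alone, and the random
#' seed-set null reproduces exactly that size effect.
#'
#' @param inter An [interactome()].
#' @param n_seeds Number N of random seeds per draw (the family size).
#' @param carriers A [map_cnvs_to_genes()] result.
#' @param observed The observed [network_association()] result.
#' @param n_perm Number of permutation draws (>= 1); default 1000.
#' @param seed RNG seed.
#' @param degree,direction Expansion parameters, matching the observed
#'   network's.
#' @param universe Symbols to draw seeds from; default all interactome
#'   symbols.
#' @param stat Permutation statistic: `"enrichment"` (odds ratio, default)
#'   or `"carriers"` (case carrier count).
#' @param n_case,n_control Cohort denominators; default from `carriers`.
#' @return A list with `p_perm` (plus-one), `p_perm_raw`, `n_exceed`,
#'   `n_perm`.
#' @export
permutation_test <- function(inter, n_seeds, carriers, observed,
                             n_perm = 1000L, seed = 1L, degree = 2L,
                             direction = "out", universe = NULL,
                             stat = c("enrichment", "carriers"),
                             n_case = NULL, n_control = NULL) {
  stat <- match.arg(stat)
  check_that(n_perm >= 1, "n_perm must be >= 1")
  if (is.null(universe)) universe <- inter$symbols
  check_that(n_seeds <= length(universe),
             "cannot draw %d seeds from a universe of %d symbols",
             n_seeds, length(universe))
  if (is.null(n_case)) n_case <- carriers$n_case
  if (is.null(n_control)) n_control <- carriers$n_control
  obs_stat <- if (stat == "enrichment") observed$enrichment
              else observed$case_carriers
  check_that(!is.null(obs_stat), "observed result lacks the chosen statistic")
  r <- 0L
  for (i in seq_len(n_perm)) {
    draw <- with_seed(derive_seed(seed, paste0("net-perm", i)),
                      sample(universe, n_seeds))
    net <- expand_network(inter, draw, degree = degree,
                          direction = direction)
    null_res <- network_association(net, carriers, n_case = n_case,
                                    n_control = n_control)
    if (!null_res$testable) next # undefined draws never exceed
    null_stat <- if (stat == "enrichment") null_res$enrichment
                 else null_res$case_carriers
    if (is.na(obs_stat)) next
    if (!is.na(null_stat) && null_stat >= obs_stat) r <- r + 1L
  }
  list(p_perm = (r + 1) / (n_perm + 1), p_perm_raw = r / n_perm,
       n_exceed = r, n_perm = as.integer(n_perm))
}

#' Rank gene-family interaction networks (GFINs)
#'
#' Builds the expanded network of every gene family, scores its cumulative
#' CNV enrichment, calibrates it with the random-seed-set permutation test,
#' and returns one row per testable family sorted by permutation p then
#' Fisher p. Families whose networks contain no informative gene are
#' excluded from the ranking and counted in a message.
#'
#' @param families Family data.frame (`root, member`).
#' @param inter An [interactome()].
#' @param carriers A [map_cnvs_to_genes()] result.
#' @param degree Expansion depth (default 2, the second-degree network).
#' @param direction Edge direction for expansion.
#' @param n_perm Permutation draws per family (default 1000).
#' @param seed Master RNG seed; each family's permutation stream is derived
#'   from it and the family root, so per-family results are reproducible in
#'   isolation.
#' @param stat Permutation statistic (see [permutation_test()]).
#' @param universe Seed universe for the null draws.
#' @param n_case,n_control Cohort denominators; default from `carriers`.
#' @return A data.frame of class `gfin_ranking` with columns `name,
#'   family_size, network_size, informative_genes, enriched_genes,
#'   case_carriers, case_freq, control_carriers, control_freq, p_fisher,
#'   enrichment, p_perm, p_perm_raw, n_perm`; attribute `n_untestable`
#'   counts skipped families.
#' @export
rank_gfins <- function(families, inter, carriers, degree = 2L,
                       direction = "out", n_perm = 1000L, seed = 1L,
                       stat = "enrichment", universe = NULL,
                       n_case = NULL, n_control = NULL) {
  check_columns(families, c("root", "member"), "gene family table")
  roots <- unique(families$root)
  rows <- list()
  n_untestable <- 0L
  for (root in roots) {
    members <- families$member[families$root == root]
    net <- expand_network(inter, members, degree = degree,
                          direction = direction)
    res <- network_association(net, carriers, n_case = n_case,
                               n_control = n_control, name = root,
                               family_size = length(members))
    if (!res$testable) {
      n_untestable <- n_untestable + 1L
      next
    }
    pt <- permutation_test(inter, length(members), carriers, res,
                           n_perm = n_perm,
                           seed = derive_seed(seed, root),
                           degree = degree, direction = direction,
                           universe = universe, stat = stat,
                           n_case = n_case, n_control = n_control)
    rows[[length(rows) + 1L]] <- data.frame(
      name = root, family_size = res$family_size,
      network_size = res$network_size,
      informative_genes = res$informative_genes,
      enriched_genes = res$enriched_genes,
      case_carriers = res$case_carriers, case_freq = res$case_freq,
      control_carriers = res$control_carriers,
      control_freq = res$control_freq,
      p_fisher = res$p_fisher, enrichment = res$enrichment,
      p_perm = pt$p_perm, p_perm_raw = pt$p_perm_raw,
      n_perm = pt$n_perm, stringsAsFactors = FALSE)
  }
  if (n_untestable > 0L) {
    message(sprintf("rank_gfins: %d famil%s without informative network genes skipped",
                    n_untestable, if (n_untestable == 1L) "y" else "ies"))
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame(
    name = character(0), family_size = integer(0), network_size = integer(0),
    informative_genes = integer(0), enriched_genes = integer(0),
    case_carriers = integer(0), case_freq = numeric(0),
    control_carriers = integer(0), control_freq = numeric(0),
    p_fisher = numeric(0), enrichment = numeric(0), p_perm = numeric(0),
    p_perm_raw = numeric(0), n_perm = integer(0), stringsAsFactors = FALSE)
  res <- res[order(res$p_perm, res$p_fisher), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_untestable") <- n_untestable
  class(res) <- c("gfin_ranking", class(res))
  res
}

#' Report-view filter for ranked networks
#'
#' The default report view keeps networks significant by permutation
#' (p_perm <= 0.05) that are enriched for CNV defects across at least 5% of
#' cases.
#'
#' @param results A `gfin_ranking` data.frame.
#' @param p_perm_max Permutation-p threshold (default 0.05).
#' @param min_case_freq Minimum case network-carrier frequency (default 0.05).
#' @return The filtered subset.
#' @export
gfin_report_filter <- function(results, p_perm_max = 0.05,
                               min_case_freq = 0.05) {
  out <- results[results$p_perm <= p_perm_max &
                   results$case_freq >= min_case_freq &
                   results$enrichment > 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan single genes as first-degree networks
#'
#' Decomposes families into their component genes and scores each gene
#' present in the interactome ("defined network") as a first-degree network
#' of its own, with the same statistics and the permutation machinery run
#' at N = 1 seed draws. Genes absent from the interactome are skipped.
#'
#' @param symbols Character vector of gene symbols (typically all family
#'   members).
#' @param inter An [interactome()].
#' @param carriers A [map_cnvs_to_genes()] result.
#' @param degree Expansion depth (default 1, the first-degree network).
#' @inheritParams rank_gfins
#' @return A `gfin_ranking` data.frame, one row per testable gene network.
#' @export
component_gene_scan <- function(symbols, inter, carriers, degree = 1L,
                                direction = "out", n_perm = 1000L,
                                seed = 1L, stat = "enrichment",
                                universe = NULL, n_case = NULL,
                                n_control = NULL) {
  symbols <- unique(toupper(as.character(symbols)))
  defined <- intersect(symbols, inter$symbols)
  # a single-gene "family": the root is the gene itself
  fam <- data.frame(root = defined, member = defined,
                    stringsAsFactors = FALSE)
  res <- rank_gfins(fam, inter, carriers, degree = degree,
                    direction = direction, n_perm = n_perm, seed = seed,
                    stat = stat, universe = universe, n_case = n_case,
                    n_control = n_control)
  res$family_size <- 1L
  res
}

#' @export
print.gfin_ranking <- function(x, ...) {
  cat(sprintf("GFIN ranking: %d testable network(s)", nrow(x)))
  if (!is.null(attr(x, "n_untestable")) && attr(x, "n_untestable") > 0) {
    cat(sprintf(" (%d without informative genes skipped)",
                attr(x, "n_untestable")))
  }
  cat("\n")
  cols <- c("name", "family_size", "network_size", "enriched_genes",
            "informative_genes", "case_carriers", "control_carriers",
            "p_fisher", "enrichment", "p_perm")
  print.data.frame(utils::head(x[, cols], 12L), digits = 3)
  invisible(x)
}
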