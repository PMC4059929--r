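#' Assemble and validate a pipeline run configuration
#'
#' Collects file paths, stage toggles and thresholds for [run_pipeline()].
#' Referenced input files must exist at construction time.
#'
#' @param calls,samples,genes Paths to the CNV call TSV, sample TSV and gene
#'   BED (required for the assoc/gfin stages).
#' @param edges Character vector of interactome edge-list paths (gfin).
#' @param families Path to the family TSV, or `NULL` to derive families
#'   from gene symbols.
#' @param ibs_pairs,features Optional paths for the QC stage (duplicate
#'   removal, ancestry classification).
#' @param replication_calls,replication_samples Optional replication-cohort
#'   inputs for discovery-replication CNVR filtering.
#' @param out Output directory (created if missing).
#' @param qc,assoc,gfin Stage toggles.
#' @param qc_thresholds QC quadruple (call rate, LRR s.d., |GCWF|, #CNVs).
#' @param ibs_threshold IBS duplicate threshold.
#' @param p_disc,p_repl Discovery / replication p thresholds.
#' @param coords Coordinate convention of call TSVs (`"onebased"`/`"bed"`).
#' @param degree,direction Network expansion parameters.
#' @param n_perm Permutation draws (networks and burden test).
#' @param p_perm_max,min_case_freq Report-view filter thresholds.
#' @param seed Master seed; per-stage streams are derived from it.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(calls = NULL, samples = NULL, genes = NULL,
                       edges = NULL, families = NULL, ibs_pairs = NULL,
                       features = NULL, replication_calls = NULL,
                       replication_samples = NULL, out = "gfinet-out",
                       qc = TRUE, assoc = TRUE, gfin = TRUE,
                       qc_thresholds = c(0.95, 0.3, 0.02, 100),
                       ibs_threshold = 0.9, p_disc = 1e-4, p_repl = 1e-3,
                       coords = "onebased", degree = 2L, direction = "out",
                       n_perm = 1000L, p_perm_max = 0.05,
                       min_case_freq = 0.05, seed = 1L) {
  cfg <- as.list(environment())
  paths <- c(cfg$calls, cfg$samples, cfg$genes, cfg$edges, cfg$families,
             cfg$ibs_pairs, cfg$features, cfg$replication_calls,
             cfg$replication_samples)
  missing <- paths[!file.exists(paths)]
  check_that(length(missing) == 0L, "input file(s) not found: %s",
             paste(missing, collapse = ", "))
  check_that(cfg$n_perm >= 1, "n_perm must be >= 1")
  check_that(cfg$ibs_threshold >= 0 && cfg$ibs_threshold <= 1,
             "ibs_threshold must lie in [0, 1]")
  check_that(cfg$coords %in% c("onebased", "bed"),
             "coords must be 'onebased' or 'bed'")
  if (cfg$assoc || cfg$gfin) {
    check_that(!is.null(cfg$calls) && !is.null(cfg$samples),
               "assoc/gfin stages require calls and samples paths")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order QC -> CNVR association -> GFIN
#' enrichment, each downstream stage consuming only the samples that
#' survived QC. Every stage writes its result tables under `config$out` and
#' a JSON run manifest records the configuration, input digests, per-stage
#' row counts and the seed, making a run auditable and repeatable:
#' identical configuration, inputs and seed give identical result tables.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with the in-memory stage results (`samples`,
#'   `qc`, `assoc`, `burden`, `replicated`, `gfin`, `gene_scan`) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  counts <- list()
  results <- list()
  fail_marker <- file.path(config$out, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", stage,
                         conditionMessage(e)), fail_marker)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  samples <- read_samples(config$samples)
  counts$samples_in <- nrow(samples)

  if (config$qc) {
    run_stage("qc", {
      flt <- filter_samples(samples, config$qc_thresholds)
      message(sprintf("qc: %d samples in, %d kept, %d excluded",
                      nrow(samples), nrow(flt$kept), nrow(flt$excluded)))
      samples <- flt$kept
      if (!is.null(config$ibs_pairs)) {
        dd <- dedupe_samples(samples, read_ibs_pairs(config$ibs_pairs),
                             config$ibs_threshold)
        message(sprintf("qc: %d duplicate sample(s) removed",
                        length(dd$removed)))
        samples <- dd$kept
      }
      if (!is.null(config$features)) {
        feats <- read_ancestry_features(config$features)
        anc <- classify_ancestry(feats, k = NULL)
        idx <- match(samples$sample_id, anc$sample_id)
        hit <- !is.na(idx)
        samples$ancestry[hit] <- anc$ancestry[idx[hit]]
        message(sprintf("qc: ancestry assigned for %d sample(s)", sum(hit)))
      }
      write_samples(flt$excluded,
                    file.path(config$out, "samples_excluded.tsv"))
      write_samples(samples, file.path(config$out, "samples_kept.tsv"))
      results$qc <- flt
    })
  }
  counts$samples_kept <- nrow(samples)
  results$samples <- samples

  calls <- NULL
  genes <- NULL
  if (config$assoc || config$gfin) {
    run_stage("input", {
      calls <- read_cnv_calls(config$calls, coords = config$coords)
      calls <- calls[calls$sample_id %in% samples$sample_id, , drop = FALSE]
      counts$calls <- nrow(calls)
      if (!is.null(config$genes)) genes <- read_genes_bed(config$genes)
    })
  }

  if (config$assoc) {
    run_stage("assoc", {
      cnvrs <- build_cnvrs(calls)
      message(sprintf("assoc: %d CNVRs built from %d calls",
                      nrow(cnvrs), nrow(calls)))
      assoc <- associate_cnvrs(cnvrs, samples, genes = genes)
      counts$cnvrs <- nrow(assoc)
      out_tab <- assoc
      class(out_tab) <- "data.frame"
      write_tsv_plain(out_tab, file.path(config$out, "cnvr_association.tsv"))
      bed <- data.frame(chrom = cnvrs$chrom, start = cnvrs$start,
                        end = cnvrs$end, id = cnvrs$id, score = 0L,
                        strand = "+")
      utils::write.table(bed, file.path(config$out, "cnvrs.bed"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      burden <- burden_test(calls, samples, n_perm = config$n_perm,
                            seed = derive_seed(config$seed, "burden"))
      jsonlite::write_json(unclass(burden),
                           file.path(config$out, "burden.json"),
                           auto_unbox = TRUE, digits = NA)
      results$assoc <- assoc
      results$burden <- burden
      if (!is.null(config$replication_calls)) {
        rsamp <- read_samples(config$replication_samples)
        rcalls <- read_cnv_calls(config$replication_calls,
                                 coords = config$coords)
        rcalls <- rcalls[rcalls$sample_id %in% rsamp$sample_id, ,
                         drop = FALSE]
        rassoc <- associate_cnvrs(build_cnvrs(rcalls), rsamp, genes = genes)
        repl <- discovery_replication(assoc, rassoc,
                                      p_disc = config$p_disc,
                                      p_repl = config$p_repl)
        message(sprintf("assoc: %d region(s) replicated", nrow(repl)))
        counts$replicated <- nrow(repl)
        write_tsv_plain(repl, file.path(config$out, "replicated_cnvrs.tsv"))
        results$replicated <- repl
      }
    })
  }

  if (config$gfin) {
    run_stage("gfin", {
      check_that(!is.null(config$edges) && !is.null(genes),
                 "gfin stage requires edges and genes paths")
      inter <- load_interactome(config$edges)
      fams <- if (!is.null(config$families)) {
        define_families(read_families(config$families))
      } else {
        define_families(genes$symbol, derive = TRUE)
      }
      carriers <- map_cnvs_to_genes(calls, genes, samples)
      gf <- rank_gfins(fams, inter, carriers, degree = config$degree,
                       direction = config$direction,
                       n_perm = config$n_perm,
                       seed = derive_seed(config$seed, "gfin"))
      counts$gfins_ranked <- nrow(gf)
      counts$gfins_untestable <- attr(gf, "n_untestable")
      write_tsv_plain(as.data.frame(gf),
                      file.path(config$out, "gfin_ranking.tsv"))
      scan <- component_gene_scan(fams$member, inter, carriers,
                                  degree = 1L,
                                  direction = config$direction,
                                  n_perm = config$n_perm,
                                  seed = derive_seed(config$seed, "scan"))
      counts$component_genes_ranked <- nrow(scan)
      write_tsv_plain(as.data.frame(scan),
                      file.path(config$out, "gene_networks.tsv"))
      results$gfin <- gf
      results$gene_scan <- scan
    })
  }

  inputs <- c(config$calls, config$samples, config$genes, config$edges,
              config$families, config$ibs_pairs, config$features,
              config$replication_calls, config$replication_samples)
  manifest <- list(
    tool = paste("gfinet",
                 as.character(utils::packageVersion("gfinet"))),
    seed = config$seed,
    config = config[setdiff(names(config), "out")],
    input_digests = as.list(tools::md5sum(inputs)),
    row_counts = counts,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Write a human-readable multi-section report
#'
#' Emits the pipeline's headline tables in a single text report: a CNVR
#' section (region coordinates, carrier counts, Fisher p, odds ratio,
#' nearest gene), a GFIN section (family name and size, enriched /
#' informative genes, case and control carrier counts and frequencies,
#' Fisher p, enrichment, permutation p) and a single-gene network section
#' with the same columns.
#'
#' @param results A list as returned by [run_pipeline()] (components
#'   `assoc`, `gfin`, `gene_scan`; any may be NULL).
#' @param path Output file path.
#' @param allow_empty Permit an all-empty report (headers only).
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, allow_empty = FALSE) {
  n_rows <- sum(vapply(results[c("assoc", "gfin", "gene_scan")],
                       function(x) if (is.null(x)) 0L else nrow(x), 0L))
  check_that(n_rows > 0L || allow_empty, "nothing to report")
  con <- file(path, "w")
  on.exit(close(con))
  section <- function(title, df, cols) {
    writeLines(sprintf("## %s", title), con)
    if (is.null(df)) df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    df <- as.data.frame(df)[, intersect(cols, names(df)), drop = FALSE]
    utils::write.table(format(df, digits = 4), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines("", con)
  }
  section("Copy-number variable regions",
          if (is.null(results$assoc)) NULL else
            results$assoc[order(results$assoc$p), ],
          c("id", "chrom", "start", "end", "type", "a", "c", "p", "or",
            "nearest_gene", "exonic"))
  section("Gene family interaction networks", results$gfin,
          c("name", "family_size", "enriched_genes", "informative_genes",
            "case_carriers", "case_freq", "control_carriers",
            "control_freq", "p_fisher", "enrichment", "p_perm"))
  section("Single-gene interaction networks", results$gene_scan,
          c("name", "enriched_genes", "informative_genes", "case_carriers",
            "case_freq", "control_carriers", "control_freq", "p_fisher",
            "enrichment", "p_perm"))
  invisible(path)
}
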