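# Synthetic genome / interactome / cohort generators.

test_that("family specification is realised exactly and genome layout is valid", {
  cfg <- small_config(seed = 3L)
  gen <- make_genome(cfg)
  expect_equal(nrow(gen$genes), cfg$n_genes)
  expect_setequal(gen$families$member[gen$families$root == "FAM01"],
                  paste0("FAM01", 1:4))
  expect_setequal(unique(gen$families$root), c("FAM01", "FAM02"))
  expect_true(all(gen$families$member %in% gen$genes$symbol))
  expect_false(anyDuplicated(gen$genes$symbol) > 0)
  # non-overlapping intervals per chromosome
  for (ch in unique(gen$genes$chrom)) {
    g <- gen$genes[gen$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start < g$end))
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    expect_true(all(g$end <= cfg$chromosome_length_bp))
  }
})

test_that("a genome of one gene with no families is the minimal case", {
  cfg <- simulation_config(n_cases = 2, n_controls = 2, n_genes = 1,
                           n_chromosomes = 1, family_spec = NULL,
                           effect_target = NULL, seed = 1)
  gen <- make_genome(cfg)
  expect_equal(nrow(gen$genes), 1L)
  expect_equal(nrow(gen$families), 0L)
})

test_that("an oversized gene footprint raises an error naming the chromosome", {
  cfg <- simulation_config(n_genes = 50, n_chromosomes = 1,
                           family_spec = NULL, effect_target = NULL,
                           gene_length_bp = 1000, chromosome_length_bp = 2e4,
                           seed = 1)
  expect_error(make_genome(cfg), "chr1")
})

test_that("all three generators are bit-reproducible for a fixed seed", {
  cfg <- small_config(seed = 99L)
  g1 <- make_genome(cfg); g2 <- make_genome(cfg)
  expect_identical(g1, g2)
  i1 <- make_interactome(g1$genes, cfg)
  i2 <- make_interactome(g1$genes, cfg)
  expect_identical(i1$edges, i2$edges)
  s1 <- simulate_cohort(g1$genes, g1$families, i1, cfg)
  s2 <- simulate_cohort(g1$genes, g1$families, i1, cfg)
  expect_identical(s1, s2)
  # and a different seed changes the output
  g3 <- make_genome(small_config(seed = 100L))
  expect_false(identical(g1, g3))
})

test_that("interactome degree matches its target and has no self-loops", {
  cfg <- simulation_config(n_genes = 200, mean_out_degree = 4,
                           family_spec = NULL, effect_target = NULL,
                           seed = 5)
  gen <- make_genome(cfg)
  inter <- make_interactome(gen$genes, cfg)
  expect_true(all(inter$edges$source != inter$edges$target))
  # empirical mean out-degree from the emitted edge list
  expect_equal(nrow(inter$edges) / 200, 4, tolerance = 0.25)
  expect_true(all(c(inter$edges$source, inter$edges$target) %in%
                    gen$genes$symbol))
  # zero degree -> empty edge set
  cfg0 <- simulation_config(n_genes = 3, mean_out_degree = 0,
                            family_spec = NULL, effect_target = NULL,
                            seed = 1)
  gen0 <- make_genome(cfg0)
  expect_equal(nrow(make_interactome(gen0$genes, cfg0)$edges), 0L)
  # mean degree must stay below the gene count
  cfg_bad <- simulation_config(n_genes = 3, mean_out_degree = 3,
                               family_spec = NULL, effect_target = NULL)
  expect_error(make_interactome(gen0$genes, cfg_bad), "mean_out_degree")
})

test_that("three-source mode duplicates edges across datasets", {
  cfg <- simulation_config(n_genes = 150, mean_out_degree = 3,
                           n_interactome_sources = 3, family_spec = NULL,
                           effect_target = NULL, seed = 8)
  inter <- make_interactome(make_genome(cfg)$genes, cfg)
  expect_setequal(unique(unlist(strsplit(inter$edges$datasets, ";"))),
                  c("S1", "S2", "S3"))
  multi <- grepl(";", inter$edges$datasets)
  expect_equal(mean(multi), 0.2, tolerance = 0.5)
})

test_that("cohort calls stay inside chromosomes with start < end", {
  cfg <- small_config(seed = 21L)
  gen <- make_genome(cfg)
  inter <- make_interactome(gen$genes, cfg)
  sim <- simulate_cohort(gen$genes, gen$families, inter, cfg)
  expect_true(all(sim$calls$start < sim$calls$end))
  expect_true(all(sim$calls$start >= 0))
  expect_true(all(sim$calls$end <= cfg$chromosome_length_bp))
  expect_true(all(sim$calls$type %in% c("del", "dup")))
  expect_true(all(sim$calls$sample_id %in% sim$samples$sample_id))
  # del/dup copy numbers are consistent
  expect_true(all(sim$calls$copy_number[sim$calls$type == "del"] <= 1))
  expect_true(all(sim$calls$copy_number[sim$calls$type == "dup"] >= 3))
})

test_that("QC failures and duplicate pairs are injected exactly as configured", {
  cfg <- simulation_config(n_cases = 50, n_controls = 50, n_genes = 30,
                           n_chromosomes = 2,
                           family_spec = c(FAM01 = 2), effect_target = NULL,
                           qc_fail_fraction = 0.1, duplicate_pairs = 3,
                           seed = 13)
  gen <- make_genome(cfg)
  inter <- make_interactome(gen$genes, cfg)
  sim <- simulate_cohort(gen$genes, gen$families, inter, cfg)
  expect_length(sim$truth$injected_qc_failures, 10L) # ceiling(0.1 * 100)
  flt <- filter_samples(sim$samples)
  expect_setequal(flt$excluded$sample_id, sim$truth$injected_qc_failures)
  expect_equal(nrow(sim$truth$injected_duplicate_pairs), 3L)
  dup_ibs <- sim$ibs_pairs$ibs[paste(sim$ibs_pairs$id_a, sim$ibs_pairs$id_b) %in%
    paste(sim$truth$injected_duplicate_pairs$id_a,
          sim$truth$injected_duplicate_pairs$id_b)]
  expect_length(dup_ibs, 3L)
  expect_true(all(dup_ibs >= 0.9))
  other <- setdiff(sim$ibs_pairs$ibs, dup_ibs)
  expect_true(all(other < 0.9))
})

test_that("an unknown effect target is rejected by name", {
  cfg <- small_config(seed = 2L)
  gen <- make_genome(cfg)
  inter <- make_interactome(gen$genes, cfg)
  cfg$effect_target <- "NOSUCH"
  expect_error(simulate_cohort(gen$genes, gen$families, inter, cfg),
               "NOSUCH")
})

test_that("null configuration gives symmetric case/control carrier rates", {
  cfg <- simulation_config(n_cases = 400, n_controls = 400, n_genes = 50,
                           n_chromosomes = 2, family_spec = c(FAM01 = 2),
                           background_carrier_rate = 0.02,
                           case_burden_multiplier = 1, effect_multiplier = 1,
                           qc_fail_fraction = 0, duplicate_pairs = 0,
                           seed = 31)
  gen <- make_genome(cfg)
  inter <- make_interactome(gen$genes, cfg)
  sim <- simulate_cohort(gen$genes, gen$families, inter, cfg)
  carr <- map_cnvs_to_genes(sim$calls, gen$genes, sim$samples)
  se <- sqrt(0.02 * 0.98 / 400)
  # genome-wide mean per-gene rate difference is within sampling error
  diffs <- vapply(gen$genes$symbol, function(g) {
    length(carr$case[[g]] %||% character(0)) / 400 -
      length(carr$control[[g]] %||% character(0)) / 400
  }, 0)
  expect_lt(abs(mean(diffs)), 3 * se / sqrt(50))
  expect_gt(mean(abs(diffs) < 3 * sqrt(2) * se), 0.95)
})

test_that("a planted effect raises the network carrier frequency in cases", {
  cfg <- simulation_config(n_cases = 500, n_controls = 500, n_genes = 200,
                           background_carrier_rate = 0.002,
                           effect_multiplier = 8, seed = 17)
  gen <- make_genome(cfg)
  inter <- make_interactome(gen$genes, cfg)
  sim <- simulate_cohort(gen$genes, gen$families, inter, cfg)
  tgt <- sim$truth$target_network_genes
  expect_gt(length(tgt), 0)
  carr <- map_cnvs_to_genes(sim$calls, gen$genes, sim$samples)
  res <- network_association(tgt, carr, name = "planted")
  expect_gt(res$case_freq, res$control_freq)
  # truth records the multiplied case rates on exactly the network genes
  expect_equal(unname(sim$truth$per_gene_case_rate[tgt]),
               rep(0.016, length(tgt)))
  off <- setdiff(names(sim$truth$per_gene_case_rate), tgt)
  expect_equal(unname(sim$truth$per_gene_case_rate[off]),
               rep(0.002, length(off)))
})

test_that("carrier-rate estimates converge to the planted truth", {
  ok <- 0L; total <- 0L
  for (rep in 1:10) {
    cfg <- simulation_config(n_cases = 300, n_controls = 300, n_genes = 40,
                             n_chromosomes = 2, family_spec = c(FAM01 = 3),
                             background_carrier_rate = 0.01,
                             effect_multiplier = 4, qc_fail_fraction = 0,
                             duplicate_pairs = 0, seed = 100 + rep)
    gen <- make_genome(cfg)
    inter <- make_interactome(gen$genes, cfg)
    sim <- simulate_cohort(gen$genes, gen$families, inter, cfg)
    carr <- map_cnvs_to_genes(sim$calls, gen$genes, sim$samples)
    for (g in gen$genes$symbol) {
      for (side in c("case", "control")) {
        rate <- sim$truth[[paste0("per_gene_", side, "_rate")]][[g]]
        est <- length(carr[[side]][[g]] %||% character(0)) / 300
        se <- sqrt(rate * (1 - rate) / 300)
        total <- total + 1L
        if (abs(est - rate) < max(3 * se, 1e-9)) ok <- ok + 1L
      }
    }
  }
  expect_gt(ok / total, 0.95)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_cases = 0), "> 0")
  expect_error(simulation_config(background_carrier_rate = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(family_spec = c(FAM01 = 1)), ">= 2")
  expect_error(simulation_config(effect_multiplier = 0.5), ">= 1")
  expect_error(simulation_config(n_genes = 5,
                                 family_spec = c(A = 4, B = 4)), "exceed")
})
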