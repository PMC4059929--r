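# Interactome loading, family derivation, network expansion, CNV-to-gene
# mapping, cumulative network enrichment and the random-set permutation test.

test_that("edge files merge by union with dataset ids concatenated", {
  d <- withr::local_tempdir()
  writeLines(c("a\tb", "b\tc"), file.path(d, "y2h1.tsv"))
  writeLines(c("A\tB\tHI", "C\tD\tHI"), file.path(d, "y2h2.tsv"))
  inter <- load_interactome(c(file.path(d, "y2h1.tsv"),
                              file.path(d, "y2h2.tsv")))
  expect_equal(nrow(inter$edges), 3L) # a->b duplicated across sources
  ab <- inter$edges[inter$edges$source == "A" & inter$edges$target == "B", ]
  expect_equal(ab$datasets, "HI;y2h1")
  # brute-force set union of the parsed tuples
  expect_setequal(paste(inter$edges$source, inter$edges$target),
                  c("A B", "B C", "C D"))
})

test_that("self-loops are dropped with a reported count", {
  expect_message(
    inter <- interactome(data.frame(source = c("A", "B"),
                                    target = c("A", "C"))),
    "1 self-loop")
  expect_equal(nrow(inter$edges), 1L)
  expect_equal(inter$n_self_dropped, 1L)
})

test_that("malformed edge lines are rejected with file and line", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.tsv")
  writeLines(c("a\tb", "oops"), f)
  expect_error(load_interactome(f), "bad\\.tsv:2")
})

test_that("families derive from symbol roots by stripping trailing digits", {
  fam <- define_families(c(paste0("GRM", 1:8), "CALM1"), derive = TRUE)
  expect_setequal(fam$member[fam$root == "GRM"], paste0("GRM", 1:8))
  expect_equal(sum(fam$root == "GRM"), 8L)
  expect_false("CALM" %in% fam$root) # singleton roots are discarded
  expect_warning(define_families("CALM1", derive = TRUE), "no gene family")
})

test_that("derived grouping equals a regex-oracle partition on mixed symbols", {
  set.seed(6)
  roots <- c("ABC", "DEF", "GH", "XYZB", "Q")
  syms <- unique(paste0(sample(roots, 50, replace = TRUE),
                        sample(c("", 1:9), 50, replace = TRUE)))
  fam <- define_families(syms, derive = TRUE)
  oracle <- split(syms, sub("[0-9]+$", "", syms))
  oracle <- oracle[lengths(oracle) >= 2]
  expect_setequal(unique(fam$root), names(oracle))
  for (r in names(oracle)) {
    expect_setequal(fam$member[fam$root == r], oracle[[r]])
  }
})

test_that("table-mode families drop singletons and duplicates", {
  tab <- data.frame(root = c("F1", "F1", "F1", "F2"),
                    member = c("F1A", "F1B", "F1A", "F2A"))
  fam <- define_families(tab)
  expect_setequal(fam$member, c("F1A", "F1B"))
})

test_that("expansion follows directed edges for one or two steps", {
  toy <- toy_interactome() # A -> B -> C
  expect_setequal(expand_network(toy, "A", degree = 1)$members, c("A", "B"))
  expect_setequal(expand_network(toy, "A", degree = 2)$members,
                  c("A", "B", "C"))
  # direction matters: nothing points into A
  expect_setequal(expand_network(toy, "A", degree = 2,
                                 direction = "in")$members, "A")
  expect_setequal(expand_network(toy, "C", degree = 1,
                                 direction = "in")$members, c("B", "C"))
  # seeds absent from the interactome contribute only themselves
  expect_setequal(expand_network(toy, "X", degree = 2)$members, "X")
})

test_that("expansion equals a hand-rolled BFS and is monotone in degree", {
  set.seed(14)
  for (i in 1:10) {
    edges <- unique(data.frame(
      source = sample(LETTERS[1:12], 25, replace = TRUE),
      target = sample(LETTERS[1:12], 25, replace = TRUE),
      stringsAsFactors = FALSE))
    edges <- edges[edges$source != edges$target, ]
    inter <- interactome(edges)
    seeds <- sample(LETTERS[1:12], 2)
    for (mode in c("out", "in", "all")) {
      d1 <- expand_network(inter, seeds, degree = 1, direction = mode)
      d2 <- expand_network(inter, seeds, degree = 2, direction = mode)
      expect_identical(d1$members, oracle_bfs(edges, sort(seeds), 1, mode))
      expect_identical(d2$members, oracle_bfs(edges, sort(seeds), 2, mode))
      expect_true(all(d1$members %in% d2$members))
    }
  }
})

test_that("gene carrier mapping respects half-open overlap semantics", {
  genes <- data.frame(chrom = "chr1", start = 200L, end = 300L,
                      symbol = "G1", stringsAsFactors = FALSE)
  samples <- toy_samples(c("A", "B"), c("case", "control"))
  touch <- data.frame(sample_id = "A", chrom = "chr1", start = 100L,
                      end = 200L, type = "del", copy_number = 1L,
                      n_snps = 5L) # abuts, no shared base
  overlap <- data.frame(sample_id = "A", chrom = "chr1", start = 150L,
                        end = 250L, type = "dup", copy_number = 3L,
                        n_snps = 5L)
  expect_length(map_cnvs_to_genes(touch, genes, samples)$case, 0L)
  expect_equal(map_cnvs_to_genes(overlap, genes, samples)$case$G1, "A")
})

test_that("carrier mapping equals the naive interval-scan oracle", {
  cfg <- simulation_config(n_cases = 40, n_controls = 40, n_genes = 60,
                           n_chromosomes = 3, family_spec = c(F = 2),
                           effect_target = NULL,
                           background_carrier_rate = 0.05,
                           qc_fail_fraction = 0, duplicate_pairs = 0,
                           seed = 23)
  gen <- make_genome(cfg)
  sim <- simulate_cohort(gen$genes, gen$families,
                         make_interactome(gen$genes, cfg), cfg)
  carr <- map_cnvs_to_genes(sim$calls, gen$genes, sim$samples)
  want <- oracle_carriers(sim$calls, gen$genes)
  cases <- sim$samples$sample_id[sim$samples$cohort == "case"]
  for (g in gen$genes$symbol) {
    expect_identical(carr$case[[g]] %||% character(0),
                     intersect(want[[g]], cases), label = g)
  }
  # carrier definition is type-blind: relabelling del<->dup changes nothing
  flipped <- sim$calls
  flipped$type <- ifelse(flipped$type == "del", "dup", "del")
  flipped$copy_number <- ifelse(flipped$type == "del", 1L, 3L)
  carr2 <- map_cnvs_to_genes(flipped, gen$genes, sim$samples)
  expect_identical(carr$case, carr2$case)
})

test_that("published network-level statistics follow from their carrier counts", {
  carr <- list(case = list(G = sprintf("k%d", 1:265)),
               control = list(G = sprintf("u%d", 1:153)))
  res <- network_association("G", carr, n_case = 4602, n_control = 4722,
                             name = "GRM-like")
  expect_equal(res$enrichment, 1.82, tolerance = 5e-3)
  expect_equal(res$p_fisher, 2.40e-9, tolerance = 1e-2)
  expect_equal(res$case_freq, 0.058, tolerance = 1e-2)
  carr2 <- list(case = list(G = sprintf("k%d", 1:14)),
                control = list(G = "u1"))
  res2 <- network_association("G", carr2, n_case = 4618, n_control = 4726)
  expect_equal(res2$enrichment, 14.37, tolerance = 1e-3)
})

test_that("a sample hitting many member genes is one network carrier", {
  carr <- list(case = stats::setNames(rep(list("s1"), 5),
                                      paste0("G", 1:5)),
               control = list())
  res <- network_association(paste0("G", 1:5), carr, n_case = 10,
                             n_control = 10)
  expect_equal(res$case_carriers, 1L)
  expect_equal(res$informative_genes, 5L)
  expect_equal(res$enriched_genes, 5L)
})

test_that("network carriers are subadditive in the per-gene counts", {
  cfg <- small_config(seed = 33L)
  gen <- make_genome(cfg)
  inter <- make_interactome(gen$genes, cfg)
  sim <- simulate_cohort(gen$genes, gen$families, inter, cfg)
  carr <- map_cnvs_to_genes(sim$calls, gen$genes, sim$samples)
  net <- expand_network(inter, gen$families$member[
    gen$families$root == "FAM01"])
  res <- network_association(net, carr)
  per_gene <- vapply(net$members, function(g) {
    length(carr$case[[g]] %||% character(0))
  }, 0L)
  expect_lte(res$case_carriers, sum(per_gene))
  expect_gte(res$case_carriers, max(per_gene, 0L))
  expect_lte(res$enriched_genes, res$informative_genes)
  expect_lte(res$informative_genes, res$network_size)
})

test_that("a network with no informative gene is flagged untestable", {
  carr <- list(case = list(), control = list())
  res <- network_association(c("G1", "G2"), carr, n_case = 5, n_control = 5)
  expect_false(res$testable)
  expect_true(is.na(res$p_fisher))
})

test_that("permutation p is bounded, seeded, and 1 for a hopeless observation", {
  cfg <- small_config(seed = 41L)
  gen <- make_genome(cfg)
  inter <- make_interactome(gen$genes, cfg)
  sim <- simulate_cohort(gen$genes, gen$families, inter, cfg)
  carr <- map_cnvs_to_genes(sim$calls, gen$genes, sim$samples)
  net <- expand_network(inter, paste0("FAM01", 1:4))
  obs <- network_association(net, carr)
  p1 <- permutation_test(inter, 4, carr, obs, n_perm = 50, seed = 2)
  p2 <- permutation_test(inter, 4, carr, obs, n_perm = 50, seed = 2)
  expect_identical(p1, p2)
  expect_gte(p1$p_perm, 1 / 51)
  expect_lte(p1$p_perm, 1)
  expect_equal(p1$p_perm_raw, p1$n_exceed / 50)
  # an observed enrichment of 0 is never beaten from below
  obs0 <- obs; obs0$enrichment <- 0
  expect_equal(permutation_test(inter, 4, carr, obs0, n_perm = 30,
                                seed = 3)$p_perm, 1)
  expect_error(permutation_test(inter, 10000, carr, obs, n_perm = 5,
                                seed = 1), "universe")
})

test_that("permutation p variability across seeds matches binomial expectation", {
  cfg <- small_config(seed = 43L)
  gen <- make_genome(cfg)
  inter <- make_interactome(gen$genes, cfg)
  sim <- simulate_cohort(gen$genes, gen$families, inter, cfg)
  carr <- map_cnvs_to_genes(sim$calls, gen$genes, sim$samples)
  net <- expand_network(inter, gen$families$member[
    gen$families$root == "FAM02"])
  obs <- network_association(net, carr)
  ps <- vapply(1:12, function(s) {
    permutation_test(inter, 2, carr, obs, n_perm = 100, seed = s)$p_perm
  }, 0)
  p_hat <- mean(ps)
  expect_lte(stats::sd(ps), 3 * sqrt(p_hat * (1 - p_hat) / 100) + 1e-9)
})

test_that("the planted family ranks first and the report filter applies", {
  cfg <- simulation_config(seed = 47L)
  gen <- make_genome(cfg)
  inter <- make_interactome(gen$genes, cfg)
  sim <- simulate_cohort(gen$genes, gen$families, inter, cfg)
  carr <- map_cnvs_to_genes(sim$calls, gen$genes, sim$samples)
  rk <- rank_gfins(define_families(gen$families), inter, carr,
                   n_perm = 100, seed = 3)
  expect_equal(rk$name[1], "FAM01")
  expect_lte(rk$p_perm[1], 0.05)
  top <- gfin_report_filter(rk)
  expect_true(all(top$p_perm <= 0.05 & top$case_freq >= 0.05))
  expect_true("FAM01" %in% top$name)
  # ranking is sorted by permutation p then Fisher p
  expect_true(!is.unsorted(rk$p_perm))
})

test_that("single-gene scan keeps only genes with defined networks", {
  inter <- toy_interactome() # vertices A, B, C
  samples <- toy_samples(c("s1", "s2"), c("case", "control"))
  carr <- list(case = list(A = "s1", B = "s1"), control = list(),
               n_case = 1L, n_control = 1L, genes = c("A", "B", "C"))
  res <- component_gene_scan(c("A", "C", "ZZZ"), inter, carr, n_perm = 20,
                             seed = 1)
  expect_false("ZZZ" %in% res$name) # absent from the interactome
  expect_true(all(res$family_size == 1L))
  # A's first-degree network is {A, B}: both informative case-only genes
  a_row <- res[res$name == "A", ]
  expect_equal(a_row$network_size, 2L)
  expect_equal(a_row$case_carriers, 1L)
  # a neighbourless vertex reduces to its own carriers
  lone <- interactome(data.frame(source = "A", target = "B"),
                      all_symbols = "Z")
  carr_z <- list(case = list(Z = "s1"), control = list(), n_case = 1L,
                 n_control = 1L, genes = "Z")
  rz <- component_gene_scan("Z", lone, carr_z, n_perm = 10, seed = 1)
  expect_equal(rz$network_size, 1L)
  expect_equal(rz$case_carriers, 1L)
})
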