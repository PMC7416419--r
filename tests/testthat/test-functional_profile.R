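test_that("KO abundance sums distinct-contig read depths", {
  contigs <- tibble::tibble(contig_id = c("c1", "c2", "c3"),
                            sample_id = "s1",
                            length_bp = 1000L, read_depth = c(10, 5, 2))
  ko <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                       contig_id = c("c1", "c2", "c1", "c1"),
                       ko = c("K1", "K1", "K2", "K2"))
  out <- ko_abundance(contigs, ko)
  expect_equal(out$abundance[out$ko == "K1"], 15)
  # two genes with the same KO on one contig count that contig once
  expect_equal(out$abundance[out$ko == "K2"], 10)
  # absent KO is simply absent (treated as 0 downstream)
  expect_false("K9" %in% out$ko)
  # unknown contig reference is an error
  expect_error(ko_abundance(contigs,
                            tibble::tibble(gene_id = "g", contig_id = "cX",
                                           ko = "K1")),
               "unknown contig")
})

test_that("pathway normalization reproduces the worked arithmetic", {
  # one sample with KO depth 6+4=10 and KO-contig depth 100; a second
  # sample bulks the dataset mean KO-contig depth up to 200
  contigs <- tibble::tibble(
    contig_id = c("a1", "a2", "a3", "b1"),
    sample_id = c("s1", "s1", "s1", "s2"),
    length_bp = 1000L,
    read_depth = c(6, 4, 90, 300))
  ko <- tibble::tibble(gene_id = paste0("g", 1:4),
                       contig_id = c("a1", "a2", "a3", "b1"),
                       ko = c("KO1", "KO2", "KO3", "KO3"))
  pw <- list(pathway_def("P", c("KO1", "KO2")))
  out <- pathway_abundance(contigs, ko, pw)
  expect_equal(out$P[out$sample_id == "s1"], 10 / 100 * 200)
})

test_that("single-sample normalization is the identity", {
  contigs <- tibble::tibble(contig_id = c("c1", "c2"), sample_id = "s1",
                            length_bp = 1000L, read_depth = c(7, 3))
  ko <- tibble::tibble(gene_id = c("g1", "g2"), contig_id = c("c1", "c2"),
                       ko = c("K1", "K2"))
  out <- pathway_abundance(contigs, ko, list(pathway_def("P", "K1")))
  expect_equal(out$P, 7)  # the two normalization factors cancel at N = 1
})

test_that("equal KO-contig depth leaves between-sample ratios unchanged", {
  contigs <- tibble::tibble(contig_id = c("c1", "c2", "d1", "d2"),
                            sample_id = c("s1", "s1", "s2", "s2"),
                            length_bp = 1000L,
                            read_depth = c(30, 70, 60, 40))
  ko <- tibble::tibble(gene_id = paste0("g", 1:4),
                       contig_id = c("c1", "c2", "d1", "d2"),
                       ko = c("K1", "K2", "K1", "K2"))
  out <- pathway_abundance(contigs, ko, list(pathway_def("P", "K1")))
  expect_equal(out$P[out$sample_id == "s1"] / out$P[out$sample_id == "s2"],
               30 / 60)
})

test_that("rescaling all read depths rescales normalized abundances", {
  withr::local_seed(5)
  contigs <- tibble::tibble(contig_id = paste0("c", 1:12),
                            sample_id = rep(c("s1", "s2", "s3"), each = 4),
                            length_bp = 1000L,
                            read_depth = stats::rexp(12, 1 / 10))
  ko <- tibble::tibble(gene_id = paste0("g", 1:12),
                       contig_id = paste0("c", 1:12),
                       ko = sample(c("K1", "K2", "K3"), 12, replace = TRUE))
  pw <- list(pathway_def("P", c("K1", "K2")),
             pathway_def("Q", "K3", aggregation = "mean"))
  base <- pathway_abundance(contigs, ko, pw)
  scaled <- pathway_abundance(
    dplyr::mutate(contigs, read_depth = .data$read_depth * 4), ko, pw)
  expect_equal(scaled$P, base$P * 4, tolerance = 1e-12)
  expect_equal(scaled$Q, base$Q * 4, tolerance = 1e-12)
})

test_that("mean aggregation averages member KO abundances", {
  contigs <- tibble::tibble(contig_id = c("c1", "c2"), sample_id = "s1",
                            length_bp = 1000L, read_depth = c(6, 4))
  ko <- tibble::tibble(gene_id = c("g1", "g2"), contig_id = c("c1", "c2"),
                       ko = c("K1", "K2"))
  s <- pathway_abundance(contigs, ko, list(pathway_def("P", c("K1", "K2"))))
  m <- pathway_abundance(contigs, ko,
                         list(pathway_def("P", c("K1", "K2"),
                                          aggregation = "mean")))
  expect_equal(s$P, 10)
  expect_equal(m$P, 5)
})

test_that("role assignment scores match the classic local-alignment scheme", {
  lib <- tibble::tibble(role = c("sox", "dsr"),
                        sequence = c("MKVLAADTGRENNKWLQERV", "MAVDLQHW"))
  # identical query: score 2 * length, role of that reference
  out <- assign_role("MKVLAADTGRENNKWLQERV", lib)
  expect_equal(out$score, 40)
  expect_equal(out$role, "sox")
  expect_false(out$tie)

  # two identical references under different roles tie, first role wins
  lib2 <- tibble::tibble(role = c("b_role", "a_role"),
                         sequence = c("MKVLAA", "MKVLAA"))
  out2 <- assign_role("MKVLAA", lib2)
  expect_equal(out2$role, "a_role")
  expect_true(out2$tie)

  expect_error(assign_role("MKV", lib[0, ]), "empty")
})

test_that("alignment engine agrees with brute-force affine DP", {
  # exhaustive on short sequences over a 3-letter alphabet
  alpha <- c("A", "K", "V")
  seqs <- unlist(lapply(1:3, function(L) {
    apply(do.call(expand.grid, rep(list(alpha), L)), 1, paste, collapse = "")
  }))
  seqs <- unique(seqs)
  # scores are accumulated and compared once; Biostrings carries fractional
  # penalties in single precision, hence the 1e-5 tolerance
  worst <- 0
  for (a in seqs) for (b in seqs) {
    worst <- max(worst, abs(meromix:::local_align_score(a, b) -
                              oracle_local_align(a, b)))
  }
  expect_lt(worst, 1e-5)
})

test_that("alignment engine matches DP oracle on random longer pairs", {
  withr::local_seed(17)
  alpha <- c("A", "C", "D", "E", "G", "K", "M", "V")
  worst <- 0; worst_sym <- 0
  for (i in 1:150) {
    a <- paste(sample(alpha, sample(4:10, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(4:10, 1), replace = TRUE), collapse = "")
    s_ab <- meromix:::local_align_score(a, b)
    worst <- max(worst, abs(s_ab - oracle_local_align(a, b)))
    worst_sym <- max(worst_sym, abs(s_ab - meromix:::local_align_score(b, a)))
  }
  expect_lt(worst, 1e-5)
  expect_lt(worst_sym, 1e-5)
  # self-alignment is 2 * length
  expect_equal(meromix:::local_align_score("ACDEGKMV", "ACDEGKMV"), 16)
})

test_that("pathway definitions round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- name: Sulfur oxidation",
               "  ko_terms: [K11180, K11181]",
               "- name: Methanogenesis",
               "  ko_terms: [K00399]",
               "  aggregation: mean"), path)
  defs <- read_pathway_defs(path)
  expect_length(defs, 2)
  expect_equal(defs[[1]]$aggregation, "sum")
  expect_equal(defs[[2]]$aggregation, "mean")
  expect_equal(defs[[1]]$ko_terms, c("K11180", "K11181"))
})
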