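# Generators: determinism, parameter recovery, planted-signal power.

test_that("all generators are deterministic under a fixed seed", {
  c1 <- meta_sim_config(seed = 42)
  expect_identical(simulate_meta_studies(c1), simulate_meta_studies(c1))
  genes <- sprintf("g%02d", 1:15)
  cc <- corpus_sim_config(200, genes, enriched_genes = genes[1:3], seed = 42)
  expect_identical(simulate_corpus(cc), simulate_corpus(cc))
  pc <- predictor_sim_config(genes, true_targets = genes[1:5], seed = 42)
  expect_identical(simulate_predictions(pc), simulate_predictions(pc))
  s1 <- simulate_genesets_and_edges(genes, n_sets = 5, set_size_range = c(3, 8),
                                    n_edges = 20, seed = 42)
  s2 <- simulate_genesets_and_edges(genes, n_sets = 5, set_size_range = c(3, 8),
                                    n_edges = 20, seed = 42)
  expect_identical(s1, s2)
  # and files are byte-identical
  f1 <- tempfile(); f2 <- tempfile()
  write_gmt(s1$collection, f1); write_gmt(s2$collection, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed changes the draw
  expect_false(identical(simulate_meta_studies(c1),
                         simulate_meta_studies(meta_sim_config(seed = 43))))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(999); before <- .Random.seed
  invisible(simulate_meta_studies(meta_sim_config(seed = 1)))
  invisible(simulate_corpus(corpus_sim_config(50, c("A", "B"), seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("huge arms pin per-study g at the true effect", {
  st <- simulate_meta_studies(meta_sim_config(
    n_studies = 5, delta = 0.63, tau = 0,
    n_case_range = c(10000, 10000), n_control_range = c(10000, 10000),
    seed = 8))
  g <- study_effects(st)$g
  expect_true(all(abs(g - 0.63) < 0.05))  # ~3.5 SE at n = 10000 per arm
})

test_that("null meta-simulations pool to zero", {
  pooled <- vapply(1:200, function(r) {
    st <- simulate_meta_studies(meta_sim_config(
      n_studies = 50, delta = 0, tau = 0, seed = 30000 + r))
    pool_random_effects(study_effects(st))$smd
  }, numeric(1))
  expect_lt(abs(mean(pooled)), 0.05)
  expect_gt(mean(abs(pooled) < 0.1), 0.95)
})

test_that("per-study effects recover delta and tau at large study counts", {
  cfg <- meta_sim_config(n_studies = 500, delta = 0.63, tau = 0.23, seed = 21)
  st <- simulate_meta_studies(cfg)
  g <- study_effects(st)$g
  se_mean <- sd(g) / sqrt(length(g))
  expect_lt(abs(mean(g) - 0.63), 3 * se_mean)
  true_eff <- attr(st, "true_effects")
  # sd of a 500-draw variance estimate is tau^2 * sqrt(2/499) ~ 0.0034
  expect_lt(abs(var(true_eff) - 0.23^2), 0.011)
})

test_that("config invariants are enforced", {
  expect_error(meta_sim_config(tau = -0.1), "tau")
  expect_error(meta_sim_config(n_case_range = c(1, 10)), "lower bound")
  expect_error(meta_sim_config(n_case_range = c(10, 5)), "ranges")
  expect_error(corpus_sim_config(100, character(0)), "non-empty")
  expect_error(corpus_sim_config(100, "A", disease_doc_rate = 1.2), "rates")
  expect_error(corpus_sim_config(100, "A", enriched_genes = "B"), "subset")
  expect_error(predictor_sim_config("A", n_tools = 0), "n_tools")
  expect_error(predictor_sim_config(c("A", "B"), hit_rate_true = 0.1,
                                    hit_rate_false = 0.5), "exceed")
  expect_error(simulate_genesets_and_edges(c("A", "B"), set_size_range = c(1, 5)),
               "exceeds")
})

test_that("a disease-free corpus yields n = 0, k = 0 and p = 1 everywhere", {
  genes <- sprintf("g%02d", 1:10)
  co <- simulate_corpus(corpus_sim_config(300, genes, disease_doc_rate = 0, seed = 5))
  expect_equal(sum(co$mentions$disease_flag), 0)
  rk <- rank_genes(co$mentions, genes = genes, n_docs = co$n_docs)
  expect_true(all(rk$n == 0))
  expect_true(all(rk$k == 0))
  expect_true(all(rk$p == 1))
})

test_that("null corpus p-values are conservative against uniform", {
  # multiplier 1 for every gene: the discrete test should reject at most
  # its nominal rate, so the empirical CDF must not exceed the uniform one
  # by more than one-sided KS noise
  ps <- unlist(lapply(1:40, function(r) {
    co <- simulate_corpus(corpus_sim_config(
      200, sprintf("g%02d", 1:10), gene_doc_rate = 0.1, seed = 60000 + r))
    rank_genes(co$mentions, n_docs = co$n_docs)$p
  }))
  for (a in c(0.01, 0.05, 0.1, 0.25))
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / length(ps)))
})

test_that("a strongly enriched gene is detected in most corpora", {
  hits <- vapply(1:25, function(r) {
    genes <- sprintf("g%02d", 1:20)
    co <- simulate_corpus(corpus_sim_config(
      2000, genes, enriched_genes = "G01", multiplier = 20, seed = 70000 + r))
    rk <- rank_genes(co$mentions, genes = genes, n_docs = co$n_docs)
    rk$p[rk$gene == "G01"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("prediction matrices have the configured shape and planted truth", {
  genes <- sprintf("g%03d", 1:60)
  targets <- genes[1:12]
  noiseless <- simulate_predictions(predictor_sim_config(
    genes, true_targets = targets, hit_rate_true = 1, hit_rate_false = 0, seed = 2))
  expect_equal(ncol(noiseless), 11)
  expect_identical(colnames(noiseless), MIRNA_PREDICTION_TOOLS)
  for (thr in c(1, 4, 11))
    expect_setequal(consensus_targets(noiseless, thr)$gene, toupper(targets))
  noisy <- simulate_predictions(predictor_sim_config(
    sprintf("g%03d", 1:400), true_targets = sprintf("g%03d", 1:200),
    hit_rate_true = 0.8, hit_rate_false = 0.1, seed = 3))
  called <- consensus_targets(noisy, 4)$gene
  recall <- length(intersect(called, toupper(sprintf("g%03d", 1:200)))) / 200
  expect_gt(recall, 0.95)  # binomial tail: P[Bin(11, 0.8) >= 4] ~ 0.9998
})

test_that("gene-set and edge simulation honours shapes and the empty case", {
  genes <- sprintf("g%02d", 1:30)
  sim <- simulate_genesets_and_edges(genes, n_sets = 5, set_size_range = c(3, 6),
                                     n_edges = 15, seed = 6)
  f <- tempfile(fileext = ".gmt")
  write_gmt(sim$collection, f)
  expect_length(readLines(f), 5)
  expect_true(all(vapply(sim$collection$sets, anyDuplicated, numeric(1)) == 0))
  expect_true(all(sim$edges$source != sim$edges$target))
  # n_edges = 0: empty edge list degrades gracefully downstream
  sim0 <- simulate_genesets_and_edges(genes, n_sets = 3, set_size_range = c(3, 6),
                                      n_edges = 0, seed = 6)
  expect_equal(nrow(sim0$edges), 0)
  g <- build_network(sim0$edges)
  expect_equal(length(connectivity(g)), 0)
})

test_that("study and mention tables round-trip through their TSV formats", {
  st <- simulate_meta_studies(meta_sim_config(n_studies = 4, seed = 12))
  f <- tempfile(fileext = ".tsv")
  write_studies_tsv(st, f)
  back <- read_studies_tsv(f)
  back <- back[match(st$study_id, back$study_id), ]
  rownames(back) <- NULL
  expect_equal(back$n_case, st$n_case)
  expect_equal(back$mean_control, st$mean_control, tolerance = 1e-12)
  co <- simulate_corpus(corpus_sim_config(40, c("A", "B", "C"), seed = 12))
  f2 <- tempfile(fileext = ".tsv")
  write_mentions_tsv(co$mentions, f2)
  back2 <- read_mentions_tsv(f2)
  expect_equal(back2$disease_flag, co$mentions$disease_flag)
  expect_equal(back2$genes, co$mentions$genes)
})
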