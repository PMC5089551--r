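test_that("zero mutation rate propagates the founder unchanged", {
  panel <- load_panel("YFILER")
  ped <- generate_pedigree(3, 4, branching = 1.6, seed = 5)
  model <- flat_mutation_model(panel, 0)
  sim <- simulate_haplotypes(ped, default_founder(panel), model, seed = 1)
  f <- default_founder(panel)
  for (col in panel$columns)
    expect_true(all(sim$haplotypes[[col]] == f[[col]]))
  expect_equal(nrow(sim$truth), 0)
})

test_that("simulation is deterministic under a seed", {
  panel <- load_panel("RM13")
  ped <- generate_pedigree(4, 5, branching = 1.7, seed = 8)
  model <- default_mutation_model(panel)
  s1 <- simulate_haplotypes(ped, default_founder(panel), model, seed = 33)
  s2 <- simulate_haplotypes(ped, default_founder(panel), model, seed = 33)
  expect_identical(s1, s2)
  p1 <- generate_pedigree(3, 4, seed = 77)
  p2 <- generate_pedigree(3, 4, seed = 77)
  expect_identical(p1$father, p2$father)
  st1 <- generate_study_pedigrees(seed = 3)
  st2 <- generate_study_pedigrees(seed = 3)
  expect_identical(st1$couples, st2$couples)
})

test_that("per-edge mutation frequency matches the model rate", {
  # single father-son edge, one high-rate locus, binomial expectation oracle
  panel <- load_panel("YFILER")
  ped <- pedigree(data.frame(child = "s", father = "f"), sampled = "s")
  rates <- stats::setNames(rep(0, 17), panel$columns)
  rates["DYS393"] <- 0.5
  model <- mutation_model(rates, p_multistep = 0)
  set.seed(12)
  n <- 3000
  hits <- sum(replicate(n, {
    sim <- simulate_haplotypes(ped, default_founder(panel), model)
    nrow(sim$truth)
  }))
  se <- sqrt(n * 0.5 * 0.5)
  expect_lt(abs(hits - n * 0.5), 3.5 * se)
})

test_that("truth-log event totals match the analytic expectation", {
  # reference per-locus rates over the study pedigrees: E[events] = sum(mu) * NGEN
  panel <- load_panel("RM13")
  model <- default_mutation_model(panel)
  ped <- generate_pedigree(4, 6, branching = 1.5, seed = 21)
  n_edges <- length(ped$father)
  lambda <- sum(model$rates) * n_edges  # events occur on every edge
  set.seed(22)
  reps <- 60
  tot <- sum(replicate(reps, {
    nrow(simulate_haplotypes(ped, default_founder(panel), model)$truth)
  }))
  se <- sqrt(reps * lambda)  # Poisson-binomial spread, approx
  expect_lt(abs(tot - reps * lambda), 4 * se)
})

test_that("generated pedigrees always validate and respect feasibility", {
  set.seed(44)
  for (i in 1:100) {
    ped <- generate_pedigree(n_sampled = sample(2:4, 1),
                             max_depth = sample(3:6, 1), branching = 1.8,
                             pedigree_id = "gp")
    expect_s3_class(ped, "pedigree")
    expect_gte(steiner_meioses(ped), 2)
  }
  expect_error(generate_pedigree(50, 1, branching = 1, seed = 1),
               "infeasible")
})

test_that("study pedigrees emulate the deep-pedigree design dimensions", {
  st <- study_fixture()
  expect_length(st$pedigrees, 26)
  expect_equal(nrow(st$couples), 27)
  expect_true(all(st$couples$meioses %in% 1:4))
  ngen <- sum(vapply(st$pedigrees, steiner_meioses, 1L))
  expect_gt(ngen, 400)
  expect_lt(ngen, 560)
  # pairwise separations populate the diachronic bins
  expect_true(any(st$pairs$meioses <= 10))
  expect_true(any(st$pairs$meioses > 10 & st$pairs$meioses <= 20))
  expect_true(any(st$pairs$meioses > 20 & st$pairs$meioses <= 26))
  # couple pairs tagged B, distant pairs A
  expect_equal(sum(st$pairs$dataset_tag == "B"), 27)
})

test_that("lineage datasets are degenerate at zero divergence and labelled", {
  panel <- load_panel("RM13")
  model <- default_mutation_model(panel)
  f <- default_founder(panel)
  ld0 <- generate_lineage_dataset(3, 4, 0, 0, model, f, seed = 2)
  expect_equal(nrow(unique(ld0$haplotypes[panel$columns])), 1)
  ld9 <- generate_lineage_dataset(9, 2, 5, 2, model, f, seed = 2)
  expect_length(unique(ld9$labels), 9)
  expect_true("R-M269*" %in% ld9$labels)
})

test_that("couple construction matches a brute-force all-pairs filter", {
  panel <- load_panel("YFILER")
  haps <- founder_table(sprintf("s%d", 1:5), panel)
  haps$DYS393[2] <- haps$DYS393[2] + 1  # s2 one step away
  haps$DYS390[3] <- haps$DYS390[3] + 2  # s3 two steps away
  cp <- make_couples(haps, panel, max_step_distance = 1)
  # brute force: all pairs with distance <= 1
  dist <- function(i, j) sum(abs(as.numeric(haps[i, panel$columns]) -
                                 as.numeric(haps[j, panel$columns])))
  expected <- 0L
  for (i in 1:4) for (j in (i + 1):5)
    if (dist(i, j) <= 1) expected <- expected + 1L
  expect_equal(nrow(cp), expected)
  # threshold edge: the two-step pair is excluded
  expect_false(any(cp$sample_a == "s3" | cp$sample_b == "s3"))
  # C1/C2 tagging by labels
  cp2 <- make_couples(haps, panel, Inf, labels = c("g1", "g1", "g2", "g2",
                                                   "g2"))
  expect_equal(sum(cp2$dataset_tag == "C1"), 1 + 3)  # within g1 + within g2
  expect_equal(sum(cp2$dataset_tag == "C2"), 6)
})

test_that("alleles are reflected away from zero with a warning", {
  panel <- load_panel("YFILER")
  ped <- pedigree(data.frame(child = "s", father = "f"), sampled = "s")
  rates <- stats::setNames(rep(0, 17), panel$columns)
  rates["DYS393"] <- 1  # certain mutation
  model <- mutation_model(rates, p_multistep = 0)
  f0 <- default_founder(panel)
  f0["DYS393"] <- 0
  set.seed(6)
  got_warning <- FALSE
  for (i in 1:30) {
    res <- withCallingHandlers(
      simulate_haplotypes(ped, f0, model),
      warning = function(w) {
        if (grepl("below zero", conditionMessage(w))) got_warning <<- TRUE
        invokeRestart("muffleWarning")
      })
    expect_gte(res$haplotypes$DYS393[1], 0)
  }
  expect_true(got_warning)
})
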