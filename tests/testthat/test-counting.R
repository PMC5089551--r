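test_that("multi-step differences follow the two counting conventions", {
  panel <- load_panel("RM13")
  a <- default_founder(panel)
  b <- a
  b[["DYF399S1"]] <- a[["DYF399S1"]] + 2  # 36 vs 34 style multi-step
  rel <- pair_mutation_count(a, b, panel, "related")
  unrel <- pair_mutation_count(a, b, panel, "unrelated")
  expect_equal(rel$total_events, 1L)
  expect_equal(unrel$total_events, 2L)
  expect_equal(pair_mutation_count(a, a, panel, "related")$total_events, 0L)
  expect_equal(pair_mutation_count(a, a, panel, "unrelated")$total_events, 0L)
})

test_that("related counts never exceed unrelated counts", {
  panel <- load_panel("RM13")
  set.seed(7)
  f <- default_founder(panel)
  for (i in 1:40) {
    a <- f + sample(-3:3, length(f), replace = TRUE)
    b <- f + sample(-3:3, length(f), replace = TRUE)
    names(a) <- names(b) <- names(f)
    rel <- pair_mutation_count(a, b, panel, "related")
    unrel <- pair_mutation_count(a, b, panel, "unrelated")
    expect_true(all(rel$per_locus_events <= unrel$per_locus_events))
    expect_lte(rel$total_events, unrel$total_events)
  }
})

test_that("parsimony counts one event for a multi-step chain and zero for identity", {
  ped <- pedigree(data.frame(child = c("A", "B"), father = c("B", "C")),
                  sampled = c("A", "C"))
  expect_equal(parsimony_event_count(ped, c(A = 36, C = 34)), 1L)
  expect_equal(parsimony_event_count(ped, c(A = 34, C = 34)), 0L)
  expect_message(
    expect_equal(parsimony_event_count(ped, c(A = 34, C = NA)), 0L),
    "fewer than 2")
})

test_that("parsimony equals exhaustive enumeration on random trees", {
  set.seed(99)
  for (i in 1:60) {
    tr <- random_labeled_tree(n_internal = sample(1:5, 1),
                              n_leaves = sample(2:6, 1),
                              allele_values = 12:16)
    ped <- pedigree(tr$edges, sampled = tr$leaves)
    expect_equal(parsimony_event_count(ped, tr$alleles),
                 brute_force_parsimony(tr$edges, tr$alleles))
  }
})

test_that("parsimony is invariant under relabeling of unsampled individuals", {
  set.seed(13)
  tr <- random_labeled_tree(4, 5, 12:15)
  ped <- pedigree(tr$edges, sampled = tr$leaves)
  relabel <- stats::setNames(sprintf("Z%d", seq_along(tr$internal)),
                             tr$internal)
  e2 <- tr$edges
  for (col in c("child", "father")) {
    hit <- e2[[col]] %in% names(relabel)
    e2[[col]][hit] <- relabel[e2[[col]][hit]]
  }
  ped2 <- pedigree(e2, sampled = tr$leaves)
  expect_equal(parsimony_event_count(ped2, tr$alleles),
               parsimony_event_count(ped, tr$alleles))
})

test_that("pedigree counting matches pair counting on two-leaf pedigrees", {
  panel <- load_panel("RM13")
  model <- default_mutation_model(panel)
  for (seed in 1:10) {
    ped <- pedigree(data.frame(child = c("a1", "a2", "b1", "b2"),
                               father = c("r", "a1", "r", "b1")),
                    sampled = c("a2", "b2"), pedigree_id = "two")
    sim <- simulate_haplotypes(ped, default_founder(panel), model,
                               seed = seed)
    mc <- count_pedigree_mutations(ped, sim$haplotypes, panel)
    pc <- pair_mutation_count(sim$haplotypes[1, ], sim$haplotypes[2, ],
                              panel, "related")
    expect_equal(mc$total_events, pc$total_events)
    expect_equal(mc$total_meioses, 4L)
  }
})

test_that("parsimony never exceeds the true simulated event count", {
  panel <- load_panel("RM13")
  model <- flat_mutation_model(panel, 0.05)  # high rate provokes collisions
  set.seed(31)
  for (i in 1:15) {
    ped <- generate_pedigree(3, 5, branching = 1.6, pedigree_id = "t")
    sim <- simulate_haplotypes(ped, default_founder(panel), model)
    mc <- count_pedigree_mutations(ped, sim$haplotypes, panel)
    expect_lte(mc$total_events, nrow(sim$truth))
    expect_equal(mc$total_events, sum(mc$per_locus_events))
  }
})

test_that("meiosis counting matches graph-search distances", {
  # canonical relationships
  ped <- pedigree(data.frame(
    child = c("f", "s", "b1", "b2", "k1", "k2"),
    father = c("g", "f", "g", "g", "b1", "b2")),
    sampled = c("s", "k1"))
  expect_equal(meioses_between(ped, "f", "s"), 1)
  expect_equal(meioses_between(ped, "b1", "b2"), 2)
  expect_equal(meioses_between(ped, "k1", "k2"), 4)
  # random trees against BFS
  set.seed(55)
  for (i in 1:20) {
    tr <- random_labeled_tree(sample(2:6, 1), sample(2:5, 1), 12:14)
    ped <- pedigree(tr$edges, sampled = tr$leaves)
    pair <- sample(tr$leaves, 2)
    expect_equal(meioses_between(ped, pair[1], pair[2]),
                 bfs_path_length(tr$edges, pair[1], pair[2]))
  }
})

test_that("Steiner meiosis count covers exactly the observable lineages", {
  ped <- pedigree(data.frame(child = c("A", "B", "C", "D"),
                             father = c("B", "C", "D", "E")),
                  sampled = c("A", "C"))
  expect_equal(steiner_meioses(ped), 2)  # edges above C are unobservable
  ped2 <- pedigree(data.frame(child = c("s1", "s2"), father = c("f", "f")),
                   sampled = c("s1", "s2"))
  expect_equal(steiner_meioses(ped2), 2)
})

test_that("couple counting requires complete membership and sums per couple", {
  panel <- load_panel("YFILER")
  haps <- founder_table(c("x", "y"), panel)
  haps$DYS393[2] <- haps$DYS393[2] + 3
  cp <- data.frame(sample_a = "x", sample_b = "y", meioses = 1L,
                   relationship = "father-son", dataset_tag = "B")
  cc <- count_couples(cp, haps, panel, "related")
  expect_equal(cc$events, 1L)
  cc2 <- count_couples(cp, haps, panel, "unrelated")
  expect_equal(cc2$events, 3L)
  cp$sample_b <- "zz"
  expect_error(count_couples(cp, haps, panel), "missing")
})
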