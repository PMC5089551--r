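# Independent oracles used across the suite. These deliberately avoid the
# package's own graph and counting code paths.

# Random rooted tree with `n_internal` unobserved internal nodes and
# `n_leaves` observed leaves; returns edge list + leaf alleles.
random_labeled_tree <- function(n_internal, n_leaves, allele_values) {
  internal <- sprintf("N%d", seq_len(n_internal))
  child <- character(0)
  father <- character(0)
  if (n_internal > 1) {
    for (i in 2:n_internal) {
      child <- c(child, internal[i])
      father <- c(father, internal[sample.int(i - 1L, 1)])
    }
  }
  leaves <- sprintf("L%d", seq_len(n_leaves))
  for (l in leaves) {
    child <- c(child, l)
    father <- c(father, internal[sample.int(n_internal, 1)])
  }
  alleles <- stats::setNames(sample(allele_values, n_leaves, replace = TRUE),
                             leaves)
  list(edges = data.frame(child = child, father = father),
       leaves = leaves, alleles = alleles, internal = internal)
}

# Exhaustive minimum over all assignments of integer states (full observed
# range) to every unobserved node; unit cost per edge whose endpoints differ.
brute_force_parsimony <- function(edges, alleles) {
  states <- seq(min(alleles), max(alleles))
  nodes <- unique(c(edges$child, edges$father))
  free <- setdiff(nodes, names(alleles))
  if (!length(free)) {
    s <- alleles[nodes]
    return(sum(alleles[edges$child] != alleles[edges$father]))
  }
  grid <- as.matrix(expand.grid(rep(list(states), length(free))))
  colnames(grid) <- free
  node_state <- function(v) {
    if (v %in% names(alleles)) rep(alleles[[v]], nrow(grid))
    else grid[, v]
  }
  cost <- integer(nrow(grid))
  for (i in seq_len(nrow(edges)))
    cost <- cost + (node_state(edges$child[i]) != node_state(edges$father[i]))
  min(cost)
}

# Breadth-first shortest path length in the undirected pedigree graph.
bfs_path_length <- function(edges, a, b) {
  adj <- list()
  add <- function(x, y) adj[[x]] <<- c(adj[[x]], y)
  for (i in seq_len(nrow(edges))) {
    add(edges$child[i], edges$father[i])
    add(edges$father[i], edges$child[i])
  }
  dist <- stats::setNames(NA_integer_, a)
  dist[a] <- 0L
  queue <- a
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == b) return(dist[[v]])
    for (w in adj[[v]]) {
      if (is.na(dist[w]) || !w %in% names(dist)) {
        dist[w] <- dist[[v]] + 1L
        queue <- c(queue, w)
      }
    }
  }
  NA_integer_
}

# study-wide fixtures reused by several files (built once per test run)
study_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_study_pedigrees(seed = 424242)
    cache
  }
})

full_panel <- function() combine_panels(load_panel("YFILER"),
                                        load_panel("RM13"))

# 27 close-relative couples: 2 differ on a Yfiler column, 4 on an RM11
# column (one of them at two RM13 columns), 5 more on the RM13-only column
# DYF399S1 -> 2/4/9 differing couples and 10 RM13 events in total
close_couple_fixture <- function() {
  panel <- full_panel()
  ids_a <- sprintf("a%02d", 1:27)
  ids_b <- sprintf("b%02d", 1:27)
  haps <- founder_table(c(ids_a, ids_b), panel)
  bump <- function(id, col, by = 1) {
    i <- match(id, haps$sample_id)
    haps[i, col] <<- haps[i, col] + by
  }
  for (k in 1:2) bump(ids_b[k], "DYS393")        # Yfiler-visible
  for (k in 3:7) bump(ids_b[k], "DYF399S1")      # RM13-only
  for (k in 8:11) bump(ids_b[k], "DYS576")       # RM11 + RM13
  bump(ids_b[8], "DYS627")                       # second RM13 event
  couples <- data.frame(sample_a = ids_a, sample_b = ids_b, meioses = 1L,
                        relationship = "father-son", dataset_tag = "B")
  list(haps = haps, couples = couples)
}

# haplotype table where every listed sample carries the founder profile
founder_table <- function(ids, panel = full_panel()) {
  f <- default_founder(panel)
  tab <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (col in names(f)) tab[[col]] <- rep(f[[col]], length(ids))
  class(tab) <- unique(c("ystr_haplotypes", class(tab)))
  tab
}
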