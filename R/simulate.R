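#' Stepwise mutation model for Y-STR simulation
#'
#' Each meiosis mutates each scored column independently with its per-locus
#' probability. A mutation is one repeat-unit step with probability
#' `1 - p_multistep`; otherwise it is a multi-step event of size
#' `2 + Geometric(step_tail)` repeat units. The direction is +/- with equal
#' probability, so two consecutive mutations at a locus cancel half the
#' time (back-mutation), the homoplasy mechanism inherent to the stepwise
#' model.
#'
#' @param rates Named numeric vector: mutation probability per meiosis for
#'   every scored column.
#' @param p_multistep Probability that a mutation event exceeds one step.
#' @param step_tail Geometric parameter for the extra steps of multi-step
#'   events.
#' @return A `mutation_model` object.
#' @seealso [default_mutation_model()], [flat_mutation_model()]
#' @export
mutation_model <- function(rates, p_multistep = 0.04, step_tail = 0.5) {
  stopifnot(is.numeric(rates), !is.null(names(rates)),
            all(rates >= 0 & rates <= 1),
            p_multistep >= 0, p_multistep < 1,
            step_tail > 0, step_tail <= 1)
  structure(list(rates = rates, p_multistep = p_multistep,
                 step_tail = step_tail),
            class = "mutation_model")
}

# Per-column event counts observed over 470 meioses in deep pedigrees,
# giving the default direct-count rates (events / 470).
.reference_events_470 <- c(
  DYS393 = 2, DYS390 = 3, DYS19 = 2, DYS391 = 1, DYS385a = 2, DYS385b = 0,
  DYS439 = 1, DYS389I = 1, DYS392 = 1, DYS389II = 2, DYS458 = 6,
  DYS437 = 1, DYS448 = 0, YGATAH4 = 1, DYS456 = 1, DYS438 = 0, DYS635 = 2,
  DYS576 = 5, DYF399S1 = 30, DYF387S1 = 6, DYS570 = 2, `DYS526A+B` = 3,
  DYS626 = 3, DYS627 = 9, DYS518 = 6, DYS612 = 5, DYS449 = 2, DYS547 = 7,
  DYF404S1 = 4, DYF403S1a = 12, DYF403S1b = 2)

# Modal allele repeat counts used as the default founder haplotype; absolute
# values are irrelevant to event counting (only differences matter) but keep
# simulated tables realistic.
.reference_founder <- c(
  DYS393 = 13, DYS390 = 24, DYS19 = 14, DYS391 = 11, DYS385a = 11,
  DYS385b = 14, DYS439 = 12, DYS389I = 13, DYS392 = 13, DYS389II = 29,
  DYS458 = 17, DYS437 = 15, DYS448 = 19, YGATAH4 = 12, DYS456 = 16,
  DYS438 = 12, DYS635 = 23, DYS576 = 18, DYF399S1 = 23, DYF387S1 = 36,
  DYS570 = 17, `DYS526A+B` = 38, DYS626 = 31, DYS627 = 21, DYS518 = 38,
  DYS612 = 28, DYS449 = 30, DYS547 = 45, DYF404S1 = 17, DYF403S1a = 46,
  DYF403S1b = 49)

#' Default per-locus mutation model for a panel
#'
#' Rates are the direct-count estimates from deep paternal pedigrees
#' (per-column observed events over 470 meioses), of order 1e-3 for the
#' Yfiler columns and up to 6e-2 for the most mutable RM column (DYF399S1).
#'
#' @param panel A [load_panel()] object (combined panels accepted).
#' @inheritParams mutation_model
#' @return A `mutation_model` over the panel's scored columns.
#' @export
default_mutation_model <- function(panel, p_multistep = 0.04,
                                   step_tail = 0.5) {
  stopifnot(inherits(panel, "ystr_panel"))
  mutation_model(.reference_events_470[panel$columns] / 470,
                 p_multistep, step_tail)
}

#' Mutation model with one flat rate across a panel
#'
#' @param panel A [load_panel()] object.
#' @param rate Per-column, per-meiosis mutation probability.
#' @inheritParams mutation_model
#' @return A `mutation_model`.
#' @export
flat_mutation_model <- function(panel, rate, p_multistep = 0.04,
                                step_tail = 0.5) {
  stopifnot(inherits(panel, "ystr_panel"))
  mutation_model(stats::setNames(rep(rate, panel$scored_locus_count),
                                 panel$columns),
                 p_multistep, step_tail)
}

#' Default founder haplotype for a panel
#'
#' @param panel A [load_panel()] object.
#' @return Named numeric vector of modal allele values over the panel's
#'   scored columns.
#' @export
default_founder <- function(panel) {
  stopifnot(inherits(panel, "ystr_panel"))
  .reference_founder[panel$columns]
}

# One meiosis for one haplotype; returns list(alleles, events) where events
# is NULL or a data frame locus/from/to. Consumes RNG in fixed column order.
.transmit <- function(alleles, model) {
  mu <- model$rates
  hit <- which(stats::runif(length(mu)) < mu)
  if (!length(hit)) return(list(alleles = alleles, events = NULL))
  ev <- vector("list", length(hit))
  for (k in seq_along(hit)) {
    j <- hit[k]
    size <- 1L
    if (stats::runif(1) < model$p_multistep)
      size <- 2L + stats::rgeom(1, model$step_tail)
    sgn <- if (stats::runif(1) < 0.5) -1L else 1L
    from <- alleles[[j]]
    to <- from + sgn * size
    if (to < 0) {
      warning("allele driven below zero at ", names(mu)[j],
              "; reflected to a +", size, " step", call. = FALSE)
      to <- from + size
    }
    alleles[[j]] <- to
    ev[[k]] <- data.frame(locus = names(mu)[j], from = from, to = to)
  }
  list(alleles = alleles, events = do.call(rbind, ev))
}

#' Simulate haplotypes down a paternal pedigree
#'
#' Evolves the founder haplotype along every child-father edge under the
#' stepwise mutation model, one meiosis per edge, and records every mutation
#' event in a truth log. Individuals are processed founders-first in
#' deterministic (depth, then lexicographic) order, so a seed fixes the
#' output exactly.
#'
#' @param ped A [pedigree()].
#' @param founder Named numeric allele vector covering the model's columns;
#'   assigned to the pedigree's founder(s).
#' @param model A [mutation_model()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return List with `haplotypes` (a `ystr_haplotypes` data frame for the
#'   sampled individuals, multi-copy tuples left in simulation order — pass
#'   through [normalize_haplotypes()] for ingest-equivalent tables) and
#'   `truth` (data frame `pedigree_id, child, locus, from, to`, one row per
#'   mutation event anywhere in the pedigree).
#' @export
simulate_haplotypes <- function(ped, founder, model, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(model, "mutation_model"))
  cols <- names(model$rates)
  if (!all(cols %in% names(founder)))
    stop("founder does not cover all model loci", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  founder <- founder[cols]
  # depth-ordered traversal: fathers always precede sons
  depth <- vapply(ped$individuals,
                  function(id) length(.ancestor_path(ped$father, id)) - 1L,
                  integer(1))
  ord <- ped$individuals[order(depth, ped$individuals)]
  haps <- list()
  truth <- list()
  for (id in ord) {
    f <- ped$father[id]
    if (is.na(f)) {
      haps[[id]] <- founder
    } else {
      tr <- .transmit(haps[[unname(f)]], model)
      haps[[id]] <- tr$alleles
      if (!is.null(tr$events)) {
        tr$events <- cbind(pedigree_id = ped$pedigree_id, child = id,
                           tr$events)
        truth[[length(truth) + 1L]] <- tr$events
      }
    }
  }
  out <- data.frame(sample_id = ped$sampled, stringsAsFactors = FALSE)
  for (j in seq_along(cols))
    out[[cols[j]]] <- vapply(ped$sampled, function(id) haps[[id]][[j]], 1)
  class(out) <- unique(c("ystr_haplotypes", class(out)))
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(pedigree_id = character(0), child = character(0),
                           locus = character(0), from = numeric(0),
                           to = numeric(0))
  rownames(truth) <- NULL
  list(haplotypes = out, truth = truth)
}

# evolve one haplotype through n meioses, ignoring the truth log
.evolve_chain <- function(alleles, n, model) {
  for (i in seq_len(n)) alleles <- .transmit(alleles, model)$alleles
  alleles
}

#' Generate a random paternal pedigree
#'
#' Grows a genealogy from a single founder: every man above the maximum
#' depth has `1 + Poisson(branching - 1)` sons, and `n_sampled` of the
#' final-generation men are marked as sampled. Deterministic under a seed.
#'
#' @param n_sampled Number of sampled individuals (>= 2).
#' @param max_depth Generations between founder and sampled men (>= 1).
#' @param branching Mean number of sons per man (>= 1).
#' @param seed Integer seed, or `NULL`.
#' @param pedigree_id Identifier.
#' @return A validated [pedigree()].
#' @export
generate_pedigree <- function(n_sampled, max_depth, branching = 1.4,
                              seed = NULL, pedigree_id = "sim") {
  stopifnot(n_sampled >= 2, max_depth >= 1, branching >= 1)
  if (!is.null(seed)) set.seed(seed)
  grow <- function() {
    counter <- 1L
    new_id <- function() {
      id <- sprintf("I%04d", counter)
      counter <<- counter + 1L
      id
    }
    root <- new_id()
    frontier <- root
    child <- character(0)
    father <- character(0)
    for (d in seq_len(max_depth)) {
      nxt <- character(0)
      for (f in frontier) {
        ns <- 1L + stats::rpois(1, branching - 1)
        for (s in seq_len(ns)) {
          id <- new_id()
          child <- c(child, id)
          father <- c(father, f)
          nxt <- c(nxt, id)
        }
      }
      frontier <- nxt
    }
    list(child = child, father = father, leaves = frontier)
  }
  # branching draws occasionally leave too few final-generation men; regrow
  # a bounded number of times before declaring the parameters infeasible
  for (try in 1:100) {
    g <- grow()
    if (length(g$leaves) >= n_sampled) {
      sampled <- sort(sample(g$leaves, n_sampled))
      return(pedigree(data.frame(child = g$child, father = g$father),
                      sampled, pedigree_id))
    }
  }
  stop("infeasible parameters: tree capacity below ", n_sampled,
       " sampled individuals", call. = FALSE)
}

# --- deep-pedigree study design -------------------------------------------

# star of disjoint chains below a root; sampled at the chain tips
.chain_star_pedigree <- function(depths, pedigree_id) {
  child <- character(0); father <- character(0); sampled <- character(0)
  root <- paste0(pedigree_id, "_R")
  for (i in seq_along(depths)) {
    prev <- root
    for (d in seq_len(depths[i])) {
      id <- sprintf("%s_c%d_%d", pedigree_id, i, d)
      child <- c(child, id); father <- c(father, prev)
      prev <- id
    }
    sampled <- c(sampled, prev)
  }
  pedigree(data.frame(child = child, father = father), sampled, pedigree_id)
}

# a close-relative couple hanging below junction node `j`; returns updated
# edge lists plus the two sampled IDs and their meiosis separation
.attach_couple <- function(relationship, j, prefix) {
  e <- function(child, father) data.frame(child = child, father = father)
  switch(relationship,
    "father-son" = {
      x <- paste0(prefix, "_f"); y <- paste0(prefix, "_s")
      list(edges = rbind(e(x, j), e(y, x)), sampled = c(x, y), meioses = 1L)
    },
    "brothers" = {
      x <- paste0(prefix, "_b1"); y <- paste0(prefix, "_b2")
      list(edges = rbind(e(x, j), e(y, j)), sampled = c(x, y), meioses = 2L)
    },
    "uncle-nephew" = {
      u <- paste0(prefix, "_u"); w <- paste0(prefix, "_w")
      z <- paste0(prefix, "_n")
      list(edges = rbind(e(u, j), e(w, j), e(z, w)), sampled = c(u, z),
           meioses = 3L)
    },
    "cousins" = {
      w1 <- paste0(prefix, "_w1"); w2 <- paste0(prefix, "_w2")
      x <- paste0(prefix, "_k1"); y <- paste0(prefix, "_k2")
      list(edges = rbind(e(w1, j), e(w2, j), e(x, w1), e(y, w2)),
           sampled = c(x, y), meioses = 4L)
    },
    stop("unknown relationship: ", relationship, call. = FALSE)
  )
}

#' Generate the deep-pedigree study genealogies
#'
#' Builds a set of paternal pedigrees emulating a two-population deep-rooted
#' pedigree study: `n_deep` pedigrees of 2-3 distantly related sampled men
#' (disjoint chains of 5-9 meioses from a common founder), and `n_couple`
#' pedigrees carrying close-relative couples (father-son, brothers,
#' uncle-nephew or cousins) at the tips of two deep branches; the last
#' couple-pedigree carries a single couple plus two distant singletons, so
#' the design yields `2 * n_couple - 1` close couples. With the defaults
#' (12 + 14 pedigrees) the genealogies span roughly 470 observable meioses
#' over 26 pedigrees, with close couples 1-4 meioses apart and distant
#' pairs up to 26.
#'
#' @param seed Integer seed, or `NULL`.
#' @param n_deep Number of distant-relative pedigrees.
#' @param n_couple Number of couple-bearing pedigrees.
#' @return List with `pedigrees` (list of [pedigree()]), `couples` (close
#'   couples: `sample_a, sample_b, meioses, relationship, dataset_tag =
#'   "B"`), and `pairs` (every within-pedigree sampled pair with its meiosis
#'   separation, the close couples tagged `"B"` and the rest `"A"`).
#' @export
generate_study_pedigrees <- function(seed = NULL, n_deep = 12,
                                     n_couple = 14) {
  if (!is.null(seed)) set.seed(seed)
  rels <- c("father-son", "brothers", "uncle-nephew", "cousins")
  peds <- list()
  couples <- list()
  for (i in seq_len(n_deep)) {
    id <- sprintf("D%02d", i)
    k <- if (i %% 2 == 0) 2L else 3L
    peds[[id]] <- .chain_star_pedigree(sample(5:9, k, replace = TRUE), id)
  }
  for (i in seq_len(n_couple)) {
    id <- sprintf("C%02d", i)
    root <- paste0(id, "_R")
    edges <- NULL
    sampled <- character(0)
    n_cpl <- if (i == n_couple) 1L else 2L
    for (b in seq_len(n_cpl)) {
      g <- sample(5:9, 1)
      prev <- root
      for (d in seq_len(g)) {
        nid <- sprintf("%s_j%d_%d", id, b, d)
        edges <- rbind(edges, data.frame(child = nid, father = prev))
        prev <- nid
      }
      rel <- sample(rels, 1)
      cpl <- .attach_couple(rel, prev, sprintf("%s_q%d", id, b))
      edges <- rbind(edges, cpl$edges)
      sampled <- c(sampled, cpl$sampled)
      couples[[length(couples) + 1L]] <- data.frame(
        sample_a = cpl$sampled[1], sample_b = cpl$sampled[2],
        meioses = cpl$meioses, relationship = rel, dataset_tag = "B")
    }
    if (n_cpl == 1L) {  # two distant singletons complete the last pedigree
      for (b in 2:3) {
        g <- sample(5:9, 1)
        prev <- root
        for (d in seq_len(g)) {
          nid <- sprintf("%s_j%d_%d", id, b, d)
          edges <- rbind(edges, data.frame(child = nid, father = prev))
          prev <- nid
        }
        sampled <- c(sampled, prev)
      }
    }
    peds[[id]] <- pedigree(edges, sampled, id)
  }
  couples <- do.call(rbind, couples)
  # every within-pedigree sampled pair, with meioses; close couples keep tag B
  pairs <- list()
  for (ped in peds) {
    s <- ped$sampled
    if (length(s) < 2L) next
    for (i in seq_len(length(s) - 1L)) for (j in seq(i + 1L, length(s))) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        pedigree_id = ped$pedigree_id, sample_a = s[i], sample_b = s[j],
        meioses = meioses_between(ped, s[i], s[j]))
    }
  }
  pairs <- do.call(rbind, pairs)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pairs$dataset_tag <- ifelse(key(pairs$sample_a, pairs$sample_b) %in%
                                key(couples$sample_a, couples$sample_b),
                              "B", "A")
  list(pedigrees = peds, couples = couples, pairs = pairs)
}

#' Generate a clustered lineage dataset (star-of-stars genealogy)
#'
#' Emulates a set of unrelated men from diverged sub-lineages of one
#' haplogroup: group founders diverge from a common root haplotype by
#' `divergence_meioses` meioses, and each sample diverges from its group
#' founder by `within_meioses` meioses. With 9 groups the labels are the
#' canonical R-M269 sub-lineage names.
#'
#' @param n_groups Number of sub-lineages (>= 2).
#' @param samples_per_group Samples per sub-lineage.
#' @param divergence_meioses Meioses from the common root to each group
#'   founder.
#' @param within_meioses Meioses from the group founder to each sample.
#' @param model A [mutation_model()].
#' @param founder Root haplotype (default [default_founder()] is not used
#'   here because the model fixes the columns; pass a named vector covering
#'   them).
#' @param seed Integer seed, or `NULL`.
#' @return List with `haplotypes` (`ystr_haplotypes` data frame) and
#'   `labels` (character vector of group labels, aligned with rows).
#' @export
generate_lineage_dataset <- function(n_groups = 9, samples_per_group = 10,
                                     divergence_meioses = 40,
                                     within_meioses = 15, model, founder,
                                     seed = NULL) {
  stopifnot(n_groups >= 2, samples_per_group >= 1,
            divergence_meioses >= 0, within_meioses >= 0,
            inherits(model, "mutation_model"))
  if (!is.null(seed)) set.seed(seed)
  cols <- names(model$rates)
  if (!all(cols %in% names(founder)))
    stop("founder does not cover all model loci", call. = FALSE)
  founder <- founder[cols]
  group_names <- if (n_groups == 9)
    c("R-M269*", "R-U106", "R-L48", "R-P312", "R-SRY2627", "R-U152",
      "R-L2", "R-L20", "R-L21")
  else sprintf("G%02d", seq_len(n_groups))
  rows <- list()
  labels <- character(0)
  for (g in seq_len(n_groups)) {
    gf <- .evolve_chain(founder, divergence_meioses, model)
    for (s in seq_len(samples_per_group)) {
      h <- .evolve_chain(gf, within_meioses, model)
      rows[[length(rows) + 1L]] <- h
      labels <- c(labels, group_names[g])
    }
  }
  out <- data.frame(sample_id = sprintf("S%03d", seq_along(rows)),
                    stringsAsFactors = FALSE)
  for (j in seq_along(cols))
    out[[cols[j]]] <- vapply(rows, `[[`, 1, j)
  class(out) <- unique(c("ystr_haplotypes", class(out)))
  list(haplotypes = out, labels = labels)
}

#' Build couples of near-identical haplotypes
#'
#' Pairs every two samples whose step distance on `panel` (sum of absolute
#' allele differences over scored columns, the unrelated-convention count)
#' is at most `max_step_distance` — the homoplasy selection used to study
#' discrimination between unrelated men with matching Yfiler profiles. A
#' sample may appear in several couples.
#'
#' @param haps Haplotype table.
#' @param panel Panel on which the distance is computed (typically Yfiler).
#' @param max_step_distance Inclusion threshold (>= 0; `Inf` keeps all
#'   pairs).
#' @param labels Optional group labels aligned with `haps` rows; couples are
#'   tagged `C1` (same group) or `C2` (different groups). Without labels all
#'   couples are tagged `C1`.
#' @return Couple data frame
#'   `sample_a, sample_b, meioses (NA), relationship ("unrelated"),
#'   dataset_tag`.
#' @export
make_couples <- function(haps, panel, max_step_distance = 1,
                         labels = NULL) {
  stopifnot(inherits(panel, "ystr_panel"), max_step_distance >= 0)
  n <- nrow(haps)
  m <- as.matrix(haps[panel$columns])
  out <- list()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d <- sum(round(abs(m[i, ] - m[j, ])), na.rm = TRUE)
    if (d <= max_step_distance) {
      tag <- if (is.null(labels)) "C1"
             else if (labels[i] == labels[j]) "C1" else "C2"
      out[[length(out) + 1L]] <- data.frame(
        sample_a = haps$sample_id[i], sample_b = haps$sample_id[j],
        meioses = NA_integer_, relationship = "unrelated",
        dataset_tag = tag)
    }
  }
  if (!length(out))
    return(data.frame(sample_a = character(0), sample_b = character(0),
                      meioses = integer(0), relationship = character(0),
                      dataset_tag = character(0)))
  do.call(rbind, out)
}
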