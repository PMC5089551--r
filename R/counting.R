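#' Maximum-parsimony mutation-event count for one locus on a pedigree
#'
#' Returns the minimum number of father-son transmissions at which the
#' allele changes, over all assignments of alleles to unsampled men on the
#' minimal subtree connecting the informative (non-missing) sampled
#' individuals. Any allele change on an edge costs one event regardless of
#' its size: within a pedigree a multi-step difference (e.g. 36 vs 34) is a
#' single mutation event, because independent hits at the same locus in few
#' meioses are far less probable than one multi-step event. With unit cost
#' the optimum is always achieved using only observed allele states, so the
#' dynamic programme runs over those states (Sankoff-style; equivalent to
#' Fitch parsimony on unordered states).
#'
#' @param ped A [pedigree()].
#' @param leaf_alleles Named numeric vector: allele value per sampled ID.
#'   `NA` entries are dropped and the subtree pruned accordingly.
#' @return Integer event count. Fewer than 2 informative individuals yields
#'   0 with a message.
#' @examples
#' ped <- pedigree(data.frame(child = c("s1", "s2"), father = c("f", "f")),
#'                 sampled = c("s1", "s2"))
#' parsimony_event_count(ped, c(s1 = 36, s2 = 34))  # 1 event
#' @export
parsimony_event_count <- function(ped, leaf_alleles) {
  stopifnot(inherits(ped, "pedigree"))
  obs <- leaf_alleles[!is.na(leaf_alleles)]
  if (length(obs) < 2L) {
    message("fewer than 2 informative individuals; event count is 0")
    return(0L)
  }
  bad <- setdiff(names(obs), ped$individuals)
  if (length(bad))
    stop("observed ID(s) not in pedigree: ", paste(bad, collapse = ", "),
         call. = FALSE)
  states <- sort(unique(unname(obs)))
  if (length(states) == 1L) return(0L)

  edges <- .steiner_edges(ped, names(obs))
  nodes <- unique(c(edges$child, edges$father))
  fa <- stats::setNames(edges$father, edges$child)
  root <- setdiff(nodes, edges$child)
  stopifnot(length(root) == 1L)

  # post-order by depth below the subtree root
  depth <- stats::setNames(integer(length(nodes)), nodes)
  for (v in nodes) {
    d <- 0L; cur <- v
    while (!is.na(fa[cur])) { cur <- unname(fa[cur]); d <- d + 1L }
    depth[v] <- d
  }
  ord <- names(sort(depth, decreasing = TRUE))

  S <- length(states)
  cost <- matrix(0, nrow = length(nodes), ncol = S,
                 dimnames = list(nodes, NULL))
  for (v in nodes) {
    if (v %in% names(obs))
      cost[v, ] <- ifelse(states == obs[[v]], 0, Inf)
  }
  for (v in ord) {
    if (v == root) next
    f <- unname(fa[v])
    below <- pmin(cost[v, ], min(cost[v, ]) + 1)  # keep state vs change (cost 1)
    cost[f, ] <- cost[f, ] + below
  }
  as.integer(min(cost[root, ]))
}

#' Count mutation events in a pedigree across a panel
#'
#' Applies [parsimony_event_count()] to every scored column of the panel and
#' counts the meioses of the minimal subtree connecting the sampled
#' individuals ([steiner_meioses()]). Loci with missing calls contribute
#' their informative subset of men; meioses are counted in full for every
#' scored locus.
#'
#' @param ped A [pedigree()].
#' @param haps `ystr_haplotypes` table holding every sampled individual.
#' @param panel A [load_panel()] object.
#' @return A `mutation_count` object: list with `unit_id`,
#'   `per_locus_events` (named integer over scored columns), `total_events`
#'   (NMUT), `total_meioses` (NGEN) and `convention = "related"`.
#' @export
count_pedigree_mutations <- function(ped, haps, panel) {
  stopifnot(inherits(ped, "pedigree"), inherits(panel, "ystr_panel"))
  idx <- match(ped$sampled, haps$sample_id)
  if (anyNA(idx))
    stop("no haplotype for sampled ID(s): ",
         paste(ped$sampled[is.na(idx)], collapse = ", "), call. = FALSE)
  events <- vapply(panel$columns, function(col) {
    alleles <- stats::setNames(haps[[col]][idx], ped$sampled)
    suppressMessages(parsimony_event_count(ped, alleles))
  }, integer(1))
  mutation_count(ped$pedigree_id, events, steiner_meioses(ped), "related")
}

#' Mutation count between two haplotypes
#'
#' Compares a pair of haplotypes column by column under one of the two
#' counting conventions: for related pairs (within pedigrees) any allele
#' difference at a scored column is one event (36 vs 34 = 1 event); for
#' unrelated pairs each repeat-unit step is an independent event (36 vs
#' 34 = 2 events). Multi-copy tuples are compared copy-wise after sorting,
#' which realises the minimal-total-difference matching. Columns missing in
#' either haplotype are skipped.
#'
#' @param a,b Single haplotype rows (one-row data frames or named vectors
#'   covering the panel columns).
#' @param panel A [load_panel()] object.
#' @param convention `"related"` or `"unrelated"`.
#' @param unit_id Label for the resulting count.
#' @param meioses Optional known meioses separating the pair (NGEN).
#' @return A `mutation_count` object.
#' @export
pair_mutation_count <- function(a, b, panel,
                                convention = c("related", "unrelated"),
                                unit_id = NULL, meioses = NA_integer_) {
  convention <- match.arg(convention)
  stopifnot(inherits(panel, "ystr_panel"))
  av <- .as_allele_vector(a, panel)
  bv <- .as_allele_vector(b, panel)
  d <- abs(av - bv)
  events <- if (convention == "related") as.integer(d > 1e-9)
            else as.integer(round(d))
  events[is.na(d)] <- 0L
  names(events) <- panel$columns
  if (is.null(unit_id))
    unit_id <- paste(attr(av, "sample_id"), attr(bv, "sample_id"), sep = "-")
  mutation_count(unit_id, events, as.integer(meioses), convention)
}

.as_allele_vector <- function(x, panel) {
  sid <- NA_character_
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    if ("sample_id" %in% names(x)) sid <- x$sample_id
    miss <- setdiff(panel$columns, names(x))
    if (length(miss))
      stop("haplotype lacks panel column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    v <- as.numeric(x[1, panel$columns])
  } else {
    miss <- setdiff(panel$columns, names(x))
    if (length(miss))
      stop("haplotype lacks panel column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    v <- as.numeric(x[panel$columns])
  }
  structure(v, sample_id = sid)
}

#' Construct a mutation-count record
#'
#' @param unit_id Pedigree ID or couple key.
#' @param per_locus_events Named non-negative integer vector, one entry per
#'   scored column.
#' @param total_meioses NGEN for the unit (may be `NA` for unrelated pairs).
#' @param convention `"related"` or `"unrelated"`.
#' @return A `mutation_count` object with `total_events = sum(per_locus_events)`.
#' @export
mutation_count <- function(unit_id, per_locus_events, total_meioses,
                           convention) {
  stopifnot(all(per_locus_events >= 0L))
  structure(
    list(unit_id = as.character(unit_id),
         per_locus_events = per_locus_events,
         total_events = as.integer(sum(per_locus_events)),
         total_meioses = as.integer(total_meioses),
         convention = convention),
    class = "mutation_count"
  )
}

#' @export
print.mutation_count <- function(x, ...) {
  cat(sprintf("mutation count '%s' (%s): NMUT=%d, NGEN=%s\n", x$unit_id,
              x$convention, x$total_events,
              ifelse(is.na(x$total_meioses), "NA", x$total_meioses)))
  invisible(x)
}

#' Mutation counts for a table of couples
#'
#' Applies [pair_mutation_count()] to every row of a couple table.
#'
#' @param couples Couple data frame (see [read_couples()]).
#' @param haps Haplotype table covering all members.
#' @param panel A [load_panel()] object.
#' @param convention Counting convention for all couples.
#' @return The couple table with an added integer column `events` (NMUT for
#'   the chosen panel and convention).
#' @export
count_couples <- function(couples, haps, panel,
                          convention = c("related", "unrelated")) {
  convention <- match.arg(convention)
  idx_a <- match(couples$sample_a, haps$sample_id)
  idx_b <- match(couples$sample_b, haps$sample_id)
  if (anyNA(idx_a) || anyNA(idx_b))
    stop("couple member(s) missing from haplotype table", call. = FALSE)
  couples$events <- vapply(seq_len(nrow(couples)), function(i) {
    mc <- pair_mutation_count(haps[idx_a[i], ], haps[idx_b[i], ], panel,
                              convention,
                              meioses = couples$meioses[i])
    mc$total_events
  }, integer(1))
  couples
}

#' Tabulate mutation counts in the NGEN/NMUT summary layout
#'
#' @param counts A list of `mutation_count` objects.
#' @return Data frame `unit_id, NGEN, NMUT, convention`, one row per unit.
#' @export
summarize_counts <- function(counts) {
  stopifnot(length(counts) > 0L,
            all(vapply(counts, inherits, TRUE, "mutation_count")))
  data.frame(
    unit_id = vapply(counts, `[[`, "", "unit_id"),
    NGEN = vapply(counts, `[[`, 1L, "total_meioses"),
    NMUT = vapply(counts, `[[`, 1L, "total_events"),
    convention = vapply(counts, `[[`, "", "convention")
  )
}
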