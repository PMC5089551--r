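#' Construct and validate a paternal pedigree graph
#'
#' A pedigree is a paternal genealogy: a set of men connected by child-father
#' edges, of whom a subset (the sampled individuals) have been genotyped.
#' Unsampled internal men are placeholders whose haplotypes are never
#' observed. Because every individual has at most one father the genealogy is
#' a forest; validation requires that all sampled individuals lie in one
#' connected component, so that mutation events between them are countable.
#'
#' @param edges Data frame with character columns `child` and `father`, one
#'   row per child-father link.
#' @param sampled Character vector of sampled individual IDs.
#' @param pedigree_id Identifier for the pedigree.
#' @return An object of class `pedigree`: list with `pedigree_id`,
#'   `individuals`, `father` (named character vector mapping child to
#'   father), and `sampled`.
#' @examples
#' ped <- pedigree(data.frame(child = c("A", "B"), father = c("B", "C")),
#'                 sampled = c("A", "C"), pedigree_id = "ex")
#' meioses_between(ped, "A", "C")  # 2
#' @export
pedigree <- function(edges, sampled, pedigree_id = "ped") {
  stopifnot(is.data.frame(edges), all(c("child", "father") %in% names(edges)))
  child <- as.character(edges$child)
  father <- as.character(edges$father)
  if (anyNA(child) || anyNA(father) || any(child == "") || any(father == ""))
    stop("pedigree edges must have non-empty child and father IDs",
         call. = FALSE)
  dup <- duplicated(child)
  if (any(dup))
    stop("individual(s) with two fathers: ",
         paste(unique(child[dup]), collapse = ", "), call. = FALSE)
  if (any(child == father))
    stop("individual cannot be its own father: ",
         paste(child[child == father], collapse = ", "), call. = FALSE)
  fmap <- stats::setNames(father, child)
  individuals <- union(child, father)
  # cycle check: walk father chains; a walk longer than the individual count
  # must have revisited someone
  n <- length(individuals)
  for (id in child) {
    cur <- id
    steps <- 0L
    while (!is.na(fmap[cur])) {
      cur <- unname(fmap[cur])
      steps <- steps + 1L
      if (steps > n)
        stop("cycle detected in pedigree involving '", id, "'",
             call. = FALSE)
      if (identical(cur, id))
        stop("cycle detected in pedigree involving '", id, "'",
             call. = FALSE)
    }
  }
  sampled <- as.character(sampled)
  missing_ids <- setdiff(sampled, individuals)
  if (length(missing_ids))
    stop("sampled ID(s) absent from pedigree: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  if (length(sampled) >= 2) {
    roots <- vapply(sampled, function(id) .walk_to_root(fmap, id), "")
    if (length(unique(roots)) > 1L)
      stop("sampled individuals are not all connected through the pedigree",
           call. = FALSE)
  }
  structure(
    list(pedigree_id = as.character(pedigree_id), individuals = individuals,
         father = fmap, sampled = sampled),
    class = "pedigree"
  )
}

.walk_to_root <- function(fmap, id) {
  cur <- id
  while (!is.na(fmap[cur])) cur <- unname(fmap[cur])
  cur
}

# path from id up to the root, inclusive
.ancestor_path <- function(fmap, id) {
  path <- id
  cur <- id
  while (!is.na(fmap[cur])) {
    cur <- unname(fmap[cur])
    path <- c(path, cur)
  }
  path
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree '%s': %d individuals, %d sampled, %d meioses spanned\n",
              x$pedigree_id, length(x$individuals), length(x$sampled),
              tryCatch(steiner_meioses(x), error = function(e) NA_integer_)))
  invisible(x)
}

#' Number of meioses separating two individuals
#'
#' The number of father-son transmissions on the unique genealogical path
#' from `a` up to their most recent common ancestor and down to `b`. A
#' father-son pair is 1 meiosis apart, brothers 2, first cousins 4.
#'
#' @param ped A [pedigree()].
#' @param a,b Individual IDs.
#' @return Integer meiosis count.
#' @export
meioses_between <- function(ped, a, b) {
  stopifnot(inherits(ped, "pedigree"))
  for (id in c(a, b))
    if (!id %in% ped$individuals)
      stop("individual '", id, "' not in pedigree", call. = FALSE)
  pa <- .ancestor_path(ped$father, a)
  pb <- .ancestor_path(ped$father, b)
  common <- intersect(pa, pb)
  if (!length(common))
    stop("individuals '", a, "' and '", b,
         "' are not connected in the pedigree", call. = FALSE)
  lca <- common[1L]  # .ancestor_path lists ancestors bottom-up
  (match(lca, pa) - 1L) + (match(lca, pb) - 1L)
}

#' Meioses spanned by the minimal subtree connecting sampled individuals
#'
#' Mutations are only observable on lineages leading to sampled men, so the
#' generation count (NGEN) of a pedigree is the number of edges of the
#' Steiner subtree of the genealogy spanning the sampled set, not of the
#' full recorded genealogy.
#'
#' @param ped A [pedigree()].
#' @param ids IDs to connect; defaults to the sampled set.
#' @return Integer edge count.
#' @export
steiner_meioses <- function(ped, ids = ped$sampled) {
  stopifnot(inherits(ped, "pedigree"))
  length(.steiner_edges(ped, ids)$child)
}

# Edges (child -> father) of the minimal subtree connecting `ids`.
# An edge is on the subtree iff both sides of its removal contain >= 1 of
# the target ids; with <= 1 father per node this reduces to: the child-side
# subtree contains between 1 and (n-1) targets.
.steiner_edges <- function(ped, ids) {
  ids <- unique(as.character(ids))
  fmap <- ped$father
  if (length(ids) < 2L)
    return(list(child = character(0), father = character(0)))
  paths <- lapply(ids, function(id) .ancestor_path(fmap, id))
  lca <- Reduce(intersect, paths)[1L]
  if (is.na(lca))
    stop("target individuals are not connected", call. = FALSE)
  childs <- unique(unlist(lapply(paths, function(p) {
    k <- match(lca, p)
    if (k == 1L) character(0) else p[seq_len(k - 1L)]
  })))
  list(child = childs, father = unname(fmap[childs]))
}

#' Read a pedigree from a tab-separated edge list
#'
#' The file has a header and columns `child`, `father`, plus either a
#' logical/0-1 column `sampled` flagging each child row, or a companion
#' argument listing the sampled IDs.
#'
#' @param path Path to the edge-list file.
#' @param sampled Optional character vector of sampled IDs, overriding any
#'   `sampled` column.
#' @param pedigree_id Pedigree identifier; defaults to the file name without
#'   extension.
#' @param sep Field separator.
#' @return A validated [pedigree()]. A message reports the number of
#'   individuals, sampled leaves and meioses spanned.
#' @export
read_pedigree <- function(path, sampled = NULL, pedigree_id = NULL,
                          sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("child", "father") %in% names(tab)))
    stop("pedigree file must have 'child' and 'father' columns",
         call. = FALSE)
  if (is.null(sampled)) {
    if (!"sampled" %in% names(tab))
      stop("no 'sampled' column in ", path,
           " and no sampled IDs supplied", call. = FALSE)
    flag <- tab$sampled %in% c("1", "TRUE", "true", "yes")
    sampled <- tab$child[flag]
  }
  if (is.null(pedigree_id))
    pedigree_id <- sub("\\.[^.]*$", "", basename(path))
  # rows with an empty father declare individuals (e.g. sampled founders)
  is_edge <- !is.na(tab$father) & tab$father != ""
  ped <- pedigree(tab[is_edge, c("child", "father")], sampled, pedigree_id)
  message(sprintf("pedigree '%s': %d individuals, %d sampled, %d meioses spanned",
                  ped$pedigree_id, length(ped$individuals),
                  length(ped$sampled), steiner_meioses(ped)))
  ped
}

#' Write a pedigree as a tab-separated edge list
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  child <- names(ped$father)
  tab <- data.frame(child = child, father = unname(ped$father),
                    sampled = as.integer(child %in% ped$sampled))
  # sampled founders have no child row; declare them with an empty father
  founders <- setdiff(ped$sampled, child)
  if (length(founders))
    tab <- rbind(tab, data.frame(child = founders, father = "",
                                 sampled = 1L))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
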