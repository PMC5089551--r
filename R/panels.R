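#' Y-STR panel definitions
#'
#' A panel is an ordered set of scored STR loci. Multi-copy loci (DYS385 in
#' Yfiler, DYF403S1 in the RM set) are scored as separate allele columns
#' suffixed `a`, `b`; each scored column is treated as an independent locus
#' when counting mutations and estimating rates, so the number of scored
#' columns `L` is the panel size used throughout.
#'
#' Three panels are available:
#' \describe{
#'   \item{YFILER}{the 17-locus forensic standard (DYS385 as two columns).}
#'   \item{RM13}{the rapidly mutating set, scored as 14 columns: 12
#'     single-column loci plus DYF403S1a/b. DYS526A and DYS526B are combined
#'     into one scored column (DYS526A+B), and DYF399S1, DYF387S1 and
#'     DYF404S1 are each scored as a single column.}
#'   \item{RM11}{RM13 after removing its two most mutable columns,
#'     DYF399S1 and DYF403S1a (12 scored columns).}
#' }
#'
#' @param name Panel name, one of `"YFILER"`, `"RM13"`, `"RM11"`
#'   (case-insensitive).
#' @return An object of class `ystr_panel`: a list with elements `name`,
#'   `loci` (data frame with columns `locus`, `column`, `copy`, one row per
#'   scored column), `columns` (character vector of scored column names in
#'   panel order) and `scored_locus_count` (`L`, the number of scored
#'   columns).
#' @examples
#' load_panel("YFILER")$scored_locus_count  # 17
#' load_panel("RM11")$columns
#' @export
load_panel <- function(name) {
  key <- toupper(as.character(name)[1])
  def <- switch(key,
    YFILER = .yfiler_loci(),
    RM13 = .rm13_loci(),
    RM11 = {
      l <- .rm13_loci()
      l[!l$column %in% c("DYF399S1", "DYF403S1a"), , drop = FALSE]
    },
    stop("unknown panel name: '", name,
         "' (expected one of YFILER, RM13, RM11)", call. = FALSE)
  )
  rownames(def) <- NULL
  structure(
    list(name = key, loci = def, columns = def$column,
         scored_locus_count = nrow(def)),
    class = "ystr_panel"
  )
}

.yfiler_loci <- function() {
  single <- c("DYS393", "DYS390", "DYS19", "DYS391")
  after <- c("DYS439", "DYS389I", "DYS392", "DYS389II", "DYS458", "DYS437",
             "DYS448", "YGATAH4", "DYS456", "DYS438", "DYS635")
  rbind(
    data.frame(locus = single, column = single, copy = 1L),
    data.frame(locus = "DYS385", column = c("DYS385a", "DYS385b"),
               copy = 1:2),
    data.frame(locus = after, column = after, copy = 1L)
  )
}

.rm13_loci <- function() {
  single <- c("DYS576", "DYF399S1", "DYF387S1", "DYS570", "DYS526A+B",
              "DYS626", "DYS627", "DYS518", "DYS612", "DYS449", "DYS547",
              "DYF404S1")
  rbind(
    data.frame(locus = single, column = single, copy = 1L),
    data.frame(locus = "DYF403S1", column = c("DYF403S1a", "DYF403S1b"),
               copy = 1:2)
  )
}

#' Combine the scored columns of two panels
#'
#' Used for joint analyses such as the Yfiler + RM11 DAPC.
#'
#' @param a,b `ystr_panel` objects.
#' @return A `ystr_panel` whose loci are the concatenation of the two panels'
#'   loci (duplicated columns are dropped from `b`).
#' @export
combine_panels <- function(a, b) {
  stopifnot(inherits(a, "ystr_panel"), inherits(b, "ystr_panel"))
  keep <- !(b$loci$column %in% a$loci$column)
  def <- rbind(a$loci, b$loci[keep, , drop = FALSE])
  rownames(def) <- NULL
  structure(
    list(name = paste(a$name, b$name, sep = "+"), loci = def,
         columns = def$column, scored_locus_count = nrow(def)),
    class = "ystr_panel"
  )
}

#' Single-copy loci of a panel
#'
#' Multi-copy loci cannot be aligned between unrelated individuals (the copy
#' assignment is not observable), so unrelated-sample analyses such as the
#' DAPC classification exclude them.
#'
#' @param panel A `ystr_panel`.
#' @return Character vector of scored column names belonging to single-copy
#'   loci. For the RM panels DYF399S1, DYF387S1 and DYF404S1 are multi-copy
#'   markers even though they are scored as one column, and are excluded too.
#' @export
single_copy_columns <- function(panel) {
  stopifnot(inherits(panel, "ystr_panel"))
  multi <- c("DYS385", "DYF403S1", "DYF399S1", "DYF387S1", "DYF404S1")
  panel$loci$column[!panel$loci$locus %in% multi]
}

#' @export
print.ystr_panel <- function(x, ...) {
  cat(sprintf("Y-STR panel %s: %d scored loci\n", x$name,
              x$scored_locus_count))
  cat(" ", paste(x$columns, collapse = ", "), "\n")
  invisible(x)
}
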