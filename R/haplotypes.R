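#' Read a haplotype table
#'
#' A haplotype table is a delimited file with a header, a first column
#' `sample_id` and one numeric column per scored locus of a panel, named as
#' in the panel (multi-copy loci suffixed `a`, `b`). Allele values are
#' repeat counts and may carry one decimal digit (microvariants such as
#' 30.2); empty cells are missing calls. Multi-copy allele pairs are sorted
#' at ingest (copy order is not observable from an electropherogram), so a
#' table with DYS385b < DYS385a reads back identically to its sorted form.
#'
#' @param path Path to the table.
#' @param panel A [load_panel()] object naming the expected loci.
#' @param sep Field separator; `"\t"` by default, pass `","` for CSV.
#' @return A data frame of class `ystr_haplotypes` with column `sample_id`
#'   followed by the panel's scored columns (numeric, `NA` = missing).
#'   Columns not in the panel are dropped with a warning; missing-cell
#'   counts are reported with a message.
#' @export
read_haplotype_table <- function(path, panel, sep = "\t") {
  stopifnot(inherits(panel, "ystr_panel"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(tab))
    stop("haplotype table must have a 'sample_id' column", call. = FALSE)
  extra <- setdiff(names(tab), c("sample_id", panel$columns))
  if (length(extra))
    warning("ignoring column(s) not in panel ", panel$name, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  absent <- setdiff(panel$columns, names(tab))
  if (length(absent))
    stop("panel column(s) missing from table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "), call. = FALSE)
  out <- data.frame(sample_id = tab$sample_id, stringsAsFactors = FALSE)
  n_missing <- 0L
  for (col in panel$columns) {
    raw <- trimws(tab[[col]])
    raw[raw == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad))
      stop(sprintf("non-numeric allele '%s' at row %d, column %s",
                   raw[bad[1]], bad[1], col), call. = FALSE)
    if (any(val < 0, na.rm = TRUE))
      stop("negative allele value in column ", col, call. = FALSE)
    n_missing <- n_missing + sum(is.na(val))
    out[[col]] <- val
  }
  if (n_missing > 0L)
    message(n_missing, " missing allele call(s) in ", path)
  normalize_haplotypes(out, panel)
}

#' Sort multi-copy allele tuples into non-decreasing order
#'
#' @param haps Haplotype data frame (`sample_id` + panel columns).
#' @param panel The [load_panel()] the columns belong to.
#' @return The table with each multi-copy locus's columns sorted row-wise
#'   (missing values kept last), classed `ystr_haplotypes`.
#' @export
normalize_haplotypes <- function(haps, panel) {
  stopifnot(is.data.frame(haps), inherits(panel, "ystr_panel"))
  for (loc in unique(panel$loci$locus)) {
    cols <- panel$loci$column[panel$loci$locus == loc]
    if (length(cols) < 2L) next
    m <- as.matrix(haps[cols])
    haps[cols] <- t(apply(m, 1L, sort, na.last = TRUE))
  }
  class(haps) <- unique(c("ystr_haplotypes", class(haps)))
  haps
}

#' Write a haplotype table
#'
#' Inverse of [read_haplotype_table()]: round-tripping preserves allele
#' values and missing flags exactly.
#'
#' @param haps Haplotype data frame.
#' @param path Output path.
#' @param sep Field separator.
#' @return Invisibly, `path`.
#' @export
write_haplotype_table <- function(haps, path, sep = "\t") {
  utils::write.table(haps, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read or write a couple table
#'
#' Couples are pairs of samples compared for mutation counting: close
#' relatives (father-son, brothers, uncle-nephew, cousins), within-pedigree
#' pairs, or unrelated pairs sharing near-identical Yfiler profiles. Columns:
#' `sample_a`, `sample_b`, `meioses` (empty for unrelated pairs),
#' `relationship`, `dataset_tag` (A, B, C1 or C2).
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A data frame with the columns above (`meioses` integer, `NA` when
#'   not applicable).
#' @export
read_couples <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_a", "sample_b", "meioses", "relationship", "dataset_tag")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("couple table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab$meioses <- suppressWarnings(as.integer(tab$meioses))
  related <- !tab$dataset_tag %in% c("C1", "C2")
  if (any(related & (is.na(tab$meioses) | tab$meioses < 1L)))
    stop("related couples must have meioses >= 1", call. = FALSE)
  tab[need]
}

#' @rdname read_couples
#' @param couples Couple data frame.
#' @export
write_couples <- function(couples, path, sep = "\t") {
  utils::write.table(couples, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
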