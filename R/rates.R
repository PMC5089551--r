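#' Pooled mutation rate by direct count
#'
#' The average per-locus, per-generation mutation rate: the total number of
#' observed mutation events divided by the total number of generations
#' (meioses) and by the number of scored loci.
#'
#' @param NMUT Total observed mutation events.
#' @param NGEN Total meioses.
#' @param L Number of scored loci (1 for a per-locus rate).
#' @return `NMUT / (NGEN * L)`.
#' @examples
#' pooled_rate(26, 470, 17)  # 0.003254..., the Yfiler deep-pedigree rate
#' @export
pooled_rate <- function(NMUT, NGEN, L) {
  if (NGEN <= 0 || L <= 0) stop("NGEN and L must be positive", call. = FALSE)
  if (NMUT < 0) stop("NMUT must be non-negative", call. = FALSE)
  NMUT / (NGEN * L)
}

#' Binomial-quantile confidence interval for a mutation rate
#'
#' The 95% interval is built from the 2.5% and 97.5% quantiles of a binomial
#' distribution with size `n = NGEN` (meioses) and success probability
#' `p = NMUT / NGEN`; the quantile counts (smallest k with CDF >= q) are
#' then divided by `NGEN * L` to put them on the per-locus rate scale.
#'
#' @inheritParams pooled_rate
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @examples
#' binomial_ci(26, 470, 17)  # c(0.00213, 0.00451) to 5 decimals
#' @export
binomial_ci <- function(NMUT, NGEN, L, alpha = 0.05) {
  if (NGEN <= 0 || L <= 0) stop("NGEN and L must be positive", call. = FALSE)
  if (NMUT < 0 || NMUT > NGEN)
    stop("NMUT must lie in [0, NGEN]", call. = FALSE)
  p <- NMUT / NGEN
  # qbinom returns the smallest k with pbinom(k, n, p) >= q; round/clamp to
  # guard against tiny (even signed-zero) negative doubles at p ~ 0
  k <- pmin(round(stats::qbinom(c(alpha / 2, 1 - alpha / 2),
                                size = NGEN, prob = p)), NGEN)
  k[k <= 0] <- 0
  k / (NGEN * L)
}

#' Pooled rate estimate with confidence interval
#'
#' @inheritParams binomial_ci
#' @param label Label for the estimate (dataset / panel).
#' @return A one-row data frame
#'   `label, NGEN, NMUT, L, rate, ci_low, ci_high, alpha`, with
#'   `rate = NMUT/(NGEN*L)` and the [binomial_ci()] endpoints.
#' @export
estimate_rate <- function(NMUT, NGEN, L, alpha = 0.05, label = "") {
  ci <- binomial_ci(NMUT, NGEN, L, alpha)
  data.frame(label = label, NGEN = NGEN, NMUT = NMUT, L = L,
             rate = pooled_rate(NMUT, NGEN, L),
             ci_low = ci[1], ci_high = ci[2], alpha = alpha)
}

#' Locus-by-locus mutation rates
#'
#' Pools per-locus event counts over pedigrees and estimates one rate (and
#' binomial-quantile CI, with `L = 1`) per scored column.
#'
#' @param counts List of `mutation_count` objects with
#'   `convention = "related"`.
#' @param panel A [load_panel()] object.
#' @param alpha Significance level.
#' @return Data frame `locus, NMUT, NGEN, rate, ci_low, ci_high`, one row
#'   per scored column in panel order.
#' @export
locus_rates <- function(counts, panel, alpha = 0.05) {
  stopifnot(inherits(panel, "ystr_panel"))
  if (!length(counts)) stop("no mutation counts supplied", call. = FALSE)
  stopifnot(all(vapply(counts, inherits, TRUE, "mutation_count")))
  if (!all(vapply(counts, `[[`, "", "convention") == "related"))
    stop("locus rates require related-convention counts", call. = FALSE)
  NGEN <- sum(vapply(counts, `[[`, 1L, "total_meioses"))
  rows <- lapply(panel$columns, function(col) {
    NMUT <- sum(vapply(counts, function(mc) mc$per_locus_events[[col]],
                       integer(1)))
    ci <- binomial_ci(NMUT, NGEN, 1L, alpha)
    data.frame(locus = col, NMUT = NMUT, NGEN = NGEN, rate = NMUT / NGEN,
               ci_low = ci[1], ci_high = ci[2])
  })
  do.call(rbind, rows)
}

#' Iterative Grubbs screening of outlier pedigrees
#'
#' Pedigrees with an extreme mutations/generations ratio are suspect of
#' hidden non-paternity events. The two-sided Grubbs statistic
#' `G = max |x - mean(x)| / sd(x)` is tested repeatedly: while its p-value
#' is at or below `alpha`, the extreme pedigree is removed and the test
#' rerun; screening stops at the first non-significant result.
#'
#' @param ratios Named numeric vector of per-pedigree mutations/generations
#'   ratios (names are pedigree IDs).
#' @param alpha Significance level (default 0.05).
#' @return A `grubbs_result` object: list with `ratios` (input), `excluded`
#'   (data frame `pedigree_id, p_value` in exclusion order), `final_p` (the
#'   last, non-significant p-value) and `kept` (surviving IDs).
#' @export
grubbs_screen <- function(ratios, alpha = 0.05) {
  if (length(ratios) < 3L)
    stop("Grubbs screening needs at least 3 pedigrees", call. = FALSE)
  if (is.null(names(ratios)))
    names(ratios) <- paste0("ped", seq_along(ratios))
  cur <- ratios
  excluded <- data.frame(pedigree_id = character(0), p_value = numeric(0))
  final_p <- 1
  repeat {
    if (length(cur) < 3L) break
    s <- stats::sd(cur)
    if (!is.finite(s) || s == 0) { final_p <- 1; break }
    dev <- abs(cur - mean(cur))
    i <- which.max(dev)
    p <- .grubbs_pvalue(dev[i] / s, length(cur))
    if (p > alpha) { final_p <- p; break }
    excluded <- rbind(excluded,
                      data.frame(pedigree_id = names(cur)[i], p_value = p))
    cur <- cur[-i]
  }
  structure(list(ratios = ratios, excluded = excluded, final_p = final_p,
                 kept = names(cur)),
            class = "grubbs_result")
}

# two-sided p-value of the single-outlier Grubbs statistic via its
# t-distribution representation
.grubbs_pvalue <- function(G, n) {
  denom <- (n - 1)^2 - n * G^2
  if (denom <= 0) return(0)
  t <- sqrt(n * (n - 2) * G^2 / denom)
  min(1, 2 * n * stats::pt(t, df = n - 2, lower.tail = FALSE))
}

#' @export
print.grubbs_result <- function(x, ...) {
  cat(sprintf("Grubbs screen: %d pedigree(s) excluded of %d (final p = %.3g)\n",
              nrow(x$excluded), length(x$ratios), x$final_p))
  if (nrow(x$excluded))
    print(x$excluded, row.names = FALSE)
  invisible(x)
}

#' Diachronically binned mutation rates
#'
#' Groups pairwise comparisons by the number of meioses separating the two
#' men and estimates one pooled rate per bin, to detect saturation (rates
#' decaying with temporal depth).
#'
#' @param couple_counts Couple table with columns `meioses` and `events`
#'   (see [count_couples()], related convention).
#' @param panel A [load_panel()] object (sets `L`).
#' @param bins List of two-element vectors `c(lo, hi)`, or strings
#'   `"lo-hi"`; bins must be disjoint. Default: the 1-10, 11-20, 21-26
#'   meiosis bins.
#' @param alpha Significance level.
#' @return Data frame `bin, NGEN, NMUT, L, rate, ci_low, ci_high`; couples
#'   outside every bin are skipped with a message, empty bins are dropped
#'   with a message.
#' @export
bin_rates <- function(couple_counts, panel,
                      bins = list(c(1, 10), c(11, 20), c(21, 26)),
                      alpha = 0.05) {
  stopifnot(inherits(panel, "ystr_panel"),
            all(c("meioses", "events") %in% names(couple_counts)))
  bins <- lapply(bins, function(b) {
    if (is.character(b)) b <- as.numeric(strsplit(b, "-", fixed = TRUE)[[1]])
    stopifnot(length(b) == 2L, b[1] <= b[2])
    b
  })
  if (length(bins) > 1L) {
    edges <- do.call(rbind, bins)
    o <- order(edges[, 1])
    if (any(edges[o, 1][-1] <= edges[o, 2][-length(bins)]))
      stop("bins must be disjoint", call. = FALSE)
  }
  m <- couple_counts$meioses
  hit <- rep(NA_integer_, length(m))
  for (i in seq_along(bins))
    hit[!is.na(m) & m >= bins[[i]][1] & m <= bins[[i]][2]] <- i
  if (anyNA(hit))
    message(sum(is.na(hit)), " couple(s) fall outside every bin; skipped")
  rows <- lapply(seq_along(bins), function(i) {
    sel <- which(!is.na(hit) & hit == i)
    lab <- paste0(bins[[i]][1], "-", bins[[i]][2])
    if (!length(sel)) {
      message("bin ", lab, " is empty; no estimate")
      return(NULL)
    }
    NGEN <- sum(m[sel])
    NMUT <- sum(couple_counts$events[sel])
    ci <- binomial_ci(NMUT, NGEN, panel$scored_locus_count, alpha)
    data.frame(bin = lab, NGEN = NGEN, NMUT = NMUT,
               L = panel$scored_locus_count,
               rate = pooled_rate(NMUT, NGEN, panel$scored_locus_count),
               ci_low = ci[1], ci_high = ci[2])
  })
  do.call(rbind, rows)
}

#' Format a rate table to the 5-decimal reporting convention
#'
#' @param tab Data frame with columns `rate`, `ci_low`, `ci_high`.
#' @return The table with those columns formatted as 5-decimal strings.
#' @export
format_rate_table <- function(tab) {
  for (col in intersect(c("rate", "ci_low", "ci_high"), names(tab)))
    tab[[col]] <- sprintf("%.5f", tab[[col]])
  tab
}
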