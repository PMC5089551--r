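#' Discriminating power of a panel over a set of couples
#'
#' The fraction of compared couples whose haplotypes differ at one or more
#' scored columns of the panel.
#'
#' @param couples Couple data frame (see [read_couples()]).
#' @param haps Haplotype table covering all members.
#' @param panel A [load_panel()] object.
#' @param convention Counting convention passed to [pair_mutation_count()];
#'   differing/not differing is the same under both.
#' @return List with `n_couples`, `n_differing`, `power` (fraction) and
#'   `power_pct` (percentage rounded to 2 decimals).
#' @export
discriminating_power <- function(couples, haps, panel,
                                 convention = "related") {
  if (!nrow(couples)) stop("empty couple list", call. = FALSE)
  cc <- count_couples(couples, haps, panel, convention)
  n_diff <- sum(cc$events > 0L)
  list(n_couples = nrow(cc), n_differing = n_diff,
       power = n_diff / nrow(cc),
       power_pct = round(100 * n_diff / nrow(cc), 2))
}

#' Mean number of mutations per couple
#'
#' @inheritParams discriminating_power
#' @return Arithmetic mean of the per-couple mutation counts.
#' @export
mean_pair_mutations <- function(couples, haps, panel,
                                convention = "related") {
  if (!nrow(couples)) stop("empty couple list", call. = FALSE)
  mean(count_couples(couples, haps, panel, convention)$events)
}

#' Bootstrap percentile confidence interval for a per-couple mean
#'
#' Resamples the couples (their mutation counts) with replacement `B`
#' times, recomputes the mean each time, and returns the empirical
#' `alpha/2` and `1 - alpha/2` percentiles.
#'
#' @param per_couple_counts Integer vector of per-couple mutation counts.
#' @param B Bootstrap replicates (default 1000).
#' @param alpha Significance level.
#' @param seed Integer seed, or `NULL`.
#' @return Numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(per_couple_counts, B = 1000, alpha = 0.05,
                         seed = NULL) {
  stopifnot(B >= 1, length(per_couple_counts) >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(per_couple_counts)
  means <- vapply(seq_len(B), function(b)
    mean(sample(per_couple_counts, n, replace = TRUE)), 1)
  unname(stats::quantile(means, c(alpha / 2, 1 - alpha / 2)))
}

#' Full discrimination summary for one panel and couple set
#'
#' @inheritParams discriminating_power
#' @inheritParams bootstrap_ci
#' @param dataset_tag Label carried into the output row.
#' @return One-row data frame `panel, dataset_tag, n_couples, n_differing,
#'   power_pct, mean_mutations, ci_low, ci_high, B, seed`.
#' @export
discrimination_summary <- function(couples, haps, panel,
                                   convention = "related", B = 1000,
                                   alpha = 0.05, seed = NULL,
                                   dataset_tag = "") {
  cc <- count_couples(couples, haps, panel, convention)
  pw <- discriminating_power(couples, haps, panel, convention)
  ci <- bootstrap_ci(cc$events, B = B, alpha = alpha, seed = seed)
  data.frame(panel = panel$name, dataset_tag = dataset_tag,
             n_couples = pw$n_couples, n_differing = pw$n_differing,
             power_pct = pw$power_pct, mean_mutations = mean(cc$events),
             ci_low = ci[1], ci_high = ci[2], B = B,
             seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Step distance between two Yfiler haplotypes
#'
#' Sum over the 17 Yfiler scored columns of the copy-matched absolute
#' allele differences (the unrelated-convention mutation count restricted
#' to Yfiler). Used to select couples of unrelated men with identical or
#' one-step-different Yfiler profiles.
#'
#' @param a,b Haplotype rows or named allele vectors carrying all Yfiler
#'   columns; missing values are an error.
#' @return Integer step distance.
#' @export
yfiler_step_distance <- function(a, b) {
  panel <- load_panel("YFILER")
  av <- .as_allele_vector(a, panel)
  bv <- .as_allele_vector(b, panel)
  if (anyNA(av) || anyNA(bv))
    stop("Yfiler step distance requires complete profiles", call. = FALSE)
  sum(as.integer(round(abs(av - bv))))
}
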