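#' Encode haplotypes as a numeric feature matrix
#'
#' Builds the samples x loci allele matrix used for classification.
#' Multi-copy loci are refused: between unrelated men the copy assignment is
#' arbitrary, so their columns are not comparable features. Missing alleles
#' are imputed by the column mean (with a message); constant columns are
#' dropped with a warning since they carry no discriminant information.
#'
#' @param haps Haplotype table.
#' @param loci Character vector of single-copy scored column names, e.g.
#'   `single_copy_columns(load_panel("YFILER"))`.
#' @return Numeric matrix (rownames = sample IDs) with an attribute `loci`
#'   giving the retained column names.
#' @export
encode_haplotypes <- function(haps, loci) {
  multi <- c("DYS385a", "DYS385b", "DYF403S1a", "DYF403S1b",
             "DYF399S1", "DYF387S1", "DYF404S1")
  bad <- intersect(loci, multi)
  if (length(bad))
    stop("multi-copy locus/loci not usable as features: ",
         paste(bad, collapse = ", "), call. = FALSE)
  miss <- setdiff(loci, names(haps))
  if (length(miss))
    stop("haplotype table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(haps) < 2) stop("need at least 2 samples", call. = FALSE)
  X <- as.matrix(haps[loci])
  rownames(X) <- haps$sample_id
  n_imputed <- sum(is.na(X))
  if (n_imputed > 0L) {
    for (j in seq_len(ncol(X))) {
      na <- is.na(X[, j])
      if (any(na)) X[na, j] <- mean(X[, j], na.rm = TRUE)
    }
    message(n_imputed, " missing allele(s) imputed by column mean")
  }
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  if (!all(keep)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  attr(X, "loci") <- colnames(X)
  X
}

#' Fit a discriminant analysis of principal components (DAPC)
#'
#' Reduces the allele matrix by principal component analysis, then fits a
#' linear discriminant analysis on the retained PC scores with equal group
#' priors. The PCA step stabilises the within-group covariance when loci
#' are many or collinear; with all components retained the procedure is
#' exactly equivalent to LDA on the raw features (PCA is a rotation).
#'
#' @param X Encoded matrix from [encode_haplotypes()].
#' @param labels Group labels, one per row of `X`; every group needs at
#'   least 2 members.
#' @param n_pc Number of principal components to retain, or `"auto"`: the
#'   smallest count explaining >= 90% of the variance, capped at one third
#'   of the sample count (a standard guard against overfitting the
#'   discriminant space).
#' @param n_da Number of discriminant axes (default `groups - 1`).
#' @param scale Scale features to unit variance before PCA? Off by
#'   default: repeat counts share a natural scale.
#' @return A `dapc_model` object (PCA rotation and centering, retained axis
#'   count, the LDA fit, group levels).
#' @export
fit_dapc <- function(X, labels, n_pc = "auto", n_da = NULL, scale = FALSE) {
  stopifnot(is.matrix(X), nrow(X) == length(labels))
  labels <- as.factor(labels)
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2))
    stop("group(s) with a single member: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  pca <- stats::prcomp(X, center = TRUE, scale. = scale)
  rank <- sum(pca$sdev > max(pca$sdev) * 1e-8)
  if (identical(n_pc, "auto")) {
    cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
    n_pc <- which(cum >= 0.90)[1]
    n_pc <- min(n_pc, max(1L, floor(nrow(X) / 3)), rank)
  } else {
    stopifnot(n_pc >= 1)
    if (n_pc > rank) {
      warning("n_pc = ", n_pc, " exceeds rank ", rank, "; clipped",
              call. = FALSE)
      n_pc <- rank
    }
  }
  k <- length(sizes)
  if (is.null(n_da)) n_da <- k - 1L
  n_da <- min(n_da, k - 1L)
  scores <- pca$x[, seq_len(n_pc), drop = FALSE]
  lda_fit <- MASS::lda(scores, grouping = labels, prior = rep(1 / k, k))
  structure(
    list(rotation = pca$rotation[, seq_len(n_pc), drop = FALSE],
         center = pca$center,
         scale = if (isFALSE(pca$scale)) NULL else pca$scale,
         n_pc = n_pc, n_da = n_da, lda = lda_fit,
         groups = levels(labels), loci = colnames(X)),
    class = "dapc_model"
  )
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("DAPC model: %d PCs retained, %d discriminant axes, %d groups\n",
              x$n_pc, x$n_da, length(x$groups)))
  invisible(x)
}

#' Posterior membership probabilities from a DAPC model
#'
#' Projects samples into the model's principal-component space and returns
#' the Gaussian (pooled within-group covariance) posterior probability of
#' each group, normalised per sample.
#'
#' @param model A [fit_dapc()] model.
#' @param X Matrix with the model's feature columns (e.g. the training
#'   matrix, or new samples encoded over the same loci).
#' @param labels Optional true labels; if given, per-group average
#'   membership probabilities (amp: the mean posterior assigned to the true
#'   group across its members) are computed.
#' @return A `membership_matrix` object: list with `posterior` (samples x
#'   groups matrix, rows summing to 1), `labels` (or `NULL`) and `amp`
#'   (named vector, or `NULL`).
#' @export
membership <- function(model, X, labels = NULL) {
  stopifnot(inherits(model, "dapc_model"), is.matrix(X))
  if (ncol(X) != length(model$loci) ||
      !all(colnames(X) == model$loci))
    stop("feature columns do not match the model's loci", call. = FALSE)
  Xc <- sweep(X, 2, model$center)
  if (!is.null(model$scale)) Xc <- sweep(Xc, 2, model$scale, "/")
  scores <- Xc %*% model$rotation
  dimen <- min(model$n_da, ncol(model$lda$scaling))
  post <- stats::predict(model$lda, scores, dimen = dimen)$posterior
  post <- post / rowSums(post)
  amp <- NULL
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(X))
    labels <- as.character(labels)
    truep <- post[cbind(seq_len(nrow(post)), match(labels, colnames(post)))]
    amp <- tapply(truep, labels, mean)
    amp <- amp[model$groups]
  }
  structure(list(posterior = post, labels = labels, amp = amp),
            class = "membership_matrix")
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat(sprintf("membership matrix: %d samples x %d groups\n",
              nrow(x$posterior), ncol(x$posterior)))
  if (!is.null(x$amp)) {
    cat("average membership probability (amp) per group:\n")
    print(round(x$amp, 3))
  }
  invisible(x)
}

#' Cross-validated membership probabilities
#'
#' Training-set membership probabilities are optimistically biased: the
#' discriminant axes are fitted to the same samples they score, so even
#' label-free data yields inflated same-group posteriors. For unbiased
#' assessment (e.g. permutation null checks) this k-fold scheme predicts
#' every sample from a model fitted without it.
#'
#' @param X Encoded matrix from [encode_haplotypes()].
#' @param labels Group labels (each group needs >= 2 members in every
#'   training fold; use moderate fold counts for small groups).
#' @param folds Number of cross-validation folds.
#' @param n_pc Passed to [fit_dapc()].
#' @param seed Integer seed for the fold assignment, or `NULL`.
#' @return A `membership_matrix` with held-out posteriors and amp.
#' @export
cv_membership <- function(X, labels, folds = 10, n_pc = "auto",
                          seed = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(labels), folds >= 2)
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  fold <- sample(rep(seq_len(folds), length.out = nrow(X)))
  post <- matrix(NA_real_, nrow(X), length(groups),
                 dimnames = list(rownames(X), groups))
  for (k in seq_len(folds)) {
    tr <- fold != k
    fit <- fit_dapc(X[tr, , drop = FALSE], labels[tr], n_pc = n_pc)
    Xk <- X[!tr, fit$loci, drop = FALSE]
    pk <- membership(fit, Xk)$posterior
    post[!tr, colnames(pk)] <- pk
  }
  truep <- post[cbind(seq_len(nrow(post)), match(labels, groups))]
  amp <- tapply(truep, labels, mean)[groups]
  structure(list(posterior = post, labels = labels, amp = amp),
            class = "membership_matrix")
}

#' Long-format membership table for admixture-like plots
#'
#' @param mm A [membership()] result.
#' @return List with `assignments` (data frame `sample_id, true_group,
#'   assigned_group, probability`, one row per sample x group, rows per
#'   sample summing to 1) and `amp` (data frame `group, amp`, or `NULL` if
#'   no labels were supplied).
#' @export
export_membership_plot <- function(mm) {
  stopifnot(inherits(mm, "membership_matrix"))
  post <- mm$posterior
  ids <- rownames(post)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(post)))
  long <- data.frame(
    sample_id = rep(ids, times = ncol(post)),
    true_group = if (is.null(mm$labels)) NA_character_
                 else rep(mm$labels, times = ncol(post)),
    assigned_group = rep(colnames(post), each = nrow(post)),
    probability = as.vector(post)
  )
  long <- long[order(long$sample_id, long$assigned_group), ]
  rownames(long) <- NULL
  amp <- if (is.null(mm$amp)) NULL
         else data.frame(group = names(mm$amp), amp = as.numeric(mm$amp))
  list(assignments = long, amp = amp)
}
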