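#' Discriminant analysis of principal components (DAPC)
#'
#' Fits a linear discriminant analysis on retained principal-component scores
#' of the (mean-centred) cell-by-wavenumber intensity matrix: PCA absorbs the
#' collinearity of adjacent wavenumbers, and the discriminant axes then
#' maximise between-group separation of the retained scores. The default PC
#' retention policy keeps the smallest number of components explaining at
#' least `var_explained` of total variance, capped at `n_cells / 3` to avoid
#' overfitting the discriminant space. Each discriminant axis is oriented so
#' the first group's centroid coordinate is non-positive, making score signs
#' reproducible across runs.
#'
#' @param x an [scrs_set] (typically cropped to the fingerprint window) or a
#'   numeric matrix, cells in rows.
#' @param groups group label per cell (factor or character); every group
#'   needs at least 2 cells.
#' @param n_pcs number of PCs to retain, or `NULL` for the variance policy.
#' @param var_explained target cumulative variance fraction for the policy.
#' @param n_lds number of discriminant axes; must be < number of groups.
#'   Default `min(n_groups - 1, 2)`, the 2-D plane used for plotting and
#'   centroid distances.
#' @return An object of class `dapc`: `coordinates` (cells x LDs),
#'   `groups`, `centroids` (groups x LDs), `retained_pcs`,
#'   `explained_variance` (per retained PC), and the projection needed by
#'   [predict.dapc()].
#' @examples
#' m <- rbind(matrix(rnorm(100), 10), matrix(rnorm(100, 3), 10))
#' fit <- fit_dapc(m, rep(c("a", "b"), each = 10))
#' fit$centroids
#' @export
fit_dapc <- function(x, groups, n_pcs = NULL, var_explained = 0.9,
                     n_lds = NULL) {
  m <- if (inherits(x, "scrs_set")) x$intensities else as.matrix(x)
  if (any(!is.finite(m))) stop("matrix must be finite")
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(groups) != nrow(m)) stop("one group label per cell required")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 cells: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  k <- nlevels(groups)
  if (is.null(n_lds)) n_lds <- min(k - 1L, 2L)
  if (n_lds >= k) stop("n_lds must be smaller than the number of groups")
  pca <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  var_frac <- pca$sdev^2 / sum(pca$sdev^2)
  positive <- sum(pca$sdev > max(pca$sdev) * 1e-8)
  if (is.null(n_pcs)) {
    n_pcs <- which(cumsum(var_frac) >= var_explained)[1L]
    n_pcs <- min(n_pcs, max(1L, floor(nrow(m) / 3)))
  }
  n_pcs <- max(n_pcs, n_lds)
  n_pcs <- min(n_pcs, positive)
  # PC scores are rescaled to unit variance before the discriminant step;
  # LD coordinates are invariant to this, but it keeps lda() well
  # conditioned when intensities are on a normalized (summing-to-one) scale.
  sdev <- pca$sdev[seq_len(n_pcs)]
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE] /
    rep(sdev, each = nrow(m))
  fit <- MASS::lda(scores, grouping = groups)
  ld_all <- stats::predict(fit, scores)$x
  n_lds <- min(n_lds, ncol(ld_all))
  coords <- ld_all[, seq_len(n_lds), drop = FALSE]
  # normalise each axis to unit pooled within-group variance (divisor n),
  # so duplicating every cell leaves the coordinates unchanged
  within <- vapply(seq_len(ncol(coords)), function(j) {
    dev <- coords[, j] - stats::ave(coords[, j], groups)
    sqrt(sum(dev^2) / length(dev))
  }, numeric(1))
  ld_rescale <- ifelse(within > 1e-12, within, 1)
  coords <- coords / rep(ld_rescale, each = nrow(coords))
  # sign convention: first group's centroid <= 0 on every axis
  first <- levels(groups)[1L]
  flip <- colMeans(coords[groups == first, , drop = FALSE]) > 0
  coords[, flip] <- -coords[, flip]
  centroids <- apply(coords, 2L, function(v) tapply(v, groups, mean))
  centroids <- matrix(centroids, nrow = k,
                      dimnames = list(levels(groups), colnames(coords)))
  structure(
    list(coordinates = coords, groups = groups, centroids = centroids,
         retained_pcs = n_pcs,
         explained_variance = var_frac[seq_len(n_pcs)],
         pca = pca, lda = fit, flip = flip, n_lds = n_lds,
         score_scale = sdev, ld_rescale = ld_rescale),
    class = "dapc"
  )
}

#' @export
print.dapc <- function(x, ...) {
  cat(sprintf(
    "<dapc> %d cells, %d groups, %d PCs retained (%.1f%% variance), %d LD axes\n",
    nrow(x$coordinates), nlevels(x$groups), x$retained_pcs,
    100 * sum(x$explained_variance), x$n_lds))
  cat("centroids:\n")
  print(round(x$centroids, 3))
  invisible(x)
}

#' Project new spectra into a fitted DAPC space
#' @param object a [fit_dapc()] result.
#' @param newdata matrix or [scrs_set] on the same wavenumber axis.
#' @param ... unused.
#' @return Matrix of discriminant coordinates for the new cells.
#' @export
predict.dapc <- function(object, newdata, ...) {
  m <- if (inherits(newdata, "scrs_set")) newdata$intensities
       else as.matrix(newdata)
  scores <- scale(m, center = object$pca$center, scale = FALSE) %*%
    object$pca$rotation[, seq_len(object$retained_pcs), drop = FALSE]
  scores <- scores / rep(object$score_scale, each = nrow(scores))
  ld <- stats::predict(object$lda, scores)$x[, seq_len(object$n_lds),
                                             drop = FALSE]
  ld <- ld / rep(object$ld_rescale, each = nrow(ld))
  ld[, object$flip] <- -ld[, object$flip]
  ld
}

#' Control-centroid to treated-cell distance summary
#'
#' Euclidean distance in discriminant space from the control group's centroid
#' to every cell of the treated group; the mean and sample standard deviation
#' summarise how far the treatment moved the phenotype. Tightly clustered
#' control/treated groups (small mean) indicate a stress-tolerant phenotype;
#' large distances indicate a stress-sensitive one.
#'
#' @param dapc a [fit_dapc()] result.
#' @param control_group,treated_group group labels present in the fit.
#' @return Data.frame with `control`, `treated`, `mean_distance`,
#'   `sd_distance`, `n_cells`.
#' @export
centroid_distances <- function(dapc, control_group, treated_group) {
  stopifnot(inherits(dapc, "dapc"))
  lv <- levels(dapc$groups)
  if (!control_group %in% lv) stop("unknown group: ", control_group)
  if (!treated_group %in% lv) stop("unknown group: ", treated_group)
  treated <- dapc$coordinates[dapc$groups == treated_group, , drop = FALSE]
  if (nrow(treated) == 0L) stop("treated group is empty")
  centre <- dapc$centroids[control_group, ]
  d <- sqrt(rowSums(sweep(treated, 2L, centre)^2))
  data.frame(control = control_group, treated = treated_group,
             mean_distance = mean(d),
             sd_distance = if (length(d) > 1) stats::sd(d) else 0,
             n_cells = length(d))
}

#' Rank-sum separation test on discriminant axes
#'
#' Two-sided Wilcoxon rank-sum p-value per discriminant axis between two
#' groups; a non-significant result on both axes indicates the groups occupy
#' the same region of DAPC space.
#'
#' @param dapc a [fit_dapc()] result.
#' @param group_a,group_b group labels, each with at least 2 cells.
#' @return Named numeric vector of p-values, one per axis.
#' @export
group_separation_test <- function(dapc, group_a, group_b) {
  stopifnot(inherits(dapc, "dapc"))
  a <- dapc$coordinates[dapc$groups == group_a, , drop = FALSE]
  b <- dapc$coordinates[dapc$groups == group_b, , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) stop("both groups need at least 2 cells")
  p <- vapply(seq_len(ncol(a)), function(j) {
    if (stats::sd(c(a[, j], b[, j])) == 0) {
      warning("constant coordinates on axis ", j, "; p = 1")
      return(1)
    }
    stats::wilcox.test(a[, j], b[, j], exact = FALSE)$p.value
  }, numeric(1))
  stats::setNames(p, colnames(dapc$coordinates))
}

#' Per-wavenumber significance screen with a normality gate
#'
#' At each wavenumber, a Shapiro-Wilk test is run on both groups at
#' `alpha_normality`; when both pass, a two-sided t test compares the
#' groups, otherwise the Wilcoxon rank-sum test is used. Direction is the
#' sign of `mean(b) - mean(a)`. No multiplicity correction is applied by
#' default (raw `p < alpha` flagging); Benjamini-Hochberg is available via
#' `adjust = "BH"`. Wavenumbers constant in both groups are assigned p = 1
#' and flagged.
#'
#' @param set_a,set_b [scrs_set]s (or matrices) on a common axis; at least 3
#'   cells per group.
#' @param alpha significance level for flagging.
#' @param alpha_normality level of the Shapiro-Wilk gate.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data.frame with `wavenumber`, `test_used`, `p_value`, `direction`
#'   (`"up"` if group b exceeds group a), `significant`, `constant`.
#' @export
peakwise_significance <- function(set_a, set_b, alpha = 0.01,
                                  alpha_normality = 0.05,
                                  adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (inherits(set_a, "scrs_set")) {
    stopifnot(inherits(set_b, "scrs_set"),
              isTRUE(all.equal(set_a$wavenumbers, set_b$wavenumbers)))
    wn <- set_a$wavenumbers
    a <- set_a$intensities
    b <- set_b$intensities
  } else {
    a <- as.matrix(set_a)
    b <- as.matrix(set_b)
    if (ncol(a) != ncol(b)) stop("groups must share a common axis")
    wn <- as.numeric(colnames(a) %||% seq_len(ncol(a)))
  }
  if (nrow(a) < 3 || nrow(b) < 3) stop("need at least 3 cells per group")
  p <- numeric(ncol(a))
  used <- character(ncol(a))
  direction <- character(ncol(a))
  constant <- logical(ncol(a))
  for (j in seq_len(ncol(a))) {
    va <- a[, j]
    vb <- b[, j]
    dm <- mean(vb) - mean(va)
    direction[j] <- if (dm >= 0) "up" else "down"
    sda <- stats::sd(va)
    sdb <- stats::sd(vb)
    if (sda == 0 && sdb == 0) {
      constant[j] <- TRUE
      used[j] <- "none"
      p[j] <- if (dm == 0) 1 else 0
      next
    }
    normal <- sda > 0 && sdb > 0 &&
      stats::shapiro.test(va)$p.value > alpha_normality &&
      stats::shapiro.test(vb)$p.value > alpha_normality
    if (normal) {
      used[j] <- "t"
      p[j] <- stats::t.test(va, vb)$p.value
    } else {
      used[j] <- "Wilcoxon"
      p[j] <- stats::wilcox.test(va, vb, exact = FALSE)$p.value
    }
  }
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  data.frame(wavenumber = wn, test_used = used, p_value = p,
             direction = direction, significant = p < alpha,
             constant = constant)
}
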