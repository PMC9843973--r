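# ANOVA-PCA: partition a spectral matrix into design-factor effect
# matrices plus interaction and residual, quantify each partition's share
# of the total sum of squares, and run PCA on (effect + residual) for
# score visualisation coloured by factor level.

#' Build an indicator design matrix from per-spectrum factor labels
#'
#' @param labels vector of factor levels, one per spectrum.
#' @param name factor name.
#' @return Object of class `design_matrix`: the 0/1 indicator matrix
#'   (`n_spectra x n_levels`, level order = first appearance), with
#'   attributes `factor_name` and `levels`.
#' @examples
#' build_design(c("A", "A", "B"))
#' @export
build_design <- function(labels, name = deparse(substitute(labels))) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) < 2L) stop("design factor needs at least 2 levels")
  D <- outer(labels, lev, "==") * 1L
  if (any(colSums(D) == 0L)) stop("design level with zero members")
  colnames(D) <- lev
  structure(D, factor_name = name, levels = lev, class = c("design_matrix", "matrix"))
}

#' Partition a spectral matrix by a two-factor design
#'
#' Classic cell-means ANOVA partitioning: the grand mean is the column
#' mean of X; the main-effect row for a spectrum in level i of factor A is
#' (level-i mean - grand mean); the interaction row is
#' (cell mean - A-level mean - B-level mean + grand mean); the residual is
#' the remainder. The partition reconstructs X exactly, and for balanced
#' designs the partitions are mutually orthogonal so their sums of
#' squares add.
#'
#' @param X numeric matrix, spectra in rows (or an [ir_collection()]).
#' @param design_a,design_b [build_design()] matrices for the two factors.
#' @return Object of class `effect_decomposition` with elements
#'   `grand_mean`, `effects` (named list of per-factor matrices),
#'   `interaction`, `residual`, `X`, `designs`, `balanced`.
#' @export
decompose_effects <- function(X, design_a, design_b) {
  if (inherits(X, "ir_collection")) X <- X$data
  X <- as.matrix(X)
  if (nrow(X) != nrow(design_a) || nrow(X) != nrow(design_b))
    stop("X row count must match both design matrices")
  la <- attr(design_a, "levels"); lb <- attr(design_b, "levels")
  na <- attr(design_a, "factor_name"); nb <- attr(design_b, "factor_name")
  cell_n <- t(design_a) %*% design_b
  if (any(cell_n == 0L)) {
    empty <- which(cell_n == 0L, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(sprintf("%s x %s", la[empty[, 1L]], lb[empty[, 2L]]),
               collapse = ", "), " - interaction undefined")
  }
  grand <- colMeans(X)
  Xc <- sweep(X, 2L, grand)
  level_mean <- function(D) {
    # rows of D %*% M pick each spectrum's level mean
    M <- diag(1 / colSums(D), ncol(D)) %*% t(D) %*% Xc
    D %*% M
  }
  eff_a <- level_mean(design_a)
  eff_b <- level_mean(design_b)
  # cell means via the combined indicator
  Dab <- matrix(0L, nrow(X), length(la) * length(lb))
  ia <- max.col(design_a); ib <- max.col(design_b)
  cell_idx <- (ia - 1L) * length(lb) + ib
  Dab[cbind(seq_len(nrow(X)), cell_idx)] <- 1L
  keep <- colSums(Dab) > 0L
  Dab <- Dab[, keep, drop = FALSE]
  cell_mean <- level_mean(Dab)
  inter <- cell_mean - eff_a - eff_b
  resid <- Xc - eff_a - eff_b - inter
  balanced <- length(unique(as.vector(cell_n))) == 1L
  effects <- list(eff_a, eff_b)
  names(effects) <- c(na, nb)
  structure(list(grand_mean = grand, effects = effects, interaction = inter,
                 residual = resid, X = X,
                 designs = list(design_a, design_b), balanced = balanced),
            class = "effect_decomposition")
}

#' @export
print.effect_decomposition <- function(x, ...) {
  cat("<effect_decomposition> ", nrow(x$X), " spectra x ", ncol(x$X),
      " channels; factors: ", paste(names(x$effects), collapse = ", "),
      if (x$balanced) " (balanced)" else " (unbalanced)", "\n", sep = "")
  invisible(x)
}

#' Sum-of-squares contribution of each partition
#'
#' @param dec an [decompose_effects()] result.
#' @return data.frame of class `effect_contribution` with one row per
#'   partition (each factor, interaction, residual): sum of squares `ss`
#'   and `fraction` of the total (fractions sum to 1).
#' @export
effect_contributions <- function(dec) {
  stopifnot(inherits(dec, "effect_decomposition"))
  parts <- c(dec$effects, list(interaction = dec$interaction,
                               residual = dec$residual))
  ss <- vapply(parts, function(m) sum(m^2), numeric(1L))
  total <- sum((sweep(dec$X, 2L, dec$grand_mean))^2)
  if (total == 0) stop("all-zero centred data: contributions undefined")
  out <- data.frame(partition = names(ss), ss = unname(ss),
                    fraction = unname(ss) / sum(ss))
  class(out) <- c("effect_contribution", "data.frame")
  attr(out, "ss_total") <- total
  out
}

#' PCA of one effect matrix plus the residual
#'
#' The named factor's effect matrix is added back to the residual matrix
#' and the sum is column-centred and decomposed by SVD; scores are
#' returned with the per-spectrum level labels so score plots can be
#' coloured by level.
#'
#' @param dec an [decompose_effects()] result.
#' @param factor name of the factor whose effect to analyse.
#' @param n_components number of components to keep (default 2).
#' @return Object of class `effect_pca`: `scores` (with level labels),
#'   `loadings` (orthonormal columns), `explained` (variance fractions,
#'   non-increasing), `factor`.
#' @export
effect_pca <- function(dec, factor, n_components = 2L) {
  stopifnot(inherits(dec, "effect_decomposition"))
  if (!factor %in% names(dec$effects))
    stop("unknown factor '", factor, "'; available: ",
         paste(names(dec$effects), collapse = ", "))
  M <- dec$effects[[factor]] + dec$residual
  M <- sweep(M, 2L, colMeans(M))
  sv <- svd(M)
  r <- sum(sv$d > max(sv$d) * 1e-12)
  if (n_components > r)
    stop("n_components (", n_components, ") exceeds matrix rank (", r, ")")
  k <- seq_len(n_components)
  which_d <- which(vapply(dec$designs, function(D)
    identical(attr(D, "factor_name"), factor), logical(1L)))[1L]
  labels <- attr(dec$designs[[which_d]], "levels")[max.col(dec$designs[[which_d]])]
  scores <- data.frame(sv$u[, k, drop = FALSE] %*% diag(sv$d[k], n_components))
  names(scores) <- paste0("PC", k)
  scores$level <- labels
  structure(list(scores = scores,
                 loadings = sv$v[, k, drop = FALSE],
                 explained = (sv$d^2 / sum(sv$d^2))[k],
                 factor = factor),
            class = "effect_pca")
}

#' @export
print.effect_pca <- function(x, ...) {
  cat("<effect_pca> factor '", x$factor, "', ", ncol(x$loadings),
      " components; explained: ",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.effect_pca <- function(x, ...) {
  lev <- factor(x$scores$level)
  graphics::plot(x$scores$PC1,
                 if (ncol(x$loadings) >= 2L) x$scores$PC2 else
                   seq_len(nrow(x$scores)),
                 col = as.integer(lev), pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1L]),
                 ylab = if (ncol(x$loadings) >= 2L)
                   sprintf("PC2 (%.1f%%)", 100 * x$explained[2L]) else "index",
                 ...)
  graphics::legend("topright", legend = levels(lev), col = seq_along(levels(lev)),
                   pch = 19, cex = 0.8)
  invisible(x)
}

#' Mean silhouette of PC1 scores grouped by level
#'
#' Convenience measure of how well the first principal component
#' separates the design levels in an [effect_pca()] result.
#'
#' @param pca an `effect_pca` object.
#' @param components how many score columns to use (default 1).
#' @return Mean silhouette width in \[-1, 1\].
#' @export
score_silhouette <- function(pca, components = 1L) {
  stopifnot(inherits(pca, "effect_pca"))
  lev <- as.integer(factor(pca$scores$level))
  S <- as.matrix(pca$scores[, seq_len(components), drop = FALSE])
  sil <- cluster::silhouette(lev, stats::dist(S))
  mean(sil[, "sil_width"])
}
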