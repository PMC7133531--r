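#' Observed richness
#'
#' Number of OTUs with a positive count.
#'
#' @param counts Non-negative count vector.
#' @return Integer richness.
#' @export
richness <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  sum(counts > 0)
}

#' Pielou's evenness
#'
#' Shannon entropy (natural log) divided by the log of richness,
#' `J = H / ln(S)`. The base of the logarithm cancels. Undefined (NA) when
#' fewer than two OTUs are present, because a single-taxon community has no
#' evenness to speak of.
#'
#' @param counts Non-negative count vector with at least one positive entry.
#' @return Evenness in \[0, 1\], or `NA` when richness < 2.
#' @export
pielou_evenness <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all-zero count vector")
  s <- richness(counts)
  if (s < 2) return(NA_real_)
  p <- counts[counts > 0] / total
  -sum(p * log(p)) / log(s)
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' The sum of absolute abundance differences divided by the total abundance
#' of the two communities: `sum(|x - y|) / sum(x + y)`. Similarity is one
#' minus this value.
#'
#' @param x,y Non-negative count vectors of equal length.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both communities are empty")
  sum(abs(x - y)) / tot
}

#' Contribution of a taxon subset to Bray-Curtis dissimilarity
#'
#' The Bray-Curtis dissimilarity attributable to a subset of taxa -- the
#' subset alone in the numerator, the whole community in the denominator --
#' divided by the total Bray-Curtis dissimilarity. The shared denominator
#' cancels, leaving `sum_{i in S} |x_i - y_i| / sum_i |x_i - y_i|`.
#' Contributions over any partition of the taxon universe therefore sum
#' to one.
#'
#' @param x,y Non-negative count vectors of equal length.
#' @param subset Integer or logical index (or character names) selecting the
#'   taxon subset.
#' @return Contribution in \[0, 1\]; `NA` when the two communities are
#'   identical (total dissimilarity zero), since no change can be
#'   apportioned.
#' @export
subset_contribution <- function(x, y, subset) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (is.character(subset)) {
    if (is.null(names(x))) stop("character subset requires named vectors")
    subset <- match(subset, names(x))
    if (anyNA(subset)) stop("subset contains unknown taxon names")
  }
  diffs <- abs(x - y)
  denom <- sum(diffs)
  if (denom == 0) return(NA_real_)
  sum(diffs[subset]) / denom
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' @param m Count matrix, samples x OTUs.
#' @return A symmetric matrix of class `dissimilarity_matrix` with zero
#'   diagonal and entries in \[0, 1\].
#' @export
bray_curtis_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  }
  structure(d, class = c("dissimilarity_matrix", "matrix", "array"))
}

#' Principal coordinates analysis with negative-eigenvalue bookkeeping
#'
#' Classical scaling: the squared dissimilarity matrix is double-centred and
#' eigendecomposed. Axes with negative eigenvalues -- which semimetric
#' dissimilarities such as Bray-Curtis routinely produce -- are retained and
#' flagged `"imaginary"`; their coordinates are scaled by the square root of
#' the eigenvalue magnitude. No Lingoes/Cailliez correction is applied.
#'
#' @param d Symmetric dissimilarity matrix (zero diagonal).
#' @param tol Eigenvalues within `tol` of zero are dropped as numerical
#'   noise.
#' @return List of class `pcoa` with `coordinates` (samples x axes),
#'   `eigenvalues` (descending), and `axis_type` (`"real"`/`"imaginary"`).
#' @export
pcoa_embed <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  a <- -0.5 * d^2
  centred <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(0.5 * (centred + t(centred)), symmetric = TRUE)
  scale0 <- max(abs(e$values), 1)
  keep <- abs(e$values) > tol * scale0
  if (!any(keep)) {
    return(structure(list(
      coordinates = matrix(0, n, 1, dimnames = list(rownames(d), "PCo1")),
      eigenvalues = 0, axis_type = "real"), class = "pcoa"))
  }
  vals <- e$values[keep]
  ord <- order(vals, decreasing = TRUE)
  vals <- vals[ord]
  vecs <- e$vectors[, keep, drop = FALSE][, ord, drop = FALSE]
  coords <- sweep(vecs, 2, sqrt(abs(vals)), `*`)
  dimnames(coords) <- list(rownames(d), paste0("PCo", seq_along(vals)))
  structure(list(coordinates = coords,
                 eigenvalues = vals,
                 axis_type = ifelse(vals >= 0, "real", "imaginary")),
            class = "pcoa")
}

#' @export
print.pcoa <- function(x, ...) {
  pos <- sum(x$axis_type == "real")
  rel <- x$eigenvalues[x$eigenvalues > 0] / sum(x$eigenvalues[x$eigenvalues > 0])
  cat(sprintf("pcoa: %d samples, %d real + %d imaginary axes\n",
              nrow(x$coordinates), pos, sum(x$axis_type == "imaginary")))
  cat("variance explained (first real axes): ",
      paste(sprintf("%.1f%%", 100 * utils::head(rel, 3)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# geometric (spatial) median by Weiszfeld iteration
spatial_median <- function(pts, tol = 1e-8, max_iter = 1000L) {
  m <- colMeans(pts)
  for (i in seq_len(max_iter)) {
    dist <- sqrt(rowSums(sweep(pts, 2, m)^2))
    if (any(dist < tol)) {
      at <- pts[which.min(dist), ]
      # median coincides with a data point; check optimality and nudge off
      others <- dist >= tol
      if (!any(others)) return(at)
      grad <- colSums(sweep(pts[others, , drop = FALSE], 2, at) / dist[others])
      if (sqrt(sum(grad^2)) <= 1) return(at)
      m <- at + grad / sum(1 / dist[others]) * 0.5
      next
    }
    w <- 1 / dist
    m_new <- colSums(pts * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Beta dispersion: distance to the group spatial median in PCoA space
#'
#' Embeds the dissimilarity matrix by [pcoa_embed()], finds each group's
#' spatial median separately on the real and imaginary axes (Weiszfeld
#' iteration), and returns each sample's dispersion as
#' `sqrt(max(0, d_real^2 - d_imag^2))` to its group median -- the
#' negative-eigenvalue convention of Anderson's `betadisper`.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param groups Factor or character vector of group labels, one per sample.
#' @return Numeric vector of per-sample dispersions, named by sample, with
#'   the group labels attached as attribute `groups`.
#' @export
beta_dispersion <- function(d, groups) {
  d <- as.matrix(d)
  if (length(groups) != nrow(d)) stop("one group label per sample required")
  groups <- as.factor(groups)
  emb <- pcoa_embed(d)
  re <- emb$coordinates[, emb$axis_type == "real", drop = FALSE]
  im <- emb$coordinates[, emb$axis_type == "imaginary", drop = FALSE]
  disp <- numeric(nrow(d))
  names(disp) <- rownames(d)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2L) {
      warning("singleton group '", g, "': dispersion set to 0")
      disp[idx] <- 0
      next
    }
    med_re <- spatial_median(re[idx, , drop = FALSE])
    d2 <- rowSums(sweep(re[idx, , drop = FALSE], 2, med_re)^2)
    if (ncol(im) > 0) {
      med_im <- spatial_median(im[idx, , drop = FALSE])
      d2 <- d2 - rowSums(sweep(im[idx, , drop = FALSE], 2, med_im)^2)
    }
    disp[idx] <- sqrt(pmax(0, d2))
  }
  attr(disp, "groups") <- groups
  disp
}

#' Per-sample alpha diversity summary
#'
#' @param m Count matrix, samples x OTUs.
#' @return data.frame with `sample_id`, `richness`, `evenness`.
#' @export
alpha_diversity <- function(m) {
  data.frame(
    sample_id = rownames(m),
    richness = apply(m, 1, richness),
    evenness = apply(m, 1, pielou_evenness),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
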