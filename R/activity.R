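#' Per-sample activity calls from paired rRNA / rRNA-gene counts
#'
#' For every (sample, OTU) cell with reads in either molecule, computes the
#' 16S rRNA : rRNA gene ratio on the rarefied counts and assigns one of four
#' states:
#' \describe{
#'   \item{active}{DNA reads > 0 and ratio strictly greater than 1.}
#'   \item{inactive}{DNA reads > 0 and ratio at most 1 (ties are inactive).}
#'   \item{phantom}{RNA reads without DNA reads; the ratio is undefined and
#'     the taxon is excluded from downstream analyses.}
#'   \item{undetected}{no reads in either molecule (only emitted when
#'     `all_cells = TRUE`).}
#' }
#' Because both libraries are rarefied to the same depth, the count ratio
#' equals the relative-abundance ratio; no pseudocounts are used.
#'
#' @param pair A [pair_counts()] object.
#' @param all_cells If `TRUE`, also emit `undetected` cells (zero in both
#'   molecules). Default `FALSE`: one row per cell with any reads.
#' @return A `data.frame` (class `activity_calls`) with columns `sample_id`,
#'   `otu_id`, `dna`, `rna`, `ratio` (NA for phantoms/undetected) and
#'   `state`. The number of phantom cells is attached as attribute
#'   `n_phantom`.
#' @export
activity_calls <- function(pair, all_cells = FALSE) {
  stopifnot(inherits(pair, "press_pair"))
  dna <- pair$dna; rna <- pair$rna
  idx <- if (all_cells) which(dna >= 0L) else which(dna > 0L | rna > 0L)
  ij <- arrayInd(idx, dim(dna))
  d <- dna[idx]; r <- rna[idx]
  state <- ifelse(d > 0L, ifelse(r > d, "active", "inactive"),
                  ifelse(r > 0L, "phantom", "undetected"))
  out <- data.frame(
    sample_id = rownames(dna)[ij[, 1]],
    otu_id = colnames(dna)[ij[, 2]],
    dna = d, rna = r,
    ratio = ifelse(d > 0L, r / d, NA_real_),
    state = state,
    stringsAsFactors = FALSE
  )
  out <- out[order(match(out$sample_id, rownames(dna)), out$otu_id), ]
  rownames(out) <- NULL
  attr(out, "n_phantom") <- sum(state == "phantom")
  attr(out, "depth") <- pair$depth
  class(out) <- c("activity_calls", "data.frame")
  out
}

#' @export
print.activity_calls <- function(x, n = 6L, ...) {
  tab <- table(factor(x$state, c("active", "inactive", "phantom", "undetected")))
  cat(sprintf("activity_calls: %d cells (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("...", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Active community table
#'
#' The Active community of each sample is the set of taxa whose rRNA :
#' rRNA-gene ratio exceeds 1 in that sample, quantified by their DNA read
#' numbers. Inactive, phantom and undetected cells are zeroed, so each
#' sample's Active community is a subset of its Total (DNA) community and
#' its total reads vary from sample to sample.
#'
#' @param pair A [pair_counts()] object.
#' @return An integer matrix (class `active_table`, samples x OTUs) of DNA
#'   counts masked to active cells, with attribute `depth` (the rarefaction
#'   depth of the Total community).
#' @export
active_table <- function(pair) {
  stopifnot(inherits(pair, "press_pair"))
  act <- pair$dna
  act[!(pair$dna > 0L & pair$rna > pair$dna)] <- 0L
  empty <- rowSums(act) == 0L
  if (any(empty))
    warning("sample(s) with no active taxa: ",
            paste(rownames(act)[empty], collapse = ", "))
  structure(act, depth = pair$depth, class = c("active_table", "matrix", "array"))
}

#' @export
print.active_table <- function(x, ...) {
  cat(sprintf("active_table: %d samples x %d OTUs; active reads per sample %s-%s of depth %s\n",
              nrow(x), ncol(x),
              format(min(rowSums(x)), big.mark = ","),
              format(max(rowSums(x)), big.mark = ","),
              format(attr(x, "depth"), big.mark = ",")))
  invisible(x)
}
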