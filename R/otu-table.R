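#' Construct an OTU count table
#'
#' An `otu_table` is a non-negative integer matrix of read counts with samples
#' as rows and OTUs as columns, tagged with the molecule it was sequenced
#' from (`"DNA"` for the 16S rRNA gene, `"RNA"` for the 16S rRNA / cDNA
#' library).
#'
#' @param counts Numeric matrix of non-negative integer counts,
#'   samples x OTUs. Row names are sample ids, column names OTU ids.
#' @param molecule `"DNA"` or `"RNA"`.
#' @return An object of class `otu_table`: the validated integer matrix with
#'   attribute `molecule`.
#' @examples
#' m <- matrix(c(5, 1, 0, 0, 2, 7), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("S1", "S2"), c("OTU1", "OTU2", "OTU3")))
#' otu_table(m, "DNA")
#' @export
otu_table <- function(counts, molecule = c("DNA", "RNA")) {
  molecule <- match.arg(molecule)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and OTU column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers; relative abundances are not supported")
  storage.mode(counts) <- "integer"
  structure(counts, molecule = molecule, class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table [%s]: %d samples x %d OTUs, %s total reads\n",
              attr(x, "molecule"), nrow(x), ncol(x),
              format(sum(as.numeric(x)), big.mark = ",")))
  depths <- rowSums(x)
  cat(sprintf("library depth: min %s / median %s / max %s\n",
              format(min(depths), big.mark = ","),
              format(stats::median(depths), big.mark = ","),
              format(max(depths), big.mark = ",")))
  invisible(x)
}

#' Read an OTU count table from TSV or BIOM
#'
#' The TSV dialect is the dominant amplicon-table convention: OTUs as rows,
#' samples as columns, first column the OTU id, tab separated. The matrix is
#' transposed on read so that samples are rows. JSON BIOM files are read via
#' the biomformat package when `format = "biom"`.
#'
#' @param path Path to the file.
#' @param molecule `"DNA"` or `"RNA"`.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, molecule = c("DNA", "RNA"),
                           format = c("tsv", "biom")) {
  molecule <- match.arg(molecule)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # OTUs x samples
    return(otu_table(t(m), molecule))
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw),
                               dimnames = dimnames(raw)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable count at OTU '%s', sample '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  otu_table(t(m), molecule)
}

#' Write an OTU count table as TSV
#'
#' Writes the conventional orientation (OTUs as rows, samples as columns);
#' [read_otu_table()] inverts it, so write/read round-trips are the identity.
#'
#' @param x An [otu_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  m <- t(unclass(x))
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `mesocosm_id`, `treatment`,
#' `week`, `temperature_C`. Treatments must be one of `control`,
#' `disturbance`, `disturbance_immigration`; a treatment must be constant
#' within a mesocosm.
#'
#' @param path Path to the metadata TSV.
#' @return A validated `data.frame` of sample records.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  validate_metadata(df)
}

#' @rdname read_sample_metadata
#' @param df A data.frame of sample records to validate in place.
#' @export
validate_metadata <- function(df) {
  required <- c("sample_id", "mesocosm_id", "treatment", "week", "temperature_C")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata is missing required column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  allowed <- c("control", "disturbance", "disturbance_immigration")
  bad <- setdiff(unique(df$treatment), allowed)
  if (length(bad))
    stop("unknown treatment '", paste(bad, collapse = "', '"),
         "'; allowed: ", paste(allowed, collapse = ", "))
  if (any(df$week != round(df$week)) || any(df$week < 0))
    stop("week must be a non-negative integer")
  df$week <- as.integer(df$week)
  tt <- unique(df[, c("mesocosm_id", "treatment")])
  if (anyDuplicated(tt$mesocosm_id))
    stop("treatment must be constant within a mesocosm: ",
         paste(tt$mesocosm_id[duplicated(tt$mesocosm_id)], collapse = ", "))
  df
}

#' Rarefy an OTU table to a fixed depth
#'
#' Each retained sample is subsampled uniformly WITHOUT replacement to
#' exactly `depth` reads (the `vegan::rrarefy` convention). Samples whose
#' library is smaller than `depth` are dropped and listed in the
#' `"discarded"` attribute of the result. Given the same seed the output is
#' bit-identical.
#'
#' @param x An [otu_table()].
#' @param depth Target depth (reads per sample), default 50000.
#' @param seed Integer seed for the subsampling RNG.
#' @return A rarefied [otu_table()] whose rows all sum to exactly `depth`,
#'   with attribute `discarded`: a data.frame (`sample_id`, `molecule`,
#'   `raw_depth`) of the dropped samples, and attribute `depth`.
#' @export
rarefy_table <- function(x, depth = 50000, seed = 1L) {
  stopifnot(inherits(x, "otu_table"))
  if (length(depth) != 1L || depth < 1) stop("depth must be a positive integer")
  if (nrow(x) == 0L) stop("empty table")
  depths <- rowSums(x)
  keep <- depths >= depth
  discarded <- data.frame(sample_id = rownames(x)[!keep],
                          molecule = rep(attr(x, "molecule"), sum(!keep)),
                          raw_depth = unname(depths[!keep]),
                          stringsAsFactors = FALSE)
  if (!any(keep)) stop("no sample reaches the rarefaction depth")
  kept <- unclass(x)[keep, , drop = FALSE]
  exact <- rowSums(kept) == depth
  sub <- kept
  if (any(!exact)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    ## rrarefy warns when the smallest observed count exceeds 1, which is
    ## routine for deeply sequenced libraries; counts here are validated
    sub[!exact, ] <- withCallingHandlers(
      vegan::rrarefy(kept[!exact, , drop = FALSE], depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  out <- otu_table(sub, attr(x, "molecule"))
  attr(out, "discarded") <- discarded
  attr(out, "depth") <- as.integer(depth)
  out
}

#' Pair rarefied DNA and RNA tables with sample metadata
#'
#' Keeps only samples present in both rarefied tables (samples for which
#' either library failed rarefaction are omitted and counted), and unions
#' the OTU sets of the two molecules with zero fill so that both matrices
#' share an identical sample and OTU order. The zero fill is what makes
#' phantom taxa (RNA reads without DNA reads) visible downstream.
#'
#' @param dna,rna Rarefied [otu_table()]s of the matching molecule.
#' @param metadata Sample metadata `data.frame` (see
#'   [read_sample_metadata()]); must cover every retained sample.
#' @return A `press_pair`: list with elements `dna`, `rna` (aligned
#'   matrices), `metadata` (rows aligned to the samples), `depth`, and
#'   `n_omitted` (candidate samples dropped because one molecule failed).
#' @export
pair_counts <- function(dna, rna, metadata) {
  stopifnot(inherits(dna, "otu_table"), inherits(rna, "otu_table"))
  if (!identical(attr(dna, "molecule"), "DNA") ||
      !identical(attr(rna, "molecule"), "RNA"))
    stop("pair_counts expects a DNA table and an RNA table, in that order")
  d_depth <- unique(rowSums(dna)); r_depth <- unique(rowSums(rna))
  if (length(d_depth) != 1L || length(r_depth) != 1L || d_depth != r_depth)
    stop("both tables must be rarefied to one common depth before pairing")
  metadata <- validate_metadata(metadata)
  candidates <- union(rownames(dna), rownames(rna))
  common <- intersect(rownames(dna), rownames(rna))
  if (length(common) == 0L) stop("zero overlapping samples between DNA and RNA")
  common <- common[order(match(common, metadata$sample_id))]
  missing_meta <- setdiff(common, metadata$sample_id)
  if (length(missing_meta))
    stop("samples without a metadata record: ", paste(missing_meta, collapse = ", "))
  otus <- sort(union(colnames(dna), colnames(rna)))
  fill <- function(m, ids) {
    out <- matrix(0L, length(common), length(ids),
                  dimnames = list(common, ids))
    out[, colnames(m)] <- m[common, , drop = FALSE]
    out
  }
  structure(list(
    dna = fill(unclass(dna), otus),
    rna = fill(unclass(rna), otus),
    metadata = metadata[match(common, metadata$sample_id), , drop = FALSE],
    depth = as.integer(d_depth),
    n_omitted = length(candidates) - length(common)
  ), class = "press_pair")
}

#' @export
print.press_pair <- function(x, ...) {
  cat(sprintf("press_pair: %d paired samples x %d OTUs at depth %s (%d candidate sample(s) omitted)\n",
              nrow(x$dna), ncol(x$dna), format(x$depth, big.mark = ","),
              x$n_omitted))
  tab <- table(x$metadata$treatment)
  cat("samples by treatment: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}
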