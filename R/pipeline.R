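#' Configuration for a full analysis run
#'
#' Either `simulate = TRUE` (the default study design is simulated) or
#' paths to DNA/RNA count tables and metadata.
#'
#' @param simulate Run the simulator instead of reading files.
#' @param dna_path,rna_path,metadata_path Input files (ignored when
#'   simulating).
#' @param sim A [sim_config()] used when simulating.
#' @param depth Rarefaction depth, default 50000.
#' @param seed Seed for rarefaction and simulation.
#' @param baseline_week,resistance_week Weeks anchoring the divergence
#'   series and the resistance index.
#' @param windows Resilience windows, list of `c(start, end)`.
#' @param top_n Number of most-abundant Active taxa to profile/classify.
#' @param phases A [phase_map()].
#' @param succession_weeks Weeks delimiting secondary succession for the
#'   responsive/immigrant contribution analysis.
#' @return List of class `press_config`.
#' @export
press_config <- function(simulate = TRUE, dna_path = NULL, rna_path = NULL,
                         metadata_path = NULL, sim = sim_config(),
                         depth = 50000, seed = 1L,
                         baseline_week = 4L, resistance_week = 10L,
                         windows = list(c(16L, 45L), c(16L, 20L), c(20L, 45L)),
                         top_n = 50L, phases = phase_map(),
                         succession_weeks = c(16L, 20L, 45L)) {
  cfg <- as.list(environment())
  for (w in windows)
    if (length(w) != 2L || w[1] >= w[2])
      stop("each window must be c(start, end) with start < end")
  referenced <- c(baseline_week, resistance_week, unlist(windows),
                  succession_weeks, as.integer(names(phases)))
  known <- if (simulate) sim$weeks else NULL
  if (!is.null(known)) {
    bad <- setdiff(referenced, known)
    if (length(bad))
      stop("config references week(s) never sampled: ",
           paste(sort(unique(bad)), collapse = ", "))
  }
  structure(cfg, class = "press_config")
}

#' Run the full press-disturbance analysis
#'
#' Orchestrates simulate/read -> rarefy -> pair -> activity designation ->
#' alpha/beta diversity -> divergence and stability indices -> top-taxon
#' profiles and response categories -> subset contributions, and returns
#' everything in one bundle together with a reproducibility manifest
#' (seed, depth, discarded samples, omitted pairs).
#'
#' @param config A [press_config()].
#' @return List of class `press_analysis` with elements `pair`, `calls`,
#'   `active`, `alpha`, `ordination` (PCoA of the Total community),
#'   `dispersion` (per-sample distance to the treatment-by-week spatial
#'   median), `divergence`, `stability`, `top_taxa`, `profiles`,
#'   `categories`, `immigrants`, `responsive`, `contributions`, `truth`
#'   (when simulated) and `manifest`.
#' @export
run_press_analysis <- function(config = press_config()) {
  stopifnot(inherits(config, "press_config"))
  truth <- NULL
  if (isTRUE(config$simulate)) {
    sim <- simulate_press_experiment(config$sim, seed = config$seed)
    dna_raw <- sim$dna; rna_raw <- sim$rna; metadata <- sim$metadata
    truth <- sim$truth
  } else {
    if (is.null(config$dna_path) || is.null(config$rna_path) ||
        is.null(config$metadata_path))
      stop("dna_path, rna_path and metadata_path are required when simulate = FALSE")
    dna_raw <- read_otu_table(config$dna_path, "DNA")
    rna_raw <- read_otu_table(config$rna_path, "RNA")
    metadata <- read_sample_metadata(config$metadata_path)
  }
  bad <- setdiff(c(config$baseline_week, config$resistance_week,
                   unlist(config$windows), config$succession_weeks),
                 metadata$week)
  if (length(bad))
    stop("config references week(s) absent from the metadata: ",
         paste(sort(unique(bad)), collapse = ", "))

  dna <- rarefy_table(dna_raw, config$depth, seed = config$seed)
  rna <- rarefy_table(rna_raw, config$depth, seed = config$seed + 1L)
  discarded <- rbind(attr(dna, "discarded"), attr(rna, "discarded"))
  pair <- pair_counts(dna, rna, metadata)

  calls <- activity_calls(pair)
  active <- suppressWarnings(active_table(pair))
  alpha <- alpha_diversity(pair$dna)
  dissim <- bray_curtis_matrix(pair$dna)
  ordination <- pcoa_embed(dissim)
  disp_groups <- interaction(pair$metadata$treatment, pair$metadata$week,
                             drop = TRUE)
  dispersion <- data.frame(
    sample_id = rownames(pair$dna),
    treatment = pair$metadata$treatment,
    week = pair$metadata$week,
    dispersion = as.numeric(
      suppressWarnings(beta_dispersion(dissim, disp_groups))),
    stringsAsFactors = FALSE)
  divergence <- divergence_series(active, pair$metadata,
                                  baseline_week = config$baseline_week)
  stability <- stability_report(divergence,
                                resistance_week = config$resistance_week,
                                windows = config$windows)
  top_taxa <- select_top_active(active, config$top_n)
  profiles <- build_profiles(pair, active, top_taxa)
  immigrants <- immigrant_set(pair,
                              week_release = config$succession_weeks[1],
                              week_recovery = config$succession_weeks[-1])
  categories <- assign_categories(profiles, config$phases, immigrants)
  responsive <- responsive_set(calls, pair$metadata,
                               weeks = config$succession_weeks)
  contributions <- contribution_report(pair, responsive, immigrants,
                                       weeks = config$succession_weeks)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pressrecover")),
    seed = config$seed, depth = config$depth,
    n_samples_paired = nrow(pair$dna), n_otus = ncol(pair$dna),
    n_pairs_omitted = pair$n_omitted,
    discarded_samples = discarded,
    n_phantom_cells = attr(calls, "n_phantom"),
    simulated = isTRUE(config$simulate),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(list(pair = pair, calls = calls, active = active, alpha = alpha,
                 ordination = ordination, dispersion = dispersion,
                 divergence = divergence, stability = stability,
                 top_taxa = top_taxa, profiles = profiles,
                 categories = categories, immigrants = immigrants,
                 responsive = responsive, contributions = contributions,
                 truth = truth, manifest = manifest, config = config),
            class = "press_analysis")
}

#' @export
print.press_analysis <- function(x, ...) {
  m <- x$manifest
  cat("press_analysis\n")
  cat(sprintf("  %d paired samples x %d OTUs at depth %s (%d pair(s) omitted, %d librar%s discarded)\n",
              m$n_samples_paired, m$n_otus, format(m$depth, big.mark = ","),
              m$n_pairs_omitted, nrow(m$discarded_samples),
              if (nrow(m$discarded_samples) == 1) "y" else "ies"))
  cat(sprintf("  phantom cells excluded: %d\n", m$n_phantom_cells))
  rs <- x$stability[x$stability$kind == "resistance", "value"]
  cat(sprintf("  resistance (week %d): median %.3f [%.3f, %.3f]\n",
              x$config$resistance_week, stats::median(rs), min(rs), max(rs)))
  print(summary(x$stability))
  cat(sprintf("  responsive taxa: %d; immigrant taxa: %d\n",
              length(x$responsive), length(x$immigrants)))
  print(x$categories)
  invisible(x)
}

#' @export
summary.press_analysis <- function(object, ...) {
  list(stability = summary(object$stability),
       categories = table(object$categories$category),
       contributions = object$contributions$summary)
}

#' @export
plot.press_analysis <- function(x, ...) plot(x$divergence, ...)

#' Write a report bundle to disk
#'
#' Emits one TSV per analysis stage (activity calls, active table, alpha
#' diversity, divergence series, stability indices, top-taxon heatmap
#' matrix, categories, contributions, discarded samples) plus a JSON run
#' manifest. Rerunning the same configuration and seed reproduces every
#' file byte for byte (except the manifest timestamp).
#'
#' @param bundle A [run_press_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "press_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  hm <- profile_matrix(bundle$profiles)
  files <- c(
    tsv(bundle$calls, "activity_calls"),
    tsv(data.frame(sample_id = rownames(bundle$active),
                   unclass(bundle$active), check.names = FALSE),
        "active_table"),
    tsv(bundle$alpha, "alpha_diversity"),
    tsv(data.frame(sample_id = rownames(bundle$ordination$coordinates),
                   bundle$ordination$coordinates, check.names = FALSE),
        "ordination_coordinates"),
    tsv(data.frame(axis = seq_along(bundle$ordination$eigenvalues),
                   eigenvalue = bundle$ordination$eigenvalues,
                   type = bundle$ordination$axis_type),
        "ordination_eigenvalues"),
    tsv(bundle$dispersion, "beta_dispersion"),
    tsv(bundle$divergence, "divergence_series"),
    tsv(bundle$stability, "stability"),
    tsv(data.frame(otu_id = rownames(hm), hm, check.names = FALSE),
        "heatmap_matrix"),
    tsv(bundle$categories, "response_categories"),
    tsv(bundle$contributions$values, "contribution_values"),
    tsv(bundle$contributions$summary, "contribution_summary"),
    tsv(bundle$manifest$discarded_samples, "discarded_samples")
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(files, manifest_path))
}
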