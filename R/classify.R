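#' Week-to-phase map of the press-disturbance design
#'
#' Default schedule: acclimation ends at week 4 (pre), the temperature ramps
#' up over weeks 5-6, holds at the press value through weeks 10 and 14,
#' ramps down over weeks 15-16, and the system recovers over weeks 20 and
#' 45 (post).
#'
#' @param pre,ramp_up,press,ramp_down,post Integer vectors of sampled weeks
#'   per phase.
#' @return Named integer-keyed character vector mapping week -> phase.
#' @export
phase_map <- function(pre = 4L, ramp_up = c(5L, 6L), press = c(10L, 14L),
                      ramp_down = c(15L, 16L), post = c(20L, 45L)) {
  weeks <- c(pre, ramp_up, press, ramp_down, post)
  if (anyDuplicated(weeks)) stop("each week must map to exactly one phase")
  stats::setNames(
    rep(c("pre", "ramp_up", "press", "ramp_down", "post"),
        c(length(pre), length(ramp_up), length(press), length(ramp_down),
          length(post))),
    weeks)
}

#' Select the n most abundant taxa of the Active communities
#'
#' Taxa are ranked by their summed Active (DNA-read) abundance across all
#' samples and weeks; ties are broken by lexicographic OTU id so the
#' selection is deterministic.
#'
#' @param active An [active_table()].
#' @param n Number of taxa to keep (default 50).
#' @return Character vector of OTU ids, most abundant first.
#' @export
select_top_active <- function(active, n = 50L) {
  if (n < 1L) stop("n must be at least 1")
  totals <- colSums(active)
  ever <- totals > 0
  if (sum(ever) < n) {
    warning("only ", sum(ever), " taxa were ever active; returning all of them")
    n <- sum(ever)
  }
  ids <- colnames(active)[ever]
  totals <- totals[ever]
  ids[order(-totals, ids)][seq_len(n)]
}

#' Activity/detection profiles for a set of taxa
#'
#' Codes every (taxon, sample) cell the way the activity heatmap does:
#' `NA` when the taxon fell below detection in the Total (DNA) community,
#' `0` when detected but inactive, and otherwise the taxon's Active (DNA)
#' abundance relative to its own maximum across disturbed mesocosms.
#'
#' @param pair A [pair_counts()] object.
#' @param active The matching [active_table()].
#' @param taxa Character vector of OTU ids (e.g. from
#'   [select_top_active()]).
#' @return data.frame of class `taxon_profiles` with columns `otu_id`,
#'   `sample_id`, `mesocosm_id`, `treatment`, `week`, `state`
#'   (active/inactive/undetected) and `code` (the heatmap value).
#' @export
build_profiles <- function(pair, active, taxa) {
  stopifnot(inherits(pair, "press_pair"))
  unknown <- setdiff(taxa, colnames(pair$dna))
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  meta <- pair$metadata
  disturbed <- meta$sample_id[meta$treatment != "control"]
  rows <- list()
  for (otu in taxa) {
    d <- pair$dna[, otu]
    a <- active[, otu]
    state <- ifelse(d == 0L, "undetected", ifelse(a > 0L, "active", "inactive"))
    ref <- max(a[disturbed])
    if (ref == 0L) ref <- max(a, 1L)  # never active in disturbed mesocosms
    code <- ifelse(d == 0L, NA_real_, ifelse(a > 0L, a / ref, 0))
    rows[[otu]] <- data.frame(
      otu_id = otu, sample_id = meta$sample_id,
      mesocosm_id = meta$mesocosm_id, treatment = meta$treatment,
      week = meta$week, state = state[meta$sample_id],
      code = code[meta$sample_id],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("taxon_profiles", "data.frame")
  out
}

#' Heatmap-ready matrix of coded profiles
#'
#' @param profiles A [build_profiles()] result.
#' @return Matrix taxa x samples of heatmap codes (NA = below detection,
#'   0 = inactive, (0, 1\] = active relative abundance), columns ordered by
#'   treatment, mesocosm and week.
#' @export
profile_matrix <- function(profiles) {
  ord <- unique(profiles[order(profiles$treatment, profiles$mesocosm_id,
                               profiles$week), "sample_id"])
  taxa <- unique(profiles$otu_id)
  m <- matrix(NA_real_, length(taxa), length(ord), dimnames = list(taxa, ord))
  m[cbind(match(profiles$otu_id, taxa), match(profiles$sample_id, ord))] <-
    profiles$code
  m
}

#' Immigrant taxon set
#'
#' A taxon is an immigrant when it (1) is undetected in every disturbed
#' mesocosm at week 16 (the release of the press), (2) is detected in at
#' least one Control mesocosm at week 16, (3) is detected in a
#' Disturbance + Immigration mesocosm at week 20 or week 45, and (4)
#' remains undetected in all Disturbance (no-immigration) mesocosms at
#' weeks 20 and 45. Detection means at least one DNA read in the rarefied
#' Total table, so it is depth dependent; the depth is recorded on the
#' result.
#'
#' @param pair A [pair_counts()] object.
#' @param week_release,week_recovery The release week (default 16) and the
#'   recovery weeks (default 20 and 45).
#' @return Character vector of immigrant OTU ids with attribute `depth`.
#' @export
immigrant_set <- function(pair, week_release = 16L,
                          week_recovery = c(20L, 45L)) {
  stopifnot(inherits(pair, "press_pair"))
  meta <- pair$metadata
  sel <- function(treats, weeks) {
    ids <- meta$sample_id[meta$treatment %in% treats & meta$week %in% weeks]
    if (length(ids) == 0L)
      stop("no sample for treatment(s) ", paste(treats, collapse = "/"),
           " at week(s) ", paste(weeks, collapse = ","))
    pair$dna[ids, , drop = FALSE]
  }
  detected <- function(m) colSums(m > 0L) > 0L
  dist_release <- sel(c("disturbance", "disturbance_immigration"), week_release)
  ctrl_release <- sel("control", week_release)
  di_recovery <- sel("disturbance_immigration", week_recovery)
  d_recovery <- sel("disturbance", week_recovery)
  keep <- !detected(dist_release) & detected(ctrl_release) &
    detected(di_recovery) & !detected(d_recovery)
  structure(colnames(pair$dna)[keep], depth = pair$depth)
}

#' Responsive taxon set
#'
#' Taxa whose activity state flipped (active to inactive or the reverse)
#' between any two of the listed weeks within any disturbed mesocosm.
#' Both endpoints of a flip must have a defined rRNA:rRNA-gene ratio, so
#' phantom and undetected cells can never trigger a flip on their own.
#'
#' @param calls An [activity_calls()] result.
#' @param metadata Sample metadata covering the calls.
#' @param weeks Weeks of the secondary succession, default 16, 20, 45.
#' @return Character vector of responsive OTU ids.
#' @export
responsive_set <- function(calls, metadata, weeks = c(16L, 20L, 45L)) {
  metadata <- validate_metadata(metadata)
  meta <- metadata[metadata$treatment != "control" & metadata$week %in% weeks, ,
                   drop = FALSE]
  sub <- calls[calls$sample_id %in% meta$sample_id &
                 calls$state %in% c("active", "inactive"), , drop = FALSE]
  sub$mesocosm_id <- meta$mesocosm_id[match(sub$sample_id, meta$sample_id)]
  key <- paste(sub$mesocosm_id, sub$otu_id)
  flips <- tapply(sub$state, key, function(s) any(s == "active") && any(s == "inactive"))
  otus <- sub("^\\S+ ", "", names(flips)[flips])
  sort(unique(otus))
}

#' Assign disturbance-response categories
#'
#' Applies the first matching rule, evaluated on disturbed mesocosms with a
#' majority criterion: a taxon counts as "active" at a week or phase when
#' it is active in more than `majority` of the disturbed-mesocosm samples
#' of that week/phase. The immigrant rule is checked right after resistant
#' -- before sensitive -- because immigrant taxa (active before the press,
#' lost during it, returning only where dispersal was supplied) would
#' otherwise always satisfy the broader sensitive clause.
#'
#' Rule order: resistant, immigrant, sensitive, early_transition,
#' late_transition, resilient, opportunist, unclassified.
#'
#' @param profiles A [build_profiles()] result.
#' @param phases A [phase_map()].
#' @param immigrants Character vector from [immigrant_set()].
#' @param majority Activity majority threshold, default 0.5 (strict).
#' @return data.frame of class `response_categories`: `otu_id`, `category`.
#' @export
assign_categories <- function(profiles, phases = phase_map(),
                              immigrants = character(), majority = 0.5) {
  dist <- profiles[profiles$treatment != "control", , drop = FALSE]
  covered <- unique(dist$week)
  needed <- as.integer(names(phases)[phases %in% c("pre", "press", "post")])
  taxa <- unique(profiles$otu_id)
  if (!all(needed %in% covered)) {
    warning("disturbed samples do not cover the pre, press and post phases; ",
            "all taxa unclassified")
    return(structure(data.frame(otu_id = taxa, category = "unclassified",
                                stringsAsFactors = FALSE),
                     class = c("response_categories", "data.frame")))
  }
  dist$phase <- unname(phases[as.character(dist$week)])
  act_frac <- function(sub, sel) {
    s <- sub$state[sel]
    if (length(s) == 0L) return(0)
    mean(s == "active")
  }
  category <- character(length(taxa))
  for (i in seq_along(taxa)) {
    sub <- dist[dist$otu_id == taxa[i], , drop = FALSE]
    act_phase <- function(p) act_frac(sub, sub$phase == p) > majority
    act_week <- function(w) act_frac(sub, sub$week == w) > majority
    act_post_d_only <- act_frac(sub, sub$phase == "post" &
                                  sub$treatment == "disturbance") > majority
    pre <- act_phase("pre"); press <- act_phase("press"); post <- act_phase("post")
    category[i] <-
      if (pre && press && post) "resistant"
      else if (taxa[i] %in% immigrants) "immigrant"
      else if (pre && !press && !post) "sensitive"
      else if (!pre && (act_week(5L) || act_week(6L)) &&
               !act_week(10L) && !act_week(14L)) "early_transition"
      else if (!pre && !act_phase("ramp_up") &&
               (act_week(10L) || act_week(14L))) "late_transition"
      else if (pre && !press && act_post_d_only) "resilient"
      else if (!pre && !press && post) "opportunist"
      else "unclassified"
  }
  structure(data.frame(otu_id = taxa, category = category,
                       stringsAsFactors = FALSE),
            class = c("response_categories", "data.frame"))
}

#' @export
print.response_categories <- function(x, ...) {
  lv <- c("resistant", "sensitive", "early_transition", "late_transition",
          "resilient", "opportunist", "immigrant", "unclassified")
  tab <- table(factor(x$category, lv))
  cat("response categories (", nrow(x), " taxa):\n", sep = "")
  print(tab)
  invisible(x)
}

#' Contribution of responsive and immigrant taxa to beta diversity
#'
#' For every disturbed mesocosm and every ordered week pair of the
#' secondary succession (start-mid, mid-end, start-end), computes the share
#' of the Total-community Bray-Curtis dissimilarity carried by the
#' responsive and by the immigrant taxon sets ([subset_contribution()]),
#' and summarises each set's contributions as min / median / max.
#'
#' @param pair A [pair_counts()] object.
#' @param responsive,immigrants Character vectors of OTU ids (either may be
#'   empty, yielding zero contributions).
#' @param weeks The succession weeks, default 16, 20, 45 (giving pairs
#'   16-20, 20-45 and 16-45).
#' @return List of class `contribution_report` with `values` (long
#'   data.frame of per-mesocosm, per-pair contributions) and `summary`
#'   (min/median/max per subset, as percentages).
#' @export
contribution_report <- function(pair, responsive, immigrants,
                                weeks = c(16L, 20L, 45L)) {
  stopifnot(inherits(pair, "press_pair"))
  meta <- pair$metadata
  weeks <- sort(weeks)
  pairs_of_weeks <- utils::combn(weeks, 2, simplify = FALSE)
  sets <- list(responsive = responsive, immigrant = immigrants)
  rows <- list()
  for (meso in unique(meta$mesocosm_id[meta$treatment != "control"])) {
    for (wp in pairs_of_weeks) {
      s1 <- meta$sample_id[meta$mesocosm_id == meso & meta$week == wp[1]]
      s2 <- meta$sample_id[meta$mesocosm_id == meso & meta$week == wp[2]]
      if (length(s1) == 0L || length(s2) == 0L) next
      x <- pair$dna[s1[1], ]; y <- pair$dna[s2[1], ]
      for (set_name in names(sets)) {
        set <- sets[[set_name]]
        contrib <- if (length(set) == 0L) 0
          else subset_contribution(x, y, match(set, colnames(pair$dna)))
        rows[[length(rows) + 1L]] <- data.frame(
          mesocosm_id = meso, week_pair = paste0(wp[1], "-", wp[2]),
          subset = set_name, contribution = contrib,
          stringsAsFactors = FALSE)
      }
    }
  }
  values <- do.call(rbind, c(rows, make.row.names = FALSE))
  summ <- do.call(rbind, lapply(names(sets), function(s) {
    v <- values$contribution[values$subset == s]
    data.frame(subset = s,
               min_pct = 100 * min(v, na.rm = TRUE),
               median_pct = 100 * stats::median(v, na.rm = TRUE),
               max_pct = 100 * max(v, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  structure(list(values = values, summary = summ),
            class = "contribution_report")
}

#' @export
print.contribution_report <- function(x, ...) {
  cat("contribution of taxon subsets to Total-community beta diversity\n")
  print.data.frame(x$summary, digits = 3)
  invisible(x)
}
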