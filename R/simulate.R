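#' Configuration for the mesocosm press-disturbance simulator
#'
#' The simulator emulates a 15-mesocosm, 45-week soil warming experiment:
#' all mesocosms start from one homogenised community, six stay at the
#' ambient temperature (control), nine are ramped to a thermal press and
#' back (disturbance), and four of the nine receive a dispersal event --
#' an inoculum of the mean control community -- one week after the press
#' is released (disturbance_immigration). Each taxon carries active (A),
#' dormant (D) and relic-DNA (R) pools governed by a Gaussian thermal
#' niche; see [step_dynamics()].
#'
#' Taxa are drawn from planted archetypes whose rates were chosen for
#' archetype separability (the field supplies no quantitative dormancy
#' rates): `mesophile_sensitive`, `immigrant_lineage`,
#' `generalist_resistant`, `thermotolerant_transition_early`,
#' `thermotolerant_transition_late`, `opportunist`, `dormant_background`
#' and `relic_background`.
#'
#' @param n_sensitive,n_immigrant,n_generalist,n_early,n_late,n_opportunist,n_dormant,n_relic
#'   Taxa per archetype (defaults total 292).
#' @param K Carrying capacity for total active cells.
#' @param temp_ambient,temp_press Ambient and press temperatures (deg C).
#' @param weeks Sampling weeks.
#' @param n_control,n_disturbance,n_immigration Mesocosms per treatment.
#' @param dispersal_week Week of the dispersal event.
#' @param dispersal_fraction Injected cells as a fraction of the recipient's
#'   living (A + D) community; default 0.02, echoing a small soil-slurry
#'   inoculum.
#' @param depth_meanlog,depth_sdlog Log-normal parameters of the per-library
#'   sequencing depth (default: median 62000 reads with ~4% of libraries
#'   below a 50000-read rarefaction threshold).
#' @param c_amp Transcription amplification of active cells (RNA weight per
#'   active cell at full niche match); > 1 so active taxa have rRNA:rDNA
#'   ratio > 1 in expectation.
#' @param beta_maint Maintenance transcription of dormant cells (RNA weight
#'   per dormant cell); small and >= 0.
#' @param init_noise_sdlog Per-mesocosm log-normal jitter on initial pools.
#' @param ext_threshold Demographic extinction cutoff: pools below this many
#'   cells are set to zero, allowing true local extinction.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sensitive = 150L, n_immigrant = 12L,
                       n_generalist = 8L, n_early = 10L, n_late = 25L,
                       n_opportunist = 12L, n_dormant = 40L, n_relic = 35L,
                       K = 1.15e8,
                       temp_ambient = 14, temp_press = 60,
                       weeks = c(4L, 5L, 6L, 10L, 14L, 15L, 16L, 20L, 45L),
                       n_control = 6L, n_disturbance = 5L, n_immigration = 4L,
                       dispersal_week = 17L, dispersal_fraction = 0.02,
                       depth_meanlog = log(62000), depth_sdlog = 0.12,
                       c_amp = 10, beta_maint = 0.05,
                       init_noise_sdlog = 0.05, ext_threshold = 1) {
  cfg <- as.list(environment())
  stopifnot(dispersal_fraction >= 0, c_amp > 1, beta_maint >= 0, K > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Temperature schedule of the press disturbance
#'
#' Ambient for a 4-week acclimation, then a ramp to the press temperature
#' in daily increments of ~3.3 deg C over two weeks, an 8-week hold, a
#' two-week ramp down, and ambient thereafter. Control mesocosms stay at
#' ambient throughout.
#'
#' @param day Day(s) since the start of the experiment.
#' @param config A [sim_config()].
#' @param disturbed If `FALSE`, returns the ambient temperature.
#' @return Temperature(s) in deg C.
#' @export
temperature_schedule <- function(day, config = sim_config(), disturbed = TRUE) {
  lo <- config$temp_ambient; hi <- config$temp_press
  if (!disturbed) return(rep(lo, length(day)))
  rate <- (hi - lo) / 14
  ifelse(day <= 28, lo,
    ifelse(day <= 42, lo + (day - 28) * rate,
      ifelse(day <= 98, hi,
        ifelse(day <= 112, hi - (day - 98) * rate, lo))))
}

# per-taxon archetype parameter table; draws use the current RNG stream
build_community <- function(config) {
  draw <- function(arch, n, mu, sigma, r, d_a, k_in, k_out,
                   delta_d, delta_r, rho, A0, D0, R0) {
    if (n == 0L) return(NULL)
    data.frame(archetype = arch, mu = mu(n), sigma = sigma(n), r = r,
               d_a = d_a, k_in = k_in, k_out = k_out, delta_d = delta_d,
               delta_r = delta_r, rho = rho, A0 = A0(n), D0 = D0(n),
               R0 = R0(n), stringsAsFactors = FALSE)
  }
  zero <- function(n) numeric(n)
  taxa <- rbind(
    draw("mesophile_sensitive", config$n_sensitive,
         mu = function(n) stats::rnorm(n, 14, 2.5),
         sigma = function(n) stats::runif(n, 5, 8),
         r = 0.3, d_a = 0.05, k_in = 0.3, k_out = 0,
         delta_d = 0.001, delta_r = 0.02, rho = 0.3,
         A0 = function(n) stats::rlnorm(n, log(3.5e5), 0.8),
         D0 = zero, R0 = zero),
    draw("immigrant_lineage", config$n_immigrant,
         mu = function(n) stats::rnorm(n, 14, 2),
         sigma = function(n) stats::runif(n, 5, 7),
         r = 0.3, d_a = 0.2, k_in = 0, k_out = 0,
         delta_d = 0, delta_r = 0.25, rho = 0.3,
         A0 = function(n) stats::rlnorm(n, log(9e5), 0.3),
         D0 = zero, R0 = zero),
    draw("generalist_resistant", config$n_generalist,
         mu = function(n) stats::rnorm(n, 35, 2),
         sigma = function(n) stats::runif(n, 35, 45),
         r = 0.08, d_a = 0.03, k_in = 0.01, k_out = 0.01,
         delta_d = 0.001, delta_r = 0.02, rho = 0.3,
         A0 = function(n) stats::rlnorm(n, log(1.5e6), 0.3),
         D0 = zero, R0 = zero),
    draw("thermotolerant_transition_early", config$n_early,
         mu = function(n) stats::rnorm(n, 35, 1.5),
         sigma = function(n) stats::runif(n, 5, 7),
         r = 0.3, d_a = 0.2, k_in = 0.1, k_out = 0.35,
         delta_d = 0.002, delta_r = 0.02, rho = 0.3,
         A0 = zero,
         D0 = function(n) stats::rlnorm(n, log(6e6), 0.3),
         R0 = zero),
    draw("thermotolerant_transition_late", config$n_late,
         mu = function(n) stats::rnorm(n, 60, 1.5),
         sigma = function(n) stats::runif(n, 3.5, 5),
         r = 0.35, d_a = 0.15, k_in = 0.15, k_out = 0.04,
         delta_d = 0.002, delta_r = 0.02, rho = 0.3,
         A0 = zero,
         D0 = function(n) stats::rlnorm(n, log(1.2e6), 0.4),
         R0 = zero),
    draw("opportunist", config$n_opportunist,
         mu = function(n) stats::rnorm(n, 16, 1.5),
         sigma = function(n) stats::runif(n, 4, 6),
         r = 0.5, d_a = 0.15, k_in = 0.05, k_out = 0.004,
         delta_d = 0.0005, delta_r = 0.02, rho = 0.3,
         A0 = zero,
         D0 = function(n) stats::rlnorm(n, log(3e4), 0.3),
         R0 = zero),
    draw("dormant_background", config$n_dormant,
         mu = function(n) stats::rnorm(n, 25, 5),
         sigma = function(n) stats::runif(n, 4, 8),
         r = 0.1, d_a = 0.1, k_in = 0.1, k_out = 0,
         delta_d = 0.0005, delta_r = 0.02, rho = 0.3,
         A0 = zero,
         D0 = function(n) stats::rlnorm(n, log(5e5), 0.5),
         R0 = zero),
    draw("relic_background", config$n_relic,
         mu = function(n) stats::rnorm(n, 25, 5),
         sigma = function(n) stats::runif(n, 4, 8),
         r = 0, d_a = 0, k_in = 0, k_out = 0,
         delta_d = 0, delta_r = 0.003, rho = 0,
         A0 = zero, D0 = zero,
         R0 = function(n) stats::rlnorm(n, log(3e5), 0.5))
  )
  taxa$otu_id <- sprintf("OTU%03d", seq_len(nrow(taxa)))
  taxa[, c("otu_id", setdiff(names(taxa), "otu_id"))]
}

#' One daily step of the dormancy / thermal-niche dynamics
#'
#' With thermal niche match `f_i(T) = exp(-(T - mu_i)^2 / (2 sigma_i^2))`,
#' the active pool grows logistically (competition over total active
#' cells), dies and initiates dormancy when outside its niche, and gains
#' resuscitated dormant cells when inside it:
#' \deqn{A' = A (1 + r f (1 - N/K)) - d_a (1-f) A - k_{in} (1-f) A + k_{out} f D}
#' The dormant pool receives the inactivation flux, loses the resuscitation
#' flux and decays at `delta_d`; the relic pool receives a fraction `rho`
#' of all death fluxes and decays at `delta_r`. All pools are floored at
#' zero, and pools that fall below the extinction cutoff are set to zero.
#'
#' @param state List with numeric vectors `A`, `D`, `R` (one entry per
#'   taxon).
#' @param temp Temperature (deg C) during the step.
#' @param taxa Per-taxon parameter table (see [sim_config()] /
#'   `build_community`).
#' @param K Carrying capacity; must be positive.
#' @param ext_threshold Extinction cutoff in cells.
#' @return Updated state list.
#' @export
step_dynamics <- function(state, temp, taxa, K, ext_threshold = 1) {
  if (K <= 0) stop("carrying capacity K must be positive")
  f <- exp(-(temp - taxa$mu)^2 / (2 * taxa$sigma^2))
  A <- state$A; D <- state$D; R <- state$R
  N <- sum(A)
  growth <- taxa$r * f * (1 - N / K) * A
  death_a <- taxa$d_a * (1 - f) * A
  inact <- taxa$k_in * (1 - f) * A
  resus <- taxa$k_out * f * D
  decay_d <- taxa$delta_d * D
  A2 <- pmax(0, A + growth - death_a - inact + resus)
  D2 <- pmax(0, D + inact - resus - decay_d)
  R2 <- pmax(0, R + taxa$rho * (death_a + decay_d) - taxa$delta_r * R)
  A2[A2 < ext_threshold] <- 0
  D2[D2 < ext_threshold] <- 0
  R2[R2 < ext_threshold] <- 0
  list(A = A2, D = D2, R = R2)
}

#' Draw paired DNA and RNA read counts from a community state
#'
#' The DNA library is a multinomial draw with per-taxon weights
#' `A + D + R` (living cells plus relic DNA); the RNA library uses weights
#' `c_amp * A * f(T) + beta_maint * D`, so taxa dominated by active cells
#' have an rRNA:rDNA ratio above 1 in expectation, dormant taxa fall below
#' 1, and relic-only taxa can never yield RNA reads.
#'
#' @param state Community state (`A`, `D`, `R`).
#' @param temp Current temperature.
#' @param taxa Parameter table.
#' @param depth Reads per library.
#' @param c_amp,beta_maint See [sim_config()].
#' @return List with integer vectors `dna` and `rna` summing to `depth`.
#' @export
sample_reads <- function(state, temp, taxa, depth, c_amp = 10,
                         beta_maint = 0.05) {
  if (depth <= 0) stop("depth must be positive")
  f <- exp(-(temp - taxa$mu)^2 / (2 * taxa$sigma^2))
  w_dna <- state$A + state$D + state$R
  w_rna <- c_amp * state$A * f + beta_maint * state$D
  if (sum(w_dna) <= 0) stop("community has no DNA to sample")
  if (sum(w_rna) <= 0) stop("community has no transcriptional activity to sample")
  list(dna = as.integer(stats::rmultinom(1, depth, w_dna)),
       rna = as.integer(stats::rmultinom(1, depth, w_rna)))
}

#' Simulate the full press-disturbance mesocosm experiment
#'
#' Runs daily dynamics for all mesocosms from one jittered initial
#' community, applies the press schedule to disturbed mesocosms and the
#' dispersal event to the immigration treatment (an inoculum proportional
#' to the mean control community, scaled to `dispersal_fraction` of the
#' recipient's living cells, split between active and dormant pools in the
#' donors' proportions), and draws paired DNA/RNA libraries at each
#' sampled week with log-normally varying depth -- so a small fraction of
#' libraries falls below a 50000-read rarefaction threshold, as real
#' sequencing runs do.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return List of class `sim_result`: `dna` and `rna` ([otu_table()]s at
#'   raw depth), `metadata` (sample records), `truth` (list: `taxa` table
#'   with planted archetypes, `trajectories` array mesocosm x week x taxon
#'   x pool), `config`.
#' @export
simulate_press_experiment <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  taxa <- build_community(config)
  n_taxa <- nrow(taxa)
  weeks <- sort(config$weeks)
  n_meso <- config$n_control + config$n_disturbance + config$n_immigration
  treatment <- rep(c("control", "disturbance", "disturbance_immigration"),
                   c(config$n_control, config$n_disturbance, config$n_immigration))
  meso_ids <- sprintf("M%02d", seq_len(n_meso))
  horizon <- max(weeks) * 7L
  dispersal_day <- config$dispersal_week * 7L

  ## per-mesocosm jittered copies of the homogenised initial community
  states <- lapply(seq_len(n_meso), function(i) {
    jit <- function(v) v * stats::rlnorm(n_taxa, 0, config$init_noise_sdlog)
    list(A = jit(taxa$A0), D = jit(taxa$D0), R = jit(taxa$R0))
  })

  traj <- array(NA_real_, dim = c(n_meso, length(weeks), n_taxa, 3),
                dimnames = list(meso_ids, paste0("W", weeks), taxa$otu_id,
                                c("A", "D", "R")))
  dna <- matrix(0L, n_meso * length(weeks), n_taxa)
  rna <- matrix(0L, n_meso * length(weeks), n_taxa)
  meta <- list()
  row <- 0L
  depths <- matrix(pmax(1000, round(stats::rlnorm(n_meso * length(weeks) * 2,
                                                  config$depth_meanlog,
                                                  config$depth_sdlog))),
                   ncol = 2)
  sample_names <- character(n_meso * length(weeks))

  for (day in seq_len(horizon)) {
    ## dispersal event: inject mean control community into D+I mesocosms
    if (day == dispersal_day && config$dispersal_fraction > 0) {
      ctrl <- which(treatment == "control")
      mean_A <- Reduce(`+`, lapply(states[ctrl], `[[`, "A")) / length(ctrl)
      mean_D <- Reduce(`+`, lapply(states[ctrl], `[[`, "D")) / length(ctrl)
      donor <- mean_A + mean_D
      frac_active <- ifelse(donor > 0, mean_A / pmax(donor, 1e-300), 0)
      for (i in which(treatment == "disturbance_immigration")) {
        total <- config$dispersal_fraction *
          sum(states[[i]]$A + states[[i]]$D)
        inj <- total * donor / sum(donor)
        states[[i]]$A <- states[[i]]$A + inj * frac_active
        states[[i]]$D <- states[[i]]$D + inj * (1 - frac_active)
      }
    }
    for (i in seq_len(n_meso)) {
      temp <- temperature_schedule(day, config,
                                   disturbed = treatment[i] != "control")
      states[[i]] <- step_dynamics(states[[i]], temp, taxa, config$K,
                                   config$ext_threshold)
    }
    if (day %% 7L == 0L && (day %/% 7L) %in% weeks) {
      w <- day %/% 7L
      wi <- match(w, weeks)
      for (i in seq_len(n_meso)) {
        row <- row + 1L
        temp <- temperature_schedule(day, config,
                                     disturbed = treatment[i] != "control")
        reads <- sample_reads(states[[i]], temp, taxa,
                              depth = depths[row, 1],
                              c_amp = config$c_amp,
                              beta_maint = config$beta_maint)
        ## RNA library drawn at its own depth
        reads$rna <- sample_reads(states[[i]], temp, taxa,
                                  depth = depths[row, 2],
                                  c_amp = config$c_amp,
                                  beta_maint = config$beta_maint)$rna
        dna[row, ] <- reads$dna
        rna[row, ] <- reads$rna
        sample_names[row] <- sprintf("%s_W%02d", meso_ids[i], w)
        meta[[row]] <- data.frame(
          sample_id = sample_names[row], mesocosm_id = meso_ids[i],
          treatment = treatment[i], week = w, temperature_C = temp,
          stringsAsFactors = FALSE)
        traj[i, wi, , ] <- cbind(states[[i]]$A, states[[i]]$D, states[[i]]$R)
      }
    }
  }
  dimnames(dna) <- dimnames(rna) <- list(sample_names, taxa$otu_id)
  structure(list(
    dna = otu_table(dna, "DNA"),
    rna = otu_table(rna, "RNA"),
    metadata = do.call(rbind, meta),
    truth = list(taxa = taxa, trajectories = traj),
    config = config,
    seed = seed
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d taxa, %d samples (%d mesocosms x %d weeks), seed %d\n",
              ncol(x$dna), nrow(x$dna),
              length(unique(x$metadata$mesocosm_id)),
              length(unique(x$metadata$week)), x$seed))
  print(table(x$truth$taxa$archetype))
  invisible(x)
}

#' Expected response category and trajectory audit for planted taxa
#'
#' Maps each planted archetype to the response category it was scripted to
#' realise, and audits the realised (stochastic) trajectories in disturbed
#' mesocosms: a taxon whose trajectory deviated from its script at this
#' seed -- e.g. an opportunist that never bloomed after the press -- is
#' flagged so it can be excluded from recovery scoring.
#'
#' @param truth The `truth` element of a [simulate_press_experiment()]
#'   result.
#' @param metadata The matching sample metadata.
#' @param detection_rel Relative-abundance detection proxy, default 4e-5
#'   (~2 reads at a 50000-read depth).
#' @return data.frame: `otu_id`, `archetype`, `category` (expected label),
#'   `deviated` (logical trajectory audit flag).
#' @export
ground_truth_labels <- function(truth, metadata, detection_rel = 4e-5) {
  taxa <- truth$taxa
  traj <- truth$trajectories
  map <- c(mesophile_sensitive = "sensitive",
           immigrant_lineage = "immigrant",
           generalist_resistant = "resistant",
           thermotolerant_transition_early = "early_transition",
           thermotolerant_transition_late = "late_transition",
           opportunist = "opportunist",
           dormant_background = "unclassified",
           relic_background = "unclassified")
  meso_treat <- unique(metadata[, c("mesocosm_id", "treatment")])
  dist_meso <- meso_treat$mesocosm_id[meso_treat$treatment != "control"]
  weeks <- as.integer(sub("^W", "", dimnames(traj)[[2]]))
  ## active-cell relative abundance per mesocosm x week x taxon
  tot <- apply(traj, c(1, 2), sum)
  rel_active <- sweep(traj[, , , "A", drop = FALSE], c(1, 2), pmax(tot, 1), "/")
  maj_above <- function(w, thr = detection_rel) {
    wi <- match(w, weeks)
    m <- rel_active[dist_meso, wi, , 1, drop = FALSE]
    apply(m >= thr, 3, mean) > 0.5
  }
  pre_hi <- maj_above(4); p10_hi <- maj_above(10); p45_hi <- maj_above(45)
  w5_hi <- maj_above(5)
  deviated <- rep(FALSE, nrow(taxa))
  a <- taxa$archetype
  deviated[a == "mesophile_sensitive"] <-
    (!pre_hi | p10_hi | p45_hi)[a == "mesophile_sensitive"]
  deviated[a == "generalist_resistant"] <-
    (!pre_hi | !p10_hi | !p45_hi)[a == "generalist_resistant"]
  deviated[a == "thermotolerant_transition_early"] <-
    (!w5_hi | p10_hi)[a == "thermotolerant_transition_early"]
  deviated[a == "thermotolerant_transition_late"] <-
    (w5_hi | !p10_hi)[a == "thermotolerant_transition_late"]
  deviated[a == "opportunist"] <-
    (pre_hi | p10_hi | !p45_hi)[a == "opportunist"]
  ## immigrants must be gone from every disturbed mesocosm at the release
  w16 <- match(16L, weeks)
  if (!is.na(w16)) {
    residual <- apply(traj[dist_meso, w16, , , drop = FALSE], 3, sum)
    gone <- residual < detection_rel * mean(tot[dist_meso, w16])
    deviated[a == "immigrant_lineage"] <- !gone[a == "immigrant_lineage"]
  }
  data.frame(otu_id = taxa$otu_id, archetype = a,
             category = unname(map[a]), deviated = deviated,
             stringsAsFactors = FALSE)
}
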