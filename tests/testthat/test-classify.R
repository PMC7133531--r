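# build a synthetic profile table: states per week, replicated over two
# disturbed mesocosms (disturbance + disturbance_immigration)
make_profile <- function(otu, states,
                         weeks = c(4L, 5L, 6L, 10L, 14L, 15L, 16L, 20L, 45L),
                         states2 = states) {
  stopifnot(length(states) == length(weeks))
  df <- rbind(
    data.frame(otu_id = otu, sample_id = paste0("D1_W", weeks),
               mesocosm_id = "D1", treatment = "disturbance",
               week = weeks, state = states),
    data.frame(otu_id = otu, sample_id = paste0("I1_W", weeks),
               mesocosm_id = "I1", treatment = "disturbance_immigration",
               week = weeks, state = states2))
  df$code <- ifelse(df$state == "active", 1,
                    ifelse(df$state == "inactive", 0, NA_real_))
  df
}

test_that("each response category is recognised from its defining motif", {
  A <- "active"; I <- "inactive"; U <- "undetected"
  profs <- rbind(
    make_profile("res", c(A, A, A, A, A, A, A, A, A)),
    make_profile("sen", c(A, I, I, U, U, U, U, I, I)),
    make_profile("ear", c(I, A, A, I, I, I, I, I, I)),
    make_profile("lat", c(U, I, I, A, A, A, I, I, I)),
    make_profile("rsl", c(A, I, I, U, U, I, I, A, A)),
    make_profile("opp", c(I, I, I, U, U, I, I, A, A)),
    make_profile("imm", c(A, I, I, U, U, U, U, U, U),
                 states2 = c(A, I, I, U, U, U, U, A, A)),
    make_profile("unc", c(I, I, I, I, I, A, A, I, I)))
  class(profs) <- c("taxon_profiles", "data.frame")
  out <- assign_categories(profs, phase_map(), immigrants = "imm")
  got <- setNames(out$category, out$otu_id)
  expect_identical(got[["res"]], "resistant")
  expect_identical(got[["sen"]], "sensitive")
  expect_identical(got[["ear"]], "early_transition")
  expect_identical(got[["lat"]], "late_transition")
  expect_identical(got[["rsl"]], "resilient")
  expect_identical(got[["opp"]], "opportunist")
  expect_identical(got[["imm"]], "immigrant")
  expect_identical(got[["unc"]], "unclassified")
  # labels are mutually exclusive and exhaustive
  expect_identical(anyDuplicated(out$otu_id), 0L)
  expect_false(any(is.na(out$category)))
})

test_that("the majority rule aggregates replicates: half-active is not active", {
  A <- "active"; I <- "inactive"
  # active during the press in one of two mesocosms only -> not press-active,
  # so the taxon reads as sensitive rather than resistant
  profs <- make_profile("amb", c(A, A, A, A, A, A, A, A, A),
                        states2 = c(A, I, I, I, I, I, I, I, I))
  class(profs) <- c("taxon_profiles", "data.frame")
  out <- assign_categories(profs, phase_map())
  expect_identical(out$category, "sensitive")
})

test_that("missing phase coverage yields unclassified with a warning", {
  A <- "active"
  profs <- make_profile("x", c(A, A, A), weeks = c(4L, 5L, 6L))
  class(profs) <- c("taxon_profiles", "data.frame")
  expect_warning(out <- assign_categories(profs, phase_map()), "cover")
  expect_identical(out$category, "unclassified")
})

test_that("top-active selection ranks by summed reads with deterministic ties", {
  m <- matrix(c(5L, 9L, 9L, 0L,
                5L, 1L, 1L, 0L), 2, 4, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("zeta", "beta", "alpha", "nil")))
  act <- structure(m, depth = 20L, class = c("active_table", "matrix", "array"))
  expect_identical(select_top_active(act, 1), "alpha")  # tie with beta: lexicographic
  expect_identical(select_top_active(act, 3), c("alpha", "beta", "zeta"))
  expect_warning(top <- select_top_active(act, 4), "ever active")
  expect_identical(length(top), 3L)
  expect_error(select_top_active(act, 0), "at least 1")
})

test_that("profiles code below-detection as NA, inactive as 0, active as relative abundance", {
  pair <- toy_pair()
  act <- suppressWarnings(active_table(pair))
  profs <- build_profiles(pair, act, colnames(pair$dna))
  cell <- function(otu, s) profs[profs$otu_id == otu & profs$sample_id == s, ]
  expect_true(is.na(cell("OTU4", "M01_W04")$code))       # dna = 0, rna = 0
  expect_identical(cell("OTU4", "M01_W04")$state, "undetected")
  expect_identical(cell("OTU2", "M01_W04")$code, 0)      # detected, rna <= dna
  # active cells are scaled to the taxon's max in disturbed mesocosms
  expect_identical(cell("OTU1", "M02_W04")$code, 1)
  expect_identical(cell("OTU4", "M02_W10")$code, 1)
  expect_error(build_profiles(pair, act, "nope"), "unknown taxa")
  hm <- profile_matrix(profs)
  expect_identical(dim(hm), c(4L, 4L))
  expect_identical(hm["OTU1", "M02_W04"], 1)
})

test_that("the four-clause immigrant rule includes and excludes correctly", {
  otus <- c("IMM", "DETD", "NOC", "FILL")
  samples <- c("C1_W16", "C1_W20", "C1_W45",
               "D1_W16", "D1_W20", "D1_W45",
               "I1_W16", "I1_W20", "I1_W45")
  dna <- matrix(0L, 9, 4, dimnames = list(samples, otus))
  dna[, "FILL"] <- 10L
  fill_to <- function(m, s, otu, n) { m[s, otu] <- n; m[s, "FILL"] <- m[s, "FILL"] - n; m }
  # IMM: absent in all disturbed at 16, in control at 16, returns in I1 only
  dna <- fill_to(dna, "C1_W16", "IMM", 3L)
  dna <- fill_to(dna, "I1_W20", "IMM", 2L)
  # DETD: like IMM but also detected in the no-immigration mesocosm at 45
  dna <- fill_to(dna, "C1_W16", "DETD", 2L)
  dna <- fill_to(dna, "I1_W45", "DETD", 2L)
  dna <- fill_to(dna, "D1_W45", "DETD", 1L)
  # NOC: returns in I1 but was never in the controls at the release
  dna <- fill_to(dna, "I1_W20", "NOC", 2L)
  rna <- matrix(0L, 9, 4, dimnames = list(samples, otus)); rna[, "FILL"] <- 10L
  meta <- data.frame(sample_id = samples,
                     mesocosm_id = rep(c("C1", "D1", "I1"), each = 3),
                     treatment = rep(c("control", "disturbance",
                                       "disturbance_immigration"), each = 3),
                     week = rep(c(16L, 20L, 45L), 3), temperature_C = 14)
  pair <- pair_counts(otu_table(dna, "DNA"), otu_table(rna, "RNA"), meta)
  imm <- immigrant_set(pair)
  expect_identical(as.character(imm), "IMM")
  expect_identical(attr(imm, "depth"), 10L)
  # a missing treatment x week stratum is an error, not a silent zero
  expect_error(immigrant_set(pair, week_release = 10L), "no sample")
})

test_that("responsive taxa are activity flips; phantoms cannot flip", {
  calls <- data.frame(
    sample_id = rep(c("D1_W16", "D1_W20", "D1_W45"), each = 3),
    otu_id = rep(c("flip", "steady", "ghost"), 3),
    state = c("inactive", "active", "phantom",
              "active", "active", "active",
              "inactive", "active", "active"))
  meta <- data.frame(sample_id = c("D1_W16", "D1_W20", "D1_W45"),
                     mesocosm_id = "D1", treatment = "disturbance",
                     week = c(16L, 20L, 45L), temperature_C = 14)
  out <- responsive_set(calls, meta)
  expect_true("flip" %in% out)
  expect_false("steady" %in% out)   # active at all three weeks
  # ghost: phantom at 16 then active -- no defined-ratio flip
  expect_false("ghost" %in% out)
})

test_that("contribution report spans zero and one at the subset extremes", {
  pair <- toy_pair()
  all_otus <- colnames(pair$dna)
  rep_all <- contribution_report(pair, responsive = all_otus,
                                 immigrants = character(), weeks = c(4L, 10L))
  vals <- rep_all$values
  expect_equal(vals$contribution[vals$subset == "responsive"], 1)
  expect_equal(vals$contribution[vals$subset == "immigrant"], 0)
  expect_identical(rep_all$summary$max_pct, c(100, 0))
})
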