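# Polarity, hydropathy and volume statistics, and the loop<->strand
# transition analysis.

test_that("the polar/nonpolar partition is exactly the published one", {
  expect_identical(unname(polarity_class(c("A", "F", "I", "L", "M", "P",
                                           "V", "W", "Y"))),
                   rep("nonpolar", 9))
  expect_identical(unname(polarity_class(c("C", "D", "E", "G", "H", "K",
                                           "N", "Q", "R", "S", "T"))),
                   rep("polar", 11))
  expect_error(polarity_class("X"), "unknown")
})

test_that("alternation fraction follows the region-denominator formula", {
  expect_equal(alternation_fraction("LTLT"), 0.75)
  expect_equal(alternation_fraction("LLLL"), 0)
  # gap: the step into the gap and the step immediately after are skipped,
  # but the denominator stays the full region length (brute-force walk: 2
  # opposite-polarity steps out of 5 positions)
  expect_equal(alternation_fraction("LT-LT"), 0.4)
  expect_equal(alternation_fraction("LTLT", gap_mask = c(FALSE, FALSE,
                                                         TRUE, FALSE)),
               1 / 4)
  expect_error(alternation_fraction("L"), "length >= 2")
  # alternative denominator counts eligible steps only
  expect_equal(alternation_fraction("LT-LT", denominator = "steps"), 1)
})

test_that("alternating regions score (L-1)/L and homopolymers 0", {
  for (L in c(2, 5, 9, 14)) {
    reg <- paste(rep(c("V", "S"), length.out = L), collapse = "")
    expect_equal(alternation_fraction(reg), (L - 1) / L)
    expect_equal(alternation_fraction(strrep("M", L)), 0)
  }
})

test_that("mean hydropathy matches the bundled scale", {
  expect_equal(mean_hydropathy("AILV"), 3.575)
  expect_equal(mean_hydropathy("W"), -0.9)
  expect_lt(mean_hydropathy("DE"), 0)
  # permutation invariance and scale bounds
  set.seed(5)
  aa <- sample(names(kd_hydropathy()), 12, replace = TRUE)
  expect_equal(mean_hydropathy(aa), mean_hydropathy(rev(aa)))
  expect_gte(mean_hydropathy(aa), min(kd_hydropathy()))
  expect_lte(mean_hydropathy(aa), max(kd_hydropathy()))
  expect_equal(mean_hydropathy("A-L", gap_mask = NULL),
               mean(kd_hydropathy()[c("A", "L")]))
  expect_error(mean_hydropathy("--"), "gap-aligned")
})

test_that("strand residue volumes average the bundled volume table", {
  ann <- tibble::tibble(strand = 1:2, start = c(1, 6), end = c(4, 9),
                        direction = c(1L, -1L))
  expect_equal(mean_strand_residue_volume(ann, "GGGGXGGGG"), 60.1)
  expect_equal(mean_strand_residue_volume(
    tibble::tibble(strand = 1, start = 1, end = 4, direction = 1L),
    "GAVL"
  ), mean(residue_volume()[c("G", "A", "V", "L")]))
  w <- mean_strand_residue_volume(
    tibble::tibble(strand = 1, start = 1, end = 3, direction = 1L), "WWW")
  a <- mean_strand_residue_volume(
    tibble::tibble(strand = 1, start = 1, end = 3, direction = 1L), "AAA")
  expect_gt(w, a)
})

make_transition_battery <- function(seeds) {
  recs <- NULL
  anns <- list()
  seqs <- character()
  for (s in seeds) {
    sc <- make_scenario("loop_to_hairpin", seed = s)
    r <- sc$record
    r$query_id <- paste0(r$query_id, "_", s)
    r$target_id <- paste0(r$target_id, "_", s)
    anns[[r$query_id]] <- sc$query$annotation
    anns[[r$target_id]] <- sc$target$annotation
    seqs[[r$query_id]] <- sc$query$sequence
    seqs[[r$target_id]] <- sc$target$sequence
    recs <- dplyr::bind_rows(recs, r)
  }
  list(recs = recs, anns = anns, seqs = seqs)
}

test_that("transition regions look strand-like, control loops do not", {
  bt <- make_transition_battery(1:4)
  cl <- classify_all(bt$recs, bt$anns)
  ts <- transition_region_stats(cl, bt$recs, bt$anns, bt$seqs)
  alt <- setNames(ts$mean_alternation, ts$group)
  # planted strand-like alternation in the transition loops: the loop
  # conformation alternates like the strand conformation, far above the
  # all-polar control loops
  expect_equal(alt[["control_loops"]], 0)
  expect_gt(alt[["loop_conformation"]], 0.8)
  expect_gt(alt[["strand_conformation"]], 0.8)
  expect_gt(alt[["loop_conformation"]], alt[["control_loops"]] + 0.5)
  # control loops are all-polar, hence strongly hydrophilic
  hyd <- setNames(ts$mean_hydropathy, ts$group)
  expect_lt(hyd[["control_loops"]], 0)
  expect_gt(hyd[["strand_conformation"]], hyd[["control_loops"]])
})

test_that("identical re-aligned regions are deduplicated", {
  bt <- make_transition_battery(7)
  # the same record twice: the same region aligned twice at 100% identity
  recs2 <- dplyr::bind_rows(bt$recs, bt$recs)
  cl <- classify_all(recs2, bt$anns)
  ts2 <- transition_region_stats(cl, recs2, bt$anns, bt$seqs)
  ts1 <- transition_region_stats(classify_all(bt$recs, bt$anns),
                                 bt$recs, bt$anns, bt$seqs)
  expect_identical(
    ts2$n_regions[ts2$group == "loop_conformation"],
    ts1$n_regions[ts1$group == "loop_conformation"]
  )
})

test_that("group means are bit-identical across repeated evaluation", {
  bt <- make_transition_battery(2:3)
  cl <- classify_all(bt$recs, bt$anns)
  a <- transition_region_stats(cl, bt$recs, bt$anns, bt$seqs)
  b <- transition_region_stats(cl, bt$recs, bt$anns, bt$seqs)
  expect_identical(a, b)
})

test_that("no transition alignments yields an empty table with a warning", {
  sc <- make_scenario("cterm_duplication", seed = 1)
  anns <- list()
  anns[[sc$record$query_id]] <- sc$query$annotation
  anns[[sc$record$target_id]] <- sc$target$annotation
  cl <- classify_all(sc$record, anns)
  seqs <- setNames(c(sc$query$sequence, sc$target$sequence),
                   c(sc$record$query_id, sc$record$target_id))
  expect_warning(ts <- transition_region_stats(cl, sc$record, anns, seqs),
                 "no loop")
  expect_identical(nrow(ts), 0L)
})
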