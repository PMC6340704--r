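# Topological classification: internal repeats and cross-barrel taxonomy.

corr_stub <- function(q_pairs, t_pairs, q_n, t_n, cross = NULL) {
  structure(
    list(
      strand_pairs = tibble::tibble(q_strand = q_pairs, t_strand = t_pairs,
                                    support = 10L),
      cross_matches = cross %||% tibble::tibble(
        q_kind = character(), q_idx = integer(),
        t_kind = character(), t_idx = integer(), support = integer()
      ),
      q_n = q_n, t_n = t_n, theta = 3
    ),
    class = "strand_correspondence"
  )
}

test_that("internal repeats classify by their strand offset", {
  expect_identical(classify_internal(corr_stub(1:7, 3:9, 10, 10)),
                   "HAIRPIN_SHIFT")
  expect_identical(classify_internal(corr_stub(1:3, 5:7, 8, 8)),
                   "DOUBLE_HAIRPIN_SHIFT")
  expect_identical(classify_internal(corr_stub(1:8, 1:8, 8, 8)), "NONE")
  expect_identical(classify_internal(corr_stub(c(1, 2), c(4, 7), 10, 10)),
                   "OTHER")
  expect_error(classify_internal(corr_stub(1:2, 1:2, 8, 10)),
               "self-alignment")
})

test_that("cross classification implements the anchoring taxonomy", {
  # strands 4-13 of a 14 vs strands 10-19 of a 22: internal offset
  expect_identical(classify_cross(corr_stub(4:13, 10:19, 14, 22))$category,
                   "INTERNAL_OFFSET")
  # 8 -> 16 with constant C-offset 0: C-terminal anchoring, all 8 covered
  res <- classify_cross(corr_stub(1:8, 9:16, 8, 16))
  expect_identical(res$category, "CTERM_ANCHORED")
  expect_true(res$covers_all_query_strands)
  expect_true(res$includes_last_strands)
  # C-anchoring without the final strand still counts (offset-based)
  res2 <- classify_cross(corr_stub(3:6, 11:14, 8, 16))
  expect_identical(res2$category, "CTERM_ANCHORED")
  expect_false(res2$includes_last_strands)
  expect_identical(classify_cross(corr_stub(1:6, 1:6, 8, 16))$category,
                   "NTERM_ANCHORED")
  # equal counts + identity: reported C-terminal but flagged ambiguous
  res3 <- classify_cross(corr_stub(1:8, 1:8, 8, 8))
  expect_identical(res3$category, "CTERM_ANCHORED")
  expect_true(res3$ambiguous_anchor)
  # insufficient evidence
  res4 <- classify_cross(corr_stub(2L, 5L, 8, 16))
  expect_identical(res4$category, "OTHER")
  expect_true(res4$insufficient)
})

test_that("every planted scenario kind is recovered noise-free", {
  for (kind in scenario_kinds) {
    for (seed in 1:3) {
      sc <- make_scenario(kind, seed = seed)
      expect_identical(recover_scenario(sc), kind,
                       info = sprintf("%s seed %d", kind, seed))
    }
  }
})

test_that("large rearrangements carry redirection and all three cross kinds", {
  sc <- make_scenario("large_rearrangement", seed = 10)
  anns <- list()
  anns[[sc$record$query_id]] <- sc$query$annotation
  anns[[sc$record$target_id]] <- sc$target$annotation
  cl <- classify_all(sc$record, anns)
  expect_identical(cl$category, "LARGE_REARRANGEMENT")
  expect_true(cl$has_redirection)
  cm <- cl$corr[[1]]$cross_matches
  expect_true(any(cm$q_kind == "loop" & cm$t_kind == "strand"))
  expect_true(any(cm$q_kind == "strand" & cm$t_kind == "loop"))
})

test_that("classification is invariant to query/target swap", {
  for (kind in c("cterm_duplication", "internal_offset",
                 "loop_to_hairpin")) {
    sc <- make_scenario(kind, seed = 6)
    corr <- map_to_strands(sc$record, sc$query$annotation,
                           sc$target$annotation)
    res <- classify_cross(corr)
    res_sw <- classify_cross(transpose_correspondence(corr))
    expect_identical(res$category, res_sw$category, info = kind)
  }
})

test_that("same-pair records in one region are flagged as alternate alignments", {
  sc1 <- make_scenario("loop_to_hairpin", seed = 21)
  sc2 <- make_scenario("loop_to_hairpin", seed = 22)
  rec <- dplyr::bind_rows(sc1$record, sc2$record)
  anns <- list()
  anns[[sc1$record$query_id]] <- sc1$query$annotation
  anns[[sc1$record$target_id]] <- sc1$target$annotation
  cl <- classify_all(rec, anns)
  expect_true(all(cl$has_alternate_alignment))
  expect_true(all(cl$category == "LOOP_TO_HAIRPIN_ALT"))
  # single records stay unflagged
  cl1 <- classify_all(sc1$record, anns)
  expect_false(cl1$has_alternate_alignment)
})

test_that("classify_all skips unannotated proteins and handles empty input", {
  sc <- make_scenario("cterm_duplication", seed = 2)
  expect_warning(
    cl <- classify_all(sc$record, list(somebody_else = sc$query$annotation)),
    "not annotated"
  )
  expect_identical(nrow(cl), 0L)
  empty <- classify_all(sc$record[0, ], list())
  expect_identical(nrow(empty), 0L)
})

test_that("a one-per-kind battery summarizes one count per category", {
  recs <- NULL
  anns <- list()
  for (i in seq_along(scenario_kinds)) {
    sc <- make_scenario(scenario_kinds[i], seed = 40 + i)
    r <- sc$record
    # distinct protein ids per scenario to keep pairs separate
    r$query_id <- paste0(r$query_id, "_", i)
    r$target_id <- if (r$is_self[1]) r$query_id else
      paste0(r$target_id, "_", i)
    anns[[r$query_id]] <- sc$query$annotation
    anns[[r$target_id]] <- sc$target$annotation
    recs <- dplyr::bind_rows(recs, r)
  }
  cl <- classify_all(recs, anns)
  expect_identical(nrow(cl), length(scenario_kinds))
  summ <- classification_summary(cl)
  expect_identical(sum(summ$n), length(scenario_kinds))
  got <- mapply(recovered_kind, cl$category, cl$repeat_class,
                recs$is_self, cl$has_redirection)
  expect_setequal(unname(got), scenario_kinds)
})
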