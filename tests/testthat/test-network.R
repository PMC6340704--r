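# Similarity network construction and the network-level statistics.

test_that("edges respect the threshold and dedup to one per pair", {
  rec <- alignment_records(
    c("A", "B"), c("B", "C"), evalue = c(1e-4, 1e-2),
    pairs = list(tibble::tibble(q_pos = 1:25, t_pos = 1:25),
                 tibble::tibble(q_pos = 1:25, t_pos = 1:25))
  )
  nw <- build_network(rec, threshold = 1e-3)
  expect_identical(glance(nw)$n_edges, 1L)
  expect_identical(glance(nw)$n_nodes, 3L)  # C kept as isolate
  empty <- build_network(rec[0, ], threshold = 1e-3,
                         nodes = tibble::tibble(protein_id = c("A", "B")))
  expect_identical(glance(empty)$n_edges, 0L)
})

test_that("edge sets nest monotonically across thresholds", {
  set.seed(71)
  ids <- sprintf("p%02d", 1:12)
  pick <- t(utils::combn(ids, 2))
  sel <- sample(nrow(pick), 30, replace = FALSE)
  rec <- alignment_records(
    pick[sel, 1], pick[sel, 2],
    evalue = 10^stats::runif(30, -15, -2),
    pairs = replicate(30, tibble::tibble(q_pos = 1:25, t_pos = 1:25),
                      simplify = FALSE)
  )
  thr <- c(1e-3, 1e-5, 1e-7, 1e-12)
  edge_sets <- lapply(thr, function(t) {
    e <- tidy(build_network(rec, threshold = t))
    paste(pmin(e$from, e$to), pmax(e$from, e$to))
  })
  for (i in 2:4) {
    expect_true(all(edge_sets[[i]] %in% edge_sets[[i - 1]]))
  }
})

test_that("largest component picks the biggest group with lexicographic ties", {
  clique <- function(ids) {
    p <- t(utils::combn(ids, 2))
    alignment_records(p[, 1], p[, 2], evalue = 1e-6,
                      pairs = replicate(nrow(p),
                                        tibble::tibble(q_pos = 1:25,
                                                       t_pos = 1:25),
                                        simplify = FALSE))
  }
  rec <- dplyr::bind_rows(clique(c("a", "b", "c", "d", "e")),
                          clique(c("x", "y", "z")))
  expect_identical(largest_component(build_network(rec, 1e-3)),
                   c("a", "b", "c", "d", "e"))
  # fully disconnected: tie broken to the lexicographically smallest node
  iso <- build_network(rec[0, ], 1e-3,
                       nodes = tibble::tibble(protein_id = c("m", "b", "k")))
  expect_identical(largest_component(iso), "b")
})

test_that("same-vs-different strand-number probabilities count pairs correctly", {
  nodes <- tibble::tibble(protein_id = c("a", "b", "c", "x", "y"),
                          n_strands = c(8L, 8L, 8L, 10L, 10L))
  same3 <- alignment_records(c("a", "a", "b"), c("b", "c", "c"),
                             evalue = 1e-6,
                             pairs = replicate(3, tibble::tibble(q_pos = 1:25,
                                                                 t_pos = 1:25),
                                               simplify = FALSE))
  pr <- same_vs_diff_probability(build_network(same3, 1e-3, nodes = nodes))
  expect_equal(pr$probability[pr$n_i == 8 & pr$n_j == 8], 1)
  expect_equal(pr$probability[pr$n_i == 10 & pr$n_j == 10], 0)
  # 3 cross edges between a 3-group and a 2-group: 3 / (3*2) = 0.5
  cross3 <- alignment_records(c("a", "b", "c"), c("x", "x", "y"),
                              evalue = 1e-6,
                              pairs = replicate(3, tibble::tibble(q_pos = 1:25,
                                                                  t_pos = 1:25),
                                                simplify = FALSE))
  pr2 <- same_vs_diff_probability(build_network(cross3, 1e-3, nodes = nodes))
  expect_equal(pr2$probability[pr2$n_i == 8 & pr2$n_j == 10], 0.5)
})

test_that("log-space mean E-value is the geometric mean", {
  expect_equal(mean_log_evalue(c(1e-3, 1e-7)), 1e-5)
  expect_equal(mean_log_evalue(1e-6), 1e-6)
  expect_equal(mean_log_evalue(c(1e-20, 1e-26)), 1e-23)
  expect_error(mean_log_evalue(numeric(0)), "empty")
  expect_error(mean_log_evalue(c(1e-3, 0)), "positive")
})

test_that("conservation profiles count both sides of every strand pair", {
  sc <- make_scenario("cterm_duplication", seed = 9)
  anns <- list()
  anns[[sc$record$query_id]] <- sc$query$annotation
  anns[[sc$record$target_id]] <- sc$target$annotation
  cl <- classify_all(sc$record, anns)
  prof <- conservation_profile(cl)
  p8 <- prof[prof$n_strands == 8, ]
  expect_identical(p8$count, rep(1L, 8))
  p16 <- prof[prof$n_strands == 16, ]
  expect_identical(p16$count[p16$position <= 8], rep(0L, 8))
  expect_identical(p16$count[p16$position > 8], rep(1L, 8))
  # total = 2 x number of strand pairs
  expect_identical(sum(prof$count),
                   2L * nrow(cl$corr[[1]]$strand_pairs))
  empty <- conservation_profile(cl[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("a C-terminally biased battery concentrates counts in the C-half", {
  recs <- NULL
  anns <- list()
  for (i in 1:6) {
    sc <- make_scenario("cterm_duplication", seed = 100 + i)
    r <- sc$record
    r$query_id <- paste0(r$query_id, "_", i)
    r$target_id <- paste0(r$target_id, "_", i)
    anns[[r$query_id]] <- sc$query$annotation
    anns[[r$target_id]] <- sc$target$annotation
    recs <- dplyr::bind_rows(recs, r)
  }
  cl <- classify_all(recs, anns)
  prof <- conservation_profile(cl)
  p16 <- prof[prof$n_strands == 16, ]
  c_half <- sum(p16$count[p16$position > 8])
  n_half <- sum(p16$count[p16$position <= 8])
  expect_gt(c_half, n_half)
})

test_that("membership overlap summarizes cross-strand-number pairs", {
  m <- generate_membership(6, 0.02, seed = 2, set_size = 100)
  ov <- membership_overlap(m)
  s <- overlap_summary(ov)
  expect_lte(s$max_overlap_pct, 3)
  expect_gte(s$mean_overlap_pct, 0)
  expect_identical(s$n_pairs, sum(!ov$same_n))
  # identical and disjoint reference cases
  two <- tibble::tibble(profile_id = c("a", "b"), n_strands = c(8L, 10L),
                        members = list(letters[1:4], letters[1:4]))
  expect_equal(membership_overlap(two)$overlap_pct, 100)
  expect_error(membership_overlap(two[1, ]), "two profiles")
})
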