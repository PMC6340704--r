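# Topological classification of strand correspondences: internal-repeat
# classes for self-alignments, anchoring/transition categories for
# cross-barrel alignments.

.CATEGORIES <- c("CTERM_ANCHORED", "NTERM_ANCHORED", "INTERNAL_OFFSET",
                 "LOOP_TO_HAIRPIN", "LOOP_TO_HAIRPIN_ALT",
                 "LARGE_REARRANGEMENT", "OTHER")
.REPEAT_CLASSES <- c("HAIRPIN_SHIFT", "DOUBLE_HAIRPIN_SHIFT", "OTHER", "NONE")

#' Classify an internal (self-alignment) repeat
#'
#' A hairpin shift is a self-alignment whose aligned strands are offset by
#' two (strands 1..7 aligned to 3..9); a double hairpin shift is offset by
#' four. The identity mapping is no repeat.
#'
#' @param corr A `strand_correspondence` from a self-alignment.
#' @return One of `"HAIRPIN_SHIFT"`, `"DOUBLE_HAIRPIN_SHIFT"`, `"OTHER"`,
#'   `"NONE"`.
#' @export
classify_internal <- function(corr) {
  if (corr$q_n != corr$t_n) abort("internal classification needs a self-alignment")
  sp <- corr$strand_pairs
  if (nrow(sp) == 0) return("OTHER")
  off <- sp$t_strand - sp$q_strand
  if (all(off == 0)) return("NONE")
  if (length(unique(off)) == 1 && nrow(sp) >= 2) {
    if (abs(off[1]) == 2) return("HAIRPIN_SHIFT")
    if (abs(off[1]) == 4) return("DOUBLE_HAIRPIN_SHIFT")
  }
  "OTHER"
}

# does a loop region on side A match two adjacent strands on side B?
.find_hairpin_cross <- function(cm) {
  for (side in c("q", "t")) {
    lk <- paste0(side, "_kind"); li <- paste0(side, "_idx")
    ok <- paste0(if (side == "q") "t" else "q", "_kind")
    oi <- paste0(if (side == "q") "t" else "q", "_idx")
    loops <- cm[cm[[lk]] == "loop" & cm[[ok]] == "strand", , drop = FALSE]
    if (nrow(loops) < 2) next
    for (lid in unique(loops[[li]])) {
      hits <- sort(loops[[oi]][loops[[li]] == lid])
      if (length(hits) >= 2 && any(diff(hits) == 1)) {
        return(list(loop_side = side, loop_idx = lid, strands = hits))
      }
    }
  }
  NULL
}

#' Classify a cross-protein alignment
#'
#' Applies the anchoring/transition taxonomy. With C-offsets
#' `c_i = (q_n - q_strand) - (t_n - t_strand)`: all `c_i = 0` is C-terminal
#' anchoring (last strands align, penultimate strands align, ...); all
#' `q_strand = t_strand` is N-terminal anchoring; a constant nonzero offset
#' with no qualifying cross-matches is an internal offset. A qualifying
#' loop-to-hairpin cross-match (one side's loop aligned to two adjacent
#' strands of the other) gives `LOOP_TO_HAIRPIN`; combined with a
#' strand-to-loop and an additional loop-to-strand match it is a
#' `LARGE_REARRANGEMENT`. Anything else is `OTHER`. Anchoring is
#' offset-based, not last-strand-based, so C-terminally anchored
#' alignments need not contain the last strand.
#'
#' @param corr A `strand_correspondence` from a cross-protein alignment.
#' @param directions_q,directions_t Optional strand directions for
#'   redirection flagging.
#' @return List with `category`, and flags `includes_last_strands`,
#'   `covers_all_query_strands`, `has_redirection`, `ambiguous_anchor`,
#'   `insufficient`.
#' @export
classify_cross <- function(corr, directions_q = NULL, directions_t = NULL) {
  sp <- corr$strand_pairs
  cm <- corr$cross_matches
  flips <- if (!is.null(directions_q) && !is.null(directions_t)) {
    detect_redirection(corr, directions_q, directions_t)
  } else tibble(q_strand = integer(), t_strand = integer())
  flags <- list(
    includes_last_strands = any(sp$q_strand == corr$q_n &
                                  sp$t_strand == corr$t_n),
    covers_all_query_strands = length(unique(sp$q_strand)) == corr$q_n,
    has_redirection = nrow(flips) > 0,
    ambiguous_anchor = FALSE,
    insufficient = FALSE
  )
  if (nrow(sp) < 2 && nrow(cm) == 0) {
    flags$insufficient <- TRUE
    return(c(list(category = "OTHER"), flags))
  }
  hp <- .find_hairpin_cross(cm)
  if (!is.null(hp)) {
    a <- hp$loop_side; b <- if (a == "q") "t" else "q"
    strand_to_loop <- any(cm[[paste0(a, "_kind")]] == "strand" &
                            cm[[paste0(b, "_kind")]] == "loop")
    other_loops <- cm[[paste0(a, "_kind")]] == "loop" &
      cm[[paste0(b, "_kind")]] == "strand" &
      cm[[paste0(a, "_idx")]] != hp$loop_idx
    if (strand_to_loop && any(other_loops)) {
      return(c(list(category = "LARGE_REARRANGEMENT"), flags))
    }
    if (!strand_to_loop) {
      return(c(list(category = "LOOP_TO_HAIRPIN"), flags))
    }
    return(c(list(category = "OTHER"), flags))
  }
  if (nrow(sp) >= 2) {
    c_off <- (corr$q_n - sp$q_strand) - (corr$t_n - sp$t_strand)
    n_off <- sp$t_strand - sp$q_strand
    if (all(c_off == 0)) {
      flags$ambiguous_anchor <- all(n_off == 0)
      return(c(list(category = "CTERM_ANCHORED"), flags))
    }
    if (all(n_off == 0)) {
      return(c(list(category = "NTERM_ANCHORED"), flags))
    }
    if (length(unique(n_off)) == 1 && n_off[1] != 0) {
      return(c(list(category = "INTERNAL_OFFSET"), flags))
    }
  }
  c(list(category = "OTHER"), flags)
}

#' Classify every alignment record against its annotations
#'
#' Maps each record onto the two annotations, classifies self-alignments
#' into repeat classes and cross-alignments into anchoring/transition
#' categories, and flags alternate alignments (two records for the same
#' protein pair overlapping in the same query region -- a hallmark of
#' duplication). Loop-to-hairpin alignments with an alternate alignment in
#' the same region become `LOOP_TO_HAIRPIN_ALT`.
#'
#' @param records Alignment-record tibble (not deduplicated).
#' @param annotations Named list of strand annotations, one per protein.
#' @param theta Optional fixed support threshold for [map_to_strands()].
#' @return Tibble with one row per classifiable record: identifiers,
#'   E-value, probability, strand counts, `category`, `repeat_class`,
#'   flags, and the underlying correspondence as a list-column `corr`.
#' @export
#' @examples
#' sc <- generate_alignment_scenario(scenario_spec("hairpin_shift_self",
#'   n_q = 10, n_t = 10))
#' anns <- list(syn10q = sc$query$annotation)
#' classify_all(sc$record, anns)$repeat_class
classify_all <- function(records, annotations, theta = NULL) {
  if (nrow(records) == 0) {
    return(tibble(query_id = character(), target_id = character(),
                  evalue = numeric(), probability = numeric(),
                  q_n = integer(), t_n = integer(), category = character(),
                  repeat_class = character(),
                  includes_last_strands = logical(),
                  covers_all_query_strands = logical(),
                  has_redirection = logical(),
                  has_alternate_alignment = logical(),
                  ambiguous_anchor = logical(), insufficient = logical(),
                  corr = list()))
  }
  rows <- map(seq_len(nrow(records)), function(i) {
    qid <- records$query_id[i]; tid <- records$target_id[i]
    if (!qid %in% names(annotations) || !tid %in% names(annotations)) {
      warn(sprintf("record %s-%s skipped: protein not annotated", qid, tid))
      return(NULL)
    }
    aq <- annotations[[qid]]; at <- annotations[[tid]]
    corr <- map_to_strands(records[i, ], aq, at, theta = theta)
    if (records$is_self[i]) {
      rc <- classify_internal(corr)
      cat_ <- "OTHER"
      flags <- list(includes_last_strands = FALSE,
                    covers_all_query_strands = FALSE,
                    has_redirection = FALSE, ambiguous_anchor = FALSE,
                    insufficient = FALSE)
    } else {
      res <- classify_cross(corr, aq, at)
      cat_ <- res$category
      rc <- "NONE"
      flags <- res[c("includes_last_strands", "covers_all_query_strands",
                     "has_redirection", "ambiguous_anchor", "insufficient")]
    }
    tibble(
      query_id = qid, target_id = tid,
      evalue = records$evalue[i], probability = records$probability[i],
      q_n = corr$q_n, t_n = corr$t_n,
      category = cat_, repeat_class = rc,
      includes_last_strands = flags$includes_last_strands,
      covers_all_query_strands = flags$covers_all_query_strands,
      has_redirection = flags$has_redirection,
      has_alternate_alignment = FALSE,
      ambiguous_anchor = flags$ambiguous_anchor,
      insufficient = flags$insufficient,
      corr = list(corr)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(out)
  # alternate alignments: same unordered pair, overlapping query region
  pair_key <- paste(pmin(out$query_id, out$target_id),
                    pmax(out$query_id, out$target_id))
  q_range <- map(out$corr, function(cc) {
    qs <- c(cc$strand_pairs$q_strand,
            cc$cross_matches$q_idx[cc$cross_matches$q_kind == "strand"])
    if (length(qs) == 0) c(NA_integer_, NA_integer_) else range(qs)
  })
  for (key in unique(pair_key[duplicated(pair_key)])) {
    ii <- which(pair_key == key)
    for (a in ii) for (b in ii) {
      if (a >= b) next
      ra <- q_range[[a]]; rb <- q_range[[b]]
      if (anyNA(ra) || anyNA(rb)) next
      if (ra[1] <= rb[2] && rb[1] <= ra[2]) {
        out$has_alternate_alignment[c(a, b)] <- TRUE
      }
    }
  }
  out$category[out$category == "LOOP_TO_HAIRPIN" &
                 out$has_alternate_alignment] <- "LOOP_TO_HAIRPIN_ALT"
  out
}

#' Per-category frequency summary of a classification table
#'
#' @param classified Output of [classify_all()].
#' @return Tibble of counts and shares by strand-count bucket and category.
#' @export
classification_summary <- function(classified) {
  if (nrow(classified) == 0) {
    return(tibble(q_n = integer(), t_n = integer(), category = character(),
                  repeat_class = character(), n = integer(),
                  share = numeric()))
  }
  classified |>
    mutate(lo = pmin(.data$q_n, .data$t_n), hi = pmax(.data$q_n, .data$t_n)) |>
    count(q_n = .data$lo, t_n = .data$hi, category = .data$category,
          repeat_class = .data$repeat_class) |>
    group_by(.data$q_n, .data$t_n) |>
    mutate(share = .data$n / sum(.data$n)) |>
    ungroup()
}

#' Recovered scenario kind from a classification row
#'
#' Maps a classification result back onto the planted-scenario taxonomy,
#' used to score planted-truth recovery of the generator battery.
#'
#' @param category,repeat_class,is_self,has_redirection Classification
#'   fields.
#' @return Scenario-kind string.
#' @export
recovered_kind <- function(category, repeat_class, is_self,
                           has_redirection) {
  if (is_self) {
    return(switch(repeat_class,
                  HAIRPIN_SHIFT = "hairpin_shift_self",
                  DOUBLE_HAIRPIN_SHIFT = "double_hairpin_shift_self",
                  "other_self"))
  }
  switch(category,
         CTERM_ANCHORED = "cterm_duplication",
         NTERM_ANCHORED = "nterm_duplication",
         INTERNAL_OFFSET = "internal_offset",
         LOOP_TO_HAIRPIN = "loop_to_hairpin",
         LOOP_TO_HAIRPIN_ALT = "loop_to_hairpin",
         LARGE_REARRANGEMENT = "large_rearrangement",
         OTHER = if (has_redirection) "topology_flip" else "other")
}
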