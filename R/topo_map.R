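# Projecting alignment residue pairs onto strand annotations: strand-level
# correspondences, loop<->strand cross-matches, and direction comparison.

# Region membership of residue positions: strand i, or loop i (= the loop
# after strand i; the N-terminal tail is loop 0, the C-terminal tail loop n).
.region_of <- function(pos, annotation) {
  n <- nrow(annotation)
  kind <- rep("loop", length(pos))
  idx <- rep(0L, length(pos))
  for (i in seq_len(n)) {
    inside <- pos >= annotation$start[i] & pos <= annotation$end[i]
    kind[inside] <- "strand"
    idx[inside] <- i
    after <- pos > annotation$end[i]
    idx[after & kind == "loop"] <- i
  }
  tibble(kind = kind, idx = idx)
}

.region_length <- function(annotation, kind, idx) {
  n <- nrow(annotation)
  if (kind == "strand") {
    return(annotation$end[idx] - annotation$start[idx] + 1L)
  }
  if (idx >= 1 && idx < n) {
    return(annotation$start[idx + 1L] - annotation$end[idx] - 1L)
  }
  NA_integer_  # chain tails: length unknown from the annotation alone
}

#' Map an alignment onto two strand annotations
#'
#' Projects the aligned residue pairs of one record onto the query and
#' target strand annotations. A strand pair `(i, j)` is emitted when at
#' least theta aligned residue pairs fall inside both strands, with
#' `theta = max(3, ceiling(0.5 * shorter region length))` (configurable).
#' Among candidate strand pairs the colinear chain (strictly increasing in
#' both strand indices) with maximal total support is selected by dynamic
#' programming; the remainder, together with loop-to-strand matches
#' passing the same theta rule, accumulates into `cross_matches`.
#'
#' @param record One-row alignment-record tibble (or a list with `pairs`).
#' @param annot_q,annot_t Strand annotations of query and target.
#' @param theta Optional fixed support threshold overriding the rule.
#' @return A `strand_correspondence`: list with `strand_pairs` (tibble
#'   `q_strand`, `t_strand`, `support`), `cross_matches` (tibble `q_kind`,
#'   `q_idx`, `t_kind`, `t_idx`, `support`), `q_n`, `t_n`, `theta`.
#' @export
#' @examples
#' sc <- generate_alignment_scenario(scenario_spec("cterm_duplication"))
#' map_to_strands(sc$record, sc$query$annotation, sc$target$annotation)
map_to_strands <- function(record, annot_q, annot_t, theta = NULL) {
  pairs <- if (is.data.frame(record)) record$pairs[[1]] else record$pairs
  if (is.null(pairs) || nrow(pairs) == 0) abort("empty aligned_pairs")
  qr <- .region_of(pairs$q_pos, annot_q)
  tr <- .region_of(pairs$t_pos, annot_t)
  tab <- tibble(q_kind = qr$kind, q_idx = qr$idx,
                t_kind = tr$kind, t_idx = tr$idx) |>
    count(.data$q_kind, .data$q_idx, .data$t_kind, .data$t_idx,
          name = "support")
  theta_for <- function(qk, qi, tk, ti) {
    if (!is.null(theta)) return(theta)
    lens <- c(.region_length(annot_q, qk, qi), .region_length(annot_t, tk, ti))
    if (all(is.na(lens))) return(3L)
    max(3L, ceiling(0.5 * min(lens, na.rm = TRUE)))
  }
  tab$theta <- pmap(tab, function(q_kind, q_idx, t_kind, t_idx, support) {
    theta_for(q_kind, q_idx, t_kind, t_idx)
  }) |> unlist()
  tab <- filter(tab, .data$support >= .data$theta,
                !(.data$q_kind == "loop" & .data$t_kind == "loop"))
  ss <- filter(tab, .data$q_kind == "strand", .data$t_kind == "strand") |>
    arrange(.data$q_idx, .data$t_idx)
  chain_rows <- integer(0)
  if (nrow(ss) > 0) {
    m <- nrow(ss)
    f <- ss$support
    prev <- rep(0L, m)
    for (i in seq_len(m)) {
      best <- 0
      for (j in seq_len(i - 1)) {
        if (ss$q_idx[j] < ss$q_idx[i] && ss$t_idx[j] < ss$t_idx[i] &&
            f[j] > best) {
          best <- f[j]
          prev[i] <- j
        }
      }
      f[i] <- ss$support[i] + best
    }
    i <- which.max(f)
    while (i > 0) {
      chain_rows <- c(i, chain_rows)
      i <- prev[i]
    }
  }
  strand_pairs <- ss[chain_rows, c("q_idx", "t_idx", "support")]
  names(strand_pairs) <- c("q_strand", "t_strand", "support")
  spill <- ss[setdiff(seq_len(nrow(ss)), chain_rows), , drop = FALSE]
  cross <- bind_rows(
    filter(tab, .data$q_kind == "loop" | .data$t_kind == "loop"),
    spill
  ) |> select("q_kind", "q_idx", "t_kind", "t_idx", "support") |>
    arrange(.data$q_idx, .data$t_idx)
  structure(
    list(strand_pairs = strand_pairs, cross_matches = cross,
         q_n = nrow(annot_q), t_n = nrow(annot_t),
         theta = theta %||% "max(3, ceil(0.5 * shorter region))"),
    class = "strand_correspondence"
  )
}

#' @export
print.strand_correspondence <- function(x, ...) {
  cat(sprintf("Strand correspondence (%d vs %d strands): %d strand pairs, %d cross-matches\n",
              x$q_n, x$t_n, nrow(x$strand_pairs), nrow(x$cross_matches)))
  if (nrow(x$strand_pairs)) print(x$strand_pairs)
  invisible(x)
}

#' Tidy a strand correspondence
#'
#' @param x A `strand_correspondence`.
#' @param what `"strand_pairs"` or `"cross_matches"`.
#' @param ... Unused.
#' @method tidy strand_correspondence
#' @export
tidy.strand_correspondence <- function(x, what = c("strand_pairs",
                                                   "cross_matches"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' Transpose a correspondence (swap query and target)
#' @param corr A `strand_correspondence`.
#' @export
transpose_correspondence <- function(corr) {
  sp <- corr$strand_pairs
  cm <- corr$cross_matches
  structure(
    list(
      strand_pairs = tibble(q_strand = sp$t_strand, t_strand = sp$q_strand,
                            support = sp$support) |>
        arrange(.data$q_strand, .data$t_strand),
      cross_matches = tibble(q_kind = cm$t_kind, q_idx = cm$t_idx,
                             t_kind = cm$q_kind, t_idx = cm$q_idx,
                             support = cm$support) |>
        arrange(.data$q_idx, .data$t_idx),
      q_n = corr$t_n, t_n = corr$q_n, theta = corr$theta
    ),
    class = "strand_correspondence"
  )
}

#' Detect redirected (flipped) strand pairs
#'
#' Flags aligned strand pairs whose membrane directions disagree --
#' an extracellular-pointing strand aligned to a periplasmic-pointing one.
#'
#' @param corr A `strand_correspondence`.
#' @param directions_q,directions_t Integer direction vectors (+1/-1) per
#'   strand, or annotations with a `direction` column.
#' @return Tibble of flipped pairs (`q_strand`, `t_strand`).
#' @export
detect_redirection <- function(corr, directions_q, directions_t) {
  dq <- if (is.data.frame(directions_q)) directions_q$direction else directions_q
  dt <- if (is.data.frame(directions_t)) directions_t$direction else directions_t
  sp <- corr$strand_pairs
  flipped <- sp[dq[sp$q_strand] != dt[sp$t_strand], c("q_strand", "t_strand")]
  flipped
}
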