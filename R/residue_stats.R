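# Residue-level statistics: the polar/nonpolar partition, polarity
# alternation, Kyte-Doolittle hydropathy, residue volumes, and the
# loop<->strand transition analysis with control sets.

.NONPOLAR <- c("A", "F", "I", "L", "M", "P", "V", "W", "Y")
.POLAR <- c("C", "D", "E", "G", "H", "K", "N", "Q", "R", "S", "T")

#' The nonpolar / polar residue partition
#'
#' A, F, I, L, M, P, V, W and Y are nonpolar; C, D, E, G, H, K, N, Q, R, S
#' and T are polar.
#' @return Character vector of one-letter codes.
#' @export
nonpolar_residues <- function() .NONPOLAR

#' @rdname nonpolar_residues
#' @export
polar_residues <- function() .POLAR

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy indices (Kyte & Doolittle 1982); positive is
#' hydrophobic, negative hydrophilic.
#' @return Named numeric vector over the 20 amino acids.
#' @export
kd_hydropathy <- function() c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Amino-acid residue volumes
#'
#' Mean residue volumes in cubic Angstrom (Zamyatnin 1972).
#' @return Named numeric vector over the 20 amino acids.
#' @export
residue_volume <- function() c(
  A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, Q = 143.8,
  E = 138.4, G = 60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
  M = 162.9, F = 189.9, P = 112.7, S = 89.0, T = 116.1, W = 227.8,
  Y = 193.6, V = 140.0
)

#' Polarity class of a residue
#'
#' @param aa One-letter code(s).
#' @return `"polar"` or `"nonpolar"` per element.
#' @export
#' @examples
#' polarity_class(c("A", "R"))
polarity_class <- function(aa) {
  aa <- toupper(aa)
  unknown <- !(aa %in% c(.NONPOLAR, .POLAR))
  if (any(unknown)) {
    abort(sprintf("unknown residue letter(s): %s",
                  paste(unique(aa[unknown]), collapse = ", ")))
  }
  ifelse(aa %in% .NONPOLAR, "nonpolar", "polar")
}

.split_region <- function(region) {
  if (length(region) == 1 && nchar(region[1]) > 1) {
    strsplit(region, "")[[1]]
  } else region
}

#' Polarity alternation fraction of a region
#'
#' The number of residues whose polarity class differs from the previous
#' residue's, divided by the total number of positions in the region.
#' The first residue never counts as a step; positions aligned to a gap
#' (given as `-` in the region or via `gap_mask`) and positions
#' immediately after a gap are excluded from the step count but remain in
#' the denominator.
#'
#' A perfectly alternating gap-free region of length L scores (L-1)/L.
#' With `denominator = "steps"` the count of eligible steps is used
#' instead (an alternative reading of the alternation formula).
#'
#' @param region Character vector of one-letter codes, or a single string;
#'   `-` marks a gap-aligned position.
#' @param gap_mask Optional logical vector marking gap-aligned positions.
#' @param denominator `"region"` (default) or `"steps"`.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' alternation_fraction("LTLT")   # 0.75
#' alternation_fraction("LLLL")   # 0
#' alternation_fraction("LT-LT")  # 0.4
alternation_fraction <- function(region, gap_mask = NULL,
                                 denominator = c("region", "steps")) {
  denominator <- match.arg(denominator)
  region <- .split_region(region)
  L <- length(region)
  if (L < 2) abort("region must have length >= 2")
  gap <- region == "-"
  if (!is.null(gap_mask)) {
    stopifnot(length(gap_mask) == L)
    gap <- gap | gap_mask
  }
  pol <- rep(NA_character_, L)
  pol[!gap] <- polarity_class(region[!gap])
  steps <- 0L
  flips <- 0L
  for (i in seq(2, L)) {
    if (gap[i] || gap[i - 1]) next  # gap positions and first after a gap
    steps <- steps + 1L
    if (pol[i] != pol[i - 1]) flips <- flips + 1L
  }
  den <- if (denominator == "region") L else steps
  if (den == 0) return(0)
  flips / den
}

#' Mean hydropathy of a region
#'
#' Arithmetic mean of the Kyte-Doolittle indices over the region's
#' residues; gap-aligned positions are excluded.
#'
#' @inheritParams alternation_fraction
#' @param scale Named hydropathy vector; defaults to [kd_hydropathy()].
#' @return Mean hydropathy (dimensionless).
#' @export
#' @examples
#' mean_hydropathy("AILV")  # 3.575
mean_hydropathy <- function(region, gap_mask = NULL, scale = kd_hydropathy()) {
  region <- .split_region(region)
  gap <- region == "-"
  if (!is.null(gap_mask)) {
    stopifnot(length(gap_mask) == length(region))
    gap <- gap | gap_mask
  }
  aa <- toupper(region[!gap])
  if (length(aa) == 0) abort("all positions are gap-aligned")
  vals <- scale[aa]
  if (anyNA(vals)) {
    abort(sprintf("unknown residue letter(s): %s",
                  paste(unique(aa[is.na(vals)]), collapse = ", ")))
  }
  mean(vals)
}

#' Mean residue volume over a barrel's strands
#'
#' @param annotation Strand annotation tibble.
#' @param sequence Full-length sequence (string).
#' @return Mean residue volume in cubic Angstrom.
#' @export
mean_strand_residue_volume <- function(annotation, sequence) {
  aa <- strsplit(sequence, "")[[1]]
  idx <- unlist(map2(annotation$start, annotation$end, seq))
  vols <- residue_volume()[toupper(aa[idx])]
  if (anyNA(vols)) {
    warn("unknown residue(s) in strands skipped")
    vols <- vols[!is.na(vols)]
  }
  mean(vols)
}

# percent identity between two region strings over their common length
.region_identity <- function(a, b) {
  a <- .split_region(a); b <- .split_region(b)
  L <- min(length(a), length(b))
  if (L == 0) return(0)
  100 * sum(a[seq_len(L)] == b[seq_len(L)]) / L
}

# collect one aligned region's residues + gap mask from an alignment's
# residue pairs: all residues of the structural region within the aligned
# span, gap-masked where no partner column exists
.aligned_region <- function(pairs, side, lo, hi, sequence) {
  pos_col <- if (side == "q") "q_pos" else "t_pos"
  inside <- pairs[[pos_col]] >= lo & pairs[[pos_col]] <= hi
  matched <- pairs[[pos_col]][inside]
  if (length(matched) == 0) return(NULL)
  span <- seq(min(matched), max(matched))
  aa <- strsplit(sequence, "")[[1]][span]
  list(residues = aa, gap_mask = !(span %in% matched))
}

#' Polarity and hydropathy of loop-to-strand transition regions
#'
#' For every loop<->strand cross-match in loop-to-hairpin and
#' large-rearrangement alignments, collects the loop-conformation residues
#' on one side and the strand-conformation residues they align to on the
#' other, then compares their mean polarity alternation and hydropathy
#' against control strands and control extracellular loops (all strands /
#' extracellular loops of the same barrels that take part in no transition
#' alignment). Regions aligned multiply are deduplicated: a repeat of the
#' same structural region is kept only when its aligned span is < 50%
#' identical to an already-kept copy.
#'
#' @param classified Output of [classify_all()]; rows with categories
#'   `LOOP_TO_HAIRPIN`, `LOOP_TO_HAIRPIN_ALT`, `LARGE_REARRANGEMENT`
#'   are used.
#' @param records The alignment records that were classified (for the
#'   residue pairs).
#' @param annotations Named list of strand annotations.
#' @param sequences Named character vector of full sequences.
#' @param denominator Passed to [alternation_fraction()].
#' @return Tibble with one row per group (`loop_conformation`,
#'   `strand_conformation`, `control_strands`, `control_loops`):
#'   `n_regions`, `mean_alternation`, `mean_hydropathy`.
#' @export
transition_region_stats <- function(classified, records, annotations,
                                    sequences,
                                    denominator = c("region", "steps")) {
  denominator <- match.arg(denominator)
  trans <- filter(classified, .data$category %in%
                    c("LOOP_TO_HAIRPIN", "LOOP_TO_HAIRPIN_ALT",
                      "LARGE_REARRANGEMENT"))
  if (nrow(trans) == 0) {
    warn("no loop-to-strand transition alignments")
    return(tibble(group = character(), n_regions = integer(),
                  mean_alternation = numeric(), mean_hydropathy = numeric()))
  }
  loop_regions <- list()
  strand_regions <- list()
  used_regions <- character(0)  # protein/kind/idx involved in transitions
  for (i in seq_len(nrow(trans))) {
    qid <- trans$query_id[i]; tid <- trans$target_id[i]
    rec <- records[records$query_id == qid & records$target_id == tid &
                     abs(records$evalue - trans$evalue[i]) <
                       1e-12 * trans$evalue[i], ]
    if (nrow(rec) == 0) next
    pairs <- rec$pairs[[1]]
    cm <- trans$corr[[i]]$cross_matches
    cm <- filter(cm, (.data$q_kind == "loop") != (.data$t_kind == "loop"))
    for (j in seq_len(nrow(cm))) {
      loop_on_q <- cm$q_kind[j] == "loop"
      lside <- if (loop_on_q) "q" else "t"
      sside <- if (loop_on_q) "t" else "q"
      lid <- if (loop_on_q) qid else tid
      sid <- if (loop_on_q) tid else qid
      lann <- annotations[[lid]]; sann <- annotations[[sid]]
      lidx <- if (loop_on_q) cm$q_idx[j] else cm$t_idx[j]
      sidx <- if (loop_on_q) cm$t_idx[j] else cm$q_idx[j]
      if (lidx < 1 || lidx >= nrow(lann)) next
      lr <- .aligned_region(pairs, lside, lann$end[lidx] + 1L,
                            lann$start[lidx + 1L] - 1L, sequences[[lid]])
      sr <- .aligned_region(pairs, sside, sann$start[sidx],
                            sann$end[sidx], sequences[[sid]])
      if (is.null(lr) || is.null(sr)) next
      used_regions <- c(used_regions,
                        paste(lid, "loop", lidx), paste(sid, "strand", sidx))
      loop_regions[[length(loop_regions) + 1]] <-
        c(list(key = paste(lid, "loop", lidx)), lr)
      strand_regions[[length(strand_regions) + 1]] <-
        c(list(key = paste(sid, "strand", sidx)), sr)
    }
  }
  dedup <- function(regions) {
    kept <- list()
    for (r in regions) {
      dup <- FALSE
      for (k in kept) {
        if (k$key == r$key &&
            .region_identity(k$residues, r$residues) >= 50) {
          dup <- TRUE
          break
        }
      }
      if (!dup) kept[[length(kept) + 1]] <- r
    }
    kept
  }
  loop_regions <- dedup(loop_regions)
  strand_regions <- dedup(strand_regions)
  # control sets: strands and extracellular loops of the same barrels not
  # part of any transition alignment
  prots <- unique(c(trans$query_id, trans$target_id))
  ctrl_strands <- list()
  ctrl_loops <- list()
  for (pid in prots) {
    ann <- annotations[[pid]]
    aa <- strsplit(sequences[[pid]], "")[[1]]
    for (s in seq_len(nrow(ann))) {
      if (paste(pid, "strand", s) %in% used_regions) next
      ctrl_strands[[length(ctrl_strands) + 1]] <-
        list(residues = aa[seq(ann$start[s], ann$end[s])],
             gap_mask = NULL)
    }
    for (l in seq_len(nrow(ann) - 1)) {
      extracellular <- ann$direction[l] == 1L  # loop after an outgoing strand
      if (!extracellular) next
      if (paste(pid, "loop", l) %in% used_regions) next
      rng <- seq(ann$end[l] + 1L, ann$start[l + 1L] - 1L)
      if (length(rng) < 2) next
      ctrl_loops[[length(ctrl_loops) + 1]] <-
        list(residues = aa[rng], gap_mask = NULL)
    }
  }
  group_stats <- function(regions, group) {
    if (length(regions) == 0) {
      return(tibble(group = group, n_regions = 0L,
                    mean_alternation = NA_real_, mean_hydropathy = NA_real_))
    }
    alt <- map_dbl(regions, function(r) {
      if (length(r$residues) < 2) return(NA_real_)
      alternation_fraction(r$residues, r$gap_mask, denominator = denominator)
    })
    hyd <- map_dbl(regions, function(r) {
      mean_hydropathy(r$residues, r$gap_mask)
    })
    tibble(group = group, n_regions = length(regions),
           mean_alternation = mean(alt, na.rm = TRUE),
           mean_hydropathy = mean(hyd, na.rm = TRUE))
  }
  bind_rows(
    group_stats(loop_regions, "loop_conformation"),
    group_stats(strand_regions, "strand_conformation"),
    group_stats(ctrl_strands, "control_strands"),
    group_stats(ctrl_loops, "control_loops")
  )
}
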