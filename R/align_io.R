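# Reading, filtering and normalizing pairwise profile-profile alignment
# records (deposited source-data tables, HH-suite-style output, synthetic
# records).

# column-name synonyms accepted by the reader, lower-cased
.COL_SYNONYMS <- list(
  query_id = c("query_id", "query", "qid", "id1", "protein1", "pdb1", "q"),
  target_id = c("target_id", "target", "tid", "id2", "protein2", "pdb2",
                "t", "hit"),
  evalue = c("evalue", "e_value", "e.value", "e-value", "eval", "e"),
  probability = c("probability", "prob", "p", "hh_prob"),
  q_start = c("q_start", "qstart", "query_start"),
  q_end = c("q_end", "qend", "query_end"),
  t_start = c("t_start", "tstart", "target_start"),
  t_end = c("t_end", "tend", "target_end"),
  q_aln = c("q_aln", "qaln", "query_aln", "qseq"),
  t_aln = c("t_aln", "taln", "target_aln", "tseq")
)

#' Derive aligned residue-position pairs from two gapped strings
#'
#' Walks a pair of equal-length gapped alignment strings (`-` for gaps) and
#' returns matched 1-based positions, offset by the alignment start
#' coordinates.
#'
#' @param q_aln,t_aln Gapped alignment strings.
#' @param q_start,t_start 1-based position of the first aligned residue.
#' @return Tibble with `q_pos`, `t_pos`, strictly increasing in both.
#' @export
pairs_from_gapped <- function(q_aln, t_aln, q_start = 1L, t_start = 1L) {
  qc <- strsplit(q_aln, "")[[1]]
  tc <- strsplit(t_aln, "")[[1]]
  if (length(qc) != length(tc)) abort("gapped strings differ in length")
  qg <- qc != "-"
  tg <- tc != "-"
  q_pos <- cumsum(qg) + q_start - 1L
  t_pos <- cumsum(tg) + t_start - 1L
  both <- qg & tg
  tibble(q_pos = as.integer(q_pos[both]), t_pos = as.integer(t_pos[both]))
}

.gapped_from_pairs <- function(pairs) {
  # inverse of pairs_from_gapped for contiguous-as-possible output
  q <- pairs$q_pos; t <- pairs$t_pos
  qa <- character(0); ta <- character(0)
  for (i in seq_along(q)) {
    if (i > 1) {
      dq <- q[i] - q[i - 1] - 1
      dt <- t[i] - t[i - 1] - 1
      if (dq > 0) { qa <- c(qa, rep("x", dq)); ta <- c(ta, rep("-", dq)) }
      if (dt > 0) { qa <- c(qa, rep("-", dt)); ta <- c(ta, rep("x", dt)) }
    }
    qa <- c(qa, "x"); ta <- c(ta, "x")
  }
  list(q_aln = paste(qa, collapse = ""), t_aln = paste(ta, collapse = ""))
}

#' Build an alignment-record tibble
#'
#' One row per pairwise alignment: identifiers, E-value, probability
#' (percent), self flag, and the aligned residue pairs as a list-column of
#' tibbles with `q_pos`/`t_pos` strictly increasing in both coordinates
#' (local, gapped, colinear alignments).
#'
#' @param query_id,target_id Protein identifiers.
#' @param evalue Positive E-values.
#' @param probability Percent in \[0, 100\] (`NA` allowed).
#' @param pairs List of tibbles with `q_pos`, `t_pos`.
#' @return Alignment-record tibble.
#' @export
alignment_records <- function(query_id, target_id, evalue,
                              probability = NA_real_, pairs = list()) {
  n <- length(query_id)
  if (length(pairs) == 0) pairs <- rep(list(tibble(q_pos = integer(),
                                                   t_pos = integer())), n)
  stopifnot(all(evalue > 0, na.rm = TRUE))
  tibble(
    query_id = query_id, target_id = target_id,
    evalue = evalue,
    probability = rep_len(probability, n),
    is_self = query_id == target_id,
    n_aligned = map_int(pairs, nrow),
    pairs = pairs
  )
}

#' Read a pairwise alignment table
#'
#' Reads whitespace- or tab-delimited alignment tables whose first row is a
#' header. Common column-name synonyms (query/target/E-value/probability,
#' start coordinates, gapped alignment strings) are mapped onto the
#' canonical schema; unknown columns are preserved. Aligned residue pairs
#' are derived from the gapped strings when present, otherwise from the
#' start/end coordinates as an ungapped block.
#'
#' @param text Path to the table, or its lines as a character vector.
#' @param dialect `"auto"` (whitespace-delimited) or `"tsv"`.
#' @return Alignment-record tibble (see [alignment_records()]); extra
#'   columns are carried through.
#' @export
read_alignment_table <- function(text, dialect = c("auto", "tsv")) {
  dialect <- match.arg(dialect)
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text)
  } else {
    text <- unlist(strsplit(text, "\n"))
  }
  text <- text[nzchar(trimws(text))]
  if (length(text) == 0) abort("empty alignment table")
  sep <- if (dialect == "tsv") "\t" else ""
  df <- utils::read.table(text = text, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  nm <- tolower(names(df))
  canon <- rep(NA_character_, ncol(df))
  for (target in names(.COL_SYNONYMS)) {
    hit <- which(nm %in% .COL_SYNONYMS[[target]])
    if (length(hit) > 0) canon[hit[1]] <- target
  }
  names(df)[!is.na(canon)] <- canon[!is.na(canon)]
  for (must in c("query_id", "target_id", "evalue")) {
    if (!must %in% names(df)) {
      abort(sprintf("missing mandatory column: %s", must))
    }
  }
  if (nrow(df) == 0) {
    warn("header-only alignment table: no records")
    return(alignment_records(character(0), character(0), numeric(0)))
  }
  ev <- suppressWarnings(as.numeric(df$evalue))
  bad <- is.na(ev) | ev <= 0
  if (any(bad)) {
    warn(sprintf("%d row(s) with malformed E-value rejected", sum(bad)))
    df <- df[!bad, , drop = FALSE]
    ev <- ev[!bad]
  }
  pairs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    if (all(c("q_aln", "t_aln") %in% names(df))) {
      qs <- if ("q_start" %in% names(df)) as.integer(df$q_start[i]) else 1L
      ts <- if ("t_start" %in% names(df)) as.integer(df$t_start[i]) else 1L
      pairs[[i]] <- pairs_from_gapped(df$q_aln[i], df$t_aln[i], qs, ts)
    } else if (all(c("q_start", "q_end", "t_start", "t_end") %in% names(df))) {
      L <- min(df$q_end[i] - df$q_start[i], df$t_end[i] - df$t_start[i]) + 1L
      pairs[[i]] <- tibble(
        q_pos = seq.int(df$q_start[i], length.out = L),
        t_pos = seq.int(df$t_start[i], length.out = L)
      )
    } else {
      pairs[[i]] <- tibble(q_pos = integer(), t_pos = integer())
    }
  }
  rec <- alignment_records(
    as.character(df$query_id), as.character(df$target_id), ev,
    if ("probability" %in% names(df)) as.numeric(df$probability) else NA_real_,
    pairs
  )
  extra <- setdiff(names(df), c(names(rec), "q_aln", "t_aln"))
  for (e in extra) rec[[e]] <- df[[e]]
  rec
}

#' Write alignment records in the canonical TSV dialect
#'
#' Canonical columns: `query_id`, `target_id`, `evalue`, `probability`,
#' `q_start`, `q_end`, `t_start`, `t_end`, `q_aln`, `t_aln` (gapped strings
#' with `-` for gaps, `x` for aligned positions).
#'
#' @param records Alignment-record tibble.
#' @param path Output file.
#' @export
write_alignment_table <- function(records, path) {
  rows <- map(seq_len(nrow(records)), function(i) {
    p <- records$pairs[[i]]
    g <- if (nrow(p) > 0) .gapped_from_pairs(p) else
      list(q_aln = "", t_aln = "")
    tibble(
      query_id = records$query_id[i], target_id = records$target_id[i],
      evalue = records$evalue[i], probability = records$probability[i],
      q_start = if (nrow(p)) min(p$q_pos) else NA_integer_,
      q_end = if (nrow(p)) max(p$q_pos) else NA_integer_,
      t_start = if (nrow(p)) min(p$t_pos) else NA_integer_,
      t_end = if (nrow(p)) max(p$t_pos) else NA_integer_,
      q_aln = g$q_aln, t_aln = g$t_aln
    )
  })
  utils::write.table(bind_rows(rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter alignment records
#'
#' Keeps records with `evalue <= max_evalue` (inclusive), at least
#' `min_aligned` aligned residue pairs (the 20-residue cutoff spans nearly
#' all hairpins), and -- when `min_probability` is set -- probability
#' strictly greater than `min_probability` (the internal-repeat filter
#' uses `> 75`).
#'
#' @param records Alignment-record tibble.
#' @param max_evalue Inclusive E-value threshold.
#' @param min_aligned Minimum number of aligned residue pairs.
#' @param min_probability Optional strict lower probability bound (percent).
#' @return Filtered tibble.
#' @export
filter_records <- function(records, max_evalue, min_aligned = 20,
                           min_probability = NULL) {
  if (max_evalue <= 0 || min_aligned <= 0) abort("thresholds must be positive")
  keep <- records$evalue <= max_evalue & records$n_aligned >= min_aligned
  if (!is.null(min_probability)) {
    keep <- keep & !is.na(records$probability) &
      records$probability > min_probability
  }
  records[keep, , drop = FALSE]
}

#' Keep the best record per unordered protein pair
#'
#' For each unordered pair (A, B) retains the record with the lowest
#' E-value; ties are broken by the longer alignment, then lexicographically
#' by identifiers. Network edges use these deduplicated minima; strand
#' classification consumes all records.
#'
#' @param records Alignment-record tibble.
#' @return Deduplicated tibble, one row per unordered pair.
#' @export
dedup_min_evalue <- function(records) {
  if (nrow(records) == 0) return(records)
  a <- pmin(records$query_id, records$target_id)
  b <- pmax(records$query_id, records$target_id)
  records |>
    mutate(.pair = paste(a, b, sep = "\r")) |>
    group_by(.data$.pair) |>
    arrange(.data$evalue, desc(.data$n_aligned), .data$query_id,
            .data$target_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".pair")
}
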