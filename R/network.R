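# The barrel similarity network: E-value-thresholded edges, connected
# components, same-vs-different strand-number probabilities, log-space mean
# E-values, strand-position conservation, and HMM-membership overlap.

#' Build the barrel similarity network
#'
#' Nodes are dataset proteins (including isolates); one edge joins each
#' unordered pair whose minimal E-value record passes the threshold
#' (inclusive). Records should already be length-filtered and
#' deduplicated; [dedup_min_evalue()] is applied defensively.
#'
#' @param records Alignment-record tibble.
#' @param threshold Inclusive E-value threshold.
#' @param nodes Tibble with `protein_id` and optionally `n_strands`; when
#'   `NULL`, nodes are the proteins appearing in `records`.
#' @return A `barrel_network` wrapping an igraph graph.
#' @export
build_network <- function(records, threshold = 1e-3, nodes = NULL) {
  records <- dedup_min_evalue(records[!records$is_self, , drop = FALSE])
  edges <- filter(records, .data$evalue <= threshold)
  if (is.null(nodes)) {
    nodes <- tibble(protein_id = sort(unique(c(records$query_id,
                                               records$target_id))))
  }
  if (!"n_strands" %in% names(nodes)) nodes$n_strands <- NA_integer_
  g <- igraph::graph_from_data_frame(
    d = tibble(from = edges$query_id, to = edges$target_id,
               evalue = edges$evalue),
    directed = FALSE,
    vertices = as.data.frame(nodes)
  )
  structure(list(graph = g, nodes = as_tibble(nodes),
                 threshold = threshold),
            class = "barrel_network")
}

#' @export
print.barrel_network <- function(x, ...) {
  cat(sprintf("Barrel network at E <= %g: %d nodes, %d edges, %d components\n",
              x$threshold, igraph::vcount(x$graph), igraph::ecount(x$graph),
              igraph::components(x$graph)$no))
  invisible(x)
}

#' Tidy a barrel network into its edge list
#'
#' @param x A `barrel_network`.
#' @param ... Unused.
#' @return Tibble with `from`, `to`, `evalue`.
#' @method tidy barrel_network
#' @export
tidy.barrel_network <- function(x, ...) {
  e <- igraph::as_data_frame(x$graph, what = "edges")
  as_tibble(e)
}

#' One-row network summary
#'
#' @param x A `barrel_network`.
#' @param ... Unused.
#' @method glance barrel_network
#' @export
glance.barrel_network <- function(x, ...) {
  comp <- igraph::components(x$graph)
  tibble(
    threshold = x$threshold,
    n_nodes = as.integer(igraph::vcount(x$graph)),
    n_edges = as.integer(igraph::ecount(x$graph)),
    n_components = comp$no,
    largest_component = max(comp$csize),
    largest_fraction = max(comp$csize) / igraph::vcount(x$graph)
  )
}

#' Members of the largest connected component
#'
#' The largest group at E <= 1e-3 operationally defines the prototypical
#' barrels. Size ties are broken by the component containing the
#' lexicographically smallest member.
#'
#' @param network A `barrel_network`.
#' @return Character vector of protein IDs.
#' @export
largest_component <- function(network) {
  comp <- igraph::components(network$graph)
  sizes <- comp$csize
  top <- which(sizes == max(sizes))
  nm <- igraph::V(network$graph)$name
  if (length(top) > 1) {
    firsts <- map_chr(top, function(k) min(nm[comp$membership == k]))
    top <- top[order(firsts)][1]
  }
  sort(nm[comp$membership == top])
}

#' Same- versus different-strand-number alignment probability
#'
#' For each strand-count bucket (n_i, n_j), the number of network edges
#' divided by the number of possible protein pairs: `choose(k, 2)` within
#' a size class, `k1 * k2` across classes. Buckets with fewer than two
#' same-n proteins are omitted.
#'
#' @param network A `barrel_network` whose nodes carry `n_strands`.
#' @return Tibble with `n_i`, `n_j`, `edges`, `possible`, `probability`,
#'   `same_n`.
#' @export
same_vs_diff_probability <- function(network) {
  nodes <- network$nodes
  if (anyNA(nodes$n_strands)) abort("all nodes need a known strand count")
  ed <- tidy(network)
  nmap <- setNames(nodes$n_strands, nodes$protein_id)
  counts <- count(nodes, .data$n_strands)
  combos <- tidyr::expand_grid(n_i = sort(unique(nodes$n_strands)),
                               n_j = sort(unique(nodes$n_strands))) |>
    filter(.data$n_i <= .data$n_j)
  res <- pmap(combos, function(n_i, n_j) {
    k1 <- counts$n[counts$n_strands == n_i]
    k2 <- counts$n[counts$n_strands == n_j]
    possible <- if (n_i == n_j) choose(k1, 2) else k1 * k2
    if (possible == 0) return(NULL)
    e1 <- nmap[ed$from]; e2 <- nmap[ed$to]
    hits <- sum((e1 == n_i & e2 == n_j) | (e1 == n_j & e2 == n_i))
    tibble(n_i = n_i, n_j = n_j, edges = hits, possible = possible,
           probability = hits / possible, same_n = n_i == n_j)
  })
  bind_rows(res)
}

#' Log-space mean E-value
#'
#' The representative E-value of a set: `10 ^ mean(log10(E))` (the
#' geometric mean), the convention used for averaging alignment E-values.
#'
#' @param evalues Positive numeric vector.
#' @return Scalar E-value.
#' @export
#' @examples
#' mean_log_evalue(c(1e-3, 1e-7))  # 1e-5
mean_log_evalue <- function(evalues) {
  if (length(evalues) == 0) abort("empty E-value set")
  if (any(is.na(evalues)) || any(evalues <= 0)) {
    abort("E-values must be positive")
  }
  10^mean(log10(evalues))
}

#' Strand-position conservation profile
#'
#' Counts, over all classified alignments (both sides), how often each
#' strand position of each barrel size participates in an aligned strand
#' pair. C-terminal anchoring shows up as counts concentrated in the
#' C-terminal half.
#'
#' @param classified Output of [classify_all()] (uses the `corr` and
#'   strand-count columns).
#' @return Tibble with `n_strands`, `position`, `count` (all positions of
#'   all observed sizes, zero-filled).
#' @export
conservation_profile <- function(classified) {
  if (nrow(classified) == 0) {
    return(tibble(n_strands = integer(), position = integer(),
                  count = integer()))
  }
  hits <- bind_rows(map(seq_len(nrow(classified)), function(i) {
    cc <- classified$corr[[i]]
    sp <- cc$strand_pairs
    bind_rows(
      tibble(n_strands = cc$q_n, position = sp$q_strand),
      tibble(n_strands = cc$t_n, position = sp$t_strand)
    )
  }))
  grid <- bind_rows(map(sort(unique(hits$n_strands)), function(nn) {
    tibble(n_strands = nn, position = seq_len(nn))
  }))
  cnt <- count(hits, .data$n_strands, .data$position, name = "count")
  left_join(grid, cnt, by = c("n_strands", "position")) |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count))
}

#' Pairwise HMM-membership overlap
#'
#' Percent overlap between homolog sets:
#' `100 * |A intersect B| / min(|A|, |B|)` by default (the denominator is
#' configurable since "percent overlap" admits several conventions).
#'
#' @param membership Tibble from [generate_membership()] or with columns
#'   `profile_id`, `n_strands`, `members`.
#' @param denominator `"min"`, `"union"`, or `"mean"`.
#' @return Tibble of profile pairs with `overlap_pct` and `same_n`.
#' @export
membership_overlap <- function(membership,
                               denominator = c("min", "union", "mean")) {
  denominator <- match.arg(denominator)
  if (nrow(membership) < 2) abort("need at least two profiles")
  idx <- utils::combn(nrow(membership), 2)
  res <- map(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    A <- membership$members[[i]]; B <- membership$members[[j]]
    if (length(A) == 0 || length(B) == 0) {
      warn("empty homolog set; overlap defined as 0")
      ov <- 0
    } else {
      inter <- length(intersect(A, B))
      den <- switch(denominator,
                    min = min(length(A), length(B)),
                    union = length(union(A, B)),
                    mean = mean(c(length(A), length(B))))
      ov <- 100 * inter / den
    }
    tibble(profile_a = membership$profile_id[i],
           profile_b = membership$profile_id[j],
           n_a = membership$n_strands[i], n_b = membership$n_strands[j],
           overlap_pct = ov,
           same_n = membership$n_strands[i] == membership$n_strands[j])
  })
  bind_rows(res)
}

#' Summary of cross-strand-number membership overlap
#'
#' Average and maximum percent overlap over profile pairs with different
#' strand counts.
#'
#' @param overlaps Tibble from [membership_overlap()].
#' @return One-row tibble with `mean_overlap_pct`, `max_overlap_pct`,
#'   `n_pairs`.
#' @export
overlap_summary <- function(overlaps) {
  x <- filter(overlaps, !.data$same_n)
  tibble(
    mean_overlap_pct = if (nrow(x)) mean(x$overlap_pct) else NA_real_,
    max_overlap_pct = if (nrow(x)) max(x$overlap_pct) else NA_real_,
    n_pairs = nrow(x)
  )
}

#' Write a network as GraphML
#'
#' @param network A `barrel_network`.
#' @param path Output file.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' Write a network edge list as TSV
#'
#' @param network A `barrel_network`.
#' @param path Output file.
#' @export
write_edge_tsv <- function(network, path) {
  utils::write.table(tidy(network), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
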