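# End-to-end orchestration: annotate a structure set, classify an
# alignment table against it, build the network series, and emit report
# tables. All stages are deterministic given the config seed.

#' Assemble a pipeline run configuration
#'
#' @param structures Directory of PDB files, or a named character vector
#'   of paths (names = protein IDs), or `NULL`.
#' @param alignment_table Path to an alignment table, or an
#'   alignment-record tibble, or `NULL`.
#' @param membership Membership tibble (see [generate_membership()]) or
#'   `NULL`.
#' @param output_dir Directory for report files.
#' @param thresholds E-value thresholds for the network series.
#' @param min_aligned Length filter (residue pairs) applied to all records.
#' @param internal_min_probability Strict probability bound for internal
#'   repeats (percent).
#' @param theta Optional fixed strand-support threshold.
#' @param alternation_denominator,overlap_denominator Decision toggles for
#'   [alternation_fraction()] and [membership_overlap()].
#' @param seed Integer seed recorded in the summary.
#' @return A `run_config` list.
#' @export
run_config <- function(structures = NULL, alignment_table = NULL,
                       membership = NULL, output_dir = tempfile("barrelrun"),
                       thresholds = c(1e-3, 1e-5, 1e-7, 1e-12),
                       min_aligned = 20, internal_min_probability = 75,
                       theta = NULL, alternation_denominator = "region",
                       overlap_denominator = "min", seed = 1L) {
  if (any(thresholds <= 0) || min_aligned <= 0) {
    abort("thresholds must be positive")
  }
  structure(
    list(structures = structures, alignment_table = alignment_table,
         membership = membership, output_dir = output_dir,
         thresholds = sort(thresholds, decreasing = TRUE),
         min_aligned = min_aligned,
         internal_min_probability = internal_min_probability,
         theta = theta,
         alternation_denominator = alternation_denominator,
         overlap_denominator = overlap_denominator,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

.structure_paths <- function(structures) {
  if (is.null(structures)) return(character(0))
  if (length(structures) == 1 && dir.exists(structures)) {
    paths <- list.files(structures, pattern = "\\.pdb$", full.names = TRUE)
    names(paths) <- sub("\\.pdb$", "", basename(paths))
    return(paths)
  }
  if (is.null(names(structures))) {
    names(structures) <- sub("\\.pdb$", "", basename(structures))
  }
  structures
}

#' Annotate every structure of a run
#'
#' Annotates each readable structure; failures are reported and skipped so
#' one bad file does not abort the run.
#'
#' @param config A [run_config()].
#' @return List with `annotations` (named list), `sequences` (named
#'   character), `failures` (character vector of IDs).
#' @export
run_annotate <- function(config) {
  paths <- .structure_paths(config$structures)
  if (length(paths) == 0) abort("no structures configured")
  annotations <- list()
  sequences <- character(0)
  failures <- character(0)
  for (id in names(paths)) {
    res <- tryCatch({
      residues <- read_backbone(paths[[id]])
      ann <- annotate_structure(residues)
      list(ann = ann, seq = paste(residues$aa, collapse = ""))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("annotation failed for %s: %s", id,
                      conditionMessage(res)))
      failures <- c(failures, id)
    } else {
      annotations[[id]] <- res$ann
      sequences[[id]] <- res$seq
    }
  }
  if (length(annotations) == 0) abort("zero successful annotations")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_annotation_tsv(annotations,
                         file.path(config$output_dir, "annotations.tsv"))
  }
  list(annotations = annotations, sequences = sequences, failures = failures)
}

#' Run the full analysis
#'
#' Executes every available stage: structure annotation, record filtering,
#' internal-repeat and cross-alignment classification, the per-threshold
#' network series with component statistics, strand-conservation profiles,
#' transition-region residue statistics, and membership overlap. Stages
#' whose inputs are absent are skipped with a notice; every summary number
#' is traceable to a written table.
#'
#' @param config A [run_config()].
#' @return A `barrel_run` list with the stage outputs and a `summary`
#'   list; report files are written under `config$output_dir`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  notes <- character(0)

  ann <- NULL
  if (!is.null(config$structures)) {
    ann <- run_annotate(config)
  } else {
    notes <- c(notes, "no structures: structure-dependent stages skipped")
  }

  records <- NULL
  if (!is.null(config$alignment_table)) {
    records <- if (is.data.frame(config$alignment_table)) {
      config$alignment_table
    } else {
      read_alignment_table(config$alignment_table)
    }
    records <- filter_records(records, max_evalue = max(config$thresholds),
                              min_aligned = config$min_aligned)
  } else {
    notes <- c(notes, "no alignment table: alignment stages skipped")
  }
  if (is.null(records)) {
    abort("run_full needs an alignment table (stage input missing: align_io)")
  }

  classified <- NULL
  repeats <- NULL
  conservation <- NULL
  res_stats <- NULL
  if (!is.null(ann)) {
    classified <- classify_all(records[!records$is_self, , drop = FALSE],
                               ann$annotations, theta = config$theta)
    int_rec <- filter_records(records[records$is_self, , drop = FALSE],
                              max_evalue = 1e-3,
                              min_aligned = config$min_aligned,
                              min_probability = config$internal_min_probability)
    int_cls <- classify_all(int_rec, ann$annotations, theta = config$theta)
    repeats <- if (nrow(int_cls)) {
      select(int_cls, "query_id", "evalue", "probability", "repeat_class")
    } else int_cls
    conservation <- conservation_profile(classified)
    res_stats <- tryCatch(
      transition_region_stats(classified, records, ann$annotations,
                              ann$sequences,
                              denominator = config$alternation_denominator),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        NULL
      })
    if (nrow(classified)) {
      utils::write.table(
        select(classified, -"corr"),
        file.path(out_dir, "classification.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
    if (!is.null(repeats) && nrow(repeats)) {
      utils::write.table(repeats, file.path(out_dir, "repeats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(conservation) && nrow(conservation)) {
      utils::write.table(conservation,
                         file.path(out_dir, "conservation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res_stats) && nrow(res_stats)) {
      utils::write.table(res_stats,
                         file.path(out_dir, "residue_stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  nodes <- NULL
  if (!is.null(ann)) {
    nodes <- tibble(protein_id = names(ann$annotations),
                    n_strands = map_int(ann$annotations, nrow))
  }
  networks <- list()
  net_summary <- list()
  for (thr in config$thresholds) {
    nw <- build_network(records, threshold = thr, nodes = nodes)
    networks[[sprintf("%g", thr)]] <- nw
    net_summary[[length(net_summary) + 1]] <- glance(nw)
    write_edge_tsv(nw, file.path(out_dir, sprintf("network_%g.tsv", thr)))
  }
  net_summary <- bind_rows(net_summary)

  overlap <- NULL
  if (!is.null(config$membership)) {
    overlap <- membership_overlap(config$membership,
                                  denominator = config$overlap_denominator)
  }

  summary <- list(
    seed = config$seed,
    thresholds = config$thresholds,
    min_aligned = config$min_aligned,
    internal_min_probability = config$internal_min_probability,
    alternation_denominator = config$alternation_denominator,
    overlap_denominator = config$overlap_denominator,
    n_records = nrow(records),
    n_records_dedup = nrow(dedup_min_evalue(records)),
    networks = net_summary,
    n_classified = if (is.null(classified)) NA_integer_ else nrow(classified),
    category_counts = if (is.null(classified) || nrow(classified) == 0) NULL
      else as.list(table(classified$category)),
    repeat_counts = if (is.null(repeats) || nrow(repeats) == 0) NULL
      else as.list(table(repeats$repeat_class)),
    membership_overlap = if (is.null(overlap)) NULL
      else as.list(overlap_summary(overlap)),
    notes = notes
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(
    list(annotations = if (is.null(ann)) NULL else ann$annotations,
         sequences = if (is.null(ann)) NULL else ann$sequences,
         records = records, classified = classified, repeats = repeats,
         conservation = conservation, residue_stats = res_stats,
         networks = networks, membership_overlap = overlap,
         summary = summary, output_dir = out_dir),
    class = "barrel_run"
  )
}

#' @export
print.barrel_run <- function(x, ...) {
  cat("Barrel analysis run\n")
  cat(sprintf("  records: %d (%d after dedup)\n", x$summary$n_records,
              x$summary$n_records_dedup))
  print(x$summary$networks)
  invisible(x)
}
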