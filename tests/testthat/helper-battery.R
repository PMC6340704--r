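# Shared fixtures: planted-scenario batteries built in code.

scenario_kinds <- c(
  "cterm_duplication", "nterm_duplication", "internal_offset",
  "hairpin_shift_self", "double_hairpin_shift_self",
  "loop_to_hairpin", "large_rearrangement", "topology_flip"
)

scenario_sizes <- function(kind) {
  if (kind %in% c("loop_to_hairpin", "large_rearrangement")) {
    c(16L, 18L)
  } else if (grepl("self", kind)) {
    c(10L, 10L)
  } else {
    c(8L, 16L)
  }
}

make_scenario <- function(kind, seed = 1L, noise = 0) {
  nn <- scenario_sizes(kind)
  generate_alignment_scenario(
    scenario_spec(kind, n_q = nn[1], n_t = nn[2], noise = noise, seed = seed)
  )
}

# classify one scenario against its ground-truth annotations and return the
# recovered scenario kind
recover_scenario <- function(sc) {
  anns <- list()
  anns[[sc$record$query_id]] <- sc$query$annotation
  anns[[sc$record$target_id]] <- sc$target$annotation
  cl <- classify_all(sc$record, anns)
  recovered_kind(cl$category, cl$repeat_class, sc$record$is_self,
                 cl$has_redirection)
}

# small alignment-record table for IO / network tests
toy_records <- function() {
  alignment_records(
    query_id = c("barA", "barA", "barB", "barC"),
    target_id = c("barB", "barB", "barA", "barA"),
    evalue = c(1e-4, 1e-6, 1e-2, 1e-8),
    probability = c(90, 95, 60, 99),
    pairs = list(
      tibble::tibble(q_pos = 1:25, t_pos = 1:25),
      tibble::tibble(q_pos = 1:30, t_pos = 11:40),
      tibble::tibble(q_pos = 1:22, t_pos = 1:22),
      tibble::tibble(q_pos = 1:40, t_pos = 1:40)
    )
  )
}
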