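# Strand assignment from backbone coordinates: phi/psi labelling, backbone
# hydrogen bonding, strand assembly, and membrane direction per strand.

#' Construct a strand annotation tibble
#'
#' An annotation is a tibble with one row per strand: 1-based inclusive
#' residue interval `start`..`end` and membrane `direction` (+1 when the
#' N-terminal end of the strand is periplasmic, i.e. the strand points
#' extracellular; -1 otherwise).
#' @noRd
new_strand_annotation <- function(tbl, flags = character(0)) {
  stopifnot(all(c("strand", "start", "end") %in% names(tbl)))
  structure(
    as_tibble(tbl),
    n_strands = nrow(tbl),
    flags = flags,
    class = c("strand_annotation", class(as_tibble(tbl)))
  )
}

#' Number of strands in an annotation
#' @param annotation A strand annotation tibble.
#' @export
n_strands <- function(annotation) nrow(annotation)

#' Read backbone coordinates from PDB text or file
#'
#' Parses `ATOM` records of the first polypeptide chain. Alternate
#' locations are resolved by keeping the highest-occupancy conformer.
#' Residues missing a CA atom are dropped with a warning; residues are
#' re-indexed sequentially from 1.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @return Tibble with `seq_index`, `aa`, and backbone atom coordinates
#'   (`n_x` .. `o_z`).
#' @export
read_backbone <- function(pdb) {
  path <- pdb
  if (length(pdb) > 1 || grepl("\n", pdb[1]) || !file.exists(pdb[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(pdb, "\n")), path)
    on.exit(unlink(path))
  }
  pdbobj <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdbobj$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) abort("no polymer residues")
  chain1 <- at$chain[1]
  at <- at[at$chain %in% chain1, , drop = FALSE]
  at <- at[at$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  # altloc: keep highest occupancy per residue/atom
  key <- paste(at$resno, at$insert, at$elety)
  at <- at[order(key, -at$o), , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety)), , drop = FALSE]
  rid <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  at$rid <- factor(rid, levels = unique(rid[order(at$resno)]))
  aa1 <- setNames(names(.AA_321), .AA_321)
  rows <- lapply(split(at, at$rid), function(d) {
    if (!"CA" %in% d$elety) return(NULL)
    get3 <- function(nm) {
      i <- match(nm, d$elety)
      if (is.na(i)) c(NA_real_, NA_real_, NA_real_) else
        c(d$x[i], d$y[i], d$z[i])
    }
    aa <- aa1[d$resid[1]]
    if (is.na(aa)) aa <- "X"
    c(list(aa = unname(aa)),
      setNames(as.list(get3("N")), c("n_x", "n_y", "n_z")),
      setNames(as.list(get3("CA")), c("ca_x", "ca_y", "ca_z")),
      setNames(as.list(get3("C")), c("c_x", "c_y", "c_z")),
      setNames(as.list(get3("O")), c("o_x", "o_y", "o_z")))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warn(sprintf("%d residue(s) without CA dropped", dropped))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) abort("no polymer residues")
  out <- bind_rows(lapply(rows, as_tibble))
  out$seq_index <- seq_len(nrow(out))
  select(out, "seq_index", dplyr::everything())
}

.res_matrix <- function(residues, atom) {
  as.matrix(residues[, paste0(atom, c("_x", "_y", "_z"))])
}

#' Backbone phi/psi dihedrals
#'
#' Standard IUPAC torsions: `phi` is undefined at the first residue and
#' `psi` at the last; collinear atom quadruples yield `NA`.
#'
#' @param residues Residue tibble from [read_backbone()] or a generated
#'   barrel.
#' @return Tibble with `seq_index`, `phi`, `psi` in degrees, \[-180, 180).
#' @export
compute_dihedrals <- function(residues) {
  n <- nrow(residues)
  if (n < 3) abort("need at least 3 residues for dihedrals")
  N <- .res_matrix(residues, "n")
  CA <- .res_matrix(residues, "ca")
  C <- .res_matrix(residues, "c")
  phi <- c(NA_real_,
           torsion_angle(C[-n, , drop = FALSE], N[-1, , drop = FALSE],
                         CA[-1, , drop = FALSE], C[-1, , drop = FALSE]))
  psi <- c(torsion_angle(N[-n, , drop = FALSE], CA[-n, , drop = FALSE],
                         C[-n, , drop = FALSE], N[-1, , drop = FALSE]),
           NA_real_)
  tibble(seq_index = residues$seq_index, phi = phi, psi = psi)
}

#' Label residues from phi/psi windows
#'
#' Residues are labelled `strand_like` for phi in \[-180, -45\] with psi in
#' \[45, 180) or \[-180, -170), `helix_like` for phi in \[-90, -35\] with psi
#' in \[-70, -15\], and `other` elsewhere (including undefined terminal
#' dihedrals). Windows are permissive Ramachandran regions and can be
#' overridden.
#'
#' @param geometry Tibble from [compute_dihedrals()].
#' @param beta_phi,beta_psi1,beta_psi2,alpha_phi,alpha_psi Window bounds
#'   `c(lo, hi)`; psi windows are half-open on the right.
#' @return Tibble with `seq_index`, `label`.
#' @export
label_residues <- function(geometry,
                           beta_phi = c(-180, -45),
                           beta_psi1 = c(45, 180),
                           beta_psi2 = c(-180, -170),
                           alpha_phi = c(-90, -35),
                           alpha_psi = c(-70, -15)) {
  phi <- geometry$phi
  psi <- geometry$psi
  in_win <- function(x, w, closed = TRUE) {
    !is.na(x) & x >= w[1] & (if (closed) x <= w[2] else x < w[2])
  }
  is_beta <- in_win(phi, beta_phi) &
    (in_win(psi, beta_psi1, closed = FALSE) |
       in_win(psi, beta_psi2, closed = FALSE))
  is_alpha <- in_win(phi, alpha_phi) & in_win(psi, alpha_psi)
  label <- ifelse(is_beta, "strand_like",
                  ifelse(is_alpha, "helix_like", "other"))
  tibble(seq_index = geometry$seq_index, label = label)
}

#' Detect backbone N-to-O hydrogen-bond contacts
#'
#' Reports residue index pairs `(i, j)` with donor `N(i)` within `cutoff`
#' of acceptor `O(j)` and `|i - j| >= min_sep`. A distance-only criterion
#' (no angle term) is used.
#'
#' @param residues Residue tibble.
#' @param cutoff Distance cutoff in Angstrom.
#' @param min_sep Minimum sequence separation.
#' @return Tibble with `donor`, `acceptor`.
#' @export
detect_hbonds <- function(residues, cutoff = 3.5, min_sep = 3) {
  N <- .res_matrix(residues, "n")
  O <- .res_matrix(residues, "o")
  ok_n <- !is.na(N[, 1]); ok_o <- !is.na(O[, 1])
  idx <- residues$seq_index
  d2 <- outer(rowSums(N^2), rowSums(O^2), "+") - 2 * N %*% t(O)
  d2[!ok_n, ] <- Inf
  d2[, !ok_o] <- Inf
  sep <- abs(outer(idx, idx, "-"))
  hit <- which(d2 <= cutoff^2 & sep >= min_sep, arr.ind = TRUE)
  tibble(donor = idx[hit[, 1]], acceptor = idx[hit[, 2]])
}

# maximal runs of strand-like labels, tolerating short interior
# interruptions (beta bulges)
.strand_runs <- function(label, min_len = 3, bulge_tol = 2) {
  is_s <- label == "strand_like"
  r <- rle(is_s)
  # absorb interior non-strand gaps of length <= bulge_tol
  v <- r$values
  if (length(v) > 2) {
    for (i in seq(2, length(v) - 1)) {
      if (!r$values[i] && r$lengths[i] <= bulge_tol &&
          r$values[i - 1] && r$values[i + 1]) {
        v[i] <- TRUE
      }
    }
  }
  merged <- rle(inverse.rle(list(lengths = r$lengths, values = v)))
  ends <- cumsum(merged$lengths)
  starts <- ends - merged$lengths + 1
  keep <- merged$values & merged$lengths >= min_len
  tibble(start = starts[keep], end = ends[keep])
}

#' Assemble strands from labels and hydrogen bonds
#'
#' Keeps maximal runs of strand-like residues (length >= `min_len`, with up
#' to `bulge_tol` consecutive interior non-strand residues tolerated) that
#' are connected to at least one other kept run by >= `min_bonds` backbone
#' hydrogen bonds; isolated runs are discarded. Strands are numbered from
#' the N terminus.
#'
#' @param labels Tibble from [label_residues()].
#' @param hbonds Tibble from [detect_hbonds()].
#' @param min_len Minimum strand length.
#' @param bulge_tol Interior interruption tolerance.
#' @param min_bonds Hydrogen bonds required between two runs.
#' @return A strand annotation tibble (no directions yet).
#' @export
assemble_strands <- function(labels, hbonds, min_len = 3, bulge_tol = 2,
                             min_bonds = 2) {
  runs <- .strand_runs(labels$label, min_len = min_len, bulge_tol = bulge_tol)
  if (nrow(runs) == 0) abort("no barrel: no strand-like runs")
  repeat {
    m <- nrow(runs)
    run_of <- rep(NA_integer_, max(labels$seq_index))
    for (i in seq_len(m)) run_of[seq(runs$start[i], runs$end[i])] <- i
    rd <- run_of[hbonds$donor]
    ra <- run_of[hbonds$acceptor]
    ok <- !is.na(rd) & !is.na(ra) & rd != ra
    if (!any(ok)) {
      runs <- runs[0, ]
      break
    }
    cnt <- table(paste(pmin(rd[ok], ra[ok]), pmax(rd[ok], ra[ok])))
    partnered <- rep(FALSE, m)
    for (nmp in names(cnt[cnt >= min_bonds])) {
      ij <- as.integer(strsplit(nmp, " ")[[1]])
      partnered[ij] <- TRUE
    }
    if (all(partnered)) break
    runs <- runs[partnered, , drop = FALSE]
    if (nrow(runs) == 0) break
  }
  if (nrow(runs) == 0) abort("no barrel: no hydrogen-bonded strand runs")
  runs <- arrange(runs, .data$start)
  new_strand_annotation(
    tibble(strand = seq_len(nrow(runs)), start = runs$start,
           end = runs$end, direction = NA_integer_)
  )
}

#' Assign membrane direction per strand
#'
#' The barrel axis is the principal axis of the strand CA coordinates,
#' signed so that the chain termini lie on the negative-z (periplasmic)
#' side (OMBB termini stay on the insertion face). A strand's direction is
#' the sign of `z(last CA) - z(first CA)` along that axis.
#'
#' @param annotation Strand annotation tibble.
#' @param residues Residue tibble.
#' @return The annotation with the `direction` column filled (+1/-1).
#' @export
strand_directions <- function(annotation, residues) {
  if (nrow(annotation) < 4) abort("need >= 4 strands for a barrel axis")
  in_strand <- unlist(map2(annotation$start, annotation$end, seq))
  CA <- .res_matrix(residues, "ca")
  sel <- residues$seq_index %in% in_strand
  X <- CA[sel, , drop = FALSE]
  cen <- colMeans(X)
  # barrel axis: strand end-to-end vectors lie on a cone around the axis
  # with alternating chain sense, so the sign-invariant second-moment
  # matrix of the (normalized) strand vectors has the axis as principal
  # eigenvector; this stays correct for wide, squat barrels where a plain
  # PCA of the CA cloud picks a radial direction.
  vs <- map(seq_len(nrow(annotation)), function(i) {
    v <- CA[match(annotation$end[i], residues$seq_index), ] -
      CA[match(annotation$start[i], residues$seq_index), ]
    v / sqrt(sum(v^2))
  })
  M <- Reduce(`+`, lapply(vs, function(v) tcrossprod(v)))
  ei <- eigen(M, symmetric = TRUE)
  if (ei$values[1] - ei$values[2] < 1e-6 * ei$values[1]) {
    abort("degenerate barrel axis")
  }
  axis <- ei$vectors[, 1]
  proj <- c(sweep(CA, 2, cen) %*% axis)
  if (diff(range(proj[sel])) < 2) abort("degenerate barrel axis")
  term <- mean(proj[c(1, nrow(CA))])
  if (term > 0) {
    axis <- -axis
    proj <- -proj
  }
  d <- map_int(seq_len(nrow(annotation)), function(i) {
    z1 <- proj[match(annotation$start[i], residues$seq_index)]
    z2 <- proj[match(annotation$end[i], residues$seq_index)]
    as.integer(sign(z2 - z1))
  })
  annotation$direction <- d
  annotation
}

#' Annotate a structure end to end
#'
#' Convenience wrapper: dihedrals, labelling, hydrogen bonds, strand
#' assembly and directions in one call.
#'
#' @param x PDB path/text or a residue tibble.
#' @param ... Passed to [assemble_strands()].
#' @return Strand annotation tibble with directions.
#' @export
#' @examples
#' b <- generate_barrel(barrel_spec(8))
#' annotate_structure(write_pdb(b))
annotate_structure <- function(x, ...) {
  residues <- if (is.data.frame(x)) x else read_backbone(x)
  labels <- label_residues(compute_dihedrals(residues))
  ann <- assemble_strands(labels, detect_hbonds(residues), ...)
  strand_directions(ann, residues)
}

#' Longest and shortest strand definitions across alternative structures
#'
#' For proteins with several solved structures, combines the per-structure
#' annotations into a longest variant (per-slot union interval) and a
#' shortest variant (per-slot intersection). Annotations that disagree on
#' strand count are flagged and returned unchanged.
#'
#' @param annotations List of strand annotation tibbles for one protein.
#' @return List with `longest`, `shortest`, and `flags` (character).
#' @export
annotation_variants <- function(annotations) {
  if (length(annotations) == 0) abort("need at least one annotation")
  ns <- map_int(annotations, nrow)
  if (length(unique(ns)) > 1) {
    return(list(longest = annotations, shortest = annotations,
                flags = "alternative structure changes strand count"))
  }
  base <- annotations[[1]]
  longest <- base
  shortest <- base
  for (i in seq_len(nrow(base))) {
    ss <- map_int(annotations, ~ .x$start[i])
    ee <- map_int(annotations, ~ .x$end[i])
    longest$start[i] <- min(ss); longest$end[i] <- max(ee)
    shortest$start[i] <- max(ss); shortest$end[i] <- min(ee)
  }
  flags <- character(0)
  if (any(shortest$start > shortest$end)) {
    flags <- "empty intersection for at least one strand"
  }
  list(longest = new_strand_annotation(longest),
       shortest = new_strand_annotation(shortest), flags = flags)
}

#' Write strand annotations as TSV
#'
#' @param annotations Named list of annotation tibbles, or a single one.
#' @param path Output file.
#' @param protein_id Identifier used when a single annotation is given.
#' @export
write_annotation_tsv <- function(annotations, path, protein_id = "protein") {
  if (is.data.frame(annotations)) {
    annotations <- setNames(list(annotations), protein_id)
  }
  tbl <- bind_rows(imap(annotations, function(a, id) {
    tibble(protein_id = id, strand_index = a$strand, start = a$start,
           end = a$end, direction = a$direction)
  }))
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
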