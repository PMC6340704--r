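# Synthetic OMBB generator: idealized barrel coordinates, strand-patterned
# sequences, and alignment scenarios with planted topological ground truth.

# Torsions of the strand backbone template. psi is chosen so the pleat does
# not precess along the strand (near-zero twist), which keeps the pleat
# radial all along a barrel strand; the resulting rise is ~3.30 A/residue.
.TEMPLATE_PHI <- -120
.TEMPLATE_PSI <- 117

#' Run code with a temporary RNG seed
#' @noRd
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify an idealized beta-barrel
#'
#' Collects the lattice parameters of an idealized, antiparallel, up-down
#' transmembrane beta-barrel. The barrel is described by its strand number
#' `n_strands` (even; bacterial OMBBs range from 8 to 26), the shear number
#' `shear` (the register offset accumulated on closing the barrel, which
#' together with the strand number sets the strand tilt and the radius),
#' the rise per residue along a strand and the inter-strand spacing.
#'
#' The default shear `n_strands + 2` is typical of small OMBBs and yields
#' strand tilts near 35-45 degrees and a radius increment of roughly 1.7 A
#' per added hairpin.
#'
#' @param n_strands Even integer >= 8; number of transmembrane strands.
#' @param shear Integer shear number; default `n_strands + 2`.
#' @param rise_per_residue Rise along the strand direction, in Angstrom.
#' @param strand_spacing Perpendicular inter-strand distance, in Angstrom.
#' @param residues_per_strand Residues in each strand (>= 3).
#' @param loop_length_extracellular,loop_length_periplasmic Number of loop
#'   residues on each membrane face (>= 2).
#' @param seed Integer seed; regenerating with the same seed reproduces the
#'   barrel exactly.
#' @return A `barrel_spec` list.
#' @export
#' @examples
#' spec <- barrel_spec(8)
#' barrel_radius(spec)
barrel_spec <- function(n_strands,
                        shear = n_strands + 2,
                        rise_per_residue = 3.3,
                        strand_spacing = 4.4,
                        residues_per_strand = 10,
                        loop_length_extracellular = 5,
                        loop_length_periplasmic = 4,
                        seed = 1L) {
  if (length(n_strands) != 1 || n_strands %% 2 != 0) {
    abort("`n_strands` must be a single even integer")
  }
  if (n_strands < 8) abort("`n_strands` must be >= 8")
  if (residues_per_strand < 3) abort("`residues_per_strand` must be >= 3")
  if (loop_length_extracellular < 2 || loop_length_periplasmic < 2) {
    abort("loop lengths must be >= 2")
  }
  if (rise_per_residue <= 0 || strand_spacing <= 0) {
    abort("lengths must be positive")
  }
  structure(
    list(
      n_strands = as.integer(n_strands),
      shear = as.integer(shear),
      rise_per_residue = rise_per_residue,
      strand_spacing = strand_spacing,
      residues_per_strand = as.integer(residues_per_strand),
      loop_length_extracellular = as.integer(loop_length_extracellular),
      loop_length_periplasmic = as.integer(loop_length_periplasmic),
      seed = as.integer(seed)
    ),
    class = "barrel_spec"
  )
}

#' Ideal barrel radius from strand number and shear
#'
#' Closed-form radius of the idealized barrel cylinder,
#' `R = sqrt((n b)^2 + (S a)^2) / (2 pi)`, with `n` strands spaced `b`
#' apart and shear `S` at rise `a`. Adding one hairpin (two strands) under
#' the default shear rule increases `R` by about 1.7 A.
#'
#' @param n_strands Strand count, or a `barrel_spec`.
#' @param shear,rise_per_residue,strand_spacing Lattice parameters; ignored
#'   when a `barrel_spec` is given.
#' @return Radius in Angstrom.
#' @export
barrel_radius <- function(n_strands, shear = n_strands + 2,
                          rise_per_residue = 3.3, strand_spacing = 4.4) {
  if (inherits(n_strands, "barrel_spec")) {
    s <- n_strands
    n_strands <- s$n_strands
    shear <- s$shear
    rise_per_residue <- s$rise_per_residue
    strand_spacing <- s$strand_spacing
  }
  sqrt((n_strands * strand_spacing)^2 + (shear * rise_per_residue)^2) / (2 * pi)
}

# Per-residue backbone atom offsets of the ideal strand template, expressed
# in the (axis, pleat, binormal) frame anchored at the axial grid points.
.strand_template <- function(L) {
  ch <- build_chain(L, .TEMPLATE_PHI, .TEMPLATE_PSI)
  CA <- ch$CA
  cen <- colMeans(CA)
  pc <- prcomp(CA)
  u <- pc$rotation[, 1]
  if (sum((CA[L, ] - CA[1, ]) * u) < 0) u <- -u
  dev <- sweep(CA, 2, cen)
  devp <- dev - outer(c(dev %*% u), u)
  alt <- devp * (-1)^(seq_len(L))
  p <- colMeans(alt)
  p <- p - sum(p * u) * u
  p <- p / sqrt(sum(p^2))
  y <- c(u[2] * p[3] - u[3] * p[2],
         u[3] * p[1] - u[1] * p[3],
         u[1] * p[2] - u[2] * p[1])
  rise <- sum((CA[L, ] - CA[1, ]) * u) / (L - 1)
  s_grid <- (seq_len(L) - (L + 1) / 2) * rise
  offs <- lapply(ch, function(A) {
    o <- sweep(A, 2, cen)
    cbind(c(o %*% u) - s_grid, c(o %*% p), c(o %*% y))
  })
  list(offsets = offs, rise = rise, s_grid = s_grid)
}

# Atoms for one strand laid along the helical strand path of the cylinder.
# sgn = +1 for strands running periplasmic -> extracellular.
.strand_atoms <- function(tmpl, R, alpha, theta0, sgn) {
  L <- length(tmpl$s_grid)
  out <- list()
  s <- tmpl$s_grid * sgn
  th <- theta0 + s * sin(alpha) / R
  z <- s * cos(alpha)
  ct <- cos(th); st <- sin(th)
  for (nm in c("N", "CA", "C", "O")) {
    d <- tmpl$offsets[[nm]]
    tx <- sgn * (-st * sin(alpha)); ty <- sgn * (ct * sin(alpha))
    tz <- sgn * cos(alpha)
    # binormal = tangent x radial
    bx <- ty * 0 - tz * st; by <- tz * ct - tx * 0
    bz <- tx * st - ty * ct
    out[[nm]] <- cbind(
      R * ct + d[, 1] * tx + d[, 2] * ct + d[, 3] * bx,
      R * st + d[, 1] * ty + d[, 2] * st + d[, 3] * by,
      z + d[, 1] * tz + d[, 3] * bz
    )
  }
  out
}

# Loop atoms along an arc over the rim from CA anchor p_from to p_to,
# bulging axially away from the membrane (face = +1 extracellular, -1
# periplasmic). Backbone offsets use the strand template mirrored through
# the path plane, which flips the torsion signs so loop residues label
# "other" (positive phi), never strand-like.
.loop_atoms <- function(tmpl, n_res, p_from, p_to, face) {
  tfrac <- seq_len(n_res) / (n_res + 1)
  th_a <- atan2(p_from[2], p_from[1])
  th_b <- atan2(p_to[2], p_to[1])
  dth <- (th_b - th_a) %% (2 * pi)
  r_a <- sqrt(p_from[1]^2 + p_from[2]^2)
  r_b <- sqrt(p_to[1]^2 + p_to[2]^2)
  bulge <- max(2.5, 1.1 * n_res)
  th <- th_a + tfrac * dth
  rr <- r_a + tfrac * (r_b - r_a) + 1.0 * sin(pi * tfrac)
  zz <- p_from[3] + tfrac * (p_to[3] - p_from[3]) + face * bulge * sin(pi * tfrac)
  P <- cbind(rr * cos(th), rr * sin(th), zz)
  ext <- rbind(p_from, P, p_to)
  out <- list(N = matrix(0, n_res, 3), CA = matrix(0, n_res, 3),
              C = matrix(0, n_res, 3), O = matrix(0, n_res, 3))
  for (i in seq_len(n_res)) {
    tv <- ext[i + 2, ] - ext[i, ]
    tv <- tv / sqrt(sum(tv^2))
    rad <- c(ext[i + 1, 1], ext[i + 1, 2], 0)
    rad <- rad - sum(rad * tv) * tv
    rad <- rad / sqrt(sum(rad^2))
    bn <- c(tv[2] * rad[3] - tv[3] * rad[2],
            tv[3] * rad[1] - tv[1] * rad[3],
            tv[1] * rad[2] - tv[2] * rad[1])
    row <- (i - 1) %% nrow(tmpl$offsets$CA) + 1
    for (nm in c("N", "CA", "C", "O")) {
      d <- tmpl$offsets[[nm]][row, ]
      d[1] <- d[1] - tmpl$s_grid[row]  # anchor at the path point
      out[[nm]][i, ] <- ext[i + 1, ] + d[1] * tv + d[2] * rad - d[3] * bn
    }
  }
  out
}

.NONPOLAR_BASE <- "L"
.POLAR_BASE <- "T"

# Strand sequence letters alternate nonpolar/polar starting nonpolar;
# seeded substitutions stay within the polarity class, so the alternation
# pattern is exact by construction.
.strand_sequence <- function(L, subst_rate = 0.3) {
  base <- rep(c(.NONPOLAR_BASE, .POLAR_BASE), length.out = L)
  swap <- stats::runif(L) < subst_rate
  base[swap & base == .NONPOLAR_BASE] <-
    sample(nonpolar_residues(), sum(swap & base == .NONPOLAR_BASE), replace = TRUE)
  swap_p <- swap & base == .POLAR_BASE
  base[swap_p] <- sample(polar_residues(), sum(swap_p), replace = TRUE)
  base
}

.loop_sequence <- function(L) {
  sample(polar_residues(), L, replace = TRUE)
}

#' Generate an idealized beta-barrel with known strand topology
#'
#' Builds backbone coordinates (N, CA, C, O) for an antiparallel up-down
#' barrel whose CA atoms lie on a cylinder of radius
#' `barrel_radius(spec)`, with alternating strand directions and both chain
#' termini on the periplasmic face. Strands carry alternating
#' nonpolar/polar sequence letters (lipid-facing positions nonpolar), loops
#' are all-polar. The backbone uses an ideal beta template so that
#' dihedral-based labelling and backbone hydrogen-bond detection recover
#' the planted topology.
#'
#' @param spec A [barrel_spec()].
#' @return A `synthetic_barrel`: list with `residues` (tibble of backbone
#'   coordinates), `sequence` (character scalar), `annotation` (the
#'   ground-truth [strand_annotation] tibble), and `spec`.
#' @export
#' @examples
#' b <- generate_barrel(barrel_spec(8, seed = 42))
#' b$annotation
generate_barrel <- function(spec) {
  if (!inherits(spec, "barrel_spec")) spec <- do.call(barrel_spec, as.list(spec))
  n <- spec$n_strands
  Ls <- spec$residues_per_strand
  with_local_seed(spec$seed, {
    tmpl <- .strand_template(Ls)
    R <- barrel_radius(spec)
    alpha <- atan2(spec$shear * spec$rise_per_residue,
                   n * spec$strand_spacing)
    atoms <- list()
    aa <- character()
    region <- character()
    strand_rows <- list()
    idx <- 0L
    for (k in seq_len(n)) {
      sgn <- if (k %% 2 == 1) 1 else -1
      st <- .strand_atoms(tmpl, R, alpha, 2 * pi * (k - 1) / n, sgn)
      atoms[[length(atoms) + 1]] <- st
      aa <- c(aa, .strand_sequence(Ls))
      region <- c(region, rep(paste0("strand", k), Ls))
      strand_rows[[k]] <- c(idx + 1L, idx + Ls)
      idx <- idx + Ls
      if (k < n) {
        face <- if (k %% 2 == 1) 1 else -1
        n_loop <- if (face == 1) spec$loop_length_extracellular else
          spec$loop_length_periplasmic
        nxt <- .strand_atoms(tmpl, R, alpha, 2 * pi * k / n, -sgn)
        lp <- .loop_atoms(tmpl, n_loop, st$CA[Ls, ], nxt$CA[1, ], face)
        atoms[[length(atoms) + 1]] <- lp
        aa <- c(aa, .loop_sequence(n_loop))
        region <- c(region, rep(paste0("loop", k), n_loop))
        idx <- idx + n_loop
      }
    }
    N <- do.call(rbind, lapply(atoms, `[[`, "N"))
    CA <- do.call(rbind, lapply(atoms, `[[`, "CA"))
    C <- do.call(rbind, lapply(atoms, `[[`, "C"))
    O <- do.call(rbind, lapply(atoms, `[[`, "O"))
    residues <- tibble(
      seq_index = seq_along(aa),
      aa = aa,
      region = region,
      n_x = N[, 1], n_y = N[, 2], n_z = N[, 3],
      ca_x = CA[, 1], ca_y = CA[, 2], ca_z = CA[, 3],
      c_x = C[, 1], c_y = C[, 2], c_z = C[, 3],
      o_x = O[, 1], o_y = O[, 2], o_z = O[, 3]
    )
    ann <- tibble(
      strand = seq_len(n),
      start = map_int(strand_rows, 1),
      end = map_int(strand_rows, 2),
      direction = rep(c(1L, -1L), length.out = n)
    )
    ann <- new_strand_annotation(ann)
    structure(
      list(residues = residues, sequence = paste(aa, collapse = ""),
           annotation = ann, spec = spec),
      class = "synthetic_barrel"
    )
  })
}

#' @export
print.synthetic_barrel <- function(x, ...) {
  cat(sprintf(
    "Idealized %d-stranded barrel: %d residues, shear %d, radius %.2f A\n",
    x$spec$n_strands, nrow(x$residues), x$spec$shear,
    barrel_radius(x$spec)
  ))
  invisible(x)
}

.AA_321 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Write backbone coordinates as PDB text
#'
#' Writes one `ATOM` record per backbone atom (N, CA, C, O), single chain
#' A, residues numbered sequentially.
#'
#' @param x A `synthetic_barrel` or a residue tibble as returned by
#'   [read_backbone()].
#' @param path Output file; if `NULL`, the PDB text is returned as a
#'   character vector of lines.
#' @return `path` invisibly, or the text lines when `path` is `NULL`.
#' @export
write_pdb <- function(x, path = NULL) {
  res <- if (inherits(x, "synthetic_barrel")) x$residues else x
  lines <- character(0)
  serial <- 0L
  atom_cols <- list(N = "n", CA = "ca", C = "c", O = "o")
  for (i in seq_len(nrow(res))) {
    res3 <- .AA_321[[res$aa[i]]]
    for (nm in names(atom_cols)) {
      pre <- atom_cols[[nm]]
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", nm), res3, res$seq_index[i],
        res[[paste0(pre, "_x")]][i], res[[paste0(pre, "_y")]][i],
        res[[paste0(pre, "_z")]][i], 1.0, 0.0, substr(nm, 1, 1)
      ))
    }
  }
  lines <- c(lines, "TER", "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write sequences in FASTA format
#'
#' @param sequences Named character vector of sequences.
#' @param path Output file; if `NULL`, lines are returned.
#' @export
write_fasta <- function(sequences, path = NULL) {
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  lines <- unlist(map2(names(sequences), unname(sequences), function(nm, s) {
    c(paste0(">", nm), gsub("(.{60})", "\\1\n", s))
  }))
  lines <- unlist(strsplit(lines, "\n"))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

.SCENARIO_KINDS <- c(
  "cterm_duplication", "nterm_duplication", "internal_offset",
  "hairpin_shift_self", "double_hairpin_shift_self",
  "loop_to_hairpin", "large_rearrangement", "topology_flip"
)

#' Specify a planted alignment scenario
#'
#' Describes a pairwise alignment between two synthetic barrels (or a
#' self-alignment) whose strand-level correspondence realizes one known
#' topological relationship: C-/N-terminal duplication anchoring, an
#' internal constant-offset alignment, hairpin-shift self-alignments
#' (offsets two and four), a loop-to-hairpin transition, a large
#' rearrangement (loop-to-hairpin plus strand-to-loop plus loop-to-strand,
#' with one redirected strand pair), or a bare topology flip.
#'
#' @param kind One of `r paste0('"', paste(.SCENARIO_KINDS, collapse='", "'), '"')`.
#' @param n_q,n_t Even strand counts of query and target barrel. Self
#'   scenarios require `n_q == n_t`.
#' @param residues_per_strand Strand length used for both barrels.
#' @param noise Fraction of alignment columns dropped at random (0 = exact
#'   planted truth).
#' @param seed Integer seed.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(kind, n_q = 8L, n_t = 16L,
                          residues_per_strand = 10L,
                          noise = 0, seed = 1L) {
  kind <- match.arg(kind, .SCENARIO_KINDS)
  if (n_q %% 2 != 0 || n_t %% 2 != 0) abort("strand counts must be even")
  self_kinds <- c("hairpin_shift_self", "double_hairpin_shift_self")
  if (kind %in% self_kinds && n_q != n_t) {
    abort("self-alignment scenarios require n_q == n_t")
  }
  if (kind %in% c("cterm_duplication", "nterm_duplication") && n_t <= n_q) {
    abort("duplication scenarios require n_t > n_q")
  }
  if (kind %in% c("loop_to_hairpin", "large_rearrangement") &&
      n_t != n_q + 2) {
    abort("loop-to-hairpin scenarios require n_t == n_q + 2")
  }
  if (noise < 0 || noise >= 1) abort("`noise` must be in [0, 1)")
  structure(
    list(kind = kind, n_q = as.integer(n_q), n_t = as.integer(n_t),
         residues_per_strand = as.integer(residues_per_strand),
         noise = noise, seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

# residue range helpers against a ground-truth annotation
.strand_range <- function(bar, i) {
  seq(bar$annotation$start[i], bar$annotation$end[i])
}
.loop_range <- function(bar, i) {
  # loop after strand i
  ann <- bar$annotation
  if (i < 1 || i >= nrow(ann)) abort("no loop after that strand")
  seq(ann$end[i] + 1L, ann$start[i + 1L] - 1L)
}

.zip_pairs <- function(q_pos, t_pos) {
  L <- min(length(q_pos), length(t_pos))
  qs <- q_pos[seq_len(L)]
  ts <- t_pos[seq_len(L)]
  tibble(q_pos = as.integer(qs), t_pos = as.integer(ts))
}

# force alternating polarity into a residue range of a barrel (used to give
# transition loops their strand-like sequence signature)
.plant_alternation <- function(bar, rng) {
  letters <- rep(c(.NONPOLAR_BASE, .POLAR_BASE), length.out = length(rng))
  aa <- strsplit(bar$sequence, "")[[1]]
  aa[rng] <- letters
  bar$sequence <- paste(aa, collapse = "")
  bar$residues$aa[rng] <- letters
  bar
}

#' Generate a pairwise alignment with planted topological ground truth
#'
#' Builds the query and target barrels and an alignment record whose
#' residue pairs, mapped through the two ground-truth annotations, realize
#' exactly the requested scenario kind. E-values are drawn log-uniformly
#' from \[1e-20, 1e-3\] and probabilities uniformly from \[80, 100\].
#'
#' @param spec A [scenario_spec()].
#' @return List with `query`, `target` (synthetic barrels), `record` (a
#'   one-row alignment record tibble, see [alignment_records()]), and
#'   `truth` (list: `kind`, planted `strand_pairs`, flipped pairs).
#' @export
#' @examples
#' sc <- generate_alignment_scenario(scenario_spec("cterm_duplication"))
#' sc$truth$strand_pairs
generate_alignment_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  kind <- spec$kind
  Ls <- spec$residues_per_strand
  with_local_seed(spec$seed, {
    long_ec <- kind %in% c("loop_to_hairpin", "large_rearrangement")
    q_spec <- barrel_spec(
      spec$n_q, residues_per_strand = Ls,
      loop_length_extracellular = if (long_ec) 2L * Ls else 5L,
      loop_length_periplasmic = 4L,
      seed = sample.int(2^30, 1)
    )
    self <- kind %in% c("hairpin_shift_self", "double_hairpin_shift_self")
    t_spec <- if (self) q_spec else barrel_spec(
      spec$n_t, residues_per_strand = Ls,
      loop_length_extracellular = if (long_ec) Ls else 5L,
      loop_length_periplasmic = 4L,
      seed = sample.int(2^30, 1)
    )
    Q <- generate_barrel(q_spec)
    T_ <- if (self) Q else generate_barrel(t_spec)
    nQ <- spec$n_q; nT <- spec$n_t
    flips <- integer(0)
    cross <- list()
    pair_tbl <- NULL
    if (kind == "cterm_duplication") {
      d <- nT - nQ
      sp <- tibble(q_strand = seq_len(nQ), t_strand = seq_len(nQ) + d)
    } else if (kind == "nterm_duplication") {
      sp <- tibble(q_strand = seq_len(nQ), t_strand = seq_len(nQ))
    } else if (kind == "internal_offset") {
      d <- nT - nQ - 2L
      if (d <= 0L) d <- nT - nQ + 2L
      q0 <- 2L
      q1 <- min(nQ - 1L, nT - d)
      sp <- tibble(q_strand = seq(q0, q1), t_strand = seq(q0, q1) + d)
    } else if (kind == "hairpin_shift_self") {
      sp <- tibble(q_strand = seq_len(nQ - 2L), t_strand = seq_len(nQ - 2L) + 2L)
    } else if (kind == "double_hairpin_shift_self") {
      sp <- tibble(q_strand = seq_len(nQ - 4L), t_strand = seq_len(nQ - 4L) + 4L)
    } else if (kind == "loop_to_hairpin") {
      k <- (nQ %/% 2) - ((nQ %/% 2 + 1) %% 2)  # odd mid strand
      Q <- .plant_alternation(Q, .loop_range(Q, k))
      sp <- bind_rows(
        tibble(q_strand = seq_len(k), t_strand = seq_len(k)),
        tibble(q_strand = seq(k + 1L, nQ), t_strand = seq(k + 3L, nT))
      )
      lp <- .loop_range(Q, k)
      cross <- list(
        list(q = c("loop", k), t = c("strand", k + 1L),
             pairs = .zip_pairs(lp[seq_len(Ls)], .strand_range(T_, k + 1L))),
        list(q = c("loop", k), t = c("strand", k + 2L),
             pairs = .zip_pairs(lp[Ls + seq_len(Ls)], .strand_range(T_, k + 2L)))
      )
    } else if (kind == "large_rearrangement") {
      k <- (nQ %/% 2) - ((nQ %/% 2 + 1) %% 2)
      Q <- .plant_alternation(Q, .loop_range(Q, k))
      Q <- .plant_alternation(Q, .loop_range(Q, k + 2L))
      sp <- bind_rows(
        tibble(q_strand = seq_len(k), t_strand = seq_len(k)),
        tibble(q_strand = k + 2L, t_strand = k + 3L),
        tibble(q_strand = seq(k + 3L, nQ), t_strand = seq(k + 5L, nT))
      )
      flips <- k + 2L
      lp <- .loop_range(Q, k)
      lp2 <- .loop_range(Q, k + 2L)
      t_loop <- .loop_range(T_, k + 2L)
      cross <- list(
        list(q = c("loop", k), t = c("strand", k + 1L),
             pairs = .zip_pairs(lp[seq_len(Ls)], .strand_range(T_, k + 1L))),
        list(q = c("loop", k), t = c("strand", k + 2L),
             pairs = .zip_pairs(lp[Ls + seq_len(Ls)], .strand_range(T_, k + 2L))),
        list(q = c("strand", k + 1L), t = c("loop", k + 2L),
             pairs = .zip_pairs(.strand_range(Q, k + 1L), t_loop)),
        list(q = c("loop", k + 2L), t = c("strand", k + 4L),
             pairs = .zip_pairs(lp2[seq_len(Ls)], .strand_range(T_, k + 4L)))
      )
    } else if (kind == "topology_flip") {
      k <- nQ %/% 2
      sp <- bind_rows(
        tibble(q_strand = seq_len(k - 1L), t_strand = seq_len(k - 1L)),
        tibble(q_strand = k, t_strand = k + 1L)
      )
      flips <- k
    }
    # residue pairs: strand-strand zips plus cross-match zips, in q order
    blocks <- c(
      pmap(sp, function(q_strand, t_strand) {
        .zip_pairs(.strand_range(Q, q_strand), .strand_range(T_, t_strand))
      }),
      map(cross, "pairs")
    )
    pair_tbl <- bind_rows(blocks) |> arrange(.data$q_pos)
    stopifnot(all(diff(pair_tbl$q_pos) > 0), all(diff(pair_tbl$t_pos) > 0))
    if (spec$noise > 0) {
      keep <- stats::runif(nrow(pair_tbl)) >= spec$noise
      pair_tbl <- pair_tbl[keep, , drop = FALSE]
    }
    q_id <- sprintf("syn%02dq", nQ)
    t_id <- if (self) q_id else sprintf("syn%02dt", nT)
    record <- tibble(
      query_id = q_id, target_id = t_id,
      evalue = 10^stats::runif(1, -20, -3),
      probability = stats::runif(1, 80, 100),
      is_self = self,
      n_aligned = nrow(pair_tbl),
      pairs = list(pair_tbl)
    )
    truth <- list(kind = kind, strand_pairs = sp, flipped = flips,
                  cross = map(cross, function(cr) c(cr$q, cr$t)))
    list(query = Q, target = T_, record = record, truth = truth)
  })
}

#' Generate synthetic HMM-profile homolog memberships
#'
#' Creates `n_profiles` profiles, alternating strand counts, each with a
#' fixed-size homolog set. Consecutive profiles (1,2), (3,4), ... are
#' designated pairs whose realized overlap fraction equals
#' `planted_overlap` to within one element; all other pairs are disjoint.
#'
#' @param n_profiles Integer >= 2.
#' @param planted_overlap Fraction in \[0, 1\].
#' @param seed Integer seed.
#' @param set_size Homolog-set size per profile.
#' @return Tibble with `profile_id`, `n_strands`, `members` (list-column of
#'   character vectors).
#' @export
generate_membership <- function(n_profiles, planted_overlap, seed = 1L,
                                set_size = 50L) {
  if (n_profiles < 2) abort("`n_profiles` must be >= 2")
  if (planted_overlap < 0 || planted_overlap > 1) {
    abort("`planted_overlap` must be in [0, 1]")
  }
  with_local_seed(seed, {
    n_shared <- as.integer(round(planted_overlap * set_size))
    counter <- 0L
    fresh <- function(k) {
      ids <- sprintf("hom%06d", counter + seq_len(k))
      counter <<- counter + k
      ids
    }
    members <- vector("list", n_profiles)
    for (i in seq(1, n_profiles - 1, by = 2)) {
      shared <- fresh(n_shared)
      members[[i]] <- c(shared, fresh(set_size - n_shared))
      members[[i + 1]] <- c(shared, fresh(set_size - n_shared))
    }
    if (n_profiles %% 2 == 1) members[[n_profiles]] <- fresh(set_size)
    tibble(
      profile_id = sprintf("prof%03d", seq_len(n_profiles)),
      n_strands = rep(c(8L, 10L, 12L, 14L, 16L, 18L, 22L),
                      length.out = n_profiles),
      members = members
    )
  })
}
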