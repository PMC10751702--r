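# Atomistic DNA target construction and PDB input/output.
#
# Every atom is a van der Waals sphere; every sphere belongs to exactly one
# molecule record (a base, a deoxyribose or a phosphate group), and each
# nucleotide contributes one molecule of each of the three groups.  The
# per-nucleotide templates below carry correct heavy-atom counts and
# approximate internal geometry; crystallographic accuracy is not needed for
# sphere-based transport, only sphere positions, radii and molecule labels.

# --- per-molecule heavy-atom templates (local coordinates, nm) --------------

.ring <- function(names, radius, phase = 0) {
  n <- length(names)
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  data.frame(name = names,
             x = radius * cos(ang), y = radius * sin(ang), z = 0,
             stringsAsFactors = FALSE)
}

.template_one <- function(kind) {
  switch(kind,
    phosphate = {
      # 1 P + 4 O in a tetrahedral arrangement, P-O bond 0.16 nm
      d <- 0.16 / sqrt(3)
      data.frame(
        name = c("P", "OP1", "OP2", "O5'", "O3'"),
        x = c(0,  d,  d, -d, -d),
        y = c(0,  d, -d,  d, -d),
        z = c(0,  d, -d, -d,  d),
        stringsAsFactors = FALSE)
    },
    deoxyribose = {
      ring <- .ring(c("C1'", "C2'", "C3'", "C4'", "O4'"), 0.118)
      rbind(ring, data.frame(name = "C5'", x = 0.05, y = 0.14, z = 0.10))
    },
    cytosine = {
      ring <- .ring(c("N1", "C2", "N3", "C4", "C5", "C6"), 0.139)
      rbind(ring,
            data.frame(name = c("O2", "N4"),
                       x = 0.26 * cos(2 * pi * c(1, 3) / 6),
                       y = 0.26 * sin(2 * pi * c(1, 3) / 6), z = 0))
    },
    thymine = {
      ring <- .ring(c("N1", "C2", "N3", "C4", "C5", "C6"), 0.139)
      rbind(ring,
            data.frame(name = c("O2", "O4", "C7"),
                       x = 0.26 * cos(2 * pi * c(1, 3, 4) / 6),
                       y = 0.26 * sin(2 * pi * c(1, 3, 4) / 6), z = 0))
    },
    adenine = {
      ring <- .ring(c("N1", "C2", "N3", "C4", "C5", "C6"), 0.139)
      rbind(ring,
            data.frame(name = c("N6", "N7", "C8", "N9"),
                       x = c(0.26 * cos(2 * pi * 5 / 6), 0.28, 0.37, 0.30),
                       y = c(0.26 * sin(2 * pi * 5 / 6), -0.10, 0.02, 0.13),
                       z = 0))
    },
    guanine = {
      ring <- .ring(c("N1", "C2", "N3", "C4", "C5", "C6"), 0.139)
      rbind(ring,
            data.frame(name = c("O6", "N2", "N7", "C8", "N9"),
                       x = c(0.26 * cos(2 * pi * 5 / 6),
                             0.26 * cos(2 * pi * 1 / 6), 0.28, 0.37, 0.30),
                       y = c(0.26 * sin(2 * pi * 5 / 6),
                             0.26 * sin(2 * pi * 1 / 6), -0.10, 0.02, 0.13),
                       z = 0))
    },
    stop("unknown molecule kind: ", kind))
}

.element_of <- function(atom_name) {
  sub("^([A-Za-z]).*$", "\\1", atom_name)
}

.templates <- local({
  out <- lapply(MOLECULE_KINDS, function(k) {
    t <- .template_one(k)
    t$element <- .element_of(t$name)
    t
  })
  names(out) <- MOLECULE_KINDS
  out
})

# molecular masses implied by the templates (heavy atoms), Daltons
.template_mass <- vapply(.templates, function(t)
  sum(ATOMIC_MASS_DA[t$element]), numeric(1))

# radial placement of each molecule's local origin, nm from the helix axis
.MOL_RADIUS <- c(adenine = 0.25, cytosine = 0.25, guanine = 0.25,
                 thymine = 0.25, deoxyribose = 0.59, phosphate = 0.89)

# canonical B-helix parameters
BDNA_RISE_NM <- 0.34
BDNA_TWIST_DEG <- 36
# angular offset of strand 2 relative to strand 1 within a base pair
.STRAND2_PHASE <- 2.67
# condensed mode: solenoidal axis path (radius / pitch per turn, nm)
.SOLENOID_RADIUS <- 12
.SOLENOID_PITCH <- 5.6

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")
.BASE_OF_LETTER <- c(A = "adenine", C = "cytosine", G = "guanine",
                     T = "thymine")

# --- model container --------------------------------------------------------

new_dna_model <- function(atoms, molecules, n_bp, n_targets = 1L,
                          sequence = NULL, mode = NA_character_) {
  atoms <- as.data.table(atoms)
  molecules <- as.data.table(molecules)
  mass <- if (nrow(atoms)) sum(ATOMIC_MASS_DA[atoms$element]) else 0
  extent <- if (nrow(atoms)) {
    rbind(lo = c(min(atoms$x - atoms$radius), min(atoms$y - atoms$radius),
                 min(atoms$z - atoms$radius)),
          hi = c(max(atoms$x + atoms$radius), max(atoms$y + atoms$radius),
                 max(atoms$z + atoms$radius)))
  } else matrix(0, 2, 3, dimnames = list(c("lo", "hi"), NULL))
  structure(list(atoms = atoms, molecules = molecules,
                 n_bp = as.integer(n_bp), n_targets = as.integer(n_targets),
                 mass = mass, extent = extent, sequence = sequence,
                 mode = mode),
            class = "dna_model")
}

validate_dna_model <- function(model) {
  stopifnot(inherits(model, "dna_model"))
  if (identical(model$mode, "phantom")) return(invisible(model))
  a <- model$atoms; m <- model$molecules
  if (!all(a$element %in% names(VDW_RADII_NM)))
    stop("atom with element outside {H,C,N,O,P}")
  if (any(a$radius <= 0)) stop("non-positive vdW radius")
  if (!all(a$molecule_id %in% m$molecule_id))
    stop("atom references unknown molecule_id")
  bad <- m$kind %in% BACKBONE_KINDS != (m$group == "backbone")
  if (any(bad)) stop("molecule kind/group annotation inconsistent")
  n_nuc <- sum(m$kind == "deoxyribose")
  if (n_nuc != 2L * model$n_bp * model$n_targets)
    stop("nucleotide count does not equal 2 x n_bp x n_targets")
  invisible(model)
}

#' @export
print.dna_model <- function(x, ...) {
  ext <- x$extent["hi", ] - x$extent["lo", ]
  cat(sprintf(
    "<dna_model> %d target(s) x %d bp | %d atoms, %d molecules | %.0f Da\n",
    x$n_targets, x$n_bp, nrow(x$atoms), nrow(x$molecules), x$mass))
  cat(sprintf("  mode: %s | extent: %.1f x %.1f x %.1f nm\n",
              x$mode, ext[1], ext[2], ext[3]))
  invisible(x)
}

# --- procedural B-DNA builder ----------------------------------------------

# axis frame at arclength s: point p plus cross-section unit vectors (e1, e2)
.axis_frame <- function(s, mode, origin, axis) {
  ob <- orthobasis(axis)
  o_mat <- matrix(origin, length(s), 3, byrow = TRUE)
  if (mode == "straight") {
    list(p = o_mat + outer(s, axis),
         e1 = matrix(ob$e1, length(s), 3, byrow = TRUE),
         e2 = matrix(ob$e2, length(s), 3, byrow = TRUE))
  } else {
    a <- .SOLENOID_RADIUS
    b <- .SOLENOID_PITCH / (2 * pi)
    t <- s / sqrt(a^2 + b^2)
    ct <- cos(t); st <- sin(t)
    p <- o_mat +
      a * (outer(ct, ob$e1) + outer(st, ob$e2)) +
      b * outer(t, axis)
    # Frenet frame of the circular solenoid axis
    nrm <- -(outer(ct, ob$e1) + outer(st, ob$e2))
    tng <- (a * (-outer(st, ob$e1) + outer(ct, ob$e2)) +
              b * matrix(axis, length(s), 3, byrow = TRUE)) / sqrt(a^2 + b^2)
    bin <- cbind(tng[, 2] * nrm[, 3] - tng[, 3] * nrm[, 2],
                 tng[, 3] * nrm[, 1] - tng[, 1] * nrm[, 3],
                 tng[, 1] * nrm[, 2] - tng[, 2] * nrm[, 1])
    list(p = p, e1 = nrm, e2 = bin)
  }
}

#' Build a procedural B-DNA double helix of van der Waals spheres
#'
#' Constructs an atomistic double helix with the canonical B-form parameters
#' (rise 0.34 nm per base pair, twist 36 degrees per base pair).  Each of the
#' `2 * n_bp` nucleotides contributes a phosphate group (1 P + 4 O spheres), a
#' deoxyribose (6 heavy-atom spheres) and a base, placed by helical symmetry
#' around the axis path.  In `condensed` mode the helix axis itself winds
#' along a solenoidal path (radius 12 nm, pitch 5.6 nm per turn) so that a
#' 1122-bp molecule folds into an overall extent of roughly 30 nm, emulating a
#' partially condensed in-vivo-like target; the exact fold of such targets is
#' not standardized, so the solenoid is a documented convention.
#'
#' @param n_bp number of base pairs (>= 1).
#' @param sequence base string for strand 1 (letters ACGT) or `"random"`.
#' @param mode `"straight"` or `"condensed"`.
#' @param origin 3-vector, nm; start of the helix axis path.
#' @param axis unit 3-vector; direction of the axis path.
#' @param seed integer; controls the random sequence draw only.
#' @return A `dna_model`: atom table (element, centre, vdW radius,
#'   molecule_id), molecule table (kind, group, strand, bp index), total mass
#'   in Daltons and bounding box.
#' @examples
#' m <- build_bdna(10, seed = 1)
#' m$mass
#' @export
build_bdna <- function(n_bp, sequence = "random",
                       mode = c("straight", "condensed"),
                       origin = c(0, 0, 0), axis = c(0, 0, 1), seed = 1L) {
  mode <- match.arg(mode)
  n_bp <- as.integer(n_bp)
  if (is.na(n_bp) || n_bp < 1) stop("n_bp must be >= 1")
  axis <- unitize(axis)

  if (identical(sequence, "random")) {
    sequence <- with_local_seed(seed,
      paste(sample(c("A", "C", "G", "T"), n_bp, replace = TRUE),
            collapse = ""))
  }
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters1) != n_bp)
    stop("sequence length (", length(letters1), ") != n_bp (", n_bp, ")")
  if (!all(letters1 %in% names(.COMPLEMENT)))
    stop("invalid base letters in sequence: ",
         paste(unique(setdiff(letters1, names(.COMPLEMENT))), collapse = ","))
  letters2 <- unname(.COMPLEMENT[letters1])

  fr <- .axis_frame(BDNA_RISE_NM * (seq_len(n_bp) - 1), mode, origin, axis)
  twist <- BDNA_TWIST_DEG * pi / 180

  atoms_list <- vector("list", 6L * n_bp)
  mol_list <- vector("list", 6L * n_bp)
  mol_id <- 0L
  k <- 0L
  for (i in seq_len(n_bp)) {
    for (s in 1:2) {
      theta <- twist * (i - 1) + if (s == 2L) .STRAND2_PHASE else 0
      u <- cos(theta) * fr$e1[i, ] + sin(theta) * fr$e2[i, ]
      v <- -sin(theta) * fr$e1[i, ] + cos(theta) * fr$e2[i, ]
      w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
      base_kind <- .BASE_OF_LETTER[[if (s == 1L) letters1[i] else letters2[i]]]
      for (kind in c("phosphate", "deoxyribose", base_kind)) {
        tpl <- .templates[[kind]]
        centre <- fr$p[i, ] + .MOL_RADIUS[[kind]] * u
        mol_id <- mol_id + 1L
        k <- k + 1L
        atoms_list[[k]] <- data.table(
          element = tpl$element, name = tpl$name,
          x = centre[1] + tpl$x * u[1] + tpl$y * v[1] + tpl$z * w[1],
          y = centre[2] + tpl$x * u[2] + tpl$y * v[2] + tpl$z * w[2],
          z = centre[3] + tpl$x * u[3] + tpl$y * v[3] + tpl$z * w[3],
          radius = unname(VDW_RADII_NM[tpl$element]),
          molecule_id = mol_id)
        mol_list[[k]] <- data.table(
          molecule_id = mol_id, kind = kind,
          group = if (kind %in% BACKBONE_KINDS) "backbone" else "base",
          strand = s, bp_index = i, target = 1L,
          atom_count = nrow(tpl), mass = unname(.template_mass[[kind]]))
      }
    }
  }
  model <- new_dna_model(rbindlist(atoms_list), rbindlist(mol_list),
                         n_bp = n_bp, sequence = sequence, mode = mode)
  validate_dna_model(model)
}

#' Arrange several DNA targets as a parallel bundle
#'
#' Replicates a procedural B-DNA target `n_targets` times on a square grid of
#' parallel molecules (axis along z), the arrangement used when several
#' targets are irradiated simultaneously.  Molecule identifiers are offset so
#' they stay unique; each molecule carries its target index.
#'
#' @param n_targets number of identical targets.
#' @param spacing centre-to-centre spacing of the bundle grid, nm.
#' @inheritParams build_bdna
#' @return A combined `dna_model` with `n_targets` set.
#' @export
build_scene <- function(n_targets = 1L, n_bp = 200L, sequence = "random",
                        mode = c("straight", "condensed"), spacing = 40,
                        seed = 1L) {
  mode <- match.arg(mode)
  n_targets <- as.integer(n_targets)
  stopifnot(n_targets >= 1L)
  base <- build_bdna(n_bp, sequence = sequence, mode = mode, seed = seed)
  if (n_targets == 1L) return(base)

  side <- ceiling(sqrt(n_targets))
  offs <- expand.grid(ix = seq_len(side) - 1, iy = seq_len(side) - 1)
  offs <- offs[seq_len(n_targets), , drop = FALSE]
  offs$ix <- (offs$ix - mean(offs$ix)) * spacing
  offs$iy <- (offs$iy - mean(offs$iy)) * spacing

  atoms <- vector("list", n_targets)
  mols <- vector("list", n_targets)
  id_off <- 0L
  for (tgt in seq_len(n_targets)) {
    a <- copy(base$atoms)
    m <- copy(base$molecules)
    a[, `:=`(x = x + offs$ix[tgt], y = y + offs$iy[tgt],
             molecule_id = molecule_id + id_off)]
    m[, `:=`(molecule_id = molecule_id + id_off, target = tgt)]
    id_off <- id_off + nrow(base$molecules)
    atoms[[tgt]] <- a
    mols[[tgt]] <- m
  }
  model <- new_dna_model(rbindlist(atoms), rbindlist(mols),
                         n_bp = base$n_bp, n_targets = n_targets,
                         sequence = base$sequence, mode = mode)
  validate_dna_model(model)
}

#' Homogeneous sphere phantom
#'
#' A single sphere of one molecule's material -- a test/diagnostic geometry
#' for verifying exponential attenuation against the closed form
#' `P(interaction) = 1 - exp(-t / lambda)` along a chord of length `t`.
#' Not a DNA model: it carries one molecule record and skips the duplex
#' validation.
#'
#' @param radius sphere radius, nm.
#' @param kind molecule kind whose material fills the sphere.
#' @param centre sphere centre, nm.
#' @return A `dna_model` with `mode = "phantom"`.
#' @export
phantom_sphere <- function(radius, kind = "phosphate", centre = c(0, 0, 0)) {
  stopifnot(radius > 0, kind %in% MOLECULE_KINDS)
  atoms <- data.table(element = "P", name = "P",
                      x = centre[1], y = centre[2], z = centre[3],
                      radius = radius, molecule_id = 1L)
  mols <- data.table(molecule_id = 1L, kind = kind,
                     group = molecule_group(kind), strand = 1L,
                     bp_index = 1L, target = 1L, atom_count = 1L,
                     mass = unname(.template_mass[[kind]]))
  new_dna_model(atoms, mols, n_bp = 1L, mode = "phantom")
}

#' Total DNA mass in Daltons
#'
#' Sum of standard atomic masses over all atoms of the model; the denominator
#' of the per-Gray-per-Dalton break yields.
#'
#' @param model a `dna_model`.
#' @return Mass in Daltons (0 for an empty model).
#' @export
dna_mass <- function(model) {
  stopifnot(inherits(model, "dna_model"))
  if (!nrow(model$atoms)) return(0)
  sum(ATOMIC_MASS_DA[model$atoms$element])
}

# --- PDB input/output -------------------------------------------------------

.PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "O1P", "O2P", "O3'", "O5'",
                      "O3*", "O5*")
.SUGAR_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'",
                  "C1*", "C2*", "C3*", "C4*", "C5*", "O4*")
.RESID_TO_BASE <- c(DA = "adenine", DC = "cytosine", DG = "guanine",
                    DT = "thymine", A = "adenine", C = "cytosine",
                    G = "guanine", T = "thymine", ADE = "adenine",
                    CYT = "cytosine", GUA = "guanine", THY = "thymine")
.BASE_TO_RESID <- c(adenine = "DA", cytosine = "DC", guanine = "DG",
                    thymine = "DT")

#' Write a DNA model to a PDB file
#'
#' Emits standard ATOM records (coordinates converted from nm to Angstrom)
#' with nucleotide residue names DA/DC/DG/DT, chains A and B for the two
#' strands, and residue numbers equal to the base-pair index, so that
#' [load_pdb()] round-trips the molecule annotations.
#'
#' @param model a single-target `dna_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "dna_model"))
  if (model$n_targets != 1L)
    stop("write_pdb() writes single-target models")
  a <- merge(model$atoms,
             model$molecules[, .(molecule_id, kind, strand, bp_index)],
             by = "molecule_id", sort = FALSE)
  setorder(a, strand, bp_index, molecule_id)
  resid <- ifelse(a$kind %in% BASE_KINDS, .BASE_TO_RESID[a$kind], NA)
  # backbone atoms take the residue name of their nucleotide's base
  base_by_nuc <- a[kind %in% BASE_KINDS,
                   .(resid = .BASE_TO_RESID[kind[1]]),
                   by = .(strand, bp_index)]
  a <- merge(a, base_by_nuc, by = c("strand", "bp_index"), sort = FALSE)
  setorder(a, strand, bp_index, molecule_id)
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, .(x, y, z)]) * 10)),
    type = rep("ATOM", nrow(a)),
    resno = a$bp_index, resid = a$resid,
    chain = c("A", "B")[a$strand],
    eleno = seq_len(nrow(a)), elety = a$name,
    o = rep(1, nrow(a)), b = rep(0, nrow(a)),
    elesy = a$element)
  invisible(path)
}

#' Read a DNA model from a PDB file
#'
#' Parses ATOM records (via bio3d), converts Angstrom to nm, assigns each atom
#' its pinned van der Waals radius, and infers molecule membership from
#' standard nucleotide atom naming: P/OP1/OP2/O3'/O5' form the phosphate
#' group, C1'-C5' and O4' the deoxyribose, all remaining heavy atoms the
#' base.  Strand is taken from the chain identifier, base-pair index from the
#' residue sequence number.
#'
#' @param path PDB file whose residues are nucleotides (DA/DC/DG/DT).
#' @return A `dna_model`.
#' @export
load_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)

  bad <- !(at$resid %in% names(.RESID_TO_BASE))
  if (any(bad))
    stop("non-nucleotide residue in PDB file: ",
         paste(unique(at$resid[bad]), collapse = ", "))

  elem <- at$elesy
  blank <- is.na(elem) | elem == "" | elem == " "
  elem[blank] <- .element_of(at$elety[blank])
  elem <- toupper(trimws(elem))
  if (!all(elem %in% names(VDW_RADII_NM)))
    stop("unknown element in PDB file: ",
         paste(unique(elem[!elem %in% names(VDW_RADII_NM)]), collapse = ", "))

  chains <- unique(at$chain)
  if (length(chains) > 2) stop("more than two chains; expected a duplex")
  strand <- match(at$chain, chains)

  name <- trimws(at$elety)
  part <- ifelse(name %in% .PHOSPHATE_ATOMS, "phosphate",
          ifelse(name %in% .SUGAR_ATOMS, "deoxyribose", "base"))

  dt <- data.table(element = elem, name = name,
                   x = at$x / 10, y = at$y / 10, z = at$z / 10,
                   strand = strand, bp_index = at$resno,
                   resid = at$resid, part = part)
  dt[, radius := unname(VDW_RADII_NM[element])]

  # one molecule per (strand, bp, part); hydrogens (if present) follow their
  # heavy-atom group assignment, base by default
  dt[, kind := ifelse(part == "base", unname(.RESID_TO_BASE[resid]), part)]
  mol_key <- dt[, paste(strand, bp_index, part)]
  dt[, molecule_id := as.integer(factor(mol_key, levels = unique(mol_key)))]

  mols <- dt[, .(kind = kind[1],
                 group = if (part[1] == "base") "base" else "backbone",
                 strand = strand[1], bp_index = bp_index[1], target = 1L,
                 atom_count = .N,
                 mass = sum(ATOMIC_MASS_DA[element])),
             by = molecule_id]
  n_bp <- max(dt[, .(n = length(unique(bp_index))), by = strand]$n)

  model <- new_dna_model(
    dt[, .(element, name, x, y, z, radius, molecule_id)],
    mols, n_bp = n_bp, mode = "loaded")
  validate_dna_model(model)
}
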