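#' Minimal ligand pose readers (mol2, SDF, PDB)
#'
#' Reads the coordinate subset of the three formats the carbocation
#' library and receptor structures come in: TRIPOS MOL2 (`ATOM`/`BOND`
#' sections, partial charges in column 9), SDF V2000 (counts line + atom
#' block), and PDB (`ATOM`/`HETATM` records only).  Everything beyond
#' names, elements, coordinates, charges and (for mol2/SDF) bonds is
#' ignored.  Malformed records raise an error naming the offending line.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension) or one of `"mol2"`, `"sdf"`,
#'   `"pdb"`.
#' @return A `pose`: list with `atoms` (data frame: `name`, `element`,
#'   `x`, `y`, `z`, `charge`), `bonds` (data frame `i`,`j` or `NULL`) and
#'   `frame_note`.
#' @export
read_pose <- function(path, format = c("auto", "mol2", "sdf", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mol2 = "mol2", sdf = "sdf", sd = "sdf",
                     pdb = "pdb", ent = "pdb",
                     stop("cannot infer format from extension: ", ext))
  }
  lines <- readLines(path, warn = FALSE)
  pose <- switch(format,
                 mol2 = parse_mol2(lines, path),
                 sdf = parse_sdf(lines, path),
                 pdb = parse_pdb(lines, path))
  validate_pose(pose)
  pose
}

new_pose <- function(atoms, bonds = NULL, frame_note = "") {
  structure(list(atoms = atoms, bonds = bonds, frame_note = frame_note),
            class = "pose")
}

validate_pose <- function(pose) {
  a <- pose$atoms
  if (nrow(a) == 0) stop("pose has no atoms")
  if (anyDuplicated(a$name)) stop("atom names must be unique within a pose")
  if (!all(is.finite(c(a$x, a$y, a$z)))) stop("non-finite coordinates in pose")
  invisible(pose)
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("Pose: %d atoms, %s bonds%s\n", nrow(x$atoms),
              if (is.null(x$bonds)) "no" else nrow(x$bonds),
              if (nzchar(x$frame_note)) paste0(" [", x$frame_note, "]") else ""))
  print.data.frame(utils::head(x$atoms, 5))
  if (nrow(x$atoms) > 5) cat("...\n")
  invisible(x)
}

parse_mol2 <- function(lines, path) {
  sect <- grep("^@<TRIPOS>", lines)
  names(sect) <- sub("^@<TRIPOS>", "", lines[sect])
  if (!"ATOM" %in% names(sect)) stop("no @<TRIPOS>ATOM section in ", path)
  span <- function(start) {
    nxt <- sect[sect > start]
    end <- if (length(nxt)) min(nxt) - 1 else length(lines)
    seq(start + 1, end)
  }
  atom_lines <- span(sect[["ATOM"]])
  atom_lines <- atom_lines[nzchar(trimws(lines[atom_lines]))]
  atoms <- do.call(rbind, lapply(atom_lines, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 6) stop("malformed mol2 ATOM record at line ", i,
                            " of ", path)
    xyz <- suppressWarnings(as.numeric(f[3:5]))
    if (any(is.na(xyz))) stop("non-numeric coordinate at line ", i, " of ", path)
    chg <- if (length(f) >= 9) suppressWarnings(as.numeric(f[9])) else 0
    data.frame(name = f[2], element = sub("\\..*$", "", f[6]),
               x = xyz[1], y = xyz[2], z = xyz[3],
               charge = if (is.na(chg)) 0 else chg,
               stringsAsFactors = FALSE)
  }))
  bonds <- NULL
  if ("BOND" %in% names(sect)) {
    bl <- span(sect[["BOND"]])
    bl <- bl[nzchar(trimws(lines[bl]))]
    if (length(bl)) {
      bonds <- do.call(rbind, lapply(bl, function(i) {
        f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
        if (length(f) < 4) stop("malformed mol2 BOND record at line ", i,
                                " of ", path)
        data.frame(i = as.integer(f[2]), j = as.integer(f[3]))
      }))
    }
  }
  new_pose(atoms, bonds, frame_note = basename(path))
}

parse_sdf <- function(lines, path) {
  if (length(lines) < 4) stop("SDF too short: ", path)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || na < 1) stop("malformed V2000 counts line at line 4 of ", path)
  atoms <- do.call(rbind, lapply(seq_len(na), function(k) {
    i <- 4 + k
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 4) stop("malformed SDF atom record at line ", i, " of ", path)
    xyz <- suppressWarnings(as.numeric(f[1:3]))
    if (any(is.na(xyz))) stop("non-numeric coordinate at line ", i, " of ", path)
    data.frame(name = paste0(f[4], k), element = f[4],
               x = xyz[1], y = xyz[2], z = xyz[3], charge = 0,
               stringsAsFactors = FALSE)
  }))
  bonds <- NULL
  if (!is.na(nb) && nb > 0) {
    bonds <- do.call(rbind, lapply(seq_len(nb), function(k) {
      i <- 4 + na + k
      bi <- suppressWarnings(as.integer(substr(lines[i], 1, 3)))
      bj <- suppressWarnings(as.integer(substr(lines[i], 4, 6)))
      if (is.na(bi) || is.na(bj)) stop("malformed SDF bond record at line ",
                                       i, " of ", path)
      data.frame(i = bi, j = bj)
    }))
  }
  # M CHG lines carry formal charges in V2000
  chg_lines <- grep("^M  CHG", lines)
  for (i in chg_lines) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    n <- as.integer(f[3])
    for (k in seq_len(n)) {
      ai <- as.integer(f[2 + 2 * k])
      atoms$charge[ai] <- as.numeric(f[3 + 2 * k])
    }
  }
  new_pose(atoms, bonds, frame_note = basename(path))
}

parse_pdb <- function(lines, path) {
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  atoms <- do.call(rbind, lapply(rec, function(i) {
    l <- lines[i]
    if (nchar(l) < 54) stop("truncated PDB record at line ", i, " of ", path)
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (any(is.na(xyz))) stop("non-numeric coordinate at line ", i, " of ", path)
    el <- trimws(substr(l, 77, 78))
    nm <- trimws(substr(l, 13, 16))
    if (!nzchar(el)) el <- sub("[0-9'].*$", "", nm)
    data.frame(name = nm, element = el, x = xyz[1], y = xyz[2], z = xyz[3],
               charge = 0, stringsAsFactors = FALSE)
  }))
  atoms$name <- make.unique(atoms$name, sep = "_")
  new_pose(atoms, NULL, frame_note = basename(path))
}

#' Write a pose as TRIPOS MOL2
#'
#' Counterpart of [read_pose()] for fixture generation; coordinates and
#' charges survive a write/read round trip exactly to printed precision.
#'
#' @param pose A `pose`.
#' @param path Output file.
#' @param name Molecule name written to the header.
#' @return `path`, invisibly.
#' @export
write_pose_mol2 <- function(pose, path, name = "LIG") {
  a <- pose$atoms
  nb <- if (is.null(pose$bonds)) 0L else nrow(pose$bonds)
  lines <- c("@<TRIPOS>MOLECULE", name,
             sprintf("%d %d 0 0 0", nrow(a), nb),
             "SMALL", "USER_CHARGES", "@<TRIPOS>ATOM",
             sprintf("%6d %-8s %10.4f %10.4f %10.4f %-5s 1 LIG %10.6f",
                     seq_len(nrow(a)), a$name, a$x, a$y, a$z, a$element,
                     a$charge))
  if (nb > 0) {
    lines <- c(lines, "@<TRIPOS>BOND",
               sprintf("%6d %6d %6d 1", seq_len(nb), pose$bonds$i,
                       pose$bonds$j))
  }
  writeLines(lines, path)
  invisible(path)
}

pose_coords <- function(pose, names = NULL) {
  a <- pose$atoms
  if (!is.null(names)) {
    i <- match(names, a$name)
    if (anyNA(i)) stop("atom(s) not in pose: ",
                       paste(names[is.na(i)], collapse = ", "))
    a <- a[i, , drop = FALSE]
  }
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$name
  m
}

#' Signed dihedral (torsion) angle
#'
#' IUPAC-signed torsion of the four points p1-p2-p3-p4, in degrees on
#' (-180, 180].  Degenerate geometry (coincident consecutive points or a
#' collinear triple) is an error, since the torsion is then undefined.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees.
#' @examples
#' dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0))  # trans, 180
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  eps <- 1e-10
  if (sqrt(sum(b1^2)) < eps || sqrt(sum(b2^2)) < eps || sqrt(sum(b3^2)) < eps) {
    stop("degenerate dihedral: coincident consecutive points")
  }
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sqrt(sum(n1^2)) < eps || sqrt(sum(n2^2)) < eps) {
    stop("degenerate dihedral: collinear triple")
  }
  x <- sum(cross(n1, n2) * b2) / sqrt(sum(b2^2))
  y <- sum(n1 * n2)
  ang <- atan2(x, y) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Classify an I1 conformer by the C16-C17-C18-H18 torsion
#'
#' The A-I1 and B-I1/C-I1 cations are chemically identical but folded
#' differently; the sign of the torsion about C16-C17-C18-H18
#' distinguishes them: positive for the hopene-channel (A-like) fold,
#' negative for the lupeol/lanosterol-type (B/C-like) fold.  Torsions
#' within `tolerance` of 0 or 180 degrees carry no usable sign, so
#' classification is refused and flagged.
#'
#' @param pose A `pose`.
#' @param atom_map Named character vector mapping the roles `C16`, `C17`,
#'   `C18`, `H18` to atom names in the pose.
#' @param tolerance Degrees within which of 0/180 the sign is considered
#'   meaningless (default 1).
#' @return A `conformer_call`: list with `class` (`"A_like"`,
#'   `"BC_like"`, or `NA` when refused), `phi` (degrees) and `refused`.
#' @export
classify_conformer <- function(pose, atom_map = c(C16 = "C16", C17 = "C17",
                                                  C18 = "C18", H18 = "H18"),
                               tolerance = 1.0) {
  need <- c("C16", "C17", "C18", "H18")
  if (!all(need %in% names(atom_map))) {
    stop("atom_map must name C16, C17, C18 and H18")
  }
  m <- pose_coords(pose, unname(atom_map[need]))
  phi <- dihedral(m[1, ], m[2, ], m[3, ], m[4, ])
  refused <- abs(phi) < tolerance || abs(abs(phi) - 180) < tolerance
  cls <- if (refused) NA_character_ else if (phi > 0) "A_like" else "BC_like"
  structure(list(class = cls, phi = phi, refused = refused),
            class = "conformer_call")
}

#' @export
print.conformer_call <- function(x, ...) {
  cat(sprintf("Conformer torsion phi = %+.2f deg -> %s\n", x$phi,
              if (x$refused) "refused (sign within noise)" else x$class))
  invisible(x)
}

#' RMSD between two poses
#'
#' Root-mean-square deviation over a named-atom correspondence, either in
#' the shared receptor frame (`fit = "in_place"`, the default: docked
#' poses and a crystal ligand already live in one frame) or after optimal
#' rigid superposition by the Kabsch algorithm (`fit = "kabsch"`).
#'
#' @param pose_a,pose_b `pose` objects, or plain n x 3 coordinate
#'   matrices.
#' @param correspondence Two-column character matrix/data frame of atom
#'   name pairs (a-name, b-name); default pairs atoms of equal name.
#'   Ignored for matrix input (rows correspond).
#' @param fit `"in_place"` or `"kabsch"`.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(pose_a, pose_b, correspondence = NULL,
                 fit = c("in_place", "kabsch")) {
  fit <- match.arg(fit)
  if (inherits(pose_a, "pose") || inherits(pose_b, "pose")) {
    if (is.null(correspondence)) {
      shared <- intersect(pose_a$atoms$name, pose_b$atoms$name)
      if (!length(shared)) stop("empty correspondence: no shared atom names")
      correspondence <- cbind(shared, shared)
    }
    correspondence <- as.matrix(correspondence)
    A <- pose_coords(pose_a, correspondence[, 1])
    B <- pose_coords(pose_b, correspondence[, 2])
  } else {
    A <- as.matrix(pose_a); B <- as.matrix(pose_b)
  }
  if (nrow(A) == 0 || nrow(A) != nrow(B)) {
    stop("correspondence must be non-empty and of equal length")
  }
  if (fit == "kabsch") {
    if (nrow(A) < 3) stop("Kabsch fit needs at least 3 atom pairs")
    A <- kabsch_superpose(A, B)
  }
  sqrt(mean(rowSums((A - B)^2)))
}

# Superpose A onto B: optimal rotation + translation (least squares).
kabsch_superpose <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(A0) %*% B0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  if (abs(det(R) - 1) > 1e-6) stop("degenerate Kabsch rotation")
  sweep(A0 %*% t(R), 2, cb, `+`)
}

#' Core-restraint check on a docked pose
#'
#' Docked carbocation poses are required to keep a defined core (the
#' shared polycyclic scaffold) within a stated in-place RMSD of a
#' reference placement, so that poses along one channel stay mutually
#' consistent.  The check is inclusive at the tolerance.
#'
#' @param pose A `pose` or coordinate matrix.
#' @param reference_core A `pose` or n x 3 matrix of reference core
#'   coordinates.
#' @param correspondence Atom-name pairs as in [rmsd()]; for matrix input
#'   rows correspond.
#' @param tolerance Angstrom (default 1.0).
#' @return Logical scalar with attribute `rmsd`.
#' @export
check_core_restraint <- function(pose, reference_core, correspondence = NULL,
                                 tolerance = 1.0) {
  r <- rmsd(pose, reference_core, correspondence, fit = "in_place")
  structure(r <= tolerance, rmsd = r)
}

#' Read an atom-name correspondence file
#'
#' Two whitespace-separated columns of atom names; `#` starts a comment.
#'
#' @param path File path.
#' @return Two-column character matrix.
#' @export
read_correspondence <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  raw <- raw[nzchar(trimws(raw))]
  rows <- strsplit(trimws(raw), "\\s+")
  bad <- vapply(rows, length, 0L) != 2
  if (any(bad)) stop("correspondence line must have two atom names (line ",
                     which(bad)[1], ")")
  m <- do.call(rbind, rows)
  colnames(m) <- c("a", "b")
  m
}
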