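#' Toy receptor pockets for constrained carbocation docking
#'
#' A desk-scale stand-in for induced-fit docking of carbocations: the
#' receptor is a rigid set of interaction sites (position, partial
#' charge, Lennard-Jones radius and well depth), one of which is the
#' anionic anchor playing the role of the catalytic aspartate that
#' protonates the substrate.  Docking requires the cation head to sit
#' near the anchor, mirroring the hydrogen-bond constraint used in the
#' full protocol.
#'
#' @param sites Data frame with columns `x`, `y`, `z` (Angstrom),
#'   `charge` (e), `rmin` (LJ optimum distance contribution, Angstrom)
#'   and `eps` (kcal/mol well depth).
#' @param anchor_site Row index of the anchor site.
#' @return A `toy_receptor`.
#' @export
toy_receptor <- function(sites, anchor_site) {
  need <- c("x", "y", "z", "charge", "rmin", "eps")
  if (!all(need %in% names(sites))) {
    stop("sites need columns: ", paste(need, collapse = ", "))
  }
  if (any(sites$rmin <= 0) || any(sites$eps < 0)) {
    stop("LJ radii must be positive and well depths non-negative")
  }
  if (!(anchor_site %in% seq_len(nrow(sites)))) stop("invalid anchor_site")
  structure(list(sites = as.data.frame(sites), anchor_site = anchor_site),
            class = "toy_receptor")
}

#' @export
print.toy_receptor <- function(x, ...) {
  cat(sprintf("Toy receptor: %d sites, anchor site %d (charge %+.2f e)\n",
              nrow(x$sites), x$anchor_site, x$sites$charge[x$anchor_site]))
  invisible(x)
}

#' Read/write toy receptor files
#'
#' Plain text: one `site x y z charge rmin eps` line per interaction
#' site, one `anchor <index>` line; `#` comments.
#'
#' @param path File path.
#' @param receptor A `toy_receptor` (writer).
#' @return The receptor (reader) or `path` invisibly (writer).
#' @export
read_toy_receptor <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw[nzchar(trimws(raw))])
  site_rows <- grep("^site\\b", raw, value = TRUE)
  anchor_row <- grep("^anchor\\b", raw, value = TRUE)
  if (!length(site_rows) || length(anchor_row) != 1) {
    stop("receptor file needs site lines and exactly one anchor line")
  }
  f <- do.call(rbind, lapply(strsplit(site_rows, "\\s+"), function(v) {
    if (length(v) != 7) stop("site line must have 6 numeric fields")
    as.numeric(v[-1])
  }))
  sites <- data.frame(x = f[, 1], y = f[, 2], z = f[, 3], charge = f[, 4],
                      rmin = f[, 5], eps = f[, 6])
  anchor <- as.integer(strsplit(anchor_row, "\\s+")[[1]][2])
  toy_receptor(sites, anchor)
}

#' @rdname read_toy_receptor
#' @export
write_toy_receptor <- function(receptor, path) {
  s <- receptor$sites
  writeLines(c("# toy receptor: site x y z charge rmin eps",
               sprintf("site %s %s %s %s %s %s",
                       fmt_num(s$x), fmt_num(s$y), fmt_num(s$z),
                       fmt_num(s$charge), fmt_num(s$rmin), fmt_num(s$eps)),
               sprintf("anchor %d", receptor$anchor_site)), path)
  invisible(path)
}

LIG_RMIN <- 1.8   # Angstrom, per ligand bead
LIG_EPS <- 0.1    # kcal/mol, per ligand bead
COULOMB_K <- 332.0636  # kcal/mol * Angstrom / e^2

#' Rigid-pose interaction score
#'
#' Pairwise Lennard-Jones 12-6 plus Coulomb energy between every receptor
#' site and every ligand atom, in kcal/mol.  The Coulomb term uses the
#' distance-dependent dielectric eps(r) = 4r, a cheap implicit-screening
#' model, so the electrostatic energy falls off as 1/r^2.  LJ parameters
#' combine as Rmin_ij = rmin_i + 1.8 A and eps_ij = sqrt(eps_i * 0.1).
#' This is a qualitative stand-in for MM/GBSA rescoring: signs and
#' orderings are meaningful, magnitudes are not.
#'
#' @param receptor A [toy_receptor()].
#' @param ligand A `pose` (partial charges used).
#' @param vdw_scale Scale factor on LJ radii (0.5 emulates the softened
#'   initial-docking potential of induced-fit protocols).
#' @return Score in kcal/mol (negative = favorable).
#' @export
score_pose <- function(receptor, ligand, vdw_scale = 1.0) {
  stopifnot(inherits(receptor, "toy_receptor"))
  S <- as.matrix(receptor$sites[, c("x", "y", "z")])
  L <- pose_coords(ligand)
  d2 <- outer(rowSums(S^2), rowSums(L^2), `+`) - 2 * S %*% t(L)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 0.05)) stop("steric clash: centers closer than 0.05 Angstrom")
  rmin <- vdw_scale * outer(receptor$sites$rmin + LIG_RMIN, rep(1, nrow(L)))
  eps <- outer(sqrt(receptor$sites$eps * LIG_EPS), rep(1, nrow(L)))
  x6 <- (rmin / r)^6
  lj <- eps * (x6^2 - 2 * x6)
  coul <- COULOMB_K * outer(receptor$sites$charge, ligand$atoms$charge) / (4 * r^2)
  sum(lj + coul)
}

# Uniform random unit quaternions -> rotation matrices (Marsaglia/Shoemake).
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

ligand_head <- function(ligand) which.max(ligand$atoms$charge)

# Local rigid-body minimization of the interaction score over
# translation + axis-angle rotation, with optional anchor/core
# constraints enforced as hard penalties.  Deterministic.
rigid_refine <- function(receptor, ligand, coords, anchor = NULL,
                         head_i = NULL, anchor_max_dist = Inf,
                         core_reference = NULL, core_tolerance = 1.0,
                         vdw_scale = 1.0) {
  ctr <- colMeans(coords)
  pose_of <- function(par) {
    R <- rodrigues(par[4:6])
    sweep(sweep(coords, 2, ctr) %*% t(R), 2, ctr + par[1:3], `+`)
  }
  obj <- function(par) {
    Lk <- pose_of(par)
    if (!is.null(anchor) &&
        sqrt(sum((Lk[head_i, ] - anchor)^2)) > anchor_max_dist) return(1e6)
    if (!is.null(core_reference)) {
      nc <- nrow(core_reference)
      if (!check_core_restraint(Lk[seq_len(nc), , drop = FALSE],
                                core_reference,
                                tolerance = core_tolerance)) return(1e6)
    }
    cand <- ligand
    cand$atoms$x <- Lk[, 1]; cand$atoms$y <- Lk[, 2]; cand$atoms$z <- Lk[, 3]
    tryCatch(score_pose(receptor, cand, vdw_scale = vdw_scale),
             error = function(e) 1e6)
  }
  fit <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-12))
  list(coords = pose_of(fit$par), score = fit$value)
}

# axis-angle (Rodrigues) rotation matrix; r = axis * angle (radians)
rodrigues <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  k <- r / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Constrained rigid docking into a toy receptor
#'
#' Samples seeded random rigid placements of the ligand (uniform random
#' rotations about the ligand centroid, translations uniform in a cube
#' around the anchor site), discards placements that violate the anchor
#' constraint (cation head within `anchor_max_dist` of the anchor site),
#' the core restraint (in-place RMSD of the core atoms to
#' `core_reference` within `core_tolerance`, cf.
#' [check_core_restraint()]), or energetic feasibility (interaction score
#' above `score_cutoff`, including steric clashes), and returns the
#' best-scoring survivor.  With no survivor the result is NO_POSE, the
#' toy analogue of a failed docking.
#'
#' @param receptor A [toy_receptor()].
#' @param ligand A `pose`.
#' @param n_samples Number of random placements (>= 1).
#' @param seed Integer seed; identical seed and inputs give an identical
#'   result.
#' @param anchor_max_dist Angstrom (default 3.0).
#' @param core_reference Optional n x 3 matrix (or `pose`) of reference
#'   coordinates for the first `nrow(core_reference)` ligand atoms.
#' @param core_tolerance Angstrom (default 1.0).
#' @param box_half Half-width of the translation cube around the anchor
#'   (default 2.0 Angstrom).
#' @param score_cutoff Poses scoring above this are counted as failed
#'   (default 0: only net-favorable poses are acceptable).
#' @param vdw_scale Passed to [score_pose()].
#' @param refine Locally minimize the best sampled pose over rigid-body
#'   degrees of freedom (Nelder-Mead, constraints enforced), mirroring
#'   the minimization stage that follows pose sampling in induced-fit
#'   protocols (default `TRUE`).
#' @return A `dock_result`: list with `no_pose`, `pose` (a `pose` or
#'   `NULL`), `score`, `n_sampled`, `n_passed_constraints`, `seed`.
#' @export
dock <- function(receptor, ligand, n_samples = 2000, seed = 1,
                 anchor_max_dist = 3.0, core_reference = NULL,
                 core_tolerance = 1.0, box_half = 2.0, score_cutoff = 0.0,
                 vdw_scale = 1.0, refine = TRUE) {
  stopifnot(inherits(receptor, "toy_receptor"), n_samples >= 1)
  anchor <- as.numeric(receptor$sites[receptor$anchor_site, c("x", "y", "z")])
  L0 <- pose_coords(ligand)
  centroid <- colMeans(L0)
  Lc <- sweep(L0, 2, centroid)
  head_i <- ligand_head(ligand)
  if (inherits(core_reference, "pose")) {
    core_reference <- pose_coords(core_reference)
  }

  best_score <- Inf
  best_coords <- NULL
  n_passed <- 0L
  with_seed(seed, {
    for (k in seq_len(n_samples)) {
      R <- random_rotation()
      tr <- anchor + stats::runif(3, -box_half, box_half)
      Lk <- sweep(Lc %*% t(R), 2, tr, `+`)
      if (sqrt(sum((Lk[head_i, ] - anchor)^2)) > anchor_max_dist) next
      if (!is.null(core_reference)) {
        nc <- nrow(core_reference)
        ok <- check_core_restraint(Lk[seq_len(nc), , drop = FALSE],
                                   core_reference, tolerance = core_tolerance)
        if (!ok) next
      }
      cand <- ligand
      cand$atoms$x <- Lk[, 1]; cand$atoms$y <- Lk[, 2]; cand$atoms$z <- Lk[, 3]
      sc <- tryCatch(score_pose(receptor, cand, vdw_scale = vdw_scale),
                     error = function(e) Inf)   # clash -> infeasible
      if (sc > score_cutoff) next
      n_passed <- n_passed + 1L
      if (sc < best_score) {
        best_score <- sc
        best_coords <- Lk
      }
    }
  })

  if (!is.null(best_coords) && refine) {
    # rigid-body polish of the sampled pose, as in the minimization stage
    # of induced-fit docking; constraints stay enforced via penalty
    ref <- rigid_refine(receptor, ligand, best_coords,
                        anchor = anchor, head_i = head_i,
                        anchor_max_dist = anchor_max_dist,
                        core_reference = core_reference,
                        core_tolerance = core_tolerance,
                        vdw_scale = vdw_scale)
    if (ref$score < best_score) {
      best_score <- ref$score
      best_coords <- ref$coords
    }
  }

  if (is.null(best_coords)) {
    res <- list(no_pose = TRUE, pose = NULL, score = NA_real_,
                n_sampled = n_samples, n_passed_constraints = n_passed,
                seed = seed)
  } else {
    out <- ligand
    out$atoms$x <- best_coords[, 1]
    out$atoms$y <- best_coords[, 2]
    out$atoms$z <- best_coords[, 3]
    res <- list(no_pose = FALSE, pose = out, score = best_score,
                n_sampled = n_samples, n_passed_constraints = n_passed,
                seed = seed)
  }
  structure(res, class = "dock_result")
}

#' @export
print.dock_result <- function(x, ...) {
  if (x$no_pose) {
    cat(sprintf("Docking: NO_POSE (%d/%d placements passed constraints)\n",
                x$n_passed_constraints, x$n_sampled))
  } else {
    cat(sprintf("Docking: score %.2f kcal/mol (%d/%d placements passed)\n",
                x$score, x$n_passed_constraints, x$n_sampled))
  }
  invisible(x)
}
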