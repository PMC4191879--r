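make_pose <- function(xyz, names = paste0("C", seq_len(nrow(xyz))),
                      charge = 0) {
  terpchannel:::new_pose(data.frame(
    name = names, element = sub("[0-9]+$", "", names),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, nrow(xyz)), stringsAsFactors = FALSE))
}

test_that("mol2 poses round-trip coordinates and charges exactly", {
  f <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "toy", "3 2 0 0 0", "SMALL",
               "USER_CHARGES", "@<TRIPOS>ATOM",
               "1 C1  0.0000  0.0000 0.0000 C.3 1 LIG  0.910000",
               "2 C2  1.5000  0.0000 0.0000 C.3 1 LIG  0.030000",
               "3 O1  2.1000  1.2000 0.3000 O.3 1 LIG -0.400000",
               "@<TRIPOS>BOND", "1 1 2 1", "2 2 3 1"), f)
  p <- read_pose(f)
  expect_equal(p$atoms$name, c("C1", "C2", "O1"))
  expect_equal(p$atoms$element, c("C", "C", "O"))
  expect_equal(p$atoms$x, c(0, 1.5, 2.1))
  expect_equal(p$atoms$charge, c(0.91, 0.03, -0.4))
  expect_equal(nrow(p$bonds), 2)

  f2 <- withr::local_tempfile(fileext = ".mol2")
  write_pose_mol2(p, f2)
  p2 <- read_pose(f2)
  expect_equal(p2$atoms$x, p$atoms$x)
  expect_equal(p2$atoms$y, p$atoms$y)
  expect_equal(p2$atoms$z, p$atoms$z)
  expect_equal(p2$atoms$charge, p$atoms$charge)
})

test_that("the same molecule reads identically from mol2 and SDF", {
  xyz <- matrix(c(0, 0, 0, 1.54, 0, 0, 2.1, 1.2, 0.3), 3, 3, byrow = TRUE)
  fm <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "m", "3 0 0 0 0", "SMALL", "NO_CHARGES",
               "@<TRIPOS>ATOM",
               sprintf("%d C%d %.4f %.4f %.4f C.3", 1:3, 1:3,
                       xyz[, 1], xyz[, 2], xyz[, 3])), fm)
  fs <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("m", "  toy", "",
               "  3  0  0  0  0  0  0  0  0  0999 V2000",
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       xyz[, 1], xyz[, 2], xyz[, 3], "C"),
               "M  END", "$$$$"), fs)
  pm <- read_pose(fm); ps <- read_pose(fs)
  expect_equal(coords_of(pm), coords_of(ps), ignore_attr = TRUE)
})

test_that("PDB reader agrees with bio3d on a minimal HETATM block", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  C1  LIG A   1      11.104  13.207   9.345  1.00  0.00           C",
    "HETATM    2  C2  LIG A   1      12.592  13.500   9.470  1.00  0.00           C",
    "HETATM    3  O1  LIG A   1      13.301  12.345  10.001  1.00  0.00           O",
    "END"), f)
  p <- read_pose(f)
  expect_equal(p$atoms$name, c("C1", "C2", "O1"))
  expect_equal(p$atoms$x, c(11.104, 12.592, 13.301))
  ref <- bio3d::read.pdb(f)
  expect_equal(p$atoms$x, ref$atom$x)
  expect_equal(p$atoms$y, ref$atom$y)
  expect_equal(p$atoms$z, ref$atom$z)
  expect_equal(p$atoms$element, ref$atom$elesy)
})

test_that("malformed pose records report the offending line", {
  f <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "bad", "1 0", "SMALL", "NO_CHARGES",
               "@<TRIPOS>ATOM", "1 C1 oops 0.0 0.0 C.3"), f)
  expect_error(read_pose(f), "line 7")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("HETATM    1  C1  LIG A   1      11.104", f2)
  expect_error(read_pose(f2), "line 1")
})

test_that("dihedral matches textbook trans/cis and the independent oracle", {
  # butane-like backbones in a plane
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)), 180)
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0)

  set.seed(8)
  for (k in 1:1000) {
    pts <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    got <- tryCatch(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                    error = function(e) NA)
    if (is.na(got)) next
    want <- oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    d <- abs(got - want)
    expect_lt(min(d, 360 - d), 1e-9)
  }

  # degenerate input refuses
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "degenerate")
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral symmetries and rigid-motion invariance hold", {
  set.seed(9)
  for (k in 1:200) {
    pts <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    got <- tryCatch(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                    error = function(e) NA)
    if (is.na(got)) next
    # reading the four atoms in reverse order leaves the torsion unchanged
    rev <- dihedral(pts[4, ], pts[3, ], pts[2, ], pts[1, ])
    expect_equal(rev, got, tolerance = 1e-9)
    # mirror reflection negates the torsion (away from the 180 branch cut)
    if (abs(abs(got) - 180) > 1e-6) {
      mir <- pts; mir[, 3] <- -mir[, 3]
      expect_equal(dihedral(mir[1, ], mir[2, ], mir[3, ], mir[4, ]),
                   -got, tolerance = 1e-9)
    }
    R <- random_rotation_matrix()
    tr <- stats::rnorm(3)
    moved <- sweep(pts %*% t(R), 2, tr, `+`)
    expect_equal(dihedral(moved[1, ], moved[2, ], moved[3, ], moved[4, ]),
                 got, tolerance = 1e-8)
  }
})

test_that("conformer classification follows the torsion sign rule", {
  # +60 degree torsion built by construction: A-like fold
  phi <- 60 * pi / 180
  xyz <- rbind(c(cos(phi), sin(phi), 1),   # C16
               c(0, 0, 1),                 # C17  (wait: order is p1..p4)
               c(0, 0, 0),                 # C18
               c(1, 0, 0))                 # H18
  # dihedral(p1,p2,p3,p4) with axis p2->p3 along -z
  pose <- make_pose(xyz, names = c("C16", "C17", "C18", "H18"))
  call <- classify_conformer(pose)
  expect_equal(abs(call$phi), 60, tolerance = 1e-6)
  expect_false(call$refused)
  expect_equal(call$class, if (call$phi > 0) "A_like" else "BC_like")

  # mirror image flips chirality, negates the torsion, flips the call
  xyz_m <- xyz; xyz_m[, 3] <- -xyz_m[, 3]
  call_m <- classify_conformer(make_pose(xyz_m,
                                         names = c("C16", "C17", "C18", "H18")))
  expect_equal(call_m$phi, -call$phi, tolerance = 1e-9)
  expect_false(call_m$class == call$class)

  # random poses: classification equals the sign of the oracle dihedral
  set.seed(10)
  for (k in 1:100) {
    pts <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    want <- tryCatch(oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                     error = function(e) NA)
    if (is.na(want) || abs(want) < 1 || abs(abs(want) - 180) < 1) next
    cl <- classify_conformer(make_pose(pts, c("C16", "C17", "C18", "H18")))
    expect_equal(cl$class, if (want > 0) "A_like" else "BC_like")
  }

  # near-planar torsions are refused
  flat <- rbind(c(1, 1e-4, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1e-4, 0))
  cl <- classify_conformer(make_pose(flat, c("C16", "C17", "C18", "H18")))
  expect_true(cl$refused)
  expect_true(is.na(cl$class))
})

test_that("RMSD handles identity, rigid shifts, and matches the Horn oracle", {
  xyz <- matrix(stats::rnorm(15), 5, 3)
  a <- make_pose(xyz)
  expect_equal(rmsd(a, a), 0)

  b <- make_pose(sweep(xyz, 2, c(1, 0, 0), `+`))
  expect_equal(rmsd(a, b, fit = "in_place"), 1)
  expect_equal(rmsd(a, b, fit = "kabsch"), 0, tolerance = 1e-8)

  set.seed(11)
  for (k in 1:200) {
    n <- sample(3:12, 1)
    A <- matrix(stats::rnorm(3 * n, sd = 2), n, 3)
    B <- matrix(stats::rnorm(3 * n, sd = 2), n, 3)
    got <- rmsd(A, B, fit = "kabsch")
    expect_equal(got, oracle_kabsch_rmsd(A, B), tolerance = 1e-8)
    # kabsch never exceeds in-place; rmsd is symmetric
    expect_lte(got, rmsd(A, B, fit = "in_place") + 1e-12)
    expect_equal(got, rmsd(B, A, fit = "kabsch"), tolerance = 1e-8)
  }

  expect_error(rmsd(A[0, , drop = FALSE], B[0, , drop = FALSE]), "non-empty")
  expect_error(rmsd(A[1:2, ], B[1:2, ], fit = "kabsch"), "at least 3")
})

test_that("core restraint is inclusive at the tolerance", {
  ref <- matrix(stats::rnorm(9), 3, 3)
  # displace all atoms by exactly 1.0 along x: in-place RMSD 1.0 -> pass
  shifted <- sweep(ref, 2, c(1, 0, 0), `+`)
  chk <- check_core_restraint(shifted, ref, tolerance = 1.0)
  expect_true(chk)
  expect_equal(attr(chk, "rmsd"), 1.0)
  # 0.42 A passes, 1.5 A fails
  expect_true(check_core_restraint(sweep(ref, 2, c(0.42, 0, 0), `+`), ref))
  expect_false(check_core_restraint(sweep(ref, 2, c(1.5, 0, 0), `+`), ref))
})

test_that("correspondence files parse with comments and validate shape", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# ligand -> crystal", "C1 C1", "C2 C2a", "", "O1 O1  # ether"),
             f)
  m <- read_correspondence(f)
  expect_equal(nrow(m), 3)
  expect_equal(m[2, ], c(a = "C2", b = "C2a"))
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("C1 C2 C3", f2)
  expect_error(read_correspondence(f2), "two atom names")
})
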