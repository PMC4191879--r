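#' Specification for synthetic docking-score profiles
#'
#' Describes the statistical shape of simulated per-enzyme docking-score
#' profiles: the planted (true) channel's representative intermediates
#' score `representative_gap` kcal/mol better than the other channels',
#' and along the planted channel the profile follows the characteristic
#' empirical pattern of sterol-channel enzymes: a highly favorable I1, a
#' strongly penalized I2, scores improving steadily from I3 down to a
#' minimum at the product-precursor index, a rise past the precursor, and
#' failed dockings (NO_POSE) at stated downstream indices.  Gaussian
#' noise of spread `noise` is added independently to every score; the
#' channel-discrimination conditions of interest are a representative gap
#' of 3 kcal/mol against 1 kcal/mol of noise.
#'
#' @param planted_channel Channel label each enzyme truly follows
#'   (recycled over enzymes), default `"C"`.
#' @param representative_gap Gap g in kcal/mol (default 3).
#' @param noise Gaussian noise sigma in kcal/mol (default 1).
#' @param precursor_index Index of the planted score minimum (default:
#'   6 for channel C, channel length otherwise).
#' @param downstream_nonbinder_indices Indices drawn as NO_POSE (default:
#'   8 for channel C, none otherwise).
#' @param n_enzymes Number of enzymes to simulate.
#' @param seed Integer seed.
#' @return A `profile_spec` list.
#' @export
profile_spec <- function(planted_channel = "C", representative_gap = 3,
                         noise = 1, precursor_index = NULL,
                         downstream_nonbinder_indices = NULL,
                         n_enzymes = 100, seed = 1) {
  stopifnot(representative_gap > 0, noise >= 0, n_enzymes >= 1)
  structure(list(planted_channel = planted_channel,
                 representative_gap = representative_gap, noise = noise,
                 precursor_index = precursor_index,
                 downstream_nonbinder_indices = downstream_nonbinder_indices,
                 n_enzymes = n_enzymes, seed = seed),
            class = "profile_spec")
}

# mean score of intermediate `i` along a planted channel of length `len`
# with its precursor minimum at `prec`
profile_mean <- function(i, len, prec) {
  if (i == 1) return(-80)
  if (i == 2) return(-45)
  if (i <= prec) {
    if (prec == 3) return(-62)
    return(-48 + (i - 3) / (prec - 3) * (-62 - -48))
  }
  -62 + 8 * (i - prec)
}

#' Generate synthetic score profiles with a planted channel
#'
#' Draws a [score_table][read_scores_csv] for `n_enzymes` simulated
#' enzymes under a [profile_spec()]: representative intermediates (I1,
#' I2) for every enabled channel, plus the full intermediate profile
#' along each enzyme's planted channel.  Deterministic given the seed
#' carried by `spec`.
#'
#' @param spec A [profile_spec()].
#' @param lib A [channel_library][read_channel_library].
#' @return List with `scores` (a `score_table`) and `truth` (data frame
#'   `enzyme`, `channel`).
#' @examples
#' sim <- gen_profiles(profile_spec(n_enzymes = 3, seed = 7),
#'                     default_channel_library())
#' head(sim$scores)
#' @export
gen_profiles <- function(spec, lib) {
  stopifnot(inherits(spec, "profile_spec"), inherits(lib, "channel_library"))
  chans <- enabled_channels(lib)
  planted <- rep_len(spec$planted_channel, spec$n_enzymes)
  if (!all(planted %in% chans)) stop("planted channel not enabled in library")
  g <- spec$representative_gap
  sig <- spec$noise

  rows <- with_seed(spec$seed, {
    out <- vector("list", spec$n_enzymes)
    for (e in seq_len(spec$n_enzymes)) {
      enz <- sprintf("SYN%04d", e)
      pch <- planted[e]
      ints <- channel_intermediates(lib, pch)
      len <- nrow(ints)
      prec <- spec$precursor_index
      if (is.null(prec)) prec <- if (pch == "C") 6L else len
      if (prec < 1 || prec > len) stop("precursor_index outside channel length")
      nb <- spec$downstream_nonbinder_indices
      if (is.null(nb)) nb <- if (pch == "C") 8L else integer()
      nb <- nb[nb > 2 & nb <= len]

      ids <- character(); sc <- numeric()
      # full planted-channel profile
      for (i in seq_len(len)) {
        ids <- c(ids, ints$id[i])
        sc <- c(sc, if (i %in% nb) NA_real_
                else profile_mean(i, len, prec) + stats::rnorm(1, 0, sig))
      }
      # representatives of the other channels, g worse on average
      for (ch in setdiff(chans, pch)) {
        for (r in 1:2) {
          ids <- c(ids, representative(lib, ch, r))
          sc <- c(sc, profile_mean(r, 2, 2) + g + stats::rnorm(1, 0, sig))
        }
      }
      out[[e]] <- data.frame(enzyme = enz, intermediate = ids, score = sc,
                             stringsAsFactors = FALSE)
    }
    out
  })
  df <- do.call(rbind, rows)
  list(scores = score_table(df$enzyme, df$intermediate, df$score),
       truth = data.frame(enzyme = sprintf("SYN%04d", seq_len(spec$n_enzymes)),
                          channel = planted, stringsAsFactors = FALSE))
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

mutate_seq <- function(s, n_mut) {
  if (n_mut == 0) return(s)
  pos <- sample(length(s), n_mut)
  s[pos] <- vapply(s[pos], function(old) sample(setdiff(AA20, old), 1), "")
  s
}

#' Generate protein families with controlled divergence
#'
#' Builds `n_families` families of `members` sequences each by seeded
#' point mutation (no indels): family ancestors diverge from a common
#' root so that between-family pairs hit `between_identity` percent, and
#' members diverge from their ancestor so that within-family pairs hit
#' `within_identity` percent (both within about +/- 2 points for
#' realistic lengths).  Families are annotated with reaction-channel
#' labels cycling A-D, for use in network segregation tests.
#'
#' @param n_families,members Counts.
#' @param within_identity,between_identity Target pairwise percent
#'   identities; must satisfy `within > between`, and `between` must be
#'   above the random-alignment baseline (~6 percent).
#' @param length Sequence length (default 300).
#' @param seed Integer seed.
#' @return List with `seqs` (named character vector) and `annotations`
#'   (data frame `id`, `channel`, `ec`).
#' @export
gen_sequences <- function(n_families, members, within_identity = 90,
                          between_identity = 25, length = 300, seed = 1) {
  if (within_identity <= between_identity) {
    stop("infeasible: within_identity must exceed between_identity")
  }
  if (between_identity < 6 || within_identity > 100) {
    stop("infeasible identity targets")
  }
  p <- 1 - sqrt(between_identity / 100)   # ancestor divergence from root
  q <- 1 - sqrt(within_identity / 100)    # member divergence from ancestor
  with_seed(seed, {
    root <- sample(AA20, length, replace = TRUE)
    seqs <- character(); ids <- character(); fams <- integer()
    for (f in seq_len(n_families)) {
      anc <- mutate_seq(root, round(p * length))
      for (m in seq_len(members)) {
        ids <- c(ids, sprintf("fam%d_m%d", f, m))
        fams <- c(fams, f)
        seqs <- c(seqs, paste(mutate_seq(anc, round(q * length)),
                              collapse = ""))
      }
    }
    names(seqs) <- ids
    ann <- data.frame(id = ids,
                      channel = c("A", "B", "C", "D")[(fams - 1) %% 4 + 1],
                      ec = "", stringsAsFactors = FALSE)
    list(seqs = seqs, annotations = ann)
  })
}

#' Write sequences as FASTA and annotations as TSV
#'
#' @param sim A [gen_sequences()] result.
#' @param fasta_path,annot_path Output files.
#' @return Invisibly, the two paths.
#' @export
write_sequence_fixtures <- function(sim, fasta_path, annot_path) {
  set <- Biostrings::AAStringSet(sim$seqs)
  Biostrings::writeXStringSet(set, fasta_path)
  utils::write.table(sim$annotations, annot_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, annot_path))
}

#' Generate a toy receptor-carbocation complex with a planted pose
#'
#' Builds a compact 4-bead cationic ligand and a pocket of 10-30
#' Lennard-Jones sites complementary to it: one anionic anchor site
#' facing the cation head (the catalytic-aspartate stand-in) and neutral
#' to weakly negative sites placed at their LJ-optimal distance from
#' randomly chosen ligand beads.  The ligand is returned in its planted
#' pose, which satisfies the anchor and core constraints of [dock()] and
#' sits at a deep score minimum.
#'
#' @param seed Integer seed.
#' @param n_sites Number of pocket sites including the anchor (10-30).
#' @return List with `receptor` (a [toy_receptor()]), `ligand` (a `pose`
#'   in the planted placement), `planted` (coordinate matrix) and
#'   `core_reference` (alias of `planted`, for [dock()]).
#' @export
gen_toy_complex <- function(seed = 1, n_sites = 14) {
  stopifnot(n_sites >= 10, n_sites <= 30)
  with_seed(seed, {
    # tetrahedral 4-bead cation, head bead carries most of the +1 charge
    d <- 1.5
    lig_xyz <- rbind(c(0, 0, 0),
                     c(d, d, d) / sqrt(3),
                     c(d, -d, -d) / sqrt(3),
                     c(-d, d, -d) / sqrt(3))
    atoms <- data.frame(name = c("CAT1", "C2", "C3", "C4"),
                        element = "C",
                        x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
                        charge = c(0.91, 0.03, 0.03, 0.03),
                        stringsAsFactors = FALSE)
    ligand <- new_pose(atoms, frame_note = "planted toy pose")

    anchor_rmin <- 1.0
    anchor_dir <- c(-1, -1, 1) / sqrt(3)        # away from the tail beads
    anchor_pos <- anchor_dir * (anchor_rmin + LIG_RMIN)
    sites <- data.frame(x = anchor_pos[1], y = anchor_pos[2], z = anchor_pos[3],
                        charge = -1.0, rmin = anchor_rmin, eps = 0.2)
    while (nrow(sites) < n_sites) {
      b <- sample(nrow(lig_xyz), 1)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      rmin <- stats::runif(1, 1.1, 1.5)
      pos <- lig_xyz[b, ] + u * (rmin + LIG_RMIN)
      dmin <- sqrt(min(rowSums(sweep(lig_xyz, 2, pos)^2)))
      if (dmin < 0.95 * (rmin + LIG_RMIN)) next   # would poke into the ligand
      dsite <- if (nrow(sites) == 0) Inf else
        sqrt(min(rowSums(sweep(as.matrix(sites[, c("x", "y", "z")]), 2, pos)^2)))
      if (dsite < 1.5) next
      sites <- rbind(sites, data.frame(x = pos[1], y = pos[2], z = pos[3],
                                       charge = stats::runif(1, -0.1, 0),
                                       rmin = rmin, eps = 0.15))
    }
    receptor <- toy_receptor(sites, anchor_site = 1L)
    # relax the constructed pose to the pocket's actual local optimum, so
    # the planted pose is a genuine score minimum
    relaxed <- rigid_refine(receptor, ligand, lig_xyz)
    ligand$atoms$x <- relaxed$coords[, 1]
    ligand$atoms$y <- relaxed$coords[, 2]
    ligand$atoms$z <- relaxed$coords[, 3]
    list(receptor = receptor, ligand = ligand, planted = relaxed$coords,
         core_reference = relaxed$coords)
  })
}
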