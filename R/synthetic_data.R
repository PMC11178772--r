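# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a sequence with planted cleavage sites
#'
#' The background alphabet excludes every residue allowed at P1' by any
#' source of the model, so no background position can ever be a site.
#' Each planted window is an 8-mer (P4..P4') whose constrained positions
#' are drawn uniformly from the chosen source's allowed sets
#' (unconstrained positions from the background). Because octamers drawn
#' this way can create accidental matches at other offsets, the
#' generator redraws (seeded, bounded) until a scan finds exactly the
#' planted sites.
#'
#' @param length sequence length.
#' @param plant_positions P1 positions of the planted sites, in the
#'   numbering defined by `start_number`.
#' @param model a `specificity_model` (default bundled actinidin).
#' @param seed RNG seed.
#' @param source evidence source drawn from, recycled per plant.
#' @param p1_res,p1prime_res optional fixed P1/P1' residues per plant
#'   (must belong to the source's sets).
#' @param start_number author number of the first residue (default 1),
#'   so sites can be planted at author-numbered positions without
#'   generating the full-length chain.
#' @return one-row sequence tibble (`id`, `seq`, `numbering`, `breaks`)
#'   compatible with [scan_sequence()].
#' @export
gen_sequence <- function(length, plant_positions = integer(),
                         model = load_specificity(), seed = 1,
                         source = names(model$sources)[which.max(lengths(model$sources))],
                         p1_res = NULL, p1prime_res = NULL,
                         start_number = 1L) {
  numbering <- seq.int(start_number, start_number + length - 1L)
  idx <- match(plant_positions, numbering)
  if (anyNA(idx)) abort("planted position outside the sequence")
  if (any(idx < 4L | idx > length - 4L)) {
    abort("planted window (P4..P4') does not fit within the sequence")
  }
  if (length(idx) > 1) {
    o <- order(idx)
    if (any(diff(idx[o]) < 8L)) abort("planted windows overlap")
  }
  source <- rep_len(source, length(idx))
  if (!is.null(p1_res)) p1_res <- rep_len(p1_res, length(idx))
  if (!is.null(p1prime_res)) p1prime_res <- rep_len(p1prime_res, length(idx))
  p1_union <- unique(unlist(lapply(model$sources, `[[`, "P1'")))
  background <- setdiff(AA_LETTERS, p1_union)
  for (k in seq_along(idx)) {
    src <- model$sources[[source[k]]]
    if (!is.null(p1_res) && !p1_res[k] %in% src$P1) {
      abort(paste0("p1_res '", p1_res[k], "' not allowed by source ", source[k]))
    }
    if (!is.null(p1prime_res) && !p1prime_res[k] %in% src[["P1'"]]) {
      abort(paste0("p1prime_res '", p1prime_res[k], "' not allowed by source ",
                   source[k]))
    }
  }
  with_seed(seed, {
    for (try in 1:1000) {
      res <- sample(background, length, replace = TRUE)
      for (k in seq_along(idx)) {
        src <- model$sources[[source[k]]]
        for (tag in POSITION_TAGS) {
          j <- idx[k] + POSITION_OFFSETS[[tag]]
          pool <- src[[tag]] %||% background
          res[j] <- sample(pool, 1)
        }
        if (!is.null(p1_res)) res[idx[k]] <- p1_res[k]
        if (!is.null(p1prime_res)) res[idx[k] + 1L] <- p1prime_res[k]
      }
      out <- tibble(id = paste0("synthetic_", seed), seq = paste(res, collapse = ""),
                    numbering = list(numbering), breaks = list(integer()))
      found <- scan_sequence(out, model)
      if (identical(sort(found$p1_pos), sort(as.integer(plant_positions)))) {
        return(out)
      }
    }
    abort("could not realise the requested plants in 1000 attempts")
  })
}

# NeRF atom placement: D such that |CD| = r, angle(B,C,D) = theta_deg and
# dihedral(A,B,C,D) = chi_deg under the package's sign convention
place_atom <- function(A, B, C, r, theta_deg, chi_deg) {
  th <- theta_deg * pi / 180
  ch <- chi_deg * pi / 180
  bc <- unit(C - B)
  ab <- unit(B - A)
  n <- unit(cross3(ab, bc))
  m <- cross3(n, bc)
  d_local <- r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  as.numeric(C + cbind(bc, m, n) %*% d_local)
}

#' Ideal-geometry polypeptide backbone
#'
#' Backbone-only chain (N, CA, C per residue, poly-alanine labels) built
#' with standard bond geometry: N-CA 1.458, CA-C 1.525, C-N 1.329
#' Angstrom; angles N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7 degrees.
#' All interior residues have exactly the requested (phi, psi); the
#' peptide bond torsion is `omega`.
#'
#' @param n_res number of residues (>= 3).
#' @param phi,psi backbone torsions, degrees.
#' @param omega peptide-bond torsion, degrees (default 180, trans).
#' @param chain chain id.
#' @return single-model atom tibble.
#' @export
gen_polypeptide <- function(n_res, phi, psi, omega = 180, chain = "A") {
  if (n_res < 3) abort("n_res must be >= 3")
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7
  coords <- vector("list", 3L * n_res)
  a <- 111.2 * pi / 180
  N1 <- c(0, 0, 0)
  CA1 <- c(b_nca, 0, 0)
  C1 <- CA1 + b_cac * c(-cos(a), sin(a), 0)
  coords[[1]] <- N1; coords[[2]] <- CA1; coords[[3]] <- C1
  for (i in 2:n_res) {
    Np <- coords[[3 * (i - 2) + 1]]
    CAp <- coords[[3 * (i - 2) + 2]]
    Cp <- coords[[3 * (i - 2) + 3]]
    Ni <- place_atom(Np, CAp, Cp, b_cn, a_cacn, psi)
    CAi <- place_atom(CAp, Cp, Ni, b_nca, a_cnca, omega)
    Ci <- place_atom(Cp, Ni, CAi, b_cac, a_ncac, phi)
    coords[[3 * (i - 1) + 1]] <- Ni
    coords[[3 * (i - 1) + 2]] <- CAi
    coords[[3 * (i - 1) + 3]] <- Ci
  }
  xyz <- do.call(rbind, coords)
  nm <- rep(c("N", "CA", "C"), n_res)
  structure(tibble(
    model = 1L,
    serial = seq_len(3L * n_res),
    name = nm,
    alt = " ",
    res_name = "ALA",
    chain = chain,
    res_seq = rep(seq_len(n_res), each = 3L),
    ins = " ",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = rep(c("N", "C", "C"), n_res),
    hetero = FALSE
  ), id = "polypeptide", class = c("pdb_tbl", "tbl_df", "tbl", "data.frame"))
}

new_atom_row <- function(serial, name, res_name, chain, res_seq, xyz, element,
                         model = 1L) {
  tibble(model = as.integer(model), serial = as.integer(serial), name = name,
         alt = " ", res_name = res_name, chain = chain,
         res_seq = as.integer(res_seq), ins = " ",
         x = xyz[1], y = xyz[2], z = xyz[3], element = element, hetero = FALSE)
}

#' Minimal enzyme-peptide pose with a planted SG-C distance
#'
#' A deliberately minimal complex: enzyme chain with the catalytic triad
#' key atoms (Cys25 SG, His162 NE2, Asn182 OD1) and a two-residue
#' peptide whose P1 carbonyl carbon sits exactly `sg_c` Angstrom from
#' the SG along x. Geometry is schematic, sufficient for distance-based
#' screening, not a physical structure.
#'
#' @param sg_c planted nucleophile-to-carbonyl distance, Angstrom.
#' @param enzyme_chain,peptide_chain chain ids (defaults match
#'   [catalytic_spec()]).
#' @return single-model atom tibble.
#' @export
gen_pose <- function(sg_c, enzyme_chain = "E", peptide_chain = "P") {
  rows <- bind_rows(
    new_atom_row(1, "N", "CYS", enzyme_chain, 25, c(-2.9, 1.2, 0), "N"),
    new_atom_row(2, "CA", "CYS", enzyme_chain, 25, c(-2.4, 0, 0.6), "C"),
    new_atom_row(3, "CB", "CYS", enzyme_chain, 25, c(-1.4, -0.5, -0.4), "C"),
    new_atom_row(4, "SG", "CYS", enzyme_chain, 25, c(0, 0, 0), "S"),
    new_atom_row(5, "CA", "HIS", enzyme_chain, 162, c(-3.0, 4.0, 1.0), "C"),
    new_atom_row(6, "NE2", "HIS", enzyme_chain, 162, c(-1.2, 3.4, 0.8), "N"),
    new_atom_row(7, "CA", "ASN", enzyme_chain, 182, c(-4.5, 5.5, 0.5), "C"),
    new_atom_row(8, "OD1", "ASN", enzyme_chain, 182, c(-3.0, 5.8, 0.2), "O"),
    new_atom_row(9, "CA", "GLY", peptide_chain, 1, c(sg_c + 1.5, 0.2, 0), "C"),
    new_atom_row(10, "C", "GLY", peptide_chain, 1, c(sg_c, 0, 0), "C"),
    new_atom_row(11, "O", "GLY", peptide_chain, 1, c(sg_c + 0.4, -1.1, 0.3), "O"),
    new_atom_row(12, "N", "GLY", peptide_chain, 2, c(sg_c + 0.7, 1.1, -0.4), "N"),
    new_atom_row(13, "CA", "GLY", peptide_chain, 2, c(sg_c + 2.1, 1.4, -0.6), "C")
  )
  structure(rows, id = "synthetic_pose",
            class = c("pdb_tbl", class(tibble())))
}

#' Normal SG-C profile with target quartiles
#'
#' Draws per-frame distances from a normal distribution whose
#' theoretical quartiles are (`q1`, `q3`).
#'
#' @param n_frames frames.
#' @param q1,q3 target lower/upper quartiles, Angstrom.
#' @param seed RNG seed.
#' @return numeric vector of length `n_frames`.
#' @export
sgc_profile_quartiles <- function(n_frames, q1, q3, seed = 1) {
  m <- (q1 + q3) / 2
  s <- (q3 - q1) / (2 * stats::qnorm(0.75))
  with_seed(seed, stats::rnorm(n_frames, m, s))
}

#' Synthetic enzyme-peptide trajectory
#'
#' Multi-frame complex with planted, recoverable analysis targets:
#' the per-frame SG-C distance follows `sg_c_profile` (+ Gaussian noise
#' `noise_sigma`), exactly `n_hbonds` donor-acceptor pairs per frame
#' satisfy ideal hydrogen-bond geometry (D-A 2.9 Angstrom, H-D-A 0
#' degrees; the remaining acceptors are far), and optional
#' `peptide_drift` applies a cumulative random walk to peptide body
#' atoms so the peptide RMSD grows while the enzyme stays put.
#'
#' @param n_frames number of frames (>= 2).
#' @param sg_c_profile scalar or per-frame vector of planted SG-C
#'   distances, Angstrom.
#' @param n_hbonds scalar or per-frame vector of planted hydrogen bonds
#'   (<= `n_acceptors`).
#' @param noise_sigma Gaussian noise on the SG-C distance, Angstrom.
#' @param peptide_drift per-frame random-walk step (Angstrom) for the
#'   peptide body atoms; 0 keeps the peptide rigid.
#' @param n_donors,n_acceptors sizes of the donor (enzyme) and acceptor
#'   (peptide) sets.
#' @param seed RNG seed.
#' @return multi-model atom tibble. Donors are enzyme backbone N atoms
#'   (residues 101...), each with an amide H; acceptors are peptide O
#'   atoms (residues 11...); body atoms are peptide CB (residues 51...).
#' @export
gen_trajectory <- function(n_frames, sg_c_profile = 4.0, n_hbonds = 3,
                           noise_sigma = 0, peptide_drift = 0,
                           n_donors = 12L, n_acceptors = 12L, seed = 1) {
  if (n_frames < 2) abort("n_frames must be >= 2")
  prof <- rep_len(sg_c_profile, n_frames)
  if (length(sg_c_profile) > 1 && length(sg_c_profile) != n_frames) {
    abort("sg_c_profile length must be 1 or n_frames")
  }
  k <- rep_len(as.integer(n_hbonds), n_frames)
  if (any(k > n_acceptors) || any(k > n_donors)) {
    abort("n_hbonds cannot exceed the donor/acceptor set size")
  }
  ec <- "E"; pc <- "P"
  donor_y <- 5 * seq_len(n_donors)
  template <- bind_rows(
    new_atom_row(1, "N", "CYS", ec, 25, c(-2.9, 1.2, 0), "N"),
    new_atom_row(2, "CA", "CYS", ec, 25, c(-2.4, 0, 0.6), "C"),
    new_atom_row(3, "SG", "CYS", ec, 25, c(0, 0, 0), "S"),
    new_atom_row(4, "CA", "HIS", ec, 162, c(-3.0, 4.0, 1.0), "C"),
    new_atom_row(5, "NE2", "HIS", ec, 162, c(-1.2, 3.4, 0.8), "N"),
    new_atom_row(6, "CA", "ASN", ec, 182, c(-4.5, 5.5, 0.5), "C"),
    new_atom_row(7, "OD1", "ASN", ec, 182, c(-3.0, 5.8, 0.2), "O"),
    # donor amide N + H, enzyme side
    purrr::map_dfr(seq_len(n_donors), function(i) bind_rows(
      new_atom_row(100 + 2 * i, "N", "GLY", ec, 100 + i, c(0, donor_y[i], 8), "N"),
      new_atom_row(101 + 2 * i, "H", "GLY", ec, 100 + i, c(0, donor_y[i], 9), "H")
    )),
    # peptide: scissile carbonyl + CA
    new_atom_row(500, "C", "GLY", pc, 1, c(4, 0, 0), "C"),
    new_atom_row(501, "CA", "GLY", pc, 1, c(5.5, 0.2, 0), "C"),
    # acceptor carbonyl O atoms, peptide side
    purrr::map_dfr(seq_len(n_acceptors), function(i)
      new_atom_row(600 + i, "O", "GLY", pc, 10 + i, c(0, donor_y[i], 30), "O")),
    # peptide body atoms (drift targets)
    purrr::map_dfr(1:5, function(i)
      new_atom_row(700 + i, "CB", "ALA", pc, 50 + i,
                   c(8 + i, -4 + 1.5 * (i %% 2), 2 * i), "C"))
  )
  nt <- nrow(template)
  full <- template[rep(seq_len(nt), n_frames), ]
  full$model <- rep(seq_len(n_frames), each = nt)

  with_seed(seed, {
    sgc <- prof + if (noise_sigma > 0) stats::rnorm(n_frames, 0, noise_sigma) else 0
    sgc <- pmax(sgc, 0.5)
    # scissile carbon (and CA, kept 1.5 A beyond) along x
    is_c <- full$chain == pc & full$res_seq == 1 & full$name == "C"
    is_ca <- full$chain == pc & full$res_seq == 1 & full$name == "CA"
    full$x[is_c] <- sgc
    full$x[is_ca] <- sgc + 1.5
    # acceptor i is bonded (z = 10.9, i.e. 2.9 above its donor) in frame t
    # iff i <= k_t, else far (z = 30)
    acc <- full$chain == pc & full$name == "O"
    acc_i <- full$res_seq[acc] - 10L
    acc_frame <- full$model[acc]
    full$z[acc] <- ifelse(acc_i <= k[acc_frame], 8 + 2.9, 30)
    if (peptide_drift > 0) {
      body <- full$chain == pc & full$name == "CB"
      for (rs in 51:55) {
        sel <- body & full$res_seq == rs
        for (col in c("x", "y", "z")) {
          full[[col]][sel] <- full[[col]][sel] +
            cumsum(stats::rnorm(n_frames, 0, peptide_drift))
        }
      }
    }
  })
  structure(full, id = "synthetic_trajectory",
            class = c("pdb_tbl", class(tibble())))
}

#' Preset synthetic trajectories
#'
#' * `"good-pose"`: SG-C relaxing from 6 to a 4.0 Angstrom plateau,
#'   about 10 hydrogen bonds per frame - emulates a catalytically
#'   competent complex;
#' * `"bad-pose"`: the 7 Angstrom negative control - SG-C briefly dips
#'   then plateaus near 6 (quartiles around 5.5-6.4), 2 bonds per frame;
#' * `"stable"`: rigid complex, constant SG-C 4.0, no drift;
#' * `"relaxing-peptide"`: like `"stable"` but the peptide body atoms
#'   random-walk, so the peptide RMSD climbs while the enzyme's stays
#'   flat.
#'
#' @param preset preset name.
#' @param n_frames frames.
#' @param seed RNG seed.
#' @return multi-model atom tibble from [gen_trajectory()].
#' @export
traj_preset <- function(preset = c("good-pose", "bad-pose", "stable",
                                   "relaxing-peptide"),
                        n_frames = 200L, seed = 1) {
  preset <- match.arg(preset)
  relax <- function(from, to) {
    n0 <- max(2L, round(n_frames * 0.1))
    c(seq(from, to, length.out = n0), rep(to, n_frames - n0))
  }
  switch(preset,
    "good-pose" = gen_trajectory(n_frames, relax(6, 4), n_hbonds = 10,
                                 noise_sigma = 0.2, seed = seed),
    "bad-pose" = gen_trajectory(n_frames, relax(7, 5.95), n_hbonds = 2,
                                noise_sigma = 0.33, seed = seed),
    "stable" = gen_trajectory(n_frames, 4.0, n_hbonds = 5,
                              noise_sigma = 0.05, seed = seed),
    "relaxing-peptide" = gen_trajectory(n_frames, 4.0, n_hbonds = 5,
                                        noise_sigma = 0.05,
                                        peptide_drift = 0.4, seed = seed)
  )
}

#' Synthetic clot-lysis replicate table
#'
#' Emulates the whole-blood clot assay: initial dry weights uniform on
#' 0.10-0.15 g, per-replicate degradation percentages normal around the
#' planted group means, final weights back-computed under the chosen
#' convention, and (optionally) released-cell counts with 10%
#' coefficient of variation. Defaults mirror a dose-ordered assay in
#' triplicate: control ~12%, mid dose ~55%, high dose ~73%, replicate
#' standard deviation 2 percentage points.
#'
#' @param group_means named numeric vector of planted mean degradation
#'   percentages.
#' @param sigma replicate standard deviation, percentage points.
#' @param n replicates per group.
#' @param cells_means optional named vector (same names) of mean
#'   released-cell counts, cells/mL.
#' @param convention weight convention used to back-compute final
#'   weights (see [degradation_pct()]).
#' @param seed RNG seed.
#' @return tibble of clot records: `group`, `replicate`,
#'   `initial_weight`, `final_weight`, `released_cells`.
#' @export
gen_clot_table <- function(group_means = c(control = 12, dose_75 = 55,
                                           dose_100 = 73),
                           sigma = 2, n = 3L,
                           cells_means = NULL,
                           convention = "as_printed", seed = 1) {
  groups <- names(group_means)
  if (is.null(groups)) abort("group_means must be named")
  total <- length(groups) * n
  with_seed(seed, {
    initial <- stats::runif(total, 0.10, 0.15)
    pct <- rep(group_means, each = n) +
      if (sigma > 0) stats::rnorm(total, 0, sigma) else 0
    final <- if (convention == "as_printed") initial / (1 + pct / 100)
             else initial * (1 - pct / 100)
    cells <- if (!is.null(cells_means)) {
      mu <- rep(cells_means[groups], each = n)
      pmax(0, stats::rnorm(total, mu, 0.1 * mu))
    } else NA_real_
    tibble(
      group = rep(groups, each = n),
      replicate = rep(seq_len(n), times = length(groups)),
      initial_weight = initial,
      final_weight = final,
      released_cells = cells
    )
  })
}

#' Synthetic fibrin-like chains with the reported cleavage layout
#'
#' Stand-in sequences (not real fibrin) carrying cleavage sites at the
#' author-numbered positions reported for the three fibrin chains:
#' A-alpha P1 at 162 (Arg-Gly) and 171 (Arg-Glu), B-beta at 346
#' (Arg-Gly), gamma at 406 (Lys-Gln). Chain lengths are of the right
#' order for fibrin but the sequences themselves are random background,
#' so the site positions survive a plain FASTA round trip.
#'
#' @param model a `specificity_model`.
#' @param seed RNG seed.
#' @return three-row sequence tibble (ids `Aa_synthetic`,
#'   `Bb_synthetic`, `Gamma_synthetic`) for [scan_sequence()].
#' @export
gen_fibrin_chains <- function(model = load_specificity(), seed = 1) {
  aa <- gen_sequence(200, c(162, 171), model, seed = derive_seed(seed, 1),
                     source = c("kiwellin", "insulin"),
                     p1_res = c("R", "R"), p1prime_res = c("G", "E"))
  bb <- gen_sequence(380, 346, model, seed = derive_seed(seed, 2),
                     source = "kiwellin", p1_res = "R", p1prime_res = "G")
  gg <- gen_sequence(440, 406, model, seed = derive_seed(seed, 3),
                     source = "insulin", p1_res = "K", p1prime_res = "Q")
  aa$id <- "Aa_synthetic"; bb$id <- "Bb_synthetic"; gg$id <- "Gamma_synthetic"
  bind_rows(aa, bb, gg)
}

#' Synthetic actinidin-like sequence pair
#'
#' Two stand-in 218-residue sequences (not real actinidin) identical
#' except at position 101, where the first carries E and the second D -
#' the single-substitution layout used to exercise pairwise identity:
#' 217/218 = 99.5%.
#'
#' @param length sequence length (default 218, the mature-protease size).
#' @param mismatch_pos position of the single substitution.
#' @param seed RNG seed.
#' @return two-row tibble (`id`, `seq`).
#' @export
gen_actinidin_pair <- function(length = 218L, mismatch_pos = 101L, seed = 1) {
  if (mismatch_pos < 1 || mismatch_pos > length) {
    abort("mismatch_pos outside the sequence")
  }
  with_seed(seed, {
    base <- sample(AA_LETTERS, length, replace = TRUE)
    a <- base; a[mismatch_pos] <- "E"
    b <- base; b[mismatch_pos] <- "D"
    tibble(id = c("ADHact_synthetic", "AC1AEC_synthetic"),
           seq = c(paste(a, collapse = ""), paste(b, collapse = "")))
  })
}
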