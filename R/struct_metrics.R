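#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of paired point sets by the Kabsch/SVD
#' method, reflections excluded. The returned transform maps `mobile`
#' onto `target`: `y ~ x %*% t(rotation) + translation`.
#'
#' @param mobile,target n x 3 coordinate matrices (or atom tibbles),
#'   paired by row, n >= 3.
#' @return object of class `superposition`: `rmsd` (Angstrom),
#'   `rotation` (3 x 3, det +1), `translation`, `n_atoms`.
#' @export
kabsch_superpose <- function(mobile, target) {
  X <- if (is.data.frame(mobile)) coords_matrix(mobile) else as.matrix(mobile)
  Y <- if (is.data.frame(target)) coords_matrix(target) else as.matrix(target)
  if (nrow(X) != nrow(Y)) abort("mobile and target must pair the same atoms")
  if (nrow(X) < 3) abort("need at least 3 paired atoms")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv_x <- svd(Xc)$d; sv_y <- svd(Yc)$d
  if (sv_x[2] < 1e-8 * max(sv_x[1], 1) || sv_y[2] < 1e-8 * max(sv_y[1], 1)) {
    abort("degenerate (collinear) point set: rotation is not determined")
  }
  C <- crossprod(Xc, Yc)            # 3x3 covariance
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  structure(
    list(rmsd = rmsd, rotation = R,
         translation = as.numeric(cy - R %*% cx), n_atoms = nrow(X)),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A over %d atoms\n", x$rmsd, x$n_atoms))
  invisible(x)
}

#' Per-frame RMSD of a trajectory against a reference frame
#'
#' Each frame is least-squares fitted (Kabsch) to the reference model on
#' the selected atoms before the RMSD is taken on the same selection -
#' the usual molecular-dynamics convention; no mass weighting.
#'
#' @param traj multi-model atom tibble.
#' @param reference_model model number of the reference frame.
#' @param chain,name optional selection filters (e.g. backbone names).
#' @return tibble `frame`, `rmsd` (Angstrom), ordered by frame.
#' @export
rmsd_series <- function(traj, reference_model = min(traj$model),
                        chain = NULL, name = NULL) {
  sel <- atom_select(traj, chain = chain, name = name)
  if (nrow(sel) == 0) abort("selection matches no atoms")
  key <- function(d) paste(d$chain, d$res_seq, d$ins, d$name)
  ref <- sel[sel$model == reference_model, ]
  ref <- ref[order(key(ref)), ]
  frames <- sort(unique(sel$model))
  rms <- vapply(frames, function(m) {
    fr <- sel[sel$model == m, ]
    fr <- fr[order(key(fr)), ]
    if (nrow(fr) != nrow(ref) || !all(key(fr) == key(ref))) {
      missing <- setdiff(key(ref), key(fr))
      abort(sprintf("frame %d is missing selected atom(s): %s", m,
                    paste(utils::head(missing, 3), collapse = "; ")))
    }
    kabsch_superpose(coords_matrix(fr), coords_matrix(ref))$rmsd
  }, numeric(1))
  tibble(frame = frames, rmsd = rms)
}

#' Bundled Ramachandran region polygons
#'
#' Deliberately simple convex outlines around the alpha-helical and
#' beta-sheet basins plus a left-handed alpha patch; `favored` is the
#' tight outline, `allowed` a dilated one. These are bundled data, not
#' derived from any external contour set, and can be overridden via the
#' `regions` argument of [backbone_torsions()].
#'
#' @return list with `favored` and `allowed`, each a list of (phi, psi)
#'   polygon matrices in degrees.
#' @export
rama_default_regions <- function() {
  list(
    favored = list(
      alpha = cbind(phi = c(-100, -100, -35, -35), psi = c(-80, 0, 0, -80)),
      beta = cbind(phi = c(-180, -180, -45, -45), psi = c(80, 180, 180, 80)),
      alphaL = cbind(phi = c(40, 40, 80, 80), psi = c(0, 80, 80, 0))
    ),
    allowed = list(
      alpha = cbind(phi = c(-160, -160, -20, -20), psi = c(-110, 45, 45, -110)),
      beta = cbind(phi = c(-180, -180, -30, -30), psi = c(50, 180, 180, 50)),
      beta2 = cbind(phi = c(-180, -180, -45, -45), psi = c(-180, -160, -160, -180)),
      alphaL = cbind(phi = c(20, 20, 100, 100), psi = c(-20, 100, 100, -20))
    )
  )
}

point_in_polygon <- function(px, py, poly) {
  # even-odd ray casting
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

classify_rama <- function(phi, psi, regions) {
  if (is.na(phi) || is.na(psi)) return("undefined")
  in_any <- function(polys) any(vapply(polys, function(p)
    point_in_polygon(phi, psi, p), logical(1)))
  if (in_any(regions$favored)) "favored"
  else if (in_any(regions$allowed)) "allowed"
  else "outlier"
}

#' Backbone phi/psi torsions with Ramachandran classification
#'
#' phi(i) = dihedral C(i-1)-N(i)-CA(i)-C(i); psi(i) =
#' N(i)-CA(i)-C(i)-N(i+1); IUPAC sign convention (see [dihedral()]).
#' Chain-terminal residues have the corresponding angle `NA` and region
#' `undefined`; so do residues with missing backbone atoms (warned).
#' Numbering gaps are treated as chain breaks.
#'
#' @param struct atom tibble.
#' @param chain chain id.
#' @param model model number (default first).
#' @param regions region polygons; default [rama_default_regions()] data.
#' @return tibble `chain`, `res_seq`, `res_name`, `phi`, `psi`, `region`.
#' @export
backbone_torsions <- function(struct, chain, model = min(struct$model),
                              regions = rama_default_regions()) {
  bb <- atom_select(struct, chain = chain, model = model,
                    name = c("N", "CA", "C"))
  bb <- bb[!bb$hetero, ]
  if (nrow(bb) == 0) abort(paste0("no backbone atoms in chain ", chain))
  res <- distinct(bb[order(bb$res_seq, bb$ins), c("res_seq", "ins")])
  get_at <- function(k, nm) {
    a <- bb[bb$res_seq == res$res_seq[k] & bb$ins == res$ins[k] & bb$name == nm, ]
    if (nrow(a) != 1) return(NULL)
    c(a$x, a$y, a$z)
  }
  nres <- nrow(res)
  phi <- rep(NA_real_, nres); psi <- rep(NA_real_, nres)
  warned <- FALSE
  contig <- function(k1, k2) res$res_seq[k2] - res$res_seq[k1] == 1L
  for (k in seq_len(nres)) {
    Nk <- get_at(k, "N"); CAk <- get_at(k, "CA"); Ck <- get_at(k, "C")
    if (is.null(Nk) || is.null(CAk) || is.null(Ck)) {
      warned <- TRUE
      next
    }
    if (k > 1 && contig(k - 1, k)) {
      Cprev <- get_at(k - 1, "C")
      if (!is.null(Cprev)) phi[k] <- dihedral(Cprev, Nk, CAk, Ck)
    }
    if (k < nres && contig(k, k + 1)) {
      Nnext <- get_at(k + 1, "N")
      if (!is.null(Nnext)) psi[k] <- dihedral(Nk, CAk, Ck, Nnext)
    }
  }
  if (warned) warn("missing backbone atoms: affected torsions are undefined")
  name_of <- vapply(seq_len(nres), function(k) {
    bb$res_name[bb$res_seq == res$res_seq[k] & bb$ins == res$ins[k]][1]
  }, character(1))
  region <- vapply(seq_len(nres), function(k) {
    if (is.na(phi[k]) && is.na(psi[k])) "undefined"
    else if (is.na(phi[k]) || is.na(psi[k])) "undefined"
    else classify_rama(phi[k], psi[k], regions)
  }, character(1))
  tibble(chain = chain, res_seq = res$res_seq, res_name = name_of,
         phi = phi, psi = psi, region = region)
}

# van der Waals radii (Angstrom), common SASA practice; override via
# the `radii` argument of sasa().
DEFAULT_VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

# deterministic near-uniform points on the unit sphere (Fibonacci spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi_g <- pi * (3 - sqrt(5))
  zc <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - zc^2))
  th <- phi_g * i
  cbind(r * cos(th), r * sin(th), zc)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom is covered with `n_points` near-uniform sphere points at
#' radius r_vdw + probe; a point is exposed iff it lies outside every
#' neighbouring atom's expanded sphere. Area = exposed fraction times
#' the full sphere area.
#'
#' @param struct atom tibble (single model; pass a filtered tibble or use
#'   `model`).
#' @param probe probe radius, Angstrom (water = 1.4).
#' @param n_points test points per atom.
#' @param model model number (default first).
#' @param radii named vdW radius table; merged over the built-in
#'   C/N/O/S/H values.
#' @return object of class `sasa_result`: `per_atom` tibble (atom columns
#'   + `area`), `per_residue` tibble (`chain`, `res_seq`, `res_name`,
#'   `area`), `probe_radius`, `n_points`, `radii`.
#' @export
sasa <- function(struct, probe = 1.4, n_points = 960L,
                 model = min(struct$model), radii = NULL) {
  at <- struct[struct$model == model, ]
  rt <- DEFAULT_VDW
  if (!is.null(radii)) rt[names(radii)] <- radii
  rv <- rt[at$element]
  if (anyNA(rv)) {
    abort(paste0("no vdW radius for element(s): ",
                 paste(unique(at$element[is.na(rv)]), collapse = ", "),
                 " (supply `radii`)"))
  }
  R <- unname(rv) + probe
  xyz <- coords_matrix(at)
  n <- nrow(at)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (R[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < R[i] + R[nb]]
    p <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    if (length(nb)) {
      exposed <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
        exposed <- exposed & dj2 > R[j]^2
        if (!any(exposed)) break
      }
      frac <- mean(exposed)
    } else {
      frac <- 1
    }
    area[i] <- frac * 4 * pi * R[i]^2
  }
  per_atom <- mutate(at, area = area)
  per_residue <- summarise(
    group_by(per_atom, chain, res_seq, res_name),
    area = sum(area), .groups = "drop"
  )
  structure(
    list(per_atom = per_atom, per_residue = per_residue,
         probe_radius = probe, n_points = n_points, radii = rt),
    class = "sasa_result"
  )
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, total %.1f A^2 (probe %.2f A, %d points)\n",
              nrow(x$per_atom), sum(x$per_atom$area), x$probe_radius,
              x$n_points))
  invisible(x)
}

#' Distance between two uniquely selected atoms
#'
#' @param struct atom tibble.
#' @param sel_a,sel_b named lists of [atom_select()] filters, each
#'   resolving to exactly one atom in the chosen model.
#' @param model model number (default first).
#' @return Euclidean distance, Angstrom.
#' @export
#' @examples
#' # atom_distance(pose, list(chain = "E", res_seq = 25, name = "SG"),
#' #                     list(chain = "P", res_seq = 1, name = "C"))
atom_distance <- function(struct, sel_a, sel_b, model = min(struct$model)) {
  pick <- function(sel, which) {
    a <- do.call(atom_select, c(list(struct = struct, model = model), sel))
    if (nrow(a) != 1) {
      abort(sprintf("selection %s matches %d atoms (need exactly 1): %s",
                    which, nrow(a),
                    paste(utils::head(paste(a$chain, a$res_seq, a$name), 5),
                          collapse = "; ")))
    }
    c(a$x, a$y, a$z)
  }
  vec_norm(pick(sel_a, "A") - pick(sel_b, "B"))
}

#' Per-frame atom-pair distance series
#'
#' Vectorised across frames; each selection must resolve to exactly one
#' atom in every frame.
#'
#' @inheritParams atom_distance
#' @return tibble `frame`, `dist` (Angstrom).
#' @export
distance_series <- function(struct, sel_a, sel_b) {
  frames <- sort(unique(struct$model))
  pick <- function(sel, which) {
    a <- do.call(atom_select, c(list(struct = struct), sel))
    if (nrow(a) != length(frames) || anyDuplicated(a$model) ||
        !all(sort(a$model) == frames)) {
      abort(paste0("selection ", which,
                   " must match exactly one atom in every frame"))
    }
    a[order(a$model), ]
  }
  a <- pick(sel_a, "A"); b <- pick(sel_b, "B")
  tibble(frame = frames,
         dist = sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2))
}
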