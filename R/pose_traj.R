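#' Catalytic-site specification for pose screening
#'
#' Defaults describe the papain-family triad of actinidin
#' (Cys25 SG nucleophile, His162 NE2, Asn182 OD1) and a maximum
#' nucleophile-to-carbonyl (SG-C) distance of 5.0 Angstrom; 4.5 is the
#' stricter literature alternative.
#'
#' @param enzyme_chain,peptide_chain chain ids of enzyme and peptide.
#' @param nucleophile list(res_seq, name) of the attacking atom.
#' @param his,asn list(res_seq, name) of the other triad members
#'   (recorded, not gated).
#' @param scissile list(res_seq, name) of the P1 carbonyl carbon.
#' @param max_sg_c acceptance threshold, Angstrom.
#' @return list of class `catalytic_spec`.
#' @export
catalytic_spec <- function(enzyme_chain = "E", peptide_chain = "P",
                           nucleophile = list(res_seq = 25, name = "SG"),
                           his = list(res_seq = 162, name = "NE2"),
                           asn = list(res_seq = 182, name = "OD1"),
                           scissile = list(res_seq = 1, name = "C"),
                           max_sg_c = 5.0) {
  if (max_sg_c <= 0) abort("max_sg_c must be positive")
  structure(list(enzyme_chain = enzyme_chain, peptide_chain = peptide_chain,
                 nucleophile = nucleophile, his = his, asn = asn,
                 scissile = scissile, max_sg_c = max_sg_c),
            class = "catalytic_spec")
}

#' Screen a docked pose for catalytic competence
#'
#' Measures the distance from the catalytic nucleophile (Cys SG by
#' default) to the scissile carbonyl carbon and accepts the pose iff
#' it does not exceed the threshold (<=). His/Asn triad geometry is
#' reported alongside but not gated.
#'
#' @param pose atom tibble of one docked enzyme-peptide complex.
#' @param spec a [catalytic_spec()].
#' @param model model number.
#' @return one-row tibble: `sg_c`, `threshold`, `verdict`
#'   ("accept"/"reject"), `his_c`, `asn_c` (triad distances, Angstrom).
#' @export
screen_pose <- function(pose, spec = catalytic_spec(), model = min(pose$model)) {
  nuc <- c(list(chain = spec$enzyme_chain), spec$nucleophile)
  sci <- c(list(chain = spec$peptide_chain), spec$scissile)
  sg_c <- atom_distance(pose, nuc, sci, model)
  aux <- function(sel) {
    tryCatch(atom_distance(pose, c(list(chain = spec$enzyme_chain), sel),
                           sci, model),
             error = function(e) NA_real_)
  }
  tibble(
    sg_c = sg_c,
    threshold = spec$max_sg_c,
    verdict = if (sg_c <= spec$max_sg_c) "accept" else "reject",
    his_c = aux(spec$his),
    asn_c = aux(spec$asn)
  )
}

#' Geometric hydrogen-bond criteria
#'
#' Defaults follow the common molecular-dynamics convention:
#' donor-acceptor distance <= 3.5 Angstrom and H-D-A angle <= 30 degrees.
#'
#' @param max_da maximum donor-acceptor distance, Angstrom.
#' @param max_angle_hda maximum hydrogen-donor-acceptor angle, degrees.
#' @export
hbond_criteria <- function(max_da = 3.5, max_angle_hda = 30) {
  if (max_da <= 0 || max_angle_hda <= 0) abort("criteria must be positive")
  structure(list(max_da = max_da, max_angle_hda = max_angle_hda),
            class = "hbond_criteria")
}

# hydrogens covalently attached to a donor: same chain+residue, element H,
# within 1.25 A
attached_hydrogens <- function(frame, donor_row) {
  h <- frame[frame$element == "H" & frame$chain == donor_row$chain &
               frame$res_seq == donor_row$res_seq & frame$ins == donor_row$ins, ]
  if (nrow(h) == 0) return(h)
  d <- sqrt((h$x - donor_row$x)^2 + (h$y - donor_row$y)^2 +
              (h$z - donor_row$z)^2)
  h[d < 1.25, ]
}

#' Count hydrogen bonds between two selections in one frame
#'
#' Pairs one donor heavy atom from `donors` with one acceptor from
#' `acceptors` when D-A <= `max_da` and, if the donor carries a hydrogen
#' (and `use_hydrogens` is `TRUE`), some H-D-A angle <= `max_angle_hda`.
#' With `use_hydrogens = FALSE` the distance criterion alone is applied.
#' Intra-selection pairs are never counted. Each (D, A) pair counts at
#' most once.
#'
#' @param frame atom tibble of a single model (the full frame; hydrogens
#'   are looked up here).
#' @param donors,acceptors atom tibbles (rows of `frame`) holding the
#'   donor and acceptor heavy atoms.
#' @param criteria an [hbond_criteria()].
#' @param use_hydrogens if `FALSE`, skip the angle term (logged once via
#'   message).
#' @return integer bond count.
#' @export
hbond_count <- function(frame, donors, acceptors,
                        criteria = hbond_criteria(), use_hydrogens = TRUE) {
  if (nrow(donors) == 0 || nrow(acceptors) == 0) {
    abort("donor and acceptor selections must be non-empty")
  }
  if (!use_hydrogens) {
    message("hydrogen positions ignored: distance criterion only")
  }
  n <- 0L
  for (i in seq_len(nrow(donors))) {
    D <- donors[i, ]
    dvec <- c(D$x, D$y, D$z)
    da <- sqrt((acceptors$x - D$x)^2 + (acceptors$y - D$y)^2 +
                 (acceptors$z - D$z)^2)
    cand <- which(da <= criteria$max_da & da > 1e-6)
    if (!length(cand)) next
    hs <- if (use_hydrogens) attached_hydrogens(frame, D) else NULL
    for (j in cand) {
      A <- acceptors[j, ]
      # exclude atoms present in both selections pairing with themselves
      if (A$chain == D$chain && A$res_seq == D$res_seq && A$name == D$name) next
      ok <- TRUE
      if (use_hydrogens && !is.null(hs) && nrow(hs) > 0) {
        avec <- c(A$x, A$y, A$z)
        ang <- vapply(seq_len(nrow(hs)), function(k) {
          hvec <- c(hs$x[k], hs$y[k], hs$z[k])
          v1 <- hvec - dvec; v2 <- avec - dvec
          acos(pmin(1, pmax(-1, sum(v1 * v2) / (vec_norm(v1) * vec_norm(v2))))) * 180 / pi
        }, numeric(1))
        ok <- any(ang <= criteria$max_angle_hda)
      }
      if (ok) n <- n + 1L
    }
  }
  n
}

#' Five-number summary of a numeric series
#'
#' Min, lower quartile, median, upper quartile, max with
#' linear-interpolation quartiles (R's default type-7 quantile).
#'
#' @param x numeric vector.
#' @return tibble `min`, `q1`, `median`, `q3`, `max`.
#' @export
five_number <- function(x) {
  q <- unname(stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  tibble(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

#' Summarise a trajectory metric
#'
#' Computes a per-frame series for one of the supported metrics and
#' attaches its mean, standard error and five-number (box-plot) summary.
#'
#' * `"sg_c"` - nucleophile-to-scissile-carbon distance per frame
#'   (needs `spec`, a [catalytic_spec()]);
#' * `"rmsd"` - fitted RMSD against a reference frame (extra arguments
#'   passed to [rmsd_series()]);
#' * `"hbond"` - hydrogen-bond count per frame (needs `donors_sel` and
#'   `acceptors_sel` as lists of [atom_select()] filters, plus optional
#'   `criteria`, `use_hydrogens`).
#'
#' @param traj multi-model atom tibble (>= 2 frames).
#' @param metric one of `"sg_c"`, `"rmsd"`, `"hbond"`.
#' @param ... metric arguments, see above.
#' @return object of class `traj_summary`: `per_frame` tibble
#'   (`frame`, `value`), `metric`, `mean`, `se`, `five_num`.
#' @export
traj_summary <- function(traj, metric = c("sg_c", "rmsd", "hbond"), ...) {
  metric <- match.arg(metric)
  frames <- sort(unique(traj$model))
  if (length(frames) < 2) abort("trajectory needs at least 2 frames")
  args <- list(...)
  per_frame <- switch(
    metric,
    sg_c = {
      spec <- args$spec %||% catalytic_spec()
      ser <- distance_series(traj,
                             c(list(chain = spec$enzyme_chain), spec$nucleophile),
                             c(list(chain = spec$peptide_chain), spec$scissile))
      tibble(frame = ser$frame, value = ser$dist)
    },
    rmsd = {
      ser <- do.call(rmsd_series, c(list(traj = traj), args))
      tibble(frame = ser$frame, value = ser$rmsd)
    },
    hbond = {
      if (is.null(args$donors_sel) || is.null(args$acceptors_sel)) {
        abort("hbond metric needs donors_sel and acceptors_sel")
      }
      crit <- args$criteria %||% hbond_criteria()
      useh <- args$use_hydrogens %||% TRUE
      vals <- vapply(frames, function(m) {
        fr <- traj[traj$model == m, ]
        dn <- do.call(atom_select, c(list(struct = fr), args$donors_sel))
        ac <- do.call(atom_select, c(list(struct = fr), args$acceptors_sel))
        hbond_count(fr, dn, ac, crit, use_hydrogens = useh)
      }, integer(1))
      tibble(frame = frames, value = as.numeric(vals))
    }
  )
  v <- per_frame$value
  structure(
    list(per_frame = per_frame, metric = metric, mean = mean(v),
         se = stats::sd(v) / sqrt(length(v)), five_num = five_number(v)),
    class = "traj_summary"
  )
}

#' @export
print.traj_summary <- function(x, ...) {
  f <- x$five_num
  cat(sprintf(
    "<traj_summary> %s over %d frames: mean %.3f +/- %.3f (se); five-number %.2f/%.2f/%.2f/%.2f/%.2f\n",
    x$metric, nrow(x$per_frame), x$mean, x$se,
    f$min, f$q1, f$median, f$q3, f$max))
  invisible(x)
}

#' Convert Gibbs binding free energy to a dissociation constant
#'
#' Kd = exp(deltaG / RT) with R = 1.9872e-3 kcal/(mol K); the
#' dimensionless exponential form, no standard-state conversion.
#' [dg_from_kd()] is the exact inverse.
#'
#' @param delta_g Gibbs free energy of binding, kcal/mol (negative for
#'   spontaneous binding).
#' @param temperature Kelvin; default 310.15 (37 C).
#' @return dissociation constant (dimensionless).
#' @export
#' @examples
#' kd_from_dg(-12.3, 310) # ~2.1e-9
kd_from_dg <- function(delta_g, temperature = 310.15) {
  if (any(temperature <= 0)) abort("temperature must be positive")
  exp(delta_g / (1.9872e-3 * temperature))
}

#' @rdname kd_from_dg
#' @param kd dissociation constant, > 0.
#' @export
dg_from_kd <- function(kd, temperature = 310.15) {
  if (any(temperature <= 0)) abort("temperature must be positive")
  if (any(kd <= 0)) abort("kd must be positive")
  1.9872e-3 * temperature * log(kd)
}

#' Compare per-frame hydrogen-bond counts across complexes
#'
#' One-way ANOVA over the per-frame counts by complex, with
#' Bonferroni/Holm-adjusted pairwise comparisons and a compact
#' letter display (groups sharing a letter are not significantly
#' different under the Holm-adjusted tests).
#'
#' @param data data frame with one row per frame per complex.
#' @param value,group column names (strings) of the count and the
#'   complex label.
#' @param alpha significance level (the negative-control contrast in
#'   this assay is usually read at 0.01).
#' @return a `clot_anova` object (see [anova_posthoc()]) with an extra
#'   `letters` element (named character vector).
#' @export
compare_hbond_groups <- function(data, value = "count", group = "complex",
                                 alpha = 0.01) {
  res <- anova_posthoc(data, value = value, group = group, alpha = alpha)
  res$letters <- cld_letters(res)
  res
}

# compact letter display from the Holm-adjusted pairwise reject flags;
# groups ordered by decreasing mean, greedy letter assignment
cld_letters <- function(res) {
  groups <- res$group_means$group[order(-res$group_means$mean)]
  differs <- function(g1, g2) {
    ph <- res$posthoc
    row <- ph[(ph$group1 == g1 & ph$group2 == g2) |
                (ph$group1 == g2 & ph$group2 == g1), ]
    nrow(row) == 1 && row$reject_holm
  }
  sets <- list()  # each element: character vector of compatible groups
  for (g in groups) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (!any(vapply(sets[[k]], function(o) differs(g, o), logical(1)))) {
        sets[[k]] <- c(sets[[k]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  out <- setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets)) {
    for (g in sets[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  out[res$group_means$group]
}
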