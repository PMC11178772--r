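# Independent oracles used across the suite. Each is written from the
# underlying definition, not by calling the implementation under test.

# --- superposition RMSD via Horn's quaternion method -------------------
quat_rmsd <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  M <- crossprod(Xc, Yc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Xc^2) + sum(Yc^2) - 2 * lam) / nrow(X)
  sqrt(max(0, msd))
}

# --- exhaustive window-by-window cleavage scan -------------------------
brute_scan <- function(seq_string, model) {
  res <- strsplit(seq_string, "")[[1]]
  n <- length(res)
  offsets <- c("P4" = -3, "P3" = -2, "P2" = -1, "P1" = 0,
               "P1'" = 1, "P2'" = 2, "P3'" = 3, "P4'" = 4)
  hits <- integer()
  for (i in seq_len(n - 1)) {
    for (lab in names(model$sources)) {
      src <- model$sources[[lab]]
      ok <- TRUE
      for (tag in names(src)) {
        j <- i + offsets[[tag]]
        if (j < 1 || j > n || res[j] == "X" || !(res[j] %in% src[[tag]])) {
          ok <- FALSE
          break
        }
      }
      if (ok) { hits <- c(hits, i); break }
    }
  }
  hits
}

# --- exhaustive geometric hydrogen-bond enumeration --------------------
brute_hbond <- function(frame, donors, acceptors, max_da = 3.5,
                        max_angle = 30) {
  count <- 0L
  for (i in seq_len(nrow(donors))) {
    for (j in seq_len(nrow(acceptors))) {
      D <- donors[i, ]; A <- acceptors[j, ]
      if (D$chain == A$chain && D$res_seq == A$res_seq && D$name == A$name) next
      da <- sqrt((D$x - A$x)^2 + (D$y - A$y)^2 + (D$z - A$z)^2)
      if (da > max_da || da < 1e-6) next
      hs <- frame[frame$element == "H" & frame$chain == D$chain &
                    frame$res_seq == D$res_seq, ]
      if (nrow(hs)) {
        dh <- sqrt((hs$x - D$x)^2 + (hs$y - D$y)^2 + (hs$z - D$z)^2)
        hs <- hs[dh < 1.25, ]
      }
      if (nrow(hs) == 0) { count <- count + 1L; next }
      angles <- sapply(seq_len(nrow(hs)), function(k) {
        v1 <- c(hs$x[k] - D$x, hs$y[k] - D$y, hs$z[k] - D$z)
        v2 <- c(A$x - D$x, A$y - D$y, A$z - D$z)
        acos(min(1, max(-1, sum(v1 * v2) /
                          (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      })
      if (any(angles <= max_angle)) count <- count + 1L
    }
  }
  count
}

# --- textbook one-way ANOVA from sums of squares -----------------------
anova_f_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); N <- length(values)
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((values - means[groups])^2)
  f <- (ss_b / (k - 1)) / (ss_w / (N - k))
  list(f = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

# --- hand-stepped multiple-testing adjustments -------------------------
bonferroni_oracle <- function(p) pmin(1, p * length(p))
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (r in seq_len(m)) {
    running <- max(running, (m - r + 1) * p[o[r]])
    adj[o[r]] <- min(1, running)
  }
  adj
}

# --- analytic SASA of two intersecting equal spheres -------------------
two_sphere_sasa <- function(R, d) {
  # each sphere loses a cap of height h = R - d/2; area of a cap = 2*pi*R*h
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# --- geometry helpers for fixtures -------------------------------------
rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

rigid_move <- function(struct, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(struct[, c("x", "y", "z")]) %*% t(R)
  struct$x <- xyz[, 1] + t[1]
  struct$y <- xyz[, 2] + t[2]
  struct$z <- xyz[, 3] + t[3]
  struct
}

# CA-only structure carrying a given sequence (for map_chains tests)
ca_structure <- function(seqs, chains = names(seqs)) {
  aa31 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  rows <- lapply(seq_along(seqs), function(k) {
    res <- strsplit(seqs[[k]], "")[[1]]
    tibble::tibble(
      model = 1L, serial = seq_along(res), name = "CA", alt = " ",
      res_name = unname(aa31[res]), chain = chains[k],
      res_seq = seq_along(res), ins = " ",
      x = 3.8 * seq_along(res), y = as.numeric(k), z = 0,
      element = "C", hetero = FALSE
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "id") <- "test"
  class(out) <- c("pdb_tbl", class(tibble::tibble()))
  out
}
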