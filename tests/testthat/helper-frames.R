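# Hand-built frames for threshold and graph semantics tests.
# Positions in Angstrom; each entry of `phosphates` is list(pos, nH);
# each water is an O position (H atoms placed trivially nearby).
makeFrame <- function(ca = NULL, phosphates = list(), waters = NULL,
                      box = NA_real_, time = 0) {
  rows <- list()
  mol <- 0L
  for (i in seq_len(NROW(ca))) {
    mol <- mol + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      element = "Ca", role = "Ca",
      x = ca[i, 1], y = ca[i, 2], z = ca[i, 3], mol = mol)
  }
  for (ph in phosphates) {
    mol <- mol + 1L
    p <- ph$pos
    rows[[length(rows) + 1L]] <- data.frame(
      element = "P", role = "P", x = p[1], y = p[2], z = p[3], mol = mol)
    for (k in seq_len(4)) {
      o <- p + 1.54 * switch(k, c(1, 0, 0), c(-1 / 3, 0.943, 0),
                             c(-1 / 3, -0.471, 0.816),
                             c(-1 / 3, -0.471, -0.816))
      rows[[length(rows) + 1L]] <- data.frame(
        element = "O", role = "O_P", x = o[1], y = o[2], z = o[3], mol = mol)
    }
    for (k in seq_len(ph$nH)) {
      h <- p + 2.5 * switch(k, c(1, 0, 0), c(-1 / 3, 0.943, 0))
      rows[[length(rows) + 1L]] <- data.frame(
        element = "H", role = "H_P", x = h[1], y = h[2], z = h[3], mol = mol)
    }
  }
  for (i in seq_len(NROW(waters))) {
    mol <- mol + 1L
    o <- waters[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      element = c("O", "H", "H"), role = c("O_W", "H_W", "H_W"),
      x = o[1] + c(0, 0.7, -0.7), y = o[2] + c(0, 0.66, 0.66),
      z = o[3], mol = mol)
  }
  atomFrame(do.call(rbind, rows), box = box, time = time)
}

# Brute-force hydration oracle: loop over waters and cluster Ca.
bruteHydration <- function(frame, cluster, radiusNm = 0.27) {
  a <- atoms(frame)
  caXYZ <- a[cluster@caAtoms, c("x", "y", "z"), drop = FALSE]
  ow <- a[a$role == "O_W", ]
  bound <- 0L
  for (i in seq_len(nrow(ow))) {
    near <- FALSE
    for (j in seq_len(nrow(caXYZ))) {
      d <- sqrt(sum((as.numeric(ow[i, c("x", "y", "z")]) -
                       as.numeric(caXYZ[j, ]))^2))
      if (d <= radiusNm * 10) near <- TRUE
    }
    if (near) bound <- bound + 1L
  }
  bound
}

# Brute-force Ca-P RMSD oracle: explicit double loop over pairs.
bruteRmsd <- function(frame, reference) {
  a <- atoms(frame); b <- atoms(reference)
  caA <- a[a$role == "Ca", c("x", "y", "z")]
  pA <- a[a$role == "P", c("x", "y", "z")]
  caB <- b[b$role == "Ca", c("x", "y", "z")]
  pB <- b[b$role == "P", c("x", "y", "z")]
  sq <- 0; n <- 0L
  for (i in seq_len(nrow(caA))) for (j in seq_len(nrow(pA))) {
    d1 <- sqrt(sum((as.numeric(caA[i, ]) - as.numeric(pA[j, ]))^2))
    d0 <- sqrt(sum((as.numeric(caB[i, ]) - as.numeric(pB[j, ]))^2))
    sq <- sq + (d1 - d0)^2
    n <- n + 1L
  }
  sqrt(sq / n)
}

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
randomRotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
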