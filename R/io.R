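## Trajectory file I/O.  The native dialect is multi-frame XYZ with a
## comment-line timestamp (and optional box edge and role/mol columns, so
## round-trips are lossless); a minimal multi-model PDB reader covers the
## other common dialect.

#' Write a trajectory as multi-frame XYZ
#'
#' Standard XYZ blocks (`natoms`, comment, one atom per line) with the
#' comment line carrying `t= <ns>` and, for periodic frames,
#' `box= <nm>`.  Two extra per-atom columns (`role`, `mol`) keep the
#' frame reconstruction lossless; XYZ readers that expect only
#' element + coordinates ignore them.
#'
#' @param traj an [IonTrajectory-class] or a list of [AtomFrame-class].
#' @param path output path.
#' @export
writeXyz <- function(traj, path) {
  frames <- if (is(traj, "IonTrajectory")) traj@frames else traj
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    a <- fr@atoms
    hdr <- sprintf("t= %.6g", fr@time)
    if (!is.na(fr@box)) hdr <- sprintf("%s box= %.6g", hdr, fr@box / 10)
    writeLines(as.character(nrow(a)), con)
    writeLines(hdr, con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f %s %d",
                       a$element, a$x, a$y, a$z, a$role, a$mol), con)
  }
  invisible(path)
}

## Role/molecule inference for plain 4-column XYZ: ions by element;
## O within 1.9 A of a P is phosphate O, H within 1.2 A of a phosphate O
## is an acidic H; remaining O are water O and remaining H attach to the
## nearest water O.
.inferRoles <- function(df) {
  el <- df$element
  xyz <- as.matrix(df[, c("x", "y", "z")])
  role <- rep("ion", nrow(df))
  role[el == "Ca"] <- "Ca"
  role[el == "P"] <- "P"
  mol <- integer(nrow(df))
  nextMol <- 0L
  for (i in which(role %in% c("Ca", "P", "ion"))) {
    nextMol <- nextMol + 1L
    mol[i] <- nextMol
  }
  pIdx <- which(el == "P")
  oIdx <- which(el == "O")
  hIdx <- which(el == "H")
  oP <- integer()
  if (length(pIdx) && length(oIdx)) {
    d <- .pairDist(xyz[oIdx, , drop = FALSE], xyz[pIdx, , drop = FALSE])
    near <- apply(d, 1, which.min)
    isP <- apply(d, 1, min) <= 1.9
    oP <- oIdx[isP]
    role[oP] <- "O_P"
    mol[oP] <- mol[pIdx[near[isP]]]
  }
  hP <- integer()
  if (length(oP) && length(hIdx)) {
    d <- .pairDist(xyz[hIdx, , drop = FALSE], xyz[oP, , drop = FALSE])
    near <- apply(d, 1, which.min)
    isP <- apply(d, 1, min) <= 1.2
    hP <- hIdx[isP]
    role[hP] <- "H_P"
    mol[hP] <- mol[oP[near[isP]]]
  }
  oW <- setdiff(oIdx, oP)
  role[oW] <- "O_W"
  for (i in oW) { nextMol <- nextMol + 1L; mol[i] <- nextMol }
  hW <- setdiff(hIdx, hP)
  if (length(hW) && length(oW)) {
    d <- .pairDist(xyz[hW, , drop = FALSE], xyz[oW, , drop = FALSE])
    near <- apply(d, 1, which.min)
    role[hW] <- "H_W"
    mol[hW] <- mol[oW[near]]
  }
  df$role <- role
  df$mol <- mol
  df
}

#' Read a multi-frame XYZ trajectory
#'
#' Accepts both the lossless 6-column dialect written by [writeXyz()] and
#' plain 4-column XYZ, in which case roles and molecule grouping are
#' inferred from elements and bonding distances.
#'
#' @param path XYZ file path.
#' @return an [IonTrajectory-class].
#' @export
readXyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    hdr <- lines[i + 1L]
    tm <- regmatches(hdr, regexec("t=\\s*([-0-9.eE+]+)", hdr))[[1]]
    bx <- regmatches(hdr, regexec("box=\\s*([-0-9.eE+]+)", hdr))[[1]]
    tVal <- if (length(tm) == 2L) as.numeric(tm[2]) else 0
    bVal <- if (length(bx) == 2L) as.numeric(bx[2]) else NA_real_
    block <- lines[(i + 2L):(i + 1L + n)]
    f <- strsplit(trimws(block), "\\s+")
    ncol <- length(f[[1]])
    df <- data.frame(
      element = vapply(f, `[`, character(1), 1),
      x = as.numeric(vapply(f, `[`, character(1), 2)),
      y = as.numeric(vapply(f, `[`, character(1), 3)),
      z = as.numeric(vapply(f, `[`, character(1), 4)))
    if (ncol >= 6L) {
      df$role <- vapply(f, `[`, character(1), 5)
      df$mol <- as.integer(vapply(f, `[`, character(1), 6))
    } else {
      df <- .inferRoles(df)
    }
    frames[[length(frames) + 1L]] <- atomFrame(df, box = bVal, time = tVal)
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("no frames in ", path)
  ionTrajectory(frames)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Minimal reader for `MODEL`/`ENDMDL`-delimited `ATOM`/`HETATM` records.
#' Elements come from columns 77-78 (falling back to the atom name);
#' water residues (`HOH`/`WAT`/`SOL`/`TIP3`) map to water roles, P and
#' its O/H within phosphate residues to phosphate roles, `CA` ions to Ca.
#' Molecule ids follow the residue sequence numbers.
#'
#' @param path PDB file path.
#' @return an [IonTrajectory-class].
#' @export
readPdbTrajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  cur <- list()
  waterRes <- c("HOH", "WAT", "SOL", "TIP3", "TIP")
  flush <- function(cur) {
    if (length(cur) == 0L) return(NULL)
    df <- do.call(rbind, cur)
    atomFrame(df, box = NA_real_, time = length(frames))
  }
  molKey <- character()
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (tag == "ENDMDL") {
      fr <- flush(cur)
      if (!is.null(fr)) frames[[length(frames) + 1L]] <- fr
      cur <- list()
      molKey <- character()
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      name <- trimws(substr(ln, 13, 16))
      res <- trimws(substr(ln, 18, 20))
      chain <- substr(ln, 22, 22)
      resSeq <- trimws(substr(ln, 23, 26))
      x <- as.numeric(substr(ln, 31, 38))
      y <- as.numeric(substr(ln, 39, 46))
      z <- as.numeric(substr(ln, 47, 54))
      el <- trimws(substr(ln, 77, 78))
      if (!nzchar(el)) el <- gsub("[0-9']", "", name)
      el <- paste0(toupper(substr(el, 1, 1)),
                   tolower(substr(el, 2, nchar(el))))
      isWater <- res %in% waterRes
      role <- if (el == "Ca") "Ca"
        else if (el == "P") "P"
        else if (el == "O" && isWater) "O_W"
        else if (el == "H" && isWater) "H_W"
        else if (el == "O") "O_P"
        else if (el == "H") "H_P"
        else "ion"
      key <- paste(chain, resSeq, sep = ":")
      if (!key %in% molKey) molKey <- c(molKey, key)
      cur[[length(cur) + 1L]] <-
        data.frame(element = el, role = role, x = x, y = y, z = z,
                   mol = match(key, molKey))
    }
  }
  fr <- flush(cur)  # file without trailing ENDMDL
  if (!is.null(fr)) frames[[length(frames) + 1L]] <- fr
  if (length(frames) == 0L) stop("no ATOM records in ", path)
  ionTrajectory(frames)
}

#' Export a distance histogram as TSV
#'
#' @param hist a `distanceHistogram`.
#' @param path output path.
#' @export
writeHistogramTsv <- function(hist, path) {
  stopifnot(inherits(hist, "distanceHistogram"))
  utils::write.table(
    data.frame(binMid = hist$mid, count = hist$counts,
               density = hist$density),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
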