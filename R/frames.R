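FRAME_ROLES <- c("water-O", "backbone-O", "sidechain-O", "ion")
ION_SPECIES <- c("Na", "K", "Cl")

#' Role-tagged atomic snapshot
#'
#' A minimal structural frame for the snapshot analyses: every atom carries
#' an explicit role (water oxygen, backbone carbonyl oxygen of a residue,
#' side-chain oxygen of a residue, or an ion of a given species) so no
#' force-field topology is needed.
#'
#' @param id Unique atom identifiers (character).
#' @param role One of "water-O", "backbone-O", "sidechain-O", "ion".
#' @param x,y,z Coordinates, A.
#' @param residue Residue tag such as "THR175" (backbone/side-chain oxygens;
#'   NA otherwise).
#' @param species Ion species "Na", "K" or "Cl" (ions only; NA otherwise).
#' @param time Frame time, ps.
#' @return A data frame of class \code{ion_frame} with attribute
#'   \code{time}.
#' @export
ion_frame <- function(id = character(), role = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      residue = NA_character_, species = NA_character_,
                      time = 0) {
  n <- length(id)
  fr <- data.frame(id = as.character(id), role = as.character(role),
                   residue = rep_len(as.character(residue), n),
                   species = rep_len(as.character(species), n),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  validate_frame(fr)
  attr(fr, "time") <- time
  class(fr) <- c("ion_frame", "data.frame")
  fr
}

validate_frame <- function(fr) {
  if (anyDuplicated(fr$id)) stop("duplicate atom identifiers in frame")
  if (nrow(fr) == 0L) return(invisible(fr))
  bad <- setdiff(unique(fr$role), FRAME_ROLES)
  if (length(bad)) stop("unknown atom role(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(fr$x) & is.finite(fr$y) & is.finite(fr$z)))
    stop("non-finite coordinates in frame")
  ions <- fr$role == "ion"
  if (any(ions) && !all(fr$species[ions] %in% ION_SPECIES))
    stop("ion species must be one of ", paste(ION_SPECIES, collapse = ", "))
  invisible(fr)
}

#' Frame time accessor
#' @param frame An \code{ion_frame}.
#' @return Frame time in ps.
#' @export
frame_time <- function(frame) attr(frame, "time")

#' Build a structural fixture from role-tagged atom placements
#'
#' Each placement is a list with elements \code{role}, \code{x}, \code{y},
#' \code{z} and, as the role requires, \code{residue} (backbone/side-chain
#' oxygens) or \code{species} (ions); an optional \code{id} overrides the
#' generated identifier.
#'
#' @param placements List of placements (possibly empty).
#' @param time Frame time, ps.
#' @return An \code{ion_frame} with exactly the requested atoms.
#' @examples
#' shell <- lapply(1:6, function(i)
#'   list(role = "water-O", x = 2.5 * cospi(i / 3), y = 2.5 * sinpi(i / 3),
#'        z = 0))
#' fr <- generate_structure_fixture(c(shell, list(
#'   list(role = "ion", species = "Na", x = 0, y = 0, z = 0))))
#' nrow(fr)  # 7
#' @export
generate_structure_fixture <- function(placements, time = 0) {
  if (length(placements) == 0L) return(ion_frame(time = time))
  get <- function(p, field, default = NA_character_) {
    v <- p[[field]]
    if (is.null(v) || length(v) != 1L || is.na(v)) default
    else as.character(v)
  }
  ids <- vapply(seq_along(placements), function(i) {
    p <- placements[[i]]
    as.character(get(p, "id", sprintf("atom%03d", i)))
  }, character(1))
  ion_frame(
    id = ids,
    role = vapply(placements, function(p) as.character(p$role), character(1)),
    residue = vapply(placements, get, character(1), field = "residue"),
    species = vapply(placements, get, character(1), field = "species"),
    x = vapply(placements, function(p) as.numeric(p$x), numeric(1)),
    y = vapply(placements, function(p) as.numeric(p$y), numeric(1)),
    z = vapply(placements, function(p) as.numeric(p$z), numeric(1)),
    time = time)
}

# PDB role mapping: water-O -> resid HOH, elety O; backbone-O -> elety O of
# the residue; sidechain-O -> the residue's canonical side-chain oxygen name
# (GLU OE1, SER OG, THR OG1, ASP OD1, TYR OH, else OX); ion -> resid/elety
# NA, K or CL.
sidechain_elety <- function(resname) {
  switch(resname, GLU = "OE1", SER = "OG", THR = "OG1", ASP = "OD1",
         TYR = "OH", "OX")
}

split_residue <- function(residue) {
  resname <- toupper(gsub("[0-9]+$", "", residue))
  resno <- suppressWarnings(as.integer(gsub("^[A-Za-z]+", "", residue)))
  list(resname = resname, resno = ifelse(is.na(resno), 1L, resno))
}

#' Write a frame as PDB
#'
#' Roles are encoded in standard PDB conventions: water oxygens as
#' \code{HOH/O}, backbone carbonyl oxygens as atom \code{O} of their
#' residue, side-chain oxygens under their canonical atom names (e.g.
#' \code{GLU/OE1}, \code{SER/OG}) and ions as \code{NA}, \code{K} or
#' \code{CL} HETATM records.  Output goes through \code{bio3d::write.pdb}.
#'
#' @param frame An \code{ion_frame}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_frame_pdb <- function(frame, file) {
  stopifnot(inherits(frame, "ion_frame"))
  n <- nrow(frame)
  if (n == 0L) stop("cannot write an empty frame as PDB")
  resname <- character(n); resno <- integer(n); elety <- character(n)
  for (i in seq_len(n)) {
    role <- frame$role[i]
    if (role == "water-O") {
      resname[i] <- "HOH"; elety[i] <- "O"; resno[i] <- 5000L + i
    } else if (role == "ion") {
      resname[i] <- toupper(frame$species[i])
      elety[i] <- toupper(frame$species[i]); resno[i] <- 9000L + i
    } else {
      rs <- split_residue(frame$residue[i])
      resname[i] <- rs$resname; resno[i] <- rs$resno
      elety[i] <- if (role == "backbone-O") "O"
                  else sidechain_elety(rs$resname)
    }
  }
  xyz <- as.numeric(t(as.matrix(frame[, c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = xyz, resno = resno, resid = resname,
                   elety = elety, chain = rep("A", n),
                   type = ifelse(frame$role %in% c("ion", "water-O"),
                                 "HETATM", "ATOM"))
  invisible(file)
}

#' Read a frame from PDB
#'
#' Inverse of \code{\link{write_frame_pdb}}: oxygens of residue HOH/TIP3/WAT
#' become water oxygens, atom \code{O} of any other residue a backbone
#' carbonyl oxygen, any other oxygen-named atom a side-chain oxygen, and
#' NA/SOD, K/POT, CL/CLA records ions.  Parsed with \code{bio3d::read.pdb}.
#'
#' @param file PDB path.
#' @param time Frame time to attach, ps.
#' @return An \code{ion_frame}.
#' @export
read_frame_pdb <- function(file, time = 0) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  n <- nrow(at)
  role <- character(n); residue <- rep(NA_character_, n)
  species <- rep(NA_character_, n)
  ion_map <- c(NA. = "Na", SOD = "Na", K = "K", POT = "K",
               CL = "Cl", CLA = "Cl")
  names(ion_map)[1] <- "NA"
  for (i in seq_len(n)) {
    resid <- toupper(at$resid[i]); elety <- toupper(at$elety[i])
    if (resid %in% names(ion_map)) {
      role[i] <- "ion"; species[i] <- ion_map[[resid]]
    } else if (resid %in% c("HOH", "TIP3", "WAT")) {
      role[i] <- "water-O"
    } else if (elety == "O") {
      role[i] <- "backbone-O"; residue[i] <- paste0(resid, at$resno[i])
    } else if (grepl("^O", elety)) {
      role[i] <- "sidechain-O"; residue[i] <- paste0(resid, at$resno[i])
    } else {
      stop("cannot assign a role to atom ", elety, " of residue ", resid)
    }
  }
  ion_frame(id = sprintf("atom%03d", seq_len(n)), role = role,
            residue = residue, species = species,
            x = at$x, y = at$y, z = at$z, time = time)
}

#' Write a frame as extended XYZ
#'
#' Lossless plain-text round-trip format: the comment line carries the frame
#' time; each atom line holds element, x, y, z, role, residue and species
#' (\code{-} for empty fields).
#'
#' @param frame An \code{ion_frame}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_frame_xyz <- function(frame, file) {
  stopifnot(inherits(frame, "ion_frame"))
  el <- ifelse(frame$role == "ion", frame$species, "O")
  dash <- function(v) ifelse(is.na(v), "-", v)
  lines <- c(
    as.character(nrow(frame)),
    sprintf("ionpmf frame t_ps=%.10g", frame_time(frame)),
    sprintf("%s %.10g %.10g %.10g %s %s %s %s", el, frame$x, frame$y,
            frame$z, frame$role, dash(frame$residue), dash(frame$species),
            frame$id))
  writeLines(lines, file)
  invisible(file)
}

#' Read a frame from extended XYZ
#'
#' @param file Path written by \code{\link{write_frame_xyz}}.
#' @return An \code{ion_frame}.
#' @export
read_frame_xyz <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 2L) stop("malformed XYZ file: ", file)
  n <- as.integer(lines[1])
  time <- 0
  m <- regmatches(lines[2], regexec("t_ps=([-0-9.eE+]+)", lines[2]))[[1]]
  if (length(m) == 2L) time <- as.numeric(m[2])
  if (n == 0L) return(ion_frame(time = time))
  fields <- strsplit(trimws(lines[2 + seq_len(n)]), "[[:space:]]+")
  undash <- function(v) ifelse(v == "-", NA_character_, v)
  ion_frame(
    id = vapply(fields, `[`, character(1), 8L),
    role = vapply(fields, `[`, character(1), 5L),
    residue = undash(vapply(fields, `[`, character(1), 6L)),
    species = undash(vapply(fields, `[`, character(1), 7L)),
    x = as.numeric(vapply(fields, `[`, character(1), 2L)),
    y = as.numeric(vapply(fields, `[`, character(1), 3L)),
    z = as.numeric(vapply(fields, `[`, character(1), 4L)),
    time = time)
}
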