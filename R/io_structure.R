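#' Write coordinates in GRO format
#'
#' Fixed-width GROMACS coordinate format, positions in nm. Accepts a
#' `nanosheet`, `md_frame` or raw position matrix. Residue name defaults
#' to `MOS` for sheets.
#'
#' @param x Object to write.
#' @param path Output file.
#' @param title Title line.
#' @param box Box vector (nm); defaults to the object's box or a bounding
#'   box.
#' @export
write_gro <- function(x, path, title = "sheetmem", box = NULL) {
  parts <- coords_for_io(x, box)
  lines <- c(title, format(nrow(parts$pos)))
  lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                            parts$resno %% 100000L, parts$resname,
                            substr(parts$name, 1, 5),
                            seq_len(nrow(parts$pos)) %% 100000L,
                            parts$pos[, 1], parts$pos[, 2], parts$pos[, 3]))
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f",
                            parts$box[1], parts$box[2], parts$box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO file
#'
#' @param path Input file.
#' @return List with `atoms` (data.frame: resno, resname, name, element),
#'   `pos` (nm matrix) and `box` (nm).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("truncated GRO file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO atom count at line 2")
  if (length(lines) < n + 3) {
    stop("truncated GRO file: expected ", n + 3, " lines, got ", length(lines))
  }
  al <- lines[3:(n + 2)]
  num <- function(s, from, to, ln) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    if (any(is.na(v))) {
      stop("malformed GRO record at line ", ln[which(is.na(v))[1]])
    }
    v
  }
  lns <- 3:(n + 2)
  atoms <- data.frame(
    resno = as.integer(num(al, 1, 5, lns)),
    resname = trimws(substr(al, 6, 10)),
    name = trimws(substr(al, 11, 15)),
    stringsAsFactors = FALSE)
  atoms$element <- guess_element(atoms$name)
  pos <- cbind(num(al, 21, 28, lns), num(al, 29, 36, lns), num(al, 37, 44, lns))
  colnames(pos) <- c("x", "y", "z")
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]]))
  if (length(box) < 3 || any(is.na(box[1:3]))) {
    stop("malformed GRO box at line ", n + 3)
  }
  list(atoms = atoms, pos = pos, box = box[1:3])
}

#' Write coordinates in PDB format
#'
#' Positions are converted from the package's internal nm to the PDB's
#' Angstrom convention. Writing goes through bio3d.
#'
#' @inheritParams write_gro
#' @export
write_pdb <- function(x, path, box = NULL) {
  parts <- coords_for_io(x, box)
  xyz <- as.vector(t(parts$pos * 10))  # nm -> Angstrom
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = parts$resno, resid = parts$resname,
                   elety = parts$name, chain = "A",
                   elesy = parts$element)
  invisible(path)
}

#' Read a PDB file
#'
#' Parsed with bio3d after a light per-line validation pass (so malformed
#' ATOM records fail with a line number); coordinates are converted from
#' Angstrom to nm.
#'
#' @param path Input file.
#' @return List with `atoms`, `pos` (nm), `box` (NULL unless CRYST1
#'   present).
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  at_lines <- grep("^(ATOM|HETATM)", lines)
  if (length(at_lines) == 0) stop("no ATOM records in ", path)
  for (i in at_lines) {
    s <- lines[i]
    if (nchar(s) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(s, 31, 38),
                                            substr(s, 39, 46),
                                            substr(s, 47, 54)))))) {
      stop("malformed PDB ATOM record at line ", i)
    }
  }
  pdb <- bio3d::read.pdb(path)
  pos <- matrix(pdb$xyz, ncol = 3, byrow = TRUE) / 10  # Angstrom -> nm
  colnames(pos) <- c("x", "y", "z")
  atoms <- data.frame(resno = pdb$atom$resno, resname = pdb$atom$resid,
                      name = pdb$atom$elety,
                      element = guess_element(pdb$atom$elety),
                      stringsAsFactors = FALSE)
  box <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) == 1) {
    box <- as.numeric(c(substr(cr, 7, 15), substr(cr, 16, 24),
                        substr(cr, 25, 33))) / 10
  }
  list(atoms = atoms, pos = pos, box = box)
}

#' Write coordinates in XYZ format
#'
#' Conventional XYZ: atom count, comment, then element and Angstrom
#' coordinates (converted from internal nm).
#'
#' @inheritParams write_gro
#' @export
write_xyz <- function(x, path, title = "sheetmem") {
  parts <- coords_for_io(x, NULL)
  lines <- c(format(nrow(parts$pos)), title,
             sprintf("%-4s %12.6f %12.6f %12.6f", parts$element,
                     parts$pos[, 1] * 10, parts$pos[, 2] * 10,
                     parts$pos[, 3] * 10))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ file
#' @param path Input file.
#' @return List with `atoms` (element), `pos` (nm), `box = NULL`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("truncated XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ atom count at line 1")
  if (length(lines) < n + 2) {
    stop("truncated XYZ file: expected ", n + 2, " lines, got ", length(lines))
  }
  toks <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  bad <- which(vapply(toks, length, integer(1)) < 4)
  if (length(bad)) stop("malformed XYZ record at line ", bad[1] + 2)
  el <- vapply(toks, `[[`, character(1), 1)
  pos <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3))) / 10
  if (anyNA(pos)) {
    stop("malformed XYZ coordinates at line ",
         which(apply(is.na(pos), 1, any))[1] + 2)
  }
  colnames(pos) <- c("x", "y", "z")
  list(atoms = data.frame(element = el, stringsAsFactors = FALSE),
       pos = pos, box = NULL)
}

#' Read a structure file by format
#'
#' Dispatches on `format` (or the file extension). All readers return
#' positions in nm.
#'
#' @param path Input file.
#' @param format `"gro"`, `"pdb"`, `"xyz"` or `"auto"`.
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("gro", "pdb", "xyz")) {
      stop("unrecognized structure format: ", format)
    }
  }
  switch(format, gro = read_gro(path), pdb = read_pdb(path),
         xyz = read_xyz(path))
}

# normalize sheet / frame / matrix input for the writers
coords_for_io <- function(x, box) {
  if (inherits(x, "nanosheet")) {
    pos <- sheet_positions(x)
    parts <- list(pos = pos, name = x$atoms$element,
                  element = x$atoms$element,
                  resname = rep("MOS", nrow(pos)),
                  resno = rep(1L, nrow(pos)))
  } else if (inherits(x, "md_frame")) {
    nm <- x$topology$name
    parts <- list(pos = x$pos, name = nm, element = x$topology$element,
                  resname = ifelse(x$topology$group == "sheet", "MOS",
                                   ifelse(x$topology$group == "water", "SOL", "LIP")),
                  resno = ifelse(is.na(x$topology$lipid_id), 1L,
                                 x$topology$lipid_id))
    if (is.null(box)) box <- x$box
  } else if (is.matrix(x)) {
    parts <- list(pos = x, name = rep("X", nrow(x)),
                  element = rep("X", nrow(x)),
                  resname = rep("UNK", nrow(x)), resno = rep(1L, nrow(x)))
  } else {
    stop("cannot write object of class ", paste(class(x), collapse = "/"))
  }
  if (is.null(box)) {
    ext <- apply(parts$pos, 2, function(v) diff(range(v)))
    box <- ext + 2
  }
  parts$box <- box
  parts
}

guess_element <- function(name) {
  up <- toupper(name)
  ifelse(substr(up, 1, 2) == "MO", "Mo",
         ifelse(substr(up, 1, 1) == "S" & substr(up, 1, 2) != "SO", "S",
                ifelse(substr(up, 1, 1) == "O", "O",
                       ifelse(substr(up, 1, 1) == "H", "H",
                              ifelse(substr(up, 1, 1) == "C", "C",
                                     substr(name, 1, 2))))))
}

#' Write a trajectory as concatenated GRO frames or a binary stream
#'
#' GRO: one GRO block per frame (title carries the time). Binary stream
#' layout (little-endian): magic bytes `SMTRJ1`, int32 n_atoms, int32
#' n_frames, 3 x float64 box; then per frame one float64 time followed by
#' 3 x n_atoms float32 positions (row-major x,y,z per atom). The reader
#' round-trips the stream exactly at float32 precision.
#'
#' @param traj An [md_trajectory()].
#' @param path Output file.
#' @param format `"bin"` or `"gro"`.
#' @export
write_trajectory <- function(traj, path, format = c("bin", "gro")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "md_trajectory"))
  if (format == "gro") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(traj$times)) {
      fr <- traj_frame(traj, i)
      tmp <- tempfile(fileext = ".gro")
      write_gro(fr, tmp, title = sprintf("frame t= %.6f ps", traj$times[i]))
      writeLines(readLines(tmp), con)
      unlink(tmp)
    }
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SMTRJ1"), con)
  writeBin(as.integer(c(nrow(traj$topology), length(traj$times))), con,
           size = 4, endian = "little")
  writeBin(as.double(traj$box), con, size = 8, endian = "little")
  for (i in seq_along(traj$times)) {
    writeBin(as.double(traj$times[i]), con, size = 8, endian = "little")
    writeBin(as.vector(t(traj$frames[[i]])), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @param topology Topology to attach to the read trajectory (the binary
#'   stream stores coordinates only).
#' @export
read_trajectory_bin <- function(path, topology = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6))
  if (magic != "SMTRJ1") stop("not a sheetmem binary trajectory: ", path)
  hdr <- readBin(con, "integer", 2, size = 4, endian = "little")
  n_atoms <- hdr[1]; n_frames <- hdr[2]
  box <- readBin(con, "double", 3, size = 8, endian = "little")
  times <- numeric(n_frames)
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    times[i] <- readBin(con, "double", 1, size = 8, endian = "little")
    p <- readBin(con, "double", 3 * n_atoms, size = 4, endian = "little")
    if (length(p) < 3 * n_atoms) stop("truncated trajectory stream: frame ", i)
    m <- matrix(p, ncol = 3, byrow = TRUE)
    colnames(m) <- c("x", "y", "z")
    frames[[i]] <- m
  }
  if (is.null(topology)) {
    topology <- data.frame(name = rep("X", n_atoms), element = "X",
                           group = "sheet", region = NA_character_,
                           leaflet = NA_character_, lipid_id = NA_integer_,
                           chain_index = NA_integer_, mass = 1,
                           stringsAsFactors = FALSE)
  }
  md_trajectory(topology, times, frames, box)
}
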