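# Multi-model PDB reading and writing.
#
# Frames are plain data.frames (one row per atom) carrying chain_id,
# residue_number, residue_name, atom_name, element and x/y/z in Angstrom,
# with attributes frame_index (0-based) and time_ns. A trajectory is a list
# of frames with class "pore_trajectory". Fixed-column parsing at the PDB
# standard's 0.001 A coordinate precision; insertion codes and altlocs are
# rejected rather than silently dropped.

# residue names recognised as water across common MD exporters
WATER_RESNAMES <- c("HOH", "TIP3", "SOL", "WAT")

#' Construct a structure frame
#'
#' Builds a single trajectory frame from per-atom vectors. Mostly used by the
#' synthetic generator and by tests; files go through [read_multimodel_pdb()].
#'
#' @param chain_id character vector of single-character chain labels.
#' @param residue_number integer vector (1-based).
#' @param residue_name residue labels (3-4 characters).
#' @param atom_name atom labels (e.g. `"CA"`, `"O"`).
#' @param x,y,z coordinates in Angstrom.
#' @param element element symbols; derived from `atom_name` when missing.
#' @param frame_index 0-based index of the frame within its trajectory.
#' @param time_ns time stamp in nanoseconds, or `NA`.
#' @return A `structure_frame` (a data.frame of atoms).
#' @export
structure_frame <- function(chain_id, residue_number, residue_name, atom_name,
                            x, y, z, element = NULL,
                            frame_index = 0L, time_ns = NA_real_) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  rec <- function(v) if (length(v) == 1L) rep(v, n) else v
  chain_id <- rec(chain_id); residue_number <- rec(residue_number)
  residue_name <- rec(residue_name); atom_name <- rec(atom_name)
  if (!is.null(element)) element <- rec(element)
  stopifnot(length(chain_id) == n, length(residue_number) == n,
            length(residue_name) == n, length(atom_name) == n)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stop("non-finite atom coordinates", call. = FALSE)
  if (any(residue_number < 1L))
    stop("residue_number must be >= 1", call. = FALSE)
  if (is.null(element)) element <- substr(gsub("[^A-Za-z].*$", "", atom_name), 1L, 1L)
  fr <- data.frame(chain_id = as.character(chain_id),
                   residue_number = as.integer(residue_number),
                   residue_name = as.character(residue_name),
                   atom_name = as.character(atom_name),
                   element = toupper(as.character(element)),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  attr(fr, "frame_index") <- as.integer(frame_index)
  attr(fr, "time_ns") <- as.numeric(time_ns)
  class(fr) <- c("structure_frame", "data.frame")
  fr
}

#' @noRd
frame_coords <- function(frame) as.matrix(frame[, c("x", "y", "z")])

#' @noRd
is_water_row <- function(frame) frame$residue_name %in% WATER_RESNAMES

#' Read a multi-model PDB file
#'
#' Parses MODEL/ENDMDL-delimited trajectory frames (or a single structure
#' when no MODEL records are present) at fixed-column precision. Insertion
#' codes and alternate locations are not supported and raise an error naming
#' the offending line.
#'
#' @param path path to a PDB file.
#' @return A `pore_trajectory`: list of `structure_frame`s in file order.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_starts <- which(startsWith(lines, "MODEL"))
  if (!any(is_atom)) stop("no atoms found in ", path, call. = FALSE)

  atom_idx <- which(is_atom)
  al <- lines[atom_idx]
  short <- nchar(al) < 54L
  if (any(short))
    stop("malformed ATOM record (truncated) at line ", atom_idx[which(short)[1L]],
         " of ", path, call. = FALSE)
  altloc <- substr(al, 17L, 17L)
  bad <- altloc != " "
  if (any(bad))
    stop("alternate location indicator not supported, line ",
         atom_idx[which(bad)[1L]], " of ", path, call. = FALSE)
  icode <- substr(al, 27L, 27L)
  bad <- icode != " "
  if (any(bad))
    stop("insertion codes not supported, line ", atom_idx[which(bad)[1L]],
         " of ", path, call. = FALSE)

  xs <- suppressWarnings(as.numeric(substr(al, 31L, 38L)))
  ys <- suppressWarnings(as.numeric(substr(al, 39L, 46L)))
  zs <- suppressWarnings(as.numeric(substr(al, 47L, 54L)))
  resno <- suppressWarnings(as.integer(substr(al, 23L, 26L)))
  bad <- !is.finite(xs) | !is.finite(ys) | !is.finite(zs) | is.na(resno)
  if (any(bad))
    stop("malformed ATOM record at line ", atom_idx[which(bad)[1L]],
         " of ", path, call. = FALSE)

  atom_name <- trimws(substr(al, 13L, 16L))
  resname <- trimws(substr(al, 18L, 21L))
  chain <- substr(al, 22L, 22L)
  element <- trimws(substr(al, 77L, 78L))
  element[element == ""] <- substr(gsub("[^A-Za-z].*$", "", atom_name[element == ""]), 1L, 1L)

  if (length(model_starts) == 0L) {
    grp <- rep.int(1L, length(atom_idx))
    n_models <- 1L
  } else {
    grp <- findInterval(atom_idx, model_starts)
    if (any(grp == 0L))
      stop("ATOM record before first MODEL at line ", atom_idx[which(grp == 0L)[1L]],
           " of ", path, call. = FALSE)
    n_models <- length(model_starts)
  }

  frames <- vector("list", n_models)
  split_idx <- split(seq_along(atom_idx), factor(grp, levels = seq_len(n_models)))
  for (m in seq_len(n_models)) {
    ii <- split_idx[[m]]
    if (length(ii) == 0L) stop("MODEL ", m, " contains no atoms in ", path, call. = FALSE)
    frames[[m]] <- structure_frame(chain[ii], resno[ii], resname[ii], atom_name[ii],
                                   xs[ii], ys[ii], zs[ii], element = element[ii],
                                   frame_index = m - 1L)
  }
  structure(frames, class = "pore_trajectory", source = path)
}

#' @noRd
solute_key <- function(frame) {
  w <- is_water_row(frame)
  paste(frame$chain_id[!w], frame$residue_number[!w], frame$atom_name[!w], sep = "|")
}

#' Write frames as a multi-model PDB file
#'
#' Emits one MODEL/ENDMDL block per frame in standard fixed columns.
#' Non-water atoms must have identical identity and ordering across frames;
#' water records may differ per frame (grand-canonical-style counts from the
#' synthetic generator).
#'
#' @param frames a `pore_trajectory` or list of `structure_frame`s.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(frames, path) {
  if (inherits(frames, "structure_frame")) frames <- list(frames)
  if (length(frames) == 0L) stop("no frames to write", call. = FALSE)
  ref <- solute_key(frames[[1L]])
  for (k in seq_along(frames)) {
    if (!identical(solute_key(frames[[k]]), ref))
      stop("inconsistent solute atom ordering at frame ", k, call. = FALSE)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    nm <- fr$atom_name
    nm4 <- ifelse(nchar(nm) >= 4L, substr(nm, 1L, 4L),
                  formatC(paste0(" ", nm), width = -4L))
    serial <- seq_len(nrow(fr)) %% 100000L
    recs <- sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    ifelse(is_water_row(fr), "HETATM", "ATOM"),
                    serial, nm4, fr$residue_name, fr$chain_id,
                    fr$residue_number, fr$x, fr$y, fr$z, 1, 0, fr$element)
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(recs, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @export
print.pore_trajectory <- function(x, ...) {
  cat("trajectory of", length(x), "frames,",
      nrow(x[[1L]]), "atoms in frame 1\n")
  invisible(x)
}
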