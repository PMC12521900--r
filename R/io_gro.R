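#' Configuration frames and trajectories
#'
#' A `frame` is one configuration: an `n x 3` position matrix in nm, an
#' orthorhombic box (three edge lengths, nm) and a time stamp in ps. A
#' `trajectory` is an ordered list of frames with strictly increasing times.
#'
#' @param positions numeric `n x 3` matrix, nm.
#' @param box numeric length-3 vector of box edges, nm.
#' @param time time stamp, ps.
#' @return an object of class `frame`.
#' @export
frame <- function(positions, box, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have 3 columns")
  box <- as.numeric(box)
  if (length(box) == 1) box <- rep(box, 3)
  if (any(box <= 0)) stop("box edges must be positive")
  structure(list(positions = positions, box = box, time = time), class = "frame")
}

#' @param frames list of `frame` objects with a common particle count.
#' @rdname frame
#' @export
trajectory <- function(frames) {
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  np <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (length(unique(np)) > 1) stop("all frames must have the same particle count")
  structure(list(frames = frames, times = times), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d particles, t = %.4g .. %.4g ps\n",
              length(x$frames), nrow(x$frames[[1]]$positions),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Read a GRO configuration file
#'
#' Fixed-column GRO dialect: title line, atom count, one 44+ character line
#' per atom with positions in columns 21-44 (three F8.3 fields, nm), then the
#' box line. Velocity fields, if present, are ignored. Files holding several
#' concatenated configurations can be read as a trajectory with
#' [read_gro_trajectory()].
#'
#' @param path file to read.
#' @return a list with `labels` (atom name strings) and `frame` (a [frame()]).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  parsed <- parse_gro_block(lines, 1L, path)
  list(labels = parsed$labels, frame = parsed$frame)
}

parse_gro_block <- function(lines, start, path) {
  if (length(lines) < start + 2) stop("truncated GRO file: ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[start + 1])))
  if (is.na(natoms))
    stop(sprintf("malformed atom count on line %d of %s", start + 1, path))
  atom_lines <- lines[(start + 2):(start + 1 + natoms)]
  if (length(atom_lines) != natoms || anyNA(atom_lines))
    stop(sprintf("GRO block starting at line %d of %s is shorter than its atom count",
                 start, path))
  x <- as.numeric(substr(atom_lines, 21, 28))
  y <- as.numeric(substr(atom_lines, 29, 36))
  z <- as.numeric(substr(atom_lines, 37, 44))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("malformed coordinate field in GRO block of ", path)
  labels <- trimws(substr(atom_lines, 11, 15))
  box <- as.numeric(strsplit(trimws(lines[start + 2 + natoms]), "\\s+")[[1]])[1:3]
  if (anyNA(box)) stop("malformed box line in ", path)
  time <- 0
  tt <- regmatches(lines[start], regexec("t= *([-0-9.eE+]+)", lines[start]))[[1]]
  if (length(tt) == 2) time <- as.numeric(tt[2])
  list(labels = labels,
       frame = frame(cbind(x, y, z), box, time),
       next_line = start + 3L + natoms)
}

#' @rdname read_gro
#' @export
read_gro_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1L; labels <- NULL
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    parsed <- parse_gro_block(lines, i, path)
    frames[[length(frames) + 1L]] <- parsed$frame
    labels <- parsed$labels
    i <- parsed$next_line
  }
  traj <- trajectory(frames)
  traj$labels <- labels
  traj
}

#' Write a GRO configuration file
#'
#' @param fr a [frame()].
#' @param path output path; opened in append mode when `append = TRUE` so
#'   trajectories can be streamed frame by frame.
#' @param labels atom name strings, recycled to the particle count.
#' @param title title line content.
#' @param append append a configuration instead of overwriting.
#' @export
write_gro <- function(fr, path, labels = "B", title = "cgmelt configuration",
                      append = FALSE) {
  n <- nrow(fr$positions)
  labels <- rep_len(labels, n)
  res_id <- seq_len(n) %% 100000L
  lines <- c(
    sprintf("%s, t= %.4f", title, fr$time),
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            res_id, "MOL", substr(labels, 1, 5), seq_len(n) %% 100000L,
            fr$positions[, 1], fr$positions[, 2], fr$positions[, 3]),
    sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]))
  con <- file(path, if (append) "a" else "w")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' @param traj a [trajectory()].
#' @rdname write_gro
#' @export
write_gro_trajectory <- function(traj, path, labels = "B") {
  writeLines(character(0), path)
  for (fr in traj$frames) write_gro(fr, path, labels = labels, append = TRUE)
  invisible(path)
}
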