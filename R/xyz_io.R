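# Multi-frame XYZ trajectory reader/writer. The comment line carries
# `s=<arclength>` when a reaction_path is written, so paths round-trip.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr")

element_symbol <- function(z) {
  if (any(z < 1L | z > length(.element_symbols)))
    stop("unsupported atomic number: ", paste(z[z < 1L | z > length(.element_symbols)], collapse = ", "))
  .element_symbols[z]
}

atomic_number <- function(sym) {
  z <- match(sym, .element_symbols)
  if (any(is.na(z))) stop("unknown element symbol: ", paste(sym[is.na(z)], collapse = ", "))
  z
}

#' Read a (multi-frame) XYZ file
#'
#' @param file path to an XYZ file (atom-count line, comment line, then one
#'   `element x y z` line per atom, repeated per frame).
#' @return list of frames; each frame is a list with `atomic_numbers`,
#'   `coords` (N x 3 matrix) and `comment`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  lines <- lines[!(seq_along(lines) > suppressWarnings(max(which(nzchar(trimws(lines))), 0)))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    comment <- if (i + 1L <= length(lines)) lines[i + 1L] else ""
    block <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(block), "\\s+")
    sym <- vapply(tok, `[[`, character(1), 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- list(atomic_numbers = atomic_number(sym),
                                          coords = xyz, comment = comment)
    i <- i + 2L + n
  }
  frames
}

#' Write frames to a multi-frame XYZ file
#'
#' @param frames list of frames as returned by [read_xyz()], or a single
#'   frame; each needs `atomic_numbers` and `coords`.
#' @param file output path.
#' @export
write_xyz <- function(frames, file) {
  if (!is.null(frames$coords)) frames <- list(frames)
  con <- file(file, "w")
  on.exit(close(con))
  for (f in frames) {
    coords <- f$coords
    writeLines(as.character(nrow(coords)), con)
    writeLines(if (is.null(f$comment)) "" else f$comment, con)
    sym <- element_symbol(f$atomic_numbers)
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f",
                       sym, coords[, 1], coords[, 2], coords[, 3]), con)
  }
  invisible(file)
}

#' Write a reaction path as an XYZ trajectory
#'
#' The per-frame comment line records the arclength as `s=<value>`.
#'
#' @param path a `reaction_path` with atomic numbers.
#' @param file output path.
#' @export
write_xyz_path <- function(path, file) {
  if (is.null(path$atomic_numbers))
    stop("path has no atomic numbers; cannot write XYZ")
  frames <- lapply(seq_len(nrow(path$points)), function(k) {
    list(atomic_numbers = path$atomic_numbers,
         coords = coords_to_matrix(path$points[k, ]),
         comment = sprintf("s=%.10f", path$arclengths[k]))
  })
  write_xyz(frames, file)
}

#' Read a reaction path from an XYZ trajectory
#'
#' @param file path to a multi-frame XYZ file.
#' @param label optional path label.
#' @return a `reaction_path`.
#' @export
read_xyz_path <- function(file, label = NULL) {
  frames <- read_xyz(file)
  build_path(lapply(frames, `[[`, "coords"),
             atomic_numbers = frames[[1L]]$atomic_numbers, label = label)
}
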