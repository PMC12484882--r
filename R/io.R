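# Conformation file I/O: XYZ (plain and multi-frame) and SDF (V2000).

element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe")

symbol_to_z <- function(sym) {
  z <- match(sym, element_symbols)
  if (anyNA(z))
    stop("unknown element symbol(s): ",
         paste(unique(sym[is.na(z)]), collapse = ", "))
  z
}

z_to_symbol <- function(z) {
  if (any(z < 1L | z > length(element_symbols)))
    stop("atomic number out of supported range: ",
         paste(z[z < 1L | z > length(element_symbols)], collapse = ", "))
  element_symbols[z]
}

#' Read conformations from an XYZ file
#'
#' Supports multi-frame XYZ; each frame becomes one conformation.
#'
#' @param path file path.
#' @return list of [conformation()] objects.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    frame <- frame + 1L
    comment <- if (i + 1L <= length(lines)) trimws(lines[i + 1L]) else ""
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    sym <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3L)))
    out[[frame]] <- conformation(symbol_to_z(sym), xyz,
                                 mol_id = if (nzchar(comment)) comment
                                          else paste0("frame", frame))
    i <- i + 2L + n
  }
  out
}

#' Write conformations (or a trajectory) to a multi-frame XYZ file
#'
#' @param confs a [conformation()], a list of them, or a list of position
#'   matrices combined with `elements`.
#' @param path output path.
#' @param elements atomic numbers, required when `confs` holds bare
#'   position matrices (e.g. a relaxation trajectory).
#' @return the path, invisibly.
#' @export
write_xyz <- function(confs, path, elements = NULL) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(confs)) {
    fr <- confs[[k]]
    if (is.matrix(fr)) {
      if (is.null(elements))
        stop("elements required when writing bare position matrices")
      pos <- fr; el <- elements; id <- paste0("frame", k)
    } else {
      pos <- fr$positions; el <- fr$elements; id <- fr$mol_id
    }
    writeLines(c(as.character(nrow(pos)), id,
                 sprintf("%-3s %14.8f %14.8f %14.8f",
                         z_to_symbol(el), pos[, 1L], pos[, 2L], pos[, 3L])),
               con)
  }
  invisible(path)
}

#' Read conformations from an SDF (V2000) file
#'
#' Parsing is delegated to the ChemmineR package.
#'
#' @param path file path.
#' @return list of [conformation()] objects.
#' @export
read_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF files requires the ChemmineR package")
  sdfs <- ChemmineR::read.SDFset(path)
  lapply(seq_along(sdfs), function(k) {
    sdf <- sdfs[[k]]
    ab <- ChemmineR::atomblock(sdf)
    sym <- sub("_.*$", "", rownames(ab))
    conformation(symbol_to_z(sym), ab[, 1:3, drop = FALSE],
                 mol_id = ChemmineR::sdfid(sdfs[k]))
  })
}
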