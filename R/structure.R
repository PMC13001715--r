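# Coordinate-file parsing. Heavy lifting (ATOM/HETATM records, mmCIF atom
# loops) is delegated to bio3d; the CRYST1 record and mmCIF cell/symmetry
# items are read directly because bio3d does not surface them.

.parse_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(ln) == 0) return(NULL)
  ln <- ln[1]
  cell <- as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                       substr(ln, 25, 33), substr(ln, 34, 40),
                       substr(ln, 41, 47), substr(ln, 48, 54)))
  names(cell) <- c("a", "b", "c", "alpha", "beta", "gamma")
  list(cell = cell, space_group = trimws(substr(ln, 56, 66)))
}

.parse_cif_cell <- function(path) {
  lines <- readLines(path, warn = FALSE)
  val <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), lines, value = TRUE)
    if (length(ln) == 0) return(NA)
    trimws(sub(paste0("^", key), "", ln[1]))
  }
  a <- as.numeric(val("_cell\\.length_a"))
  if (is.na(a)) return(NULL)
  cell <- c(a = a,
            b = as.numeric(val("_cell\\.length_b")),
            c = as.numeric(val("_cell\\.length_c")),
            alpha = as.numeric(val("_cell\\.angle_alpha")),
            beta = as.numeric(val("_cell\\.angle_beta")),
            gamma = as.numeric(val("_cell\\.angle_gamma")))
  sg <- val("_symmetry\\.space_group_name_H-M")
  if (is.na(sg)) sg <- val("_space_group\\.name_H-M_alt")
  list(cell = cell, space_group = gsub("^['\"]|['\"]$", "", sg))
}

# Altloc policy: one atom per (chain, resno, insert, resid, name) key,
# keeping the highest occupancy; ties resolved in favour of altloc 'A'.
.resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               atoms$name, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    sub <- atoms[idx, ]
    best <- which(sub$occ == max(sub$occ))
    if (length(best) > 1) {
      a <- which(sub$alt[best] == "A")
      if (length(a)) best <- best[a]
    }
    idx[best[1]]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Parse a macromolecular coordinate file
#'
#' Reads all atoms of the first model of a PDB or mmCIF file (heteroatoms,
#' metals and waters included), resolves alternate locations (highest
#' occupancy wins, ties go to altloc 'A'), and records the unit cell and
#' space group when present. A missing cell is not an error here; it only
#' becomes one when [min_symmetry_contact()] is called.
#'
#' @param path coordinate file path.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by file extension).
#' @return A `cu_structure`: list with `atoms` (data.frame: serial, name,
#'   element, resid, resno, chain, x/y/z in Angstrom, occ, b, alt, hetatm),
#'   `unit_cell` (named a,b,c,alpha,beta,gamma or NULL), `space_group`
#'   (Hermann-Mauguin symbol or NA) and `id`.
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "CRYST1   93.430   93.430  141.750  90.00  90.00 120.00 P 61",
#'   "ATOM      1  N   ASP A   1       1.000   2.000   3.000  1.00 10.00           N",
#'   "END"), pdb)
#' s <- parse_structure(pdb)
#' s$unit_cell
parse_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE,
                                         rm.alt = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("cannot parse '", path, "' as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- raw$atom
  if (nrow(at) == 0) stop("no atoms in '", path, "'", call. = FALSE)
  ele <- toupper(trimws(as.character(at$elesy)))
  miss <- is.na(ele) | ele == ""
  if (any(miss)) {
    ele[miss] <- toupper(suppressWarnings(bio3d::atom2ele(at$elety[miss])))
  }
  occ <- at$o
  occ[is.na(occ)] <- 1
  occ <- pmin(pmax(occ, 0), 1)
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = ele,
    resid = trimws(at$resid), resno = at$resno,
    chain = ifelse(is.na(at$chain), "", at$chain),
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z, occ = occ, b = at$b,
    alt = ifelse(is.na(at$alt), "", at$alt),
    hetatm = at$type == "HETATM",
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in '", path, "'", call. = FALSE)
  if (any(atoms$element == ""))
    stop("atoms with empty element symbol in '", path, "'", call. = FALSE)
  atoms <- .resolve_altlocs(atoms)
  rownames(atoms) <- NULL
  cr <- if (format == "pdb") .parse_cryst1(path) else .parse_cif_cell(path)
  if (!is.null(cr)) {
    if (any(cr$cell[1:3] <= 0) || any(cr$cell[4:6] <= 0) ||
        any(cr$cell[4:6] >= 180))
      stop("invalid unit cell in '", path, "'", call. = FALSE)
  }
  structure(list(atoms = atoms,
                 unit_cell = if (is.null(cr)) NULL else cr$cell,
                 space_group = if (is.null(cr)) NA_character_ else cr$space_group,
                 id = basename(path)),
            class = "cu_structure")
}

#' @export
print.cu_structure <- function(x, ...) {
  cat("<cu_structure>", x$id, "\n")
  cat("  atoms:", nrow(x$atoms), "\n")
  if (!is.null(x$unit_cell)) {
    cat("  cell:", paste(format(x$unit_cell, digits = 6), collapse = " "),
        " space group:", x$space_group, "\n")
  } else {
    cat("  cell: absent\n")
  }
  invisible(x)
}
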