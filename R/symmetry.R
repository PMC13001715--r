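# Crystallographic symmetry: embedded operator table (general positions
# from the International Tables), fractional/orthogonal conversion and
# minimum symmetry-image contact distances.

.sg_ops <- local({
  op <- function(R, t) list(R = matrix(R, 3, 3, byrow = TRUE), t = t)
  list(
    "P1" = list(op(c(1, 0, 0, 0, 1, 0, 0, 0, 1), c(0, 0, 0))),
    # P61 (no. 169): 6_1 screw along c.
    "P61" = list(
      op(c(1, 0, 0, 0, 1, 0, 0, 0, 1), c(0, 0, 0)),
      op(c(0, -1, 0, 1, -1, 0, 0, 0, 1), c(0, 0, 1 / 3)),
      op(c(-1, 1, 0, -1, 0, 0, 0, 0, 1), c(0, 0, 2 / 3)),
      op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(0, 0, 1 / 2)),
      op(c(0, 1, 0, -1, 1, 0, 0, 0, 1), c(0, 0, 5 / 6)),
      op(c(1, -1, 0, 1, 0, 0, 0, 0, 1), c(0, 0, 1 / 6))),
    # P212121 (no. 19).
    "P212121" = list(
      op(c(1, 0, 0, 0, 1, 0, 0, 0, 1), c(0, 0, 0)),
      op(c(1, 0, 0, 0, -1, 0, 0, 0, -1), c(1 / 2, 1 / 2, 0)),
      op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(0, 1 / 2, 1 / 2)),
      op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(1 / 2, 0, 1 / 2))))
})

.normalize_sg <- function(symbol) gsub("[ _]", "", toupper(symbol))

#' Symmetry operators of a supported space group
#'
#' Returns the general-position operators (fractional rotation matrix and
#' translation) with the identity first. Supported groups: P1, P61,
#' P212121.
#'
#' @param space_group Hermann-Mauguin symbol (spaces optional, e.g.
#'   `"P 61"` or `"P61"`).
#' @return List of `list(R = 3x3 matrix, t = length-3 vector)` in
#'   fractional coordinates.
#' @export
#' @examples
#' length(symmetry_ops("P 61"))  # 6
symmetry_ops <- function(space_group) {
  key <- .normalize_sg(space_group)
  ops <- .sg_ops[[key]]
  if (is.null(ops))
    stop("unsupported space group: ", space_group,
         " (supported: ", paste(names(.sg_ops), collapse = ", "), ")",
         call. = FALSE)
  ops
}

#' Crystallographic orthogonalisation matrix
#'
#' Standard convention with the a axis along Cartesian x and b in the
#' x-y plane: Cartesian = M %*% fractional.
#'
#' @param cell named numeric vector `(a, b, c, alpha, beta, gamma)` with
#'   lengths in Angstrom and angles in degrees.
#' @return 3x3 orthogonalisation matrix.
#' @export
orthogonalization_matrix <- function(cell) {
  stopifnot(length(cell) == 6, all(cell[1:3] > 0),
            all(cell[4:6] > 0), all(cell[4:6] < 180))
  a <- cell[[1]]; b <- cell[[2]]; cc <- cell[[3]]
  al <- cell[[4]] * pi / 180; be <- cell[[5]] * pi / 180
  ga <- cell[[6]] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, cc * v / sin(ga)), 3, 3, byrow = TRUE)
}

.resolve_selection <- function(selection, atoms) {
  idx <- if (is.function(selection)) which(selection(atoms))
  else if (is.logical(selection)) which(selection)
  else as.integer(selection)
  if (length(idx) == 0) stop("empty atom selection", call. = FALSE)
  if (any(idx < 1 | idx > nrow(atoms)))
    stop("selection index out of range", call. = FALSE)
  idx
}

#' Minimum distance to a crystallographic symmetry image
#'
#' Applies every space-group operator combined with lattice translations
#' in `[-shell, +shell]^3` to all atoms and returns the minimum distance
#' between any selected atom and any atom of any non-identity image (the
#' identity operator with zero lattice shift is excluded).
#'
#' @param structure a [parse_structure()] result with unit cell and a
#'   supported space group.
#' @param selection atom predicate: a function of the atom data.frame
#'   returning a logical vector, a logical vector, or integer row indices.
#' @param shell lattice translation range (default 1 -> 27 cells).
#' @return List: `distance` (Angstrom), `sel_serial`, `image_serial`,
#'   `op` (operator index), `shift` (lattice translation).
#' @export
min_symmetry_contact <- function(structure, selection, shell = 1) {
  stopifnot(inherits(structure, "cu_structure"))
  if (is.null(structure$unit_cell))
    stop("no cell: structure has no unit cell; cannot build symmetry images",
         call. = FALSE)
  if (is.na(structure$space_group))
    stop("no space group recorded in structure", call. = FALSE)
  ops <- symmetry_ops(structure$space_group)
  atoms <- structure$atoms
  sel <- .resolve_selection(selection, atoms)
  M <- orthogonalization_matrix(structure$unit_cell)
  Minv <- solve(M)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  frac <- xyz %*% t(Minv)
  sxyz <- xyz[sel, , drop = FALSE]
  shifts <- as.matrix(expand.grid(-shell:shell, -shell:shell, -shell:shell))
  best <- list(distance = Inf)
  for (k in seq_along(ops)) {
    base <- frac %*% t(ops[[k]]$R)
    for (s in seq_len(nrow(shifts))) {
      tv <- ops[[k]]$t + shifts[s, ]
      if (k == 1 && all(tv == 0)) next
      img <- sweep(base, 2, tv, "+") %*% t(M)
      # squared distances selected x image, vectorised
      d2 <- outer(rowSums(sxyz^2), rowSums(img^2), "+") -
        2 * sxyz %*% t(img)
      mn <- which.min(d2)
      if (d2[mn] < best$distance^2) {
        i <- (mn - 1) %% nrow(sxyz) + 1
        j <- (mn - 1) %/% nrow(sxyz) + 1
        best <- list(distance = sqrt(max(d2[mn], 0)),
                     sel_serial = atoms$serial[sel[i]],
                     image_serial = atoms$serial[j],
                     op = k, shift = unname(unlist(shifts[s, ])))
      }
    }
  }
  best
}
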