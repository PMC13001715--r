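# Metal-site detection, canonical labelling, Cu-Cu distance tables and
# disulfide counting.

.known_elements <- c(
  "H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE", "NA", "MG", "AL",
  "SI", "P", "S", "CL", "AR", "K", "CA", "SC", "TI", "V", "CR", "MN", "FE",
  "CO", "NI", "CU", "ZN", "GA", "GE", "AS", "SE", "BR", "KR", "RB", "SR",
  "Y", "ZR", "NB", "MO", "RU", "RH", "PD", "AG", "CD", "IN", "SN", "SB",
  "TE", "I", "XE", "CS", "BA", "W", "RE", "OS", "IR", "PT", "AU", "HG",
  "TL", "PB", "BI", "U")

# Canonical albumin Cu sites keyed by the residue numbers of their donor
# spheres: ATCUN (Asp1-Thr2-His3), site B (His9/Asp13), site A
# (His67/His246/Asp248), His287/Glu152, His317/Asp211, His509/Glu564.
.canonical_sites <- list(
  ATCUN = c(1, 2, 3), siteB = c(9, 13), siteA = c(67, 246, 248),
  H287 = c(152, 287), H317 = c(211, 317), H509 = c(509, 564))

#' Canonical albumin Cu site labels
#'
#' @return Named list mapping the six canonical site labels to the donor
#'   residue numbers that identify them.
#' @export
canonical_site_labels <- function() .canonical_sites

.assign_site_labels <- function(sites) {
  taken <- character()
  for (i in seq_along(sites)) {
    resnos <- unique(sites[[i]]$donors$resno)
    hits <- vapply(.canonical_sites,
                   function(rs) length(intersect(rs, resnos)), integer(1))
    hits[names(hits) %in% taken] <- 0L
    if (any(hits > 0)) {
      lab <- names(hits)[which.max(hits)]
      sites[[i]]$label <- lab
      taken <- c(taken, lab)
    }
  }
  n_auto <- 0
  for (i in seq_along(sites)) {
    if (is.na(sites[[i]]$label)) {
      n_auto <- n_auto + 1
      sites[[i]]$label <- paste0("site", n_auto)
    }
  }
  sites
}

#' Detect metal sites and their donor spheres
#'
#' One site per metal atom of the requested element. Donors are protein or
#' water N, O and S atoms within `donor_cutoff` Angstrom of the metal
#' (hydrogens and other metal atoms excluded), sorted by distance. Sites
#' are ordered by their first (lowest) donor residue number, matching the
#' convention of listing sites in numerical order along the chain, and are
#' mapped to the canonical albumin labels (ATCUN, siteA, siteB, H287,
#' H317, H509) when their donor residue numbers identify them; unmatched
#' sites get `"siteN"` labels.
#'
#' @param structure a [parse_structure()] result.
#' @param element metal element symbol (default `"Cu"`).
#' @param donor_cutoff donor search radius in Angstrom. The default 3.0 A
#'   covers Cu-N/Cu-O coordination bonds with thermal scatter.
#' @return List of `metal_site` objects: `label`, `metal` (one-row atom
#'   data.frame), `donors` (data.frame with serial, name, element, resid,
#'   resno, chain, dist), `site_index`. Empty list when the structure
#'   contains no such metal.
#' @export
detect_metal_sites <- function(structure, element = "Cu", donor_cutoff = 3.0) {
  stopifnot(inherits(structure, "cu_structure"), donor_cutoff > 0)
  el <- toupper(element)
  if (!el %in% .known_elements)
    stop("unknown element symbol: ", element, call. = FALSE)
  atoms <- structure$atoms
  midx <- which(atoms$element == el)
  if (length(midx) == 0) return(list())
  didx <- which(atoms$element %in% c("N", "O", "S"))
  dxyz <- as.matrix(atoms[didx, c("x", "y", "z")])
  sites <- lapply(midx, function(i) {
    d <- sqrt(colSums((t(dxyz) - as.numeric(atoms[i, c("x", "y", "z")]))^2))
    sel <- which(d <= donor_cutoff)
    sel <- sel[order(d[sel])]
    donors <- cbind(atoms[didx[sel], c("serial", "name", "element", "resid",
                                       "resno", "chain")],
                    dist = d[sel])
    rownames(donors) <- NULL
    structure(list(label = NA_character_, metal = atoms[i, ],
                   donors = donors, site_index = NA_integer_),
              class = "metal_site")
  })
  ord <- order(vapply(sites, function(s) {
    if (nrow(s$donors)) min(s$donors$resno) else Inf
  }, numeric(1)), vapply(sites, function(s) s$metal$serial, numeric(1)))
  sites <- sites[ord]
  for (i in seq_along(sites)) sites[[i]]$site_index <- i
  .assign_site_labels(sites)
}

#' @export
print.metal_site <- function(x, ...) {
  cat("<metal_site>", x$label, "-", x$metal$element,
      "serial", x$metal$serial, "with", nrow(x$donors), "donors\n")
  if (nrow(x$donors)) {
    cat(paste0("  ", x$donors$resid, x$donors$resno, ":", x$donors$name,
               " @ ", round(x$donors$dist, 2), " A", collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Pairwise metal-metal distance table (nm)
#'
#' Euclidean distances between the metal atoms of the given sites,
#' converted from Angstrom to nm (exactly x 0.1).
#'
#' @param sites list of metal sites from [detect_metal_sites()].
#' @return Symmetric `distance_table` matrix (nm) with zero diagonal,
#'   labelled by site.
#' @export
pairwise_distances <- function(sites) {
  if (length(sites) < 2)
    stop("need at least 2 sites for a distance table", call. = FALSE)
  xyz <- t(vapply(sites, function(s)
    as.numeric(s$metal[, c("x", "y", "z")]), numeric(3)))
  m <- as.matrix(stats::dist(xyz)) * 0.1
  labs <- vapply(sites, function(s) s$label, character(1))
  dimnames(m) <- list(labs, labs)
  structure(m, class = c("distance_table", "matrix"))
}

#' Count disulfide bridges
#'
#' Counts unordered CYS SG -- CYS SG pairs within `sg_cutoff` Angstrom.
#' Each SG participates in at most one bridge; pairs are matched greedily
#' from the shortest distance up, which is deterministic and correct for
#' well-separated bridges.
#'
#' @param structure a [parse_structure()] result.
#' @param sg_cutoff S-S bond cutoff in Angstrom (default 2.5).
#' @return Integer count (0 when there are no cysteines).
#' @export
count_disulfides <- function(structure, sg_cutoff = 2.5) {
  stopifnot(inherits(structure, "cu_structure"))
  atoms <- structure$atoms
  sg <- atoms[atoms$resid == "CYS" & atoms$name == "SG", , drop = FALSE]
  n <- nrow(sg)
  if (n < 2) return(0L)
  d <- as.matrix(stats::dist(sg[, c("x", "y", "z")]))
  pairs <- which(upper.tri(d) & d <= sg_cutoff, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(0L)
  pairs <- pairs[order(d[pairs]), , drop = FALSE]
  used <- logical(n)
  count <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used[i] && !used[j]) {
      used[i] <- used[j] <- TRUE
      count <- count + 1L
    }
  }
  count
}
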