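# Plain-text readers and writers: two-column traces, distance tables,
# HYSCORE matrices, spin-system YAML. All files are TSV-style with '#'
# comment headers so they survive version control and diffing.

#' Write a two-column trace to a plain-text file
#'
#' @param path output file path.
#' @param x,y numeric vectors of equal length (e.g. time and amplitude).
#' @param header optional character vector of metadata lines, written as
#'   `# key value` comments before the data.
#' @return `path`, invisibly.
#' @export
write_trace <- function(path, x, y, header = character()) {
  stopifnot(length(x) == length(y))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  write.table(data.frame(x = x, y = y), con, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column trace written by [write_trace()]
#'
#' @param path input file path.
#' @return data.frame with columns `x` and `y`; header comment lines are
#'   returned in the `"header"` attribute.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- sub("^#\\s*", "", grep("^#", lines, value = TRUE))
  d <- read.table(path, comment.char = "#", col.names = c("x", "y"))
  attr(d, "header") <- hdr
  d
}

#' Read an experimental distance distribution from two-column text
#'
#' Reads `(r nm, density)` pairs and renormalizes to unit trapezoidal
#' integral, returning a [distance_distribution()] tagged `"experimental"`.
#'
#' @param path input file path.
#' @param source provenance tag for the resulting distribution.
#' @return a `distance_distribution`.
#' @export
read_distribution <- function(path, source = "experimental") {
  d <- read_trace(path)
  distance_distribution(d$x, d$y, source = source)
}

#' Write a distance distribution as two-column text
#'
#' @param dist a [distance_distribution()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "distance_distribution"))
  write_trace(path, dist$r, dist$density,
              header = paste("source", dist$source))
}

#' Write a pairwise Cu-Cu distance table as TSV
#'
#' Distances are written in nm to 3 decimals with site labels as the
#' header row and first column.
#'
#' @param table a `distance_table` from [pairwise_distances()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_distance_table <- function(table, path) {
  m <- format(round(unclass(table), 3), nsmall = 3, trim = TRUE)
  df <- data.frame(site = rownames(table), m, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a distance table written by [write_distance_table()]
#'
#' @param path input file path.
#' @return a symmetric `distance_table` matrix (nm).
#' @export
read_distance_table <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  structure(m, class = c("distance_table", "matrix"))
}

#' Write a metal-site report as TSV
#'
#' One row per donor: site label, metal serial, donor residue, donor atom
#' and donor distance in Angstrom.
#'
#' @param sites list of metal sites from [detect_metal_sites()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(sites, path) {
  rows <- lapply(sites, function(s) {
    if (nrow(s$donors) == 0) return(NULL)
    data.frame(site = s$label, metal_serial = s$metal$serial,
               donor_residue = paste0(s$donors$resid, s$donors$resno),
               donor_atom = s$donors$name,
               distance_A = round(s$donors$dist, 2))
  })
  write.table(do.call(rbind, rows), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a HYSCORE time matrix with axis headers
#'
#' @param data a [hyscore_data()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hyscore <- function(data, path) {
  stopifnot(inherits(data, "hyscore_data"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# tau_ns", data$tau),
               paste("# t1_ns", paste(data$t1, collapse = " ")),
               paste("# t2_ns", paste(data$t2, collapse = " "))), con)
  write.table(data$matrix, con, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a HYSCORE matrix written by [write_hyscore()]
#'
#' @param path input file path.
#' @return a [hyscore_data()] object.
#' @export
read_hyscore <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(key) {
    ln <- grep(paste0("^#\\s*", key), lines, value = TRUE)[1]
    as.numeric(strsplit(trimws(sub(paste0("^#\\s*", key), "", ln)), "\\s+")[[1]])
  }
  m <- as.matrix(read.table(path, comment.char = "#"))
  dimnames(m) <- NULL
  hyscore_data(grab("t1_ns"), grab("t2_ns"), m, tau = grab("tau_ns")[1])
}

#' Read an axial spin system from a YAML config
#'
#' Expected keys: `g_par`, `g_perp`, `A_par_mhz`, `A_perp_mhz`,
#' `gauss_fwhm` (G), optional `label`.
#'
#' @param path YAML file path.
#' @return a [spin_system()].
#' @export
read_spin_system <- function(path) {
  y <- yaml::read_yaml(path)
  spin_system(g_par = y$g_par, g_perp = y$g_perp,
              A_par_mhz = y$A_par_mhz, A_perp_mhz = y$A_perp_mhz,
              gauss_fwhm = if (is.null(y$gauss_fwhm)) 30 else y$gauss_fwhm,
              label = if (is.null(y$label)) "" else y$label)
}
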