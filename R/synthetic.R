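# Synthetic-data generators: a decoy albumin-like structure whose six Cu
# sites honour the published distance envelopes, CW titration series,
# ESEEM/HYSCORE traces, and RIDME fixtures, plus a manifest writer. Every
# generator is a pure function of (spec, seed): identical inputs give
# identical bytes.

#' Specification for the decoy six-site structure
#'
#' Constrained anchors (defaults): ATCUN-siteB 1.8 nm (the short edge of
#' the 1.5-2.0 nm band), ATCUN-H287 3.5 nm, all H317 pairs within
#' 4.0-4.9 nm, all H509 pairs within 4.5-7.6 nm. Unconstrained pairs are
#' whatever the embedding produces; no full distance table is invented.
#'
#' @param seed RNG seed controlling the rigid placement and donor radii.
#' @param atcun_siteB_nm,atcun_h287_nm constrained distances in nm.
#' @param h317_range_nm,h509_range_nm allowed envelopes in nm.
#' @return A `decoy_spec` list.
#' @export
decoy_spec <- function(seed = 1, atcun_siteB_nm = 1.8, atcun_h287_nm = 3.5,
                       h317_range_nm = c(4.0, 4.9),
                       h509_range_nm = c(4.5, 7.6)) {
  structure(list(seed = seed, atcun_siteB_nm = atcun_siteB_nm,
                 atcun_h287_nm = atcun_h287_nm,
                 h317_range_nm = h317_range_nm,
                 h509_range_nm = h509_range_nm),
            class = "decoy_spec")
}

# Base Cu coordinates (Angstrom) realising the default anchors exactly:
# |ATCUN-siteB| = 18, |ATCUN-H287| = 35 (7-24-25 triangle scaled),
# H317 at 41.4-43.8 from its four partners, H509 at 48.2-73.5 / 57.4.
.decoy_cu_base <- function(spec) {
  u287 <- c(28, 21, 0) / 35
  rbind(ATCUN = c(0, 0, 0),
        siteB = c(10 * spec$atcun_siteB_nm, 0, 0),
        siteA = c(0, 20, 0),
        H287 = 10 * spec$atcun_h287_nm * u287,
        H317 = c(14, 10, -40),
        H509 = c(50, -30, -20))
}

# Donor shells: residue name/number/atom/element per site; waters at siteA.
.decoy_donors <- list(
  ATCUN = data.frame(resid = c("ASP", "THR", "HIS"), resno = c(1, 2, 3),
                     name = c("N", "N", "NE2"), element = c("N", "N", "N"),
                     het = FALSE),
  siteB = data.frame(resid = c("HIS", "ASP"), resno = c(9, 13),
                     name = c("NE2", "OD1"), element = c("N", "O"),
                     het = FALSE),
  siteA = data.frame(resid = c("HIS", "HIS", "ASP", "HOH"),
                     resno = c(67, 246, 248, 701),
                     name = c("NE2", "NE2", "OD1", "O"),
                     element = c("N", "N", "O", "O"),
                     het = c(FALSE, FALSE, FALSE, TRUE)),
  H287 = data.frame(resid = c("GLU", "HIS"), resno = c(152, 287),
                    name = c("OE1", "NE2"), element = c("O", "N"),
                    het = FALSE),
  H317 = data.frame(resid = c("ASP", "HIS"), resno = c(211, 317),
                    name = c("OD1", "NE2"), element = c("O", "N"),
                    het = FALSE),
  H509 = data.frame(resid = c("HIS", "GLU"), resno = c(509, 564),
                    name = c("NE2", "OE1"), element = c("N", "O"),
                    het = FALSE))

# Fixed unit directions for placing donors around each Cu.
.donor_dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))

.check_decoy_anchors <- function(cu, spec) {
  d <- as.matrix(stats::dist(cu)) * 0.1
  resid <- c(abs(d["ATCUN", "siteB"] - spec$atcun_siteB_nm),
             abs(d["ATCUN", "H287"] - spec$atcun_h287_nm))
  h317 <- d["H317", c("ATCUN", "siteA", "siteB", "H287")]
  h509 <- d["H509", c("ATCUN", "siteA", "siteB", "H287", "H317")]
  ok <- all(resid < 1e-6) &&
    all(h317 >= spec$h317_range_nm[1] & h317 <= spec$h317_range_nm[2]) &&
    all(h509 >= spec$h509_range_nm[1] & h509 <= spec$h509_range_nm[2])
  if (!ok) {
    stop("decoy constraints unsatisfiable with this spec; residuals: ",
         paste(signif(resid, 3), collapse = ", "),
         "; H317 range ", paste(signif(range(h317), 3), collapse = "-"),
         "; H509 range ", paste(signif(range(h509), 3), collapse = "-"),
         call. = FALSE)
  }
  invisible(d)
}

.pdb_atom_line <- function(record, serial, name, resid, chain, resno,
                           xyz, occ, b, element) {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, "", resid, chain, resno, "",
          xyz[1], xyz[2], xyz[3], occ, b, element)
}

#' Generate the decoy six-site structure and write it as PDB
#'
#' Places six Cu ions at coordinates realising the constrained distance
#' anchors exactly, applies a seeded rigid rotation and translation
#' (distance-preserving), surrounds each Cu with 2-4 donor atoms (His
#' NE2 / Asp OD1-style names, canonical albumin residue numbers) at
#' 2.0-2.3 Angstrom, and writes a P1 PDB with a box enclosing all atoms
#' plus a 20 Angstrom margin. Anchor residuals are checked before
#' writing; violated constraints raise an error with a residual report.
#'
#' @param spec a [decoy_spec()].
#' @param path output PDB path (default: a tempfile).
#' @return The parsed `cu_structure`, invisibly carrying the file path in
#'   the `"path"` attribute.
#' @export
#' @examples
#' decoy <- make_decoy_structure(decoy_spec(seed = 1))
#' length(detect_metal_sites(decoy))  # 6
make_decoy_structure <- function(spec = decoy_spec(),
                                 path = tempfile(fileext = ".pdb")) {
  stopifnot(inherits(spec, "decoy_spec"))
  cu <- .decoy_cu_base(spec)
  .check_decoy_anchors(cu, spec)
  set.seed(spec$seed)
  # seeded proper rotation (QR of a random matrix, det fixed to +1)
  qrd <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  cu <- cu %*% t(Q)
  labels <- rownames(cu)
  atoms <- list()
  serial <- 0
  for (i in seq_along(labels)) {
    lab <- labels[i]
    don <- .decoy_donors[[lab]]
    radii <- runif(nrow(don), 2.0, 2.3)
    for (j in seq_len(nrow(don))) {
      serial <- serial + 1
      pos <- cu[i, ] + radii[j] * as.numeric(.donor_dirs[j, ] %*% t(Q))
      atoms[[length(atoms) + 1]] <- list(
        record = if (don$het[j]) "HETATM" else "ATOM",
        serial = serial, name = don$name[j], resid = don$resid[j],
        chain = "A", resno = don$resno[j], xyz = pos, occ = 1, b = 20,
        element = don$element[j])
    }
  }
  for (i in seq_along(labels)) {
    serial <- serial + 1
    atoms[[length(atoms) + 1]] <- list(
      record = "HETATM", serial = serial, name = "CU", resid = "CU",
      chain = "A", resno = 600 + i, xyz = cu[i, ], occ = 1, b = 30,
      element = "CU")
  }
  xyz <- do.call(rbind, lapply(atoms, `[[`, "xyz"))
  shift <- 20 - apply(xyz, 2, min)
  box <- apply(xyz, 2, function(v) diff(range(v))) + 40
  lines <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s", box[1], box[2],
            box[3], 90, 90, 90, "P 1"),
    vapply(atoms, function(a)
      .pdb_atom_line(a$record, a$serial, a$name, a$resid, a$chain,
                     a$resno, a$xyz + shift, a$occ, a$b, a$element),
      character(1)),
    "END")
  writeLines(lines, path)
  out <- parse_structure(path, format = "pdb")
  attr(out, "path") <- path
  attr(out, "spec") <- spec
  invisible(out)
}

#' Generate a CW pseudo-titration series
#'
#' Two axial Cu(2+) species: an ATCUN-like species (g_par = 2.198,
#' A_par = 607 MHz) whose weight grows with added equivalents but
#' saturates at 1 equivalent (the high-affinity site is then full), and a
#' secondary His/O-coordinated species taking up the remainder, so the
#' total species weight -- and hence the double integral -- is exactly
#' proportional to the added equivalents. Optional seeded Gaussian noise
#' is scaled to the maximum amplitude of the noiseless series.
#'
#' @param equivalents molar equivalents of added Cu(2+).
#' @param settings a [spectrometer_settings()].
#' @param noise_sigma noise s.d. as a fraction of the maximum amplitude.
#' @param seed optional RNG seed.
#' @param n_orientations powder quadrature nodes per species.
#' @param atcun_fraction fraction of the first equivalent bound at the
#'   ATCUN-like site.
#' @return List with `spectra` (list of `cw_spectrum`), `equivalents`,
#'   `weights` (species weight matrix) and `systems`.
#' @export
make_cw_titration <- function(equivalents = seq(0.5, 5, by = 0.5),
                              settings = spectrometer_settings(),
                              noise_sigma = 0, seed = NULL,
                              n_orientations = 301,
                              atcun_fraction = 0.4) {
  atcun <- spin_system(2.198, 2.05, 607, 60, gauss_fwhm = 25,
                       label = "ATCUN")
  secondary <- spin_system(2.30, 2.06, 480, 40, gauss_fwhm = 35,
                           label = "secondary")
  sp_a <- powder_spectrum(atcun, settings, n_orientations)
  sp_s <- powder_spectrum(secondary, settings, n_orientations)
  w_a <- atcun_fraction * pmin(equivalents, 1)
  w_s <- equivalents - w_a
  spectra <- Map(function(wa, ws) superpose(list(sp_a, sp_s), c(wa, ws)),
                 w_a, w_s)
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    amp <- max(vapply(spectra, function(s) max(abs(s$intensity)),
                      numeric(1)))
    spectra <- lapply(spectra, function(s) {
      s$intensity <- s$intensity +
        rnorm(length(s$intensity), 0, noise_sigma * amp)
      s
    })
  }
  list(spectra = spectra, equivalents = equivalents,
       weights = cbind(ATCUN = w_a, secondary = w_s),
       systems = list(atcun = atcun, secondary = secondary))
}

#' Write an ESEEM fixture file
#'
#' Thin wrapper around [simulate_nqi_eseem()] that writes the trace as
#' two-column text with metadata headers.
#'
#' @param path output file path.
#' @param seed RNG seed (also recorded in the header).
#' @param ... passed to [simulate_nqi_eseem()].
#' @return The simulated [eseem_trace()], invisibly.
#' @export
make_eseem_fixture <- function(path, seed = 1, ...) {
  tr <- simulate_nqi_eseem(seed = seed, ...)
  write_trace(path, tr$T_ns, tr$amplitude,
              header = c(paste("tau_ns", tr$tau_ns),
                         paste("dwell_ns", tr$dwell_ns),
                         paste("seed", seed)))
  invisible(tr)
}

#' Write a HYSCORE fixture file
#'
#' @param path output file path.
#' @param seed RNG seed.
#' @param ... passed to [simulate_hyscore_tones()].
#' @param nu1_mhz,nu2_mhz tone frequencies in MHz.
#' @return The simulated [hyscore_data()], invisibly.
#' @export
make_hyscore_fixture <- function(path, seed = 1, ..., nu1_mhz = 4,
                                 nu2_mhz = 7) {
  hd <- simulate_hyscore_tones(nu1_mhz, nu2_mhz, seed = seed, ...)
  write_hyscore(hd, path)
  invisible(hd)
}

#' Write a RIDME fixture built from a decoy occupancy configuration
#'
#' Builds the decoy structure, extracts its Cu-Cu distance table,
#' simulates the Gaussian distance distribution of the given occupancy
#' configuration (sigma = 0.1 nm, equal pair amplitudes) and writes the
#' corresponding RIDME trace. Inverting the fixture recovers the
#' configuration's pair distances (e.g. the 3.5 nm ATCUN-H287 mode).
#'
#' @param path output file path.
#' @param seed RNG seed for both the decoy and the trace noise.
#' @param config occupied site labels.
#' @param bg a [background_model()].
#' @param t_us time grid in us.
#' @param noise_sigma trace noise s.d.
#' @param r_grid distance grid for the simulated distribution.
#' @return List with the trace, the distribution and the distance table,
#'   invisibly.
#' @export
make_ridme_fixture <- function(path, seed = 1,
                               config = c("ATCUN", "siteB", "H287"),
                               bg = background_model(),
                               t_us = seq(0, 2.2, length.out = 140),
                               noise_sigma = 0.02,
                               r_grid = seq(1, 10, by = 0.02)) {
  decoy <- make_decoy_structure(decoy_spec(seed = seed))
  sites <- detect_metal_sites(decoy)
  tab <- pairwise_distances(sites)
  P <- simulate_distribution(config, tab, sigma = 0.1, r_grid = r_grid)
  tr <- simulate_ridme(P, bg = bg, t_us = t_us,
                       noise_sigma = noise_sigma, seed = seed)
  write_trace(path, tr$t_us, tr$signal,
              header = c(paste("config", paste(config, collapse = ",")),
                         paste("lambda", bg$lambda),
                         paste("seed", seed)))
  invisible(list(trace = tr, distribution = P, table = tab))
}

#' Generate the full fixture set with a manifest
#'
#' Writes the decoy PDB, an ESEEM trace, a HYSCORE matrix and a RIDME
#' trace under `dir`, plus `manifest.tsv` listing every file with its
#' seed.
#'
#' @param dir output directory (created if absent).
#' @param seed base RNG seed.
#' @return data.frame manifest, invisibly.
#' @export
make_fixture_set <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(decoy = "decoy.pdb", eseem = "eseem.txt",
             hyscore = "hyscore.txt", ridme = "ridme.txt")
  make_decoy_structure(decoy_spec(seed = seed),
                       path = file.path(dir, files["decoy"]))
  make_eseem_fixture(file.path(dir, files["eseem"]), seed = seed,
                     noise_sigma = 0.005)
  make_hyscore_fixture(file.path(dir, files["hyscore"]), seed = seed)
  make_ridme_fixture(file.path(dir, files["ridme"]), seed = seed)
  manifest <- data.frame(file = unname(files), kind = names(files),
                         seed = seed)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
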