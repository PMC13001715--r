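# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: the spin-Hamiltonian oracle diagonalizes
# the full 8x8 matrix, the kernel oracle is a midpoint Riemann sum, and
# the symmetry oracle materialises every image atom explicitly.

# --- minimal PDB fixture writer (independent of the package's writer) ---

pdb_line <- function(record, serial, name, resid, chain, resno, x, y, z,
                     occ = 1, b = 10, element = substr(name, 1, 1),
                     alt = "") {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resid, chain, resno, x, y, z, occ, b,
          element)
}

write_mini_pdb <- function(lines, cryst1 = NULL,
                           path = tempfile(fileext = ".pdb")) {
  writeLines(c(cryst1, lines, "END"), path)
  path
}

cubic_cryst1 <- function(a, sg = "P 1") {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s", a, a, a,
          90, 90, 90, sg)
}

# --- 8x8 spin-Hamiltonian oracle for S = 1/2, I = 3/2 -------------------

.ladder <- function(s) {
  m <- seq(s, -s)
  n <- length(m)
  Sp <- matrix(0, n, n)
  for (i in 2:n) Sp[i - 1, i] <- sqrt(s * (s + 1) - m[i] * (m[i] + 1))
  list(Sx = (Sp + t(Sp)) / 2, Sy = (Sp - t(Sp)) / (2i), Sz = diag(m))
}

# Exact resonance fields for effective scalar g and isotropic coupling A
# (MHz) at microwave frequency nu (GHz): root-find the field where each
# delta-mS = 1, delta-mI = 0 transition matches h nu.
oracle_resonance_fields <- function(g, A_mhz, nu_ghz,
                                    interval = c(1000, 6000)) {
  h <- 6.62607015e-34
  muB <- 9.2740100783e-24
  S <- .ladder(0.5)
  I <- .ladder(1.5)
  Hhf <- A_mhz * 1e6 * (kronecker(S$Sx, I$Sx) + kronecker(S$Sy, I$Sy) +
                          kronecker(S$Sz, I$Sz))
  Hz <- kronecker(S$Sz, diag(4))
  SzOp <- kronecker(S$Sz, diag(4))
  IzOp <- kronecker(diag(2), I$Sz)
  trans <- function(B_g) {
    H <- (g * muB * B_g * 1e-4 / h) * Hz + Hhf
    ev <- eigen(H, symmetric = TRUE)
    mS <- Re(diag(Conj(t(ev$vectors)) %*% SzOp %*% ev$vectors))
    mI <- Re(diag(Conj(t(ev$vectors)) %*% IzOp %*% ev$vectors))
    up <- order(mI[mS > 0])
    lo <- order(mI[mS < 0])
    list(f = ev$values[mS > 0][up] - ev$values[mS < 0][lo],
         mI = round(2 * mI[mS > 0][up]) / 2)
  }
  nu <- nu_ghz * 1e9
  B <- vapply(1:4, function(k) {
    stats::uniroot(function(b) trans(b)$f[k] - nu, interval,
                   tol = 1e-9)$root
  }, numeric(1))
  data.frame(m_I = trans(mean(B))$mI, field = B)
}

# --- brute-force symmetry-contact oracle --------------------------------

oracle_min_contact <- function(structure, sel_idx, shell = 1) {
  ops <- symmetry_ops(structure$space_group)
  M <- orthogonalization_matrix(structure$unit_cell)
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  frac <- xyz %*% t(solve(M))
  best <- Inf
  for (k in seq_along(ops)) {
    for (i1 in -shell:shell) for (i2 in -shell:shell)
      for (i3 in -shell:shell) {
        tv <- ops[[k]]$t + c(i1, i2, i3)
        if (k == 1 && all(tv == 0)) next
        img <- sweep(frac %*% t(ops[[k]]$R), 2, tv, "+") %*% t(M)
        for (s in sel_idx) {
          d <- sqrt(rowSums(sweep(img, 2, xyz[s, ])^2))
          best <- min(best, d)
        }
      }
  }
  best
}

# --- local maxima of a spectrum -----------------------------------------

find_peaks <- function(x, y, min_height = 0.05 * max(y)) {
  i <- which(diff(sign(diff(y))) == -2) + 1
  i <- i[y[i] >= min_height]
  data.frame(x = x[i], y = y[i])
}

# Frequency of the highest point within +/- win of f0.
peak_near <- function(freq, mag, f0, win = 0.35) {
  sel <- which(abs(freq - f0) <= win)
  freq[sel[which.max(mag[sel])]]
}

# FWHM of the dominant peak of a sampled density.
fwhm_of <- function(r, p) {
  i <- which.max(p)
  h <- p[i] / 2
  lo <- max(which(p[1:i] <= h))
  hi <- i - 1 + min(which(p[i:length(p)] <= h))
  r[hi] - r[lo]
}
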