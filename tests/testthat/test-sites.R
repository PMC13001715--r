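toy_cu_site <- function() {
  # one Cu with a His NE2 exactly 2.0 A away, plus a far-away O
  write_mini_pdb(c(
    pdb_line("ATOM", 1, "NE2", "HIS", "A", 3, 2.0, 0, 0, element = "N"),
    pdb_line("ATOM", 2, "OD1", "ASP", "A", 50, 9.0, 0, 0, element = "O"),
    pdb_line("HETATM", 3, "CU", "CU", "A", 601, 0, 0, 0, element = "CU")))
}

test_that("donor spheres are found within the cutoff and sorted", {
  s <- parse_structure(toy_cu_site())
  sites <- detect_metal_sites(s)
  expect_length(sites, 1)
  expect_equal(nrow(sites[[1]]$donors), 1)
  expect_equal(sites[[1]]$donors$dist, 2.0, tolerance = 1e-6)
  expect_equal(sites[[1]]$donors$name, "NE2")
  # widen cutoff: both donors, ascending distance
  sites2 <- detect_metal_sites(s, donor_cutoff = 10)
  expect_equal(sites2[[1]]$donors$dist, c(2, 9), tolerance = 1e-6)
})

test_that("no metals gives an empty list; unknown element errors", {
  p <- write_mini_pdb(pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0,
                               element = "C"))
  s <- parse_structure(p)
  expect_identical(detect_metal_sites(s), list())
  expect_error(detect_metal_sites(s, element = "Xx"), "unknown element")
})

test_that("site detection is invariant to atom input order", {
  lines <- c(
    pdb_line("ATOM", 1, "NE2", "HIS", "A", 3, 2.0, 0, 0, element = "N"),
    pdb_line("ATOM", 2, "NE2", "HIS", "A", 9, 30, 0, 0, element = "N"),
    pdb_line("HETATM", 3, "CU", "CU", "A", 601, 0, 0, 0, element = "CU"),
    pdb_line("HETATM", 4, "CU", "CU", "A", 602, 31.9, 0, 0,
             element = "CU"))
  s1 <- parse_structure(write_mini_pdb(lines))
  s2 <- parse_structure(write_mini_pdb(rev(lines)))
  fp <- function(s) lapply(detect_metal_sites(s), function(x)
    list(x$label, x$donors$resno, round(x$donors$dist, 6)))
  expect_identical(fp(s1), fp(s2))
})

test_that("pairwise distances convert Angstrom to nm exactly", {
  p <- write_mini_pdb(c(
    pdb_line("ATOM", 1, "NE2", "HIS", "A", 3, 2.0, 0, 0, element = "N"),
    pdb_line("ATOM", 2, "NE2", "HIS", "A", 9, 33, 0, 0, element = "N"),
    pdb_line("HETATM", 3, "CU", "CU", "A", 601, 0, 0, 0, element = "CU"),
    pdb_line("HETATM", 4, "CU", "CU", "A", 602, 35, 0, 0,
             element = "CU")))
  sites <- detect_metal_sites(parse_structure(p))
  tab <- pairwise_distances(sites)
  expect_equal(tab[1, 2], 3.5)
  expect_equal(tab[1, 2] * 10, 35)  # nm -> A round trip, exactly x 0.1
  expect_error(pairwise_distances(sites[1]), "at least 2")
})

test_that("distance tables are symmetric with zero diagonal (random sets)", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    xyz <- matrix(runif(3 * n, 0, 60), ncol = 3)
    lines <- c(
      vapply(seq_len(n), function(i)
        pdb_line("HETATM", i, "CU", "CU", "A", 600 + i, xyz[i, 1],
                 xyz[i, 2], xyz[i, 3], element = "CU"), character(1)))
    sites <- detect_metal_sites(parse_structure(write_mini_pdb(lines)))
    tab <- unclass(pairwise_distances(sites))
    expect_equal(tab, t(tab))
    expect_equal(unname(diag(tab)), rep(0, n))
    expect_true(all(tab[upper.tri(tab)] > 0))
  }
})

test_that("disulfide counting pairs each SG at most once, greedily", {
  two <- write_mini_pdb(c(
    pdb_line("ATOM", 1, "SG", "CYS", "A", 10, 0, 0, 0, element = "S"),
    pdb_line("ATOM", 2, "SG", "CYS", "A", 20, 2.04, 0, 0, element = "S")))
  expect_equal(count_disulfides(parse_structure(two)), 1L)
  # three mutually close SG: greedy pairing leaves one unpaired
  three <- write_mini_pdb(c(
    pdb_line("ATOM", 1, "SG", "CYS", "A", 10, 0, 0, 0, element = "S"),
    pdb_line("ATOM", 2, "SG", "CYS", "A", 20, 2.0, 0, 0, element = "S"),
    pdb_line("ATOM", 3, "SG", "CYS", "A", 30, 1.0, 1.5, 0,
             element = "S")))
  expect_equal(count_disulfides(parse_structure(three)), 1L)
  # no cysteines
  none <- write_mini_pdb(pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0,
                                  element = "C"))
  expect_equal(count_disulfides(parse_structure(none)), 0L)
})

test_that("disulfide count is invariant under chain relabelling", {
  mk <- function(chains) write_mini_pdb(c(
    pdb_line("ATOM", 1, "SG", "CYS", chains[1], 10, 0, 0, 0,
             element = "S"),
    pdb_line("ATOM", 2, "SG", "CYS", chains[2], 20, 2.04, 0, 0,
             element = "S"),
    pdb_line("ATOM", 3, "SG", "CYS", chains[3], 30, 40, 0, 0,
             element = "S"),
    pdb_line("ATOM", 4, "SG", "CYS", chains[4], 40, 42.04, 0, 0,
             element = "S")))
  a <- count_disulfides(parse_structure(mk(c("A", "A", "B", "B"))))
  b <- count_disulfides(parse_structure(mk(c("X", "Y", "Z", "W"))))
  expect_equal(a, 2L)
  expect_identical(a, b)
})
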