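test_that("extended XYZ frames parse with cell, pbc and molecule ids", {
  lines <- c(
    "8",
    'Lattice="10 0 0 0 10 0 0 0 10" Properties=species:S:1:pos:R:3:mol:I:1 Time=0.5',
    paste(rep(c("C", "O"), 4), c(0:7), c(0:7) / 2, "0.1", rep(1:4, each = 2)),
    "8",
    'Lattice="10 0 0 0 10 0 0 0 10" Properties=species:S:1:pos:R:3:mol:I:1',
    paste(rep(c("C", "O"), 4), c(0:7) + 1, c(0:7) / 2, "0.2", rep(1:4, each = 2)))
  path <- withr::local_tempfile(fileext = ".extxyz")
  writeLines(lines, path)
  frames <- read_frames(path, "extxyz")
  expect_length(frames, 2L)
  expect_equal(n_atoms(frames[[1]]), 8L)
  expect_equal(frames[[1]]$cell, diag(c(10, 10, 10)))
  expect_equal(frames[[1]]$molecule_ids, rep(1:4, each = 2))
  expect_equal(frames[[1]]$time, 0.5)
  expect_equal(frames[[2]]$positions[1, 1], 1)
})

test_that("LAMMPS dumps map columns and populate molecule ids", {
  lines <- c("ITEM: TIMESTEP", "100", "ITEM: NUMBER OF ATOMS", "4",
             "ITEM: BOX BOUNDS pp pp pp", "0 12", "0 12", "0 12",
             "ITEM: ATOMS id mol type x y z",
             "2 1 C 1 1 1", "1 1 O 0 0 0", "3 2 C 5 5 5", "4 2 O 6 6 6")
  path <- withr::local_tempfile(fileext = ".dump")
  writeLines(lines, path)
  fr <- read_frames(path, "lammps_dump")[[1]]
  expect_equal(fr$molecule_ids, c(1L, 1L, 2L, 2L))
  ## records come back sorted by atom id
  expect_equal(fr$positions[1, ], c(0, 0, 0))
  expect_equal(fr$atom_types, c("O", "C", "C", "O"))
  expect_equal(fr$cell, diag(c(12, 12, 12)))
})

test_that("malformed input errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".extxyz")
  writeLines(c("2", "Properties=species:S:1:pos:R:3", "C 0 0 0", "O 1 bad 0"),
             path)
  expect_error(read_frames(path, "extxyz"), "line 4")
  writeLines(c("2", "Properties=species:S:1:pos:R:3", "Qq 0 0 0", "O 1 0 0"),
             path)
  expect_error(read_frames(path, "extxyz"), "unknown element")
})

test_that("write/read round-trips are idempotent in both dialects", {
  set.seed(42)
  pos <- matrix(runif(150, 0, 12), 50)
  fr <- simulation_frame(pos, rep(c("C", "N", "O", "H", "S"), 10),
                        cell = rbind(c(12, 0, 0), c(1, 12, 0), c(0.5, 0.7, 12)),
                        molecule_ids = rep(1:10, each = 5), time = 2.5)
  for (fmt in c("extxyz", "lammps_dump")) {
    path <- withr::local_tempfile()
    write_frames(fr, path, format = fmt)
    back <- read_frames(path, fmt)[[1]]
    expect_equal(back$positions, fr$positions, tolerance = 1e-6)
    expect_equal(back$atom_types, fr$atom_types)
    expect_equal(back$molecule_ids, fr$molecule_ids)
    expect_equal(back$cell, fr$cell, tolerance = 1e-9)
    ## a second round-trip is bit-stable
    path2 <- withr::local_tempfile()
    write_frames(back, path2, format = fmt)
    again <- read_frames(path2, fmt)[[1]]
    expect_identical(again$positions, back$positions)
  }
})

test_that("group_molecules honors ids, falls back to blocks, checks composition", {
  pos <- matrix(0, 4, 3)
  fr <- simulation_frame(pos, c("C", "O", "C", "O"),
                         molecule_ids = c(1L, 1L, 2L, 2L))
  g <- group_molecules(fr)
  expect_equal(lapply(g, `[[`, "atom_indices"), list(1:2, 3:4))
  ## block mode
  fr2 <- simulation_frame(matrix(0, 16, 3), rep(c("C", "O", "N", "H",
                                                  "H", "H", "H", "O"), 2))
  expect_length(group_molecules(fr2, molecule_size = 8L), 2L)
  expect_error(group_molecules(fr2, molecule_size = 5L), "divisible")
  ## composition check against a template
  expect_error(group_molecules(fr, template = c("C", "N")), "molecule 0")
})

test_that("grouping is invariant to atom permutations when ids are present", {
  set.seed(7)
  res <- make_lattice_polymorph(fixture_polymorphs()$alpha, c(2, 2, 2))
  fr <- res$frame
  perm <- sample(n_atoms(fr))
  fr2 <- simulation_frame(fr$positions[perm, ], fr$atom_types[perm],
                          cell = fr$cell, pbc = fr$pbc,
                          molecule_ids = fr$molecule_ids[perm])
  g1 <- group_molecules(fr)
  g2 <- group_molecules(fr2)
  for (k in seq_along(g1)) {
    expect_equal(sort(perm[g2[[k]]$atom_indices]), g1[[k]]$atom_indices)
    expect_equal(g2[[k]]$species_signature, g1[[k]]$species_signature)
  }
})

test_that("minimum_image matches the exhaustive image search", {
  expect_equal(minimum_image(c(0, 0, 0), diag(3) * 10), c(0, 0, 0))
  expect_equal(minimum_image(c(9, 0, 0), diag(3) * 10), c(-1, 0, 0))
  expect_error(minimum_image(c(1, 1, 1), matrix(1, 3, 3)), "invertible")
  set.seed(11)
  cell <- rbind(c(8, 0, 0), c(2.5, 7, 0), c(-1.5, 2, 9))
  for (i in 1:50) {
    delta <- runif(3, -15, 15)
    expect_equal(minimum_image(delta, cell),
                 oracle_min_image(delta, cell, range = 4L),
                 tolerance = 1e-12)
  }
})

test_that("neighbor lists equal the O(N^2) scalar scan", {
  expect_length(build_neighbor_list(matrix(0, 1, 3), cutoff = 5)$neighbor_ids[[1]],
                0L)
  nl <- build_neighbor_list(rbind(c(0, 0, 0), c(5, 0, 0)), cutoff = 6)
  expect_equal(nl$neighbor_ids, list(2L, 1L))
  expect_equal(nl$distances[[1]], 5)
  set.seed(23)
  for (rep in 1:6) {
    n <- sample(50:200, 1)
    periodic <- rep %% 2 == 0
    cell <- if (periodic) rbind(c(14, 0, 0), c(2, 13, 0), c(0, 1, 15))
    pts <- matrix(runif(n * 3, 0, 13), n)
    cutoff <- runif(1, 3, 5)
    nl <- build_neighbor_list(pts, cell, cutoff)
    got <- nl_pair_keys(nl)
    orc <- oracle_pairs(pts, cell, cutoff)
    expect_setequal(got$keys, orc$keys)
    ord1 <- order(got$keys); ord2 <- order(orc$keys)
    expect_equal(got$dists[ord1], orc$dists[ord2], tolerance = 1e-10)
  }
})

test_that("periodic cutoffs beyond the safe half-width are refused", {
  expect_error(build_neighbor_list(matrix(0, 2, 3), diag(3) * 8, cutoff = 5),
               "half-width")
})
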