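# DNA builder, protein loading, contact derivation and crowder placement.

test_that("ideal B-DNA geometry follows the helical parameters", {
  dna <- build_ideal_bdna(random_dna_sequence(100, seed = 1),
                          rise = 3.4, twist = 34.3)
  ctr <- crowdsearch:::.bp_centers_from(dna$beads, dna$info, dna$n_bp)
  # 99 steps of 3.4 A along z
  expect_equal(max(ctr[, 3]) - min(ctr[, 3]), 99 * 3.4, tolerance = 1e-10)
  expect_equal(diff(ctr[, 3]), rep(3.4, 99), tolerance = 1e-10)
  # 3 beads per nucleotide minus the two missing 5'-terminal phosphates
  expect_equal(nrow(dna$beads), 6 * 100 - 2)
  expect_equal(sum(dna$charges), -(2 * 100 - 2))          # phosphates at -1 e
  expect_equal(dna$target_window, 46:54)                  # centred 9-bp window
})

test_that("DNA builder rejects bad sequences and records the position", {
  expect_error(build_ideal_bdna("ACGTACGTXA"), "position 9")
  expect_error(build_ideal_bdna("ACGT"), "at least 10")
})

test_that("as-built DNA has an all-zero deformation profile", {
  asm <- fix_bound_asm()
  prof <- deformation_profile(static_traj(asm), normalize = FALSE)
  expect_true(all(abs(prof$raw) < 1e-10))
})

test_that("protein loads from PDB with residue charges and CA beads", {
  p <- fix_protein()
  pdb_file <- tempfile(fileext = ".pdb")
  atom <- function(serial, name, res, resno, xyz)
    sprintf("ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, res, resno, xyz[1], xyz[2], xyz[3])
  lines <- unlist(lapply(seq_len(p$n_res), function(i) c(
    atom(2 * i - 1, " N  ", p$residues[i], i, p$beads[i, ] + c(1, 0, 0)),
    atom(2 * i,     " CA ", p$residues[i], i, p$beads[i, ]))))
  writeLines(c(lines, "END"), pdb_file)
  q <- load_protein(pdb_file, chain = "A", recognition_helix = 43:60)
  expect_equal(q$n_res, 60)
  expect_equal(sum(q$residues %in% c("ARG", "LYS")), 6)
  expect_equal(sum(q$residues %in% c("GLU", "ASP")), 4)
  expect_equal(sum(q$charges), 2)                         # net +2 e
  expect_equal(q$beads, p$beads, tolerance = 1e-3, ignore_attr = TRUE)
  # drop one CA -> one fewer bead, with a warning
  writeLines(c(lines[-20], "END"), pdb_file)               # CA of residue 10
  expect_warning(q2 <- load_protein(pdb_file, chain = "A",
                                    recognition_helix = 43:59),
                 "without a C-alpha")
  expect_equal(q2$n_res, 59)
})

test_that("native contacts equal a brute-force all-pairs scan", {
  p <- fix_protein()
  nc <- derive_native_contacts(p, 8)
  d <- as.matrix(dist(p$beads))
  brute <- which(upper.tri(d) & d <= 8 &
                 abs(outer(1:60, 1:60, "-")) >= 4, arr.ind = TRUE)
  expect_equal(nrow(nc), nrow(brute))
  expect_true(all(nc$j - nc$i >= 4))
  expect_equal(nc$r0, d[cbind(nc$i, nc$j)])
  # straight chain at 3.8 A spacing: all |i-j| >= 4 pairs are >= 15.2 A
  straight <- crowdsearch:::.new_protein(cbind(3.8 * (0:19), 0, 0),
                                         rep("ALA", 20), 1:5)
  expect_equal(nrow(derive_native_contacts(straight, 8)), 0)
  expect_equal(nrow(derive_native_contacts(p, 0)), 0)
})

test_that("specific contacts: 18 in the default bound pose, all in-window", {
  dna <- fix_dna40(); prot <- fix_docked()
  sc <- prot$specific_contacts
  expect_equal(nrow(sc), 18)
  expect_true(all(dna$info$bp[sc$dna_bead] %in% dna$target_window))
  # brute-force oracle over (recognition +/- 1 flank) x window beads
  rh <- sort(unique(pmax(1, pmin(60, c(outer(prot$recognition_helix, -1:1, "+"))))))
  win <- which(dna$info$bp %in% dna$target_window)
  d <- crowdsearch:::.cross_dist(prot$beads[rh, ], dna$beads[win, ],
                                 simulation_box(c(1e6, 1e6, 1e6)))
  expect_equal(nrow(sc), sum(d <= 7))
  expect_error(derive_specific_contacts(prot, dna, 0), "not bound")
})

test_that("crowder counting inverts the volume-fraction formula", {
  box <- simulation_box()                                  # 150 x 150 x 400
  expect_equal(as.integer(count_crowders(0.2, 10, box)), 430L)
  expect_equal(as.integer(count_crowders(0.1, 10, box)), 215L)
  expect_equal(as.integer(count_crowders(0, 10, box)), 0L)
  expect_error(count_crowders(0.65, 10, box), "packing")
  n <- count_crowders(0.2, 10, box)
  # realized phi within one crowder volume of the request
  expect_lt(abs(attr(n, "phi_realized") - 0.2),
            4 * pi * 10^3 / (3 * prod(box$lengths)) + 1e-12)
})

test_that("crowder placement is reproducible and overlap-free", {
  box <- simulation_box(c(120, 120, 180))
  a <- place_crowders(124, 10, box, seed = 7)
  b <- place_crowders(124, 10, box, seed = 7)
  expect_identical(a$positions, b$positions)
  expect_equal(place_crowders(0, 10, box)$n, 0)
  # brute-force minimum-image audit across several seeds
  for (s in c(7, 8, 9)) {
    cf <- place_crowders(124, 10, box, seed = s)
    dmin <- min(vapply(seq_len(cf$n - 1), function(i) {
      d <- minimum_image(sweep(cf$positions[(i + 1):cf$n, , drop = FALSE],
                               2, cf$positions[i, ]), box)
      min(rowSums(d^2))
    }, numeric(1)))
    expect_gte(sqrt(dmin), 2 * 10)
  }
  # exclusion beads respected
  excl <- matrix(c(0, 0, 0), 1, 3)
  cf <- place_crowders(60, 10, box, exclusions = excl, exclusion_radius = 5,
                       seed = 1)
  d <- sqrt(rowSums(minimum_image(cf$positions, box)^2))
  expect_true(all(d >= 15))
  # dense packing falls back to the lattice and still satisfies >= 2R
  dense <- place_crowders(248, 10, box, seed = 3)
  expect_equal(dense$n, 248)
})

test_that("assembly archives round-trip through JSON", {
  asm <- fix_bound_asm()
  f <- tempfile(fileext = ".json")
  write_assembly(asm, f)
  back <- read_assembly(f)
  expect_equal(back$positions, asm$positions, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$dna$sequence, asm$dna$sequence)
  expect_equal(back$protein$specific_contacts$r0,
               asm$protein$specific_contacts$r0, tolerance = 1e-12)
  expect_true(back$include_specific)
})
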