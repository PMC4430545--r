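# minimal hand-built frame: one donor-H pair and one acceptor at a
# controlled distance/angle
tiny_frame <- function(da_dist = 3.0, angle = 165, acc_segment = "PEP",
                       acc_resid = 5L) {
  # donor at origin, H along +x; acceptor placed so that the D-H...A angle
  # (vertex at H) equals `angle` and |D - A| = da_dist
  d <- c(0, 0, 0); h <- c(1.0, 0, 0)
  th <- (180 - angle) * pi / 180  # direction of (A - H) vs (H - D) = +x
  # choose r along that direction so that |A - D| = da_dist
  u <- c(cos(th), sin(th), 0)
  f <- function(r) sqrt(sum((h + r * u - d)^2)) - da_dist
  r <- uniroot(f, c(0.1, 20))$root
  a_pos <- h + r * u
  atoms <- data.frame(
    id = 1:3, name = c("N", "H", "O"), element = c("N", "H", "O"),
    resid = c(1L, 1L, acc_resid),
    segment = c("PEP", "PEP", acc_segment),
    role = c("donor", "hydrogen", "acceptor"),
    x = c(d[1], h[1], a_pos[1]), y = c(d[2], h[2], a_pos[2]),
    z = c(d[3], h[3], a_pos[3]))
  structure_frame(atoms, data.frame(hydrogen = 2L, donor = 1L),
                  list(ee = c(1L, 2L)))
}

test_that("detection applies the distance and angle gates", {
  b <- detect_hbonds(tiny_frame(3.0, 165))
  expect_equal(nrow(b), 1)
  expect_equal(b$distance, 3.0, tolerance = 1e-9)
  expect_equal(b$angle, 165, tolerance = 1e-6)
  expect_equal(nrow(detect_hbonds(tiny_frame(5.0, 165))), 0)  # too far
  expect_equal(nrow(detect_hbonds(tiny_frame(3.0, 120))), 0)  # too bent
  # same-residue pairs are never emitted
  fr <- tiny_frame(3.0, 165, acc_resid = 1L)
  expect_equal(nrow(detect_hbonds(fr)), 0)
})

test_that("detection is invariant under rigid motions", {
  fr <- generate_helix_fixture(12)
  b0 <- detect_hbonds(fr)
  set.seed(8)
  for (rep in 1:5) {
    fr2 <- transform_frame(fr, random_rotation(), rnorm(3, sd = 50))
    b1 <- detect_hbonds(fr2)
    expect_equal(nrow(b1), nrow(b0))
    expect_equal(b1$distance, b0$distance, tolerance = 1e-9)
    expect_equal(b1$angle, b0$angle, tolerance = 1e-9)
  }
})

test_that("contacts classify by residue offset and segment flags", {
  fr <- generate_helix_fixture(10)
  counts <- classify_contacts(detect_hbonds(fr), fr)
  expect_equal(counts[["i4"]], 6L)
  expect_equal(sum(counts), 6L)
  # offset 2 -> other_intrapeptide
  fr2 <- tiny_frame(3.0, 165, acc_resid = 3L)
  expect_equal(classify_contacts(detect_hbonds(fr2),
                                 fr2)[["other_intrapeptide"]], 1L)
  # offsets 3 and 5 land in i3/i5
  fr3 <- tiny_frame(3.0, 165, acc_resid = 4L)
  expect_equal(classify_contacts(detect_hbonds(fr3), fr3)[["i3"]], 1L)
  fr5 <- tiny_frame(3.0, 165, acc_resid = 6L)
  expect_equal(classify_contacts(detect_hbonds(fr5), fr5)[["i5"]], 1L)
  # a solvent-flagged partner makes the bond peptide_solvent
  frs <- tiny_frame(3.0, 165, acc_segment = "SOL")
  expect_equal(classify_contacts(detect_hbonds(frs),
                                 frs)[["peptide_solvent"]], 1L)
})

test_that("labelling errors are caught", {
  atoms <- data.frame(id = 1:2, name = c("H", "O"), element = c("H", "O"),
                      resid = c(1L, 2L), segment = "PEP",
                      role = c("hydrogen", "acceptor"),
                      x = c(0, 1), y = 0, z = 0)
  expect_error(structure_frame(atoms, data.frame(hydrogen = integer(0),
                                                 donor = integer(0)),
                               list(ee = c(1L, 2L))),
               "hydrogen")
})

test_that("work-weighted profile reproduces hand-computed weights", {
  # counts {2, 4} with works {0, kT ln 3}: weights {3/4, 1/4} -> mean 2.5
  counts <- array(c(2, 4), dim = c(2, 1, 1),
                  dimnames = list(NULL, NULL, "i4"))
  p <- work_weighted_profile(counts, c(0, kT300 * log(3)), 300)
  expect_equal(unname(p$mean[1, "i4"]), 2.5, tolerance = 1e-12)
  # equal works -> arithmetic mean
  p2 <- work_weighted_profile(counts, c(1.7, 1.7), 300)
  expect_equal(unname(p2$mean[1, "i4"]), 3)
  # single trajectory -> its own counts
  p3 <- work_weighted_profile(array(7, c(1, 1, 1),
                                    dimnames = list(NULL, NULL, "i4")),
                              5, 300)
  expect_equal(unname(p3$mean[1, "i4"]), 7)
  # enormous works must not overflow to 0/0
  p4 <- work_weighted_profile(counts, c(5000, 9000), 300)
  expect_equal(unname(p4$mean[1, "i4"]), 2, tolerance = 1e-6)
})

test_that("weighted means stay inside the raw count envelope", {
  set.seed(30)
  for (rep in 1:20) {
    n_traj <- sample(2:8, 1); n_ext <- sample(2:6, 1)
    counts <- array(rpois(n_traj * n_ext * 3, 3),
                    dim = c(n_traj, n_ext, 3),
                    dimnames = list(NULL, NULL, c("i3", "i4", "i5")))
    works <- matrix(rnorm(n_traj * n_ext, sd = 2), n_traj, n_ext)
    p <- work_weighted_profile(counts, works, 300)
    for (g in seq_len(n_ext)) {
      for (cl in 1:3) {
        expect_gte(p$mean[g, cl], min(counts[, g, cl]) - 1e-9)
        expect_lte(p$mean[g, cl], max(counts[, g, cl]) + 1e-9)
      }
    }
  }
})

test_that("2D histogram conserves mass and matches a brute-force tally", {
  h <- hbond_histogram_2d(3, 5)
  expect_equal(sum(h), 1L)
  expect_equal(h["3", "5"], 1L)
  set.seed(31)
  pp <- sample(0:8, 1000, replace = TRUE)
  ps <- sample(0:12, 1000, replace = TRUE)
  h2 <- hbond_histogram_2d(pp, ps)
  expect_equal(sum(h2), 1000L)
  for (idx in sample(1000, 25)) {
    expect_equal(h2[as.character(pp[idx]), as.character(ps[idx])],
                 sum(pp == pp[idx] & ps == ps[idx]))
  }
  expect_error(hbond_histogram_2d(c(1, -1), c(0, 0)), ">= 0")
})

test_that("effective solvent counts average over a fixed-peptide ensemble", {
  fr <- generate_helix_fixture(10)
  ens <- lapply(1:3, function(s) generate_solvated_fixture(fr, 20, 2, s))
  m <- effective_solvent_hbonds(fr, ens)
  expect_equal(as.numeric(m), 2.0)
  expect_equal(attr(m, "intrapeptide"), 6L)
  # zero placed waters everywhere -> 0.0
  ens0 <- lapply(4:5, function(s) generate_solvated_fixture(fr, 10, 0, s))
  expect_equal(as.numeric(effective_solvent_hbonds(fr, ens0)), 0.0)
  # a moved peptide violates the fixed-structure contract
  bad <- ens
  bad[[2]]$atoms$x[1] <- bad[[2]]$atoms$x[1] + 0.5
  expect_error(effective_solvent_hbonds(fr, bad), "contract violation")
})
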