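hb_frame <- function(d, angle_deg, dh = 0.1) {
  # donor at origin, acceptor along +x; hydrogen placed for the requested
  # D-H-A angle by the triangle construction
  theta <- angle_deg * pi / 180
  ang_A <- asin(min(1, dh * sin(theta) / d))
  ang_D <- pi - theta - ang_A
  H <- c(dh * cos(ang_D), dh * sin(ang_D), 0)
  coords <- rbind(c(0, 0, 0), H, c(d, 0, 0)) + 5
  top <- as_topology(data.frame(
    atom_id = 1:3, atom_name = c("OD", "HD", "OA"), residue_id = c(1, 1, 2),
    species = c("DON", "DON", "ACC"), subregion = "other",
    element = c("O", "H", "O"), mass_amu = c(16, 1, 16),
    vdw_radius_nm = c(0.25, 0.11, 0.25),
    is_donor = c(TRUE, FALSE, FALSE), is_hydrogen = c(FALSE, TRUE, FALSE),
    is_acceptor = c(FALSE, FALSE, TRUE), donor_of = c(NA, 1, NA),
    leaflet_hint = NA))
  list(frame = list(coords = coords, box = c(10, 10, 10)), topology = top)
}

test_that("hydrogen-bond detection applies both geometric criteria", {
  good <- hb_frame(0.28, 180)
  expect_equal(nrow(detect_hbonds(good$frame, good$topology)), 1)
  ang_ok <- hb_frame(0.28, 170)
  expect_equal(nrow(detect_hbonds(ang_ok$frame, ang_ok$topology)), 1)
  ang_bad <- hb_frame(0.28, 120)
  expect_equal(nrow(detect_hbonds(ang_bad$frame, ang_bad$topology)), 0)
  d_bad <- hb_frame(0.305, 170)
  expect_equal(nrow(detect_hbonds(d_bad$frame, d_bad$topology)), 0)

  # reported geometry matches construction
  rec <- detect_hbonds(good$frame, good$topology)
  expect_equal(rec$distance_nm, 0.28, tolerance = 1e-9)
  expect_equal(rec$angle_deg, 180, tolerance = 1e-6)

  # pair filter restricts species pairs
  rec2 <- detect_hbonds(good$frame, good$topology,
                        pair_filter = cbind("PSM", "CHOL"))
  expect_equal(nrow(rec2), 0)
})

test_that("detection is exact on planted geometries (precision = recall = 1)", {
  for (s in 1:5) {
    pl <- plant_hbond_geometries(30, 15, 15, seed = 50 + s)
    rec <- detect_hbonds(pl$frame, pl$topology)
    truth <- pl$truth[pl$truth$is_bond, ]
    found <- paste(rec$hydrogen, rec$acceptor)
    expected <- paste(truth$hydrogen, truth$acceptor)
    expect_setequal(found, expected)
  }
})

test_that("minimum-image convention: detection survives box translations", {
  good <- hb_frame(0.28, 170)
  fr <- good$frame
  fr$coords <- fr$coords + matrix(c(10, 20, -10), 3, 3, byrow = TRUE)
  fr$coords <- wrap_coords(fr$coords, fr$box)
  expect_equal(nrow(detect_hbonds(fr, good$topology)), 1)
})

test_that("hbond_summary aggregates per pair and per donor name over frames", {
  pl <- plant_hbond_geometries(12, 6, 0, seed = 60)
  xyz <- pl$frame$coords
  tr <- trajectory(array(c(xyz, xyz), c(nrow(xyz), 3, 2)), pl$frame$box,
                   time = c(0, 1))
  sm <- hbond_summary(tr, pl$topology)
  expect_equal(sm$per_frame, c(12, 12))
  expect_equal(sm$by_pair$mean[sm$by_pair$key == "DON-ACC"], 12)
  expect_equal(sum(sm$by_donor_name$mean), 12)
})

test_that("contact counts respect the strict cutoff and subregion split", {
  top <- point_topology(3)
  top$subregion <- c("ligand", "phosphate", "tails")
  top$species <- c("LIG", "POPC", "POPC")
  # distances 0.375 and 0.4375 nm are exactly representable in binary,
  # so the strict-inequality convention is tested without rounding slack
  xyz <- rbind(c(1, 1, 1), c(1.375, 1, 1), c(1, 1.4375, 1))
  tr <- one_frame(xyz, c(6, 6, 6))
  cs <- count_contacts(tr, top, 1, 2:3, cutoff = 0.45)
  expect_equal(cs$count, 2L)   # both within a 4.5 A cutoff
  cs2 <- count_contacts(tr, top, 1, 2:3, cutoff = 0.4375)
  expect_equal(cs2$count, 1L)  # pair exactly at the cutoff excluded (strict <)
  cs3 <- count_contacts(tr, top, 1, 2:3, cutoff = 0.375)
  expect_equal(cs3$count, 0L)
  bysub <- count_contacts(tr, top, 1, 2:3, cutoff = 0.5, by_subregion = TRUE)
  expect_equal(bysub$count[bysub$group == "phosphate"], 1L)
  expect_equal(bysub$count[bysub$group == "tails"], 1L)

  # cutoff beyond minimum-image validity refused
  expect_error(count_contacts(tr, top, 1, 2:3, cutoff = 3.5), "half")
})

test_that("cell-list contact counts equal the all-pairs oracle", {
  set.seed(61)
  for (rep in 1:10) {
    box <- c(runif(1, 3, 6), runif(1, 3, 6), runif(1, 3, 6))
    n <- 400
    xyz <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
    top <- point_topology(n)
    tr <- one_frame(xyz, box)
    for (ct in c(0.16, 0.45, 0.5)) {
      g <- count_contacts(tr, top, 1:80, 81:n, cutoff = ct, method = "grid")
      b <- count_contacts(tr, top, 1:80, 81:n, cutoff = ct, method = "brute")
      expect_identical(g$count, b$count)
    }
  }
})

test_that("contact counts are invariant under whole-system box translation", {
  set.seed(62)
  box <- c(5, 5, 5)
  xyz <- matrix(runif(300 * 3, 0, 5), ncol = 3)
  top <- point_topology(300)
  base <- count_contacts(one_frame(xyz, box), top, 1:50, 51:300, cutoff = 0.5)
  shifted <- wrap_coords(sweep(xyz, 2, c(5, -10, 15), "+"), box)
  moved <- count_contacts(one_frame(shifted, box), top, 1:50, 51:300,
                          cutoff = 0.5)
  expect_identical(base$count, moved$count)
})

test_that("minimum distance matches construction and the brute oracle", {
  top <- point_topology(4)
  xyz <- rbind(c(1, 1, 1), c(2, 1, 1), c(1, 3, 1), c(1, 1, 1))
  tr <- one_frame(xyz, c(8, 8, 8))
  expect_equal(min_distance(tr, 1, 2:3), 1.0)
  expect_equal(min_distance(tr, 4, 1), 0)
  # periodic image: 7.5 apart in an 8-box is really 0.5
  xyz2 <- rbind(c(0.25, 1, 1), c(7.75, 1, 1))
  expect_equal(min_distance(one_frame(xyz2, c(8, 8, 8)), 1, 2), 0.5)
})

test_that("strong binding time counts strictly-above-threshold frames", {
  series <- data.frame(frame = 1:4, group = "all",
                       count = c(900, 850, 700, 820))
  bt <- strong_binding_time(series, threshold = 800, dt = 0.1)
  expect_equal(bt$strong_binding_time_ns, 0.3)
  bt0 <- strong_binding_time(data.frame(frame = 1:5, group = "all",
                                        count = rep(800, 5)),
                             threshold = 800, dt = 0.1)
  expect_equal(bt0$strong_binding_time_ns, 0)

  # monotone non-increasing in the threshold; threshold -1 = full length
  counts <- c(0, 500, 801, 900, 100, 1200)
  s <- data.frame(frame = seq_along(counts), group = "all", count = counts)
  times <- vapply(c(-1, 0, 500, 800, 1100),
                  function(th) strong_binding_time(s, th, dt = 1)$strong_binding_time_ns, 0)
  expect_true(all(diff(times) <= 0))
  expect_equal(times[1], length(counts))

  # generator round trip at zero dispersion is exact
  spec <- binding_kinetics_spec(k_on = 0.05, k_off = 0.02, dispersion = 0,
                                n_frames = 5000, dt = 0.1, seed = 63)
  trace <- simulate_binding_trace(spec)
  bt2 <- strong_binding_time(data.frame(frame = seq_along(trace$counts),
                                        group = "all", count = trace$counts),
                             threshold = 800, dt = 0.1)
  expect_equal(bt2$strong_binding_time_ns, trace$bound_time_true)
})

test_that("SASA reproduces the closed form and partitions consistently", {
  # isolated sphere r = 0.2 nm, probe 0.14 nm: total = 4 pi (0.34)^2 nm^2
  top <- point_topology(1, radius = 0.2)
  sp <- sasa_partition(list(coords = matrix(c(5, 5, 5), 1), box = c(10, 10, 10)),
                       top, ligand = 1)
  expect_equal(sp$total, 4 * pi * 3.4^2, tolerance = 1e-6)
  expect_equal(sp$solvent, sp$total)
  expect_equal(sp$headgroup + sp$tails + sp$solvent, sp$total,
               tolerance = 1e-9)

  # occlusion is monotone: a close partner reduces per-atom SASA
  top2 <- point_topology(2, radius = 0.2)
  top2$subregion <- c("ligand", "tails")
  sp2 <- sasa_partition(list(coords = rbind(c(5, 5, 5), c(5.5, 5, 5)),
                             box = c(10, 10, 10)), top2, ligand = 1)
  expect_lt(sp2$total, sp$total)
  expect_gt(sp2$tails, 0)   # exposed points facing the partner are tail-contact
  expect_equal(sp2$headgroup + sp2$tails + sp2$solvent, sp2$total,
               tolerance = 1e-9)

  # attribution switches with the neighbour's subregion tag
  top3 <- top2; top3$subregion <- c("ligand", "phosphate")
  sp3 <- sasa_partition(list(coords = rbind(c(5, 5, 5), c(5.5, 5, 5)),
                             box = c(10, 10, 10)), top3, ligand = 1)
  expect_equal(sp3$headgroup, sp2$tails, tolerance = 1e-9)
  expect_equal(sp3$tails, 0)
})

test_that("SASA point sampling is self-converged at the default density", {
  set.seed(64)
  n <- 30
  xyz <- matrix(rnorm(n * 3, 5, 0.25), ncol = 3)
  top <- point_topology(n, radius = 0.17)
  fr <- list(coords = xyz, box = c(10, 10, 10))
  a960 <- sasa_partition(fr, top, ligand = seq_len(n), n_points = 960)
  a10k <- sasa_partition(fr, top, ligand = seq_len(n), n_points = 10000)
  expect_lt(abs(a960$total - a10k$total) / a10k$total, 0.02)
})
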