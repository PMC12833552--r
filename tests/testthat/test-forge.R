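test_that("interface topology is built deterministically with the declared contents", {
  spec <- interface_spec(2, n_bulk_waters = 5)
  top <- build_interface_topology(spec)
  top2 <- build_interface_topology(spec)
  expect_identical(top, top2)
  expect_setequal(unique(top$atoms$chain[!top$atoms$is_water]), c("A", "B"))
  expect_equal(length(unique(paste(top$atoms$chain, top$atoms$resno)[
    top$atoms$is_water])), 5)
  # every polar donor-capable atom carries at least one attached hydrogen
  da <- assign_donors_acceptors(top)
  expect_true(all(top$atoms$element[da$donors$hydrogen] == "H"))
  expect_true(all(da$donors$donor %in%
                    which(top$atoms$element %in% c("N", "O", "S"))))
  # backbone of one chain in a 2-residue synthetic chain: 4 atoms/residue
  expect_length(select_atoms(top, "chain A and backbone"), 8)
  # water selection: 3 atoms per water group
  expect_length(select_atoms(top, "water"), 15)
})

test_that("invalid interface specs are rejected with the violated invariant named", {
  expect_error(interface_spec(0), "n_residues_per_chain")
  expect_error(interface_spec(2, noise_sigma = -1), "noise_sigma")
  expect_error(interface_spec(2, chain_separation = 5), "chain_separation")
  expect_error(interface_spec(2, donor_sites = 5), "site")
})

test_that("bridge schedules honour their occupancy targets and seeds", {
  # degenerate schedule: occupancy 1 -> always on
  m <- simulate_bridge_schedule(list(planted_bridge(1, 1, occupancy = 1)),
                                100, seed = 5)
  expect_true(all(m$bridges[[1]]$on))
  expect_equal(m$bridges[[1]]$realized, 1)

  # binomial oracle: realized occupancy within 3*sqrt(p(1-p)/n) of target
  m2 <- simulate_bridge_schedule(list(planted_bridge(1, 1, occupancy = 0.7)),
                                 2000, seed = 11)
  expect_lt(abs(m2$bridges[[1]]$realized - 0.7), 3 * sqrt(0.7 * 0.3 / 2000))

  # markov schedule: stationary occupancy validated, realized close to it
  expect_error(planted_bridge(1, 1, occupancy = 0.5, schedule = "markov",
                              p_on = 0.1, p_off = 0.2), "stationary")
  mk <- planted_bridge(1, 1, occupancy = 1 / 3, schedule = "markov",
                       p_on = 0.1, p_off = 0.2)
  m3 <- simulate_bridge_schedule(list(mk), 4000, seed = 2)
  expect_lt(abs(m3$bridges[[1]]$realized - 1 / 3), 0.06)

  # seed determinism
  m4 <- simulate_bridge_schedule(list(planted_bridge(1, 1, occupancy = 0.4)),
                                 500, seed = 9)
  m5 <- simulate_bridge_schedule(list(planted_bridge(1, 1, occupancy = 0.4)),
                                 500, seed = 9)
  expect_identical(m4$bridges[[1]]$on, m5$bridges[[1]]$on)
  expect_error(simulate_bridge_schedule(list(planted_bridge(1, 1)), 0, 1),
               "n_frames")
})

test_that("rendered bridge geometry sits inside the criteria with margin", {
  sys <- tiny_system(list(planted_bridge(1, 1, order = 1),
                          planted_bridge(2, 2, order = 2)),
                     n_frames = 3, noise = 0)
  hb <- detect_hbonds(sys$trajectory$coords[[1]],
                      assign_donors_acceptors(sys$topology)$donors,
                      assign_donors_acceptors(sys$topology)$acceptors)
  a <- sys$topology$atoms
  # order-1: site O - water O links at most 2.9 A and nearly collinear
  wlinks <- hb[a$is_water[hb$donor] | a$is_water[hb$acceptor], ]
  expect_true(all(wlinks$distance <= 2.9 + 1e-9))
  expect_true(all(wlinks$angle >= 130))
  # order-2 "on" frame: the two dedicated waters are mutually H-bonded
  wid <- c(NA, NA)
  b2 <- sys$manifest$bridges[[2]]
  o_idx <- which(a$is_water & a$resno %in% b2$water_ids & a$element == "O")
  ww <- hb[hb$donor %in% o_idx & hb$acceptor %in% o_idx, ]
  expect_gte(nrow(ww), 1)
})

test_that("static noiseless rendering gives identical frames and zero RMSF", {
  spec <- interface_spec(2, n_bulk_waters = 2, noise_sigma = 0,
                         rigid_body_amplitude = 0)
  sys <- forge_system(spec, list(planted_bridge(1, 1, occupancy = 1)),
                      n_frames = 5, seed = 3)
  for (f in 2:5)
    expect_identical(sys$trajectory$coords[[f]], sys$trajectory$coords[[1]])
  prof <- rmsf_profile(sys$trajectory, sys$topology)
  expect_true(all(prof$atom$rmsf == 0))
})

test_that("geometric infeasibility and pool exhaustion are rejected at build time", {
  spec <- interface_spec(2, n_bulk_waters = 4, chain_separation = 11)
  top <- build_interface_topology(spec)
  # gap 11 - 4.4 = 6.6 A: too far for one mediating water
  man <- simulate_bridge_schedule(list(planted_bridge(1, 1, order = 1)), 2, 1)
  expect_error(render_trajectory(top, man, spec), "too far")
  # order 2 spans it fine
  man2 <- simulate_bridge_schedule(list(planted_bridge(1, 1, order = 2)), 2, 1)
  expect_silent(render_trajectory(top, man2, spec))
  # dedicated waters must fit in the pool
  spec3 <- interface_spec(2, n_bulk_waters = 1)
  top3 <- build_interface_topology(spec3)
  man3 <- simulate_bridge_schedule(list(planted_bridge(1, 1, order = 2)), 2, 1)
  expect_error(render_trajectory(top3, man3, spec3), "pool")
})

test_that("emitted trajectory files are byte-identical under one seed", {
  spec <- interface_spec(2, n_bulk_waters = 3, noise_sigma = 0.05)
  br <- list(planted_bridge(1, 1, occupancy = 0.6))
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  forge_system(spec, br, 10, seed = 21, path = p1)
  forge_system(spec, br, 10, seed = 21, path = p2)
  expect_identical(readLines(p1), readLines(p2))
  p3 <- tempfile(fileext = ".pdb")
  forge_system(spec, br, 10, seed = 22, path = p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("manifest round-trips through its plain-text form", {
  m <- simulate_bridge_schedule(list(planted_bridge(1, 2, order = 2,
                                                    occupancy = 0.5)),
                                50, seed = 4)
  p <- tempfile(fileext = ".json")
  write_manifest(m, p)
  m2 <- read_manifest(p)
  expect_equal(m2$bridges[[1]]$on, m$bridges[[1]]$on)
  expect_equal(m2$bridges[[1]]$realized, m$bridges[[1]]$realized)
  expect_identical(truth_pair_statistics(m2), truth_pair_statistics(m))
})
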