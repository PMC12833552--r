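test_that("planted bridges are recovered with their order and water path", {
  sys <- tiny_system(list(planted_bridge(1, 1, order = 1),
                          planted_bridge(3, 3, order = 2)),
                     n_frames = 2, noise = 0)
  bs <- run_bridge_pipeline(sys)
  per_frame <- split(bs, bs$frame)
  for (fb in per_frame) {
    expect_equal(nrow(fb), 2)
    expect_setequal(fb$order, c(1L, 2L))
    o2 <- fb[fb$order == 2, ]
    expect_equal(length(strsplit(o2$waters, "+", fixed = TRUE)[[1]]), 2)
    expect_setequal(fb$pair, c("Ser1-Ser1", "Ser3-Ser3"))
  }
  # endpoints sit on distinct chains
  a <- sys$topology$atoms
  expect_true(all(a$chain[bs$atom1] == "A" & a$chain[bs$atom2] == "B"))
})

test_that("a chain of three waters does not count as a bridge", {
  # manually build A-w1-w2-w3-B: every link a perfect H-bond, but the path
  # needs three mediating waters, beyond order 2
  rows <- list(); xyz <- list(); k <- 0
  add <- function(name, el, resname, resno, chain, wat, pos) {
    k <<- k + 1
    rows[[k]] <<- data.frame(serial = k, name = name, element = el,
                             resname = resname, resno = resno, chain = chain,
                             is_water = wat)
    xyz[[k]] <<- pos
  }
  add("OG", "O", "SER", 1, "A", FALSE, c(0, 0, 0))
  add("HG", "H", "SER", 1, "A", FALSE, c(0.96, 0, 0))
  for (w in 1:3) {
    o <- c(2.8 * w, 0, 0)
    add("OW", "O", "HOH", w, "W", TRUE, o)
    add("HW1", "H", "HOH", w, "W", TRUE, o + c(0.96, 0, 0))
    add("HW2", "H", "HOH", w, "W", TRUE, o + c(0, 0.96, 0))
  }
  add("OG", "O", "SER", 1, "B", FALSE, c(2.8 * 4, 0, 0))
  add("HG", "H", "SER", 1, "B", FALSE, c(2.8 * 4 + 0.96, 0, 0))
  top <- topology(do.call(rbind, rows), ref_coords = do.call(rbind, xyz))
  hb <- detect_hbonds(top$ref_coords, assign_donors_acceptors(top)$donors,
                      assign_donors_acceptors(top)$acceptors)
  g1 <- select_atoms(top, "chain A"); g2 <- select_atoms(top, "chain B")
  expect_gte(nrow(hb), 4)   # the four chain links are all present
  bs <- enumerate_water_bridges(hb, top, g1, g2, max_order = 2)
  expect_equal(nrow(bs), 0)
})

test_that("bridge enumeration matches the exhaustive path oracle on random systems", {
  set.seed(404)
  n_checked <- 0
  for (rep in 1:50) {
    top <- random_polar_system(n_heavy = 16, n_waters = 8, spread = 8)
    da <- assign_donors_acceptors(top)
    hb <- detect_hbonds(top$ref_coords, da$donors, da$acceptors)
    if (nrow(hb) == 0) next
    a <- top$atoms
    g1 <- which(a$chain == "A" & a$element %in% c("N", "O"))
    g2 <- which(a$chain == "B" & a$element %in% c("N", "O"))
    got <- enumerate_water_bridges(hb, top, g1, g2)
    want <- oracle_bridges(hb, interwater:::water_ids(top), g1, g2)
    expect_identical(bridge_key(got), bridge_key(want))
    n_checked <- n_checked + nrow(got)
  }
  expect_gt(n_checked, 20)   # the random systems actually exercised paths
})

test_that("swapping the groups mirrors the bridges", {
  sys <- tiny_system(list(planted_bridge(1, 1), planted_bridge(2, 2,
                                                               order = 2)),
                     n_frames = 1, noise = 0)
  g <- groups_ab(sys$topology)
  hb <- detect_hbonds_frames(sys$trajectory, sys$topology)
  fwd <- enumerate_water_bridges(hb, sys$topology, g$g1, g$g2)
  rev <- enumerate_water_bridges(hb, sys$topology, g$g2, g$g1)
  expect_identical(bridge_key(fwd),
                   bridge_key(data.frame(atom1 = rev$atom2,
                                         atom2 = rev$atom1,
                                         order = rev$order,
                                         waters = rev$waters)))
})

test_that("every reported bridge link is independently verifiable as an H-bond", {
  sys <- tiny_system(list(planted_bridge(1, 1), planted_bridge(3, 3,
                                                               order = 2)),
                     n_frames = 5, noise = 0.02, seed = 6)
  g <- groups_ab(sys$topology)
  hb <- detect_hbonds_frames(sys$trajectory, sys$topology)
  bs <- enumerate_water_bridges(hb, sys$topology, g$g1, g$g2)
  a <- sys$topology$atoms
  wid <- interwater:::water_ids(sys$topology)
  linked <- function(f, i, j) {
    sub <- hb[hb$frame == f, ]
    any((sub$donor == i & sub$acceptor == j) |
          (sub$donor == j & sub$acceptor == i))
  }
  water_o <- function(w) which(wid == w & a$element == "O")
  for (r in seq_len(nrow(bs))) {
    ws <- as.integer(strsplit(bs$waters[r], "+", fixed = TRUE)[[1]])
    path <- c(bs$atom1[r], vapply(ws, water_o, integer(1)), bs$atom2[r])
    for (s in seq_len(length(path) - 1))
      expect_true(linked(bs$frame[r], path[s], path[s + 1]))
  }
})

test_that("direct inter-protein H-bonds are counted per frame", {
  # separated chains with only water bridges: zero direct bonds
  sys <- tiny_system(list(planted_bridge(1, 1)), n_frames = 3, noise = 0)
  g <- groups_ab(sys$topology)
  hb <- detect_hbonds_frames(sys$trajectory, sys$topology)
  d <- count_direct_interface_hbonds(hb, g$g1, g$g2, n_frames = 3)
  expect_equal(d$n_direct, c(0L, 0L, 0L))

  # one engineered direct contact at 2.8 A / 180 deg
  atoms <- data.frame(serial = 1:3, name = c("OG", "HG", "OXT"),
                      element = c("O", "H", "O"), resname = "SER",
                      resno = 1, chain = c("A", "A", "B"), is_water = FALSE)
  xyz <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(2.8, 0, 0))
  top <- topology(atoms, ref_coords = xyz)
  da <- assign_donors_acceptors(top)
  hb1 <- detect_hbonds(xyz, da$donors, da$acceptors)
  d1 <- count_direct_interface_hbonds(hb1, 1L, 3L, n_frames = 1)
  expect_equal(d1$n_direct, 1L)

  # counts equal a brute-force filter of the oracle output
  set.seed(52)
  for (rep in 1:50) {
    top <- random_polar_system(n_heavy = 20, n_waters = 4, spread = 8)
    da <- assign_donors_acceptors(top)
    a <- top$atoms
    g1 <- which(a$chain == "A" & !a$is_water)
    g2 <- which(a$chain == "B" & !a$is_water)
    hb <- detect_hbonds(top$ref_coords, da$donors, da$acceptors)
    got <- count_direct_interface_hbonds(hb, g1, g2, n_frames = 1)$n_direct
    orc <- oracle_hbonds(top$ref_coords, da$donors, da$acceptors,
                         hbond_criteria())
    want <- sum((orc$donor %in% g1 & orc$acceptor %in% g2) |
                  (orc$donor %in% g2 & orc$acceptor %in% g1))
    expect_equal(got, want)
  }
})

test_that("order-2 water-water link requirement is configurable", {
  # two waters each bonded to one protein side but 3.1 A apart: no H-bond
  # between them, yet within a 3.5 A oxygen-oxygen proximity cutoff
  rows <- list(); xyz <- list(); k <- 0
  add <- function(name, el, resname, resno, chain, wat, pos) {
    k <<- k + 1
    rows[[k]] <<- data.frame(serial = k, name = name, element = el,
                             resname = resname, resno = resno, chain = chain,
                             is_water = wat)
    xyz[[k]] <<- pos
  }
  add("OG", "O", "SER", 1, "A", FALSE, c(0, 0, 0))
  add("HG", "H", "SER", 1, "A", FALSE, c(0.96, 0, 0))
  add("OW", "O", "HOH", 1, "W", TRUE, c(2.8, 0, 0))
  add("HW1", "H", "HOH", 1, "W", TRUE, c(2.8, 0.96, 0))
  add("HW2", "H", "HOH", 1, "W", TRUE, c(2.8, 0, 0.96))
  add("OW", "O", "HOH", 2, "W", TRUE, c(5.9, 0, 0))
  add("HW1", "H", "HOH", 2, "W", TRUE, c(5.9 + 0.96, 0, 0))
  add("HW2", "H", "HOH", 2, "W", TRUE, c(5.9, 0, 0.96))
  add("OG", "O", "SER", 1, "B", FALSE, c(8.7, 0, 0))
  add("HG", "H", "SER", 1, "B", FALSE, c(8.7 + 0.96, 0, 0))
  top <- topology(do.call(rbind, rows), ref_coords = do.call(rbind, xyz))
  tr <- trajectory(list(top$ref_coords))
  da <- assign_donors_acceptors(top)
  hb <- detect_hbonds(top$ref_coords, da$donors, da$acceptors)
  g1 <- select_atoms(top, "chain A"); g2 <- select_atoms(top, "chain B")
  strict <- enumerate_water_bridges(hb, top, g1, g2)
  relaxed <- enumerate_water_bridges(hb, top, g1, g2,
                                     ww_link = "oo_distance", traj = tr,
                                     oo_cutoff = 3.5)
  expect_equal(nrow(strict), 0)
  expect_equal(nrow(relaxed), 1)
  expect_equal(relaxed$order, 2L)
})
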