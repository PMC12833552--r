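test_that("occupancy and frequency follow their definitions", {
  # one water bridges the pair in all 100 frames, a second in 50 of them
  b <- rbind(
    data.frame(frame = 1:100, atom1 = 7L, atom2 = 40L, order = 1L,
               waters = "1", pair = "Ser1-Ser1"),
    data.frame(frame = 1:50, atom1 = 7L, atom2 = 40L, order = 1L,
               waters = "2", pair = "Ser1-Ser1"))
  st <- pair_statistics(b, 100)
  expect_equal(st$occupancy, 1.0)
  expect_equal(st$frequency, 1.5)
  expect_true(all(st$frequency >= st$occupancy))

  # duplicated records (same water set, frame, order) count once
  st2 <- pair_statistics(rbind(b, b[1, ]), 100)
  expect_equal(st2$frequency, 1.5)

  # an order-1 and an order-2 path via the same first water are distinct
  b3 <- rbind(b[1, ], transform(b[1, ], order = 2L, waters = "1+3"))
  st3 <- pair_statistics(b3, 100)
  expect_equal(st3$frequency, 2 / 100)
  expect_equal(st3$occupancy, 1 / 100)

  # no bridges: empty table; zero frames rejected
  expect_equal(nrow(pair_statistics(b[0, ], 10)), 0)
  expect_error(pair_statistics(b, 0), "n_frames")
})

test_that("statistics are invariant under frame reordering", {
  sys <- tiny_system(list(planted_bridge(1, 1, occupancy = 0.5),
                          planted_bridge(2, 2, order = 2, occupancy = 0.7)),
                     n_frames = 60, seed = 14)
  bs <- run_bridge_pipeline(sys)
  st <- pair_statistics(bs, 60)
  perm <- sample(60)
  bs2 <- bs
  bs2$frame <- perm[bs2$frame]
  st2 <- pair_statistics(bs2, 60)
  expect_equal(st[c("pair", "occupancy", "frequency", "mean_order")],
               st2[c("pair", "occupancy", "frequency", "mean_order")])
})

test_that("the persistence filter is inclusive at the threshold and idempotent", {
  mk <- function(occ) {
    frames <- seq_len(round(occ * 100))
    data.frame(frame = frames, atom1 = 1L, atom2 = 2L, order = 1L,
               waters = "1", pair = sprintf("occ%.2f", occ))
  }
  b <- rbind(mk(0.19), mk(0.20), mk(0.55))
  st <- pair_statistics(b, 100)
  kept <- apply_persistence_filter(st, 0.20)
  expect_setequal(kept$pair, c("occ0.20", "occ0.55"))   # 0.19 removed
  expect_identical(apply_persistence_filter(kept, 0.20)$pair, kept$pair)
  # threshold 0 keeps everything
  expect_equal(nrow(apply_persistence_filter(st, 0)), 3)
  expect_error(apply_persistence_filter(st, 1.5), "threshold")
})

test_that("the contiguous persistence variant uses the longest run", {
  # 30 bridged frames: one pair scattered, one in a single block
  scattered <- data.frame(frame = seq(1, 90, by = 3), atom1 = 1L, atom2 = 2L,
                          order = 1L, waters = "1", pair = "scattered")
  block <- data.frame(frame = 31:60, atom1 = 3L, atom2 = 4L,
                      order = 1L, waters = "2", pair = "block")
  st <- pair_statistics(rbind(scattered, block), 90)
  expect_equal(sort(apply_persistence_filter(st, 1 / 3)$pair),
               c("block", "scattered"))
  cont <- apply_persistence_filter(st, 1 / 3, mode = "contiguous")
  expect_identical(cont$pair, "block")
})

test_that("apo/holo comparison joins pairs and recovers planted differences", {
  mkstats <- function(occ_by_pair, rep) {
    b <- do.call(rbind, lapply(names(occ_by_pair), function(p) {
      nf <- round(occ_by_pair[[p]] * 100)
      if (nf == 0) return(NULL)
      data.frame(frame = seq_len(nf), atom1 = 1L, atom2 = 2L, order = 1L,
                 waters = "1", pair = p)
    }))
    if (is.null(b)) b <- data.frame(frame = integer(0), atom1 = integer(0),
                                    atom2 = integer(0), order = integer(0),
                                    waters = character(0), pair = character(0))
    pair_statistics(b, 100, replica = rep)
  }
  apo <- rbind(mkstats(list(P = 0.2, Q = 0.8), "1"),
               mkstats(list(P = 0.25, Q = 0.75), "2"))
  holo <- rbind(mkstats(list(P = 0.8, R = 0.5), "1"),
                mkstats(list(P = 0.85, R = 0.45), "2"))
  class(apo) <- class(holo) <- c("iw_pair_stats", "data.frame")
  cmp <- compare_apo_holo(apo, holo)
  # planted increase on P recovered in every replica
  expect_true(all(cmp$delta_frequency[cmp$pair == "P"] > 0))
  # R exists only in holo: apo frequency reported as 0, pair retained
  expect_true(all(cmp$freq_apo[cmp$pair == "R"] == 0))
  expect_true("R" %in% cmp$pair)
  summ <- attr(cmp, "summary")
  expect_equal(summ$mean_delta[summ$pair == "P"], mean(c(0.6, 0.6)))
  # identical inputs: all deltas zero
  cmp0 <- compare_apo_holo(apo, apo)
  expect_true(all(cmp0$delta_frequency == 0))
})

test_that("disjoint residue numbering between inputs triggers a warning", {
  mk <- function(pair) {
    b <- data.frame(frame = 1:50, atom1 = 1L, atom2 = 2L, order = 1L,
                    waters = "1", pair = pair)
    pair_statistics(b, 100)
  }
  expect_warning(compare_apo_holo(mk("Ser5-Ser5"), mk("Ser2105-Ser7")),
                 "numbering")
})

test_that("pipeline statistics agree with the manifest oracle", {
  # noiseless: exact equality between detection-based and truth statistics
  sys <- tiny_system(list(planted_bridge(1, 1, occupancy = 0.35),
                          planted_bridge(2, 2, order = 2, occupancy = 0.6),
                          planted_bridge(3, 3, occupancy = 0.85)),
                     n_frames = 300, seed = 19, noise = 0)
  bs <- run_bridge_pipeline(sys)
  st <- pair_statistics(bs, 300)
  truth <- truth_pair_statistics(sys$manifest)
  expect_equal(st$pair, truth$pair)
  expect_equal(st$occupancy, truth$occupancy)
  expect_equal(st$frequency, truth$frequency)
  expect_equal(st$mean_order, truth$mean_order)

  # with mild thermal noise the estimates stay exact (0.2 A distance margin)
  sysn <- tiny_system(list(planted_bridge(1, 1, occupancy = 0.5)),
                      n_frames = 300, seed = 23, noise = 0.02)
  stn <- pair_statistics(run_bridge_pipeline(sysn), 300)
  expect_equal(stn$occupancy, truth_pair_statistics(sysn$manifest)$occupancy)
})
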