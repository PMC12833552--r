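# Independent brute-force oracles and random-system builders used across the
# suite. The oracles deliberately share no code with the package internals:
# plain double loops and closed-form geometry only.

# All-pairs hydrogen-bond detection by explicit loops.
oracle_hbonds <- function(coords, donors, acceptors, criteria) {
  hits <- list()
  for (i in seq_len(nrow(donors))) {
    d <- donors$donor[i]; h <- donors$hydrogen[i]
    for (acc in acceptors) {
      if (acc == d) next
      dist <- sqrt(sum((coords[d, ] - coords[acc, ])^2))
      if (criteria$heavy_only) {
        if (dist <= criteria$heavy_cutoff)
          hits[[length(hits) + 1L]] <- c(min(d, acc), NA, max(d, acc))
      } else {
        if (dist > criteria$da_cutoff) next
        v1 <- coords[d, ] - coords[h, ]
        v2 <- coords[acc, ] - coords[h, ]
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= criteria$dha_min_angle)
          hits[[length(hits) + 1L]] <- c(d, h, acc)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0)))
  m <- unique(do.call(rbind, hits))
  data.frame(donor = m[, 1], hydrogen = m[, 2], acceptor = m[, 3])
}

# Exhaustive order<=2 path enumeration over an undirected link table.
oracle_bridges <- function(hb, wid, group1, group2, max_order = 2) {
  edge <- new.env()
  put <- function(i, j) assign(paste(i, j), TRUE, envir = edge)
  for (r in seq_len(nrow(hb))) {
    put(hb$donor[r], hb$acceptor[r]); put(hb$acceptor[r], hb$donor[r])
  }
  has <- function(i, j) !is.null(edge[[paste(i, j)]])
  # collapse atom-level edges to protein-atom <-> water-id and water <-> water
  atoms_w <- which(!is.na(wid))
  pw <- function(p, w_id) any(vapply(atoms_w[wid[atoms_w] == w_id],
                                     function(aw) has(p, aw), logical(1)))
  ww <- function(w1, w2) {
    a1 <- atoms_w[wid[atoms_w] == w1]; a2 <- atoms_w[wid[atoms_w] == w2]
    any(outer(a1, a2, Vectorize(has)))
  }
  waters <- sort(unique(wid[!is.na(wid)]))
  out <- list()
  for (p1 in group1) for (p2 in group2) {
    for (w in waters)
      if (pw(p1, w) && pw(p2, w))
        out[[length(out) + 1L]] <- data.frame(
          atom1 = p1, atom2 = p2, order = 1L, waters = as.character(w))
    if (max_order >= 2)
      for (w1 in waters) for (w2 in waters) {
        if (w1 >= w2) next
        if (((pw(p1, w1) && ww(w1, w2) && pw(p2, w2)) ||
             (pw(p1, w2) && ww(w1, w2) && pw(p2, w1))))
          out[[length(out) + 1L]] <- data.frame(
            atom1 = p1, atom2 = p2, order = 2L,
            waters = paste(w1, w2, sep = "+"))
      }
  }
  if (length(out) == 0L)
    return(data.frame(atom1 = integer(0), atom2 = integer(0),
                      order = integer(0), waters = character(0)))
  unique(do.call(rbind, out))
}

# Bridge set as a canonical sorted key vector (order-2 water sets sorted).
bridge_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  ws <- vapply(strsplit(as.character(df$waters), "+", fixed = TRUE),
               function(w) paste(sort(as.integer(w)), collapse = "+"),
               character(1))
  sort(paste(df$atom1, df$atom2, df$order, ws))
}

# Horn's quaternion method for optimal superposition RMSD.
oracle_quaternion_rmsd <- function(mobile, ref) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(ref, 2, colMeans(ref))
  M <- crossprod(P, Q)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

# Random polar system: scattered N/O/C heavy atoms with attached hydrogens
# plus free waters, in a compact box so hydrogen bonds are plentiful.
random_polar_system <- function(n_heavy = 30, n_waters = 8, spread = 9,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); xyz <- list(); k <- 0L
  add <- function(name, element, resname, resno, chain, is_water, pos) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(serial = k, name = name, element = element,
                             resname = resname, resno = resno, chain = chain,
                             is_water = is_water, stringsAsFactors = FALSE)
    xyz[[k]] <<- pos
  }
  for (i in seq_len(n_heavy)) {
    el <- sample(c("N", "O", "C"), 1, prob = c(0.3, 0.4, 0.3))
    chain <- if (i <= n_heavy / 2) "A" else "B"
    pos <- runif(3, 0, spread)
    add(el, el, "UNK", i, chain, FALSE, pos)
    if (el %in% c("N", "O")) {
      for (hj in seq_len(sample(0:2, 1))) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        add(paste0("H", el, hj), "H", "UNK", i, chain, FALSE, pos + u)
      }
    }
  }
  for (w in seq_len(n_waters)) {
    pos <- runif(3, 0, spread)
    add("OW", "O", "HOH", w, "W", TRUE, pos)
    u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
    add("HW1", "H", "HOH", w, "W", TRUE, pos + 0.96 * u1)
    add("HW2", "H", "HOH", w, "W", TRUE, pos + 0.96 * u2)
  }
  topology(do.call(rbind, rows), ref_coords = do.call(rbind, xyz))
}

# Shorthand: minimal planted system.
tiny_system <- function(bridges, n_frames = 10, seed = 1, noise = 0,
                        nres = 3, nwat = 6, sep = 9.2, ...) {
  spec <- interface_spec(nres, n_bulk_waters = nwat, chain_separation = sep,
                         noise_sigma = noise, ...)
  forge_system(spec, bridges, n_frames, seed)
}

groups_ab <- function(top) {
  list(g1 = select_atoms(top, "chain A"), g2 = select_atoms(top, "chain B"))
}

run_bridge_pipeline <- function(sys, criteria = hbond_criteria()) {
  g <- groups_ab(sys$topology)
  hb <- detect_hbonds_frames(sys$trajectory, sys$topology, criteria)
  enumerate_water_bridges(hb, sys$topology, g$g1, g$g2)
}
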