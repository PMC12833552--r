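# Geometry constants for the synthetic interface (Angstrom).
# Residues are serine-like (N,H,CA,CB,C,O,OG,HG); the hydroxyl OG protrudes
# toward the interface and serves as the bridge anchor site.
FORGE_RES_DX <- 5.5      # spacing between residues along the chain axis
FORGE_SIDE_EXT <- 2.2    # OG extension from the backbone plane
FORGE_LINK <- 2.8        # planted donor-acceptor distance (inside 3.0 cutoff)
FORGE_LINK_MAX <- 2.9    # largest link allowed (0.1 A margin to the cutoff)
FORGE_OH <- 0.96         # O-H covalent length
FORGE_CLEARANCE <- 3.2   # minimum distance for any non-planted polar contact

#' Specification of a synthetic two-chain solvated interface
#'
#' Describes a pair of protein-like chains (A and B) facing each other across
#' a solvated gap, used by [build_interface_topology()] and
#' [render_trajectory()]. Every residue is a minimal serine-like unit whose
#' side-chain hydroxyl oxygen (OG) points into the interface and can anchor a
#' planted water bridge.
#'
#' @param n_residues_per_chain residues per chain (>= 1).
#' @param n_bulk_waters size of the water pool. Waters dedicated to planted
#'   bridges are drawn from this pool (first come), the rest sit in a bulk
#'   region far from the interface.
#' @param chain_separation distance (Angstrom) between the two backbone
#'   planes; must exceed twice the hydrogen-bond cutoff (6 Angstrom) so that
#'   no accidental direct inter-chain contacts arise.
#' @param noise_sigma per-coordinate Gaussian thermal noise (Angstrom, >= 0).
#' @param rigid_body_amplitude RMS amplitude (Angstrom) of a shared rigid-body
#'   wobble applied to chain B each frame (0 disables it).
#' @param donor_sites,acceptor_sites integer residue indices (per chain) whose
#'   hydroxyl sites may anchor bridges; default all residues.
#' @param water_dialect atom naming for waters: `"OW"` (OW/HW1/HW2) or
#'   `"O"` (O/H1/H2).
#' @return An object of class `iw_interface_spec`.
#' @export
interface_spec <- function(n_residues_per_chain,
                           n_bulk_waters = 8,
                           chain_separation = 9.2,
                           noise_sigma = 0.02,
                           rigid_body_amplitude = 0,
                           donor_sites = seq_len(n_residues_per_chain),
                           acceptor_sites = seq_len(n_residues_per_chain),
                           water_dialect = c("OW", "O")) {
  if (!is.numeric(n_residues_per_chain) || n_residues_per_chain < 1)
    stop("invalid spec: n_residues_per_chain must be >= 1")
  if (n_bulk_waters < 0)
    stop("invalid spec: n_bulk_waters must be >= 0")
  if (chain_separation <= 6.0)
    stop("invalid spec: chain_separation must exceed twice the H-bond cutoff ",
         "(> 6 Angstrom)")
  if (noise_sigma < 0)
    stop("invalid spec: noise_sigma must be >= 0")
  if (rigid_body_amplitude < 0)
    stop("invalid spec: rigid_body_amplitude must be >= 0")
  sites <- c(donor_sites, acceptor_sites)
  if (any(sites < 1 | sites > n_residues_per_chain))
    stop("invalid spec: donor/acceptor site indices out of residue range")
  structure(list(
    n_residues_per_chain = as.integer(n_residues_per_chain),
    n_bulk_waters = as.integer(n_bulk_waters),
    chain_separation = chain_separation,
    noise_sigma = noise_sigma,
    rigid_body_amplitude = rigid_body_amplitude,
    donor_sites = as.integer(donor_sites),
    acceptor_sites = as.integer(acceptor_sites),
    water_dialect = match.arg(water_dialect)),
    class = "iw_interface_spec")
}

#' Declare a planted water bridge
#'
#' A ground-truth water-mediated hydrogen bond between a residue of chain A
#' and a residue of chain B, mediated by one (order 1) or two (order 2)
#' dedicated water molecules, switched on/off over frames by an occupancy
#' schedule.
#'
#' @param res_a,res_b 1-based residue index on chain A / chain B.
#' @param order 1 or 2 mediating waters.
#' @param occupancy target fraction of frames in \[0, 1\] with the bridge on.
#' @param schedule `"bernoulli"` (per-frame independent draws) or `"markov"`
#'   (two-state chain with rates `p_on`, `p_off`).
#' @param p_on,p_off Markov transition probabilities off->on and on->off; the
#'   stationary occupancy `p_on / (p_on + p_off)` must equal `occupancy`
#'   (within 1e-9).
#' @return An object of class `iw_planted_bridge`.
#' @export
planted_bridge <- function(res_a, res_b, order = 1, occupancy = 1,
                           schedule = c("bernoulli", "markov"),
                           p_on = NULL, p_off = NULL) {
  schedule <- match.arg(schedule)
  if (!order %in% c(1, 2)) stop("bridge order must be 1 or 2")
  if (!is.numeric(occupancy) || occupancy < 0 || occupancy > 1)
    stop("occupancy_target must lie in [0, 1]")
  if (schedule == "markov") {
    if (is.null(p_on) || is.null(p_off))
      stop("markov schedule requires p_on and p_off")
    if (p_on < 0 || p_on > 1 || p_off < 0 || p_off > 1)
      stop("p_on and p_off must lie in [0, 1]")
    stat <- p_on / (p_on + p_off)
    if (abs(stat - occupancy) > 1e-9)
      stop("stationary occupancy p_on/(p_on+p_off) = ", signif(stat, 6),
           " does not match occupancy_target = ", occupancy)
  }
  structure(list(res_a = as.integer(res_a), res_b = as.integer(res_b),
                 order = as.integer(order), occupancy = occupancy,
                 schedule = schedule, p_on = p_on, p_off = p_off),
            class = "iw_planted_bridge")
}

#' Build the synthetic interface topology
#'
#' Two chains (A and B) of minimal serine-like residues face each other
#' across the interface; the water pool starts in a bulk region far from the
#' interface. Atom ordering is deterministic: chain A residues, chain B
#' residues, then waters. Residue numbering is 1-based per chain.
#'
#' @param spec an [interface_spec()].
#' @return An [topology()] whose `ref_coords` hold the idealised base
#'   coordinates.
#' @export
build_interface_topology <- function(spec) {
  if (!inherits(spec, "iw_interface_spec"))
    stop("spec must be an iw_interface_spec")
  sep <- spec$chain_separation
  nres <- spec$n_residues_per_chain
  wnames <- if (spec$water_dialect == "OW") c("OW", "HW1", "HW2")
            else c("O", "H1", "H2")

  rows <- list(); coords <- list(); k <- 0L
  add <- function(name, element, resname, resno, chain, is_water, xyz) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(serial = k, name = name, element = element,
                             resname = resname, resno = resno, chain = chain,
                             is_water = is_water, stringsAsFactors = FALSE)
    coords[[k]] <<- xyz
  }
  for (chain in c("A", "B")) {
    zb <- if (chain == "A") 0 else sep          # backbone plane
    dz <- if (chain == "A") 1 else -1           # direction toward interface
    for (i in seq_len(nres)) {
      x0 <- (i - 1) * FORGE_RES_DX
      add("N",  "N", "SER", i, chain, FALSE, c(x0, 0, zb))
      add("H",  "H", "SER", i, chain, FALSE, c(x0, 0, zb - dz * 1.0))
      add("CA", "C", "SER", i, chain, FALSE, c(x0 + 1.5, 0, zb))
      add("CB", "C", "SER", i, chain, FALSE, c(x0 + 1.5, 0, zb + dz * 1.1))
      add("C",  "C", "SER", i, chain, FALSE, c(x0 + 2.4, 0, zb))
      add("O",  "O", "SER", i, chain, FALSE, c(x0 + 2.4, 1.3, zb))
      add("OG", "O", "SER", i, chain, FALSE,
          c(x0 + 1.5, 0, zb + dz * FORGE_SIDE_EXT))
      add("HG", "H", "SER", i, chain, FALSE,
          c(x0 + 1.5, -FORGE_OH, zb + dz * FORGE_SIDE_EXT))
    }
  }
  for (w in seq_len(spec$n_bulk_waters)) {
    o <- bulk_water_position(w)
    add(wnames[1], "O", "HOH", w, "W", TRUE, o)
    add(wnames[2], "H", "HOH", w, "W", TRUE, o + c(FORGE_OH, 0, 0))
    add(wnames[3], "H", "HOH", w, "W", TRUE, o + c(0, FORGE_OH, 0))
  }
  atoms <- do.call(rbind, rows)
  xyz <- do.call(rbind, coords)
  topology(atoms, ref_coords = xyz)
}

# Bulk pool: grid far on the +y side of the interface.
bulk_water_position <- function(i) {
  c(((i - 1) %% 8) * 5.0, 14 + ((i - 1) %/% 8) * 5.0, 4.0)
}

# Parking spots for displaced ("off") dedicated waters: far -y side.
park_water_position <- function(i) {
  c(((i - 1) %% 8) * 5.0, -14 - ((i - 1) %/% 8) * 5.0, 4.0)
}

#' Simulate per-frame on/off schedules for planted bridges
#'
#' Draws the per-frame state of every planted bridge from its occupancy
#' schedule and records the realisation in a ground-truth manifest. The
#' manifest alone is sufficient to recompute every planted pair statistic
#' without the rendered trajectory (see [truth_pair_statistics()]).
#' Dedicated water ids are assigned sequentially from the pool in bridge
#' declaration order (order-2 bridges take two).
#'
#' @param bridges list of [planted_bridge()] objects.
#' @param n_frames number of frames (>= 1).
#' @param seed integer RNG seed; identical seeds give identical schedules.
#' @return An object of class `iw_truth_manifest`.
#' @export
simulate_bridge_schedule <- function(bridges, n_frames, seed) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (inherits(bridges, "iw_planted_bridge")) bridges <- list(bridges)
  ok <- vapply(bridges, inherits, logical(1), "iw_planted_bridge")
  if (!all(ok)) stop("bridges must be a list of planted_bridge objects")
  set.seed(as.integer(seed))
  next_water <- 1L
  recs <- lapply(bridges, function(b) {
    if (b$schedule == "bernoulli") {
      on <- stats::rbinom(n_frames, 1L, b$occupancy) == 1L
    } else {
      on <- logical(n_frames)
      state <- stats::runif(1) < b$occupancy   # start from stationary law
      for (f in seq_len(n_frames)) {
        u <- stats::runif(1)
        state <- if (state) u >= b$p_off else u < b$p_on
        on[f] <- state
      }
    }
    wids <- seq.int(next_water, length.out = b$order)
    next_water <<- next_water + b$order
    c(b, list(water_ids = wids, on = on, realized = mean(on)))
  })
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 bridges = recs, n_dedicated_waters = next_water - 1L),
            class = "iw_truth_manifest")
}

#' @export
print.iw_truth_manifest <- function(x, ...) {
  cat("iw_truth_manifest:", length(x$bridges), "planted bridge(s),",
      x$n_frames, "frames, seed", x$seed, "\n")
  for (b in x$bridges)
    cat(sprintf("  A:%d - B:%d order %d target %.3f realized %.3f\n",
                b$res_a, b$res_b, b$order, b$occupancy, b$realized))
  invisible(x)
}

# Orthonormal basis perpendicular to unit vector v.
perp_basis <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# "On" positions of a bridge's water oxygens, given site coordinates.
# Order 1: one oxygen on the mid-plane, laterally offset so each link is
# FORGE_LINK (or the minimal on-axis link if the span allows it directly).
# Order 2: symmetric zigzag with all three links equal to FORGE_LINK.
# theta selects the lateral direction so simultaneous bridges on one pair
# stay apart. Returns a matrix (order x 3) or NULL when infeasible.
bridge_water_on_positions <- function(a_pos, b_pos, order, theta) {
  v <- b_pos - a_pos
  L <- sqrt(sum(v^2))
  vhat <- v / L
  pb <- perp_basis(vhat)
  u <- cos(theta) * pb$e1 + sin(theta) * pb$e2
  if (order == 1L) {
    if (L > 2 * FORGE_LINK_MAX) return(NULL)
    r0sq <- FORGE_LINK^2 - (L / 2)^2
    r0 <- if (r0sq > 0) sqrt(r0sq) else 0   # L in (5.6, 5.8]: on-axis water
    rbind(a_pos + vhat * (L / 2) + u * r0)
  } else {
    z1 <- (L - FORGE_LINK) / 2
    if (z1 < 0 || z1 > FORGE_LINK) return(NULL)
    a <- sqrt(FORGE_LINK^2 - z1^2)
    rbind(a_pos + vhat * z1 + u * a,
          a_pos + vhat * (L - z1) + u * a)
  }
}

#' Render a synthetic trajectory from a topology and truth manifest
#'
#' For every frame, each planted bridge that is "on" has its dedicated
#' water(s) placed so that every link of the path satisfies the
#' hydrogen-bond criterion with margin (donor-acceptor 2.8-2.9 Angstrom
#' against the 3.0 cutoff, collinear O-H...O geometry); when "off" the
#' dedicated waters are displaced to a parking region far beyond the cutoff.
#' Gaussian noise of scale `noise_sigma` is then added to every coordinate,
#' and an optional rigid-body wobble is applied to chain B. Geometric
#' feasibility (sites close enough for the requested order, no accidental
#' polar contacts between planted waters and unrelated sites) is verified
#' before any frame is produced.
#'
#' @param top topology from [build_interface_topology()].
#' @param manifest schedule from [simulate_bridge_schedule()].
#' @param spec the [interface_spec()] used to build `top`.
#' @param path optional output path; when given the trajectory is also
#'   written as a multi-model PDB file.
#' @return An [trajectory()]; when `path` is given, with attribute `"path"`.
#' @export
render_trajectory <- function(top, manifest, spec, path = NULL) {
  if (!inherits(manifest, "iw_truth_manifest"))
    stop("manifest must come from simulate_bridge_schedule()")
  if (manifest$n_dedicated_waters > spec$n_bulk_waters)
    stop("water pool too small: ", manifest$n_dedicated_waters,
         " dedicated waters needed but n_bulk_waters = ", spec$n_bulk_waters)
  a <- top$atoms
  base <- top$ref_coords
  site_idx <- function(chain, resno) {
    i <- which(a$chain == chain & a$resno == resno & a$name == "OG")
    if (length(i) != 1L)
      stop("no hydroxyl site for chain ", chain, " residue ", resno)
    i
  }
  wat_o <- function(wid) {
    i <- which(a$is_water & a$resno == wid & a$element == "O")
    if (length(i) != 1L) stop("no water with id ", wid)
    i
  }
  # lateral slot angles per pair: opposite first, diagonals later
  slot_seq <- c(pi / 2, 3 * pi / 2, 0, pi, pi / 4, 5 * pi / 4)
  pair_key <- vapply(manifest$bridges, function(b)
    paste(b$res_a, b$res_b), character(1))
  slot_of <- stats::ave(seq_along(pair_key), pair_key, FUN = seq_along)

  # precompute "on" geometry and verify feasibility / clearance
  plans <- vector("list", length(manifest$bridges))
  for (bi in seq_along(manifest$bridges)) {
    b <- manifest$bridges[[bi]]
    ia <- site_idx("A", b$res_a); ib <- site_idx("B", b$res_b)
    if (slot_of[bi] > length(slot_seq))
      stop("too many simultaneous bridges planted on pair A:", b$res_a,
           " - B:", b$res_b)
    pos <- bridge_water_on_positions(base[ia, ], base[ib, ], b$order,
                                     slot_seq[slot_of[bi]])
    if (is.null(pos))
      stop("geometric infeasibility: sites of bridge A:", b$res_a, " - B:",
           b$res_b, " are too far apart for an order-", b$order, " bridge")
    plans[[bi]] <- list(ia = ia, ib = ib, o_pos = pos,
                        o_idx = vapply(b$water_ids, wat_o, integer(1)))
  }
  check_bridge_clearance(a, base, plans)

  nf <- manifest$n_frames
  set.seed(manifest$seed + 1L)   # noise stream distinct from the schedule
  chainb <- which(a$chain == "B")
  coords <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- base
    for (bi in seq_along(manifest$bridges)) {
      b <- manifest$bridges[[bi]]; p <- plans[[bi]]
      if (b$on[f]) {
        o <- p$o_pos
        if (b$order == 1L) {
          xyz <- place_water(xyz, p$o_idx[1], o[1, ],
                             targets = rbind(base[p$ia, ], base[p$ib, ]))
        } else {
          xyz <- place_water(xyz, p$o_idx[1], o[1, ],
                             targets = rbind(base[p$ia, ], o[2, ]))
          xyz <- place_water(xyz, p$o_idx[2], o[2, ],
                             targets = rbind(base[p$ib, ], NA))
        }
      } else {
        for (j in seq_along(p$o_idx)) {
          park <- park_water_position(b$water_ids[j])
          xyz <- place_water(xyz, p$o_idx[j], park, targets = NULL)
        }
      }
    }
    if (spec$noise_sigma > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$noise_sigma),
                          ncol = 3)
    if (spec$rigid_body_amplitude > 0) {
      shift <- stats::rnorm(3, 0, spec$rigid_body_amplitude / sqrt(3))
      xyz[chainb, ] <- sweep(xyz[chainb, , drop = FALSE], 2, shift, "+")
    }
    coords[[f]] <- xyz
  }
  traj <- trajectory(coords)
  if (!is.null(path)) {
    write_multimodel_pdb(top, traj, path)
    attr(traj, "path") <- path
  }
  traj
}

# Position a water's O and point its hydrogens at up to two targets
# (collinear O-H...target, H at 0.96 A); missing targets get orthogonal
# default orientations.
place_water <- function(xyz, o_idx, o_pos, targets = NULL) {
  h_idx <- o_idx + c(1L, 2L)   # forge waters are emitted as O,H,H
  xyz[o_idx, ] <- o_pos
  for (j in 1:2) {
    tgt <- if (!is.null(targets) && !anyNA(targets[j, ])) targets[j, ] else NULL
    if (is.null(tgt)) {
      dir <- if (j == 1L) c(1, 0, 0) else c(0, 1, 0)
    } else {
      dir <- tgt - o_pos
      dir <- dir / sqrt(sum(dir^2))
    }
    xyz[h_idx[j], ] <- o_pos + FORGE_OH * dir
  }
  xyz
}

# Every planted water oxygen, in its "on" position, must stay at least
# FORGE_CLEARANCE away from all polar atoms (N/O/S) and other bridge waters
# it is not explicitly linked to, so no unplanned hydrogen bonds can appear.
check_bridge_clearance <- function(atoms, base, plans) {
  polar <- which(!atoms$is_water & atoms$element %in% c("N", "O", "S"))
  for (bi in seq_along(plans)) {
    p <- plans[[bi]]
    own <- c(p$ia, p$ib)
    for (j in seq_len(nrow(p$o_pos))) {
      o <- p$o_pos[j, ]
      others <- setdiff(polar, own)
      d <- sqrt(colSums((t(base[others, , drop = FALSE]) - o)^2))
      if (any(d < FORGE_CLEARANCE))
        stop("planted bridge ", bi, " water would contact an unrelated ",
             "polar atom (", round(min(d), 2), " Angstrom); ",
             "adjust sites or chain_separation")
      for (bj in seq_along(plans)) {
        if (bj == bi) next
        q <- plans[[bj]]$o_pos
        dq <- sqrt(rowSums(sweep(q, 2, o)^2))
        if (any(dq < FORGE_CLEARANCE))
          stop("planted bridges ", bi, " and ", bj,
               " would place waters within ", round(min(dq), 2),
               " Angstrom of each other; use different lateral slots or ",
               "a smaller occupancy overlap")
      }
    }
  }
  invisible(TRUE)
}

#' Ground-truth pair statistics from a manifest alone
#'
#' Recomputes, per residue pair, the occupancy (fraction of frames with at
#' least one planted path on) and the frequency of occurrence (mean number
#' of planted paths on per frame) directly from the manifest's on/off
#' records, without touching any trajectory. Used as the oracle against
#' which the detection pipeline is validated.
#'
#' @param manifest an `iw_truth_manifest`.
#' @return data.frame with columns `pair`, `occupancy`, `frequency`,
#'   `mean_order`, `n_frames`.
#' @export
truth_pair_statistics <- function(manifest) {
  if (length(manifest$bridges) == 0L)
    return(data.frame(pair = character(0), occupancy = numeric(0),
                      frequency = numeric(0), mean_order = numeric(0),
                      n_frames = integer(0)))
  keys <- vapply(manifest$bridges, function(b)
    forge_pair_key(b$res_a, b$res_b), character(1))
  out <- lapply(unique(keys), function(k) {
    bs <- manifest$bridges[keys == k]
    onmat <- vapply(bs, function(b) b$on, logical(manifest$n_frames))
    onmat <- matrix(onmat, nrow = manifest$n_frames)
    npaths <- rowSums(onmat)
    orders <- vapply(bs, function(b) b$order, integer(1))
    data.frame(pair = k,
               occupancy = mean(npaths >= 1),
               frequency = mean(npaths),
               mean_order = if (sum(npaths) > 0)
                 sum(onmat %*% orders) / sum(npaths) else NA_real_,
               n_frames = manifest$n_frames,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Residue-pair key for forge systems, matching pair_statistics() keys:
# chain A side first.
forge_pair_key <- function(res_a, res_b) {
  paste(residue_label("SER", res_a), residue_label("SER", res_b), sep = "-")
}

#' Write / read a truth manifest as plain text (JSON)
#'
#' @param manifest an `iw_truth_manifest`.
#' @param path file path.
#' @return `path` invisibly; `read_manifest()` returns the manifest.
#' @export
write_manifest <- function(manifest, path) {
  x <- unclass(manifest)
  x$bridges <- lapply(x$bridges, function(b) {
    b$on <- as.integer(b$on)
    b[!vapply(b, is.null, logical(1))]
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$bridges <- lapply(x$bridges, function(b) {
    b$on <- as.logical(b$on)
    b$res_a <- as.integer(b$res_a); b$res_b <- as.integer(b$res_b)
    b$order <- as.integer(b$order)
    b$water_ids <- as.integer(b$water_ids)
    b
  })
  x$seed <- as.integer(x$seed); x$n_frames <- as.integer(x$n_frames)
  x$n_dedicated_waters <- as.integer(x$n_dedicated_waters)
  structure(x, class = "iw_truth_manifest")
}

#' Generate a complete synthetic system in one call
#'
#' Convenience wrapper: builds the topology, simulates the schedules and
#' renders the trajectory.
#'
#' @param spec an [interface_spec()].
#' @param bridges list of [planted_bridge()] objects.
#' @param n_frames frames to render.
#' @param seed RNG seed.
#' @param path optional multi-model PDB output path.
#' @return list with `topology`, `manifest`, `trajectory`.
#' @export
forge_system <- function(spec, bridges, n_frames, seed, path = NULL) {
  top <- build_interface_topology(spec)
  man <- simulate_bridge_schedule(bridges, n_frames, seed)
  traj <- render_trajectory(top, man, spec, path = path)
  list(topology = top, manifest = man, trajectory = traj)
}
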