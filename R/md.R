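# Trajectory statistics: occupancy, exchange, permeation, axial density -----

#' Construct a trajectory
#'
#' Frames of coordinates for a fixed atom set.  `coords` is an
#' `n_frames x n_atoms x 3` array (or a list of `n_atoms x 3` matrices);
#' `atom_meta` mirrors the structure atom table (at least `resname`,
#' `resno`, `atom`, `element`).
#'
#' @param coords coordinate array or list of per-frame matrices, Angstrom.
#' @param atom_meta tibble of per-atom metadata.
#' @param dt time per frame, ns.
#' @param box optional per-frame orthorhombic box lengths (n_frames x 3),
#'   Angstrom; enables minimum-image unwrapping along the axis.
#' @return an `aqp_trajectory` list.
#' @export
trajectory <- function(coords, atom_meta, dt, box = NULL) {
  if (is.list(coords)) {
    coords <- simplify2array(coords)      # n_atoms x 3 x n_frames
    coords <- aperm(coords, c(3, 1, 2))   # n_frames x n_atoms x 3
  }
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort("coords must be an n_frames x n_atoms x 3 array")
  }
  if (dim(coords)[2] != nrow(atom_meta)) {
    abort("atom_meta rows must match the atom count of coords")
  }
  if (!is.numeric(dt) || dt <= 0) abort("dt must be > 0 (ns per frame)")
  structure(list(coords = coords, atom_meta = tibble::as_tibble(atom_meta),
                 dt = dt, box = box,
                 n_frames = dim(coords)[1], n_atoms = dim(coords)[2]),
            class = "aqp_trajectory")
}

#' @export
print.aqp_trajectory <- function(x, ...) {
  cat(sprintf("<aqp_trajectory> %d frames x %d atoms, dt = %g ns (%g ns total)\n",
              x$n_frames, x$n_atoms, x$dt, x$n_frames * x$dt))
  invisible(x)
}

#' @rdname trajectory
#' @param x an `aqp_trajectory`.
#' @param ... unused.
#' @export
tidy.aqp_trajectory <- function(x, ...) {
  frames <- rep(seq_len(x$n_frames), each = x$n_atoms)
  tibble(frame = frames,
         atom = rep(seq_len(x$n_atoms), times = x$n_frames),
         x = as.numeric(aperm(x$coords, c(2, 1, 3))[, , 1]),
         y = as.numeric(aperm(x$coords, c(2, 1, 3))[, , 2]),
         z = as.numeric(aperm(x$coords, c(2, 1, 3))[, , 3]))
}

#' Read and write multi-frame XYZ trajectories
#'
#' Plain XYZ with one block per frame: atom count line, comment line, then
#' `element x y z` rows.  All frames must share the atom count and order.
#'
#' @param path file path.
#' @param dt ns per frame.
#' @param atom_meta optional metadata; defaults to elements from the file.
#' @return an `aqp_trajectory`.
#' @export
read_xyz_frames <- function(path, dt = 0.1, atom_meta = NULL) {
  lines <- readLines(path)
  i <- 1
  frames <- list()
  elements <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) abort(sprintf("bad atom-count line %d in %s", i, path))
    block <- lines[(i + 2):(i + 1 + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), double(3)))
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + nat
  }
  meta <- atom_meta %||% tibble(element = toupper(elements),
                                atom = elements,
                                resname = "MOL",
                                resno = seq_along(elements))
  trajectory(frames, meta, dt = dt)
}

#' @rdname read_xyz_frames
#' @param traj an `aqp_trajectory`.
#' @export
write_xyz_frames <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  el <- traj$atom_meta$element
  for (f in seq_len(traj$n_frames)) {
    writeLines(c(as.character(traj$n_atoms), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.4f %.4f %.4f", el,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  invisible(path)
}

frame_atoms_xyz <- function(traj, frame, atoms) {
  matrix(traj$coords[frame, atoms, , drop = FALSE], nrow = length(atoms),
         ncol = 3)
}

frame_axis_z <- function(traj, frame, axis, atoms) {
  rel <- sweep(frame_atoms_xyz(traj, frame, atoms), 2, axis$origin)
  as.numeric(rel %*% axis$direction)
}

#' Per-frame occupancy counts of a channel region
#'
#' Counts selected atoms inside the region (axial z inside
#' `spec$channel_z`, lateral distance at most `lateral_max`) in every
#' frame.
#'
#' @param traj an `aqp_trajectory`.
#' @param axis a [channel_axis()]; with `anchor_atoms` given, the axis
#'   origin is re-derived each frame from the anchors' centroid (direction
#'   is kept), absorbing protein drift.
#' @param spec a [region_spec()].
#' @param selection integer atom indices to count (e.g. water oxygens).
#' @param lateral_max lateral cap of the region, Angstrom.
#' @param anchor_atoms optional atom indices whose per-frame centroid
#'   replaces the axis origin.
#' @return tibble (`frame`, `count`) with `mean` and `sd` (population)
#'   attributes and a `glance`-style summary via [summary()].
#' @export
channel_counts <- function(traj, axis, spec, selection, lateral_max = 6,
                           anchor_atoms = NULL) {
  if (length(selection) == 0) abort("empty selection")
  counts <- vapply(seq_len(traj$n_frames), function(f) {
    ax <- axis
    if (!is.null(anchor_atoms)) {
      org <- colMeans(frame_atoms_xyz(traj, f, anchor_atoms))
      ax <- channel_axis(org, axis$direction, axis$z_range)
    }
    xyz <- frame_atoms_xyz(traj, f, selection)
    ac <- axis_coords(xyz, ax)
    sum(ac$z >= spec$channel_z[1] & ac$z <= spec$channel_z[2] &
          ac$lateral <= lateral_max)
  }, integer(1))
  structure(tibble(frame = seq_len(traj$n_frames), count = counts),
            mean = mean(counts),
            sd = sqrt(mean((counts - mean(counts))^2)))
}

#' Site occupancy statistics over a trajectory
#'
#' A frame is occupied when at least one candidate atom lies within
#' `site$radius` of `site$center`; the occupant is the nearest such atom.
#'
#' @param traj an `aqp_trajectory`.
#' @param site list with `center` (length-3), `radius` (Angstrom) and
#'   optionally `label`.
#' @param candidates integer atom indices eligible to occupy the site.
#' @return an `occupancy_stats` list: `occupancy`, `occupant_history`
#'   (atom index per frame, `NA` when vacant), `n_frames`, `dt`, `label`.
#' @export
site_occupancy <- function(traj, site, candidates) {
  if (length(candidates) == 0) abort("empty candidate selection")
  if (traj$n_frames == 0) abort("trajectory has no frames")
  if (is.null(site$radius) || site$radius <= 0) abort("site radius must be > 0")
  history <- vapply(seq_len(traj$n_frames), function(f) {
    xyz <- frame_atoms_xyz(traj, f, candidates)
    d <- sqrt(colSums((t(xyz) - site$center)^2))
    i <- which.min(d)
    if (d[i] <= site$radius) candidates[i] else NA_integer_
  }, integer(1))
  structure(list(occupancy = mean(!is.na(history)),
                 occupant_history = history,
                 n_frames = traj$n_frames, dt = traj$dt,
                 label = site$label %||% "site"),
            class = "occupancy_stats")
}

#' @export
print.occupancy_stats <- function(x, ...) {
  cat(sprintf("<occupancy_stats '%s'> occupancy %.3f over %d frames\n",
              x$label, x$occupancy, x$n_frames))
  invisible(x)
}

#' @rdname site_occupancy
#' @param x an `occupancy_stats`.
#' @param ... unused.
#' @export
tidy.occupancy_stats <- function(x, ...) {
  tibble(frame = seq_len(x$n_frames), occupant = x$occupant_history,
         occupied = !is.na(x$occupant_history))
}

#' @rdname site_occupancy
#' @export
glance.occupancy_stats <- function(x, ...) {
  ep <- residence_episodes(x$occupant_history, gap_tolerance = 1)
  tibble(occupancy = x$occupancy, n_frames = x$n_frames,
         n_episodes = nrow(ep))
}

residence_episodes <- function(history, gap_tolerance = 1) {
  n <- length(history)
  episodes <- list()
  cur_id <- NA_integer_
  cur_start <- NA_integer_
  last_seen <- NA_integer_
  close_episode <- function() {
    if (!is.na(cur_id)) {
      episodes[[length(episodes) + 1]] <<-
        c(id = cur_id, start = cur_start, end = last_seen)
    }
  }
  for (f in seq_len(n)) {
    id <- history[f]
    if (!is.na(cur_id)) {
      if (!is.na(id) && id == cur_id) {
        last_seen <- f
        next
      }
      # interruption: vacant frames within gap_tolerance are bridged
      if (is.na(id) && f - last_seen <= gap_tolerance) next
      close_episode()
      cur_id <- NA_integer_
    }
    if (!is.na(id)) {
      cur_id <- id
      cur_start <- f
      last_seen <- f
    }
  }
  close_episode()
  if (length(episodes) == 0) {
    return(tibble(occupant = integer(0), start = integer(0),
                  end = integer(0), frames = integer(0)))
  }
  m <- do.call(rbind, episodes)
  tibble(occupant = m[, "id"], start = m[, "start"], end = m[, "end"],
         frames = m[, "end"] - m[, "start"] + 1L)
}

#' Mean exchange (residence) time of a site
#'
#' Residence episodes are maximal runs of one occupant identity, with
#' vacant interruptions up to `gap_tolerance` frames bridged (suppressing
#' single-frame flicker); the exchange time tau is the mean episode
#' duration times `dt`.
#'
#' @param stats an `occupancy_stats` (or a raw occupant-history vector).
#' @param dt ns per frame; defaults to the trajectory's.
#' @param gap_tolerance frames of interruption to bridge (default 1).
#' @return one-row tibble: `tau` (ns), `n_episodes`, `mean_frames`.
#' @export
exchange_time <- function(stats, dt = NULL, gap_tolerance = 1) {
  history <- if (inherits(stats, "occupancy_stats")) stats$occupant_history
             else stats
  dt <- dt %||% (if (inherits(stats, "occupancy_stats")) stats$dt else
    abort("dt required when passing a raw history"))
  ep <- residence_episodes(history, gap_tolerance)
  if (nrow(ep) == 0) abort("no residence episodes; tau undefined")
  tibble(tau = mean(ep$frames) * dt, n_episodes = nrow(ep),
         mean_frames = mean(ep$frames))
}

unwrap_z <- function(z, box_z) {
  # remove minimum-image jumps along the axis for one molecule's series
  if (is.null(box_z)) return(z)
  dz <- diff(z)
  dz <- dz - round(dz / box_z) * box_z
  cumsum(c(z[1], dz))
}

#' Count full channel permeation events
#'
#' An event is a molecule whose axial coordinate crosses `z_top` and later
#' `z_bottom` (direction `"in"`, extracellular to intracellular) or the
#' reverse (`"out"`) without re-crossing its entry boundary in between;
#' partial entries are discarded.
#'
#' @param traj an `aqp_trajectory`.
#' @param axis a [channel_axis()].
#' @param z_top,z_bottom boundary planes on the axis coordinate, with
#'   `z_top < z_bottom` (top = extracellular, i.e. more negative z).
#' @param selection integer atom indices, one per tracked molecule.
#' @return tibble of `PermeationEvent`s: `molecule`, `entry_frame`,
#'   `exit_frame`, `direction`.
#' @export
count_permeations <- function(traj, axis, z_top, z_bottom, selection) {
  if (z_top >= z_bottom) abort("z_top must be below z_bottom on the axis")
  events <- list()
  box_z <- if (!is.null(traj$box)) {
    abs(sum(traj$box[1, ] * axis$direction))
  } else NULL
  for (a in selection) {
    z <- vapply(seq_len(traj$n_frames), function(f)
      frame_axis_z(traj, f, axis, a), double(1))
    z <- unwrap_z(z, box_z)
    state <- "outside"
    entry_frame <- NA_integer_
    entry_side <- NA_character_
    for (f in seq_len(length(z))) {
      inside <- z[f] > z_top & z[f] < z_bottom
      if (state == "outside") {
        if (inside) {
          state <- "inside"
          entry_frame <- f
          entry_side <- if (f == 1) NA_character_ else
            if (z[f - 1] <= z_top) "top" else "bottom"
        }
      } else if (!inside) {
        exit_side <- if (z[f] <= z_top) "top" else "bottom"
        if (!is.na(entry_side) && exit_side != entry_side) {
          events[[length(events) + 1]] <- tibble(
            molecule = a, entry_frame = entry_frame, exit_frame = f,
            direction = if (entry_side == "top") "in" else "out")
        }
        state <- "outside"
        entry_side <- NA_character_
      }
    }
  }
  if (length(events) == 0) {
    return(tibble(molecule = integer(0), entry_frame = integer(0),
                  exit_frame = integer(0), direction = character(0)))
  }
  dplyr::bind_rows(events)
}

#' Axial density profile with bottleneck detection
#'
#' Mean per-frame count of selected atoms in z bins along the axis.
#' Bottlenecks are contiguous interior bin runs whose density falls below
#' `bottleneck_frac` times the median bin density while being flanked by
#' higher-density bins on both sides; in a channel they mark regions the
#' selected species cannot freely occupy.
#'
#' @param traj an `aqp_trajectory`.
#' @param axis a [channel_axis()].
#' @param selection integer atom indices.
#' @param bin bin width, Angstrom.
#' @param bottleneck_frac fraction of the median defining "low" (default
#'   0.25); 0 disables detection.
#' @param lateral_max lateral cap, Angstrom; `Inf` to disable.
#' @return an `axial_density` tibble (`z`, `density`) with a `bottlenecks`
#'   attribute tibble (`z_start`, `z_end`).
#' @export
axial_density <- function(traj, axis, selection, bin = 1,
                          bottleneck_frac = 0.25, lateral_max = Inf) {
  if (bin <= 0) abort("bin must be > 0")
  if (traj$n_frames < 1) abort("need at least one frame")
  breaks <- seq(axis$z_range[1], axis$z_range[2] + bin, by = bin)
  mids <- breaks[-length(breaks)] + bin / 2
  acc <- numeric(length(mids))
  for (f in seq_len(traj$n_frames)) {
    xyz <- frame_atoms_xyz(traj, f, selection)
    ac <- axis_coords(xyz, axis)
    keep <- ac$lateral <= lateral_max & ac$z >= breaks[1] &
      ac$z < breaks[length(breaks)]
    if (any(keep)) {
      h <- findInterval(ac$z[keep], breaks, rightmost.closed = TRUE)
      tb <- tabulate(h, nbins = length(mids))
      acc <- acc + tb
    }
  }
  dens <- acc / traj$n_frames
  bn <- find_bottlenecks(mids, dens, bottleneck_frac)
  structure(tibble(z = mids, density = dens),
            class = c("axial_density", class(tibble())),
            bottlenecks = bn)
}

find_bottlenecks <- function(z, dens, frac) {
  empty <- tibble(z_start = double(0), z_end = double(0))
  if (frac <= 0 || length(dens) == 0) return(empty)
  thr <- frac * stats::median(dens)
  low <- dens < thr
  if (!any(low)) return(empty)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rows <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    s <- starts[i]; e <- ends[i]
    if (s == 1 || e == length(dens)) next  # must be flanked on both sides
    if (dens[s - 1] >= thr && dens[e + 1] >= thr) {
      rows[[length(rows) + 1]] <- tibble(z_start = z[s], z_end = z[e])
    }
  }
  if (length(rows) == 0) empty else dplyr::bind_rows(rows)
}
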