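# Channel axis and maximal-inscribed-sphere pore profiling ------------------

#' Van der Waals radius table
#'
#' Bondi-style radii (Angstrom) used as the channel wall surface.  Unlisted
#' elements fall back to `default`.
#'
#' @param ... named overrides, e.g. `C = 1.8`.
#' @param default radius for elements not in the table.
#' @return named numeric vector with a `default` attribute.
#' @export
vdw_table <- function(..., default = 1.7) {
  base <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
            P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, SE = 1.90, SI = 2.10,
            NA. = 2.27, MG = 1.73, K = 2.75, CA = 2.31, ZN = 1.39, FE = 1.56)
  names(base)[names(base) == "NA."] <- "NA"
  over <- c(...)
  if (length(over) > 0) base[toupper(names(over))] <- over
  attr(base, "default") <- default
  base
}

vdw_of <- function(element, vdw) {
  r <- unname(vdw[toupper(element)])
  r[is.na(r)] <- attr(vdw, "default") %||% 1.7
  r
}

#' Define a channel axis
#'
#' An axis is an origin, a unit direction (oriented extracellular to
#' intracellular, so extracellular positions have negative axial coordinate
#' z) and a z range.  [define_axis()] derives one from a structure: the
#' origin defaults to the midpoint of the side-chain amide nitrogens (ND2)
#' of the two NPA-motif asparagines given as `anchors`; the direction is the
#' least-squares line through labelled channel-water oxygens when at least
#' four are supplied, otherwise the line through the two anchor C-alpha
#' atoms.  The sign is chosen so the first anchor is on the negative
#' (extracellular) side.
#'
#' @param origin length-3 numeric, Angstrom.
#' @param direction length-3 numeric; normalised internally.
#' @param z_range length-2 numeric interval (z = 0 at the origin).
#' @return a `channel_axis` list.
#' @export
channel_axis <- function(origin, direction, z_range = c(-25, 25)) {
  direction <- as.numeric(direction)
  n <- sqrt(sum(direction^2))
  if (n == 0) abort("axis direction must be non-zero")
  if (diff(z_range) <= 0) abort("z_range must be a non-empty interval")
  structure(list(origin = as.numeric(origin), direction = direction / n,
                 z_range = as.numeric(z_range)),
            class = "channel_axis")
}

#' @export
print.channel_axis <- function(x, ...) {
  cat(sprintf("<channel_axis> origin (%s), direction (%s), z in [%g, %g]\n",
              paste(signif(x$origin, 4), collapse = ", "),
              paste(signif(x$direction, 4), collapse = ", "),
              x$z_range[1], x$z_range[2]))
  invisible(x)
}

#' Axial and lateral coordinates relative to an axis
#'
#' @param xyz n x 3 matrix or data frame with x, y, z.
#' @param axis a [channel_axis()].
#' @return tibble with `z` (axial) and `lateral` (off-axis distance).
#' @export
axis_coords <- function(xyz, axis) {
  if (is.data.frame(xyz)) xyz <- as.matrix(xyz[, c("x", "y", "z")])
  xyz <- rbind(xyz)
  rel <- sweep(xyz, 2, axis$origin)
  z <- as.numeric(rel %*% axis$direction)
  lat2 <- rowSums(rel^2) - z^2
  tibble(z = z, lateral = sqrt(pmax(lat2, 0)))
}

#' @rdname channel_axis
#' @param model `aqp_structure`.
#' @param chain chain identifier.
#' @param anchors two author residue numbers (the NPA asparagines), first
#'   the extracellular-side one.
#' @param water_labels optional water residue numbers (in `chain`) whose
#'   oxygens define the direction when at least four are given.
#' @export
define_axis <- function(model, chain, anchors, water_labels = NULL,
                        z_range = c(-25, 25)) {
  res <- model[model$chain == chain & model$primary, , drop = FALSE]
  # anchor point: side-chain amide N if present, else C-alpha, else the
  # residue centroid (covers pseudo-atom toys)
  pick <- function(resno) {
    a <- res[res$resno == resno, , drop = FALSE]
    if (nrow(a) == 0) {
      abort(sprintf(
        "anchor residue %s not found in chain %s; available residues: %s",
        resno, chain,
        paste(utils::head(sort(unique(res$resno)), 30), collapse = " ")))
    }
    for (nm in c("ND2", "CA")) {
      hit <- a[a$atom == nm, , drop = FALSE]
      if (nrow(hit) > 0) return(as.numeric(hit[1, c("x", "y", "z")]))
    }
    colMeans(as.matrix(a[, c("x", "y", "z")]))
  }
  n1 <- pick(anchors[1])
  n2 <- pick(anchors[2])
  origin <- (n1 + n2) / 2
  direction <- NULL
  if (!is.null(water_labels)) {
    wat <- model[model$water & model$primary & model$element == "O" &
                   model$resno %in% water_labels, , drop = FALSE]
    if (nrow(wat) >= 4) {
      xyz <- as.matrix(wat[, c("x", "y", "z")])
      pc <- stats::prcomp(xyz, center = TRUE)
      direction <- pc$rotation[, 1]
    }
  }
  if (is.null(direction)) {
    direction <- n2 - n1
    if (all(direction == 0)) direction <- c(0, 0, 1)
  }
  # orient extracellular (first anchor) towards negative z
  if (sum((n1 - origin) * direction) > 0) direction <- -direction
  channel_axis(origin, direction, z_range)
}

# maximal inscribed sphere radius at in-plane centre c:
#   r(c) = min_i ( ||c - a_i|| - w_i )
# maximised over the disc of radius `max_off_axis` in the plane normal to
# the axis: deterministic coarse grid then shrinking pattern search.
optimize_slice <- function(point, e1, e2, atom_xyz, atom_w, max_off_axis,
                           coarse, refine, max_radius) {
  score <- function(u, v) {
    centers <- cbind(point[1] + u * e1[1] + v * e2[1],
                     point[2] + u * e1[2] + v * e2[2],
                     point[3] + u * e1[3] + v * e2[3])
    if (nrow(atom_xyz) == 0) {
      return(rep(max_radius, nrow(centers)))
    }
    d2 <- outer(rowSums(centers^2), rowSums(atom_xyz^2), `+`) -
      2 * centers %*% t(atom_xyz)
    pmin(apply(sweep(sqrt(pmax(d2, 0)), 2, atom_w), 1, min), max_radius)
  }
  g <- seq(-max_off_axis, max_off_axis, by = coarse)
  grid <- expand.grid(u = g, v = g)
  grid <- grid[grid$u^2 + grid$v^2 <= max_off_axis^2, ]
  sc <- score(grid$u, grid$v)
  best <- which.max(sc)
  u <- grid$u[best]; v <- grid$v[best]; r <- sc[best]
  step <- coarse / 2
  while (step >= refine) {
    moves <- cbind(u + c(-1, 1, 0, 0, -1, -1, 1, 1) * step,
                   v + c(0, 0, -1, 1, -1, 1, -1, 1) * step)
    keep <- moves[, 1]^2 + moves[, 2]^2 <= max_off_axis^2
    improved <- FALSE
    if (any(keep)) {
      mv <- moves[keep, , drop = FALSE]
      sm <- score(mv[, 1], mv[, 2])
      i <- which.max(sm)
      if (sm[i] > r + 1e-12) {
        u <- mv[i, 1]; v <- mv[i, 2]; r <- sm[i]
        improved <- TRUE
      }
    }
    if (!improved) step <- step / 2
  }
  list(center = point + u * e1 + v * e2, radius = r)
}

plane_basis <- function(direction) {
  ref <- if (abs(direction[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * direction) * direction
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(direction[2] * e1[3] - direction[3] * e1[2],
          direction[3] * e1[1] - direction[1] * e1[3],
          direction[1] * e1[2] - direction[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Compute a maximal-inscribed-sphere pore profile
#'
#' At each axial position z the centre of the probe sphere is optimised in
#' the plane normal to the axis (deterministic coarse grid followed by a
#' shrinking pattern search, no stochastic annealing) to maximise
#' `r = min over wall atoms of (distance - vdW radius)`.  By default the
#' wall consists of polymer (non-hetero) atoms only; named waters can be
#' added to the wall with `wall_waters` (see
#' [profile_with_wall_waters()]).  Planes with no wall atom within reach
#' report `radius = max_radius` with `open = TRUE`.
#'
#' @param model `aqp_structure`.
#' @param axis a [channel_axis()].
#' @param step axial sampling interval, Angstrom.
#' @param vdw a [vdw_table()].
#' @param max_off_axis in-plane search cap, Angstrom.  The default (3) keeps
#'   the probe near the axis: a looser cap lets the sphere slip through the
#'   wall and report open space at flared or sparsely sampled slices.
#' @param coarse,refine grid spacings of the planar search, Angstrom.
#' @param max_radius radius cap for open planes, Angstrom.
#' @param wall_waters water residue numbers whose oxygens join the wall.
#' @return a `pore_profile` tibble: `z`, `cx`, `cy`, `cz`, `radius`,
#'   `diameter`, `open`; attributes `step`, `axis`, `wall_water_labels`.
#' @export
compute_profile <- function(model, axis, step = 0.25, vdw = vdw_table(),
                            max_off_axis = 3, coarse = 0.2, refine = 0.02,
                            max_radius = 10, wall_waters = NULL) {
  if (step <= 0) abort("step must be > 0")
  wall <- model[model$primary & !model$hetero &
                  !is_hydrogen(model$element), , drop = FALSE]
  if (!is.null(wall_waters) && length(wall_waters) > 0) {
    wsel <- model$water & model$primary & model$element == "O" &
      model$resno %in% wall_waters
    missing <- setdiff(wall_waters, model$resno[model$water])
    if (length(missing) > 0) {
      abort(paste0("unknown wall water residue number(s): ",
                   paste(missing, collapse = ", ")))
    }
    wall <- dplyr::bind_rows(wall, model[wsel, , drop = FALSE])
  }
  wall_xyz <- as.matrix(wall[, c("x", "y", "z")])
  wall_w <- vdw_of(wall$element, vdw)
  ac <- if (nrow(wall_xyz)) axis_coords(wall_xyz, axis) else
    tibble(z = numeric(0), lateral = numeric(0))
  basis <- plane_basis(axis$direction)
  zs <- seq(axis$z_range[1], axis$z_range[2], by = step)
  wmax <- if (length(wall_w)) max(wall_w) else 0
  rows <- lapply(zs, function(z) {
    sel <- which(abs(ac$z - z) <= max_radius + wmax)
    point <- axis$origin + z * axis$direction
    opt <- optimize_slice(point, basis$e1, basis$e2,
                          wall_xyz[sel, , drop = FALSE], wall_w[sel],
                          max_off_axis, coarse, refine, max_radius)
    tibble(z = z, cx = opt$center[1], cy = opt$center[2], cz = opt$center[3],
           radius = max(opt$radius, 0), open = opt$radius >= max_radius)
  })
  out <- dplyr::bind_rows(rows)
  out$diameter <- 2 * out$radius
  out <- out[, c("z", "cx", "cy", "cz", "radius", "diameter", "open")]
  structure(out, class = c("pore_profile", class(tibble())),
            step = step, axis = axis,
            wall_water_labels = wall_waters %||% integer(0))
}

#' Pore profile with selected waters as wall
#'
#' Identical to [compute_profile()] except that the named waters' oxygens
#' are treated as part of the channel wall (with the oxygen vdW radius), so
#' every sample radius is less than or equal to the water-free profile.
#'
#' @inheritParams compute_profile
#' @param water_labels water residue numbers to include as wall.
#' @export
profile_with_wall_waters <- function(model, axis, step = 0.25,
                                     vdw = vdw_table(), water_labels,
                                     ...) {
  compute_profile(model, axis, step = step, vdw = vdw,
                  wall_waters = water_labels, ...)
}

#' Narrowest constriction of a profile
#'
#' @param profile a `pore_profile`.
#' @return one-row tibble `z`, `diameter` (global minimum; ties resolved to
#'   the smallest z).
#' @export
min_constriction <- function(profile) {
  if (nrow(profile) == 0) abort("empty profile")
  i <- which.min(profile$radius)  # which.min takes the first (smallest z)
  tibble(z = profile$z[i], diameter = profile$diameter[i])
}

#' Pore length around the constriction
#'
#' The contiguous z extent, containing the narrowest constriction, over
#' which the profile radius stays below `bulk_radius_threshold`.  The
#' vestibules flare beyond the threshold and terminate the run.
#'
#' @param profile a `pore_profile`.
#' @param bulk_radius_threshold radius (Angstrom) separating pore from
#'   vestibule/bulk; default 5.
#' @return one-row tibble: `length`, `z_start`, `z_end`.
#' @export
pore_length <- function(profile, bulk_radius_threshold = 5) {
  below <- profile$radius < bulk_radius_threshold
  if (!any(below)) {
    abort("profile never drops below the bulk radius threshold; pore length undefined")
  }
  i <- which.min(profile$radius)
  if (!below[i]) abort("constriction not below threshold")  # unreachable
  lo <- i
  while (lo > 1 && below[lo - 1]) lo <- lo - 1
  hi <- i
  while (hi < length(below) && below[hi + 1]) hi <- hi + 1
  tibble(length = profile$z[hi] - profile$z[lo],
         z_start = profile$z[lo], z_end = profile$z[hi])
}
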