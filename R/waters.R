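# Crystallographic water networks -------------------------------------------
#
# A 1.8-Angstrom structure has no deposited hydrogens, so hydrogen bonds are
# called on donor-acceptor heavy-atom distance alone (no angular term) and
# donor/acceptor assignment is rule-based.

polar_atoms <- function(model, include_s = FALSE) {
  el <- c("O", "N", if (include_s) "S")
  a <- model[model$primary & model$element %in% el, , drop = FALSE]
  tibble::as_tibble(a)
}

#' Water oxygen sites of a structure
#'
#' @param model `aqp_structure`.
#' @param chain optional chain filter.
#' @return tibble of water oxygens (one row per water molecule).
#' @export
water_sites <- function(model, chain = NULL) {
  w <- model[model$water & model$primary & model$element == "O", ,
             drop = FALSE]
  if (!is.null(chain)) w <- w[w$chain %in% chain, , drop = FALSE]
  tibble::as_tibble(w)
}

#' Detect hydrogen bonds between polar atoms
#'
#' All oxygen/nitrogen atom pairs (sulfur excluded by default) within
#' `d_max` of each other are reported as hydrogen bonds; bonds at or below
#' `d_typical` are classed `"typical"`, the rest `"standard"`.  Both cutoffs
#' are inclusive.  Pairs belonging to the same residue are excluded
#' (covalent neighbours, not hydrogen bonds).  Each unordered pair is
#' reported once.
#'
#' @param model `aqp_structure`.
#' @param d_max maximum donor-acceptor distance, Angstrom (default 3.4:
#'   beyond it a pair no longer counts as hydrogen bonded).
#' @param d_typical distance at or below which a bond is a typical, strong
#'   hydrogen bond (default 2.8).
#' @param include_s include sulfur atoms as polar partners.
#' @return tibble of bonds: partner identifiers (`chain`, `resno`,
#'   `resname`, `atom`, `eleno` for each side), `distance`, `klass`.
#' @export
detect_hbonds <- function(model, d_max = 3.4, d_typical = 2.8,
                          include_s = FALSE) {
  p <- polar_atoms(model, include_s)
  empty <- tibble(eleno_a = integer(0), chain_a = character(0),
                  resno_a = integer(0), resname_a = character(0),
                  atom_a = character(0), eleno_b = integer(0),
                  chain_b = character(0), resno_b = integer(0),
                  resname_b = character(0), atom_b = character(0),
                  distance = double(0), klass = character(0))
  if (nrow(p) < 2) return(empty)
  xyz <- as.matrix(p[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  resid <- paste(p$chain, p$resno, p$insert)
  idx <- which(upper.tri(d) & d <= d_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  i <- idx[, 1]; j <- idx[, 2]
  same_res <- resid[i] == resid[j]
  i <- i[!same_res]; j <- j[!same_res]
  if (length(i) == 0) return(empty)
  dist_ij <- d[cbind(i, j)]
  tibble(eleno_a = p$eleno[i], chain_a = p$chain[i], resno_a = p$resno[i],
         resname_a = p$resname[i], atom_a = p$atom[i],
         eleno_b = p$eleno[j], chain_b = p$chain[j], resno_b = p$resno[j],
         resname_b = p$resname[j], atom_b = p$atom[j],
         distance = dist_ij,
         klass = ifelse(dist_ij <= d_typical, "typical", "standard")) |>
    dplyr::arrange(.data$distance)
}

#' Define channel/vestibule regions along an axis
#'
#' Boundaries are calibration knobs (the census counts are observed, the
#' region limits are not): a water is in the channel when its axial z lies
#' in `channel_z` and its off-axis distance is at most the local pore
#' radius plus `margin`; vestibule waters lie in the flanking z intervals
#' within `vestibule_lateral_max` of the axis; everything else is bulk.
#'
#' @param channel_z length-2 interval, Angstrom.
#' @param extracellular_z,intracellular_z flanking intervals; defaults
#'   extend 10 Angstrom beyond the channel on either side.
#' @param margin lateral slack added to the local pore radius (default 1.4,
#'   one water radius).
#' @param vestibule_lateral_max lateral cap for vestibule membership.
#' @return a `region_spec` list.
#' @export
region_spec <- function(channel_z, extracellular_z = NULL,
                        intracellular_z = NULL, margin = 1.4,
                        vestibule_lateral_max = 10) {
  channel_z <- sort(as.numeric(channel_z))
  extracellular_z <- extracellular_z %||% c(channel_z[1] - 10, channel_z[1])
  intracellular_z <- intracellular_z %||% c(channel_z[2], channel_z[2] + 10)
  ints <- rbind(sort(extracellular_z), channel_z, sort(intracellular_z))
  if (any(ints[-1, 1] < ints[-3, 2] - 1e-9)) {
    abort("region intervals must be disjoint and ordered along z")
  }
  structure(list(channel_z = channel_z,
                 extracellular_z = sort(extracellular_z),
                 intracellular_z = sort(intracellular_z),
                 margin = margin,
                 vestibule_lateral_max = vestibule_lateral_max),
            class = "region_spec")
}

local_radius <- function(z, profile) {
  if (is.null(profile) || nrow(profile) == 0) return(rep(Inf, length(z)))
  stats::approx(profile$z, profile$radius, xout = z, rule = 2)$y
}

#' Classify waters into channel, vestibule and bulk regions
#'
#' @param model `aqp_structure`.
#' @param axis a [channel_axis()].
#' @param profile a `pore_profile` for the same chain (supplies the local
#'   radius of the lateral rule); `NULL` disables the lateral radius bound.
#' @param spec a [region_spec()].
#' @param chain optional chain filter for the waters.
#' @return tibble of water oxygens with `axial_z`, `lateral` and `region` columns
#'   (`channel`, `extracellular_vestibule`, `intracellular_vestibule`,
#'   `bulk`); the per-region census is in the `census` attribute.
#' @export
classify_waters <- function(model, axis, profile = NULL, spec, chain = NULL) {
  w <- water_sites(model, chain)
  ac <- axis_coords(w, axis)
  w$axial_z <- ac$z
  w$lateral <- ac$lateral
  in_int <- function(z, int) z >= int[1] & z <= int[2]
  rad <- local_radius(w$axial_z, profile)
  region <- rep("bulk", nrow(w))
  region[in_int(w$axial_z, spec$extracellular_z) &
           w$lateral <= spec$vestibule_lateral_max] <- "extracellular_vestibule"
  region[in_int(w$axial_z, spec$intracellular_z) &
           w$lateral <= spec$vestibule_lateral_max] <- "intracellular_vestibule"
  chn <- in_int(w$axial_z, spec$channel_z) & w$lateral <= rad + spec$margin
  region[chn] <- "channel"
  w$region <- region
  census <- dplyr::count(
    tibble(region = factor(region,
                           levels = c("channel", "extracellular_vestibule",
                                      "intracellular_vestibule", "bulk"))),
    .data$region, .drop = FALSE)
  structure(dplyr::arrange(w, .data$axial_z), census = census)
}

#' Mutually exclusive water pairs and exclusion groups
#'
#' Water positions closer than `cutoff` cannot be occupied simultaneously;
#' transitively linked pairs are merged into exclusion groups, within which
#' a single molecule is presumed to hop between the alternative sites.
#'
#' @param waters tibble of water oxygens (x, y, z and identifying columns).
#' @param cutoff exclusivity distance, Angstrom; strictly-below comparisons
#'   (default 2.5, between the 2.3 Angstrom exemplar of an alternating pair
#'   and the 2.8 Angstrom typical hydrogen bond).
#' @return tibble of pairs `i`, `j` (row indices into `waters`), `distance`,
#'   `group`; the per-water group assignment is in the `groups` attribute.
#' @export
exclusive_pairs <- function(waters, cutoff = 2.5) {
  n <- nrow(waters)
  if (n < 2) {
    return(structure(tibble(i = integer(0), j = integer(0),
                            distance = double(0), group = integer(0)),
                     groups = integer(n)))
  }
  d <- as.matrix(stats::dist(as.matrix(waters[, c("x", "y", "z")])))
  idx <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(structure(tibble(i = integer(0), j = integer(0),
                            distance = double(0), group = integer(0)),
                     groups = integer(n)))
  }
  g <- igraph::graph_from_edgelist(cbind(idx[, 1], idx[, 2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # renumber groups so only multi-member clusters get a group id
  sizes <- table(comp)
  keep <- as.integer(names(sizes)[sizes > 1])
  gid <- match(comp, keep)
  out <- tibble(i = idx[, 1], j = idx[, 2], distance = d[idx],
                group = gid[idx[, 1]])
  structure(dplyr::arrange(out, .data$group, .data$distance),
            groups = ifelse(is.na(gid), 0L, gid))
}

#' Single-file segmentation of channel waters
#'
#' Channel waters are ordered by axial z and partitioned into maximal runs
#' whose consecutive oxygen-oxygen distances are at most `gap_max`; a
#' z gap larger than `gap_max` is a `disconnected` boundary, through which
#' no hydrogen-bonded chain (and hence no Grotthuss proton wire) can run.
#' A run is `single_file` unless two of its waters share a z window of
#' width `z_window` while sitting more than `lateral_max` apart off-axis,
#' in which case it is `multi_file`.
#'
#' @param waters classified water tibble (from [classify_waters()]); only
#'   rows with `region == "channel"` are used.
#' @param axis a [channel_axis()].
#' @param gap_max neighbour distance ceiling, Angstrom (default 3.4).
#' @param lateral_max allowed lateral spread of coeval waters, Angstrom.
#' @param z_window z width within which two waters count as coeval;
#'   defaults to `gap_max / 2`.
#' @return tibble of segments: `segment`, `z_start`, `z_end`, `n_waters`,
#'   `status` (`single_file` / `multi_file`), with `disconnected`
#'   boundaries between consecutive segments implied by their z gaps.
#' @export
single_file_segments <- function(waters, axis, gap_max = 3.4,
                                 lateral_max = 2, z_window = NULL) {
  z_window <- z_window %||% (gap_max / 2)
  if ("region" %in% names(waters)) {
    waters <- waters[waters$region == "channel", , drop = FALSE]
  }
  if (!"axial_z" %in% names(waters)) {
    ac <- axis_coords(waters, axis)
    waters$axial_z <- ac$z
    waters$lateral <- ac$lateral
  }
  waters <- dplyr::arrange(tibble::as_tibble(waters), .data$axial_z)
  n <- nrow(waters)
  if (n == 0) {
    return(tibble(segment = integer(0), z_start = double(0),
                  z_end = double(0), n_waters = integer(0),
                  status = character(0)))
  }
  xyz <- as.matrix(waters[, c("x", "y", "z")])
  gap <- if (n > 1) sqrt(rowSums((xyz[-1, , drop = FALSE] -
                                    xyz[-n, , drop = FALSE])^2)) else numeric(0)
  seg_id <- cumsum(c(1, as.integer(gap > gap_max)))
  segs <- lapply(unique(seg_id), function(s) {
    rows <- which(seg_id == s)
    status <- "single_file"
    if (length(rows) > 1) {
      sub <- xyz[rows, , drop = FALSE]
      zs <- waters$axial_z[rows]
      for (a in seq_along(rows)[-length(rows)]) {
        for (b in (a + 1):length(rows)) {
          if (abs(zs[a] - zs[b]) <= z_window) {
            lat <- sqrt(sum((sub[a, ] - sub[b, ])^2) - (zs[a] - zs[b])^2)
            if (lat > lateral_max) status <- "multi_file"
          }
        }
      }
    }
    tibble(segment = s, z_start = min(waters$axial_z[rows]),
           z_end = max(waters$axial_z[rows]), n_waters = length(rows),
           status = status)
  })
  dplyr::bind_rows(segs)
}

# acceptor-only heavy atoms: backbone carbonyl O and side-chain O that have
# no attached donatable hydrogen in the standard residues
ACCEPTOR_ONLY <- list(
  backbone = "O",
  sidechain = c(ASP = "OD1", ASP2 = "OD2", GLU = "OE1", GLU2 = "OE2",
                ASN = "OD1", GLN = "OE1"))

is_acceptor_only <- function(resname, atom) {
  atom == "O" |
    (resname == "ASP" & atom %in% c("OD1", "OD2")) |
    (resname == "GLU" & atom %in% c("OE1", "OE2")) |
    (resname == "ASN" & atom == "OD1") |
    (resname == "GLN" & atom == "OE1")
}

#' Infer the orientation of a channel water from its hydrogen bonds
#'
#' Without hydrogens, orientation is inferred by a two-acceptor rule: when a
#' water donates at least two hydrogen bonds to acceptor-only partners
#' (backbone carbonyl O, carboxylate/amide side-chain O, or a hydroxyl O
#' such as Thr OG1 already committed as a donor elsewhere) that both sit on
#' the wall side of the water, its hydrogens face the wall and its oxygen
#' lone pairs face the channel.  Anything else is ambiguous.  A rationale
#' string is always emitted for audit.
#'
#' @param model `aqp_structure`.
#' @param water one-row water tibble (an entry of [water_sites()]).
#' @param bonds output of [detect_hbonds()] for the model.
#' @param axis a [channel_axis()].
#' @param accept_hydroxyl treat Ser/Thr/Tyr hydroxyl oxygens as acceptors
#'   for this water (default `TRUE`; their proton is typically committed to
#'   a neighbouring backbone carbonyl).
#' @return one-row tibble: `orientation` (`oxygen_toward_channel`,
#'   `hydrogens_toward_channel` or `ambiguous`) and `rationale`.
#' @export
infer_orientation <- function(model, water, bonds, axis,
                              accept_hydroxyl = TRUE) {
  wid <- water$eleno[1]
  mine <- bonds[bonds$eleno_a == wid | bonds$eleno_b == wid, , drop = FALSE]
  if (nrow(mine) == 0) {
    return(tibble(orientation = "ambiguous", rationale = ""))
  }
  partner_ids <- ifelse(mine$eleno_a == wid, mine$eleno_b, mine$eleno_a)
  partners <- model[match(partner_ids, model$eleno), , drop = FALSE]
  hydroxyl <- partners$resname %in% c("SER", "THR", "TYR") &
    partners$atom %in% c("OG", "OG1", "OH")
  acc <- is_acceptor_only(partners$resname, partners$atom) |
    (accept_hydroxyl & hydroxyl)
  acc[partners$water] <- FALSE  # water-water bonds carry no orientation
  if (sum(acc) < 2) {
    return(tibble(orientation = "ambiguous",
                  rationale = sprintf(
                    "%d acceptor-only partner(s); two donated bonds required",
                    sum(acc))))
  }
  wxyz <- as.numeric(water[1, c("x", "y", "z")])
  zc <- axis_coords(rbind(wxyz), axis)$z
  foot <- axis$origin + zc * axis$direction
  toward_axis <- foot - wxyz
  nt <- sqrt(sum(toward_axis^2))
  if (nt < 1e-9) {
    return(tibble(orientation = "ambiguous",
                  rationale = "water lies on the axis; wall side undefined"))
  }
  toward_axis <- toward_axis / nt
  pa <- partners[acc, , drop = FALSE]
  disp <- sweep(as.matrix(pa[, c("x", "y", "z")]), 2, wxyz)
  wallside <- (disp %*% toward_axis) < 0
  labels <- paste0(pa$resname, pa$resno, ":", pa$atom)
  if (sum(wallside) >= 2) {
    tibble(orientation = "oxygen_toward_channel",
           rationale = paste0("donates to wall-side acceptors ",
                              paste(labels[wallside], collapse = ", ")))
  } else {
    tibble(orientation = "ambiguous",
           rationale = paste0(
             "acceptor partners not concentrated on the wall side (",
             paste(labels, collapse = ", "), ")"))
  }
}
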