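# Silicic acid Si(OH)4 placement by water overlap ---------------------------
#
# Silicic acid is an uncharged tetrahedron of four hydroxyls around Si.
# Candidate substrate positions inside the channel are generated by rigidly
# superposing the hydroxyl oxygens of an ideal template onto subsets of
# crystallographic water oxygen positions, the premise being that the
# hydroxyls favour the hydrophilic spots the ordered waters mark.

#' Ideal silicic acid template
#'
#' Si at the origin, four oxygens at tetrahedral vertices with
#' `|Si-O| = d_si_o` (1.63 Angstrom by default); all O-Si-O angles are
#' 109.47 degrees and the O-O edge is `2 d sin(109.47/2) ~ 2.662` Angstrom.
#'
#' @param d_si_o Si-O bond length, Angstrom.
#' @return a `silicic_acid` list: `si` (length-3), `oxygens` (4 x 3 matrix).
#' @export
silicic_template <- function(d_si_o = 1.63) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  structure(list(si = c(0, 0, 0), oxygens = v * d_si_o, d_si_o = d_si_o),
            class = "silicic_acid")
}

#' @export
print.silicic_acid <- function(x, ...) {
  cat(sprintf("<silicic_acid> Si at (%s), |Si-O| = %.3f Angstrom\n",
              paste(signif(x$si, 4), collapse = ", "), x$d_si_o))
  invisible(x)
}

transform_silicic <- function(template, rotation, translation) {
  structure(list(si = as.numeric(apply_rigid(rbind(template$si), rotation,
                                             translation)),
                 oxygens = apply_rigid(template$oxygens, rotation,
                                       translation),
                 d_si_o = template$d_si_o),
            class = "silicic_acid")
}

count_clashes <- function(si_positions, model, vdw, clash_tol) {
  prot <- model[model$primary & !model$hetero &
                  !is_hydrogen(model$element), , drop = FALSE]
  if (nrow(prot) == 0) return(0L)
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  pw <- vdw_of(prot$element, vdw)
  total <- 0L
  radii <- c(SI = 2.10, O = 1.52)
  for (i in seq_len(nrow(si_positions))) {
    p <- si_positions[i, ]
    d <- sqrt(colSums((t(pxyz) - p)^2))
    total <- total + sum(d < pw + radii[[if (i == 1) "SI" else "O"]] -
                           clash_tol)
  }
  total
}

spin_about_axis <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  c_ <- cos(theta); s_ <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
               byrow = TRUE)
  c_ * diag(3) + s_ * ux + (1 - c_) * tcrossprod(u)
}

#' Fit the silicic template onto 2-4 water positions
#'
#' Over all injective assignments of the four template oxygens to the given
#' waters, the template is rigidly superposed (Kabsch) onto the water
#' oxygens; the best assignment by (RMSD, clash count) wins.  With only two
#' waters the rotation about the O-O axis is unresolved by the fit; it is
#' fixed by scanning the spin angle and minimising clashes, then maximising
#' hydrogen-bond partners, against `model` when supplied.
#'
#' @param template a [silicic_template()].
#' @param waters 2-4 row tibble of distinct water oxygens (x, y, z; a
#'   `resno` or `label` column names the mapping).
#' @param model optional `aqp_structure` used for clash counting.
#' @param vdw a [vdw_table()].
#' @param clash_tol overlap tolerance subtracted from the vdW sum before a
#'   contact counts as a clash, Angstrom.
#' @param d_max hydrogen-bond cutoff used for the two-point spin tie-break.
#' @param spin_step spin-scan resolution, degrees.
#' @return a `si_placement` list: transformed `silicic`, `mapping` (tibble
#'   oxygen index -> water), `rmsd`, `clashes`.
#' @export
fit_to_waters <- function(template, waters, model = NULL, vdw = vdw_table(),
                          clash_tol = 0.4, d_max = 3.4, spin_step = 5) {
  waters <- tibble::as_tibble(waters)
  k <- nrow(waters)
  if (k < 2 || k > 4) abort("need 2-4 waters (choose subsets upstream)")
  wxyz <- as.matrix(waters[, c("x", "y", "z")])
  if (anyDuplicated(round(wxyz, 6)) > 0) abort("duplicate water positions")
  labels <- if ("label" %in% names(waters)) as.character(waters$label)
            else if ("resno" %in% names(waters)) as.character(waters$resno)
            else as.character(seq_len(k))
  perms <- all_injections(4, k)
  best <- NULL
  for (p in perms) {
    fit <- kabsch(template$oxygens[p, , drop = FALSE], wxyz)
    cand <- list(perm = p, fit = fit)
    if (is.null(best) || fit$rmsd < best$fit$rmsd - 1e-12) best <- cand
  }
  placed <- transform_silicic(template, best$fit$rotation,
                              best$fit$translation)
  if (k == 2) {
    # residual spin freedom about the two-water axis: after a 2-point
    # Kabsch fit the mapped template oxygens lie on the line through the
    # water centroid parallel to the water-water vector, so spinning about
    # that line leaves the fit residual unchanged
    axis_u <- wxyz[2, ] - wxyz[1, ]
    pivot <- colMeans(wxyz)
    thetas <- seq(0, 2 * pi - 1e-9, by = spin_step * pi / 180)
    score_best <- NULL
    for (th in thetas) {
      rot <- spin_about_axis(axis_u, th)
      cand <- transform_silicic(placed, rot,
                                as.numeric(pivot - rot %*% pivot))
      cl <- if (is.null(model)) 0L else
        count_clashes(rbind(cand$si, cand$oxygens), model, vdw, clash_tol)
      hb <- if (is.null(model)) 0L else
        nrow(placement_partner_table(cand, model, d_max))
      sc <- c(cl, -hb)
      if (is.null(score_best) || sc[1] < score_best$sc[1] ||
          (sc[1] == score_best$sc[1] && sc[2] < score_best$sc[2])) {
        score_best <- list(sc = sc, cand = cand)
      }
    }
    placed <- score_best$cand
  }
  clashes <- if (is.null(model)) 0L else
    count_clashes(rbind(placed$si, placed$oxygens), model, vdw, clash_tol)
  out <- list(silicic = placed,
              mapping = tibble(oxygen = best$perm, water = labels),
              rmsd = best$fit$rmsd, clashes = clashes)
  class(out) <- "si_placement"
  out
}

all_injections <- function(n_from, n_to) {
  # injective maps of n_to targets onto n_from template indices, as the
  # template-oxygen index vector (length n_to)
  perm_rec <- function(avail, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (a in avail) {
      for (rest in perm_rec(setdiff(avail, a), k - 1)) {
        out[[length(out) + 1]] <- c(a, rest)
      }
    }
    out
  }
  perm_rec(seq_len(n_from), n_to)
}

#' @export
print.si_placement <- function(x, ...) {
  cat(sprintf(
    "<si_placement> %d mapped oxygens, rmsd %.3f Angstrom, %d clashes\n",
    nrow(x$mapping), x$rmsd, x$clashes))
  invisible(x)
}

#' @rdname fit_to_waters
#' @param x an `si_placement`.
#' @param ... unused.
#' @export
glance.si_placement <- function(x, ...) {
  tibble(n_mapped = nrow(x$mapping), rmsd = x$rmsd, clashes = x$clashes)
}

placement_partner_table <- function(silicic, model, d_max) {
  p <- polar_atoms(model)
  if (nrow(p) == 0) {
    return(tibble(oxygen = integer(0), chain = character(0),
                  resno = integer(0), resname = character(0),
                  atom = character(0), distance = double(0)))
  }
  pxyz <- as.matrix(p[, c("x", "y", "z")])
  rows <- lapply(1:4, function(i) {
    d <- sqrt(colSums((t(pxyz) - silicic$oxygens[i, ])^2))
    hit <- which(d <= d_max)
    if (length(hit) == 0) return(NULL)
    tibble(oxygen = i, chain = p$chain[hit], resno = p$resno[hit],
           resname = p$resname[hit], atom = p$atom[hit],
           distance = d[hit])
  })
  dplyr::bind_rows(rows)
}

#' Hydrogen-bond partners of a placed silicic acid
#'
#' Polar protein/water atoms within `d_max` of each hydroxyl oxygen.
#'
#' @param placement an `si_placement`.
#' @param model `aqp_structure`.
#' @param d_max cutoff, Angstrom.
#' @return tibble: `oxygen` (template index), partner identity, `distance`.
#' @export
placement_hbonds <- function(placement, model, d_max = 3.4) {
  placement_partner_table(placement$silicic, model, d_max)
}

#' Enumerate silicic acid placements over channel waters
#'
#' Candidate water subsets are z-contiguous windows of 2-4 channel waters
#' (ordered along the axis, mirroring the axial ladder of sites a substrate
#' traverses); each subset is fitted with [fit_to_waters()], placements
#' with `rmsd <= rmsd_max` and zero clashes are kept, ranked by (more
#' mapped oxygens, smaller rmsd), and near-duplicates (Si-Si distance
#' below `dedup_dist`) are collapsed keeping the better-ranked.
#'
#' @param model `aqp_structure` (used for clash counting; pass `NULL` to
#'   skip).
#' @param channel_waters water tibble ordered along the axis (e.g. the
#'   channel rows of [classify_waters()]).
#' @param rmsd_max acceptance threshold on the fit RMSD, Angstrom.
#' @param clash_tol clash tolerance, Angstrom.
#' @param sizes window sizes to try (subset of 2:4).
#' @param dedup_dist Si-Si deduplication radius, Angstrom.
#' @param vdw a [vdw_table()].
#' @return tibble of ranked placements: `rank`, `n_mapped`, `rmsd`,
#'   `clashes`, `si_x/y/z`, `waters` (comma-joined labels); the
#'   `si_placement` objects are in the `placements` attribute.
#' @export
enumerate_placements <- function(model, channel_waters, rmsd_max = 1,
                                 clash_tol = 0.4, sizes = 2:4,
                                 dedup_dist = 2, vdw = vdw_table()) {
  channel_waters <- tibble::as_tibble(channel_waters)
  n <- nrow(channel_waters)
  if (n < 2) abort("need at least two channel waters")
  template <- silicic_template()
  cands <- list()
  for (k in sort(sizes, decreasing = TRUE)) {
    if (k > n) next
    for (start in seq_len(n - k + 1)) {
      sub <- channel_waters[start:(start + k - 1), , drop = FALSE]
      pl <- fit_to_waters(template, sub, model = model, vdw = vdw,
                          clash_tol = clash_tol)
      if (pl$rmsd <= rmsd_max && pl$clashes == 0) {
        cands[[length(cands) + 1]] <- pl
      }
    }
  }
  if (length(cands) == 0) {
    return(structure(tibble(rank = integer(0), n_mapped = integer(0),
                            rmsd = double(0), clashes = integer(0),
                            si_x = double(0), si_y = double(0),
                            si_z = double(0), waters = character(0)),
                     placements = list()))
  }
  nm <- vapply(cands, function(p) nrow(p$mapping), integer(1))
  rm_ <- vapply(cands, function(p) p$rmsd, double(1))
  ord <- order(-nm, rm_)
  cands <- cands[ord]
  kept <- list()
  for (p in cands) {
    dup <- any(vapply(kept, function(q)
      sqrt(sum((p$silicic$si - q$silicic$si)^2)) < dedup_dist, logical(1)))
    if (!dup) kept[[length(kept) + 1]] <- p
  }
  tbl <- purrr::map_dfr(seq_along(kept), function(i) {
    p <- kept[[i]]
    tibble(rank = i, n_mapped = nrow(p$mapping), rmsd = p$rmsd,
           clashes = p$clashes, si_x = p$silicic$si[1],
           si_y = p$silicic$si[2], si_z = p$silicic$si[3],
           waters = paste(p$mapping$water, collapse = ","))
  })
  structure(tbl, placements = kept)
}
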