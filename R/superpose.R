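# Rigid-body geometry -------------------------------------------------------

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum ||R p_i + t - q_i||^2` over paired coordinate sets.
#'
#' @param p,q n x 3 matrices of paired coordinates (p is moved onto q).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   and `rmsd` after superposition.
#' @export
kabsch <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(ncol(p) == 3, ncol(q) == 3, nrow(p) == nrow(q), nrow(p) >= 1)
  cp <- colMeans(p); cq <- colMeans(q)
  pp <- sweep(p, 2, cp); qq <- sweep(q, 2, cq)
  h <- crossprod(pp, qq)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cq - as.numeric(rot %*% cp)
  moved <- sweep(p %*% t(rot), 2, trans, `+`)
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums((moved - q)^2))))
}

apply_rigid <- function(xyz, rotation, translation) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, translation, `+`)
}

random_rotation <- function() {
  # QR-based Haar-ish rotation; only used by generators/tests via exported API
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Apply a rigid transform to an atom table
#'
#' @param model `aqp_structure` or data frame with x, y, z columns.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 vector, Angstrom.
#' @return the model with transformed coordinates.
#' @export
transform_structure <- function(model, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- apply_rigid(as.matrix(model[, c("x", "y", "z")]), rotation,
                     translation)
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

# Superposition --------------------------------------------------------------

ca_table <- function(model, chain_id) {
  a <- model[model$chain == chain_id & !model$hetero & model$primary &
               model$atom == "CA" & !is_hydrogen(model$element), ,
             drop = FALSE]
  dplyr::arrange(tibble::as_tibble(a), .data$resno, .data$insert)
}

#' Superpose two chains by aligned C-alpha atoms
#'
#' Globally aligns the two chain sequences (identity scoring: match +1,
#' mismatch -1, linear gap -2 by default), then superposes the C-alpha atoms
#' of aligned non-gap residue pairs by Kabsch least squares.  Optionally one
#' round of outlier rejection (pairs with residual deviation more than
#' `outlier_factor` times the RMSD) followed by a re-fit.
#'
#' @param model_a,model_b `aqp_structure` tables.
#' @param chain_a,chain_b chain identifiers.
#' @param match,mismatch,gap alignment scores (gap is the linear per-residue
#'   penalty, given as a positive cost).
#' @param reject_outliers logical; default `FALSE`.
#' @param outlier_factor multiple of the RMSD beyond which a pair is dropped.
#' @return an `aqp_superposition` object: list with `rotation`,
#'   `translation`, `rmsd`, `n_pairs` and `alignment` (tibble of paired
#'   author residue numbers with per-pair deviations).
#' @export
superpose <- function(model_a, model_b, chain_a, chain_b,
                      match = 1, mismatch = -1, gap = 2,
                      reject_outliers = FALSE, outlier_factor = 2) {
  sa <- extract_sequence(model_a, chain_a)
  sb <- extract_sequence(model_b, chain_b)
  letters_all <- unique(c(strsplit(attr(sa, "sequence"), "")[[1]],
                          strsplit(attr(sb, "sequence"), "")[[1]]))
  sub <- matrix(mismatch, length(letters_all), length(letters_all),
                dimnames = list(letters_all, letters_all))
  diag(sub) <- match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(attr(sa, "sequence")),
    Biostrings::BString(attr(sb, "sequence")),
    type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = gap)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  keep <- pa != "-" & pb != "-"
  pairs <- tibble(ia = ia[keep], ib = ib[keep])
  ca_a <- ca_table(model_a, chain_a)
  ca_b <- ca_table(model_b, chain_b)
  # map sequence index -> CA row (residues missing a CA are dropped)
  res_a <- paste(sa$resno, sa$insert)
  res_b <- paste(sb$resno, sb$insert)
  ra <- match(res_a[pairs$ia], paste(ca_a$resno, ca_a$insert))
  rb <- match(res_b[pairs$ib], paste(ca_b$resno, ca_b$insert))
  ok <- !is.na(ra) & !is.na(rb)
  ra <- ra[ok]; rb <- rb[ok]
  if (length(ra) < 3) {
    abort(sprintf("only %d aligned C-alpha pairs; need at least 3",
                  length(ra)))
  }
  p <- as.matrix(ca_a[ra, c("x", "y", "z")])
  q <- as.matrix(ca_b[rb, c("x", "y", "z")])
  fit <- kabsch(p, q)
  dev <- sqrt(rowSums((apply_rigid(p, fit$rotation, fit$translation) - q)^2))
  dropped <- 0L
  if (reject_outliers) {
    keep2 <- dev <= outlier_factor * fit$rmsd
    if (sum(keep2) >= 3 && any(!keep2)) {
      dropped <- sum(!keep2)
      p <- p[keep2, , drop = FALSE]; q <- q[keep2, , drop = FALSE]
      ra <- ra[keep2]; rb <- rb[keep2]
      fit <- kabsch(p, q)
      dev <- sqrt(rowSums((apply_rigid(p, fit$rotation, fit$translation) -
                             q)^2))
    }
  }
  out <- list(rotation = fit$rotation, translation = fit$translation,
              rmsd = fit$rmsd, n_pairs = length(ra), n_rejected = dropped,
              alignment = tibble(resno_a = ca_a$resno[ra],
                                 resno_b = ca_b$resno[rb],
                                 deviation = dev))
  class(out) <- "aqp_superposition"
  out
}

#' @export
print.aqp_superposition <- function(x, ...) {
  cat(sprintf("<aqp_superposition> %d C-alpha pairs, RMSD %.3f Angstrom\n",
              x$n_pairs, x$rmsd))
  invisible(x)
}

#' @rdname superpose
#' @param x an `aqp_superposition` object.
#' @param ... unused.
#' @export
tidy.aqp_superposition <- function(x, ...) x$alignment

#' @rdname superpose
#' @export
glance.aqp_superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_pairs = x$n_pairs, n_rejected = x$n_rejected)
}
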